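## Transformer-encoder selection model, implemented directly in R with
## hand-written backpropagation (forward caches every intermediate; the
## backward pass is verified against finite differences in the test suite).
## Layout per layer (post-norm encoder): multi-head self-attention with
## key-padding masking -> residual -> LayerNorm -> ReLU feed-forward ->
## residual -> LayerNorm. A per-site scalar linear head emits the wiggle
## pre-activation.

.LN_EPS <- 1e-5

#' @noRd
.sinusoidal_pe <- function(max_len, d) {
  pos <- seq_len(max_len) - 1
  i <- seq_len(d)
  # even columns sin, odd columns cos, shared frequency per pair
  freq <- 1 / 10000^((2 * ((i - 1) %/% 2)) / d)
  ang <- outer(pos, freq)
  pe <- matrix(0, max_len, d)
  odd <- seq(1L, d, by = 2L)
  even <- seq(2L, d, by = 2L)
  pe[, odd] <- sin(ang[, odd, drop = FALSE])
  pe[, even] <- cos(ang[, even, drop = FALSE])
  pe
}

#' @noRd
.build_transformer <- function(config, seed) {
  set.seed(seed)
  d <- config$d_model
  dff <- config$d_ff
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  layer <- function() {
    list(Wq = rmat(d, d), bq = numeric(d),
         Wk = rmat(d, d), bk = numeric(d),
         Wv = rmat(d, d), bv = numeric(d),
         Wo = rmat(d, d), bo = numeric(d),
         ln1_g = rep(1, d), ln1_b = numeric(d),
         W1 = rmat(d, dff), b1 = numeric(dff),
         W2 = rmat(dff, d), b2 = numeric(d),
         ln2_g = rep(1, d), ln2_b = numeric(d))
  }
  params <- list(emb = rmat(config$vocab, d),
                 layers = lapply(seq_len(config$layers), function(i) layer()),
                 head_w = stats::rnorm(d, sd = 0.02),
                 head_b = 0)
  structure(list(params = params, config = config,
                 pe = .sinusoidal_pe(config$max_len, d),
                 beta = config$beta),
            class = c("transformer_model", "selection_model"))
}

#' @export
n_parameters.transformer_model <- function(model) {
  length(.flatten_params(model$params))
}

#' @export
predict_selection.transformer_model <- function(model, aa_seq, ...) {
  tok <- .aa_tokens(aa_seq)
  fw <- .preactivation(model, tok, train = FALSE)
  f <- exp_wiggle(fw$x, model$beta)
  f[tok == .PAD_TOKEN] <- NA_real_
  f
}

#' @noRd
#' affine map with bias folded into one BLAS call
.affine <- function(X, W, b) cbind(X, 1) %*% rbind(W, b)

#' @noRd
#' add a per-feature row vector to every row (column-major rep trick)
.addrow <- function(M, b) M + rep(b, each = nrow(M))

#' @noRd
.mulrow <- function(M, g) M * rep(g, each = nrow(M))

#' @noRd
.rowmax <- function(S) S[cbind(seq_len(nrow(S)), max.col(S, "first"))]

#' @noRd
.layernorm_fwd <- function(R, g, b) {
  mu <- rowMeans(R)
  xc <- R - mu
  sd <- sqrt(rowMeans(xc^2) + .LN_EPS)
  xhat <- xc / sd
  list(Y = .addrow(.mulrow(xhat, g), b), xhat = xhat, sd = sd)
}

#' @noRd
.layernorm_bwd <- function(dY, cache, g) {
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dxhat <- .mulrow(dY, g)
  dR <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) / cache$sd
  list(dR = dR, dg = dg, db = db)
}

#' @export
.preactivation.transformer_model <- function(model, tok, train = FALSE) {
  cfg <- model$config
  L <- length(tok)
  if (L > cfg$max_len) {
    stop("sequence length ", L, " exceeds model maximum ", cfg$max_len)
  }
  p <- model$params
  d <- cfg$d_model
  H <- cfg$heads
  dh <- cfg$d_head
  drop_p <- if (train) cfg$dropout else 0
  kmask <- tok != .PAD_TOKEN
  if (!any(kmask)) {
    # fully ambiguous input: no real site to predict
    return(list(x = rep(0, L), cache = list(tok = tok, empty = TRUE)))
  }
  X <- p$emb[tok, , drop = FALSE] + model$pe[seq_len(L), , drop = FALSE]
  caches <- vector("list", cfg$layers)
  anymask <- !all(kmask)
  for (l in seq_len(cfg$layers)) {
    w <- p$layers[[l]]
    Xin <- X
    QKV <- .affine(X, cbind(w$Wq, w$Wk, w$Wv), c(w$bq, w$bk, w$bv))
    Q <- QKV[, 1:d, drop = FALSE]
    K <- QKV[, (d + 1L):(2L * d), drop = FALSE]
    V <- QKV[, (2L * d + 1L):(3L * d), drop = FALSE]
    Ctx <- matrix(0, L, d)
    A_list <- vector("list", H)
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) /
        sqrt(dh)
      if (anymask) S[, !kmask] <- -Inf
      A <- exp(S - .rowmax(S))
      A <- A / rowSums(A)
      A_list[[h]] <- A
      Ctx[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    O <- .affine(Ctx, w$Wo, w$bo)
    m1 <- NULL
    if (drop_p > 0) {
      m1 <- matrix((stats::runif(L * d) >= drop_p) / (1 - drop_p), L, d)
      O <- O * m1
    }
    ln1 <- .layernorm_fwd(Xin + O, w$ln1_g, w$ln1_b)
    X1 <- ln1$Y
    H1pre <- .affine(X1, w$W1, w$b1)
    H1 <- H1pre * (H1pre > 0)
    FF <- .affine(H1, w$W2, w$b2)
    m2 <- NULL
    if (drop_p > 0) {
      m2 <- matrix((stats::runif(L * d) >= drop_p) / (1 - drop_p), L, d)
      FF <- FF * m2
    }
    ln2 <- .layernorm_fwd(X1 + FF, w$ln2_g, w$ln2_b)
    caches[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, A = A_list, Ctx = Ctx,
                        m1 = m1, ln1 = ln1, X1 = X1, H1 = H1, m2 = m2,
                        ln2 = ln2)
    X <- ln2$Y
  }
  x <- as.numeric(X %*% p$head_w) + p$head_b
  list(x = x, cache = list(tok = tok, Xfinal = X, layers = caches))
}

#' @export
.model_backward.transformer_model <- function(model, cache, dx) {
  cfg <- model$config
  p <- model$params
  d <- cfg$d_model
  H <- cfg$heads
  dh <- cfg$d_head
  tok <- cache$tok
  L <- length(tok)
  if (isTRUE(cache$empty)) {
    return(.zero_grads(p))
  }
  g <- list(emb = matrix(0, cfg$vocab, d),
            layers = vector("list", cfg$layers),
            head_w = numeric(d), head_b = 0)
  dX <- outer(dx, p$head_w)
  g$head_w <- as.numeric(t(cache$Xfinal) %*% dx)
  g$head_b <- sum(dx)
  for (l in rev(seq_len(cfg$layers))) {
    w <- p$layers[[l]]
    cc <- cache$layers[[l]]
    gl <- list()
    bw2 <- .layernorm_bwd(dX, cc$ln2, w$ln2_g)
    gl$ln2_g <- bw2$dg; gl$ln2_b <- bw2$db
    dR2 <- bw2$dR
    dFF <- dR2
    if (!is.null(cc$m2)) dFF <- dFF * cc$m2
    gl$W2 <- crossprod(cc$H1, dFF)
    gl$b2 <- colSums(dFF)
    dH1 <- tcrossprod(dFF, w$W2)
    dH1pre <- dH1 * (cc$H1 > 0)
    gl$W1 <- crossprod(cc$X1, dH1pre)
    gl$b1 <- colSums(dH1pre)
    dX1 <- dR2 + tcrossprod(dH1pre, w$W1)
    bw1 <- .layernorm_bwd(dX1, cc$ln1, w$ln1_g)
    gl$ln1_g <- bw1$dg; gl$ln1_b <- bw1$db
    dR1 <- bw1$dR
    dO <- dR1
    if (!is.null(cc$m1)) dO <- dO * cc$m1
    gl$Wo <- crossprod(cc$Ctx, dO)
    gl$bo <- colSums(dO)
    dCtx <- tcrossprod(dO, w$Wo)
    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$A[[h]]
      dA <- tcrossprod(dCtx[, idx, drop = FALSE], cc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dCtx[, idx, drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- (dS %*% cc$K[, idx, drop = FALSE]) / sqrt(dh)
      dK[, idx] <- crossprod(dS, cc$Q[, idx, drop = FALSE]) / sqrt(dh)
    }
    gl$Wq <- crossprod(cc$Xin, dQ); gl$bq <- colSums(dQ)
    gl$Wk <- crossprod(cc$Xin, dK); gl$bk <- colSums(dK)
    gl$Wv <- crossprod(cc$Xin, dV); gl$bv <- colSums(dV)
    dX <- dR1 + tcrossprod(dQ, w$Wq) + tcrossprod(dK, w$Wk) +
      tcrossprod(dV, w$Wv)
    g$layers[[l]] <- gl[names(w)]
  }
  # embedding gradient: scatter-add rows by token
  for (tt in unique(tok)) {
    rows <- which(tok == tt)
    g$emb[tt, ] <- colSums(dX[rows, , drop = FALSE])
  }
  g
}

## ---- batched passes ----------------------------------------------------------
## Training batches stack same-length sequences into one (B*L) x d matrix so
## that embeddings, projections, feed-forward and LayerNorm run as single
## large matrix operations; only the attention softmax is per (sequence,
## head). Semantics are identical to the per-sequence pass.

#' @noRd
#' tokmat: B x L integer matrix, one sequence per row.
.preactivation_batch <- function(model, tokmat, train = FALSE) {
  cfg <- model$config
  B <- nrow(tokmat)
  L <- ncol(tokmat)
  if (L > cfg$max_len) {
    stop("sequence length ", L, " exceeds model maximum ", cfg$max_len)
  }
  p <- model$params
  d <- cfg$d_model
  H <- cfg$heads
  dh <- cfg$d_head
  N <- B * L
  drop_p <- if (train) cfg$dropout else 0
  tokvec <- as.integer(t(tokmat))
  kmask <- tokvec != .PAD_TOKEN
  rows_of <- function(b) ((b - 1L) * L + 1L):(b * L)
  X <- p$emb[tokvec, , drop = FALSE] +
    model$pe[rep(seq_len(L), B), , drop = FALSE]
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    w <- p$layers[[l]]
    Xin <- X
    QKV <- .affine(X, cbind(w$Wq, w$Wk, w$Wv), c(w$bq, w$bk, w$bv))
    Q <- QKV[, 1:d, drop = FALSE]
    K <- QKV[, (d + 1L):(2L * d), drop = FALSE]
    V <- QKV[, (2L * d + 1L):(3L * d), drop = FALSE]
    Ctx <- matrix(0, N, d)
    A_list <- vector("list", H * B)
    for (b in seq_len(B)) {
      rws <- rows_of(b)
      km <- kmask[rws]
      anymask <- !all(km)
      for (h in seq_len(H)) {
        idx <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rws, idx, drop = FALSE],
                        K[rws, idx, drop = FALSE]) / sqrt(dh)
        if (anymask) S[, !km] <- -Inf
        A <- exp(S - .rowmax(S))
        A <- A / rowSums(A)
        A_list[[(b - 1L) * H + h]] <- A
        Ctx[rws, idx] <- A %*% V[rws, idx, drop = FALSE]
      }
    }
    O <- .affine(Ctx, w$Wo, w$bo)
    m1 <- NULL
    if (drop_p > 0) {
      m1 <- matrix((stats::runif(N * d) >= drop_p) / (1 - drop_p), N, d)
      O <- O * m1
    }
    ln1 <- .layernorm_fwd(Xin + O, w$ln1_g, w$ln1_b)
    X1 <- ln1$Y
    H1pre <- .affine(X1, w$W1, w$b1)
    H1 <- H1pre * (H1pre > 0)
    FF <- .affine(H1, w$W2, w$b2)
    m2 <- NULL
    if (drop_p > 0) {
      m2 <- matrix((stats::runif(N * d) >= drop_p) / (1 - drop_p), N, d)
      FF <- FF * m2
    }
    ln2 <- .layernorm_fwd(X1 + FF, w$ln2_g, w$ln2_b)
    caches[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, A = A_list, Ctx = Ctx,
                        m1 = m1, ln1 = ln1, X1 = X1, H1 = H1, m2 = m2,
                        ln2 = ln2)
    X <- ln2$Y
  }
  x <- as.numeric(X %*% p$head_w) + p$head_b
  # x is stacked sequence-major: matrix(x, L, B) has one sequence per column
  list(x = matrix(x, nrow = L), cache = list(tokvec = tokvec, B = B, L = L,
                                             Xfinal = X, layers = caches))
}

#' @noRd
#' dxmat: L x B matrix of per-site loss gradients (one sequence per column).
.model_backward_batch <- function(model, cache, dxmat) {
  cfg <- model$config
  p <- model$params
  d <- cfg$d_model
  H <- cfg$heads
  dh <- cfg$d_head
  B <- cache$B
  L <- cache$L
  tokvec <- cache$tokvec
  rows_of <- function(b) ((b - 1L) * L + 1L):(b * L)
  dx <- as.numeric(dxmat)
  g <- list(emb = matrix(0, cfg$vocab, d),
            layers = vector("list", cfg$layers),
            head_w = numeric(d), head_b = 0)
  dX <- outer(dx, p$head_w)
  g$head_w <- as.numeric(crossprod(cache$Xfinal, dx))
  g$head_b <- sum(dx)
  for (l in rev(seq_len(cfg$layers))) {
    w <- p$layers[[l]]
    cc <- cache$layers[[l]]
    gl <- list()
    bw2 <- .layernorm_bwd(dX, cc$ln2, w$ln2_g)
    gl$ln2_g <- bw2$dg; gl$ln2_b <- bw2$db
    dR2 <- bw2$dR
    dFF <- dR2
    if (!is.null(cc$m2)) dFF <- dFF * cc$m2
    gl$W2 <- crossprod(cc$H1, dFF)
    gl$b2 <- colSums(dFF)
    dH1pre <- tcrossprod(dFF, w$W2) * (cc$H1 > 0)
    gl$W1 <- crossprod(cc$X1, dH1pre)
    gl$b1 <- colSums(dH1pre)
    dX1 <- dR2 + tcrossprod(dH1pre, w$W1)
    bw1 <- .layernorm_bwd(dX1, cc$ln1, w$ln1_g)
    gl$ln1_g <- bw1$dg; gl$ln1_b <- bw1$db
    dR1 <- bw1$dR
    dO <- dR1
    if (!is.null(cc$m1)) dO <- dO * cc$m1
    gl$Wo <- crossprod(cc$Ctx, dO)
    gl$bo <- colSums(dO)
    dCtx <- tcrossprod(dO, w$Wo)
    dQ <- matrix(0, B * L, d); dK <- matrix(0, B * L, d)
    dV <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rws <- rows_of(b)
      for (h in seq_len(H)) {
        idx <- ((h - 1L) * dh + 1L):(h * dh)
        A <- cc$A[[(b - 1L) * H + h]]
        dA <- tcrossprod(dCtx[rws, idx, drop = FALSE],
                         cc$V[rws, idx, drop = FALSE])
        dV[rws, idx] <- crossprod(A, dCtx[rws, idx, drop = FALSE])
        dS <- A * (dA - rowSums(dA * A))
        dQ[rws, idx] <- (dS %*% cc$K[rws, idx, drop = FALSE]) / sqrt(dh)
        dK[rws, idx] <- crossprod(dS, cc$Q[rws, idx, drop = FALSE]) / sqrt(dh)
      }
    }
    gl$Wq <- crossprod(cc$Xin, dQ); gl$bq <- colSums(dQ)
    gl$Wk <- crossprod(cc$Xin, dK); gl$bk <- colSums(dK)
    gl$Wv <- crossprod(cc$Xin, dV); gl$bv <- colSums(dV)
    dX <- dR1 + tcrossprod(dQ, w$Wq) + tcrossprod(dK, w$Wk) +
      tcrossprod(dV, w$Wv)
    g$layers[[l]] <- gl[names(w)]
  }
  for (tt in unique(tokvec)) {
    g$emb[tt, ] <- colSums(dX[tokvec == tt, , drop = FALSE])
  }
  g
}

#' @noRd
.zero_grads <- function(params) {
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    out <- x
    out[] <- 0
    out
  }
  walk(params)
}

## ---- parameter flattening (for the optimizer) -------------------------------

#' @noRd
.flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

#' @noRd
.unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  fill(skeleton)
}
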