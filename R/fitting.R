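## Mutation-selection composition and model fitting.
##
## The mutation-selection transition probability at codon site j for a
## non-WT codon c is the neutral probability scaled by the site's selection
## factor when c codes a different amino acid, unscaled when c is a
## synonymous codon, and 0 when c is a stop codon; the WT codon receives the
## remainder. Branch lengths are estimated by maximizing the codon-level
## likelihood of these transitions; the selection model itself is trained
## with a binary cross-entropy loss on the per-site indicator of amino-acid
## substitution.

.DEFAULT_CLAMP <- 1 - 1e-6

#' Neutral codon probabilities for a parent sequence
#'
#' Evaluates the per-nucleotide Poisson model at branch length `t`, giving
#' for every codon site the probability of each of the 64 codons. At
#' `t = 0` the parent codon has probability 1 at every site.
#'
#' @param parent in-frame nucleotide sequence.
#' @param provider a neutral provider.
#' @param t nonnegative branch length.
#' @return An object of class `neutral_codon_probs` with matrix `P`
#'   (sites x 64, rows summing to 1; `NA` rows at ambiguous codons).
#' @export
neutral_codon_probs <- function(parent, provider, t) {
  if (t < 0) stop("t must be nonnegative")
  nt <- .check_codon_seq(parent, "parent")
  rates <- neutral_rates(provider, parent)
  P <- .neutral_codon_matrix(nt, rates, t)
  cod <- .codon_indices(nt)
  structure(list(P = P, codon_idx = cod, aa_idx = .aa_indices(cod), t = t),
            class = "neutral_codon_probs")
}

#' Mutation-selection transition probabilities
#'
#' Composes neutral codon probabilities with a selection profile: codons for
#' non-WT amino acids are scaled by `f_j`, synonymous codons are left at
#' their neutral probability (selection factors for synonymous changes are
#' fixed at 1), stop codons are assigned probability 0, and the WT codon
#' receives one minus the sum of the rest. When the scaled aggregate
#' nonsynonymous probability would push the non-WT mass past `clamp`, it is
#' capped there (the nonsynonymous entries are rescaled proportionally) so
#' every site remains a valid distribution.
#'
#' @param neutral a [neutral_codon_probs()].
#' @param profile numeric vector of nonnegative selection factors, one per
#'   codon site (`NA` allowed at masked sites).
#' @param clamp cap, a little less than 1.
#' @return An object of class `mutsel_probs` with matrix `M` (sites x 64),
#'   aggregate nonsynonymous probability `m`, and logical `clamped`.
#' @export
mutsel_probs <- function(neutral, profile, clamp = .DEFAULT_CLAMP) {
  stopifnot(inherits(neutral, "neutral_codon_probs"))
  if (clamp <= 0 || clamp >= 1) stop("clamp must lie in (0, 1)")
  L <- nrow(neutral$P)
  if (length(profile) != L) {
    stop("profile length ", length(profile), " does not match ", L, " sites")
  }
  aa <- neutral$aa_idx
  s <- .site_sums(neutral$P, aa, neutral$codon_idx)
  agg <- .clamped_aggregate(profile, s$ns, s$syn, clamp)
  M <- neutral$P
  ok <- which(!is.na(aa) & !is.na(M[, 1L]))
  if (length(ok)) {
    sc <- matrix(1, length(ok), 64L)
    nsm <- NONSYN_MASK_BY_AA[aa[ok], , drop = FALSE]
    sc[nsm] <- rep(agg$scale[ok], 64L)[which(nsm)]
    sub <- M[ok, , drop = FALSE] * sc
    sub[, is.na(CODON_AA_IDX)] <- 0
    sub[cbind(seq_along(ok), neutral$codon_idx[ok])] <-
      1 - agg$m[ok] - s$syn[ok]
    M[ok, ] <- sub
  }
  structure(list(M = M, m = agg$m, clamped = agg$clamped,
                 codon_idx = neutral$codon_idx, aa_idx = aa),
            class = "mutsel_probs")
}

#' @noRd
#' Per-site neutral sums: ns = nonsynonymous (non-stop) mass, syn =
#' synonymous non-WT mass, both NA at masked sites.
.site_sums <- function(P, aa_idx, codon_idx) {
  L <- nrow(P)
  ns <- rep(NA_real_, L)
  syn <- rep(NA_real_, L)
  ok <- which(!is.na(aa_idx) & !is.na(P[, 1L]))
  if (length(ok)) {
    nsm <- NONSYN_MASK_BY_AA[aa_idx[ok], , drop = FALSE]
    sym <- SYN_MASK_BY_AA[aa_idx[ok], , drop = FALSE]
    Pok <- P[ok, , drop = FALSE]
    ns[ok] <- rowSums(Pok * nsm)
    syn[ok] <- rowSums(Pok * sym) - Pok[cbind(seq_along(ok), codon_idx[ok])]
  }
  list(ns = ns, syn = syn)
}

#' @noRd
#' Clamped aggregate nonsynonymous probability and the implied rescale of
#' per-codon nonsynonymous entries. The cap keeps total non-WT mass at most
#' `clamp` so the WT remainder stays positive.
.clamped_aggregate <- function(f, ns, syn, clamp) {
  raw <- f * ns
  cap <- pmax(clamp - syn, 0)
  clamped <- !is.na(raw) & raw > cap
  m <- ifelse(clamped, cap, raw)
  # effective per-codon multiplier: f when unclamped, m/ns when clamped
  scale <- ifelse(clamped, ifelse(ns > 0, m / ns, 0), f)
  list(m = m, scale = scale, clamped = clamped)
}

## ---- PCP context ------------------------------------------------------------

#' @noRd
#' Precomputed, t-independent context for one PCP. With `kcoef = TRUE`,
#' additionally factors the neutral codon probabilities by mutation pattern:
#' p_{j,c}(t) = contrib[j,c] * w_{S}(t) where S is the subset of the codon's
#' three positions that changed, w_S(t) the product of exp(-lambda_i t) /
#' (1 - exp(-lambda_i t)) terms, and contrib the t-free substitution-bias
#' product. Collapsing codons into the 8 patterns gives per-site coefficient
#' matrices so that the per-site nonsynonymous/synonymous sums cost O(8) per
#' branch-length evaluation instead of O(64).
.pcp_env <- function(parent, child, provider, kcoef = FALSE) {
  nt_p <- .check_codon_seq(parent, "parent")
  nt_c <- .check_codon_seq(child, "child")
  if (length(nt_p) != length(nt_c)) {
    stop("parent and child lengths differ")
  }
  rates <- neutral_rates(provider, parent)
  cod_p <- .codon_indices(nt_p)
  cod_c <- .codon_indices(nt_c)
  aa_p <- .aa_indices(cod_p)
  aa_c <- .aa_indices(cod_c)
  mask <- !is.na(aa_p) & !is.na(aa_c)
  y <- ifelse(mask, as.integer(aa_p != aa_c), NA_integer_)
  aa_chr <- ifelse(is.na(aa_p), NA_character_, AA_ALPHABET[aa_p])
  env <- list(parent = parent, nt = nt_p, rates = rates, cod_p = cod_p,
              cod_c = cod_c, aa_p = aa_p, y = y, mask = mask,
              L = length(cod_p), aa_chr = aa_chr,
              lamL3 = matrix(rates$lambda, ncol = 3L, byrow = TRUE),
              nt_diff = mean(nt_p != nt_c, na.rm = TRUE))
  if (kcoef) env$K <- .build_kcoef(env)
  env
}

#' @noRd
.build_kcoef <- function(env) {
  nt <- env$nt
  L <- env$L
  i1 <- seq.int(1L, 3L * L, by = 3L)
  Qs <- env$rates$sub
  okpos <- which(!is.na(nt))
  Qs[cbind(okpos, nt[okpos])] <- 1  # unchanged position contributes factor 1
  Q1 <- Qs[i1, , drop = FALSE]
  Q2 <- Qs[i1 + 1L, , drop = FALSE]
  Q3 <- Qs[i1 + 2L, , drop = FALSE]
  p1 <- outer(nt[i1], CODON_BASE_IDX[, 1L], "!=")
  p2 <- outer(nt[i1 + 1L], CODON_BASE_IDX[, 2L], "!=")
  p3 <- outer(nt[i1 + 2L], CODON_BASE_IDX[, 3L], "!=")
  sid <- 1L + p1 + 2L * p2 + 4L * p3  # pattern index 1..8, NA at ambiguous
  contrib <- matrix(0, L, 64L)
  for (c in seq_len(64L)) {
    contrib[, c] <- Q1[, CODON_BASE_IDX[c, 1L]] *
      Q2[, CODON_BASE_IDX[c, 2L]] *
      Q3[, CODON_BASE_IDX[c, 3L]]
  }
  okr <- which(!is.na(env$aa_p))
  nsm <- matrix(FALSE, L, 64L)
  nsm[okr, ] <- NONSYN_MASK_BY_AA[env$aa_p[okr], , drop = FALSE]
  sym <- matrix(FALSE, L, 64L)
  sym[okr, ] <- SYN_MASK_BY_AA[env$aa_p[okr], , drop = FALSE]
  sym[cbind(okr, env$cod_p[okr])] <- FALSE
  Kns <- matrix(NA_real_, L, 8L)
  Ksyn <- matrix(NA_real_, L, 8L)
  for (s in seq_len(8L)) {
    sel <- !is.na(sid) & sid == s
    Kns[okr, s] <- rowSums((contrib * (sel & nsm))[okr, , drop = FALSE])
    Ksyn[okr, s] <- rowSums((contrib * (sel & sym))[okr, , drop = FALSE])
  }
  changed <- which(env$mask & env$cod_c != env$cod_p)
  list(Kns = Kns, Ksyn = Ksyn, changed = changed,
       sid_child = sid[cbind(changed, env$cod_c[changed])],
       sprod_child = contrib[cbind(changed, env$cod_c[changed])],
       nonsyn_child = env$aa_p[changed] != .aa_indices(env$cod_c[changed]))
}

#' @noRd
#' Pattern weights w_S(t) for the 8 change patterns of a codon: product of
#' exp(-lambda t) over unchanged and (1 - exp(-lambda t)) over changed
#' positions, per site.
.pattern_weights <- function(env, t) {
  A <- exp(-env$lamL3 * t)
  a1 <- A[, 1L]; a2 <- A[, 2L]; a3 <- A[, 3L]
  b1 <- 1 - a1; b2 <- 1 - a2; b3 <- 1 - a3
  cbind(a1 * a2 * a3, b1 * a2 * a3, a1 * b2 * a3, b1 * b2 * a3,
        a1 * a2 * b3, b1 * a2 * b3, a1 * b2 * b3, b1 * b2 * b3)
}

#' @noRd
#' Per-site neutral sums at branch length t via the pattern factorization.
.site_sums_fast <- function(env, t) {
  W <- .pattern_weights(env, t)
  list(ns = rowSums(env$K$Kns * W), syn = rowSums(env$K$Ksyn * W), W = W)
}

#' @noRd
#' Codon-level negative log-likelihood of the observed child codons given
#' selection profile f at branch length t (used for branch-length
#' optimization, where synonymous substitutions anchor t).
.codon_nll <- function(env, f, t, clamp = .DEFAULT_CLAMP) {
  s <- .site_sums_fast(env, t)
  agg <- .clamped_aggregate(f, s$ns, s$syn, clamp)
  K <- env$K
  same <- setdiff(which(env$mask & !is.na(s$ns)), K$changed)
  ll <- sum(log(pmax(1 - agg$m[same] - s$syn[same], .PROB_FLOOR)))
  if (length(K$changed)) {
    pch <- K$sprod_child * s$W[cbind(K$changed, K$sid_child)] *
      ifelse(K$nonsyn_child, agg$scale[K$changed], 1)
    ll <- ll + sum(log(pmax(pch, .PROB_FLOOR)))
  }
  -ll
}

## ---- losses -----------------------------------------------------------------

#' Binary cross-entropy loss for one PCP
#'
#' The negative log-likelihood of the per-site indicators of amino-acid
#' substitution between parent and child under the mutation-selection model:
#' `-sum_j [ y_j log m_j + (1 - y_j) log(1 - m_j) ]`, with sites containing
#' ambiguous codons excluded. A site with `m_j = 0` but an observed
#' substitution yields an infinite loss (surfaced, not clipped).
#'
#' @param pcp a single-row [pcp_table] or a list with `parent` and `child`.
#' @param model a selection model.
#' @param provider a neutral provider.
#' @param t nonnegative branch length.
#' @param clamp aggregate-probability cap.
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
pcp_loss <- function(pcp, model, provider, t, clamp = .DEFAULT_CLAMP) {
  if (t < 0) stop("t must be nonnegative")
  env <- .pcp_env(pcp$parent[[1L]], pcp$child[[1L]], provider, kcoef = TRUE)
  f <- predict_selection(model, env$aa_chr)
  .bce_loss(env, f, t, clamp)
}

#' @noRd
.bce_loss <- function(env, f, t, clamp) {
  s <- .site_sums_fast(env, t)
  agg <- .clamped_aggregate(f, s$ns, s$syn, clamp)
  .bce_terms(agg$m, env$y, env$mask)
}

#' @noRd
.bce_terms <- function(m, y, mask) {
  ok <- mask & !is.na(m)
  m <- m[ok]
  y <- y[ok]
  term <- numeric(length(m))
  pos <- y == 1L
  term[pos] <- -log(m[pos])
  term[!pos] <- -log1p(-m[!pos])
  sum(term)
}

## ---- branch-length optimization ----------------------------------------------

#' Optimize the branch length of one PCP
#'
#' Maximizes the codon-level likelihood of the observed parent-to-child
#' transitions over `t` with the selection profile held fixed, by Brent
#' search on log t over a bounded interval. Branch lengths from upstream
#' phylogenetic tree inference are ignored. A PCP with no substitutions at
#' all is pinned at the lower bound (attribute `pinned`).
#'
#' @inheritParams pcp_loss
#' @param lower,upper search bounds on t.
#' @param tol convergence tolerance on log t.
#' @return Optimized branch length `t*`, with attribute `pinned` when no
#'   substitution signal was present.
#' @export
optimize_branch_length <- function(pcp, model, provider,
                                   lower = 1e-6, upper = 5, tol = 1e-8,
                                   clamp = .DEFAULT_CLAMP) {
  env <- .pcp_env(pcp$parent[[1L]], pcp$child[[1L]], provider, kcoef = TRUE)
  f <- predict_selection(model, env$aa_chr)
  .optimize_t(env, f, lower, upper, tol, clamp)
}

#' @noRd
.optimize_t <- function(env, f, lower = 1e-6, upper = 5, tol = 1e-8,
                        clamp = .DEFAULT_CLAMP) {
  if (identical(env$cod_p, env$cod_c)) {
    return(structure(lower, pinned = TRUE))
  }
  opt <- stats::optimize(function(lt) .codon_nll(env, f, exp(lt), clamp),
                         interval = log(c(lower, upper)), tol = tol)
  structure(exp(opt$minimum), pinned = FALSE)
}

## ---- training ---------------------------------------------------------------

#' Fit a selection model to PCP data
#'
#' Alternates, for `cycles` rounds, (1) per-PCP branch-length optimization
#' under the current model, after which the per-site neutral nonsynonymous
#' sums are recomputed and cached, and (2) selection-model training by
#' RMSprop on the binary cross-entropy loss. With `cycles = 0` the model is
#' returned untouched with branch lengths from a single optimization round.
#'
#' @param pcps a [pcp_table] (already filtered: no naive edges, no identical
#'   pairs).
#' @param model initial selection model.
#' @param provider neutral provider.
#' @param cycles number of alternation cycles (default 4).
#' @param epochs gradient epochs per cycle.
#' @param batch_size PCPs per gradient step.
#' @param lr RMSprop learning rate.
#' @param rms_alpha,rms_eps RMSprop smoothing constant and stabilizer.
#' @param clip global gradient-norm clip.
#' @param val_frac fraction of PCPs held out for validation loss.
#' @param seed master seed (initial shuffling, dropout).
#' @param clamp aggregate-probability cap.
#' @param t_bounds branch-length search interval.
#' @param verbose print per-epoch losses.
#' @return A `train_state`: the fitted model, per-PCP branch lengths, the
#'   loss trace (per-site mean BCE), and a clamp-event counter.
#' @export
fit <- function(pcps, model, provider, cycles = 4L, epochs = 2L,
                batch_size = 32L, lr = 1e-3, rms_alpha = 0.99,
                rms_eps = 1e-8, clip = 1, val_frac = 0.1, seed = 1L,
                clamp = .DEFAULT_CLAMP, t_bounds = c(1e-6, 5),
                verbose = FALSE) {
  if (nrow(pcps) == 0L) stop("empty training set")
  set.seed(seed)
  envs <- lapply(seq_len(nrow(pcps)),
                 function(i) .pcp_env(pcps$parent[i], pcps$child[i], provider,
                                      kcoef = TRUE))
  n <- length(envs)
  n_val <- floor(val_frac * n)
  val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (!length(train_idx)) stop("no training PCPs after validation split")

  # group PCPs by parent so each unique parent gets one forward/backward pass
  parent_key <- vapply(envs, `[[`, "", "parent")
  mean_lambda <- mean(vapply(envs, function(e) mean(e$rates$lambda), 0))
  tvec <- pmin(pmax(vapply(envs, `[[`, 0, "nt_diff") /
                      max(mean_lambda, 1e-12), t_bounds[1L]), t_bounds[2L])

  skeleton <- model$params
  v <- .flatten_params(.zero_grads(skeleton))
  trace <- list()
  clamp_events <- 0L
  pns <- vector("list", n)

  parent_groups <- split(seq_len(n), parent_key)
  seq_lens <- vapply(envs, `[[`, 0L, "L")
  batched <- inherits(model, "transformer_model") &&
    length(unique(seq_lens)) == 1L
  tok_of <- function(i) .aa_tokens(envs[[i]]$aa_chr)

  # evaluation-mode selection profiles for a set of representative PCPs,
  # batched through the encoder where possible
  eval_profiles <- function(reps) {
    prof <- vector("list", length(reps))
    if (batched) {
      chunks <- split(seq_along(reps), ceiling(seq_along(reps) / 64))
      for (ch in chunks) {
        tokmat <- do.call(rbind, lapply(reps[ch], tok_of))
        xs <- .preactivation_batch(model, tokmat, train = FALSE)$x
        for (k in seq_along(ch)) {
          f <- exp_wiggle(xs[, k], model$beta)
          f[tokmat[k, ] == .PAD_TOKEN] <- NA_real_
          prof[[ch[k]]] <- f
        }
      }
    } else {
      for (k in seq_along(reps)) {
        prof[[k]] <- predict_selection(model, envs[[reps[k]]]$aa_chr)
      }
    }
    prof
  }

  refresh_profiles <- function() {
    reps <- vapply(parent_groups, `[[`, 0L, 1L)
    prof <- eval_profiles(reps)
    names(prof) <- names(parent_groups)
    prof
  }

  optimize_all <- function(profiles) {
    for (i in seq_len(n)) {
      tvec[i] <<- as.numeric(.optimize_t(envs[[i]], profiles[[parent_key[i]]],
                                         t_bounds[1L], t_bounds[2L],
                                         1e-8, clamp))
    }
    # recompute and cache the neutral nonsynonymous sums at the new t's
    for (i in seq_len(n)) {
      s <- .site_sums_fast(envs[[i]], tvec[i])
      pns[[i]] <<- list(ns = s$ns, syn = s$syn)
    }
  }

  dataset_loss <- function(idx) {
    if (!length(idx)) return(NA_real_)
    inset <- logical(n)
    inset[idx] <- TRUE
    gkeep <- Filter(function(g) any(inset[g]), parent_groups)
    prof <- eval_profiles(vapply(gkeep, `[[`, 0L, 1L))
    tot <- 0
    nsite <- 0L
    for (k in seq_along(gkeep)) {
      members <- gkeep[[k]]
      members <- members[inset[members]]
      f <- prof[[k]]
      for (i in members) {
        e <- envs[[i]]
        agg <- .clamped_aggregate(f, pns[[i]]$ns, pns[[i]]$syn, clamp)
        tot <- tot + .bce_terms(agg$m, e$y, e$mask)
        nsite <- nsite + sum(e$mask & !is.na(agg$m))
      }
    }
    tot / nsite
  }

  if (cycles == 0L) {
    optimize_all(refresh_profiles())
    trace[[1L]] <- data.frame(cycle = 0L, epoch = 0L,
                              train = dataset_loss(train_idx),
                              val = dataset_loss(val_idx))
    return(structure(list(model = model, branch_lengths = tvec,
                          trace = do.call(rbind, trace),
                          clamp_events = clamp_events, val_idx = val_idx),
                     class = "train_state"))
  }

  for (cycle in seq_len(cycles)) {
    optimize_all(refresh_profiles())
    for (epoch in seq_len(epochs)) {
      order <- sample(train_idx)
      batches <- split(order, ceiling(seq_along(order) / batch_size))
      run_loss <- 0
      run_sites <- 0L
      for (bt in batches) {
        nsite_batch <- 0L
        ups <- unique(parent_key[bt])
        reps <- bt[match(ups, parent_key[bt])]
        # per-PCP gradient of the mean BCE w.r.t. the pre-activations of its
        # (shared) parent, accumulated per unique parent in the batch
        site_grad <- function(fx, dfx, members) {
          dx <- numeric(length(fx))
          for (i in members) {
            ei <- envs[[i]]
            agg <- .clamped_aggregate(fx, pns[[i]]$ns, pns[[i]]$syn, clamp)
            m <- agg$m
            usable <- ei$mask & !is.na(m) & m > 0 & m < 1 & !agg$clamped
            clamp_events <<- clamp_events + sum(agg$clamped, na.rm = TRUE)
            dm <- numeric(ei$L)
            dm[usable] <- (m[usable] - ei$y[usable]) /
              (m[usable] * (1 - m[usable]))
            dx <- dx + ifelse(usable, dm * pns[[i]]$ns * dfx, 0)
            nsite_batch <<- nsite_batch + sum(ei$mask & !is.na(m))
            run_loss <<- run_loss + .bce_terms(m, ei$y, ei$mask)
          }
          dx
        }
        if (batched) {
          tokmat <- do.call(rbind, lapply(reps, tok_of))
          fw <- .preactivation_batch(model, tokmat, train = TRUE)
          dxmat <- matrix(0, ncol(tokmat), length(ups))
          for (k in seq_along(ups)) {
            x <- fw$x[, k]
            dxmat[, k] <- site_grad(exp_wiggle(x, model$beta),
                                    .d_exp_wiggle(x, model$beta),
                                    bt[parent_key[bt] == ups[k]])
          }
          gacc <- .flatten_params(.model_backward_batch(model, fw$cache,
                                                        dxmat))
        } else {
          gacc <- NULL
          for (k in seq_along(ups)) {
            e <- envs[[reps[k]]]
            fw <- .preactivation(model, tok_of(reps[k]), train = TRUE)
            dx <- site_grad(exp_wiggle(fw$x, model$beta),
                            .d_exp_wiggle(fw$x, model$beta),
                            bt[parent_key[bt] == ups[k]])
            g <- .flatten_params(.model_backward(model, fw$cache, dx))
            gacc <- if (is.null(gacc)) g else gacc + g
          }
        }
        if (any(!is.finite(gacc))) {
          stop("divergent gradient (NaN/Inf) at cycle ", cycle,
               ", epoch ", epoch)
        }
        run_sites <- run_sites + nsite_batch
        gacc <- gacc / max(nsite_batch, 1L)
        gn <- sqrt(sum(gacc^2))
        if (gn > clip) gacc <- gacc * (clip / gn)
        v <- rms_alpha * v + (1 - rms_alpha) * gacc^2
        theta <- .flatten_params(model$params) -
          lr * gacc / (sqrt(v) + rms_eps)
        model$params <- .unflatten_params(theta, skeleton)
      }
      # train loss is the running per-site average over the epoch's batches
      # (each batch evaluated under the then-current parameters)
      tr <- run_loss / max(run_sites, 1L)
      vl <- dataset_loss(val_idx)
      if (!is.finite(tr)) {
        stop("divergent loss at cycle ", cycle, ", epoch ", epoch,
             " (train loss = ", tr, ")")
      }
      trace[[length(trace) + 1L]] <- data.frame(cycle = cycle, epoch = epoch,
                                                train = tr, val = vl)
      if (verbose) {
        message(sprintf("cycle %d epoch %d train %.6f val %.6f",
                        cycle, epoch, tr, vl))
      }
    }
  }
  structure(list(model = model, branch_lengths = tvec,
                 trace = do.call(rbind, trace),
                 clamp_events = clamp_events, val_idx = val_idx),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat("train_state:", length(x$branch_lengths), "PCPs,",
      nrow(x$trace), "logged epochs; final train loss",
      format(utils::tail(x$trace$train, 1), digits = 6), "\n")
  invisible(x)
}
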