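## Goodness-of-fit and model-comparison metrics: observed-vs-expected
## per-site substitution aggregation, the histogram-overlap statistic,
## log-selection-factor R-squared against the y = x line, and weighted
## Shannon entropy of per-site amino-acid usage.

#' Observed vs expected substitutions per aligned site
#'
#' For every PCP, computes the model's per-site probability of amino-acid
#' substitution `m_j` and the observed substitution indicator, then totals
#' both per aligned position (optionally within groups such as V-gene
#' families). The expected count at a position is the sum of the `m_j` over
#' contributing PCP sites; its standard deviation is
#' `sqrt(sum m_j (1 - m_j))` (an independent-Bernoulli sum).
#'
#' @param pcps a [pcp_table]; every row must have a branch length.
#' @param model selection model.
#' @param provider neutral provider.
#' @param site_map optional data.frame with columns `clone_id`, `site`
#'   (1-based codon site) and `position` (aligned position, e.g. IMGT);
#'   sites not covered by the map are dropped (count reported in attribute
#'   `n_unmapped`). `NULL` means the identity mapping.
#' @param group optional character vector, one group label per PCP.
#' @param clamp aggregate-probability cap.
#' @return data.frame with columns `group`, `position`, `observed`,
#'   `expected`, `sd`.
#' @export
site_obs_exp <- function(pcps, model, provider, site_map = NULL,
                         group = NULL, clamp = .DEFAULT_CLAMP) {
  if (anyNA(pcps$branch_length)) {
    stop("PCP without branch length at row ",
         which(is.na(pcps$branch_length))[1L])
  }
  if (is.null(group)) group <- rep("all", nrow(pcps))
  stopifnot(length(group) == nrow(pcps))
  glevels <- unique(group)
  # per-group accumulators indexed by aligned position, grown on demand
  acc <- lapply(glevels, function(g) list(obs = numeric(0), expd = numeric(0),
                                          varr = numeric(0), seen = logical(0)))
  names(acc) <- glevels
  n_unmapped <- 0L
  prof_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pcps))) {
    env <- .pcp_env(pcps$parent[i], pcps$child[i], provider)
    key <- pcps$parent[i]
    f <- if (exists(key, prof_cache, inherits = FALSE)) get(key, prof_cache)
    else {
      ff <- predict_selection(model, env$aa_chr)
      assign(key, ff, prof_cache)
      ff
    }
    P <- .neutral_codon_matrix(env$nt, env$rates, pcps$branch_length[i])
    s <- .site_sums(P, env$aa_p, env$cod_p)
    agg <- .clamped_aggregate(f, s$ns, s$syn, clamp)
    ok <- which(env$mask & !is.na(agg$m))
    pos <- ok
    if (!is.null(site_map)) {
      sm <- site_map[site_map$clone_id == pcps$clone_id[i], , drop = FALSE]
      pos <- sm$position[match(ok, sm$site)]
      drop <- is.na(pos)
      n_unmapped <- n_unmapped + sum(drop)
      ok <- ok[!drop]
      pos <- pos[!drop]
    }
    if (!length(ok)) next
    g <- group[i]
    a <- acc[[g]]
    mx <- max(pos)
    if (mx > length(a$obs)) {
      extra <- mx - length(a$obs)
      a$obs <- c(a$obs, numeric(extra))
      a$expd <- c(a$expd, numeric(extra))
      a$varr <- c(a$varr, numeric(extra))
      a$seen <- c(a$seen, logical(extra))
    }
    m <- agg$m[ok]
    a$obs[pos] <- a$obs[pos] + env$y[ok]
    a$expd[pos] <- a$expd[pos] + m
    a$varr[pos] <- a$varr[pos] + m * (1 - m)
    a$seen[pos] <- TRUE
    acc[[g]] <- a
  }
  out <- do.call(rbind, lapply(glevels, function(g) {
    a <- acc[[g]]
    keep <- which(a$seen)
    data.frame(group = g, position = keep, observed = a$obs[keep],
               expected = a$expd[keep], sd = sqrt(a$varr[keep]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Histogram overlap
#'
#' The size of the intersection of two nonnegative histograms divided by the
#' average of their areas: `sum(pmin(o, e)) / (0.5 * (sum(o) + sum(e)))`.
#' Equals 1 for identical histograms and 0 for disjoint support.
#'
#' @param observed,expected nonnegative numeric vectors of equal length
#'   (one bin per aligned site).
#' @return Scalar in `[0, 1]`.
#' @export
overlap <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must have equal length")
  }
  if (any(observed < 0) || any(expected < 0)) {
    stop("histograms must be nonnegative")
  }
  tot <- sum(observed) + sum(expected)
  if (tot == 0) stop("overlap undefined: both histograms are all-zero")
  sum(pmin(observed, expected)) / (tot / 2)
}

#' Log-selection-factor agreement with the identity line
#'
#' Pools the log selection factors predicted by two models over every site
#' of every panel sequence and measures agreement against perfect identity
#' (the y = x line), not against a refitted regression:
#' `1 - sum((a - b)^2) / sum((a - g)^2 + (b - g)^2)` with `g` the grand mean
#' of the pooled logs. Symmetric in the two models; 1 when they agree
#' exactly. Sites where either factor is 0 (log undefined) or masked are
#' excluded, with the count in attribute `n_excluded`.
#'
#' @param model_a,model_b selection models.
#' @param panel character vector of amino-acid sequences.
#' @return Scalar `<= 1` with attribute `n_excluded`.
#' @export
log_factor_r2 <- function(model_a, model_b, panel) {
  a <- numeric(0)
  b <- numeric(0)
  n_excluded <- 0L
  for (seq in panel) {
    fa <- predict_selection(model_a, seq)
    fb <- predict_selection(model_b, seq)
    ok <- !is.na(fa) & !is.na(fb) & fa > 0 & fb > 0
    n_excluded <- n_excluded + sum(!ok)
    a <- c(a, log(fa[ok]))
    b <- c(b, log(fb[ok]))
  }
  if (!length(a)) stop("no usable sites in panel")
  g <- mean(c(a, b))
  ss_res <- sum((a - b)^2)
  ss_tot <- sum((a - g)^2 + (b - g)^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res == 0) 1 else -Inf
  } else {
    1 - ss_res / ss_tot
  }
  structure(r2, n_excluded = n_excluded)
}

#' Weighted Shannon entropy of per-site amino-acid usage
#'
#' Entropy (log base 2) of the weighted frequency distribution at each site.
#' Weights multiply the counts column-wise (e.g. presence weights for each
#' amino acid); the default weight is 1.
#'
#' @param aa_counts numeric matrix (sites x amino acids) of nonnegative
#'   counts, or a single site's count vector.
#' @param weights optional nonnegative weights, recycled across the count
#'   columns.
#' @return Per-site entropy in bits; `NA` for all-zero sites.
#' @export
weighted_entropy <- function(aa_counts, weights = NULL) {
  if (is.null(dim(aa_counts))) aa_counts <- matrix(aa_counts, nrow = 1L)
  if (any(aa_counts < 0)) stop("counts must be nonnegative")
  if (!is.null(weights)) {
    aa_counts <- sweep(aa_counts, 2L, weights, `*`)
  }
  apply(aa_counts, 1L, function(cnt) {
    tot <- sum(cnt)
    if (tot == 0) return(NA_real_)
    p <- cnt[cnt > 0] / tot
    -sum(p * log2(p))
  })
}
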