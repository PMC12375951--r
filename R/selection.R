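## Selection-factor models: map an amino-acid sequence to one nonnegative
## factor per codon site that scales the neutral probability of
## nonsynonymous substitution (>1 diversifying, <1 purifying, 0 strongest
## possible purifying selection).

## Amino acids treated as hydrophobic by the context-rule ground-truth family
## (positive Kyte-Doolittle hydropathy).
HYDROPHOBIC_AA <- c("A", "C", "F", "I", "L", "M", "V")

#' Wiggle output activation
#'
#' Squashes an unconstrained model output into a positive selection factor
#' with sub-linear growth above 1: `exp_wiggle(x, beta)` equals
#' `exp(beta * (x - 1))` for `x < 1` and `x^beta` for `x >= 1`. It is
#' continuous and strictly increasing, equals 1 at `x = 1`, and its log is
#' `wiggle()`. The operating default is `beta = 0.3`.
#'
#' @param x numeric vector of pre-activations.
#' @param beta positive shape parameter.
#' @return `wiggle`: the log selection factor; `exp_wiggle`: the selection
#'   factor itself.
#' @export
wiggle <- function(x, beta = 0.3) {
  if (beta <= 0) stop("beta must be positive")
  ifelse(x < 1, beta * (x - 1), beta * log(x))
}

#' @rdname wiggle
#' @export
exp_wiggle <- function(x, beta = 0.3) {
  if (beta <= 0) stop("beta must be positive")
  ifelse(x < 1, exp(beta * (x - 1)), x^beta)
}

#' @noRd
#' derivative of exp_wiggle w.r.t. x (continuous at x = 1)
.d_exp_wiggle <- function(x, beta) {
  ifelse(x < 1, beta * exp(beta * (x - 1)), beta * x^(beta - 1))
}

#' @noRd
#' pre-activation giving a requested factor value
.inv_exp_wiggle <- function(f, beta) {
  ifelse(f < 1, 1 + log(f) / beta, f^(1 / beta))
}

## ---- tokenization -----------------------------------------------------------

.PAD_TOKEN <- 21L

#' @noRd
#' Amino-acid sequence -> integer tokens 1..20; ambiguous (X or NA) -> PAD
#' token 21, masked out of predictions and loss. Unknown symbols error.
.aa_tokens <- function(aa) {
  if (is.character(aa) && length(aa) == 1L && nchar(aa) > 1L) {
    aa <- strsplit(aa, "")[[1]]
  }
  tok <- match(aa, AA_ALPHABET)
  amb <- is.na(aa) | aa == "X"
  bad <- is.na(tok) & !amb
  if (any(bad)) {
    stop("unknown amino-acid symbol(s): ",
         paste(unique(aa[bad]), collapse = ", "))
  }
  tok[amb] <- .PAD_TOKEN
  tok
}

## ---- model configuration ----------------------------------------------------

#' Selection-model configuration
#'
#' @param family `"single_factor"`, `"per_position"`, or `"transformer"`.
#' @param heads,d_head,layers transformer shape; the embedding width is
#'   `heads * d_head`.
#' @param ff_mult feed-forward width as a multiple of the embedding width.
#' @param dropout dropout rate used during training (disabled at evaluation).
#' @param max_len maximum sequence length (amino acids).
#' @param beta wiggle shape parameter (fixed, not trained).
#' @return A `selection_model_config` list.
#' @export
selection_model_config <- function(family = c("transformer", "single_factor",
                                              "per_position"),
                                   heads = 8L, d_head = 16L, layers = 5L,
                                   ff_mult = 4L, dropout = 0.1,
                                   max_len = 512L, beta = 0.3) {
  family <- match.arg(family)
  if (beta <= 0) stop("beta must be positive")
  if (family == "transformer") {
    stopifnot(heads >= 1L, d_head >= 1L, layers >= 1L, ff_mult >= 1L,
              dropout >= 0, dropout < 1)
  }
  structure(list(family = family, heads = as.integer(heads),
                 d_head = as.integer(d_head), layers = as.integer(layers),
                 d_model = as.integer(heads * d_head),
                 d_ff = as.integer(ff_mult * heads * d_head),
                 ff_mult = as.integer(ff_mult),
                 dropout = dropout, max_len = as.integer(max_len),
                 beta = beta, vocab = .PAD_TOKEN),
            class = "selection_model_config")
}

#' Build a selection model
#'
#' Constructs a selection model from a configuration with seeded, reproducible
#' initialization. The transformer family is a shared amino-acid embedding,
#' fixed sinusoidal positional encoding, a transformer-encoder stack, and a
#' per-site scalar linear head whose output passes through [exp_wiggle()].
#'
#' @param config a [selection_model_config()].
#' @param seed integer seed for parameter initialization.
#' @return A selection model object.
#' @export
build_selection_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "selection_model_config"))
  switch(config$family,
         single_factor = single_factor_model(beta = config$beta),
         per_position = per_position_model(max_len = config$max_len,
                                           beta = config$beta),
         transformer = .build_transformer(config, seed))
}

#' Constant (repertoire-wide) selection baseline
#'
#' A single trainable selection factor shared by every site of every
#' sequence: the model analogous to repertoire-wide selection analyses in
#' which all sequences are assumed to be under the same pressure.
#'
#' @param factor initial selection factor.
#' @param beta wiggle shape.
#' @return A `single_factor_model`.
#' @export
single_factor_model <- function(factor = 1, beta = 0.3) {
  structure(list(params = list(theta = .inv_exp_wiggle(factor, beta)),
                 beta = beta),
            class = c("single_factor_model", "selection_model"))
}

#' Per-position selection baseline
#'
#' One trainable factor per alignment position, independent of sequence
#' content.
#'
#' @param max_len maximum sequence length.
#' @param factor initial factor at every position.
#' @param beta wiggle shape.
#' @return A `per_position_model`.
#' @export
per_position_model <- function(max_len = 512L, factor = 1, beta = 0.3) {
  structure(list(params = list(theta = rep(.inv_exp_wiggle(factor, beta),
                                           max_len)),
                 max_len = as.integer(max_len), beta = beta),
            class = c("per_position_model", "selection_model"))
}

#' Predict per-site selection factors
#'
#' @param model a selection model (trainable or analytic ground truth).
#' @param aa_seq amino-acid sequence: a single string or a character vector
#'   of one-letter symbols. `X`/`NA` marks an ambiguous site, returned as
#'   `NA` in the profile.
#' @param ... passed to methods.
#' @return Numeric vector of nonnegative factors, one per site.
#' @export
predict_selection <- function(model, aa_seq, ...) UseMethod("predict_selection")

#' @export
predict_selection.single_factor_model <- function(model, aa_seq, ...) {
  tok <- .aa_tokens(aa_seq)
  f <- rep(exp_wiggle(model$params$theta, model$beta), length(tok))
  f[tok == .PAD_TOKEN] <- NA_real_
  f
}

#' @export
predict_selection.per_position_model <- function(model, aa_seq, ...) {
  tok <- .aa_tokens(aa_seq)
  if (length(tok) > model$max_len) {
    stop("sequence length ", length(tok), " exceeds model maximum ",
         model$max_len)
  }
  f <- exp_wiggle(model$params$theta[seq_along(tok)], model$beta)
  f[tok == .PAD_TOKEN] <- NA_real_
  f
}

#' Number of trainable parameters
#'
#' @param model a selection model.
#' @return Integer count of trainable scalars.
#' @export
n_parameters <- function(model) UseMethod("n_parameters")

#' @export
n_parameters.single_factor_model <- function(model) 1L

#' @export
n_parameters.per_position_model <- function(model) length(model$params$theta)

## Internal training interface implemented by every trainable model:
## .preactivation(model, tok, train) -> list(x = numeric, cache = ...)
## .model_backward(model, cache, dx)  -> gradient list shaped like $params
.preactivation <- function(model, tok, train = FALSE) {
  UseMethod(".preactivation")
}

.model_backward <- function(model, cache, dx) UseMethod(".model_backward")

#' @export
.preactivation.single_factor_model <- function(model, tok, train = FALSE) {
  list(x = rep(model$params$theta, length(tok)), cache = length(tok))
}

#' @export
.model_backward.single_factor_model <- function(model, cache, dx) {
  list(theta = sum(dx))
}

#' @export
.preactivation.per_position_model <- function(model, tok, train = FALSE) {
  list(x = model$params$theta[seq_along(tok)], cache = length(tok))
}

#' @export
.model_backward.per_position_model <- function(model, cache, dx) {
  g <- numeric(length(model$params$theta))
  g[seq_along(dx)] <- dx
  list(theta = g)
}
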