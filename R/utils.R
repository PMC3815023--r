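#' Mean of the three quartiles
#'
#' The summary used throughout the package for pathway scores, pair-correlation
#' summaries and tissue-variance summaries: `(Q1 + Q2 + Q3) / 3`. Quartiles use
#' linear interpolation between order statistics (R's default, `type = 7`); the
#' convention is exposed as an argument and recorded in run manifests.
#'
#' @param x Numeric vector with at least one finite value.
#' @param quartile_type Quantile algorithm passed to [stats::quantile()].
#' @return A single number.
#' @examples
#' quartile_mean(1:5) # (2 + 3 + 4) / 3 = 3
#' @export
quartile_mean <- function(x, quartile_type = 7) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) {
    abort("`x` must contain at least one finite value.")
  }
  mean(quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = quartile_type))
}

# Fast path for the default convention (type 7), used inside permutation loops.
quartile_mean7 <- function(x) {
  s <- sort.int(x, method = "quick")
  n <- length(s)
  if (n == 1L) {
    return(s)
  }
  h <- (n - 1) * c(0.25, 0.5, 0.75) + 1
  lo <- floor(h)
  hi <- pmin(lo + 1L, n)
  mean(s[lo] + (h - lo) * (s[hi] - s[lo]))
}

#' Derive per-stage random seeds from one global seed
#'
#' Each generator and permutation stage draws its own substream seed from the
#' single run seed, so stages are individually reproducible.
#'
#' @param seed Integer scalar.
#' @return Named integer vector with elements `genome`, `ontology`, `genesets`,
#'   `expression`, `background`, `permutation`.
#' @export
dpg_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  stages <- c("genome", "ontology", "genesets", "expression", "background",
              "permutation")
  # affine substreams kept inside 32-bit signed integer range
  vals <- (abs(seed) %% 1000003L) * 1009L + seq_along(stages) * 7919L
  setNames(as.integer(vals %% .Machine$integer.max), stages)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
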