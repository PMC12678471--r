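#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile median rnorm runif rlnorm glm binomial coef
#'   predict qbeta wilcox.test chisq.test sd setNames
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used when formatting percentages: exact halves round
#' away from zero (0.05 -> 0.1), unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Format a proportion as a percentage to one decimal
#'
#' @param p proportion in \[0,1\].
#' @param digits decimal places (default 1).
#' @return numeric percentage rounded half away from zero.
#' @export
as_pct <- function(p, digits = 1) round_half_away(100 * p, digits)

# Derive a 31-bit stream seed from a master seed and an index, so that
# per-patient (or per-view) draws are reproducible independently of how many
# other patients were generated. Plain LCG mixing; collisions are irrelevant
# at cohort scale.
derive_seed <- function(master, index, salt = 0L) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 + as.double(index) * 16807 +
    as.double(salt) * 69621
  as.integer(s %% (m - 1)) + 1L
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_badx <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "badx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_badx <- function(msg, class, ...) {
  warning(structure(
    class = c(class, "badx_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
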