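# Shared numerical helpers. Seeded code paths use withr::with_seed so that
# generators are deterministic without clobbering the caller's RNG stream.

#' Draw from a normal distribution truncated to an interval
#'
#' Inverse-CDF sampling: uniform draws on `[Phi(lower), Phi(upper)]` are pushed
#' through `qnorm`. Every draw lies strictly inside `[lower, upper]`.
#'
#' @param n number of draws.
#' @param mean,sd parameters of the parent (untruncated) normal; `sd > 0`.
#' @param lower,upper truncation bounds, `lower < upper`.
#' @return numeric vector of length `n`.
#' @examples
#' x <- rtruncnorm(100, 6.3, 1.9, 2.6, 13.8)
#' range(x)
#' @export
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < .Machine$double.eps)
    stop("truncation interval [", lower, ", ", upper,
         "] carries no probability mass under N(", mean, ", ", sd, ")")
  u <- stats::runif(n, plo, phi)
  out <- stats::qnorm(u, mean, sd)
  pmin(pmax(out, lower), upper)
}

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and standard deviation of a normal distribution with
#' parent parameters `(mean, sd)` truncated to `[lower, upper]`. Truncation to
#' an asymmetric interval shifts the mean toward the interval's center, so the
#' truncated mean generally differs from the parent `mean`; these are the
#' values sample averages of [rtruncnorm()] draws converge to.
#'
#' @inheritParams rtruncnorm
#' @return list with elements `mean` and `sd` of the truncated distribution.
#' @export
truncnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / z
  ea <- if (is.finite(a)) a * da else 0
  eb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (ea - eb) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}

# Evaluate `code` under `seed` when given, restoring the RNG state afterwards;
# with seed = NULL the ambient RNG stream is used as-is.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# FNV-1a hash of a character scalar, as 8 hex digits. Used to fingerprint a
# pipeline configuration in output manifests (provenance, not cryptography).
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256 # xor with a byte only touches the low 8 bits
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply by the FNV prime 16777619, done in two halves
    # because doubles lose integrality past 2^53
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Shared column validator: fail fast naming the offending columns.
check_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}
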