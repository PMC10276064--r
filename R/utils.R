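# Internal helpers shared across modules.

#' Truncated-normal random draws
#'
#' Inverse-CDF sampler for a normal distribution truncated to
#' `[lower, upper]`. Used throughout the synthetic cohort generator, where
#' published group moments (mean +/- SD) must be honoured while keeping
#' physical quantities strictly positive and percentages inside (0, 100).
#' With `sd = 0` the mean is returned for every draw (degenerate
#' distribution).
#'
#' @param n Number of draws.
#' @param mean,sd Moments of the parent (untruncated) normal.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower <= upper)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      abort("Degenerate (sd = 0) distribution with mean outside bounds.")
    }
    return(rep(mean, n))
  }
  if (lower == upper) abort("Empty truncation interval for sd > 0.")
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# Modal value of an integer-valued pixel sample (background estimation).
int_mode <- function(x) {
  x <- as.integer(round(x))
  tab <- tabulate(x - min(x) + 1L)
  as.numeric(min(x) + which.max(tab) - 1L)
}

# Validate a mean/SD pair given as c(mean, sd).
check_moments <- function(x, name, positive_mean = TRUE) {
  if (length(x) != 2 || !is.numeric(x) || anyNA(x)) {
    abort(paste0("`", name, "` must be a numeric c(mean, sd) pair."))
  }
  if (x[2] < 0) abort(paste0("`", name, "`: SD must be >= 0."))
  if (positive_mean && x[1] <= 0) {
    abort(paste0("`", name, "`: mean must be > 0."))
  }
  invisible(x)
}

# Disk offsets (pixel neighbourhood) of radius r, as a 2-column matrix.
disk_offsets <- function(r) {
  d <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dr = d, dc = d)
  g <- g[g$dr^2 + g$dc^2 <= r^2, ]
  as.matrix(g)
}

# Stamp a disk of `value` into matrix `m` at (row, col); returns the
# modified matrix and the linear indices written.
stamp_disk <- function(m, row, col, r, value) {
  off <- disk_offsets(r)
  rr <- row + off[, 1]
  cc <- col + off[, 2]
  keep <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  idx <- cbind(rr[keep], cc[keep])
  lin <- (idx[, 2] - 1L) * nrow(m) + idx[, 1]
  m[lin] <- value
  list(m = m, idx = lin)
}
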