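# Shared fixtures, built in code at test time.

zero_noise_optics <- function(...) optics_params(noise_sd = 0, ...)

# A one-row subject with explicit ground truth, for bespoke sections.
make_subject <- function(mb1 = 0.41, mb2 = 0.33, pct1 = 66,
                         fcsa1 = 6469, fcsa2 = 6724,
                         myonuclei = 4.34, satellites = 0.13) {
  tibble::tibble(
    subject_id = "T01",
    mb_type1_mM = mb1, mb_type2_mM = mb2, pct_type1 = pct1,
    fcsa_type1_um2 = fcsa1, fcsa_type2_um2 = fcsa2,
    myonuclei_per_fiber = myonuclei, satellites_per_fiber = satellites
  )
}

# One zero-noise demo section reused across test files (cached).
demo_section <- local({
  sec <- NULL
  function() {
    if (is.null(sec)) {
      subj <- generate_cohort(cohort_params(seed = 101))[1, ]
      sec <<- generate_section(subj, zero_noise_optics(), n_fibers = 30,
                               seed = 5)
    }
    sec
  }
})

# Vertices of a regular n-gon of radius r (centred at c(10, 10)).
regular_polygon <- function(n, r = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = 10 + r * cos(th), y = 10 + r * sin(th))
}

# Dense polygonal approximation of an axis-aligned ellipse.
ellipse_polygon <- function(a, b, n = 512) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = a * cos(th), y = b * sin(th))
}

# Match each truth fragment to the nearest detected fragment centroid.
match_fragments <- function(truth, detected, max_dist = 2.5) {
  stopifnot(nrow(truth) > 0)
  idx <- vapply(seq_len(nrow(truth)), function(j) {
    d2 <- (detected$row - truth$row[j])^2 + (detected$col - truth$col[j])^2
    k <- which.min(d2)
    if (d2[k] <= max_dist^2) k else NA_integer_
  }, integer(1))
  tibble::tibble(truth_class = truth$class,
                 detected_class = detected$assigned_class[idx],
                 matched = !is.na(idx))
}

# Mean of a normal truncated below at `lower` (analytic, for moment checks).
truncnorm_mean <- function(mean, sd, lower) {
  if (sd == 0) return(mean)
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}
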