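#' Relative expression from qPCR cycle thresholds
#'
#' `2^-(CT_target - CT_housekeeping)`: expression of the target gene relative
#' to the housekeeping gene (here Mb relative to 18S rRNA). Invariant under
#' an equal shift of both CTs.
#'
#' @param ct_mb Target-gene cycle threshold(s).
#' @param ct_18s Housekeeping-gene cycle threshold(s).
#' @param ct_range Admissible CT range; values outside raise an error.
#' @return Dimensionless relative expression, > 0.
#' @examples
#' relative_expression(19.9, 16)  # 2^-3.9 ~ 0.067
#' @export
relative_expression <- function(ct_mb, ct_18s, ct_range = c(0, 45)) {
  ok <- function(x) all(is.finite(x) & x > ct_range[1] & x < ct_range[2])
  if (!ok(ct_mb) || !ok(ct_18s)) {
    abort(sprintf("CT values must lie in (%g, %g).", ct_range[1], ct_range[2]))
  }
  2^(-(ct_mb - ct_18s))
}

#' Total RNA yield per mg muscle
#'
#' @param total_rna_ng Total RNA recovered, ng.
#' @param muscle_mass_mg Wet mass of the homogenised sample, mg, > 0.
#' @return ng RNA per mg muscle.
#' @examples
#' rna_per_mg(534, 10)  # 53.4
#' @export
rna_per_mg <- function(total_rna_ng, muscle_mass_mg) {
  if (any(muscle_mass_mg <= 0)) abort("`muscle_mass_mg` must be > 0.")
  if (any(total_rna_ng < 0)) abort("`total_rna_ng` must be >= 0.")
  total_rna_ng / muscle_mass_mg
}

#' Per-subject expression measures from a CT table
#'
#' Adds relative Mb mRNA expression (2^-dCT against 18S) and RNA yield per
#' mg to a qPCR table such as the one produced by [generate_qpcr_table()].
#'
#' @param ct_table Tibble with `ct_mb`, `ct_18s`, `total_rna_ng`,
#'   `muscle_mass_mg`.
#' @return The table with `mrna_relative` and `rna_per_mg` columns appended.
#' @export
measure_expression <- function(ct_table) {
  stopifnot(is.data.frame(ct_table))
  need <- c("ct_mb", "ct_18s", "total_rna_ng", "muscle_mass_mg")
  if (!all(need %in% names(ct_table))) {
    abort(paste("`ct_table` must carry:", paste(need, collapse = ", ")))
  }
  mutate(ct_table,
         mrna_relative = relative_expression(.data$ct_mb, .data$ct_18s),
         rna_per_mg = rna_per_mg(.data$total_rna_ng, .data$muscle_mass_mg))
}
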