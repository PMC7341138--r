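## MNase sensitivity: log2(light/heavy) with MSF/MRF sign semantics.

#' Differential MNase sensitivity matrix
#'
#' Cell-wise `log2((light + pseudocount) / (heavy + pseudocount))` of two
#' matched promoter matrices. Positive values are MNase-sensitive fragments
#' (MSFs, preferentially released by light digestion); negative values are
#' MNase-resistant fragments (MRFs, recovered even after heavy digestion).
#' The pseudocount (default 1 FPM) keeps empty cells finite and
#' zero-centered.
#'
#' @param light,heavy [promoter_matrix()] objects sharing gene order,
#'   window grid and normalization tag.
#' @param pseudocount positive value added to both numerator and
#'   denominator.
#' @return a `sensitivity_matrix` (also a `promoter_matrix`).
#' @export
sensitivity_matrix <- function(light, heavy, pseudocount = 1) {
  check_matched_grids(light, heavy)
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be > 0.")
  }
  l <- as.matrix(light); h <- as.matrix(heavy)
  vals <- log2((l + pseudocount) / (h + pseudocount))
  out <- pm_rewrap(light, vals,
                   label = paste0("log2(", pm_meta(light)$label, "/",
                                  pm_meta(heavy)$label, ")"),
                   normalization = "log2_ratio")
  meta <- attr(out, "pm_meta")
  meta$pseudocount <- pseudocount
  meta$sources <- c(light = pm_meta(light)$label,
                    heavy = pm_meta(heavy)$label)
  attr(out, "pm_meta") <- meta
  class(out) <- c("sensitivity_matrix", class(out))
  out
}

#' Label matrix cells as MNase-sensitive or MNase-resistant
#'
#' Applies the sign rule: sensitivity above `threshold` is MSF, below
#' `-threshold` is MRF, otherwise neutral (a non-zero threshold creates a
#' neutral band; the default 0 is the plain sign rule).
#'
#' @param sens a [sensitivity_matrix()].
#' @param threshold non-negative half-width of the neutral band.
#' @return tidy tibble (`gene_id`, `offset`, `sensitivity`, `label`) with
#'   `label` a factor in `{MSF, neutral, MRF}`.
#' @export
classify_msf_mrf <- function(sens, threshold = 0) {
  stopifnot_pm(sens, "sens")
  if (threshold < 0) abort("`threshold` must be >= 0.")
  long <- tidy(sens)
  names(long)[names(long) == "value"] <- "sensitivity"
  long$label <- factor(
    dplyr::case_when(
      long$sensitivity > threshold ~ "MSF",
      long$sensitivity < -threshold ~ "MRF",
      TRUE ~ "neutral"
    ),
    levels = c("MSF", "neutral", "MRF")
  )
  long
}

#' Cell-wise differential occupancy between two conditions
#'
#' `b - a` on matched grids and matching normalization, e.g. 20 min
#' post-stimulation minus untreated.
#'
#' @param a,b matched [promoter_matrix()] objects (baseline `a`).
#' @return a `promoter_matrix` of differences.
#' @export
differential_occupancy <- function(a, b) {
  check_matched_grids(a, b)
  out <- pm_rewrap(a, as.matrix(b) - as.matrix(a),
                   label = paste0(pm_meta(b)$label, " - ", pm_meta(a)$label),
                   normalization = paste0("diff_", pm_meta(a)$normalization))
  out
}
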