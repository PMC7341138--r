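#' TSS-anchored promoter signal matrices
#'
#' A `promoter_matrix` is a tibble with one row per gene and one numeric
#' column per window position. The first column, `gene_id`, identifies the
#' promoter; the remaining column names are window-center offsets in bp
#' relative to the TSS, strand-oriented so that positive offsets are
#' downstream of transcription. Offsets are strictly increasing left to
#' right. Metadata (digest/condition label, normalization tag, window size,
#' step, flank) travels in the `pm_meta` attribute.
#'
#' @param values numeric matrix, genes x windows.
#' @param gene_ids character vector of row identifiers (unique).
#' @param centers numeric vector of window-center offsets (strictly
#'   increasing), one per column of `values`.
#' @param label free-text source tag, e.g. `"light_untreated"`.
#' @param normalization `"fpm"` (fragments per million) or `"counts"`.
#' @param window,step,flank window geometry in bp (may be `NA` for derived
#'   matrices).
#' @return A `promoter_matrix` (tibble subclass).
#' @export
promoter_matrix <- function(values, gene_ids, centers, label = "",
                            normalization = "fpm", window = NA_real_,
                            step = NA_real_, flank = NA_real_) {
  values <- as.matrix(values)
  if (length(gene_ids) != nrow(values)) {
    abort("`gene_ids` must have one entry per row of `values`.")
  }
  if (length(centers) != ncol(values)) {
    abort("`centers` must have one entry per column of `values`.")
  }
  if (anyDuplicated(gene_ids)) abort("`gene_ids` must be unique.")
  if (ncol(values) > 1 && any(diff(centers) <= 0)) {
    abort("`centers` must be strictly increasing.")
  }
  out <- as_tibble(values, .name_repair = "minimal")
  names(out) <- format_centers(centers)
  out <- dplyr::bind_cols(tibble(gene_id = as.character(gene_ids)), out)
  attr(out, "pm_meta") <- list(
    centers = as.numeric(centers), label = label,
    normalization = normalization, window = window, step = step,
    flank = flank
  )
  class(out) <- c("promoter_matrix", class(tibble()))
  out
}

format_centers <- function(centers) {
  format(centers, trim = TRUE, scientific = FALSE)
}

#' @rdname promoter_matrix
#' @param x a `promoter_matrix`.
#' @export
pm_centers <- function(x) {
  meta <- attr(x, "pm_meta")
  if (!is.null(meta$centers)) meta$centers else as.numeric(names(x)[-1])
}

#' @rdname promoter_matrix
#' @export
pm_meta <- function(x) attr(x, "pm_meta")

#' Extract the numeric gene x window matrix from a promoter_matrix
#'
#' @param x a `promoter_matrix`.
#' @param ... ignored.
#' @return numeric matrix with gene_id rownames and offset colnames.
#' @export
as.matrix.promoter_matrix <- function(x, ...) {
  m <- as.matrix(as.data.frame(x[-1]))
  rownames(m) <- x$gene_id
  colnames(m) <- names(x)[-1]
  m
}

## Rebuild a promoter_matrix from an existing one with new values/rows,
## keeping metadata coherent. Internal.
pm_rewrap <- function(template, values, gene_ids = NULL, label = NULL,
                      normalization = NULL) {
  meta <- pm_meta(template)
  promoter_matrix(
    values,
    gene_ids = gene_ids %||% template$gene_id,
    centers = pm_centers(template),
    label = label %||% meta$label,
    normalization = normalization %||% meta$normalization,
    window = meta$window, step = meta$step, flank = meta$flank
  )
}

stopifnot_pm <- function(x, arg = "matrix") {
  if (!inherits(x, "promoter_matrix")) {
    abort(paste0("`", arg, "` must be a promoter_matrix."))
  }
  invisible(x)
}

## Grid compatibility check used by all two-matrix operations.
check_matched_grids <- function(a, b, check_normalization = TRUE) {
  stopifnot_pm(a, "a"); stopifnot_pm(b, "b")
  if (!identical(a$gene_id, b$gene_id)) {
    abort("Matrices have mismatched gene_id order.")
  }
  if (!isTRUE(all.equal(pm_centers(a), pm_centers(b)))) {
    abort("Matrices have mismatched window grids.")
  }
  if (check_normalization &&
      !identical(pm_meta(a)$normalization, pm_meta(b)$normalization)) {
    abort("Matrices have mismatched normalization tags.")
  }
  invisible(TRUE)
}

#' @export
tidy.promoter_matrix <- function(x, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(unclass_pm(x)), -"gene_id",
    names_to = "offset", values_to = "value"
  )
  long$offset <- as.numeric(long$offset)
  long
}

unclass_pm <- function(x) {
  class(x) <- setdiff(class(x), c("sensitivity_matrix", "promoter_matrix"))
  attr(x, "pm_meta") <- NULL
  x
}

#' @export
glance.promoter_matrix <- function(x, ...) {
  meta <- pm_meta(x)
  tibble(
    n_genes = nrow(x), n_windows = length(pm_centers(x)),
    window = meta$window, step = meta$step,
    normalization = meta$normalization, label = meta$label
  )
}

#' @export
print.promoter_matrix <- function(x, ...) {
  meta <- pm_meta(x)
  cat(sprintf(
    "# promoter_matrix: %d genes x %d windows [%s, %s] (label: %s, %s)\n",
    nrow(x), length(pm_centers(x)),
    format(min(pm_centers(x))), format(max(pm_centers(x))),
    if (nzchar(meta$label %||% "")) meta$label else "unlabelled",
    meta$normalization %||% "?"
  ))
  NextMethod()
}
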