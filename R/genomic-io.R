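## Readers and writers for the plain-text genomic formats the pipeline
## touches. All coordinates are 0-based half-open (BED convention)
## internally; the TSS of a minus-strand BED6 record is end - 1.

split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

is_int_string <- function(x) grepl("^-?[0-9]+$", x)

read_text_lines <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

#' Read paired-end fragment intervals from a BED3+ file
#'
#' One fragment per line, 0-based half-open coordinates. Fragments are
#' strand-less: a read pair is represented by its merged outer span.
#'
#' @param path path to a BED3(+) file.
#' @param label optional named list or character tag recording digest level,
#'   condition and replicate (stored in the `label` attribute).
#' @return tibble with columns `chrom`, `start`, `end` (a fragment set);
#'   `attr(., "label")` carries the tags.
#' @export
read_fragments_bed <- function(path, label = NULL) {
  lines <- read_text_lines(path)
  if (length(lines) == 0) {
    return(fragment_set(tibble(chrom = character(), start = integer(),
                               end = integer()), label))
  }
  fields <- split_fields(lines)
  n_col <- lengths(fields)
  bad <- which(n_col < 3)
  if (length(bad)) {
    abort(sprintf("Malformed BED line %d: fewer than 3 fields.", bad[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  s_chr <- vapply(fields, `[[`, "", 2)
  e_chr <- vapply(fields, `[[`, "", 3)
  bad <- which(!is_int_string(s_chr) | !is_int_string(e_chr))
  if (length(bad)) {
    abort(sprintf("Malformed BED line %d: non-integer coordinates.", bad[1]))
  }
  start <- as.integer(s_chr); end <- as.integer(e_chr)
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    abort(sprintf("Malformed BED line %d: end <= start (or start < 0).",
                  bad[1]))
  }
  fragment_set(tibble(chrom = chrom, start = start, end = end), label)
}

fragment_set <- function(df, label = NULL) {
  out <- as_tibble(df)
  attr(out, "label") <- label
  out
}

#' Write fragment intervals to BED3
#'
#' @param fragments fragment tibble (`chrom`, `start`, `end`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  readr::write_tsv(fragments[c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a TSS annotation from a BED6-like file
#'
#' The TSS is the `start` coordinate for `+`-strand records and `end - 1`
#' for `-`-strand records (RefSeq-derived convention).
#'
#' @param path path to a BED6 file (`chrom start end name score strand`).
#' @param flank bp of promoter window on each side of the TSS (default 1000,
#'   i.e. the 2 kb capture window).
#' @return tibble (`gene_id`, `chrom`, `tss`, `strand`) with a `flank`
#'   attribute.
#' @export
read_tss_annotation <- function(path, flank = 1000) {
  lines <- read_text_lines(path)
  fields <- split_fields(lines)
  bad <- which(lengths(fields) < 6)
  if (length(bad)) {
    abort(sprintf("TSS annotation line %d: fewer than 6 fields.", bad[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- as.integer(vapply(fields, `[[`, "", 2))
  end <- as.integer(vapply(fields, `[[`, "", 3))
  gene_id <- vapply(fields, `[[`, "", 4)
  strand <- vapply(fields, `[[`, "", 6)
  if (any(!strand %in% c("+", "-"))) {
    abort("TSS annotation strand must be '+' or '-'.")
  }
  if (anyDuplicated(gene_id)) {
    abort(paste0("Duplicate gene_id in TSS annotation: ",
                 gene_id[duplicated(gene_id)][1]))
  }
  tss_annotation(tibble(
    gene_id = gene_id, chrom = chrom,
    tss = ifelse(strand == "+", start, end - 1L), strand = strand
  ), flank = flank)
}

tss_annotation <- function(df, flank = 1000) {
  out <- as_tibble(df)
  if (anyDuplicated(out$gene_id)) abort("gene_id must be unique.")
  if (any(!out$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'.")
  }
  attr(out, "flank") <- flank
  out
}

tss_flank <- function(annotation, flank = NULL) {
  f <- flank %||% attr(annotation, "flank") %||% 1000
  as.integer(f)
}

#' Write a TSS annotation as BED6
#'
#' The inverse of [read_tss_annotation()]: a `+`-strand gene gets
#' `start = tss`, a `-`-strand gene `end = tss + 1`; the record spans the
#' promoter window.
#'
#' @param annotation TSS annotation tibble.
#' @param path output path.
#' @param span bp of annotation interval written downstream of the TSS.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(annotation, path, span = 2000) {
  start <- ifelse(annotation$strand == "+", annotation$tss,
                  annotation$tss - span + 1L)
  bed <- tibble(
    chrom = annotation$chrom, start = pmax(start, 0L),
    end = ifelse(annotation$strand == "+", annotation$tss + span,
                 annotation$tss + 1L),
    name = annotation$gene_id, score = 0L, strand = annotation$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read ENCODE narrowPeak records
#'
#' narrowPeak is BED6+4: `chrom start end name score strand signalValue
#' pValue qValue peak`, where `peak` is the summit offset from `start`
#' (-1 when absent).
#'
#' @param path path to a narrowPeak file.
#' @param factor regulatory-factor name attached to all records (e.g.
#'   `"NFkB"`).
#' @return tibble of peaks with a `summit` column (`NA` when the file has
#'   -1) and a `factor` column.
#' @export
read_narrowpeak <- function(path, factor = NA_character_) {
  lines <- read_text_lines(path)
  fields <- split_fields(lines)
  bad <- which(lengths(fields) < 10)
  if (length(bad)) {
    abort(sprintf("narrowPeak line %d: expected 10 columns, found %d.",
                  bad[1], lengths(fields)[bad[1]]))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  out <- tibble(
    chrom = col(1), start = as.integer(col(2)), end = as.integer(col(3)),
    name = col(4), score = as.numeric(col(5)), strand = col(6),
    signal_value = as.numeric(col(7)), p_value = as.numeric(col(8)),
    q_value = as.numeric(col(9)), summit = as.integer(col(10)),
    factor = factor
  )
  if (any(is.na(out$signal_value)) || any(out$signal_value < 0)) {
    abort("narrowPeak signalValue must be a non-negative number.")
  }
  if (any(out$end <= out$start)) abort("narrowPeak interval has end <= start.")
  if (any(!is.na(out$summit) & out$summit >= 0 &
          out$summit >= out$end - out$start)) {
    abort("narrowPeak summit offset must be < interval length (or -1).")
  }
  out$summit[out$summit < 0] <- NA_integer_
  out
}

#' Write peaks as narrowPeak
#'
#' @param peaks peak tibble as returned by [read_narrowpeak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$name %||% ".", score = peaks$score %||% 0,
    strand = peaks$strand %||% ".",
    signal_value = peaks$signal_value,
    p_value = peaks$p_value %||% -1, q_value = peaks$q_value %||% -1,
    summit = ifelse(is.na(peaks$summit), -1L, peaks$summit)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a two-column expression table
#'
#' Tab-separated `gene_id <TAB> value`, no header; values are non-negative
#' expression estimates in arbitrary units (TPM/FPKM-like).
#'
#' @param path path to the TSV.
#' @return tibble (`gene_id`, `expression`).
#' @export
read_expression_table <- function(path) {
  lines <- read_text_lines(path)
  fields <- split_fields(lines)
  bad <- which(lengths(fields) < 2)
  if (length(bad)) {
    abort(sprintf("Expression table line %d: expected 2 columns.", bad[1]))
  }
  out <- tibble(
    gene_id = vapply(fields, `[[`, "", 1),
    expression = as.numeric(vapply(fields, `[[`, "", 2))
  )
  if (anyDuplicated(out$gene_id)) {
    abort("Expression table has duplicate gene_id.")
  }
  if (any(is.na(out$expression)) || any(out$expression < 0)) {
    abort("Expression values must be non-negative numbers.")
  }
  out
}

#' Write an expression table
#' @param expression tibble (`gene_id`, `expression`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  readr::write_tsv(expression[c("gene_id", "expression")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write a promoter matrix as TSV
#'
#' Tab-delimited text: header row `gene_id` followed by the window-center
#' offsets, one gene per line, missing cells as `NA`. Values round-trip at
#' full precision through [read_matrix()].
#'
#' @param matrix a `promoter_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot_pm(matrix)
  if (nrow(matrix) == 0 || length(pm_centers(matrix)) == 0) {
    abort("Cannot write an empty promoter_matrix.")
  }
  readr::write_tsv(as_tibble(unclass_pm(matrix)), path, na = "NA")
  invisible(path)
}

#' Read a promoter matrix written by [write_matrix()]
#'
#' @param path path to the TSV.
#' @param label,normalization metadata to attach (the TSV itself carries
#'   only gene ids and offsets).
#' @return a `promoter_matrix`.
#' @export
read_matrix <- function(path, label = "", normalization = "fpm") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), na = "NA", progress = FALSE)
  centers <- as.numeric(names(df)[-1])
  promoter_matrix(as.matrix(df[-1]), df$gene_id, centers,
                  label = label, normalization = normalization)
}
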