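## Fragment sets -> per-bp coverage and TSS-anchored midpoint-density
## matrices.

#' Retain mononucleosome-sized fragments
#'
#' Keeps fragments whose length (`end - start`) lies in
#' `[min_len, max_len]`, the ~150 bp mononucleosomal band. Retained and
#' discarded counts are reported via `message()` and attached as the
#' `filter_counts` attribute.
#'
#' @param fragments fragment tibble (`chrom`, `start`, `end`).
#' @param min_len,max_len inclusive length bounds in bp (defaults 140-160).
#' @param quiet suppress the count message.
#' @return filtered fragment tibble.
#' @export
filter_mononucleosome <- function(fragments, min_len = 140, max_len = 160,
                                  quiet = FALSE) {
  if (min_len >= max_len) abort("`min_len` must be < `max_len`.")
  len <- fragments$end - fragments$start
  keep <- len >= min_len & len <= max_len
  out <- fragments[keep, , drop = FALSE]
  attr(out, "label") <- attr(fragments, "label")
  attr(out, "filter_counts") <- c(retained = sum(keep),
                                  discarded = sum(!keep))
  if (!quiet) {
    message(sprintf("filter_mononucleosome: retained %d, discarded %d (bounds %g-%g bp)",
                    sum(keep), sum(!keep), min_len, max_len))
  }
  out
}

## Map fragment midpoints to annotation rows. Returns, per gene, the
## genomic offsets (midpoint - tss) of midpoints inside [tss-flank,
## tss+flank), plus the number of distinct fragments assigned to at least
## one gene (the FPM denominator).
assign_midpoints <- function(fragments, annotation, flank) {
  mids <- fragments$start + (fragments$end - fragments$start) %/% 2L
  n_frag <- length(mids)
  assigned <- logical(n_frag)
  offsets <- vector("list", nrow(annotation))
  for (chr in unique(annotation$chrom)) {
    idx <- which(fragments$chrom == chr)
    if (length(idx) == 0) next
    ord <- idx[order(mids[idx])]
    v <- as.double(mids[ord])
    g_rows <- which(annotation$chrom == chr)
    ## one binary search over all gene boundaries at once
    bnd <- findInterval(
      c(annotation$tss[g_rows] - flank - 0.5,
        annotation$tss[g_rows] + flank - 0.5), v
    )
    i1s <- bnd[seq_along(g_rows)]
    i2s <- bnd[seq_along(g_rows) + length(g_rows)]
    for (j in seq_along(g_rows)) {
      g <- g_rows[j]
      if (i2s[j] > i1s[j]) {
        sel <- ord[(i1s[j] + 1):i2s[j]]
        offsets[[g]] <- mids[sel] - annotation$tss[g]
        assigned[sel] <- TRUE
      } else {
        offsets[[g]] <- integer(0)
      }
    }
  }
  empty <- vapply(offsets, is.null, logical(1))
  offsets[empty] <- list(integer(0))
  list(offsets = offsets, n_assigned = sum(assigned))
}

#' TSS-anchored fragment-midpoint density matrix
#'
#' The core occupancy statistic: for each gene, fragment midpoints
#' (`floor((start+end)/2)`) are counted in sliding windows of width
#' `window` at a `step` bp step across the TSS +/- flank region. Window
#' centers run from `-flank + window/2` to `flank - window/2`; a midpoint
#' at oriented offset `o` belongs to the window centered at `c` iff
#' `c - window/2 <= o < c + window/2`. Minus-strand genes have their
#' columns reversed so positive offsets are downstream of transcription.
#' With `normalization = "fpm"` each cell is
#' `count / n_assigned * 1e6`, where `n_assigned` is the number of
#' fragments whose midpoint falls inside the captured region set.
#'
#' @param fragments fragment tibble (typically mononucleosome-filtered).
#' @param annotation TSS annotation tibble (with a `flank` attribute).
#' @param window window width in bp (default 60).
#' @param step window step in bp (default 10).
#' @param normalization `"fpm"` (default) or `"counts"`.
#' @param flank optional override of the annotation's flank.
#' @return a [promoter_matrix()] with one row per annotated gene.
#' @export
midpoint_matrix <- function(fragments, annotation, window = 60, step = 10,
                            normalization = c("fpm", "counts"),
                            flank = NULL) {
  normalization <- match.arg(normalization)
  flank <- tss_flank(annotation, flank)
  if (window <= 0 || step <= 0) abort("`window` and `step` must be > 0.")
  if (window > 2 * flank) abort("`window` must be <= 2 * flank.")
  annotation <- drop_edge_genes(annotation, flank)
  centers <- seq(-flank + window / 2, flank - window / 2, by = step)
  asg <- assign_midpoints(fragments, annotation, flank)
  fast <- window %% step == 0
  n_bins <- ceiling(2 * flank / step)
  wpb <- window %/% step
  rowfun <- function(off) {
    if (fast) {
      bins <- tabulate((off + flank) %/% step + 1L, nbins = n_bins)
      cs <- c(0, cumsum(bins))
      cs[seq_along(centers) + wpb] - cs[seq_along(centers)]
    } else {
      vapply(centers, function(cc) {
        sum(off >= cc - window / 2 & off < cc + window / 2)
      }, numeric(1))
    }
  }
  values <- t(vapply(asg$offsets, rowfun, numeric(length(centers))))
  minus <- annotation$strand == "-"
  if (any(minus)) {
    values[minus, ] <- values[minus, rev(seq_along(centers)), drop = FALSE]
  }
  if (normalization == "fpm") {
    if (asg$n_assigned > 0) values <- values / asg$n_assigned * 1e6
  }
  lab <- attr(fragments, "label")
  pm <- promoter_matrix(
    values, annotation$gene_id, centers,
    label = if (is.null(lab)) "" else paste(unlist(lab), collapse = "_"),
    normalization = normalization, window = window, step = step,
    flank = flank
  )
  attr(pm, "n_assigned") <- asg$n_assigned
  pm
}

drop_edge_genes <- function(annotation, flank) {
  bad <- annotation$tss - flank < 0
  if (any(bad)) {
    warn(sprintf("Dropping %d gene(s) whose promoter window extends past the chromosome start.",
                 sum(bad)))
    annotation <- annotation[!bad, , drop = FALSE]
  }
  annotation
}

#' Per-bp fragments-per-million coverage over promoter windows
#'
#' The value at base `b` is the number of fragments whose interval contains
#' `b`, divided by the number of fragments overlapping the captured region
#' set, times 1e6. Offsets are strand-oriented (positive downstream of
#' transcription).
#'
#' @param fragments fragment tibble; must be non-empty.
#' @param annotation TSS annotation tibble.
#' @param flank optional override of the annotation's flank.
#' @return tidy tibble (`gene_id`, `offset`, `fpm`) with `offset` running
#'   `-flank .. flank - 1`; the FPM denominator is in the
#'   `total_count` attribute.
#' @export
coverage_fpm <- function(fragments, annotation, flank = NULL) {
  if (nrow(fragments) == 0) abort("Empty fragment set.")
  flank <- tss_flank(annotation, flank)
  annotation <- drop_edge_genes(annotation, flank)
  offs <- seq.int(-flank, flank - 1L)
  out <- vector("list", nrow(annotation))
  total <- 0L
  for (chr in unique(annotation$chrom)) {
    f <- fragments[fragments$chrom == chr, ]
    g_rows <- which(annotation$chrom == chr)
    fr <- IRanges::IRanges(start = f$start + 1L, end = f$end)
    cov <- IRanges::coverage(fr)
    win <- IRanges::IRanges(start = annotation$tss[g_rows] - flank + 1L,
                            end = annotation$tss[g_rows] + flank)
    total <- total + sum(IRanges::countOverlaps(fr, win) > 0)
    for (i in seq_along(g_rows)) {
      g <- g_rows[i]
      lo <- annotation$tss[g] - flank + 1L
      hi <- annotation$tss[g] + flank
      vals <- numeric(2L * flank)
      hi_c <- min(hi, length(cov))
      if (hi_c >= lo) {
        vals[seq_len(hi_c - lo + 1L)] <-
          as.numeric(cov[IRanges::IRanges(lo, hi_c)])
      }
      if (annotation$strand[g] == "-") vals <- rev(vals)
      out[[g]] <- tibble(gene_id = annotation$gene_id[g], offset = offs,
                         fpm = vals)
    }
  }
  res <- dplyr::bind_rows(out)
  if (total > 0) res$fpm <- res$fpm / total * 1e6
  attr(res, "total_count") <- total
  res
}
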