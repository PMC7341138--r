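# Independent brute-force oracles. These deliberately use naive loops and
# none of the package's internal machinery, so that agreement with the
# vectorized implementations is a real cross-check.

make_annotation <- function(gene_id, chrom, tss, strand, flank = 1000) {
  ann <- tibble::tibble(gene_id = gene_id, chrom = chrom, tss = tss,
                        strand = strand)
  attr(ann, "flank") <- flank
  ann
}

make_fragments <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end))
}

make_pm <- function(values, gene_ids = NULL, centers = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(centers)) centers <- seq_len(ncol(values))
  nucsens::promoter_matrix(values, gene_ids, centers, ...)
}

# Per-base fragment containment, fragments-per-million scaled.
oracle_coverage <- function(fragments, annotation, flank) {
  n_over <- 0L
  for (i in seq_len(nrow(fragments))) {
    hit <- FALSE
    for (g in seq_len(nrow(annotation))) {
      if (fragments$chrom[i] == annotation$chrom[g] &&
          fragments$start[i] < annotation$tss[g] + flank &&
          fragments$end[i] > annotation$tss[g] - flank) hit <- TRUE
    }
    if (hit) n_over <- n_over + 1L
  }
  rows <- list()
  for (g in seq_len(nrow(annotation))) {
    vals <- numeric(2 * flank)
    bases <- (annotation$tss[g] - flank):(annotation$tss[g] + flank - 1)
    for (j in seq_along(bases)) {
      b <- bases[j]
      for (i in seq_len(nrow(fragments))) {
        if (fragments$chrom[i] == annotation$chrom[g] &&
            fragments$start[i] <= b && b < fragments$end[i]) {
          vals[j] <- vals[j] + 1
        }
      }
    }
    if (annotation$strand[g] == "-") vals <- rev(vals)
    rows[[g]] <- vals
  }
  list(values = do.call(rbind, rows),
       total = n_over,
       fpm = do.call(rbind, rows) / max(n_over, 1) * 1e6)
}

# Midpoint-in-window counts by triple loop; minus-strand rows reversed.
oracle_midpoint_matrix <- function(fragments, annotation, window, step,
                                   flank, normalization = "fpm") {
  centers <- seq(-flank + window / 2, flank - window / 2, by = step)
  mids <- floor((fragments$start + fragments$end) / 2)
  assigned <- rep(FALSE, nrow(fragments))
  values <- matrix(0, nrow(annotation), length(centers))
  for (g in seq_len(nrow(annotation))) {
    for (i in seq_len(nrow(fragments))) {
      if (fragments$chrom[i] != annotation$chrom[g]) next
      off <- mids[i] - annotation$tss[g]
      if (off >= -flank && off < flank) assigned[i] <- TRUE
      for (w in seq_along(centers)) {
        if (off >= centers[w] - window / 2 && off < centers[w] + window / 2) {
          values[g, w] <- values[g, w] + 1
        }
      }
    }
    if (annotation$strand[g] == "-") values[g, ] <- rev(values[g, ])
  }
  if (normalization == "fpm" && sum(assigned) > 0) {
    values <- values / sum(assigned) * 1e6
  }
  list(values = values, centers = centers, n_assigned = sum(assigned))
}

# Interval-overlap accumulation of narrowPeak signal values.
oracle_peak_matrix <- function(peaks, annotation, window, step, flank,
                               mode = "signal") {
  centers <- seq(-flank + window / 2, flank - window / 2, by = step)
  values <- matrix(0, nrow(annotation), length(centers))
  for (g in seq_len(nrow(annotation))) {
    for (w in seq_along(centers)) {
      ws <- annotation$tss[g] + centers[w] - window / 2
      we <- ws + window
      for (i in seq_len(nrow(peaks))) {
        if (peaks$chrom[i] == annotation$chrom[g] &&
            peaks$start[i] < we && peaks$end[i] > ws) {
          values[g, w] <- if (mode == "signal") {
            values[g, w] + peaks$signal_value[i]
          } else 1
        }
      }
    }
    if (annotation$strand[g] == "-") values[g, ] <- rev(values[g, ])
  }
  values
}

# Pair-counting adjusted Rand index.
oracle_ari <- function(x, y) {
  n <- length(x)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- x[i] == x[j]; sy <- y[i] == y[j]
      if (sx && sy) n11 <- n11 + 1
      else if (sx && !sy) n10 <- n10 + 1
      else if (!sx && sy) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# Random small genome fixture: genes on two chromosomes, mixed strands.
random_fixture <- function(seed, n_genes = 4, n_frags = 80, flank = 200) {
  set.seed(seed)
  ann <- make_annotation(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    chrom = sample(c("chrA", "chrB"), n_genes, replace = TRUE),
    tss = flank + sample.int(2000, n_genes) + seq_len(n_genes) * 900,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    flank = flank
  )
  len <- sample(80:220, n_frags, replace = TRUE)
  start <- sample.int(4500, n_frags)
  frags <- make_fragments(
    chrom = sample(c("chrA", "chrB"), n_frags, replace = TRUE),
    start = start, end = start + len
  )
  list(annotation = ann, fragments = frags, flank = flank)
}
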