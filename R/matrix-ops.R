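## Sorting, quartiling, clustering and summarizing promoter matrices the
## way the heatmap figures do.

#' Sort order by per-gene maximum signal
#'
#' Key = each gene's maximum over all windows (NA-ignoring); descending
#' order, ties broken by lexicographic gene_id.
#'
#' @param matrix a [promoter_matrix()].
#' @return a `sort_order` tibble (`gene_id`, `key`) in sorted order; the
#'   key name is in the `key_name` attribute.
#' @export
sort_by_max_signal <- function(matrix) {
  stopifnot_pm(matrix)
  if (nrow(matrix) == 0) abort("Matrix is empty.")
  m <- as.matrix(matrix)
  key <- apply(m, 1, function(r) if (all(is.na(r))) NA_real_ else
    max(r, na.rm = TRUE))
  ord <- order(-key, matrix$gene_id)
  out <- tibble(gene_id = matrix$gene_id[ord], key = unname(key[ord]))
  attr(out, "key_name") <- "max_signal"
  class(out) <- c("sort_order", class(out))
  out
}

#' Reorder a promoter matrix by a sort order
#'
#' Enables cross-dataset overlays: the order derived from one matrix (e.g.
#' maximum sensitivity) applied to another (e.g. a TF peak matrix) on the
#' same genes.
#'
#' @param matrix a [promoter_matrix()].
#' @param order a `sort_order` (or anything with a `gene_id` column) that
#'   is a permutation of the matrix's genes.
#' @return the row-reordered `promoter_matrix`.
#' @export
apply_sort <- function(matrix, order) {
  stopifnot_pm(matrix)
  ids <- if (is.data.frame(order)) order$gene_id else as.character(order)
  if (!setequal(ids, matrix$gene_id) ||
      length(ids) != nrow(matrix)) {
    abort("`order` must be a permutation of the matrix's gene ids.")
  }
  idx <- match(ids, matrix$gene_id)
  pm_rewrap(matrix, as.matrix(matrix)[idx, , drop = FALSE], gene_ids = ids)
}

#' Split genes into quartiles by a ranking key
#'
#' Genes are ranked by `key` descending (ties broken by gene_id) and split
#' into 4 contiguous groups; with `n` not divisible by 4 the earlier
#' quartiles take the extra gene. Q1 holds the highest keys.
#'
#' @param keys tibble with columns `gene_id` and a key column, or a named
#'   numeric vector.
#' @param key_col name of the key column when `keys` is a data frame
#'   (default: the second column).
#' @return tibble (`gene_id`, `key`, `quartile`) with `quartile` a factor
#'   Q1..Q4, in ranked order.
#' @export
quartiles_by_key <- function(keys, key_col = NULL) {
  if (is.data.frame(keys)) {
    key_col <- key_col %||% names(keys)[2]
    df <- tibble(gene_id = keys$gene_id, key = keys[[key_col]])
  } else {
    df <- tibble(gene_id = names(keys), key = as.numeric(keys))
  }
  n <- nrow(df)
  if (n < 4) abort("Quartiles need at least 4 genes.")
  df <- df[order(-df$key, df$gene_id), ]
  df$quartile <- factor(rep(paste0("Q", 1:4), times = quartile_sizes(n)),
                        levels = paste0("Q", 1:4))
  df
}

## Lloyd's k-means with a fixed number of random restarts, deterministic
## given `seed`. Implemented directly because the contract requires defined
## behaviour on degenerate inputs (duplicate rows, k = n) where
## stats::kmeans(algorithm = "Lloyd") stops with an error; an emptied
## cluster is re-seeded with the point farthest from its assigned center.
lloyd_once <- function(x, k, iter_max = 100) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  xsq <- rowSums(x^2)
  for (it in seq_len(iter_max)) {
    ## squared Euclidean distances via the expansion |x|^2 - 2x.c + |c|^2
    d2 <- xsq - 2 * x %*% t(centers) +
      rep(rowSums(centers^2), each = n)
    d2[d2 < 0] <- 0
    assign_new <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(assign_new == j)) {
        far <- which.max(d2[cbind(seq_len(n), assign_new)])
        assign_new[far] <- j
      }
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
    }
  }
  wcss <- sum((x - centers[assign_old, , drop = FALSE])^2)
  list(cluster = assign_old, centers = centers, wcss = wcss)
}

#' k-means clustering of promoter profiles
#'
#' Lloyd's algorithm on matrix rows (Euclidean distance), best of `n_init`
#' random restarts by within-cluster sum of squares, deterministic given
#' `seed`. Rows containing NA are mean-imputed per column for the
#' clustering only (and flagged); optionally rows are z-scored first.
#'
#' @param matrix a [promoter_matrix()] (e.g. a sensitivity matrix).
#' @param k number of clusters (>= 2, <= number of genes).
#' @param seed integer seed for the restarts.
#' @param n_init number of random restarts.
#' @param scale_rows z-score each row before clustering.
#' @param iter_max Lloyd iteration cap per restart.
#' @return a `cluster_assignment` tibble (`gene_id`, `cluster`) with
#'   attributes `k`, `seed`, `sizes`, `wcss`, `imputed` (gene ids that had
#'   NA cells) and `mean_profiles` (per-cluster mean profile tibble).
#' @export
kmeans_profiles <- function(matrix, k = 6, seed = 1, n_init = 10,
                            scale_rows = FALSE, iter_max = 100) {
  stopifnot_pm(matrix)
  if (k < 2) abort("`k` must be >= 2.")
  if (k > nrow(matrix)) abort("`k` must be <= the number of genes.")
  x <- as.matrix(matrix)
  imputed <- matrix$gene_id[apply(x, 1, anyNA)]
  if (length(imputed)) {
    for (j in seq_len(ncol(x))) {
      cm <- mean(x[, j], na.rm = TRUE)
      x[is.na(x[, j]), j] <- if (is.finite(cm)) cm else 0
    }
  }
  if (scale_rows) {
    x <- t(apply(x, 1, function(r) {
      s <- sd(r)
      if (s > 0) (r - mean(r)) / s else r - mean(r)
    }))
  }
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- lloyd_once(x, k, iter_max)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  out <- tibble(gene_id = matrix$gene_id, cluster = best$cluster)
  class(out) <- c("cluster_assignment", class(out))
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  attr(out, "sizes") <- tabulate(best$cluster, k)
  attr(out, "wcss") <- best$wcss
  attr(out, "imputed") <- imputed
  attr(out, "mean_profiles") <- cluster_average_profiles(matrix, out)
  out
}

#' Per-group mean promoter profiles
#'
#' Arithmetic mean of each window column within each group (NA-ignoring),
#' the "average plot" companion of a clustered or quartiled heatmap.
#'
#' @param matrix a [promoter_matrix()].
#' @param groups a `cluster_assignment`, a [quartiles_by_key()] result, or
#'   any tibble mapping `gene_id` to a grouping column (the first
#'   non-`gene_id`, non-`key` column); every gene in `matrix` must be
#'   assigned.
#' @return tidy tibble (`group`, `offset`, `value`, `n_genes`).
#' @export
cluster_average_profiles <- function(matrix, groups) {
  stopifnot_pm(matrix)
  if (!is.data.frame(groups)) {
    groups <- tibble(gene_id = names(groups), group = as.vector(groups))
  }
  gcol <- setdiff(names(groups), c("gene_id", "key"))[1]
  if (is.na(gcol)) abort("`groups` must contain a grouping column.")
  map <- groups[[gcol]][match(matrix$gene_id, groups$gene_id)]
  if (anyNA(map)) abort("Every gene in the matrix must be assigned a group.")
  long <- tidy(matrix)
  long$group <- map[match(long$gene_id, matrix$gene_id)]
  out <- long |>
    dplyr::group_by(.data$group, .data$offset) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     n_genes = dplyr::n(), .groups = "drop")
  class(out) <- c("profile_summary", class(out))
  out
}

#' Regulatory-factor peak matrix on the promoter window grid
#'
#' For each gene and window, the summed narrowPeak `signal_value` of peaks
#' whose interval overlaps the (genomic) window; `mode = "binary"` records
#' presence/absence instead. Orientation follows [midpoint_matrix()]:
#' minus-strand rows are reversed.
#'
#' @param peaks peak tibble from [read_narrowpeak()].
#' @param annotation TSS annotation tibble.
#' @param window,step grid geometry in bp (defaults 60/10).
#' @param mode `"signal"` (sum of signalValue) or `"binary"`.
#' @param flank optional override of the annotation's flank.
#' @return a [promoter_matrix()] (normalization tag `"peak_signal"` or
#'   `"peak_binary"`).
#' @export
peak_matrix <- function(peaks, annotation, window = 60, step = 10,
                        mode = c("signal", "binary"), flank = NULL) {
  mode <- match.arg(mode)
  flank <- tss_flank(annotation, flank)
  if (window <= 0 || step <= 0) abort("`window` and `step` must be > 0.")
  if (window > 2 * flank) abort("`window` must be <= 2 * flank.")
  annotation <- drop_edge_genes(annotation, flank)
  centers <- seq(-flank + window / 2, flank - window / 2, by = step)
  n <- nrow(annotation)
  values <- matrix(0, n, length(centers))
  for (chr in unique(annotation$chrom)) {
    p <- peaks[peaks$chrom == chr, ]
    g_rows <- which(annotation$chrom == chr)
    if (nrow(p) == 0 || length(g_rows) == 0) next
    pr <- IRanges::IRanges(start = p$start + 1L, end = p$end)
    ## one IRanges per (gene, window): windows are genomic, half-open
    win_start <- rep(annotation$tss[g_rows], each = length(centers)) +
      rep(centers - window / 2, length(g_rows))
    wr <- IRanges::IRanges(start = win_start + 1L,
                           width = as.integer(window))
    ov <- IRanges::findOverlaps(wr, pr)
    if (length(ov) > 0) {
      q <- as.data.frame(ov)
      contrib <- if (mode == "signal") p$signal_value[q$subjectHits] else
        rep(1, nrow(q))
      acc <- tapply(contrib, q$queryHits, sum)
      qi <- as.integer(names(acc))
      gi <- g_rows[(qi - 1L) %/% length(centers) + 1L]
      wi <- (qi - 1L) %% length(centers) + 1L
      values[cbind(gi, wi)] <- as.numeric(acc)
    }
  }
  if (mode == "binary") values[values > 0] <- 1
  minus <- annotation$strand == "-"
  if (any(minus)) {
    values[minus, ] <- values[minus, rev(seq_along(centers)), drop = FALSE]
  }
  promoter_matrix(values, annotation$gene_id, centers,
                  label = paste0("peaks_", peaks$factor[1] %||% ""),
                  normalization = paste0("peak_", mode),
                  window = window, step = step, flank = flank)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 = identical partitions, ~0 = random agreement. Used to score recovery
#' of planted cluster structure.
#'
#' @param x,y label vectors of equal length.
#' @return numeric ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
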