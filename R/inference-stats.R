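## Region-level promoter summaries, the paired t-test between conditions,
## and the expression-vs-differential-occupancy correlation check.

#' Per-gene mean signal over an offset band
#'
#' Averages each gene's row over the window columns whose center lies in
#' `[band[1], band[2]]` (strand-oriented offsets; the -1 nucleosome band is
#' `c(-200, 0)`). NA cells are ignored; a gene with only NA cells gets NA.
#'
#' @param matrix a [promoter_matrix()] (occupancy or sensitivity).
#' @param band length-2 numeric, inclusive offset bounds in bp.
#' @return a `region_summary` tibble (`gene_id`, `value`) with `band` and
#'   `source` attributes.
#' @export
region_summary <- function(matrix, band = c(-200, 0)) {
  stopifnot_pm(matrix)
  centers <- pm_centers(matrix)
  if (band[1] > band[2]) abort("`band` must satisfy band[1] <= band[2].")
  if (band[2] < min(centers) || band[1] > max(centers)) {
    abort("`band` lies outside the matrix offset range.")
  }
  keep <- centers >= band[1] & centers <= band[2]
  if (!any(keep)) abort("No window centers fall inside `band`.")
  m <- as.matrix(matrix)[, keep, drop = FALSE]
  val <- rowMeans(m, na.rm = TRUE)
  val[!is.finite(val)] <- NA_real_
  out <- tibble(gene_id = matrix$gene_id, value = unname(val))
  attr(out, "band") <- band
  attr(out, "source") <- pm_meta(matrix)$label
  class(out) <- c("region_summary", class(out))
  out
}

#' Paired t-test between two per-gene region summaries
#'
#' Per-gene differences `d = b - a`; `t = mean(d) / (sd(d)/sqrt(n))` with
#' the sample (n-1) standard deviation and a two-sided p-value from
#' Student's t with n-1 df. Pairs with NA in either summary are dropped
#' listwise. Degenerate cases follow fixed contracts: zero variance with a
#' non-zero mean reports `t = +/-Inf`, `p = 0`; zero variance with zero
#' mean reports `t = NA` (undefined), `p = 1`.
#'
#' @param a,b [region_summary()] tibbles (baseline `a`).
#' @param genes optional character vector restricting the test to a gene
#'   subset (e.g. the top expression quartile).
#' @return a `paired_ttest` object; see [tidy.paired_ttest()].
#' @export
paired_t_test <- function(a, b, genes = NULL) {
  df <- dplyr::inner_join(
    tibble(gene_id = a$gene_id, a = a$value),
    tibble(gene_id = b$gene_id, b = b$value),
    by = "gene_id"
  )
  if (!is.null(genes)) df <- df[df$gene_id %in% genes, ]
  n_dropped <- sum(!complete.cases(df))
  df <- df[complete.cases(df), ]
  n <- nrow(df)
  if (n < 2) abort("Paired t-test needs >= 2 complete pairs.")
  d <- df$b - df$a
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (md == 0) {
      t_stat <- NA_real_; p <- 1; flag <- "undefined_t"
    } else {
      t_stat <- sign(md) * Inf; p <- 0; flag <- "zero_variance"
    }
  } else {
    t_stat <- md / (s / sqrt(n))
    p <- 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
    flag <- "ok"
  }
  structure(list(
    t = t_stat, df = n - 1L, p_value = p, n = n, mean_difference = md,
    sd_difference = s, flag = flag, n_dropped = n_dropped,
    band = attr(b, "band") %||% attr(a, "band"),
    gene_set = if (is.null(genes)) "all" else paste0("subset(n=", n, ")")
  ), class = "paired_ttest")
}

#' @describeIn paired_t_test one-row tibble of the test result
#'   (broom-style).
#' @param x a `paired_ttest`.
#' @param ... ignored.
#' @export
tidy.paired_ttest <- function(x, ...) {
  tibble(
    estimate = x$mean_difference, statistic = x$t,
    p.value = x$p_value, parameter = x$df, n = x$n,
    method = "paired t-test", flag = x$flag
  )
}

#' @describeIn paired_t_test alias of `tidy()` for one-row summaries.
#' @export
glance.paired_ttest <- function(x, ...) tidy(x)

#' @export
print.paired_ttest <- function(x, ...) {
  cat("Paired t-test (", x$gene_set, ")\n", sep = "")
  cat(sprintf("  t = %s, df = %d, p = %.4g (%s)\n",
              format(x$t, digits = 5), x$df, x$p_value, x$flag))
  cat(sprintf("  mean difference = %.5g over n = %d pairs (%d dropped)\n",
              x$mean_difference, x$n, x$n_dropped))
  invisible(x)
}

#' Correlation of expression with differential occupancy
#'
#' Rank (Spearman) correlation, by default, of per-gene expression against
#' a per-gene differential signal (e.g. a [region_summary()] of a
#' [differential_occupancy()] matrix), with a two-sided p-value. Pearson is
#' available by flag.
#'
#' @param expression tibble (`gene_id`, `expression`).
#' @param diff a `region_summary` or any tibble (`gene_id`, `value`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return one-row tibble (`estimate`, `p.value`, `n`, `method`).
#' @export
expression_occupancy_correlation <- function(expression, diff,
                                             method = c("spearman",
                                                        "pearson")) {
  method <- match.arg(method)
  df <- dplyr::inner_join(
    tibble(gene_id = expression$gene_id, x = expression$expression),
    tibble(gene_id = diff$gene_id, y = diff$value),
    by = "gene_id"
  )
  df <- df[complete.cases(df), ]
  if (nrow(df) < 3) abort("Correlation needs >= 3 complete gene pairs.")
  ct <- suppressWarnings(
    cor.test(df$x, df$y, method = method, exact = FALSE)
  )
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
         n = nrow(df), method = method)
}
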