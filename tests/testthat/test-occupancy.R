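test_that("mononucleosome filter applies inclusive length bounds", {
  fr <- make_fragments("chr1", c(0, 0, 0, 0), c(100, 150, 151, 200))
  out <- filter_mononucleosome(fr, 140, 160, quiet = TRUE)
  expect_equal(out$end - out$start, c(150L, 151L))
  expect_equal(unname(attr(out, "filter_counts")), c(2L, 2L))

  expect_equal(nrow(filter_mononucleosome(fr, 1, 1e6, quiet = TRUE)), 4)
  expect_error(filter_mononucleosome(fr, 160, 140), "min_len")
})

test_that("coverage_fpm matches its definition and the brute-force oracle", {
  ann <- make_annotation("gA", "chr1", tss = 200, strand = "+", flank = 200)
  fr <- make_fragments("chr1", 100, 250)
  cov <- coverage_fpm(fr, ann)
  expect_equal(unique(cov$fpm[cov$offset >= -100 & cov$offset < 50]), 1e6)
  expect_equal(unique(cov$fpm[cov$offset >= 50]), 0)

  # two identical fragments: numerator and denominator both double
  fr2 <- make_fragments("chr1", c(100, 100), c(250, 250))
  cov2 <- coverage_fpm(fr2, ann)
  expect_equal(cov2$fpm, cov$fpm)

  expect_error(coverage_fpm(fr[0, ], ann), "Empty")

  # random 50-fragment set vs per-base containment count
  fix <- random_fixture(seed = 101, n_genes = 3, n_frags = 50, flank = 150)
  got <- coverage_fpm(fix$fragments, fix$annotation)
  want <- oracle_coverage(fix$fragments, fix$annotation, fix$flank)
  gm <- matrix(got$fpm, nrow = nrow(fix$annotation), byrow = TRUE)
  expect_equal(gm, want$fpm, ignore_attr = TRUE)
  expect_equal(attr(got, "total_count"), want$total)
})

test_that("midpoint_matrix reproduces the single-fragment worked example", {
  # fragment [940, 1090) has midpoint 1015; TSS 1000 => offset +15
  ann <- make_annotation("gA", "chr1", tss = 1000, strand = "+",
                         flank = 1000)
  fr <- make_fragments("chr1", 940, 1090)
  m <- midpoint_matrix(fr, ann, window = 60, step = 10)
  vals <- as.matrix(m)[1, ]
  centers <- pm_centers(m)
  hot <- centers[vals > 0]
  expect_equal(hot, c(-10, 0, 10, 20, 30, 40))
  expect_true(all(vals[vals > 0] == 1e6))

  # no fragments near a second gene: all-zero row
  ann2 <- make_annotation(c("gA", "gB"), "chr1", c(1000, 50000),
                          c("+", "+"), flank = 1000)
  m2 <- midpoint_matrix(fr, ann2)
  expect_true(all(as.matrix(m2)["gB", ] == 0))
})

test_that("midpoint_matrix equals the brute-force oracle on random inputs", {
  for (seed in c(11, 12, 13)) {
    fix <- random_fixture(seed, n_genes = 4, n_frags = 100, flank = 200)
    for (norm in c("fpm", "counts")) {
      got <- midpoint_matrix(fix$fragments, fix$annotation, window = 60,
                             step = 10, normalization = norm)
      want <- oracle_midpoint_matrix(fix$fragments, fix$annotation,
                                     60, 10, fix$flank, norm)
      expect_equal(unname(as.matrix(got)), want$values)
      expect_equal(pm_centers(got), want$centers)
      expect_equal(attr(got, "n_assigned"), want$n_assigned)
    }
    # non-divisible window/step combination exercises the generic path
    got <- midpoint_matrix(fix$fragments, fix$annotation, window = 45,
                           step = 20, normalization = "counts")
    want <- oracle_midpoint_matrix(fix$fragments, fix$annotation,
                                   45, 20, fix$flank, "counts")
    expect_equal(unname(as.matrix(got)), want$values)
  }
})

test_that("strand flip reverses rows and is an involution", {
  fix <- random_fixture(21, n_genes = 4, n_frags = 60, flank = 200)
  ann_p <- fix$annotation; ann_p$strand <- "+"
  ann_m <- fix$annotation; ann_m$strand <- "-"
  mp <- as.matrix(midpoint_matrix(fix$fragments, ann_p))
  mm <- as.matrix(midpoint_matrix(fix$fragments, ann_m))
  expect_equal(unname(mm), unname(mp[, rev(seq_len(ncol(mp)))]))

  flip <- function(s) ifelse(s == "+", "-", "+")
  ann_ff <- fix$annotation; ann_ff$strand <- flip(flip(ann_ff$strand))
  expect_equal(as.matrix(midpoint_matrix(fix$fragments, ann_ff)),
               as.matrix(midpoint_matrix(fix$fragments, fix$annotation)))
})

test_that("disjoint-window mass relation and FPM duplication invariance hold", {
  fix <- random_fixture(31, n_genes = 3, n_frags = 90, flank = 200)
  ann <- fix$annotation; ann$strand <- "+"
  m <- midpoint_matrix(fix$fragments, ann, window = 60, step = 10,
                       normalization = "counts")
  centers <- pm_centers(m)
  mids <- with(fix$fragments, start + (end - start) %/% 2L)
  take <- seq(1, length(centers), by = 6) # windows tile without overlap
  for (g in seq_len(nrow(ann))) {
    off <- mids[fix$fragments$chrom == ann$chrom[g]] - ann$tss[g]
    in_union <- vapply(take, function(w) {
      sum(off >= centers[w] - 30 & off < centers[w] + 30)
    }, numeric(1))
    expect_equal(unname(as.matrix(m)[g, take]), in_union)
  }

  # duplicating the whole fragment set leaves FPM coverage unchanged
  cov1 <- coverage_fpm(fix$fragments, ann)
  cov2 <- coverage_fpm(dplyr::bind_rows(fix$fragments, fix$fragments), ann)
  expect_equal(cov1$fpm, cov2$fpm)

  expect_error(midpoint_matrix(fix$fragments, ann, window = 1000),
               "flank")
})
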