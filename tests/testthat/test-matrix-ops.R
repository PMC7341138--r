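test_that("max-signal sort orders genes descending with lexicographic ties", {
  m <- make_pm(rbind(c(1, 5), c(9, 2), c(7, 0)), c("gC", "gA", "gB"), 1:2)
  so <- sort_by_max_signal(m)
  expect_equal(so$gene_id, c("gA", "gB", "gC"))
  expect_equal(so$key, c(9, 7, 5))

  tie <- make_pm(matrix(3, 3, 2), c("gB", "gA", "gC"), 1:2)
  expect_equal(sort_by_max_signal(tie)$gene_id, c("gA", "gB", "gC"))

  set.seed(5)
  big <- make_pm(matrix(rnorm(50 * 20), 50), sprintf("g%02d", 1:50), 1:20)
  so2 <- sort_by_max_signal(big)
  maxima <- apply(as.matrix(big), 1, max)
  expect_equal(so2$gene_id, names(sort(maxima, decreasing = TRUE)))
})

test_that("apply_sort permutes rows, preserves the row multiset, and inverts", {
  set.seed(6)
  m <- make_pm(matrix(rnorm(24), 6), sprintf("g%d", 1:6), 1:4)
  so <- sort_by_max_signal(m)
  sorted <- apply_sort(m, so)
  expect_identical(apply_sort(sorted, tibble::tibble(gene_id = m$gene_id)),
                   m)
  # multiset of rows preserved
  expect_equal(
    as.matrix(sorted)[order(sorted$gene_id), ],
    as.matrix(m)[order(m$gene_id), ]
  )
  # shared-order contract: order from m applied to another matrix
  m2 <- make_pm(matrix(rnorm(24), 6), sprintf("g%d", 1:6), 1:4)
  s2 <- apply_sort(m2, so)
  expect_equal(s2$gene_id, sorted$gene_id)
  expect_error(apply_sort(m, tibble::tibble(gene_id = c("g1", "gX"))),
               "permutation")
})

test_that("quartiles split ranked genes contiguously with the remainder rule", {
  q8 <- quartiles_by_key(tibble::tibble(gene_id = letters[1:8], key = 8:1))
  expect_equal(as.character(q8$quartile), rep(paste0("Q", 1:4), each = 2))
  expect_equal(q8$gene_id[q8$quartile == "Q1"], c("a", "b"))

  q10 <- quartiles_by_key(tibble::tibble(gene_id = letters[1:10], key = 10:1))
  expect_equal(as.vector(table(q10$quartile)), c(3L, 3L, 2L, 2L))

  set.seed(8)
  q100 <- quartiles_by_key(tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                                          key = rnorm(100)))
  expect_equal(as.vector(table(q100$quartile)), rep(25L, 4))
  # keys weakly decrease across quartile boundaries
  expect_true(min(q100$key[q100$quartile == "Q1"]) >=
                max(q100$key[q100$quartile == "Q2"]))
  expect_true(min(q100$key[q100$quartile == "Q3"]) >=
                max(q100$key[q100$quartile == "Q4"]))
  # partition: every gene exactly once
  expect_equal(sort(q100$gene_id), sprintf("g%03d", 1:100))
  expect_error(quartiles_by_key(tibble::tibble(gene_id = "a", key = 1)),
               "4 genes")
})

test_that("kmeans separates planted profiles and honors degenerate k", {
  # two groups of identical rows, far apart: perfect recovery
  x <- rbind(matrix(0, 5, 8), matrix(100, 5, 8))
  m <- make_pm(x, sprintf("g%02d", 1:10), 1:8)
  km <- kmeans_profiles(m, k = 2, seed = 1, n_init = 5)
  expect_equal(adjusted_rand_index(km$cluster, rep(1:2, each = 5)), 1)

  # k = n_genes: every gene its own cluster, WCSS 0
  m2 <- make_pm(matrix(rnorm(5 * 4), 5), sprintf("g%d", 1:5), 1:4)
  km2 <- kmeans_profiles(m2, k = 5, seed = 1, n_init = 3)
  expect_equal(sort(km2$cluster), 1:5)
  expect_equal(attr(km2, "wcss"), 0)

  expect_error(kmeans_profiles(m2, k = 6), "number of genes")
  expect_error(kmeans_profiles(m2, k = 1), "k")

  # determinism given seed
  km3 <- kmeans_profiles(m, k = 2, seed = 7, n_init = 5)
  km4 <- kmeans_profiles(m, k = 2, seed = 7, n_init = 5)
  expect_identical(km3$cluster, km4$cluster)
})

test_that("kmeans matches stats::kmeans on well-separated data and never exceeds its WCSS by much", {
  set.seed(33)
  centers <- matrix(rnorm(3 * 10, sd = 10), 3)
  x <- centers[rep(1:3, each = 20), ] + matrix(rnorm(60 * 10), 60)
  m <- make_pm(x, sprintf("g%02d", 1:60), 1:10)
  km <- kmeans_profiles(m, k = 3, seed = 2, n_init = 10)
  ref <- stats::kmeans(x, centers = 3, nstart = 10)
  expect_equal(adjusted_rand_index(km$cluster, ref$cluster), 1)
  expect_lt(attr(km, "wcss"), ref$tot.withinss * (1 + 1e-6) + 1e-6)

  # NA rows are mean-imputed and flagged
  x_na <- x; x_na[1, 3] <- NA
  km_na <- kmeans_profiles(make_pm(x_na, sprintf("g%02d", 1:60), 1:10),
                           k = 3, seed = 2, n_init = 5)
  expect_equal(attr(km_na, "imputed"), "g01")
})

test_that("cluster averages equal brute-force group means", {
  m <- make_pm(rbind(c(0, 2), c(2, 0)), c("gA", "gB"), 1:2)
  grp <- tibble::tibble(gene_id = c("gA", "gB"), cluster = c(1, 1))
  prof <- cluster_average_profiles(m, grp)
  expect_equal(prof$value, c(1, 1))
  expect_equal(prof$n_genes, c(2L, 2L))

  # single-gene group is its own row
  grp1 <- tibble::tibble(gene_id = c("gA", "gB"), cluster = c(1, 2))
  p1 <- cluster_average_profiles(m, grp1)
  expect_equal(p1$value[p1$group == 1], c(0, 2))

  set.seed(12)
  big <- make_pm(matrix(rnorm(20 * 6), 20), sprintf("g%02d", 1:20), 1:6)
  groups <- tibble::tibble(gene_id = big$gene_id,
                           cluster = sample(1:3, 20, TRUE))
  prof2 <- cluster_average_profiles(big, groups)
  for (g in 1:3) {
    rows <- which(groups$cluster == g)
    want <- colMeans(as.matrix(big)[rows, , drop = FALSE])
    got <- prof2$value[prof2$group == g][order(prof2$offset[prof2$group == g])]
    expect_equal(got, unname(want))
  }
  # whole matrix as one group = column means
  all1 <- cluster_average_profiles(big, tibble::tibble(
    gene_id = big$gene_id, cluster = 1
  ))
  expect_equal(all1$value, unname(colMeans(as.matrix(big))))

  expect_error(cluster_average_profiles(big, groups[-1, ]), "assigned")
})

test_that("peak matrices localize overlap and match the brute-force oracle", {
  ann <- make_annotation(c("gA", "gB"), "chr1", c(1000, 9000), c("+", "+"),
                         flank = 1000)
  nfr_peak <- tibble::tibble(chrom = "chr1", start = 950L, end = 1041L,
                             name = "p1", score = 0, strand = ".",
                             signal_value = 7, p_value = -1, q_value = -1,
                             summit = 45L, factor = "NFkB")
  pm <- peak_matrix(nfr_peak, ann)
  vals <- as.matrix(pm)
  hot <- pm_centers(pm)[vals["gA", ] > 0]
  expect_true(all(hot >= -80 & hot <= 71))
  expect_true(all(vals["gB", ] == 0))
  expect_true(all(vals["gA", vals["gA", ] > 0] == 7))

  # empty peak set: zero matrix
  expect_true(all(as.matrix(peak_matrix(nfr_peak[0, ], ann)) == 0))

  set.seed(17)
  fix <- random_fixture(77, n_genes = 3, n_frags = 10, flank = 150)
  s <- sample.int(4000, 12)
  peaks <- tibble::tibble(chrom = sample(c("chrA", "chrB"), 12, TRUE),
                          start = s, end = s + sample(50:400, 12, TRUE),
                          name = sprintf("p%d", 1:12), score = 0,
                          strand = ".", signal_value = runif(12, 1, 20),
                          p_value = -1, q_value = -1, summit = -1L,
                          factor = "Pu1")
  for (mode in c("signal", "binary")) {
    got <- peak_matrix(peaks, fix$annotation, window = 60, step = 10,
                       mode = mode)
    want <- oracle_peak_matrix(peaks, fix$annotation, 60, 10, fix$flank,
                               mode)
    expect_equal(unname(as.matrix(got)), want)
  }
})

test_that("adjusted Rand index agrees with pair counting", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(19)
  for (i in 1:5) {
    x <- sample(1:3, 12, TRUE)
    y <- sample(1:4, 12, TRUE)
    expect_equal(adjusted_rand_index(x, y), oracle_ari(x, y))
  }
})
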