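test_that("config invariants are enforced", {
  expect_error(simulation_config(n_genes = 3), "n_genes")
  expect_error(simulation_config(depth = 0), "depth")
  expect_error(simulation_config(frag_len_min = 200, frag_len_max = 100),
               "bounds")
  expect_error(simulation_config(release_light = 1.5), "probabilities")
  expect_error(simulation_config(dyad_offsets = c(-2000, 0)), "flank")
  expect_error(simulation_config(background = 2), "background")
})

test_that("simulation is deterministic and conserves per-gene depth", {
  cfg <- simulation_config(n_genes = 12, depth = 80, seed = 7,
                           randomize_strand = TRUE)
  sim1 <- simulate_experiment(cfg)
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim1$genes, sim2$genes)
  expect_identical(sim1$fragments, sim2$fragments)

  # byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(sim1, d1); write_simulation(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }

  # exactly `depth` fragments per gene per digest (conservation)
  fr <- sim1$fragments$untreated$light
  mids <- fr$start + (fr$end - fr$start) %/% 2L
  for (g in seq_len(nrow(sim1$genes))) {
    in_win <- sum(mids >= sim1$genes$tss[g] - cfg$flank &
                    mids < sim1$genes$tss[g] + cfg$flank)
    expect_equal(in_win, cfg$depth)
  }

  # all lengths inside the truncation bounds
  for (cond in names(sim1$fragments)) {
    for (dg in c("light", "heavy")) {
      len <- with(sim1$fragments[[cond]][[dg]], end - start)
      expect_true(all(len >= cfg$frag_len_min & len <= cfg$frag_len_max))
    }
  }
})

test_that("degenerate single-dyad config places every midpoint at TSS-100", {
  cfg <- simulation_config(
    n_genes = 4, depth = 10, seed = 1, jitter_sd = 0, background = 0,
    frag_len_sd = 0, frag_len_mean = 150,
    dyad_offsets = -100, occupancy = 1, effect_dyad = -100,
    conditions = "untreated"
  )
  sim <- simulate_experiment(cfg)
  fr <- sim$fragments$untreated$light
  mids <- fr$start + (fr$end - fr$start) %/% 2L
  expected <- rep(sim$genes$tss - 100L, each = 10)
  expect_equal(sort(mids), sort(expected))
  expect_true(all(fr$end - fr$start == 150))
})

test_that("dyad shares follow the exact multinomial expectation of the sampling weights", {
  # light releases the first dyad twice as readily as heavy; other dyads equal
  k <- 6
  cfg <- simulation_config(
    n_genes = 4, depth = 20000, seed = 5, jitter_sd = 0, background = 0,
    frag_len_sd = 0,
    release_light = c(1, rep(0.5, k - 1)), release_heavy = rep(0.5, k)
  )
  sim <- simulate_experiment(cfg)
  d1_pos <- sim$genes$tss[1] + cfg$dyad_offsets[1]
  share <- function(fr) {
    mids <- fr$start + (fr$end - fr$start) %/% 2L
    win <- mids >= sim$genes$tss[1] - cfg$flank &
      mids < sim$genes$tss[1] + cfg$flank
    mean(mids[win] == d1_pos)
  }
  p_light <- share(sim$fragments$untreated$light)
  p_heavy <- share(sim$fragments$untreated$heavy)
  # oracle: multinomial expectations from the weights
  exp_light <- 2 / (2 + (k - 1))
  exp_heavy <- 1 / k
  tol <- 4 * sqrt(exp_light * (1 - exp_light) / cfg$depth)
  expect_lt(abs(p_light - exp_light), tol)
  expect_lt(abs(p_heavy - exp_heavy), tol)
  expect_gt(p_light, p_heavy)
  # weight ratio recovered: share ratio -> (2k)/(k+1)
  expect_lt(abs(p_light / p_heavy - 2 * k / (k + 1)), 0.1)
})

test_that("pure background fragments are uniform over the window", {
  cfg <- simulation_config(n_genes = 4, depth = 10000, seed = 9,
                           background = 1)
  sim <- simulate_experiment(cfg)
  fr <- sim$fragments$untreated$light
  mids <- fr$start + (fr$end - fr$start) %/% 2L
  off <- mids - sim$genes$tss[1]
  off <- off[off >= -cfg$flank & off < cfg$flank]
  bins <- cut(off, breaks = seq(-cfg$flank, cfg$flank, length.out = 21))
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("null effect leaves conditions statistically exchangeable", {
  # effect_size 1: the -1 dyad weight is never modified, so both conditions
  # draw from identical distributions (different streams)
  cfg <- simulation_config(n_genes = 8, depth = 4000, seed = 3,
                           effect_size = 1)
  sim <- simulate_experiment(cfg)
  expect_equal(unname(cfg$condition_effects), c(1, 1))
  d1 <- sim$genes$tss[1] - 100L
  cnt <- function(fr) {
    mids <- fr$start + (fr$end - fr$start) %/% 2L
    sum(abs(mids - d1) <= 30)
  }
  n_un <- cnt(sim$fragments$untreated$light)
  n_20 <- cnt(sim$fragments$`20min`$light)
  # equal expected counts: difference within 5 sd of binomial noise
  expect_lt(abs(n_un - n_20), 5 * sqrt(n_un + n_20))
})
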