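## Synthetic mTSS-seq digestion simulator.
##
## The generative model: each promoter carries positioned nucleosomes at
## canonical dyad offsets (-3..-1, +1..+3 relative to the TSS) around a
## nucleosome-free region (NFR) at the TSS. A digest releases a fragment
## from a dyad with probability proportional to occupancy x release
## probability; the contrast between light- and heavy-digest release
## probabilities encodes MNase sensitivity. Fragment midpoints scatter
## around the dyad with Gaussian jitter; fragment lengths come from a
## truncated normal centred on the ~150 bp mononucleosomal band; a fixed
## fraction of fragments is uniform background.

#' Configuration for the synthetic digestion simulator
#'
#' Defaults state the simulated world: a 2 kb promoter window, six
#' positioned nucleosomes at offsets -350, -200, -100, +50, +200, +350 with
#' an NFR over about -50..+40, mononucleosome fragment lengths ~N(150, 10)
#' truncated to 120-180 bp, dyad jitter sd 20 bp, 15% uniform background,
#' and equal light/heavy release probabilities of 0.5 everywhere except the
#' planted effect: in stimulated conditions the -1 dyad (offset -100) of
#' top-expression-tier "treated" genes has its light release probability
#' multiplied by `effect_size` (default 2.0, i.e. raised to 1.0).
#'
#' @param n_genes number of promoters (>= 4 so quartiles are non-empty).
#' @param flank bp on each side of the TSS.
#' @param depth fragments per gene per digest per condition (emitted
#'   exactly).
#' @param seed single global seed; per-gene random streams are derived from
#'   it via a seed table so gene subsets reproduce exactly.
#' @param effect_size multiplier on `release_light` at the `effect_dyad` of
#'   treated genes in non-baseline conditions (1 = null).
#' @param background fraction of fragments placed uniformly in the window.
#' @param frag_len_mean,frag_len_sd,frag_len_min,frag_len_max truncated
#'   normal fragment-length distribution (bp).
#' @param jitter_sd Gaussian sd of midpoint scatter around the dyad (bp).
#' @param conditions condition labels; the first is the unstimulated
#'   baseline and receives no effect.
#' @param dyad_offsets nucleosome dyad offsets relative to the TSS (bp,
#'   strand-oriented).
#' @param occupancy per-dyad non-negative occupancy weights.
#' @param release_light,release_heavy per-dyad release probabilities in
#'   \[0, 1\] (scalars are recycled).
#' @param effect_dyad the dyad offset that carries the planted effect
#'   (default -100, the -1 nucleosome).
#' @param tf_peak_fraction fraction of top-tier genes given a TF peak in
#'   their NFR.
#' @param randomize_strand if `TRUE`, gene strands are drawn at random to
#'   exercise orientation code (default all `+`).
#' @param chrom name of the synthetic chromosome.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 500, flank = 1000, depth = 2000,
                              seed = 1, effect_size = 2, background = 0.15,
                              frag_len_mean = 150, frag_len_sd = 10,
                              frag_len_min = 120, frag_len_max = 180,
                              jitter_sd = 20,
                              conditions = c("untreated", "20min"),
                              dyad_offsets = c(-350, -200, -100, 50, 200, 350),
                              occupancy = 1,
                              release_light = 0.5, release_heavy = 0.5,
                              effect_dyad = -100, tf_peak_fraction = 0.5,
                              randomize_strand = FALSE, chrom = "chrSim1") {
  if (n_genes < 4) abort("`n_genes` must be >= 4 (quartiles non-empty).")
  if (depth <= 0) abort("`depth` must be > 0.")
  if (!(frag_len_min > 0 && frag_len_min < frag_len_max)) {
    abort("Fragment length truncation bounds must satisfy 0 < min < max.")
  }
  if (background < 0 || background > 1) {
    abort("`background` must be in [0, 1].")
  }
  k <- length(dyad_offsets)
  occupancy <- rep_len(occupancy, k)
  release_light <- rep_len(release_light, k)
  release_heavy <- rep_len(release_heavy, k)
  if (any(occupancy < 0)) abort("Occupancy weights must be >= 0.")
  if (any(release_light < 0 | release_light > 1) ||
      any(release_heavy < 0 | release_heavy > 1)) {
    abort("Release probabilities must be in [0, 1].")
  }
  if (any(abs(dyad_offsets) > flank)) {
    abort("Dyad offsets must lie within +/- flank.")
  }
  if (effect_size < 0) abort("`effect_size` must be >= 0.")
  if (!effect_dyad %in% dyad_offsets) {
    abort("`effect_dyad` must be one of `dyad_offsets`.")
  }
  if (length(conditions) < 1 || anyDuplicated(conditions)) {
    abort("`conditions` must be a non-empty set of unique labels.")
  }
  condition_effects <- c(1, rep(effect_size, length(conditions) - 1))
  names(condition_effects) <- conditions
  structure(list(
    n_genes = as.integer(n_genes), flank = as.integer(flank),
    depth = as.integer(depth), seed = as.integer(seed),
    effect_size = effect_size, background = background,
    frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
    frag_len_min = frag_len_min, frag_len_max = frag_len_max,
    jitter_sd = jitter_sd, conditions = conditions,
    dyad_offsets = dyad_offsets, occupancy = occupancy,
    release_light = release_light, release_heavy = release_heavy,
    effect_dyad = effect_dyad, condition_effects = condition_effects,
    tf_peak_fraction = tf_peak_fraction,
    randomize_strand = isTRUE(randomize_strand), chrom = chrom
  ), class = "simulation_config")
}

## Expression is drawn log-uniform from disjoint per-tier ranges so that
## expression tiers are strictly ordered (Q1 highest).
tier_expression_range <- function(tier) {
  switch(tier,
    Q1 = c(1e3, 1e4), Q2 = c(1e2, 1e3), Q3 = c(10, 100), Q4 = c(0.1, 10)
  )
}

## Contiguous quartile sizes, earlier quartiles get the remainder.
quartile_sizes <- function(n) {
  base <- n %/% 4L
  sizes <- rep(base, 4L)
  r <- n %% 4L
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  sizes
}

#' Generate synthetic promoter ground truth
#'
#' Places `n_genes` promoters on one synthetic chromosome with
#' non-overlapping windows (spacing `2*flank + 1000` bp), assigns
#' expression tiers Q1..Q4 (Q1 highest) with log-uniform expression from
#' disjoint per-tier ranges, marks all Q1 genes as "treated" (carriers of
#' the planted -1 sensitivity effect in stimulated conditions), places TF
#' peaks in the NFR of a random `tf_peak_fraction` of Q1 genes, and draws
#' the per-gene random-stream seed table. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a `promoter_truth` list: `genes` (gene-level tibble), `dyads`
#'   (per-dyad occupancies and release probabilities), `annotation`
#'   (TSS annotation), `expression`, `peaks` (narrowPeak-style tibble),
#'   `streams` (seed table), `config`.
#' @export
simulate_truth <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from simulation_config().")
  }
  n <- config$n_genes
  set.seed(config$seed)
  ## Draw order below is fixed; do not reorder (determinism contract).
  n_streams <- n * 2L * length(config$conditions)
  streams <- sample.int(.Machine$integer.max - 1L, n_streams)
  gene_id <- sprintf("g%05d", seq_len(n))
  spacing <- 2L * config$flank + 1000L
  tss <- config$flank + 500L + (seq_len(n) - 1L) * spacing
  strand <- if (config$randomize_strand) {
    sample(c("+", "-"), n, replace = TRUE)
  } else rep("+", n)
  sizes <- quartile_sizes(n)
  tier <- rep(c("Q1", "Q2", "Q3", "Q4"), times = sizes)
  lr <- vapply(tier, tier_expression_range, numeric(2))
  expression <- exp(runif(n, log(lr[1, ]), log(lr[2, ])))
  treated <- tier == "Q1"
  q1_idx <- which(treated)
  n_peak <- round(config$tf_peak_fraction * length(q1_idx))
  peak_idx <- sort(sample(q1_idx, n_peak))
  has_tf_peak <- seq_len(n) %in% peak_idx

  genes <- tibble(
    gene_id = gene_id, chrom = config$chrom, tss = tss, strand = strand,
    tier = tier, treated = treated, has_tf_peak = has_tf_peak,
    expression = expression
  )
  k <- length(config$dyad_offsets)
  dyads <- tibble(
    gene_id = rep(gene_id, each = k),
    offset = rep(config$dyad_offsets, n),
    occupancy = rep(config$occupancy, n),
    release_light = rep(config$release_light, n),
    release_heavy = rep(config$release_heavy, n)
  )
  annotation <- tss_annotation(genes[c("gene_id", "chrom", "tss", "strand")],
                               flank = config$flank)
  peaks <- synth_nfr_peaks(genes[genes$has_tf_peak, ])
  stream_tbl <- expand.grid(
    gene_index = seq_len(n), digest = c("light", "heavy"),
    condition = config$conditions,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  stream_tbl$seed <- streams
  structure(list(
    genes = genes, dyads = dyads, annotation = annotation,
    expression = genes[c("gene_id", "expression")],
    peaks = peaks, streams = as_tibble(stream_tbl), config = config
  ), class = "promoter_truth")
}

## TF peaks spanning the NFR (oriented offsets about -50..+40) of the
## designated genes; signalValue log-uniform in [5, 50].
synth_nfr_peaks <- function(genes, factor = "NFkB") {
  n <- nrow(genes)
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character(),
                  signal_value = numeric(), p_value = numeric(),
                  q_value = numeric(), summit = integer(), factor = character()))
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - 50L, genes$tss - 40L)
  end <- ifelse(plus, genes$tss + 41L, genes$tss + 51L)
  tibble(
    chrom = genes$chrom, start = as.integer(start), end = as.integer(end),
    name = paste0("peak_", genes$gene_id), score = 0, strand = ".",
    signal_value = exp(runif(n, log(5), log(50))),
    p_value = -1, q_value = -1, summit = as.integer((end - start) %/% 2),
    factor = factor
  )
}

## Truncated-normal draw via inverse CDF (exact truncation, vectorized).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

stream_seed <- function(truth, gene_index, digest, condition) {
  s <- truth$streams
  hit <- s$gene_index == gene_index & s$digest == digest &
    s$condition == condition
  s$seed[hit][1]
}

#' Simulate one MNase digest of the synthetic promoters
#'
#' For each gene, emits exactly `depth` fragments: a `background` fraction
#' placed uniformly in the promoter window, the remainder assigned to
#' nucleosome dyads with probability proportional to
#' `occupancy x release_prob(digest, condition)`, midpoints jittered with
#' Gaussian sd `jitter_sd`, lengths from the truncated normal. In
#' non-baseline conditions the light-digest release probability at the
#' effect dyad of treated genes is multiplied by the configured condition
#' effect (capped at 1). Deterministic given the truth's seed table.
#'
#' @param truth a `promoter_truth` from [simulate_truth()].
#' @param digest `"light"` or `"heavy"`.
#' @param condition one of `config$conditions`.
#' @param config simulation config; defaults to the one inside `truth`.
#' @return fragment tibble (`chrom`, `start`, `end`) with a `label`
#'   attribute `list(digest=, condition=)`.
#' @export
simulate_digest <- function(truth, digest = c("light", "heavy"), condition,
                            config = truth$config) {
  if (!inherits(truth, "promoter_truth")) {
    abort("`truth` must come from simulate_truth().")
  }
  digest <- match.arg(digest)
  if (!condition %in% config$conditions) {
    abort(paste0("Unknown condition: ", condition))
  }
  genes <- truth$genes
  n <- nrow(genes)
  k <- length(config$dyad_offsets)
  depth <- config$depth
  n_bg <- as.integer(round(depth * config$background))
  n_nuc <- depth - n_bg
  eff <- unname(config$condition_effects[condition])
  eff_j <- match(config$effect_dyad, config$dyad_offsets)
  streams <- truth$streams[truth$streams$digest == digest &
                             truth$streams$condition == condition, ]
  seeds <- streams$seed[order(streams$gene_index)]
  dy <- truth$dyads
  occ_m <- matrix(dy$occupancy, nrow = k)
  rel_m <- if (digest == "light") matrix(dy$release_light, nrow = k) else
    matrix(dy$release_heavy, nrow = k)

  chroms <- starts <- ends <- vector("list", n)
  for (g in seq_len(n)) {
    set.seed(seeds[g])
    rel <- rel_m[, g]
    if (digest == "light" && genes$treated[g] && eff != 1) {
      rel[eff_j] <- min(1, rel[eff_j] * eff)
    }
    w <- occ_m[, g] * rel
    tss <- genes$tss[g]
    sign <- if (genes$strand[g] == "+") 1L else -1L
    if (n_nuc > 0) {
      if (sum(w) <= 0) abort("All dyad sampling weights are zero.")
      di <- sample.int(k, n_nuc, replace = TRUE, prob = w)
      jit <- if (config$jitter_sd > 0) {
        round(rnorm(n_nuc, 0, config$jitter_sd))
      } else 0
      mid_nuc <- tss + sign * config$dyad_offsets[di] + jit
    } else mid_nuc <- integer(0)
    mid_bg <- if (n_bg > 0) {
      floor(runif(n_bg, tss - config$flank, tss + config$flank))
    } else integer(0)
    mid <- c(mid_nuc, mid_bg)
    len <- pmin(pmax(round(rtruncnorm(
      depth, config$frag_len_mean, config$frag_len_sd,
      config$frag_len_min, config$frag_len_max
    )), config$frag_len_min), config$frag_len_max)
    s <- as.integer(mid - len %/% 2L)
    chroms[[g]] <- rep(genes$chrom[g], depth)
    starts[[g]] <- s
    ends[[g]] <- as.integer(s + len)
  }
  fragment_set(
    tibble(chrom = unlist(chroms), start = unlist(starts),
           end = unlist(ends)),
    label = list(digest = digest, condition = condition)
  )
}

#' Simulate a full light/heavy, multi-condition experiment
#'
#' @param config a [simulation_config()].
#' @return list with the truth bundle plus `fragments`, a nested named list
#'   `fragments[[condition]][[digest]]`.
#' @export
simulate_experiment <- function(config) {
  truth <- simulate_truth(config)
  fragments <- lapply(config$conditions, function(cond) {
    list(light = simulate_digest(truth, "light", cond),
         heavy = simulate_digest(truth, "heavy", cond))
  })
  names(fragments) <- config$conditions
  c(truth, list(fragments = fragments))
}

#' Write a simulated experiment to plain-text files
#'
#' Emits BED3 fragments per digest/condition, a BED6 TSS annotation, the
#' expression TSV, a narrowPeak file, and gene/dyad ground-truth TSVs.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(sim$fragments)) {
    for (dg in names(sim$fragments[[cond]])) {
      write_fragments_bed(sim$fragments[[cond]][[dg]],
                          file.path(dir, paste0("fragments_", dg, "_",
                                                cond, ".bed")))
    }
  }
  write_tss_bed(sim$annotation, file.path(dir, "tss.bed"),
                span = 2L * sim$config$flank)
  write_expression_table(sim$expression, file.path(dir, "expression.tsv"))
  if (nrow(sim$peaks) > 0) {
    write_narrowpeak(sim$peaks, file.path(dir, "peaks_NFkB.narrowPeak"))
  }
  readr::write_tsv(sim$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(sim$dyads, file.path(dir, "truth_dyads.tsv"))
  invisible(dir)
}
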