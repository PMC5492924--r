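test_that("identical seeds give bitwise-identical datasets", {
  cfg <- sim_config(n_genera = 50, genomes_per_genus = c(1, 3),
                    n_cogs = 30, seed = 7)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1, ds2)
})

test_that("degenerate configurations behave as specified", {
  # zero detection probability: no observation rows, full census
  cfg <- sim_config(n_genera = 5, n_environments = 4,
                    samples_per_environment = 50,
                    baseline_detection_prob = 0, n_cogs = 10, seed = 1)
  obs <- simulate_dataset(cfg)$observations
  expect_identical(nrow(obs), 0L)
  expect_identical(nrow(attr(obs, "samples")), 200L)
  expect_identical(length(unique(attr(obs, "samples")$sample_id)), 200L)

  # zero slope and zero noise: every genome exactly the intercept
  cfg <- sim_config(n_genera = 6, size_slope_per_env = 0,
                    size_noise_sd = 0, size_intercept = 3e6,
                    n_cogs = 10, seed = 2)
  gs <- simulate_dataset(cfg)$genomes
  expect_true(all(gs$genomes$genome_size == 3e6))

  # zero substitution rate: all 16S copies identical within a genome
  cfg <- sim_config(n_genera = 4, rrna_substitution_rate = 0,
                    n_cogs = 10, seed = 3)
  gs <- simulate_dataset(cfg)$genomes
  expect_true(all(gs$genomes$rrna16s_distinct == 1L))

  expect_error(sim_config(n_genera = 0), "config error")
  expect_error(sim_config(baseline_detection_prob = 1.5), "0, 1")
})

test_that("null tables carry no planted structure and vary by seed", {
  cfg <- sim_config(n_genera = 8, seed = 11, n_cogs = 10,
                    preference_map = data.frame(
                      genus = "g001", environment = "env1",
                      multiplier = 20))
  obs <- simulate_null_observations(cfg)
  truth <- attr(obs, "truth")
  expect_identical(nrow(truth$planted_links), 0L)
  expect_true(all(truth$planted_ubiquity == 1L))
  cfg2 <- cfg
  cfg2$seed <- 12
  obs2 <- simulate_null_observations(cfg2)
  # statistical, not logical: two seeds coincide with negligible probability
  expect_false(identical(as.data.frame(obs), as.data.frame(obs2)))
})

test_that("detection frequencies converge to the odds-scaled probability", {
  mult <- 5
  p0 <- 0.1
  cfg <- sim_config(n_genera = 5, n_environments = 2,
                    samples_per_environment = 1000,
                    baseline_detection_prob = p0, n_cogs = 10,
                    genomes_per_genus = 1, seed = 21,
                    preference_map = data.frame(
                      genus = "g001", environment = "env1",
                      multiplier = mult))
  obs <- simulate_dataset(cfg)$observations
  census <- attr(obs, "samples")
  p_exp <- (mult * p0 / (1 - p0)) / (1 + mult * p0 / (1 - p0))
  for (e in c("env1", "env2")) {
    n_e <- sum(census$environment == e)
    hits <- sum(obs$genus == "g001" & obs$environment == e)
    p_true <- if (e == "env1") p_exp else p0
    expect_lt(abs(hits / n_e - p_true),
              3 * sqrt(p_true * (1 - p_true) / n_e))
  }
})

test_that("genome sizes follow the planted linear model per ubiquity class", {
  pm <- data.frame(
    genus = rep(sprintf("g%03d", 1:30), times = rep(1:3, each = 10)),
    environment = unlist(lapply(rep(1:3, each = 10), function(k)
      sprintf("env%d", seq_len(k)))),
    multiplier = 5)
  cfg <- sim_config(n_genera = 30, genomes_per_genus = 10,
                    n_environments = 4, samples_per_environment = 5,
                    size_intercept = 3e6, size_slope_per_env = 2e5,
                    size_noise_sd = 3e5, n_cogs = 10,
                    preference_map = pm, seed = 31)
  ds <- simulate_dataset(cfg)
  g <- ds$genomes$genomes
  u <- ds$truth$planted_ubiquity[g$genus]
  for (uu in 1:3) {
    sizes <- g$genome_size[u == uu]
    expect_lt(abs(mean(sizes) - (3e6 + 2e5 * uu)),
              3 * 3e5 / sqrt(length(sizes)))
  }
})

test_that("annotation ratios are truncated to (0,1] with the right mean", {
  cfg <- sim_config(n_genera = 250, genomes_per_genus = 8,
                    n_environments = 2, samples_per_environment = 5,
                    n_cogs = 10, seed = 41)
  gs <- simulate_dataset(cfg)$genomes
  r <- annotation_ratio(gs)
  expect_identical(length(r), 2000L)
  expect_true(all(r > 0 & r <= 1))
  expect_lt(abs(mean(r) - 0.715), 0.02)
})

test_that("written dataset round-trips through the text formats", {
  cfg <- sim_config(n_genera = 4, genomes_per_genus = 2,
                    n_environments = 3, samples_per_environment = 10,
                    n_cogs = 15, size_intercept = 5e5,
                    size_noise_sd = 5e4, seed = 51)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  gs2 <- read_genome_annotations(paths["annotations"])
  expect_identical(gs2$genomes$genome_id, ds$genomes$genomes$genome_id)
  expect_identical(gs2$genomes$n_annotated_orfs,
                   ds$genomes$genomes$n_annotated_orfs)
  cogs <- colnames(ds$genomes$cog_counts)
  present <- cogs[colSums(ds$genomes$cog_counts) > 0]
  expect_identical(gs2$cog_counts[, sort(present), drop = FALSE],
                   ds$genomes$cog_counts[, sort(present), drop = FALSE])
  gs2 <- attach_rrna(gs2, fasta = paths["rrna"])
  expect_identical(gs2$genomes$rrna16s_copies,
                   ds$genomes$genomes$rrna16s_copies)
  expect_identical(gs2$genomes$rrna16s_distinct,
                   ds$genomes$genomes$rrna16s_distinct)
  obs2 <- read_observation_table(paths["observations"], paths["samples"])
  expect_identical(as.data.frame(obs2), as.data.frame(ds$observations))
})
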