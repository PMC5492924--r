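test_that("observation tables enforce the one-environment-per-sample rule", {
  bad <- data.frame(sample_id = c("s1", "s1"),
                    environment = c("envA", "envB"),
                    genus = c("gA", "gB"))
  expect_error(observation_table(bad), "more than one environment")
  dup <- data.frame(sample_id = c("s1", "s1"), environment = "envA",
                    genus = c("gA", "gA"))
  expect_error(observation_table(dup), "duplicated")
})

test_that("frequency table applies the single-sample exclusion per cell", {
  obs <- obs_from_counts(list(envA = list(gA = 1),
                              envB = list(gA = 3),
                              envC = list()))
  freq <- build_frequency_table(obs)
  expect_identical(freq$counts["gA", "envA"], 0L)  # observed once: excluded
  expect_identical(freq$counts["gA", "envB"], 3L)
  expect_identical(freq$counts["gA", "envC"], 0L)  # never observed
  expect_identical(unname(freq$env_totals), c(10L, 10L, 10L))
})

test_that("enrichment p-values are the exact hypergeometric upper tail", {
  expect_equal(fisher_enrichment(2, 2, 2, 2), 53 / 70)
  expect_equal(fisher_enrichment(5, 0, 0, 5), 1 / 252)
  expect_equal(fisher_enrichment(0, 0, 0, 0), 1)
  expect_error(fisher_enrichment(-1, 0, 0, 0), "negative")
  # cross-check against the one-sided Fisher exact test on random tables
  set.seed(5)
  for (i in 1:25) {
    cells <- rpois(4, 6)
    ref <- fisher.test(matrix(cells[c(1, 3, 2, 4)], 2),
                       alternative = "greater")$p.value
    expect_equal(fisher_enrichment(cells[1], cells[2], cells[3], cells[4]),
                 ref, tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the step-up examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("link_taxa builds sample-level tables with conserved margins", {
  obs <- obs_from_counts(list(envA = list(gA = 6, gB = 2),
                              envB = list(gA = 2, gB = 7),
                              envC = list(gB = 3)),
                         samples_per_env = 12)
  freq <- build_frequency_table(obs)
  assoc <- link_taxa(freq, alpha = 0.05)
  # only count>0 cells tested; family size equals the tested pairs
  expect_identical(attr(assoc, "n_tested"), sum(freq$counts > 0))
  expect_true(all(assoc$a + assoc$b + assoc$c + assoc$d == 36))
  expect_true(all(assoc$a + assoc$b ==
                    freq$env_totals[assoc$environment]))
  expect_true(all(assoc$adjusted_p >= assoc$raw_p))
  expect_true(all(assoc$linked == (assoc$adjusted_p < 0.05)))
  # cells: gA in envA -> a=6, b=6, c=2 (envB), d=22
  row <- assoc[assoc$genus == "gA" & assoc$environment == "envA", ]
  expect_identical(unlist(row[c("a", "b", "c", "d")], use.names = FALSE),
                   c(6L, 6L, 2L, 22L))
  expect_equal(row$raw_p, fisher_enrichment(6, 6, 2, 22))
})

test_that("a single tested pair is its own adjustment family", {
  obs <- obs_from_counts(list(envA = list(gA = 8), envB = list()),
                         samples_per_env = 10)
  assoc <- link_taxa(build_frequency_table(obs))
  expect_identical(nrow(as.data.frame(assoc)), 1L)
  expect_equal(assoc$adjusted_p, assoc$raw_p)
  expect_identical(assoc$linked, assoc$raw_p < 0.01)
})

test_that("two-sided alternative uses the Fisher exact test", {
  obs <- obs_from_counts(list(envA = list(gA = 6, gB = 2),
                              envB = list(gA = 2, gB = 7)),
                         samples_per_env = 12)
  freq <- build_frequency_table(obs)
  two <- link_taxa(freq, alternative = "two.sided")
  row <- two[two$genus == "gA" & two$environment == "envA", ]
  ref <- fisher.test(matrix(c(row$a, row$c, row$b, row$d), 2),
                     alternative = "two.sided")$p.value
  expect_equal(row$raw_p, ref)
})

test_that("ubiquity counts post-exclusion environments", {
  obs <- obs_from_counts(list(envA = list(gA = 3, gB = 1),
                              envB = list(gA = 2, gB = 5),
                              envC = list()))
  freq <- build_frequency_table(obs)
  u <- ubiquity(freq)
  expect_identical(u[["gA"]], 2L)
  expect_identical(u[["gB"]], 1L)  # the single-sample envA cell was zeroed
  # excluded everywhere
  obs2 <- obs_from_counts(list(envA = list(gA = 1, gB = 2),
                               envB = list(gA = 1, gB = 2)))
  expect_identical(ubiquity(build_frequency_table(obs2))[["gA"]], 0L)
})

test_that("randomization control is seeded and near-silent on one genus", {
  obs <- obs_from_counts(list(envA = list(gA = 5), envB = list(gA = 3)),
                         samples_per_env = 15)
  r1 <- randomization_control(obs, n_tables = 20, seed = 9)
  r2 <- randomization_control(obs, n_tables = 20, seed = 9)
  expect_identical(r1$linked_per_table, r2$linked_per_table)
  # a lone genus tested against m = 1 families can yield at most one link
  expect_true(all(r1$linked_per_table %in% 0:2))
  expect_error(randomization_control(obs, n_tables = 0), "n_tables")
})

test_that("observation tables round-trip through TSV", {
  obs <- obs_from_counts(list(envA = list(gA = 2, gB = 3),
                              envB = list(gA = 4)))
  dir <- withr::local_tempdir()
  op <- file.path(dir, "obs.tsv")
  sp <- file.path(dir, "samples.tsv")
  utils::write.table(as.data.frame(obs), op, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(attr(obs, "samples"), sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_observation_table(op, sp)
  expect_equal(as.data.frame(back), as.data.frame(obs))
  expect_equal(attr(back, "samples"), attr(obs, "samples"))
})
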