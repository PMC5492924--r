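test_that("simple OLS reports slope, R-squared and slope p-value", {
  x <- 1:5
  fit <- linear_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  # hand OLS: Sxy = 4, Sxx = 5 -> slope 0.8; r = 0.8 -> R^2 = 0.64
  fit <- linear_regression(c(1, 2, 3, 4), c(1, 2, 4, 3))
  expect_equal(fit$slope, 0.8)
  expect_equal(fit$r_squared, 0.64)
  expect_equal(fit$adjusted_r_squared, 1 - (1 - 0.64) * 3 / 2)

  # zero-variance response is defined, not an error
  fit <- linear_regression(1:4, rep(2, 4))
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$p_value, 1)

  expect_error(linear_regression(rep(1, 4), 1:4), "constant predictor")
  expect_error(linear_regression(1:2, 1:2), "at least 3")
})

test_that("R-squared equals the squared Pearson correlation", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(20)
    y <- 0.5 * x + rnorm(20)
    expect_equal(linear_regression(x, y)$r_squared, cor(x, y)^2)
  }
})

test_that("Kruskal-Wallis H matches the rank formula and handles ties", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7,
               tolerance = 1e-12)
  kw0 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty group")
})

test_that("Mann-Whitney exact p-values match the enumeration examples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p_value, 0.1)  # 2/20 rankings as or more extreme
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "empty group")
})

test_that("exact and approximate Mann-Whitney agree at moderate n", {
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(25)
    y <- rnorm(25, 0.3)
    pe <- mann_whitney(x, y, exact = TRUE)$p_value
    pa <- mann_whitney(x, y, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(19)
  x <- rnorm(8)
  y <- rnorm(6, 0.5)
  f <- function(v) exp(v) + v^3  # strictly increasing
  mw1 <- mann_whitney(x, y)
  mw2 <- mann_whitney(f(x), f(y))
  expect_equal(mw1$statistic, mw2$statistic)
  expect_equal(mw1$p_value, mw2$p_value)
  g1 <- list(rnorm(4), rnorm(4, 1), rnorm(4))
  g2 <- lapply(g1, f)
  kw1 <- kruskal_wallis(g1)
  kw2 <- kruskal_wallis(g2)
  expect_equal(kw1$statistic, kw2$statistic)
  expect_equal(kw1$p_value, kw2$p_value)
})

test_that("trait_by_ubiquity pairs the regression with the rank test", {
  set.seed(23)
  tt <- data.frame(ubiquity = rep(1:5, each = 4))
  tt$mean_genome_size <- 3e6 + 2e5 * tt$ubiquity + rnorm(20, 0, 1e5)
  res <- trait_by_ubiquity(tt, "mean_genome_size")
  expect_gt(res$regression$slope, 0)
  expect_lt(res$regression$p_value, 0.01)
  expect_lt(res$kruskal$p_value, 0.05)
  expect_error(trait_by_ubiquity(data.frame(ubiquity = rep(1, 5), y = 1:5),
                                 "y"), "distinct ubiquity")

  # bin-mean regression merges sparse bins upward
  tt2 <- data.frame(ubiquity = c(1, 1, 1, 2, 3, 3, 3, 4, 5, 5, 5))
  tt2$y <- 0.1 * tt2$ubiquity
  res2 <- trait_by_ubiquity(tt2, "y", on_bins = TRUE, min_bin = 3)
  expect_equal(res2$regression$r_squared, 1)
})

test_that("environment comparisons group linked genera per environment", {
  set.seed(29)
  n <- 30
  tt <- data.frame(genus = sprintf("g%02d", 1:n), ubiquity = 2L,
                   mean_genome_size = rnorm(n, 4e6, 2e5),
                   mean_16s_copies = rnorm(n, 4, 1),
                   stringsAsFactors = FALSE)
  # envA genera get small genomes (planted shift)
  tt$mean_genome_size[1:10] <- rnorm(10, 2.5e6, 2e5)
  linked <- c(
    stats::setNames(rep(list("envA"), 10), tt$genus[1:10]),
    stats::setNames(rep(list("envB"), 10), tt$genus[11:20]),
    stats::setNames(rep(list(c("envB", "envC")), 5), tt$genus[21:25]))
  tt <- structure(tt, linked = linked,
                  class = c("trait_table", "data.frame"))
  res <- trait_by_environment(tt, c("mean_genome_size", "mean_16s_copies"))
  kwrow <- res[res$analysis == "kruskal_global" &
                 res$trait == "mean_genome_size", ]
  expect_lt(kwrow$p_value, 0.01)
  # a genus linked to two environments is counted in both groups
  expect_identical(kwrow$n1, 10L + 15L + 5L)
  mwrow <- res[res$analysis == "mannwhitney_env" & res$environment == "envA" &
                 res$trait == "mean_genome_size", ]
  expect_lt(mwrow$p_value, 0.01)
  expect_identical(c(mwrow$n1, mwrow$n2), c(10L, 20L))

  # a single linked environment: global test skipped with warning
  tt1 <- tt
  attr(tt1, "linked") <- linked[1:10]
  expect_warning(res1 <- trait_by_environment(tt1, "mean_genome_size"),
                 "skipped")
  expect_true(all(res1$analysis == "mannwhitney_env"))
})

test_that("class-vs-size regressions flag planted dependence only", {
  set.seed(31)
  n <- 24
  tt <- data.frame(genus = sprintf("g%02d", 1:n), ubiquity = 2L,
                   mean_genome_size = seq(2e6, 6e6, length.out = n),
                   stringsAsFactors = FALSE)
  tt$cog_ratio.J <- 0.5 - 5e-8 * tt$mean_genome_size + rnorm(n, 0, 0.005)
  tt$cog_ratio.K <- rnorm(n, 0.2, 0.02)  # size-independent
  linked <- stats::setNames(rep(list("envA"), n), tt$genus)
  tt <- structure(tt, linked = linked,
                  class = c("trait_table", "data.frame"))
  res <- class_vs_genome_size(tt)
  rj <- res[res$class == "J", ]
  expect_true(rj$significant)
  expect_lt(rj$slope, 0)
  # n = 2 group: skipped with warning
  tt2 <- tt
  attr(tt2, "linked") <- c(linked[1:2],
                           stats::setNames(rep(list("envB"), 22),
                                           tt$genus[3:24]))
  expect_warning(res2 <- class_vs_genome_size(tt2), "fewer than 3")
  expect_true(all(res2$environment == "envB"))
})
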