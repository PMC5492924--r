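#' @export
print.trait_test <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4), sep = "")
  if (!is.null(x$r_squared)) {
    cat(", R^2 = ", format(x$r_squared, digits = 4),
        " (adj. ", format(x$adjusted_r_squared, digits = 4), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

trait_test <- function(test, statistic, p_value, ...) {
  structure(c(list(test = test, statistic = unname(statistic),
                   p_value = unname(p_value)), list(...)),
            class = "trait_test")
}

#' Ordinary least-squares regression summary
#'
#' Simple OLS of `y` on `x` via [stats::lm()], reporting slope,
#' intercept, R-squared, adjusted R-squared
#' (1 - (1 - R^2)(n - 1)/(n - 2)) and the two-sided slope p-value from
#' the t distribution. A zero-variance response is defined (slope 0,
#' R^2 = 0, p = 1) rather than an error; constant predictors are errors.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return A `trait_test` with fields `slope`, `intercept`, `r_squared`,
#'   `adjusted_r_squared`, `n`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor", call. = FALSE)
  n <- length(x)
  if (stats::sd(y) == 0) {
    return(trait_test("linear_regression", statistic = 0, p_value = 1,
                      slope = 0, intercept = y[1], r_squared = 0,
                      adjusted_r_squared = 0, n = n))
  }
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # perfect fits warn but are valid here
  co <- s$coefficients
  trait_test("linear_regression",
             statistic = co["x", "t value"],
             p_value = co["x", "Pr(>|t|)"],
             slope = unname(co["x", "Estimate"]),
             intercept = unname(co["(Intercept)", "Estimate"]),
             r_squared = s$r.squared,
             adjusted_r_squared = s$adj.r.squared,
             n = n)
}

# exact null distribution of the tie-corrected H statistic by complete
# enumeration of group assignments (conditional on the pooled values)
kw_exact_p <- function(values, sizes, h_obs) {
  N <- length(values)
  r <- rank(values)
  tie_c <- kw_tie_correction(values)
  if (tie_c == 0) return(1)
  const <- 12 / (N * (N + 1))
  hs <- numeric(0)
  rec <- function(remaining, gi, acc) {
    if (gi == length(sizes)) {
      rs <- c(acc, sum(r[remaining]))
      h <- (const * sum(rs^2 / sizes) - 3 * (N + 1)) / tie_c
      hs[[length(hs) + 1]] <<- h
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (pk in picks) {
      rec(setdiff(remaining, pk), gi + 1, c(acc, sum(r[pk])))
    }
  }
  rec(seq_len(N), 1, numeric(0))
  mean(unlist(hs) >= h_obs - 1e-9)
}

kw_tie_correction <- function(values) {
  t <- table(values)
  N <- length(values)
  1 - sum(t^3 - t) / (N^3 - N)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared (k - 1 df) p-value via
#' [stats::kruskal.test()]. With `exact = TRUE` (pooled n <= 10) the
#' p-value is instead the exact permutation tail probability
#' P(H >= H_obs) over all group assignments, conditional on the pooled
#' values.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @param exact Use the exact enumeration p-value.
#' @return A `trait_test` with field `group_ns`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) stop("need at least 3 observations", call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1) {
    # all observations tied: H defined as 0
    return(trait_test("kruskal_wallis", statistic = 0, p_value = 1,
                      group_ns = lengths(groups)))
  }
  kt <- stats::kruskal.test(values, g)
  h <- unname(kt$statistic)
  p <- if (exact) {
    if (length(values) > 10) {
      stop("exact enumeration limited to pooled n <= 10", call. = FALSE)
    }
    kw_exact_p(values, lengths(groups), h)
  } else {
    unname(kt$p.value)
  }
  trait_test("kruskal_wallis", statistic = h, p_value = p,
             group_ns = lengths(groups))
}

# distribution of the doubled rank sum of a size-n1 subset, by the
# shift (generating-function) algorithm; handles midranks from ties
rank_sum_counts <- function(dr, n1) {
  ord <- sort(dr, decreasing = TRUE)
  maxsum <- sum(ord[seq_len(n1)])
  counts <- matrix(0, n1 + 1, maxsum + 1)
  counts[1, 1] <- 1
  for (v in dr) {
    for (sz in rev(seq_len(n1))) {
      if (v + 1 <= maxsum + 1) {
        src <- counts[sz, seq_len(maxsum + 1 - v)]
        counts[sz + 1, (v + 1):(maxsum + 1)] <-
          counts[sz + 1, (v + 1):(maxsum + 1)] + src
      }
    }
  }
  counts[n1 + 1, ]  # index s+1 holds the count of doubled sum s
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided test on the U statistic. For pooled n <= 20 (or when
#' `exact = TRUE`) the p-value is exact: the rank-sum distribution over
#' all subsets is computed by a shift algorithm on (doubled) midranks, so
#' ties are handled exactly, and p = min(1, 2 min(P(U <= u), P(U >= u))).
#' Larger samples use the normal approximation with tie correction via
#' [stats::wilcox.test()].
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact path;
#'   `NULL` picks by pooled size.
#' @return A `trait_test` with statistic U and field `group_ns`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) stop("empty group", call. = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  if (is.null(exact)) exact <- (n1 + n2) <= 20
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (exact) {
    dr <- as.integer(round(2 * r))
    dist <- rank_sum_counts(dr, n1)
    total <- sum(dist)
    w2 <- as.integer(round(2 * w))
    ple <- sum(dist[seq_len(w2 + 1)]) / total
    pge <- sum(dist[(w2 + 1):length(dist)]) / total
    p <- min(1, 2 * min(ple, pge))
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  trait_test("mann_whitney", statistic = u, p_value = p,
             group_ns = c(n1, n2))
}

#' Assemble the genus-level trait table
#'
#' Joins genus profiles with ubiquity and (optionally) the significant
#' genus-environment links into the one-row-per-genus table all trait
#' analyses consume. Class ratio columns are named
#' `cog_ratio.<class>` / `orf_ratio.<class>`.
#'
#' @param profiles A [aggregate_genus()] result.
#' @param ubiq Named integer vector from [ubiquity()]. Genera absent from
#'   it get ubiquity 0.
#' @param assoc Optional [link_taxa()] result supplying linked
#'   environments.
#' @return data.frame of class `trait_table`; the per-genus linked
#'   environment list is attribute `"linked"`.
#' @export
trait_table <- function(profiles, ubiq, assoc = NULL) {
  stopifnot(inherits(profiles, "genus_profiles"))
  tt <- profiles$traits
  tt$ubiquity <- as.integer(ubiq[tt$genus])
  tt$ubiquity[is.na(tt$ubiquity)] <- 0L
  for (kind in c("cog_ratio", "orf_ratio")) {
    m <- profiles[[kind]]
    if (!is.null(m)) {
      m <- m[tt$genus, , drop = FALSE]
      colnames(m) <- paste(kind, colnames(m), sep = ".")
      tt <- cbind(tt, as.data.frame(m))
    }
  }
  linked <- if (!is.null(assoc)) linked_environments(assoc) else list()
  rownames(tt) <- NULL
  structure(tt, linked = linked, class = c("trait_table", "data.frame"))
}

# merge ubiquity bins with fewer than min_bin members into the next
# higher bin (remainder folds back into the last closed bin)
merge_bins_upward <- function(u, min_bin) {
  lev <- sort(unique(u))
  bin_of <- integer(length(u))
  cur <- 0L
  members <- integer(0)
  for (lv in lev) {
    members <- c(members, which(u == lv))
    if (length(members) >= min_bin) {
      cur <- cur + 1L
      bin_of[members] <- cur
      members <- integer(0)
    }
  }
  if (length(members)) {
    if (cur == 0L) cur <- 1L
    bin_of[members] <- cur
  }
  bin_of
}

#' Trait versus ubiquity
#'
#' Runs a linear regression of the genus-level trait on ubiquity and a
#' Kruskal-Wallis test of the trait grouped by ubiquity value. With
#' `on_bins = TRUE` the regression is computed on ubiquity-bin means
#' (bins with fewer than `min_bin` genera merged upward), the granularity
#' at which class-ratio trends are summarized.
#'
#' @param traits A [trait_table()] (any data.frame with an `ubiquity`
#'   column works).
#' @param trait Column name of the trait.
#' @param on_bins Regress on bin means instead of genus-level points.
#' @param min_bin Minimum genera per bin when binning.
#' @return List of class `trait_by_ubiquity` with elements `regression`
#'   and `kruskal`.
#' @export
trait_by_ubiquity <- function(traits, trait, on_bins = FALSE, min_bin = 3) {
  if (!trait %in% names(traits)) stop("unknown trait: ", trait, call. = FALSE)
  u <- traits$ubiquity
  y <- traits[[trait]]
  if (length(unique(u)) < 2) {
    stop("need at least 2 distinct ubiquity values", call. = FALSE)
  }
  reg <- if (on_bins) {
    b <- merge_bins_upward(u, min_bin)
    xb <- as.vector(tapply(u, b, mean))
    yb <- as.vector(tapply(y, b, mean))
    if (length(xb) < 3) stop("fewer than 3 bins after merging", call. = FALSE)
    linear_regression(xb, yb)
  } else {
    linear_regression(u, y)
  }
  kw <- kruskal_wallis(split(y, u))
  structure(list(regression = reg, kruskal = kw, trait = trait,
                 on_bins = on_bins),
            class = "trait_by_ubiquity")
}

#' @export
print.trait_by_ubiquity <- function(x, ...) {
  cat("Trait vs ubiquity:", x$trait,
      if (x$on_bins) "(bin means)" else "(genus level)", "\n")
  print(x$regression)
  print(x$kruskal)
  invisible(x)
}

#' Trait comparisons across environmental preference groups
#'
#' For each trait: a global Kruskal-Wallis across environment groups (a
#' genus linked to k environments is a member of all k groups), plus a
#' per-environment Mann-Whitney comparing the genera linked to that
#' environment against all remaining genera. Environments with no linked
#' genus are skipped with a warning, as is the global test when fewer
#' than two environments have linked genera.
#'
#' @param traits A [trait_table()] whose `"linked"` attribute is
#'   non-empty.
#' @param trait_names Trait columns to analyze.
#' @return data.frame of class `trait_env_tests`: one row per test with
#'   columns `trait`, `analysis`, `environment`, `statistic`, `p_value`,
#'   `n1`, `n2`.
#' @export
trait_by_environment <- function(traits,
                                 trait_names = c("mean_genome_size",
                                                 "mean_16s_copies",
                                                 "mean_16s_distinct")) {
  linked <- attr(traits, "linked")
  if (is.null(linked) || length(linked) == 0) {
    stop("trait table carries no linked environments", call. = FALSE)
  }
  env_members <- split(rep(names(linked), lengths(linked)),
                       unlist(linked, use.names = FALSE))
  envs <- names(env_members)[lengths(env_members) > 0]
  rows <- list()
  for (tr in trait_names) {
    vals <- stats::setNames(traits[[tr]], traits$genus)
    if (length(envs) >= 2) {
      groups <- lapply(env_members[envs], function(g) unname(vals[g]))
      kw <- kruskal_wallis(groups)
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, analysis = "kruskal_global", environment = "",
        statistic = kw$statistic, p_value = kw$p_value,
        n1 = sum(lengths(groups)), n2 = NA_integer_,
        stringsAsFactors = FALSE)
    } else {
      warning("fewer than 2 environments with linked genera; ",
              "global test skipped for ", tr)
    }
    for (e in envs) {
      inn <- env_members[[e]]
      out <- setdiff(traits$genus, inn)
      if (length(inn) == 0 || length(out) == 0) {
        warning("environment ", e, " skipped for ", tr)
        next
      }
      mw <- mann_whitney(unname(vals[inn]), unname(vals[out]))
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, analysis = "mannwhitney_env", environment = e,
        statistic = mw$statistic, p_value = mw$p_value,
        n1 = length(inn), n2 = length(out), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("trait_env_tests", "data.frame"))
}

#' Class-ratio versus genome-size confound regressions
#'
#' Within each environmental preference group, regresses every
#' functional-class ratio (both kinds) on mean genome size, flagging
#' significant instances. Detects whether apparent class-abundance
#' differences between environments are mere genome-size effects.
#'
#' @param traits A [trait_table()] with class ratio columns and linked
#'   environments.
#' @param alpha Significance threshold (default 0.01).
#' @return data.frame: one row per (environment, class, kind) with
#'   columns `environment`, `class`, `kind`, `n`, `slope`, `p_value`,
#'   `r_squared`, `adjusted_r_squared`, `significant`.
#' @export
class_vs_genome_size <- function(traits, alpha = 0.01) {
  linked <- attr(traits, "linked")
  if (is.null(linked) || length(linked) == 0) {
    stop("trait table carries no linked environments", call. = FALSE)
  }
  env_members <- split(rep(names(linked), lengths(linked)),
                       unlist(linked, use.names = FALSE))
  ratio_cols <- grep("^(cog|orf)_ratio\\.", names(traits), value = TRUE)
  if (length(ratio_cols) == 0) {
    stop("trait table has no class ratio columns", call. = FALSE)
  }
  rows <- list()
  for (e in names(env_members)) {
    idx <- match(env_members[[e]], traits$genus)
    if (length(idx) < 3) {
      warning("environment ", e, " has fewer than 3 linked genera; skipped")
      next
    }
    sizes <- traits$mean_genome_size[idx]
    for (col in ratio_cols) {
      kind <- sub("\\..*$", "", col)
      cls <- sub("^[a-z_]+\\.", "", col)
      res <- tryCatch(linear_regression(sizes, traits[[col]][idx]),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- data.frame(
        environment = e, class = cls, kind = kind, n = length(idx),
        slope = res$slope, p_value = res$p_value,
        r_squared = res$r_squared,
        adjusted_r_squared = res$adjusted_r_squared,
        significant = res$p_value < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(environment = character(0), class = character(0),
               kind = character(0), n = integer(0), slope = numeric(0),
               p_value = numeric(0), r_squared = numeric(0),
               adjusted_r_squared = numeric(0), significant = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
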