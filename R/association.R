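#' Construct an environmental observation table
#'
#' Rows record one detection each: a genus observed in a sample, every
#' sample carrying a unique environment label. A sample census (all
#' samples and their environments, including samples with no detections)
#' can be supplied so that environment totals are not undercounted; by
#' default it is derived from the rows themselves.
#'
#' @param obs data.frame with columns `sample_id`, `environment`, `genus`.
#' @param samples Optional census data.frame with columns `sample_id`,
#'   `environment` covering at least every sample appearing in `obs`.
#' @return data.frame of class `observation_table` with the census in
#'   attribute `"samples"`.
#' @export
observation_table <- function(obs, samples = NULL) {
  req <- c("sample_id", "environment", "genus")
  if (!is.data.frame(obs) || !all(req %in% names(obs))) {
    stop("obs must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  obs <- obs[req]
  if (anyDuplicated(obs[c("sample_id", "genus")])) {
    stop("duplicated (sample_id, genus) pairs", call. = FALSE)
  }
  derived <- unique(obs[c("sample_id", "environment")])
  if (anyDuplicated(derived$sample_id)) {
    stop("a sample_id maps to more than one environment", call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- derived[order(derived$sample_id), , drop = FALSE]
  } else {
    if (!all(c("sample_id", "environment") %in% names(samples))) {
      stop("samples census needs columns sample_id, environment",
           call. = FALSE)
    }
    samples <- unique(samples[c("sample_id", "environment")])
    if (anyDuplicated(samples$sample_id)) {
      stop("census maps a sample_id to more than one environment",
           call. = FALSE)
    }
    i <- match(derived$sample_id, samples$sample_id)
    if (anyNA(i) || any(samples$environment[i] != derived$environment)) {
      stop("observation rows disagree with the sample census", call. = FALSE)
    }
  }
  rownames(obs) <- NULL
  rownames(samples) <- NULL
  structure(obs, samples = samples, class = c("observation_table",
                                              "data.frame"))
}

#' Read an observation TSV (`sample_id<TAB>environment<TAB>genus`)
#'
#' @param path Observation TSV.
#' @param samples_path Optional census TSV (`sample_id`, `environment`).
#' @return An [observation_table()].
#' @export
read_observation_table <- function(path, samples_path = NULL) {
  obs <- read_tsv(path, col_classes = "character")
  samples <- if (!is.null(samples_path)) {
    read_tsv(samples_path, col_classes = "character")
  }
  observation_table(obs, samples = samples)
}

#' Genus x environment frequency table
#'
#' Counts, for every genus and environment, the number of samples of that
#' environment containing the genus. Cells where a genus was observed in
#' just one sample of an environment are set to zero (single-sample
#' detections are treated as unreliable); environment totals are
#' untouched by the exclusion.
#'
#' @param obs An [observation_table()].
#' @return Object of class `frequency_table`: list with `counts` (genus x
#'   environment integer matrix) and `env_totals` (named integer vector).
#' @export
build_frequency_table <- function(obs) {
  stopifnot(inherits(obs, "observation_table"))
  if (nrow(obs) == 0) stop("empty observation table", call. = FALSE)
  census <- attr(obs, "samples")
  envs <- sort(unique(census$environment))
  genera <- sort(unique(obs$genus))
  counts <- unclass(table(factor(obs$genus, levels = genera),
                          factor(obs$environment, levels = envs)))
  counts <- matrix(as.integer(counts), nrow = length(genera),
                   dimnames = list(genera, envs))
  counts[counts == 1L] <- 0L
  env_totals <- stats::setNames(
    as.integer(table(factor(census$environment, levels = envs))), envs)
  structure(list(counts = counts, env_totals = env_totals),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("frequency_table:", nrow(x$counts), "genera x", ncol(x$counts),
      "environments;", sum(x$env_totals), "samples\n")
  invisible(x)
}

#' One-sided Fisher enrichment p-value for a 2x2 table
#'
#' Exact hypergeometric upper-tail probability of observing `a` or more
#' samples of the focal environment containing the focal genus, given the
#' table margins: with N = a+b+c+d, K = a+c (samples containing the
#' genus) and n = a+b (samples of the environment), returns
#' P(X >= a) for X ~ hypergeometric(N, K, n). All-zero tables return 1 by
#' convention. Vectorized over the four cells.
#'
#' @param a,b,c,d Non-negative integer cells: `a` samples of the
#'   environment with the genus, `b` without; `c` samples of other
#'   environments with the genus, `d` without.
#' @return Numeric vector of p-values.
#' @examples
#' fisher_enrichment(5, 0, 0, 5)  # 1/252
#' @export
fisher_enrichment <- function(a, b, c, d) {
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    stop("negative contingency cells", call. = FALSE)
  }
  N <- a + b + c + d
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  p[N == 0] <- 1
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (via [stats::p.adjust()]), returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  check_prob(pvalues, "pvalues")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call significant genus-environment links
#'
#' For every (genus, environment) cell with a positive post-exclusion
#' count, a 2x2 contingency table is built at the sample level (samples
#' of the environment with/without the genus vs samples of all other
#' environments with/without it), the one-sided enrichment p-value
#' computed, and all tested pairs adjusted jointly by Benjamini-Hochberg.
#' A genus is linked to an environment when the adjusted p-value is below
#' `alpha`. Cells with count zero are never tested and never enter the
#' adjustment family.
#'
#' @param freq A [build_frequency_table()] result.
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.01).
#' @param alternative `"greater"` (enrichment, the default) or
#'   `"two.sided"` (via [stats::fisher.test()]).
#' @return data.frame of class `env_association` with columns `genus`,
#'   `environment`, `a`, `b`, `c`, `d`, `raw_p`, `adjusted_p`, `linked`.
#' @export
link_taxa <- function(freq, alpha = 0.01,
                      alternative = c("greater", "two.sided")) {
  stopifnot(inherits(freq, "frequency_table"))
  alternative <- match.arg(alternative)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  cnt <- freq$counts
  tot <- freq$env_totals
  idx <- which(cnt > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  genus <- rownames(cnt)[idx[, 1]]
  env <- colnames(cnt)[idx[, 2]]
  a <- cnt[idx]
  b <- tot[env] - a
  genus_tot <- rowSums(cnt)
  cc <- genus_tot[genus] - a
  d <- (sum(tot) - tot[env]) - cc
  raw_p <- if (alternative == "greater") {
    fisher_enrichment(a, b, cc, d)
  } else {
    vapply(seq_along(a), function(i) {
      stats::fisher.test(matrix(c(a[i], cc[i], b[i], d[i]), 2),
                         alternative = "two.sided")$p.value
    }, numeric(1))
  }
  adj <- bh_adjust(raw_p)
  out <- data.frame(genus = genus, environment = env,
                    a = as.integer(a), b = as.integer(b),
                    c = as.integer(cc), d = as.integer(d),
                    raw_p = unname(raw_p), adjusted_p = unname(adj),
                    linked = unname(adj < alpha),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, alpha = alpha, alternative = alternative,
            n_tested = nrow(out), total_samples = sum(tot),
            class = c("env_association", "data.frame"))
}

#' @export
print.env_association <- function(x, ...) {
  cat("env_association:", attr(x, "n_tested"), "tested pairs,",
      sum(x$linked), "linked (adjusted p <", attr(x, "alpha"), ")\n")
  if (any(x$linked)) {
    print.data.frame(x[x$linked, c("genus", "environment", "a", "b",
                                   "raw_p", "adjusted_p")],
                     row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.env_association <- function(object, ...) {
  linked <- object[object$linked, , drop = FALSE]
  out <- list(n_tested = attr(object, "n_tested"),
              n_linked = nrow(linked),
              alpha = attr(object, "alpha"),
              links_per_environment = table(linked$environment),
              links_per_genus = table(linked$genus))
  class(out) <- "summary.env_association"
  out
}

#' @export
print.summary.env_association <- function(x, ...) {
  cat("Tested pairs:", x$n_tested, "\nLinked pairs:", x$n_linked,
      "(alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Extract significant links as a per-genus environment list
#'
#' @param assoc An `env_association`.
#' @return Named list: genus -> character vector of linked environments.
#' @export
linked_environments <- function(assoc) {
  stopifnot(inherits(assoc, "env_association"))
  linked <- assoc[assoc$linked, , drop = FALSE]
  split(linked$environment, linked$genus)
}

#' Ubiquity: number of environments where each genus was found
#'
#' Presence is read from the post-exclusion frequency table: a genus is
#' present in an environment when at least 2 samples of that environment
#' contain it.
#'
#' @param freq A [build_frequency_table()] result.
#' @return Named integer vector, one entry per genus.
#' @export
ubiquity <- function(freq) {
  stopifnot(inherits(freq, "frequency_table"))
  stats::setNames(as.integer(rowSums(freq$counts >= 2)),
                  rownames(freq$counts))
}

#' Randomized frequency-table control
#'
#' Checks that the significant links are not artifacts of the testing
#' procedure: each replicate redistributes every genus's detections
#' uniformly across all samples (preserving each genus's total detection
#' count and every sample's environment label), rebuilds the frequency
#' table with the single-sample exclusion, and reruns the linking. On
#' preference-free data essentially no replicate should yield a link.
#'
#' @param obs An [observation_table()].
#' @param n_tables Number of randomized tables (default 100).
#' @param alpha Passed to [link_taxa()].
#' @param seed Optional integer seed; fixed seeds give identical
#'   replicate counts.
#' @return Object of class `randomization_control`: list with
#'   `linked_per_table` (integer vector), `frac_tables_with_link`,
#'   `mean_linked`, `n_tables`, `alpha`.
#' @export
randomization_control <- function(obs, n_tables = 100, alpha = 0.01,
                                  seed = NULL) {
  stopifnot(inherits(obs, "observation_table"))
  if (!is_count1(n_tables)) stop("n_tables must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  census <- attr(obs, "samples")
  det_per_genus <- table(obs$genus)
  genera <- names(det_per_genus)
  linked_per_table <- integer(n_tables)
  for (t in seq_len(n_tables)) {
    perm <- do.call(rbind, lapply(genera, function(g) {
      ids <- sample(census$sample_id, det_per_genus[[g]])
      data.frame(sample_id = ids,
                 environment = census$environment[match(ids,
                                                        census$sample_id)],
                 genus = g, stringsAsFactors = FALSE)
    }))
    ptab <- observation_table(perm, samples = census)
    linked_per_table[t] <- sum(link_taxa(build_frequency_table(ptab),
                                         alpha = alpha)$linked)
  }
  structure(list(linked_per_table = linked_per_table,
                 frac_tables_with_link = mean(linked_per_table > 0),
                 mean_linked = mean(linked_per_table),
                 n_tables = n_tables, alpha = alpha),
            class = "randomization_control")
}

#' @export
print.randomization_control <- function(x, ...) {
  cat(sprintf(paste0("randomization_control: %d tables; mean linked pairs ",
                     "%.3f; fraction of tables with >=1 link %.3f\n"),
              x$n_tables, x$mean_linked, x$frac_tables_with_link))
  invisible(x)
}
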