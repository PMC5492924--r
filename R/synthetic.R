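#' Canonical genus / environment labels used by the simulator
#'
#' @param n Number of labels.
#' @return Character vector (`g001`, `g002`, ... / `env1`, `env2`, ...).
#' @export
genus_labels <- function(n) sprintf("g%03d", seq_len(n))

#' @rdname genus_labels
#' @export
environment_labels <- function(n) sprintf("env%d", seq_len(n))

#' Configuration for the synthetic microbial dataset generator
#'
#' The generator emulates the two inputs of the analysis — a cohort of
#' annotated genomes grouped into genera, and an environmental
#' sample-observation table in which every sample carries a unique
#' environment label — with known planted structure: genus-environment
#' preferences on the odds scale, a linear genome-size gradient along
#' planted ubiquity, environment-specific 16S copy-number regimes,
#' "adaptive" COG families whose presence rises with ubiquity, and
#' annotation-completeness noise.
#'
#' @param n_genera,n_environments,samples_per_environment Counts (>= 1).
#' @param genomes_per_genus Single count, or a length-2 range sampled
#'   uniformly per genus.
#' @param baseline_detection_prob Probability that a genus is detected in
#'   a sample of an environment it has no preference for.
#' @param preference_map Optional data.frame (`genus`, `environment`,
#'   `multiplier`): odds multipliers > 1 plant a preference. A genus's
#'   planted ubiquity is its number of environments with multiplier > 1
#'   (1 if none).
#' @param size_intercept,size_slope_per_env,size_noise_sd Genome size
#'   model (bp): size = intercept + slope x planted ubiquity + N(0, sd).
#' @param rrna_regime_map Optional data.frame (`environment`,
#'   `mean_copies`, `dispersion`); 16S copy number of a genome is drawn
#'   from the regime of its genus's primary environment (rounded, min 1).
#'   Default: mean 4, dispersion 1.5 everywhere.
#' @param n_cogs,n_adaptive_cogs COG universe size and number of adaptive
#'   families (the first `n_adaptive_cogs` ids).
#' @param adaptive_presence_range Presence probability of adaptive COGs at
#'   planted ubiquity 1 and at the maximum (= `n_environments`), linearly
#'   interpolated in between. Non-adaptive COGs get a ubiquity-independent
#'   presence probability drawn once per family from U(0.05, 0.95).
#' @param annotation_ratio_mean,annotation_ratio_sd Truncated-normal (on
#'   (0, 1]) parameters of the per-genome annotation ratio. Defaults 0.715
#'   and 0.157, the completeness regime typical of public complete-genome
#'   cohorts.
#' @param rrna_seq_length,rrna_substitution_rate Each genome's 16S copies
#'   derive from one fixed reference string with independent per-site
#'   substitutions at this rate; rate 0 makes all copies identical.
#' @param orf_density Expected ORFs per bp (default 9e-4, about one gene
#'   per 1.1 kb).
#' @param seed Optional integer; identical seeds give identical datasets.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genera = 20, genomes_per_genus = 3,
                       n_environments = 6, samples_per_environment = 50,
                       baseline_detection_prob = 0.1, preference_map = NULL,
                       size_intercept = 3e6, size_slope_per_env = 2e5,
                       size_noise_sd = 4e5, rrna_regime_map = NULL,
                       n_cogs = 200, n_adaptive_cogs = 10,
                       adaptive_presence_range = c(0.1, 0.9),
                       annotation_ratio_mean = 0.715,
                       annotation_ratio_sd = 0.157,
                       rrna_seq_length = 200, rrna_substitution_rate = 0.005,
                       orf_density = 9e-4, seed = NULL) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  cerr <- function(...) stop("config error: ", ..., call. = FALSE)
  for (f in c("n_genera", "n_environments", "samples_per_environment",
              "n_cogs")) {
    if (!is_count1(cfg[[f]])) cerr(f, " must be a count >= 1")
  }
  g <- cfg$genomes_per_genus
  if (!(length(g) %in% 1:2) || any(g < 1) || any(g != round(g))) {
    cerr("genomes_per_genus must be a count or a range of counts >= 1")
  }
  if (!is.numeric(cfg$n_adaptive_cogs) || cfg$n_adaptive_cogs < 0 ||
      cfg$n_adaptive_cogs > cfg$n_cogs) {
    cerr("n_adaptive_cogs must be between 0 and n_cogs")
  }
  check_prob(cfg$baseline_detection_prob, "baseline_detection_prob")
  check_prob(cfg$adaptive_presence_range, "adaptive_presence_range")
  if (length(cfg$adaptive_presence_range) != 2) {
    cerr("adaptive_presence_range must be a pair of probabilities")
  }
  check_prob(cfg$annotation_ratio_mean, "annotation_ratio_mean")
  check_prob(cfg$rrna_substitution_rate, "rrna_substitution_rate")
  if (cfg$annotation_ratio_sd < 0 || cfg$size_noise_sd < 0) {
    cerr("standard deviations must be >= 0")
  }
  pm <- cfg$preference_map
  if (!is.null(pm)) {
    if (!is.data.frame(pm) ||
        !all(c("genus", "environment", "multiplier") %in% names(pm))) {
      cerr("preference_map needs columns genus, environment, multiplier")
    }
    if (any(pm$multiplier <= 0)) cerr("odds multipliers must be > 0")
    if (!all(pm$genus %in% genus_labels(cfg$n_genera)) ||
        !all(pm$environment %in% environment_labels(cfg$n_environments))) {
      cerr("preference_map refers to unknown genus or environment labels")
    }
  }
  cfg
}

# truncated normal on (0, 1] by rejection; simple and adequate here
rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rnorm(n, mean, sd)
    out <- c(out, d[d > 0 & d <= 1])
  }
  out[seq_len(n)]
}

mutate_sequence <- function(ref_chars, rate) {
  hit <- which(stats::runif(length(ref_chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      ref_chars[i] <- sample(bases[bases != ref_chars[i]], 1)
    }
  }
  paste(ref_chars, collapse = "")
}

# odds-scale preference: multiplier m turns baseline p into
# (m*p/(1-p)) / (1 + m*p/(1-p)); valid for any m > 0
scale_odds <- function(p, mult) {
  if (p >= 1) {
    out <- mult
    out[] <- 1
    return(out)
  }
  odds <- mult * p / (1 - p)
  odds / (1 + odds)
}

#' Generate a synthetic dataset with planted structure
#'
#' See [sim_config()] for the generative model. The returned ground truth
#' records the planted genus-environment links, per-genus planted
#' ubiquity, the adaptive COG ids and the true size slope, providing the
#' truth channel for parameter-recovery checks.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_dataset`: list with elements
#'   `genomes` ([genome_set()]), `observations` ([observation_table()]),
#'   `scheme` ([cog_scheme()]), `truth` (list: `planted_links`,
#'   `planted_ubiquity`, `adaptive_cog_ids`, `true_size_slope`) and
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  config <- validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- config$n_genera
  E <- config$n_environments
  genera <- genus_labels(G)
  envs <- environment_labels(E)

  mult <- matrix(1, G, E, dimnames = list(genera, envs))
  pm <- config$preference_map
  if (!is.null(pm) && nrow(pm) > 0) {
    mult[cbind(match(pm$genus, genera), match(pm$environment, envs))] <-
      pm$multiplier
  }
  planted_ubiquity <- stats::setNames(pmax(1L, rowSums(mult > 1)), genera)

  ## --- genomes ------------------------------------------------------
  gpg <- config$genomes_per_genus
  n_per <- if (length(gpg) == 1) rep(gpg, G) else
    sample(seq(gpg[1], gpg[2]), G, replace = TRUE)
  genus_of <- rep(genera, n_per)
  genome_id <- unlist(lapply(seq_len(G), function(i)
    sprintf("%s_gen%02d", genera[i], seq_len(n_per[i]))), use.names = FALSE)
  n_gen <- length(genome_id)
  u_of <- planted_ubiquity[genus_of]

  size <- config$size_intercept + config$size_slope_per_env * u_of +
    stats::rnorm(n_gen, 0, config$size_noise_sd)
  size <- pmax(1e5, round(size))
  n_orfs <- pmax(50L, as.integer(round(size * config$orf_density)))
  ratio <- rtruncnorm01(n_gen, config$annotation_ratio_mean,
                        config$annotation_ratio_sd)
  n_annot <- as.integer(round(ratio * n_orfs))

  ## COG content: presence, then ORF counts over present families
  cog_ids <- sprintf("COG%04d", seq_len(config$n_cogs))
  n_ad <- config$n_adaptive_cogs
  cog_class <- sample(names(cog_class_descriptions), config$n_cogs,
                      replace = TRUE)
  null_base <- stats::runif(config$n_cogs, 0.05, 0.95)
  lo <- config$adaptive_presence_range[1]
  hi <- config$adaptive_presence_range[2]
  p_adapt <- if (E > 1) lo + (hi - lo) * (u_of - 1) / (E - 1) else rep(lo, n_gen)
  prob <- matrix(rep(null_base, each = n_gen), n_gen, config$n_cogs)
  if (n_ad > 0) prob[, seq_len(n_ad)] <- p_adapt
  pres <- matrix(stats::rbinom(n_gen * config$n_cogs, 1, prob),
                 n_gen, config$n_cogs,
                 dimnames = list(genome_id, cog_ids))
  empty <- which(rowSums(pres) == 0)
  for (i in empty) pres[i, sample(config$n_cogs, 1)] <- 1L

  counts <- matrix(0L, n_gen, config$n_cogs,
                   dimnames = list(genome_id, cog_ids))
  for (i in seq_len(n_gen)) {
    present <- which(pres[i, ] == 1)
    m <- length(present)
    ni <- max(n_annot[i], m)
    extra <- stats::rmultinom(1, ni - m, rep(1, m))[, 1]
    counts[i, present] <- 1L + as.integer(extra)
  }

  ## 16S copies per genome from the primary-environment regime
  regime <- data.frame(environment = envs, mean_copies = 4, dispersion = 1.5,
                       stringsAsFactors = FALSE)
  rm_map <- config$rrna_regime_map
  if (!is.null(rm_map)) {
    i <- match(rm_map$environment, regime$environment)
    regime$mean_copies[i] <- rm_map$mean_copies
    regime$dispersion[i] <- rm_map$dispersion
  }
  primary_env <- vapply(genera, function(g) {
    row <- mult[g, ]
    if (any(row > 1)) envs[which.max(row)] else envs[sample(E, 1)]
  }, character(1))
  reg_i <- match(primary_env[genus_of], regime$environment)
  copies <- pmax(1L, as.integer(round(stats::rnorm(
    n_gen, regime$mean_copies[reg_i], regime$dispersion[reg_i]))))
  ref <- sample(c("A", "C", "G", "T"), config$rrna_seq_length, replace = TRUE)
  rrna_seqs <- lapply(seq_len(n_gen), function(i) {
    vapply(seq_len(copies[i]), function(j)
      mutate_sequence(ref, config$rrna_substitution_rate), character(1))
  })
  names(rrna_seqs) <- genome_id

  genomes <- data.frame(genome_id = genome_id, genus = genus_of,
                        genome_size = size, n_orfs = n_orfs,
                        stringsAsFactors = FALSE)
  gs <- genome_set(genomes, counts, rrna_seqs = rrna_seqs)

  ## --- observations -------------------------------------------------
  S <- config$samples_per_environment
  total <- E * S
  sample_id <- sprintf("s%05d", seq_len(total))
  sample_env <- rep(envs, each = S)
  p0 <- config$baseline_detection_prob
  pprime <- scale_odds(p0, mult)  # G x E detection probabilities
  rows <- vector("list", E)
  for (e in seq_len(E)) {
    ids <- sample_id[sample_env == envs[e]]
    det <- matrix(stats::rbinom(S * G, 1, rep(pprime[, e], each = S)), S, G)
    w <- which(det == 1, arr.ind = TRUE)
    rows[[e]] <- data.frame(sample_id = ids[w[, 1]],
                            environment = rep(envs[e], nrow(w)),
                            genus = genera[w[, 2]], stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  obs <- obs[order(obs$sample_id, obs$genus), , drop = FALSE]
  rownames(obs) <- NULL
  census <- data.frame(sample_id = sample_id, environment = sample_env,
                       stringsAsFactors = FALSE)
  obs_tab <- observation_table(obs, samples = census)

  truth <- list(
    planted_links = if (!is.null(pm) && nrow(pm) > 0)
      pm[pm$multiplier > 1, c("genus", "environment")] else
      data.frame(genus = character(0), environment = character(0),
                 stringsAsFactors = FALSE),
    planted_ubiquity = planted_ubiquity,
    adaptive_cog_ids = cog_ids[seq_len(n_ad)],
    true_size_slope = config$size_slope_per_env
  )
  rownames(truth$planted_links) <- NULL

  structure(list(genomes = gs,
                 observations = obs_tab,
                 scheme = cog_scheme(stats::setNames(cog_class, cog_ids)),
                 truth = truth,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$genomes$genomes), "genomes /",
      x$config$n_genera, "genera;",
      nrow(attr(x$observations, "samples")), "samples in",
      x$config$n_environments, "environments;",
      nrow(x$truth$planted_links), "planted links\n")
  invisible(x)
}

#' Generate a null observation table
#'
#' Same generative process as [simulate_dataset()] but with every odds
#' multiplier forced to 1: no genus has any environmental preference.
#' Used for null controls mirroring randomized frequency-table checks.
#'
#' @param config A [sim_config()].
#' @return An [observation_table()]; the (empty-link) ground truth is
#'   attached as attribute `"truth"`.
#' @export
simulate_null_observations <- function(config) {
  config <- validate_sim_config(config)
  config$preference_map <- NULL
  ds <- simulate_dataset(config)
  obs <- ds$observations
  attr(obs, "truth") <- ds$truth
  obs
}

#' Write a synthetic dataset to its canonical text formats
#'
#' Emits the genome annotation TSV (one row per gene, genes without a COG
#' leaving `cog_id` empty), a 16S FASTA (headers `genomeID_rrna_N`), the
#' observation and sample-census TSVs, the class-scheme TSV and the
#' ground-truth TSVs.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  gs <- ds$genomes
  g <- gs$genomes

  gene_rows <- lapply(seq_len(nrow(g)), function(i) {
    cnt <- gs$cog_counts[g$genome_id[i], ]
    present <- cnt[cnt > 0]
    cog_col <- c(rep(names(present), present),
                 rep("", g$n_orfs[i] - sum(present)))
    data.frame(genome_id = g$genome_id[i], genus = g$genus[i],
               genome_size_bp = g$genome_size[i], n_orfs = g$n_orfs[i],
               gene_id = sprintf("%s_g%05d", g$genome_id[i],
                                 seq_len(g$n_orfs[i])),
               cog_id = cog_col,
               class_letters = c(ds$scheme$cog_to_classes[
                 cog_col[nzchar(cog_col)]],
                 rep("", sum(!nzchar(cog_col)))),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, gene_rows), p("annotations.tsv"))

  seqs <- unlist(lapply(names(gs$rrna_seqs), function(id) {
    stats::setNames(gs$rrna_seqs[[id]],
                    sprintf("%s_rrna_%d", id, seq_along(gs$rrna_seqs[[id]])))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), p("rrna.fasta"))

  write_tsv(as.data.frame(ds$observations), p("observations.tsv"))
  write_tsv(attr(ds$observations, "samples"), p("samples.tsv"))
  write_class_scheme(ds$scheme, p("scheme.tsv"))
  write_tsv(ds$truth$planted_links, p("truth_links.tsv"))
  write_tsv(data.frame(genus = names(ds$truth$planted_ubiquity),
                       planted_ubiquity =
                         as.integer(ds$truth$planted_ubiquity),
                       stringsAsFactors = FALSE), p("truth_genera.tsv"))
  write_tsv(data.frame(cog_id = colnames(gs$cog_counts),
                       adaptive = colnames(gs$cog_counts) %in%
                         ds$truth$adaptive_cog_ids,
                       stringsAsFactors = FALSE), p("truth_cogs.tsv"))
  invisible(c(annotations = p("annotations.tsv"), rrna = p("rrna.fasta"),
              observations = p("observations.tsv"), samples = p("samples.tsv"),
              scheme = p("scheme.tsv")))
}
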