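#' Pipeline configuration
#'
#' Bundles the inputs and constants of an end-to-end run: either file
#' paths (annotation TSV, 16S FASTA or count TSV, observation TSV with
#' optional sample census) or a synthetic-data configuration; the
#' significance threshold on adjusted p-values; the number of randomized
#' control tables; the class scheme; and the screen's R-squared gate.
#'
#' @param synthetic Optional [sim_config()]; when present the inputs are
#'   simulated (and written next to the outputs).
#' @param annotations,rrna_fasta,rrna_counts,observations,samples_census
#'   Input file paths for a file-based run.
#' @param scheme `"COG"` (derive the mapping from the annotation file,
#'   default classes) or a path to a scheme TSV.
#' @param alpha Adjusted p-value threshold for linking (default 0.01).
#' @param n_random_tables Randomized-control replicates (default 100).
#' @param r2_threshold Adjusted R-squared gate of the COG screen
#'   (default 0.7).
#' @param min_bins Minimum ubiquity bins for the screen (default 4).
#' @param out_dir Output directory.
#' @param seed Integer seed governing all randomness of the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, annotations = NULL,
                            rrna_fasta = NULL, rrna_counts = NULL,
                            observations = NULL, samples_census = NULL,
                            scheme = "COG", alpha = 0.01,
                            n_random_tables = 100, r2_threshold = 0.7,
                            min_bins = 4, out_dir = NULL, seed = NULL) {
  if (alpha <= 0 || alpha >= 1 || r2_threshold <= 0 || r2_threshold >= 1) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  if (!is_count1(n_random_tables)) {
    stop("n_random_tables must be >= 1", call. = FALSE)
  }
  if (is.null(synthetic) && (is.null(annotations) || is.null(observations))) {
    stop("supply either a synthetic config or input file paths",
         call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "sim_config"))
  structure(list(synthetic = synthetic, annotations = annotations,
                 rrna_fasta = rrna_fasta, rrna_counts = rrna_counts,
                 observations = observations,
                 samples_census = samples_census, scheme = scheme,
                 alpha = alpha, n_random_tables = n_random_tables,
                 r2_threshold = r2_threshold, min_bins = min_bins,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `synthetic`
#' mapping is passed to [sim_config()] (its `preference_map` and
#' `rrna_regime_map` entries as data.frames of their listed columns).
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (e.g. `seed`, `out_dir`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    syn <- y$synthetic
    for (f in c("preference_map", "rrna_regime_map")) {
      if (!is.null(syn[[f]])) {
        syn[[f]] <- as.data.frame(lapply(syn[[f]], unlist),
                                  stringsAsFactors = FALSE)
      }
    }
    if (!is.null(syn$adaptive_presence_range)) {
      syn$adaptive_presence_range <- unlist(syn$adaptive_presence_range)
    }
    if (!is.null(syn$genomes_per_genus)) {
      syn$genomes_per_genus <- unlist(syn$genomes_per_genus)
    }
    y$synthetic <- do.call(sim_config, syn)
  }
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

pipeline_trait_tests <- function(traits, alpha) {
  rows <- list()
  add <- function(analysis, trait, group, tt) {
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, trait = trait, group = group,
      statistic = tt$statistic, p_value = tt$p_value,
      slope = tt$slope %||% NA_real_,
      r_squared = tt$r_squared %||% NA_real_,
      adjusted_r_squared = tt$adjusted_r_squared %||% NA_real_,
      n = tt$n %||% sum(tt$group_ns), stringsAsFactors = FALSE)
  }
  base_traits <- intersect(c("mean_genome_size", "mean_16s_copies",
                             "mean_16s_distinct"), names(traits))
  for (tr in base_traits) {
    tu <- trait_by_ubiquity(traits, tr)
    add("trait_vs_ubiquity_regression", tr, "", tu$regression)
    add("trait_vs_ubiquity_kruskal", tr, "", tu$kruskal)
  }
  ratio_cols <- grep("^(cog|orf)_ratio\\.", names(traits), value = TRUE)
  for (col in ratio_cols) {
    tu <- tryCatch(trait_by_ubiquity(traits, col, on_bins = TRUE),
                   error = function(e) NULL)
    if (is.null(tu)) next
    add("class_ratio_vs_ubiquity_regression", col, "", tu$regression)
    add("class_ratio_vs_ubiquity_kruskal", col, "", tu$kruskal)
  }
  if (length(attr(traits, "linked"))) {
    te <- withCallingHandlers(
      tryCatch(trait_by_environment(traits, base_traits),
               error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!is.null(te)) {
      for (i in seq_len(nrow(te))) {
        rows[[length(rows) + 1]] <- data.frame(
          analysis = paste0("environment_", te$analysis[i]),
          trait = te$trait[i], group = te$environment[i],
          statistic = te$statistic[i], p_value = te$p_value[i],
          slope = NA_real_, r_squared = NA_real_,
          adjusted_r_squared = NA_real_,
          n = te$n1[i] + ifelse(is.na(te$n2[i]), 0L, te$n2[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Sequences every stage: annotation-completeness filter, per-genome
#' functional profiles, genus aggregation, frequency table with the
#' single-sample exclusion, Fisher/BH genus-environment linking,
#' ubiquity, the trait test battery, the genome-size confound
#' regressions, the per-COG ubiquity screen, and the randomized-table
#' control. All stage outputs are written as TSV into the output
#' directory together with a YAML manifest of stage counts; identical
#' seeds and inputs yield byte-identical outputs. Genera with ubiquity 0
#' (present in no environment after exclusion) are excluded from the
#' trait and screen stages; the manifest reports how many.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional override of `config$out_dir`.
#' @return The manifest list, invisibly, with class `pipeline_run`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("no output directory", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(config$seed)) set.seed(config$seed)

  ## inputs ----------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    if (is.null(syn$seed)) syn$seed <- config$seed
    ds <- simulate_dataset(syn)
    write_dataset(ds, p("inputs"))
    gs <- ds$genomes
    scheme <- ds$scheme
    obs <- ds$observations
  } else {
    scheme <- if (identical(config$scheme, "COG")) NULL else
      read_class_scheme(config$scheme)
    gs <- read_genome_annotations(config$annotations, scheme = scheme)
    scheme <- attr(gs, "scheme")
    if (!is.null(config$rrna_fasta)) {
      gs <- attach_rrna(gs, fasta = config$rrna_fasta)
    } else if (!is.null(config$rrna_counts)) {
      gs <- attach_rrna(gs, counts = config$rrna_counts)
    }
    obs <- read_observation_table(config$observations,
                                  config$samples_census)
  }
  message("inputs: ", nrow(gs$genomes), " genomes, ",
          nrow(attr(obs, "samples")), " samples")

  ## genomes ---------------------------------------------------------
  kept <- filter_by_annotation(gs)
  rep_f <- attr(kept, "filter_report")
  message(sprintf("annotation filter: kept %d of %d (mean %.3f, sd %.3f)",
                  rep_f$n_kept, rep_f$n_in, rep_f$mean, rep_f$sd))
  prof <- functional_profiles(kept, scheme)
  gen <- aggregate_genus(kept, prof)

  ## associations ----------------------------------------------------
  freq <- build_frequency_table(obs)
  assoc <- link_taxa(freq, alpha = config$alpha)
  ubiq <- ubiquity(freq)
  message("associations: ", attr(assoc, "n_tested"), " tested pairs, ",
          sum(assoc$linked), " linked")

  ## trait battery ---------------------------------------------------
  traits <- trait_table(gen, ubiq, assoc)
  observed <- traits[traits$ubiquity >= 1, , drop = FALSE]
  attr(observed, "linked") <- attr(traits, "linked")
  n_unobserved <- nrow(traits) - nrow(observed)
  if (n_unobserved > 0) {
    message(n_unobserved,
            " genera present in no environment; excluded from trait stages")
  }
  trait_tests <- if (length(unique(observed$ubiquity)) >= 2) {
    pipeline_trait_tests(observed, config$alpha)
  } else {
    message("fewer than 2 ubiquity values; trait battery skipped")
    NULL
  }
  confound <- if (length(attr(observed, "linked"))) {
    withCallingHandlers(class_vs_genome_size(observed, config$alpha),
                        warning = function(w) {
                          message("note: ", conditionMessage(w))
                          invokeRestart("muffleWarning")
                        })
  } else NULL

  ## COG screen ------------------------------------------------------
  screen <- NULL
  pres <- gen$presence[rownames(gen$presence) %in% observed$genus, ,
                       drop = FALSE]
  if (length(unique(ubiq[rownames(pres)])) >= config$min_bins) {
    pooled <- pool_by_ubiquity(pres, ubiq)
    screen <- screen_cogs(pooled, min_bins = config$min_bins,
                          alpha = config$alpha,
                          r2_threshold = config$r2_threshold)
    message("cog screen: ", sum(screen$selected), " of ", nrow(screen),
            " families selected")
  } else {
    message("fewer than ", config$min_bins,
            " ubiquity bins; COG screen skipped")
  }

  ## randomized control ---------------------------------------------
  ctrl <- randomization_control(obs, n_tables = config$n_random_tables,
                                alpha = config$alpha)
  message(sprintf("randomized control: mean linked pairs %.3f over %d tables",
                  ctrl$mean_linked, ctrl$n_tables))

  ## outputs ---------------------------------------------------------
  gp <- gen$traits
  write_tsv(gp, p("genus_profiles.tsv"))
  write_tsv(data.frame(genus = rownames(freq$counts), freq$counts,
                       check.names = FALSE, stringsAsFactors = FALSE),
            p("frequency_table.tsv"))
  write_tsv(as.data.frame(assoc), p("associations.tsv"))
  write_tsv(data.frame(genus = names(ubiq), ubiquity = unname(ubiq),
                       stringsAsFactors = FALSE), p("ubiquity.tsv"))
  if (!is.null(trait_tests)) write_tsv(trait_tests, p("trait_tests.tsv"))
  if (!is.null(confound)) write_tsv(confound, p("class_size_regressions.tsv"))
  if (!is.null(screen)) write_tsv(as.data.frame(screen), p("cog_screen.tsv"))
  write_tsv(data.frame(table = seq_along(ctrl$linked_per_table),
                       linked_pairs = ctrl$linked_per_table),
            p("randomization.tsv"))

  manifest <- list(
    package = "envubiq",
    version = as.character(utils::packageVersion("envubiq")),
    seed = config$seed,
    alpha = config$alpha,
    n_random_tables = config$n_random_tables,
    r2_threshold = config$r2_threshold,
    counts = list(
      genomes_in = rep_f$n_in,
      genomes_kept = rep_f$n_kept,
      genera = nrow(gen$traits),
      samples = nrow(attr(obs, "samples")),
      observations = nrow(obs),
      tested_pairs = attr(assoc, "n_tested"),
      linked_pairs = sum(assoc$linked),
      genera_unobserved = n_unobserved,
      trait_tests = if (is.null(trait_tests)) 0L else nrow(trait_tests),
      cogs_screened = if (is.null(screen)) 0L else nrow(screen),
      cogs_selected = if (is.null(screen)) 0L else sum(screen$selected),
      randomization_mean_linked = ctrl$mean_linked
    )
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(structure(manifest, class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run (seed ", x$seed %||% "none", ")\n", sep = "")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-28s %s\n", nm, format(x$counts[[nm]])))
  }
  invisible(x)
}
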