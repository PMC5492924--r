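# small in-code fixtures shared across tests

# genome set where genome i has annotation ratio ratios[i]
# (n_orfs fixed at 1000, all annotated ORFs in a single family)
gs_from_ratios <- function(ratios, genus = NULL) {
  n <- length(ratios)
  ids <- sprintf("gen%02d", seq_len(n))
  counts <- matrix(as.integer(round(ratios * 1000)), ncol = 1,
                   dimnames = list(ids, "COG0001"))
  genome_set(data.frame(genome_id = ids,
                        genus = genus %||% rep("gA", n),
                        genome_size = 4e6, n_orfs = 1000L,
                        stringsAsFactors = FALSE),
             counts)
}

# genome set from an explicit family count matrix
gs_from_counts <- function(counts, genus = NULL, n_orfs = NULL,
                           sizes = NULL, copies = NULL, distinct = NULL) {
  ids <- rownames(counts)
  g <- data.frame(genome_id = ids,
                  genus = genus %||% rep("gA", nrow(counts)),
                  genome_size = sizes %||% rep(4e6, nrow(counts)),
                  n_orfs = n_orfs %||% rep(1000L, nrow(counts)),
                  stringsAsFactors = FALSE)
  if (!is.null(copies)) {
    g$rrna16s_copies <- copies
    g$rrna16s_distinct <- distinct
  }
  genome_set(g, counts)
}

# observation table from a compact spec: list(envA = list(gA = n_samples...))
# detections spread over the first n samples of each environment block
obs_from_counts <- function(det, samples_per_env = 10) {
  envs <- names(det)
  census <- data.frame(
    sample_id = sprintf("%s_s%02d", rep(envs, each = samples_per_env),
                        rep(seq_len(samples_per_env), length(envs))),
    environment = rep(envs, each = samples_per_env),
    stringsAsFactors = FALSE)
  rows <- list()
  for (e in envs) {
    for (g in names(det[[e]])) {
      k <- det[[e]][[g]]
      if (k > 0) {
        ids <- census$sample_id[census$environment == e][seq_len(k)]
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = ids, environment = e, genus = g,
          stringsAsFactors = FALSE)
      }
    }
  }
  observation_table(do.call(rbind, rows), samples = census)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
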