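#' Construct a set of annotated genomes
#'
#' A `genome_set` bundles the genome-level annotation table with the
#' per-genome COG content. COG content is stored as an integer count
#' matrix (genomes x families: number of ORFs assigned to each family),
#' from which both distinct-family presence and ORF-level abundance are
#' derived. 16S rRNA gene sequences may be attached, in which case copy
#' and distinct-copy counts are (re)computed from them.
#'
#' @param genomes data.frame with columns `genome_id`, `genus`,
#'   `genome_size` (bp), `n_orfs`; optionally `rrna16s_copies` and
#'   `rrna16s_distinct` when no sequences are supplied.
#' @param cog_counts Integer matrix, rows named by `genome_id`, columns by
#'   family (COG) id. `n_annotated_orfs` is defined as its row sums.
#' @param rrna_seqs Optional named list (by `genome_id`) of character
#'   vectors of 16S sequences.
#' @return An object of class `genome_set`.
#' @export
genome_set <- function(genomes, cog_counts, rrna_seqs = NULL) {
  req <- c("genome_id", "genus", "genome_size", "n_orfs")
  if (!is.data.frame(genomes) || !all(req %in% names(genomes))) {
    stop("genomes must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(genomes$genome_id)) {
    stop("duplicated genome_id", call. = FALSE)
  }
  if (any(genomes$genome_size <= 0)) stop("genome_size must be > 0", call. = FALSE)
  if (!is.matrix(cog_counts) || is.null(rownames(cog_counts)) ||
      !setequal(rownames(cog_counts), genomes$genome_id)) {
    stop("cog_counts must be a matrix with rownames matching genome_id",
         call. = FALSE)
  }
  if (any(cog_counts < 0) || any(cog_counts != round(cog_counts))) {
    stop("cog_counts must hold non-negative integer counts", call. = FALSE)
  }
  cog_counts <- cog_counts[genomes$genome_id, , drop = FALSE]
  genomes$n_annotated_orfs <- as.integer(rowSums(cog_counts))
  if (any(genomes$n_annotated_orfs > genomes$n_orfs)) {
    stop("n_annotated_orfs exceeds n_orfs for some genome", call. = FALSE)
  }
  if (!is.null(rrna_seqs)) {
    rrna_seqs <- rrna_seqs[genomes$genome_id]
    cnt <- t(vapply(genomes$genome_id, function(g) {
      count_16s(rrna_seqs[[g]] %||% character(0), quiet = TRUE)
    }, integer(2)))
    genomes$rrna16s_copies <- cnt[, 1]
    genomes$rrna16s_distinct <- cnt[, 2]
  }
  if (all(c("rrna16s_copies", "rrna16s_distinct") %in% names(genomes)) &&
      any(genomes$rrna16s_distinct > genomes$rrna16s_copies)) {
    stop("rrna16s_distinct cannot exceed rrna16s_copies", call. = FALSE)
  }
  rownames(genomes) <- NULL
  structure(list(genomes = genomes, cog_counts = cog_counts,
                 rrna_seqs = rrna_seqs),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", nrow(x$genomes), "genomes,",
      length(unique(x$genomes$genus)), "genera,",
      ncol(x$cog_counts), "COG families\n")
  rep <- attr(x, "filter_report")
  if (!is.null(rep)) {
    cat(sprintf("  annotation filter: mean %.3f, sd %.3f; kept %d of %d\n",
                rep$mean, rep$sd, rep$n_kept, rep$n_in))
  }
  invisible(x)
}

subset_genome_set <- function(gs, keep_ids) {
  gn <- gs$genomes[match(keep_ids, gs$genomes$genome_id), , drop = FALSE]
  rownames(gn) <- NULL
  structure(list(genomes = gn,
                 cog_counts = gs$cog_counts[keep_ids, , drop = FALSE],
                 rrna_seqs = if (is.null(gs$rrna_seqs)) NULL else
                   gs$rrna_seqs[keep_ids]),
            class = "genome_set")
}

#' Annotation completeness of each genome
#'
#' Ratio of COG-annotated ORFs to total ORFs, the quantity the cohort
#' completeness filter operates on.
#'
#' @param gs A [genome_set()].
#' @return Named numeric vector of ratios in \[0, 1\].
#' @export
annotation_ratio <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  if (any(gs$genomes$n_orfs == 0)) {
    stop("degenerate genome with zero ORFs", call. = FALSE)
  }
  stats::setNames(gs$genomes$n_annotated_orfs / gs$genomes$n_orfs,
                  gs$genomes$genome_id)
}

#' Filter genomes by annotation completeness
#'
#' Scarcely (or excessively) annotated genomes distort functional
#' profiles. The filter keeps genomes whose annotation ratio falls within
#' one sample standard deviation of the cohort mean, boundaries
#' inclusive. With a single genome the SD is defined as 0 and the genome
#' is kept. The filter is applied once per cohort; re-running it on the
#' kept set recomputes the window and may drop further genomes.
#'
#' @param gs A [genome_set()].
#' @return The filtered `genome_set`, carrying a `filter_report` attribute
#'   with elements `mean`, `sd`, `n_in`, `n_kept`.
#' @export
filter_by_annotation <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  if (nrow(gs$genomes) == 0) stop("empty genome set", call. = FALSE)
  r <- annotation_ratio(gs)
  m <- mean(r)
  s <- if (length(r) > 1) stats::sd(r) else 0
  keep <- names(r)[r >= m - s & r <= m + s]
  out <- subset_genome_set(gs, keep)
  attr(out, "filter_report") <- list(mean = m, sd = s,
                                     n_in = length(r), n_kept = length(keep))
  out
}

#' Count 16S rRNA gene copies and distinct copies
#'
#' Distinct copies are non-identical sequences under exact string
#' equality after uppercasing.
#'
#' @param sequences Character vector of nucleotide sequences.
#' @param quiet Suppress the empty-input warning.
#' @return Integer vector `c(copies, distinct)`; `c(0L, 0L)` (with a
#'   warning) for empty input.
#' @examples
#' count_16s(c("ACGT", "acgt", "ACGA"))  # 3 copies, 2 distinct
#' @export
count_16s <- function(sequences, quiet = FALSE) {
  if (length(sequences) == 0) {
    if (!quiet) warning("no 16S sequences supplied; returning (0, 0)")
    return(c(copies = 0L, distinct = 0L))
  }
  up <- toupper(sequences)
  c(copies = length(up), distinct = length(unique(up)))
}

#' Per-genome normalized functional profiles
#'
#' For every genome, the fraction of distinct COG families in each
#' functional class (`cog_ratio`, distinct families in class divided by
#' total distinct families) and the fraction of ORFs assigned to each
#' class (`orf_ratio`, ORFs carrying a family of the class divided by
#' total ORFs). Families mapped to k classes contribute fractionally
#' (1/k) to each, so `cog_ratio` rows always sum to 1.
#'
#' @param gs A [genome_set()].
#' @param scheme A [cog_scheme()] covering the assigned family ids.
#' @param unknown What to do with family ids absent from the scheme:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return Object of class `functional_profiles`: list with matrices
#'   `cog_ratio` and `orf_ratio` (genomes x classes).
#' @export
functional_profiles <- function(gs, scheme, unknown = c("drop", "error")) {
  stopifnot(inherits(gs, "genome_set"), inherits(scheme, "class_scheme"))
  unknown <- match.arg(unknown)
  cogs <- colnames(gs$cog_counts)
  miss <- setdiff(cogs, names(scheme$cog_to_classes))
  if (length(miss)) {
    if (unknown == "error") {
      stop(length(miss), " family ids missing from scheme '",
           scheme$scheme_name, "'", call. = FALSE)
    }
    warning("dropping ", length(miss), " family ids missing from scheme '",
            scheme$scheme_name, "'")
  }
  known <- setdiff(cogs, miss)
  counts <- gs$cog_counts[, known, drop = FALSE]
  pres <- (counts > 0) + 0
  n_distinct <- rowSums(pres)
  if (any(n_distinct == 0)) {
    stop("genome(s) with no annotated COGs: ",
         paste(rownames(counts)[n_distinct == 0], collapse = ", "),
         call. = FALSE)
  }
  W <- scheme_weights(scheme, known)
  cog_ratio <- (pres %*% W) / n_distinct
  orf_ratio <- (counts %*% W) / gs$genomes$n_orfs
  structure(list(cog_ratio = cog_ratio, orf_ratio = orf_ratio,
                 scheme_name = scheme$scheme_name, classes = scheme$classes),
            class = "functional_profiles")
}

#' Aggregate genomes to genus level
#'
#' Each genus can contain several species/strains; traits and profiles
#' are averaged (unweighted arithmetic mean) over its member genomes.
#' The per-COG presence of a genus is the fraction of its genomes
#' carrying at least one copy of the family, a value between zero and
#' one.
#'
#' @param gs A (typically filtered) [genome_set()].
#' @param profiles Optional [functional_profiles()] for the same set; if
#'   supplied, class ratio matrices are averaged too.
#' @return Object of class `genus_profiles`: list with `traits`
#'   (data.frame: genus, n_genomes, mean_genome_size, mean_16s_copies,
#'   mean_16s_distinct), `presence` (genus x COG fraction matrix) and,
#'   when profiles were given, `cog_ratio` / `orf_ratio` matrices.
#' @export
aggregate_genus <- function(gs, profiles = NULL) {
  stopifnot(inherits(gs, "genome_set"))
  g <- gs$genomes
  genus <- factor(g$genus, levels = sort(unique(g$genus)))
  n <- as.vector(table(genus))
  mean_by <- function(x) as.vector(rowsum(x, genus) / n)
  traits <- data.frame(
    genus = levels(genus),
    n_genomes = n,
    mean_genome_size = mean_by(g$genome_size),
    mean_16s_copies = if ("rrna16s_copies" %in% names(g))
      mean_by(g$rrna16s_copies) else NA_real_,
    mean_16s_distinct = if ("rrna16s_distinct" %in% names(g))
      mean_by(g$rrna16s_distinct) else NA_real_,
    stringsAsFactors = FALSE
  )
  presence <- rowsum((gs$cog_counts > 0) + 0, genus) / n
  out <- list(traits = traits, presence = presence)
  if (!is.null(profiles)) {
    stopifnot(inherits(profiles, "functional_profiles"))
    out$cog_ratio <- rowsum(profiles$cog_ratio[g$genome_id, , drop = FALSE],
                            genus) / n
    out$orf_ratio <- rowsum(profiles$orf_ratio[g$genome_id, , drop = FALSE],
                            genus) / n
    out$classes <- profiles$classes
  }
  structure(out, class = "genus_profiles")
}

#' @export
print.genus_profiles <- function(x, ...) {
  cat("genus_profiles:", nrow(x$traits), "genera,",
      ncol(x$presence), "COG families\n")
  invisible(x)
}

#' Read a genome annotation TSV
#'
#' Expected columns: `genome_id`, `genus`, `genome_size_bp`, `n_orfs`,
#' `gene_id`, `cog_id`, `class_letters` — one row per gene; genes without
#' a COG assignment leave `cog_id` empty. The family-to-class mapping is
#' taken from the `class_letters` column unless a scheme is supplied.
#'
#' @param path Annotation TSV path.
#' @param scheme Optional [cog_scheme()]; if `NULL`, derived from the file.
#' @return A [genome_set()] with the scheme attached as attribute
#'   `"scheme"`.
#' @export
read_genome_annotations <- function(path, scheme = NULL) {
  df <- read_tsv(path, col_classes = c(
    genome_id = "character", genus = "character", gene_id = "character",
    cog_id = "character", class_letters = "character"))
  req <- c("genome_id", "genus", "genome_size_bp", "n_orfs",
           "gene_id", "cog_id", "class_letters")
  if (!all(req %in% names(df))) {
    stop("annotation TSV needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df$cog_id[is.na(df$cog_id)] <- ""
  gmeta <- unique(df[c("genome_id", "genus", "genome_size_bp", "n_orfs")])
  if (anyDuplicated(gmeta$genome_id)) {
    bad <- gmeta$genome_id[duplicated(gmeta$genome_id)][1]
    stop("inconsistent genome-level fields for ", bad, call. = FALSE)
  }
  genomes <- data.frame(genome_id = gmeta$genome_id, genus = gmeta$genus,
                        genome_size = gmeta$genome_size_bp,
                        n_orfs = gmeta$n_orfs, stringsAsFactors = FALSE)
  ann <- df[nzchar(df$cog_id), , drop = FALSE]
  counts <- unclass(table(factor(ann$genome_id, levels = genomes$genome_id),
                          ann$cog_id))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts), colnames(counts)))
  if (is.null(scheme)) {
    map <- unique(ann[c("cog_id", "class_letters")])
    if (anyDuplicated(map$cog_id)) {
      stop("conflicting class_letters for some cog_id", call. = FALSE)
    }
    scheme <- cog_scheme(stats::setNames(map$class_letters, map$cog_id))
  }
  gs <- genome_set(genomes, counts)
  attr(gs, "scheme") <- scheme
  gs
}

#' Attach 16S data to a genome set
#'
#' Either from a FASTA of per-genome 16S copies (headers
#' `>genomeID_rrna_N`) or from a precomputed count TSV with columns
#' `genome_id`, `copies`, `distinct`.
#'
#' @param gs A [genome_set()].
#' @param fasta,counts Path to one of the two input forms.
#' @return The updated `genome_set`.
#' @export
attach_rrna <- function(gs, fasta = NULL, counts = NULL) {
  stopifnot(inherits(gs, "genome_set"))
  if (!is.null(fasta)) {
    seqs <- read_rrna_fasta(fasta)
    return(genome_set(gs$genomes[setdiff(names(gs$genomes),
                                         c("n_annotated_orfs"))],
                      gs$cog_counts, rrna_seqs = seqs))
  }
  if (!is.null(counts)) {
    df <- read_tsv(counts, col_classes = c(genome_id = "character"))
    i <- match(gs$genomes$genome_id, df$genome_id)
    if (anyNA(i)) stop("16S counts missing for some genomes", call. = FALSE)
    gs$genomes$rrna16s_copies <- df$copies[i]
    gs$genomes$rrna16s_distinct <- df$distinct[i]
    if (any(gs$genomes$rrna16s_distinct > gs$genomes$rrna16s_copies)) {
      stop("rrna16s_distinct cannot exceed rrna16s_copies", call. = FALSE)
    }
    return(gs)
  }
  stop("supply fasta or counts", call. = FALSE)
}

#' Read per-genome 16S sequences from FASTA
#'
#' Headers follow `genomeID_rrna_N`; the `_rrna_N` suffix is stripped to
#' recover the genome id.
#'
#' @param path FASTA path.
#' @return Named list of character vectors, one per genome.
#' @export
read_rrna_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("_rrna_\\d+$", "", names(set))
  split(as.character(set), ids)
}
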