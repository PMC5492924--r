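#' Functional class descriptions of the default COG scheme
#'
#' The 18 single-letter functional classes of the classic COG
#' classification, with their long descriptions. Each COG identifier maps
#' to one or more of these letters; profiles are computed per class.
#'
#' @format Named character vector: names are class letters, values are
#'   descriptions.
#' @export
cog_class_descriptions <- c(
  J = "Translation, ribosomal structure and biogenesis",
  K = "Transcription",
  L = "Replication, recombination and repair",
  D = "Cell cycle control, cell division, chromosome partitioning",
  O = "Posttranslational modification, protein turnover, chaperones",
  M = "Cell wall/membrane/envelope biogenesis",
  N = "Cell motility",
  P = "Inorganic ion transport and metabolism",
  T = "Signal transduction mechanisms",
  C = "Energy production and conversion",
  G = "Carbohydrate transport and metabolism",
  E = "Amino acid transport and metabolism",
  F = "Nucleotide transport and metabolism",
  H = "Coenzyme transport and metabolism",
  I = "Lipid transport and metabolism",
  Q = "Secondary metabolites biosynthesis, transport and catabolism",
  R = "General function prediction only",
  S = "Function unknown"
)

#' Build a functional class scheme
#'
#' A class scheme maps gene-family identifiers (COG ids, or KEGG-style ids
#' for an alternative scheme) to one or more functional class identifiers.
#' The default class set is the 18-class COG scheme
#' (see [cog_class_descriptions]); any other ordered class set can be
#' supplied, which makes the profile machinery scheme-agnostic.
#'
#' @param cog_classes Named character vector. Names are family (COG) ids,
#'   values are strings of class identifiers, e.g. `"E"` or `"EG"` for a
#'   family mapped to two classes.
#' @param classes Ordered character vector of valid class identifiers.
#' @param scheme_name Label for the scheme.
#' @return An object of class `class_scheme`.
#' @examples
#' sch <- cog_scheme(c(COG0001 = "E", COG0002 = "EG"))
#' @export
cog_scheme <- function(cog_classes, classes = names(cog_class_descriptions),
                       scheme_name = "COG") {
  if (!is.character(cog_classes) || is.null(names(cog_classes)) ||
      anyNA(cog_classes) || any(!nzchar(cog_classes))) {
    stop("cog_classes must be a named character vector of class letters",
         call. = FALSE)
  }
  if (anyDuplicated(names(cog_classes))) {
    stop("duplicated family ids in cog_classes", call. = FALSE)
  }
  used <- unique(unlist(strsplit(cog_classes, "", fixed = TRUE)))
  bad <- setdiff(used, classes)
  if (length(bad)) {
    stop("class identifiers not in the scheme: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(scheme_name = scheme_name,
                 classes = classes,
                 cog_to_classes = cog_classes),
            class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("Class scheme '", x$scheme_name, "': ", length(x$classes),
      " classes, ", length(x$cog_to_classes), " mapped families\n", sep = "")
  invisible(x)
}

# families x classes weight matrix; a family mapped to k classes
# contributes 1/k to each (fractional counting keeps ratios summing to 1)
scheme_weights <- function(scheme, cogs) {
  cl <- scheme$cog_to_classes[cogs]
  parts <- strsplit(cl, "", fixed = TRUE)
  k <- lengths(parts)
  W <- matrix(0, nrow = length(cogs), ncol = length(scheme$classes),
              dimnames = list(cogs, scheme$classes))
  W[cbind(rep(seq_along(cogs), k), match(unlist(parts), scheme$classes))] <-
    rep(1 / k, k)
  W
}

#' Read / write a class scheme as TSV
#'
#' The file holds one row per family: `cog_id<TAB>class_letters`.
#'
#' @param path File path.
#' @param classes,scheme_name Passed to [cog_scheme()].
#' @return `read_class_scheme` returns a `class_scheme`;
#'   `write_class_scheme` returns `path` invisibly.
#' @export
read_class_scheme <- function(path, classes = names(cog_class_descriptions),
                              scheme_name = "COG") {
  df <- read_tsv(path, col_classes = "character")
  if (!all(c("cog_id", "class_letters") %in% names(df))) {
    stop("scheme TSV needs columns cog_id, class_letters", call. = FALSE)
  }
  cog_scheme(stats::setNames(df$class_letters, df$cog_id),
             classes = classes, scheme_name = scheme_name)
}

#' @rdname read_class_scheme
#' @param scheme A `class_scheme`.
#' @export
write_class_scheme <- function(scheme, path) {
  write_tsv(data.frame(cog_id = names(scheme$cog_to_classes),
                       class_letters = unname(scheme$cog_to_classes),
                       stringsAsFactors = FALSE), path)
}
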