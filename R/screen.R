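#' Pool per-genus COG presence by ubiquity
#'
#' Genera found in the same number of environments are pooled, and the
#' pooled value of each COG is the unweighted mean of the genus-level
#' presences in the bin. Empty bins are absent from the output.
#'
#' @param presence Genus x COG presence matrix (fractions in \[0, 1\]),
#'   rows named by genus — typically `aggregate_genus()$presence`.
#' @param ubiq Named ubiquity vector covering every row of `presence`.
#' @return Matrix bins x COGs; rownames are the ubiquity values.
#' @export
pool_by_ubiquity <- function(presence, ubiq) {
  if (is.null(rownames(presence))) stop("presence needs rownames",
                                        call. = FALSE)
  u <- ubiq[rownames(presence)]
  if (anyNA(u)) stop("ubiquity missing for some genera", call. = FALSE)
  f <- factor(u, levels = sort(unique(u)))
  pooled <- rowsum(presence, f) / as.vector(table(f))
  rownames(pooled) <- levels(f)
  pooled
}

#' Per-COG ubiquity regression screen
#'
#' Regresses each COG's pooled presence on the ubiquity bin value
#' (ordinary least squares on bin means) and selects families whose
#' presence tracks ubiquity strongly and linearly: slope p-value below
#' `alpha` and adjusted R-squared above `r2_threshold`. By default only
#' positive slopes (presence rising with ubiquity) are selected; negative
#' trends can pass the gate when `positive_only = FALSE`.
#'
#' @param pooled Bin x COG matrix from [pool_by_ubiquity()].
#' @param min_bins Minimum number of distinct bins (default 4, keeping
#'   the n - 2 df adjusted R-squared stable).
#' @param alpha Slope p-value threshold (default 0.01).
#' @param r2_threshold Adjusted R-squared threshold (default 0.7).
#' @param positive_only Require slope > 0 for selection.
#' @return data.frame of class `cog_screen`, sorted by adjusted
#'   R-squared descending: columns `cog_id`, `slope`, `p_value`,
#'   `r_squared`, `adjusted_r_squared`, `selected`.
#' @export
screen_cogs <- function(pooled, min_bins = 4, alpha = 0.01,
                        r2_threshold = 0.7, positive_only = TRUE) {
  bins <- suppressWarnings(as.numeric(rownames(pooled)))
  if (anyNA(bins)) stop("pooled rownames must be numeric bin values",
                        call. = FALSE)
  if (length(bins) < min_bins) {
    stop("fewer than min_bins (", min_bins, ") ubiquity bins", call. = FALSE)
  }
  res <- lapply(seq_len(ncol(pooled)), function(j) {
    r <- linear_regression(bins, pooled[, j])
    c(slope = r$slope, p_value = r$p_value, r_squared = r$r_squared,
      adjusted_r_squared = r$adjusted_r_squared)
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(data.frame(cog_id = colnames(pooled),
                          stringsAsFactors = FALSE), out)
  out$selected <- out$p_value < alpha &
    out$adjusted_r_squared > r2_threshold &
    (!positive_only | out$slope > 0)
  out <- out[order(-out$adjusted_r_squared, out$cog_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, alpha = alpha, r2_threshold = r2_threshold,
            positive_only = positive_only, n_bins = length(bins),
            class = c("cog_screen", "data.frame"))
}

#' @export
print.cog_screen <- function(x, n = 10, ...) {
  cat("cog_screen:", nrow(x), "families over", attr(x, "n_bins"),
      "ubiquity bins;", sum(x$selected), "selected (p <", attr(x, "alpha"),
      ", adj. R^2 >", attr(x, "r2_threshold"), ")\n")
  if (sum(x$selected) > 0) {
    print.data.frame(utils::head(x[x$selected, , drop = FALSE], n),
                     row.names = FALSE, digits = 4)
  }
  invisible(x)
}
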