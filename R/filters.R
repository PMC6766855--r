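# The site-selection cascade: per-library depth window, within-group
# replicate heterogeneity chi-square, cross-group intersection, and the
# polymorphism call on group-pooled counts.

#' Filter configuration
#'
#' @param min_depth minimum per-library depth (inclusive); sites with fewer
#'   reads in any library are removed.
#' @param max_depth maximum per-library depth (inclusive); deeper sites are
#'   treated as repetitive DNA and removed.
#' @param heterogeneity_alpha significance level of the replicate
#'   concordance chi-square: sites whose replicate nucleotide counts differ
#'   at this level (within either group) are removed. The default 1e-8 is
#'   deliberately stringent: replicate pools of 25 individuals differ in
#'   composition, which inflates the read-count chi-square ~2.5-fold at
#'   100x depth, so a conventional 0.05 cut would discard a large share of
#'   genuinely concordant polymorphic sites (see the methods vignette);
#'   the default targets gross discordance (sample swaps, paralogous
#'   mis-mapping) only.
#' @param min_minor_count,min_minor_freq a site is called polymorphic when,
#'   in counts pooled over all libraries, the second-most-frequent base
#'   reaches both this count and this frequency.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 25L, max_depth = 1000L,
                          heterogeneity_alpha = 1e-8,
                          min_minor_count = 2L, min_minor_freq = 0.01) {
  if (!(min_depth > 0 && min_depth <= max_depth)) {
    stopf("need 0 < min_depth <= max_depth")
  }
  if (!(heterogeneity_alpha > 0 && heterogeneity_alpha < 1)) {
    stopf("heterogeneity_alpha must be in (0, 1)")
  }
  structure(list(min_depth = as.integer(min_depth),
                 max_depth = as.integer(max_depth),
                 heterogeneity_alpha = heterogeneity_alpha,
                 min_minor_count = as.integer(min_minor_count),
                 min_minor_freq = min_minor_freq),
            class = "filter_config")
}

#' Depth-window filter
#'
#' Keeps a site iff every considered library's depth lies in
#' `[min_depth, max_depth]` (both inclusive). Libraries marked missing (NA
#' counts) fail the window.
#'
#' @param x a [pool_counts] object.
#' @param config a [filter_config].
#' @param libraries optional character vector of library ids to consider
#'   (default: all).
#' @return logical keep vector, one element per site.
#' @export
depth_filter <- function(x, config = filter_config(), libraries = NULL) {
  d <- site_depths(x)
  if (!is.null(libraries)) d <- d[, libraries, drop = FALSE]
  ok <- d >= config$min_depth & d <= config$max_depth
  ok[is.na(ok)] <- FALSE
  rowSums(ok) == ncol(d)
}

#' Replicate heterogeneity chi-square test
#'
#' Pearson chi-square on the 2 x n table of per-nucleotide counts of two
#' replicate libraries, where n is the number of bases observed (count > 0)
#' in either replicate, with df = n - 1. Monomorphic sites (n = 1) return
#' `(chi2 0, df 0, p 1)` by convention. No continuity correction or
#' pseudocounts are applied.
#'
#' @param counts_rep1,counts_rep2 numeric vectors of length 4 (A, C, G, T
#'   counts) for the two replicates.
#' @return list with `chi2`, `df`, `p`.
#' @export
replicate_heterogeneity_test <- function(counts_rep1, counts_rep2) {
  r1 <- as.numeric(counts_rep1); r2 <- as.numeric(counts_rep2)
  if (length(r1) != 4 || length(r2) != 4) {
    stopf("replicate counts must be length-4 vectors (A, C, G, T)")
  }
  if (anyNA(r1) || anyNA(r2) || (sum(r1) == 0 && sum(r2) == 0)) {
    stopf("all-zero or missing replicate counts")
  }
  pearson_chisq_one(r1, r2)
}

# vectorised within-group replicate concordance: TRUE = concordant (keep).
# For groups with >2 replicates the test compares each replicate against the
# sum of the others and keeps the site only if all pass.
group_concordant <- function(x, group, alpha) {
  libs <- group_libs(x, group)
  if (length(libs) < 2) return(rep(TRUE, nrow(x$sites)))
  keep <- rep(TRUE, nrow(x$sites))
  if (length(libs) == 2) {
    a <- matrix(x$counts[, , libs[1]], ncol = 4)
    b <- matrix(x$counts[, , libs[2]], ncol = 4)
    res <- pearson_chisq_rows(a, b)
    keep <- res$p >= alpha
  } else {
    total <- pooled_counts(x, group)
    for (j in libs) {
      a <- matrix(x$counts[, , j], ncol = 4)
      res <- pearson_chisq_rows(a, total - a)
      keep <- keep & res$p >= alpha
    }
  }
  keep[is.na(keep)] <- FALSE
  keep
}

# polymorphism call on counts pooled over all libraries
polymorphic_call <- function(pooled, config) {
  pooled <- as.matrix(pooled)
  if (nrow(pooled) == 0) return(logical(0))
  depth <- rowSums(pooled)
  sorted <- t(apply(pooled, 1, sort, decreasing = TRUE))
  minor <- sorted[, 2]
  depth > 0 & minor >= config$min_minor_count &
    minor / depth >= config$min_minor_freq
}

#' Run the full site-selection cascade
#'
#' Stages, in order: per-library depth window within each phenotype group;
#' replicate heterogeneity chi-square within each group; intersection of the
#' sites retained by both groups; polymorphism call on the counts pooled
#' over all libraries. Filters never modify counts: the result is a subset
#' of the input records.
#'
#' @param x a [pool_counts] object.
#' @param config a [filter_config].
#' @return list with `records` (the retained, polymorphic [pool_counts]),
#'   `common` (the retained common sites before the polymorphism call) and
#'   `report` (a `filter_report` data.frame of per-stage tallies).
#' @export
filter_sites <- function(x, config = filter_config()) {
  n <- nrow(x$sites)
  stages <- list()
  keep_group <- list()
  for (grp in c("resistant", "susceptible")) {
    libs <- x$libraries$id[x$libraries$group == grp]
    dk <- depth_filter(x, config, libraries = libs)
    hk <- dk & group_concordant(x, grp, config$heterogeneity_alpha)
    keep_group[[grp]] <- hk
    stages[[paste0("depth_", grp)]] <- sum(dk)
    stages[[paste0("concordant_", grp)]] <- sum(hk)
  }
  common <- keep_group$resistant & keep_group$susceptible
  stages$common <- sum(common)
  xc <- x[common]
  poly <- polymorphic_call(pooled_counts(xc, "resistant") +
                             pooled_counts(xc, "susceptible"), config)
  stages$polymorphic <- sum(poly)
  report <- data.frame(stage = c("input", names(stages)),
                       n_sites = c(n, unlist(stages, use.names = FALSE)))
  class(report) <- c("filter_report", class(report))
  list(records = xc[poly], common = xc, report = report)
}

#' Select common polymorphic sites given per-group retention
#'
#' Lower-level entry point matching the cascade's final stages: intersect
#' per-group retained sites and call polymorphism on the pooled counts.
#'
#' @param x a [pool_counts] object.
#' @param keep_resistant,keep_susceptible logical vectors of sites retained
#'   by the per-group depth + concordance filters.
#' @param config a [filter_config].
#' @return as [filter_sites] (without the per-group stages in the report).
#' @export
select_common_polymorphic_sites <- function(x, keep_resistant,
                                            keep_susceptible,
                                            config = filter_config()) {
  common <- keep_resistant & keep_susceptible
  xc <- x[common]
  poly <- if (nrow(xc$sites)) {
    polymorphic_call(pooled_counts(xc, "resistant") +
                       pooled_counts(xc, "susceptible"), config)
  } else logical(0)
  report <- data.frame(stage = c("input", "common", "polymorphic"),
                       n_sites = c(nrow(x$sites), sum(common), sum(poly)))
  class(report) <- c("filter_report", class(report))
  list(records = xc[poly], common = xc, report = report)
}
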