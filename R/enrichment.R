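# Gene-category polymorphism enrichment: exact Fisher tests on 2x2 tables
# of polymorphic vs non-polymorphic analysed sites, inside vs outside a
# gene category, per chromosome.

#' Exact Fisher test on a 2 x 2 table
#'
#' Exact hypergeometric test computed by accumulating `stats::dhyper` mass
#' over the full support of the table's top-left cell, so it remains exact
#' at arbitrarily large margins. The two-sided p-value follows the
#' minimum-likelihood convention: the sum of the probabilities of all
#' tables no more likely than the observed one (with the customary 1e-7
#' relative tolerance for ties).
#'
#' @param a,b,c,d the table counts (row 1: a, b; row 2: c, d).
#' @param alternative `"two_sided"`, `"greater"` (positive association of
#'   row 1 with column 1) or `"less"`.
#' @return the exact p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("table counts must be non-negative integers")
  }
  m <- a + b          # row-1 margin
  n <- c + d          # row-2 margin
  k <- a + c          # column-1 margin
  if (m + n == 0) stopf("empty table")
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  switch(alternative,
         greater = sum(dens[support >= a]),
         less = sum(dens[support <= a]),
         two_sided = sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Polymorphism enrichment of a gene category
#'
#' Builds, per chromosome, the 2 x 2 table of analysed sites classified as
#' polymorphic / non-polymorphic and inside / outside the genes tagged with
#' `category`, and tests it with [fisher_exact_2x2]. The site universe is
#' all filter-passing analysed sites (polymorphic and monomorphic alike).
#'
#' @param sites data.frame of analysed sites with columns `chrom`, `pos`.
#' @param polymorphic logical vector flagging the polymorphic subset.
#' @param models gene-model intervals (carrying category tags).
#' @param category a tag from `r paste(CATEGORY_TAGS, collapse = ", ")`, or
#'   `"detox"` for the union of CYP, CCE, GST and Redox.
#' @param per_chromosome build one table per chromosome (default) or a
#'   single pooled table.
#' @param alternative passed to [fisher_exact_2x2].
#' @return data.frame with one row per chromosome: the four counts `a`
#'   (polymorphic, in category), `b`, `c`, `d`, the two proportions, and
#'   `fisher_p` (NA, flagged `undefined`, when the category has no analysed
#'   sites on that chromosome).
#' @export
category_polymorphism_enrichment <- function(sites, polymorphic, models,
                                             category = "detox",
                                             per_chromosome = TRUE,
                                             alternative = "two_sided") {
  stopifnot(nrow(sites) == length(polymorphic))
  tags <- if (identical(category, "detox")) DETOX_TAGS else category
  if (!all(tags %in% CATEGORY_TAGS)) {
    stopf("unknown category '%s'; allowed: detox, %s", category,
          paste(CATEGORY_TAGS, collapse = ", "))
  }
  cats <- gene_categories(models)
  spans <- gene_spans(models)
  spans <- spans[cats[spans$gene_id] %in% tags, , drop = FALSE]
  in_cat <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(spans))) {
    in_cat <- in_cat | (sites$chrom == spans$chrom[i] &
                          sites$pos >= spans$start[i] &
                          sites$pos <= spans$end[i])
  }
  grp <- if (per_chromosome) as.character(sites$chrom) else
    rep("all", nrow(sites))
  out <- lapply(unique(grp), function(cc) {
    sel <- grp == cc
    a <- sum(sel & in_cat & polymorphic)
    b <- sum(sel & in_cat & !polymorphic)
    c_ <- sum(sel & !in_cat & polymorphic)
    d <- sum(sel & !in_cat & !polymorphic)
    undefined <- (a + b) == 0
    data.frame(category = category, chromosome = cc,
               a = a, b = b, c = c_, d = d,
               proportion_in = if (a + b > 0) a / (a + b) else NA_real_,
               proportion_out = if (c_ + d > 0) c_ / (c_ + d) else NA_real_,
               fisher_p = if (undefined) NA_real_ else
                 fisher_exact_2x2(a, b, c_, d, alternative),
               undefined = undefined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
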