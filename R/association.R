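# Resistant-vs-susceptible association: pooled contingency chi-square per
# site, and per-chromosome Benjamini-Hochberg FDR control.

#' Association test at a single site
#'
#' Replicate libraries are summed within each phenotype group and the
#' resulting 2 x n group-by-allele table is scored with a Pearson
#' chi-square (df = n - 1, n = alleles observed in the pooled table; no
#' continuity correction; alleles absent from both groups are dropped).
#'
#' @param resistant_counts,susceptible_counts either length-4 vectors of
#'   pooled A/C/G/T counts or matrices with one row per replicate (rows are
#'   summed).
#' @param neg_log10_cap cap applied to `-log10(p)` when p underflows to 0
#'   (the capped state is flagged in `capped`).
#' @return list with `chi2`, `df`, `p`, `neg_log10_p`, `capped`,
#'   `freq_resistant`, `freq_susceptible` (per-base frequency vectors).
#' @export
association_test <- function(resistant_counts, susceptible_counts,
                             neg_log10_cap = 320) {
  r <- if (is.matrix(resistant_counts)) colSums(resistant_counts) else
    as.numeric(resistant_counts)
  s <- if (is.matrix(susceptible_counts)) colSums(susceptible_counts) else
    as.numeric(susceptible_counts)
  if (length(r) != 4 || length(s) != 4) {
    stopf("group counts must have 4 nucleotide columns (A, C, G, T)")
  }
  if (sum((r + s) > 0) < 2) {
    stopf("monomorphic pooled table: the polymorphism filter should have removed this site")
  }
  res <- pearson_chisq_one(r, s)
  nlp <- -log10(res$p)
  capped <- !is.finite(nlp) | nlp > neg_log10_cap
  if (capped) nlp <- neg_log10_cap
  list(chi2 = res$chi2, df = res$df, p = res$p, neg_log10_p = nlp,
       capped = capped,
       freq_resistant = r / sum(r), freq_susceptible = s / sum(s))
}

#' Score all sites of a filtered count set
#'
#' Vectorised association scan over a [pool_counts] object (normally the
#' polymorphic records returned by [filter_sites]). The reported alternate
#' allele is the most frequent non-reference base in the overall pooled
#' counts; `freq_resistant` / `freq_susceptible` are that allele's
#' within-group frequencies.
#'
#' @param x a [pool_counts] object of polymorphic sites.
#' @param neg_log10_cap see [association_test].
#' @return data.frame of association records: `chrom`, `pos`, `ref`, `alt`,
#'   pooled per-group counts, `chi2`, `df`, `p`, `neg_log10_p`, `capped`,
#'   `freq_resistant`, `freq_susceptible` (columns `fdr_pass` and
#'   `fdr_threshold` are added by [apply_fdr]).
#' @export
associate_sites <- function(x, neg_log10_cap = 320) {
  r <- pooled_counts(x, "resistant")
  s <- pooled_counts(x, "susceptible")
  res <- pearson_chisq_rows(r, s)
  total <- r + s
  refidx <- match(x$sites$ref, BASES)
  masked <- total
  masked[cbind(seq_len(nrow(total)), refidx)] <- -1L
  altidx <- max.col(masked, ties.method = "first")
  alt <- BASES[altidx]
  pick <- cbind(seq_len(nrow(total)), altidx)
  nlp <- -log10(res$p)
  capped <- !is.finite(nlp) | nlp > neg_log10_cap
  nlp[capped] <- neg_log10_cap
  rd <- rowSums(r); sd_ <- rowSums(s)
  data.frame(chrom = x$sites$chrom, pos = x$sites$pos, ref = x$sites$ref,
             alt = alt,
             depth_resistant = rd, depth_susceptible = sd_,
             alt_resistant = r[pick], alt_susceptible = s[pick],
             chi2 = res$chi2, df = res$df, p = res$p,
             neg_log10_p = nlp, capped = capped,
             freq_resistant = ifelse(rd > 0, r[pick] / rd, NA_real_),
             freq_susceptible = ifelse(sd_ > 0, s[pick] / sd_, NA_real_),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up thresholds per chromosome
#'
#' For each chromosome, sorts the p-values ascending and finds the largest k
#' with `p(k) <= k * alpha / m`; all sites with `p <= p(k)` are discoveries
#' (the standard step-up tie convention). The reported threshold is
#' `-log10(p(k))`, i.e. the score of the least-significant passing SNP.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param chrom chromosome of each p-value.
#' @param alpha FDR level (default 0.01).
#' @return data.frame with one row per chromosome: `chromosome`, `alpha`,
#'   `m` (tests), `k` (discoveries), `threshold_neg_log10` (NA when k = 0).
#' @export
bh_thresholds <- function(p, chrom, alpha = 0.01) {
  stopifnot(length(p) == length(chrom))
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0, 1)")
  chroms <- unique(as.character(chrom))
  out <- lapply(chroms, function(cc) {
    pc <- p[chrom == cc]
    m <- length(pc)
    if (m == 0) {
      return(data.frame(chromosome = cc, alpha = alpha, m = 0L, k = 0L,
                        threshold_neg_log10 = NA_real_))
    }
    ps <- sort(pc)
    ok <- which(ps <= seq_len(m) * alpha / m)
    if (length(ok) == 0) {
      data.frame(chromosome = cc, alpha = alpha, m = m, k = 0L,
                 threshold_neg_log10 = NA_real_)
    } else {
      k <- max(ok)
      data.frame(chromosome = cc, alpha = alpha, m = m,
                 k = sum(pc <= ps[k]),
                 threshold_neg_log10 = -log10(ps[k]))
    }
  })
  do.call(rbind, out)
}

#' Flag FDR-passing records
#'
#' @param records association records from [associate_sites].
#' @param alpha FDR level, applied per chromosome.
#' @return `records` with added logical `fdr_pass` and numeric
#'   `fdr_threshold` (the chromosome's `-log10` threshold), plus the
#'   threshold table as attribute `"fdr"`.
#' @export
apply_fdr <- function(records, alpha = 0.01) {
  fdr <- bh_thresholds(records$p, records$chrom, alpha)
  idx <- match(records$chrom, fdr$chromosome)
  thr <- fdr$threshold_neg_log10[idx]
  records$fdr_pass <- !is.na(thr) & records$neg_log10_p >= thr
  records$fdr_threshold <- thr
  attr(records, "fdr") <- fdr
  records
}
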