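# Selective-sweep diagnostics: per-group expected heterozygosity at
# significant SNPs, per-chromosome paired t tests of Het(alive) - Het(dead),
# and a focal-region profile for plotting.

#' Expected heterozygosity of a site
#'
#' `H_exp = 1 - sum(p_i^2)` over the allele frequencies at the site; for
#' nucleotide data the maximum is 0.75 (four equifrequent alleles).
#'
#' @param frequencies numeric vector of allele frequencies; must sum to 1
#'   (tolerance 1e-9).
#' @return `H_exp` in `[0, 0.75]`.
#' @export
site_heterozygosity <- function(frequencies) {
  check_prob(frequencies, "frequencies")
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stopf("frequencies must sum to 1 (got %.12f)", sum(frequencies))
  }
  1 - sum(frequencies^2)
}

# rowwise H_exp from a count matrix (n x 4); rows with zero depth -> NA
het_from_counts <- function(counts) {
  d <- rowSums(counts)
  f <- counts / d
  ifelse(d > 0, 1 - rowSums(f^2), NA_real_)
}

#' Per-site sweep records at significant SNPs
#'
#' Computes expected heterozygosity per phenotype group from the
#' group-pooled read counts (replicates summed, consistent with the
#' association table) and their difference Het(alive) - Het(dead).
#'
#' @param x the filtered [pool_counts] records underlying `records`.
#' @param records association records (with `fdr_pass` from [apply_fdr]).
#' @param significant_only keep only FDR-passing SNPs (default TRUE, the
#'   sweep test's universe).
#' @return data.frame with `chrom`, `pos`, `het_resistant`,
#'   `het_susceptible`, `diff`, `neg_log10_p`.
#' @export
sweep_records <- function(x, records, significant_only = TRUE) {
  stopifnot(nrow(x$sites) == nrow(records))
  hr <- het_from_counts(pooled_counts(x, "resistant"))
  hs <- het_from_counts(pooled_counts(x, "susceptible"))
  out <- data.frame(chrom = records$chrom, pos = records$pos,
                    het_resistant = hr, het_susceptible = hs,
                    diff = hr - hs, neg_log10_p = records$neg_log10_p,
                    stringsAsFactors = FALSE)
  if (significant_only) {
    if (is.null(records$fdr_pass)) stopf("records carry no fdr_pass flag; run apply_fdr()")
    out <- out[records$fdr_pass, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Paired t test of heterozygosity differences on one chromosome
#'
#' One-sample two-sided t test of the per-SNP differences
#' Het(alive) - Het(dead) against zero (equivalently a paired t test of the
#' two heterozygosity vectors), with a directional sweep call: a chromosome
#' is flagged `"Y"` iff the mean difference is negative (variation reduced
#' in survivors) and p < 0.05.
#'
#' @param diffs numeric vector of per-SNP differences (one chromosome).
#' @param chromosome label carried into the result.
#' @return data.frame row: `chromosome`, `n`, `mean`, `cl_low`, `cl_high`,
#'   `t`, `p`, `sweep` ("Y"/"N"). With fewer than 2 finite diffs the test
#'   fields are NA and `sweep` is `"N"`.
#' @export
het_difference_test <- function(diffs, chromosome = NA_character_) {
  d <- diffs[is.finite(diffs)]
  n <- length(d)
  if (n < 2) {
    return(data.frame(chromosome = chromosome, n = n,
                      mean = if (n) mean(d) else NA_real_,
                      cl_low = NA_real_, cl_high = NA_real_,
                      t = NA_real_, p = NA_real_, sweep = "N",
                      stringsAsFactors = FALSE))
  }
  m <- mean(d)
  if (stats::sd(d) == 0) {
    # degenerate: identical diffs
    p <- if (m == 0) 1 else 0
    tval <- if (m == 0) 0 else sign(m) * Inf
    ci <- c(m, m)
  } else {
    tt <- stats::t.test(d, mu = 0)
    p <- tt$p.value
    tval <- unname(tt$statistic)
    ci <- as.numeric(tt$conf.int)
  }
  data.frame(chromosome = chromosome, n = n, mean = m,
             cl_low = ci[1], cl_high = ci[2], t = tval, p = p,
             sweep = if (m < 0 && p < 0.05) "Y" else "N",
             stringsAsFactors = FALSE)
}

#' Sweep test for every chromosome
#'
#' @param sw sweep records from [sweep_records].
#' @param chromosomes chromosomes to report (default: those present).
#' @return data.frame, one [het_difference_test] row per chromosome.
#' @export
sweep_tests <- function(sw, chromosomes = NULL) {
  chromosomes <- chromosomes %||% unique(sw$chrom)
  if (length(chromosomes) == 0) {
    return(het_difference_test(numeric(0), NA_character_)[0, ])
  }
  out <- lapply(chromosomes, function(cc)
    het_difference_test(sw$diff[sw$chrom == cc], cc))
  do.call(rbind, out)
}

#' Region profile around a focal span
#'
#' Orders the significant SNPs inside `[start - flank, end + flank]` on the
#' focal chromosome, carrying per-group heterozygosity and association
#' score, with gene boundaries attached for plotting.
#'
#' @param sw sweep records from [sweep_records].
#' @param chrom,start,end focal span (1-based inclusive).
#' @param flank bases added on both sides (default 1.4 Mb).
#' @param models optional gene models; when supplied, each SNP is labelled
#'   with its containing gene and the gene spans inside the window are
#'   returned as attribute `"genes"`.
#' @return data.frame sorted by position.
#' @export
region_profile <- function(sw, chrom, start, end, flank = 1.4e6,
                           models = NULL) {
  if (flank < 0) stopf("flank must be >= 0")
  lo <- start - flank
  hi <- end + flank
  out <- sw[sw$chrom == chrom & sw$pos >= lo & sw$pos <= hi, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(models)) {
    spans <- gene_spans(models)
    spans <- spans[spans$chrom == chrom & spans$end >= lo & spans$start <= hi,
                   , drop = FALSE]
    out$gene_id <- vapply(out$pos, function(pp) {
      hit <- spans$gene_id[spans$start <= pp & spans$end >= pp]
      if (length(hit)) hit[1] else "intergenic"
    }, character(1))
    attr(out, "genes") <- spans
  }
  out
}
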