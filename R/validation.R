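# Pool-vs-genotype allele-frequency validation: compare the resistance
# allele frequency estimated from pooled library reads with the frequency
# obtained by genotyping the pooled individuals.

#' Allele counts from an individual genotype table
#'
#' @param genotypes data.frame with columns `individual`, `library`,
#'   `genotype` (RR / RS / SS), e.g. from [read_genotype_table].
#' @param libraries optional library ids to restrict to (e.g. the two
#'   replicates of one phenotype group).
#' @return list with `count` (resistant alleles = 2 RR + RS), `total`
#'   (2 x individuals) and `frequency`.
#' @export
genotype_allele_counts <- function(genotypes, libraries = NULL) {
  if (!is.null(libraries)) {
    genotypes <- genotypes[genotypes$library %in% libraries, , drop = FALSE]
  }
  bad <- setdiff(unique(genotypes$genotype), c("RR", "RS", "SS"))
  if (length(bad)) stopf("unknown genotype code: %s", paste(bad, collapse = ", "))
  n <- nrow(genotypes)
  count <- 2L * sum(genotypes$genotype == "RR") + sum(genotypes$genotype == "RS")
  total <- 2L * n
  list(count = count, total = total,
       frequency = if (total > 0) count / total else NA_real_)
}

#' Concordance of two allele-frequency estimates
#'
#' Compares two (resistant allele, other allele) count vectors — replicate
#' vs replicate, or library reads vs individual genotyping — with the exact
#' Fisher test and the Pearson heterogeneity chi-square on the 2 x 2 table.
#' The comparison is symmetric in its two arguments.
#'
#' @param counts_a,counts_b numeric length-2 vectors `(resistant, other)`.
#' @param threshold the estimates are declared concordant when both p-values
#'   are at or above this level (default 0.05).
#' @return list with `fisher_p`, `chi2_p`, `concordant`.
#' @export
frequency_concordance <- function(counts_a, counts_b, threshold = 0.05) {
  a <- as.numeric(counts_a); b <- as.numeric(counts_b)
  if (length(a) != 2 || length(b) != 2) {
    stopf("allele count vectors must have length 2 (resistant, other)")
  }
  if (sum(a) == 0 || sum(b) == 0) stopf("zero total allele count in one source")
  fp <- fisher_exact_2x2(a[1], a[2], b[1], b[2], "two_sided")
  cp <- pearson_chisq_one(a, b)$p
  list(fisher_p = fp, chi2_p = cp,
       concordant = fp >= threshold && cp >= threshold)
}

#' Pairwise pool-vs-genotype validation report
#'
#' Mirrors the pairwise structure of a replicate/technique comparison:
#' within-technique replicate 1 vs 2, and between techniques per group.
#'
#' @param read_counts named list of length-2 `(resistant, other)` read-count
#'   vectors per library id.
#' @param genotypes genotype table (see [genotype_allele_counts]) whose
#'   `library` column matches the names of `read_counts`.
#' @param groups named character vector mapping library id to phenotype
#'   group.
#' @param threshold concordance threshold.
#' @return data.frame with one row per comparison: the two sources, their
#'   frequencies, both p-values and the concordance flag.
#' @export
validation_report <- function(read_counts, genotypes, groups,
                              threshold = 0.05) {
  geno_counts <- lapply(names(read_counts), function(lib) {
    g <- genotype_allele_counts(genotypes, lib)
    c(g$count, g$total - g$count)
  })
  names(geno_counts) <- names(read_counts)
  rows <- list()
  addcmp <- function(label_a, a, label_b, b) {
    fc <- frequency_concordance(a, b, threshold)
    rows[[length(rows) + 1]] <<- data.frame(
      source_a = label_a, source_b = label_b,
      freq_a = a[1] / sum(a), freq_b = b[1] / sum(b),
      fisher_p = fc$fisher_p, chi2_p = fc$chi2_p,
      concordant = fc$concordant, stringsAsFactors = FALSE)
  }
  for (grp in unique(groups)) {
    libs <- names(groups)[groups == grp]
    if (length(libs) == 2) {
      addcmp(paste0("reads:", libs[1]), read_counts[[libs[1]]],
             paste0("reads:", libs[2]), read_counts[[libs[2]]])
      addcmp(paste0("geno:", libs[1]), geno_counts[[libs[1]]],
             paste0("geno:", libs[2]), geno_counts[[libs[2]]])
    }
    for (lib in libs) {
      addcmp(paste0("reads:", lib), read_counts[[lib]],
             paste0("geno:", lib), geno_counts[[lib]])
    }
  }
  do.call(rbind, rows)
}
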