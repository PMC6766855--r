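# Pearson chi-square on 2 x n nucleotide-count tables, vectorised over sites.
#
# Conventions (shared by the replicate-concordance filter and the
# resistant-vs-susceptible association test):
#   * n = number of allele columns observed (count > 0) in either row;
#   * df = n - 1; a monomorphic table (n = 1) returns (chi2 0, df 0, p 1);
#   * no continuity correction, no pseudocounts; columns absent from both
#     rows are dropped before computing the statistic and df.

# top, bottom: numeric matrices (n_sites x n_alleles) of counts for the two
# rows of each site's table. Returns list(chi2, df, p) of length n_sites.
pearson_chisq_rows <- function(top, bottom) {
  top <- as.matrix(top)
  bottom <- as.matrix(bottom)
  stopifnot(identical(dim(top), dim(bottom)))
  tot <- top + bottom
  r <- rowSums(top)
  s <- rowSums(bottom)
  n <- r + s
  observed <- tot > 0
  # expected counts; (r / n) recycles down rows, matching matrix layout
  e_top <- (r / n) * tot
  e_bot <- (s / n) * tot
  term <- function(obs, exp) {
    out <- (obs - exp)^2 / exp
    out[!observed | exp == 0] <- 0
    out
  }
  chi2 <- rowSums(term(top, e_top)) + rowSums(term(bottom, e_bot))
  df <- rowSums(observed) - 1L
  degenerate <- df < 1L | !is.finite(chi2)
  chi2[degenerate] <- 0
  df[df < 0L] <- 0L
  p <- rep(1, length(chi2))
  ok <- !degenerate
  p[ok] <- stats::pchisq(chi2[ok], df[ok], lower.tail = FALSE)
  list(chi2 = chi2, df = as.integer(df), p = p)
}

# Single-table convenience used by the exported scalar operations.
pearson_chisq_one <- function(top, bottom) {
  res <- pearson_chisq_rows(matrix(top, nrow = 1), matrix(bottom, nrow = 1))
  list(chi2 = res$chi2[1], df = res$df[1], p = res$p[1])
}
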