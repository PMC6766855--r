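#' Pooled per-site nucleotide count container
#'
#' `pool_counts` is the atomic data structure of the pipeline: per-site,
#' per-library counts of the four nucleotides, together with the library
#' design (phenotype group and replicate of each pooled library).
#'
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (1-based integer position) and `ref` (reference base, one of A/C/G/T).
#' @param counts integer array of dimension `n_sites x 4 x n_libraries`;
#'   the second dimension is ordered A, C, G, T. `NA` marks a library
#'   without data at a site (such sites are excluded by the filters).
#' @param libraries data.frame describing the pooled libraries, with columns
#'   `id`, `group` (`"resistant"` or `"susceptible"`) and `replicate`
#'   (integer >= 1). `(group, replicate)` pairs must be unique and each
#'   group must have at least one replicate.
#'
#' @return An object of class `pool_counts`.
#' @export
pool_counts <- function(sites, counts, libraries) {
  sites <- as.data.frame(sites)
  libraries <- as.data.frame(libraries)
  required <- c("chrom", "pos", "ref")
  if (!all(required %in% names(sites))) {
    stopf("sites must have columns %s", paste(required, collapse = ", "))
  }
  if (any(sites$pos < 1)) stopf("positions must be >= 1 (1-based)")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  if (!all(sites$ref %in% BASES)) stopf("reference bases must be A, C, G or T")
  if (anyDuplicated(sites[c("chrom", "pos")])) {
    stopf("duplicate (chromosome, position) in sites")
  }
  if (!all(c("id", "group", "replicate") %in% names(libraries))) {
    stopf("libraries must have columns id, group, replicate")
  }
  if (anyDuplicated(libraries$id)) stopf("library ids must be unique")
  if (anyDuplicated(libraries[c("group", "replicate")])) {
    stopf("(group, replicate) pairs must be unique")
  }
  if (!all(libraries$group %in% c("resistant", "susceptible"))) {
    stopf("library group must be 'resistant' or 'susceptible'")
  }
  counts <- array(as.integer(counts),
                  dim = c(nrow(sites), 4L, nrow(libraries)),
                  dimnames = list(NULL, BASES, libraries$id))
  if (any(counts < 0, na.rm = TRUE)) stopf("counts must be non-negative")
  structure(list(sites = sites, counts = counts, libraries = libraries),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts: %d sites x %d libraries (%s)\n",
              nrow(x$sites), nrow(x$libraries),
              paste(x$libraries$id, collapse = ", ")))
  invisible(x)
}

#' @export
`[.pool_counts` <- function(x, i, ...) {
  structure(list(sites = x$sites[i, , drop = FALSE],
                 counts = x$counts[i, , , drop = FALSE],
                 libraries = x$libraries),
            class = "pool_counts")
}

#' @export
length.pool_counts <- function(x) nrow(x$sites)

#' Per-site, per-library sequencing depth
#'
#' @param x a [pool_counts] object.
#' @return integer matrix `n_sites x n_libraries` of total nucleotide counts.
#' @export
site_depths <- function(x) {
  stopifnot(inherits(x, "pool_counts"))
  apply(x$counts, c(1, 3), sum)
}

#' Pool nucleotide counts over the libraries of one phenotype group
#'
#' Replicate libraries are summed (not averaged), matching the construction
#' of the grouped contingency tables.
#'
#' @param x a [pool_counts] object.
#' @param group `"resistant"` or `"susceptible"`.
#' @return integer matrix `n_sites x 4` (columns A, C, G, T).
#' @export
pooled_counts <- function(x, group = c("resistant", "susceptible")) {
  group <- match.arg(group)
  libs <- which(x$libraries$group == group)
  if (length(libs) == 0) stopf("no libraries in group '%s'", group)
  out <- matrix(0L, nrow(x$sites), 4, dimnames = list(NULL, BASES))
  for (j in libs) out <- out + matrix(x$counts[, , j], ncol = 4)
  out
}

# library indices per group, in replicate order
group_libs <- function(x, group) {
  idx <- which(x$libraries$group == group)
  idx[order(x$libraries$replicate[idx])]
}
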