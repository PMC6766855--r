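# Reading and writing per-site nucleotide count tables.
#
# Two dialects are supported:
#  * "tsv"  — the package's native table: chrom, pos, ref, then one column per
#             library holding "A:C:G:T" counts (an optional fifth colon field
#             carries the library depth and is validated against the counts;
#             "." marks a library without data at that site);
#  * "sync" — the popoolation2 pooled-count standard: chrom, pos, ref, then
#             one "A:T:C:G:N:del" column per library (N and deletion counts
#             are ignored; depth is the sum of the four nucleotides).
# Both readers accept gzip-compressed files.

SYNC_ORDER <- c("A", "T", "C", "G")   # sync fields 1..4 (then N, del)

#' Read a per-site nucleotide count table
#'
#' @param path path to a tab-separated file (optionally gzipped).
#' @param libraries data.frame with columns `id`, `group`, `replicate`
#'   describing the pooled libraries, in the column order of the file
#'   (for sync, which carries no header) or matched by header id (tsv).
#' @param format `"tsv"` (native dialect) or `"sync"` (popoolation2).
#' @return a [pool_counts] object; row order of the file is preserved.
#' @export
read_site_counts <- function(path, libraries, format = c("tsv", "sync")) {
  format <- match.arg(format)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (format == "tsv") {
    if (length(lines) < 1) stopf("empty file: %s", path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(header) < 4 || !identical(header[1:3], c("chrom", "pos", "ref"))) {
      stopf("tsv header must start with 'chrom pos ref': %s", path)
    }
    ids <- header[-(1:3)]
    if (!setequal(ids, libraries$id)) {
      stopf("tsv header libraries (%s) do not match supplied libraries (%s)",
            paste(ids, collapse = ","), paste(libraries$id, collapse = ","))
    }
    body <- lines[-1]
    offset <- 1L
  } else {
    body <- lines
    ids <- libraries$id
    offset <- 0L
  }
  n <- length(body)
  sites <- data.frame(chrom = character(n), pos = integer(n),
                      ref = character(n))
  counts <- array(NA_integer_, dim = c(n, 4, length(ids)),
                  dimnames = list(NULL, BASES, ids))
  if (n > 0) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    want <- 3L + length(ids)
    bad <- which(nf != want)
    if (length(bad)) {
      stopf("line %d: expected %d tab-separated fields, found %d",
            bad[1] + offset, want, nf[bad[1]])
    }
    m <- matrix(unlist(fields), nrow = n, byrow = TRUE)
    sites$chrom <- m[, 1]
    pos <- suppressWarnings(as.integer(m[, 2]))
    if (anyNA(pos)) {
      stopf("line %d: malformed position '%s'",
            which(is.na(pos))[1] + offset, m[which(is.na(pos))[1], 2])
    }
    sites$pos <- pos
    sites$ref <- toupper(m[, 3])
    badref <- which(!sites$ref %in% BASES)
    if (length(badref)) {
      stopf("line %d: unknown reference base '%s'",
            badref[1] + offset, sites$ref[badref[1]])
    }
    for (j in seq_along(ids)) {
      col <- m[, 3 + j]
      if (format == "tsv") {
        counts[, , j] <- parse_tsv_counts(col, j, ids[j], offset)
      } else {
        counts[, , j] <- parse_sync_counts(col, offset)
      }
    }
  }
  x <- pool_counts(sites, counts, libraries)
  # pool_counts() errors on duplicate (chrom, pos); reorder columns already done
  x
}

parse_tsv_counts <- function(col, j, id, offset) {
  out <- matrix(NA_integer_, length(col), 4)
  missing <- col == "."
  todo <- which(!missing)
  if (length(todo)) {
    parts <- strsplit(col[todo], ":", fixed = TRUE)
    np <- lengths(parts)
    bad <- which(!np %in% c(4L, 5L))
    if (length(bad)) {
      stopf("line %d, library %s: expected 'A:C:G:T' counts, got '%s'",
            todo[bad[1]] + offset, id, col[todo[bad[1]]])
    }
    vals <- suppressWarnings(lapply(parts, function(p) as.integer(p)))
    badv <- which(vapply(vals, anyNA, logical(1)))
    if (length(badv)) {
      stopf("line %d, library %s: non-integer count in '%s'",
            todo[badv[1]] + offset, id, col[todo[badv[1]]])
    }
    four <- t(vapply(vals, function(v) v[1:4], integer(4)))
    withdepth <- which(np == 5L)
    if (length(withdepth)) {
      declared <- vapply(vals[withdepth], function(v) v[5], integer(1))
      mism <- which(declared != rowSums(four[withdepth, , drop = FALSE]))
      if (length(mism)) {
        k <- withdepth[mism[1]]
        stopf("line %d, library %s: declared depth %d inconsistent with counts '%s'",
              todo[k] + offset, id, declared[mism[1]], col[todo[k]])
      }
    }
    out[todo, ] <- four
  }
  out
}

parse_sync_counts <- function(col, offset) {
  parts <- strsplit(col, ":", fixed = TRUE)
  np <- lengths(parts)
  bad <- which(np != 6L)
  if (length(bad)) {
    stopf("line %d: sync field must have 6 colon-separated counts, got '%s'",
          bad[1] + offset, col[bad[1]])
  }
  vals <- suppressWarnings(matrix(as.integer(unlist(parts)), ncol = 6,
                                  byrow = TRUE))
  if (anyNA(vals)) {
    stopf("line %d: non-integer count in sync field",
          which(apply(vals, 1, anyNA))[1] + offset)
  }
  # sync order A:T:C:G -> internal A,C,G,T
  vals[, match(BASES, SYNC_ORDER), drop = FALSE]
}

#' Write a per-site nucleotide count table
#'
#' @param x a [pool_counts] object.
#' @param path output path.
#' @param format `"tsv"` or `"sync"` (see [read_site_counts]).
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(x, path, format = c("tsv", "sync")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "pool_counts"))
  n <- nrow(x$sites)
  cols <- character(0)
  for (j in seq_len(nrow(x$libraries))) {
    m <- matrix(x$counts[, , j], ncol = 4)
    if (format == "tsv") {
      fld <- paste(m[, 1], m[, 2], m[, 3], m[, 4], sep = ":")
    } else {
      s <- m[, match(SYNC_ORDER, BASES), drop = FALSE]
      fld <- paste(s[, 1], s[, 2], s[, 3], s[, 4], 0L, 0L, sep = ":")
    }
    fld[apply(is.na(m), 1, any)] <- if (format == "tsv") "." else "0:0:0:0:0:0"
    cols <- cbind(cols, fld)
  }
  body <- cbind(x$sites$chrom, x$sites$pos, x$sites$ref, cols)
  lines <- apply(body, 1, paste, collapse = "\t")
  if (format == "tsv") {
    header <- paste(c("chrom", "pos", "ref", x$libraries$id), collapse = "\t")
    lines <- c(header, lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write annotated association results
#'
#' The tsv layout mirrors a per-SNP supplementary table: position, feature
#' class, substitution type, per-group alternate-allele frequencies,
#' chi-square statistic and `-log10(p)`, and the FDR flag. The BED variant
#' uses 0-based half-open intervals (score column = `neg_log10_p`).
#'
#' @param records data.frame of association records, optionally joined to
#'   annotations (missing annotation columns are written as NA).
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  cols <- c("chrom", "pos", "ref", "alt", "feature_class",
            "substitution_type", "residue_number", "codon_position",
            "freq_resistant", "freq_susceptible", "chi2", "df",
            "neg_log10_p", "fdr_pass")
  for (col in setdiff(cols, names(records))) {
    records[[col]] <- rep(NA, nrow(records))
  }
  if (format == "tsv") {
    utils::write.table(records[cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (nrow(records) == 0) {
      writeLines(character(0), path)
    } else {
      bed <- data.frame(chrom = records$chrom,
                        start = records$pos - 1L,   # 1-based -> 0-based half-open
                        end = records$pos,
                        name = paste0(records$ref, ">", records$alt),
                        score = records$neg_log10_p)
      utils::write.table(bed, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a results tsv written by [write_results]
#'
#' @param path path to the tsv.
#' @return data.frame with the result columns.
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read an individual genotype table
#'
#' Expected columns: `individual`, `library`, `genotype` (RR / RS / SS),
#' optionally `locus`.
#'
#' @param path path to a tab-separated genotype table.
#' @return data.frame of genotypes.
#' @export
read_genotype_table <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("individual", "library", "genotype")
  if (!all(need %in% names(g))) {
    stopf("genotype table must have columns %s", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(g$genotype), c("RR", "RS", "SS"))
  if (length(bad)) stopf("unknown genotype code: %s", paste(bad, collapse = ", "))
  g
}
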