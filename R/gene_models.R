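# Gene models: stranded feature intervals (UTR / CDS / intron / ncRNA) plus
# functional category tags. Represented as a plain data.frame with one row
# per interval:
#   gene_id, chrom, strand, feature, start, end, category, cds_ok
# Coordinates are 1-based inclusive (the GFF3 convention, kept internally).

CATEGORY_TAGS <- c("CYP", "CCE", "GST", "Redox", "neuro", "cuticle", "other")
DETOX_TAGS <- c("CYP", "CCE", "GST", "Redox")

FEATURE_CLASSES <- c("five_prime_utr", "three_prime_utr", "cds", "intron",
                     "ncrna", "intergenic")

#' Read gene models from GFF3 plus a gene-category table
#'
#' Builds one set of typed intervals per gene from its canonical transcript
#' (the transcript with the longest total CDS; for non-coding genes, the
#' longest total exon length). Introns are derived as the gaps between
#' consecutive exons; UTRs are taken from explicit `five_prime_UTR` /
#' `three_prime_UTR` features when present, otherwise derived as the exonic
#' sequence outside the CDS span, oriented by strand.
#'
#' @param gff3_path path to a GFF3 file (optionally gzipped).
#' @param category_path optional path to a two-column tab-separated table
#'   (`gene_id`, `category`) tagging genes with one of
#'   `r paste(CATEGORY_TAGS, collapse = ", ")`. Untagged genes get `"other"`.
#' @return data.frame of gene-model intervals (see file header for schema).
#'   Genes whose total CDS length is not divisible by 3 are kept but flagged
#'   `cds_ok = FALSE` and excluded from codon-effect annotation.
#' @export
read_gene_models <- function(gff3_path, category_path = NULL) {
  gff <- as.data.frame(rtracklayer::readGFF(gff3_path))
  gff$type <- as.character(gff$type)
  gff$ID <- as.character(gff$ID)
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stopf("no gene features in %s", gff3_path)
  tx_types <- c("mRNA", "transcript", "ncRNA", "ncRNA_gene", "lnc_RNA", "tRNA", "rRNA")
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- gff[gff$type %in% tx_types & !is.na(gff$Parent) &
                gff$Parent == g$ID, , drop = FALSE]
    if (nrow(tx) == 0) {
      # gene with direct exon/CDS children: treat the gene itself as transcript
      tx_ids <- g$ID
    } else {
      tx_ids <- tx$ID
    }
    parts <- gff[!is.na(gff$Parent) & gff$Parent %in% tx_ids, , drop = FALSE]
    # pick canonical transcript: longest total CDS, else longest exon total
    pick <- tx_ids[1]
    if (length(tx_ids) > 1) {
      score <- vapply(tx_ids, function(id) {
        p <- parts[parts$Parent == id, , drop = FALSE]
        cds_len <- sum(p$end[p$type == "CDS"] - p$start[p$type == "CDS"] + 1)
        if (cds_len > 0) cds_len + 1e9 else
          sum(p$end[p$type == "exon"] - p$start[p$type == "exon"] + 1)
      }, numeric(1))
      pick <- tx_ids[which.max(score)]
    }
    p <- parts[parts$Parent == pick, , drop = FALSE]
    noncoding <- nrow(tx) > 0 && any(tx$ID == pick & tx$type %in%
                                       c("ncRNA", "lnc_RNA", "tRNA", "rRNA"))
    out[[i]] <- build_gene_intervals(g, p, noncoding)
  }
  models <- do.call(rbind, out)
  models$category <- "other"
  if (!is.null(category_path)) {
    cat_tab <- utils::read.table(category_path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
    if (!all(c("gene_id", "category") %in% names(cat_tab))) {
      stopf("category table must have columns gene_id, category")
    }
    bad <- setdiff(unique(cat_tab$category), CATEGORY_TAGS)
    if (length(bad)) {
      stopf("unknown category tag '%s'; allowed: %s", bad[1],
            paste(CATEGORY_TAGS, collapse = ", "))
    }
    idx <- match(models$gene_id, cat_tab$gene_id)
    models$category[!is.na(idx)] <- cat_tab$category[idx[!is.na(idx)]]
  }
  rownames(models) <- NULL
  models
}

# g: one gene row; p: canonical transcript child features (exon/CDS/UTR rows)
build_gene_intervals <- function(g, p, noncoding = FALSE) {
  id <- g$ID %||% g$Name
  strand <- as.character(g$strand)
  exons <- p[p$type == "exon", , drop = FALSE]
  cds <- p[p$type == "CDS", , drop = FALSE]
  if (nrow(cds) && (min(cds$start) < g$start || max(cds$end) > g$end)) {
    stopf("gene %s: CDS extends outside the gene span", id)
  }
  if (nrow(exons) == 0) exons <- if (nrow(cds)) cds else g
  exons <- exons[order(exons$start), , drop = FALSE]
  iv <- list()
  add <- function(feature, start, end) {
    if (length(start) && any(end >= start)) {
      keep <- end >= start
      iv[[length(iv) + 1]] <<- data.frame(feature = feature,
                                          start = start[keep], end = end[keep])
    }
  }
  # introns: gaps between consecutive exons
  if (nrow(exons) > 1) {
    add("intron", exons$end[-nrow(exons)] + 1L, exons$start[-1] - 1L)
  }
  if (nrow(cds) == 0 || noncoding) {
    add("ncrna", exons$start, exons$end)
    cds_ok <- FALSE
  } else {
    cds <- cds[order(cds$start), , drop = FALSE]
    add("cds", cds$start, cds$end)
    cds_ok <- sum(cds$end - cds$start + 1) %% 3 == 0
    utr5 <- p[p$type %in% c("five_prime_UTR", "five_prime_utr"), , drop = FALSE]
    utr3 <- p[p$type %in% c("three_prime_UTR", "three_prime_utr"), , drop = FALSE]
    if (nrow(utr5) || nrow(utr3)) {
      add("five_prime_utr", utr5$start, utr5$end)
      add("three_prime_utr", utr3$start, utr3$end)
    } else {
      # derive UTRs: exonic sequence outside the CDS span
      lo <- min(cds$start); hi <- max(cds$end)
      left_s <- pmin(exons$start, lo - 1L); left_e <- pmin(exons$end, lo - 1L)
      keep <- exons$start < lo
      right_s <- pmax(exons$start, hi + 1L); right_e <- pmax(exons$end, hi + 1L)
      keepr <- exons$end > hi
      left_lab <- if (strand == "-") "three_prime_utr" else "five_prime_utr"
      right_lab <- if (strand == "-") "five_prime_utr" else "three_prime_utr"
      add(left_lab, left_s[keep], left_e[keep])
      add(right_lab, right_s[keepr], right_e[keepr])
    }
  }
  iv <- do.call(rbind, iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  data.frame(gene_id = id, chrom = as.character(g$seqid), strand = strand,
             feature = iv$feature, start = as.integer(iv$start),
             end = as.integer(iv$end), cds_ok = cds_ok,
             stringsAsFactors = FALSE)
}

# per-gene span table
gene_spans <- function(models) {
  first <- !duplicated(models$gene_id)
  ids <- models$gene_id[first]
  data.frame(gene_id = ids,
             chrom = models$chrom[first],
             strand = models$strand[first],
             start = as.integer(tapply(models$start, models$gene_id, min)[ids]),
             end = as.integer(tapply(models$end, models$gene_id, max)[ids]),
             stringsAsFactors = FALSE)
}

# category tag of each gene (first interval's tag)
gene_categories <- function(models) {
  first <- !duplicated(models$gene_id)
  stats::setNames(models$category[first], models$gene_id[first])
}
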