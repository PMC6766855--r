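# SNP functional annotation: genomic feature class, codon-level substitution
# effect, and per-gene / per-category aggregation.

#' Assign a genomic position to a feature class and gene
#'
#' @param chrom chromosome identifier.
#' @param pos 1-based position.
#' @param models gene-model intervals from [read_gene_models] (or
#'   [sim_gene_models]).
#' @return data.frame with one row per containing gene (several rows for
#'   overlapping loci, with a warning), columns `gene_id`, `feature_class`,
#'   `category`. Positions outside every gene return a single
#'   `gene_id = "intergenic"` row.
#' @export
classify_site <- function(chrom, pos, models) {
  spans <- gene_spans(models)
  hit_genes <- spans$gene_id[spans$chrom == chrom &
                               spans$start <= pos & spans$end >= pos]
  if (length(hit_genes) == 0) {
    return(data.frame(gene_id = "intergenic", feature_class = "intergenic",
                      category = "other", stringsAsFactors = FALSE))
  }
  if (length(hit_genes) > 1) {
    warnf("position %s:%d lies in %d overlapping genes (%s); one annotation per gene",
          chrom, pos, length(hit_genes), paste(hit_genes, collapse = ", "))
  }
  cats <- gene_categories(models)
  out <- lapply(hit_genes, function(g) {
    iv <- models[models$gene_id == g & models$start <= pos & models$end >= pos,
                 , drop = FALSE]
    # gene span positions not covered by any typed interval fall back to intron
    feat <- if (nrow(iv)) iv$feature[1] else "intron"
    data.frame(gene_id = g, feature_class = feat,
               category = unname(cats[g]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Codon-level effect of a single-base substitution
#'
#' @param cds_seq coding sequence in coding orientation (character string or
#'   `Biostrings::DNAString`); length must be a multiple of 3 for complete
#'   terminal codons.
#' @param cds_offset 0-based offset of the substituted base within `cds_seq`.
#' @param ref_base,alt_base reference and alternate base on the genomic plus
#'   strand.
#' @param strand `"+"` or `"-"`; for minus-strand genes the bases are
#'   complemented before comparison with the coding sequence.
#' @return list with `substitution_type` (`"synonymous"`, `"nonsynonymous"`
#'   or `"not_applicable"`), `residue_number`, `codon_position` (1..3),
#'   `ref_aa`, `alt_aa` and `label` (e.g. `"V410L"`).
#' @export
substitution_effect <- function(cds_seq, cds_offset, ref_base, alt_base,
                                strand = "+") {
  seq <- toupper(as.character(cds_seq))
  n <- nchar(seq)
  if (cds_offset < 0 || cds_offset >= n) {
    stopf("cds_offset %d outside coding sequence of length %d", cds_offset, n)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- toupper(ref_base); alt <- toupper(alt_base)
  if (identical(strand, "-")) {
    ref <- unname(comp[ref]); alt <- unname(comp[alt])
  }
  have <- substr(seq, cds_offset + 1, cds_offset + 1)
  if (!identical(have, ref)) {
    stopf("reference base mismatch at CDS offset %d: sequence has %s, expected %s",
          cds_offset, have, ref)
  }
  codon_index <- cds_offset %/% 3          # 0-based codon
  codon_position <- cds_offset %% 3 + 1
  residue_number <- codon_index + 1
  codon_start <- codon_index * 3 + 1
  if (codon_start + 2 > n) {
    warnf("partial terminal codon at CDS offset %d; effect not applicable",
          cds_offset)
    return(list(substitution_type = "not_applicable",
                residue_number = residue_number,
                codon_position = codon_position,
                ref_aa = NA_character_, alt_aa = NA_character_,
                label = NA_character_))
  }
  codon <- substr(seq, codon_start, codon_start + 2)
  mutated <- codon
  substr(mutated, codon_position, codon_position) <- alt
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[codon])
  alt_aa <- unname(code[mutated])
  if (is.na(ref_aa) || is.na(alt_aa)) {
    return(list(substitution_type = "not_applicable",
                residue_number = residue_number,
                codon_position = codon_position,
                ref_aa = ref_aa, alt_aa = alt_aa, label = NA_character_))
  }
  list(substitution_type = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
       residue_number = residue_number,
       codon_position = codon_position,
       ref_aa = ref_aa, alt_aa = alt_aa,
       label = paste0(ref_aa, residue_number, alt_aa))
}

# 0-based offset of a genomic position within a gene's spliced CDS,
# in coding orientation. cds: data.frame(start, end) sorted by start.
cds_offset_of <- function(cds, pos, strand) {
  cds <- cds[order(cds$start), , drop = FALSE]
  lens <- cds$end - cds$start + 1L
  total <- sum(lens)
  hit <- which(cds$start <= pos & cds$end >= pos)
  if (length(hit) == 0) return(NA_integer_)
  before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0L
  plus_off <- before + (pos - cds$start[hit])
  if (identical(strand, "-")) total - 1L - plus_off else plus_off
}

# spliced CDS sequence in coding orientation
extract_cds_seq <- function(genome, chrom, cds, strand) {
  cds <- cds[order(cds$start), , drop = FALSE]
  chromseq <- genome[[chrom]]
  pieces <- vapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(chromseq, cds$start[i], cds$end[i])),
    character(1))
  s <- paste(pieces, collapse = "")
  if (identical(strand, "-")) {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Annotate association records with feature class and coding effect
#'
#' Joins each SNP to its containing gene(s), classifies the feature, and for
#' CDS SNPs in genes with a complete CDS computes the codon-level effect of
#' the most frequent alternate allele.
#'
#' @param records association records (data.frame from [associate_sites];
#'   needs columns `chrom`, `pos`, `ref`, `alt`).
#' @param models gene-model intervals.
#' @param genome optional `Biostrings::DNAStringSet` (or FASTA path) giving
#'   the reference sequence; required for substitution effects.
#' @return data.frame with one row per (SNP, containing gene).
#' @export
annotate_snps <- function(records, models, genome = NULL) {
  records <- as.data.frame(records)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), feature_class = character(0),
                      category = character(0), substitution_type = character(0),
                      residue_number = integer(0), codon_position = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  cds_by_gene <- split(models[models$feature == "cds", c("start", "end")],
                       models$gene_id[models$feature == "cds"])
  spans <- gene_spans(models)
  cds_ok <- stats::setNames(models$cds_ok[!duplicated(models$gene_id)],
                            models$gene_id[!duplicated(models$gene_id)])
  seq_cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    cls <- classify_site(records$chrom[i], records$pos[i], models)
    rows <- lapply(seq_len(nrow(cls)), function(k) {
      ann <- data.frame(chrom = records$chrom[i], pos = records$pos[i],
                        ref = records$ref[i], alt = records$alt[i],
                        gene_id = cls$gene_id[k],
                        feature_class = cls$feature_class[k],
                        category = cls$category[k],
                        substitution_type = "not_applicable",
                        residue_number = NA_integer_,
                        codon_position = NA_integer_,
                        label = NA_character_, stringsAsFactors = FALSE)
      g <- cls$gene_id[k]
      if (cls$feature_class[k] == "cds" && !is.null(genome) &&
          isTRUE(unname(cds_ok[g]))) {
        strand <- spans$strand[spans$gene_id == g]
        cds <- cds_by_gene[[g]]
        off <- cds_offset_of(cds, records$pos[i], strand)
        if (!is.na(off)) {
          if (!exists(g, envir = seq_cache)) {
            assign(g, extract_cds_seq(genome, records$chrom[i], cds, strand),
                   envir = seq_cache)
          }
          eff <- substitution_effect(get(g, envir = seq_cache), off,
                                     records$ref[i], records$alt[i], strand)
          ann$substitution_type <- eff$substitution_type
          ann$residue_number <- eff$residue_number
          ann$codon_position <- eff$codon_position
          ann$label <- eff$label %||% NA_character_
        }
      }
      ann
    })
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Aggregate annotations per gene and per category
#'
#' @param annotations output of [annotate_snps].
#' @param records association records carrying `neg_log10_p` (matched on
#'   `chrom` + `pos`).
#' @return list with data.frames `per_gene` (SNP count, max `-log10(p)`,
#'   nonsynonymous count) and `per_category` (SNP count and percentage
#'   share over annotated SNPs).
#' @export
aggregate_annotations <- function(annotations, records) {
  if (nrow(annotations) == 0) {
    return(list(per_gene = data.frame(gene_id = character(0),
                                      n_snps = integer(0),
                                      max_neg_log10_p = numeric(0),
                                      n_nonsynonymous = integer(0)),
                per_category = data.frame(category = character(0),
                                          n_snps = integer(0),
                                          pct_share = numeric(0))))
  }
  key <- paste(annotations$chrom, annotations$pos)
  rkey <- paste(records$chrom, records$pos)
  score <- records$neg_log10_p[match(key, rkey)]
  per_gene <- do.call(rbind, lapply(split(seq_len(nrow(annotations)),
                                          annotations$gene_id), function(idx) {
    data.frame(gene_id = annotations$gene_id[idx[1]],
               n_snps = length(idx),
               max_neg_log10_p = suppressWarnings(max(score[idx], na.rm = TRUE)),
               n_nonsynonymous = sum(annotations$substitution_type[idx] ==
                                       "nonsynonymous"),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  tab <- table(annotations$category)
  per_category <- data.frame(category = names(tab),
                             n_snps = as.integer(tab),
                             pct_share = 100 * as.integer(tab) / sum(tab),
                             stringsAsFactors = FALSE)
  list(per_gene = per_gene, per_category = per_category)
}
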