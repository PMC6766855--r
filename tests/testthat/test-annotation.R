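# Feature classification and codon-level substitution effects.

toy_models <- function() {
  data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
             feature = c("five_prime_utr", "cds", "three_prime_utr"),
             start = c(1001L, 1101L, 1901L), end = c(1100L, 1900L, 2000L),
             cds_ok = TRUE, category = "other", stringsAsFactors = FALSE)
}

test_that("positions resolve to UTR, CDS or intergenic", {
  m <- toy_models()
  expect_equal(classify_site("chr1", 1050, m)$feature_class, "five_prime_utr")
  expect_equal(classify_site("chr1", 1500, m)$feature_class, "cds")
  cls <- classify_site("chr1", 500, m)
  expect_equal(cls$feature_class, "intergenic")
  expect_equal(cls$gene_id, "intergenic")
})

test_that("overlapping genes yield one annotation per gene with a warning", {
  m <- rbind(toy_models(),
             data.frame(gene_id = "g2", chrom = "chr1", strand = "-",
                        feature = "cds", start = 1800L, end = 2200L,
                        cds_ok = TRUE, category = "other"))
  expect_warning(cls <- classify_site("chr1", 1850, m), "overlapping")
  expect_equal(sort(cls$gene_id), c("g1", "g2"))
})

test_that("codon effects follow the standard genetic code", {
  # GTA codon, first position G->T: Val -> Leu (the kdr-class change)
  eff <- substitution_effect("GTAAAA", 0, "G", "T")
  expect_equal(eff$substitution_type, "nonsynonymous")
  expect_equal(eff$ref_aa, "V")
  expect_equal(eff$alt_aa, "L")
  expect_equal(eff$label, "V1L")
  # AAA third position A->G: Lys -> Lys, synonymous
  eff <- substitution_effect("AAAGGG", 2, "A", "G")
  expect_equal(eff$substitution_type, "synonymous")
  expect_equal(eff$codon_position, 3)
  expect_equal(eff$residue_number, 1)
  # minus strand: genomic bases are complemented before comparison
  eff <- substitution_effect("GTAAAA", 0, "C", "A", strand = "-")
  expect_equal(eff$ref_aa, "V")
  expect_equal(eff$alt_aa, "L")
  # reference mismatch is an error naming the offset
  expect_error(substitution_effect("GTAAAA", 0, "A", "T"), "offset 0")
  # partial terminal codon
  expect_warning(eff <- substitution_effect("GTAAA", 3, "A", "G"), "partial")
  expect_equal(eff$substitution_type, "not_applicable")
})

test_that("all single-base mutations of a 30-codon CDS match a translate-and-compare oracle", {
  set.seed(61)
  cds <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
               collapse = "")
  for (off in 0:89) {
    ref <- substr(cds, off + 1, off + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      eff <- substitution_effect(cds, off, ref, alt)
      mutated <- cds
      substr(mutated, off + 1, off + 1) <- alt
      aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                                   no.init.codon = TRUE))
      aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(mutated),
                                                   no.init.codon = TRUE))
      expect_equal(eff$substitution_type,
                   if (aa_ref == aa_alt) "synonymous" else "nonsynonymous")
      res <- off %/% 3 + 1
      expect_equal(eff$residue_number, res)
      expect_equal(eff$ref_aa, substr(aa_ref, res, res))
      expect_equal(eff$alt_aa, substr(aa_alt, res, res))
    }
  }
})

test_that("minus-strand classification equals the reverse-complement plus-strand case", {
  # same physical gene annotated on either strand; effects must agree after
  # reverse-complementing the coding sequence
  genome <- toy_genome(4000)
  cds <- data.frame(start = 1001L, end = 1300L)
  plus_seq <- poolscan:::extract_cds_seq(genome, "chr1", cds, "+")
  minus_seq <- poolscan:::extract_cds_seq(genome, "chr1", cds, "-")
  expect_equal(minus_seq,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(plus_seq))))
  pos <- 1105L
  off_plus <- poolscan:::cds_offset_of(cds, pos, "+")
  off_minus <- poolscan:::cds_offset_of(cds, pos, "-")
  expect_equal(off_minus, 300L - 1L - off_plus)
})

test_that("aggregation summarises per gene and per category", {
  ann <- data.frame(chrom = "1", pos = c(10, 20, 30),
                    ref = "A", alt = "C", gene_id = "g1",
                    feature_class = "cds", category = "CYP",
                    substitution_type = c("synonymous", "nonsynonymous",
                                          "nonsynonymous"),
                    residue_number = 1:3, codon_position = 1L,
                    label = NA_character_)
  rec <- data.frame(chrom = "1", pos = c(10, 20, 30),
                    neg_log10_p = c(2, 5, 11))
  agg <- aggregate_annotations(ann, rec)
  expect_equal(agg$per_gene$n_snps, 3L)
  expect_equal(agg$per_gene$max_neg_log10_p, 11)
  expect_equal(agg$per_gene$n_nonsynonymous, 2L)

  # category shares: 62/20/16/4 SNPs over 102 -> 60.8/19.6/15.7/3.9%
  ann2 <- data.frame(chrom = "1", pos = seq_len(102), ref = "A", alt = "C",
                     gene_id = "g", feature_class = "cds",
                     category = rep(c("CYP", "CCE", "Redox", "GST"),
                                    c(62, 20, 16, 4)),
                     substitution_type = "synonymous", residue_number = 1L,
                     codon_position = 1L, label = NA_character_)
  rec2 <- data.frame(chrom = "1", pos = seq_len(102), neg_log10_p = 1)
  shares <- aggregate_annotations(ann2, rec2)$per_category
  got <- stats::setNames(round(shares$pct_share, 1), shares$category)
  expect_equal(got[c("CYP", "CCE", "Redox", "GST")],
               c(CYP = 60.8, CCE = 19.6, Redox = 15.7, GST = 3.9))

  empty <- aggregate_annotations(ann[0, ], rec[0, ])
  expect_equal(nrow(empty$per_gene), 0)
  expect_equal(nrow(empty$per_category), 0)
})

test_that("feature classes partition a simulated significant SNP set", {
  ex <- simulate_experiment(small_sim_config(seed = 9))
  flt <- filter_sites(ex$counts)
  rec <- apply_fdr(associate_sites(flt$records), 0.05)
  sig <- rec[rec$fdr_pass, ]
  genome <- sim_reference(ex$cohort)
  ann <- annotate_snps(sig, ex$models, genome)
  # single-gene layout: each SNP annotated exactly once
  expect_equal(nrow(ann), nrow(sig))
  expect_true(all(ann$feature_class %in%
                    c("five_prime_utr", "three_prime_utr", "cds", "intron",
                      "ncrna", "intergenic")))
  expect_equal(sum(table(ann$feature_class)), nrow(sig))
  # synonymous + nonsynonymous = classifiable CDS SNPs
  cds <- ann[ann$feature_class == "cds", ]
  classifiable <- cds$substitution_type != "not_applicable"
  expect_equal(sum(cds$substitution_type == "synonymous") +
                 sum(cds$substitution_type == "nonsynonymous"),
               sum(classifiable))
  expect_true(all(classifiable))  # simulated CDSs are complete
})
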