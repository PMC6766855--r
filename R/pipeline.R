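# End-to-end orchestration: filter -> associate -> annotate -> sweep ->
# enrich -> validate, with per-stage row-count logging and tsv outputs.

#' Pipeline configuration
#'
#' @param counts a [pool_counts] object, or a path to a count table.
#' @param libraries library data.frame (required when `counts` is a path).
#' @param counts_format `"tsv"` or `"sync"` (when `counts` is a path).
#' @param models gene-model intervals (data.frame) or a GFF3 path.
#' @param categories category-table path (when `models` is a GFF3 path).
#' @param genome `Biostrings::DNAStringSet` or FASTA path (optional; needed
#'   for substitution effects).
#' @param genotypes genotype table or path (optional; enables validation).
#' @param validation_read_counts named list of `(resistant, other)` read
#'   count vectors per library at the validation locus (optional).
#' @param filter a [filter_config].
#' @param fdr_alpha per-chromosome FDR level.
#' @param sweep_flank flank in bases for the focal region profile.
#' @param enrich_category category for the enrichment test.
#' @param outdir output directory (created); `NULL` = no files written.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, libraries = NULL, counts_format = "tsv",
                            models = NULL, categories = NULL, genome = NULL,
                            genotypes = NULL, validation_read_counts = NULL,
                            filter = filter_config(), fdr_alpha = 0.01,
                            sweep_flank = 1.4e6, enrich_category = "detox",
                            outdir = NULL) {
  if (!(fdr_alpha > 0 && fdr_alpha < 1)) stopf("fdr_alpha must be in (0, 1)")
  structure(list(counts = counts, libraries = libraries,
                 counts_format = counts_format, models = models,
                 categories = categories, genome = genome,
                 genotypes = genotypes,
                 validation_read_counts = validation_read_counts,
                 filter = filter, fdr_alpha = fdr_alpha,
                 sweep_flank = sweep_flank,
                 enrich_category = enrich_category, outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in the fixed order filter, associate, annotate (if gene
#' models supplied), sweep, enrich (if gene models supplied), validate (if
#' genotypes supplied). Any stage failure aborts with the stage name. With
#' an `outdir`, each stage's table is written as tsv alongside a run log of
#' input/output row counts.
#'
#' @param config a [pipeline_config].
#' @return list with `filter_report`, `records` (association records with
#'   FDR flags), `fdr`, `annotations`, `aggregates`, `sweep` (records),
#'   `sweep_tests`, `region` (focal profile around the top SNP's gene),
#'   `enrichment`, `validation`, `log`.
#' @export
run_pipeline <- function(config) {
  log <- list()
  t0 <- proc.time()[["elapsed"]]
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1]] <<- data.frame(
      stage = stage, input_rows = n_in, output_rows = n_out,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  x <- config$counts
  if (is.character(x)) {
    if (is.null(config$libraries)) stopf("libraries required to read counts from a path")
    x <- run_stage("read", read_site_counts(x, config$libraries,
                                            config$counts_format))
  }
  models <- config$models
  if (is.character(models)) {
    models <- run_stage("gene_models",
                        read_gene_models(models, config$categories))
  }
  # filter
  flt <- run_stage("filter", filter_sites(x, config$filter))
  note("filter", nrow(x$sites), nrow(flt$records$sites))
  # associate
  if (nrow(flt$records$sites) == 0) {
    records <- associate_empty()
    fdr <- NULL
    note("associate", 0, 0)
  } else {
    records <- run_stage("associate", {
      r <- associate_sites(flt$records)
      apply_fdr(r, config$fdr_alpha)
    })
    fdr <- attr(records, "fdr")
    note("associate", nrow(flt$records$sites), sum(records$fdr_pass))
  }
  sig <- records[records$fdr_pass %||% logical(0), , drop = FALSE]
  # annotate
  annotations <- NULL; aggregates <- NULL
  if (!is.null(models)) {
    annotations <- run_stage("annotate",
                             annotate_snps(sig, models, config$genome))
    aggregates <- aggregate_annotations(annotations, sig)
    note("annotate", nrow(sig), nrow(annotations))
  }
  # sweep
  sw <- run_stage("sweep", sweep_records(flt$records, records))
  swt <- sweep_tests(sw, chromosomes = unique(x$sites$chrom))
  note("sweep", nrow(sw), nrow(swt))
  region <- NULL
  if (!is.null(models) && nrow(sw) > 0) {
    top <- sig[which.max(sig$neg_log10_p), , drop = FALSE]
    if (nrow(top) == 1) {
      cls <- classify_site(top$chrom, top$pos, models)
      spans <- gene_spans(models)
      focal <- spans[spans$gene_id == cls$gene_id[1], , drop = FALSE]
      if (nrow(focal) == 1 && cls$gene_id[1] != "intergenic") {
        region <- region_profile(sw, focal$chrom, focal$start, focal$end,
                                 config$sweep_flank, models)
      }
    }
  }
  # enrich
  enrichment <- NULL
  if (!is.null(models)) {
    enrichment <- run_stage("enrich", category_polymorphism_enrichment(
      flt$common$sites,
      polymorphic_call(pooled_counts(flt$common, "resistant") +
                         pooled_counts(flt$common, "susceptible"),
                       config$filter),
      models, config$enrich_category))
    note("enrich", nrow(flt$common$sites), nrow(enrichment))
  }
  # validate
  validation <- NULL
  if (!is.null(config$genotypes) && !is.null(config$validation_read_counts)) {
    genotypes <- config$genotypes
    if (is.character(genotypes)) genotypes <- read_genotype_table(genotypes)
    groups <- stats::setNames(x$libraries$group, x$libraries$id)
    validation <- run_stage("validate", validation_report(
      config$validation_read_counts, genotypes,
      groups[names(config$validation_read_counts)]))
    note("validate", nrow(genotypes), nrow(validation))
  }
  log <- do.call(rbind, log)
  out <- list(filter_report = flt$report, records = records, fdr = fdr,
              annotations = annotations, aggregates = aggregates,
              sweep = sw, sweep_tests = swt, region = region,
              enrichment = enrichment, validation = validation, log = log)
  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

associate_empty <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), depth_resistant = integer(0),
             depth_susceptible = integer(0), alt_resistant = integer(0),
             alt_susceptible = integer(0), chi2 = numeric(0),
             df = integer(0), p = numeric(0), neg_log10_p = numeric(0),
             capped = logical(0), freq_resistant = numeric(0),
             freq_susceptible = numeric(0), fdr_pass = logical(0),
             fdr_threshold = numeric(0), stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(out$filter_report, "filter_report.tsv")
  if (!is.null(out$records) && nrow(out$records)) {
    write_results(merge_annotation_cols(out$records, out$annotations),
                  file.path(outdir, "association.tsv"), "tsv")
    write_results(out$records[out$records$fdr_pass, , drop = FALSE],
                  file.path(outdir, "significant.bed"), "bed")
  }
  wt(out$fdr, "fdr_summary.tsv")
  wt(out$annotations, "annotations.tsv")
  wt(out$sweep, "sweep_records.tsv")
  wt(out$sweep_tests, "sweep_tests.tsv")
  wt(out$enrichment, "enrichment.tsv")
  wt(out$validation, "validation.tsv")
  wt(out$log, "run_log.tsv")
  invisible(outdir)
}

merge_annotation_cols <- function(records, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0) return(records)
  key <- paste(records$chrom, records$pos)
  akey <- paste(annotations$chrom, annotations$pos)
  idx <- match(key, akey)
  records$feature_class <- annotations$feature_class[idx]
  records$substitution_type <- annotations$substitution_type[idx]
  records$residue_number <- annotations$residue_number[idx]
  records$codon_position <- annotations$codon_position[idx]
  records
}
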