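# Shared fixtures: tiny count sets, toy gene models, and toy reference
# sequences, all built in code.

std_libraries <- function() {
  data.frame(id = c("R1", "R2", "S1", "S2"),
             group = c("resistant", "resistant", "susceptible", "susceptible"),
             replicate = c(1L, 2L, 1L, 2L), stringsAsFactors = FALSE)
}

# counts_by_lib: list of n x 4 matrices named by library id
make_counts <- function(chrom, pos, ref, counts_by_lib,
                        libraries = std_libraries()) {
  n <- length(pos)
  arr <- array(NA_integer_, dim = c(n, 4, nrow(libraries)),
               dimnames = list(NULL, c("A", "C", "G", "T"), libraries$id))
  for (id in names(counts_by_lib)) arr[, , id] <- counts_by_lib[[id]]
  pool_counts(data.frame(chrom = chrom, pos = pos, ref = ref), arr, libraries)
}

# one site with explicit per-library A/C/G/T rows
one_site_counts <- function(r1, r2, s1, s2, ref = "A", chrom = "1", pos = 100L) {
  make_counts(chrom, pos, ref,
              list(R1 = matrix(r1, 1), R2 = matrix(r2, 1),
                   S1 = matrix(s1, 1), S2 = matrix(s2, 1)))
}

# toy GFF3: geneA (+, 2 exons, CDS with flanking UTRs), geneB (- strand,
# single exon coding), geneC (ncRNA). Returns the file path.
write_toy_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1001\t2000\t.\t+\t.\tID=geneA",
    "chr1\ttoy\tmRNA\t1001\t2000\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "chr1\ttoy\texon\t1001\t1400\t.\t+\t.\tID=geneA.e1;Parent=geneA.t1",
    "chr1\ttoy\texon\t1501\t2000\t.\t+\t.\tID=geneA.e2;Parent=geneA.t1",
    "chr1\ttoy\tCDS\t1101\t1400\t.\t+\t0\tID=geneA.c1;Parent=geneA.t1",
    "chr1\ttoy\tCDS\t1501\t1900\t.\t+\t0\tID=geneA.c2;Parent=geneA.t1",
    "chr1\ttoy\tgene\t3001\t3600\t.\t-\t.\tID=geneB",
    "chr1\ttoy\tmRNA\t3001\t3600\t.\t-\t.\tID=geneB.t1;Parent=geneB",
    "chr1\ttoy\texon\t3001\t3600\t.\t-\t.\tID=geneB.e1;Parent=geneB.t1",
    "chr1\ttoy\tCDS\t3101\t3500\t.\t-\t0\tID=geneB.c1;Parent=geneB.t1",
    "chr1\ttoy\tgene\t5001\t5400\t.\t+\t.\tID=geneC",
    "chr1\ttoy\tncRNA\t5001\t5400\t.\t+\t.\tID=geneC.t1;Parent=geneC",
    "chr1\ttoy\texon\t5001\t5400\t.\t+\t.\tID=geneC.e1;Parent=geneC.t1")
  writeLines(lines, path)
  path
}

write_toy_categories <- function(path = tempfile(fileext = ".tsv"),
                                 tags = c(geneA = "CYP")) {
  writeLines(c("gene_id\tcategory",
               paste(names(tags), tags, sep = "\t")), path)
  path
}

# deterministic toy chromosome: repeats of ACGT
toy_genome <- function(len = 6000, chrom = "chr1") {
  s <- paste(rep(c("A", "C", "G", "T"), length.out = len), collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- chrom
  g
}

small_sim_config <- function(...) {
  sim_config(sites_per_chromosome = 400L, ...)
}
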