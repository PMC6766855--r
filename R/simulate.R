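# Forward simulation of the pooled exome study design: a causal biallelic
# resistance locus on one founder haplotype background, linked sweep-marker
# loci whose association with the causal allele decays with distance,
# unlinked neutral polymorphism, genotype-dependent survival under
# insecticide exposure (with an excluded "recovered" class), duplicate
# 25-female pools per phenotype, and read sampling with overdispersed depth
# and a small base-miscall rate.

#' Simulation configuration
#'
#' Defaults emulate the pooled exome study design: 390 exposed females
#' phenotyped into knockdown-resistant / susceptible / recovered classes
#' (roughly 38/38/24%), pools of 25 in duplicate per phenotype group, a
#' causal locus at intermediate frequency on chromosome 3, sequencing depth
#' overdispersed around 100x inside the analysable 25-1000x window, and a
#' small base-miscall rate.
#'
#' @param n_chromosomes number of chromosomes.
#' @param sites_per_chromosome sites on each chromosome.
#' @param site_spacing distance in bases between consecutive sites.
#' @param polymorphic_fraction fraction of sites segregating in the source
#'   population (the study's exome showed ~6.4%).
#' @param maf_range range of the uniform minor-allele-frequency draw for
#'   neutral polymorphic sites.
#' @param include_causal plant a causal resistance locus (`FALSE` gives the
#'   null model: survival independent of genotype at rate `null_survival`).
#' @param causal_chromosome chromosome carrying the causal locus.
#' @param resistant_allele_freq frequency of the resistance allele in the
#'   source population.
#' @param survival_probs named vector `c(RR=, RS=, SS=)` of probabilities of
#'   remaining active under the discriminating exposure.
#' @param recovery_prob probability that a knocked-down individual recovers
#'   (recovered individuals are labelled and excluded from pooling).
#' @param null_survival activity probability under `include_causal = FALSE`.
#' @param linked_block_size distance in bases over which linkage with the
#'   causal site decays to zero (linear decay).
#' @param marker_background_freq range of the frequency at which sweep-marker
#'   alleles also segregate on non-resistant haplotype backgrounds
#'   (standing variation; keeps the causal site the most diverged locus).
#' @param marker_retention_max ceiling on the marker-causal haplotype
#'   association: even adjacent markers track the swept background with at
#'   most this probability, because the sweep acted on standing variation
#'   spread over several backgrounds.
#' @param category_poly_multiplier multiplier on the polymorphism rate
#'   inside genes tagged with a detox category (CYP/CCE/GST/Redox); 1 =
#'   same rate everywhere.
#' @param n_individuals_exposed exposed cohort size.
#' @param pool_size individuals per pooled library.
#' @param n_replicates replicate pools per phenotype group.
#' @param depth_mean,depth_dispersion negative-binomial depth model per site
#'   per library (`mu`, `size`); depth 0 is allowed and yields all-zero
#'   counts. `depth_dispersion = Inf` gives constant depth `depth_mean`.
#' @param error_rate per-read probability of a miscall to a uniformly chosen
#'   different base.
#' @param seed master seed; each simulation stage derives its own substream
#'   so stages are independently reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 3L,
                       sites_per_chromosome = 2000L,
                       site_spacing = 500L,
                       polymorphic_fraction = 0.064,
                       maf_range = c(0.05, 0.5),
                       include_causal = TRUE,
                       causal_chromosome = "3",
                       resistant_allele_freq = 0.5,
                       survival_probs = c(RR = 0.9, RS = 0.3, SS = 0.02),
                       recovery_prob = 0.39,
                       null_survival = 0.38,
                       linked_block_size = 2e5,
                       marker_background_freq = c(0.55, 0.7),
                       marker_retention_max = 0.8,
                       category_poly_multiplier = 1,
                       n_individuals_exposed = 390L,
                       pool_size = 25L,
                       n_replicates = 2L,
                       depth_mean = 150,
                       depth_dispersion = 10,
                       error_rate = 0.002,
                       seed = 1L) {
  check_prob(c(polymorphic_fraction, resistant_allele_freq, survival_probs,
               recovery_prob, null_survival, error_rate), "probabilities")
  if (!all(c("RR", "RS", "SS") %in% names(survival_probs))) {
    stopf("survival_probs must be named RR, RS, SS")
  }
  if (pool_size * n_replicates * 2 > n_individuals_exposed) {
    stopf("pool_size x n_replicates x 2 (%d) exceeds the exposed cohort (%d)",
          pool_size * n_replicates * 2, n_individuals_exposed)
  }
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              sites_per_chromosome = as.integer(sites_per_chromosome),
              site_spacing = as.integer(site_spacing),
              polymorphic_fraction = polymorphic_fraction,
              maf_range = maf_range,
              include_causal = isTRUE(include_causal),
              causal_chromosome = as.character(causal_chromosome),
              resistant_allele_freq = resistant_allele_freq,
              survival_probs = survival_probs,
              recovery_prob = recovery_prob,
              null_survival = null_survival,
              linked_block_size = linked_block_size,
              marker_background_freq = marker_background_freq,
              marker_retention_max = marker_retention_max,
              category_poly_multiplier = category_poly_multiplier,
              n_individuals_exposed = as.integer(n_individuals_exposed),
              pool_size = as.integer(pool_size),
              n_replicates = as.integer(n_replicates),
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              error_rate = error_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# deterministic gene tiling: genes of 30 sites (5'UTR 3, CDS 24, 3'UTR 3)
# separated by 10-site gaps, strand alternating, categories cycling through
# a fixed pattern; the gene containing the causal site is tagged "neuro"
# (a sodium-channel-like target gene).
GENE_SITES <- 30L
GAP_SITES <- 10L
CATEGORY_CYCLE <- c("other", "other", "CYP", "other", "other", "CCE",
                    "other", "neuro", "other", "GST", "other", "other",
                    "Redox", "other", "cuticle", "other")

#' Gene models of the simulated genome
#'
#' @param config a [sim_config].
#' @return gene-model intervals in the same schema as [read_gene_models].
#' @export
sim_gene_models <- function(config) {
  s <- config$site_spacing
  per <- (GENE_SITES + GAP_SITES) * s
  chrom_len <- config$sites_per_chromosome * s
  causal <- sim_causal_site(config)
  out <- list()
  g <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    cc <- as.character(ci)
    start <- s  # first site position
    k <- 0L
    while (start + GENE_SITES * s - 1 <= chrom_len + s) {
      g <- g + 1L; k <- k + 1L
      gene_id <- sprintf("gene%s_%03d", cc, k)
      utr5 <- 3L * s; cds <- 24L * s; utr3 <- 3L * s
      # CDS base length must be divisible by 3
      cds <- (cds %/% 3L) * 3L
      strand <- if (k %% 2 == 0) "-" else "+"
      b0 <- start
      iv <- data.frame(
        feature = if (strand == "+") c("five_prime_utr", "cds", "three_prime_utr")
        else c("three_prime_utr", "cds", "five_prime_utr"),
        start = c(b0, b0 + utr5, b0 + utr5 + cds),
        end = c(b0 + utr5 - 1L, b0 + utr5 + cds - 1L,
                b0 + utr5 + cds + utr3 - 1L))
      category <- CATEGORY_CYCLE[(g - 1L) %% length(CATEGORY_CYCLE) + 1L]
      if (config$include_causal && cc == causal$chrom &&
          causal$pos >= b0 && causal$pos <= b0 + utr5 + cds + utr3 - 1L) {
        category <- "neuro"
      }
      out[[g]] <- data.frame(gene_id = gene_id, chrom = cc, strand = strand,
                             feature = iv$feature,
                             start = as.integer(iv$start),
                             end = as.integer(iv$end),
                             cds_ok = TRUE, category = category,
                             stringsAsFactors = FALSE)
      start <- start + per
    }
  }
  do.call(rbind, out)
}

# the causal site: CDS midpoint of the middle gene of the causal chromosome
sim_causal_site <- function(config) {
  s <- config$site_spacing
  per <- GENE_SITES + GAP_SITES
  n_genes <- config$sites_per_chromosome %/% per
  mid_gene <- max(1L, n_genes %/% 2L)
  # site index of the middle of the mid gene's CDS (sites 4..27 of the gene)
  site_idx <- (mid_gene - 1L) * per + 15L
  list(chrom = config$causal_chromosome, pos = site_idx * s)
}

#' Simulate the exposed cohort
#'
#' Draws per-individual genotypes at every polymorphic site and a phenotype
#' label per individual. The resistance allele resides on a single founder
#' haplotype background; polymorphic sites within `linked_block_size` of
#' the causal locus act as sweep markers whose association with that
#' background decays linearly with distance, while also segregating at
#' `marker_background_freq` on other backgrounds. Phenotype is drawn as
#' Bernoulli(survival prob of the causal genotype); knocked-down
#' individuals recover with `recovery_prob` and are labelled "recovered"
#' (excluded from pooling).
#'
#' @param config a [sim_config].
#' @return list of class `pool_cohort`: `sites` (all sites with ref/alt,
#'   polymorphism flag and map position), `dosage` (individuals x
#'   polymorphic-site matrix of alternate-allele dosages 0/1/2),
#'   `phenotype` (per-individual label), `truth` (per-site true allele
#'   frequencies in the survivor and knocked-down classes, causal flag and
#'   distance to the causal site) and `config`.
#' @export
simulate_cohort <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  n_ind <- config$n_individuals_exposed
  s <- config$site_spacing
  nc <- config$n_chromosomes
  nsite <- config$sites_per_chromosome
  sites <- data.frame(
    chrom = rep(as.character(seq_len(nc)), each = nsite),
    pos = rep(seq_len(nsite) * s, nc),
    stringsAsFactors = FALSE)
  n <- nrow(sites)
  sites$ref <- sample(BASES, n, replace = TRUE)
  models <- sim_gene_models(config)
  # polymorphism: optionally elevated inside detox-tagged genes
  poly_rate <- rep(config$polymorphic_fraction, n)
  if (config$category_poly_multiplier != 1) {
    cats <- gene_categories(models)
    spans <- gene_spans(models)
    spans <- spans[cats[spans$gene_id] %in% DETOX_TAGS, , drop = FALSE]
    in_detox <- rep(FALSE, n)
    for (i in seq_len(nrow(spans))) {
      in_detox <- in_detox | (sites$chrom == spans$chrom[i] &
                                sites$pos >= spans$start[i] &
                                sites$pos <= spans$end[i])
    }
    poly_rate[in_detox] <- pmin(1, poly_rate[in_detox] *
                                  config$category_poly_multiplier)
  }
  sites$polymorphic <- stats::runif(n) < poly_rate
  causal <- sim_causal_site(config)
  causal_row <- which(sites$chrom == causal$chrom & sites$pos == causal$pos)
  if (config$include_causal) sites$polymorphic[causal_row] <- TRUE
  sites$alt <- NA_character_
  poly <- which(sites$polymorphic)
  sites$alt[poly] <- vapply(sites$ref[poly], function(rb)
    sample(setdiff(BASES, rb), 1), character(1))
  sites$causal <- FALSE
  sites$dist_to_causal <- NA_real_
  if (config$include_causal) {
    sites$causal[causal_row] <- TRUE
    on_cc <- sites$chrom == causal$chrom
    sites$dist_to_causal[on_cc] <- abs(sites$pos[on_cc] - causal$pos)
  }
  # genotypes at polymorphic sites
  npoly <- length(poly)
  dosage <- matrix(0L, n_ind, npoly)
  maf <- stats::runif(npoly, config$maf_range[1], config$maf_range[2])
  is_marker <- rep(FALSE, npoly)
  if (config$include_causal) {
    dist <- sites$dist_to_causal[poly]
    is_causal_col <- poly == causal_row
    is_marker <- !is.na(dist) & dist > 0 & dist <= config$linked_block_size
    # founder background per haplotype (2 per individual)
    b1 <- stats::rbinom(n_ind, 1, config$resistant_allele_freq)
    b2 <- stats::rbinom(n_ind, 1, config$resistant_allele_freq)
    dosage[, is_causal_col] <- b1 + b2
    retention <- config$marker_retention_max *
      pmax(0, 1 - dist / config$linked_block_size)
    mbf <- stats::runif(npoly, config$marker_background_freq[1],
                        config$marker_background_freq[2])
    for (j in which(is_marker)) {
      r <- retention[j]
      popfreq <- config$resistant_allele_freq +
        (1 - config$resistant_allele_freq) * mbf[j]
      hap_allele <- function(bg) {
        retained <- stats::runif(n_ind) < r
        ifelse(retained,
               ifelse(bg == 1, 1L, stats::rbinom(n_ind, 1, mbf[j])),
               stats::rbinom(n_ind, 1, popfreq))
      }
      dosage[, j] <- hap_allele(b1) + hap_allele(b2)
    }
  }
  neutral <- which(!is_marker & !(poly %in% causal_row[config$include_causal]))
  if (length(neutral)) {
    dosage[, neutral] <- stats::rbinom(n_ind * length(neutral), 2,
                                       rep(maf[neutral], each = n_ind))
  }
  # phenotype from the causal genotype
  if (config$include_causal) {
    g <- dosage[, which(poly == causal_row)]
    surv <- unname(config$survival_probs[c("SS", "RS", "RR")])[g + 1L]
  } else {
    surv <- rep(config$null_survival, n_ind)
  }
  active <- stats::rbinom(n_ind, 1, surv) == 1
  recovered <- !active & stats::rbinom(n_ind, 1, config$recovery_prob) == 1
  phenotype <- ifelse(active, "resistant",
                      ifelse(recovered, "recovered", "susceptible"))
  # truth table: class allele frequencies at every site
  truth <- sites[c("chrom", "pos", "ref", "alt", "polymorphic", "causal",
                   "dist_to_causal")]
  truth$freq_resistant <- 0
  truth$freq_susceptible <- 0
  res_idx <- phenotype == "resistant"
  sus_idx <- phenotype == "susceptible"
  if (any(res_idx)) {
    truth$freq_resistant[poly] <- colSums(dosage[res_idx, , drop = FALSE]) /
      (2 * sum(res_idx))
  }
  if (any(sus_idx)) {
    truth$freq_susceptible[poly] <- colSums(dosage[sus_idx, , drop = FALSE]) /
      (2 * sum(sus_idx))
  }
  cats <- gene_categories(models)
  spans <- gene_spans(models)
  truth$category <- "other"
  for (i in seq_len(nrow(spans))) {
    hit <- truth$chrom == spans$chrom[i] & truth$pos >= spans$start[i] &
      truth$pos <= spans$end[i]
    truth$category[hit] <- unname(cats[spans$gene_id[i]])
  }
  structure(list(sites = sites, dosage = dosage, poly_index = poly,
                 phenotype = phenotype, truth = truth, models = models,
                 config = config),
            class = "pool_cohort")
}

#' @export
print.pool_cohort <- function(x, ...) {
  cat(sprintf("pool_cohort: %d individuals (%s), %d sites (%d polymorphic)\n",
              length(x$phenotype),
              paste(sprintf("%s %d", names(table(x$phenotype)),
                            table(x$phenotype)), collapse = ", "),
              nrow(x$sites), length(x$poly_index)))
  invisible(x)
}

#' Draw pooled libraries from the phenotyped cohort
#'
#' Samples `pool_size` individuals per replicate without replacement from
#' the matching phenotype class (recovered individuals are never pooled).
#'
#' @param cohort a `pool_cohort`.
#' @param share_replicates sequence the same pool membership into both
#'   replicate libraries of a group (technical replication; used for
#'   calibration studies of the replicate-concordance filter).
#' @param share_groups use the resistant pool memberships for the
#'   susceptible libraries as well (a pure technical null in which all four
#'   libraries resample one set of chromosomes).
#' @return list of class `pool_design`: `libraries` (id/group/replicate)
#'   and `members` (list of individual indices per library).
#' @export
draw_pools <- function(cohort, share_replicates = FALSE,
                       share_groups = FALSE) {
  config <- cohort$config
  set.seed(derive_seed(config$seed, 2L))
  need <- config$pool_size * config$n_replicates
  members <- list()
  libraries <- data.frame(id = character(0), group = character(0),
                          replicate = integer(0), stringsAsFactors = FALSE)
  for (grp in c("resistant", "susceptible")) {
    cls <- which(cohort$phenotype == grp)
    if (grp == "susceptible" && share_groups) {
      for (r in seq_len(config$n_replicates)) {
        id <- sprintf("S%d", r)
        members[[id]] <- members[[sprintf("R%d", r)]]
        libraries <- rbind(libraries, data.frame(id = id, group = grp,
                                                 replicate = r))
      }
      next
    }
    n_draw <- if (share_replicates) config$pool_size else need
    if (length(cls) < n_draw) {
      stopf("phenotype class '%s' has only %d individuals; %d required for %d pool(s) of %d",
            grp, length(cls), n_draw,
            if (share_replicates) 1L else config$n_replicates,
            config$pool_size)
    }
    drawn <- sample(cls, n_draw)
    for (r in seq_len(config$n_replicates)) {
      id <- sprintf("%s%d", if (grp == "resistant") "R" else "S", r)
      members[[id]] <- if (share_replicates) drawn else
        drawn[((r - 1) * config$pool_size + 1):(r * config$pool_size)]
      libraries <- rbind(libraries, data.frame(id = id, group = grp,
                                               replicate = r))
    }
  }
  structure(list(libraries = libraries, members = members),
            class = "pool_design")
}

#' Sequence the pooled libraries
#'
#' Per site and library, depth is drawn from the negative-binomial depth
#' model; read alleles are drawn with replacement from the pool's
#' chromosomes; each read is miscalled to a uniformly chosen different base
#' with probability `error_rate`. Counts always sum to the drawn depth.
#'
#' @param cohort a `pool_cohort`.
#' @param design a `pool_design` from [draw_pools].
#' @return a [pool_counts] object.
#' @export
sequence_pools <- function(cohort, design) {
  config <- cohort$config
  set.seed(derive_seed(config$seed, 3L))
  n <- nrow(cohort$sites)
  libs <- design$libraries
  counts <- array(0L, dim = c(n, 4, nrow(libs)),
                  dimnames = list(NULL, BASES, libs$id))
  refidx <- match(cohort$sites$ref, BASES)
  altidx <- match(cohort$sites$alt, BASES)   # NA at monomorphic sites
  poly <- cohort$poly_index
  err <- config$error_rate
  for (j in seq_len(nrow(libs))) {
    memb <- design$members[[libs$id[j]]]
    depth <- if (is.finite(config$depth_dispersion)) {
      stats::rnbinom(n, size = config$depth_dispersion,
                     mu = config$depth_mean)
    } else {
      rep(as.integer(round(config$depth_mean)), n)  # Inf dispersion = constant
    }
    f <- rep(0, n)
    f[poly] <- colSums(cohort$dosage[memb, , drop = FALSE]) /
      (2 * length(memb))
    alt_reads <- stats::rbinom(n, depth, f)
    ref_reads <- depth - alt_reads
    m <- matrix(0L, n, 4)
    m[cbind(seq_len(n), refidx)] <- ref_reads
    ok <- !is.na(altidx)
    m[cbind(which(ok), altidx[ok])] <- m[cbind(which(ok), altidx[ok])] +
      alt_reads[ok]
    if (err > 0) {
      for (b in 1:4) {
        mis <- stats::rbinom(n, m[, b], err)
        if (!any(mis > 0)) next
        m[, b] <- m[, b] - mis
        others <- setdiff(1:4, b)
        m1 <- stats::rbinom(n, mis, 1 / 3)
        m2 <- stats::rbinom(n, mis - m1, 1 / 2)
        m3 <- mis - m1 - m2
        m[, others[1]] <- m[, others[1]] + m1
        m[, others[2]] <- m[, others[2]] + m2
        m[, others[3]] <- m[, others[3]] + m3
      }
    }
    counts[, , j] <- m
  }
  pool_counts(cohort$sites[c("chrom", "pos", "ref")], counts, libs)
}

#' Simulate a complete pooled experiment
#'
#' Convenience wrapper: [simulate_cohort] + [draw_pools] + [sequence_pools].
#'
#' @param config a [sim_config].
#' @param ... passed to [draw_pools].
#' @return list with `counts` ([pool_counts]), `cohort`, `design`, `truth`
#'   and `models` (the simulated gene models).
#' @export
simulate_experiment <- function(config = sim_config(), ...) {
  cohort <- simulate_cohort(config)
  design <- draw_pools(cohort, ...)
  counts <- sequence_pools(cohort, design)
  list(counts = counts, cohort = cohort, design = design,
       truth = cohort$truth, models = cohort$models)
}

#' Reference sequence of the simulated genome
#'
#' Random chromosome sequences consistent with the simulated site table
#' (each site's position carries its reference base), for codon-effect
#' annotation of simulated SNPs.
#'
#' @param cohort a `pool_cohort`.
#' @return a `Biostrings::DNAStringSet`, one entry per chromosome.
#' @export
sim_reference <- function(cohort) {
  config <- cohort$config
  set.seed(derive_seed(config$seed, 4L))
  len <- config$sites_per_chromosome * config$site_spacing + config$site_spacing
  out <- character(config$n_chromosomes)
  for (ci in seq_len(config$n_chromosomes)) {
    cc <- as.character(ci)
    seqv <- sample(BASES, len, replace = TRUE)
    rows <- cohort$sites$chrom == cc
    seqv[cohort$sites$pos[rows]] <- cohort$sites$ref[rows]
    out[ci] <- paste(seqv, collapse = "")
  }
  names(out) <- as.character(seq_len(config$n_chromosomes))
  Biostrings::DNAStringSet(out)
}
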