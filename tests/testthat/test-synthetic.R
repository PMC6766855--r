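# The forward simulator: survival model, pooling design, read sampling,
# reproducibility, and the statistical structure the analysis assumes.

test_that("deterministic survival separates carriers from non-carriers", {
  cfg <- sim_config(sites_per_chromosome = 200,
                    survival_probs = c(RR = 1, RS = 1, SS = 0),
                    recovery_prob = 0, seed = 3)
  cohort <- simulate_cohort(cfg)
  g <- cohort$dosage[, which(cohort$poly_index ==
                               which(cohort$sites$causal))]
  expect_true(all(g[cohort$phenotype == "resistant"] >= 1))
  expect_true(all(g[cohort$phenotype == "susceptible"] == 0))
})

test_that("survivors carry the resistance allele in excess in every cohort", {
  # Monte-Carlo check of the configured survival model
  for (s in 1:200) {
    cfg <- sim_config(n_chromosomes = 1L, causal_chromosome = "1",
                      sites_per_chromosome = 50L, seed = s)
    cohort <- simulate_cohort(cfg)
    tr <- cohort$truth[cohort$truth$causal, ]
    expect_gt(tr$freq_resistant, tr$freq_susceptible)
  }
})

test_that("the pooling design mirrors the study: duplicate pools of 25 without replacement", {
  cohort <- simulate_cohort(small_sim_config(seed = 13))
  design <- draw_pools(cohort)
  expect_equal(design$libraries$id, c("R1", "R2", "S1", "S2"))
  expect_equal(lengths(design$members), c(R1 = 25L, R2 = 25L,
                                          S1 = 25L, S2 = 25L))
  expect_equal(anyDuplicated(c(design$members$R1, design$members$R2)), 0L)
  expect_equal(anyDuplicated(c(design$members$S1, design$members$S2)), 0L)
  expect_true(all(cohort$phenotype[design$members$R1] == "resistant"))
  expect_true(all(cohort$phenotype[design$members$S2] == "susceptible"))
})

test_that("an undersized phenotype class fails with an error naming the class", {
  cfg <- sim_config(sites_per_chromosome = 100, include_causal = FALSE,
                    null_survival = 0.02, n_individuals_exposed = 120L,
                    seed = 2)
  cohort <- simulate_cohort(cfg)
  expect_error(draw_pools(cohort), "resistant")
})

test_that("read counts conserve depth and respect the error model", {
  # constant depth: all counts must sum to exactly that depth, even with a
  # high miscall rate
  cfg <- sim_config(sites_per_chromosome = 300, depth_dispersion = Inf,
                    depth_mean = 80, error_rate = 0.3, seed = 19)
  ex <- simulate_experiment(cfg)
  expect_true(all(site_depths(ex$counts) == 80L))

  # no miscalls: monomorphic sites carry reads only on the reference base
  cfg0 <- sim_config(sites_per_chromosome = 300, depth_dispersion = Inf,
                     depth_mean = 100, error_rate = 0, seed = 19)
  ex0 <- simulate_experiment(cfg0)
  mono <- which(!ex0$cohort$sites$polymorphic)
  refidx <- match(ex0$cohort$sites$ref[mono], c("A", "C", "G", "T"))
  for (lib in c("R1", "S2")) {
    cnt <- matrix(ex0$counts$counts[mono, , lib], ncol = 4)
    expect_true(all(cnt[cbind(seq_along(mono), refidx)] == 100L))
  }
})

test_that("read-level alternate frequencies are binomial around the pool frequency", {
  # all-heterozygote pool: true frequency exactly 0.5 at every site
  cfg <- sim_config(n_chromosomes = 1L, causal_chromosome = "1",
                    sites_per_chromosome = 1000L, polymorphic_fraction = 1,
                    include_causal = FALSE, depth_dispersion = Inf,
                    depth_mean = 100, error_rate = 0, seed = 23)
  cohort <- simulate_cohort(cfg)
  cohort$dosage[] <- 1L                   # force heterozygosity everywhere
  design <- draw_pools(cohort)
  x <- sequence_pools(cohort, design)
  altidx <- match(cohort$sites$alt, c("A", "C", "G", "T"))
  cnt <- matrix(x$counts[, , "R1"], ncol = 4)
  f <- cnt[cbind(seq_len(nrow(cnt)), altidx)] / rowSums(cnt)
  se <- sqrt(0.5 * 0.5 / (100 * length(f)))
  expect_lt(abs(mean(f) - 0.5), 3 * se)
})

test_that("a constant depth of 24 is removed entirely by the depth filter", {
  cfg <- sim_config(sites_per_chromosome = 100, depth_dispersion = Inf,
                    depth_mean = 24, seed = 29)
  ex <- simulate_experiment(cfg)
  flt <- filter_sites(ex$counts)
  expect_equal(nrow(flt$records$sites), 0)
  expect_equal(flt$report$n_sites[flt$report$stage == "common"], 0)
})

test_that("identical seed and config reproduce the experiment bit for bit", {
  a <- simulate_experiment(small_sim_config(seed = 37))
  b <- simulate_experiment(small_sim_config(seed = 37))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$cohort$dosage, b$cohort$dosage)
  expect_identical(a$design$members, b$design$members)
  c_ <- simulate_experiment(small_sim_config(seed = 38))
  expect_false(identical(a$counts$counts, c_$counts$counts))
})

test_that("without genotype-dependent survival the causal divergence is pure noise", {
  diffs <- vapply(1:50, function(s) {
    cfg <- sim_config(n_chromosomes = 1L, causal_chromosome = "1",
                      sites_per_chromosome = 50L,
                      survival_probs = c(RR = 0.38, RS = 0.38, SS = 0.38),
                      seed = 400 + s)
    tr <- simulate_cohort(cfg)$truth
    tr <- tr[tr$causal, ]
    tr$freq_resistant - tr$freq_susceptible
  }, numeric(1))
  # mean difference compatible with zero at 3 MC SE
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("group divergence decays with distance from the causal site", {
  # expectation over seeds: divergence in the inner half of the linked block
  # exceeds the outer half, which exceeds unlinked sites
  inner <- c(); outer <- c(); far <- c()
  for (s in 1:100) {
    cfg <- sim_config(n_chromosomes = 1L, causal_chromosome = "1",
                      sites_per_chromosome = 1200L, seed = 600 + s)
    tr <- simulate_cohort(cfg)$truth
    tr <- tr[tr$polymorphic & !tr$causal, ]
    d <- abs(tr$freq_resistant - tr$freq_susceptible)
    L <- cfg$linked_block_size
    inner <- c(inner, d[tr$dist_to_causal <= L / 2])
    outer <- c(outer, d[tr$dist_to_causal > L / 2 & tr$dist_to_causal <= L])
    far <- c(far, d[tr$dist_to_causal > L])
  }
  expect_gt(mean(inner), mean(outer))
  expect_gt(mean(outer), mean(far))
})
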