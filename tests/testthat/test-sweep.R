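# Expected heterozygosity and the per-chromosome sweep t test.

test_that("H_exp follows 1 - sum(p^2)", {
  expect_equal(site_heterozygosity(1), 0)
  expect_equal(site_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(site_heterozygosity(rep(0.25, 4)), 0.75)
  expect_error(site_heterozygosity(c(0.5, 0.4)), "sum to 1")
  expect_error(site_heterozygosity(c(1.2, -0.2)), "0, 1")
})

test_that("H_exp increases toward uniformity (pairwise majorization)", {
  # moving mass from the majority to the minority allele raises H_exp
  p <- seq(0.5, 0.99, by = 0.01)
  h <- vapply(p, function(q) site_heterozygosity(c(q, 1 - q)), numeric(1))
  expect_true(all(diff(h) < 0))
})

test_that("the paired t test matches its textbook example and edge cases", {
  r <- het_difference_test(c(-0.1, -0.2, -0.15), "3")
  expect_equal(r$mean, -0.15)
  expect_equal(r$t, -5.196, tolerance = 1e-3)
  expect_equal(r$p, 0.0351, tolerance = 1e-3)
  expect_equal(r$sweep, "Y")

  r <- het_difference_test(rep(0, 5), "1")
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$sweep, "N")

  r <- het_difference_test(rep(-0.1, 5), "1")   # zero variance, nonzero mean
  expect_equal(r$p, 0)
  expect_equal(r$sweep, "Y")

  r <- het_difference_test(c(-0.1), "1")        # too few records
  expect_equal(r$sweep, "N")
  expect_true(is.na(r$p))
})

test_that("the t test equals an independent closed-form computation", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    d <- stats::rnorm(n, sd = 0.1)
    r <- het_difference_test(d, "x")
    m <- mean(d); s <- stats::sd(d)
    tval <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tval), n - 1)
    half <- stats::qt(0.975, n - 1) * s / sqrt(n)
    expect_equal(r$t, tval, tolerance = 1e-10)
    expect_equal(r$p, p, tolerance = 1e-10)
    expect_equal(c(r$cl_low, r$cl_high), c(m - half, m + half),
                 tolerance = 1e-10)
  }
})

test_that("sweep records carry group heterozygosities from pooled counts", {
  x <- one_site_counts(c(90, 10, 0, 0), c(95, 5, 0, 0),
                       c(50, 50, 0, 0), c(55, 45, 0, 0))
  rec <- associate_sites(x)
  rec$fdr_pass <- TRUE
  sw <- sweep_records(x, rec)
  expect_equal(sw$het_resistant, site_heterozygosity(c(185, 15) / 200))
  expect_equal(sw$het_susceptible, site_heterozygosity(c(105, 95) / 200))
  expect_equal(sw$diff, sw$het_resistant - sw$het_susceptible)
  expect_true(sw$diff < 0)
})

test_that("region profile windows, orders and labels significant SNPs", {
  sw <- data.frame(chrom = "3", pos = c(5000L, 1500L, 9000L, 30000L),
                   het_resistant = 0.1, het_susceptible = 0.3,
                   diff = -0.2, neg_log10_p = 5)
  models <- data.frame(gene_id = "vgsc_like", chrom = "3", strand = "+",
                       feature = "cds", start = 1000L, end = 6000L,
                       cds_ok = TRUE, category = "neuro",
                       stringsAsFactors = FALSE)
  # flank 0: only SNPs inside the focal gene
  prof <- region_profile(sw, "3", 1000, 6000, flank = 0, models = models)
  expect_equal(prof$pos, c(1500L, 5000L))
  expect_equal(unique(prof$gene_id), "vgsc_like")
  # flank extends the window
  prof <- region_profile(sw, "3", 1000, 6000, flank = 4000, models = models)
  expect_equal(prof$pos, c(1500L, 5000L, 9000L))
  expect_equal(prof$gene_id[3], "intergenic")
  expect_error(region_profile(sw, "3", 1000, 6000, flank = -1), "flank")
})

test_that("the linked block shows stronger heterozygosity loss than the rest of the genome", {
  # mean diff inside the swept block vs outside, over seeds
  inside <- c(); outside <- c()
  for (s in 1:15) {
    ex <- simulate_experiment(sim_config(sites_per_chromosome = 600, seed = s))
    flt <- filter_sites(ex$counts)
    rec <- apply_fdr(associate_sites(flt$records), 0.05)
    sw <- sweep_records(flt$records, rec, significant_only = FALSE)
    key <- paste(sw$chrom, sw$pos)
    tkey <- paste(ex$truth$chrom, ex$truth$pos)
    d <- ex$truth$dist_to_causal[match(key, tkey)]
    in_block <- !is.na(d) & d <= ex$cohort$config$linked_block_size
    inside <- c(inside, sw$diff[in_block])
    outside <- c(outside, sw$diff[!in_block])
  }
  expect_true(mean(inside, na.rm = TRUE) < mean(outside, na.rm = TRUE))
})
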