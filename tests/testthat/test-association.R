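# Pooled contingency association and per-chromosome BH FDR.

test_that("association test matches hand-computed Pearson values", {
  # no divergence
  r <- association_test(c(100, 100, 0, 0), c(100, 100, 0, 0))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(r$neg_log10_p, 0)
  # worked 2x2: expected 107.5 / 92.5 per group
  r <- association_test(c(175, 25, 0, 0), c(40, 160, 0, 0))
  expect_equal(r$chi2, 183.281, tolerance = 1e-4)
  expect_equal(r$df, 1L)
  expect_equal(r$p, stats::pchisq(r$chi2, 1, lower.tail = FALSE))
  # replicate matrices are summed, not averaged
  r2 <- association_test(rbind(c(100, 10, 0, 0), c(75, 15, 0, 0)),
                         rbind(c(30, 70, 0, 0), c(10, 90, 0, 0)))
  expect_equal(r2$chi2,
               association_test(c(175, 25, 0, 0), c(40, 160, 0, 0))$chi2)
  expect_error(association_test(c(100, 0, 0, 0), c(50, 0, 0, 0)),
               "monomorphic")
})

test_that("a 2x2 chi-square equals the squared two-proportion z statistic", {
  set.seed(21)
  for (i in 1:30) {
    a <- rpois(1, 80) + 1; b <- rpois(1, 60) + 1
    c_ <- rpois(1, 50) + 1; d <- rpois(1, 90) + 1
    r <- association_test(c(a, b, 0, 0), c(c_, d, 0, 0))
    n1 <- a + b; n2 <- c_ + d
    p1 <- a / n1; p2 <- c_ / n2; pp <- (a + c_) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(r$chi2, z^2, tolerance = 1e-10)
  }
})

test_that("BH step-up reproduces worked examples and brute force", {
  r <- bh_thresholds(c(0.001, 0.008, 0.039, 0.041), rep("1", 4), alpha = 0.05)
  expect_equal(r$k, 4L)                 # 0.041 <= 0.05 rescues 0.039
  expect_equal(r$threshold_neg_log10, -log10(0.041), tolerance = 1e-4)
  expect_equal(round(r$threshold_neg_log10, 4), 1.3872)

  r <- bh_thresholds(c(0.001, 0.02, 0.06, 0.9), rep("1", 4), alpha = 0.05)
  expect_equal(r$k, 2L)
  expect_equal(round(r$threshold_neg_log10, 4), 1.6990)

  r <- bh_thresholds(rep(1, 5), rep("1", 5), alpha = 0.05)
  expect_equal(r$k, 0L)
  expect_true(is.na(r$threshold_neg_log10))

  # brute-force BH definition on random vectors, plus p.adjust cross-check
  brute <- function(p, alpha) {
    m <- length(p); ps <- sort(p)
    ok <- which(ps <= seq_len(m) * alpha / m)
    if (!length(ok)) return(logical(m))
    p <= ps[max(ok)]
  }
  set.seed(31)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    alpha <- stats::runif(1, 0.01, 0.2)
    res <- bh_thresholds(p, rep("1", m), alpha)
    flags <- brute(p, alpha)
    expect_identical(res$k, as.integer(sum(flags)))
    expect_identical(unname(stats::p.adjust(p, "BH") <= alpha), flags)
  }
})

test_that("discoveries are monotone non-decreasing in alpha", {
  set.seed(41)
  p <- stats::runif(200)^2
  ks <- vapply(c(0.01, 0.05, 0.1, 0.2),
               function(a) bh_thresholds(p, rep("1", 200), a)$k, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("fdr flags are applied per chromosome at the step-up threshold", {
  rec <- data.frame(chrom = rep(c("1", "2"), each = 3),
                    pos = rep(1:3, 2) * 10,
                    p = c(0.0001, 0.2, 0.9, 0.5, 0.6, 0.7))
  rec$neg_log10_p <- -log10(rec$p)
  out <- apply_fdr(rec, alpha = 0.05)
  expect_equal(out$fdr_pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  fdr <- attr(out, "fdr")
  expect_equal(fdr$m, c(3L, 3L))
  expect_equal(fdr$k, c(1L, 0L))
})

test_that("a V410L-like frequency pattern tops its chromosome", {
  # resistant replicate freqs 0.88 / 0.73, susceptible 0.10 / 0.30 at ~150x,
  # against a background of weakly diverged sites
  set.seed(51)
  n <- 40
  libs <- std_libraries()
  mk <- function(freqs) {
    m <- matrix(0L, n, 4)
    d <- rep(150L, n)
    alt <- rbinom(n, d, freqs)
    m[, 2] <- alt; m[, 1] <- d - alt
    m
  }
  base <- stats::runif(n, 0.3, 0.5)   # shared background frequencies
  cl <- list(R1 = mk(base), R2 = mk(base), S1 = mk(base), S2 = mk(base))
  x <- make_counts("3", 1:n * 1000, rep("A", n), cl)
  kdr <- 10L
  x$counts[kdr, , "R1"] <- c(150 - 132, 132, 0, 0)  # freq 0.88
  x$counts[kdr, , "R2"] <- c(150 - 110, 110, 0, 0)  # freq 0.73
  x$counts[kdr, , "S1"] <- c(150 - 15, 15, 0, 0)    # freq 0.10
  x$counts[kdr, , "S2"] <- c(150 - 45, 45, 0, 0)    # freq 0.30
  rec <- associate_sites(x)
  expect_equal(which.max(rec$neg_log10_p), kdr)
})

test_that("p-value underflow is capped and flagged", {
  r <- association_test(c(1e6, 0, 0, 10), c(10, 0, 0, 1e6))
  expect_true(r$capped)
  expect_equal(r$neg_log10_p, 320)
})
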