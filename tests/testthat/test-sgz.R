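# SGZ model: log-ratio formula, segmentation, purity/ploidy fit,
# classification.

test_that("expected log-ratio follows the purity/ploidy formula", {
  expect_equal(expected_logratio(1, 2, 2), 0)
  expect_equal(expected_logratio(0.5, 4, 2), log2(3 / 2))  # hand: (2+1)/(1+1)
  expect_equal(expected_logratio(1e-9, 5, 2), 0, tolerance = 1e-6)  # no-signal limit
  # strictly increasing in C at fixed P, psi
  lr <- expected_logratio(0.7, 0:6, 2.4)
  expect_true(all(diff(lr) > 0))
  expect_equal(expected_logratio(1, 0, 2), -Inf)
})

test_that("coverage segmentation recovers flat, stepped and single-bin profiles", {
  flat <- data.frame(chrom = "chr1", start = seq(1, 991, 10), end = seq(10, 1000, 10),
                     logratio = rep(0, 100))
  expect_equal(nrow(segment_coverage(flat)), 1L)

  set.seed(5)
  step <- flat
  step$logratio <- c(rnorm(50, 0, 0.05), rnorm(50, 1, 0.05))
  segs <- segment_coverage(step)
  expect_equal(nrow(segs), 2L)
  expect_lt(abs(which(step$start == segs$start[2]) - 51), 3)  # breakpoint within 2 bins
  expect_equal(segs$observed_logratio[2], 1, tolerance = 0.05)

  single <- flat[1, ]
  out <- segment_coverage(single)
  expect_equal(nrow(out), 1L)
  expect_equal(out$observed_logratio, single$logratio)
  expect_error(segment_coverage(flat[0, ]), "no coverage bins")
})

test_that("exact partitioning finds alternating changepoints greedy splitting misses", {
  set.seed(8)
  x <- c(rnorm(14, 0.08, 0.02), rnorm(14, 0.39, 0.02), rnorm(14, -0.2, 0.02),
         rnorm(14, 0.31, 0.02), rnorm(14, 0.1, 0.02))
  bins <- data.frame(chrom = "chr1", start = seq_along(x), end = seq_along(x),
                     logratio = x)
  expect_equal(nrow(segment_coverage(bins)), 5L)
})

test_that("noiseless purity-1 fit recovers each segment copy number exactly", {
  truthC <- c(1L, 2L, 3L, 2L, 4L)
  truthM <- c(0L, 1L, 1L, 0L, 2L)
  P <- 1; psi <- mean(truthC)
  segs <- data.frame(chrom = "chr1", start = (0:4) * 1000 + 1, end = (1:5) * 1000,
                     n_bins = 10L, observed_logratio = expected_logratio(P, truthC, psi))
  snp_af <- lapply(seq_along(truthC), function(i) {
    m <- truthM[i]
    rep(c((P * m + (1 - P)) / (P * truthC[i] + 2 * (1 - P)),
          (P * (truthC[i] - m) + (1 - P)) / (P * truthC[i] + 2 * (1 - P))), 10)
  })
  fit <- fit_purity_ploidy(segs, snp_af)
  expect_equal(fit$segments$C, truthC)
  expect_equal(fit$purity, 1)
  expect_equal(fit$ploidy, psi, tolerance = 0.01)
})

test_that("fit recovers purity and ploidy from noisy segments with het SNPs", {
  set.seed(13)
  errP <- errPsi <- numeric(10)
  for (g in 1:10) {
    P <- runif(1, 0.3, 0.9)
    states <- rbind(c(2, 1), c(2, 1), c(1, 0), c(3, 1), c(2, 0),
                    c(2, 1), c(4, 2), c(2, 1), c(3, 1), c(2, 1))
    psi <- mean(states[, 1])
    segs <- data.frame(chrom = "chr1", start = (0:9) * 1000 + 1, end = (1:10) * 1000,
                       n_bins = 14L,
                       observed_logratio = expected_logratio(P, states[, 1], psi) +
                         rnorm(10, 0, 0.03))
    snp_af <- lapply(1:10, function(i) {
      C <- states[i, 1]; m <- sample(c(states[i, 2], C - states[i, 2]), 60, replace = TRUE)
      e <- (P * m + (1 - P)) / (P * C + 2 * (1 - P))
      rbinom(60, 800, e) / 800
    })
    fit <- fit_purity_ploidy(segs, snp_af)
    errP[g] <- abs(fit$purity - P); errPsi[g] <- abs(fit$ploidy - psi)
  }
  expect_lte(median(errP), 0.05)
  expect_lte(median(errPsi), 0.1)
})

test_that("a flat genome is flagged unidentifiable and returned at the default purity", {
  segs <- data.frame(chrom = "chr1", start = 1, end = 1000, n_bins = 100,
                     observed_logratio = 0.001)
  fit <- fit_purity_ploidy(segs, list(rbinom(200, 1000, 0.5) / 1000))
  expect_false(fit$identifiable)
  expect_equal(fit$purity, 0.5)
  expect_equal(fit$segments$C, 2L)
})

test_that("tumor_model methods expose coefficients and predictions", {
  m <- toy_model(P = 0.6, C = 3L, M = 1L, psi = 2)
  expect_equal(unname(coef(m)), c(0.6, 2))
  expect_equal(predict(m, C = 2), 0, tolerance = 1e-12)
  expect_output(print(m), "purity 0.60")
})

test_that("error log-ratio is the absolute segment difference", {
  expect_equal(error_logratio(0.8, 0.5), 0.3)
  expect_equal(error_logratio(-0.8, -0.5), 0.3)
  expect_equal(error_logratio(0.5, 0.5), 0)
})

test_that("classification follows the expected-AF families", {
  # purity-1 diploid het at af 0.5 -> germline
  m <- toy_model(P = 1, C = 2L, M = 1L)
  rec <- passing_record(pos = 100L, af = 0.5, dp_t = 1000)
  call <- classify_variants(rec, m)
  expect_equal(call$label, "germline")

  # af 0.25 at P 0.5 diploid: somatic k=1 expects 0.25, germline het 0.5
  m <- toy_model(P = 0.5, C = 2L, M = 1L)
  call <- classify_variants(passing_record(pos = 100L, af = 0.25, dp_t = 1000), m)
  expect_equal(call$label, "somatic")
  expect_equal(call$expected_af_somatic, 0.25)
  expect_equal(call$expected_af_germline, 0.5)

  # huge error log-ratio -> ambiguous regardless of af (depth far off
  # the sample's bin-normalized expectation)
  recs <- variant_records(data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                                     ref = "A", alt = "G", af = 0.25,
                                     dp_t = c(4000, 1000, 1000),
                                     status = "StrongSomatic"), "tumor_only")
  call <- classify_variants(recs, m)
  expect_gt(call$error_logratio[1], 0.5)
  expect_equal(call$label[1], "ambiguous")
  expect_equal(call$label[2], "somatic")

  # af above 0.9 -> germline outright
  call <- classify_variants(passing_record(pos = 100L, af = 0.97, dp_t = 1000), m)
  expect_equal(call$label, "germline")

  # variant outside all segments errors
  expect_error(classify_variants(passing_record(pos = 99999999L, af = 0.5), m),
               "outside")
})

test_that("classification is deterministic given model and thresholds", {
  m <- toy_model(P = 0.7, C = 3L, M = 1L, psi = 2.2)
  rec <- random_records(50, seed = 77)
  rec$pos <- seq_len(50) * 100L
  rec$af[is.na(rec$af)] <- 0.3
  rec$dp_t[is.na(rec$dp_t)] <- 500
  a <- classify_variants(rec, m)
  b <- classify_variants(rec, m)
  expect_identical(a, b)
})

test_that("degenerate somatic/germline separations defer to library evidence", {
  # LOH segment at purity 0.5: somatic k=1 and het-on-deleted-allele collide
  m <- toy_model(P = 0.5, C = 2L, M = 0L)
  rec <- passing_record(pos = 100L, af = 0.25, dp_t = 1000)
  expect_equal(classify_variants(rec, m)$label, "germline")  # conservative default
  expect_equal(classify_variants(rec, m, in_library = TRUE)$label, "germline")
  expect_equal(classify_variants(rec, m, in_library = FALSE)$label, "somatic")
})

test_that("classification error-log-ratio uses depth normalized like coverage bins", {
  expect_equal(variant_logratio(c(100, 100, 100)), c(0, 0, 0))
  expect_equal(variant_logratio(c(50, 100, 200))[1], -1)
})
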