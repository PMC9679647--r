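# Cutoff determination and clinical statistics.

make_cohort <- function(tmb, dcb, os = NULL, ev = NULL) {
  n <- length(tmb)
  data.frame(patient_id = sprintf("P%d", seq_len(n)), tmb = tmb, dcb = dcb,
             os_months = os %||% rep(12, n), os_event = ev %||% rep(1L, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("DCB derivation matches the response/duration rule exactly", {
  expect_true(derive_dcb("PR"))
  expect_true(derive_dcb("CR"))
  expect_false(derive_dcb("PD"))
  expect_equal(derive_dcb(c("SD", "SD"), c(24, 23)), c(TRUE, FALSE))  # >= 24 boundary
  expect_error(derive_dcb("SD", NA), "sd_duration")
  expect_error(derive_dcb("XX"), "response")
})

test_that("AUC equals brute-force Mann-Whitney pair counting, with symmetries", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))$auc, 1)
  set.seed(41)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    scores <- sample(1:8, n, replace = TRUE)  # ties on purpose
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, auc_bruteforce(scores, labels))
    expect_equal(roc_auc(scores, !labels)$auc, 1 - roc_auc(scores, labels)$auc)
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("ROC sweep reports Youden J per threshold", {
  roc <- roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  row <- roc$sweep[roc$sweep$threshold == 3, ]
  expect_equal(row$sensitivity, 1)
  expect_equal(row$specificity, 1)
  expect_equal(row$youden_j, 1)
})

test_that("log-rank: null on duplicated groups, matches manual statistic and permutations", {
  t0 <- c(3, 5, 8, 12, 20); e0 <- c(1, 1, 0, 1, 1)
  res <- logrank_test(c(t0, t0), c(e0, e0), rep(c(TRUE, FALSE), each = 5))
  expect_equal(res$chisq, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-10)

  set.seed(19)
  times <- c(rexp(20, 1 / 10), rexp(20, 1 / 16))
  events <- rbinom(40, 1, 0.8)
  group <- rep(c(FALSE, TRUE), each = 20)
  res <- logrank_test(times, events, group)
  expect_equal(res$chisq, logrank_stat_manual(times, events, group), tolerance = 1e-8)
  p_perm <- perm_logrank_p(times, events, group, B = 4000)
  expect_lt(abs(res$p - p_perm), 0.05)
  expect_error(logrank_test(times, events, rep(TRUE, 40)), "empty group")
})

test_that("strong simulated separation is detected in almost all replicates", {
  set.seed(77)
  hits <- 0
  for (r in 1:40) {
    g <- rep(c(FALSE, TRUE), each = 30)
    times <- ifelse(g, rexp(60, 1 / 25), rexp(60, 1 / 5))
    if (logrank_test(times, rep(1, 60), g)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("Kaplan-Meier equals empirical survival without censoring", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_true(all(km_curve(c(4, 8), c(0, 0))$surv == 1))
  # hand-computed product-limit with censoring:
  # t=2: 4/5; t=4 (risk 3, 1 event): 4/5*2/3; t=8 censored only
  km <- km_curve(c(2, 4, 4, 6, 8), c(1, 1, 0, 1, 0))
  expect_equal(km$surv[km$time == 2], 0.8)
  expect_equal(km$surv[km$time == 4], 0.8 * 3 / 4, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 6], 0.8 * 3 / 4 * 1 / 2, tolerance = 1e-12)
  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
})

test_that("select_cutoff finds a constructed separation at 7 mut/Mb", {
  tmb <- c(1:6, 7:15)                 # NDB below 7, DCB at 7 and above
  dcb <- tmb >= 7
  cohort <- make_cohort(tmb, dcb, os = ifelse(dcb, 30, 6) + seq_along(tmb) / 10,
                        ev = rep(1L, 15))
  res <- select_cutoff(cohort)
  expect_equal(res$cutoff, 7)
  expect_equal(res$auc, 1)
  expect_equal(res$youden_j, 1)
  expect_false(res$non_informative)
  expect_equal(res$n_high + res$n_low, 15)
  expect_lt(res$logrank_p, 0.01)
})

test_that("exchangeable labels yield a non-informative cutoff flag", {
  set.seed(101)
  tmb <- runif(80, 1, 20)
  cohort <- make_cohort(tmb, sample(c(TRUE, FALSE), 80, replace = TRUE),
                        os = rexp(80, 1 / 12), ev = rbinom(80, 1, 0.8))
  res <- select_cutoff(cohort)
  expect_lt(res$youden_j, 0.25)
  expect_true(res$non_informative || res$youden_j < 0.25)
})

test_that("select_cutoff is invariant to patient order and monotone TMB transforms", {
  set.seed(55)
  tmb <- round(runif(60, 1, 20), 1)
  dcb <- runif(60) < plogis(1.0 * (tmb - 7))
  if (length(unique(dcb)) < 2) dcb[1:2] <- c(TRUE, FALSE)
  cohort <- make_cohort(tmb, dcb, os = rexp(60, 1 / 12), ev = rbinom(60, 1, 0.8))
  res <- select_cutoff(cohort)
  perm <- cohort[sample(60), ]
  expect_equal(select_cutoff(perm)$cutoff, res$cutoff)
  # strictly monotone transform of scores and candidate grid
  g <- function(x) exp(x / 10)
  cohort2 <- cohort; cohort2$tmb <- g(cohort2$tmb)
  res2 <- select_cutoff(cohort2, candidates = g(1:20))
  expect_equal(res2$cutoff, g(res$cutoff))
  expect_equal(res2$auc, res$auc)
})

test_that("degenerate cohorts are rejected", {
  expect_error(select_cutoff(make_cohort(c(1, 1, 1), c(TRUE, FALSE, TRUE))),
               "degenerate")
  expect_error(select_cutoff(make_cohort(seq(2, 18, length.out = 20), rep(TRUE, 20))),
               "degenerate")
})

test_that("Cox regression recovers a simulated hazard ratio and flags bad input", {
  set.seed(61)
  n <- 300
  grp <- rbinom(n, 1, 0.5)
  times <- rexp(n, 0.08 * 2^grp)   # HR 2 for grp = 1
  cens <- rexp(n, 0.02)
  cohort <- data.frame(os_months = pmin(times, cens),
                       os_event = as.integer(times <= cens), grp = grp)
  fit <- cox_multivariate(cohort, "grp")
  expect_true(fit$converged)
  expect_gt(fit$table$upper, 2); expect_lt(fit$table$lower, 2)
  cohort$os_event <- 0L
  expect_error(cox_multivariate(cohort, "grp"), "no events")
})

test_that("a covariate independent of outcome has a CI spanning 1 in most replicates", {
  set.seed(71)
  reps <- 60
  hits <- 0
  for (r in seq_len(reps)) {
    n <- 120
    noise <- rbinom(n, 1, 0.5)
    times <- rexp(n, 0.1)
    cohort <- data.frame(os_months = times, os_event = 1L, noise = noise)
    fit <- cox_multivariate(cohort, "noise")
    if (fit$table$lower < 1 && fit$table$upper > 1) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("Welch t-test behaves on identical, shifted and swapped groups", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_tmb_groups(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(81)
  a <- rnorm(50, 10, 1); b <- rnorm(50, 13, 1)
  expect_lt(compare_tmb_groups(a, b)$p, 0.001)
  expect_equal(compare_tmb_groups(b, a)$t, -compare_tmb_groups(a, b)$t)
  expect_equal(compare_tmb_groups(b, a)$p, compare_tmb_groups(a, b)$p)
  expect_error(compare_tmb_groups(1, x), "n >= 2")
})

test_that("Fisher exact utility matches stats::fisher.test", {
  res <- fisher_rate_test(8, 10, 2, 10)
  ref <- fisher.test(matrix(c(8, 2, 2, 8), 2))
  expect_equal(res$p, ref$p.value)
})
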