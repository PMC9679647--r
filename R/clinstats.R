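# Cutoff determination and clinical statistics: durable-clinical-benefit
# derivation, ROC/Youden sweep, log-rank validation, Kaplan-Meier, Cox
# regression, Welch t and Fisher tests. The survival machinery is
# delegated to the survival package; the ROC sweep and cutoff selection
# are implemented here.

#' Derive durable clinical benefit (DCB)
#'
#' CR or PR, or SD lasting at least 24 weeks, is DCB; SD shorter than 24
#' weeks or PD is NDB.
#'
#' @param response vector in \{CR, PR, SD, PD\}.
#' @param sd_duration_weeks SD duration; required (non-NA) for SD rows.
#' @return logical vector, TRUE = DCB.
#' @export
derive_dcb <- function(response, sd_duration_weeks = NULL) {
  if (!all(response %in% c("CR", "PR", "SD", "PD")))
    stopf("response values must be CR, PR, SD or PD")
  if (is.null(sd_duration_weeks)) sd_duration_weeks <- rep(NA_real_, length(response))
  sd_na <- response == "SD" & is.na(sd_duration_weeks)
  if (any(sd_na)) stopf("SD response without sd_duration_weeks in %d row(s)", sum(sd_na))
  response %in% c("CR", "PR") | (response == "SD" & na_false(sd_duration_weeks >= 24))
}

#' ROC curve and AUC for a continuous score
#'
#' AUC is the Mann-Whitney probability P(score_pos > score_neg) with
#' ties counted 1/2. The sweep evaluates the rule `score >= threshold ->
#' positive` at every distinct score, reporting sensitivity, specificity
#' and Youden J.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels logical class labels.
#' @return list: `auc`, `sweep` data.frame (threshold, sensitivity,
#'   specificity, youden_j).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) sum(labels & scores >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(!labels & scores < t) / n0, numeric(1))
  list(auc = auc,
       sweep = data.frame(threshold = thr, sensitivity = sens, specificity = spec,
                          youden_j = sens + spec - 1))
}

#' One-degree-of-freedom log-rank test
#'
#' @param times survival times (>= 0).
#' @param events event indicators (TRUE/1 = event, FALSE/0 = censored).
#' @param group logical group membership.
#' @return list: `chisq`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.logical(group)
  if (any(times < 0)) stopf("negative survival times")
  if (sum(group) == 0L || sum(!group) == 0L) stopf("empty group")
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  chisq <- as.numeric(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimate
#'
#' With no censoring this equals the empirical survival function.
#'
#' @param times survival times (>= 0).
#' @param events event indicators.
#' @return data.frame: time, n_risk, n_event, surv.
#' @export
km_curve <- function(times, events) {
  if (any(times < 0)) stopf("negative survival times")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Select the TMB cutoff by ROC/Youden with log-rank corroboration
#'
#' The primary criterion maximizes Youden J of the rule `tmb >= cutoff
#' -> DCB` over the candidate grid; ties break toward the smaller
#' cutoff. For each evaluable candidate (both groups of size >= 2) the
#' log-rank statistic on the chosen endpoint is reported; setting
#' `criterion = "logrank"` instead picks the candidate with the largest
#' log-rank statistic (multiplicity of the scan is not corrected —
#' flagged in the result).
#'
#' @param cohort data.frame with tmb, dcb, and the endpoint columns
#'   (os_months/os_event or pfs_months/pfs_event).
#' @param candidates candidate cutoffs (default integers 1..20 mut/Mb).
#' @param endpoint "os" or "pfs".
#' @param criterion "youden" (default) or "logrank".
#' @return `tmb_cutoff` object: cutoff, auc, youden_j, logrank_chisq,
#'   logrank_p, group sizes, the evaluation grid, non_informative flag.
#' @export
select_cutoff <- function(cohort, candidates = 1:20, endpoint = c("os", "pfs"),
                          criterion = c("youden", "logrank")) {
  endpoint <- match.arg(endpoint)
  criterion <- match.arg(criterion)
  stopifnot(all(c("tmb", "dcb") %in% names(cohort)))
  tcol <- paste0(endpoint, "_months"); ecol <- paste0(endpoint, "_event")
  n <- nrow(cohort)
  eval_ok <- vapply(candidates, function(c) {
    hi <- sum(cohort$tmb >= c); hi >= 2L && (n - hi) >= 2L
  }, logical(1))
  if (!any(eval_ok)) stopf("degenerate cohort: no candidate cutoff leaves >= 2 patients per group")
  if (length(unique(cohort$dcb)) < 2L) stopf("degenerate cohort: single DCB class")
  roc <- roc_auc(cohort$tmb, cohort$dcb)
  grid <- data.frame(cutoff = candidates, evaluable = eval_ok)
  grid$sensitivity <- vapply(candidates, function(c)
    sum(cohort$dcb & cohort$tmb >= c) / sum(cohort$dcb), numeric(1))
  grid$specificity <- vapply(candidates, function(c)
    sum(!cohort$dcb & cohort$tmb < c) / sum(!cohort$dcb), numeric(1))
  grid$youden_j <- grid$sensitivity + grid$specificity - 1
  grid$logrank_chisq <- grid$logrank_p <- NA_real_
  has_surv <- all(c(tcol, ecol) %in% names(cohort))
  if (has_surv) {
    for (i in which(eval_ok)) {
      lr <- logrank_test(cohort[[tcol]], cohort[[ecol]], cohort$tmb >= candidates[i])
      grid$logrank_chisq[i] <- lr$chisq
      grid$logrank_p[i] <- lr$p
    }
  }
  pick <- if (criterion == "youden") {
    ok <- which(eval_ok)
    ok[which.max(grid$youden_j[ok])]  # which.max keeps the first (smallest) on ties
  } else {
    ok <- which(eval_ok & !is.na(grid$logrank_chisq))
    ok[which.max(grid$logrank_chisq[ok])]
  }
  cutoff <- candidates[pick]
  out <- list(cutoff = cutoff, auc = roc$auc, youden_j = grid$youden_j[pick],
              logrank_chisq = grid$logrank_chisq[pick], logrank_p = grid$logrank_p[pick],
              n_high = sum(cohort$tmb >= cutoff), n_low = sum(cohort$tmb < cutoff),
              endpoint = endpoint, criterion = criterion, grid = grid,
              roc = roc, non_informative = grid$youden_j[pick] < 0.1)
  class(out) <- "tmb_cutoff"
  out
}

#' @export
print.tmb_cutoff <- function(x, ...) {
  cat(sprintf("TMB cutoff: %g mut/Mb (criterion: %s, endpoint: %s)\n",
              x$cutoff, x$criterion, x$endpoint))
  cat(sprintf("  AUC %.3f, Youden J %.3f; groups: %d high / %d low\n",
              x$auc, x$youden_j, x$n_high, x$n_low))
  if (!is.na(x$logrank_chisq))
    cat(sprintf("  log-rank at cutoff: chisq %.3f, p %.4g\n", x$logrank_chisq, x$logrank_p))
  if (x$non_informative) cat("  WARNING: low Youden J - cutoff is non-informative\n")
  if (x$criterion == "logrank")
    cat("  note: log-rank scan p-values are not corrected for multiplicity\n")
  invisible(x)
}

#' @export
summary.tmb_cutoff <- function(object, ...) {
  print(object)
  cat("Candidate grid:\n")
  print(object$grid, row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
plot.tmb_cutoff <- function(x, ...) {
  sw <- x$roc$sweep
  graphics::plot(1 - sw$specificity, sw$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC %.3f), cutoff %g mut/Mb", x$auc, x$cutoff), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Multivariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; returns hazard
#' ratios with 95% CIs per covariate. Non-convergence is flagged on the
#' result rather than silently ignored.
#'
#' @param cohort data.frame with the endpoint columns and covariates.
#' @param covariates character vector of covariate column names.
#' @param endpoint "os" or "pfs".
#' @return list: `table` (term, hr, lower, upper, p), `converged`.
#' @export
cox_multivariate <- function(cohort, covariates, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_months"); ecol <- paste0(endpoint, "_event")
  n_events <- sum(as.integer(cohort[[ecol]]))
  if (n_events == 0L) stopf("no events in cohort")
  if (n_events < length(covariates))
    stopf("fewer events (%d) than covariates (%d)", n_events, length(covariates))
  fml <- stats::as.formula(paste0("survival::Surv(", tcol, ", as.integer(", ecol, ")) ~ ",
                                  paste(covariates, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = cohort, ties = "efron"),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    hr = s$coefficients[, "exp(coef)"],
                    lower = s$conf.int[, "lower .95"],
                    upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, converged = converged, fit = fit)
}

#' Welch two-sample t-test on TMB values
#'
#' @param tmb_a,tmb_b numeric TMB vectors (each n >= 2).
#' @return list: `t`, `p`, `mean_a`, `mean_b`.
#' @export
compare_tmb_groups <- function(tmb_a, tmb_b) {
  if (length(tmb_a) < 2L || length(tmb_b) < 2L) stopf("each group needs n >= 2")
  tt <- stats::t.test(tmb_a, tmb_b)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_a = mean(tmb_a), mean_b = mean(tmb_b))
}

#' Fisher exact test on a 2x2 response table
#'
#' Two-sided, no mid-p correction. Used for DCB/ORR rate contrasts
#' between TMB groups.
#'
#' @param positive_a,n_a successes and size of group A.
#' @param positive_b,n_b successes and size of group B.
#' @return list: `p`, `odds_ratio`.
#' @export
fisher_rate_test <- function(positive_a, n_a, positive_b, n_b) {
  m <- matrix(c(positive_a, n_a - positive_a, positive_b, n_b - positive_b), nrow = 2)
  ft <- stats::fisher.test(m)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}
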