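# Cohort-level concordance between the paired and tumor-only pipelines.

#' Paired vs tumor-only concordance on a simulated cohort
#'
#' Runs both pipelines on every sample of a simulated cohort (the
#' background library is built from the cohort's normal samples),
#' returning the per-sample TMB vectors, their Pearson correlation, and
#' the pooled recall: the fraction of paired-mode somatic call keys
#' also called somatic by the tumor-only pipeline.
#'
#' @param sim a cohort from [simulate_cohort()].
#' @param lib optional pre-built `background_library`; defaults to one
#'   built from `sim$background`.
#' @return list: `paired_tmb`, `tumor_only_tmb`, `pearson_r`,
#'   `recall_pct`, `n_samples`, `purity` (true, per sample).
#' @export
cohort_concordance <- function(sim, lib = NULL) {
  if (is.null(lib)) lib <- build_library(sim$background)
  n <- length(sim$samples)
  paired_tmb <- tonly_tmb <- numeric(n)
  rec_num <- rec_den <- 0L
  for (i in seq_len(n)) {
    s <- sim$samples[[i]]
    rp <- tmb_paired(s$paired, sim$regions)
    rt <- tmb_tumor_only(s$tumor_only, lib, sim$regions, bins = s$bins)
    paired_tmb[i] <- rp$tmb
    tonly_tmb[i] <- rt$tmb
    pk <- variant_key(rp$calls$chrom, rp$calls$pos, rp$calls$ref, rp$calls$alt)
    tk <- variant_key(rt$calls$chrom, rt$calls$pos, rt$calls$ref, rt$calls$alt)
    rec_num <- rec_num + sum(pk %in% tk)
    rec_den <- rec_den + length(pk)
  }
  list(paired_tmb = paired_tmb, tumor_only_tmb = tonly_tmb,
       pearson_r = stats::cor(paired_tmb, tonly_tmb),
       recall_pct = 100 * rec_num / rec_den,
       n_samples = n,
       purity = vapply(sim$samples, `[[`, numeric(1), "purity"))
}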