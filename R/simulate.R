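# Synthetic tumor/normal cohort simulator with known somatic/germline
# truth: population germline SNPs shared across samples (so the
# background library is informative), private somatic mutations at a
# per-Mb rate, segment-level copy-number states, tumor purity, Poisson
# depths with binomially sampled alt reads, coverage-bin log-ratio
# profiles, and a clinical outcome layer where response and survival
# depend on true TMB.

#' Simulator configuration
#'
#' Defaults emulate a 1.4 Mb targeted panel sequenced at 1027x (tumor) /
#' 455x (normal) mean depth: shared germline sites at population allele
#' frequencies 0.5/0.25/0.1/0.05/0.01 yielding roughly 1500 carrier
#' sites per sample, ~20 private rare germline variants, clonal somatic
#' mutations at a per-sample rate drawn uniformly from 1-30 mut/Mb,
#' purity uniform on 0.4-0.9, and segment copy-number states dominated
#' by diploid-balanced with gains, losses and LOH.
#'
#' @param seed integer RNG seed.
#' @param ... overrides of any default listed above.
#' @return list of configuration values.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_samples = 62L,
    n_background_normals = 100L,
    footprint_mb = 1.4,
    n_segments = 10L,
    bin_bp = 10000L,
    germline_spectrum = data.frame(af = c(0.5, 0.25, 0.1, 0.05, 0.01),
                                   n_sites = c(600L, 700L, 1500L, 2500L, 11000L)),
    n_private_germline = 20L,
    somatic_rate_range = c(1, 30),
    purity_range = c(0.4, 0.9),
    cn_states = data.frame(C = c(2L, 2L, 1L, 3L, 4L, 4L),
                           M = c(1L, 0L, 0L, 1L, 2L, 1L),
                           prob = c(0.60, 0.08, 0.10, 0.14, 0.05, 0.03)),
    depth_tumor = 1027,
    depth_normal = 455,
    lr_noise_sd = 0.1,
    indel_frac = 0.1,
    hotspot_frac = 0.03,
    min_alt_reads = 3L,
    snv_effects = c(missense = 0.55, nonsense = 0.08, splice = 0.05, synonymous = 0.32),
    indel_effects = c(frameshift = 0.7, inframe = 0.2, noncoding = 0.1),
    germline_effects = c(missense = 0.35, synonymous = 0.45, noncoding = 0.20),
    clinical = list(dcb_center = 7, dcb_slope = 1.0, os_hr = 2.5,
                    base_median_os = 10, base_median_pfs = 4, censor_median = 30)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown sim_config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$footprint_mb <= 0) stopf("footprint must be positive")
  cfg
}

BASES <- c("A", "C", "G", "T")

sample_alt <- function(ref_base, n = length(ref_base)) {
  vapply(seq_len(n), function(i) sample(setdiff(BASES, ref_base[i]), 1L), character(1))
}

sample_effect <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Shared catalogue of population germline sites on the panel.
build_catalogue <- function(cfg, L) {
  n_total <- sum(cfg$germline_spectrum$n_sites)
  pos <- sort(sample.int(L, n_total))
  ref <- sample(BASES, n_total, replace = TRUE)
  data.frame(pos = pos, ref = ref, alt = sample_alt(ref),
             pop_af = rep(cfg$germline_spectrum$af, cfg$germline_spectrum$n_sites)[
               sample.int(n_total)],
             effect = sample_effect(n_total, cfg$germline_effects),
             stringsAsFactors = FALSE)
}

#' Simulate a tumor cohort with known truth
#'
#' Produces, per sample, a paired and a tumor-only variant record
#' table, a binned coverage log-ratio profile, and the generative truth
#' (origin, true AF, copy state per variant; purity, ploidy and true
#' TMB per sample); plus a cohort of background normal samples sharing
#' the germline site catalogue, the panel regions, and a clinical table
#' driven by true TMB. Fully reproducible from `cfg$seed`.
#'
#' Observed depths are Poisson around the configured means scaled by
#' local copy mass; alt reads are Binomial(depth, expected AF) with
#' expected AF from the SGZ allele-fraction model given (purity, C, M).
#' Variants with fewer than `min_alt_reads` supporting reads are not
#' "called" (absent from the record tables, present in the truth).
#'
#' @param cfg configuration from [sim_config()].
#' @return list: samples (per-sample list with tumor_only, paired,
#'   bins, purity, ploidy, somatic_rate, true_tmb), background (list of
#'   record tables), truth (data.frame), clinical (data.frame), regions,
#'   catalogue, config.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  L <- as.integer(round(cfg$footprint_mb * 1e6))
  regions <- target_regions("chr1", 1L, L)
  seg_len <- L %/% cfg$n_segments
  seg_start <- (0:(cfg$n_segments - 1L)) * seg_len + 1L
  seg_end <- c(seg_start[-1L] - 1L, L)
  seg_of <- function(pos) pmin(((pos - 1L) %/% seg_len) + 1L, cfg$n_segments)

  cat <- build_catalogue(cfg, L)
  n_cat <- nrow(cat)

  # background normals: HWE genotypes at catalogue sites
  background <- vector("list", cfg$n_background_normals)
  for (b in seq_len(cfg$n_background_normals)) {
    g <- stats::rbinom(n_cat, 2L, cat$pop_af)
    idx <- which(g > 0L)
    dp <- stats::rpois(length(idx), cfg$depth_normal)
    dp[dp < 1L] <- 1L
    alt <- stats::rbinom(length(idx), dp, ifelse(g[idx] == 2L, 1, 0.5))
    called <- alt >= cfg$min_alt_reads
    background[[b]] <- variant_records(data.frame(
      chrom = "chr1", pos = cat$pos[idx][called], ref = cat$ref[idx][called],
      alt = cat$alt[idx][called], status = "Germline", af = alt[called] / dp[called],
      vd = alt[called], dp_t = dp[called], effect = cat$effect[idx][called],
      stringsAsFactors = FALSE), mode = "tumor_only")
  }

  samples <- vector("list", cfg$n_samples)
  truth_rows <- list()
  for (i in seq_len(cfg$n_samples)) {
    P <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
    rate <- stats::runif(1, cfg$somatic_rate_range[1], cfg$somatic_rate_range[2])
    st <- sample(nrow(cfg$cn_states), cfg$n_segments, replace = TRUE, prob = cfg$cn_states$prob)
    segC <- cfg$cn_states$C[st]
    segM <- cfg$cn_states$M[st]
    psi <- mean(segC)
    den_psi <- P * psi + 2 * (1 - P)

    # germline: catalogue carriers + private rare variants
    g <- stats::rbinom(n_cat, 2L, cat$pop_af)
    gidx <- which(g > 0L)
    gl <- data.frame(pos = cat$pos[gidx], ref = cat$ref[gidx], alt = cat$alt[gidx],
                     effect = cat$effect[gidx], zyg = ifelse(g[gidx] == 2L, "hom", "het"),
                     stringsAsFactors = FALSE)
    free_pos <- setdiff(seq_len(L), cat$pos)
    priv_pos <- sample(free_pos, cfg$n_private_germline)
    priv_ref <- sample(BASES, cfg$n_private_germline, replace = TRUE)
    gl <- rbind(gl, data.frame(
      pos = priv_pos, ref = priv_ref, alt = sample_alt(priv_ref),
      effect = sample_effect(cfg$n_private_germline, cfg$germline_effects),
      zyg = sample(c("het", "hom"), cfg$n_private_germline, TRUE, prob = c(0.9, 0.1)),
      stringsAsFactors = FALSE))
    gl$origin <- "germline"
    gl$hotspot <- "."

    # somatic: private clonal mutations (k = 1 mutated copy)
    n_som <- stats::rpois(1, rate * cfg$footprint_mb)
    som_pos <- sample(setdiff(free_pos, gl$pos), n_som)
    is_indel <- stats::runif(n_som) < cfg$indel_frac
    som_ref <- sample(BASES, n_som, replace = TRUE)
    som_alt <- sample_alt(som_ref, n_som)
    # deletions: REF gains one base, ALT is the anchor
    som_alt[is_indel] <- som_ref[is_indel]
    som_ref[is_indel] <- paste0(som_ref[is_indel],
                                sample(BASES, sum(is_indel), replace = TRUE))
    som_eff <- character(n_som)
    som_eff[!is_indel] <- sample_effect(sum(!is_indel), cfg$snv_effects)
    som_eff[is_indel] <- sample_effect(sum(is_indel), cfg$indel_effects)
    som <- data.frame(pos = som_pos, ref = som_ref, alt = som_alt, effect = som_eff,
                      zyg = rep("somatic", n_som), origin = rep("somatic", n_som),
                      hotspot = ifelse(stats::runif(n_som) < cfg$hotspot_frac, "hs", "."),
                      stringsAsFactors = FALSE)

    v <- rbind(gl, som)
    v <- v[order(v$pos), , drop = FALSE]
    seg <- seg_of(v$pos)
    C <- segC[seg]; M <- segM[seg]
    den_c <- P * C + 2 * (1 - P)
    m_alt <- ifelse(stats::runif(nrow(v)) < 0.5, M, C - M)  # het: alt on minor or major
    true_af <- ifelse(v$zyg == "hom", 1,
                      ifelse(v$zyg == "het", (P * m_alt + (1 - P)) / den_c,
                             P / den_c))
    dp_t <- stats::rpois(nrow(v), cfg$depth_tumor * den_c / den_psi)
    dp_t[dp_t < 1L] <- 1L
    alt_t <- stats::rbinom(nrow(v), dp_t, true_af)
    dp_n <- stats::rpois(nrow(v), cfg$depth_normal)
    dp_n[dp_n < 1L] <- 1L
    alt_n <- stats::rbinom(nrow(v), dp_n,
                           ifelse(v$zyg == "hom", 1, ifelse(v$zyg == "het", 0.5, 0)))

    called <- alt_t >= cfg$min_alt_reads
    base <- data.frame(
      chrom = "chr1", pos = v$pos, ref = v$ref, alt = v$alt,
      hotspot = v$hotspot, effect = v$effect,
      sor = 0, vd = alt_t, af = alt_t / dp_t, ssf = 0.001,
      fpdb = ".", germline = ".", msi = 0, msilen = 1,
      pmean_t = 35, mq_t = 60, qual_t = 38, nm_t = 1, dp_t = dp_t,
      bias_t = "2;2", sbf_t = 0.6, vds_t = alt_t,
      stringsAsFactors = FALSE)[called, , drop = FALSE]
    tumor_only <- variant_records(cbind(base, status = "StrongSomatic"),
                                  mode = "tumor_only")
    paired <- variant_records(cbind(
      base, status = ifelse(v$origin[called] == "somatic", "StrongSomatic", "Germline"),
      pmean_n = 35, mq_n = 60, qual_n = 38, nm_n = 1, dp_n = dp_n[called],
      bias_n = "2;2", sbf_n = 0.6, vds_n = alt_n[called]), mode = "paired")

    # coverage bins
    bin_start <- seq(1L, L, by = cfg$bin_bp)
    bin_end <- pmin(bin_start + cfg$bin_bp - 1L, L)
    bC <- segC[seg_of(bin_start)]
    bins <- data.frame(chrom = "chr1", start = bin_start, end = bin_end,
                       logratio = log2((P * bC + 2 * (1 - P)) / den_psi) +
                         stats::rnorm(length(bin_start), 0, cfg$lr_noise_sd),
                       stringsAsFactors = FALSE)

    true_nonsyn <- (variant_type(v$ref, v$alt) == "snp" &
                      v$effect %in% c("missense", "nonsense", "splice")) |
      (variant_type(v$ref, v$alt) == "indel" & v$effect %in% c("frameshift", "inframe"))
    true_tmb <- sum(v$origin == "somatic" & true_nonsyn) / cfg$footprint_mb

    truth_rows[[i]] <- data.frame(
      sample = i, key = variant_key("chr1", v$pos, v$ref, v$alt),
      origin = v$origin, true_af = true_af, C = C, M = M, called = called,
      purity = P, ploidy = psi, true_tmb = true_tmb, stringsAsFactors = FALSE)
    samples[[i]] <- list(tumor_only = tumor_only, paired = paired, bins = bins,
                         purity = P, ploidy = psi, somatic_rate = rate,
                         true_tmb = true_tmb)
  }
  truth <- do.call(rbind, truth_rows)
  clinical <- simulate_clinical(vapply(samples, `[[`, numeric(1), "true_tmb"),
                                cfg$clinical)
  list(samples = samples, background = background, truth = truth,
       clinical = clinical, regions = regions, catalogue = cat, config = cfg)
}

#' Simulate a clinical outcome layer driven by TMB
#'
#' DCB ~ Bernoulli(logistic(slope * (tmb - center))); responses are
#' drawn consistently with the DCB label (CR/PR/long SD vs short SD/PD).
#' OS and PFS are exponential with the configured hazard ratio between
#' the TMB >= center and < center groups, independently censored by an
#' exponential clock.
#'
#' @param tmb numeric TMB values (one patient each).
#' @param layer list with dcb_center, dcb_slope, os_hr, base_median_os,
#'   base_median_pfs, censor_median (see [sim_config()]).
#' @param seed optional seed; NULL uses the current RNG state.
#' @return clinical data.frame in the package's standard schema, plus
#'   the derived `dcb` column.
#' @export
simulate_clinical <- function(tmb, layer = sim_config()$clinical, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tmb)
  p_dcb <- stats::plogis(layer$dcb_slope * (tmb - layer$dcb_center))
  dcb <- stats::runif(n) < p_dcb
  response <- character(n)
  sd_dur <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (dcb[i]) {
      response[i] <- sample(c("CR", "PR", "SD"), 1L, prob = c(0.08, 0.52, 0.40))
      if (response[i] == "SD") sd_dur[i] <- 24 + stats::rexp(1, 1 / 20)
    } else {
      response[i] <- sample(c("SD", "PD"), 1L, prob = c(0.3, 0.7))
      if (response[i] == "SD") sd_dur[i] <- stats::runif(1, 4, 23.9)
    }
  }
  high <- tmb >= layer$dcb_center
  draw_surv <- function(base_median) {
    rate <- log(2) / ifelse(high, base_median * layer$os_hr, base_median)
    t_ev <- stats::rexp(n, rate)
    t_cn <- stats::rexp(n, log(2) / layer$censor_median)
    list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
  }
  os <- draw_surv(layer$base_median_os)
  pfs <- draw_surv(layer$base_median_pfs)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)), tmb = tmb,
             response = response, sd_duration_weeks = sd_dur,
             os_months = os$time, os_event = os$event,
             pfs_months = pfs$time, pfs_event = pfs$event,
             age = round(stats::runif(n, 35, 80)),
             gender = sample(c("M", "F"), n, replace = TRUE),
             drug = sample(c("pembrolizumab", "nivolumab", "atezolizumab"), n, TRUE),
             cancer_type = sample(c("LUAD", "LUSC", "other"), n, TRUE,
                                  prob = c(0.5, 0.3, 0.2)),
             dcb = dcb, stringsAsFactors = FALSE)
}

# Artifact templates: a baseline record that passes every filter, then
# one tag perturbed per named clause so that exactly that clause fires.
artifact_registry <- function() {
  list(
    basic_len     = list(ref = paste(rep("A", 60), collapse = "")),
    basic_status  = list(status = "Germline"),
    hs_sor        = list(hotspot = "hs", sor = 2),
    hs_vd         = list(hotspot = "hs", vd = 4),
    hs_af         = list(hotspot = "hs", af = 0.006),
    hs_ssf        = list(hotspot = "hs", ssf = 0.06),
    fpdb_tag      = list(fpdb = "3"),
    germline_tag  = list(germline = "0"),
    pmean_lt_20   = list(pmean_t = 10),
    weak_support  = list(ssf = 0.02),
    af_mq_50      = list(af = 0.04, mq_t = 49),
    mq_lt_30      = list(mq_t = 25),
    af_qual_30    = list(af = 0.04, qual_t = 25),
    msi_low_af    = list(msi = 11, af = 0.25),
    msi_indel     = list(ref = "AT", alt = "A", msi = 4, msilen = 1, af = 0.08),
    nm2_mq60_af   = list(nm_t = 3, mq_t = 59, af = 0.15),
    nm3_mq55      = list(nm_t = 4, mq_t = 54),
    dp_lt_30      = list(dp_t = 25, vd = 20, vds_t = 20),
    vd_lt_10      = list(vd = 9),
    strand_bias   = list(bias_t = "2;1"),
    sbf_vd_50     = list(sbf_t = 0.01, vds_t = 40),
    sor10_mq60    = list(sor = 9, mq_t = 59)
  )
}

#' A record passing every filter clause
#'
#' Baseline used by [inject_artifacts()] and the test suite: somatic
#' status, non-hotspot, comfortable support and quality tags.
#'
#' @param pos position (also varied to keep keys unique).
#' @param mode record mode.
#' @param ... field overrides.
#' @return single-row variant record table.
#' @export
passing_record <- function(pos = 1000L, mode = "tumor_only", ...) {
  base <- list(chrom = "chr1", pos = pos, ref = "A", alt = "G",
               status = "StrongSomatic", hotspot = ".", fpdb = ".", germline = ".",
               effect = "missense", sor = 0, vd = 60, af = 0.35, ssf = 0.001,
               msi = 0, msilen = 1, pmean_t = 35, mq_t = 60, qual_t = 38,
               nm_t = 1, dp_t = 200, bias_t = "2;2", sbf_t = 0.5, vds_t = 60)
  if (mode == "paired") {
    base <- c(base, list(pmean_n = 35, mq_n = 60, qual_n = 38, nm_n = 1,
                         dp_n = 200, bias_n = "2;2", sbf_n = 0.6, vds_n = 0))
  }
  over <- list(...)
  base[names(over)] <- over
  variant_records(as.data.frame(base, stringsAsFactors = FALSE), mode = mode)
}

#' Inject filter-trippable artifact records
#'
#' For every named clause, appends one record that fails that clause
#' and only that clause (built from the passing baseline).
#'
#' @param records variant record table to extend.
#' @param clauses character vector of clause names; see
#'   `names(tmbforge:::artifact_registry())`.
#' @return list: `records` (input plus artifacts), `log` (data.frame
#'   clause/key of each injected record).
#' @export
inject_artifacts <- function(records, clauses) {
  reg <- artifact_registry()
  unknown <- setdiff(clauses, names(reg))
  if (length(unknown)) stopf("unknown artifact clause(s): %s", paste(unknown, collapse = ", "))
  if (length(clauses) == 0L) {
    return(list(records = records,
                log = data.frame(clause = character(0), key = character(0))))
  }
  mode <- records_mode(records)
  base_pos <- if (nrow(records)) max(records$pos) else 0L
  added <- list(); keys <- character(length(clauses))
  for (j in seq_along(clauses)) {
    ov <- reg[[clauses[j]]]
    rec <- do.call(passing_record, c(list(pos = base_pos + 10L * j, mode = mode), ov))
    keys[j] <- variant_key(rec$chrom, rec$pos, rec$ref, rec$alt)
    added[[j]] <- rec
  }
  out <- do.call(rbind, c(list(records), added))
  attr(out, "mode") <- mode
  list(records = out, log = data.frame(clause = clauses, key = keys,
                                       stringsAsFactors = FALSE))
}

#' Write a simulated cohort to disk
#'
#' Emits per-sample tumor-only and paired VCFs, background normal VCFs,
#' coverage bin TSVs, the panel BED, the truth table and the clinical
#' table under `dir`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sim$samples)) {
    s <- sim$samples[[i]]
    write_variants(s$tumor_only, file.path(dir, sprintf("sample%02d_tumor_only.vcf", i)))
    write_variants(s$paired, file.path(dir, sprintf("sample%02d_paired.vcf", i)))
    utils::write.table(s$bins, file.path(dir, sprintf("sample%02d_bins.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (b in seq_along(sim$background)) {
    write_variants(sim$background[[b]], file.path(dir, sprintf("normal%03d.vcf", b)))
  }
  gr <- sim$regions$gr
  writeLines(paste(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), sep = "\t"),
             file.path(dir, "panel.bed"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
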