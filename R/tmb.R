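# Tumor mutational burden: nonsynonymous somatic SNVs plus coding
# indels per megabase of examined panel footprint, in paired and
# tumor-only (filters -> SGZ -> background filter) pipelines.

new_tmb_result <- function(n_mutations, footprint_mb, mode, stages = NULL, calls = NULL) {
  out <- list(n_mutations = n_mutations, footprint_mb = footprint_mb,
              tmb = n_mutations / footprint_mb, mode = mode,
              stages = stages, calls = calls)
  class(out) <- "tmb_result"
  out
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf("TMB (%s): %.3f mut/Mb  (%d qualifying mutation(s) / %.4f Mb)\n",
              x$mode, x$tmb, x$n_mutations, x$footprint_mb))
  if (!is.null(x$stages)) {
    cat("  records per stage: ",
        paste(sprintf("%s=%d", names(x$stages), unlist(x$stages)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compute TMB from a filtered somatic call set
#'
#' Counts records that are nonsynonymous (see [is_nonsynonymous()]) and
#' fall inside the target regions, divided by the footprint in Mb.
#'
#' @param records variant record table of somatic calls.
#' @param regions `target_regions`.
#' @param mode label recorded on the result.
#' @param count_hotspots if FALSE, hotspot-tagged variants are excluded
#'   from the count (some assays drop known drivers from TMB).
#' @return `tmb_result`.
#' @export
compute_tmb <- function(records, regions, mode = "tumor_only", count_hotspots = TRUE) {
  stopifnot(inherits(regions, "target_regions"))
  if (regions$footprint_mb <= 0) stopf("panel footprint must be positive")
  qual <- is_nonsynonymous(records) & in_regions(records, regions)
  if (!count_hotspots) qual <- qual & !is_hotspot(records)
  new_tmb_result(sum(qual), regions$footprint_mb, mode)
}

#' Paired-mode TMB
#'
#' Runs the false-positive filter cascade on matched tumor/normal
#' records (the caller's somatic status plus the filters remove
#' germline) and computes TMB over the panel.
#'
#' @param records paired-mode variant record table.
#' @param regions `target_regions`.
#' @param ... passed to [compute_tmb()].
#' @return `tmb_result` with mode "paired" and the surviving call set in
#'   `$calls`.
#' @export
tmb_paired <- function(records, regions, ...) {
  if (records_mode(records) != "paired") stopf("tmb_paired() needs paired-mode records")
  flt <- apply_filters(records)
  res <- compute_tmb(flt$kept, regions, mode = "paired", ...)
  res$stages <- list(input = nrow(records), post_filter = nrow(flt$kept))
  res$calls <- flt$kept
  res
}

#' Tumor-only TMB via the optimized SGZ pipeline
#'
#' Composition: false-positive filters -> SGZ somatic/germline
#' classification -> background-library filter -> TMB on records
#' labeled somatic. The tumor model is either supplied, or fitted here
#' from the sample's coverage bins (putative germline het SNPs for the
#' allele-fraction term are taken as filtered variants present in the
#' background library with AF in (0.1, 0.9)).
#'
#' @param records tumor-only variant record table.
#' @param lib `background_library`.
#' @param regions `target_regions`.
#' @param model fitted `tumor_model`, or NULL to fit from `bins`.
#' @param bins coverage bin data.frame (chrom, start, end, logratio),
#'   required when `model` is NULL.
#' @param purity optional known tumor purity; when given, the grid
#'   search is constrained to it (e.g. a histology estimate).
#' @param tau_af,tau_lr,af_germline classifier thresholds
#'   (see [classify_variants()]).
#' @param policy,max_count,af_retain background-filter policy
#'   (see [background_filter()]).
#' @param ... passed to [compute_tmb()].
#' @return `tmb_result` with mode "tumor_only", per-stage record counts
#'   in `$stages`, the final somatic call set in `$calls`, and the
#'   fitted model in `$model`.
#' @export
tmb_tumor_only <- function(records, lib, regions, model = NULL, bins = NULL,
                           purity = NULL,
                           tau_af = 0.1, tau_lr = 0.5, af_germline = 0.9,
                           policy = "literal", max_count = 5L, af_retain = 0.9, ...) {
  if (records_mode(records) != "tumor_only") stopf("tmb_tumor_only() needs tumor-only records")
  flt <- apply_filters(records)
  kept <- flt$kept
  center_lr <- 0
  if (is.null(model)) {
    if (is.null(bins)) stopf("supply either a fitted model or coverage bins")
    segs <- segment_coverage(bins)
    center_lr <- stats::median(bins$logratio)
    in_lib <- library_counts(lib, kept) >= 1L
    het_like <- in_lib & na_false(kept$af > 0.1 & kept$af < 0.9)
    segs <- refine_segments_af(segs, bins, kept$pos[het_like], kept$af[het_like],
                               het_chrom = kept$chrom[het_like])
    seg_idx <- assign_segments(kept, segs)
    snp_af <- lapply(seq_len(nrow(segs)), function(s) kept$af[het_like & seg_idx == s])
    model <- if (is.null(purity)) fit_purity_ploidy(segs, snp_af) else
      fit_purity_ploidy(segs, snp_af, P_grid = purity)
    if (is.null(purity) && !model$identifiable) {
      # copy-number-flat genome: recover purity from the somatic AF cluster
      p_af <- estimate_purity_af(kept, lib)
      if (!is.na(p_af)) {
        model$purity <- p_af
        model$purity_source <- "af_cluster"
      }
    }
  } else if (!is.null(bins)) {
    center_lr <- stats::median(bins$logratio)
  }
  calls <- classify_variants(kept, model, tau_af = tau_af, tau_lr = tau_lr,
                             af_germline = af_germline,
                             in_library = library_counts(lib, kept) > 0L,
                             center_lr = center_lr)
  somatic <- keep_records(kept, calls$label == "somatic")
  bg <- background_filter(somatic, lib, policy = policy,
                          max_count = max_count, af_retain = af_retain)
  res <- compute_tmb(bg$kept, regions, mode = "tumor_only", ...)
  res$stages <- list(input = nrow(records), post_filter = nrow(kept),
                     somatic = nrow(somatic), post_background = nrow(bg$kept))
  res$calls <- bg$kept
  res$model <- model
  res
}
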