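# Somatic-germline-zygosity (SGZ) core: the copy-number log-ratio
# model, coverage segmentation, purity/ploidy grid-search fit, and the
# somatic-vs-germline classifier for tumor-only variants.
#
# Model: a specimen with tumor purity P and tumor ploidy Psi, where a
# locus has integer total copy number C in the tumor cells (and 2 in
# admixed normal cells), has expected coverage log-ratio
#   log2( (P*C + 2*(1-P)) / (P*Psi + 2*(1-P)) ).
# An allele present on m of the C tumor copies and g of the 2 normal
# copies has expected allele fraction (P*m + g*(1-P)) / (P*C + 2*(1-P));
# germline het g = 1, germline hom g = 2, somatic g = 0.

#' Expected coverage log-ratio under the purity/ploidy model
#'
#' @param P tumor purity in (0, 1].
#' @param C integer total copy number (>= 0); vectorized.
#' @param psi tumor ploidy (> 0).
#' @return log2 ratio; 0 when C == psi, -Inf for C = 0 at P = 1.
#' @export
expected_logratio <- function(P, C, psi) {
  stopifnot(P > 0, P <= 1, psi > 0)
  denom <- P * psi + 2 * (1 - P)
  log2((P * C + 2 * (1 - P)) / denom)
}

# Expected allele fractions at a locus with total copy number C.
expected_af_germline_het <- function(P, m, C) (P * m + (1 - P)) / (P * C + 2 * (1 - P))
expected_af_germline_hom <- function(P, m, C) (P * m + 2 * (1 - P)) / (P * C + 2 * (1 - P))
expected_af_somatic <- function(P, k, C) (P * k) / (P * C + 2 * (1 - P))

#' Segment a binned coverage log-ratio profile
#'
#' Least-squares binary segmentation with a BIC stopping rule, applied
#' per chromosome: the split maximizing the residual-sum-of-squares
#' reduction is accepted while it lowers
#' n*log(RSS/n) + penalty * k * log(n).
#'
#' @param bins data.frame with chrom, start, end, logratio, sorted by
#'   coordinate within chromosome.
#' @param min_bins smallest allowed segment, in bins.
#' @param penalty BIC penalty multiplier.
#' @return data.frame of segments: chrom, start, end, n_bins,
#'   observed_logratio (mean of member bins).
#' @export
segment_coverage <- function(bins, min_bins = 3L, penalty = 2) {
  stopifnot(is.data.frame(bins))
  if (nrow(bins) == 0L) stopf("no coverage bins supplied")
  need <- c("chrom", "start", "end", "logratio")
  if (!all(need %in% names(bins))) stopf("bins need columns %s", paste(need, collapse = ", "))
  out <- lapply(split(bins, bins$chrom), function(b) {
    b <- b[order(b$start), , drop = FALSE]
    cuts <- bs_segment(b$logratio, min_bins = min_bins, penalty = penalty)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, nrow(b))
    data.frame(chrom = b$chrom[1], start = b$start[starts], end = b$end[ends],
               n_bins = ends - starts + 1L,
               observed_logratio = vapply(seq_along(starts), function(i)
                 mean(b$logratio[starts[i]:ends[i]]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Exact least-squares changepoint partitioning of one vector (optimal
# partitioning dynamic program): minimizes sum of segment RSS plus
# penalty * log(n) * sigma^2 per extra segment, where sigma is a robust
# noise estimate from successive differences. Greedy binary splitting
# can miss changepoints in alternating up/down profiles; the exact DP
# cannot. Returns sorted breakpoints (index of the last element of each
# left part). O(n^2), fine at panel scale.
bs_segment <- function(x, min_bins, penalty) {
  n <- length(x)
  if (n < 2L * min_bins) return(integer(0))
  d <- diff(x)
  sig2 <- (stats::mad(d) / sqrt(2))^2
  if (!is.finite(sig2) || sig2 <= 0) sig2 <- stats::var(x) / n
  if (!is.finite(sig2) || sig2 <= 0) return(integer(0))
  beta <- penalty * log(n) * sig2
  cs <- c(0, cumsum(x)); cq <- c(0, cumsum(x^2))
  rss <- function(i, j) {  # segment (i+1)..j, i vectorized
    len <- j - i
    cq[j + 1L] - cq[i + 1L] - (cs[j + 1L] - cs[i + 1L])^2 / len
  }
  F <- rep(Inf, n + 1L); F[1L] <- -beta
  prev <- integer(n + 1L)
  for (j in min_bins:n) {
    iv <- 0:(j - min_bins)
    iv <- iv[iv == 0L | iv >= min_bins]
    iv <- iv[is.finite(F[iv + 1L])]
    if (!length(iv)) next
    vals <- F[iv + 1L] + rss(iv, j) + beta
    k <- which.min(vals)
    F[j + 1L] <- vals[k]
    prev[j + 1L] <- iv[k]
  }
  cuts <- integer(0)
  j <- n
  while (j > 0L) {
    i <- prev[j + 1L]
    if (i > 0L) cuts <- c(i, cuts)
    j <- i
  }
  cuts
}

#' Refine coverage segments on heterozygous-SNP allele fractions
#'
#' Coverage-only segmentation cannot separate regions with the same
#' total copy number but different minor-allele counts (e.g. balanced
#' diploid vs copy-neutral LOH). This pass splits each coverage segment
#' at changepoints of the folded het-SNP allele fraction (same binary
#' segmentation and BIC rule as [segment_coverage()]), recomputing each
#' sub-segment's observed log-ratio from its member bins.
#'
#' @param segments data.frame from [segment_coverage()].
#' @param bins the coverage bins the segments were built from.
#' @param het_pos,het_af positions and allele fractions of putative
#'   germline heterozygous SNPs.
#' @param het_chrom chromosome of each het SNP; NULL if all on the
#'   segments' (single) chromosome.
#' @param min_snps smallest allowed sub-segment, in SNPs.
#' @param penalty BIC penalty multiplier.
#' @return data.frame of (possibly split) segments.
#' @export
refine_segments_af <- function(segments, bins, het_pos, het_af, het_chrom = NULL,
                               min_snps = 10L, penalty = 3) {
  if (is.null(het_chrom)) het_chrom <- rep(segments$chrom[1], length(het_pos))
  ord <- order(het_chrom, het_pos)
  het_pos <- het_pos[ord]; het_af <- het_af[ord]; het_chrom <- het_chrom[ord]
  folded <- pmin(het_af, 1 - het_af)
  out <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    inside <- which(het_chrom == seg$chrom & het_pos >= seg$start & het_pos <= seg$end)
    cuts <- if (length(inside) >= 2L * min_snps)
      bs_segment(folded[inside], min_bins = min_snps, penalty = penalty) else integer(0)
    bounds <- c(seg$start,
                if (length(cuts)) floor((het_pos[inside][cuts] +
                                           het_pos[inside][cuts + 1L]) / 2),
                seg$end)
    for (j in seq_len(length(bounds) - 1L)) {
      lo <- if (j == 1L) bounds[1] else bounds[j] + 1L
      hi <- bounds[j + 1L]
      bsel <- bins$chrom == seg$chrom & bins$start >= lo & bins$start <= hi
      out[[length(out) + 1L]] <- data.frame(
        chrom = seg$chrom, start = lo, end = hi,
        n_bins = max(1L, sum(bsel)),
        observed_logratio = if (any(bsel)) mean(bins$logratio[bsel]) else
          seg$observed_logratio,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit tumor purity and ploidy by grid search
#'
#' Scans P in \{0.05..1.00 by 0.01\} x Psi in \{1.0..6.0 by 0.05\}. For
#' each candidate, every segment is assigned the integer copy state
#' (C, M) minimizing the squared log-ratio error plus the squared error
#' of the heterozygous-SNP allele fractions against the nearer of the
#' two allele-configuration expectations (alt on the minor or the major
#' allele), (P*m + (1-P)) / (P*C + 2*(1-P)) for m in \{M, C-M\}. The
#' unfolded form avoids the downward bias that folding (mirroring)
#' allele fractions induces at balanced segments. The
#' bin-weighted objective's argmin is returned; ties break toward lower
#' C (parsimony), then lower P and Psi. After the scan, ploidy is
#' refined once to the length-weighted mean of the assigned C. A flat
#' profile (all segments diploid-balanced-like) is flagged
#' `identifiable = FALSE` and returned at the configured default purity
#' rather than an arbitrary argmin.
#'
#' @param segments data.frame from [segment_coverage()] (columns chrom,
#'   start, end, observed_logratio; optional n_bins weights).
#' @param snp_af list (one element per segment) of observed allele
#'   fractions of putative germline heterozygous SNPs, or NULL.
#' @param P_grid,psi_grid candidate grids.
#' @param C_max largest copy number considered.
#' @param af_weight weight of the allele-fraction term relative to the
#'   log-ratio term.
#' @param psi_prior_weight weight of a near-diploid ploidy prior,
#'   `psi_prior_weight * (psi - 2)^2`, added to the objective. The
#'   whole-genome-doubled solution (2C, 2M, 2*psi at a compensating
#'   purity) reproduces segment log-ratios and het allele fractions
#'   almost exactly, so the data alone cannot resolve it; the prior
#'   breaks the tie toward the lower-ploidy solution. Set to 0 to
#'   disable.
#' @param cn_prior_weight weight of a per-segment aberrant-state prior,
#'   `cn_prior_weight * (C - 2)^2`. At low candidate purity the integer
#'   copy levels lie arbitrarily close in log-ratio space, so a
#'   low-purity solution can absorb log-ratio noise by assigning
#'   far-from-diploid states; a genuinely aberrant segment carries a
#'   log-ratio signal that dwarfs the penalty.
#' @param c0_penalty additional objective penalty for assigning a segment C = 0.
#'   At low purity a homozygously deleted segment is indistinguishable
#'   from diploid (only admixed normal DNA is observed: AF 0.5 and a
#'   modest log-ratio drop), which opens a spurious low-purity solution
#'   with most of the genome deleted; biologically, homozygous
#'   deletions are rare and focal. A true deletion with a strong
#'   negative log-ratio still overcomes the penalty.
#' @param default_purity purity reported for unidentifiable fits.
#' @return An object of class `tumor_model`: purity, ploidy, segments
#'   (with fitted C, M and expected_logratio), fit_score, identifiable.
#' @export
fit_purity_ploidy <- function(segments, snp_af = NULL,
                              P_grid = seq(0.05, 1.00, by = 0.01),
                              psi_grid = seq(1.0, 6.0, by = 0.05),
                              C_max = 8L, af_weight = 1,
                              psi_prior_weight = 0.002, cn_prior_weight = 0.003,
                              c0_penalty = 0.05, default_purity = 0.5) {
  stopifnot(nrow(segments) >= 1L)
  lr <- segments$observed_logratio
  w <- if ("n_bins" %in% names(segments)) segments$n_bins else rep(1, nrow(segments))
  w <- w / sum(w)
  S <- nrow(segments)
  if (is.null(snp_af)) snp_af <- rep(list(numeric(0)), S)
  stopifnot(length(snp_af) == S)

  # flat-profile degeneracy: nothing distinguishes purity
  af_flat <- all(vapply(snp_af, function(a)
    length(a) == 0L || abs(mean(pmin(a, 1 - a)) - 0.5) < 0.05, logical(1)))
  if (max(abs(lr - mean(lr))) < 0.05 && af_flat) {
    segs <- segments
    segs$C <- 2L; segs$M <- 1L
    segs$expected_logratio <- 0
    out <- list(purity = default_purity, ploidy = 2, segments = segs,
                fit_score = NA_real_, identifiable = FALSE)
    class(out) <- "tumor_model"
    return(out)
  }

  # (C, M) state table, ordered by C then M so ties pick the lowest C
  states <- do.call(rbind, lapply(0:C_max, function(C)
    data.frame(C = C, M = 0:(C %/% 2))))
  best <- list(score = Inf)
  for (P in P_grid) {
    den_c <- P * states$C + 2 * (1 - P)
    # AF error per segment x state is independent of psi
    e1 <- (P * states$M + (1 - P)) / den_c
    e2 <- (P * (states$C - states$M) + (1 - P)) / den_c
    af_err <- matrix(0, S, nrow(states))
    for (s in seq_len(S)) {
      if (length(snp_af[[s]])) {
        a <- snp_af[[s]]
        af_err[s, ] <- vapply(seq_len(nrow(states)), function(k)
          mean(pmin((a - e1[k])^2, (a - e2[k])^2)), numeric(1))
      }
    }
    af_err[!is.finite(af_err)] <- Inf
    num <- log2(den_c)  # log2(P*C + 2(1-P))
    state_pen <- cn_prior_weight * (states$C - 2)^2 + ifelse(states$C == 0L, c0_penalty, 0)
    for (psi in psi_grid) {
      e_lr <- num - log2(P * psi + 2 * (1 - P))
      err <- outer(lr, e_lr, function(o, e) (o - e)^2) + af_weight * af_err +
        rep(state_pen, each = S)
      pick <- max.col(-err, ties.method = "first")
      score <- sum(w * err[cbind(seq_len(S), pick)]) +
        psi_prior_weight * (psi - 2)^2
      if (score < best$score - 1e-12) {
        best <- list(score = score, P = P, psi = psi, pick = pick)
      }
    }
  }
  # refine psi to the bin-weighted mean assigned C, re-assign states once
  P <- best$P
  psi <- sum(w * states$C[best$pick])
  psi <- max(psi, 0.5)
  den_c <- P * states$C + 2 * (1 - P)
  e1 <- (P * states$M + (1 - P)) / den_c
  e2 <- (P * (states$C - states$M) + (1 - P)) / den_c
  af_err <- matrix(0, S, nrow(states))
  for (s in seq_len(S)) {
    if (length(snp_af[[s]])) {
      a <- snp_af[[s]]
      af_err[s, ] <- vapply(seq_len(nrow(states)), function(k)
        mean(pmin((a - e1[k])^2, (a - e2[k])^2)), numeric(1))
    }
  }
  af_err[!is.finite(af_err)] <- Inf
  e_lr_states <- log2(den_c) - log2(P * psi + 2 * (1 - P))
  err <- outer(lr, e_lr_states, function(o, e) (o - e)^2) + af_weight * af_err +
    rep(cn_prior_weight * (states$C - 2)^2 +
          ifelse(states$C == 0L, c0_penalty, 0), each = S)
  pick <- max.col(-err, ties.method = "first")
  score <- sum(w * err[cbind(seq_len(S), pick)]) + psi_prior_weight * (psi - 2)^2

  segs <- segments
  segs$C <- states$C[pick]
  segs$M <- states$M[pick]
  segs$expected_logratio <- e_lr_states[pick]
  out <- list(purity = P, ploidy = psi, segments = segs,
              fit_score = score, identifiable = TRUE)
  class(out) <- "tumor_model"
  out
}

#' @export
print.tumor_model <- function(x, ...) {
  cat(sprintf("SGZ tumor model: purity %.2f, ploidy %.2f (%s), %d segment(s), fit score %s\n",
              x$purity, x$ploidy,
              if (x$identifiable) "identifiable" else "NOT identifiable",
              nrow(x$segments),
              if (is.na(x$fit_score)) "NA" else sprintf("%.4g", x$fit_score)))
  invisible(x)
}

#' @export
summary.tumor_model <- function(object, ...) {
  print(object)
  cat("Segments:\n")
  print(object$segments[, c("chrom", "start", "end", "observed_logratio",
                            "expected_logratio", "C", "M")], row.names = FALSE)
  invisible(object)
}

#' @export
coef.tumor_model <- function(object, ...) {
  c(purity = object$purity, ploidy = object$ploidy)
}

#' Predict expected log-ratios from a fitted tumor model
#'
#' @param object a `tumor_model`.
#' @param C integer copy numbers; defaults to the fitted segment states.
#' @param ... unused.
#' @export
predict.tumor_model <- function(object, C = NULL, ...) {
  if (is.null(C)) C <- object$segments$C
  expected_logratio(object$purity, C, object$ploidy)
}

#' @export
plot.tumor_model <- function(x, ...) {
  s <- x$segments
  idx <- seq_len(nrow(s))
  graphics::plot(idx, s$observed_logratio, pch = 16,
                 xlab = "segment", ylab = "log2 ratio",
                 main = sprintf("purity %.2f, ploidy %.2f", x$purity, x$ploidy), ...)
  graphics::segments(idx - 0.3, s$expected_logratio, idx + 0.3, s$expected_logratio,
                     col = "red", lwd = 2)
  graphics::legend("topleft", legend = c("observed", "fitted"), pch = c(16, NA),
                   lty = c(NA, 1), col = c("black", "red"), bty = "n")
  invisible(x)
}

# Map variant positions to fitted segments; error if any falls outside.
assign_segments <- function(records, segments) {
  seg_gr <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start, segments$end))
  q <- GenomicRanges::GRanges(records$chrom, IRanges::IRanges(records$pos, records$pos))
  hit <- GenomicRanges::findOverlaps(q, seg_gr, select = "first")
  if (anyNA(hit)) stopf("%d variant(s) fall outside all segments", sum(is.na(hit)))
  hit
}

#' Estimate purity from the somatic allele-fraction cluster
#'
#' Fallback for copy-number-flat (diploid balanced) genomes, where the
#' log-ratio/allele-fraction fit cannot identify purity: clonal somatic
#' variants on a diploid background sit at AF = purity / 2, so purity is
#' estimated as twice the median AF of variants absent from the
#' background library with AF below the heterozygous-germline band.
#'
#' @param records filtered tumor-only variant record table.
#' @param lib `background_library`.
#' @param af_max upper AF bound of the putative somatic cluster.
#' @param min_n minimum cluster size; below it NA is returned.
#' @return estimated purity in (0, 1], or NA.
#' @export
estimate_purity_af <- function(records, lib, af_max = 0.47, min_n = 5L) {
  not_in_lib <- library_counts(lib, records) == 0L
  cl <- records$af[not_in_lib & na_false(records$af < af_max)]
  if (length(cl) < min_n) return(NA_real_)
  min(1, 2 * stats::median(cl))
}

#' Variant-level coverage log-ratio
#'
#' Normalizes each variant's local tumor depth the same way as the
#' coverage bins: log2(depth / D0), where the reference depth D0 is
#' chosen so that the sample-median variant log-ratio matches
#' `center_lr` (the median bin log-ratio; 0 for a balanced profile).
#'
#' @param dp tumor depths at the variant positions.
#' @param center_lr median bin log-ratio of the same sample.
#' @return numeric log-ratios.
#' @export
variant_logratio <- function(dp, center_lr = 0) {
  d0 <- stats::median(dp) / 2^center_lr
  log2(dp / d0)
}

#' Absolute log-ratio error of a variant against its segment
#'
#' @param variant_lr variant-level log-ratio(s).
#' @param segment_lr containing segment's observed log-ratio(s).
#' @return non-negative |variant_lr - segment_lr|.
#' @export
error_logratio <- function(variant_lr, segment_lr) {
  abs(variant_lr - segment_lr)
}

#' Classify tumor-only variants as somatic, germline or ambiguous
#'
#' For each variant the expected allele fractions of the germline
#' families (het with the alt on m in \{M, C-M\} tumor copies; hom with
#' m = C) and the somatic family (k in 1..C mutated copies) are computed
#' from the fitted (purity, C, M) of its containing segment. The label
#' is the family with the nearest expectation, provided that distance is
#' within `tau_af` and the variant's error log-ratio is within `tau_lr`;
#' otherwise "ambiguous". Observed AF above `af_germline` is called
#' germline outright (homozygous germline signature); ties between
#' families break toward germline (conservative for TMB).
#'
#' @param records tumor-only variant record table (post filtering).
#' @param model fitted `tumor_model`.
#' @param tau_af allele-fraction tolerance (default 0.1).
#' @param tau_lr error-log-ratio tolerance (default 0.5).
#' @param tau_sep minimum separation between the nearest somatic and
#'   nearest germline expectation for a confident call (default 0.04):
#'   when the two model families predict nearly the same allele
#'   fraction (e.g. a clonal somatic variant vs a het on the deleted
#'   allele of an LOH segment at purity near 0.5), the observation
#'   cannot arbitrate; the call falls back on the background-library
#'   evidence when supplied (`in_library`), else "ambiguous".
#' @param af_germline high-AF germline rule threshold (default 0.9).
#' @param in_library optional logical vector (one per record): whether
#'   the variant key occurs in the background library; used only to
#'   arbitrate model-degenerate calls (separation below `tau_sep`).
#' @param center_lr median bin log-ratio used to normalize variant depth.
#' @return data.frame of calls: key, chrom, pos, ref, alt, af, label,
#'   error_logratio, expected_af_germline, expected_af_somatic.
#' @export
classify_variants <- function(records, model, tau_af = 0.1, tau_lr = 0.5,
                              tau_sep = 0.04, af_germline = 0.9,
                              in_library = NULL, center_lr = 0) {
  stopifnot(inherits(model, "tumor_model"))
  n <- nrow(records)
  if (n == 0L) {
    return(data.frame(key = character(0), chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0), af = numeric(0),
                      label = character(0), error_logratio = numeric(0),
                      expected_af_germline = numeric(0), expected_af_somatic = numeric(0)))
  }
  seg_idx <- assign_segments(records, model$segments)
  P <- model$purity
  v_lr <- variant_logratio(records$dp_t, center_lr)
  err_lr <- error_logratio(v_lr, model$segments$observed_logratio[seg_idx])

  label <- character(n)
  eg <- es <- numeric(n)
  for (i in seq_len(n)) {
    C <- model$segments$C[seg_idx[i]]
    M <- model$segments$M[seg_idx[i]]
    af <- records$af[i]
    het_m <- unique(c(M, C - M))
    g_exp <- c(expected_af_germline_het(P, het_m, C), expected_af_germline_hom(P, C, C))
    # somatic multiplicities 1..C-1 (1 for C = 1): a clonal mutation on
    # all C copies is indistinguishable from the homozygous-germline
    # direction and is conservatively left to the germline family
    k_max <- if (C <= 1L) C else C - 1L
    s_exp <- if (k_max >= 1L) expected_af_somatic(P, seq_len(k_max), C) else numeric(0)
    d_g <- min(abs(af - g_exp))
    d_s <- if (length(s_exp)) min(abs(af - s_exp)) else Inf
    eg[i] <- g_exp[which.min(abs(af - g_exp))]
    es[i] <- if (length(s_exp)) s_exp[which.min(abs(af - s_exp))] else NA_real_
    sep <- if (is.finite(d_s)) abs(eg[i] - es[i]) else Inf
    label[i] <- if (!is.na(af) && af > af_germline) "germline"
    else if (err_lr[i] > tau_lr) "ambiguous"
    else if (is.na(af) || min(d_g, d_s) > tau_af) "ambiguous"
    else if (sep < tau_sep) {
      # model-degenerate zone: the observation cannot separate the
      # families, so the call falls back on population evidence -- a
      # key seen in the background normals is germline, an unseen key
      # is somatic. Without library information, germline is the
      # conservative default.
      if (is.null(in_library)) "germline"
      else if (in_library[i]) "germline" else "somatic"
    }
    else if (d_s < d_g) "somatic" else "germline"
  }
  data.frame(key = variant_key(records$chrom, records$pos, records$ref, records$alt),
             chrom = records$chrom, pos = records$pos, ref = records$ref,
             alt = records$alt, af = records$af, label = label,
             error_logratio = err_lr, expected_af_germline = eg,
             expected_af_somatic = es, stringsAsFactors = FALSE)
}
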