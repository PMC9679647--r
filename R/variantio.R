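# Variant, region and clinical-table I/O.
#
# Variant call sets are held as plain data.frames, one row per
# (site, alt allele), with the INFO tags the filter engine needs as
# columns and per-sample FORMAT tags suffixed `_t` (tumor) / `_n`
# (matched normal; all-NA in tumor-only mode). The sample mode
# ("tumor_only" or "paired") travels as the "mode" attribute.

INFO_STRING_TAGS <- c(status = "STATUS", hotspot = "HOTSPOT", fpdb = "FPDB",
                      germline = "GERMLINE", effect = "EFF")
INFO_NUM_TAGS <- c(sor = "SOR", vd = "VD", af = "AF", ssf = "SSF",
                   msi = "MSI", msilen = "MSILEN")
FMT_NUM_TAGS <- c(pmean = "PMEAN", mq = "MQ", qual = "QUAL", nm = "NM",
                  dp = "DP", sbf = "SBF", vds = "VD")
FMT_STRING_TAGS <- c(bias = "BIAS")

record_columns <- function() {
  samp <- c(names(FMT_NUM_TAGS), names(FMT_STRING_TAGS))
  c("chrom", "pos", "ref", "alt", "vtype",
    names(INFO_STRING_TAGS), names(INFO_NUM_TAGS),
    paste0(samp, "_t"), paste0(samp, "_n"))
}

#' Construct a variant record table
#'
#' Coerces a data.frame into the canonical variant-record layout used by
#' every downstream module, filling absent tags with their sentinel
#' values ("." for string tags, NA for numeric tags) and deriving
#' `vtype` from allele lengths (indel iff lengths differ).
#'
#' @param df data.frame with at least chrom, pos, ref, alt.
#' @param mode "tumor_only" or "paired".
#' @return data.frame in canonical column order with a "mode" attribute.
#' @export
variant_records <- function(df, mode = c("tumor_only", "paired")) {
  mode <- match.arg(mode)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  out <- data.frame(chrom = as.character(df$chrom), pos = as.integer(df$pos),
                    ref = as.character(df$ref), alt = as.character(df$alt),
                    stringsAsFactors = FALSE)
  if (any(out$pos < 1L)) stopf("positions must be >= 1 (1-based)")
  out$vtype <- variant_type(out$ref, out$alt)
  str_cols <- c(names(INFO_STRING_TAGS),
                paste0(names(FMT_STRING_TAGS), "_t"), paste0(names(FMT_STRING_TAGS), "_n"))
  num_cols <- c(names(INFO_NUM_TAGS),
                paste0(names(FMT_NUM_TAGS), "_t"), paste0(names(FMT_NUM_TAGS), "_n"))
  for (cc in str_cols) {
    v <- if (cc %in% names(df)) as.character(df[[cc]]) else rep(".", nrow(out))
    v[is.na(v)] <- "."
    out[[cc]] <- v
  }
  for (cc in num_cols) {
    out[[cc]] <- if (cc %in% names(df)) as.numeric(df[[cc]]) else rep(NA_real_, nrow(out))
  }
  bad_af <- !is.na(out$af) & (out$af < 0 | out$af > 1)
  if (any(bad_af)) stopf("AF outside [0,1] in %d record(s)", sum(bad_af))
  out <- out[record_columns()]
  attr(out, "mode") <- mode
  out
}

#' @export
records_mode <- function(records) {
  m <- attr(records, "mode", exact = TRUE)
  if (is.null(m)) stopf("record table has no mode attribute; build it with variant_records()")
  m
}

# Subset rows while preserving the mode attribute.
keep_records <- function(records, idx) {
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- attr(records, "mode", exact = TRUE)
  out
}

#' Nonsynonymous flag
#'
#' A record counts toward TMB when it is a nonsynonymous SNV (missense,
#' nonsense, splice) or a coding indel (frameshift/inframe). The class
#' list is configurable.
#'
#' @param records variant record table.
#' @param snv_classes,indel_classes effect classes counted for each type.
#' @return logical vector.
#' @export
is_nonsynonymous <- function(records,
                             snv_classes = c("missense", "nonsense", "splice"),
                             indel_classes = c("frameshift", "inframe")) {
  (records$vtype == "snp" & records$effect %in% snv_classes) |
    (records$vtype == "indel" & records$effect %in% indel_classes)
}

#' Read an annotated VCF into a variant record table
#'
#' Multiallelic sites are split into one record per alt allele
#' (comma-separated per-allele INFO/FORMAT values are distributed when
#' their arity matches the alt count). Absent tags map to "." (string)
#' or NA (numeric). Paired mode requires at least two sample columns,
#' read as tumor then matched normal.
#'
#' @param path VCF 4.x file.
#' @param mode "tumor_only" or "paired".
#' @return variant record table (see [variant_records()]).
#' @export
read_vcf <- function(path, mode = c("tumor_only", "paired")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body_at <- which(!startsWith(lines, "#"))
  if (!any(startsWith(lines, "#CHROM"))) stopf("malformed VCF %s: no #CHROM header line", path)
  for (i in body_at) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 8L)
      stopf("malformed VCF %s: fewer than 8 fields at line %d", path, i)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n_rec <- nrow(fix)
  gt <- v@gt
  n_samples <- if (is.null(gt)) 0L else ncol(gt) - 1L
  if (mode == "paired" && n_samples < 2L)
    stopf("paired mode requires 2 sample columns, found %d", n_samples)

  rows <- vector("list", n_rec)
  if (n_rec > 0L) {
    for (i in seq_len(n_rec)) {
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      k <- length(alts)
      info <- parse_info(fix[i, "INFO"])
      fmt <- if (n_samples > 0L) parse_format(gt[i, ], n_samples) else NULL
      sub <- vector("list", k)
      for (a in seq_len(k)) {
        rec <- list(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                    ref = fix[i, "REF"], alt = alts[a])
        for (nm in names(INFO_STRING_TAGS))
          rec[[nm]] <- pick_allele(info[[INFO_STRING_TAGS[nm]]], a, k) %||% "."
        for (nm in names(INFO_NUM_TAGS))
          rec[[nm]] <- num_or_na(pick_allele(info[[INFO_NUM_TAGS[nm]]], a, k) %||% NA)
        for (s in seq_len(min(n_samples, 2L))) {
          suf <- if (s == 1L) "_t" else "_n"
          for (nm in names(FMT_NUM_TAGS))
            rec[[paste0(nm, suf)]] <-
              num_or_na(pick_allele(fmt[[s]][[FMT_NUM_TAGS[nm]]], a, k) %||% NA)
          for (nm in names(FMT_STRING_TAGS))
            rec[[paste0(nm, suf)]] <- pick_allele(fmt[[s]][[FMT_STRING_TAGS[nm]]], a, k) %||% "."
        }
        sub[[a]] <- as.data.frame(rec, stringsAsFactors = FALSE)
      }
      rows[[i]] <- do.call(rbind, sub)
    }
  }
  df <- if (n_rec > 0L) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(), alt = character())
  variant_records(df, mode)
}

parse_info <- function(s) {
  if (is.na(s) || s == "." || s == "") return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- list()
  for (p in kv) out[[p[1]]] <- if (length(p) > 1L) p[2] else "TRUE"
  out
}

parse_format <- function(gt_row, n_samples) {
  keys <- strsplit(gt_row[[1]], ":", fixed = TRUE)[[1]]
  lapply(seq_len(n_samples), function(s) {
    vals <- strsplit(gt_row[[s + 1L]], ":", fixed = TRUE)[[1]]
    out <- list()
    for (j in seq_along(keys)) {
      v <- if (j <= length(vals)) vals[j] else "."
      out[[keys[j]]] <- if (identical(v, ".")) NULL else v
    }
    out
  })
}

# Distribute a comma-joined per-allele value: take the a-th part when the
# arity matches the alt count, otherwise the whole value.
pick_allele <- function(val, a, k) {
  if (is.null(val) || (length(val) == 1L && is.na(val))) return(NULL)
  parts <- strsplit(as.character(val), ",", fixed = TRUE)[[1]]
  if (k > 1L && length(parts) == k) parts[a] else val
}

#' Write a variant record table as VCF
#'
#' Serializes the typed columns back to INFO/FORMAT tags so that
#' `read_vcf(write_variants(x))` round-trips every field. Sentinel "."
#' strings are written as "."; missing numeric tags are written as the
#' VCF missing value ".".
#'
#' @param records variant record table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(records, path) {
  mode <- records_mode(records)
  fmt_num <- function(x) {
    out <- formatC(x, format = "g", digits = 15)
    out[is.na(x)] <- "."
    out
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="%s">',
                   INFO_STRING_TAGS, names(INFO_STRING_TAGS)),
           sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
                   INFO_NUM_TAGS, names(INFO_NUM_TAGS)),
           sprintf('##FORMAT=<ID=%s,Number=1,Type=Float,Description="%s">',
                   FMT_NUM_TAGS, names(FMT_NUM_TAGS)),
           sprintf('##FORMAT=<ID=%s,Number=1,Type=String,Description="%s">',
                   FMT_STRING_TAGS, names(FMT_STRING_TAGS)),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
                   if (mode == "paired") c("TUMOR", "NORMAL") else "TUMOR"), collapse = "\t"))
  n <- nrow(records)
  fmt_keys <- paste(c(FMT_NUM_TAGS, FMT_STRING_TAGS), collapse = ":")
  lines <- character(0)
  if (n > 0L) {
    info_parts <- c(
      lapply(names(INFO_STRING_TAGS), function(nm)
        paste0(INFO_STRING_TAGS[nm], "=", records[[nm]])),
      lapply(names(INFO_NUM_TAGS), function(nm)
        paste0(INFO_NUM_TAGS[nm], "=", fmt_num(records[[nm]]))))
    info <- do.call(paste, c(info_parts, sep = ";"))
    sample_field <- function(suf) {
      parts <- c(lapply(names(FMT_NUM_TAGS), function(nm)
        fmt_num(records[[paste0(nm, suf)]])),
        lapply(names(FMT_STRING_TAGS), function(nm) records[[paste0(nm, suf)]]))
      do.call(paste, c(parts, sep = ":"))
    }
    cols <- list(records$chrom, records$pos, ".", records$ref, records$alt,
                 ".", ".", info, fmt_keys, sample_field("_t"))
    if (mode == "paired") cols <- c(cols, list(sample_field("_n")))
    lines <- do.call(paste, c(cols, sep = "\t"))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read panel target regions from BED
#'
#' 0-based half-open BED intervals are converted to 1-based inclusive
#' coordinates, merged, and summarized as a footprint in megabases.
#'
#' @param path BED file with at least 3 columns.
#' @return A `target_regions` object.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stopf("BED format error in %s: %s", path, conditionMessage(e)))
  if (length(gr) == 0L) stopf("BED file %s contains no intervals", path)
  target_regions(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Construct target regions from coordinates
#'
#' @param chrom,start,end 1-based inclusive intervals (internal convention).
#' @return A `target_regions` object: merged GRanges plus `footprint_mb`.
#' @export
target_regions <- function(chrom, start, end) {
  if (length(chrom) == 0L) stopf("no intervals supplied")
  if (any(end < start)) stopf("interval end < start")
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = as.integer(start), end = as.integer(end))))
  out <- list(gr = gr, footprint_mb = sum(as.numeric(GenomicRanges::width(gr))) / 1e6)
  class(out) <- "target_regions"
  out
}

#' @export
print.target_regions <- function(x, ...) {
  cat(sprintf("Target regions: %d merged interval(s), footprint %.4f Mb\n",
              length(x$gr), x$footprint_mb))
  invisible(x)
}

in_regions <- function(records, regions) {
  stopifnot(inherits(regions, "target_regions"))
  if (nrow(records) == 0L) return(logical(0))
  q <- GenomicRanges::GRanges(records$chrom, IRanges::IRanges(records$pos, records$pos))
  IRanges::overlapsAny(q, regions$gr)
}

#' Read a clinical cohort table
#'
#' Tab-separated with columns patient_id, tmb, response (CR/PR/SD/PD),
#' sd_duration_weeks, os_months, os_event, pfs_months, pfs_event, age,
#' gender, drug, cancer_type. Adds the derived durable-clinical-benefit
#' flag `dcb` (see [derive_dcb()]).
#'
#' @param path TSV file.
#' @return data.frame with a `dcb` column.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "tmb", "response", "sd_duration_weeks", "os_months",
            "os_event", "pfs_months", "pfs_event", "age", "gender", "drug", "cancer_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) stopf("clinical table missing columns: %s",
                                  paste(missing_cols, collapse = ", "))
  if (any(df$os_months < 0 | df$pfs_months < 0)) stopf("negative survival times")
  df$dcb <- derive_dcb(df$response, df$sd_duration_weeks)
  df
}
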