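# False-positive variant filter engine.
#
# Four hard-coded exclusion predicates over the caller's INFO/FORMAT
# tags, applied in order: basic, hotspot, false-positive-database, and
# the stringent "normal" filter. Hotspot variants (HOTSPOT != ".") are
# subject only to the lenient hotspot thresholds; all other variants are
# subject to the fpdb and normal filters — the gating is mutually
# exclusive. A clause that references a missing tag never fires
# (conservative: missing evidence is not grounds for exclusion).
#
# Clauses that index the matched-normal sample (DP[1], NM[1]) are
# skipped in tumor-only mode.

# clause name -> evaluator(records, paired) returning a logical vector
normal_clauses <- function() {
  list(
    germline_tag   = function(r, p) r$germline != ".",
    pmean_lt_20    = function(r, p) na_false(r$pmean_t < 20),
    weak_support   = function(r, p) na_false(r$sor != 0 & r$sor < 5) |
      na_false(r$af < 0.02) | na_false(r$ssf > 0.01),
    af_mq_50       = function(r, p) na_false(r$af < 0.05 & r$mq_t < 50),
    mq_lt_30       = function(r, p) na_false(r$mq_t < 30),
    af_qual_30     = function(r, p) na_false(r$af < 0.05 & r$qual_t < 30),
    msi_low_af     = function(r, p) (na_false(r$msi > 10) |
      na_false(r$msilen > 1 & r$msi > 4)) & na_false(r$af < 0.3),
    msi_indel      = function(r, p) na_false(r$vtype != "snp") & na_false(r$msi > 3) &
      (na_false(r$msilen == nchar(r$ref) - 1) | na_false(r$msilen == nchar(r$alt) - 1)) &
      na_false(r$af < 0.1),
    nm2_mq60_af    = function(r, p) na_false(r$nm_t > 2 & r$mq_t < 60) & na_false(r$af < 0.2),
    nm3_mq55       = function(r, p) na_false(r$nm_t > 3) &
      (na_false(r$mq_t < 55) | (if (p) na_false(r$nm_n > 3) else FALSE)),
    dp_lt_30       = function(r, p) na_false(r$dp_t < 30) |
      (if (p) na_false(r$dp_n < 30) else FALSE),
    vd_lt_10       = function(r, p) na_false(r$vd < 10),
    strand_bias    = function(r, p) bias_codes(r$bias_t, 1) == "2" &
      bias_codes(r$bias_t, 2) == "1",
    sbf_vd_50      = function(r, p) na_false(r$sbf_t < 0.05) & na_false(r$vds_t < 50),
    sor10_mq60     = function(r, p) na_false(r$sor != 0 & r$sor < 10) & na_false(r$mq_t < 60)
  )
}

# i-th numeric strand code of a VarDict-style BIAS string ("2;1" -> "2","1").
bias_codes <- function(bias, i) {
  codes <- strsplit(ifelse(is.na(bias), ".", bias), "[^0-9]+")
  vapply(codes, function(cc) {
    cc <- cc[nzchar(cc)]
    if (length(cc) >= i) cc[i] else ""
  }, character(1))
}

is_hotspot <- function(records) !is.na(records$hotspot) & records$hotspot != "."

#' Basic filter: oversized alleles or non-somatic caller status
#'
#' Excludes records with REF or ALT longer than 50 bases, or whose
#' caller STATUS string does not contain "Somatic" (substring match,
#' mirroring regex non-match semantics). A missing status never fires.
#'
#' @param records variant record table.
#' @return logical exclusion vector (TRUE = exclude).
#' @export
basic_filter <- function(records) {
  long_allele <- nchar(records$ref) > 50 | nchar(records$alt) > 50
  status <- records$status
  non_somatic <- !is.na(status) & status != "." & !grepl("Somatic", status, fixed = TRUE)
  long_allele | non_somatic
}

#' Hotspot filter: lenient thresholds for hotspot variants
#'
#' Applies only when HOTSPOT != "."; excludes on (SOR != 0 & SOR < 3),
#' VD < 5, AF < 0.007, or SSF > 0.05.
#'
#' @inheritParams basic_filter
#' @return logical exclusion vector.
#' @export
hotspot_filter <- function(records) {
  is_hotspot(records) &
    (na_false(records$sor != 0 & records$sor < 3) |
       na_false(records$vd < 5) |
       na_false(records$af < 0.007) |
       na_false(records$ssf > 0.05))
}

#' False-positive-database filter
#'
#' Applies only to non-hotspot variants; excludes when the FPDB tag or
#' the GERMLINE tag is set to anything other than "0" or ".".
#'
#' @inheritParams basic_filter
#' @return logical exclusion vector.
#' @export
fpdb_filter <- function(records) {
  tag_set <- function(x) !is.na(x) & x != "0" & x != "."
  !is_hotspot(records) & (tag_set(records$fpdb) | tag_set(records$germline))
}

#' Normal filter: the stringent 15-clause artifact screen
#'
#' Applies only to non-hotspot variants. Excludes on any of: germline
#' tag present; PMEAN[0] < 20; weak support (SOR in (0,5), AF < 0.02 or
#' SSF > 0.01); low-AF mapping-quality combinations; microsatellite
#' signatures; mismatch-count/mapping-quality combinations; DP < 30 in
#' either sample; VD < 10; forward/reverse strand-bias code "2"/"1";
#' strand-bias p < 0.05 with sample VD < 50; SOR in (0,10) with
#' MQ < 60. Matched-normal clauses are skipped in tumor-only mode.
#'
#' @inheritParams basic_filter
#' @param detail if TRUE return the clause matrix instead of the vector.
#' @return logical exclusion vector, or a logical matrix (one column per
#'   clause) when `detail = TRUE`.
#' @export
normal_filter <- function(records, detail = FALSE) {
  paired <- records_mode(records) == "paired"
  cl <- normal_clauses()
  m <- vapply(cl, function(f) na_false(f(records, paired)), logical(nrow(records)))
  if (nrow(records) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(cl)))
  m <- m & !is_hotspot(records)
  if (detail) m else rowSums(m) > 0L
}

#' Apply the full false-positive filter cascade
#'
#' Runs basic, hotspot, fpdb and normal filters and removes any record
#' excluded by at least one. Idempotent; hotspot gating makes the
#' hotspot filter and the fpdb/normal filters mutually exclusive per
#' record.
#'
#' @param records variant record table.
#' @param disable character vector of filter/clause names to disable
#'   (one of "basic", "hotspot", "fpdb", or a normal-filter clause name).
#' @return list with `kept` (surviving records) and `verdicts`
#'   (data.frame: key, excluded, reasons — comma-joined names of every
#'   clause that fired).
#' @export
apply_filters <- function(records, disable = character(0)) {
  n <- nrow(records)
  clause_mat <- cbind(
    basic = basic_filter(records),
    hotspot = hotspot_filter(records),
    fpdb = fpdb_filter(records),
    if (n > 0L) normal_filter(records, detail = TRUE) else
      matrix(logical(0), 0, length(normal_clauses()),
             dimnames = list(NULL, names(normal_clauses())))
  )
  if (n == 0L) {
    return(list(kept = records,
                verdicts = data.frame(key = character(0), excluded = logical(0),
                                      reasons = character(0))))
  }
  if (length(disable)) {
    unknown <- setdiff(disable, colnames(clause_mat))
    if (length(unknown)) stopf("unknown filter/clause: %s", paste(unknown, collapse = ", "))
    clause_mat[, disable] <- FALSE
  }
  excluded <- rowSums(clause_mat) > 0L
  reasons <- apply(clause_mat, 1L, function(z) paste(colnames(clause_mat)[z], collapse = ","))
  verdicts <- data.frame(
    key = variant_key(records$chrom, records$pos, records$ref, records$alt),
    excluded = excluded, reasons = reasons, stringsAsFactors = FALSE)
  list(kept = keep_records(records, !excluded), verdicts = verdicts)
}
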