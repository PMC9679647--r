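# Panel-of-normals background library: occurrence counts of normalized
# variant keys across a cohort of normal samples, used in tumor-only
# mode to strip recurrent population germline variants and artifacts.

#' Build a background library from normal samples
#'
#' Each sample contributes each variant key at most once (split or
#' duplicated records are deduplicated per sample); the library count is
#' the number of contributing samples.
#'
#' @param normals list of variant record tables and/or VCF file paths.
#' @return `background_library`: data.frame `counts` (chrom, pos, ref,
#'   alt, key, count) and `n_samples`.
#' @export
build_library <- function(normals) {
  if (length(normals) == 0L) stopf("at least one normal sample is required")
  per_sample <- lapply(normals, function(x) {
    r <- if (is.character(x)) read_vcf(x, mode = "tumor_only") else x
    k <- variant_key(r$chrom, r$pos, r$ref, r$alt)
    dup <- duplicated(k)
    data.frame(chrom = r$chrom[!dup], pos = r$pos[!dup], ref = r$ref[!dup],
               alt = r$alt[!dup], key = k[!dup], stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_sample)
  agg <- stats::aggregate(list(count = rep(1L, nrow(all))), by = list(key = all$key), FUN = sum)
  first <- all[!duplicated(all$key), c("chrom", "pos", "ref", "alt", "key")]
  counts <- merge(first, agg, by = "key", sort = FALSE)
  counts <- counts[order(counts$chrom, counts$pos, counts$ref, counts$alt),
                   c("chrom", "pos", "ref", "alt", "key", "count")]
  rownames(counts) <- NULL
  out <- list(counts = counts, n_samples = length(normals))
  class(out) <- "background_library"
  out
}

#' Merge background libraries
#'
#' Counts add per key; sample counts add.
#'
#' @param ... `background_library` objects.
#' @return merged `background_library`.
#' @export
merge_libraries <- function(...) {
  libs <- list(...)
  stopifnot(length(libs) >= 1L, all(vapply(libs, inherits, logical(1), "background_library")))
  all <- do.call(rbind, lapply(libs, `[[`, "counts"))
  agg <- stats::aggregate(list(count = all$count), by = list(key = all$key), FUN = sum)
  first <- all[!duplicated(all$key), c("chrom", "pos", "ref", "alt", "key")]
  counts <- merge(first, agg, by = "key", sort = FALSE)
  counts <- counts[order(counts$chrom, counts$pos, counts$ref, counts$alt),
                   c("chrom", "pos", "ref", "alt", "key", "count")]
  rownames(counts) <- NULL
  out <- list(counts = counts, n_samples = sum(vapply(libs, `[[`, numeric(1), "n_samples")))
  class(out) <- "background_library"
  out
}

#' @export
print.background_library <- function(x, ...) {
  cat(sprintf("Background library: %d variant key(s) across %d normal sample(s)\n",
              nrow(x$counts), x$n_samples))
  invisible(x)
}

#' Look up library occurrence counts for records
#'
#' @param lib `background_library`.
#' @param records variant record table (or data.frame with chrom, pos,
#'   ref, alt).
#' @return integer counts (0 for keys absent from the library).
#' @export
library_counts <- function(lib, records) {
  stopifnot(inherits(lib, "background_library"))
  k <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  cnt <- lib$counts$count[match(k, lib$counts$key)]
  cnt[is.na(cnt)] <- 0L
  as.integer(cnt)
}

#' Background-library filter for tumor-only calls
#'
#' Default ("literal") policy: exclude a record iff its key occurs more
#' than `max_count` times in the library AND its observed allele
#' fraction is at or below `af_retain` — high-AF variants are retained.
#' Alternative policy "high_vaf_germline": exclude iff the key occurs
#' more than `max_count` times OR the allele fraction exceeds
#' `af_retain` (treats high-VAF variants as homozygous germline).
#'
#' @param records variant record table (must carry `af`).
#' @param lib `background_library`.
#' @param policy "literal" or "high_vaf_germline".
#' @param max_count occurrence threshold (exclude strictly above it).
#' @param af_retain allele-fraction threshold (retain strictly above it
#'   under the literal policy).
#' @return list: `kept` records, `removed` data.frame (key, af, count).
#' @export
background_filter <- function(records, lib, policy = c("literal", "high_vaf_germline"),
                              max_count = 5L, af_retain = 0.9) {
  policy <- match.arg(policy)
  cnt <- library_counts(lib, records)
  recurrent <- cnt > max_count
  high_af <- na_false(records$af > af_retain)
  drop <- if (policy == "literal") recurrent & !high_af else recurrent | high_af
  removed <- data.frame(
    key = variant_key(records$chrom, records$pos, records$ref, records$alt)[drop],
    af = records$af[drop], count = cnt[drop], stringsAsFactors = FALSE)
  list(kept = keep_records(records, !drop), removed = removed)
}

#' Write a background library as TSV
#'
#' Columns chrom, pos, ref, alt, count with a `#n_samples=` header line.
#'
#' @param lib `background_library`.
#' @param path output path.
#' @export
write_library <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#n_samples=%d", lib$n_samples), con)
  utils::write.table(lib$counts[, c("chrom", "pos", "ref", "alt", "count")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a background library TSV
#'
#' @param path file written by [write_library()].
#' @return `background_library`.
#' @export
read_library <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#n_samples=\\d+$", first)) stopf("missing #n_samples header in %s", path)
  n_samples <- as.integer(sub("^#n_samples=", "", first))
  counts <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  counts$key <- variant_key(counts$chrom, counts$pos, counts$ref, counts$alt)
  out <- list(counts = counts[, c("chrom", "pos", "ref", "alt", "key", "count")],
              n_samples = n_samples)
  class(out) <- "background_library"
  out
}
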