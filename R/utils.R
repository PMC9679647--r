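# Internal helpers shared across modules.

# NA-safe condition: a clause referencing a missing tag never fires.
na_false <- function(x) {
  x[is.na(x)] <- FALSE
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

num_or_na <- function(x) suppressWarnings(as.numeric(x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Canonical variant key
#'
#' Builds the normalized `chrom:pos:ref:alt` key used to match a variant
#' across samples (e.g. against a background library). Alleles are
#' normalized reference-free: the shared allele suffix is trimmed first,
#' then the shared prefix (always keeping at least one base), with the
#' position advanced accordingly. Multiallelic records must already be
#' split, one alt per record.
#'
#' @param chrom,pos,ref,alt vectors describing one variant per element.
#' @return Character vector of keys, one per input variant.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(pos) == n, length(ref) == n, length(alt) == n)
  norm <- normalize_alleles(pos, ref, alt)
  paste(chrom, norm$pos, norm$ref, norm$alt, sep = ":")
}

# Reference-free allele normalization: trim common suffix, then common
# prefix (keeping one anchor base); position advances with the prefix trim.
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # suffix trim
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # prefix trim
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "snp", "indel")
}
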