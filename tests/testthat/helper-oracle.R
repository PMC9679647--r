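# Independent, record-at-a-time re-evaluation of the printed filter
# expressions. Written separately from the vectorized engine: plain
# scalar logic, one clause at a time, with explicit missing-tag
# handling (a clause over a missing tag is FALSE).

ck <- function(x) isTRUE(x)  # NA/NULL-safe scalar condition

naive_excluded <- function(r, paired) {
  status <- r$status
  # basicfilter: (STRLEN(REF)>50 || STRLEN(ALT)>50) || STATUS !~ "Somatic"
  if (ck(nchar(r$ref) > 50) || ck(nchar(r$alt) > 50)) return(TRUE)
  if (!is.na(status) && status != "." && !grepl("Somatic", status)) return(TRUE)
  hot <- !is.na(r$hotspot) && r$hotspot != "."
  if (hot) {
    # hotspotfilter
    if (ck(r$sor != 0 && r$sor < 3)) return(TRUE)
    if (ck(r$vd < 5)) return(TRUE)
    if (ck(r$af < 0.007)) return(TRUE)
    if (ck(r$ssf > 0.05)) return(TRUE)
    return(FALSE)
  }
  # fpdbfilter
  if (ck(r$fpdb != "0" && r$fpdb != ".")) return(TRUE)
  if (ck(r$germline != "0" && r$germline != ".")) return(TRUE)
  # normalfilter, clause by clause
  if (ck(r$germline != ".")) return(TRUE)
  if (ck(r$pmean_t < 20)) return(TRUE)
  if (ck(r$sor != 0 && r$sor < 5) || ck(r$af < 0.02) || ck(r$ssf > 0.01)) return(TRUE)
  if (ck(r$af < 0.05 && r$mq_t < 50)) return(TRUE)
  if (ck(r$mq_t < 30)) return(TRUE)
  if (ck(r$af < 0.05 && r$qual_t < 30)) return(TRUE)
  if ((ck(r$msi > 10) || ck(r$msilen > 1 && r$msi > 4)) && ck(r$af < 0.3)) return(TRUE)
  if (ck(r$vtype != "snp") && ck(r$msi > 3) &&
      (ck(r$msilen == nchar(r$ref) - 1) || ck(r$msilen == nchar(r$alt) - 1)) &&
      ck(r$af < 0.1)) return(TRUE)
  if (ck(r$nm_t > 2 && r$mq_t < 60) && ck(r$af < 0.2)) return(TRUE)
  if (ck(r$nm_t > 3) && (ck(r$mq_t < 55) || (paired && ck(r$nm_n > 3)))) return(TRUE)
  if (ck(r$dp_t < 30) || (paired && ck(r$dp_n < 30))) return(TRUE)
  if (ck(r$vd < 10)) return(TRUE)
  codes <- regmatches(r$bias_t, gregexpr("[0-9]+", r$bias_t))[[1]]
  if (length(codes) >= 2 && codes[1] == "2" && codes[2] == "1") return(TRUE)
  if (ck(r$sbf_t < 0.05 && r$vds_t < 50)) return(TRUE)
  if (ck(r$sor != 0 && r$sor < 10) && ck(r$mq_t < 60)) return(TRUE)
  FALSE
}

# random record generator concentrating mass near the filter thresholds
random_records <- function(n, mode = "tumor_only", seed = 1) {
  set.seed(seed)
  pick <- function(vals) sample(vals, n, replace = TRUE)
  maybe_na <- function(x, p = 0.15) {
    x[runif(n) < p] <- NA
    x
  }
  df <- data.frame(
    chrom = "chr1", pos = seq_len(n),
    ref = pick(c("A", "C", paste(rep("A", 51), collapse = ""), "AT", "ATT")),
    alt = pick(c("G", "T", paste(rep("G", 60), collapse = ""), "A")),
    status = pick(c("StrongSomatic", "LikelySomatic", "Germline", "SomaticAndGermline", ".")),
    hotspot = pick(c(".", ".", ".", "hs")),
    fpdb = pick(c(".", "0", "3")),
    germline = pick(c(".", ".", "0", "rs12")),
    sor = maybe_na(pick(c(0, 1, 2.9, 3, 4.9, 5, 9.9, 10, 12))),
    vd = maybe_na(pick(c(1, 4, 5, 9, 10, 49, 60))),
    af = maybe_na(pick(c(0.001, 0.006, 0.007, 0.019, 0.02, 0.04, 0.05, 0.1, 0.19,
                         0.25, 0.3, 0.5, 0.95))),
    ssf = maybe_na(pick(c(0.0001, 0.009, 0.011, 0.049, 0.06))),
    msi = maybe_na(pick(c(0, 1, 3, 4, 5, 10, 11))),
    msilen = maybe_na(pick(c(1, 1, 2, 3))),
    pmean_t = maybe_na(pick(c(10, 19, 20, 35))),
    mq_t = maybe_na(pick(c(20, 29, 30, 49, 54, 55, 59, 60))),
    qual_t = maybe_na(pick(c(20, 29, 30, 45))),
    nm_t = maybe_na(pick(c(0, 2, 3, 4, 6))),
    dp_t = maybe_na(pick(c(20, 29, 30, 200, 1000))),
    bias_t = pick(c("2;2", "2;1", "1;1", "0;2", ".")),
    sbf_t = maybe_na(pick(c(0.01, 0.049, 0.05, 0.5))),
    vds_t = maybe_na(pick(c(10, 49, 50, 80))),
    stringsAsFactors = FALSE)
  if (mode == "paired") {
    df$dp_n <- maybe_na(pick(c(20, 29, 30, 150)))
    df$nm_n <- maybe_na(pick(c(1, 3, 4)))
    df$pmean_n <- 35; df$mq_n <- 60; df$qual_n <- 40
    df$bias_n <- "2;2"; df$sbf_n <- 0.5; df$vds_n <- 0
  }
  variant_records(df, mode)
}
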