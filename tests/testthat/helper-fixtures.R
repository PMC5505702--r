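# Shared fixture builders and independent oracles.

tiny_assembly <- function(len = 50000, n = 1) {
  genome_assembly(paste0("chr", seq_len(n)), rep(len, n))
}

# track from explicit segments on one small chromosome
seg_track <- function(starts, ends, values, assembly = tiny_assembly(),
                      chrom = "chr1", strain = "s", replicate = "r1") {
  enrichment_track(data.frame(chrom = chrom, start = starts, end = ends,
                              value = values),
                   assembly, strain = strain, replicate = replicate)
}

# random piecewise-constant track with gaps, plus its per-base expansion
random_track <- function(len = 2000, n_seg = 30, gap_prob = 0.2,
                         assembly = tiny_assembly(len)) {
  cuts <- sort(sample(seq(0, len, by = 10), n_seg + 1))
  cuts <- unique(c(0, cuts, len))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  keep <- ends > starts & stats::runif(length(starts)) > gap_prob
  starts <- starts[keep]; ends <- ends[keep]
  values <- round(stats::runif(length(starts), 0, 5), 3)
  per_base <- rep(NA_real_, len)
  for (i in seq_along(starts))
    per_base[(starts[i] + 1):ends[i]] <- values[i]
  list(track = seg_track(starts, ends, values, assembly = assembly),
       per_base = per_base)
}

# per-base oracle for length-weighted interval mean (0-based half-open)
oracle_interval_mean <- function(per_base, start, end) {
  v <- per_base[(start + 1):end]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

# per-base oracle for bin means with the 50% coverage rule
oracle_bin_means <- function(per_base, start, end, bin = 10, min_cov = 0.5) {
  n <- (end - start) %/% bin
  vapply(seq_len(n), function(j) {
    b0 <- start + (j - 1) * bin
    v <- per_base[(b0 + 1):(b0 + bin)]
    if (mean(!is.na(v)) < min_cov) NA_real_ else mean(v, na.rm = TRUE)
  }, 1)
}

# the package's window-test statistic, reached directly for oracle checks
mwu_p_for_test <- function(x, y) tespread:::mwu_p(x, y, "greater")

# exact Mann-Whitney enumeration oracle (one-sided greater, no ties)
oracle_mwu_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  us <- apply(combs, 2, function(i) sum(r[i]) - n * (n + 1) / 2)
  mean(us >= u_obs)
}

# Fisher 2x2 two-sided p by hypergeometric point-probability summation
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# sort-substitute quantile normalization oracle (no ties assumed)
oracle_quantile_normalize <- function(mat) {
  target <- rowMeans(apply(mat, 2, sort))
  apply(mat, 2, function(col) target[rank(col)])
}

# stranded + canonical k-mer counting oracle, character-by-character
oracle_count_kmers <- function(reads, k = 12) {
  revcomp1 <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  out <- new.env()
  for (r in reads) {
    if (nchar(r) < k) next
    for (i in seq_len(nchar(r) - k + 1)) {
      km <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- revcomp1(km)
      can <- if (km <= rc) km else rc
      out[[can]] <- (if (is.null(out[[can]])) 0L else out[[can]]) + 1L
    }
  }
  v <- unlist(as.list(out))
  v[order(names(v))]
}

# presence-calling rule oracle, written straight from the calling rules
oracle_presence <- function(spans, absent_bp = 50, present_bp = 30) {
  if (nrow(spans) == 0) return("missing")
  for (i in seq_len(nrow(spans)))
    if (spans$spans_insertion_site[i] &&
        spans$bp_left[i] >= absent_bp && spans$bp_right[i] >= absent_bp)
      return("absent")
  for (i in seq_len(nrow(spans)))
    if (spans$te_hit[i] && !spans$spans_insertion_site[i] &&
        (spans$bp_left[i] >= present_bp || spans$bp_right[i] >= present_bp))
      return("present")
  "missing"
}

# small TE table builder
te_row <- function(id, chrom, start, end, family = "roo", type = "LTR",
                   strain = "s1", confidence = 5) {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             family = family, te_type = type, strain = strain,
             confidence = confidence, stringsAsFactors = FALSE)
}
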