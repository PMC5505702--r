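#' Fold-enrichment track
#'
#' A per-strain, per-replicate piecewise-constant ChIP fold-enrichment (FE)
#' signal over genome coordinates, as produced from an IP/input comparison
#' and distributed as bedGraph. Internally each chromosome is stored as a
#' run-length-encoded vector over `[0, chrom_length)`; positions not covered
#' by any bedGraph interval are `NA` (missing, never imputed) and are
#' excluded from all means and window samples.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open; `value >= 0`). Segments must not overlap; adjacent
#'   segments with equal value are merged.
#' @param assembly a [genome_assembly()].
#' @param strain,replicate identifiers carried as metadata.
#' @return An object of class `enrichment_track`.
#' @export
enrichment_track <- function(segments, assembly, strain = "s", replicate = "r1") {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(segments)))
  if (nrow(segments) == 0) stop("empty segment table")
  if (any(segments$value < 0)) stop("negative fold-enrichment values")
  validate_coords(assembly, segments$chrom, segments$start, segments$end,
                  "track segment")
  segments <- segments[order(match(segments$chrom, assembly$chrom_names),
                             segments$start), , drop = FALSE]
  rles <- list()
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (any(seg$start[-1] < seg$end[-nrow(seg)]))
      stop("overlapping track segments on ", ch)
    rles[[ch]] <- segments_to_rle(seg, assembly$chrom_lengths[[ch]])
  }
  structure(list(rles = rles, assembly = assembly,
                 strain = strain, replicate = replicate),
            class = "enrichment_track")
}

# seg: sorted non-overlapping 0-based rows for one chromosome
segments_to_rle <- function(seg, chrom_len) {
  n <- nrow(seg)
  gap_before <- seg$start - c(0, seg$end[-n])
  vals <- as.vector(rbind(NA_real_, seg$value))
  lens <- as.vector(rbind(gap_before, seg$end - seg$start))
  tail_gap <- chrom_len - seg$end[n]
  if (tail_gap > 0) {
    vals <- c(vals, NA_real_)
    lens <- c(lens, tail_gap)
  }
  keep <- lens > 0
  S4Vectors::Rle(vals[keep], lens[keep])
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat("enrichment_track", paste0("[", x$strain, "/", x$replicate, "]"),
      length(x$rles), "chromosome(s)\n")
  invisible(x)
}

track_chrom_rle <- function(track, chrom) {
  r <- track$rles[[chrom]]
  if (is.null(r)) stop("track has no data for chromosome ", chrom)
  r
}

#' Length-weighted mean fold enrichment over an interval
#'
#' Missing (uncovered) positions are excluded from the mean. Used for
#' average enrichment over gene bodies and other fixed spans.
#'
#' @param track an [enrichment_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @return numeric; `NA` if no covered base falls in the interval.
#' @export
mean_signal <- function(track, chrom, start, end) {
  if (end <= start) stop("zero-length or reversed interval")
  r <- track_chrom_rle(track, chrom)
  if (start < 0 || end > length(r)) stop("interval outside chromosome")
  v <- IRanges::Views(r, start = start + 1, end = end)
  IRanges::viewMeans(v, na.rm = TRUE)[1]
}

#' Fixed-bin resampling of a track interval
#'
#' Decomposes `[start, end)` into consecutive `bin_bp` bins and returns the
#' covered-base mean of each bin; a bin with less than `min_cov` fraction of
#' covered bases is `NA`. This is the sampling unit used by the per-window
#' rank tests (default 10 bp, at most 100 observations per 1-kb window).
#'
#' @inheritParams mean_signal
#' @param bin_bp bin width in bp; must divide into at least one full bin.
#' @param min_cov minimum covered fraction of a bin (default 0.5).
#' @return numeric vector, one value per full bin.
#' @export
bin_means <- function(track, chrom, start, end, bin_bp = 10, min_cov = 0.5) {
  stopifnot(bin_bp >= 1, end > start)
  r <- track_chrom_rle(track, chrom)
  n_bins <- (end - start) %/% bin_bp
  if (n_bins < 1) stop("interval shorter than one bin")
  starts <- start + bin_bp * (seq_len(n_bins) - 1)
  # clip bins to the chromosome: out-of-range bins are NA
  ok <- starts >= 0 & (starts + bin_bp) <= length(r)
  out <- rep(NA_real_, n_bins)
  if (any(ok)) {
    v <- IRanges::Views(r, start = starts[ok] + 1, end = starts[ok] + bin_bp)
    m <- IRanges::viewMeans(v, na.rm = TRUE)
    na_rle <- S4Vectors::Rle(as.numeric(is.na(S4Vectors::runValue(r))),
                             S4Vectors::runLength(r))
    cv <- 1 - IRanges::viewMeans(IRanges::Views(na_rle, start = starts[ok] + 1,
                                                end = starts[ok] + bin_bp))
    m[cv < min_cov] <- NA_real_
    out[ok] <- m
  }
  out
}

#' Combine replicate tracks by per-position averaging
#'
#' @param tracks list of [enrichment_track()] objects for one strain.
#' @return an `enrichment_track` whose value at each position is the mean
#'   over replicates (NA where all replicates are missing).
#' @export
combine_replicates <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  if (length(tracks) == 1) return(tracks[[1]])
  out <- tracks[[1]]
  chroms <- names(out$rles)
  for (ch in chroms) {
    rs <- lapply(tracks, function(t) track_chrom_rle(t, ch))
    stopifnot(length(unique(vapply(rs, length, 1))) == 1)
    acc <- rs[[1]]
    for (i in 2:length(rs)) acc <- acc + rs[[i]]
    out$rles[[ch]] <- acc / length(rs)
  }
  out$replicate <- "combined"
  out
}

#' Export a track to bedGraph
#'
#' Uncovered (NA) runs are omitted; adjacent equal-valued runs are merged by
#' the run-length encoding itself.
#'
#' @param track an [enrichment_track()].
#' @param path output file path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$rles)) {
    r <- track$rles[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- !is.na(vals)
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.10g", ch, starts[keep], ends[keep],
                       vals[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph file into an enrichment track
#'
#' @param path bedGraph path (0-based half-open intervals, no header needed).
#' @param assembly a [genome_assembly()] the coordinates must lie on.
#' @param strain,replicate metadata identifiers.
#' @return an [enrichment_track()]. Overlapping intervals or negative values
#'   are a format error.
#' @export
read_bedgraph <- function(path, assembly, strain = "s", replicate = "r1") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- as.data.frame(gr)
  seg <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1, end = df$end,
                    value = df$score)
  enrichment_track(seg, assembly, strain = strain, replicate = replicate)
}
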