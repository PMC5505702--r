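#' Simple-repeat density in a 10-kb window around a TE insertion
#'
#' Fraction of bases annotated as simple repeat within a window of
#' `window_bp` centered on the insertion midpoint, clipped at the
#' chromosome ends.
#'
#' @param te one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param repeat_intervals data.frame `chrom, start, end` of repeat-masked
#'   intervals, 0-based half-open, sorted within chromosome.
#' @param assembly a [genome_assembly()] (for clipping).
#' @param window_bp window size (default 10000).
#' @return fraction in `[0, 1]`.
#' @export
repeat_density_10kb <- function(te, repeat_intervals, assembly,
                                window_bp = 10000) {
  mid <- floor((te$start + te$end) / 2)
  w0 <- max(0, mid - window_bp %/% 2)
  w1 <- min(assembly$chrom_lengths[[te$chrom]], mid + window_bp %/% 2)
  if (w1 <= w0) return(0)
  ri <- repeat_intervals[repeat_intervals$chrom == te$chrom, , drop = FALSE]
  if (nrow(ri) == 0) return(0)
  q <- IRanges::IRanges(start = w0 + 1, end = w1)
  r <- IRanges::reduce(IRanges::IRanges(start = ri$start + 1, end = ri$end))
  ov <- IRanges::pintersect(IRanges::findOverlapPairs(r, q))
  sum(IRanges::width(ov)) / (w1 - w0)
}

#' Interpolated recombination rate at a TE insertion
#'
#' Linear interpolation between the midpoints of 1-Mb windows carrying
#' average recombination-rate estimates (cM/Mb); positions beyond the
#' terminal midpoints take the nearest window's rate.
#'
#' @param te one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param windows_1mb data.frame `chrom, midpoint, rate`.
#' @return rate in cM/Mb.
#' @export
interpolate_recombination <- function(te, windows_1mb) {
  w <- windows_1mb[windows_1mb$chrom == te$chrom, , drop = FALSE]
  if (nrow(w) == 0) stop("no recombination windows for chromosome ", te$chrom)
  w <- w[order(w$midpoint), , drop = FALSE]
  pos <- (te$start + te$end) / 2
  if (nrow(w) == 1) return(w$rate[1])
  stats::approx(w$midpoint, w$rate, xout = pos, rule = 2)$y
}
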