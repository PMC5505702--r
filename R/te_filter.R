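#' Euchromatin buffer filter
#'
#' Keeps a TE only if it lies entirely within the euchromatin span of its
#' chromosome after shrinking that span by `buffer_bp` on each side. The
#' buffer makes the analyzed set conservatively euchromatic: sequences
#' within 0.5 Mb of the epigenetically defined boundary are discarded.
#'
#' @param tes TE data.frame (`id, chrom, start, end`).
#' @param assembly a [genome_assembly()] whose euchromatin bounds are the
#'   *unbuffered* epigenetically defined boundaries.
#' @param buffer_bp buffer width (default 5e5).
#' @return logical vector, TRUE = kept.
#' @export
apply_euchromatin_buffer <- function(tes, assembly, buffer_bp = 500000) {
  keep <- logical(nrow(tes))
  for (ch in unique(tes$chrom)) {
    eu <- euchromatin_span(assembly, ch)
    lo <- eu[1] + buffer_bp
    hi <- eu[2] - buffer_bp
    i <- tes$chrom == ch
    if (hi <= lo) {
      warning("buffer exceeds euchromatin span on ", ch,
              "; all TEs there removed")
      keep[i] <- FALSE
    } else {
      keep[i] <- tes$start[i] >= lo & tes$end[i] <= hi
    }
  }
  keep
}

#' Flag TEs shared between two strains
#'
#' A TE is shared when the other strain carries a same-family insertion
#' whose insertion point (interval midpoint) lies within `tolerance_bp`.
#' Shared insertions carry no between-strain contrast and are excluded
#' from the two-strain analysis.
#'
#' @param tes_a,tes_b TE data.frames for the two strains.
#' @param tolerance_bp positional tolerance for matching calls (default 100).
#' @return list of two logical vectors (`a`, `b`), TRUE = strain-unique.
#' @export
mark_strain_unique <- function(tes_a, tes_b, tolerance_bp = 100) {
  midpoint <- function(t) (t$start + t$end) / 2
  shared_with <- function(x, y) {
    mx <- midpoint(x); my <- midpoint(y)
    vapply(seq_len(nrow(x)), function(i)
      any(y$chrom == x$chrom[i] & y$family == x$family[i] &
            abs(my - mx[i]) <= tolerance_bp), TRUE)
  }
  list(a = !shared_with(tes_a, tes_b), b = !shared_with(tes_b, tes_a))
}

#' Merge same-family calls and exclude cross-family clusters
#'
#' Same-family calls on one chromosome whose spans are within 500 bp
#' (closest-edge distance) are merged into one insertion. After merging,
#' any two insertions of *different* families within 2 kb are flagged as a
#' putative TE cluster and both excluded. Merging runs first, so a
#' same-family pair inside 500 bp can never trigger the cluster rule.
#'
#' @param te_calls TE data.frame (`id, chrom, start, end, family`, other
#'   columns carried from the first member of each merge group).
#' @param merge_bp same-family merge distance (default 500).
#' @param cluster_bp cross-family cluster distance (default 2000).
#' @return list with `merged` (data.frame, cluster members removed),
#'   `cluster_ids` (ids removed as clusters), `merge_map` (data.frame
#'   original id -> merged id).
#' @export
merge_and_cluster <- function(te_calls, merge_bp = 500, cluster_bp = 2000) {
  if (nrow(te_calls) == 0)
    return(list(merged = te_calls, cluster_ids = character(0),
                merge_map = data.frame(id = character(0),
                                       merged_id = character(0))))
  x <- te_calls[order(te_calls$chrom, te_calls$start, te_calls$end), ,
                drop = FALSE]
  # transitive same-family merging via single-linkage chaining
  grp <- integer(nrow(x))
  g <- 0
  for (key in unique(paste(x$chrom, x$family))) {
    i <- which(paste(x$chrom, x$family) == key)
    g <- g + 1
    grp[i[1]] <- g
    if (length(i) > 1)
      for (k in 2:length(i)) {
        gap <- x$start[i[k]] - max(x$end[i[1:(k - 1)]][grp[i[1:(k - 1)]] == g])
        if (gap <= merge_bp) grp[i[k]] <- g
        else { g <- g + 1; grp[i[k]] <- g }
      }
  }
  groups <- split(seq_len(nrow(x)), grp)
  merged <- do.call(rbind, lapply(groups, function(i) {
    r <- x[i[1], , drop = FALSE]
    r$start <- min(x$start[i]); r$end <- max(x$end[i])
    r
  }))
  rownames(merged) <- NULL
  rep_id <- vapply(groups, function(i) x$id[i[1]], "")
  merge_map <- data.frame(id = x$id,
                          merged_id = rep_id[match(grp, as.integer(names(groups)))],
                          stringsAsFactors = FALSE)
  ord <- order(merged$chrom, merged$start)
  merged <- merged[ord, , drop = FALSE]
  rownames(merged) <- NULL
  # cross-family cluster exclusion on merged calls (closest-edge distance)
  n <- nrow(merged)
  clustered <- logical(n)
  if (n > 1)
    for (i in 1:(n - 1))
      for (j in (i + 1):n) {
        if (merged$chrom[j] != merged$chrom[i]) next
        gap <- max(merged$start[j] - merged$end[i],
                   merged$start[i] - merged$end[j], 0)
        if (gap > cluster_bp) next
        if (merged$family[i] != merged$family[j])
          clustered[c(i, j)] <- TRUE
      }
  list(merged = merged[!clustered, , drop = FALSE],
       cluster_ids = merged$id[clustered],
       merge_map = merge_map)
}

#' Annotate TE calls from blast hit records
#'
#' Per query locus, keeps the hit with the smallest e-value; a tie between
#' two or more families at the smallest e-value makes the locus ambiguous
#' and excluded. Calls shorter than 100 bp or below 80% identity to the
#' canonical TE are excluded, as is the INE-1 family (ancient, essentially
#' fixed, uninformative for polymorphic-insertion analysis).
#'
#' @param hits data.frame `locus, te_family, length, identity, evalue,
#'   chrom, start, end`.
#' @param min_length,min_identity call thresholds (defaults 100 bp, 80).
#' @param exclude_families families always dropped (default `"INE-1"`).
#' @return list with `calls` (one row per retained locus) and `report`
#'   (per-locus disposition: kept / ambiguous_family / short / low_identity
#'   / excluded_family).
#' @export
annotate_from_hits <- function(hits, min_length = 100, min_identity = 80,
                               exclude_families = "INE-1") {
  stopifnot(all(c("locus", "te_family", "length", "identity", "evalue")
                %in% names(hits)))
  out <- lapply(split(hits, hits$locus), function(h) {
    best <- h[h$evalue == min(h$evalue), , drop = FALSE]
    if (length(unique(best$te_family)) > 1)
      return(list(call = NULL, reason = "ambiguous_family"))
    best <- best[1, , drop = FALSE]
    if (best$length < min_length) return(list(call = NULL, reason = "short"))
    if (best$identity < min_identity)
      return(list(call = NULL, reason = "low_identity"))
    if (best$te_family %in% exclude_families)
      return(list(call = NULL, reason = "excluded_family"))
    list(call = best, reason = "kept")
  })
  report <- data.frame(locus = names(out),
                       disposition = vapply(out, `[[`, "", "reason"),
                       stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(out, `[[`, "call"))
  rownames(calls) <- NULL
  list(calls = calls, report = report)
}

overlaps_any <- function(tes, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0)
    return(rep(FALSE, nrow(tes)))
  hit <- logical(nrow(tes))
  for (ch in unique(tes$chrom)) {
    i <- which(tes$chrom == ch)
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) next
    q <- IRanges::IRanges(tes$start[i] + 1, tes$end[i])
    s <- IRanges::IRanges(iv$start + 1, iv$end)
    hit[i] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Exclude TEs overlapping exons or shared enrichment peaks
#'
#' Any overlap of one base or more with an exon or with an H3K9me2 peak
#' shared between the two strains removes the TE (a shared peak means the
#' local enrichment is not attributable to the strain-unique insertion).
#' Features that merely touch at a shared endpoint do not overlap under
#' the half-open convention.
#'
#' @param tes TE data.frame.
#' @param exons data.frame `chrom, start, end` (or NULL).
#' @param shared_peaks data.frame `chrom, start, end` (or NULL).
#' @return data.frame `exonic`, `shared_peak` logical flags per TE.
#' @export
exclude_exonic_and_shared_peaks <- function(tes, exons = NULL,
                                            shared_peaks = NULL) {
  data.frame(exonic = overlaps_any(tes, exons),
             shared_peak = overlaps_any(tes, shared_peaks))
}

#' Full TE-catalog curation for one strain pair
#'
#' Applies, in order: euchromatin buffer, same-family merging and
#' cross-family cluster exclusion, strain-shared exclusion, and
#' exon/shared-peak exclusion. Returns the analyzable strain-unique TE set
#' per strain plus a disposition report in which every input TE appears
#' exactly once.
#'
#' @param tes_a,tes_b per-strain TE data.frames.
#' @param assembly a [genome_assembly()].
#' @param exons,shared_peaks optional interval data.frames.
#' @param buffer_bp,merge_bp,cluster_bp,tolerance_bp rule distances.
#' @return list with `kept` (list `a`, `b` of data.frames) and `report`
#'   (data.frame `id, strain, disposition`).
#' @export
curate_tes <- function(tes_a, tes_b, assembly, exons = NULL,
                       shared_peaks = NULL, buffer_bp = 500000,
                       merge_bp = 500, cluster_bp = 2000,
                       tolerance_bp = 100) {
  one <- function(tes, other, strain) {
    disp <- rep(NA_character_, nrow(tes))
    names(disp) <- tes$id
    in_eu <- apply_euchromatin_buffer(tes, assembly, buffer_bp)
    disp[!in_eu] <- "heterochromatic"
    cur <- tes[in_eu, , drop = FALSE]
    mc <- merge_and_cluster(cur, merge_bp, cluster_bp)
    disp[mc$cluster_ids] <- "cluster"
    merged_away <- setdiff(mc$merge_map$id,
                           c(mc$merged$id, mc$cluster_ids))
    disp[merged_away] <- "merged"
    cur <- mc$merged
    uniq <- mark_strain_unique(cur, other, tolerance_bp)$a
    disp[cur$id[!uniq]] <- "shared_between_strains"
    cur <- cur[uniq, , drop = FALSE]
    ov <- exclude_exonic_and_shared_peaks(cur, exons, shared_peaks)
    disp[cur$id[ov$exonic]] <- "exonic"
    disp[cur$id[!ov$exonic & ov$shared_peak]] <- "shared_peak"
    cur <- cur[!ov$exonic & !ov$shared_peak, , drop = FALSE]
    disp[cur$id] <- "kept"
    list(kept = cur,
         report = data.frame(id = tes$id, strain = strain,
                             disposition = unname(disp[tes$id]),
                             stringsAsFactors = FALSE))
  }
  ra <- one(tes_a, tes_b, "a")
  rb <- one(tes_b, tes_a, "b")
  list(kept = list(a = ra$kept, b = rb$kept),
       report = rbind(ra$report, rb$report))
}
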