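#' Gene-body enrichment matrix per replicate
#'
#' Average fold enrichment over each gene body (annotated span including
#' introns) for every strain x replicate track.
#'
#' @param genes gene data.frame (`id, chrom, start, end`).
#' @param tracks nested list `strain -> replicate ->` [enrichment_track()].
#' @param assembly a [genome_assembly()].
#' @return list with `mat` (genes x samples matrix) and `samples`
#'   (data.frame `sample, strain, replicate`).
#' @export
gene_body_enrichment <- function(genes, tracks, assembly) {
  samples <- do.call(rbind, lapply(names(tracks), function(s)
    data.frame(sample = paste(s, names(tracks[[s]]), sep = "_"),
               strain = s, replicate = names(tracks[[s]]),
               stringsAsFactors = FALSE)))
  mat <- matrix(NA_real_, nrow(genes), nrow(samples),
                dimnames = list(genes$id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    tr <- tracks[[samples$strain[j]]][[samples$replicate[j]]]
    mat[, j] <- vapply(seq_len(nrow(genes)), function(i)
      mean_signal(tr, genes$chrom[i], genes$start[i], genes$end[i]), 1)
  }
  list(mat = mat, samples = samples)
}

#' Quantile normalization across replicate columns
#'
#' Maps every column onto the common (mean) sorted profile; ties share the
#' average of their target quantiles. Preserves within-column rank order.
#'
#' @param mat numeric matrix (genes x replicates).
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Distance category of each gene to the nearest TE
#'
#' Shortest edge-to-edge distance from the gene span to any TE of one
#' strain's curated set, binned as 0-1, 1-2, 2-5, 5-10 kb, or no TE within
#' 10 kb; a TE overlapping the gene has distance 0.
#'
#' @param genes gene data.frame.
#' @param tes one strain's TE data.frame.
#' @param max_dist "no TE" cutoff in bp (default 10000).
#' @return data.frame `gene_id, nearest_te, distance, category`.
#' @export
assign_distance_category <- function(genes, tes, max_dist = 10000) {
  out <- data.frame(gene_id = genes$id, nearest_te = NA_character_,
                    distance = Inf, stringsAsFactors = FALSE)
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    ti <- which(tes$chrom == ch)
    if (!length(ti)) next
    q <- IRanges::IRanges(genes$start[gi] + 1, genes$end[gi])
    s <- IRanges::IRanges(tes$start[ti] + 1, tes$end[ti])
    d <- IRanges::distance(rep(q, each = length(s)),
                           rep(s, length(gi)))
    dm <- matrix(d, nrow = length(s))
    nearest <- apply(dm, 2, which.min)
    out$distance[gi] <- dm[cbind(nearest, seq_along(gi))]
    out$nearest_te[gi] <- tes$id[ti][nearest]
  }
  out$category <- cut(out$distance, c(-1, 1000, 2000, 5000, 10000, Inf),
                      labels = c("0-1 kb", "1-2 kb", "2-5 kb", "5-10 kb",
                                 "none"), right = FALSE)
  out$category[out$distance >= max_dist] <- "none"
  out$nearest_te[out$category == "none"] <- NA_character_
  out
}

#' Per-gene allele-level epigenetic records
#'
#' Combines distance categories in both strains with quantile-normalized
#' gene-body enrichment to produce, per gene: the allele z-score
#' `(mean of the with-TE strain - mean of the without-TE strain) / mean of
#' the two strains' replicate SDs` (defined only for unambiguous genes:
#' TE within 10 kb in exactly one strain), and the fixed-reference z-score
#' with the same denominator but `mean(other) - mean(reference)` numerator
#' regardless of TE status.
#'
#' @param genes gene data.frame.
#' @param enr result of [gene_body_enrichment()] (after
#'   [quantile_normalize()] of `$mat`).
#' @param tes_by_strain named list (two strains) of curated TE data.frames.
#' @param reference_strain strain used as reference for `z_ref`.
#' @param effects optional [spread_effects()] table for nearest-TE effect
#'   annotation.
#' @param freqs optional [estimate_frequencies()] table for nearest-TE
#'   frequency class.
#' @param max_dist "no TE" cutoff (default 10000).
#' @return data.frame, one row per gene.
#' @export
gene_epi_table <- function(genes, enr, tes_by_strain, reference_strain,
                           effects = NULL, freqs = NULL, max_dist = 10000) {
  strains <- names(tes_by_strain)
  stopifnot(length(strains) == 2, reference_strain %in% strains)
  other_strain <- setdiff(strains, reference_strain)
  cat_by_strain <- lapply(tes_by_strain, function(t)
    assign_distance_category(genes, t, max_dist))
  mats <- lapply(strains, function(s)
    enr$mat[, enr$samples$strain == s, drop = FALSE])
  names(mats) <- strains
  mu <- vapply(mats, rowMeans, numeric(nrow(genes)))
  sds <- vapply(mats, function(m) apply(m, 1, stats::sd),
                numeric(nrow(genes)))
  if (is.null(dim(mu))) {  # single-gene input drops to vectors
    mu <- matrix(mu, 1, dimnames = list(genes$id, strains))
    sds <- matrix(sds, 1, dimnames = list(genes$id, strains))
  }
  denom <- rowMeans(sds)

  has_te <- vapply(strains, function(s)
    cat_by_strain[[s]]$category != "none", logical(nrow(genes)))
  if (is.null(dim(has_te)))
    has_te <- matrix(has_te, 1, dimnames = list(NULL, strains))
  ambiguous <- rowSums(has_te) == 2
  with_strain <- ifelse(rowSums(has_te) == 1,
                        strains[apply(has_te, 1, which.max)], NA)
  z_allele <- rep(NA_real_, nrow(genes))
  idx <- which(!is.na(with_strain) & denom > 0)
  for (i in idx) {
    ws <- with_strain[i]
    z_allele[i] <- (mu[i, ws] - mu[i, setdiff(strains, ws)]) / denom[i]
  }
  z_ref <- ifelse(denom > 0,
                  (mu[, other_strain] - mu[, reference_strain]) / denom,
                  NA_real_)

  nearest <- ifelse(is.na(with_strain), NA_character_,
                    vapply(seq_len(nrow(genes)), function(i)
                      if (is.na(with_strain[i])) NA_character_ else
                        cat_by_strain[[with_strain[i]]]$nearest_te[i], ""))
  category <- ifelse(is.na(with_strain), "none",
                     vapply(seq_len(nrow(genes)), function(i)
                       if (is.na(with_strain[i])) "none" else
                         as.character(cat_by_strain[[with_strain[i]]]$category[i]),
                       ""))
  rec <- data.frame(gene_id = genes$id,
                    with_strain = with_strain,
                    category = category,
                    nearest_te = nearest,
                    ambiguous = ambiguous,
                    z_allele = ifelse(ambiguous, NA_real_, z_allele),
                    z_ref = z_ref,
                    stringsAsFactors = FALSE)
  for (s in strains) {
    rec[[paste0("mean_", s)]] <- mu[, s]
    rec[[paste0("category_", s)]] <- as.character(cat_by_strain[[s]]$category)
  }
  if (!is.null(effects)) {
    m <- match(rec$nearest_te, effects$te_id)
    rec$te_has_effect <- effects$has_effect[m]
    rec$te_extent_kb <- effects$extent_kb[m]
    rec$te_pct_increase <- effects$pct_increase[m]
  }
  if (!is.null(freqs)) {
    m <- match(rec$nearest_te, freqs$te_id)
    rec$te_high_frequency <- freqs$high_frequency[m]
  }
  rec
}

#' Stratified comparisons of gene z-scores
#'
#' Mann-Whitney comparisons of allele z-scores between gene strata
#' (TE-adjacent vs no TE within 10 kb, using the fixed-reference z for the
#' no-TE stratum; effect vs no-effect nearest TE; low- vs high-frequency
#' nearest TE), overall and per distance category, plus Spearman
#' correlations of z with the nearest TE's extent and percent increase.
#' Strata with no genes are omitted with a warning.
#'
#' @param records output of [gene_epi_table()].
#' @return list `tests` (data.frame) and `correlations` (data.frame).
#' @export
stratified_z_comparisons <- function(records) {
  te_genes <- records[!records$ambiguous & !is.na(records$z_allele), ,
                      drop = FALSE]
  none_genes <- records[records$category == "none" & !records$ambiguous, ,
                        drop = FALSE]
  rows <- list()
  add <- function(comparison, category, x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) {
      warning("empty stratum for ", comparison, " [", category, "]; omitted")
      return()
    }
    rows[[length(rows) + 1]] <<- data.frame(
      comparison = comparison, category = category,
      n1 = length(x), n2 = length(y),
      median1 = stats::median(x), median2 = stats::median(y),
      p = mwu_p(x, y, alternative = "two.sided"),
      stringsAsFactors = FALSE)
  }
  add("te_vs_none", "all", te_genes$z_allele, none_genes$z_ref)
  cats <- setdiff(unique(te_genes$category), "none")
  for (cc in sort(cats))
    add("te_vs_none", cc, te_genes$z_allele[te_genes$category == cc],
        none_genes$z_ref)
  if ("te_has_effect" %in% names(te_genes)) {
    eff <- te_genes$te_has_effect
    add("effect_vs_noeffect", "all",
        te_genes$z_allele[eff %in% TRUE], te_genes$z_allele[eff %in% FALSE])
    for (cc in sort(cats))
      add("effect_vs_noeffect", cc,
          te_genes$z_allele[eff %in% TRUE & te_genes$category == cc],
          te_genes$z_allele[eff %in% FALSE & te_genes$category == cc])
  }
  if ("te_high_frequency" %in% names(te_genes)) {
    hf <- te_genes$te_high_frequency
    add("lowfreq_vs_highfreq", "all",
        te_genes$z_allele[hf %in% FALSE], te_genes$z_allele[hf %in% TRUE])
  }
  tests <- do.call(rbind, rows)

  correlations <- NULL
  if ("te_extent_kb" %in% names(te_genes)) {
    correlations <- do.call(rbind, lapply(
      c("te_extent_kb", "te_pct_increase"), function(v) {
        ok <- !is.na(te_genes[[v]])
        ct <- suppressWarnings(stats::cor.test(te_genes$z_allele[ok],
                                               te_genes[[v]][ok],
                                               method = "spearman"))
        data.frame(index = v, n = sum(ok), rho = unname(ct$estimate),
                   p = ct$p.value, stringsAsFactors = FALSE)
      }))
  }
  list(tests = tests, correlations = correlations)
}
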