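#' Window profile around one TE insertion
#'
#' Decomposes the 20 kb on each side of a TE insertion into 20
#' non-overlapping 1-kb windows (window 1 = 0-1 kb from the TE edge) and
#' collects, per window and strain, the fold-enrichment sample vector
#' (10-bp bin means; missing-coverage bins excluded). The 20-40 kb flanks
#' on both sides give each strain's background normalizer (median over the
#' union of both flanks).
#'
#' A window is unusable when it extends past the euchromatin bounds, when
#' under half of it is covered, or when either strain has fewer than 5
#' usable bins; unusable windows are never significant.
#'
#' @param te one-row TE data.frame (`id, chrom, start, end`).
#' @param track_with,track_without combined [enrichment_track()]s of the
#'   strain carrying the TE and the strain lacking it.
#' @param assembly a [genome_assembly()].
#' @param window_kb window width (default 1).
#' @param span_kb windows per side (default 20).
#' @param flank_kb background flank, kb from the TE edge (default 20-40).
#' @param bin_bp sampling bin (default 10).
#' @return object of class `window_profile`.
#' @export
build_profile <- function(te, track_with, track_without, assembly,
                          window_kb = 1, span_kb = 20, flank_kb = c(20, 40),
                          bin_bp = 10) {
  wbp <- window_kb * 1000
  n_win <- span_kb %/% window_kb
  reach <- flank_kb[2] * 1000
  eu <- euchromatin_span(assembly, te$chrom)
  tracks <- list(with = track_with, without = track_without)

  # one bin-resampling call per side per strain over the whole reach,
  # then slice windows and flanks out of the resulting vectors
  region <- lapply(tracks, function(tr) list(
    left = bin_means(tr, te$chrom, te$start - reach, te$start,
                     bin_bp = bin_bp),
    right = bin_means(tr, te$chrom, te$end, te$end + reach,
                      bin_bp = bin_bp)))
  n_reach <- reach %/% bin_bp
  n_bins_full <- wbp %/% bin_bp
  slice <- function(side, lo_bp, hi_bp) {
    # bp offsets from the TE edge outward -> bin indices in region vectors
    i0 <- lo_bp %/% bin_bp + 1
    i1 <- hi_bp %/% bin_bp
    if (side == "left") (n_reach + 1 - i1):(n_reach + 1 - i0)
    else i0:i1
  }

  samples <- list(left = vector("list", n_win),
                  right = vector("list", n_win))
  usable <- matrix(FALSE, 2, n_win, dimnames = list(c("left", "right"), NULL))
  for (side in c("left", "right"))
    for (i in seq_len(n_win)) {
      idx <- slice(side, (i - 1) * wbp, i * wbp)
      sw <- region$with[[side]][idx]
      so <- region$without[[side]][idx]
      sw <- sw[!is.na(sw)]; so <- so[!is.na(so)]
      b <- if (side == "right") c(te$end + (i - 1) * wbp, te$end + i * wbp)
      else c(te$start - i * wbp, te$start - (i - 1) * wbp)
      in_eu <- b[1] >= eu[1] && b[2] <= eu[2]
      usable[side, i] <- in_eu &&
        length(sw) >= max(5, 0.5 * n_bins_full) &&
        length(so) >= max(5, 0.5 * n_bins_full)
      samples[[side]][[i]] <- list(with = sw, without = so)
    }

  fidx <- lapply(c(left = "left", right = "right"), function(side)
    slice(side, flank_kb[1] * 1000, flank_kb[2] * 1000))
  flank_samp <- lapply(region, function(rg)
    lapply(c(left = "left", right = "right"), function(side) {
      v <- rg[[side]][fidx[[side]]]
      v[!is.na(v)]
    }))
  flank_norm <- vapply(flank_samp, function(fs)
    stats::median(c(fs$left, fs$right)), 1)
  flank_medians <- lapply(flank_samp, function(fs)
    c(left = stats::median(fs$left), right = stats::median(fs$right)))

  structure(list(te_id = te$id, samples = samples, usable = usable,
                 flank_norm = flank_norm, flank_medians = flank_medians,
                 n_win = n_win, normalized = FALSE),
            class = "window_profile")
}

#' Normalize a window profile between strains
#'
#' Divides each strain's sample values by that strain's flank normalizer
#' (median enrichment over its 20-40 kb flanks), removing baseline
#' differences in global enrichment between the two strains while
#' preserving within-strain rank order.
#'
#' @param profile a [build_profile()] result.
#' @return the profile with normalized samples.
#' @export
normalize_between_strains <- function(profile) {
  if (profile$normalized) return(profile)
  fn <- profile$flank_norm
  if (any(!is.finite(fn)) || any(fn <= 0))
    stop("flank normalizer not positive for TE ", profile$te_id)
  for (side in c("left", "right"))
    for (i in seq_len(profile$n_win)) {
      profile$samples[[side]][[i]]$with <-
        profile$samples[[side]][[i]]$with / fn[["with"]]
      profile$samples[[side]][[i]]$without <-
        profile$samples[[side]][[i]]$without / fn[["without"]]
    }
  profile$normalized <- TRUE
  profile
}

#' Per-window between-strain test
#'
#' One-sided Mann-Whitney U test of whether enrichment in window `i` on
#' `side` is higher in the strain carrying the TE. Unusable windows are
#' never significant.
#'
#' @param profile a (normalized) [build_profile()] result.
#' @param i window index (1 = 0-1 kb).
#' @param side `"left"` or `"right"`.
#' @param alpha significance level (default 0.05).
#' @return list `p`, `significant`.
#' @export
window_test <- function(profile, i, side, alpha = 0.05) {
  if (!profile$usable[side, i])
    return(list(p = NA_real_, significant = FALSE))
  s <- profile$samples[[side]][[i]]
  p <- mwu_p(s$with, s$without, alternative = "greater")
  list(p = p, significant = is.finite(p) && p < alpha)
}

#' Extent of spread from per-window significance
#'
#' Per side, the farthest window such that windows 1..k are all
#' significant (consecutive from the TE edge); the reported extent is the
#' smaller of the two sides (conservative), and a TE has an epigenetic
#' effect only when window 1 is significant on both sides.
#'
#' @param sig_left,sig_right logical vectors over windows 1..n.
#' @return list `extent_kb`, `has_effect`.
#' @export
extent_of_spread <- function(sig_left, sig_right) {
  run1 <- function(s) {
    k <- match(FALSE, c(s, FALSE)) - 1
    k
  }
  extent <- min(run1(sig_left), run1(sig_right))
  list(extent_kb = extent, has_effect = extent >= 1)
}

#' Percent increase of enrichment next to the TE
#'
#' Difference of median (normalized) enrichment between the two strains in
#' the pooled left+right 0-1 kb windows, with-TE minus without-TE, divided
#' by the without-TE median.
#'
#' @param profile a normalized [build_profile()] result.
#' @return numeric fraction (0.8 = 80% increase); may be negative.
#' @export
pct_increase <- function(profile) {
  w <- c(profile$samples$left[[1]]$with, profile$samples$right[[1]]$with)
  o <- c(profile$samples$left[[1]]$without, profile$samples$right[[1]]$without)
  if (!length(w) || !length(o)) return(NA_real_)
  mo <- stats::median(o)
  if (mo == 0) stop("zero without-TE median enrichment for TE ",
                    profile$te_id)
  (stats::median(w) - mo) / mo
}

#' Two-strain epigenetic effect of one TE
#'
#' @inheritParams build_profile
#' @param alpha per-window significance level.
#' @return one-row data.frame: `te_id, method, has_effect, extent_kb,
#'   pct_increase`.
#' @export
two_strain_effect <- function(te, track_with, track_without, assembly,
                              alpha = 0.05, ...) {
  pr <- build_profile(te, track_with, track_without, assembly, ...)
  pr <- normalize_between_strains(pr)
  sig <- vapply(c("left", "right"), function(side)
    vapply(seq_len(pr$n_win), function(i)
      window_test(pr, i, side, alpha)$significant, TRUE),
    logical(pr$n_win))
  ext <- extent_of_spread(sig[, "left"], sig[, "right"])
  data.frame(te_id = te$id, method = "two_strain",
             has_effect = ext$has_effect, extent_kb = ext$extent_kb,
             pct_increase = pct_increase(pr), stringsAsFactors = FALSE)
}

#' Single-genome relative window profile
#'
#' For analyses without a second strain: samples are divided by the higher
#' of the two flank medians (20-40 kb, left vs right), the conservative
#' choice of background.
#'
#' @param te one-row TE data.frame.
#' @param track combined [enrichment_track()] of the carrier strain.
#' @inheritParams build_profile
#' @return object of class `relative_profile`.
#' @export
relative_profile <- function(te, track, assembly, window_kb = 1,
                             span_kb = 20, flank_kb = c(20, 40),
                             bin_bp = 10) {
  pr <- build_profile(te, track, track, assembly, window_kb = window_kb,
                      span_kb = span_kb, flank_kb = flank_kb,
                      bin_bp = bin_bp)
  fm <- pr$flank_medians$with
  norm <- max(fm, na.rm = TRUE)
  if (!is.finite(norm) || norm <= 0)
    stop("flank normalizer not positive for TE ", te$id)
  samples <- lapply(pr$samples, function(side)
    lapply(side, function(s) s$with / norm))
  structure(list(te_id = te$id, samples = samples, usable = pr$usable,
                 norm = norm, n_win = pr$n_win),
            class = "relative_profile")
}

#' Epigenetic effect by the single-genome relative-enrichment method
#'
#' Per window, an exact one-sided sign test of whether the relative
#' enrichment exceeds 1 (the background level); extent and has-effect
#' follow the same consecutive-window rule as the two-strain method, and
#' the increase is the pooled 0-1 kb median relative enrichment minus one.
#'
#' @param rp a [relative_profile()].
#' @param alpha per-window significance level.
#' @return one-row data.frame (`method = "relative"`).
#' @export
relative_effect <- function(rp, alpha = 0.05) {
  sig <- vapply(c("left", "right"), function(side)
    vapply(seq_len(rp$n_win), function(i) {
      if (!rp$usable[side, i]) return(FALSE)
      p <- sign_test_p(rp$samples[[side]][[i]], mu = 1,
                       alternative = "greater")
      is.finite(p) && p < alpha
    }, TRUE), logical(rp$n_win))
  ext <- extent_of_spread(sig[, "left"], sig[, "right"])
  pooled <- c(rp$samples$left[[1]], rp$samples$right[[1]])
  data.frame(te_id = rp$te_id, method = "relative",
             has_effect = ext$has_effect, extent_kb = ext$extent_kb,
             pct_increase = stats::median(pooled) - 1,
             stringsAsFactors = FALSE)
}

#' Batch per-TE effects for a curated TE set
#'
#' Runs the chosen method over every TE. For the two-strain method each
#' TE's carrier strain (its `strain` column) supplies the with-TE track
#' and the other strain the without-TE track.
#'
#' @param tes TE data.frame with `id, chrom, start, end, family, te_type,
#'   strain`.
#' @param tracks named list of combined [enrichment_track()]s, one per
#'   strain.
#' @param assembly a [genome_assembly()].
#' @param method `"two_strain"` or `"relative"`.
#' @param alpha per-window significance level.
#' @param ... passed to [build_profile()] / [relative_profile()].
#' @return data.frame of per-TE effects with family and type columns.
#' @export
spread_effects <- function(tes, tracks, assembly,
                           method = c("two_strain", "relative"),
                           alpha = 0.05, ...) {
  method <- match.arg(method)
  strains <- names(tracks)
  rows <- lapply(seq_len(nrow(tes)), function(k) {
    te <- tes[k, , drop = FALSE]
    eff <- if (method == "two_strain") {
      other <- setdiff(strains, te$strain)[1]
      two_strain_effect(te, tracks[[te$strain]], tracks[[other]], assembly,
                        alpha = alpha, ...)
    } else {
      relative_effect(relative_profile(te, tracks[[te$strain]], assembly,
                                       ...), alpha = alpha)
    }
    eff$family <- te$family
    eff$te_type <- te$te_type
    eff$strain <- te$strain
    eff
  })
  do.call(rbind, rows)
}

#' Family-level effect summaries and LTR-vs-other comparisons
#'
#' Per family (families with at least two observations only): number of
#' TEs, proportion with an epigenetic effect, mean extent of spread, and
#' mean percent increase. LTR-type families are compared with the others
#' on each metric by Mann-Whitney.
#'
#' @param effects output of [spread_effects()].
#' @param min_n minimum family size (default 2).
#' @return list with `families` (data.frame) and `ltr_tests` (data.frame
#'   `metric, p, median_ltr, median_other`).
#' @export
family_summaries <- function(effects, min_n = 2) {
  fam <- do.call(rbind, lapply(split(effects, effects$family), function(e)
    data.frame(family = e$family[1], te_type = e$te_type[1], n = nrow(e),
               prop_with_effect = mean(e$has_effect),
               mean_extent_kb = mean(e$extent_kb),
               mean_pct_increase = mean(e$pct_increase),
               stringsAsFactors = FALSE)))
  fam <- fam[fam$n >= min_n, , drop = FALSE]
  rownames(fam) <- NULL
  metrics <- c("prop_with_effect", "mean_extent_kb", "mean_pct_increase")
  is_ltr <- fam$te_type == "LTR"
  ltr_tests <- do.call(rbind, lapply(metrics, function(m) {
    if (sum(is_ltr) == 0 || sum(!is_ltr) == 0)
      return(data.frame(metric = m, p = NA_real_, median_ltr = NA_real_,
                        median_other = NA_real_))
    data.frame(metric = m,
               p = mwu_p(fam[[m]][is_ltr], fam[[m]][!is_ltr],
                         alternative = "two.sided"),
               median_ltr = stats::median(fam[[m]][is_ltr]),
               median_other = stats::median(fam[[m]][!is_ltr]),
               stringsAsFactors = FALSE)
  }))
  list(families = fam, ltr_tests = ltr_tests)
}

#' Spearman correlations of family covariates with effect metrics
#'
#' Rank correlations between family-level covariates (piRNA counts in two
#' genotypes, siRNA counts from two sources, family copy number, ...) and
#' the three family effect metrics, optionally leaving out named outlier
#' families.
#'
#' @param fam_sum `families` data.frame from [family_summaries()].
#' @param covariates data.frame keyed by `family` with numeric covariate
#'   columns.
#' @param exclude_families optional families to drop before testing.
#' @return data.frame `covariate, metric, n, rho, p`.
#' @export
covariate_correlations <- function(fam_sum, covariates,
                                   exclude_families = NULL) {
  df <- merge(fam_sum, covariates, by = "family")
  if (!is.null(exclude_families))
    df <- df[!(df$family %in% exclude_families), , drop = FALSE]
  metrics <- c("prop_with_effect", "mean_extent_kb", "mean_pct_increase")
  covs <- setdiff(names(covariates), "family")
  grid <- expand.grid(covariate = covs, metric = metrics,
                      stringsAsFactors = FALSE)
  grid$n <- nrow(df)
  res <- t(vapply(seq_len(nrow(grid)), function(i) {
    ct <- suppressWarnings(
      stats::cor.test(df[[grid$covariate[i]]], df[[grid$metric[i]]],
                      method = "spearman"))
    c(ct$estimate, ct$p.value)
  }, c(rho = 1, p = 1)))
  grid$rho <- res[, 1]
  grid$p <- res[, 2]
  grid
}

#' Mean meta-profile of enrichment around a TE set
#'
#' Convenience summary for plotting: per 1-kb window index and side, the
#' across-TE mean of the median normalized enrichment per strain, with an
#' optional LOESS smooth over signed distance (span 0.1).
#'
#' @param tes curated TE data.frame with `strain`.
#' @param tracks named list of combined tracks per strain.
#' @param assembly a [genome_assembly()].
#' @param span LOESS span (default 0.1); `NULL` to skip smoothing.
#' @param ... passed to [build_profile()].
#' @return data.frame `distance_kb, mean_with, mean_without, smooth_with,
#'   smooth_without`.
#' @export
meta_profile <- function(tes, tracks, assembly, span = 0.1, ...) {
  strains <- names(tracks)
  acc <- list()
  for (k in seq_len(nrow(tes))) {
    te <- tes[k, , drop = FALSE]
    other <- setdiff(strains, te$strain)[1]
    pr <- normalize_between_strains(
      build_profile(te, tracks[[te$strain]], tracks[[other]], assembly, ...))
    for (side in c("left", "right"))
      for (i in seq_len(pr$n_win)) {
        s <- pr$samples[[side]][[i]]
        acc[[length(acc) + 1]] <- data.frame(
          distance_kb = if (side == "right") i - 0.5 else -(i - 0.5),
          med_with = stats::median(s$with),
          med_without = stats::median(s$without))
      }
  }
  d <- do.call(rbind, acc)
  out <- stats::aggregate(cbind(med_with, med_without) ~ distance_kb, d, mean)
  names(out)[2:3] <- c("mean_with", "mean_without")
  if (!is.null(span) && nrow(out) > 10) {
    # a 10% span needs enough points per neighbourhood; floor it so the
    # local fits stay determined on short meta-profiles
    sp <- max(span, 7 / nrow(out))
    out$smooth_with <- stats::predict(
      stats::loess(mean_with ~ distance_kb, out, span = sp))
    out$smooth_without <- stats::predict(
      stats::loess(mean_without ~ distance_kb, out, span = sp))
  }
  out
}
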