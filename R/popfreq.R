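#' Call TE presence/absence for one individual from contig spans
#'
#' Calling rules, applied to all contigs of one (TE, individual) pair:
#' absent if any contig spans the insertion site with at least 50 aligned
#' bp on both sides (direct evidence of the empty site; takes precedence);
#' otherwise present if any contig with a blast hit to TE sequence aligns
#' at least 30 bp left or right of the insertion site without spanning it;
#' anything else is missing data.
#'
#' @param spans data.frame of contig records for one TE x individual:
#'   `bp_left, bp_right, spans_insertion_site, te_hit`.
#' @param absent_bp,present_bp rule thresholds (defaults 50 and 30).
#' @return `"present"`, `"absent"`, or `"missing"`.
#' @export
call_presence <- function(spans, absent_bp = 50, present_bp = 30) {
  if (is.null(spans) || nrow(spans) == 0) return("missing")
  if (any(spans$spans_insertion_site & spans$bp_left >= absent_bp &
            spans$bp_right >= absent_bp))
    return("absent")
  if (any(spans$te_hit & !spans$spans_insertion_site &
            (spans$bp_left >= present_bp | spans$bp_right >= present_bp)))
    return("present")
  "missing"
}

#' Presence calls for a whole span table
#'
#' @param spans data.frame with `te_id, individual` plus the columns of
#'   [call_presence()].
#' @param individuals optional full individual roster; pairs with no
#'   contig record are called missing.
#' @inheritParams call_presence
#' @return data.frame `te_id, individual, call` (one row per pair).
#' @export
call_presence_all <- function(spans, individuals = NULL,
                              absent_bp = 50, present_bp = 30) {
  if (is.null(individuals)) individuals <- sort(unique(spans$individual))
  te_ids <- sort(unique(spans$te_id))
  key <- split(seq_len(nrow(spans)),
               list(te = spans$te_id, ind = spans$individual), drop = TRUE)
  grid <- expand.grid(individual = individuals, te_id = te_ids,
                      stringsAsFactors = FALSE)[, c("te_id", "individual")]
  grid$call <- vapply(seq_len(nrow(grid)), function(i) {
    idx <- key[[paste(grid$te_id[i], grid$individual[i], sep = ".")]]
    if (is.null(idx)) "missing"
    else call_presence(spans[idx, , drop = FALSE], absent_bp, present_bp)
  }, "")
  grid
}

#' Population frequency per TE
#'
#' Frequency is `present / (present + absent)`; TEs with fewer than
#' `min_called` informative alleles (of the panel's `total_alleles`) are
#' excluded. A TE observed in at least one sampled genome is classed high
#' frequency; one absent from every called genome is low frequency.
#'
#' @param calls data.frame from [call_presence_all()].
#' @param min_called minimum called alleles to include a TE (default 100).
#' @param total_alleles panel size, recorded for reference (default 197).
#' @return data.frame `te_id, n_called, n_present, frequency,
#'   high_frequency` (excluded TEs dropped).
#' @export
estimate_frequencies <- function(calls, min_called = 100,
                                 total_alleles = 197) {
  out <- do.call(rbind, lapply(split(calls, calls$te_id), function(x) {
    n_called <- sum(x$call != "missing")
    n_present <- sum(x$call == "present")
    data.frame(te_id = x$te_id[1], n_called = n_called,
               n_present = n_present,
               frequency = if (n_called > 0) n_present / n_called else NA_real_,
               high_frequency = n_present >= 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "total_alleles") <- total_alleles
  out[out$n_called >= min_called, , drop = FALSE]
}

#' Tests relating population frequency to epigenetic effects
#'
#' Fisher's exact test on the 2x2 table of frequency class (low = absent
#' from the population sample) x epigenetic-effect call, Mann-Whitney
#' comparisons of extent and percent increase between frequency classes,
#' and Spearman correlations of each index with per-TE frequency.
#'
#' @param effects [spread_effects()] table.
#' @param freqs [estimate_frequencies()] table.
#' @return list `fisher` (`odds_ratio, p, table`), `mw` (data.frame),
#'   `spearman` (data.frame).
#' @export
frequency_effect_tests <- function(effects, freqs) {
  df <- merge(effects, freqs, by = "te_id")
  tab <- table(factor(!df$high_frequency, c(TRUE, FALSE),
                      c("low", "high")),
               factor(df$has_effect, c(TRUE, FALSE),
                      c("effect", "no_effect")))
  ft <- stats::fisher.test(tab)
  mw <- do.call(rbind, lapply(c("extent_kb", "pct_increase"), function(v)
    data.frame(index = v,
               median_low = stats::median(df[[v]][!df$high_frequency]),
               median_high = stats::median(df[[v]][df$high_frequency]),
               p = mwu_p(df[[v]][!df$high_frequency],
                         df[[v]][df$high_frequency],
                         alternative = "two.sided"),
               stringsAsFactors = FALSE)))
  sp <- do.call(rbind, lapply(c("extent_kb", "pct_increase"), function(v) {
    ct <- tryCatch(
      suppressWarnings(stats::cor.test(df[[v]], df$frequency,
                                       method = "spearman")),
      error = function(e) list(estimate = NA_real_, p.value = NA_real_))
    data.frame(index = v, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  list(fisher = list(odds_ratio = unname(ft$estimate), p = ft$p.value,
                     table = tab),
       mw = mw, spearman = sp)
}

fit_one <- function(expr, env = parent.frame()) {
  tryCatch(suppressWarnings(suppressMessages(eval(expr, env))),
           error = function(e) NULL)
}

coef_row <- function(model_name, fit, term = "effect") {
  if (is.null(fit))
    return(data.frame(model = model_name, estimate = NA_real_,
                      se = NA_real_, p = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE))
  if (inherits(fit, "merMod")) {
    cc <- lme4::fixef(fit)
    vc <- sqrt(diag(as.matrix(stats::vcov(fit))))
    est <- cc[[term]]; se <- vc[[which(names(cc) == term)]]
    p <- 2 * stats::pnorm(-abs(est / se))
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
  } else if (inherits(fit, "lme")) {  # glmmPQL
    tt <- summary(fit)$tTable
    est <- tt[term, "Value"]; se <- tt[term, "Std.Error"]
    p <- tt[term, "p-value"]; conv <- TRUE
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[term, 1]; se <- sm[term, 2]; p <- sm[term, 4]
    conv <- is.null(fit$converged) || isTRUE(fit$converged)
    if (!is.null(fit$boundary) && fit$boundary) conv <- FALSE
    # quasi-complete separation leaves glm "converged" with an exploding
    # standard error; flag it as divergence
    if (!is.finite(se) || se > 50) conv <- FALSE
  }
  data.frame(model = model_name, estimate = unname(est), se = unname(se),
             p = unname(p), converged = conv, stringsAsFactors = FALSE)
}

#' Family-aware regressions of population frequency on epigenetic effects
#'
#' Fits the six model forms relating a TE's population frequency to its
#' epigenetic effect with TE family as covariate: logistic on the
#' high/low-frequency indicator, quasi-Poisson and negative binomial on
#' the insertion count, each with family as a fixed effect (glm /
#' MASS::glm.nb) or as a random intercept (lme4::glmer / glmer.nb;
#' quasi-Poisson random intercept via MASS::glmmPQL). Non-converging fits
#' are flagged and reported as NA rows.
#'
#' @param df data.frame with columns `effect` (the epigenetic-effect
#'   index), `family`, `high_freq` (0/1), `count` (non-negative integer).
#' @param models subset of the six model names to fit.
#' @return data.frame `model, estimate, se, p, converged` for the effect
#'   coefficient.
#' @export
fit_frequency_models <- function(df,
                                 models = c("logistic_fixed",
                                            "logistic_random",
                                            "quasipoisson_fixed",
                                            "quasipoisson_random",
                                            "negbin_fixed",
                                            "negbin_random")) {
  if (length(unique(df$effect)) < 2) {
    return(data.frame(model = models, estimate = NA_real_, se = NA_real_,
                      p = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  df$family <- factor(df$family)
  one_family <- nlevels(df$family) < 2
  f_bin <- if (one_family) high_freq ~ effect else high_freq ~ effect + family
  f_cnt <- if (one_family) count ~ effect else count ~ effect + family
  res <- list()
  for (m in models) {
    fit <- switch(
      m,
      logistic_fixed = fit_one(quote(
        stats::glm(f_bin, stats::binomial, data = df))),
      logistic_random = if (one_family) NULL else fit_one(quote(
        lme4::glmer(high_freq ~ effect + (1 | family), data = df,
                    family = stats::binomial))),
      quasipoisson_fixed = fit_one(quote(
        stats::glm(f_cnt, stats::quasipoisson, data = df))),
      quasipoisson_random = if (one_family) NULL else fit_one(quote(
        MASS::glmmPQL(count ~ effect, random = ~ 1 | family,
                      family = stats::quasipoisson, data = df,
                      verbose = FALSE))),
      negbin_fixed = fit_one(quote(
        MASS::glm.nb(f_cnt, data = df))),
      negbin_random = if (one_family) NULL else fit_one(quote(
        lme4::glmer.nb(count ~ effect + (1 | family), data = df))))
    res[[m]] <- coef_row(m, fit)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
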