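#!/usr/bin/env Rscript
# Stage 5 — population frequencies: presence/absence calls from contig
# alignment spans across the 197-allele panel, frequency estimation,
# frequency-vs-effect tests, and the family-aware regressions.

source("analysis/00_config.R")

cfg <- analysis_config()
sim <- simulate_tracks(cfg)
combined <- lapply(sim$tracks, combine_replicates)
cur <- curate_tes(sim$te_tables$s1, sim$te_tables$s2, sim$assembly,
                  buffer_bp = 0)
names(cur$kept) <- names(sim$tracks)
tes <- rbind(cur$kept$s1, cur$kept$s2)
eff <- spread_effects(tes, combined, sim$assembly, method = "two_strain")

panel <- simulate_population_panel(sim$truth, cfg)
calls <- call_presence_all(
  panel$spans,
  individuals = sprintf("ind%03d", seq_len(cfg$population$n_individuals)))
freqs <- estimate_frequencies(calls,
                              min_called = cfg$population$min_called,
                              total_alleles = cfg$population$n_individuals)
cat(sprintf("TEs with >= %d called alleles: %d; low-frequency (absent): %.1f%%\n",
            cfg$population$min_called, nrow(freqs),
            100 * mean(!freqs$high_frequency)))

ft <- frequency_effect_tests(eff, freqs)
cat(sprintf("\nlow/high frequency x effect: OR = %.2f, Fisher p = %.3g\n",
            ft$fisher$odds_ratio, ft$fisher$p))
print(ft$mw, digits = 3)
print(ft$spearman, digits = 3)

mdf <- merge(eff, freqs, by = "te_id")
models <- do.call(rbind, lapply(c("extent_kb", "pct_increase"), function(v) {
  out <- fit_frequency_models(
    data.frame(effect = mdf[[v]], family = mdf$family,
               high_freq = as.integer(mdf$high_frequency),
               count = mdf$n_present))
  out$index <- v
  out
}))
cat("\nfrequency ~ effect + family model fits:\n")
print(models, digits = 3)

d <- results_dir()
write_tsv(calls, file.path(d, "presence_calls.tsv"))
write_tsv(freqs, file.path(d, "frequencies.tsv"))
write_tsv(models, file.path(d, "frequency_models.tsv"))
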