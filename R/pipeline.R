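#' Run the full synthetic-data pipeline
#'
#' One-command end-to-end run on generated data with known ground truth:
#' simulate tracks, curate the TE catalogs, quantify per-TE epigenetic
#' effects by both methods, run the gene-level, population-frequency,
#' expression, and k-mer analyses, and (optionally) write every result
#' table to a directory. Re-running with the same configuration yields
#' byte-identical tables.
#'
#' @param config a [sim_config()]; its `seed` drives every stage.
#' @param outdir output directory for TSV tables; `NULL` to skip writing.
#' @param buffer_bp euchromatin buffer passed to [curate_tes()]; the
#'   generator places TEs inside already-analyzable euchromatin, so the
#'   default here is 0 (real catalogs use 5e5).
#' @return (invisibly) a list with all stage outputs and a `manifest`.
#' @export
run_full <- function(config = sim_config(), outdir = NULL, buffer_bp = 0) {
  sim <- simulate_tracks(config)
  strains <- names(config$strain_baseline)
  combined <- lapply(sim$tracks, combine_replicates)

  cur <- curate_tes(sim$te_tables[[1]], sim$te_tables[[2]], sim$assembly,
                    buffer_bp = buffer_bp)
  names(cur$kept) <- strains
  tes <- rbind(cur$kept[[1]], cur$kept[[2]])

  eff2 <- spread_effects(tes, combined, sim$assembly, method = "two_strain")
  effr <- spread_effects(tes, combined, sim$assembly, method = "relative")
  fam <- family_summaries(eff2)

  genes <- simulate_genes(sim$truth, config)
  expr_sim <- simulate_expression(genes, sim$truth, config)
  enr <- gene_body_enrichment(genes, sim$tracks, sim$assembly)
  enr$mat <- quantile_normalize(enr$mat)

  panel <- simulate_population_panel(sim$truth, config)
  calls <- call_presence_all(panel$spans,
                             individuals = sprintf("ind%03d",
                                                   seq_len(config$population$n_individuals)))
  min_called <- if (!is.null(config$population$min_called))
    config$population$min_called else 100
  freqs <- estimate_frequencies(calls, min_called = min_called,
                                total_alleles = config$population$n_individuals)
  freq_tests <- frequency_effect_tests(eff2, freqs)
  mdf <- merge(eff2, freqs, by = "te_id")
  freq_models <- do.call(rbind, lapply(
    c(extent_kb = "extent_kb", pct_increase = "pct_increase"),
    function(v) {
      d <- data.frame(effect = mdf[[v]], family = mdf$family,
                      high_freq = as.integer(mdf$high_frequency),
                      count = mdf$n_present)
      out <- fit_frequency_models(d)
      out$index <- v
      out
    }))

  rec <- gene_epi_table(genes, enr,
                        tes_by_strain = cur$kept,
                        reference_strain = strains[1],
                        effects = eff2, freqs = freqs)
  strata <- stratified_z_comparisons(rec)

  lfc <- log2_fold_change(expr_sim$counts, expr_sim$samples,
                          strain_a = strains[2], strain_b = strains[1])
  rp <- rpkm(expr_sim$counts, expr_sim$gene_length)
  filt <- expressed_filter(expr_sim$counts, expr_sim$expressed, rp)
  expr_by_strain <- lapply(strains, function(s)
    rowMeans(rp[, expr_sim$samples$strain == s, drop = FALSE]))
  names(expr_by_strain) <- strains
  enr_expr <- enrichment_expression_correlation(rec, expr_by_strain)
  quad <- quadrant_contingency(rec, lfc, reference_strain = strains[1])

  kmer <- kmer_species_analysis(simulate_reads(config))

  manifest <- data.frame(
    key = c("seed", "n_tes", "n_shared_tes", "n_curated", "n_genes",
            "n_individuals", "n_freq_tes", "n_kmer_libraries"),
    value = c(config$seed, config$n_tes, config$n_shared_tes, nrow(tes),
              nrow(genes), config$population$n_individuals, nrow(freqs),
              nrow(kmer$amounts)))

  res <- list(config = config, sim = sim, curation = cur,
              effects_two_strain = eff2, effects_relative = effr,
              family_summaries = fam, genes = genes,
              gene_records = rec, strata = strata,
              presence_calls = calls, frequencies = freqs,
              frequency_tests = freq_tests, frequency_models = freq_models,
              expression = expr_sim, log2fc = lfc,
              expressed_report = filt$report,
              enrichment_expression = enr_expr, quadrant = quad,
              kmer = kmer, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) write_tsv(df, file.path(outdir, name))
    w(res$curation$report, "curation_report.tsv")
    w(eff2, "effects_two_strain.tsv")
    w(effr, "effects_relative.tsv")
    w(fam$families, "family_summaries.tsv")
    w(fam$ltr_tests, "family_ltr_tests.tsv")
    w(rec, "gene_epi.tsv")
    w(strata$tests, "gene_strata_tests.tsv")
    w(calls, "presence_calls.tsv")
    w(freqs, "frequencies.tsv")
    w(freq_models, "frequency_models.tsv")
    w(data.frame(index = freq_tests$mw$index, p = freq_tests$mw$p,
                 fisher_or = freq_tests$fisher$odds_ratio,
                 fisher_p = freq_tests$fisher$p),
      "frequency_tests.tsv")
    w(kmer$amounts, "kmer_amounts.tsv")
    w(kmer$anova, "kmer_anova.tsv")
    w(data.frame(gene_id = names(lfc), log2fc = unname(lfc)),
      "log2_fold_change.tsv")
    w(quad$by_gene, "quadrant_genes.tsv")
    w(manifest, "manifest.tsv")
  }
  invisible(res)
}
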