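#!/usr/bin/env Rscript
# Stage 7 — expression consequences: RPKM, between-strain fold changes,
# the enrichment/expression quadrant contingency, and between-"species"
# rank z-scores with a gene-set shift test (here the two strains stand in
# for the two species panels).

source("analysis/00_config.R")

cfg <- analysis_config()
sim <- simulate_tracks(cfg)
combined <- lapply(sim$tracks, combine_replicates)
cur <- curate_tes(sim$te_tables$s1, sim$te_tables$s2, sim$assembly,
                  buffer_bp = 0)
names(cur$kept) <- names(sim$tracks)
tes <- rbind(cur$kept$s1, cur$kept$s2)
eff <- spread_effects(tes, combined, sim$assembly, method = "two_strain")
genes <- simulate_genes(sim$truth, cfg)
enr <- gene_body_enrichment(genes, sim$tracks, sim$assembly)
enr$mat <- quantile_normalize(enr$mat)
rec <- gene_epi_table(genes, enr, tes_by_strain = cur$kept,
                      reference_strain = "s1", effects = eff)

ex <- simulate_expression(genes, sim$truth, cfg)
rp <- rpkm(ex$counts, ex$gene_length)
filt <- expressed_filter(ex$counts, ex$expressed, rp)
cat("expressed-gene filter:\n"); print(filt$report, digits = 3)

lfc <- log2_fold_change(ex$counts, ex$samples, "s2", "s1")
quad <- quadrant_contingency(rec, lfc, reference_strain = "s1")
cat("\nquadrant contingency (all TE-adjacent genes vs 'neither'):\n")
print(quad$table)
cat(sprintf("Fisher OR = %.2f, p = %.3g\n",
            quad$fisher$odds_ratio, quad$fisher$p))

expr_by_strain <- lapply(c("s1", "s2"), function(s)
  rowMeans(rp[, ex$samples$strain == s, drop = FALSE]))
names(expr_by_strain) <- c("s1", "s2")
cat("\nenrichment vs expression among TE-adjacent genes (Spearman):\n")
print(enrichment_expression_correlation(rec, expr_by_strain), digits = 3)

ortho <- data.frame(gene_a = rownames(rp), gene_b = rownames(rp))
z <- species_rank_z(rp[, ex$samples$strain == "s2", drop = FALSE],
                    rp[, ex$samples$strain == "s1", drop = FALSE], ortho)
zv <- setNames(z$z, z$gene_a)
shift_set <- rec$gene_id[!is.na(rec$te_has_effect) & rec$te_has_effect]
gs <- gene_set_shift(zv, shift_set)
cat(sprintf("\nrank-z shift of genes near effect-TEs: KS D = %.3f, p = %.3g (n = %d)\n",
            gs$ks$statistic, gs$ks$p, length(shift_set)))

d <- results_dir()
write_tsv(data.frame(gene_id = names(lfc), log2fc = unname(lfc)),
          file.path(d, "log2_fold_change.tsv"))
write_tsv(quad$by_gene, file.path(d, "quadrant_genes.tsv"))
write_tsv(z, file.path(d, "species_rank_z.tsv"))
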