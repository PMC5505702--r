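# Shared settings for the analysis scripts. Everything downstream is
# deterministic given this seed; rerun any script independently and it
# regenerates what it needs.

library(tespread)

ANALYSIS_SEED <- 20260922L

analysis_config <- function(seed = ANALYSIS_SEED) {
  sim_config(
    seed = seed,
    n_chroms = 2, chrom_length = 2.3e6,   # 88 insertion slots
    n_tes = 80, n_shared_tes = 6,
    spread = list(boost = 3, extent_kb = 0:8, decay_kb = 1),
    kmer = utils::modifyList(sim_config()$kmer, list(n_reads = 2500)))
}

results_dir <- function() {
  d <- "results"
  dir.create(d, showWarnings = FALSE)
  d
}
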