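#!/usr/bin/env Rscript
# Stage 2 — curate the per-strain TE catalogs: same-family merging,
# cross-family cluster exclusion, strain-shared exclusion. The simulated
# euchromatin bounds are already the analyzable span, so no boundary
# buffer is applied here (real catalogs use 0.5 Mb).

source("analysis/00_config.R")

cfg <- analysis_config()
sim <- simulate_tracks(cfg)
cur <- curate_tes(sim$te_tables$s1, sim$te_tables$s2, sim$assembly,
                  buffer_bp = 0)

cat("curation dispositions:\n")
print(table(cur$report$disposition))
stopifnot(sum(cur$report$disposition == "kept") ==
            nrow(cur$kept$a) + nrow(cur$kept$b))
cat(sprintf("analyzable strain-unique TEs: %d (s1) + %d (s2)\n",
            nrow(cur$kept$a), nrow(cur$kept$b)))

write_tsv(cur$report, file.path(results_dir(), "curation_report.tsv"))
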