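# Generator contracts: determinism, marginals, injected structure.

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length = 4e5, n_tes = 5)
  s1 <- simulate_tracks(cfg)
  s2 <- simulate_tracks(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(S4Vectors::runValue(s1$tracks$s1$r1$rles$chr1),
                   S4Vectors::runValue(s2$tracks$s1$r1$rles$chr1))
  p1 <- simulate_population_panel(s1$truth, cfg)
  p2 <- simulate_population_panel(s2$truth, cfg)
  expect_identical(p1$spans, p2$spans)
  r1 <- simulate_reads(cfg)
  r2 <- simulate_reads(cfg)
  expect_identical(r1$libraries$ip$reads, r2$libraries$ip$reads)
})

test_that("background marginals match the configured lognormal", {
  cfg <- sim_config(seed = 3, n_chroms = 1, chrom_length = 1.1e6, n_tes = 2,
                    strain_baseline = c(s1 = 1, s2 = 1),
                    spread = list(boost = 1, extent_kb = 0, decay_kb = 1))
  sim <- simulate_tracks(cfg)
  v <- as.numeric(sim$tracks$s1$r1$rles$chr1)
  expect_gte(length(v), 1e5)  # >= 1e6 bases at 10-bp resolution
  target <- exp(cfg$background$meanlog + cfg$background$sdlog^2 / 2)
  expect_lt(abs(mean(v) - target) / target, 0.02)
})

test_that("boost 1 yields exchangeable strains; boost 3 injects a 3x plateau", {
  null_cfg <- sim_config(seed = 8, n_chroms = 1, chrom_length = 4e5,
                         n_tes = 4, strain_baseline = c(s1 = 1, s2 = 1),
                         replicate = list(n = 1, sdlog = 0),
                         spread = list(boost = 1, extent_kb = 5, decay_kb = 1))
  sim <- simulate_tracks(null_cfg)
  t1 <- sim$truth[1, ]
  w <- bin_means(sim$tracks$s1$r1, t1$chrom, t1$end, t1$end + 5000)
  o <- bin_means(sim$tracks$s2$r1, t1$chrom, t1$end, t1$end + 5000)
  expect_lt(abs(log(median(w) / median(o))), 0.2)

  cfg <- sim_config(seed = 8, n_chroms = 1, chrom_length = 4e5,
                    n_tes = 4, strain_baseline = c(s1 = 1, s2 = 1),
                    replicate = list(n = 1, sdlog = 0),
                    spread = list(boost = 3, extent_kb = 5, decay_kb = 1))
  sim <- simulate_tracks(cfg)
  for (i in 1:4) {
    te <- sim$truth[i, ]
    with_tr <- sim$tracks[[te$carrier]]$r1
    without_tr <- sim$tracks[[setdiff(c("s1", "s2"), te$carrier)]]$r1
    inside_w <- bin_means(with_tr, te$chrom, te$end, te$end + 5000)
    inside_o <- bin_means(without_tr, te$chrom, te$end, te$end + 5000)
    beyond_w <- bin_means(with_tr, te$chrom, te$end + 7000, te$end + 12000)
    beyond_o <- bin_means(without_tr, te$chrom, te$end + 7000, te$end + 12000)
    expect_lt(abs(median(inside_w) / median(inside_o) - 3), 0.45)
    expect_lt(abs(median(beyond_w) / median(beyond_o) - 1), 0.15)
  }
})

test_that("placement density errors when the genome cannot hold the TEs", {
  expect_error(simulate_tracks(sim_config(n_chroms = 1, chrom_length = 2e5,
                                          n_tes = 50)),
               "infeasible")
})

test_that("population panel couples frequency to effect size as configured", {
  cfg0 <- sim_config(seed = 17, n_chroms = 1, chrom_length = 1.6e6,
                     n_tes = 30,
                     population = list(n_individuals = 60, intercept = 0,
                                       coupling = 0, missing_rate = 0.1))
  sim <- simulate_tracks(cfg0)
  p0 <- simulate_population_panel(sim$truth, cfg0)
  expect_true(all(p0$truth$true_freq == 0.5))  # null coupling

  cfg1 <- sim_config(seed = 17, n_chroms = 1, chrom_length = 1.6e6,
                     n_tes = 30,
                     population = list(n_individuals = 60, intercept = 0,
                                       coupling = 1, missing_rate = 0.1))
  p1 <- simulate_population_panel(sim$truth, cfg1)
  calls <- call_presence_all(p1$spans,
                             individuals = sprintf("ind%03d", 1:60))
  fr <- estimate_frequencies(calls, min_called = 10, total_alleles = 60)
  m <- merge(fr, p1$truth, by = "te_id")
  expect_lt(suppressWarnings(
    cor(m$frequency, m$extent_kb, method = "spearman")), -0.5)

  cfg2 <- sim_config(seed = 17, n_chroms = 1, chrom_length = 1.6e6,
                     n_tes = 30,
                     population = list(n_individuals = 20, intercept = 0,
                                       coupling = 0, missing_rate = 1))
  p2 <- simulate_population_panel(sim$truth, cfg2)
  calls2 <- call_presence_all(p2$spans,
                              individuals = sprintf("ind%03d", 1:20))
  expect_true(all(calls2$call == "missing"))
})

test_that("expression counts are negatively coupled to gene-body enrichment", {
  base <- list(seed = 19, n_chroms = 1, chrom_length = 2.6e6, n_tes = 50)
  cfg <- do.call(sim_config, c(base, list(
    spread = list(boost = 3, extent_kb = c(0, 4, 8), decay_kb = 1))))
  sim <- simulate_tracks(cfg)
  genes <- simulate_genes(sim$truth, cfg)
  ex <- simulate_expression(genes, sim$truth, cfg)
  s1 <- rowMeans(ex$counts[, ex$samples$strain == "s1"])
  ok <- !genes$silent
  rho <- suppressWarnings(cor(ex$true_mult[ok, "s1"], s1[ok],
                              method = "spearman"))
  expect_lt(rho, -0.2)

  cfg0 <- do.call(sim_config, c(base, list(
    expression = utils::modifyList(cfg$expression, list(coupling = 0)))))
  ex0 <- simulate_expression(genes, sim$truth, cfg0)
  s10 <- rowMeans(ex0$counts[, ex0$samples$strain == "s1"])
  rho0 <- suppressWarnings(cor(ex$true_mult[ok, "s1"], s10[ok],
                               method = "spearman"))
  expect_lt(abs(rho0), 0.15)
})

test_that("read simulation respects k-mer feasibility and embeds repeat structure", {
  cfg <- sim_config(kmer = utils::modifyList(sim_config()$kmer,
                                             list(read_length = 8)))
  expect_error(simulate_reads(cfg), "shorter than k")

  cfg <- sim_config(seed = 23,
                    kmer = utils::modifyList(sim_config()$kmer,
                                             list(n_reads = 800)))
  sim <- simulate_reads(cfg)
  expect_named(sim$libraries, c("ip", "input",
                                paste(rep(c("melanogaster", "simulans"),
                                          each = 4),
                                      rep(rep(c("prepA", "prepB"), each = 2), 2),
                                      rep(c("r1", "r2"), 4), sep = "_")),
               ignore.order = TRUE)
  expect_true(all(nchar(sim$libraries$ip$reads) == 100))
  # repeat reads really come from the repeat units
  unit_kmers <- count_kmers(sim$truth$units, k = 12)
  ip_kmers <- count_kmers(sim$libraries$ip$reads[1:200], k = 12)
  expect_gt(length(intersect(names(unit_kmers), names(ip_kmers))), 0)
})
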