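# Per-TE epigenetic-effect quantification.

# minimal profile object for formula-level tests
fake_profile <- function(w1_with, w1_without, n_win = 20) {
  samples <- list(left = vector("list", n_win),
                  right = vector("list", n_win))
  for (side in c("left", "right"))
    for (i in seq_len(n_win))
      samples[[side]][[i]] <- list(with = w1_with, without = w1_without)
  structure(list(te_id = "te", samples = samples,
                 usable = matrix(TRUE, 2, n_win,
                                 dimnames = list(c("left", "right"), NULL)),
                 flank_norm = c(with = 1, without = 1),
                 n_win = n_win, normalized = TRUE),
            class = "window_profile")
}

test_that("window profiles reproduce constant tracks and flag boundary windows", {
  asm <- genome_assembly("chr1", 2e5,
                         data.frame(chrom = "chr1", start = 0, end = 2e5))
  w <- seg_track(0, 2e5, 2, assembly = asm, chrom = "chr1")
  o <- seg_track(0, 2e5, 1, assembly = asm, chrom = "chr1")
  te <- te_row("t", "chr1", 1e5, 1e5 + 6)
  pr <- build_profile(te, w, o, asm)
  expect_true(all(pr$usable))
  expect_true(all(vapply(pr$samples$left, function(s)
    all(s$with == 2) && all(s$without == 1), TRUE)))
  expect_equal(unname(pr$flank_norm), c(2, 1))

  # TE 19 kb from the right euchromatin edge: window 20 unusable on that side
  asm2 <- genome_assembly("chr1", 2e5,
                          data.frame(chrom = "chr1", start = 0, end = 119006))
  pr2 <- build_profile(te, w, o, asm2)
  expect_false(pr2$usable["right", 20])
  expect_true(pr2$usable["right", 19])
  expect_true(all(pr2$usable["left", ]))
})

test_that("profile samples match the per-base binning oracle on random tracks", {
  len <- 100000
  asm <- genome_assembly("chr1", len,
                         data.frame(chrom = "chr1", start = 0, end = len))
  set.seed(21)
  rw <- random_track(len = len, n_seg = 300, assembly = asm)
  ro <- random_track(len = len, n_seg = 300, assembly = asm)
  te <- te_row("t", "chr1", 50000, 50006)
  pr <- build_profile(te, rw$track, ro$track, asm)
  for (i in c(1, 7, 20)) {
    b <- c(te$end + (i - 1) * 1000, te$end + i * 1000)
    o <- oracle_bin_means(rw$per_base, b[1], b[2], 10)
    expect_equal(pr$samples$right[[i]]$with, o[!is.na(o)])
    b <- c(te$start - i * 1000, te$start - (i - 1) * 1000)
    o <- oracle_bin_means(ro$per_base, b[1], b[2], 10)
    expect_equal(pr$samples$left[[i]]$without, o[!is.na(o)])
  }
})

test_that("between-strain normalization removes baselines and needs positive flanks", {
  pr <- fake_profile(rep(2, 50) * (1 + 1e-3 * 1:50),
                     rep(1, 50) * (1 + 1e-3 * 1:50))
  pr$flank_norm <- c(with = 2, without = 1)
  pr$normalized <- FALSE
  npr <- normalize_between_strains(pr)
  expect_equal(npr$samples$left[[1]]$with, npr$samples$left[[1]]$without)
  # monotone transform: rank order within strain unchanged
  expect_equal(rank(npr$samples$left[[1]]$with),
               rank(pr$samples$left[[1]]$with))
  pr$flank_norm <- c(with = 0, without = 1)
  expect_error(normalize_between_strains(pr), "not positive")
})

test_that("per-window test agrees with exact enumeration for small groups", {
  set.seed(13)
  for (n in c(4, 6, 8)) for (m in c(4, 8)) {
    x <- round(stats::runif(n, 0, 10), 6)
    y <- round(stats::runif(m, 0, 10), 6)
    pr <- fake_profile(x, y)
    got <- window_test(pr, 1, "left")$p
    expect_equal(got, oracle_mwu_exact(x, y), tolerance = 1e-12)
  }
  # identical samples are never significant
  pr <- fake_profile(rep(1.3, 40), rep(1.3, 40))
  expect_false(window_test(pr, 3, "right")$significant)
  # clear separation at n = 100 is
  pr <- fake_profile(stats::rnorm(100, 5), stats::rnorm(100, 0, 0.1))
  expect_true(window_test(pr, 1, "left")$significant)
  # unusable window -> not significant regardless of data
  pr$usable["left", 1] <- FALSE
  expect_false(window_test(pr, 1, "left")$significant)
})

test_that("extent of spread uses consecutive windows and the conservative side", {
  sig <- function(idx, n = 20) seq_len(n) %in% idx
  # left {1,2,3}, right {1,2} -> 2 (window closer to the TE)
  expect_equal(extent_of_spread(sig(1:3), sig(1:2))$extent_kb, 2)
  # consecutiveness breaks at 3 on the left
  expect_equal(extent_of_spread(sig(c(1, 2, 4)), sig(1:4))$extent_kb, 2)
  # window 1 not significant on one side -> no effect
  r <- extent_of_spread(sig(c(2, 3)), sig(1:3))
  expect_equal(r$extent_kb, 0)
  expect_false(r$has_effect)
  expect_true(extent_of_spread(sig(1), sig(1))$has_effect)
  # never exceeds the analyzed span
  expect_lte(extent_of_spread(sig(1:20), sig(1:20))$extent_kb, 20)
})

test_that("percent increase follows the median-difference formula", {
  pr <- fake_profile(c(1.7, 1.8, 1.9), c(0.9, 1.0, 1.1))
  expect_equal(pct_increase(pr), 0.8)
  pr <- fake_profile(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pct_increase(pr), 0)
  pr <- fake_profile(c(1, 2, 3), c(0, 0, 0))
  expect_error(pct_increase(pr), "zero")
})

test_that("relative profiles normalize by the higher flank median", {
  len <- 2e5
  asm <- genome_assembly("chr1", len,
                         data.frame(chrom = "chr1", start = 0, end = len))
  te <- te_row("t", "chr1", 1e5, 1e5 + 6)
  # left flank at 1.0, right flank at 1.2, windows at 1.1
  tr <- seg_track(c(0, 80000, 120006), c(80000, 120006, len),
                  c(1.0, 1.1, 1.2), assembly = asm)
  rp <- relative_profile(te, tr, asm)
  expect_equal(rp$norm, 1.2)
  expect_equal(rp$samples$right[[1]], rep(1.1 / 1.2, 100))

  # constant track -> all relative values 1; doubling changes nothing
  ct <- seg_track(0, len, 3, assembly = asm)
  rp1 <- relative_profile(te, ct, asm)
  expect_true(all(abs(unlist(rp1$samples) - 1) < 1e-12))
  ct2 <- seg_track(0, len, 6, assembly = asm)
  rp2 <- relative_profile(te, ct2, asm)
  expect_equal(unlist(rp2$samples), unlist(rp1$samples))
})

test_that("relative effect applies the sign test and median-minus-one increase", {
  rp <- structure(list(
    te_id = "t",
    samples = list(left = rep(list(rep(1, 100)), 20),
                   right = rep(list(rep(1, 100)), 20)),
    usable = matrix(TRUE, 2, 20, dimnames = list(c("left", "right"), NULL)),
    norm = 1, n_win = 20), class = "relative_profile")
  e <- relative_effect(rp)
  expect_false(e$has_effect)
  expect_equal(e$extent_kb, 0)
  expect_equal(e$pct_increase, 0)

  up <- rep(1.6, 100) + seq(0, 0.01, length.out = 100)
  rp$samples$left[[1]] <- up
  rp$samples$right[[1]] <- up
  e <- relative_effect(rp)
  expect_true(e$has_effect)
  expect_equal(e$pct_increase, stats::median(up) - 1)
})

test_that("family summaries require n >= 2 and match a direct rank-sum check", {
  eff <- data.frame(
    te_id = sprintf("t%02d", 1:9),
    family = c("roo", "roo", "gypsy", "gypsy", "jockey", "jockey",
               "pogo", "pogo", "lone"),
    te_type = c("LTR", "LTR", "LTR", "LTR", "non-LTR", "non-LTR",
                "TIR", "TIR", "TIR"),
    has_effect = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    extent_kb = c(5, 3, 6, 0, 0, 0, 2, 0, 9),
    pct_increase = c(2, 1.5, 2.5, -0.1, 0, 0.1, 0.7, 0, 3))
  fs <- family_summaries(eff)
  expect_false("lone" %in% fs$families$family)  # n = 1 excluded
  roo <- fs$families[fs$families$family == "roo", ]
  expect_equal(roo$n, 2)
  expect_equal(roo$prop_with_effect, 1)
  expect_equal(roo$mean_extent_kb, 4)
  expect_equal(roo$mean_pct_increase, 1.75)
  # LTR-vs-other comparison equals a direct wilcox on family values
  fam <- fs$families
  direct <- stats::wilcox.test(fam$mean_extent_kb[fam$te_type == "LTR"],
                               fam$mean_extent_kb[fam$te_type != "LTR"])$p.value
  expect_equal(fs$ltr_tests$p[fs$ltr_tests$metric == "mean_extent_kb"],
               direct)
})

test_that("covariate correlations reproduce the rank-based definition", {
  fam <- data.frame(family = paste0("f", 1:8),
                    te_type = "LTR", n = 2,
                    prop_with_effect = (1:8) / 8,
                    mean_extent_kb = c(3, 1, 4, 1, 5, 9, 2, 6),
                    mean_pct_increase = c(2, 7, 1, 8, 2, 8, 1, 8) / 4)
  cov <- data.frame(family = paste0("f", 1:8),
                    copy_number = fam$mean_extent_kb)       # identical -> rho 1
  res <- covariate_correlations(fam, cov)
  expect_equal(res$rho[res$metric == "mean_extent_kb"], 1)

  set.seed(2)
  cov$pirna <- sample(100:200, 8)
  res <- covariate_correlations(fam, cov)
  r <- res[res$covariate == "pirna" & res$metric == "mean_pct_increase", ]
  # midrank formula oracle
  oracle <- stats::cor(rank(cov$pirna), rank(fam$mean_pct_increase))
  expect_equal(r$rho, oracle, tolerance = 1e-12)
  # leave-one-out drops the named family
  res2 <- covariate_correlations(fam, cov, exclude_families = "f6")
  expect_true(all(res2$n == 7))
})

test_that("two-strain and relative methods recover injected spread on one fixture", {
  cfg <- sim_config(seed = 11, n_chroms = 1, chrom_length = 6e5, n_tes = 10,
                    spread = list(boost = 3, extent_kb = c(0, 2, 4, 6, 8),
                                  decay_kb = 1))
  sim <- simulate_tracks(cfg)
  combined <- lapply(sim$tracks, combine_replicates)
  tes <- do.call(rbind, lapply(names(sim$te_tables), function(s)
    sim$te_tables[[s]]))
  e2 <- spread_effects(tes, combined, sim$assembly, method = "two_strain")
  er <- spread_effects(tes, combined, sim$assembly, method = "relative")
  truth <- sim$truth[match(e2$te_id, sim$truth$te_id), ]
  expect_true(all(abs(e2$extent_kb - truth$extent_kb) <= 1))
  expect_true(all(e2$has_effect[truth$extent_kb >= 2]))
  expect_true(all(er$has_effect[truth$extent_kb >= 2]))
  expect_true(all(e2$extent_kb <= 20))
})
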