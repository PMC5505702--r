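# Domain types, coordinate arithmetic, file I/O, covariate utilities.

test_that("TE table reading applies the confidence threshold and validates input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "chr1", start = c(100, 200, 300),
                   end = c(110, 210, 310),
                   family = c("roo", "copia", "gypsy"),
                   te_type = "LTR", strain = "s1",
                   confidence = c(3.0, 2.9, 7.5))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  te <- read_te_table(path, min_confidence = 3)
  expect_equal(te$family, c("roo", "gypsy"))  # 3.0 retained, 2.9 dropped

  # empty file with header -> empty result
  write.table(df[0, ], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_te_table(path)), 0)

  # malformed numeric column names the offending line
  writeLines(c("chrom\tstart\tend\tfamily\tte_type\tstrain\tconfidence",
               "chr1\t100\t110\troo\tLTR\ts1\t5",
               "chr1\tfoo\t210\tcopia\tLTR\ts1\t5"), path)
  expect_error(read_te_table(path), "line 3")

  # unknown chromosome fails validation against the assembly
  write.table(transform(df, chrom = c("chr1", "chr1", "chrX")), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_te_table(path, assembly = tiny_assembly()), "chrX")
})

test_that("bedGraph round trip merges equal-valued neighbours and rejects overlaps", {
  asm <- tiny_assembly(1000)
  # adjacent intervals with equal value collapse to one run
  tr <- seg_track(c(0, 10), c(10, 20), c(1.5, 1.5), assembly = asm)
  expect_equal(sum(!is.na(S4Vectors::runValue(tr$rles$chr1))), 1)

  expect_error(seg_track(c(0, 5), c(10, 15), c(1, 2), assembly = asm),
               "overlap")
  expect_error(seg_track(0, 10, -1, assembly = asm), "negative")

  # write -> read reproduces the identical signal
  rt <- random_track(assembly = asm, len = 1000)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(rt$track, path)
  back <- read_bedgraph(path, asm)
  expect_identical(S4Vectors::runValue(back$rles$chr1),
                   S4Vectors::runValue(rt$track$rles$chr1))
  expect_identical(S4Vectors::runLength(back$rles$chr1),
                   S4Vectors::runLength(rt$track$rles$chr1))
})

test_that("mean_signal is a length-weighted mean matching a per-base oracle", {
  asm <- tiny_assembly(1000)
  const <- seg_track(0, 1000, 2.0, assembly = asm)
  expect_equal(mean_signal(const, "chr1", 123, 456), 2.0)
  halves <- seg_track(c(0, 500), c(500, 1000), c(1, 3), assembly = asm)
  expect_equal(mean_signal(halves, "chr1", 0, 1000), 2.0)
  expect_error(mean_signal(const, "chr1", 10, 10), "zero-length")

  set.seed(42)
  for (rep in 1:5) {
    rt <- random_track(assembly = asm, len = 1000)
    a <- sort(sample(0:999, 2)); if (a[1] == a[2]) a[2] <- a[2] + 1
    expect_equal(mean_signal(rt$track, "chr1", a[1], a[2]),
                 oracle_interval_mean(rt$per_base, a[1], a[2]))
  }
})

test_that("mean_signal is invariant under re-splitting of an identical signal", {
  asm <- tiny_assembly(1000)
  one <- seg_track(0, 1000, 2.5, assembly = asm)
  many <- seg_track(seq(0, 990, 10), seq(10, 1000, 10), rep(2.5, 100),
                    assembly = asm)
  for (iv in list(c(0, 1000), c(37, 613), c(995, 1000)))
    expect_equal(mean_signal(one, "chr1", iv[1], iv[2]),
                 mean_signal(many, "chr1", iv[1], iv[2]))
})

test_that("bin_means matches the per-base oracle including the coverage rule", {
  asm <- tiny_assembly(2000)
  set.seed(7)
  for (rep in 1:5) {
    rt <- random_track(assembly = asm, len = 2000, gap_prob = 0.3)
    got <- bin_means(rt$track, "chr1", 200, 1800, bin_bp = 10)
    expect_equal(got, oracle_bin_means(rt$per_base, 200, 1800, 10))
  }
  # bins beyond the chromosome are NA, not an error
  rt <- random_track(assembly = asm, len = 2000, gap_prob = 0)
  v <- bin_means(rt$track, "chr1", 1950, 2050, bin_bp = 10)
  expect_true(all(is.na(v[6:10])))
})

test_that("repeat density equals base-wise coverage of the 10-kb window", {
  asm <- tiny_assembly(50000)
  te <- list(chrom = "chr1", start = 25000, end = 25006)
  none <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0))
  expect_equal(repeat_density_10kb(te, none, asm), 0)
  full <- data.frame(chrom = "chr1", start = 0, end = 50000)
  expect_equal(repeat_density_10kb(te, full, asm), 1)

  set.seed(11)
  for (rep in 1:5) {
    s <- sort(sample(0:49000, 20))
    iv <- data.frame(chrom = "chr1", start = s, end = s + sample(50:900, 20))
    iv$end <- pmin(iv$end, 50000)
    mid <- 25003
    w <- c(mid - 5000, mid + 5000)
    base <- rep(FALSE, 50000)
    for (i in seq_len(nrow(iv))) base[(iv$start[i] + 1):iv$end[i]] <- TRUE
    expect_equal(repeat_density_10kb(te, iv, asm),
                 mean(base[(w[1] + 1):w[2]]))
  }
})

test_that("recombination interpolation is linear with nearest-value extension", {
  w <- data.frame(chrom = "chr1", midpoint = c(5e5, 15e5, 25e5),
                  rate = c(1, 3, 2))
  at <- function(pos) interpolate_recombination(
    list(chrom = "chr1", start = pos, end = pos), w)
  expect_equal(at(15e5), 3)          # knot identity
  expect_equal(at(10e5), 2)          # midway between rates 1 and 3
  expect_equal(at(1e5), 1)           # before first midpoint
  expect_equal(at(30e5), 2)          # beyond last midpoint
  expect_error(interpolate_recombination(
    list(chrom = "chrX", start = 1, end = 2), w), "chrX")
})

test_that("interval semantics are half-open: touching features do not overlap", {
  tes <- te_row("t1", "chr1", 100, 200)
  flags <- exclude_exonic_and_shared_peaks(
    tes, exons = data.frame(chrom = "chr1", start = 200, end = 300))
  expect_false(flags$exonic)
  flags <- exclude_exonic_and_shared_peaks(
    tes, exons = data.frame(chrom = "chr1", start = 199, end = 300))
  expect_true(flags$exonic)
})
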