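# TE catalog curation rules.

test_that("euchromatin buffer keeps only TEs fully past the 0.5-Mb buffer", {
  asm <- genome_assembly("chr1", 5e6,
                         data.frame(chrom = "chr1", start = 0, end = 5e6))
  tes <- rbind(te_row("near", "chr1", 3e5, 3e5 + 100),     # 0.3 Mb inside
               te_row("far", "chr1", 6e5, 6e5 + 100),      # 0.6 Mb inside
               te_row("straddle", "chr1", 499950, 500050)) # crosses buffer
  keep <- apply_euchromatin_buffer(tes, asm, buffer_bp = 5e5)
  expect_equal(keep, c(FALSE, TRUE, FALSE))

  small <- genome_assembly("chr2", 8e5,
                           data.frame(chrom = "chr2", start = 0, end = 8e5))
  t2 <- te_row("x", "chr2", 4e5, 4e5 + 100)
  expect_warning(keep2 <- apply_euchromatin_buffer(t2, small, 5e5),
                 "buffer exceeds")
  expect_false(keep2)
})

test_that("strain-shared flags follow the family x distance rule table", {
  a <- te_row("a1", "chr1", 1000, 1100)
  # same family, identical coordinates -> shared
  expect_false(mark_strain_unique(a, te_row("b1", "chr1", 1000, 1100))$a)
  # same family 600 bp apart, tolerance 100 -> unique
  expect_true(mark_strain_unique(a, te_row("b1", "chr1", 1600, 1700))$a)
  # different family at the same position -> unique
  expect_true(mark_strain_unique(
    a, te_row("b1", "chr1", 1000, 1100, family = "copia"))$a)

  # enumeration over the family x distance grid
  for (fam in c("roo", "copia"))
    for (d in c(0, 50, 100, 101, 400)) {
      b <- te_row("b1", "chr1", 1000 + d, 1100 + d, family = fam)
      expected_shared <- (fam == "roo") && (d <= 100)
      expect_equal(mark_strain_unique(a, b, tolerance_bp = 100)$a,
                   !expected_shared)
    }
})

test_that("same-family merging precedes cross-family cluster exclusion", {
  # two roo calls 300 bp apart -> one merged call
  x <- rbind(te_row("r1", "chr1", 1000, 1200),
             te_row("r2", "chr1", 1500, 1700))
  m <- merge_and_cluster(x)
  expect_equal(nrow(m$merged), 1)
  expect_equal(m$merged$start, 1000)
  expect_equal(m$merged$end, 1700)

  # roo and copia 1.5 kb apart -> both cluster-excluded
  y <- rbind(te_row("r1", "chr1", 1000, 1200),
             te_row("c1", "chr1", 2700, 2900, family = "copia"))
  m <- merge_and_cluster(y)
  expect_equal(nrow(m$merged), 0)
  expect_setequal(m$cluster_ids, c("r1", "c1"))

  # chain: A-B same family 400 bp apart merge; merged span then clusters
  # with C (different family, 1.9 kb away)
  z <- rbind(te_row("a", "chr1", 1000, 1200),
             te_row("b", "chr1", 1600, 1800),
             te_row("c", "chr1", 3700, 3900, family = "copia"))
  m <- merge_and_cluster(z)
  expect_equal(nrow(m$merged), 0)
  expect_setequal(m$cluster_ids, c("a", "c"))
  expect_equal(m$merge_map$merged_id[m$merge_map$id == "b"], "a")
})

test_that("merge_and_cluster is idempotent and order-independent", {
  set.seed(3)
  pos <- sort(sample(seq(1000, 60000, by = 100), 15))
  x <- do.call(rbind, lapply(seq_along(pos), function(i)
    te_row(paste0("t", i), "chr1", pos[i], pos[i] + 150,
           family = sample(c("roo", "copia", "gypsy"), 1))))
  m1 <- merge_and_cluster(x)
  m2 <- merge_and_cluster(m1$merged)
  expect_equal(m2$merged$start, m1$merged$start)
  expect_equal(m2$merged$end, m1$merged$end)
  expect_length(m2$cluster_ids, 0)

  perm <- x[sample(nrow(x)), ]
  mp <- merge_and_cluster(perm)
  expect_equal(mp$merged[order(mp$merged$start), c("start", "end", "family")],
               m1$merged[order(m1$merged$start), c("start", "end", "family")],
               ignore_attr = TRUE)
})

test_that("hit annotation enforces length, identity, uniqueness, and INE-1 rules", {
  hits <- data.frame(
    locus = c("L1", "L2", "L2", "L3", "L4", "L5"),
    te_family = c("roo", "roo", "copia", "gypsy", "INE-1", "roo"),
    length = c(90, 500, 400, 300, 500, 250),
    identity = c(95, 92, 93, 75, 95, 88),
    evalue = c(1e-30, 1e-40, 1e-40, 1e-20, 1e-50, 1e-10),
    chrom = "chr1", start = 1:6 * 1000, end = 1:6 * 1000 + 300)
  res <- annotate_from_hits(hits)
  disp <- setNames(res$report$disposition, res$report$locus)
  expect_equal(disp[["L1"]], "short")            # best hit only 90 bp
  expect_equal(disp[["L2"]], "ambiguous_family") # tie at smallest e-value
  expect_equal(disp[["L3"]], "low_identity")
  expect_equal(disp[["L4"]], "excluded_family")  # INE-1 always out
  expect_equal(disp[["L5"]], "kept")
  expect_equal(res$calls$locus, "L5")
})

test_that("exon/peak overlap exclusion matches a base-wise oracle", {
  set.seed(9)
  for (rep in 1:5) {
    tes <- do.call(rbind, lapply(1:10, function(i) {
      s <- sample(0:9000, 1)
      te_row(paste0("t", i), "chr1", s, s + sample(50:500, 1))
    }))
    s <- sample(0:9000, 8)
    exons <- data.frame(chrom = "chr1", start = s, end = s + sample(50:400, 8))
    base <- rep(FALSE, 10000)
    for (i in seq_len(nrow(exons)))
      base[(exons$start[i] + 1):pmin(exons$end[i], 10000)] <- TRUE
    oracle <- vapply(seq_len(nrow(tes)), function(i)
      any(base[(tes$start[i] + 1):pmin(tes$end[i], 10000)]), TRUE)
    expect_equal(exclude_exonic_and_shared_peaks(tes, exons)$exonic, oracle)
  }
})

test_that("curation report partitions the input TE set", {
  asm <- genome_assembly("chr1", 4e6,
                         data.frame(chrom = "chr1", start = 0, end = 4e6))
  set.seed(5)
  mk <- function(strain, n) do.call(rbind, lapply(seq_len(n), function(i) {
    s <- sample(seq(1e5, 3.8e6, by = 1000), 1)
    te_row(paste0(strain, "_t", i), "chr1", s, s + 200,
           family = sample(c("roo", "copia", "gypsy"), 1), strain = strain)
  }))
  a <- mk("s1", 30); b <- mk("s2", 30)
  b[1:3, c("start", "end", "family")] <- a[1:3, c("start", "end", "family")]
  exons <- data.frame(chrom = "chr1", start = seq(5e5, 3.5e6, by = 3e5),
                      end = seq(5e5, 3.5e6, by = 3e5) + 5000)
  cur <- curate_tes(a, b, asm, exons = exons, buffer_bp = 5e5)
  expect_equal(nrow(cur$report), nrow(a) + nrow(b))
  expect_setequal(cur$report$id, c(a$id, b$id))
  expect_equal(sum(cur$report$disposition == "kept"),
               nrow(cur$kept$a) + nrow(cur$kept$b))
  expect_true(all(cur$report$disposition %in%
                    c("kept", "heterochromatic", "shared_between_strains",
                      "cluster", "merged", "exonic", "shared_peak")))
  # the three planted shared TEs are flagged in both strains (when they
  # survive the earlier steps)
  shared_rows <- cur$report[cur$report$id %in% c(a$id[1:3], b$id[1:3]), ]
  expect_true(all(shared_rows$disposition %in%
                    c("shared_between_strains", "heterochromatic",
                      "cluster", "merged", "exonic")))
})
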