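#' RPKM normalization
#'
#' Reads per kilobase of exon per million mapped reads:
#' `count / (gene_kb * library_millions)`.
#'
#' @param counts genes x samples count matrix.
#' @param gene_length exonic length per gene (bp), named or in row order.
#' @param lib_sizes per-sample library sizes; column sums when NULL.
#' @return RPKM matrix.
#' @export
rpkm <- function(counts, gene_length, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  stopifnot(length(gene_length) == nrow(counts),
            length(lib_sizes) == ncol(counts), all(lib_sizes > 0))
  sweep(sweep(counts, 1, gene_length / 1000, "/"), 2, lib_sizes / 1e6, "/")
}

#' Median-of-ratios size factors
#'
#' Standard library-size normalization: per sample, the median across
#' genes of the ratio to the geometric-mean reference (genes with a zero
#' anywhere are excluded from the reference).
#'
#' @param counts genes x samples count matrix.
#' @return numeric size factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) stop("no gene with nonzero counts in every sample")
  apply(counts, 2, function(cj) exp(stats::median(log(cj[use]) -
                                                    log_geo[use])))
}

#' Between-strain log2 expression fold change
#'
#' Size-factor-normalized mean counts per strain, log2 ratio with a
#' pseudocount; positive values mean higher expression in `strain_a`. The
#' reference convention matters only through the sign: swapping the
#' strains negates the result.
#'
#' @param counts genes x samples count matrix.
#' @param samples data.frame `sample, strain` matching the columns.
#' @param strain_a,strain_b numerator and denominator (reference) strains.
#' @param pseudocount added to normalized means (default 0.5).
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(counts, samples, strain_a, strain_b,
                             pseudocount = 0.5) {
  counts <- as.matrix(counts)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  ma <- rowMeans(norm[, samples$strain == strain_a, drop = FALSE])
  mb <- rowMeans(norm[, samples$strain == strain_b, drop = FALSE])
  log2((ma + pseudocount) / (mb + pseudocount))
}

#' Restrict a count matrix to annotated expressed genes
#'
#' @param counts genes x samples matrix.
#' @param expressed character vector of expressed gene ids.
#' @param rpkm_mat optional RPKM matrix for the dropped-vs-kept report.
#' @return list `counts` (filtered), `report` (median RPKM in dropped and
#'   kept groups, when `rpkm_mat` given).
#' @export
expressed_filter <- function(counts, expressed, rpkm_mat = NULL) {
  keep <- rownames(counts) %in% expressed
  if (!any(keep)) warning("no genes left after expressed-gene filter")
  report <- NULL
  if (!is.null(rpkm_mat))
    report <- data.frame(
      group = c("kept", "dropped"),
      n = c(sum(keep), sum(!keep)),
      median_rpkm = c(stats::median(rpkm_mat[keep, ]),
                      if (any(!keep)) stats::median(rpkm_mat[!keep, ])
                      else NA_real_))
  list(counts = counts[keep, , drop = FALSE], report = report)
}

#' Correlation of gene-body enrichment with expression
#'
#' Per strain, Spearman correlation between gene-body H3K9me2 enrichment
#' and expression among genes with a TE within 10 kb in that strain.
#'
#' @param records [gene_epi_table()] output (needs `mean_<strain>` and
#'   `category_<strain>` columns).
#' @param expr named per-gene expression values per strain (list of named
#'   vectors keyed by strain).
#' @return data.frame `strain, n, rho, p`.
#' @export
enrichment_expression_correlation <- function(records, expr) {
  do.call(rbind, lapply(names(expr), function(s) {
    near <- records[records[[paste0("category_", s)]] != "none", ,
                    drop = FALSE]
    e <- expr[[s]][near$gene_id]
    h <- near[[paste0("mean_", s)]]
    ok <- !is.na(e) & !is.na(h)
    ct <- suppressWarnings(stats::cor.test(h[ok], e[ok],
                                           method = "spearman"))
    data.frame(strain = s, n = sum(ok), rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }))
}

#' Quadrant concordance of enrichment and expression differences
#'
#' Classifies each gene by whether its allelic differences support a
#' repressive effect of the TE-adjacent allele's chromatin state — higher
#' enrichment and lower expression of that allele — and cross-tabulates
#' the classification against TE status (TE adjacent in one strain vs no
#' TE within 10 kb) with Fisher's exact test. `z_ref` and `log2fc` must
#' share the reference convention (positive z = higher enrichment in the
#' non-reference strain; positive log2fc = higher expression in the
#' non-reference strain). Genes exactly on either axis count as
#' non-concordant.
#'
#' @param records [gene_epi_table()] output.
#' @param log2fc named per-gene log2 fold change (non-reference over
#'   reference strain).
#' @param reference_strain the strain used as reference.
#' @param effect_only restrict TE-adjacent genes to effect-TEs.
#' @return list `table` (2x2), `fisher` (`odds_ratio, p`), `by_gene`.
#' @export
quadrant_contingency <- function(records, log2fc, reference_strain,
                                 effect_only = FALSE) {
  df <- records[!records$ambiguous, , drop = FALSE]
  df$log2fc <- log2fc[df$gene_id]
  df <- df[!is.na(df$log2fc) & !is.na(df$z_ref), , drop = FALSE]
  te_adj <- !is.na(df$with_strain)
  if (effect_only && "te_has_effect" %in% names(df))
    te_adj <- te_adj & df$te_has_effect %in% TRUE
  # concordant for a TE-adjacent gene: the TE-carrying allele has both
  # higher enrichment and lower expression; for 'neither' genes, any
  # opposite-sign quadrant
  sign_towards_te <- ifelse(is.na(df$with_strain), NA,
                            ifelse(df$with_strain == reference_strain, -1, 1))
  conc_te <- !is.na(sign_towards_te) &
    sign(df$z_ref) == sign_towards_te &
    sign(df$log2fc) == -sign_towards_te
  conc_none <- df$z_ref != 0 & df$log2fc != 0 &
    sign(df$z_ref) == -sign(df$log2fc)
  concordant <- ifelse(!is.na(df$with_strain), conc_te, conc_none)
  cls <- ifelse(te_adj, "te_adjacent",
                ifelse(is.na(df$with_strain), "neither", NA))
  use <- !is.na(cls)
  tab <- table(factor(cls[use], c("te_adjacent", "neither")),
               factor(concordant[use], c(TRUE, FALSE),
                      c("concordant", "other")))
  ft <- stats::fisher.test(tab)
  list(table = tab,
       fisher = list(odds_ratio = unname(ft$estimate), p = ft$p.value),
       by_gene = data.frame(gene_id = df$gene_id[use], class = cls[use],
                            concordant = concordant[use],
                            stringsAsFactors = FALSE))
}

#' Between-species expression rank z-scores
#'
#' Genes are ranked within each library from highest expression (rank 1)
#' to lowest; for each ortholog pair the z-score is
#' `(mean rank in species A - mean rank in species B) / mean of the two
#' species' rank SDs`. With A as the non-reference species, positive z
#' means a larger (worse) rank in A, i.e. relatively higher expression in
#' the reference species B.
#'
#' @param rpkm_a,rpkm_b genes x libraries RPKM matrices for the two
#'   species (rownames = gene ids).
#' @param orthologs data.frame `gene_a, gene_b` mapping ortholog pairs;
#'   genes missing from either matrix are dropped.
#' @return data.frame `gene_a, gene_b, mean_rank_a, mean_rank_b, z`.
#' @export
species_rank_z <- function(rpkm_a, rpkm_b, orthologs) {
  rank_mat <- function(m)
    apply(as.matrix(m), 2, function(x) rank(-x, ties.method = "average"))
  ra <- rank_mat(rpkm_a); rb <- rank_mat(rpkm_b)
  ok <- orthologs$gene_a %in% rownames(ra) &
    orthologs$gene_b %in% rownames(rb)
  o <- orthologs[ok, , drop = FALSE]
  ma <- rowMeans(ra[o$gene_a, , drop = FALSE])
  mb <- rowMeans(rb[o$gene_b, , drop = FALSE])
  sda <- apply(ra[o$gene_a, , drop = FALSE], 1, stats::sd)
  sdb <- apply(rb[o$gene_b, , drop = FALSE], 1, stats::sd)
  denom <- (sda + sdb) / 2
  data.frame(gene_a = o$gene_a, gene_b = o$gene_b,
             mean_rank_a = ma, mean_rank_b = mb,
             z = ifelse(denom > 0, (ma - mb) / denom, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Distribution shift of a gene set's expression-difference z-scores
#'
#' Two-sample Kolmogorov-Smirnov test of the set's z distribution against
#' all other genes, plus per-gene flags for membership in the genome-wide
#' 5% tails (the conventional cutoff for calling a gene's between-species
#' expression difference extreme).
#'
#' @param z named numeric vector of z-scores for all genes.
#' @param gene_set character vector of set members.
#' @param tail fraction defining each tail (default 0.05).
#' @return list `ks` (`statistic, p`), `flags` (data.frame `gene, in_set,
#'   low_tail, high_tail`).
#' @export
gene_set_shift <- function(z, gene_set, tail = 0.05) {
  z <- z[!is.na(z)]
  in_set <- names(z) %in% gene_set
  if (!any(in_set)) stop("gene set has no members with z-scores")
  ks <- if (all(in_set))
    list(statistic = 0, p.value = 1)
  else suppressWarnings(stats::ks.test(z[in_set], z[!in_set]))
  q <- stats::quantile(z, c(tail, 1 - tail))
  list(ks = list(statistic = unname(ks$statistic), p = ks$p.value),
       flags = data.frame(gene = names(z), in_set = in_set,
                          low_tail = z < q[1], high_tail = z > q[2],
                          row.names = NULL, stringsAsFactors = FALSE))
}
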