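#' Count k-mers in a read set
#'
#' Every length-k substring of every read is counted; by default k-mers
#' are collapsed to their canonical form (lexicographic minimum of the
#' forward k-mer and its reverse complement), since both strands of a
#' library are sequenced. K-mers containing characters outside A/C/G/T
#' (ambiguity codes, N) are skipped; reads shorter than k contribute
#' nothing.
#'
#' @param reads character vector of read sequences.
#' @param k k-mer length (default 12).
#' @param canonical collapse strands (default TRUE).
#' @return named integer vector of counts.
#' @export
count_kmers <- function(reads, k = 12, canonical = TRUE) {
  stopifnot(k >= 1)
  reads <- toupper(reads[nchar(reads) >= k])
  if (!length(reads)) return(structure(integer(0), names = character(0)))
  n_k <- nchar(reads) - k + 1
  starts <- unlist(lapply(n_k, seq_len), use.names = FALSE)
  kms <- substring(rep(reads, n_k), starts, starts + k - 1)
  kms <- kms[grepl("^[ACGT]+$", kms)]
  if (!length(kms)) return(structure(integer(0), names = character(0)))
  if (canonical) kms <- canonical_kmer(kms)
  tab <- table(kms)
  structure(as.integer(tab), names = names(tab))
}

#' Canonical form of k-mers
#' @param kmers character vector (A/C/G/T).
#' @return the lexicographic minimum of each k-mer and its reverse
#'   complement.
#' @export
canonical_kmer <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' Normalize k-mer counts by a library normalizer
#'
#' Divides counts by the number of reads mapping uniquely to the reference
#' (MAPQ >= 30) supplied as library metadata, giving repeat abundance
#' relative to the single-copy genome.
#'
#' @param counts named count vector from [count_kmers()].
#' @param normalizer positive scalar.
#' @return named numeric vector.
#' @export
normalize_counts <- function(counts, normalizer) {
  if (!is.finite(normalizer) || normalizer <= 0)
    stop("normalizer must be a positive count")
  counts / normalizer
}

#' Select heterochromatin-enriched k-mers
#'
#' A k-mer is enriched when its normalized IP count is at least
#' `threshold` times its normalized input count. K-mers absent from the
#' input have an undefined ratio and are excluded (an optional pseudocount
#' added to both libraries changes this).
#'
#' @param ip_norm,input_norm normalized count vectors.
#' @param threshold fold-enrichment cutoff (default 1.5).
#' @param pseudocount added to both normalized counts (default 0).
#' @return list `kmers` (character), `threshold`, `fraction_of_total`
#'   (enriched / all k-mers seen in either library).
#' @export
select_enriched <- function(ip_norm, input_norm, threshold = 1.5,
                            pseudocount = 0) {
  all_k <- union(names(ip_norm), names(input_norm))
  ip <- ifelse(is.na(ip_norm[all_k]), 0, ip_norm[all_k]) + pseudocount
  inp <- ifelse(is.na(input_norm[all_k]), 0, input_norm[all_k]) + pseudocount
  ok <- inp > 0 & (ip / inp) >= threshold
  list(kmers = sort(all_k[ok]), threshold = threshold,
       fraction_of_total = sum(ok) / length(all_k))
}

#' Heterochromatic-repeat amount of a genomic library
#'
#' Total count of enriched k-mer instances in the library divided by the
#' library's normalizer (read coverage of orthologous exonic regions, or
#' all uniquely mapped reads).
#'
#' @param counts [count_kmers()] result for the library.
#' @param enriched [select_enriched()] result (or character vector).
#' @param normalizer positive scalar.
#' @return numeric normalized amount.
#' @export
quantify_library <- function(counts, enriched, normalizer) {
  if (is.list(enriched)) enriched <- enriched$kmers
  if (!is.finite(normalizer) || normalizer <= 0)
    stop("normalizer must be a positive count")
  sum(counts[names(counts) %in% enriched]) / normalizer
}

#' Two-factor comparison of heterochromatic-repeat amounts
#'
#' Additive two-factor ANOVA (species + library preparation method) on
#' per-library normalized amounts, as used to compare heterochromatic
#' repeat content between species while controlling for prep.
#'
#' @param amounts data.frame `amount, species, prep`.
#' @return data.frame `factor, df, F, p`.
#' @export
compare_species <- function(amounts) {
  stopifnot(all(c("amount", "species", "prep") %in% names(amounts)))
  if (length(unique(amounts$species)) < 2)
    stop("species factor needs at least two levels")
  fit <- stats::aov(amount ~ species + prep, data = amounts)
  sm <- summary(fit)[[1]]
  keep <- trimws(rownames(sm)) != "Residuals"
  out <- data.frame(factor = trimws(rownames(sm)[keep]),
                    df = sm$Df[keep], F = sm$`F value`[keep],
                    p = sm$`Pr(>F)`[keep], stringsAsFactors = FALSE)
  # a factor with zero sum of squares has F = 0, p = 1 even when the
  # residual variance is also zero (identical libraries)
  zero <- !is.finite(out$F) & sm$`Sum Sq`[keep] < 1e-12
  out$F[zero] <- 0
  out$p[zero] <- 1
  out
}

#' End-to-end k-mer comparison on a simulated read set
#'
#' Identifies enriched k-mers from the IP/input pair, quantifies every
#' genomic library, and runs the species + prep comparison.
#'
#' @param sim result of [simulate_reads()].
#' @param k k-mer length (default 12).
#' @param threshold fold-enrichment cutoff (default 1.5).
#' @return list `enriched`, `amounts` (data.frame), `anova`.
#' @export
kmer_species_analysis <- function(sim, k = 12, threshold = 1.5) {
  libs <- sim$libraries
  cnt <- function(l) count_kmers(l$reads, k = k)
  ip_c <- cnt(libs$ip); in_c <- cnt(libs$input)
  enriched <- select_enriched(normalize_counts(ip_c, libs$ip$n_unique_reads),
                              normalize_counts(in_c, libs$input$n_unique_reads),
                              threshold = threshold)
  gen <- libs[vapply(libs, function(l) l$role == "genomic", TRUE)]
  amounts <- do.call(rbind, lapply(gen, function(l)
    data.frame(library = l$id, species = l$species, prep = l$prep,
               amount = quantify_library(cnt(l), enriched,
                                         l$n_unique_reads),
               stringsAsFactors = FALSE)))
  rownames(amounts) <- NULL
  list(enriched = enriched, amounts = amounts,
       anova = compare_species(amounts))
}
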