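#' Simulation configuration
#'
#' One object holding every knob of the synthetic-data generator. Defaults
#' describe the study conditions the pipeline is validated under: two
#' strains of one species mapped to a shared reference, paired-replicate
#' fold-enrichment tracks with lognormal background, a plateau-plus-linear-
#' taper spread signal of known extent at strain-unique TE insertions, a
#' 197-allele population panel whose insertion frequencies fall with the
#' injected epigenetic effect, expression counts negatively coupled to
#' local enrichment, and read sets embedding tandem repeat units.
#'
#' @param seed integer master seed; every generator derives its stream from
#'   it (tracks: `seed`; population panel: `seed + 101`; expression:
#'   `seed + 202`; reads: `seed + 303`).
#' @param n_chroms,chrom_length chromosome count and length (bp);
#'   `chrom_length` must be a multiple of the background resolution.
#' @param n_tes strain-unique TE insertions to place (split between the two
#'   strains); `n_shared_tes` additional insertions carried by both strains.
#' @param te_length insertion footprint in reference coordinates (bp).
#' @param families family catalog: data.frame `family, te_type, abundance`.
#' @param background lognormal background fold enrichment:
#'   `meanlog`, `sdlog`, and `resolution_bp` (independent draw per bin).
#' @param strain_baseline multiplicative baseline per strain (the two real
#'   strains differ slightly in global enrichment; flank normalization must
#'   remove this).
#' @param spread `boost` (multiplicative enrichment over the plateau),
#'   `extent_kb` (vector recycled over TEs; the plateau half-width each side
#'   of the insertion), `decay_kb` (linear taper back to background).
#' @param replicate `n` replicates per strain and lognormal `sdlog` of the
#'   per-bin replicate noise.
#' @param population panel settings: `n_individuals`, logit `intercept`,
#'   `coupling` (per kb of true extent, subtracted on the log-odds scale),
#'   `missing_rate`.
#' @param expression `baseline_log_mean`, `coupling` of log-mean to
#'   (gene-body multiplier - 1), negative-binomial `size`, `gene_length`,
#'   per-TE gene offsets `gene_distances` (bp, cycled), `n_far_genes`,
#'   `n_silent_genes`, `lib_factors` per replicate.
#' @param kmer `k`, `unit_length`, `n_units`, `unique_length`, per-species
#'   repeat `copy_number` list, `ip_factor` (over-representation of repeat
#'   reads in the IP library), `prep_bias` per library preparation,
#'   `read_length`, `n_reads` per library, `n_rep` libraries per
#'   species x prep.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2,
                       chrom_length = 5.3e6,
                       n_tes = 200,
                       n_shared_tes = 0,
                       te_length = 6,
                       families = default_family_catalog(),
                       background = list(meanlog = 0, sdlog = 0.3,
                                         resolution_bp = 10),
                       strain_baseline = c(s1 = 1, s2 = 1.3),
                       spread = list(boost = 3, extent_kb = 0:8, decay_kb = 1),
                       replicate = list(n = 2, sdlog = 0.05),
                       population = list(n_individuals = 197, intercept = -5,
                                         coupling = 0.7, missing_rate = 0.1,
                                         min_called = 100),
                       expression = list(baseline_log_mean = log(200),
                                         coupling = 1, size = 10,
                                         gene_length = 2000,
                                         gene_distances = c(300, 1500, 3000, 7000),
                                         n_far_genes = 100,
                                         n_silent_genes = 50,
                                         lib_factors = c(1, 1.2)),
                       kmer = list(k = 12, unit_length = 150, n_units = 2,
                                   unique_length = 20000,
                                   copy_number = list(melanogaster = c(400, 400),
                                                      simulans = c(320, 320)),
                                   ip_factor = 3,
                                   prep_bias = c(prepA = 1, prepB = 0.7),
                                   read_length = 100, n_reads = 4000,
                                   n_rep = 2)) {
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              chrom_length = chrom_length, n_tes = n_tes,
              n_shared_tes = n_shared_tes, te_length = te_length,
              families = families, background = background,
              strain_baseline = strain_baseline, spread = spread,
              replicate = replicate, population = population,
              expression = expression, kmer = kmer)
  stopifnot(cfg$chrom_length %% cfg$background$resolution_bp == 0,
            all(cfg$spread$extent_kb >= 0), all(cfg$spread$boost >= 0),
            cfg$population$missing_rate >= 0, cfg$population$missing_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Default TE family catalog
#'
#' Ten families across the three TE types, with relative abundances used to
#' sample family labels for simulated insertions.
#' @return data.frame `family, te_type, abundance`.
#' @export
default_family_catalog <- function() {
  data.frame(
    family = c("gypsy", "copia", "roo", "412",
               "jockey", "Doc", "F-element",
               "P-element", "hobo", "pogo"),
    te_type = c("LTR", "LTR", "LTR", "LTR",
                "non-LTR", "non-LTR", "non-LTR",
                "TIR", "TIR", "TIR"),
    abundance = c(3, 2, 4, 2, 3, 2, 2, 1, 1, 1),
    stringsAsFactors = FALSE)
}

sim_assembly <- function(config) {
  genome_assembly(paste0("chr", seq_len(config$n_chroms)),
                  rep(config$chrom_length, config$n_chroms))
}

# deterministic TE placement: 50-kb slots with +/-2 kb jitter, >= 20 kb
# inside euchromatin bounds, so no TE's 40-kb analysis span touches
# another TE's spread signal
place_tes <- function(config, assembly) {
  spacing <- 50000
  margin <- 25000
  total <- config$n_tes + config$n_shared_tes
  slots <- list()
  for (ch in assembly$chrom_names) {
    eu <- euchromatin_span(assembly, ch)
    pos <- seq(eu[1] + margin, eu[2] - margin, by = spacing)
    slots[[ch]] <- pos
  }
  capacity <- sum(lengths(slots))
  if (capacity < total)
    stop("infeasible TE placement density: ", total, " TEs but only ",
         capacity, " slots; use longer or more chromosomes")
  slot_df <- do.call(rbind, lapply(names(slots), function(ch)
    data.frame(chrom = ch, pos = slots[[ch]])))
  slot_df <- slot_df[seq_len(total), , drop = FALSE]
  slot_df$pos <- slot_df$pos + sample.int(4001, total, replace = TRUE) - 2001
  slot_df
}

#' Simulate paired-strain fold-enrichment tracks with known ground truth
#'
#' Places TE insertions on a shared reference coordinate system, assigns
#' each strain-unique insertion to a carrier strain, and emits per-strain,
#' per-replicate enrichment tracks: a lognormal background landscape shared
#' by the two (near-isogenic) strains, times the strain baseline, with the
#' carrier strain additionally multiplied by the spread signal (plateau of
#' `boost` over `extent_kb` each side, linear taper to 1 over `decay_kb`).
#' Replicates differ by multiplicative lognormal noise.
#'
#' @param config a [sim_config()].
#' @return list with `assembly`, `tracks` (nested `strain -> replicate ->`
#'   [enrichment_track()]), `te_tables` (per-strain TE call data.frames, as
#'   [read_te_table()] would return), and `truth` (per-TE `extent_kb`,
#'   `boost`, carrier strain, `shared` flag).
#' @export
simulate_tracks <- function(config) {
  assembly <- sim_assembly(config)
  set.seed(config$seed)
  slot_df <- place_tes(config, assembly)
  total <- nrow(slot_df)
  fam_idx <- sample.int(nrow(config$families), total, replace = TRUE,
                        prob = config$families$abundance)
  strains <- names(config$strain_baseline)
  carrier <- sample(strains, total, replace = TRUE)
  shared <- rep(FALSE, total)
  if (config$n_shared_tes > 0)
    shared[(config$n_tes + 1):total] <- TRUE
  truth <- data.frame(
    te_id = sprintf("te%04d", seq_len(total)),
    chrom = slot_df$chrom,
    start = slot_df$pos,
    end = slot_df$pos + config$te_length,
    family = config$families$family[fam_idx],
    te_type = config$families$te_type[fam_idx],
    carrier = ifelse(shared, "both", carrier),
    shared = shared,
    extent_kb = rep_len(config$spread$extent_kb, total),
    boost = rep_len(config$spread$boost, total),
    stringsAsFactors = FALSE)

  res <- config$background$resolution_bp
  nbin <- config$chrom_length %/% res
  # spread multiplier per chromosome per strain (1 = background)
  mult <- lapply(strains, function(s) lapply(assembly$chrom_names,
                                             function(ch) rep(1, nbin)))
  names(mult) <- strains
  for (s in strains) names(mult[[s]]) <- assembly$chrom_names
  for (i in seq_len(nrow(truth))) {
    tgt <- if (truth$shared[i]) strains else truth$carrier[i]
    prof <- spread_multiplier_bins(truth$start[i], truth$end[i],
                                   truth$extent_kb[i], truth$boost[i],
                                   config$spread$decay_kb, res, nbin)
    for (s in tgt) {
      m <- mult[[s]][[truth$chrom[i]]]
      # profiles never overlap by construction; pmax is a safety net
      m[prof$idx] <- pmax(m[prof$idx], prof$values)
      mult[[s]][[truth$chrom[i]]] <- m
    }
  }

  tracks <- list()
  starts <- res * (seq_len(nbin) - 1)
  # one shared background landscape: the strains are near-isogenic, so
  # away from strain-unique TEs they differ only by baseline, spread
  # signal, and replicate noise
  bg_land <- lapply(assembly$chrom_names, function(ch)
    stats::rlnorm(nbin, config$background$meanlog, config$background$sdlog))
  names(bg_land) <- assembly$chrom_names
  for (s in strains) {
    tracks[[s]] <- list()
    bg <- lapply(assembly$chrom_names, function(ch)
      bg_land[[ch]] * config$strain_baseline[[s]] * mult[[s]][[ch]])
    names(bg) <- assembly$chrom_names
    for (r in seq_len(config$replicate$n)) {
      seg <- do.call(rbind, lapply(assembly$chrom_names, function(ch) {
        noise <- stats::rlnorm(nbin, 0, config$replicate$sdlog)
        data.frame(chrom = ch, start = starts, end = starts + res,
                   value = bg[[ch]] * noise)
      }))
      tracks[[s]][[paste0("r", r)]] <-
        enrichment_track(seg, assembly, strain = s,
                         replicate = paste0("r", r))
    }
  }

  te_tables <- lapply(strains, function(s) {
    keep <- truth$carrier == s | truth$shared
    df <- truth[keep, c("te_id", "chrom", "start", "end", "family", "te_type"),
                drop = FALSE]
    names(df)[1] <- "id"
    df$strain <- rep(s, nrow(df))
    df$confidence <- 3 + round(stats::runif(nrow(df), 0, 7), 2)
    rownames(df) <- NULL
    df
  })
  names(te_tables) <- strains

  list(assembly = assembly, tracks = tracks, te_tables = te_tables,
       truth = truth, config = config)
}

# multiplier profile over resolution bins for one TE: plateau `boost` over
# [edge, edge + extent], linear taper to 1 over the next `decay` kb
spread_multiplier_bins <- function(start, end, extent_kb, boost, decay_kb,
                                   res, nbin) {
  ext <- extent_kb * 1000
  dec <- decay_kb * 1000
  lo <- max(0, start - ext - dec)
  hi <- min(nbin * res, end + ext + dec)
  idx <- seq(lo %/% res + 1, (hi - 1) %/% res + 1)
  mid <- res * (idx - 1) + res / 2
  d <- ifelse(mid < start, start - mid, ifelse(mid >= end, mid - end, 0))
  v <- ifelse(d <= ext, boost,
              ifelse(d <= ext + dec, boost - (boost - 1) * (d - ext) / dec, 1))
  list(values = v, idx = idx)
}

#' True gene-body spread multiplier per strain
#'
#' Noiseless expectation of the spread signal over each gene body, used as
#' the enrichment covariate when simulating expression counts.
#'
#' @param genes gene data.frame (`chrom, start, end`).
#' @param truth the `truth` component of [simulate_tracks()] output.
#' @param config the [sim_config()] used.
#' @return matrix genes x strains of mean multipliers.
#' @export
true_gene_multiplier <- function(genes, truth, config) {
  strains <- names(config$strain_baseline)
  res <- config$background$resolution_bp
  nbin <- config$chrom_length %/% res
  out <- matrix(1, nrow(genes), length(strains),
                dimnames = list(genes$id, strains))
  for (i in seq_len(nrow(genes))) {
    cand <- which(truth$chrom == genes$chrom[i] &
                    abs(truth$start - genes$start[i]) < 60000)
    if (!length(cand)) next
    bins <- seq(genes$start[i] %/% res + 1, (genes$end[i] - 1) %/% res + 1)
    for (j in cand) {
      prof <- spread_multiplier_bins(truth$start[j], truth$end[j],
                                     truth$extent_kb[j], truth$boost[j],
                                     config$spread$decay_kb, res, nbin)
      vals <- rep(1, length(bins))
      hit <- match(bins, prof$idx)
      vals[!is.na(hit)] <- prof$values[hit[!is.na(hit)]]
      m <- mean(vals)
      tgt <- if (truth$shared[j]) strains else truth$carrier[j]
      for (s in tgt) out[i, s] <- out[i, s] * m
    }
  }
  out
}

#' Simulate a population presence/absence panel with contig span records
#'
#' Each TE's true population frequency is
#' `plogis(intercept - coupling * extent_kb)`: insertions with larger
#' injected epigenetic effects segregate at lower frequency, emulating
#' purifying selection against them. For every individual a contig
#' alignment-span record consistent with the truth is emitted: a spanning
#' contig (>= 50 bp both sides) for absent alleles, a one-sided >= 30 bp
#' contig with a TE hit for present alleles, and either no contig or an
#' uninformative short contig for missing data.
#'
#' @param truth per-TE truth from [simulate_tracks()].
#' @param config a [sim_config()].
#' @return list with `spans` (data.frame `te_id, individual, contig,
#'   bp_left, bp_right, spans_insertion_site, te_hit`), `truth`
#'   (per-TE `true_freq` added).
#' @export
simulate_population_panel <- function(truth, config) {
  set.seed(config$seed + 101L)
  pop <- config$population
  n <- pop$n_individuals
  truth$true_freq <- stats::plogis(pop$intercept -
                                     pop$coupling * truth$extent_kb)
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    state <- ifelse(stats::runif(n) < pop$missing_rate, "missing",
                    ifelse(stats::runif(n) < truth$true_freq[i],
                           "present", "absent"))
    bp_left <- integer(n); bp_right <- integer(n)
    spans <- logical(n); hit <- logical(n); emit <- rep(TRUE, n)
    pres <- state == "present"
    abs_ <- state == "absent"
    mis <- state == "missing"
    k <- sum(pres)
    if (k) {
      side_left <- stats::runif(k) < 0.5
      bp <- 30L + sample.int(120L, k, replace = TRUE) - 1L
      bp_left[pres] <- ifelse(side_left, bp, 0L)
      bp_right[pres] <- ifelse(side_left, 0L, bp)
      hit[pres] <- TRUE
    }
    k <- sum(abs_)
    if (k) {
      bp_left[abs_] <- 50L + sample.int(150L, k, replace = TRUE) - 1L
      bp_right[abs_] <- 50L + sample.int(150L, k, replace = TRUE) - 1L
      spans[abs_] <- TRUE
    }
    k <- sum(mis)
    if (k) {
      none <- stats::runif(k) < 0.5
      emit[mis][none] <- FALSE
      short <- !none
      bp_left[mis][short] <- sample.int(30L, sum(short), replace = TRUE) - 1L
      hit[mis][short] <- stats::runif(sum(short)) < 0.5
    }
    rows[[i]] <- data.frame(
      te_id = truth$te_id[i],
      individual = sprintf("ind%03d", seq_len(n)),
      contig = sprintf("%s_c%03d", truth$te_id[i], seq_len(n)),
      bp_left = bp_left, bp_right = bp_right,
      spans_insertion_site = spans, te_hit = hit,
      stringsAsFactors = FALSE)[emit, , drop = FALSE]
  }
  list(spans = do.call(rbind, rows), truth = truth)
}

#' Model-matched simulation of TE population-frequency responses
#'
#' Draws regression responses directly from the families the frequency
#' models fit — a Bernoulli high/low-frequency indicator with a
#' logit-linear effect, and a negative-binomial insertion count with a
#' log-linear effect — with a family-level intercept. Used to calibrate
#' and validate the Table-2-shaped fits (coefficient recovery and type-I
#' error), separately from the mechanistic per-individual panel generator.
#'
#' @param n_tes number of TEs.
#' @param n_families number of families (balanced assignment).
#' @param coef true effect coefficient (per unit of the effect covariate).
#' @param intercept baseline (logit scale for the indicator, log scale for
#'   the count).
#' @param family_sd SD of the Gaussian family intercepts.
#' @param theta negative-binomial dispersion (size).
#' @param seed integer seed.
#' @return data.frame `te_id, family, effect, high_freq, count`.
#' @export
simulate_te_frequencies <- function(n_tes = 300, n_families = 10,
                                    coef = -1, intercept = 1,
                                    family_sd = 0.5, theta = 5, seed = 1) {
  set.seed(seed)
  fam <- paste0("fam", rep_len(seq_len(n_families), n_tes))
  u <- stats::rnorm(n_families, 0, family_sd)
  names(u) <- paste0("fam", seq_len(n_families))
  x <- stats::runif(n_tes, 0, 2)
  eta_logit <- intercept + u[fam] + coef * x
  high <- stats::rbinom(n_tes, 1, stats::plogis(eta_logit))
  eta_log <- log(20) + u[fam] + coef * x
  count <- stats::rnbinom(n_tes, mu = exp(eta_log), size = theta)
  data.frame(te_id = sprintf("te%04d", seq_len(n_tes)), family = fam,
             effect = x, high_freq = high, count = count,
             stringsAsFactors = FALSE)
}

#' Place synthetic gene models around simulated TEs
#'
#' One gene near each TE (edge-to-edge offsets cycling through
#' `gene_distances`, alternating side) plus `n_far_genes` genes at least
#' 20 kb from every TE, plus `n_silent_genes` far genes flagged as not
#' expressed. Each gene has two exons.
#'
#' @param truth per-TE truth from [simulate_tracks()].
#' @param config a [sim_config()].
#' @return data.frame of gene models with `near_te` (TE id or NA) and
#'   `silent` flag; `expressed` ids are all non-silent genes.
#' @export
simulate_genes <- function(truth, config) {
  ex <- config$expression
  glen <- ex$gene_length
  n_te <- nrow(truth)
  dist <- rep_len(ex$gene_distances, n_te)
  side <- rep_len(c(1, -1), n_te)
  start <- ifelse(side > 0, truth$end + dist,
                  truth$start - dist - glen)
  near <- data.frame(id = sprintf("g_near%04d", seq_len(n_te)),
                     chrom = truth$chrom, start = start, end = start + glen,
                     strand = "+", near_te = truth$te_id,
                     silent = FALSE, stringsAsFactors = FALSE)
  n_far <- ex$n_far_genes + ex$n_silent_genes
  far_anchor <- truth[rep_len(seq_len(n_te), n_far), ]
  fstart <- far_anchor$start + 23000  # mid-gap: >= 20 kb from flanking TEs
  fstart <- pmin(fstart, config$chrom_length - glen - 100)
  far <- data.frame(id = sprintf("g_far%04d", seq_len(n_far)),
                    chrom = far_anchor$chrom, start = fstart,
                    end = fstart + glen, strand = "+",
                    near_te = NA_character_,
                    silent = rep(c(FALSE, TRUE),
                                 c(ex$n_far_genes, ex$n_silent_genes)),
                    stringsAsFactors = FALSE)
  genes <- rbind(near, far)
  genes$exons <- lapply(seq_len(nrow(genes)), function(i)
    cbind(start = c(genes$start[i], genes$start[i] + glen %/% 2 + 100),
          end = c(genes$start[i] + glen %/% 2 - 100, genes$end[i])))
  genes
}

#' Simulate expression counts coupled to local enrichment
#'
#' Negative-binomial counts per gene, strain, and replicate with
#' `log mean = baseline - coupling * (gene-body spread multiplier - 1) +
#' log(library factor)`; silent genes have a near-zero mean. Library sizes
#' are recorded.
#'
#' @param genes output of [simulate_genes()].
#' @param truth per-TE truth from [simulate_tracks()].
#' @param config a [sim_config()].
#' @return list with `counts` (genes x samples matrix), `samples`
#'   (data.frame `sample, strain, replicate, lib_size`), `gene_length`
#'   (exonic bp per gene), `expressed` (ids), `true_mult` (genes x strains).
#' @export
simulate_expression <- function(genes, truth, config) {
  set.seed(config$seed + 202L)
  ex <- config$expression
  strains <- names(config$strain_baseline)
  mult <- true_gene_multiplier(genes, truth, config)
  nrep <- length(ex$lib_factors)
  samples <- expand.grid(replicate = paste0("r", seq_len(nrep)),
                         strain = strains, stringsAsFactors = FALSE)
  samples <- samples[, c("strain", "replicate")]
  samples$sample <- paste(samples$strain, samples$replicate, sep = "_")
  counts <- matrix(0L, nrow(genes), nrow(samples),
                   dimnames = list(genes$id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    s <- samples$strain[j]
    lf <- ex$lib_factors[match(samples$replicate[j],
                               paste0("r", seq_len(nrep)))]
    mu <- exp(ex$baseline_log_mean - ex$coupling * (mult[, s] - 1)) * lf
    mu[genes$silent] <- 0.1 * lf
    counts[, j] <- stats::rnbinom(nrow(genes), mu = mu, size = ex$size)
  }
  gene_length <- vapply(genes$exons, function(e) sum(e[, 2] - e[, 1]), 1)
  samples$lib_size <- colSums(counts)
  list(counts = counts, samples = samples, gene_length = gene_length,
       expressed = genes$id[!genes$silent], true_mult = mult)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate read sets for the heterochromatic k-mer analysis
#'
#' Builds a genome per species from one shared unique region plus tandem
#' arrays of shared repeat units at species-specific copy numbers, then
#' samples reads. The IP library over-represents repeat-derived reads by
#' `ip_factor` relative to its input; genomic libraries are drawn per
#' species x library-prep with a prep-specific repeat recovery bias. The
#' number of unique-region reads per library is recorded as the
#' normalizer (the stand-in for uniquely mapped / orthologous-exon reads).
#'
#' @param config a [sim_config()].
#' @return list with `libraries` (each: `id, species, prep, role, reads`
#'   (character vector), `n_unique_reads`) and `truth` (`units`, repeat
#'   copy numbers per species).
#' @export
simulate_reads <- function(config) {
  km <- config$kmer
  if (km$read_length < km$k)
    stop("read length shorter than k; no k-mers can be formed")
  set.seed(config$seed + 303L)
  unique_region <- random_dna(km$unique_length)
  units <- vapply(seq_len(km$n_units), function(i) random_dna(km$unit_length),
                  "")
  species <- names(km$copy_number)
  genomes <- lapply(species, function(sp) {
    reps <- paste(mapply(function(u, n) paste(rep(u, n), collapse = ""),
                         units, km$copy_number[[sp]]), collapse = "")
    list(unique = unique_region, repeats = reps)
  })
  names(genomes) <- species

  draw_library <- function(genome, repeat_factor, n_reads, id, sp, prep, role) {
    ulen <- nchar(genome$unique) - km$read_length + 1
    rlen <- nchar(genome$repeats) - km$read_length + 1
    p_rep <- (rlen * repeat_factor) / (rlen * repeat_factor + ulen)
    from_rep <- stats::runif(n_reads) < p_rep
    starts_u <- sample.int(ulen, sum(!from_rep), replace = TRUE)
    starts_r <- sample.int(rlen, sum(from_rep), replace = TRUE)
    reads <- character(n_reads)
    reads[!from_rep] <- substring(genome$unique, starts_u,
                                  starts_u + km$read_length - 1)
    reads[from_rep] <- substring(genome$repeats, starts_r,
                                 starts_r + km$read_length - 1)
    list(id = id, species = sp, prep = prep, role = role, reads = reads,
         n_unique_reads = sum(!from_rep))
  }

  libs <- list()
  sp1 <- species[1]
  libs$ip <- draw_library(genomes[[sp1]], km$ip_factor, km$n_reads,
                          "ip", sp1, "chip", "ip")
  libs$input <- draw_library(genomes[[sp1]], 1, km$n_reads,
                             "input", sp1, "chip", "input")
  for (sp in species)
    for (prep in names(km$prep_bias))
      for (r in seq_len(km$n_rep)) {
        id <- paste(sp, prep, paste0("r", r), sep = "_")
        libs[[id]] <- draw_library(genomes[[sp]], km$prep_bias[[prep]],
                                   km$n_reads, id, sp, prep, "genomic")
      }
  list(libraries = libs,
       truth = list(units = units, copy_number = km$copy_number,
                    unique_region = unique_region))
}

#' Write reads to FASTQ
#' @param reads character vector of read sequences.
#' @param path output path.
#' @param id_prefix read-name prefix.
#' @export
write_fastq <- function(reads, path, id_prefix = "read") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s%06d", id_prefix, seq_along(reads))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                vapply(nchar(reads),
                                       function(n) strrep("I", n), "")))
  invisible(path)
}

#' Read sequences from FASTQ
#' @param path FASTQ path.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
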