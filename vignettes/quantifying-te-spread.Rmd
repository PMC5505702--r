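---
title: "Quantifying heterochromatin spread from TE insertions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heterochromatin spread from TE insertions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tespread)
```

# The problem

Transposable element (TE) insertions are targeted by small-RNA-guided
silencing that deposits repressive chromatin marks (H3K9me2) on the element
itself. That mark can spread beyond the insertion into flanking euchromatin,
silencing sequence — including genes — that has nothing to do with the TE.
If such spreading is common and harmful, natural selection should remove
insertions with large epigenetic effects from populations, which ties a
chromatin phenotype to population-genetic fate.

`tespread` implements the complete quantitative machinery for this question:

1. per-TE quantification of H3K9me2 spreading from fold-enrichment tracks
   (two methods);
2. curation of TE catalogs into an analyzable, strain-unique, euchromatic set;
3. gene-level allele z-scores linking spreading to the chromatin state of
   neighbouring genes;
4. population presence/absence calling from contig alignment spans,
   frequency estimation, and family-aware frequency-on-effect regressions;
5. heterochromatin-enriched 12-mer quantification across species;
6. expression-side analyses (fold changes, quadrant concordance,
   cross-species rank z-scores, gene-set shift tests).

Because the original measurements require strain ChIP-seq and hundreds of
resequenced genomes, the package ships a synthetic-data generator with known
ground truth; every stage is validated against that truth or against
brute-force oracles.

# The spread indexes

For a TE with edges $(s, e)$ on the shared reference coordinate system, the
20 kb on each side is cut into 20 non-overlapping 1-kb windows, window 1
being 0–1 kb from the edge. Within each window the piecewise-constant
fold-enrichment (FE) track is resampled to 10-bp bins (at most 100
observations per window per strain); bins with under half their bases
covered are dropped, and a window is unusable if it leaves euchromatin or
retains fewer than 5 bins in either strain.

**Two-strain method.** The strains' baselines differ slightly for technical
and biological reasons, so each strain's samples are first divided by that
strain's *flank normalizer*: the median FE over its 20–40-kb flanks (both
sides pooled, computed per TE). Window $i$ is then tested one-sided
(Mann–Whitney U) for higher enrichment in the strain carrying the TE, at
$\alpha = 0.05$ with no multiple-testing correction — deliberately mirroring
the original liberal choice. Three indexes follow:

* `has_effect`: window 1 significant on **both** sides;
* `extent_kb`: per side, the largest $k$ with windows $1..k$ all
  significant (consecutive from the edge); the reported extent is the
  **minimum** of the two sides (conservative);
* `pct_increase`: (median(with-TE) − median(without-TE)) / median(without-TE)
  over the pooled left+right 0–1-kb windows, on normalized samples.

**Single-genome (relative) method.** When no homologous TE-free allele is
available, samples are divided by the *higher* of the left and right
20–40-kb flank medians (conservative) and each window is tested against the
background value 1. The reference is a constant, so the rank test degenerates
to the exact one-sample sign test, which is what the package uses; the
increase index is the pooled 0–1-kb median relative enrichment minus 1.

Numerical choices that the source procedure leaves open, fixed here:

* sampling unit = 10-bp bin means (deterministic, resolution-matched,
  avoids pseudo-replicating run-length segments); bin size is an argument;
* Mann–Whitney p-values: exact enumeration when both groups have ≤ 8
  observations and no ties, otherwise midrank normal approximation with
  continuity correction;
* flank normalization is division (preserves the ratio scale of FE) and is
  computed per TE, since the procedure ties it to each insertion;
* `pct_increase` pools the two 0–1-kb windows before taking medians;
* fully tied samples give p = 1; a non-positive flank normalizer is an error.

# Catalog curation

The analyzable set keeps TEs that are: called with coverage-ratio
confidence ≥ 3; entirely inside the euchromatin span after shrinking it by
0.5 Mb per side (full containment, the conservative reading); not within
100 bp (configurable tolerance) of a same-family call in the other strain;
not in an exon or a shared H3K9me2 peak (≥ 1 bp overlap removes);
and not in a cluster. Same-family calls within 500 bp are merged *first*;
after merging, any two calls of different families within 2 kb (closest
edges) are excluded as a putative cluster — merging first is the only order
under which the same-family rule cannot also trigger the cluster rule.
Hit-table annotation keeps the smallest-e-value family per locus, drops
e-value ties across families as ambiguous, requires ≥ 100 bp and ≥ 80%
identity, and always excludes INE-1 (an ancient, essentially fixed family).
The curation report is a partition: every input TE receives exactly one
disposition.

# Gene-level analysis

Gene-body mean FE (annotated span including introns) is computed per
replicate and quantile-normalized across replicate columns (ties averaged).
Genes are binned by shortest edge-to-edge distance to a kept TE (0–1, 1–2,
2–5, 5–10 kb, none within 10 kb; an overlapping TE is distance 0). The
allele z-score is

$$z = \frac{\bar{x}_{\text{with TE}} - \bar{x}_{\text{without TE}}}
           {\tfrac12 (s_{\text{with}} + s_{\text{without}})}$$

with replicate means and sample SDs ($n-1$); "mean standard deviation" is
read literally as the mean of the two strains' SDs (not pooled variances).
It is defined only for genes with a TE within 10 kb in exactly one strain;
anything else is ambiguous and excluded. A fixed-reference variant keeps the
same denominator but always subtracts the reference strain's mean, so genes
without any nearby TE also get a (sign-conventional) score. A zero
denominator is flagged as NA rather than propagated.

# Population frequency

Per individual and TE, contigs assembled from reads near the insertion site
are summarized as alignment spans. Calling rules, in order of precedence:
**absent** if any contig spans the site with ≥ 50 aligned bp on both sides
(direct observation of the empty allele); otherwise **present** if a contig
with a blast hit to TE sequence aligns ≥ 30 bp on one side without spanning;
otherwise **missing**. TEs with fewer than 100 called alleles (of 197) are
excluded. Frequency is present/called; a TE seen in at least one genome is
"high frequency".

The frequency–effect models mirror the original six: logistic on the
high/low indicator and quasi-Poisson / negative-binomial on the insertion
count, with family as fixed effect (`glm`, `MASS::glm.nb`) or as a random
intercept (`lme4::glmer`, `lme4::glmer.nb`, and `MASS::glmmPQL` for the
quasi-Poisson random-intercept case, which `lme4` does not provide). Only a
random intercept is used — no random slopes. Non-convergence, boundary fits
and quasi-separation (exploding standard errors) are flagged, and flagged
rows are reported as NA rather than dropped silently.

Model calibration uses a *model-matched* generator
(`simulate_te_frequencies()`): responses drawn from the same family the
model fits, with a known coefficient. The mechanistic panel generator
(per-individual presence with logit-linear dependence on the true extent)
is the right input for the end-to-end pipeline, but its coupling constant
is not the coefficient of the fitted models' link scales, so it cannot
serve as the truth in a coefficient-recovery check.

# Heterochromatic k-mers

12-mers are counted canonically (lexicographic minimum of a k-mer and its
reverse complement; k-mers containing N are skipped), normalized by the
library's uniquely-mapped read count (supplied as metadata — mapping is out
of scope), and a k-mer is heterochromatin-enriched when its normalized
IP/input ratio is ≥ 1.5 (boundary included). K-mers absent from the input
have an undefined ratio and are excluded; a pseudocount is available.
Genomic libraries are scored by total enriched-k-mer instances over an
orthologous-exon read normalizer, and species are compared by additive
two-factor ANOVA (species + library preparation), because the paired
library preps are a known technical factor.

# The synthetic-data generator

`sim_config()` fixes the study conditions. Defaults and reasons:

* **Background**: lognormal FE, meanlog 0, sdlog 0.3, at 10-bp resolution —
  median FE 1 with realistic skew; the resolution equals the analysis bin
  so each bin is one independent draw (no pseudo-replication under the
  null). One background landscape is shared by both strains: they are
  near-isogenic, so away from strain-unique insertions they differ only by
  a global baseline (1 vs 1.3; the flank normalization must remove it),
  the spread signal, and replicate noise (lognormal, sdlog 0.05, 2
  replicates per strain).
* **Spread signal**: a plateau of `boost` (default 3×) over `extent_kb`
  each side of the insertion, tapering linearly to background over 1 kb.
  The original data show decay with distance but no functional form; a
  plateau-plus-taper makes "true extent" well defined for recovery tests.
* **Placement**: insertions on a 50-kb grid with ±2-kb jitter, ≥ 25 kb from
  the span ends, so no TE's 40-kb analysis reach overlaps another TE's
  signal, and the generator's euchromatin bounds are already the analyzable
  span (the 0.5-Mb boundary buffer is exercised on dedicated fixtures).
  Infeasible densities are an error, not silent crowding.
* **Population panel**: per-individual presence probability
  `plogis(-5 - 0.7 × extent_kb)` with 10% missing data across 197
  individuals. The intercept puts most insertion frequencies near zero —
  as in the real population sample, where about two-thirds of insertions
  are unobserved — which keeps the high/low dichotomy informative; the
  negative coupling emulates selection against insertions with larger
  epigenetic effects.
* **Expression**: negative-binomial counts with
  log-mean = baseline − coupling × (gene-body multiplier − 1), library
  factors per replicate, plus silent genes (near-zero mean) to exercise
  the expressed-gene filter.
* **Reads**: one shared unique region plus tandem arrays of shared repeat
  units at species-specific copy numbers (default 20% fewer in the second
  species); the IP library over-samples repeat reads by `ip_factor`
  (with unique-read normalization the expected IP/input ratio of repeat
  k-mers is exactly that factor), and two library preps differ by a repeat
  recovery bias, giving the ANOVA a true prep factor.

Every stage derives its RNG stream from one master seed (tracks: seed;
panel: +101; expression: +202; reads: +303), so runs are reproducible byte
for byte.

What the generator does **not** emulate: real sequence composition and
mappability, piRNA biogenesis, regionally correlated replicate noise,
assembly/alignment artifacts in span records, or LOESS-scale meta-structure
in the background. Two consequences worth knowing. First, with iid per-bin
replicate noise the gene-level z-scores at effect genes are far larger in
magnitude than in real data (the denominator shrinks like the square root
of the number of bins per gene body); orderings, stratified comparisons and
sign conventions are the validated quantities, not z magnitudes. Second,
passing recovery tests here demonstrates correctness of the machinery under
the stated signal model, not performance on noisy real tracks.

# Validation layout and problem sizes

Unit tests check every rule against hand-built fixtures and brute-force
oracles (per-base expansion for interval means and binning; exact U
enumeration; hypergeometric tail sums; sort-substitute quantile
normalization; substring-enumeration k-mer counts; an exhaustive
presence-rule grid). The end-to-end suite uses 200-TE simulations on two
5.3-Mb chromosomes for spread recovery, type-I control and method
concordance; 50 replicates of n = 300 for coefficient recovery plus 200
null replicates for calibration; a 210-TE run with genes at ≤ 1 kb for the
gene-level coupling checks; and 20 seeded read sets for the species
comparison. These sizes give stable pass/fail behaviour on a single CPU in
minutes; `scripts/acceptance.R` recomputes the same quantities from scratch
at the same sizes. The analysis scripts under `analysis/` run a smaller
(80-TE) configuration meant for interactive reading.

# Known limitations

* The per-window α = 0.05 with no correction is the source procedure's
  choice; with 40 windows per TE it is liberal for `extent_kb` (though the
  both-sides requirement keeps `has_effect` conservative).
* Whether the original per-window test sampled per-base values or bins is
  unknown; bin size is exposed for sensitivity analysis.
* The quasi-Poisson random-intercept fit (penalized quasi-likelihood) is
  not a true likelihood fit; its p-values are approximate.
* `estimate_frequencies` treats individuals as alleles (inbred panel);
  no diploid genotype model.
* The k-mer counter is in-memory and desk-scale; counting genome-scale
  libraries would need a disk-based counter.
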