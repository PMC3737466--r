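---
title: "Methods: two-colour microarray cross-treatment analysis in crossarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-colour microarray cross-treatment analysis}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossarray)
```

# The analysis this package implements

`crossarray` implements the computational chain used to ask whether several
pharmacological treatments act on the same transcriptional programme when
each treatment is profiled on two-colour spotted microarrays against its
own control:

1. **Spot-level normalization and differential calls.** Each hybridisation
   yields two channel intensities per spot. Log-ratios
   \(M = \log_2(\mathrm{ch}_1/\mathrm{ch}_2)\) are corrected for the
   intensity-dependent dye bias by loess on
   \(A = \tfrac12(\log_2 \mathrm{ch}_1 + \log_2 \mathrm{ch}_2)\), print-tip
   effects are removed by per-block median centering, dye-swap technical
   replicates are sign-corrected and averaged into one log-ratio per
   biological replicate, and each probe is tested against zero with a
   paired t statistic whose variance is pooled across probes after
   trimming. Probes with a Bonferroni-adjusted p below 0.05 are classified
   `UP` or `DOWN` by the sign of their mean log-ratio, all others `NC`.
2. **Cross-treatment enrichment.** The class calls of two treatments are
   cross-classified on their common signal probes into a 3×3 table
   (9 behaviour categories). Cell counts expected under independence are
   \(T_{ij} = R_i C_j / N\); the ratio \(O_{ij}/T_{ij}\) measures how
   strongly a joint behaviour is enriched, and Pearson's chi-squared
   \(\sum (O-T)^2/T\) (df 4) tests independence. For three treatments the
   joint `(UP,UP,UP)` cell is compared with \(N p_1 p_2 p_3\) from the
   marginal class proportions.
3. **Signature similarity.** The K most up- and K most down-regulated
   probes (default K = 200), with their mean log-ratios as reference,
   form a signature; compendium experiments are ranked by the Pearson
   correlation of their log-ratios with the reference over the signature
   genes.
4. **Promoter motif over-representation.** Promoters (up to 1000 bp
   upstream, truncated at neighbouring genes and contig edges, 5'UTRs
   excluded) are scanned for every exact 4–10 bp word occurring in the
   foreground set; each word's promoter presence/absence counts in
   foreground versus a genome-wide background are tested by 2×2 Pearson
   chi-squared at a fixed 1e-5 threshold, and significant words are
   clustered into IUPAC consensus modules that are matched against a
   small editable catalogue of plant cis-elements.

Every stage is driven by the synthetic-data generator, so the whole chain
runs — and is tested — without any external download.

# The synthetic generator and what it emulates

`generator_config()` / `simulate_experiment()` emulate a CATMA-style
design: two biological replicates, each hybridised twice with fluorochrome
reversal (four hybridisations per comparison). For each spot the simulator
draws a base abundance on the log2-intensity scale (normal with mean 10,
sd 1.5, i.e. log-normal intensities), adds the signed true effect to the
treatment channel (sign flipped on swapped arrays), a quadratic
intensity-dependent dye bias (the classic banana-shaped M–A artifact loess
is designed to remove), a per-block print-tip offset, and Gaussian spot
noise; 1% of spots are flagged as badly formed features.

Cross-treatment dependence is controlled by a single dial: a latent
"pathway" pool of regulated genes with a fixed direction of regulation per
gene. A fraction `frac_shared` of each treatment's regulated genes is the
same deterministic subset of that pool (with the pool's directions); the
rest are treatment-specific with random directions. At `frac_shared = 0`
the regulated sets are sampled independently; at 1 they are identical.
Effect magnitudes are constant at `effect_size_log2` (so that parameter
*is* the mean absolute log2 ratio).

The defaults — 2000–4000 probes, 5% regulated, |log2 ratio| = 2, spot
noise sd 0.3 — are desk-scale stand-ins for genome-scale arrays (20,000+
probes). What the generator deliberately does **not** model: probe
cross-hybridisation, spatial scratch artifacts, probe-specific variance
heterogeneity, RNA-pooling structure within biological replicates (pooling
is absorbed into replicate noise), or correlated invalid-spot patterns.
Passing tests therefore demonstrate that the implementation recovers known
structure under the stated noise model, not that the statistics are robust
to every artifact of real slides.

Promoter sets are i.i.d. sequences with base composition
A/T = 0.34, C/G = 0.16 — the AT-richness typical of Arabidopsis
intergenic/promoter regions. This matters statistically: in 1 kb of
uniform-composition sequence a specific 5-mer is present by chance in
~86% of sequences and promoter-level presence/absence carries almost no
signal; at plant-like composition chance presence of `CCGAC` drops to
~35–40% and a planting rate of 0.5 is comfortably detectable.

# Statistical choices and their rationale

**Pooled trimmed variance.** The per-probe sample variance across two
replicates is a very noisy scale estimate, so variances are pooled: probe
variances inside the empirical [0.025, 0.975] quantile band (probes that
do not display extreme variance) are averaged. Two refinements make this
estimator well calibrated:

* *Spot-count weighting.* A replicate that averaged \(k\) technical spots
  has variance \(\sigma^2/k\). Probe variances are therefore rescaled to
  the spot-noise scale by \(n/\sum_i 1/k_i\) before pooling, and each
  probe's standard error is
  \(\sqrt{\hat\sigma^2 \sum_i 1/k_i}\,/\,n\). For complete dye-swap data
  this reduces exactly to \(t = \bar M / \sqrt{s^2_{\rm trim}/n}\);
  without it, probes that lose one technical spot to the invalid-feature
  filter have 1.5–2× the assumed variance and dominate the family-wise
  false positives.
* *Trimming bias correction.* With \(n = 2\) replicates the variances are
  \(\sigma^2 \chi^2_1\)-distributed and the upper 2.5% tail carries ~17%
  of the mean, so the raw trimmed mean underestimates \(\sigma^2\) by
  ~13%. The trimmed mean is divided by its expectation under normality,
  available in closed form from the identity
  \(x f_k(x) = k f_{k+2}(x)\) for the chi-squared density
  (`trim_attenuation()`).

**Reference distribution.** The pooled variance aggregates thousands of
probes, so the statistic is nearly normal — but Bonferroni thresholds sit
at \(z \approx 4\)–4.5, where even a 2–5% sampling jitter in the pooled
variance inflates tail probabilities convexly. The default reference is
therefore Student t with Satterthwaite-matched degrees of freedom
(`trim_effective_df()`, about \(1.33\,m\) for the default band), which
converges to the normal reference at genome scale and keeps the measured
family-wise error of null experiments at the nominal ~5% at desk scale
(`df = Inf` selects the plain normal reference). Whether the original
trimmed-variance procedure pooled variances or substituted per-gene
estimates is not documented; the pooled interpretation is implemented and
both the band and the reference are configurable.

**Loess parameters.** Span 0.3, degree-1 local fits, 3 robustifying
iterations (`limma::loessFit`, which with equal weights is exactly
`stats::lowess`). The normalization chain is *not* idempotent to machine
precision on noisy data — loess is a linear smoother, not a projection, so
a second pass moves log-ratios by \(O(\sigma/\sqrt{\text{span}\cdot n})\),
about 0.01–0.05 at desk scale, whatever loess implementation is used. The
tests assert exact idempotence (1e-6) only on data the smoother fits
exactly (constant or linear trends) and a 0.05 bound on noisy data.

**Chi-squared conventions.** No continuity correction anywhere (plain
Pearson form). 3×3 tables with a theoretical cell below 5 trigger a
warning only; zero marginals reduce the degrees of freedom and mark the
affected ratios undefined. p-values below 2.2e-16 are additionally
reported as the string `"< 2.2e-16"`. Enrichment ratios render with 2
decimals (1 decimal at values ≥ 10; `"0"` for empty observed cells), the
display convention of the published tables.

**Motif testing.** Candidate words are seeded from the foreground only (a
word absent from the foreground cannot be foreground-enriched), both
strands are searched and each word is identified with its reverse
complement (single-strand mode available), counting is promoter
presence/absence (which makes the 2×2 test well defined), and the
foreground remains inside the genome-wide background by default. The fixed
1e-5 threshold is used without further multiplicity correction, read as
"significant below 1e-5". One guard is added: significance requires every
expected cell of the 2×2 table to be at least 5 (Cochran's rule,
`min_expected`). Without it the asymptotic chi-squared approximation
collapses for words present in a handful of foreground promoters and
absent from the background (nominal p ≈ 1e-23 from counts of 2 vs 0), and
thousands of words per run would be called significant under a null in
which the foreground is drawn from the background. With the guard the
null false-positive count matches the test multiplicity expectation.
All words remain reported with their chi-squared p and an `eligible`
flag; only the significance call is gated.

**Clustering and consensus.** Significant words are linked when their
best-offset ungapped similarity (match fraction over an overlap of ≥ 4,
both orientations) reaches 0.75; clusters are the connected components
(single linkage at a fixed threshold). Members are aligned to the
cluster's longest word (ties broken alphabetically) and a position-wise
IUPAC code over the aligned columns gives the consensus. Catalogue
matching scores IUPAC-compatibility (base-set intersection) at the best
offset; equal fractions prefer the longer overlap, remaining ties are
broken alphabetically and flagged.

**Promoter extraction.** The anchor is the gene's 5'-most coordinate
including any annotated 5'UTR (so promoters never contain 5'UTR
sequence), the region is truncated at the nearest boundary of any other
annotated gene on either strand and at the contig edge (both recorded as
`neighbor_overlap` / `contig_start`), minus-strand promoters are
reverse-complemented, and promoters shorter than 20 bp are dropped with a
record. GFF coordinates are handled 1-based inclusive via `rtracklayer`.

**Degenerate inputs and tie-breaks.** A significant probe with mean
log-ratio exactly zero has no direction and is classified `NC`. A probe
absent from both members of a dye-swap pair is excluded; present in one,
it keeps the available measurement with its spot count recorded. A
zero-variance compendium experiment has an undefined correlation and is
flagged and ranked last. An all-zero experiment yields p = 1 everywhere
rather than an error.

# Problem sizes used by the tests and the acceptance script

The suites run at desk scale, chosen as the package's own test design:
null-calibration batteries use 100 simulated experiments of 2000 probes;
the dependence dial uses 10 seeds × 3 shared-fraction levels at 2000
probes; motif recovery uses 10 seeds of 100 foreground vs 5000 background
promoters of 1000 bp with `CCGAC` planted at rate 0.5; signature recovery
uses 10 seeds of 50-experiment compendia. The published contingency
tables are recomputed exactly from their observed counts, which ship as
plain-text fixtures.

# Known limitations

* The generator's noise is homoscedastic per spot; empirical-Bayes or
  per-probe variance modelling is out of scope, as are background
  subtraction and between-array quantile normalization.
* The chi-squared enrichment machinery reports each table singly; no
  multiplicity correction is applied across contingency analyses.
* Motif discovery is exact-word based: gapped motifs, PWMs and
  under-represented (depleted) words are not searched.
* Catalogue matching replaces live motif-database lookups with a small
  packaged file; it identifies the closest packaged pattern, nothing more.
* Published probe counts that depend on the deposited hybridisations
  (e.g. how many genes a given inhibitor induces) are not reproducible
  from synthetic data; the tests target the published tables'
  internally consistent derived cells and property-based substitutes
  instead.
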