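---
title: "Methods: genus-environment associations and genomic correlates of ubiquity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genus-environment associations and genomic correlates of ubiquity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`envubiq` relates genomic characteristics of prokaryotic genera — genome
size, 16S rRNA gene copy number, the number of distinct (non-identical)
16S genes per genome, and COG functional-class content — to two
ecological quantities derived from environmental survey data: the
*ubiquity* of a genus (in how many environments it is found) and its
*environmental preferences* (which environments it is significantly
over-represented in). The evidence for the ecological side is an
observation table of taxonomically classified environmental samples,
each sample carrying exactly one environment label; the evidence for the
genomic side is a cohort of annotated genomes grouped into genera.

The pipeline has five statistical stages, each exposed as a standalone
function and sequenced by `run_pipeline()`:

1. **Annotation-completeness filter.** Public genome cohorts mix deeply
   and shallowly annotated genomes, and functional profiles of the
   latter are distorted. For each genome the annotation ratio
   (COG-annotated ORFs / total ORFs) is computed and only genomes within
   one sample standard deviation of the cohort mean are kept
   (`filter_by_annotation()`). The window is inclusive at its
   boundaries: excluding a measure-zero boundary would be arbitrary and
   would drop degenerate cohorts in which every ratio equals the mean.
   The sample (n-1) SD is used, as is standard for cohort estimates.
   The filter is applied exactly once; re-running it on the kept set
   recomputes the window and is *not* a no-op, which is why the pipeline
   never iterates it.

2. **Functional profiles and genus aggregation.** Per genome, the
   fraction of distinct COG families in each of the 18 functional
   classes (`cog_ratio`) and the fraction of all ORFs assigned to each
   class (`orf_ratio`). The first measures repertoire breadth, the
   second gene investment (paralog expansions move `orf_ratio` but not
   `cog_ratio`). A family mapped to k classes contributes 1/k to each;
   this fractional rule is what keeps `cog_ratio` rows summing to
   exactly 1, the normalization the class-ratio comparisons rely on.
   Family ids missing from the scheme are dropped with a warning by
   default (strict erroring is available), since real annotation dumps
   routinely contain retired ids. Genus values are unweighted arithmetic
   means over member genomes, and the per-COG *presence* of a genus is
   the fraction of member genomes carrying the family — a value in
   [0, 1].

3. **Genus-environment linking.** The genus x environment frequency
   table counts samples of each environment containing each genus,
   after setting to zero any cell in which a genus was seen in exactly
   one sample of an environment (single detections are treated as
   unreliable, e.g. misclassified reads). For every cell with a positive
   count a 2x2 sample-level contingency table is formed — samples of the
   focal environment with/without the genus versus samples of all other
   environments with/without it — and the one-sided Fisher exact
   (hypergeometric upper-tail) p-value computed. One-sided enrichment is
   the deliberate reading of "linked to an environment": a link claims
   over-representation, not mere difference; a two-sided mode is
   available behind `alternative = "two.sided"`. All tested pairs form a
   single Benjamini-Hochberg family (per-environment families would
   change the meaning of the reported FDR and were rejected); cells
   with zero count are never tested and never enter the family. A pair
   is linked when the adjusted p-value is below 0.01.

4. **Ubiquity and the trait battery.** Ubiquity counts environments with
   post-exclusion presence (at least 2 containing samples), i.e. it is
   an observational quantity, not a significance-based one; the linked
   set is kept separately for the environmental-preference groupings.
   Traits are compared across ubiquity by ordinary least squares and by
   Kruskal-Wallis on ubiquity groups, and across environments by a
   global Kruskal-Wallis plus per-environment Mann-Whitney tests of
   linked genera versus all others. A genus linked to several
   environments belongs to every such group (membership by preference,
   not partition); primary-environment-only grouping would discard the
   generalists the analysis is about. Class-ratio-versus-genome-size
   regressions within each environment group check that class
   differences between environments are not genome-size artifacts. No
   multiple-testing correction is applied across this battery — each
   test is reported with its raw p-value against the uniform 0.01
   working threshold — a deliberate reproduction of how such trait
   batteries are conventionally reported.

5. **Per-COG ubiquity screen.** For each COG, genera are pooled by
   ubiquity, bin means of presence computed, and presence regressed on
   the bin value. The regression is on bin means, not genus-level
   points: that is the literal reading of the pooling procedure, and it
   is what makes a high R-squared attainable at all (genus-level
   presences are Bernoulli-noisy). A family is selected when the slope
   p-value is below 0.01 and the *adjusted* R-squared exceeds 0.7 — the
   adjusted form is gated on (and both are reported) because the n - 2
   df penalty is what makes the threshold meaningful at a handful of
   bins; `min_bins = 4` keeps it defined and stable. A positive-slope
   filter is on by default, since the screen targets families whose
   presence rises with ubiquity; declining families can pass the fit
   gate when the filter is disabled.

6. **Randomized-table control.** Each replicate redistributes every
   genus's detections uniformly across all samples, preserving the two
   margins the Fisher test conditions on — each genus's total detection
   count and every sample's environment label — then reruns exclusion,
   testing and adjustment. The per-replicate linked-pair counts and the
   fraction of replicates with any link are both reported; on
   preference-free data the combination of Fisher discreteness and FDR
   control at 0.01 makes links vanishingly rare.

# The synthetic-data generator

No snapshot of the original genome cohort or of the environmental sample
database is redistributable, so the package ships a generator
(`simulate_dataset()`) whose defaults define the study conditions used
throughout the tests:

* **Detections.** Genus g is detected in a sample of environment e with
  probability obtained by scaling the baseline p = 0.1 on the odds
  scale: a preference multiplier m gives
  p' = (m p/(1-p)) / (1 + m p/(1-p)). Odds scaling keeps probabilities
  valid for any m > 0 and matches the enrichment-test target. The
  default cohort is 20 genera, 6 environments, 50 samples per
  environment.
* **Planted ubiquity** of a genus is its number of environments with
  multiplier > 1 (1 if none) — the single knob the trait gradients key
  on.
* **Genome size** is linear in planted ubiquity:
  3 Mb + 200 kb x ubiquity + N(0, 400 kb). The default effect is half a
  noise SD per environment — large enough to be a real gradient, small
  enough that detection is a statistical question.
* **16S copies** are drawn per the regime (mean, dispersion) of the
  genus's primary environment (the one with the largest multiplier;
  uniform random for preference-free genera), rounded with a floor of
  1; default mean 4, dispersion 1.5, the typical prokaryotic range.
  Copies derive from one fixed 200-nt reference with per-site
  substitutions at rate 0.005, so distinct-copy counting (exact string
  equality after uppercasing — the only parameter-free reading of
  "non-identical") is genuinely exercised; rate 0 makes all copies
  identical.
* **COG content.** Adaptive families' presence probability interpolates
  linearly from 0.1 at ubiquity 1 to 0.9 at the maximum; null families
  get a ubiquity-independent probability drawn once per family from
  U(0.05, 0.95). Annotated-ORF counts are distributed multinomially over
  the present families, so the annotation ratio and the COG content are
  mutually consistent.
* **Annotation ratio** per genome is truncated-normal on (0, 1] with
  mean 0.715 and SD 0.157, the completeness regime typical of public
  complete-genome cohorts; rejection sampling is simple and adequate at
  these scales. Truncation at 1 shifts the realized mean to about 0.70
  and the within-one-SD mass to about 0.66-0.68 — the filter-retention
  checks account for this.
* **Sample census.** The observation table carries all samples,
  including detection-free ones, mirroring survey semantics (a sample
  with no detected genus is still a sample of its environment); deriving
  environment totals from detection rows alone would undercount them by
  the probability mass of empty samples.

What the generator does *not* emulate: real 16S sequence evolution,
chimeras or amplicon noise; the taxonomy-assignment step that produces
genus calls from reads; phylogenetic correlation between genera;
covariation between genome size and COG repertoire beyond the planted
gradients. Passing recovery tests therefore demonstrates that the
statistical machinery detects the structure it claims to detect under a
clean generative model — not that real survey data are free of the
confounders the generator omits. Genera present in samples but absent
from the genome cohort are not generated; the pipeline handles them on
real inputs by leaving them out of the trait stages.

# Numerical choices and degenerate inputs

* `fisher_enrichment()` is the vectorized hypergeometric upper tail;
  the all-zero table returns p = 1 by convention.
* `mann_whitney()` is exact (shift-algorithm enumeration of the
  rank-sum distribution on doubled midranks, so ties are handled
  exactly) up to pooled n = 20, with
  p = min(1, 2 min(P(U <= u), P(U >= u))); larger samples use the
  normal approximation with tie correction. `kruskal_wallis()` reports
  the tie-corrected H with the chi-squared p-value, plus an exact
  enumeration mode for pooled n <= 10; with all observations tied, H is
  defined as 0 and p = 1.
* `linear_regression()` defines the zero-variance response case (slope
  0, R-squared 0, p = 1) instead of erroring, because constant pooled
  presences occur routinely in the screen; constant predictors are
  errors.
* Ubiquity bins with fewer than 3 genera are merged upward for bin-mean
  regressions (class-ratio trends), with the remainder folding into the
  last closed bin; no minimum occupancy is imposed on the screen's
  pooling itself, where a lone genus legitimately defines its bin.
* Class-ratio-versus-ubiquity regressions run on bin means by default
  (genus-level points remain available via `on_bins = FALSE`), the
  granularity at which such trends are summarized.
* All randomness flows through explicit seeds (`sim_config(seed = )`,
  `randomization_control(seed = )`, `pipeline_config(seed = )`);
  identical seeds give byte-identical pipeline output directories.

# Problem sizes used by the shipped checks

The test-suite and acceptance-script simulations use cohort sizes chosen
a priori by power analysis of the generative model: association recovery
uses 20 genera x 6 environments x 100 samples per environment with
multiplier-10 preferences (expected per-pair power ~1 under the
hypergeometric tail); size-trend recovery uses 150 genera over
ubiquities 1-6 with a 0.5-SD-per-environment effect (expected t around
14); the COG screen uses 9 ubiquity bins x 6 genera x 5 genomes, i.e. 30
genomes per bin, for which the binomial-noise model predicts selection
power above 0.99 at the 0.7 adjusted R-squared gate; the null control
uses the default cohort with 100 randomized tables. Replicate counts
(100-200 seeds per recovery check) put the Monte-Carlo error of the
reported rates well below the margins asserted.

# Known limitations

* Exact rank-test paths are enumeration-bounded (pooled n of 20 for
  Mann-Whitney, 10 for exact Kruskal-Wallis); beyond that the usual
  approximations apply.
* The contingency construction treats samples as exchangeable units
  within and across environments; hierarchical sampling designs
  (multiple samples from one site) would need a different null.
* The screen's bin-mean regression discards bin occupancy: a bin of one
  genus weighs as much as a bin of fifty. This is faithful to the
  pooling definition but means sparse extreme bins can drive fits.
* Genus aggregation is unweighted over genomes, so heavily sequenced
  species dominate their genus mean exactly as they would in the
  motivating analysis.
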