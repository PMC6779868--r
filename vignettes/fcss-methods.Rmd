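---
title: "Inferring plant reproductive modes from flow cytometric seed screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring plant reproductive modes from flow cytometric seed screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcss)
```

## The model

A flow cytometric seed screen (FCSS) measures the relative DNA contents
of a seed's embryo and endosperm nuclei in one run. Because the embryo
and the endosperm are assembled from a small, enumerable set of gametic
contributions, their C-value ratio identifies the formation pathway
without knowing absolute ploidy. `fcss` makes the underlying bookkeeping
an explicit, testable calculus. A *scenario* is

* maternal ploidy $m$ (in multiples of the monoploid genome $x$),
* whether the egg cell was meiotically reduced ($m/2$) or not ($m$),
* whether the embryo was fertilized (one sperm),
* the number of polar nuclei in the central cell, $k \in \{2, 3\}$
  (three only in rare tri-nucleate embryo sacs), and their reduction,
* the number of sperm fusing with the central cell, $s \in \{0, 1, 2\}$
  ($s = 0$ is autonomous endosperm), with pollen ploidy $p$ and sperm
  reduction.

Then

$$C_{embryo} = C_{egg} + f\,C_{sperm}, \qquad
  C_{endosperm} = k\,C_{polar} + s\,C_{sperm},$$

with $f = 1$ for a fertilized embryo. Sexual double fertilization in a
diploid gives the familiar 2C embryo / 3C endosperm (quotient 1.5);
autonomous apomixis gives 2/4; pseudogamy with one reduced or unreduced
sperm gives 2/5 or 2/6; tri-nucleate variants reach 2/7–2/10; the BIII
hybrid (unreduced egg fertilized by an unreduced sperm) gives 4/6.
Fractional C-values arising from reduced gametes of odd ploidy are
multiples of $x/2$ and are carried exactly.

`enumerate_scenarios()` builds candidate sets. The default set for a
diploid comprises the four canonical profiles 2/3, 2/4, 2/5 and 2/6,
with both mechanistic routes to 2/6 (one unreduced sperm; two reduced
sperms) kept as separate entries so classification can report the tie —
they are indistinguishable by DNA amount and genuinely ambiguous. The
*extended* set (per species, via configuration rather than code) adds
tri-nucleate central cells, the two-unreduced-sperm combination and BIII
hybrids; we keep these out of the default because they would otherwise
inflate the candidate set for the many taxa where they never occur, and
only a minority of taxa show such profiles.

## Classification and its tolerance

`classify_quotient()` matches an observed endosperm:embryo quotient to
the nearest expected quotient by relative deviation. The default
tolerance of 8% was chosen from the geometry of the default diploid set:
adjacent expected quotients (1.5, 2.0, 2.5, 3.0) differ by 20–33%, so an
8% band separates them cleanly while absorbing realistic peak-position
error (simulated CVs of ~3% give quotient errors well under 2%).
Quotients matching nothing are reported `unresolved`, never force-fitted;
real screens contain such seeds (aneuploid or unbalanced gametes) and the
honest output is the deviation, which is always reported for audit.

Where a quotient ties across *mode classes* — e.g. BIII 4/6 and sexual
2/3 both give 1.5 when the extended set is active — the ratio alone
cannot decide, and the call keeps all tied scenarios. The reported
single `mode` follows a parsimony preference (sexual, then pseudogamous,
then autonomous, then BIII), reflecting base rates in screens; resolving
such ties properly requires absolute genome sizes, which is what the
back-calculation below is for.

## Internal standards and gamete back-calculation

With a co-chopped internal standard of known 2C content (leaf tissue of
*Pisum sativum* 'Ctirad', 2C = 9.09 pg, or *Bellis perennis*, 2C = 3.38
pg), fluorescence converts to picograms by simple proportionality
(`relative_genome_size()`, linearity assumed). `gamete_backcalc()` then
solves each candidate scenario for the gamete genome sizes it implies:
with $u$ the maternal genome size per $x$ and $v$ the sperm genome size,

$$\mathrm{embryo} = C_{egg} u + f v, \qquad
  \mathrm{endosperm} = k\,C_{polar} u + s v .$$

Parthenogenetic scenarios fix $u$ from the embryo alone and leave the
endosperm equation as a residual check; fertilized-embryo scenarios are
a 2×2 linear solve. A scenario is *consistent* when every implied gamete
is close (default 10% relative) to the unreduced or half the reduced
maternal genome size — for parthenogenetic embryos that reference equals
the embryo genome size, the natural comparison point; for fertilized
embryos (sexual, BIII) the maternal reference is the coherent
generalization, since the embryo then contains the sperm as well.
Equally consistent scenarios are returned as alternates rather than
picked arbitrarily.

## Histogram analysis

`detect_peaks()` is deliberately simple and auditable: a 5-channel
moving average, local maxima above a prominence floor (4% of the tallest
smoothed channel; boundary channels excluded, which also discards the
monotone debris edge), sigma estimated from the full width at half
maximum, and moments computed from the raw counts in a ±2.5 sigma
window (≥ 98% of a Gaussian peak, limited debris leakage). Histograms
under 5000 recorded particles are analysed with a warning rather than
refused — weak samples from herbarium seeds are common and a soft gate
keeps them visible. Peaks with CV above 8% are flagged, not dropped.

`assign_roles()` encodes the screen's reading rules:

* the **embryo** is the dominant peak — largest nuclei count outside the
  internal-standard window; an exact tie is broken toward the lower
  position and logged;
* the **endosperm G1** is the nearest peak above the embryo with a
  quotient in [1.2, 6.0] and a nuclei count at least 15% of the embryo
  count (endosperm counts run near 40% of embryo counts in typical
  seeds, so this floor is permissive); weak peaks at ~2× the embryo with
  under 20% of its count are flagged as the embryo G2 replicate;
* the **endopolyploidy second-peak rule**: when the only endosperm
  signal is a weak peak at ~2× an expected endosperm position and the
  corresponding G1 position is empty, that second peak's parameters are
  recorded and its mean fluorescence divided by two. The count condition
  is what disambiguates this from a genuine strong peak at a valid
  quotient (e.g. a true 2/6 endosperm), mirroring the screen's trigger —
  the rule exists for taxa whose endosperm G1 is suppressed by strong
  endopolyploidy;
* a lone embryo peak yields a *no-endosperm* measurement; species whose
  every sample ends there are excluded from mode inference rather than
  guessed at.

The endosperm percentage of a seed is the endosperm share of G1 nuclei
counts, and species/family summaries average per-seed percentages (not
pooled counts), so seeds with different totals weigh equally.

## The synthetic-data generator

`simulate_histogram()` draws each of `total_particles` events from a
mixture of Gaussian peaks and exponential debris and bins them on 1024
linear channels, so histogram totals are exact and runs are bitwise
reproducible under a seed. Defaults encode the screen conditions the
package is validated under: 5000 recorded particles per sample, peak CV
3%, embryo at channel 100, endosperm counts 40% of embryo counts (the
ratio seen in large seed-screen summaries), G2 replicates at 10% of
their G1 peak at exactly twice its position, 20% debris with a 20-channel
decay constant, and an endopolyploid variant that suppresses the
endosperm G1 and leaves only a weak (12% of embryo) replicate peak.
Scenario mixes are allocated to seeds by largest-remainder rounding and
then shuffled, so a 20:2 mix of 22 seeds contains exactly two apomictic
seeds in every run — facultative-apomixis recovery is testable without
Monte Carlo slack.

What the generator does *not* emulate: fluorochrome base-composition
bias (DAPI's AT preference), S-phase continua between G1 and G2,
instrument drift, aggregates/doublets, or non-linear amplifier response.
Passing tests therefore demonstrate that the analysis chain is correct
under idealized Gaussian-plus-debris signals, not that it is robust to
every instrument artifact; on real data the manual-review hooks (logged
tie-breaks, deviations, CV flags) matter.

The trait-table generator emulates a screen-scale comparison: 220
species, 13 of them apomicts, continuous traits as unit-variance
Gaussians with configurable standardized group shifts, and binary
clonal-growth indicators with per-group prevalences. Its default effect
settings encode a strong clonality contrast (prevalence 0.85 in apomicts
vs 0.33 in sexuals) and moderate (0.5 sd) moisture and elevation-range
shifts; these are effect-size settings for power checking, not data to
be reproduced.

## Trait comparison

`rda_pseudo_F()` implements redundancy analysis for a single binary
predictor directly as a projection: trait columns are centered and
scaled to unit variance (the traits mix %, pg, cm and indicator units;
without scaling the largest-variance trait dominates), and with $q = 1$
constrained axis

$$F = \frac{SS_{explained}/1}{SS_{residual}/(n-2)} .$$

On one column this is exactly the classical two-group ANOVA F, which the
test suite verifies to 1e-10 against the closed form, alongside a
cross-check against an independent constrained-ordination implementation.
`permutation_test()` permutes the group labels ($p = (1 + \#\{F^\ast \ge
F\})/(1 + n_{perm})$, so the attainable minimum is $1/(n_{perm}+1)$);
screens conventionally use 9999 permutations and that is the default.
The univariate summary uses a permutation test on the mean difference
for continuous traits and Fisher's exact test for binary traits, with
conventional unadjusted significance stars (a Holm flag is available) —
trait tables in this literature print unadjusted stars.

`run_compare()` reports the all-traits analysis followed by one analysis
per trait group (whole-plant, organ, clonal, ecological by default),
because a syndrome can be significant overall while residing in one
group.

## Reproducibility and problem sizes

Every simulation and permutation takes an explicit integer seed;
`run_screen()`/`run_compare()` write the seed, tolerances and a config
hash into their logs and reruns are byte-identical. The validation suite
sizes were chosen to give tight Monte Carlo bands at interactive
runtimes: 200 simulated seeds per scenario for end-to-end mode recovery
(binomial 95% band ±3% around the 95% threshold), 1000 histograms for
peak-position accuracy, 100 random instances for the ANOVA equivalence,
and 500 null replicates at 999 permutations for the type-I error check
(95% band [0.032, 0.068] at the nominal 0.05).

## Known limitations

* Pooled multi-seed samples with *mixed* reproductive modes produce
  superimposed peak sets; the pipeline analyses such samples as one seed
  and will typically return extra unresolved peaks. The screen practice
  of re-measuring single seeds when variation is suspected applies.
* Fluorescence is assumed linear; log-amplified data must be linearized
  upstream.
* The quotient calculus cannot separate mechanisms sharing a DNA amount
  (2/6's two routes; BIII 4/6 vs sexual 2/3 without a standard); the
  package surfaces these as explicit ties instead of deciding.
* Empirical constants of any particular published screen (species
  counts, trait means, pseudo-F values) depend on raw data that travels
  with that study, not with this package; the test suite validates the
  machinery on synthetic ground truth instead.
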