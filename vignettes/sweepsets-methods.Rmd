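---
title: "Detecting polygenic selection with sweepsets: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting polygenic selection with sweepsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepsets)
```

## The problem

Complex traits are polygenic: selection acting on them shifts allele
frequencies at many loci, each too weakly to clear a genome-wide
significance threshold on its own. A per-SNP selection scan therefore
misses polygenic adaptation almost by construction. The remedy this
package implements is to combine two complementary SNP-level scans with
gene-set-level permutation tests: individually unremarkable signals that
co-occur inside a functionally related set of genes become detectable at
the set level.

The pipeline has seven stages, each exposed as an ordinary function that
accepts and returns plain tables: two selection scans (`ihs_scan()`,
`xpclr_scan()`), SNP-to-gene assignment (`assign_snps_to_genes()`, with
`consensus_position_filter()` for reconciling two position sources),
gene-set preparation (`prepare_genesets()`), two permutation enrichment
engines (`sumscore_gsea()` with `prune_overlapping_genes()`, and
`candidate_gsea()`), false-discovery-rate control (`compute_qvalues()`),
and disease-gene outlier flagging (`flag_disease_genes()`).
`run_pipeline()` chains them end to end from a config.

Because the analyses that motivated this design ran on resources far
beyond a test suite (millions of genotyped SNPs across human
populations, thousands of curated gene sets), the package ships a
first-class synthetic-data module — a forward
Wright–Fisher simulator with recombination and planted sweeps — so that
every stage, and the pipeline as a whole, is testable against known
ground truth.

## The haplotype-homozygosity scan (iHS)

For a focal SNP with ancestral/derived polarity, the extended haplotype
homozygosity (EHH) at a flanking SNP $x$ is the probability that two
randomly drawn haplotypes carrying the same core allele are identical
over the whole stretch from the focal SNP to $x$:

$$\mathrm{EHH}(x) = \frac{\sum_h \binom{n_h}{2}}{\binom{n}{2}},$$

where $n_h$ counts carriers of each distinct extended haplotype $h$.
The curve starts at 1 and decays with distance; a recent sweep retards
the decay on the swept allele's background. Each curve is extended while
EHH $\ge 0.05$ and stops at the first SNP below that value; the area
under the curve against genetic distance (trapezoid rule, including the
crossing segment) is the integrated haplotype homozygosity, iHH. The
unstandardized score is $\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$, and scores
are standardized to mean 0, variance 1 within derived-allele-frequency
bins (20 equal-width bins by default; bins with fewer than two defined
scores or zero spread merge leftwards), because the expected decay
depends strongly on the derived frequency.

Two rules make the statistic undefined, and the scan reports the reason
rather than a number: the curve reaches the chromosome end, or the
physical gap to the next SNP exceeds 200 kb, before crossing the
stopping value. The gap is measured between consecutive SNPs, not from
the focal SNP. The stopping rule is stated in the literature in a form
that is self-contradictory for a decaying curve ("until EHH is equal to
or larger than 0.05"); we read it as *extend while EHH $\ge$ 0.05* and
include the crossing segment in the integral, and both the threshold and
the gap size are arguments of `compute_ehh()`.

Defaults: minor-allele-frequency floor 0.05; two-sided candidate
polarity ($|z|$), since extreme scores of either sign indicate sweeps on
the derived or the ancestral background.

## The cross-population composite-likelihood scan (XP-CLR style)

The second scan contrasts an *objective* population (tested for
selection) against a *reference* population (standing in for neutrality)
using multilocus allele-frequency differentiation. Only SNPs polymorphic
in both samples are used — scores at fixed SNPs are dominated by false
positives. A physical grid is laid every 200 bp; the window at a grid
point holds the nearest 50 retained SNPs (25 per side where available).

Under neutral drift the objective frequency $p_1$ given the reference
frequency $p_2$ is modelled as $Z \sim \mathcal N(p_2,\,\omega\,
p_2(1-p_2))$ truncated to $(0,1)$ and renormalized, with the drift
coefficient $\omega$ estimated by the method of moments,
$\hat\omega = \overline{(p_1-p_2)^2 / (p_2(1-p_2))}$, floored at
$10^{-4}$. Under a sweep of scale $q$ (Morgans) at the grid point, a
lineage at recombination distance $r_k$ escapes the sweep with
probability $c_k = 1 - e^{-r_k/q}$ ($c_k = 1$ at $q = 0$, which
reproduces neutrality exactly), giving the two-component mixture

$$p_1 = \begin{cases} (1-c_k) + c_k Z & \text{with probability } p_2\\
c_k Z & \text{with probability } 1-p_2.\end{cases}$$

The window statistic is $2\,[\max_{q \in Q} \ell(q) - \ell(0)] \ge 0$
with $Q = \{0\} \cup$ 15 log-spaced points in $[10^{-6}, 0.1]$ Morgans,
and per-SNP weights $w_k = 1/m_k$, where $m_k$ counts window SNPs in
strong linkage disequilibrium with SNP $k$ ($r^2 \ge 0.95$ in the
reference panel), so that a block of redundant SNPs contributes like one
observation. These internals follow the logic of the established
cross-population composite-likelihood method; where the original
publications defer details, the choices here are explicit, config-
switchable, and pinned down by a numerical-quadrature oracle in the test
suite (the mixture density integrates to 1 within $10^{-6}$ across the
tested $(p_2, \omega, c)$ grid, and log-densities match independent
quadrature).

Each SNP inherits the score of its nearest grid point (ties toward the
lower coordinate), and SNP scores are normalized genome-wide to mean 0,
unit variance, separately per population pair. Per-SNP log-densities are
floored at $-50$ to keep one outlier from dominating a window. Windows
are 50 SNPs *in total* (not per side), and both population orientations
can be run by swapping `objective` and `reference`.

## From SNPs to genes to sets

SNP positions can be taken from two independent mapping sources; only
SNPs placed at the identical chromosome and position by both are kept
(`consensus_position_filter()`). Genes with several isoforms are
collapsed to the utmost start and end over all isoforms, and a SNP
belongs to a gene iff it lies inside that union interval (1-based,
inclusive on both ends); a SNP inside overlapping genes counts for all
of them. No flank is added by default (`flank_bp = 0` is exposed).

Gene-set hygiene mirrors standard curation practice: members are
restricted to genes that received at least one scored SNP, sets with
fewer than 10 genes are dropped, and near-duplicate sets are merged
greedily while any pair exceeds 95% similarity — the highest-similarity
pair first, ties broken lexicographically, which makes the procedure
deterministic and order-independent. "Similarity" is the Jaccard index
by default; the overlap coefficient is available behind a flag because
the original analyses do not pin the measure down. The size floor is
re-applied after merging: unions only grow, but the restriction to
scored genes can shrink sets.

## The two enrichment engines

Both engines calculate set-level significance by permutation and are
deliberately different, because they answer slightly different
questions.

**Sum-of-scores engine** (`sumscore_gsea()`). The gene score is the
maximum $|z|$ over the gene's SNPs, and the set statistic is the sum of
its gene scores. Long genes contain more SNPs and therefore higher
maxima by chance; the null corrects this *gene-length bias* by binning
genes on SNP count (equal-occupancy rank bins; ties share a bin) and
replacing each member with a random unused gene from the same bin. With
$B$ permutations, $p = (1 + \#\{S_\text{null} \ge S_\text{obs}\})/(1+B)$
— never zero. Overlap between sets is corrected by one-pass pruning
(`prune_overlapping_genes()`): sets are ranked by $p$ (ties: smaller set
first, then name), genes claimed by a better-ranked set are removed from
worse-ranked ones, sets falling below the size floor are dropped, and
pruned survivors are re-tested. One pass, not a fixpoint iteration:
deterministic and sufficient to stop one swept region shared by many
sets from flooding the results.

**Candidate-SNP engine** (`candidate_gsea()`). Candidates are SNPs with
$|z|$ in the top percentile (1% by default; ties at the cutoff all
included). The set statistic is the number of member genes containing at
least one candidate, and each permutation redraws the same number of
SNPs uniformly from all scored SNPs. Because genes are hit in proportion
to their SNP content, this null absorbs gene length and overlap without
explicit correction. In the one-SNP-per-gene limit the permutation
p-value converges to the hypergeometric tail, which the test suite
checks at $B = 10^5$ against `phyper()`. Gene-level counting is the
default; SNP-level counting sits behind `mode = "snp"`.

q-values are Benjamini–Hochberg (`stats::p.adjust`), with significance
reported at $q \le 0.09$; the original q-value procedure is not printed
in the sources this design follows, so the standard step-up estimator
was chosen and is exposed as a function boundary rather than buried.
Engine defaults are $B = 10^4$ (sum) and $10^5$ (candidate); tests and
the acceptance script use smaller $B$ (300–20 000) chosen so that the
Monte-Carlo error, $\sqrt{p(1-p)/B}$, is well below the tolerance of
each assertion.

**Disease genes** (`flag_disease_genes()`). Genes whose score reaches
the top 1% of gene scores are flagged (ties at the cutoff included, so
the flag set is invariant under monotone transformations), and a
user-supplied disease list is tested for over-representation among the
flagged genes with a one-sided hypergeometric test over all scored
genes. The 1% cutoff is applied to *gene*-level scores; a SNP-level
variant is a documented alternative.

## The synthetic-data generator

`simulate_sweep_panel()` is a forward diploid Wright–Fisher simulation:
random mating, additive fitnesses $1, 1+s, 1+2s$ at a single selected
site, and per-generation Poisson crossovers placed on the genetic map.
Two populations are built from founder pools of $K = 200$ haplotypes —
each founder a recombinant mosaic (expected segment 0.05 cM) of random
binary haplotypes whose per-SNP frequencies come from a
Uniform(0.05, 0.95) ancestral prior — and drift independently for 30
generations. The pool must be large: founder-pool sampling adds variance
$p(1-p)/2K$ to each population's frequencies, so a small pool (tens of
founders) both inflates realized differentiation well beyond the
configured $F$ and lets whole drifted founder haplotypes masquerade as
selective sweeps — clustered blocks of extreme differentiation that no
scan can tell from the real thing. At $K = 200$ the pool term
($\approx 0.0025$) is negligible against $F = 0.05$ and the realized
per-SNP differentiation matches the Balding–Nichols moments the
frequency generator is tested against. Population divergence is supplied by the Balding–Nichols
model at the founder level: each population's founder frequencies are
beta-distributed around the shared ancestral frequency with its own
coefficient $F$ (0.05 by default), exactly mirroring the frequency-level
generator `simulate_divergence_freqs()` whose moments are checked
analytically ($\mathbb E[(p_1-p_2)^2/\bar p(1-\bar p)] \approx 2F$).

This founder-level divergence is a deliberate design choice, not a
shortcut. Producing $F = 0.05$ by drift alone at a simulable population
size requires $G/2N \approx 0.05$, which forces roughly 5% of haplotype
pairs to be identical by descent — above the 0.05 EHH stopping value, so
iHS would be undefined genome-wide. Decoupling frequency divergence
(Balding–Nichols founders) from haplotype diversity (short drift phase)
keeps both in the regime the scans assume. For the same reason the
default map is long relative to the sweeps simulated: 2 Mb at a flat
3 cM/Mb (a 6 cM map) against sweep footprints of roughly $s/\ln(2Ns)$
Morgans ($\approx$ 1.3 cM at $s = 0.1$). On a 1 cM map the footprint
exceeds the chromosome and EHH never reaches its stopping value near a
sweep.

Defaults, chosen once as a realistic desk-scale study and used as the
fixed conditions of the acceptance tests: $N = 1000$ diploids per
population (50 sampled for the panel), 1500 SNPs, hard sweeps from a
single new copy run to fixation (lost or stalled attempts restarted from
a fresh seed stream, cap 100), incomplete sweeps from 5% standing
variation stopped at the first generation the target frequency (0.5) is
reached, both populations always sampled at the same generation. With
$s = 0$ the tracked site is a martingale, which the tests verify over
replicates.

`generate_annotation_bundle()` adds the annotation side: genes tiling
the chromosome (3–12 kb, 1–3 isoforms whose union reproduces the gene
span), random gene sets with configurable size and pairwise Jaccard
overlap, one *planted* set containing the genes within 30 kb of the
sweep, and a disease list overlapping the planted genes at a
configurable rate.

The end-to-end enrichment checks use a scenario chosen deliberately
inside the regime the method is designed for: a still-segregating sweep
of a single new mutation (stopped at frequency 0.9, $s = 0.2$) in a
high-recombination region (10 cM/Mb) of a two-chromosome genome (the
second chromosome is neutral), with the planted gene set spanning 150 kb
around the site. Each ingredient removes a failure mode that is an
artifact of desk-scale genomes rather than of the method: a completed
sweep fixes its core, and the polymorphic-in-both filter then leaves the
planted genes unscorable; a slow sweep accumulates drift background for
hundreds of generations; at average recombination the sweep footprint
($\approx s/\ln(2Ns)$ Morgans) spans a quarter of a 2 Mb chromosome;
and on a one-chromosome genome the planted set is so large a fraction of
all genes that random null sets overlap the signal and set-level
contrast vanishes. On a real genome scan none of these constraints
bind — a sweep occupies a vanishing fraction of the genome.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: coalescent-scale deep genealogies
(desk-scale $N$ compresses haplotype diversity), demographic history
beyond a single split (no bottlenecks, expansions, migration),
background selection, variable recombination hotspots (piecewise-
constant maps are supported but the default is flat), genotyping error
and ascertainment bias, and soft sweeps from recurrent mutation
(soft-sweep-like signals arise only via the standing-variation mode).

## Numerical and procedural choices

- Internal coordinates are 1-based inclusive everywhere (VCF
  convention); BED's 0-based half-open intervals are converted at the
  parsing boundary, once.
- Ancestral alleles come from a VCF INFO key (`AA` by default); records
  that are multiallelic, unphased, or lack a usable annotation are
  rejected in strict mode or dropped with a count in lenient mode.
- Genetic positions interpolate piecewise-linearly from the map; sites
  outside the mapped range clamp to the nearest endpoint with a warning.
- The sweep-scale grid maximization is a fixed 16-point grid rather than
  a continuous optimizer: the profile over $q$ is cheap, global, and
  reproducible, and $0 \in Q$ guarantees non-negative scores.
- Degenerate cases return flagged values, not silent numbers: single-
  point EHH curves (zero area), windows with fewer than two SNPs
  (skipped, logged), frequency bins too small to standardize (merged,
  counted), density underflows (floored at $-50$ per SNP, counted).
- All randomness flows from explicit seeds; the pipeline derives
  per-stage seeds from the global seed by a stable label hash so a stage
  re-run in isolation reproduces its in-pipeline result, and re-running
  a config is byte-identical.

## Problem sizes used by the tests

Unit tests run on constructed panels of tens of haplotypes and tens of
SNPs where oracles (pairwise enumeration for EHH, double loops for
interval assignment, quadrature for the mixture density, exhaustive
subset enumeration and closed-form hypergeometric tails for the engines)
are exact or cheap. The acceptance checks run the full generator at its
default conditions: 20 hard-sweep replicates for scan power, 20
end-to-end replicates for enrichment power (the planted set must reach
$q \le 0.09$ under both engines in at least 80% of replicates), three
neutral panels for the 1% cutoff calibration, and $10^5$ permutations
for the hypergeometric convergence check. One calibration caveat is
documented rather than hidden: at a 2 Mb simulated genome the top 1% of
grid points lies *inside* a planted sweep's own footprint, so the
power check compares the sweep-proximal mean against the 99th percentile
of grid points more than 500 kb from the site — the uncontaminated
estimator of the genome-wide background cutoff that the property
presumes (in a real genome scan a single sweep occupies a vanishing
fraction of grid points and the distinction disappears).

## Known limitations

The drift kernel is a truncated normal, adequate for moderate $F$ and
interior frequencies but thin-tailed relative to the beta distribution
near fixation; sample-frequency noise is not modelled in the likelihood
(a documented non-goal), which inflates background scores at extreme
reference frequencies; the method-of-moments $\hat\omega$ is sensitive
to those same extremes. The one-pass pruning is order-dependent by
design (better-ranked sets claim genes first). iHS is undefined — by
rule, and correctly so — near chromosome ends, across >200 kb gaps, and
wherever haplotype diversity is too low for EHH to decay below 0.05;
on desk-scale panels this removes a substantial fraction of extreme-
frequency SNPs, and the scan reports exactly which and why.
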