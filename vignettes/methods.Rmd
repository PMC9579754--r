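---
title: "Methods: windowed selection scans for two-founder E&R experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed selection scans for two-founder E&R experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experimental design and what is being estimated

Two fully homozygous *Drosophila melanogaster* founder strains are mixed —
30% of flies carrying the focal founder genotype, 70% the other — and
replicate populations of census size N = 1500 evolve for 20 discrete
generations under one of two temperature regimes (18°C or 29°C), three
replicates each. At generation 20 each replicate is pool-sequenced, and
read counts at *marker SNPs* — sites where the founders carry different,
(nearly) fixed alleles — estimate the frequency of the focal founder's
haplotype along the genome.

Because both regimes share the same laboratory environment, the response
decomposes: windows that change identically in both regimes reflect
laboratory adaptation; windows changing in only one regime, or in opposite
directions, reflect temperature-specific selection; windows changing in
the same direction but with different magnitude reflect a joint effect.
The package's unit of inference is the *windowed allele frequency change*

AFC_w = (mean focal-allele frequency over the w SNPs of the window) − p₀,

with p₀ = 0.3, compared per regime against a simulated neutral null and
between regimes with a linear model.

# Pipeline stages and their parameters

## Marker catalogue

A site qualifies as a marker when one parent is genotyped 0/0 with an
alternate-allele frequency below 0.05 and the other 1/1 with a frequency
above 0.95 (strict inequalities). The bounds allow residual heterozygosity
in the inbred lines without diluting the founder signal; genotypes are
taken as given (the caller is upstream of this package). Sites whose
reference alleles disagree between the two call sets are rejected loudly,
since they indicate coordinate mismatches.

## Sync parsing and frequencies

Counts arrive in PoPoolation2 sync format. Conventions, fixed across the
package:

* coverage = A+T+C+G (N and deletion counts excluded);
* frequencies are biallelic: focal/(focal+other); reads matching neither
  parental allele are ignored and tallied per sample;
* zero informative reads means *missing*, never frequency 0;
* positions are 1-based everywhere, matching the format.

Only markers measured in every sample of both regimes are retained, so
both regimes are windowed over the identical marker set.

## Coverage down-sampling

The regimes were sequenced at very different depths (means ≈ 12, 11, 9×
versus ≈ 123, 107, 133×). To equalize Pool-Seq sampling noise, samples
above 1.5× the target coverage (default 12×) are down-sampled: per marker,
a new coverage is drawn from Poisson(12) and a new focal count from
Binomial(new coverage, old frequency). A drawn coverage of 0 marks the
marker missing. This preserves the expected frequency (verified by a
Monte-Carlo test at 3 standard errors) while matching the low-coverage
noise level. Each sample consumes a random stream derived from the master
seed and its column index, so down-sampling any subset is reproducible.

## Windowing

Windows contain exactly w consecutive retained markers (defaults offered:
50, 250, 500; 250 is the headline scale). The two arms of a metacentric
chromosome are concatenated (2L then 2R, 3L then 3R) before cutting
windows — this is the only scheme consistent with the published totals
that this package reproduces in its acceptance tests (8021/1603/801
autosomal and 1275/255/127 X windows from the published per-arm retained
counts) — so a window may span the centromere. The trailing partial window
is dropped by default (`keep_partial = TRUE` retains it, flagged, for
diagnostics). The dot chromosome (label "4") is excluded from windowing by
default: in the real design it carries ~72 markers and no recombination.
A window's *centre* is the midpoint of its first and last marker on the
concatenated-arm coordinate. Within a window, missing markers are skipped
in the mean; a window is missing for a sample only if that sample has no
measured marker in it.

Window statistics per regime: replicate AFCs, their mean, standard error
(sd/√3) and 95% CI (mean ± 1.96 s.e.).

## The forward simulator and the neutral null

Deviation from drift is judged against an individual-based Wright–Fisher
simulation that mimics the experiment: N diploids per generation, initial
fraction p₀ of focal-genotype individuals (round(N·p₀) flies, sexes
alternating within founder class), discrete generations, parents drawn per
offspring — mothers among females, fathers among males, uniformly under
neutrality or proportionally to fitness under selection.

Genomes are *ancestry mosaics*: each chromosome copy is a list of
breakpoints between founder ancestries. With two founders this is lossless
and keeps gamete formation O(breakpoints), independent of marker count;
the core is compiled (Rcpp). Meiosis follows the organism: females place
Poisson(genetic length) crossovers by inverse-CDF on the cumulative cM/Mb
map (no interference); males are achiasmatic and transmit whole copies;
the X is hemizygous in males (sons receive the maternal X; X frequency
counts two copies per female, one per male; at X-linked targets males have
fitness 1 or 1+s). Fitnesses at a target are 1, 1+hs, 1+s with h = 0.5 by
default, multiplied across targets. Census 1500 is used as the breeding
size; bottle substructure is not modelled. There is no mutation and no
migration: markers are founder differences, which is what the assay
measures.

The null distribution is built from 100 neutral runs: per run, 3
replicates are simulated to generation 20, window means computed, and the
replicate-mean AFC of every window pooled *per chromosome* across runs and
windows. Pooling across windows is a deliberate choice: it gives the
empirical p-values a resolution of 1/(100 · windows-per-chromosome)
rather than 1/100, which a per-chromosome BH correction at 5–15% FDR
needs. Windows of one chromosome are exchangeable under neutrality to a
good approximation, since all markers start at the same frequency.

The null can optionally layer Pool-Seq noise on the simulated frequencies
(Poisson depth at the common down-sampled coverage, binomial reads). The
pipeline enables this (at the down-sampling target, 12×) so that the null
describes the *measured* windowed AFC under neutrality, not the latent
one; without it the null is ~6% narrower than the observation noise
warrants.

Determinism: every (run, replicate) pair derives its RNG stream from the
master seed and its indices; the experiment generator uses stream tags
1000+regime so a shared master seed never collides with null streams.
Identical configurations give byte-identical outputs.

## Empirical p-values, BH, and the temperature contrast

The empirical p-value of a window is directional, as the original analysis
defined it: for a positive observed AFC, the fraction of pooled null
values strictly greater; for a negative one, the fraction strictly
smaller; an observed AFC of exactly 0 gets p = 1. No pseudocount is added,
so p = 0 occurs and is a legal BH input. Two consequences worth knowing:
under neutrality this p is approximately Uniform(0, ½) rather than
Uniform(0, 1) — the test is anti-conservative by about a factor two — and
because whole chromosomes drift as correlated blocks in this design, the
per-window false-positive indicator is strongly correlated along a
chromosome. Calibration checks should therefore look at rates over
replicate experiments, not at single draws (see the validation section).

BH is applied per chromosome and per regime. The temperature contrast is a
per-window linear model AFC ~ regime with 18°C as reference; the intercept
is computed directly as the 18°C replicate mean (exactly, not via a
numerical solver), the temperature coefficient as the difference of means,
and its two-sided p-value equals a pooled-variance two-sample t-test with
4 df (asserted against that closed form to 1e-10 in the tests). With zero
replicate variance the p-value is 1 for a zero contrast and 0 otherwise.
The LM p-values are BH-adjusted per chromosome over the *non-neutral*
windows only (those significant at at least one regime at the chosen FDR).

## The six classes

With sig18/sig29 the per-regime significance calls and sigLM the contrast
call, each window gets exactly one label:

| sig18 | sig29 | sigLM | AFC signs | class |
|---|---|---|---|---|
| no | no | – | – | drift only |
| yes | no | – | – | change 18°C only |
| no | yes | – | – | change 29°C only |
| yes | yes | no | – | no temperature effect |
| yes | yes | yes | same | different magnitude |
| yes | yes | yes | opposite | different direction |

Direction is read from the signs of the two observed mean AFCs, not from
the sign pair (intercept, contrast): the latter — a literal reading of the
original description — would label a response of +0.2 at 18°C and +0.1 at
29°C (coefficients +0.2, −0.1) as a direction change although the same
allele rose in both regimes. Windows significant at both regimes with
opposite AFC signs but a non-significant contrast land in "no temperature
effect", the only remaining branch; they are rare edge cases. The genome-
wide class composition is the unweighted mean of per-chromosome fractions
(a window-weighted variant is available), plus, among different-magnitude
windows, the share whose AFC is more extreme at 29°C.

## Autocorrelation

Window-series autocorrelation (stats::acf, mean-centred) is computed per
chromosome, replicate and regime; the profile records the first lag below
the 5% bound 1.96/√n and converts it to base pairs with the mean window-
centre spacing of that chromosome (the conversion is not specified in the
original analysis; mean spacing is the obvious estimator for equal-w
windows). A pooled-replicate variant is available behind a flag. Constant
series are an error, not a zero.

# The synthetic experiment generator

`generator_config()` describes a complete experiment: a genome of 2,000
markers per arm placed uniformly at random on arms 2L/2R/3L/3R (20 Mb,
2.7 cM/Mb ≈ 0.54 Morgans each, near the real female map), X (22 Mb,
3.0 cM/Mb) and a fourth autosome labelled "4" (20 Mb, 2.7 cM/Mb); census
1500, p₀ = 0.3, 20 generations, 3 replicates; Pool-Seq coverages 12/11/9×
(cold) and 123/107/133× (hot), so the down-sampling step is exercised
exactly as on real data. Note that label "4" here is a convenience name
for a fourth, ordinary linkage group used to separate planted classes; it
is not a model of the real 1.3-Mb achiasmatic dot chromosome (exclude it
from windowing to reproduce the real chromosome set).

Selection is planted as *regions* of 500 markers with a single selected
marker at the centre, one of five class archetypes: change 18°C only
(s₁₈ = 0.4, s₂₉ = 0), change 29°C only (0, 0.4), no temperature effect
(0.4, 0.4), different magnitude (0.3, 0.6 — the hot coefficient double the
cold one, matching the synergistic pattern this design was built to
detect), different direction (−0.4, +0.4); h = 0.5. The coefficients were
chosen from the deterministic one-locus trajectory
p′ = p(1+s(p+hq))/(1+s(p²+2hpq)): |s| ≥ 0.3 moves the focal frequency from
0.3 to ≈0.9 (or ≈0.03) in 20 generations — unambiguous against a null
whose replicate-mean sd is ≈0.02 — while s₁₈ = 0.3 vs s₂₉ = 0.6 leaves a
contrast of ≈0.1–0.2, comfortably detectable at 3 replicates.

Placement follows a fixed compatibility policy — change-18°C-only on
chromosome 2, change-29°C-only on 3, no-temperature-effect on 4, and the
two both-regime classes on opposite ends of X — because of a property of
two-founder experiments that the simulator reproduces: at generation 0
*every* marker is in complete LD with every other, so a strong target
drags the entire genome (not just its chromosome) during the first
generations, before recombination and independent assortment decay the
association. A class whose definition requires *no* signal at one regime
therefore cannot share a genome with any selection at that regime.
Recovery validation consequently uses *single-class* experiments
(`single_class_config()`): the two regimes are separate populations, so a
change-18°C-only experiment has a genuinely neutral 29°C genome.
Multi-class genomes remain fully supported and are instructive precisely
because they reproduce the real-data situation in which almost no window
looks drift-only.

What the generator does not emulate: mapping bias, reference bias, indel
artefacts, sequencing error (third-allele reads), bottle substructure
within replicates, or varying marker density along arms. Passing tests on
synthetic data therefore validate the statistical machinery and the
simulator's population genetics, not robustness to read-level artefacts.

# Validation choices and problem sizes

The test suite and the acceptance script use these scales, chosen to keep
a full run in minutes on one CPU while staying at the experiment's
parameters (N = 1500, t = 20, R = 3 are never scaled down):

* drift calibration: 300 single-marker replicates against the closed form
  p₀(1−p₀)(1−(1−1/2N)^t) ≈ 1.40 × 10⁻³, tolerance 15%;
* recovery: five single-class experiments (2,000 markers/arm, w = 100 so
  a 500-marker region spans ~5 windows, FDR 10%, 100-run null shared
  across experiments of identical geometry), requiring ≥80% of each
  region's windows to get the intended label;
* neutral calibration: the drift-only fraction pooled over three
  all-neutral experiments must stay ≥85%. Pooling is deliberate: a single
  experiment's escape fraction is heavy-tailed (a chromosome occasionally
  drifts 2–3σ as one block and the directional p-value flags much of it),
  so a rate, not a single draw, is the meaningful quantity;
* statistical oracles: the window LM against the pooled t-test closed
  form (1e-10 on 1,000 random triplet pairs), BH against a brute-force
  step-up, empirical p-values against exhaustive counting, the classifier
  against its full 32-point factorial.

# Known limitations

* The directional empirical p-value is anti-conservative under
  neutrality (≈U(0, ½)); it is kept because it defines the method being
  implemented. Treat "drift only" fractions as having an effective FDR
  roughly double the nominal one.
* The null pools windows per chromosome; if marker density (hence window
  physical size) varied grossly along a chromosome, exchangeability would
  weaken. At the study's densities this is immaterial.
* Selection is modelled as constant per-generation coefficients acting on
  parent sampling; fecundity and viability selection are not
  distinguished.
* Crossover interference is not modelled, and the X dosage compensation
  of fitness in hemizygous males is the simple 1/(1+s) scheme.
* With w-SNP windows the last partial window per chromosome is dropped;
  regions in the trailing ~w markers of a chromosome are invisible unless
  `keep_partial = TRUE`.
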