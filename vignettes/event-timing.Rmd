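---
title: "Timing somatic driver events from bulk tumor sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing somatic driver events from bulk tumor sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumortime)
```

## The problem

A primary tumor sequenced once, at diagnosis, still carries a record of its
own history. Somatic point mutations accumulate steadily on each chromosome
copy; when a chromosome arm is duplicated, every mutation already present on
the duplicated copy is carried along and appears at multiplicity two, while
mutations arising afterwards sit on a single copy. The balance of
high-multiplicity versus single-copy clonal mutations on a gained region
therefore dates the gain, and the copy context of a driver mutation (two
copies on a doubled region = before the doubling) sets ordering constraints
among events. `tumortime` implements this inference chain end to end:
per-mutation multiplicity and cancer-cell-fraction (CCF) posteriors, per-tumor
molecular-time posteriors for gains, losses, whole-genome events and driver
mutations, cohort-level consensus ordering, conversion of molecular time to
years before diagnosis with a CpG>T mutational clock, and intratumor
heterogeneity metrics. A synthetic-cohort generator with complete ground
truth supports validation of every stage.

## Mutation annotation

For a mutation at multiplicity $m$ in a fraction $c$ of cancer cells, with
sample purity $p$ and local total copy number $N$, the expected variant
allele fraction is

$$\mathrm{VAF} = \frac{m\,c\,p}{2(1-p) + pN}.$$

`annotate_mutation()` evaluates the binomial likelihood of the observed alt
count over a grid of states ($m$ from 1 to the major copy number; $c$ on 101
uniform points). The CCF prior is spike-and-slab: half the mass on $c = 1$,
half uniform. The spike is not cosmetic — on a gained segment the states
$(m=1, c=1)$ and $(m=2, c \approx 0.5)$ predict the same VAF, so a flat
prior splits their posterior roughly evenly, degrading both clonality calls
and multiplicity estimates; placing prior weight on clonality (most somatic
mutations in a clonally expanded tumor are clonal) resolves the tie in favor
of the state that is overwhelmingly more common. The weight is a visible
argument (`clonal_prior_weight`, default 0.5).

A mutation is called clonal when its posterior mass at CCF $\ge 0.85$ is at
least 0.5, ties called clonal; both numbers are arguments. Sites below 10
reads are flagged unpowered and excluded from timing, but retained for MATH,
which deliberately uses raw allele fractions.

## Timing a gain

Mutations accrue per chromosome copy per unit time. If a gain at molecular
time $t$ duplicated $d$ of the pre-gain copies, left $u$ unduplicated, and
produced $C$ total copies, the expected fraction of clonal mutations at high
multiplicity is

$$\phi(t) = \frac{d\,t}{(d+u)\,t + C(1-t)},$$

increasing from 0 to $d/(d+u)$. With a uniform prior on $\phi$, the counts
$(n_{hi}, n_1)$ give a conjugate Beta$(n_{hi}+1,\,n_1+1)$ posterior on
$\phi$, truncated to its attainable range and pushed through $t(\phi)$.
`time_segment_gain()` computes this deterministically on a 2001-point grid in
$t$ carrying the Jacobian $|d\phi/dt|$ (the exact pushforward), and the test
suite checks its posterior mean against an independent quadrature in
$\phi$-space for every count pair up to 30. Counts are power-weighted by
$1/P(\text{detect})$, the probability of observing at least three variant
reads for a clonal single-copy mutation at the site's depth, so timing is
not biased by depth-dependent dropout. When both counts are zero the event
is unpowered and the posterior is uniform.

Whole-genome events are timed by `time_wgd()`, which multiplies the per-arm
count likelihoods of all doubled arms on a common time grid; arms with the
same copy configuration contribute exactly like pooled counts, and credible
intervals shrink as informative arms accumulate. Arms whose individual
timings disagree strongly (range of per-arm means above 0.5) flag the result
`discordant_arms`.

## The within-tumor pi scale

Event times are reported as posteriors on a molecular scale $\pi \in [0,1]$
anchored at the tumor's first and last clonal events. We operationalize
$\pi$ of an event as the fraction of clonal point-mutation mass occurring
before it, with each mutation weighted by $2m/C$ — its inverse copies-at-risk
exposure at the time it arose — which normalizes mutation density across
copy states (the same weighting makes the CpG>T burden exposure-correct, see
below). `assemble_patient_timing()` draws 1,000 joint samples (configurable):
gains and whole-genome events from their count posteriors; drivers at
multiplicity two on gained segments uniform before their gain's sampled
time; multiplicity-one drivers on cleanly duplicated segments uniform after
it; losses whose surviving allele was later doubled before that doubling;
untimeable clonal events uniform; subclonal events a point mass at
$\pi = 1$. Pre-gain mutations precede their gain in every joint sample by
construction, and every histogram sums to one.

Two details are deliberate choices the data cannot settle. First, the
mutation mass defining $\pi$ uses all clonal mutations by default
(`mass_mode = "all"`); restricting to copy states where pre/post-gain status
is identifiable (`"timeable"`) is available but makes the scale depend on
the tumor's own copy profile. Second, the mass can be restricted to CpG>T
context (`contexts = "CpG>T"`) to express $\pi$ on the clock scale used for
real-time conversion; in the generator both scales agree in expectation
because all contexts accrue linearly in time, and the pipeline uses the
all-context scale throughout.

HPV integration breakpoints, supplied as pre-extracted read support, are
annotated and timed exactly like driver mutations, except that
APOBEC-context mutations (which cluster near integration sites) are removed
from the local counts before the gain is timed; the earliest-timed site
represents the participant.

## Cohort ordering and comparisons

`league_aggregate()` combines tumors: in each of 200 iterations, tumors are
included independently with probability 0.63 (matching the stated average of
a 63% subsample without replacement; the exact scheme is not printed, and
binomial inclusion keeps every iteration exchangeable), one $\pi$ draw per
event per included tumor is averaged into a per-event score, and scores are
rescaled within the iteration so the earliest event sits at 0 and the latest
at 1. Iterations with fewer than two scored events are discarded (the
anchors need two events). The union of per-iteration scores forms each
event's relative-timing trace; the median is the mRT point estimate.
Rescaling is per-iteration rather than global — with subsampling, the event
set present varies by iteration, and per-iteration anchoring keeps every
trace on a common interpretable scale. Draws are organized per entity in
sorted-identifier order, so results are invariant to input order.

`compare_cohorts()` runs paired leagues and differences the per-iteration
scores. The one-way p value is the fraction of the difference trace above
zero, with exact zeros counted half — without the tie rule, a degenerate
all-zero trace (which arises whenever only two events are shared, since
rescaling pins both) would masquerade as maximally significant. Two-way
p values fold the one-way value ($P_{2\text{-way}} = 1 - 2|0.5 -
P_{1\text{-way}}|$) and are corrected across events by Benjamini–Hochberg.
Events must have at least three carriers in each cohort (configurable).

## Real time: the CpG>T clock

Clonal C>T mutations at CpG sites accrue roughly linearly with age.
`count_clock_mutations()` computes each tumor's clonal CpG>T burden per Mb
of CpG sites at risk, weighting each mutation by $2m/C$; under per-copy
accrual this correction is exact in expectation (a doubled genome doubles
both the mutation count and the exposure). `fit_aging_rate()` takes
per-tumor slopes (burden/age), removes the top and bottom 5% — per-tumor
slope trimming, the only reading under which individual "slopes" exist —
and fits a zero-intercept least-squares line (a newborn has no somatic
burden). The fitted rate converts an event's $\pi$ posterior to years before
diagnosis: $\text{years} = B(1-\pi)/r$, truncated to $[0, \text{age}]$,
where $B$ is the tumor's burden at diagnosis. The cohort rate is used for
every tumor by default; a per-tumor rate can be passed instead, but a
single-tumor slope is one Poisson draw and noisier than the cohort estimate.

Whole-genome doublings convert over time to triploid-profile tumors (an
early doubling leaves decades for losses to erode the average copy number
toward three). With a fixed annual conversion rate $\lambda$ and a fraction
$f$ that never converts,

$$P(\mathrm{WGT} \mid \tau) = (1-f)\left(1 - e^{-\lambda\tau}\right)$$

for an event $\tau$ years before diagnosis. `fit_wgd_wgt_conversion()`
maximizes the binomial likelihood over $(\lambda, f)$ and reports 95%
profile-likelihood intervals. The two parameters trade off against each
other in small samples (a high rate with a large immune fraction can mimic
a low rate), so single-cohort estimates at around 100 events are wide;
recovery experiments pool replicates.

## Heterogeneity metrics

MATH is $100 \times 1.4826 \times \mathrm{MAD}/\mathrm{median}$ of raw
mutant allele fractions at depth $\ge 20$ (1.4826 = $1/\Phi^{-1}(0.75)$
scales a normal MAD to its standard deviation); it is invariant under
rescaling all MAFs. Ploidy class is assigned from length-weighted genome
fractions at total copy 2/3/4: diploid above 0.65 diploid fraction, else
triploid above 0.35 triploid fraction, else tetraploid. A whole-genome event
is called when at least half the arms are amplified, or at least four arms
are amplified on both alleles, and is labeled WGT or WGD by ploidy class; an
event call in a diploid-class genome is QC-flagged. "Amplified" means arm
copy above the diploid baseline over at least half the arm length — the
boundary the event call needs but that is not pinned down by the class
definitions. FGA is the length-weighted fraction of the genome whose
allelic copies deviate by more than 0.2 from one copy per allele (two after
a whole-genome event); genomic segment length is used as the weight.
Profiles of paired samples from one tumor are merged by averaging MATH (and
FGA, by the same convention), with a QC flag on discordant class calls.

## The synthetic cohort

`simulate_cohort()` generates tumors whose ground truth (event order,
molecular and calendar times, multiplicities, purity) is fully known, and
writes the same TSV formats the analysis reads. The genome is abstracted to
the 39 non-acrocentric autosomal arms with realistic megabase lengths.
Clonal mutations accrue per surviving lineage copy per unit time — an arm
with a gain at molecular time $g$ has observable-mutation intensity
$((d+u)g + C(1-g))/2$ relative to diploid, a lost arm one half — which is
the generative assumption the timing model inverts and which makes the
$2m/C$ exposure correction exact. Mutations before a gain land on a
duplicated copy with probability $d/(d+u)$ and inherit its post-gain count.
Read counts are binomial at the purity-diluted expected VAF with Poisson
depth. Contexts are categorical labels (CpG>T / APOBEC-motif / other)
rather than sequence-derived, so no reference genome is needed; a real-data
adapter can supply true trinucleotide contexts. CpG>T counts are Poisson
with mean rate × age × covered CpG Mb (defaults 0.37/Mb/yr and 30 Mb).
Whole-genome doublings originate 5–35 years before diagnosis and convert to
WGT with rate 0.11/yr and immune fraction 0.35; an optional subclone at
configurable CCF labels its mutations subclonal in the truth ledger.

What the generator does not emulate: sequencing artifacts and strand bias,
kataegis and regional mutation-rate variation, subclonal copy-number
change, multi-step gains (copy numbers above 2 per allele), and germline
contamination. Passing recovery tests therefore demonstrates correctness of
the inference chain under its own model assumptions, not robustness to
real-data artifacts — that is exactly what upstream callers (variant
calling, purity/ploidy estimation) are trusted for in this pipeline, since
their outputs are consumed as given.

## Numerical choices and problem sizes

Gain posteriors use a 2001-point computation grid binned to 100 histogram
bins; joint sampling uses 1,000 samples per tumor by default (tests use
300–400, which changes posterior means by well under a bin width). League
runs use 200 iterations. The validation suite simulates cohorts of 100–400
tumors for parameter-recovery checks (clock-rate recovery within ±0.05 at
400 tumors; ten staggered gains re-ranked with Kendall tau ≥ 0.8 at 100
tumors; conversion-model recovery pooling 25 replicates of 103 whole-genome
events), and 200 simulated null splits for the calibration of two-way
p values — sizes chosen to match the scale of the cohorts the method is
meant for while keeping the whole suite runnable on a laptop.

## Known limitations

Arm events are called from modal copy states assuming a 1:1 ancestral
state; copy numbers above two per allele are not timed. Losses without a
subsequent doubling are untimeable from mutation data and receive uniform
posteriors — their cohort mRT is then driven by prevalence-weighted
resampling, not by within-tumor signal. The clonality threshold (CCF 0.85)
and the clonal prior weight are conventions, not estimates; both are
exposed as arguments. The league model's two-way p values are calibrated
under exchangeable nulls in simulation but are resampling quantities, not
frequentist p values in the strict sense.
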