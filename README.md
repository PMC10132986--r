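# tumortime

Molecular timing of somatic driver events in tumor cohorts, from bulk DNA
sequencing of primary tumors taken at diagnosis.

Many cancers have no obtainable premalignant tissue, so the order of the
genetic events that built them cannot be read off a biopsy series. This
package reconstructs that order from the tumor itself: a chromosomal gain
copies every mutation already present on the duplicated allele, so the
balance of high-multiplicity versus single-copy clonal mutations dates the
gain, and the copy context of a driver mutation orders it against the gains
around it. `tumortime` is written for cancer-genomics analysts who already
have somatic calls, purity and allelic copy number from standard upstream
tools and want per-tumor event timing, cohort-level consensus ordering,
calendar-time estimates and heterogeneity metrics — with a fully
ground-truthed simulator to validate every step.

## The model in brief

* **Mutation annotation.** Expected variant allele fraction
  `VAF = m·c·p / (2(1−p) + p·N)` for multiplicity `m`, cancer cell fraction
  `c`, purity `p`, local total copy number `N`; binomial likelihood over a
  `(m, c)` grid with a clonal spike-and-slab prior gives multiplicity/CCF
  posteriors and a clonality call.
* **Gain timing.** A gain at molecular time `t` that duplicated `d` of the
  pre-gain copies (leaving `u`, producing `C` total) leaves a fraction
  `φ(t) = d·t / ((d+u)·t + C(1−t))` of clonal mutations at high
  multiplicity; counts `(n_hi, n_1)` give a Beta(n_hi+1, n_1+1) posterior on
  `φ`, pushed through `t(φ)`. Doubled arms pool into the whole-genome event.
* **π scale.** Each event's time is reported as a posterior on `[0, 1]`
  anchored at the tumor's first and last clonal events (subclonal events are
  a point mass at 1, `δ(π − 1)`).
* **League model.** 200 resampling iterations (tumors included w.p. 0.63),
  one π draw per event per tumor, per-iteration rescaling to `[0, 1]`; the
  median of the pooled trace is the mRT point estimate, and cohort
  differences get one-way/two-way p values
  (`P_2way = 1 − 2|0.5 − P_1way|`) with Benjamini–Hochberg correction.
* **Real time.** Clonal CpG>T mutations per Mb at risk accrue linearly with
  age; a trimmed zero-intercept regression fits the rate (≈0.37/Mb/yr in
  HPV-negative head-and-neck cohorts), converting π to years before
  diagnosis. Whole-genome doublings convert to triploid profiles as
  `P(WGT | τ) = (1−f)(1 − e^(−λτ))` — rate `λ` and never-converting
  fraction `f` fitted by maximum likelihood.
* **Heterogeneity.** MATH (`100 × 1.4826 × MAD/median` of raw allele
  fractions), fraction of genome altered, ploidy fractions and aneuploidy
  class, and the whole-genome event call.

## Worked example

Simulate a 30-tumor cohort with known ground truth, time every tumor, and
rank the shared events:

```r
library(tumortime)

cfg <- sim_config(n_tumors = 30, seed = 42)     # HNSCC-like default menu
coh <- simulate_cohort(cfg)

pi_lists <- list(); burdens <- numeric(30)
for (k in 1:30) {
  id   <- coh$metadata$tumor_id[k]
  segs <- coh$segments[coh$segments$tumor_id == id, ]
  ann  <- annotate_mutations(coh$mutations[coh$mutations$tumor_id == id, ],
                             segs, coh$metadata$purity[k])
  set.seed(100 + k)
  tt <- assemble_patient_timing(ann, segs, n_samples = 400)
  pi_lists[[id]] <- setNames(tt$pi, tt$event)
  burdens[k] <- count_clock_mutations(ann, covered_cpg_mb = 30)
}
league_aggregate(pi_lists, seed = 7)
#> Cohort relative timing (30 tumors, 200 iterations):
#>   loss_3p              mRT 0.17  [0.00, 0.45]  prevalence 73%
#>   loss_13q             mRT 0.19  [0.00, 0.52]  prevalence 50%
#>   loss_9p              mRT 0.25  [0.00, 0.52]  prevalence 83%
#>   TP53                 mRT 0.26  [0.00, 0.54]  prevalence 73%
#>   loss_8p              mRT 0.28  [0.02, 0.60]  prevalence 63%
#>   loss_17p             mRT 0.32  [0.00, 0.64]  prevalence 50%
#>   gain_3q              mRT 0.68  [0.47, 0.87]  prevalence 37%
#>   gain_8q              mRT 0.85  [0.68, 1.00]  prevalence 40%
#>   wgd                  mRT 1.00  [0.93, 1.00]  prevalence 50%

fit_aging_rate(burdens, coh$metadata$age)
#> CpG>T clock: 0.354 mutations/Mb/year (IQR of per-tumor slopes 0.342-0.368, n = 28 retained of 30)
```

The recovered order — arm losses and the `TP53` mutation early, the 3q and
8q gains mid-progression, the whole-genome doubling last — matches the
configured true timing windows, and the fitted clock rate sits a few percent
below the simulated 0.37/Mb/yr (the cost of the ~5% of clonal mutations the
clonality gate misses). `pi_to_years()` then converts any event's π
posterior to years before diagnosis, and `heterogeneity_profile()` returns
MATH, FGA, aneuploidy class and the WGD/WGT call per tumor.

`run_pipeline()` (or `inst/scripts/run_pipeline.R` from a shell) chains all
stages — simulate/load, annotate, time, league, real-time, heterogeneity,
cohort comparison — into an output directory with a manifest that
reproduces the run bit for bit from its seed.

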