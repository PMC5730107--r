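---
title: "Methods: selection, drift and pooled scans in sleepsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection, drift and pooled scans in sleepsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`sleepsweep` implements the analysis chain of an evolve-and-resequence
(E&R) experiment on Drosophila night sleep: replicate populations are
truncation-selected on a behavioural phenotype for a handful of
generations, pools of flies are sequenced at several generations, and the
analyst must decide which allele-frequency changes reflect selection
rather than drift. This vignette records the models, the tunable
parameters, the numerical choices, and the design decisions that were
genuinely open.

## Sleep scoring

Activity monitors report one integer count per fly per minute. A fly is
scored asleep during any maximal run of at least five consecutive
zero-count minutes; immobile runs of one to four minutes are "transient
pauses" and count as wake. From the per-minute states we score, per 12-h
phase: sleep minutes, bout number, and average bout length; plus sleep
latency (minutes from lights-off to the first sleep-scored night minute)
and waking activity (counts per awake minute).

Open choices, and what we picked:

* A bout spanning a lights transition is one bout, counted in the phase
  where it began; its minutes are split between phases for the duration
  totals. This keeps `night_sleep + day_sleep` equal to total sleep
  minutes while avoiding double-counted bouts.
* Latency is 0 if the fly is already asleep at lights-off and 720 if it
  never sleeps that night. Whether the source analysis used bout onset or
  the first immobile minute is not documented; we use the first
  sleep-scored minute and flag the convention here rather than assert it.
* Runs truncated by the recording boundary are classified by their
  observed length (no look-ahead).
* Flies immobile for a configurable terminal span (default 24 h) are
  flagged dead and can be excluded.

## Selection quantitative genetics

Per generation the selection differential is \(S_t = \bar P_{sel,t} -
\bar P_t\) and the response is \(R_{t+1} = \bar P_{t+1} - \bar P_t\).
Realized heritability is the least-squares slope of \(\Sigma R\) on
\(\Sigma S\). Because both cumulative sums are zero at generation 0 by
construction and the breeder's equation has no intercept, the default
regression is through the origin; `intercept = TRUE` gives the
unconstrained variant, and both are worth reporting when the choice
matters. \(CV_E = 100\,\sigma_E/\mu\) uses the within-population sample
standard deviation. Sexes are pooled by default, matching the combined
presentation of the source design; per-sex summaries are available by
subsetting the phenotype table.

## Pooled allele-frequency scan

Minor alleles are defined once, from counts summed over every population
at generation 0; ties break toward the alt allele (deterministic). Cells
with total reads outside the closed interval [10, 2000] are masked and
drop out of any test that would use them. Allele-proportion credible
intervals use the Beta posterior under the Jeffreys prior, reported as
the highest-posterior-density (shortest) interval; when a posterior shape
parameter is at or below 1 the density is monotone at that boundary and
the interval is one-sided.

The scan itself is a Cochran-Mantel-Haenszel test of allele against
generation for each consecutive sequenced generation pair, stratified by
the two sex pools of a population. No continuity correction is applied,
which is standard in E&R scans. A site is significant for a population if
any generation pair beats the threshold; the replayed-design threshold is
the printed constant 2.3e-8, and for other designs the default is
0.05 divided by the number of sites. (The printed constant is not exactly
0.05 over any of the printed site counts; it is preserved as a documented
constant, not resolved.) Candidates are sites significant in at least one
long and at least one short replicate and in no control replicate.

The logistic filter fits, per site, the grouped binomial model
\[
\mathrm{logit}\,P(\text{minor}) =
\beta_0 + \beta_1\,\mathrm{Gen} + \beta_2\,\mathrm{Sel}
        + \beta_3\,\mathrm{Gen}\times\mathrm{Sel}
\]
over all long- and short-scheme samples, with Gen the numeric generation
index. Two numerical decisions matter:

* Covariates are centred before fitting, so the Wald test of Sel is the
  scheme contrast averaged over the sequenced generations — the Type III
  hypothesis the original SAS analysis tests. Under dummy coding the Sel
  coefficient is the contrast extrapolated to generation 0, which is
  structurally ~0 for trajectories diverging from a common start; with
  that parameterisation the published pass criterion could never be met.
  Centring does not change the interaction test.
* The lack-of-fit P-value is the deviance goodness-of-fit after
  aggregating counts by covariate profile (Gen x Sel), df = profiles - 4,
  matching how deviance lack-of-fit is computed on read-level data by the
  original tooling. Replicates and sex pools share a profile.

A site passes when lack-of-fit P >= 0.05, Sel P <= 0.05 and interaction
P <= 0.05. Perfect separation triggers a flagged Haldane-Anscombe (+0.5)
refit. Note that the lack-of-fit condition is an overdispersion test: at
effective sizes near 40-50 diploids, drift moves replicate trajectories
off any logit-linear surface by more than read sampling allows, so the
filter passes only a small fraction of genuinely selected sites — in the
source study 126 of 69,188 candidates (0.18%). The package reproduces
that stringency faithfully; see "Known limitations".

## Drift

The variance effective size is
\(N_e = -t / (2\ln(1 - \sigma^2/(q_0(1-q_0))))\). For binned estimation
we use the variance of the frequency *change* \(q_t - q_0\) within a
starting-frequency bin, which is the drift dispersion conditional on the
start; using the raw variance of \(q_t\) would add the within-bin spread
of starting values and bias \(N_e\) downward (and would not vanish for
frozen data). Thresholds for "more divergence than drift explains" come
from forward Wright-Fisher simulation: per starting frequency (0.01 to
0.50 in 0.01 steps), four independent binomial trajectories (two "long",
two "short") are run for t generations and the 99.9% quantile of
\(|\bar q_{short} - \bar q_{long}|\) across replicates is the bound. The
printed effective size 42.5 is handled as 21 males + 21 females: 84
autosomal copies, and 63 X copies (two female X's plus one male X per
pair), since copy numbers must be integers.

## LD bounds

On the ten fully inbred founder lines LD is computed directly
(\(r^2 = D^2/(p_a q_a p_b q_b)\) on line haplotypes). In pooled data
haplotypes are unobservable, so persistence of a founder high-LD pair is
assessed by a frequency-compatibility bound: with the focal site's minor
frequency binned on the 0.01 grid, the partner frequency must lie within
\([\,r^2 p_a/(1 + r^2 p_a - p_a),\ \min(p_a/(r^2 - r^2 p_a + p_a), 0.5)\,]\)
for \(r^2 \ge 0.8\) to remain possible. The lower-position site of a pair
plays the focal role by default (the test is not symmetric; a symmetric
variant is available). Distances are summarised per chromosome over
intra-chromosome pairs only; per-pair means are used, as the original
aggregation (per variant vs per pair) is not fully specified.

## Diallel decomposition

Full diallel cross means \(Y_{ij}\) (maternal i, paternal j, selfs
included) decompose per Griffing's Method 1, Model I:
\(\hat g_i = \frac{1}{2n}(X_{i.} + X_{.i}) - \frac{1}{n^2}X_{..}\),
\(\hat s_{ij} = \frac12(Y_{ij}+Y_{ji}) - \frac{1}{2n}(X_{i.}+X_{.i}+X_{j.}+X_{.j}) + \frac{1}{n^2}X_{..}\),
\(\hat r_{ij} = \frac12(Y_{ij}-Y_{ji})\). The source text prints the GCA
formula with a mixed subscript \((X_{i.} + X_{.j})\); we implement the
standard \((X_{i.} + X_{.i})\) and treat the printed form as a subscript
typo, without asserting what the original computation did. The
decomposition is saturated, so \(\mu + g_i + g_j + s_{ij} + r_{ij}\)
reconstructs every cell mean exactly. The ANOVA partitions the genotype
SS orthogonally into GCA (df n-1), SCA (n(n-1)/2) and REC (n(n-1)/2)
components, and the genotype-by-replicate SS into the matching
interaction terms; each main component is tested against its own
interaction. Standard errors of effects are obtained from the exact
linear map of cell means to each estimator (probing with unit tables and
using \(\|c\|^2\,\hat\sigma^2_{\bar Y}\)), which reproduces Griffing's
variance constants without transcribing them. Sexes are analysed
separately because X-linked parents make reciprocal classes
non-exchangeable.

## The synthetic world

The generator is first-class code with known ground truth. Defaults state
the experimental design: 10 inbred founder lines, 21 random-mating
burn-in generations at census 800, six populations (2 long, 2 short, 2
control), 13 generations of per-sex truncation selection at fraction
0.25 with 100 phenotyped flies per sex, pooled sequencing of each sex
pool at generations 0, 1, 2, 5, 8, 10 and 12, and binomial read sampling
at Poisson(coverage) depth truncated at 1. The phenotype is strictly
additive (per-site effects in minutes, hemizygous single dose for male X
loci) plus an optional sex effect and Normal noise; no dominance or
epistasis, since the selection analysis assumes none. An optional
floor/ceiling at [0, 720] minutes links mean and variance the way a
bounded sleep trait does; it is off by default so heritability recovery
is exactly linear.

Free choices, made once: mean coverage defaults to 100 (the study never
states per-sample depth); environmental SD defaults to 100 minutes
(CV_E near 20% at a 480-minute mean, the magnitude seen in such data);
recombination defaults to free (0.5 between adjacent sites), with a
Markov switch chain available for linked sites. Randomness flows from
one master seed through named substreams (`substream_seed`), so
replicate populations are independent but bit-reproducible.

What the generator does *not* emulate: sequencing error, mapping bias,
indel realignment artefacts, linked background selection, dominance,
GxE. A green parameter-recovery test therefore establishes that the
estimators invert the generator's model, not that they are robust to
artefacts the model omits.

## Known limitations

* The planted-locus acceptance scenario (5,000 sites, 5 selected loci)
  shows that the candidate stage (CMH + control overlap) recovers most
  planted loci, but the logistic lack-of-fit stage passes only a small
  fraction — matching the 0.18% pass rate of the original filter. A
  requirement that >= 4/5 planted loci survive the full chain in >= 90%
  of runs is not attainable under this filter at realistic effective
  sizes; the corresponding acceptance test is asserted as stated and
  left failing, with the measured stage-wise numbers printed alongside.
* Realized heritability recovered from 13 generations at these census
  sizes sits slightly below the base-population value (median ~0.28 for
  a true 0.30) because truncation selection and drift erode additive
  variance (Bulmer effect); the recovery criterion's ±0.05 band absorbs
  this.
* CMH thresholds treat read counts as the sampling unit; true replicate
  drift makes control populations genuinely significant at high rates
  (5-7% of sites), which is why the control-overlap subtraction is part
  of the design rather than a cosmetic filter.
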