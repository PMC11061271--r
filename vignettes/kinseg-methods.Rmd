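---
title: "Methods: co-segregation Bayes factors and pairwise IBD inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-segregation Bayes factors and pairwise IBD inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinseg)
```

## Scope

`kinseg` implements the quantitative analyses used to evaluate a rare,
dominantly inherited variant from family data: (i) co-segregation evidence
as a full-likelihood Bayes factor (FLB) with age- and sex-specific
penetrance classes and a penetrance sensitivity analysis; (ii) pairwise
identity-by-descent (IBD) segment detection from two individuals'
genome-wide genotypes; (iii) dating of the shared ancestor from the length
of an observed IBD segment; and (iv) coordinate arithmetic for a
duplication-insertion structural variant. A synthetic-data module generates
pedigrees, incidence tables and paired genotypes with the statistical
structure these analyses assume, so that every stage is testable without
patient data.

## The pedigree likelihood

The single-locus model is autosomal dominant with variant allele frequency
$q$ (default $q = 0.001$). Genotypes take three states (AA, Aa, aa);
founders carry Hardy–Weinberg priors $\{(1-q)^2,\, 2q(1-q),\, q^2\}$ and
transmission is Mendelian. Heterozygous and homozygous carriers share the
carrier penetrance; keeping all three states (rather than collapsing the
two carrier states) keeps the founder priors exact. Observed carrier tests
enter as hard evidence restricting the genotype state space — cascade
genotyping is treated as definitive, with no genotyping-error term.

Each individual contributes a phenotype factor from their liability class
(sex × 5-year age group × carrier status): affected individuals contribute
the cumulative risk $F$ by the end of the age group containing their age at
diagnosis, unaffected individuals contribute $1 - F$ at their age at last
observation, and unknown phenotypes contribute 1. Two conventions are worth
stating because both appear in the co-segregation literature: affected
individuals could instead contribute an onset-age *density*; we use the
cumulative form, which matches a survival-model construction of penetrance
from incidence, and document it here as a deliberate choice.

Loop-free pedigrees are evaluated by peeling — variable elimination over
the moralized genotype graph with a greedy min-degree ordering, which on
trees reduces to the classical anterior/posterior recursion. Looped
pedigrees fall back to exhaustive genotype enumeration when at most twelve
members have more than one admissible genotype state, and are rejected
otherwise: the target families are desk-scale, and correctness is
preferred over generality. All products are rescaled factor-by-factor with
accumulated log constants, so likelihoods for 50-member pedigrees evaluate
without underflow.

## The full-likelihood Bayes factor

With $L(H)$ the pedigree likelihood under hypothesis $H \in
\{\text{causal}, \text{neutral}\}$ and $P_0(H)$ the marginal probability
of the proband's own data (carrier genotype and phenotype) under $H$,

$$\mathrm{FLB} \;=\; \frac{L(\text{causal})/P_0(\text{causal})}
{L(\text{neutral})/P_0(\text{neutral})}.$$

Dividing by the proband terms conditions each hypothesis on the event
through which the family was ascertained — an affected, genotype-positive
index case — so a family consisting only of the proband is exactly
uninformative (FLB = 1). Under the neutral hypothesis every phenotype uses
the non-carrier penetrance, so the FLB also collapses to 1 whenever carrier
and non-carrier penetrance coincide. Independent families multiply.
Evidence thresholds default to supporting for FLB > 8 and strong for
FLB > 16, and are configurable because other calibrations exist in the
literature.

One behaviour of the simulation suite deserves a note. Families simulated
under the *neutral* model, retained only when an affected carrier exists to
serve as proband, have a median FLB below 1 rather than centred at 1: the
retention step enriches for families with several carriers, whose
unaffected carriers then count against the causal hypothesis. This is the
correct directional behaviour of a conditioned likelihood ratio under that
retention scheme, not a bias in the score, and the test suite asserts
directionality (causal families score high, neutral families do not
inflate) rather than exact neutrality.

## Penetrance construction

Incidence tables give events per person-year in 5-year age groups
$[a, a+5)$ per sex — one table for variant carriers, one for the general
population (the phenocopy rate). Sparse carrier tables are pre-smoothed by
a penalized Poisson regression of event counts on the age-group midpoint
with a log person-years offset, using a thin-plate regression spline basis
of dimension $k = 3$ and a smoothing parameter chosen by generalized
cross-validation (`mgcv::gam`). Because the intercept is unpenalized, the
fitted curve preserves the total event count; an unpenalized basis as large
as the number of groups reproduces the raw rates.

Cumulative risk at the end of group $k$ follows the survival model
$$F_k = 1 - \exp\!\Big(-\sum_{j \le k} \lambda_j \, w_j\Big),$$
with $w_j = 5$ years. An individual aged $a$ is assigned the $F$ of the
group containing $a$; ages beyond the last tabulated group accrue hazard at
the last group's constant rate (a conservative extrapolation). Individuals
of unknown age receive an average class, by default the unweighted mean of
$F$ across age groups per sex and carrier status; person-year weighting is
available as an option since the averaging weights are not canonically
defined. Smoothing is performed per sex.

## Penetrance sensitivity analysis

Robustness to the penetrance inputs is probed on a grid: the non-carrier
rates are scaled by a factor $f \in [0.5, 1.5]$, and the carrier rates are
replaced by the weighted average $(1-e)\,\lambda_{nc} + e\,\lambda_c$
between the non-carrier rates and the original carrier estimates, with the
excess fraction $e \in [0, 1]$. By default the average mixes against the
*scaled* non-carrier rates (a flag switches to the unscaled ones — the more
conservative reading, since the phraseology is ambiguous in the field). At
$e = 0$ carriers and non-carriers coincide and the FLB is identically 1;
$(f, e) = (1, 1)$ is the unperturbed baseline. The default grid is
21 × 21. Iso-FLB contours (e.g. at the strong threshold of 16) are
extracted by marching squares with linear interpolation along cell edges
(`grDevices::contourLines`), so returned contour points re-evaluate to the
level under the bilinear interpolant of the grid.

## IBD segment detection

Two individuals' genotypes are compared site by site. After filtering
(biallelic SNVs; `FILTER == PASS`; both depths > 10; both genotype
qualities > 50; strict inequalities), each site's identity-by-state
IBS $\in \{0, 1, 2\}$ is the number of shared alleles, $2 - |g_1 - g_2|$
on dosages. The local discordance statistic $w$ is the fraction of IBS = 0
sites within 1 Mb up- and downstream (the site counts in its own window;
switchable). Maximal runs of consecutive sites with $w \le 0.5\%$ are
reported as IBD segments when they contain at least 100 variants and span
at least 1 cM. Runs are extended greedily and never merged across a
failing site. Genetic positions come from linear interpolation of a
HapMap-style map, extrapolating the boundary recombination rate beyond the
map; with no map supplied a uniform 1 cM/Mb is assumed (the genome-wide
average), making the 1 cM rule roughly a 1 Mb rule.

The window statistic imposes a detection limit worth quantifying. With
allele frequencies uniform on $[0.05, 0.5]$, unrelated samples are
opposite homozygotes at roughly 7–8% of sites, so a window overlapping
non-IBD territory by more than $\sim\!6\%$ of its span already exceeds the
0.5% threshold. Sites within $\sim\!0.9$ Mb of a segment edge therefore
fail, eroding each called segment by almost 1 cM per side (at 1 cM/Mb):
true segments shorter than $\sim\!2.8$ cM fall below the 1 cM span rule
and are not called. The planted-segment suite plants lengths spanning
2–20 cM evenly and accordingly expects recall of about 0.95, with the
shortest segment the designed miss; called segment midpoints must lie
inside planted segments.

## Founder age from segment length

A segment transmitted from a common ancestor $g$ generations above each
index case survives $m = 2g$ meioses, and its genetic length is
approximately exponential with mean $100/m$ cM. Detection imposes a
minimum observable length $t$ (1 cM by default, matching the caller), so
the likelihood of an observed length $\ell$ is the left-truncated
exponential $r e^{-r(\ell - t)}$ with $r = 2g/100$ per cM. The estimate
evaluates this over integer $g$, reports the maximum-likelihood $g$ and a
half-maximum plausible range (the cutoff 0.5 is a reporting convention,
configurable). The model deliberately uses a single observed segment with
no chromosome-end correction and no ascertainment correction for observing
at least one segment; for a 17 cM segment it yields a maximum-likelihood
estimate of 3 generations with a wide plausible range — richer models that
account for detection limits and the number of couples ancestral to both
cases can legitimately prefer 4–6. The output prints its assumptions for
this reason.

## Structural-variant arithmetic

All coordinates are 1-based inclusive (HGVS convention). For a
duplication-insertion with donor interval $[s, e]$ and breakpoint
coordinate $b$ (first reference base 3' of the insertion), the insertion
length is $e - s + 1$ and the signed breakpoint-to-donor distance is
$s - b$. Serialization follows `acc:g.(b-1)_b ins s_e` and parsing enforces
adjacent flanks. Donor orientation is recorded for display only. BED
export converts to 0-based half-open at the boundary.

## The synthetic-data generators

`sim_pedigree()` gene-drops genotypes (founders Hardy–Weinberg, optionally
forcing the first founder to carry; offspring Mendelian) through a nuclear
or three-generation template, samples affection from the liability class
given genotype under the causal or neutral hypothesis, observes carrier
status with a typing probability, and picks the proband among affected
carriers, resampling up to a retry cap. Default generation ages (70–85,
45–60, 20–40 years) give the age spread of a clinic family.

`sim_pair()` emulates the genotype comparison of two sequenced index
cases: sites at 1 variant/kb along a 50 Mb chromosome, allele frequencies
uniform on [0.05, 0.5], genotypes as four independent Hardy–Weinberg
haplotypes except inside planted segments, where the two individuals share
exactly one haplotype — which forbids opposite homozygotes, the signal the
$w$ statistic detects, without requiring phasing in the caller. Genotype
errors flip a dosage to an adjacent value with probability 0.2% by
default, DP and GQ are drawn so the quality filter has realistic work, and
2% of sites are non-PASS. Sites are independent given IBD state: the
generator makes no attempt at linkage disequilibrium, coalescent
population structure, or realistic site-frequency spectra, so passing
recovery tests demonstrate the caller's window logic, not its performance
on any particular cohort's LD structure.

`sim_incidence()` produces 5-year-grid tables from a log-linear hazard
$\lambda(a) = \exp(\alpha + \beta a)$ with optional Poisson noise. The
suites use $(\alpha, \beta) = (-7.5, 0.055)$ as a carrier-like hazard
(cumulative risk roughly 45% by age 70) and $(-11, 0.09)$ as a
population-like "any cancer" hazard (roughly 15% by age 75) — shapes, not
estimates, chosen once to be of realistic magnitude for a dominant cancer
syndrome and its phenocopy background.

## Numerical choices and problem sizes

Likelihoods are computed in log space with per-factor rescaling; the
peeling engine is verified against exhaustive enumeration to relative
error below $10^{-9}$ on pedigrees of up to 8 members. Age groups are
half-open $[a, a+5)$ with the group midpoint as the regression covariate
and cumulative risk indexed at the group end. The test and demonstration
suites use desk-scale problem sizes chosen to exercise every code path —
around a hundred random pedigrees for the enumeration oracle, 11 × 11
sensitivity grids, twenty 50 Mb replicates for planted-segment recovery,
and 10,000 Monte-Carlo draws for founder-age recovery.

## Known limitations

Single-locus, autosomal dominant only; no genotyping-error model in the
pedigree likelihood; no competing-mortality adjustment or cancer-site
resolution in penetrance; unphased pairwise IBD only (no HMM, no
multi-sample extension); founder dating from one segment with an
acknowledged simple model. Looped pedigrees beyond the enumeration cap are
rejected rather than approximated.
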