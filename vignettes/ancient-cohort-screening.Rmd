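---
title: "Screening an ancient-DNA cohort: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening an ancient-DNA cohort: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

paleokin implements the genetic stages of a mass-burial cohort analysis:
authenticity screening, kinship, pedigree consistency, runs of homozygosity
(ROH) with effective-population-size inference, and admixture proportions.
This vignette is the package's account of the underlying models, the
parameters that matter, and the choices made where the design was genuinely
open. Every number quoted here is computed by the test suite or the
acceptance script; nothing is asserted beyond what the code demonstrates.

## Authenticity screening

Low-coverage ancient libraries are screened per individual from read-count
summaries, not from reads. Four criteria:

1. **Terminal damage**: the C→T substitution rate at the final read position
   must be at least 3% (`damage_check`). Authentic ancient molecules
   accumulate terminal deamination; modern contaminants do not.
2. **mtDNA consensus match**: the upper bound of the two-sided 95% CI of the
   match rate to the sample's own mitochondrial consensus must exceed 98%
   (`mt_consensus_check`).
3. **X polymorphism in males**: with a single X, positions covered at least
   twice should be monomorphic. Evaluated only in males with ≥ 200 such
   positions; passes when the lower 95% CI bound of the polymorphic fraction
   is below 1% (`x_contamination_check`).
4. **Sex ratio**: Y reads over X+Y reads above 35% (male) or below 3%
   (female); ratios between are left undetermined (`assign_sex`).

Decisions taken here:

* **Interval construction.** No specific CI method is canonical for these
  screens; we use the Wilson score interval because it behaves correctly at
  proportions near 0 and 1 (where Wald collapses), with Clopper–Pearson
  available via `ci_method = "clopper-pearson"` for users who prefer a
  conservative exact interval.
* **Boundaries are applied exactly as stated**: ≥ for the 3% damage floor,
  strict > and < for the ratio and CI rules. The unit tests pin behaviour at
  the exact boundary values (30/1000 damaged passes; a 35.0% Y ratio is
  undetermined, 35.1% is male).
* **`not_evaluable` never fails an individual.** A criterion that cannot be
  evaluated (no reads, female X test, too few X sites) is reported and
  excluded; only an evaluable failure marks the individual. A manual
  `mt_override` flag lets the analyst waive the mtDNA criterion for
  low-coverage libraries vetted by other means (e.g. haplotype-defining
  positions covered twice); the package does not guess such a rescue rule.
* **The X test is a reduced form**: a per-site both-alleles-observed
  proportion at ≥2× sites, rather than a read-level likelihood model. The
  decision rule (lower CI bound < 1%) is preserved with desk-scale inputs.

## Kinship from pseudo-haploid mismatch rates

With one random allele sampled per individual per SNP, two unrelated
individuals from a population with alt-allele frequencies $p_s$ mismatch at
an expected rate $\mathrm{base} = \frac{1}{S}\sum_s 2 p_s (1 - p_s)$; a pair
with kinship coefficient $\varphi$ mismatches at $(1 - \varphi)\cdot
\mathrm{base}$. Writing $b = \mathrm{base}/2$, the relatedness coefficient

$$ r = 1 - \frac{x - b}{b} = 2 - \frac{x}{b}, \qquad E[r] = 2\varphi $$

is 1 for identical genomes, 0.5 for parent–offspring or full siblings, 0.25
for second degree, 0.125 for third, 0 for unrelated pairs.

* **Baseline calibration**: `base` is the median pairwise mismatch rate among
  individuals with **more than 100,000** called SNPs, assuming most pairs are
  unrelated. The median is robust to the handful of related pairs a burial
  cohort contains.
* **Degree windows**: the field reports degrees, not cutoffs, so the windows
  are the midpoints of the expected values on the halving scale: identical
  r ≥ 0.7, first [0.35, 0.7), second [0.1875, 0.35), third
  [0.09375, 0.1875), unrelated below. They are configurable
  (`default_degree_windows`).
* **Uncertainty**: a delete-one-block jackknife over 5 cM genetic-map blocks
  (size configurable). The baseline $b$ is held fixed across jackknife
  replicates: its own sampling error (a median over hundreds of pairs, each
  averaging the whole panel) is an order of magnitude below a single pair's.
  Estimates within $2\,\widehat{se}$ of a window boundary are reported as
  `unresolved` rather than forced into a class.
* **Pair-level floor**: pairs with fewer than 15,000 overlapping SNPs are
  listed but not classified. The only coverage rule stated for the method
  concerns the baseline cohort; 15,000 is the package's choice, below which
  the mismatch SE (≈ 0.004 at base ≈ 0.37) makes second/third degree
  distinctions meaningless.
* Autosomal r cannot distinguish parent–offspring from full siblings, nor
  half-siblings from avuncular from grandparental pairs ($\varphi = 1/8$ in
  all three). The pedigree module treats the $\varphi = 1/8$ relationships as
  an equivalence class, resolved only by sex, uniparental-lineage and age
  side constraints — deliberately preserved ambiguity.

## Pedigree consistency

`expected_kinship` runs the standard recursive kinship algorithm over the
pedigree DAG with founders assumed unrelated and inbreeding ignored (the ROH
screen justifies this assumption for the cohorts this package targets; for
strongly inbred pedigrees the recursion would underestimate $\varphi$).
`check_consistency` evaluates four rules: mtDNA follows the mother (R1), Y
follows the father for sons (R2), observed degree class matches the expected
class (R3), and parental roles match genetic sex calls (R4). R3 allows one
class of slack because pseudo-haploid noise near a window boundary is
expected; an `unresolved` call is never a violation. The module checks
proposed topologies — it does not search over them.

## ROH and effective population size

An ROH of genetic length $l$ arises where an individual's two haplotypes
coalesce $t$ generations ago; recombination breaks such segments at rate $2t$
per Morgan. Under a constant-size panmictic diploid population of effective
size $N$, coalescence times are geometric, $P_N(t) = \frac{1}{2N}(1 -
\frac{1}{2N})^{t-1}$, and the expected number of segments per individual with
length in $[l_1, l_2]$ on a chromosome of $G$ Morgans is

$$ E(N) = \sum_{t \ge 1} P_N(t) \int_{l_1}^{l_2}
   \left[ (G - l)(2t)^2 + 2(2t) \right] e^{-2tl}\, dl , $$

interior segments plus the two chromosome-edge terms. Numerical choices:

* The bin integral is evaluated **in closed form per $t$** (exponential
  integrals), and the $t$-sum is truncated where $e^{-2 t l_1}$ leaves less
  than $10^{-12}$ relative mass (capped at $8N$; the geometric tail beyond
  $8N$ carries $e^{-4}$ of the mass and is irrelevant for the ≥ 4 cM bins
  used). Additivity over adjacent bins holds to $10^{-8}$ relative.
* The likelihood treats per-individual bin counts as independent Poisson with
  mean $E_b(N)$, summed over the default bins [4,8), [8,12), [12,20) cM;
  the exact partition within 4–20 cM is a configuration choice. Maximization
  is a bounded scalar search over $\log N \in [\log 10^2, \log 10^7]$
  (tolerance $10^{-4}$); the 95% CI is the profile set
  $\{N : \ell(N) \ge \ell_{max} - 1.92\}$, located by root finding
  (endpoints reproduce $\ell_{max} - 1.92$ to $10^{-3}$).
* **Zero observed segments** drive the MLE to the upper search bound; the
  estimate is flagged `no_segments` and only the profile lower bound is
  informative. This is the honest answer when a small cohort shows no 4–20 cM
  ROH at all.
* Poisson independence across individuals is assumed, as is standard for this
  estimator; for cohorts containing close relatives the effective number of
  independent genomes is slightly lower than the count, an acknowledged
  limitation.
* Sums of ROH above 4/8/12/20 cM use strict >; eligibility requires at least
  400,000 called SNPs on the full capture panel (scaled proportionally for
  thinned synthetic panels). The >20 cM flag marks close-kin parental
  inbreeding; note a large panmictic population still produces the occasional
  >20 cM segment by chance, so a single flag is a prompt, not a verdict.
* The default genetic map is 22 autosomes with standard sex-averaged lengths
  totalling ≈ 35.4 Morgans; any map can be supplied.

**The Monte-Carlo cross-check.** `simulate_roh_lengths` is an independent
sampler of the same model used as the estimator's oracle. One subtlety
deserves a record: the geometric law $P_N(t)$ is the coalescence time at a
*point* of the genome; *segments* are sampled length-biased, so the time law
per segment is $P_N(t)\cdot 2t / (4N)$ — a size-biased geometric, realized
exactly as the sum of two independent geometrics minus one. Segment starts
form a Poisson process of rate $\sum_t P_N(t)\,2t$ per Morgan with
$\mathrm{Exp}(2t)$ lengths truncated at the chromosome end (producing the
right-edge term), and the stationary segment covering position 0 carries the
plain geometric law with an exponential residual (the left-edge term).
Drawing plain-geometric times per segment — the naive renewal reading — does
*not* reproduce the analytic density and fails the cross-check. The test
suite verifies analytic/Monte-Carlo agreement within 3 SE at
$N \in \{1000, 5000, 20000\}$ over 2000 genomes, and 95% profile-CI coverage
of 0.95 ± 0.04 over 200 replicates at $N = 5000$ with 27 individuals.

The included `simple_roh_caller` (fixed genetic-map windows, maximal runs
with at most a set number of heterozygote calls) is plumbing for dense
synthetic diploid data so the pipeline can run end to end; it is **not** a
substitute for haplotype-copying HMM callers on sparse pseudo-haploid data,
and real ROH calls are expected as pipeline input. Windows without SNP data
carry no heterozygote evidence and do not break a run; calls are clipped to
the covered range per chromosome.

## Admixture proportions

`f4(A,B;C,D)` is the per-SNP mean of $(p_A - p_B)(p_C - p_D)$ over SNPs with
complete data in the quadruple, with a 5 cM block-jackknife SE. `qpadm_lite`
builds the target's f4 vector over outgroup pairs anchored on the first
outgroup, $f_4(\mathrm{target}, O_1; O_j, O_1)$, the analogous source
vectors, and solves the weighted least squares problem under $\sum w = 1$
with the jackknife covariance of the target vector as weights; weight SEs
come from refitting on each delete-one-block replicate. Design notes:

* This is deliberately a **reduced qpAdm**: one small mixture fit, no rank
  tests on the full f4 matrix, no nested-model p-values, no parity with
  ADMIXTOOLS output claimed. Collinear sources abort with an explicit error
  rather than a silently arbitrary answer; a singular jackknife covariance
  falls back to its diagonal with a warning.
* The anchor choice is arbitrary and invariance-tested: weights are invariant
  to reordering the non-anchor outgroups and to SNP reordering.
* Allele frequencies are used as given (complete-case per statistic); no
  finite-sample bias correction is applied by default.

The simulation test bed (`simulate_admixed_freqs`) uses a two-lineage
population tree with Balding–Nichols drift: an ancestral spectrum splits into
two lineages (drift F = 0.02); each source drifts from its own lineage
(F = 0.005); the target drifts (F = 0.005) from the mixture
$\alpha p_{S1} + (1-\alpha) p_{S2}$; outgroups drift (F = 0.01) from the
root or from one of the lineages. Outgroups *must* share lineage drift
asymmetrically for $\alpha$ to be identifiable: with all outgroups drifting
independently from the root, every f4 row is identical in expectation and the
weights are undetermined — the tree structure is what makes the f4 system
informative. The planted $\alpha = 0.09$ (a typical minority
hunter-gatherer ancestry fraction in Neolithic European farmers) is recovered
within 2 SE in ≥ 90 of 100 replicates at 100,000 SNPs.

## What the generators emulate — and what they do not

`simulate_cohort` draws founder frequencies uniform on [0.05, 0.95], builds
pedigrees by Mendelian transmission (unlinked per SNP for kinship work;
linked with Poisson crossovers on the genetic map when ROH realism is
needed — the mode is explicit because unlinked transmission is an order of
magnitude faster and sufficient for mismatch expectations), then thins calls
per individual. Uniparental lineage labels propagate maternally (mtDNA) and
paternally (Y).

The preset cohort (`mass_burial_preset`) fixes the study conditions: 38 sampled
individuals; four pedigrees planting exactly 11 close-kin individuals —
(i) a father, two daughters and a brother's son; (ii) two sisters and a
maternal first cousin; (iii) a father and son; (iv) paternal half-siblings —
27 singletons; 20 F / 18 M; founder lineage labels arranged so the cohort
carries 30 distinct mtDNA and 6 distinct Y lineages; call rate 0.95 for 27
individuals and 0.25 for 11 singletons, so the low-coverage subset falls
below both the 100,000-SNP baseline floor and the scaled ROH eligibility
floor. The panel is 200,000 SNPs — the full ~1.24M capture panel thinned,
which leaves every planted degree ≥ 5 SE from its window boundaries while
keeping the replicated validation runs tractable.

Deliberately **not** emulated: linkage disequilibrium between panel SNPs
(founders are drawn independently per SNP), SNP ascertainment bias,
damage-driven genotype errors, reference bias, within-cohort population
substructure, and time-stratified sampling. Passing tests therefore
demonstrate the estimators' statistical correctness under their own model
assumptions, not robustness to these real-data pathologies — the usual gap
between simulation validation and field performance.

## Validation problem sizes

The acceptance suite runs: the kinship grid $\varphi \in \{0, 1/16, 1/8,
1/4, 1/2\}$ at 500,000 SNPs × 50 replicates (mean $\hat r$ within ±0.03 of
$2\varphi$); 100 preset-cohort replicates (the 11 close-kin individuals and
every planted degree class recovered in ≥ 95); boundary-exact QC rules; the
ROH analytic/Monte-Carlo match and CI coverage described above; and the
$\alpha = 0.09$ recovery. These sizes are the package's validation choices:
large enough that failure would indicate a real defect, small enough to run
routinely.

## Interface note

The package's functions plus the numbered drivers under `analysis/` are the
interface; there is no shell wrapper. `run_pipeline` orchestrates the stages
from one seeded config, logs per-stage counts to stderr, and records a config
hash so that any threshold change is visible in the provenance record.

## Known limitations

* The kinship baseline assumes a homogeneous cohort; strong internal
  structure would inflate `base` and compress all $r$ estimates toward 0.
* $\varphi = 1/8$ and deeper relationships are equivalence classes from
  autosomes alone; third degree vs unrelated is resolution-limited at low
  overlap.
* The Ne estimator conditions on the constant-size panmictic model; recent
  bottlenecks or admixture would bias it, and related individuals violate
  Poisson independence.
* `simple_roh_caller` requires dense diploid data and tolerates no genotype
  error by default (`max_het_per_window = 0`).
* `qpadm_lite` offers no model-adequacy test beyond the residual statistic.
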