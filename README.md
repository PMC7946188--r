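# paleokin

Genetic screening of low-coverage ancient-DNA cohorts genotyped on a fixed
SNP capture panel: authenticity and contamination QC, genetic sex, pairwise
kinship and pedigree consistency, runs-of-homozygosity (ROH) inbreeding and
effective-population-size inference, and two-source admixture modelling —
with synthetic-data generators that plant known ground truth for every stage.

The intended user is an archaeogeneticist analysing a burial cohort: who in
the pit is related to whom, was anyone inbred, how large was the community
the victims came from, and what ancestry did they carry?

## Methods at a glance

**Authenticity screen.** Four read-count criteria per individual: terminal
C→T deamination rate ≥ 3%; mtDNA consensus match with the upper bound of its
95% CI (Wilson score) above 98%; in males with ≥ 200 X-chromosome positions
covered ≥ 2×, a polymorphism rate whose lower 95% CI bound is below 1%; and a
Y/(X+Y) read ratio above 35% (male) or below 3% (female) for sex assignment.
Non-evaluable criteria are reported, never counted as failures.

**Kinship.** On pseudo-haploid calls (one random allele per site per
individual) the mismatch rate *x* of a pair is compared with the baseline *b*
= (median pairwise mismatch among individuals with > 100,000 called SNPs) / 2:

    r = 1 − ((x − b) / b) = 2 − x / b,     E[r] = 2φ

with φ the kinship coefficient, so r ≈ 1 for identical genomes, 0.5 for
first degree, 0.25 second, 0.125 third, 0 for unrelated pairs. Standard
errors come from a 5 cM block jackknife; estimates within 2 SE of a degree
boundary are reported as unresolved. Pedigree hypotheses are checked against
the observed degrees, genetic sexes, and mtDNA/Y lineage transmission.

**ROH and Ne.** Per individual we report total ROH length above 4, 8, 12 and
20 cM; any segment over 20 cM flags close-kin parental inbreeding. Counts of
4–20 cM segments are fit by maximum likelihood under a constant-size
panmictic coalescent, where the expected number of segments of length
l ∈ [l₁, l₂] Morgans on a chromosome of G Morgans is

    Σ_t P_N(t) ∫ [ (G − l)(2t)² + 2(2t) ] e^(−2tl) dl,
    P_N(t) = (1/2N)(1 − 1/2N)^(t−1),

and the 95% CI is the likelihood profile 1.92 log-units below the maximum.

**Admixture.** f4 statistics f4(A,B;C,D) = mean over SNPs of
(p_A − p_B)(p_C − p_D) with block-jackknife SEs; a target's f4 vector against
an outgroup set is modelled as a mixture of source vectors by weighted least
squares under Σw = 1 (a deliberately reduced qpAdm: one small mixture fit, no
rank tests).

## Worked example

```r
library(paleokin)
cfg <- run_config(seed = 11, cohort = mass_burial_preset(seed = 11),
                  admixture = list(alpha = 0.09, n_snps = 100000))
report <- run_pipeline(cfg)
print(report)
```

```
<cohort_report>
  sex tally: 20 F / 18 M / 0 U
  close kin: 11 individuals (unrelated fraction 0.711)
  lineages: 30 mtDNA, 6 Y
  inbreeding flags: 0 of 27 eligible
  Ne: 71776 (95% CI 23240-431529)
  mixture: S1 0.091, S2 0.909
```

Reading this: the QC stage assigned 20 females and 18 males; 11 of the 38
simulated individuals have a relative at third degree or closer (the four
planted pedigrees), so 71% of the cohort has no close kin among the dead; the
cohort carries 30 distinct maternal and 6 distinct paternal lineages; none of
the 27 well-covered individuals shows a >20 cM ROH (no close-kin parental
inbreeding); the 4–20 cM ROH rate yields a recent effective population size
estimate with a wide profile CI that covers the planted truth (40,000); and
the two-source fit recovers the planted 9% minority ancestry as 0.091 ± se.

The same analysis, stage by stage with persisted tables, is in the numbered
scripts under `analysis/` (run them in order from the repository root).

## Scope

Input formats are ASCII EIGENSTRAT (geno/snp/ind), TSV read-count summaries,
TSV ROH segment tables and TSV uniparental profiles. Upstream read alignment,
haplotype-copying ROH calling on sparse data, haplogroup calling and PCA are
out of scope; ROH calls and lineage labels are pipeline inputs (a simple
window caller for dense diploid data is included as plumbing). See the
methods vignette (`vignettes/ancient-cohort-screening.Rmd`) for model
assumptions, parameter defaults and limitations.
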