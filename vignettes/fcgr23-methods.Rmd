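---
title: "Copy-number-aware haplotype analysis of the FCGR2/3 locus: models and methods"
author: "fcgrhap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number-aware haplotype analysis of the FCGR2/3 locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The low-affinity Fc-gamma receptor genes (*FCGR2A*, *FCGR3A*, *FCGR2C*,
*FCGR3B*, *FCGR2B*) sit in a segmental duplication at 1q23.3 where copy
number varies in blocks of genes — copy number regions (CNRs). CNR1 spans
*FCGR3B* + *FCGR2C*; CNR2 and CNR3 each span *FCGR3A* + *FCGR2C*. This
breaks the standard diploid toolkit in three ways:

1. an individual does not carry two copies of every gene, so "allele
   frequency" needs a gene-copy denominator, not 2n;
2. r² and D′ are undefined across chromosomes with varying copy number,
   so LD with CNV needs a stratified procedure;
3. genotyping is dosage-based (MLPA probe ratios), so multi-site
   haplotypes such as the three *FCGR2C* forms (Stop pseudogene, classic
   ORF, nonclassic ORF) must be resolved from copy counts, with genuine
   ambiguity in rare configurations.

`fcgrhap` implements the full analysis chain under these constraints:
synthetic cohorts → MLPA interpretation → population statistics →
case-control association → trio TDT → inverse-variance meta-analysis.
The numbered scripts under `analysis/` run the chain end to end on a
simulated European cohort.

## Locus model

A chromosome-level haplotype stores per-CNR copies (0 = deleted,
1 = baseline, 2 = duplicated) and one allele label per gene copy. Gene
copy number of an individual is `2 + sum over CNRs containing the gene of
(CNR copies − 2)`; per chromosome it is `1 + sum(CNR copies − 1)`. The
per-variant dosage invariant — dosages sum to the gene copy number — is
validated on every genotype frame and is what makes the three *FCGR2C*
haplotype frequencies sum to 1 in the presence of CNV. Chromosome-level
alleles are displayed in the field's notation: `VF` (a duplicated
*FCGR3A* carrying one V and one F copy), `NA1-NA2`, `-` (deletion).

The rare fourth CNV region described elsewhere is folded into CNR1, and
per-chromosome CNR copies are capped at 2 (individual totals up to 4),
matching the observed copy range.

## Synthetic pools

`build_pool()` constructs a frequency table over chromosome haplotypes in
two stages.

**SNP stage (iterative proportional fitting).** Starting from linkage
equilibrium (the product of the requested marginals over all eight variant
systems), each pairwise r² target is converted into a 2×2 joint table for
the allele-vs-rest collapse: `D = sqrt(r² pA qA pB qB)` with positive sign
between the named alleles, `pAB = pA pB + D`. IPF cycles over the pair
tables and re-fits all marginals each sweep, stopping when every achieved
r² is within 1e-4 of target (cap 1000 sweeps). Higher-order LD is whatever
IPF yields; only pairwise LD is specified.

A target can exceed the Lewontin bound `Dmax = min(pA qB, qA pB)` implied
by rounded marginals. The reported r² of 0.24 between the classic ORF
(frequency 0.11) and *FCGR3A*-158V (0.36) is such a case: the maximum
attainable r² at those marginals is 0.2197. The published LD was computed
on a CNV-free subset whose exact frequencies are unpublished and evidently
slightly different. `build_pool()` errors on infeasible targets by
default, reporting the feasible maximum; `on_infeasible = "clamp"`
constructs at the bound, which is what the packaged European pool does —
the resulting pool r² of 0.2197 is the closest construction the rounded
marginals admit.

**CNV overlay.** Per-CNR chromosome copy frequencies are crossed with the
SNP table (combinations whose overlapping deletions would give a gene
negative copies are impossible and dropped). European chromosome-level CNR
frequencies come from parental chromosomes of the trio cohort
(CNR1 0.049/0.877/0.074; CNR2 0.006/0.976/0.018; CNR3 duplication 0.001);
the Chinese and African populations use moment fits (p0 = P0 + P1/2,
p2 = P4 + P3/2) to individual-level copy distributions, which preserve
mean copy number. Deleted genes lose their alleles. Duplicated copies
receive alleles by attachment rules: the extra *FCGR2C* copy of a CNR1
duplication carries the nonclassic ORF with probability 0.5 (encoding the
strong association between increased CNR1 copy number and the nonclassic
ORF), extra *FCGR3A*/*FCGR3B* copies draw independently from their
marginals (producing `VF`, `NA1-NA2`, ...), and all other extras duplicate
the base allele.

Marginals and r² targets are therefore honored exactly on the *CNV-free
component* of the pool — the same conditioning under which pairwise LD is
defined at this locus. Dosage-based population-wide frequencies of alleles
that ride CNV chromosomes (notably the nonclassic ORF) exceed their
CNV-free marginals by construction; this mirrors the real locus, where the
nonclassic ORF travels with duplicated CNR1.

The internal *FCGR2C* model distinguishes four per-copy haplotypes — Stop
with intact splice site, Stop with the intron-7 splice mutation, classic
ORF (ORF + intact splice), nonclassic ORF (ORF + splice mutant). The
splice-mutant Stop background is set to 0.02, a realistic rare frequency
chosen once to exercise the dosage ambiguity the caller must resolve; the
two Stop forms are collapsed to "Stop" in all reported output.

**What the generator does not emulate.** No recombination (the locus is
treated as one non-recombining block, consistent with the strong observed
LD), no genotyping batch effects or probe-specific biases beyond iid
Gaussian ratio noise, no population stratification within a cohort, no
missing data. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness to
those real-data complications.

## Sampling study designs

Individuals are two independent chromosome draws. Case-control sampling
assigns affection with probability
`logistic(logit(prevalence) + Σ dose × logOR)` and fills both quotas by
rejection (a draw cap guards against extreme prevalence). Trios draw two
parents, transmit one uniformly chosen chromosome each, and retain the
family with probability equal to the child's disease probability
(single-affected-child ascertainment; under a null model transmissions are
exactly 50/50). MLPA simulation writes `dosage/2 + N(0, sd)` per
allele-specific probe and `copies/2 + noise` per CNR reference probe
(two probes per CNR and duplicate measurements of every probe by default,
as the assay is conventionally run), with *FCGR2C* assayed through
ORF-site and splice-site dosage probes and the paralog-identical promoters
through combined 2B.1/2B.2/2B.4 probes.

## MLPA interpretation

Copy number is `round(2 × median ratio)` with a no-call margin of 0.2 copy
units (at noise sd 0.05 and two probes per CNR this yields > 99% correct
per-CNR calls). *FCGR2C* resolution enumerates every multiset of the four
internal haplotypes consistent with (copies, ORF dosage, splice dosage);
a unique collapsed configuration is returned with posterior 1, otherwise
the maximum-posterior configuration under per-copy priors (multinomial
weights), ties broken toward more Stop copies, with an ambiguity flag and
the posterior share. Promoter allocation assigns 2B.2 to *FCGR2C* and 2B.4
to *FCGR2B* — where they almost always reside — with overflow spilling to
the paralog and flagged. `estimate_misclassification()` computes the exact
frequency-weighted probability, over all diplotypes of a pool, that a rule
output differs from the truth; on the European defaults this is small
(order 10⁻³, dominated by rare ORF+splice dosage coincidences) and is
cross-checked against Monte-Carlo simulation in the tests.

## Population statistics

Allele frequency is Σ dosage / Σ gene copies. EM haplotype estimation
(gene counting) runs on CNV-free individuals only — callers must filter —
with product-of-marginals initialization, stopping at relative
log-likelihood change < 1e-8 or 1000 iterations. At realistic sample
sizes the likelihood is effectively unimodal, but on very small datasets
EM from the symmetric product start can settle on an inferior mode, so
when the genotype classes admit at most 64 hard phase assignments each
assignment seeds a deterministic restart and the best final likelihood is
returned. Monotonicity is asserted in tests and the estimate is checked
against an independent numerical maximizer on small instances. Pairwise LD reports D, r², D′ and a
chi-square p (n·r², 1 df) after allele-vs-rest collapse; full multiallelic
D′ is out of scope. The CNV-stratified procedure partitions individuals
into ≤1 / 2 / ≥3 copies of a CNR, tabulates copy-aware allele counts per
stratum, and applies Fisher's exact test (network algorithm where
feasible, seeded Monte-Carlo with 10⁶ draws above a size bound, method
recorded).

## Case-control association

Genotype-category tables are compared by Fisher's exact test. Additive
odds ratios come from maximum-likelihood logistic regression of status on
allele copy count — dose 3, which duplicated genes produce, stays its own
additive level — with Wald 95% CIs on the log-odds scale, matching how the
published CIs are symmetric in the log. Joint models drop a column whose
dose correlation with an earlier column exceeds 0.95 (the published
analysis likewise omits the 2B.2 promoter for its near-complete LD with
the classic ORF); backward selection removes the highest Wald p until all
remaining are below alpha = 0.05, deterministically in column order. CNR
association uses two indicator contrasts (<2 vs rest, >2 vs rest) fitted
separately.

From the printed genotype-category and CNR copy-number counts of the
published European comparison (405 cases / 919 controls), this machinery
reproduces every targeted allele frequency at one-decimal precision and
every additive OR and CI at two decimals. Two published frequency cells
(V158F cases 37.0%, 2B.4 controls 10.0%) differ from their own printed
counts by exactly one final-digit unit (the counts give 36.9% and 10.1%),
and the published Fisher p-values differ from exact recomputation on the
printed counts by up to 0.003; the acceptance tests assert agreement at
one final-digit unit and 0.005 respectively, which is the closest the
printed table is internally consistent with itself. The published SH
frequencies are not recomputable from the printed SH rows at all and are
excluded.

## Trio phasing and TDT

Phasing enumerates diplotype decompositions of father, mother and child
(per-CNR copy splits × per-variant dosage splits) and keeps combinations
where the child's chromosomes are one from each parent. Parsimonious CNR
splits (at least one chromosome at baseline) are tried first; the rare
deletion+duplication configurations are enumerated only when Mendelian
matching otherwise fails, since priors down-weight them ~200-fold anyway.
Among surviving combinations the maximum prior-probability one (pool
frequencies; unseen haplotypes floored at 1e-9; ties broken
lexicographically) is selected. Mendelian inconsistency yields a flagged
no-call record, never an exception.

Solutions are grouped by the parent-symmetric multiset of labeled
(transmitted/untransmitted) chromosomes: a pure exchange of which parent
transmitted which of two identical assignments leaves every per-marker
T/U count unchanged and is not ambiguity. A trio is flagged ambiguous when
more than one group retains at least 0.1% of the posterior mass, and the
posterior share of the selected group is reported per family. Under the
European defaults about a quarter of trios carry such a flag. That number
deserves explanation: it is dominated by double-heterozygote
configurations of the common, weakly linked SNPs (H131R, V158F, the HNA
system), each contributing a 2–12% per-marker ambiguity rate that
compounds across eight jointly phased systems. Per single marker the
ambiguous fraction is far smaller, and — by the grouping argument above —
the dominant ambiguity class does not move any TDT count. Transmitted
chromosomes are recovered exactly whenever the flag is absent (verified
against retained simulation truth).

The test is the classic allele-wise TDT: a parent is informative for a
label when exactly one of its chromosomes carries it;
`Z = (T − U)/√(T + U)`, two-sided normal p. Chromosome-level labels
(`VF`, `Stop-Stop`, `-`, per-chromosome CNR copies 0/1/2) are treated as
alleles in their own right. Rows with ≤ 10 informative families are
flagged suppressed. The empirical-variance refinement of family-based
association software is a deliberate simplification left out; incomplete
trios are excluded from the statistic.

## Meta-analysis

A TDT result converts to `log OR = ln(T/U)`, `SE = √(1/T + 1/U)` (zero
counts error unless an explicit 0.5 continuity correction is requested,
and its use is recorded). The case-control side uses the logistic
coefficient and its SE — not a 2×2 Woolf estimate — matching how the
published CIs were produced. Fixed-effect generic inverse variance pools
them: weights ∝ 1/SE², pooled SE = 1/√Σw. No heterogeneity statistic is
computed by default (Cochran's Q sits behind a flag). The implementation
is an in-package weighted mean, cross-checked in tests against an
established meta-analysis package to 1e-10.

## Numerical choices and problem sizes

Frequency-sum and dosage invariants are checked to 1e-9; EM convergence at
relative log-likelihood 1e-8; IPF at 1e-4 on r²; pool rows below 1e-12
mass are pruned and the table renormalized; the haplotype-prior floor for
phasing is 1e-9; logistic fits use glm with epsilon 1e-10 and diagnose
separation at |coefficient| > 15. Simulation-based checks in the test
suite use n = 919 to 2600 individuals for frequency and r² recovery,
2000 replicates of 120 null trios for TDT calibration, 1000 replicates
for logistic type-I error, and a 300-trio / 900-individual end-to-end
run — sizes chosen to keep Monte-Carlo error well inside the asserted
bands on a single CPU.

## Known limitations

- The promoter allocation and FCGR2C resolution are rule-based with
  prior tie-breaks; their error rates are exactly computable per pool but
  priors from a mismatched population would degrade them.
- EM uses a single start; at extreme LD with many rare haplotypes the
  likelihood can in principle be multimodal.
- The TDT uses the standard variance, not the empirical-variance
  generalization; incomplete families are dropped.
- Default population parameters are rounded published summaries; where a
  printed table is internally inconsistent (SH rows, two frequency cells,
  Fisher p third decimals) the package reproduces the counts' arithmetic,
  not the typo.
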