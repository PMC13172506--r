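---
title: "Trio pooled-WES: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio pooled-WES: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolwes)
```

## The problem

Trio exome sequencing — proband plus both parents — is the most
effective sequencing design for neurodevelopmental disorders because it
resolves variant inheritance directly, and de novo variants are the
dominant pathogenic mechanism in these conditions. Its cost, three
individual exomes per family, limits routine use. The pooled-trio design
sequences the proband individually but combines parental DNA into one
maternal and one paternal pool at elevated depth. The pools cannot yield
individual parental genotypes; they answer a weaker question that is
sufficient for trio interpretation: *is this proband variant present in
the mothers' pool, in the fathers' pool, in both, or in neither?*

`poolwes` implements that design end to end: pool dimensioning,
simulation of pooled read evidence, inheritance classification,
inheritance-aware variant prioritization, a solo-exome CNV filter, and
the validation statistics that qualify the approach.

## Pool design mathematics

A pool of $n$ parents contains $2n$ allele shares. A variant carried
heterozygously by exactly one pooled individual (the singleton case —
the expected situation for ultra-rare variants, gnomAD MAF $< 10^{-4}$)
has expected pool VAF

$$N = \frac{1}{2n},$$

5% for $n = 10$. Observing at least $r$ reads per heterozygous allele
per individual ($r = 20$ by convention, the depth at which a germline
heterozygote is reliably detectable) requires mean pool depth

$$D = n \times 2 \times r,$$

400X for $n = 10$, 320X for $n = 8$. `required_pool_depth()` reports the
exact integer; rounding to sequencer lane granularity is left to the
facility.

The cost model (`cost_model()`, `trio_cost_reduction()`) prices a pooled
run at `pooled_multiplier` standard-WES units (default 1.28 — the deeper
pooled library costs about 28% more than a standard exome) and amortizes
each pool over its `pool_size` parents, one mother and one father per
trio: a pooled trio costs $1 + 2 \times 1.28/8 = 1.32$ units against 3
for a standard trio, a 56% reduction. The reduction is bounded above by
$2/3$ for any multiplier $\ge 1$: the individually sequenced proband is
a cost floor.

## The inheritance classifier

Proband variants first pass QC: VAF $\ge$ 0.3 and DP $\ge$ 20, both
inclusive — the reliability envelope for a germline heterozygous call.
Each surviving variant is looked up in both pools and called **present**
when the pool VAF is at or above the presence threshold, default **1%**
(inclusive). The threshold reflects the empirical separation between
inherited variants (pool VAF of 1–5% when a carrier parent is present)
and background noise at pooled depth; it is deliberately below the
expected singleton balance of 5–6% to tolerate unequal sample
representation. Sub-threshold reads are treated as absent: at 400X, one
or two alternate reads are indistinguishable from sequencing error. This
makes the method's one documented failure mode explicit — an inherited
variant whose carrier parent is badly under-represented can sit below 1%
(e.g. 1 read in 180, 0.56%) and be miscalled de novo; the classifier
reproduces this behavior by design, and confirmation of apparently
de novo calls by an orthogonal method remains part of the intended
workflow.

Pool evidence is taken from **per-site read-count tables** (the
"recount" path, standing in for a systematic pileup review of the pooled
alignments) rather than from a pool variant caller's emitted VAFs: a
caller may drop low-fraction sites entirely, while the decision needs
raw counts at every proband site. A site with no usable pool coverage is
classified **undetermined**, never silently de novo — the conservative
clinical behavior.

The decision table on autosomes (and for female X variants) is the
obvious 2×2 over maternal/paternal presence. On chrX for a hemizygous
variant in a male proband, the paternal pool is non-informative (fathers
do not transmit an X to sons): the maternal pool alone decides, and its
insufficiency makes the call undetermined. Unknown proband sex on chrX
is undetermined with an explanatory flag, as are chrY and mitochondrial
contigs, which the pooling design does not cover. Every cell of this
table is asserted against a hand-enumerated oracle in the test suite.

Compound-heterozygote phasing (`phase_compound_hets()`) follows from
classification: two heterozygous variants in one gene are in trans when
one is maternal and the other paternal; same-origin pairs are in cis;
pairs involving a biparental member are unphaseable from pools (the
carrier could be either parent), as are pairs with undetermined members.

## The prioritization cascade

Frequency filtering is MOI-aware: dominant and X-linked contexts keep
variants with total gnomAD allele count $< 5$; recessive contexts keep
gnomAD allele frequency $< 0.1\%$. ClinVar overrides both directions —
benign/likely-benign is always dropped, pathogenic/likely-pathogenic is
always kept — and these overrides take precedence over every other rule.
Genes of unknown MOI use the recessive cutoff, the permissive branch,
because the stricter dominant rule would discard candidate-recessive
variants; variants missing from gnomAD count as absent (AC 0).

In-silico prioritization scores missense variants against CADD $> 20$,
REVEL $> 0.5$, AlphaMissense $> 0.6$ and SIFT $< 0.01$. The published
thresholds do not come with an explicit boolean connective, so the
combination rule is a parameter: `majority` (default — a strict majority
of the predictors with available scores), `all_of`, or `any_of`.
Missing scores are excluded from the denominator, and a missense variant
with no scores at all is never prioritized on vacuous evidence.
Loss-of-function variants are prioritized without missense predictors;
synonymous and splice-region variants use SpliceAI $\ge 0.6$ — inclusive
because observed reportable splice variants sit exactly at 0.6.

Reportable calls follow three criteria that partition on zygosity and
inheritance: (1) de novo variants in known dominant/X-linked genes or in
candidate genes with a Domino score $\ge 0.6$; (2) hemizygous variants
in X-linked genes, regardless of Domino; (3) homozygous or in-trans
compound-heterozygous variants in known recessive genes or candidate
genes with Domino $< 0.6$. "Known" means in the diagnostic panel with
the matching MOI (`tier = "known_gene"`); everything else is assessed as
a candidate. Genes with unknown MOI and no Domino score fall to the
recessive branch for biallelic variants only, flagged
`no_moi_evidence`, since the criteria partition on a score that may be
missing in practice. Candidate-gene interpretation is supported by
constraint flags (pLI $> 0.9$, pNull $< 0.1$, LOEUF $< 0.6$, missense
Z $> 3.09$, Domino $\ge 0.6$, gnomAD AC $\le 1$) with **no composite
cutoff** — the flags rank, they do not gate.

## The CNV filter

CNV analysis runs on solo exome data only: pooled reads average
coverage across individuals and erase the dosage signal, so pools cannot
segregate CNVs. The cascade drops calls outside the panel, calls
recurring in multiple individuals of a sequencing run, single-caller
calls, then applies dosage-sensitivity filters: deletions kept with
haploinsufficiency percentile $< 40$ and not fully contained in a benign
population deletion, duplications analogously with triplosensitivity
$< 40$. One rule required an interpretation decision: the published
wording excludes calls with "LOEUF < 0.6 (indicative of low functional
impact)", which inverts standard LOEUF semantics (low LOEUF marks
*constrained* genes). The default `loeuf_rule = "literal"` implements
the wording as printed and warns; `"semantic"` excludes unconstrained
genes instead; `"off"` disables the rule. Multi-gene calls aggregate
gene scores by minimum — the most constrained gene governs, the
clinically conservative choice. Ranking of retained calls is a stable
deterministic sort: caller count, coding impact, phenotype match, then
shorter span.

## The simulator

`simulate_cohort()` generates trios under seven inheritance scenarios
(de novo, maternal, paternal, biparental, compound het, maternal
hemizygous X, homozygous biallelic) with proband reads at 100X and pool
reads at the design depth. Pool alternate counts are binomial at the
carrier-allele share $k/(2n)$, perturbed by a symmetric per-read error
(default $10^{-3}$, a typical post-filter substitution error rate) and
optionally by **overdispersion**: per-sample pool weights drawn from a
symmetric Dirichlet with concentration $1/\text{overdispersion}$, drawn
once per pool so that an under-represented individual fails consistently
across their variants — the mechanism invoked to explain missed
validation variants clustering in a few individuals. No specific
overdispersion value is claimed to match any real pool. Per-site depths
are Poisson around the mean (`poisson_depth = FALSE` fixes them for
exact tests). All draws flow from one seed; outputs are bit-for-bit
reproducible on one platform.

What the simulator does **not** emulate: mapping artifacts, strand or
context-specific errors, indel realignment, capture-kit coverage
heterogeneity, and pool-specific library effects. Passing simulation
tests therefore demonstrates the logic of the classifier and cascade
under the stated read model, not performance on real sequencing data.

`simulate_singleton_validation()` reproduces the validation experiment
design: ultra-rare variants, each carried by exactly one individual in
one pool, looked up in pooled counts — the input for sensitivity and
allelic-balance estimation.

## Validation statistics

`sensitivity()` is $100 \times TP/(TP+FN)$; `detection_breakdown()`
partitions pool VAFs into contiguous half-open bins labelled after the
conventional reporting ranges ($\ge 1\%$; 0.55–1%; >0–0.55%; no reads);
the printed ranges have gaps, so the implementation uses a total
partition that reproduces the printed counts on the printed data.
Percentages round half-up to two decimals, matching printed values
(`round()`'s banker's rounding would not). Specificity is not estimable
from this design — a variant present in another pooled individual is not
a false positive — and is not implemented.

`allelic_balance_test()` wraps the Wilcoxon signed-rank test of pool
VAFs against the expected balance $1/(2n)$: zero differences dropped,
exact null up to 25 nonzero differences, normal approximation with
continuity correction beyond. Two numerical choices matter. First,
differences are rounded to 9 decimals before ranking: in doubles,
$|0.04 - 0.05| \ne |0.06 - 0.05|$ in the last bit, which would
systematically misrank perfectly symmetric data; real read-count ratios
never differ at $10^{-9}$. Second, a caveat: pool VAFs at depth
$\sim$400 are right-skewed binomial proportions, so the signed-rank
symmetry assumption holds only approximately and the test over-rejects
somewhat under the null (about 15% at $\alpha = 0.05$ in simulation at
$n = 500$); its p-value should be read as a descriptive check of central
location, which is how it is used here.

`yield_summary()` recomputes all percentages from raw counts with
phase-appropriate denominators (solo phase: all patients; trio phase:
patients entering it); no stored percentage is trusted.

## Problem sizes and reproducibility

The test suite and examples run at desk scale: singleton experiments of
300–1127 variants, cohorts of 10–100 trios, 20 replicate seeds for
stochastic checks — sizes at which the binomial read model's analytic
expectations (mean VAF $k/(2n)$ within three standard errors, $\ge 99\%$
singleton detection at design depth, $\ge 99\%$ label recovery on
error-free cohorts) are sharp. The per-variant VAFs of the real
validation cohort are not published, so its specific findings (median
VAF, signed-rank p-value, the individual candidate genes) are not
reproducible and are deliberately not asserted anywhere; what the
package verifies is the arithmetic on printed counts and the behavior of
the method under its own stated read model.

## Known limitations

* Parental mosaicism and carrier identity within a pool are invisible by
  construction; only presence/absence is inferred.
* The 1% threshold trades a small, documented false-negative rate for
  de novo specificity; laboratories with different pool sizes or depths
  should re-derive it (`pool_presence()` takes it as a parameter).
* The in-silico combination rule is configurable because the published
  thresholds do not state one; results should report the mode used.
* `run_workflow()` models trio-phase entry as "no solo diagnosis and
  pools available"; the clinical judgment of what counts as a compelling
  solo VUS is outside its scope.
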