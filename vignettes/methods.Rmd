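---
title: "Methods: partner triage, knockdown concordance, and isoform usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partner triage, knockdown concordance, and isoform usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otxtools)
```

otxtools models the desk-scale computations of a choroid-plexus (ChP)
knockdown study of the OTX2 homeoprotein: which proteins co-precipitate with
the bait beyond IgG background, which genes respond consistently across
several knockdown models, which annotation terms are over-represented, which
transcript isoforms switch usage, and how qPCR folds quantify against a
reference gene. This vignette explains each model, its assumptions, the
tunable parameters, and the deliberate design choices where the procedure
was genuinely open.

## Partner triage from bait-vs-control peptide counts

An affinity-purification mass-spectrometry screen yields, per protein and
experiment, the number of distinct peptides identified in the bait (OTX2)
co-IP, $O$, and in the IgG control co-IP, $I$. Peptide counts are treated as
distinct peptide sequences rather than spectral matches. A protein reported
in only one co-IP carries count 0 in the other; once paired, a record is
never missing.

The triage accepts a protein as a putative partner through three routes:

1. **unique** — $I = 0$ and $O \ge 3$: solid evidence found exclusively
   with the bait;
2. **selected** — $O \ge 3$, $I \ge 1$, and relative peptide difference
   above 50 %;
3. **unique small** — $I = 0$, $O \ge 1$, and molecular mass
   $\le 25$ kDa (inclusive): small proteins produce few detectable
   peptides, so the peptide floor is waived for bait-exclusive ones.

The relative peptide difference is
$$\mathrm{rel\Delta} = \frac{O - I}{O},$$
clamped to $[0,1]$, with bait-exclusive detection scoring 1 and $O = 0$
undefined. The published tables never print the formula, and both
$(O-I)/O$ and $(O-I)/I$ are consistent with every tabulated row at the
$> 0.5$ threshold; $(O-I)/O$ is the default because it reads directly as
"relative peptide difference", and the $(O-I)/I$ variant is available as
`rel_delta(mode = "control")` (also clamped to $[0,1]$; the cap cannot
affect a 0.5 threshold).

**Category algebra.** `selected` requires detection in the control
($I \ge 1$), making it disjoint from `unique`. This is forced by the
published per-structure bookkeeping: a structure can report far more unique
than selected proteins, which is impossible if exclusive proteins also
counted as selected. `unique` and `unique_small` can overlap (a small
protein with $\ge 3$ exclusive peptides), so the partner total obeys
$$|U \cup S \cup V| = |U| + |S| + |V| - |U \cap V|.$$

**Consensus and cross-structure comparison.** Consensus partners within a
structure are the strict intersection of the per-replicate partner sets.
The cross-structure report uses the *high-confidence* filter — $O \ge 3$
and $\mathrm{rel\Delta} > 0.5$, with exclusivity counting as 1 — because the
published shared-partner table labels bait-exclusive rows as passing the
50 % criterion. A protein with no record in a structure counts 0 peptides
there and fails. Reports are ordered by descending bait evidence, then ID
(the source tables print no order).

Molecular weight, when computed from a sequence, uses average (not
monoisotopic) residue masses plus one water; a supplied `mw_kda` always
takes precedence over a sequence. One published total ("1195 of 4814"
partners in ChP) cannot be reconstructed from the printed per-category
counts by any simple union arithmetic, so no union total is asserted for
that structure.

## Knockdown differential-expression concordance

Inputs are per-gene condition means ("mean reads") and facility-computed
adjusted p-values; the package consumes `p_adj`, it never recomputes a
differential-expression test on real data. Fold changes are ratios of the
supplied means under the negative-reciprocal convention: $+k/c$ when
expression rises, $-c/k$ when it falls, $\pm\infty$ when one condition is
silent, undefined at $0/0$, and $+1$ at no change. Folds are reported at
two significant figures. Because the upstream engine normalised per sample,
a few published fold entries are not ratios of the printed means; only
ratio-consistent rows are asserted in tests. Percent knockdown is
$100(1 - k/c)$, rounded to the nearest integer for reporting (one published
percentage appears floored rather than rounded and is not asserted).

Significance is strict: $p_{\mathrm{adj}} < \alpha$ (default 0.05), with
direction from the fold sign; a gene silent in the control counts as up,
silent in the knockdown as down. The consensus list across comparisons
(default: the lateral-ventricle conditional, fourth-ventricle conditional,
and constitutive heterozygote comparisons) requires significance *and* a
consistent direction in every required comparison; genes significant
everywhere but direction-discordant are reported separately and belong to
neither list. Venn region counts are exclusive regions of 2–3 sets and sum
to the union. The `>10 mean reads in at least one condition` expression
floor is available as the enrichment background.

## Term over-representation

Enrichment of a query set against term annotations over a background uses
the upper-tail hypergeometric probability
$$p = P[X \ge k], \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$
i.e. a one-sided Fisher test, with Benjamini–Hochberg adjustment across all
tested terms. This is intentionally the plain textbook statistic: the
original ontology analysis used a web tool with a modified score and
unstated background, so printed enrichment p-values are not reproduced and
not asserted. Terms smaller than `min_term_size` (default 2, so singleton
terms cannot dominate) are not tested; annotated genes outside the
background are dropped, and query genes outside the background are dropped
with a warning.

## Isoform usage and switches

Isoform fraction is the isoform's share of its gene's expression per
condition, $\mathrm{IF} = x_{\mathrm{iso}} / x_{\mathrm{gene}}$ on
replicate-pooled counts — the simplest reading of "% of total isoforms". A
per-replicate-mean mode is available for designs with very unequal depths.
The usage difference is $\mathrm{dIF} = \mathrm{IF}_{kd} -
\mathrm{IF}_{ctrl}$; per gene, fractions sum to 1 in each condition and
dIF sums to 0.

A switch requires both an effect size, $|\mathrm{dIF}| \ge 0.15$
(inclusive, the conventional cutoff), and significance, BH-adjusted
$p < 0.05$. The significance test is a two-proportion z-test (no continuity
correction) of the isoform's pooled count against the gene's pooled total
across conditions. When any expected cell count of the underlying 2×2 table
is below 5 the large-sample test is unreliable, and the exact conditional
(Fisher) test of the same table is used instead. This deliberately replaces
the generalized-linear-model machinery of full differential-transcript-usage
pipelines: it captures the same question (did this isoform's share of the
gene change?) at desk scale, but ignores replicate-level dispersion, so its
p-values on real overdispersed data would be anti-conservative. The planted
switch genes in the bundled simulations — not any published switch gene
list — are the recovery targets.

## qPCR relative quantification

The 2^−ΔΔCt method: per sample, $\Delta C_t = C_t^{target} -
C_t^{ref}$; $\Delta\Delta C_t$ subtracts the *arithmetic mean* of the
calibrator group's $\Delta C_t$ (log-space averaging, matching comparison
to mean control expression), and the fold is $2^{-\Delta\Delta C_t}$. Two
consequences are tested as invariants: the calibrator group's fold has
geometric mean exactly 1, and folds are invariant to any constant plate
shift in Ct. Technical replicates are averaged on the Ct scale before
$\Delta C_t$ (the scale on which replicate noise is approximately
symmetric); amplification-efficiency correction is out of scope. Group
comparison uses a two-sample t-test on the fold values.

## Synthetic-data generators

Each generator is a pure function of a spec and a seed, and emits truth
tables keyed by the same IDs as the data.

- **Co-IP screens** (`simulate_coip`): true partners are bait-exclusive
  with Poisson peptide counts (mean 8, truncated at 1), contaminants carry
  independent Poisson counts with a common mean (10) in both co-IPs
  (relative difference ≈ 0), and small exclusive proteins have mean 2 bait
  peptides and masses uniform in 5–25 kDa. Defaults plant 60 partners, 300
  contaminants, and 30 small proteins over 3 replicates — the scale of a
  ChP consensus experiment. `noise_free = TRUE` fixes counts at class
  means, the regime in which triage recovery is exact by construction.
- **DE tables** (`simulate_de`): log-normal baseline means (median ≈ 300
  reads, σ(log) = 1.5), planted consensus genes with a common direction and
  log-normal fold effects (median ≈ 3, floored at 1.2) in all three
  comparisons, comparison-specific extra genes, optional discordant genes,
  and directly generated adjusted p-values (significant genes strictly
  below 0.05, null genes at or above). Defaults mirror the study: 15000
  genes, per-comparison significant totals 375 / 808 / 528, consensus
  42 up + 34 down.
- **Transcript counts** (`simulate_isoforms`): per gene, condition, and
  replicate, multinomial draws around planted isoform fractions (optionally
  Dirichlet-multinomial via `dirichlet_precision`). Switch genes exchange
  exactly `target_dif` (default 0.30) of usage between two focal isoforms
  holding a fixed combined share (default 0.9); other genes reuse one
  Dirichlet-drawn fraction vector in both conditions. Defaults: 2
  replicates, 1000 reads per gene and condition.

What the generators do *not* emulate: peptide-level FDR and spectral
identification noise, per-sample normalisation artefacts (the reason some
published folds are not ratios of printed means), gene-level expression
changes coupled to isoform switches, and library-size variation. Passing
recovery tests therefore demonstrates correctness of the downstream logic
under clean count models, not robustness to those upstream effects.

## Numerical choices and test scales

Degenerate inputs are representable outcomes, not errors, wherever the
quantity is well-defined on the boundary: $\mathrm{rel\Delta}$ undefined at
$O = 0$, folds $\pm\infty$ with a silent condition, percent knockdown
undefined at zero control. Strictness follows the conventions above:
$> 0.5$ and $p < \alpha$ strict, $\le 25$ kDa and $|\mathrm{dIF}| \ge 0.15$
inclusive. Ties in report ordering break lexicographically by ID.

The test suite verifies triage and enrichment against independent oracles
(exhaustive per-protein rule evaluation on universes of up to 20 proteins;
enumeration of all $\binom{N}{n}$ query draws for $N \le 15$), and runs the
stochastic recovery checks at 200 seeded simulations each: planted
$\mathrm{dIF} = 0.30$ switches at 1000 reads per gene (recovery ≥ 95 %
required) and null screens of 10 genes (false-positive gene rate within
$\alpha + 3\,\mathrm{SE}$). These sizes give the Monte-Carlo assertions
comfortable margins while keeping the whole suite under a minute.

## Known limitations

- The two-proportion switch test ignores biological replicate dispersion
  (see above); treat real-data p-values as exploratory.
- Enrichment results depend strongly on the background choice; the
  expression floor is a reasonable default only downstream of the
  differential-expression tables.
- The triage is a deterministic rule set, not a probabilistic scoring model
  (no interaction-probability estimates, no contaminant-repository priors).
- qPCR folds assume perfect doubling per cycle; efficiency-corrected
  methods are out of scope.
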