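---
title: "Methods: metabolite-mediated cell-cell communication scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolite-mediated cell-cell communication scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlrcomm)
```

## The model

Metabolite ligands are invisible in scRNA-seq, so `mlrcomm` estimates a
sender cell type's capacity to supply a metabolite from the expression of the
annotated machinery around it. Intracellular concentration tracks the balance
of synthesis and degradation; export to the extracellular space requires
transporters. Both proxies are built from *per-cell-type mean expression on a
linear scale*:

* net enzyme expression
  $E = \left(\prod_{i=1}^{m} P_i\right)^{1/m} - \left(\prod_{j=1}^{n} S_j\right)^{1/n}$,
  where $P_i$ are the mean expressions of the $m$ producer enzymes and $S_j$
  of the $n$ consumer enzymes in the sender;
* transporter expression $T$, the geometric mean of the $k$ transporter
  genes in the sender;
* availability $M = \sqrt{E^2 + T^2}$;
* receptor expression $R$, the geometric mean of the $q$ receptor-complex
  subunits in the receiver (all subunits must be expressed — one silent
  subunit zeroes $R$);
* the communication score $MR = \sqrt{M^2 + R^2}$.

The Euclidean norm treats availability and receptor expression as two
orthogonal components of one signal: it is symmetric, bounded by
$\max(M,R) \le MR \le M + R$, and penalizes a single extreme component less
than a product rule would. Every quantity is degree-1 homogeneous in the
expression scale, so the overall scale of the matrix (and thus the CPM
target constant) cannot change rankings or p-values — a property the test
suite checks explicitly.

**Assumptions worth stating.** Enzyme/transporter transcript abundance is
taken as a monotone proxy for metabolic flux — no kinetic constants
(Km, kcat), no flux balance, no units: $M$ is a relative, unitless quantity.
Metabolites are assumed to act locally enough that every ordered pair of
cell types in the dataset (including autocrine pairs, kept by default) is a
candidate channel.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_frac_pct` (N) | 10 | a gene counts for a cell type only if expressed (> 0) in at least N% of its cells; the boundary passes, because the filter removes genes expressed in *fewer* than N% |
| `n_perm` | 100 | label permutations; the smallest attainable p is 1/(n_perm+1) |
| `alpha` | 0.05 | reporting threshold for the bubble plot / CLI summary only — all rows are always written |
| `negative_e_policy` | `"literal"` | what to do when consumption dominates (E < 0), see below |
| `normalization` | `"cpm"` | each cell rescaled to sum 10,000 (use `"none"` for TPM input) |
| `include_autocrine` | `TRUE` | keep sender = receiver pairs |
| `seed` | 0 | drives the permutation RNG; fixed seed ⇒ byte-identical results files |

The filter is applied *site-specifically*: enzyme and transporter sets
against the sender's expressed fractions, receptor subunits against the
receiver's. Each gene set only has biological meaning in the cell type whose
expression feeds its equation; applying both sides' filters to all sets
would entangle unrelated cell types. A triple whose receptor loses any
subunit to the receiver's filter is dropped from the table entirely; a
triple that survives filtering but scores $MR = 0$ (all machinery at zero
mean, possible at N = 0) is kept, flagged untestable, and assigned
p = q = 1.

## Significance

For each of `n_perm` permutations the cell-type labels are shuffled
uniformly over **all** cells (type sizes preserved) and the entire pipeline
— profiling, filtering, scoring — is recomputed, so the null distribution
reflects every data-dependent step, not just the final score. The one-sided
empirical p-value uses the add-one convention
$p = (1 + \#\{MR^{perm} \ge MR^{obs}\})/(n_{perm}+1)$, which avoids p = 0 and
makes p-values valid (slightly super-uniform) under exchangeability. A
triple skipped in some permutation (receptor filtered out there) contributes
$MR^{perm} = 0$ for that permutation: no receptor, no communication.
Benjamini–Hochberg q-values are added over all testable triples jointly;
raw p-values are always retained.

Whether shuffling should be global or restricted to the focal pair's cells
is a genuinely open design point; the global shuffle matches the stated
"permute the group labels of cells", keeps the null exchangeable across the
whole dataset, and lets one permutation pass serve every triple at once.

## Numerical and degenerate-input choices

* **Geometric means in the log domain.** Products of tens of small means
  underflow double precision; `geometric_mean` computes
  $\exp(\mathrm{mean}(\log x))$ with an exact early exit on zero. The test
  suite checks agreement with the direct product-root form to 1e-9 relative
  over 1000 random draws.
* **Empty-set convention.** A metabolite with no annotated producers
  contributes 0 to the first term of E; no transporters ⇒ T = 0; absent
  machinery is absent signal. An empty receptor, by contrast, is an error —
  a receptor must have at least one subunit.
* **Negative E.** The availability formula squares E, so a strongly
  net-consuming sender would *raise* M under the literal form. The default
  (`"literal"`) implements the formula exactly as written; `"clamp"`
  (floor E at 0) is exposed for users who consider that behavior a bug in
  the model rather than a feature. Tests cover both.
* **Dual-role enzymes.** Genes annotated `"both"` enter the producer *and*
  the consumer product — the annotation asserts dual capacity, and dropping
  either side would silently reweight the other.
* **KB genes absent from the matrix** are removed by the expressed-fraction
  filter (they are expressed in 0% of cells and, additionally, never
  retained even at N = 0). An alternative convention — keep them with mean 0,
  zeroing their set's geometric mean — is available through the scoring-level
  functions, but the pipeline uses the filter rule: a gene the experiment
  never measured should not veto the genes it did.
* **Ties and ordering.** Output is sorted by (p ascending, MR descending,
  sender, receiver, metabolite_id, receptor) with locale-independent radix
  ordering — a total order, so results files are byte-stable. Numbers are
  serialized at 6 significant digits, enough to round-trip the score at the
  tolerance the tests assert while keeping files diffable.
* **Complex identity** is order-insensitive (sorted, `";"`-joined subunits);
  duplicate interactions under that identity are deduplicated before
  scoring and reported by `validate_kb` as warnings.

## What the synthetic data does and does not establish

`make_toy_kb` fabricates a KB whose *shape* mirrors real annotation — 1–3
producers and consumers, 0–2 dual-role enzymes, 0–2 transporters per
metabolite, 1- or 2-subunit receptors — with synthetic, role-disjoint gene
symbols. `generate_null_dataset` draws every gene i.i.d. across all cells
from one negative binomial (default mean 5, dispersion 0.5, plus 20
background genes), chosen over Poisson because overdispersion is what makes
the permutation-calibration test honest. Labels are then exchangeable *by
construction*, which is exactly the null hypothesis of the permutation
test. `generate_planted_dataset` layers a single multiplicative signal
(default 8×) on the planted triple's machinery, suppressing the consumer
enzymes in the sender so the recovery test does not entangle with the
negative-E policy; dual-role enzymes are left untouched because boosting a
gene that sits in both products is directionally ambiguous.

Consequently a green suite establishes: the equations are implemented as
specified, the permutation test is calibrated under exchangeability, and a
strong planted effect is recovered. It does **not** establish performance on
real atlases: no batch effects, no dropout structure beyond the NB zeros, no
cell-type hierarchies, no correlated gene programs, and effect sizes far
cleaner than biology provides.

## Known limitations

* Transcript abundance stands in for enzymatic flux and transport capacity;
  the proxy ignores post-transcriptional regulation and kinetics entirely.
* M and R are combined without rescaling to a common range; whichever
  component lives on a larger numeric scale dominates the norm.
* The permutation test assumes cells are exchangeable under the null —
  strong batch structure violates this and will miscalibrate p-values.
* Ortholog mapping is symbol-level and one-to-one; paralog expansions are
  resolved by dropping unmappable entries (all-or-nothing for complexes),
  with counts reported.
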