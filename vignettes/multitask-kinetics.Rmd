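---
title: "Multitask prediction of enzyme kinetic parameters: methods notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask prediction of enzyme kinetic parameters: methods notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetmoe)
```

kinetmoe predicts the turnover number *k*cat and the Michaelis constant
*K*m jointly, from enzyme sequence, substrate SMILES and assay
conditions. This vignette records the modelling choices, their
assumptions, and the limits of what the offline test suite can and
cannot show.

## Data model and curation

A raw record is one database measurement: EC number, enzyme type
(wild-type or mutant with substitution codes), amino-acid sequence,
substrate SMILES, organism, pH, temperature, and one kinetic value with
its unit. Canonical units are s⁻¹ for *k*cat and mM for *K*m — the units
in which medians and predictions are conventionally reported — and the
conversion table is deliberately closed (s⁻¹/min⁻¹/h⁻¹; M/mM/µM/nM): a
record in any other unit is rejected with a reason code rather than
guessed at, because silent mis-scaling is the most damaging curation
error in kinetic corpora.

Cleaning runs in a fixed order: completeness filter, unit
normalization, mutation application, SMILES canonicalization (Open
Babel), structural filter, value filter, duplicate handling, log10
transform, task join. The structural filter keeps substrates with heavy
atom count h in 2 < h ≤ 128 and no fragment dot; the value filter
requires strictly positive values (a non-positive kinetic constant has
no log10 and is always a data error). Mutation codes use the standard
1-based `A123V` notation applied to the wild-type sequence; only
substitutions are supported, and a reference-residue mismatch rejects
the record instead of silently mutating the wrong position.

Duplicate handling distinguishes two cases that a single "drop
duplicates" rule would conflate: byte-identical repeats (same assay key
*and* value) collapse as duplicates, while same-key records with
different values are aggregated to the *maximum* *k*cat and the
*minimum* *K*m before the log transform — the optimistic-extremum
convention for repeated assays. Aggregation therefore never invents a
value: every retained value is one of the inputs. The final outer join
on the assay key (canonical SMILES, sequence, pH, temperature,
organism) produces joint entries carrying both labels where both exist;
the accounting identities (`n_union = n_both + n_kcat_only +
n_km_only`, and the per-task totals) hold by construction and are
property-tested.

Temperature is kept in °C as collected; the RBF encoding below is
shift-invariant up to center placement, so a Kelvin conversion would
change nothing. pH and temperature enter the duplicate key exactly as
given, without rounding.

The pipeline is idempotent: converting curated entries back to records
(mutations already applied, hence codes cleared) and re-running changes
nothing. This is the practical guarantee that curation is a projection,
not a drifting transformation.

## Featurization

The fused input is `[enzyme ‖ substrate ‖ auxiliary]`. Enzyme and
substrate embedders are pluggable behind a small contract (fixed output
dimension, deterministic). The shipped defaults are hash embedders:
two independent rolling hashes of (salt, text) seed a fixed
pseudo-random draw that is L2-normalized. They carry no biochemical
prior — they are exchangeable identities, not representations — but
they are deterministic, sensitive to single-residue substitutions, and
collision-free in practice (both 31-bit hashes must collide; tested at
10⁴ sequences). Adapters around pretrained protein/molecule language
models satisfy the same contract when their embeddings are available;
nothing downstream changes.

Continuous covariates are expanded over Gaussian radial basis
functions, `e_m(x) = exp(−γ(x − μ_m)²)` with γ = 10 and centers from
the training minimum to maximum at stride 0.1. Centers are frozen from
the *training* split only; prediction-time values outside the span fall
on the Gaussian tails and are never an error. With γ = 10 a value 0.1
(one stride) from a center responds exp(−0.1) ≈ 0.905, so neighbouring
centers overlap strongly and the encoding is effectively a smooth
soft-binning. Note that in double precision the far tails underflow to
exactly zero beyond ~27 units of distance; the mathematical property
"components in (0, 1]" holds on any realistic pH/temperature span.

The linear maps from the RBF expansions to the auxiliary dimension and
the organism embedding table are *trainable* model parameters,
optimized jointly with the network (the alternative — fixed random
projections — was rejected because the organism table is explicitly an
embedding and there is no separate training procedure for it). Missing
pH, temperature or organism contribute zero vectors, matching the
optional-input semantics of a prediction service: the model then falls
back on sequence and substrate alone.

## The multitask core

The customized-gate-control architecture uses, per task, m_k specific
experts plus m_s shared experts; a per-task softmax gate over the raw
fused input weights the expert outputs; a per-task tower maps the fused
representation to the scalar log10 prediction. Defaults follow the
reference setup (4 + 4 experts, expert width 768, dropout 0.2, towers
128–128–1, Adam at 1e-4, batch size 1, 50 epochs); tests and the
bundled benchmark shrink widths and raise the batch size and learning
rate, because the behaviour being verified (descent, decoupling,
gate properties, recovery of a known signal) does not depend on the
full-scale capacity.

Two deliberate deviations from a literal reading are worth recording.
First, the tower head is linear, with ReLU only between hidden layers:
a ReLU output would forbid negative log10 values, which real *K*m
medians (and any sub-1 s⁻¹ *k*cat) require. Second, "expert's number:
4" is read as 4 specific experts per task *and* 4 shared experts; both
counts are configurable and the interpretation is recorded as such.

Training minimizes a masked L2 loss: the mean squared error over the
labels each entry actually carries. This is the only loss treatment
consistent with a corpus in which a third of entries carry a single
label — those entries still inform their task and the shared experts,
which is precisely the point of joint training. An all-masked batch is
an error, not a zero. Model selection keeps the parameters of the
epoch with the lowest validation loss, earliest epoch on ties.

With `n_cgc_layers > 1` the stacked (progressive-layered-extraction
style) variant is enabled: intermediate layers maintain an additional
gated shared path whose gate sees all experts. The default stays at
one layer, which also performed better in the reference comparison.
The entire backward pass is hand-derived matrix code; it is verified
against central finite differences to ~1e-10 for both architectures,
including the gradients flowing into the auxiliary encoder. Gradient
flow also respects the architecture: with m_s = 0 the task losses
decouple exactly (zero cross-task gradients), which is tested.

All randomness — initialization (symmetric uniform fan-in scaling),
epoch shuffling, dropout — threads through a single seed, and seeded
runs reproduce training histories bit-for-bit.

## Evaluation

Splits are 8:1:1, stratified by label pattern (both / kcat-only /
km-only) with floor + largest-remainder rounding per stratum, so the
three splits preserve the label-pattern mix; strata under 3 entries go
to training with a warning. Metrics are the Pearson correlation, R²
and RMSE on the log10 scale, with the two-sided t-test on the PCC and
the two-sided Wilcoxon rank-sum test (exact for small untied samples)
for group comparisons — and nothing else, by design.

Subtest partitions mirror standard practice: wild-type vs mutant;
promiscuity (wild-type enzymes with ≥ 2 substrates; the
highest-*k*cat or lowest-*K*m substrate is "preferred", ties all
preferred and logged); mutation fold-change (linear ratio bands
0.5–2.0 / > 2 / < 0.5, scale-invariant); and the strictly unseen
subset (sequence *and* substrate absent from training — the stricter
of the two possible readings, chosen because it is the one that
actually probes joint novelty). Fold-change classification needs a
wild-type reference per mutant; the matching rule — same (EC,
organism, canonical substrate), closest (pH, temperature) — is a
package decision, and unmatched mutants are excluded rather than
force-matched.

The hit ratio for engineering panels compares *directions*: variant i
scores a hit when sign(predicted efficiency change) equals
sign(experimental efficiency change) relative to the reference, with
efficiency = log10 *k*cat − log10 *K*m (monotone-equivalent to the
linear *k*cat/*K*m ratio, hence invariant under any strictly
increasing transform of the predictions — also tested). Exact ties
with the reference are excluded and logged rather than counted either
way.

## The synthetic benchmark

The generator emulates the *shape* of a curated kinetic corpus, not
its content: label-pattern proportions default to the real corpus
(50.4% both, 12.9% kcat-only, 36.6% Km-only); enzymes are drawn from a
pool so they recur with several substrates (exercising the promiscuity
partition); mutants are emitted as wild-type sequence + substitution
codes; values are rendered in mixed legal units; same-key worse
measurements are planted so max/min aggregation provably recovers the
intended label; and every cleaning filter has an on-demand violator
mode with exact planted counts.

Labels are linear in the fused generative features:
`label_t = ρ·u + (1 − ρ)·v_t + ε_t`, with u a shared projection, v_t
task-specific projections, signals standardized to unit variance, and
ε_t Gaussian with sd `noise_sd`. Linearity is the point — it makes the
Bayes-optimal R² analytically known, `1 / (1 + noise_sd²)`, so
"learning worked" is a well-posed claim. The benchmark conditions are
ρ = 0.9 and noise_sd = 0.5 (Bayes R² = 0.8) at n = 2000 with reduced
embedding dimensions (16/8/8); under these conditions the test suite
requires held-out R² ≥ 0.5 per task (5-seed median) and multitask
performance within 0.02 of matched-capacity single-task models.
Remaining desk-scale choices, fixed once: 20 organisms, 35% mutants,
10% duplicate rate — magnitudes a curated corpus of this size would
plausibly show.

What passing these tests does *not* show: anything about real
sequences or chemistry. Hash embeddings carry no structure, the label
surface is linear, and the label noise is homoscedastic Gaussian;
real kinetic data have heavy tails, assay batch effects, and
nonlinear sequence–function relationships. The benchmark validates
the *machinery* — curation bookkeeping, gradient correctness,
optimization, evaluation plumbing — and deliberately not the
headline accuracies, which require the real corpus and pretrained
embedders.

## Numerical and degenerate-input conventions

* Softmax is computed with row-max subtraction; gates are validated to
  sum to 1 within 1e−9.
* `build_rbf_centers` extends the grid by one stride when the maximum
  is not on the grid, so the last center always covers the range.
* Empty inputs: an empty record table curates to an empty entry table
  with all counts zero; an empty training set is an error.
* Zero-variance vectors are errors for PCC and R² (not NaN).
* `|PCC| = 1` returns p = 0 by convention.
* Ties: duplicate-extremum substrates are all "preferred" (logged);
  hit-ratio ties with the reference are excluded (logged); validation
  loss ties keep the earliest epoch.

## Known limitations

* No pretrained-embedding adapters ship in the package; the contract
  is the extension point.
* The stacked extraction variant shares the training loop but has seen
  less tuning; it exists for architecture comparisons.
* Sequence-identity binning of test entries (an external-tool workflow)
  is not reimplemented; a precomputed identity column can drive the
  same report.
* Training is plain R matrix code on one CPU: fine at benchmark scale
  (seconds to minutes), not intended for corpus-scale runs with
  1024-dimensional embeddings.
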