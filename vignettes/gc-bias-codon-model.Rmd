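---
title: "A CTMC model of codon usage under GC mutational bias: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A CTMC model of codon usage under GC mutational bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcodon)
```

## The model and its assumptions

`gcodon` models synonymous codon usage as the stationary distribution of a
continuous-time Markov chain on each amino acid's codon set. The assumptions
are deliberately minimal:

* **Synonymous point mutations only.** Non-synonymous changes are excluded,
  so each amino acid's codons evolve on the network of single-nucleotide
  synonymous substitutions. Serine is the one amino acid whose codons split
  into two blocks (TCN and AGY) that cannot reach each other synonymously;
  they are modelled as separate groups, Ser4 and Ser2, each renormalized to
  its own total.
* **GC-biased rates.** A substitution that adds a G or C runs at
  `base_rate * B`, one that removes a G or C at `base_rate * (1 - B)`, and a
  GC-preserving substitution is symmetric. `B` is the GC bias — the
  equilibrium probability that a neutrally evolving site is G or C — and the
  classical ratio of GC-gaining to GC-losing rates is `lambda = B / (1 - B)`.
* **Equilibrium.** Observed usage is identified with the chain's stationary
  distribution. The network of each group is a tree-with-cycles on at most 6
  states whose GC-changing edges all have the same (B, 1−B) ratio, so the
  chain is reversible and detailed balance yields

  `pi(c) = B^g (1-B)^(m-g) / sum_c' B^g(c') (1-B)^(m-g(c'))`

  where `g` counts G/C among the group's synonymously variable positions
  (third position; first *and* third for arginine and leucine) and `m` is
  the number of variable positions. The base rates cancel: transition /
  transversion asymmetries do not move the equilibrium, which is why the
  model has a single parameter.

Three qualitative families follow. Two- and four-codon groups are linear in
`B` (usage `1-B`/`B`, halved for four-codon groups). Isoleucine, with three
codons, is nonlinear but monotone (`(1-B)/(2-B)` twice, `B/(2-B)` once).
Arginine and leucine have three codon classes — 0×GC, 1×GC, 2×GC by G/C
count at the two variable positions — with usage `(1-B)^2`, `B(1-B)` and
`B^2`, each over `(1+B)`. The 1×GC per-codon curve peaks at
`B* = sqrt(2) - 1 ≈ 0.414` (usage `3 - 2*sqrt(2) ≈ 0.172`): the peak sits
left of neutral because each group has two 2×GC codons competing against a
single 0×GC codon. Over any reasonably wide panel of biases this peaked
curve correlates *negatively* with GC3, which is the model's explanation for
the anomalous behaviour of AGG and TTG — the two G-ending 1×GC codons.

Summed over a group's G/C-ending codons, equilibrium usage equals `B` for
every group except isoleucine (`B/(2-B) <= B`): per-amino-acid GC3 tracks
genomic GC3 one-to-one, with isoleucine the sole exception.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `B` | GC bias, fraction in [0, 1] | — (the free parameter) | sole model parameter; estimated by GC3 or by MLE |
| `base_rates` | symmetric per-edge rates, free scale | 1.0 | equilibrium provably invariant; exposed to demonstrate that invariance |
| `min_cds` | records kept if built from at least this many CDS | 50 | species summaries below ~50 CDS estimate usage poorly |
| `min_aa_count` | per-record minimum codons of an amino acid | 0 (genome), 10 for gene-level work | a gene with <10 codons of an amino acid gives noise-dominated frequencies |
| `span`, `degree` (LOESS) | smoother bandwidth and local polynomial order | 1.0, 2 | the conventional settings for usage-vs-GC3 curves |

GC3 denominators always exclude stop codons; ATG and TGG are also excluded
by default since they carry no synonymous signal (a flag restores the strict
all-sense-codon denominator, as the convention differs between authors).

## Numerical choices

* **Stationary solve.** `pi Q = 0` with one balance equation replaced by
  `sum(pi) = 1` — a dense linear solve, deterministic and well conditioned
  for chains of at most six states. Eigen-decomposition would add nothing
  but tie-break ambiguity.
* **(B, 1−B) rather than (lambda, 1) rate scaling.** Identical equilibria
  wherever `lambda` is finite, but the endpoints `B = 0` and `B = 1` remain
  valid generators (the chain simply freezes in its most AT- or GC-rich
  reachable state). `bias_to_lambda(1)` raises an error pointing at this
  parameterization.
* **Peak finding.** The 1×GC maximum is the positive root of
  `1 - 2B - B^2`, i.e. `sqrt(2) - 1`; a golden-section search at tolerance
  1e-10 confirms it at construction time. Monotone and linear classes return
  no peak. Ties cannot arise (the curve is strictly concave).
* **Degenerate inputs.** Codons with ambiguous bases are skipped and
  QC-tallied, never imputed; sequences with length not divisible by three
  are skipped with a warning; groups below the count threshold are marked
  absent (`NA`) rather than zero-filled, and every analysis drops records
  pairwise per codon, not listwise.

## The Harvey-Collier test and the choice of regressor

Nonlinearity of each codon's usage curve is scored with the Harvey-Collier
test: regress usage on GC3, order records by GC3 (ties broken by record id
for determinism), and t-test the mean of the recursive residuals. The
implementation delegates to `lmtest::harvtest` — the standard R
implementation of the test — and recovers the sign of the mean recursive
residual through an internal recursion that the test-suite also uses as an
independent cross-check of the statistic's magnitude.

One subtlety is worth spelling out. On panels generated from the model
itself, record GC3 is not exactly the generating bias `B`: isoleucine's
predicted GC3 is `B/(2-B) < B`, so whole-record GC3 is a slightly
*nonlinear* monotone transform of `B`. On low-noise synthetic panels this
curvature is detectable, and even a codon whose usage is perfectly linear in
`B` (say AAC) is flagged as nonlinear against the GC3 axis. For that reason
`harvey_collier()`, `linearity_report()`, `variance_explained()` and
`deviation_screen()` accept an explicit per-record `B` override: linearity
and exactness checks on synthetic data are made against the axis in which
the property truly holds, while GC3 remains the default regressor — the
correct choice for real data, where the generating bias is unobservable.
The Arg/Leu-versus-two-codon separation in Harvey-Collier magnitude is
robust to the choice of axis.

## Variance explained

For a unit `u` (a codon, or a group's GC class with observed and predicted
usage summed within the class),

`VE(u) = 1 - Var(model_u(B_r) - obs_u_r) / Var(obs_u_r)`

across records `r`, with `B_r` the record's GC3 unless overridden. Weighted
averages use the total codon count entering each unit's calculation — the
natural reading of weighting "by the number of codons used". VE can be
negative (model worse than the record mean); adding a constant to both model
and observation leaves it unchanged; independent noise strictly lowers its
expectation. Class-level VE is at least codon-level VE whenever the noise
exchanges usage *within* a class (e.g. G- versus C-ending codons trading
usage), because the class sums cancel it — the mechanism behind class-level
fits being systematically better than codon-level ones.

## What the synthetic generator emulates — and what it does not

`simulate_panel()` draws, per record, a bias `B` and then per synonym group
a multinomial sample of fixed size around the closed-form frequencies. This
mirrors the two regimes of real panels: genome-scale records (many codons
per group, count noise negligible) and gene-scale records (tens of codons,
noise-dominated). Optional perturbations apply a relative usage shift to
named codons with group-local renormalization — the shape of codon-specific
avoidance effects (such as the well-known GGG under-usage attributed to
guanine-run avoidance) without committing to a selection model. Amino-acid
composition is uniform across groups by default; the model is
composition-agnostic, so this costs no generality for the statistics
computed here, but it means simulated GC3 weights all amino acids equally,
unlike any real proteome.

What the generator does **not** emulate: selection on translational
efficiency, GC skew (strand asymmetry), context-dependent mutation,
non-equilibrium lineages (recent lateral transfers), or correlated usage
across groups. Passing tests on synthetic panels therefore demonstrate the
correctness of the machinery and the internal consistency of the model —
not that real genomes obey it; on real data those unmodelled forces appear
as reduced variance explained and as codons flagged by the deviation
screen.

`evolve_sequence()` complements the closed forms with an exact event-driven
(Gillespie) simulation. Because the model is context-free, codons evolve
independently, and each position is simulated by exponential waiting times
from its current exit rate; this is statistically identical to a global
Gillespie simulation of the whole sequence and converges to the closed-form
equilibrium (verified by chi-square goodness of fit in the test-suite).

## Problem sizes and determinism

The test-suite and the acceptance script use: 1000 random
(group, bias, base-rate) draws for the closed-form/solver equivalence; a
500-record panel with `B ~ U(0.2, 0.8)` and 1e4 codons per group for the
correlation-sign, nonlinearity-ranking, parameter-recovery and
variance-explained checks; and a 1e4-codon arginine sequence evolved to time
60 for simulator convergence. These sizes put Monte-Carlo error well below
the assertion margins while keeping a full run in tens of seconds. Every
stochastic step funnels through an explicit integer seed; identical seeds
reproduce byte-identical panels, FASTA emissions and pipeline outputs.

## Known limitations

* Only genetic codes with the standard codon-to-amino-acid map (NCBI tables
  1 and 11) are accepted; other codes change the synonym networks and would
  silently invalidate the closed forms, so they are rejected outright.
* The Ser2/Ser4 split means the model is silent on the relative usage of
  the two serine blocks.
* Met and Trp carry no synonymous signal and are excluded from modelling
  (and, by default, from GC3).
* The per-record bias MLE assumes independent multinomial counts per group;
  for real data with linkage and shared phylogeny it is an approximation,
  which is why it is reserved for parameter-recovery experiments rather
  than the default analysis path.
* The count of model-predicted nonlinear codons can be read as 12 (arginine
  and leucine) or 15 (adding isoleucine's three codons, whose closed forms
  are also nonlinear); `nonlinear_codons()` exposes both lists.
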