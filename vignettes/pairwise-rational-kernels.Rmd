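---
title: "Pairwise rational kernels: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise rational kernels: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prkern)
```

## The inference problem

A metabolic pathway is a chain of reactions in which the product of one
reaction is a substrate of the next. Writing enzymes as nodes and joining
two enzymes whenever they catalyze successive reactions turns the pathway
map of an organism into an undirected graph; completing a partially known
map becomes supervised edge prediction on that graph. `prkern` treats each
known enzyme pair as a training point — label `+1` if the edge is present,
`-1` otherwise — and learns a pairwise support vector machine whose kernel
compares *pairs* of genes. Because the base similarity is computed from raw
nucleotide sequence, no gene annotation enters the model, and annotation
errors cannot propagate into the predicted network.

## Rational kernels and the n-gram base kernel

A weighted finite-state transducer over the real `(+, ×)` semiring assigns
to a pair of strings the sum, over all accepting paths with that
input/output labelling, of the product of the initial weight, the transition
weights and the final weight. A kernel realized by such a machine `U` is a
*rational kernel*; its value on `(x, y)` is computed mechanically as the
path sum of `M_x ∘ U ∘ M_y`, where the `M` are the trivial chain acceptors
of the two sequences.

The base kernel used throughout is the n-gram (spectrum) kernel
`k_n(x, y) = Σ_{|z|=n} c_x(z) c_y(z)`, realized by `U_n = T_n ∘ T_n⁻¹`,
where the counting transducer `T_n` has states `0..n`, skip self-loops
`(σ:ε)` at both ends and `(σ:σ)` advances in between, so that each
accepting path reads all of `x` and emits exactly one of its length-`n`
windows. The `T ∘ T⁻¹` form guarantees a positive definite symmetric
kernel, the condition the SVM dual requires.

Two implementation routes coexist and are tested against each other:

* a **count-vector route** — sparse n-gram count profiles and their dot
  product, linear in sequence length; this is what all large computations
  use;
* a **transducer route** — literal composition and path summation; this is
  the semantics, kept executable as the reference.

## The four pairwise constructions

Given base values `U(·, ·)`, the package implements the direct-sum, tensor
(Kronecker), metric-learning and Cartesian pairwise kernels exactly as
their defining formulas are written (see the README table). Notable
commitments:

* **Unordered pairs.** Edges are undirected, so a pair is canonicalized to
  lexicographic id order before any kernel evaluation; the kernel is then
  well defined without leaning on the formulas' built-in symmetrization.
* **Direct sum with both cross terms.** The direct-sum formula here
  includes `U(y₁,x₂)` and `U(x₁,y₂)`; it factors as
  `⟨φ(x₁)+φ(y₁), φ(x₂)+φ(y₂)⟩`, hence remains PSD.
* **Identity deltas compare identifiers.** In the Cartesian kernel,
  `δ(a=b)` compares gene ids, not sequences: two genes with identical
  sequence are still distinct entities.
* **Caching.** Base values are cached per unordered gene pair, so a
  pairwise Gram matrix over `m` pairs costs `O(m)` distinct base
  evaluations, not `O(m²)`.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `n` | 3 | n-gram length; 3 (codon-length words over `{A,C,G,T}`, a 64-dimensional profile) is the standard choice for nucleotide spectrum kernels |
| `alphabet` | `A,C,G,T` | windows containing any other symbol (e.g. `N`) are skipped with a warning rather than counted, so ambiguity codes never inflate similarity; input is uppercased first |
| `normalize` | `TRUE` | cosine normalization `K/√(K_xx K_yy)` with `0/0 := 0`, removing the advantage longer sequences gain simply by containing more n-grams |
| `center_base` | `TRUE` (study pipeline) | double-centering `K ← HKH` of the base Gram before the pairwise construction; see below |
| `C` | 1 | SVM box constraint; no grid search is performed |
| `k` | 10 | cross-validation folds, stratified by class |
| `level` | 0.95 | AUC confidence level |

### Why the base kernel is centered

Spectrum kernels of equal-length random sequences concentrate near a large
positive constant (any two 300-mers share many 3-grams), so the cosine-
normalized base Gram is "1 + small structure". The metric construction is
algebraically immune — its combination
`U(x₁,x₂) − U(x₁,y₂) − U(y₁,x₂) + U(y₁,y₂)` cancels any additive row/column
offset exactly — but the tensor and Cartesian constructions multiply base
values, inheriting an almost rank-one component that dominates the pairwise
Gram spectrum; a box-constrained SVM then saturates its coefficients and
underfits. Removing the embedded mean (`K ← HKH`, `H = I − 11'/n`) is the
standard kernel-methods remedy and is applied to the base Gram by default
in the study pipeline (`center_gram()`, CLI flag `--center-base`).
Precomputed external kernels supplied as matrices are taken as-is unless
the flag is set.

## Training set construction

All unordered node pairs of the known graph form the labelling universe;
`count_noninteracting()` gives the (always much larger) negative count.
Because the classes are severely unbalanced, training uses all positives
plus a *balanced* sample of negatives. The default sampler draws each
endpoint with probability proportional to its degree in the positive set,
rejecting edges, self-pairs and duplicates, so that the node-frequency
distribution of the negatives approximates that of the positives and the
classifier cannot score pairs by node popularity alone. A uniform sampler
is available as a fallback. The sampler takes the negative count as an
explicit parameter rather than fixing a parity convention.

## SVM, evaluation and comparison

`train_svm()` solves the soft-margin dual on the precomputed pairwise Gram
matrix with an interior-point quadratic program (`kernlab::ipop`), chosen
because spectrum-kernel Gram matrices are low-rank and sequential-minimal
solvers were observed to stall on such matrices; the interior-point route
satisfies the KKT conditions to well below the package's `1e-3` contract.
The offset `b` is recovered from interior support vectors (mean of
`d_i − f_i`), falling back to the midpoint of the feasible KKT interval
when every coefficient is at a bound. Exactly duplicated training pairs
make the dual Hessian singular; the solver escalates a proportional ridge
(`1e-8 → 1e-4` of the diagonal scale) until the factorization succeeds.
A query pair is classified interacting exactly when `f ≥ 0`; the tie at
zero goes to `+1`.

ROC AUC is computed by the Mann–Whitney rank formulation (ties count ½),
which equals the trapezoidal area under the empirical curve. Confidence
intervals use the Hanley–McNeil distribution-free variance, parameterized
by the AUC and the two class counts; the interface also accepts the
classification-error count so that error-based variance estimators can be
slotted in without an API change. Cross-validation is stratified and
seeded; the whole procedure is bit-reproducible given the seed. Paired
classifiers are compared by the signed McNemar statistic
`z = (N_fs − N_sf)/√(N_fs + N_sf)` — zero when the classifiers perform
alike, positive when the second classifier wins more discordant cases —
with a continuity-corrected variant behind a flag. The uncorrected, signed
form is used as the default because it is the only form consistent with
both of those conventions simultaneously.

## The synthetic benchmark

`generate_synthetic()` emulates the situation the pipeline assumes: a set
of genes, a partially known interaction graph and sequence-borne signal.
Genes are split into pathway modules (sizes as equal as possible, remainder
to the earliest modules); within-module pairs are edges; each module owns
private random 6-mer motifs inserted — replacing background characters, so
sequence length is invariant and normalization effects stay isolated —
into every member's i.i.d.-uniform background sequence at non-overlapping
positions. Defaults: 60 genes × 300 bp, 6 modules, 2 motifs × 3 copies.
A GC-bias parameter exists but defaults off. `motif_copies = 0` gives the
matched no-signal null: same graph, pure background.

What the generator does *not* emulate: codon structure, repeat families,
homology gradients, alignment-scale similarity, or realistic degree
distributions (planted modules are cliques). Passing the benchmark shows
that the kernels detect shared exact k-mer content against a uniform
background — the mechanism the method relies on — not that any particular
AUC will be reached on real genomes, where both the signal and the
negatives are harder.

Study sizes used by the test suite: 200 training pairs (100 positives, 100
degree-matched negatives) per seed, 10 seeds, 10-fold cross-validation;
these sizes give stable AUC means while keeping the whole suite
interactive. Under those conditions the tensor, metric and Cartesian
kernels reach mean AUC ≈ 0.9 and the direct-sum kernel stays near chance,
reproducing the expected qualitative ordering of this kernel family; the
null model calibrates to AUC ≈ 0.5.

## Numerical and degenerate-case choices

* **Epsilon filtering in composition.** Without a filter, paths in which
  both machines move on the shared tape with ε are counted once per
  interleaving, breaking `(T₁∘T₂)(x,y) = Σ_z T₁(x,z) T₂(z,y)`. The
  standard three-state filter is used, forcing "all left-machine ε moves,
  then all right-machine ε moves" between synchronized steps.
* **Acyclicity.** Path sums are exact, by topological forward
  accumulation after trimming states off initial→final paths; cyclic
  machines are rejected with a state on a cycle named, never approximated.
  All machines the pipeline evaluates (compositions with chain acceptors)
  are acyclic by construction.
* **Tolerances.** Gram symmetry and PSD checks use `1e-9` relative and
  `−1e-8·max eigenvalue` respectively; dual-route kernel agreement is
  asserted to `1e-9` relative; weights are never flushed to zero.
* **Degenerate inputs.** Empty strings are accepted by the one-state
  acceptor; machines with empty final support have path sum 0; sequences
  shorter than `n` have an empty profile and cosine value 0 against
  everything (0/0 := 0).

## Known limitations

* Exact path summation restricts the algebra to acyclic machines; kernels
  over cyclic automata (infinite weighted languages) are out of scope, as
  are gappy/mismatch kernels and transducer determinization/minimization.
* The external-evidence kernels (phylogenetic, domain content) enter only
  as precomputed matrices; their construction is not reproduced here.
* The interior-point solver is dense `O(m³)`; pairwise problems beyond a
  few thousand pairs would need a chunked or SMO-style solver.
* Degree-matched rejection sampling can stall on graphs whose positive-
  degree nodes form near-cliques (few eligible non-edges); the uniform
  mode covers that corner.
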