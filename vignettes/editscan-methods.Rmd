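---
title: "editscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{editscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`editscan` treats A-to-I editing-site prediction as supervised
classification of fixed-length DNA windows. The object being classified
is the *editing-sequence context*: the odd-length window centered on a
candidate adenine, read on the strand carrying that adenine (a
forward-strand `T` is a minus-strand candidate; its context is the
reverse complement of the forward window). The working assumption is the
one that makes the whole approach possible: whatever drives ADAR
targeting is at least partly encoded in the local DNA sequence, so
contexts of true editing sites are more similar to one another than to
background adenine contexts.

Similarity is a combined string distance

$$D(a,b) \;=\; w\,\frac{D_{edit}(a,b)}{L_1} \;+\;
  (1-w)\,\frac{D_{ham}(a,b)}{L_2},$$

with the Levenshtein term computed on the full $L_1$-mer and the Hamming
term on the centered inner $L_2$-mer. Each term is normalized by its own
window length, so $D \in [0,1]$ for equal-length inputs. The distance
feeds a Gaussian-type string kernel $K(a,b) = \exp(-\gamma D(a,b)^2)$ on
which two maximal-margin machines are trained: a binary soft-margin
classifier (positives vs sampled background) and a one-class
$\nu$-machine (positives only) used as a permissive pre-filter in genome
scans. The rationale for mixing the two distances: Hamming is the
conservative, substitution-only view appropriate when editing contexts
are positionally conserved; the edit distance tolerates small indel-like
register shifts between contexts and matters more when conservation is
weaker.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `flank` / `L1` | context half-width / full length (nt) | 20 / 41 | performance saturates around 41-mers; shorter contexts lose specificity |
| `L2` | inner Hamming window (nt) | 31 | Hamming term saturates at 31-mers; `L2 > L1` is rejected rather than guessed |
| `w` | edit-vs-Hamming weight, unitless in $[0,1]$ | 0.2 (0.5 for fly-like data) | chosen by cross-validated sweep; `sweep_w()` recombines cached component matrices so the sweep costs one distance pass |
| `gamma` | kernel width | 0.1 | the conventional default for this kernel family; with $D \le 1$ the kernel is deliberately flat |
| `C` | binary soft-margin cost | 1 | no published value exists; exposed, not guessed. On tiny separable samples the flat kernel needs larger `C` for a hard-margin-like fit (the test suite uses `C = 10` there) |
| `nu` | one-class training-rejection bound | 0.1 | small $\nu$ keeps nearly all true sites in stage 1 of the scan at the cost of false positives, which stage 2 absorbs |
| `rate` | background sampling probability per nucleotide per strand | 1e-4 | matches the density of known human editing events per sequenced base |
| `identity_threshold` | redundancy cutoff | 0.8 | a sequence is redundant when identity with a representative exceeds 0.8, on either orientation |
| `max_mismatch` | seed-scan substitution budget | 0 (≤ 3) | exact seeding for calling; up to 3 mismatches, no indels, for sensitivity surveys |

## Numerical choices

* **The kernel is indefinite.** $\exp(-\gamma D^2)$ over a Levenshtein
  mixture is not positive semi-definite; measured Gram matrices have
  most-negative eigenvalues around $-0.05$. The matrix is passed to the
  solver as-is — fidelity over kernel repair — and `kernel_matrix(...,
  check_psd = TRUE)` warns when a sampled submatrix is strongly
  indefinite (eigenvalue below $-10^{-6}$). SMO only requires the
  two-point subproblem curvature to be positive, which is safeguarded by
  a floor.
* **The solver** is an in-package SMO (C++) for both formulations:
  binary C-SVC and the Schölkopf one-class $\nu$-problem, with
  maximal-violating-pair selection and the standard $m(\alpha) -
  M(\alpha) < \varepsilon$ stopping rule ($\varepsilon = 10^{-3}$
  binary, $10^{-4}$ one-class). During development it was checked
  against an independent LIBSVM-derived implementation on shared
  precomputed kernels: binary decision values agreed to $2\times10^{-7}$,
  one-class to $6\times10^{-7}$ after accounting for the $\nu n$
  dual-scaling convention. Non-convergence is an error, never a silent
  approximation.
* **Ties at zero.** The decision label is $+1$ iff $f(x) > 0$; exactly
  zero is called $-1$ (non-editing), the conservative direction.
* **`N` handling.** `N` never matches anything, including another `N`,
  in Hamming and identity computations; extraction rejects windows with
  more than 20% `N`. Assembly gaps therefore cannot manufacture
  similarity.
* **Oversampling lives in training folds only.** Minority positives are
  duplicated cyclically (whole copies plus a seeded remainder without
  replacement) up to the training fold's negative count; held-out
  evaluation always uses original instances. Pooled metrics come from
  summed confusion counts; this reconstruction is what makes the
  published fly-scale accuracy arithmetic internally consistent.
* **Persistence.** Models are versioned JSON; coefficients are stored
  both as decimals (readable) and C99 hex floats (authoritative), so a
  load reproduces predictions bit-for-bit.
* **Comparisons with printed values** round half-up to 3 decimals, and
  tests allow ±0.0015 where counts must first be reconstructed from
  rounded sensitivities.

## Design choices where the design was open

* *Clustering semantics, not CD-HIT's heuristics.* Redundancy filtering
  is greedy in input order over equal-length sequences: join the first
  representative with identity (matches/length, best of the two
  orientations) strictly above threshold, else found a new cluster. This
  reproduces the threshold semantics of CD-HIT-EST/-EST-2D without its
  alignment shortcuts, and is idempotent by construction.
* *Background sampling* is one Bernoulli draw per position per strand at
  the stated rate, fully seeded. Whether the original negatives were
  drawn per strand or forward-only, and whether reselection was seeded,
  is unrecorded; both strands is the symmetric choice, and the seed is
  exposed so any draw is reproducible.
* *Seed-scan center rule.* A hit must be adenine-centered on its own
  strand (forward `A` for `+`, forward `T` for `-`); the mismatch budget
  applies to the flanks. Without this rule a "hit" need not be a
  candidate editing site at all. Overlapping hits at one
  `(chrom, pos, strand)` keep the lowest-mismatch seed, ties by seed
  order.
* *`L2 > L1` rejected.* Only the nested-window case is meaningful with a
  centered inner window; the unconstrained phrasing is treated as a
  degenerate corner, not a feature.
* *Coordinates.* Inputs and in-memory sites are 1-based (database
  style); BED output converts to 0-based half-open.

## The synthetic benchmark: what it is and is not

`make_benchmark()` emulates the *statistical shape* of the training
problem: an i.i.d. background genome; `n_sites` non-overlapping planted
contexts drawn from a single adenine-centered consensus with independent
per-position mutation probability `p` (center preserved; minus-strand
plants reverse-complemented onto the forward strand, probability ½ per
strand); negatives sampled exactly as the real pipeline samples them.
Defaults are desk-scale: 200 kb, 150 sites, `p = 0.05`, and a background
rate of 2e-3 — the rate is deliberately above the genome-scale 1e-4
default of `sample_negative_sites()` so that a 200 kb genome yields a
negative set of useful size with the same machinery; the generator's
*mechanism*, not its genome size, is what carries over.

What it does not emulate: real ADAR preference (which is not a single
consensus), Alu-driven repeat structure, chromatin or RNA secondary
structure, and the heterogeneity of curated site lists. Consequently a
green benchmark test establishes that the pipeline is *correct* (wiring,
coordinates, solver, metrics) and that it can learn a planted signal of
known strength — it does not certify the published real-data accuracies,
which require the original genomes and site lists. The signal-free
benchmark (`p = 0.75`, mutating to a random different base, which leaves
contexts indistinguishable from background) pins the other end: held-out
AUC must be chance.

## Known limitations

* The mismatch seed scanner is an early-exit linear scan — fine to tens
  of Mb on one CPU, not a substitute for an FM-index at whole-genome
  scale.
* Kernel matrices are dense; training is practical to a few thousand
  support candidates, matching the published training sizes but not
  beyond.
* One-class accuracy is intrinsically limited (no negative signal during
  training); it is a filter, not a caller.
* No probability calibration, no PSD kernel repair, no spectrum/mismatch
  kernels, no liftover or annotation of hits.
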