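---
title: "Profile-HMM protein identification and model validation for cryo-EM model building"
author: "densid authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-HMM protein identification and model validation for cryo-EM model building}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densid)
```

## The problem

Automated model builders for cryo-EM maps trace backbones and, for every
built residue, predict a probability distribution over the twenty amino
acids together with a confidence score. When the sample contains proteins
of unknown identity — a common situation for complexes purified from
endogenous sources — those per-residue probability vectors carry far more
information than a single best-guess sequence. `densid` turns them into
profile hidden Markov models (HMMs), searches the profiles against a
proteome to identify which protein each chain is, applies the standard
post-processing rules of automated builders (mutation of matched
residues, chain connection, pruning, a backbone-confidence score stored
in the B-factor column), and evaluates built models against references
with the field's metric suite (C$\alpha$/backbone RMSD, recall,
precision, amino-acid accuracy, completeness, Q-score, FSC).

## From probability profiles to profile HMMs

A `ResidueProfile` holds, for one chain of $L$ residues, an $L \times 20$
matrix $P$ with $P_{ia}$ the predicted probability that residue $i$ has
amino-acid identity $a$, plus a confidence $c(i) \in [0,1]$ per residue.
`buildProfile()` maps this onto a profile HMM with one match state per
residue:

* **Match emissions** are the predicted probability rows themselves.
* **Insert emissions** are the background distribution (uniform by
  default, a Swiss-Prot-like composition via
  `aaComposition("swissprot")`). The predictions say nothing about
  residues that were *not* built, so the background is the only
  defensible choice.
* **Transitions** come from the confidence, with a decay constant $d$
  and a floor $m_{\min}$ (both 0.5 by default):
  $P_{M\to M}(i) = \max(c(i) - d,\ m_{\min})$,
  $P_{M\to I} = P_{M\to D} = (1 - P_{M\to M})/2$,
  $P_{I\to M} = P_{D\to M} = 1 - d$,
  $P_{I\to I} = P_{D\to D} = d$, and
  $P_{I\to D} = P_{D\to I} = 0$.

Note an algebraic quirk of the defaults: for $c \in [0,1]$ and
$d = m_{\min} = 0.5$, $\max(c - 0.5, 0.5)$ is identically $0.5$, so the
match-to-match probability does not actually depend on the confidence.
We implement the formula literally and expose both constants; lowering
`d` or `mmin` restores confidence dependence
(`buildTransitions(0.9, d = 0.2, mmin = 0)` gives $P_{M\to M} = 0.7$).

Profiles serialize to the HMMER3/f text format (`writeHMMER3()`), with
scores stored as negative natural logs, zero probability as `*`.
Two boundary conventions are imposed by the format: the begin-state line
reuses the node-1 transitions, and the end state is reached from the last
match state with probability one. Files are accepted by stock HMMER3
tooling (`hmmsearch` runs on them directly; a test verifies this), so
users can hand the profiles to an external HMMER installation if they
prefer its calibrated E-values. The nominal `STATS` lines we write make
external HMMER's E-values advisory, not reproduced by this package.

## Search engine

`forwardScore()`/`viterbiAlign()` implement local profile alignment in
log-odds space: a path enters any match node at any target position with
entry probability $1/L$, runs through the core match/insert/delete states,
exits freely from any match state, and flanking target residues are
emitted by the background (their contribution cancels in the odds ratio).
Scores are $\log_2$ odds against the background null. The local model was
chosen because identified chains are routinely partial — a fragment of a
few dozen residues must still find its parent protein. Viterbi ties are
broken by state priority M > D > I for reproducibility; `X` in a target
emits the background in every state; probability zero is a $-\infty$
sentinel throughout. The dynamic programming kernels are compiled (Rcpp);
an exhaustive path-enumeration oracle in plain R pins them down on all
profiles with $L \le 3$ and sequences up to length 4.

E-values come from `calibrate()`: Forward scores of $n$ i.i.d.
background sequences are fitted with a Gumbel law by maximum likelihood,
and `searchDb()` reports $E = N \cdot P(S > s)$ for a database of $N$
sequences. Forward scores are not exactly Gumbel (the classical theory
applies to optimal-alignment scores), so the far tail of the fit is
approximate — tests hold the survival function to binomial error in the
bulk and to a small factor at the 2% tail. Ranking is unaffected: within
one search, E-values are monotone in the bit score. `aggregateHits()`
implements the cross-referencing trick for pseudo-symmetric complexes:
chains are grouped by their best-hit target and bit scores summed, so
several individually unconvincing hits that agree on the same protein
rise to the top together.

## Post-processing

`buildResidueGraph()` connects each residue to its 20 nearest neighbours
by anchor-atom distance (C$\alpha$ for protein, P for nucleotides) —
the neighbourhood structure used by graph-based builders. Ties break
toward the lower residue index; systems with $n \le k$ residues get
$n - 1$ neighbours.

`assignAndMutate()` takes each chain's best hit and mutates the residues
aligned to match states to the target sequence's letter, recording the
matched position. Unmatched residues keep the argmax identity of their
profile; `unmatchedAsUnk = TRUE` gives the conservative poly-UNK
behaviour instead. `connectChains()` merges chains assigned to the same
target when their matched ranges are in order (gap $g \ge 0$) and the
gap-end anchors are within $d_{\max}(g+1)$, with $d_{\max} = 3.8$ Å —
the C$\alpha$ virtual bond length, so a gap of $g$ unbuilt residues may
span at most $g + 1$ peptide bonds. Merging is greedy by ascending gap
then distance, a deterministic order the underlying rule does not
prescribe. `pruneChains()` then removes chains shorter than 4 residues;
pruning runs *after* connection so connectable short fragments survive.
`rmsdToScore()` maps a predicted backbone RMSD to the $[0,1]$ confidence
written to the B-factor column: 0.5 Å $\to$ 1, 1.2 Å $\to$ 0, linear in
between, clamped outside (the linear range saturates).

## Metrics

`matchResidues()` pairs predicted and reference residues one-to-one by
mutual nearest neighbour under a 3 Å anchor-atom cutoff; the cutoff is
the published criterion, the mutual-NN assignment is our choice of
scheme. No superposition is applied anywhere — both models live in the
map's coordinate frame. From a correspondence, `rmsdMetrics()` pools
per-atom distances (C$\alpha$; backbone CA, C, O, N; nucleotide backbone
OP1, P, OP2, O5') and `classificationMetrics()` computes recall
(paired / reference), precision (paired / predicted), identity accuracy
(correct / paired) and completeness (paired *and* correct / reference),
so completeness $\le$ recall by construction.

`qscore()` measures atom resolvability: map values are interpolated
(trilinear) at deterministic Fibonacci points on concentric shells
(radii 0–2 Å, 0.1 Å spacing, 8 points per shell) around each atom,
points closer to another atom are excluded, and the Pearson correlation
against a reference Gaussian ($\sigma = 0.6$ Å) is reported per atom,
per residue, and for the model. The numeric defaults follow the
original Q-score method and are exposed as parameters. Pearson
correlation makes the score invariant to affine map rescaling.
`fsc()` computes the Fourier shell correlation between two maps on an
identical grid and the 0.5-crossing frequency. Model-to-map FSC uses
`renderMap()` (Gaussian atoms), an admitted simplification of
scattering-factor rendering.

## Synthetic data: what it does and does not emulate

The generators make the whole pipeline testable without downloads:

* `genStructure()` builds ideal $\alpha$-helical backbones (rise 1.5 Å,
  100° twist, radius 2.3 Å), giving the canonical ~3.8 Å C$\alpha$
  spacing so graph degrees and the chain-connection distance rule behave
  realistically. Chains sit on a 14 Å lattice to avoid clashes.
* `genProfile()` emulates builder output with a single interpretable
  knob: $P_i = (1-\eta)\,\mathrm{onehot}(s_i) + \eta/20$. $\eta = 0$ is
  perfect, $\eta = 1$ uninformative. Confidences are Uniform(0.5, 1) by
  default — the true distribution of a trained network's confidence is
  unknown, and this is a declared placeholder.
* `genProteome()` embeds each true sequence in a random host (Poisson
  padding, mean 40 residues per side) among i.i.d. decoys with lengths
  50 + Poisson(250), a realistic protein-length spread.
* `renderMap()`/`perturbModel()` provide maps and known-error models for
  the metric suite.

All generators are pure functions of their seed. What passing tests show
is that the machinery is correct under this noise model; real residue
probability vectors are correlated along the chain, confidence correlates
with local resolution, and real maps have coloured noise and B-factor
gradients — none of which the mixture model reproduces. Identification
performance on real data therefore cannot be read off these tests.

## Numerical choices and problem sizes

Probability-table rows are renormalized when within $10^{-3}$ of 1 and
rejected otherwise; profile row sums are held to $10^{-9}$ after
construction; HMMER3 round-trips are exact to $10^{-5}$ (five decimals
of the negative-log scores). The identification benchmarks in the test
suite use a 200-residue query against 100 decoys over 100 seeded trials
(and a 33-residue fragment of a 400-residue target at $\eta = 0.3$),
with per-profile calibration at $n = 100$ sequences of length 150 —
sizes chosen to make the statistics sharp while the whole suite stays
desk-scale. Calibration requires $n \ge 100$ and refuses degenerate
(zero-variance) score distributions.

The pipeline configuration is a plain R list (`pipelineConfig()`); the
command-line wrapper reads YAML config files with flags taking
precedence, and every stage seed is derived from the single top-level
seed.

## Known limitations

* Single-domain (unihit) local alignment only: no multi-segment model,
  no biased-composition correction, no domain envelopes.
* E-values from the internal Gumbel calibration are approximate in the
  far tail; published E-values from externally calibrated HMMER on real
  proteomes are not reproduced by design.
* Nucleotide chains are carried through models and metrics (P-anchored),
  but profile construction and identification are protein-only.
* No ligands, altlocs, insertion codes, or anisotropic B handling in the
  coordinate I/O; mmCIF support covers the polymer `atom_site` loop.
* `fsc()` against a model uses Gaussian-atom rendering, not scattering
  factors; absolute model-to-map FSC values should be read accordingly.
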