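---
title: "Methods: scoring substitution models of antibody affinity maturation"
author: "shmbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring substitution models of antibody affinity maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmbench)
```

## The problem

B-cell receptors (BCRs) evolve inside germinal centers by somatic
hypermutation (SHM) — a strongly context-biased nucleotide mutation
process — followed by selection for antigen binding. Reconstructed B-cell
lineages decompose this history into *parent-child pairs* (PCPs): aligned
nucleotide sequences connected by one branch of the lineage tree. A model
of affinity maturation, whatever its internal representation, can be asked
a concrete question about each pair: *at which codon sites will the amino
acid change, and to what?*

`shmbench` standardizes that question. Every model is reduced to a common
currency — a probability distribution over the 20 amino acids at every
codon site of the parent, at a branch length fitted to the pair — and
scored with four dataset-level metrics. Three model families are
supported:

* **NT framework** — nucleotide-context SHM models reporting a per-site
  rate $\lambda_i$ and conditional target-base probabilities
  $(p_{i,a}, p_{i,c}, p_{i,g}, p_{i,t})$ (k-mer mutability tables;
  per-site rate tables measured against a fixed naive sequence).
* **NT-AA framework** — the same, combined with per-amino-acid selection
  factors derived from a substitution matrix (e.g. BLOSUM62) or a deep
  mutational scan (DMS).
* **AA framework** — per-site amino-acid probability tables, e.g. softmaxed
  logits of a masked protein language model, scaled onto the branch.

## From rates to amino-acid probabilities

Each nucleotide site is modeled with an exponential waiting time until
mutation: over branch length $\tau$ the site stays unchanged with
probability $e^{-\lambda_i \tau}$ and mutates to base $x$ with probability

$$P_{i,x}(\tau) = (1 - e^{-\lambda_i \tau})\, p_{i,x}.$$

The conditional probabilities are conditioned on a mutation occurring, so
the wildtype entry is zero — unlike the rows of a CTMC rate matrix. A
codon outcome $x_0x_1x_2$ has probability equal to the product of its
three per-position terms (stay where the base matches the parent, $P$
where it differs). This is a *single-hit* approximation — no multiple
mutations per site along the branch — which is accurate in the regime
BCR lineages occupy, where branches carry far less than one expected
mutation per site.

Because evaluation data exclude stop codons, stop outcomes are removed
and the 61 sense outcomes renormalized at each codon site (conditioning
on a non-stop outcome). Each amino acid then collects the probability of
its codons; the wildtype amino acid additionally holds the no-change
term. This conditioning is applied *before* selection factors (below), so
a selection profile of all ones reproduces the neutral distribution
exactly — a property the test suite asserts to $10^{-12}$.

### Selection factors

A selection model supplies a preference ratio $R_{r,X}$ of candidate
amino acid $X$ over the parent at site $r$:

* substitution matrix: $R = 2^{M_{X',X}/2}$ (the half undoes the fixed
  scaling built into BLOSUM log-odds);
* DMS: $R = K_D^{parent}/K_D^{child} = 10^{\,b_{child} - b_{parent}}$
  with $b = -\log_{10} K_D$ the measured binding strength.

Raw ratios can be enormous, so they are passed through the bounded
transform

$$F = \frac{2}{1 + 1/R},$$

which fixes $F(1) = 1$, increases monotonically, and approaches 0 and 2
in the limits. Every non-wildtype codon outcome probability is multiplied
by the $F$ of its amino acid; in the rare case that a single product
exceeds one it is clamped at one, and if the non-wildtype mass exceeds
one it is renormalized to one with the no-change probability set to zero
(clamp first, then test the sum). Both event types are counted and
reported, never silent. Note that for a symmetric log-odds matrix the
ratios satisfy $R(X \to X') = R(X' \to X)$ — preferences derived from a
symmetric matrix are direction-free.

### Amino-acid-level models

Per-site logits are softmaxed over the 20 standard amino acids and scaled
onto the branch with the mutability of a unit-rate exponential clock:

$$P_{r,X}(\tau) = \begin{cases}
e^{-\tau} + (1 - e^{-\tau}) P_{r,X} & X \text{ wildtype},\\
(1 - e^{-\tau}) P_{r,X} & \text{otherwise}.
\end{cases}$$

Scaling changes calibration (and hence overlap and perplexity) but not
the within-site ranking of non-wildtype amino acids, so rank-based
metrics are invariant to it. Whether the logits came from a
masked-marginals or wt-marginals pass is carried as metadata; the engine
treats both identically. The package does not embed any language model:
it consumes precomputed per-pair logit tables, keeping the artifact
self-contained while real model adapters can sit behind the same file
contract.

## Branch-length fitting

The branch length is a per-pair, per-model nuisance parameter: it is
fitted by maximizing the framework's likelihood of the child —
nucleotide-wise for NT (stay terms where the child matches, $P_{i,x}$
where it differs), codon-wise under the selection-modified outcome
distribution for NT-AA, residue-wise under the scaled probabilities for
AA. Codons containing `n` in either sequence are skipped everywhere;
sequencing pipelines pad missing 5' reads with `n`, and evaluation is
restricted to unambiguous sequence.

Numerically, the search maximizes over $\log \tau$ on
$[10^{-9}, 10]$ with `stats::optimize` at tolerance $10^{-8}$ —
deterministic, derivative-free, and robust for these smooth unimodal
profiles. The initialization is the pair's normalized nucleotide mutation
frequency; it also serves as a fallback so the fitted log-likelihood is
never below the log-likelihood at the initialization. Under uniform rates
the maximizer has the closed form $\hat\tau = -\ln(1 - m/n)/\lambda$ for
$m$ of $n$ sites mutated; the optimizer reproduces it to relative error
$10^{-5}$ across a grid (asserted in the tests). Observed outcomes with
zero model probability are floored at $10^{-12}$ in log-likelihoods (with
a warning outside optimization loops) so the search remains finite.

Rate tables are consumed as given, with no normalization to the $\tau$
time scale: the branch-length fit absorbs any overall rate scale, which
is also why fitted $\tau$ values are comparable within, not across,
models.

## Metrics

Let SSP$_r = 1 - P_{r,wt}$ be the *site substitution probability* and
CSP$_{r,X'} = P_{r,X'}/(1 - P_{r,wt})$ the *conditional substitution
probability* (the outcome distribution given that a substitution
occurred; undefined where SSP $= 0$, and such sites are excluded with a
warning).

* **Overlap** — observed substitution counts per IMGT position are
  compared with expected counts (summed SSPs) via
  $\sum_i \min(O_i, E_i) \big/ \sum_i (O_i + E_i)/2$: 1 for identical
  distributions, 0 for disjoint ones.
* **R-precision** — for a pair with $k$ observed substitutions, the
  fraction of observed sites among the top-$k$ SSP sites, averaged over
  pairs. Ties at the $k$-th rank are resolved by seeded uniform random
  choice among the tied sites; sites strictly above the boundary are
  always included.
* **Substitution accuracy** — the fraction of substitution events whose
  outcome attains the maximal CSP at its site, all events weighted
  equally; argmax ties are broken by the same seeded stream.
* **CSP perplexity** — the geometric mean inverse CSP of observed
  outcomes, $(\prod_i 1/p_i)^{1/N}$, computed in log space; 1 is perfect,
  a uniform CSP over 19 alternatives scores 19. Zero-probability events
  are floored at $10^{-10}$ and flagged.

All four are reported overall, restricted to each FWR/CDR region (IMGT
ranges FWR1 1–26 through FWR4 118–128; positions are string labels so
insertion codes like `111.1` resolve by their integer part), stratified
by substitutions per pair, and — for calibration — as observed versus
expected counts per SSP bin. Empty slices are reported as missing rather
than zero. Percentile ranks of named (e.g. conserved) sites use the
strictly-smaller-count fraction with a midpoint adjustment for ties.

All stochastic tie-breaking flows from a single dataset-level seed
recorded in the report, so reruns are exact.

## The synthetic generator

The generator exists so that every engine and metric is testable with
known ground truth and no external data. Its defaults are fixed study
conditions, chosen once:

* generating model: a 3-mer context model with per-k-mer rates drawn
  lognormal (sdlog 1, scaled to mean 1) — roughly the tenfold
  hot/coldspot dynamic range of SHM mutability — and Dirichlet(1,1,1)
  conditional probabilities over the three non-wildtype bases;
* parents: uniform over sense codons, 300 nt;
* branch lengths: log-uniform on $[0.01, 0.3]$, spanning sparse (about
  one mutation per pair) to heavily mutated (tens of mutations) branches
  while staying below the 30% divergence filter.

Children are sampled per codon from the *same* codon outcome distribution
the likelihood engine computes — not from a per-nucleotide Gillespie
process — so the generating model is exactly the model under which the
data are distributed. This model-consistency makes parameter-recovery
tests sharp: with 500 pairs the fitted branch lengths correlate with
truth at Spearman $\rho > 0.8$ (the acceptance suite requires this, and
the observed values are well above), the generating model beats a
rate-permuted null on likelihood and CSP perplexity, and binned
observed-versus-expected SSP counts pass a chi-square calibration check.
A per-nucleotide simulator allowing multi-hits would instead quantify the
single-hit approximation's error; that is a documented extension, not a
default.

Two conditioning details matter for tests. First, emitted pairs are by
default resampled until they carry at least one amino-acid substitution
and pass the divergence filter — mirroring data preparation — which
inflates observed counts relative to expected; the truth record stores
resample counts, and calibration tests generate *unconditioned* data.
Second, per-pair RNG streams are split off the master seed by counter, so
growing a dataset never reshuffles earlier pairs.

What the generator does **not** emulate: real clonal-family structure
(shared parents, tree topology), V(D)J germline composition, indels,
sequencing error, context widths beyond 3-mers, and real selection
landscapes. Passing tests therefore demonstrate correctness of the
machinery and recoverability under the stated process, not performance
claims about biological repertoires.

## Design choices that were genuinely open

* **Stop-codon mass.** The formulation is ambiguous between folding stop
  mass into the wildtype term and renormalizing over sense outcomes;
  renormalization was chosen because the outcome probabilities are stated
  to form a distribution on codons, and because it makes the neutral and
  selection paths consistent.
* **Naive-parent pairs.** Repertoire pipelines sometimes exclude pairs
  whose parent is the inferred naive sequence (germline-inference error),
  while controlled single-lineage experiments analyze them. The package
  takes no side: filtering is rule-based and any such exclusion is the
  caller's upstream decision.
* **Window filter placement.** The 10-mutations-in-20-sites filter is
  defined against the inferred naive sequence, which is upstream
  information; it is exposed as an optional pre-filter against a supplied
  reference (default off) rather than silently applied.
* **Per-site models on mutated parents.** Naive-coordinate models keep
  their conditional zeros at the naive base. Mass assigned to the current
  parent base is folded into the stay probability, keeping the per-site
  distribution normalized without re-estimating the table.
* **R-precision ties.** Randomization applies only to sites tied exactly
  at the $k$-th rank boundary; strictly higher sites are always selected.

## Problem sizes

The shipped tests run the oracle-equivalence check on 1,000 random codon
draws, the closed-form branch-length grid, a 10,000-draw Monte-Carlo
check of the tie-breaking rule, and a recovery study of 20 replicate
datasets of 500 pairs x 300 nt; the acceptance script evaluates one
500-pair dataset per seed. These sizes give comfortable statistical
resolution for every asserted property while keeping a full run in the
minutes range on one CPU.

## Known limitations

* The single-hit approximation ignores multiple mutations per site per
  branch; fitted $\hat\tau$ compensates but the distribution shape at
  long branches is approximate.
* Selection factors act multiplicatively per amino acid and cannot
  express epistasis within a codon or across sites.
* The AA framework's unit-rate clock makes $\tau$ comparable only within
  a model.
* Metrics treat pairs as independent; branches of one lineage share
  history, so dataset-level uncertainties are optimistic if lineages are
  large.
* No statistical test between models is provided; reports are
  descriptive.
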