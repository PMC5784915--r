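---
title: "Google matrix and reduced Google matrix analysis of directed regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Google matrix and reduced Google matrix analysis of directed regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmatrix)
```

## The model

A directed biological network — a signaling network, a transcriptional
regulatory network, or their merge — is summarized by its 0/1 adjacency
$A_{ij}$, equal to 1 when node $j$ points to node $i$.  The Markov
transition matrix divides each column by the out-degree,
$S_{ij} = A_{ij}/k_{out}(j)$, and replaces the column of a *dangling* node
(no outgoing links) by the uniform column $1/N$.  The Google matrix

$$G = \alpha S + (1 - \alpha)\,\tfrac{1}{N}\mathbf{1}\mathbf{1}^T$$

describes a random surfer that follows links with probability $\alpha$ and
teleports uniformly otherwise.  Its stationary state is the PageRank vector
$P$ ($GP = P$), high for nodes accumulating many or important incoming
regulations; the PageRank of the edge-reversed network is the CheiRank
$P^*$, high for strong regulators.  Nodes are indexed by $K$ (descending
$P$) and $K^*$ (descending $P^*$); the 2DRank $K_2$ orders nodes by the
first square of growing side in the $(K, K^*)$ plane that covers their
cell.  The complex spectrum of $G$ refines this picture: apart from the
unit eigenvalue, every eigenvalue of $G$ is $\alpha$ times an eigenvalue of
$S$, and the inverse participation ratio
$\xi = (\sum_n |\psi_n|^2)^2 / \sum_n |\psi_n|^4$ measures how many nodes
support an eigenvector (1 = localized, $N$ = uniform).  One printed form of
this ratio in the literature omits the outer square, which is dimensionally
inconsistent with the stated range $1 \ldots N$; this package uses the
standard support-size definition above.

## The reduced Google matrix

For a subset of $N_r$ nodes (a pathway, a signature) embedded in the
network, write $G$ in block form with "r" the subset and "s" the
complementary *scattering* network of $N_s = N - N_r$ nodes.  Eliminating
the scattering block from $GP = P$ gives the exact effective matrix

$$G_R = G_{rr} + G_{rs}\,(1 - G_{ss})^{-1} G_{sr},$$

an $N_r \times N_r$ column-stochastic matrix whose fixed point is the
global PageRank restricted to the subset (up to normalization).  Expanding
the resolvent around the leading eigenpair of $G_{ss}$
($G_{ss}\psi_R = \lambda_c \psi_R$, normalized $E_s^T\psi_R = 1$,
$\psi_L^T\psi_R = 1$) yields three components:

$$G_R = G_{rr} + G_{pr} + G_{qr}, \qquad
  G_{pr} = \frac{G_{rs}\,\psi_R \psi_L^T\, G_{sr}}{1 - \lambda_c}, \qquad
  G_{qr} = G_{rs}\Big[Q_c \sum_{l \ge 0} \bar G_{ss}^{\,l}\Big] G_{sr},$$

with $Q_c = 1 - \psi_R\psi_L^T$ and $\bar G_{ss} = Q_c G_{ss} Q_c$.
$G_{rr}$ carries the direct links among subset members; $G_{pr}$ is an
exactly rank-one background set by the subset's global PageRank context and
usually dominates the column sums; $G_{qr}$ is the interesting part — it
accumulates all *indirect* paths through the scattering network.  Its
off-diagonal entries $G_{qrnd}$ score hidden causal relations between
distinct subset members; the diagonal $G_{qrd}$ is the probability of
leaving and returning to the same node and is never reported as an
interaction.  Component strengths are summarized by weights
$W_{rr} + W_{pr} + W_{qr} = 1$ (entry sums divided by $N_r$).

Deflating the leading eigenvalue is what makes the series practical: the
eigenvalues of $\bar G_{ss}$ sit roughly below $\alpha$, so the increments
decay geometrically and a few hundred terms suffice, while the plain
Neumann series in $G_{ss}$ converges at rate $\lambda_c$, which approaches
1 for subsets carrying little PageRank mass ($1 - \lambda_c \approx
\Sigma_P$, the PageRank probability on the subset).  Because of $Q_c$ some
$G_{qr}$ entries can come out slightly negative; they are retained
verbatim and their total weight is reported (`negative_weight`), not
clipped.

## Numerical choices

* **Damping factor** `alpha = 0.85` everywhere, the conventional value for
  directed-network centrality; configurable in every entry point.
* **Power iterations** start from the uniform vector and stop at an L1
  residual below `1e-12` (cap 10 000 iterations).  This is far tighter than
  needed for the probabilities themselves; it is chosen so integer rank
  indexes are reproducible.
* **Rank ties** are broken by ascending node label, making every rank
  index, and everything downstream of it, deterministic.
* **2DRank sweep order** inside the square of side $s$: the new right
  column ($K = s$) top-to-bottom, then the new bottom row ($K^* = s$)
  left-to-right.  The original definition delegates this micro-order to a
  reference that leaves tie cases open; the convention is fixed here so
  that implementation and test oracle agree.
* **Series truncation** at L1 increment below `1e-12`, cap 10 000 terms.
  $1 - \lambda_c$ is taken from $\|G_{rs}\psi_R\|_1$ — exact by column
  stochasticity and free of the cancellation that hits $1 - \lambda_c$
  computed directly when $\lambda_c \to 1$.
* **Matrix-free blocks.**  All four blocks of $G$ include the teleportation
  term and the dangling correction; they are applied as sparse slice +
  rank-one uniform terms.  Dense matrices are formed only for $N_r$-sized
  results, for the dense-inverse oracle (`direct_oracle`, capped at
  $N \le 2000$), and for small-N eigendecompositions (`dense_cutoff = 300`
  in `leading_spectrum`, above which the Arnoldi iteration is used).
* **Degenerate subset = whole network** returns $G_R = G$ with
  $G_{pr} = G_{qr} = 0$ and weights $(1, 0, 0)$ — a convenient identity
  case rather than an error.
* **Eigenvector phases** in the spectrum are fixed by making the
  largest-modulus component real positive.

## Two-condition comparison

Given "condition A" and "condition B" networks (e.g. the same signaling
layer merged with two cell-line-specific transcriptional layers),
`compare_ranks()` reports per-node $\log_{10}(K_B/K_A)$ and
$\log_{10}(K^*_B/K^*_A)$ with per-axis standard deviations and the nodes
beyond $\pm 1\sigma$ and $\pm 2\sigma$ (both tails; the $2\sigma$ rule for
the primary selections, the $1\sigma$ rule for filtered follow-up analyses
that need more members).  `infer_hidden()` thresholds $G_{qrnd}$ (default
0.01, strictly greater-than) and classifies pairs as `common`,
`emergent_in_b` or `disappearing_in_b`.  Counts are reported for ordered
off-diagonal pairs — a documented convention, since an unordered or
diagonal-inclusive count would differ.  `connectivity_summary()` uses weak
(direction-ignoring) connectivity for component membership, and
`short_paths()` explains a hidden link by the shortest directed paths and
all simple paths one step longer ("second shortest": the lengths attained
once an edge of a shortest path is removed; the two definitions coincide on
the fixtures used here and the path-length form is deterministic).

## What the synthetic generators emulate — and what they do not

`random_network()` draws per-node out-degrees geometrically around a mean
of 2.7 links/node (the density scale of curated human signaling networks:
a few thousand nodes, a few thousand links), places a small number of
fan-like hubs at ten times the mean out-degree (transcription-factor-like
fans), and makes a fraction of nodes dangling.  The default dangling
fraction of 0.15 reflects that curated signaling networks end in many
terminal effectors without outgoing regulation.  `planted_relay()` adds a
directed chain through exclusive external nodes between two subset members
with no direct edge — a ground-truth hidden link.  `two_condition_pair()`
keeps the signaling layer bit-identical and rewires a chosen fraction of
transcriptional-layer targets.

These generators reproduce the *structural* features the method relies on
(sparsity, hubs, dangling nodes, relay paths, layered rewiring), so green
tests demonstrate the correctness of the linear algebra and of the
inference conventions.  They do not reproduce the correlated, curated
wiring of real pathway subsets: real subsets of interest have dense
internal connectivity and sit high in the global PageRank, which pushes
$W_{rr}$ and $W_{qr}$ up and keeps the negative weight of $G_{qr}$ tiny
(order $10^{-3}$).  A uniformly sampled synthetic subset captures little
PageRank mass, so its $W_{qr}$ can be near zero or slightly negative and
the negative-weight metric larger than on curated pathways.  Passing tests
therefore validate the machinery, not any biological claim about a
particular network.

Problem sizes used by the test-suite and the acceptance script — fixture
sweeps at $n \in [10, 100]$ with $N_r \le 10$ against the dense-inverse
oracle, and one signaling-scale run at $n = 2432$, mean out-degree 2.7,
$N_r = 63$ — were chosen to mirror the regimes the method targets while
keeping every check exact (dense oracles are feasible through
$N \le 2000$).

## Worked example

```{r example}
pl <- planted_relay(n_background = 60, subset_size = 6, relay_length = 1,
                    seed = 77)
model <- build_transition(pl$network)          # alpha = 0.85
rgm <- compute_reduced(model, pl$gene_set$labels)
glance(rgm)

hid <- infer_hidden(rgm, threshold = 0.01, top_k = 5)
hid

# the planted pair is recovered
pl$pair
```

The local ranking inside the subset follows the global PageRank order:

```{r local}
local_pagerank_ranks(rgm)
```

## Known limitations

* Dense $N_r \times N_r$ results assume a modest subset size (tens of
  nodes); the scattering side stays sparse/matrix-free, but no low-rank or
  out-of-core acceleration is provided for networks beyond roughly $10^6$
  nodes.
* Interaction signs (activation/inhibition) are metadata only; propagation
  is unsigned, as in the underlying random-surfer model.
* Label matching between gene sets and networks is exact and
  case-sensitive — identifier harmonization has to happen upstream.
* The hidden-link threshold (default 0.01) is a reporting convention, not a
  significance level; no null distribution is attached to $G_{qrnd}$
  scores.
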