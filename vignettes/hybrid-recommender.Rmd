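---
title: "A hybrid neighbor/graph recommender for microbe-disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid neighbor/graph recommender for microbe-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the data model

Clinically curated microbe–disease association catalogs are sparse binary
tables: a few hundred literature-confirmed (disease, microbe) pairs over a
few dozen diseases and a few hundred microbes. The prediction task is a
recommender problem — rank the unobserved cells of the disease-by-microbe
adjacency matrix $A \in \{0,1\}^{n_d \times n_m}$ so that genuinely
associated pairs rise to the top — under the working assumption that
functionally similar microbes take part in similar diseases, the biological
analogue of "similar users like similar items".

`mdhybrid` scores every cell with the unweighted average of two single
recommenders computed from the same similarity inputs:

$$S = \tfrac12 (NS + GS)$$

where $NS$ is a neighbor-based collaborative-filtering score and $GS$ a
two-step similarity-weighted diffusion score on the bipartite association
graph.

## Similarities

Both axes get a Gaussian interaction-profile kernel. For diseases,

$$DS_{G}(i,j) = \exp\!\left(-\gamma_d \lVert A_{i,*} - A_{j,*}\rVert^2\right),
\qquad
\gamma_d = \gamma_d' \Big/ \tfrac{1}{n_d}\sum_k \lVert A_{k,*}\rVert^2,$$

with $\gamma_d' = 0.5$ by default, and the mirror construction over columns
for microbes ($\gamma_m' = 0.5$). The bandwidth normalization makes the
kernel invariant to a uniform rescaling of the profiles only if the
normalized rate multiplies the squared distance; a variant that divides the
squared distance by $\gamma$ instead is available through
`kernel_params(exponent_convention = "as_printed_division")`, because the
two typeset conventions circulate in the link-prediction literature and
they differ materially (the division form collapses to a near-delta kernel
on sparse data). The product form is the default; the choice is exposed
rather than silently fixed, and the package makes no claim about which one
any particular historical implementation used.

When a symptom-based disease similarity is available (an external,
precomputed matrix; the package consumes it as a CSV aligned by identifier,
see `load_similarity()`), the disease similarity used everywhere downstream
is the plain average $DS = (DS_{G} + DS_{sym})/2$. The ablation
`model = "neighbor_no_symptom"` uses $DS_G$ unchanged rather than averaging
with a zero matrix: the ablation is meant to remove the information, and
averaging with zeros would merely halve the kernel uniformly — a rescaling
the fixed-denominator CF sum would not absorb.

## The two single models

**Neighbor CF.** User-based and item-based scores with constant
denominators,

$$S_{dis}(d_i, m_j) = \frac{1}{n_d}\sum_k DS(d_i,d_k)\, A_{kj}, \qquad
S_{mic}(d_i, m_j) = \frac{1}{n_m}\sum_k MS(m_j,m_k)\, A_{ik},$$

averaged into $NS$. The denominators are deliberately the axis sizes, not
the similarity sums of the more common weighted-mean CF; a weighted-mean
variant is out of scope. There is no top-$k$ neighbor truncation — the sums
run over all diseases and microbes.

**Graph diffusion.** Two similarity-weighted adjacencies are formed,
$A_d = DS \cdot A$ and $A_m = A \cdot MS$. In step one every microbe column
distributes mass to disease nodes, normalized by the column sums of the
weighted adjacencies; in step two the accumulated disease weights return to
microbe nodes, normalized by the row sums:

$$s(d_i) = \alpha \sum_j \frac{A_m(i,j)\,A_{*,j}}{\sum_t A_m(t,j)}
         + (1-\alpha) \sum_j \frac{A_d(i,j)\,A_{*,j}}{\sum_t A_d(t,j)},$$

$$s'(m_j) = \beta \sum_k \frac{A_m(k,j)\, s(d_k)}{\sum_t A_m(k,t)}
          + (1-\beta) \sum_k \frac{A_d(k,j)\, s(d_k)}{\sum_t A_d(k,t)},$$

with $GS = [\,s'(m_1), \dots, s'(m_{n_m})\,]$. The asymmetry — column-sum
normalizers in step one, row-sum normalizers in step two — is preserved as
stated in the source formulation even though it may be unintended; both
steps are checked against elementwise loop oracles in the test suite. Any
$0/0$ from an empty column or row (which cross-validation masking can
produce) is defined as $0$: a node with no weighted connections transfers
no mass. The walk stops after two steps by design — on a matrix this small
and sparse, longer walks mostly mix toward the degree distribution. The
damping factors default to $\alpha = \beta = 0.5$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma_prime_d`, `gamma_prime_m` | 0.5 | kernel bandwidth inputs (dimensionless; larger means faster similarity decay) |
| `exponent_convention` | `scaled_product` | Gaussian kernel exponent form |
| `alpha`, `beta` | 0.5 | diffusion blend between $A_m$ and $A_d$ in steps 1 and 2 |
| `use_symptom_similarity` | on when supplied | integrate the external disease similarity |
| `svd_rank` | full | baseline SVD truncation |
| `n_factors`, `learning_rate`, `l2_penalty`, `n_epochs` | 100, 0.01, 0.01, 200 | latent-factor baseline (only the factor count is anchored in the source method; the optimizer settings are exposed defaults) |
| `katz_beta`, `max_path_length` | 0.01, 3 | truncated Katz baseline; length 3 lets the similarity blocks contribute |

## Evaluation protocol

Both cross-validation modes rank held-out positives against the *candidate
set*: every cell that is zero in the **original** matrix. In LOOCV each
positive is masked in turn, the scorer is retrained on the masked matrix,
and the held-out score is compared with the candidate scores from that same
masked run; the AUC is the concordance over all (held-out, candidate) pairs
with ties credited one half. The reported ROC curve is the empirical
distribution of the per-run normalized candidate ranks, and its trapezoid
integral equals that AUC identically. In repeated $k$-fold CV (default
$5$ folds, $100$ repetitions) the concordant-pair counts of a repetition's
folds pool into one AUC per repetition, and the summary is the mean and
standard deviation over repetitions — one number per random re-partition.

Two decisions here materially affect results and are therefore explicit:

* **Kernels are retrained inside every masked run** by default. The
  Gaussian similarities are functions of $A$, so computing them from the
  full matrix would leak the held-out association into the training
  similarity. A `static_from` option freezes the similarities for
  comparison, since the alternative protocol is also plausible; the
  external symptom similarity is static by nature.
* **Ties use the midrank convention**, which is what makes the trapezoid
  ROC area and the Mann–Whitney concordance coincide exactly — an identity
  the suite asserts on hundreds of random configurations.

## The synthetic generator

`simulate_associations()` plants the structure the method assumes: diseases
and microbes fall into paired groups (5 + 5 by default, at the 39 × 292
scale of the real catalogs); matched group pairs associate with probability
`p_in = 0.25`, everything else with `p_out = 0.01`; the symptom similarity
is `0.6` within disease groups and `0.1` between, plus Gaussian noise
(sd `0.05`), symmetrized and clipped to $[0,1]$. Any all-zero profile is
rescued with one forced matched association rather than rejection-sampled,
keeping generation linear-time and deterministic per seed.

What it deliberately does **not** emulate: the heavy-tailed degree
distribution of real catalogs (hub diseases studied in dozens of reports,
and the long tail of microbes reported exactly once), taxonomic structure
among microbes, and any correlation between study effort and association
probability. This matters for interpreting the tests: on real catalogs a
large share of a recommender's ranking power comes from degree
heterogeneity (well-studied microbes are recommended everywhere — a known
popularity bias of this model family), and that channel is absent here by
construction.

Two consequences, both computed by the test suite on the default fixture:

* Because associations are i.i.d. Bernoulli given block membership, the
  block-membership oracle is Bayes optimal, and its LOOCV AUC — about
  0.86 at the default settings — is the ceiling for *any* scorer. The
  ceiling is far below 1 because roughly one positive in eight is a
  background (`p_out`) cell carrying no recoverable signal, and a masked
  positive is exchangeable with the zero cells of its own block.
* The hybrid model lands well below that ceiling (around 0.57, with the
  neighbor branch near 0.73 and the graph branch near chance). The graph
  branch suffers most: the Gaussian kernels on homogeneous sparse profiles
  have a high similarity floor, so $A_m = A \cdot MS$ is nearly uniform and
  diffusion mass no longer tracks the planted blocks, whereas with identity
  similarities the same diffusion separates matched from background zeros
  several-fold. Passing tests on this fixture therefore demonstrate
  correctness of the machinery and the presence of the planted signal in
  the scores, not the headline accuracy attainable on real, heterogeneous
  catalogs.

Problem sizes used by the automated checks: oracle equivalences on 100–200
random 5 × 7 to 6 × 8 instances; ranking checks on 20 × 50 fixtures;
structure-recovery and cluster-correlation checks at the full default
39 × 292 scale.

## Cluster-correlation analysis

Each entity is represented by its similarity-profile feature vector (its
column of $DS$ or $MS$). For every microbe with at least `min_degree = 2`
records, the Pearson correlations of all unordered pairs of its partner
diseases' feature vectors are averaged into a cluster score (diseases
mirror this with their microbe partners; the disease-side default follows
the "more than 10 records" convention, i.e. `min_degree = 11`). The
baseline is the mean of the full pairwise correlation matrix, diagonal
included (a flag excludes it); entities more than one standard deviation of
the cluster-score distribution from the baseline are flagged. Pearson is
used because the plain "correlation" of the source analysis is
unqualified; correlations involving a constant feature vector are defined
as 0 and logged. No significance test is attached to the mean-vs-baseline
gap — the analysis is directional.

## Baselines

The three comparison scorers are intentionally plain: full (or truncated)
SVD reconstruction of $A$; a latent factor model $P Q^\top$ fitted by
full-gradient descent on the squared error over **all** cells (zeros as
weak negatives) with L2 penalty, divergence detected by a non-finite loss;
and a truncated Katz sum $\sum_{l \le L} \beta^l H^l$ on the heterogeneous
block matrix $H = \begin{bmatrix} DS & A \\ A^\top & MS \end{bmatrix}$. No
attempt is made to reproduce any published AUC for these baselines — their
original configurations (SVD rank, LFM optimizer settings, Katz damping)
are under-specified, so every knob is exposed instead.

## Numerical and interface choices

* Identifiers match exactly (case preserved); no fuzzy name matching
  between the association file and the similarity file. Missing identifiers
  are surfaced by `missing_policy` ("zero" fills a zero row/column,
  including the diagonal; "error" refuses).
* Input similarity asymmetry up to $10^{-8}$ is symmetrized as
  $(M + M^\top)/2$; beyond that it is an error, not a warning.
* Ranked outputs are sorted by score descending within each disease with
  stable (disease, microbe) tie order, and scores print with 6 significant
  digits so files diff reproducibly.
* All randomness (fold assignment, generator, factor initialization, the
  random reference scorer) flows from integer seeds; seeded helpers
  restore the caller's RNG state.

## Known limitations

* Cold start: entities with no known association in the training matrix
  receive no similarity-borne signal (their kernel profile is empty), and
  a masked positive on a degree-one microbe is scored from an empty
  column — on small fixtures this makes leave-one-out AUC *anti*-predictive
  for that stratum, which is a property of the protocol, not a bug.
* The popularity bias of the model family: high-degree entities attract
  high scores everywhere.
* The ensemble is a fixed unweighted average; no learned weighting.
* The symptom similarity is consumed as given; computing it from
  bibliographic co-occurrence is out of scope.
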