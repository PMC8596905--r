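---
title: "Optimal mBIC segmentation of single-cell copy-number profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal mBIC segmentation of single-cell copy-number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnvdp)
```

## The model

`scnvdp` segments single-cell DNA-sequencing copy-number profiles one
chromosome at a time. The input is a pair of bins × cells matrices: raw
read counts $Y$ and a normalised matrix $\hat Y$ whose entry $(i,j)$ is the
depth cell $j$ would be expected to produce in bin $i$ *if it were diploid
there* (library size and bin-level efficiency absorbed). The modelling
assumptions are:

* bins are small enough that copy number is constant within a bin, and
  breakpoints shared by a subpopulation of cells fall on bin boundaries;
* conditional on its integer copy number $c$, a cell's count in a bin is
  Poisson with mean $(c/2)\,\hat Y_{ij}$;
* breakpoints are shared across cells (one segmentation per chromosome),
  while each cell carries its own integer copy number per segment.

For a candidate partition $S=(s_1,\dots,s_\ell)$ with per-cell segment
means $X_{k,j}$ and $\hat X_{k,j}$, the score is a simplified modified
Bayesian information criterion

$$\beta(S) \;=\; \log\frac{L_\tau}{L_0}
  \;-\; \log\binom{m}{\ell-1} \;-\; (\ell-1)(\kappa_1-\kappa_2),$$

where the first term is the generalized log-likelihood ratio of the
copy-number model against the all-diploid null,

$$\log\frac{L_\tau}{L_0} \;=\; \sum_{k=1}^{\ell} |s_k| \sum_{j=1}^{n}
  \left[ \hat X_{k,j}\Bigl(1-\frac{c_{k,j}}{2}\Bigr)
  + X_{k,j}\,\log\frac{c_{k,j}}{2} \right],
  \qquad c_{k,j} = \Bigl\lfloor 2X_{k,j}/\hat X_{k,j} \Bigr\rceil .$$

The $|s_k|$ weight matters: it is what makes the criterion the *bin-summed*
Poisson log-likelihood ratio. Dropping it (i.e. scoring each segment once
from its means, regardless of length) makes every segment's contribution
length-free, so splitting any homogeneous non-diploid segment in half
roughly doubles its positive contribution for a penalty of a few nats — the
optimum then degenerates to the maximum allowed number of segments. With
the weight, a split that leaves every cell's rounded copy number unchanged
is *exactly* neutral (the per-bin term is linear in the segment means at
fixed $c$), and only genuine changes in the rounded state move the
likelihood.

A purely diploid cell contributes exactly $0$ to every segment, so a fully
diploid matrix scores $\beta = 0$ at $\ell = 1$ — the analytic null case
used in the tests.

## The dynamic programme

Let $l(i,j)$ be the single-segment score of bins $i..j$ (an upper
triangular $m \times m$ table, built with prefix sums in $O(m^2 n)$). The
recursion maximises likelihood only:

$$L(k,i) = \max_{k-1 \le i' < i}\; L(k-1,i') + l(i'+1, i),$$

with the backpointer $T(k,i)$ recording the argmax (ties broken towards the
smallest $i'$). Because the penalty depends only on the layer $k$, it is
added afterwards, $\beta(k,i) = L(k,i) - \log\binom{m}{k-1} -
(k-1)(\kappa_1-\kappa_2)$; inside a layer it is constant, so it cannot
disturb the argmax, and $\beta(k,m)$ equals the explicit criterion for the
best $k$-segmentation. Adding the $\ell$-dependent penalty inside the
recursion instead would count it once per transition, i.e.
$\ell-1$ times over. The segment count is chosen as $k^\* = \arg\max_k
\beta(k,m)$ (smallest $k$ on ties) and the turning points are read off $T$
backwards. Total cost $O(m^2 n + m^2 K)$, with $K = \min(m, 15)$ by
default — genuinely more than ~14 shared breakpoints on one chromosome is
outside the regime this model targets, and $K$ is configurable.

Correctness is not argued, it is tested: for hundreds of random instances
with $m \le 12$ the DP's $\beta(k, m)$ is compared layer-by-layer against
explicit enumeration of all $\binom{m-1}{k-1}$ segmentations scored by
`score_segmentation()`, which evaluates the criterion directly and shares
no code path with the table recursion.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `kappa1 - kappa2` | $n \log 2$ (pipeline) | cost per changepoint, nats |
| `cn_cap` | 10 | largest reported copy number |
| `log_floor` | $10^{-4}$ | effective CN inside the log at $c = 0$ |
| `K` | $\min(m, 15)$ | segment budget per chromosome |
| `eps` (normaliser) | $10^{-8}$ | positivity floor for $\hat Y$ |

**The changepoint cost must scale with the number of cells.** Each new
segment frees one integer copy-number level *per cell*. Under Poisson
sampling noise that freedom is worth real likelihood even where no
breakpoint exists: a sub-segment mean that drifts across a rounding
threshold lets one cell re-round, and the best split position harvests
these slacks across all aberrant cells. Empirically the best spurious split
gains roughly half a nat per aberrant cell (measured maxima ≈ 50 nats at 50
aberrant cells of 100), so any constant penalty of a few nats over-segments
as soon as the data carry real aberrations. The default
$\kappa_1-\kappa_2 = n\log 2$ — one *bit* per cell per changepoint, read as
the description cost of "did this cell's state change here?" — sits an
order of magnitude above the per-cell overfitting slack while staying well
below the evidence of the weakest boundary the simulator is allowed to
plant (a two-cell clone changing by one copy over five bins carries ≈ 110
nats at the default depth). In a validation sweep of 337 simulated
chromosomes spanning the full scenario grid the decision margin never fell
below ≈ 20 nats against over-segmentation and ≈ 95 nats against
under-segmentation. `default_mbic_params(n)` encodes this rule; explicit
`mbic_params()` accepts any constants for users who want the raw criterion.

**Rounding.** $\lfloor\cdot\rceil$ is half-away-from-zero (2.5 → 3). The
notation does not fix tie behaviour; this choice is documented and tested.
One subtlety is worth knowing: the rounded integer is *not always* the
likelihood-optimal integer (the likelihood switch-point from $c$ to $c+1$
sits at ratio $1/\log\frac{c+1}{c}$, slightly below $c + 1/2$), so
refining a segmentation can occasionally *lower* the likelihood term — by
at most a few hundredths of $\hat X$ per cell-bin, and more near $c = 0$
where the `log_floor` takes over. The package therefore never assumes
refinement monotonicity; the DP optimum is exact regardless.

**Zero copy number.** $\log(0/2)$ is undefined; the implementation
substitutes `log_floor` for the rounded 0 inside the log only, keeping
homozygous deletions finitely but strongly penalised (a deleted segment
still pays $\hat X$ per bin through the linear term, and gains nothing from
the log term since $X \approx 0$).

**Copy-number calling** uses segment-level means — the same quantity the
objective is built from — never per-bin ratios; values above `cn_cap` are
clamped and flagged in an overflow mask.

## What the simulator emulates — and what it does not

`sim_params()` defaults encode the benchmark conditions: 100 cells × 70
bins on one chromosome (500-kb bins), half the cells diploid normals, four
tumour subclones sharing 7 segments (6 turning points), 10% noise, Poisson
counts at 200 expected reads per diploid bin with log-normal library-size
factors (10% CV). Aberrant clone states are drawn from {1, 3, 4, 5} — the
realistic somatic range of hemizygous loss and low-amplitude gains; at very
high copy number a ±10% depth perturbation on a segment mean can cross a
rounding threshold, which would make "zero false positives" an unfair ask
of *any* method. Planted segments are at least 5 bins (clone-level CNAs
span megabases), and the generator guarantees every planted boundary
changes the copy number of at least one clone, so all turning points are
identifiable in principle.

Two noise mechanisms are available. The default, `"multiplicative"`, scales
each entry's expected depth by $1+e$, $e \sim U(-r, +r)$: measurement
noise, under which the planted boundaries remain the only true ones.
`"replace"` substitutes a random different copy number into a fraction $r$
of entries: this plants genuine single-cell, single-bin CNVs, and an
optimal segmenter will — correctly — fence the strongest of them with extra
boundaries. The replacement mode is useful for studying that behaviour, but
turning-point precision against the *clone-level* truth is only a
meaningful yardstick under measurement noise, which is why it is the
default. `count_model = "nbinom"` adds over-dispersion
($\mathrm{Var} = \mu + \phi\mu^2$); `"deterministic"` is the zero-variance
limit (counts equal rounded expectations) used for the exact round-trip
test.

The simulator deliberately omits features of real scDNA-seq data:
GC-content and mappability bias (assumed removed by the upstream
normaliser), breakpoints private to single cells, doublets, whole-genome
duplications, and cell-cycle effects. Passing the synthetic benchmarks
therefore demonstrates that the optimiser solves the stated objective and
that the objective separates clone structure from count noise *under the
stated model* — not that the model captures everything in real tumours.
On real data the quality of $\hat Y$ is the binding constraint;
`normalize_baseline()` is a deliberately simple rank-one stand-in
(per-bin baseline × per-cell library factor, floored at `eps`), and
externally normalised matrices are accepted everywhere.

## Numerical and degenerate-input choices

* Bin coordinates are 1-based inclusive in memory; BED I/O converts from
  0-based half-open on disk. Turning points are the index of the last bin
  of the left segment.
* A 1-bin chromosome yields a single segment with no turning points; an
  empty chromosome is an error.
* `normalize_baseline()` refuses all-zero bins and all-zero cells, naming
  the offender — silent imputation would leak into every downstream ratio.
* Ties in the DP argmax and in $k^\*$ go to the smallest index/count,
  making results deterministic and letting the enumeration oracle mirror
  the choice.
* Hierarchical clustering of cells (`cluster_cells()`) uses Euclidean
  distance with Ward linkage (`ward.D2`); the cluster count is
  user-supplied. ARI, NMI (arithmetic-mean normalisation) and the
  pair-counting Jaccard index are computed from the contingency table; the
  degenerate both-single-cluster case defines NMI = 1. The Gini coefficient
  of a cell's sum-normalised bin profile (mean-absolute-difference form)
  flags aneuploid cells at the conventional 0.12 cutoff; whether it is
  computed on counts or called CN is the caller's choice (counts by
  default).

## Problem sizes used by the test-suite

Unit and property tests run on matrices up to 70 × 100 (the benchmark
scenario), enumeration oracles on $m \le 12$, $n \le 6$, and the empirical
complexity check times $m = 150$ versus $m = 300$ at $n = 15$ — sizes
chosen so the whole suite completes in well under a minute while still
exercising every code path at the benchmark's full scale. Per-chromosome
segmentation at realistic scale (thousands of cells, a few hundred bins per
chromosome) remains a sub-second operation per chromosome on one core,
since the tables are filled by vectorised prefix-sum arithmetic.

## Known limitations

* Breakpoints are shared across cells by construction; a subclone private
  breakpoint below the bin grid or carried by a single cell is invisible.
* The Poisson/rounded-CN likelihood treats $\hat Y$ as known; errors in the
  normaliser propagate directly into copy-number calls.
* The criterion compares segmentations, not clusterings: subclone
  assignment is downstream (hierarchical clustering on the called CNV
  matrix).
* `K` caps the segment count per chromosome; pathological chromosomes with
  more true shared breakpoints than `K` will be under-segmented (raise `K`
  explicitly for such data).
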