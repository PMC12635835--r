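---
title: "Topological analysis of dynamic functional connectivity with dfcmapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological analysis of dynamic functional connectivity with dfcmapper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcmapper)
```

## The analysis in one paragraph

`dfcmapper` characterizes how functional connectivity (FC) between
large-scale brain networks evolves over a scan, and how that evolution
relates to a continuous stimulus rating. Per-subject region-by-time
matrices are converted into a sequence of windowed, subject-averaged,
thresholded FC matrices ("states"). The states form a finite metric space
under the Manhattan distance; Vietoris--Rips persistent homology summarizes
the shape of that space (how many components, how many loops), and a Mapper
graph -- built from a 2-D Isomap lens, an overlapping rectangular cover, and
single-link partial clustering in the original metric -- reproduces that
shape as a small combinatorial object. Random-walk communities, a node
taxonomy (connector / cyclic / bridge nodes, transition states), six
within/between-network connectivity-weight series, change points, and a
phase-randomized surrogate test complete the picture.

## Sliding-window states

For window width $W$ and step $S$, window $w$ covers volumes
$[1+(w-1)S,\,(w-1)S+W]$ and yields the Pearson correlation matrix over
regions; there are $U=\lfloor (T-W)/S\rfloor + 1$ windows ($T-W+1$ for
$S=1$). The defaults $W=18$ volumes and $S=1$ give, at $T=193$ and
$\mathrm{TR}=2.47$ s, a window span of about $44.5$ s -- inside the 30--60 s
range where windowed FC is generally considered stable -- and $U=176$
states.

Cross-subject averaging is done per window through Fisher's transform:
entrywise $\tanh(\mathrm{mean}(\mathrm{artanh}\, r))$. Correlations at
exactly $\pm 1$ are clipped to $\pm(1-10^{-7})$ so the transform stays
finite; a window in which a region has zero variance produces correlation 0
with a warning by default (`zero_variance = "error"` turns this into an
abort).

A single global threshold $\tau$ removes negative and weak connections:
entries below $\tau$ become 0. $\tau$ is the smallest value on the grid
$0.3, 0.4, \dots$ at which every state's connection density
$\kappa = 2\varepsilon/(N(N-1))$ falls strictly below $0.5$, the density
above which brain connectomes tend toward random topology. Averaging
happens before thresholding; negatives are zeroed only at the thresholding
step.

## The state metric space and its homology

States are vectorized as upper triangles (diagonal excluded) and compared
by the Manhattan distance, which behaves well in high dimension and weighs
each region pair equally. Persistent homology of the Vietoris--Rips
filtration is computed up to dimension 1 over scales $0<\varepsilon\le R$,
with $R$ defaulting to the largest pairwise distance -- the scale at which
every 1-cycle has necessarily filled in. Dimension 0 uses a union--find
pass over the edge filtration; dimension 1 reduces the triangle boundary
matrix over GF(2) (in C++), the standard dimension-by-dimension scheme. A
configurable cap (default 2000 points) guards against the cubic triangle
count; subsample beyond it.

The *dominant* Betti signature condenses the diagram into the counts a
Mapper graph should reproduce. Per dimension, classes are ranked by
persistence (infinite classes first, scored at $R-\mathrm{birth}$); the
dominant set is cut at the topmost position where the persistence ratio
between consecutive classes is at least 2. If no ratio reaches 2, every
class above half the maximum persistence is dominant, so exact ties stay
together. Cutting at the *topmost* qualifying gap rather than the globally
largest one is deliberate: diagram tails contain near-zero persistences
whose mutual ratios are arbitrarily large, and a global-ratio rule would
place the cut inside the tail. On a ranked list such as
$\{97, 25, 20, \dots\}$ the rule isolates the single class with persistence
97.

## Mapper construction and tuning

The lens is classical multidimensional scaling of the geodesic distance
matrix (shortest paths on the union-symmetrized $k$-NN graph, $k=30$) down
to two dimensions -- the Isomap construction. Axis signs are fixed by
flipping any axis on which the first state is negative, making the output
reproducible. A disconnected $k$-NN graph is an error naming the component
sizes; nothing is silently bridged.

The cover splits the bounding box into $n$ intervals per dimension, each
extended symmetrically by $(o/100)\cdot L/2$ per side ($L$ the base
length), so adjacent intervals overlap by $o\%$ of $L$; the outer edges are
pinned to the bounding box so rounding can never exclude the extreme
points. Within each rectangle, members are clustered by single link in the
*original* Manhattan metric. The cut uses the "continuous" heuristic: a
Gaussian KDE (Silverman bandwidth) of the merge heights is evaluated
between the smallest and largest height and the cut falls at the global
density minimum -- but only when that minimum is a *near-empty valley*
(below 5% of the KDE peak). The guard matters: an evenly spaced chain of
states has unimodal merge heights, and an unconditional minimum rule
shatters such chains into singletons. One merge height, or all-zero
distances, give a single cluster.

Nodes are clusters; two nodes share an edge exactly when their member sets
intersect. For comparison with the data-space homology, `graph_betti()`
reports the number of components and the first Betti number of the nerve
*with common-intersection 3-cliques filled in*: a state lying in three or
four overlapping rectangles creates a clique of nodes through that single
point, and such cliques bound no hole in the nerve although they inflate
the raw cycle rank $|E|-|V|+\#\mathrm{components}$ (available via
`fill_triangles = FALSE`). On circular data the raw rank exceeds 1 for
every cover merely because the loop crosses rectangle corners, so only the
filled count can be matched against a target signature.

`tune_parameters()` evaluates the full grid $n \in \{4,\dots,8\}$,
$o \in \{25,30,\dots,45\}$ (25 covers), keeps the graphs whose Betti pair
equals the dominant signature of the data, and returns the match with the
fewest nodes; ties resolve to smaller $n$, then smaller $o$. If nothing
matches, the closest graph by $|\Delta h_0|+|\Delta h_1|$ is returned with
a warning.

## Communities, taxonomy, dynamics

Communities come from the walktrap procedure (walk length 4, the method's
customary default; transition probabilities are exact so the result is
deterministic), cut at maximal modularity; modularity itself is evaluated
directly from its defining sum on the unweighted adjacency, and an
edgeless graph gets $Q=0$ with a warning. `detect_communities()` can also
cut the walktrap dendrogram at a fixed community count, which is the
appropriate evaluation mode when the number of planted groups is known.
A node is a *connector* if removing it disconnects its component, *cyclic*
if removing it lowers the cycle rank, and a *bridge* if it has an edge into
another community; *transition states* are the member states shared by two
bridge nodes of different communities.

Connectivity weights average the thresholded FC over within-network pairs
($2/(n_1(n_1-1))\sum c_{ij}$) and between-network pairs
($1/(n_1 n_2)\sum c_{ij}$), giving six series in the fixed order
salience--salience, frontoparietal--frontoparietal,
salience--frontoparietal, default--default, salience--default,
frontoparietal--default. The rating trace is aligned to states by the
window-mean convention (the value of a state is the mean rating over its
window; a window-center alternative is provided); for a linear trace the
two conventions coincide. Correlations are computed from state 29 to the
last state by default, matching the convention that the opening
low-arousal section is excluded; the end point is exposed as an argument.

Change points in a series are found by exact penalized least-squares
segmentation with a per-segment linear model, solved by PELT-pruned
dynamic programming (pruning never changes the optimum). The default
penalty is BIC-like, $3\hat\sigma^2\log n$ per change point, with
$\hat\sigma^2$ estimated from first differences; a floor of
$10^{-8}\cdot\mathrm{var}(y)$ keeps the penalty above the rounding noise of
the cumulative segment costs on noise-free signals. Segments are at least
3 samples so a line fit is never saturated.

## Surrogate validation

The null model of *static* FC is approximated by phase-randomized
surrogates: per subject, one phase function $\psi(f)\sim U[0,2\pi)$ is
added to every region's Fourier phases, with Hermitian symmetry preserved
($\psi(-f)=-\psi(f)$, DC untouched, the Nyquist bin rotated by 0 or
$\pi$). Sharing $\psi$ across regions preserves all auto- and
cross-correlations of the full series -- the full-length correlation matrix
is reproduced to machine precision -- while destroying time-localized
structure. The dFC statistic $\eta$ is the mean over region pairs of the
temporal variance of the pair's windowed FC (computed pre-thresholding);
dynamics inflate $\eta$, so its test is upper-tailed. Suspense
correlations are tested two-sided. The optional modularity statistic takes
the maximum walktrap $Q$ over the untuned 25-cover grid per surrogate,
which is conservative for the alternative. Significance at level
$\alpha=0.05$ means the observed value's percentile p-value
$(1+\#\{\eta_{\mathrm{null}}\ge\eta_0\})/(B+1)$ does not exceed $\alpha$.

## What the synthetic generator emulates -- and what it does not

Real multi-echo fMRI of the study's kind is out of reach for automated
validation, so `generate_dataset()` plants the features the pipeline is
supposed to detect. Volumes are zero-mean Gaussian draws from a
block-structured correlation matrix (one coupling per network, one per
network pair), switched instantaneously between regimes by a per-volume
schedule, plus independent observation noise (`noise_sd = 0.2`). The
defaults mirror the study's dimensions scaled to three networks: $P=20$
subjects, $N = 12+10+21 = 43$ regions, $T=193$ volumes, $\mathrm{TR} =
2.47$ s. Three regimes (`low`, `mid`, `high`) move the
salience--frontoparietal coupling up while every default-involving
coupling moves down; their block correlation matrices are verified
positive definite at build time. The default schedule is one closed lap
low $\to$ mid $\to$ high $\to$ low in 48-volume blocks: the trajectory
leaves the low phase and revisits it, so the state space has the homology
of a circle, while keeping the secondary loops created by repeated noisy
traversals well below the dominant class. The suspense trace is an affine
function of the scheduled salience--frontoparietal coupling rescaled to
$[0,10]$, which plants the sign pattern $(+,+,+,-,-,-)$ for the six
weight-series correlations.

The generator does **not** model hemodynamic response convolution, scanner
drift or physiological noise spectra, gradual regime transitions, or
inter-subject variability in the schedule. Passing tests on this data
therefore demonstrate that the pipeline recovers planted covariance
structure, not that real fMRI satisfies the model's assumptions.

## Problem sizes and numerical conventions

The test-suite and acceptance computations run at the study-scale default
($P=20$, $N=43$, $T=193$, $U=176$ states, 100 surrogates for the variance
test) plus reduced configurations ($P=4$, $N=15$, $T\approx120$, 25--40
surrogates, 50 repetitions for the false-positive-rate check) where many
independent repetitions are needed. Further conventions, all chosen once:

* user-facing state and volume indices are 1-based; window $w$ starts at
  volume $1+(w-1)S$;
* state vectors use the column-major upper triangle, documented in the
  states file header;
* hierarchical merge ties follow `stats::hclust` ordering (lowest pair
  index first);
* `igraph` supplies walktrap, graph components and GraphML export; the
  modularity formula, the persistence computation, the Mapper
  construction, the change-point solver and the surrogate scheme are
  implemented in the package and oracle-tested against independent
  brute-force implementations.

## Known limitations

* Only homology dimensions 0 and 1 are computed; spheres and higher voids
  are invisible.
* The dominance rule and the clustering valley rule are declared
  conventions; no published numeric criterion exists for either, and other
  reasonable conventions would select slightly different dominant sets or
  partial clusters.
* The untuned-grid modularity null is expensive (25 Mapper graphs per
  surrogate) and is therefore off by default in `null_test()`.
* With very short series ($U < 2$ windows, networks of fewer than 2
  regions) the corresponding statistics are undefined and raise errors
  rather than guessing.
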