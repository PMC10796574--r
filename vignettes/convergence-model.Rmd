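---
title: "A distance-based model of convergent evolution on clock-like trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A distance-based model of convergent evolution on clock-like trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeconv)
```

## The model

Distance-based phylogenetics usually assumes that once two lineages split
they diverge at a roughly constant rate, so that the pairwise distance
matrix of a set of taxa $X$ is the path-length metric
$d_T(x,y) = 2\,h(\mathrm{lca}(x,y))$ of a rooted, binary, edge-weighted
*equidistant* tree $\mathcal{T}$ (every root-to-leaf path has the same
length; $h(\cdot)$ is the height of a point above leaf level).
Convergent evolution breaks this: two ancestral lineages that adapt to the
same niche become more similar than the clock predicts, without exchanging
genetic material.

`treeconv` implements a minimal deterministic model of one such episode.
A **convergence scenario** $(\mathcal{T}, R, \varepsilon)$ places four
points on the tree: top points $r, s$ at height $\beta$ where convergence
begins (looking forward in time) and bottom points $r'$ (below $r$) and
$s'$ (below $s$) at height $\alpha$ where it ends, with
$0 < \alpha < \beta < h(\rho)$, all four points strictly inside edges,
$\alpha, \beta$ distinct from every vertex height (the tree must be
*generic*: no two internal vertices at the same height), and the two
converging paths disjoint. The strength $\varepsilon \ge 0$ scales the
effect. For a leaf pair $x, y$ split across the two top points the
adjusted dissimilarity is

$$d_\varepsilon(x,y) \;=\; d_T(x,y) \;-\; 2\varepsilon\,\bigl(\beta - h_R(x,y)\bigr),
\qquad h_R(x,y) = \max\{h(\mathrm{lca}(r',x)),\, h(\mathrm{lca}(s',y))\},$$

with $r'$ matched to the side of $x$; all other pairs keep $d_T$. The
quantity $\beta - h_R(x,y)$ is the length of the convergence episode that
the ancestries of $x$ and $y$ actually experienced, so $h_R \in
[\alpha, \beta]$ and $d_\varepsilon \le d_T$ entrywise. Negative entries
are possible and deliberately preserved ($d_\varepsilon$ is a
dissimilarity map; whether it is a distance is one of the questions the
package answers).

The scientific questions are then: for which strengths does
$d_\varepsilon$ remain a distance / a metric / a tree metric / an
ultrametric, when can the *topology* of $\mathcal{T}$ still be recovered
from $d_\varepsilon$, and when is the tree *height* identifiable?

## Closed-form thresholds and their oracles

All characterizations are strict-inequality bounds on $\varepsilon$;
`diagnose()` evaluates them and (by default for $n \le 12$) cross-checks
every verdict against brute-force definition-level oracles
(`check_distance_axioms()`): positivity, all triangle inequalities, the
four-point condition over all quadruples, the ultrametric three-point
condition.

* **Distance.** $d_\varepsilon$ is a distance iff
  $\varepsilon < h(\mathrm{lca}(R))/(\beta-\alpha)$
  (`distance_threshold()`).
* **Triplet respect.** Rooted triplets are read off a dissimilarity by the
  strict-minimum rule ($((x,y),z)$ iff $d(x,y)$ is strictly smallest), and
  $d_\varepsilon$ is *triplet respecting* when this set equals the tree's
  induced triplets — then the Build (Aho) algorithm recovers the topology
  (`build_tree()`). For non-cherry scenarios this holds iff
  $\varepsilon$ is below `triplet_threshold()` (the minimum of
  $(d_T(x,z)-d_T(x,y))/2(\beta-\alpha)$ over ordered pairs strictly below
  the convergence set and triplets $((x,y),z)$); scenarios confined to the
  two pendant edges of a cherry are always triplet respecting.
  `internal_edge_bound()` ($\min w(e)/(\beta-\alpha)$ over internal edges)
  is a cheaper sufficient bound; the caterpillar example below shows it is
  far from necessary.
* **Metric.** Under the triplet-respecting-distance hypothesis,
  $d_\varepsilon$ is a metric iff $\varepsilon$ is below
  `metric_threshold()` (minimum of
  $d_T(x,y)/2(\min\{\beta, h(\mathrm{lca}(x,y))\}-\alpha)$ over qualifying
  triples whose $\mathrm{lca}(x,y)$ is not below a bottom point). Every
  qualifying ratio exceeds 1, so $\varepsilon \le 1$ always yields a
  metric.
* **Tree metric and ultrametric.** `tree_metric_configuration()`
  classifies the placement of the four points into three families:
  (a) the two paths inside sibling edges, (b) one path inside a root edge
  and the other inside a single edge hanging below the opposite root
  child, (c) one path inside a root edge with the opposite path split
  between the other root edge and an edge below it. Under the
  triplet-respecting-metric hypothesis, family (a) always gives an
  ultrametric (and is the only ultrametric family).

**A correction discovered by oracle testing.** The families (b) and (c)
alone do *not* decide tree-metricity. When at least two leaves hang below
the bottom point of the path that is not confined to a root edge, the
quadruples that mix two of them with a leaf outside that subtree and a
leaf from the far side of the root satisfy the four-point condition only
up to an explicit strength bound, which `tree_metric_bound()` returns
(non-strict): with $u$ the root child above that path and $v$ the child
endpoint of the bottom point's edge,
$\varepsilon \le (h(u)-h(v))/(\beta-\alpha)$ in family (b) and
$\varepsilon \le (h(u)-h(v))/(h(u)-\alpha)$ in family (c). A minimal
witness, verified by the four-point oracle in the test suite: on
`((a:1,(b:0.5,c:0.5):0.5):9,d:10)` place $r$ in the root edge at
$\beta = 5/4$, $r'$ in the edge above $\mathrm{lca}(b,c)$ at
$\alpha = 3/4$, and $s, s'$ in `d`'s root edge; the dissimilarity is a
triplet-respecting metric for $\varepsilon \in (0,4)$, and the placement
(family (c), bound 2) yields a tree metric at $\varepsilon = 1$ but not at
$\varepsilon = 3$. The package therefore reports the positional family
as stated, but its `is_tree_metric` verdict applies the refined rule;
the refinement was validated against the brute-force oracle on more than
a thousand scenario/strength combinations across all families.

Verdicts whose hypotheses fail are reported as `NA`, never extrapolated:
there are placements whose dissimilarity is an ultrametric even though the
classification above does not apply, because triplet respect fails.

## Restriction to three leaves

Many proofs and computations reduce to 3-leaf subsets.
`restrict_scenario()` builds, for any triple $Y$ on which
$d_\varepsilon \ne d_T$, a scenario on the induced 3-leaf tree (rooted at
$h(\mathrm{lca}(Y))$, edge weighting induced by suppression) whose
adjusted dissimilarity equals $d_\varepsilon|_Y$ exactly: the top points
keep their positions and the bottom points are raised to the common height
$\gamma = \max\{h_{r'}, h_{s'}, \alpha\}$, where $h_{r'}, h_{s'}$ are the
heights at which the upward paths from the original bottom points first
meet the restricted tree, each placed on the side of its joining leaf.
This construction can legitimately land a bottom point exactly on the
restricted tree's internal vertex, so restricted scenarios relax the
strictly-inside-an-edge validation; $d_\varepsilon$ is well defined
regardless. The equivalence is enforced by a randomized test over every
applicable triple of hundreds of scenarios.

## Height identifiability and confounders

Even when the topology is recoverable, the height may not be:
`confounding_configuration()` detects the three placement families (A:
paths inside sibling edges below a non-root vertex; B: top points in the
two root edges; C: one path inside a root edge, the other inside an edge
directly below the opposite root child) for which an alternative edge
weighting and convergence set with the same strength reproduces
$d_\varepsilon$ entrywise with a *different* root height.
`construct_confounder()` builds that alternative explicitly — in all three
constructions the root edges grow by $\varepsilon\delta$, so the
confounded height is $h(\rho) + \varepsilon\delta$ — and the package
verifies the entrywise equality rather than trusting the algebra. The
default $\delta$ is a quarter of the configuration's slack; in family C
the construction forces $\alpha' = h(u) - (\beta-\alpha)$, which in
degenerate cases can collide with a vertex height, and the confounder is
then still returned under relaxed validation (its dissimilarity equality
is always checked).

Outside these families — equivalently, when one of the five root-relative
placement cases of `root_placement_case()` holds together with
non-membership in family A — the height is identifiable and equals half
the maximum entry of $d_\varepsilon$ (`recover_height()`), exactly. A
triplet-respecting *tree metric* always falls in a confounding family, so
its height is never identifiable. `assess_height_identifiability()` runs
the whole analysis and refuses when the triplet-respecting-metric
hypothesis fails.

## Synthetic data

`random_equidistant_tree()` draws coalescent-style trees: $n-1$ distinct
internal-vertex heights on a dyadic grid ($2^{16}$ steps of the total
height, default height 1) with random merge order, which guarantees
equidistance and genericity by construction. `random_scenario()` samples
$\beta$, then two incomparable edges crossing it, walks the two paths down
to a sampled $\alpha$, and validates; placement families (cherry, sibling
pairs, root tops, the b/c families, split pairs) are obtained by
constrained placement with rejection (bounded at 1000 retries). Strengths
default to the unit interval, where metrics are common; the
characterization tests sweep $\varepsilon$ to $1/64$ on either side of
each closed-form threshold instead, so both verdict signs are exercised
for every scenario.

What the generator emulates is exactly the model's assumptions — a single
convergence episode on a clock-like tree, distances observed without
noise. It does not emulate sequence-level sampling error, rate variation,
or multiple episodes, so passing tests certify the combinatorial
machinery, not robustness of inference on noisy empirical distances.

## Numerical choices

All arithmetic is double precision with a fixed comparison tolerance of
$10^{-9}$ for equality, tie and containment decisions. The generator's
dyadic grid makes every height, threshold numerator and dissimilarity
entry in the test suite exactly representable in binary floating point, so
strict-inequality verdicts never hinge on rounding; the thresholds
themselves are evaluated as printed, with strict `<` (at
$\varepsilon$ equal to a threshold the property already fails), while the
tree-metric refinement bound is non-strict, matching the four-point
oracle's behaviour at the boundary. Triplet extraction suppresses ties
within the tolerance rather than guessing. Newick and matrix writers emit
the shortest decimal that round-trips the double exactly, and order
children by smallest descendant leaf label, so serialization is canonical
and deterministic.

Problem sizes in the test and acceptance runs — 200 random scenarios on
4–8 leaves with roughly nine verdict/oracle comparisons each, 60 recovery
scenarios, 48 identifiability scenarios — keep the brute-force
$O(n^4)$ four-point oracles comfortably exact while exercising every
placement family; the counts are stated in the tests themselves.

## Known limitations

* Only a single pair of converging paths is modelled; multiple episodes
  and varying $\varepsilon$ across scenarios (where even the height
  identifiability question changes character) are out of scope, as is
  fitting scenarios to empirical distance data.
* Non-clock trees, multifurcations, and zero-length edges are rejected at
  parse time.
* The positional tree-metric families are reported alongside the refined
  strength bound; users comparing against the literature should note the
  correction described above.
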