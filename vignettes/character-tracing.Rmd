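---
title: "Tracing discrete ecological characters on molecular phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing discrete ecological characters on molecular phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylochar)
```

## The problem

Deep-sea chemosymbiotic clams (vesicomyid bivalves) occur at cold seeps,
hydrothermal vents and coastal reducing sediments across a very wide
bathymetric range, and their genus-level taxonomy — built on shell and soft
part morphology — is frequently contradicted by mitochondrial COI
phylogenies.  Two recurring analyses in this literature are:

1. **Character tracing**: discretize each species' maximum occurrence depth
   into ordered depth intervals, code its habitat into a handful of
   categories, and reconstruct ancestral states on the molecular tree by
   parsimony, asking whether ecology tracks phylogeny (e.g. stepwise
   colonization from shallow to abyssal depths).
2. **Taxonomic congruence**: ask which morphologically defined genera are
   recovered as monophyletic, and how divergent the haplotypes within a
   genus are.

`phylochar` implements both, together with the randomization test used to
decide whether a character is *significantly* associated with the tree, a
GTR+I+G likelihood evaluator for fixed topologies, and a fully synthetic
data generator with known ground truth so every step can be validated.

## The parsimony engine

For a character with $k$ states and a step matrix $C$ ($C_{ii} = 0$,
$C_{ij} \ge 0$), the parsimony length of a rooted tree is the minimum of
$\sum_{(u,v) \in E} C_{s_u s_v}$ over all assignments of states to internal
nodes, with tips fixed at their observed states.  Two engines share this
definition:

* **Fitch** (`fitch_length`): the classic set algorithm for unit costs on
  binary trees — intersect the two child sets, otherwise union and count a
  step.  This is the compiled fast path used inside the randomization test.
* **Sankoff** (`ancestral_parsimony`): the general dynamic programme.  A
  bottom-up pass computes per-node, per-state subtree costs (polytomies are
  handled natively, each child contributing
  $\min_b (C_{ab} + S_{\text{child}}(b))$); a top-down pass computes the
  cost of the rest of the tree, and the **MPR set** of a node is every state
  whose combined cost attains the global minimum.  A node with more than one
  MPR state is flagged *equivocal* — ties are reported as sets, never broken
  silently.  For a figure-style single labelling,
  `write_annotated_newick()` documents that equivocal nodes carry the whole
  set.

Alongside the cost, the engine tracks the minimal number of *changed
branches* among minimal-cost reconstructions (a lexicographic secondary
objective in the same DP).  Under unit costs this equals the length; under
the ordered (Wagner) matrix $C_{ij} = |i - j|$ a single $0 \to 2$ jump
costs 2 but counts as one transition.  `count_transitions()` exposes both
readings because published "numbers of transitions" rarely say which was
meant.

Correctness is established against an exhaustive enumeration oracle
(all $k^{\,\text{internal}}$ labelings) on hundreds of random instances —
length, transition count and full MPR sets — and by a clamping property:
forcing a node to a state inside its MPR set reproduces the optimum, any
state outside it strictly exceeds the optimum.

## The phylogenetic-signal test

`signal_test()` compares the observed parsimony length with lengths on $N$
randomized trees (default $N = 1000$):

* `random_topology` (default): new topologies drawn **uniformly** over all
  labelled rooted binary topologies on the same tips, by sequential random
  addition — each next tip is inserted on an edge chosen uniformly,
  including the root edge, giving every topology probability
  $1/(2n-3)!!$.  This matches the equiprobable-trees convention of classic
  character-tracing software.  Branch lengths are irrelevant: parsimony
  ignores them, so the null randomizes topology only.
* `shuffle_tips`: the observed topology is kept and labels are permuted —
  useful when the tree's *shape* should be held fixed.

Fewer steps than expected means related taxa share states: phylogenetic
signal.  The one-tailed p-value uses the add-one rank rule

$$p = \frac{1 + \#\{L_{\text{null}} \le L_{\text{obs}}\}}{N + 1},$$

which is never zero and is a valid permutation p-value.  The traditional
mean comparison is reported too, as the descriptive z-like score
$(L_{\text{obs}} - \bar L_{\text{null}}) / \text{sd}(L_{\text{null}})$.

**A deliberate caveat on calibration.**  Parsimony length is an integer
with a handful of likely values (at 24 tips and 4 states the null
concentrates on roughly five).  Rank-based p-values that count ties with
"$\le$" are therefore *conservative*: in our own calibration experiment
(1000 independent character/tree pairs, $N = 199$; recomputed by
`scripts/acceptance.R` as `calibration_rejection_rate`) the rejection rate
at $\alpha = 0.05$ is about 0.02–0.03, and $P(p \le \alpha) \le \alpha$
held at every level we probed.  The test never over-rejects; users should
expect it to be somewhat strict on small trees with few states.  The
calibration experiment draws its "observed" trees from the same uniform
topology distribution as the null so that observed and null lengths are
exchangeable by construction; using Yule-shaped observed trees against
uniform-topology nulls would confound the check with tree-shape mismatch.

## Characters: depth intervals and habitat categories

`depth_binning()` discretizes maximum occurrence depth into 13 half-open
metre intervals by default, `[0,200) [200,500) … [5000,6000) [6000,Inf)` —
a sublittoral band up to the shelf break followed by 500 m bathyal and
1000 m abyssal slices.  Published analyses of this kind rarely print their
exact boundaries, so the edges are fully configurable and nothing
downstream depends on them; a depth exactly on a boundary belongs to the
deeper interval.  `encode_habitat()` fixes the four-category alphabet
*Seeps, Vents, Seeps and Vents, Coastal* (case-folded, synonym-mapped,
strict on unknowns).

The depth character is treated as **unordered by default** — matching the
unweighted-parsimony convention of the analyses this package emulates —
with the ordered Wagner mode one flag away (`costs = "ordered"`), which is
the biologically natural choice for ranked depth intervals.  Taxa with a
missing state are pruned from the tree for that character's analysis
rather than treated as wildcards, so step counts stay determinate.

## Monophyly and divergence

`monophyly_status()` classifies a named group on the rooted tree: the
minimal spanning clade is located; no intruders means *monophyletic*;
intruders that themselves form one clade mean *paraphyletic* (removing a
single nested clade of non-members leaves the group exclusive); anything
else is *polyphyletic*.  Groups with fewer than two tips present are
*not assessable* — with members absent from the tree dropped under a
warning, since public-database taxon sets rarely match exactly.
Monophyly is a rooted-tree notion, so results are reported relative to the
rooting supplied.

Sequence divergence is the **uncorrected p-distance** under pairwise
deletion (both symbols in `ACGT`), the standard reading of
percent-divergence statements in COI barcoding; a K2P-corrected variant
sits behind `model = "K2P"`.  `max_intragroup_divergence()` returns the
worst within-group pair in percent.

## GTR+I+G likelihood

`tree_log_likelihood()` evaluates (never optimizes) the likelihood of an
alignment on a fixed tree under GTR+I+G by Felsenstein pruning with
site-pattern compression.  Choices a user should know:

* the rate matrix is scaled so the expected substitution rate over the
  *variable* fraction is 1, making branch lengths comparable with standard
  ML tools;
* the invariable-site term contributes only when every observed symbol at a
  site is identical, with gaps/ambiguities counting as compatible (the
  common +I convention — stated here because papers are usually silent);
* gaps, `?` and `N` enter the pruning as all-ones partial likelihoods;
* discrete-gamma rates are the equal-probability category means of
  $\Gamma(\alpha, \alpha)$, normalized to mean 1 (`discrete_gamma_rates`);
* transition matrices come from the symmetrized eigendecomposition of the
  reversible generator, accurate to machine precision (the test suite
  checks it against independent matrix exponentials), and reversibility
  makes the value reroot-invariant, which the tests verify to `1e-8`.

Typical COI parameter values ($p_{\text{inv}} = 0.39$, $\alpha = 0.54$)
are the simulation defaults.

## The synthetic-data generator

`simulate_study()` emulates the *shape* of a family-wide COI study: 87
taxa on a Yule tree, a 630-column GTR+I+G alignment, and a 13-state depth
plus 4-state habitat character evolved by a symmetric Mk process on the
same tree, with characters carried by a 53-taxon ingroup subset.  Defaults,
chosen once:

* **Yule birth rate 1** (tree in units of expected lineage lifetimes; root
  height expectation $\sum_{k=2}^{n} 1/(\lambda k)$, verified against the
  closed form);
* **sequence scale 0.05** substitutions per variable site per tree unit,
  giving family-plausible COI divergences (up to roughly 20–25% between
  distant tips);
* **Mk rate 0.1** per alternative state for the characters — the signal
  knob; 0.05 is the "strong signal" setting used in the power studies.
  `rate` is the instantaneous rate towards *each* alternative state, fixed
  by the two-state identity $P(\text{change}) = (1 - e^{-2rt})/2$;
* characters and sequences are simulated independently on the same tree
  (coupling them through a shared tree is exactly what the default does;
  they are independent *given* the tree).

What the generator does **not** emulate: real COI base composition and
codon structure, rate variation across lineages, alignment error, and any
correlation between depth and habitat beyond their shared tree.  Passing
tests therefore demonstrate algorithmic correctness and statistical
behaviour under the stated model, not robustness to those real-data
features.

Ground truth (true tree, true ancestral states, all generating parameters)
is written to `truth.json`, and identical seeds give byte-identical
bundles.

## Numerical and scale choices

* Cost comparisons in the Sankoff DP use an absolute `1e-9` slack so that
  integer and Wagner costs never suffer floating-point tie misses; Newick
  branch lengths are serialized with 10 significant digits (round trips
  agree within `1e-9`).
* The null-distribution inner loop (uniform topology generation plus unit
  cost Fitch) is compiled C using R's own RNG stream, so seeds behave
  identically across the fast and fallback paths; the R Sankoff engine is
  the general path for arbitrary step matrices and polytomies, and the two
  are cross-checked on shared instances.
* Root-state recovery in the power study counts success when the true root
  state lies in the root's MPR set, consistent with the package-wide rule
  that ties are sets.  At $k = 13$ on 53 tips many states are unobserved at
  the tips and the root set rarely pins down the truth, so recovery is
  only meaningful at small $k$; the headline recovery condition is
  $k = 4$, rate 0.05.
* Test-suite problem sizes: oracle equivalence on 300–500 random instances
  (≤ 12 tips; enumeration at ≤ 7 tips, ≤ 4 states), calibration on 1000
  replicates of 24 tips with $N = 199$, power on 200 replicates of 53 tips
  with $N = 1000$, simulator fidelity at 2000 Yule replicates and a 50 kb
  two-taxon alignment.  These sizes keep every Monte Carlo standard error
  a few times smaller than the property bands being checked.

## A small worked example

```{r example}
bundle <- simulate_study(file.path(tempdir(), "demo"), seed = 7,
                         n_taxa = 24, n_character_taxa = 18,
                         seq_length = 200)
rep <- run_character_test(bundle$tree, bundle$character_matrix, "habitat",
                          N = 499, seed = 8)
rep
summary(rep$reconstruction)[19:23, ]
```

## Known limitations

* Likelihood evaluation only: no branch-length or parameter optimization,
  no tree search, no bootstrap — trees and model parameters are inputs.
* The signal test is conservative on small trees with few states (tied
  integer statistic; see above).
* Parsimony assumes every analysed tip has a determinate state; wildcards
  are not supported by design.
* Monophyly classification depends on the rooting; reroot first if the
  outgroup placement is in doubt.
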