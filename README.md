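# phyloConcord

Joint analysis of genetic ancestry and gene-expression state in tumor
single-cell RNA-seq data.

Tumors evolve along two coupled axes. Somatic mutations accumulate and
define a cell phylogeny, whose clades are *genetic ancestries* (a proxy for
clones). Gene-expression programs evolve too — sometimes tracking the
genetic ancestry (*divergent* expression evolution: one ancestry splits
into several expression states), sometimes crossing it (*convergent*
evolution: cells from genetically distinct ancestries share one expression
state). phyloConcord quantifies which of the two regimes a tumor is in,
for researchers who have (i) one or more rooted cell phylogenies built
from scRNA-seq-derived SNVs and (ii) a normalized expression matrix for
the same cells.

## What it computes

**Tree shape.** The MLE of Aldous' beta-splitting parameter. A subtree of
*n* tips splits into child subtrees of *i* and *n − i* tips with
probability

    q_n(i; β) = w_n(i; β) / Σ_j w_n(j; β),
    w_n(i; β) = Γ(β+1+i) Γ(β+1+n−i) / (Γ(i+1) Γ(n−i+1)),   β > −2,

and the tree log-likelihood is the sum of log q over internal nodes
(`treeBalance()`). β̂ < −1.5 (the PDA point) flags a ladder-like,
unbalanced tree; β̂ > −1.5 a balanced, Yule-like tree. β = 0 is exactly
Yule.

**Ancestry annotation.** Clade-based partitioning of the phylogeny:
`balancedAnnotation()` picks the disjoint clade pair with the least summed
within-clade mean patristic distance subject to size constraints, then
grows to `nClades` by largest remaining disjoint clades;
`unbalancedAnnotation()` cuts a ladder-like tree into `nClades` groups of
near-equal size. Normal (non-cancerous) cells are excluded and labelled
`normal`.

**Annotation agreement.** For every pair of annotations (including their
consensus), the contingency table over shared cells, a Pearson chi-square
test and Cramér's V = √(χ² / (n·(min(r,c)−1))). Agreement is "supported"
when V > 0.2 and p < 0.01 (`ancestryComparison()`, `agreementHeatmap()`).

**Concordance indices.** Genes are ranked by Kruskal–Wallis H between
ancestries; a deterministic trajectory (z-score → PCA → minimum spanning
tree, rooted at a normal cell with pseudotime 0) assigns each cell an
expression state. For a uniqueness threshold u (default 0.8):

* **SCI(a)** — the number of states whose cells are >u ancestry *a*
  (divergence of ancestry *a*);
* **OCI** — the fraction of all states unique to any single ancestry
  (whole-tumor concordance).

Both are swept over gene scales 200, 300, …, 1000 (`phyloTrajectory()`),
because a small scale concentrates ancestry signal and a large one dilutes
it.

A seeded simulator (`simulateTumor()`) generates coupled phylogenies,
genotype matrices (with allelic dropout and missing calls) and expression
matrices with known ancestry/program ground truth, in the exact file
formats the readers accept.

## Worked example

```r
library(phyloConcord)

sim <- simulateTumor("concordant", seed = 42)   # 60 cancer + 3 normal cells
treeBalance(sim@tree)
#> Beta-splitting estimate: beta = 3.4472 (balanced tree; threshold -1.50)
#>   log-likelihood -55.5832 on 63 tips
#>   suggested annotation: balancedAnnotation()

nrm <- names(sim@ancestry)[sim@ancestry == "normal"]
ann <- balancedAnnotation(sim@tree, nClades = 3, minTotalFrac = 0.66,
                          normalCells = nrm, provenance = "beam_tree")
ann
#> AncestryAnnotation: 63 cells [beam_tree]
#>   ancestry_1: 20, ancestry_2: 20, ancestry_3: 20, normal: 3

phyloTrajectory(sim@expression, ann, rootCell = nrm[1],
                scales = c(200, 500, 1000))
#> ConcordanceReport: 1 annotation(s), 3 gene scale(s), u = 0.80
#>  annotation scale       oci nStates nUnique
#>   beam_tree   200 1.0000000       9       9
#>   beam_tree   500 0.8888889       9       8
#>   beam_tree  1000 0.8750000       8       7
```

The tree is classified balanced (β̂ = 3.45 ≫ −1.5), the three simulated
clades are recovered exactly (20/20/20), and — since every expression
program is ancestry-specific in the `concordant` preset — 7–9 of the 8–9
expression states are unique to a single ancestry, so the OCI stays near 1
across gene scales. In the `convergent` preset part of one ancestry adopts
another's program and the OCI drops (≈0.67 at scale 200, averaged over
seeds).

A command-line front end with the same verbs is installed at
`exec/phyloconcord`:

```sh
phyloconcord simulate --preset concordant --seed 1 --out sim/
phyloconcord treebalance sim/tree.nwk
phyloconcord annotate sim/tree.nwk --mode auto --out ann.tsv
```

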