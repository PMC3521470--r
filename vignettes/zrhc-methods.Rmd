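---
title: "Zero-recombinant haplotype phasing on general pedigrees: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-recombinant haplotype phasing on general pedigrees: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zrhc)
```

## The problem

A pedigree records parent-child relationships among `n` individuals, some of
whom (the founders) have no recorded parents. Genotyping at `m` bi-allelic
marker loci yields, per individual and locus, an *unordered* allele pair; the
phased *haplotypes* — which alleles sit together on the chromosome inherited
from the father, and which on the one from the mother — are not observed.
Under the zero-recombination assumption, natural for tightly linked markers,
each child inherits one *complete* haplotype from each parent. The task is to
recover, for every individual, the paternal allele `p_i[l]` at every locus:
the zero-recombinant haplotype configuration (ZRHC).

Two features make this more than bookkeeping. First, pedigrees may contain
*mating loops* (a couple sharing an ancestor), which defeat the simple
peeling arguments that work on tree pedigrees. Second, the data usually do
not determine the configuration uniquely, so a useful answer is a *general
solution*: a parameterisation of every configuration consistent with the
genotypes, not one arbitrary representative.

## The parity model

Everything is linear over GF(2). With genotype codes `g` (0 = homozygous
0/0, 1 = homozygous 1/1, 2 = heterozygous), define per node the
heterozygosity indicator `w_i[l] = [g_i[l] == 2]`, and per parent-child edge
the transmission indicator `h_{i,j}` — 0 if parent `i` passed its paternal
haplotype to child `j`, 1 otherwise. Zero recombination is precisely the
statement that `h_{i,j}` does not depend on the locus. With the per-edge,
per-locus constant `d_{i,j}[l]` (0 on father edges, `w_j[l]` on mother
edges), inheritance at every edge and locus is the single relation

```
p_i[l] + w_i[l] * h_{i,j} = p_j[l] + d_{i,j}[l]     (over GF(2))
```

A node whose own genotype, or one of whose parents, is homozygous at `l` is
*predetermined* there: its `p_i[l]` is a known constant. Summing the
relation along a path whose endpoints are predetermined (and whose interior
is not) eliminates the unknown `p`'s and leaves a parity constraint on the
`h`'s along the path; summing around a cycle needs no predetermined nodes at
all. Restricting to the locus graph `G_l` (only edges whose parent endpoint
is heterozygous at `l`, since `w_i[l] = 0` removes `h` from the relation)
makes every such constraint available by a linear scan.

## The algorithm

The package avoids generic Gaussian elimination on the `O(mn)`-equation
system; instead it exploits the graph structure in four steps.

1. **Preprocessing.** Build the pedigree graph (one edge per parent-child
   pair), a depth-first spanning tree per connected component (root at the
   smallest individual id, neighbours in ascending id order — so the tree is
   reproducible), locus graphs, `w`/`d` constants, predetermined `p` values,
   and a single-locus Mendelian feasibility check for every child. Non-tree
   edges are classified by their fundamental cycle: a length-4 cycle formed
   by a couple and two common children is *local* (a sibling cycle); others
   are *global* and their count `k` is the effective mating-loop number
   under this tree.

2. **Constraint generation.** For each non-tree edge and locus: if the whole
   fundamental cycle lies in `G_l`, a *cycle constraint* (the d-sum around
   the cycle); otherwise a *path constraint* from walking to the first
   predetermined node on each side of the edge. Tree constraints connect
   predetermined nodes within each locus-forest component, seeded at the
   smallest-id predetermined node. All three sets are keyed, so duplicates
   collapse; a key re-inserted with a different parity is a genotype
   inconsistency and is logged (checkpoint one), not thrown.

3. **Reduction.** Each path constraint of an edge that also has a cycle
   constraint is linearly dependent on it plus a tree constraint, and is
   converted accordingly (Type-1). The remaining tree constraints become the
   *constraint graph*: within each connected component ("frame"), a
   breadth-first pass assigns each node a cumulative parity `W` relative to
   the frame seed; revisits must agree (checkpoint two). Global non-tree
   edges still lacking a cycle constraint may acquire a *synthetic* one: the
   edge's path constraints, viewed as a multigraph on frames, contain the
   edge's `h` once each, so an odd cycle of them (self-loops first, then the
   first odd cycle found by deterministic two-colouring) sums — via
   `W[n_i] + W[n_j] + b_p` per constraint — to the missing cycle parity.
   Synthesis converts that edge's path constraints to tree constraints,
   merges frames, and iterates, since one merge can enable another. Local
   edges are never attempted: a case analysis of the four ways a sibling
   cycle can appear in a locus graph shows no new tree constraint can come
   from them.

4. **Haplotype determination.** Founders cannot be constraint endpoints, so
   each is attached to its smallest-id tree child by a weight-0 edge — the
   convention that it transmits its paternal haplotype there (see gauge
   below). Remaining path constraints whose side pairs each lie within a
   frame determine their non-tree edge's transmission
   (`h = b_p + W[n_k] + W[n_i] + W[n_j] + W[n_l]`) and link frames in the
   connectivity sense only: the W-relation between two frames joined by a
   non-tree edge equals that edge's unobserved cycle constraint, so their W
   origins are kept independent. Residual components are joined by a star of
   fresh *linker* variables between frame seeds. Tree edges inside a frame
   then carry `h = W[i] + W[j]`; a non-tree edge with a cycle constraint
   `b_c` and both endpoints in one frame carries `h = b_c + W[i] + W[j]`.
   Finally `p` expressions are propagated per locus from the predetermined
   nodes.

The result is a set of affine GF(2) expressions — per-edge `h`, per-node
per-locus `p` — over the free variables, plus a consistency status.

## Free variables, the founder gauge, and anchors

Three kinds of free variables can appear, recorded with provenance in a
registry:

* **linker** — the unknown tree constraint between two frame seeds that no
  data connect;
* **anchor** — the genuinely free phase of a region that is heterozygous
  throughout a locus, assigned to the smallest undetermined (locus, node)
  pair when propagation stalls;
* **edge_h** — reserved for transmissions left entirely unconstrained.

The founder attachment is a *gauge choice*: the paternal/maternal labelling
of a founder's two haplotypes is unobservable, and fixing `h = 0` towards
one designated child picks one representative per relabelling orbit. The
enumerated family is therefore a canonical slice of the full solution set.
`canonical_phase()` maps any valid configuration to its representative under
the same convention, which is how the test suite compares the family with a
brute-force enumeration — the two agree exactly on the instances checked.

Two refinements keep that agreement exact. During `p`-propagation, before
any anchor is introduced, an edge whose transmission is still unknown but
whose endpoint alleles are both determined at some heterozygous locus has
its `h` recovered there (`h = p_i + p_j + d`) and reused at every other
locus. And when two derivations of the same quantity meet with expressions
that differ but still contain free variables, the difference is a binding
affine relation: the highest-id variable in it is substituted out
everywhere. This is deliberate single-equation back-substitution on the few
variables the graph machinery could not orient — not general matrix
elimination, which the whole design exists to avoid. A constant-1 relation
is a genuine genotype inconsistency and goes to the conflict log.

## Consistency checking

Inconsistencies (genotyping errors, wrong parentage) surface at four places:
the single-locus Mendelian check, constraint insertion (checkpoint one),
W-assignment revisits (checkpoint two), and the final audit
(`verify_family()`), which re-checks the inheritance identity on every edge
and locus, derives the transmission of every unresolved edge at each
heterozygous locus and requires all derivations to be equal (the
cross-locus zero-recombination condition), and confirms every homozygous
genotype is reproduced. The pipeline never throws on inconsistency; it
returns status `"inconsistent"` with located messages, so checking mode can
report everything it finds. On small corrupted instances the verdict agrees
with brute force (configuration exists vs not) in every case tested.

## The simulator

`simulate_pedigree()` grows a pedigree from one founder couple by marrying a
random existing member to a new founder, each couple having 1-4 children,
then creates each requested mating loop by mating an opposite-sex pair that
shares an ancestor (neither being an ancestor of the other) — the
first-cousin-style mechanism that produces loops in real pedigrees. Loop
matings are given exactly one child, so each contributes exactly one
independent cycle. `gene_drop()` gives founders two independent random
haplotypes (allele-1 frequency 0.5 by default; configurable to stress how
dense predetermination is) and draws one transmission bit per parent-child
pair — never per locus, which is the zero-recombination model itself — and
records the full truth. `inject_errors()` flips chosen genotype codes for
the checking experiments.

Reported loop counts are tree-relative: a sibling cycle entangled with a
loop can acquire a long fundamental cycle under the ascending-id DFS tree
and be counted global, so the achieved `k` can exceed the requested number
(never fall below it); with zero requested loops the count is reliably zero.

What the generator does *not* emulate: realistic human demography and
generation overlap, missing genotypes, statistical genotyping-error models,
multi-allelic markers, linkage-disequilibrium structure among founder
haplotypes, and actual recombination. Passing tests therefore demonstrate
correctness of the algebra and the algorithm on complete, error-free (or
deliberately corrupted) bi-allelic data — not robustness to the
missing-data patterns of real studies, which the input layer rejects
explicitly.

## Numerical and design choices

* Expressions are kept canonical (sorted, duplicate-free variable sets), so
  semantic equality of affine GF(2) functions is structural equality —
  every consistency check is an `identical()`-grade comparison.
* All "arbitrary" choices in the method are made deterministic: spanning
  trees by ascending-id DFS, seeds as the smallest node id (a frame merge
  keeps the smallest old seed automatically), odd cycles self-loop-first
  then first-found by two-colouring, linker stars anchored at the component
  with the smallest node. Identical input gives a byte-identical report.
* Degenerate inputs: `m = 1` runs with the cross-locus check vacuous;
  disconnected tables are phased per component (no linker ever joins two
  families); childless isolated individuals stay singleton frames with
  per-locus anchors; half-specified parents and missing alleles are rejected
  at the input layer rather than imputed.
* The worked 19-member looped example enters at the constraint level and is
  reproduced exactly: two Type-1 tree constraints, one synthetic cycle with
  parity 0 yielding three more, and a final family with exactly one free
  variable. Its one-dimensional family flips the global non-tree edge's
  transmission together with one tree edge's, as the synthesised cycle
  constraint requires; parameterisations that flip the non-tree edge alone
  would violate that parity.
* Problem sizes in the test suite were chosen to exercise each regime while
  keeping runs comfortable: exact oracle equivalence on 200 pedigrees with
  `n <= 8`, `m <= 4` (where brute force over transmission bits is cheap),
  truth membership and audits on 100 pedigrees up to `n = 60`, `m = 30`,
  requested loops up to 3, and 100 many-locus runs (`m = 30`) for the
  free-variable census, where 99% of runs need no free variable at all.

## Limitations

* The general solution's parameterisation is not canonical: different valid
  choices (which odd cycle, which linker star) give different but equivalent
  coordinate systems on the same solution set. Compare solution *sets* (via
  enumeration or `canonical_phase()`), not expression strings.
* `k` is a property of the spanning tree, not the pedigree alone; it upper-
  bounds the true mating-loop count.
* Complete data only: missing alleles and half-specified parents are
  rejected by design. Recombination and mutation are outside the model.
* Enumeration is exponential in the number of free variables by nature; it
  is an inspection/testing tool, with the expression-level general solution
  being the scalable output.
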