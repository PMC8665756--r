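---
title: "Phylogenetic splits from k-mer presence/absence: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic splits from k-mer presence/absence: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmersplits)
```

## The model

`kmersplits` estimates the evolutionary relationships of $n$ genomes
from shared sequence content. A sequence segment present in exactly the
subset $A$ of the genomes is evidence for the bipartition (split)
$A \mid B$ of the taxon set, and the amount of such sequence — counted
in distinct k-mers — determines the split's weight, i.e. the length of
the corresponding edge in the phylogeny.

Concretely, every input file $i$ contributes a set $K_i$ of canonical
k-mers (a k-mer and its reverse complement are identified; the smaller
word under A<C<G<T is stored). Each k-mer carries a presence/absence
bit pattern over the $n$ files. Patterns are tabulated; a pattern $p$
and its complement $\bar p$ describe the same bipartition and are
merged into one split with two counts $(c_p, c_{\bar p})$. The weight
is the geometric mean, by default with a pseudocount of one added to
each count:

$$ w(A \mid B) \;=\; \sqrt{(c_A + 1)\,(c_B + 1)} . $$

The pseudocount keeps one-sided splits (one count zero — typical for
trivial splits, whose complement side would require a k-mer shared by
*all other* genomes but missing from one) at a positive weight while
preserving the ordering by support; without pseudocounts a one-sided
split has weight 0. k-mers present in all $n$ genomes separate nothing
and are discarded (reported as `n_core`).

Key modelling assumptions, inherited from the k-mer framework:

* **Presence/absence only.** Distinct k-mers are counted, not their
  occurrences; copy number carries no signal here.
* **No positional information.** A k-mer shared by chance (homoplasy,
  repeats) is indistinguishable from one shared by descent; for
  realistic $k$ (21–31) chance sharing is rare.
* **Saturation.** A clade's supporting k-mers must survive unmutated in
  *every* clade member; deep splits between divergent genomes lose
  support roughly like $e^{-k\,\mu\,\ell}$ for per-site divergence
  $\mu$ along the spanning path $\ell$. The method is therefore most
  informative within genera/species complexes.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `k` | 31 | window length (bases). 21–31 is conventional for bacterial genomes: long enough that chance k-mer sharing is negligible ($4^{21} \gg$ genome size), short enough to tolerate divergence. The bundled evaluation uses $k=21$. |
| `iupac_cap` | 64 | maximum DNA words one ambiguous window may expand to. Isolated codes expand to 2–4 words; a cap bounds the exponential blow-up of poly-N runs. `0` disables expansion (ambiguous windows are skipped and counted). |
| `pseudocount` | `TRUE` | add one to each of the two counts before the geometric mean (see above). |
| filter | `none` | `topx` (x heaviest splits), `strict` (greedy tree), `2tree` (two greedy trees), `weakly` (greedy weakly compatible set). |

## Algorithmic choices

* **Canonical k-mers.** Without strand canonicalization a
  reverse-complemented assembly of an identical genome would share no
  k-mers with the original; the package canonicalizes and tests this
  invariance explicitly. The canonical order is defined by the 2-bit
  encoding A=00, C=01, G=10, T=11 (first base most significant); since
  that order is exactly alphabetical, the implementation compares
  strings directly, which stays exact for any $k$ (the packed-integer
  form, `encode_kmer()`, is exact in a double only up to $k=26$).
* **Window resets.** Windows never span record (contig/read)
  boundaries, and any character outside the IUPAC alphabet invalidates
  the windows covering it: adjacency across contigs is an assembly
  artifact, not genomic adjacency.
* **Canonical split storage.** A split is keyed by the bit pattern of
  its smaller side; for even splits ($|A| = n/2$) the side containing
  taxon 1 is kept. Ties in the weight ordering are broken by the side
  pattern (ascending), so every output file is byte-reproducible.
* **Greedy filters.** All filters scan the system in that total order.
  `strict` keeps a split iff it is compatible with everything kept;
  `2tree` offers rejects to a second bin (never rebalanced — the
  simplest reading of "a second tree"); `weakly` checks only triples
  involving the candidate, which suffices by induction since weak
  compatibility of a set is a condition on triples; the test suite
  still audits all triples of the output against a brute-force
  orientation enumeration.
* **Tree construction.** A pairwise-compatible system is turned into a
  rooted tree by orienting every nontrivial split to the side *not*
  containing taxon 1; compatibility makes these clusters laminar, and
  nesting them by decreasing size yields the tree. The root is
  synthetic (Newick needs one); the unrooted split system is preserved
  exactly, and `tree_to_splits()` inverts the construction (the two
  edges flanking the root of a rooted binary input describe the same
  unrooted split and are merged, summing weights). Children are ordered
  by smallest contained taxon index; branch lengths print with 6
  significant digits. Missing trivial splits become leaf edges of
  length 0 (absence of private k-mers, not an error). Newick is emitted
  only when the (filtered) system passes the pairwise-compatibility
  check; otherwise the TSV/NEXUS split outputs represent the network.
* **Degenerate inputs.** Identical genomes produce only all-ones
  patterns, hence an empty split system. With exactly two genomes, the
  two trivial splits are the same bipartition; complement merging
  stores it once with the two genomes' private k-mer counts as its two
  counts. Precision/recall with a zero denominator report 0 with a
  warning.

## What the simulator emulates — and what it does not

`simulate_tree()` draws a rooted binary topology by sequential random
joins (every edge has length 1); `evolve_sequences()` evolves a
uniform-random root genome site-by-site, substituting each site on each
edge with probability `sub_prob` (uniform over the three alternatives —
a Jukes–Cantor-like process parameterized per edge);
`corrupt_with_iupac()` replaces bases by `N` independently with
probability `n_prob`. Everything is bit-reproducible under a seed.

Defaults (20 taxa, 10 kb genomes, 1% substitutions per edge, $k=21$,
0.2% N-corruption where used) are chosen so that a realistic amount of
divergence accumulates (every edge leaves a few hundred diagnostic
k-mers) while full pipeline runs finish in seconds; the N rate matches
the order of ambiguous-base rates in draft assemblies. The simulator
deliberately omits indels, rearrangements, recombination, horizontal
transfer, sequencing error and coverage variation. A green recovery
test therefore establishes that the pipeline correctly turns clean
presence/absence signal into splits — not that the method is robust to
every process shaping real pangenomes (conflicting transfer signal is
precisely what the network output is for, but it is not simulated
here).

The N-corruption experiment in the acceptance suite mirrors the scale
of a 100-genome simulation but runs at 50 genomes × 10 kb to stay
inside the suite's runtime budget; the measured effect (skipping
ambiguous k-mers loses recall, expansion restores it to within 0.05 of
the uncorrupted run) holds at both sizes. The mechanism: with per-site
N probability 0.002 and $k=21$, about 4% of each genome's windows are
ambiguous; skipping them removes the genome from the pattern of every
affected k-mer, so a clade of size $m$ loses roughly
$1-(1-0.04)^m$ of its supporting patterns to spurious sub-patterns,
which starves weakly supported splits. Expansion regenerates the true
word among the $\le 4$ expansions and restores the pattern.

## Numerical and degenerate-case conventions

* Weights are exact doubles; file round trips preserve them to the 6
  significant digits printed (`%.6g`), and tests compare at 1e-5.
* The weight order with pseudocounts is strictly monotone in each
  count, so filter results are stable to count perturbations of ±1.
* `x <= rc(x)` string comparison is locale-independent for uppercase
  A/C/G/T.
* Empty systems serialize to an empty TSV and a valid NEXUS with
  `NSPLITS=0`; `k` longer than every sequence yields an empty table
  with a warning.

## Known limitations

* The whole k-mer table is held in memory as R character vectors; the
  sequential reference implementation targets tens to a few hundred
  bacterial-scale genomes, not thousands.
* `filter_weakly` is quadratic in the kept set per candidate; on
  systems with many thousands of splits it is the slowest filter.
* Newick output refuses incompatible systems rather than computing a
  consensus; that is a design decision, not a limitation of the format
  alone.
* Only substitutions are simulated; see above for what recovery tests
  do and do not establish.
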