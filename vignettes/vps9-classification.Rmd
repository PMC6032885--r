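---
title: "Classifying divergent gene families with backbone-anchored phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying divergent gene families with backbone-anchored phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrollsaw)
```

## The problem

Rab5-subfamily GTPases are switched on by guanine nucleotide exchange
factors (GEFs) that share a single catalytic module, the Vps9 domain —
roughly 104 residues, embedded in otherwise highly divergent proteins.
Across eukaryotes the family splits into subfamilies (Rabex5, GAPVD1,
Varp, Alsin, a Vps9-domain-only protein, and the holozoan RIN proteins),
but the domain is short and fast-evolving, so naive all-against-all
phylogenetics yields unresolved trees. This package implements a
classification strategy built for exactly this regime:

1. **Homology screen.** Candidate family members are found by local
   alignment (Smith–Waterman, affine gaps, BLOSUM62) under a
   Karlin–Altschul E-value gate, retained only as reciprocal best hits
   against a curated source proteome. Domain architectures are annotated
   by sliding-window position-specific scoring.
2. **Backbone profile alignment.** A trusted, well-resolved backbone
   alignment (in the motivating study: metazoan sequences) defines a
   fixed column set; each candidate is aligned to the backbone profile
   independently, never altering the backbone. Unreliable columns are
   masked by backbone occupancy.
3. **Trees.** Poisson-corrected distances over masked columns feed
   neighbor-joining with column-bootstrap supports.
4. **Scrollsaw classification.** Queries are assigned to the subfamily
   of the smallest supported clade that contains them together with
   backbone members of exactly one subfamily; per lineage and subfamily,
   the shortest-branching (slowest-evolving) member is selected as the
   representative for deep phylogeny, with depths normalised against a
   reference anchor so they compare across trees.
5. **Ancestral reconstruction.** Presence/absence matrices over
   supergroup-labelled taxa feed the LECA (Last Eukaryotic Common
   Ancestor) complement rule and Dollo-parsimony gain/loss mapping.

## The ancestral-presence rule

Eukaryotes are grouped into three domains: Amorphea (Opisthokonta,
Amoebozoa, Apusozoa), Diaphoretickes (Archaeplastida, SAR, haptophytes,
cryptophytes) and Excavata. Wherever the eukaryote root falls among the
three, a character present in **two of the three** domains must straddle
the root, so `infer_ancestral_set()` defaults to the two-of-three rule.
The narrower Amorphea-plus-Excavata form is kept as `rule = "strict"`
for audit. The generalisation matters: Varp and the Vps9-domain-only
protein have no excavate representatives, yet their presence in both
Amorphea and Diaphoretickes places them in the LECA — only the
two-of-three rule reproduces that reading. Unknown states (transcriptome
taxa with no hit) never count as presence and never force a Dollo loss:
absence cannot be asserted from a transcriptome.

The Rabex5+GAPVD1 pair is treated as one root character (their split is
an ancient but post-LECA duplication), spanning the resolved Rabex5 and
GAPVD1 columns plus megaclade-fallback assignments. Whether the
Vps9-domain-only protein and Alsin form one root character or two is
genuinely open; both encodings ship
(`fixture_presence_matrix("split")` / `"united"`), giving ancestral
complements of 4 and 3 characters respectively.

```{r leca}
pm <- fixture_presence_matrix()
sort(infer_ancestral_set(pm))
count_family_free_taxa(pm)
```

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `e_max` | 0.05 | E-value gate, both RBH directions |
| gap open / extend | 11 / 1 | affine gap costs (BLOSUM62 convention) |
| lambda, K | 0.267, 0.041 | Karlin–Altschul parameters for gapped BLOSUM62 11/1 |
| `min_occupancy` | 0.5 | backbone non-gap fraction to retain a column (boundary inclusive) |
| distance cap | 5.0 | substitutions/site assigned to saturated pairs (p ≥ 0.95 or < 10 shared columns) |
| `boots` | 100 | bootstrap pseudoreplicates |
| `min_support` | 0.80 | clade support needed for an assignment |
| `prune_factor` | 3.0 | long-branch removal multiplier |
| `leca_rule` | two-of-three | ancestral-presence rule |

The published protocol fixes the E-gate and the 100 pseudoreplicates;
the remaining thresholds are this package's documented choices, exposed
in `pipeline_config()` so that every judgement call is auditable.

## Numerical and algorithmic choices

* **Tree inference surrogate.** Bayesian/ML engines are out of scope
  here; the package's claims concern the classification and ancestral
  layers, which consume trees. NJ on Poisson-corrected distances is the
  built-in engine, and externally computed newick trees (any engine) are
  first-class inputs via `read_gene_tree()`, which normalises both the
  0–1 and 0–100 support dialects.
* **Determinism contracts.** NJ breaks Q-criterion ties toward the
  lexicographically smallest joined label pair; negative estimated
  branch lengths are clamped to zero with the deficit moved to the
  sister branch, keeping trees metric for depth computations.
  Smith–Waterman ties resolve toward the smallest start coordinates;
  profile-alignment traceback prefers match over gaps, then residue-drop
  over column-gap. All coordinates are 0-based half-open.
* **Profile alignment.** Backbone columns are never split: query
  residues that would insert between columns are dropped and counted,
  so downstream distances use only backbone-homologous columns — the
  automated analogue of masking non-homologous positions. Each sequence
  is aligned against the original backbone, never against previously
  augmented rows, making augmentation order-independent.
* **Long-branch removal.** A tip's divergence is its *median* path
  length to all other tips — rooting-free and robust: a median is not
  inflated by the outlier being measured, whereas root-to-tip depths
  after midpoint rooting equalise the two extremes of the tree (the
  most divergent tip and its antipode always sit at diameter/2), which
  would make a single outlier invisible at any sensible factor. Tips
  above `prune_factor` times the median-of-medians are removed worst
  first; backbone anchors are never removed, only flagged.
* **Working root for assignment.** On an unrooted gene tree the root is
  placed on the edge whose bipartition splits the fewest backbone
  subfamilies (ties: most even backbone split), mimicking how an
  outgroup-aware reader orients such trees. Nodes without a support
  label (the root of an unrooted representation) never block an
  assignment on their own.
* **Megaclade fallback.** A query grouping with Rabex5 and GAPVD1
  backbone sequences together, but with neither alone, is assigned the
  Rabex5+GAPVD1 megaclade with a flag — such sequences are common
  outside Amorphea and are evidence for the pre-duplication state.
* **Scrollsaw depths.** Depth is measured from the tip to the base
  (MRCA) of its subfamily clade; a single-tip clade uses the pendant
  edge. Depths are divided by the anchor's depth within its own clade
  (default: the human RIN2 orthologue within RIN, a clade confined to
  Holozoa whose internal branch lengths are stable across trees); when
  the anchor is absent the raw depth is used and flagged.
* **Dollo mapping.** One gain at the MRCA of presence tips (or the root,
  for characters the LECA rule places there); losses are one edge per
  maximal presence-free subtree that contains at least one *known*
  absence. This is provably minimal, and the test suite cross-checks it
  against exhaustive subset enumeration, as it does Fitch counts against
  exhaustive internal labelings and both alignment DPs against
  brute-force path enumeration.

## The synthetic generator

`simulate_history()` walks a labelled species tree root-to-tips; on each
branch every live lineage is lost with `loss_prob` (default 0.2) and
duplicated with `dup_prob` (default 0.1) — events are per branch, not
per unit length, matching how gain/loss maps are drawn on species trees.
`evolve_sequences()` evolves a root protein per subfamily under a
Poisson/uniform-replacement model: a site of rate *r* on a branch of
length *t* mutates with probability 1 − exp(−*rt*) to a uniformly chosen
different residue. Proteins carry a slowly evolving 104-residue
"Vps9-like" block (relative rate 0.25) between fast linkers (length 100,
relative rate 1), at overall rate scale 0.5. Domain-block sequences are
drawn once for the family — subfamily roots share them, since a single
domain model must detect every subfamily — while linkers are independent
per subfamily, carrying the classification signal.

One integer seed drives a single RNG stream in documented order
(family blocks, then per subfamily: root linkers, then pre-order branch
mutations); identical parameters reproduce FASTA and event lists
byte-for-byte.

Two deliberate simplifications: the substitution process is uniform
replacement rather than an empirical exchangeability matrix (the
pipeline needs tunable divergence, not realism — it stands in for the
model-selection step of a real analysis), and there are no indels, so
profile alignment of simulated data is easier than of real data. Rate
variation exists only between blocks (plus optional per-taxon
multipliers). Passing recovery benchmarks therefore demonstrates the
correctness of the pipeline's logic — clade support, purity, depth
selection, ancestral inference — not robustness to alignment error.

`run_benchmark()` additionally conditions the simulation on survival
along one reference taxon of the backbone supergroup
(`protected_taxa`): subfamilies are ascertained through their
characterised reference members, so a subfamily extinct in the reference
lineage would never have entered the backbone in the first place. Loss
draws are still consumed, so protection does not shift the stream.

## Benchmark conditions and what they showed

The default benchmark uses a balanced 32-taxon species tree (depth 5,
branch length 0.2; eight supergroups across the three eukaryote
domains), six subfamilies, and yields roughly 160 sequences of length
304, of which the four Holozoa taxa provide the backbone; trees carry
100 bootstrap replicates. Within-subfamily identity sits near 50%
(≥ 40% in linkers), between-subfamily identity at the random floor
outside the domain block. At these sizes the whole benchmark runs in
about a minute on one CPU; the test suite uses a depth-4 tree and 20
replicates where only determinism is at stake.

One taxon (`t08`) can be simulated at 5× rate to verify that Scrollsaw
representative selection never picks rate-accelerated tips. The
acceptance checks assert assignment accuracy ≥ 0.90 with a wrong-label
rate ≤ 0.02, exact recovery of the simulated root complement for every
character surviving in at least two eukaryote domains, and byte-identical
reports across repeated runs.

## Known limitations

* The fixture presence matrix encodes distributions stated in the
  source survey's text; counts shown only graphically are conservative
  placeholders and editable by the user.
* No indel simulation and no composition-based score corrections; the
  PSSM domain scan is gapless and will miss heavily truncated domains.
* Dollo mapping assumes vertical descent — a horizontally transferred
  character would be modelled as an extra gain only if encoded as a
  separate character.
* NJ is a surrogate: for publication-grade trees, import externally
  computed newick files and run only the classification layers.
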