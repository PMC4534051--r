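---
title: "Growing and scoring gene networks from literature-derived focus genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing and scoring gene networks from literature-derived focus genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cipnnet)
```

## The problem

Chemotherapy-induced peripheral neuropathy (CIPN) is a dose-limiting
toxicity of platinum compounds and taxanes. Genetic-association studies of
CIPN each implicate a handful of genes; a network view asks what those
genes do *together*. Starting from literature-derived **focus genes**,
cipnnet grows gene networks over a typed molecular-interaction knowledge
base, scores each network for focus-gene enrichment, and reports highly
connected **hubs** as candidate genes for follow-up.

The proprietary commercial interactome used in the original analyses cannot
be redistributed, so the package pairs the algorithm with a synthetic
knowledge-base generator that provides ground truth for recovery tests, and
packages the curated literature tables (64 study records, the agent-by-gene
evidence matrix, the three focus-gene sets and the two published hub
tables) as machine-readable fixtures.

## The growth procedure

All connectivity notions live on the *undirected simple view* of the
knowledge base: parallel edges (several relation types between the same
pair) collapse to one adjacency, and self-loops are dropped. The working
hypothesis is that biological function involves locally dense interaction
neighborhoods, so the algorithm tries to build networks that are as densely
connected as possible:

1. **Ranking.** Focus genes are ranked by *triangular connectivity* — the
   number of connected neighbor pairs (triangles) through the gene. The
   top-ranked gene is the first starting seed. Isolated focus genes
   (degree 0) are excluded and reported.
2. **Seed networks.** A *neighborhood* is a gene plus the genes exactly one
   connection away. The first seed network is the seed plus all remaining
   focus genes in its neighborhood; the next seed is the top-ranked focus
   gene not yet covered; the process repeats until every connected focus
   gene is in exactly one seed network. Growth is a single one-hop step —
   iterated growth is the expansion phase's job.
3. **Merging.** Seed networks are combined through an *additional non-focus
   bridge gene* adjacent to at least two of them. Merging is greedy: the
   bridge with the highest specific connectivity with respect to the
   candidate pair's union goes first, and the pool is re-evaluated after
   every merge. A bridge absorbed by an earlier merge still connects its
   network to any further network it touches.
4. **Expansion.** While the network is below the size cap, the outside gene
   with the highest *specific connectivity* is admitted:
   `|neighborhood ∩ network| / |neighborhood ∪ network|`. The union term
   penalizes large neighborhoods, so the criterion simultaneously favors
   genes with large overlap and few neighbors; no separate neighbor-count
   rule is applied. Expansion stops at the cap or when the best candidate
   scores zero. Candidates are all knowledge-base molecules outside the
   network, focus or not.
5. **Scoring.** A network of `n` genes containing `n_f` focus genes is
   scored with the exact right-tailed hypergeometric test: the probability
   of `n_f` or more focus genes among `n` genes drawn at random from the
   knowledge base (`N` genes, `K` of them focus). The score is
   `-log10(p)`; networks with `p < 1e-5` (score > 5) are called
   significant. No multiple-testing correction is applied across networks —
   the published analyses use the nominal threshold.

```{r}
sim <- generate_kb(synthetic_kb_config(
  n_background = 1000, m_attach = 2,
  planted_modules = list(planted_module(20, 10, 0.5)), seed = 8))
res <- core_analysis(sim$kb, sim$truth$id[sim$truth$is_focus],
                     analysis_config(max_network_size = 60))
res
```

## Parameters that matter

* `max_network_size` (default **140** genes) — the published setting; large
  enough that a single network can hold all focus genes of one agent.
* `max_networks` (default **25**) — cap on networks returned per analysis,
  applied after scoring and sorting.
* `significance_p` (default **1e-5**, i.e. score > 5) — the nominal
  selection threshold used in the published analyses.
* `hub_min_connections` (default **15**) — a gene with at least this many
  within-network connections is reported as a hub.
* `count_nongene_nodes` (default `TRUE`) — whether complexes, chemicals and
  other non-gene molecules count toward `n` and the population `N`.
  Published pathway networks display such nodes as ordinary members, hence
  the default. The flag switches the population and the network count
  together so the hypergeometric null is always well formed (a mixed
  convention could make `n` exceed `N`).

## The synthetic knowledge base

`generate_kb()` emulates the global interactome the algorithm queries:

* a **preferential-attachment scaffold** (`n_background` nodes, `m_attach`
  edges per new node, hence `(n_background - m_attach) * m_attach` edges)
  gives the heavy-tailed, approximately power-law degree structure in which
  interactome degree distributions are usually discussed;
* **planted dense modules** emulate pathway neighborhoods: independent
  intra-module edges at `intra_density`, tied to the scaffold by
  `attach_edges` random edges, with the first `focus_count` members flagged
  as focus genes in the returned ground truth;
* edge **relation types** are sampled from the ten-value interaction
  vocabulary (uniformly by default) and edges are direct with probability
  0.7 — display metadata that never influences connectivity metrics.

Values not fixed by the study design were chosen once as field-realistic
defaults: `attach_edges = 5` couples a module to the background sparsely,
the way a pathway touches the wider interactome; `n_background = 5000`,
`m_attach = 2` give a sparse scaffold of realistic density for a curated
interactome at desk scale.

Recovery tests use one planted module of 30 genes (20 focus) at density
0.4 on a 3000-node scaffold: across 20 seeds the top-scoring network
recovers on average at least 90 % of the planted focus genes and always
scores above 5. The generator is deliberately simple: it does **not**
imitate real interactome content, tissue specificity, literature-confidence
weights, or correlated module overlap. Passing recovery tests therefore
shows that the algorithm finds locally dense planted structure under
realistic degree heterogeneity — not that it reproduces any particular
published network.

## Numerical and tie-breaking choices

* **Simple view everywhere.** Whether "connections" should count parallel
  edges separately is not specified anywhere authoritative; collapsing them
  is this package's convention and is applied consistently.
* **Lexicographic ties.** Every tie — equal triangular connectivity, equal
  specific connectivity, bridge choice — breaks lexicographically on
  molecule id under C collation (`method = "radix"`), making the whole
  pipeline deterministic and locale-independent.
* **Exact tail, log space.** The hypergeometric tail is summed exactly from
  `lchoose()` terms, smallest first with Kahan compensation; tests pin the
  result to an independent big-integer Pascal-triangle oracle at relative
  error below 1e-10 for all populations up to 200, and to `phyper()` as a
  cross-check.
* **Seed ranking is computed once.** Whether the ranking should be redone
  after each seed network is consumed is an open interpretive point; the
  initial ranking is reused, which keeps seed selection independent of
  network order.
* **The 25-network cap applies after scoring**, so it truncates the
  ranked list rather than the growth process.
* **Degenerate inputs.** Isolated focus genes are excluded up front and
  reported; an all-isolated focus set yields an empty result plus the
  exclusion report; empty knowledge bases and empty networks score p = 1.
* **Power-law diagnostic.** The log-log fit uses raw degree-frequency
  points (the classic plot), with a CCDF mode offered because raw
  frequency fits are noisy in the tail. Only degrees ≥ 1 enter. No
  scale-free verdict is emitted: a straight-line fit cannot establish one,
  and the interesting output is the slope and R² themselves.

## Problem sizes used by the tests

The suite checks oracle agreement on 200 random graphs of up to 12 nodes,
exhaustive expansion recomputation on instances up to 50 nodes, and
recovery on 20 independent 3000-node scaffolds — sizes chosen so the whole
suite documents the algorithm's behavior while running in well under a
minute per module.

## Known limitations

* Node-for-node reproduction of the published CIPN networks requires the
  proprietary knowledge base and is out of scope; the packaged hub tables
  record the published results, they are not recomputed.
* The merge rule is greedy; no backtracking or global optimization is
  attempted (nor is one described for the original software).
* Gene identity is the id string; there is no HGNC/Entrez mapping layer,
  so focus lists must use the knowledge base's own symbols.
* The hypergeometric null treats the knowledge base as a uniform urn;
  ascertainment bias in curated interactomes (well-studied genes have more
  edges) inflates enrichment for popular genes, as it does in the original
  method.
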