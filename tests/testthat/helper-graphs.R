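# Build a knowledge base from compact "A-B" edge strings; relation/direct are
# irrelevant to connectivity metrics, so fixed values are used.
make_kb <- function(edges, molecules = NULL, name = "test-kb") {
  if (length(edges) == 0) {
    return(knowledge_base(
      data.frame(source = character(), relation = character(),
                 target = character(), direct = logical()),
      molecules = molecules, name = name))
  }
  parts <- strsplit(edges, "-", fixed = TRUE)
  knowledge_base(
    data.frame(source = vapply(parts, `[[`, "", 1),
               relation = "binding",
               target = vapply(parts, `[[`, "", 2),
               direct = TRUE, stringsAsFactors = FALSE),
    molecules = molecules, name = name)
}

kb_triangle <- function() make_kb(c("A-B", "B-C", "A-C"))

kb_star <- function(leaves = 4) {
  make_kb(paste0("c-", paste0("l", seq_len(leaves))))
}

kb_k4 <- function() {
  make_kb(c("A-B", "A-C", "A-D", "B-C", "B-D", "C-D"))
}

# Erdos-Renyi style random KB on `n` nodes (ids a01, a02, ...)
random_kb <- function(n, p, seed) {
  ids <- sprintf("a%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  set.seed(seed)
  on <- stats::runif(ncol(pairs)) < p
  mols <- data.frame(id = ids, symbol = ids, kind = "gene",
                     stringsAsFactors = FALSE)
  edges <- if (any(on)) paste0(ids[pairs[1, on]], "-", ids[pairs[2, on]])
           else character(0)
  make_kb(edges, molecules = mols)
}

# Independent oracle: count triangles through a node by enumerating all
# unordered triples of molecule ids.
brute_triangles_through <- function(kb, g) {
  ids <- kb$molecules$id
  if (length(ids) < 3) return(stats::setNames(rep(0L, length(g)), g))
  has_edge <- function(u, v) {
    any((kb$interactions$source == u & kb$interactions$target == v) |
        (kb$interactions$source == v & kb$interactions$target == u))
  }
  triples <- utils::combn(ids, 3)
  counts <- stats::setNames(integer(length(ids)), ids)
  for (j in seq_len(ncol(triples))) {
    tr <- triples[, j]
    if (has_edge(tr[1], tr[2]) && has_edge(tr[2], tr[3]) &&
        has_edge(tr[1], tr[3])) {
      counts[tr] <- counts[tr] + 1L
    }
  }
  counts[g]
}

# Oracle for one expansion step: exhaustive specific-connectivity
# recomputation over every outside gene, lexicographic tie-break.
best_expansion_candidate <- function(kb, genes) {
  outside <- setdiff(kb$ids, genes)
  if (length(outside) == 0) return(NULL)
  sc <- vapply(outside, specific_connectivity, 0, kb = kb,
               network_genes = genes)
  best <- max(sc)
  if (best == 0) return(NULL)
  hits <- sort(outside[sc == best], method = "radix")
  list(gene = hits[1], sc = best)
}
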