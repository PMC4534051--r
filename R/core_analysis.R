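#' Analysis settings for network generation
#'
#' Defaults follow the published settings for this analysis: at most 140
#' genes per network, at most 25 networks per analysis, significance level
#' p < 1e-5 (score > 5) and a 15-connection hub threshold.
#'
#' @param max_network_size maximum genes per network.
#' @param max_networks maximum networks returned per analysis.
#' @param significance_p p-value threshold defining a significant network.
#' @param hub_min_connections connection count at or above which a gene is
#'   reported as a hub.
#' @param tie_break tie-breaking rule; only `"lexicographic"` (on molecule
#'   id, C collation) is provided — it makes every step of the greedy
#'   algorithm deterministic.
#' @param count_nongene_nodes if `TRUE` (default) all molecule kinds count
#'   toward network size and the null population; if `FALSE` only
#'   gene-kind molecules do. Published pathway networks include complexes
#'   and chemicals as ordinary nodes, hence the default.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(max_network_size = 140,
                            max_networks = 25,
                            significance_p = 1e-5,
                            hub_min_connections = 15,
                            tie_break = c("lexicographic"),
                            count_nongene_nodes = TRUE) {
  tie_break <- match.arg(tie_break)
  stopifnot(max_network_size >= 2, max_networks >= 1,
            significance_p > 0, significance_p < 1,
            hub_min_connections >= 1)
  structure(list(max_network_size = as.integer(max_network_size),
                 max_networks = as.integer(max_networks),
                 significance_p = significance_p,
                 hub_min_connections = as.integer(hub_min_connections),
                 tie_break = tie_break,
                 count_nongene_nodes = count_nongene_nodes),
            class = "analysis_config")
}

new_gene_network <- function(genes, focus_genes, provenance) {
  provenance$step <- seq_len(nrow(provenance))
  structure(list(genes = genes, focus_genes = focus_genes,
                 provenance = provenance),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network: %d genes, %d focus>\n",
              length(x$genes), length(x$focus_genes)))
  invisible(x)
}

#' Map focus-gene symbols onto a knowledge base
#'
#' Symbols are matched against molecule symbols first, then ids. Unmapped
#' symbols are reported, never silently dropped.
#'
#' @param kb a `knowledge_base`.
#' @param symbols character vector of gene symbols.
#' @return List with `ids` (mapped molecule ids, input order) and
#'   `unmapped` (symbols absent from the knowledge base).
#' @export
map_focus_genes <- function(kb, symbols) {
  symbols <- unique(as.character(symbols))
  i <- match(symbols, kb$molecules$symbol)
  miss <- is.na(i)
  i[miss] <- match(symbols[miss], kb$molecules$id)
  list(ids = kb$molecules$id[i[!is.na(i)]],
       unmapped = symbols[is.na(i)])
}

#' Rank focus genes by triangular connectivity
#'
#' Focus genes are sorted in decreasing order of triangular connectivity;
#' the top-ranked gene becomes the first starting seed. Ties break
#' lexicographically on molecule id. Isolated focus genes (simple-view
#' degree 0) are placed last and flagged as excluded — a gene with no
#' connections cannot take part in any network.
#'
#' @param kb a `knowledge_base`.
#' @param focus character vector of focus molecule ids present in `kb`.
#' @return Character vector of the focus ids in rank order, with attribute
#'   `"excluded"` (the isolated ids) and `"tc"` (named triangle counts).
#' @export
rank_focus_genes <- function(kb, focus) {
  focus <- unique(as.character(focus))
  if (length(focus) == 0) stop("no mappable focus genes to rank")
  vi <- kb_vertex(kb, focus)
  deg <- lengths(kb$adj)[vi]
  tc <- triangular_connectivity(kb, focus)
  excluded <- focus[deg == 0]
  active <- focus[deg > 0]
  active <- active[order(-tc[active], active, method = "radix")]
  out <- c(active, lex_sort(excluded))
  attr(out, "excluded") <- lex_sort(excluded)
  attr(out, "tc") <- tc[out]
  out
}

#' Grow one seed gene network
#'
#' The seed network is the starting seed gene plus every remaining focus
#' gene inside its neighborhood (one connection away) — a single one-hop
#' step; wider growth is the expansion phase's job.
#'
#' @param kb a `knowledge_base`.
#' @param seed a focus molecule id.
#' @param remaining_focus focus ids not yet covered by earlier networks.
#' @return A `gene_network` whose genes are all focus genes.
#' @export
grow_seed_network <- function(kb, seed, remaining_focus) {
  stopifnot(length(seed) == 1)
  kb_vertex(kb, seed)
  nb <- neighborhood(kb, seed)
  added <- lex_sort(intersect(setdiff(remaining_focus, seed), nb))
  genes <- c(seed, added)
  prov <- data.frame(
    gene = genes,
    rule = c("seed", rep("neighborhood", length(added))),
    detail = c("", rep(paste0("neighbor of ", seed), length(added))),
    stringsAsFactors = FALSE)
  new_gene_network(genes, genes, prov)
}

#' Build all seed gene networks
#'
#' Repeatedly takes the top-ranked focus gene not yet covered by a network
#' as the next starting seed and grows its one-hop seed network, until every
#' non-excluded focus gene is represented. The resulting networks are
#' disjoint in focus genes.
#'
#' @param kb a `knowledge_base`.
#' @param focus character vector of focus molecule ids present in `kb`.
#' @return List of `gene_network` objects, with attribute `"excluded"`
#'   naming isolated focus genes left out of the ranking.
#' @export
build_seed_networks <- function(kb, focus) {
  ranked <- rank_focus_genes(kb, focus)
  excluded <- attr(ranked, "excluded")
  uncovered <- setdiff(as.character(ranked), excluded)
  order_rank <- setdiff(as.character(ranked), excluded)
  nets <- list()
  while (length(uncovered) > 0) {
    seed <- order_rank[order_rank %in% uncovered][1]
    net <- grow_seed_network(kb, seed, setdiff(uncovered, seed))
    uncovered <- setdiff(uncovered, net$genes)
    nets[[length(nets) + 1]] <- net
  }
  attr(nets, "excluded") <- excluded
  nets
}

#' Specific connectivity of a gene with respect to a network
#'
#' The greedy admission score for network expansion: the number of genes in
#' the intersection of the gene's neighborhood and the existing network,
#' divided by the number of genes in their union. A small neighborhood that
#' lies mostly inside the network scores high, so the metric favors genes
#' with large overlap and few neighbors at once.
#'
#' @param kb a `knowledge_base`.
#' @param g a molecule id.
#' @param network_genes non-empty character vector of network member ids.
#' @return Ratio in \[0, 1\].
#' @export
specific_connectivity <- function(kb, g, network_genes) {
  stopifnot(length(g) == 1, length(network_genes) > 0)
  nb <- neighborhood(kb, g)
  length(intersect(nb, network_genes)) / length(union(nb, network_genes))
}

#' Merge seed networks through bridging non-focus genes
#'
#' While some non-focus gene outside the networks is adjacent to at least
#' two of them and the merged network would not exceed the size cap, the
#' pair whose bridge has the highest specific connectivity with respect to
#' the pair's union is merged (greedily, re-evaluated after every merge).
#' Ties break lexicographically on bridge id, then on network positions.
#'
#' @param kb a `knowledge_base`.
#' @param nets list of `gene_network`s from [build_seed_networks()].
#' @param config an [analysis_config()].
#' @return List of `gene_network`s; a no-op when no bridge exists.
#' @export
merge_networks <- function(kb, nets, config = analysis_config()) {
  focus_all <- unique(unlist(lapply(nets, `[[`, "focus_genes")))
  repeat {
    if (length(nets) < 2) break
    members <- unique(unlist(lapply(nets, `[[`, "genes")))
    # molecules adjacent to each network
    nbrs <- lapply(nets, function(nt) {
      vi <- kb_vertex(kb, nt$genes)
      kb$ids[unique(unlist(kb$adj[vi]))]
    })
    best <- NULL
    for (i in seq_len(length(nets) - 1)) {
      for (j in seq.int(i + 1, length(nets))) {
        u <- union(nets[[i]]$genes, nets[[j]]$genes)
        # a bridge absorbed into one network during an earlier merge still
        # connects it to any other network it touches, at no size cost
        reach_i <- union(nbrs[[i]], nets[[i]]$genes)
        reach_j <- union(nbrs[[j]], nets[[j]]$genes)
        bridges <- setdiff(intersect(reach_i, reach_j), focus_all)
        bridges <- setdiff(bridges, intersect(nets[[i]]$genes,
                                              nets[[j]]$genes))
        bridges <- bridges[bridges %in% c(nbrs[[i]], nbrs[[j]])]
        new_size <- length(u) + as.integer(!(bridges %in% u))
        keep <- new_size <= config$max_network_size
        bridges <- bridges[keep]
        if (length(bridges) == 0) next
        sc <- vapply(bridges, specific_connectivity, 0, kb = kb,
                     network_genes = u)
        o <- order(-sc, bridges, method = "radix")[1]
        cand <- list(sc = sc[o], bridge = bridges[o], i = i, j = j)
        if (is.null(best) ||
            cand$sc > best$sc ||
            (cand$sc == best$sc &&
             (cand$bridge < best$bridge ||
              (cand$bridge == best$bridge &&
               (cand$i < best$i || (cand$i == best$i && cand$j < best$j)))))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    a <- nets[[best$i]]; b <- nets[[best$j]]
    genes <- c(a$genes, setdiff(b$genes, a$genes))
    prov <- rbind(a$provenance[, c("gene", "rule", "detail")],
                  b$provenance[b$provenance$gene %in%
                                 setdiff(b$genes, a$genes),
                               c("gene", "rule", "detail")])
    if (!best$bridge %in% genes) {
      genes <- c(genes, best$bridge)
      prov <- rbind(prov,
                    data.frame(gene = best$bridge, rule = "bridge",
                               detail = sprintf("joins networks (sc=%.6g)",
                                                best$sc),
                               stringsAsFactors = FALSE))
    }
    merged <- new_gene_network(genes,
                               union(a$focus_genes, b$focus_genes), prov)
    nets[[best$i]] <- merged
    nets[[best$j]] <- NULL
  }
  nets
}

#' Expand a network by specific connectivity
#'
#' Repeatedly admits the outside gene with the highest specific connectivity
#' (ties broken lexicographically) until the network reaches
#' `max_network_size` or the best remaining candidate scores 0. Candidates
#' are all knowledge-base molecules not yet in the network. The intersection
#' counts are maintained incrementally; each admission is logged in the
#' provenance.
#'
#' @param kb a `knowledge_base`.
#' @param net a `gene_network`.
#' @param config an [analysis_config()].
#' @return The expanded `gene_network`.
#' @export
expand_network <- function(kb, net, config = analysis_config()) {
  cap <- config$max_network_size
  if (length(net$genes) >= cap) return(net)
  nv <- length(kb$ids)
  member <- logical(nv)
  member[kb_vertex(kb, net$genes)] <- TRUE
  deg <- lengths(kb$adj)
  inter <- integer(nv)
  for (i in which(member)) {
    nb <- kb$adj[[i]]
    inter[nb] <- inter[nb] + 1L
  }
  genes <- net$genes
  prov <- net$provenance[, c("gene", "rule", "detail")]
  netsize <- length(genes)
  while (netsize < cap) {
    cand <- which(!member)
    if (length(cand) == 0) break
    sc <- inter[cand] / (deg[cand] + 1 + netsize - inter[cand])
    best_sc <- max(sc)
    if (best_sc == 0) break
    hits <- cand[sc == best_sc]
    b <- hits[lex_order(kb$ids[hits])[1]]
    member[b] <- TRUE
    nb <- kb$adj[[b]]
    inter[nb] <- inter[nb] + 1L
    netsize <- netsize + 1L
    genes <- c(genes, kb$ids[b])
    prov <- rbind(prov, data.frame(
      gene = kb$ids[b], rule = "expansion",
      detail = sprintf("sc=%.6g", best_sc), stringsAsFactors = FALSE))
  }
  new_gene_network(genes, net$focus_genes, prov)
}

#' Run the full core analysis
#'
#' The complete network-generation pipeline for one focus-gene set:
#' map symbols onto the knowledge base, rank focus genes by triangular
#' connectivity, grow one-hop seed networks until every connected focus
#' gene is covered, merge networks through bridging non-focus genes, expand
#' each network greedily by specific connectivity to the size cap, score
#' every network with the right-tailed hypergeometric test, and return the
#' networks sorted by descending score, truncated to `max_networks`.
#' Deterministic given `kb`, `focus` and `config`.
#'
#' @param kb a `knowledge_base`.
#' @param focus character vector of focus-gene symbols (e.g. one of the
#'   packaged [cipn_focus_gene_sets()]).
#' @param config an [analysis_config()].
#' @return A `core_analysis_result`: list with `networks` (scored networks,
#'   best first), `excluded` (data.frame of focus genes left out, with
#'   reasons `unmapped` or `isolated`), `N`, `K` and `config`.
#' @export
core_analysis <- function(kb, focus, config = analysis_config()) {
  mapped <- map_focus_genes(kb, focus)
  if (length(mapped$ids) == 0) {
    stop("none of the focus genes map onto the knowledge base")
  }
  nets <- build_seed_networks(kb, mapped$ids)
  isolated <- attr(nets, "excluded")
  nets <- merge_networks(kb, nets, config)
  nets <- lapply(nets, expand_network, kb = kb, config = config)
  nets <- lapply(nets, score_network, kb = kb, focus_ids = mapped$ids,
                 config = config)
  first_gene <- vapply(nets, function(x) x$genes[1], "")
  o <- order(-vapply(nets, `[[`, 0, "score"), first_gene, method = "radix")
  nets <- nets[o]
  if (length(nets) > config$max_networks) {
    nets <- nets[seq_len(config$max_networks)]
  }
  excluded <- data.frame(
    gene = c(mapped$unmapped, isolated),
    reason = c(rep("unmapped", length(mapped$unmapped)),
               rep("isolated", length(isolated))),
    stringsAsFactors = FALSE)
  structure(list(networks = nets, excluded = excluded,
                 N = if (isTRUE(config$count_nongene_nodes)) n_molecules(kb)
                     else sum(kb$molecules$kind == "gene"),
                 K = length(mapped$ids),
                 config = config, kb_name = kb$name),
            class = "core_analysis_result")
}

#' @export
print.core_analysis_result <- function(x, ...) {
  cat(sprintf("<core_analysis_result: %d network(s), N = %d, K = %d>\n",
              length(x$networks), x$N, x$K))
  for (i in seq_along(x$networks)) {
    nt <- x$networks[[i]]
    cat(sprintf("  %2d. n = %3d, n_f = %2d, score = %6.2f%s\n",
                i, nt$n, nt$n_f, nt$score,
                if (isTRUE(nt$significant)) " *" else ""))
  }
  if (nrow(x$excluded) > 0) {
    cat("  excluded:",
        paste(sprintf("%s (%s)", x$excluded$gene, x$excluded$reason),
              collapse = ", "), "\n")
  }
  invisible(x)
}
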