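#' Interaction relation vocabulary
#'
#' The closed set of relation types an interaction edge may carry. These are
#' the relationship categories used by curated molecular-interaction
#' knowledge bases: activation, binding, causation, chemical-chemical
#' interaction, expression, enzyme catalysis, inhibition, biochemical
#' modification, protein-protein binding and transcription.
#'
#' @return Character vector of the ten admissible relation strings.
#' @export
kb_relations <- function() {
  c("activation", "binding", "causation", "chemical-chemical interaction",
    "expression", "enzyme catalysis", "inhibition",
    "biochemical modification", "protein-protein binding", "transcription")
}

#' Molecule kind vocabulary
#'
#' Node types that can appear in a knowledge base: genes, chemicals,
#' complexes, biological processes, protein families and microRNA species.
#'
#' @return Character vector of the six admissible molecule kinds.
#' @export
molecule_kinds <- function() {
  c("gene", "chemical", "complex", "process", "protein-family", "microRNA")
}

# locale-independent lexicographic order (C collation), used for every
# deterministic tie-break in the package
lex_order <- function(x, ...) order(x, ..., method = "radix")

lex_sort <- function(x) x[lex_order(x)]

#' Construct a molecular-interaction knowledge base
#'
#' A knowledge base is a typed multigraph: a molecule table and an
#' interaction table. All connectivity metrics ([neighborhood()],
#' [triangular_connectivity()], [specific_connectivity()], degrees) operate
#' on the *undirected simple view*: parallel edges between the same pair of
#' molecules collapse to a single adjacency and self-loops are dropped.
#' Molecule identity is the `id` string, case-sensitive; `symbol` is
#' display-only.
#'
#' @param interactions data.frame with columns `source`, `relation`,
#'   `target` and logical (or 0/1) `direct`. `relation` must be one of
#'   [kb_relations()].
#' @param molecules optional data.frame with columns `id`, `symbol`, `kind`;
#'   if omitted, molecules are inferred from interaction endpoints with
#'   `kind = "gene"`. Supplying it explicitly is the only way to keep
#'   isolated molecules.
#' @param name label for the knowledge base.
#' @return An object of class `knowledge_base`.
#' @examples
#' kb <- knowledge_base(data.frame(
#'   source = c("A", "B", "A"),
#'   relation = c("binding", "activation", "inhibition"),
#'   target = c("B", "C", "C"),
#'   direct = TRUE))
#' neighborhood(kb, "A")
#' triangular_connectivity(kb, "A")
#' @export
knowledge_base <- function(interactions, molecules = NULL, name = "kb") {
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (nrow(interactions) == 0 && !all(c("source", "relation", "target") %in%
                                      names(interactions))) {
    interactions <- data.frame(source = character(), relation = character(),
                               target = character(), direct = logical())
  }
  required <- c("source", "relation", "target")
  if (!all(required %in% names(interactions))) {
    stop("interactions must have columns source, relation, target")
  }
  if (is.null(interactions$direct)) interactions$direct <- TRUE
  interactions$source <- as.character(interactions$source)
  interactions$target <- as.character(interactions$target)
  interactions$relation <- as.character(interactions$relation)
  interactions$direct <- as.logical(interactions$direct)
  bad_rel <- setdiff(unique(interactions$relation), kb_relations())
  if (length(bad_rel) > 0) {
    stop("unknown relation type(s): ", paste(bad_rel, collapse = ", "))
  }
  if (anyNA(interactions$direct)) stop("direct flag must be logical or 0/1")

  if (is.null(molecules)) {
    ids <- lex_sort(unique(c(interactions$source, interactions$target)))
    molecules <- data.frame(id = ids, symbol = ids,
                            kind = rep("gene", length(ids)),
                            stringsAsFactors = FALSE)
  } else {
    molecules <- as.data.frame(molecules, stringsAsFactors = FALSE)
    if (!"id" %in% names(molecules)) stop("molecules must have an id column")
    molecules$id <- as.character(molecules$id)
    if (is.null(molecules$symbol)) molecules$symbol <- molecules$id
    if (is.null(molecules$kind)) molecules$kind <- "gene"
    molecules <- molecules[, c("id", "symbol", "kind")]
  }
  if (any(!nzchar(molecules$id)) || anyNA(molecules$id)) {
    stop("molecule ids must be non-empty")
  }
  if (anyDuplicated(molecules$id)) {
    stop("duplicate molecule id(s): ",
         paste(unique(molecules$id[duplicated(molecules$id)]), collapse = ", "))
  }
  bad_kind <- setdiff(unique(molecules$kind), molecule_kinds())
  if (length(bad_kind) > 0) {
    stop("unknown molecule kind(s): ", paste(bad_kind, collapse = ", "))
  }
  dangling <- setdiff(unique(c(interactions$source, interactions$target)),
                      molecules$id)
  if (length(dangling) > 0) {
    stop("dangling interaction endpoint(s): ",
         paste(dangling, collapse = ", "))
  }

  kb <- structure(
    list(molecules = molecules, interactions = interactions, name = name),
    class = "knowledge_base")
  kb <- kb_index(kb)
  kb
}

# build the undirected simple view and an integer adjacency list; cached on
# the object because every metric and the greedy growth loops consume it
kb_index <- function(kb) {
  ids <- kb$molecules$id
  idx <- seq_along(ids)
  names(idx) <- ids
  adj <- vector("list", length(ids))
  if (nrow(kb$interactions) > 0) {
    s <- idx[kb$interactions$source]
    t <- idx[kb$interactions$target]
    keep <- s != t                       # simple view: drop self-loops
    a <- pmin(s[keep], t[keep])
    b <- pmax(s[keep], t[keep])
    key <- (a - 1) * length(ids) + b     # collapse parallel edges
    dup <- duplicated(key)
    a <- a[!dup]; b <- b[!dup]
    ends <- c(a, b)
    nbrs <- c(b, a)
    o <- order(ends, nbrs)
    adj <- unname(split(nbrs[o], factor(ends[o], levels = idx)))
  } else {
    adj <- rep(list(integer()), length(ids))
  }
  kb$ids <- ids
  kb$id_index <- idx
  kb$adj <- lapply(adj, as.integer)
  kb
}

kb_vertex <- function(kb, g) {
  i <- kb$id_index[g]
  if (anyNA(i)) {
    stop("unknown molecule id(s): ", paste(g[is.na(i)], collapse = ", "))
  }
  unname(i)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base '%s': %d molecules, %d interactions, %d simple edges>\n",
              x$name, nrow(x$molecules), nrow(x$interactions),
              sum(lengths(x$adj)) / 2))
  invisible(x)
}

#' Number of molecules / interactions in a knowledge base
#'
#' @param kb a `knowledge_base`.
#' @return Integer count.
#' @export
n_molecules <- function(kb) nrow(kb$molecules)

#' @rdname n_molecules
#' @export
n_interactions <- function(kb) nrow(kb$interactions)

#' Neighborhood of a molecule
#'
#' The neighborhood of a gene is the gene itself plus all genes exactly one
#' connection away from it on the undirected simple view of the knowledge
#' base.
#'
#' @param kb a `knowledge_base`.
#' @param g a single molecule id present in `kb`.
#' @return Character vector of molecule ids (sorted), always containing `g`.
#' @export
neighborhood <- function(kb, g) {
  stopifnot(length(g) == 1)
  i <- kb_vertex(kb, g)
  lex_sort(c(g, kb$ids[kb$adj[[i]]]))
}

#' Triangular connectivity of molecules
#'
#' The number of triangles through a gene: unordered pairs of its neighbors
#' that are themselves connected. This is the metric used to rank focus
#' genes when choosing starting seeds, computed on the undirected simple
#' view.
#'
#' @param kb a `knowledge_base`.
#' @param g vector of molecule ids; defaults to every molecule.
#' @return Named integer vector of triangle counts.
#' @export
triangular_connectivity <- function(kb, g = kb$ids) {
  vi <- kb_vertex(kb, g)
  mark <- logical(length(kb$ids))
  out <- vapply(vi, function(i) {
    nb <- kb$adj[[i]]
    if (length(nb) < 2) return(0L)
    mark[nb] <- TRUE
    tri <- sum(vapply(nb, function(u) sum(mark[kb$adj[[u]]]), integer(1)))
    mark[nb] <- FALSE
    as.integer(tri / 2)
  }, integer(1))
  names(out) <- g
  out
}

#' Induced subnetwork
#'
#' Materializes the subgraph on a gene set: exactly the given molecules plus
#' every knowledge-base interaction with both endpoints inside the set.
#'
#' @param kb a `knowledge_base`.
#' @param genes character vector of molecule ids, all present in `kb`.
#' @return A `knowledge_base` restricted to `genes`.
#' @export
induced_network <- function(kb, genes) {
  genes <- unique(as.character(genes))
  kb_vertex(kb, genes)  # validates
  keep <- kb$interactions$source %in% genes & kb$interactions$target %in% genes
  knowledge_base(kb$interactions[keep, , drop = FALSE],
                 molecules = kb$molecules[kb$molecules$id %in% genes, ,
                                          drop = FALSE],
                 name = paste0(kb$name, ":induced"))
}

#' Degree sequence of a knowledge base
#'
#' Simple-view degrees of all molecules, in descending order.
#'
#' @param kb a `knowledge_base`.
#' @return Integer vector, descending.
#' @export
degree_sequence <- function(kb) {
  sort(lengths(kb$adj), decreasing = TRUE)
}

#' Read a knowledge base from disk
#'
#' Two formats are supported. `"sif"` is a tab-separated interaction list:
#' `source TAB relation TAB target TAB direct` with `direct` coded 0/1 (a
#' missing fourth field defaults to 1), UTF-8, one interaction per line,
#' `#` comment lines allowed. `"graphml"` round-trips molecule kinds,
#' symbols and isolated molecules as well; sif keeps interactions only.
#'
#' @param path file to read.
#' @param format `"sif"` or `"graphml"`.
#' @param name label for the loaded knowledge base; defaults to the file
#'   name.
#' @return A `knowledge_base`.
#' @seealso [save_kb()] — `save_kb(load_kb(f))` is byte-identical to `f` for
#'   a canonical (comment-free, 4-field) sif file.
#' @export
load_kb <- function(path, format = c("sif", "graphml"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("knowledge base file not found: ", path)
  if (is.null(name)) name <- basename(path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    molecules <- data.frame(
      id = va$name,
      symbol = if (!is.null(va$symbol)) va$symbol else va$name,
      kind = if (!is.null(va$kind)) va$kind else "gene",
      stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g, names = TRUE)
    ea <- igraph::edge_attr(g)
    interactions <- data.frame(
      source = el[, 1],
      relation = if (!is.null(ea$relation)) ea$relation
                 else rep("binding", nrow(el)),
      target = el[, 2],
      direct = if (!is.null(ea$direct)) as.logical(ea$direct)
               else rep(TRUE, nrow(el)),
      stringsAsFactors = FALSE)
    return(knowledge_base(interactions, molecules, name = name))
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3 | nf > 4)
  if (length(bad) > 0) {
    stop(sprintf("malformed sif line %d: expected 3 or 4 tab-separated fields, got %d",
                 rows[bad[1]], nf[bad[1]]))
  }
  src <- vapply(fields, `[[`, "", 1)
  rel <- vapply(fields, `[[`, "", 2)
  tgt <- vapply(fields, `[[`, "", 3)
  dflag <- vapply(fields, function(f) if (length(f) == 4) f[[4]] else "1", "")
  bad_rel <- which(!(rel %in% kb_relations()))
  if (length(bad_rel) > 0) {
    stop(sprintf("malformed sif line %d: unknown relation '%s'",
                 rows[bad_rel[1]], rel[bad_rel[1]]))
  }
  bad_dir <- which(!(dflag %in% c("0", "1")))
  if (length(bad_dir) > 0) {
    stop(sprintf("malformed sif line %d: direct flag must be 0 or 1, got '%s'",
                 rows[bad_dir[1]], dflag[bad_dir[1]]))
  }
  knowledge_base(
    data.frame(source = src, relation = rel, target = tgt,
               direct = dflag == "1", stringsAsFactors = FALSE),
    name = name)
}

#' Write a knowledge base to disk
#'
#' @param kb a `knowledge_base`.
#' @param path output file.
#' @param format `"sif"` (interactions only, canonical 4-field dialect) or
#'   `"graphml"` (full fidelity: kinds, symbols, isolated molecules).
#' @return `path`, invisibly.
#' @export
save_kb <- function(kb, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    con <- file(path, open = "wb")  # fixed \n endings for byte-stable output
    on.exit(close(con))
    if (nrow(kb$interactions) > 0) {
      writeLines(paste(kb$interactions$source, kb$interactions$relation,
                       kb$interactions$target,
                       as.integer(kb$interactions$direct), sep = "\t"),
                 con = con, useBytes = TRUE)
    }
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    kb$interactions[, c("source", "target", "relation", "direct")],
    directed = FALSE, vertices = kb$molecules)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
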