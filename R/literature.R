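#' Chemotherapy-agent group labels
#'
#' The 17 agent (or agent-combination) groups under which the curated
#' neuropathy studies are summarized: platinum (P), taxane (T),
#' platinum/taxane (P/T), bortezomib (B), bortezomib/vincristine (B/V),
#' thalidomide (Th), methotrexate (M), cytarabine (Cyt) and the remaining
#' combination regimens.
#'
#' @return Character vector of the 17 agent codes, in canonical order.
#' @export
agent_levels <- function() {
  c("P", "T", "P/T", "B", "B/V", "Th", "M", "Cyt", "P/F", "P/S", "T/G",
    "P/F/L", "P/F/I", "Pr/V/M", "P/C", "P/F/I/L", "R/Cyc/D/V/Pr")
}

ethnicity_levels <- function() c("W", "A", "AA", "H", "NA")

cipn_fixture_path <- function(file = "") {
  p <- system.file("extdata", "cipn", file, package = "cipnnet")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

#' Verify packaged fixture checksums
#'
#' Compares the MD5 of every packaged curation file against the shipped
#' manifest; any mismatch is an integrity error.
#'
#' @return Invisibly `TRUE` on success.
#' @export
verify_fixture_checksums <- function() {
  man <- utils::read.delim(cipn_fixture_path("MANIFEST.tsv"),
                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(man))) {
    got <- unname(tools::md5sum(cipn_fixture_path(man$file[i])))
    if (!identical(got, man$md5[i])) {
      stop("fixture checksum mismatch for ", man$file[i],
           ": expected ", man$md5[i], ", got ", got)
    }
  }
  invisible(TRUE)
}

#' Packaged study records
#'
#' The curated genetic-association studies of chemotherapy-induced
#' peripheral neuropathy (2003-2014): publication year, first author,
#' ethnicity of the patient population, cancer type, sample size, phenotype,
#' agent group and the significant genes reported (IPA symbol spelling).
#' Studies that reported no significant gene are retained with an empty
#' gene set — they still count toward per-agent paper totals.
#'
#' @param path optional path to a study TSV; defaults to the packaged table.
#' @return data.frame with one row per study; `ethnicity` and `genes` are
#'   list columns of character vectors.
#' @export
cipn_studies <- function(path = NULL) {
  if (is.null(path)) path <- cipn_fixture_path("studies.tsv")
  # "NA" is the not-available ethnicity code, not a missing value
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  df$year <- as.integer(df$year)
  df$sample_size <- as.integer(df$sample_size)
  split_field <- function(x) {
    lapply(strsplit(x, ",", fixed = TRUE),
           function(v) trimws(v[nzchar(trimws(v))]))
  }
  df$ethnicity <- split_field(df$ethnicity)
  df$genes <- split_field(df$genes)
  if (any(df$year < 2003 | df$year > 2014)) {
    stop("study year outside the curated range 2003-2014")
  }
  if (any(df$sample_size < 1)) stop("sample_size must be >= 1")
  bad <- setdiff(unique(df$agent), agent_levels())
  if (length(bad) > 0) stop("unknown agent group(s): ",
                            paste(bad, collapse = ", "))
  bad_eth <- setdiff(unique(unlist(df$ethnicity)), ethnicity_levels())
  if (length(bad_eth) > 0) stop("unknown ethnicity code(s): ",
                                paste(bad_eth, collapse = ", "))
  df
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB ...`.
#'
#' @param path file to read or write.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, ""), con = con, useBytes = TRUE)
  invisible(path)
}

#' Packaged focus-gene sets
#'
#' The literature-derived focus genes for the three agent groups studied
#' often enough to analyze: 26 platinum, 19 taxane and 7 platinum/taxane
#' genes.
#'
#' @param path optional path to a GMT file; defaults to the packaged sets.
#' @return Named list of character vectors
#'   (`platinum`, `taxane`, `platinum/taxane`).
#' @export
cipn_focus_gene_sets <- function(path = NULL) {
  if (is.null(path)) path <- cipn_fixture_path("focus_genes.gmt")
  sets <- read_gmt(path)
  if (any(vapply(sets, anyDuplicated, 0L) > 0)) {
    stop("duplicate gene symbol within a focus gene set")
  }
  sets
}

#' Focus genes for one agent
#'
#' Looks up the packaged focus-gene list for an agent group. Only platinum,
#' taxane and platinum/taxane have focus lists; any other agent raises a
#' not-available error naming the agent.
#'
#' @param sets named list of focus gene sets (see
#'   [cipn_focus_gene_sets()]).
#' @param agent agent name (`"platinum"`, `"taxane"`, `"platinum/taxane"`)
#'   or the corresponding code (`"P"`, `"T"`, `"P/T"`).
#' @return Character vector of focus-gene symbols.
#' @export
focus_genes_for_agent <- function(sets, agent) {
  key <- switch(agent,
                "P" = "platinum", "T" = "taxane", "P/T" = "platinum/taxane",
                agent)
  if (!key %in% names(sets)) {
    stop("no focus-gene list available for agent '", agent, "'")
  }
  sets[[key]]
}

#' Summarize study records by agent
#'
#' Builds the agent-by-gene evidence matrix: cell (g, a) is the number of
#' studies in agent group a that list gene g among their significant genes.
#' Studies with no significant genes contribute to the per-agent paper
#' totals but to no cell.
#'
#' @param records study records as returned by [cipn_studies()].
#' @return An `agent_gene_matrix`: integer matrix (genes x the 17 agent
#'   groups) with attributes `papers_per_agent`, `genes_per_agent` and
#'   `agents_per_gene`.
#' @export
summarize_by_agent <- function(records) {
  if (nrow(records) == 0) stop("no study records to summarize")
  agents <- agent_levels()
  genes <- lex_sort(unique(unlist(records$genes)))
  m <- matrix(0L, nrow = length(genes), ncol = length(agents),
              dimnames = list(genes, agents))
  for (i in seq_len(nrow(records))) {
    g <- records$genes[[i]]
    if (length(g) > 0) {
      m[cbind(match(g, genes), match(records$agent[i], agents))] <-
        m[cbind(match(g, genes), match(records$agent[i], agents))] + 1L
    }
  }
  papers <- vapply(agents, function(a) sum(records$agent == a), integer(1))
  structure(m,
            papers_per_agent = papers,
            genes_per_agent = colSums(m > 0),
            agents_per_gene = rowSums(m > 0),
            class = c("agent_gene_matrix", "matrix", "array"))
}

#' Packaged agent-by-gene evidence matrix
#'
#' The frozen summary matrix derived from the packaged study records (the
#' packaged records reproduce it cell-for-cell through
#' [summarize_by_agent()]).
#'
#' @param path optional path to a matrix TSV; defaults to the packaged
#'   fixture.
#' @return Integer matrix, genes in rows, the 17 agent groups in columns.
#' @export
cipn_agent_gene_matrix <- function(path = NULL) {
  if (is.null(path)) path <- cipn_fixture_path("agent_gene_matrix.tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (any(rowSums(m) < 1)) stop("agent-gene matrix has an empty gene row")
  m
}

#' Packaged hub tables
#'
#' The published hub listings (genes with at least 15 connections in the
#' most significant network), for the platinum and the platinum/taxane
#' analyses, ranked by connection count.
#'
#' @param analysis `"platinum"` or `"platinum/taxane"`.
#' @param path optional path to a hub TSV; defaults to the packaged table.
#' @return data.frame with columns `gene`, `connections`, `is_focus`.
#' @export
cipn_hub_table <- function(analysis = c("platinum", "platinum/taxane"),
                           path = NULL) {
  analysis <- match.arg(analysis)
  if (is.null(path)) {
    file <- if (analysis == "platinum") "hubs_platinum.tsv"
            else "hubs_platinum_taxane.tsv"
    path <- cipn_fixture_path(file)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$connections <- as.integer(df$connections)
  df$is_focus <- as.logical(df$is_focus)
  if (any(df$connections < 15)) {
    stop("hub table entry below the 15-connection filter")
  }
  if (is.unsorted(rev(df$connections))) {
    stop("hub table must be sorted by descending connection count")
  }
  df
}

#' Load all packaged curation fixtures
#'
#' Verifies the fixture checksums, loads the study records, the agent-gene
#' matrix, the focus-gene sets and both hub tables, and cross-checks the
#' matrix against the per-agent paper totals.
#'
#' @return List with elements `studies`, `matrix`, `focus_sets`, `hubs`
#'   (list with `platinum` and `platinum/taxane`).
#' @export
load_fixtures <- function() {
  verify_fixture_checksums()
  studies <- cipn_studies()
  m <- cipn_agent_gene_matrix()
  papers <- vapply(agent_levels(), function(a) sum(studies$agent == a),
                   integer(1))
  # a cell can never exceed the number of packaged papers for its agent
  cap <- matrix(papers[colnames(m)], nrow(m), ncol(m), byrow = TRUE)
  if (any(m > cap)) {
    over <- which(m > cap, arr.ind = TRUE)
    stop("agent-gene matrix cell exceeds per-agent paper count: ",
         paste(rownames(m)[over[, 1]], colnames(m)[over[, 2]],
               collapse = "; "))
  }
  list(studies = studies,
       matrix = m,
       focus_sets = cipn_focus_gene_sets(),
       hubs = list("platinum" = cipn_hub_table("platinum"),
                   "platinum/taxane" = cipn_hub_table("platinum/taxane")))
}
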