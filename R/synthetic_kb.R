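# run expr with a private RNG stream; the caller's .Random.seed is untouched
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Describe a planted dense module
#'
#' A planted module emulates a pathway neighborhood: `module_size` new
#' molecules whose induced subgraph has independent internal edges at
#' probability `intra_density`, tied into the background scaffold by
#' `attach_edges` random edges. The first `focus_count` members are recorded
#' as focus genes in the ground truth, giving recovery tests a known answer.
#'
#' @param module_size number of molecules in the module.
#' @param focus_count how many members are designated focus genes
#'   (`<= module_size`).
#' @param intra_density probability in \[0, 1\] of each intra-module edge.
#' @param attach_edges number of edges tying the module to the scaffold.
#' @return A list describing the module, for `planted_modules` in
#'   [synthetic_kb_config()].
#' @export
planted_module <- function(module_size, focus_count, intra_density,
                           attach_edges = 5L) {
  stopifnot(module_size >= 1, focus_count >= 0,
            focus_count <= module_size,
            intra_density >= 0, intra_density <= 1,
            attach_edges >= 0)
  list(module_size = as.integer(module_size),
       focus_count = as.integer(focus_count),
       intra_density = intra_density,
       attach_edges = as.integer(attach_edges))
}

#' Configuration for the synthetic knowledge-base generator
#'
#' The generator stands in for a proprietary curated interactome. It builds
#' a preferential-attachment scaffold (heavy-tailed degrees, the regime in
#' which interactome degree distributions are usually discussed), plants
#' locally dense modules carrying designated focus genes, samples relation
#' types from the ten-value interaction vocabulary and flags edges as
#' direct/indirect. All randomness flows from the single `seed`; identical
#' configurations produce byte-identical knowledge bases.
#'
#' @param n_background number of scaffold molecules.
#' @param m_attach edges added per new scaffold node (preferential
#'   attachment); total scaffold edges are
#'   `(n_background - m_attach) * m_attach`.
#' @param planted_modules list of [planted_module()] descriptions.
#' @param relation_weights named numeric vector of sampling weights over
#'   [kb_relations()]; default uniform.
#' @param scatter_focus number of additional focus genes scattered on the
#'   scaffold (negatives for recovery tests).
#' @param focus_symbols optional character vector of ids to give focus
#'   genes (module focus members first, then scattered ones), so that a
#'   packaged focus-gene list can be planted into a synthetic knowledge
#'   base.
#' @param direct_prob probability that an edge is a direct interaction.
#' @param seed integer RNG seed.
#' @param name label for the generated knowledge base.
#' @return A `synthetic_kb_config` list.
#' @export
synthetic_kb_config <- function(n_background = 5000, m_attach = 2,
                                planted_modules = list(),
                                relation_weights = NULL,
                                scatter_focus = 0,
                                focus_symbols = NULL,
                                direct_prob = 0.7,
                                seed = 1,
                                name = "synthetic-kb") {
  if (is.null(relation_weights)) {
    relation_weights <- stats::setNames(rep(1, length(kb_relations())),
                                        kb_relations())
  }
  if (is.null(names(relation_weights)) ||
      !all(names(relation_weights) %in% kb_relations())) {
    stop("relation_weights must be named by relation types from kb_relations()")
  }
  if (any(relation_weights < 0) || sum(relation_weights) <= 0) {
    stop("relation_weights must be non-negative and not all zero")
  }
  stopifnot(n_background >= 2, m_attach >= 1, m_attach < n_background,
            scatter_focus >= 0, direct_prob >= 0, direct_prob <= 1)
  if (length(planted_modules) > 0) {
    ok <- vapply(planted_modules, function(m) {
      all(c("module_size", "focus_count", "intra_density", "attach_edges")
          %in% names(m))
    }, logical(1))
    if (!all(ok)) stop("planted_modules must be built with planted_module()")
    if (any(vapply(planted_modules, `[[`, 0, "attach_edges") > n_background)) {
      stop("attach_edges cannot exceed n_background")
    }
  }
  structure(list(n_background = as.integer(n_background),
                 m_attach = as.integer(m_attach),
                 planted_modules = planted_modules,
                 relation_weights = relation_weights,
                 scatter_focus = as.integer(scatter_focus),
                 focus_symbols = focus_symbols,
                 direct_prob = direct_prob,
                 seed = as.integer(seed),
                 name = name),
            class = "synthetic_kb_config")
}

#' Generate a synthetic knowledge base with ground truth
#'
#' Builds the preferential-attachment scaffold, plants the configured dense
#' modules and returns both the knowledge base and a ground-truth table
#' (molecule id, module membership, focus flag) for recovery tests.
#' Fully reproducible: the same configuration (including seed) always yields
#' an identical knowledge base.
#'
#' @param config a [synthetic_kb_config()].
#' @return List with elements `kb` (a `knowledge_base`) and `truth`
#'   (data.frame with columns `id`, `module`, `is_focus`).
#' @examples
#' sim <- generate_kb(synthetic_kb_config(
#'   n_background = 200, m_attach = 2,
#'   planted_modules = list(planted_module(10, 5, 0.8)), seed = 7))
#' sim$kb
#' table(sim$truth$module, useNA = "ifany")
#' @export
generate_kb <- function(config) {
  if (!inherits(config, "synthetic_kb_config")) {
    stop("config must be built with synthetic_kb_config()")
  }
  with_local_seed(config$seed, {
    n <- config$n_background
    m <- config$m_attach
    wid <- max(5L, nchar(as.character(n)))
    scaffold_ids <- sprintf(paste0("G%0", wid, "d"), seq_len(n))

    # preferential attachment: each node past the first m attaches to m
    # distinct earlier nodes with probability proportional to degree + 1
    deg <- integer(n)
    total <- (n - m) * m
    e_from <- integer(total)
    e_to <- integer(total)
    k <- 0L
    for (i in seq.int(m + 1L, n)) {
      targets <- sample.int(i - 1L, m, prob = deg[seq_len(i - 1L)] + 1)
      e_from[k + seq_len(m)] <- i
      e_to[k + seq_len(m)] <- targets
      deg[targets] <- deg[targets] + 1L
      deg[i] <- deg[i] + m
      k <- k + m
    }
    src <- scaffold_ids[e_from]
    tgt <- scaffold_ids[e_to]

    ids <- scaffold_ids
    module_of <- rep(NA_integer_, n)
    focus <- logical(n)
    focus_slots <- integer()   # indices of focus genes, in assignment order

    for (j in seq_along(config$planted_modules)) {
      mod <- config$planted_modules[[j]]
      sz <- mod$module_size
      mids <- sprintf("M%d_%03d", j, seq_len(sz))
      base <- length(ids)
      ids <- c(ids, mids)
      module_of <- c(module_of, rep(j, sz))
      f <- logical(sz)
      f[seq_len(mod$focus_count)] <- TRUE
      focus <- c(focus, f)
      focus_slots <- c(focus_slots, base + seq_len(mod$focus_count))

      if (sz >= 2) {
        pairs <- utils::combn(sz, 2)
        on <- stats::runif(ncol(pairs)) < mod$intra_density
        if (any(on)) {
          src <- c(src, mids[pairs[1, on]])
          tgt <- c(tgt, mids[pairs[2, on]])
        }
      }
      if (mod$attach_edges > 0) {
        anchors <- sample.int(n, mod$attach_edges, replace = FALSE)
        members <- sample.int(sz, mod$attach_edges, replace = TRUE)
        src <- c(src, mids[members])
        tgt <- c(tgt, scaffold_ids[anchors])
      }
    }

    if (config$scatter_focus > 0) {
      sc <- sample.int(n, config$scatter_focus, replace = FALSE)
      focus[sc] <- TRUE
      focus_slots <- c(focus_slots, sc)
    }

    if (!is.null(config$focus_symbols)) {
      syms <- unique(as.character(config$focus_symbols))
      take <- min(length(syms), length(focus_slots))
      if (take > 0) {
        old <- ids[focus_slots[seq_len(take)]]
        new <- syms[seq_len(take)]
        names(new) <- old
        ids[focus_slots[seq_len(take)]] <- new
        hit_s <- src %in% old
        hit_t <- tgt %in% old
        src[hit_s] <- new[src[hit_s]]
        tgt[hit_t] <- new[tgt[hit_t]]
      }
    }

    w <- config$relation_weights
    relation <- sample(names(w), length(src), replace = TRUE,
                       prob = w / sum(w))
    direct <- stats::runif(length(src)) < config$direct_prob

    kb <- knowledge_base(
      data.frame(source = src, relation = relation, target = tgt,
                 direct = direct, stringsAsFactors = FALSE),
      molecules = data.frame(id = ids, symbol = ids, kind = "gene",
                             stringsAsFactors = FALSE),
      name = config$name)
    truth <- data.frame(id = ids, module = module_of, is_focus = focus,
                        stringsAsFactors = FALSE)
    list(kb = kb, truth = truth)
  })
}

#' Write generator ground truth as TSV
#'
#' @param truth the `truth` component returned by [generate_kb()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
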