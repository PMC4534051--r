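test_that("focus genes rank by descending triangular connectivity with lexicographic ties", {
  kb <- make_kb(c("A-B", "A-C", "A-D", "B-C", "B-D", "C-D"),
                molecules = data.frame(id = c("A", "B", "C", "D", "E")))
  ranked <- rank_focus_genes(kb, c("E", "D", "C", "B", "A"))
  expect_equal(as.character(ranked), c("A", "B", "C", "D", "E"))
  expect_equal(attr(ranked, "excluded"), "E")

  # star with all ties at zero triangles: fully lexicographic
  star <- kb_star(4)
  ranked <- rank_focus_genes(star, c("l2", "c", "l1"))
  expect_equal(as.character(ranked), c("c", "l1", "l2"))
  expect_length(attr(ranked, "excluded"), 0)

  expect_equal(as.character(rank_focus_genes(star, "l3")), "l3")
  expect_error(rank_focus_genes(star, character()), "no mappable")
})

test_that("seed networks grow exactly one hop from the seed", {
  star <- kb_star(4)
  net <- grow_seed_network(star, "c", c("l1", "l3"))
  expect_setequal(net$genes, c("c", "l1", "l3"))
  expect_equal(net$provenance$rule, c("seed", "neighborhood", "neighborhood"))

  net <- grow_seed_network(star, "l1", character())
  expect_equal(net$genes, "l1")

  # focus genes on a 4-cycle: the two-hop diagonal gene is not added
  kb <- make_kb(c("f1-f2", "f2-f3", "f3-f4", "f4-f1",
                  "f1-x1", "x1-x2", "x2-x3", "x3-x4"))
  net <- grow_seed_network(kb, "f1", c("f2", "f3", "f4"))
  expect_setequal(net$genes, c("f1", "f2", "f4"))
  expect_false("f3" %in% net$genes)
})

test_that("seed networks cover all focus genes and are focus-disjoint", {
  # two disjoint focus components -> two seed networks
  kb <- make_kb(c("a-b", "p-q"))
  nets <- build_seed_networks(kb, c("a", "b", "p", "q"))
  expect_length(nets, 2)
  # mutually adjacent focus genes -> a single network
  nets <- build_seed_networks(kb_triangle(), c("A", "B", "C"))
  expect_length(nets, 1)
  # property: coverage and disjointness on random instances
  for (seed in 1:10) {
    kb <- random_kb(20, 0.15, seed = seed)
    focus <- kb$ids[seq(1, 20, by = 2)]
    nets <- build_seed_networks(kb, focus)
    covered <- unlist(lapply(nets, `[[`, "focus_genes"))
    expect_equal(anyDuplicated(covered), 0)
    expect_setequal(c(covered, attr(nets, "excluded")), focus)
  }
})

test_that("seed networks recover planted clique modules with ground truth", {
  sim <- generate_kb(synthetic_kb_config(
    n_background = 400, m_attach = 2,
    planted_modules = list(planted_module(12, 6, 1.0, attach_edges = 2),
                           planted_module(12, 6, 1.0, attach_edges = 2)),
    seed = 11))
  focus <- sim$truth$id[sim$truth$is_focus]
  nets <- build_seed_networks(sim$kb, focus)
  expect_length(nets, 2)
  got <- lapply(nets, function(x) sort(x$focus_genes))
  want <- lapply(split(sim$truth$id[sim$truth$is_focus],
                       sim$truth$module[sim$truth$is_focus]), sort)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
})

test_that("specific connectivity is intersection over union of neighborhood and network", {
  kb <- make_kb(c("g-a", "g-b", "g-c", "d-e"))
  expect_equal(specific_connectivity(kb, "g", c("g", "a", "b", "c")), 1)
  expect_equal(specific_connectivity(kb, "g", c("d", "e")), 0)
  # neighborhood {g,a,b,c} vs network {b,c,d}: 2 / 5
  expect_equal(specific_connectivity(kb, "g", c("b", "c", "d")), 0.4)
})

test_that("networks merge through the best bridging non-focus gene", {
  kb <- make_kb(c("f1-f2", "g1-g2", "f1-x", "g1-x", "f2-y"))
  nets <- build_seed_networks(kb, c("f1", "f2", "g1", "g2"))
  expect_length(nets, 2)
  merged <- merge_networks(kb, nets)
  expect_length(merged, 1)
  expect_true("x" %in% merged[[1]]$genes)
  prov <- merged[[1]]$provenance
  expect_equal(prov$gene[prov$rule == "bridge"], "x")
  expect_setequal(merged[[1]]$focus_genes, c("f1", "f2", "g1", "g2"))

  # no connecting non-focus gene: merging is a no-op
  kb2 <- make_kb(c("f1-f2", "g1-g2"))
  nets2 <- build_seed_networks(kb2, c("f1", "f2", "g1", "g2"))
  expect_identical(merge_networks(kb2, nets2), nets2)

  # the size cap blocks a merge that would exceed it
  small <- analysis_config(max_network_size = 4)
  expect_length(merge_networks(kb, nets, small), 2)
})

test_that("three planted modules sharing one hub merge through it", {
  # hub h touches one focus gene of each clique module
  kb <- make_kb(c("a1-a2", "b1-b2", "c1-c2", "a1-h", "b1-h", "c1-h"))
  nets <- build_seed_networks(kb, c("a1", "a2", "b1", "b2", "c1", "c2"))
  expect_length(nets, 3)
  merged <- merge_networks(kb, nets)
  expect_length(merged, 1)
  expect_true("h" %in% merged[[1]]$genes)
})

test_that("expansion is capped, admits only positive scorers and is greedy-optimal", {
  kb <- make_kb(c("a-b", "a-c", "b-c", "d-e"))
  net <- grow_seed_network(kb, "a", c("b"))
  # already at cap: unchanged
  same <- expand_network(kb, net, analysis_config(max_network_size = 2))
  expect_equal(same$genes, net$genes)
  # c's neighborhood is inside net + itself; d, e are disjoint: only c joins
  grown <- expand_network(kb, net, analysis_config(max_network_size = 4))
  expect_equal(setdiff(grown$genes, net$genes), "c")
  expect_length(grown$genes, 3)  # stopped at best score 0, not at the cap
})

test_that("each expansion step picks the exhaustive-recomputation winner", {
  replay_matches_oracle <- function(kb, start, cap) {
    net <- expand_network(kb, start, analysis_config(max_network_size = cap))
    added <- net$provenance$gene[net$provenance$rule == "expansion"]
    genes <- start$genes
    for (g in added) {
      oracle <- best_expansion_candidate(kb, genes)
      expect_equal(g, oracle$gene)
      genes <- c(genes, g)
    }
    # termination was justified: cap hit or no positive candidate left
    if (length(genes) < cap) {
      expect_null(best_expansion_candidate(kb, genes))
    }
    net
  }
  # 12-node handcrafted instance, cap 6
  kb <- random_kb(12, 0.3, seed = 5)
  start <- grow_seed_network(kb, kb$ids[1], kb$ids[2])
  replay_matches_oracle(kb, start, 6)
  # random instances up to 50 nodes
  for (seed in 1:8) {
    n <- 20 + 3 * seed
    kb <- random_kb(n, 0.12, seed = 100 + seed)
    start <- grow_seed_network(kb, kb$ids[1], kb$ids[1:6])
    replay_matches_oracle(kb, start, min(n, 18))
  }
})

test_that("raising the size cap only extends the admission sequence", {
  kb <- random_kb(30, 0.15, seed = 77)
  start <- grow_seed_network(kb, kb$ids[1], kb$ids[1:4])
  small <- expand_network(kb, start, analysis_config(max_network_size = 8))
  large <- expand_network(kb, start, analysis_config(max_network_size = 16))
  expect_identical(small$genes, large$genes[seq_along(small$genes)])
})

test_that("core analysis is deterministic and accounts for every focus gene", {
  cfg <- synthetic_kb_config(
    n_background = 500, m_attach = 2,
    planted_modules = list(planted_module(15, 8, 0.6, attach_edges = 3)),
    scatter_focus = 3, seed = 21)
  sim <- generate_kb(cfg)
  focus <- sim$truth$id[sim$truth$is_focus]
  res1 <- core_analysis(sim$kb, focus, analysis_config(max_network_size = 40))
  res2 <- core_analysis(sim$kb, focus, analysis_config(max_network_size = 40))
  expect_identical(res1$networks, res2$networks)
  expect_identical(res1$excluded, res2$excluded)

  in_nets <- unlist(lapply(res1$networks, `[[`, "focus_genes"))
  expect_equal(anyDuplicated(in_nets), 0)
  expect_setequal(c(in_nets, res1$excluded$gene), focus)
  expect_true(all(diff(vapply(res1$networks, `[[`, 0, "score")) <= 0))
  expect_true(all(vapply(res1$networks, function(x)
    length(x$genes) <= 40, logical(1))))
})

test_that("isolated and unmapped focus genes end up in the exclusion report", {
  kb <- make_kb("A-B", molecules = data.frame(id = c("A", "B", "LONE")))
  res <- core_analysis(kb, c("LONE", "GHOST"),
                       analysis_config(max_network_size = 5))
  expect_length(res$networks, 0)
  expect_setequal(res$excluded$gene, c("LONE", "GHOST"))
  expect_equal(res$excluded$reason[res$excluded$gene == "LONE"], "isolated")
  expect_equal(res$excluded$reason[res$excluded$gene == "GHOST"], "unmapped")
  expect_error(core_analysis(kb, "GHOST"), "none of the focus genes")
})

test_that("the returned network count respects max_networks", {
  kb <- make_kb(c("a-b", "p-q", "x-y"))
  res <- core_analysis(kb, c("a", "b", "p", "q", "x", "y"),
                       analysis_config(max_network_size = 10,
                                       max_networks = 2))
  expect_length(res$networks, 2)
})
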