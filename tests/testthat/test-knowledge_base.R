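test_that("sif parsing builds the expected molecules and interactions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tbinding\tB", "B\tactivation\tC", "A\tinhibition\tC"), f)
  kb <- load_kb(f)
  expect_equal(nrow(kb$molecules), 3)
  expect_equal(nrow(kb$interactions), 3)
  expect_setequal(kb$molecules$id, c("A", "B", "C"))
  expect_true(all(kb$interactions$direct))  # missing flag defaults to direct

  writeLines(character(), f)
  empty <- load_kb(f)
  expect_equal(nrow(empty$molecules), 0)
  expect_equal(nrow(empty$interactions), 0)
})

test_that("malformed sif input is rejected with the offending line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\tbinding\tB\t1", "A\tbinding"), f)
  expect_error(load_kb(f), "line 3")
  writeLines(c("A\tfriendship\tB\t1"), f)
  expect_error(load_kb(f), "unknown relation")
  expect_error(load_kb(f), "line 1")
  writeLines(c("A\tbinding\tB\t2"), f)
  expect_error(load_kb(f), "direct flag")
})

test_that("knowledge base invariants are enforced at construction", {
  expect_error(knowledge_base(
    data.frame(source = "A", relation = "binding", target = "B"),
    molecules = data.frame(id = "A")), "dangling")
  expect_error(knowledge_base(
    data.frame(source = "A", relation = "binding", target = "B"),
    molecules = data.frame(id = c("A", "A", "B"))), "duplicate")
  expect_error(knowledge_base(
    data.frame(source = "A", relation = "binding", target = "B"),
    molecules = data.frame(id = c("A", "B"), kind = "widget")),
    "unknown molecule kind")
})

test_that("sif save/load round-trips byte-identically on the packaged fixture", {
  src <- system.file("extdata", "example_kb.tsv", package = "cipnnet")
  kb <- load_kb(src)
  out <- withr::local_tempfile(fileext = ".tsv")
  save_kb(kb, out, "sif")
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(src, "raw", file.size(src)))
})

test_that("graphml round-trip preserves molecules, kinds and relations", {
  kb <- knowledge_base(
    data.frame(source = c("A", "B"), relation = c("binding", "inhibition"),
               target = c("B", "C"), direct = c(TRUE, FALSE)),
    molecules = data.frame(id = c("A", "B", "C", "LONER"),
                           symbol = c("a", "b", "c", "x"),
                           kind = c("gene", "chemical", "gene", "complex")))
  f <- withr::local_tempfile(fileext = ".graphml")
  save_kb(kb, f, "graphml")
  kb2 <- load_kb(f, "graphml")
  expect_setequal(kb2$molecules$id, kb$molecules$id)
  expect_equal(kb2$molecules$kind[match(kb$molecules$id, kb2$molecules$id)],
               kb$molecules$kind)
  expect_setequal(paste(kb2$interactions$source, kb2$interactions$relation,
                        kb2$interactions$target),
                  paste(kb$interactions$source, kb$interactions$relation,
                        kb$interactions$target))
})

test_that("neighborhood is the gene plus its one-hop neighbors", {
  star <- kb_star(4)
  expect_setequal(neighborhood(star, "c"), c("c", "l1", "l2", "l3", "l4"))
  expect_equal(neighborhood(star, "l1"), c("c", "l1"))

  iso <- make_kb("A-B", molecules = data.frame(id = c("A", "B", "I")))
  expect_equal(neighborhood(iso, "I"), "I")

  expect_setequal(neighborhood(kb_triangle(), "A"), c("A", "B", "C"))
  expect_error(neighborhood(star, "nope"), "unknown molecule")
})

test_that("triangular connectivity matches the definitional cases", {
  expect_equal(unname(triangular_connectivity(kb_triangle(), "A")), 1L)
  expect_equal(unname(triangular_connectivity(kb_star(5), "c")), 0L)
  # complete graph on 4 nodes: every node sits in choose(3, 2) = 3 triangles
  expect_equal(unname(triangular_connectivity(kb_k4())), rep(3L, 4))
})

test_that("triangular connectivity agrees with brute-force enumeration on random graphs", {
  total_checked <- 0
  for (i in 1:200) {
    n <- 3 + (i %% 10)
    kb <- random_kb(n, p = c(0.1, 0.3, 0.5, 0.8)[1 + (i %% 4)], seed = i)
    got <- triangular_connectivity(kb)
    want <- brute_triangles_through(kb, kb$molecules$id)
    expect_identical(got, want)
    # triangle handshake: each triangle is counted once per corner
    n_tri <- sum(igraph::count_triangles(
      igraph::graph_from_data_frame(
        kb$interactions[, c("source", "target")], directed = FALSE,
        vertices = kb$molecules$id))) / 3
    expect_equal(sum(got), 3 * n_tri)
    total_checked <- total_checked + 1
  }
  expect_equal(total_checked, 200)
})

test_that("neighborhood size equals simple-view degree plus one", {
  for (seed in 1:20) {
    kb <- random_kb(10, 0.3, seed = seed)
    deg <- lengths(kb$adj)
    for (j in seq_along(kb$ids)) {
      expect_length(neighborhood(kb, kb$ids[j]), deg[j] + 1)
    }
  }
})

test_that("parallel edges and self-loops are collapsed in the simple view", {
  kb <- knowledge_base(data.frame(
    source = c("A", "A", "A"),
    relation = c("binding", "activation", "binding"),
    target = c("B", "B", "A"),
    direct = TRUE))
  expect_equal(unname(degree_sequence(kb)), c(1L, 1L))
  expect_equal(neighborhood(kb, "A"), c("A", "B"))
})

test_that("induced networks keep exactly the inside genes and edges", {
  tri <- kb_triangle()
  whole <- induced_network(tri, c("A", "B", "C"))
  expect_equal(n_molecules(whole), 3)
  expect_equal(n_interactions(whole), 3)

  single <- induced_network(tri, "A")
  expect_equal(n_molecules(single), 1)
  expect_equal(n_interactions(single), 0)

  pair <- induced_network(tri, c("A", "B"))
  expect_equal(n_molecules(pair), 2)
  expect_equal(n_interactions(pair), 1)

  expect_error(induced_network(tri, c("A", "Z")), "unknown molecule")
})
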