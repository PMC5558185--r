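test_that("a minimal well-formed graph loads with all roles and indices", {
  g <- minimal_graph()
  expect_s3_class(g, "pdr_graph")
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)
  expect_equal(nrow(validate_graph(g)), 0)
})

test_that("TSV loading reports schema violations with line numbers", {
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "nodes.tsv")
  edges <- file.path(dir, "edges.tsv")
  readr::write_lines(c("id\tname\tis_gene\tis_disease\tis_phenotype",
                       "g1\tgene\t1\t0\t0", "d1\tdis\t0\t1\t0"), nodes)

  readr::write_lines(c("source\ttarget\tkind", "g1\td1\tXX"), edges)
  expect_error(load_graph(nodes, edges), "line 2.*unknown edge kind.*XX")

  readr::write_lines(c("source\ttarget\tkind", "g1\td1\tGD",
                       "g1\tmissing\tGD"), edges)
  expect_error(load_graph(nodes, edges), "line 3.*missing")

  readr::write_lines(c("id\tname\tis_gene\tis_disease\tis_phenotype",
                       "g1\tgene\t1\t0\t0", "g1\tgene\t1\t0\t0"), nodes)
  readr::write_lines(c("source\ttarget\tkind", "g1\tg1\tGD"), edges)
  expect_error(load_graph(nodes, edges), "line 3.*duplicate node id")
})

test_that("a cycle in the hierarchy fails validation at load", {
  nodes <- dplyr::bind_rows(
    node_row("t1", phenotype = TRUE), node_row("t2", phenotype = TRUE)
  )
  edges <- tibble::tibble(source = c("t1", "t2"), target = c("t2", "t1"),
                          kind = "PH")
  expect_error(pdr_graph(nodes, edges), "PH-cycle")
  rep <- validate_graph(pdr_graph(nodes, edges, check = FALSE))
  expect_true("PH-cycle" %in% rep$violation)
})

test_that("validate_graph reports direction violations and isolated genes", {
  # DP edge whose source is not flagged as a disease
  g <- pdr_graph(
    nodes = dplyr::bind_rows(node_row("x", phenotype = TRUE),
                             node_row("p", phenotype = TRUE)),
    edges = tibble::tibble(source = "x", target = "p", kind = "DP"),
    check = FALSE
  )
  rep <- validate_graph(g)
  expect_equal(rep$violation[rep$severity == "error"],
               "DP-source-not-disease")
  expect_equal(rep$count[rep$violation == "DP-source-not-disease"], 1)

  # isolated gene is a warning, not an error
  g2 <- pdr_graph(
    nodes = dplyr::bind_rows(node_row("g1", gene = TRUE),
                             node_row("d1", disease = TRUE),
                             node_row("p1", phenotype = TRUE)),
    edges = tibble::tibble(source = "d1", target = "p1", kind = "DP")
  )
  rep2 <- validate_graph(g2)
  expect_equal(rep2$violation, "gene-with-no-GD-edge")
  expect_equal(rep2$severity, "warning")
})

test_that("direct disease counts match a brute-force scan of the edge table", {
  for (seed in 1:20) {
    rg <- random_small_graph(seed)
    g <- rg$graph
    dp <- g$edges[g$edges$kind == "DP", ]
    for (p in rg$phenotypes) {
      expect_identical(
        direct_disease_count(g, p),
        length(unique(dp$source[dp$target == p])),
        info = sprintf("seed %d phenotype %s", seed, p)
      )
    }
  }
  expect_error(direct_disease_count(minimal_graph(), "nope"),
               "unknown node")
})

test_that("candidate diseases follow GD edges with gene back-references", {
  g <- example_graph()
  expect_equal(candidate_diseases(g, "g1")$disease, "d1")
  expect_equal(nrow(candidate_diseases(g, character(0))), 0)

  # two genes sharing a disease are both recorded as implicating
  g2 <- pdr_graph(
    nodes = dplyr::bind_rows(node_row("g1", gene = TRUE),
                             node_row("g2", gene = TRUE),
                             node_row("d1", disease = TRUE),
                             node_row("p1", phenotype = TRUE)),
    edges = tibble::tibble(source = c("g1", "g2", "d1"),
                           target = c("d1", "d1", "p1"),
                           kind = c("GD", "GD", "DP"))
  )
  cd <- candidate_diseases(g2, c("g2", "g1"))
  expect_equal(cd$disease, "d1")
  expect_equal(cd$genes[[1]], c("g1", "g2"))

  # non-gene ids are skipped, not fatal
  cd2 <- candidate_diseases(g, c("g1", "p1", "zz"))
  expect_equal(cd2$disease, "d1")
  expect_setequal(attr(cd2, "skipped"), c("p1", "zz"))
})

test_that("candidate diseases distribute over gene-set union", {
  for (seed in 1:10) {
    rg <- random_small_graph(seed)
    g <- rg$graph
    gene_ids <- g$nodes$id[g$nodes$is_gene]
    g1 <- sample(gene_ids, max(1, length(gene_ids) %/% 2))
    g2 <- sample(gene_ids, max(1, length(gene_ids) %/% 2))
    expect_setequal(
      candidate_diseases(g, union(g1, g2))$disease,
      union(candidate_diseases(g, g1)$disease,
            candidate_diseases(g, g2)$disease)
    )
  }
})

test_that("load -> save -> load round-trips the edge multiset and flags", {
  net <- generate_network(n_genes = 10, n_diseases = 8, n_phenotypes = 30,
                          mean_phenotypes_per_disease = 5,
                          mean_diseases_per_gene = 2, seed = 5)
  dir <- withr::local_tempdir()
  n1 <- file.path(dir, "n.tsv"); e1 <- file.path(dir, "e.tsv")
  write_graph(net$graph, n1, e1)
  g2 <- load_graph(n1, e1)
  key <- function(g) sort(paste(g$edges$source, g$edges$target, g$edges$kind))
  expect_identical(key(g2), key(net$graph))
  expect_identical(dplyr::arrange(g2$nodes, id),
                   dplyr::arrange(net$graph$nodes, id))
})

test_that("OBO import maps is_a to general-to-specific PH edges", {
  dir <- withr::local_tempdir()
  obo <- file.path(dir, "t.obo")
  readr::write_lines(c(
    "format-version: 1.2", "",
    "[Term]", "id: HP:0000001", "name: root term", "",
    "[Term]", "id: HP:0000002", "name: child term",
    "alt_id: HP:0009999",
    'synonym: "child synonym" EXACT []',
    "is_a: HP:0000001 ! root term", "",
    "[Term]", "id: HP:0000003", "name: gone", "is_obsolete: true"
  ), obo)
  res <- read_obo(obo)
  expect_equal(res$nodes$id, c("HP:0000001", "HP:0000002"))
  expect_equal(res$edges,
               tibble::tibble(source = "HP:0000001", target = "HP:0000002",
                              kind = "PH"))
  lex <- build_lexicon(res$lexicon)
  expect_equal(map_term(lex, "HP:0009999")$matched_node, "HP:0000002")
  expect_equal(map_term(lex, "child synonym")$match_kind, "synonym")
})
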