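test_that("specificity weight follows the logarithmic decay formula", {
  expect_identical(specificity_weight(0), 1)
  expect_identical(specificity_weight(1), 1)
  expect_identical(specificity_weight(10), 0.5)
  # direct, independent evaluation at the knowledge base's maximum
  # phenotype degree; monotone below the N = 100 value
  expect_equal(specificity_weight(1403), 1 / (1 + log10(1403)))
  expect_lt(specificity_weight(1403), specificity_weight(100))
  expect_identical(specificity_weight(1000, b = 0), 1)
  expect_error(specificity_weight(-1), "nonnegative")
  expect_error(specificity_weight(5, b = -1), ">= 0")
})

test_that("specificity weight is non-increasing in N and 1 iff N <= 1", {
  N <- 0:2000
  w <- specificity_weight(N)
  expect_true(all(diff(w) <= 0))
  expect_identical(which(w == 1), which(N <= 1))
})

test_that("path weight is the geometric decay with a unit direct link", {
  expect_identical(path_weight(1), 1)
  expect_identical(path_weight(2), 0.75)
  expect_identical(path_weight(3), 0.5625)
  expect_identical(path_weight(4), 0.75^3)
  expect_identical(path_weight(1:4, a = 1), rep(1, 4))
  expect_true(all(diff(path_weight(1:4, a = 0.75)) < 0))
  expect_error(path_weight(0), "path length")
  expect_error(path_weight(5), "path length")
})

test_that("direct links and one-hop hierarchy paths are found", {
  g <- example_graph()
  res <- constrained_shortest_paths(g, "p1", "d1")
  expect_equal(res$disease, "d1")
  expect_equal(res$length, 1L)
  expect_equal(res$paths[[1]][[1]]$nodes, c("p1", "d1"))
  expect_equal(res$paths[[1]][[1]]$kinds, "DP")

  res2 <- constrained_shortest_paths(g, "p1", c("d1", "d2"))
  d2 <- res2[res2$disease == "d2", ]
  expect_equal(d2$length, 2L)
  expect_equal(d2$paths[[1]][[1]]$nodes, c("p1", "t1", "d2"))
  expect_equal(d2$paths[[1]][[1]]$kinds, c("PH", "DP"))
})

test_that("the path-length cap drops diseases beyond reach", {
  # 4 hierarchy terms -> 5 edges needed -> unreachable
  g5 <- chain_graph(4)
  expect_equal(nrow(constrained_shortest_paths(g5, "p", "d")), 0)
  expect_equal(nrow(score_diseases(g5, "p", "d")), 0)
  # 3 hierarchy terms -> 4 edges -> scored at a^3
  g4 <- chain_graph(3)
  s <- score_diseases(g4, "p", "d")
  expect_equal(s$score, 0.75^3)
})

test_that("candidate diseases cannot serve as intermediates", {
  # p -DP-> dA (dual role: dA is also a phenotype of dB); with both in D
  # the path to dB through dA is blocked, but with D = {dB} it is allowed
  nodes <- dplyr::bind_rows(
    node_row("p", phenotype = TRUE),
    node_row("dA", disease = TRUE, phenotype = TRUE),
    node_row("dB", disease = TRUE)
  )
  edges <- tibble::tibble(source = c("dA", "dB"), target = c("p", "dA"),
                          kind = "DP")
  g <- pdr_graph(nodes, edges)
  both <- constrained_shortest_paths(g, "p", c("dA", "dB"))
  expect_equal(both$disease, "dA")
  only_b <- constrained_shortest_paths(g, "p", "dB")
  expect_equal(only_b$disease, "dB")
  expect_equal(only_b$length, 2L)
})

test_that("a phenotype that is itself a candidate disease scores as direct", {
  nodes <- dplyr::bind_rows(
    node_row("g", gene = TRUE),
    node_row("dp", disease = TRUE, phenotype = TRUE),
    node_row("q", phenotype = TRUE),
    node_row("d2", disease = TRUE)
  )
  edges <- tibble::tibble(
    source = c("g", "dp", "d2"), target = c("dp", "q", "dp"),
    kind = c("GD", "DP", "DP")
  )
  g <- pdr_graph(nodes, edges)
  res <- constrained_shortest_paths(g, "dp", "dp")
  expect_true(res$self)
  expect_equal(res$length, 1L)
  s <- score_diseases(g, "dp", "dp")
  # path weight 1 by the direct-case rule; specificity from the node's own
  # disease in-degree (here 1)
  expect_equal(s$score, 1)
})

test_that("disease scores sum per-phenotype contributions once each", {
  # two phenotypes: N=1 at L=1 contributes 1; N=10 at L=2 contributes
  # 0.5 * 0.75; hand evaluation gives 1.375
  nodes <- dplyr::bind_rows(
    node_row("d", disease = TRUE),
    purrr::map_dfr(sprintf("dx%02d", 1:9), ~ node_row(.x, disease = TRUE)),
    node_row("p1", phenotype = TRUE),
    node_row("p2", phenotype = TRUE),
    node_row("t", phenotype = TRUE)
  )
  edges <- dplyr::bind_rows(
    tibble::tibble(source = "d", target = c("p1", "t"), kind = "DP"),
    tibble::tibble(source = c("d", sprintf("dx%02d", 1:9)), target = "p2",
                   kind = "DP"),
    tibble::tibble(source = "t", target = "p2", kind = "PH")
  )
  g <- pdr_graph(nodes, edges)
  expect_identical(direct_disease_count(g, "p2"), 10L)
  s <- score_diseases(g, c("p1", "p2"), "d")
  # p2 is directly linked (L=1, w_s=0.5) AND reachable via t (L=2), but
  # only the shortest path counts, once
  expect_equal(s$score, 1 + 0.5)
  expect_equal(nrow(s$contributions[[1]]), 2)

  # same topology but d reaches p2 only through t, with a tenth background
  # disease keeping N = 10: hand evaluation gives 1 + 0.5 * 0.75 = 1.375
  nodes2 <- dplyr::bind_rows(nodes, node_row("dx10", disease = TRUE))
  edges2 <- dplyr::bind_rows(
    edges[!(edges$source == "d" & edges$target == "p2"), ],
    tibble::tibble(source = "dx10", target = "p2", kind = "DP")
  )
  g2 <- pdr_graph(nodes2, edges2)
  expect_identical(direct_disease_count(g2, "p2"), 10L)
  s2 <- score_diseases(g2, c("p1", "p2"), "d")
  expect_equal(s2$score, 1.375)
  # adding a connected phenotype strictly increases the score
  s3 <- score_diseases(g2, c("p1", "p2", "t"), "d")
  expect_gt(s3$score, s2$score)
})

test_that("ranking is deterministic: score, then breadth, then id", {
  scores <- tibble::tibble(
    disease = c("dB", "dA", "dC", "dD"),
    score = c(1.0, 2.0, 1.0, 1.0),
    n_phenotypes = c(2L, 1L, 2L, 3L)
  )
  expect_equal(rank_diseases(scores)$disease, c("dA", "dD", "dB", "dC"))
  withr::with_seed(9, {
    for (i in 1:20) {
      perm <- scores[sample(nrow(scores)), ]
      expect_equal(rank_diseases(perm)$disease, c("dA", "dD", "dB", "dC"))
    }
  })
})

test_that("scores are invariant to phenotype and disease input order", {
  rg <- random_small_graph(17)
  g <- rg$graph
  if (length(rg$D) > 0) {
    s1 <- score_diseases(g, rg$phenotypes, rg$D)
    s2 <- score_diseases(g, rev(rg$phenotypes), sample(rg$D))
    expect_equal(tibble::as_tibble(s1)[c("disease", "score")],
                 tibble::as_tibble(s2)[c("disease", "score")])
  }
})

test_that("search agrees with exhaustive path enumeration on random graphs", {
  for (seed in 1:40) {
    rg <- random_small_graph(seed)
    if (length(rg$D) == 0) next
    for (p in rg$phenotypes) {
      expect_true(isTRUE(compare_with_oracle(rg$graph, p, rg$D)),
                  info = sprintf("seed %d phenotype %s", seed, p))
    }
  }
})

test_that("evidence subnetworks contain exactly the supporting paths", {
  g <- worked_case()
  D <- candidate_diseases(g, c("GENE_A", "GENE_B"))
  s <- score_diseases(g, c("PH_1", "PH_2", "PH_3", "PH_4", "PH_5"), D)
  expect_equal(s$disease[1], "DIS_A")
  sub <- evidence_subnetwork(s, "DIS_A", g)
  # the renal phenotype reaches the disease through the two intermediate
  # hierarchy terms, and only those intermediates appear
  expect_setequal(sub$nodes$id[sub$nodes$category == "intermediate"],
                  c("INT_1", "INT_2"))
  expect_setequal(sub$nodes$id[sub$nodes$category == "gene"], "GENE_A")
  # subnetwork edges are a subset of graph edges
  key <- function(e) paste(e$source, e$target, e$kind)
  expect_true(all(key(sub$edges) %in% key(g$edges)))
  # single direct path plus gene: 3 nodes, 2 edges
  g0 <- example_graph()
  s0 <- score_diseases(g0, "p1", candidate_diseases(g0, "g1"))
  sub0 <- evidence_subnetwork(s0, "d1", g0)
  expect_equal(nrow(sub0$nodes), 3)
  expect_equal(nrow(sub0$edges), 2)
})

test_that("tidy and glance expose the score breakdown", {
  g <- example_graph()
  s <- score_diseases(g, c("p1", "p2"), c("d1", "d2"))
  td <- tidy(s)
  expect_equal(nrow(td), 4)
  expect_equal(td$contribution, td$w_s * td$w_p)
  gl <- glance(s)
  expect_equal(gl$n_scored, 2L)
  expect_equal(gl$top_disease, "d1")
})
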