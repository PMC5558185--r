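# Independent brute-force oracle: exhaustively enumerates every simple path
# from a phenotype that satisfies the traversal constraints (DP edges walked
# phenotype-to-disease, PH edges walked either way, last edge DP into a
# candidate disease, no candidate disease as intermediate, length capped),
# then keeps the minimal-length paths per disease. Works directly off the
# edge table and shares no code with the package's search.
oracle_paths <- function(edges, p, D, Lmax = 4) {
  dp <- edges[edges$kind == "DP", ]
  ph <- edges[edges$kind == "PH", ]
  found <- list()
  record <- function(d, nodes, kinds) {
    cur <- found[[d]]
    if (is.null(cur)) {
      found[[d]] <<- list(len = length(kinds),
                          paths = list(list(nodes = nodes, kinds = kinds)))
    } else if (length(kinds) < cur$len) {
      found[[d]] <<- list(len = length(kinds),
                          paths = list(list(nodes = nodes, kinds = kinds)))
    } else if (length(kinds) == cur$len) {
      cur$paths[[length(cur$paths) + 1]] <- list(nodes = nodes,
                                                 kinds = kinds)
      found[[d]] <<- cur
    }
  }
  recurse <- function(nodes, kinds) {
    if (length(kinds) >= Lmax) return()
    u <- nodes[length(nodes)]
    for (v in dp$source[dp$target == u]) {
      if (v %in% nodes) next
      if (v %in% D) {
        record(v, c(nodes, v), c(kinds, "DP"))
      } else {
        recurse(c(nodes, v), c(kinds, "DP"))
      }
    }
    for (v in c(ph$target[ph$source == u], ph$source[ph$target == u])) {
      if (v %in% nodes || v %in% D) next
      recurse(c(nodes, v), c(kinds, "PH"))
    }
  }
  recurse(p, character(0))
  if (p %in% D) {
    found[[p]] <- list(len = 1L, paths = list(list(nodes = p,
                                                   kinds = character(0))))
  }
  found
}

canon_paths <- function(paths) {
  sort(vapply(paths, function(pt) {
    paste(paste(pt$nodes, collapse = ">"),
          paste(pt$kinds, collapse = ","), sep = "|")
  }, character(1)))
}

# Compare the package search against the oracle on one graph for one
# phenotype; returns TRUE or a description of the first discrepancy.
compare_with_oracle <- function(g, p, D, params = pdr_params()) {
  got <- constrained_shortest_paths(g, p, D, params)
  want <- oracle_paths(g$edges, p, D, Lmax = params$max_path_length)
  if (!setequal(got$disease, names(want))) {
    return(sprintf("phenotype %s: diseases differ (got %s, want %s)", p,
                   paste(got$disease, collapse = ","),
                   paste(names(want), collapse = ",")))
  }
  for (d in got$disease) {
    row <- got[got$disease == d, ]
    if (row$length != want[[d]]$len) {
      return(sprintf("phenotype %s disease %s: length %d != %d", p, d,
                     row$length, want[[d]]$len))
    }
    if (!identical(canon_paths(row$paths[[1]]),
                   canon_paths(want[[d]]$paths))) {
      return(sprintf("phenotype %s disease %s: path sets differ", p, d))
    }
  }
  TRUE
}

# Brute-force score: oracle paths + direct formula evaluation, for checking
# the scoring pipeline end to end.
oracle_scores <- function(g, P, D, params = pdr_params()) {
  dp <- g$edges[g$edges$kind == "DP", ]
  rows <- purrr::map_dfr(sort(P), function(p) {
    found <- oracle_paths(g$edges, p, D, Lmax = params$max_path_length)
    if (length(found) == 0) return(tibble::tibble())
    N <- length(unique(dp$source[dp$target == p]))
    tibble::tibble(
      disease = names(found),
      contribution = (1 / (1 + params$b * log10(max(1, N)))) *
        params$a^(vapply(found, function(f) f$len, numeric(1)) - 1)
    )
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(disease = character(), score = numeric(),
                          n_phenotypes = integer()))
  }
  rows |>
    dplyr::group_by(disease) |>
    dplyr::summarise(score = sum(contribution),
                     n_phenotypes = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(score), dplyr::desc(n_phenotypes), disease)
}

# Small random graph with adversarial structure for oracle comparison:
# random DAG hierarchy (not a forest), dual-role nodes, random DP/GD
# attachment. At most ~60 nodes.
random_small_graph <- function(seed) {
  withr::with_seed(seed, {
    n_ph <- sample(8:30, 1)
    n_dis <- sample(3:10, 1)
    n_gene <- sample(2:6, 1)
    p_ids <- sprintf("p%02d", seq_len(n_ph))
    d_ids <- sprintf("d%02d", seq_len(n_dis))
    g_ids <- sprintf("g%02d", seq_len(n_gene))
    dual <- sample(p_ids, ceiling(0.2 * n_ph))

    # hierarchy edges only from earlier to later phenotype index -> acyclic
    n_phe <- sample(0:(2 * n_ph), 1)
    ph <- NULL
    if (n_phe > 0) {
      a <- sample(n_ph, n_phe, replace = TRUE)
      b <- sample(n_ph, n_phe, replace = TRUE)
      keep <- a < b
      ph <- tibble::tibble(source = p_ids[a[keep]], target = p_ids[b[keep]],
                           kind = "PH")
    }
    all_dis <- c(d_ids, dual)
    dp <- purrr::map_dfr(all_dis, function(d) {
      pool <- setdiff(p_ids, d)
      k <- sample(seq_len(min(5, length(pool))), 1)
      tibble::tibble(source = d, target = sample(pool, k), kind = "DP")
    })
    gd <- purrr::map_dfr(g_ids, function(gn) {
      k <- sample(1:3, 1)
      tibble::tibble(source = gn,
                     target = sample(all_dis, min(k, length(all_dis))),
                     kind = "GD")
    })
    nodes <- dplyr::bind_rows(
      tibble::tibble(id = p_ids, name = p_ids, is_gene = FALSE,
                     is_disease = p_ids %in% dual, is_phenotype = TRUE),
      tibble::tibble(id = d_ids, name = d_ids, is_gene = FALSE,
                     is_disease = TRUE, is_phenotype = FALSE),
      tibble::tibble(id = g_ids, name = g_ids, is_gene = TRUE,
                     is_disease = FALSE, is_phenotype = FALSE)
    )
    edges <- dplyr::distinct(dplyr::bind_rows(ph, dp, gd),
                             source, target, kind)
    g <- pdr_graph(nodes, edges)
    genes <- sample(g_ids, sample(seq_len(n_gene), 1))
    list(graph = g, genes = genes,
         D = candidate_diseases(g, genes)$disease,
         phenotypes = p_ids)
  })
}
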