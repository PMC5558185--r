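#' Specificity weight of a phenotype
#'
#' A phenotype directly associated with many diseases discriminates poorly
#' between them. The specificity weight
#' \deqn{w_s = \frac{1}{1 + b\,\log_{10}(\max(1, N))}}{w_s = 1 / (1 + b log10(max(1, N)))}
#' is 1 for a phenotype attached to 0 or 1 diseases and decays with the
#' order of magnitude of `N`, so it separates phenotypes attached to 1, 10,
#' 100 or 1000 diseases without suppressing unspecific phenotypes entirely.
#'
#' @param N Number of diseases the phenotype is directly connected to
#'   (nonnegative integer, vectorised).
#' @param b Specificity-decay factor, >= 0 (default 1).
#' @return Numeric vector of weights in (0, 1].
#' @examples
#' specificity_weight(c(0, 1, 10, 100))
#' @export
specificity_weight <- function(N, b = 1) {
  if (any(N < 0)) stop("N must be nonnegative", call. = FALSE)
  if (length(b) != 1 || b < 0) stop("b must be a single value >= 0",
                                    call. = FALSE)
  1 / (1 + b * log10(pmax(1, N)))
}

#' Path weight of a phenotype-to-disease connection
#'
#' Confidence in a disease-phenotype association decreases with every
#' hierarchy link traversed: a phenotype reaching a disease through a
#' shortest path of `L` edges contributes with weight `a^(L - 1)`. A direct
#' disease-phenotype link (`L = 1`) — including the special case where the
#' phenotype is itself a gene-associated disease — has weight exactly 1.
#'
#' @param L Shortest-path length in edges (vectorised); must lie in
#'   `[1, max_path_length]`.
#' @param a Path-decay factor in (0, 1] (default 0.75).
#' @param max_path_length Maximum admissible path length (default 4).
#' @return Numeric vector of weights in (0, 1].
#' @examples
#' path_weight(1:4)
#' @export
path_weight <- function(L, a = 0.75, max_path_length = 4L) {
  if (length(a) != 1 || a <= 0 || a > 1) {
    stop("a must be a single value in (0, 1]", call. = FALSE)
  }
  if (any(L < 1) || any(L > max_path_length)) {
    stop("path length must lie in [1, ", max_path_length, "]",
         call. = FALSE)
  }
  a^(L - 1)
}

#' Constrained shortest paths from a phenotype to candidate diseases
#'
#' Breadth-first search from a phenotype through the knowledge graph under
#' the traversal rules of the ranking algorithm:
#'
#' * disease-phenotype (DP) edges are traversed phenotype-to-disease, i.e.
#'   against their stored direction;
#' * hierarchy (PH) edges are traversed in either direction (towards more
#'   general and towards more specific terms);
#' * the last edge of a path must be a DP traversal into the disease;
#' * no intermediate node may belong to the candidate set `D` (diseases
#'   outside `D`, e.g. dual-role phenotype/disease nodes, may be crossed);
#' * paths are capped at `params$max_path_length` edges.
#'
#' For every disease in `D` reached under these rules the minimal length
#' and the complete set of minimal-length paths are returned. If the
#' starting phenotype is itself a member of `D` it is reported as a direct
#' connection (`length = 1`, `self = TRUE`), the case in which the path
#' weight is defined to be 1.
#'
#' @param g A `pdr_graph`.
#' @param phenotype A single phenotype node id.
#' @param D Character vector of candidate disease ids (nonempty).
#' @param params A [pdr_params()] object.
#' @return A tibble with one row per reachable disease: `disease`, `length`
#'   (shortest length in edges), `self`, `n_paths` and `paths` (list column;
#'   each path is a list with `nodes` — `length + 1` ids from phenotype to
#'   disease — and `kinds` — the `length` traversed edge kinds). Unreachable
#'   diseases are absent.
#' @export
constrained_shortest_paths <- function(g, phenotype, D,
                                       params = pdr_params()) {
  p <- as.character(phenotype)
  if (length(p) != 1 || !has_node(g, p)) {
    stop("unknown phenotype node: ", phenotype, call. = FALSE)
  }
  D <- unique(as.character(D))
  if (length(D) == 0) stop("candidate disease set is empty", call. = FALSE)
  Lmax <- params$max_path_length

  in_D <- new.env(parent = emptyenv(), size = max(29L, length(D)))
  for (d in D) assign(d, TRUE, envir = in_D)
  is_cand <- function(v) exists(v, envir = in_D, inherits = FALSE)

  dist <- new.env(parent = emptyenv())
  preds <- new.env(parent = emptyenv())
  term <- new.env(parent = emptyenv())
  assign(p, 0L, envir = dist)

  frontier <- p
  depth <- 0L
  while (length(frontier) > 0 && depth < Lmax) {
    depth <- depth + 1L
    nxt <- character(0)
    relax <- function(u, v, kind) {
      if (v == p) return()
      if (!exists(v, envir = dist, inherits = FALSE)) {
        assign(v, depth, envir = dist)
        assign(v, list(c(u, kind)), envir = preds)
        nxt <<- c(nxt, v)
      } else if (get(v, envir = dist, inherits = FALSE) == depth) {
        assign(v, c(get(v, envir = preds, inherits = FALSE),
                    list(c(u, kind))), envir = preds)
      }
    }
    for (u in frontier) {
      for (d in idx_get(g$idx$dp_in, u)) {
        if (is_cand(d)) {
          if (d == p) next
          if (!exists(d, envir = term, inherits = FALSE)) {
            assign(d, list(len = depth, preds = u), envir = term)
          } else {
            t <- get(d, envir = term, inherits = FALSE)
            if (t$len == depth) {
              t$preds <- c(t$preds, u)
              assign(d, t, envir = term)
            }
          }
        } else {
          relax(u, d, "DP")
        }
      }
      for (v in c(idx_get(g$idx$ph_out, u), idx_get(g$idx$ph_in, u))) {
        if (is_cand(v) && v != p) next
        relax(u, v, "PH")
      }
    }
    frontier <- unique(nxt)
  }

  backtrack <- function(v) {
    if (v == p) return(list(list(nodes = p, kinds = character(0))))
    out <- list()
    for (pr in get(v, envir = preds, inherits = FALSE)) {
      for (sub in backtrack(pr[1])) {
        out[[length(out) + 1]] <- list(nodes = c(sub$nodes, v),
                                       kinds = c(sub$kinds, pr[2]))
      }
    }
    out
  }

  rows <- list()
  if (is_cand(p)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      disease = p, length = 1L, self = TRUE, n_paths = 1L,
      paths = list(list(list(nodes = p, kinds = character(0))))
    )
  }
  for (d in ls(term)) {
    t <- get(d, envir = term, inherits = FALSE)
    paths <- list()
    for (u in unique(t$preds)) {
      for (sub in backtrack(u)) {
        paths[[length(paths) + 1]] <- list(nodes = c(sub$nodes, d),
                                           kinds = c(sub$kinds, "DP"))
      }
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      disease = d, length = t$len, self = FALSE,
      n_paths = length(paths), paths = list(paths)
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(disease = character(), length = integer(),
                          self = logical(), n_paths = integer(),
                          paths = list()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$disease)
}

#' Score candidate diseases against a patient phenotype set
#'
#' Runs the constrained shortest-path search from every patient phenotype,
#' then scores each candidate disease as the sum over connected phenotypes
#' of specificity weight times path weight,
#' \eqn{S = \sum_i w_s^i \, w_p^i}. Each phenotype contributes at most once
#' per disease (at its shortest path length), however many distinct
#' shortest paths exist; all shortest paths are retained for the evidence
#' subnetwork. Candidate diseases connected to no phenotype within the path
#' length cap are dropped. The result is ranked with [rank_diseases()].
#'
#' @param g A `pdr_graph`.
#' @param phenotypes Character vector of phenotype node ids (the set `P`).
#' @param diseases Candidate diseases: either a character vector of disease
#'   ids or the tibble returned by [candidate_diseases()] (whose
#'   gene back-references are then carried through).
#' @param params A [pdr_params()] object.
#' @return A tibble of class `pdr_scores`, one row per retained disease in
#'   rank order: `disease`, `disease_name`, `score`, `n_phenotypes`,
#'   `genes` (list column of implicating genes), `contributions` (list
#'   column of per-phenotype breakdown tibbles with `phenotype`, `N`, `L`,
#'   `w_s`, `w_p`, `contribution`) and `paths` (list column of evidence
#'   paths). Attributes: `params`, `phenotypes`, `n_candidates`,
#'   `n_dropped`.
#' @examples
#' g <- example_graph()
#' score_diseases(g, phenotypes = c("p1", "p2"), diseases = c("d1", "d2"))
#' @export
score_diseases <- function(g, phenotypes, diseases,
                           params = pdr_params()) {
  phenotypes <- sort(unique(as.character(phenotypes)))
  if (length(phenotypes) == 0) stop("no phenotypes supplied", call. = FALSE)
  if (is.data.frame(diseases)) {
    gene_map <- stats::setNames(diseases$genes, diseases$disease)
    D <- diseases$disease
  } else {
    D <- unique(as.character(diseases))
    gene_map <- stats::setNames(vector("list", length(D)), D)
  }
  if (length(D) == 0) stop("candidate disease set is empty", call. = FALSE)

  per_pheno <- purrr::map(
    stats::setNames(phenotypes, phenotypes),
    ~ constrained_shortest_paths(g, .x, D, params)
  )
  hits <- purrr::imap_dfr(per_pheno, function(res, p) {
    if (nrow(res) == 0) return(tibble::tibble())
    tibble::tibble(phenotype = p, disease = res$disease, L = res$length,
                   paths = res$paths)
  })
  n_cand <- length(D)
  if (nrow(hits) == 0) {
    out <- tibble::tibble(
      disease = character(), disease_name = character(), score = numeric(),
      n_phenotypes = integer(), genes = list(), contributions = list(),
      paths = list()
    )
  } else {
    hits <- dplyr::mutate(
      hits,
      N = direct_disease_count(g, .data$phenotype),
      w_s = specificity_weight(.data$N, params$b),
      w_p = path_weight(.data$L, params$a, params$max_path_length),
      contribution = .data$w_s * .data$w_p
    )
    out <- hits |>
      dplyr::arrange(.data$disease, .data$phenotype) |>
      dplyr::group_by(.data$disease) |>
      dplyr::summarise(
        score = sum(.data$contribution),
        n_phenotypes = dplyr::n(),
        contributions = list(dplyr::pick(
          "phenotype", "N", "L", "w_s", "w_p", "contribution"
        )),
        paths = list(stats::setNames(.data$paths, .data$phenotype)),
        .groups = "drop"
      )
    out <- dplyr::mutate(
      out,
      disease_name = g$nodes$name[match(.data$disease, g$nodes$id)],
      genes = unname(gene_map[.data$disease]),
      .after = "disease"
    )
    out <- dplyr::relocate(out, "score", "n_phenotypes", "genes",
                           .after = "disease_name")
  }
  out <- rank_diseases(out)
  attr(out, "params") <- params
  attr(out, "phenotypes") <- phenotypes
  attr(out, "n_candidates") <- n_cand
  attr(out, "n_dropped") <- n_cand - nrow(out)
  class(out) <- c("pdr_scores", class(tibble::tibble()))
  out
}

#' Rank scored diseases
#'
#' Orders diseases by descending score. Exact ties are broken by descending
#' number of contributing phenotypes, then by lexicographic disease id, so
#' the ranking is deterministic and independent of input order.
#'
#' @param scores A tibble with at least `disease`, `score`, `n_phenotypes`.
#' @return The same tibble in rank order.
#' @export
rank_diseases <- function(scores) {
  dplyr::arrange(scores, dplyr::desc(.data$score),
                 dplyr::desc(.data$n_phenotypes), .data$disease)
}

# Stored-orientation edges along one traversal path.
path_edges <- function(g, path) {
  n <- length(path$kinds)
  if (n == 0) return(tibble::tibble(source = character(),
                                    target = character(),
                                    kind = character()))
  purrr::map_dfr(seq_len(n), function(i) {
    u <- path$nodes[i]
    v <- path$nodes[i + 1]
    if (path$kinds[i] == "DP") {
      tibble::tibble(source = v, target = u, kind = "DP")
    } else if (v %in% idx_get(g$idx$ph_out, u)) {
      tibble::tibble(source = u, target = v, kind = "PH")
    } else {
      tibble::tibble(source = v, target = u, kind = "PH")
    }
  })
}

#' Evidence subnetwork for one scored disease
#'
#' Assembles the union of all shortest paths that support a disease's score
#' plus the GD edge(s) from its implicating gene(s) — the subgraph a user
#' inspects to understand why the disease ranked where it did. Nodes are
#' categorised as `gene`, `disease` (the scored disease), `phenotype`
#' (patient phenotypes contributing to the score) or `intermediate`
#' (crossed hierarchy terms or dual-role nodes).
#'
#' @param scores A `pdr_scores` tibble from [score_diseases()].
#' @param disease The disease id to extract (must be a row of `scores`).
#' @param g The `pdr_graph` the scores were computed on.
#' @return A list with tibbles `nodes` (`id`, `name`, `category`) and
#'   `edges` (`source`, `target`, `kind`), each a subset of the graph.
#' @export
evidence_subnetwork <- function(scores, disease, g) {
  row <- scores[scores$disease == disease, ]
  if (nrow(row) == 0) {
    stop("disease ", disease, " is not in the score table", call. = FALSE)
  }
  all_paths <- purrr::flatten(row$paths[[1]])
  edges <- dplyr::distinct(purrr::map_dfr(all_paths, ~ path_edges(g, .x)))
  path_nodes <- unique(unlist(purrr::map(all_paths, "nodes")))
  genes <- row$genes[[1]]
  if (length(genes) > 0) {
    gd <- dplyr::filter(g$edges, .data$kind == "GD",
                        .data$source %in% genes,
                        .data$target == disease)
    edges <- dplyr::distinct(dplyr::bind_rows(
      edges, dplyr::select(gd, "source", "target", "kind")
    ))
  }
  contributing <- row$contributions[[1]]$phenotype
  ids <- unique(c(path_nodes, genes, disease))
  nodes <- tibble::tibble(
    id = ids,
    name = g$nodes$name[match(ids, g$nodes$id)],
    category = dplyr::case_when(
      ids == disease ~ "disease",
      ids %in% genes ~ "gene",
      ids %in% contributing ~ "phenotype",
      TRUE ~ "intermediate"
    )
  )
  list(nodes = nodes, edges = edges)
}

#' Write an evidence subnetwork as node/edge TSV files
#'
#' @param subnetwork A list from [evidence_subnetwork()].
#' @param node_table,edge_table Output paths.
#' @return Invisibly, the two paths.
#' @export
write_subnetwork <- function(subnetwork, node_table, edge_table) {
  readr::write_tsv(subnetwork$nodes, node_table, progress = FALSE)
  readr::write_tsv(subnetwork$edges, edge_table, progress = FALSE)
  invisible(list(node_table = node_table, edge_table = edge_table))
}

#' Small built-in example graph
#'
#' A six-node toy network (one gene per disease, two diseases, two
#' phenotypes, one hierarchy term) used in examples and tests: `g1 -> d1`,
#' `g2 -> d2` (GD); `d1 -> p1`, `d1 -> p2`, `d2 -> p2` (DP); hierarchy term
#' `t1` with `t1 -> p1` (PH) and `d2 -> t1` (DP) so that `p1` reaches `d2`
#' through one intermediate term.
#'
#' @return A `pdr_graph`.
#' @export
example_graph <- function() {
  pdr_graph(
    nodes = tibble::tibble(
      id = c("g1", "g2", "d1", "d2", "p1", "p2", "t1"),
      name = c("gene one", "gene two", "disease one", "disease two",
               "phenotype one", "phenotype two", "term one"),
      is_gene = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
      is_disease = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
      is_phenotype = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
    ),
    edges = tibble::tibble(
      source = c("g1", "g2", "d1", "d1", "d2", "t1", "d2"),
      target = c("d1", "d2", "p1", "p2", "p2", "p1", "t1"),
      kind = c("GD", "GD", "DP", "DP", "DP", "PH", "DP")
    )
  )
}
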