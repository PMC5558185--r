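#' Construct a phenotype-disease-gene knowledge graph
#'
#' The knowledge graph is the substrate of the ranking algorithm. Nodes are
#' genes, diseases and phenotypes; a node may play more than one role (some
#' phenotypes act as diseases themselves and carry their own downstream
#' phenotypes). Edges are directed and typed:
#'
#' * `GD` — gene to associated disease (causal or correlated),
#' * `DP` — disease to associated phenotype,
#' * `PH` — more general hierarchy term to more specific term.
#'
#' The hierarchy (`PH`) portion must be acyclic; `GD`/`DP` edges are exempt
#' from the acyclicity requirement because dual-role nodes legitimately
#' create disease-phenotype-disease chains.
#'
#' @param nodes A data frame with columns `id`, `name`, `is_gene`,
#'   `is_disease`, `is_phenotype` (flags coercible to logical).
#' @param edges A data frame with columns `source`, `target`, `kind`
#'   (`"GD"`, `"DP"` or `"PH"`). Optional columns `causal` (values
#'   `"causal"`/`"correlated"`, `NA` = unknown) and `moi`
#'   (`"dominant"`/`"recessive"`, `NA` = unknown) annotate GD edges.
#' @param check If `TRUE` (default) run [validate_graph()] and abort on any
#'   violation.
#' @return An object of class `pdr_graph`: a list with tibbles `nodes` and
#'   `edges` plus internal adjacency indices.
#' @examples
#' g <- pdr_graph(
#'   nodes = tibble::tibble(
#'     id = c("g1", "d1", "p1"), name = c("gene 1", "disease 1", "pheno 1"),
#'     is_gene = c(TRUE, FALSE, FALSE), is_disease = c(FALSE, TRUE, FALSE),
#'     is_phenotype = c(FALSE, FALSE, TRUE)
#'   ),
#'   edges = tibble::tibble(
#'     source = c("g1", "d1"), target = c("d1", "p1"), kind = c("GD", "DP")
#'   )
#' )
#' direct_disease_count(g, "p1")
#' @export
pdr_graph <- function(nodes, edges, check = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  req_n <- c("id", "name", "is_gene", "is_disease", "is_phenotype")
  req_e <- c("source", "target", "kind")
  if (!all(req_n %in% names(nodes))) {
    stop("node table must have columns: ", paste(req_n, collapse = ", "),
         call. = FALSE)
  }
  if (!all(req_e %in% names(edges))) {
    stop("edge table must have columns: ", paste(req_e, collapse = ", "),
         call. = FALSE)
  }
  nodes <- dplyr::mutate(
    nodes,
    id = as.character(.data$id),
    name = as.character(.data$name),
    dplyr::across(dplyr::all_of(c("is_gene", "is_disease", "is_phenotype")),
                  ~ as.logical(as.integer(.x)))
  )
  edges <- dplyr::mutate(
    edges,
    source = as.character(.data$source),
    target = as.character(.data$target),
    kind = as.character(.data$kind)
  )
  if (!"causal" %in% names(edges)) edges$causal <- NA_character_
  if (!"moi" %in% names(edges)) edges$moi <- NA_character_

  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup) > 0) {
    stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(edges$kind), c("GD", "DP", "PH"))
  if (length(bad_kind) > 0) {
    stop("unknown edge kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  missing_ep <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(missing_ep) > 0) {
    stop("edge endpoint(s) not in node table: ",
         paste(utils::head(missing_ep, 5), collapse = ", "), call. = FALSE)
  }

  g <- structure(
    list(nodes = nodes, edges = edges, idx = build_indices(nodes, edges)),
    class = "pdr_graph"
  )
  if (check) {
    rep <- validate_graph(g)
    err <- dplyr::filter(rep, .data$severity == "error")
    if (nrow(err) > 0) {
      stop("invalid graph:\n",
           paste(sprintf("  %s (%d)", err$violation, err$count),
                 collapse = "\n"),
           call. = FALSE)
    }
  }
  g
}

# Adjacency indices as environments (O(1) amortised lookup by node id).
# dp_in:  phenotype -> diseases with a DP edge into it (defines N_i)
# dp_out: disease   -> its DP phenotypes
# gd_out: gene      -> its GD diseases;  gd_in: disease -> its GD genes
# ph_out: term      -> more specific PH children; ph_in: term -> PH parents
build_indices <- function(nodes, edges) {
  mk <- function(keys, values) {
    e <- new.env(parent = emptyenv(), size = max(29L, length(keys)))
    if (length(keys) > 0) {
      sp <- split(values, keys)
      for (k in names(sp)) assign(k, unique(sp[[k]]), envir = e)
    }
    e
  }
  dp <- edges[edges$kind == "DP", ]
  gd <- edges[edges$kind == "GD", ]
  ph <- edges[edges$kind == "PH", ]
  roles <- new.env(parent = emptyenv(), size = max(29L, nrow(nodes)))
  for (i in seq_len(nrow(nodes))) {
    assign(nodes$id[i],
           c(gene = nodes$is_gene[i], disease = nodes$is_disease[i],
             phenotype = nodes$is_phenotype[i]),
           envir = roles)
  }
  list(
    dp_in = mk(dp$target, dp$source),
    dp_out = mk(dp$source, dp$target),
    gd_out = mk(gd$source, gd$target),
    gd_in = mk(gd$target, gd$source),
    ph_out = mk(ph$source, ph$target),
    ph_in = mk(ph$target, ph$source),
    roles = roles
  )
}

idx_get <- function(env, key) {
  if (exists(key, envir = env, inherits = FALSE)) {
    get(key, envir = env, inherits = FALSE)
  } else {
    character(0)
  }
}

has_node <- function(g, id) {
  exists(id, envir = g$idx$roles, inherits = FALSE)
}

node_role <- function(g, id, role) {
  if (!has_node(g, id)) return(FALSE)
  unname(get(id, envir = g$idx$roles, inherits = FALSE)[role])
}

#' @export
print.pdr_graph <- function(x, ...) {
  kinds <- table(factor(x$edges$kind, levels = c("GD", "DP", "PH")))
  cat("<pdr_graph>\n")
  cat(sprintf(
    "  %d nodes (%d genes, %d diseases, %d phenotypes; %d dual disease/phenotype)\n",
    nrow(x$nodes), sum(x$nodes$is_gene), sum(x$nodes$is_disease),
    sum(x$nodes$is_phenotype), sum(x$nodes$is_disease & x$nodes$is_phenotype)
  ))
  cat(sprintf("  %d edges (GD %d, DP %d, PH %d)\n",
              nrow(x$edges), kinds[["GD"]], kinds[["DP"]], kinds[["PH"]]))
  invisible(x)
}

#' Load a knowledge graph from node and edge TSV tables
#'
#' The node table has header `id name is_gene is_disease is_phenotype`
#' (tab-separated, 0/1 flags); the edge table has header
#' `source target kind` with kind in `{GD, DP, PH}` and may carry the
#' optional `causal` and `moi` columns. Schema violations are reported with
#' the offending line number (header is line 1).
#'
#' @param node_table,edge_table Paths to the TSV files.
#' @param check Validate the assembled graph (default `TRUE`).
#' @return A `pdr_graph`.
#' @export
load_graph <- function(node_table, edge_table, check = TRUE) {
  nodes <- readr::read_tsv(node_table, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  edges <- readr::read_tsv(edge_table, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)

  req_n <- c("id", "name", "is_gene", "is_disease", "is_phenotype")
  if (!all(req_n %in% names(nodes))) {
    stop(node_table, ": line 1: expected header columns ",
         paste(req_n, collapse = ", "), call. = FALSE)
  }
  if (!all(c("source", "target", "kind") %in% names(edges))) {
    stop(edge_table, ": line 1: expected header columns source, target, kind",
         call. = FALSE)
  }
  dup <- which(duplicated(nodes$id))
  if (length(dup) > 0) {
    stop(node_table, ": line ", dup[1] + 1L, ": duplicate node id '",
         nodes$id[dup[1]], "'", call. = FALSE)
  }
  bad <- which(!edges$kind %in% c("GD", "DP", "PH"))
  if (length(bad) > 0) {
    stop(edge_table, ": line ", bad[1] + 1L, ": unknown edge kind '",
         edges$kind[bad[1]], "'", call. = FALSE)
  }
  bad <- which(!(edges$source %in% nodes$id & edges$target %in% nodes$id))
  if (length(bad) > 0) {
    stop(edge_table, ": line ", bad[1] + 1L,
         ": edge references missing node '",
         setdiff(c(edges$source[bad[1]], edges$target[bad[1]]), nodes$id)[1],
         "'", call. = FALSE)
  }
  pdr_graph(nodes, edges, check = check)
}

#' Write a knowledge graph back to node and edge TSV tables
#'
#' Inverse of [load_graph()]: a load/save/load round trip preserves the node
#' set and the edge multiset.
#'
#' @param g A `pdr_graph`.
#' @param node_table,edge_table Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_graph <- function(g, node_table, edge_table) {
  nodes <- dplyr::mutate(
    g$nodes,
    dplyr::across(dplyr::all_of(c("is_gene", "is_disease", "is_phenotype")),
                  as.integer)
  )
  edges <- g$edges
  if (all(is.na(edges$causal)) && all(is.na(edges$moi))) {
    edges <- dplyr::select(edges, "source", "target", "kind")
  }
  readr::write_tsv(nodes, node_table, progress = FALSE)
  readr::write_tsv(edges, edge_table, progress = FALSE)
  invisible(list(node_table = node_table, edge_table = edge_table))
}

#' Validate knowledge-graph invariants
#'
#' Checks the edge-direction rules (GD runs gene to disease, DP disease to
#' phenotype, PH between hierarchy terms), rejects self-loops and duplicate
#' edges, verifies that the PH subgraph is acyclic, and warns about genes
#' with no GD edge. Structural problems are errors; isolated genes are
#' warnings.
#'
#' @param g A `pdr_graph`.
#' @return A tibble with columns `violation`, `severity` (`"error"` or
#'   `"warning"`), `count` and `detail` (up to five offending items). Zero
#'   rows means the graph is valid.
#' @export
validate_graph <- function(g) {
  nodes <- g$nodes
  edges <- g$edges
  out <- list()
  add <- function(violation, severity, items) {
    if (length(items) == 0) return()
    out[[length(out) + 1]] <<- tibble::tibble(
      violation = violation, severity = severity, count = length(items),
      detail = paste(utils::head(items, 5), collapse = ", ")
    )
  }
  role <- function(ids, r) {
    vapply(ids, function(i) node_role(g, i, r), logical(1))
  }

  add("no-role-node", "error",
      nodes$id[!(nodes$is_gene | nodes$is_disease | nodes$is_phenotype)])
  add("self-loop", "error",
      with(edges, paste0(source, "->", target)[source == target]))
  key <- paste(edges$source, edges$target, edges$kind)
  add("duplicate-edge", "error", key[duplicated(key)])

  gd <- edges[edges$kind == "GD", ]
  dp <- edges[edges$kind == "DP", ]
  ph <- edges[edges$kind == "PH", ]
  add("GD-source-not-gene", "error", gd$source[!role(gd$source, "gene")])
  add("GD-target-not-disease", "error",
      gd$target[!role(gd$target, "disease")])
  add("DP-source-not-disease", "error",
      dp$source[!role(dp$source, "disease")])
  add("DP-target-not-phenotype", "error",
      dp$target[!role(dp$target, "phenotype")])

  cyc <- ph_cycle_nodes(ph)
  add("PH-cycle", "error", cyc)

  lonely <- setdiff(nodes$id[nodes$is_gene], gd$source)
  add("gene-with-no-GD-edge", "warning", lonely)

  if (length(out) == 0) {
    tibble::tibble(violation = character(), severity = character(),
                   count = integer(), detail = character())
  } else {
    dplyr::bind_rows(out)
  }
}

# Kahn's algorithm on the PH subgraph; returns ids left on a cycle.
ph_cycle_nodes <- function(ph) {
  if (nrow(ph) == 0) return(character(0))
  ids <- unique(c(ph$source, ph$target))
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(ph$target)
  indeg[names(tab)] <- as.integer(tab)
  out_adj <- split(ph$target, factor(ph$source, levels = ids))
  queue <- ids[indeg == 0]
  removed <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    removed <- removed + 1L
    for (w in out_adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (removed == length(ids)) character(0) else ids[indeg > 0]
}

#' Number of diseases directly associated with a phenotype
#'
#' Counts the distinct disease nodes that carry a DP edge into the given
#' phenotype. This is the quantity `N` that drives the specificity weight:
#' a phenotype attached to many diseases is a weak discriminator and is
#' down-weighted accordingly.
#'
#' @param g A `pdr_graph`.
#' @param phenotype A phenotype node id (vectorised).
#' @return An integer vector of direct-disease counts, one per input id.
#' @seealso [specificity_weight()]
#' @export
direct_disease_count <- function(g, phenotype) {
  vapply(as.character(phenotype), function(p) {
    if (!has_node(g, p)) {
      stop("unknown node id: ", p, call. = FALSE)
    }
    length(idx_get(g$idx$dp_in, p))
  }, integer(1), USE.NAMES = FALSE)
}

#' Candidate diseases implicated by a gene set
#'
#' The first step of the ranking algorithm: collect every disease reachable
#' by one GD edge from any input gene, keeping back-references to the
#' implicating gene(s). Inputs that are not gene nodes are skipped and
#' reported, not fatal.
#'
#' @param g A `pdr_graph`.
#' @param genes Character vector of gene node ids.
#' @return A tibble with columns `disease`, `genes` (list column of
#'   implicating gene ids) and `n_genes`, sorted by disease id. The
#'   character vector of skipped inputs is attached as attribute
#'   `"skipped"`.
#' @export
candidate_diseases <- function(g, genes) {
  genes <- unique(as.character(genes))
  ok <- vapply(genes, function(x) node_role(g, x, "gene"), logical(1))
  skipped <- genes[!ok]
  genes <- genes[ok]
  pairs <- purrr::map_dfr(genes, function(gn) {
    ds <- idx_get(g$idx$gd_out, gn)
    if (length(ds) == 0) return(tibble::tibble())
    tibble::tibble(disease = ds, gene = gn)
  })
  if (nrow(pairs) == 0) {
    out <- tibble::tibble(disease = character(), genes = list(),
                          n_genes = integer())
  } else {
    out <- pairs |>
      dplyr::group_by(.data$disease) |>
      dplyr::summarise(genes = list(sort(unique(.data$gene))),
                       n_genes = length(genes[[1]]), .groups = "drop") |>
      dplyr::arrange(.data$disease)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Import an OBO hierarchy as graph tables
#'
#' Minimal reader for OBO 1.2/1.4 term stanzas: each `[Term]` becomes a
#' phenotype node, each `is_a` relation becomes a PH edge from the more
#' general parent to the more specific child, and names, synonyms, primary
#' and alternate identifiers are collected into a lexicon table suitable
#' for [build_lexicon()]. Obsolete terms are dropped.
#'
#' @param path Path to an OBO file.
#' @return A list of tibbles `nodes`, `edges`, `lexicon` in the formats
#'   accepted by [pdr_graph()] and [build_lexicon()].
#' @export
read_obo <- function(path) {
  lines <- readr::read_lines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  terms <- purrr::map(seq_along(starts), function(i) {
    blk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    blk <- blk[blk != "" & !startsWith(blk, "[")]
    kv <- stringr::str_match(blk, "^([a-z_]+):\\s*(.*)$")
    kv <- kv[!is.na(kv[, 1]), , drop = FALSE]
    fields <- split(kv[, 3], kv[, 2])
    if (!is.null(fields$is_obsolete) && any(fields$is_obsolete == "true")) {
      return(NULL)
    }
    syn <- character(0)
    if (!is.null(fields$synonym)) {
      syn <- stringr::str_match(fields$synonym, '^"([^"]*)"')[, 2]
      syn <- syn[!is.na(syn)]
    }
    list(
      id = fields$id[1],
      name = if (is.null(fields$name)) fields$id[1] else fields$name[1],
      alt_id = if (is.null(fields$alt_id)) character(0) else fields$alt_id,
      is_a = if (is.null(fields$is_a)) character(0) else
        stringr::str_trim(stringr::str_remove(fields$is_a, "!.*$")),
      synonyms = syn
    )
  })
  terms <- purrr::compact(terms)
  ids <- purrr::map_chr(terms, "id")
  nodes <- tibble::tibble(
    id = ids,
    name = purrr::map_chr(terms, "name"),
    is_gene = FALSE, is_disease = FALSE, is_phenotype = TRUE
  )
  edges <- purrr::map_dfr(terms, function(t) {
    parents <- intersect(t$is_a, ids)
    if (length(parents) == 0) return(tibble::tibble())
    tibble::tibble(source = parents, target = t$id, kind = "PH")
  })
  lexicon <- purrr::map_dfr(terms, function(t) {
    dplyr::bind_rows(
      tibble::tibble(surface = t$id, node = t$id, entry_kind = "primary_id"),
      tibble::tibble(surface = t$name, node = t$id,
                     entry_kind = "primary_name"),
      if (length(t$alt_id) > 0)
        tibble::tibble(surface = t$alt_id, node = t$id,
                       entry_kind = "alternate_id"),
      if (length(t$synonyms) > 0)
        tibble::tibble(surface = t$synonyms, node = t$id,
                       entry_kind = "synonym")
    )
  })
  list(nodes = nodes, edges = edges, lexicon = dplyr::distinct(lexicon))
}
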