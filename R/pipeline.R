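variant_severity <- function(classification, hgmd_dm, consequence) {
  dplyr::case_when(
    classification %in% "pathogenic" ~ 1L,
    classification %in% "likely_pathogenic" ~ 2L,
    hgmd_dm ~ 3L,
    consequence %in% lof_consequences ~ 4L,
    consequence %in% "missense" ~ 5L,
    TRUE ~ 6L
  )
}

#' Run the full phenotype-driven ranking pipeline
#'
#' End-to-end orchestration: map the patient's phenotype terms onto network
#' nodes, run the variant filter cascade to obtain the variant-impacted
#' gene set `G`, collect the candidate diseases `D` implicated by `G`,
#' score `D` against the mapped phenotypes with the constrained
#' shortest-path heuristic, and assemble the ranked, truncated
#' disease/gene/variant result table. Restricting the scoring to diseases
#' with variant-impacted genes is equivalent to scoring everything and
#' intersecting afterwards, because only `G`'s diseases can carry
#' implicating genes.
#'
#' Failure modes are distinct, named conditions: `pdr_no_phenotypes` (no
#' input term mapped — check spelling or supply HPO-style identifiers),
#' `pdr_no_variants` (nothing survived the filter cascade — check the
#' annotation sidecar), and `pdr_empty_result` (no candidate disease
#' connects to any phenotype within the path-length cap).
#'
#' @param graph A `pdr_graph`.
#' @param lexicon A `pdr_lexicon` for term mapping.
#' @param phenotypes Character vector of free-text terms / identifiers
#'   (e.g. from [read_phenotype_list()]).
#' @param variants A variant tibble from [read_variants()].
#' @param trio Optional trio genotypes ([trio_genotypes()]) enabling the de
#'   novo restriction.
#' @param params A [pdr_params()] object.
#' @param min_quality,max_freq,freq_mode Filter thresholds, see
#'   [filter_variants()].
#' @param log_path Optional path; when given, a JSON-lines log of mapping
#'   results, filter traces and candidate counts is written there.
#' @return A tibble of class `pdr_result` with one row per unique
#'   disease-gene-variant combination, in disease rank order: `rank`,
#'   `disease`, `disease_name`, `score`, `gene`, `variant`,
#'   `classification`, `causal`, `moi`, `moi_consistent`, `breakdown`.
#'   Rows sharing a disease share its score and breakdown. At most
#'   `params$table_limit` disease/gene pairs are kept and at most
#'   `params$variants_per_gene_limit` variant rows per pair. Attributes:
#'   `scores` (the full [score_diseases()] result), `mapping`,
#'   `trace`, `genes`, `truncation` (pairs shown / pairs total).
#' @export
run_pdr <- function(graph, lexicon, phenotypes, variants, trio = NULL,
                    params = pdr_params(), min_quality = 20,
                    max_freq = 0.005, freq_mode = "any", log_path = NULL) {
  mapping <- map_phenotype_list(lexicon, phenotypes)
  if (length(mapping$phenotypes) == 0) {
    rlang::abort(
      paste0("no phenotypes mapped (", length(mapping$unmapped),
             " unmapped input(s)); check spelling or supply identifiers"),
      class = "pdr_no_phenotypes"
    )
  }
  filtered <- filter_variants(variants, min_quality = min_quality,
                              max_freq = max_freq, freq_mode = freq_mode,
                              trio = trio)
  if (nrow(filtered) == 0) {
    rlang::abort(
      "no variants survive the filter cascade; inspect filter_trace()",
      class = "pdr_no_variants"
    )
  }
  genes <- variant_genes(filtered)
  if (nrow(genes) == 0) {
    rlang::abort(
      "surviving variants carry no gene assignment",
      class = "pdr_no_variants"
    )
  }
  D <- candidate_diseases(graph, genes$gene)
  if (nrow(D) == 0) {
    rlang::abort(
      "no candidate diseases: none of the variant-impacted genes has a known disease association",
      class = "pdr_empty_result"
    )
  }
  scores <- score_diseases(graph, mapping$phenotypes, D, params)
  if (nrow(scores) == 0) {
    rlang::abort(
      paste0("no candidate disease connects to any mapped phenotype within ",
             params$max_path_length, " edges"),
      class = "pdr_empty_result"
    )
  }

  result <- assemble_result(graph, scores, genes, params)
  attr(result, "scores") <- scores
  attr(result, "mapping") <- mapping
  attr(result, "trace") <- filter_trace(filtered)
  attr(result, "genes") <- genes

  if (!is.null(log_path)) {
    write_run_log(log_path, mapping, filter_trace(filtered), D, scores,
                  attr(result, "truncation"))
  }
  result
}

breakdown_string <- function(contributions) {
  paste(sprintf("%s:%.6f", contributions$phenotype,
                contributions$contribution), collapse = ";")
}

assemble_result <- function(graph, scores, genes, params) {
  gd <- dplyr::filter(graph$edges, .data$kind == "GD")
  variants_by_gene <- stats::setNames(genes$variants, genes$gene)

  pairs <- purrr::map_dfr(seq_len(nrow(scores)), function(i) {
    gs <- scores$genes[[i]]
    if (is.null(gs) || length(gs) == 0) return(tibble::tibble())
    tibble::tibble(
      disease_rank = i,
      disease = scores$disease[i],
      disease_name = scores$disease_name[i],
      score = scores$score[i],
      breakdown = breakdown_string(scores$contributions[[i]]),
      gene = sort(gs)
    )
  })
  pairs_total <- nrow(pairs)
  pairs <- utils::head(pairs, params$table_limit)

  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    edge <- gd[gd$source == pr$gene & gd$target == pr$disease, ]
    vs <- variants_by_gene[[pr$gene]]
    vs <- vs |>
      dplyr::mutate(severity = variant_severity(
        .data$classification, .data$hgmd_dm, .data$consequence
      )) |>
      dplyr::arrange(.data$severity, .data$chrom, .data$pos, .data$alt) |>
      utils::head(params$variants_per_gene_limit)
    tibble::tibble(
      rank = pr$disease_rank,
      disease = pr$disease,
      disease_name = pr$disease_name,
      score = pr$score,
      gene = pr$gene,
      variant = vs$key,
      classification = dplyr::coalesce(vs$classification, "absent"),
      genotype = vs$genotype,
      causal = dplyr::coalesce(edge$causal[1], "unknown"),
      moi = dplyr::coalesce(edge$moi[1], "unknown"),
      breakdown = pr$breakdown
    )
  })
  rows <- moi_consistency(rows, genes)
  rows <- dplyr::select(
    rows, "rank", "disease", "disease_name", "score", "gene", "variant",
    "classification", "causal", "moi", "moi_consistent", "breakdown"
  )
  structure(
    rows,
    truncation = list(pairs_shown = nrow(pairs), pairs_total = pairs_total),
    params = params,
    class = c("pdr_result", class(tibble::tibble()))
  )
}

#' Annotate result rows with mode-of-inheritance consistency
#'
#' Checks the zygosity of a gene's filter-passing variants against the
#' disease's annotated mode of inheritance: a dominant disease is
#' consistent with at least one heterozygous variant; a recessive disease
#' with a homozygous-alternate variant or with two or more distinct
#' heterozygous variants in the gene (gene-level counting is used as a
#' proxy for compound heterozygosity — phase is not assessed). Unknown MOI
#' yields `"unknown"`.
#'
#' @param rows A result-row tibble with columns `gene` and `moi`.
#' @param variants_by_gene The gene table from [variant_genes()].
#' @return `rows` with a `moi_consistent` column
#'   (`"yes"`/`"no"`/`"unknown"`).
#' @export
moi_consistency <- function(rows, variants_by_gene) {
  vmap <- stats::setNames(variants_by_gene$variants, variants_by_gene$gene)
  rows$moi_consistent <- purrr::map2_chr(rows$gene, rows$moi,
                                         function(gn, moi) {
    if (is.na(moi) || moi == "unknown") return("unknown")
    vs <- vmap[[gn]]
    if (is.null(vs)) return("unknown")
    n_het <- sum(vs$genotype == "het")
    n_hom <- sum(vs$genotype == "hom_alt")
    ok <- switch(moi,
      dominant = n_het >= 1,
      recessive = n_hom >= 1 || n_het >= 2,
      return("unknown")
    )
    if (ok) "yes" else "no"
  })
  rows
}

fmt_cell <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

#' Write a result table to TSV or JSON
#'
#' Column order is fixed (`rank, disease, score, gene, variant,
#' classification, causal, moi, moi_consistent, breakdown`), scores are
#' printed with six decimal places, and output is byte-identical across
#' repeated runs on identical input.
#'
#' @param result A `pdr_result` tibble.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  cols <- c("rank", "disease", "score", "gene", "variant", "classification",
            "causal", "moi", "moi_consistent", "breakdown")
  tab <- tibble::as_tibble(result)[, cols]
  tab$score <- sprintf("%.6f", as.numeric(tab$score))
  if (format == "tsv") {
    lines <- c(
      paste(cols, collapse = "\t"),
      purrr::map_chr(seq_len(nrow(tab)), function(i) {
        paste(purrr::map_chr(cols, ~ fmt_cell(tab[[.x]][i])),
              collapse = "\t")
      })
    )
    readr::write_lines(lines, path)
  } else {
    tab$rank <- as.integer(tab$rank)
    jsonlite::write_json(tab, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"json"`.
#' @return A tibble with the ten result columns; `rank` integer, `score`
#'   numeric.
#' @export
read_result_table <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- readr::read_tsv(path, col_types = readr::cols(
      rank = readr::col_integer(), score = readr::col_double(),
      .default = readr::col_character()
    ), progress = FALSE)
  } else {
    out <- tibble::as_tibble(jsonlite::fromJSON(path))
    if (nrow(out) > 0) {
      out$rank <- as.integer(out$rank)
      out$score <- as.numeric(out$score)
    }
  }
  out
}

write_run_log <- function(path, mapping, trace, D, scores, truncation) {
  entries <- c(
    list(list(event = "phenotype_mapping",
              n_input = nrow(mapping$matches),
              n_mapped = length(mapping$phenotypes),
              mapped_fraction = mapping$mapped_fraction,
              unmapped = mapping$unmapped)),
    purrr::map(seq_len(nrow(trace)), function(i) {
      list(event = "filter", filter = trace$filter[i],
           n_in = trace$n_in[i], n_out = trace$n_out[i])
    }),
    list(list(event = "candidates", n_candidate_diseases = nrow(D),
              n_scored = nrow(scores),
              n_dropped = attr(scores, "n_dropped"),
              pairs_shown = truncation$pairs_shown,
              pairs_total = truncation$pairs_total))
  )
  readr::write_lines(
    purrr::map_chr(entries, ~ jsonlite::toJSON(.x, auto_unbox = TRUE)),
    path
  )
  invisible(path)
}
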