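#' Tidy a disease score table into one row per phenotype contribution
#'
#' @param x A `pdr_scores` object from [score_diseases()].
#' @param ... Unused.
#' @return A tibble with one row per (disease, phenotype) contribution:
#'   `disease`, `disease_name`, `rank`, `phenotype`, `N` (direct disease
#'   count), `L` (shortest path length), `w_s`, `w_p`, `contribution`.
#' @export
tidy.pdr_scores <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("disease", "disease_name", "rank", "contributions") |>
    tidyr::unnest("contributions")
}

#' One-row summary of a disease score table
#'
#' @param x A `pdr_scores` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_candidates`, `n_scored`, `n_dropped`,
#'   `n_phenotypes`, `top_disease`, `top_score`.
#' @export
glance.pdr_scores <- function(x, ...) {
  tibble::tibble(
    n_candidates = attr(x, "n_candidates"),
    n_scored = nrow(x),
    n_dropped = attr(x, "n_dropped"),
    n_phenotypes = length(attr(x, "phenotypes")),
    top_disease = if (nrow(x) > 0) x$disease[1] else NA_character_,
    top_score = if (nrow(x) > 0) x$score[1] else NA_real_
  )
}

#' Tidy a pipeline result table
#'
#' @param x A `pdr_result` object from [run_pdr()].
#' @param ... Unused.
#' @return The result rows as a plain tibble.
#' @export
tidy.pdr_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `pdr_result` object.
#' @param ... Unused.
#' @return A one-row tibble with mapping, filtering, truncation and
#'   top-ranked summaries.
#' @export
glance.pdr_result <- function(x, ...) {
  mapping <- attr(x, "mapping")
  trace <- attr(x, "trace")
  trunc <- attr(x, "truncation")
  tibble::tibble(
    n_terms = nrow(mapping$matches),
    mapped_fraction = mapping$mapped_fraction,
    n_variants_in = if (nrow(trace) > 0) trace$n_in[1] else 0L,
    n_variants_pass = if (nrow(trace) > 0)
      trace$n_out[nrow(trace)] else 0L,
    pairs_shown = trunc$pairs_shown,
    pairs_total = trunc$pairs_total,
    top_disease = if (nrow(x) > 0) x$disease[1] else NA_character_,
    top_gene = if (nrow(x) > 0) x$gene[1] else NA_character_,
    top_score = if (nrow(x) > 0) x$score[1] else NA_real_
  )
}

#' Tidy a recovery experiment
#'
#' @param x A `pdr_recovery` object from [recovery_experiment()].
#' @param ... Unused.
#' @return The per-cutoff recovery tibble.
#' @export
tidy.pdr_recovery <- function(x, ...) {
  tibble::as_tibble(x)
}
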