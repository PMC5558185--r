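#' Normalize a phenotype term for matching
#'
#' Lower-cases the term, replaces hyphens and underscores with spaces,
#' collapses runs of whitespace and strips leading/trailing whitespace.
#' Matching of free-text terms against the lexicon happens on normalized
#' strings only, so spacing, capitalization and hyphenation differences do
#' not matter. The function is idempotent.
#'
#' @param term Character vector of raw terms.
#' @return Character vector of normalized terms.
#' @examples
#' normalize_term("Uni-lateral  Renal Agenesis")
#' @export
normalize_term <- function(term) {
  term |>
    stringr::str_to_lower() |>
    stringr::str_replace_all("[-_]", " ") |>
    stringr::str_squish()
}

hpo_id_pattern <- "^[A-Za-z]+:[0-9]{7}$"

normalize_id <- function(x) stringr::str_to_upper(stringr::str_trim(x))

#' Build a term lexicon for phenotype mapping
#'
#' A lexicon maps surface strings — primary names, synonyms, primary and
#' alternate HPO-style identifiers — onto phenotype nodes of a knowledge
#' graph. Name and synonym surfaces are indexed by their normalized form;
#' identifier surfaces by their upper-cased form. When two entries of the
#' same kind share a normalized surface but point at different nodes the
#' surface is ambiguous: it is reported in the `collisions` attribute and
#' deliberately matches nothing (silent arbitrary resolution would corrupt
#' downstream scores).
#'
#' @param entries A data frame with columns `surface`, `node`, `entry_kind`
#'   (one of `primary_name`, `synonym`, `primary_id`, `alternate_id`).
#' @param graph Optional `pdr_graph`; when given, entries whose node is
#'   absent from the graph are rejected.
#' @return An object of class `pdr_lexicon`; attribute `"collisions"` holds
#'   a tibble of ambiguous surfaces.
#' @export
build_lexicon <- function(entries, graph = NULL) {
  kinds <- c("primary_name", "synonym", "primary_id", "alternate_id")
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("surface", "node", "entry_kind") %in% names(entries)))
  bad <- setdiff(unique(entries$entry_kind), kinds)
  if (length(bad) > 0) {
    stop("unknown entry_kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(entries$surface))) {
    stop("empty surface string in lexicon", call. = FALSE)
  }
  if (!is.null(graph)) {
    missing <- setdiff(unique(entries$node), graph$nodes$id)
    if (length(missing) > 0) {
      stop("lexicon node(s) absent from graph: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  is_id <- entries$entry_kind %in% c("primary_id", "alternate_id")
  entries <- dplyr::mutate(
    entries,
    key = dplyr::if_else(is_id, normalize_id(.data$surface),
                         normalize_term(.data$surface))
  )
  collisions <- entries |>
    dplyr::distinct(.data$key, .data$entry_kind, .data$node) |>
    dplyr::count(.data$key, .data$entry_kind) |>
    dplyr::filter(.data$n > 1)
  ambiguous <- unique(paste(collisions$key, collisions$entry_kind))
  entries <- dplyr::distinct(entries, .data$key, .data$entry_kind,
                             .data$node, .keep_all = TRUE)
  entries$ambiguous <- paste(entries$key, entries$entry_kind) %in% ambiguous
  structure(entries, class = c("pdr_lexicon", class(entries)),
            collisions = collisions)
}

#' Read a lexicon from a TSV file
#'
#' Expected header: `surface  node  entry_kind` (tab-separated).
#'
#' @param path Path to the lexicon TSV.
#' @param graph Optional `pdr_graph` for node cross-checking.
#' @return A `pdr_lexicon`.
#' @export
read_lexicon <- function(path, graph = NULL) {
  entries <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  build_lexicon(entries, graph = graph)
}

#' Write a lexicon to TSV
#' @param lexicon A `pdr_lexicon` or compatible data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lexicon <- function(lexicon, path) {
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(lexicon), "surface", "node",
                  "entry_kind"),
    path, progress = FALSE
  )
  invisible(path)
}

lookup_kind <- function(lexicon, key, kind) {
  hit <- lexicon[lexicon$key == key & lexicon$entry_kind == kind, ]
  if (nrow(hit) == 0) return(NULL)
  if (any(hit$ambiguous)) return("__ambiguous__")
  hit$node[1]
}

#' Map a single term or identifier onto a phenotype node
#'
#' Strings shaped like an HPO identifier (`HP:` plus seven digits, any
#' prefix of letters accepted) are looked up as primary then alternate
#' identifiers; everything else is normalized and looked up against primary
#' names then synonyms. Precedence is deterministic:
#' id > primary name > synonym. A miss is a result (`match_kind = "none"`),
#' not an error; an ambiguous surface also yields `"none"` with a
#' diagnostic note.
#'
#' @param lexicon A `pdr_lexicon`.
#' @param term A single input string.
#' @return A one-row tibble: `query`, `normalized_query`, `matched_node`
#'   (`NA` if unmatched), `match_kind` (`id`, `exact_name`, `synonym`,
#'   `none`) and `note`.
#' @export
map_term <- function(lexicon, term) {
  stopifnot(is.character(term), length(term) == 1)
  res <- function(node, kind, norm, note = NA_character_) {
    tibble::tibble(query = term, normalized_query = norm,
                   matched_node = node, match_kind = kind, note = note)
  }
  if (stringr::str_detect(stringr::str_trim(term), hpo_id_pattern)) {
    key <- normalize_id(term)
    for (kind in c("primary_id", "alternate_id")) {
      node <- lookup_kind(lexicon, key, kind)
      if (identical(node, "__ambiguous__")) {
        return(res(NA_character_, "none", key, "ambiguous identifier"))
      }
      if (!is.null(node)) return(res(node, "id", key))
    }
    return(res(NA_character_, "none", key))
  }
  key <- normalize_term(term)
  if (!nzchar(key)) return(res(NA_character_, "none", key))
  name_node <- lookup_kind(lexicon, key, "primary_name")
  syn_node <- lookup_kind(lexicon, key, "synonym")
  shadow <- NA_character_
  if (!is.null(name_node) && !is.null(syn_node) &&
      !identical(name_node, syn_node)) {
    shadow <- "surface matches both a primary name and another node's synonym; primary name takes precedence"
  }
  if (identical(name_node, "__ambiguous__")) {
    return(res(NA_character_, "none", key, "ambiguous primary name"))
  }
  if (!is.null(name_node)) return(res(name_node, "exact_name", key, shadow))
  if (identical(syn_node, "__ambiguous__")) {
    return(res(NA_character_, "none", key, "ambiguous synonym"))
  }
  if (!is.null(syn_node)) return(res(syn_node, "synonym", key))
  res(NA_character_, "none", key)
}

#' Map a patient phenotype list onto network nodes
#'
#' Maps every input through [map_term()], collapses duplicates after
#' mapping, and reports the unmapped inputs verbatim. Mapping is
#' order-independent: permuting the inputs yields the same node set.
#'
#' @param lexicon A `pdr_lexicon`.
#' @param terms Character vector of free-text terms and/or identifiers.
#' @return A list with elements `phenotypes` (sorted character vector of
#'   matched node ids), `matches` (per-input tibble from [map_term()]),
#'   `unmapped` (inputs with no match) and `mapped_fraction`.
#' @export
map_phenotype_list <- function(lexicon, terms) {
  terms <- terms[!is.na(terms)]
  if (length(terms) == 0) {
    stop("no phenotypes supplied", call. = FALSE)
  }
  matches <- purrr::map_dfr(terms, ~ map_term(lexicon, .x))
  mapped <- matches$matched_node[!is.na(matches$matched_node)]
  list(
    phenotypes = sort(unique(mapped)),
    matches = matches,
    unmapped = matches$query[is.na(matches$matched_node)],
    mapped_fraction = mean(!is.na(matches$matched_node))
  )
}

#' Read a phenotype input file
#'
#' One free-text term or identifier per line, UTF-8; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path Path to the phenotype list.
#' @return Character vector of terms.
#' @export
read_phenotype_list <- function(path) {
  lines <- stringr::str_trim(readr::read_lines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
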