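#' Scoring and reporting parameters
#'
#' Bundles the tunable constants of the ranking heuristic and the result
#' table. The defaults are the published operating point of the method:
#' path decay `a = 0.75`, specificity decay `b = 1`, a maximum traversal
#' depth of 4 edges through the phenotype-disease hierarchy, a result table
#' truncated at the 50 highest-scoring disease/gene pairs, and at most 5
#' variant rows per disease/gene pair.
#'
#' @param a Path-decay factor in (0, 1]. The path weight of a phenotype
#'   reaching a disease through a shortest path of `L` edges is `a^(L - 1)`,
#'   so `a = 1` disables path decay.
#' @param b Specificity-decay factor (>= 0). The specificity weight of a
#'   phenotype directly connected to `N` diseases is
#'   `1 / (1 + b * log10(max(1, N)))`; `b = 0` disables specificity decay.
#' @param max_path_length Maximum number of edges allowed on a
#'   phenotype-to-disease path (positive integer).
#' @param table_limit Maximum number of disease/gene pairs kept in the
#'   result table.
#' @param variants_per_gene_limit Maximum number of variant rows shown per
#'   disease/gene pair.
#'
#' @return An object of class `pdr_params`: a named list of the five
#'   validated parameters.
#' @examples
#' pdr_params()
#' pdr_params(a = 0.9, max_path_length = 3)
#' @export
pdr_params <- function(a = 0.75,
                       b = 1,
                       max_path_length = 4L,
                       table_limit = 50L,
                       variants_per_gene_limit = 5L) {
  stopifnot(
    is.numeric(a), length(a) == 1, a > 0, a <= 1,
    is.numeric(b), length(b) == 1, b >= 0,
    is.numeric(max_path_length), length(max_path_length) == 1,
    max_path_length >= 1, max_path_length == as.integer(max_path_length),
    is.numeric(table_limit), table_limit >= 1,
    table_limit == as.integer(table_limit),
    is.numeric(variants_per_gene_limit), variants_per_gene_limit >= 1,
    variants_per_gene_limit == as.integer(variants_per_gene_limit)
  )
  structure(
    list(
      a = as.numeric(a),
      b = as.numeric(b),
      max_path_length = as.integer(max_path_length),
      table_limit = as.integer(table_limit),
      variants_per_gene_limit = as.integer(variants_per_gene_limit)
    ),
    class = "pdr_params"
  )
}

#' @export
print.pdr_params <- function(x, ...) {
  cat("<pdr_params>\n")
  cat(sprintf("  a (path decay):            %g\n", x$a))
  cat(sprintf("  b (specificity decay):     %g\n", x$b))
  cat(sprintf("  max path length:           %d\n", x$max_path_length))
  cat(sprintf("  table limit (pairs):       %d\n", x$table_limit))
  cat(sprintf("  variants shown per gene:   %d\n", x$variants_per_gene_limit))
  invisible(x)
}

#' Read scoring parameters from a flat key-value config file
#'
#' The config format is one `key = value` (or `key: value`) pair per line;
#' `#` starts a comment. Recognised keys are the five fields of
#' [pdr_params()]. Values given in `overrides` (typically from the command
#' line) win over the file, and the file wins over the defaults.
#'
#' @param path Path to the config file, or `NULL` for defaults only.
#' @param overrides Named list of parameter overrides applied on top of the
#'   file values.
#' @return A `pdr_params` object.
#' @export
read_params <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readr::read_lines(path)
    lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
    lines <- lines[lines != ""]
    m <- stringr::str_match(lines, "^([A-Za-z_]+)\\s*[:=]\\s*(.+)$")
    bad <- which(is.na(m[, 1]))
    if (length(bad) > 0) {
      stop("config line not of the form 'key = value': ", lines[bad[1]],
           call. = FALSE)
    }
    vals <- stats::setNames(as.list(as.numeric(m[, 3])), m[, 2])
  }
  vals[names(overrides)] <- overrides
  known <- c("a", "b", "max_path_length", "table_limit",
             "variants_per_gene_limit")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pdr_params, vals)
}
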