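syn_adjectives <- c("congenital", "unilateral", "bilateral", "progressive",
                    "recurrent", "proximal", "distal", "focal", "diffuse",
                    "severe", "mild", "atypical", "juvenile", "neonatal",
                    "chronic", "episodic")
syn_nouns <- c("dysgenesis", "agenesis", "hypoplasia", "hyperplasia",
               "atrophy", "dystrophy", "stenosis", "aplasia", "dysplasia",
               "sclerosis", "weakness", "anomaly", "malformation",
               "degeneration", "insufficiency", "dysfunction")

#' Generate a seeded synthetic phenotype-disease-gene network
#'
#' Builds a random network with the structural features of a curated
#' disease knowledge base — a multi-level term hierarchy, diseases attached
#' to tens of phenotypes, phenotypes shared across many diseases, genes
#' associated with several diseases, and a small fraction of dual-role
#' nodes that are both phenotype and disease — at node counts small enough
#' for simulation studies. Degree targets default to the reported content
#' means of the knowledge base the method was published on (43.4 phenotypes
#' per disease, 6.8 diseases per gene, ~6% dual-role phenotypes); counts
#' are drawn from Poisson distributions around those means. The hierarchy
#' is a random forest (each non-root term has one more-general parent), so
#' the PH subgraph is acyclic by construction. A synonym lexicon with 1-3
#' synonyms and `HPX:`-style primary (and some alternate) identifiers per
#' phenotype is generated alongside; the reserved `HPX:` prefix avoids
#' implying real HPO semantics. Output is a pure function of the
#' parameters and seed.
#'
#' @param n_genes,n_diseases,n_phenotypes Node counts (positive integers).
#' @param hierarchy_depth Number of levels in the term hierarchy.
#' @param mean_phenotypes_per_disease Poisson mean of DP out-degree.
#' @param mean_diseases_per_gene Poisson mean of GD out-degree.
#' @param dual_role_fraction Fraction of phenotypes that also act as
#'   diseases with their own downstream phenotypes.
#' @param dual_role_mean_phenotypes Poisson mean of the DP out-degree of
#'   dual-role nodes.
#' @param seed Integer seed; all randomness is local to this call.
#' @return A list of class `pdr_network`: `graph` (a validated
#'   [pdr_graph()]), `lexicon` (a [build_lexicon()] object), and the raw
#'   `nodes`, `edges`, `lexicon_table` tibbles.
#' @examples
#' net <- generate_network(n_genes = 10, n_diseases = 6, n_phenotypes = 30,
#'                         mean_phenotypes_per_disease = 5,
#'                         mean_diseases_per_gene = 2, seed = 1)
#' net$graph
#' @export
generate_network <- function(n_genes = 120,
                             n_diseases = 50,
                             n_phenotypes = 300,
                             hierarchy_depth = 4,
                             mean_phenotypes_per_disease = 43.4,
                             mean_diseases_per_gene = 6.8,
                             dual_role_fraction = 0.06,
                             dual_role_mean_phenotypes = 5,
                             seed = 1) {
  stopifnot(n_genes >= 1, n_diseases >= 1, n_phenotypes >= 2,
            hierarchy_depth >= 1, mean_phenotypes_per_disease > 0,
            mean_diseases_per_gene > 0,
            dual_role_fraction >= 0, dual_role_fraction <= 1)
  if (mean_phenotypes_per_disease > n_phenotypes) {
    stop("infeasible parameters: mean_phenotypes_per_disease exceeds ",
         "n_phenotypes", call. = FALSE)
  }
  if (mean_diseases_per_gene > n_diseases) {
    stop("infeasible parameters: mean_diseases_per_gene exceeds n_diseases",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    p_ids <- sprintf("P%04d", seq_len(n_phenotypes))
    p_names <- sprintf("%s %s %03d",
                       sample(syn_adjectives, n_phenotypes, replace = TRUE),
                       sample(syn_nouns, n_phenotypes, replace = TRUE),
                       seq_len(n_phenotypes))
    d_ids <- sprintf("D%03d", seq_len(n_diseases))
    d_names <- sprintf("%s syndrome %03d",
                       sample(syn_nouns, n_diseases, replace = TRUE),
                       seq_len(n_diseases))
    g_ids <- sprintf("G%04d", seq_len(n_genes))
    g_names <- sprintf("GEN%04d", seq_len(n_genes))

    # term hierarchy: a forest over the phenotype terms
    levels <- sample(rep_len(seq_len(hierarchy_depth), n_phenotypes))
    ph_edges <- purrr::map_dfr(which(levels > 1), function(i) {
      parents <- p_ids[levels == levels[i] - 1L]
      tibble::tibble(source = sample(parents, 1), target = p_ids[i],
                     kind = "PH")
    })

    dual <- sample(p_ids, round(dual_role_fraction * n_phenotypes))
    all_disease_ids <- c(d_ids, dual)

    dp_core <- purrr::map_dfr(seq_len(n_diseases), function(k) {
      n_k <- min(n_phenotypes,
                 max(1L, stats::rpois(1, mean_phenotypes_per_disease)))
      tibble::tibble(source = d_ids[k],
                     target = sample(p_ids, n_k), kind = "DP")
    })
    dp_dual <- purrr::map_dfr(dual, function(d) {
      pool <- setdiff(p_ids, d)
      n_k <- min(length(pool),
                 max(1L, stats::rpois(1, dual_role_mean_phenotypes)))
      tibble::tibble(source = d, target = sample(pool, n_k), kind = "DP")
    })
    gd <- purrr::map_dfr(seq_len(n_genes), function(j) {
      n_j <- min(length(all_disease_ids),
                 max(1L, stats::rpois(1, mean_diseases_per_gene)))
      tibble::tibble(
        source = g_ids[j],
        target = sample(all_disease_ids, n_j), kind = "GD",
        causal = sample(c("causal", "correlated"), n_j, replace = TRUE,
                        prob = c(0.6, 0.4)),
        moi = sample(c("dominant", "recessive", NA), n_j, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
      )
    })

    nodes <- dplyr::bind_rows(
      tibble::tibble(id = p_ids, name = p_names, is_gene = FALSE,
                     is_disease = p_ids %in% dual, is_phenotype = TRUE),
      tibble::tibble(id = d_ids, name = d_names, is_gene = FALSE,
                     is_disease = TRUE, is_phenotype = FALSE),
      tibble::tibble(id = g_ids, name = g_names, is_gene = TRUE,
                     is_disease = FALSE, is_phenotype = FALSE)
    )
    edges <- dplyr::bind_rows(ph_edges, dp_core, dp_dual, gd)

    n_syn <- sample(1:3, n_phenotypes, replace = TRUE)
    lexicon_table <- purrr::map_dfr(seq_len(n_phenotypes), function(i) {
      word <- strsplit(p_names[i], " ")[[1]]
      syns <- sprintf("%s-%s %03d type %d", word[1], word[2], i,
                      seq_len(n_syn[i]))
      dplyr::bind_rows(
        tibble::tibble(surface = p_names[i], node = p_ids[i],
                       entry_kind = "primary_name"),
        tibble::tibble(surface = sprintf("HPX:%07d", i), node = p_ids[i],
                       entry_kind = "primary_id"),
        if (i %% 3 == 0)
          tibble::tibble(surface = sprintf("HPX:%07d", 5000000L + i),
                         node = p_ids[i], entry_kind = "alternate_id"),
        tibble::tibble(surface = syns, node = p_ids[i],
                       entry_kind = "synonym")
      )
    })

    graph <- pdr_graph(nodes, edges, check = TRUE)
    structure(
      list(graph = graph,
           lexicon = build_lexicon(lexicon_table, graph = graph),
           nodes = nodes, edges = edges, lexicon_table = lexicon_table),
      class = "pdr_network"
    )
  })
}

#' Write a synthetic network to TSV tables
#'
#' Emits `nodes.tsv`, `edges.tsv` and `lexicon.tsv` in the formats read by
#' [load_graph()] and [read_lexicon()].
#'
#' @param net A `pdr_network` from [generate_network()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    nodes = file.path(dir, "nodes.tsv"),
    edges = file.path(dir, "edges.tsv"),
    lexicon = file.path(dir, "lexicon.tsv")
  )
  write_graph(net$graph, paths$nodes, paths$edges)
  write_lexicon(net$lexicon_table, paths$lexicon)
  invisible(paths)
}

#' Plant a simulated patient case in a synthetic network
#'
#' Emulates a solved rare-disease case: a causal disease and one of its
#' associated genes are drawn at random, the observed phenotype list is
#' sampled from the disease's directly attached phenotypes (expressed as a
#' random mix of primary names, synonyms and identifiers to exercise term
#' mapping) plus optional noise phenotypes drawn from outside the
#' disease's phenotype set, and a single-sample VCF plus annotation
#' sidecar is written containing one filter-passing variant in the causal
#' gene, one filter-passing decoy variant in each of `n_decoy_genes` other
#' genes, and `n_fail_variants` variants constructed to fail the cascade
#' (cycling through low call quality, high population frequency, and a
#' non-deleterious annotation).
#'
#' @param net A `pdr_network` from [generate_network()].
#' @param n_true Number of phenotypes sampled from the causal disease.
#' @param n_noise Number of noise phenotypes from outside its set.
#' @param n_decoy_genes Number of decoy genes with one passing variant.
#' @param n_fail_variants Number of additional filter-failing variants.
#' @param seed Integer seed.
#' @param dir Output directory (default a fresh temporary directory).
#' @return A list of class `pdr_case`: file paths (`phenotype_file`, `vcf`,
#'   `sidecar`, `truth_file`, `dir`), the surface `phenotypes`, and `truth`
#'   (causal disease, gene and variant key plus the sampling settings).
#' @export
plant_case <- function(net, n_true = 5, n_noise = 0, n_decoy_genes = 0,
                       n_fail_variants = 0, seed = 1,
                       dir = tempfile("pdr_case")) {
  g <- net$graph
  withr::with_seed(seed, {
    d_ids <- g$nodes$id[g$nodes$is_disease]
    eligible <- d_ids[vapply(d_ids, function(d) {
      length(idx_get(g$idx$dp_out, d)) >= n_true &&
        length(idx_get(g$idx$gd_in, d)) >= 1
    }, logical(1))]
    if (length(eligible) == 0) {
      stop("no disease with >= ", n_true,
           " phenotypes and an associated gene; regenerate the network ",
           "with higher mean_phenotypes_per_disease", call. = FALSE)
    }
    causal_disease <- sample(eligible, 1)
    causal_gene <- sample(idx_get(g$idx$gd_in, causal_disease), 1)
    own <- idx_get(g$idx$dp_out, causal_disease)
    true_ph <- sample(own, n_true)
    noise_pool <- setdiff(g$nodes$id[g$nodes$is_phenotype], own)
    noise_ph <- if (n_noise > 0) sample(noise_pool, n_noise) else character(0)

    surface_of <- function(node) {
      entries <- net$lexicon_table[net$lexicon_table$node == node, ]
      entries$surface[sample(nrow(entries), 1)]
    }
    surfaces <- vapply(c(true_ph, noise_ph), surface_of, character(1))
    surfaces <- sample(surfaces)

    gene_pool <- setdiff(g$nodes$id[g$nodes$is_gene], causal_gene)
    decoys <- if (n_decoy_genes > 0) sample(gene_pool, n_decoy_genes)
              else character(0)
    fail_genes <- if (n_fail_variants > 0)
      sample(gene_pool, n_fail_variants, replace = TRUE) else character(0)

    n_var <- 1L + length(decoys) + length(fail_genes)
    pos <- sort(sample(10000:999999, n_var))
    mk_var <- function(i, gene, qual, freq, consequence, classification,
                       dm) {
      tibble::tibble(
        chrom = "1", pos = pos[i], ref = "A", alt = "G", qual = qual,
        gene = gene, classification = classification, hgmd_dm = dm,
        consequence = consequence, freq = freq
      )
    }
    vars <- list(mk_var(1, causal_gene, 60, 1e-4, "stop_gain",
                        "pathogenic", 1L))
    for (j in seq_along(decoys)) {
      vars[[length(vars) + 1]] <-
        mk_var(1L + j, decoys[j], 50, 1e-4, "missense", "vus", 0L)
    }
    for (j in seq_along(fail_genes)) {
      mode <- (j - 1L) %% 3L
      vars[[length(vars) + 1]] <- switch(
        as.character(mode),
        "0" = mk_var(1L + length(decoys) + j, fail_genes[j], 5, 1e-4,
                     "missense", "vus", 0L),
        "1" = mk_var(1L + length(decoys) + j, fail_genes[j], 50, 0.2,
                     "missense", "vus", 0L),
        "2" = mk_var(1L + length(decoys) + j, fail_genes[j], 50, 1e-4,
                     "other", "vus", 0L)
      )
    }
    vars <- dplyr::bind_rows(vars)

    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    phenotype_file <- file.path(dir, "phenotypes.txt")
    vcf <- file.path(dir, "case.vcf")
    sidecar <- file.path(dir, "sidecar.tsv")
    truth_file <- file.path(dir, "truth.json")

    readr::write_lines(c("# simulated patient phenotypes", surfaces),
                       phenotype_file)
    readr::write_lines(c(
      "##fileformat=VCFv4.2",
      "##contig=<ID=1>",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "PROBAND"), collapse = "\t"),
      sprintf("1\t%d\t.\tA\tG\t%g\tPASS\t.\tGT\t0/1", vars$pos, vars$qual)
    ), vcf)
    readr::write_tsv(tibble::tibble(
      key = sprintf("1:%d:A:G", vars$pos),
      gene = vars$gene,
      classification = vars$classification,
      hgmd_dm = vars$hgmd_dm,
      consequence = vars$consequence,
      freq_1000g = vars$freq, freq_evs = vars$freq,
      freq_exac = vars$freq, freq_afc = vars$freq
    ), sidecar, progress = FALSE)
    truth <- list(
      causal_disease = causal_disease,
      causal_gene = causal_gene,
      causal_variant = sprintf("1:%d:A:G", pos[1]),
      true_phenotypes = unname(true_ph),
      noise_phenotypes = unname(noise_ph),
      n_true = n_true, n_noise = n_noise,
      n_decoy_genes = n_decoy_genes, n_fail_variants = n_fail_variants,
      seed = seed
    )
    jsonlite::write_json(truth, truth_file, auto_unbox = TRUE,
                         pretty = TRUE)
    structure(
      list(dir = dir, phenotype_file = phenotype_file, vcf = vcf,
           sidecar = sidecar, truth_file = truth_file,
           phenotypes = surfaces, truth = truth),
      class = "pdr_case"
    )
  })
}

#' Rank of the planted gene in a pipeline result
#'
#' Genes are ranked by first appearance in the (disease-ranked) result
#' table; `Inf` when the gene is absent.
#'
#' @param result A `pdr_result` tibble.
#' @param gene The planted causal gene id.
#' @return A numeric scalar rank.
#' @export
planted_gene_rank <- function(result, gene) {
  genes <- unique(result$gene)
  r <- match(gene, genes)
  if (is.na(r)) Inf else as.numeric(r)
}

#' Planted-case recovery experiment
#'
#' Repeatedly plants a case in a fixed network (replicate `i` uses seed
#' `seed + i`), runs the full pipeline on the simulated inputs, and records
#' the rank of the planted causal gene. Reports the fraction of replicates
#' in which the gene was recovered within each cutoff `k`, with binomial
#' standard errors.
#'
#' @param net A `pdr_network`.
#' @param n_reps Number of replicates.
#' @param k Integer cutoffs for top-k recovery (use `Inf` for "survives at
#'   all").
#' @param n_true,n_noise,n_decoy_genes,n_fail_variants Case parameters,
#'   see [plant_case()].
#' @param params A [pdr_params()] object.
#' @param seed Base seed.
#' @return A tibble of class `pdr_recovery` with columns `k`, `n_reps`,
#'   `n_recovered`, `fraction`, `se`; the per-replicate ranks are attached
#'   as attribute `"ranks"`.
#' @export
recovery_experiment <- function(net, n_reps = 50, k = c(1, 5, 10),
                                n_true = 5, n_noise = 0, n_decoy_genes = 0,
                                n_fail_variants = 0,
                                params = pdr_params(), seed = 1) {
  stopifnot(n_reps >= 1)
  ranks <- vapply(seq_len(n_reps), function(i) {
    case <- plant_case(net, n_true = n_true, n_noise = n_noise,
                       n_decoy_genes = n_decoy_genes,
                       n_fail_variants = n_fail_variants, seed = seed + i)
    on.exit(unlink(case$dir, recursive = TRUE), add = TRUE)
    vs <- read_variants(case$vcf, case$sidecar)
    res <- tryCatch(
      run_pdr(net$graph, net$lexicon,
              read_phenotype_list(case$phenotype_file), vs,
              params = params),
      pdr_empty_result = function(e) NULL,
      pdr_no_variants = function(e) NULL
    )
    if (is.null(res)) Inf else planted_gene_rank(res, case$truth$causal_gene)
  }, numeric(1))
  out <- tibble::tibble(
    k = as.numeric(k),
    n_reps = as.integer(n_reps),
    n_recovered = vapply(k, function(kk) sum(ranks <= kk), integer(1))
  )
  out$fraction <- out$n_recovered / n_reps
  out$se <- sqrt(out$fraction * (1 - out$fraction) / n_reps)
  attr(out, "ranks") <- ranks
  class(out) <- c("pdr_recovery", class(tibble::tibble()))
  out
}
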