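# In-code fixtures shared across test files.

node_row <- function(id, name = id, gene = FALSE, disease = FALSE,
                     phenotype = FALSE) {
  tibble::tibble(id = id, name = name, is_gene = gene, is_disease = disease,
                 is_phenotype = phenotype)
}

# Minimal 3-node graph: g1 -GD-> d1 -DP-> p1.
minimal_graph <- function() {
  pdr_graph(
    nodes = dplyr::bind_rows(
      node_row("g1", gene = TRUE),
      node_row("d1", disease = TRUE),
      node_row("p1", phenotype = TRUE)
    ),
    edges = tibble::tibble(source = c("g1", "d1"), target = c("d1", "p1"),
                           kind = c("GD", "DP"))
  )
}

# Chain graph: phenotype p reaches the only disease d through n_ph hierarchy
# terms, i.e. the shortest valid path has n_ph + 1 edges.
chain_graph <- function(n_ph) {
  terms <- sprintf("t%d", seq_len(n_ph))
  nodes <- dplyr::bind_rows(
    node_row("g", gene = TRUE),
    node_row("d", disease = TRUE),
    node_row("p", phenotype = TRUE),
    purrr::map_dfr(terms, ~ node_row(.x, phenotype = TRUE))
  )
  chain <- c("p", terms)
  ph <- tibble::tibble(
    source = chain[-1], target = chain[-length(chain)], kind = "PH"
  )
  edges <- dplyr::bind_rows(
    tibble::tibble(source = "g", target = "d", kind = "GD"),
    tibble::tibble(source = "d", target = terms[n_ph], kind = "DP"),
    ph
  )
  pdr_graph(nodes, edges)
}

# A solved-case style fixture: one disease with an associated gene, four
# directly attached phenotypes and a fifth connected only through two
# intermediate hierarchy terms (so its shortest path has 3 edges). A decoy
# disease shares two of the direct phenotypes.
worked_case <- function() {
  direct <- c("meningomyelocele", "prominent nose", "hirsutism",
              "retrognathia")
  nodes <- dplyr::bind_rows(
    node_row("GENE_A", "gene A", gene = TRUE),
    node_row("GENE_B", "gene B", gene = TRUE),
    node_row("DIS_A", "syndrome A", disease = TRUE),
    node_row("DIS_B", "syndrome B", disease = TRUE),
    purrr::map_dfr(sprintf("PH_%d", 1:4), ~ node_row(.x, phenotype = TRUE)),
    node_row("PH_5", "unilateral renal agenesis", phenotype = TRUE),
    node_row("INT_1", "dysgenesis", phenotype = TRUE),
    node_row("INT_2", "unilateral renal dysgenesis", phenotype = TRUE)
  )
  nodes$name[match(sprintf("PH_%d", 1:4), nodes$id)] <- direct
  edges <- dplyr::bind_rows(
    tibble::tibble(source = c("GENE_A", "GENE_B"),
                   target = c("DIS_A", "DIS_B"), kind = "GD",
                   causal = c("causal", "correlated"),
                   moi = c("dominant", NA)),
    tibble::tibble(source = "DIS_A", target = sprintf("PH_%d", 1:4),
                   kind = "DP"),
    tibble::tibble(source = "DIS_B", target = c("PH_1", "PH_2"),
                   kind = "DP"),
    # hierarchy INT_1 > INT_2 > PH_5; the disease attaches at INT_1, so
    # PH_5 reaches DIS_A in 3 edges crossing both intermediates
    tibble::tibble(source = c("INT_1", "INT_2"),
                   target = c("INT_2", "PH_5"), kind = "PH"),
    tibble::tibble(source = "DIS_A", target = "INT_1", kind = "DP")
  )
  pdr_graph(nodes, edges)
}

worked_case_lexicon <- function() {
  build_lexicon(tibble::tibble(
    surface = c("meningomyelocele", "unilateral renal agenesis",
                "prominent nose", "hirsutism", "retrognathia",
                "HP:0000001", "meningo-myelocele"),
    node = c("PH_1", "PH_5", "PH_2", "PH_3", "PH_4", "PH_1", "PH_1"),
    entry_kind = c(rep("primary_name", 5), "primary_id", "synonym")
  ))
}

# Write a small single- or multi-sample VCF; gts is a named list of
# genotype strings per sample, each the same length as pos.
write_toy_vcf <- function(path, pos, qual, gts = list(PROBAND = NULL),
                          ref = "A", alt = "G", chrom = "1") {
  n <- length(pos)
  qual <- rep_len(qual, n)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  samples <- names(gts)
  gts <- purrr::map(gts, ~ if (is.null(.x)) rep("0/1", n) else .x)
  body <- vapply(seq_len(n), function(i) {
    paste(c(chrom, pos[i], ".", ref[i], alt[i], qual[i], "PASS", ".", "GT",
            vapply(samples, function(s) gts[[s]][i], character(1))),
          collapse = "\t")
  }, character(1))
  readr::write_lines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}

# Matching sidecar writer; defaults make every variant pass the
# deleterious and common-variant filters.
write_toy_sidecar <- function(path, keys, gene,
                              classification = "vus",
                              hgmd_dm = 0L,
                              consequence = "missense",
                              freq = 1e-4) {
  n <- length(keys)
  readr::write_tsv(tibble::tibble(
    key = keys,
    gene = rep_len(gene, n),
    classification = rep_len(classification, n),
    hgmd_dm = rep_len(hgmd_dm, n),
    consequence = rep_len(consequence, n),
    freq_1000g = rep_len(freq, n),
    freq_evs = rep_len(freq, n),
    freq_exac = rep_len(freq, n),
    freq_afc = rep_len(freq, n)
  ), path, progress = FALSE)
  path
}

toy_variants <- function(pos, qual, gene, dir = withr::local_tempdir(
                           .local_envir = parent.frame()), ...) {
  vcf <- write_toy_vcf(file.path(dir, "t.vcf"), pos, qual)
  keys <- sprintf("1:%d:A:G", pos)
  sc <- write_toy_sidecar(file.path(dir, "t.tsv"), keys, gene, ...)
  read_variants(vcf, sc)
}
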