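consequence_levels <- c("frameshift", "start_loss", "start_gain",
                        "stop_loss", "stop_gain", "splice_site", "missense",
                        "other")
lof_consequences <- c("frameshift", "start_loss", "start_gain", "stop_loss",
                      "stop_gain", "splice_site")
classification_levels <- c("pathogenic", "likely_pathogenic", "vus",
                           "likely_benign", "benign")
freq_cols <- c("freq_1000g", "freq_evs", "freq_exac", "freq_afc")

# Decompose a vcfR object into one row per (site, alt allele, sample).
decompose_gt <- function(vcf, sample) {
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!sample %in% samples) {
    stop("sample '", sample, "' not found in VCF (has: ",
         paste(samples, collapse = ", "), ")", call. = FALSE)
  }
  gt_field <- function(i) {
    fmt <- strsplit(vcf@gt[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    val <- strsplit(vcf@gt[i, sample], ":", fixed = TRUE)[[1]]
    pos <- match("GT", fmt)
    if (is.na(pos) || pos > length(val)) NA_character_ else val[pos]
  }
  purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gt <- gt_field(i)
    alleles <- if (is.na(gt)) character(0) else
      strsplit(gt, "[/|]")[[1]]
    purrr::map_dfr(seq_along(alts), function(a) {
      geno <- if (length(alleles) == 0 || all(alleles == ".")) {
        "missing"
      } else {
        known <- alleles[alleles != "."]
        n_alt <- sum(known == as.character(a))
        if (length(known) == 1 && n_alt == 1) "hemi"
        else if (n_alt == 0) "ref"
        else if (n_alt == length(known)) "hom_alt"
        else "het"
      }
      tibble::tibble(
        chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]),
        ref = fix$REF[i],
        alt = alts[a],
        call_quality = suppressWarnings(as.numeric(fix$QUAL[i])),
        genotype = geno
      )
    })
  })
}

#' Read variants from a VCF with an annotation sidecar
#'
#' Reads a VCF 4.x file (plain or bgzipped, via \pkg{vcfR}), decomposes
#' multi-allelic sites into one record per alternate allele, derives the
#' proband zygosity from the GT field, and joins the annotation sidecar by
#' the `chrom:pos:ref:alt` key. Inputs are assumed left-normalized; no
#' re-normalization is attempted. Variants without a sidecar row keep all
#' annotation fields absent (`NA`) — they are not dropped here.
#'
#' The sidecar is a TSV with header
#' `key gene classification hgmd_dm consequence freq_1000g freq_evs
#' freq_exac freq_afc`; empty cells mean "absent". Frequencies are
#' fractions in `[0, 1]`; `classification` uses the five ACMG tiers;
#' `consequence` is one of `r paste(consequence_levels, collapse = ", ")`.
#'
#' @param vcf Path to the VCF file.
#' @param sidecar Path to the annotation sidecar TSV.
#' @param sample VCF sample name for genotype extraction; default the first
#'   sample column.
#' @return A tibble with one row per bi-allelic variant record: `key`,
#'   coordinates, `call_quality` (the VCF QUAL), `genotype` (`het`,
#'   `hom_alt`, `hemi`, `ref`, `missing`; `ref` is kept distinct from
#'   `missing` because the trio filter must tell a genotyped
#'   homozygous-reference parent from an uncalled one) and the joined
#'   annotation columns.
#' @export
read_variants <- function(vcf, sidecar, sample = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  if (is.null(sample)) sample <- colnames(v@gt)[2]
  vs <- decompose_gt(v, sample)
  vs <- dplyr::mutate(
    vs, key = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"),
    .before = 1
  )
  ann <- readr::read_tsv(sidecar, col_types = readr::cols(
    key = readr::col_character(),
    gene = readr::col_character(),
    classification = readr::col_character(),
    hgmd_dm = readr::col_character(),
    consequence = readr::col_character(),
    freq_1000g = readr::col_double(),
    freq_evs = readr::col_double(),
    freq_exac = readr::col_double(),
    freq_afc = readr::col_double()
  ), progress = FALSE)
  dup <- ann$key[duplicated(ann$key)]
  if (length(dup) > 0) {
    stop("sidecar key collision: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_cls <- setdiff(stats::na.omit(unique(ann$classification)),
                     classification_levels)
  if (length(bad_cls) > 0) {
    stop("unknown classification value(s): ",
         paste(bad_cls, collapse = ", "), call. = FALSE)
  }
  bad_csq <- setdiff(stats::na.omit(unique(ann$consequence)),
                     consequence_levels)
  if (length(bad_csq) > 0) {
    stop("unknown consequence value(s): ",
         paste(bad_csq, collapse = ", "), call. = FALSE)
  }
  ann <- dplyr::mutate(
    ann,
    hgmd_dm = .data$hgmd_dm %in% c("1", "TRUE", "true", "yes")
  )
  out <- dplyr::left_join(vs, ann, by = "key")
  out$hgmd_dm[is.na(out$hgmd_dm)] <- FALSE
  bad_f <- purrr::map_lgl(freq_cols, function(cl) {
    any(!is.na(out[[cl]]) & (out[[cl]] < 0 | out[[cl]] > 1))
  })
  if (any(bad_f)) {
    stop("allele frequencies must be fractions in [0, 1] (check column ",
         freq_cols[which(bad_f)[1]], ")", call. = FALSE)
  }
  attr(out, "trace") <- new_trace()
  out
}

new_trace <- function() {
  tibble::tibble(filter = character(), n_in = integer(), n_out = integer(),
                 removed = list())
}

apply_filter <- function(vs, keep, name) {
  keep[is.na(keep)] <- FALSE
  trace <- attr(vs, "trace")
  if (is.null(trace)) trace <- new_trace()
  out <- vs[keep, , drop = FALSE]
  attr(out, "trace") <- dplyr::bind_rows(trace, tibble::tibble(
    filter = name, n_in = nrow(vs), n_out = nrow(out),
    removed = list(vs$key[!keep])
  ))
  out
}

#' Per-filter trace of a variant cascade
#'
#' Each filter records how many variants it saw, how many survived, and
#' which keys it removed; counts telescope (the survivors of one filter are
#' the inputs of the next).
#'
#' @param vs A variant tibble that has passed through one or more filters.
#' @return A tibble `filter`, `n_in`, `n_out`, `removed` (list column).
#' @export
filter_trace <- function(vs) {
  tr <- attr(vs, "trace")
  if (is.null(tr)) new_trace() else tr
}

#' Confidence filter: drop low-quality calls
#'
#' Retains variants whose call quality (VCF QUAL) is at least the
#' threshold; the published cascade removes calls with quality below 20,
#' so a call of exactly 20 survives. Records with missing quality are
#' removed (conservative).
#'
#' @param vs A variant tibble from [read_variants()].
#' @param min_quality Minimum retained call quality (default 20).
#' @return The surviving variants, with an updated [filter_trace()].
#' @export
confidence_filter <- function(vs, min_quality = 20) {
  apply_filter(vs, !is.na(vs$call_quality) & vs$call_quality >= min_quality,
               "confidence")
}

#' Common-variant filter: drop variants frequent in the population
#'
#' A variant is removed when its allele frequency exceeds `max_freq`
#' (default 0.5%) in at least one of the four sources (1000 Genomes,
#' NHLBI-EVS, ExAC, Allele Frequency Community); a frequency of exactly
#' `max_freq` is retained. Absent frequencies count as 0 (rare). Set
#' `mode = "all"` to remove only variants common in every source that
#' reports them.
#'
#' @param vs A variant tibble.
#' @param max_freq Maximum retained allele frequency (fraction, default
#'   0.005).
#' @param mode `"any"` (default) or `"all"` source semantics.
#' @return The surviving variants, with an updated [filter_trace()].
#' @export
common_variant_filter <- function(vs, max_freq = 0.005,
                                  mode = c("any", "all")) {
  mode <- match.arg(mode)
  f <- as.matrix(vs[, freq_cols])
  f[is.na(f)] <- 0
  common <- if (mode == "any") {
    apply(f > max_freq, 1, any)
  } else {
    apply(f > max_freq, 1, all)
  }
  if (nrow(vs) == 0) common <- logical(0)
  apply_filter(vs, !common, "common_variant")
}

#' Predicted-deleterious filter
#'
#' Retains a variant when any of the following holds: it has been
#' classified pathogenic or likely pathogenic (ACMG tiers, consumed as an
#' input annotation, never computed here); it carries the HGMD
#' disease-causing-mutation (DM) tag; its consequence implies loss or gain
#' of function (frameshift, start/stop loss or gain, splice site); or it
#' is a missense variant.
#'
#' @param vs A variant tibble.
#' @return The surviving variants, with an updated [filter_trace()].
#' @export
deleterious_filter <- function(vs) {
  keep <- (vs$classification %in% c("pathogenic", "likely_pathogenic")) |
    vs$hgmd_dm |
    (vs$consequence %in% lof_consequences) |
    (vs$consequence %in% "missense")
  apply_filter(vs, keep, "deleterious")
}

#' Extract trio genotypes from a VCF
#'
#' Decomposes the same VCF as [read_variants()] for the proband and both
#' parents, returning one row per variant key with the three zygosities.
#'
#' @param vcf Path to a VCF containing all three samples.
#' @param proband,mother,father Sample names in the VCF.
#' @return A tibble `key`, `proband`, `mother`, `father`.
#' @export
trio_genotypes <- function(vcf, proband, mother, father) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  one <- function(s) {
    decompose_gt(v, s) |>
      dplyr::transmute(
        key = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"),
        genotype = .data$genotype
      )
  }
  out <- one(proband) |>
    dplyr::rename(proband = "genotype") |>
    dplyr::left_join(dplyr::rename(one(mother), mother = "genotype"),
                     by = "key") |>
    dplyr::left_join(dplyr::rename(one(father), father = "genotype"),
                     by = "key")
  out
}

#' De novo filter against trio genotypes
#'
#' Optional restriction used when whole-genome data of both parents is
#' available: retain a variant only when the proband carries at least one
#' alternate allele and both parents are genotyped homozygous reference at
#' that key. A missing or uncalled parental genotype removes the variant
#' (conservative).
#'
#' @param vs A variant tibble.
#' @param trio A tibble from [trio_genotypes()], or `NULL`.
#' @return The surviving variants, with an updated [filter_trace()].
#' @export
denovo_filter <- function(vs, trio) {
  if (is.null(trio) || !all(c("proband", "mother", "father") %in%
                            names(trio))) {
    stop("trio genotypes for both parents are required; ",
         "skip this optional filter when parental data is unavailable",
         call. = FALSE)
  }
  m <- match(vs$key, trio$key)
  proband <- trio$proband[m]
  mother <- trio$mother[m]
  father <- trio$father[m]
  keep <- proband %in% c("het", "hom_alt", "hemi") &
    mother %in% "ref" & father %in% "ref"
  apply_filter(vs, keep, "de_novo")
}

#' Run the full variant filter cascade
#'
#' Applies, in order: confidence, common-variant, predicted-deleterious,
#' and (when trio genotypes are supplied) the de novo filter. The first
#' three filters are pointwise predicates, so the surviving set is
#' order-independent; only the trace attributes depend on the order.
#'
#' @param vs A variant tibble from [read_variants()].
#' @param min_quality,max_freq,freq_mode Thresholds passed to the
#'   individual filters.
#' @param trio Optional trio genotypes for the de novo restriction.
#' @return Surviving variants with the accumulated [filter_trace()].
#' @export
filter_variants <- function(vs, min_quality = 20, max_freq = 0.005,
                            freq_mode = "any", trio = NULL) {
  out <- vs |>
    confidence_filter(min_quality) |>
    common_variant_filter(max_freq, mode = freq_mode) |>
    deleterious_filter()
  if (!is.null(trio)) out <- denovo_filter(out, trio)
  out
}

#' Variant-impacted gene set
#'
#' Collapses surviving variants to the distinct genes they impact — the
#' gene set `G` that is intersected with disease genes. Variants without a
#' gene assignment are excluded and counted in the trace.
#'
#' @param vs A variant tibble (typically after [filter_variants()]).
#' @return A tibble `gene`, `n_variants`, `variants` (list column of
#'   per-gene variant tibbles), sorted by gene id; attribute
#'   `"n_unassigned"` counts variants without a gene.
#' @export
variant_genes <- function(vs) {
  unassigned <- sum(is.na(vs$gene))
  out <- vs |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      variants = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene)
  attr(out, "n_unassigned") <- unassigned
  out
}
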