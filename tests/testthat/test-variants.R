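test_that("VCF records join the sidecar and decompose multi-allelic sites", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  readr::write_lines(c(
    "##fileformat=VCFv4.2", "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    "1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
    "1\t200\t.\tA\tC,T\t40\tPASS\t.\tGT\t1/2",
    "1\t300\t.\tG\tA\t30\tPASS\t.\tGT\t1/1"
  ), vcf)
  sc <- write_toy_sidecar(file.path(dir, "t.tsv"),
                          c("1:100:A:G", "1:200:A:C", "1:300:G:A"),
                          gene = c("gA", "gB", "gC"))
  vs <- read_variants(vcf, sc)
  expect_equal(nrow(vs), 4) # multi-allelic site contributes two records
  expect_equal(sum(vs$pos == 200), 2)
  expect_equal(vs$genotype[vs$key == "1:200:A:C"], "het")
  expect_equal(vs$genotype[vs$key == "1:300:G:A"], "hom_alt")
  # the T allele has no sidecar row: annotations absent, not dropped
  expect_true(is.na(vs$gene[vs$key == "1:200:A:T"]))
  expect_equal(vs$gene[vs$key == "1:100:A:G"], "gA")
})

test_that("sidecar key collisions and bad enum values are rejected", {
  dir <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(dir, "t.vcf"), 100, 50)
  sc <- write_toy_sidecar(file.path(dir, "dup.tsv"),
                          c("1:100:A:G", "1:100:A:G"), gene = "gA")
  expect_error(read_variants(vcf, sc), "key collision")
  sc2 <- write_toy_sidecar(file.path(dir, "bad.tsv"), "1:100:A:G",
                           gene = "gA", classification = "oddball")
  expect_error(read_variants(vcf, sc2), "classification")
})

test_that("confidence filter keeps the quality-20 boundary", {
  vs <- toy_variants(pos = c(100, 200, 300), qual = c(19.9, 20, 25),
                     gene = "gA")
  out <- confidence_filter(vs)
  expect_equal(out$call_quality, c(20, 25))
  tr <- filter_trace(out)
  expect_equal(tr$n_in, 3L)
  expect_equal(tr$n_out, 2L)
  expect_equal(tr$removed[[1]], "1:100:A:G")
  # identity on high qualities; empty input stays empty with a 0/0 trace
  expect_equal(nrow(confidence_filter(toy_variants(1:3 * 100, rep(100, 3),
                                                   "gA"))), 3)
  empty <- confidence_filter(vs[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(filter_trace(empty)$n_in, 0L)
})

test_that("common-variant filter removes on any-source excess above 0.5%", {
  vs <- toy_variants(pos = c(100, 200, 300), qual = 50, gene = "gA")
  vs$freq_1000g <- c(0.004, 0.005, NA)
  vs$freq_evs <- c(NA, 0.005, NA)
  vs$freq_exac <- c(0.006, 0.005, NA)
  vs$freq_afc <- c(NA, 0.005, NA)
  out <- common_variant_filter(vs)
  # one source above threshold -> removed; all exactly 0.005 -> kept;
  # no data -> rare -> kept
  expect_equal(out$pos, c(200, 300))
  # all-source mode only removes when every reporting source is common
  out2 <- common_variant_filter(vs, mode = "all")
  expect_equal(nrow(out2), 3)
  vs$freq_1000g <- 0.01
  vs$freq_evs <- 0.01
  vs$freq_exac <- 0.01
  vs$freq_afc <- 0.01
  expect_equal(nrow(common_variant_filter(vs, mode = "all")), 0)
})

test_that("deleterious filter clauses fire independently", {
  dir <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(dir, "t.vcf"), 1:5 * 100, rep(50, 5))
  keys <- sprintf("1:%d:A:G", 1:5 * 100)
  sc <- write_toy_sidecar(
    file.path(dir, "t.tsv"), keys, gene = "gA",
    classification = c("benign", "vus", "likely_pathogenic", "vus", "vus"),
    hgmd_dm = c(0L, 1L, 0L, 0L, 0L),
    consequence = c("missense", "other", "other", "frameshift", "other")
  )
  vs <- read_variants(vcf, sc)
  out <- deleterious_filter(vs)
  # benign missense kept (missense clause); DM-with-other kept; likely
  # pathogenic kept; frameshift kept; plain vus/other removed
  expect_equal(out$pos, 1:4 * 100)
  expect_equal(filter_trace(out)$removed[[1]], "1:500:A:G")
})

test_that("de novo filter requires alt in proband and hom-ref parents", {
  dir <- withr::local_tempdir()
  pos <- 1:4 * 100
  vcf <- write_toy_vcf(
    file.path(dir, "trio.vcf"), pos, rep(50, 4),
    gts = list(
      KID = c("0/1", "0/1", "0/1", "0/0"),
      MOM = c("0/0", "0/1", "./.", "0/0"),
      DAD = c("0/0", "0/0", "0/0", "0/0")
    )
  )
  sc <- write_toy_sidecar(file.path(dir, "t.tsv"),
                          sprintf("1:%d:A:G", pos), gene = "gA")
  vs <- read_variants(vcf, sc, sample = "KID")
  trio <- trio_genotypes(file.path(dir, "trio.vcf"), "KID", "MOM", "DAD")
  expect_equal(trio$mother, c("ref", "het", "missing", "ref"))
  out <- denovo_filter(vs, trio)
  # kept: proband het + both parents hom-ref; removed: inherited (father
  # het), missing mother genotype, and proband without the alt allele
  expect_equal(out$pos, 100)
  expect_error(denovo_filter(vs, NULL), "skip this optional filter")
})

test_that("the survivor set is order-independent across filter orderings", {
  withr::with_seed(31, {
    dir <- withr::local_tempdir()
    n <- 40
    pos <- sort(sample(1000:99999, n))
    vcf <- write_toy_vcf(file.path(dir, "t.vcf"), pos,
                         qual = sample(c(5, 19, 20, 90), n, replace = TRUE))
    sc <- write_toy_sidecar(
      file.path(dir, "t.tsv"), sprintf("1:%d:A:G", pos),
      gene = sample(c("gA", "gB"), n, replace = TRUE),
      classification = sample(c("pathogenic", "vus", "benign"), n,
                              replace = TRUE),
      hgmd_dm = sample(0:1, n, replace = TRUE),
      consequence = sample(c("missense", "other", "splice_site"), n,
                           replace = TRUE),
      freq = sample(c(1e-4, 0.004, 0.02), n, replace = TRUE)
    )
    vs <- read_variants(vcf, sc)
    canonical <- filter_variants(vs)
    reordered <- vs |>
      deleterious_filter() |>
      common_variant_filter() |>
      confidence_filter()
    expect_setequal(canonical$key, reordered$key)

    # every removed variant appears in exactly one removed-list and the
    # trace counts telescope
    tr <- filter_trace(canonical)
    removed <- unlist(tr$removed)
    expect_equal(sort(c(removed, canonical$key)), sort(vs$key))
    expect_equal(tr$n_in[-1], tr$n_out[-nrow(tr)])
    expect_equal(tr$n_out, tr$n_in - lengths(tr$removed))
  })
})

test_that("variant-impacted genes collapse surviving variants", {
  vs <- toy_variants(pos = c(100, 200, 300), qual = 50,
                     gene = c("gB", "gA", "gB"))
  G <- variant_genes(vs)
  expect_equal(G$gene, c("gA", "gB"))
  expect_equal(G$n_variants, c(1L, 2L))
  vs2 <- vs
  vs2$gene <- NA_character_
  G2 <- variant_genes(vs2)
  expect_equal(nrow(G2), 0)
  expect_equal(attr(G2, "n_unassigned"), 3L)
  # order-invariant
  expect_equal(variant_genes(vs[c(3, 1, 2), ])$gene, G$gene)
})
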