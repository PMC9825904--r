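test_that("read_vcf converts diploid genotypes to allele counts", {
  path <- make_vcf(list(
    list(chrom = "1", pos = 100, ref = "A", alt = "G",
         gt = c("0/1", "1/1", "0/0", "./.")),
    list(chrom = "2", pos = 200, ref = "C", alt = "T",
         gt = c("0|1", ".", "1/.", "1|1"))
  ), samples = c("s1", "s2", "s3", "s4"))
  g <- read_vcf(path)
  expect_equal(unname(g$counts["1:100:A:G", ]), c(1L, 2L, 0L, NA))
  # phased separators count the same; half-calls and '.' are missing
  expect_equal(unname(g$counts["2:200:C:T", ]), c(1L, NA, NA, 2L))
})

test_that("multiallelic records split into one entry per alternate allele", {
  # enumerate every diploid genotype over alleles {0,1,2} and check the
  # split counts against direct allele counting
  gts <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2")
  expected <- function(gt, allele) {
    sum(as.integer(strsplit(gt, "/")[[1]]) == allele)
  }
  path <- make_vcf(list(
    list(chrom = "1", pos = 500, ref = "C", alt = "A,G", gt = gts)
  ), samples = sprintf("s%d", seq_along(gts)))
  g <- read_vcf(path)
  expect_equal(nrow(g$loci), 2L)
  for (j in seq_along(gts)) {
    expect_identical(g$counts["1:500:C:A", j], expected(gts[j], 1L))
    expect_identical(g$counts["1:500:C:G", j], expected(gts[j], 2L))
  }
  # splitting conserves the total alternate-allele count per sample
  totals <- colSums(g$counts)
  expect_equal(unname(totals),
               vapply(gts, function(x) sum(as.integer(strsplit(x, "/")[[1]]) > 0),
                      numeric(1), USE.NAMES = FALSE))
})

test_that("read_vcf validates sample subsets and malformed input", {
  path <- make_vcf(list(
    list(chrom = "1", pos = 1, ref = "A", alt = "T", gt = c("0/1", "0/0"))
  ), samples = c("s1", "s2"))
  g <- read_vcf(path, sample_subset = "s2")
  expect_identical(colnames(g$counts), "s2")
  expect_error(read_vcf(path, sample_subset = c("s1", "nope")), "nope")
  bad <- write_tmp_vcf(c("not a vcf at all", "still not"))
  expect_error(read_vcf(bad))
})

test_that("annotation reader maps sentinels and normalizes ClinVar", {
  path <- tempfile(fileext = ".tsv")
  df <- rbind(
    make_variant(pos = 1L, phylop = -100.0, cadd_phred = 14.7),
    make_variant(pos = 2L, maf_gnomad = NA, clinvar = "Pathogenic/likely pathogenic"),
    make_variant(pos = 3L, clinvar = "VUS", grantham = 98)
  )
  write_result_table(df[, setdiff(names(df), "key")], path)
  ann <- read_annotation_table(path)
  expect_true(is.na(ann$phylop[1]))            # -100.0 sentinel means absent
  expect_true(is.na(ann$maf_gnomad[2]))
  expect_identical(ann$clinvar[2], "pathogenic_or_likely_pathogenic")
  expect_identical(ann$clinvar[3], "vus")
})

test_that("annotation reader rejects schema and value errors", {
  path <- tempfile(fileext = ".tsv")
  df <- make_variant()
  write_result_table(df[, setdiff(names(df), c("key", "clinvar"))], path)
  expect_error(read_annotation_table(path), "clinvar")
  df2 <- make_variant(cadd_phred = "abc")
  write_result_table(df2[, setdiff(names(df2), "key")], path)
  expect_error(read_annotation_table(path), "row 1")
})

test_that("clinvar normalization covers the vocabulary", {
  expect_identical(
    normalize_clinvar(c("Pathogenic", "Likely pathogenic",
                        "Pathogenic/likely pathogenic", "VUS",
                        "Uncertain significance", "Likely benign", "Benign",
                        "Benign/likely benign",
                        "Conflicting interpretations of pathogenicity",
                        "NA", "")),
    c("pathogenic", "likely_pathogenic", "pathogenic_or_likely_pathogenic",
      "vus", "vus", "likely_benign", "benign", "benign_or_likely_benign",
      "conflicting", "not_reported", "not_reported"))
  expect_error(normalize_clinvar("gibberish"), "gibberish")
})

test_that("assemble_cohort joins and enforces invariants", {
  ann <- make_variants(
    make_variant(pos = 100L, gene = "CFH"),
    make_variant(pos = 200L, gene = "C3"),
    make_variant(pos = 300L, gene = "LDLR")
  )
  path <- make_vcf(list(
    list(chrom = "1", pos = 100, ref = "A", alt = "G", gt = c("0/1", "0/0")),
    list(chrom = "1", pos = 200, ref = "A", alt = "G", gt = c("1/1", "./."))
  ), samples = c("c01", "e01"))
  g <- read_vcf(path)
  phen <- tiny_phenotypes(1, 1)
  coh <- assemble_cohort(g, ann, phen, default_gene_registry())
  expect_s3_class(coh, "eodm_cohort")
  expect_equal(nrow(coh$variants), 3L)
  expect_true(all(is.na(coh$counts["1:300:A:G", ])))  # annotated, ungenotyped
  expect_equal(coh$join_stats$n_genotyped, 2L)

  dup <- rbind(ann, ann[1, ])
  expect_error(assemble_cohort(g, dup, phen, default_gene_registry()),
               "duplicate")
  other <- tiny_phenotypes(1, 1)
  other$sample_id <- c("x1", "x2")
  expect_error(assemble_cohort(g, ann, other, default_gene_registry()),
               "no overlap")
  expect_error(assemble_cohort(g, ann, phen[0, ], default_gene_registry()),
               "empty")
})

test_that("variants only in the VCF are kept with absent scores", {
  ann <- make_variant(pos = 100L, gene = "CFH")
  path <- make_vcf(list(
    list(chrom = "1", pos = 100, ref = "A", alt = "G", gt = "0/1"),
    list(chrom = "9", pos = 999, ref = "T", alt = "C", gt = "1/1")
  ), samples = "e01")
  phen <- tiny_phenotypes(0, 1)
  coh <- assemble_cohort(read_vcf(path), ann, phen, default_gene_registry())
  expect_equal(nrow(coh$variants), 2L)
  extra <- coh$variants[coh$variants$key == "9:999:T:C", ]
  expect_true(is.na(extra$cadd_phred))
  expect_identical(coh$counts["9:999:T:C", "e01"], 2L)
})

test_that("phenotype validation enforces the stage-subtype rule", {
  phen <- tiny_phenotypes()
  expect_silent(validate <- read_phenotype_table(local({
    p <- tempfile(fileext = ".tsv"); write_result_table(phen, p); p
  })))
  bad <- phen; bad$stage[3] <- 4L  # stage 4 without subtype
  p <- tempfile(fileext = ".tsv"); write_result_table(bad, p)
  expect_error(read_phenotype_table(p), "subtype")
  bad2 <- phen; bad2$stage4_subtype[1] <- "GA"  # subtype without stage 4
  write_result_table(bad2, p)
  expect_error(read_phenotype_table(p), "stage")
})

test_that("result tables round-trip through the TSV format", {
  ann <- make_variants(
    make_variant(pos = 100L, phylop = 3.1, cadd_phred = 24.2, grantham = 98,
                 clinvar = "vus", maf_gnomad = 0.002),
    make_variant(pos = 200L, gene = "C3", hgvs_p = NA_character_,
                 consequence = "splice_acceptor_variant", hgvs_c = "c.2437-2A>G")
  )
  path <- tempfile(fileext = ".tsv")
  write_result_table(ann[, setdiff(names(ann), "key")], path)
  back <- read_annotation_table(path)
  for (col in eodmtools:::annotation_required_cols) {
    expect_equal(back[[col]], ann[[col]], info = col)
  }
})

test_that("gene registry round-trips through YAML", {
  reg <- default_gene_registry()
  path <- tempfile(fileext = ".yaml")
  write_gene_registry(reg, path)
  back <- read_gene_registry(path)
  expect_identical(back$lists, reg$lists)
  expect_identical(back$ird, reg$ird)
  expect_identical(back$known_ird_events$description,
                   reg$known_ird_events$description)
  expect_error(gene_registry(ird = c(ABCA4 = "XL")), "AD or AR")
})
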