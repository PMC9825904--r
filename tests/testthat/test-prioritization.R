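test_that("rare filter is conjunctive over both databases, missing passes", {
  v <- make_variants(
    make_variant(pos = 1L, maf_gnomad = 0.0075, maf_internal = NA),
    make_variant(pos = 2L, maf_gnomad = 0.02, maf_internal = NA),
    make_variant(pos = 3L, maf_gnomad = NA, maf_internal = NA),
    make_variant(pos = 4L, maf_gnomad = 0.005, maf_internal = 0.02),
    make_variant(pos = 5L, maf_gnomad = 0.009999, maf_internal = 0.0099)
  )
  expect_identical(filter_rare(v), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  # monotone in the threshold
  tighter <- default_thresholds(maf_max = 0.005)
  expect_true(all(filter_rare(v, tighter) <= filter_rare(v)))
})

test_that("candidate annotation records multi-list membership", {
  reg <- default_gene_registry()
  v <- make_variants(
    make_variant(pos = 1L, gene = "LDLR"),
    make_variant(pos = 2L, gene = "CSMD1"),
    make_variant(pos = 3L, gene = "NOTAGENE")
  )
  hits <- annotate_candidates(v, reg)
  expect_setequal(hits[[1]], c("lipid", "mouse_model"))
  expect_identical(hits[[2]], "complement")
  expect_length(hits[[3]], 0L)
})

test_that("deleteriousness agrees with an enumerated three-rule oracle", {
  # independent oracle: direct logical expression over the rule grid
  oracle <- function(vt, phylop, cadd, grantham, clinvar) {
    r1 <- vt %in% c("nonsense", "frameshift", "stop_loss", "canonical_splice")
    r2 <- !is.na(phylop) && phylop > 2.7 && !is.na(cadd) && cadd > 15 &&
      !is.na(grantham) && grantham > 80
    r3 <- clinvar %in% c("pathogenic", "likely_pathogenic",
                         "pathogenic_or_likely_pathogenic")
    r1 || r2 || r3
  }
  types <- c("missense", "nonsense", "frameshift", "stop_loss",
             "canonical_splice", "splice_region", "synonymous", "other")
  phylops <- c(NA, 2.0, 2.7, 3.5)
  cadds <- c(NA, 10, 15, 20)
  granthams <- c(NA, 50, 80, 120)
  clinvars <- c("not_reported", "vus", "benign", "benign_or_likely_benign",
                "conflicting", "likely_pathogenic", "pathogenic",
                "pathogenic_or_likely_pathogenic")
  grid <- expand.grid(vt = types, ph = phylops, ca = cadds, gr = granthams,
                      cv = clinvars, stringsAsFactors = FALSE)
  v <- make_variant(pos = 1L)
  v <- v[rep(1, nrow(grid)), ]
  v$pos <- seq_len(nrow(grid)); v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  v$variant_type <- grid$vt
  v$phylop <- grid$ph; v$cadd_phred <- grid$ca; v$grantham <- grid$gr
  v$clinvar <- grid$cv
  dec <- is_deleterious(v)
  expected <- mapply(oracle, grid$vt, grid$ph, grid$ca, grid$gr, grid$cv)
  expect_identical(dec$deleterious, unname(expected))
  # decision invariant: verdict is exactly the rule disjunction
  expect_identical(dec$deleterious,
                   dec$rule_type_fired | dec$rule_insilico_fired |
                     dec$rule_clinvar_fired)
})

test_that("threshold boundaries are strict and benign ClinVar never vetoes", {
  v <- make_variants(
    # exactly at the thresholds: must NOT fire the in-silico rule
    make_variant(pos = 1L, variant_type = "missense", phylop = 2.7,
                 cadd_phred = 15, grantham = 80, clinvar = "vus"),
    # smallest passing values seen in practice (Grantham 81)
    make_variant(pos = 2L, variant_type = "missense", phylop = 5.3,
                 cadd_phred = 22.5, grantham = 81, clinvar = "not_reported"),
    # CADD just below cut blocks the all-three rule
    make_variant(pos = 3L, variant_type = "missense", phylop = 3.0,
                 cadd_phred = 14.9, grantham = 90, clinvar = "vus"),
    # strong in-silico profile with benign ClinVar: rescue-only, still fires
    make_variant(pos = 4L, variant_type = "missense", phylop = 7.6,
                 cadd_phred = 26.5, grantham = 194,
                 clinvar = "benign_or_likely_benign")
  )
  v$variant_type <- c("missense", "missense", "missense", "missense")
  dec <- is_deleterious(v)
  expect_identical(dec$deleterious, c(FALSE, TRUE, FALSE, TRUE))
  expect_true(dec$rule_insilico_fired[4])
  expect_false(dec$rule_clinvar_fired[4])
})

test_that("raising any in-silico threshold never grows the flagged set", {
  set.seed(13)
  n <- 120
  v <- make_variant(pos = 1L)[rep(1, n), ]
  v$pos <- seq_len(n); v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  v$variant_type <- sample(c("missense", "nonsense", "splice_region"), n, TRUE)
  v$phylop <- round(stats::runif(n, -2, 8), 2)
  v$cadd_phred <- round(stats::runif(n, 0, 40), 1)
  v$grantham <- sample(0:215, n, TRUE)
  v$clinvar <- sample(c("vus", "not_reported", "pathogenic"), n, TRUE,
                      prob = c(0.6, 0.3, 0.1))
  base <- is_deleterious(v)$deleterious
  for (arg in list(list(cadd_min = 25), list(phylop_min = 5),
                   list(grantham_min = 150))) {
    th <- do.call(default_thresholds, arg)
    expect_true(all(is_deleterious(v, th)$deleterious <= base))
  }
})

test_that("gene recurrence counts distinct carriers, not variants", {
  v <- make_variants(
    make_variant(pos = 1L, gene = "LDLR"),
    make_variant(pos = 2L, gene = "CFH"),
    make_variant(pos = 3L, gene = "CFH"),
    make_variant(pos = 4L, gene = "C9"),
    make_variant(pos = 5L, gene = "C9")
  )
  counts <- matrix(0L, nrow = 5, ncol = 3,
                   dimnames = list(v$key, c("p1", "p2", "p3")))
  counts[1, c("p1", "p2")] <- 1L        # one variant, two patients
  counts[2, "p3"] <- 1L; counts[3, "p3"] <- 2L  # two variants, same patient
  counts[4, "p1"] <- 1L; counts[5, "p2"] <- 1L  # two variants, two patients
  rec <- recurrent_genes(v, counts, min_patients = 2L)
  expect_setequal(rec$gene, c("LDLR", "C9"))
  expect_equal(rec$n_carriers[rec$gene == "LDLR"], 2L)
})

test_that("cascade masks deleterious verdicts by rarity and candidacy", {
  v <- make_variants(
    make_variant(pos = 1L, gene = "CFH", variant_type = "nonsense"),
    make_variant(pos = 2L, gene = "CFH", variant_type = "nonsense",
                 maf_gnomad = 0.05),
    make_variant(pos = 3L, gene = "NOTAGENE", variant_type = "nonsense")
  )
  res <- prioritize_variants(v, registry = default_gene_registry())
  expect_identical(res$decisions$deleterious, c(TRUE, FALSE, FALSE))
  expect_identical(res$steps,
                   list(n_input = 3L, n_rare = 2L, n_candidate = 1L,
                        n_deleterious = 1L))
  # with the candidate requirement disabled the non-list gene qualifies
  res2 <- prioritize_variants(v, registry = default_gene_registry(),
                              lists = NULL)
  expect_identical(res2$decisions$deleterious, c(TRUE, FALSE, TRUE))
})

make_ird_cohort <- function(variant_rows, count_rows, samples) {
  v <- do.call(rbind, variant_rows)
  counts <- do.call(rbind, count_rows)
  dimnames(counts) <- list(v$key, samples)
  phen <- tiny_phenotypes(0, length(samples))
  phen$sample_id <- samples
  structure(list(variants = v, counts = counts, samples = phen,
                 registry = default_gene_registry(),
                 join_stats = list()), class = "eodm_cohort")
}

test_that("IRD screen applies dominant and recessive carrier rules", {
  samples <- c("e01", "e02", "e03")
  cohort <- make_ird_cohort(list(
    # AD gene: one heterozygous qualifying variant flags
    make_variant(pos = 1L, gene = "TIMP3", hgvs_c = "c.70T>G",
                 hgvs_p = "p.Cys24Gly"),
    # AR gene: single het must not flag; compound het flags
    make_variant(pos = 2L, gene = "ABCA4", hgvs_p = "p.Gly863Ala"),
    make_variant(pos = 3L, gene = "ABCA4", hgvs_p = "p.Asn1868Ile"),
    # AR gene: homozygous flags
    make_variant(pos = 4L, gene = "MERTK", hgvs_p = "p.Arg466Lys")
  ), list(
    c(1L, 0L, 0L),
    c(1L, 1L, 0L),
    c(0L, 1L, 0L),
    c(0L, 0L, 2L)
  ), samples)
  res <- ird_screen(cohort)
  get <- function(gene, s) res$flagged[res$gene == gene & res$sample_id == s]
  expect_true(get("TIMP3", "e01"))
  expect_false(get("ABCA4", "e01"))           # monoallelic AR
  expect_true(get("ABCA4", "e02"))            # compound heterozygous
  expect_identical(res$basis[res$gene == "ABCA4" & res$sample_id == "e02"],
                   "recessive_biallelic")
  expect_true(get("MERTK", "e03"))            # homozygous AR
})

test_that("IRD screen matches known intronic events by exact description", {
  samples <- "e01"
  cohort <- make_ird_cohort(list(
    make_variant(pos = 1L, gene = "ABCA4", hgvs_c = "c.5196+1137G>A",
                 hgvs_p = NA_character_, consequence = "intron_variant")
  ), list(matrix(1L, 1, 1)), samples)
  res <- ird_screen(cohort)
  expect_true(res$flagged[1])
  expect_identical(res$basis[1], "known_event")
})

test_that("common variants in IRD genes do not enter the screen", {
  cohort <- make_ird_cohort(list(
    make_variant(pos = 1L, gene = "TIMP3", maf_gnomad = 0.2)
  ), list(matrix(1L, 1, 1)), "e01")
  expect_equal(nrow(ird_screen(cohort)), 0L)
})
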