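test_that("the demonstration panel satisfies the panel invariants", {
  panel <- default_risk_panel()
  expect_equal(nrow(panel), 52L)
  expect_equal(sum(panel$pathway == "complement"), 19L)
  expect_equal(sum(panel$pathway == "lipid"), 7L)
  expect_true(all(is.finite(panel$beta)))
  expect_true(all(panel$freq > 0 & panel$freq <= 0.5))
  expect_true(all(panel$effect_allele == panel$alt))
})

test_that("configuration validation rejects invalid parameters", {
  expect_error(simulation_config(stage_distribution = c(a = 0.5, b = 0.2)),
               "sum to 1")
  expect_error(simulation_config(fraction_deleterious = 1.5), "fraction")
  bad_panel <- default_risk_panel()
  bad_panel$freq[1] <- 0.9
  expect_error(simulation_config(panel = bad_panel), "frequencies")
})

test_that("identical seeds give byte-identical cohort files", {
  cfg <- simulation_config(n_controls = 20, n_cases = 10, seed = 99)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  p1 <- write_cohort(simulate_cohort(cfg), d1)
  p2 <- write_cohort(simulate_cohort(cfg), d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), info = nm)
  }
  cfg2 <- simulation_config(n_controls = 20, n_cases = 10, seed = 100)
  p3 <- write_cohort(simulate_cohort(cfg2), d3)
  expect_false(identical(readLines(p1[["truth"]]), readLines(p3[["truth"]])))
})

test_that("null odds ratios give equal case and control frequencies", {
  panel <- default_risk_panel()
  panel$beta <- rep(0, 52)
  cfg <- simulation_config(n_controls = 2000, n_cases = 2000, panel = panel,
                           seed = 17)
  g <- simulate_common_genotypes(cfg)
  ctrl <- grepl("^ctrl_", colnames(g$counts))
  for (i in c(1L, 26L, 52L)) {
    f_ctrl <- mean(g$counts[i, ctrl]) / 2
    f_case <- mean(g$counts[i, !ctrl]) / 2
    p <- cfg$panel$freq[i]
    se <- sqrt(p * (1 - p) / (2 * 2000))
    expect_lt(abs(f_ctrl - f_case), 6 * se)
  }
  expect_equal(expected_mean_grs(cfg, "control"), 0)
  expect_equal(expected_mean_grs(cfg, "case"), 0)
})

test_that("case allele frequency follows the odds-ratio reweighting", {
  # p = 0.2, OR = 2 -> case frequency 0.2*2/(0.8 + 0.4) = 1/3
  panel <- default_risk_panel()[1:1, ]
  panel$freq <- 0.2; panel$beta <- log(2)
  panel <- risk_panel(as.data.frame(panel))
  cfg <- simulation_config(n_controls = 10, n_cases = 20000, panel = panel,
                           seed = 23)
  g <- simulate_common_genotypes(cfg)
  f_case <- mean(g$counts[1, grepl("^eodm_", colnames(g$counts))]) / 2
  se <- sqrt(1 / 3 * 2 / 3 / (2 * 20000))
  expect_lt(abs(f_case - 1 / 3), 3 * se)
})

test_that("closed-form expected GRS has the obvious special cases", {
  panel <- default_risk_panel()[1:1, ]
  panel$freq <- 0.5; panel$beta <- 1
  panel <- risk_panel(as.data.frame(panel))
  cfg <- simulation_config(panel = panel)
  expect_equal(expected_mean_grs(cfg, "control"), 1)   # 2 * 0.5 * 1
  expect_gt(expected_mean_grs(cfg, "case"), 1)
})

test_that("planted rare variants carry consistent truth labels", {
  cfg <- simulation_config(n_controls = 30, n_cases = 25, n_rare_genes = 15,
                           rare_variants_per_gene = 2, seed = 41)
  rare <- simulate_rare_variants(cfg)
  expect_equal(nrow(rare$truth), nrow(rare$annotations))
  expect_setequal(rare$truth$key, rare$annotations$key)
  # every named rule is represented among the planted deleterious variants
  del_rules <- rare$truth$intended_rule[rare$truth$class == "deleterious"]
  expect_true(all(c("type", "insilico", "clinvar") %in% del_rules))
  # planted rare frequencies stay below the filter; common ones above
  ann <- rare$annotations
  rare_rows <- rare$truth$class %in% c("deleterious", "benign", "ird")
  expect_true(all(ann$maf_gnomad[rare_rows] < 0.01, na.rm = TRUE))
  expect_true(all(ann$maf_gnomad[rare$truth$class == "common_benign"] >= 0.01))
})

test_that("each planted deleterious variant fires exactly its intended rule", {
  cfg <- simulation_config(n_controls = 10, n_cases = 20, n_rare_genes = 15,
                           rare_variants_per_gene = 2,
                           fraction_deleterious = 0.5, seed = 53)
  rare <- simulate_rare_variants(cfg)
  dec <- is_deleterious(rare$annotations)
  truth <- rare$truth
  for (i in seq_len(nrow(truth))) {
    row <- dec[dec$key == truth$key[[i]], ]
    fired <- c(type = row$rule_type_fired, insilico = row$rule_insilico_fired,
               clinvar = row$rule_clinvar_fired)
    if (truth$class[[i]] == "deleterious") {
      expect_identical(names(which(fired)), truth$intended_rule[[i]],
                       info = truth$key[[i]])
    } else {
      expect_false(any(fired), info = truth$key[[i]])
    }
  }
})

test_that("written cohorts round-trip through the readers", {
  cfg <- simulation_config(n_controls = 15, n_cases = 10, seed = 61)
  sim <- simulate_cohort(cfg)
  paths <- write_cohort(sim, tempfile())
  g <- read_vcf(paths[["vcf"]])
  expect_equal(ncol(g$counts), 25L)
  expect_setequal(g$loci$key, sim$genotypes$loci$key)
  expect_identical(g$counts[rownames(sim$genotypes$counts),
                            colnames(sim$genotypes$counts)],
                   sim$genotypes$counts)
  ann <- read_annotation_table(paths[["annotations"]])
  expect_equal(nrow(ann), nrow(sim$annotations))
  phen <- read_phenotype_table(paths[["phenotypes"]])
  expect_identical(phen$sample_id, sim$phenotypes$sample_id)
  coh <- assemble_cohort(g, ann, phen, read_gene_registry(paths[["registry"]]))
  expect_equal(nrow(coh$samples), 25L)
  truth <- utils::read.delim(paths[["truth"]], stringsAsFactors = FALSE)
  expect_setequal(truth$key, sim$truth$key)
})

test_that("the severity gradient raises advanced-stage risk scores", {
  cfg <- simulation_config(n_controls = 50, n_cases = 600,
                           severity_gradient = TRUE, seed = 71)
  sim <- simulate_cohort(cfg)
  prof <- grs_profiles(sim$genotypes, cfg$panel, missing_policy = "exclude")
  phen <- sim$phenotypes
  case <- phen$group == "eodm"
  scores <- prof$grs_overall[match(phen$sample_id, prof$sample_id)]
  adv <- scores[case & phen$stage == 4]
  early <- scores[case & phen$stage <= 2]
  expect_gt(mean(adv), mean(early))
})
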