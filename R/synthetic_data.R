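# Synthetic cohort generator. Controls draw Hardy-Weinberg genotypes at the
# panel allele frequencies; cases reweight genotype g by OR^g (per-allele
# multiplicative odds), which is again Hardy-Weinberg at
# p' = p*OR / (1 - p + p*OR) and has a closed-form expected GRS for testing.
# Rare variants are planted with annotations engineered to fire exactly one
# named cascade rule (or none, for the benign class), with truth labels
# recorded out of band.

#' Synthetic 52-variant demonstration risk panel
#'
#' A deterministic, clearly synthetic stand-in for a real AMD GWAS panel:
#' 19 complement-tagged, 7 lipid-tagged and 26 other variants with literal
#' effect sizes (natural-log odds ratios; complement effects mostly risk
#' increasing, lipid effects mostly mildly protective) and allele
#' frequencies spread over (0.05, 0.45). Effect sizes are invented for
#' demonstration and testing; real analyses must supply the published panel.
#'
#' @return A [risk_panel()] of 52 variants.
#' @export
default_risk_panel <- function() {
  n <- 52L
  pathway <- c(rep("complement", 19), rep("lipid", 7), rep("other", 26))
  beta <- c(
    # complement: net risk-increasing with a few protective alleles
    0.90, -0.45, 0.55, 0.30, -0.25, 0.70, 0.20, 0.40, -0.15, 0.60,
    0.35, -0.30, 0.50, 0.25, 0.45, -0.20, 0.65, 0.15, 0.38,
    # lipid: mostly mildly protective
    -0.15, -0.22, -0.10, 0.08, -0.18, -0.12, -0.06,
    # other loci
    0.25, -0.12, 0.30, 0.18, -0.08, 0.22, 0.14, -0.16, 0.28, 0.10,
    0.20, -0.10, 0.26, 0.12, 0.16, -0.14, 0.24, 0.08, 0.32, 0.06,
    0.18, -0.05, 0.21, 0.09, 0.15, 0.11
  )
  freq <- round(seq(0.05, 0.45, length.out = n), 3)
  bases <- c("A", "C", "G", "T")
  ref <- bases[(seq_len(n) - 1L) %% 4L + 1L]
  alt <- bases[seq_len(n) %% 4L + 1L]
  risk_panel(data.frame(
    id = sprintf("demo_var_%02d", seq_len(n)),
    chrom = as.character(rep_len(1:22, n)),
    pos = 1000000L + seq_len(n) * 1000L,
    ref = ref, alt = alt, effect_allele = alt,
    beta = beta, pathway = pathway, freq = freq,
    stringsAsFactors = FALSE
  ))
}

#' Demonstration candidate-gene registry
#'
#' Editable demo registry with the four candidate lists (complement, lipid,
#' mouse-model, AMD-loci), 18 inherited-retinal-dystrophy genes (12 AD, 6 AR)
#' and a few known pathogenic intronic-event lookups. List membership
#' overlaps on purpose (e.g. LDLR is on the lipid and mouse-model lists).
#' The lists are a synthetic reconstruction for demonstration; supply your
#' own registry for real analyses.
#'
#' @return A [gene_registry()].
#' @export
default_gene_registry <- function() {
  gene_registry(
    complement = c("CFH", "CFI", "CFB", "CFD", "CFP", "C2", "C3", "C4A",
                   "C4B", "C5", "C6", "C7", "C8A", "C8B", "C8G", "C9",
                   "CFHR1", "CFHR2", "CFHR3", "CFHR4", "CFHR5", "CD46",
                   "CD55", "CD59", "CR1", "CR2", "C1QA", "C1QB", "C1QC",
                   "C1R", "C1S", "MASP1", "MASP2", "FCN1", "FCN2", "FCN3",
                   "CSMD1", "CSMD2", "CSMD3", "VTN", "CLU", "SERPING1",
                   "ELANE"),
    lipid = c("LDLR", "APOB", "APOE", "ABCA1", "ABCA7", "CETP", "LIPC",
              "LPL", "MTTP", "CYP4V2", "ACAT1", "SCARB1", "PLTP", "APOA1",
              "APOC1"),
    mouse_model = c("LDLR", "APOB", "APOE", "C3", "CFH", "CX3CR1", "CD36",
                    "CCL2", "CCR2", "NFE2L2", "SOD1", "SOD2", "TTR",
                    "VLDLR", "EFEMP1", "MMP2"),
    amd_loci = c("ARMS2", "HTRA1", "SLC16A8", "COL8A1", "COL10A1",
                 "ADAMTS9", "TGFBR1", "VEGFA", "TNFRSF10A", "RAD51B",
                 "B3GLCT", "ARHGAP21", "PILRA", "PILRB", "TSPAN10", "SYN3",
                 "TIMP3", "CTRB1", "CTRB2", "KMT2E", "RORB", "SPEF2",
                 "PRLR", "MMP9", "CFHR5", "CNN2", "APOE", "CETP", "LIPC",
                 "C2", "C3", "C9", "CFI", "CFB", "ABCA7"),
    ird = c(BEST1 = "AD", PRPH2 = "AD", TIMP3 = "AD", EFEMP1 = "AD",
            ELOVL4 = "AD", C1QTNF5 = "AD", CTNNA1 = "AD", FSCN2 = "AD",
            PRDM13 = "AD", RP1L1 = "AD", PROM1 = "AD", HMCN1 = "AD",
            ABCA4 = "AR", ABCC6 = "AR", CDH3 = "AR", MFSD8 = "AR",
            IMPG1 = "AR", MERTK = "AR"),
    known_ird_events = data.frame(
      gene = c("ABCA4", "ABCA4", "PRPH2"),
      description = c("c.5196+1137G>A", "c.4539+2001G>A",
                      "c.-359_+1646del"),
      stringsAsFactors = FALSE)
  )
}

#' Simulation configuration
#'
#' Bundles every parameter the generator needs. Defaults mirror the study
#' conditions: 925 controls, a 49-patient case arm with the published stage
#' distribution (10 stage-1/2, 17 stage-3, 22 stage-4 split 13 GA / 8 CNV /
#' 1 mixed), the 52-variant demonstration panel, and benign/deleterious
#' in-silico score distributions that straddle the cascade thresholds with a
#' margin (benign CADD ~ N(8, 3) truncated below 14.5; deleterious CADD ~
#' N(25, 4) truncated above 15.5; analogous for PhyloP and Grantham).
#'
#' @param n_controls,n_cases Group sizes.
#' @param panel A [risk_panel()] with `freq` (used as control MAF) and
#'   `beta` (per-allele log odds ratio) per variant.
#' @param stage_distribution Probabilities over case stage classes
#'   `stage_1_2`, `stage_3`, `stage_4` (must sum to 1).
#' @param stage4_subtype_distribution Probabilities over `GA`, `CNV`,
#'   `mixed` for stage-4 cases.
#' @param n_rare_genes Candidate genes seeded with rare variants.
#' @param rare_variants_per_gene Poisson mean of variants per seeded gene.
#' @param fraction_deleterious Fraction of rare variants planted as
#'   deleterious (each fires exactly one named rule).
#' @param max_case_carriers Upper bound on case carriers per rare variant.
#' @param n_common_benign Planted common variants (removed by the MAF filter).
#' @param n_ird_ad,n_ird_ar_het Planted single-heterozygous variants in AD /
#'   AR IRD genes (the AR ones must not flag).
#' @param ird_plant_biallelic Plant one compound-heterozygous AR pair
#'   (off by default: the emulated study observed none).
#' @param severity_gradient If `TRUE`, case betas are inflated by
#'   `gradient_strength`/2 for stage-3 and `gradient_strength` for stage-4
#'   cases, emulating a risk gradient over disease stages. Off by default so
#'   stage is independent of genotype under the null.
#' @param gradient_strength Relative beta inflation for stage-4 cases.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(n_controls = 925L, n_cases = 49L,
                              panel = default_risk_panel(),
                              stage_distribution = c(stage_1_2 = 10, stage_3 = 17,
                                                     stage_4 = 22) / 49,
                              stage4_subtype_distribution = c(GA = 13, CNV = 8,
                                                              mixed = 1) / 22,
                              n_rare_genes = 20L,
                              rare_variants_per_gene = 1.5,
                              fraction_deleterious = 0.3,
                              max_case_carriers = 3L,
                              n_common_benign = 5L,
                              n_ird_ad = 2L, n_ird_ar_het = 2L,
                              ird_plant_biallelic = FALSE,
                              severity_gradient = FALSE,
                              gradient_strength = 0.5,
                              seed = 1L) {
  if (any(panel$freq <= 0 | panel$freq > 0.5)) {
    stop("panel allele frequencies must lie in (0, 0.5]", call. = FALSE)
  }
  if (any(exp(panel$beta) <= 0)) stop("odds ratios must be positive", call. = FALSE)
  if (abs(sum(stage_distribution) - 1) > 1e-8) {
    stop("stage_distribution must sum to 1", call. = FALSE)
  }
  if (abs(sum(stage4_subtype_distribution) - 1) > 1e-8) {
    stop("stage4_subtype_distribution must sum to 1", call. = FALSE)
  }
  if (fraction_deleterious < 0 || fraction_deleterious > 1) {
    stop("fraction_deleterious must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_controls = as.integer(n_controls), n_cases = as.integer(n_cases),
    panel = panel, stage_distribution = stage_distribution,
    stage4_subtype_distribution = stage4_subtype_distribution,
    n_rare_genes = as.integer(n_rare_genes),
    rare_variants_per_gene = rare_variants_per_gene,
    fraction_deleterious = fraction_deleterious,
    max_case_carriers = as.integer(max_case_carriers),
    n_common_benign = as.integer(n_common_benign),
    n_ird_ad = as.integer(n_ird_ad), n_ird_ar_het = as.integer(n_ird_ar_het),
    ird_plant_biallelic = isTRUE(ird_plant_biallelic),
    severity_gradient = isTRUE(severity_gradient),
    gradient_strength = gradient_strength,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# case-group effect-allele frequency under per-allele odds-ratio reweighting
.case_freq <- function(p, or) p * or / (1 - p + p * or)

.stage_beta_multiplier <- function(config, stage_class) {
  if (!config$severity_gradient) return(rep(1, length(stage_class)))
  ifelse(stage_class == "stage_4", 1 + config$gradient_strength,
         ifelse(stage_class == "stage_3", 1 + config$gradient_strength / 2, 1))
}

#' Closed-form expected mean GRS under the simulation model
#'
#' Controls: `E[GRS] = sum_i 2 p_i beta_i` (Hardy-Weinberg). Cases: the same
#' sum at the reweighted frequency `p_i' = p_i OR_i / (1 - p_i + p_i OR_i)`.
#' With the severity gradient on, the case value is the stage-distribution
#' mixture of the per-stage values.
#'
#' @param config A [simulation_config()].
#' @param group `"control"` or `"case"`.
#' @return Numeric scalar.
#' @export
expected_mean_grs <- function(config, group = c("control", "case")) {
  group <- match.arg(group)
  p <- config$panel$freq
  beta <- config$panel$beta
  if (group == "control") return(sum(2 * p * beta))
  stages <- names(config$stage_distribution)
  mix <- 0
  for (s in seq_along(stages)) {
    mult <- .stage_beta_multiplier(config, stages[[s]])
    or_s <- exp(beta * mult)
    mix <- mix + config$stage_distribution[[s]] * sum(2 * .case_freq(p, or_s) * beta)
  }
  unname(mix)
}

.sim_sample_ids <- function(config) {
  list(controls = sprintf("ctrl_%04d", seq_len(config$n_controls)),
       cases = sprintf("eodm_%04d", seq_len(config$n_cases)))
}

.sim_phenotypes <- function(config) {
  ids <- .sim_sample_ids(config)
  stage_class <- sample(names(config$stage_distribution), config$n_cases,
                        replace = TRUE, prob = config$stage_distribution)
  stage <- ifelse(stage_class == "stage_1_2",
                  sample(1:2, config$n_cases, replace = TRUE),
                  ifelse(stage_class == "stage_3", 3L, 4L))
  subtype <- rep(NA_character_, config$n_cases)
  n4 <- sum(stage == 4)
  if (n4) {
    subtype[stage == 4] <- sample(names(config$stage4_subtype_distribution),
                                  n4, replace = TRUE,
                                  prob = config$stage4_subtype_distribution)
  }
  case_age <- round(pmax(30, stats::rnorm(config$n_cases, 51.8, 9.2)), 1)
  ctrl_age <- round(65 + stats::rexp(config$n_controls, 1 / 8), 1)
  df <- data.frame(
    sample_id = c(ids$controls, ids$cases),
    group = c(rep("control", config$n_controls), rep("eodm", config$n_cases)),
    stage = c(rep(0L, config$n_controls), as.integer(stage)),
    stage4_subtype = c(rep(NA_character_, config$n_controls), subtype),
    age = c(ctrl_age, case_age),
    age_at_diagnosis = c(rep(NA_real_, config$n_controls),
                         round(pmax(25, case_age - stats::rexp(config$n_cases, 1 / 4)), 1)),
    sex = c(sample(c("male", "female"), config$n_controls, replace = TRUE),
            sample(c("male", "female"), config$n_cases, replace = TRUE,
                   prob = c(0.327, 0.673))),
    stringsAsFactors = FALSE)
  attr(df, "stage_class") <- stage_class
  df
}

.sim_common_counts <- function(config, phenotypes) {
  ids <- .sim_sample_ids(config)
  panel <- config$panel
  stage_class <- attr(phenotypes, "stage_class")
  mult <- .stage_beta_multiplier(config, stage_class)
  counts <- matrix(NA_integer_, nrow = nrow(panel),
                   ncol = config$n_controls + config$n_cases,
                   dimnames = list(panel$key, c(ids$controls, ids$cases)))
  for (i in seq_len(nrow(panel))) {
    p <- panel$freq[[i]]
    counts[i, ids$controls] <- stats::rbinom(config$n_controls, 2L, p)
    p_case <- .case_freq(p, exp(panel$beta[[i]] * mult))
    counts[i, ids$cases] <- stats::rbinom(config$n_cases, 2L, p_case)
  }
  # panel effect alleles are the VCF alternates in the demo panel
  counts
}

#' Simulate common-panel genotypes
#'
#' Controls are Hardy-Weinberg at the panel frequency; case genotype g is
#' reweighted by OR^g (equivalently Hardy-Weinberg at the reweighted
#' frequency). Fully determined by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return `"eodm_genotypes"` object over the panel loci.
#' @export
simulate_common_genotypes <- function(config) {
  set.seed(config$seed)
  phen <- .sim_phenotypes(config)
  counts <- .sim_common_counts(config, phen)
  loci <- data.frame(chrom = config$panel$chrom, pos = config$panel$pos,
                     ref = config$panel$ref, alt = config$panel$alt,
                     key = config$panel$key, stringsAsFactors = FALSE)
  structure(list(loci = loci, counts = counts), class = "eodm_genotypes")
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.aa_pairs <- function(min_d = NULL, max_d = NULL) {
  m <- grantham_matrix
  idx <- which(upper.tri(m), arr.ind = TRUE)
  d <- m[idx]
  keep <- rep(TRUE, length(d))
  if (!is.null(min_d)) keep <- keep & d > min_d
  if (!is.null(max_d)) keep <- keep & d <= max_d
  data.frame(ref = rownames(m)[idx[keep, 1]], alt = colnames(m)[idx[keep, 2]],
             d = d[keep], stringsAsFactors = FALSE)
}

.sim_one_rare <- function(gene, chrom, pos, class, rule, benign_flavour = "missense") {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1); alt <- sample(setdiff(bases, ref), 1)
  cpos <- sample(60:4500, 1)
  ppos <- max(1L, cpos %/% 3L)
  row <- list(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
              consequence = NA_character_, hgvs_c = NA_character_,
              hgvs_p = NA_character_, maf_gnomad = NA_real_,
              maf_internal = NA_real_, cadd_phred = NA_real_,
              phylop = NA_real_, grantham = NA_real_,
              clinvar = "not_reported")
  benign_scores <- function(row) {
    row$cadd_phred <- round(.rtrunc_norm(1, 8, 3, 0, 14.5), 1)
    row$phylop <- round(.rtrunc_norm(1, 0.5, 1.2, -5, 2.5), 1)
    row
  }
  missense_with <- function(row, pair) {
    row$consequence <- "missense_variant"
    row$hgvs_c <- sprintf("c.%d%s>%s", cpos, ref, alt)
    row$hgvs_p <- sprintf("p.%s%d%s", pair$ref, ppos, pair$alt)
    row$grantham <- pair$d
    row
  }
  if (class == "deleterious" && rule == "type") {
    sub <- sample(c("nonsense", "frameshift", "stop_loss", "canonical_splice"), 1)
    row <- benign_scores(row)
    row$clinvar <- sample(c("not_reported", "vus"), 1)
    if (sub == "nonsense") {
      row$consequence <- "stop_gained"
      row$hgvs_c <- sprintf("c.%d%s>%s", cpos, ref, alt)
      row$hgvs_p <- sprintf("p.%s%d*", sample(names(aa3), 1), ppos)
      row$grantham <- 1000
    } else if (sub == "frameshift") {
      row$consequence <- "frameshift_variant"
      row$hgvs_c <- sprintf("c.%ddel", cpos)
      row$hgvs_p <- sprintf("p.%s%d%sfs*%d", sample(names(aa3), 1), ppos,
                            sample(names(aa3), 1), sample(3:40, 1))
      row$grantham <- 0
    } else if (sub == "stop_loss") {
      row$consequence <- "stop_lost"
      row$hgvs_c <- sprintf("c.%d%s>%s", cpos, ref, alt)
      row$hgvs_p <- sprintf("p.*%d%sext*%d", ppos, sample(names(aa3), 1),
                            sample(10:80, 1))
      row$grantham <- 1000
    } else {
      row$consequence <- sample(c("splice_donor_variant", "splice_acceptor_variant"), 1)
      off <- sample(c(-2L, -1L, 1L, 2L), 1)
      row$hgvs_c <- sprintf("c.%d%+d%s>%s", cpos, off, ref, alt)
      row$grantham <- 0
    }
  } else if (class == "deleterious" && rule == "insilico") {
    pair <- .aa_pairs(min_d = 80)[sample(nrow(.aa_pairs(min_d = 80)), 1), ]
    row <- missense_with(row, pair)
    row$cadd_phred <- round(.rtrunc_norm(1, 25, 4, 15.5, 60), 1)
    row$phylop <- round(.rtrunc_norm(1, 5, 1.2, 2.8, 12), 1)
    row$clinvar <- sample(c("not_reported", "vus", "benign", "likely_benign"), 1,
                          prob = c(0.5, 0.3, 0.1, 0.1))
  } else if (class == "deleterious" && rule == "clinvar") {
    pair <- .aa_pairs(max_d = 80)[sample(nrow(.aa_pairs(max_d = 80)), 1), ]
    row <- benign_scores(missense_with(row, pair))
    row$clinvar <- sample(clinvar_pathogenic, 1)
  } else {
    # benign class: must fire no rule
    flavour <- benign_flavour
    if (flavour == "missense") {
      pair <- .aa_pairs(max_d = 80)[sample(nrow(.aa_pairs(max_d = 80)), 1), ]
      row <- benign_scores(missense_with(row, pair))
    } else if (flavour == "synonymous") {
      aa <- sample(names(aa3), 1)
      row$consequence <- "synonymous_variant"
      row$hgvs_c <- sprintf("c.%d%s>%s", cpos, ref, alt)
      row$hgvs_p <- sprintf("p.%s%d=", aa, ppos)
      row <- benign_scores(row)
      row$grantham <- 0
    } else if (flavour == "splice_region") {
      row$consequence <- "splice_region_variant"
      off <- sample(c(-8:-3, 3:8), 1)
      row$hgvs_c <- sprintf("c.%d%+d%s>%s", cpos, off, ref, alt)
      row <- benign_scores(row)
      row$grantham <- 0
    } else {
      row$consequence <- "intron_variant"
      off <- sample(c(-60:-20, 20:60), 1)
      row$hgvs_c <- sprintf("c.%d%+d%s>%s", cpos, off, ref, alt)
      row <- benign_scores(row)
      row$grantham <- 0
    }
    row$clinvar <- sample(c("not_reported", "vus", "likely_benign", "benign",
                            "conflicting"), 1)
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

.sim_rare_variants <- function(config, registry, phenotypes) {
  cand_genes <- unique(unlist(registry$lists[c("complement", "lipid", "mouse_model")]))
  genes <- sample(cand_genes, min(config$n_rare_genes, length(cand_genes)))
  ann <- list(); truth <- list()
  chrom_for <- function(i) as.character((i - 1L) %% 22L + 1L)
  gi <- 0L
  add_variant <- function(gene, class, rule, flavour = "missense") {
    gi <<- gi + 1L
    pos <- 5000000L + gi * 997L
    row <- .sim_one_rare(gene, chrom_for(gi), pos, class, rule, flavour)
    # frequencies: rare by construction (or common for the common class)
    if (class == "common_benign") {
      row$maf_gnomad <- round(stats::runif(1, 0.02, 0.2), 4)
      row$maf_internal <- round(stats::runif(1, 0.02, 0.2), 4)
    } else {
      row$maf_gnomad <- if (stats::runif(1) < 0.7) round(stats::runif(1, 0, 0.009), 5) else NA_real_
      row$maf_internal <- if (stats::runif(1) < 0.7) round(stats::runif(1, 0, 0.009), 5) else NA_real_
    }
    ann[[length(ann) + 1L]] <<- row
    truth[[length(truth) + 1L]] <<- data.frame(
      key = variant_key(row$chrom, row$pos, row$ref, row$alt),
      gene = gene, class = class, intended_rule = rule,
      stringsAsFactors = FALSE)
    row
  }
  rules <- c("type", "insilico", "clinvar")
  forced <- 0L
  for (g in genes) {
    n_var <- stats::rpois(1, config$rare_variants_per_gene)
    for (v in seq_len(n_var)) {
      if (forced < 3L) {
        # guarantee at least one planted variant per named rule
        forced <- forced + 1L
        add_variant(g, "deleterious", rules[[forced]])
      } else if (stats::runif(1) < config$fraction_deleterious) {
        add_variant(g, "deleterious", sample(rules, 1))
      } else {
        add_variant(g, "benign", "none",
                    sample(c("missense", "synonymous", "splice_region",
                             "intron"), 1))
      }
    }
  }
  while (forced < 3L) {  # tiny configs: still cover every rule
    forced <- forced + 1L
    add_variant(sample(genes, 1), "deleterious", rules[[forced]])
  }
  for (i in seq_len(config$n_common_benign)) {
    add_variant(sample(cand_genes, 1), "common_benign", "none")
  }
  ad_genes <- names(registry$ird)[registry$ird == "AD"]
  ar_genes <- names(registry$ird)[registry$ird == "AR"]
  for (i in seq_len(config$n_ird_ad)) {
    add_variant(sample(ad_genes, 1), "ird", "none")
  }
  for (i in seq_len(config$n_ird_ar_het)) {
    add_variant(sample(ar_genes, 1), "ird", "none")
  }
  if (config$ird_plant_biallelic) {
    g <- sample(ar_genes, 1)
    add_variant(g, "ird_biallelic", "none")
    add_variant(g, "ird_biallelic", "none")
  }
  annotations <- do.call(rbind, ann)
  annotations$key <- variant_key(annotations$chrom, annotations$pos,
                                 annotations$ref, annotations$alt)
  truth <- do.call(rbind, truth)

  # carriers: rare variants sit in one to max_case_carriers cases (the
  # biallelic IRD pair shares one carrier); common variants follow HWE
  ids <- .sim_sample_ids(config)
  counts <- matrix(0L, nrow = nrow(annotations),
                   ncol = length(ids$controls) + length(ids$cases),
                   dimnames = list(annotations$key, c(ids$controls, ids$cases)))
  biallelic_carrier <- if (config$ird_plant_biallelic) sample(ids$cases, 1) else NULL
  for (i in seq_len(nrow(annotations))) {
    cls <- truth$class[[i]]
    if (cls == "common_benign") {
      f <- annotations$maf_internal[[i]]
      counts[i, ] <- stats::rbinom(ncol(counts), 2L, f)
    } else if (cls == "ird_biallelic") {
      counts[i, biallelic_carrier] <- 1L
    } else {
      n_carr <- 1L + stats::rbinom(1, config$max_case_carriers - 1L, 0.25)
      carriers <- sample(ids$cases, min(n_carr, length(ids$cases)))
      counts[i, carriers] <- 1L
    }
  }
  list(annotations = annotations, truth = truth, counts = counts)
}

#' Simulate rare variants with planted truth labels
#'
#' Plants rare variants in candidate genes. Deleterious-class variants are
#' engineered to fire exactly one named cascade rule (type, in-silico or
#' ClinVar) and benign-class variants to fire none; planted frequencies are
#' below 1% by construction; common-class variants are added so the MAF
#' filter has something to remove. At least one deleterious variant per rule
#' is always planted.
#'
#' @param config A [simulation_config()].
#' @param registry A [gene_registry()].
#' @return List: `annotations` (annotation data.frame), `truth` (key, gene,
#'   class, intended_rule), `counts` (variant x sample matrix).
#' @export
simulate_rare_variants <- function(config, registry = default_gene_registry()) {
  set.seed(config$seed + 1L)
  phen <- .sim_phenotypes(config)
  .sim_rare_variants(config, registry, phen)
}

#' Simulate a complete cohort
#'
#' One seeded draw of phenotypes, common-panel genotypes and rare variants,
#' assembled into the pieces every pipeline stage consumes.
#'
#' @param config A [simulation_config()].
#' @param registry A [gene_registry()].
#' @return List of class `"eodm_simulation"`: `genotypes`
#'   (`"eodm_genotypes"` over panel + rare loci), `annotations` (rare-variant
#'   annotation table), `phenotypes`, `panel`, `truth`, `registry`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            registry = default_gene_registry()) {
  set.seed(config$seed)
  phen <- .sim_phenotypes(config)
  common_counts <- .sim_common_counts(config, phen)
  rare <- .sim_rare_variants(config, registry, phen)
  loci <- rbind(
    data.frame(chrom = config$panel$chrom, pos = config$panel$pos,
               ref = config$panel$ref, alt = config$panel$alt,
               key = config$panel$key, stringsAsFactors = FALSE),
    rare$annotations[, c("chrom", "pos", "ref", "alt", "key")]
  )
  counts <- rbind(common_counts, rare$counts)
  phen2 <- phen; attr(phen2, "stage_class") <- NULL
  structure(list(
    genotypes = structure(list(loci = loci, counts = counts),
                          class = "eodm_genotypes"),
    annotations = rare$annotations, phenotypes = phen2,
    panel = config$panel, truth = rare$truth, registry = registry,
    config = config
  ), class = "eodm_simulation")
}

.gt_string <- function(count) {
  ifelse(is.na(count), "./.",
         ifelse(count == 0L, "0/0", ifelse(count == 1L, "0/1", "1/1")))
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf` (VCF 4.2, GT-only), `annotations.tsv`,
#' `phenotypes.tsv`, `panel.tsv`, `truth.tsv` and `registry.yaml` in
#' `out_dir`. The VCF round-trips through [read_vcf()].
#'
#' @param sim An `"eodm_simulation"` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  loci <- sim$genotypes$loci
  counts <- sim$genotypes$counts
  ord <- order(suppressWarnings(as.integer(loci$chrom)), loci$chrom, loci$pos)
  loci <- loci[ord, ]; counts <- counts[ord, , drop = FALSE]
  samples <- colnames(counts)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=eodmtools synthetic cohort generator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt <- apply(counts, 2, .gt_string)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(loci))
  body <- vapply(seq_len(nrow(loci)), function(i) {
    paste(c(loci$chrom[[i]], loci$pos[[i]], ".", loci$ref[[i]], loci$alt[[i]],
            ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  paths <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    annotations = file.path(out_dir, "annotations.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    panel = file.path(out_dir, "panel.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    registry = file.path(out_dir, "registry.yaml"))
  writeLines(c(header, body), paths[["vcf"]])
  ann <- sim$annotations[, setdiff(names(sim$annotations), "key")]
  write_result_table(ann, paths[["annotations"]])
  write_result_table(sim$phenotypes, paths[["phenotypes"]])
  panel_df <- as.data.frame(sim$panel)[, c("id", "chrom", "pos", "ref", "alt",
                                           "effect_allele", "beta", "pathway",
                                           "freq")]
  write_result_table(panel_df, paths[["panel"]])
  write_result_table(sim$truth, paths[["truth"]])
  write_gene_registry(sim$registry, paths[["registry"]])
  invisible(paths)
}
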