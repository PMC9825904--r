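# Bundled reference data from the published EODM whole-genome study this
# pipeline reimplements: the table of rare variants prioritized in the
# 49-patient cohort, and the cohort's printed stage/sex composition. Used to
# validate the cascade and the descriptive statistics against the printed
# results.

#' Reported rare variants of the EODM reference cohort
#'
#' The published set of rare variants prioritized in 49 EODM patients, with
#' the reported variant type, PhyloP, CADD, Grantham, ClinVar category,
#' carrier counts and gnomAD frequency, converted to the annotation-table
#' layout this package consumes. Loci are placeholders (the published table
#' reports HGVS, not VCF coordinates); frequencies are converted from
#' percent to fractions; the PhyloP sentinel -100.0 and "NA" cells are
#' mapped to missing; the cohort carrier frequency is **not** used as the
#' rare-filter frequency (the emulated filter ran against an internal
#' reference database and gnomAD, so `maf_internal` is absent here).
#'
#' @return Annotation data.frame (see [read_annotation_table()]) with extra
#'   columns `gene_list` (the published candidate-list label),
#'   `variant_type_reported`, `n_patients` and `maf_cohort_pct`.
#' @export
reported_rare_variants <- function() {
  path <- system.file("extdata", "eodm_reported_rare_variants.tsv",
                      package = "eodmtools", mustWork = TRUE)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), quote = "")
  n <- nrow(raw)
  alleles <- regmatches(raw$hgvs_c, regexec("([ACGT])>([ACGT])$", raw$hgvs_c))
  ref <- vapply(alleles, function(m) if (length(m)) m[2] else "AT", character(1))
  alt <- vapply(alleles, function(m) if (length(m)) m[3] else "A", character(1))
  phylop <- raw$phylop
  phylop[!is.na(phylop) & phylop <= -100] <- NA_real_
  df <- data.frame(
    chrom = "1", pos = seq_len(n) * 1000L, ref = ref, alt = alt,
    gene = raw$gene, consequence = NA_character_,
    hgvs_c = raw$hgvs_c, hgvs_p = raw$hgvs_p,
    maf_gnomad = raw$maf_gnomad / 100, maf_internal = NA_real_,
    cadd_phred = raw$cadd_phred, phylop = phylop, grantham = raw$grantham,
    clinvar = normalize_clinvar(raw$clinvar),
    gene_list = raw$gene_list,
    variant_type_reported = raw$variant_type_reported,
    n_patients = raw$n_patients, maf_cohort_pct = raw$maf_cohort_pct,
    stringsAsFactors = FALSE)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' Phenotype table matching the reported EODM cohort composition
#'
#' Builds a 49-patient phenotype table reproducing the published cohort
#' counts: 33 female / 16 male; 10 patients at Rotterdam stage 1/2, 17 at
#' stage 3, and 22 at stage 4 (13 geographic atrophy, 8 choroidal
#' neovascularization, 1 mixed). Ages are deterministic placeholders; only
#' the categorical composition is meaningful.
#'
#' @return Phenotype data.frame ([read_phenotype_table()] layout).
#' @export
reported_cohort_phenotypes <- function() {
  stage <- c(rep(1L, 10), rep(3L, 17), rep(4L, 22))
  subtype <- c(rep(NA_character_, 27), rep("GA", 13), rep("CNV", 8), "mixed")
  df <- data.frame(
    sample_id = sprintf("eodm_%02d", 1:49),
    group = "eodm",
    stage = stage,
    stage4_subtype = subtype,
    age = round(seq(35, 68, length.out = 49), 1),
    age_at_diagnosis = round(seq(32, 64, length.out = 49), 1),
    sex = c(rep("female", 33), rep("male", 16)),
    stringsAsFactors = FALSE)
  validate_phenotypes(df)
}
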