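# Shared fixture builders. Everything is generated in code; no binary data.

write_tmp_vcf <- function(lines, dir = tempdir()) {
  path <- tempfile("fixture", tmpdir = dir, fileext = ".vcf")
  writeLines(lines, path)
  path
}

# minimal VCF with arbitrary genotype strings; records = list of
# list(chrom, pos, ref, alt, gt = character vector per sample)
make_vcf <- function(records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", "GT", r$gt),
          collapse = "\t")
  }, character(1))
  write_tmp_vcf(c(header, body))
}

# one-row annotation data.frame with overridable fields
make_variant <- function(...) {
  defaults <- list(
    chrom = "1", pos = 1000L, ref = "A", alt = "G", gene = "CFH",
    consequence = "missense_variant", hgvs_c = "c.100A>G",
    hgvs_p = "p.Lys34Glu", maf_gnomad = NA_real_, maf_internal = NA_real_,
    cadd_phred = NA_real_, phylop = NA_real_, grantham = NA_real_,
    clinvar = "not_reported")
  args <- list(...)
  defaults[names(args)] <- args
  df <- as.data.frame(defaults, stringsAsFactors = FALSE)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

make_variants <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

tiny_phenotypes <- function(n_ctrl = 2, n_case = 2) {
  data.frame(
    sample_id = c(sprintf("c%02d", seq_len(n_ctrl)),
                  sprintf("e%02d", seq_len(n_case))),
    group = c(rep("control", n_ctrl), rep("eodm", n_case)),
    stage = c(rep(0L, n_ctrl), rep(3L, n_case)),
    stage4_subtype = NA_character_,
    age = 60, age_at_diagnosis = NA_real_,
    sex = "female", stringsAsFactors = FALSE)
}

# brute-force exact Kruskal-Wallis permutation p over all n! orderings
# (independent of the package's assignment enumeration)
kw_permutation_oracle <- function(values, groups) {
  groups <- as.character(groups)
  H_obs <- unname(stats::kruskal.test(values, factor(groups))$statistic)
  n <- length(values)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_p <- perms(seq_len(n))
  hs <- vapply(all_p, function(idx) {
    unname(stats::kruskal.test(values[idx], factor(groups))$statistic)
  }, numeric(1))
  mean(hs >= H_obs - 1e-10)
}
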