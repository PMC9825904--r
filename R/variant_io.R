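# Readers/writers for the four input artifacts (VCF genotypes, annotation
# table, gene-list registry, phenotype table) and the assembled in-memory
# cohort. All loci are 1-based VCF coordinates throughout.

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt Locus components.
#' @return `"chrom:pos:ref:alt"` string (vectorized).
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

clinvar_levels <- c("pathogenic", "likely_pathogenic",
                    "pathogenic_or_likely_pathogenic", "vus", "likely_benign",
                    "benign", "benign_or_likely_benign", "conflicting",
                    "not_reported")

#' Normalize free-text ClinVar classifications
#'
#' Maps the strings found in annotation exports ("Pathogenic/likely
#' pathogenic", "VUS", "Uncertain significance", "Benign/likely benign",
#' "Conflicting interpretations of pathogenicity", "NA", "") onto the
#' controlled vocabulary used by the cascade.
#'
#' @param x Character vector.
#' @return Character vector over the controlled vocabulary.
#' @export
normalize_clinvar <- function(x) {
  out <- character(length(x))
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[/,]", " ", y)
  y <- gsub("[_-]", " ", y)
  y <- gsub("\\s+", " ", y)
  for (i in seq_along(y)) {
    v <- y[[i]]
    out[[i]] <-
      if (is.na(v) || v %in% c("", "na", "not reported", "none", ".")) "not_reported"
      else if (grepl("conflict", v)) "conflicting"
      else if (v %in% c("vus", "uncertain significance", "variant of uncertain significance")) "vus"
      else if (grepl("pathogenic", v) && grepl("likely pathogenic", v) &&
               grepl("^pathogenic", v)) "pathogenic_or_likely_pathogenic"
      else if (grepl("benign", v) && grepl("likely benign", v) &&
               grepl("^benign", v)) "benign_or_likely_benign"
      else if (v == "likely pathogenic") "likely_pathogenic"
      else if (v == "pathogenic") "pathogenic"
      else if (v == "likely benign") "likely_benign"
      else if (v == "benign") "benign"
      else stop("unrecognized ClinVar classification: '", x[[i]], "'",
                call. = FALSE)
  }
  out
}

.parse_gt_counts <- function(gt, n_alt) {
  # gt: character vector of GT strings for one site; returns matrix
  # n_alt x length(gt) of per-alternate allele counts, NA for missing and
  # half-calls
  counts <- matrix(NA_integer_, nrow = n_alt, ncol = length(gt))
  for (j in seq_along(gt)) {
    g <- gt[[j]]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) next
    toks <- strsplit(g, "[/|]")[[1]]
    if (length(toks) != 2L || any(toks == ".")) next  # half-call -> missing
    al <- suppressWarnings(as.integer(toks))
    if (any(is.na(al))) next
    for (a in seq_len(n_alt)) counts[a, j] <- sum(al == a)
  }
  counts
}

#' Read genotypes from a multi-sample VCF
#'
#' Reads a VCF 4.x file and returns per-sample alternate-allele counts keyed
#' by (chrom, pos, ref, alt). Multiallelic records are split into one entry
#' per alternate allele (a 1/2 genotype contributes count 1 to each split
#' entry). Missing genotypes (`./.`) and half-calls (`1/.`) are kept as `NA`.
#'
#' @param path Path to a VCF file (optionally bgzipped).
#' @param sample_subset Optional character vector of sample ids to keep;
#'   a requested sample absent from the header is an error.
#' @return A list of class `"eodm_genotypes"` with elements `loci`
#'   (data.frame `chrom`, `pos`, `ref`, `alt`, `key`) and `counts`
#'   (integer matrix, rows = variant keys, columns = samples).
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) {
                    stop("failed to parse VCF '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    stop("VCF '", path, "' carries no sample genotype columns", call. = FALSE)
  }
  samples <- colnames(gt_raw)[-1]
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, samples)
    if (length(missing)) {
      stop("samples requested but absent from VCF header: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    samples <- sample_subset
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, samples))
  gt <- gt[, samples, drop = FALSE]

  chroms <- character(0); poss <- integer(0)
  refs <- character(0); alts <- character(0)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alt_alleles <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    cnt <- .parse_gt_counts(gt[i, ], length(alt_alleles))
    for (a in seq_along(alt_alleles)) {
      chroms <- c(chroms, fix[i, "CHROM"])
      poss <- c(poss, as.integer(fix[i, "POS"]))
      refs <- c(refs, fix[i, "REF"])
      alts <- c(alts, alt_alleles[[a]])
      rows[[length(rows) + 1L]] <- cnt[a, ]
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- samples
  keys <- variant_key(chroms, poss, refs, alts)
  if (anyDuplicated(keys)) {
    stop("duplicate (chrom,pos,ref,alt) records in VCF: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  rownames(counts) <- keys
  loci <- data.frame(chrom = chroms, pos = poss, ref = refs, alt = alts,
                     key = keys, stringsAsFactors = FALSE)
  structure(list(loci = loci, counts = counts), class = "eodm_genotypes")
}

annotation_required_cols <- c("chrom", "pos", "ref", "alt", "gene",
                              "consequence", "hgvs_c", "hgvs_p", "maf_gnomad",
                              "maf_internal", "cadd_phred", "phylop",
                              "grantham", "clinvar")

.num_col <- function(df, col) {
  raw <- df[[col]]
  if (is.numeric(raw)) return(as.numeric(raw))
  raw <- trimws(as.character(raw))
  raw[raw %in% c("", "NA", ".")] <- NA
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(out))
  if (length(bad)) {
    stop("unparsable number in column '", col, "' at row ", bad[[1]], ": '",
         raw[[bad[[1]]]], "'", call. = FALSE)
  }
  out
}

#' Read a per-variant annotation table
#'
#' Reads the tab-separated annotation export (one row per variant, canonical
#' transcript). The PhyloP sentinel -100.0 and empty/"NA" frequency cells are
#' mapped to missing; ClinVar strings are normalized onto the controlled
#' vocabulary.
#'
#' @param path Path to the TSV.
#' @return data.frame with the columns of `annotation_required_cols` plus
#'   `key` and any extra columns present in the file.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""),
                          quote = "")
  missing <- setdiff(annotation_required_cols, names(df))
  if (length(missing)) {
    stop("annotation table '", path, "' lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("maf_gnomad", "maf_internal", "cadd_phred", "phylop", "grantham")) {
    df[[col]] <- .num_col(df, col)
  }
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(.num_col(df, "pos"))
  df$phylop[!is.na(df$phylop) & df$phylop <= -100] <- NA_real_
  df$clinvar <- normalize_clinvar(df$clinvar)
  validate_annotations(df)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' @keywords internal
validate_annotations <- function(df) {
  if (any(df$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1", call. = FALSE)
  if (any(df$ref == df$alt, na.rm = TRUE)) stop("ref and alt alleles must differ", call. = FALSE)
  for (col in c("maf_gnomad", "maf_internal")) {
    v <- df[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("column '", col, "' must lie in [0,1] (fractions, not percent)",
           call. = FALSE)
    }
  }
  g <- df$grantham
  if (any(g < 0 | g > 1000, na.rm = TRUE)) {
    stop("grantham values must lie in [0,1000]", call. = FALSE)
  }
  bad <- setdiff(unique(df$clinvar), clinvar_levels)
  if (length(bad)) stop("invalid clinvar categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  invisible(df)
}

rotterdam_stages <- 0:4
stage4_subtypes <- c("GA", "CNV", "mixed")

#' Read a sample phenotype table
#'
#' Tab-separated with columns `sample_id`, `group` (control/eodm), `stage`
#' (Rotterdam 0-4), `stage4_subtype` (GA/CNV/mixed, required iff stage 4),
#' `age`, `age_at_diagnosis` (optional), `sex` (male/female).
#'
#' @param path Path to the TSV.
#' @return Validated data.frame.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "")
  required <- c("sample_id", "group", "stage", "age", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("phenotype table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"stage4_subtype" %in% names(df)) df$stage4_subtype <- NA_character_
  if (!"age_at_diagnosis" %in% names(df)) df$age_at_diagnosis <- NA_real_
  validate_phenotypes(df)
  df
}

#' @keywords internal
validate_phenotypes <- function(df) {
  if (nrow(df) == 0L) stop("phenotype table is empty", call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (!all(df$group %in% c("control", "eodm"))) {
    stop("group must be 'control' or 'eodm'", call. = FALSE)
  }
  if (!all(df$stage %in% rotterdam_stages)) {
    stop("stage must be a Rotterdam grade 0-4", call. = FALSE)
  }
  if (!all(df$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  is4 <- df$stage == 4
  if (any(is4 & (is.na(df$stage4_subtype) | !df$stage4_subtype %in% stage4_subtypes))) {
    stop("stage-4 samples need a subtype in {GA, CNV, mixed}", call. = FALSE)
  }
  if (any(!is4 & !is.na(df$stage4_subtype))) {
    stop("stage4_subtype must be absent unless stage = 4", call. = FALSE)
  }
  if (any(df$age <= 0, na.rm = TRUE) || any(df$age_at_diagnosis <= 0, na.rm = TRUE)) {
    stop("ages must be positive", call. = FALSE)
  }
  invisible(df)
}

#' Construct a candidate-gene registry
#'
#' Bundles the four candidate gene lists (complement, lipid, mouse-model,
#' AMD-loci), the IRD gene inheritance map, and the lookup list of known
#' pathogenic intronic/structural IRD events. A gene may sit on several lists;
#' multi-list membership is preserved.
#'
#' @param complement,lipid,mouse_model,amd_loci Character vectors of symbols.
#' @param ird Named character vector: gene symbol -> "AD" or "AR".
#' @param known_ird_events data.frame with columns `gene`, `description`
#'   (exact variant descriptions to match), or NULL.
#' @return Object of class `"gene_registry"`.
#' @export
gene_registry <- function(complement = character(), lipid = character(),
                          mouse_model = character(), amd_loci = character(),
                          ird = character(), known_ird_events = NULL) {
  ird <- unlist(ird)
  if (length(ird)) {
    if (is.null(names(ird)) || any(!nzchar(names(ird)))) {
      stop("ird must be a named vector of inheritance modes", call. = FALSE)
    }
    bad <- setdiff(unique(ird), c("AD", "AR"))
    if (length(bad)) stop("IRD inheritance modes must be AD or AR, got: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(known_ird_events)) {
    known_ird_events <- data.frame(gene = character(), description = character(),
                                   stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "description") %in% names(known_ird_events)))
  structure(list(
    lists = list(complement = unique(complement), lipid = unique(lipid),
                 mouse_model = unique(mouse_model), amd_loci = unique(amd_loci)),
    ird = ird,
    known_ird_events = known_ird_events
  ), class = "gene_registry")
}

#' Read a gene registry from YAML
#'
#' Expects top-level keys `complement`, `lipid`, `mouse_model`, `amd_loci`
#' (sequences of symbols), `ird` (map symbol -> AD/AR) and optional
#' `known_ird_events` (sequence of maps with `gene` and `description`).
#'
#' @param path YAML file path.
#' @return A [gene_registry()].
#' @export
read_gene_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  ev <- NULL
  if (!is.null(cfg$known_ird_events)) {
    ev <- do.call(rbind, lapply(cfg$known_ird_events, function(e) {
      data.frame(gene = e$gene, description = e$description,
                 stringsAsFactors = FALSE)
    }))
  }
  gene_registry(
    complement = unlist(cfg$complement), lipid = unlist(cfg$lipid),
    mouse_model = unlist(cfg$mouse_model), amd_loci = unlist(cfg$amd_loci),
    ird = unlist(cfg$ird), known_ird_events = ev
  )
}

#' Write a gene registry to YAML
#' @param registry A [gene_registry()].
#' @param path Output path.
#' @export
write_gene_registry <- function(registry, path) {
  ev <- registry$known_ird_events
  yaml::write_yaml(list(
    complement = registry$lists$complement,
    lipid = registry$lists$lipid,
    mouse_model = registry$lists$mouse_model,
    amd_loci = registry$lists$amd_loci,
    ird = as.list(registry$ird),
    known_ird_events = if (nrow(ev)) {
      lapply(seq_len(nrow(ev)), function(i) as.list(ev[i, , drop = FALSE]))
    } else list()
  ), path)
  invisible(path)
}

#' Assemble the in-memory cohort dataset
#'
#' Joins genotypes, annotations, gene registry and phenotypes on the
#' (chrom,pos,ref,alt) key / sample id. Variants present in the VCF but
#' absent from the annotation table are kept with absent scores (they can
#' still be frequency-filtered); annotated variants without genotypes are
#' kept with all-missing counts.
#'
#' @param genotypes `"eodm_genotypes"` from [read_vcf()], or NULL.
#' @param annotations Annotation data.frame from [read_annotation_table()].
#' @param phenotypes Phenotype data.frame from [read_phenotype_table()].
#' @param registry A [gene_registry()].
#' @return Object of class `"eodm_cohort"`: `variants` (annotation rows for
#'   every known locus), `counts` (variants x samples integer matrix),
#'   `samples`, `registry`, `join_stats`.
#' @export
assemble_cohort <- function(genotypes, annotations, phenotypes, registry) {
  validate_phenotypes(phenotypes)
  if (!"key" %in% names(annotations)) {
    annotations$key <- variant_key(annotations$chrom, annotations$pos,
                                   annotations$ref, annotations$alt)
  }
  if (anyDuplicated(annotations$key)) {
    stop("duplicate (chrom,pos,ref,alt) in annotation table: ",
         paste(unique(annotations$key[duplicated(annotations$key)]),
               collapse = ", "), call. = FALSE)
  }
  sample_ids <- phenotypes$sample_id
  if (!is.null(genotypes)) {
    geno_samples <- colnames(genotypes$counts)
    shared <- intersect(geno_samples, sample_ids)
    if (!length(shared)) {
      stop("no overlap between VCF samples and phenotype sample ids",
           call. = FALSE)
    }
    extra_keys <- setdiff(genotypes$loci$key, annotations$key)
    if (length(extra_keys)) {
      loci <- genotypes$loci[match(extra_keys, genotypes$loci$key), ]
      pad <- annotations[0, , drop = FALSE]
      pad[seq_along(extra_keys), ] <- NA
      pad$chrom <- loci$chrom; pad$pos <- loci$pos
      pad$ref <- loci$ref; pad$alt <- loci$alt; pad$key <- loci$key
      pad$clinvar <- "not_reported"
      annotations <- rbind(annotations, pad)
    }
    counts <- matrix(NA_integer_, nrow = nrow(annotations), ncol = length(sample_ids),
                     dimnames = list(annotations$key, sample_ids))
    hit <- intersect(annotations$key, rownames(genotypes$counts))
    counts[hit, shared] <- genotypes$counts[hit, shared]
  } else {
    counts <- matrix(NA_integer_, nrow = nrow(annotations), ncol = length(sample_ids),
                     dimnames = list(annotations$key, sample_ids))
  }
  join_stats <- list(
    n_variants = nrow(annotations),
    n_genotyped = if (is.null(genotypes)) 0L else sum(annotations$key %in% rownames(genotypes$counts)),
    n_samples = length(sample_ids),
    n_samples_with_genotypes = if (is.null(genotypes)) 0L else length(intersect(colnames(genotypes$counts), sample_ids))
  )
  structure(list(variants = annotations, counts = counts,
                 samples = phenotypes, registry = registry,
                 join_stats = join_stats),
            class = "eodm_cohort")
}

#' @export
print.eodm_cohort <- function(x, ...) {
  cat("EODM cohort dataset\n")
  cat("  variants:", nrow(x$variants),
      sprintf("(%d genotyped)", x$join_stats$n_genotyped), "\n")
  cat("  samples: ", nrow(x$samples),
      sprintf("(%d eodm / %d control)", sum(x$samples$group == "eodm"),
              sum(x$samples$group == "control")), "\n")
  invisible(x)
}

#' Write a result table as TSV
#'
#' All result tables use tab separation, no quoting, `NA` for missing.
#'
#' @param df data.frame.
#' @param path Output path.
#' @export
write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a JSON run summary
#'
#' @param summary Named list.
#' @param path Output path.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
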