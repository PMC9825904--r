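# Genetic risk scores: GRS = sum_i G_i * beta_i over a panel of AMD-associated
# variants, where G_i counts effect (minor) alleles and beta_i is the natural
# log of the fully conditioned odds ratio. Pathway sub-scores (complement,
# lipid) use the tagged panel subsets.

grs_pathways <- c("complement", "lipid", "other")

#' Construct / validate a risk panel
#'
#' @param df data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `effect_allele`, `beta`, `pathway` (one of complement/lipid/other) and
#'   optional `freq` (panel allele frequency of the effect allele, used for
#'   mean imputation of missing genotypes).
#' @return The validated data.frame with class `"risk_panel"` prepended and a
#'   `key` column added.
#' @export
risk_panel <- function(df) {
  required <- c("id", "chrom", "pos", "ref", "alt", "effect_allele", "beta",
                "pathway")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("risk panel lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"freq" %in% names(df)) df$freq <- NA_real_
  if (any(!is.finite(df$beta))) stop("panel betas must be finite", call. = FALSE)
  bad <- df$effect_allele != df$ref & df$effect_allele != df$alt
  if (any(bad)) {
    stop("effect allele matches neither ref nor alt for panel variant(s): ",
         paste(df$id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- !df$pathway %in% grs_pathways
  if (any(bad)) {
    stop("unknown pathway tag(s): ", paste(unique(df$pathway[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) stop("duplicate panel variant ids", call. = FALSE)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  class(df) <- c("risk_panel", "data.frame")
  df
}

#' Read a risk panel TSV
#'
#' Tab-separated panel file with the [risk_panel()] columns.
#'
#' @param path File path.
#' @return A `risk_panel`.
#' @export
read_risk_panel <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "")
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$beta <- as.numeric(df$beta)
  if ("freq" %in% names(df)) df$freq <- as.numeric(df$freq)
  risk_panel(df)
}

#' Effect-allele dosage for one panel variant
#'
#' Converts stored alternate-allele counts into effect-allele dosages. When
#' the effect allele is the VCF alternate allele the dosage equals the count;
#' when it is the reference allele the coding flips to `2 - count`. Missing
#' genotypes are mean-imputed as `2 * freq` when a panel frequency is
#' configured (the standard PRS convention), else left `NA` for the caller's
#' missing policy.
#'
#' @param counts Integer vector of alternate-allele counts (NA = missing).
#' @param ref,alt,effect_allele Alleles of the locus.
#' @param freq Optional panel effect-allele frequency for imputation.
#' @return Numeric dosage vector in `[0, 2]` (or NA).
#' @export
dosage <- function(counts, ref, alt, effect_allele, freq = NA_real_) {
  if (effect_allele == alt) {
    d <- as.numeric(counts)
  } else if (effect_allele == ref) {
    d <- 2 - as.numeric(counts)
  } else {
    stop("effect allele '", effect_allele, "' matches neither ref '", ref,
         "' nor alt '", alt, "'", call. = FALSE)
  }
  if (!is.na(freq)) d[is.na(d)] <- 2 * freq
  d
}

.panel_dosage_matrix <- function(cohort_counts, panel, missing_policy) {
  samples <- colnames(cohort_counts)
  d <- matrix(NA_real_, nrow = nrow(panel), ncol = length(samples),
              dimnames = list(panel$id, samples))
  for (i in seq_len(nrow(panel))) {
    key <- panel$key[[i]]
    counts <- if (key %in% rownames(cohort_counts)) {
      cohort_counts[key, ]
    } else {
      rep(NA_integer_, length(samples))  # locus absent: treat as all-missing
    }
    freq <- if (missing_policy == "impute") panel$freq[[i]] else NA_real_
    d[i, ] <- dosage(counts, panel$ref[[i]], panel$alt[[i]],
                     panel$effect_allele[[i]], freq)
  }
  d
}

#' Per-sample genetic risk scores
#'
#' Computes overall, complement and lipid GRS for every sample:
#' `GRS = sum_i G_i beta_i` over the respective panel subset.
#'
#' @param cohort An `"eodm_cohort"` (or an `"eodm_genotypes"` object).
#' @param panel A [risk_panel()].
#' @param missing_policy `"impute"` (default; missing genotype contributes
#'   `2 * freq * beta` when the panel provides a frequency) or `"exclude"`
#'   (missing genotypes contribute 0 and are tallied).
#' @return data.frame with `sample_id`, `grs_overall`, `grs_complement`,
#'   `grs_lipid`, `grs_other` and `n_missing_overall` / `_complement` /
#'   `_lipid` (panel genotypes that were unavailable before imputation).
#' @export
grs_profiles <- function(cohort, panel, missing_policy = c("impute", "exclude")) {
  missing_policy <- match.arg(missing_policy)
  counts <- if (inherits(cohort, "eodm_cohort")) cohort$counts
            else if (inherits(cohort, "eodm_genotypes")) cohort$counts
            else stop("cohort must be an eodm_cohort or eodm_genotypes object",
                      call. = FALSE)
  d <- .panel_dosage_matrix(counts, panel, missing_policy)
  raw_missing <- is.na(.panel_dosage_matrix(counts, panel, "exclude"))
  d[is.na(d)] <- 0  # exclude policy (and impute without freq): drop term
  subset_score <- function(rows) {
    if (!any(rows)) return(rep(0, ncol(d)))
    colSums(d[rows, , drop = FALSE] * panel$beta[rows])
  }
  data.frame(
    sample_id = colnames(counts),
    grs_overall = subset_score(rep(TRUE, nrow(panel))),
    grs_complement = subset_score(panel$pathway == "complement"),
    grs_lipid = subset_score(panel$pathway == "lipid"),
    grs_other = subset_score(panel$pathway == "other"),
    n_missing_overall = colSums(raw_missing),
    n_missing_complement = colSums(raw_missing[panel$pathway == "complement", , drop = FALSE]),
    n_missing_lipid = colSums(raw_missing[panel$pathway == "lipid", , drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' GRS for one sample over a panel subset
#'
#' Scalar convenience wrapper around the same sum; `subset` selects panel
#' rows (logical/integer index or a pathway name).
#'
#' @param sample_counts Named integer vector of alternate-allele counts keyed
#'   by variant key (NA allowed).
#' @param panel A [risk_panel()].
#' @param subset Pathway name, or index into the panel; default all rows.
#' @param missing_policy See [grs_profiles()].
#' @return Numeric scalar.
#' @export
compute_grs <- function(sample_counts, panel, subset = NULL,
                        missing_policy = c("impute", "exclude")) {
  missing_policy <- match.arg(missing_policy)
  if (is.character(subset) && length(subset) == 1L && subset %in% grs_pathways) {
    subset <- which(panel$pathway == subset)
  }
  sub <- if (is.null(subset)) panel else panel[subset, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("empty panel subset; GRS defined as 0")
    return(0)
  }
  total <- 0
  for (i in seq_len(nrow(sub))) {
    counts <- sample_counts[sub$key[[i]]]
    if (is.null(counts)) counts <- NA_integer_
    freq <- if (missing_policy == "impute") sub$freq[[i]] else NA_real_
    d <- dosage(unname(counts), sub$ref[[i]], sub$alt[[i]],
                sub$effect_allele[[i]], freq)
    if (is.na(d)) d <- 0
    total <- total + d * sub$beta[[i]]
  }
  total
}

#' Group summaries of GRS profiles
#'
#' Mean, sample SD (n-1 denominator; NA for n = 1), median, IQR and n per
#' group for each score column.
#'
#' @param profiles Output of [grs_profiles()].
#' @param grouping Vector of group labels aligned with `profiles` rows.
#' @param scores Score columns to summarize.
#' @return data.frame, one row per (group, score).
#' @export
grs_group_summary <- function(profiles, grouping,
                              scores = c("grs_overall", "grs_complement",
                                         "grs_lipid")) {
  if (length(grouping) != nrow(profiles)) {
    stop("grouping length must match profiles", call. = FALSE)
  }
  if (!length(grouping) || all(is.na(grouping))) {
    stop("empty grouping", call. = FALSE)
  }
  out <- list()
  for (sc in scores) {
    for (g in unique(grouping[!is.na(grouping)])) {
      x <- profiles[[sc]][grouping == g & !is.na(grouping)]
      out[[length(out) + 1L]] <- data.frame(
        score = sc, group = as.character(g), n = length(x),
        mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
        median = stats::median(x),
        iqr_lower = unname(stats::quantile(x, 0.25)),
        iqr_upper = unname(stats::quantile(x, 0.75)),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
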