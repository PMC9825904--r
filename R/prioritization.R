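# Rare-variant prioritization cascade: MAF filter (< 1% in both the internal
# database and gnomAD, missing = pass), candidate-gene intersection,
# deleteriousness (variant type OR all-three in-silico thresholds OR ClinVar
# pathogenic/likely pathogenic), gene recurrence across distinct carriers,
# and the inherited-retinal-dystrophy mimic screen.

#' Default cascade thresholds
#'
#' MAF < 1%, CADD > 15, PhyloP > 2.7, Grantham > 80 (all strict
#' inequalities), gene recurrence in >= 2 distinct patients.
#'
#' @param maf_max,cadd_min,phylop_min,grantham_min,min_recurrent_patients
#'   Override any threshold.
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(maf_max = 0.01, cadd_min = 15,
                               phylop_min = 2.7, grantham_min = 80,
                               min_recurrent_patients = 2L) {
  th <- list(maf_max = maf_max, cadd_min = cadd_min, phylop_min = phylop_min,
             grantham_min = grantham_min,
             min_recurrent_patients = as.integer(min_recurrent_patients))
  if (any(unlist(th) <= 0)) stop("thresholds must be positive", call. = FALSE)
  th
}

deleterious_types <- c("nonsense", "frameshift", "stop_loss", "canonical_splice")
clinvar_pathogenic <- c("pathogenic", "likely_pathogenic",
                        "pathogenic_or_likely_pathogenic")

#' Rare-variant frequency filter
#'
#' A variant survives iff its internal-database MAF and its gnomAD MAF are
#' both below `maf_max`; an absent frequency counts as 0 (rare), mirroring
#' the retention of variants that population databases have never seen.
#'
#' @param variants Annotation data.frame (fraction-scale frequencies).
#' @param thresholds From [default_thresholds()].
#' @return Logical vector (`TRUE` = survives), same length as rows.
#' @export
filter_rare <- function(variants, thresholds = default_thresholds()) {
  gn <- variants$maf_gnomad
  int <- variants$maf_internal
  gn[is.na(gn)] <- 0
  int[is.na(int)] <- 0
  gn < thresholds$maf_max & int < thresholds$maf_max
}

#' Candidate-list membership per variant
#'
#' @param variants Annotation data.frame with a `gene` column.
#' @param registry A [gene_registry()].
#' @param lists Which registry lists to intersect (default the four
#'   candidate lists).
#' @return List (one element per variant) of character vectors of list names
#'   the gene belongs to (may be empty, may have several entries).
#' @export
annotate_candidates <- function(variants, registry,
                                lists = c("complement", "lipid",
                                          "mouse_model", "amd_loci")) {
  lapply(variants$gene, function(g) {
    if (is.na(g)) return(character(0))
    names(which(vapply(registry$lists[lists], function(l) g %in% l, logical(1))))
  })
}

#' Deleteriousness decision with reason codes
#'
#' Applies the three-rule disjunction to each variant:
#' * type rule: variant type in {nonsense, frameshift, stop_loss,
#'   canonical_splice};
#' * in-silico rule: PhyloP, CADD **and** Grantham all present and strictly
#'   above their thresholds;
#' * ClinVar rule: classification pathogenic / likely pathogenic /
#'   pathogenic-or-likely-pathogenic.
#' A benign or likely-benign ClinVar status never vetoes the other rules; a
#' missing score fails its own comparison only.
#'
#' Variant type is taken from a `variant_type` column when present, else
#' derived via [classify_variant_type()]; a missing `grantham` value is
#' filled from the protein change via [variant_grantham()] where possible.
#'
#' @param variants Annotation data.frame.
#' @param thresholds From [default_thresholds()].
#' @return data.frame with `key`, `gene`, `variant_type`, the three
#'   `rule_*_fired` flags and `deleterious`.
#' @export
is_deleterious <- function(variants, thresholds = default_thresholds()) {
  n <- nrow(variants)
  vt <- if ("variant_type" %in% names(variants)) variants$variant_type
        else rep(NA_character_, n)
  gr <- if ("grantham" %in% names(variants)) variants$grantham
        else rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(vt[[i]])) {
      has_any <- any(!is.na(c(variants$hgvs_c[[i]], variants$hgvs_p[[i]],
                              variants$consequence[[i]])))
      # unannotated loci (e.g. genotyped but absent from the annotation
      # table) fall through as "other": they can never fire the type rule
      vt[[i]] <- if (has_any) {
        classify_variant_type(variants$hgvs_c[[i]], variants$hgvs_p[[i]],
                              variants$consequence[[i]])
      } else "other"
    }
    if (is.na(gr[[i]])) {
      p <- variants$hgvs_p[[i]]
      if (!is.null(p) && !is.na(p)) {
        parsed <- tryCatch(parse_hgvs_p(p), error = function(e) NULL)
        if (!is.null(parsed) && vt[[i]] == "missense") {
          gr[[i]] <- grantham_score(parsed$ref_aa, parsed$alt_aa)
        } else {
          gr[[i]] <- variant_grantham(vt[[i]])
        }
      }
    }
  }
  above <- function(x, cut) !is.na(x) & x > cut
  rule_type <- vt %in% deleterious_types
  rule_insilico <- above(variants$phylop, thresholds$phylop_min) &
    above(variants$cadd_phred, thresholds$cadd_min) &
    above(gr, thresholds$grantham_min)
  cv <- if ("clinvar" %in% names(variants)) variants$clinvar
        else rep("not_reported", n)
  rule_clinvar <- !is.na(cv) & cv %in% clinvar_pathogenic
  data.frame(
    key = if ("key" %in% names(variants)) variants$key else
      variant_key(variants$chrom, variants$pos, variants$ref, variants$alt),
    gene = variants$gene,
    variant_type = vt,
    grantham_used = gr,
    rule_type_fired = rule_type,
    rule_insilico_fired = rule_insilico,
    rule_clinvar_fired = rule_clinvar,
    deleterious = rule_type | rule_insilico | rule_clinvar,
    stringsAsFactors = FALSE
  )
}

#' Carrier samples per variant
#'
#' A carrier has allele count >= 1 (homozygotes count once).
#'
#' @param counts Variant x sample count matrix.
#' @param keys Variant keys (rownames of `counts` to use).
#' @param samples Optional sample subset.
#' @return Named list key -> character vector of carrier sample ids.
#' @export
variant_carriers <- function(counts, keys = rownames(counts), samples = NULL) {
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  out <- lapply(keys, function(k) {
    if (!k %in% rownames(counts)) return(character(0))
    v <- counts[k, ]
    names(v)[!is.na(v) & v >= 1L]
  })
  names(out) <- keys
  out
}

#' Genes recurrently hit across distinct patients
#'
#' A gene qualifies iff the union of carriers over its (rare) variants has at
#' least `min_patients` distinct members -- the same patient carrying two
#' variants counts once; two patients carrying different variants count.
#'
#' @param variants Annotation data.frame (typically already rare-filtered).
#' @param counts Variant x sample count matrix.
#' @param samples Sample ids to consider (typically the case group).
#' @param min_patients Recurrence threshold (default 2).
#' @return data.frame `gene`, `n_carriers`, `n_variants`, `carriers`
#'   (comma-joined), qualifying genes only, ordered by decreasing carriers.
#' @export
recurrent_genes <- function(variants, counts, samples = colnames(counts),
                            min_patients = 2L) {
  carr <- variant_carriers(counts, variants$key, samples)
  out <- list()
  for (g in unique(variants$gene[!is.na(variants$gene)])) {
    keys <- variants$key[!is.na(variants$gene) & variants$gene == g]
    union_carr <- unique(unlist(carr[keys]))
    if (length(union_carr) >= min_patients) {
      out[[length(out) + 1L]] <- data.frame(
        gene = g, n_carriers = length(union_carr), n_variants = length(keys),
        carriers = paste(sort(union_carr), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), n_carriers = integer(),
                      n_variants = integer(), carriers = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(-res$n_carriers, res$gene), , drop = FALSE]
}

#' Run the full prioritization cascade
#'
#' Sequence: rare-frequency filter, candidate-gene intersection,
#' deleteriousness rules, carrier sets. Step counts are recorded so cohort
#' runs are auditable (input -> rare -> candidate -> deleterious).
#'
#' @param cohort An `"eodm_cohort"` (or a bare annotation data.frame plus
#'   `registry =`).
#' @param thresholds From [default_thresholds()].
#' @param lists Candidate lists to use; `NULL` disables the candidate-gene
#'   requirement (all rare variants are scored).
#' @param registry Registry override when `cohort` is a plain data.frame.
#' @param case_samples Samples used for carrier counts; defaults to the
#'   `eodm` group when phenotypes are available.
#' @return List of class `"prioritization_result"`: `decisions` (per-variant
#'   table with reason codes and carrier counts), `recurrent`
#'   (qualifying genes), `steps` (cascade counts), `thresholds`.
#' @export
prioritize_variants <- function(cohort, thresholds = default_thresholds(),
                                lists = c("complement", "lipid", "mouse_model"),
                                registry = NULL, case_samples = NULL) {
  if (inherits(cohort, "eodm_cohort")) {
    variants <- cohort$variants
    counts <- cohort$counts
    registry <- cohort$registry
    if (is.null(case_samples)) {
      case_samples <- cohort$samples$sample_id[cohort$samples$group == "eodm"]
      if (!length(case_samples)) case_samples <- cohort$samples$sample_id
    }
  } else {
    variants <- cohort
    counts <- NULL
    if (is.null(registry)) stop("registry required when no cohort is given",
                                call. = FALSE)
  }
  rare <- filter_rare(variants, thresholds)
  cand <- annotate_candidates(variants, registry,
                              lists = lists %||% c("complement", "lipid",
                                                   "mouse_model", "amd_loci"))
  cand_hit <- if (is.null(lists)) rep(TRUE, nrow(variants))
              else lengths(cand) > 0L
  dec <- is_deleterious(variants, thresholds)
  dec$passes_rare_filter <- rare
  dec$candidate_lists_hit <- vapply(cand, paste, character(1), collapse = ",")
  dec$in_candidate_gene <- cand_hit
  # cascade semantics: deleterious verdict only for variants surviving the
  # earlier steps; reason codes are kept for every variant
  dec$deleterious <- dec$deleterious & rare & cand_hit
  if (!is.null(counts)) {
    carr <- variant_carriers(counts, dec$key, case_samples)
    dec$n_carriers <- lengths(carr)
    dec$carrier_sample_ids <- vapply(carr, paste, character(1), collapse = ",")
    rec <- recurrent_genes(variants[rare & cand_hit, , drop = FALSE], counts,
                           case_samples, thresholds$min_recurrent_patients)
  } else {
    dec$n_carriers <- rep(NA_integer_, nrow(dec))
    dec$carrier_sample_ids <- rep(NA_character_, nrow(dec))
    rec <- NULL
  }
  steps <- list(n_input = nrow(variants), n_rare = sum(rare),
                n_candidate = sum(rare & cand_hit),
                n_deleterious = sum(dec$deleterious))
  structure(list(decisions = dec, recurrent = rec, steps = steps,
                 thresholds = thresholds),
            class = "prioritization_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ird_qualifying_types <- c("nonsense", "frameshift", "stop_loss",
                          "canonical_splice", "splice_region", "missense",
                          "inframe_indel")

#' Screen inherited-retinal-dystrophy genes for AMD mimics
#'
#' For each configured IRD gene, finds samples whose rare qualifying variants
#' (nonsense, frameshift, protein-altering or splice-site) satisfy the
#' inheritance rule: autosomal dominant genes flag on a single qualifying
#' variant, autosomal recessive genes only on a biallelic state (two or more
#' distinct rare variants, assumed in trans, or one homozygous variant).
#' Known pathogenic intronic/structural events are matched by exact
#' (gene, description) lookup against `hgvs_c` and flag regardless of type.
#'
#' @param cohort An `"eodm_cohort"` whose registry configures `ird` modes.
#' @param thresholds From [default_thresholds()] (rare filter).
#' @param samples Samples to screen; defaults to the `eodm` group.
#' @return data.frame `gene`, `inheritance`, `sample_id`, `n_variants`,
#'   `n_hom`, `flagged`, `basis`, `variant_keys`; one row per (gene, sample)
#'   with at least one qualifying variant.
#' @export
ird_screen <- function(cohort, thresholds = default_thresholds(),
                       samples = NULL) {
  registry <- cohort$registry
  if (!length(registry$ird)) stop("registry configures no IRD genes", call. = FALSE)
  if (is.null(samples)) {
    samples <- cohort$samples$sample_id[cohort$samples$group == "eodm"]
    if (!length(samples)) samples <- cohort$samples$sample_id
  }
  variants <- cohort$variants
  rare <- filter_rare(variants, thresholds)
  dec <- is_deleterious(variants, thresholds)
  qualifying <- rare & !is.na(variants$gene) &
    variants$gene %in% names(registry$ird) &
    dec$variant_type %in% ird_qualifying_types
  known <- registry$known_ird_events
  known_hit <- rep(FALSE, nrow(variants))
  if (nrow(known)) {
    known_hit <- paste(variants$gene, variants$hgvs_c) %in%
      paste(known$gene, known$description)
  }
  use <- qualifying | known_hit
  out <- list()
  for (g in intersect(unique(variants$gene[use]), names(registry$ird))) {
    mode <- registry$ird[[g]]
    idx <- which(use & variants$gene == g)
    keys <- variants$key[idx]
    sub <- cohort$counts[keys, samples, drop = FALSE]
    for (s in samples) {
      v <- sub[, s]
      carried <- !is.na(v) & v >= 1L
      if (!any(carried)) next
      n_var <- sum(carried)
      n_hom <- sum(!is.na(v) & v == 2L)
      hit_known <- any(known_hit[idx][carried])
      flagged <- if (hit_known) TRUE
                 else if (mode == "AD") n_var >= 1L
                 else n_var >= 2L || n_hom >= 1L
      basis <- if (hit_known) "known_event"
               else if (mode == "AD") "dominant_single_variant"
               else if (n_hom >= 1L) "recessive_homozygous"
               else if (n_var >= 2L) "recessive_biallelic"
               else "recessive_monoallelic_not_flagged"
      out[[length(out) + 1L]] <- data.frame(
        gene = g, inheritance = mode, sample_id = s, n_variants = n_var,
        n_hom = n_hom, flagged = flagged, basis = basis,
        variant_keys = paste(keys[carried], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), inheritance = character(),
                      sample_id = character(), n_variants = integer(),
                      n_hom = integer(), flagged = logical(),
                      basis = character(), variant_keys = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
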