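# Descriptive cohort statistics and stage-stratified group comparisons.
# Skewed scores are compared with Kruskal-Wallis, normal ones with one-way
# ANOVA; in auto mode per-group Shapiro-Wilk at alpha = 0.05 selects the test.

#' Descriptive summary of a phenotype table
#'
#' Categorical fields are reported as n (%) with percentages rounded to one
#' decimal; continuous fields as mean (SD) when no Shapiro-Wilk rejection at
#' alpha = 0.05, else median (IQR). Also reports the proportion of advanced
#' (Rotterdam stage 4) disease.
#'
#' @param samples Phenotype data.frame ([read_phenotype_table()] layout).
#' @return List with `n`, `continuous` (data.frame), `categorical`
#'   (data.frame of field/level/n/percent), and `advanced_stage_percent`.
#' @export
describe_cohort <- function(samples) {
  if (nrow(samples) == 0L) stop("empty phenotype table", call. = FALSE)
  n <- nrow(samples)
  pct <- function(k) round(100 * k / n, 1)

  cont_summary <- function(x, label) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NULL)
    normal <- length(unique(x)) > 2 && length(x) >= 3 && length(x) <= 5000 &&
      stats::shapiro.test(x)$p.value >= 0.05
    data.frame(
      field = label, n = length(x),
      display = if (normal) "mean_sd" else "median_iqr",
      mean = mean(x), sd = stats::sd(x), median = stats::median(x),
      iqr_lower = unname(stats::quantile(x, 0.25)),
      iqr_upper = unname(stats::quantile(x, 0.75)),
      stringsAsFactors = FALSE)
  }
  continuous <- do.call(rbind, Filter(Negate(is.null), list(
    cont_summary(samples$age, "age"),
    cont_summary(samples$age_at_diagnosis, "age_at_diagnosis")
  )))

  cat_rows <- function(field, values) {
    tab <- table(values, useNA = "no")
    if (!length(tab)) return(NULL)
    data.frame(field = field, level = names(tab), n = as.integer(tab),
               percent = pct(as.integer(tab)), stringsAsFactors = FALSE)
  }
  stage_label <- ifelse(samples$stage == 4,
                        paste0("stage4_", samples$stage4_subtype),
                        paste0("stage", samples$stage))
  categorical <- do.call(rbind, Filter(Negate(is.null), list(
    cat_rows("sex", samples$sex),
    cat_rows("group", samples$group),
    cat_rows("stage", stage_label)
  )))

  list(n = n, continuous = continuous, categorical = categorical,
       advanced_stage_percent = pct(sum(samples$stage == 4)))
}

# enumerate all distinct assignments of n observations into groups of the
# given sizes; calls fun(index vector of group labels) for each
.for_each_assignment <- function(sizes, fun) {
  n <- sum(sizes)
  labels <- integer(n)
  recurse <- function(remaining, gi) {
    if (gi > length(sizes)) {
      fun(labels)
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining, sizes[[gi]], simplify = FALSE)
    for (p in picks) {
      labels[p] <<- gi
      recurse(setdiff(remaining, p), gi + 1L)
    }
  }
  recurse(seq_len(n), 1L)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H on midranks (via [stats::kruskal.test()]). The p-value
#' comes from the chi-square approximation with k-1 degrees of freedom, or
#' from the exact permutation distribution (all distinct assignments of the
#' pooled observations to the observed group sizes) when `exact = TRUE` or
#' when `exact = "auto"` and the total sample size is at most
#' `exact_cutoff`. The chi-square approximation is poor at such sizes, which
#' is why small inputs default to the exact distribution.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels aligned with `values`.
#' @param exact `TRUE`, `FALSE` or `"auto"` (default).
#' @param exact_cutoff Total-n cutoff for auto mode (default 8).
#' @return List: `statistic` (H), `df`, `p_value`, `method`
#'   (`"chi_square"` or `"exact_permutation"`).
#' @export
kruskal_wallis <- function(values, groups, exact = "auto", exact_cutoff = 8L) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least two groups", call. = FALSE)
  if (length(unique(values)) == 1L) {
    stop("all observations identical: rank test degenerate (tie correction ",
         "divides by zero)", call. = FALSE)
  }
  kt <- stats::kruskal.test(values, factor(groups))
  H <- unname(kt$statistic)
  use_exact <- isTRUE(exact) ||
    (identical(exact, "auto") && length(values) <= exact_cutoff)
  if (!use_exact) {
    return(list(statistic = H, df = unname(kt$parameter),
                p_value = kt$p.value, method = "chi_square"))
  }
  # exact permutation distribution of H under exchangeability
  stat_for <- function(labels) {
    unname(stats::kruskal.test(values, factor(labels))$statistic)
  }
  total <- 0L; extreme <- 0L
  .for_each_assignment(as.integer(sizes), function(labels) {
    total <<- total + 1L
    if (stat_for(labels) >= H - 1e-10) extreme <<- extreme + 1L
  })
  list(statistic = H, df = length(sizes) - 1L, p_value = extreme / total,
       method = "exact_permutation")
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA (between/within decomposition,
#' via [stats::oneway.test()] with `var.equal = TRUE`).
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return List: `statistic` (F), `df_between`, `df_within`, `p_value`.
#' @export
anova_oneway <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L)) stop("each group needs at least two observations",
                            call. = FALSE)
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0)) {
    stop("zero within-group variance everywhere: F undefined", call. = FALSE)
  }
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       df_between = unname(ft$parameter[1]),
       df_within = unname(ft$parameter[2]),
       p_value = ft$p.value)
}

#' Compare groups with automatic test selection
#'
#' In `auto` mode a per-group Shapiro-Wilk test at alpha = 0.05 selects
#' one-way ANOVA iff no group rejects normality (groups too small to assess,
#' n < 3, count as rejecting); otherwise Kruskal-Wallis. `force_kw` /
#' `force_anova` override the selection.
#'
#' @param values Numeric vector of scores.
#' @param groups Group labels.
#' @param policy `"auto"`, `"force_kw"` or `"force_anova"`.
#' @param shapiro_alpha Normality alpha (default 0.05).
#' @return List of class `"group_comparison"`: `test_used`, `statistic`,
#'   `p_value`, `per_group` (n/mean/sd/median/IQR), `normality`
#'   (per-group Shapiro p-values; NA where not assessable).
#' @export
select_and_compare <- function(values, groups,
                               policy = c("auto", "force_kw", "force_anova"),
                               shapiro_alpha = 0.05) {
  policy <- match.arg(policy)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  glev <- unique(groups)
  shapiro_p <- vapply(glev, function(g) {
    x <- values[groups == g]
    if (length(x) < 3L || length(x) > 5000L || length(unique(x)) == 1L) {
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  use_anova <- switch(policy,
    force_kw = FALSE,
    force_anova = TRUE,
    auto = !any(is.na(shapiro_p)) && all(shapiro_p >= shapiro_alpha)
  )
  res <- if (use_anova) anova_oneway(values, groups)
         else kruskal_wallis(values, groups)
  per_group <- do.call(rbind, lapply(glev, function(g) {
    x <- values[groups == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               median = stats::median(x),
               iqr_lower = unname(stats::quantile(x, 0.25)),
               iqr_upper = unname(stats::quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    test_used = if (use_anova) "anova" else "kruskal_wallis",
    statistic = res$statistic, p_value = res$p_value,
    per_group = per_group, normality = shapiro_p, policy = policy
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (policy %s)\n",
              x$test_used, x$statistic, x$p_value, x$policy))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}
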