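# Descriptive surfaces over a classified cohort: tier/reason proportions,
# age/sex cross-tabulation, last-year comorbidity incidence with pairwise
# standardized differences, and diagnostic-test usage.

#' Tier and reason proportions
#'
#' Tier proportions are the number of (living, eligible) people in each
#' tier divided by the cohort size; reason shares are computed within each
#' tier. Both sum to one exactly (up to floating arithmetic) and are
#' invariant to row order.
#'
#' @param results Classification results tibble (from
#'   [classify_cohort()]`$results`).
#' @return List with `tiers` (tibble `tier`, `n`, `proportion`) and
#'   `reasons` (tibble `tier`, `reason`, `n`, `share`).
#' @export
tier_proportions <- function(results) {
  if (nrow(results) == 0) abort_data("empty cohort: no classification results")
  tiers <- dplyr::count(results, .data$tier, .drop = FALSE)
  tiers$proportion <- tiers$n / sum(tiers$n)
  reasons <- dplyr::count(results, .data$tier, .data$reason)
  reasons <- dplyr::mutate(dplyr::group_by(reasons, .data$tier),
                           share = .data$n / sum(.data$n))
  list(tiers = tiers, reasons = dplyr::ungroup(reasons))
}

age_band_levels <- function() {
  c("18-30", "30-40", "40-50", "50-60", "60-70", "70-80", ">80")
}

# Bands are (18,30], (30,40], ..., (80, Inf) on index-date age; the first
# band additionally admits age exactly 18 so every eligible adult lands in
# a band.
age_band <- function(age) {
  cut(age, breaks = c(17, 30, 40, 50, 60, 70, 80, Inf),
      labels = age_band_levels(), right = TRUE)
}

#' Age and sex distribution by likelihood tier
#'
#' Cross-tabulates the classified cohort by sex and index-date age band.
#' Cells are percentages of the whole cohort, so the three tier columns sum
#' row-wise to the cohort column and the `All` row of the cohort column is
#' 100.
#'
#' @param persons Persons tibble.
#' @param results Classification results tibble.
#' @param window A [cohort_window()] (supplies the index date for age).
#' @return Tibble with a `group` column (`All`, `Female`, `Male`, then age
#'   bands) and numeric columns `high`, `moderate`, `low`, `cohort`.
#' @export
age_sex_table <- function(persons, results, window = cohort_window()) {
  d <- dplyr::left_join(results, persons, by = "person_id")
  if (anyNA(d$birth_year)) {
    bad <- d$person_id[is.na(d$birth_year)][1]
    abort_data(paste0("result row does not join to a person: ", bad))
  }
  n <- nrow(d)
  age <- event_year(window$index_date) - d$birth_year
  band <- age_band(age)
  row_for <- function(sel) {
    vapply(tier_levels(), function(t) 100 * sum(sel & d$tier == t) / n,
           numeric(1))
  }
  sels <- c(list(All = rep(TRUE, n),
                 Female = d$sex == "female",
                 Male = d$sex == "male"),
            lapply(stats::setNames(age_band_levels(), age_band_levels()),
                   function(b) !is.na(band) & band == b))
  m <- t(vapply(sels, row_for, numeric(3)))
  tibble(group = names(sels),
         high = unname(m[, "high"]), moderate = unname(m[, "moderate"]),
         low = unname(m[, "low"]), cohort = unname(rowSums(m)))
}

#' Standardized difference between two proportions
#'
#' The standard pooled form for a binary covariate:
#' `(p2 - p1) / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`. With the
#' higher-burden group passed first, a larger first proportion yields a
#' negative value. Equal proportions give exactly zero (including the
#' degenerate all-zero / all-one cases, where the denominator vanishes).
#' Absolute values of at most 0.1 are conventionally negligible for binary
#' variables.
#'
#' @param p1,p2 Proportions in `[0, 1]` (vectorized).
#' @return Dimensionless standardized difference(s).
#' @examples
#' standardized_difference(0.239, 0.025)
#' @export
standardized_difference <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    abort_data("proportions must lie in [0, 1]")
  }
  den <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  ifelse(p1 == p2, 0, (p2 - p1) / den)
}

persons_matching <- function(events, codelist) {
  unique(events$person_id[code_matches(codelist, events)])
}

tier_fraction <- function(results, tier, ids) {
  members <- results$person_id[results$tier == tier]
  if (length(members) == 0) return(0)
  mean(members %in% ids)
}

#' Last-year comorbidity incidence by tier, with effect sizes
#'
#' For each comorbidity code list, the fraction of each tier's persons with
#' at least one matching diagnosis dated within the final 365 days of their
#' observation (`[last_date - 364, last_date]`, where `last_date` is
#' enrollment end clamped at the index date). Each person counts once per
#' comorbidity however many claims they have. Pairwise standardized
#' differences are reported with the conventional `|sd| <= 0.1` negligibility
#' flag.
#'
#' @param persons Persons tibble.
#' @param events Events tibble.
#' @param results Classification results tibble.
#' @param registry Code-list registry (its `comorbidities` block is used).
#' @param window A [cohort_window()].
#' @return Tibble with one row per comorbidity: `comorbidity`, `p_high`,
#'   `p_moderate`, `p_low`, `sd_high_low`, `sd_high_mod`, `sd_mod_low`, and
#'   logical `neg_high_low`, `neg_high_mod`, `neg_mod_low`.
#' @export
comorbidity_incidence <- function(persons, events, results, registry,
                                  window = cohort_window()) {
  stopifnot(inherits(registry, "aghd_registry"))
  if (length(registry$comorbidities) == 0) {
    abort_config("registry carries no comorbidity code lists")
  }
  ob <- observation_bounds(persons, window = window)
  diag <- events[events$kind == "diagnosis", , drop = FALSE]
  diag <- dplyr::left_join(diag, ob, by = "person_id")
  in_win <- !is.na(diag$last_date) &
    diag$service_date >= diag$last_date - 364L &
    diag$service_date <= diag$last_date
  diag <- diag[in_win, , drop = FALSE]

  rows <- lapply(names(registry$comorbidities), function(nm) {
    ids <- persons_matching(diag, registry$comorbidities[[nm]])
    ph <- tier_fraction(results, "high", ids)
    pm <- tier_fraction(results, "moderate", ids)
    pl <- tier_fraction(results, "low", ids)
    tibble(comorbidity = nm, p_high = ph, p_moderate = pm, p_low = pl,
           sd_high_low = standardized_difference(ph, pl),
           sd_high_mod = standardized_difference(ph, pm),
           sd_mod_low = standardized_difference(pm, pl))
  })
  out <- dplyr::bind_rows(rows)
  out$neg_high_low <- abs(out$sd_high_low) <= 0.1
  out$neg_high_mod <- abs(out$sd_high_mod) <= 0.1
  out$neg_mod_low <- abs(out$sd_mod_low) <= 0.1
  out
}

#' Diagnostic-test usage in the high and moderate tiers
#'
#' For each labelled test in the `GHD_TEST_CPT` list, the fraction of the
#' high- and moderate-tier persons with at least one matching procedure
#' claim anywhere in their observation. The low tier is omitted by design;
#' an empty tier yields a zero column, not an error.
#'
#' @inheritParams comorbidity_incidence
#' @return Tibble `test`, `p_high`, `p_moderate`.
#' @export
diagnostic_test_usage <- function(persons, events, results, registry) {
  stopifnot(inherits(registry, "aghd_registry"))
  cl <- registry$lists$GHD_TEST_CPT
  if (all(is.na(cl$entries$label))) {
    abort_config("GHD_TEST_CPT entries carry no per-test labels")
  }
  proc <- events[events$kind == "procedure", , drop = FALSE]
  labels <- unique(cl$entries$label[!is.na(cl$entries$label)])
  rows <- lapply(labels, function(lb) {
    sub <- cl
    sub$entries <- cl$entries[!is.na(cl$entries$label) & cl$entries$label == lb, ,
                              drop = FALSE]
    ids <- persons_matching(proc, sub)
    tibble(test = lb,
           p_high = tier_fraction(results, "high", ids),
           p_moderate = tier_fraction(results, "moderate", ids))
  })
  dplyr::bind_rows(rows)
}
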