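# The likelihood rule engine.
#
# High tier (any one, evaluated in fixed precedence order):
#   GROUP_A   >=1 diagnosis of a predefined condition, at any age
#   GROUP_B   >=1 diagnosis of a predefined condition, only as an adult
#   PIT_DEF_3 diagnoses on >= min_deficiency_axes distinct non-GH pituitary axes
#   GH_RX     >=1 adult GH prescription, with no exclusion-list diagnosis
#   HRT_3     >= min_replacement_classes distinct replacement classes, each
#             prescribed at least once within one calendar year as an adult,
#             with no exclusion-list diagnosis
# Moderate tier (only if no high path fired and no GH veto applies):
#   TEST_GHD     >=1 GHD-specific diagnostic test
#   TEST_AXIS_3  tests on >= min_deficiency_axes distinct non-GH axes
# Everyone else is low. A person whose only GH prescription evidence was
# vetoed by the exclusion lists bypasses the moderate tier entirely (GH
# treatment as an adult rules out moderate by construction); the bypass is
# a config flag because it is the one consequential flowchart reading.
#
# Exclusion lists touch ONLY the two prescription paths, are applied as the
# union of both lists, and are searched over the whole observation with no
# temporal tie to the prescription.

#' Algorithm configuration
#'
#' @param registry Code-list registry from [load_codelists()] or
#'   [default_codelists()].
#' @param min_deficiency_axes Minimum number of distinct non-GH pituitary
#'   axes for the deficiency-diagnosis and axis-test rules (default 3; the
#'   final design raised this from two to three).
#' @param min_replacement_classes Minimum number of distinct hormone
#'   replacement classes within one calendar year (default 3).
#' @param window A [cohort_window()]; supplies the index date and adult age.
#' @param replacement_window How "within the same year" is read; only
#'   `"calendar_year"` is implemented.
#' @param gh_veto_bypasses_moderate When `TRUE` (default), a person whose
#'   adult GH prescription was vetoed by an exclusion-list diagnosis is
#'   assigned low directly, never moderate.
#' @return An `aghd_config` list.
#' @export
algorithm_config <- function(registry,
                             min_deficiency_axes = 3L,
                             min_replacement_classes = 3L,
                             window = cohort_window(),
                             replacement_window = "calendar_year",
                             gh_veto_bypasses_moderate = TRUE) {
  stopifnot(inherits(registry, "aghd_registry"))
  if (min_deficiency_axes < 1) abort_config("min_deficiency_axes must be >= 1")
  if (min_replacement_classes < 1) abort_config("min_replacement_classes must be >= 1")
  if (!identical(replacement_window, "calendar_year")) {
    abort_config("only replacement_window = 'calendar_year' is implemented")
  }
  structure(list(registry = registry,
                 min_deficiency_axes = as.integer(min_deficiency_axes),
                 min_replacement_classes = as.integer(min_replacement_classes),
                 window = window,
                 replacement_window = replacement_window,
                 gh_veto_bypasses_moderate = isTRUE(gh_veto_bypasses_moderate)),
            class = "aghd_config")
}

# Per-person boolean predicates, computed set-wise over the whole cohort so
# single-person and cohort classification share one code path.
person_predicates <- function(persons, events, cfg) {
  reg <- cfg$registry$lists
  adult <- cfg$window$adult_age
  ev <- dplyr::left_join(events,
                         persons[, c("person_id", "birth_year")],
                         by = "person_id")
  ev$age <- event_year(ev$service_date) - ev$birth_year
  diag <- ev[ev$kind == "diagnosis", , drop = FALSE]
  proc <- ev[ev$kind == "procedure", , drop = FALSE]
  rx <- ev[ev$kind == "pharmacy", , drop = FALSE]

  ids_where <- function(df, flag) unique(df$person_id[flag])
  axis_ids <- function(df, codelist, k) {
    hits <- axis_hits(df, codelist)
    if (nrow(hits) == 0) return(character(0))
    cnt <- dplyr::count(hits, .data$person_id)
    cnt$person_id[cnt$n >= k]
  }

  ga <- ids_where(diag, code_matches(reg$GROUP_A_CONDITIONS, diag))
  gb <- ids_where(diag, code_matches(reg$GROUP_B_CONDITIONS, diag) &
                    diag$age >= adult)
  excl <- union(ids_where(diag, code_matches(reg$EXCLUSION_1, diag)),
                ids_where(diag, code_matches(reg$EXCLUSION_2, diag)))
  pd <- axis_ids(diag, reg$PITUITARY_DEFICIENCY_DX, cfg$min_deficiency_axes)
  gh <- ids_where(rx, code_matches(reg$GH_THERAPY_RX, rx) & rx$age >= adult)

  # HRT: distinct replacement classes within one calendar year, adult events only
  rx_adult <- rx[rx$age >= adult, , drop = FALSE]
  hr <- character(0)
  if (nrow(rx_adult) > 0) {
    hits <- axis_hits(
      tibble(person_id = paste(rx_adult$person_id,
                               event_year(rx_adult$service_date), sep = "\r"),
             system = rx_adult$system, code = rx_adult$code),
      reg$HORMONE_REPLACEMENT_RX)
    if (nrow(hits) > 0) {
      per_py <- dplyr::count(hits, .data$person_id)
      hr <- unique(sub("\r.*$", "", per_py$person_id[
        per_py$n >= cfg$min_replacement_classes]))
    }
  }

  tg <- ids_where(proc, code_matches(reg$GHD_TEST_CPT, proc))
  ta <- axis_ids(proc, reg$AXIS_TEST_CPT, cfg$min_deficiency_axes)

  pid <- persons$person_id
  tibble(person_id = pid,
         group_a = pid %in% ga, group_b = pid %in% gb,
         pitdef3 = pid %in% pd, ghrx = pid %in% gh,
         hrt3 = pid %in% hr, exclusion = pid %in% excl,
         test_ghd = pid %in% tg, test_axis3 = pid %in% ta)
}

classify_from_predicates <- function(pred, cfg) {
  n <- nrow(pred)
  high_reason <- rep(NA_character_, n)
  take <- function(cur, cond, val) ifelse(is.na(cur) & cond, val, cur)
  high_reason <- take(high_reason, pred$group_a, "GROUP_A")
  high_reason <- take(high_reason, pred$group_b, "GROUP_B")
  high_reason <- take(high_reason, pred$pitdef3, "PIT_DEF_3")
  high_reason <- take(high_reason, pred$ghrx & !pred$exclusion, "GH_RX")
  high_reason <- take(high_reason, pred$hrt3 & !pred$exclusion, "HRT_3")

  vet_gh <- pred$ghrx & pred$exclusion
  vet_hrt <- pred$hrt3 & pred$exclusion
  bypass <- vet_gh & cfg$gh_veto_bypasses_moderate

  is_high <- !is.na(high_reason)
  is_mod <- !is_high & !bypass & (pred$test_ghd | pred$test_axis3)
  tier <- ifelse(is_high, "high", ifelse(is_mod, "moderate", "low"))
  reason <- ifelse(is_high, high_reason,
                   ifelse(is_mod, ifelse(pred$test_ghd, "TEST_GHD", "TEST_AXIS_3"),
                          "NONE"))
  excluded_paths <- mapply(function(g, h) {
    paste(c(if (g) "GH_RX", if (h) "HRT_3"), collapse = ";")
  }, vet_gh, vet_hrt, USE.NAMES = FALSE)
  if (n == 0) excluded_paths <- character(0)

  tibble(person_id = pred$person_id,
         tier = factor(tier, levels = tier_levels()),
         reason = factor(reason, levels = reason_levels()),
         excluded_paths = as.character(excluded_paths))
}

#' Classify a whole cohort
#'
#' Applies the rule engine to every eligible person. Ineligible persons are
#' listed separately with their first failed criterion; events referencing
#' unknown person ids raise a warning and are ignored. Output is
#' deterministic given identical inputs, and invariant to event order and
#' duplication (all rules are set-valued).
#'
#' @param persons Persons tibble (see [read_persons()]).
#' @param events Events tibble (see [read_events()]).
#' @param cfg An [algorithm_config()].
#' @return An `aghd_classification`: list with `results` (tibble
#'   `person_id`, `tier`, `reason`, `excluded_paths`; one row per eligible
#'   person, in input order), `ineligible` (tibble `person_id`, `reason`),
#'   and `codelist_version`.
#' @export
classify_cohort <- function(persons, events, cfg) {
  stopifnot(inherits(cfg, "aghd_config"))
  unknown <- setdiff(unique(events$person_id), persons$person_id)
  if (length(unknown)) {
    warn(paste0(length(unknown), " event person_id(s) not in the persons table; ",
                "their events are ignored (e.g. ", unknown[1], ")"))
    events <- events[!events$person_id %in% unknown, , drop = FALSE]
  }
  elig <- eligibility(persons, cfg$window)
  ep <- persons[elig$eligible, , drop = FALSE]
  ev <- events[events$person_id %in% ep$person_id, , drop = FALSE]
  results <- classify_from_predicates(person_predicates(ep, ev, cfg), cfg)
  structure(list(results = results,
                 ineligible = elig[!elig$eligible, c("person_id", "reason")],
                 codelist_version = cfg$registry$version),
            class = "aghd_classification")
}

#' @export
print.aghd_classification <- function(x, ...) {
  cat("<aghd_classification> code lists:", x$codelist_version, "\n")
  cat("  eligible:", nrow(x$results), " ineligible:", nrow(x$ineligible), "\n")
  if (nrow(x$results)) print(table(x$results$tier))
  invisible(x)
}

one_person_tbl <- function(person) {
  person <- as_tibble(person)
  stopifnot(nrow(person) == 1)
  person
}

#' Classify a single person
#'
#' @param person One-row persons tibble; must be eligible under
#'   `cfg$window`.
#' @param events Events tibble for that person.
#' @param cfg An [algorithm_config()].
#' @return One-row tibble `person_id`, `tier`, `reason`, `excluded_paths`.
#' @export
classify_person <- function(person, events, cfg) {
  person <- one_person_tbl(person)
  el <- eligible(person, cfg$window)
  if (!el$eligible) {
    abort_data(paste0("person ", person$person_id, " is not eligible (",
                      el$reason, ")"))
  }
  classify_from_predicates(person_predicates(person, events, cfg), cfg)
}

#' Satisfied high-likelihood criteria, in precedence order
#'
#' Evaluates the five high paths for one eligible person and returns every
#' satisfied path in the fixed precedence order GROUP_A, GROUP_B,
#' PIT_DEF_3, GH_RX, HRT_3. Precedence affects only which reason is
#' reported by [classify_person()], never the tier. Prescription paths
#' whose predicate held but were vetoed by an exclusion-list diagnosis are
#' reported in `excluded_paths`.
#'
#' @inheritParams classify_person
#' @return List with `reasons` (character, possibly empty) and
#'   `excluded_paths` (character).
#' @export
high_criteria <- function(person, events, cfg) {
  person <- one_person_tbl(person)
  p <- person_predicates(person, events, cfg)
  reasons <- c(if (p$group_a) "GROUP_A",
               if (p$group_b) "GROUP_B",
               if (p$pitdef3) "PIT_DEF_3",
               if (p$ghrx && !p$exclusion) "GH_RX",
               if (p$hrt3 && !p$exclusion) "HRT_3")
  list(reasons = as.character(reasons %||% character(0)),
       excluded_paths = c(if (p$ghrx && p$exclusion) "GH_RX",
                          if (p$hrt3 && p$exclusion) "HRT_3") %||% character(0))
}

#' Satisfied moderate-likelihood criteria, in order
#'
#' Evaluates the two moderate paths (at least one GHD-specific diagnostic
#' test; tests on at least `min_deficiency_axes` distinct non-GH axes) for
#' a person who satisfied no high path. Test results themselves are unknown
#' in claims data; only their occurrence is used.
#'
#' @inheritParams classify_person
#' @return List with `reasons` (character, possibly empty).
#' @export
moderate_criteria <- function(person, events, cfg) {
  person <- one_person_tbl(person)
  p <- person_predicates(person, events, cfg)
  list(reasons = as.character(c(if (p$test_ghd) "TEST_GHD",
                                if (p$test_axis3) "TEST_AXIS_3") %||%
                                character(0)))
}
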