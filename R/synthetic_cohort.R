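# Seeded synthetic-claims generator.
#
# Tier membership is planted constructively: archetype counts are fixed by
# largest-remainder apportionment of the weights, and each person receives
# the exact defining events of their archetype, so a correct classifier
# recovers the truth file with zero error. Comorbidity diagnoses, by
# contrast, are sampled (Bernoulli at the configured prevalence, placed in
# the last observation year) because they feed statistical, not logical,
# checks. Randomness is reproducible: one per-person stream, seeded from a
# master stream derived from the run seed, so identical (config, seed)
# yields byte-identical output files.

archetype_targets <- function() {
  c(A_CONDITION = "high", PANHYPOPIT = "high", GH_TREATED_ADULT = "high",
    GH_TREATED_EXCLUDED = "low", TEST_ONLY_MODERATE = "moderate",
    HEALTHY_LOW = "low")
}

# Age-band sampling weights per tier, shaped like a large private-insurance
# cohort: high/moderate tiers skew older (peaking around 60-70 and 50-60),
# the low tier skews young; essentially nobody over 80.
tier_age_probs <- function() {
  norm <- function(x) x / sum(x)
  list(high = norm(c(0.06, 0.05, 0.08, 0.12, 0.13, 0.03, 0.001)),
       moderate = norm(c(0.63, 0.97, 1.45, 1.79, 1.03, 0.12, 0.001)),
       low = norm(c(23.43, 18.25, 16.72, 17.29, 13.99, 3.84, 0.03)))
}

# Per-tier comorbidity prevalence defaults (fractions), in the layout of a
# claims comorbidity table: substantial burden in the high tier, an
# intermediate moderate tier, and a younger, healthier low tier.
tier_prevalence <- function() {
  list(
    high = c(hypertensive_disorder = 0.314, hyperlipidemia = 0.326,
             heart_disease = 0.156, diabetes_or_impaired_glucose = 0.141,
             osteoarthritis = 0.171, malignant_neoplastic_disease = 0.239,
             malignant_tumor_of_breast = 0.088, depressive_disorder = 0.139,
             visual_system_disorder = 0.239, acute_respiratory_disease = 0.302,
             cerebrovascular_disease = 0.037),
    moderate = c(hypertensive_disorder = 0.259, hyperlipidemia = 0.288,
                 heart_disease = 0.107, diabetes_or_impaired_glucose = 0.118,
                 osteoarthritis = 0.149, malignant_neoplastic_disease = 0.057,
                 malignant_tumor_of_breast = 0.013, depressive_disorder = 0.133,
                 visual_system_disorder = 0.190, acute_respiratory_disease = 0.296,
                 cerebrovascular_disease = 0.018),
    low = c(hypertensive_disorder = 0.146, hyperlipidemia = 0.146,
            heart_disease = 0.054, diabetes_or_impaired_glucose = 0.057,
            osteoarthritis = 0.062, malignant_neoplastic_disease = 0.025,
            malignant_tumor_of_breast = 0.005, depressive_disorder = 0.056,
            visual_system_disorder = 0.110, acute_respiratory_disease = 0.201,
            cerebrovascular_disease = 0.008))
}

#' Default generator configuration
#'
#' The defaults emulate the study conditions this package models: tier
#' structure 0.5% high / 6% moderate / 93.5% low, a female excess in the
#' high and moderate tiers, an older age skew in those tiers, per-tier
#' comorbidity prevalences at claims-typical levels, and a small share
#' (2.2%) of the moderate-tier archetype planted with a GHD-specific test
#' rather than three axis tests.
#'
#' @param n Number of persons.
#' @param weights Named archetype weights summing to 1; any subset of
#'   `A_CONDITION`, `PANHYPOPIT`, `GH_TREATED_ADULT`, `GH_TREATED_EXCLUDED`,
#'   `TEST_ONLY_MODERATE`, `HEALTHY_LOW`.
#' @param registry Code-list registry supplying the planted codes.
#' @param window A [cohort_window()].
#' @return A generator-config list.
#' @export
default_generator_config <- function(n = 1000L,
                                     weights = c(A_CONDITION = 0.003,
                                                 PANHYPOPIT = 0.001,
                                                 GH_TREATED_ADULT = 0.001,
                                                 GH_TREATED_EXCLUDED = 0.005,
                                                 TEST_ONLY_MODERATE = 0.060,
                                                 HEALTHY_LOW = 0.930),
                                     registry = default_codelists(),
                                     window = cohort_window()) {
  list(n = as.integer(n), weights = weights, registry = registry,
       window = window,
       female_share = c(A_CONDITION = 0.593, PANHYPOPIT = 0.593,
                        GH_TREATED_ADULT = 0.593, GH_TREATED_EXCLUDED = 0.504,
                        TEST_ONLY_MODERATE = 0.716, HEALTHY_LOW = 0.504),
       age_band_probs = tier_age_probs(),
       prevalence = tier_prevalence(),
       moderate_ghd_test_share = 0.022)
}

largest_remainder <- function(weights, n) {
  exact <- weights * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Resolve the concrete codes planted for each branch from the registry;
# prefix patterns are themselves valid instances of their own class.
planting_codes <- function(registry) {
  reg <- registry$lists
  first_entry <- function(cl) cl$entries[1, , drop = FALSE]
  axis_firsts <- function(cl, axes) {
    en <- cl$entries[!is.na(cl$entries$axis), , drop = FALSE]
    do.call(rbind, lapply(axes, function(a) en[en$axis == a, ][1, , drop = FALSE]))
  }
  list(group_a = first_entry(reg$GROUP_A_CONDITIONS),
       pit_axes = axis_firsts(reg$PITUITARY_DEFICIENCY_DX,
                              c("thyroid", "adrenal", "gonadal")),
       gh_rx = first_entry(reg$GH_THERAPY_RX),
       exclusion = first_entry(reg$EXCLUSION_1),
       hrt = axis_firsts(reg$HORMONE_REPLACEMENT_RX,
                         c("gonadal", "adrenal", "thyroid")),
       ghd_test = first_entry(reg$GHD_TEST_CPT),
       axis_tests = axis_firsts(reg$AXIS_TEST_CPT,
                                c("thyroid", "adrenal", "gonadal")),
       comorb = lapply(registry$comorbidities,
                       function(cl) cl$entries[1, , drop = FALSE]))
}

band_age_range <- function(band) {
  lo <- c(19L, 31L, 41L, 51L, 61L, 71L, 81L)
  hi <- c(30L, 40L, 50L, 60L, 70L, 80L, 95L)
  c(lo[band], hi[band])
}

#' Generate a synthetic claims cohort with planted archetypes
#'
#' @param config Generator config from [default_generator_config()].
#' @param seed Integer seed; identical (config, seed) pairs reproduce the
#'   cohort exactly.
#' @return List of tibbles: `persons`, `events`, `truth` (`person_id`,
#'   `intended_tier`, `archetype`).
#' @export
generate_cohort <- function(config, seed) {
  w <- config$weights
  bad <- setdiff(names(w), names(archetype_targets()))
  if (length(bad)) abort_config(paste0("unknown archetype: ", bad[1]))
  if (abs(sum(w) - 1) > 1e-9) {
    abort_config(paste0("archetype weights sum to ", format(sum(w)), ", not 1"))
  }
  n <- config$n
  counts <- largest_remainder(w, n)
  arch <- rep(names(w), counts)
  target <- unname(archetype_targets()[arch])
  within_arch <- sequence(counts)  # position inside each archetype block

  pc <- planting_codes(config$registry)
  comorb_names <- names(pc$comorb)
  ncom <- length(comorb_names)
  com_sys <- vapply(pc$comorb, function(e) e$system, character(1))
  com_code <- vapply(pc$comorb, function(e) e$pattern, character(1))

  window <- config$window
  index_num <- as.numeric(window$index_date)
  index_year <- event_year(window$index_date)
  n_ghd_test <- floor(config$moderate_ghd_test_share *
                        sum(counts[names(w) == "TEST_ONLY_MODERATE"]))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  pseeds <- sample.int(2147483646L, n, replace = TRUE)

  sex <- character(n); birth <- integer(n); estart <- numeric(n)
  max_ev <- n * (4L + ncom)
  ev_pid <- integer(max_ev); ev_date <- numeric(max_ev)
  ev_sys <- character(max_ev); ev_code <- character(max_ev)
  ev_kind <- character(max_ev)
  cur <- 0L

  push <- function(i, sys, code, kind, date) {
    cur <<- cur + 1L
    ev_pid[cur] <<- i; ev_date[cur] <<- date
    ev_sys[cur] <<- sys; ev_code[cur] <<- code; ev_kind[cur] <<- kind
  }

  for (i in seq_len(n)) {
    set.seed(pseeds[i])
    a <- arch[i]; t <- target[i]
    sex[i] <- if (runif(1) < config$female_share[[a]]) "female" else "male"
    band <- sample.int(7L, 1L, prob = config$age_band_probs[[t]])
    rng <- band_age_range(band)
    age <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    birth[i] <- index_year - age
    estart[i] <- index_num - sample(365:2555, 1L) + 1

    def <- switch(a,
      A_CONDITION = pc$group_a,
      PANHYPOPIT = pc$pit_axes,
      GH_TREATED_ADULT = pc$gh_rx,
      GH_TREATED_EXCLUDED = rbind(pc$gh_rx, pc$exclusion),
      TEST_ONLY_MODERATE = if (within_arch[i] <= n_ghd_test) pc$ghd_test else pc$axis_tests,
      HEALTHY_LOW = NULL)
    if (!is.null(def)) {
      offs <- sample(0:179, nrow(def), replace = TRUE)
      for (j in seq_len(nrow(def))) {
        push(i, def$system[j], def$pattern[j],
             kind_for_system(def$system[j]), index_num - offs[j])
      }
    }
    if (ncom > 0) {
      u <- runif(ncom)
      offs <- sample(0:364, ncom, replace = TRUE)
      prev <- config$prevalence[[t]][comorb_names]
      hit <- which(u < prev)
      for (j in hit) {
        push(i, com_sys[j], com_code[j], "diagnosis", index_num - offs[j])
      }
    }
  }

  pid <- sprintf("S%06d", seq_len(n))
  persons <- tibble(person_id = pid, sex = sex, birth_year = birth,
                    enroll_start = as.Date(estart, origin = "1970-01-01"),
                    enroll_end = rep(window$index_date, n),
                    death_date = as.Date(rep(NA_integer_, n),
                                         origin = "1970-01-01"))
  idx <- seq_len(cur)
  events <- tibble(person_id = pid[ev_pid[idx]],
                   service_date = as.Date(ev_date[idx], origin = "1970-01-01"),
                   system = ev_sys[idx], code = ev_code[idx],
                   kind = ev_kind[idx])
  truth <- tibble(person_id = pid, intended_tier = target, archetype = arch)
  list(persons = persons, events = events, truth = truth)
}

#' Write a generated cohort as canonical delimited files
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(persons = file.path(dir, "persons.csv"),
             events = file.path(dir, "events.csv"),
             truth = file.path(dir, "truth.csv"))
  write_persons(cohort$persons, paths["persons"])
  write_events(cohort$events, paths["events"])
  readr::write_csv(cohort$truth, paths["truth"], progress = FALSE)
  paths
}

classifier_predicates <- function() {
  c("groupA", "groupB", "pitdef3", "ghrx", "hrt3", "exclusion",
    "testGHD", "testAxis3")
}

#' Build the smallest person/event set realizing a predicate combination
#'
#' Fixture factory for exhaustive truth-table testing: given any subset of
#' the eight classifier predicates, returns an eligible adult carrying
#' exactly the events that make those predicates (and no others) true under
#' the supplied code lists.
#'
#' @param predicates Character vector, subset of `groupA`, `groupB`,
#'   `pitdef3`, `ghrx`, `hrt3`, `exclusion`, `testGHD`, `testAxis3`.
#' @param registry Code-list registry.
#' @param window A [cohort_window()].
#' @return List with `person` (one-row tibble) and `events` (tibble).
#' @export
make_minimal_person <- function(predicates, registry = default_codelists(),
                                window = cohort_window()) {
  bad <- setdiff(predicates, classifier_predicates())
  if (length(bad)) {
    abort_config(paste0("unknown classifier predicate: ", bad[1]))
  }
  person <- tibble(person_id = "MIN1", sex = "unknown", birth_year = 1977L,
                   enroll_start = window$index_date - 729L,
                   enroll_end = window$index_date,
                   death_date = as.Date(NA_integer_, origin = "1970-01-01"))
  pc <- planting_codes(registry)
  d <- window$index_date - 30L
  rows <- list()
  add <- function(entries, date = d) {
    tibble(person_id = "MIN1", service_date = date,
           system = entries$system, code = entries$pattern,
           kind = kind_for_system(entries$system))
  }
  if ("groupA" %in% predicates) rows <- c(rows, list(add(pc$group_a)))
  if ("groupB" %in% predicates) {
    gb <- registry$lists$GROUP_B_CONDITIONS$entries[1, , drop = FALSE]
    rows <- c(rows, list(add(gb)))
  }
  if ("pitdef3" %in% predicates) rows <- c(rows, list(add(pc$pit_axes)))
  if ("ghrx" %in% predicates) rows <- c(rows, list(add(pc$gh_rx)))
  if ("hrt3" %in% predicates) rows <- c(rows, list(add(pc$hrt)))
  if ("exclusion" %in% predicates) rows <- c(rows, list(add(pc$exclusion)))
  if ("testGHD" %in% predicates) rows <- c(rows, list(add(pc$ghd_test)))
  if ("testAxis3" %in% predicates) rows <- c(rows, list(add(pc$axis_tests)))
  events <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(person_id = character(0),
           service_date = as.Date(character(0)),
           system = character(0), code = character(0), kind = character(0))
  list(person = person, events = events)
}

#' Random fuzz cohort drawing events from every code list
#'
#' Stress generator for property checks: persons with arbitrary ages
#' (including minors and pre-index deaths, to exercise eligibility) and a
#' Poisson number of events drawn uniformly from the pooled entries of all
#' algorithm and comorbidity lists, with kinds implied by the coding
#' system. Unlike [generate_cohort()], nothing is planted and no truth file
#' exists.
#'
#' @param n Number of persons.
#' @param registry Code-list registry.
#' @param seed Integer seed.
#' @param window A [cohort_window()].
#' @param mean_events Mean events per person.
#' @return List of tibbles `persons`, `events`.
#' @export
random_claims_cohort <- function(n, registry = default_codelists(), seed = 1L,
                                 window = cohort_window(), mean_events = 4) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed %% 2147483647))

  pool <- dplyr::bind_rows(lapply(c(registry$lists, registry$comorbidities),
                                  function(cl) cl$entries[, c("system", "pattern")]))
  pool <- dplyr::distinct(pool)

  pid <- sprintf("F%05d", seq_len(n))
  index_num <- as.numeric(window$index_date)
  estart <- index_num - sample(60:3650, n, replace = TRUE)
  eend <- index_num - sample(c(rep(0L, 8), 100L, 400L), n, replace = TRUE)
  death_off <- ifelse(runif(n) < 0.05, sample(-200:400, n, replace = TRUE), NA)
  persons <- tibble(person_id = pid,
                    sex = sample(c("female", "male"), n, replace = TRUE),
                    birth_year = sample(1930:2004, n, replace = TRUE),
                    enroll_start = as.Date(estart, origin = "1970-01-01"),
                    enroll_end = as.Date(eend, origin = "1970-01-01"),
                    death_date = as.Date(index_num - death_off,
                                         origin = "1970-01-01"))
  m <- stats::rpois(n, mean_events)
  tot <- sum(m)
  who <- rep(seq_len(n), m)
  k <- sample.int(nrow(pool), tot, replace = TRUE)
  suffix <- ifelse(runif(tot) < 0.5, "", "1")
  events <- tibble(person_id = pid[who],
                   service_date = as.Date(index_num -
                                            sample(0:2000, tot, replace = TRUE),
                                          origin = "1970-01-01"),
                   system = pool$system[k],
                   code = paste0(pool$pattern[k], suffix),
                   kind = kind_for_system(pool$system[k]))
  list(persons = persons, events = events)
}
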