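# Shared fixtures: memoized default registry/config, tiny table builders,
# and an independent truth-table oracle for the rule engine.

.fixture_env <- new.env(parent = emptyenv())

test_registry <- function() {
  if (is.null(.fixture_env$registry)) {
    .fixture_env$registry <- default_codelists()
  }
  .fixture_env$registry
}

test_config <- function(...) algorithm_config(test_registry(), ...)

mk_person <- function(id = "P1", sex = "female", birth = 1980L,
                      start = "2016-01-01", end = "2017-12-31", death = NA) {
  tibble::tibble(person_id = id, sex = sex, birth_year = as.integer(birth),
                 enroll_start = as.Date(start), enroll_end = as.Date(end),
                 death_date = as.Date(death))
}

mk_events <- function(id, date, system, code, kind = NULL) {
  if (is.null(kind)) {
    kind <- c(ICD9CM = "diagnosis", ICD10CM = "diagnosis",
              CPT = "procedure", ATC = "pharmacy")[system]
  }
  tibble::tibble(person_id = id, service_date = as.Date(date),
                 system = system, code = code, kind = unname(kind))
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Independent oracle: a literal transcription of the flowchart as nested
# if-rules over the eight branch predicates, written without reference to
# the engine's code path.
oracle_classify <- function(p, bypass = TRUE) {
  if (p[["groupA"]]) return(c(tier = "high", reason = "GROUP_A"))
  if (p[["groupB"]]) return(c(tier = "high", reason = "GROUP_B"))
  if (p[["pitdef3"]]) return(c(tier = "high", reason = "PIT_DEF_3"))
  if (p[["ghrx"]] && !p[["exclusion"]]) return(c(tier = "high", reason = "GH_RX"))
  if (p[["hrt3"]] && !p[["exclusion"]]) return(c(tier = "high", reason = "HRT_3"))
  if (p[["ghrx"]] && p[["exclusion"]] && bypass) {
    return(c(tier = "low", reason = "NONE"))
  }
  if (p[["testGHD"]]) return(c(tier = "moderate", reason = "TEST_GHD"))
  if (p[["testAxis3"]]) return(c(tier = "moderate", reason = "TEST_AXIS_3"))
  c(tier = "low", reason = "NONE")
}

predicate_names <- function() {
  c("groupA", "groupB", "pitdef3", "ghrx", "hrt3", "exclusion",
    "testGHD", "testAxis3")
}

# all 2^8 predicate combinations as a logical matrix
predicate_grid <- function() {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  names(g) <- predicate_names()
  g
}
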