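# Persons and coded events: delimited-file I/O with row-level rejection
# reporting, cohort-window eligibility, and observation bounds.
#
# Conventions: dates are whole days, all intervals closed [start, end];
# enrollment (not claim dates) is the observation denominator; age is
# year-granular (index year minus birth year), matching what claims
# extracts typically expose.

#' Cohort window: index date, minimum enrollment, adult age
#'
#' Defaults follow the study design this package implements: index date
#' 2017-12-31, at least 183 days (six months) of enrollment, adulthood at
#' 18 years.
#'
#' @param index_date Date at which age, vital status and membership are
#'   evaluated.
#' @param min_enrollment_days Minimum enrollment overlap, in days (> 0).
#' @param adult_age Adult age threshold in years (>= 0).
#' @return A `cohort_window` list.
#' @export
cohort_window <- function(index_date = as.Date("2017-12-31"),
                          min_enrollment_days = 183L,
                          adult_age = 18L) {
  index_date <- as.Date(index_date)
  if (min_enrollment_days <= 0) abort_config("min_enrollment_days must be > 0")
  if (adult_age < 0) abort_config("adult_age must be >= 0")
  structure(list(index_date = index_date,
                 min_enrollment_days = as.integer(min_enrollment_days),
                 adult_age = as.integer(adult_age)),
            class = "cohort_window")
}

#' Default table dialect for persons/events files
#'
#' A dialect names the delimiter, maps file headers to canonical column
#' names, maps raw sex codes to `female`/`male`/`unknown`, and fixes the
#' date format. No sniffing is performed: what the dialect declares is what
#' is parsed.
#'
#' @param delim Field delimiter.
#' @param columns Named character vector mapping canonical column names to
#'   the file's header names.
#' @param sex_map Named character vector mapping raw sex codes (names) to
#'   canonical values.
#' @param date_format `strptime`-style date format.
#' @return A dialect list.
#' @examples
#' # a file coding sex as 1/2:
#' default_dialect(sex_map = c(`1` = "male", `2` = "female"))
#' @export
default_dialect <- function(delim = ",",
                            columns = NULL,
                            sex_map = c(female = "female", male = "male",
                                        unknown = "unknown"),
                            date_format = "%Y-%m-%d") {
  base_cols <- c(person_id = "person_id", sex = "sex", birth_year = "birth_year",
                 enroll_start = "enroll_start", enroll_end = "enroll_end",
                 death_date = "death_date", service_date = "service_date",
                 system = "system", code = "code", kind = "kind")
  if (!is.null(columns)) base_cols[names(columns)] <- columns
  bad <- setdiff(unname(sex_map), c("female", "male", "unknown"))
  if (length(bad)) abort_config(paste0("sex_map targets unknown value: ", bad[1]))
  list(delim = delim, columns = base_cols, sex_map = sex_map,
       date_format = date_format)
}

read_raw_table <- function(path, dialect, needed, optional = character(0)) {
  if (!file.exists(path)) abort_config(paste0("input file not found: ", path))
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), trim_ws = TRUE,
                           progress = FALSE, show_col_types = FALSE)
  have <- names(raw)
  for (canon in needed) {
    if (!dialect$columns[[canon]] %in% have) {
      abort_config(paste0("missing mandatory column '", dialect$columns[[canon]],
                          "' (", canon, ") in ", path))
    }
  }
  out <- lapply(c(needed, optional), function(canon) {
    col <- dialect$columns[[canon]]
    if (col %in% have) raw[[col]] else rep("", nrow(raw))
  })
  names(out) <- c(needed, optional)
  as_tibble(out)
}

parse_dates <- function(x, fmt) {
  d <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  nz <- nzchar(x)
  d[nz] <- as.Date(x[nz], format = fmt)
  d
}

# first-failure bookkeeping for rejection reasons
flag_reason <- function(current, cond, reason) {
  ifelse(is.na(current) & cond, reason, current)
}

#' Read a persons table with row-level validation
#'
#' Every input row either becomes a person or appears in the rejection
#' report with a reason; rows are never silently dropped, and input order
#' is preserved. An empty `death_date` field means the person is alive.
#'
#' @param path Delimited text file.
#' @param dialect Table dialect from [default_dialect()].
#' @return List with `persons` (tibble: `person_id`, `sex`, `birth_year`,
#'   `enroll_start`, `enroll_end`, `death_date`), `rejections` (tibble:
#'   `row`, `reason`), and `n_input`.
#' @export
read_persons <- function(path, dialect = default_dialect()) {
  raw <- read_raw_table(path, dialect,
                        needed = c("person_id", "sex", "birth_year",
                                   "enroll_start", "enroll_end"),
                        optional = "death_date")
  n <- nrow(raw)
  reason <- rep(NA_character_, n)

  sex <- unname(dialect$sex_map[raw$sex])
  reason <- flag_reason(reason, is.na(sex), "unrecognized sex code")

  birth_year <- suppressWarnings(as.integer(raw$birth_year))
  reason <- flag_reason(reason, is.na(birth_year), "unparseable birth_year")

  es <- parse_dates(raw$enroll_start, dialect$date_format)
  reason <- flag_reason(reason, is.na(es), "unparseable date (enroll_start)")
  ee <- parse_dates(raw$enroll_end, dialect$date_format)
  reason <- flag_reason(reason, is.na(ee), "unparseable date (enroll_end)")
  dd <- parse_dates(raw$death_date, dialect$date_format)
  reason <- flag_reason(reason, nzchar(raw$death_date) & is.na(dd),
                        "unparseable date (death_date)")

  reason <- flag_reason(reason, !is.na(es) & !is.na(ee) & ee < es,
                        "inverted enrollment")
  birth_jan1 <- as.Date(paste0(birth_year, "-01-01"))
  reason <- flag_reason(reason, !is.na(dd) & !is.na(birth_jan1) & dd < birth_jan1,
                        "death precedes birth")
  reason <- flag_reason(reason, !nzchar(raw$person_id), "empty person_id")
  reason <- flag_reason(reason, duplicated(raw$person_id), "duplicate person_id")

  keep <- is.na(reason)
  persons <- tibble(person_id = raw$person_id[keep], sex = sex[keep],
                    birth_year = birth_year[keep],
                    enroll_start = es[keep], enroll_end = ee[keep],
                    death_date = dd[keep])
  list(persons = persons,
       rejections = tibble(row = which(!keep), reason = reason[!keep]),
       n_input = n)
}

#' Read a coded-events table with row-level validation
#'
#' Codes are normalized via [normalize_code()] before storage, and the
#' kind/system pairing is enforced (diagnoses are ICD, procedures CPT,
#' pharmacy ATC); violations become rejection rows, never silent drops.
#'
#' @inheritParams read_persons
#' @return List with `events` (tibble: `person_id`, `service_date`,
#'   `system`, `code`, `kind`), `rejections`, and `n_input`.
#' @export
read_events <- function(path, dialect = default_dialect()) {
  raw <- read_raw_table(path, dialect,
                        needed = c("person_id", "service_date", "system",
                                   "code", "kind"))
  n <- nrow(raw)
  reason <- rep(NA_character_, n)

  reason <- flag_reason(reason, !raw$system %in% code_systems(), "unknown system")
  reason <- flag_reason(reason, !raw$kind %in% event_kinds(), "unknown kind")
  ok_sys <- raw$system %in% code_systems()
  mismatch <- ok_sys & raw$kind %in% event_kinds() &
    raw$kind != kind_for_system(ifelse(ok_sys, raw$system, "CPT"))
  reason <- flag_reason(reason, mismatch, "kind/system mismatch")

  sd <- parse_dates(raw$service_date, dialect$date_format)
  reason <- flag_reason(reason, is.na(sd), "unparseable date (service_date)")

  code <- rep(NA_character_, n)
  code[ok_sys] <- norm_code_impl(raw$system[ok_sys], raw$code[ok_sys])
  reason <- flag_reason(reason, ok_sys & !nzchar(code), "empty code")
  reason <- flag_reason(reason, !nzchar(raw$person_id), "empty person_id")

  keep <- is.na(reason)
  events <- tibble(person_id = raw$person_id[keep], service_date = sd[keep],
                   system = raw$system[keep], code = code[keep],
                   kind = raw$kind[keep])
  list(events = events,
       rejections = tibble(row = which(!keep), reason = reason[!keep]),
       n_input = n)
}

fmt_date_col <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))

#' Write persons/events/rejections in canonical form
#'
#' Canonical form is comma-delimited, literal column names, ISO-8601 dates,
#' empty field for a missing death date. Reading a canonical file and
#' writing it again reproduces it byte for byte.
#'
#' @param persons,events,rejections Tibbles as produced by the readers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_persons <- function(persons, path) {
  out <- tibble(person_id = persons$person_id, sex = persons$sex,
                birth_year = persons$birth_year,
                enroll_start = fmt_date_col(persons$enroll_start),
                enroll_end = fmt_date_col(persons$enroll_end),
                death_date = fmt_date_col(persons$death_date))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_persons
#' @export
write_events <- function(events, path) {
  out <- tibble(person_id = events$person_id,
                service_date = fmt_date_col(events$service_date),
                system = events$system, code = events$code, kind = events$kind)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_persons
#' @export
write_rejections <- function(rejections, path) {
  readr::write_csv(rejections, path, progress = FALSE)
  invisible(path)
}

#' Cohort eligibility at the index date
#'
#' A person is eligible when (index year - birth year) meets the adult age,
#' the enrollment span overlapping the study period (clamped at the index
#' date, closed interval) covers at least `min_enrollment_days`, and the
#' person is alive at the index date. The reported reason is the first
#' failed criterion, in that order.
#'
#' @param persons Persons tibble.
#' @param window A [cohort_window()].
#' @return Tibble `person_id`, `eligible`, `reason` (`NA` when eligible).
#' @export
eligibility <- function(persons, window = cohort_window()) {
  age <- event_year(window$index_date) - persons$birth_year
  days <- as.integer(pmin(persons$enroll_end, window$index_date) -
                       persons$enroll_start) + 1L
  dead <- !is.na(persons$death_date) & persons$death_date <= window$index_date
  reason <- rep(NA_character_, nrow(persons))
  reason <- flag_reason(reason, age < window$adult_age, "age")
  reason <- flag_reason(reason, days < window$min_enrollment_days, "enrollment")
  reason <- flag_reason(reason, dead, "deceased")
  tibble(person_id = persons$person_id, eligible = is.na(reason),
         reason = reason)
}

#' @rdname eligibility
#' @param person A one-row persons tibble (or list coercible to one).
#' @return `eligible()` returns a list with `eligible` and `reason`.
#' @export
eligible <- function(person, window = cohort_window()) {
  person <- as_tibble(person)
  r <- eligibility(person[1, , drop = FALSE], window)
  list(eligible = r$eligible[[1]], reason = r$reason[[1]])
}

#' Observation bounds per person
#'
#' The observed interval is the enrollment span clamped at the index date:
#' `[enroll_start, min(enroll_end, index_date)]`. Claim dates play no role;
#' enrollment is the denominator period. This anchors the last-year
#' comorbidity window.
#'
#' @inheritParams eligibility
#' @param events Unused; accepted so callers can pass the person's claims
#'   alongside (bounds are defined from enrollment alone, even with zero
#'   events).
#' @return Tibble `person_id`, `first_date`, `last_date`.
#' @export
observation_bounds <- function(persons, events = NULL, window = cohort_window()) {
  tibble(person_id = persons$person_id,
         first_date = persons$enroll_start,
         last_date = pmin(persons$enroll_end, window$index_date))
}
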