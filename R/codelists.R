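# Code-list registry: normalization, deterministic matching, axis counting.
#
# A code list is a named set of (system, pattern, match_mode) entries,
# optionally labelled with a pituitary axis (for deficiency/replacement/test
# counting) or a free-text sublabel (for per-test reporting). Matching is
# pure string work — exact equality or positional prefix — so results are
# reproducible across runs and sites.

mandatory_lists <- function() {
  c("GROUP_A_CONDITIONS", "GROUP_B_CONDITIONS", "PITUITARY_DEFICIENCY_DX",
    "EXCLUSION_1", "EXCLUSION_2", "GH_THERAPY_RX", "HORMONE_REPLACEMENT_RX",
    "GHD_TEST_CPT", "AXIS_TEST_CPT")
}

# One-pass normalization rule; exported wrapper errors on empty results.
norm_code_impl <- function(system, raw) {
  sys <- rep_len(as.character(system), length(raw))
  out <- toupper(trimws(as.character(raw)))
  icd <- sys %in% c("ICD9CM", "ICD10CM")
  out[icd] <- gsub("[.[:space:]]", "", out[icd])
  out
}

#' Normalize a claim code for matching
#'
#' Codes are uppercased and trimmed; ICD-9-CM/ICD-10-CM codes additionally
#' have dots and internal whitespace removed (so `"e23.0"` becomes `"E230"`).
#' CPT codes are kept as their 5-character strings and ATC codes are left
#' structurally unchanged. The rule is idempotent: normalizing twice equals
#' normalizing once.
#'
#' @param system Coding system, one of `"ICD9CM"`, `"ICD10CM"`, `"CPT"`,
#'   `"ATC"` (recycled against `raw`).
#' @param raw Character vector of raw codes.
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code("ICD10CM", "e23.0")
#' normalize_code("ATC", "h01ac01")
#' @export
normalize_code <- function(system, raw) {
  if (!all(system %in% code_systems())) {
    abort_config(paste0("unknown coding system: ",
                        paste(setdiff(system, code_systems()), collapse = ", ")))
  }
  out <- norm_code_impl(system, raw)
  if (any(!nzchar(out))) {
    abort_data("code is empty after normalization")
  }
  out
}

new_code_list <- function(name, entries, version = NULL) {
  entries <- as_tibble(entries)
  if (nrow(entries) == 0) {
    abort_config(paste0("code list ", name, " has no entries"))
  }
  for (col in c("system", "pattern", "match_mode")) {
    if (!col %in% names(entries)) {
      abort_config(paste0("code list ", name, " entries lack column '", col, "'"))
    }
  }
  if (!"axis" %in% names(entries)) entries$axis <- NA_character_
  if (!"label" %in% names(entries)) entries$label <- NA_character_
  bad_sys <- setdiff(unique(entries$system), code_systems())
  if (length(bad_sys)) {
    abort_config(paste0("code list ", name, ": unknown system ", bad_sys[1]))
  }
  if (!all(entries$match_mode %in% c("exact", "prefix"))) {
    abort_config(paste0("code list ", name, ": match_mode must be exact or prefix"))
  }
  entries$pattern <- norm_code_impl(entries$system, entries$pattern)
  if (any(!nzchar(entries$pattern))) {
    abort_config(paste0("code list ", name, ": empty pattern"))
  }
  wild <- entries$match_mode == "prefix" & grepl("[*?%]", entries$pattern)
  if (any(wild)) {
    abort_config(paste0("code list ", name, ": prefix pattern contains wildcard: ",
                        entries$pattern[which(wild)[1]]))
  }
  bad_axis <- !is.na(entries$axis) & !entries$axis %in% pituitary_axes()
  if (any(bad_axis)) {
    abort_config(paste0("code list ", name, ": unknown axis label ",
                        entries$axis[which(bad_axis)[1]]))
  }
  key <- paste(entries$system, entries$pattern, entries$match_mode)
  if (anyDuplicated(key)) {
    abort_config(paste0("code list ", name, ": duplicate entry (",
                        key[duplicated(key)][1], ")"))
  }
  structure(list(name = name, entries = entries, version = version),
            class = "aghd_codelist")
}

#' Match claim events against a code list
#'
#' An event matches when some entry shares its coding system and either
#' equals the event's normalized code (`exact`) or is a leading substring of
#' it (`prefix`). Events from a different coding system never match,
#' whatever the pattern.
#'
#' @param codelist A code list from [load_codelists()].
#' @param events Tibble of coded events (columns `system`, `code`; codes
#'   already normalized as by [normalize_code()]).
#' @return Logical vector, one element per event row.
#' @export
code_matches <- function(codelist, events) {
  stopifnot(inherits(codelist, "aghd_codelist"))
  n <- nrow(events)
  out <- rep(FALSE, n)
  if (n == 0) return(out)
  en <- codelist$entries
  for (i in seq_len(nrow(en))) {
    sel <- events$system == en$system[i]
    if (en$match_mode[i] == "exact") {
      sel <- sel & events$code == en$pattern[i]
    } else {
      sel <- sel & startsWith(events$code, en$pattern[i])
    }
    out <- out | sel
  }
  out
}

# (person_id, axis) pairs for events matching axis-labelled entries;
# the gh axis is dropped here, implementing the besides-GH rule once.
axis_hits <- function(events, codelist) {
  en <- codelist$entries[!is.na(codelist$entries$axis), , drop = FALSE]
  en <- en[en$axis != "gh", , drop = FALSE]
  pid <- character(0)
  ax <- character(0)
  for (i in seq_len(nrow(en))) {
    sel <- events$system == en$system[i]
    if (en$match_mode[i] == "exact") {
      sel <- sel & events$code == en$pattern[i]
    } else {
      sel <- sel & startsWith(events$code, en$pattern[i])
    }
    if (any(sel)) {
      pid <- c(pid, events$person_id[sel])
      ax <- c(ax, rep(en$axis[i], sum(sel)))
    }
  }
  dplyr::distinct(tibble(person_id = pid, axis = ax))
}

#' Distinct pituitary axes touched by a set of events
#'
#' Counts how many distinct pituitary axes are evidenced by at least one
#' matching event. Repeated claims on one axis count once, and the GH axis
#' itself is never counted (the algorithm's thresholds are "besides GH").
#'
#' @inheritParams code_matches
#' @return Sorted character vector of axis labels (possibly empty).
#' @export
distinct_axes <- function(events, codelist) {
  stopifnot(inherits(codelist, "aghd_codelist"))
  if (all(is.na(codelist$entries$axis))) {
    abort_config(paste0("code list ", codelist$name,
                        " carries no axis labels; cannot count axes"))
  }
  sort(unique(axis_hits(events, codelist)$axis))
}

parse_entry_block <- function(name, raw) {
  if (is.null(raw) || length(raw) == 0) {
    abort_config(paste0("code list ", name, " has no entries"))
  }
  rows <- lapply(raw, function(e) {
    tibble(system = e$system %||% NA_character_,
           pattern = as.character(e$pattern %||% ""),
           match_mode = e$match_mode %||% default_match_mode(e$system %||% ""),
           axis = e$axis %||% NA_character_,
           label = e$label %||% NA_character_)
  })
  dplyr::bind_rows(rows)
}

# Terminology-appropriate defaults: hierarchical systems (ICD, ATC) match on
# prefixes, CPT codes are atomic and match exactly.
default_match_mode <- function(system) {
  if (identical(system, "CPT")) "exact" else "prefix"
}

#' Load a code-list registry from a YAML configuration file
#'
#' The file carries a top-level `version` string, a `lists` block with the
#' nine algorithm lists (`GROUP_A_CONDITIONS`, `GROUP_B_CONDITIONS`,
#' `PITUITARY_DEFICIENCY_DX`, `EXCLUSION_1`, `EXCLUSION_2`, `GH_THERAPY_RX`,
#' `HORMONE_REPLACEMENT_RX`, `GHD_TEST_CPT`, `AXIS_TEST_CPT`), and a
#' `comorbidities` block with one diagnosis list per reported comorbidity.
#' Every entry is `system`, `pattern`, optional `match_mode` (defaulting to
#' `prefix` for ICD/ATC and `exact` for CPT), optional `axis`, optional
#' `label`. The registry's version string is stamped into all downstream
#' reports so locally edited lists are never mistaken for another site's.
#'
#' @param path Path to the YAML file.
#' @return An `aghd_registry`: list with elements `version`, `lists`
#'   (named list of code lists), and `comorbidities`.
#' @seealso [default_codelists()] for the shipped approximate defaults.
#' @export
load_codelists <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("code-list file not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  version <- raw$version
  if (is.null(version) || !nzchar(version)) {
    abort_config("code-list config lacks a top-level version string")
  }
  missing <- setdiff(mandatory_lists(), names(raw$lists))
  if (length(missing)) {
    abort_config(paste0("missing code list ", missing[1]))
  }
  lists <- lapply(names(raw$lists), function(nm) {
    new_code_list(nm, parse_entry_block(nm, raw$lists[[nm]]), version)
  })
  names(lists) <- names(raw$lists)
  for (nm in c("PITUITARY_DEFICIENCY_DX", "HORMONE_REPLACEMENT_RX", "AXIS_TEST_CPT")) {
    if (all(is.na(lists[[nm]]$entries$axis))) {
      abort_config(paste0("code list ", nm, " must carry axis labels"))
    }
  }
  if (all(is.na(lists$GHD_TEST_CPT$entries$label))) {
    abort_config("code list GHD_TEST_CPT must carry per-test labels")
  }
  comorb <- lapply(names(raw$comorbidities %||% list()), function(nm) {
    new_code_list(nm, parse_entry_block(nm, raw$comorbidities[[nm]]), version)
  })
  names(comorb) <- names(raw$comorbidities %||% list())
  structure(list(version = version, lists = lists, comorbidities = comorb),
            class = "aghd_registry")
}

#' Shipped default code lists
#'
#' Loads the package's built-in registry. These defaults are deliberately
#' approximate placeholders assembled from widely known terminology anchors
#' (e.g. ATC `H01AC` for somatropin-type GH therapy, `G03`/`H02AB`/`H03AA`
#' for the three replacement classes); production use should supply a
#' site-curated file via [load_codelists()].
#'
#' @return An `aghd_registry`.
#' @export
default_codelists <- function() {
  load_codelists(system.file("extdata", "codelists.yaml",
                             package = "aghdscreen", mustWork = TRUE))
}

#' @export
print.aghd_registry <- function(x, ...) {
  cat("<aghd_registry> version:", x$version, "\n")
  cat("  algorithm lists:", paste(names(x$lists), collapse = ", "), "\n")
  cat("  comorbidity lists:", length(x$comorbidities), "\n")
  invisible(x)
}
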