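# Raw data model: participants, per-wave self-report records, medical records.
#
# All tables are plain data.frames in long format (one row per
# participant-wave for the wave table). Missing values are NA throughout and
# are never coerced to FALSE/0; booleans are serialized as 0/1 in CSV,
# missing as the empty cell.

#' Column dictionary for the three cohort input tables
#'
#' Names and types of the columns expected in the participants, wave-record,
#' and medical-record CSVs consumed by [read_cohort()]. Unknown columns in an
#' input file are ignored with a warning; missing optional columns are filled
#' with `NA`.
#'
#' @return A named list with elements `participants`, `waves`, `medical`,
#'   each a named character vector mapping column name to one of
#'   `"character"`, `"integer"`, `"logical"`, or a comma-separated set of
#'   admissible factor levels.
#' @export
#' @examples
#' names(moha_columns()$waves)
moha_columns <- function() {
  list(
    participants = c(
      participant_id     = "character",
      sex                = "levels:female,male",
      birth_year         = "integer",
      is_mother          = "logical",
      single_wave_sample = "logical"
    ),
    waves = c(
      participant_id               = "character",
      wave                         = "integer",
      rural                        = "logical",
      sexual_debut_age             = "age",
      ever_sexual_abuse            = "logical",
      consistent_unprotected_sex   = "logical",
      transactional_sex            = "logical",
      multiple_partners            = "logical",
      partner_age_gap_5plus        = "logical",
      mother_vital                 = "levels:alive,dead",
      mother_death_cause           = "levels:hiv_aids,unknown,illness,poison,other",
      mother_on_art_or_symptomatic = "logical",
      father_vital                 = "levels:alive,dead",
      father_death_cause           = "levels:hiv_aids,unknown,illness,poison,other",
      father_on_art_or_symptomatic = "logical",
      age_at_mother_death          = "age",
      age_at_father_death          = "age",
      cognitive_delay_indicator    = "logical",
      poor_physical_health         = "logical",
      art_init_age_selfreport      = "age",
      first_hiv_test_age           = "age",
      hiv_status_aware             = "logical",
      art_naive                    = "logical"
    ),
    medical = c(
      participant_id      = "character",
      art_init_age_record = "age"
    )
  )
}

# admissible integer-year range for every age-valued column
.age_range <- c(0L, 25L)

.stop_moha <- function(msg, class) {
  stop(structure(
    class = c(class, "moha_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Parse one raw character column to its declared type; returns list(values,
# bad_idx). Empty string / NA are missing.
.parse_column <- function(x, type) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x <- trimws(x)
  bad <- rep(FALSE, length(x))
  if (type == "character") {
    vals <- x
  } else if (type %in% c("integer", "age")) {
    suppressWarnings(v <- as.numeric(x))
    ok <- is.na(x) | (!is.na(v) & v == round(v))
    bad <- bad | !ok
    vals <- as.integer(round(v))
    if (type == "age") {
      out_of_range <- !is.na(vals) & (vals < .age_range[1] | vals > .age_range[2])
      bad <- bad | out_of_range
      vals[out_of_range] <- NA_integer_
    }
  } else if (type == "logical") {
    vals <- rep(NA, length(x))
    vals[!is.na(x) & x %in% c("1", "TRUE", "true")] <- TRUE
    vals[!is.na(x) & x %in% c("0", "FALSE", "false")] <- FALSE
    bad <- !is.na(x) & !(x %in% c("0", "1", "TRUE", "FALSE", "true", "false"))
  } else if (startsWith(type, "levels:")) {
    levs <- strsplit(sub("^levels:", "", type), ",")[[1]]
    bad <- !is.na(x) & !(x %in% levs)
    vals <- x
    vals[bad] <- NA_character_
  } else {
    stop("unknown column type: ", type)
  }
  list(values = vals, bad = bad)
}

# Coerce a raw data.frame read from CSV to a typed table per the dictionary.
# Row-level validation errors name the participant_id and offending column.
.typed_table <- function(raw, dict, what) {
  extra <- setdiff(names(raw), names(dict))
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown column(s): %s",
                    what, paste(extra, collapse = ", ")), call. = FALSE)
  }
  out <- list()
  problems <- character()
  ids <- if ("participant_id" %in% names(raw)) as.character(raw$participant_id)
         else rep(NA_character_, nrow(raw))
  for (col in names(dict)) {
    if (!col %in% names(raw)) {
      parsed <- .parse_column(rep(NA_character_, nrow(raw)), dict[[col]])
    } else {
      parsed <- .parse_column(raw[[col]], dict[[col]])
    }
    if (any(parsed$bad)) {
      bad_ids <- ids[parsed$bad]
      problems <- c(problems, sprintf(
        "column '%s': invalid value for participant_id %s",
        col, paste(unique(bad_ids), collapse = ", ")))
    }
    out[[col]] <- parsed$values
  }
  if (length(problems)) {
    .stop_moha(paste0(what, " validation failed:\n  ",
                      paste(problems, collapse = "\n  ")),
               "moha_validation_error")
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a cohort from its three CSV tables
#'
#' Reads and validates the participants, wave-record, and medical-record
#' tables. Missing cells (empty in CSV) become `NA`; booleans are accepted as
#' `0/1` or `TRUE/FALSE`. Ages must be integers in `[0, 25]`. A duplicate
#' `(participant_id, wave)` pair or a malformed value is an error naming the
#' participant and column; unknown columns are dropped with a warning.
#'
#' @param wave_csv_path path to the long-format wave-record CSV.
#' @param medical_csv_path path to the medical-record CSV, or `NULL` for a
#'   cohort with no medical-record abstraction (self-report fallback only).
#' @param participants_csv_path path to the participants CSV.
#' @return An object of class `moha_cohort`: a list with data.frames
#'   `participants`, `waves`, `medical`. `participants` gains a
#'   `waves_present` character column (e.g. `"1,2,3"`) derived from the wave
#'   table.
#' @seealso [write_cohort()], [harmonize_cohort()], [moha_columns()]
#' @export
read_cohort <- function(wave_csv_path, medical_csv_path, participants_csv_path) {
  dict <- moha_columns()
  read_raw <- function(p) utils::read.csv(p, colClasses = "character",
                                          check.names = TRUE)
  participants <- .typed_table(read_raw(participants_csv_path),
                               dict$participants, "participants")
  waves <- .typed_table(read_raw(wave_csv_path), dict$waves, "waves")
  if (!is.null(medical_csv_path) && file.exists(medical_csv_path) &&
      length(readLines(medical_csv_path, n = 2)) >= 1) {
    medical_raw <- read_raw(medical_csv_path)
  } else {
    medical_raw <- data.frame(participant_id = character(),
                              art_init_age_record = character())
  }
  medical <- .typed_table(medical_raw, dict$medical, "medical")
  validate_cohort(new_cohort(participants, waves, medical))
}

#' Construct a cohort object from in-memory tables
#'
#' @param participants,waves,medical data.frames with the columns of
#'   [moha_columns()].
#' @return A `moha_cohort` list.
#' @export
new_cohort <- function(participants, waves,
                       medical = data.frame(participant_id = character(),
                                            art_init_age_record = integer())) {
  wp <- vapply(participants$participant_id, function(id) {
    paste(sort(unique(waves$wave[waves$participant_id == id])), collapse = ",")
  }, character(1))
  participants$waves_present <- unname(wp)
  structure(list(participants = participants, waves = waves, medical = medical),
            class = "moha_cohort")
}

#' Validate cohort invariants
#'
#' Checks uniqueness of participant ids, uniqueness of
#' `(participant_id, wave)`, non-empty wave presence, that every wave record
#' belongs to a known participant, that the single-wave (young mothers)
#' sample is observed only at wave 3 and flagged as mothers, and that at most
#' one medical record exists per participant.
#'
#' @param cohort a `moha_cohort`.
#' @return The cohort, invisibly unchanged, or an error of class
#'   `moha_validation_error`.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$participants; w <- cohort$waves; m <- cohort$medical
  if (anyDuplicated(p$participant_id)) {
    .stop_moha(sprintf("duplicate participant_id: %s",
               paste(unique(p$participant_id[duplicated(p$participant_id)]),
                     collapse = ", ")), "moha_validation_error")
  }
  key <- paste(w$participant_id, w$wave)
  if (anyDuplicated(key)) {
    .stop_moha(sprintf("duplicate (participant_id, wave): %s",
               paste(unique(key[duplicated(key)]), collapse = "; ")),
               "moha_validation_error")
  }
  if (any(!w$wave %in% 1:3)) {
    .stop_moha("wave must be 1, 2, or 3", "moha_validation_error")
  }
  orphan <- setdiff(w$participant_id, p$participant_id)
  if (length(orphan)) {
    .stop_moha(sprintf("wave records for unknown participant(s): %s",
                       paste(orphan, collapse = ", ")), "moha_validation_error")
  }
  no_wave <- setdiff(p$participant_id, w$participant_id)
  if (length(no_wave)) {
    .stop_moha(sprintf("participant(s) with no wave record: %s",
                       paste(no_wave, collapse = ", ")), "moha_validation_error")
  }
  if (anyDuplicated(m$participant_id)) {
    .stop_moha("more than one medical record for a participant",
               "moha_validation_error")
  }
  sw <- p$participant_id[!is.na(p$single_wave_sample) & p$single_wave_sample]
  for (id in sw) {
    ws <- w$wave[w$participant_id == id]
    if (!identical(sort(unique(ws)), 3L)) {
      .stop_moha(sprintf(
        "single-wave-sample participant %s observed outside wave 3", id),
        "moha_validation_error")
    }
    if (!isTRUE(p$is_mother[p$participant_id == id])) {
      .stop_moha(sprintf(
        "single-wave-sample participant %s is not flagged as a mother", id),
        "moha_validation_error")
    }
  }
  invisible(cohort)
}

#' @export
print.moha_cohort <- function(x, ...) {
  cat(sprintf("<moha_cohort> %d participants, %d wave records, %d medical records\n",
              nrow(x$participants), nrow(x$waves), nrow(x$medical)))
  n_sw <- sum(x$participants$single_wave_sample, na.rm = TRUE)
  if (n_sw > 0) cat(sprintf("  incl. %d single-wave (young mothers) participants\n", n_sw))
  invisible(x)
}

# serialize a typed data.frame back to the CSV conventions (logical -> 0/1,
# NA -> empty cell)
.serialize_table <- function(df) {
  out <- df
  for (col in names(out)) {
    v <- out[[col]]
    if (is.logical(v)) v <- ifelse(is.na(v), NA_character_,
                                   ifelse(v, "1", "0"))
    out[[col]] <- v
  }
  out
}

#' Write a cohort to the three CSV tables
#'
#' Inverse of [read_cohort()]: `read_cohort()` applied to the written files
#' reproduces the cohort exactly (round-trip identity), including per-column
#' missingness.
#'
#' @param cohort a `moha_cohort`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(participants = file.path(dir, "participants.csv"),
             waves = file.path(dir, "waves.csv"),
             medical = file.path(dir, "medical.csv"))
  p <- cohort$participants
  p$waves_present <- NULL
  utils::write.csv(.serialize_table(p), paths["participants"],
                   row.names = FALSE, na = "")
  utils::write.csv(.serialize_table(cohort$waves), paths["waves"],
                   row.names = FALSE, na = "")
  utils::write.csv(.serialize_table(cohort$medical), paths["medical"],
                   row.names = FALSE, na = "")
  invisible(paths)
}

#' Write logic-tree allocations to CSV
#'
#' Columns: `participant_id, label, arm, exit_branch, switched,
#' affirmatory_count`. Unclassified participants carry label
#' `"unclassified"` and an empty `exit_branch` cell. The file is re-readable
#' losslessly with [read_allocations()].
#'
#' @param allocations a data.frame as returned by [allocate_moha()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_allocations <- function(allocations, path) {
  stopifnot(nrow(allocations) > 0)
  out <- data.frame(
    participant_id    = allocations$participant_id,
    label             = allocations$label,
    arm               = allocations$arm_entered,
    exit_branch       = ifelse(is.na(allocations$exit_branch), "",
                               allocations$exit_branch),
    switched          = ifelse(allocations$switched, "1", "0"),
    affirmatory_count = allocations$affirmatory_count,
    stringsAsFactors  = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a logic-tree allocation CSV written by [write_allocations()]
#'
#' @param path CSV path.
#' @return data.frame with columns `participant_id, label, arm_entered,
#'   exit_branch, switched, affirmatory_count`.
#' @export
read_allocations <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  data.frame(
    participant_id    = raw$participant_id,
    label             = raw$label,
    arm_entered       = raw$arm,
    exit_branch       = ifelse(raw$exit_branch == "", NA_character_,
                               raw$exit_branch),
    switched          = raw$switched == "1",
    affirmatory_count = as.integer(raw$affirmatory_count),
    stringsAsFactors  = FALSE
  )
}
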