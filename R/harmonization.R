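# Cross-wave harmonization: collapse wave-level self-reports into the
# per-participant derived factors the classifiers consume. Convention for
# every boolean factor is OR over available waves; a factor whose inputs are
# missing at every wave is FALSE with availability "unobserved" (the tree
# treats absent evidence as non-confirming, never as counter-evidence).

#' Logic-tree configuration
#'
#' Bundles the tunable constants of the classification pipeline. Defaults are
#' the operational constants of the South African adolescent setting the
#' method was developed in.
#'
#' @param cutoff_ages integer vector of candidate ART-initiation-age cutoffs
#'   (years), strictly increasing. Default `10:15`.
#' @param art_rollout_year first year of public-sector ART rollout;
#'   initiation strictly before it confirms vertical acquisition. Default
#'   2005.
#' @param orphan_age_threshold maximum age (years) at a parent's unexplained
#'   death for presumed HIV orphanhood. Default 10, justified by the median
#'   `seroconversion_to_death_years` in untreated adults: a parent dying that
#'   young in the child's life would have been infected around conception.
#' @param discordance_gap_years minimum excess (years) of the wave-1 sexual
#'   debut age over a later-wave report to count as discordant disclosure.
#'   Default 3.
#' @param first_test_age_threshold first-HIV-test age (years) strictly below
#'   which testing is taken as childhood diagnosis. Default 10.
#' @param seroconversion_to_death_years documentation constant (median years
#'   from adult seroconversion to AIDS death, untreated); justifies
#'   `orphan_age_threshold`. Default 10.2.
#' @param enabled_branches character vector of branch ids to evaluate.
#'   Default: all of [moha_branches()].
#' @param force_sexual_gateway if `TRUE` every participant enters the sexual
#'   arm regardless of reported sexual activity (the young-mothers variant).
#' @param mothers_variant convenience switch for the single-wave young-mothers
#'   sample: forces the sexual gateway and disables the branches that need
#'   multi-wave or wave-1-only data (S3 discordant disclosure, V3/V7
#'   presumed orphanhood at age 10 or younger).
#' @return A list of class `moha_tree_config`.
#' @export
#' @examples
#' tree_config()
#' tree_config(mothers_variant = TRUE)$enabled_branches
tree_config <- function(cutoff_ages = 10:15,
                        art_rollout_year = 2005L,
                        orphan_age_threshold = 10L,
                        discordance_gap_years = 3L,
                        first_test_age_threshold = 10L,
                        seroconversion_to_death_years = 10.2,
                        enabled_branches = NULL,
                        force_sexual_gateway = FALSE,
                        mothers_variant = FALSE) {
  cutoff_ages <- as.integer(cutoff_ages)
  if (length(cutoff_ages) == 0 || any(diff(cutoff_ages) <= 0)) {
    stop("cutoff_ages must be strictly increasing")
  }
  stopifnot(orphan_age_threshold > 0, discordance_gap_years > 0,
            first_test_age_threshold > 0, seroconversion_to_death_years > 0)
  all_branches <- moha_branches()$branch_id
  if (is.null(enabled_branches)) enabled_branches <- all_branches
  if (!all(enabled_branches %in% all_branches)) {
    stop("unknown branch id(s): ",
         paste(setdiff(enabled_branches, all_branches), collapse = ", "))
  }
  if (mothers_variant) {
    enabled_branches <- setdiff(enabled_branches, c("S3", "V3", "V7"))
    force_sexual_gateway <- TRUE
  }
  structure(list(
    cutoff_ages = cutoff_ages,
    art_rollout_year = as.integer(art_rollout_year),
    orphan_age_threshold = as.integer(orphan_age_threshold),
    discordance_gap_years = as.integer(discordance_gap_years),
    first_test_age_threshold = as.integer(first_test_age_threshold),
    seroconversion_to_death_years = seroconversion_to_death_years,
    enabled_branches = enabled_branches,
    force_sexual_gateway = force_sexual_gateway,
    mothers_variant = mothers_variant
  ), class = "moha_tree_config")
}

#' @export
print.moha_tree_config <- function(x, ...) {
  cat("<moha_tree_config>\n")
  cat("  cutoffs:", paste(x$cutoff_ages, collapse = ","), "\n")
  cat("  rollout year:", x$art_rollout_year,
      "| orphan age <=", x$orphan_age_threshold,
      "| discordance gap >=", x$discordance_gap_years,
      "| first test <", x$first_test_age_threshold, "\n")
  cat("  gateway forced sexual:", x$force_sexual_gateway,
      "| enabled:", paste(x$enabled_branches, collapse = " "), "\n")
  invisible(x)
}

#' Youngest ART-initiation age with source precedence
#'
#' The medical-record age, when abstracted, takes strict precedence; the
#' self-reported fallback is the youngest non-missing age across the waves.
#'
#' @param medical_record one-row data.frame with `art_init_age_record`, or
#'   `NULL` / zero rows when no record was abstracted.
#' @param wave_records data.frame of the participant's wave records.
#' @return `list(age =, source =)` with `source` in
#'   `c("medical", "self_report")`, or `NULL` when no evidence exists.
#' @export
youngest_art_initiation_age <- function(medical_record, wave_records) {
  med <- if (!is.null(medical_record) && nrow(medical_record) >= 1) {
    medical_record$art_init_age_record[1]
  } else NA_integer_
  if (!is.na(med)) return(list(age = as.integer(med), source = "medical"))
  sr <- wave_records$art_init_age_selfreport
  sr <- sr[!is.na(sr)]
  if (length(sr) == 0) return(NULL)
  list(age = as.integer(min(sr)), source = "self_report")
}

#' Discordant disclosure of sexual debut
#'
#' True when the participant either (1) reported no sexual debut age at the
#' face-to-face wave-1 interview but reported one at a later (ACASI) wave, or
#' (2) reported a wave-1 debut age at least `gap` years older than a
#' later-wave report. Requires a wave-1 record plus at least one later wave;
#' returns `FALSE` otherwise.
#'
#' @param wave_records data.frame of the participant's wave records.
#' @param gap minimum wave-1 excess in years (default 3).
#' @return logical scalar.
#' @export
detect_discordant_disclosure <- function(wave_records, gap = 3L) {
  w1 <- wave_records[wave_records$wave == 1L, , drop = FALSE]
  later <- wave_records[wave_records$wave > 1L, , drop = FALSE]
  if (nrow(w1) == 0 || nrow(later) == 0) return(FALSE)
  d1 <- w1$sexual_debut_age[1]
  dl <- later$sexual_debut_age[!is.na(later$sexual_debut_age)]
  if (length(dl) == 0) return(FALSE)
  if (is.na(d1)) return(TRUE)                 # rule (1): concealed at wave 1
  any(d1 - dl >= gap)                         # rule (2): inflated at wave 1
}

#' Parental HIV history and presumed orphanhood flags
#'
#' Collapses the per-wave maternal and paternal vital status, cause of death,
#' ART/symptom indicators and (wave-1-only) age at parental death into the
#' five parental tree factors. A parent reported dead of HIV/AIDS at any wave
#' sets the HIV-orphan flag; death with cause "I don't know" / illness /
#' poison at participant age `<= orphan_age_threshold` sets the presumed
#' flag; cause "other" never does.
#'
#' @param wave_records data.frame of the participant's wave records.
#' @param orphan_age_threshold integer years (default 10).
#' @return Named logical vector: `maternal_hiv_orphan`, `mother_on_art`,
#'   `maternal_orphan_le10_presumed`, `paternal_hiv_orphan_or_dad_art`,
#'   `paternal_orphan_le10_presumed`.
#' @export
classify_parental_history <- function(wave_records, orphan_age_threshold = 10L) {
  one_parent <- function(vital, cause, on_art, age_at_death) {
    dead <- !is.na(vital) & vital == "dead"
    hiv_orphan <- any(dead & !is.na(cause) & cause == "hiv_aids")
    art <- any(!is.na(on_art) & on_art)
    presumed_cause <- dead & !is.na(cause) &
      cause %in% c("unknown", "illness", "poison")
    # age at death is documented at wave 1 only; take first non-missing in
    # wave order
    ord <- order(wave_records$wave)
    aad <- age_at_death[ord][!is.na(age_at_death[ord])]
    aad <- if (length(aad)) aad[1] else NA_integer_
    presumed <- any(presumed_cause) && !is.na(aad) &&
      aad <= orphan_age_threshold
    c(hiv_orphan = hiv_orphan, on_art = art, presumed = presumed)
  }
  m <- one_parent(wave_records$mother_vital, wave_records$mother_death_cause,
                  wave_records$mother_on_art_or_symptomatic,
                  wave_records$age_at_mother_death)
  f <- one_parent(wave_records$father_vital, wave_records$father_death_cause,
                  wave_records$father_on_art_or_symptomatic,
                  wave_records$age_at_father_death)
  c(maternal_hiv_orphan            = unname(m["hiv_orphan"]),
    mother_on_art                  = unname(m["on_art"]),
    maternal_orphan_le10_presumed  = unname(m["presumed"]),
    paternal_hiv_orphan_or_dad_art = unname(f["hiv_orphan"] || f["on_art"]),
    paternal_orphan_le10_presumed  = unname(f["presumed"]))
}

# names of the boolean factors carried on a harmonized profile
.factor_names <- c(
  "ever_sexual_activity", "ever_sexual_abuse", "discordant_disclosure",
  "consistent_unprotected_sex", "other_risky_behaviour", "hiv_status_aware",
  "maternal_hiv_orphan", "mother_on_art", "maternal_orphan_le10_presumed",
  "paternal_hiv_orphan_or_dad_art", "paternal_orphan_le10_presumed",
  "cognitive_delay", "poor_physical_health"
)

.or_waves <- function(x) any(!is.na(x) & x)
.observed <- function(...) any(!vapply(list(...), function(v) all(is.na(v)),
                                       logical(1)))

#' Harmonize one participant's records into a profile
#'
#' Applies the cross-wave rules: OR over waves for boolean indicators,
#' youngest age for sexual debut and (within self-reports) ART initiation,
#' medical-record precedence for ART initiation age, derived ART initiation
#' year (`birth_year + art_init_age`), discordant-disclosure detection, and
#' the parental-history flags. For single-wave-sample participants (young
#' mothers observed at wave 3 only), discordant disclosure and both presumed
#' orphan-at-10-or-younger flags are structurally unobservable and are forced
#' `FALSE` with availability "unobserved". Contradictory vital status (a
#' parent dead at one wave, alive at a later wave) resolves toward death with
#' a warning.
#'
#' @param participant one-row data.frame from a cohort's participants table.
#' @param wave_records that participant's wave records.
#' @param medical_record that participant's medical record (0 or 1 rows), or
#'   `NULL`.
#' @param config a [tree_config()].
#' @return One-row data.frame (class `moha_profile` row); see
#'   [harmonize_cohort()] for the column set.
#' @export
harmonize <- function(participant, wave_records, medical_record = NULL,
                      config = tree_config()) {
  w <- wave_records[order(wave_records$wave), , drop = FALSE]
  single <- isTRUE(participant$single_wave_sample)

  # contradictory vital status: death is not retractable
  for (par in c("mother", "father")) {
    vit <- w[[paste0(par, "_vital")]]
    dead_at <- which(!is.na(vit) & vit == "dead")
    alive_at <- which(!is.na(vit) & vit == "alive")
    if (length(dead_at) && length(alive_at) &&
        max(alive_at) > min(dead_at)) {
      warning(sprintf(
        "participant %s: %s reported dead at wave %d but alive later; keeping 'dead'",
        participant$participant_id, par, w$wave[min(dead_at)]), call. = FALSE)
    }
  }

  art <- youngest_art_initiation_age(medical_record, w)
  art_init_age <- if (is.null(art)) NA_integer_ else art$age
  art_source <- if (is.null(art)) NA_character_ else art$source
  birth_year <- participant$birth_year
  art_init_year <- if (!is.na(art_init_age) && !is.na(birth_year)) {
    as.integer(birth_year + art_init_age)
  } else NA_integer_
  # ART naive only when there is no initiation evidence anywhere: no
  # abstracted or self-reported age and no wave denying naivety
  denies_naive <- any(!is.na(w$art_naive) & !w$art_naive)
  art_naive <- is.na(art_init_age) && !denies_naive

  debut <- w$sexual_debut_age[!is.na(w$sexual_debut_age)]
  sexual_debut_age <- if (length(debut)) as.integer(min(debut)) else NA_integer_

  fht <- w$first_hiv_test_age[!is.na(w$first_hiv_test_age)]
  first_hiv_test_age <- if (length(fht)) as.integer(min(fht)) else NA_integer_

  parental <- classify_parental_history(w, config$orphan_age_threshold)
  discordant <- if (single) FALSE else
    detect_discordant_disclosure(w, config$discordance_gap_years)

  prof <- data.frame(
    participant_id = participant$participant_id,
    sex = participant$sex,
    birth_year = birth_year,
    is_mother = isTRUE(participant$is_mother),
    single_wave_sample = single,
    n_waves = nrow(w),
    art_init_age = art_init_age,
    art_init_source = art_source,
    art_init_year = art_init_year,
    art_naive = art_naive,
    sexual_debut_age = sexual_debut_age,
    first_hiv_test_age = first_hiv_test_age,
    ever_sexual_activity = length(debut) > 0,
    ever_sexual_abuse = .or_waves(w$ever_sexual_abuse),
    discordant_disclosure = discordant,
    consistent_unprotected_sex = .or_waves(w$consistent_unprotected_sex),
    other_risky_behaviour = .or_waves(w$transactional_sex) ||
      .or_waves(w$multiple_partners) || .or_waves(w$partner_age_gap_5plus),
    hiv_status_aware = .or_waves(w$hiv_status_aware),
    maternal_hiv_orphan = parental[["maternal_hiv_orphan"]],
    mother_on_art = parental[["mother_on_art"]],
    maternal_orphan_le10_presumed = if (single) FALSE else
      parental[["maternal_orphan_le10_presumed"]],
    paternal_hiv_orphan_or_dad_art = parental[["paternal_hiv_orphan_or_dad_art"]],
    paternal_orphan_le10_presumed = if (single) FALSE else
      parental[["paternal_orphan_le10_presumed"]],
    cognitive_delay = .or_waves(w$cognitive_delay_indicator),
    poor_physical_health = .or_waves(w$poor_physical_health),
    stringsAsFactors = FALSE
  )

  avail <- c(
    ever_sexual_activity = .observed(w$sexual_debut_age),
    ever_sexual_abuse = .observed(w$ever_sexual_abuse),
    discordant_disclosure = !single && nrow(w[w$wave == 1L, ]) > 0 &&
      nrow(w[w$wave > 1L, ]) > 0,
    consistent_unprotected_sex = .observed(w$consistent_unprotected_sex),
    other_risky_behaviour = .observed(w$transactional_sex, w$multiple_partners,
                                      w$partner_age_gap_5plus),
    hiv_status_aware = .observed(w$hiv_status_aware),
    maternal_hiv_orphan = .observed(w$mother_vital),
    mother_on_art = .observed(w$mother_on_art_or_symptomatic),
    maternal_orphan_le10_presumed = !single && .observed(w$mother_vital) &&
      (.observed(w$age_at_mother_death) ||
         !any(!is.na(w$mother_vital) & w$mother_vital == "dead")),
    paternal_hiv_orphan_or_dad_art = .observed(w$father_vital,
                                               w$father_on_art_or_symptomatic),
    paternal_orphan_le10_presumed = !single && .observed(w$father_vital) &&
      (.observed(w$age_at_father_death) ||
         !any(!is.na(w$father_vital) & w$father_vital == "dead")),
    cognitive_delay = .observed(w$cognitive_delay_indicator),
    poor_physical_health = .observed(w$poor_physical_health)
  )
  for (f in .factor_names) prof[[paste0("avail_", f)]] <- unname(avail[f])
  prof
}

#' Harmonize a whole cohort
#'
#' Applies [harmonize()] to every participant and stacks the profiles.
#'
#' @param cohort a `moha_cohort` (see [read_cohort()]).
#' @param config a [tree_config()].
#' @return data.frame of class `moha_profiles`, one row per participant.
#' @export
harmonize_cohort <- function(cohort, config = tree_config()) {
  p <- cohort$participants
  waves_by_id <- split(cohort$waves, cohort$waves$participant_id)
  med_by_id <- split(cohort$medical, cohort$medical$participant_id)
  rows <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    id <- p$participant_id[i]
    rows[[i]] <- harmonize(p[i, , drop = FALSE],
                           waves_by_id[[id]],
                           med_by_id[[id]],
                           config)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("moha_profiles", "data.frame")
  out
}

#' Write harmonized profiles to a CSV audit file
#'
#' @param profiles a `moha_profiles` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(.serialize_table(as.data.frame(profiles)), path,
                   row.names = FALSE, na = "")
  invisible(path)
}
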