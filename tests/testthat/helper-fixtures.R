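# Builders for small in-memory fixtures. A wave record defaults to all
# missing; pass only the fields a test cares about.

blank_wave <- function(participant_id = "p1", wave = 1L, ...) {
  w <- data.frame(
    participant_id = participant_id, wave = as.integer(wave), rural = NA,
    sexual_debut_age = NA_integer_, ever_sexual_abuse = NA,
    consistent_unprotected_sex = NA, transactional_sex = NA,
    multiple_partners = NA, partner_age_gap_5plus = NA,
    mother_vital = NA_character_, mother_death_cause = NA_character_,
    mother_on_art_or_symptomatic = NA,
    father_vital = NA_character_, father_death_cause = NA_character_,
    father_on_art_or_symptomatic = NA,
    age_at_mother_death = NA_integer_, age_at_father_death = NA_integer_,
    cognitive_delay_indicator = NA, poor_physical_health = NA,
    art_init_age_selfreport = NA_integer_, first_hiv_test_age = NA_integer_,
    hiv_status_aware = NA, art_naive = NA,
    stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) w[[nm]] <- dots[[nm]]
  w
}

make_participant <- function(participant_id = "p1", sex = "female",
                             birth_year = 1998L, is_mother = FALSE,
                             single_wave_sample = FALSE) {
  data.frame(participant_id = participant_id, sex = sex,
             birth_year = as.integer(birth_year), is_mother = is_mother,
             single_wave_sample = single_wave_sample,
             stringsAsFactors = FALSE)
}

# a blank harmonized profile row; override factor fields via ...
blank_profile <- function(participant_id = "p1", ...) {
  p <- data.frame(
    participant_id = participant_id, sex = "female", birth_year = 1998L,
    is_mother = FALSE, single_wave_sample = FALSE, n_waves = 3L,
    art_init_age = NA_integer_, art_init_source = NA_character_,
    art_init_year = NA_integer_, art_naive = FALSE,
    sexual_debut_age = NA_integer_, first_hiv_test_age = NA_integer_,
    ever_sexual_activity = FALSE, ever_sexual_abuse = FALSE,
    discordant_disclosure = FALSE, consistent_unprotected_sex = FALSE,
    other_risky_behaviour = FALSE, hiv_status_aware = FALSE,
    maternal_hiv_orphan = FALSE, mother_on_art = FALSE,
    maternal_orphan_le10_presumed = FALSE,
    paternal_hiv_orphan_or_dad_art = FALSE,
    paternal_orphan_le10_presumed = FALSE,
    cognitive_delay = FALSE, poor_physical_health = FALSE,
    stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  p
}

# three participants with distinct routes: sexual (S1), vertical (V1),
# unclassified
toy_cohort3 <- function() {
  p <- rbind(make_participant("a"), make_participant("b", sex = "male"),
             make_participant("c"))
  w <- rbind(
    blank_wave("a", 1, sexual_debut_age = 13L, art_init_age_selfreport = 15L),
    blank_wave("a", 2, sexual_debut_age = 13L),
    blank_wave("b", 1, mother_vital = "dead", mother_death_cause = "hiv_aids"),
    blank_wave("c", 1))
  m <- data.frame(participant_id = "b", art_init_age_record = 4L,
                  stringsAsFactors = FALSE)
  new_cohort(p, w, m)
}

# a complete tiny cohort: one three-wave participant
toy_cohort <- function() {
  p <- make_participant("p1")
  w <- rbind(
    blank_wave("p1", 1, sexual_debut_age = 14L, hiv_status_aware = TRUE,
               mother_vital = "alive", art_init_age_selfreport = 9L),
    blank_wave("p1", 2, sexual_debut_age = 14L, consistent_unprotected_sex = TRUE),
    blank_wave("p1", 3, first_hiv_test_age = 8L))
  m <- data.frame(participant_id = "p1", art_init_age_record = 7L,
                  stringsAsFactors = FALSE)
  new_cohort(p, w, m)
}
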