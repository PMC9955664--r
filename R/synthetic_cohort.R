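# Synthetic cohorts with known true mode of acquisition. The generator
# emulates the structure the pipeline consumes: a three-wave community-traced
# cohort (baseline complete, follow-up by retention), an optional single-wave
# young-mothers sample observed at wave 3 only, partial medical-record
# abstraction, wave-1 under-reporting of sexual debut relative to the later
# ACASI waves, and label-conditional factor expression. Factors confirming
# the OPPOSITE arm appear only at `noise_rate`, so at noise_rate = 0 the
# tree can err only by abstention (unclassified), never by mislabeling.

#' Configuration for the synthetic-cohort generator
#'
#' Defaults state the cohort the method was developed on: n = 1107
#' adolescents, 57% female, ~70% vertically infected, medical-record coverage
#' 88.1%, follow-up retention 93.6% and 91.5%, ART start age peaked at 5
#' years for vertical acquisition, sexual debut peaked at 15 years.
#'
#' @param n cohort size (three-wave sample).
#' @param p_vertical probability a cohort participant's true mode is
#'   vertical.
#' @param p_female probability female.
#' @param single_wave_mothers_n size of the additional single-wave
#'   young-mothers sample (observed at wave 3 only; all female, all mothers).
#' @param p_vertical_mothers probability a young mother's true mode is
#'   vertical (default 0.05; sexual acquisition dominates in that group).
#' @param medical_record_coverage probability an ART-initiated participant
#'   has an abstracted medical record.
#' @param wave2_retention,wave3_retention follow-up probabilities for waves 2
#'   and 3 (cohort participants; wave 1 is complete).
#' @param wave1_underreport_prob probability a truly sexually active cohort
#'   participant conceals (or inflates by 3+ years) their sexual debut at the
#'   face-to-face wave-1 interview, disclosing under ACASI later — the
#'   mechanism behind discordant disclosure.
#' @param factor_informativeness named vector of probabilities that a
#'   label-consistent factor is expressed; names: `abuse`,
#'   `consistent_unprotected`, `other_risky`, `hiv_aware` (sexual arm);
#'   `mother_hiv_dead`, `mother_on_art`, `mother_dead_other_young`,
#'   `father_hiv_or_art`, `father_dead_other_young`, `cognitive`, `physical`
#'   (vertical arm; the three mother states and two father states are
#'   mutually exclusive and must sum to at most 1 per parent).
#' @param noise_rate probability a factor confirming the opposite arm is
#'   expressed (contradicting the true label).
#' @param p_sexually_active_vertical probability a vertically infected cohort
#'   participant is sexually active (debut after diagnosis; exercises the
#'   sexual-to-vertical switch path).
#' @param art_naive_rate probability a vertically infected participant is ART
#'   naive (slow-progressor candidate).
#' @param selfreport_art_prob per-wave probability an initiated participant
#'   self-reports the ART initiation age.
#' @param factor_obs_prob per-wave probability a factor that is absent is
#'   recorded as an explicit 0 rather than left missing.
#' @param birth_year_range integer length-2; cohort birth years are uniform
#'   on this range (default 1995-2004: ages 10-19 at a 2014 baseline).
#' @param mothers_birth_year_range birth years for the young-mothers sample
#'   (default 1997-2001).
#' @param seed integer RNG seed.
#' @return list of class `moha_synthetic_config`.
#' @export
synthetic_config <- function(n = 1107L,
                             p_vertical = 0.70,
                             p_female = 0.57,
                             single_wave_mothers_n = 0L,
                             p_vertical_mothers = 0.05,
                             medical_record_coverage = 0.881,
                             wave2_retention = 0.936,
                             wave3_retention = 0.915,
                             wave1_underreport_prob = 0.25,
                             factor_informativeness = c(
                               abuse = 0.39,
                               consistent_unprotected = 0.76,
                               other_risky = 0.55,
                               hiv_aware = 0.91,
                               mother_hiv_dead = 0.38,
                               mother_on_art = 0.20,
                               mother_dead_other_young = 0.25,
                               father_hiv_or_art = 0.18,
                               father_dead_other_young = 0.28,
                               cognitive = 0.51,
                               physical = 0.18),
                             noise_rate = 0.05,
                             p_sexually_active_vertical = 0.25,
                             art_naive_rate = 0.005,
                             selfreport_art_prob = 0.8,
                             factor_obs_prob = 0.95,
                             birth_year_range = c(1995L, 2004L),
                             mothers_birth_year_range = c(1997L, 2001L),
                             seed = 1L) {
  probs <- c(p_vertical = p_vertical, p_female = p_female,
             p_vertical_mothers = p_vertical_mothers,
             medical_record_coverage = medical_record_coverage,
             wave2_retention = wave2_retention,
             wave3_retention = wave3_retention,
             wave1_underreport_prob = wave1_underreport_prob,
             noise_rate = noise_rate,
             p_sexually_active_vertical = p_sexually_active_vertical,
             art_naive_rate = art_naive_rate,
             selfreport_art_prob = selfreport_art_prob,
             factor_obs_prob = factor_obs_prob,
             factor_informativeness)
  bad <- probs[is.na(probs) | probs < 0 | probs > 1]
  if (length(bad)) {
    .stop_moha(paste0("probabilities outside [0,1]: ",
                      paste(names(bad), collapse = ", ")),
               "moha_config_error")
  }
  if (n <= 0) .stop_moha("n must be positive", "moha_config_error")
  if (single_wave_mothers_n < 0) {
    .stop_moha("single_wave_mothers_n must be non-negative", "moha_config_error")
  }
  fi <- factor_informativeness
  needed <- c("abuse", "consistent_unprotected", "other_risky", "hiv_aware",
              "mother_hiv_dead", "mother_on_art", "mother_dead_other_young",
              "father_hiv_or_art", "father_dead_other_young",
              "cognitive", "physical")
  if (!all(needed %in% names(fi))) {
    .stop_moha(paste0("factor_informativeness missing: ",
                      paste(setdiff(needed, names(fi)), collapse = ", ")),
               "moha_config_error")
  }
  if (fi["mother_hiv_dead"] + fi["mother_on_art"] +
        fi["mother_dead_other_young"] > 1 ||
      fi["father_hiv_or_art"] + fi["father_dead_other_young"] > 1) {
    .stop_moha("parent state probabilities must sum to at most 1",
               "moha_config_error")
  }
  structure(list(
    n = as.integer(n), p_vertical = p_vertical, p_female = p_female,
    single_wave_mothers_n = as.integer(single_wave_mothers_n),
    p_vertical_mothers = p_vertical_mothers,
    medical_record_coverage = medical_record_coverage,
    wave2_retention = wave2_retention, wave3_retention = wave3_retention,
    wave1_underreport_prob = wave1_underreport_prob,
    factor_informativeness = fi, noise_rate = noise_rate,
    p_sexually_active_vertical = p_sexually_active_vertical,
    art_naive_rate = art_naive_rate,
    selfreport_art_prob = selfreport_art_prob,
    factor_obs_prob = factor_obs_prob,
    birth_year_range = as.integer(birth_year_range),
    mothers_birth_year_range = as.integer(mothers_birth_year_range),
    seed = as.integer(seed)
  ), class = "moha_synthetic_config")
}

# discrete age samplers (Poisson weights give integer-year unimodal
# distributions with the stated medians)
.sample_init_age_vertical <- function(n) {
  ages <- 0:12
  sample(ages, n, replace = TRUE, prob = stats::dpois(ages, 5))
}
.sample_debut_age <- function(n, median_age = 15) {
  ages <- 12:19
  sample(ages, n, replace = TRUE, prob = stats::dpois(ages - 12, median_age - 12))
}

# report a boolean factor across a participant's present waves: TRUE carriers
# are guaranteed at least one affirmative wave; non-carriers get explicit 0s
# with prob obs_prob, else missing
.spread_flag <- function(carrier, waves_present, obs_prob) {
  k <- length(waves_present)
  if (carrier) {
    rep_at <- stats::runif(k) < 0.7
    if (!any(rep_at)) rep_at[sample.int(k, 1)] <- TRUE
    out <- ifelse(rep_at, TRUE, NA)
  } else {
    out <- ifelse(stats::runif(k) < obs_prob, FALSE, NA)
  }
  out
}

#' Generate a synthetic cohort with known true labels
#'
#' Reproducible given `config$seed`. Returns a validated `moha_cohort`
#' (always passes [validate_cohort()]) plus the true per-participant labels.
#'
#' @param config a [synthetic_config()].
#' @return list of class `moha_synthetic` with elements `cohort`
#'   (`moha_cohort`), `true_labels` (data.frame `participant_id`,
#'   `true_label`), and `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "moha_synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  fi <- config$factor_informativeness
  n_total <- config$n + config$single_wave_mothers_n
  ids <- sprintf("P%05d", seq_len(n_total))
  is_sw <- c(rep(FALSE, config$n), rep(TRUE, config$single_wave_mothers_n))

  part_rows <- vector("list", n_total)
  wave_rows <- vector("list", n_total)
  med_rows <- vector("list", n_total)
  true_label <- character(n_total)

  wave_template <- function(id, wv) {
    data.frame(participant_id = id, wave = wv, rural = NA,
               sexual_debut_age = NA_integer_, ever_sexual_abuse = NA,
               consistent_unprotected_sex = NA, transactional_sex = NA,
               multiple_partners = NA, partner_age_gap_5plus = NA,
               mother_vital = NA_character_, mother_death_cause = NA_character_,
               mother_on_art_or_symptomatic = NA,
               father_vital = NA_character_, father_death_cause = NA_character_,
               father_on_art_or_symptomatic = NA,
               age_at_mother_death = NA_integer_,
               age_at_father_death = NA_integer_,
               cognitive_delay_indicator = NA, poor_physical_health = NA,
               art_init_age_selfreport = NA_integer_,
               first_hiv_test_age = NA_integer_, hiv_status_aware = NA,
               art_naive = NA, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_total)) {
    sw <- is_sw[i]
    vertical <- stats::runif(1) <
      (if (sw) config$p_vertical_mothers else config$p_vertical)
    true_label[i] <- if (vertical) "vertical" else "sexual"
    female <- if (sw) TRUE else stats::runif(1) < config$p_female
    byr <- if (sw) {
      sample(config$mothers_birth_year_range[1]:config$mothers_birth_year_range[2], 1)
    } else {
      sample(config$birth_year_range[1]:config$birth_year_range[2], 1)
    }

    # wave presence: cohort has complete baseline; mothers are wave-3 only
    waves <- if (sw) 3L else {
      c(1L,
        if (stats::runif(1) < config$wave2_retention) 2L,
        if (stats::runif(1) < config$wave3_retention) 3L)
    }
    k <- length(waves)
    w <- do.call(rbind, lapply(waves, function(wv) wave_template(ids[i], wv)))
    w$rural <- stats::runif(k) < 0.25

    # sexual activity and ages
    debut <- NA_integer_
    if (!vertical) {
      debut <- if (sw) .sample_debut_age(1, 16) else .sample_debut_age(1, 15)
      delay <- sample(0:4, 1, prob = c(0.35, 0.25, 0.2, 0.1, 0.1))
      init_age <- min(25L, debut + delay)
      naive <- FALSE
    } else {
      if (stats::runif(1) < config$p_sexually_active_vertical) {
        debut <- sample(13:19, 1)
      }
      naive <- stats::runif(1) < config$art_naive_rate
      init_age <- if (naive) NA_integer_ else .sample_init_age_vertical(1)
    }
    test_age <- if (naive) sample(0:9, 1) else max(0L, init_age - sample(0:1, 1))

    # ART evidence: medical record, per-wave self-report, naivety flags
    if (!naive) {
      if (stats::runif(1) < config$medical_record_coverage) {
        med_rows[[i]] <- data.frame(participant_id = ids[i],
                                    art_init_age_record = init_age)
      }
      rep_sr <- stats::runif(k) < config$selfreport_art_prob
      sr_age <- rep(init_age, k)
      jitter <- stats::runif(k) < config$noise_rate
      sr_age[jitter] <- pmin(25L, pmax(0L, sr_age[jitter] +
                                         sample(c(-1L, 1L), sum(jitter), replace = TRUE)))
      w$art_init_age_selfreport[rep_sr] <- sr_age[rep_sr]
      w$art_naive <- ifelse(stats::runif(k) < 0.9, FALSE, NA)
    } else {
      w$art_naive <- TRUE
    }
    w$first_hiv_test_age[stats::runif(k) < 0.8] <- test_age

    # sexual debut reporting with wave-1 concealment (ACASI mechanism);
    # concealment applies to truly sexually infected participants only —
    # mislabeled discordance is noise_rate territory
    if (!is.na(debut)) {
      w$sexual_debut_age <- debut
      if (!vertical && !sw && 1L %in% waves &&
          stats::runif(1) < config$wave1_underreport_prob) {
        if (stats::runif(1) < 0.5 || debut + 3L > 25L) {
          w$sexual_debut_age[w$wave == 1L] <- NA_integer_
        } else {
          w$sexual_debut_age[w$wave == 1L] <- debut + 3L + sample(0:2, 1)
        }
      }
    }

    # sexual-arm factors: informative for sexual truth, noise for vertical
    p_of <- function(nm) if (!vertical) fi[[nm]] else config$noise_rate
    w$ever_sexual_abuse <- .spread_flag(stats::runif(1) < p_of("abuse"),
                                        waves, config$factor_obs_prob)
    w$consistent_unprotected_sex <-
      .spread_flag(stats::runif(1) < p_of("consistent_unprotected"),
                   waves, config$factor_obs_prob)
    risky <- stats::runif(1) < p_of("other_risky")
    if (risky) {
      which_risky <- sample(c("transactional_sex", "multiple_partners",
                              "partner_age_gap_5plus"), 1)
      for (col in c("transactional_sex", "multiple_partners",
                    "partner_age_gap_5plus")) {
        w[[col]] <- .spread_flag(col == which_risky, waves,
                                 config$factor_obs_prob)
      }
    } else {
      for (col in c("transactional_sex", "multiple_partners",
                    "partner_age_gap_5plus")) {
        w[[col]] <- .spread_flag(FALSE, waves, config$factor_obs_prob)
      }
    }
    w$hiv_status_aware <- .spread_flag(stats::runif(1) < p_of("hiv_aware"),
                                       waves, config$factor_obs_prob)

    # parental states: coherent per parent, label-conditional
    mother_state <- if (vertical) {
      if (sw) "hiv_dead"   # vertical young mothers confirm at the top branch
      else sample(c("hiv_dead", "on_art", "dead_other_young", "alive"), 1,
                  prob = c(fi[["mother_hiv_dead"]], fi[["mother_on_art"]],
                           fi[["mother_dead_other_young"]],
                           1 - fi[["mother_hiv_dead"]] - fi[["mother_on_art"]] -
                             fi[["mother_dead_other_young"]]))
    } else if (stats::runif(1) < config$noise_rate) {
      sample(c("hiv_dead", "on_art", "dead_other_young"), 1)
    } else "alive"
    father_state <- if (vertical) {
      sample(c("hiv_or_art", "dead_other_young", "alive"), 1,
             prob = c(fi[["father_hiv_or_art"]],
                      fi[["father_dead_other_young"]],
                      1 - fi[["father_hiv_or_art"]] -
                        fi[["father_dead_other_young"]]))
    } else if (stats::runif(1) < config$noise_rate) {
      sample(c("hiv_or_art", "dead_other_young"), 1)
    } else "alive"

    if (mother_state == "hiv_dead") {
      w$mother_vital <- "dead"; w$mother_death_cause <- "hiv_aids"
      if (1L %in% waves) w$age_at_mother_death[w$wave == 1L] <- sample(0:15, 1)
    } else if (mother_state == "on_art") {
      w$mother_vital <- "alive"; w$mother_on_art_or_symptomatic <- TRUE
    } else if (mother_state == "dead_other_young") {
      w$mother_vital <- "dead"
      w$mother_death_cause <- sample(c("unknown", "illness", "poison"), 1)
      if (1L %in% waves) w$age_at_mother_death[w$wave == 1L] <- sample(0:10, 1)
    } else {
      w$mother_vital <- "alive"
      w$mother_on_art_or_symptomatic <-
        ifelse(stats::runif(k) < config$factor_obs_prob, FALSE, NA)
    }
    if (father_state == "hiv_or_art") {
      if (stats::runif(1) < 0.5) {
        w$father_vital <- "dead"; w$father_death_cause <- "hiv_aids"
        if (1L %in% waves) w$age_at_father_death[w$wave == 1L] <- sample(0:15, 1)
      } else {
        w$father_vital <- "alive"; w$father_on_art_or_symptomatic <- TRUE
      }
    } else if (father_state == "dead_other_young") {
      w$father_vital <- "dead"
      w$father_death_cause <- sample(c("unknown", "illness", "poison"), 1)
      if (1L %in% waves) w$age_at_father_death[w$wave == 1L] <- sample(0:10, 1)
    } else {
      w$father_vital <- "alive"
      w$father_on_art_or_symptomatic <-
        ifelse(stats::runif(k) < config$factor_obs_prob, FALSE, NA)
    }

    # vertical-development factors: informative for vertical, noise otherwise
    p_vf <- function(nm) if (vertical) fi[[nm]] else config$noise_rate
    w$cognitive_delay_indicator <-
      .spread_flag(stats::runif(1) < p_vf("cognitive"), waves,
                   config$factor_obs_prob)
    w$poor_physical_health <-
      .spread_flag(stats::runif(1) < p_vf("physical"), waves,
                   config$factor_obs_prob)

    wave_rows[[i]] <- w
    part_rows[[i]] <- data.frame(
      participant_id = ids[i],
      sex = if (female) "female" else "male",
      birth_year = byr,
      is_mother = sw || (female && !is.na(debut) && stats::runif(1) < 0.5),
      single_wave_sample = sw,
      stringsAsFactors = FALSE)
  }

  participants <- do.call(rbind, part_rows)
  waves_df <- do.call(rbind, wave_rows)
  medical <- do.call(rbind, med_rows[!vapply(med_rows, is.null, logical(1))])
  if (is.null(medical)) {
    medical <- data.frame(participant_id = character(),
                          art_init_age_record = integer())
  }
  rownames(participants) <- rownames(waves_df) <- rownames(medical) <- NULL
  cohort <- validate_cohort(new_cohort(participants, waves_df, medical))
  structure(list(cohort = cohort,
                 true_labels = data.frame(participant_id = ids,
                                          true_label = true_label,
                                          stringsAsFactors = FALSE),
                 config = config),
            class = "moha_synthetic")
}

#' End-to-end recovery experiment on synthetic data
#'
#' Generates a cohort, harmonizes it, allocates with the logic tree (the
#' single-wave young-mothers subset, if any, with the mothers variant of the
#' configuration), evaluates every cutoff against both the tree reference and
#' the generative truth, and reports tree accuracy against truth on the
#' classified subset plus the unclassified rate. With `noise_grid`, repeats
#' over a grid of `noise_rate` values to show degradation.
#'
#' @param config a [synthetic_config()].
#' @param tree_cfg a [tree_config()] (the cohort variant; the mothers variant
#'   is derived from it).
#' @param noise_grid optional numeric vector of noise rates; when given, the
#'   returned list gains a `noise_sweep` data.frame (`noise_rate`,
#'   `tree_accuracy`, `unclassified_rate`).
#' @return list with `tree_accuracy` (vs truth, classified subset),
#'   `unclassified_rate`, `true_vertical_fraction`, `metrics_vs_tree` and
#'   `metrics_vs_truth` ([evaluate_cutoffs()] tables), `allocations`,
#'   `profiles`, `true_labels`, and optionally `noise_sweep`.
#' @export
recovery_experiment <- function(config = synthetic_config(),
                                tree_cfg = tree_config(),
                                noise_grid = NULL) {
  one_run <- function(cfg) {
    syn <- generate_cohort(cfg)
    profiles <- harmonize_cohort(syn$cohort, tree_cfg)
    sw <- profiles$single_wave_sample
    alloc_main <- if (any(!sw)) {
      allocate_moha(profiles[!sw, , drop = FALSE], tree_cfg)
    }
    alloc_moms <- if (any(sw)) {
      mcfg <- tree_cfg; mcfg$enabled_branches <-
        setdiff(mcfg$enabled_branches, c("S3", "V3", "V7"))
      mcfg$force_sexual_gateway <- TRUE
      allocate_moha(profiles[sw, , drop = FALSE], mcfg)
    }
    allocations <- rbind(alloc_main, alloc_moms)
    truth <- syn$true_labels$true_label[
      match(allocations$participant_id, syn$true_labels$participant_id)]
    classified <- allocations$label %in% c("vertical", "sexual")
    list(
      profiles = profiles, allocations = allocations,
      true_labels = syn$true_labels,
      tree_accuracy = mean(allocations$label[classified] == truth[classified]),
      unclassified_rate = mean(!classified),
      true_vertical_fraction = mean(syn$true_labels$true_label == "vertical"))
  }
  run <- one_run(config)
  truth_alloc <- data.frame(participant_id = run$true_labels$participant_id,
                            label = run$true_labels$true_label,
                            stringsAsFactors = FALSE)
  out <- list(
    tree_accuracy = run$tree_accuracy,
    unclassified_rate = run$unclassified_rate,
    true_vertical_fraction = run$true_vertical_fraction,
    metrics_vs_tree = evaluate_cutoffs(run$profiles, run$allocations, tree_cfg),
    metrics_vs_truth = evaluate_cutoffs(run$profiles, truth_alloc, tree_cfg),
    allocations = run$allocations,
    profiles = run$profiles,
    true_labels = run$true_labels)
  if (!is.null(noise_grid)) {
    sweep <- do.call(rbind, lapply(noise_grid, function(nr) {
      cfg <- config; cfg$noise_rate <- nr
      r <- one_run(cfg)
      data.frame(noise_rate = nr, tree_accuracy = r$tree_accuracy,
                 unclassified_rate = r$unclassified_rate)
    }))
    out$noise_sweep <- sweep
  }
  out
}
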