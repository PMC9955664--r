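# The logic-tree reference classifier. Two ordered arms of pure predicates
# over a harmonized profile; the first true predicate on the entered arm is
# the exit branch and fixes the label. Participants who enter the sexual arm
# (gateway: any reported sexual activity or penetrative sexual abuse) but
# clear every sexual branch are re-run down the vertical arm restricted to
# the switcher-eligible branches; fall-through everywhere is "unclassified".
# Branch order within each arm is the printed exit order (strongest evidence
# first) and is fixed.

#' Branch registry of the logic tree
#'
#' The ordered branch definitions of both arms: id, arm, order index, the
#' label a branch confirms, whether it is offered to sexual-to-vertical
#' switchers, and a short description. Predicates (pure functions of a
#' harmonized profile row and a [tree_config()]) are carried in the
#' `predicate` attribute, indexed by branch id.
#'
#' Sexual arm: S1 sexual debut strictly before HIV diagnosis/ART initiation;
#' S2 history of penetrative sexual abuse; S3 discordant disclosure of sexual
#' debut; S4 consistent unprotected sex; S5 other risky sexual behaviour
#' (transactional sex, multiple partners, or a partner 5+ years older); S6
#' HIV-status awareness. Vertical arm: V1 maternal HIV/AIDS orphan; V2 mother
#' on ART or HIV-symptomatic; V3 presumed maternal orphan at age <= 10; V4
#' cognitive delay; V5 chronic poor physical health; V6 paternal HIV orphan
#' or father on ART; V7 presumed paternal orphan at age <= 10; V8 ART
#' initiated before the public rollout year; V9 first HIV test before age 10
#' in an ART-initiated participant; SLOW ART-naive with first HIV test before
#' age 10 (slow progressor). Only V1, V2, V3, V6 and V7 are offered to
#' switchers.
#'
#' @return data.frame with columns `branch_id`, `arm`, `order`, `label`,
#'   `available_to_switchers`, `description`, and a `predicate` attribute.
#' @export
moha_branches <- function() {
  ref_age <- function(p) {
    # the "diagnosis" reference: earlier of ART initiation and first HIV test
    v <- c(p$art_init_age, p$first_hiv_test_age)
    v <- v[!is.na(v)]
    if (length(v)) min(v) else NA_integer_
  }
  preds <- list(
    S1 = function(p, cfg) {
      r <- ref_age(p)
      !is.na(p$sexual_debut_age) && !is.na(r) && p$sexual_debut_age < r
    },
    S2 = function(p, cfg) isTRUE(p$ever_sexual_abuse),
    S3 = function(p, cfg) isTRUE(p$discordant_disclosure),
    S4 = function(p, cfg) isTRUE(p$consistent_unprotected_sex),
    S5 = function(p, cfg) isTRUE(p$other_risky_behaviour),
    S6 = function(p, cfg) isTRUE(p$hiv_status_aware),
    V1 = function(p, cfg) isTRUE(p$maternal_hiv_orphan),
    V2 = function(p, cfg) isTRUE(p$mother_on_art),
    V3 = function(p, cfg) isTRUE(p$maternal_orphan_le10_presumed),
    V4 = function(p, cfg) isTRUE(p$cognitive_delay),
    V5 = function(p, cfg) isTRUE(p$poor_physical_health),
    V6 = function(p, cfg) isTRUE(p$paternal_hiv_orphan_or_dad_art),
    V7 = function(p, cfg) isTRUE(p$paternal_orphan_le10_presumed),
    V8 = function(p, cfg) !is.na(p$art_init_year) &&
      p$art_init_year < cfg$art_rollout_year,
    V9 = function(p, cfg) !isTRUE(p$art_naive) &&
      !is.na(p$first_hiv_test_age) &&
      p$first_hiv_test_age < cfg$first_test_age_threshold,
    SLOW = function(p, cfg) isTRUE(p$art_naive) &&
      !is.na(p$first_hiv_test_age) &&
      p$first_hiv_test_age < cfg$first_test_age_threshold
  )
  df <- data.frame(
    branch_id = names(preds),
    arm = c(rep("sexual", 6), rep("vertical", 10)),
    order = c(1:6, 1:10),
    label = c(rep("sexual", 6), rep("vertical", 10)),
    available_to_switchers =
      names(preds) %in% c("V1", "V2", "V3", "V6", "V7"),
    description = c(
      "Sex before HIV+ diagnosis / initiating on ART",
      "History of sexual abuse",
      "Discordant sex disclosure",
      "Consistent unprotected sex",
      "Risky sex behaviour",
      "HIV+ status awareness",
      "Maternal HIV orphan",
      "Mom on ART",
      "Maternal orphan <=10yo",
      "Cognitive issues",
      "Chronic physical disability",
      "Paternal HIV orphan or dad on ART",
      "Paternal orphan <=10yo",
      "ART initiated before rollout year",
      "First HIV test age < threshold",
      "Slow progressor (ART naive, first test < threshold)"),
    stringsAsFactors = FALSE
  )
  attr(df, "predicate") <- preds
  df
}

# profiles as a list of plain per-participant lists (data.frame row
# subsetting is too slow for per-row predicate evaluation)
.profile_rows <- function(profiles) {
  cols <- as.list(profiles)
  lapply(seq_len(nrow(profiles)), function(i) lapply(cols, `[[`, i))
}

# logical matrix of all branch predicates over all profiles
.branch_matrix <- function(profiles, config, rows = NULL) {
  br <- moha_branches()
  preds <- attr(br, "predicate")
  if (is.null(rows)) rows <- .profile_rows(profiles)
  m <- matrix(FALSE, nrow = length(rows), ncol = nrow(br),
              dimnames = list(NULL, br$branch_id))
  for (j in seq_len(nrow(br))) {
    f <- preds[[br$branch_id[j]]]
    for (i in seq_along(rows)) {
      m[i, j] <- isTRUE(f(rows[[i]], config))
    }
  }
  m
}

#' Gateway decision: which arm a profile enters
#'
#' Sexual arm iff the participant ever reported sexual activity or
#' penetrative sexual abuse at any wave, or `config$force_sexual_gateway` is
#' set (the young-mothers variant, where the whole sample enters the sexual
#' arm); vertical arm otherwise.
#'
#' @param profile one-row harmonized profile.
#' @param config a [tree_config()].
#' @return `"sexual"` or `"vertical"`.
#' @export
gateway <- function(profile, config = tree_config()) {
  if (config$force_sexual_gateway ||
      isTRUE(profile$ever_sexual_activity) ||
      isTRUE(profile$ever_sexual_abuse)) "sexual" else "vertical"
}

.first_hit <- function(truth, branch_ids) {
  hit <- branch_ids[truth[branch_ids]]
  if (length(hit)) hit[1] else NA_character_
}

#' Run the sexual arm of the logic tree
#'
#' Evaluates the enabled sexual branches in exit order and returns the first
#' confirming branch, or `NULL` on fall-through (the profile then becomes a
#' candidate to switch to the vertical arm).
#'
#' @param profile one-row harmonized profile.
#' @param config a [tree_config()].
#' @return `list(label = "sexual", exit_branch =)` or `NULL`.
#' @export
run_sexual_arm <- function(profile, config = tree_config()) {
  br <- moha_branches()
  ids <- br$branch_id[br$arm == "sexual" &
                        br$branch_id %in% config$enabled_branches]
  preds <- attr(br, "predicate")
  for (id in ids) {
    if (isTRUE(preds[[id]](profile, config))) {
      return(list(label = "sexual", exit_branch = id))
    }
  }
  NULL
}

#' Run the vertical arm of the logic tree
#'
#' Evaluates the enabled vertical branches in exit order; for a switcher
#' (entered the sexual arm, cleared all its branches) only the
#' switcher-eligible branches V1, V2, V3, V6, V7 are offered.
#'
#' @param profile one-row harmonized profile.
#' @param config a [tree_config()].
#' @param switcher logical; `TRUE` when re-running a sexual-arm fall-through.
#' @return `list(label = "vertical", exit_branch =)` or `NULL`.
#' @export
run_vertical_arm <- function(profile, config = tree_config(),
                             switcher = FALSE) {
  br <- moha_branches()
  keep <- br$arm == "vertical" & br$branch_id %in% config$enabled_branches
  if (switcher) keep <- keep & br$available_to_switchers
  ids <- br$branch_id[keep]
  preds <- attr(br, "predicate")
  for (id in ids) {
    if (isTRUE(preds[[id]](profile, config))) {
      return(list(label = "vertical", exit_branch = id))
    }
  }
  NULL
}

#' Count affirmatory factors on an arm
#'
#' Number of the arm's enabled branch predicates (ignoring the switcher
#' restriction) evaluating true for the profile. Any classified participant
#' has a count of at least 1 (the exit branch itself).
#'
#' @param profile one-row harmonized profile.
#' @param arm `"sexual"` or `"vertical"`.
#' @param config a [tree_config()].
#' @return non-negative integer.
#' @export
count_affirmatory_factors <- function(profile, arm, config = tree_config()) {
  br <- moha_branches()
  ids <- br$branch_id[br$arm == arm &
                        br$branch_id %in% config$enabled_branches]
  preds <- attr(br, "predicate")
  sum(vapply(ids, function(id) isTRUE(preds[[id]](profile, config)),
             logical(1)))
}

#' Allocate mode of HIV acquisition by the logic tree
#'
#' Runs the gateway and the entered arm for every profile. Sexual-arm
#' fall-throughs switch to the vertical arm (switcher-restricted branches);
#' fall-through everywhere is `"unclassified"`. Countering factors — opposite
#' -arm predicates that are also true — are surfaced in `conflict_flags`
#' (semicolon-separated branch ids) for audit; they never change a label.
#'
#' @param profiles a `moha_profiles` data.frame or a single profile row.
#' @param config a [tree_config()].
#' @return data.frame of class `moha_allocations` with columns
#'   `participant_id`, `label` (`vertical`/`sexual`/`unclassified`),
#'   `arm_entered`, `exit_branch` (NA when unclassified), `switched`,
#'   `affirmatory_count`, `conflict_flags`.
#' @export
allocate_moha <- function(profiles, config = tree_config()) {
  br <- moha_branches()
  rows <- .profile_rows(profiles)
  m <- .branch_matrix(profiles, config, rows = rows)
  enabled <- intersect(br$branch_id, config$enabled_branches)
  sx_ids <- br$branch_id[br$arm == "sexual" & br$branch_id %in% enabled]
  vt_ids <- br$branch_id[br$arm == "vertical" & br$branch_id %in% enabled]
  vt_sw_ids <- vt_ids[br$available_to_switchers[match(vt_ids, br$branch_id)]]

  n <- nrow(profiles)
  label <- character(n); arm_entered <- character(n)
  exit_branch <- rep(NA_character_, n); switched <- logical(n)
  aff <- integer(n); conflicts <- character(n)

  for (i in seq_len(n)) {
    p <- rows[[i]]
    truth <- m[i, ]
    arm_entered[i] <- gateway(p, config)
    if (arm_entered[i] == "sexual") {
      hit <- .first_hit(truth, sx_ids)
      if (!is.na(hit)) {
        label[i] <- "sexual"; exit_branch[i] <- hit
      } else {
        hit <- .first_hit(truth, vt_sw_ids)
        if (!is.na(hit)) {
          label[i] <- "vertical"; exit_branch[i] <- hit; switched[i] <- TRUE
        } else label[i] <- "unclassified"
      }
    } else {
      hit <- .first_hit(truth, vt_ids)
      if (!is.na(hit)) {
        label[i] <- "vertical"; exit_branch[i] <- hit
      } else label[i] <- "unclassified"
    }
    if (label[i] %in% c("sexual", "vertical")) {
      own <- if (label[i] == "sexual") sx_ids else vt_ids
      other <- if (label[i] == "sexual") vt_ids else sx_ids
      aff[i] <- sum(truth[own])
      cf <- other[truth[other]]
      conflicts[i] <- paste(cf, collapse = ";")
    }
  }
  out <- data.frame(participant_id = profiles$participant_id,
                    label = label, arm_entered = arm_entered,
                    exit_branch = exit_branch, switched = switched,
                    affirmatory_count = aff, conflict_flags = conflicts,
                    stringsAsFactors = FALSE)
  class(out) <- c("moha_allocations", "data.frame")
  out
}

#' Exit-branch frequency table
#'
#' Counts of classified participants by exit branch and label, in branch
#' order, with per-label totals (conservation: totals equal the branch sums).
#'
#' @param allocations a `moha_allocations` data.frame.
#' @return data.frame with `label`, `exit_branch`, `n`; attribute `totals`
#'   holds per-label classified counts.
#' @export
exit_frequency_table <- function(allocations) {
  br <- moha_branches()
  cl <- allocations[allocations$label %in% c("sexual", "vertical"), ]
  rows <- do.call(rbind, lapply(seq_len(nrow(br)), function(j) {
    data.frame(label = br$label[j], exit_branch = br$branch_id[j],
               n = sum(cl$exit_branch == br$branch_id[j], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  attr(rows, "totals") <- c(sexual = sum(cl$label == "sexual"),
                            vertical = sum(cl$label == "vertical"),
                            unclassified = sum(allocations$label == "unclassified"))
  rows
}

#' Affirmatory-factor summary (Table-4 style)
#'
#' Per arm: number classified, arithmetic mean and sample standard deviation
#' (n-1 denominator) of the affirmatory-factor count; per branch: how many of
#' the arm's classified participants affirmed that factor, with percentage.
#' An arm with no classified participants is omitted with a message.
#'
#' @param allocations a `moha_allocations` data.frame.
#' @param profiles the matching `moha_profiles`.
#' @param config a [tree_config()].
#' @return list with data.frames `arms` (`arm`, `n`, `mean`, `sd`) and
#'   `factors` (`arm`, `branch_id`, `description`, `n`, `pct`).
#' @export
affirmatory_summary <- function(allocations, profiles,
                                config = tree_config()) {
  br <- moha_branches()
  m <- .branch_matrix(profiles, config)
  idx <- match(allocations$participant_id, profiles$participant_id)
  arms <- list(); factors <- list()
  for (arm in c("sexual", "vertical")) {
    sel <- allocations$label == arm
    if (!any(sel)) {
      message("no participants classified ", arm, "; arm omitted from summary")
      next
    }
    counts <- allocations$affirmatory_count[sel]
    arms[[arm]] <- data.frame(
      arm = arm, n = sum(sel), mean = mean(counts),
      sd = if (sum(sel) > 1) stats::sd(counts) else NA_real_)
    ids <- br$branch_id[br$arm == arm & br$branch_id %in% config$enabled_branches]
    sub <- m[idx[sel], ids, drop = FALSE]
    factors[[arm]] <- data.frame(
      arm = arm, branch_id = ids,
      description = br$description[match(ids, br$branch_id)],
      n = colSums(sub),
      pct = round_half_up(100 * colSums(sub) / sum(sel), 1),
      stringsAsFactors = FALSE)
  }
  list(arms = do.call(rbind, c(arms, list(make.row.names = FALSE))),
       factors = do.call(rbind, c(factors, list(make.row.names = FALSE))))
}
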