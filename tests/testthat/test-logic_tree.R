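# The logic-tree reference classifier.

cfg <- tree_config()

test_that("gateway routes on sexual activity, abuse, or the forced variant", {
  expect_equal(gateway(blank_profile(), cfg), "vertical")
  expect_equal(gateway(blank_profile(ever_sexual_activity = TRUE), cfg),
               "sexual")
  expect_equal(gateway(blank_profile(ever_sexual_abuse = TRUE), cfg),
               "sexual")
  mothers <- tree_config(mothers_variant = TRUE)
  expect_equal(gateway(blank_profile(), mothers), "sexual")
})

test_that("sexual arm exits in order S1..S6; fall-through returns NULL", {
  # S1: debut strictly before the earlier of ART initiation and first test
  p <- blank_profile(sexual_debut_age = 13L, art_init_age = 15L,
                     ever_sexual_activity = TRUE)
  expect_equal(run_sexual_arm(p, cfg)$exit_branch, "S1")
  # the diagnosis reference is the EARLIER of init and first test
  p$first_hiv_test_age <- 12L
  expect_null(run_sexual_arm(p, cfg))                 # 13 not < 12
  p$first_hiv_test_age <- 14L
  expect_equal(run_sexual_arm(p, cfg)$exit_branch, "S1")
  # S2 without any debut age
  p <- blank_profile(ever_sexual_abuse = TRUE)
  expect_equal(run_sexual_arm(p, cfg)$exit_branch, "S2")
  # later branches
  expect_equal(run_sexual_arm(blank_profile(discordant_disclosure = TRUE),
                              cfg)$exit_branch, "S3")
  expect_equal(run_sexual_arm(blank_profile(consistent_unprotected_sex = TRUE),
                              cfg)$exit_branch, "S4")
  expect_equal(run_sexual_arm(blank_profile(other_risky_behaviour = TRUE),
                              cfg)$exit_branch, "S5")
  expect_equal(run_sexual_arm(blank_profile(hiv_status_aware = TRUE),
                              cfg)$exit_branch, "S6")
  # order: an earlier branch wins
  p <- blank_profile(ever_sexual_abuse = TRUE, hiv_status_aware = TRUE)
  expect_equal(run_sexual_arm(p, cfg)$exit_branch, "S2")
  expect_null(run_sexual_arm(blank_profile(), cfg))
})

test_that("vertical arm exits in order; switchers see only V1,V2,V3,V6,V7", {
  expect_equal(run_vertical_arm(blank_profile(maternal_hiv_orphan = TRUE),
                                cfg)$exit_branch, "V1")
  expect_equal(run_vertical_arm(blank_profile(mother_on_art = TRUE),
                                cfg)$exit_branch, "V2")
  expect_equal(
    run_vertical_arm(blank_profile(art_init_year = 2003L), cfg)$exit_branch,
    "V8")
  expect_equal(
    run_vertical_arm(blank_profile(first_hiv_test_age = 8L), cfg)$exit_branch,
    "V9")
  # switcher restriction: V4 (cognitive delay) is not offered to switchers
  p <- blank_profile(cognitive_delay = TRUE)
  expect_equal(run_vertical_arm(p, cfg, switcher = FALSE)$exit_branch, "V4")
  expect_null(run_vertical_arm(p, cfg, switcher = TRUE))
  for (b in c("V5", "V8", "V9")) {
    p <- switch(b,
                V5 = blank_profile(poor_physical_health = TRUE),
                V8 = blank_profile(art_init_year = 2000L),
                V9 = blank_profile(first_hiv_test_age = 5L))
    expect_null(run_vertical_arm(p, cfg, switcher = TRUE), label = b)
  }
  p <- blank_profile(paternal_orphan_le10_presumed = TRUE)
  expect_equal(run_vertical_arm(p, cfg, switcher = TRUE)$exit_branch, "V7")
})

test_that("slow progressors: ART naive with an early first test", {
  p <- blank_profile(art_naive = TRUE, first_hiv_test_age = 8L)
  expect_equal(run_vertical_arm(p, cfg)$exit_branch, "SLOW")
  # V9 is reserved for ART-initiated profiles, so SLOW is reachable
  p_init <- blank_profile(art_naive = FALSE, first_hiv_test_age = 8L)
  expect_equal(run_vertical_arm(p_init, cfg)$exit_branch, "V9")
  # at or past the threshold age: neither fires
  p$first_hiv_test_age <- 10L
  expect_null(run_vertical_arm(p, cfg))
})

test_that("allocate_moha: arms, switching, conflicts, unclassified", {
  profs <- rbind(
    # sexual with a countering vertical factor: label stays sexual,
    # conflict surfaced
    blank_profile("sx", ever_sexual_activity = TRUE, sexual_debut_age = 13L,
                  art_init_age = 15L, maternal_hiv_orphan = TRUE),
    # no informative factor at all
    blank_profile("none"),
    # gateway-vertical, mother on ART
    blank_profile("v2", mother_on_art = TRUE),
    # enters sexual arm, clears it, switches and exits V1
    blank_profile("switch", ever_sexual_activity = TRUE,
                  sexual_debut_age = 16L, art_init_age = 5L,
                  maternal_hiv_orphan = TRUE),
    # enters sexual arm, clears it, only non-switcher vertical evidence
    blank_profile("stuck", ever_sexual_activity = TRUE,
                  sexual_debut_age = 16L, art_init_age = 5L,
                  cognitive_delay = TRUE))
  al <- allocate_moha(profs, cfg)
  expect_equal(al$label, c("sexual", "unclassified", "vertical", "vertical",
                           "unclassified"))
  expect_equal(al$exit_branch, c("S1", NA, "V2", "V1", NA))
  expect_equal(al$arm_entered, c("sexual", "vertical", "vertical", "sexual",
                                 "sexual"))
  expect_equal(al$switched, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_match(al$conflict_flags[1], "V1")
  # unclassified iff exit branch absent; switched implies vertical via sexual
  expect_equal(is.na(al$exit_branch), al$label == "unclassified")
  expect_true(all(al$label[al$switched] == "vertical"))
  expect_true(all(al$arm_entered[al$switched] == "sexual"))
})

test_that("affirmatory counts are pure predicate sums on the final arm", {
  p <- blank_profile(ever_sexual_activity = TRUE, sexual_debut_age = 13L,
                     art_init_age = 15L, consistent_unprotected_sex = TRUE,
                     hiv_status_aware = TRUE)
  expect_equal(count_affirmatory_factors(p, "sexual", cfg), 3L)  # S1,S4,S6
  # V1 and V2 both count even though jointly impossible in real data
  p <- blank_profile(maternal_hiv_orphan = TRUE, mother_on_art = TRUE)
  expect_equal(count_affirmatory_factors(p, "vertical", cfg), 2L)
  al <- allocate_moha(p, cfg)
  expect_equal(al$affirmatory_count, 2L)
  expect_equal(al$exit_branch, "V1")
  # any classified participant affirms at least the exit branch
  expect_gte(al$affirmatory_count, 1L)
})

test_that("first-hit semantics: branches after the exit are irrelevant", {
  set.seed(7)
  syn <- generate_cohort(synthetic_config(n = 120, seed = 7))
  profiles <- harmonize_cohort(syn$cohort, cfg)
  al <- allocate_moha(profiles, cfg)
  br <- moha_branches()
  for (i in which(!is.na(al$exit_branch))[1:40]) {
    exit <- al$exit_branch[i]
    arm <- br$arm[br$branch_id == exit]
    later <- br$branch_id[br$arm == arm & br$order > br$order[br$branch_id == exit]]
    if (length(later) == 0) next
    cfg_cut <- cfg
    cfg_cut$enabled_branches <- setdiff(cfg$enabled_branches, later)
    al_cut <- allocate_moha(profiles[i, , drop = FALSE], cfg_cut)
    expect_equal(al_cut$label, al$label[i])
    expect_equal(al_cut$exit_branch, exit)
  }
})

test_that("determinism: same profiles and config give the same allocation", {
  syn <- generate_cohort(synthetic_config(n = 60, seed = 11))
  profiles <- harmonize_cohort(syn$cohort, cfg)
  expect_identical(allocate_moha(profiles, cfg), allocate_moha(profiles, cfg))
})

test_that("labels partition the cohort; switcher exits are the starred set", {
  syn <- generate_cohort(synthetic_config(n = 250, noise_rate = 0.15,
                                          seed = 13))
  profiles <- harmonize_cohort(syn$cohort, cfg)
  al <- allocate_moha(profiles, cfg)
  expect_true(all(al$label %in% c("vertical", "sexual", "unclassified")))
  expect_equal(nrow(al), nrow(profiles))
  expect_true(all(al$exit_branch[al$switched] %in%
                    c("V1", "V2", "V3", "V6", "V7")))
  tab <- exit_frequency_table(al)
  totals <- attr(tab, "totals")
  expect_equal(sum(tab$n[tab$label == "sexual"]), unname(totals["sexual"]))
  expect_equal(sum(tab$n[tab$label == "vertical"]), unname(totals["vertical"]))
  expect_equal(sum(totals), nrow(al))
})

test_that("exit_frequency_table counts by branch", {
  al <- data.frame(participant_id = c("a", "b", "c"),
                   label = c("sexual", "sexual", "vertical"),
                   arm_entered = c("sexual", "sexual", "vertical"),
                   exit_branch = c("S1", "S1", "V1"),
                   switched = FALSE, affirmatory_count = 1L,
                   conflict_flags = "", stringsAsFactors = FALSE)
  tab <- exit_frequency_table(al)
  expect_equal(tab$n[tab$exit_branch == "S1"], 2L)
  expect_equal(tab$n[tab$exit_branch == "V1"], 1L)
  expect_equal(sum(tab$n), 3L)
})

test_that("affirmatory_summary: means, sample SD, per-factor counts", {
  profs <- rbind(
    blank_profile("a", maternal_hiv_orphan = TRUE, mother_on_art = TRUE,
                  cognitive_delay = TRUE),
    blank_profile("b", maternal_hiv_orphan = TRUE, cognitive_delay = TRUE),
    blank_profile("c", mother_on_art = TRUE))
  al <- allocate_moha(profs, cfg)
  s <- affirmatory_summary(al, profs, cfg)
  row <- s$arms[s$arms$arm == "vertical", ]
  expect_equal(row$n, 3L)
  expect_equal(row$mean, 2.0)      # counts {3, 2, 1}
  expect_equal(row$sd, 1.0)        # sample SD, n-1 denominator
  f <- s$factors[s$factors$arm == "vertical", ]
  expect_equal(f$n[f$branch_id == "V1"], 2)
  expect_equal(f$n[f$branch_id == "V4"], 2)
  expect_equal(f$pct[f$branch_id == "V2"], 66.7)
  # zero-variance arm
  profs0 <- rbind(blank_profile("x", mother_on_art = TRUE),
                  blank_profile("y", mother_on_art = TRUE))
  s0 <- suppressMessages(
    affirmatory_summary(allocate_moha(profs0, cfg), profs0, cfg))
  expect_equal(s0$arms$mean[s0$arms$arm == "vertical"], 1.0)
  expect_equal(s0$arms$sd[s0$arms$arm == "vertical"], 0.0)
  # an empty arm is omitted with a message
  expect_message(s1 <- affirmatory_summary(allocate_moha(profs0, cfg),
                                           profs0, cfg), "sexual")
  expect_false("sexual" %in% s1$arms$arm)
})

test_that("mothers variant disables S3/V3/V7 and forces the sexual gateway", {
  mothers_cfg <- tree_config(mothers_variant = TRUE)
  expect_false(any(c("S3", "V3", "V7") %in% mothers_cfg$enabled_branches))
  # a profile whose only evidence sits on disabled branches -> unclassified
  p <- blank_profile(ever_sexual_activity = TRUE,
                     discordant_disclosure = TRUE,
                     maternal_orphan_le10_presumed = TRUE,
                     paternal_orphan_le10_presumed = TRUE)
  al <- allocate_moha(p, mothers_cfg)
  expect_equal(al$label, "unclassified")
  expect_equal(al$arm_entered, "sexual")   # forced gateway
  # same profile under the cohort config exits S3
  expect_equal(allocate_moha(p, cfg)$exit_branch, "S3")
})
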