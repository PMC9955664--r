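# Age-at-ART-initiation cutoff classifier. Boundary convention: initiation
# strictly before the cutoff age is vertical; AT the cutoff age or older is
# sexual. This is deliberate and load-bearing — an off-by-one here shifts
# every downstream validation metric.

#' Allocate mode of acquisition by an ART-initiation-age cutoff
#'
#' @param profiles a `moha_profiles` data.frame ([harmonize_cohort()]).
#' @param cutoff_age integer cutoff in years.
#' @return data.frame with `participant_id`, `cutoff_age`, and `label` in
#'   `c("vertical", "sexual", "missing")`; `missing` iff `art_init_age` is
#'   absent.
#' @export
#' @examples
#' prof <- data.frame(participant_id = c("a", "b", "c"),
#'                    art_init_age = c(9L, 10L, NA))
#' allocate_by_cutoff(prof, 10)$label
allocate_by_cutoff <- function(profiles, cutoff_age) {
  age <- profiles$art_init_age
  label <- ifelse(is.na(age), "missing",
                  ifelse(age < cutoff_age, "vertical", "sexual"))
  data.frame(participant_id = profiles$participant_id,
             cutoff_age = as.integer(cutoff_age),
             label = label,
             stringsAsFactors = FALSE)
}

#' Allocate all configured cutoffs
#'
#' One allocation row per (participant, cutoff age).
#'
#' @param profiles a `moha_profiles` data.frame.
#' @param config a [tree_config()]; `config$cutoff_ages` is the cutoff list.
#' @return data.frame as in [allocate_by_cutoff()], stacked over cutoffs,
#'   with a `summary` attribute giving per-cutoff vertical/sexual/missing
#'   counts.
#' @export
allocate_all_cutoffs <- function(profiles, config = tree_config()) {
  out <- do.call(rbind, lapply(config$cutoff_ages, function(a) {
    allocate_by_cutoff(profiles, a)
  }))
  rownames(out) <- NULL
  tab <- do.call(rbind, lapply(split(out, out$cutoff_age), function(d) {
    data.frame(cutoff_age = d$cutoff_age[1],
               vertical = sum(d$label == "vertical"),
               sexual = sum(d$label == "sexual"),
               missing = sum(d$label == "missing"))
  }))
  rownames(tab) <- NULL
  attr(out, "summary") <- tab
  out
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value (0.0005 -> 0.001),
#' the convention used for all reported proportions; base `round()` rounds
#' ties to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Label shares for a Table-2 style allocation summary
#'
#' Counts and percentage shares (to one decimal, half-up) of each label among
#' a vector of allocation labels, denominator the full vector length
#' (unclassified/missing included in the denominator, as in cohort reporting).
#'
#' @param labels character vector of labels.
#' @return data.frame with `label`, `n`, `pct`.
#' @export
#' @examples
#' allocation_summary(c("vertical", "vertical", "sexual", "unclassified"))
allocation_summary <- function(labels) {
  tab <- table(labels)
  data.frame(label = names(tab),
             n = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / length(labels), 1),
             stringsAsFactors = FALSE)
}
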