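# Exact scenario operating characteristics, all derived from the
# enumerated pathway distribution. Every quantity is a finite sum over
# pathways weighted by exact occurrence probabilities — no simulation and
# no approximation is involved.

pw_probs <- function(ps) vapply(ps$pathways, `[[`, numeric(1), "probability")
pw_n     <- function(ps) vapply(ps$pathways, function(p) as.numeric(p$n),
                                numeric(1))
pw_dlts  <- function(ps) vapply(ps$pathways,
                                function(p) as.numeric(p$total_dlts),
                                numeric(1))
pw_npat_matrix <- function(ps) {
  matrix(unlist(lapply(ps$pathways,
                       function(p) as.numeric(p$patients_per_dose))),
         ncol = ps$scenario$n_doses, byrow = TRUE)
}
pw_ndlt_matrix <- function(ps) {
  matrix(unlist(lapply(ps$pathways,
                       function(p) as.numeric(p$dlts_per_dose))),
         ncol = ps$scenario$n_doses, byrow = TRUE)
}

#' Exact distribution of the total trial sample size
#'
#' Aggregates pathway probabilities by total number of patients treated.
#'
#' @param ps A `"pathway_set"` from [enumerate_pathways()].
#' @return A data frame with columns `n` (attainable total sample sizes,
#'   ascending) and `prob`; probabilities sum to one.
#' @export
sample_size_distribution <- function(ps) {
  stopifnot(inherits(ps, "pathway_set"))
  pr <- pw_probs(ps); n <- pw_n(ps)
  agg <- tapply(pr, n, sum)
  out <- data.frame(n = as.integer(names(agg)), prob = as.numeric(agg))
  out[order(out$n), , drop = FALSE]
}

#' Exact experimentation percentages per dose level
#'
#' For each dose the expected within-trial proportion of patients treated
#' there, as a percentage: \eqn{100 \sum_\omega \Pr(\omega)\, n_j(\omega) /
#' N(\omega)}, summing over pathways \eqn{\omega}. Because each pathway's
#' per-dose proportions sum to one, the percentages sum to 100 across
#' doses. This is the exact pathway-weighted definition, not the ratio of
#' expectations \eqn{E[n_j]/E[N]} used by approximate approaches.
#'
#' @param ps A `"pathway_set"` from [enumerate_pathways()].
#' @return Numeric vector of percentages, one per dose level.
#' @export
experimentation_pct <- function(ps) {
  stopifnot(inherits(ps, "pathway_set"))
  pr <- pw_probs(ps); n <- pw_n(ps)
  100 * colSums(pw_npat_matrix(ps) * (pr / n))
}

#' Exact MTD recommendation distribution
#'
#' Probability (as a percentage) that each dose is recommended as the MTD,
#' plus the two no-MTD categories: the trial stopping with no dose deemed
#' safe (`none_too_toxic`) and the trial escalating past the top dose with
#' every dose tolerated (`all_tolerated`). The full set of percentages sums
#' to 100. `fold_all_tolerated` controls how the latter category is
#' reported: as its own row (default), folded into the top dose's
#' recommendation percentage, or folded into the no-MTD category.
#'
#' @param ps A `"pathway_set"` from [enumerate_pathways()].
#' @param fold_all_tolerated One of `"separate"`, `"top_dose"`, `"no_mtd"`.
#' @return A data frame with columns `category` (`"dose_1"`, ...,
#'   `"none_too_toxic"`, `"all_tolerated"`), `dose` (index or `NA`) and
#'   `pct`.
#' @export
mtd_distribution <- function(ps, fold_all_tolerated = c("separate",
                                                        "top_dose",
                                                        "no_mtd")) {
  stopifnot(inherits(ps, "pathway_set"))
  fold_all_tolerated <- match.arg(fold_all_tolerated)
  J <- ps$scenario$n_doses
  pr <- pw_probs(ps)
  outc <- vapply(ps$pathways, `[[`, character(1), "outcome")
  mtd <- vapply(ps$pathways, function(p) as.integer(p$mtd), integer(1))
  sel <- vapply(seq_len(J), function(j)
    sum(pr[outc == "selected" & !is.na(mtd) & mtd == j]), numeric(1))
  p_safety <- sum(pr[outc == "none_too_toxic"])
  p_all <- sum(pr[outc == "all_tolerated"])
  if (fold_all_tolerated == "top_dose") {
    sel[J] <- sel[J] + p_all; p_all <- 0
  } else if (fold_all_tolerated == "no_mtd") {
    p_safety <- p_safety + p_all; p_all <- 0
  }
  out <- data.frame(
    category = c(paste0("dose_", seq_len(J)), "none_too_toxic",
                 "all_tolerated"),
    dose = c(seq_len(J), NA_integer_, NA_integer_),
    pct = 100 * c(sel, p_safety, p_all),
    stringsAsFactors = FALSE)
  if (fold_all_tolerated != "separate")
    out <- out[out$category != "all_tolerated", , drop = FALSE]
  out
}

#' Expected toxicity level (ETL)
#'
#' The expected true DLT probability of the dose selected as the MTD,
#' conditional on an MTD being declared:
#' \eqn{\sum_j p_j \Pr(\mathrm{MTD} = d_j) / \sum_j \Pr(\mathrm{MTD} =
#' d_j)}. By default trials that escalate past the top dose with every dose
#' tolerated are counted as declaring the top dose the MTD
#' (`fold_all_tolerated = TRUE`); set `FALSE` to condition strictly on an
#' interior selection. Errors when no pathway declares an MTD (the
#' conditional expectation is then undefined).
#'
#' @param ps A `"pathway_set"` from [enumerate_pathways()].
#' @param fold_all_tolerated Count full escalation past the top dose as
#'   selecting the top dose (default `TRUE`).
#' @return A probability in \[0, 1\].
#' @export
expected_toxicity_level <- function(ps, fold_all_tolerated = TRUE) {
  stopifnot(inherits(ps, "pathway_set"))
  md <- mtd_distribution(ps, fold_all_tolerated =
                           if (fold_all_tolerated) "top_dose" else "separate")
  sel <- md$pct[!is.na(md$dose)] / 100
  if (sum(sel) <= 0)
    stop("ETL is undefined: no pathway selects an MTD", call. = FALSE)
  sum(ps$scenario$dlt_probs * sel) / sum(sel)
}

#' Expected overall toxicity rate (EOTR)
#'
#' The expected proportion of trial patients experiencing a DLT. The
#' default (`"ratio_of_expectations"`) is the expected total number of
#' DLTs divided by the expected total sample size,
#' \eqn{E[\mathrm{DLTs}] / E[N]} — the overall DLT rate across a long run
#' of identical trials. The alternative `"per_trial"` averages the
#' within-trial rate pathway by pathway,
#' \eqn{\sum_\omega \Pr(\omega)\, \mathrm{DLTs}(\omega) / N(\omega)}; the
#' two differ slightly because the sample size is random.
#'
#' @param ps A `"pathway_set"` from [enumerate_pathways()].
#' @param method `"ratio_of_expectations"` (default) or `"per_trial"`.
#' @return A probability in \[0, 1\].
#' @export
eotr <- function(ps, method = c("ratio_of_expectations", "per_trial")) {
  stopifnot(inherits(ps, "pathway_set"))
  method <- match.arg(method)
  pr <- pw_probs(ps)
  if (method == "per_trial") sum(pr * pw_dlts(ps) / pw_n(ps))
  else sum(pr * pw_dlts(ps)) / sum(pr * pw_n(ps))
}

#' Expected number of DLTs in the trial
#'
#' @param ps A `"pathway_set"` from [enumerate_pathways()].
#' @return The pathway-probability-weighted mean of the total DLT count.
#' @export
mean_dlts <- function(ps) {
  stopifnot(inherits(ps, "pathway_set"))
  sum(pw_probs(ps) * pw_dlts(ps))
}

#' Exact distribution of the within-trial DLT rate
#'
#' Aggregates pathway probability by the exact rational rate
#' `total_dlts / n`. Rates are reported as numeric values; pathways whose
#' rates are equal as rationals (e.g. 1/3 and 2/6) are pooled.
#'
#' @param ps A `"pathway_set"` from [enumerate_pathways()].
#' @return A data frame with columns `rate` (ascending) and `prob`;
#'   probabilities sum to one.
#' @export
dlt_rate_distribution <- function(ps) {
  stopifnot(inherits(ps, "pathway_set"))
  pr <- pw_probs(ps)
  rate <- pw_dlts(ps) / pw_n(ps)
  key <- sprintf("%.15g", rate)
  agg <- tapply(pr, key, sum)
  rt <- vapply(names(agg), as.numeric, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(rate = rt, prob = as.numeric(agg))
  out[order(out$rate), , drop = FALSE]
}

# Bin index for the true-DLT-probability intervals
# [0,0.2], (0.2,0.4], (0.4,0.6], (0.6,0.8], (0.8,1]. The first bin is
# closed on the left; every bin is closed on the right.
tox_interval_bin <- function(p) {
  # small guard so that 0.8 / 0.2 = 4.0000000000000009 still lands in bin 4
  ifelse(p <= 0.2, 1L, pmin(5L, as.integer(ceiling(p / 0.2 - 1e-9))))
}

#' Experimentation and recommendation percentages by toxicity interval
#'
#' Sums per-dose experimentation and MTD recommendation percentages over
#' doses whose true DLT probability falls in each of the intervals
#' \[0, 0.2\], (0.2, 0.4\], (0.4, 0.6\], (0.6, 0.8\] and (0.8, 1\]. A
#' probability exactly on a boundary belongs to the lower interval (each
#' interval is closed on the right).
#'
#' @param ocs A `"scenario_ocs"` object from [operating_characteristics()].
#' @return A data frame with columns `interval`, `experimentation_pct`,
#'   `recommendation_pct`.
#' @export
interval_summaries <- function(ocs) {
  stopifnot(inherits(ocs, "scenario_ocs"))
  bins <- tox_interval_bin(ocs$dose_table$true_dlt_prob)
  labels <- c("[0,0.2]", "(0.2,0.4]", "(0.4,0.6]", "(0.6,0.8]", "(0.8,1]")
  exp_b <- vapply(1:5, function(b)
    sum(ocs$dose_table$experimentation_pct[bins == b]), numeric(1))
  rec_b <- vapply(1:5, function(b)
    sum(ocs$dose_table$recommendation_pct[bins == b]), numeric(1))
  data.frame(interval = labels, experimentation_pct = exp_b,
             recommendation_pct = rec_b, stringsAsFactors = FALSE)
}

#' Compute all exact scenario operating characteristics
#'
#' Convenience wrapper that derives every scenario-dependent operating
#' characteristic from one pathway enumeration: the sample-size
#' distribution, per-dose experimentation and MTD recommendation
#' percentages with expected patient and DLT counts, the probabilities of
#' the two no-MTD outcomes, the ETL, the EOTR, the mean number of DLTs,
#' the DLT-rate distribution and the toxicity-interval summaries.
#'
#' @param ps A `"pathway_set"` from [enumerate_pathways()], or arguments
#'   `design` and `scenario` to enumerate one.
#' @param design,scenario Alternative to `ps`: an [ab_design()] and a
#'   [tox_scenario()] to be enumerated first.
#' @return An object of class `"scenario_ocs"`: a list with elements
#'   `dose_table` (per-dose data frame), `sample_size` (distribution),
#'   `dlt_rates` (distribution), `intervals` (interval summaries),
#'   `prob_no_mtd_safety`, `prob_all_tolerated`, `etl` (or `NA` if no
#'   pathway declares an MTD), `eotr` (ratio of expectations),
#'   `eotr_per_trial`, `mean_dlts`, `expected_n`, plus the `design`,
#'   `scenario` and pathway count.
#' @examples
#' ocs <- operating_characteristics(
#'   design = ab_design(3, 3, 1, 1, 1),
#'   scenario = tox_scenario(c(0.05, 0.10, 0.33, 0.60)))
#' ocs
#' @export
operating_characteristics <- function(ps = NULL, design = NULL,
                                      scenario = NULL) {
  if (is.null(ps)) {
    if (is.null(design) || is.null(scenario))
      stop("supply either 'ps' or both 'design' and 'scenario'",
           call. = FALSE)
    ps <- enumerate_pathways(design, scenario)
  }
  stopifnot(inherits(ps, "pathway_set"))
  J <- ps$scenario$n_doses
  pr <- pw_probs(ps)
  npat <- pw_npat_matrix(ps)
  ndlt <- pw_ndlt_matrix(ps)
  md <- mtd_distribution(ps)
  dose_table <- data.frame(
    dose = seq_len(J),
    true_dlt_prob = ps$scenario$dlt_probs,
    experimentation_pct = experimentation_pct(ps),
    recommendation_pct = md$pct[!is.na(md$dose)],
    expected_patients = colSums(npat * pr),
    expected_dlts = colSums(ndlt * pr))
  p_sel <- sum(dose_table$recommendation_pct) / 100
  out <- structure(list(
    design = ps$design,
    scenario = ps$scenario,
    n_pathways = length(ps$pathways),
    dose_table = dose_table,
    sample_size = sample_size_distribution(ps),
    dlt_rates = dlt_rate_distribution(ps),
    prob_no_mtd_safety = md$pct[md$category == "none_too_toxic"] / 100,
    prob_all_tolerated = md$pct[md$category == "all_tolerated"] / 100,
    etl = if (p_sel > 0 || md$pct[md$category == "all_tolerated"] > 0)
      expected_toxicity_level(ps) else NA_real_,
    eotr = eotr(ps),
    eotr_per_trial = eotr(ps, method = "per_trial"),
    mean_dlts = mean_dlts(ps),
    expected_n = sum(pr * pw_n(ps))), class = "scenario_ocs")
  out$intervals <- interval_summaries(out)
  out
}

#' @export
print.scenario_ocs <- function(x, ...) {
  cat(sprintf("Exact operating characteristics (%d pathways)\n",
              x$n_pathways))
  cat(sprintf("  design %d+%d {%d,%d,%d,%d,%d}, de-escalation %s\n",
              x$design$A, x$design$B, x$design$A, x$design$B, x$design$C,
              x$design$D, x$design$E,
              if (x$design$deescalate) "permitted" else "not permitted"))
  tab <- x$dose_table
  tab$experimentation_pct <- round_half_away(tab$experimentation_pct, 1)
  tab$recommendation_pct <- round_half_away(tab$recommendation_pct, 1)
  tab$expected_patients <- round_half_away(tab$expected_patients, 2)
  tab$expected_dlts <- round_half_away(tab$expected_dlts, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("  P(no MTD, safety) = %.1f%%   P(all doses tolerated) = %.1f%%\n",
              100 * x$prob_no_mtd_safety, 100 * x$prob_all_tolerated))
  cat(sprintf("  ETL = %.3f   EOTR = %.3f   mean DLTs = %.2f   E[N] = %.2f\n",
              x$etl, x$eotr, x$mean_dlts, x$expected_n))
  invisible(x)
}
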