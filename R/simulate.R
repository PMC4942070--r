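# Monte-Carlo trial simulator. Serves as an independent stochastic
# cross-check of the exact pathway enumeration: each simulated trial draws
# cohort DLT counts from the binomial at the current dose and applies the
# same decision functions (stage1_decision / stage2_decision /
# determine_mtd) as the exact engine, so any systematic disagreement
# between empirical and exact operating characteristics indicates a bug.

#' Simulate a single A+B trial
#'
#' Draws one trial realisation under the design and scenario: cohort DLT
#' counts are binomial draws at each dose visited, and escalation,
#' expansion, halting and de-escalation follow [stage1_decision()],
#' [stage2_decision()] and [determine_mtd()]. Uses R's current RNG stream;
#' call [set.seed()] for reproducibility.
#'
#' @param design An [ab_design()] object.
#' @param scenario A [tox_scenario()] object.
#' @return A `"trial_pathway"` object with the same structure as those from
#'   [enumerate_pathways()], except that `probability` is `NA` (it can be
#'   recomputed with [pathway_probability()]).
#' @examples
#' set.seed(1)
#' simulate_trial(ab_design(3, 3, 1, 1, 1),
#'                tox_scenario(c(0.05, 0.10, 0.33, 0.60)))
#' @export
simulate_trial <- function(design, scenario) {
  stopifnot(inherits(design, "ab_design"), inherits(scenario, "tox_scenario"))
  tr <- sim_trial_core(design, scenario)
  structure(list(
    cohorts = data.frame(dose = tr$dose_seq, size = tr$size_seq,
                         dlts = tr$dlt_seq, phase = tr$phase_seq,
                         stringsAsFactors = FALSE),
    probability = NA_real_,
    outcome = tr$outcome,
    mtd = tr$mtd,
    n = sum(tr$npat),
    total_dlts = sum(tr$ndlt),
    patients_per_dose = tr$npat,
    dlts_per_dose = tr$ndlt), class = "trial_pathway")
}

# Single-trial simulation core (no data-frame assembly; used by both
# simulate_trial and estimate_ocs so the decision code is exercised
# identically either way).
sim_trial_core <- function(design, scenario) {
  A <- design$A; B <- design$B
  J <- scenario$n_doses
  p <- scenario$dlt_probs
  npat <- integer(J); ndlt <- integer(J)
  dose_seq <- integer(0); size_seq <- integer(0); dlt_seq <- integer(0)
  phase_seq <- character(0)
  j <- 1L
  halt_dose <- NA_integer_
  repeat {
    x <- stats::rbinom(1L, A, p[j])
    npat[j] <- npat[j] + A; ndlt[j] <- ndlt[j] + x
    dose_seq <- c(dose_seq, j); size_seq <- c(size_seq, A)
    dlt_seq <- c(dlt_seq, x); phase_seq <- c(phase_seq, "escalation")
    dec <- stage1_decision(design, x)
    if (dec == "expand") {
      z <- stats::rbinom(1L, B, p[j])
      npat[j] <- npat[j] + B; ndlt[j] <- ndlt[j] + z
      dose_seq <- c(dose_seq, j); size_seq <- c(size_seq, B)
      dlt_seq <- c(dlt_seq, z); phase_seq <- c(phase_seq, "escalation")
      dec <- stage2_decision(design, ndlt[j])
    }
    if (dec == "escalate") {
      if (j == J) break             # escalated past the top dose
      j <- j + 1L
    } else {                        # halt
      halt_dose <- j
      break
    }
  }
  res <- determine_mtd(design, halt_dose, npat, ndlt,
                       expand = function(k) stats::rbinom(1L, B, p[k]))
  ec <- res$extra_cohorts
  if (nrow(ec)) {
    dose_seq <- c(dose_seq, ec$dose); size_seq <- c(size_seq, ec$size)
    dlt_seq <- c(dlt_seq, ec$dlts)
    phase_seq <- c(phase_seq, rep("deescalation", nrow(ec)))
    for (i in seq_len(nrow(ec))) {
      npat[ec$dose[i]] <- npat[ec$dose[i]] + ec$size[i]
      ndlt[ec$dose[i]] <- ndlt[ec$dose[i]] + ec$dlts[i]
    }
  }
  list(dose_seq = dose_seq, size_seq = size_seq, dlt_seq = dlt_seq,
       phase_seq = phase_seq, outcome = res$outcome, mtd = res$mtd,
       npat = npat, ndlt = ndlt)
}

#' Estimate operating characteristics by Monte-Carlo simulation
#'
#' Simulates `n_sims` independent trials and returns empirical analogues of
#' the exact operating characteristics together with standard errors:
#' per-dose experimentation proportions (mean of within-trial proportions)
#' and MTD recommendation proportions, the no-MTD outcome proportions, the
#' empirical ETL, EOTR and mean DLT count, and the empirical sample-size
#' and DLT-rate distributions. Standard errors are the usual
#' \eqn{s/\sqrt{n}} for means and \eqn{\sqrt{\hat q(1-\hat q)/n}} for
#' proportions.
#'
#' @param design An [ab_design()] object.
#' @param scenario A [tox_scenario()] object.
#' @param n_sims Number of simulated trials (>= 1).
#' @param seed Optional integer seed; if supplied, [set.seed()] is called.
#' @return An object of class `"mc_ocs"`: a list with `dose_table` (columns
#'   `dose`, `experimentation_pct`, `experimentation_se_pct`,
#'   `recommendation_pct`, `recommendation_se_pct`), scalars
#'   `prob_no_mtd_safety`, `prob_all_tolerated`, `etl` (mean true DLT
#'   probability at interior selections), `etl_se`, `eotr` and `eotr_se`
#'   (ratio of totals, delta-method SE), `eotr_per_trial` and
#'   `eotr_per_trial_se`, `mean_dlts`, `mean_dlts_se`, `expected_n`,
#'   `expected_n_se`,
#'   distributions `sample_size` and `dlt_rates`, and `n_sims`.
#' @examples
#' est <- estimate_ocs(ab_design(3, 3, 1, 1, 1),
#'                     tox_scenario(c(0.05, 0.10, 0.33, 0.60)),
#'                     n_sims = 2000, seed = 7)
#' est$dose_table
#' @export
estimate_ocs <- function(design, scenario, n_sims, seed = NULL) {
  stopifnot(inherits(design, "ab_design"), inherits(scenario, "tox_scenario"))
  if (length(n_sims) != 1L || !is.numeric(n_sims) || is.na(n_sims) ||
      n_sims < 1)
    stop("'n_sims' must be a positive integer", call. = FALSE)
  n_sims <- as.integer(n_sims)
  if (!is.null(seed)) set.seed(seed)
  J <- scenario$n_doses
  prop_mat <- matrix(0, n_sims, J)    # within-trial patient proportions
  sel <- matrix(FALSE, n_sims, J)     # MTD selections
  outc <- character(n_sims)
  n_tot <- integer(n_sims); dlt_tot <- integer(n_sims)
  for (i in seq_len(n_sims)) {
    tr <- sim_trial_core(design, scenario)
    ni <- sum(tr$npat)
    prop_mat[i, ] <- tr$npat / ni
    if (tr$outcome == "selected") sel[i, tr$mtd] <- TRUE
    outc[i] <- tr$outcome
    n_tot[i] <- ni
    dlt_tot[i] <- sum(tr$ndlt)
  }
  prop_se <- function(q) sqrt(q * (1 - q) / n_sims)
  exp_hat <- colMeans(prop_mat)
  exp_se <- apply(prop_mat, 2, stats::sd) / sqrt(n_sims)
  rec_hat <- colMeans(sel)
  dose_table <- data.frame(
    dose = seq_len(J),
    experimentation_pct = 100 * exp_hat,
    experimentation_se_pct = 100 * exp_se,
    recommendation_pct = 100 * rec_hat,
    recommendation_se_pct = 100 * prop_se(rec_hat))
  rate <- dlt_tot / n_tot
  p_safety <- mean(outc == "none_too_toxic")
  p_all <- mean(outc == "all_tolerated")
  any_sel <- rowSums(sel) > 0
  etl_draws <- scenario$dlt_probs[apply(sel[any_sel, , drop = FALSE], 1,
                                        which)]
  ss <- as.data.frame(table(n_tot) / n_sims, stringsAsFactors = FALSE)
  names(ss) <- c("n", "prob")
  ss$n <- as.integer(ss$n)
  dr <- as.data.frame(table(sprintf("%.15g", rate)) / n_sims,
                      stringsAsFactors = FALSE)
  names(dr) <- c("rate", "prob")
  dr$rate <- as.numeric(dr$rate)
  dr <- dr[order(dr$rate), , drop = FALSE]
  structure(list(
    design = design, scenario = scenario, n_sims = n_sims,
    dose_table = dose_table,
    prob_no_mtd_safety = p_safety,
    prob_no_mtd_safety_se = prop_se(p_safety),
    prob_all_tolerated = p_all,
    prob_all_tolerated_se = prop_se(p_all),
    etl = if (any(any_sel)) mean(etl_draws) else NA_real_,
    etl_se = if (sum(any_sel) > 1)
      stats::sd(etl_draws) / sqrt(sum(any_sel)) else NA_real_,
    eotr = sum(dlt_tot) / sum(n_tot),
    # delta-method SE for the ratio of means R = mean(D)/mean(N)
    eotr_se = stats::sd(dlt_tot - (sum(dlt_tot) / sum(n_tot)) * n_tot) /
      (sqrt(n_sims) * mean(n_tot)),
    eotr_per_trial = mean(rate),
    eotr_per_trial_se = stats::sd(rate) / sqrt(n_sims),
    mean_dlts = mean(dlt_tot),
    mean_dlts_se = stats::sd(dlt_tot) / sqrt(n_sims),
    expected_n = mean(n_tot),
    expected_n_se = stats::sd(n_tot) / sqrt(n_sims),
    sample_size = ss,
    dlt_rates = dr), class = "mc_ocs")
}

#' @export
print.mc_ocs <- function(x, ...) {
  cat(sprintf("Monte-Carlo operating characteristics (%d simulated trials)\n",
              x$n_sims))
  tab <- x$dose_table
  tab[-1] <- lapply(tab[-1], round_half_away, digits = 2)
  print(tab, row.names = FALSE)
  cat(sprintf("  ETL = %.3f (se %.4f)   EOTR = %.3f (se %.4f)\n",
              x$etl, x$etl_se, x$eotr, x$eotr_se))
  invisible(x)
}

#' Compare exact and Monte-Carlo operating characteristics
#'
#' Convenience table for verifying the exact engine against the simulator:
#' each row pairs an exact value with its empirical estimate and reports
#' the z-score (difference over standard error).
#'
#' @param ocs A `"scenario_ocs"` object from [operating_characteristics()].
#' @param mc An `"mc_ocs"` object from [estimate_ocs()] for the same design
#'   and scenario.
#' @return A data frame with columns `quantity`, `exact`, `mc`, `se`, `z`.
#' @export
compare_exact_mc <- function(ocs, mc) {
  stopifnot(inherits(ocs, "scenario_ocs"), inherits(mc, "mc_ocs"))
  J <- nrow(ocs$dose_table)
  rows <- list()
  for (j in seq_len(J)) {
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = sprintf("experimentation_pct_dose_%d", j),
      exact = ocs$dose_table$experimentation_pct[j],
      mc = mc$dose_table$experimentation_pct[j],
      se = mc$dose_table$experimentation_se_pct[j])
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = sprintf("recommendation_pct_dose_%d", j),
      exact = ocs$dose_table$recommendation_pct[j],
      mc = mc$dose_table$recommendation_pct[j],
      se = mc$dose_table$recommendation_se_pct[j])
  }
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "eotr", exact = ocs$eotr, mc = mc$eotr, se = mc$eotr_se)
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "eotr_per_trial", exact = ocs$eotr_per_trial,
    mc = mc$eotr_per_trial, se = mc$eotr_per_trial_se)
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "mean_dlts", exact = ocs$mean_dlts, mc = mc$mean_dlts,
    se = mc$mean_dlts_se)
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "expected_n", exact = ocs$expected_n, mc = mc$expected_n,
    se = mc$expected_n_se)
  out <- do.call(rbind, rows)
  out$z <- ifelse(out$se > 0, (out$mc - out$exact) / out$se,
                  ifelse(out$mc == out$exact, 0, Inf))
  out
}
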