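# Exact enumeration of all possible A+B trial pathways.
#
# A pathway is the ordered sequence of (dose, cohort size, DLT count)
# triples a trial can realise, together with its exact occurrence
# probability (a product of binomial terms) and the terminal MTD outcome.
# Enumeration is a depth-first walk of the decision tree: at every reachable
# state each cohort outcome 0..cohort_size is branched on, so the resulting
# pathway set is exhaustive and mutually exclusive and its probabilities
# sum to one. No branch is pruned, however improbable.

PHASE_ESCALATION   <- "escalation"
PHASE_DEESCALATION <- "deescalation"

OUTCOME_SELECTED       <- "selected"
OUTCOME_NONE_TOO_TOXIC <- "none_too_toxic"
OUTCOME_ALL_TOLERATED  <- "all_tolerated"

#' Enumerate all possible trial pathways of an A+B design
#'
#' Walks the complete decision tree of the design under a dose-toxicity
#' scenario, branching on every possible DLT count at every cohort, and
#' returns the exhaustive set of distinct trial pathways with their exact
#' occurrence probabilities. The probabilities of the returned pathways sum
#' to one (up to floating-point rounding); nothing is pruned.
#'
#' @param design An [ab_design()] object.
#' @param scenario A [tox_scenario()] object.
#' @return An object of class `"pathway_set"`: a list with elements
#'   `design`, `scenario` and `pathways` (a list of `"trial_pathway"`
#'   objects). Each pathway holds `cohorts` (data frame with columns `dose`,
#'   `size`, `dlts`, `phase`), `probability`, `outcome` (one of
#'   `"selected"`, `"none_too_toxic"`, `"all_tolerated"`), `mtd` (selected
#'   dose index or `NA`), `n`, `total_dlts`, `patients_per_dose` and
#'   `dlts_per_dose`.
#' @examples
#' ps <- enumerate_pathways(ab_design(3, 3, 1, 1, 1),
#'                          tox_scenario(c(0.05, 0.10, 0.33, 0.60)))
#' length(ps$pathways)
#' sum(vapply(ps$pathways, function(p) p$probability, numeric(1)))
#' @export
enumerate_pathways <- function(design, scenario) {
  stopifnot(inherits(design, "ab_design"), inherits(scenario, "tox_scenario"))
  A <- design$A; B <- design$B; C <- design$C; D <- design$D; E <- design$E
  J <- scenario$n_doses
  p <- scenario$dlt_probs

  acc <- vector("list", 64L)
  n_acc <- 0L
  emit <- function(cohorts, prob, outcome, mtd, npat, ndlt) {
    pw <- structure(list(
      cohorts = data.frame(
        dose  = vapply(cohorts, `[[`, integer(1), "dose"),
        size  = vapply(cohorts, `[[`, integer(1), "size"),
        dlts  = vapply(cohorts, `[[`, integer(1), "dlts"),
        phase = vapply(cohorts, `[[`, character(1), "phase"),
        stringsAsFactors = FALSE),
      probability = prob,
      outcome = outcome,
      mtd = mtd,
      n = sum(npat),
      total_dlts = sum(ndlt),
      patients_per_dose = npat,
      dlts_per_dose = ndlt), class = "trial_pathway")
    n_acc <<- n_acc + 1L
    if (n_acc > length(acc)) length(acc) <<- 2L * n_acc
    acc[[n_acc]] <<- pw
  }

  # De-escalation phase: walk downward from dose k, expanding doses that
  # hold only A patients; never re-escalates.
  walk_down <- function(k, cohorts, prob, npat, ndlt) {
    if (k < 1L) {
      emit(cohorts, prob, OUTCOME_NONE_TOO_TOXIC, NA_integer_, npat, ndlt)
    } else if (npat[k] == A + B) {
      if (ndlt[k] <= E)
        emit(cohorts, prob, OUTCOME_SELECTED, k, npat, ndlt)
      else
        walk_down(k - 1L, cohorts, prob, npat, ndlt)
    } else {
      # dose k was escalated from after the first cohort; treat B more
      for (z in 0:B) {
        co2 <- c(cohorts, list(list(dose = k, size = B, dlts = z,
                                    phase = PHASE_DEESCALATION)))
        pr2 <- prob * stats::dbinom(z, B, p[k])
        np2 <- npat; np2[k] <- np2[k] + B
        nd2 <- ndlt; nd2[k] <- nd2[k] + z
        if (nd2[k] <= E)
          emit(co2, pr2, OUTCOME_SELECTED, k, np2, nd2)
        else
          walk_down(k - 1L, co2, pr2, np2, nd2)
      }
    }
  }

  halt <- function(j, cohorts, prob, npat, ndlt) {
    if (design$deescalate) {
      walk_down(j - 1L, cohorts, prob, npat, ndlt)
    } else if (j > 1L) {
      emit(cohorts, prob, OUTCOME_SELECTED, j - 1L, npat, ndlt)
    } else {
      emit(cohorts, prob, OUTCOME_NONE_TOO_TOXIC, NA_integer_, npat, ndlt)
    }
  }

  visit_dose <- function(j, cohorts, prob, npat, ndlt) {
    for (x in 0:A) {
      co1 <- c(cohorts, list(list(dose = j, size = A, dlts = x,
                                  phase = PHASE_ESCALATION)))
      pr1 <- prob * stats::dbinom(x, A, p[j])
      np1 <- npat; np1[j] <- np1[j] + A
      nd1 <- ndlt; nd1[j] <- nd1[j] + x
      if (x <= C - 1L) {
        if (j == J)
          emit(co1, pr1, OUTCOME_ALL_TOLERATED, NA_integer_, np1, nd1)
        else
          visit_dose(j + 1L, co1, pr1, np1, nd1)
      } else if (x <= D) {
        for (z in 0:B) {
          co2 <- c(co1, list(list(dose = j, size = B, dlts = z,
                                  phase = PHASE_ESCALATION)))
          pr2 <- pr1 * stats::dbinom(z, B, p[j])
          np2 <- np1; np2[j] <- np2[j] + B
          nd2 <- nd1; nd2[j] <- nd2[j] + z
          if (nd2[j] <= E) {
            if (j == J)
              emit(co2, pr2, OUTCOME_ALL_TOLERATED, NA_integer_, np2, nd2)
            else
              visit_dose(j + 1L, co2, pr2, np2, nd2)
          } else {
            halt(j, co2, pr2, np2, nd2)
          }
        }
      } else {
        halt(j, co1, pr1, np1, nd1)
      }
    }
  }

  visit_dose(1L, list(), 1.0, integer(J), integer(J))
  structure(list(design = design, scenario = scenario,
                 pathways = acc[seq_len(n_acc)]),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  tot <- sum(vapply(x$pathways, `[[`, numeric(1), "probability"))
  cat(sprintf("Exact pathway set: %d distinct trial pathways\n",
              length(x$pathways)))
  cat(sprintf("  design %d+%d {%d,%d,%d,%d,%d}, de-escalation %s\n",
              x$design$A, x$design$B, x$design$A, x$design$B, x$design$C,
              x$design$D, x$design$E,
              if (x$design$deescalate) "permitted" else "not permitted"))
  cat(sprintf("  %d dose levels; total probability %.15f\n",
              x$scenario$n_doses, tot))
  invisible(x)
}

#' Exact occurrence probability of a trial pathway
#'
#' Recomputes the probability of a pathway from first principles as the
#' product over its cohorts of binomial probabilities
#' \eqn{\binom{m}{x} p_j^x (1-p_j)^{m-x}}, where \eqn{m} is the cohort
#' size, \eqn{x} its DLT count and \eqn{p_j} the scenario's true DLT
#' probability at the cohort's dose. For pathways produced by
#' [enumerate_pathways()] this equals the stored `probability` field; it is
#' also used to check simulated pathways.
#'
#' @param pathway A `"trial_pathway"` object (or any list with a `cohorts`
#'   data frame holding `dose`, `size`, `dlts`).
#' @param scenario A [tox_scenario()] object.
#' @return The pathway probability, a number in \[0, 1\].
#' @export
pathway_probability <- function(pathway, scenario) {
  stopifnot(inherits(scenario, "tox_scenario"))
  co <- pathway$cohorts
  prod(stats::dbinom(co$dlts, co$size, scenario$dlt_probs[co$dose]))
}

#' Determine the MTD outcome at the end of escalation
#'
#' Applies the trial-termination rules given the state at which escalation
#' halted. Without de-escalation: a halt at dose `j > 1` selects dose
#' `j - 1` as the MTD, a halt at dose 1 ends the trial with no MTD for
#' safety reasons, and escalating past the top dose ends it with every dose
#' tolerated. With de-escalation: doses below the halting dose are examined
#' in descending order; a dose already holding `A + B` patients is selected
#' iff its total DLTs are at most `E`, and a dose holding only `A` patients
#' receives a further cohort of `B` (drawn via `expand`) before the same
#' check. Exhausting dose 1 without success yields no MTD.
#'
#' @param design An [ab_design()] object.
#' @param halt_dose Dose index at which escalation halted, or `NA` if the
#'   top dose was escalated past (trial completed with all doses
#'   tolerated).
#' @param npat Integer vector of patients treated so far per dose.
#' @param ndlt Integer vector of DLTs observed so far per dose.
#' @param expand For de-escalation designs, a function `function(dose)`
#'   returning the DLT count of a new cohort of `B` patients at `dose`
#'   (e.g. a binomial draw in simulation). Ignored otherwise.
#' @return A list with `outcome` (`"selected"`, `"none_too_toxic"` or
#'   `"all_tolerated"`), `mtd` (selected dose index or `NA`), and
#'   `extra_cohorts` (data frame of de-escalation cohorts added: columns
#'   `dose`, `size`, `dlts`).
#' @export
determine_mtd <- function(design, halt_dose, npat, ndlt, expand = NULL) {
  stopifnot(inherits(design, "ab_design"))
  no_extra <- data.frame(dose = integer(0), size = integer(0),
                         dlts = integer(0))
  if (is.na(halt_dose))
    return(list(outcome = OUTCOME_ALL_TOLERATED, mtd = NA_integer_,
                extra_cohorts = no_extra))
  if (!design$deescalate) {
    if (halt_dose > 1L)
      return(list(outcome = OUTCOME_SELECTED, mtd = halt_dose - 1L,
                  extra_cohorts = no_extra))
    return(list(outcome = OUTCOME_NONE_TOO_TOXIC, mtd = NA_integer_,
                extra_cohorts = no_extra))
  }
  A <- design$A; B <- design$B; E <- design$E
  extra <- list()
  k <- halt_dose - 1L
  while (k >= 1L) {
    if (npat[k] < A + B) {
      if (!is.function(expand))
        stop("'expand' must be supplied for de-escalation designs",
             call. = FALSE)
      z <- expand(k)
      extra[[length(extra) + 1L]] <- list(dose = k, size = B, dlts = z)
      npat[k] <- npat[k] + B
      ndlt[k] <- ndlt[k] + z
    }
    if (ndlt[k] <= E) {
      ec <- if (length(extra)) data.frame(
        dose = vapply(extra, `[[`, integer(1), "dose"),
        size = vapply(extra, `[[`, integer(1), "size"),
        dlts = vapply(extra, function(e) as.integer(e$dlts), integer(1)))
      else no_extra
      return(list(outcome = OUTCOME_SELECTED, mtd = k, extra_cohorts = ec))
    }
    k <- k - 1L
  }
  ec <- if (length(extra)) data.frame(
    dose = vapply(extra, `[[`, integer(1), "dose"),
    size = vapply(extra, `[[`, integer(1), "size"),
    dlts = vapply(extra, function(e) as.integer(e$dlts), integer(1)))
  else no_extra
  list(outcome = OUTCOME_NONE_TOO_TOXIC, mtd = NA_integer_,
       extra_cohorts = ec)
}

#' Tabulate a pathway set
#'
#' One row per pathway: an id, the cohort sequence encoded as
#' `"dose:size:dlts;..."` (de-escalation cohorts marked with a trailing
#' `d`), the exact probability, total sample size, total DLTs and the MTD
#' outcome.
#'
#' @param ps A `"pathway_set"` from [enumerate_pathways()].
#' @return A data frame with columns `pathway`, `cohorts`, `probability`,
#'   `n`, `total_dlts`, `outcome`, `mtd`.
#' @export
pathway_table <- function(ps) {
  stopifnot(inherits(ps, "pathway_set"))
  enc <- vapply(ps$pathways, function(pw) {
    co <- pw$cohorts
    paste(sprintf("%d:%d:%d%s", co$dose, co$size, co$dlts,
                  ifelse(co$phase == PHASE_DEESCALATION, "d", "")),
          collapse = ";")
  }, character(1))
  data.frame(
    pathway = seq_along(ps$pathways),
    cohorts = enc,
    probability = vapply(ps$pathways, `[[`, numeric(1), "probability"),
    n = vapply(ps$pathways, function(p) as.integer(p$n), integer(1)),
    total_dlts = vapply(ps$pathways, function(p) as.integer(p$total_dlts),
                        integer(1)),
    outcome = vapply(ps$pathways, `[[`, character(1), "outcome"),
    mtd = vapply(ps$pathways, function(p) as.integer(p$mtd), integer(1)),
    stringsAsFactors = FALSE)
}
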