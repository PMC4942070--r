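# Scenario-independent design characteristics: the terminal data states
# possible at the selected MTD, exact (Clopper-Pearson) and Wilson score
# confidence intervals for the DLT probability given those data, the
# escalation-probability curve, and the tipping point of the design.

#' Possible terminal data states at the selected MTD
#'
#' Enumerates every (DLT count, sample size) pair that can be observed at
#' the dose finally selected as the MTD. Without de-escalation the MTD may
#' have been escalated from after only the first cohort (`x <= C - 1` DLTs
#' out of `A`) or after expansion (`y <= E` total DLTs out of `A + B`, with
#' `y >= C` since expansion requires at least `C` first-stage DLTs). With
#' de-escalation the selected MTD always holds `A + B` patients with at
#' most `E` DLTs; any count `0..E` is reachable via a de-escalation
#' expansion of a dose originally escalated on few DLTs.
#'
#' @param design An [ab_design()] object.
#' @return A data frame with columns `dlts` and `n`, ordered by `n` then
#'   `dlts`.
#' @examples
#' mtd_data_states(ab_design(3, 3, 1, 1, 1))            # (0,3), (1,6)
#' mtd_data_states(ab_design(3, 3, 1, 1, 1, TRUE))      # (0,6), (1,6)
#' @export
mtd_data_states <- function(design) {
  stopifnot(inherits(design, "ab_design"))
  A <- design$A; B <- design$B; C <- design$C; E <- design$E
  if (design$deescalate) {
    # reachable totals at A+B patients cap at D + B (worst case: D DLTs in
    # the first cohort, all B in the expansion)
    states <- data.frame(dlts = 0:min(E, design$D + B), n = A + B)
  } else {
    st1 <- data.frame(dlts = 0:(C - 1L), n = A)
    # total DLTs at an expanded, escalated-from dose: at least C (expansion
    # needs C first-stage DLTs), at most min(E, D + B)
    ymax <- min(E, design$D + B)
    st2 <- if (C <= ymax) data.frame(dlts = C:ymax, n = A + B)
           else data.frame(dlts = integer(0), n = integer(0))
    states <- rbind(st1, st2)
  }
  states[order(states$n, states$dlts), , drop = FALSE]
}

#' Exact Clopper-Pearson confidence interval for a binomial proportion
#'
#' The exact interval obtained by inverting equal-tailed binomial tests,
#' computed via beta quantiles: with `a = 1 - level`, the lower limit is
#' the `a/2` quantile of Beta(`x`, `n - x + 1`) (zero when `x = 0`) and the
#' upper limit the `1 - a/2` quantile of Beta(`x + 1`, `n - x`) (one when
#' `x = n`).
#'
#' @param x Number of successes (DLTs), `0 <= x <= n`.
#' @param n Number of trials (patients), `n >= 1`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A list of class `"binom_ci"` with elements `lower`, `upper`,
#'   `level`, `method`, `x`, `n`.
#' @examples
#' clopper_pearson_ci(0, 3)  # upper limit about 0.708
#' clopper_pearson_ci(1, 6)  # (0.0042, 0.6412)
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  check_ci_args(x, n, level)
  a <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  structure(list(lower = lower, upper = upper, level = level,
                 method = "clopper-pearson", x = as.integer(x),
                 n = as.integer(n)), class = "binom_ci")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval obtained by inverting the normal approximation to
#' the score test; narrower than the exact interval, especially at the
#' boundaries. Endpoints are clipped to \[0, 1\].
#'
#' @inheritParams clopper_pearson_ci
#' @return A list of class `"binom_ci"` with elements `lower`, `upper`,
#'   `level`, `method`, `x`, `n`.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  check_ci_args(x, n, level)
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  structure(list(lower = max(0, centre - half),
                 upper = min(1, centre + half), level = level,
                 method = "wilson", x = as.integer(x), n = as.integer(n)),
            class = "binom_ci")
}

check_ci_args <- function(x, n, level) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n != round(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) ||
      x < 0 || x > n)
    stop("'x' must be an integer in [0, n]", call. = FALSE)
  if (length(level) != 1L || !is.numeric(level) || is.na(level) ||
      level <= 0 || level >= 1)
    stop("'level' must lie strictly between 0 and 1", call. = FALSE)
  invisible(NULL)
}

#' @export
print.binom_ci <- function(x, ...) {
  cat(sprintf("%d/%d DLTs: %.0f%% %s interval (%.2f%%, %.2f%%)\n",
              x$x, x$n, 100 * x$level,
              if (x$method == "clopper-pearson") "Clopper-Pearson"
              else "Wilson score",
              100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Probability of escalating from a dose
#'
#' The probability, as a function of a dose's true DLT probability `p`,
#' that the design escalates from that dose:
#' \deqn{\sum_{x=0}^{C-1} \binom{A}{x} p^x (1-p)^{A-x} +
#'       \sum_{x=C}^{D} \binom{A}{x} p^x (1-p)^{A-x}
#'       \sum_{y=0}^{E-x} \binom{B}{y} p^y (1-p)^{B-y},}
#' the inner sum being empty when `E - x < 0`. Continuous and
#' non-increasing in `p`, equal to one at `p = 0`.
#'
#' @param design An [ab_design()] object.
#' @param p True DLT probability (vectorised), each in \[0, 1\].
#' @return Escalation probability, same length as `p`.
#' @export
escalation_prob <- function(design, p) {
  stopifnot(inherits(design, "ab_design"))
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  A <- design$A; B <- design$B; C <- design$C; D <- design$D; E <- design$E
  vapply(p, function(pp) {
    s1 <- sum(stats::dbinom(0:(C - 1L), A, pp))
    xs <- C:D
    s2 <- sum(vapply(xs, function(x) {
      if (E - x < 0) return(0)
      stats::dbinom(x, A, pp) * stats::pbinom(E - x, B, pp)
    }, numeric(1)))
    s1 + s2
  }, numeric(1))
}

#' Tipping point of an A+B design
#'
#' The true DLT probability at which a dose is equally likely to be
#' escalated from as not — the root of `escalation_prob(design, p) = 1/2`
#' on (0, 1). Doses with true DLT probability above the tipping point are
#' unlikely MTD candidates: without de-escalation the modal MTD has true
#' DLT probability at most the tipping point, and with de-escalation the
#' total probability of selecting a dose above it is at most 50%. The
#' classical 3+3 design has tipping point 0.297.
#'
#' The escalation probability is strictly decreasing whenever `D < A` or
#' `E < A + B`; for the fully degenerate design (`D = A` and `E = A + B`)
#' escalation is certain at every `p` and the tipping point is undefined
#' (an error).
#'
#' @param design An [ab_design()] object.
#' @param tol Solver tolerance for the root finder (default 1e-10).
#' @return A list of class `"tipping_point"` with elements `value` (the
#'   root), `design`.
#' @examples
#' tipping_point(ab_design(3, 3, 1, 1, 1))$value           # 0.297
#' tipping_point(ab_design(2, 4, 1, 1, 2, TRUE))$value     # 0.448
#' @export
tipping_point <- function(design, tol = 1e-10) {
  stopifnot(inherits(design, "ab_design"))
  if (design$D >= design$A && design$E >= design$A + design$B)
    stop("tipping point undefined: this design escalates with probability 1 ",
         "at every DLT probability", call. = FALSE)
  f <- function(p) escalation_prob(design, p) - 0.5
  eps <- 1e-12
  if (f(1 - eps) > 0)
    stop("tipping point undefined: escalation probability never drops to ",
         "one half on (0, 1)", call. = FALSE)
  root <- stats::uniroot(f, interval = c(eps, 1 - eps), tol = tol)$root
  structure(list(value = root, design = design), class = "tipping_point")
}

#' @export
print.tipping_point <- function(x, ...) {
  cat(sprintf("Tipping point: %.3f\n", round_half_away(x$value, 3)))
  cat(sprintf(
    "  (escalation and non-escalation equiprobable for design {%d,%d,%d,%d,%d})\n",
    x$design$A, x$design$B, x$design$C, x$design$D, x$design$E))
  invisible(x)
}

#' All scenario-independent design characteristics
#'
#' Tabulates every possible terminal data state at the selected MTD with
#' both confidence-interval methods at the requested level, and computes
#' the design's tipping point (when defined).
#'
#' @param design An [ab_design()] object.
#' @param conf_level Confidence level for the intervals, in (0, 1).
#' @return An object of class `"design_ocs"`: a list with `ci_table` (one
#'   row per terminal state and method: columns `dlts`, `n`, `method`,
#'   `lower`, `upper`, `level`), `tipping_point` (numeric, or `NA` when
#'   undefined) and `design`.
#' @examples
#' design_characteristics(ab_design(3, 3, 1, 1, 1))
#' @export
design_characteristics <- function(design, conf_level = 0.95) {
  stopifnot(inherits(design, "ab_design"))
  if (length(conf_level) != 1L || !is.numeric(conf_level) ||
      is.na(conf_level) || conf_level <= 0 || conf_level >= 1)
    stop("'conf_level' must lie strictly between 0 and 1", call. = FALSE)
  states <- mtd_data_states(design)
  rows <- lapply(seq_len(nrow(states)), function(i) {
    cp <- clopper_pearson_ci(states$dlts[i], states$n[i], conf_level)
    wi <- wilson_ci(states$dlts[i], states$n[i], conf_level)
    data.frame(dlts = rep(states$dlts[i], 2), n = rep(states$n[i], 2),
               method = c("clopper-pearson", "wilson"),
               lower = c(cp$lower, wi$lower), upper = c(cp$upper, wi$upper),
               level = conf_level, stringsAsFactors = FALSE)
  })
  tp <- tryCatch(tipping_point(design)$value, error = function(e) NA_real_)
  structure(list(design = design, ci_table = do.call(rbind, rows),
                 tipping_point = tp), class = "design_ocs")
}

#' @export
print.design_ocs <- function(x, ...) {
  cat("Design operating characteristics\n")
  cat(sprintf("  design %d+%d {%d,%d,%d,%d,%d}, de-escalation %s\n",
              x$design$A, x$design$B, x$design$A, x$design$B, x$design$C,
              x$design$D, x$design$E,
              if (x$design$deescalate) "permitted" else "not permitted"))
  tab <- x$ci_table
  tab$lower <- sprintf("%.2f%%", 100 * tab$lower)
  tab$upper <- sprintf("%.2f%%", 100 * tab$upper)
  print(tab, row.names = FALSE)
  if (is.na(x$tipping_point))
    cat("  tipping point: undefined for this design\n")
  else
    cat(sprintf("  tipping point: %.3f\n",
                round_half_away(x$tipping_point, 3)))
  invisible(x)
}
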