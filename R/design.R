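#' Specify an A+B dose-escalation design
#'
#' An A+B design is a rule-based dose-escalation scheme governed by five
#' integers and a de-escalation flag. At each dose a first cohort of `A`
#' patients is treated; depending on the number of dose-limiting toxicities
#' (DLTs) observed, the dose is escalated, expanded by a second cohort of
#' `B` patients, or escalation stops (with optional de-escalation to lower
#' doses). The classical 3+3 design is `ab_design(3, 3, 1, 1, 1)`.
#'
#' The decision rules are:
#' \itemize{
#'   \item With `x` DLTs among the first `A` patients: escalate if
#'     `x <= C - 1`; treat `B` more at the same dose if `C <= x <= D`;
#'     otherwise stop escalating (and de-escalate if permitted).
#'   \item With `y` total DLTs among all `A + B` patients at an expanded
#'     dose: escalate if `y <= E`; otherwise stop/de-escalate.
#' }
#'
#' @param A Number of patients in the first cohort at each dose (>= 1).
#' @param B Number of patients in the second cohort, when required (>= 1).
#' @param C Minimum number of DLTs out of `A` patients that triggers
#'   treating `B` more at the same dose; `1 <= C <= D`.
#' @param D Maximum number of DLTs out of `A` patients that still allows
#'   treating `B` more; `C <= D <= A`. More than `D` DLTs stops escalation.
#' @param E Maximum number of DLTs out of `A + B` patients that still
#'   allows escalation; `0 <= E <= A + B`.
#' @param deescalate Logical; if `TRUE`, excessive toxicity triggers
#'   stepping down to lower doses (expanding each to `A + B` patients)
#'   rather than stopping the trial outright.
#' @return An object of class `"ab_design"`: a list with elements `A`, `B`,
#'   `C`, `D`, `E` and `deescalate`.
#' @examples
#' ab_design(3, 3, 1, 1, 1)                     # classical 3+3
#' ab_design(2, 4, 1, 1, 2, deescalate = TRUE)  # a 2+4 design
#' @export
ab_design <- function(A, B, C, D, E, deescalate = FALSE) {
  for (nm in c("A", "B", "C", "D", "E")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v != round(v))
      stop("'", nm, "' must be a single integer", call. = FALSE)
  }
  A <- as.integer(A); B <- as.integer(B); C <- as.integer(C)
  D <- as.integer(D); E <- as.integer(E)
  if (!is.logical(deescalate) || length(deescalate) != 1L || is.na(deescalate))
    stop("'deescalate' must be TRUE or FALSE", call. = FALSE)
  if (A < 1L) stop("'A' must be at least 1 (got ", A, ")", call. = FALSE)
  if (B < 1L) stop("'B' must be at least 1 (got ", B, ")", call. = FALSE)
  if (C < 1L) stop("'C' must be at least 1 (got ", C, ")", call. = FALSE)
  if (C > D) stop("'C' must not exceed 'D' (got C = ", C, ", D = ", D, ")",
                  call. = FALSE)
  if (D > A) stop("'D' must not exceed 'A' (got D = ", D, ", A = ", A, ")",
                  call. = FALSE)
  if (E < 0L) stop("'E' must be non-negative (got ", E, ")", call. = FALSE)
  if (E > A + B) stop("'E' must not exceed A + B (got E = ", E, ", A + B = ",
                      A + B, ")", call. = FALSE)
  if (E < C)
    warning("E < C: a dose expanded to A + B patients can never be escalated ",
            "from", call. = FALSE)
  else if (E < D)
    warning("E < D: some expanded doses can never be escalated from",
            call. = FALSE)
  structure(list(A = A, B = B, C = C, D = D, E = E, deescalate = deescalate),
            class = "ab_design")
}

#' @export
print.ab_design <- function(x, ...) {
  cat(sprintf("%d+%d dose-escalation design\n", x$A, x$B))
  cat(sprintf("  {A, B, C, D, E} = {%d, %d, %d, %d, %d}\n",
              x$A, x$B, x$C, x$D, x$E))
  cat("  dose de-escalation:", if (x$deescalate) "permitted" else
    "not permitted", "\n")
  invisible(x)
}

#' Specify a dose-toxicity scenario
#'
#' A scenario is an ordered vector of true DLT probabilities, one per dose
#' level. Non-monotone probabilities are legal (plateaus and local dips
#' occur in practice) and trigger a warning only.
#'
#' @param dlt_probs Numeric vector of true DLT probabilities, one per dose
#'   level, each in \[0, 1\].
#' @return An object of class `"tox_scenario"`: a list with elements
#'   `n_doses` and `dlt_probs`.
#' @examples
#' tox_scenario(c(0.05, 0.10, 0.33, 0.60))
#' @export
tox_scenario <- function(dlt_probs) {
  if (length(dlt_probs) < 1L || !is.numeric(dlt_probs) || anyNA(dlt_probs))
    stop("'dlt_probs' must be a non-empty numeric vector without NAs",
         call. = FALSE)
  if (any(dlt_probs < 0) || any(dlt_probs > 1))
    stop("all DLT probabilities must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(dlt_probs))
    warning("DLT probabilities are not non-decreasing in dose", call. = FALSE)
  structure(list(n_doses = length(dlt_probs),
                 dlt_probs = as.numeric(dlt_probs)),
            class = "tox_scenario")
}

#' @export
print.tox_scenario <- function(x, ...) {
  cat(sprintf("Dose-toxicity scenario: %d dose level%s\n", x$n_doses,
              if (x$n_doses == 1L) "" else "s"))
  cat("  true DLT probabilities:",
      paste(format(x$dlt_probs, trim = TRUE), collapse = ", "), "\n")
  invisible(x)
}

#' First-stage escalation decision
#'
#' Decision after observing `x` DLTs among the first cohort of `A` patients
#' at a dose: `"escalate"` when `x <= C - 1`, `"expand"` (treat `B` more at
#' the same dose) when `C <= x <= D`, and `"halt"` when `x > D`. `"halt"`
#' means escalation stops; for designs permitting de-escalation it triggers
#' the de-escalation phase.
#'
#' @param design An [ab_design()] object.
#' @param x Number of DLTs observed among the `A` patients (`0 <= x <= A`).
#' @return One of `"escalate"`, `"expand"`, `"halt"`.
#' @examples
#' d33 <- ab_design(3, 3, 1, 1, 1)
#' stage1_decision(d33, 0)  # "escalate"
#' stage1_decision(d33, 1)  # "expand"
#' stage1_decision(d33, 2)  # "halt"
#' @export
stage1_decision <- function(design, x) {
  stopifnot(inherits(design, "ab_design"))
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) ||
      x < 0 || x > design$A)
    stop("'x' must be an integer in [0, A]", call. = FALSE)
  if (x <= design$C - 1L) "escalate"
  else if (x <= design$D) "expand"
  else "halt"
}

#' Second-stage escalation decision
#'
#' Decision after a dose has been expanded to `A + B` patients, based on the
#' total number of DLTs `y` among all of them (first-stage DLTs included):
#' `"escalate"` when `y <= E`, `"halt"` otherwise.
#'
#' @param design An [ab_design()] object.
#' @param y Total DLTs among all `A + B` patients at the dose
#'   (`C <= y <= A + B`; the lower bound holds because expansion requires at
#'   least `C` first-stage DLTs).
#' @return One of `"escalate"`, `"halt"`.
#' @examples
#' d24 <- ab_design(2, 4, 1, 1, 2, deescalate = TRUE)
#' stage2_decision(d24, 2)  # "escalate"
#' stage2_decision(d24, 3)  # "halt"
#' @export
stage2_decision <- function(design, y) {
  stopifnot(inherits(design, "ab_design"))
  if (length(y) != 1L || !is.numeric(y) || is.na(y) || y != round(y) ||
      y < design$C || y > design$A + design$B)
    stop("'y' must be an integer in [C, A + B]", call. = FALSE)
  if (y <= design$E) "escalate" else "halt"
}
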