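# Independent brute-force enumerator used as an oracle for the exact
# engine. Deliberately self-contained: it transcribes the escalation /
# expansion / halt / de-escalation flow directly, stores cohorts as bare
# matrices, and computes each pathway probability only at the very end as
# a product of binomial pmf terms. It shares no code with the package.
oracle_enumerate <- function(A, B, C, D, E, deesc, p) {
  J <- length(p)
  res <- list()
  add <- function(co, outcome, mtd)
    res[[length(res) + 1L]] <<- list(co = co, outcome = outcome, mtd = mtd)
  walk_down <- function(k, co) {
    if (k < 1) {
      add(co, "none_too_toxic", NA)
      return(invisible(NULL))
    }
    n_k <- sum(co[co[, 1] == k, 2])
    d_k <- sum(co[co[, 1] == k, 3])
    if (n_k == A + B) {
      if (d_k <= E) add(co, "selected", k) else walk_down(k - 1, co)
    } else {
      for (z in 0:B) {
        co2 <- rbind(co, c(k, B, z, 1))
        if (d_k + z <= E) add(co2, "selected", k)
        else walk_down(k - 1, co2)
      }
    }
  }
  stop_at <- function(j, co) {
    if (deesc) walk_down(j - 1, co)
    else if (j > 1) add(co, "selected", j - 1)
    else add(co, "none_too_toxic", NA)
  }
  go <- function(j, co) {
    for (x in 0:A) {
      co1 <- rbind(co, c(j, A, x, 0))
      if (x < C) {
        if (j == J) add(co1, "all_tolerated", NA) else go(j + 1, co1)
      } else if (x <= D) {
        for (z in 0:B) {
          co2 <- rbind(co1, c(j, B, z, 0))
          if (x + z <= E) {
            if (j == J) add(co2, "all_tolerated", NA) else go(j + 1, co2)
          } else stop_at(j, co2)
        }
      } else stop_at(j, co1)
    }
  }
  go(1, matrix(numeric(0), 0, 4))
  lapply(res, function(r) {
    list(cohorts = r$co,
         probability = prod(stats::dbinom(r$co[, 3], r$co[, 2],
                                          p[r$co[, 1]])),
         outcome = r$outcome, mtd = r$mtd)
  })
}

# canonical string key for a cohort sequence (dose:size:dlts:phase;...)
oracle_key <- function(co)
  paste(apply(co, 1, paste, collapse = ":"), collapse = ";")

pathway_key <- function(pw)
  paste(sprintf("%d:%d:%d:%d", pw$cohorts$dose, pw$cohorts$size,
                pw$cohorts$dlts,
                as.integer(pw$cohorts$phase == "deescalation")),
        collapse = ";")

# the four worked example configurations used throughout the tests
example_configs <- function() {
  list(
    I   = list(design = ab_design(3, 3, 1, 1, 1),
               probs = c(0.05, 0.10, 0.33, 0.60)),
    II  = list(design = ab_design(3, 3, 1, 1, 1),
               probs = c(0.04, 0.08, 0.16, 0.32, 0.64, 0.80)),
    III = list(design = ab_design(3, 3, 1, 1, 1, deescalate = TRUE),
               probs = c(0.06, 0.15, 0.29, 0.31, 0.33, 0.35)),
    IV  = list(design = ab_design(2, 4, 1, 1, 2, deescalate = TRUE),
               probs = c(0.06, 0.20, 0.30, 0.40, 0.45)))
}

# random valid design under the size caps used in property tests
random_design <- function(a_max = 3, b_max = 3) {
  A <- sample.int(a_max, 1)
  B <- sample.int(b_max, 1)
  D <- sample.int(A, 1)
  C <- sample.int(D, 1)
  E <- sample(0:(A + B), 1)
  suppressWarnings(ab_design(A, B, C, D, E,
                             deescalate = runif(1) < 0.5))
}
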