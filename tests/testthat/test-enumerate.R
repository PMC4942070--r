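test_that("zero toxicity yields the single full-escalation pathway", {
  ps <- enumerate_pathways(ab_design(3, 3, 1, 1, 1),
                           tox_scenario(rep(0, 4)))
  probs <- vapply(ps$pathways, `[[`, numeric(1), "probability")
  expect_identical(sum(probs == 1), 1L)
  main <- ps$pathways[[which(probs == 1)]]
  expect_identical(main$outcome, "all_tolerated")
  expect_identical(main$n, 12L)
  expect_identical(main$total_dlts, 0L)
  expect_identical(nrow(main$cohorts), 4L)
})

test_that("certain toxicity at a single dose halts immediately with no MTD", {
  ps <- enumerate_pathways(ab_design(3, 3, 1, 1, 1), tox_scenario(1))
  probs <- vapply(ps$pathways, `[[`, numeric(1), "probability")
  main <- ps$pathways[[which.max(probs)]]
  expect_equal(main$probability, 1)
  expect_identical(main$outcome, "none_too_toxic")
  expect_identical(main$n, 3L)
  expect_identical(main$total_dlts, 3L)
})

test_that("pathway probabilities sum to one for the worked examples", {
  for (cfg in example_configs()) {
    ps <- enumerate_pathways(cfg$design, tox_scenario(cfg$probs))
    probs <- vapply(ps$pathways, `[[`, numeric(1), "probability")
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
})

test_that("no dose ever exceeds A+B patients and tallies are consistent", {
  for (cfg in example_configs()) {
    d <- cfg$design
    ps <- enumerate_pathways(d, tox_scenario(cfg$probs))
    for (pw in ps$pathways) {
      expect_true(all(pw$patients_per_dose <= d$A + d$B))
      expect_identical(sum(pw$cohorts$size), as.integer(pw$n))
      expect_identical(sum(pw$cohorts$dlts), as.integer(pw$total_dlts))
      expect_identical(as.integer(sum(pw$patients_per_dose)),
                       as.integer(pw$n))
      expect_identical(as.integer(sum(pw$dlts_per_dose)),
                       as.integer(pw$total_dlts))
      expect_lte(pw$total_dlts, pw$n)
    }
  }
})

test_that("pathways are pairwise distinct in their cohort sequences", {
  for (cfg in example_configs()[c("I", "IV")]) {
    ps <- enumerate_pathways(cfg$design, tox_scenario(cfg$probs))
    keys <- vapply(ps$pathways, pathway_key, character(1))
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("stored probabilities equal the binomial product recomputation", {
  for (cfg in example_configs()[c("I", "III")]) {
    s <- tox_scenario(cfg$probs)
    ps <- enumerate_pathways(cfg$design, s)
    recomputed <- vapply(ps$pathways, pathway_probability, numeric(1),
                         scenario = s)
    expect_equal(recomputed,
                 vapply(ps$pathways, `[[`, numeric(1), "probability"),
                 tolerance = 1e-14)
  }
})

test_that("single-cohort pathway probabilities match closed forms", {
  s5 <- tox_scenario(0.5)
  pw <- list(cohorts = data.frame(dose = 1L, size = 3L, dlts = 0L))
  expect_equal(pathway_probability(pw, s5), 0.125)
  s33 <- tox_scenario(0.33)
  pw1 <- list(cohorts = data.frame(dose = 1L, size = 3L, dlts = 1L))
  expect_equal(pathway_probability(pw1, s33), 3 * 0.33 * 0.67^2,
               tolerance = 1e-12)
})

test_that("a hand-computed three-cohort pathway probability is exact", {
  # escalate on 0/3 twice, then 2 DLTs out of 3 at dose 3
  s <- tox_scenario(c(0.05, 0.10, 0.33, 0.60))
  pw <- list(cohorts = data.frame(dose = 1:3, size = 3L, dlts = c(0L, 0L, 2L)))
  hand <- 0.95^3 * 0.90^3 * (3 * 0.33^2 * 0.67)
  expect_equal(pathway_probability(pw, s), hand, tolerance = 1e-14)
  # and that exact pathway exists in the enumeration with that probability
  ps <- enumerate_pathways(ab_design(3, 3, 1, 1, 1), s)
  keys <- vapply(ps$pathways, pathway_key, character(1))
  hit <- which(keys == "1:3:0:0;2:3:0:0;3:3:2:0")
  expect_length(hit, 1L)
  expect_equal(ps$pathways[[hit]]$probability, hand, tolerance = 1e-14)
  expect_identical(ps$pathways[[hit]]$outcome, "selected")
  expect_identical(ps$pathways[[hit]]$mtd, 2L)
})

test_that("enumeration is deterministic", {
  cfg <- example_configs()$IV
  ps1 <- enumerate_pathways(cfg$design, tox_scenario(cfg$probs))
  ps2 <- enumerate_pathways(cfg$design, tox_scenario(cfg$probs))
  expect_identical(pathway_table(ps1), pathway_table(ps2))
})

test_that("enumeration matches the independent brute-force oracle exactly", {
  set.seed(42)
  for (rep in 1:8) {
    d <- random_design(a_max = 3, b_max = 3)
    J <- sample.int(3, 1)
    p <- round(runif(J, 0.02, 0.9), 2)
    s <- suppressWarnings(tox_scenario(p))
    ps <- enumerate_pathways(d, s)
    orc <- oracle_enumerate(d$A, d$B, d$C, d$D, d$E, d$deescalate, p)
    expect_identical(length(ps$pathways), length(orc))
    got <- vapply(ps$pathways, pathway_key, character(1))
    want <- vapply(orc, function(o) oracle_key(o$cohorts), character(1))
    expect_setequal(got, want)
    m <- match(want, got)
    expect_equal(vapply(ps$pathways[m], `[[`, numeric(1), "probability"),
                 vapply(orc, `[[`, numeric(1), "probability"),
                 tolerance = 1e-13)
    expect_identical(vapply(ps$pathways[m], `[[`, character(1), "outcome"),
                     vapply(orc, `[[`, character(1), "outcome"))
    got_mtd <- vapply(ps$pathways[m], function(x) as.integer(x$mtd),
                      integer(1))
    want_mtd <- vapply(orc, function(o) as.integer(o$mtd), integer(1))
    expect_identical(got_mtd, want_mtd)
  }
})

test_that("MTD determination handles halting and completion states", {
  d <- ab_design(3, 3, 1, 1, 1)
  # halt at dose 3 after doses 1-2 tolerated: select dose 2
  r <- determine_mtd(d, 3L, npat = c(3L, 3L, 3L, 0L),
                     ndlt = c(0L, 0L, 2L, 0L))
  expect_identical(r$outcome, "selected")
  expect_identical(r$mtd, 2L)
  # halt at the lowest dose: no MTD
  r <- determine_mtd(d, 1L, npat = c(3L, 0L, 0L, 0L),
                     ndlt = c(2L, 0L, 0L, 0L))
  expect_identical(r$outcome, "none_too_toxic")
  # escalated past the top dose
  r <- determine_mtd(d, NA_integer_, npat = rep(3L, 4), ndlt = rep(0L, 4))
  expect_identical(r$outcome, "all_tolerated")
})

test_that("de-escalation expands lower doses before declaring the MTD", {
  d <- ab_design(3, 3, 1, 1, 1, deescalate = TRUE)
  # dose 2 escalated on 0/3; halt at dose 3; de-escalation cohort adds 1 DLT
  r <- determine_mtd(d, 3L, npat = c(3L, 3L, 3L, 0L, 0L, 0L),
                     ndlt = c(0L, 0L, 2L, 0L, 0L, 0L),
                     expand = function(k) 1L)
  expect_identical(r$outcome, "selected")
  expect_identical(r$mtd, 2L)
  expect_identical(r$extra_cohorts$dose, 2L)
  expect_identical(r$extra_cohorts$dlts, 1L)
  # with 2 extra DLTs at dose 2 (total 2 > E), the walk continues to dose 1
  r <- determine_mtd(d, 3L, npat = c(3L, 3L, 3L, 0L, 0L, 0L),
                     ndlt = c(0L, 0L, 2L, 0L, 0L, 0L),
                     expand = function(k) if (k == 2L) 2L else 0L)
  expect_identical(r$mtd, 1L)
  expect_identical(r$extra_cohorts$dose, c(2L, 1L))
  # a dose already expanded with tolerable DLTs is selected without refill
  r <- determine_mtd(d, 3L, npat = c(3L, 6L, 3L, 0L, 0L, 0L),
                     ndlt = c(0L, 1L, 2L, 0L, 0L, 0L))
  expect_identical(r$mtd, 2L)
  expect_identical(nrow(r$extra_cohorts), 0L)
  # exhausting every dose yields no MTD
  r <- determine_mtd(d, 2L, npat = c(3L, 3L, 0L, 0L, 0L, 0L),
                     ndlt = c(0L, 3L, 0L, 0L, 0L, 0L),
                     expand = function(k) 3L)
  expect_identical(r$outcome, "none_too_toxic")
})

test_that("simulated de-escalation cohorts replay through determine_mtd", {
  # the enumerator's de-escalation branches must agree with determine_mtd
  # when the recorded cohort outcomes are fed back in
  cfg <- example_configs()$III
  ps <- enumerate_pathways(cfg$design, tox_scenario(cfg$probs))
  deesc_pws <- Filter(function(pw) any(pw$cohorts$phase == "deescalation"),
                      ps$pathways)
  expect_gt(length(deesc_pws), 0)
  for (pw in deesc_pws[seq_len(min(50, length(deesc_pws)))]) {
    co <- pw$cohorts
    esc <- co[co$phase == "escalation", ]
    halt_dose <- esc$dose[nrow(esc)]
    J <- length(pw$patients_per_dose)
    npat <- integer(J); ndlt <- integer(J)
    for (i in seq_len(nrow(esc))) {
      npat[esc$dose[i]] <- npat[esc$dose[i]] + esc$size[i]
      ndlt[esc$dose[i]] <- ndlt[esc$dose[i]] + esc$dlts[i]
    }
    dd <- co[co$phase == "deescalation", ]
    feed <- stats::setNames(dd$dlts, dd$dose)
    r <- determine_mtd(cfg$design, halt_dose, npat, ndlt,
                       expand = function(k) feed[[as.character(k)]])
    expect_identical(r$outcome, pw$outcome)
    expect_identical(as.integer(r$mtd), as.integer(pw$mtd))
  }
})
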