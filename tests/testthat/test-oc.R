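ps_I <- enumerate_pathways(ab_design(3, 3, 1, 1, 1),
                           tox_scenario(c(0.05, 0.10, 0.33, 0.60)))

test_that("degenerate scenarios give point-mass distributions", {
  ps0 <- enumerate_pathways(ab_design(3, 3, 1, 1, 1),
                            tox_scenario(rep(0, 4)))
  ss <- sample_size_distribution(ps0)
  expect_equal(ss$prob[ss$n == 12], 1)
  dr <- dlt_rate_distribution(ps0)
  expect_equal(dr$prob[dr$rate == 0], 1)
  md <- mtd_distribution(ps0)
  expect_equal(md$pct[md$category == "all_tolerated"], 100)
  expect_equal(eotr(ps0), 0)
  expect_equal(mean_dlts(ps0), 0)

  ps1 <- enumerate_pathways(ab_design(3, 3, 1, 1, 1), tox_scenario(1))
  ss1 <- sample_size_distribution(ps1)
  expect_equal(ss1$prob[ss1$n == 3], 1)
  dr1 <- dlt_rate_distribution(ps1)
  expect_equal(dr1$prob[dr1$rate == 1], 1)
})

test_that("sample-size distribution aggregates pathway probabilities", {
  ss <- sample_size_distribution(ps_I)
  expect_equal(sum(ss$prob), 1, tolerance = 1e-12)
  expect_true(all(ss$n >= 3 & ss$n <= 24))
  # expectation from the distribution equals the direct pathway sum
  direct <- sum(vapply(ps_I$pathways, function(p)
    p$probability * p$n, numeric(1)))
  expect_equal(sum(ss$n * ss$prob), direct, tolerance = 1e-12)
  # and matches the brute-force oracle
  orc <- oracle_enumerate(3, 3, 1, 1, 1, FALSE, c(0.05, 0.10, 0.33, 0.60))
  orc_en <- sum(vapply(orc, function(o)
    o$probability * sum(o$cohorts[, 2]), numeric(1)))
  expect_equal(sum(ss$n * ss$prob), orc_en, tolerance = 1e-12)
})

test_that("experimentation percentages sum to 100 and use within-trial proportions", {
  e <- experimentation_pct(ps_I)
  expect_equal(sum(e), 100, tolerance = 1e-9)
  # single-dose scenario: all experimentation at dose 1 whatever p is
  ps1 <- enumerate_pathways(ab_design(3, 3, 1, 1, 1), tox_scenario(0.4))
  expect_equal(experimentation_pct(ps1), 100, tolerance = 1e-12)
  # the within-trial definition must differ from the ratio-of-expectations
  # approximation for a non-degenerate scenario
  pr <- vapply(ps_I$pathways, `[[`, numeric(1), "probability")
  npat <- t(vapply(ps_I$pathways,
                   function(p) as.numeric(p$patients_per_dose), numeric(4)))
  n <- vapply(ps_I$pathways, function(p) as.numeric(p$n), numeric(1))
  ratio_of_exp <- 100 * colSums(npat * pr) / sum(n * pr)
  expect_gt(max(abs(e - ratio_of_exp)), 0.5)
})

test_that("MTD distribution covers all outcomes and respects folding", {
  md <- mtd_distribution(ps_I)
  expect_equal(sum(md$pct), 100, tolerance = 1e-9)
  # without de-escalation the top dose can never be selected outright
  expect_equal(md$pct[md$category == "dose_4"], 0)
  fold_top <- mtd_distribution(ps_I, fold_all_tolerated = "top_dose")
  expect_equal(sum(fold_top$pct), 100, tolerance = 1e-9)
  expect_equal(fold_top$pct[fold_top$category == "dose_4"],
               md$pct[md$category == "all_tolerated"])
  fold_no <- mtd_distribution(ps_I, fold_all_tolerated = "no_mtd")
  expect_equal(fold_no$pct[fold_no$category == "none_too_toxic"],
               sum(md$pct[md$category %in% c("none_too_toxic",
                                             "all_tolerated")]),
               tolerance = 1e-12)
})

test_that("ETL is a weighted mean of scenario probabilities within bounds", {
  p <- ps_I$scenario$dlt_probs
  etl <- expected_toxicity_level(ps_I)
  expect_gte(etl, min(p))
  expect_lte(etl, max(p))
  # degenerate: only dose 1 selectable in a two-dose scenario with p2 = 1
  ps <- suppressWarnings(enumerate_pathways(ab_design(3, 3, 1, 1, 1),
                                            tox_scenario(c(0, 1))))
  expect_equal(expected_toxicity_level(ps), 0)
  # errors when nothing is ever selected or tolerated
  ps_tox <- enumerate_pathways(ab_design(3, 3, 1, 1, 1), tox_scenario(1))
  expect_error(expected_toxicity_level(ps_tox), "undefined")
})

test_that("EOTR and mean DLTs match a direct hand enumeration at J = 1", {
  # single dose, 3+3: outcomes are x = 0 (stop after one cohort of 3,
  # all tolerated); x = 1 (expand, any z); x >= 2 (halt)
  p <- 0.3
  ps <- enumerate_pathways(ab_design(3, 3, 1, 1, 1), tox_scenario(p))
  q <- function(x) choose(3, x) * p^x * (1 - p)^(3 - x)
  hand_dlts <- q(0) * 0 +
    sum(vapply(0:3, function(z) q(1) * q(z) * (1 + z), numeric(1))) +
    q(2) * 2 + q(3) * 3
  expect_equal(mean_dlts(ps), hand_dlts, tolerance = 1e-12)
  hand_rate_num <- q(0) * 0 +
    sum(vapply(0:3, function(z) q(1) * q(z) * (1 + z), numeric(1))) +
    q(2) * 2 + q(3) * 3
  hand_n <- q(0) * 3 + q(1) * 6 + (q(2) + q(3)) * 3
  expect_equal(eotr(ps), hand_rate_num / hand_n, tolerance = 1e-12)
  hand_per_trial <- q(0) * 0 +
    sum(vapply(0:3, function(z) q(1) * q(z) * (1 + z) / 6, numeric(1))) +
    q(2) * 2 / 3 + q(3) * 1
  expect_equal(eotr(ps, method = "per_trial"), hand_per_trial,
               tolerance = 1e-12)
})

test_that("DLT-rate distribution pools equal rational rates and sums to one", {
  dr <- dlt_rate_distribution(ps_I)
  expect_equal(sum(dr$prob), 1, tolerance = 1e-12)
  expect_false(is.unsorted(dr$rate))
  expect_identical(anyDuplicated(dr$rate), 0L)
  expect_true(all(dr$rate >= 0 & dr$rate <= 1))
})

test_that("interval summaries bin doses by true DLT probability", {
  ocs <- operating_characteristics(ps_I)
  ints <- interval_summaries(ocs)
  expect_identical(nrow(ints), 5L)
  # Example scenario: doses 1-2 in [0,0.2], dose 3 in (0.2,0.4],
  # dose 4 in (0.4,0.6]
  expect_equal(ints$experimentation_pct[1],
               sum(ocs$dose_table$experimentation_pct[1:2]),
               tolerance = 1e-12)
  expect_equal(ints$experimentation_pct[2],
               ocs$dose_table$experimentation_pct[3], tolerance = 1e-12)
  expect_equal(ints$experimentation_pct[4:5], c(0, 0))
  expect_equal(sum(ints$experimentation_pct), 100, tolerance = 1e-9)
  # boundary values belong to the lower (right-closed) interval
  ocs2 <- operating_characteristics(
    design = ab_design(3, 3, 1, 1, 1),
    scenario = tox_scenario(c(0.2, 0.4, 0.6, 0.8)))
  ints2 <- interval_summaries(ocs2)
  expect_equal(ints2$experimentation_pct[1],
               ocs2$dose_table$experimentation_pct[1], tolerance = 1e-12)
  expect_equal(ints2$experimentation_pct[5], 0)
  # a scenario entirely inside one interval holds 100% of experimentation
  ocs3 <- operating_characteristics(
    design = ab_design(3, 3, 1, 1, 1),
    scenario = tox_scenario(c(0.25, 0.3, 0.4)))
  expect_equal(interval_summaries(ocs3)$experimentation_pct[2], 100,
               tolerance = 1e-9)
})

test_that("normalisation holds across randomized designs and scenarios", {
  set.seed(99)
  for (rep in 1:6) {
    d <- random_design()
    J <- sample(2:4, 1)
    s <- suppressWarnings(tox_scenario(round(runif(J, 0, 0.95), 2)))
    ps <- enumerate_pathways(d, s)
    probs <- vapply(ps$pathways, `[[`, numeric(1), "probability")
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    expect_equal(sum(experimentation_pct(ps)), 100, tolerance = 1e-9)
    expect_equal(sum(mtd_distribution(ps)$pct), 100, tolerance = 1e-9)
    expect_equal(sum(dlt_rate_distribution(ps)$prob), 1, tolerance = 1e-12)
  }
})

test_that("raising toxicity at the first dose drives P(no MTD) to one", {
  prev <- -1
  for (p1 in c(0.2, 0.5, 0.8, 0.99)) {
    s <- suppressWarnings(tox_scenario(c(p1, 0.99)))
    md <- mtd_distribution(enumerate_pathways(ab_design(3, 3, 1, 1, 1), s))
    cur <- md$pct[md$category == "none_too_toxic"]
    expect_gt(cur, prev)
    prev <- cur
  }
  expect_gt(prev, 95)
})
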