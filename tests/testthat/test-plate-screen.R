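test_that("growth normalisation divides signal by growth and enforces the floor", {
  expect_equal(growth_normalize(500, 0.5), 1000)
  expect_equal(growth_normalize(0, 1.0), 0)
  expect_equal(growth_normalize(c(10, 20), c(0.5, 0.2)), c(20, 100))
  expect_error(growth_normalize(300, 0.01), class = "rs_low_growth")
  expect_error(growth_normalize(300, 0.04, floor = 0.05),
               class = "rs_low_growth")
  expect_silent(growth_normalize(300, 0.04, floor = 0.01))
  expect_error(growth_normalize(-1, 0.5), class = "rs_invalid_parameter")
})

test_that("plate standardisation centres, scales and is affine-invariant", {
  expect_equal(plate_standardize(c(1, 2, 3)), c(-1, 0, 1))

  set.seed(42)
  for (i in 1:10) {
    v <- rnorm(sample(3:96, 1), mean = runif(1, 0, 100), sd = runif(1, 0.1, 9))
    z <- plate_standardize(v)
    expect_equal(mean(z), 0)
    expect_equal(sd(z), 1)
    # affine invariance and idempotence
    expect_equal(plate_standardize(3.7 * v + 11), z)
    expect_equal(plate_standardize(z), z)
  }

  expect_error(plate_standardize(c(2, 2, 2)), class = "rs_degenerate_plate")
  expect_error(plate_standardize(c(1, 2)), class = "rs_insufficient_data")
})

test_that("outlier selection is one-sided, strict, and handles edge cases", {
  z <- c(a = 2.5, b = 1.9, c = -3.0)
  expect_equal(select_outliers(z, 2), "a")
  expect_equal(select_outliers(z, 2, two_sided = TRUE), c("a", "c"))
  expect_equal(select_outliers(c(a = 2.0), 2), character(0)) # strict >
  expect_equal(select_outliers(numeric(0), 2), character(0))

  set.seed(1)
  zz <- setNames(rnorm(4000), paste0("c", 1:4000))
  frac <- length(select_outliers(zz, 0)) / 4000
  expect_true(abs(frac - 0.5) < 4 * sqrt(0.25 / 4000))
})

test_that("multi-round screening intersects survivors across rounds", {
  # hand-built two-round data: one plate, eight clones
  mk <- function(round, signals) {
    data.frame(plate = "p1", well = paste0("w", 1:8),
               clone = paste0("cl", 1:8), signal = signals,
               growth = 1, round = round)
  }
  # cl1 is extreme in both rounds; cl2 extreme only in round 1
  m <- rbind(mk(1, c(100, 90, 10, 10, 10, 10, 10, 10)),
             mk(2, c(100, 10, 10, 10, 10, 10, 10, 10)))
  hs <- run_screen_rounds(m, thresholds = c(1, 1))
  expect_s3_class(hs, "hit_set")
  expect_true("cl1" %in% hs$survivors[[1]] && "cl2" %in% hs$survivors[[1]])
  expect_equal(hs$hits, "cl1")
  expect_true(all(hs$survivors[[2]] %in% hs$survivors[[1]]))

  # vacuous threshold
  hs_inf <- run_screen_rounds(mk(1, c(100, 90, 10, 10, 10, 10, 10, 10)),
                              thresholds = Inf)
  expect_equal(hs_inf$hits, character(0))

  # prior survivor missing from round 2 counts as a failed re-screen
  m_missing <- rbind(mk(1, c(100, 90, 10, 10, 10, 10, 10, 10)),
                     mk(2, c(90, 12, 10, 9, 10, 11, 10, 10))[-1, ])
  expect_warning(hs2 <- run_screen_rounds(m_missing, thresholds = c(1, 1)),
                 "failed re-screen")
  expect_false("cl1" %in% hs2$hits)
})

test_that("hit tally counts constructs of the final survivors", {
  d <- make_library_design(8, 8)
  tr <- screen_ground_truth(d, fold_effects = c("P004::C002" = 12),
                            well_cv = 0.1)
  sim <- simulate_screen(d, tr, coverage = 2, seed = 3)
  hs <- suppressWarnings(run_screen_rounds(sim$measurements, sim$clone_map))
  expect_equal(sum(hs$tally$count), length(hs$hits))
  expect_true("P004::C002" %in% hs$tally$construct)
  expect_equal(hs$tally$construct[which.max(hs$tally$count)], "P004::C002")
})

test_that("raising a hit clone's signal never removes it from the hit set", {
  d <- make_library_design(8, 8)
  tr <- screen_ground_truth(d, fold_effects = c("P004::C002" = 12),
                            well_cv = 0.1)
  sim <- simulate_screen(d, tr, coverage = 2, seed = 3)
  hs <- suppressWarnings(run_screen_rounds(sim$measurements, sim$clone_map))
  hit <- hs$hits[1]
  m2 <- sim$measurements
  m2$signal[m2$clone == hit] <- m2$signal[m2$clone == hit] * 2
  hs2 <- suppressWarnings(run_screen_rounds(m2, sim$clone_map))
  expect_true(hit %in% hs2$hits)
})

test_that("low-growth wells are excluded with a message, not normalised", {
  m <- data.frame(plate = "p1", well = paste0("w", 1:6),
                  clone = paste0("cl", 1:6),
                  signal = c(50, 10, 11, 9, 10, 3),
                  growth = c(1, 1, 1, 1, 1, 0.01), round = 1)
  expect_message(hs <- run_screen_rounds(m, thresholds = 1), "low-growth")
  expect_false("cl6" %in% hs$z$clone)
  expect_true("cl1" %in% hs$hits)
})

test_that("fold change is the ratio of means with delta-method SE", {
  fc <- fold_change(c(14, 14, 14), c(1, 1, 1))
  expect_equal(fc$fold, 14)
  expect_equal(fc$se, 0)
  expect_equal(fold_change(c(3, 5, 7), c(3, 5, 7))$fold, 1)

  # known-truth recovery: 44 vs 44 lognormal draws at true ratio 14
  va <- simulate_validation_assay(44, fold_effect = 14, well_cv = 0.2,
                                  seed = 101)
  fc2 <- fold_change(growth_normalize(va$rewired_signal, va$rewired_growth),
                     growth_normalize(va$control_signal, va$control_growth))
  expect_true(abs(fc2$fold - 14) < 3 * fc2$se)

  expect_error(fold_change(numeric(0), c(1, 2)),
               class = "rs_invalid_parameter")
  expect_error(fold_change(c(1, 2), c(0, 0)), class = "rs_invalid_baseline")
})

test_that("percent enhancement is 100 * (fold - 1) with matching SE", {
  pe <- percent_enhancement(c(3, 3, 3), c(2, 2, 2))
  expect_equal(pe$percent, 50)
  expect_equal(pe$se, 0)
})

test_that("paired t-test matches the hand formula and the reference implementation", {
  x <- c(2, 4, 6); y <- c(1, 2, 3) # d = 1, 2, 3
  r <- paired_t_test(x, y)
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(r$degrees_of_freedom, 2)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    a <- rnorm(n); b <- rnorm(n, 0.3)
    mine <- paired_t_test(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    # translation invariance
    shifted <- paired_t_test(a + 5, b + 5)
    expect_equal(shifted$statistic, mine$statistic, tolerance = 1e-10)
    # one-sided options
    expect_equal(paired_t_test(a, b, tail = "greater")$p_value,
                 t.test(a, b, paired = TRUE,
                        alternative = "greater")$p.value, tolerance = 1e-12)
  }
})

test_that("paired t-test degenerate contracts", {
  r <- paired_t_test(c(1, 2, 3), c(1, 2, 3)) # identical vectors: no evidence
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(paired_t_test(c(1, 2), c(1, 2, 3)), class = "rs_pairing_error")
  # constant nonzero differences leave t undefined
  expect_error(paired_t_test(c(2, 3, 4), c(1, 2, 3)),
               class = "rs_degenerate")
})

test_that("lycopene signal is dilution-scaled growth normalisation", {
  expect_equal(lycopene_signal(0.4, 0.8, 5), 2.5)
  expect_equal(lycopene_signal(0.3, 0.6, 1), growth_normalize(0.3, 0.6))
  expect_error(lycopene_signal(0.4, 0.01, 5), class = "rs_low_growth")
})
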