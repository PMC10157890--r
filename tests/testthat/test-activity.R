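test_that("normalization fixes the reference at 1 and propagates error", {
  recs <- list(
    activity_record("FRK(ac)WR", mean = 0.20, sd = 0.02, n = 4),
    activity_record("FRK(ac)WA", mean = 0.10, sd = 0.01, n = 4),
    activity_record("FRK(ac)RA", mean = NA, sd = NA, n = 4,
                    detection_limit = 0.001))
  norm <- normalize_activities(recs)
  expect_equal(norm$value[norm$sequence == "FRK(ac)WR"], 1)
  expect_equal(norm$value[norm$sequence == "FRK(ac)WA"], 0.5)
  # reference sd is the self-ratio propagation: sqrt(2) * relative sd
  expect_equal(norm$sd[norm$sequence == "FRK(ac)WR"], sqrt(2) * 0.02 / 0.20)
  # censored record excluded
  expect_false("FRK(ac)RA" %in% norm$sequence)
  # below-detection reference is an error
  expect_error(normalize_activities(recs, reference = "FRK(ac)RA"),
               "below detection")
})

test_that("normalized values are invariant under global rescaling", {
  set.seed(4)
  peps <- derivative_panel_sequences()
  means <- runif(16, 0.01, 0.3)
  sds <- means * 0.1
  mk <- function(scale) lapply(seq_along(peps), function(i)
    activity_record(peps[i], mean = scale * means[i], sd = scale * sds[i],
                    n = 4))
  n1 <- normalize_activities(mk(1))
  n2 <- normalize_activities(mk(37.5))
  expect_equal(n1$value, n2$value)
  expect_equal(n1$sd, n2$sd)
})

test_that("pairwise t-test matrix is antisymmetric and detects separation", {
  recs <- list(
    activity_record("AK(ac)WA", replicates = c(10, 10.1, 9.9, 10)),
    activity_record("AK(ac)AA", replicates = c(1, 1.1, 0.9, 1)),
    activity_record("AK(ac)RA", replicates = c(1.02, 1.08, 0.95, 1.0)))
  res <- pairwise_activity_ttests(recs)
  expect_equal(res$codes["AK(ac)WA", "AK(ac)AA"], "row")
  expect_equal(res$codes["AK(ac)AA", "AK(ac)WA"], "col")
  expect_equal(res$codes["AK(ac)AA", "AK(ac)RA"], "ns")
  expect_equal(diag(res$codes), rep("", 3), ignore_attr = TRUE)
  # identical replicate sets are never significant
  same <- list(activity_record("AK(ac)WA", replicates = c(1, 2, 3, 4)),
               activity_record("AK(ac)AA", replicates = c(1, 2, 3, 4)))
  expect_equal(pairwise_activity_ttests(same)$codes["AK(ac)WA", "AK(ac)AA"],
               "ns")
  # full antisymmetry on a random panel
  set.seed(12)
  panel <- generate_activity_panel(derivative_panel_sequences(),
                                   noise_sd_log = 0.3, seed = 12)
  m <- pairwise_activity_ttests(panel)$codes
  for (i in 1:15) for (j in (i + 1):16) {
    expect_true((m[i, j] == "ns" && m[j, i] == "ns") ||
                (m[i, j] == "row" && m[j, i] == "col") ||
                (m[i, j] == "col" && m[j, i] == "row"))
  }
})

test_that("activity ratios propagate relative errors and invert cleanly", {
  a <- activity_record("AK(ac)WA", mean = 0.2, sd = 0.02)
  b <- activity_record("AK(ac)AA", mean = 0.1, sd = 0.01)
  r <- activity_ratio_with_error(a, b)
  expect_equal(unname(r["ratio"]), 2)
  expect_equal(unname(r["sd"]), 2 * sqrt(0.01 + 0.01))
  expect_equal(unname(activity_ratio_with_error(a, a)["ratio"]), 1)
  rab <- activity_ratio_with_error(a, b)["ratio"]
  rba <- activity_ratio_with_error(b, a)["ratio"]
  expect_equal(unname(rab * rba), 1)
  censored <- activity_record("AK(ac)RA", mean = NA, sd = NA,
                              detection_limit = 0.001)
  expect_error(activity_ratio_with_error(a, censored), "undefined ratio")
})

test_that("initial rates recover slopes exactly", {
  tc <- data.frame(conc = rep(10, 4), time = c(0, 60, 120, 180))
  tc$product <- 0.5 * tc$time
  r <- suppressWarnings(initial_rates(tc))
  expect_equal(r$v0, 0.5)
  flat <- data.frame(conc = rep(10, 4), time = c(0, 60, 120, 180),
                     product = 7)
  expect_equal(suppressWarnings(initial_rates(flat))$v0, 0)
  short <- data.frame(conc = 10, time = c(0, 60), product = c(0, 1))
  expect_error(initial_rates(short), "insufficient")
  # noiseless synthetic timecourses give the MM rate at machine precision
  tc2 <- generate_timecourses(28, 0.23, 100, noise_sd = 0)
  r2 <- suppressWarnings(initial_rates(tc2))
  expected <- 0.23 * 0.1 * r2$conc / (28 + r2$conc)
  expect_equal(r2$v0, expected, tolerance = 1e-12)
})

test_that("Michaelis-Menten fit recovers noiseless parameters exactly", {
  tc <- generate_timecourses(28, 0.23, 100, noise_sd = 0)
  fit <- suppressWarnings(
    fit_michaelis_menten(initial_rates(tc), enzyme_conc = 100))
  expect_equal(fit$K_M, 28, tolerance = 1e-6)
  expect_equal(fit$k_cat, 0.23, tolerance = 1e-6)
  expect_equal(fit$efficiency, 0.23 / 28e-6, tolerance = 1e-6)
  expect_true(fit$reliable)
  # too few concentrations is an error
  tc1 <- generate_timecourses(28, 0.23, 100, concentrations = c(10, 50),
                              noise_sd = 0)
  expect_error(
    fit_michaelis_menten(suppressWarnings(initial_rates(tc1)), 100),
    "insufficient")
  # saturating-only data leaves K_M unidentified and flagged
  tc3 <- generate_timecourses(2, 0.23, 100,
                              concentrations = c(500, 600, 700, 800, 900),
                              noise_sd = 0.02, seed = 5)
  fit3 <- suppressWarnings(
    fit_michaelis_menten(initial_rates(tc3), enzyme_conc = 100))
  expect_false(fit3$reliable)
})

test_that("efficiency units audit against published kinetic rows", {
  # printed rows agree with kcat/(KM*1e-6) within printed rounding
  rows <- list(list(KM = 28, kcat = 0.23, eff = 8300),
               list(KM = 70, kcat = 0.07, eff = 970),
               list(KM = 154, kcat = 0.110, eff = 650),
               list(KM = 1900, kcat = 0.080, eff = 44))
  for (r in rows)
    expect_equal(r$kcat / (r$KM * 1e-6), r$eff, tolerance = 0.10)
})

test_that("endpoint activities track catalytic efficiency", {
  set.seed(6)
  kms <- c(28, 70, 154, 400, 680, 1900)
  kcats <- c(0.23, 0.07, 0.11, 0.02, 0.43, 0.08)
  names <- sprintf("p%d", 1:6)
  fits <- setNames(lapply(1:6, function(i) {
    tc <- generate_timecourses(kms[i], kcats[i], 100, noise_sd = 0)
    suppressWarnings(fit_michaelis_menten(initial_rates(tc), 100))
  }), names)
  eff <- vapply(fits, `[[`, 0, "efficiency")
  endpoints <- setNames(eff * 1e-5 * (1 + rnorm(6, 0, 0.05)), names)
  res <- endpoint_efficiency_correlation(endpoints, fits)
  expect_gt(res$r, 0.9)
  # proportional endpoints give r = 1, anti-correlated toy data r < 0
  expect_equal(endpoint_efficiency_correlation(
    setNames(eff * 2, names), fits)$r, 1)
  expect_lt(endpoint_efficiency_correlation(
    setNames(max(eff) - eff, names), fits)$r, 0)
})

test_that("published panels validate residue-presence preferences", {
  t2 <- read_activity_table(fixture_path("table2_kdac6.csv"),
                            enzyme = "KDAC6", detection_limit = 0.0013)
  expect_length(t2, 30)
  arom1 <- function(p) residue_at(p, 1) %in% c("Y", "W", "F")
  r <- residue_presence_fisher(t2, arom1)
  expect_equal(unname(r$table), matrix(c(10, 0, 10, 10), 2, byrow = TRUE))
  expect_equal(r$p_value, 0.011, tolerance = 0.05)

  t3 <- read_activity_table(fixture_path("table3_kdac8.csv"),
                            enzyme = "KDAC8", detection_limit = 0.0004)
  expect_length(t3, 29)
  arom12 <- function(p) any(c(residue_at(p, 1), residue_at(p, 2)) %in%
                              c("Y", "W", "F"), na.rm = TRUE)
  r3 <- residue_presence_fisher(t3, arom12)
  expect_equal(unname(r3$table), matrix(c(15, 3, 5, 6), 2, byrow = TRUE))
  expect_equal(r3$p_value, 0.048, tolerance = 0.05)
  expect_error(residue_presence_fisher(t2, function(p) TRUE), "split")
})

test_that("null predicates give roughly uniform Fisher p-values", {
  set.seed(44)
  peps <- derivative_panel_sequences()
  ps <- replicate(200, {
    panel <- lapply(peps, function(s)
      activity_record(s, mean = runif(1), sd = 0.01,
                      detection_limit = 0.5))
    flag <- setNames(runif(16) < 0.5, peps)
    if (all(flag) || !any(flag)) return(NA_real_)
    residue_presence_fisher(panel, function(p) flag[[p$sequence]])$p_value
  })
  ps <- ps[!is.na(ps)]
  expect_lt(mean(ps <= 0.05), 0.10)    # discrete, conservative test
})

test_that("activity ranks put below-detection peptides last", {
  t2 <- read_activity_table(fixture_path("table2_kdac6.csv"),
                            enzyme = "KDAC6", detection_limit = 0.0013)
  rk <- activity_ranks(t2)
  expect_equal(rk$rank[rk$sequence == "AFGK(ac)YCR"], 1)
  expect_true(all(rk$rank[is.na(rk$mean)] > 20))
})
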