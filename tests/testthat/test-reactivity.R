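# Fixtures here place the reactivity atoms by hand so every expected value
# is known by construction.

rx_fixture <- function(tip_z, ceil_z = c(8, 8, 8), nuc = c(-2, 0, -10),
                       cc = c(0, 0, -14), co = c(1.23, 0, -14)) {
  top <- topology(name = c("T1", "O1", "O2", "O3", "SG", "C1", "OC"),
                  resname = c("LIG", "SER", "SER", "SER", "CYS", "LIG",
                              "LIG"),
                  resid = c(1, 29, 185, 217, 156, 1, 1),
                  chain = c("L", "A", "A", "A", "A", "L", "L"),
                  element = c("C", "O", "O", "O", "S", "C", "O"))
  xyz <- rbind(c(0, 0, tip_z), c(1, 0, ceil_z[1]), c(-1, 1, ceil_z[2]),
               c(-1, -1, ceil_z[3]), nuc, cc, co)
  trajectory(top, xyz)
}

rx_sel <- list(terminal_c = "name T1", ceiling = "resid 29 185 217",
               nucleophile = "name SG", carbonyl_c = "name C1",
               carbonyl_o = "name OC")

test_that("D1 is the Z offset between tail tip and ceiling COM", {
  tr <- rx_fixture(tip_z = 8)     # tip exactly at ceiling COM height
  expect_equal(compute_d1(tr, "name T1", "resid 29 185 217"), 0)
  tr2 <- rx_fixture(tip_z = 5)    # constructed 3 A below
  expect_equal(compute_d1(tr2, "name T1", "resid 29 185 217"), -3)
  expect_error(compute_d1(tr2, "resid 1", "resid 29 185 217"),
               "exactly 1")
})

test_that("D2 and the attack angle recover constructed geometry", {
  tr <- rx_fixture(tip_z = 5, nuc = c(0, 0, -9))      # 5 A above carbonyl
  expect_equal(compute_d2(tr, "name SG", "name C1"), 5)
  # nucleophile anti to the carbonyl O, on the C=O axis: 180 degrees
  tr180 <- rx_fixture(tip_z = 5, nuc = c(-3, 0, -14))
  expect_equal(compute_abd(tr180, "name SG", "name C1", "name OC"), 180)
  # perpendicular approach: 90 degrees
  tr90 <- rx_fixture(tip_z = 5, nuc = c(0, 0, -10))
  expect_equal(compute_abd(tr90, "name SG", "name C1", "name OC"), 90)
})

test_that("per-frame series equals a brute-force loop oracle", {
  sys <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 40, seed = 21, reactive_prob = 0.5))
  tr <- sys$traj; sel <- sys$selections
  d2 <- compute_d2(tr, sel$nucleophile, sel$carbonyl_c)
  i <- resolve_selection(sel$nucleophile, tr$topology)
  j <- resolve_selection(sel$carbonyl_c, tr$topology)
  manual <- vapply(seq_len(n_frames(tr)),
                   function(f) dist_oracle(tr$xyz[i, , f], tr$xyz[j, , f]),
                   numeric(1))
  expect_equal(d2, manual, tolerance = 1e-12)
})

test_that("reactive classification uses strict thresholds", {
  crit <- reactivity_criteria()
  # representative palmitoyl geometry: clearly reactive
  cl <- classify_reactive(5.1, 112, crit)
  expect_true(cl$reactive); expect_false(cl$improper)
  # crystal-structure-like geometry: too far, not reactive
  cl2 <- classify_reactive(6.6, 127, crit)
  expect_false(cl2$reactive); expect_false(cl2$improper)
  # exact boundaries are neither reactive nor improper
  cl3 <- classify_reactive(c(6.0, 5.0), c(120, 90.0), crit)
  expect_equal(cl3$reactive, c(FALSE, FALSE))
  expect_equal(cl3$improper, c(FALSE, FALSE))
  expect_error(classify_reactive(1:3, 1:2, crit), "length")
})

test_that("classification is monotone in the criteria", {
  set.seed(31)
  d2 <- runif(500, 3, 9); abd <- runif(500, 10, 170)
  base <- sum(classify_reactive(d2, abd, reactivity_criteria(6, 90))$reactive)
  for (k in 1:20) {
    tighter <- reactivity_criteria(runif(1, 3, 6), runif(1, 90, 150))
    expect_lte(sum(classify_reactive(d2, abd, tighter)$reactive), base)
  }
  cl <- classify_reactive(d2, abd)
  expect_true(all(!(cl$reactive & cl$improper)))
  expect_lte(mean(cl$reactive) + mean(cl$improper), 1)
})

test_that("summary statistics apply conditional averaging", {
  ser <- data.frame(d1 = c(-2, -2, -2), d2 = c(5, 7, 5),
                    abd = c(100, 40, 120),
                    reactive = c(TRUE, FALSE, TRUE),
                    improper = c(FALSE, FALSE, FALSE))
  s <- summarize_reactivity(ser)
  expect_equal(s$d2_mean, 5)          # middle frame excluded (d2 = 7)
  expect_equal(s$abd_mean, 110)
  expect_equal(s$d1_mean, -2); expect_equal(s$d1_sd, 0)
  expect_equal(s$sd_type, "sample")
  # constant series: sd zero, mean exact
  cs <- data.frame(d1 = rep(-2, 4), d2 = rep(5, 4), abd = rep(100, 4),
                   reactive = TRUE, improper = FALSE)
  expect_equal(summarize_reactivity(cs)$d1_sd, 0)
  # no close-approach frame: flagged undefined, not zero
  far <- data.frame(d1 = -2, d2 = 8, abd = 100, reactive = FALSE,
                    improper = FALSE)
  sf <- summarize_reactivity(far)
  expect_false(sf$conditional_defined)
  expect_true(is.na(sf$d2_mean) && is.na(sf$abd_mean))
  # the alternative reading: average over reactive frames only
  s2 <- summarize_reactivity(ser, condition = "reactive")
  expect_equal(s2$abd_mean, 110)
})

test_that("summaries equal the filter-then-average oracle on synthetic runs", {
  for (seed in c(3, 17)) {
    sys <- generate_synthetic_trajectory(
      synthetic_spec(n_frames = 300, seed = seed, reactive_prob = 0.4,
                     improper_prob = 0.3))
    ser <- reactivity_series(sys$traj, sys$selections)
    s <- summarize_reactivity(ser)
    o <- summary_oracle(ser)
    expect_equal(s$d1_mean, o$d1_mean)
    expect_equal(s$d2_mean, o$d2_mean)
    expect_equal(s$abd_mean, o$abd_mean)
    expect_equal(s$d2_sd, o$d2_sd)
    expect_equal(s$reactive_fraction, o$reactive_fraction)
  }
})

test_that("reactive fraction is exact bookkeeping", {
  expect_equal(reactive_fraction(c(TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(reactive_fraction(rep(FALSE, 10)), 0)
  expect_error(reactive_fraction(logical(0)), "empty")
  sys <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 500, seed = 8, reactive_prob = 0.6))
  ser <- reactivity_series(sys$traj, sys$selections)
  expect_equal(reactive_fraction(ser$reactive),
               sys$truth$realized_reactive_fraction)
})

test_that("selectivity profile normalizes to 100 percent", {
  p <- selectivity_profile(c(C16 = 0.2, C12 = 0, C14 = 0, C18 = 0,
                             C20 = 0))
  expect_equal(p$normalized_reactive_pct[p$chain == "C16"], 100)
  expect_equal(sum(p$normalized_reactive_pct), 100)
  p2 <- selectivity_profile(setNames(rep(0.3, 5),
                                     paste0("C", c(12, 14, 16, 18, 20))))
  expect_equal(p2$normalized_reactive_pct, rep(20, 5))
  f <- c(C12 = 0.05, C14 = 0.10, C16 = 0.60, C18 = 0.30, C20 = 0.05)
  p3 <- selectivity_profile(f)
  expect_equal(p3$normalized_reactive_pct, as.numeric(100 * f / sum(f)),
               tolerance = 1e-12)
  expect_equal(p3$normalized_reactive_pct[1], 100 * 0.05 / 1.1)
  expect_warning(pz <- selectivity_profile(c(a = 0, b = 0)), "zero")
  expect_equal(pz$normalized_reactive_pct, c(0, 0))
  expect_error(selectivity_profile(c(a = -0.1)), "negative")
})

test_that("2D density mode matches an exhaustive bin-scan oracle", {
  # all frames identical: single occupied bin centered on the point
  d <- density2d(rep(5, 10), rep(110, 10))
  expect_equal(sum(d$counts), 10)
  expect_equal(sum(d$counts > 0), 1)
  expect_equal(as.numeric(d$mode), c(5.125, 112.5))
  # 90/10 split: mode sits in the dominant cluster
  d2v <- c(rep(5, 90), rep(8, 10)); av <- c(rep(120, 90), rep(40, 10))
  d2 <- density2d(d2v, av)
  expect_lt(d2$mode[["d2"]], 6); expect_gt(d2$mode[["abd"]], 90)
  # bimodal sample vs brute-force scan over all bins
  set.seed(44)
  x <- c(rnorm(300, 5, 0.3), rnorm(200, 7.5, 0.3))
  y <- c(rnorm(300, 120, 8), rnorm(200, 50, 8))
  dd <- density2d(x, y)
  best <- c(-Inf, NA, NA)
  for (i in seq_len(nrow(dd$counts))) for (j in seq_len(ncol(dd$counts))) {
    n <- sum(x >= dd$d2_edges[i] & x < dd$d2_edges[i + 1] &
               y >= dd$abd_edges[j] & y < dd$abd_edges[j + 1])
    if (n > best[1]) best <- c(n, i, j)
  }
  expect_equal(dd$counts[best[2], best[3]], max(dd$counts))
  expect_equal(dd$mode[["d2"]],
               mean(dd$d2_edges[best[2] + c(0, 1)]))
  expect_error(density2d(numeric(0), numeric(0)), "empty")
})
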