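test_that("topology construction is deterministic and correctly labelled", {
  sp <- synthetic_spec(chain_length = 16, n_frames = 1, seed = 5)
  t1 <- build_synthetic_topology(sp)
  t2 <- build_synthetic_topology(sp)
  expect_identical(t1$xyz, t2$xyz)
  expect_identical(t1$topology, t2$topology)
  acyl <- resolve_selection("resname ACO and element C", t1$topology)
  expect_equal(sum(grepl("^C[0-9]+$",
                         t1$topology$name[acyl])), 16)
  expect_true("C16" %in% t1$topology$name)
  # teepee orientation: ceiling COM above the catalytic nucleophile
  nuc <- resolve_selection("resid 156 and name SG", t1$topology)
  expect_gt(t1$anchors$ceiling_com[3], t1$xyz[nuc, 3])
  expect_error(synthetic_spec(chain_length = 15), "even")
  expect_error(synthetic_spec(chain_length = 22), "12-20")
})

test_that("sampled scalars are realized exactly in the coordinates", {
  # degenerate distributions collapse onto the means
  sp <- synthetic_spec(n_frames = 5, seed = 2, d2_mean = 5, d2_sd = 0,
                       abd_mean = 110, abd_sd = 0, d1_mean = -3,
                       d1_sd = 0)
  sys <- generate_synthetic_trajectory(sp)
  ser <- reactivity_series(sys$traj, sys$selections)
  expect_equal(ser$d2, rep(5, 5), tolerance = 1e-9)
  expect_equal(ser$abd, rep(110, 5), tolerance = 1e-9)
  expect_equal(ser$d1, rep(-3, 5), tolerance = 1e-9)
  # stochastic case: ledger values reproduced to 1e-6 on every frame
  sys2 <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 200, seed = 3, reactive_prob = 0.5))
  ser2 <- reactivity_series(sys2$traj, sys2$selections)
  truth <- sys2$truth$frames
  expect_lt(max(abs(ser2$d1 - truth$d1)), 1e-6)
  expect_lt(max(abs(ser2$d2 - truth$d2)), 1e-6)
  expect_lt(max(abs(ser2$abd - truth$abd)), 1e-6)
  expect_identical(ser2$reactive, truth$reactive)
  expect_identical(ser2$improper, truth$improper)
})

test_that("same seed gives bit-identical systems, different seeds differ", {
  sp <- synthetic_spec(n_frames = 20, seed = 77, reactive_prob = 0.4)
  a <- generate_synthetic_trajectory(sp)
  b <- generate_synthetic_trajectory(sp)
  expect_identical(a$traj$xyz, b$traj$xyz)
  expect_identical(a$truth$frames, b$truth$frames)
  sp2 <- synthetic_spec(n_frames = 20, seed = 78, reactive_prob = 0.4)
  expect_false(identical(generate_synthetic_trajectory(sp2)$traj$xyz,
                         a$traj$xyz))
})

test_that("realized fractions are exact bookkeeping and near prescription", {
  sys <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 5000, seed = 10, reactive_prob = 0.6))
  tru <- sys$truth
  expect_equal(tru$realized_reactive_fraction,
               mean(tru$frames$reactive))
  se <- sqrt(0.6 * 0.4 / 5000)
  expect_lt(abs(tru$realized_reactive_fraction - 0.6), 3 * se)
})

test_that("unconditional draws follow the truncated normals (KS)", {
  sp <- synthetic_spec(n_frames = 5000, seed = 15)
  sys <- generate_synthetic_trajectory(sp)
  d2 <- sys$truth$frames$d2
  ptrunc <- function(q) {
    lo <- pnorm(sp$d2_bounds[1], sp$d2_mean, sp$d2_sd)
    hi <- pnorm(sp$d2_bounds[2], sp$d2_mean, sp$d2_sd)
    (pnorm(q, sp$d2_mean, sp$d2_sd) - lo) / (hi - lo)
  }
  expect_gt(suppressWarnings(ks.test(d2, ptrunc))$p.value, 0.01)
  expect_true(all(d2 > sp$d2_bounds[1] & d2 < sp$d2_bounds[2]))
  expect_true(all(sys$truth$frames$abd > 0 &
                    sys$truth$frames$abd < 180))
})

test_that("AR(1) correlation produces autocorrelated series", {
  s_iid <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 2000, seed = 31))
  s_ar <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 2000, seed = 31, ar1 = 0.9))
  ac <- function(x) cor(x[-1], x[-length(x)])
  expect_lt(abs(ac(s_iid$truth$frames$d2)), 0.1)
  expect_gt(ac(s_ar$truth$frames$d2), 0.5)
})

test_that("benchmark suite peaks at C16 and is seed-stable on disk", {
  suite <- make_benchmark_suite(seed = 2, n_frames = 150)
  expect_named(suite, c("C12", "C14", "C16", "C18", "C20"))
  expect_true(all(vapply(suite, function(s) n_frames(s$traj),
                         integer(1)) == 150L))
  fr <- vapply(suite, function(s) s$truth$realized_reactive_fraction,
               numeric(1))
  expect_equal(names(which.max(fr)), "C16")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_synthetic_system(suite$C16, d1)
  p2 <- write_synthetic_system(make_benchmark_suite(seed = 2,
                                                    n_frames = 150)$C16,
                               d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
})

test_that("the crystal stand-in realizes its constructed reference geometry", {
  cs <- synthetic_crystal_standin(d1 = -4.07, d2 = 6.6, abd = 127)
  expect_equal(n_frames(cs$traj), 1L)
  # mutant nucleophile: residue 156 is SER with a hydroxyl O
  top <- cs$traj$topology
  expect_equal(unique(top$resname[top$resid == 156]), "SER")
  expect_length(resolve_selection("resid 156 and name OG", top), 1L)
  expect_identical(cs$traj$xyz,
                   synthetic_crystal_standin(d1 = -4.07, d2 = 6.6,
                                             abd = 127)$traj$xyz)
})
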