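ctc_fixture <- function(dist_xy) {
  # one ligand atom at a controlled distance from one Ser29 atom
  top <- topology(name = c("CB", "CB", "CT"),
                  resname = c("SER", "VAL", "LIG"),
                  resid = c(29, 185, 1), chain = c("A", "A", "L"),
                  element = "C")
  xyz <- rbind(c(0, 0, 0), c(20, 0, 0), c(dist_xy, 0, 0))
  trajectory(top, xyz)
}

test_that("contact map applies the 4 A cutoff per frame", {
  cm <- contact_map(ctc_fixture(3.9), "resid 1", "resid 29 185")
  expect_equal(cm["A:SER29", "CT"], 1.0)
  expect_equal(cm["A:VAL185", "CT"], 0.0)
  cm2 <- contact_map(ctc_fixture(4.1), "resid 1", "resid 29 185")
  expect_equal(cm2["A:SER29", "CT"], 0.0)
  # two frames, contact in one -> 0.5
  top <- ctc_fixture(1)$topology
  xyz <- array(0, c(3, 3, 2))
  xyz[2, 1, ] <- 20
  xyz[3, 1, 1] <- 3.0; xyz[3, 1, 2] <- 9.0
  cm3 <- contact_map(trajectory(top, xyz), "resid 1", "resid 29 185")
  expect_equal(cm3["A:SER29", "CT"], 0.5)
  expect_error(contact_map(ctc_fixture(1), "name ZZ", "resid 29"),
               "empty")
})

test_that("terminal carbon of the synthetic cavity contacts only the ceiling triad", {
  sys <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 5, seed = 6, d1_mean = -2, d1_sd = 0))
  cm <- contact_map(sys$traj, sys$selections$terminal_c,
                    sys$selections$protein)
  touching <- rownames(cm)[rowSums(cm) > 0]
  expect_setequal(touching, c("A:SER29", "A:VAL185", "A:SER217"))
})

test_that("contact map equals the brute-force all-pairs oracle", {
  sys <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 6, seed = 9, reactive_prob = 0.5))
  tr <- sys$traj
  lig <- resolve_selection(sys$selections$ligand, tr$topology)
  prot <- resolve_selection("chain A and resid 140:160", tr$topology)
  cm <- contact_map(tr, lig, prot)
  oracle <- contact_oracle(tr, lig, prot)
  expect_equal(unclass(cm)[rownames(oracle), colnames(oracle)],
               oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

hb_fixture <- function(on_frames, n = 4, da_on = 2.8, da_off = 5) {
  top <- topology(name = c("OG", "HG", "OX"),
                  resname = c("SER", "SER", "LIG"),
                  resid = c(143, 143, 1), chain = c("A", "A", "L"),
                  element = c("O", "H", "O"))
  xyz <- array(0, c(3, 3, n))
  xyz[2, 1, ] <- 0.96
  xyz[3, 1, ] <- ifelse(seq_len(n) %in% on_frames, da_on, da_off)
  trajectory(top, xyz)
}

test_that("hydrogen bonds use the distance-and-angle criterion", {
  hb <- find_hbonds(hb_fixture(1:4), "name OG", "name OX")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$lifetime, 1.0)
  # broken in half the frames by stretching the donor-acceptor distance
  hb2 <- find_hbonds(hb_fixture(c(1, 2)), "name OG", "name OX")
  expect_equal(hb2$lifetime, 0.5)
  # donor without a bonded hydrogen is skipped with a warning
  tr <- hb_fixture(1:4)
  expect_warning(none <- find_hbonds(tr, "name OX", "name OG"),
                 "without a bonded hydrogen")
  expect_equal(nrow(none), 0)
})

test_that("prescribed synthetic H-bond occupancy is recovered exactly", {
  sys <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 50, seed = 4, hbond_occupancy = 0.30))
  hb <- find_hbonds(sys$traj, sys$selections$hbond_donors,
                    sys$selections$hbond_acceptors)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$lifetime, 0.30)
  expect_equal(hb$donor_res, "A:SER143")
})

test_that("lifetime filter is strict and honours any-trajectory rescue", {
  recs <- data.frame(donor_res = c("a", "b", "c"),
                     acceptor_res = "x",
                     lifetime = c(0.05, 0.10, 0.11))
  kept <- filter_hbonds(recs)
  expect_equal(kept$lifetime, 0.11)
  expect_equal(nrow(filter_hbonds(recs[0, ])), 0)
  # multi-trajectory: passes in at least one -> kept in all
  r1 <- data.frame(donor_res = "a", acceptor_res = "x", lifetime = 0.05)
  r2 <- data.frame(donor_res = "a", acceptor_res = "x", lifetime = 0.4)
  both <- filter_hbonds(list(r1, r2))
  expect_equal(nrow(both[[1]]), 1)   # rescued by the second trajectory
  expect_equal(nrow(both[[2]]), 1)
})

pc_fixture <- function(cation, n = 1) {
  th <- (0:5) * pi / 3
  top <- topology(name = c(paste0("R", 1:6), "CZ"),
                  resname = c(rep("ADE", 6), "ARG"),
                  resid = c(rep(1, 6), 246), chain = c(rep("L", 6), "A"),
                  element = c(rep("C", 6), "C"))
  xyz0 <- rbind(cbind(1.4 * cos(th), 1.4 * sin(th), 0), cation)
  trajectory(top, array(rep(xyz0, n), c(7, 3, n)))
}

test_that("pi-cation counts face-stacked geometry only", {
  expect_equal(pi_cation(pc_fixture(c(0, 0, 4)), "name CZ",
                         "resname ADE")$lifetime, 1.0)
  # in-plane at 4 A: tilt 90 degrees -> never counted
  expect_equal(pi_cation(pc_fixture(c(4, 0, 0)), "name CZ",
                         "resname ADE")$lifetime, 0.0)
  expect_error(pi_cation(pc_fixture(c(0, 0, 4)), "name CZ", "name R1 R2"),
               ">= 5")
})

test_that("synthetic stacking occupancy 0.95 is recovered exactly", {
  sys <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 100, seed = 12, pi_cation_occupancy = 0.95))
  pc <- pi_cation(sys$traj, sys$selections$pi_cation_cation,
                  sys$selections$pi_cation_ring)
  expect_equal(pc$lifetime, 0.95)
})

test_that("lifetimes are monotone in the geometric cutoffs", {
  sys <- generate_synthetic_trajectory(
    synthetic_spec(n_frames = 30, seed = 14, deterministic_toggle = FALSE,
                   hbond_occupancy = 0.5, pi_cation_occupancy = 0.5))
  tr <- sys$traj; sel <- sys$selections
  l1 <- find_hbonds(tr, sel$hbond_donors, sel$hbond_acceptors,
                    d_max = 3.0)$lifetime
  l2 <- find_hbonds(tr, sel$hbond_donors, sel$hbond_acceptors,
                    d_max = 8.0)$lifetime
  expect_lte(ifelse(length(l1) == 0, 0, l1), l2)
  p1 <- pi_cation(tr, sel$pi_cation_cation, sel$pi_cation_ring,
                  d_max = 4.5)$lifetime
  p2 <- pi_cation(tr, sel$pi_cation_cation, sel$pi_cation_ring,
                  d_max = 9.0, tilt_max = 95)$lifetime
  expect_lte(p1, p2)
  expect_true(all(c(l2, p1, p2) >= 0 & c(l2, p1, p2) <= 1))
})
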