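# Shared fixtures and independent oracles, built in code at test time.

# minimal topology of n identical carbon pseudo-atoms
toy_topology <- function(n, chain = "A") {
  topology(name = paste0("C", seq_len(n)), resname = "TOY",
           resid = seq_len(n), chain = chain, element = "C")
}

toy_traj <- function(xyz, box = NULL) {
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3, 1))
  trajectory(toy_topology(dim(xyz)[1]), xyz, box = box)
}

# the spec'd handwritten 3-atom PDB (catalytic cysteine with its thiol S)
write_cys_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   CYS A 156      11.104  13.207   2.100  1.00  0.00           N",
    "ATOM      2  CA  CYS A 156      12.560  13.300   2.300  1.00  0.00           C",
    "ATOM      3  SG  CYS A 156      13.000  14.000   3.000  1.00  0.00           S",
    "END"), path)
  path
}

# independent per-component distance oracle (explicit loop, no vector norm)
dist_oracle <- function(p, q) {
  acc <- 0
  for (k in 1:3) acc <- acc + (p[k] - q[k]) * (p[k] - q[k])
  sqrt(acc)
}

euler_rotation <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  rz1 <- rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1))
  ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  rz2 <- rbind(c(cc, -sc, 0), c(sc, cc, 0), c(0, 0, 1))
  rz1 %*% ry %*% rz2
}

# grid-search superposition oracle: exhaustive Euler sweep refined to the
# requested angular resolution (deg), independent of the SVD construction
grid_rmsd_oracle <- function(A, B, final_step = 0.5) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  eval_rmsd <- function(a, b, c) {
    R <- euler_rotation(a, b, c)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  deg <- pi / 180
  best <- c(0, 0, 0); best_v <- Inf
  for (a in seq(0, 350, 10) * deg)
    for (b in seq(0, 180, 10) * deg)
      for (c in seq(0, 350, 10) * deg) {
        v <- eval_rmsd(a, b, c)
        if (v < best_v) { best_v <- v; best <- c(a, b, c) }
      }
  step <- 10 * deg
  while (step > final_step * deg) {
    step <- step / 5
    grid <- seq(-5 * step, 5 * step, step)
    for (da in grid) for (db in grid) for (dc in grid) {
      v <- eval_rmsd(best[1] + da, best[2] + db, best[3] + dc)
      if (v < best_v) { best_v <- v; best2 <- best + c(da, db, dc) }
    }
    if (exists("best2")) { best <- best2; rm(best2) }
  }
  best_v
}

# brute-force filter-then-average summary oracle
summary_oracle <- function(series, d2_max = 6) {
  keep <- series$d2 < d2_max
  list(d1_mean = mean(series$d1),
       d2_mean = if (any(keep)) mean(series$d2[keep]) else NA_real_,
       abd_mean = if (any(keep)) mean(series$abd[keep]) else NA_real_,
       d2_sd = if (sum(keep) > 1) sd(series$d2[keep]) else NA_real_,
       reactive_fraction = mean(series$reactive))
}

# brute-force all-pairs contact oracle
contact_oracle <- function(traj, lig_idx, prot_idx, cutoff = 4) {
  top <- traj$topology
  lig_idx <- lig_idx[top$element[lig_idx] != "H"]
  prot_idx <- prot_idx[top$element[prot_idx] != "H"]
  res <- paste0(top$chain[prot_idx], ":", top$resname[prot_idx],
                top$resid[prot_idx])
  ures <- unique(res)
  out <- matrix(0, length(ures), length(lig_idx),
                dimnames = list(ures, top$name[lig_idx]))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- traj$xyz[, , f]
    for (r in seq_along(ures)) for (jc in seq_along(lig_idx)) {
      hit <- FALSE
      for (p in prot_idx[res == ures[r]])
        if (dist_oracle(xyz[p, ], xyz[lig_idx[jc], ]) < cutoff) hit <- TRUE
      out[r, jc] <- out[r, jc] + hit
    }
  }
  out / nf
}
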