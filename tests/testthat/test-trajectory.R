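test_that("Kabsch superposition recovers identity, translation, and known rotations", {
  ref <- tetrahedron()
  k0 <- kabsch_superpose(ref, ref)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  expect_lt(k0$rmsd, 1e-9)
  kt <- kabsch_superpose(ref, ref + matrix(c(5, 0, 0), 4, 3, byrow = TRUE))
  expect_lt(kt$rmsd, 1e-9)
  # forward-constructed 60-degree axis rotation: fit must apply its inverse
  R0 <- quat_to_matrix(quat_from_axis_angle(c(1, 1, 0), pi / 3))
  mob <- ref %*% t(R0) + matrix(c(1, -2, 3), 4, 3, byrow = TRUE)
  k <- kabsch_superpose(ref, mob)
  expect_equal(k$rotation, t(R0), tolerance = 1e-6)
  expect_lt(k$rmsd, 1e-6)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(tetrahedron()[1:2, ], tetrahedron()[1:2, ]),
               "at least 3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("ligand RMSD series reports a constructed 4 A displacement as 0.4 nm", {
  topo <- make_line_topology(8)
  lig <- select_atoms(topo, chain = "L")
  rec <- select_atoms(topo, chain = "A")
  frames <- lapply(1:6, function(i) {
    f <- coords(topo)
    if (i > 1) f[lig, 1] <- f[lig, 1] + 4
    f
  })
  rs <- ligand_rmsd_series(trajectory(topo, frames), lig, rec)
  expect_equal(rs$units, "nm")
  expect_equal(rs$values[1], 0, tolerance = 1e-12)
  expect_equal(rs$values[-1], rep(0.4, 5), tolerance = 1e-9)
})

test_that("ligand RMSD is zero for static frames and invariant to global motion", {
  topo <- make_line_topology(8)
  lig <- select_atoms(topo, chain = "L")
  rec <- select_atoms(topo, chain = "A")
  static <- trajectory(topo, replicate(4, coords(topo), simplify = FALSE))
  expect_equal(ligand_rmsd_series(static, lig, rec)$values, rep(0, 4),
               tolerance = 1e-9)
  # jointly translating and rotating receptor+ligand per frame
  moved <- lapply(1:5, function(i) {
    R <- quat_to_matrix(quat_from_axis_angle(c(0, 0, 1), 0.2 * i))
    coords(topo) %*% t(R) + matrix(c(i, -i, 2 * i), nrow(topo$atoms), 3,
                                   byrow = TRUE)
  })
  rs <- ligand_rmsd_series(trajectory(topo, moved), lig, rec)
  expect_equal(rs$values, rep(0, 5), tolerance = 1e-6)
})

test_that("RMSF is zero for a static trajectory and needs at least two frames", {
  topo <- make_line_topology(6)
  static <- trajectory(topo, replicate(3, coords(topo), simplify = FALSE))
  prof <- rmsf_profile(static, select_atoms(topo, chain = "A"),
                       select_atoms(topo, chain = "A"))
  expect_equal(prof$values, rep(0, 6), tolerance = 1e-12)
  one <- trajectory(topo, list(coords(topo)))
  expect_error(rmsf_profile(one, 1:6, 1:6), "at least 2 frames")
})

test_that("residue groups with 2:1 jitter amplitudes show a 2:1 RMSF ratio", {
  topo <- make_line_topology(10)
  amp <- c(rep(0, 4), rep(0.8, 3), rep(0.4, 3), 0)  # + ligand residue
  tr <- simulate_trajectory(topo, amp, n_frames = 2000, seed = 17)
  prof <- rmsf_profile(tr, select_atoms(topo, chain = "A"),
                       fit = select_atoms(topo, chain = "A", resno = 1:4))
  hi <- mean(prof$values[5:7]); lo <- mean(prof$values[8:10])
  expect_equal(hi / lo, 2, tolerance = 0.1)
})

test_that("RMSF and occupancy are invariant under a global rigid transform of all frames", {
  topo <- make_line_topology(8)
  amp <- c(rep(0.5, 8), 0)
  tr <- simulate_trajectory(topo, amp, n_frames = 40, seed = 23)
  R <- quat_to_matrix(quat_from_axis_angle(c(2, -1, 1), 0.8))
  shift <- c(4, 5, -6)
  tr2 <- trajectory(topo, lapply(tr$frames, function(f)
    f %*% t(R) + matrix(shift, nrow(f), 3, byrow = TRUE)))
  sel <- select_atoms(topo, chain = "A")
  lig <- select_atoms(topo, chain = "L")
  p1 <- rmsf_profile(tr, sel, sel); p2 <- rmsf_profile(tr2, sel, sel)
  expect_equal(p1$values, p2$values, tolerance = 1e-6)
  o1 <- contact_occupancy(tr, lig); o2 <- contact_occupancy(tr2, lig)
  expect_equal(o1$values, o2$values, tolerance = 1e-6)
})

test_that("contact occupancy counts contact frames and matches a brute-force scan", {
  topo <- make_line_topology(10)
  lig <- select_atoms(topo, chain = "L")
  cp <- list(ligand = lig, chain_id = "A", residue_number = 4, fraction = 0.3)
  tr <- simulate_trajectory(topo, rep(0, 11), n_frames = 10, seed = 1,
                            contact_pattern = cp)
  occ <- contact_occupancy(tr, lig)
  expect_equal(occ$values[occ$keys$residue_number == 4], 0.3)
  expect_true(all(occ$values >= 0 & occ$values <= 1))
  # random-jitter fixture vs an independent per-frame double loop
  tr2 <- simulate_trajectory(topo, rep(1.5, 11), n_frames = 15, seed = 9)
  got <- contact_occupancy(tr2, lig, cutoff = 6)
  at <- topo$atoms
  rec_idx <- select_atoms(topo, chain = "A")
  want <- sapply(rec_idx, function(ri) {
    mean(sapply(tr2$frames, function(f) {
      any(sqrt(colSums((t(f[lig, , drop = FALSE]) - f[ri, ])^2)) <= 6)
    }))
  })
  keyorder <- match(at$residue_number[rec_idx],
                    got$keys$residue_number[got$keys$chain_id == "A"])
  expect_equal(got$values[got$keys$chain_id == "A"][keyorder], unname(want))
})

test_that("a far-away ligand has zero occupancy everywhere and occupancy grows with cutoff", {
  topo <- make_line_topology(8)
  lig <- select_atoms(topo, chain = "L")
  frames <- lapply(1:5, function(i) {
    f <- coords(topo); f[lig, 3] <- f[lig, 3] + 30; f
  })
  tr <- trajectory(topo, frames)
  expect_true(all(contact_occupancy(tr, lig)$values == 0))
  tr2 <- simulate_trajectory(topo, rep(1, 9), n_frames = 20, seed = 3)
  o_small <- contact_occupancy(tr2, lig, cutoff = 4)
  o_large <- contact_occupancy(tr2, lig, cutoff = 8)
  expect_true(all(o_large$values >= o_small$values))
})

test_that("the enthalpy series equals the pairwise oracle with a hand-checked moving average", {
  topo <- make_line_topology(5)
  lig <- select_atoms(topo, chain = "L")
  rec <- select_atoms(topo, chain = "A")
  set.seed(41)
  frames <- lapply(1:5, function(i)
    coords(topo) + matrix(rnorm(nrow(topo$atoms) * 3, sd = 0.4),
                          nrow(topo$atoms), 3))
  tr <- trajectory(topo, frames)
  es <- enthalpy_series(tr, lig, rec, window = 3)
  # per-frame values against the independent oracle
  at <- topo$atoms
  for (i in 1:5) {
    la <- at[lig, ]; la[, c("x", "y", "z")] <- frames[[i]][lig, ]
    ra <- at[rec, ]; ra[, c("x", "y", "z")] <- frames[[i]][rec, ]
    sys <- pair_system(as.matrix(ra[, c("x", "y", "z")]),
                       as.matrix(la[, c("x", "y", "z")]))
    want <- oracle_score(sys$receptor,
                         pose(sys$ligand,
                              colMeans(as.matrix(la[, c("x", "y", "z")]))))
    expect_equal(es$values[i], want$total, tolerance = 1e-9)
  }
  v <- es$values
  expect_equal(es$moving_average,
               c(mean(v[1:2]), mean(v[1:3]), mean(v[2:4]), mean(v[3:5]),
                 mean(v[4:5])))
})

test_that("window-1 moving averages equal the raw series; constant series stay constant", {
  topo <- make_line_topology(5)
  lig <- select_atoms(topo, chain = "L")
  rec <- select_atoms(topo, chain = "A")
  tr <- trajectory(topo, replicate(4, coords(topo), simplify = FALSE))
  es1 <- enthalpy_series(tr, lig, rec, window = 1)
  expect_identical(es1$moving_average, es1$values)
  expect_equal(diff(es1$values), rep(0, 3))
  expect_error(enthalpy_series(tr, lig, rec, window = 10), "window")
})

test_that("multi-model PDB trajectories round-trip through disk", {
  topo <- make_line_topology(6)
  tr <- simulate_trajectory(topo, rep(0.3, 7), n_frames = 4, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_length(tr2$frames, 4L)
  for (i in 1:4)
    expect_equal(tr2$frames[[i]], round(tr$frames[[i]], 3),
                 ignore_attr = TRUE)
  expect_equal(tr2$topology$atoms$residue_number, topo$atoms$residue_number)
})
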