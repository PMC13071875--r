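test_that("ligand beyond the nonbonded cutoff scores exactly zero", {
  sys <- pair_system(matrix(c(0, 0, 0), 1),
                     matrix(c(0, 0, 0, 1, 0, 0), 2, byrow = TRUE))
  p <- pose(sys$ligand, translation = c(100, 0, 0))
  s <- score_pose(sys$receptor, p)
  expect_identical(unname(c(s$lj, s$electrostatic, s$clash_penalty, s$total)),
                   rep(0, 4))
})

test_that("a pair at the Lennard-Jones minimum distance scores -epsilon", {
  sp <- scoring_params()
  rm <- 2 * vdw_radius("C")  # combined radii of two carbons
  # second ligand atom parked far beyond the cutoff: exactly one active pair
  sys <- pair_system(matrix(c(0, 0, 0), 1),
                     matrix(c(0, 0, 0, 0, 0, 30), 2, byrow = TRUE))
  s <- score_pose(sys$receptor, pose(sys$ligand, c(rm, 0, 15)), sp)
  expect_equal(s$lj, -sp$epsilon, tolerance = 1e-12)
  expect_equal(s$electrostatic, 0)
  expect_equal(s$clash_penalty, 0)
  expect_equal(s$total, s$lj)
})

test_that("score_pose matches the independent brute-force oracle on small systems", {
  set.seed(31)
  for (rep in 1:12) {
    nr <- sample(2:5, 1); nl <- sample(2:4, 1)
    sys <- pair_system(matrix(rnorm(3 * nr, sd = 2), nr),
                       matrix(rnorm(3 * nl, sd = 1), nl),
                       rec_charge = runif(nr, -0.5, 0.5),
                       lig_charge = runif(nl, -0.5, 0.5))
    p <- pose(sys$ligand, translation = rnorm(3, sd = 2),
              rotation = random_quaternion())
    got <- score_pose(sys$receptor, p)
    want <- oracle_score(sys$receptor, p)
    expect_equal(got$lj, want$lj, tolerance = 1e-9)
    expect_equal(got$electrostatic, want$electrostatic, tolerance = 1e-9)
    expect_equal(got$clash_penalty, want$clash_penalty, tolerance = 1e-9)
    expect_equal(got$total, want$total, tolerance = 1e-9)
  }
})

test_that("the score breakdown total is the exact sum of its components", {
  toy <- toy_fixture_fast()
  set.seed(5)
  for (i in 1:10) {
    p <- random_pose(toy$ligand, toy$box)
    s <- score_pose(toy$receptor, p)
    expect_identical(s$total, s$lj + s$electrostatic + s$clash_penalty)
  }
})

test_that("scores are invariant under a joint rigid transform of receptor and pose", {
  toy <- toy_fixture_fast()
  set.seed(6)
  qg <- quat_from_axis_angle(c(1, 2, -1), 1.1)
  Rg <- quat_to_matrix(qg)
  tg <- c(3, -7, 2)
  rec2 <- toy$receptor
  rec2$atoms[, c("x", "y", "z")] <- coords(toy$receptor) %*% t(Rg) +
    matrix(tg, nrow(rec2$atoms), 3, byrow = TRUE)
  for (i in 1:5) {
    p <- random_pose(toy$ligand, toy$box)
    p2 <- pose(toy$ligand, as.vector(Rg %*% p$translation) + tg,
               quat_multiply(qg, p$rotation))
    s1 <- score_pose(toy$receptor, p)
    s2 <- score_pose(rec2, p2)
    expect_equal(s2$total, s1$total, tolerance = 1e-6)
  }
})

test_that("random poses fill the box uniformly and are seed-reproducible", {
  toy <- toy_fixture_fast()
  big <- search_box(c(2, -1, 4), edge = 15)
  set.seed(7)
  cent <- t(replicate(10000, random_pose(toy$ligand, big)$translation))
  bb <- box_bounds(big)
  for (k in 1:3) {
    expect_true(all(cent[, k] >= bb[1, k] & cent[, k] <= bb[2, k]))
    expect_lt(abs(mean(cent[, k]) - big$center[k]), 0.5)
  }
  set.seed(99); p1 <- random_pose(toy$ligand, big)
  set.seed(99); p2 <- random_pose(toy$ligand, big)
  expect_identical(p1, p2)
})

test_that("random orientations are uniform on SO(3)", {
  set.seed(8)
  n <- 50000
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  # mean rotation matrix of a uniform distribution is the zero matrix
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  entries <- cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                   2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                   2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  expect_true(all(abs(colMeans(entries)) < 0.02))
})

test_that("mutation with zero step sds is the identity and clipping holds at faces", {
  toy <- toy_fixture_fast()
  ga0 <- ga_params(10, 5, 1, translation_step_sd = 0, rotation_step_sd = 0)
  p <- pose(toy$ligand, toy$box$center, random_quaternion())
  expect_identical(mutate_pose(p, toy$box, ga0), p)
  # parent on a box face: offspring centroids stay inside
  bb <- box_bounds(toy$box)
  face <- pose(toy$ligand, c(bb[2, 1], toy$box$center[2], toy$box$center[3]))
  ga1 <- ga_params(10, 5, 1, translation_step_sd = 5)
  set.seed(10)
  for (i in 1:50) {
    m <- mutate_pose(face, toy$box, ga1)
    expect_true(in_box(toy$box, m$translation))
  }
})

test_that("mutation step sizes realize the requested standard deviation", {
  toy <- toy_fixture_fast()
  huge <- search_box(c(0, 0, 0), edge = 200)
  p <- pose(toy$ligand, c(0, 0, 0))
  ga1 <- ga_params(10, 5, 1, translation_step_sd = 1)
  set.seed(12)
  disp <- t(replicate(1000, mutate_pose(p, huge, ga1)$translation))
  for (k in 1:3) expect_lt(abs(sd(disp[, k]) - 1), 0.1)
})

test_that("a zero-generation schedule degenerates to pure random search", {
  toy <- toy_fixture_fast()
  res <- ga_dock(toy$receptor, toy$ligand, toy$box,
                 ga_params(300, 30, 0, seed = 3))
  expect_length(res$per_generation_best, 1L)
  expect_equal(res$best_score, res$per_generation_best[1])
  expect_equal(res$evaluations, 300L)
})

test_that("docking is bit-reproducible from its seed", {
  toy <- toy_fixture_fast()
  ga <- ga_params(200, 20, 4, seed = 77)
  r1 <- ga_dock(toy$receptor, toy$ligand, toy$box, ga)
  r2 <- ga_dock(toy$receptor, toy$ligand, toy$box, ga)
  expect_identical(r1, r2)
})

test_that("invalid GA parameters are rejected", {
  expect_error(ga_params(n_poses = 10, n_elite = 20), "n_elite")
  expect_error(ga_params(n_generations = -1), "n_generations")
})

test_that("screening ranks the compound sitting in the toy well first", {
  toy <- toy_fixture_fast()
  # a decoy ligand with strongly repulsive charge against the pocket floor
  decoy <- conformer("ZZZ_DECOY", within(toy$ligand$atoms, charge <- c(0, 0.3, 0)))
  cfs <- list(decoy, toy$ligand)
  tab <- screen_library(toy$receptor, cfs, toy$box,
                        ga_params(200, 20, 5, seed = 13))
  expect_equal(tab$compound_id[1], "TOY")
  expect_lt(tab$total[1], tab$total[2])
})

test_that("screening order does not change per-compound results", {
  toy <- toy_fixture_fast()
  other <- conformer("AAA", within(toy$ligand$atoms, charge <- 0))
  ga <- ga_params(150, 15, 3, seed = 21)
  t1 <- screen_library(toy$receptor, list(toy$ligand, other), toy$box, ga)
  t2 <- screen_library(toy$receptor, list(other, toy$ligand), toy$box, ga)
  expect_equal(t1, t2, ignore_attr = TRUE)
})

test_that("undersized conformers are skipped with a warning and counted", {
  toy <- toy_fixture_fast()
  bad <- toy$ligand
  bad$atoms <- bad$atoms[1, , drop = FALSE]
  expect_warning(
    tab <- screen_library(toy$receptor, list(toy$ligand, bad), toy$box,
                          ga_params(100, 10, 2, seed = 2)),
    "fewer than 2 atoms")
  expect_equal(nrow(tab), 1L)
  expect_equal(attr(tab, "skipped"), 1L)
})
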