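# Rigid-conformer elitist genetic-algorithm docking.  Each generation keeps
# the n_elite lowest-energy poses and refills the population by Gaussian
# translation/rotation mutation of uniformly chosen elites; no crossover.
# Scale defaults follow the published screen scheme (20,000 poses, 1,000
# elites, 10 generations); tests and the toy system run smaller instances.

#' Genetic-algorithm parameters
#'
#' @param n_poses population size per generation (default 20000).
#' @param n_elite number of lowest-energy poses carried over (default 1000).
#' @param n_generations number of mutation/selection cycles after the initial
#'   random generation (default 10); 0 means pure random search.
#' @param translation_step_sd Gaussian mutation step per axis, Angstrom.
#' @param rotation_step_sd Gaussian rotation mutation angle, radians.
#' @param seed integer RNG seed; every run is reproducible from it.
#' @return list of class `ga_params`.
#' @export
ga_params <- function(n_poses = 20000, n_elite = 1000, n_generations = 10,
                      translation_step_sd = 1.0, rotation_step_sd = 0.26,
                      seed = 1L) {
  if (!(n_elite > 0 && n_elite <= n_poses))
    stop("n_elite must satisfy 0 < n_elite <= n_poses")
  if (n_generations < 0) stop("n_generations must be >= 0")
  structure(list(n_poses = as.integer(n_poses), n_elite = as.integer(n_elite),
                 n_generations = as.integer(n_generations),
                 translation_step_sd = translation_step_sd,
                 rotation_step_sd = rotation_step_sd, seed = as.integer(seed)),
            class = "ga_params")
}

# run expr under a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Draw a random pose uniformly in a search box
#'
#' Centroid uniform over the box; orientation uniform on SO(3) (quaternion
#' from four standard normals, normalized).  Draws from the current RNG
#' stream — seed outside for reproducibility.
#'
#' @param conf a `Conformer`.
#' @param box a `SearchBox`.
#' @return a `Pose`.
#' @export
random_pose <- function(conf, box) {
  b <- box_bounds(box)
  pose(conf, stats::runif(3, b[1, ], b[2, ]), random_quaternion())
}

.clip_to_box <- function(p3, box) {
  b <- box_bounds(box)
  pmin(pmax(p3, b[1, ]), b[2, ])
}

#' Mutate a pose by Gaussian translation and rotation steps
#'
#' Translation steps are independent Gaussians per axis, clipped so the
#' centroid stays inside the box; the rotation is composed with a small
#' random rotation about a uniform axis.  Step sd 0 leaves that component
#' unchanged exactly.  The parent pose is not modified.
#'
#' @param p a `Pose`.
#' @param box a `SearchBox`.
#' @param params a [ga_params()] list (step sds are read from it).
#' @return a new `Pose`.
#' @export
mutate_pose <- function(p, box, params) {
  tr <- p$translation
  if (params$translation_step_sd > 0)
    tr <- .clip_to_box(tr + stats::rnorm(3, 0, params$translation_step_sd), box)
  q <- p$rotation
  if (params$rotation_step_sd > 0) {
    ax <- stats::rnorm(3)
    ang <- stats::rnorm(1, 0, params$rotation_step_sd)
    q <- quat_normalize(quat_multiply(quat_from_axis_angle(ax, ang), q))
  }
  pose(p$conformer, tr, q)
}

# batch mutation used inside the GA loop: vectorized over n offspring
.mutate_batch <- function(trans, quat, box, params) {
  n <- nrow(trans)
  if (params$translation_step_sd > 0) {
    step <- matrix(stats::rnorm(3 * n, 0, params$translation_step_sd), n, 3)
    b <- box_bounds(box)
    trans <- trans + step
    for (k in 1:3) trans[, k] <- pmin(pmax(trans[, k], b[1, k]), b[2, k])
  }
  if (params$rotation_step_sd > 0) {
    ax <- matrix(stats::rnorm(3 * n), n, 3)
    ax <- ax / sqrt(rowSums(ax^2))
    ang <- stats::rnorm(n, 0, params$rotation_step_sd)
    dq <- cbind(cos(ang / 2), sin(ang / 2) * ax)
    # Hamilton product dq * quat, row-wise
    w1 <- dq[, 1]; x1 <- dq[, 2]; y1 <- dq[, 3]; z1 <- dq[, 4]
    w2 <- quat[, 1]; x2 <- quat[, 2]; y2 <- quat[, 3]; z2 <- quat[, 4]
    quat <- cbind(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
                  w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
                  w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
                  w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
    quat <- quat / sqrt(rowSums(quat^2))
  }
  list(trans = trans, quat = quat)
}

#' Dock one rigid conformer with the elitist genetic algorithm
#'
#' Generation 0 scores `n_poses` random poses; each subsequent generation
#' keeps the `n_elite` lowest-total poses and refills the population to
#' `n_poses` with mutants of uniformly chosen elites.  Fully reproducible
#' from `ga$seed`.
#'
#' @param receptor a `Structure`.
#' @param conf a `Conformer`.
#' @param box a `SearchBox`.
#' @param ga a [ga_params()] list.
#' @param scoring a [scoring_params()] list.
#' @return list of class `DockingResult`: `best_pose` (with its
#'   `ScoreBreakdown` attached), `best_score` (kcal/mol),
#'   `per_generation_best` (length `n_generations + 1`, non-increasing),
#'   `evaluations`.
#' @export
ga_dock <- function(receptor, conf, box, ga = ga_params(),
                    scoring = scoring_params()) {
  stopifnot(inherits(receptor, "Structure"), inherits(conf, "Conformer"),
            inherits(box, "SearchBox"))
  .with_seed(ga$seed, {
    n <- ga$n_poses
    b <- box_bounds(box)
    trans <- cbind(stats::runif(n, b[1, 1], b[2, 1]),
                   stats::runif(n, b[1, 2], b[2, 2]),
                   stats::runif(n, b[1, 3], b[2, 3]))
    quat <- matrix(stats::rnorm(4 * n), n, 4)
    quat <- quat / sqrt(rowSums(quat^2))
    sc <- .score_batch(receptor, conf, trans, quat, scoring)
    evals <- n
    gen_best <- numeric(ga$n_generations + 1)
    gen_best[1] <- min(sc[, "total"])
    if (ga$n_generations > 0) {
      for (g in seq_len(ga$n_generations)) {
        elite <- order(sc[, "total"])[seq_len(ga$n_elite)]
        n_off <- n - ga$n_elite
        parents <- elite[sample.int(ga$n_elite, n_off, replace = TRUE)]
        off <- .mutate_batch(trans[parents, , drop = FALSE],
                             quat[parents, , drop = FALSE], box, ga)
        off_sc <- .score_batch(receptor, conf, off$trans, off$quat, scoring)
        evals <- evals + n_off
        trans <- rbind(trans[elite, , drop = FALSE], off$trans)
        quat <- rbind(quat[elite, , drop = FALSE], off$quat)
        sc <- rbind(sc[elite, , drop = FALSE], off_sc)
        gen_best[g + 1] <- min(sc[, "total"])
      }
    }
    i <- which.min(sc[, "total"])
    best <- pose(conf, trans[i, ], quat[i, ])
    best$score <- structure(list(lj = unname(sc[i, "lj"]),
                                 electrostatic = unname(sc[i, "electrostatic"]),
                                 clash_penalty = unname(sc[i, "clash"]),
                                 total = unname(sc[i, "total"])),
                            class = "ScoreBreakdown")
    structure(list(best_pose = best, best_score = unname(sc[i, "total"]),
                   per_generation_best = gen_best, evaluations = evals),
              class = "DockingResult")
  })
}

# per-conformer seed derived from the master seed and the conformer identity,
# so screening order cannot change any result
.conformer_seed <- function(master, compound_id, conformer_index) {
  h <- sum(utf8ToInt(compound_id) * seq_along(utf8ToInt(compound_id)))
  as.integer((as.numeric(master) * 48271 + h * 2654435 +
              conformer_index * 97003) %% 2147483646) + 1L
}

#' Screen a conformer library against a receptor pocket
#'
#' Runs [ga_dock()] per conformer (with a per-conformer seed derived from the
#' master seed and the conformer identity) and reports the best score per
#' compound.  Conformers with fewer than 2 atoms are skipped with a warning
#' and counted.  Ties in total score are broken by compound id.
#'
#' @param receptor a `Structure`.
#' @param conformers list of `Conformer` objects (possibly several per
#'   compound id).
#' @param box a `SearchBox`.
#' @param ga a [ga_params()] list; `ga$seed` is the master seed.
#' @param scoring a [scoring_params()] list.
#' @param progress_every emit a progress message every this many compounds
#'   (0 silences).
#' @return data frame sorted by ascending total score with columns
#'   `compound_id`, `best_conformer`, `lj`, `electrostatic`, `clash`,
#'   `total`; attribute `skipped` counts invalid conformers.
#' @export
screen_library <- function(receptor, conformers, box, ga = ga_params(),
                           scoring = scoring_params(), progress_every = 0) {
  stopifnot(length(conformers) > 0)
  rows <- list(); skipped <- 0L
  ids <- vapply(conformers, function(cf) cf$compound_id, "")
  for (ci in seq_along(conformers)) {
    cf <- conformers[[ci]]
    if (!inherits(cf, "Conformer") || nrow(cf$atoms) < 2L) {
      warning("skipping conformer ", ci, ": fewer than 2 atoms")
      skipped <- skipped + 1L
      next
    }
    ga_i <- ga
    ga_i$seed <- .conformer_seed(ga$seed, cf$compound_id, cf$conformer_index)
    res <- ga_dock(receptor, cf, box, ga_i, scoring)
    s <- res$best_pose$score
    rows[[length(rows) + 1L]] <- data.frame(
      compound_id = cf$compound_id, conformer_index = cf$conformer_index,
      lj = s$lj, electrostatic = s$electrostatic, clash = s$clash_penalty,
      total = s$total, stringsAsFactors = FALSE)
    if (progress_every > 0 && ci %% progress_every == 0)
      message(sprintf("screened %d / %d conformers", ci, length(conformers)))
  }
  if (length(rows) == 0L) stop("no valid conformers to screen")
  tab <- do.call(rbind, rows)
  # best conformer per compound
  best <- do.call(rbind, lapply(split(tab, tab$compound_id), function(d) {
    d[order(d$total, d$conformer_index)[1L], ]
  }))
  best <- best[order(best$total, best$compound_id), ]
  names(best)[names(best) == "conformer_index"] <- "best_conformer"
  rownames(best) <- NULL
  attr(best, "skipped") <- skipped
  best
}

#' Exhaustive grid enumeration of the pose space (reference oracle)
#'
#' Scores every pose on a regular grid: centroid translations on a cubic
#' lattice spanning the box and orientations on a z-y-z Euler-angle lattice.
#' Intended as the brute-force reference for small toy systems; cost grows as
#' (edge/step + 1)^3 x orientation count.
#'
#' @param receptor a `Structure`.
#' @param conf a `Conformer`.
#' @param box a `SearchBox`.
#' @param translation_step lattice spacing, Angstrom (default 0.25).
#' @param angle_step Euler-angle spacing, degrees (default 15).
#' @param scoring a [scoring_params()] list.
#' @return list with `best_pose`, `best_score`, `n_poses`.
#' @export
grid_minimum <- function(receptor, conf, box, translation_step = 0.25,
                         angle_step = 15, scoring = scoring_params()) {
  b <- box_bounds(box)
  ax <- lapply(1:3, function(k) seq(b[1, k], b[2, k], by = translation_step))
  tr <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                              KEEP.OUT.ATTRS = FALSE))
  alpha <- seq(0, 360 - angle_step, by = angle_step) * pi / 180
  beta  <- seq(0, 180, by = angle_step) * pi / 180
  gamma <- seq(0, 360 - angle_step, by = angle_step) * pi / 180
  eul <- expand.grid(a = alpha, b = beta, g = gamma, KEEP.OUT.ATTRS = FALSE)
  # z-y-z Euler angles as a quaternion product qz(a) qy(b) qz(g)
  qa <- cbind(cos(eul$a / 2), 0, 0, sin(eul$a / 2))
  qb <- cbind(cos(eul$b / 2), 0, sin(eul$b / 2), 0)
  qg <- cbind(cos(eul$g / 2), 0, 0, sin(eul$g / 2))
  qm <- function(p, q) cbind(
    p[, 1] * q[, 1] - p[, 2] * q[, 2] - p[, 3] * q[, 3] - p[, 4] * q[, 4],
    p[, 1] * q[, 2] + p[, 2] * q[, 1] + p[, 3] * q[, 4] - p[, 4] * q[, 3],
    p[, 1] * q[, 3] - p[, 2] * q[, 4] + p[, 3] * q[, 1] + p[, 4] * q[, 2],
    p[, 1] * q[, 4] + p[, 2] * q[, 3] - p[, 3] * q[, 2] + p[, 4] * q[, 1])
  quats <- qm(qm(qa, qb), qg)
  best_total <- Inf; best_t <- NULL; best_q <- NULL
  n_total <- nrow(tr) * nrow(quats)
  # chunk over orientations to bound memory
  for (oi in seq_len(nrow(quats))) {
    q <- quats[oi, ]
    sc <- .score_batch(receptor, conf, tr,
                       matrix(q, nrow(tr), 4, byrow = TRUE), scoring)
    i <- which.min(sc[, "total"])
    if (sc[i, "total"] < best_total) {
      best_total <- sc[i, "total"]; best_t <- tr[i, ]; best_q <- q
    }
  }
  bp <- pose(conf, best_t, best_q)
  bp$score <- score_pose(receptor, bp, scoring)
  list(best_pose = bp, best_score = unname(best_total), n_poses = n_total)
}
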