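# Empirical intermolecular scoring and rigid-pose geometry.  The functional
# form (softened 12-6 + screened Coulomb + linear clash penalty) is this
# package's own; all constants live in scoring_params() so a user can retune
# without touching code.

#' Scoring parameters for the empirical intermolecular function
#'
#' @param cutoff nonbonded pair cutoff, Angstrom.
#' @param epsilon Lennard-Jones well depth per pair, kcal/mol.
#' @param coulomb_k Coulomb constant, kcal*Angstrom/(mol*e^2).
#' @param dielectric_slope slope of the distance-dependent dielectric
#'   eps(r) = slope * r (dimensionless per Angstrom).
#' @param repulsion_cap maximum per-pair Lennard-Jones repulsion, kcal/mol.
#' @param clash_scale fraction of the combined vdW radii below which the
#'   linear clash penalty turns on.
#' @param clash_k clash penalty slope, kcal/mol per Angstrom of overlap.
#' @return a list of class `scoring_params`.
#' @export
scoring_params <- function(cutoff = 8, epsilon = 0.2, coulomb_k = 332.0636,
                           dielectric_slope = 4, repulsion_cap = 10,
                           clash_scale = 0.6, clash_k = 10) {
  stopifnot(cutoff > 0, epsilon > 0, clash_scale > 0, clash_scale < 1)
  structure(list(cutoff = cutoff, epsilon = epsilon, coulomb_k = coulomb_k,
                 dielectric_slope = dielectric_slope,
                 repulsion_cap = repulsion_cap, clash_scale = clash_scale,
                 clash_k = clash_k),
            class = "scoring_params")
}

## ---- quaternion helpers (w, x, y, z convention) ----

#' Normalize a quaternion to unit length
#' @param q numeric length-4 (w, x, y, z).
#' @export
quat_normalize <- function(q) q / sqrt(sum(q^2))

#' Hamilton product of two quaternions
#' @param a,b numeric length-4 quaternions (w, x, y, z).
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation matrix of a unit quaternion
#' @param q numeric length-4 (w, x, y, z); normalized internally.
#' @return 3 x 3 proper rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Quaternion for a rotation about an axis
#' @param axis numeric length-3 axis (normalized internally).
#' @param angle rotation angle, radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Uniform random unit quaternion (uniform on SO(3))
#'
#' Four standard normals, normalized; draws from the current RNG stream.
#' @export
random_quaternion <- function() quat_normalize(stats::rnorm(4))

## ---- conformers and poses ----

#' Construct a rigid ligand conformer
#' @param compound_id compound identifier string.
#' @param atoms atom data frame (see [make_structure()]); >= 2 atoms.
#' @param conformer_index integer index within the compound's conformer set.
#' @return an object of class `Conformer`.
#' @export
conformer <- function(compound_id, atoms, conformer_index = 1L) {
  s <- make_structure(atoms)
  if (nrow(s$atoms) < 2L) stop("a conformer needs at least 2 atoms")
  structure(list(compound_id = compound_id,
                 conformer_index = as.integer(conformer_index),
                 atoms = s$atoms),
            class = "Conformer")
}

.lig_local <- function(conf) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  sweep(xyz, 2, colMeans(xyz))
}

#' Construct a pose: rigid placement of a conformer
#'
#' `translation` is the absolute centroid position of the placed ligand;
#' `rotation` (unit quaternion) acts about the ligand centroid.
#'
#' @param conf a `Conformer`.
#' @param translation numeric length-3 centroid position, Angstrom.
#' @param rotation numeric length-4 quaternion (w, x, y, z).
#' @return an object of class `Pose`.
#' @export
pose <- function(conf, translation, rotation = c(1, 0, 0, 0)) {
  stopifnot(inherits(conf, "Conformer"), length(translation) == 3,
            length(rotation) == 4)
  nrm <- sqrt(sum(rotation^2))
  if (abs(nrm - 1) > 1e-9) rotation <- rotation / nrm
  structure(list(conformer = conf, translation = as.numeric(translation),
                 rotation = as.numeric(rotation), score = NULL),
            class = "Pose")
}

#' Ligand coordinates of a pose in the receptor frame
#' @param p a `Pose`.
#' @return n x 3 coordinate matrix.
#' @export
pose_coords <- function(p) {
  R <- quat_to_matrix(p$rotation)
  sweep(.lig_local(p$conformer) %*% t(R), 2, p$translation, "+")
}

## ---- scoring ----

.score_batch <- function(receptor, conf, trans, quat, params) {
  ra <- receptor$atoms
  la <- conf$atoms
  .score_poses_cpp(as.matrix(ra[, c("x", "y", "z")]), ra$charge, ra$radius,
                   .lig_local(conf), la$charge, la$radius,
                   trans, quat,
                   params$cutoff, params$epsilon, params$coulomb_k,
                   params$dielectric_slope, params$repulsion_cap,
                   params$clash_scale, params$clash_k)
}

#' Score a pose against a receptor
#'
#' Pairwise sum over receptor-ligand atom pairs within the nonbonded cutoff
#' of (a) a softened 12-6 Lennard-Jones term whose minimum sits at the sum of
#' the two vdW radii, with per-pair repulsion capped, (b) a Coulomb term with
#' distance-dependent dielectric eps(r) = slope*r, and (c) a linear clash
#' penalty for pair distances below `clash_scale * (r_i + r_j)`.
#' Deterministic; zero pairs within the cutoff gives all-zero components.
#'
#' @param receptor a non-empty `Structure`.
#' @param p a `Pose`.
#' @param params a [scoring_params()] list.
#' @return list of class `ScoreBreakdown` with `lj`, `electrostatic`,
#'   `clash_penalty`, `total` (kcal/mol); `total` is their exact sum.
#' @export
score_pose <- function(receptor, p, params = scoring_params()) {
  stopifnot(inherits(receptor, "Structure"), nrow(receptor$atoms) > 0,
            inherits(p, "Pose"))
  m <- .score_batch(receptor, p$conformer,
                    matrix(p$translation, 1), matrix(p$rotation, 1), params)
  structure(list(lj = unname(m[1, "lj"]),
                 electrostatic = unname(m[1, "electrostatic"]),
                 clash_penalty = unname(m[1, "clash"]),
                 total = unname(m[1, "total"])),
            class = "ScoreBreakdown")
}

#' Interaction energy between two atom sets at fixed coordinates
#'
#' The same pairwise function as [score_pose()], evaluated on coordinates as
#' given (no rigid transform).  Used by the trajectory enthalpy series.
#'
#' @param receptor_atoms,ligand_atoms atom data frames with coordinates,
#'   `charge` and `radius` columns.
#' @param params a [scoring_params()] list.
#' @return total interaction energy, kcal/mol.
#' @export
interaction_energy <- function(receptor_atoms, ligand_atoms,
                               params = scoring_params()) {
  lig_xyz <- as.matrix(ligand_atoms[, c("x", "y", "z")])
  cen <- colMeans(lig_xyz)
  m <- .score_poses_cpp(as.matrix(receptor_atoms[, c("x", "y", "z")]),
                        receptor_atoms$charge, receptor_atoms$radius,
                        sweep(lig_xyz, 2, cen), ligand_atoms$charge,
                        ligand_atoms$radius,
                        matrix(cen, 1), matrix(c(1, 0, 0, 0), 1),
                        params$cutoff, params$epsilon, params$coulomb_k,
                        params$dielectric_slope, params$repulsion_cap,
                        params$clash_scale, params$clash_k)
  m[1, "total"]
}
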