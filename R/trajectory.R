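# MD trajectory readouts: Kabsch superposition, ligand RMSD time series,
# per-residue RMSF (two-pass mean-structure fit), ligand-contact occupancy,
# and the per-frame molecular-mechanics interaction-enthalpy series.
# Native trajectory format is multi-model PDB (read through bio3d); RMSD and
# RMSF are computed in Angstrom and reported in nm to match the plotting
# convention of MD figures.

#' Construct a Trajectory
#' @param topology a `Structure` shared by all frames.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param frame_interval metadata: time between frames, ps.
#' @return an object of class `Trajectory`.
#' @export
trajectory <- function(topology, frames, frame_interval = 100) {
  stopifnot(inherits(topology, "Structure"), length(frames) >= 1)
  n <- nrow(topology$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n && ncol(f) == 3,
               TRUE)
  if (!all(ok)) stop("every frame must be an n_atoms x 3 matrix matching the topology")
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms (%.0f ps/frame)\n",
              length(x$frames), nrow(x$topology$atoms), x$frame_interval))
  invisible(x)
}

#' Read a multi-model PDB file as a Trajectory
#' @param pdb file path or PDB text (one MODEL block per frame).
#' @param frame_interval metadata: time between frames, ps.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(pdb, frame_interval = 100) {
  file <- .as_pdb_input(pdb)
  .validate_pdb_lines(file)
  p <- suppressWarnings(bio3d::read.pdb(file, multi = TRUE, verbose = FALSE))
  keep <- is.na(p$atom$alt) | p$atom$alt %in% c("", "A")
  at <- p$atom[keep, , drop = FALSE]
  topo <- make_structure(data.frame(
    serial = at$eleno, name = at$elety,
    residue_name = at$resid, chain_id = ifelse(is.na(at$chain), "", at$chain),
    residue_number = at$resno,
    x = 0, y = 0, z = 0,
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             .guess_element(at$elety), at$elesy)),
    stringsAsFactors = FALSE))
  cols <- atom2xyz(which(keep))
  frames <- lapply(seq_len(nrow(p$xyz)), function(i)
    matrix(p$xyz[i, cols], ncol = 3, byrow = TRUE))
  topo$atoms[, c("x", "y", "z")] <- frames[[1]]
  trajectory(topo, frames, frame_interval)
}

#' Write a Trajectory as a multi-model PDB file
#' @param traj a `Trajectory`.
#' @param file output path.
#' @export
write_trajectory <- function(traj, file) {
  a <- traj$topology$atoms
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.vector(t(f))))
  bio3d::write.pdb(file = file, xyz = xyz, resno = a$residue_number,
                   resid = a$residue_name, eleno = a$serial, elety = a$name,
                   chain = a$chain_id, elesy = a$element)
  invisible(file)
}

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `reference`; reflections are corrected by the determinant sign flip.
#'
#' @param reference,mobile m x 3 coordinate matrices with matched rows,
#'   m >= 3.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   mobile is `mobile %*% t(rotation) + translation`), and `rmsd` (Angstrom,
#'   after transform).
#' @export
kabsch_superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (nrow(reference) != nrow(mobile) || ncol(reference) != 3 || ncol(mobile) != 3)
    stop("reference and mobile must be matched m x 3 matrices")
  m <- nrow(reference)
  if (m < 3) stop("at least 3 points are required for superposition")
  w <- if (is.null(weights)) rep(1, m) else weights
  stopifnot(length(w) == m, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cr <- colSums(reference * w); cm <- colSums(mobile * w)
  A <- sweep(reference, 2, cr); B <- sweep(mobile, 2, cm)
  H <- t(B * w) %*% A
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2)
    stop("degenerate point set: rank-deficient covariance")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cr - as.vector(R %*% cm)
  fitted <- mobile %*% t(R) + matrix(tr, m, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

.apply_fit <- function(xyz, fit) xyz %*% t(fit$rotation) +
  matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)

#' Ligand RMSD time series
#'
#' Each frame is superposed onto frame 1 using the fit selection (typically
#' receptor atoms); the RMSD of the ligand atoms is then computed without
#' further fitting.  Reported in nm.
#'
#' @param traj a `Trajectory`.
#' @param ligand integer atom indices of the ligand.
#' @param fit integer atom indices used for superposition.
#' @param window moving-average window, frames (edge-truncated, centered).
#' @return list of class `SeriesResult`: `values` (nm), `units`,
#'   `moving_average`, `window`.  The first value is 0 by construction.
#' @export
ligand_rmsd_series <- function(traj, ligand, fit, window = 1) {
  stopifnot(length(ligand) > 0, length(fit) > 0)
  ref <- traj$frames[[1]]
  vals <- vapply(traj$frames, function(f) {
    k <- kabsch_superpose(ref[fit, , drop = FALSE], f[fit, , drop = FALSE])
    lig <- .apply_fit(f[ligand, , drop = FALSE], k)
    sqrt(mean(rowSums((lig - ref[ligand, , drop = FALSE])^2)))
  }, 0)
  series_result(vals / 10, "nm", window)
}

#' Build a SeriesResult with an edge-truncated centered moving average
#' @param values numeric series.
#' @param units unit string (`"nm"` or `"kcal/mol"`).
#' @param window window width in frames (>= 1); at the edges the window is
#'   truncated, never padded.
#' @export
series_result <- function(values, units, window = 1) {
  n <- length(values)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window exceeds the number of frames")
  left <- floor((window - 1) / 2); right <- floor(window / 2)
  ma <- vapply(seq_len(n), function(i)
    mean(values[max(1, i - left):min(n, i + right)]), 0)
  structure(list(values = unname(values), units = units,
                 moving_average = ma, window = as.integer(window)),
            class = "SeriesResult")
}

# frames superposed to the running-average structure: fit to frame 1,
# average, refit every frame to the mean (two-pass)
.fit_to_mean <- function(traj, fit) {
  ref <- traj$frames[[1]]
  pass1 <- lapply(traj$frames, function(f) {
    k <- kabsch_superpose(ref[fit, , drop = FALSE], f[fit, , drop = FALSE])
    .apply_fit(f, k)
  })
  mean_xyz <- Reduce(`+`, pass1) / length(pass1)
  lapply(traj$frames, function(f) {
    k <- kabsch_superpose(mean_xyz[fit, , drop = FALSE], f[fit, , drop = FALSE])
    .apply_fit(f, k)
  })
}

#' Per-residue RMSF profile
#'
#' Frames are superposed to the mean structure (two-pass fit), the selected
#' atoms of each residue are collapsed to their centroid per frame, and the
#' RMSF is the root-mean-square deviation of that centroid from its time
#' mean, reported in nm.
#'
#' @param traj a `Trajectory` with >= 2 frames.
#' @param selection integer atom indices to profile (grouped by residue).
#' @param fit integer atom indices used for superposition.
#' @return list of class `ProfileResult` with `keys` (data frame of
#'   `chain_id`, `residue_number`), `values` (nm), `units`.
#' @export
rmsf_profile <- function(traj, selection, fit) {
  if (length(traj$frames) < 2) stop("RMSF needs at least 2 frames")
  fitted <- .fit_to_mean(traj, fit)
  at <- traj$topology$atoms[selection, , drop = FALSE]
  grp <- interaction(at$chain_id, at$residue_number, drop = TRUE, lex.order = TRUE)
  idx <- split(selection, grp)
  # per-frame residue centroids: n_res x 3 per frame
  cent <- lapply(fitted, function(f)
    t(vapply(idx, function(i) colMeans(f[i, , drop = FALSE]), numeric(3))))
  mean_cent <- Reduce(`+`, cent) / length(cent)
  msf <- Reduce(`+`, lapply(cent, function(cc) rowSums((cc - mean_cent)^2))) /
    length(cent)
  keys <- do.call(rbind, lapply(idx, function(i)
    traj$topology$atoms[i[1], c("chain_id", "residue_number")]))
  rownames(keys) <- NULL
  structure(list(keys = keys, values = unname(sqrt(msf)) / 10, units = "nm"),
            class = "ProfileResult")
}

#' Ligand-contact occupancy per receptor residue
#'
#' For each residue, the fraction of frames in which any ligand heavy atom
#' lies within `cutoff` of any heavy atom of the residue.
#'
#' @param traj a `Trajectory`.
#' @param ligand integer atom indices of the ligand.
#' @param residues integer atom indices of the receptor atoms to profile
#'   (grouped by residue); defaults to all non-ligand atoms.
#' @param cutoff contact distance cutoff, Angstrom (default 4.0, heavy
#'   atoms).
#' @return a `ProfileResult` with occupancy fractions in [0, 1].
#' @export
contact_occupancy <- function(traj, ligand, residues = NULL, cutoff = 4.0) {
  stopifnot(cutoff > 0, length(ligand) > 0)
  at <- traj$topology$atoms
  if (is.null(residues)) residues <- setdiff(seq_len(nrow(at)), ligand)
  heavy <- at$element != "H"
  ligand <- ligand[heavy[ligand]]
  residues <- residues[heavy[residues]]
  ra <- at[residues, , drop = FALSE]
  grp <- interaction(ra$chain_id, ra$residue_number, drop = TRUE, lex.order = TRUE)
  idx <- split(residues, grp)
  cut2 <- cutoff^2
  counts <- numeric(length(idx))
  for (f in traj$frames) {
    lig <- f[ligand, , drop = FALSE]
    for (k in seq_along(idx)) {
      res <- f[idx[[k]], , drop = FALSE]
      d2 <- outer(rowSums(lig^2), rowSums(res^2), "+") - 2 * lig %*% t(res)
      if (any(d2 <= cut2)) counts[k] <- counts[k] + 1
    }
  }
  keys <- do.call(rbind, lapply(idx, function(i)
    at[i[1], c("chain_id", "residue_number")]))
  rownames(keys) <- NULL
  structure(list(keys = keys, values = counts / length(traj$frames),
                 units = "fraction"),
            class = "ProfileResult")
}

#' Per-frame receptor-ligand interaction-enthalpy series
#'
#' Evaluates the empirical pairwise interaction energy of [score_pose()] on
#' each frame's coordinates (molecular-mechanics term only — no solvation)
#' and attaches an edge-truncated moving average.
#'
#' @param traj a `Trajectory`.
#' @param ligand,receptor integer atom index selections.
#' @param params a [scoring_params()] list.
#' @param window moving-average window in frames (default 50, truncated to
#'   the series length is an error: choose `window <= n_frames`).
#' @return a `SeriesResult` in kcal/mol.
#' @export
enthalpy_series <- function(traj, ligand, receptor, params = scoring_params(),
                            window = 50) {
  stopifnot(length(ligand) > 0, length(receptor) > 0)
  at <- traj$topology$atoms
  vals <- vapply(traj$frames, function(f) {
    ra <- at[receptor, , drop = FALSE]; ra[, c("x", "y", "z")] <- f[receptor, , drop = FALSE]
    la <- at[ligand, , drop = FALSE];   la[, c("x", "y", "z")] <- f[ligand, , drop = FALSE]
    interaction_energy(ra, la, params)
  }, 0)
  series_result(vals, "kcal/mol", window)
}

#' Write a SeriesResult to TSV (frame, value, moving_average)
#' @param x a `SeriesResult`.
#' @param file output path.
#' @export
write_series_tsv <- function(x, file) {
  utils::write.table(
    data.frame(frame = seq_along(x$values), value = x$values,
               moving_average = x$moving_average),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a ProfileResult to TSV (chain, residue, value)
#' @param x a `ProfileResult`.
#' @param file output path.
#' @export
write_profile_tsv <- function(x, file) {
  utils::write.table(
    data.frame(chain = x$keys$chain_id, residue = x$keys$residue_number,
               value = x$values),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
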