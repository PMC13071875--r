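# Seeded synthetic-data generators: a toy receptor-ligand complex with a
# known score minimum, trajectories with prescribed per-residue Gaussian
# fluctuations and contact patterns, and assay datasets drawn from packaged
# presets whose ground truths are the reported assay values the recovery
# tests aim to reproduce.

#' Load the packaged synthetic presets
#'
#' Presets bundle the ground truths (IC50s, half-lives, fluctuation
#' amplitudes), the sampling design (doses, timepoints, replicates) and the
#' noise level used by the generators and the recovery tests.
#'
#' @param path optional path to an alternative preset JSON file.
#' @return named list of presets.
#' @export
load_presets <- function(path = system.file("extdata", "presets.json",
                                            package = "nfyscreen")) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Fetch one preset by name
#' @param name preset name, e.g. `"ic50_human"`.
#' @param presets preset list (default: packaged).
#' @export
get_preset <- function(name, presets = load_presets()) {
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

# mean-one lognormal noise factors for a given coefficient of variation
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate reporter dose-response data from a preset
#'
#' Responses are the four-parameter-logistic curve at the preset's truth
#' parameters multiplied by mean-one lognormal noise of the preset's
#' coefficient of variation.
#'
#' @param preset a dose-response preset (see [load_presets()]).
#' @param seed RNG seed; defaults to the preset's own seed.
#' @return a [dose_response_data()] object.
#' @export
simulate_dose_response <- function(preset, seed = preset$seed) {
  need <- c("ic50_truth", "hill", "top", "bottom", "doses", "replicates",
            "noise_cv")
  miss <- setdiff(need, names(preset))
  if (length(miss) > 0) stop("preset lacks parameter(s): ",
                             paste(miss, collapse = ", "))
  .with_seed(seed, {
    doses <- rep(preset$doses, each = preset$replicates)
    mu <- .fourpl(doses, preset$ic50_truth, preset$hill, preset$top,
                  preset$bottom)
    resp <- mu * .lognormal_noise(length(doses), preset$noise_cv)
    dose_response_data(doses, resp,
                       rep(seq_len(preset$replicates), length(preset$doses)))
  })
}

#' Simulate cycloheximide-chase decay data from a preset
#'
#' Levels follow first-order decay at the preset's true half-life times
#' mean-one lognormal noise; the t = 0 levels are then normalized to mean 1.
#'
#' @param preset a chase preset (see [load_presets()]).
#' @param seed RNG seed; defaults to the preset's own seed.
#' @param condition condition label carried into the dataset.
#' @return a [chase_data()] object.
#' @export
simulate_chase <- function(preset, seed = preset$seed,
                           condition = preset$description %||% "synthetic") {
  need <- c("t_half_truth", "timepoints", "replicates", "noise_cv")
  miss <- setdiff(need, names(preset))
  if (length(miss) > 0) stop("preset lacks parameter(s): ",
                             paste(miss, collapse = ", "))
  if (length(preset$timepoints) < 2)
    stop("chase design needs at least 2 timepoints")
  .with_seed(seed, {
    times <- rep(preset$timepoints, each = preset$replicates)
    lv <- exp(-log(2) * times / preset$t_half_truth) *
      .lognormal_noise(length(times), preset$noise_cv)
    lv <- lv / mean(lv[times == 0])
    chase_data(times, lv, condition,
               rep(seq_len(preset$replicates), length(preset$timepoints)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a toy receptor-ligand complex with a known score minimum
#'
#' The receptor is a ~20-atom concave cup (lower half of a sphere) with
#' weakly charged atoms at the pocket floor; the ligand is a rigid 3-atom
#' rod with an oppositely charged center, so the scoring function has a
#' well-defined minimum inside the pocket.  Receptor coordinates are
#' jittered by the seed, making each fixture geometrically distinct.  The
#' global minimum under the default scoring parameters is located by
#' exhaustive grid enumeration ([grid_minimum()]) and returned with the
#' fixture.
#'
#' @param seed integer seed for the geometry jitter.
#' @param box_edge search-box edge, Angstrom (default 6: somewhat wider than
#'   the pocket mouth, so the search problem is non-trivial while exhaustive
#'   enumeration stays tractable).
#' @param compute_minimum if `TRUE` (default) run the exhaustive enumeration
#'   and store its result as `known_minimum`; set `FALSE` to skip the
#'   (seconds-long) enumeration when the reference minimum is not needed.
#' @param translation_step,angle_step enumeration grid resolution
#'   (default 0.25 Angstrom / 15 degrees).
#' @param scoring a [scoring_params()] list.
#' @return list with `receptor` (`Structure`), `ligand` (`Conformer`),
#'   `box` (`SearchBox`) and `known_minimum` (from [grid_minimum()], or
#'   `NULL`).
#' @export
make_toy_complex <- function(seed = 1L, box_edge = 6,
                             compute_minimum = TRUE,
                             translation_step = 0.25, angle_step = 15,
                             scoring = scoring_params()) {
  .with_seed(seed, {
    # lower-hemisphere cup of radius 4 A around the origin: 3 rings + floor
    ring <- function(theta, n) {
      phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      cbind(4 * sin(theta) * cos(phi), 4 * sin(theta) * sin(phi),
            -4 * cos(theta))
    }
    xyz <- rbind(ring(80 * pi / 180, 8), ring(50 * pi / 180, 7),
                 ring(25 * pi / 180, 4), c(0, 0, -4))
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, 0.15), nrow(xyz), 3)
    n <- nrow(xyz)
    elem <- rep("C", n)
    charge <- rep(0, n)
    floor_atoms <- which(xyz[, 3] < -3)
    elem[floor_atoms] <- "O"
    charge[floor_atoms] <- 0.2
    receptor <- make_structure(data.frame(
      serial = seq_len(n), name = elem, residue_name = "POC",
      chain_id = "B", residue_number = seq_len(n),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = elem, charge = charge), title = "toy pocket")
    lig <- conformer("TOY", data.frame(
      serial = 1:3, name = c("C1", "N1", "C2"), residue_name = "LIG",
      chain_id = "L", residue_number = c(1, 1, 1),
      x = c(-1.2, 0, 1.2), y = 0, z = 0,
      element = c("C", "N", "C"), charge = c(0, -0.3, 0)))
    box <- search_box(c(0, 0, 0), box_edge)
    km <- if (compute_minimum)
      grid_minimum(receptor, lig, box, translation_step, angle_step, scoring)
    else NULL
    list(receptor = receptor, ligand = lig, box = box, known_minimum = km)
  })
}

#' Simulate a trajectory with prescribed per-residue fluctuations
#'
#' Frames are the topology coordinates plus independent Gaussian jitter with
#' a per-residue standard deviation (per coordinate, Angstrom).  An optional
#' contact schedule overrides the position of a ligand atom group so that a
#' target residue is in contact (within `cutoff`) in exactly
#' `round(fraction * n_frames)` frames and far away otherwise.
#'
#' @param topology a `Structure`.
#' @param amplitudes numeric vector of per-coordinate jitter sds (Angstrom),
#'   one per residue in topology order (chain, then residue number).
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed.
#' @param contact_pattern optional list with elements `ligand` (atom
#'   indices), `chain_id`, `residue_number` (target residue), `fraction`
#'   (desired occupancy) and optional `cutoff` (default 4).
#' @param frame_interval metadata, ps per frame.
#' @return a `Trajectory`.
#' @export
simulate_trajectory <- function(topology, amplitudes, n_frames, seed = 1L,
                                contact_pattern = NULL, frame_interval = 100) {
  stopifnot(inherits(topology, "Structure"), n_frames >= 2,
            all(amplitudes >= 0))
  at <- topology$atoms
  grp <- interaction(at$chain_id, at$residue_number, drop = TRUE,
                     lex.order = TRUE)
  n_res <- nlevels(grp)
  if (length(amplitudes) != n_res)
    stop(sprintf("amplitudes has length %d but the topology has %d residues",
                 length(amplitudes), n_res))
  sd_atom <- amplitudes[as.integer(grp)]
  base <- coords(topology)
  .with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(i) {
      base + matrix(stats::rnorm(length(base), 0, sd_atom), nrow(base), 3)
    })
    if (!is.null(contact_pattern)) {
      cp <- contact_pattern
      cutoff <- cp$cutoff %||% 4
      tgt <- which(at$chain_id == cp$chain_id &
                   at$residue_number == cp$residue_number)
      if (length(tgt) == 0) stop("contact_pattern target residue not found")
      n_on <- round(cp$fraction * n_frames)
      on_frames <- seq_len(n_on)  # deterministic: contact in the first frames
      for (i in seq_len(n_frames)) {
        f <- frames[[i]]
        lig_cent <- colMeans(f[cp$ligand, , drop = FALSE])
        dest <- if (i %in% on_frames)
          colMeans(f[tgt, , drop = FALSE]) + c(0, 0, cutoff / 4)
        else
          colMeans(f[tgt, , drop = FALSE]) + c(0, 0, 10 * cutoff)
        f[cp$ligand, ] <- sweep(f[cp$ligand, , drop = FALSE], 2,
                                dest - lig_cent, "+")
        frames[[i]] <- f
      }
    }
    trajectory(topology, frames, frame_interval)
  })
}

#' A small helical peptide-like topology for trajectory fixtures
#'
#' One chain of `n_residues` single-atom residues on a gentle helix
#' (receptor) plus a 2-atom ligand chain.  One atom per residue makes the
#' closed-form RMSF recovery exact, and the helix keeps the coordinates
#' non-degenerate for superposition.
#'
#' @param n_residues number of receptor residues.
#' @param spacing rise per residue, Angstrom.
#' @return a `Structure` with receptor chain "A" and ligand chain "L".
#' @export
make_line_topology <- function(n_residues = 10, spacing = 3) {
  i <- seq_len(n_residues)
  rec <- data.frame(
    serial = i, name = "CA", residue_name = "GLY",
    chain_id = "A", residue_number = i,
    x = spacing * (i - 1), y = 1.5 * sin(i), z = 1.5 * cos(i),
    element = "C", charge = 0)
  lig <- data.frame(
    serial = n_residues + 1:2, name = c("C1", "C2"), residue_name = "LIG",
    chain_id = "L", residue_number = c(1, 1),
    x = c(0, 1.5), y = 5, z = 0, element = "C", charge = 0)
  make_structure(rbind(rec, lig), title = "line topology")
}
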