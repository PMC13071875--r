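# Shared fixtures and independent oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

# default-seed toy complex with its exhaustive-enumeration minimum; the
# enumeration takes on the order of a minute, so it is computed once and
# shared across test files
toy_fixture <- function() {
  if (is.null(.fixture_cache$toy))
    .fixture_cache$toy <- make_toy_complex(seed = 1)
  .fixture_cache$toy
}

toy_fixture_fast <- function(seed = 1) make_toy_complex(seed, compute_minimum = FALSE)

# Independent brute-force pose scorer: plain R loops and a quaternion
# sandwich product, sharing no code with the compiled scorer.
oracle_score <- function(receptor, p, sp = scoring_params()) {
  q <- p$rotation / sqrt(sum(p$rotation^2))
  qmul <- function(a, b) c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
  rot <- function(v) qmul(qmul(q, c(0, v)), c(q[1], -q[2:4]))[2:4]
  la <- p$conformer$atoms
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  cen <- colMeans(lxyz)
  ra <- receptor$atoms
  lj <- 0; elec <- 0; clash <- 0
  for (i in seq_len(nrow(la))) {
    pos <- rot(lxyz[i, ] - cen) + p$translation
    for (j in seq_len(nrow(ra))) {
      r <- sqrt(sum((pos - c(ra$x[j], ra$y[j], ra$z[j]))^2))
      if (r > sp$cutoff) next
      rm <- la$radius[i] + ra$radius[j]
      e <- sp$epsilon * ((rm / r)^12 - 2 * (rm / r)^6)
      lj <- lj + min(e, sp$repulsion_cap)
      elec <- elec + sp$coulomb_k * la$charge[i] * ra$charge[j] /
        (sp$dielectric_slope * r^2)
      if (r < sp$clash_scale * rm) clash <- clash + sp$clash_k * (sp$clash_scale * rm - r)
    }
  }
  list(lj = lj, electrostatic = elec, clash_penalty = clash,
       total = lj + elec + clash)
}

# regular tetrahedron, edge sqrt(8)
tetrahedron <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
}

# tiny two-atom receptor / two-atom ligand system for closed-form checks
pair_system <- function(rec_xyz, lig_xyz, rec_charge = 0, lig_charge = 0,
                        element = "C") {
  n <- nrow(rec_xyz)
  rec <- make_structure(data.frame(
    serial = seq_len(n), x = rec_xyz[, 1], y = rec_xyz[, 2], z = rec_xyz[, 3],
    element = element, charge = rec_charge, chain_id = "R",
    residue_number = seq_len(n), residue_name = "REC", name = element))
  m <- nrow(lig_xyz)
  lig <- conformer("LIG", data.frame(
    serial = seq_len(m), x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
    element = element, charge = lig_charge, chain_id = "L",
    residue_number = rep(1, m), residue_name = "LIG",
    name = paste0(element, seq_len(m))))
  list(receptor = rec, ligand = lig)
}

# a one-line PDB ATOM record with given coordinates
atom_line <- function(serial = 1, name = "CA", resid = "ALA", chain = "A",
                      resno = 1, x = 0, y = 0, z = 0, element = "C") {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resid, chain, resno, x, y, z, element)
}
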