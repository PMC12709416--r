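KB <- 0.00831446261815324   # kJ mol^-1 K^-1
F_ELEC <- 138.935           # kJ mol^-1 nm e^-2, molar Coulomb constant
EPS_AH <- 0.8368            # kJ mol^-1, Ashbaugh-Hatch well depth scale
BOND_K <- 8368              # kJ mol^-1 nm^-2
BOND_L <- 0.38              # nm

#' Harmonic bond energy
#'
#' `(k/2)(r - l)^2` with spring constant `k = 8368` kJ/mol/nm^2 and
#' equilibrium length `l = 0.38` nm, the pseudo-bond between consecutive
#' residue beads.
#'
#' @param r bead separation, nm.
#' @param k spring constant, kJ/mol/nm^2.
#' @param l equilibrium bond length, nm.
#' @return energy, kJ/mol.
#' @export
bonded_energy <- function(r, k = BOND_K, l = BOND_L) {
  stopifnot(all(r >= 0))
  0.5 * k * (r - l)^2
}

#' Ashbaugh-Hatch pair potential
#'
#' Lennard-Jones based potential whose attractive part is scaled by the
#' pair stickiness lambda while the repulsive core is lambda-independent:
#' `U_LJ + eps*(1-lambda)` below the minimum at `2^(1/6) sigma`,
#' `lambda*U_LJ` out to
#' the cutoff, zero beyond.  With `shift = TRUE` the value at the cutoff
#' is subtracted from both branches (cut-and-shift).
#'
#' @param r separation, nm (vectorized).
#' @param sigma_ij pair diameter, nm.
#' @param lam_ij pair stickiness in \[0,1\].
#' @param rc_lj cutoff, nm (default 2.0).
#' @param eps well-depth scale, kJ/mol.
#' @param shift subtract the cutoff value (default FALSE, plain
#'   truncation).
#' @return energy, kJ/mol.
#' @export
ah_potential <- function(r, sigma_ij, lam_ij, rc_lj = 2.0, eps = EPS_AH,
                         shift = FALSE) {
  stopifnot(all(r > 0))
  ulj <- function(x) 4 * eps * ((sigma_ij / x)^12 - (sigma_ij / x)^6)
  rmin <- 2^(1 / 6) * sigma_ij
  sh <- if (shift) lam_ij * ulj(rc_lj) else 0
  out <- ifelse(r <= rmin, ulj(r) + eps * (1 - lam_ij) - sh,
                lam_ij * ulj(r) - sh)
  out[r > rc_lj] <- 0
  out
}

#' Debye-Hueckel screened electrostatic potential
#'
#' `f q_i q_j / (eps_r r) exp(-r / lambda_D)` truncated at `rc_elec`,
#' with `f = 138.935` kJ mol^-1 nm e^-2.  Defaults reproduce
#' physiological conditions: screening length 1 nm, relative dielectric
#' 80, cutoff 4 nm.
#'
#' @param r separation, nm (vectorized).
#' @param qi,qj charges, e.
#' @param debye_length Debye screening length, nm.
#' @param dielectric relative dielectric constant.
#' @param rc_elec cutoff, nm.
#' @param shift subtract the cutoff value.
#' @return energy, kJ/mol.
#' @export
dh_potential <- function(r, qi, qj, debye_length = 1.0, dielectric = 80,
                         rc_elec = 4.0, shift = FALSE) {
  stopifnot(all(r > 0))
  u <- F_ELEC * qi * qj / (dielectric * r) * exp(-r / debye_length)
  sh <- if (shift) F_ELEC * qi * qj / (dielectric * rc_elec) *
    exp(-rc_elec / debye_length) else 0
  out <- u - sh
  out[r > rc_elec] <- 0
  out
}

#' Build a bead topology from sequence records
#'
#' Resolves per-bead sigma, lambda, charge and mass from a parameter
#' table, applying the terminal-charge and His-charge conventions, and
#' records the chain structure (bonds join consecutive beads within each
#' chain only).
#'
#' @param chains a `seq_record` or list of `seq_record`s (one per chain).
#' @param table a `param_table`.
#' @param termini_charged,his_charge passed to [assign_charges()].
#' @param species optional character vector labelling each chain's
#'   species (defaults to the record ids' first token, or "A").
#' @return a `cg_topology` list with vectors `sigma`, `lambda`, `charge`,
#'   `mass`, `chain_id` (1-based, per bead), `residue` (one-letter code
#'   per bead), `chain_species`, `n_beads`, `chain_lengths`.
#' @export
create_topology <- function(chains, table = default_param_table(),
                            termini_charged = TRUE, his_charge = 0,
                            species = NULL) {
  if (inherits(chains, "seq_record")) chains <- list(chains)
  stopifnot(length(chains) > 0,
            all(vapply(chains, inherits, TRUE, "seq_record")))
  if (is.null(species))
    species <- vapply(chains, function(s) s$id, "")
  stopifnot(length(species) == length(chains))
  per <- lapply(seq_along(chains), function(i) {
    s <- chains[[i]]
    p <- param_lookup(table, s$residues)
    list(sigma = p$sigma, lambda = p$lambda,
         charge = assign_charges(s, table, termini_charged, his_charge),
         mass = p$mass, residue = s$residues,
         chain_id = rep(i, length(s$residues)))
  })
  structure(list(
    sigma = unlist(lapply(per, `[[`, "sigma")),
    lambda = unlist(lapply(per, `[[`, "lambda")),
    charge = unlist(lapply(per, `[[`, "charge")),
    mass = unlist(lapply(per, `[[`, "mass")),
    residue = unlist(lapply(per, `[[`, "residue")),
    chain_id = unlist(lapply(per, `[[`, "chain_id")),
    chain_species = as.character(species),
    chain_lengths = vapply(chains, function(s) length(s$residues), 1L),
    n_beads = sum(vapply(chains, function(s) length(s$residues), 1L))),
    class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("cg_topology: %d chains, %d beads, net charge %+.1f e\n",
              length(x$chain_lengths), x$n_beads, sum(x$charge)))
  invisible(x)
}

#' Simulation configuration
#'
#' Collects the thermodynamic and numerical settings of a Langevin run.
#' Defaults follow the residue-level protocol: 10 fs timestep, LJ cutoff
#' 2 nm, electrostatic cutoff 4 nm, Debye length 1 nm, dielectric 80,
#' plain truncation.  Friction defaults to 0.01 ps^-1 for efficient
#' diffusive sampling.
#'
#' @param temperature K.
#' @param timestep fs.
#' @param n_steps number of integration steps.
#' @param friction ps^-1.
#' @param seed integer seed controlling initial velocities and noise.
#' @param rc_lj,rc_elec cutoffs, nm.
#' @param debye_length nm.
#' @param dielectric unitless.
#' @param shift_at_cutoff cut-and-shift both nonbonded terms.
#' @param save_every save a frame every this many steps.
#' @param skin Verlet-list skin, nm.
#' @return a `sim_config` list.
#' @export
sim_config <- function(temperature = 300, timestep = 10, n_steps = 10000,
                       friction = 0.01, seed = 1L, rc_lj = 2.0,
                       rc_elec = 4.0, debye_length = 1.0, dielectric = 80,
                       shift_at_cutoff = FALSE, save_every = 100,
                       skin = 0.3) {
  stopifnot(timestep > 0, n_steps >= 1, friction >= 0, temperature >= 0)
  structure(list(temperature = temperature, timestep = timestep,
                 n_steps = as.integer(n_steps), friction = friction,
                 seed = as.integer(seed), rc_lj = rc_lj, rc_elec = rc_elec,
                 debye_length = debye_length, dielectric = dielectric,
                 shift_at_cutoff = shift_at_cutoff,
                 save_every = as.integer(save_every), skin = skin),
            class = "sim_config")
}

check_box <- function(box, config) {
  stopifnot(length(box) == 3, all(box > 0))
  if (2 * config$rc_lj > min(box) || 2 * config$rc_elec > min(box))
    warning("cutoff exceeds half the smallest box edge; ",
            "minimum-image results may be inconsistent")
  invisible(box)
}

#' Total potential energy and forces of a frame
#'
#' Sums harmonic bonds over consecutive beads of each chain and
#' Ashbaugh-Hatch plus Debye-Hueckel terms over all other pairs within
#' their cutoffs, under the minimum-image convention; bonded (1-2) pairs
#' are excluded from the nonbonded sums.  Forces are the exact analytic
#' negative gradients of the implemented energy.
#'
#' @param positions n_beads x 3 matrix, nm.
#' @param topology a `cg_topology`.
#' @param box orthorhombic edge lengths, nm (length-3).
#' @param config a `sim_config`.
#' @param use_nlist evaluate through a freshly built Verlet neighbor
#'   list instead of the all-pairs double loop (identical result).
#' @return list with components `bonded`, `ashbaugh_hatch`,
#'   `electrostatic`, `total` (kJ/mol) and `forces` (n x 3, kJ/mol/nm).
#' @export
total_energy_forces <- function(positions, topology, box,
                                config = sim_config(), use_nlist = FALSE) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            nrow(positions) == topology$n_beads)
  check_box(box, config)
  cpp_energy_forces(positions, as.numeric(box),
                    as.integer(topology$chain_id), topology$sigma,
                    topology$lambda, topology$charge, topology$mass,
                    BOND_K, BOND_L, config$rc_lj, config$rc_elec,
                    config$debye_length, config$dielectric,
                    config$shift_at_cutoff, use_nlist, config$skin)
}

new_trajectory <- function(coords, box, times, topology = NULL,
                           extra = list()) {
  structure(c(list(coords = coords, box = box, times = times,
                   topology = topology), extra),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames x %d beads, box %.1f x %.1f x %.1f nm\n",
              dim(x$coords)[1], dim(x$coords)[2], x$box[1], x$box[2],
              x$box[3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Run BAOAB Langevin dynamics
#'
#' Integrates the coarse-grained model with the BAOAB splitting of
#' Langevin dynamics at the configured timestep, friction and
#' temperature, using a Verlet neighbor list rebuilt automatically from
#' bead displacements.  Initial velocities are drawn from the
#' Maxwell-Boltzmann distribution at the target temperature (or taken
#' from `velocities`).  Identical seed and inputs give an identical
#' trajectory.
#'
#' @param positions n x 3 starting coordinates, nm.
#' @param topology a `cg_topology`.
#' @param box edge lengths, nm.
#' @param config a `sim_config`.
#' @param velocities optional n x 3 starting velocities, nm/ps.
#' @return a `cg_trajectory` with `coords` (frames x beads x 3), `times`
#'   (ps), `box`, `topology`, per-frame potential `energies`, the
#'   whole-run mean `kinetic_temperature` (K), per-frame
#'   `kinetic_temperature_saved`, and `final` positions/velocities for
#'   restarts.
#' @export
langevin_run <- function(positions, topology, box, config = sim_config(),
                         velocities = NULL) {
  stopifnot(is.matrix(positions), nrow(positions) == topology$n_beads)
  check_box(box, config)
  set.seed(config$seed)
  if (is.null(velocities)) {
    sd_v <- sqrt(KB * config$temperature / topology$mass)
    velocities <- matrix(stats::rnorm(3 * topology$n_beads), ncol = 3) * sd_v
    if (config$temperature == 0) velocities[] <- 0
  }
  dt_ps <- config$timestep / 1000
  res <- cpp_langevin(positions, velocities, as.numeric(box),
                      as.integer(topology$chain_id), topology$sigma,
                      topology$lambda, topology$charge, topology$mass,
                      BOND_K, BOND_L, config$rc_lj, config$rc_elec,
                      config$debye_length, config$dielectric,
                      config$shift_at_cutoff, dt_ps, config$friction,
                      config$temperature, config$n_steps,
                      config$save_every, config$skin)
  coords <- aperm(array(res$frames, dim = dim(res$frames)), c(3, 2, 1))
  en <- res$energies
  colnames(en) <- c("bonded", "ashbaugh_hatch", "electrostatic")
  new_trajectory(coords, as.numeric(box), res$times, topology,
                 extra = list(
                   energies = en,
                   kinetic_temperature = res$kinetic_temperature,
                   kinetic_temperature_saved = res$kinetic_temperature_saved,
                   final = list(positions = res$positions,
                                velocities = res$velocities),
                   config = config))
}

#' Place chains randomly in a slab box
#'
#' Each chain is grown as a random walk at the equilibrium bond length;
#' every new bead must stay at least `min_separation` (minimum image)
#' from all previously placed beads other than its own bonded
#' predecessor.  With `slab_thickness` set, chains are confined to a
#' central slab of that thickness along z, the usual initialization for
#' coexistence runs (the dilute phase then forms by evaporation rather
#' than by slow cluster coalescence).  Reproducible by seed.
#'
#' @param topology a `cg_topology`.
#' @param box edge lengths, nm.
#' @param seed integer.
#' @param min_separation nm, applied to all non-bonded bead pairs.
#' @param slab_thickness nm; NULL places chains anywhere in the box.
#' @param max_tries growth attempts per chain before a packing error.
#' @return n_beads x 3 coordinate matrix, nm.
#' @export
build_slab_system <- function(topology, box, seed = 1L,
                              min_separation = 0.4,
                              slab_thickness = NULL, max_tries = 200) {
  set.seed(seed)
  box <- as.numeric(box)
  zlim <- if (is.null(slab_thickness)) c(0, box[3])
  else box[3] / 2 + c(-1, 1) * min(slab_thickness, box[3]) / 2
  placed <- matrix(numeric(0), ncol = 3)
  coords <- vector("list", length(topology$chain_lengths))
  for (ci in seq_along(topology$chain_lengths)) {
    nres <- topology$chain_lengths[ci]
    ok <- FALSE
    for (attempt in seq_len(max_tries)) {
      pts <- matrix(NA_real_, nres, 3)
      pts[1, ] <- c(stats::runif(2) * box[1:2],
                    stats::runif(1, zlim[1], zlim[2]))
      if (nrow(placed) &&
          min(cpp_min_dists(pts[1, , drop = FALSE], placed, box)) <
            min_separation) next
      grown <- TRUE
      for (b in seq_len(nres - 1L)) {
        found <- FALSE
        for (k in 1:40) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- pts[b, ] + BOND_L * u
          if (cand[3] < zlim[1] || cand[3] > zlim[2]) next
          prev <- pts[seq_len(b - 1L), , drop = FALSE]  # excl. bonded bead
          if (nrow(prev) &&
              min(cpp_min_dists(matrix(cand, 1), prev, box)) <
                min_separation) next
          if (nrow(placed) &&
              min(cpp_min_dists(matrix(cand, 1), placed, box)) <
                min_separation) next
          pts[b + 1L, ] <- cand
          found <- TRUE
          break
        }
        if (!found) { grown <- FALSE; break }
      }
      if (grown) {
        coords[[ci]] <- pts
        placed <- rbind(placed, pts)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("packing error: could not place chain ", ci, " after ",
           max_tries, " tries")
  }
  do.call(rbind, coords)
}

#' Write a trajectory as a multi-frame XYZ file
#'
#' Plain-text XYZ: per frame an atom count, a comment line carrying the
#' time and box, then one `<code> x y z` line per bead (coordinates nm).
#'
#' @param traj a `cg_trajectory`.
#' @param path output path.
#' @export
write_xyz <- function(traj, path) {
  n <- dim(traj$coords)[2]
  codes <- if (!is.null(traj$topology)) traj$topology$residue
  else rep("X", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time_ps=%g box=%g,%g,%g", traj$times[f],
                       traj$box[1], traj$box[2], traj$box[3]), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    writeLines(sprintf("%s %.6f %.6f %.6f", codes, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file written by [write_xyz()]
#'
#' @param path XYZ file.
#' @return a `cg_trajectory` (without topology).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  times <- numeric(0)
  box <- c(NA_real_, NA_real_, NA_real_)
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    tm <- as.numeric(sub(".*time_ps=([-0-9.eE+]+).*", "\\1", hdr))
    bx <- strsplit(sub(".*box=([^ ]+).*", "\\1", hdr), ",")[[1]]
    box <- as.numeric(bx)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3)
    times <- c(times, tm)
    i <- i + 2L + n
  }
  coords <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  new_trajectory(coords, box, times)
}

#' Write bead topology as a PDB file (one CA-like atom per bead)
#'
#' Coordinates are taken from the stated frame and written in Angstrom
#' per PDB convention.  Uses bio3d when available.
#'
#' @param traj a `cg_trajectory` with a topology.
#' @param path output path.
#' @param frame frame index to write.
#' @export
write_pdb_topology <- function(traj, path, frame = 1L) {
  top <- traj$topology
  stopifnot(!is.null(top))
  xyz <- traj$coords[frame, , , drop = TRUE] * 10  # nm -> Angstrom
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  resid3 <- aa3[top$residue]
  resno <- stats::ave(seq_len(top$n_beads), top$chain_id,
                      FUN = seq_along)
  chain_letters <- rep(c(LETTERS, letters),
                       length.out = length(top$chain_lengths))
  ch <- chain_letters[top$chain_id]
  if (requireNamespace("bio3d", quietly = TRUE)) {
    bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                     type = rep("ATOM", top$n_beads),
                     resno = resno, resid = resid3, chain = ch,
                     elety = rep("CA", top$n_beads))
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(top$n_beads), resid3, ch, resno, xyz[, 1], xyz[, 2],
      xyz[, 3]), con)
    writeLines("END", con)
  }
  invisible(path)
}

#' Save / load a checkpoint for restarting a run
#'
#' The checkpoint is a JSON file holding positions, velocities, the step
#' count, box, and the R random-number-generator state, so a restarted
#' run continues the same stochastic sequence.
#'
#' @param state list with elements `positions`, `velocities`, `step`,
#'   `box` (as produced from a `cg_trajectory`'s `final` element).
#' @param path file path.
#' @export
write_checkpoint <- function(state, path) {
  obj <- list(positions = state$positions, velocities = state$velocities,
              step = state$step, box = state$box,
              rng_state = .GlobalEnv$.Random.seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$positions <- matrix(unlist(obj$positions), ncol = 3)
  obj$velocities <- matrix(unlist(obj$velocities), ncol = 3)
  if (!is.null(obj$rng_state))
    assign(".Random.seed", as.integer(obj$rng_state), envir = .GlobalEnv)
  obj
}
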