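# Seed-deterministic generators for every analysis stage: homopolymer
# chains, coexistence curves from the scaling law, contact-structure
# trajectories, and pi-interaction geometries with closed-form labels.

#' Synthetic homopolymer sequence and parameter table
#'
#' Builds an `n_res`-residue homopolymer with the stated bead
#' parameters, together with a self-contained parameter table assigning
#' those parameters to all 20 codes (so downstream code needing a
#' complete table works unchanged).  Defaults describe a generic
#' residue-sized bead: diameter 0.6 nm, mass 110 g/mol, uncharged.
#'
#' @param n_res chain length.
#' @param lam stickiness in \[0,1\].
#' @param sigma bead diameter, nm.
#' @param charge bead charge, e.
#' @param mass bead mass, g/mol.
#' @param code one-letter code used for the beads.
#' @return list with `seq` (a `seq_record`) and `table` (a
#'   `param_table`, provenance "synthetic-homopolymer").
#' @export
make_homopolymer <- function(n_res, lam, sigma = 0.6, charge = 0,
                             mass = 110, code = "A") {
  stopifnot(lam >= 0, lam <= 1, n_res >= 1)
  tab <- load_parameter_table(
    data.frame(code = AA_CODES, sigma_nm = sigma, lambda = lam,
               charge_e = charge, mass_gmol = mass),
    provenance = "synthetic-homopolymer")
  list(seq = seq_record(sprintf("homopolymer_%s%d_lam%.2f", code, n_res,
                                lam),
                        rep(code, n_res)),
       table = tab)
}

#' Assemble a homopolymer slab system ready to simulate
#'
#' Study-condition defaults for desk-scale phase-behavior checks: 10
#' chains of 50 beads in a 10 x 10 x 60 nm slab, uncharged (no terminal
#' charges), grown by [build_slab_system()] inside a 15-nm central slab
#' so coexistence is approached by evaporation.
#'
#' @param lam stickiness.
#' @param n_chains,n_res system size.
#' @param box slab edge lengths, nm.
#' @param seed placement seed.
#' @param slab_thickness initial central-slab thickness, nm.
#' @param ... forwarded to [make_homopolymer()].
#' @return list with `topology`, `positions`, `box`, `seq`, `table`.
#' @export
homopolymer_system <- function(lam, n_chains = 10, n_res = 50,
                               box = c(10, 10, 60), seed = 1L,
                               slab_thickness = 15, ...) {
  hp <- make_homopolymer(n_res, lam, ...)
  chains <- rep(list(hp$seq), n_chains)
  top <- create_topology(chains, hp$table, termini_charged = FALSE,
                         species = rep("A", n_chains))
  # 0.55 nm keeps initial core overlaps mild (a few kJ/mol), so the run
  # thermalizes immediately instead of dumping repulsive energy
  pos <- build_slab_system(top, box, seed = seed, min_separation = 0.55,
                           slab_thickness = slab_thickness)
  list(topology = top, positions = pos, box = box, seq = hp$seq,
       table = hp$table)
}

#' Generate a coexistence curve from the critical scaling law
#'
#' Inverts the fitting model: the order parameter follows
#' `delta_rho = B (1 - T/Tc)^beta` (beta = 0.325) and the diameter the
#' rectilinear law `(rho_h + rho_l)/2 = rho_c + C (Tc - T)`, giving
#' `rho_h/l = diameter +/- delta_rho/2`, with optional multiplicative
#' Gaussian noise.  Defaults are the study conditions for the
#' scaffold-construct phase diagram: Tc = 296 K with the simulated
#' temperature ladder below it, and amplitude/diameter parameters giving
#' a dense branch near 800 mg/mL and a dilute branch under 100 mg/mL at
#' the lowest temperature.
#'
#' @param Tc critical temperature, K.
#' @param B critical amplitude (density units).
#' @param rho_c critical density.
#' @param C rectilinear-diameter slope (density per K, positive).
#' @param temps temperatures, K, all below Tc.
#' @param noise_rel relative noise amplitude (0 = exact law).
#' @param seed RNG seed.
#' @param beta critical exponent.
#' @return a `coexistence_curve`.
#' @export
gen_coexistence_data <- function(Tc = 296, B = 1400, rho_c = 350, C = 2,
                                 temps = c(260, 265, 270, 275, 280, 285,
                                           290, 291, 292, 293, 295),
                                 noise_rel = 0, seed = 1L,
                                 beta = 0.325) {
  if (any(temps >= Tc)) stop("all temperatures must be below Tc")
  if (is.unsorted(temps, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  set.seed(seed)
  drho <- B * (1 - temps / Tc)^beta
  dbar <- rho_c + C * (Tc - temps)
  rho_h <- dbar + drho / 2
  rho_l <- dbar - drho / 2
  if (any(rho_l < 0))
    stop("parameters give negative dilute density; draw rejected")
  if (noise_rel > 0) {
    for (k in 1:100) {
      rl <- rho_l * (1 + noise_rel * stats::rnorm(length(temps)))
      rh <- rho_h * (1 + noise_rel * stats::rnorm(length(temps)))
      if (all(rl >= 0) && all(rh > rl)) break
    }
    if (!(all(rl >= 0) && all(rh > rl)))
      stop("noise level incompatible with a valid curve")
    rho_l <- rl; rho_h <- rh
  }
  coexistence_curve(temps, rho_l, rho_h,
                    sem_l = noise_rel * rho_l, sem_h = noise_rel * rho_h)
}

# Realize one binary inter-chain contact pattern as 3D coordinates.
# Contacts target 0.5*cutoff, non-contacts at least 1.5*cutoff; the
# pattern is verified by brute force against the actual cutoff.
realize_contact_pattern <- function(X, cutoff, max_restarts = 25) {
  na <- nrow(X); nb <- ncol(X)
  s <- 3 * cutoff
  for (restart in seq_len(max_restarts)) {
    A <- cbind((seq_len(na) - 1) * s, 0, 0)
    if (restart > 1) A <- A + matrix(stats::rnorm(3 * na, 0, 0.3 * cutoff),
                                     na, 3)
    B <- matrix(0, nb, 3)
    for (j in seq_len(nb)) {
      Sj <- which(X[, j] == 1)
      B[j, ] <- if (!length(Sj)) c((j - 1) * s, 6 * cutoff, 0)
      else colMeans(A[Sj, , drop = FALSE]) + c(0, 0.5 * cutoff, 0) +
        stats::rnorm(3, 0, 0.05 * cutoff)
    }
    for (iter in 1:500) {
      D <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), `+`) -
                       2 * A %*% t(B), 0))
      viol_close <- X == 1 & D > 0.7 * cutoff
      viol_far <- X == 0 & D < 1.3 * cutoff
      if (!any(viol_close) && !any(viol_far)) break
      for (idx in which(viol_close | viol_far)) {
        i <- (idx - 1) %% na + 1
        j <- (idx - 1) %/% na + 1
        dvec <- B[j, ] - A[i, ]
        d <- sqrt(sum(dvec^2))
        u <- if (d > 1e-9) dvec / d else {
          v <- stats::rnorm(3); v / sqrt(sum(v^2))
        }
        # move both endpoints so multiply-constrained residues can relax
        if (X[i, j] == 1) {
          shift <- 0.4 * (d - 0.5 * cutoff)
        } else {
          shift <- -0.5 * (1.5 * cutoff - d)
        }
        B[j, ] <- B[j, ] - shift * u
        A[i, ] <- A[i, ] + shift * u
      }
    }
    D <- sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B))
    ok <- all((D < cutoff) == (X == 1)) &&
      all(abs(D - cutoff) > 0.05 * cutoff)
    if (ok) return(rbind(A, B))
  }
  stop("packing error: contact pattern not geometrically realizable")
}

#' Trajectory fixture with known contact probabilities
#'
#' Draws, for every frame, an independent Bernoulli contact state for
#' each inter-chain residue pair from `p_matrix`, and places one chain
#' of species "A" (rows) and one of species "B" (columns) so that
#' exactly the drawn pairs fall inside the cutoff (verified by brute
#' force; coordinates are re-drawn, never the contact states, if a
#' placement fails).  The empirical contact map over many frames
#' converges to `p_matrix` at the binomial rate.
#'
#' @param p_matrix matrix of contact probabilities in \[0,1\].
#' @param n_frames number of frames.
#' @param cutoff contact cutoff, nm.
#' @param seed RNG seed.
#' @return list with `traj` (a `cg_trajectory` with topology), `seq_a`,
#'   `seq_b`, `table`, `cutoff`, and the per-frame `states` array.
#' @export
gen_contact_fixture <- function(p_matrix, n_frames, cutoff = 0.5,
                                seed = 1L) {
  stopifnot(all(p_matrix >= 0 & p_matrix <= 1))
  set.seed(seed)
  na <- nrow(p_matrix); nb <- ncol(p_matrix)
  hp <- make_homopolymer(2, 0.5)   # dummy table for the topology
  seq_a <- seq_record("A", rep("A", na))
  seq_b <- seq_record("B", rep("A", nb))
  top <- create_topology(list(seq_a, seq_b), hp$table,
                         termini_charged = FALSE, species = c("A", "B"))
  L <- 3 * cutoff * (max(na, nb) + 14)
  box <- c(L, L, L)
  coords <- array(0, dim = c(n_frames, na + nb, 3))
  states <- array(0L, dim = c(n_frames, na, nb))
  for (f in seq_len(n_frames)) {
    X <- matrix(stats::rbinom(na * nb, 1, as.numeric(p_matrix)), na, nb)
    states[f, , ] <- X
    pts <- realize_contact_pattern(X, cutoff)
    # keep everything well inside the box, away from boundaries
    pts <- sweep(pts, 2, apply(pts, 2, min)) + 2 * cutoff
    coords[f, , ] <- pts
  }
  traj <- new_trajectory(coords, box, times = seq_len(n_frames) - 1,
                         topology = top)
  list(traj = traj, seq_a = seq_a, seq_b = seq_b, table = hp$table,
       cutoff = cutoff, states = states)
}

rotation_about <- function(axis, angle_deg) {
  u <- unit_vec(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st,
           ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),
           uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st,
           ct + uz^2 * (1 - ct)), 3, 3, byrow = TRUE)
}

hexagon_ring <- function(radius = 0.1395) {
  ang <- (0:5) * pi / 3
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

guanidinium_group <- function() {
  # CZ at the center, NE/NH1/NH2 at ~1.33 A in the plane
  rbind(c(0, 0, 0),
        0.133 * cbind(cos(c(0, 2 * pi / 3, 4 * pi / 3)),
                      sin(c(0, 2 * pi / 3, 4 * pi / 3)), 0))
}

#' Constructed pi-interaction geometry with closed-form ground truth
#'
#' Builds an ideal phenol ring in the xy-plane plus a partner group at
#' the stated geometry: the partner sits `separation` nm along the ring
#' normal, shifted `lateral_offset` nm in-plane, with its own plane (or
#' the donor axis, for hydrogen bonds) tilted by `tilt` degrees.  The
#' expected classification is computed from the criteria's closed-form
#' geometry (explicit vector arithmetic), independent of the detector
#' implementations.
#'
#' @param separation center-center distance along the ring normal, nm.
#' @param tilt degrees; tilts the partner plane (sp2), is ignored for
#'   cation, and bends the donor-H-acceptor angle for hbond
#'   (0 = collinear).
#' @param lateral_offset in-plane shift of the partner, nm.
#' @param kind `"cation"`, `"sp2"` or `"hbond"`.
#' @return list with `pair` (observation in the layout of
#'   [interaction_percentages()]), `expected` (logical), `kind`, and
#'   the generating parameters.
#' @export
build_pi_fixture <- function(separation, tilt = 0, lateral_offset = 0,
                             kind = c("cation", "sp2", "hbond")) {
  kind <- match.arg(kind)
  stopifnot(is.finite(separation), is.finite(tilt),
            is.finite(lateral_offset))
  ring <- hexagon_ring()
  if (kind == "cation") {
    n_pos <- c(lateral_offset, 0, separation)
    d <- sqrt(lateral_offset^2 + separation^2)
    cosang <- if (d > 0) abs(separation) / d else 1
    expected <- (d < 0.6) && (cosang > 0.8)
    pair <- list(ring = ring, cation_n = matrix(n_pos, 1, 3))
    geom <- list(distance = d, cos_angle = cosang)
  } else if (kind == "sp2") {
    Rt <- rotation_about(c(1, 0, 0), tilt)
    com_g <- c(lateral_offset, 0, separation)
    gua <- t(Rt %*% t(guanidinium_group())) +
      matrix(com_g, 4, 3, byrow = TRUE)
    d <- sqrt(lateral_offset^2 + separation^2)
    n_ring <- c(0, 0, 1)
    n_g <- as.numeric(Rt %*% c(0, 0, 1))
    cosn <- abs(sum(n_ring * n_g))
    # orient each normal toward the other center, elevate 0.15 nm
    dir_rg <- com_g                      # ring com is the origin
    nr <- if (sum(n_ring * dir_rg) >= 0) n_ring else -n_ring
    ng <- if (sum(n_g * -dir_rg) >= 0) n_g else -n_g
    e_ring <- 0.15 * nr
    e_g <- com_g + 0.15 * ng
    de <- sqrt(sum((e_g - e_ring)^2))
    expected <- (d < 0.8) && (cosn > 0.8) && (de < 0.4)
    pair <- list(ring = ring, guanidinium = gua)
    geom <- list(com_distance = d, cos_normals = cosn,
                 elevated_distance = de)
  } else {
    acceptor <- c(0, 0, 0)
    donor <- c(0, 0, separation)
    phi <- tilt * pi / 180
    h <- donor + 0.1 * c(-sin(phi), 0, -cos(phi))
    v1 <- donor - h; v2 <- acceptor - h
    ang <- acos(min(1, max(-1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    expected <- (separation <= 0.35) && (ang >= 150)
    pair <- list(ring = ring,
                 hbond = list(donor_heavy = donor, donor_h = h,
                              acceptor = acceptor))
    geom <- list(distance = separation, angle = ang)
  }
  list(pair = pair, expected = expected, kind = kind,
       separation = separation, tilt = tilt,
       lateral_offset = lateral_offset, geometry = geom)
}

#' Multi-frame pi-geometry trajectory with prescribed event states
#'
#' Builds one observation per frame whose cation-pi, sp2-pi and
#' hydrogen-bond states match the given logical vectors, using ideal
#' (clearly inside/outside the criteria) geometries.
#'
#' @param cation,sp2,hbond logical vectors of equal length (one entry
#'   per frame).
#' @return list of frames for [interaction_percentages()].
#' @export
gen_pi_trajectory <- function(cation, sp2 = rep(FALSE, length(cation)),
                              hbond = rep(FALSE, length(cation))) {
  stopifnot(length(cation) == length(sp2),
            length(cation) == length(hbond))
  lapply(seq_along(cation), function(f) {
    ring <- hexagon_ring()
    n_sep <- if (cation[f]) 0.4 else 0.9
    gua_sep <- if (sp2[f]) 0.35 else 1.2
    gua <- guanidinium_group() + matrix(c(0, 0, gua_sep), 4, 3,
                                        byrow = TRUE)
    hb_sep <- if (hbond[f]) 0.30 else 0.50
    list(list(ring = ring,
              cation_n = matrix(c(0, 0, n_sep), 1, 3),
              guanidinium = gua,
              hbond = list(donor_heavy = c(2, 0, hb_sep),
                           donor_h = c(2, 0, hb_sep - 0.1),
                           acceptor = c(2, 0, 0))))
  })
}
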