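# Independent oracles implemented from the model definitions, written
# separately from the package internals (plain R double loops).

kb_const <- 0.00831446261815324

# minimum-image displacement
mi_disp <- function(d, box) d - box * round(d / box)

# Brute-force total energy by an explicit double loop; independent of
# the compiled implementation.
r_brute_energy <- function(pos, top, box, cfg) {
  n <- nrow(pos)
  eb <- ea <- ee <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum(mi_disp(pos[i, ] - pos[j, ], box)^2))
      bonded <- top$chain_id[i] == top$chain_id[j] && j == i + 1
      if (bonded) {
        eb <- eb + 0.5 * 8368 * (d - 0.38)^2
        next
      }
      sij <- (top$sigma[i] + top$sigma[j]) / 2
      lij <- (top$lambda[i] + top$lambda[j]) / 2
      if (d <= cfg$rc_lj) {
        ulj <- 4 * 0.8368 * ((sij / d)^12 - (sij / d)^6)
        ea <- ea + if (d <= 2^(1 / 6) * sij)
          ulj + 0.8368 * (1 - lij) else lij * ulj
        if (cfg$shift_at_cutoff) {
          uc <- 4 * 0.8368 * ((sij / cfg$rc_lj)^12 - (sij / cfg$rc_lj)^6)
          ea <- ea - lij * uc
        }
      }
      qq <- top$charge[i] * top$charge[j]
      if (qq != 0 && d <= cfg$rc_elec) {
        ee <- ee + 138.935 * qq / (cfg$dielectric * d) *
          exp(-d / cfg$debye_length)
        if (cfg$shift_at_cutoff)
          ee <- ee - 138.935 * qq / (cfg$dielectric * cfg$rc_elec) *
            exp(-cfg$rc_elec / cfg$debye_length)
      }
    }
  }
  list(bonded = eb, ashbaugh_hatch = ea, electrostatic = ee,
       total = eb + ea + ee)
}

# Brute-force minimum-image distance matrix between two point sets.
r_dist_matrix <- function(a, b, box) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      out[i, j] <- sqrt(sum(mi_disp(a[i, ] - b[j, ], box)^2))
  out
}

# Random test system: 3 chains x 10 beads with heterogeneous parameters,
# positions drawn away from singularities and cutoff edges.
random_test_system <- function(seed, n_chains = 3, n_res = 10,
                               box = c(6, 6, 8), charged = TRUE) {
  set.seed(seed)
  tab <- load_parameter_table(data.frame(
    code = cgphase:::AA_CODES,
    sigma_nm = runif(20, 0.45, 0.68),
    lambda = runif(20),
    charge_e = sample(c(-1, 0, 0, 1), 20, replace = TRUE) *
      as.integer(charged),
    mass_gmol = runif(20, 57, 186)), provenance = "test")
  chains <- lapply(seq_len(n_chains), function(i)
    seq_record(paste0("c", i),
               sample(cgphase:::AA_CODES, n_res, replace = TRUE)))
  top <- create_topology(chains, tab, termini_charged = charged,
                         species = rep("A", n_chains))
  cfg <- sim_config(rc_lj = 2.0, rc_elec = 2.5)
  repeat {
    pos <- matrix(runif(3 * top$n_beads), ncol = 3) %*% diag(box)
    D <- r_dist_matrix(pos, pos, box)
    diag(D) <- 1
    near_cut <- abs(D - cfg$rc_lj) < 2e-3 | abs(D - cfg$rc_elec) < 2e-3
    if (min(D) > 0.25 && !any(near_cut)) break
  }
  list(top = top, pos = pos, box = box, cfg = cfg, table = tab)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(coords, R, t) {
  sweep(as.matrix(coords) %*% t(R), 2, -t)
}
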