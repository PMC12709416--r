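test_that("scalar potentials reproduce hand-derived values", {
  expect_equal(bonded_energy(0.38), 0)
  expect_equal(bonded_energy(0.48), 41.84)      # 0.5 * 8368 * 0.1^2
  expect_equal(bonded_energy(0.28), 41.84)      # symmetry about l

  # lambda = 1 collapses to plain LJ below the cutoff
  r <- seq(0.55, 1.9, by = 0.05)
  ulj <- 4 * 0.8368 * ((0.6 / r)^12 - (0.6 / r)^6)
  expect_equal(ah_potential(r, 0.6, 1), ulj)
  # at r = sigma the LJ term vanishes: U = eps * (1 - lambda)
  expect_equal(ah_potential(0.6, 0.6, 0.5), 0.4184)
  # at the minimum both branches give -eps * lambda
  expect_equal(ah_potential(2^(1 / 6) * 0.6, 0.6, 0.5), -0.4184)
  expect_equal(ah_potential(2^(1 / 6) * 0.6 - 1e-12, 0.6, 0.5),
               ah_potential(2^(1 / 6) * 0.6 + 1e-12, 0.6, 0.5),
               tolerance = 1e-6)
  expect_equal(ah_potential(2.5, 0.6, 0.9), 0)  # beyond cutoff

  expect_equal(dh_potential(1.5, 0, 1), 0)
  expect_equal(dh_potential(1, 1, 1), 138.935 / 80 * exp(-1))
  expect_equal(dh_potential(4.5, 1, 1), 0)      # beyond 4 nm truncation
})

test_that("total energy matches the brute-force double-loop oracle", {
  for (seed in c(2, 7, 19)) {
    sys <- random_test_system(seed)
    ef <- total_energy_forces(sys$pos, sys$top, sys$box, sys$cfg)
    oracle <- r_brute_energy(sys$pos, sys$top, sys$box, sys$cfg)
    expect_equal(ef$bonded, oracle$bonded, tolerance = 1e-9)
    expect_equal(ef$ashbaugh_hatch, oracle$ashbaugh_hatch,
                 tolerance = 1e-9)
    expect_equal(ef$electrostatic, oracle$electrostatic,
                 tolerance = 1e-9)
    expect_equal(ef$total, oracle$total, tolerance = 1e-9)
    expect_equal(ef$total,
                 ef$bonded + ef$ashbaugh_hatch + ef$electrostatic)
  }
  # cut-and-shift variant against the same oracle
  sys <- random_test_system(5)
  sys$cfg$shift_at_cutoff <- TRUE
  ef <- total_energy_forces(sys$pos, sys$top, sys$box, sys$cfg)
  oracle <- r_brute_energy(sys$pos, sys$top, sys$box, sys$cfg)
  expect_equal(ef$total, oracle$total, tolerance = 1e-9)
})

test_that("neighbor-list energies equal brute force on many frames", {
  sys <- random_test_system(1)
  set.seed(101)
  for (f in 1:100) {
    pos <- matrix(runif(3 * sys$top$n_beads), ncol = 3) %*%
      diag(sys$box)
    a <- total_energy_forces(pos, sys$top, sys$box, sys$cfg,
                             use_nlist = FALSE)
    b <- total_energy_forces(pos, sys$top, sys$box, sys$cfg,
                             use_nlist = TRUE)
    expect_identical(a$total, b$total)
    expect_identical(a$forces, b$forces)
  }
})

test_that("forces are the negative gradient of the energy", {
  h <- 1e-5
  for (seed in c(3, 13)) {
    sys <- random_test_system(seed)
    ef <- total_energy_forces(sys$pos, sys$top, sys$box, sys$cfg)
    fscale <- max(abs(ef$forces))
    for (i in seq_len(sys$top$n_beads)) {
      for (d in 1:3) {
        pp <- sys$pos; pp[i, d] <- pp[i, d] + h
        pm <- sys$pos; pm[i, d] <- pm[i, d] - h
        fn <- -(total_energy_forces(pp, sys$top, sys$box, sys$cfg)$total -
                  total_energy_forces(pm, sys$top, sys$box, sys$cfg)$total) /
          (2 * h)
        expect_lt(abs(fn - ef$forces[i, d]) / fscale, 1e-6)
      }
    }
    # Newton's third law: forces sum to zero
    expect_lt(max(abs(colSums(ef$forces))), 1e-9 * max(1, fscale))
  }
})

test_that("energy evaluation rejects overlapping beads", {
  sys <- random_test_system(4)
  pos <- sys$pos
  pos[2, ] <- pos[5, ] + 1e-8
  expect_error(total_energy_forces(pos, sys$top, sys$box, sys$cfg),
               "overlap")
})

test_that("langevin runs are seed-deterministic and stable", {
  sys <- random_test_system(8, n_chains = 2, n_res = 6)
  cfg <- sim_config(temperature = 300, n_steps = 2000, save_every = 100,
                    seed = 42, rc_elec = 2.5)
  t1 <- langevin_run(sys$pos, sys$top, sys$box, cfg)
  t2 <- langevin_run(sys$pos, sys$top, sys$box, cfg)
  expect_identical(t1$coords, t2$coords)
  expect_equal(n_frames(t1), 20)
  cfg2 <- cfg; cfg2$seed <- 43L
  t3 <- langevin_run(sys$pos, sys$top, sys$box, cfg2)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("zero-temperature free bead stays put", {
  hp <- make_homopolymer(1, 0.5)
  top <- create_topology(hp$seq, hp$table, termini_charged = FALSE)
  pos <- matrix(c(2, 2, 2), 1, 3)
  cfg <- sim_config(temperature = 0, n_steps = 500, save_every = 50,
                    rc_elec = 2.0)
  tr <- langevin_run(pos, top, c(5, 5, 5), cfg)
  expect_equal(tr$coords[n_frames(tr), 1, ], c(2, 2, 2))
})

test_that("purely repulsive nonbonded dimer separates monotonically at T=0", {
  hp <- make_homopolymer(1, 0)          # lambda = 0: repulsion only
  top <- create_topology(list(hp$seq, hp$seq), hp$table,
                         termini_charged = FALSE, species = c("A", "B"))
  r0 <- 0.5                              # inside 2^(1/6) * 0.6 = 0.674
  pos <- rbind(c(3, 3, 3), c(3, 3, 3 + r0))
  cfg <- sim_config(temperature = 0, n_steps = 3000, save_every = 30,
                    friction = 5, rc_elec = 2.0)
  tr <- langevin_run(pos, top, c(8, 8, 8), cfg,
                     velocities = matrix(0, 2, 3))
  sep <- apply(tr$coords, 1, function(xy) sqrt(sum((xy[2, ] - xy[1, ])^2)))
  expect_true(all(diff(sep) > -1e-9))
  expect_gte(max(sep), 2^(1 / 6) * 0.6 - 1e-3)
})

test_that("thermostatted dimer matches equipartition targets", {
  hp <- make_homopolymer(2, 0.5)
  top <- create_topology(hp$seq, hp$table, termini_charged = FALSE)
  pos <- rbind(c(2.5, 2.5, 2.5), c(2.5, 2.5, 2.88))
  # friction 1/ps gives ~5000 independent kinetic-energy samples over
  # 10 ns, so the 2% band is several standard errors wide
  cfg <- sim_config(temperature = 300, n_steps = 1e6, friction = 1.0,
                    seed = 7, save_every = 200, rc_elec = 2.0)
  tr <- langevin_run(pos, top, c(5, 5, 5), cfg)
  expect_lt(abs(tr$kinetic_temperature - 300) / 300, 0.02)
  # mean bond potential ~ kB T / 2 (radial-mode equipartition)
  expect_equal(mean(tr$energies[, "bonded"]), kb_const * 300 / 2,
               tolerance = 0.08)
})

test_that("slab builder respects geometry, separation and seed", {
  hp <- make_homopolymer(3, 0.5)
  top1 <- create_topology(hp$seq, hp$table, termini_charged = FALSE)
  p <- build_slab_system(top1, c(8, 8, 20), seed = 3)
  expect_equal(sqrt(sum((p[2, ] - p[1, ])^2)), 0.38, tolerance = 1e-12)
  expect_equal(sqrt(sum((p[3, ] - p[2, ])^2)), 0.38, tolerance = 1e-12)

  hp2 <- make_homopolymer(8, 0.5)
  top20 <- create_topology(rep(list(hp2$seq), 20), hp2$table,
                           termini_charged = FALSE,
                           species = rep("A", 20))
  box <- c(10, 10, 30)
  pa <- build_slab_system(top20, box, seed = 5, min_separation = 0.4)
  pb <- build_slab_system(top20, box, seed = 5, min_separation = 0.4)
  expect_identical(pa, pb)
  # brute-force check: all non-bonded pairs at least min_separation apart
  D <- r_dist_matrix(pa, pa, box)
  bonded <- abs(outer(seq_len(160), seq_len(160), `-`)) == 1 &
    outer(top20$chain_id, top20$chain_id, `==`)
  D[bonded] <- Inf
  diag(D) <- Inf
  expect_gte(min(D), 0.4)
  # slab confinement keeps initial z inside the central band
  pc <- build_slab_system(top20, box, seed = 5, slab_thickness = 8)
  expect_true(all(pc[, 3] >= 15 - 4 & pc[, 3] <= 15 + 4))
})

test_that("XYZ trajectory round trip and checkpoint restore state", {
  sys <- random_test_system(9, n_chains = 2, n_res = 4)
  cfg <- sim_config(n_steps = 300, save_every = 100, seed = 2,
                    rc_elec = 2.5)
  tr <- langevin_run(sys$pos, sys$top, sys$box, cfg)
  f <- tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  back <- read_xyz(f)
  expect_equal(back$coords, tr$coords, tolerance = 1e-5)
  expect_equal(back$box, tr$box)
  expect_equal(back$times, tr$times)

  ck <- tempfile(fileext = ".json")
  write_checkpoint(list(positions = tr$final$positions,
                        velocities = tr$final$velocities,
                        step = cfg$n_steps, box = sys$box), ck)
  st <- read_checkpoint(ck)
  expect_equal(st$positions, tr$final$positions)
  expect_equal(st$velocities, tr$final$velocities)
  expect_equal(st$step, cfg$n_steps)

  pdb <- tempfile(fileext = ".pdb")
  write_pdb_topology(tr, pdb)
  expect_true(file.exists(pdb))
  expect_gt(length(grep("^ATOM", readLines(pdb))), 0)
})
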