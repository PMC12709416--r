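two_chain_traj <- function(posA, posB, box, lamtab = make_homopolymer(2, 0.5)$table,
                           codesA = rep("A", nrow(posA)),
                           codesB = rep("A", nrow(posB))) {
  top <- create_topology(list(seq_record("A", codesA),
                              seq_record("B", codesB)),
                         lamtab, termini_charged = FALSE,
                         species = c("A", "B"))
  co <- array(0, dim = c(1, nrow(posA) + nrow(posB), 3))
  co[1, , ] <- rbind(posA, posB)
  cgphase:::new_trajectory(co, box, 0, top)
}

test_that("hand-placed two-chain frame gives the expected contact matrix", {
  box <- c(20, 20, 20)
  # only pair (residue 1 of A, residue 2 of B) within the 0.5 nm cutoff
  posA <- rbind(c(5, 5, 5), c(5, 5, 5.38))
  posB <- rbind(c(12, 12, 12), c(5.4, 5, 5))
  tr <- two_chain_traj(posA, posB, box)
  map <- interchain_contact_map(tr, "A", "B", rule = "fixed",
                                cutoff = 0.5)
  expect_equal(map$matrix, rbind(c(0, 1), c(0, 0)))
  # matches the exhaustive distance oracle
  D <- r_dist_matrix(posA, posB, box)
  expect_equal(map$matrix, (D < 0.5) * 1)

  # all chains beyond the cutoff -> zero matrix
  far <- two_chain_traj(posA, posA + 8, box)
  expect_equal(interchain_contact_map(far, "A", "B", rule = "fixed",
                                      cutoff = 0.5)$matrix,
               matrix(0, 2, 2))
})

test_that("duplicated frames leave the contact map unchanged", {
  set.seed(30)
  box <- c(15, 15, 15)
  posA <- matrix(runif(12) * 4 + 4, ncol = 3)
  posB <- matrix(runif(12) * 4 + 4, ncol = 3)
  tr1 <- two_chain_traj(posA, posB, box)
  co2 <- array(0, dim = c(3, 8, 3))
  for (f in 1:3) co2[f, , ] <- rbind(posA, posB)
  tr3 <- tr1; tr3$coords <- co2; tr3$times <- 0:2
  m1 <- interchain_contact_map(tr1, "A", "B", rule = "fixed", cutoff = 1)
  m3 <- interchain_contact_map(tr3, "A", "B", rule = "fixed", cutoff = 1)
  expect_equal(m1$matrix, m3$matrix)
})

test_that("calvados rule uses pair-specific cutoffs from bead diameters", {
  # heterogeneous sigmas: contact iff d < 2^(1/6) * (s_i + s_j)/2
  df <- data.frame(code = cgphase:::AA_CODES, sigma_nm = 0.5,
                   lambda = 0.5, charge_e = 0, mass_gmol = 110)
  df$sigma_nm[df$code == "G"] <- 0.45
  df$sigma_nm[df$code == "W"] <- 0.678
  tab <- load_parameter_table(df)
  box <- c(20, 20, 20)
  d <- 0.58   # between 2^(1/6)*0.475 = 0.533 and 2^(1/6)*0.589 = 0.661
  posA <- rbind(c(5, 5, 5), c(5, 5, 5.38))
  posB <- rbind(c(5, 5, 5 - d), c(5 + d, 5, 5.38))
  tr <- two_chain_traj(posA, posB, box, lamtab = tab,
                       codesA = c("G", "W"), codesB = c("G", "W"))
  map <- interchain_contact_map(tr, "A", "B", rule = "calvados")
  # G-G pair at 0.58 > 0.533: no contact; W-W pair at 0.58 < 0.661: contact
  expect_equal(map$matrix[1, 1], 0)
  expect_equal(map$matrix[2, 2], 1)
  expect_equal(map$cutoff_rule, "calvados")
})

test_that("contact maps match the brute-force oracle on random frames", {
  set.seed(31)
  hp <- make_homopolymer(5, 0.5)
  top <- create_topology(rep(list(hp$seq), 4), hp$table,
                         termini_charged = FALSE,
                         species = rep("A", 4))
  box <- c(6, 6, 6)
  for (rep in 1:50) {
    co <- array(runif(20 * 3) * 6, dim = c(1, 20, 3))
    tr <- cgphase:::new_trajectory(co, box, 0, top)
    map <- interchain_contact_map(tr, rule = "fixed", cutoff = 0.8)
    # oracle: average over ordered chain pairs, then symmetrize
    acc <- matrix(0, 5, 5); np <- 0
    for (i in 1:4) for (j in 1:4) if (i != j) {
      D <- r_dist_matrix(co[1, (i - 1) * 5 + 1:5, , drop = FALSE][1, , ],
                         co[1, (j - 1) * 5 + 1:5, , drop = FALSE][1, , ],
                         box)
      acc <- acc + (D < 0.8); np <- np + 1
    }
    oracle <- acc / np
    oracle <- (oracle + t(oracle)) / 2
    expect_equal(map$matrix, oracle, tolerance = 1e-12)
    expect_true(all(map$matrix >= 0 & map$matrix <= 1))
    expect_equal(map$matrix, t(map$matrix))
  }
})

test_that("chain relabeling leaves maps and reductions unchanged", {
  set.seed(32)
  hp <- make_homopolymer(4, 0.5)
  box <- c(8, 8, 8)
  co <- array(runif(16 * 3) * 6 + 1, dim = c(1, 16, 3))
  top <- create_topology(rep(list(hp$seq), 4), hp$table,
                         termini_charged = FALSE, species = rep("A", 4))
  tr <- cgphase:::new_trajectory(co, box, 0, top)
  perm <- c(3, 1, 4, 2)
  co2 <- co
  for (k in 1:4)
    co2[1, (k - 1) * 4 + 1:4, ] <- co[1, (perm[k] - 1) * 4 + 1:4, ]
  tr2 <- cgphase:::new_trajectory(co2, box, 0, top)
  m1 <- interchain_contact_map(tr, rule = "fixed", cutoff = 1)
  m2 <- interchain_contact_map(tr2, rule = "fixed", cutoff = 1)
  expect_equal(m1$matrix, m2$matrix, tolerance = 1e-12)
  expect_equal(project_1d(m1, "A"), project_1d(m2, "A"))
})

test_that("grouped (atomistic) resolution takes the minimum atom distance", {
  # two chains of 2 residues x 3 atoms each
  hp <- make_homopolymer(2, 0.5)
  top <- create_topology(list(seq_record("A", "AA"),
                              seq_record("B", "AA")),
                         hp$table, termini_charged = FALSE,
                         species = c("A", "B"))
  top$chain_id <- rep(1:2, each = 6)
  top$n_beads <- 12
  atom_residue <- rep(rep(1:2, each = 3), 2)
  box <- c(20, 20, 20)
  co <- array(0, dim = c(1, 12, 3))
  base <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0))
  co[1, 1:3, ] <- base + 5            # chain A residue 1
  co[1, 4:6, ] <- base + 7            # chain A residue 2
  co[1, 7:9, ] <- sweep(base, 2, c(5.2 + 0.44, 5, 5), "+")  # B res 1
  co[1, 10:12, ] <- base + 12         # B residue 2
  tr <- cgphase:::new_trajectory(co, box, 0, top)
  map <- interchain_contact_map(tr, "A", "B", rule = "fixed",
                                cutoff = 0.45, resolution = "atomistic",
                                atom_residue = atom_residue)
  # closest atoms of A1 and B1 are 0.44 apart -> contact; others far
  expect_equal(map$matrix, rbind(c(1, 0), c(0, 0)))
})

test_that("1D projections are means along the other axis", {
  m <- cgphase:::new_contact_map(rbind(c(0, 1), c(0, 0)), "fixed", 0.5,
                                 "residue-bead", 1, 1, c("A", "B"))
  expect_equal(project_1d(m, "A"), c(0.5, 0))
  expect_equal(project_1d(m, "B"), c(0, 0.5))
  const <- cgphase:::new_contact_map(matrix(0.3, 4, 4), "fixed", 0.5,
                                     "residue-bead", 1, 1, c("A", "A"))
  expect_equal(project_1d(const, "A"), rep(0.3, 4))
  expect_equal(mean(project_1d(m, "A")), mean(m$matrix))
})

test_that("region averages reduce blocks and recover planted structure", {
  m <- cgphase:::new_contact_map(matrix(0.2, 6, 6), "fixed", 0.5,
                                 "residue-bead", 1, 1, c("A", "A"))
  all_reg <- list(region("all", 1, 6))
  expect_equal(region_average(m, all_reg)[1, 1], 0.2)

  half <- matrix(0.1, 6, 6); half[4:6, 4:6] <- 0.7
  mh <- cgphase:::new_contact_map(half, "fixed", 0.5, "residue-bead",
                                  1, 1, c("A", "A"))
  regs <- list(region("first", 1, 3), region("second", 4, 6))
  blocks <- region_average(mh, regs)
  expect_equal(blocks["first", "first"], 0.1)
  expect_equal(blocks["second", "second"], 0.7)

  # planted enrichment ordering: FFR:FFR > FFR:M8BR > M8BR:M8BR
  set.seed(33)
  n <- 40
  planted <- matrix(runif(n * n, 0, 0.05), n, n)
  planted[21:40, 21:40] <- planted[21:40, 21:40] + 0.5
  planted[1:20, 21:40] <- planted[1:20, 21:40] + 0.2
  planted[21:40, 1:20] <- t(planted[1:20, 21:40])
  planted <- (planted + t(planted)) / 2
  mp <- cgphase:::new_contact_map(planted, "fixed", 0.5, "residue-bead",
                                  1, 1, c("A", "A"))
  regs <- list(region("M8BR", 1, 20), region("FFR", 21, 40))
  b <- region_average(mp, regs)
  expect_gt(b["FFR", "FFR"], b["FFR", "M8BR"])
  expect_gt(b["FFR", "M8BR"], b["M8BR", "M8BR"])

  expect_error(region_average(m, list(region("x", 1, 8))), "range")
  expect_error(region_average(m, list(region("a", 1, 4),
                                      region("b", 3, 6))), "overlap")
})

test_that("residue-type maps sum, normalize and guard absent pairs", {
  ones <- cgphase:::new_contact_map(matrix(1, 2, 2), "fixed", 0.5,
                                    "residue-bead", 1, 1, c("A", "B"))
  tm <- residue_type_map(ones, seq_record("a", "AY"),
                         seq_record("b", "AY"))
  expect_equal(tm$matrix["A", "Y"], 1)
  expect_equal(tm$matrix["Y", "A"], 1)
  expect_equal(tm$matrix["A", "A"], 1)
  expect_true(is.na(tm$matrix["W", "F"]))

  # planted: one Y-R position pair carries 0.6 among 4 Y-R pairs
  sa <- seq_record("a", "YRYR")
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.6    # Y at A position 1, R at B position 2
  cm <- cgphase:::new_contact_map(m, "fixed", 0.5, "residue-bead", 1, 1,
                                  c("A", "B"))
  tmu <- residue_type_map(cm, sa, sa, normalized = FALSE)
  tmn <- residue_type_map(cm, sa, sa, normalized = TRUE)
  expect_equal(tmu$matrix["Y", "R"], 0.6)
  expect_equal(tmn$pair_counts["Y", "R"], 8)  # 2x2 positions, both orders
  expect_equal(tmn$matrix["Y", "R"], 0.075)
  # normalized x counts = unnormalized wherever defined
  sel <- tmn$pair_counts > 0
  expect_equal(tmn$matrix[sel] * tmn$pair_counts[sel], tmu$matrix[sel])
  expect_equal(tmn$matrix, t(tmn$matrix))
  expect_error(residue_type_map(cm, seq_record("short", "YR"), sa),
               "match")
})

test_that("lambda correlation detects linear, inverted and null structure", {
  pt <- default_param_table()
  lam <- pt$lambda
  score <- outer(lam, lam, function(a, b) (a + b) / 2)
  dimnames(score) <- list(cgphase:::AA_CODES, cgphase:::AA_CODES)
  counts <- matrix(4, 20, 20, dimnames = dimnames(score))
  mk_tm <- function(mat) structure(
    list(matrix = mat, unnormalized = mat * counts,
         pair_counts = counts, normalized = TRUE),
    class = "residue_type_map")
  expect_equal(lambda_contact_correlation(mk_tm(0.01 + 0.3 * score),
                                          pt)$r, 1)
  expect_equal(lambda_contact_correlation(mk_tm(1 - 0.3 * score),
                                          pt)$r, -1)
  # permutation null: shuffled maps decorrelate
  set.seed(34)
  rs <- replicate(300, {
    idx <- sample(210)
    shuf <- score
    shuf[upper.tri(shuf, diag = TRUE)] <-
      score[upper.tri(score, diag = TRUE)][idx]
    shuf[lower.tri(shuf)] <- t(shuf)[lower.tri(shuf)]
    lambda_contact_correlation(mk_tm(shuf), pt)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_lt(stats::quantile(abs(rs), 0.5), 0.15)
  # product-form score option is honored
  r2 <- lambda_contact_correlation(mk_tm(0.01 + outer(lam, lam) / 2),
                                   pt, score = "product_half")$r
  expect_equal(r2, 1)
})

test_that("contact map writer produces TSV plus JSON sidecar", {
  m <- cgphase:::new_contact_map(matrix(0.25, 3, 3), "fixed", 0.6,
                                 "near-atomic", 10, 2, c("A", "B"))
  f <- tempfile(fileext = ".tsv")
  write_contact_map(m, f)
  expect_equal(unname(as.matrix(utils::read.delim(f, header = FALSE))),
               m$matrix)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$cutoff_value, 0.6)
  expect_equal(side$resolution, "near-atomic")
})
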