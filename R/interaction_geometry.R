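unit_vec <- function(v) v / sqrt(sum(v^2))

#' Best-fit plane of a planar group
#'
#' Returns the centroid and the unit normal of the least-squares plane
#' through the given atom coordinates (the smallest principal direction
#' of the centered coordinates).  Used for the Tyr phenol ring (six ring
#' carbons) and the Arg guanidinium group (CZ, NE, NH1, NH2).
#'
#' @param coords n x 3 matrix, nm, n >= 3 non-collinear points.
#' @return a `pi_plane` list: `com` (nm), `normal` (unit vector),
#'   `member_coords`.
#' @export
ring_plane <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 3)
  com <- colMeans(coords)
  centered <- sweep(coords, 2, com)
  sv <- svd(centered)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: points are collinear")
  structure(list(com = com, normal = unit_vec(sv$v[, 3]),
                 member_coords = coords),
            class = "pi_plane")
}

#' @export
print.pi_plane <- function(x, ...) {
  cat(sprintf("pi_plane: com (%.3f, %.3f, %.3f) nm, normal (%.3f, %.3f, %.3f)\n",
              x$com[1], x$com[2], x$com[3], x$normal[1], x$normal[2],
              x$normal[3]))
  invisible(x)
}

#' Cation-pi geometric detector
#'
#' A charged nitrogen and an aromatic ring form a cation-pi contact when
#' the nitrogen sits within 6 A of the ring center and the vector from
#' ring center to nitrogen is aligned with the ring normal (absolute
#' cosine > 0.8).
#'
#' @param n_coord nitrogen coordinate, nm (length-3).
#' @param ring a `pi_plane` for the aromatic ring.
#' @param dist_cut nm (default 0.6).
#' @param cos_cut minimum absolute cosine (default 0.8).
#' @return list `hit` (logical), `distance` (nm), `cos_angle`.
#' @export
detect_cation_pi <- function(n_coord, ring, dist_cut = 0.6,
                             cos_cut = 0.8) {
  v <- as.numeric(n_coord) - ring$com
  d <- sqrt(sum(v^2))
  ca <- if (d > 0) abs(sum(unit_vec(v) * ring$normal)) else 1
  list(hit = (d < dist_cut) && (ca > cos_cut), distance = d,
       cos_angle = ca)
}

#' sp2-pi stacking detector
#'
#' Two planar sp2 groups (guanidinium and aromatic ring) stack when
#' their centers are within 8 A, their normals are parallel (absolute
#' cosine > 0.8), and, after displacing each center 1.5 A along its
#' normal oriented toward the other plane, the displaced centers are
#' within 4 A.
#'
#' @param plane_a,plane_b `pi_plane` objects.
#' @param dist_cut center-center cutoff, nm (default 0.8).
#' @param cos_cut minimum absolute cosine between normals.
#' @param elevation displacement along each normal, nm (default 0.15).
#' @param elev_cut displaced-center cutoff, nm (default 0.4).
#' @param orient_toward_partner displace along the normal oriented
#'   toward the other plane's center (default); FALSE uses the stored
#'   normal signs as-is.
#' @return list `hit`, `com_distance`, `cos_normals`,
#'   `elevated_distance`.
#' @export
detect_sp2_pi <- function(plane_a, plane_b, dist_cut = 0.8,
                          cos_cut = 0.8, elevation = 0.15,
                          elev_cut = 0.4, orient_toward_partner = TRUE) {
  dcom <- plane_b$com - plane_a$com
  d <- sqrt(sum(dcom^2))
  cn <- abs(sum(plane_a$normal * plane_b$normal))
  na <- plane_a$normal
  nb <- plane_b$normal
  if (orient_toward_partner) {
    if (sum(na * dcom) < 0) na <- -na
    if (sum(nb * -dcom) < 0) nb <- -nb
  }
  ea <- plane_a$com + elevation * na
  eb <- plane_b$com + elevation * nb
  de <- sqrt(sum((eb - ea)^2))
  list(hit = (d < dist_cut) && (cn > cos_cut) && (de < elev_cut),
       com_distance = d, cos_normals = cn, elevated_distance = de)
}

#' Hydrogen-bond detector
#'
#' Standard geometric criterion: donor-acceptor heavy-atom distance at
#' most 3.5 A and donor-H...acceptor angle at least 150 degrees.  With
#' `heavy_only = TRUE` (for structures without hydrogens) only the
#' distance gate applies.
#'
#' @param donor_heavy,donor_h,acceptor coordinates, nm.
#' @param dist_cut nm (default 0.35).
#' @param angle_cut degrees (default 150).
#' @param heavy_only ignore the angle criterion.
#' @return list `hit`, `distance`, `angle` (degrees).
#' @export
detect_hbond <- function(donor_heavy, donor_h = NULL, acceptor,
                         dist_cut = 0.35, angle_cut = 150,
                         heavy_only = is.null(donor_h)) {
  d <- sqrt(sum((as.numeric(acceptor) - as.numeric(donor_heavy))^2))
  if (heavy_only)
    return(list(hit = d <= dist_cut, distance = d, angle = NA_real_))
  v1 <- as.numeric(donor_heavy) - as.numeric(donor_h)
  v2 <- as.numeric(acceptor) - as.numeric(donor_h)
  ang <- acos(pmin(1, pmax(-1, sum(unit_vec(v1) * unit_vec(v2))))) *
    180 / pi
  list(hit = (d <= dist_cut) && (ang >= angle_cut), distance = d,
       angle = ang)
}

evaluate_pair <- function(pair, cation_atoms) {
  ring <- ring_plane(pair$ring)
  cat_hit <- FALSE
  if (!is.null(pair$cation_n)) {
    nmat <- matrix(as.numeric(pair$cation_n), ncol = 3)
    for (k in seq_len(nrow(nmat)))
      if (detect_cation_pi(nmat[k, ], ring)$hit) { cat_hit <- TRUE; break }
  }
  sp2_hit <- FALSE
  if (!is.null(pair$guanidinium))
    sp2_hit <- detect_sp2_pi(ring_plane(pair$guanidinium), ring)$hit
  hb_hit <- FALSE
  if (!is.null(pair$hbond))
    hb_hit <- detect_hbond(pair$hbond$donor_heavy, pair$hbond$donor_h,
                           pair$hbond$acceptor)$hit
  c(cation_pi = cat_hit, sp2_pi = sp2_hit, hbond = hb_hit)
}

#' Interaction percentages over a trajectory of residue pairs
#'
#' Classifies every (frame, pair) observation with the cation-pi, sp2-pi
#' and hydrogen-bond detectors and reports the percentage of positive
#' observations per interaction kind, together with the conditional
#' hydrogen-bond percentage computed only over observations already
#' forming the cation-pi interaction.
#'
#' Input is a list of frames; each frame is a list of pair observations,
#' each a list with elements `ring` (ring-atom coordinate matrix, nm)
#' and optionally `cation_n` (matrix of candidate charged-nitrogen
#' coordinates; the pair counts as cation-pi if any nitrogen passes),
#' `guanidinium` (sp2-plane atom matrix) and `hbond` (list
#' `donor_heavy`, `donor_h`, `acceptor`).  [build_pi_fixture()] and
#' [gen_pi_trajectory()] produce this layout.
#'
#' @param frames list of frames as described.
#' @return list with `pct` (named percentages), `conditional_hbond_pct`
#'   (NA with `conditional_defined = FALSE` when no cation-pi events),
#'   `n_obs`, and the per-observation logical `events` matrix.
#' @export
interaction_percentages <- function(frames) {
  if (!length(frames) || !length(frames[[1]]))
    stop("empty selection: no frames or no pairs")
  events <- do.call(rbind, lapply(frames, function(fr)
    t(vapply(fr, evaluate_pair, logical(3), cation_atoms = NULL))))
  pct <- 100 * colMeans(events)
  n_cat <- sum(events[, "cation_pi"])
  cond <- if (n_cat > 0)
    100 * sum(events[, "cation_pi"] & events[, "hbond"]) / n_cat
  else NA_real_
  list(pct = pct, conditional_hbond_pct = cond,
       conditional_defined = n_cat > 0, n_obs = nrow(events),
       events = events)
}

parse_selection <- function(sel) {
  # "chain resno [resname]" tokens, e.g. "A 45 ARG"; resname optional
  parts <- strsplit(trimws(sel), "\\s+")[[1]]
  if (length(parts) < 2) stop("selection needs 'chain resno [resname]'")
  list(chain = parts[1], resno = as.integer(parts[2]),
       resname = if (length(parts) >= 3) toupper(parts[3]) else NA)
}

TYR_RING_ATOMS <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
GUANIDINIUM_ATOMS <- c("CZ", "NE", "NH1", "NH2")

residue_atoms <- function(pdb, sel, atoms) {
  idx <- which(pdb$atom$chain == sel$chain & pdb$atom$resno == sel$resno &
                 pdb$atom$elety %in% atoms)
  if (!is.na(sel$resname))
    idx <- idx[pdb$atom$resid[idx] == sel$resname]
  idx
}

#' Build pi-interaction observations from an atomistic structure
#'
#' Reads a PDB (single- or multi-model) with bio3d and assembles, for
#' every (cation residue, tyrosine) selection pair and every frame, the
#' observation layout consumed by [interaction_percentages()]: the Tyr
#' phenol ring (six ring carbons), the candidate charged nitrogens (Arg
#' NE/NH1/NH2 or Lys NZ), the guanidinium plane for Arg, and a
#' heavy-atom hydrogen-bond geometry (Arg NH1 donor to the Tyr backbone
#' carbonyl O).  Selections are strings `"chain resno [resname]"`, e.g.
#' `"A 45 ARG"`.  Coordinates are converted from Angstrom to nm.
#'
#' @param pdb_path path to a PDB file.
#' @param cation_sel character vector of Arg/Lys selections.
#' @param tyr_sel character vector of Tyr selections.
#' @return list of frames for [interaction_percentages()].
#' @export
pi_frames_from_pdb <- function(pdb_path, cation_sel, tyr_sel) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("pi_frames_from_pdb needs the bio3d package")
  if (!length(cation_sel) || !length(tyr_sel))
    stop("empty selection")
  pdb <- bio3d::read.pdb(pdb_path, multi = TRUE)
  xyz <- pdb$xyz                       # n_frames x 3*n_atoms, Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords_of <- function(frame, idx)
    matrix(xyz[frame, as.numeric(bio3d::atom2xyz(idx))],
           ncol = 3, byrow = TRUE) / 10
  cs <- lapply(cation_sel, parse_selection)
  ts <- lapply(tyr_sel, parse_selection)
  lapply(seq_len(nrow(xyz)), function(f) {
    obs <- list()
    for (cc in cs) {
      resname <- if (!is.na(cc$resname)) cc$resname else {
        i <- which(pdb$atom$chain == cc$chain & pdb$atom$resno == cc$resno)
        if (!length(i)) stop("selection matches no atoms: ", cc$chain,
                             " ", cc$resno)
        pdb$atom$resid[i[1]]
      }
      n_atoms <- if (resname == "ARG") c("NE", "NH1", "NH2") else "NZ"
      n_idx <- residue_atoms(pdb, cc, n_atoms)
      gua_idx <- if (resname == "ARG")
        residue_atoms(pdb, cc, GUANIDINIUM_ATOMS) else integer(0)
      donor_idx <- if (resname == "ARG")
        residue_atoms(pdb, cc, "NH1") else residue_atoms(pdb, cc, "NZ")
      for (tt in ts) {
        ring_idx <- residue_atoms(pdb, tt, TYR_RING_ATOMS)
        if (length(ring_idx) < 3 || !length(n_idx))
          stop("selection lacks required atoms (chain ", tt$chain,
               " resno ", tt$resno, ")")
        o_idx <- residue_atoms(pdb, tt, "O")
        pair <- list(ring = coords_of(f, ring_idx),
                     cation_n = coords_of(f, n_idx))
        if (length(gua_idx) == 4)
          pair$guanidinium <- coords_of(f, gua_idx)
        if (length(o_idx) && length(donor_idx))
          pair$hbond <- list(
            donor_heavy = as.numeric(coords_of(f, donor_idx[1])),
            donor_h = NULL,
            acceptor = as.numeric(coords_of(f, o_idx[1])))
        obs[[length(obs) + 1L]] <- pair
      }
    }
    obs
  })
}

#' Donnan-style ion partitioning prediction
#'
#' Predicts local small-ion concentrations from per-bin concentrations
#' of protein cationic and anionic residues, imposing local
#' electroneutrality and a fixed ion activity product
#' `cation * anion = c0^2` set by the bulk salt concentration: with net
#' protein charge concentration `Delta = c_cationic - c_anionic`,
#' `anion = (Delta + sqrt(Delta^2 + 4 c0^2))/2` and
#' `cation = c0^2 / anion`.
#'
#' @param protein_cation_conc,protein_anion_conc per-bin concentrations
#'   of positively / negatively charged residues, mM.
#' @param bulk_salt bulk salt concentration c0, mM (> 0).
#' @param bin_centers optional bin coordinates, nm.
#' @return an `ion_profile` data.frame with per-bin protein charge,
#'   predicted cation and anion concentrations (mM).
#' @export
predict_ion_profiles <- function(protein_cation_conc, protein_anion_conc,
                                 bulk_salt, bin_centers = NULL) {
  stopifnot(bulk_salt > 0,
            length(protein_cation_conc) == length(protein_anion_conc))
  delta <- protein_cation_conc - protein_anion_conc
  anion <- (delta + sqrt(delta^2 + 4 * bulk_salt^2)) / 2
  cation <- bulk_salt^2 / anion
  if (is.null(bin_centers)) bin_centers <- seq_along(delta)
  df <- data.frame(bin_center = bin_centers,
                   protein_cation_conc = protein_cation_conc,
                   protein_anion_conc = protein_anion_conc,
                   net_protein_charge = delta,
                   predicted_cation = cation,
                   predicted_anion = anion)
  attr(df, "bulk_salt") <- bulk_salt
  class(df) <- c("ion_profile", "data.frame")
  df
}
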