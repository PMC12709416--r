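new_contact_map <- function(matrix, cutoff_rule, cutoff_value, resolution,
                            n_frames, n_chain_pairs, species,
                            offsets = c(1L, 1L)) {
  structure(list(matrix = matrix, cutoff_rule = cutoff_rule,
                 cutoff_value = cutoff_value, resolution = resolution,
                 n_frames = n_frames, n_chain_pairs = n_chain_pairs,
                 species = species, offsets = offsets),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "contact_map %dx%d (%s vs %s), rule=%s, resolution=%s, %d frames, %d chain pairs\n",
    nrow(x$matrix), ncol(x$matrix), x$species[1], x$species[2],
    x$cutoff_rule, x$resolution, x$n_frames, x$n_chain_pairs))
  invisible(x)
}

pair_cutoff_matrix <- function(sigma_a, sigma_b) {
  2^(1 / 6) * outer(sigma_a, sigma_b, function(a, b) (a + b) / 2)
}

min_by_residue <- function(D, res_a, res_b, na_res, nb_res) {
  out <- matrix(Inf, na_res, nb_res)
  for (a in seq_len(na_res)) {
    rows <- which(res_a == a)
    sub <- D[rows, , drop = FALSE]
    for (b in seq_len(nb_res)) {
      cols <- which(res_b == b)
      out[a, b] <- min(sub[, cols])
    }
  }
  out
}

#' Inter-chain residue contact map
#'
#' For every frame and every inter-chain pairing, a residue pair is in
#' contact when its minimum-image distance falls below the cutoff:
#' pair-specific `2^(1/6) sigma_ij` under the `"calvados"` rule
#' (residue-bead resolution) or a fixed distance (6 A for near-atomic
#' and 4.5 A for atomistic resolutions, where the residue-residue
#' distance is the minimum over constituent atoms).  The binary contact
#' matrices are averaged over chain pairs, then over frames.  Homotypic
#' maps (same species on both axes) are averaged over ordered chain
#' pairs and symmetrized.
#'
#' @param traj a `cg_trajectory`; its topology labels each chain with a
#'   species.
#' @param species_a,species_b species labels selecting the two map axes;
#'   defaults to the single species present (homotypic).
#' @param rule `"calvados"` (pair-specific cutoff from bead diameters)
#'   or `"fixed"`.
#' @param cutoff fixed-rule cutoff, nm.
#' @param resolution `"residue-bead"`, `"near-atomic"` or
#'   `"atomistic"`; the latter two require `atom_residue`, a per-atom
#'   integer vector of residue indices within each chain.
#' @param atom_residue integer vector, one entry per trajectory
#'   particle, giving the 1-based residue index within its chain
#'   (required for grouped resolutions).
#' @return a `contact_map`.
#' @export
interchain_contact_map <- function(traj, species_a = NULL,
                                   species_b = NULL,
                                   rule = c("calvados", "fixed"),
                                   cutoff = NULL,
                                   resolution = "residue-bead",
                                   atom_residue = NULL) {
  rule <- match.arg(rule)
  top <- traj$topology
  stopifnot(!is.null(top))
  if (!resolution %in% c("residue-bead", "near-atomic", "atomistic"))
    stop("unknown resolution: ", resolution)
  sp <- top$chain_species
  if (is.null(species_a)) species_a <- sp[1]
  if (is.null(species_b)) species_b <- species_a
  chains_a <- which(sp == species_a)
  chains_b <- which(sp == species_b)
  homotypic <- identical(species_a, species_b)
  if (homotypic && length(chains_a) < 2)
    stop("homotypic contact map needs at least two chains of species '",
         species_a, "'")
  if (!length(chains_a) || !length(chains_b))
    stop("no chains of the requested species")
  if (rule == "fixed" && is.null(cutoff))
    stop("fixed rule requires a cutoff (nm)")
  if (rule == "calvados" && resolution != "residue-bead")
    stop("the calvados rule applies at residue-bead resolution")

  bead_chain <- top$chain_id
  grouped <- resolution != "residue-bead"
  if (grouped && is.null(atom_residue))
    stop("grouped resolutions require atom_residue")

  res_per_chain <- function(ci) {
    idx <- which(bead_chain == ci)
    if (grouped) list(idx = idx, res = atom_residue[idx],
                      n_res = max(atom_residue[idx]))
    else list(idx = idx, res = seq_along(idx), n_res = length(idx))
  }
  ca1 <- res_per_chain(chains_a[1])
  cb1 <- res_per_chain(chains_b[1])
  na_res <- ca1$n_res
  nb_res <- cb1$n_res

  cutmat <- if (rule == "calvados")
    pair_cutoff_matrix(top$sigma[ca1$idx], top$sigma[cb1$idx])
  else matrix(cutoff, na_res, nb_res)

  pairs <- list()
  for (i in chains_a)
    for (j in chains_b)
      if (i != j) pairs[[length(pairs) + 1L]] <- c(i, j)
  nf <- n_frames(traj)
  acc <- matrix(0, na_res, nb_res)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[f, , , drop = TRUE]
    facc <- matrix(0, na_res, nb_res)
    for (p in pairs) {
      ia <- res_per_chain(p[1]); ib <- res_per_chain(p[2])
      D <- cpp_min_dists(xyz[ia$idx, , drop = FALSE],
                         xyz[ib$idx, , drop = FALSE], traj$box)
      if (grouped)
        D <- min_by_residue(D, ia$res, ib$res, na_res, nb_res)
      facc <- facc + (D < cutmat)
    }
    acc <- acc + facc / length(pairs)
  }
  m <- acc / nf
  if (homotypic) m <- (m + t(m)) / 2
  offs <- c(1L, 1L)
  new_contact_map(m, rule, if (rule == "fixed") cutoff else NA_real_,
                  resolution, nf, length(pairs),
                  c(species_a, species_b), offs)
}

#' 1D projection of a contact map
#'
#' Relative per-residue contact probability: the mean of the map over
#' the other axis.
#'
#' @param map a `contact_map`.
#' @param axis `"A"` (rows) or `"B"` (columns).
#' @return numeric vector.
#' @export
project_1d <- function(map, axis = c("A", "B")) {
  axis <- match.arg(axis)
  if (axis == "A") rowMeans(map$matrix) else colMeans(map$matrix)
}

#' Region-wise block averages of a contact map
#'
#' Each block is the mean of the submatrix delimited by a pair of
#' regions.  Regions are given in map-position numbering (1-based along
#' each axis); an `offset` per axis converts parent-protein numbering.
#'
#' @param map a `contact_map`.
#' @param regions_a,regions_b lists of `region` objects for the row and
#'   column axes.
#' @param offset_a,offset_b numbering of the first map row / column
#'   (default 1; e.g. 633 for a construct starting at residue 633).
#' @return matrix of block means with region names on dimnames.
#' @export
region_average <- function(map, regions_a, regions_b = regions_a,
                           offset_a = 1L, offset_b = 1L) {
  check_regions <- function(regs, n, off) {
    idx <- lapply(regs, function(r) {
      i <- (r$start - off + 1L):(r$end - off + 1L)
      if (min(i) < 1L || max(i) > n)
        stop("region ", r$name, " out of map range")
      i
    })
    all_i <- unlist(idx)
    if (anyDuplicated(all_i)) stop("overlapping regions")
    idx
  }
  ia <- check_regions(regions_a, nrow(map$matrix), offset_a)
  ib <- check_regions(regions_b, ncol(map$matrix), offset_b)
  out <- matrix(0, length(ia), length(ib),
                dimnames = list(vapply(regions_a, `[[`, "", "name"),
                                vapply(regions_b, `[[`, "", "name")))
  for (a in seq_along(ia))
    for (b in seq_along(ib))
      out[a, b] <- mean(map$matrix[ia[[a]], ib[[b]]])
  out
}

#' Residue-type (amino-acid pair) contact statistics
#'
#' Sums map entries over all position pairs of each residue-type pair
#' (combining both orientations so the result is symmetric), and
#' optionally normalizes by the number of such position pairs.  Type
#' pairs absent from the sequences are NA.
#'
#' @param map a `contact_map`.
#' @param seq_a,seq_b `seq_record`s matching the map dimensions.
#' @param normalized divide sums by pair counts.
#' @return a `residue_type_map`: list with 20x20 `matrix`,
#'   `pair_counts`, `normalized`, `unnormalized` sums.
#' @export
residue_type_map <- function(map, seq_a, seq_b, normalized = TRUE) {
  ra <- seq_a$residues; rb <- seq_b$residues
  if (length(ra) != nrow(map$matrix) || length(rb) != ncol(map$matrix))
    stop("sequence lengths do not match map dimensions")
  sums <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  counts <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  fa <- factor(ra, levels = AA_CODES)
  fb <- factor(rb, levels = AA_CODES)
  # sum map entries by (type of row, type of column)
  agg <- rowsum(t(rowsum(map$matrix, fa, reorder = TRUE)), fb,
                reorder = TRUE)
  # agg is type_b x type_a; align to 20x20 with zeros for absent types
  S <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  S[rownames(agg), colnames(agg)] <- agg
  S <- t(S)  # now type_a x type_b
  na_t <- table(fa); nb_t <- table(fb)
  N <- outer(as.numeric(na_t), as.numeric(nb_t))
  dimnames(N) <- list(AA_CODES, AA_CODES)
  sums <- S + t(S); counts <- N + t(N)
  diag(sums) <- diag(S); diag(counts) <- diag(N)
  norm <- sums / counts
  norm[counts == 0] <- NA_real_
  structure(list(matrix = if (normalized) norm else sums,
                 unnormalized = sums, pair_counts = counts,
                 normalized = normalized),
            class = "residue_type_map")
}

#' @export
print.residue_type_map <- function(x, ...) {
  cat(sprintf("residue_type_map (%s), %d type pairs present\n",
              if (x$normalized) "normalized" else "unnormalized",
              sum(x$pair_counts[upper.tri(x$pair_counts, diag = TRUE)] > 0)))
  invisible(x)
}

#' Correlation between type-pair contact probability and stickiness
#'
#' Pearson correlation between the normalized residue-type contact
#' probabilities and a pair stickiness score over all type pairs present
#' in the sequences.  The default score is the model's own combination
#' rule, the arithmetic mean `(lambda_i + lambda_j)/2`; the literal
#' product form `lambda_i lambda_j / 2` is available as an option.
#'
#' @param typemap a normalized `residue_type_map`.
#' @param params a `param_table` supplying per-residue lambda.
#' @param score `"mean"` or `"product_half"`.
#' @return list with `r` (Pearson), `n_pairs`, `score` used.
#' @export
lambda_contact_correlation <- function(typemap, params,
                                       score = c("mean", "product_half")) {
  score <- match.arg(score)
  stopifnot(inherits(typemap, "residue_type_map"))
  if (!typemap$normalized)
    stop("lambda correlation requires a normalized type map")
  lam <- params[AA_CODES, "lambda"]
  smat <- if (score == "mean") outer(lam, lam, function(a, b) (a + b) / 2)
  else outer(lam, lam) / 2
  sel <- upper.tri(typemap$matrix, diag = TRUE) & typemap$pair_counts > 0 &
    is.finite(typemap$matrix)
  if (sum(sel) < 3)
    stop("need at least 3 valid type pairs for a correlation")
  list(r = stats::cor(typemap$matrix[sel], smat[sel]),
       n_pairs = sum(sel), score = score)
}

#' Write a contact map as TSV plus a JSON sidecar
#'
#' @param map a `contact_map`.
#' @param path TSV path; metadata goes to `<path>.json`.
#' @export
write_contact_map <- function(map, path) {
  utils::write.table(map$matrix, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(cutoff_rule = map$cutoff_rule, cutoff_value = map$cutoff_value,
         resolution = map$resolution, n_frames = map$n_frames,
         n_chain_pairs = map$n_chain_pairs, species = map$species),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
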