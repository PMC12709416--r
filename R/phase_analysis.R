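AVOGADRO <- 6.02214076e23
# (g/mol per nm^3) -> mg/mL
GMOL_NM3_TO_MGML <- 1e21 / AVOGADRO * 1000

new_density_profile <- function(bin_centers, values, sem, axis, bin_width,
                                units, extra = list()) {
  df <- data.frame(bin_center = bin_centers, value = values, sem = sem)
  attr(df, "axis") <- axis
  attr(df, "bin_width") <- bin_width
  attr(df, "units") <- units
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("density_profile", "data.frame")
  df
}

wrap_coord <- function(z, L) z - L * floor(z / L)

# Per-frame circular centering: locate the densest z-window (mass
# histogram, circular moving sum), then refine with the local center of
# mass of the beads near that peak, and map it to the box center.  Using
# the windowed peak first keeps the dominant cluster centered even when
# several clusters coexist.
center_shift <- function(z, L, masses, nbins) {
  bw <- L / nbins
  zw <- wrap_coord(z, L)
  idx <- pmin(floor(zw / bw) + 1L, nbins)
  counts <- as.numeric(tapply(masses, factor(idx, levels = seq_len(nbins)),
                              sum, default = 0))
  counts[is.na(counts)] <- 0
  win <- max(3L, round(5 / bw))             # ~5 nm window
  if (win %% 2 == 0) win <- win + 1L
  sm <- stats::filter(counts, rep(1, win), circular = TRUE)
  zc <- (which.max(sm) - 0.5) * bw
  # fixed-point refinement with a smooth circular (raised-cosine) weight
  # anchored at the current center; the update commutes with periodic
  # translation, so the converged center is shift-equivariant
  for (k in 1:25) {
    d <- zw - zc
    d <- d - L * round(d / L)               # displacement in (-L/2, L/2]
    w <- masses * (1 + cos(2 * pi * d / L))
    step <- sum(w * d) / sum(w)
    zc <- zc + step
    if (abs(step) < 1e-10) break
  }
  L / 2 - zc
}

#' Density profile along the slab (z) axis
#'
#' Bins bead mass along z for every frame and averages, reporting mass
#' density in mg/mL.  With `center = TRUE` (the default) each frame is
#' first translated circularly so its densest region sits at the box
#' center, which resolves slab wrap-around before plateau analysis.
#' The standard error is estimated by block averaging over
#' `n_blocks` equal trajectory blocks.
#'
#' @param traj a `cg_trajectory` whose topology provides bead masses.
#' @param bin_width nm (default 1).
#' @param center translate the densest region to the box center.
#' @param n_blocks blocks for the SEM estimate.
#' @return a `density_profile` (axis "z").
#' @export
z_density_profile <- function(traj, bin_width = 1.0, center = TRUE,
                              n_blocks = 5L) {
  stopifnot(inherits(traj, "cg_trajectory"))
  Lz <- traj$box[3]
  if (bin_width >= Lz) stop("bin_width must be smaller than the box length")
  masses <- if (!is.null(traj$topology)) traj$topology$mass
  else rep(1, dim(traj$coords)[2])
  nbins <- max(1L, round(Lz / bin_width))
  bw <- Lz / nbins
  area <- traj$box[1] * traj$box[2]
  nf <- n_frames(traj)
  per_frame <- matrix(0, nf, nbins)
  for (f in seq_len(nf)) {
    z <- traj$coords[f, , 3]
    if (center) z <- z + center_shift(z, Lz, masses, nbins)
    z <- wrap_coord(z, Lz)
    idx <- pmin(floor(z / bw) + 1L, nbins)
    m <- as.numeric(tapply(masses, factor(idx, levels = seq_len(nbins)),
                           sum, default = 0))
    m[is.na(m)] <- 0
    per_frame[f, ] <- m / (area * bw) * GMOL_NM3_TO_MGML
  }
  vals <- colMeans(per_frame)
  nb <- min(n_blocks, nf)
  if (nb >= 2) {
    blocks <- split(seq_len(nf), cut(seq_len(nf), nb, labels = FALSE))
    bmeans <- t(vapply(blocks, function(ii)
      colMeans(per_frame[ii, , drop = FALSE]), numeric(nbins)))
    sem <- apply(bmeans, 2, stats::sd) / sqrt(nb)
    sem[is.na(sem)] <- 0
  } else {
    sem <- rep(0, nbins)
  }
  new_density_profile((seq_len(nbins) - 0.5) * bw, vals, sem, "z", bw,
                      "mg/mL", extra = list(box = traj$box,
                                            n_frames = nf,
                                            centered = center))
}

#' Radial density profile about the system center of mass
#'
#' Density versus distance from the mass-weighted center of the system,
#' normalized by spherical-shell volumes; default bin width 1 nm.
#'
#' @param traj a `cg_trajectory`.
#' @param bin_width nm.
#' @param r_max outermost radius, nm (default: half the smallest box
#'   edge).
#' @param n_blocks blocks for the SEM.
#' @return a `density_profile` (axis "radial").
#' @export
radial_density_profile <- function(traj, bin_width = 1.0, r_max = NULL,
                                   n_blocks = 5L) {
  stopifnot(inherits(traj, "cg_trajectory"))
  masses <- if (!is.null(traj$topology)) traj$topology$mass
  else rep(1, dim(traj$coords)[2])
  if (is.null(r_max)) r_max <- min(traj$box) / 2
  nbins <- max(1L, ceiling(r_max / bin_width))
  edges <- (0:nbins) * bin_width
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  nf <- n_frames(traj)
  per_frame <- matrix(0, nf, nbins)
  for (f in seq_len(nf)) {
    xyz <- matrix(traj$coords[f, , ], ncol = 3)
    com <- colSums(xyz * masses) / sum(masses)
    r <- sqrt(rowSums(sweep(xyz, 2, com)^2))
    idx <- pmin(floor(r / bin_width) + 1L, nbins)
    keep <- r < r_max
    m <- as.numeric(tapply(masses[keep],
                           factor(idx[keep], levels = seq_len(nbins)),
                           sum, default = 0))
    m[is.na(m)] <- 0
    per_frame[f, ] <- m / shell_vol * GMOL_NM3_TO_MGML
  }
  vals <- colMeans(per_frame)
  nb <- min(n_blocks, nf)
  if (nb >= 2) {
    blocks <- split(seq_len(nf), cut(seq_len(nf), nb, labels = FALSE))
    bmeans <- t(vapply(blocks, function(ii)
      colMeans(per_frame[ii, , drop = FALSE]), numeric(nbins)))
    sem <- apply(bmeans, 2, stats::sd) / sqrt(nb)
    sem[is.na(sem)] <- 0
  } else {
    sem <- rep(0, nbins)
  }
  new_density_profile(edges[-1] - bin_width / 2, vals, sem, "radial",
                      bin_width, "mg/mL",
                      extra = list(n_frames = nf))
}

#' Dilute- and dense-phase densities from a centered slab profile
#'
#' Locates the two interfaces of the central slab by fitting a symmetric
#' two-sided sigmoid (difference of tanh fronts), then averages the
#' central plateau (dense phase) and the outer plateau (dilute phase),
#' excluding a buffer around each interface midpoint.  A profile without
#' a detectable interface is returned flagged, with both densities equal
#' to the profile mean.
#'
#' @param profile a centered z `density_profile`.
#' @param buffer nm excluded on each side of each interface (default 2).
#' @param contrast_min minimum max/mean ratio below which the profile is
#'   declared single-phase.
#' @return list with `rho_l`, `rho_h`, `sem_l`, `sem_h`,
#'   `phase_separated` flag, interface half-width `z0` and the buffer
#'   used.
#' @export
coexistence_densities <- function(profile, buffer = 2.0,
                                  contrast_min = 2.0) {
  stopifnot(inherits(profile, "density_profile"))
  z <- profile$bin_center
  v <- profile$value
  s <- profile$sem
  L <- max(z) + attr(profile, "bin_width") / 2
  zc <- L / 2
  mono_sem <- function(ii) if (length(ii))
    sqrt(mean(s[ii]^2) / length(ii)) else NA_real_
  if (max(v) <= 0 || max(v) / max(mean(v), 1e-12) < contrast_min) {
    m <- mean(v)
    return(list(rho_l = m, rho_h = m, sem_l = mono_sem(seq_along(v)),
                sem_h = mono_sem(seq_along(v)), phase_separated = FALSE,
                z0 = NA_real_, buffer = buffer))
  }
  bw <- attr(profile, "bin_width")
  vmax <- max(v); vmin <- min(v)
  # robust interface guess: contiguous half-maximum width about the center
  sm <- stats::filter(v, rep(1 / 3, 3), circular = TRUE)
  half <- (max(sm) + vmin) / 2
  above <- sm > half
  ic <- which.min(abs(z - zc))
  lo <- ic
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- ic
  while (hi < length(z) && above[hi + 1]) hi <- hi + 1
  z0_half <- max(bw, (z[hi] - z[lo] + bw) / 2)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    v ~ rl + (rh - rl) / 2 * (tanh((z - (zc - z0)) / w) -
                                tanh((z - (zc + z0)) / w)),
    start = list(rl = max(vmin, 1e-6), rh = vmax, z0 = z0_half, w = 1),
    lower = c(0, 0, bw / 2, 0.05),
    upper = c(vmax, 2 * vmax, L / 2, L / 4),
    control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
  z0 <- z0_half
  wid <- 1
  if (!inherits(fit, "try-error")) {
    z0_fit <- coef(fit)[["z0"]]
    # accept the refined interface only if it stayed in a sane range
    if (z0_fit > bw / 2 && z0_fit < L / 2 - buffer &&
        abs(z0_fit - z0_half) < max(4 * bw, z0_half)) {
      z0 <- z0_fit
      wid <- coef(fit)[["w"]]
    }
  }
  # widen the exclusion zone when the interface itself is wide, so the
  # tanh tails do not leak into the plateau averages
  buf_eff <- max(buffer, 4 * wid)
  dense_idx <- which(abs(z - zc) < pmax(z0 - buf_eff, min(z0, bw)))
  dilute_idx <- which(abs(z - zc) > z0 + buf_eff)
  if (!length(dense_idx)) dense_idx <- which.max(v)
  if (!length(dilute_idx)) dilute_idx <- which.min(v)
  list(rho_l = mean(v[dilute_idx]), rho_h = mean(v[dense_idx]),
       sem_l = mono_sem(dilute_idx), sem_h = mono_sem(dense_idx),
       phase_separated = TRUE, z0 = unname(z0), buffer = buf_eff)
}

#' Construct a coexistence curve
#'
#' @param temperature K, strictly increasing.
#' @param rho_l,rho_h dilute and dense densities (any consistent
#'   concentration unit); `rho_h >= rho_l` pointwise.
#' @param sem_l,sem_h optional standard errors.
#' @param phase_separated logical vector; points flagged FALSE are
#'   excluded from critical-point fitting.
#' @return a `coexistence_curve` data.frame.
#' @export
coexistence_curve <- function(temperature, rho_l, rho_h, sem_l = NA,
                              sem_h = NA, phase_separated = TRUE) {
  stopifnot(length(temperature) == length(rho_l),
            length(rho_l) == length(rho_h))
  if (is.unsorted(temperature, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  if (any(rho_h < rho_l))
    stop("rho_h must be >= rho_l at every temperature")
  df <- data.frame(temperature = temperature, rho_l = rho_l,
                   rho_h = rho_h, sem_l = sem_l, sem_h = sem_h,
                   phase_separated = phase_separated)
  class(df) <- c("coexistence_curve", "data.frame")
  df
}

#' Fit the critical point of a coexistence curve
#'
#' Two-step fit: (1) nonlinear least squares of the order parameter
#' `rho_h - rho_l = B (1 - T/Tc)^beta` with the 3D Ising exponent
#' `beta = 0.325` held fixed, estimating the critical amplitude B and
#' critical temperature Tc; (2) with Tc from step 1 held fixed, a linear
#' rectilinear-diameter fit `(rho_h + rho_l)/2 = rho_c + C (Tc - T)`
#' giving the critical density and slope.
#'
#' @param curve a `coexistence_curve`.
#' @param beta critical exponent (fixed, not fitted).
#' @return a `critical_fit` object with methods `print`, `summary`,
#'   `coef`, `predict` and `plot`.
#' @export
fit_critical_point <- function(curve, beta = 0.325) {
  stopifnot(inherits(curve, "coexistence_curve"))
  use <- curve$phase_separated & (curve$rho_h > curve$rho_l)
  d <- curve[use, ]
  if (nrow(d) < 3)
    stop("insufficient data: need >= 3 temperatures with rho_h > rho_l")
  drho <- d$rho_h - d$rho_l
  Tv <- d$temperature
  Tmax <- max(Tv)
  Tc0 <- Tmax + 0.05 * diff(range(Tv)) + 0.5
  B0 <- max(drho) / (1 - min(Tv) / Tc0)^beta
  fit1 <- minpack.lm::nlsLM(
    drho ~ B * (1 - Tv / Tc)^beta,
    start = list(B = B0, Tc = Tc0),
    lower = c(1e-12, Tmax + 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (!fit1$convInfo$isConv)
    stop("critical-point fit did not converge: ",
         fit1$convInfo$stopMessage)
  B <- coef(fit1)[["B"]]
  Tc <- coef(fit1)[["Tc"]]
  dbar <- (d$rho_h + d$rho_l) / 2
  tdiff <- Tc - Tv
  fit2 <- stats::lm(dbar ~ tdiff)
  rho_c <- unname(coef(fit2)[1])
  C <- unname(coef(fit2)[2])
  if (is.na(C) || C <= 0)
    warning("rectilinear-diameter slope C is not positive")
  structure(list(
    coefficients = c(Tc = Tc, B = B, rho_c = rho_c, C = C),
    beta = beta,
    residual_norm = sqrt(sum(stats::resid(fit1)^2) +
                           sum(stats::resid(fit2)^2)),
    cov_order_parameter = stats::vcov(fit1),
    n_points = nrow(d),
    curve = curve,
    fits = list(order_parameter = fit1, diameter = fit2)),
    class = "critical_fit")
}

#' @export
coef.critical_fit <- function(object, ...) object$coefficients

#' @export
print.critical_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Critical-point fit (order parameter exponent beta =",
      format(x$beta), "fixed)\n")
  cat(sprintf("  Tc    = %.4f K\n  B     = %.6g\n  rho_c = %.6g\n  C     = %.6g per K\n",
              cf["Tc"], cf["B"], cf["rho_c"], cf["C"]))
  cat(sprintf("  %d coexistence points, residual norm %.3g\n",
              x$n_points, x$residual_norm))
  invisible(x)
}

#' @export
summary.critical_fit <- function(object, ...) {
  print(object)
  cat("\nOrder-parameter fit:\n")
  print(summary(object$fits$order_parameter))
  cat("Rectilinear-diameter fit:\n")
  print(summary(object$fits$diameter))
  invisible(object)
}

#' Predict binodal densities at new temperatures
#'
#' @param object a `critical_fit`.
#' @param temperature temperatures (K), each below the fitted Tc.
#' @param ... unused.
#' @return data.frame with `temperature`, `rho_l`, `rho_h`,
#'   `delta_rho`, `diameter`.
#' @export
predict.critical_fit <- function(object, temperature, ...) {
  cf <- object$coefficients
  if (any(temperature > cf["Tc"]))
    warning("temperatures above Tc: order parameter undefined, set to 0")
  drho <- ifelse(temperature >= cf["Tc"], 0,
                 cf["B"] * (1 - temperature / cf["Tc"])^object$beta)
  dbar <- cf["rho_c"] + cf["C"] * (cf["Tc"] - temperature)
  data.frame(temperature = temperature,
             rho_l = dbar - drho / 2, rho_h = dbar + drho / 2,
             delta_rho = drho, diameter = dbar)
}

#' @export
plot.critical_fit <- function(x, ...) {
  cv <- x$curve
  cf <- x$coefficients
  Ts <- seq(min(cv$temperature), cf["Tc"], length.out = 200)
  pred <- predict(x, Ts)
  graphics::plot(c(cv$rho_l, cv$rho_h), rep(cv$temperature, 2),
                 xlab = "density", ylab = "temperature (K)",
                 main = "Coexistence curve", ...)
  graphics::lines(pred$rho_l, Ts)
  graphics::lines(pred$rho_h, Ts)
  graphics::points(cf["rho_c"], cf["Tc"], pch = 8)
  invisible(x)
}

#' Chain number concentration in a box
#'
#' @param n_chains number of chains.
#' @param box edge lengths, nm.
#' @return concentration in mM.
#' @export
chain_concentration <- function(n_chains, box) {
  stopifnot(all(box > 0))
  v_litre <- prod(box) * 1e-24
  n_chains / (AVOGADRO * v_litre) * 1e3
}

#' Peak-to-mean density contrast of a profile
#'
#' Ratio of the maximum binned density to the box-average density; a
#' ratio well above 1 signals a condensed region.
#'
#' @param profile a `density_profile`.
#' @return numeric ratio.
#' @export
peak_density_ratio <- function(profile) {
  max(profile$value) / mean(profile$value)
}

#' Write a density profile or coexistence curve as TSV with metadata
#'
#' @param x a `density_profile` or `coexistence_curve`.
#' @param path output path.
#' @export
write_profile_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(axis = attr(x, "axis"), bin_width = attr(x, "bin_width"),
            units = attr(x, "units"))
  meta <- meta[!vapply(meta, is.null, TRUE)]
  for (nm in names(meta))
    writeLines(sprintf("# %s = %s", nm, meta[[nm]]), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
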