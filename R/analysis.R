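# Ion-distribution analysis around an (ideal) helical axis: radial
# concentration profiles, association counts, neutralization degree,
# PMF-scale comparisons and radial-angle maps.
#
# Helicoidal (curvilinear) coordinates are replaced by cylindrical
# coordinates about the ideal axis; valid here because all analyzed solutes
# are fixed or heavily restrained ideal models.

.traj_positions <- function(traj, frame) matrix(traj$frames[, , frame], ncol = 3)

.select_ions <- function(system, species) {
  if (is.null(species)) return(which(system$class %in% c("cation", "anion")))
  if (all(species %in% .topo_classes)) return(which(system$class %in% species))
  which(system$species %in% species)
}

.axis_coords <- function(pos, axis) {
  if (is.null(axis)) axis <- list(point = c(0, 0, 0), dir = c(0, 0, 1))
  u <- axis$dir / sqrt(sum(axis$dir^2))
  w <- sweep(pos, 2, axis$point)
  ax <- as.numeric(w %*% u)
  rad2 <- rowSums(w^2) - ax^2
  list(axial = ax, radial = sqrt(pmax(rad2, 0)))
}

#' Cylindrical ion concentration profile around a helical axis
#'
#' Time-averaged concentration c(r) of the selected ions in cylindrical
#' bins about the axis, counting only ions inside the axial slab of length
#' `h` centred on the axis point. The bulk value c(inf) is the mean
#' concentration over the `bulk_range` annulus (default 28-30 A).
#' Concentrations are reported in mol/L; binwise count bookkeeping is exact,
#' so summing c(r) times the bin volumes recovers the mean ion count inside
#' the analysis cylinder.
#'
#' @param traj a `gbion_trajectory`.
#' @param species ion selection: NULL for all ions, a vector of species
#'   labels (e.g. "NA"), or topology classes ("cation"/"anion").
#' @param axis list with `point` and `dir` (default: z axis through the
#'   origin, the fixture convention).
#' @param r_max largest radius analyzed in A.
#' @param dr radial bin width in A.
#' @param h axial slab length in A (default: the solute axial length stored
#'   by the fixture builder, or the full axial extent of the frames).
#' @param bulk_range two radii in A defining the bulk annulus.
#' @param frames optional frame subset (indices).
#' @return object of class `ion_profile`: data.frame `bins` (r_lo, r_hi,
#'   r_mid, mean_count, conc), scalar `c_inf` (mol/L), plus geometry
#'   metadata.
#' @export
cylindrical_profile <- function(traj, species = NULL, axis = NULL,
                                r_max = 30, dr = 0.5, h = NULL,
                                bulk_range = c(28, 30), frames = NULL) {
  stopifnot(inherits(traj, "gbion_trajectory"))
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  if (length(frames) < 1) stop("empty trajectory")
  idx <- .select_ions(traj$system, species)
  if (!length(idx)) stop("no particles match the requested species")
  if (is.null(h)) {
    h <- traj$system$meta$axis_length
    if (is.null(h)) h <- diff(range(traj$frames[, 3, frames])) + dr
  }
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  z_m <- numeric(length(idx))
  for (f in frames) {
    pos <- .traj_positions(traj, f)[idx, , drop = FALSE]
    cc <- .axis_coords(pos, axis)
    keep <- abs(cc$axial) <= h / 2 & cc$radial < r_max
    if (any(keep)) {
      b <- findInterval(cc$radial[keep], edges, rightmost.closed = TRUE)
      tab <- tabulate(b, nbins = nb)
      counts <- counts + tab
    }
  }
  mean_count <- counts / length(frames)
  vol <- pi * (edges[-1]^2 - edges[-(nb + 1)]^2) * h
  conc <- per_A3_to_conc(mean_count / vol)
  bins <- data.frame(r_lo = edges[-(nb + 1)], r_hi = edges[-1],
                     r_mid = (edges[-1] + edges[-(nb + 1)]) / 2,
                     mean_count = mean_count, conc = conc)
  bulk_bins <- bins$r_lo >= bulk_range[1] & bins$r_hi <= bulk_range[2]
  c_inf <- if (any(bulk_bins)) {
    per_A3_to_conc(sum(mean_count[bulk_bins]) / sum(vol[bulk_bins]))
  } else NA_real_
  structure(list(bins = bins, c_inf = c_inf, h = h,
                 geometry = "cylindrical", bulk_range = bulk_range,
                 species = species, n_frames = length(frames)),
            class = "ion_profile")
}

#' Spherical radial concentration profile around a point
#'
#' Companion of [cylindrical_profile()] for spherically symmetric systems
#' (e.g. the ion cloud around a single fixed charge).
#'
#' @inheritParams cylindrical_profile
#' @param center centre of the shells (default origin).
#' @return an `ion_profile` with `geometry = "spherical"`.
#' @export
radial_profile <- function(traj, species = NULL, center = c(0, 0, 0),
                           r_max = 30, dr = 0.5, bulk_range = c(28, 30),
                           frames = NULL) {
  stopifnot(inherits(traj, "gbion_trajectory"))
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  if (length(frames) < 1) stop("empty trajectory")
  idx <- .select_ions(traj$system, species)
  if (!length(idx)) stop("no particles match the requested species")
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  for (f in frames) {
    pos <- .traj_positions(traj, f)[idx, , drop = FALSE]
    r <- sqrt(rowSums(sweep(pos, 2, center)^2))
    keep <- r < r_max
    if (any(keep))
      counts <- counts + tabulate(findInterval(r[keep], edges,
                                               rightmost.closed = TRUE),
                                  nbins = nb)
  }
  mean_count <- counts / length(frames)
  vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  conc <- per_A3_to_conc(mean_count / vol)
  bins <- data.frame(r_lo = edges[-(nb + 1)], r_hi = edges[-1],
                     r_mid = (edges[-1] + edges[-(nb + 1)]) / 2,
                     mean_count = mean_count, conc = conc)
  bulk_bins <- bins$r_lo >= bulk_range[1] & bins$r_hi <= bulk_range[2]
  c_inf <- if (any(bulk_bins)) {
    per_A3_to_conc(sum(mean_count[bulk_bins]) / sum(vol[bulk_bins]))
  } else NA_real_
  structure(list(bins = bins, c_inf = c_inf, h = NA_real_,
                 geometry = "spherical", bulk_range = bulk_range,
                 species = species, n_frames = length(frames)),
            class = "ion_profile")
}

#' @export
print.ion_profile <- function(x, ...) {
  cat("ion_profile (", x$geometry, "): ", nrow(x$bins), " bins to ",
      max(x$bins$r_hi), " A over ", x$n_frames, " frames\n", sep = "")
  cat("  bulk c(inf) =", format(x$c_inf, digits = 4), "M over",
      paste(x$bulk_range, collapse = "-"), "A\n")
  invisible(x)
}

.bin_volumes <- function(profile) {
  b <- profile$bins
  if (profile$geometry == "cylindrical")
    pi * (b$r_hi^2 - b$r_lo^2) * profile$h
  else
    4 / 3 * pi * (b$r_hi^3 - b$r_lo^3)
}

#' Number of ions associated with the solute
#'
#' Integrates the excess concentration over the cylinder up to the bulk
#' region, N = Integral_0^R (c(r) - c(inf)) 2 pi r h dr, evaluated binwise
#' (exact for the histogram estimator of c(r)).
#'
#' @param profile a cylindrical [cylindrical_profile()].
#' @param r_cut upper integration radius in A (default: the lower edge of
#'   the bulk region).
#' @return excess ion count (can be negative for co-ions).
#' @export
ions_associated <- function(profile, r_cut = NULL) {
  stopifnot(inherits(profile, "ion_profile"))
  if (is.na(profile$c_inf) || profile$c_inf <= 0)
    stop("profile has no positive bulk concentration c(inf)")
  if (is.null(r_cut)) r_cut <- profile$bulk_range[1]
  vol <- .bin_volumes(profile)
  use <- profile$bins$r_hi <= r_cut + 1e-9
  sum(conc_to_per_A3(profile$bins$conc[use] - profile$c_inf) * vol[use])
}

#' Degree of solute charge neutralization
#'
#' 100 * (mean total ion charge within a cylindrical distance `cutoff` of
#' the axis) / |Q_solute|. The cutoff is an explicit parameter (default
#' 16 A, the outer edge of the external ion-binding shell) and is reported
#' alongside the value.
#'
#' @param traj a `gbion_trajectory`.
#' @param solute_charge solute net charge in e (default: sum over solute
#'   particles of the trajectory's system).
#' @param cutoff cylindrical radius in A.
#' @param axis as in [cylindrical_profile()].
#' @param frames optional frame subset.
#' @return list with `percent`, `cutoff`, `mean_ion_charge`.
#' @export
neutralization_degree <- function(traj, solute_charge = NULL, cutoff = 16,
                                  axis = NULL, frames = NULL) {
  stopifnot(inherits(traj, "gbion_trajectory"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  sys <- traj$system
  idx <- which(sys$class %in% c("cation", "anion"))
  if (is.null(solute_charge))
    solute_charge <- sum(sys$charge[sys$class == "solute"])
  if (length(idx) == 0 || solute_charge == 0)
    return(list(percent = 0, cutoff = cutoff, mean_ion_charge = 0))
  qi <- sys$charge[idx]
  acc <- 0
  for (f in frames) {
    cc <- .axis_coords(.traj_positions(traj, f)[idx, , drop = FALSE], axis)
    acc <- acc + sum(qi[cc$radial < cutoff])
  }
  mean_q <- acc / length(frames)
  # neutralizing charge is opposite in sign to the solute charge
  list(percent = 100 * mean_q / (-solute_charge),
       cutoff = cutoff, mean_ion_charge = mean_q)
}

#' Potential of mean force from a concentration profile
#'
#' W(r) = -ln(c(r)/c(inf)) in units of k_B T; bins with c(r) = 0 are
#' masked (NA).
#'
#' @param profile an [cylindrical_profile()] or [radial_profile()].
#' @return data.frame with `r_mid` and `W`.
#' @export
pmf_profile <- function(profile) {
  stopifnot(inherits(profile, "ion_profile"))
  if (is.na(profile$c_inf) || profile$c_inf <= 0)
    stop("profile has no positive bulk concentration c(inf)")
  W <- -log(profile$bins$conc / profile$c_inf)
  W[profile$bins$conc <= 0] <- NA_real_
  data.frame(r_mid = profile$bins$r_mid, W = W)
}

#' Compare two ion profiles on the PMF scale
#'
#' Maximum absolute PMF difference over bins where both profiles have
#' non-zero concentration, and the ratio of the areas under the first
#' concentration peak (region: the first contiguous run of bins of profile
#' `a` above its bulk value).
#'
#' @param a,b two `ion_profile`s with identical binning.
#' @return list with `max_dW` (k_B T), `peak_area_ratio`, `peak_bins`.
#' @export
profile_compare <- function(a, b) {
  stopifnot(inherits(a, "ion_profile"), inherits(b, "ion_profile"))
  if (!isTRUE(all.equal(a$bins$r_lo, b$bins$r_lo)) ||
      !isTRUE(all.equal(a$bins$r_hi, b$bins$r_hi)))
    stop("profiles must share a common binning")
  both <- a$bins$conc > 0 & b$bins$conc > 0
  if (!any(both)) stop("profiles have disjoint supports")
  Wa <- -log(a$bins$conc[both] / a$c_inf)
  Wb <- -log(b$bins$conc[both] / b$c_inf)
  max_dW <- max(abs(Wa - Wb))

  above <- a$bins$conc > a$c_inf
  first <- which(above)[1]
  if (is.na(first)) {
    peak <- integer(0); ratio <- NA_real_
  } else {
    last <- first
    while (last < nrow(a$bins) && above[last + 1]) last <- last + 1
    peak <- first:last
    va <- .bin_volumes(a)[peak]
    area_a <- sum(conc_to_per_A3(a$bins$conc[peak]) * va)
    area_b <- sum(conc_to_per_A3(b$bins$conc[peak]) * .bin_volumes(b)[peak])
    ratio <- area_a / area_b
  }
  list(max_dW = max_dW, peak_area_ratio = ratio, peak_bins = peak)
}

#' Radial-angle ion density map about the helical axis
#'
#' 2D histogram of ion positions in (radius, azimuth) where the azimuth is
#' taken relative to the local phosphate phase of an ideal helix:
#' phi_rel = phi - phase0 - twist * z / rise (mod 360). Summing the map
#' over the angle bins reproduces the 1D cylindrical profile exactly (same
#' frames, same radial bins, same slab).
#'
#' @inheritParams cylindrical_profile
#' @param n_angle number of azimuthal bins.
#' @param twist helix twist per base pair in degrees.
#' @param rise helix rise per base pair in A.
#' @param phase0 reference phase in degrees.
#' @return object of class `ion_map`: matrix `conc` (mol/L, r x angle),
#'   `mean_count`, bin edge vectors and the geometry metadata.
#' @export
radial_angle_map <- function(traj, species = NULL, axis = NULL,
                             r_max = 30, dr = 1, n_angle = 36,
                             h = NULL, twist = 36, rise = 3.4, phase0 = 0,
                             frames = NULL) {
  stopifnot(inherits(traj, "gbion_trajectory"))
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  if (length(frames) < 1) stop("empty trajectory")
  idx <- .select_ions(traj$system, species)
  if (!length(idx)) stop("no particles match the requested species")
  if (is.null(h)) {
    h <- traj$system$meta$axis_length
    if (is.null(h)) h <- diff(range(traj$frames[, 3, frames])) + dr
  }
  r_edges <- seq(0, r_max, by = dr)
  a_edges <- seq(0, 360, length.out = n_angle + 1)
  nr <- length(r_edges) - 1
  counts <- matrix(0, nr, n_angle)
  for (f in frames) {
    pos <- .traj_positions(traj, f)[idx, , drop = FALSE]
    cc <- .axis_coords(pos, axis)
    keep <- abs(cc$axial) <= h / 2 & cc$radial < r_max
    if (!any(keep)) next
    p <- pos[keep, , drop = FALSE]
    phi <- atan2(p[, 2], p[, 1]) * 180 / pi
    phi_rel <- (phi - phase0 - twist * cc$axial[keep] / rise) %% 360
    rb <- findInterval(cc$radial[keep], r_edges, rightmost.closed = TRUE)
    ab <- pmin(findInterval(phi_rel, a_edges, rightmost.closed = TRUE),
               n_angle)
    for (m in seq_along(rb)) counts[rb[m], ab[m]] <- counts[rb[m], ab[m]] + 1
  }
  mean_count <- counts / length(frames)
  vol <- (pi * (r_edges[-1]^2 - r_edges[-(nr + 1)]^2) * h) / n_angle
  conc <- per_A3_to_conc(sweep(mean_count, 1, vol, "/"))
  structure(list(conc = conc, mean_count = mean_count,
                 r_edges = r_edges, a_edges = a_edges, h = h,
                 species = species, n_frames = length(frames)),
            class = "ion_map")
}

#' Collapse a radial-angle map to the 1D radial profile
#'
#' Marginalizes an [radial_angle_map()] over the azimuth; the result matches
#' [cylindrical_profile()] computed with the same frames, bins and slab.
#'
#' @param map an `ion_map`.
#' @param bulk_range bulk annulus for c(inf).
#' @return an `ion_profile`.
#' @export
map_to_profile <- function(map, bulk_range = c(28, 30)) {
  stopifnot(inherits(map, "ion_map"))
  nr <- length(map$r_edges) - 1
  mean_count <- rowSums(map$mean_count)
  vol <- pi * (map$r_edges[-1]^2 - map$r_edges[-(nr + 1)]^2) * map$h
  conc <- per_A3_to_conc(mean_count / vol)
  bins <- data.frame(r_lo = map$r_edges[-(nr + 1)], r_hi = map$r_edges[-1],
                     r_mid = (map$r_edges[-1] + map$r_edges[-(nr + 1)]) / 2,
                     mean_count = mean_count, conc = conc)
  bulk_bins <- bins$r_lo >= bulk_range[1] & bins$r_hi <= bulk_range[2]
  c_inf <- if (any(bulk_bins)) {
    per_A3_to_conc(sum(mean_count[bulk_bins]) / sum(vol[bulk_bins]))
  } else NA_real_
  structure(list(bins = bins, c_inf = c_inf, h = map$h,
                 geometry = "cylindrical", bulk_range = bulk_range,
                 species = map$species, n_frames = map$n_frames),
            class = "ion_profile")
}

#' Profile convergence across averaging windows
#'
#' Splits the trajectory frames into non-overlapping windows of the given
#' sizes, computes a profile per window, and reports the across-window
#' variance of the binned concentrations (averaged over bins). Longer
#' averaging windows give smaller variance; the decay rate indicates how
#' fast the ion atmosphere equilibrates.
#'
#' @param traj a `gbion_trajectory`.
#' @param window_sizes frame counts per window (each must allow >= 2
#'   windows).
#' @param ... passed to [cylindrical_profile()] or [radial_profile()].
#' @param geometry "cylindrical" or "spherical".
#' @return data.frame with `window` (frames) and `variance`.
#' @export
profile_convergence <- function(traj, window_sizes, geometry = "spherical",
                                ...) {
  stopifnot(inherits(traj, "gbion_trajectory"))
  out <- data.frame(window = window_sizes, variance = NA_real_)
  for (k in seq_along(window_sizes)) {
    w <- window_sizes[k]
    nw <- traj$n_frames %/% w
    if (nw < 2) stop("window of ", w, " frames leaves fewer than 2 windows")
    mats <- sapply(seq_len(nw), function(m) {
      fr <- ((m - 1) * w + 1):(m * w)
      p <- if (geometry == "spherical") radial_profile(traj, frames = fr, ...)
           else cylindrical_profile(traj, frames = fr, ...)
      p$bins$conc
    })
    out$variance[k] <- mean(apply(mats, 1, var))
  }
  out
}
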