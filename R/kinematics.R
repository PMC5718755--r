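# Triad-based domain kinematics relative to the microtubule frame, and
# per-residue mobility statistics.

#' Build the microtubule-frame orthonormal triad
#'
#' Longitudinal direction `uL` points from the alpha- to the beta-tubulin
#' H12 center of mass; the normal `uN` is proportional to
#' `u_alpha4 x uL` (into the microtubule for the standard geometry); the
#' transverse `uT = uL x uN` completes a right-handed triad.
#'
#' @param R_alpha,R_beta centers of mass of the two tubulin H12 helices
#'   (Angstrom).
#' @param u_alpha4_ref reference alpha4 helix axis (need not be unit).
#' @return object of class `"triad"` with unit vectors `uL`, `uN`, `uT`
#'   and the stored `R_alpha_tub`, `R_beta_tub`, `u_alpha4_ref`.
#' @export
build_triad <- function(R_alpha, R_beta, u_alpha4_ref) {
  if (vnorm(R_beta - R_alpha) < 1e-9) stop("R_alpha and R_beta coincide")
  uL <- unit(R_beta - R_alpha)
  cr <- cross3(unit(u_alpha4_ref), uL)
  if (vnorm(cr) < 1e-9) stop("u_alpha4_ref is parallel to uL")
  uN <- unit(cr)
  uT <- cross3(uL, uN)
  structure(list(uL = uL, uN = uN, uT = uT,
                 R_alpha_tub = as.numeric(R_alpha),
                 R_beta_tub = as.numeric(R_beta),
                 u_alpha4_ref = unit(u_alpha4_ref)),
            class = "triad")
}

#' @export
print.triad <- function(x, ...) {
  cat("<triad>\n")
  for (nm in c("uL", "uN", "uT"))
    cat(sprintf("  %s: % .4f % .4f % .4f\n", nm, x[[nm]][1], x[[nm]][2],
                x[[nm]][3]))
  invisible(x)
}

#' Helix axis as the principal component of a Calpha set
#'
#' The axis is the direction of largest variance, sign-oriented from the
#' N-terminal to the C-terminal atom (first to last in the selection).
#'
#' @param coords `n x 3` matrix, n >= 4, in residue order.
#' @return unit 3-vector.
#' @export
helix_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stop("helix axis needs at least 4 atoms")
  cc <- sweep(coords, 2, colMeans(coords))
  v <- svd(cc)$v[, 1]
  span <- coords[nrow(coords), ] - coords[1, ]
  if (sum(v * span) < 0) v <- -v
  unit(v)
}

#' Major and normal axes of the least-square-fit plane of a point set
#'
#' `v1` is the in-plane major axis (largest variance), `v2` the plane
#' normal (smallest variance). If `reference_axes` is given, signs are
#' matched to it so the axes vary continuously along a trajectory.
#'
#' @param coords `n x 3` matrix, n >= 3 and not all collinear.
#' @param reference_axes optional list with `v1`, `v2` for sign matching.
#' @return list with unit vectors `v1` and `v2`.
#' @export
plane_axes <- function(coords, reference_axes = NULL) {
  coords <- as.matrix(coords)
  cc <- sweep(coords, 2, colMeans(coords))
  s <- svd(cc)
  if (s$d[2] < 1e-9 * max(s$d[1], 1))
    stop("degenerate point set: atoms are collinear or coincident")
  v1 <- s$v[, 1]; v2 <- s$v[, 3]
  if (!is.null(reference_axes)) {
    if (sum(v1 * reference_axes$v1) < 0) v1 <- -v1
    if (sum(v2 * reference_axes$v2) < 0) v2 <- -v2
  } else {
    span <- coords[nrow(coords), ] - coords[1, ]
    if (sum(v1 * span) < 0) v1 <- -v1
    if (v2[3] < 0) v2 <- -v2
  }
  list(v1 = unit(v1), v2 = unit(v2))
}

#' Position and orientation of a domain in the triad frame
#'
#' Projects the domain center of mass (relative to the alpha-tubulin H12
#' center) onto the triad directions; with a `reference_pose`, reports the
#' differences as the longitudinal/normal/transverse displacements
#' `dL`, `dN`, `dT`. Orientation angles (degrees):
#' * `theta_beta` — forward tilt: projection of the sheet-section major
#'   axis `v1` onto span(uL, uN), measured from uL;
#' * `phi_beta` — azimuth: projection of `v1` onto span(uL, uT), from uL;
#' * `omega_beta` — transverse tilt: projection of the sheet normal `v2`
#'   onto span(uN, uT), from uN;
#' * `phi_alpha6`, `omega_alpha6` — same construction for the alpha6 axis;
#' * `psi_alpha4` — angle between the alpha4 axis and uT.
#' With a reference pose, all angles are reported as differences wrapped to
#' (-180, 180].
#'
#' @param coords `n_atoms x 3` frame coordinates, already aligned to the
#'   H12 reference frame.
#' @param triad a [build_triad()] result.
#' @param domain_selection atom indices whose COM is tracked.
#' @param axis_selections optional list with any of `sheet_section`,
#'   `alpha4`, `alpha6` index vectors.
#' @param reference_pose a pose computed on the reference coordinates
#'   (leave NULL to create one).
#' @param match_axes axes used for sign continuity of the fitted plane
#'   axes (default: the reference pose's axes; [pose_series()] passes the
#'   previous frame's axes so orientations track continuously past 90
#'   degrees).
#' @return object of class `"domain_pose"`; when `reference_pose` is given
#'   the fields are differences from it.
#' @export
domain_pose <- function(coords, triad, domain_selection,
                        axis_selections = list(), reference_pose = NULL,
                        match_axes = NULL) {
  com <- colMeans(coords[domain_selection, , drop = FALSE])
  rel <- com - triad$R_alpha_tub
  proj <- c(L = sum(rel * triad$uL), N = sum(rel * triad$uN),
            T = sum(rel * triad$uT))
  ref_axes <- if (!is.null(match_axes)) match_axes
              else if (!is.null(reference_pose)) reference_pose$axes
              else NULL
  ang <- c(theta_beta = NA_real_, phi_beta = NA_real_, omega_beta = NA_real_,
           phi_alpha6 = NA_real_, omega_alpha6 = NA_real_,
           psi_alpha4 = NA_real_)
  axes <- list()
  if (!is.null(axis_selections$sheet_section)) {
    ax <- plane_axes(coords[axis_selections$sheet_section, , drop = FALSE],
                     ref_axes$sheet)
    axes$sheet <- ax
    ang["theta_beta"] <- plane_angle(ax$v1, triad$uL, triad$uN)
    ang["phi_beta"] <- plane_angle(ax$v1, triad$uL, triad$uT)
    ang["omega_beta"] <- plane_angle(ax$v2, triad$uN, triad$uT)
  }
  if (!is.null(axis_selections$alpha6)) {
    a6 <- helix_axis(coords[axis_selections$alpha6, , drop = FALSE])
    axes$alpha6 <- a6
    ang["phi_alpha6"] <- plane_angle(a6, triad$uL, triad$uT)
    ang["omega_alpha6"] <- plane_angle(a6, triad$uN, triad$uT)
  }
  if (!is.null(axis_selections$alpha4)) {
    a4 <- helix_axis(coords[axis_selections$alpha4, , drop = FALSE])
    axes$alpha4 <- a4
    ang["psi_alpha4"] <- deg(acos(max(-1, min(1, sum(a4 * triad$uT)))))
  }
  pose <- structure(list(dL = proj[["L"]], dN = proj[["N"]], dT = proj[["T"]],
                         angles = ang, axes = axes, is_reference = TRUE),
                    class = "domain_pose")
  if (is.null(reference_pose)) return(pose)
  pose$dL <- pose$dL - reference_pose$dL
  pose$dN <- pose$dN - reference_pose$dN
  pose$dT <- pose$dT - reference_pose$dT
  pose$angles <- wrap_angle(pose$angles - reference_pose$angles)
  pose$is_reference <- FALSE
  pose
}

#' @export
print.domain_pose <- function(x, ...) {
  lbl <- if (x$is_reference) "reference pose" else "pose (vs reference)"
  cat(sprintf("<%s> dL=%.3f dN=%.3f dT=%.3f A\n", lbl, x$dL, x$dN, x$dT))
  a <- x$angles[!is.na(x$angles)]
  if (length(a))
    cat("  ", paste(sprintf("%s=%.2f", names(a), a), collapse = "  "), "\n")
  invisible(x)
}

#' Pose time series over a trajectory
#'
#' Runs [domain_pose()] on every frame against the pose of the supplied
#' reference coordinates. Frames must already be aligned to the H12
#' reference (see [align_trajectory()]).
#'
#' @inheritParams domain_pose
#' @param traj aligned trajectory.
#' @param reference reference coordinates (default: frame 1).
#' @return data.frame with one row per frame: `frame`, `time_ns`, `dL`,
#'   `dN`, `dT` and the angle columns.
#' @export
pose_series <- function(traj, triad, domain_selection,
                        axis_selections = list(), reference = NULL) {
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  ref_pose <- domain_pose(reference, triad, domain_selection, axis_selections)
  nf <- n_frames(traj)
  prev_axes <- ref_pose$axes
  rows <- vector("list", nf)
  for (k in seq_len(nf)) {
    p <- domain_pose(frame_coords(traj, k), triad, domain_selection,
                     axis_selections, ref_pose, match_axes = prev_axes)
    prev_axes <- p$axes
    rows[[k]] <- c(dL = p$dL, dN = p$dN, dT = p$dT, p$angles)
  }
  data.frame(frame = seq_len(nf), time_ns = frame_times(traj),
             do.call(rbind, rows))
}

# Residue table (one Calpha per residue) for mobility selections.
.mobility_residues <- function(traj, selection = NULL) {
  at <- traj$atoms
  idx <- if (is.null(selection)) which(at$elety == "CA") else selection
  key <- paste(at$chain[idx], at$resno[idx])
  if (anyDuplicated(key))
    stop("mobility selections need exactly one Calpha per residue")
  list(idx = idx, chain = at$chain[idx], resno = at$resno[idx])
}

#' Per-residue mobility profile: mean displacement and RMSD
#'
#' After superposing every window frame onto the reference frame using
#' `align_selection`, reports per residue (one Calpha each):
#' * `displacement` — time-mean of the distance to the reference position
#'   (deformation);
#' * `rmsd` — by default the fluctuation about the window-mean position
#'   (RMSF-like); set `rmsd_about = "reference"` for the RMS distance to
#'   the reference position instead.
#'
#' @param traj trajectory object.
#' @param align_selection atom indices for the superposition.
#' @param window `c(start_ns, end_ns)` time window (inclusive).
#' @param reference_frame frame supplying reference positions (default 1).
#' @param residue_selection Calpha indices to profile (default: all CA).
#' @param rmsd_about `"window_mean"` (fluctuation) or `"reference"`.
#' @return data.frame: `chain`, `resno`, `displacement`, `rmsd` (Angstrom).
#' @export
mobility_profile <- function(traj, align_selection = NULL, window = NULL,
                             reference_frame = 1, residue_selection = NULL,
                             rmsd_about = c("window_mean", "reference")) {
  rmsd_about <- match.arg(rmsd_about)
  tt <- frame_times(traj)
  if (is.null(window)) window <- range(tt)
  frames <- which(tt >= window[1] & tt <= window[2])
  if (!length(frames)) stop("empty window")
  res <- .mobility_residues(traj, residue_selection)
  ref <- frame_coords(traj, reference_frame)
  nr <- length(res$idx)
  pos <- array(NA_real_, dim = c(nr, 3L, length(frames)))
  for (j in seq_along(frames)) {
    k <- frames[j]
    tf <- superpose(traj$coords[, , k], ref, align_selection)
    pos[, , j] <- apply_transform(traj$coords[res$idx, , k], tf)
  }
  refp <- ref[res$idx, , drop = FALSE]
  d_ref <- sqrt((pos[, 1, , drop = FALSE] - refp[, 1])^2 +
                (pos[, 2, , drop = FALSE] - refp[, 2])^2 +
                (pos[, 3, , drop = FALSE] - refp[, 3])^2)
  disp <- rowMeans(matrix(d_ref, nrow = nr))
  ctr <- if (rmsd_about == "window_mean")
    apply(pos, c(1, 2), mean) else refp
  dev2 <- (pos[, 1, , drop = FALSE] - ctr[, 1])^2 +
          (pos[, 2, , drop = FALSE] - ctr[, 2])^2 +
          (pos[, 3, , drop = FALSE] - ctr[, 3])^2
  rmsd <- sqrt(rowMeans(matrix(dev2, nrow = nr)))
  data.frame(chain = res$chain, resno = res$resno,
             displacement = disp, rmsd = rmsd)
}

#' Rolling mean displacement of mobile residues
#'
#' Per frame, the mean displacement from the reference frame over the
#' Calpha residues (minus `exclude_selection`) whose instantaneous
#' displacement exceeds `threshold`; frames where no residue passes yield
#' NA. The series is then smoothed with a centered rolling mean of
#' `window_ns` (converted to frames via the frame interval, truncated at
#' the edges).
#'
#' @inheritParams mobility_profile
#' @param exclude_selection atom indices excluded from the average (e.g.
#'   cover strand and neck linker).
#' @param threshold displacement cutoff in Angstrom (>= 0, default 1).
#' @param window_ns rolling-window length in ns (default 100).
#' @return data.frame: `frame`, `time_ns`, `mean_displacement`, `rolling`.
#' @export
rolling_mean_displacement <- function(traj, align_selection = NULL,
                                      exclude_selection = NULL, threshold = 1,
                                      window_ns = 100, reference_frame = 1,
                                      residue_selection = NULL) {
  if (threshold < 0) stop("threshold must be >= 0")
  res <- .mobility_residues(traj, residue_selection)
  keep <- !(res$idx %in% exclude_selection)
  idx <- res$idx[keep]
  ref <- frame_coords(traj, reference_frame)
  refp <- ref[idx, , drop = FALSE]
  nf <- n_frames(traj)
  series <- rep(NA_real_, nf)
  for (k in seq_len(nf)) {
    tf <- superpose(traj$coords[, , k], ref, align_selection)
    p <- apply_transform(traj$coords[idx, , k], tf)
    d <- sqrt(rowSums((p - refp)^2))
    pass <- d > threshold
    if (any(pass)) series[k] <- mean(d[pass])
  }
  wf <- max(1L, round(window_ns / traj$frame_interval))
  data.frame(frame = seq_len(nf), time_ns = frame_times(traj),
             mean_displacement = series,
             rolling = rolling_mean(series, wf))
}
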