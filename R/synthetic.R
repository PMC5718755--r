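# Synthetic-trajectory generators with known ground truth. These define the
# study conditions under which every analysis stage is validated; they make
# no attempt at physical realism (no force field, no excluded volume).

#' Regular xy anchor grid for sheet fixtures
#' @param n_side anchors per side (grid has `n_side^2` points).
#' @param half_extent grid spans `[-half_extent, half_extent]` Angstrom.
#' @return `n_side^2 x 2` matrix of (x, y).
#' @export
sheet_grid <- function(n_side = 7, half_extent = 3) {
  g <- seq(-half_extent, half_extent, length.out = n_side)
  as.matrix(expand.grid(x = g, y = g))
}

.quadric_z <- function(xy, a) {
  a[1] + a[2] * xy[, 1] + a[3] * xy[, 1]^2 + a[4] * xy[, 2] +
    a[5] * xy[, 1] * xy[, 2] + a[6] * xy[, 2]^2
}

#' Synthetic curved-sheet trajectory
#'
#' Places pseudo-Calpha atoms at `(x, y, z(x, y) + eps)` where `z` follows
#' the quadric `a0 + a1 x + a2 x^2 + a3 y + a4 x y + a5 y^2` with per-frame
#' coefficients, and `eps ~ Normal(0, noise_sd)` independently per atom and
#' frame (on the surface-normal coordinate only, so least-squares recovery
#' of the coefficients is unbiased). Atoms are emitted as CA of sequential
#' residues so selections work unmodified.
#'
#' @param anchor_xy `n x 2` matrix of anchor (x, y) positions (Angstrom);
#'   at least 6 anchors.
#' @param coeff_schedule numeric vector of 6 coefficients (constant over
#'   frames) or `n_frames x 6` matrix.
#' @param n_frames number of frames (defaults to rows of the schedule).
#' @param noise_sd Gaussian positional noise SD (Angstrom, >= 0).
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @param frame_interval ns between frames.
#' @return trajectory object.
#' @export
make_sheet_trajectory <- function(anchor_xy, coeff_schedule, n_frames = NULL,
                                  noise_sd = 0, seed = 1,
                                  frame_interval = 0.24) {
  anchor_xy <- as.matrix(anchor_xy)
  if (nrow(anchor_xy) < 6) stop("need at least 6 anchor points")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.vector(coeff_schedule)) {
    if (is.null(n_frames)) n_frames <- 1L
    coeff_schedule <- matrix(coeff_schedule, nrow = n_frames, ncol = 6,
                             byrow = TRUE)
  }
  coeff_schedule <- as.matrix(coeff_schedule)
  stopifnot(ncol(coeff_schedule) == 6)
  nf <- nrow(coeff_schedule)
  na <- nrow(anchor_xy)
  set.seed(seed)
  coords <- array(NA_real_, dim = c(na, 3L, nf))
  for (k in seq_len(nf)) {
    z <- .quadric_z(anchor_xy, coeff_schedule[k, ])
    if (noise_sd > 0) z <- z + rnorm(na, sd = noise_sd)
    coords[, , k] <- cbind(anchor_xy, z)
  }
  trajectory(atom_table(n = na), coords, frame_interval)
}

#' Two-state telegraph schedule
#'
#' Discrete-time two-state Markov chain: per-frame switching probabilities
#' `rate_on` (off -> on) and `rate_off` (on -> off); the initial state is
#' drawn from the stationary distribution `p_on = rate_on/(rate_on+rate_off)`.
#'
#' @param n_frames number of frames.
#' @param rate_on,rate_off per-frame switching probabilities in (0, 1].
#' @param seed RNG seed.
#' @return logical vector, TRUE = on (contact formed).
#' @export
telegraph_states <- function(n_frames, rate_on, rate_off, seed = 1) {
  stopifnot(rate_on > 0, rate_off > 0, rate_on <= 1, rate_off <= 1)
  set.seed(seed)
  p_on <- rate_on / (rate_on + rate_off)
  s <- logical(n_frames)
  s[1] <- runif(1) < p_on
  u <- runif(n_frames - 1)
  for (k in seq_len(n_frames - 1)) {
    s[k + 1] <- if (s[k]) u[k] >= rate_off else u[k] < rate_on
  }
  s
}

#' Synthetic contact-pair trajectory
#'
#' Two pseudo-residues whose key inter-atom distance follows a prescribed
#' schedule. For `kind = "hbond"` the pair is donor(N-H) / acceptor(O) and
#' the schedule sets the H...O distance; for `kind = "nonpolar"` two
#' near-neutral carbons (q = 0.1 e) sit at the scheduled distance.
#'
#' @param distance_schedule per-frame distance (Angstrom), all > 0. Either
#'   this or `telegraph` must be given.
#' @param telegraph list `(n_frames, rate_on, rate_off)` generating a
#'   two-state schedule with `d_on` when formed, `d_off` when broken.
#' @param kind `"hbond"` or `"nonpolar"`.
#' @param d_on,d_off distances used for telegraph states (Angstrom).
#' @param seed RNG seed (telegraph only).
#' @param frame_interval ns between frames.
#' @return trajectory with sidecar-style annotations already set.
#' @export
make_contact_trajectory <- function(distance_schedule = NULL, telegraph = NULL,
                                    kind = c("hbond", "nonpolar"),
                                    d_on = 2.0, d_off = 5.0, seed = 1,
                                    frame_interval = 0.24) {
  kind <- match.arg(kind)
  if (is.null(distance_schedule)) {
    if (is.null(telegraph)) stop("give distance_schedule or telegraph")
    st <- telegraph_states(telegraph$n_frames, telegraph$rate_on,
                           telegraph$rate_off, seed = seed)
    distance_schedule <- ifelse(st, d_on, d_off)
  }
  if (any(distance_schedule <= 0)) stop("distances must be > 0")
  nf <- length(distance_schedule)
  if (kind == "hbond") {
    # atoms: 1 = donor N, 2 = donor H (at origin), 3 = acceptor O
    atoms <- atom_table(n = 3, elety = c("N", "HN", "O"),
                        element = c("N", "H", "O"),
                        resno = c(1L, 1L, 2L), resid = c("ASN", "ASN", "SER"),
                        charge = c(-0.47, 0.31, -0.51),
                        is_donor = c(TRUE, FALSE, FALSE),
                        donor_h = c("2", "", ""),
                        is_acceptor = c(FALSE, FALSE, TRUE))
    fixed <- rbind(c(-1, 0, 0), c(0, 0, 0))
    coords <- array(NA_real_, dim = c(3L, 3L, nf))
    for (k in seq_len(nf))
      coords[, , k] <- rbind(fixed, c(distance_schedule[k], 0, 0))
  } else {
    atoms <- atom_table(n = 2, elety = c("CB", "CB"), element = c("C", "C"),
                        resno = c(1L, 2L), resid = c("ALA", "VAL"),
                        charge = c(0.1, 0.1))
    coords <- array(NA_real_, dim = c(2L, 3L, nf))
    for (k in seq_len(nf))
      coords[, , k] <- rbind(c(0, 0, 0), c(distance_schedule[k], 0, 0))
  }
  trajectory(atoms, coords, frame_interval)
}

#' Synthetic hydration trajectory
#'
#' A fixed box is spanned by two corner reference atoms. Each hotspot is a
#' grid cell (given the grid `spacing` and the box origin at the lower
#' corner) whose water oxygen is present with probability `presence_prob`
#' per frame, placed at the cell center; when absent the water is parked
#' far outside the box. Background waters are uniform in the box each frame.
#'
#' @param box_extent box edge lengths, length-3 (Angstrom).
#' @param hotspot_cells integer matrix `m x 3` of cell indices (1-based).
#' @param presence_prob per-hotspot presence probability, recycled.
#' @param n_background_waters uniform waters per frame.
#' @param n_frames number of frames.
#' @param spacing grid cell size (Angstrom).
#' @param seed RNG seed.
#' @param frame_interval ns between frames.
#' @return trajectory; atoms 1-2 are the corner CA markers, the rest are
#'   water oxygens (`is_water_oxygen` set).
#' @export
make_hydration_trajectory <- function(box_extent = c(7, 7, 7),
                                      hotspot_cells, presence_prob = 1,
                                      n_background_waters = 0, n_frames = 100,
                                      spacing = 0.7, seed = 1,
                                      frame_interval = 0.24) {
  hotspot_cells <- matrix(as.integer(hotspot_cells), ncol = 3)
  m <- nrow(hotspot_cells)
  presence_prob <- rep_len(presence_prob, m)
  stopifnot(all(presence_prob >= 0), all(presence_prob <= 1))
  nw <- m + n_background_waters
  atoms <- rbind(
    atom_table(n = 2, elety = "CA", resno = 1:2, resid = "GLY", chain = "A"),
    atom_table(n = nw, elety = "OH2", element = "O", resno = seq_len(nw),
               resid = "TIP3", chain = "W", is_water_oxygen = TRUE)
  )
  atoms$index <- seq_len(nrow(atoms))
  corners <- rbind(c(0, 0, 0), box_extent)
  centers <- sweep(hotspot_cells - 0.5, 2, c(spacing, spacing, spacing), "*")
  park <- matrix(rep(c(1e4, 1e4, 1e4), m), ncol = 3, byrow = TRUE)
  set.seed(seed)
  coords <- array(NA_real_, dim = c(2L + nw, 3L, n_frames))
  for (k in seq_len(n_frames)) {
    present <- runif(m) < presence_prob
    hot <- ifelse(matrix(rep(present, 3), ncol = 3), centers, park)
    bg <- if (n_background_waters > 0)
      matrix(runif(3 * n_background_waters), ncol = 3) %*% diag(box_extent)
    else NULL
    coords[, , k] <- rbind(corners, hot, bg)
  }
  trajectory(atoms, coords, frame_interval)
}

#' Synthetic rigid-motion trajectory
#'
#' A rigid body follows a prescribed per-frame translation and rotation
#' exactly; optional static anchor atoms (e.g. triad markers) are appended
#' unchanged. Frame k coordinates are `R_k %*% (x - c) + c + t_k` with `c`
#' the body centroid, so rotations are about the body center.
#'
#' @param body_points `n x 3` matrix of body coordinates at frame 1.
#' @param translation_schedule `n_frames x 3` matrix of translations
#'   (Angstrom), or NULL for none.
#' @param rotation_schedule list of 3x3 proper rotations, or NULL.
#' @param static_points optional `m x 3` matrix of immobile atoms, appended
#'   after the body.
#' @param frame_interval ns between frames.
#' @return trajectory of CA pseudo-atoms (body = chain "A", static = "S").
#' @export
make_rigid_motion_trajectory <- function(body_points, translation_schedule = NULL,
                                         rotation_schedule = NULL,
                                         static_points = NULL,
                                         frame_interval = 0.24) {
  body_points <- as.matrix(body_points)
  nf <- if (!is.null(translation_schedule)) nrow(translation_schedule)
        else length(rotation_schedule)
  if (is.null(nf) || nf < 1) stop("need a translation or rotation schedule")
  if (is.null(translation_schedule))
    translation_schedule <- matrix(0, nrow = nf, ncol = 3)
  ctr <- colMeans(body_points)
  nb <- nrow(body_points)
  ns <- if (is.null(static_points)) 0L else nrow(static_points)
  atoms <- atom_table(n = nb + ns, elety = "CA", resno = seq_len(nb + ns),
                      chain = rep(c("A", "S"), c(nb, max(ns, 0L)))[seq_len(nb + ns)])
  coords <- array(NA_real_, dim = c(nb + ns, 3L, nf))
  for (k in seq_len(nf)) {
    R <- if (is.null(rotation_schedule)) diag(3) else rotation_schedule[[k]]
    if (abs(det(R) - 1) > 1e-9) stop("rotation schedule must be proper")
    b <- sweep(sweep(body_points, 2, ctr) %*% t(R), 2,
               ctr + translation_schedule[k, ], "+")
    coords[, , k] <- rbind(b, static_points)
  }
  trajectory(atoms, coords, frame_interval)
}

#' Rotation matrix about an axis
#' @param axis length-3 vector (normalized internally).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Synthetic phosphate-like fragment
#'
#' Builds a two-phosphate fragment (PB, three beta oxygens, bridging O3B,
#' PG, three gamma oxygens) whose beta/gamma oxygen triples sit at 120
#' degree spacing about the PB-PG axis, the gamma triple offset by the
#' requested torsion: 0 = eclipsed, 60 = staggered. Multiple torsions give
#' one frame each. Optionally adds an Mg ion placed equidistant (2.0 A)
#' from either one beta + one gamma oxygen (`"bidentate"`) or one beta +
#' two gamma oxygens (`"tridentate"`).
#'
#' @param phi_gamma_deg torsion(s) in degrees, each within \[0, 60\].
#' @param obeta_pgamma_length O3B-PG bond length (Angstrom).
#' @param mg `"none"`, `"bidentate"` or `"tridentate"`.
#' @param frame_interval ns between frames.
#' @return trajectory; atom names PB, O1B, O2B, O3A (non-axis beta
#'   oxygens), O3B (bridge), PG, O1G, O2G, O3G (+ MG).
#' @export
make_phosphate_fragment <- function(phi_gamma_deg, obeta_pgamma_length = 1.586,
                                    mg = c("none", "bidentate", "tridentate"),
                                    frame_interval = 0.24) {
  mg <- match.arg(mg)
  if (any(phi_gamma_deg < 0 | phi_gamma_deg > 60))
    stop("phi_gamma_deg must lie in [0, 60]")
  nf <- length(phi_gamma_deg)
  d_po <- 1.48      # terminal P-O bond
  tilt <- rad(110)  # angle of terminal P-O from the P-P axis
  pb <- c(0, 0, 0)
  o3b <- c(1.60, 0, 0)
  pg <- c(1.60 + obeta_pgamma_length, 0, 0)
  ring <- function(origin, axis_sign, azimuths_deg) {
    t(vapply(azimuths_deg, function(a) {
      origin + d_po * c(axis_sign * cos(tilt),
                        sin(tilt) * cos(rad(a)), sin(tilt) * sin(rad(a)))
    }, numeric(3)))
  }
  # O1B/O2B/O3A: the three non-axis beta oxygens; O3B: the bridging oxygen.
  names <- c("PB", "O1B", "O2B", "O3A", "O3B", "PG", "O1G", "O2G", "O3G")
  has_mg <- mg != "none"
  if (has_mg) names <- c(names, "MG")
  atoms <- atom_table(n = length(names), elety = names,
                      element = c("P", "O", "O", "O", "O", "P", "O", "O", "O",
                                  if (has_mg) "MG"),
                      resno = 1L, resid = "ATP", chain = "X")
  coords <- array(NA_real_, dim = c(length(names), 3L, nf))
  for (k in seq_len(nf)) {
    ob <- ring(pb, -1, c(0, 120, 240))
    og <- ring(pg, +1, phi_gamma_deg[k] + c(0, 120, 240))
    pts <- rbind(pb, ob, o3b, pg, og)
    if (has_mg) {
      # coordinate the gamma oxygens nearest the chosen beta oxygen
      d_og <- sqrt(rowSums(sweep(og, 2, ob[1, ])^2))
      near <- order(d_og)
      targets <- if (mg == "bidentate") rbind(ob[1, ], og[near[1], ])
                 else rbind(ob[1, ], og[near[1], ], og[near[2], ])
      pts <- rbind(pts, .place_equidistant(targets, 2.0, pts))
    }
    coords[, , k] <- pts
  }
  trajectory(atoms, coords, frame_interval)
}

# Point at exact distance d from each of 2 or 3 target atoms, placed on
# the side away from `others` (sphere-intersection / trilateration).
.place_equidistant <- function(targets, d, others) {
  away <- colMeans(targets) - colMeans(others)
  if (nrow(targets) == 2) {
    axis <- targets[2, ] - targets[1, ]
    half <- vnorm(axis) / 2
    if (half >= d) stop("targets too far apart for the requested distance")
    mid <- colMeans(targets)
    perp <- away - sum(away * unit(axis)) * unit(axis)
    if (vnorm(perp) < 1e-9) perp <- cross3(axis, c(0, 0, 1))
    return(mid + sqrt(d^2 - half^2) * unit(perp))
  }
  # three spheres of equal radius d
  p1 <- targets[1, ]; p2 <- targets[2, ]; p3 <- targets[3, ]
  ex <- unit(p2 - p1)
  i <- sum(ex * (p3 - p1))
  ey <- unit(p3 - p1 - i * ex)
  ez <- cross3(ex, ey)
  dd <- vnorm(p2 - p1)
  j <- sum(ey * (p3 - p1))
  x <- dd / 2
  y <- (i^2 + j^2 - 2 * i * x) / (2 * j)
  z2 <- d^2 - x^2 - y^2
  if (z2 < 0) stop("targets too far apart for the requested distance")
  base <- p1 + x * ex + y * ey
  cand <- rbind(base + sqrt(z2) * ez, base - sqrt(z2) * ez)
  cand[which.max(c(sum((cand[1, ] - colMeans(others))^2),
                   sum((cand[2, ] - colMeans(others))^2))), ]
}
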