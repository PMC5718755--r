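# Quadric fitting of the central beta-sheet, curvature time series, and
# 2-D free-energy landscapes over (M^2, G) with count-weighted merging.

#' Least-squares quadric surface fit
#'
#' Fits `z(x, y) = a0 + a1 x + a2 x^2 + a3 y + a4 x y + a5 y^2` to a set of
#' points by linear least squares. Units: a0 in Angstrom, a1/a3
#' dimensionless, a2/a4/a5 in 1/Angstrom.
#'
#' @param points `n x 3` matrix of (x, y, z), n >= 6.
#' @return object of class `"quadric_fit"`: named coefficients `a0..a5`,
#'   `residual_rms` (Angstrom) and `n`.
#' @export
fit_quadric <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 6) stop("need at least 6 points")
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  X <- cbind(1, x, x^2, y, x * y, y^2)
  qr_x <- qr(X)
  if (qr_x$rank < 6L)
    stop("rank-deficient design: points are degenerate in the xy-plane")
  a <- qr.coef(qr_x, z)
  res <- z - as.numeric(X %*% a)
  structure(list(coefficients = setNames(as.numeric(a),
                                         paste0("a", 0:5)),
                 residual_rms = sqrt(mean(res^2)), n = nrow(points)),
            class = "quadric_fit")
}

#' @export
print.quadric_fit <- function(x, ...) {
  cat("<quadric fit> z = a0 + a1 x + a2 x^2 + a3 y + a4 xy + a5 y^2\n")
  print(round(x$coefficients, 6))
  cat(sprintf("residual RMS: %.4g A over %d points\n", x$residual_rms, x$n))
  invisible(x)
}

#' Mean and Gaussian curvature of a fitted quadric
#'
#' Computed from the fit coefficients as `M = 2 (a2 + a5)` (1/Angstrom) and
#' `G = a4^2 - 4 a2 a5` (1/Angstrom^2). Note this `G` is the negative of
#' the differential-geometry Gaussian curvature of the graph surface at a
#' critical point: it is positive for saddles and negative for bowls. The
#' convention is kept as such ("saddle-point curvature"); see the vignette.
#'
#' @param fit a `quadric_fit` (or a numeric vector `a0..a5`).
#' @return list with `M`, `G` and `M_sq = M^2`.
#' @export
curvature <- function(fit) {
  a <- if (inherits(fit, "quadric_fit")) fit$coefficients else fit
  M <- 2 * (a[["a2"]] + a[["a5"]])
  G <- a[["a4"]]^2 - 4 * a[["a2"]] * a[["a5"]]
  list(M = M, G = G, M_sq = M^2)
}

#' Canonicalize a reference sheet: least-squares plane to xy, COM to origin
#'
#' Rotates the coordinates so the least-square-fit plane of the point set
#' lies in the xy-plane (plane normal along +z, major axis along +x) and
#' translates the center of mass to the origin. Curvature series computed
#' against this canonical reference are then reproducible from any starting
#' pose.
#'
#' @param coords `n x 3` coordinate matrix.
#' @return list with canonical `coords` and the `transform` applied.
#' @export
canonicalize_reference <- function(coords) {
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  s <- svd(cc)
  V <- s$v  # columns: major, minor, normal directions
  if (det(V) < 0) V[, 3] <- -V[, 3]
  R <- t(V)  # maps major -> x, minor -> y, normal -> z
  tf <- rigid_transform(R, -as.numeric(R %*% ctr))
  list(coords = apply_transform(coords, tf), transform = tf)
}

#' Per-frame curvature of a sheet selection
#'
#' For every frame: superpose the sheet atoms onto the (canonical)
#' reference, fit the quadric to the transformed coordinates, and compute
#' mean and Gaussian curvature. The reference must be canonicalized
#' (least-square plane in xy, COM at origin), or pass
#' `canonicalize = TRUE` to do it here.
#'
#' @param traj trajectory object.
#' @param sheet_selection atom indices of the sheet Calpha set.
#' @param reference `n_sel x 3` reference coordinates of the same atoms
#'   (default: frame 1 of `traj`).
#' @param canonicalize canonicalize the reference first (default TRUE).
#' @return data.frame with one row per frame: `frame`, `time_ns`, `a0..a5`,
#'   `residual_rms`, `M`, `G`, `M_sq`.
#' @export
curvature_series <- function(traj, sheet_selection = NULL, reference = NULL,
                             canonicalize = TRUE) {
  if (is.null(sheet_selection)) sheet_selection <- seq_len(n_atoms(traj))
  if (is.null(reference))
    reference <- frame_coords(traj, 1)[sheet_selection, , drop = FALSE]
  if (canonicalize) reference <- canonicalize_reference(reference)$coords
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nrow = nf, ncol = 10,
                dimnames = list(NULL, c(paste0("a", 0:5), "residual_rms",
                                        "M", "G", "M_sq")))
  for (k in seq_len(nf)) {
    sheet <- traj$coords[sheet_selection, , k, drop = TRUE]
    tf <- superpose(sheet, reference)
    fit <- fit_quadric(apply_transform(sheet, tf))
    cv <- curvature(fit)
    out[k, ] <- c(fit$coefficients, fit$residual_rms, cv$M, cv$G, cv$M_sq)
  }
  data.frame(frame = seq_len(nf), time_ns = frame_times(traj), out)
}

#' Build a 2-D free-energy landscape over (M^2, G)
#'
#' Histograms the samples, normalizes counts by the maximum count to get
#' the density `rho`, and sets the free energy `E = -kBT * ln(rho)` so the
#' most occupied bin sits at exactly 0. Empty bins carry `+Inf`.
#'
#' @param msq,g numeric sample vectors (M^2 in 1/A^2, G in 1/A^2), equal
#'   length; alternatively pass a `curvature_series()` data.frame as `msq`.
#' @param msq_edges,g_edges bin boundaries; default `n_bins` equal-width
#'   bins spanning the sample range.
#' @param n_bins default bin count per axis when edges are not given.
#' @param kBT thermal energy unit (energies are reported in kBT).
#' @return object of class `"pmf_grid"`: `msq_edges`, `g_edges`, `counts`,
#'   `rho`, `energy` (matrices, M^2 on rows), `kBT`, `n_samples`.
#' @export
build_pmf <- function(msq, g = NULL, msq_edges = NULL, g_edges = NULL,
                      n_bins = 30, kBT = 1) {
  if (is.data.frame(msq)) {
    g <- msq$G
    msq <- msq$M_sq
  }
  stopifnot(length(msq) == length(g), length(msq) >= 1)
  if (is.null(msq_edges)) msq_edges <- .spread_edges(msq, n_bins)
  if (is.null(g_edges)) g_edges <- .spread_edges(g, n_bins)
  ix <- findInterval(msq, msq_edges, rightmost.closed = TRUE)
  iy <- findInterval(g, g_edges, rightmost.closed = TRUE)
  nx <- length(msq_edges) - 1L
  ny <- length(g_edges) - 1L
  keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  if (!any(keep)) stop("all samples fall outside the bin range")
  counts <- matrix(0L, nx, ny)
  tt <- table(factor(ix[keep], levels = seq_len(nx)),
              factor(iy[keep], levels = seq_len(ny)))
  counts[] <- as.integer(tt)
  rho <- counts / max(counts)
  energy <- -kBT * log(rho)  # empty bins -> +Inf
  structure(list(msq_edges = msq_edges, g_edges = g_edges, counts = counts,
                 rho = rho, energy = energy, kBT = kBT,
                 n_samples = sum(keep)),
            class = "pmf_grid")
}

.spread_edges <- function(x, n_bins) {
  r <- range(x)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = n_bins + 1L)
}

#' @export
print.pmf_grid <- function(x, ...) {
  occ <- sum(x$counts > 0)
  cat(sprintf("<pmf grid: %d x %d bins, %d occupied, %d samples, kBT = %g>\n",
              nrow(x$counts), ncol(x$counts), occ, x$n_samples, x$kBT))
  invisible(x)
}

#' Merge two free-energy landscapes on a shared grid
#'
#' Finds the constant shift `Delta` to add to landscape `b` so the
#' count-weighted mean-square difference over the jointly occupied bins is
#' minimized: `Delta = sum(rho_a rho_b (E_a - E_b)) / sum(rho_a rho_b)`.
#' The merged energy in an overlap bin is the rho-weighted average
#' `(rho_a E_a + rho_b (E_b + Delta)) / (rho_a + rho_b)`; bins occupied in
#' only one landscape keep that landscape's energy (shifted by `Delta` for
#' `b`).
#'
#' @param a,b `pmf_grid` objects on identical bin edges.
#' @return object of class `"pmf_merge"`: `delta` (kBT), `energy` matrix,
#'   `overlap` logical matrix, plus the shared edges.
#' @export
merge_pmfs <- function(a, b) {
  if (!isTRUE(all.equal(a$msq_edges, b$msq_edges)) ||
      !isTRUE(all.equal(a$g_edges, b$g_edges)))
    stop("landscapes must share identical bin edges")
  occ_a <- is.finite(a$energy)
  occ_b <- is.finite(b$energy)
  overlap <- occ_a & occ_b
  if (!any(overlap)) stop("no overlapping occupied bins; cannot merge")
  w <- a$rho[overlap] * b$rho[overlap]
  delta <- sum(w * (a$energy[overlap] - b$energy[overlap])) / sum(w)
  energy <- matrix(Inf, nrow(a$energy), ncol(a$energy))
  energy[occ_a] <- a$energy[occ_a]
  energy[occ_b] <- b$energy[occ_b] + delta
  energy[overlap] <- (a$rho[overlap] * a$energy[overlap] +
                      b$rho[overlap] * (b$energy[overlap] + delta)) /
                     (a$rho[overlap] + b$rho[overlap])
  structure(list(delta = delta, energy = energy, overlap = overlap,
                 msq_edges = a$msq_edges, g_edges = a$g_edges,
                 kBT = a$kBT),
            class = "pmf_merge")
}

#' @export
print.pmf_merge <- function(x, ...) {
  cat(sprintf("<merged pmf: delta = %.4f kBT, %d overlap bins>\n",
              x$delta, sum(x$overlap)))
  invisible(x)
}

#' Export a landscape as CSV (long format), with an optional JSON header
#'
#' One row per bin with bin centers, counts/rho where available, and
#' energy. For merged landscapes a JSON sidecar carries `delta` and the
#' bin edges.
#'
#' @param pmf a `pmf_grid` or `pmf_merge`.
#' @param csv_path output CSV path.
#' @param json_path optional JSON header path (recommended for merges).
#' @export
write_pmf <- function(pmf, csv_path, json_path = NULL) {
  xc <- (head2(pmf$msq_edges) + tail2(pmf$msq_edges)) / 2
  yc <- (head2(pmf$g_edges) + tail2(pmf$g_edges)) / 2
  grid <- expand.grid(msq = xc, g = yc)
  df <- data.frame(grid, energy = as.vector(pmf$energy))
  if (!is.null(pmf$counts)) {
    df$counts <- as.vector(pmf$counts)
    df$rho <- as.vector(pmf$rho)
  }
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    hdr <- list(msq_edges = pmf$msq_edges, g_edges = pmf$g_edges,
                kBT = pmf$kBT)
    if (!is.null(pmf$delta)) hdr$delta <- pmf$delta
    jsonlite::write_json(hdr, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1]
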