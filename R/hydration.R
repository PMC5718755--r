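# Water-density grids with MRC export and blob segmentation, Shrake-Rupley
# solvent-accessible surface area, buried interface area, and two-water
# bridge counting.

#' Time-averaged water-density grid
#'
#' Frames are superposed onto the reference via `ref_selection`; a fixed
#' search box is taken as the bounding box of the reference-domain atoms
#' padded by `padding` on every side, divided into cubic cells of
#' `spacing` (0.7 Angstrom default). The per-cell statistic is the fraction
#' of frames in which at least one water oxygen falls in the cell, divided
#' by the cell volume (units 1/Angstrom^3); `count_mode = TRUE` instead
#' averages the number of water oxygens per frame per cell volume.
#'
#' @param traj trajectory with `is_water_oxygen` flags.
#' @param ref_selection atom indices defining both the alignment and the
#'   box domain (NULL: no alignment, box from all non-water atoms).
#' @param reference reference coordinates (default: frame 1).
#' @param padding box padding in Angstrom (default 15).
#' @param spacing cubic cell edge in Angstrom (default 0.7).
#' @param box optional explicit box as `list(origin=, dims=)` overriding
#'   the padded bounding box.
#' @param count_mode use mean water count instead of binary presence.
#' @param align superpose frames onto the reference first (default TRUE
#'   when `ref_selection` is given; the selection needs >= 3 non-collinear
#'   atoms). With `align = FALSE` the selection only defines the box.
#' @return object of class `"density_grid"`: `origin` (A), `spacing`,
#'   `dims`, `values` (3-D array, 1/A^3), `n_frames`.
#' @export
water_density_map <- function(traj, ref_selection = NULL, reference = NULL,
                              padding = 15, spacing = 0.7, box = NULL,
                              count_mode = FALSE,
                              align = !is.null(ref_selection)) {
  waters <- which(traj$atoms$is_water_oxygen)
  if (!length(waters)) stop("no water oxygens flagged in the topology")
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  if (is.null(box)) {
    dom <- if (align) ref_selection else which(!traj$atoms$is_water_oxygen)
    bb <- reference[dom, , drop = FALSE]
    origin <- apply(bb, 2, min) - padding
    dims <- pmax(1L, as.integer(ceiling((apply(bb, 2, max) + padding - origin) /
                                          spacing)))
  } else {
    origin <- box$origin
    dims <- as.integer(box$dims)
  }
  nf <- n_frames(traj)
  acc <- array(0, dim = dims)
  for (k in seq_len(nf)) {
    fc <- frame_coords(traj, k)
    if (align) fc <- apply_transform(fc, superpose(fc, reference, ref_selection))
    w <- fc[waters, , drop = FALSE]
    ci <- floor(sweep(w, 2, origin) / spacing) + 1L
    inside <- ci[, 1] >= 1 & ci[, 1] <= dims[1] &
              ci[, 2] >= 1 & ci[, 2] <= dims[2] &
              ci[, 3] >= 1 & ci[, 3] <= dims[3]
    ci <- ci[inside, , drop = FALSE]
    if (!nrow(ci)) next
    lin <- ci[, 1] + dims[1] * (ci[, 2] - 1L) + dims[1] * dims[2] * (ci[, 3] - 1L)
    if (count_mode) {
      tb <- table(lin)
      acc[as.integer(names(tb))] <- acc[as.integer(names(tb))] + as.integer(tb)
    } else {
      acc[unique(lin)] <- acc[unique(lin)] + 1
    }
  }
  structure(list(origin = as.numeric(origin), spacing = spacing, dims = dims,
                 values = acc / nf / spacing^3, n_frames = nf),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density grid %d x %d x %d, %.2f A cells, %d frames, max %.3f A^-3>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$n_frames,
              max(x$values)))
  invisible(x)
}

#' Segment a density grid into blobs above a cutoff
#'
#' Cells with density above `k * bulk` (bulk water number density 0.0333
#' 1/Angstrom^3 by default) are grouped into connected components under
#' 26-neighbor connectivity.
#'
#' @param grid a `density_grid`.
#' @param k cutoff multiple of the bulk density (> 0; 3 highlights
#'   high-probability hydration sites).
#' @param bulk bulk water density in 1/Angstrom^3.
#' @return data.frame with one row per blob: `blob`, `n_cells`,
#'   `volume` (A^3), density-weighted centroid `x`, `y`, `z` (A), and
#'   `max_density`; zero rows when nothing exceeds the cutoff.
#' @export
threshold_blobs <- function(grid, k = 3, bulk = 0.0333) {
  if (k <= 0) stop("k must be > 0")
  mask <- grid$values > k * bulk
  idx <- which(mask)
  empty <- data.frame(blob = integer(0), n_cells = integer(0),
                      volume = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), max_density = numeric(0))
  if (!length(idx)) return(empty)
  dims <- grid$dims
  coord <- arrayInd(idx, dims)
  lookup <- new.env(parent = emptyenv())
  for (r in seq_along(idx)) assign(as.character(idx[r]), r, lookup)
  label <- integer(length(idx))
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  for (r in seq_along(idx)) {
    if (label[r] > 0L) next
    cur <- cur + 1L
    queue <- r
    label[r] <- cur
    while (length(queue)) {
      q <- queue[[1L]]; queue <- queue[-1L]
      for (s in seq_len(nrow(nb))) {
        cc <- coord[q, ] + nb[s, ]
        if (any(cc < 1L) || any(cc > dims)) next
        li <- as.character(cc[1] + dims[1] * (cc[2] - 1L) +
                           dims[1] * dims[2] * (cc[3] - 1L))
        if (!exists(li, lookup)) next
        rr <- get(li, lookup)
        if (label[rr] == 0L) {
          label[rr] <- cur
          queue <- c(queue, rr)
        }
      }
    }
  }
  centers <- sweep((coord - 0.5) * grid$spacing, 2, grid$origin, "+")
  vals <- grid$values[idx]
  out <- lapply(seq_len(cur), function(b) {
    sel <- label == b
    w <- vals[sel] / sum(vals[sel])
    data.frame(blob = b, n_cells = sum(sel),
               volume = sum(sel) * grid$spacing^3,
               x = sum(centers[sel, 1] * w), y = sum(centers[sel, 2] * w),
               z = sum(centers[sel, 3] * w), max_density = max(vals[sel]))
  })
  do.call(rbind, out)
}

# ------------------------------------------------------------- MRC I/O ----

#' Write a density grid as an MRC2014 volume (mode 2, float32)
#'
#' Little-endian MRC2014 with unit cell = dims * spacing, axis order
#' x fastest, and the grid origin stored in the ORIGIN header words.
#'
#' @param grid a `density_grid`.
#' @param path output file path.
#' @export
write_mrc <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- as.integer(grid$dims)
  v <- as.numeric(grid$values)
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(dims)                    # NX NY NZ
  wi(2L)                      # MODE 2 = float32
  wi(c(0L, 0L, 0L))           # NXSTART..
  wi(dims)                    # MX MY MZ
  wf(dims * grid$spacing)     # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(c(1L, 2L, 3L))           # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))               # ISPG NSYMBT
  wi(rep(0L, 2L))             # EXTRA words 26-27
  writeBin(charToRaw("MRCO"), con)   # EXTTYP
  wi(20140L)                  # NVERSION
  wi(rep(0L, 21L))            # EXTRA words 29-49
  wf(grid$origin)             # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(v))                   # RMS
  wi(0L)                      # NLABL
  writeBin(raw(800L), con)    # labels
  wf(v)
  invisible(path)
}

#' Read an MRC2014 mode-2 volume into a density grid
#' @param path MRC file path.
#' @return a `density_grid` (spacing from CELLA/MX; must be cubic cells).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("only MRC mode 2 (float32) is supported")
  ri(3)                       # NXSTART
  m <- ri(3)                  # MX MY MZ
  cella <- rf(3)
  rf(3)                       # CELLB
  mapcrs <- ri(3)
  if (!all(mapcrs == 1:3)) stop("malformed header: unsupported axis order")
  rf(3); ri(2); ri(2)
  readBin(con, "raw", 4)      # EXTTYP
  ri(1)                       # NVERSION
  ri(21)
  origin <- rf(3)
  map_id <- rawToChar(readBin(con, "raw", 4))
  if (map_id != "MAP ") stop("malformed header: missing MAP identifier")
  readBin(con, "raw", 4)      # MACHST
  rf(1)                       # RMS
  ri(1)                       # NLABL
  readBin(con, "raw", 800)
  spacing <- cella / m
  if (max(abs(spacing - spacing[1])) > 1e-5) stop("non-cubic cells")
  v <- rf(prod(dims))
  structure(list(origin = origin, spacing = spacing[1], dims = dims,
                 values = array(v, dim = dims), n_frames = NA_integer_),
            class = "density_grid")
}

# ---------------------------------------------------------------- SASA ----

# Deterministic quasi-uniform unit-sphere points (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, quasi-uniform points are placed on a sphere of radius
#' `vdw + probe`; the accessible fraction (points not inside any
#' neighbor's expanded sphere) times the sphere area gives the per-atom
#' SASA.
#'
#' @param coords `n x 3` coordinates (Angstrom).
#' @param radii per-atom van der Waals radii (Angstrom, > 0).
#' @param probe probe radius (default 1.4 Angstrom, water).
#' @param n_points sphere points per atom (default 960).
#' @return object of class `"sasa_result"`: `per_atom` (A^2), `total`,
#'   `probe`, `n_points`.
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  radii <- rep_len(radii, n)
  if (any(radii <= 0)) stop("radii must be > 0")
  sph <- fibonacci_sphere(n_points)
  rext <- radii + probe
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(coords) - coords[i, ])^2))
    nbr <- which(di < rext[i] + rext & seq_len(n) != i)
    if (!length(nbr)) {
      per_atom[i] <- 4 * pi * rext[i]^2
      next
    }
    pts <- sweep(sph * rext[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(free)) break
      dj2 <- (pts[free, 1] - coords[j, 1])^2 + (pts[free, 2] - coords[j, 2])^2 +
             (pts[free, 3] - coords[j, 3])^2
      free[free] <- dj2 >= rext[j]^2
    }
    per_atom[i] <- mean(free) * 4 * pi * rext[i]^2
  }
  structure(list(per_atom = per_atom, total = sum(per_atom), probe = probe,
                 n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<SASA: %.2f A^2 over %d atoms (probe %.2f A, %d points)>\n",
              x$total, length(x$per_atom), x$probe, x$n_points))
  invisible(x)
}

#' Buried interface area between two selections along a trajectory
#'
#' Per frame: `SASA(A) + SASA(B) - SASA(A union B)` with a 1.4 Angstrom
#' probe, then a centered rolling mean (100 ns window by default). The
#' measure is symmetric in A and B.
#'
#' @param traj trajectory object.
#' @param selection_a,selection_b disjoint atom index sets.
#' @param probe probe radius (Angstrom).
#' @param n_points sphere points per atom.
#' @param window_ns rolling-window length in ns.
#' @return data.frame: `frame`, `time_ns`, `buried` (A^2), `rolling`.
#' @export
buried_area_trace <- function(traj, selection_a, selection_b, probe = 1.4,
                              n_points = 960, window_ns = 100) {
  if (length(intersect(selection_a, selection_b)))
    stop("selections overlap")
  r <- traj$atoms$vdw
  nf <- n_frames(traj)
  buried <- numeric(nf)
  for (k in seq_len(nf)) {
    fc <- frame_coords(traj, k)
    sa <- sasa(fc[selection_a, , drop = FALSE], r[selection_a], probe, n_points)
    sb <- sasa(fc[selection_b, , drop = FALSE], r[selection_b], probe, n_points)
    su <- sasa(fc[c(selection_a, selection_b), , drop = FALSE],
               r[c(selection_a, selection_b)], probe, n_points)
    buried[k] <- sa$total + sb$total - su$total
  }
  wf <- max(1L, round(window_ns / traj$frame_interval))
  data.frame(frame = seq_len(nf), time_ns = frame_times(traj),
             buried = buried, rolling = rolling_mean(buried, wf))
}

#' Count two-water bridges between two sites in one frame
#'
#' A two-water bridge is an unordered pair of distinct water oxygens
#' (w1, w2) with w1 within `d_max` of some site-A atom, w2 within `d_max`
#' of some site-B atom, and w1-w2 within `d_max`. Each unordered pair is
#' counted once even if it satisfies the geometry in both orientations.
#'
#' @param coords `n_atoms x 3` frame coordinates.
#' @param atoms annotation table (`is_water_oxygen` flags needed).
#' @param site_a_atoms,site_b_atoms nonempty atom index sets (e.g. the
#'   gamma-phosphate oxygens and the catalytic glutamate carboxylate).
#' @param d_max distance cutoff for all three legs (default 3.5 Angstrom).
#' @return integer bridge count.
#' @export
two_water_bridge_count <- function(coords, atoms, site_a_atoms, site_b_atoms,
                                   d_max = 3.5) {
  if (!length(site_a_atoms) || !length(site_b_atoms))
    stop("site selections must be nonempty")
  w <- which(atoms$is_water_oxygen)
  if (length(w) < 2) return(0L)
  wc <- coords[w, , drop = FALSE]
  near <- function(sites) {
    sc <- coords[sites, , drop = FALSE]
    apply(wc, 1, function(p)
      min(sqrt(rowSums(sweep(sc, 2, p)^2))) <= d_max)
  }
  na_ <- near(site_a_atoms)
  nb_ <- near(site_b_atoms)
  count <- 0L
  for (i in seq_len(length(w) - 1L)) {
    for (j in seq.int(i + 1L, length(w))) {
      if (vnorm(wc[i, ] - wc[j, ]) > d_max) next
      if ((na_[i] && nb_[j]) || (na_[j] && nb_[i])) count <- count + 1L
    }
  }
  count
}

#' Per-frame two-water-bridge counts over a trajectory
#' @inheritParams two_water_bridge_count
#' @param traj trajectory object.
#' @return data.frame: `frame`, `time_ns`, `n_bridges`.
#' @export
bridge_count_series <- function(traj, site_a_atoms, site_b_atoms,
                                d_max = 3.5) {
  nf <- n_frames(traj)
  n <- vapply(seq_len(nf), function(k)
    two_water_bridge_count(frame_coords(traj, k), traj$atoms,
                           site_a_atoms, site_b_atoms, d_max),
    integer(1))
  data.frame(frame = seq_len(nf), time_ns = frame_times(traj), n_bridges = n)
}
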