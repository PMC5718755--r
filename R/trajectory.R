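#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Element-based van der Waals radii (Angstrom), Bondi-style defaults.
# Overridable per atom through the sidecar table.
.default_vdw <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                  P = 1.80, MG = 1.73, F = 1.47, CL = 1.75, NA. = 2.27,
                  K = 2.75, ZN = 1.39)

.vdw_for_element <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  r <- .default_vdw[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

.guess_element <- function(elety) {
  # First alphabetic character of the atom name, except two-letter ions.
  up <- toupper(elety)
  el <- ifelse(up %in% c("MG", "ZN", "CL", "NA", "FE", "MN", "CA2"), up,
               substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", up)), 1, 1))
  el[el == ""] <- "C"
  el
}

#' Construct an atom annotation table
#'
#' One row per atom; the column set mirrors what the analysis stages need:
#' identity (name, element, residue, chain), partial charge (e), van der
#' Waals radius (Angstrom), water-oxygen flag, and hydrogen-bond
#' donor/acceptor annotations. `donor_h` holds the indices (1-based,
#' semicolon-separated) of the hydrogens attached to a donor heavy atom.
#'
#' @param n number of atoms (used when only defaults are wanted).
#' @param elety,element,resno,resid,chain per-atom vectors, recycled.
#' @param charge partial charges in units of e (NA when unannotated).
#' @param vdw van der Waals radii (Angstrom); defaults by element.
#' @param is_water_oxygen,is_donor,is_acceptor logical flags.
#' @param donor_h character vector, semicolon-separated hydrogen indices.
#' @return data.frame with one row per atom and an `index` column (1-based).
#' @export
atom_table <- function(n = length(elety), elety = "CA", element = NULL,
                       resno = seq_len(n), resid = "GLY", chain = "A",
                       charge = NA_real_, vdw = NULL,
                       is_water_oxygen = FALSE, is_donor = FALSE,
                       is_acceptor = FALSE, donor_h = "") {
  elety <- rep_len(elety, n)
  if (is.null(element)) element <- .guess_element(elety)
  element <- rep_len(element, n)
  if (is.null(vdw)) vdw <- .vdw_for_element(element)
  at <- data.frame(
    index = seq_len(n),
    elety = elety,
    element = element,
    resno = as.integer(rep_len(resno, n)),
    resid = rep_len(resid, n),
    chain = rep_len(chain, n),
    charge = rep_len(as.numeric(charge), n),
    vdw = rep_len(as.numeric(vdw), n),
    is_water_oxygen = rep_len(as.logical(is_water_oxygen), n),
    is_donor = rep_len(as.logical(is_donor), n),
    donor_h = rep_len(as.character(donor_h), n),
    is_acceptor = rep_len(as.logical(is_acceptor), n),
    stringsAsFactors = FALSE
  )
  stopifnot(all(at$vdw > 0))
  bad <- at$is_donor != (nzchar(at$donor_h))
  if (any(bad)) stop("donor_h must be nonempty exactly for donor atoms (rows ",
                     paste(which(bad), collapse = ", "), ")")
  at
}

#' Create a trajectory object
#'
#' A trajectory is an ordered set of coordinate frames over a fixed,
#' annotated atom table with uniform time spacing. Coordinates are in
#' Angstrom, time in nanoseconds; frame times are `(k-1) * frame_interval`.
#'
#' @param atoms atom annotation table, see [atom_table()].
#' @param coords numeric array `n_atoms x 3 x n_frames` (a single
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @param frame_interval time between saved frames in ns (default 0.24).
#' @return an object of class `"kindyn_traj"`.
#' @export
trajectory <- function(atoms, coords, frame_interval = 0.24) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  if (dim(coords)[1L] != nrow(atoms))
    stop("frame has ", dim(coords)[1L], " atoms but topology has ", nrow(atoms))
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(atoms = atoms, coords = coords,
                 frame_interval = frame_interval),
            class = "kindyn_traj")
}

#' @export
print.kindyn_traj <- function(x, ...) {
  cat(sprintf("<kindyn trajectory: %d atoms, %d frames, dt = %g ns (%g ns total)>\n",
              n_atoms(x), n_frames(x), x$frame_interval,
              (n_frames(x) - 1) * x$frame_interval))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a trajectory object.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[1L]

#' @rdname trajectory
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$frame_interval

#' Extract the coordinate matrix of one frame
#' @param traj a trajectory object.
#' @param k frame number (1-based).
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, k) {
  stopifnot(k >= 1, k <= n_frames(traj))
  traj$coords[, , k, drop = TRUE]
}

# ---------------------------------------------------------------- I/O ----

.water_resnames <- c("HOH", "TIP3", "TIP", "WAT", "SPC", "SOL")

#' Load a trajectory from disk
#'
#' The canonical interchange format is multi-model PDB (MODEL/ENDMDL
#' records); a CHARMM/X-PLOR DCD file may instead supply the coordinates,
#' paired with a single-model PDB topology. An optional sidecar CSV merges
#' per-atom annotations (partial charges, donor/acceptor flags, radii)
#' that PDB cannot carry; without it those fields stay unset and stages
#' that need them refuse to run.
#'
#' @param topology_path multi-model (or single-model) PDB file.
#' @param coords_path optional DCD (or second PDB) supplying frames.
#' @param sidecar_path optional annotation CSV; columns: `index` (1-based),
#'   then any of `partial_charge`, `is_donor`, `donor_hydrogens`,
#'   `is_acceptor`, `vdw_radius`, `is_water_oxygen`.
#' @param frame_interval time between frames in ns.
#' @return a trajectory object.
#' @export
load_trajectory <- function(topology_path, coords_path = NULL,
                            sidecar_path = NULL, frame_interval = 0.24) {
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)
  nat <- nrow(pdb$atom)
  atoms <- atom_table(
    n = nat,
    elety = pdb$atom$elety,
    element = if (!is.null(pdb$atom$elesy) && any(nzchar(trimws(pdb$atom$elesy))))
      ifelse(nzchar(trimws(pdb$atom$elesy)), toupper(trimws(pdb$atom$elesy)),
             .guess_element(pdb$atom$elety))
    else .guess_element(pdb$atom$elety),
    resno = pdb$atom$resno,
    resid = pdb$atom$resid,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain)
  )
  atoms$is_water_oxygen <- atoms$resid %in% .water_resnames &
    atoms$element == "O"

  xyz <- pdb$xyz
  if (!is.null(coords_path)) {
    if (grepl("\\.dcd$", coords_path, ignore.case = TRUE)) {
      xyz <- bio3d::read.dcd(coords_path, verbose = FALSE)
    } else {
      xyz <- bio3d::read.pdb(coords_path, multi = TRUE, verbose = FALSE)$xyz
    }
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nat)
    stop("coordinate frames have ", ncol(xyz) / 3, " atoms but topology has ", nat)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nat, 3L, nf))
  for (k in seq_len(nf))
    coords[, , k] <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
  if (any(!is.finite(coords))) stop("unparseable frame: non-finite coordinates")

  traj <- trajectory(atoms, coords, frame_interval)
  if (!is.null(sidecar_path)) traj <- apply_sidecar(traj, sidecar_path)
  traj
}

#' Merge a sidecar annotation table into a trajectory
#' @param traj a trajectory object.
#' @param sidecar_path CSV path, see [load_trajectory()].
#' @return trajectory with annotations merged.
#' @export
apply_sidecar <- function(traj, sidecar_path) {
  sc <- read.csv(sidecar_path, stringsAsFactors = FALSE)
  if (!"index" %in% names(sc)) stop("sidecar must have an 'index' column")
  if (anyDuplicated(sc$index)) stop("duplicate atom index in sidecar")
  if (any(sc$index < 1 | sc$index > n_atoms(traj)))
    stop("sidecar index out of range")
  i <- sc$index
  at <- traj$atoms
  if ("partial_charge" %in% names(sc)) at$charge[i] <- sc$partial_charge
  if ("vdw_radius" %in% names(sc)) {
    keep <- !is.na(sc$vdw_radius)
    at$vdw[i[keep]] <- sc$vdw_radius[keep]
  }
  if ("is_donor" %in% names(sc)) at$is_donor[i] <- as.logical(sc$is_donor)
  if ("donor_hydrogens" %in% names(sc))
    at$donor_h[i] <- ifelse(is.na(sc$donor_hydrogens), "",
                            as.character(sc$donor_hydrogens))
  if ("is_acceptor" %in% names(sc)) at$is_acceptor[i] <- as.logical(sc$is_acceptor)
  if ("is_water_oxygen" %in% names(sc))
    at$is_water_oxygen[i] <- as.logical(sc$is_water_oxygen)
  if (any(at$vdw <= 0)) stop("sidecar vdw_radius must be > 0")
  bad <- at$is_donor & !nzchar(at$donor_h)
  if (any(bad)) stop("donor atoms need donor_hydrogens in sidecar (rows ",
                     paste(which(bad), collapse = ","), ")")
  traj$atoms <- at
  traj
}

#' Write a trajectory as a multi-model PDB (and optional sidecar CSV)
#' @param traj trajectory object.
#' @param path output PDB path.
#' @param sidecar_path optional path for the annotation CSV.
#' @export
write_trajectory <- function(traj, path, sidecar_path = NULL) {
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * n_atoms(traj))
  for (k in seq_len(nf)) xyz[k, ] <- as.numeric(t(traj$coords[, , k]))
  at <- traj$atoms
  bio3d::write.pdb(file = path, xyz = xyz, elety = at$elety,
                   resno = at$resno, resid = at$resid, chain = at$chain)
  if (!is.null(sidecar_path)) write_sidecar(traj, sidecar_path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_sidecar <- function(traj, sidecar_path) {
  at <- traj$atoms
  sc <- data.frame(index = at$index, partial_charge = at$charge,
                   is_donor = at$is_donor, donor_hydrogens = at$donor_h,
                   is_acceptor = at$is_acceptor, vdw_radius = at$vdw,
                   is_water_oxygen = at$is_water_oxygen)
  write.csv(sc, sidecar_path, row.names = FALSE)
  invisible(sidecar_path)
}

# --------------------------------------------------------- selections ----

#' Select atoms by chain, residue range and atom name
#'
#' @param traj trajectory object (or atom table).
#' @param chain chain id(s), or NULL for any.
#' @param resno residue numbers (vector or range), or NULL for any.
#' @param elety atom name(s), or NULL for any.
#' @return integer vector of atom indices (1-based, topology order).
#' @export
select_atoms <- function(traj, chain = NULL, resno = NULL, elety = NULL) {
  at <- if (inherits(traj, "kindyn_traj")) traj$atoms else traj
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  which(keep)
}

#' Read named atom selections from a YAML config
#'
#' Each selection is a list of triples `{chain, resno: [from, to], elety}`;
#' the union of the triples, in topology order, is the selection.
#'
#' @param traj trajectory object.
#' @param path YAML file of named selection definitions.
#' @return named list of integer index vectors.
#' @export
read_selections <- function(traj, path) {
  defs <- yaml::read_yaml(path)
  lapply(defs, function(def) resolve_selection(traj, def))
}

#' @rdname read_selections
#' @param def a single selection definition (list of triples).
#' @export
resolve_selection <- function(traj, def) {
  idx <- integer(0)
  for (tr in def) {
    rr <- tr$resno
    if (length(rr) == 2L) rr <- seq.int(rr[[1L]], rr[[2L]])
    idx <- c(idx, select_atoms(traj, chain = tr$chain, resno = rr,
                               elety = tr$elety))
  }
  sort(unique(idx))
}

# ------------------------------------------------------- superposition ----

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected atoms of `mobile` onto `reference`. Reflections are rejected:
#' the returned rotation always has determinant +1, matching physical
#' rigid-body motion.
#'
#' @param mobile,reference `n x 3` coordinate matrices over the same atoms.
#' @param selection atom indices used for the fit (default: all).
#' @return object of class `"rigid_transform"`: list with 3x3 `rotation`
#'   and length-3 `translation` such that `x -> rotation %*% x + translation`.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L) stop("selection needs at least 3 atoms")
  X <- mobile[selection, , drop = FALSE]
  Y <- reference[selection, , drop = FALSE]
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  sv_chk <- svd(Xc)$d
  if (sv_chk[2L] < 1e-8 * max(sv_chk[1L], 1))
    stop("degenerate selection: atoms are (near-)collinear")
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- ym - as.numeric(R %*% xm)
  rigid_transform(R, t)
}

#' @rdname superpose
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param coords `n x 3` matrix.
#' @param transform a `rigid_transform`.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(coords %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' RMSD between two coordinate sets
#' @param a,b `n x 3` matrices.
#' @param selection optional atom indices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b, selection = NULL) {
  if (!is.null(selection)) {
    a <- a[selection, , drop = FALSE]
    b <- b[selection, , drop = FALSE]
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @param traj trajectory object.
#' @param reference `n x 3` reference coordinates (default: frame 1).
#' @param selection atom indices used for the fit.
#' @return trajectory with every frame transformed.
#' @export
align_trajectory <- function(traj, reference = NULL, selection = NULL) {
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  out <- traj
  for (k in seq_len(n_frames(traj))) {
    tf <- superpose(traj$coords[, , k], reference, selection)
    out$coords[, , k] <- apply_transform(traj$coords[, , k], tf)
  }
  out
}
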