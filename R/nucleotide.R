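# Internal-coordinate analysis of the nucleotide phosphate moiety:
# bond lengths/angles, the eclipsed/staggered gamma-phosphate torsion, and
# Mg coordination denticity.

.pick3 <- function(coords, i) as.numeric(coords[i, ])

#' Bond length between two atoms
#' @param coords `n x 3` frame coordinates (Angstrom).
#' @param i,j distinct atom indices.
#' @return distance in Angstrom.
#' @export
bond_length <- function(coords, i, j) {
  if (i == j) stop("repeated atom index")
  vnorm(.pick3(coords, i) - .pick3(coords, j))
}

#' Bond angle i-j-k
#' @inheritParams bond_length
#' @param k vertex-flanking atom index (angle at `j`).
#' @return angle in degrees, in \[0, 180\].
#' @export
bond_angle <- function(coords, i, j, k) {
  if (anyDuplicated(c(i, j, k))) stop("repeated atom index")
  v1 <- .pick3(coords, i) - .pick3(coords, j)
  v2 <- .pick3(coords, k) - .pick3(coords, j)
  if (vnorm(v1) < 1e-9 || vnorm(v2) < 1e-9) stop("zero-length bond vector")
  deg(acos(max(-1, min(1, sum(unit(v1) * unit(v2))))))
}

#' Torsion angle i-j-k-l (IUPAC sign convention)
#'
#' 0 for cis (eclipsed), 180 for trans; per the standard convention the
#' torsion is invariant under complete chain reversal,
#' `dihedral(i,j,k,l) = dihedral(l,k,j,i)`. Reported in (-180, 180\].
#'
#' @inheritParams bond_angle
#' @param l fourth atom index.
#' @return torsion in degrees.
#' @export
dihedral <- function(coords, i, j, k, l) {
  if (anyDuplicated(c(i, j, k, l))) stop("repeated atom index")
  p1 <- .pick3(coords, i); p2 <- .pick3(coords, j)
  p3 <- .pick3(coords, k); p4 <- .pick3(coords, l)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (min(vnorm(b1), vnorm(b2), vnorm(b3)) < 1e-9)
    stop("zero-length bond vector")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  wrap_angle(deg(atan2(sum(m1 * n2), sum(n1 * n2))))
}

#' Eclipsed/staggered torsion of the gamma-phosphate oxygens
#'
#' For every pair of one beta and one gamma non-bridging oxygen, the
#' torsion about the Pbeta-Pgamma axis (via the bridging
#' Pbeta-O3beta-Pgamma linkage) is evaluated as `dihedral(Ob, Pbeta,
#' Pgamma, Og)`; the reported angle is the minimum absolute pairwise
#' torsion. With both triples at threefold (120 degree) spacing this lies
#' in \[0, 60\]: 0 = eclipsed (cis), 60 = staggered (trans). Invariant
#' under any permutation within each oxygen triple.
#'
#' @param coords `n x 3` frame coordinates.
#' @param pbeta_oxygens indices of the three non-bridging beta oxygens.
#' @param bridge_axis_atoms indices `c(Pbeta, O3beta, Pgamma)`.
#' @param pgamma_oxygens indices of the three gamma oxygens.
#' @return angle in degrees.
#' @export
phi_gamma <- function(coords, pbeta_oxygens, bridge_axis_atoms,
                      pgamma_oxygens) {
  if (length(pbeta_oxygens) != 3 || length(pgamma_oxygens) != 3)
    stop("need three oxygens on each side")
  if (length(bridge_axis_atoms) != 3) stop("bridge axis needs Pb, O3b, Pg")
  pb <- bridge_axis_atoms[1]; pg <- bridge_axis_atoms[3]
  tors <- outer(pbeta_oxygens, pgamma_oxygens,
                Vectorize(function(ob, og) dihedral(coords, ob, pb, pg, og)))
  min(abs(tors))
}

#' Mg coordination counts and denticity
#'
#' Counts the beta and gamma phosphate oxygens within `cutoff` of the Mg
#' ion. Denticity labels follow the motor-nucleotide convention:
#' one oxygen from each phosphate (1, 1) is *bidentate*; one beta plus two
#' gamma oxygens (1, 2) is *tridentate*; anything else is *other*.
#'
#' @param coords `n x 3` frame coordinates.
#' @param mg_index index of the Mg ion.
#' @param pbeta_oxygens,pgamma_oxygens oxygen index sets.
#' @param cutoff Mg-O contact cutoff (default 2.5 Angstrom, the typical
#'   first coordination shell).
#' @return list with `n_from_pbeta`, `n_from_pgamma`, `denticity`.
#' @export
mg_coordination <- function(coords, mg_index, pbeta_oxygens, pgamma_oxygens,
                            cutoff = 2.5) {
  mg <- .pick3(coords, mg_index)
  nb <- sum(vapply(pbeta_oxygens, function(i)
    vnorm(.pick3(coords, i) - mg) <= cutoff, logical(1)))
  ng <- sum(vapply(pgamma_oxygens, function(i)
    vnorm(.pick3(coords, i) - mg) <= cutoff, logical(1)))
  denticity <- if (nb == 1 && ng == 1) "bidentate"
               else if (nb == 1 && ng == 2) "tridentate"
               else "other"
  list(n_from_pbeta = nb, n_from_pgamma = ng, denticity = denticity)
}

#' Per-frame phosphate geometry with summary statistics
#'
#' Evaluates, for every frame: the (cleavable) O3beta-Pgamma bond length,
#' a configurable list of bond angles, the eclipsed/staggered torsion, and
#' (when an Mg atom is mapped) the coordination counts and denticity.
#'
#' @param traj trajectory object.
#' @param atom_map named list of atom indices: `PB`, `O3B`, `PG`, triples
#'   `pbeta_oxygens` and `pgamma_oxygens`, optional `MG`.
#' @param angle_triples named list of index triples (i, j, k) for bond
#'   angles; default: the bridge angle `PB-O3B-PG`.
#' @param mg_cutoff Mg-O cutoff (Angstrom).
#' @return list with `per_frame` (data.frame) and `summary` (mean and SD
#'   per numeric quantity).
#' @export
geometry_series <- function(traj, atom_map, angle_triples = NULL,
                            mg_cutoff = 2.5) {
  need <- c("PB", "O3B", "PG", "pbeta_oxygens", "pgamma_oxygens")
  miss <- setdiff(need, names(atom_map))
  if (length(miss)) stop("atom_map lacks: ", paste(miss, collapse = ", "))
  if (is.null(angle_triples))
    angle_triples <- list(bridge_angle = c(atom_map$PB, atom_map$O3B,
                                           atom_map$PG))
  nf <- n_frames(traj)
  rows <- lapply(seq_len(nf), function(k) {
    fc <- frame_coords(traj, k)
    row <- c(obeta_pgamma_length = bond_length(fc, atom_map$O3B, atom_map$PG))
    for (nm in names(angle_triples)) {
      tr <- angle_triples[[nm]]
      row[nm] <- bond_angle(fc, tr[1], tr[2], tr[3])
    }
    row["phi_gamma"] <- phi_gamma(fc, atom_map$pbeta_oxygens,
                                  c(atom_map$PB, atom_map$O3B, atom_map$PG),
                                  atom_map$pgamma_oxygens)
    if (!is.null(atom_map$MG)) {
      mc <- mg_coordination(fc, atom_map$MG, atom_map$pbeta_oxygens,
                            atom_map$pgamma_oxygens, mg_cutoff)
      row["n_from_pbeta"] <- mc$n_from_pbeta
      row["n_from_pgamma"] <- mc$n_from_pgamma
    }
    row
  })
  per_frame <- data.frame(frame = seq_len(nf), time_ns = frame_times(traj),
                          do.call(rbind, rows))
  if (!is.null(atom_map$MG)) {
    per_frame$denticity <- ifelse(
      per_frame$n_from_pbeta == 1 & per_frame$n_from_pgamma == 1, "bidentate",
      ifelse(per_frame$n_from_pbeta == 1 & per_frame$n_from_pgamma == 2,
             "tridentate", "other"))
  }
  num <- setdiff(names(per_frame)[vapply(per_frame, is.numeric, logical(1))],
                 c("frame", "time_ns"))
  summary <- data.frame(
    quantity = num,
    mean = vapply(num, function(nm) mean(per_frame[[nm]]), numeric(1)),
    sd = vapply(num, function(nm) sd(per_frame[[nm]]), numeric(1)),
    row.names = NULL)
  list(per_frame = per_frame, summary = summary)
}

#' Resolve an atom map from atom names in the annotation table
#'
#' Convenience for phosphate fragments whose atoms follow the usual
#' naming: non-bridging beta oxygens O1B/O2B/O3A, bridging O3B, and
#' gamma oxygens O1G/O2G/O3G (plus optional MG).
#'
#' @param traj trajectory object.
#' @return atom_map list for [geometry_series()].
#' @export
phosphate_atom_map <- function(traj) {
  at <- traj$atoms
  find1 <- function(nm) {
    i <- which(at$elety == nm)
    if (length(i) != 1) stop("cannot resolve atom name: ", nm)
    i
  }
  map <- list(PB = find1("PB"), O3B = find1("O3B"), PG = find1("PG"),
              pbeta_oxygens = c(find1("O1B"), find1("O2B"), find1("O3A")),
              pgamma_oxygens = c(find1("O1G"), find1("O2G"), find1("O3G")))
  if (any(at$elety == "MG")) map$MG <- find1("MG")
  map
}
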