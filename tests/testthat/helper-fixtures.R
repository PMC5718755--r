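# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Random rigid transform (proper rotation + translation).
random_transform <- function() {
  ax <- rnorm(3)
  rigid_transform(rotation_about(ax, runif(1, -180, 180)),
                  rnorm(3, sd = 5))
}

# The canonical residue pair of make_contact_trajectory fixtures.
contact_pair <- list(chain_a = "A", res_a = 1L, chain_b = "A", res_b = 2L)

# Randomized annotated fixture for contact-detection oracles: n_res
# residues of 4 atoms each (donor N with an H, acceptor O, neutral-ish C)
# at uniform positions in a box.
random_contact_fixture <- function(n_res = 10, box = 8) {
  n <- 4 * n_res
  res <- rep(seq_len(n_res), each = 4)
  elety <- rep(c("N", "HN", "O", "CB"), n_res)
  idx_h <- which(elety == "HN")
  donor_h <- character(n)
  donor_h[elety == "N"] <- as.character(idx_h)
  atoms <- atom_table(n = n, elety = elety,
                      element = rep(c("N", "H", "O", "C"), n_res),
                      resno = res, resid = "GLY", chain = "A",
                      charge = runif(n, -0.6, 0.6),
                      is_donor = elety == "N", donor_h = donor_h,
                      is_acceptor = elety == "O")
  coords <- matrix(runif(3 * n, 0, box), ncol = 3)
  list(atoms = atoms, coords = coords)
}

# Brute-force H-bond oracle: every donor-hydrogen/acceptor pair in
# different residues with distance <= cutoff.
oracle_hbonds <- function(coords, atoms, cutoff = 2.4) {
  keys <- character(0)
  for (d in which(atoms$is_donor)) {
    h <- as.integer(strsplit(atoms$donor_h[d], ";")[[1]])
    for (a in which(atoms$is_acceptor)) {
      if (atoms$chain[a] == atoms$chain[d] &&
          atoms$resno[a] == atoms$resno[d]) next
      for (p in h) {
        if (sqrt(sum((coords[p, ] - coords[a, ])^2)) <= cutoff) {
          r <- sort(c(paste(atoms$chain[d], atoms$resno[d]),
                      paste(atoms$chain[a], atoms$resno[a])))
          keys <- c(keys, paste(r, collapse = "|"))
        }
      }
    }
  }
  sort(unique(keys))
}

# Brute-force nonpolar oracle: triple loop over atom pairs.
oracle_nonpolar <- function(coords, atoms, q_max = 0.3, cutoff = 3.0) {
  keys <- character(0)
  n <- nrow(atoms)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (is.na(atoms$charge[i]) || is.na(atoms$charge[j])) next
      if (abs(atoms$charge[i]) >= q_max || abs(atoms$charge[j]) >= q_max) next
      if (atoms$chain[i] == atoms$chain[j] &&
          atoms$resno[i] == atoms$resno[j]) next
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff) {
        r <- sort(c(paste(atoms$chain[i], atoms$resno[i]),
                    paste(atoms$chain[j], atoms$resno[j])))
        keys <- c(keys, paste(r, collapse = "|"))
      }
    }
  }
  sort(unique(keys))
}

pair_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(unique(paste(paste(df$chain_a, df$res_a),
                    paste(df$chain_b, df$res_b), sep = "|")))
}

# Accessible area of sphere 1 when overlapped by sphere 2 (expanded
# radii r1, r2, center distance d): full area minus the buried cap.
cap_accessible_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  cos_t <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  h <- r1 * (1 - cos_t)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# Anisotropic rigid body (major axis along x) plus static anchor points;
# the first two anchors are the triad H12 markers, the extra two make the
# anchor set usable as a (non-collinear) alignment selection.
kinematics_fixture <- function() {
  body <- cbind(as.matrix(expand.grid(seq(-4, 4, 2), seq(-1, 1, 1))), 0)
  anchors <- rbind(c(0, 0, -20), c(80, 0, -20), c(0, 30, -20),
                   c(40, 15, -25))
  triad <- build_triad(anchors[1, ], anchors[2, ], c(0, 1, 0))
  list(body = body, anchors = anchors, triad = triad,
       body_sel = seq_len(nrow(body)),
       anchor_sel = nrow(body) + 1:4)
}
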