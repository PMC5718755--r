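# Per-frame hydrogen-bond and nonpolar contact detection, occupancy traces,
# and irreversible formation/breakage classification.

.res_key <- function(chain, resno) paste(chain, resno, sep = ":")

# Canonically ordered residue-pair table from index pairs (i, j).
.pair_table <- function(atoms, i, j, kind) {
  ka <- .res_key(atoms$chain[i], atoms$resno[i])
  kb <- .res_key(atoms$chain[j], atoms$resno[j])
  flip <- kb < ka
  chain_a <- ifelse(flip, atoms$chain[j], atoms$chain[i])
  res_a <- ifelse(flip, atoms$resno[j], atoms$resno[i])
  chain_b <- ifelse(flip, atoms$chain[i], atoms$chain[j])
  res_b <- ifelse(flip, atoms$resno[i], atoms$resno[j])
  df <- data.frame(kind = rep_len(kind, length(chain_a)),
                   chain_a = chain_a, res_a = res_a,
                   chain_b = chain_b, res_b = res_b,
                   stringsAsFactors = FALSE)
  unique(df)
}

.parse_donor_h <- function(s) as.integer(strsplit(s, ";", fixed = TRUE)[[1L]])

#' Detect hydrogen bonds in one frame
#'
#' A donor/acceptor pair (different residues) forms an H-bond when the
#' configured distance is at most `cutoff` (default 2.4 Angstrom). By
#' default the distance is measured from each donor hydrogen to the
#' acceptor heavy atom (`mode = "hydrogen"`); `mode = "heavy"` measures
#' the donor heavy atom to acceptor distance literally. Salt bridges are
#' not separately classified — they satisfy the same criterion. No angular
#' criterion is applied.
#'
#' @param coords `n_atoms x 3` frame coordinates.
#' @param atoms atom annotation table with donor/acceptor flags set.
#' @param cutoff distance cutoff in Angstrom.
#' @param mode `"hydrogen"` (H...acceptor) or `"heavy"` (donor...acceptor).
#' @return data.frame of canonically ordered residue pairs: `kind`,
#'   `chain_a`, `res_a`, `chain_b`, `res_b` (zero rows when none).
#' @export
detect_hbonds_frame <- function(coords, atoms, cutoff = 2.4,
                                mode = c("hydrogen", "heavy")) {
  mode <- match.arg(mode)
  don <- which(atoms$is_donor)
  acc <- which(atoms$is_acceptor)
  if (!length(don) || !length(acc))
    stop("missing annotations: no donor/acceptor flags set")
  out_i <- integer(0); out_j <- integer(0)
  for (d in don) {
    probes <- if (mode == "hydrogen") .parse_donor_h(atoms$donor_h[d]) else d
    a_ok <- acc[!(atoms$chain[acc] == atoms$chain[d] &
                  atoms$resno[acc] == atoms$resno[d])]
    if (!length(a_ok)) next
    for (p in probes) {
      dd <- sqrt(colSums((t(coords[a_ok, , drop = FALSE]) - coords[p, ])^2))
      hit <- a_ok[dd <= cutoff]
      out_i <- c(out_i, rep(d, length(hit)))
      out_j <- c(out_j, hit)
    }
  }
  .pair_table(atoms, out_i, out_j, "hbond")
}

#' Detect nonpolar contacts in one frame
#'
#' A residue pair is in nonpolar contact when any atom pair — both atoms
#' near-neutral, absolute partial charge below `q_max` — is closer than
#' `cutoff`. All atoms (including hydrogens) are considered by default;
#' `heavy_only = TRUE` restricts to non-hydrogens.
#'
#' @param coords `n_atoms x 3` frame coordinates.
#' @param atoms annotation table with partial charges set.
#' @param q_max charge threshold in units of e (default 0.3).
#' @param cutoff distance cutoff in Angstrom (default 3.0, strict `<`).
#' @param heavy_only drop hydrogens first.
#' @return data.frame of canonically ordered residue pairs.
#' @export
detect_nonpolar_frame <- function(coords, atoms, q_max = 0.3, cutoff = 3.0,
                                  heavy_only = FALSE) {
  if (all(is.na(atoms$charge)))
    stop("missing annotations: no partial charges set")
  cand <- which(!is.na(atoms$charge) & abs(atoms$charge) < q_max)
  if (heavy_only) cand <- cand[atoms$element[cand] != "H"]
  if (length(cand) < 2) return(.pair_table(atoms, integer(0), integer(0),
                                           "nonpolar"))
  cc <- coords[cand, , drop = FALSE]
  d2 <- as.matrix(stats::dist(cc))^2
  hit <- which(d2 < cutoff^2 & upper.tri(d2), arr.ind = TRUE)
  i <- cand[hit[, 1]]; j <- cand[hit[, 2]]
  same <- atoms$chain[i] == atoms$chain[j] & atoms$resno[i] == atoms$resno[j]
  .pair_table(atoms, i[!same], j[!same], "nonpolar")
}

.pair_present_series <- function(traj, pair, kind, ...) {
  nf <- n_frames(traj)
  vapply(seq_len(nf), function(k) {
    df <- if (kind == "hbond")
      detect_hbonds_frame(frame_coords(traj, k), traj$atoms, ...)
    else
      detect_nonpolar_frame(frame_coords(traj, k), traj$atoms, ...)
    any(df$chain_a == pair$chain_a & df$res_a == pair$res_a &
        df$chain_b == pair$chain_b & df$res_b == pair$res_b)
  }, logical(1))
}

#' Occupancy trace of one contact pair
#'
#' Binary presence per frame, its mean (the occupancy: fraction of frames
#' where the contact is formed), and a centered rolling average with a
#' 400-frame window (96 ns at the 0.24 ns frame interval) by default.
#'
#' @param traj trajectory with the needed annotations.
#' @param pair list or one-row data.frame with `chain_a`, `res_a`,
#'   `chain_b`, `res_b` (canonical order, see [detect_hbonds_frame()]).
#' @param kind `"hbond"` or `"nonpolar"`.
#' @param window_frames rolling-window length in frames (default 400).
#' @param ... passed to the frame detector (cutoffs, mode).
#' @return object of class `"occupancy_trace"`: logical `present`,
#'   `occupancy`, numeric `rolling`, `time_ns`, plus `pair` and `kind`.
#' @export
occupancy_trace <- function(traj, pair, kind = c("hbond", "nonpolar"),
                            window_frames = 400, ...) {
  kind <- match.arg(kind)
  pair <- as.list(pair)
  present <- .pair_present_series(traj, pair, kind, ...)
  structure(list(present = present, occupancy = mean(present),
                 rolling = rolling_mean(as.numeric(present), window_frames),
                 time_ns = frame_times(traj), window_frames = window_frames,
                 pair = pair, kind = kind),
            class = "occupancy_trace")
}

#' @export
print.occupancy_trace <- function(x, ...) {
  cat(sprintf("<%s trace %s:%s - %s:%s> occupancy %.3f over %d frames\n",
              x$kind, x$pair$chain_a, x$pair$res_a, x$pair$chain_b,
              x$pair$res_b, x$occupancy, length(x$present)))
  invisible(x)
}

#' Classify irreversible formation and breakage of a contact
#'
#' Occupancy is evaluated over the first and last `edge_window` frames
#' (200 frames = 48 ns by default). The contact *formed* when the initial
#' occupancy is below `low` (0.05) and the final above `high` (0.5); it
#' *broke* in the mirrored case. The transition time is where the local
#' (rolling) occupancy first exceeds `high` scanning forward (formation)
#' or last exceeds `high` scanning backward (breakage).
#'
#' @param trace an [occupancy_trace()].
#' @param edge_window frames in each edge window (default 200).
#' @param low,high occupancy thresholds (defaults 0.05 and 0.5).
#' @return data.frame (possibly zero rows): `kind` (`"formed"`/`"broken"`),
#'   `transition_time_ns`, `initial_occupancy`, `final_occupancy`.
#' @export
classify_transitions <- function(trace, edge_window = 200, low = 0.05,
                                 high = 0.5) {
  n <- length(trace$present)
  if (n < 2 * edge_window)
    stop("trajectory shorter than two edge windows (", 2 * edge_window,
         " frames)")
  init <- mean(trace$present[seq_len(edge_window)])
  fin <- mean(trace$present[seq.int(n - edge_window + 1L, n)])
  roll <- trace$rolling
  events <- data.frame(kind = character(0), transition_time_ns = numeric(0),
                       initial_occupancy = numeric(0),
                       final_occupancy = numeric(0))
  if (init < low && fin > high) {
    k <- which(!is.na(roll) & roll > high)[1L]
    events[1L, ] <- list("formed", trace$time_ns[k], init, fin)
  } else if (init > high && fin < low) {
    hits <- which(!is.na(roll) & roll > high)
    k <- hits[length(hits)]
    events[1L, ] <- list("broken", trace$time_ns[k], init, fin)
  }
  events
}

#' Census of contact occupancies over a trajectory
#'
#' Enumerates every residue pair that forms a contact in at least one
#' frame, computes per-pair occupancy, histograms the occupancies and
#' counts pairs above a threshold (default 0.8), partitioned into
#' intra-molecular (same chain) and inter-molecular (different chain).
#'
#' @param traj annotated trajectory.
#' @param kinds subset of `c("hbond", "nonpolar")`.
#' @param occupancy_bins histogram bin edges over \[0, 1\].
#' @param threshold high-occupancy cutoff (strict `>`).
#' @param ... passed to the frame detectors.
#' @return list with `pairs` (per-pair table incl. `occupancy` and
#'   `intra`), `histogram` (counts per bin per kind), and
#'   `n_above_threshold` (by kind x intra/inter).
#' @export
contact_census <- function(traj, kinds = c("hbond", "nonpolar"),
                           occupancy_bins = seq(0, 1, 0.1), threshold = 0.8,
                           ...) {
  nf <- n_frames(traj)
  tally <- new.env(parent = emptyenv())
  for (k in seq_len(nf)) {
    fc <- frame_coords(traj, k)
    found <- do.call(rbind, lapply(kinds, function(kd) {
      if (kd == "hbond") detect_hbonds_frame(fc, traj$atoms, ...)
      else detect_nonpolar_frame(fc, traj$atoms, ...)
    }))
    if (is.null(found) || !nrow(found)) next
    keys <- do.call(paste, c(found, sep = "|"))
    for (key in keys)
      assign(key, (if (exists(key, tally)) get(key, tally) else 0L) + 1L,
             tally)
  }
  keys <- ls(tally)
  if (!length(keys)) {
    pairs <- data.frame(kind = character(0), chain_a = character(0),
                        res_a = integer(0), chain_b = character(0),
                        res_b = integer(0), occupancy = numeric(0),
                        intra = logical(0))
  } else {
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    pairs <- data.frame(kind = parts[, 1], chain_a = parts[, 2],
                        res_a = as.integer(parts[, 3]), chain_b = parts[, 4],
                        res_b = as.integer(parts[, 5]),
                        occupancy = vapply(keys, get, numeric(1),
                                           envir = tally) / nf,
                        row.names = NULL, stringsAsFactors = FALSE)
    pairs$intra <- pairs$chain_a == pairs$chain_b
    pairs <- pairs[order(pairs$kind, pairs$chain_a, pairs$res_a,
                         pairs$chain_b, pairs$res_b), ]
    row.names(pairs) <- NULL
  }
  hist_by_kind <- lapply(split(pairs$occupancy, pairs$kind), function(o)
    hist(o, breaks = occupancy_bins, plot = FALSE, include.lowest = TRUE)$counts)
  above <- stats::aggregate(occupancy ~ kind + intra, data = pairs,
                            FUN = function(o) sum(o > threshold))
  list(pairs = pairs, histogram = hist_by_kind,
       occupancy_bins = occupancy_bins,
       n_above_threshold = if (nrow(pairs)) above else
         data.frame(kind = character(0), intra = logical(0),
                    occupancy = integer(0)),
       threshold = threshold)
}

#' @importFrom graphics hist
NULL
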