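# Configuration-driven entry point tying the analysis stages into
# reproducible runs. Each run writes its outputs plus a JSON manifest
# (inputs, parameters, package version, seed) from which it can be
# reproduced exactly.

.common_keys <- c("out", "seed", "topology", "coords", "sidecar",
                  "frame_interval", "verbose")

.subcommand_keys <- list(
  synth = c("generator", "n_frames", "n_side", "half_extent", "coeffs",
            "noise_sd", "rate_on", "rate_off", "kind", "phi_gamma_deg", "mg"),
  curvature = c("sheet_selection", "n_bins"),
  `pmf-merge` = c("series_a", "series_b", "n_bins", "kBT"),
  pose = c("align_selection", "domain_selection", "sheet_section", "alpha4",
           "alpha6", "r_alpha", "r_beta", "u_alpha4"),
  mobility = c("align_selection", "window_ns_start", "window_ns_end",
               "exclude_selection", "threshold", "window_ns"),
  contacts = c("kinds", "threshold", "cutoff", "edge_window"),
  hydration = c("ref_selection", "padding", "spacing", "blob_k", "bulk"),
  sasa = c("selection_a", "selection_b", "probe", "n_points", "window_ns"),
  bridges = c("site_a", "site_b", "d_max"),
  nucgeo = c("mg_cutoff")
)

#' Read and validate a run configuration
#'
#' Configurations are flat YAML (or JSON) key-value files; unknown keys
#' fail fast, listing the offenders. Values given in `overrides` replace
#' config values (CLI flags take precedence over the file).
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @param subcommand the subcommand the config is for.
#' @param overrides named list of overriding values.
#' @return validated named list.
#' @export
read_run_config <- function(config, subcommand, overrides = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a named list")
  config[names(overrides)] <- overrides
  if (!subcommand %in% names(.subcommand_keys))
    stop("unknown subcommand: ", subcommand)
  allowed <- c(.common_keys, .subcommand_keys[[subcommand]])
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop("invalid config keys for '", subcommand, "': ",
         paste(bad, collapse = ", "))
  if (is.null(config$out)) stop("config needs an 'out' directory")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$frame_interval)) config$frame_interval <- 0.24
  config
}

.load_from_config <- function(cfg) {
  load_trajectory(cfg$topology, cfg$coords, cfg$sidecar,
                  frame_interval = cfg$frame_interval)
}

.write_manifest <- function(cfg, subcommand, outputs) {
  manifest <- list(subcommand = subcommand,
                   package = "kindyn",
                   version = as.character(packageVersion("kindyn")),
                   seed = cfg$seed,
                   parameters = cfg,
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.say <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

#' Run an analysis subcommand
#'
#' Subcommands: `synth` (write a synthetic trajectory), `curvature`
#' (quadric/curvature series CSV), `pmf-merge` (merge two landscape
#' CSVs), `pose` (triad pose series), `mobility` (per-residue profile and
#' rolling mobile-residue displacement), `contacts` (census and
#' transition events), `hydration` (density map MRC + blob table),
#' `sasa` (buried-area trace), `bridges` (two-water-bridge series),
#' `nucgeo` (phosphate geometry series + summary). Every run writes a
#' `manifest.json` echoing all parameters; no parameter defaults are
#' applied silently — the resolved values are in the manifest.
#'
#' @param subcommand one of the names above.
#' @param config config file path or list, see [read_run_config()].
#' @param overrides named list overriding config values.
#' @return (invisibly) named list of output paths.
#' @export
run_analysis <- function(subcommand, config, overrides = list()) {
  cfg <- read_run_config(config, subcommand, overrides)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  out <- switch(subcommand,
    synth = .run_synth(cfg),
    curvature = .run_curvature(cfg),
    `pmf-merge` = .run_pmf_merge(cfg),
    pose = .run_pose(cfg),
    mobility = .run_mobility(cfg),
    contacts = .run_contacts(cfg),
    hydration = .run_hydration(cfg),
    sasa = .run_sasa(cfg),
    bridges = .run_bridges(cfg),
    nucgeo = .run_nucgeo(cfg))
  .write_manifest(cfg, subcommand, out)
  invisible(out)
}

.run_synth <- function(cfg) {
  gen <- cfg$generator
  if (is.null(gen)) stop("synth needs a 'generator'")
  traj <- switch(gen,
    sheet = {
      grid <- sheet_grid(cfg$n_side %||% 7, cfg$half_extent %||% 3)
      co <- cfg$coeffs %||% c(0, 0, 0.05, 0, 0, 0.05)
      make_sheet_trajectory(grid, unlist(co), n_frames = cfg$n_frames %||% 100,
                            noise_sd = cfg$noise_sd %||% 0.1,
                            seed = cfg$seed,
                            frame_interval = cfg$frame_interval)
    },
    contact = make_contact_trajectory(
      telegraph = list(n_frames = cfg$n_frames %||% 1000,
                       rate_on = cfg$rate_on %||% 0.05,
                       rate_off = cfg$rate_off %||% 0.05),
      kind = cfg$kind %||% "hbond", seed = cfg$seed,
      frame_interval = cfg$frame_interval),
    phosphate = make_phosphate_fragment(
      unlist(cfg$phi_gamma_deg %||% 30), mg = cfg$mg %||% "none",
      frame_interval = cfg$frame_interval),
    stop("unknown generator: ", gen))
  pdb <- file.path(cfg$out, "trajectory.pdb")
  sc <- file.path(cfg$out, "sidecar.csv")
  write_trajectory(traj, pdb, sidecar_path = sc)
  .say(cfg, "wrote ", pdb)
  list(trajectory = pdb, sidecar = sc)
}

.run_curvature <- function(cfg) {
  traj <- .load_from_config(cfg)
  sel <- if (is.null(cfg$sheet_selection)) NULL
         else resolve_selection(traj, cfg$sheet_selection)
  cs <- curvature_series(traj, sel)
  path <- file.path(cfg$out, "curvature_series.csv")
  write.csv(cs, path, row.names = FALSE)
  list(curvature_series = path)
}

.run_pmf_merge <- function(cfg) {
  sa <- read.csv(cfg$series_a)
  sb <- read.csv(cfg$series_b)
  n_bins <- cfg$n_bins %||% 30
  kBT <- cfg$kBT %||% 1
  msq_edges <- .spread_edges(c(sa$M_sq, sb$M_sq), n_bins)
  g_edges <- .spread_edges(c(sa$G, sb$G), n_bins)
  pa <- build_pmf(sa$M_sq, sa$G, msq_edges, g_edges, kBT = kBT)
  pb <- build_pmf(sb$M_sq, sb$G, msq_edges, g_edges, kBT = kBT)
  mg <- merge_pmfs(pa, pb)
  csv <- file.path(cfg$out, "merged_pmf.csv")
  hdr <- file.path(cfg$out, "merged_pmf.json")
  write_pmf(mg, csv, hdr)
  list(merged_pmf = csv, header = hdr)
}

.run_pose <- function(cfg) {
  traj <- .load_from_config(cfg)
  align <- if (is.null(cfg$align_selection)) NULL
           else resolve_selection(traj, cfg$align_selection)
  traj <- align_trajectory(traj, selection = align)
  triad <- build_triad(unlist(cfg$r_alpha), unlist(cfg$r_beta),
                       unlist(cfg$u_alpha4))
  dom <- resolve_selection(traj, cfg$domain_selection)
  ax <- list()
  for (nm in c("sheet_section", "alpha4", "alpha6"))
    if (!is.null(cfg[[nm]])) ax[[nm]] <- resolve_selection(traj, cfg[[nm]])
  ps <- pose_series(traj, triad, dom, ax)
  path <- file.path(cfg$out, "pose_series.csv")
  write.csv(ps, path, row.names = FALSE)
  list(pose_series = path)
}

.run_mobility <- function(cfg) {
  traj <- .load_from_config(cfg)
  align <- if (is.null(cfg$align_selection)) NULL
           else resolve_selection(traj, cfg$align_selection)
  window <- c(cfg$window_ns_start %||% 0,
              cfg$window_ns_end %||% max(frame_times(traj)))
  prof <- mobility_profile(traj, align, window)
  excl <- if (is.null(cfg$exclude_selection)) NULL
          else resolve_selection(traj, cfg$exclude_selection)
  roll <- rolling_mean_displacement(traj, align, excl,
                                    threshold = cfg$threshold %||% 1,
                                    window_ns = cfg$window_ns %||% 100)
  p1 <- file.path(cfg$out, "mobility_profile.csv")
  p2 <- file.path(cfg$out, "rolling_displacement.csv")
  write.csv(prof, p1, row.names = FALSE)
  write.csv(roll, p2, row.names = FALSE)
  list(mobility_profile = p1, rolling_displacement = p2)
}

.run_contacts <- function(cfg) {
  traj <- .load_from_config(cfg)
  kinds <- unlist(cfg$kinds %||% c("hbond", "nonpolar"))
  census <- contact_census(traj, kinds, threshold = cfg$threshold %||% 0.8)
  edge_window <- cfg$edge_window %||% 200
  long_enough <- n_frames(traj) >= 2 * edge_window
  if (!long_enough)
    .say(cfg, "trajectory shorter than two edge windows; skipping events")
  events <- do.call(rbind, lapply(seq_len(nrow(census$pairs)), function(r) {
    if (!long_enough) return(NULL)
    p <- census$pairs[r, ]
    tr <- occupancy_trace(traj, p, kind = p$kind)
    ev <- classify_transitions(tr, edge_window = edge_window)
    if (!nrow(ev)) return(NULL)
    cbind(p[rep(1, nrow(ev)), c("kind", "chain_a", "res_a", "chain_b",
                                "res_b", "occupancy")],
          event = ev$kind, time_ns = ev$transition_time_ns)
  }))
  p1 <- file.path(cfg$out, "contact_census.csv")
  p2 <- file.path(cfg$out, "contact_events.csv")
  write.csv(census$pairs, p1, row.names = FALSE)
  if (is.null(events))
    events <- data.frame(kind = character(0), chain_a = character(0),
                         res_a = integer(0), chain_b = character(0),
                         res_b = integer(0), occupancy = numeric(0),
                         event = character(0), time_ns = numeric(0))
  write.csv(events, p2, row.names = FALSE)
  list(census = p1, events = p2)
}

.run_hydration <- function(cfg) {
  traj <- .load_from_config(cfg)
  sel <- if (is.null(cfg$ref_selection)) NULL
         else resolve_selection(traj, cfg$ref_selection)
  grid <- water_density_map(traj, sel, padding = cfg$padding %||% 15,
                            spacing = cfg$spacing %||% 0.7)
  blobs <- threshold_blobs(grid, k = cfg$blob_k %||% 3,
                           bulk = cfg$bulk %||% 0.0333)
  p1 <- file.path(cfg$out, "water_density.mrc")
  p2 <- file.path(cfg$out, "blobs.csv")
  write_mrc(grid, p1)
  write.csv(blobs, p2, row.names = FALSE)
  list(density_map = p1, blobs = p2)
}

.run_sasa <- function(cfg) {
  traj <- .load_from_config(cfg)
  tr <- buried_area_trace(traj,
                          resolve_selection(traj, cfg$selection_a),
                          resolve_selection(traj, cfg$selection_b),
                          probe = cfg$probe %||% 1.4,
                          n_points = cfg$n_points %||% 960,
                          window_ns = cfg$window_ns %||% 100)
  path <- file.path(cfg$out, "buried_area.csv")
  write.csv(tr, path, row.names = FALSE)
  list(buried_area = path)
}

.run_bridges <- function(cfg) {
  traj <- .load_from_config(cfg)
  bc <- bridge_count_series(traj,
                            resolve_selection(traj, cfg$site_a),
                            resolve_selection(traj, cfg$site_b),
                            d_max = cfg$d_max %||% 3.5)
  path <- file.path(cfg$out, "bridge_counts.csv")
  write.csv(bc, path, row.names = FALSE)
  list(bridge_counts = path)
}

.run_nucgeo <- function(cfg) {
  traj <- .load_from_config(cfg)
  gs <- geometry_series(traj, phosphate_atom_map(traj),
                        mg_cutoff = cfg$mg_cutoff %||% 2.5)
  p1 <- file.path(cfg$out, "phosphate_geometry.csv")
  p2 <- file.path(cfg$out, "phosphate_summary.csv")
  write.csv(gs$per_frame, p1, row.names = FALSE)
  write.csv(gs$summary, p2, row.names = FALSE)
  list(geometry = p1, summary = p2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
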