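# End-to-end pipeline stages tying the modules together, each optionally
# writing tidy CSV outputs plus a machine-readable run manifest.

write_manifest <- function(out_dir, stage, params, seed = NULL) {
  manifest <- list(
    stage = stage,
    package = "curvsense",
    version = as.character(utils::packageVersion("curvsense")),
    r_version = R.version.string,
    seed = seed,
    params = params,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Curvature-sensing analysis: map a trajectory and build the statistics
#'
#' The full sensing pipeline: read (or accept) frames, map every snapshot
#' onto the buckle ([map_trajectory()]), build the occupancy/curvature maps
#' ([occupancy_map()]) and the free-energy profile along the radius of
#' curvature ([free_energy_profile()]), and evaluate the binding free energy
#' at `R_bind` if requested.
#'
#' @param frames A list of [labeled_frame()]s, or a file path readable by
#'   [read_frames()].
#' @param profile The [buckle_profile()].
#' @param R_bind Optional radius (nm) at which to report
#'   [binding_free_energy()].
#' @param s_bins,theta_bins Occupancy binning.
#' @param R_edges Radius bin edges for the free-energy profile.
#' @param correct_dos Apply the density-of-states correction (default TRUE).
#' @param out_dir Optional directory: writes `placements.csv`,
#'   `occupancy.csv`, `free_energy.csv` and a run manifest.
#' @param ... Passed to [read_frames()] when `frames` is a path.
#' @return A list with `placements`, `landscape`, `free_energy`, `dG_bind`
#'   (or `NULL`).
#' @export
run_sense <- function(frames, profile, R_bind = NULL,
                      s_bins = 50L, theta_bins = 45L,
                      R_edges = default_R_edges(), correct_dos = TRUE,
                      out_dir = NULL, ...) {
  input <- if (is.character(frames)) frames else "<in-memory frames>"
  if (is.character(frames)) frames <- read_frames(frames, ...)
  placements <- map_trajectory(frames, profile)
  landscape <- occupancy_map(placements, profile, s_bins, theta_bins)
  fe <- free_energy_profile(placements, profile, R_edges, correct_dos)
  dG <- if (!is.null(R_bind)) binding_free_energy(fe, R_bind) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(placements, file.path(out_dir, "placements.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy(landscape), file.path(out_dir, "occupancy.csv"),
                     row.names = FALSE)
    utils::write.csv(fe, file.path(out_dir, "free_energy.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, "sense",
                   list(input = input, n_frames = length(frames),
                        gamma = profile$gamma, L = profile$L,
                        s_bins = s_bins, theta_bins = theta_bins,
                        correct_dos = correct_dos, R_bind = R_bind))
  }
  list(placements = placements, landscape = landscape, free_energy = fe,
       dG_bind = dG)
}

#' Membrane bending analysis: radius-of-curvature time series
#'
#' @param frames A list of [labeled_frame()]s or a file path.
#' @param out_dir Optional output directory (`radius_series.csv` + manifest).
#' @param ... Passed to [read_frames()] or [membrane_radius_series()].
#' @return The tibble from [membrane_radius_series()].
#' @export
run_bend <- function(frames, out_dir = NULL, ...) {
  input <- if (is.character(frames)) frames else "<in-memory frames>"
  if (is.character(frames)) frames <- read_frames(frames)
  series <- membrane_radius_series(frames, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(series, file.path(out_dir, "radius_series.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, "bend",
                   list(input = input, n_frames = length(frames)))
  }
  series
}

#' Tube-coverage estimate from elastic theory
#'
#' @param kc Bending rigidity, kBT.
#' @param R_bind Radius of curvature, nm.
#' @param dG_bind Binding free energy, kBT (negative = favourable).
#' @param out_file Optional JSON output path.
#' @return A `tube_coverage` object ([required_density()]).
#' @export
run_theory <- function(kc, R_bind, dG_bind, out_file = NULL) {
  cov <- required_density(kc, R_bind, dG_bind)
  if (!is.null(out_file)) {
    jsonlite::write_json(unclass(cov), out_file, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  cov
}

#' Generate a synthetic ground-truth data set
#'
#' Runs the Boltzmann placement sampler, renders the requested frames, and
#' (optionally) writes them in a coordinate dialect together with the
#' ground-truth sidecar table.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Optional directory: writes `trajectory.<dialect>`,
#'   `truth.csv` and a manifest.
#' @param dialect Output coordinate dialect (default `"gro"`).
#' @param render_rows Which samples to render as frames (default all).
#' @return A list with `truth`, `frames`, `acceptance_rate`.
#' @export
run_generate <- function(cfg, out_dir = NULL, dialect = "gro",
                         render_rows = NULL) {
  sb <- sample_boltzmann_trajectory(cfg)
  if (is.null(render_rows)) render_rows <- seq_len(nrow(sb$truth))
  frames <- render_trajectory(cfg, sb$truth, rows = render_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_frames(frames, file.path(out_dir, paste0("trajectory.", dialect)),
                 dialect)
    utils::write.csv(sb$truth[render_rows, ],
                     file.path(out_dir, "truth.csv"), row.names = FALSE)
    write_manifest(out_dir, "generate",
                   list(gamma = cfg$gamma, L = cfg$L, Ly = cfg$Ly,
                        noise_sigma = cfg$noise_sigma,
                        energy_model = cfg$energy_model,
                        n_frames = cfg$n_frames, dialect = dialect),
                   seed = cfg$seed)
  }
  list(truth = sb$truth, frames = frames, acceptance_rate = sb$acceptance_rate)
}
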