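# Two-stage pipeline: cmd_compute() turns topology + trajectories into tidy
# metric tables on disk (one TSV per metric per run, plus a machine-readable
# manifest); cmd_compare() reads two such directories and writes the
# group-comparison report. A thin command-line wrapper around these lives in
# inst/cli/btkloop.R.

.supported_metrics <- c("rmsd", "rgyr", "rmsf", "angle", "distance", "sasa")

.parse_metric <- function(m) {
  parts <- strsplit(m, ":", fixed = TRUE)[[1]]
  name <- parts[1]
  if (!name %in% .supported_metrics) {
    abort(sprintf("Unknown metric '%s' (supported: %s).", name,
                  paste(.supported_metrics, collapse = ", ")),
          class = "btkloop_usage_error")
  }
  region <- if (length(parts) > 1) parts[2] else
    switch(name, rmsd = "global", rgyr = "global", rmsf = "global",
           sasa = "a_loop_cterm", NULL)
  if (!is.null(region) && grepl("^[0-9]+-[0-9]+$", region)) {
    region <- as.numeric(strsplit(region, "-")[[1]])
  }
  list(name = name, region = region)
}

.compute_one <- function(traj, spec, regions, hbond, saltbridge,
                         sasa_probe, sasa_points) {
  switch(spec$name,
    rmsd = rmsd_series(traj, spec$region, regions = regions),
    rgyr = rgyr_series(traj, spec$region, regions = regions),
    rmsf = rmsf_profile(traj, spec$region, regions = regions),
    angle = line_angle_series(traj, regions = regions),
    distance = dfg_atp_distance_series(traj, regions = regions),
    sasa = sasa_region_series(traj, spec$region, probe = sasa_probe,
                              n_points = sasa_points, regions = regions)
  )
}

#' Compute metric tables for one group of runs
#'
#' Reads the topology (PDB) and one trajectory per run (DCD, or multi-model
#' PDB), evaluates the requested metrics, and writes one TSV per metric per
#' run plus a `manifest.json` recording inputs, configuration and package
#' version. Re-running with identical inputs produces byte-identical
#' tables.
#'
#' @param topology Path to a PDB file providing the topology.
#' @param trajectories Character vector of trajectory paths, one per run
#'   (`.dcd`, or `.pdb` for multi-model files).
#' @param metrics Metric specs, `"name"` or `"name:region"`; names from
#'   `rmsd, rgyr, rmsf, angle, distance, sasa`.
#' @param out_dir Output directory (created if needed).
#' @param regions A `region_set` or path to a YAML region config; defaults
#'   to [btk_default_regions()].
#' @param frames Optional `c(first, last)` frame window.
#' @param hbond,saltbridge Criteria objects (reserved for bond metrics
#'   driven through the timeline API).
#' @param sasa_probe,sasa_points SASA probe radius (Angstrom) and lattice
#'   points.
#' @return The manifest, invisibly.
#' @export
cmd_compute <- function(topology, trajectories, metrics, out_dir,
                        regions = btk_default_regions(), frames = NULL,
                        hbond = hbond_criteria(),
                        saltbridge = saltbridge_criteria(),
                        sasa_probe = 1.4, sasa_points = 960) {
  specs <- lapply(metrics, .parse_metric)  # validate before any computation
  if (is.character(regions)) regions <- read_regions(regions)
  if (!file.exists(topology)) {
    abort(sprintf("Topology file not found: %s", topology),
          class = "btkloop_usage_error")
  }
  missing <- trajectories[!file.exists(trajectories)]
  if (length(missing) > 0) {
    abort(sprintf("Trajectory file(s) not found: %s",
                  paste(missing, collapse = ", ")),
          class = "btkloop_usage_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  top_traj <- read_pdb(topology)
  files <- list()
  frame_counts <- integer(length(trajectories))
  for (r in seq_along(trajectories)) {
    path <- trajectories[r]
    traj <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
      read_dcd(path, top_traj$topology)
    } else {
      read_pdb(path)
    }
    if (!is.null(frames)) {
      traj <- frame_window(traj, seq(frames[1], min(frames[2],
                                                    n_frames(traj))))
    }
    frame_counts[r] <- n_frames(traj)
    for (k in seq_along(specs)) {
      tab <- .compute_one(traj, specs[[k]], regions, hbond, saltbridge,
                          sasa_probe, sasa_points)
      fn <- sprintf("run%d_%s.tsv", r, gsub(":", "_", metrics[k]))
      write_metric_table(tab, file.path(out_dir, fn))
      files[[length(files) + 1L]] <- list(run = r, metric = metrics[k],
                                          file = fn)
    }
  }
  manifest <- list(
    tool = "btkloop",
    version = as.character(utils::packageVersion("btkloop")),
    topology = topology, trajectories = as.list(trajectories),
    metrics = as.list(metrics), frames = frames,
    frame_counts = frame_counts,
    criteria = list(hbond_dist = hbond$da_cutoff,
                    hbond_angle = hbond$angle_cutoff,
                    saltbridge_dist = saltbridge$no_cutoff,
                    sasa_probe = sasa_probe, sasa_points = sasa_points),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.load_group <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    abort(sprintf("No manifest.json in %s; run cmd_compute() first.", dir),
          class = "btkloop_usage_error")
  }
  mf <- jsonlite::read_json(mf_path)
  rows <- purrr::map(mf$files, function(f) {
    tab <- read_metric_table(file.path(dir, f$file))
    tibble(run = f$run, metric = f$metric, value = tab$value)
  })
  dplyr::bind_rows(rows)
}

#' Compare two computed metric directories
#'
#' Loads the manifests written by [cmd_compute()] for groups A and B,
#' aggregates each run to its time mean (default) and writes the Student's
#' t-test comparison report as TSV and readable text. The report header
#' records the inference unit; frame-level inference adds an explicit
#' pseudo-replication warning.
#'
#' @param dir_a,dir_b Output directories of [cmd_compute()].
#' @param out_dir Directory for `report.tsv` / `report.txt`.
#' @param unit `"run_mean"` or `"frame"`.
#' @param alpha Significance level.
#' @param labels Group labels for the report.
#' @return The [compare_groups()] result, invisibly.
#' @export
cmd_compare <- function(dir_a, dir_b, out_dir, unit = "run_mean",
                        alpha = 0.05, labels = c("A", "B")) {
  ga <- .load_group(dir_a)
  gb <- .load_group(dir_b)
  if (length(intersect(unique(ga$metric), unique(gb$metric))) == 0) {
    abort("The two groups share no metrics; nothing to compare.",
          class = "btkloop_comparison_error")
  }
  shared <- intersect(unique(ga$metric), unique(gb$metric))
  cmp <- compare_groups(ga[ga$metric %in% shared, ],
                        gb[gb$metric %in% shared, ],
                        unit = unit, alpha = alpha, labels = labels)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_metric_table(tidy(cmp), file.path(out_dir, "report.tsv"))
  writeLines(utils::capture.output(print(cmp)),
             file.path(out_dir, "report.txt"))
  invisible(cmp)
}
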