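# End-to-end orchestration: extract/generate -> secondary structure ->
# clustering (full tail + tip) -> reach -> pose ranking -> contacts ->
# tetranucleosome reachability, with per-stage CSV outputs and a
# machine-readable summary JSON. Identical config + seed gives a
# byte-identical summary (no timestamps are recorded).

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline with the canonical
#' analysis values as defaults: 13 A single-linkage cutoff, 15-residue
#' tip selection, P43 reach anchor, 5 A contact cutoff, 3 x 3 docking grid
#' with 400 poses per cell.
#'
#' @param n_frames Frames per synthetic trajectory.
#' @param dt Frame spacing, ps.
#' @param seed Integer seed driving every stochastic stage.
#' @param cluster_cutoff Single-linkage RMSD cutoff, Angstrom.
#' @param tip_length Number of N-terminal residues in the tip selection.
#' @param anchor_res Reach anchor residue.
#' @param contact_cutoff Contact distance cutoff, Angstrom.
#' @param grid_rows,grid_cols,grid_overlap Docking grid shape and overlap.
#' @param poses_per_cell Docking poses per grid cell.
#' @param trajectories Optional named list of multi-MODEL PDB paths; when
#'   `NULL` (default) a synthetic active/inactive pair is generated.
#' @param pose_table Optional path to a pose-table CSV; when `NULL` a
#'   synthetic table with planted best cells is generated.
#' @param out_dir Output directory (created if missing).
#' @param verbose Log one line per stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_frames = 200, dt = 25, seed = 1,
                            cluster_cutoff = 13, tip_length = 15,
                            anchor_res = 43, contact_cutoff = 5,
                            grid_rows = 3, grid_cols = 3, grid_overlap = 0.25,
                            poses_per_cell = 400,
                            trajectories = NULL, pose_table = NULL,
                            out_dir = tempfile("tailscope_run_"),
                            verbose = FALSE) {
  stopifnot(
    n_frames >= 10, dt > 0, cluster_cutoff > 0, tip_length >= 3,
    anchor_res >= 2, contact_cutoff > 0, grid_rows >= 1, grid_cols >= 1,
    grid_overlap >= 0, grid_overlap <= 0.5, poses_per_cell >= 1
  )
  structure(
    list(
      n_frames = n_frames, dt = dt, seed = seed,
      cluster_cutoff = cluster_cutoff, tip_length = tip_length,
      anchor_res = anchor_res, contact_cutoff = contact_cutoff,
      grid_rows = grid_rows, grid_cols = grid_cols,
      grid_overlap = grid_overlap, poses_per_cell = poses_per_cell,
      trajectories = trajectories, pose_table = pose_table,
      out_dir = out_dir, verbose = verbose
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

run_stage <- function(name, config, out_files, expr) {
  if (config$verbose) {
    message("[tailscope] stage ", name)
  }
  tryCatch(expr, error = function(e) {
    marker <- file.path(config$out_dir, paste0(name, ".FAILED"))
    writeLines(conditionMessage(e), marker)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_stage_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on synthetic or file inputs, writing
#' per-stage CSV/PDB outputs plus `summary.json` into the configured
#' output directory. Rerunning the same config and seed reproduces the
#' summary byte for byte.
#'
#' @param config A [pipeline_config()] or a path to a YAML config.
#' @return Invisibly, the summary list (also serialised as
#'   `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(list.files(config$out_dir, pattern = "\\.FAILED$", full.names = TRUE))
  outputs <- list()

  # Stage 1: inputs (generate or read, extracting tails as needed).
  trajs <- run_stage("input", config, outputs, {
    if (is.null(config$trajectories)) {
      pair <- gen_active_inactive_pair(
        n_frames = config$n_frames,
        seed = config$seed
      )
      pair
    } else {
      lapply(config$trajectories, read_trajectory, dt = config$dt)
    }
  })
  isoforms <- names(trajs)

  # Stage 2: secondary structure + occupancy.
  occ_list <- run_stage("secondary_structure", config, outputs, {
    res <- list()
    for (iso in isoforms) {
      m <- ss_matrix(trajs[[iso]])
      outputs[[paste0("ss_matrix_", iso)]] <- write_stage_csv(
        tidy(m), file.path(config$out_dir, paste0("ss_matrix_", iso, ".csv"))
      )
      occ <- occupancy(m)
      outputs[[paste0("occupancy_", iso)]] <- write_stage_csv(
        occ, file.path(config$out_dir, paste0("occupancy_", iso, ".csv"))
      )
      res[[iso]] <- occ
    }
    res
  })

  # Stage 3: clustering, full tail and 15-residue tip.
  clusterings <- run_stage("clustering", config, outputs, {
    res <- list()
    for (iso in isoforms) {
      traj <- trajs[[iso]]
      for (sel in c("full", "tip")) {
        selection <- if (sel == "tip") seq_len(config$tip_length) else NULL
        cl <- single_linkage(
          rmsd_matrix(traj, selection = selection),
          cutoff = config$cluster_cutoff
        )
        tag <- paste0(iso, "_", sel)
        outputs[[paste0("clusters_", tag)]] <- write_stage_csv(
          tidy(cl), file.path(config$out_dir, paste0("clusters_", tag, ".csv"))
        )
        rep_path <- file.path(config$out_dir, paste0("representative_", tag, ".pdb"))
        write_structure(representative(traj, cl, 1), rep_path)
        outputs[[paste0("representative_", tag)]] <- rep_path
        res[[tag]] <- cl
      }
    }
    res
  })

  # Stage 4: reach series, summaries, Welch comparison.
  reach <- run_stage("reach", config, outputs, {
    series <- lapply(trajs, reach_series, anchor_res = config$anchor_res)
    for (iso in isoforms) {
      outputs[[paste0("reach_", iso)]] <- write_stage_csv(
        series[[iso]], file.path(config$out_dir, paste0("reach_", iso, ".csv"))
      )
    }
    summaries <- lapply(series, summarize_reach)
    welch <- if (length(series) >= 2) {
      welch_test(series[[2]], series[[1]])
    } else {
      NULL
    }
    if (!is.null(welch)) {
      outputs[["welch"]] <- write_stage_csv(
        welch, file.path(config$out_dir, "welch.csv")
      )
    }
    list(series = series, summaries = summaries, welch = welch)
  })

  # Stage 5: docking grid + pose ranking.
  dock <- run_stage("dock_rank", config, outputs, {
    receptor_assembly <- gen_toy_nucleosome()
    receptor <- receptor_assembly$structures[[1]]
    grid <- make_grid(receptor,
      rows = config$grid_rows, cols = config$grid_cols,
      overlap_frac = config$grid_overlap
    )
    poses <- if (is.null(config$pose_table)) {
      planted <- stats::setNames(
        grid$cell[1 + (seq_along(isoforms) - 1) %% nrow(grid)],
        isoforms
      )
      gen_pose_table(grid, isoforms, planted, seed = config$seed + 100L)
    } else {
      read_pose_table(config$pose_table)
    }
    ranked <- rank_poses(poses)
    outputs[["pose_rank"]] <- write_stage_csv(
      ranked, file.path(config$out_dir, "pose_rank.csv")
    )
    list(
      receptor_assembly = receptor_assembly, receptor = receptor,
      grid = grid, ranked = ranked
    )
  })

  # Stage 6: contacts of the top tip structure with the nucleosome.
  contacts <- run_stage("contacts", config, outputs, {
    tip_tag <- paste0(isoforms[1], "_tip")
    tip <- representative(trajs[[isoforms[1]]], clusterings[[tip_tag]], 1)
    tip <- tip[tip$res_seq <= config$tip_length, ]
    # Place the tip at the annotated binding site of the toy nucleosome.
    site <- dock$receptor_assembly$site_points
    site <- site[grepl("tip_site", site$site_id), ]
    shift <- c(mean(site$x), mean(site$y), mean(site$z)) -
      colMeans(structure_coords(tip))
    tip$x <- tip$x + shift[1]
    tip$y <- tip$y + shift[2]
    tip$z <- tip$z + shift[3]
    ct <- find_contacts(tip, dock$receptor, cutoff = config$contact_cutoff)
    outputs[["contacts"]] <- write_stage_csv(
      ct, file.path(config$out_dir, "contacts.csv")
    )
    summary <- contact_summary(ct)
    outputs[["contact_summary"]] <- write_stage_csv(
      summary, file.path(config$out_dir, "contact_summary.csv")
    )
    summary
  })

  # Stage 7: tetranucleosome reach shells + site classification.
  chromatin <- run_stage("chromatin", config, outputs, {
    tetra <- gen_tetranucleosome()
    res <- list()
    for (iso in isoforms) {
      shells <- build_shells(tetra, summary = reach$summaries[[iso]])
      cls <- classify_reachable_sites(tetra, shells)
      outputs[[paste0("reachability_", iso)]] <- write_stage_csv(
        cls, file.path(config$out_dir, paste0("reachability_", iso, ".csv"))
      )
      res[[iso]] <- cls
    }
    res
  })

  summary <- list(
    package = "tailscope",
    version = as.character(utils::packageVersion("tailscope")),
    seed = config$seed,
    parameters = config[c(
      "n_frames", "dt", "cluster_cutoff", "tip_length", "anchor_res",
      "contact_cutoff", "grid_rows", "grid_cols", "grid_overlap",
      "poses_per_cell"
    )],
    isoforms = isoforms,
    n_clusters = lapply(clusterings, function(cl) length(cl$sizes)),
    reach_summaries = lapply(reach$summaries, as.list),
    welch = if (!is.null(reach$welch)) as.list(reach$welch) else NULL,
    pose_rank = lapply(
      split(dock$ranked, seq_len(nrow(dock$ranked))),
      as.list
    ),
    contact_totals = as.list(contacts[contacts$component == "total", ]),
    reachable_sites = lapply(chromatin, function(cls) {
      sum(cls$reachable)
    }),
    outputs = lapply(outputs, basename)
  )
  json_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, json_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (config$verbose) {
    message("[tailscope] wrote ", json_path)
  }
  invisible(summary)
}
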