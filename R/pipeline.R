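required_field <- function(cfg, path) {
  node <- cfg
  for (p in strsplit(path, "\\$")[[1]]) {
    node <- node[[p]]
    if (is.null(node))
      stop("config is missing required field '", path, "'", call. = FALSE)
  }
  node
}

#' Run the full analysis pipeline from a declarative config
#'
#' Executes the requested stages — simulate (or load), node extraction,
#' network construction, source/sink path analysis and betweenness,
#' receptor clustering, pose rescoring, ligand contact fractions — and
#' writes all tabular outputs plus a machine-readable run manifest under
#' `output_dir`. Stages run only when their config section is present;
#' failures abort with a stage-tagged error.
#'
#' The config is YAML (or an equivalent R list) with sections:
#' \preformatted{
#' output_dir: out
#' seed: 1
#' simulate:            # or input: {topology: x.pdb, trajectory: x.dcd}
#'   n_subunits: 4
#'   residues_per_subunit: 10
#'   n_frames: 500
#'   path_nodes: [3, 4, 5, 6, 7, 8]
#'   rho_path: 0.9
#'   ligand: false
#' network:
#'   kernel: {cutoff: 7.0, d_cut: 10.0, epsilon: 1.0e-5}
#'   mi: {bins: 16, range_sd: 3}
#'   source: {center: "A:3", radius: 7.0, occupancy: 0.7}
#'   sink:   {center: "A:8", radius: 7.0, occupancy: 0.7}
#' cluster: {k: 4, resno: [1, 2, 3]}
#' rescore: {poses: poses.tsv, kT: 0.593, rmsd_threshold: 2.0}
#' contacts: {cutoff: 4.5}
#' }
#'
#' @param config Path to a YAML file or a named list.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML path or a list",
                          call. = FALSE)
  out_dir <- required_field(cfg, "output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  results <- list()
  files <- character()

  # --- input: synthetic or loaded -----------------------------------------
  system <- NULL
  if (!is.null(cfg$simulate)) {
    system <- stage("simulate", {
      sc <- cfg$simulate
      spec <- toy_channel_spec(
        n_subunits = sc$n_subunits %||% 4L,
        residues_per_subunit = sc$residues_per_subunit %||% 10L,
        glycine_at = sc$glycine_at %||% integer())
      ref <- generate_toy_channel(spec, ligand = isTRUE(sc$ligand))
      cov <- planted_covariance(
        path_nodes = as.integer(sc$path_nodes %||% integer()),
        rho_path = sc$rho_path %||% 0.9,
        rho_background = sc$rho_background %||% 0,
        noise_sd = sc$noise_sd %||% 0.8)
      sys <- generate_trajectory(ref, cov, n_frames = sc$n_frames %||% 500L,
                                 seed = seed)
      files <- c(files, write_trajectory(sys, file.path(out_dir,
                                                         "synthetic")))
      sys
    })
  } else if (!is.null(cfg$input)) {
    system <- stage("load", {
      top <- required_field(cfg, "input$topology")
      if (!file.exists(top))
        stop("topology file not found: ", top)
      trj <- cfg$input$trajectory
      if (!is.null(trj) && !file.exists(trj))
        stop("trajectory file not found: ", trj)
      load_system(top, trj, frame_selection = cfg$input$frame_selection,
                  system_label = cfg$input$system_label %||% "")
    })
  }

  series <- NULL
  if (!is.null(system)) {
    series <- stage("nodes", {
      lm <- cfg$ligand_map
      extract_node_series(system, ligand_map = lm,
                          align = isTRUE(cfg$align))
    })
  }

  if (!is.null(cfg$network)) {
    stage("network", {
      if (is.null(series)) stop("network stage needs a trajectory input")
      nc <- cfg$network
      kp <- kernel_params(cutoff = nc$kernel$cutoff %||% 7,
                          d_cut = nc$kernel$d_cut %||% 10,
                          epsilon = nc$kernel$epsilon %||% 1e-5,
                          sigma = nc$kernel$sigma)
      st <- mi_settings(bins = nc$mi$bins %||% 16L,
                        range_sd = nc$mi$range_sd %||% 3,
                        min_frames = nc$mi$min_frames %||% 100L)
      C <- contact_map(series, kp)
      mi <- mi_matrix(series, st)
      net <- build_network(C, mi$M_hat, nodes = series$nodes,
                           exclude_adjacent = nc$exclude_adjacent %||% 0L)
      write.csv(C, file.path(out_dir, "contact_map.csv"))
      write.csv(mi$M_hat, file.path(out_dir, "mi_normalized.csv"))
      files <- c(files, file.path(out_dir, c("contact_map.csv",
                                              "mi_normalized.csv")),
                  write_network(net, file.path(out_dir, "network")))
      results$network <- net
      if (!is.null(nc$source) && !is.null(nc$sink)) {
        src <- detect_region(series, required_field(nc, "source$center"),
                             nc$source$radius %||% 7,
                             nc$source$occupancy %||% 0.7)
        snk <- detect_region(series, required_field(nc, "sink$center"),
                             nc$sink$radius %||% 7,
                             nc$sink$occupancy %||% 0.7)
        snk <- setdiff(snk, src)
        pr <- min_path(net, src, snk)
        bt <- betweenness_centrality(net)
        jsonlite::write_json(
          list(d_min = pr$d_min, best_path = pr$best_path,
               n_co_minimal = length(pr$all_paths),
               source_set = src, sink_set = snk,
               reachable = pr$reachable),
          file.path(out_dir, "path_result.json"), auto_unbox = TRUE,
          digits = NA)
        write.csv(data.frame(node = names(bt), betweenness = as.numeric(bt)),
                  file.path(out_dir, "betweenness.csv"), row.names = FALSE)
        files <- c(files, file.path(out_dir, c("path_result.json",
                                                "betweenness.csv")))
        results$path <- pr
        results$betweenness <- bt
      }
    })
  }

  if (!is.null(cfg$cluster)) {
    stage("cluster", {
      if (is.null(system)) stop("cluster stage needs a trajectory input")
      cc <- cfg$cluster
      aug <- symmetry_expand(system)
      sel <- cluster_selection(resno = cc$resno, chains = cc$chains)
      rcs <- kmeans_rmsd(aug, sel, k = cc$k %||% 10L, seed = seed)
      write.csv(rcs$assignments,
                file.path(out_dir, "cluster_assignments.csv"),
                row.names = FALSE)
      jsonlite::write_json(as.list(rcs$populations),
                           file.path(out_dir, "cluster_populations.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, file.path(out_dir, c("cluster_assignments.csv",
                                              "cluster_populations.json")))
      results$receptor_clusters <- rcs
    })
  }

  if (!is.null(cfg$rescore)) {
    stage("rescore", {
      rc <- cfg$rescore
      pth <- required_field(rc, "poses")
      if (!file.exists(pth)) stop("poses file not found: ", pth)
      poses <- read_pose_table(pth)
      pj <- rc$receptor_populations
      if (!is.null(pj)) pj <- unlist(pj)
      ranked <- rescore_pose_table(poses,
                                   rmsd_threshold = rc$rmsd_threshold %||% 2,
                                   receptor_populations = pj,
                                   kT = rc$kT %||% 0.593)
      write.csv(ranked, file.path(out_dir, "rescored_clusters.csv"),
                row.names = FALSE)
      jsonlite::write_json(ranked,
                           file.path(out_dir, "rescored_clusters.json"),
                           digits = NA)
      files <- c(files, file.path(out_dir, c("rescored_clusters.csv",
                                              "rescored_clusters.json")))
      results$rescored <- ranked
    })
  }

  if (!is.null(cfg$contacts)) {
    stage("contacts", {
      if (is.null(system)) stop("contacts stage needs a trajectory input")
      cf <- contact_fractions(system, cutoff = cfg$contacts$cutoff %||% 4.5)
      write.csv(cf, file.path(out_dir, "contact_fractions.csv"),
                row.names = FALSE)
      files <- c(files, file.path(out_dir, "contact_fractions.csv"))
      results$contact_fractions <- cf
    })
  }

  manifest <- list(
    package = "allopath",
    version = as.character(utils::packageVersion("allopath")),
    seed = seed,
    config = cfg,
    outputs = as.list(tools::md5sum(files[file.exists(files)])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
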