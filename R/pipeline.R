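# Config-driven orchestration: run the full analysis battery over a set of
# systems x replicas and collate CSV/JSON outputs under a run directory.

#' Assemble an analysis configuration
#'
#' @param systems named list: system label -> `Trajectory`, list of replica
#'   `Trajectory`s, or character vector of multi-model PDB paths.
#' @param selections named selection list (default: [default_selections()];
#'   must contain `ash`, `alpha_c`, `hinge`; interface/distance stages use
#'   `n_lobe` and `alpha_f` when present).
#' @param exclude_ns equilibration cutoff (ns).
#' @param salt_cutoff,hydrophobic_cutoff contact cutoffs (Angstrom).
#' @param heatmap_threshold replica-persistence threshold (percent).
#' @param pc_retention PC retention threshold (variance fraction).
#' @param contact_specs optional list of [contact_spec()]s for the contact
#'   stage.
#' @param run_pca,run_sse stage switches.
#' @param frame_time_map ns/frame used when `systems` holds file paths.
#' @param seed RNG seed recorded in the manifest.
#' @return object of class `AnalysisConfig`.
#' @export
analysis_config <- function(systems, selections = default_selections(),
                            exclude_ns = 250, salt_cutoff = 4.0,
                            hydrophobic_cutoff = 2.5,
                            heatmap_threshold = 30, pc_retention = 0.09,
                            contact_specs = NULL, run_pca = TRUE,
                            run_sse = FALSE, frame_time_map = 1,
                            seed = 1L) {
  stopifnot(length(systems) >= 1L, !is.null(names(systems)))
  structure(list(systems = systems, selections = selections,
                 exclude_ns = exclude_ns, salt_cutoff = salt_cutoff,
                 hydrophobic_cutoff = hydrophobic_cutoff,
                 heatmap_threshold = heatmap_threshold,
                 pc_retention = pc_retention, contact_specs = contact_specs,
                 run_pca = run_pca, run_sse = run_sse,
                 frame_time_map = frame_time_map, seed = as.integer(seed)),
            class = "AnalysisConfig")
}

.config_hash <- function(config) {
  # digest of the deparsed config (trajectory coordinates included via
  # their summary statistics to keep hashing cheap but content-sensitive)
  strip <- rapply(config, function(x) {
    if (is.numeric(x) && length(x) > 100L)
      c(length(x), sum(x), stats::sd(x)) else x
  }, how = "replace")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(strip), f)
  unname(tools::md5sum(f))
}

.as_replica_list <- function(entry, frame_time_map) {
  if (inherits(entry, "Trajectory")) return(list(entry))
  if (is.character(entry))
    return(lapply(seq_along(entry), function(i)
      read_trajectory(traj_path = entry[i], format = "pdb",
                      frame_time_map = frame_time_map, replica_index = i)))
  stopifnot(all(vapply(entry, inherits, TRUE, "Trajectory")))
  entry
}

.write_series_csv <- function(series_list, path) {
  df <- do.call(rbind, lapply(series_list, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Per system: replica-aggregated RMSF, apex-angle series with pooled
#' boxplot summaries, interface cog distances (dimer topologies), shared
#' PCA scores, optional contact-frequency tables with replica heatmaps,
#' and optional %SSE series. Stage failures are recorded in the manifest
#' and do not stop independent stages. Re-running an unchanged config on
#' the same output directory is a no-op unless `force = TRUE`.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @param force re-run even when the manifest shows an identical config.
#' @return the run manifest (list), invisibly written as
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "AnalysisConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, hash)) {
      old$cache_hit <- TRUE
      jsonlite::write_json(old, manifest_path, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      return(invisible(old))
    }
  }
  systems <- lapply(config$systems, .as_replica_list,
                    frame_time_map = config$frame_time_map)
  sel <- config$selections
  manifest <- list(config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("kinasedyn")),
                   seed = config$seed, cache_hit = FALSE,
                   stages = list(), outputs = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    status <- tryCatch({ fun(); "ok" },
                       error = function(e) paste("failed:",
                                                 conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = status,
      wall_clock_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  record <- function(key, path) manifest$outputs[[key]] <<- path

  run_stage("rmsf", function() {
    for (lab in names(systems)) {
      r <- rmsf_per_residue(systems[[lab]], exclude_ns = config$exclude_ns)
      df <- cbind(system = lab, r$residues,
                  mean_rmsf_nm = r$mean, sd_rmsf_nm = r$sd)
      p <- file.path(out_dir, paste0("rmsf_", lab, ".csv"))
      utils::write.csv(df, p, row.names = FALSE)
      record(paste0("rmsf_", lab), p)
    }
  })

  run_stage("angle", function() {
    chains <- unique(unlist(lapply(systems, function(trs)
      unique(trs[[1]]$topology$chain[!trs[[1]]$topology$is_water]))))
    for (lab in names(systems)) {
      for (ch in chains) {
        defn <- angle_definition(chain = ch)
        ok <- tryCatch({ resolve_selection(systems[[lab]][[1]], defn$ray_a)
                         TRUE }, error = function(e) FALSE)
        if (!ok) next
        series <- lapply(systems[[lab]], angle_series, defn = defn,
                         exclude_ns = config$exclude_ns)
        p <- file.path(out_dir, paste0("angle_", lab, "_", ch, ".csv"))
        .write_series_csv(series, p)
        record(paste0("angle_", lab, "_", ch), p)
        bs <- boxplot_summary(series)   # pooled replicas
        pj <- file.path(out_dir, paste0("angle_", lab, "_", ch,
                                        "_boxplot.json"))
        jsonlite::write_json(unclass(bs), pj, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        record(paste0("angle_boxplot_", lab, "_", ch), pj)
      }
    }
  })

  run_stage("distance", function() {
    for (lab in names(systems)) {
      top <- systems[[lab]][[1]]$topology
      chains <- unique(top$chain[!top$is_water])
      if (length(chains) < 2L) next      # interface distances need a dimer
      for (nm in intersect(c("n_lobe", "ash", "alpha_f"), names(sel))) {
        sA <- sel[[nm]]; sA$chain_id <- chains[1]
        sB <- sel[[nm]]; sB$chain_id <- chains[2]
        series <- lapply(systems[[lab]], distance_series, sel_a = sA,
                         sel_b = sB, exclude_ns = config$exclude_ns)
        p <- file.path(out_dir, paste0("distance_", nm, "_", lab, ".csv"))
        .write_series_csv(series, p)
        record(paste0("distance_", nm, "_", lab), p)
      }
    }
  })

  if (config$run_pca) run_stage("pca", function() {
    all_trajs <- unlist(systems, recursive = FALSE)
    model <- fit_pca(all_trajs)
    retained <- retain_pcs(model, config$pc_retention)
    jsonlite::write_json(
      list(variance_fractions = model$variance_fractions,
           eigenvalues = model$eigenvalues, retained_pcs = retained),
      file.path(out_dir, "pca_model.json"), digits = NA)
    record("pca_model", file.path(out_dir, "pca_model.json"))
    for (lab in names(systems)) for (i in seq_along(systems[[lab]])) {
      sc <- project_scores(model, systems[[lab]][[i]])
      p <- file.path(out_dir, sprintf("pca_scores_%s_r%d.csv", lab, i))
      utils::write.csv(data.frame(system = lab, replica = i,
                                  frame = seq_len(nrow(sc)), sc),
                       p, row.names = FALSE)
      record(sprintf("pca_scores_%s_r%d", lab, i), p)
    }
  })

  if (!is.null(config$contact_specs)) run_stage("contacts", function() {
    tab <- interaction_table(lapply(systems, identity),
                             config$contact_specs,
                             min_reporting_delta = 0,
                             exclude_ns = config$exclude_ns)
    p <- file.path(out_dir, "contact_frequencies.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    record("contact_frequencies", p)
    hm <- sapply(names(systems), function(lab)
      vapply(config$contact_specs, function(sp) {
        series <- lapply(systems[[lab]], contact_frequency, spec = sp,
                         exclude_ns = config$exclude_ns)
        replica_heatmap(series, config$heatmap_threshold)
      }, 0L))
    hm <- matrix(hm, nrow = length(config$contact_specs),
                 dimnames = list(vapply(config$contact_specs,
                                        function(s) s$label, ""),
                                 names(systems)))
    p2 <- file.path(out_dir, "contact_replica_heatmap.csv")
    utils::write.csv(as.data.frame(hm), p2, row.names = TRUE)
    record("contact_replica_heatmap", p2)
  })

  if (config$run_sse) run_stage("sse", function() {
    for (lab in names(systems)) {
      series <- lapply(systems[[lab]], function(tr)
        percent_sse(tr, sel$ash, "helix",
                    exclude_ns = config$exclude_ns)$series)
      p <- file.path(out_dir, paste0("sse_", lab, ".csv"))
      .write_series_csv(series, p)
      record(paste0("sse_", lab), p)
    }
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Crystal-structure reference report
#'
#' Computes, from a two-chain structure, the per-subunit apex angle
#' (activation-segment helix / hinge / alphaC-helix) and the inter-subunit
#' cog distances for the interface triad (N-lobe section, ASH, alphaF-helix)
#' and the four N-lobe sub-intervals. These are the reference values that
#' trajectory metrics are compared against.
#'
#' @param structure a PDB path or a `Trajectory`/`Frame`.
#' @param selections named selection list as in [default_selections()]
#'   (chain field is overridden per subunit).
#' @return list with `angles` (data.frame chain/angle_deg) and `distances`
#'   (data.frame interval/distance_nm).
#' @export
crystal_reference_report <- function(structure,
                                     selections = default_selections()) {
  frame <- if (is.character(structure))
    get_frame(read_structure(structure), 1L)
  else if (inherits(structure, "Trajectory")) get_frame(structure, 1L)
  else structure
  top <- frame$topology
  chains <- unique(top$chain[!top$is_water])
  if (length(chains) < 2L)
    stop("selection error: reference report needs a two-chain structure")
  chains <- chains[1:2]
  with_chain <- function(s, ch) { s$chain_id <- ch; s }
  angles <- data.frame(
    chain = chains,
    angle_deg = vapply(chains, function(ch)
      segment_angle(frame, angle_definition(chain = ch)), 0))
  dist_names <- intersect(c("n_lobe", "ash", "alpha_f", "nlobe_116_120",
                            "nlobe_120_127", "nlobe_164_168",
                            "nlobe_111_114"), names(selections))
  distances <- data.frame(
    interval = dist_names,
    distance_nm = vapply(dist_names, function(nm)
      cog_distance(frame, with_chain(selections[[nm]], chains[1]),
                   with_chain(selections[[nm]], chains[2])), 0))
  rownames(distances) <- NULL
  list(angles = angles, distances = distances)
}
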