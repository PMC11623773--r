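#' Default end-to-end run configuration
#'
#' Nested named list with one section per stage. Unknown keys are rejected
#' by [validate_run_config()] before any compute; the resolved
#' configuration is written beside every run's outputs.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "cfdecon-run",
    simulation = list(
      n_cell_types = 5, n_cpgs = 5000, n_chroms = 1,
      spacing_model = "island", spacing_bp = 25, gap_bp = 6000,
      island_cpgs = c(6, 12), blocks_per_cell_type = 20,
      low_propensity = 0.10, high_propensity = 0.90,
      frag_len_mean = 5, frag_len_max = 20, miscall_rate = 0.005,
      coverage = 10
    ),
    segmentation = list(min_cpg = 4, max_bp = 5000, homogeneity_tol = 0.25),
    markers = list(min_diff = 0.3, alpha = 0.05, max_na_frac = 1 / 3,
                   min_depth = 5, direction = "hypomethylated", k = 25),
    deconvolution = list(u_threshold = 0.25, m_threshold = 0.75,
                         min_fragment_cpgs = 3, min_fragments_per_marker = 1,
                         detection_epsilon = 0),
    spikein = list(fractions = c(0, 0.01, 0.05, 0.10), coverages = 10,
                   replicates = 3, n_ref_reps = 3, ref_coverage = 30,
                   background_coverage = 12, spike_coverage = 30),
    pk = list(d = 0.03, t_half = 114, vd = 3.0, n_cells = 5e5,
              genome_mass = 6.46, duration = 1440, total_cfdna = 297,
              durations_years = 1:5, d_values = c(0.03, 3e-5))
  ), class = "run_config")
}

#' Validate a run configuration against the default template
#'
#' Every key must exist in [default_run_config()]; unknown keys are an
#' error (catching typos before any compute). Missing keys inherit the
#' default.
#'
#' @param config Nested list (e.g. from [read_run_config()]).
#' @return The merged, validated `run_config`.
#' @export
validate_run_config <- function(config) {
  template <- default_run_config()
  unknown <- setdiff(names(config), names(template))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in names(config)) {
    if (is.list(template[[sec]]) && !is.null(names(template[[sec]]))) {
      if (!is.list(config[[sec]])) stop("section '", sec, "' must be a mapping")
      bad <- setdiff(names(config[[sec]]), names(template[[sec]]))
      if (length(bad)) {
        stop("unknown configuration key(s) in '", sec, "': ",
             paste(bad, collapse = ", "))
      }
      template[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      template[[sec]] <- config[[sec]]
    }
  }
  template
}

#' Read a YAML run configuration
#' @param path Path to a YAML file with (a subset of) the sections of
#'   [default_run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the whole pipeline: simulate, segment, select markers, build the
#' atlas, evaluate spike-ins, and compute the pharmacokinetic bound
#'
#' Stages run in order, each logging its parameters and counts; a stage
#' failure halts the run naming the stage, with earlier outputs persisted.
#' All tabular outputs are TSV; the resolved configuration is written as
#' YAML beside them. Re-running with the same seed reproduces every output
#' byte for byte.
#'
#' @param config A `run_config` (list), or a path to a YAML file.
#' @param out_dir Output directory (created); defaults to
#'   `config$out_dir`.
#' @return Invisibly, a list with the key in-memory objects and output
#'   paths.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim_cfg <- do.call(sim_config, c(config$simulation, list(seed = config$seed)))
  mk_cfg <- do.call(marker_config, config$markers)
  dc_cfg <- do.call(deconv_config, config$deconvolution)
  sp <- config$spikein

  assets <- stage("simulate+segment+markers+atlas", {
    a <- prepare_spikein_assets(
      sim_cfg, n_ref_reps = sp$n_ref_reps, ref_coverage = sp$ref_coverage,
      n_individuals = sp$replicates,
      background_coverage = sp$background_coverage,
      spike_coverage = sp$spike_coverage,
      min_cpg_values = config$segmentation$min_cpg,
      max_bp = config$segmentation$max_bp,
      marker_cfg = mk_cfg, deconv_cfg = dc_cfg, seed = config$seed)
    write_ledger_bed(a$refs, file.path(out_dir, "planted_blocks.bed"))
    pm <- a$per_min_cpg[[1]]
    write_blocks(pm$blocks, file.path(out_dir, "blocks.tsv"))
    message(sprintf("  %d blocks, %d candidate markers",
                    nrow(pm$blocks), nrow(pm$union_markers)))
    sel <- do.call(rbind, lapply(a$refs$cell_types, function(ct) {
      suppressWarnings(rank_and_select(pm$candidates[[ct]], mk_cfg$k,
                                       cell_type = ct))
    }))
    write_markers(sel, file.path(out_dir, "markers.tsv"))
    ids <- paste(sel$start_cpg, sel$cell_type)
    pos <- match(ids, paste(pm$union_markers$start_cpg, pm$union_markers$cell_type))
    atlas <- atlas_from_counts(lapply(pm$counts, function(m) m[pos, , drop = FALSE]),
                               sel, dc_cfg)
    write_atlas(atlas, file.path(out_dir, "atlas.tsv"))
    a
  })

  results <- stage("spike-eval", {
    grid <- spike_grid_config(fractions = sp$fractions,
                              coverages = sp$coverages,
                              k = mk_cfg$k,
                              min_cpg = config$segmentation$min_cpg,
                              replicates = sp$replicates,
                              base_seed = config$seed)
    res <- run_spikein_grid(grid, assets)
    utils::write.table(res, file.path(out_dir, "spikein_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary(res), file.path(out_dir, "spikein_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("  %d grid records", nrow(res)))
    res
  })

  pk <- stage("pk", {
    pk_cfg <- config$pk
    params <- pk_params(d = pk_cfg$d, t_half = pk_cfg$t_half, vd = pk_cfg$vd,
                        n_cells = pk_cfg$n_cells,
                        genome_mass = pk_cfg$genome_mass,
                        duration = pk_cfg$duration,
                        total_cfdna = pk_cfg$total_cfdna)
    grid <- scenario_grid(durations = pk_cfg$durations_years * 525960,
                          d_values = pk_cfg$d_values, params = params)
    utils::write.table(grid, file.path(out_dir, "pk_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(point = steady_state_concentration(params), grid = grid)
  })

  invisible(list(assets = assets, results = results, pk = pk,
                 out_dir = out_dir))
}
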