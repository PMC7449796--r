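#' Run configuration for the full analysis
#'
#' Either an input stack (`stack_path`) or a phantom specification
#' (`phantom`) must be given. Channel names default to the phantom
#' generator's conventions and can be remapped for real stacks.
#'
#' @param stack_path path to a TIFF written by [write_stack()], or `NULL`.
#' @param phantom a [phantom_config()], or `NULL`.
#' @param channels named list mapping roles (`rfp`, `gfp`, `trachea`) to
#'   channel names.
#' @param segmentation list of [segment_nuclei()] parameters.
#' @param tracheal list of [extract_tracheal_map()] parameters.
#' @param fit_method [fit_decay()] method.
#' @param compartment_mask_path optional TIFF of a compartment mask
#'   (1 = central brain, 2 = optic lobe); phantoms derive it from their
#'   config.
#' @param cell_types `NULL` to skip cell typing, or a [cell_type_rules()].
#' @param out_dir output directory, or `NULL` to skip writing artifacts.
#' @param seed seed recorded in the report and used for any stochastic
#'   stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(stack_path = NULL, phantom = NULL,
                       channels = list(rfp = "rfp", gfp = "gfp",
                                       trachea = "trachea"),
                       segmentation = list(), tracheal = list(),
                       fit_method = "least_squares",
                       compartment_mask_path = NULL, cell_types = NULL,
                       out_dir = NULL, seed = 1L) {
  if (is.null(stack_path) && is.null(phantom)) {
    stop("run_config needs either stack_path or a phantom config")
  }
  structure(list(stack_path = stack_path, phantom = phantom,
                 channels = channels, segmentation = segmentation,
                 tracheal = tracheal, fit_method = fit_method,
                 compartment_mask_path = compartment_mask_path,
                 cell_types = cell_types, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file; the `phantom` section is passed to
#'   [phantom_config()], everything else to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$phantom)) {
    raw$phantom <- do.call(phantom_config, raw$phantom)
  }
  if (!is.null(raw$cell_types)) {
    raw$cell_types <- do.call(cell_type_rules, raw$cell_types)
  }
  do.call(run_config, raw)
}

#' Run the full hypoxia-mapping pipeline
#'
#' Simulate (or load) -> segment nuclei -> measure ratios -> extract
#' tracheal map -> distances -> fit the oxygenation decay model -> render
#' the predicted-ratio heatmap -> compartment assignment -> optional cell
#' typing -> group summaries -> central brain vs optic lobe comparison.
#' Artifacts (tables, fit JSON, prediction map) are written to
#' `config$out_dir` when set.
#'
#' @param config a [run_config()].
#' @return A `run_report`: list with per-stage counts, the parameters
#'   used, the nucleus table, the decay fit, group summaries, the
#'   compartment test, the file manifest and the package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  phantom <- NULL
  stack <- stage("input", {
    if (!is.null(config$phantom)) {
      phantom <- generate_phantom(config$phantom)
      phantom$stack
    } else {
      read_stack(config$stack_path)
    }
  })
  for (role in c("rfp", "gfp", "trachea")) {
    ch <- config$channels[[role]]
    if (is.null(ch) || !(ch %in% stack$channel_names)) {
      stop("config is missing required channel '", role, "' (",
           if (is.null(ch)) "unmapped" else ch, ")")
    }
  }
  seg <- stage("segment", do.call(segment_nuclei, c(
    list(stack = stack, channel = config$channels$rfp),
    config$segmentation)))
  table <- stage("measure", measure_ratios(
    stack, seg$labels, gfp_channel = config$channels$gfp,
    rfp_channel = config$channels$rfp, nuclei = seg$nuclei))
  table <- stage("normalize", normalize_to_hemisphere(table))
  trachea <- stage("tracheal_map", do.call(extract_tracheal_map, c(
    list(stack = stack, channel = config$channels$trachea),
    config$tracheal)))
  fit <- NULL
  pred_map <- NULL
  if (nrow(trachea$coords_um) > 0) {
    table <- stage("distance", add_distances(table, trachea))
    ok <- !table$flagged
    fit <- stage("fit", fit_decay(table$dist_um[ok], table$inv_ratio[ok],
                                  method = config$fit_method))
    pred_map <- stage("predict", render_prediction_map(
      fit, seg$labels, table, stack$voxel_size))
  }
  cmask <- stage("compartments", {
    if (!is.null(config$phantom)) {
      compartment_mask(config$phantom)
    } else if (!is.null(config$compartment_mask_path)) {
      m <- read_stack(config$compartment_mask_path)
      array(as.integer(round(get_channel(m, 1))), dim(m$data)[2:4])
    } else NULL
  })
  if (!is.null(cmask)) {
    table <- stage("compartments",
                   assign_compartment(table, cmask, stack$voxel_size))
  }
  if (!is.null(config$cell_types)) {
    table <- stage("celltypes", assign_cell_types(
      stack, seg$labels, table, config$cell_types,
      ne_mask = ne_mask_from_stack(stack)))
  }
  group_keys <- intersect(c("cell_type", "compartment"), names(table))
  summaries <- if (length(group_keys) > 0) {
    summarize_groups(table, group_keys)
  } else NULL
  comp_test <- NULL
  if ("compartment" %in% names(table)) {
    cb <- table$ratio[table$compartment == "central_brain" & !table$flagged]
    ol <- table$ratio[table$compartment == "optic_lobe" & !table$flagged]
    if (length(cb) >= 3 && length(ol) >= 3) {
      comp_test <- stage("stats", compare_groups(cb, ol))
    }
  }
  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- stage("write", {
      fits <- list()
      if (!is.null(fit)) {
        fits$decay_fit <- list(params = unclass(fit$params), se = fit$se,
                               residual_rms = fit$residual_rms, n = fit$n,
                               method = fit$method,
                               converged = fit$converged)
      }
      if (!is.null(comp_test)) fits$compartment_test <- unclass(comp_test)
      tabs <- list(nuclei = table)
      if (!is.null(summaries)) tabs$group_summaries <- summaries
      m <- write_results(tabs, fits, config$out_dir)
      if (!is.null(pred_map)) {
        write_stack(pred_map, file.path(config$out_dir,
                                        "predicted_ratio.tif"))
      }
      m
    })
  }
  structure(list(
    n_nuclei = nrow(table), n_flagged = sum(table$flagged),
    n_tracheal_voxels = nrow(trachea$coords_um),
    parameters = list(segmentation = config$segmentation,
                      tracheal = config$tracheal,
                      fit_method = config$fit_method,
                      channels = config$channels),
    seed = config$seed, table = table, fit = fit, summaries = summaries,
    compartment_test = comp_test, manifest = manifest,
    phantom_truth = if (!is.null(phantom)) phantom$truth else NULL,
    version = as.character(utils::packageVersion("hypoxiamap"))),
    class = "run_report")
}

# neuroepithelium region mask from the phantom's marker channel, if present
ne_mask_from_stack <- function(stack) {
  ch <- "marker_neuroepithelium"
  if (!(ch %in% stack$channel_names)) return(NULL)
  get_channel(stack, ch) > 0.5
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", x$n_nuclei, "nuclei (", x$n_flagged, "flagged ),",
      x$n_tracheal_voxels, "tracheal voxels, seed", x$seed, "\n")
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$compartment_test)) print(x$compartment_test)
  invisible(x)
}

#' Command-line interface dispatcher
#'
#' Thin wrapper used by the `hypoxiamap` CLI script
#' (`system.file("cli", "hypoxiamap.R", package = "hypoxiamap")`).
#' Subcommands: `simulate` (write a phantom stack and ground truth), `run`
#' (full pipeline from a config file) and `fit` (decay fit from a nucleus
#' CSV with `dist_um` and `inv_ratio` columns). Each accepts `--config`,
#' `--seed`, `--out` and `--condition` as relevant.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
hypoxia_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hypoxiamap <simulate|run|fit> [options]",
    "  simulate --out DIR [--seed N] [--condition normoxia|hyperoxia|hypoxia]",
    "  run      --config FILE.yaml|json [--out DIR] [--seed N]",
    "  fit      --table FILE.csv --out FILE.json [--method least_squares|odr]",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  if (!is.null(opts$error)) { message(opts$error, "\n", usage); return(invisible(1L)) }
  status <- tryCatch({
    switch(cmd,
      simulate = {
        if (is.null(opts$out)) stop("simulate requires --out")
        cfg <- phantom_config(
          condition = if (is.null(opts$condition)) "normoxia" else opts$condition,
          seed = if (is.null(opts$seed)) 1L else as.integer(opts$seed))
        ph <- generate_phantom(cfg)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        write_stack(ph$stack, file.path(opts$out, "phantom.tif"))
        write_results(list(ground_truth_nuclei = ph$truth$nuclei),
                      list(ground_truth_model = unclass(ph$truth$model)),
                      opts$out)
        0L
      },
      run = {
        if (is.null(opts$config)) stop("run requires --config")
        cfg <- read_run_config(opts$config)
        if (!is.null(opts$out)) cfg$out_dir <- opts$out
        if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
        rep <- run_pipeline(cfg)
        print(rep)
        0L
      },
      fit = {
        if (is.null(opts$table) || is.null(opts$out)) {
          stop("fit requires --table and --out")
        }
        tab <- utils::read.csv(opts$table)
        if (!all(c("dist_um", "inv_ratio") %in% names(tab))) {
          stop("table must have dist_um and inv_ratio columns")
        }
        method <- if (is.null(opts$method)) "least_squares" else opts$method
        f <- fit_decay(tab$dist_um, tab$inv_ratio, method = method)
        jsonlite::write_json(list(params = unclass(f$params), se = f$se,
                                  residual_rms = f$residual_rms, n = f$n,
                                  converged = f$converged),
                             opts$out, auto_unbox = TRUE, digits = NA)
        0L
      },
      { message("unknown subcommand '", cmd, "'\n", usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

parse_cli_opts <- function(args) {
  known <- c("--config", "--seed", "--out", "--condition", "--table",
             "--method", "--verbose")
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!(a %in% known)) return(list(error = paste0("unknown flag: ", a)))
    if (a == "--verbose") { opts$verbose <- TRUE; i <- i + 1L; next }
    if (i == length(args)) return(list(error = paste0(a, " needs a value")))
    opts[[sub("^--", "", a)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
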