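#' Run a config-driven analysis pipeline
#'
#' Executes generate / fit / simulate / screen stages from a single
#' configuration (a YAML file or an equivalent nested list), writing every
#' table as TSV into `output_dir` together with a JSON manifest recording
#' inputs, outputs (with MD5 content hashes), per-stage seeds, package
#' version and wall time. A fixed top-level seed makes the whole run — and
#' therefore every output hash — reproducible.
#'
#' The configuration is validated before any stage runs (schema version tag,
#' referenced input files, scenario consistency such as a global-inhibition
#' simulation carrying `global_pa`), so misconfiguration surfaces
#' immediately rather than mid-run. Per-stage seeds are derived
#' deterministically from the top-level seed (`seed * 1009 + 101 * stage
#' index, mod 2^31 - 1`), so any stage can be re-run in isolation.
#'
#' Supported stage blocks, executed in dependency order when present:
#' `generate` (sub-blocks `clonogenic`, `growth`, `expression`, `qpcr`,
#' `dye`, each forwarding its fields to the matching `gen_*()` generator),
#' `fit_lq`, `fit_growth`, `doublings`, `de_screen`, `ddct`, `dye_profile`
#' and `simulate` (fields forwarded to [ca_params()] / [run_scenario()]).
#' Fit stages consume the files generated upstream unless an explicit
#' `input` path is given; a missing upstream file is a dependency error
#' naming the stage.
#'
#' @param config Path to a YAML file, or a list.
#' @param output_dir Output directory (created if needed); overrides
#'   `config$output_dir`.
#' @param seed Top-level seed; overrides `config$seed`.
#' @return The manifest, invisibly, as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL) {
  t0 <- Sys.time()
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out <- output_dir %||% config$output_dir %||%
    stop("no output_dir configured", call. = FALSE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  validate_pipeline_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage_order <- c("generate", "fit_lq", "fit_growth", "doublings",
                   "de_screen", "ddct", "dye_profile", "simulate")
  stages <- config$stages
  outputs <- character()
  seeds <- list()
  add <- function(path) outputs <<- c(outputs, path)
  path_of <- function(f) file.path(out, f)
  need_upstream <- function(stage, f) {
    p <- path_of(f)
    if (!file.exists(p)) {
      stop(sprintf("stage '%s' is missing upstream output '%s'", stage, f),
           call. = FALSE)
    }
    p
  }

  idx <- 0
  for (stage in intersect(stage_order, names(stages))) {
    idx <- idx + 1
    s_seed <- (seed * 1009 + 101 * idx) %% 2147483647L
    seeds[[stage]] <- s_seed
    blk <- stages[[stage]]

    if (stage == "generate") {
      gens <- list(
        clonogenic = function(a) do.call(gen_clonogenic, a),
        growth = function(a) do.call(gen_growth_trajectories, a),
        qpcr = function(a) {
          a$conditions <- dplyr::as_tibble(a$conditions)
          do.call(gen_qpcr, a)
        },
        dye = function(a) do.call(gen_dye_intensities, a)
      )
      for (what in intersect(names(gens), names(blk))) {
        args <- blk[[what]]
        args$seed <- args$seed %||%
          ((s_seed + match(what, names(gens))) %% 2147483647L)
        readr::write_tsv(gens[[what]](args), path_of(paste0(what, ".tsv")))
        add(path_of(paste0(what, ".tsv")))
      }
      if ("expression" %in% names(blk)) {
        args <- blk$expression
        args$seed <- args$seed %||% ((s_seed + 11L) %% 2147483647L)
        study <- do.call(gen_expression_study, args)
        write_expression_study(study, path_of("expression_matrix.tsv"),
                               path_of("expression_samples.tsv"))
        add(path_of("expression_matrix.tsv"))
        add(path_of("expression_samples.tsv"))
      }
    } else if (stage == "fit_lq") {
      src <- blk$input %||% need_upstream(stage, "clonogenic.tsv")
      rec <- readr::read_tsv(src, show_col_types = FALSE)
      fit <- fit_lq(rec, method = blk$method %||% "least_squares")
      readr::write_tsv(tidy(fit), path_of("lq_fit.tsv"))
      add(path_of("lq_fit.tsv"))
    } else if (stage == "fit_growth") {
      src <- blk$input %||% need_upstream(stage, "growth.tsv")
      tr <- readr::read_tsv(src, show_col_types = FALSE)
      fits <- tr |>
        dplyr::group_by(.data$dose, .data$subject) |>
        dplyr::group_modify(function(d, key) {
          f <- try(fit_exponential_growth(
            data.frame(time = d$time, value = d$value),
            min_value = blk$min_value %||% 200), silent = TRUE)
          if (inherits(f, "try-error")) {
            dplyr::tibble(rate = NA_real_, r_squared = NA_real_,
                          doubling_time = NA_real_, n_points = 0L)
          } else {
            dplyr::tibble(rate = f$rate, r_squared = f$r_squared,
                          doubling_time = f$doubling_time,
                          n_points = f$n_points)
          }
        }) |>
        dplyr::ungroup()
      readr::write_tsv(fits, path_of("growth_fits.tsv"))
      add(path_of("growth_fits.tsv"))
    } else if (stage == "doublings") {
      src <- blk$input %||%
        stop("stage 'doublings' needs an `input` passage table",
             call. = FALSE)
      ps <- readr::read_tsv(src, show_col_types = FALSE)
      readr::write_tsv(cumulative_population_doublings(ps),
                       path_of("doublings.tsv"))
      add(path_of("doublings.tsv"))
    } else if (stage == "de_screen") {
      mp <- blk$matrix %||% need_upstream(stage, "expression_matrix.tsv")
      sp <- blk$samples %||% need_upstream(stage, "expression_samples.tsv")
      study <- read_expression_study(mp, sp)
      res <- de_pipeline(study, q = blk$q %||% 0.10,
                         fc_threshold = blk$fc_threshold %||% 1.5)
      readr::write_tsv(dplyr::as_tibble(res), path_of("de_screen.tsv"))
      add(path_of("de_screen.tsv"))
    } else if (stage == "ddct") {
      src <- blk$input %||% need_upstream(stage, "qpcr.tsv")
      rec <- readr::read_tsv(src, show_col_types = FALSE)
      readr::write_tsv(
        ddct_fold_change(rec, control_condition = blk$control_condition),
        path_of("ddct.tsv"))
      add(path_of("ddct.tsv"))
    } else if (stage == "dye_profile") {
      src <- blk$input %||% need_upstream(stage, "dye.tsv")
      x <- readr::read_tsv(src, show_col_types = FALSE)
      prof <- fit_division_profile(x$intensity,
                                   reference_mu0 = blk$reference_mu0,
                                   G = blk$G %||% 6)
      readr::write_tsv(tidy(prof), path_of("division_profile.tsv"))
      add(path_of("division_profile.tsv"))
    } else if (stage == "simulate") {
      par_args <- blk$params %||% list()
      params <- do.call(ca_params, par_args)
      reps <- blk$reps %||% 1
      res <- withr::with_seed(s_seed, {
        purrr::map(seq_len(reps), function(r) {
          run_scenario(
            params, n0 = blk$n0 %||% 2000,
            surviving_fraction = blk$surviving_fraction %||% 1,
            scenario = blk$scenario %||% "none",
            t_max = blk$t_max %||% 60,
            detection_size = blk$detection_size %||% 500,
            stop_size = blk$stop_size %||% 8000)
        })
      })
      traj <- purrr::imap_dfr(res, function(r, i) {
        dplyr::mutate(r$trajectory, rep = i)
      })
      readr::write_tsv(traj, path_of("simulation_trajectories.tsv"))
      add(path_of("simulation_trajectories.tsv"))
      readr::write_tsv(purrr::map_dfr(res, glance),
                       path_of("simulation_summary.tsv"))
      add(path_of("simulation_summary.tsv"))
      hist <- purrr::imap_dfr(res, function(r, i) {
        if (is.null(r$final_state)) return(dplyr::tibble())
        dplyr::mutate(dormancy_histogram(r$final_state), rep = i)
      })
      readr::write_tsv(hist, path_of("dormancy_histogram.tsv"))
      add(path_of("dormancy_histogram.tsv"))
    }
  }

  manifest <- list(
    schema_version = config$schema_version,
    package_version = as.character(utils::packageVersion("regrowr")),
    seed = seed,
    stage_seeds = seeds,
    config = config,
    outputs = lapply(unique(outputs), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Fail fast on malformed configs, before any stage runs.
validate_pipeline_config <- function(config) {
  if (is.null(config$schema_version)) {
    stop("config lacks a `schema_version` tag", call. = FALSE)
  }
  if (!is.list(config$stages) || length(config$stages) == 0) {
    stop("config has no `stages`", call. = FALSE)
  }
  sim <- config$stages$simulate
  if (!is.null(sim) && identical(sim$scenario, "global") &&
      is.null(sim$params$global_pa)) {
    stop("simulate: global scenario requires params$global_pa",
         call. = FALSE)
  }
  if (!is.null(sim) && identical(sim$scenario, "local") &&
      (sim$params$inhibition_radius %||% 0) < 1) {
    stop("simulate: local scenario requires params$inhibition_radius >= 1",
         call. = FALSE)
  }
  for (stage in names(config$stages)) {
    blk <- config$stages[[stage]]
    for (f in intersect(c("input", "matrix", "samples"), names(blk))) {
      if (is.character(blk[[f]]) && !file.exists(blk[[f]])) {
        stop(sprintf("stage '%s': input file '%s' does not exist",
                     stage, blk[[f]]), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
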