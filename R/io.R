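# Trajectory serialisation and run configuration.
#
# Trajectories go to long-format CSV (path_id, step, time, state), one row per
# grid point, numbers written with full (17 significant digit) precision so a
# round trip reproduces the states bitwise and identical configurations give
# byte-identical files.

#' Write an ensemble to CSV
#'
#' @param paths A `feller_paths` object (or a data frame with columns
#'   `path_id`, `step`, `time`, `state`).
#' @param file Destination path.
#' @return The destination, invisibly.
#' @export
write_paths_csv <- function(paths, file) {
  cols <- c("path_id", "step", "time", "state")
  if (nrow(paths) == 0 || !all(cols %in% names(paths))) {
    stop("`paths` must be a non-empty trajectory table with columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  lines <- c(paste(cols, collapse = ","),
             sprintf("%d,%d,%.17g,%.17g",
                     as.integer(paths$path_id), as.integer(paths$step),
                     paths$time, paths$state))
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(file)
}

#' Read a trajectory CSV written by [write_paths_csv()]
#'
#' @param file Source path.
#' @return A data frame with columns `path_id`, `step`, `time`, `state`; the
#'   states are bitwise identical to the written ones.
#' @export
read_paths_csv <- function(file) {
  utils::read.csv(file, colClasses = c(path_id = "integer", step = "integer",
                                       time = "numeric", state = "numeric"))
}

# --- function descriptors for JSON configs --------------------------------

# Named functional forms so custom families need no code: every example
# family's parameter/mixing function is expressible in one of these.
resolve_function_descriptor <- function(desc) {
  if (is.numeric(desc) && length(desc) == 1) {
    return(as_state_fn(desc))
  }
  stopifnot(is.list(desc), !is.null(desc$form))
  form <- desc$form
  switch(form,
    constant = as_state_fn(desc$value),
    triangle = {
      base <- desc$base %||% 0
      amplitude <- desc$amplitude %||% 1
      period <- desc$period %||% (2 * pi)
      function(x) base + amplitude * triangle_wave(2 * pi * x / period)
    },
    tanh = {
      amplitude <- desc$amplitude %||% 1
      scale <- desc$scale %||% 1
      center <- desc$center %||% 0
      offset <- desc$offset %||% 0
      function(x) offset + amplitude * tanh((x - center) / scale)
    },
    gaussian_bump = {
      base <- desc$base %||% 0
      height <- desc$height %||% 1
      width <- desc$width %||% 1
      center <- desc$center %||% 0
      function(x) base + height * exp(-(x - center)^2 / (2 * width^2))
    },
    piecewise_linear = {
      xs <- unlist(desc$x); ys <- unlist(desc$y)
      stopifnot(length(xs) == length(ys), length(xs) >= 2)
      function(x) stats::approx(xs, ys, xout = x, rule = 2)$y
    },
    stop(sprintf("unknown function form '%s'", form), call. = FALSE)
  )
}

resolve_component_descriptor <- function(desc) {
  stopifnot(is.list(desc), !is.null(desc$type))
  switch(desc$type,
    brownian = levy_brownian(desc$drift %||% 0, desc$sigma %||% 1),
    poisson = levy_poisson(desc$rate %||% 1),
    stable = levy_stable(desc$alpha, desc$scale %||% 1),
    gamma = levy_gamma(desc$shape_rate %||% 1, desc$rate %||% 1),
    nig = levy_nig(desc$alpha, desc$beta %||% 0, desc$delta %||% 1,
                   desc$mu %||% 0),
    meixner = levy_meixner(desc$a %||% 1, desc$b %||% 0, desc$d %||% 1,
                           desc$m %||% 0),
    stop(sprintf("unknown component type '%s'", desc$type), call. = FALSE)
  )
}

# model: either a registry name, or a list describing a custom family:
#   {"kind": "mixture", "components": [...], "regions": [[lo, hi], ...],
#    "epsilon": 1}
#   {"kind": "stable" | "nig" | "meixner", "params": {name: descriptor},
#    "eps0": 0.01}
resolve_model <- function(model) {
  if (inherits(model, "levy_family")) return(model)
  if (is.character(model) && length(model) == 1) {
    return(named_family(model))
  }
  stopifnot(is.list(model), !is.null(model$kind))
  if (model$kind == "mixture") {
    components <- lapply(model$components, resolve_component_descriptor)
    mixers <- region_mixers(lapply(model$regions, unlist),
                            epsilon = model$epsilon %||% 1)
    mixture_family(components, mixers, label = model$label %||% "custom-mixture")
  } else {
    param_fns <- lapply(model$params, resolve_function_descriptor)
    parameter_field_family(model$kind, param_fns,
                           eps0 = model$eps0 %||% 1e-2,
                           label = model$label %||% paste0("custom-", model$kind))
  }
}

#' Read a simulation run configuration from JSON
#'
#' The file mirrors the command-line flags: `model` (registry name or a
#' custom-family descriptor), `x0`, `horizon` (alias `T`), `h`, `n_paths`,
#' `seed`, `out`, optional `plot`. Custom families are described by component
#' kind plus named function descriptors (`constant`, `triangle`, `tanh`,
#' `gaussian_bump`, `piecewise_linear`).
#'
#' @param file Path to the JSON configuration.
#' @return A `run_config` list.
#' @export
read_run_config <- function(file) {
  cfg <- jsonlite::fromJSON(file, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  run_config(model = cfg$model, x0 = cfg$x0 %||% 0,
             horizon = cfg$horizon %||% cfg$T %||% 10,
             h = cfg$h %||% 1e-3, n_paths = cfg$n_paths %||% 1,
             seed = cfg$seed %||% 1, out = cfg$out, plot = cfg$plot)
}

#' @rdname read_run_config
#' @param model Registry name, custom descriptor list, or `levy_family`.
#' @param x0,horizon,h,n_paths,seed Simulation parameters (see
#'   [simulate_feller()]).
#' @param out Destination CSV path, or `NULL` to skip writing.
#' @param plot Optional destination for a color-coded path plot (PNG).
#' @export
run_config <- function(model, x0 = 0, horizon = 10, h = 1e-3, n_paths = 1,
                       seed = 1, out = NULL, plot = NULL) {
  validate_config(x0, horizon, h, n_paths)
  structure(list(model = model, x0 = x0, horizon = horizon, h = h,
                 n_paths = n_paths, seed = seed, out = out, plot = plot),
            class = "run_config")
}

#' Execute a simulation run configuration
#'
#' Resolves the model, simulates the ensemble, writes the trajectory CSV
#' (when `out` is set) and the color-coded plot (when `plot` is set), and
#' logs the run parameters. Identical configurations produce byte-identical
#' CSVs.
#'
#' @param config A `run_config` (see [run_config()]/[read_run_config()]).
#' @param quiet Suppress the log message.
#' @return The simulated `feller_paths`, invisibly.
#' @export
run_simulate <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  family <- resolve_model(config$model)
  t0 <- proc.time()[["elapsed"]]
  paths <- simulate_feller(family, x0 = config$x0, horizon = config$horizon,
                           h = config$h, n_paths = config$n_paths,
                           seed = config$seed)
  if (!is.null(config$out)) write_paths_csv(paths, config$out)
  if (!is.null(config$plot)) {
    plot_paths(paths, value_fn = family$value_fn, file = config$plot)
  }
  if (!quiet) {
    message(sprintf(
      "model=%s seed=%s h=%g T=%g K=%d n_paths=%d elapsed=%.2fs%s",
      family$label, format(config$seed), config$h, config$horizon,
      max(paths$step), config$n_paths, proc.time()[["elapsed"]] - t0,
      if (is.null(config$out)) "" else paste0(" out=", config$out)))
  }
  invisible(paths)
}
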