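.commands <- c("simulate", "fixed-points", "thresholds", "continue",
               "boundary", "sweep", "compare-variants")

#' Load and validate a run specification
#'
#' Builds a fully validated run specification from a YAML config file
#' and/or an override list (CLI flags).  Every default that is filled in
#' is reported via \code{message()} so a run is reproducible from its log
#' alone.  Physically inadmissible values (negative rates, \code{delta}
#' outside \eqn{[0,1]}, unknown keys or presets) are rejected before any
#' computation starts.
#'
#' Recognized keys: \code{command}, \code{model} ("simple"/"detailed"),
#' \code{preset}, \code{set} (named list of dimensional parameter
#' overrides in SI units as documented in the parameter constructors),
#' \code{variant}, \code{horizon}, \code{s0} (named list), \code{param},
#' \code{range}, \code{steps} (continuation), \code{param_x},
#' \code{param_y}, \code{xlim}, \code{ylim}, \code{resolution},
#' \code{log_x}, \code{log_y} (boundary), \code{beta_grid},
#' \code{Gc_grid}, \code{delta}, \code{variants} (sweeps), \code{rtol},
#' \code{atol}, \code{out}.
#'
#' @param path optional YAML config file
#' @param args optional named list of overrides (highest precedence)
#' @param quiet suppress default-filling messages?
#' @return a validated list of class \code{run_spec}
#' @export
load_run_spec <- function(path = NULL, args = NULL, quiet = FALSE) {
  spec <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    spec <- yaml::read_yaml(path)
  }
  for (k in names(args)) spec[[k]] <- args[[k]]

  known <- c("command", "model", "preset", "set", "variant", "horizon",
             "s0", "param", "range", "steps", "param_x", "param_y",
             "xlim", "ylim", "resolution", "log_x", "log_y", "beta_grid",
             "Gc_grid", "delta", "variants", "rtol", "atol", "out")
  bad <- setdiff(names(spec), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(spec$command) || !spec$command %in% .commands)
    stop("'command' must be one of: ", paste(.commands, collapse = ", "),
         call. = FALSE)

  note <- function(key, value) {
    if (!quiet)
      message(sprintf("run_spec default: %s = %s", key,
                      paste(format(value), collapse = ",")))
    value
  }
  if (is.null(spec$preset)) spec$preset <- note("preset", "fig1-simple")
  if (!spec$preset %in% preset_names())
    stop("no such preset: ", spec$preset, call. = FALSE)
  if (is.null(spec$model))
    spec$model <- note("model",
                       if (grepl("detailed", spec$preset)) "detailed"
                       else "simple")
  spec$model <- match.arg(spec$model, c("simple", "detailed"))
  if (is.null(spec$variant)) spec$variant <- note("variant", "baseline")
  spec$variant <- match.arg(spec$variant, .variants)
  if (is.null(spec$rtol)) spec$rtol <- note("rtol", 1e-8)
  if (is.null(spec$atol)) spec$atol <- note("atol", 1e-12)
  if (is.null(spec$out)) spec$out <- note("out", "crisprcoevo-run")

  # build the parameter record: preset, then dimensional overrides
  dimp <- preset(spec$preset)
  for (k in names(spec$set)) {
    v <- spec$set[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("override '", k, "' must be a single number", call. = FALSE)
    dimp <- .with_param(dimp, k, v)
  }
  if (!is.null(spec$delta)) {
    .check_delta_strict(spec$delta)
    if (!spec$command %in% c("sweep", "compare-variants"))
      dimp <- .with_param(dimp, "delta", spec$delta)
  }
  p <- if (inherits(dimp, "dim_simple_params"))
    nondimensionalize_simple(dimp)
  else nondimensionalize_detailed(dimp)
  if (spec$model == "simple" && !inherits(p, "simple_params"))
    stop("preset '", spec$preset, "' is not a simple-model preset",
         call. = FALSE)
  if (spec$model == "detailed" && !inherits(p, "detailed_params"))
    stop("preset '", spec$preset, "' is not a detailed-model preset",
         call. = FALSE)

  if (spec$command %in% c("sweep", "compare-variants")) {
    if (is.null(spec$beta_grid))
      spec$beta_grid <- note("beta_grid", 10^seq(-2, 2, length.out = 9))
    if (is.null(spec$Gc_grid))
      spec$Gc_grid <- note("Gc_grid", 10^seq(0, 6, length.out = 9))
    if (!length(spec$beta_grid) || !length(spec$Gc_grid))
      stop("sweep grids must be nonempty", call. = FALSE)
  }
  if (spec$command == "continue") {
    if (is.null(spec$param)) spec$param <- note("param", "delta")
    if (is.null(spec$range)) spec$range <- note("range", c(0, 1.2))
    if (is.null(spec$steps)) spec$steps <- note("steps", 61L)
  }
  if (spec$command == "boundary") {
    if (is.null(spec$param_x)) spec$param_x <- note("param_x", "delta")
    if (is.null(spec$param_y)) spec$param_y <- note("param_y", "G_Qphi")
    if (is.null(spec$xlim)) spec$xlim <- note("xlim", c(0.01, 1.5))
    if (is.null(spec$ylim)) spec$ylim <- note("ylim", c(0.01, 4))
    if (is.null(spec$resolution)) spec$resolution <-
        note("resolution", 9L)
    if (is.null(spec$log_x)) spec$log_x <- FALSE
    if (is.null(spec$log_y)) spec$log_y <- FALSE
  }
  spec$params <- p
  spec$dim_params <- dimp
  structure(spec, class = "run_spec")
}

#' Execute a run specification
#'
#' Runs the requested command and writes its artifacts (long-format CSV
#' and/or JSON) plus a JSON run manifest carrying the complete parameter
#' set, solver settings, package version and wall time, so that every
#' artifact references the inputs that produced it.
#'
#' @param rs a \code{run_spec} from [load_run_spec()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a character vector of the files written
#' @export
execute_run <- function(rs, out_dir = ".") {
  stopifnot(inherits(rs, "run_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(out_dir, rs$out)
  t0 <- Sys.time()
  p <- rs$params
  files <- character()

  if (rs$command == "simulate") {
    s0 <- if (!is.null(rs$s0)) unlist(rs$s0) else NULL
    traj <- integrate_model(rs$model, p, s0 = s0, horizon = rs$horizon,
                            variant = rs$variant, rtol = rs$rtol,
                            atol = rs$atol)
    f <- paste0(stem, "-trajectory.csv")
    write_trajectory_csv(traj, f)
    files <- c(f, sub("\\.csv$", ".json", f))
  } else if (rs$command == "fixed-points") {
    if (rs$model == "simple") {
      fps <- fixed_points_simple(p)
      tab <- fixed_points_table(fps, p)
      rec <- lapply(fps, function(f)
        list(kind = f$kind, state = as.list(f$state),
             feasible = f$feasible, stability = f$stability))
    } else {
      fp <- phage_free_fixed_point(p, rs$variant)
      tab <- data.frame(kind = fp$kind, t(fp$state),
                        feasible = fp$feasible,
                        stability = fp$stability)
      rec <- list(F = list(kind = fp$kind, state = as.list(fp$state),
                           feasible = fp$feasible))
    }
    fj <- paste0(stem, "-fixed-points.json")
    jsonlite::write_json(rec, fj, auto_unbox = TRUE, digits = NA)
    fc <- paste0(stem, "-fixed-points.csv")
    utils::write.csv(tab, fc, row.names = FALSE)
    files <- c(fj, fc)
  } else if (rs$command == "thresholds") {
    rec <- if (rs$model == "simple") {
      c(delta_thresholds(p),
        tryCatch(coexistence_boundary(p),
                 error = function(e) list(K1 = NA, K2 = NA,
                                          note = conditionMessage(e))))
    } else list(delta_max = delta_max(p))
    f <- paste0(stem, "-thresholds.json")
    jsonlite::write_json(rec, f, auto_unbox = TRUE, digits = NA)
    files <- f
  } else if (rs$command == "continue") {
    br <- continue_fixed_point_1d(p, rs$param, rs$range, rs$steps,
                                  model = rs$model,
                                  variant = rs$variant)
    tabs <- lapply(Filter(Negate(is.null), br), function(b)
      data.frame(kind = b$kind, value = b$values, b$states,
                 feasible = b$feasible, stability = b$stability))
    f <- paste0(stem, "-branches.csv")
    utils::write.csv(do.call(rbind, tabs), f, row.names = FALSE)
    sp <- do.call(rbind, lapply(Filter(Negate(is.null), br), function(b)
      if (nrow(b$special_points))
        cbind(kind = b$kind, b$special_points) else NULL))
    fj <- paste0(stem, "-special-points.json")
    jsonlite::write_json(sp, fj, auto_unbox = TRUE, digits = NA)
    files <- c(f, fj)
  } else if (rs$command == "boundary") {
    cc <- trace_boundary_2d(rs$model, p, rs$param_x, rs$param_y,
                            rs$xlim, rs$ylim, rs$resolution,
                            variant = rs$variant, log_x = rs$log_x,
                            log_y = rs$log_y)
    f <- paste0(stem, "-boundary.csv")
    utils::write.csv(as.data.frame(cc), f, row.names = FALSE)
    files <- f
  } else if (rs$command == "sweep") {
    map <- sweep_regimes(p, rs$beta_grid, rs$Gc_grid, delta = rs$delta,
                         variant = rs$variant)
    f <- paste0(stem, "-regimes.csv")
    write_regime_map_csv(map, f)
    files <- f
  } else if (rs$command == "compare-variants") {
    variants <- rs$variants
    if (is.null(variants)) variants <- c("baseline", "no_abi")
    cmp <- compare_variants(p, rs$beta_grid, rs$Gc_grid,
                            delta = rs$delta, variants = variants)
    for (v in names(cmp$maps)) {
      f <- paste0(stem, "-regimes-", v, ".csv")
      write_regime_map_csv(cmp$maps[[v]], f)
      files <- c(files, f)
    }
    f <- paste0(stem, "-differences.csv")
    utils::write.csv(cmp$differences, f, row.names = FALSE)
    files <- c(files, f)
  }

  manifest <- list(
    command = rs$command, model = rs$model, preset = rs$preset,
    variant = rs$variant,
    dimensional_params = unclass(rs$dim_params),
    nondimensional_params = unclass(rs$params),
    solver = list(method = "lsoda", rtol = rs$rtol, atol = rs$atol),
    package_version = as.character(utils::packageVersion("crisprcoevo")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = basename(files))
  fm <- paste0(stem, "-manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fm))
}
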