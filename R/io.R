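## Configuration files, result/profile writers and the command-line
## interface.

.meta_header <- function(settings) {
  ver <- tryCatch(as.character(utils::packageVersion("linacsim")),
                  error = function(e) "dev")
  c(sprintf("# linacsim %s", ver),
    sprintf("# %s = %s", names(settings),
            vapply(settings, function(v) format(v, digits = 10),
                   character(1L))))
}

#' Write / read a run configuration
#'
#' Configurations are YAML with a `settings:` section (control fields) and
#' optional physics sections (`klystron:`, `gun:`, `accelerator:`,
#' `transport:`) whose keys override the corresponding [linac_params()]
#' defaults. A written configuration re-read reproduces identical results.
#'
#' @param settings A [control_settings()].
#' @param path File path.
#' @return `read_run_config` returns a list with elements `settings`
#'   (a [control_settings()]) and `params` (a [linac_params()]).
#' @export
write_run_config <- function(settings, path) {
  # full double precision so a round-tripped config reproduces identical runs
  yaml::write_yaml(list(settings = unclass(settings)), path, precision = 17L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  s <- control_settings()
  for (k in names(cfg$settings)) {
    if (!k %in% names(s)) stop("unknown settings field ", sQuote(k))
    s[[k]] <- cfg$settings[[k]]
  }
  kp <- do.call(klystron_params, cfg$klystron %||% list())
  gp <- do.call(gun_params, cfg$gun %||% list())
  ap <- do.call(accelerator_params, cfg$accelerator %||% list())
  tp <- cfg$transport %||% list()
  bp <- do.call(bend_params, tp[intersect(names(tp),
                                          c("k2", "acceptance_halfwidth"))])
  sp <- do.call(steering_params, tp[intersect(names(tp),
                                              c("coil_gain", "drift_d"))])
  list(settings = s,
       params = linac_params(klystron = kp, gun = gp, accelerator = ap,
                             bend = bp, steering = sp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulation result as JSON
#'
#' Flat key-value JSON of the scalar readouts, plus the resolved settings.
#'
#' @param result A `linac_result` from [simulate_linac()].
#' @param path Output path.
#' @export
write_simulation_result <- function(result, path) {
  out <- list(
    rf_out_MW = result$rf_out, gun_current_mA = result$gun_current,
    target_current_mA = result$target_current,
    beam_energy_MeV = result$beam_energy,
    transmitted_energy_MeV = result$transmitted_energy,
    dose_rate_cGy_min = result$dose_rate, flatness = result$flatness,
    symmetry_r_pct = result$symmetry_r, symmetry_t_pct = result$symmetry_t,
    pfn_kV = result$pfn_kv, kly_current_A = result$kly_current_a,
    settings = unclass(result$settings))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a dose profile along a principal axis as CSV
#'
#' Comma-separated `(position_cm, dose_cGy_per_min)` rows with `#` metadata
#' comment lines carrying the package version, resolved settings and beam
#' metrics.
#'
#' @param result A `linac_result`.
#' @param path Output path.
#' @param axis `"r"` (in-plane) or `"t"` (cross-plane).
#' @export
write_dose_profile <- function(result, path, axis = c("r", "t")) {
  axis <- match.arg(axis)
  pr <- .axis_profile(result$dose_grid, axis)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.meta_header(result$settings),
               sprintf("# flatness = %.5f", result$flatness),
               sprintf("# symmetry_r = %.4f %%", result$symmetry_r),
               sprintf("# symmetry_t = %.4f %%", result$symmetry_t),
               "position_cm,dose_cGy_per_min"), con)
  writeLines(sprintf("%.6g,%.8g", pr$pos, pr$dose), con)
  invisible(path)
}

#' Write a sweep table as CSV
#'
#' @param tab Data frame from [sweep_parameter()].
#' @param settings The base settings (for the metadata header).
#' @param path Output path.
#' @export
write_sweep_table <- function(tab, settings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(settings), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

.cli_usage <- function() {
  paste(
    "usage: linacsim <command> [options]",
    "",
    "commands:",
    "  presets                                list available presets",
    "  run     --preset NAME [--config F] [--set k=v ...] [--out out.json]",
    "          [--grid grid.csv]              run one simulation",
    "  sweep   --preset NAME --param P --from A --to B --steps N",
    "          --out out.csv [--set k=v ...]  sweep one parameter",
    "  profile --preset NAME [--axis r|t] [--set k=v ...] --out out.csv",
    "                                         export a dose profile",
    sep = "\n")
}

.cli_parse <- function(args) {
  opts <- list(set = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument ", sQuote(a))
    key <- substring(a, 3L)
    if (i == length(args)) stop("missing value for --", key)
    val <- args[[i + 1L]]
    if (key == "set") opts$set <- c(opts$set, val) else opts[[key]] <- val
    i <- i + 2L
  }
  opts
}

.cli_settings <- function(opts) {
  if (!is.null(opts$config)) {
    cfg <- read_run_config(opts$config)
    s <- cfg$settings
    params <- cfg$params
  } else {
    params <- linac_params()
    s <- NULL
  }
  if (!is.null(opts$preset)) s <- load_preset(opts$preset, params)
  if (is.null(s)) stop("either --preset or --config is required")
  for (kv in opts$set) {
    parts <- strsplit(kv, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("--set expects field=value, got ", sQuote(kv))
    if (!parts[1L] %in% names(s)) stop("unknown settings field ", sQuote(parts[1L]))
    s[[parts[1L]]] <- as.numeric(parts[2L])
  }
  list(settings = s, params = params)
}

#' Command-line entry point
#'
#' Implements the `presets`, `run`, `sweep` and `profile` commands used by
#' the `inst/cli/linacsim` script. Overrides win over the config file, which
#' wins over the preset.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Integer exit status (0 on success), invisibly.
#' @export
linac_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      cat(.cli_usage(), "\n")
      return(invisible(1L))
    }
    cmd <- args[[1L]]
    opts <- .cli_parse(args[-1L])
    if (cmd == "presets") {
      cat("6MV\n15MV\n")
    } else if (cmd == "run") {
      cfg <- .cli_settings(opts)
      viol <- validate_settings(cfg$settings)
      if (nrow(viol)) {
        message("invalid settings:")
        message(paste(utils::capture.output(print(viol)), collapse = "\n"))
        return(invisible(1L))
      }
      message("stage: simulate")
      res <- simulate_linac(cfg$settings, params = cfg$params)
      if (!is.null(opts$out)) write_simulation_result(res, opts$out)
      if (!is.null(opts$grid)) {
        g <- res$dose_grid
        dat <- data.frame(x_cm = rep(g$x, times = length(g$y)),
                          y_cm = rep(g$y, each = length(g$x)),
                          dose_cGy_per_min = as.vector(g$values))
        utils::write.csv(dat, opts$grid, row.names = FALSE)
      }
      print(res)
    } else if (cmd == "sweep") {
      cfg <- .cli_settings(opts)
      if (is.null(opts$param) || is.null(opts$from) || is.null(opts$to) ||
          is.null(opts$steps))
        stop("sweep requires --param, --from, --to, --steps")
      n <- as.integer(opts$steps)
      if (is.na(n) || n < 1L) stop("--steps must be a positive integer")
      values <- seq(as.numeric(opts$from), as.numeric(opts$to),
                    length.out = n)
      message("stage: sweep ", opts$param)
      tab <- sweep_parameter(cfg$settings, opts$param, values,
                             params = cfg$params)
      if (is.null(opts$out)) stop("sweep requires --out")
      write_sweep_table(tab, cfg$settings, opts$out)
    } else if (cmd == "profile") {
      cfg <- .cli_settings(opts)
      message("stage: profile")
      res <- simulate_linac(cfg$settings, params = cfg$params)
      if (is.null(opts$out)) stop("profile requires --out")
      write_dose_profile(res, opts$out, axis = opts$axis %||% "r")
    } else {
      stop("unknown command ", sQuote(cmd), "\n", .cli_usage())
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
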