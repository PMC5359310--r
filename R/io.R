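# CSV readers/writers and the command-line dispatcher. All series travel as
# plain CSV with header rows; units are fixed by the schema (m, degrees C,
# W/m^2, ppm, y). Writers keep full double precision so write/read round
# trips are lossless.

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path,
                               call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (nm in names(x)) {
    if (!is.numeric(x[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[nm]]))))[1]
      stop(what, " file ", path, ": column '", nm,
           "' is not numeric (first bad row: ",
           if (is.na(bad)) "NA" else bad, ")", call. = FALSE)
    }
  }
  x
}

#' Read and write forcing, measurement and trajectory CSV files
#'
#' \code{read_forcing()} expects columns \code{year,T,Q1,Cg} (optionally
#' \code{Ra}); \code{read_measurements()} expects \code{age,height}
#' (optionally \code{radius}, \code{density}). Both validate monotone time
#' and report the offending row/column on failure.
#' \code{write_trajectory()} / \code{read_trajectory()} round-trip a
#' [simulate_tree()] result at full precision (solver metadata travels in
#' a JSON sidecar column-free header comment is avoided: metadata is
#' re-attached only by \code{write_manifest()} artifacts).
#'
#' @param path CSV file path.
#' @return A [forcing_series()], [measurement_series()] or data frame.
#' @export
read_forcing <- function(path) {
  forcing_series(read_csv_checked(path, c("year", "T", "Q1", "Cg"),
                                  "forcing"))
}

#' @rdname read_forcing
#' @export
read_measurements <- function(path) {
  measurement_series(read_csv_checked(path, c("age", "height"),
                                      "measurements"))
}

#' @rdname read_forcing
#' @param x a data frame-like object to write.
#' @export
write_series <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_forcing
#' @param traj a [simulate_tree()] trajectory.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_forcing
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# JSON run manifest: everything needed to re-run bit-identically
write_manifest <- function(path, command, args, params, seed = NULL,
                           extra = list()) {
  man <- c(list(command = command, args = as.list(args),
                parameters = params[intersect(names(formals(tree_params)),
                                              names(params))],
                seed = seed,
                solver = list(method = "ode45 (Dormand-Prince 4(5))",
                              rtol = 1e-8, atol = 1e-10, hmax = 1),
                package_version =
                  as.character(utils::packageVersion("sinksource")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: treegrow <command> [flags]",
    "",
    "commands:",
    "  simulate           forward simulation (needs --forcing)",
    "  fit                calibrate to a stand (--measurements, --forcing)",
    "  predict            predict a stand from a parameter file",
    "  regime-map         Amax x age regime sweep",
    "  sink-off           height gain when the sink limit is removed",
    "  co2-counterfactual ramped vs constant-CO2 paired runs",
    "  sensitivity        initial-condition sensitivity fan",
    "  synth              generate synthetic forcing + stand CSVs",
    "",
    "flags: --params FILE --forcing FILE --measurements FILE --out DIR",
    "       --seed INT --t-span A,B --r0 X --h0 X --free-params a,b,c",
    "       --bounds X", sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'\n", cli_usage(), call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("flag --", key, " needs a value", call. = FALSE)
    flags[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

#' Command-line interface to the tree growth toolkit
#'
#' A thin dispatcher over the package functions, designed to be called from
#' the bundled \code{inst/cli/treegrow.R} Rscript. Each command writes CSV
#' artifacts plus a JSON run manifest (inputs, parameter values, solver
#' settings, seed) into \code{--out}.
#'
#' @param args character vector of command-line arguments (first element is
#'   the command).
#' @return Exit status, invisibly (0 on success).
#' @export
#' @examples
#' \donttest{
#' out <- tempfile(); dir.create(out)
#' tree_cli(c("synth", "--out", out, "--seed", "7"))
#' tree_cli(c("simulate", "--forcing", file.path(out, "forcing.csv"),
#'            "--out", out, "--t-span", "48,188"))
#' }
tree_cli <- function(args) {
  if (!length(args) || args[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  known <- c("simulate", "fit", "predict", "regime-map", "sink-off",
             "co2-counterfactual", "sensitivity", "synth")
  if (!cmd %in% known) {
    message("unknown command '", cmd, "'\n", cli_usage())
    return(invisible(2L))
  }
  flags <- tryCatch(parse_flags(args[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags))
    return(invisible(2L))
  }
  out_dir <- flags$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- if (!is.null(flags$params)) read_params(flags$params)
            else tree_params()
  seed <- if (!is.null(flags$seed)) as.integer(flags$seed)
          else sample.int(.Machine$integer.max, 1)
  t_span <- if (!is.null(flags$t_span))
    as.numeric(strsplit(flags$t_span, ",")[[1]]) else c(48, 188)
  r0 <- as.numeric(flags$r0 %||% 0.08)
  h0 <- as.numeric(flags$h0 %||% 15)
  init <- tree_state(r0, h0, params$S1)
  message("[treegrow] ", cmd, " -> ", out_dir, " (seed ", seed, ")")

  status <- 0L
  if (cmd == "synth") {
    fc <- synth_forcing(seq(t_span[1], t_span[2]), seed = seed)
    # without an explicit config, synthetic stands use the reference
    # calibration (the Table-value centres cannot sustain growth)
    p_synth <- if (is.null(flags$params)) reference_params() else params
    st <- synth_stand(stand_scenario(start_age = t_span[1],
                                     end_age = t_span[2], r0 = r0, h0 = h0,
                                     params = p_synth, seed = seed), fc)
    write_series(fc, file.path(out_dir, "forcing.csv"))
    write_series(st$measurements, file.path(out_dir, "measurements.csv"))
    write_manifest(file.path(out_dir, "manifest.json"), cmd, args, p_synth,
                   seed)
    return(invisible(0L))
  }

  forcing <- if (!is.null(flags$forcing)) read_forcing(flags$forcing)
             else synth_forcing(seq(t_span[1], t_span[2]), seed = seed)

  if (cmd == "simulate") {
    tr <- simulate_tree(init, params, forcing, t_span, quiet = TRUE)
    write_trajectory(tr, file.path(out_dir, "trajectory.csv"))
    write_manifest(file.path(out_dir, "manifest.json"), cmd, args, params,
                   seed)
  } else if (cmd == "fit") {
    if (is.null(flags$measurements)) {
      message("fit needs --measurements"); return(invisible(2L))
    }
    meas <- read_measurements(flags$measurements)
    spec <- if (!is.null(flags$free_params))
      fit_spec(free = strsplit(flags$free_params, ",")[[1]],
               rel_bound = as.numeric(flags$bounds %||% 0.2))
    else fit_spec()
    ft <- fit_tree(meas, forcing, params0 = params, spec = spec)
    write_params(ft$params, file.path(out_dir, "fitted_params.yaml"))
    write_series(data.frame(age = meas$age, observed = meas$height,
                            fitted = ft$fitted_heights,
                            residual = ft$residuals),
                 file.path(out_dir, "fit.csv"))
    write_manifest(file.path(out_dir, "manifest.json"), cmd, args,
                   ft$params, seed,
                   extra = list(r_squared = ft$r_squared, ssr = ft$ssr,
                                converged = ft$convergence$converged))
    message(sprintf("[treegrow] fit R^2 = %.4f", ft$r_squared))
  } else if (cmd == "predict") {
    ages <- seq(t_span[1], t_span[2])
    pr <- predict_stand(params, forcing, c(r0, h0), ages)
    if (!is.null(flags$measurements)) {
      meas <- read_measurements(flags$measurements)
      r2 <- r_squared(pr$height[match(round(meas$age), pr$age)],
                      meas$height)
      message(sprintf("[treegrow] prediction R^2 = %.4f", r2))
    }
    write_series(pr, file.path(out_dir, "prediction.csv"))
    write_manifest(file.path(out_dir, "manifest.json"), cmd, args, params,
                   seed)
  } else if (cmd == "regime-map") {
    rm_ <- regime_map(params, forcing, init, ages = seq(t_span[1],
                                                        t_span[2]))
    long <- expand.grid(amax_mult = rm_$amax_mult, age = rm_$ages)
    long$height <- as.vector(rm_$height)
    long$regime <- as.vector(rm_$regime)
    write_series(long, file.path(out_dir, "regime_map.csv"))
    write_manifest(file.path(out_dir, "manifest.json"), cmd, args, params,
                   seed)
  } else if (cmd == "sink-off") {
    so <- sink_off_comparison(params, forcing, init,
                              ages = seq(t_span[1], t_span[2]))
    long <- expand.grid(amax_mult = so$amax_mult, age = so$ages)
    long$height_diff <- as.vector(so$height_diff)
    write_series(long, file.path(out_dir, "sink_off.csv"))
    write_manifest(file.path(out_dir, "manifest.json"), cmd, args, params,
                   seed)
  } else if (cmd == "co2-counterfactual") {
    cf <- co2_counterfactual(params, forcing, init, t_span)
    write_series(cf$difference, file.path(out_dir, "co2_difference.csv"))
    write_manifest(file.path(out_dir, "manifest.json"), cmd, args, params,
                   seed)
  } else if (cmd == "sensitivity") {
    fan <- sensitivity_fan(init, params, forcing, t_span)
    write_series(fan, file.path(out_dir, "sensitivity_fan.csv"))
    write_manifest(file.path(out_dir, "manifest.json"), cmd, args, params,
                   seed)
  }
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
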