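#' Read a model configuration from YAML
#'
#' The configuration has sections `kinetics` (the seven rate
#' constants, 1/h), `transport` (`De0` mm^2/h, `alpha_e`), `geometry`
#' (`L` mm, optional `N`), `initial` (`C0`, optional `A0`) and
#' optional `solver` (`t_end`, `output_times`, `rtol`, `atol`,
#' `max_step`, `method`) and `observables` (`residual`).  Unknown
#' sections or fields are errors (fail-fast), as is a missing
#' required section; error messages name the offending field path.
#'
#' @param path YAML file path.
#' @return List with validated `kinetics`, `transport`, `geometry`,
#'   `initial`, `solver`, `residual` components.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("kinetics", "transport", "geometry", "initial", "solver",
             "observables")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in c("kinetics", "transport", "geometry", "initial"))
    if (is.null(cfg[[sec]]))
      stop("config missing required section '", sec, "'", call. = FALSE)

  check_fields <- function(sec, allowed, required = allowed) {
    extra <- setdiff(names(cfg[[sec]]), allowed)
    if (length(extra) > 0)
      stop("unknown field(s) in '", sec, "': ",
           paste(paste0(sec, ".", extra), collapse = ", "), call. = FALSE)
    miss <- setdiff(required, names(cfg[[sec]]))
    if (length(miss) > 0)
      stop("missing field(s): ",
           paste(paste0(sec, ".", miss), collapse = ", "), call. = FALSE)
  }
  check_fields("kinetics",
               c("k1", "k_m1", "k3", "k_m3", "k_conv", "k_deg_C", "k_deg_A"))
  check_fields("transport", c("De0", "alpha_e"), required = "De0")
  check_fields("geometry", c("L", "N"), required = "L")
  check_fields("initial", c("C0", "A0"), required = "C0")
  if (!is.null(cfg$solver))
    check_fields("solver", c("t_end", "output_times", "rtol", "atol",
                             "max_step", "method"), required = character())
  if (!is.null(cfg$observables))
    check_fields("observables", "residual", required = character())

  geometry <- if (is.null(cfg$geometry$N))
    film_geometry(cfg$geometry$L)
  else film_geometry(cfg$geometry$L, cfg$geometry$N)
  solver <- do.call(solver_settings, as.list(cfg$solver))
  residual <- if (is.null(cfg$observables$residual)) "bound_complexes"
              else cfg$observables$residual

  list(kinetics = do.call(kinetic_parameters, cfg$kinetics),
       transport = do.call(transport_parameters, cfg$transport),
       geometry = geometry,
       initial = do.call(initial_composition, cfg$initial),
       solver = solver,
       residual = residual,
       raw = cfg)
}

#' Write the packaged case-study configuration
#'
#' Serialises [case_study_parameters()] as a YAML config file, a
#' convenient starting point for edited configurations.
#'
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_case_study_config <- function(path) {
  cs <- case_study_parameters()
  cfg <- list(
    kinetics = unclass(cs$kinetics),
    transport = unclass(cs$transport),
    geometry = list(L = cs$geometry$L, N = cs$geometry$N),
    initial = list(C0 = cs$initial$C0),
    solver = list(t_end = cs$solver$t_end, rtol = cs$solver$rtol,
                  atol = cs$solver$atol, max_step = cs$solver$max_step))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Every command-line run drops a JSON manifest next to its outputs:
#' the configuration snapshot, package version, seeds, checksums of
#' input files and a timestamp — enough to re-run the command.
#'
#' @param out_dir output directory.
#' @param command subcommand name.
#' @param config configuration list (as read).
#' @param seeds named list/vector of seeds used.
#' @param input_files character vector of input file paths to
#'   checksum.
#' @return Manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, command, config = NULL, seeds = NULL,
                               input_files = character()) {
  manifest <- list(
    command = command,
    package = "filmdeg",
    version = as.character(utils::packageVersion("filmdeg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    config = config,
    inputs = if (length(input_files) > 0)
      as.list(tools::md5sum(input_files)) else NULL)
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
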