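#' Construct a degradation dataset
#'
#' A degradation dataset is the joint observation record the model is
#' calibrated against: weight-loss and crystallinity time series in
#' percent, each with per-point measurement standard deviations.
#'
#' @param data data frame with columns `observable` (one of
#'   `"weight_loss"`, `"crystallinity"`), `time_h`, `value_pct`,
#'   `sd_pct`.
#' @return An object of class `degradation_dataset` (the validated
#'   data frame).
#' @export
degradation_dataset <- function(data) {
  required <- c("observable", "time_h", "value_pct", "sd_pct")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0)
    stop("dataset lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad_obs <- setdiff(unique(data$observable),
                     c("weight_loss", "crystallinity"))
  if (length(bad_obs) > 0)
    stop("unknown observable(s): ", paste(bad_obs, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(data$time_h)) || any(data$time_h < 0))
    stop("observation times must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(data$value_pct)))
    stop("non-finite observation values", call. = FALSE)
  if (any(!is.finite(data$sd_pct)) || any(data$sd_pct <= 0))
    stop("all measurement standard deviations must be positive",
         call. = FALSE)
  if (anyDuplicated(data[c("observable", "time_h")]) > 0)
    stop("duplicate (observable, time) pairs", call. = FALSE)
  if (!any(data$observable == "weight_loss"))
    stop("dataset must contain at least one weight_loss observation",
         call. = FALSE)
  rownames(data) <- NULL
  wl_only <- !any(data$observable == "crystallinity")
  structure(data[order(match(data$observable,
                             c("weight_loss", "crystallinity")),
                       data$time_h), , drop = FALSE],
            wl_only = wl_only, class = c("degradation_dataset", "data.frame"))
}

#' Read a degradation dataset from CSV
#'
#' Expects a header `observable,time_h,value_pct,sd_pct`; parses
#' strictly and refuses rows with missing or non-positive standard
#' deviations.  A file with no crystallinity rows loads as a
#' weight-loss-only dataset (joint fitting then degrades to a single
#' objective).
#'
#' @param path CSV file path.
#' @return A `degradation_dataset`.
#' @export
read_degradation_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  degradation_dataset(df)
}

#' Write a degradation dataset to CSV
#'
#' Inverse of [read_degradation_dataset()]; a write/read round trip
#' reproduces the dataset exactly.
#'
#' @param dataset a `degradation_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_degradation_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Specification of a synthetic degradation experiment
#'
#' Defines the generating model and the sampling design used by
#' [generate_synthetic()]: true parameters, observation times per
#' observable, Gaussian noise standard deviations, and an RNG seed.
#'
#' @param kinetics,transport,geometry,initial,solver generating model
#'   configuration (see [simulate_degradation()]).
#' @param times_wl,times_chi observation times (h) of the weight-loss
#'   and crystallinity series.
#' @param sd_wl,sd_chi measurement standard deviations (percentage
#'   points), recycled to the length of the time vectors.
#' @param seed integer RNG seed recorded in the provenance.
#' @param residual weight-loss convention, see [weight_loss_percent()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kinetics, transport, geometry, initial,
                           solver = NULL,
                           times_wl = c(0, 4, 8, 16, 20, 24, 40, 64),
                           times_chi = times_wl,
                           sd_wl = 2, sd_chi = 2, seed = 1L,
                           residual = "bound_complexes") {
  sd_wl <- rep_len(sd_wl, length(times_wl))
  sd_chi <- rep_len(sd_chi, length(times_chi))
  if (any(c(sd_wl, sd_chi) <= 0))
    stop("noise standard deviations must be positive", call. = FALSE)
  t_end <- max(times_wl, times_chi, 72)
  if (is.null(solver))
    solver <- solver_settings(t_end = t_end,
                              output_times = sort(unique(c(times_wl,
                                                           times_chi))))
  structure(list(kinetics = kinetics, transport = transport,
                 geometry = geometry, initial = initial, solver = solver,
                 times_wl = times_wl, times_chi = times_chi,
                 sd_wl = sd_wl, sd_chi = sd_chi, seed = as.integer(seed),
                 residual = residual),
            class = "synthetic_spec")
}

#' Default synthetic experiment mirroring the PCL case study
#'
#' A film of full thickness 0.5 mm (half-thickness 0.25 mm), initial
#' crystallinity 30.2%, degraded over 72 h with observations at the
#' case-study sampling times \{0, 4, 8, 16, 20, 24, 40, 64\} h and
#' 2-percentage-point Gaussian measurement noise on both observables,
#' simulated at the calibrated parameters.
#'
#' @param seed RNG seed.
#' @param sd_wl,sd_chi noise standard deviations (percentage points).
#' @return A `synthetic_spec`.
#' @export
case_study_template <- function(seed = 1L, sd_wl = 2, sd_chi = 2) {
  cs <- case_study_parameters()
  synthetic_spec(cs$kinetics, cs$transport, cs$geometry, cs$initial,
                 sd_wl = sd_wl, sd_chi = sd_chi, seed = seed)
}

# noise-free model observables at a spec's observation times
model_observables <- function(spec) {
  traj <- simulate_degradation(spec$kinetics, spec$transport, spec$geometry,
                               spec$initial, spec$solver)
  obs <- observable_series(traj, residual = spec$residual)
  list(wl = obs$weight_loss_pct[match(spec$times_wl, obs$time_h)],
       chi = obs$crystallinity_pct[match(spec$times_chi, obs$time_h)])
}

#' Generate a synthetic degradation dataset
#'
#' Simulates the forward model at the spec's parameters and draws
#' independent Gaussian observations with the stated per-point
#' standard deviations.  Values are kept inside the physical range
#' `[0, 100]`% by resampling out-of-range draws (not by clipping, which
#' would bias the noise scale).  Deterministic for a given seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A `degradation_dataset`.
#' @export
generate_synthetic <- function(spec) {
  truth <- model_observables(spec)
  if (anyNA(truth$wl) || anyNA(truth$chi))
    stop("spec observation times missing from solver output times",
         call. = FALSE)
  set.seed(spec$seed)
  draw_truncated <- function(mu, sd) {
    y <- stats::rnorm(length(mu), mu, sd)
    for (r in seq_len(100)) {
      bad <- y < 0 | y > 100
      if (!any(bad)) break
      y[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
    }
    pmin(pmax(y, 0), 100)
  }
  df <- rbind(
    data.frame(observable = "weight_loss", time_h = spec$times_wl,
               value_pct = draw_truncated(truth$wl, spec$sd_wl),
               sd_pct = spec$sd_wl),
    data.frame(observable = "crystallinity", time_h = spec$times_chi,
               value_pct = draw_truncated(truth$chi, spec$sd_chi),
               sd_pct = spec$sd_chi)
  )
  out <- degradation_dataset(df)
  attr(out, "seed") <- spec$seed
  out
}
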