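#' Log-uniform prior over the feasible box
#'
#' Each parameter is independently log-uniform on its box interval:
#' the density in natural space is `1 / (theta_j * log(max_j/min_j))`
#' inside the box, zero outside.  Equivalently, the prior is flat on
#' `log10(theta)` — the scale the sampler works on.
#'
#' @param box a [feasible_box()].
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(box = feasible_box()) {
  structure(list(box = box), class = "prior_spec")
}

#' Log prior density
#'
#' @param theta length-8 parameter vector (natural scale).
#' @param prior a [prior_spec()].
#' @return Log density (natural-space), `-Inf` outside the box.
#' @export
log_prior <- function(theta, prior) {
  box <- prior$box
  if (!in_box(theta, box)) return(-Inf)
  sum(-log(theta) - log(log(box$max / box$min)))
}

#' Joint Gaussian log likelihood
#'
#' Independent Gaussian measurement errors with the dataset's
#' per-point standard deviations, over both observables jointly:
#' `logL = sum [ -log(sigma sqrt(2 pi)) - (yhat - y)^2 / (2 sigma^2) ]`.
#' Up to an additive constant this is `-L(theta)/2` with `L` the
#' weighted least-squares objective ([wls_objective()]).
#'
#' @param theta length-8 parameter vector (natural scale).
#' @param dataset a `degradation_dataset`.
#' @param geometry,initial,alpha_e,residual model configuration, as in
#'   [wls_objective()].
#' @return Scalar log likelihood; `-Inf` if the simulation fails.
#' @export
log_likelihood <- function(theta, dataset, geometry, initial, alpha_e = 1,
                           residual = "bound_complexes") {
  pred <- predict_at_data_times(theta, dataset, geometry, initial,
                                alpha_e = alpha_e, residual = residual)
  if (is.null(pred)) return(-Inf)
  wl <- dataset[dataset$observable == "weight_loss", ]
  chi <- dataset[dataset$observable == "crystallinity", ]
  ll <- sum(stats::dnorm(wl$value_pct, pred$wl, wl$sd_pct, log = TRUE))
  if (nrow(chi) > 0)
    ll <- ll + sum(stats::dnorm(chi$value_pct, pred$chi, chi$sd_pct,
                                log = TRUE))
  ll
}

#' Sampler configuration for DE-MCz
#'
#' Defaults follow the reference analysis: 40 parallel chains
#' initialised around the least-squares estimate, 500 generations,
#' thinning 5, retaining `n_chains * n_iterations / thinning = 4000`
#' draws.  No burn-in is removed by default (set `burn_in` to drop
#' initial generations before recording).
#'
#' @param n_chains number of parallel chains.
#' @param n_iterations generations per chain (counted before
#'   thinning).
#' @param thinning record every `thinning`-th generation.
#' @param burn_in generations discarded before recording begins.
#' @param sigma_init standard deviation (log10 units) of the Gaussian
#'   jitter applied to the starting point per chain.
#' @param snooker_prob probability of a snooker update instead of a
#'   parallel-direction jump.
#' @param gamma jump scale; `NULL` uses the standard
#'   `2.38 / sqrt(2 d)`.
#' @param jitter small additive proposal noise (log10 units).
#' @param archive_stride append current chain states to the sampling
#'   archive every this many generations.
#' @param seed RNG seed.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 40, n_iterations = 500, thinning = 5,
                           burn_in = 0, sigma_init = 0.1,
                           snooker_prob = 0.1, gamma = NULL, jitter = 1e-6,
                           archive_stride = 10, seed = 1L) {
  if (n_chains < 4) stop("need at least 4 chains", call. = FALSE)
  if (n_iterations %% thinning != 0)
    warning("n_iterations not divisible by thinning; retained count is ",
            "n_chains * floor(n_iterations / thinning)")
  if (sigma_init <= 0)
    stop("sigma_init must be positive (identical chains give a degenerate ",
         "initial population)", call. = FALSE)
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 thinning = thinning, burn_in = burn_in,
                 sigma_init = sigma_init, snooker_prob = snooker_prob,
                 gamma = gamma, jitter = jitter,
                 archive_stride = archive_stride, seed = as.integer(seed)),
            class = "sampler_config")
}

#' Differential-evolution MCMC with snooker updates (DE-MCz)
#'
#' Generic sampler over an arbitrary log-density.  Proposals are
#' differences of states drawn from a growing archive of past chain
#' states (parallel-direction jumps scaled by
#' `gamma = 2.38 / sqrt(2 d)`, with `gamma = 1` every tenth generation
#' for mode jumping), mixed with snooker updates (probability
#' `snooker_prob`) whose acceptance includes the
#' `(|x* - z| / |x - z|)^(d-1)` projection correction.
#'
#' @param log_post function of a length-`d` numeric vector returning a
#'   scalar log density (`-Inf` allowed).
#' @param init numeric matrix `n_chains x d` of starting states; rows
#'   must not be all identical.
#' @param config a [sampler_config()] (its `sigma_init` is not used
#'   here; `init` is taken as given).
#' @param archive_init optional matrix of additional initial archive
#'   states (e.g. overdispersed prior draws).  Archive states are raw
#'   material for proposal differences, never evaluated, so
#'   overdispersing them accelerates exploration of weakly identified
#'   directions.
#' @return List with `draws` (matrix retained x d), `chain`,
#'   `iteration` (generation index), `log_posterior`,
#'   `acceptance_rate`.
#' @export
demcz_sample <- function(log_post, init, config = sampler_config(),
                         archive_init = NULL) {
  init <- as.matrix(init)
  n_chains <- nrow(init); d <- ncol(init)
  if (n_chains != config$n_chains)
    stop("init must have config$n_chains rows", call. = FALSE)
  if (max(apply(init, 2, function(v) diff(range(v)))) == 0)
    stop("degenerate initial population: all chains identical", call. = FALSE)
  set.seed(config$seed)
  gamma_def <- if (is.null(config$gamma)) 2.38 / sqrt(2 * d) else config$gamma

  Z <- init                       # archive of past states
  if (!is.null(archive_init)) Z <- rbind(Z, as.matrix(archive_init))
  X <- init
  lp <- apply(X, 1, log_post)
  if (all(!is.finite(lp)))
    stop("log posterior is -Inf at every starting state", call. = FALSE)

  n_rec_gen <- sum(seq_len(config$n_iterations) > config$burn_in &
                   seq_len(config$n_iterations) %% config$thinning == 0)
  draws <- matrix(NA_real_, n_rec_gen * n_chains, d)
  chain_id <- integer(n_rec_gen * n_chains)
  iter_id <- integer(n_rec_gen * n_chains)
  lp_rec <- numeric(n_rec_gen * n_chains)
  rec <- 0L
  n_acc <- 0L; n_prop <- 0L

  for (gen in seq_len(config$n_iterations)) {
    gamma_g <- if (gen %% 10 == 0) 1 else gamma_def
    for (i in seq_len(n_chains)) {
      n_prop <- n_prop + 1L
      if (stats::runif(1) < config$snooker_prob && nrow(Z) >= 3) {
        # snooker update along the direction x - z
        rr <- sample.int(nrow(Z), 3)
        z <- Z[rr[1], ]; z1 <- Z[rr[2], ]; z2 <- Z[rr[3], ]
        dvec <- X[i, ] - z
        nrm2 <- sum(dvec^2)
        if (nrm2 < 1e-300) next
        proj <- function(p) sum(p * dvec) / nrm2 * dvec
        gs <- stats::runif(1, 1.2, 2.2)
        xp <- X[i, ] + gs * (proj(z1) - proj(z2))
        lpp <- log_post(xp)
        log_ratio <- lpp - lp[i] +
          (d - 1) * (log(sqrt(sum((xp - z)^2))) - log(sqrt(nrm2)))
        if (is.finite(lpp) && log(stats::runif(1)) < log_ratio) {
          X[i, ] <- xp; lp[i] <- lpp; n_acc <- n_acc + 1L
        }
      } else {
        rr <- sample.int(nrow(Z), 2)
        xp <- X[i, ] + gamma_g * (Z[rr[1], ] - Z[rr[2], ]) +
          stats::rnorm(d, 0, config$jitter)
        lpp <- log_post(xp)
        if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp[i]) {
          X[i, ] <- xp; lp[i] <- lpp; n_acc <- n_acc + 1L
        }
      }
    }
    if (gen %% config$archive_stride == 0) Z <- rbind(Z, X)
    if (gen > config$burn_in && gen %% config$thinning == 0) {
      idx <- rec * n_chains + seq_len(n_chains)
      draws[idx, ] <- X
      chain_id[idx] <- seq_len(n_chains)
      iter_id[idx] <- gen
      lp_rec[idx] <- lp
      rec <- rec + 1L
    }
  }
  list(draws = draws, chain = chain_id, iteration = iter_id,
       log_posterior = lp_rec, acceptance_rate = n_acc / n_prop)
}

#' Sample the parameter posterior
#'
#' Runs DE-MCz on `log10(theta)` with the log-uniform prior (flat on
#' the log scale inside the box) and the joint Gaussian likelihood.
#' Chains start at the least-squares estimate perturbed by seeded
#' log-space Gaussian jitter.
#'
#' @param dataset a `degradation_dataset`.
#' @param geometry,initial,alpha_e,residual model configuration.
#' @param prior a [prior_spec()].
#' @param config a [sampler_config()].
#' @param start least-squares estimate (length-8, natural scale) used
#'   to initialise the chains; if `NULL` a quick [fit_parameters()]
#'   run provides it.
#' @return An object of class `posterior_samples`: `draws` (retained
#'   draws x 8, natural scale, named columns), `chain`, `iteration`,
#'   `log_posterior`, `acceptance_rate`, `config`, `prior`.
#' @export
sample_posterior <- function(dataset, geometry, initial,
                             prior = prior_spec(),
                             config = sampler_config(), start = NULL,
                             alpha_e = 1, residual = "bound_complexes") {
  box <- prior$box
  if (is.null(start)) {
    start <- fit_parameters(dataset, geometry, initial, box = box,
                            n_presearch = 20, n_local = 2,
                            seed = config$seed, alpha_e = alpha_e,
                            residual = residual)$theta
  }
  if (!in_box(start, box))
    stop("start must lie inside the prior box", call. = FALSE)
  lo <- log10(box$min); hi <- log10(box$max)
  log_post <- function(lt) {
    if (any(lt < lo) || any(lt > hi)) return(-Inf)
    log_likelihood(10^lt, dataset, geometry, initial, alpha_e = alpha_e,
                   residual = residual)
  }
  set.seed(config$seed)
  init <- matrix(rep(log10(start), each = config$n_chains),
                 config$n_chains, 8) +
    matrix(stats::rnorm(config$n_chains * 8, 0, config$sigma_init),
           config$n_chains, 8)
  init <- pmin(pmax(init, matrix(lo, config$n_chains, 8, byrow = TRUE)),
               matrix(hi, config$n_chains, 8, byrow = TRUE))
  # seed the proposal archive with overdispersed prior draws so the
  # sampler can traverse weakly identified directions from the start
  n_z0 <- 10 * 8
  Z0 <- matrix(stats::runif(n_z0 * 8, rep(lo, each = n_z0),
                            rep(hi, each = n_z0)), n_z0, 8)
  res <- demcz_sample(log_post, init, config, archive_init = Z0)
  draws <- 10^res$draws
  colnames(draws) <- THETA_NAMES
  structure(list(draws = draws, chain = res$chain,
                 iteration = res$iteration,
                 log_posterior = res$log_posterior,
                 acceptance_rate = res$acceptance_rate,
                 config = config, prior = prior),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("Posterior samples:", nrow(x$draws), "retained draws (",
      x$config$n_chains, "chains x", x$config$n_iterations,
      "generations, thinning", x$config$thinning, "), acceptance rate",
      round(x$acceptance_rate, 3), "\n")
  invisible(x)
}

#' Posterior means and central credible intervals
#'
#' @param samples a `posterior_samples` object (or a plain draw
#'   matrix with named columns).
#' @param level credible level (default 0.95; central quantile
#'   interval).
#' @return Data frame with columns `parameter`, `mean`, `lower`,
#'   `upper`, `level`.
#' @export
credible_intervals <- function(samples, level = 0.95) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws
           else as.matrix(samples)
  if (nrow(draws) < 100)
    warning("fewer than 100 retained draws; intervals are crude")
  a <- (1 - level) / 2
  data.frame(
    parameter = colnames(draws),
    mean = unname(colMeans(draws)),
    lower = unname(apply(draws, 2, stats::quantile, probs = a,
                         names = FALSE)),
    upper = unname(apply(draws, 2, stats::quantile, probs = 1 - a,
                         names = FALSE)),
    level = level, row.names = NULL)
}

#' Posterior-predictive credible bands
#'
#' Propagates posterior draws through the forward model and computes
#' pointwise central credible bands for weight loss and crystallinity,
#' plus the trajectory at the posterior-mean parameter vector.
#'
#' @param samples a `posterior_samples` object.
#' @param geometry,initial,alpha_e,residual model configuration.
#' @param times output times (h).
#' @param level band level (default 0.95).
#' @param max_draws cap on the number of (unique) draws propagated;
#'   `NULL` propagates all unique draws.
#' @return List with `bands` (data frame: `time_h`, `observable`,
#'   `lower`, `upper`, `mean_curve`), `n_used`, `n_failed`.
#' @export
predictive_bands <- function(samples, geometry, initial, times,
                             level = 0.95, max_draws = NULL,
                             alpha_e = 1, residual = "bound_complexes") {
  draws <- unique(samples$draws)
  if (!is.null(max_draws) && nrow(draws) > max_draws) {
    set.seed(samples$config$seed)
    draws <- draws[sample.int(nrow(draws), max_draws), , drop = FALSE]
  }
  settings <- solver_settings(t_end = max(times), output_times = times)
  run_one <- function(theta) {
    tryCatch({
      p <- theta_to_parameters(theta, alpha_e = alpha_e)
      traj <- simulate_degradation(p$kinetics, p$transport, geometry,
                                   initial, settings)
      observable_series(traj, residual = residual)
    }, error = function(e) NULL)
  }
  runs <- lapply(seq_len(nrow(draws)), function(i) run_one(draws[i, ]))
  failed <- vapply(runs, is.null, logical(1))
  runs <- runs[!failed]
  if (length(runs) == 0) stop("all posterior draws failed to simulate",
                              call. = FALSE)
  wl_mat <- matrix(vapply(runs, `[[`, numeric(length(times)),
                          "weight_loss_pct"), nrow = length(times))
  chi_mat <- matrix(vapply(runs, `[[`, numeric(length(times)),
                           "crystallinity_pct"), nrow = length(times))
  mean_obs <- run_one(colMeans(samples$draws))
  a <- (1 - level) / 2
  q <- function(m) t(apply(m, 1, stats::quantile, probs = c(a, 1 - a),
                           names = FALSE))
  qw <- q(wl_mat); qc <- q(chi_mat)
  bands <- rbind(
    data.frame(time_h = times, observable = "weight_loss",
               lower = qw[, 1], upper = qw[, 2],
               mean_curve = mean_obs$weight_loss_pct),
    data.frame(time_h = times, observable = "crystallinity",
               lower = qc[, 1], upper = qc[, 2],
               mean_curve = mean_obs$crystallinity_pct))
  list(bands = bands, n_used = length(runs), n_failed = sum(failed))
}
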