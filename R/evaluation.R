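#' Chemotactic efficiency of a policy
#'
#' Efficiency compares the realised arrival time with the minimal time a
#' cell of speed v needs to cover the initial distance:
#' \deqn{\eta = \left\langle \frac{d_0 - \delta}{v\,\tau} \right\rangle,}
#' averaged over independent episodes.  Policies are evaluated in
#' deterministic mode.  Episodes that fail to arrive within the
#' evaluation horizon are, by default, included with `tau` set to the
#' horizon (a conservative convention); set `condition_on_arrival = TRUE`
#' to average over successful runs only.  The failure fraction is always
#' reported.
#'
#' @inheritParams run_episodes
#' @param n_runs Number of evaluation episodes.
#' @param horizon Evaluation horizon (s); defaults to `4 * config$t_max`
#'   and may differ from the training horizon.
#' @param condition_on_arrival If `TRUE`, failures are excluded from the
#'   mean instead of being capped at the horizon.
#' @param n_boot Bootstrap replicates for the standard error.
#' @param chunk_size Episodes are simulated in chunks of this size, each
#'   chunk seeded as `seed + chunk index`; the estimate is therefore
#'   invariant to how a total run count is split across calls under the
#'   same seed schedule.
#' @return An object of class `"efficiency_estimate"`: a list with
#'   `eta_mean`, `stderr`, `n_runs`, `failure_fraction`, `horizon` and
#'   the per-run efficiencies `eta_runs`.
#' @export
chemotactic_efficiency <- function(policy, config, field, cell, n_runs,
                                   horizon = NULL, deterministic = TRUE,
                                   condition_on_arrival = FALSE,
                                   n_boot = 200, chunk_size = 256,
                                   seed = NULL) {
  stopifnot(n_runs >= 1)
  horizon <- horizon %||% (4 * config$t_max)
  starts <- seq(1L, n_runs, by = chunk_size)
  eta <- numeric(0)
  reached_all <- logical(0)
  for (k in seq_along(starts)) {
    nk <- min(chunk_size, n_runs - starts[k] + 1L)
    b <- run_episodes(policy, config, field, cell, n = nk,
                      deterministic = deterministic, horizon = horizon,
                      seed = if (!is.null(seed)) seed + k else NULL)
    tau_eff <- ifelse(b$reached, b$tau, horizon)
    eta <- c(eta, (b$d_init - config$delta) / (cell$speed * tau_eff))
    reached_all <- c(reached_all, b$reached)
  }
  if (condition_on_arrival) eta <- eta[reached_all]
  n_eff <- length(eta)
  eta_mean <- if (n_eff > 0) mean(eta) else NA_real_
  stderr <- if (n_eff > 1) {
    bs <- vapply(seq_len(n_boot),
                 function(i) mean(eta[sample.int(n_eff, replace = TRUE)]),
                 numeric(1))
    stats::sd(bs)
  } else NA_real_
  structure(list(eta_mean = eta_mean, stderr = stderr, n_runs = n_runs,
                 failure_fraction = mean(!reached_all), horizon = horizon,
                 condition_on_arrival = condition_on_arrival,
                 eta_runs = eta),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("eta = %.4f +/- %.4f  (n = %d, failures %.1f%%)\n",
              x$eta_mean, x$stderr, x$n_runs, 100 * x$failure_fraction))
  invisible(x)
}

#' Arrival-time distribution of a policy
#'
#' Runs `n_runs` evaluation episodes and summarises the arrival times of
#' the successful ones (mean, median, skewness) together with the count
#' of failures; histogram counts over successes and failures sum to
#' `n_runs`.
#'
#' @inheritParams chemotactic_efficiency
#' @param breaks Passed to [graphics::hist()].
#' @return A list with `times` (successful arrival times, s),
#'   `histogram`, `mean`, `median`, `skewness`, `n_failures`, `n_runs`
#'   and `all_failed`.
#' @export
arrival_time_distribution <- function(policy, config, field, cell, n_runs,
                                      horizon = NULL, deterministic = TRUE,
                                      breaks = 30, seed = NULL) {
  stopifnot(n_runs >= 1)
  horizon <- horizon %||% (4 * config$t_max)
  b <- run_episodes(policy, config, field, cell, n = n_runs,
                    deterministic = deterministic, horizon = horizon,
                    seed = seed)
  times <- b$tau[b$reached]
  all_failed <- length(times) == 0
  list(times = times,
       histogram = if (!all_failed)
         graphics::hist(times, breaks = breaks, plot = FALSE) else NULL,
       mean = if (!all_failed) mean(times) else NA_real_,
       median = if (!all_failed) stats::median(times) else NA_real_,
       skewness = if (!all_failed) sample_skewness(times) else NA_real_,
       n_failures = sum(!b$reached), n_runs = n_runs,
       all_failed = all_failed)
}

#' Train-and-evaluate sweep over cell sizes
#'
#' For every combination of policy variant and cell radius, trains a
#' fresh policy under an identical budget and evaluates its chemotactic
#' efficiency, emitting one long-format row per cell of the sweep.
#' Failures of individual trainings are caught and reported as `NA` rows
#' without aborting the sweep.
#'
#' @param variants Character vector of [policy_spec()] variants.
#' @param radii Numeric vector of cell radii (um).
#' @param config,field Environment definition.
#' @param cell_template A [cell_params()] whose radius is replaced per
#'   sweep cell (the sensor radius is rederived).
#' @param ppo A [ppo_config()] training budget, identical across cells.
#' @param n_eval Evaluation episodes per cell.
#' @param spec_args Extra arguments passed to [policy_spec()].
#' @param seed Integer seed; each sweep cell derives its own sub-seed.
#' @return A data frame with columns `variant`, `radius`, `eta`,
#'   `stderr`, `failure_fraction`, `n_eval`, `seed`, plus the trained
#'   policies in `attr(, "policies")`.
#' @export
size_sweep <- function(variants, radii, config, field, cell_template, ppo,
                       n_eval = 256, spec_args = list(), seed = 1) {
  rows <- list()
  policies <- list()
  i <- 0L
  for (variant in variants) {
    for (radius in radii) {
      i <- i + 1L
      sub_seed <- (seed * 1000L + i) %% .Machine$integer.max
      cell <- cell_params(radius = radius,
                          n_sensors = cell_template$n_sensors,
                          speed = cell_template$speed,
                          rot_diffusion = cell_template$rot_diffusion)
      row <- tryCatch({
        spec <- do.call(policy_spec,
                        c(list(variant = variant,
                               n_sensors = cell$n_sensors), spec_args))
        run <- train_policy(spec, config, field, cell, ppo, seed = sub_seed)
        eff <- chemotactic_efficiency(run$policy, config, field, cell,
                                      n_runs = n_eval)
        policies[[paste(variant, radius, sep = "_")]] <- run$policy
        data.frame(variant = variant, radius = radius,
                   eta = eff$eta_mean, stderr = eff$stderr,
                   failure_fraction = eff$failure_fraction,
                   n_eval = n_eval, seed = sub_seed)
      }, error = function(e) {
        warning("sweep cell (", variant, ", R = ", radius, ") failed: ",
                conditionMessage(e), call. = FALSE)
        data.frame(variant = variant, radius = radius, eta = NA_real_,
                   stderr = NA_real_, failure_fraction = NA_real_,
                   n_eval = n_eval, seed = sub_seed)
      })
      rows[[i]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "policies") <- policies
  out
}
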