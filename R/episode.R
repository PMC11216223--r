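#' Episode configuration
#'
#' Parameters of a single chemotaxis episode: where the cell starts, when
#' it is considered arrived, how long it may search, the integration step,
#' and the range from which the per-episode concentration scale C0 is
#' sampled (log-uniformly), which sets the signal-to-noise ratio of the
#' sensing problem.
#'
#' @param d0_range Interval (um) of initial distances to the source; the
#'   lower bound must exceed `delta`.
#' @param delta Arrival threshold distance (um), positive.
#' @param t_max Episode horizon (s).
#' @param dt Time step (s); `t_max >= dt > 0`.
#' @param conc_range Interval (particles/um^2) for the per-episode peak
#'   concentration C0, sampled log-uniformly. Default `c(16, 160)`, i.e.
#'   C_q to 10 C_q with C_q = 16/um^2.
#' @param seed Optional integer seed stored with the config.
#' @return An object of class `"episode_config"`.
#' @export
episode_config <- function(d0_range = c(100, 500), delta = 10,
                           t_max = 2000, dt = 0.1,
                           conc_range = c(16, 160), seed = NULL) {
  stopifnot(length(d0_range) == 2, d0_range[1] <= d0_range[2],
            delta > 0, d0_range[1] > delta,
            dt > 0, t_max >= dt,
            length(conc_range) == 2, all(conc_range > 0),
            conc_range[1] <= conc_range[2])
  structure(list(d0_range = as.numeric(d0_range), delta = delta,
                 t_max = t_max, dt = dt,
                 conc_range = as.numeric(conc_range), seed = seed),
            class = "episode_config")
}

#' Terminal episode reward
#'
#' The episodic reward
#' \deqn{R = \frac{t_{max}-\tau}{t_{max}} +
#'       \max\!\left(-1, \frac{\delta-d}{d_0-\delta}\right),}
#' where exactly one term is nonzero per episode: an episode that reaches
#' the source (final distance \eqn{d \le \delta}) earns only the
#' normalized time term, while a timed-out episode earns only the
#' (negative) distance term.  The reward lies in `[-1, 1]`.
#'
#' @param tau Elapsed episode time (s), `<= t_max`.
#' @param d_final Final distance to the source (um).
#' @param d_init Initial distance d0 (um); must exceed `config$delta`.
#' @param config An [episode_config()].
#' @return Numeric reward(s) in `[-1, 1]` (vectorised).
#' @export
compute_reward <- function(tau, d_final, d_init, config) {
  if (any(d_init <= config$delta))
    stop("invalid episode: d_init must exceed delta", call. = FALSE)
  if (any(tau > config$t_max + 1e-9))
    stop("tau exceeds t_max", call. = FALSE)
  reached <- d_final <= config$delta
  ifelse(reached,
         (config$t_max - pmin(tau, config$t_max)) / config$t_max,
         pmax(-1, (config$delta - d_final) / (d_init - config$delta)))
}

#' Sample an initial episode condition
#'
#' Draws the initial distance d0 uniformly over `d0_range`, places the
#' cell in a uniformly random direction from the source with a uniformly
#' random heading theta0, and samples the per-episode concentration scale
#' C0 log-uniformly over `conc_range`.
#'
#' @param config An [episode_config()].
#' @param field A [field_params()] template; its `C0` is replaced by the
#'   per-episode draw.
#' @return A list with elements `state` ([cell_state()]), `field`
#'   ([field_params()] with episode C0) and `d0`.
#' @export
reset_episode <- function(config, field) {
  d0 <- stats::runif(1, config$d0_range[1], config$d0_range[2])
  phi <- stats::runif(1, 0, 2 * pi)
  theta0 <- stats::runif(1, 0, 2 * pi)
  C0 <- exp(stats::runif(1, log(config$conc_range[1]),
                         log(config$conc_range[2])))
  f <- field
  f$C0 <- C0
  list(state = cell_state(position = d0 * c(cos(phi), sin(phi)),
                          heading = theta0),
       field = f, d0 = d0)
}

#' Run a batch of independent episodes
#'
#' Vectorised episode engine: `n` cells are simulated in parallel
#' (results are independent of the batching), each looping
#' observe -> act -> step until it comes within `config$delta` of the
#' source or the horizon is exceeded.
#'
#' @param policy A policy object (see [neural_policy()], [blind_policy()],
#'   [kernel_policy()], [switching_policy()], [oracle_policy()]).
#' @param config An [episode_config()].
#' @param field A [field_params()] template (per-episode C0 is sampled).
#' @param cell A [cell_params()].
#' @param n Number of episodes.
#' @param deterministic If `TRUE`, policies act on their mean output
#'   (evaluation mode).
#' @param record If `TRUE`, keep full per-step trajectories (time, state,
#'   counts, measurements, actions, policy outputs and pre-update hidden
#'   states).
#' @param collect If `TRUE`, additionally return padded arrays of network
#'   inputs, actions, log-probabilities and values for policy
#'   optimisation (neural policies only).
#' @param horizon Optional evaluation horizon (s) overriding
#'   `config$t_max` as the stopping time; rewards are always computed
#'   with respect to `config$t_max`.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return A list of class `"episode_batch"` with per-episode vectors
#'   `tau`, `d_final`, `d_init`, `reached`, `reward`, `C0`, and (when
#'   requested) `trajectories` and rollout arrays.
#' @export
run_episodes <- function(policy, config, field, cell, n,
                         deterministic = FALSE, record = FALSE,
                         collect = FALSE, horizon = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  dt <- config$dt
  t_end <- horizon %||% config$t_max
  n_steps_max <- as.integer(ceiling(t_end / dt - 1e-9))
  K <- cell$n_sensors

  d0 <- stats::runif(n, config$d0_range[1], config$d0_range[2])
  phi <- stats::runif(n, 0, 2 * pi)
  pos <- cbind(d0 * cos(phi), d0 * sin(phi))
  theta <- stats::runif(n, 0, 2 * pi)
  C0 <- exp(stats::runif(n, log(config$conc_range[1]),
                         log(config$conc_range[2])))

  hidden <- policy_init_hidden(policy, n)
  prev_a <- numeric(n)
  tau <- rep(t_end, n)
  d_final <- rep(NA_real_, n)
  reached <- rep(FALSE, n)
  len <- integer(n)
  needs_obs <- policy_needs_obs(policy)
  area <- pi * cell$sensor_radius^2

  if (collect) {
    din <- policy_input_dim(policy, cell)
    X_arr <- array(0, c(n_steps_max, n, din))
    A_arr <- matrix(0, n_steps_max, n)
    LP_arr <- matrix(0, n_steps_max, n)
    V_arr <- matrix(0, n_steps_max, n)
  }
  if (record) {
    traj <- lapply(seq_len(n), function(i)
      list(t = numeric(0), x = NULL, theta = numeric(0),
           M = NULL, m = NULL, action = numeric(0), mu = numeric(0),
           sigma = numeric(0), value = numeric(0),
           prev_action = numeric(0), h_pre = NULL))
    # preallocated row-major stores, trimmed at the end
    rec_t <- matrix(NA_real_, n_steps_max, n)
    rec_x <- array(NA_real_, c(n_steps_max, n, 2))
    rec_th <- matrix(NA_real_, n_steps_max, n)
    rec_M <- array(NA_real_, c(n_steps_max, n, K))
    rec_a <- matrix(NA_real_, n_steps_max, n)
    rec_mu <- matrix(NA_real_, n_steps_max, n)
    rec_sd <- matrix(NA_real_, n_steps_max, n)
    rec_v <- matrix(NA_real_, n_steps_max, n)
    rec_pa <- matrix(NA_real_, n_steps_max, n)
    hdim <- policy_hidden_dim(policy)
    rec_h <- if (hdim > 0) array(NA_real_, c(n_steps_max, n, hdim)) else NULL
  }

  idx <- seq_len(n)
  s <- 0L
  while (length(idx) > 0L && s < n_steps_max) {
    s <- s + 1L
    na <- length(idx)
    m <- NULL
    M <- NULL
    if (needs_obs) {
      dmat <- sensor_dist_batch(pos[idx, , drop = FALSE], theta[idx], cell)
      em <- conc_shape(field, dmat) * area * C0[idx]  # recycles C0 row-wise
      M <- matrix(stats::rpois(length(em), em), nrow = na)
      m <- log(M + 1)
    }
    hsub <- h_sub(hidden, idx)
    act <- policy_act(policy, m, hsub, prev_a[idx], deterministic,
                      state = list(pos = pos[idx, , drop = FALSE],
                                   theta = theta[idx],
                                   t = (s - 1L) * dt, dt = dt))
    if (record) {
      rec_t[s, idx] <- (s - 1L) * dt
      rec_x[s, idx, ] <- pos[idx, ]
      rec_th[s, idx] <- theta[idx]
      if (needs_obs) rec_M[s, idx, ] <- M
      rec_a[s, idx] <- act$action
      rec_mu[s, idx] <- act$mu
      rec_sd[s, idx] <- act$sigma
      rec_v[s, idx] <- act$value
      rec_pa[s, idx] <- prev_a[idx]
      if (!is.null(rec_h)) rec_h[s, idx, ] <- as.matrix(hsub)
    }
    if (collect) {
      X_arr[s, idx, ] <- act$X
      A_arr[s, idx] <- act$action
      LP_arr[s, idx] <- act$logp
      V_arr[s, idx] <- act$value
    }
    hidden <- h_set(hidden, idx, act$hidden)
    prev_a[idx] <- act$action
    stepped <- env_step_batch(pos[idx, , drop = FALSE], theta[idx],
                              act$action, cell, dt)
    pos[idx, ] <- stepped$pos
    theta[idx] <- stepped$theta
    len[idx] <- s
    dist <- sqrt(rowSums(stepped$pos^2))
    done <- dist <= config$delta
    if (any(done)) {
      di <- idx[done]
      tau[di] <- s * dt
      d_final[di] <- dist[done]
      reached[di] <- TRUE
      idx <- idx[!done]
    }
  }
  if (length(idx) > 0L)
    d_final[idx] <- sqrt(rowSums(pos[idx, , drop = FALSE]^2))

  reward <- compute_reward(pmin(tau, config$t_max), d_final, d0, config)
  out <- list(tau = tau, d_final = d_final, d_init = d0,
              reached = reached, reward = reward, C0 = C0, len = len,
              n = n, dt = dt, horizon = t_end)
  if (collect) {
    Tm <- max(len)
    out$rollout <- list(
      X = X_arr[seq_len(Tm), , , drop = FALSE],
      actions = A_arr[seq_len(Tm), , drop = FALSE],
      logp = LP_arr[seq_len(Tm), , drop = FALSE],
      values = V_arr[seq_len(Tm), , drop = FALSE],
      len = len, reward = reward, d_init = d0)
  }
  if (record) {
    out$trajectories <- lapply(seq_len(n), function(i) {
      si <- seq_len(len[i])
      M <- if (needs_obs) matrix(rec_M[si, i, ], ncol = K) else NULL
      list(t = rec_t[si, i], x = matrix(rec_x[si, i, ], ncol = 2),
           theta = rec_th[si, i],
           M = M, m = if (needs_obs) log(M + 1) else NULL,
           action = rec_a[si, i], mu = rec_mu[si, i],
           sigma = rec_sd[si, i], value = rec_v[si, i],
           prev_action = rec_pa[si, i],
           h_pre = if (!is.null(rec_h)) matrix(rec_h[si, i, ], ncol = hdim)
                   else NULL)
    })
  }
  class(out) <- "episode_batch"
  out
}

#' Run a single episode
#'
#' Convenience wrapper around [run_episodes()] with `n = 1`.
#'
#' @inheritParams run_episodes
#' @return A list of class `"episode_result"` with scalar fields `tau`,
#'   `d_final`, `d_init`, `reached`, `reward` and, when `record = TRUE`,
#'   a `trajectory` element.
#' @export
run_episode <- function(policy, config, field, cell, record = FALSE,
                        deterministic = FALSE, horizon = NULL, seed = NULL) {
  b <- run_episodes(policy, config, field, cell, n = 1,
                    deterministic = deterministic, record = record,
                    horizon = horizon, seed = seed)
  structure(list(tau = b$tau[1], d_final = b$d_final[1],
                 d_init = b$d_init[1], reached = b$reached[1],
                 reward = b$reward[1], C0 = b$C0[1],
                 trajectory = if (record) b$trajectories[[1]] else NULL),
            class = "episode_result")
}
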