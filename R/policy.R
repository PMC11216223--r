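#' Policy architecture specification
#'
#' Describes one of the three neural navigation-policy variants:
#' \describe{
#'   \item{spatial}{a stateless feedforward network acting on the K
#'     instantaneous per-sensor measurements only;}
#'   \item{temporal}{a recurrent network receiving only the mean
#'     measurement `<m>` (plus its own previous action), forced to derive
#'     gradient information from memory;}
#'   \item{combined}{a recurrent network receiving all K per-sensor
#'     measurements plus the previous action, free to mix spatial and
#'     temporal information.}
#' }
#' Recurrent variants route their input through a gated recurrent unit
#' whose hidden state plays the role of the cell's biochemical memory;
#' the network heads emit the mean and standard deviation of a Gaussian
#' action distribution and a value estimate of the terminal reward.
#'
#' @param variant `"spatial"`, `"temporal"` or `"combined"`.
#' @param n_sensors Number of sensors K the policy expects.
#' @param hidden_size Recurrent state width (ignored for spatial).
#' @param mlp_widths Integer vector of MLP layer widths.
#' @param action_scale Maximum |mu| (rad/s); the mu head is
#'   tanh-squashed to `[-action_scale, action_scale]`.
#' @param feed_back_action If `TRUE` (default), recurrent variants
#'   receive the previous action as an input; the spatial variant never
#'   does, staying memoryless by construction.
#' @param sigma_init Initial action standard deviation (rad/s); defaults
#'   to half the action scale.
#' @return An object of class `"policy_spec"`.
#' @export
policy_spec <- function(variant = c("combined", "spatial", "temporal"),
                        n_sensors = 5, hidden_size = 32,
                        mlp_widths = c(64, 64), action_scale = pi,
                        feed_back_action = TRUE, sigma_init = NULL) {
  variant <- match.arg(variant)
  recurrent <- variant %in% c("temporal", "combined")
  if (recurrent) stopifnot(hidden_size >= 1)
  stopifnot(action_scale > 0, length(mlp_widths) >= 1, all(mlp_widths >= 1))
  n_meas <- if (variant == "temporal") 1L else as.integer(n_sensors)
  n_inputs <- n_meas + if (recurrent && feed_back_action) 1L else 0L
  structure(list(variant = variant, n_sensors = as.integer(n_sensors),
                 hidden_size = if (recurrent) as.integer(hidden_size) else 0L,
                 mlp_widths = as.integer(mlp_widths),
                 action_scale = action_scale,
                 feed_back_action = isTRUE(feed_back_action) && recurrent,
                 recurrent = recurrent,
                 n_meas = n_meas, n_inputs = n_inputs,
                 sigma_init = sigma_init %||% (0.5 * action_scale)),
            class = "policy_spec")
}

#' Create a neural policy
#'
#' Initialises network parameters for a [policy_spec()].  Weights use
#' Gaussian fan-in initialisation; the mu and sigma heads start small so
#' that the initial policy is nearly unbiased with standard deviation
#' `spec$sigma_init`.
#'
#' @param spec A [policy_spec()].
#' @param params Optional explicit parameter tree (as produced by a
#'   previous call or [load_checkpoint()]).
#' @return An object of class `c("neural_policy", "chemo_policy")`.
#' @export
neural_policy <- function(spec, params = NULL) {
  stopifnot(inherits(spec, "policy_spec"))
  structure(list(spec = spec, params = params %||% nn_policy_init(spec)),
            class = c("neural_policy", "chemo_policy"))
}

#' Evaluate a policy network on one observation
#'
#' Single-step forward pass of a neural policy: maps an observation (and,
#' for recurrent variants, the hidden state and previous action) to the
#' action distribution parameters, the value estimate, and the next
#' hidden state.  Deterministic given (params, inputs).
#'
#' @param policy A [neural_policy()].
#' @param obs An [observation()] or a numeric vector of K measurements
#'   m_i.
#' @param hidden Numeric hidden-state vector h (zeros at episode start);
#'   ignored for the spatial variant.
#' @param prev_action Previous action a_{t-1} (rad/s); only used when the
#'   spec feeds actions back.
#' @return A list of class `"policy_output"` with `mu`, `sigma`, `value`
#'   and `next_hidden`.
#' @export
policy_forward <- function(policy, obs, hidden = NULL, prev_action = 0) {
  stopifnot(inherits(policy, "neural_policy"))
  spec <- policy$spec
  m <- if (inherits(obs, "observation")) obs$measurements else as.numeric(obs)
  if (length(m) != spec$n_sensors)
    stop("observation has ", length(m), " sensors but the policy expects ",
         spec$n_sensors, call. = FALSE)
  if (any(!is.finite(m)) || !is.finite(prev_action))
    stop("non-finite policy input", call. = FALSE)
  xin <- if (spec$variant == "temporal") mean(m) else m
  if (spec$feed_back_action) xin <- c(xin, prev_action)
  H <- NULL
  if (spec$recurrent) {
    h <- hidden %||% numeric(spec$hidden_size)
    if (is.list(h)) h <- h$values
    stopifnot(length(h) == spec$hidden_size)
    H <- matrix(h, 1)
  }
  o <- nn_policy_forward(spec, policy$params, matrix(xin, 1), H)
  structure(list(mu = o$mu, sigma = o$sigma, value = o$value,
                 next_hidden = if (spec$recurrent) as.numeric(o$h) else NULL),
            class = "policy_output")
}

#' Sample an action from a policy output
#'
#' Draws from `Normal(mu, sigma)`, or returns `mu` in deterministic
#' (evaluation) mode.
#'
#' @param output A `"policy_output"` (or any list with `mu`, `sigma`).
#' @param deterministic If `TRUE`, return the mean action.
#' @return Angular velocity a_t (rad/s).
#' @export
sample_action <- function(output, deterministic = FALSE) {
  if (deterministic || all(output$sigma == 0)) return(output$mu)
  stats::rnorm(length(output$mu), output$mu, output$sigma)
}

# ---- internal batched policy interface -------------------------------------
# policy_act(policy, m, hidden, prev_action, deterministic, state) where m
# is a B x K measurement matrix.  Every policy returns action/mu/sigma/
# value/logp vectors, the updated hidden container, and X (its network
# input rows, used by the rollout collector).

policy_act <- function(policy, m, hidden, prev_action, deterministic, state)
  UseMethod("policy_act")

policy_init_hidden <- function(policy, n) UseMethod("policy_init_hidden")
policy_needs_obs <- function(policy) UseMethod("policy_needs_obs")
policy_hidden_dim <- function(policy) UseMethod("policy_hidden_dim")

policy_needs_obs.default <- function(policy) TRUE
policy_hidden_dim.default <- function(policy) 0L
policy_init_hidden.default <- function(policy, n) NULL

policy_input_dim <- function(policy, cell) {
  if (inherits(policy, "neural_policy")) policy$spec$n_inputs
  else stop("rollout collection requires a neural policy", call. = FALSE)
}

# neural -----------------------------------------------------------------

policy_init_hidden.neural_policy <- function(policy, n) {
  if (policy$spec$recurrent) matrix(0, n, policy$spec$hidden_size) else NULL
}

policy_hidden_dim.neural_policy <- function(policy) policy$spec$hidden_size

neural_inputs <- function(spec, m, prev_action) {
  xin <- if (spec$variant == "temporal") matrix(rowMeans(m), ncol = 1) else m
  if (spec$feed_back_action) xin <- cbind(xin, prev_action)
  xin
}

policy_act.neural_policy <- function(policy, m, hidden, prev_action,
                                     deterministic, state) {
  spec <- policy$spec
  X <- neural_inputs(spec, m, prev_action)
  o <- nn_policy_forward(spec, policy$params, X, hidden)
  a <- if (deterministic) o$mu else stats::rnorm(length(o$mu), o$mu, o$sigma)
  logp <- stats::dnorm(a, o$mu, pmax(o$sigma, 1e-12), log = TRUE)
  list(action = a, mu = o$mu, sigma = o$sigma, value = o$value,
       logp = logp, hidden = o$h, X = X)
}

# blind ------------------------------------------------------------------

#' Blind baseline policy
#'
#' Ignores all sensory input and always outputs zero angular velocity:
#' the trajectory is straight-line motion randomised only by rotational
#' diffusion.
#' @return A policy object.
#' @export
blind_policy <- function() {
  structure(list(), class = c("blind_policy", "chemo_policy"))
}

policy_needs_obs.blind_policy <- function(policy) FALSE

policy_act.blind_policy <- function(policy, m, hidden, prev_action,
                                    deterministic, state) {
  n <- length(prev_action)
  z <- numeric(n)
  list(action = z, mu = z, sigma = z, value = z, logp = z, hidden = NULL,
       X = NULL)
}

# oracle -----------------------------------------------------------------

#' Perfect-aim oracle policy (testing aid)
#'
#' A cheating policy that reads the true cell state and, each step, turns
#' exactly onto the bearing of the source (plus an optional constant
#' offset).  With `rot_diffusion = 0` and zero offset the cell takes the
#' straight-line path; a constant offset `phi` produces an equiangular
#' spiral whose arrival time is `1/cos(phi)` times the minimal time.
#'
#' @param offset Constant aiming offset (rad).
#' @return A policy object.
#' @export
oracle_policy <- function(offset = 0) {
  structure(list(offset = offset), class = c("oracle_policy", "chemo_policy"))
}

policy_needs_obs.oracle_policy <- function(policy) FALSE

policy_act.oracle_policy <- function(policy, m, hidden, prev_action,
                                     deterministic, state) {
  target <- atan2(-state$pos[, 2], -state$pos[, 1]) + policy$offset
  a <- wrap_pi(target - state$theta) / state$dt
  z <- numeric(length(a))
  list(action = a, mu = a, sigma = z, value = z, logp = z, hidden = NULL,
       X = NULL)
}

# kernel -----------------------------------------------------------------

#' Memory-kernel baseline policy
#'
#' An analytic strategy that integrates temporal information into a
#' spatial comparator: it keeps a rolling window of past per-sensor
#' measurements, weights lags by `kernel_weights` (index 1 = current
#' step), and turns at a rate proportional to the left-right contrast
#' \deqn{a_t = g \sum_\ell w_\ell \sum_k \sin(\phi_k)\, m_{t-\ell+1,k},}
#' where `phi_k = 2*pi*k/K` is the body-frame sensor angle (the front
#' sensor has weight 0, left-side sensors positive).  A delta kernel
#' (`kernel_weights = 1`) reduces to an instantaneous left-right
#' comparator; before the window fills, missing lags count as zero.
#'
#' @param kernel_weights Numeric vector of lag weights (finite).
#' @param gain Scalar gain g (rad/s per measurement unit).
#' @param n_sensors Number of sensors K.
#' @return A policy object.
#' @export
kernel_policy <- function(kernel_weights = 1, gain = 1, n_sensors = 5) {
  stopifnot(all(is.finite(kernel_weights)), is.finite(gain))
  structure(list(w = as.numeric(kernel_weights), gain = gain,
                 K = as.integer(n_sensors),
                 sinw = sin(2 * pi * (seq_len(n_sensors) - 1L) / n_sensors)),
            class = c("kernel_policy", "chemo_policy"))
}

policy_init_hidden.kernel_policy <- function(policy, n) {
  # rolling buffer of the last length(w) contrast values, most recent first
  matrix(0, n, length(policy$w))
}

policy_act.kernel_policy <- function(policy, m, hidden, prev_action,
                                     deterministic, state) {
  contrast <- as.numeric(m %*% policy$sinw)
  L <- length(policy$w)
  buf <- if (L > 1) cbind(contrast, hidden[, -L, drop = FALSE])
         else matrix(contrast, ncol = 1)
  a <- policy$gain * as.numeric(buf %*% policy$w)
  z <- numeric(length(a))
  list(action = a, mu = a, sigma = z, value = z, logp = z, hidden = buf,
       X = NULL)
}

# switching --------------------------------------------------------------

#' Temporal-to-spatial switching policy
#'
#' Delegates to a (noise-robust) temporal policy while the mean
#' measurement is below `threshold` and to a (reactive) spatial policy
#' once the threshold is first crossed.  The switch latches: after the
#' first crossing the episode stays in the spatial regime.
#'
#' @param temporal_policy,spatial_policy Sub-policies implementing the
#'   policy interface.
#' @param threshold Mean-measurement switching threshold.
#' @return A policy object.
#' @export
switching_policy <- function(temporal_policy, spatial_policy, threshold) {
  stopifnot(inherits(temporal_policy, "chemo_policy"),
            inherits(spatial_policy, "chemo_policy"))
  structure(list(temporal = temporal_policy, spatial = spatial_policy,
                 threshold = threshold),
            class = c("switching_policy", "chemo_policy"))
}

policy_init_hidden.switching_policy <- function(policy, n) {
  list(temporal = policy_init_hidden(policy$temporal, n),
       spatial = policy_init_hidden(policy$spatial, n),
       switched = rep(FALSE, n))
}

policy_act.switching_policy <- function(policy, m, hidden, prev_action,
                                        deterministic, state) {
  switched <- hidden$switched | (rowMeans(m) >= policy$threshold)
  ot <- policy_act(policy$temporal, m, hidden$temporal, prev_action,
                   deterministic, state)
  os <- policy_act(policy$spatial, m, hidden$spatial, prev_action,
                   deterministic, state)
  pick <- function(a, b) ifelse(switched, b, a)
  list(action = pick(ot$action, os$action), mu = pick(ot$mu, os$mu),
       sigma = pick(ot$sigma, os$sigma), value = pick(ot$value, os$value),
       logp = pick(ot$logp, os$logp),
       hidden = list(temporal = ot$hidden, spatial = os$hidden,
                     switched = switched),
       X = NULL)
}
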