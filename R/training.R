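#' PPO hyperparameter configuration
#'
#' Hyperparameters of the proximal-policy-optimisation loop used to train
#' the navigation policies on the episodic terminal reward.
#'
#' @param clip_epsilon Clipping radius of the probability-ratio surrogate.
#' @param discount Discount factor gamma in `(0, 1]`.  The reward is
#'   purely terminal; `gamma < 1` merely stabilises value learning, and
#'   `gamma = 1` is fully supported.
#' @param gae_lambda Generalised-advantage-estimation mixing parameter.
#' @param epochs_per_update Optimisation passes per collected batch.
#' @param minibatch_size Episodes per gradient step; `NULL` (default)
#'   uses the full batch.
#' @param learning_rate Adam step size; linearly decayed to 0 over
#'   `total_updates` when `lr_decay = TRUE`.
#' @param lr_decay Whether to decay the learning rate linearly.
#' @param entropy_coeff Entropy-bonus coefficient.
#' @param value_coeff Value-regression loss coefficient.
#' @param max_grad_norm Global gradient-norm clip (set `Inf` to disable).
#' @param n_parallel_episodes Episodes collected per update.
#' @param total_updates Number of collect/update iterations.
#' @param seed Optional integer seed stored with the config.
#' @return An object of class `"ppo_config"`.
#' @export
ppo_config <- function(clip_epsilon = 0.2, discount = 0.99,
                       gae_lambda = 0.95, epochs_per_update = 4,
                       minibatch_size = NULL, learning_rate = 3e-4,
                       lr_decay = TRUE, entropy_coeff = 1e-3,
                       value_coeff = 0.5, max_grad_norm = 0.5,
                       n_parallel_episodes = 256, total_updates = 200,
                       seed = NULL) {
  stopifnot(clip_epsilon > 0, discount > 0, discount <= 1,
            gae_lambda >= 0, gae_lambda <= 1,
            epochs_per_update >= 1, learning_rate > 0,
            n_parallel_episodes >= 1, total_updates >= 1)
  structure(list(clip_epsilon = clip_epsilon, discount = discount,
                 gae_lambda = gae_lambda,
                 epochs_per_update = as.integer(epochs_per_update),
                 minibatch_size = minibatch_size,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 entropy_coeff = entropy_coeff, value_coeff = value_coeff,
                 max_grad_norm = max_grad_norm,
                 n_parallel_episodes = as.integer(n_parallel_episodes),
                 total_updates = as.integer(total_updates), seed = seed),
            class = "ppo_config")
}

#' Collect a batch of rollout sequences
#'
#' Runs `n_episodes` independent stochastic episodes with the current
#' policy and returns padded transition arrays (network inputs, actions,
#' log-probabilities, values), per-episode lengths and terminal rewards.
#' Each sequence carries its episodic reward only on the final step.
#'
#' @inheritParams run_episodes
#' @param n_episodes Number of episodes to collect.
#' @return The `rollout` element of an [run_episodes()] batch, augmented
#'   with the batch itself as attribute fields `tau`/`reached`.
#' @export
collect_rollouts <- function(policy, config, field, cell, n_episodes,
                             seed = NULL) {
  b <- run_episodes(policy, config, field, cell, n = n_episodes,
                    deterministic = FALSE, collect = TRUE, seed = seed)
  r <- b$rollout
  r$tau <- b$tau
  r$reached <- b$reached
  r
}

#' Generalised advantage estimation for one sequence
#'
#' Standard GAE recursion with terminal bootstrap 0:
#' `delta_t = r_t + gamma*V_{t+1} - V_t`,
#' `A_t = delta_t + gamma*lambda*A_{t+1}`, and `returns = A + V`.
#'
#' @param values Value estimates V_t (length T).
#' @param rewards Per-step rewards (length T; here all zero except the
#'   terminal step).
#' @param discount Discount factor gamma.
#' @param gae_lambda GAE mixing parameter lambda.
#' @return A list with numeric vectors `advantages` and `returns`.
#' @export
compute_gae <- function(values, rewards, discount, gae_lambda) {
  T_ <- length(values)
  stopifnot(length(rewards) == T_)
  adv <- numeric(T_)
  nxt <- 0
  vnext <- 0
  for (t in rev(seq_len(T_))) {
    delta <- rewards[t] + discount * vnext - values[t]
    nxt <- delta + discount * gae_lambda * nxt
    adv[t] <- nxt
    vnext <- values[t]
  }
  list(advantages = adv, returns = adv + values)
}

# batched GAE over padded arrays: V (T x B), terminal reward (B), len (B)
gae_batch <- function(V, reward, len, discount, gae_lambda) {
  T_ <- nrow(V); B <- ncol(V)
  adv <- matrix(0, T_, B)
  nxt <- numeric(B)
  vnext <- numeric(B)
  for (t in rev(seq_len(T_))) {
    at_end <- (t == len)
    active <- (t <= len)
    r_t <- ifelse(at_end, reward, 0)
    vn <- ifelse(at_end, 0, vnext)       # terminal bootstrap 0
    nx <- ifelse(at_end, 0, nxt)
    delta <- r_t + discount * vn - V[t, ]
    a_t <- delta + discount * gae_lambda * nx
    adv[t, ] <- ifelse(active, a_t, 0)
    nxt <- ifelse(active, a_t, nxt)
    vnext <- ifelse(active, V[t, ], vnext)
  }
  list(advantages = adv, returns = adv + V)
}

# elementwise PPO loss gradients.  All arguments are equal-length numeric
# vectors of valid transitions; returns loss terms and dmu/dsigma/dvalue.
ppo_loss_grads <- function(mu, sigma, value, a, logp_old, adv, ret, cfg, N) {
  s <- pmax(sigma, 1e-12)
  z <- (a - mu) / s
  logp <- -0.5 * z^2 - log(s) - 0.5 * log(2 * pi)
  ratio <- exp(logp - logp_old)
  surr1 <- ratio * adv
  lo <- 1 - cfg$clip_epsilon; hi <- 1 + cfg$clip_epsilon
  surr2 <- pmin(pmax(ratio, lo), hi) * adv
  use1 <- surr1 <= surr2
  dlogp <- -(adv * ratio * use1) / N
  dmu <- dlogp * z / s
  dsigma <- dlogp * (z^2 / s - 1 / s) - cfg$entropy_coeff / (s * N)
  dvalue <- 2 * cfg$value_coeff * (value - ret) / N
  list(policy_loss = -sum(pmin(surr1, surr2)) / N,
       value_loss = cfg$value_coeff * sum((value - ret)^2) / N,
       entropy = sum(0.5 * log(2 * pi * exp(1)) + log(s)) / N,
       dmu = dmu, dsigma = dsigma, dvalue = dvalue)
}

clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  nrm <- sqrt(sum(tree_flatten(grads)^2))
  if (nrm > max_norm) grads <- tree_map(function(g) g * (max_norm / nrm), grads)
  grads
}

# forward + backward over a minibatch of full sequences for a recurrent
# policy.  Returns accumulated parameter grads and loss diagnostics.
replay_recurrent <- function(spec, params, X, a, logp_old, adv, ret, len, cfg) {
  T_ <- dim(X)[1]; B <- dim(X)[2]
  H <- matrix(0, B, spec$hidden_size)
  caches <- vector("list", T_)
  mu <- matrix(0, T_, B); sg <- matrix(0, T_, B); vl <- matrix(0, T_, B)
  for (t in seq_len(T_)) {
    o <- nn_policy_forward(spec, params, matrix(X[t, , ], B), H, cache = TRUE)
    caches[[t]] <- o$cache
    mu[t, ] <- o$mu; sg[t, ] <- o$sigma; vl[t, ] <- o$value
    H <- o$h
  }
  mask <- outer(seq_len(T_), len, `<=`)
  N <- sum(mask)
  lg <- ppo_loss_grads(mu[mask], sg[mask], vl[mask], a[mask], logp_old[mask],
                       adv[mask], ret[mask], cfg, N)
  dmu <- matrix(0, T_, B); dsg <- matrix(0, T_, B); dvl <- matrix(0, T_, B)
  dmu[mask] <- lg$dmu; dsg[mask] <- lg$dsigma; dvl[mask] <- lg$dvalue
  gacc <- NULL
  dH <- matrix(0, B, spec$hidden_size)
  for (t in rev(seq_len(T_))) {
    bk <- nn_policy_backward(spec, params, caches[[t]], dmu[t, ], dsg[t, ],
                             dvl[t, ], dh_out = dH)
    dH <- bk$dH
    gacc <- if (is.null(gacc)) bk$grads else nn_add(gacc, bk$grads)
  }
  list(grads = gacc, policy_loss = lg$policy_loss,
       value_loss = lg$value_loss, entropy = lg$entropy,
       mean_sigma = mean(sg[mask]))
}

replay_feedforward <- function(spec, params, X, a, logp_old, adv, ret, len,
                               cfg) {
  T_ <- dim(X)[1]; B <- dim(X)[2]; din <- dim(X)[3]
  mask <- outer(seq_len(T_), len, `<=`)
  rows <- which(as.vector(mask))
  Xm <- matrix(X, T_ * B, din)[rows, , drop = FALSE]
  N <- length(rows)
  o <- nn_policy_forward(spec, params, Xm, NULL, cache = TRUE)
  lg <- ppo_loss_grads(o$mu, o$sigma, o$value, a[mask], logp_old[mask],
                       adv[mask], ret[mask], cfg, N)
  bk <- nn_policy_backward(spec, params, o$cache, lg$dmu, lg$dsigma,
                           lg$dvalue)
  list(grads = bk$grads, policy_loss = lg$policy_loss,
       value_loss = lg$value_loss, entropy = lg$entropy,
       mean_sigma = mean(o$sigma))
}

#' One PPO update from a collected batch
#'
#' Optimises the clipped-surrogate policy loss plus value regression and
#' entropy bonus over `epochs_per_update` passes of the batch,
#' minibatched over episodes.  Advantages are normalised once per update.
#' Recurrent variants replay full sequences in order from their initial
#' (zero) hidden states.
#'
#' @param policy A [neural_policy()].
#' @param batch A batch from [collect_rollouts()].
#' @param cfg A [ppo_config()].
#' @param opt_state Adam optimiser state (from a previous call), or
#'   `NULL` to initialise.
#' @param lr Learning rate for this update; defaults to
#'   `cfg$learning_rate`.
#' @return A list with the updated `policy`, `opt_state`, and a
#'   `diagnostics` row (mean reward, loss terms, mean sigma).
#' @export
ppo_update <- function(policy, batch, cfg, opt_state = NULL, lr = NULL) {
  stopifnot(inherits(policy, "neural_policy"))
  spec <- policy$spec
  params <- policy$params
  if (is.null(opt_state)) opt_state <- adam_init(params)
  lr <- lr %||% cfg$learning_rate
  B <- length(batch$len)
  stopifnot(B >= 1)
  T_ <- dim(batch$X)[1]
  g <- gae_batch(batch$values, batch$reward, batch$len, cfg$discount,
                 cfg$gae_lambda)
  mask <- outer(seq_len(T_), batch$len, `<=`)
  av <- g$advantages[mask]
  adv_n <- g$advantages
  adv_n[mask] <- (av - mean(av)) / (stats::sd(av) + 1e-8)
  adv_n[!mask] <- 0
  mb_size <- min(cfg$minibatch_size %||% B, B)
  diag_acc <- c(policy_loss = 0, value_loss = 0, entropy = 0,
                mean_sigma = 0)
  n_steps <- 0L
  for (ep in seq_len(cfg$epochs_per_update)) {
    perm <- sample.int(B)
    starts <- seq(1L, B, by = mb_size)
    for (s0 in starts) {
      ids <- perm[s0:min(s0 + mb_size - 1L, B)]
      Xs <- batch$X[, ids, , drop = FALSE]
      rep_fn <- if (spec$recurrent) replay_recurrent else replay_feedforward
      r <- rep_fn(spec, params, Xs, batch$actions[, ids, drop = FALSE],
                  batch$logp[, ids, drop = FALSE],
                  adv_n[, ids, drop = FALSE],
                  g$returns[, ids, drop = FALSE], batch$len[ids], cfg)
      if (!all(is.finite(tree_flatten(r$grads))))
        stop("non-finite PPO loss gradient; diagnostics: policy_loss = ",
             r$policy_loss, ", value_loss = ", r$value_loss, call. = FALSE)
      gr <- clip_grads(r$grads, cfg$max_grad_norm)
      au <- adam_update(params, gr, opt_state, lr)
      params <- au$params
      opt_state <- au$state
      diag_acc <- diag_acc + c(r$policy_loss, r$value_loss, r$entropy,
                               r$mean_sigma)
      n_steps <- n_steps + 1L
    }
  }
  policy$params <- params
  list(policy = policy, opt_state = opt_state,
       diagnostics = data.frame(
         mean_reward = mean(batch$reward),
         mean_length = mean(batch$len),
         policy_loss = diag_acc[["policy_loss"]] / n_steps,
         value_loss = diag_acc[["value_loss"]] / n_steps,
         entropy = diag_acc[["entropy"]] / n_steps,
         mean_sigma = diag_acc[["mean_sigma"]] / n_steps))
}

#' Train a navigation policy by PPO
#'
#' Alternates [collect_rollouts()] and [ppo_update()] for
#' `ppo$total_updates` iterations, logging per-update mean reward, mean
#' episode length and mean action standard deviation.  All randomness
#' flows from `seed` through a single RNG stream, so runs are exactly
#' reproducible.
#'
#' @param spec A [policy_spec()] (or an existing [neural_policy()] to
#'   continue training).
#' @param config,field,cell Environment definition as in
#'   [run_episodes()].
#' @param ppo A [ppo_config()].
#' @param verbose Print a progress line per update.
#' @param checkpoint_dir Optional directory for periodic checkpoints.
#' @param checkpoint_every Updates between checkpoints.
#' @param seed Integer seed.
#' @return A list of class `"training_run"` with the trained `policy` and
#'   a `log` data frame (one row per update).
#' @export
train_policy <- function(spec, config, field, cell, ppo, verbose = FALSE,
                         checkpoint_dir = NULL, checkpoint_every = 50,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  policy <- if (inherits(spec, "neural_policy")) spec else neural_policy(spec)
  opt_state <- NULL
  log <- vector("list", ppo$total_updates)
  for (u in seq_len(ppo$total_updates)) {
    lr <- if (isTRUE(ppo$lr_decay))
      ppo$learning_rate * (1 - (u - 1) / ppo$total_updates)
    else ppo$learning_rate
    batch <- collect_rollouts(policy, config, field, cell,
                              ppo$n_parallel_episodes)
    res <- tryCatch(
      ppo_update(policy, batch, ppo, opt_state, lr = lr),
      error = function(e) {
        if (!is.null(checkpoint_dir)) {
          save_checkpoint(policy,
                          file.path(checkpoint_dir, "abort_checkpoint.json"),
                          metadata = list(update = u, error = conditionMessage(e)))
        }
        stop(e)
      })
    policy <- res$policy
    opt_state <- res$opt_state
    log[[u]] <- cbind(update = u, res$diagnostics, lr = lr)
    if (verbose)
      message(sprintf(
        "update %3d  reward %+.3f  len %6.1f  sigma %.3f", u,
        res$diagnostics$mean_reward, res$diagnostics$mean_length,
        res$diagnostics$mean_sigma))
    if (!is.null(checkpoint_dir) && (u %% checkpoint_every == 0L ||
                                     u == ppo$total_updates)) {
      save_checkpoint(policy,
                      file.path(checkpoint_dir,
                                sprintf("checkpoint_%04d.json", u)),
                      metadata = list(update = u))
    }
  }
  structure(list(policy = policy, log = do.call(rbind, log)),
            class = "training_run")
}
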