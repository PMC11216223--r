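# Configuration, checkpoints, fixtures, trajectory output and run
# manifests.

CHECKPOINT_VERSION <- 1L

#' Default configuration
#'
#' The full default configuration as a nested list with sections `field`
#' (concentration profile), `cell` (geometry and motility), `episode`
#' (initial conditions, horizon, step) and `ppo` (training
#' hyperparameters).  Physical defaults: lambda = 0.032/um,
#' C_q = 16/um^2 with C0 sampled over [C_q, 10 C_q], R = 2 um, K = 5,
#' v = 5 um/s, D_R = 0.025/s, delta = 10 um, dt = 0.1 s.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    field = list(C0 = 16, lambda = 0.032, kind = "exponential", r_match = 2),
    cell = list(radius = 2, n_sensors = 5, speed = 5, rot_diffusion = 0.025),
    episode = list(d0_range = c(100, 500), delta = 10, t_max = 2000,
                   dt = 0.1, conc_range = c(16, 160)),
    policy = list(hidden_size = 32, mlp_widths = c(64, 64),
                  action_scale = pi, feed_back_action = TRUE),
    ppo = unclass(ppo_config()))
}

#' Desk-scale study configuration
#'
#' The scaled-down training/evaluation conditions used by the package's
#' own directional experiments: a 2 um cell in the high-concentration
#' regime (C0 fixed at 10 C_q = 160/um^2), short episodes (d0 in
#' [60, 100] um, delta = 10 um, t_max = 60 s, dt = 0.2 s — a straight
#' path takes at most ~18 s, and the blind agent almost never arrives),
#' compact networks (hidden 16, MLP 32x32, initial sigma 0.8 rad/s), and
#' a matched 256-episode x 100-update PPO budget per variant with
#' gamma = 1 and lambda = 1 (the reward is purely terminal, so
#' whole-episode credit assignment with normalised advantages converges
#' fastest at this scale) and learning rate 1e-3 with linear decay.  See
#' the methods vignette for the rationale behind each choice.
#'
#' @return A list with ready-made `field`, `cell`, `config` (episode),
#'   and the constructor functions `spec_for(variant)` and
#'   `ppo_for(variant)` (the recurrent variants use larger minibatches
#'   to bound backpropagation-through-time cost; the environment budget
#'   is identical across variants).
#' @export
scaled_study_config <- function() {
  field <- field_params(C0 = 160, lambda = 0.032)
  cell <- cell_params(radius = 2, n_sensors = 5, speed = 5,
                      rot_diffusion = 0.025)
  config <- episode_config(d0_range = c(60, 100), delta = 10, t_max = 60,
                           dt = 0.2, conc_range = c(160, 160))
  ppo_for <- function(variant)
    ppo_config(discount = 1, gae_lambda = 1, learning_rate = 1e-3,
               minibatch_size = if (variant == "spatial") 64L else 128L,
               n_parallel_episodes = 256, total_updates = 100)
  spec_for <- function(variant)
    policy_spec(variant = variant, n_sensors = cell$n_sensors,
                hidden_size = 16, mlp_widths = c(32, 32),
                sigma_init = 0.8)
  list(field = field, cell = cell, config = config,
       ppo_for = ppo_for, spec_for = spec_for)
}

#' Write / read a configuration file
#'
#' Configurations are stored as YAML with sections field/cell/episode;
#' values omitted from the file fall back to [default_config()] (file
#' values override defaults, layered).
#'
#' @param config A nested configuration list.
#' @param path File path.
#' @return `read_config_file` returns the merged configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config_file <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists(default_config(), user)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' @rdname write_config
#' @export
config_dump <- function(config = default_config()) {
  cat(yaml::as.yaml(config))
  invisible(config)
}

# ---- checkpoints -----------------------------------------------------------

encode_params <- function(p) {
  if (is.list(p)) return(lapply(p, encode_params))
  list(.dim = dim(p) %||% length(p), .data = as.numeric(p))
}

decode_params <- function(e) {
  if (is.list(e) && !is.null(e$.data)) {
    v <- as.numeric(unlist(e$.data))
    dims <- as.integer(unlist(e$.dim))
    if (length(dims) == 2) dim(v) <- dims
    return(v)
  }
  lapply(e, decode_params)
}

#' Save / load a policy checkpoint
#'
#' Checkpoints are portable JSON containers holding the policy spec, a
#' metadata block (training seed, code version, timestamps, free-form
#' entries) and all named parameter arrays at full precision (17
#' significant digits, which round-trips IEEE doubles bit-exactly).
#'
#' @param policy A [neural_policy()].
#' @param path Output file path (`.json`).
#' @param metadata Optional named list merged into the metadata block.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored [neural_policy()] with the metadata attached
#'   as attribute `"metadata"`.
#' @export
save_checkpoint <- function(policy, path, metadata = list()) {
  stopifnot(inherits(policy, "neural_policy"))
  obj <- list(
    format = "chemonav-checkpoint",
    version = CHECKPOINT_VERSION,
    package_version = as.character(utils::packageVersion("chemonav")),
    spec = unclass(policy$spec),
    metadata = metadata,
    params = encode_params(policy$params))
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("corrupted or unreadable checkpoint: ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "chemonav-checkpoint"))
    stop("not a chemonav checkpoint file", call. = FALSE)
  if (!identical(as.integer(obj$version), CHECKPOINT_VERSION))
    stop("checkpoint version ", obj$version,
         " does not match supported version ", CHECKPOINT_VERSION,
         "; explicit migration required", call. = FALSE)
  s <- obj$spec
  spec <- policy_spec(variant = s$variant,
                      n_sensors = as.integer(s$n_sensors),
                      hidden_size = max(as.integer(s$hidden_size), 1L),
                      mlp_widths = as.integer(unlist(s$mlp_widths)),
                      action_scale = as.numeric(s$action_scale),
                      feed_back_action = isTRUE(s$feed_back_action),
                      sigma_init = as.numeric(s$sigma_init))
  params <- decode_params(obj$params)
  pol <- neural_policy(spec, params = params)
  attr(pol, "metadata") <- obj$metadata
  pol
}

# ---- trajectory output -----------------------------------------------------

#' Write a recorded trajectory to CSV
#'
#' Long-format per-step table with header columns
#' `t, x, y, theta, action, M_0..M_{K-1}, m_0..m_{K-1}` plus an
#' `episode` id and a `manifest` reference column.
#'
#' @param trajectory A recorded trajectory (from
#'   `run_episode(record = TRUE)`) or a list of them.
#' @param path Output CSV path.
#' @param manifest_ref Manifest reference string written to every row.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, manifest_ref = "") {
  trajs <- if (!is.null(trajectory$t)) list(trajectory) else trajectory
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    K <- ncol(tr$M %||% tr$m)
    df <- data.frame(episode = i, t = tr$t, x = tr$x[, 1], y = tr$x[, 2],
                     theta = tr$theta, action = tr$action)
    if (!is.null(tr$M)) {
      Mdf <- as.data.frame(tr$M)
      names(Mdf) <- paste0("M_", seq_len(K) - 1L)
      mdf <- as.data.frame(tr$m)
      names(mdf) <- paste0("m_", seq_len(K) - 1L)
      df <- cbind(df, Mdf, mdf)
    }
    df$manifest <- manifest_ref
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# ---- run manifest ----------------------------------------------------------

#' Write a run manifest
#'
#' Records the exact conditions of a run: configuration snapshot, seeds,
#' code version, timestamp and an inventory of output files with MD5
#' checksums.  Re-running with an identical manifest reproduces
#' identical outputs on the same platform.
#'
#' @param path Manifest output path (`.json`).
#' @param config Configuration list snapshot.
#' @param seeds Named list or vector of seeds used.
#' @param outputs Character vector of produced file paths.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, seeds, outputs = character(0)) {
  inv <- if (length(outputs))
    data.frame(file = outputs, md5 = unname(tools::md5sum(outputs)))
  else NULL
  obj <- list(format = "chemonav-manifest",
              package_version =
                as.character(utils::packageVersion("chemonav")),
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"),
              seeds = seeds, config = config, outputs = inv)
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

# ---- fixtures --------------------------------------------------------------

#' Deterministic test fixtures
#'
#' Generates tiny deterministic assets used in tests and examples:
#' \describe{
#'   \item{`"oracle_episode"`}{a 50-step noise-free episode steered by
#'     the perfect-aim oracle (distance decreases monotonically);}
#'   \item{`"linear_policy"`}{a linear toy policy with known weights,
#'     whose integrated-gradients attributions are `w_i x_i` in closed
#'     form, plus a probe input;}
#'   \item{`"poisson_batch"`}{a 3-episode Poisson-sensing batch at a
#'     fixed state for moment tests.}
#' }
#'
#' @param name Fixture name (see above); an unknown name lists the
#'   available fixtures in the error.
#' @param seed Integer seed; identical seeds give identical fixtures
#'   (and byte-identical files).
#' @param dir Optional directory: when supplied, the fixture is also
#'   written there as plain-text files (CSV/JSON).
#' @return The fixture object (list).
#' @export
generate_fixture <- function(name, seed = 1, dir = NULL) {
  fixtures <- c("oracle_episode", "linear_policy", "poisson_batch")
  if (!name %in% fixtures)
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  set.seed(seed)
  out <- switch(name,
    oracle_episode = {
      cell <- cell_params(radius = 2, rot_diffusion = 0)
      config <- episode_config(d0_range = c(30, 30.0001), delta = 5,
                               t_max = 5, dt = 0.1,
                               conc_range = c(160, 160))
      field <- field_params(C0 = 160)
      res <- run_episode(oracle_policy(), config, field, cell,
                         record = TRUE, deterministic = TRUE)
      list(result = res, config = config, field = field, cell = cell)
    },
    linear_policy = {
      w <- round(stats::rnorm(6), 3)
      x <- round(stats::rnorm(6), 3)
      list(policy = linear_policy(w), weights = w, input = x)
    },
    poisson_batch = {
      cell <- cell_params(radius = 2)
      field <- field_params(C0 = 160)
      state <- cell_state(position = c(40, 0), heading = pi / 4)
      draws <- t(replicate(3, sample_observation(field, cell, state)$counts))
      list(state = state, field = field, cell = cell,
           expected = expected_counts(field, cell, state), draws = draws)
    })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    switch(name,
      oracle_episode =
        write_trajectory_csv(out$result$trajectory,
                             file.path(dir, "oracle_episode.csv"),
                             manifest_ref = paste0("fixture-seed-", seed)),
      linear_policy =
        writeLines(jsonlite::toJSON(list(weights = out$weights,
                                         input = out$input),
                                    digits = I(17)),
                   file.path(dir, "linear_policy.json")),
      poisson_batch =
        utils::write.csv(out$draws, file.path(dir, "poisson_batch.csv"),
                         row.names = FALSE))
  }
  out
}
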