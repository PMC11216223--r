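# Integrated-gradients attribution of trained policies: per-input
# importances of the deterministic steering output mu, the memory-usage
# statistic U_h, and through-time (unrolled) sensor attributions.

#' Canonical attribution input layout of a neural policy
#'
#' The single-step policy input vector is laid out as
#' `[measurement inputs, previous action (if fed back), hidden state]`.
#'
#' @param policy A [neural_policy()].
#' @return A list with integer index vectors `meas`, `action`, `hidden`,
#'   a `labels` character vector, and the total input length `n`.
#' @export
policy_input_layout <- function(policy) {
  spec <- policy$spec
  dm <- spec$n_meas
  meas <- seq_len(dm)
  action <- if (spec$feed_back_action) dm + 1L else integer(0)
  hidden <- if (spec$recurrent)
    (dm + length(action)) + seq_len(spec$hidden_size) else integer(0)
  labels <- c(if (spec$variant == "temporal") "mean_m"
              else paste0("m_", seq_len(dm) - 1L),
              if (length(action)) "prev_action",
              if (length(hidden)) paste0("h_", seq_len(spec$hidden_size)))
  list(meas = meas, action = action, hidden = hidden, labels = labels,
       n = dm + length(action) + length(hidden))
}

#' Batched value-and-gradient evaluation
#'
#' Generic used by [integrated_gradients()]: evaluates a scalar
#' differentiable function (the deterministic steering output mu for
#' neural policies) and its input gradient on a batch of inputs.
#'
#' @param obj A policy-like object with a method.
#' @param X A B x d matrix of input rows.
#' @return A list with `value` (length B) and `grad` (B x d).
#' @export
value_and_grad <- function(obj, X) UseMethod("value_and_grad")

#' @export
value_and_grad.neural_policy <- function(obj, X) {
  spec <- obj$spec
  lay <- policy_input_layout(obj)
  stopifnot(ncol(X) == lay$n)
  Xin <- X[, c(lay$meas, lay$action), drop = FALSE]
  H <- if (spec$recurrent) X[, lay$hidden, drop = FALSE] else NULL
  o <- nn_policy_forward(spec, obj$params, Xin, H, cache = TRUE)
  B <- nrow(X)
  bk <- nn_policy_backward(spec, obj$params, o$cache, dmu = rep(1, B),
                           dsigma = numeric(B), dvalue = numeric(B))
  grad <- if (spec$recurrent) cbind(bk$dX, bk$dH) else bk$dX
  list(value = o$mu, grad = grad)
}

#' Linear toy policy for attribution tests
#'
#' A policy whose deterministic output is the inner product `w . x`; its
#' integrated-gradients attributions from a zero baseline are `w_i x_i`
#' in closed form.
#'
#' @param weights Numeric weight vector w.
#' @return An object usable with [integrated_gradients()].
#' @export
linear_policy <- function(weights) {
  structure(list(w = as.numeric(weights)), class = "linear_policy")
}

#' @export
value_and_grad.linear_policy <- function(obj, X) {
  list(value = as.numeric(X %*% obj$w),
       grad = matrix(obj$w, nrow(X), length(obj$w), byrow = TRUE))
}

#' Integrated-gradients attribution
#'
#' Computes the importance of each input of a differentiable policy
#' output by integrating the output gradient along the straight path
#' from a baseline `x'` to the input `x`:
#' \deqn{I_i = (x_i - x_i')\int_0^1
#'       \frac{\partial \pi(x' + \alpha(x - x'))}{\partial x_i}\,d\alpha.}
#' The path integral is approximated by a midpoint Riemann sum over
#' `n_steps` points.  The attribution target is the deterministic action
#' output mu.  Completeness — attributions summing to
#' `pi(x) - pi(x')` — is reported and checked against `tolerance`.
#'
#' @param policy A [neural_policy()], [linear_policy()], or any object
#'   with a `value_and_grad` method.
#' @param x Input vector (for neural policies, laid out as in
#'   [policy_input_layout()]).
#' @param baseline Baseline input x'; defaults to all zeros (no input).
#' @param n_steps Integration resolution (>= 2).
#' @param tolerance Relative completeness tolerance; a warning suggests
#'   raising `n_steps` when exceeded.
#' @return An object of class `"attribution_record"`: a list with
#'   `importances`, `baseline`, `n_steps`, `completeness_error`
#'   (absolute), `completeness_rel`, `value`, `value_baseline` and, for
#'   neural policies, the input `partition`.
#' @export
integrated_gradients <- function(policy, x, baseline = NULL, n_steps = 512,
                                 tolerance = 1e-3) {
  stopifnot(n_steps >= 2)
  x <- as.numeric(x)
  baseline <- if (is.null(baseline)) numeric(length(x)) else as.numeric(baseline)
  stopifnot(length(baseline) == length(x))
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  dxv <- x - baseline
  Xpath <- outer(alphas, dxv) + matrix(baseline, n_steps, length(x),
                                       byrow = TRUE)
  Xall <- rbind(Xpath, x, baseline)
  vg <- value_and_grad(policy, Xall)
  g <- vg$grad[seq_len(n_steps), , drop = FALSE]
  I <- dxv * colMeans(g)
  f_x <- vg$value[n_steps + 1L]
  f_b <- vg$value[n_steps + 2L]
  err <- abs(f_x - f_b - sum(I))
  rel <- err / max(abs(f_x - f_b), 1e-12)
  if (rel > tolerance && err > 1e-12)
    warning(sprintf(paste0("integrated-gradients completeness error %.2e ",
                           "(relative %.2e) exceeds tolerance %.1e; ",
                           "consider raising n_steps"), err, rel, tolerance),
            call. = FALSE)
  rec <- list(importances = I, baseline = baseline, n_steps = n_steps,
              completeness_error = err, completeness_rel = rel,
              value = f_x, value_baseline = f_b)
  if (inherits(policy, "neural_policy"))
    rec$partition <- policy_input_layout(policy)
  structure(rec, class = "attribution_record")
}

#' Memory-usage statistic U_h
#'
#' The fraction of total absolute attribution carried by the recurrent
#' hidden-state inputs relative to hidden plus instantaneous
#' measurements:
#' \deqn{U_h = \frac{\sum_{i\in h}|I_i|}
#'       {\sum_{i\in h}|I_i| + \sum_{i\in m}|I_i|}.}
#' Previous-action attributions are excluded from both sums.  `U_h = 1`
#' means the decision relies on memory only; `U_h = 0` means it relies
#' on instantaneous measurements only.  For a policy without hidden
#' inputs (spatial variant) `U_h` is 0 by construction.  If both sums
#' vanish the statistic is undefined and `NA` is returned with attribute
#' `"undefined"`.
#'
#' @param record An `"attribution_record"` from [integrated_gradients()]
#'   on a neural policy (must carry the input partition), or a list with
#'   `importances` and `partition`.
#' @return A numeric scalar in `[0, 1]` (or `NA` with attribute
#'   `undefined = TRUE`).
#' @export
memory_usage <- function(record) {
  part <- record$partition
  if (is.null(part))
    stop("attribution record carries no input partition", call. = FALSE)
  I <- record$importances
  sh <- sum(abs(I[part$hidden]))
  sm <- sum(abs(I[part$meas]))
  if (length(part$hidden) == 0) return(0)
  if (sh + sm == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  sh / (sh + sm)
}

# single recorded trajectory step -> attribution input vector
step_input_vector <- function(policy, traj, s) {
  spec <- policy$spec
  mrow <- traj$m[s, ]
  xm <- if (spec$variant == "temporal") mean(mrow) else mrow
  c(xm, if (spec$feed_back_action) traj$prev_action[s],
    if (spec$recurrent) traj$h_pre[s, ])
}

#' Attribution of one trajectory step
#'
#' Convenience wrapper: builds the single-step input vector (current
#' measurements, previous action, pre-update hidden state) from a
#' recorded trajectory and applies [integrated_gradients()].
#'
#' @param policy The [neural_policy()] that generated the trajectory.
#' @param trajectory A recorded trajectory from
#'   `run_episode(record = TRUE)`.
#' @param s Step index (1-based).
#' @inheritParams integrated_gradients
#' @return An `"attribution_record"`.
#' @export
step_attribution <- function(policy, trajectory, s, n_steps = 512,
                             tolerance = 1e-3) {
  integrated_gradients(policy, step_input_vector(policy, trajectory, s),
                       n_steps = n_steps, tolerance = tolerance)
}

#' Through-time sensor attributions of a recurrent policy
#'
#' Expresses the current deterministic action as a function of the last
#' `T_back` observation vectors by unrolling the recurrence from the
#' stored hidden state `T_back` steps earlier, then attributes the
#' action jointly over all lagged measurement inputs (and the initial
#' hidden state) with integrated gradients from a zero baseline.  The
#' recorded previous actions are held fixed along the integration path,
#' so completeness holds over the attributed inputs.  Curves are
#' averaged over the requested trajectory positions.
#'
#' For the temporal variant the network's measurement input is the
#' scalar mean `<m>`; the per-lag scalar attribution is split equally
#' across the K sensors, which preserves completeness and realises the
#' variant's designed sensor symmetry exactly.  For the spatial variant
#' all positive-lag attributions are exactly zero.
#'
#' @param policy A [neural_policy()].
#' @param trajectory A recorded trajectory (with hidden states) from
#'   `run_episode(record = TRUE)`.
#' @param T_back Unroll horizon in steps.
#' @param n_steps Integration resolution.
#' @param positions Trajectory step indices at which to attribute;
#'   defaults to all steps with a full `T_back` history (if none exist,
#'   the final step is used with a truncated horizon and the result is
#'   flagged).
#' @return An object of class `"unrolled_attribution"`: list with
#'   `importances` (lag x sensor matrix, lag 0 = current step),
#'   `hidden_importance` (total attribution of the unroll-initial hidden
#'   state), `completeness_error` (worst absolute completeness defect
#'   over positions) and `completeness_rel` (that defect relative to the
#'   largest output change seen across positions — a per-position
#'   relative error would be meaningless at positions where the action
#'   barely responds), `n_positions`, `lags` and `truncated`.
#' @export
unrolled_attribution <- function(policy, trajectory, T_back = 300,
                                 n_steps = 128, positions = NULL) {
  stopifnot(inherits(policy, "neural_policy"))
  spec <- policy$spec
  K <- spec$n_sensors
  Tn <- length(trajectory$t)
  truncated <- FALSE
  if (is.null(positions)) {
    positions <- which(seq_len(Tn) >= T_back)
    if (length(positions) == 0) {
      positions <- Tn
      truncated <- TRUE
    }
  }
  L <- min(T_back, min(positions))

  if (!spec$recurrent) {
    # stateless policy: only lag 0 can carry attribution
    imp <- matrix(0, L, K)
    err <- 0; dmax <- 0
    for (t in positions) {
      rec <- suppressWarnings(
        step_attribution(policy, trajectory, t, n_steps = n_steps))
      imp[1, ] <- imp[1, ] + rec$importances[rec$partition$meas]
      err <- max(err, rec$completeness_error)
      dmax <- max(dmax, abs(rec$value - rec$value_baseline))
    }
    imp[1, ] <- imp[1, ] / length(positions)
    return(structure(list(importances = imp, hidden_importance = 0,
                          completeness_error = err,
                          completeness_rel = err / max(dmax, 1e-12),
                          n_positions = length(positions),
                          lags = seq_len(L) - 1L, truncated = truncated),
                     class = "unrolled_attribution"))
  }

  dm <- spec$n_meas
  alphas <- c((seq_len(n_steps) - 0.5) / n_steps, 1, 0)
  B <- length(alphas)
  imp_acc <- matrix(0, L, K)
  hid_acc <- 0
  err <- 0; dmax <- 0
  for (t in positions) {
    Lp <- min(L, t)
    s0 <- t - Lp + 1L
    h0 <- trajectory$h_pre[s0, ]
    H <- outer(alphas, h0)
    caches <- vector("list", Lp)
    meas <- vector("list", Lp)
    for (j in seq_len(Lp)) {
      s <- s0 + j - 1L
      mrow <- trajectory$m[s, ]
      xm <- if (spec$variant == "temporal") mean(mrow) else mrow
      meas[[j]] <- xm
      Xj <- outer(alphas, xm)
      if (spec$feed_back_action)
        Xj <- cbind(Xj, rep(trajectory$prev_action[s], B))
      o <- nn_policy_forward(spec, policy$params, Xj, H, cache = TRUE)
      caches[[j]] <- o$cache
      H <- o$h
      if (j == Lp) mu_ends <- o$mu[(n_steps + 1L):(n_steps + 2L)]
    }
    # backward: dmu = 1 at the final unroll step only
    dH <- matrix(0, B, spec$hidden_size)
    Imat <- matrix(0, Lp, dm)
    for (j in rev(seq_len(Lp))) {
      dmu <- if (j == Lp) rep(1, B) else numeric(B)
      bk <- nn_policy_backward(spec, policy$params, caches[[j]], dmu,
                               numeric(B), numeric(B), dh_out = dH)
      dH <- bk$dH
      gmeas <- bk$dX[seq_len(n_steps), seq_len(dm), drop = FALSE]
      Imat[j, ] <- meas[[j]] * colMeans(gmeas)
    }
    I_h0 <- h0 * colMeans(dH[seq_len(n_steps), , drop = FALSE])
    total <- sum(Imat) + sum(I_h0)
    e <- abs(mu_ends[1] - mu_ends[2] - total)
    err <- max(err, e)
    dmax <- max(dmax, abs(mu_ends[1] - mu_ends[2]))
    # lag 0 = current step = unroll step Lp
    sensor_I <- if (spec$variant == "temporal")
      matrix(rev(Imat[, 1]) / K, Lp, K)
    else Imat[rev(seq_len(Lp)), , drop = FALSE]
    if (Lp < L) sensor_I <- rbind(sensor_I, matrix(0, L - Lp, K))
    imp_acc <- imp_acc + sensor_I
    hid_acc <- hid_acc + sum(I_h0)
    if (Lp < L) truncated <- TRUE
  }
  structure(list(importances = imp_acc / length(positions),
                 hidden_importance = hid_acc / length(positions),
                 completeness_error = err,
                 completeness_rel = err / max(dmax, 1e-12),
                 n_positions = length(positions),
                 lags = seq_len(L) - 1L, truncated = truncated),
            class = "unrolled_attribution")
}

#' Memory-usage map over cell sizes and concentration scales
#'
#' Evaluates the memory-usage statistic U_h at recorded steps of
#' evaluation trajectories for each (cell size, concentration scale)
#' combination, and aggregates it both as a mean per combination and as
#' a distance-to-source-resolved profile.
#'
#' @param policies Named list of trained [neural_policy()] objects (one
#'   per cell size).
#' @param cells Named list of matching [cell_params()] (same names).
#' @param conc_scales Numeric vector of fixed peak concentrations C0
#'   (particles/um^2) at which to evaluate.
#' @param config An [episode_config()] template; its `conc_range` is
#'   replaced by each fixed scale.
#' @param field A [field_params()] template.
#' @param n_runs Trajectories per combination.
#' @param n_steps Integration resolution per evaluated step.
#' @param stride Evaluate U_h every `stride`-th trajectory step.
#' @param n_bins Distance bins for the resolved profile.
#' @param seed Integer seed.
#' @return A list with data frames `table` (radius x scale -> mean U_h)
#'   and `profile` (distance-binned U_h mean/sd).
#' @export
memory_usage_map <- function(policies, cells, conc_scales, config, field,
                             n_runs = 8, n_steps = 64, stride = 5,
                             n_bins = 6, seed = NULL) {
  stopifnot(identical(sort(names(policies)), sort(names(cells))))
  if (!is.null(seed)) set.seed(seed)
  tab <- list(); prof <- list(); i <- 0L
  for (nm in names(policies)) {
    pol <- policies[[nm]]
    cell <- cells[[nm]]
    for (cs in conc_scales) {
      i <- i + 1L
      cfg <- config
      cfg$conc_range <- c(cs, cs)
      b <- run_episodes(pol, cfg, field, cell, n = n_runs,
                        deterministic = TRUE, record = TRUE)
      uh <- numeric(0); dist <- numeric(0)
      for (tr in b$trajectories) {
        steps <- seq(1L, length(tr$t), by = stride)
        for (s in steps) {
          rec <- suppressWarnings(
            step_attribution(pol, tr, s, n_steps = n_steps))
          u <- memory_usage(rec)
          if (!is.na(u)) {
            uh <- c(uh, u)
            dist <- c(dist, sqrt(sum(tr$x[s, ]^2)))
          }
        }
      }
      tab[[i]] <- data.frame(radius = cell$radius, conc_scale = cs,
                             mean_Uh = mean(uh), n_steps_evaluated = length(uh))
      if (length(uh) >= n_bins) {
        br <- unique(stats::quantile(dist, probs = seq(0, 1, length.out = n_bins + 1)))
        bin <- cut(dist, br, include.lowest = TRUE)
        prof[[i]] <- data.frame(
          radius = cell$radius, conc_scale = cs,
          bin_lo = br[-length(br)], bin_hi = br[-1],
          mean_Uh = tapply(uh, bin, mean),
          sd_Uh = tapply(uh, bin, stats::sd),
          n = as.integer(table(bin)), row.names = NULL)
      }
    }
  }
  list(table = do.call(rbind, tab),
       profile = if (length(prof)) do.call(rbind, prof) else NULL)
}
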