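test_that("variant input designs are enforced by construction", {
  # temporal: only the mean measurement enters
  pt <- random_tiny_policy("temporal")
  m1 <- c(1, 2, 3, 4, 5)
  m2 <- rev(m1)                     # same mean, different layout
  h <- rnorm(pt$spec$hidden_size)
  o1 <- policy_forward(pt, m1, hidden = h, prev_action = 0.2)
  o2 <- policy_forward(pt, m2, hidden = h, prev_action = 0.2)
  expect_identical(o1, o2)
  m3 <- m1 + 0.5                    # different mean
  o3 <- policy_forward(pt, m3, hidden = h, prev_action = 0.2)
  expect_false(identical(o1$mu, o3$mu))

  # spatial: stateless, ignores hidden/prev_action, sensitive to layout
  ps <- random_tiny_policy("spatial")
  a1 <- policy_forward(ps, m1)
  a2 <- policy_forward(ps, m1, hidden = rnorm(4), prev_action = 99)
  expect_identical(a1[c("mu", "sigma", "value")],
                   a2[c("mu", "sigma", "value")])
  expect_null(a1$next_hidden)
  expect_false(identical(a1$mu, policy_forward(ps, m2)$mu))

  expect_error(policy_forward(ps, m1[1:3]), "expects")
})

test_that("zeroed parameters give the analytic degenerate outputs", {
  for (v in c("spatial", "temporal", "combined")) {
    p <- zeroed_policy(v)
    o <- policy_forward(p, c(1, 2, 3, 4, 5),
                        hidden = rep(0.3, p$spec$hidden_size))
    expect_identical(o$mu, 0)
    expect_identical(o$value, 0)
    expect_equal(o$sigma, log(2))   # softplus(0)
  }
})

test_that("the mu head is bounded by the action scale", {
  set.seed(8)
  p <- random_tiny_policy("combined")
  # inflate weights to drive the heads into saturation
  p$params <- chemonav:::tree_map(function(x) x * 50, p$params)
  for (i in 1:20) {
    o <- policy_forward(p, rnorm(5, sd = 5),
                        hidden = rnorm(p$spec$hidden_size),
                        prev_action = rnorm(1))
    expect_lte(abs(o$mu), p$spec$action_scale)
  }
})

test_that("analytic network gradients match finite differences", {
  ns <- asNamespace("chemonav")
  set.seed(42)
  for (variant in c("spatial", "temporal", "combined")) {
    p <- random_tiny_policy(variant, seed = 42)
    spec <- p$spec
    B <- 3
    X <- matrix(rnorm(B * spec$n_inputs), B)
    H <- if (spec$recurrent) matrix(rnorm(B * spec$hidden_size), B) else NULL
    cm <- rnorm(B); cs <- rnorm(B); cv <- rnorm(B)
    loss <- function(pars) {
      o <- ns$nn_policy_forward(spec, pars, X, H)
      sum(cm * o$mu + cs * o$sigma + cv * o$value)
    }
    o <- ns$nn_policy_forward(spec, p$params, X, H, cache = TRUE)
    bk <- ns$nn_policy_backward(spec, p$params, o$cache, cm, cs, cv)
    ga <- ns$tree_flatten(bk$grads)
    flat <- ns$tree_flatten(p$params)
    eps <- 1e-6
    gn <- vapply(seq_along(flat), function(i) {
      p1 <- flat; p1[i] <- p1[i] + eps
      p2 <- flat; p2[i] <- p2[i] - eps
      (loss(ns$tree_unflatten(p$params, p1)) -
         loss(ns$tree_unflatten(p$params, p2))) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(ga - gn)), 1e-7)
    # input and hidden-state gradients
    gX <- vapply(seq_along(X), function(i) {
      x1 <- X; x1[i] <- x1[i] + eps
      x2 <- X; x2[i] <- x2[i] - eps
      o1 <- ns$nn_policy_forward(spec, p$params, x1, H)
      o2 <- ns$nn_policy_forward(spec, p$params, x2, H)
      (sum(cm * o1$mu + cs * o1$sigma + cv * o1$value) -
         sum(cm * o2$mu + cs * o2$sigma + cv * o2$value)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(as.numeric(bk$dX) - gX)), 1e-7)
    if (spec$recurrent) {
      gH <- vapply(seq_along(H), function(i) {
        h1 <- H; h1[i] <- h1[i] + eps
        h2 <- H; h2[i] <- h2[i] - eps
        o1 <- ns$nn_policy_forward(spec, p$params, X, h1)
        o2 <- ns$nn_policy_forward(spec, p$params, X, h2)
        (sum(cm * o1$mu + cs * o1$sigma + cv * o1$value) -
           sum(cm * o2$mu + cs * o2$sigma + cv * o2$value)) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(as.numeric(bk$dH) - gH)), 1e-7)
    }
  }
})

test_that("action sampling follows the Gaussian policy head", {
  out <- list(mu = 0.4, sigma = 0)
  expect_identical(sample_action(out), 0.4)
  out2 <- list(mu = -0.2, sigma = 0.5)
  expect_identical(sample_action(out2, deterministic = TRUE), -0.2)
  set.seed(12)
  a <- replicate(1e4, sample_action(out2))
  expect_lt(abs(mean(a) + 0.2), 4 * 0.5 / sqrt(1e4))
  set.seed(3); a1 <- sample_action(out2)
  set.seed(3); a2 <- sample_action(out2)
  expect_identical(a1, a2)
})

test_that("the blind policy never turns", {
  env <- tiny_env(rot_diffusion = 0)
  res <- run_episode(blind_policy(), env$config, env$field, env$cell,
                     record = TRUE, seed = 4)
  expect_true(all(res$trajectory$action == 0))
  expect_equal(stats::sd(res$trajectory$theta), 0)  # straight line
})

test_that("kernel policies reduce to their algebraic identities", {
  K <- 5
  sinw <- sin(2 * pi * (0:4) / K)
  act_seq <- function(pol, ms) {
    h <- chemonav:::policy_init_hidden(pol, 1)
    out <- numeric(nrow(ms))
    for (i in seq_len(nrow(ms))) {
      a <- chemonav:::policy_act(pol, ms[i, , drop = FALSE], h, 0, TRUE, NULL)
      out[i] <- a$action
      h <- a$hidden
    }
    out
  }
  set.seed(10)
  ms <- matrix(runif(12 * K, 0, 3), 12, K)
  # zero signal -> zero turn
  expect_identical(act_seq(kernel_policy(c(0.5, 0.3), 2), 0 * ms),
                   rep(0, 12))
  # delta kernel == instantaneous left-right comparator
  a_delta <- act_seq(kernel_policy(1, gain = 1.7), ms)
  expect_equal(a_delta, 1.7 * as.numeric(ms %*% sinw))
  # uniform kernel of length L == comparator on L-step moving averages
  L <- 4
  a_unif <- act_seq(kernel_policy(rep(1 / L, L), gain = 2), ms)
  contrast <- as.numeric(ms %*% sinw)
  mov <- sapply(seq_len(12), function(i)
    mean(c(rep(0, max(0, L - i)), contrast[max(1, i - L + 1):i])))
  expect_equal(a_unif, 2 * mov)
})

test_that("the switching policy latches from temporal to spatial", {
  pt <- random_tiny_policy("temporal", seed = 1)
  ps <- random_tiny_policy("spatial", seed = 2)
  run_sw <- function(threshold, ms) {
    pol <- switching_policy(pt, ps, threshold)
    h <- chemonav:::policy_init_hidden(pol, 1)
    acts <- numeric(nrow(ms)); regime <- logical(nrow(ms))
    for (i in seq_len(nrow(ms))) {
      o <- chemonav:::policy_act(pol, ms[i, , drop = FALSE], h, 0, TRUE, NULL)
      acts[i] <- o$action; regime[i] <- o$hidden$switched
      h <- o$hidden
    }
    list(acts = acts, regime = regime)
  }
  run_plain <- function(pol, ms) {
    h <- chemonav:::policy_init_hidden(pol, 1)
    acts <- numeric(nrow(ms))
    for (i in seq_len(nrow(ms))) {
      o <- chemonav:::policy_act(pol, ms[i, , drop = FALSE], h, 0, TRUE, NULL)
      acts[i] <- o$action
      h <- o$hidden
    }
    acts
  }
  set.seed(11)
  # mean measurement rises then falls below the threshold again
  ms <- matrix(rep(c(1, 1.5, 2.5, 3, 2.5, 1, 0.5), each = 5), ncol = 5,
               byrow = TRUE)
  expect_identical(run_sw(Inf, ms)$acts, run_plain(pt, ms))
  expect_identical(run_sw(0, ms)$acts, run_plain(ps, ms))
  r <- run_sw(2, ms)
  expect_identical(r$regime, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(which(diff(r$regime) != 0), 2L)  # switches exactly once
})
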