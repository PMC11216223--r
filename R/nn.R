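# Self-contained neural-network layers with analytic gradients.
#
# The policies are small (a GRU of a few dozen units feeding a two-layer
# tanh MLP with mu/sigma/value heads), so the package carries its own
# dependency-light, fully vectorised implementations: batched forward
# passes cache activations, and backward passes return exact parameter
# and input gradients.  All matrices are row-batched (one row per
# episode/sample).

# Gaussian fan-in initialisation; `scale` multiplies the 1/sqrt(fan_in)
# factor (tanh-friendly default).
nn_init_mat <- function(n_in, n_out, scale = 1) {
  matrix(stats::rnorm(n_in * n_out, sd = scale / sqrt(n_in)), n_in, n_out)
}

# ---- dense / MLP -----------------------------------------------------------

mlp_init <- function(n_in, widths) {
  layers <- list()
  prev <- n_in
  for (i in seq_along(widths)) {
    layers[[i]] <- list(W = nn_init_mat(prev, widths[i]), b = numeric(widths[i]))
    prev <- widths[i]
  }
  layers
}

# X: B x n_in.  Returns list(out, cache)
mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers))
  H <- X
  for (i in seq_along(layers)) {
    H <- tanh(sweep(H %*% layers[[i]]$W, 2, -layers[[i]]$b))
    acts[[i]] <- H
  }
  list(out = H, cache = list(X = X, acts = acts))
}

# dOut: B x n_last gradient at the MLP output.
# Returns list(grads = per-layer list(W, b), dX)
mlp_backward <- function(layers, cache, dOut) {
  n <- length(layers)
  grads <- vector("list", n)
  d <- dOut
  for (i in rev(seq_len(n))) {
    A <- cache$acts[[i]]
    dpre <- d * (1 - A * A)
    inp <- if (i == 1) cache$X else cache$acts[[i - 1]]
    grads[[i]] <- list(W = crossprod(inp, dpre), b = colSums(dpre))
    d <- dpre %*% t(layers[[i]]$W)
  }
  list(grads = grads, dX = d)
}

# ---- GRU cell --------------------------------------------------------------
# r = sigmoid(X Wr + H Ur + br)
# z = sigmoid(X Wz + H Uz + bz)
# ntil = tanh(X Wn + bin + r * (H Un + bhn))
# h' = (1 - z) * ntil + z * H

gru_init <- function(n_in, n_hidden) {
  list(Wr = nn_init_mat(n_in, n_hidden), Ur = nn_init_mat(n_hidden, n_hidden),
       br = numeric(n_hidden),
       Wz = nn_init_mat(n_in, n_hidden), Uz = nn_init_mat(n_hidden, n_hidden),
       bz = numeric(n_hidden),
       Wn = nn_init_mat(n_in, n_hidden), Un = nn_init_mat(n_hidden, n_hidden),
       bin = numeric(n_hidden), bhn = numeric(n_hidden))
}

gru_forward <- function(g, X, H) {
  r <- sigmoid(sweep(X %*% g$Wr + H %*% g$Ur, 2, -g$br))
  z <- sigmoid(sweep(X %*% g$Wz + H %*% g$Uz, 2, -g$bz))
  hn <- sweep(H %*% g$Un, 2, -g$bhn)
  ntil <- tanh(sweep(X %*% g$Wn, 2, -g$bin) + r * hn)
  hnew <- (1 - z) * ntil + z * H
  list(h = hnew, cache = list(X = X, H = H, r = r, z = z, hn = hn, ntil = ntil))
}

# dH_new: B x hidden gradient at the updated hidden state.
# Returns list(grads, dX, dH) where dH is the gradient at the previous
# hidden state.
gru_backward <- function(g, cache, dH_new) {
  X <- cache$X; H <- cache$H
  r <- cache$r; z <- cache$z; hn <- cache$hn; ntil <- cache$ntil
  dz <- dH_new * (H - ntil)
  dn <- dH_new * (1 - z)
  dH <- dH_new * z
  dn_pre <- dn * (1 - ntil * ntil)
  dr <- dn_pre * hn
  dhn <- dn_pre * r
  dH <- dH + dhn %*% t(g$Un)
  dz_pre <- dz * z * (1 - z)
  dr_pre <- dr * r * (1 - r)
  dH <- dH + dz_pre %*% t(g$Uz) + dr_pre %*% t(g$Ur)
  dX <- dn_pre %*% t(g$Wn) + dz_pre %*% t(g$Wz) + dr_pre %*% t(g$Wr)
  grads <- list(
    Wr = crossprod(X, dr_pre), Ur = crossprod(H, dr_pre), br = colSums(dr_pre),
    Wz = crossprod(X, dz_pre), Uz = crossprod(H, dz_pre), bz = colSums(dz_pre),
    Wn = crossprod(X, dn_pre), Un = crossprod(H, dhn), bin = colSums(dn_pre),
    bhn = colSums(dhn))
  list(grads = grads, dX = dX, dH = dH)
}

# ---- full policy network ---------------------------------------------------
# spatial:            X -> MLP -> heads
# temporal/combined:  X, H -> GRU -> MLP -> heads
# heads: mu = action_scale * tanh(z_mu); sigma = softplus(z_sigma); value.

nn_policy_init <- function(spec) {
  din <- spec$n_inputs
  p <- list()
  if (spec$recurrent) {
    p$gru <- gru_init(din, spec$hidden_size)
    mlp_in <- spec$hidden_size
  } else {
    mlp_in <- din
  }
  p$mlp <- mlp_init(mlp_in, spec$mlp_widths)
  last <- utils::tail(spec$mlp_widths, 1)
  p$heads <- list(
    mu = list(W = nn_init_mat(last, 1, scale = 0.01), b = numeric(1)),
    sigma = list(W = nn_init_mat(last, 1, scale = 0.01),
                 b = softplus_inv(spec$sigma_init)),
    value = list(W = nn_init_mat(last, 1), b = numeric(1)))
  p
}

# X: B x n_inputs; H: B x hidden (ignored / NULL for non-recurrent).
# Returns mu, sigma, value (length-B vectors), h (B x hidden or NULL) and,
# when cache = TRUE, the activation cache for nn_policy_backward.
nn_policy_forward <- function(spec, params, X, H = NULL, cache = FALSE) {
  gcache <- NULL
  if (spec$recurrent) {
    if (is.null(H)) H <- matrix(0, nrow(X), spec$hidden_size)
    gf <- gru_forward(params$gru, X, H)
    feat <- gf$h
    gcache <- gf$cache
    hnew <- gf$h
  } else {
    feat <- X
    hnew <- NULL
  }
  mf <- mlp_forward(params$mlp, feat)
  top <- mf$out
  z_mu <- as.numeric(top %*% params$heads$mu$W + params$heads$mu$b)
  tz <- tanh(z_mu)
  mu <- spec$action_scale * tz
  z_s <- as.numeric(top %*% params$heads$sigma$W + params$heads$sigma$b)
  sigma <- softplus(z_s)
  value <- as.numeric(top %*% params$heads$value$W + params$heads$value$b)
  out <- list(mu = mu, sigma = sigma, value = value, h = hnew)
  if (cache)
    out$cache <- list(gru = gcache, mlp = mf$cache, top = top,
                      tz = tz, z_s = z_s, X = X)
  out
}

# dmu, dsigma, dvalue: length-B gradients of the loss wrt the heads.
# dh_out: optional B x hidden gradient flowing into the *updated* hidden
# state from later time steps (backprop through time).
# Returns list(grads (same tree as params), dX, dH).
nn_policy_backward <- function(spec, params, cache, dmu, dsigma, dvalue,
                               dh_out = NULL) {
  B <- length(dmu)
  top <- cache$top
  dz_mu <- dmu * spec$action_scale * (1 - cache$tz^2)
  dz_s <- dsigma * sigmoid(cache$z_s)
  dv <- dvalue
  h <- params$heads
  grads_heads <- list(
    mu = list(W = crossprod(top, matrix(dz_mu, B, 1)), b = sum(dz_mu)),
    sigma = list(W = crossprod(top, matrix(dz_s, B, 1)), b = sum(dz_s)),
    value = list(W = crossprod(top, matrix(dv, B, 1)), b = sum(dv)))
  dTop <- matrix(dz_mu, B, 1) %*% t(h$mu$W) +
    matrix(dz_s, B, 1) %*% t(h$sigma$W) +
    matrix(dv, B, 1) %*% t(h$value$W)
  mb <- mlp_backward(params$mlp, cache$mlp, dTop)
  if (spec$recurrent) {
    dh_new <- mb$dX
    if (!is.null(dh_out)) dh_new <- dh_new + dh_out
    gb <- gru_backward(params$gru, cache$gru, dh_new)
    list(grads = list(gru = gb$grads, mlp = mb$grads, heads = grads_heads),
         dX = gb$dX, dH = gb$dH)
  } else {
    list(grads = list(mlp = mb$grads, heads = grads_heads),
         dX = mb$dX, dH = NULL)
  }
}

nn_zero_like <- function(params) tree_map(function(x) x * 0, params)

nn_add <- function(a, b) tree_map2(`+`, a, b)

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = nn_zero_like(params), v = nn_zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
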