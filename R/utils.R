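# Small internal helpers shared across modules.

# wrap an angle to [0, 2*pi)
wrap_angle <- function(theta) theta %% (2 * pi)

# wrap an angle difference to [-pi, pi)
wrap_pi <- function(dtheta) ((dtheta + pi) %% (2 * pi)) - pi

# numerically stable softplus and its inverse
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}
sigmoid <- function(x) 1 / (1 + exp(-x))

# recursive map over two parameter trees with identical structure
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) tree_map(f, x))
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

# flatten a parameter tree to a single numeric vector (for norms/tests)
tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_flatten), use.names = FALSE) else as.numeric(a)
}

# rebuild a tree with the structure of `template` from a flat vector
tree_unflatten <- function(template, flat) {
  i <- 0L
  rebuild <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, rebuild)
      names(out) <- names(x)
      out
    } else {
      n <- length(x)
      v <- flat[(i + 1L):(i + n)]
      i <<- i + n
      if (is.matrix(x)) dim(v) <- dim(x)
      v
    }
  }
  out <- rebuild(template)
  stopifnot(i == length(flat))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# subset / assign rows of an opaque hidden-state container (NULL, vector,
# matrix, or list thereof); first dimension indexes episodes
h_sub <- function(h, idx) {
  if (is.null(h)) return(NULL)
  if (is.list(h)) return(lapply(h, h_sub, idx = idx))
  if (is.matrix(h)) h[idx, , drop = FALSE] else h[idx]
}

h_set <- function(h, idx, val) {
  if (is.null(h)) return(NULL)
  if (is.list(h)) {
    for (k in seq_along(h)) h[[k]] <- h_set(h[[k]], idx, val[[k]])
    return(h)
  }
  if (is.matrix(h)) h[idx, ] <- val else h[idx] <- val
  h
}

sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
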