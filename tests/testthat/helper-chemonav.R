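# Shared fixtures built in code.

# a small, fast environment: strong signal, short episodes
tiny_env <- function(d0 = c(30, 50), t_max = 20, dt = 0.2, C0 = 160,
                     rot_diffusion = 0.025) {
  list(field = field_params(C0 = C0),
       cell = cell_params(radius = 2, rot_diffusion = rot_diffusion),
       config = episode_config(d0_range = d0, delta = 10, t_max = t_max,
                               dt = dt, conc_range = c(C0, C0)))
}

tiny_spec <- function(variant, ...) {
  policy_spec(variant, n_sensors = 5, hidden_size = 6, mlp_widths = c(8, 8),
              ...)
}

random_tiny_policy <- function(variant, seed = 1, ...) {
  set.seed(seed)
  neural_policy(tiny_spec(variant, ...))
}

zeroed_policy <- function(variant) {
  p <- random_tiny_policy(variant)
  p$params <- chemonav:::tree_map(function(x) x * 0, p$params)
  p
}

# a combined-variant policy whose measurement input columns are severed,
# so only the hidden state (and fed-back action) can influence outputs
hidden_only_policy <- function(seed = 4) {
  p <- random_tiny_policy("combined", seed = seed)
  nm <- p$spec$n_meas
  for (w in c("Wr", "Wz", "Wn")) p$params$gru[[w]][seq_len(nm), ] <- 0
  p
}
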