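#' Cell geometry and motility parameters
#'
#' A circular model cell of radius `radius` carries `n_sensors` circular
#' detection areas spaced uniformly around its perimeter.  Each sensor has
#' detection radius `sensor_radius = radius * sin(pi / n_sensors)` so that
#' the sensor disks tile the cell surface.  The cell swims at constant
#' speed and steers by its angular velocity, subject to rotational
#' diffusion.
#'
#' @param radius Cell radius R (um), positive.
#' @param n_sensors Number of sensors K (integer, >= 1).
#' @param speed Swimming speed v (um/s), positive.
#' @param rot_diffusion Rotational diffusion coefficient D_R (1/s), >= 0.
#' @param sensor_radius Sensor detection radius r_s (um). Defaults to
#'   `radius * sin(pi / n_sensors)`; an explicitly supplied value must
#'   agree with that expression to within 1e-12 relative.
#' @return An object of class `"cell_params"`.
#' @export
cell_params <- function(radius = 2, n_sensors = 5, speed = 5,
                        rot_diffusion = 0.025, sensor_radius = NULL) {
  stopifnot(radius > 0, n_sensors >= 1, n_sensors == as.integer(n_sensors),
            speed > 0, rot_diffusion >= 0)
  rs <- radius * sin(pi / n_sensors)
  if (!is.null(sensor_radius)) {
    if (abs(sensor_radius - rs) > 1e-12 * rs)
      stop("sensor_radius must equal radius * sin(pi/n_sensors) = ", rs,
           call. = FALSE)
    rs <- sensor_radius
  }
  structure(list(radius = radius, n_sensors = as.integer(n_sensors),
                 sensor_radius = rs, speed = speed,
                 rot_diffusion = rot_diffusion),
            class = "cell_params")
}

#' Cell kinematic state
#'
#' @param position Length-2 numeric position x (um).
#' @param heading Orientation theta (rad); wrapped to `[0, 2*pi)`.
#' @param time Elapsed time t (s), >= 0.
#' @return An object of class `"cell_state"`.
#' @export
cell_state <- function(position = c(0, 0), heading = 0, time = 0) {
  stopifnot(length(position) == 2, is.finite(heading), time >= 0)
  structure(list(position = as.numeric(position),
                 heading = wrap_angle(heading), time = time),
            class = "cell_state")
}

#' Sensor center positions
#'
#' Sensors sit on the cell perimeter at body-frame angles `2*pi*k/K`,
#' k = 0..K-1, with sensor 0 aligned with the heading; the whole sensor
#' frame co-rotates with the body.
#'
#' @param cell A [cell_params()] object.
#' @param state A [cell_state()] object.
#' @return A K x 2 matrix of sensor center coordinates (um).
#' @export
sensor_positions <- function(cell, state) {
  k <- seq_len(cell$n_sensors) - 1L
  ang <- state$heading + 2 * pi * k / cell$n_sensors
  cbind(state$position[1] + cell$radius * cos(ang),
        state$position[2] + cell$radius * sin(ang))
}

# batched sensor-center distances to the origin.
# pos: n x 2, theta: length n  ->  n x K matrix of radial distances
sensor_dist_batch <- function(pos, theta, cell) {
  K <- cell$n_sensors
  offs <- 2 * pi * (seq_len(K) - 1L) / K
  ang <- outer(theta, offs, `+`)          # n x K
  sx <- pos[, 1] + cell$radius * cos(ang)
  sy <- pos[, 2] + cell$radius * sin(ang)
  sqrt(sx^2 + sy^2)
}

#' Expected sensor counts
#'
#' The mean particle count in each sensor's detection area, using the
#' locally flat approximation
#' \deqn{E(M_i) = \int_A C(x)\,dA \approx C(d_i)\,\pi r_s^2,}
#' where \eqn{d_i} is the distance from the center of sensor i to the
#' source at the origin.
#'
#' @inheritParams sensor_positions
#' @param field A [field_params()] object.
#' @return Numeric vector of K expected counts (all >= 0).
#' @export
expected_counts <- function(field, cell, state) {
  d <- sensor_dist_batch(matrix(state$position, 1), state$heading, cell)
  as.numeric(field$C0 * conc_shape(field, d[1, ]) * pi * cell$sensor_radius^2)
}

#' Construct an observation from raw counts
#'
#' Applies the Weber--Fechner transform `m = log(M + 1)` to integer
#' particle counts.
#'
#' @param counts Nonnegative integer vector of per-sensor counts M_i.
#' @return An object of class `"observation"` with fields `counts`,
#'   `measurements` (m_i) and `mean_measurement`.
#' @export
observation <- function(counts) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  m <- log(counts + 1)
  structure(list(counts = as.integer(counts), measurements = m,
                 mean_measurement = mean(m)),
            class = "observation")
}

#' Sample a noisy sensor observation
#'
#' Each sensor reports an independent Poisson draw with mean given by
#' [expected_counts()] (the perfect-instrument model: all particles in the
#' detection area are counted instantaneously, and successive draws are
#' independent).
#'
#' @inheritParams expected_counts
#' @return An [observation()] object.
#' @export
sample_observation <- function(field, cell, state) {
  em <- expected_counts(field, cell, state)
  observation(stats::rpois(length(em), em))
}

#' Advance the cell state by one time step
#'
#' Euler--Maruyama update of the heading equation
#' \deqn{d\theta = a_t\,dt + \sqrt{2 D_R}\,dW,}
#' followed by translation at speed v along the *new* heading.  Positive
#' actions turn the cell counterclockwise (left).
#'
#' @param state A [cell_state()].
#' @param action Angular velocity a_t (rad/s); must be finite.
#' @param cell A [cell_params()].
#' @param dt Time step (s), positive.
#' @return The updated [cell_state()].
#' @export
step_cell <- function(state, action, cell, dt) {
  stopifnot(dt > 0)
  if (!is.finite(action))
    stop("non-finite action at t = ", state$time, ": ", action, call. = FALSE)
  z <- stats::rnorm(1)
  theta <- wrap_angle(state$heading + action * dt +
                        sqrt(2 * cell$rot_diffusion * dt) * z)
  cell_state(position = state$position +
               cell$speed * dt * c(cos(theta), sin(theta)),
             heading = theta, time = state$time + dt)
}

# batched dynamics update used by the episode engine
env_step_batch <- function(pos, theta, action, cell, dt) {
  if (any(!is.finite(action)))
    stop("non-finite action in batched step", call. = FALSE)
  z <- stats::rnorm(length(theta))
  theta <- wrap_angle(theta + action * dt +
                        sqrt(2 * cell$rot_diffusion * dt) * z)
  pos[, 1] <- pos[, 1] + cell$speed * dt * cos(theta)
  pos[, 2] <- pos[, 2] + cell$speed * dt * sin(theta)
  list(pos = pos, theta = theta)
}
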