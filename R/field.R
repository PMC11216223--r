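#' Chemoattractant field parameters
#'
#' Defines a static, radially symmetric chemoattractant concentration
#' profile peaking at the origin.  The default is an exponential decay
#' \deqn{C(x) = C_0 \exp(-\lambda |x|).}
#' Particles released at the origin at rate \eqn{\rho} that diffuse with
#' coefficient \eqn{D} and decay at rate \eqn{\kappa} produce, at steady
#' state in 2D, a modified-Bessel profile proportional to
#' \eqn{K_0(\lambda r)} with decay length set by
#' \eqn{\lambda = \sqrt{\kappa/D}}; an algebraic profile is included for
#' shape comparisons.
#'
#' @param C0 Peak concentration scale (particles/um^2). Must be positive.
#' @param lambda Inverse decay length \eqn{\lambda} (1/um). If `D` and
#'   `kappa` are both supplied, `lambda` is derived as `sqrt(kappa/D)`;
#'   an explicitly supplied value must then agree to within 1e-12
#'   relative.
#' @param kind Profile shape: `"exponential"` (default), `"algebraic"`,
#'   or `"bessel"`.
#' @param D Particle diffusion coefficient (um^2/s, optional).
#' @param kappa Particle decay rate (1/s, optional).
#' @param rho Particle release rate at the origin (particles/s, optional,
#'   metadata only: the field is parameterised by `C0` directly).
#' @param r_match Radius (um) at which the Bessel profile is pinned to
#'   the exponential profile's value, so the two are comparable at the
#'   cell scale. Default 2 um.
#'
#' @return An object of class `"field_params"`.
#' @examples
#' f <- field_params(C0 = 16, D = 100, kappa = 0.1)
#' f$lambda  # sqrt(0.1/100) ~ 0.032 1/um
#' @export
field_params <- function(C0 = 16, lambda = 0.032,
                         kind = c("exponential", "algebraic", "bessel"),
                         D = NULL, kappa = NULL, rho = NULL, r_match = 2) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown profile kind: ",
                                            paste(kind, collapse = "/"),
                                            call. = FALSE))
  if (!is.null(D) && !is.null(kappa)) {
    stopifnot(D > 0, kappa > 0)
    lam <- sqrt(kappa / D)
    if (!missing(lambda) && abs(lam - lambda) > 1e-12 * abs(lam)) {
      stop("supplied lambda (", lambda, ") inconsistent with sqrt(kappa/D) = ",
           lam, call. = FALSE)
    }
    lambda <- lam
  }
  stopifnot(is.numeric(C0), length(C0) == 1, C0 > 0,
            is.numeric(lambda), length(lambda) == 1, lambda > 0,
            r_match > 0)
  structure(list(C0 = C0, lambda = lambda, kind = kind,
                 D = D, kappa = kappa, rho = rho, r_match = r_match),
            class = "field_params")
}

# dimensionless radial shape s(r) with C(r) = C0 * s(r); vectorised over r.
# The Bessel shape is normalised so C(r_match) equals the exponential
# profile's value there.
conc_shape <- function(field, r) {
  lam <- field$lambda
  switch(field$kind,
    exponential = exp(-lam * r),
    algebraic = 1 / (1 + lam * r)^2,
    bessel = {
      rr <- pmax(r, 1e-9)  # K0 diverges logarithmically at the origin
      exp(-lam * field$r_match) *
        besselK(lam * rr, nu = 0) / besselK(lam * field$r_match, nu = 0)
    },
    stop("unknown profile kind: ", field$kind, call. = FALSE)
  )
}

#' Concentration at a point
#'
#' Evaluates the chemoattractant concentration of a [field_params()]
#' profile at one or more points.
#'
#' @param field A [field_params()] object.
#' @param point A length-2 numeric vector (um), or an n x 2 matrix of
#'   points.
#' @return Concentration(s) in particles/um^2 (numeric vector).
#' @examples
#' f <- field_params(C0 = 16, lambda = 0.032)
#' concentration_at(f, c(0, 0))          # C0
#' concentration_at(f, c(1 / 0.032, 0))  # C0 / e
#' @export
concentration_at <- function(field, point) {
  stopifnot(inherits(field, "field_params"))
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 2)
    r <- sqrt(rowSums(point^2))
  } else {
    stopifnot(length(point) == 2)
    r <- sqrt(sum(point^2))
  }
  field$C0 * conc_shape(field, r)
}
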