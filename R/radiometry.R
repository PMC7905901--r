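#' Stefan-Boltzmann constant
#'
#' CODATA value of the Stefan-Boltzmann constant in W m^-2 K^-4. All radiance
#' computations in the package take \code{sigma} as an argument defaulting to
#' this value; the constant cancels exactly from emissivity estimates, so its
#' precision never affects them (see the sigma-invariance property in the
#' test suite).
#'
#' @export
SIGMA_SB <- 5.670374419e-8

#' Celsius/Kelvin conversion
#'
#' @param t_c temperature(s) in degrees Celsius; must exceed -273.15.
#' @return temperature(s) in Kelvin.
#' @examples
#' celsius_to_kelvin(25) # 298.15
#' @export
celsius_to_kelvin <- function(t_c) {
  if (!is.numeric(t_c) || anyNA(t_c) || any(!is.finite(t_c)))
    stop("temperature must be finite numeric", call. = FALSE)
  if (any(t_c <= -273.15))
    stop("temperature at or below absolute zero", call. = FALSE)
  t_c + 273.15
}

#' @rdname celsius_to_kelvin
#' @param t_k temperature(s) in Kelvin; must be positive.
#' @export
kelvin_to_celsius <- function(t_k) {
  if (!is.numeric(t_k) || anyNA(t_k) || any(!is.finite(t_k)))
    stop("temperature must be finite numeric", call. = FALSE)
  if (any(t_k <= 0))
    stop("Kelvin temperature must be positive", call. = FALSE)
  t_k - 273.15
}

#' Radiometric scene conditions
#'
#' Bundles the environmental quantities entering the radiometric forward
#' model: the reflected temperature of the surroundings, the air temperature
#' of the environment, the air-path transmissivity, and the Stefan-Boltzmann
#' constant. Distance and relative humidity are carried as metadata only; no
#' humidity/distance-to-transmissivity model is implemented (the camera
#' manufacturers' transmission function is proprietary), so \code{rho} is a
#' direct input, assumed 0.99 by default -- consistent with near-perfect
#' transmission over the short (~0.5 m) working distances of both protocols.
#'
#' @param t_ref reflected temperature, K (surroundings radiation reflected off
#'   the target; measured with a crumpled-foil multidirectional mirror, or
#'   taken equal to \code{t_env} when no mirror reading exists).
#' @param t_env environment air temperature, K. Default 298.15 K (25 C, the
#'   assumed lab temperature in both protocols).
#' @param rho air-path transmissivity in (0, 1]. Default 0.99.
#' @param sigma Stefan-Boltzmann constant, W m^-2 K^-4.
#' @param distance_m camera-target distance in metres (metadata only).
#' @param rel_humidity relative humidity as a fraction (metadata only).
#' @param protocol optional provenance tag ("thermocouple" or "water_bath");
#'   used to assert that protocol defaults are never mixed downstream.
#' @return an object of class \code{"scene_conditions"} (a list).
#' @examples
#' sc <- scene_conditions(t_ref = 295)
#' sc$rho
#' @export
scene_conditions <- function(t_ref = 298.15, t_env = 298.15, rho = 0.99,
                             sigma = SIGMA_SB, distance_m = 0.5,
                             rel_humidity = 0.5, protocol = NULL) {
  stopifnot(is.numeric(t_ref), is.numeric(t_env), is.numeric(rho),
            is.numeric(sigma), length(rho) == 1L, length(sigma) == 1L)
  if (any(!is.finite(t_ref)) || any(!is.finite(t_env)))
    stop("scene temperatures must be finite", call. = FALSE)
  if (any(t_ref < 250) || any(t_ref > 400))
    stop("t_ref outside plausible range [250, 400] K", call. = FALSE)
  if (any(t_env < 250) || any(t_env > 400))
    stop("t_env outside plausible range [250, 400] K", call. = FALSE)
  if (rho <= 0 || rho > 1)
    stop("rho must lie in (0, 1]", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  structure(list(t_ref = t_ref, t_env = t_env, rho = rho, sigma = sigma,
                 distance_m = distance_m, rel_humidity = rel_humidity,
                 protocol = protocol),
            class = "scene_conditions")
}

#' @export
print.scene_conditions <- function(x, ...) {
  cat("Radiometric scene conditions\n")
  cat(sprintf("  t_ref: %s K\n", paste(format(unique(round(x$t_ref, 2))),
                                       collapse = ", ")))
  cat(sprintf("  t_env: %.2f K   rho: %.3f   sigma: %.6g W m-2 K-4\n",
              x$t_env[1L], x$rho, x$sigma))
  cat(sprintf("  distance: %.2f m   RH: %.0f%%%s\n", x$distance_m,
              100 * x$rel_humidity,
              if (!is.null(x$protocol)) paste0("   protocol: ", x$protocol)
              else ""))
  invisible(x)
}

.check_temp <- function(t, what) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop(what, " must be finite numeric", call. = FALSE)
  if (any(t < 250) || any(t > 400))
    stop(what, " outside plausible range [250, 400] K", call. = FALSE)
  invisible(t)
}

#' Radiometric forward model: total radiance reaching the camera
#'
#' Total thermal-infrared radiance entering the camera from a grey-body
#' target of temperature \code{t_obj} and emissivity \code{epsilon}:
#' the emitted term \eqn{\epsilon \sigma \rho T_{obj}^4}, the reflected term
#' \eqn{(1-\epsilon) \sigma \rho T_{ref}^4}, and the atmospheric term
#' \eqn{\sigma (1-\rho) T_{env}^4}. The target is assumed non-transmissive
#' (true of biological tissue). \code{epsilon} is deliberately not restricted
#' to [0, 1]: estimation workflows downstream may produce and propagate
#' values outside the theoretical limits.
#'
#' @param t_obj object temperature, K (in [250, 400]).
#' @param epsilon emissivity (any finite value).
#' @param scene a \code{\link{scene_conditions}} object.
#' @return radiance, W m^-2 (vectorised over inputs).
#' @export
total_radiance <- function(t_obj, epsilon, scene) {
  stopifnot(inherits(scene, "scene_conditions"))
  .check_temp(t_obj, "t_obj")
  if (!is.numeric(epsilon) || anyNA(epsilon) || any(!is.finite(epsilon)))
    stop("epsilon must be finite numeric", call. = FALSE)
  s <- scene$sigma; rho <- scene$rho
  epsilon * s * rho * t_obj^4 +
    (1 - epsilon) * s * rho * scene$t_ref^4 +
    s * (1 - rho) * scene$t_env^4
}

#' Apparent-temperature radiance
#'
#' Radiance implied by the camera's apparent temperature reading, i.e. the
#' reading obtained with emissivity set to 1 and distance set to 0 so that
#' no emissivity, reflection or atmosphere corrections are applied:
#' \eqn{W = \sigma T_{app}^4}.
#'
#' @param t_app apparent temperature, K (in [250, 400]).
#' @param sigma Stefan-Boltzmann constant.
#' @return radiance, W m^-2.
#' @export
apparent_radiance <- function(t_app, sigma = SIGMA_SB) {
  .check_temp(t_app, "t_app")
  sigma * t_app^4
}

#' @rdname apparent_radiance
#' @param w radiance, W m^-2; must be positive.
#' @return \code{radiance_to_apparent}: apparent temperature, K.
#' @export
radiance_to_apparent <- function(w, sigma = SIGMA_SB) {
  if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)))
    stop("radiance must be finite numeric", call. = FALSE)
  if (any(w <= 0)) stop("degenerate radiance: w must be > 0", call. = FALSE)
  (w / sigma)^0.25
}

#' Closed-form emissivity estimate
#'
#' Rearranges the radiometric forward model for emissivity given the observed
#' radiance and the known object temperature:
#' \deqn{\epsilon = \frac{W - \sigma\rho T_{ref}^4 - \sigma(1-\rho)T_{env}^4}
#'                       {\sigma\rho T_{obj}^4 - \sigma\rho T_{ref}^4}.}
#' The result is \emph{not} clipped to [0, 1]; with a near-1 true emissivity
#' and sensor noise, estimates slightly above 1 are expected and clipping
#' them would conceal protocol error (an optional \code{clamp} exists for
#' users who want camera-admissible values).
#'
#' The denominator vanishes as \eqn{T_{ref} \to T_{obj}} and turns negative
#' when the surroundings are warmer than the target; such records produced
#' wild outliers in real data. Records whose signed denominator falls at or
#' below \code{floor_frac * sigma * rho * t_obj^4} (i.e. including all
#' records with \eqn{T_{ref} \ge T_{obj}}) are flagged degenerate and return
#' \code{NA} rather than a number.
#'
#' @param w_obs observed radiance, W m^-2 (typically
#'   \code{apparent_radiance(t_app)}).
#' @param t_obj known object temperature, K.
#' @param scene a \code{\link{scene_conditions}} object.
#' @param floor_frac degeneracy floor as a fraction of \eqn{\sigma\rho T_{obj}^4}.
#' @param clamp if \code{TRUE}, clip results into [0, 1] (default off).
#' @return numeric vector of emissivity estimates, \code{NA} where degenerate,
#'   with a logical attribute \code{"degenerate"}.
#' @export
emissivity_calc <- function(w_obs, t_obj, scene, floor_frac = 1e-6,
                            clamp = FALSE) {
  stopifnot(inherits(scene, "scene_conditions"))
  .check_temp(t_obj, "t_obj")
  if (!is.numeric(w_obs) || anyNA(w_obs) || any(!is.finite(w_obs)))
    stop("w_obs must be finite numeric", call. = FALSE)
  .emissivity_from_x(w_obs / scene$sigma, t_obj, scene,
                     floor_frac = floor_frac, clamp = clamp)
}

# Core of the closed form, in blackbody-equivalent T^4 space
# (x_obs = W/sigma). sigma cancels algebraically from the estimate, and
# factoring it out here makes the cancellation exact: estimates computed
# from apparent temperatures are bit-identical for any sigma.
.emissivity_from_x <- function(x_obs, t_obj, scene, floor_frac = 1e-6,
                               clamp = FALSE) {
  rho <- scene$rho
  num <- x_obs - rho * scene$t_ref^4 - (1 - rho) * scene$t_env^4
  den <- rho * (t_obj^4 - scene$t_ref^4)
  degen <- den <= floor_frac * rho * t_obj^4
  eps <- ifelse(degen, NA_real_, num / den)
  if (clamp) eps <- pmin(pmax(eps, 0), 1)
  attr(eps, "degenerate") <- degen
  eps
}

#' Object temperature retrieved at an assumed emissivity
#'
#' Inverts the radiometric forward model for object temperature given an
#' assumed emissivity -- the computation a thermal camera performs when the
#' user inputs an emissivity value. With \code{epsilon = 0.98} this is the
#' "T0.98" retrieval convention of floral thermography.
#'
#' @param w_obs observed radiance, W m^-2.
#' @param epsilon assumed emissivity, > 0.
#' @param scene a \code{\link{scene_conditions}} object.
#' @return temperature, K; \code{NA} (flagged via attribute
#'   \code{"degenerate"}) where the bracketed quantity is non-positive.
#' @export
object_temp_at_emissivity <- function(w_obs, epsilon, scene) {
  stopifnot(inherits(scene, "scene_conditions"))
  if (!is.numeric(w_obs) || anyNA(w_obs) || any(!is.finite(w_obs)))
    stop("w_obs must be finite numeric", call. = FALSE)
  if (any(epsilon <= 0)) stop("epsilon must be > 0", call. = FALSE)
  s <- scene$sigma; rho <- scene$rho
  q <- (w_obs - (1 - epsilon) * s * rho * scene$t_ref^4 -
          s * (1 - rho) * scene$t_env^4) / (epsilon * s * rho)
  degen <- q <= 0
  tk <- rep(NA_real_, length(q))
  tk[!degen] <- q[!degen]^0.25
  attr(tk, "degenerate") <- degen
  tk
}
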