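#' Measurement locations
#'
#' The three per-flower sampling points: on or about the carpel or disc
#' florets ("reproductive_structures"), towards the base of the adaxial petal
#' surface ("petal_base"), and towards the petal periphery ("petal_edge").
#' @export
LOCATIONS <- c("reproductive_structures", "petal_base", "petal_edge")

# Maps the deposited-file location codes ("A: repro struc", "B: petal base",
# "C: petal edge", case/space variants) onto the internal labels.
normalize_location <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x0))
  out[grepl("repro", x0)] <- "reproductive_structures"
  out[grepl("base", x0)] <- "petal_base"
  out[grepl("edge", x0)] <- "petal_edge"
  out[x0 %in% LOCATIONS] <- x0[x0 %in% LOCATIONS]
  out
}

.require_cols <- function(records, cols) {
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
}

.range_flag <- function(t) {
  !is.na(t) & (t < 250 | t > 400)
}

#' Build measurement points from a thermocouple-protocol table
#'
#' Converts raw thermocouple records into measurement points under the
#' protocol's parameter conventions: the object temperature is the
#' thermocouple reading (Celsius converted to Kelvin if only the Celsius
#' column is present); the reflected temperature comes from the record's
#' multidirectional-mirror measurement, falling back to the assumed
#' environment temperature when absent; environment temperature and
#' transmissivity default to 298.15 K (25 C) and 0.99.
#'
#' @param records a data frame with (normalised) columns \code{species},
#'   \code{measurement_location}, \code{tapp_k}, and \code{tobj_k} and/or
#'   \code{thermocouple_c}; optional \code{tref_k}, \code{individual},
#'   \code{measurement}.
#' @param defaults a \code{\link{scene_conditions}} object holding
#'   \code{t_env}, \code{rho} and \code{sigma} defaults.
#' @return a data frame of measurement points (one per record) with columns
#'   \code{species}, \code{individual}, \code{location}, \code{protocol},
#'   \code{bath_set_temp} (\code{NA}), \code{t_obj}, \code{t_app},
#'   \code{t_ref}, \code{flag}; scene defaults attached as attribute
#'   \code{"scene"}.
#' @export
build_thermocouple_points <- function(records,
                                      defaults = scene_conditions(
                                        protocol = "thermocouple")) {
  stopifnot(is.data.frame(records), inherits(defaults, "scene_conditions"))
  .require_cols(records, c("species", "measurement_location", "tapp_k"))
  if (!("tobj_k" %in% names(records)) &&
      !("thermocouple_c" %in% names(records)))
    stop("missing required column(s): tobj_k (or thermocouple_c)",
         call. = FALSE)
  n <- nrow(records)
  t_obj <- if ("tobj_k" %in% names(records)) as.numeric(records$tobj_k)
           else rep(NA_real_, n)
  if ("thermocouple_c" %in% names(records)) {
    tc <- as.numeric(records$thermocouple_c)
    fill <- is.na(t_obj) & !is.na(tc)
    t_obj[fill] <- tc[fill] + 273.15
  }
  t_ref <- if ("tref_k" %in% names(records)) as.numeric(records$tref_k)
           else rep(NA_real_, n)
  t_ref[is.na(t_ref)] <- defaults$t_env
  loc <- normalize_location(records$measurement_location)
  t_app <- as.numeric(records$tapp_k)
  flag <- rep("", n)
  flag[is.na(loc)] <- "unknown_location"
  bad <- .range_flag(t_obj) | .range_flag(t_app) | .range_flag(t_ref) |
    is.na(t_obj) | is.na(t_app)
  flag[bad & flag == ""] <- "temperature_out_of_range"
  pts <- data.frame(
    measurement = if ("measurement" %in% names(records))
      as.character(records$measurement) else as.character(seq_len(n)),
    species = as.character(records$species),
    individual = if ("individual" %in% names(records))
      as.character(records$individual) else as.character(seq_len(n)),
    location = loc,
    protocol = rep("thermocouple", n),
    bath_set_temp = rep(NA_real_, n),
    t_obj = t_obj, t_app = t_app, t_ref = t_ref,
    flag = flag,
    stringsAsFactors = FALSE)
  attr(pts, "scene") <- defaults
  pts
}

#' Build measurement points from a water-bath-protocol table
#'
#' Converts raw water-bath records into measurement points. The object
#' temperature of every flower point is the temperature of the water
#' proximal to the flower, retrieved from the camera's water-point reading
#' with the accepted emissivity of water (0.98), distance 0.5 m, relative
#' humidity 50% and environment temperature 298.15 K. When the table carries
#' both a raw water-point apparent temperature and a pre-retrieved water
#' temperature, the retrieval is recomputed from the apparent reading and
#' cross-checked against the deposited column (0.1 K tolerance; mismatches
#' are flagged, not silently accepted). The set bath temperature is carried
#' both as a categorical label (35C / 45C) and in Kelvin.
#'
#' @param records a data frame with columns \code{species},
#'   \code{measurement_location}, \code{bath_set} (labels "35C"/"45C" or the
#'   numbers 35/45), \code{tapp_k}, \code{tref_k}, and
#'   \code{water_tapp_k} and/or \code{water_t098_k}; optional
#'   \code{thermometer_c}, \code{individual}, \code{measurement}.
#' @param defaults scene defaults, as in
#'   \code{\link{build_thermocouple_points}}.
#' @param water_epsilon emissivity used for the water retrieval.
#' @param crosscheck_tol tolerance (K) for the recomputed-vs-deposited water
#'   temperature cross-check.
#' @return a measurement-point data frame; columns as in
#'   \code{\link{build_thermocouple_points}} with \code{bath_set_temp} in K
#'   and an extra \code{bath_set} label column.
#' @export
build_waterbath_points <- function(records,
                                   defaults = scene_conditions(
                                     protocol = "water_bath"),
                                   water_epsilon = 0.98,
                                   crosscheck_tol = 0.1) {
  stopifnot(is.data.frame(records), inherits(defaults, "scene_conditions"))
  .require_cols(records, c("species", "measurement_location", "bath_set",
                           "tapp_k", "tref_k"))
  has_app <- "water_tapp_k" %in% names(records)
  has_ret <- "water_t098_k" %in% names(records)
  if (!has_app && !has_ret)
    stop("missing required column(s): water_tapp_k (or water_t098_k)",
         call. = FALSE)
  n <- nrow(records)
  set_c <- suppressWarnings(as.numeric(gsub("[^0-9.]", "",
                                            as.character(records$bath_set))))
  if (anyNA(set_c) || !all(set_c %in% c(35, 45)))
    stop("bath_set labels must be 35C or 45C", call. = FALSE)
  t_ref <- as.numeric(records$tref_k)
  flag <- rep("", n)
  # retrieve water temperature (the protocol's T_obj) per record
  if (has_app) {
    t_obj <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      sc_i <- scene_conditions(t_ref = t_ref[i], t_env = defaults$t_env,
                               rho = defaults$rho, sigma = defaults$sigma,
                               protocol = "water_bath")
      t_obj[i] <- tryCatch(
        as.numeric(object_temp_at_emissivity(
          apparent_radiance(as.numeric(records$water_tapp_k[i]),
                            defaults$sigma),
          water_epsilon, sc_i)),
        error = function(e) NA_real_)
    }
    if (has_ret) {
      dep <- as.numeric(records$water_t098_k)
      off <- !is.na(dep) & !is.na(t_obj) & abs(dep - t_obj) > crosscheck_tol
      flag[off] <- "water_temp_crosscheck"
    }
  } else {
    t_obj <- as.numeric(records$water_t098_k)
  }
  if ("thermometer_c" %in% names(records)) {
    th <- as.numeric(records$thermometer_c)
    dev <- !is.na(th) & abs(th - set_c) > 1
    flag[dev & flag == ""] <- "bath_temp_deviation"
  }
  loc <- normalize_location(records$measurement_location)
  t_app <- as.numeric(records$tapp_k)
  flag[is.na(loc) & flag == ""] <- "unknown_location"
  bad <- .range_flag(t_obj) | .range_flag(t_app) | .range_flag(t_ref) |
    is.na(t_obj) | is.na(t_app)
  flag[bad] <- "temperature_out_of_range"
  pts <- data.frame(
    measurement = if ("measurement" %in% names(records))
      as.character(records$measurement) else as.character(seq_len(n)),
    species = as.character(records$species),
    individual = if ("individual" %in% names(records))
      as.character(records$individual) else as.character(seq_len(n)),
    location = loc,
    protocol = rep("water_bath", n),
    bath_set = paste0(set_c, "C"),
    bath_set_temp = set_c + 273.15,
    t_obj = t_obj, t_app = t_app, t_ref = t_ref,
    flag = flag,
    stringsAsFactors = FALSE)
  attr(pts, "scene") <- defaults
  pts
}

#' Fixed-emissivity temperature retrieval deltas
#'
#' For every measurement point, retrieves the temperature the camera would
#' report at an assumed emissivity (default 0.98, the floral-thermography
#' convention: "T0.98") and differences it against the known object
#' temperature. A positive delta means the camera underestimates the true
#' temperature at that emissivity setting; for a true emissivity above the
#' assumed value and a target warmer than its surroundings the delta is
#' negative (the camera overestimates). Deltas are reported in Kelvin,
#' identical to Celsius differences.
#'
#' @param points a measurement-point data frame (see the builders).
#' @param epsilon_used assumed emissivity. Default 0.98.
#' @param scene scene defaults; taken from the points attribute by default.
#' @return a data frame with the point identity columns plus \code{t_098}
#'   and \code{delta} (= \code{t_obj - t_098}); degenerate retrievals are
#'   \code{NA} and flagged.
#' @export
compute_t098_deltas <- function(points, epsilon_used = 0.98,
                                scene = attr(points, "scene")) {
  stopifnot(is.data.frame(points))
  if (is.null(scene)) scene <- scene_conditions()
  n <- nrow(points)
  t098 <- rep(NA_real_, n)
  flag <- if ("flag" %in% names(points)) points$flag else rep("", n)
  for (i in seq_len(n)) {
    if (nzchar(flag[i]) && flag[i] != "water_temp_crosscheck" &&
        flag[i] != "bath_temp_deviation") next
    sc_i <- scene_conditions(t_ref = points$t_ref[i], t_env = scene$t_env,
                             rho = scene$rho, sigma = scene$sigma,
                             protocol = scene$protocol)
    t098[i] <- tryCatch(
      as.numeric(object_temp_at_emissivity(
        apparent_radiance(points$t_app[i], scene$sigma), epsilon_used, sc_i)),
      error = function(e) NA_real_)
  }
  out <- points
  out$flag <- flag
  out$t_098 <- t098
  out$delta <- points$t_obj - t098
  out$flag[is.na(t098) & !nzchar(out$flag)] <- "degenerate_retrieval"
  attr(out, "scene") <- scene
  out
}
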