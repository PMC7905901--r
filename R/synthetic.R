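#' Default sensor noise magnitudes
#'
#' Manufacturer accuracy specs quote error bounds, not standard deviations;
#' the package interprets a quoted +/- bound as a 95% interval of a Gaussian,
#' so the default SD is bound/1.96. The thermal camera is quoted at +/- 2 C;
#' the K-type thermocouple at +/- 2.2 C or +/- 0.75% of the reading
#' (in Celsius), whichever is greater.
#'
#' @return standard deviation in K.
#' @export
default_camera_noise_sd <- function() 2 / 1.96

#' @rdname default_camera_noise_sd
#' @param t_k the true reading, K (the percentage term applies to the
#'   Celsius reading).
#' @export
default_thermocouple_noise_sd <- function(t_k) {
  pmax(2.2, 0.0075 * (t_k - 273.15)) / 1.96
}

#' Gaussian measurement perturbation
#'
#' Adds zero-mean Gaussian noise of the given standard deviation to a true
#' value, using the current RNG state. \code{sd = 0} is the identity.
#'
#' @param true_value true value(s), K.
#' @param sd standard deviation, K; must be >= 0.
#' @return perturbed value(s).
#' @export
apply_measurement_noise <- function(true_value, sd) {
  if (any(sd < 0)) stop("noise sd must be non-negative", call. = FALSE)
  true_value + stats::rnorm(length(true_value), 0, sd)
}

# Deterministic 31-bit stream seed from a key; gives every
# (species, individual, location) its own substream so that subsetting a
# config leaves all other rows untouched.
.stream_seed <- function(...) {
  key <- paste(unlist(list(...)), collapse = "|")
  v <- utf8ToInt(key)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483629
  as.integer(h)
}

.location_codes <- c(reproductive_structures = "A: repro struc",
                     petal_base = "B: petal base",
                     petal_edge = "C: petal edge")

#' Default species rosters
#'
#' Species and replication mirroring the study design the generator
#' emulates: ten species with 19-21 individuals for the thermocouple
#' protocol, six species with 12 individuals for the water bath. True
#' emissivity defaults to 0.98 at every location (near-1 floral tissue);
#' profiles are fully config-driven.
#'
#' @param protocol "thermocouple" or "water_bath".
#' @param epsilon default true emissivity for every location.
#' @return a named list (one element per species) of per-location emissivity
#'   vectors, each carrying an \code{"n_individuals"} attribute.
#' @export
default_species_profiles <- function(protocol = c("thermocouple",
                                                  "water_bath"),
                                     epsilon = 0.98) {
  protocol <- match.arg(protocol)
  roster <- switch(protocol,
    thermocouple = c("Bellis perennis" = 19, "Campanula sp." = 21,
                     "Cistus Snow Fire" = 21, "Coreopsis verticillata" = 20,
                     "Geranium pratense" = 20, "Geranium psilostemon" = 20,
                     "Helianthemum sp." = 20, "Leucanthemum vulgare" = 20,
                     "Papaver cambricum" = 20, "Taraxacum agg." = 20),
    water_bath = c("Bellis perennis" = 12, "Campanula sp." = 12,
                   "Eschscholzia californica" = 12,
                   "Leucanthemum vulgare" = 12, "Potentilla fruticosa" = 12,
                   "Taraxacum agg." = 12))
  out <- lapply(names(roster), function(sp) {
    structure(stats::setNames(rep(epsilon, 3L), LOCATIONS),
              n_individuals = unname(roster[sp]))
  })
  stats::setNames(out, names(roster))
}

#' Synthetic measurement-generator configuration
#'
#' Collects everything the generator needs: per-species, per-location true
#' emissivities; the protocol's object-temperature model; sensor noise SDs;
#' the protocol bias artefacts; replication; and the seed.
#'
#' Object-temperature models (fixed by the protocols being emulated):
#' thermocouple flowers are heated above room temperature, with true
#' temperatures uniform over 296.9-309.2 K and reflected temperatures
#' coupled to the flower (flower minus 5-13 K, clipped to the observed
#' 287.0-300.5 K envelope); water-bath flowers sit at the set bath
#' temperature (308.15 or 318.15 K), with reflected temperatures uniform
#' over the observed 299.5-301.6 K.
#'
#' Bias artefacts (all default 0; switch on to emulate the protocols'
#' systematic errors): \code{contact_bias} is subtracted from the recorded
#' thermocouple temperature on petal locations (poor contact on pliant
#' petals under-reads the surface, inflating emissivity estimates);
#' \code{elevation_bias} is subtracted from the true temperature of
#' structures held above the waterline (they never reach bath temperature,
#' deflating estimates); \code{submersion_bias} is added for structures
#' below the waterline (the submerged-exemplar pattern).
#'
#' @param species_profiles named list: species -> named numeric vector of
#'   true emissivity per location (names in \code{LOCATIONS}); a scalar is
#'   recycled to all three locations. Default: the protocol-agnostic
#'   thermocouple roster at 0.98.
#' @param n_individuals individuals per species; \code{NULL} uses the
#'   profile's own \code{n_individuals} attribute (or 12).
#' @param camera_noise_sd camera noise SD, K.
#' @param thermocouple_noise_sd thermocouple noise SD, K; \code{NULL} uses
#'   the reading-dependent manufacturer rule
#'   (\code{\link{default_thermocouple_noise_sd}}).
#' @param contact_bias,elevation_bias,submersion_bias bias magnitudes, K.
#' @param bath_set_temps_c set bath temperatures, Celsius.
#' @param submerged_species species whose reproductive structures sit below
#'   the waterline (all others are above it).
#' @param tobj_range_k thermocouple true-temperature range, K.
#' @param tref_offset_range_k thermocouple flower-minus-reflected offset
#'   range, K.
#' @param tref_range_k thermocouple reflected-temperature envelope, K.
#' @param tref_range_waterbath_k water-bath reflected-temperature range, K.
#' @param t_env,rho,sigma scene defaults.
#' @param thermometer_noise_sd SD of the bath-verification thermometer, K.
#' @param round_digits decimals to round emitted temperatures to
#'   (\code{NULL} = no rounding; 1 mimics thermal-software exports).
#' @param seed integer seed driving all per-row substreams.
#' @return an object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(species_profiles = NULL,
                             n_individuals = NULL,
                             camera_noise_sd = default_camera_noise_sd(),
                             thermocouple_noise_sd = NULL,
                             contact_bias = 0,
                             elevation_bias = 0,
                             submersion_bias = 0,
                             bath_set_temps_c = c(35, 45),
                             submerged_species = "Campanula sp.",
                             tobj_range_k = c(296.9, 309.2),
                             tref_offset_range_k = c(5, 13),
                             tref_range_k = c(287.0, 300.5),
                             tref_range_waterbath_k = c(299.5, 301.6),
                             t_env = 298.15, rho = 0.99, sigma = SIGMA_SB,
                             thermometer_noise_sd = 0.2,
                             round_digits = NULL,
                             seed = 1L) {
  if (is.null(species_profiles))
    species_profiles <- default_species_profiles("thermocouple")
  stopifnot(is.list(species_profiles), length(species_profiles) > 0)
  species_profiles <- lapply(species_profiles, function(p) {
    if (length(p) == 1L && is.null(names(p)))
      p <- stats::setNames(rep(as.numeric(p), 3L), LOCATIONS)
    if (!all(LOCATIONS %in% names(p)))
      stop("species profile must name all locations", call. = FALSE)
    if (any(!is.finite(unlist(p[LOCATIONS]))))
      stop("emissivities must be finite", call. = FALSE)
    p
  })
  if (camera_noise_sd < 0 || (!is.null(thermocouple_noise_sd) &&
                              thermocouple_noise_sd < 0))
    stop("noise sd must be non-negative", call. = FALSE)
  stopifnot(all(bath_set_temps_c %in% c(35, 45)))
  structure(list(species_profiles = species_profiles,
                 n_individuals = n_individuals,
                 camera_noise_sd = camera_noise_sd,
                 thermocouple_noise_sd = thermocouple_noise_sd,
                 contact_bias = contact_bias,
                 elevation_bias = elevation_bias,
                 submersion_bias = submersion_bias,
                 bath_set_temps_c = bath_set_temps_c,
                 submerged_species = submerged_species,
                 tobj_range_k = tobj_range_k,
                 tref_offset_range_k = tref_offset_range_k,
                 tref_range_k = tref_range_k,
                 tref_range_waterbath_k = tref_range_waterbath_k,
                 t_env = t_env, rho = rho, sigma = sigma,
                 thermometer_noise_sd = thermometer_noise_sd,
                 round_digits = round_digits,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.cfg_n <- function(config, profile) {
  if (!is.null(config$n_individuals)) return(config$n_individuals)
  n <- attr(profile, "n_individuals")
  if (is.null(n)) 12L else n
}

.maybe_round <- function(x, digits) {
  if (is.null(digits)) x else round(x, digits)
}

#' Generate a synthetic protocol measurement table
#'
#' Emits a raw measurement table in the same long dialect the protocol
#' pipelines read: one row per individual x location (water bath: x set
#' temperature as well). Apparent temperatures are computed through the
#' radiometric forward model at the configured true emissivity and then
#' perturbed by camera noise; recorded object temperatures carry the
#' protocol's own noise and bias artefacts. A shared seed drives an
#' independent substream per (species, individual, location), so removing a
#' species from the config changes no other row, and identical seed + config
#' give byte-identical tables.
#'
#' @param protocol "thermocouple" or "water_bath".
#' @param config a \code{\link{synthetic_config}}.
#' @return a raw-table data frame with a \code{"truth"} attribute (data
#'   frame of the generating emissivities and true temperatures, for
#'   parameter-recovery checks).
#' @export
generate_dataset <- function(protocol = c("thermocouple", "water_bath"),
                             config = synthetic_config()) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (protocol == "thermocouple") .gen_thermocouple(config)
  else .gen_waterbath(config)
}

.gen_thermocouple <- function(cfg) {
  rows <- list(); truths <- list(); k <- 0L
  for (sp in names(cfg$species_profiles)) {
    prof <- cfg$species_profiles[[sp]]
    for (ind in seq_len(.cfg_n(cfg, prof))) {
      for (loc in LOCATIONS) {
        k <- k + 1L
        set.seed(.stream_seed(cfg$seed, "thermocouple", sp, ind, loc))
        tobj_true <- stats::runif(1, cfg$tobj_range_k[1], cfg$tobj_range_k[2])
        off <- stats::runif(1, cfg$tref_offset_range_k[1],
                            cfg$tref_offset_range_k[2])
        tref <- min(max(tobj_true - off, cfg$tref_range_k[1]),
                    cfg$tref_range_k[2])
        eps <- unname(prof[[loc]])
        sc <- scene_conditions(t_ref = tref, t_env = cfg$t_env,
                               rho = cfg$rho, sigma = cfg$sigma,
                               protocol = "thermocouple")
        tapp_true <- radiance_to_apparent(total_radiance(tobj_true, eps, sc),
                                          cfg$sigma)
        tapp <- apply_measurement_noise(tapp_true, cfg$camera_noise_sd)
        tc_sd <- if (is.null(cfg$thermocouple_noise_sd))
          default_thermocouple_noise_sd(tobj_true) else
            cfg$thermocouple_noise_sd
        bias <- if (loc %in% c("petal_base", "petal_edge"))
          cfg$contact_bias else 0
        tobj_rec <- apply_measurement_noise(tobj_true - bias, tc_sd)
        rows[[k]] <- data.frame(
          measurement = sprintf("%s_%02d_%s", gsub(" ", "_", sp), ind,
                                substr(.location_codes[[loc]], 1, 1)),
          individual_within_species = ind,
          individual = k,
          species = sp,
          measurement_location = .location_codes[[loc]],
          thermocouple_c = .maybe_round(tobj_rec - 273.15, cfg$round_digits),
          tobj_k = .maybe_round(tobj_rec, cfg$round_digits),
          tref_k = .maybe_round(tref, cfg$round_digits),
          tapp_k = .maybe_round(tapp, cfg$round_digits),
          stringsAsFactors = FALSE)
        truths[[k]] <- data.frame(species = sp, individual = ind,
                                  location = loc, epsilon_true = eps,
                                  t_obj_true = tobj_true,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) {
    out <- data.frame(measurement = character(0),
                      individual_within_species = integer(0),
                      individual = integer(0), species = character(0),
                      measurement_location = character(0),
                      thermocouple_c = numeric(0), tobj_k = numeric(0),
                      tref_k = numeric(0), tapp_k = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- NULL
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truths)
  out
}

.gen_waterbath <- function(cfg) {
  rows <- list(); truths <- list(); k <- 0L; flower_id <- 0L
  for (sp in names(cfg$species_profiles)) {
    prof <- cfg$species_profiles[[sp]]
    for (ind in seq_len(.cfg_n(cfg, prof))) {
      flower_id <- flower_id + 1L
      for (set_c in cfg$bath_set_temps_c) {
        # scene-level stream: shared by the three location rows of a flower
        set.seed(.stream_seed(cfg$seed, "water_bath", sp, ind, set_c,
                              "scene"))
        tref <- stats::runif(1, cfg$tref_range_waterbath_k[1],
                             cfg$tref_range_waterbath_k[2])
        water_true <- set_c + 273.15
        sc <- scene_conditions(t_ref = tref, t_env = cfg$t_env,
                               rho = cfg$rho, sigma = cfg$sigma,
                               protocol = "water_bath")
        w_water <- total_radiance(water_true, 0.98, sc)
        water_tapp <- apply_measurement_noise(
          radiance_to_apparent(w_water, cfg$sigma), cfg$camera_noise_sd)
        water_t098 <- as.numeric(object_temp_at_emissivity(
          apparent_radiance(water_tapp, cfg$sigma), 0.98, sc))
        thermometer_c <- apply_measurement_noise(set_c,
                                                 cfg$thermometer_noise_sd)
        for (loc in LOCATIONS) {
          k <- k + 1L
          set.seed(.stream_seed(cfg$seed, "water_bath", sp, ind, set_c, loc))
          eps <- unname(prof[[loc]])
          submerged <- sp %in% cfg$submerged_species
          struct_true <- water_true
          if (loc == "reproductive_structures") {
            struct_true <- if (submerged)
              water_true + cfg$submersion_bias
            else water_true - cfg$elevation_bias
          }
          tapp_true <- radiance_to_apparent(
            total_radiance(struct_true, eps, sc), cfg$sigma)
          tapp <- apply_measurement_noise(tapp_true, cfg$camera_noise_sd)
          rows[[k]] <- data.frame(
            measurement = sprintf("%s_%02d_%dC_%s", gsub(" ", "_", sp), ind,
                                  set_c,
                                  substr(.location_codes[[loc]], 1, 1)),
            individual_within_species = ind,
            individual = flower_id,
            species = sp,
            measurement_location = .location_codes[[loc]],
            bath_set = paste0(set_c, "C"),
            thermometer_c = .maybe_round(thermometer_c, cfg$round_digits),
            tref_k = .maybe_round(tref, cfg$round_digits),
            water_tapp_k = .maybe_round(water_tapp, cfg$round_digits),
            water_t098_k = .maybe_round(water_t098, cfg$round_digits),
            tapp_k = .maybe_round(tapp, cfg$round_digits),
            stringsAsFactors = FALSE)
          truths[[k]] <- data.frame(species = sp, individual = ind,
                                    bath_set = paste0(set_c, "C"),
                                    location = loc, epsilon_true = eps,
                                    t_obj_true = struct_true,
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!k) {
    out <- data.frame(measurement = character(0),
                      individual_within_species = integer(0),
                      individual = integer(0), species = character(0),
                      measurement_location = character(0),
                      bath_set = character(0), thermometer_c = numeric(0),
                      tref_k = numeric(0), water_tapp_k = numeric(0),
                      water_t098_k = numeric(0), tapp_k = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- NULL
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truths)
  out
}

#' Read a synthetic-generator configuration from a YAML file
#'
#' The file may set any argument of \code{\link{synthetic_config}};
#' \code{species_profiles} is a mapping from species name to either a single
#' emissivity or a per-location mapping.
#'
#' @param path path to a YAML file.
#' @return a \code{\link{synthetic_config}}.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$species_profiles)) {
    raw$species_profiles <- lapply(raw$species_profiles, function(p) {
      if (is.list(p)) unlist(p) else p
    })
  }
  do.call(synthetic_config, raw)
}
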