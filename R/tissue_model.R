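#' Optical properties of a turbid medium
#'
#' Bundle of the four wavelength-dependent quantities that govern light
#' transport in a turbid medium: absorption coefficient `mu_a` (mm^-1),
#' scattering coefficient `mu_s` (mm^-1), scattering anisotropy `g`
#' (mean cosine of the single-scattering deflection), and refractive
#' index `n`. All arguments may be vectors of equal length (one entry per
#' wavelength); scalars are recycled.
#'
#' @param mu_a Absorption coefficient, mm^-1 (>= 0).
#' @param mu_s Scattering coefficient, mm^-1 (>= 0).
#' @param g Scattering anisotropy, in (-1, 1).
#' @param n Refractive index (>= 1).
#' @return An object of class `optical_properties` (a list of the four
#'   numeric vectors, recycled to common length).
#' @export
#' @examples
#' optical_properties(mu_a = 0.01, mu_s = 2, g = 0, n = 1.5)
optical_properties <- function(mu_a, mu_s, g = 0, n = 1.4) {
  len <- max(length(mu_a), length(mu_s), length(g), length(n))
  props <- list(mu_a = rep_len(as.numeric(mu_a), len),
                mu_s = rep_len(as.numeric(mu_s), len),
                g = rep_len(as.numeric(g), len),
                n = rep_len(as.numeric(n), len))
  if (any(!is.finite(props$mu_a)) || any(props$mu_a < 0))
    stop("mu_a must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(props$mu_s)) || any(props$mu_s < 0))
    stop("mu_s must be finite and >= 0", call. = FALSE)
  if (any(abs(props$g) >= 1))
    stop("g must lie strictly inside (-1, 1)", call. = FALSE)
  if (any(props$n < 1))
    stop("refractive index n must be >= 1", call. = FALSE)
  structure(props, class = "optical_properties")
}

#' Cylindrical blood vessel embedded in a slab
#'
#' The vessel axis runs parallel to the slab surface (along y, through
#' x = 0) at axis depth `axis_depth_mm` measured from the illuminated
#' surface to the axis. Diameter is accepted in micrometres, the field's
#' customary unit for capillary calibre, and converted to mm internally.
#'
#' @param diameter_um Vessel diameter, micrometres (> 0).
#' @param axis_depth_mm Depth of the vessel axis below the illuminated
#'   surface, mm.
#' @param blood Blood [optical_properties()] (may be per-wavelength).
#' @return Object of class `cylindrical_vessel`.
#' @export
cylindrical_vessel <- function(diameter_um, axis_depth_mm,
                               blood = blood_default()) {
  stopifnot(is.numeric(diameter_um), length(diameter_um) == 1L,
            is.numeric(axis_depth_mm), length(axis_depth_mm) == 1L)
  if (diameter_um <= 0) stop("vessel diameter must be > 0", call. = FALSE)
  if (!inherits(blood, "optical_properties"))
    stop("blood must be an optical_properties object", call. = FALSE)
  structure(list(diameter_um = diameter_um,
                 axis_depth_mm = axis_depth_mm,
                 radius_mm = diameter_um / 2000,
                 blood = blood),
            class = "cylindrical_vessel")
}

#' Default blood optical properties (synthetic template)
#'
#' Hemoglobin-like synthetic absorption (see [hemoglobin_like_mu_a()])
#' with modest scattering; a stand-in for unavailable whole-blood
#' measurements, clearly synthetic.
#'
#' @param wavelengths_nm Wavelength grid, nm.
#' @param scale Multiplier on the absorption template.
#' @return An [optical_properties()] object with one entry per wavelength.
#' @export
blood_default <- function(wavelengths_nm = 550, scale = 1) {
  optical_properties(mu_a = hemoglobin_like_mu_a(wavelengths_nm, scale),
                     mu_s = 1.0, g = 0, n = 1.37)
}

#' Slab phantom model with an optional embedded vessel
#'
#' Geometry follows the epoxy/intralipid phantom convention: a slab of
#' `thickness_mm` (default 2 mm) with square lateral half-width
#' `lateral_mm` (default 15 mm full extent), illuminated from above
#' (z = 0 surface), ambient media above and below.
#'
#' @param thickness_mm Slab thickness, mm.
#' @param lateral_mm Full lateral extent, mm (square cross-section).
#' @param background Background [optical_properties()].
#' @param vessel Optional [cylindrical_vessel()].
#' @param n_above,n_below Ambient refractive indices.
#' @return Object of class `phantom_model`.
#' @export
#' @examples
#' m <- phantom_model(background = optical_properties(0.01, 2, 0, 1.5),
#'                    vessel = cylindrical_vessel(300, 0.65))
phantom_model <- function(thickness_mm = 2.0, lateral_mm = 15,
                          background = optical_properties(0.01, 2, 0, 1.5),
                          vessel = NULL,
                          n_above = 1.0, n_below = 1.0) {
  if (thickness_mm <= 0) stop("thickness must be > 0", call. = FALSE)
  if (lateral_mm <= 0) stop("lateral extent must be > 0", call. = FALSE)
  if (!inherits(background, "optical_properties"))
    stop("background must be an optical_properties object", call. = FALSE)
  if (!is.null(vessel)) {
    if (!inherits(vessel, "cylindrical_vessel"))
      stop("vessel must be a cylindrical_vessel object", call. = FALSE)
    rv <- vessel$radius_mm
    if (vessel$axis_depth_mm - rv <= 0)
      stop("vessel protrudes through the illuminated surface: need ",
           "axis_depth - D/2000 > 0", call. = FALSE)
    if (vessel$axis_depth_mm + rv >= thickness_mm)
      stop("vessel protrudes through the bottom surface: need ",
           "axis_depth + D/2000 < thickness", call. = FALSE)
  }
  structure(list(thickness_mm = thickness_mm, lateral_mm = lateral_mm,
                 background = background, vessel = vessel,
                 n_above = n_above, n_below = n_below),
            class = "phantom_model")
}

#' Beam specification
#'
#' Flat-top circular beam at normal incidence with a strictly increasing
#' wavelength grid in the 300-1200 nm band.
#'
#' @param spot_mm Beam spot diameter, mm. The default 0.5 mm is the
#'   recommended compromise between signal strength and vessel contrast.
#' @param wavelengths_nm Strictly increasing wavelengths, nm.
#' @param profile Beam profile; only `"flat_top"` is supported.
#' @return Object of class `beam_spec`.
#' @export
beam_spec <- function(spot_mm = 0.5,
                      wavelengths_nm = seq(400, 600, length.out = 10),
                      profile = "flat_top") {
  profile <- match.arg(profile, "flat_top")
  if (spot_mm <= 0) stop("spot diameter must be > 0", call. = FALSE)
  wl <- as.numeric(wavelengths_nm)
  if (any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(wl < 300 | wl > 1200))
    stop("wavelengths must lie within [300, 1200] nm", call. = FALSE)
  structure(list(spot_mm = spot_mm, wavelengths_nm = wl, profile = profile),
            class = "beam_spec")
}

#' Monte Carlo sampling configuration
#'
#' @param photons Photons per wavelength (>= 1).
#' @param seed Master seed (non-negative integer-valued).
#' @param roulette_threshold Weight below which Russian roulette engages.
#' @param roulette_survival Survival probability in roulette.
#' @param tally_fluence Record a voxelized absorption grid.
#' @param voxel_mm Voxel pitch for the absorption grid, mm.
#' @param vessel_fresnel Apply Fresnel events at the vessel wall (off by
#'   default: the blood/background index step is small).
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(photons = 1e5, seed = 1,
                      roulette_threshold = 1e-4, roulette_survival = 0.1,
                      tally_fluence = FALSE, voxel_mm = 0.25,
                      vessel_fresnel = FALSE) {
  if (photons < 1) stop("photon_count must be >= 1", call. = FALSE)
  if (roulette_threshold <= 0 || roulette_threshold >= 1)
    stop("roulette_threshold must be in (0, 1)", call. = FALSE)
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("roulette_survival must be in (0, 1)", call. = FALSE)
  if (seed < 0 || seed != floor(seed))
    stop("seed must be a non-negative integer", call. = FALSE)
  structure(list(photons = as.integer(photons), seed = seed,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 tally_fluence = isTRUE(tally_fluence), voxel_mm = voxel_mm,
                 vessel_fresnel = isTRUE(vessel_fresnel)),
            class = "mc_config")
}

#' Region label at a position
#'
#' Partitions space into exactly one of five labels. Coordinates are mm,
#' z pointing down from the illuminated surface (z = 0), vessel axis
#' along y through x = 0.
#'
#' @param position Numeric length-3 vector (x, y, z) in mm.
#' @param model A [phantom_model()].
#' @return One of `"ambient_above"`, `"background"`, `"vessel"`,
#'   `"ambient_below"`, `"lateral_exit"`.
#' @export
#' @examples
#' m <- phantom_model(vessel = cylindrical_vessel(300, 0.65))
#' region_at(c(0, 0, 0.65), m)  # "vessel"
region_at <- function(position, model) {
  stopifnot(inherits(model, "phantom_model"),
            is.numeric(position), length(position) == 3L)
  x <- position[1]; y <- position[2]; z <- position[3]
  if (z < 0) return("ambient_above")
  if (z > model$thickness_mm) return("ambient_below")
  h <- model$lateral_mm / 2
  if (abs(x) > h || abs(y) > h) return("lateral_exit")
  v <- model$vessel
  if (!is.null(v)) {
    if (x^2 + (z - v$axis_depth_mm)^2 < v$radius_mm^2) return("vessel")
  }
  "background"
}

#' Flip a phantom model upside down
#'
#' Relabels the model as if illuminated from the opposite face: a vessel
#' at axis depth d moves to thickness - d and the ambient indices swap.
#' Mirrors the experimental trick of flipping the physical phantom to
#' double the number of accessible vessel depths.
#'
#' @param model A [phantom_model()].
#' @return The flipped `phantom_model`.
#' @export
flip_phantom <- function(model) {
  stopifnot(inherits(model, "phantom_model"))
  v <- model$vessel
  if (!is.null(v))
    v <- cylindrical_vessel(v$diameter_um,
                            model$thickness_mm - v$axis_depth_mm,
                            blood = v$blood)
  phantom_model(thickness_mm = model$thickness_mm,
                lateral_mm = model$lateral_mm,
                background = model$background, vessel = v,
                n_above = model$n_below, n_below = model$n_above)
}

# Subset per-wavelength optical properties to a single wavelength index.
props_at <- function(props, i) {
  idx <- function(v) if (length(v) == 1L) v else v[i]
  optical_properties(idx(props$mu_a), idx(props$mu_s), idx(props$g),
                     idx(props$n))
}

#' Read a phantom/beam/MC configuration from JSON
#'
#' Expected keys: `geometry{thickness_mm, lateral_mm, n_above, n_below}`,
#' optional `vessel{diameter_um, axis_depth_mm}`,
#' `beam{spot_mm, wavelengths_nm}`,
#' `mc{photons, seed, roulette_threshold, roulette_survival}`, and
#' optional `background{mu_a, mu_s, g, n}` / `blood{mu_a, mu_s, g, n}`
#' per-wavelength property tables.
#'
#' @param path Path to a JSON file.
#' @return List with elements `model`, `beam`, `mc`.
#' @export
read_config_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- function(x, key, where) {
    if (is.null(x)) stop("config missing key: ", where, "$", key,
                         call. = FALSE)
    x
  }
  geo <- need(cfg$geometry, "geometry", "")
  bg <- if (!is.null(cfg$background))
    optical_properties(cfg$background$mu_a, cfg$background$mu_s,
                       cfg$background$g %||% 0, cfg$background$n %||% 1.5)
  else optical_properties(0.01, 2, 0, 1.5)
  vessel <- NULL
  if (!is.null(cfg$vessel)) {
    blood <- if (!is.null(cfg$blood))
      optical_properties(cfg$blood$mu_a, cfg$blood$mu_s,
                         cfg$blood$g %||% 0, cfg$blood$n %||% 1.37)
    else blood_default(cfg$beam$wavelengths_nm %||% 550)
    vessel <- cylindrical_vessel(
      need(cfg$vessel$diameter_um, "diameter_um", "vessel"),
      need(cfg$vessel$axis_depth_mm, "axis_depth_mm", "vessel"),
      blood = blood)
  }
  model <- phantom_model(
    thickness_mm = need(geo$thickness_mm, "thickness_mm", "geometry"),
    lateral_mm = geo$lateral_mm %||% 15,
    background = bg, vessel = vessel,
    n_above = geo$n_above %||% 1.0, n_below = geo$n_below %||% 1.0)
  bm <- need(cfg$beam, "beam", "")
  beam <- beam_spec(spot_mm = bm$spot_mm %||% 0.5,
                    wavelengths_nm = need(bm$wavelengths_nm,
                                          "wavelengths_nm", "beam"))
  mcc <- cfg$mc %||% list()
  mc <- mc_config(photons = mcc$photons %||% 1e5,
                  seed = need(mcc$seed, "seed", "mc"),
                  roulette_threshold = mcc$roulette_threshold %||% 1e-4,
                  roulette_survival = mcc$roulette_survival %||% 0.1)
  list(model = model, beam = beam, mc = mc)
}

#' Write a configuration to JSON
#'
#' Inverse of [read_config_json()].
#'
#' @param model A [phantom_model()].
#' @param beam A [beam_spec()].
#' @param mc An [mc_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(model, beam, mc, path) {
  cfg <- list(
    geometry = list(thickness_mm = model$thickness_mm,
                    lateral_mm = model$lateral_mm,
                    n_above = model$n_above, n_below = model$n_below),
    background = unclass(model$background),
    beam = list(spot_mm = beam$spot_mm,
                wavelengths_nm = beam$wavelengths_nm),
    mc = list(photons = mc$photons, seed = mc$seed,
              roulette_threshold = mc$roulette_threshold,
              roulette_survival = mc$roulette_survival))
  if (!is.null(model$vessel)) {
    cfg$vessel <- list(diameter_um = model$vessel$diameter_um,
                       axis_depth_mm = model$vessel$axis_depth_mm)
    cfg$blood <- unclass(model$vessel$blood)
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
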