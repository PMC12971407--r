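# Synthetic landscapes with the statistical structure the pipeline assumes:
# spatially autocorrelated fields, a topographic gradient, human pressure
# negatively coupled to ecological condition, and planted nonlinear driver
# thresholds. Everything is deterministic under (config, seed).

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1013904223 + 1103515245 * k) %% 2147483647)
}

#' Seeded Gaussian random field
#'
#' Zero-mean, unit-sample-variance field built by FFT convolution of white
#' noise with a periodic Gaussian kernel of standard deviation
#' `correlation_range` cells. `correlation_range = 0` returns i.i.d. noise.
#'
#' @param shape `(rows, cols)`.
#' @param correlation_range Kernel standard deviation in cells (>= 0).
#' @param seed Integer seed.
#' @return An [eco_grid()].
#' @export
gaussian_field <- function(shape, correlation_range, seed) {
  stopifnot(length(shape) == 2L, correlation_range >= 0)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  set.seed(seed)
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (correlation_range > 0) {
    z <- fft_smooth(z, correlation_range)
  }
  z <- (z - mean(z)) / sd(z)
  eco_grid(z)
}

# periodic Gaussian smoothing via FFT; used for fields and proximity layers
fft_smooth <- function(z, range_cells) {
  nr <- nrow(z); nc <- ncol(z)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- outer(exp(-dr^2 / (2 * range_cells^2)),
             exp(-dc^2 / (2 * range_cells^2)))
  k <- k / sum(k)
  Re(fft(fft(z) * fft(k), inverse = TRUE)) / (nr * nc)
}

zsc <- function(m) (m - mean(m)) / sd(as.vector(m))

#' Synthetic elevation surface
#'
#' Smooth random relief plus an optional north-high / south-low trend so
#' that mountains and plains form coherent regions.
#'
#' @param shape `(rows, cols)`.
#' @param correlation_range Relief smoothness in cells.
#' @param trend Strength of the row-wise gradient (0 disables it).
#' @param seed Integer seed.
#' @return An [eco_grid()] in meters (roughly 200-1500 m).
#' @export
synth_elevation <- function(shape, correlation_range, trend = 1, seed = 1) {
  relief <- gaussian_field(shape, correlation_range, seed)$values
  grad <- matrix(rep(seq(1, -1, length.out = shape[1]), shape[2]),
                 shape[1], shape[2])
  z <- zsc(relief + trend * grad)
  eco_grid(700 + 280 * z)
}

# elevation affinity order, low to high ground
lc_affinity <- c("construction", "farmland", "water", "grassland",
                 "desert", "forest")

#' Synthetic land cover from a latent field and elevation
#'
#' Cells are ranked by a combined score of the latent field and elevation
#' and sliced at the cumulative requested proportions, walking the classes
#' from low-ground types (construction, farmland) up to forest. Realized
#' shares therefore match the request to within rounding, and forest sits
#' higher than construction by design.
#'
#' @param latent Spatially autocorrelated [eco_grid()] driving patchiness.
#' @param elevation Elevation [eco_grid()] (same shape).
#' @param proportions Named vector of class proportions summing to 1 over
#'   (a subset of) the six legend classes.
#' @param seed Integer seed (tie-breaking jitter).
#' @param latent_weight,elev_weight Score weights; setting both to 0 gives
#'   spatially unstructured (i.i.d.) class assignment.
#' @return An [eco_catgrid()].
#' @export
synth_landcover <- function(latent, elevation, proportions, seed = 1,
                            latent_weight = 1, elev_weight = 0.8) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1", call. = FALSE)
  bad <- setdiff(names(proportions), names(lc_legend()))
  if (length(bad))
    stop("unknown land-cover class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  nr <- nrow(latent$values); nc <- ncol(latent$values)
  set.seed(sub_seed(seed, 17L))
  score <- latent_weight * zsc(latent$values) +
    elev_weight * zsc(elevation$values) +
    1e-3 * matrix(rnorm(nr * nc), nr, nc)
  ord <- lc_affinity[lc_affinity %in% names(proportions)[proportions > 0]]
  probs <- proportions[ord]
  cuts <- quantile(score, probs = cumsum(probs), names = FALSE)
  codes <- matrix(unname(lc_legend()[ord[1]]), nr, nc)
  if (length(ord) > 1) {
    for (k in 2:length(ord)) {
      codes[score > cuts[k - 1]] <- unname(lc_legend()[ord[k]])
    }
  }
  eco_catgrid(codes, cell_size = latent$cell_size)
}

#' Synthetic human-activity layers
#'
#' Population density, nighttime lights and GDP density are generated on a
#' log scale (heavy-tailed when exponentiated) as decreasing functions of
#' elevation, elevated near construction land, with an optional coupling
#' term that ties them to an ecological-condition layer: negative
#' `coupling_strength` concentrates human pressure where condition is poor.
#'
#' @param landcover An [eco_catgrid()].
#' @param elevation An [eco_grid()].
#' @param coupling_strength Real in [-1, 1].
#' @param seed Integer seed.
#' @param condition Optional [eco_grid()] of ecological condition (e.g.
#'   NPP). Defaults to a vegetation score derived from land cover.
#' @return List of [eco_grid()]s: `pop_density`, `ntl`, `gdp` (all >= 0).
#' @export
synth_human_layers <- function(landcover, elevation, coupling_strength,
                               seed = 1, condition = NULL) {
  stopifnot(coupling_strength >= -1, coupling_strength <= 1)
  nr <- nrow(landcover$codes); nc <- ncol(landcover$codes)
  constr <- (landcover$codes == lc_legend()[["construction"]]) * 1
  constr_prox <- fft_smooth(constr, 3)
  constr_prox <- if (sd(constr_prox) > 0) zsc(constr_prox) else constr_prox * 0
  if (is.null(condition)) {
    veg <- matrix(0, nr, nc)
    veg_score <- c(farmland = 0.4, forest = 1, grassland = 0.8, water = 0.5,
                   construction = 0, desert = 0.1)
    for (cls in names(lc_legend()))
      veg[landcover$codes == lc_legend()[[cls]]] <- veg_score[[cls]]
    cond_z <- if (sd(veg) > 0) zsc(veg) else veg * 0
  } else {
    cond_z <- zsc(condition$values)
  }
  elev_z <- zsc(elevation$values)
  # moderate log-scale dispersion: strong enough for heavy tails, damped
  # enough that the coupling survives exponentiation at the unit level
  base <- -0.35 * elev_z + 0.3 * constr_prox +
    1.7 * coupling_strength * cond_z
  mk <- function(k, scale, sdlog) {
    set.seed(sub_seed(seed, k))
    eps <- fft_smooth(matrix(rnorm(nr * nc), nr, nc), 2)
    eps <- if (sd(eps) > 0) sdlog * zsc(eps) else eps
    eco_grid(scale * exp(base + eps), cell_size = landcover$cell_size)
  }
  list(pop_density = mk(31L, 50, 0.4),
       ntl = mk(32L, 10, 0.4),
       gdp = mk(33L, 200, 0.5))
}

eval_response <- function(x, spec_entry) {
  shape <- spec_entry$shape %||% "linear"
  eff <- spec_entry$effect %||% 1
  if (shape == "linear") {
    eff * x
  } else if (shape == "piecewise") {
    b <- spec_entry$breakpoint
    s <- spec_entry$slopes
    stopifnot(length(s) == 2L, is.numeric(b))
    eff * ifelse(x < b, s[1] * (x - b), s[2] * (x - b))
  } else stop("unknown response shape: ", shape, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic NPP and ecosystem-service layers
#'
#' NPP is the sum of the configured driver responses (linear or piecewise
#' with a slope change exactly at the breakpoint) plus Gaussian noise. The
#' five service layers (carbon storage, food production, environmental
#' quality, soil retention, water yield) are distinct monotone transforms
#' of NPP, soil moisture and land cover with independent noise, so entropy
#' weights over them are non-degenerate.
#'
#' @param drivers Named list of [eco_grid()] covariate layers.
#' @param driver_spec List of entries `list(feature, shape, effect,
#'   breakpoint, slopes)`; `shape` is `"linear"` or `"piecewise"`.
#' @param noise_sd NPP noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param landcover Optional [eco_catgrid()] feeding the food-production
#'   layer.
#' @param intercept Baseline NPP added to the responses.
#' @return List with `npp` ([eco_grid()]) and `services` (named list of
#'   five [eco_grid()]s).
#' @export
synth_npp_and_services <- function(drivers, driver_spec, noise_sd = 0,
                                   seed = 1, landcover = NULL,
                                   intercept = 0) {
  stopifnot(noise_sd >= 0)
  miss <- setdiff(vapply(driver_spec, function(e) e$feature, ""),
                  names(drivers))
  if (length(miss))
    stop("driver_spec references missing feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  shp <- dim(drivers[[1]]$values)
  npp <- matrix(intercept, shp[1], shp[2])
  for (e in driver_spec)
    npp <- npp + eval_response(drivers[[e$feature]]$values, e)
  if (noise_sd > 0) {
    set.seed(sub_seed(seed, 41L))
    npp <- npp + noise_sd * matrix(rnorm(prod(shp)), shp[1], shp[2])
  }
  npp_z <- if (sd(npp) > 0) zsc(npp) else npp * 0
  moist <- if ("plant_available_water" %in% names(drivers))
    zsc(drivers$plant_available_water$values) else matrix(0, shp[1], shp[2])
  farm <- if (!is.null(landcover)) {
    f <- fft_smooth((landcover$codes == lc_legend()[["farmland"]]) * 1, 3)
    if (sd(f) > 0) zsc(f) else f * 0
  } else matrix(0, shp[1], shp[2])
  svc <- function(k, m) {
    set.seed(sub_seed(seed, k))
    eco_grid(m + 0.3 * matrix(rnorm(prod(shp)), shp[1], shp[2]))
  }
  services <- list(
    carbon = svc(51L, 0.9 * npp_z),
    food = svc(52L, 0.4 * npp_z + 0.7 * farm),
    quality = svc(53L, 0.6 * npp_z + 0.4 * moist),
    soil_retention = svc(54L, 0.3 * npp_z + 0.6 * moist),
    water_yield = svc(55L, 0.8 * moist)
  )
  list(npp = eco_grid(npp), services = services)
}

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' a 100 x 100 cell landscape with 8-cell autocorrelation, a mixed
#' forest-grassland-farmland cover, human pressure negatively coupled to
#' ecological condition (-0.8), an upward drift in the human layers across
#' years, and a piecewise PET response with its breakpoint at 850 mm.
#'
#' @param shape `(rows, cols)`.
#' @param correlation_range Field autocorrelation in cells.
#' @param class_proportions Named class shares summing to 1.
#' @param coupling_strength Human-ecology coupling in [-1, 1].
#' @param driver_spec NPP response specification (see
#'   [synth_npp_and_services()]).
#' @param noise_sd NPP noise sd (gC m-2 yr-1 scale).
#' @param years Number of annual snapshots.
#' @param drift Multiplicative per-year growth of the human layers.
#' @param elev_trend Row-gradient strength of the elevation surface.
#' @param lc_structured If `FALSE`, land cover is assigned i.i.d. (no
#'   latent/elevation structure).
#' @param seed Integer seed.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(shape = c(100, 100),
                            correlation_range = 8,
                            class_proportions = c(farmland = 0.15,
                                                  forest = 0.35,
                                                  grassland = 0.30,
                                                  water = 0.05,
                                                  construction = 0.10,
                                                  desert = 0.05),
                            coupling_strength = -0.8,
                            driver_spec = default_driver_spec(),
                            noise_sd = 30,
                            years = 2,
                            drift = 0.2,
                            elev_trend = 1,
                            lc_structured = TRUE,
                            seed = 1) {
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1", call. = FALSE)
  stopifnot(noise_sd >= 0, years >= 1,
            coupling_strength >= -1, coupling_strength <= 1)
  structure(list(shape = shape, correlation_range = correlation_range,
                 class_proportions = class_proportions,
                 coupling_strength = coupling_strength,
                 driver_spec = driver_spec, noise_sd = noise_sd,
                 years = years, drift = drift, elev_trend = elev_trend,
                 lc_structured = lc_structured, seed = seed),
            class = "scenario_config")
}

#' Default NPP driver responses
#'
#' Temperature and plant-available water act linearly and positively; PET
#' follows a piecewise response whose slope steepens beyond 850 mm, the
#' planted nonlinear threshold the attribution stage is asked to recover.
#'
#' @return List of driver response entries.
#' @export
default_driver_spec <- function() {
  list(
    list(feature = "temperature", shape = "linear", effect = 10),
    list(feature = "plant_available_water", shape = "linear", effect = 600),
    list(feature = "pet", shape = "piecewise", effect = 1,
         breakpoint = 850, slopes = c(-0.2, -0.6))
  )
}

#' Named scenario presets
#'
#' `"negative_coupling"`: the default study conditions (coupling -0.8,
#' drifting human layers). `"null"`: no coupling, no drift, a uniform
#' grassland cover (land use would otherwise tie the two index families
#' together: farmland raises both the disturbance score and the
#' food-production service), and a short correlation range so unit-level
#' values are effectively exchangeable and permutation inference is
#' calibrated.
#' `"piecewise"`: the attribution scenario — a fine unit lattice and the
#' planted 850 mm PET breakpoint dominating the NPP signal.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name = c("negative_coupling", "null",
                                     "piecewise"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    negative_coupling = scenario_config(seed = seed),
    null = scenario_config(coupling_strength = 0, drift = 0,
                           correlation_range = 2, elev_trend = 0,
                           lc_structured = FALSE,
                           class_proportions = c(grassland = 1),
                           seed = seed),
    piecewise = scenario_config(
      coupling_strength = -0.4, years = 1, drift = 0,
      driver_spec = list(
        list(feature = "temperature", shape = "linear", effect = 6),
        list(feature = "plant_available_water", shape = "linear",
             effect = 300),
        list(feature = "pet", shape = "piecewise", effect = 1,
             breakpoint = 850, slopes = c(-0.2, -0.6))),
      noise_sd = 10, seed = seed)
  )
}

#' Generate a multi-year synthetic dataset
#'
#' Produces elevation/slope, land cover, driver covariates, NPP, the five
#' service layers and the human-activity layers for each year, with a
#' monotone multiplicative drift in the human layers across years. The
#' planted parameters are returned as a `truth` record.
#'
#' @param config A [scenario_config()].
#' @return A `synthetic_dataset` list: `elevation`, `slope`, `landcover`,
#'   `drivers` (named list of grids), `years` (list with `npp`, `services`,
#'   `pop_density`, `ntl`, `gdp` per year), `truth`, `config`.
#' @export
make_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  shp <- config$shape; seed <- config$seed
  elevation <- synth_elevation(shp, max(config$correlation_range, 4),
                               trend = config$elev_trend,
                               seed = sub_seed(seed, 1L))
  slope <- local({
    e <- elevation$values
    gx <- cbind(e[, -1], e[, ncol(e)]) - e
    gy <- rbind(e[-1, ], e[nrow(e), ]) - e
    eco_grid(sqrt(gx^2 + gy^2))
  })
  latent <- gaussian_field(shp, config$correlation_range,
                           sub_seed(seed, 2L))
  lw <- if (config$lc_structured) 1 else 0
  ew <- if (config$lc_structured) 0.8 else 0
  landcover <- synth_landcover(latent, elevation, config$class_proportions,
                               seed = sub_seed(seed, 3L),
                               latent_weight = lw, elev_weight = ew)
  gen_drv <- function(k, mu, sdv) {
    f <- gaussian_field(shp, config$correlation_range, sub_seed(seed, k))
    eco_grid(mu + sdv * f$values)
  }
  drivers <- list(
    temperature = gen_drv(11L, -1, 3),
    precipitation = gen_drv(12L, 450, 100),
    pet = gen_drv(13L, 850, 150),
    plant_available_water = gen_drv(14L, 0.15, 0.05),
    rainfall_erosivity = gen_drv(15L, 1000, 300),
    elevation = elevation,
    slope = slope
  )
  drivers$plant_available_water$values <-
    pmax(drivers$plant_available_water$values, 0.01)
  years <- vector("list", config$years)
  for (y in seq_len(config$years)) {
    ns <- synth_npp_and_services(drivers, config$driver_spec,
                                 noise_sd = config$noise_sd,
                                 seed = sub_seed(seed, 100L + y),
                                 landcover = landcover, intercept = 500)
    hum <- synth_human_layers(landcover, elevation,
                              config$coupling_strength,
                              seed = sub_seed(seed, 200L + y),
                              condition = ns$npp)
    growth <- (1 + config$drift)^(y - 1)
    for (nm in names(hum)) hum[[nm]]$values <- hum[[nm]]$values * growth
    years[[y]] <- c(list(npp = ns$npp, services = ns$services), hum)
  }
  names(years) <- paste0("year", seq_len(config$years))
  truth <- list(
    coupling_strength = config$coupling_strength,
    drift = config$drift,
    breakpoints = Filter(Negate(is.null), lapply(config$driver_spec,
      function(e) if (identical(e$shape, "piecewise"))
        list(feature = e$feature, breakpoint = e$breakpoint,
             slopes = e$slopes))),
    seed = config$seed
  )
  structure(list(elevation = elevation, slope = slope,
                 landcover = landcover, drivers = drivers, years = years,
                 truth = truth, config = config),
            class = "synthetic_dataset")
}
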