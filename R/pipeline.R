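# End-to-end orchestration: synthetic (or user-supplied) rasters ->
# per-unit indices (EHI, HAI) -> spatial statistics -> coupling /
# quadrants -> driver attribution, collected into a reproducible,
# machine-readable run report. Every stage draws its randomness from a
# seed derived from the global seed plus a stage offset, so stages are
# independently reproducible.

#' Pipeline configuration
#'
#' @param scenario A [scenario_config()] (synthetic input mode), or NULL
#'   when `layers` supplies pre-built grids.
#' @param layers Optional pre-built input set shaped like the output of
#'   [make_scenario()].
#' @param unit_cells Analysis-unit block edge in cells.
#' @param connectivity Patch connectivity for landscape metrics.
#' @param eo_mode `"flat"` or `"nested"` organization weights.
#' @param level_scheme `"equal_interval"` or `"quantile"` index grading.
#' @param esi_weighting `"entropy"` or `"equal"` service weights.
#' @param t_mode Coordination index form, `"additive"` or
#'   `"multiplicative"`.
#' @param weights_scheme Spatial contiguity, `"queen"` or `"rook"`.
#' @param n_perm Moran permutation count.
#' @param drivers_enabled Run the attribution stage?
#' @param driver_targets Targets among `"ehi"`, `"hai"`, `"d"`.
#' @param driver_features Feature columns for the attribution stage.
#' @param param_grid Hyperparameter grid for [fit_gbt()]; the pipeline
#'   default is a reduced 4-point grid (full grid via
#'   [default_param_grid()]).
#' @param cv_folds,test_fraction Attribution CV folds and held-out share.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = scenario_config(), layers = NULL,
                       unit_cells = 10, connectivity = 8,
                       eo_mode = "flat", level_scheme = "equal_interval",
                       esi_weighting = "entropy", t_mode = "additive",
                       weights_scheme = "queen", n_perm = 999,
                       drivers_enabled = TRUE,
                       driver_targets = c("ehi", "hai", "d"),
                       driver_features = c("temperature", "precipitation",
                                           "pet", "plant_available_water",
                                           "rainfall_erosivity", "gdp",
                                           "pop_density", "ntl",
                                           "elevation", "slope"),
                       param_grid = expand.grid(max_depth = c(3, 5),
                                                eta = 0.1, nrounds = 200,
                                                lambda = 1),
                       cv_folds = 3, test_fraction = 0.3, seed = 1) {
  stopifnot(xor(is.null(scenario), is.null(layers)) ||
              (!is.null(scenario) && is.null(layers)))
  structure(list(scenario = scenario, layers = layers,
                 unit_cells = unit_cells, connectivity = connectivity,
                 eo_mode = eo_mode, level_scheme = level_scheme,
                 esi_weighting = esi_weighting, t_mode = t_mode,
                 weights_scheme = weights_scheme, n_perm = n_perm,
                 drivers_enabled = drivers_enabled,
                 driver_targets = driver_targets,
                 driver_features = driver_features,
                 param_grid = param_grid, cv_folds = cv_folds,
                 test_fraction = test_fraction, seed = seed),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar keys override [run_config()] defaults; `scenario:` keys override
#' [scenario_config()] defaults (or `preset: <name>` picks a
#' [scenario_preset()]). Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), c("scenario", "layers",
                                                 "param_grid"))
  bad <- setdiff(names(y), c(known, "scenario"))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sc <- if (!is.null(y$scenario)) {
    sy <- y$scenario
    if (!is.null(sy$preset)) {
      scenario_preset(sy$preset, seed = sy$seed %||% 1)
    } else {
      sbad <- setdiff(names(sy), names(formals(scenario_config)))
      if (length(sbad))
        stop("unknown scenario key(s): ", paste(sbad, collapse = ", "),
             call. = FALSE)
      if (!is.null(sy$class_proportions))
        sy$class_proportions <- unlist(sy$class_proportions)
      if (!is.null(sy$shape)) sy$shape <- unlist(sy$shape)
      do.call(scenario_config, sy)
    }
  } else scenario_config()
  args <- c(list(scenario = sc), y[intersect(names(y), known)])
  do.call(run_config, args)
}

unit_means <- function(grid, unit_cells) {
  suppressMessages(aggregate_to_units(grid, unit_cells, "mean"))
}

#' Run the full assessment-coupling-driving pipeline
#'
#' Stages in order: synthetic generation (or supplied layers), per-unit
#' indices (EHI with pooled-across-years normalization; HAI), spatial
#' autocorrelation (univariate and bivariate Moran's I, Gi*), coupling
#' coordination and quadrant zoning, and driver attribution on the final
#' year. All normalizations pool every year so indices are temporally
#' comparable.
#'
#' @param config A `run_config`.
#' @return A `run_report` list (see the elements returned).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  ds <- config$layers
  if (is.null(ds)) {
    sc <- config$scenario
    sc$seed <- sub_seed(seed, 1L)
    ds <- make_scenario(sc)
  }
  uc <- config$unit_cells
  years <- names(ds$years)
  n_years <- length(years)

  props <- unit_class_proportions(ds$landcover, uc)
  units <- props[c("unit_id", "block_row", "block_col")]
  n_units <- nrow(units)

  # --- organization (land cover is shared across years here) ------------
  um <- suppressMessages(unit_metrics(ds$landcover, uc,
                                      config$connectivity))
  um_pooled <- dplyr::bind_rows(lapply(years, function(y)
    dplyr::mutate(um, year = y)))
  eo_tab <- suppressWarnings(suppressMessages(
    organization_index(um_pooled, mode = config$eo_mode)))

  # --- pooled unit means ------------------------------------------------
  pool <- dplyr::bind_rows(lapply(years, function(y) {
    yr <- ds$years[[y]]
    out <- units
    out$year <- y
    out$npp <- unit_means(yr$npp, uc)$value
    for (s in names(yr$services))
      out[[s]] <- unit_means(yr$services[[s]], uc)$value
    out$pop_density <- unit_means(yr$pop_density, uc)$value
    out$ntl <- unit_means(yr$ntl, uc)$value
    out$gdp <- unit_means(yr$gdp, uc)$value
    out
  }))

  # --- VORS components --------------------------------------------------
  svc_names <- names(ds$years[[1]]$services)
  ev <- vitality(pool$npp)
  svc_n <- sapply(svc_names, function(s) minmax_norm(pool[[s]]))
  w_svc <- if (config$esi_weighting == "entropy") entropy_weights(svc_n)
           else setNames(rep(1 / length(svc_names), length(svc_names)),
                         svc_names)
  esi <- service_index(svc_n, w_svc)
  er <- rep(resilience(props), n_years)
  eo <- eo_tab$eo
  vors_tab <- tibble::tibble(year = pool$year, unit_id = pool$unit_id,
                             block_row = pool$block_row,
                             block_col = pool$block_col,
                             ev = ev, eo = eo, er = er, esi = esi,
                             ehi = ehi(ev, eo, er, esi))

  # --- HAI --------------------------------------------------------------
  slucc_raw <- rep(slucc(props), n_years)
  hai_tab <- suppressWarnings(
    hai_index(slucc_raw, pool$pop_density, pool$ntl))
  hai_tab <- dplyr::bind_cols(
    tibble::tibble(year = pool$year, unit_id = pool$unit_id,
                   slucc_raw = slucc_raw), hai_tab)

  # --- level shares -----------------------------------------------------
  lv <- function(x) classify_levels(x, scheme = config$level_scheme)
  level_shares <- list(
    ehi = lapply(split(vors_tab$ehi, vors_tab$year),
                 function(x) suppressWarnings(lv(x))$shares),
    hai = lapply(split(hai_tab$hai, hai_tab$year),
                 function(x) suppressWarnings(lv(x))$shares))

  # --- spatial statistics -----------------------------------------------
  W <- suppressMessages(build_weights(units, config$weights_scheme, "row"))
  moran_rows <- list()
  gistar <- list()
  for (y in years) {
    e <- vors_tab$ehi[vors_tab$year == y]
    h <- hai_tab$hai[hai_tab$year == y]
    me <- morans_i(e, W, config$n_perm, seed = sub_seed(seed, 301L))
    mh <- morans_i(h, W, config$n_perm, seed = sub_seed(seed, 302L))
    mb <- bivariate_morans_i(h, e, W, config$n_perm,
                             seed = sub_seed(seed, 303L))
    moran_rows[[y]] <- tibble::tibble(
      year = y, variable = c("ehi", "hai", "hai_x_ehi"),
      I = c(me$I, mh$I, mb$I),
      p_value = c(me$p_value, mh$p_value, mb$p_value),
      p_two_sided = c(me$p_two_sided, mh$p_two_sided, mb$p_two_sided),
      z_score = c(me$z_score, mh$z_score, mb$z_score))
    gistar[[y]] <- list(ehi = getis_ord_gstar(e, W),
                        hai = getis_ord_gstar(h, W))
  }
  moran_tab <- dplyr::bind_rows(moran_rows)

  # --- coupling and quadrants -------------------------------------------
  C <- coupling_degree(vors_tab$ehi, hai_tab$hai)
  Tt <- coordination_index(vors_tab$ehi, hai_tab$hai,
                           mode = config$t_mode)
  D <- ccd(C, Tt)
  coupling_tab <- tibble::tibble(year = pool$year,
                                 unit_id = pool$unit_id,
                                 C = C, T = as.numeric(Tt), D = D,
                                 level = classify_ccd(D))
  ccd_shares <- lapply(split(coupling_tab$level, coupling_tab$year),
                       function(l) 100 * as.numeric(table(l)) / length(l))
  ccd_shares <- lapply(ccd_shares, function(s) {
    names(s) <- levels(coupling_tab$level); s })
  quad <- dplyr::bind_rows(lapply(years, function(y) {
    sel <- pool$year == y
    q <- quadrant_assign(vors_tab$ehi[sel], hai_tab$hai[sel])
    dplyr::bind_cols(tibble::tibble(year = y,
                                    unit_id = pool$unit_id[sel]), q)
  }))
  zones <- zone_summary(quad$quadrant, coupling_tab$D, year = quad$year)

  # --- driver attribution (final year) ----------------------------------
  drivers_out <- NULL
  if (isTRUE(config$drivers_enabled)) {
    y_last <- years[n_years]
    sel <- pool$year == y_last
    feat_tab <- units
    for (f in setdiff(config$driver_features,
                      c("gdp", "pop_density", "ntl")))
      feat_tab[[f]] <- unit_means(ds$drivers[[f]], uc)$value
    feat_tab$gdp <- pool$gdp[sel]
    feat_tab$pop_density <- pool$pop_density[sel]
    feat_tab$ntl <- pool$ntl[sel]
    feat_tab$ehi <- vors_tab$ehi[sel]
    feat_tab$hai <- hai_tab$hai[sel]
    feat_tab$d <- coupling_tab$D[sel]
    drivers_out <- lapply(config$driver_targets, function(tg) {
      dm <- suppressMessages(assemble_design(
        feat_tab, config$driver_features, tg,
        test_fraction = config$test_fraction,
        seed = sub_seed(seed, 401L)))
      fit <- fit_gbt(dm, param_grid = config$param_grid,
                     cv_folds = config$cv_folds,
                     seed = sub_seed(seed, 402L))
      sh <- shap_attribution(fit)
      thr <- lapply(ds$truth$breakpoints, function(b) {
        dependence_threshold(sh, b$feature,
                             n_boot = 100,
                             seed = sub_seed(seed, 403L))
      })
      list(target = tg, report = fit$report,
           best_params = fit$best_params,
           importance_share = sh$importance_share,
           local_accuracy_err = max(abs(
             sh$prediction - predict(fit$model, fit$dm$X))),
           thresholds = thr)
    })
    names(drivers_out) <- config$driver_targets
  }

  structure(list(
    seed = seed, n_units = n_units, years = years,
    unit_cells = uc,
    vors = vors_tab, hai = hai_tab,
    service_weights = w_svc,
    level_shares = level_shares,
    moran = moran_tab, gistar = gistar,
    coupling = coupling_tab, ccd_level_shares = ccd_shares,
    quadrants = quad, zone_summary = zones,
    drivers = drivers_out,
    truth = ds$truth
  ), class = "run_report")
}

#' Serialize a run report to JSON
#'
#' Deterministic serialization (fixed digit budget, stable key order) so
#' identical config + seed gives a byte-identical file.
#'
#' @param report A `run_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  r <- report
  r$gistar <- lapply(r$gistar, function(y)
    lapply(y, function(tb) as.list(table(tb$class))))
  r$quadrants <- NULL  # per-unit detail lives in the CSV outputs
  json <- jsonlite::toJSON(unclass(r), digits = 10, auto_unbox = TRUE,
                           force = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Hash a run report
#'
#' MD5 of the deterministic JSON serialization; two runs with the same
#' config and seed hash identically.
#'
#' @param report A `run_report`.
#' @return Character MD5 digest.
#' @export
report_hash <- function(report) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_report(report, tmp)
  unname(tools::md5sum(tmp))
}
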