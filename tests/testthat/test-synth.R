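test_that("gaussian fields are seeded, standardized and correlated as requested", {
  f1 <- gaussian_field(c(100, 100), 10, seed = 5)
  f2 <- gaussian_field(c(100, 100), 10, seed = 5)
  expect_identical(f1$values, f2$values)
  expect_equal(mean(f1$values), 0, tolerance = 1e-12)
  expect_equal(sd(f1$values), 1, tolerance = 1e-12)
  expect_gt(lag1_autocorr(f1$values), 0.5)

  f0 <- gaussian_field(c(100, 100), 0, seed = 5)
  expect_lt(abs(lag1_autocorr(f0$values)), 0.05)
  expect_error(gaussian_field(c(10, 10), -1, 1))
})

test_that("synthetic land cover hits requested shares and the elevation gradient", {
  lat <- gaussian_field(c(200, 200), 6, seed = 2)
  ele <- synth_elevation(c(200, 200), 10, seed = 3)
  lc <- synth_landcover(lat, ele, c(forest = 0.5, grassland = 0.5),
                        seed = 4)
  share_forest <- mean(lc$codes == lc_legend()[["forest"]])
  expect_true(share_forest >= 0.48 && share_forest <= 0.52)

  lc2 <- synth_landcover(lat, ele,
                         c(forest = 0.4, construction = 0.2,
                           farmland = 0.2, grassland = 0.2), seed = 4)
  mean_elev <- function(cls)
    mean(ele$values[lc2$codes == lc_legend()[[cls]]])
  expect_lt(mean_elev("construction"), mean_elev("forest"))
  expect_lt(mean_elev("farmland"), mean_elev("forest"))

  all_forest <- synth_landcover(lat, ele, c(forest = 1), seed = 4)
  expect_true(all(all_forest$codes == lc_legend()[["forest"]]))
  expect_error(synth_landcover(lat, ele, c(forest = 0.7)), "sum to 1")
})

test_that("human layers are non-negative, terrain-bound and coupled on demand", {
  # short correlation range: enough effective replicates that a sample
  # correlation near zero is distinguishable from a planted one
  lat <- gaussian_field(c(100, 100), 3, seed = 6)
  ele <- synth_elevation(c(100, 100), 3, seed = 7)
  lc <- synth_landcover(lat, ele,
                        c(forest = 0.4, grassland = 0.3,
                          construction = 0.15, farmland = 0.15), seed = 8)
  npp <- eco_grid(gaussian_field(c(100, 100), 3, seed = 9)$values * 50 +
                  400)

  h0 <- synth_human_layers(lc, ele, 0, seed = 10, condition = npp)
  expect_true(all(h0$pop_density$values >= 0))
  expect_true(all(h0$ntl$values >= 0))
  expect_true(all(h0$gdp$values >= 0))
  expect_lt(abs(cor(as.vector(h0$pop_density$values),
                    as.vector(npp$values))), 0.1)
  expect_lt(cor(as.vector(h0$pop_density$values),
                as.vector(ele$values)), 0)

  hn <- synth_human_layers(lc, ele, -0.8, seed = 10, condition = npp)
  expect_lt(cor(as.vector(hn$pop_density$values),
                as.vector(npp$values)), -0.4)
})

test_that("NPP responses are planted exactly and services derive from them", {
  x <- eco_grid(matrix(seq(700, 1000, length.out = 400), 20, 20))
  # noiseless single linear response of slope 1: NPP equals the driver
  out <- synth_npp_and_services(list(pet = x),
                                list(list(feature = "pet",
                                          shape = "linear", effect = 1)),
                                noise_sd = 0, seed = 1)
  expect_equal(out$npp$values, x$values)
  expect_named(out$services,
               c("carbon", "food", "quality", "soil_retention",
                 "water_yield"))

  # tent response peaks at the breakpoint
  tent <- synth_npp_and_services(
    list(pet = x),
    list(list(feature = "pet", shape = "piecewise", effect = 1,
              breakpoint = 850, slopes = c(1, -1))),
    noise_sd = 0, seed = 1)
  peak <- x$values[which.max(tent$npp$values)]
  expect_lt(abs(peak - 850), 5)

  # determinism and config validation
  a <- synth_npp_and_services(list(pet = x),
                              list(list(feature = "pet",
                                        shape = "linear", effect = 2)),
                              noise_sd = 10, seed = 33)
  b <- synth_npp_and_services(list(pet = x),
                              list(list(feature = "pet",
                                        shape = "linear", effect = 2)),
                              noise_sd = 10, seed = 33)
  expect_identical(a$npp$values, b$npp$values)
  expect_identical(a$services$carbon$values, b$services$carbon$values)
  expect_error(
    synth_npp_and_services(list(pet = x),
                           list(list(feature = "gdp", shape = "linear",
                                     effect = 1)), 0, 1),
    "missing feature")
})

test_that("scenarios are deterministic, layer-consistent and drift upward", {
  cfg <- scenario_config(shape = c(50, 50), years = 2, seed = 12)
  ds1 <- make_scenario(cfg)
  ds2 <- make_scenario(cfg)
  expect_identical(ds1$years$year1$npp$values, ds2$years$year1$npp$values)
  expect_identical(ds1$landcover$codes, ds2$landcover$codes)

  shp <- dim(ds1$landcover$codes)
  for (lay in c("npp", "pop_density", "ntl", "gdp"))
    expect_equal(dim(ds1$years$year2[[lay]]$values), shp)
  for (s in names(ds1$years$year1$services))
    expect_equal(dim(ds1$years$year1$services[[s]]$values), shp)

  # upward drift in the human layers
  expect_gt(mean(ds1$years$year2$ntl$values),
            mean(ds1$years$year1$ntl$values))
  expect_gt(mean(ds1$years$year2$pop_density$values),
            mean(ds1$years$year1$pop_density$values))

  # truth record carries the planted parameters
  expect_equal(ds1$truth$coupling_strength, cfg$coupling_strength)
  expect_equal(ds1$truth$breakpoints[[1]]$feature, "pet")
  expect_equal(ds1$truth$breakpoints[[1]]$breakpoint, 850)
})
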