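forest <- lc_legend()[["forest"]]
grassland <- lc_legend()[["grassland"]]
water <- lc_legend()[["water"]]

test_that("patch delineation matches hand counts", {
  # uniform 2x2 forest: one patch, area 4, perimeter 8
  ps <- label_patches(eco_catgrid(matrix(forest, 2, 2)))
  expect_equal(nrow(ps$patches), 1)
  expect_equal(ps$patches$area, 4)
  expect_equal(ps$patches$perimeter, 8)

  # diagonal pair: one patch under 8-connectivity, two under 4
  codes <- matrix(grassland, 2, 2)
  codes[1, 1] <- forest; codes[2, 2] <- forest
  cg <- eco_catgrid(codes)
  p8 <- label_patches(cg, 8)$patches
  p4 <- label_patches(cg, 4)$patches
  expect_equal(sum(p8$code == forest), 1)
  expect_equal(sum(p4$code == forest), 2)

  # 3x3 forest ring around one grassland cell: perimeter 12 + 4
  ring <- matrix(forest, 3, 3); ring[2, 2] <- grassland
  pr <- label_patches(eco_catgrid(ring))$patches
  expect_equal(pr$perimeter[pr$code == forest], 16)
  expect_equal(pr$area[pr$code == forest], 8)

  expect_error(label_patches(eco_catgrid(matrix(NA_integer_, 2, 2))),
               "empty landscape")
})

test_that("diversity, division, fractal and interspersion formulas", {
  expect_equal(shdi(c(0.5, 0.5)), log(2))
  expect_equal(shdi(1), 0)
  expect_equal(shdi(rep(0.25, 4)), log(4))

  expect_equal(shei(rep(1 / 3, 3)), 1)
  expect_equal(shei(1), 0)
  expect_equal(shei(c(0.9, 0.1)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)) / log(2))

  # division: single patch 0; n equal patches 1 - 1/n
  one <- tibble::tibble(area = 16)
  expect_equal(division(one, 16), 0)
  four <- tibble::tibble(area = rep(4, 4))
  expect_equal(division(four, 16), 0.75)
  for (n in c(2, 5, 10)) {
    eq <- tibble::tibble(area = rep(3, n))
    expect_equal(division(eq, 3 * n), 1 - 1 / n)
  }

  # FRAC: squares are 1 at every side length; strip worked by hand
  for (s in 2:5) {
    sq <- tibble::tibble(area = s^2, perimeter = 4 * s)
    expect_equal(frac_am(sq), 1)
  }
  expect_equal(frac_am(tibble::tibble(area = 1, perimeter = 4)), 1)
  strip <- tibble::tibble(area = c(8, 16), perimeter = c(18, 16))
  hand <- (8 * (2 * log(0.25 * 18) / log(8)) + 16 * 1) / 24
  expect_equal(frac_am(strip), hand)
  expect_equal(2 * log(4.5) / log(8), 1.4465, tolerance = 1e-4)

  # IJI: all pairs equal -> 100; single adjacent pair -> 0; hand value
  expect_equal(iji(c(5, 5, 5), 3), 100)
  expect_equal(iji(c(7, 0, 0), 3), 0)
  expect_equal(iji(c(2, 1, 1), 3),
               100 * (-(0.5 * log(0.5) + 2 * 0.25 * log(0.25))) / log(3),
               tolerance = 1e-12)
  expect_true(is.na(iji(c(4), 2)))
})

test_that("contagion follows the adjacency formula and its conventions", {
  # single class -> 100
  m1 <- landscape_metrics(eco_catgrid(matrix(forest, 4, 4)))
  expect_equal(m1$contag, 100)
  expect_equal(m1$shdi, 0)
  expect_equal(m1$division, 0)
  expect_true(is.na(m1$iji))

  # 10x10 checkerboard: all adjacencies inter-class; oracle agreement
  chk <- matrix(forest, 10, 10)
  chk[(row(chk) + col(chk)) %% 2 == 0] <- grassland
  got <- landscape_metrics(eco_catgrid(chk))
  orc <- oracle_landscape_metrics(chk)
  expect_equal(got$contag, orc$contag, tolerance = 1e-12)
  expect_lte(got$contag, 50)
})

test_that("all six metrics agree with the brute-force oracle on random 8x8 landscapes", {
  for (s in 1:50) {
    k <- 2 + (s %% 4)
    cg <- random_catgrid(8, 8, k = k, seed = 1000 + s)
    conn <- if (s %% 2 == 0) 8 else 4
    got <- landscape_metrics(cg, connectivity = conn)
    orc <- oracle_landscape_metrics(cg$codes, connectivity = conn)
    for (mname in c("shdi", "shei", "division", "contag", "frac_am")) {
      expect_equal(got[[mname]], orc[[mname]], tolerance = 1e-9,
                   label = sprintf("%s (seed %d)", mname, s))
    }
    expect_equal(is.na(got$iji), is.na(orc$iji))
    if (!is.na(got$iji))
      expect_equal(got$iji, orc$iji, tolerance = 1e-9,
                   label = sprintf("iji (seed %d)", s))
  }
})

test_that("metrics respect bounds and are invariant to class relabeling", {
  for (s in 1:10) {
    cg <- random_catgrid(12, 12, k = 4, seed = 2000 + s)
    m <- landscape_metrics(cg)
    expect_gte(m$shdi, 0)
    expect_true(m$shei >= 0 && m$shei <= 1)
    expect_true(m$division >= 0 && m$division <= 1)
    expect_true(m$contag >= 0 && m$contag <= 100)
    expect_true(m$frac_am >= 1 && m$frac_am <= 2)
    if (!is.na(m$iji)) expect_true(m$iji >= 0 && m$iji <= 100)

    # permute legend codes 1..4 -> 4..1
    perm <- eco_catgrid(5 - cg$codes)
    mp <- landscape_metrics(perm)
    expect_equal(as.numeric(m[1, 1:6]), as.numeric(mp[1, 1:6]),
                 tolerance = 1e-12)

    # patch areas conserve the unmasked cell count
    ps <- label_patches(cg)
    expect_equal(sum(ps$patches$area), sum(!cg$nodata_mask))
  }
})

test_that("per-unit metrics treat each block as its own landscape", {
  # two disjoint identical units give identical records
  block <- matrix(c(forest, forest, grassland, water,
                    forest, grassland, grassland, water,
                    forest, forest, water, water,
                    grassland, grassland, water, forest), 4, 4)
  codes <- cbind(block, block)
  um <- suppressMessages(unit_metrics(eco_catgrid(codes), 4))
  expect_equal(nrow(um), 2)
  expect_equal(as.numeric(um[1, c("shdi", "shei", "division", "iji",
                                  "contag", "frac_am")]),
               as.numeric(um[2, c("shdi", "shei", "division", "iji",
                                  "contag", "frac_am")]))

  # uniform unit: degenerate conventions, IJI missing not zero
  uni <- suppressMessages(unit_metrics(eco_catgrid(matrix(forest, 4, 4)), 4))
  expect_equal(uni$shdi, 0)
  expect_equal(uni$contag, 100)
  expect_equal(uni$division, 0)
  expect_true(is.na(uni$iji))

  # unit metrics equal whole-landscape metrics of the extracted block
  one <- suppressMessages(unit_metrics(eco_catgrid(block), 4))
  whole <- landscape_metrics(eco_catgrid(block))
  expect_equal(as.numeric(one[1, c("shdi", "shei", "division", "iji",
                                   "contag", "frac_am")]),
               as.numeric(whole[1, 1:6]))
})

test_that("organization index combines normalized metrics with the published weights", {
  set.seed(9)
  rec <- tibble::tibble(
    unit_id = 1:20,
    shdi = runif(20), shei = runif(20), division = runif(20),
    iji = c(runif(18, 0, 100), NA, NA), contag = runif(20, 0, 100),
    frac_am = runif(20, 1, 1.4))
  out <- suppressMessages(organization_index(rec))
  expect_true(all(out$eo >= 0 & out$eo <= 1))

  # a synthetic unit at the max of every metric gets EO ~ 1 (flat weights
  # sum to 1.0000 within 5e-4); at the min, EO = 0
  hi <- rec[1, ]
  for (mcol in c("shdi", "shei", "division", "iji", "contag", "frac_am"))
    hi[[mcol]] <- max(rec[[mcol]], na.rm = TRUE) + 1
  lo <- hi; for (mcol in c("shdi", "shei", "division", "iji", "contag",
                           "frac_am")) lo[[mcol]] <- -1
  out2 <- suppressMessages(organization_index(dplyr::bind_rows(rec, hi, lo)))
  expect_equal(out2$eo[21], 1, tolerance = 5e-4)
  expect_equal(out2$eo[22], 0, tolerance = 1e-12)

  # nested mode re-applies the group weights: EO_nested = 0.3001*LC +
  # 0.4366*LH + 0.2633*IC with the same sub-weighted terms
  flat <- suppressMessages(organization_index(rec, "flat"))
  nest <- suppressMessages(organization_index(rec, "nested"))
  w <- eo_weights()
  lc <- w$shdi * flat$shdi_n + w$shei * flat$shei_n
  lh <- w$division * flat$division_n + w$iji * flat$iji_n +
    w$contag * flat$contag_n
  ic <- w$frac_am * flat$frac_am_n
  expect_equal(nest$eo, 0.3001 * lc + 0.4366 * lh + 0.2633 * ic)
  expect_false(isTRUE(all.equal(nest$eo, flat$eo)))

  # constant metric normalizes to 0.5 with a warning
  rec$shdi <- 1
  expect_warning(suppressMessages(organization_index(rec)), "constant")
})
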