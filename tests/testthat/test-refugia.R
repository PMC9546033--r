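test_that("projection reproduces training-point scores on the training landscape", {
  land <- make_small_world(seed = 53, n = 25)
  sp <- true_species(p_bad_accuracy = 0, p_old_year = 0,
                     p_wrong_season = 0, p_bad_habitat = 0)
  recs <- simulate_occurrences(sp, land, 600, seed = 17)
  th <- thin_to_cells(recs, land$grid)
  bg <- buffer_background(th$presences, n_points = 600,
                          grid = land$grid, seed = 18)
  # background-mean bio1 for all points so raster and SWD values agree
  swd <- extract_swd(th$presences, bg, land$predictors, NULL, land$grid)
  m <- maxent(swd, rm = 0.5)
  suit <- project_suitability(
    m, list(bio1 = land$climate$bio1_mean, bio7 = land$climate$bio7,
            bio12 = land$climate$bio12, bio15 = land$climate$bio15),
    land$predictors)
  at_points <- extract_at(suit, swd$x, swd$y)
  expect_equal(at_points, predict(m, swd, type = "cloglog"),
               tolerance = 1e-12)
  expect_true(all(suit$values > 0 & suit$values < 1))
  expect_error(project_suitability(m, list(), list()), "bio1")
})

test_that("clamping only changes predictions outside the training range", {
  df <- data.frame(class = rep(c("presence", "background"), c(5, 20)),
                   v = seq(0, 1, length.out = 25))
  m <- maxent(df, vars = "v", rm = 0.5)
  inside <- data.frame(v = c(0.2, 0.8))
  outside <- data.frame(v = c(-0.5, 1.5))
  expect_equal(predict(m, inside, clamp = TRUE),
               predict(m, inside, clamp = FALSE))
  if (m$k > 0)
    expect_false(isTRUE(all.equal(predict(m, outside, clamp = TRUE),
                                  predict(m, outside, clamp = FALSE))))
})

test_that("binarization is strict and extent counts suitable cells", {
  g <- grid_spec(0, 1000, 1000, 1, 3)
  suit <- raster_layer(g, "s", matrix(c(0.1, 0.19, 0.5), 1, 3))
  expect_equal(as.vector(binarize(suit, 0.19)$values),
               c(FALSE, FALSE, TRUE))
  expect_equal(as.vector(binarize(suit, 0)$values), rep(TRUE, 3))
  expect_equal(as.vector(binarize(suit, 1)$values), rep(FALSE, 3))
  g10 <- grid_spec(0, 10000, 1000, 10, 10)
  expect_equal(extent_km2(make_toy_mask(g10, TRUE)), 100)
  expect_equal(extent_km2(make_toy_mask(g10, FALSE)), 0)
  checker <- outer(1:10, 1:10, function(i, j) (i + j) %% 2 == 0)
  expect_equal(extent_km2(make_toy_mask(g10, checker)), 50)
})

test_that("mean elevation averages over suitable cells only", {
  g <- grid_spec(0, 2000, 1000, 2, 1)
  elev <- raster_layer(g, "elevation", matrix(c(2000, 2400), 2, 1))
  expect_equal(mean_elevation(make_toy_mask(g, c(TRUE, FALSE)), elev),
               2000)
  expect_equal(mean_elevation(make_toy_mask(g, c(TRUE, TRUE)), elev),
               2200)
  expect_warning(out <- mean_elevation(make_toy_mask(g, FALSE), elev),
                 "empty")
  expect_true(is.na(out))
})

test_that("refugia codes match the definitions over all suitability combinations", {
  g <- grid_spec(0, 32000, 1000, 32, 1)
  combos <- expand.grid(cur = c(FALSE, TRUE), f1 = c(FALSE, TRUE),
                        f2 = c(FALSE, TRUE), f3 = c(FALSE, TRUE),
                        f4 = c(FALSE, TRUE))
  cur <- make_toy_mask(g, combos$cur)
  futs <- lapply(paste0("f", 1:4), function(f)
    make_toy_mask(g, combos[[f]]))
  ref <- classify_refugia(cur, futs, species = "toy")
  nfut <- rowSums(combos[paste0("f", 1:4)])
  expected <- ifelse(combos$cur & nfut == 4, 1L,
                     ifelse(!combos$cur & nfut == 4, 2L,
                            ifelse(!combos$cur & nfut == 3, 3L, 0L)))
  expect_equal(as.vector(ref$values), expected)
  # spot checks mirroring the published definitions
  expect_equal(expected[combos$cur & nfut == 4][1], 1L)  # always suitable
  expect_equal(expected[!combos$cur & nfut == 3][1], 3L)
  expect_equal(expected[combos$cur & nfut == 3][1], 0L)  # no code
  expect_error(classify_refugia(cur, futs[1:3]), "exactly 4")
})

test_that("refugia invariants hold on a synthetic warming experiment", {
  land <- make_small_world(seed = 59, n = 30)
  sp <- true_species(linear = c(bio1 = -2), quadratic = c(bio1 = -0.8),
                     p_bad_accuracy = 0, p_old_year = 0,
                     p_wrong_season = 0, p_bad_habitat = 0)
  recs <- simulate_occurrences(sp, land, 1200, seed = 19)
  th <- thin_to_cells(recs, land$grid)
  bg <- buffer_background(th$presences, n_points = 1200,
                          grid = land$grid, seed = 20)
  swd <- extract_swd(th$presences, bg, land$predictors,
                     land$climate$bio1_by_year, land$grid)
  m <- maxent(swd, rm = 0.5)
  tau <- percentile_threshold(
    predict(m, swd[swd$class == "presence", ], type = "cloglog"), 10)
  clim <- function(d) list(
    bio1 = raster_layer(land$grid, "bio1",
                        land$climate$bio1_mean$values + d),
    bio7 = land$climate$bio7, bio12 = land$climate$bio12,
    bio15 = land$climate$bio15)
  masks <- lapply(c(0, 1, 2, 3, 4), function(d)
    binarize(project_suitability(m, clim(d), land$predictors), tau))
  ext <- vapply(masks, extent_km2, 0)
  expect_true(all(diff(ext) <= 0))
  elevs <- vapply(masks, mean_elevation, 0, elevation = land$elevation)
  expect_true(all(diff(elevs) >= -1e-9))
  # refugia classification consistency on the four warmed conditions
  ref <- classify_refugia(masks[[1]], masks[2:5])
  cur <- masks[[1]]$values
  expect_true(all(ref$values[!cur] != 1L))
  expect_true(all(ref$values[cur] %in% c(0L, 1L)))
  t1 <- raster_layer(land$grid, "t1", ref$values == 1L)
  expect_lte(extent_km2(t1), extent_km2(masks[[1]]))
})

test_that("multispecies refugia count per-cell type-1 membership", {
  g <- grid_spec(0, 1000, 1000, 1, 4)
  m1 <- make_toy_mask(g, c(TRUE, TRUE, FALSE, FALSE))
  m2 <- make_toy_mask(g, c(TRUE, TRUE, TRUE, FALSE))
  m3 <- make_toy_mask(g, c(TRUE, FALSE, TRUE, FALSE))
  m4 <- make_toy_mask(g, c(TRUE, TRUE, TRUE, TRUE))
  out <- multispecies_refugia(list(m1, m2, m3, m4), min_species = 3)
  expect_equal(as.vector(out$values), c(TRUE, TRUE, TRUE, FALSE))
  # identical masks reproduce themselves; 2 species < 3 fails the count
  same <- multispecies_refugia(list(m4, m4, m4, m4), min_species = 3)
  expect_equal(same$values, m4$values)
  two <- multispecies_refugia(list(m1, m1, m3, m3), min_species = 3)
  expect_equal(as.vector(two$values), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("change summaries reproduce the published worked examples", {
  tab <- read.csv(system.file("extdata", "alpine_extent_km2.csv",
                              package = "refugium"),
                  check.names = FALSE)
  rp <- tab[tab$species == "rock ptarmigan", ]
  cs <- change_summary(rp$current,
                       unlist(rp[c("GFDL-ESM4", "IPSL-CM6A-LR",
                                   "MRI-ESM2-0", "UKESM1-0-LL")]))
  expect_equal(round(attr(cs, "mean_pct_change"), 1), -35.7)
  wp <- tab[tab$species == "water pipit", ]
  cs_wp <- change_summary(wp$current,
                          unlist(wp[c("GFDL-ESM4", "IPSL-CM6A-LR",
                                      "MRI-ESM2-0", "UKESM1-0-LL")]))
  expect_equal(round(attr(cs_wp, "mean_pct_change"), 1), 2.1)
  # no change when futures equal current
  cs0 <- change_summary(100, c(a = 100, b = 100, c = 100, d = 100))
  expect_true(all(cs0$pct_change == 0))
  expect_equal(attr(cs0, "mean_pct_change"), 0)
  # zero current extent signals invalid percentages
  expect_warning(bad <- change_summary(0, c(a = 10)), "zero")
  expect_true(is.na(bad$pct_change))
})

test_that("change summary accepts masks with an elevation layer", {
  g <- grid_spec(0, 2000, 1000, 2, 2)
  elev <- raster_layer(g, "elevation",
                       matrix(c(1000, 2000, 3000, 4000), 2, 2))
  cur <- make_toy_mask(g, c(TRUE, TRUE, TRUE, FALSE))
  fut <- list(w1 = make_toy_mask(g, c(FALSE, TRUE, TRUE, FALSE)),
              w2 = make_toy_mask(g, c(FALSE, FALSE, TRUE, FALSE)))
  cs <- change_summary(cur, fut, elev)
  expect_equal(attr(cs, "current_extent_km2"), 3)
  expect_equal(cs$extent_km2, c(2, 1))
  expect_equal(cs$pct_change, 100 * c(2 - 3, 1 - 3) / 3)
  expect_equal(cs$mean_elev_m, c(2500, 3000))
  expect_equal(cs$elev_shift_m, c(500, 1000))
})
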