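test_that("slope is zero on flat terrain and 45 degrees on a unit plane", {
  flat <- matrix(500, 8, 8)
  expect_equal(refugium:::slope_from_elevation(flat, 1000)$slope_deg,
               matrix(0, 8, 8))
  # elevation rising 1000 m per 1000 m in x
  plane <- matrix(rep((0:7) * 1000, each = 8), 8, 8)
  sl <- refugium:::slope_from_elevation(plane, 1000)$slope_deg
  expect_equal(sl[2:7, 2:7], matrix(45, 6, 6))
})

test_that("terrain generation is deterministic and validates the grid", {
  g <- grid_spec(0, 30000, 1000, 30, 30)
  a <- generate_terrain(g, seed = 5)
  b <- generate_terrain(g, seed = 5)
  expect_identical(a$elevation$values, b$elevation$values)
  expect_identical(a$solar_med$values, b$solar_med$values)
  expect_false(identical(a$elevation$values,
                         generate_terrain(g, seed = 6)$elevation$values))
  expect_true(all(a$elevation$values >= 0))
  expect_true(all(a$slope$values >= 0 & a$slope$values < 90))
  expect_error(generate_terrain(grid_spec(0, 1000, 1000, 1, 1)),
               "grid too small for slope")
})

test_that("temperature follows the elevational lapse rate exactly when noiseless", {
  g <- grid_spec(0, 2000, 1000, 2, 1)
  elev <- raster_layer(g, "elevation", matrix(c(0, 2000), 2, 1))
  cl <- generate_climate(elev, lapse_rate = -6.5, sea_level_temp = 10,
                         years = 2005, noise_sd = 0, year_sd = 0,
                         seed = 1)
  expect_equal(cl$bio1_mean$values[1, 1] - cl$bio1_mean$values[2, 1],
               13.0)
  # single year, no noise: the yearly layer equals the background mean
  expect_equal(cl$bio1_by_year[["2005"]]$values, cl$bio1_mean$values)
  expect_error(generate_climate(elev, years = integer(0)), "empty")
})

test_that("bio1_mean is the cell-wise mean of the yearly layers and cools with elevation", {
  land <- make_small_world(seed = 11, n = 30)
  stack <- sapply(land$climate$bio1_by_year, function(l)
    as.vector(l$values))
  expect_equal(rowMeans(stack), as.vector(land$climate$bio1_mean$values),
               tolerance = 1e-12)
  expect_lt(cor(as.vector(land$climate$bio1_mean$values),
                as.vector(land$elevation$values)), 0)
})

test_that("a configured warming trend is recovered by regression on year", {
  g <- grid_spec(0, 20000, 1000, 20, 20)
  elev <- raster_layer(g, "elevation", matrix(1500, 20, 20))
  years <- 2000:2019
  cl <- generate_climate(elev, years = years, noise_sd = 0.3,
                         trend_per_year = 0.03, year_sd = 0.1, seed = 3)
  means <- vapply(cl$bio1_by_year, function(l) mean(l$values), 0)
  fit <- summary(lm(means ~ years))$coefficients
  expect_lt(abs(fit["years", "Estimate"] - 0.03),
            2 * fit["years", "Std. Error"])
})

test_that("future conditions shift exactly the four climate layers", {
  land <- make_small_world(seed = 13, n = 20)
  zero <- future_condition("none", c(bio1 = 0, bio7 = 0, bio12 = 0,
                                     bio15 = 0))
  fut0 <- generate_future(land$climate, list(none = zero))$none
  expect_equal(fut0$bio1$values, land$climate$bio1_mean$values)
  expect_equal(fut0$bio12$values, land$climate$bio12$values)
  warm <- future_condition("warm", c(bio1 = 2.54, bio7 = 0, bio12 = 0,
                                     bio15 = 0))
  futw <- generate_future(land$climate, list(warm = warm))$warm
  expect_equal(mean(futw$bio1$values) - mean(land$climate$bio1_mean$values),
               2.54, tolerance = 1e-12)
  expect_error(future_condition("bad", c(bio1 = 1, bio7 = 0, bio12 = 0)),
               "bio15")
})

test_that("land-cover fractions form a sub-simplex with alpine zonation", {
  land <- make_small_world(seed = 17, n = 40)
  fr <- sapply(land$landcover, function(l) as.vector(l$values))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(rowSums(fr) <= 1 + 1e-9))
  elev <- as.vector(land$elevation$values)
  # forest classes vanish above the treeline
  high <- elev > 2000
  forest <- rowSums(fr[, c("lc311", "lc312", "lc313", "lc324")])
  expect_true(all(forest[high] == 0))
  open <- rowSums(fr[, c("lc321", "lc332")])
  expect_gt(cor(elev, open, method = "spearman"), 0)
})

test_that("protected areas and countries satisfy their contracts", {
  g <- grid_spec(0, 30000, 1000, 30, 30)
  none <- generate_pa_countries(g, n_pa = 0, n_countries = 1, seed = 1)
  expect_true(all(none$pa_mask$values == 0))
  expect_true(all(none$country_raster$values == 1))
  some <- generate_pa_countries(g, n_pa = 10, n_countries = 4, seed = 2)
  ids <- setdiff(unique(as.vector(some$pa_mask$values)), 0)
  expect_true(all(ids %in% some$pa_table$pa_id))
  expect_true(all(some$country_raster$values %in% 1:4))
  expect_true(all(some$pa_table$iucn_category %in% c(1:4, NA)))
})

test_that("occurrence sampling follows the true intensity", {
  land <- make_small_world(seed = 19, n = 20)
  expect_equal(nrow(simulate_occurrences(true_species(), land, 0)), 0)
  # one huge coefficient concentrates all records in the best cell
  spike <- true_species(linear = c(bio1 = -1e6), quadratic = NULL,
                        p_bad_accuracy = 0, p_old_year = 0,
                        p_wrong_season = 0, p_bad_habitat = 0)
  tru <- true_suitability(spike, land)
  best <- which(tru$values == max(tru$values), arr.ind = TRUE)
  recs <- simulate_occurrences(spike, land, 50, seed = 4)
  idx <- cell_of(recs$x, recs$y, land$grid)
  expect_true(all(idx$row == best[1, "row"] & idx$col == best[1, "col"]))
  # near-uniform intensity: per-cell counts consistent with multinomial
  flat <- true_species(linear = c(bio1 = 1e-9), quadratic = NULL,
                       p_bad_accuracy = 0, p_old_year = 0,
                       p_wrong_season = 0, p_bad_habitat = 0)
  recs <- simulate_occurrences(flat, land, 20000, seed = 5)
  idx <- cell_of(recs$x, recs$y, land$grid)
  counts <- tabulate(idx$cell, nbins = 400)
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("empirical cell frequencies converge to the normalized intensity", {
  land <- make_small_world(seed = 23, n = 20)
  sp <- true_species(linear = c(bio1 = -1.5), quadratic = c(bio1 = -0.5),
                     p_bad_accuracy = 0, p_old_year = 0,
                     p_wrong_season = 0, p_bad_habitat = 0)
  tru <- as.vector(true_suitability(sp, land)$values)
  recs <- simulate_occurrences(sp, land, 1e5, seed = 6)
  idx <- cell_of(recs$x, recs$y, land$grid)
  emp <- tabulate(idx$cell, nbins = 400) / 1e5
  expect_lt(sum(abs(emp - tru)) / 2, 0.05)
})

test_that("degenerate intensity is rejected", {
  land <- make_small_world(seed = 29, n = 10)
  sp <- true_species(linear = c(bio1 = -1))
  tru_bad <- land
  tru_bad$predictors$bio1$values[] <- NA
  expect_error(simulate_occurrences(sp, tru_bad, 10), "degenerate")
})
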