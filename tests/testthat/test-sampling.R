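test_that("background points stay within the presence buffers", {
  g <- grid_spec(0, 20000, 1000, 20, 20)
  pres <- data.frame(x = 10000, y = 10000)
  bg <- buffer_background(pres, radius_m = 2000, n_points = 500,
                          grid = g, seed = 1)
  expect_equal(nrow(bg), 500)
  expect_true(all(sqrt((bg$x - 10000)^2 + (bg$y - 10000)^2) <= 2000))
  # multi-presence support constraint
  pres2 <- data.frame(x = c(3000, 15000), y = c(3000, 15000))
  bg2 <- buffer_background(pres2, radius_m = 2000, n_points = 2000,
                           grid = g, seed = 2)
  dmin <- pmin(sqrt((bg2$x - 3000)^2 + (bg2$y - 3000)^2),
               sqrt((bg2$x - 15000)^2 + (bg2$y - 15000)^2))
  expect_lte(max(dmin), 2000)
})

test_that("background is uniform over the union of equal disjoint buffers", {
  g <- grid_spec(0, 40000, 1000, 40, 40)
  pres <- data.frame(x = c(10000, 30000), y = c(20000, 20000))
  n <- 50000
  bg <- buffer_background(pres, radius_m = 2000, n_points = n,
                          grid = g, seed = 3)
  in_first <- sqrt((bg$x - 10000)^2 + (bg$y - 20000)^2) <= 2000
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(sum(in_first), ci[1])
  expect_lte(sum(in_first), ci[2])
  # reproducible under a fixed seed
  bg_again <- buffer_background(pres, radius_m = 2000, n_points = n,
                                grid = g, seed = 3)
  expect_identical(bg, bg_again)
})

test_that("checkerboard-2 labels follow the two-scale parity formula", {
  g <- grid_spec(0, 64000, 1000, 64, 64)
  # origin corner cell: both parities zero
  expect_equal(checkerboard2_assign(data.frame(x = 10, y = 63990), g), 1L)
  # c1 = 4000: x = 500 vs 4500 near the top differ in fine parity only
  labs <- checkerboard2_assign(data.frame(x = c(500, 4500),
                                          y = c(63990, 63990)), g)
  expect_equal(labs, c(1L, 2L))
  # translation periodicity with period 2*c2 = 16 km
  set.seed(4)
  pts <- data.frame(x = runif(200, 0, 48000), y = runif(200, 16000, 64000))
  shifted <- data.frame(x = pts$x + 16000, y = pts$y - 16000)
  expect_equal(checkerboard2_assign(pts, g),
               checkerboard2_assign(shifted, g))
})

test_that("checkerboard partitions tile the plane in equal measure", {
  g <- grid_spec(0, 1e5, 1000, 100, 100)
  set.seed(5)
  pts <- data.frame(x = runif(1e5, 0, 1e5), y = runif(1e5, 0, 1e5))
  tab <- table(checkerboard2_assign(pts, g)) / 1e5
  expect_length(tab, 4)
  expect_true(all(abs(tab - 0.25) < 0.01))
})

test_that("train/test split holds out exactly the chosen partition", {
  swd <- data.frame(point_id = 1:8, species = "s",
                    x = 1:8, y = 1:8,
                    class = rep(c("presence", "background"), 4),
                    partition = rep(1:4, each = 2),
                    year = NA_integer_, v = rnorm(8))
  class(swd) <- c("swd", "data.frame")
  parts <- split_train_test(swd, test_partition = 4)
  expect_equal(parts$test$point_id, 7:8)
  expect_equal(parts$train$point_id, 1:6)
  expect_equal(sort(c(parts$train$point_id, parts$test$point_id)),
               swd$point_id)
  bad <- swd
  bad$class[bad$partition == 4] <- "background"
  expect_error(split_train_test(bad, 4), "zero presences")
})

test_that("SWD extraction reads the containing cell and per-year bio1", {
  g <- grid_spec(0, 3000, 1000, 3, 3)
  base <- matrix(1:9, 3, 3)
  bio1 <- raster_layer(g, "bio1", base)
  other <- raster_layer(g, "slope", base * 10)
  bio1_y <- list(`2010` = raster_layer(g, "bio1", base + 1))
  pres <- data.frame(species = "s", x = 1500, y = 1500, year = 2010)
  bg <- data.frame(x = c(1500, 2500), y = c(1500, 500))
  swd <- extract_swd(pres, bg, list(bio1 = bio1, slope = other),
                     bio1_y, g)
  # presence and co-located background differ by the +1 year offset
  expect_equal(swd$bio1[swd$class == "presence"], base[2, 2] + 1)
  expect_equal(swd$bio1[swd$class == "background"][1], base[2, 2])
  expect_equal(swd$slope[swd$class == "background"][2], base[3, 3] * 10)
  # missing year layer is an error naming the year
  pres99 <- data.frame(species = "s", x = 1500, y = 1500, year = 1999)
  expect_error(extract_swd(pres99, bg, list(bio1 = bio1, slope = other),
                           bio1_y, g), "1999")
  # nodata rows are dropped and logged
  holed <- base; holed[3, 3] <- NA
  swd2 <- extract_swd(pres, bg,
                      list(bio1 = bio1,
                           slope = raster_layer(g, "slope", holed)),
                      bio1_y, g)
  expect_equal(nrow(swd2), 2)
  expect_equal(attr(swd2, "dropped")$reason, "nodata")
})

test_that("collinearity screening honours the threshold exactly", {
  set.seed(6)
  n <- 2000
  a <- rnorm(n)
  make_cor <- function(r) r * a + sqrt(1 - r^2) * rnorm(n)
  swd <- data.frame(point_id = 1:n, species = "s", x = 0, y = 0,
                    class = "background", partition = 1,
                    year = NA_integer_, a = a, dup = a,
                    ind = rnorm(n))
  class(swd) <- c("swd", "data.frame")
  out <- collinearity_check(swd)
  expect_false(out$pass)
  expect_true(any(out$failing_pairs$var1 == "a" &
                    out$failing_pairs$var2 == "dup"))
  # independent noise passes
  swd2 <- swd; swd2$dup <- rnorm(n)
  expect_true(collinearity_check(swd2)$pass)
  # |r| = 0.69 passes, 0.71 fails (exact threshold semantics)
  expect_false(collinearity_check(swd, threshold = 0.99)$pass)  # r = 1
  e <- resid(lm(make_cor(0) ~ a))
  with_r <- function(r) {
    s <- swd
    s$dup <- r * scale(a)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
    collinearity_check(s, threshold = 0.7)
  }
  expect_equal(max(abs(with_r(0.69)$correlations$r)), 0.69,
               tolerance = 1e-10)
  expect_true(with_r(0.69)$pass)
  expect_false(with_r(0.71)$pass)
})

test_that("zero-variance predictors are flagged and excluded", {
  swd <- data.frame(point_id = 1:10, species = "s", x = 0, y = 0,
                    class = "background", partition = 1,
                    year = NA_integer_, a = rnorm(10), b = 1,
                    c = rnorm(10))
  class(swd) <- c("swd", "data.frame")
  out <- collinearity_check(swd)
  expect_equal(out$zero_variance, "b")
  expect_false("b" %in% c(out$correlations$var1, out$correlations$var2))
})

test_that("SWD CSV round trip preserves the table", {
  land <- make_small_world(seed = 43, n = 15)
  sp <- true_species(p_bad_accuracy = 0, p_old_year = 0,
                     p_wrong_season = 0, p_bad_habitat = 0)
  recs <- simulate_occurrences(sp, land, 300, seed = 11)
  th <- thin_to_cells(recs, land$grid)
  bg <- buffer_background(th$presences, n_points = 300,
                          grid = land$grid, seed = 12)
  swd <- extract_swd(th$presences, bg, land$predictors,
                     land$climate$bio1_by_year, land$grid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_swd(swd, path)
  back <- read_swd(path)
  expect_equal(swd_predictors(back), swd_predictors(swd))
  expect_equal(back$bio1, swd$bio1, tolerance = 1e-10)
  expect_equal(back$partition, swd$partition)
})
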