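#' @title Synthetic alpine landscape generator
#' @description Seeded generators for a synthetic alpine world on a 1-km
#'   projected grid: terrain, lapse-rate climate with per-year temperature
#'   layers, CORINE-like fractional land cover, protected areas, countries,
#'   and citizen-science style occurrence records drawn from a known
#'   ground-truth species.  Every generator is deterministic given its seed,
#'   so the full modelling pipeline can be exercised and tested without any
#'   external data download.
#' @name synthetic-landscape
NULL

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Smoothed Gaussian random field via FFT circular convolution of white noise
# with a Gaussian kernel; standardized to mean 0, sd 1.  range_cells sets the
# kernel sd (spatial correlation length) in cells.
smooth_field <- function(nr, nc, range_cells = 10) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells <= 0) return(z)
  di <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dj <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  k <- exp(-outer(di^2, dj^2, "+") / (2 * range_cells^2))
  k <- k / sum(k)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate synthetic terrain (elevation, slope, solar radiation index)
#'
#' Elevation is a seeded smoothed random field (spectral smoothing of white
#' noise) rescaled to an alpine relief; slope is computed from central
#' differences of elevation, and the solar radiation index is a smooth field
#' driven by slope orientation (south-facing steep slopes score high).
#'
#' @param grid a [grid_spec()]; must be at least 2 x 2.
#' @param relief_params list with `mean_elev` (m), `relief_sd` (m) and
#'   `range_km` (correlation length of the terrain field).
#' @param seed integer RNG seed.
#' @return list of [raster_layer()]s: `elevation` (m asl, >= 0), `slope`
#'   (degrees, in `[0, 90)`), `solar_med` (unitless index in `[0, 1]`).
#' @export
generate_terrain <- function(grid,
                             relief_params = list(mean_elev = 1500,
                                                  relief_sd = 800,
                                                  range_km = 15),
                             seed = 1) {
  if (grid$n_rows < 2 || grid$n_cols < 2) stop("grid too small for slope")
  elev_m <- with_seed(seed, {
    z <- smooth_field(grid$n_rows, grid$n_cols,
                      relief_params$range_km * 1000 / grid$cell_size)
    pmax(relief_params$mean_elev + relief_params$relief_sd * z, 0)
  })
  slopes <- slope_from_elevation(elev_m, grid$cell_size)
  list(elevation = raster_layer(grid, "elevation", elev_m),
       slope = raster_layer(grid, "slope", slopes$slope_deg),
       solar_med = raster_layer(grid, "solar_med", slopes$solar))
}

# Central differences in the interior, one-sided at edges.  y axis points
# up, row 1 is north, so dz/dy uses row i-1 minus row i+1.
slope_from_elevation <- function(elev, cell_size) {
  nr <- nrow(elev); nc <- ncol(elev)
  dzdx <- matrix(0, nr, nc); dzdy <- matrix(0, nr, nc)
  if (nc >= 3)
    dzdx[, 2:(nc - 1)] <- (elev[, 3:nc] - elev[, 1:(nc - 2)]) /
      (2 * cell_size)
  dzdx[, 1] <- (elev[, 2] - elev[, 1]) / cell_size
  dzdx[, nc] <- (elev[, nc] - elev[, nc - 1]) / cell_size
  if (nr >= 3)
    dzdy[2:(nr - 1), ] <- (elev[1:(nr - 2), ] - elev[3:nr, ]) /
      (2 * cell_size)
  dzdy[1, ] <- (elev[1, ] - elev[2, ]) / cell_size
  dzdy[nr, ] <- (elev[nr - 1, ] - elev[nr, ]) / cell_size
  gmag <- sqrt(dzdx^2 + dzdy^2)
  slope_deg <- atan(gmag) * 180 / pi
  # southness = downhill direction pointing south; flat cells get 0.5
  southness <- ifelse(gmag > 0, dzdy / gmag, 0)
  solar <- 0.5 + 0.5 * sin(atan(gmag)) * southness
  list(slope_deg = slope_deg, solar = solar)
}

#' Generate lapse-rate climate layers with per-year temperature
#'
#' Annual mean temperature (`bio1`) follows a linear elevational lapse rate
#' plus a per-year anomaly (linear warming trend + interannual noise) and
#' smooth spatial noise.  The background layer `bio1_mean` is the exact
#' cell-wise mean of the per-year layers over the reference period,
#' mirroring the use of a multi-year background mean versus per-record-year
#' values.  `bio7`, `bio12` and `bio15` are smooth fields with moderate
#' elevation correlation (kept below the collinearity screening threshold).
#'
#' @param elevation elevation [raster_layer()] (m asl).
#' @param lapse_rate degrees C per km of elevation gain; must be negative.
#' @param sea_level_temp degrees C at 0 m.
#' @param years integer vector of reference-period years (default
#'   2000:2019).
#' @param noise_sd sd (degrees C) of the smooth spatial noise added to each
#'   yearly layer.
#' @param trend_per_year warming trend (degrees C / yr) across the period
#'   (default 0: interannual anomalies are mean-zero; see the vignette for
#'   why a common-mode trend interacts with most-recent-year cell
#'   deduplication).
#' @param year_sd sd of the scalar interannual anomaly.
#' @param seed integer RNG seed.
#' @return list with `bio1_mean`, `bio7`, `bio12`, `bio15`
#'   ([raster_layer()]s) and `bio1_by_year` (named list of layers, one per
#'   year).
#' @export
generate_climate <- function(elevation, lapse_rate = -6.5,
                             sea_level_temp = 14, years = 2000:2019,
                             noise_sd = 0.3, trend_per_year = 0,
                             year_sd = 0.15, seed = 1) {
  stopifnot(lapse_rate < 0)
  if (length(years) == 0) stop("years list is empty")
  grid <- elevation$grid
  elev <- elevation$values
  nr <- grid$n_rows; nc <- grid$n_cols
  rng_cells <- max(2, 10000 / grid$cell_size)
  with_seed(seed, {
    base <- sea_level_temp + lapse_rate * elev / 1000
    by_year <- lapply(seq_along(years), function(k) {
      anom <- trend_per_year * (years[k] - mean(years)) +
        stats::rnorm(1, 0, year_sd)
      noise <- if (noise_sd > 0)
        noise_sd * smooth_field(nr, nc, rng_cells) else 0
      base + anom + noise
    })
    names(by_year) <- as.character(years)
    bio1_mean <- Reduce(`+`, by_year) / length(by_year)
    bio7 <- 22 + 0.0005 * elev + 2.5 * smooth_field(nr, nc, rng_cells)
    bio12 <- pmax(900 + 0.1 * elev +
                    180 * smooth_field(nr, nc, rng_cells), 100)
    bio15 <- pmax(30 - 0.002 * elev +
                    5 * smooth_field(nr, nc, rng_cells), 1)
    list(bio1_mean = raster_layer(grid, "bio1", bio1_mean),
         bio1_by_year = lapply(stats::setNames(names(by_year),
                                               names(by_year)),
                               function(y) raster_layer(grid, "bio1",
                                                        by_year[[y]])),
         bio7 = raster_layer(grid, "bio7", bio7),
         bio12 = raster_layer(grid, "bio12", bio12),
         bio15 = raster_layer(grid, "bio15", bio15))
  })
}

#' Define a future climate condition
#'
#' @param condition_id label, e.g. a GCM name such as `"MRI-ESM2-0"`.
#' @param deltas named numeric vector of additive changes; must contain all
#'   of `bio1`, `bio7`, `bio12`, `bio15`.
#' @return object of class `future_condition`.
#' @export
future_condition <- function(condition_id, deltas) {
  need <- c("bio1", "bio7", "bio12", "bio15")
  miss <- setdiff(need, names(deltas))
  if (length(miss))
    stop("missing delta for variable(s): ", paste(miss, collapse = ", "))
  structure(list(condition_id = condition_id,
                 deltas = deltas[need]), class = "future_condition")
}

#' Default set of four future climate conditions
#'
#' Two 'colder' and two 'warmer' conditions spanning the range of
#' mid-century (2041-2070) high-emission temperature anomalies over the
#' Alps: +2.54 degrees C for the mildest model (MRI-ESM2-0) and +4.19 for
#' the most extreme (UKESM1-0-LL), relative to the 2000-2019 reference,
#' with the other two models intermediate.
#'
#' @return named list of four [future_condition()]s.
#' @export
default_future_conditions <- function() {
  mk <- function(id, dt) future_condition(id, c(bio1 = dt, bio7 = 0.5,
                                                bio12 = -40, bio15 = 2))
  list(`GFDL-ESM4` = mk("GFDL-ESM4", 3.1),
       `IPSL-CM6A-LR` = mk("IPSL-CM6A-LR", 3.6),
       `MRI-ESM2-0` = mk("MRI-ESM2-0", 2.54),
       `UKESM1-0-LL` = mk("UKESM1-0-LL", 4.19))
}

#' Build future climate stacks from current climate plus deltas
#'
#' Exactly the four climate variables are replaced (`bio1` from the
#' background mean layer); non-climate layers are left untouched by
#' construction, mirroring projections that hold land cover and topography
#' constant.
#'
#' @param current_climate output of [generate_climate()].
#' @param conditions list of [future_condition()]s.
#' @return named list (by condition id) of lists with `bio1`, `bio7`,
#'   `bio12`, `bio15` [raster_layer()]s.
#' @export
generate_future <- function(current_climate,
                            conditions = default_future_conditions()) {
  out <- lapply(conditions, function(cond) {
    if (!inherits(cond, "future_condition"))
      cond <- do.call(future_condition, cond)
    g <- current_climate$bio1_mean$grid
    shift <- function(layer, nm)
      raster_layer(g, nm, layer$values + cond$deltas[[nm]])
    list(bio1 = shift(current_climate$bio1_mean, "bio1"),
         bio7 = shift(current_climate$bio7, "bio7"),
         bio12 = shift(current_climate$bio12, "bio12"),
         bio15 = shift(current_climate$bio15, "bio15"))
  })
  names(out) <- vapply(conditions, function(cond)
    if (inherits(cond, "future_condition")) cond$condition_id
    else cond$condition_id, "")
  out
}

#' Generate CORINE-like fractional land-cover layers
#'
#' Per-cell fractions for ten land-cover classes (broad-leaved, coniferous
#' and mixed forest, transitional woodland-shrub, pastures, natural
#' grassland, moors, bare rocks, sparsely vegetated, glaciers) driven by
#' elevation bands with smooth random variation.  Forest classes taper
#' linearly to zero at the treeline and are exactly zero above it;
#' grassland, rock and sparse-vegetation fractions increase above the
#' treeline.  Fractions are non-negative and sum to at most 1 per cell.
#'
#' @param elevation elevation [raster_layer()].
#' @param treeline_m treeline elevation (m; default 2000).
#' @param seed integer RNG seed.
#' @param coverage total fraction allotted to the modelled classes
#'   (remainder is unmodelled cover such as urban/water).
#' @param wobble strength of the independent log-normal spatial variation
#'   multiplying each class weight; large enough by default that land
#'   cover is not collinear with temperature (pairwise |r| < 0.7).
#' @return named list of fractional [raster_layer()]s (`lc311` ... `lc335`).
#' @export
generate_landcover <- function(elevation, treeline_m = 2000, seed = 1,
                               coverage = 0.9, wobble = 1.6) {
  grid <- elevation$grid
  e <- elevation$values
  nr <- grid$n_rows; nc <- grid$n_cols
  bump <- function(center, width) exp(-((e - center) / width)^2)
  sigm <- function(center, width) 1 / (1 + exp(-(e - center) / width))
  taper <- pmin(1, pmax(0, (treeline_m - e) / 300))  # 0 at/above treeline
  with_seed(seed, {
    # strong independent spatial variation keeps land cover from being a
    # deterministic function of elevation, so the predictor set passes
    # the |r| < 0.7 collinearity screening applied before modelling
    wob <- function() exp(wobble * smooth_field(nr, nc, 6))
    w <- list(
      lc311 = taper * bump(700, 600) * wob(),
      lc312 = taper * bump(1600, 600) * wob(),
      lc313 = taper * bump(1150, 500) * wob(),
      lc324 = taper * bump(treeline_m - 200, 400) * wob(),
      lc231 = bump(900, 700) * wob(),
      lc321 = sigm(treeline_m - 100, 300) * bump(treeline_m + 350, 800) *
        wob(),
      lc322 = bump(treeline_m, 450) * 0.5 * wob(),
      lc332 = sigm(treeline_m + 600, 450) * wob(),
      lc333 = sigm(treeline_m + 100, 400) * bump(treeline_m + 600, 900) *
        wob(),
      lc335 = sigm(3000, 250) * wob())
    total <- Reduce(`+`, w)
    total[total < 1e-12] <- 1e-12
    lapply(stats::setNames(names(w), names(w)), function(nm)
      raster_layer(grid, nm, coverage * w[[nm]] / total))
  })
}

#' Generate a synthetic protected-area system and country partition
#'
#' Protected areas are random rectangular blocks of cells carrying a PA id
#' (later PAs overwrite earlier on overlap); each id has an IUCN category
#' (1-4 or NA) and a designation label in an attribute table.  Countries
#' partition all cells by nearest-seed (Voronoi) assignment.
#'
#' @param grid a [grid_spec()].
#' @param n_pa number of protected areas (>= 0).
#' @param n_countries number of countries (>= 1).
#' @param seed integer RNG seed.
#' @return list with `pa_mask` (integer [raster_layer()], 0 = unprotected),
#'   `pa_table` (data.frame `pa_id`, `iucn_category`, `designation`) and
#'   `country_raster` (integer [raster_layer()], values 1..n_countries).
#' @export
generate_pa_countries <- function(grid, n_pa = 25, n_countries = 7,
                                  seed = 1) {
  stopifnot(n_pa >= 0, n_countries >= 1)
  nr <- grid$n_rows; nc <- grid$n_cols
  designations <- c("Natura 2000 SCI/SAC", "Natura 2000 SPA",
                    "national park", "regional park",
                    "national forest reserve", "natural monument",
                    "national private nature reserve",
                    "landscape protection area")
  with_seed(seed, {
    pa <- matrix(0L, nr, nc)
    if (n_pa > 0) {
      for (id in seq_len(n_pa)) {
        ci <- sample.int(nr, 1); cj <- sample.int(nc, 1)
        hi <- sample(2:max(2, nr %/% 10), 1)
        hj <- sample(2:max(2, nc %/% 10), 1)
        rows <- max(1, ci - hi):min(nr, ci + hi)
        cols <- max(1, cj - hj):min(nc, cj + hj)
        pa[rows, cols] <- id
      }
    }
    pa_table <- data.frame(
      pa_id = seq_len(n_pa),
      iucn_category = if (n_pa > 0)
        sample(c(1:4, NA), n_pa, replace = TRUE,
               prob = c(.1, .25, .15, .2, .3)) else integer(0),
      designation = if (n_pa > 0)
        sample(designations, n_pa, replace = TRUE) else character(0),
      stringsAsFactors = FALSE)
    seeds_i <- sample.int(nr, n_countries, replace = n_countries > nr)
    seeds_j <- sample.int(nc, n_countries, replace = n_countries > nc)
    ii <- matrix(seq_len(nr), nr, nc)
    jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d2 <- lapply(seq_len(n_countries), function(k)
      (ii - seeds_i[k])^2 + (jj - seeds_j[k])^2)
    country <- matrix(max.col(-do.call(cbind, lapply(d2, as.vector)),
                              ties.method = "first"), nr, nc)
    list(pa_mask = raster_layer(grid, "pa_mask", pa),
         pa_table = pa_table,
         country_raster = raster_layer(grid, "country", country))
  })
}

#' Define a ground-truth species for simulation
#'
#' The true species has a log-linear suitability with linear and quadratic
#' terms on standardized predictors; occurrence records are drawn with
#' probability proportional to `exp(score)` per cell.  Metadata noise rates
#' give the fraction of records independently corrupted in each way the QC
#' filters must catch.
#'
#' @param name species label.
#' @param linear named numeric vector of linear coefficients on
#'   standardized predictors; at least one climate variable
#'   (`bio1`/`bio7`/`bio12`/`bio15`) must be nonzero.
#' @param quadratic named numeric vector of quadratic coefficients.
#' @param n_records expected record count used by convenience wrappers.
#' @param p_bad_accuracy,p_old_year,p_wrong_season,p_bad_habitat
#'   independent corruption probabilities in `[0, 1]`.
#' @return object of class `true_species`.
#' @export
true_species <- function(name = "synthetic alpine bird",
                         linear = c(bio1 = -1.5, lc321 = 0.8, lc332 = 0.5),
                         quadratic = c(bio1 = -0.5),
                         n_records = 5000,
                         p_bad_accuracy = 0.05, p_old_year = 0.05,
                         p_wrong_season = 0.05, p_bad_habitat = 0.05) {
  rates <- c(p_bad_accuracy, p_old_year, p_wrong_season, p_bad_habitat)
  stopifnot(all(rates >= 0), all(rates <= 1))
  clim <- intersect(names(linear)[linear != 0],
                    c("bio1", "bio7", "bio12", "bio15"))
  clim2 <- intersect(names(quadratic)[quadratic != 0],
                     c("bio1", "bio7", "bio12", "bio15"))
  if (length(clim) + length(clim2) == 0)
    stop("true species must have at least one nonzero climate coefficient")
  structure(list(name = name, linear = linear, quadratic = quadratic,
                 n_records = n_records,
                 p_bad_accuracy = p_bad_accuracy, p_old_year = p_old_year,
                 p_wrong_season = p_wrong_season,
                 p_bad_habitat = p_bad_habitat),
            class = "true_species")
}

# standardized predictor matrix (cells x variables) over a predictor list
standardize_predictors <- function(predictors, vars) {
  sapply(vars, function(v) {
    m <- predictors[[v]]$values
    mu <- mean(m, na.rm = TRUE); s <- stats::sd(m, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    as.vector((m - mu) / s)
  })
}

#' True suitability of a ground-truth species over a landscape
#'
#' Returns the normalized intensity `exp(score)/sum` as a raster; used as
#' the reference surface in parameter-recovery tests.
#'
#' @param species a [true_species()].
#' @param landscape a [synthetic_landscape()] (or any list with a
#'   `predictors` element of named [raster_layer()]s).
#' @return a [raster_layer()] of relative suitability.
#' @export
true_suitability <- function(species, landscape) {
  grid <- landscape$grid
  vars <- union(names(species$linear), names(species$quadratic))
  miss <- setdiff(vars, names(landscape$predictors))
  if (length(miss))
    stop("landscape lacks predictor(s): ", paste(miss, collapse = ", "))
  z <- standardize_predictors(landscape$predictors, vars)
  score <- as.vector(z[, names(species$linear), drop = FALSE] %*%
                       species$linear)
  if (length(species$quadratic))
    score <- score + as.vector(
      z[, names(species$quadratic), drop = FALSE]^2 %*% species$quadratic)
  mx <- suppressWarnings(max(score, na.rm = TRUE))
  if (is.finite(mx)) {
    w <- exp(score - mx)
    w[is.na(w)] <- 0
  } else {
    w <- rep(0, length(score))
  }
  raster_layer(grid, paste0("truth_", species$name),
               matrix(w / sum(w), grid$n_rows, grid$n_cols))
}

#' Simulate citizen-science style occurrence records
#'
#' Record cells are drawn multinomially with probability proportional to
#' the true species' `exp(score)`; positions are uniform within the cell.
#' Clean records get an in-season date, a post-2000 year from the
#' landscape's reference period, accuracy below 1 km, a breeding code in
#' {possible, probable, certain} and a plausible-habitat flag.  Independent
#' Bernoulli corruption then degrades the configured fractions (pre-2000
#' year, accuracy > 1 km, out-of-season date, implausible habitat) so that
#' every QC rejection class is exercised.
#'
#' @param species a [true_species()].
#' @param landscape a [synthetic_landscape()].
#' @param n_records number of records to draw (>= 0).
#' @param seed integer RNG seed.
#' @param season `c(start, end)` month-day strings for clean dates
#'   (default `c("05-15", "07-15")`).
#' @return data.frame with columns `record_id`, `species`, `x`, `y`,
#'   `date`, `year`, `accuracy_m`, `breeding_code`, `habitat_plausible`.
#' @export
simulate_occurrences <- function(species, landscape, n_records = 5000,
                                 seed = 1, season = c("05-15", "07-15")) {
  stopifnot(n_records >= 0)
  grid <- landscape$grid
  truth <- true_suitability(species, landscape)
  w <- as.vector(truth$values)
  if (all(w == 0) || !any(is.finite(w))) stop("degenerate intensity")
  if (n_records == 0)
    return(data.frame(record_id = integer(0), species = character(0),
                      x = numeric(0), y = numeric(0),
                      date = as.Date(character(0)), year = integer(0),
                      accuracy_m = numeric(0), breeding_code = character(0),
                      habitat_plausible = logical(0)))
  years_avail <- as.integer(names(landscape$climate$bio1_by_year))
  with_seed(seed, {
    cells <- sample.int(length(w), n_records, replace = TRUE, prob = w)
    row <- ((cells - 1) %% grid$n_rows) + 1
    col <- ((cells - 1) %/% grid$n_rows) + 1
    x <- grid$origin_x + (col - 1 + stats::runif(n_records)) *
      grid$cell_size
    y <- grid$origin_y - (row - 1 + stats::runif(n_records)) *
      grid$cell_size
    year <- sample(years_avail, n_records, replace = TRUE)
    d0 <- as.Date(paste0("2001-", season[1]))
    d1 <- as.Date(paste0("2001-", season[2]))
    doy <- sample(as.integer(d0):as.integer(d1), n_records, replace = TRUE)
    monthday <- format(as.Date(doy, origin = "1970-01-01"), "%m-%d")
    accuracy <- stats::runif(n_records, 5, 800)
    breeding <- sample(c("possible", "probable", "certain"), n_records,
                       replace = TRUE, prob = c(.3, .4, .3))
    habitat <- rep(TRUE, n_records)
    flip <- function(p) stats::runif(n_records) < p
    old <- flip(species$p_old_year)
    year[old] <- sample(1985:1999, sum(old), replace = TRUE)
    bad_acc <- flip(species$p_bad_accuracy)
    accuracy[bad_acc] <- stats::runif(sum(bad_acc), 1001, 5000)
    off <- flip(species$p_wrong_season)
    monthday[off] <- sample(c("01-20", "02-10", "11-05", "12-15"),
                            sum(off), replace = TRUE)
    habitat[flip(species$p_bad_habitat)] <- FALSE
    data.frame(record_id = seq_len(n_records), species = species$name,
               x = x, y = y,
               date = as.Date(paste0(year, "-", monthday)),
               year = year, accuracy_m = accuracy,
               breeding_code = breeding, habitat_plausible = habitat,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic alpine landscape
#'
#' Convenience wrapper chaining terrain, climate, land cover, protected
#' areas and countries on one grid, and collecting the SDM predictor stack
#' (`bio1`, `bio7`, `bio12`, `bio15`, `slope`, `solar_med`, land-cover
#' fractions).
#'
#' @param n_rows,n_cols grid dimensions (1-km cells).
#' @param seed integer RNG seed (drives all component generators).
#' @param years reference-period years for per-year temperature layers.
#' @param treeline_m treeline elevation (m).
#' @param n_pa,n_countries protected-area and country counts.
#' @param relief_params passed to [generate_terrain()].
#' @return object of class `synthetic_landscape`: a list with `grid`,
#'   `elevation`, `slope`, `solar_med`, `climate`, `landcover`, `pa_mask`,
#'   `pa_table`, `country_raster` and `predictors`.
#' @export
synthetic_landscape <- function(n_rows = 100, n_cols = 100, seed = 1,
                                years = 2000:2019, treeline_m = 2000,
                                n_pa = 25, n_countries = 7,
                                relief_params = list(mean_elev = 1500,
                                                     relief_sd = 800,
                                                     range_km = 15)) {
  grid <- grid_spec(origin_x = 4e6, origin_y = 2.6e6, cell_size = 1000,
                    n_rows = n_rows, n_cols = n_cols)
  terr <- generate_terrain(grid, relief_params, seed = seed)
  clim <- generate_climate(terr$elevation, years = years, seed = seed + 1)
  lc <- generate_landcover(terr$elevation, treeline_m = treeline_m,
                           seed = seed + 2)
  pac <- generate_pa_countries(grid, n_pa = n_pa,
                               n_countries = n_countries, seed = seed + 3)
  predictors <- c(list(bio1 = clim$bio1_mean, bio7 = clim$bio7,
                       bio12 = clim$bio12, bio15 = clim$bio15,
                       slope = terr$slope, solar_med = terr$solar_med),
                  lc)
  structure(list(grid = grid, elevation = terr$elevation,
                 slope = terr$slope, solar_med = terr$solar_med,
                 climate = clim, landcover = lc,
                 pa_mask = pac$pa_mask, pa_table = pac$pa_table,
                 country_raster = pac$country_raster,
                 predictors = predictors, years = years),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf(paste0("synthetic_landscape: %d x %d km, elevation ",
                     "%.0f-%.0f m, %d predictors, %d PAs, %d countries\n"),
              x$grid$n_rows, x$grid$n_cols, min(x$elevation$values),
              max(x$elevation$values), length(x$predictors),
              nrow(x$pa_table),
              length(unique(as.vector(x$country_raster$values)))))
  invisible(x)
}
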