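#' @title Background sampling, spatial partitioning and SWD extraction
#' @description Places random background points inside 2-km buffers around
#'   presences (so the background mirrors the sampled region), assigns
#'   four-fold checkerboard-2 spatial cross-validation partitions, extracts
#'   predictor values into samples-with-data (SWD) tables, and screens
#'   predictor collinearity.
#' @name sampling-partition
NULL

#' Sample background points within buffers around presences
#'
#' Points are uniform over the union of disks of radius `radius_m` around
#' the presence points, clipped to the grid extent, via rejection sampling
#' from the bounding box.
#'
#' @param presences data.frame with `x`, `y` (e.g. from [thin_to_cells()]).
#' @param radius_m buffer radius in metres (default 2000).
#' @param n_points number of background points (default 50000).
#' @param grid a [grid_spec()].
#' @param seed integer RNG seed.
#' @return data.frame with `x`, `y`; exactly `n_points` rows, every point
#'   within `radius_m` of at least one presence.
#' @export
buffer_background <- function(presences, radius_m = 2000,
                              n_points = 50000, grid, seed = 1) {
  stopifnot(nrow(presences) >= 1, radius_m > 0)
  px <- presences$x; py <- presences$y
  xmin <- max(grid$origin_x, min(px) - radius_m)
  xmax <- min(grid$origin_x + grid$n_cols * grid$cell_size,
              max(px) + radius_m)
  ymin <- max(grid$origin_y - grid$n_rows * grid$cell_size,
              min(py) - radius_m)
  ymax <- min(grid$origin_y, max(py) + radius_m)
  if (xmin >= xmax || ymin >= ymax)
    stop("buffer does not intersect the grid")
  r2 <- radius_m^2
  # within-radius test via chunked distance to presences hashed by cell
  within_buffer <- function(cx, cy) {
    ok <- logical(length(cx))
    chunk <- 2000L
    for (s in seq(1, length(cx), by = chunk)) {
      e <- min(s + chunk - 1L, length(cx))
      dx <- outer(cx[s:e], px, "-")
      dy <- outer(cy[s:e], py, "-")
      ok[s:e] <- rowSums(dx * dx + dy * dy <= r2) > 0
      storage.mode(dx) <- "double"
    }
    ok
  }
  with_seed(seed, {
    out_x <- numeric(0); out_y <- numeric(0)
    guard <- 0L
    while (length(out_x) < n_points && guard < 1000L) {
      guard <- guard + 1L
      need <- n_points - length(out_x)
      m <- max(2L * need, 1000L)
      cx <- stats::runif(m, xmin, xmax)
      cy <- stats::runif(m, ymin, ymax)
      keep <- within_buffer(cx, cy)
      out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
    }
    if (length(out_x) < n_points)
      stop("buffer does not intersect the grid")
    data.frame(x = out_x[seq_len(n_points)], y = out_y[seq_len(n_points)])
  })
}

#' Assign checkerboard-2 spatial partitions
#'
#' Two-scale checkerboard tiling: with `c1 = factors[1] * cell_size` and
#' `c2 = factors[2] * c1`, a point's fine and coarse parities are
#' `p_k = (floor((x - origin_x)/c_k) + floor((origin_y - y)/c_k)) mod 2`
#' and the partition label is `2*p2 + p1 + 1`.  Deterministic; no RNG.
#'
#' @param points data.frame with `x`, `y`.
#' @param grid a [grid_spec()].
#' @param factors aggregation factors (default `c(4, 2)`).
#' @return integer vector of labels in 1..4.
#' @export
checkerboard2_assign <- function(points, grid, factors = c(4, 2)) {
  stopifnot(all(factors >= 1), all(factors == as.integer(factors)))
  c1 <- factors[1] * grid$cell_size
  c2 <- factors[2] * c1
  parity <- function(ck)
    (floor((points$x - grid$origin_x) / ck) +
       floor((grid$origin_y - points$y) / ck)) %% 2
  as.integer(2 * parity(c2) + parity(c1) + 1)
}

#' Extract predictor values into an SWD table
#'
#' Each point receives the value of the cell containing it for every
#' predictor.  Presences take `bio1` from the per-year layer matching the
#' record's collection year; background points take the multi-year
#' background mean `bio1`.  Rows hitting nodata cells are dropped and
#' logged.
#'
#' @param presences data.frame with `x`, `y`, `year` (and optionally
#'   `species`).
#' @param background data.frame with `x`, `y`.
#' @param predictors named list of static predictor [raster_layer()]s
#'   (including the background-mean `bio1`).
#' @param bio1_by_year named list (by year) of per-year `bio1` layers;
#'   `NULL` to use the background mean for presences too.
#' @param grid a [grid_spec()].
#' @param factors checkerboard aggregation factors for partition labels.
#' @return object of class `swd` (a data.frame with columns `point_id`,
#'   `species`, `x`, `y`, `class`, `partition`, `year`, then one column per
#'   predictor) with a `dropped` attribute logging nodata rows.
#' @export
extract_swd <- function(presences, background, predictors,
                        bio1_by_year = NULL, grid, factors = c(4, 2)) {
  sp <- if (!is.null(presences$species) && nrow(presences) > 0)
    presences$species[1] else "species"
  pts <- data.frame(
    x = c(presences$x, background$x),
    y = c(presences$y, background$y),
    class = rep(c("presence", "background"),
                c(nrow(presences), nrow(background))),
    year = c(as.integer(presences$year),
             rep(NA_integer_, nrow(background))))
  vals <- sapply(names(predictors), function(v)
    extract_at(predictors[[v]], pts$x, pts$y))
  vals <- matrix(vals, nrow = nrow(pts),
                 dimnames = list(NULL, names(predictors)))
  if (!is.null(bio1_by_year) && nrow(presences) > 0) {
    yrs <- unique(pts$year[pts$class == "presence"])
    missing_years <- setdiff(as.character(yrs), names(bio1_by_year))
    if (length(missing_years))
      stop("no per-year bio1 layer for year(s): ",
           paste(missing_years, collapse = ", "))
    for (yy in as.character(yrs)) {
      sel <- pts$class == "presence" & pts$year == as.integer(yy)
      vals[sel, "bio1"] <- extract_at(bio1_by_year[[yy]], pts$x[sel],
                                      pts$y[sel])
    }
  }
  bad <- rowSums(is.na(vals)) > 0
  swd <- data.frame(point_id = seq_len(nrow(pts)), species = sp,
                    pts[c("x", "y", "class")],
                    partition = checkerboard2_assign(pts, grid, factors),
                    year = pts$year, stringsAsFactors = FALSE)
  swd <- cbind(swd, as.data.frame(vals))[!bad, , drop = FALSE]
  rownames(swd) <- NULL
  attr(swd, "dropped") <- data.frame(
    point_id = which(bad), reason = rep("nodata", sum(bad)))
  attr(swd, "predictors") <- names(predictors)
  class(swd) <- c("swd", "data.frame")
  swd
}

#' Predictor column names of an SWD table
#' @param swd an `swd` table.
#' @return character vector.
#' @export
swd_predictors <- function(swd) {
  attr(swd, "predictors") %||%
    setdiff(names(swd), c("point_id", "species", "x", "y", "class",
                          "partition", "year"))
}

#' Split an SWD table into training and testing partitions
#'
#' The held-out checkerboard partition becomes the test set; the other
#' three train the model.
#'
#' @param swd an `swd` table with `partition` labels 1..4.
#' @param test_partition which partition to hold out (default 4).
#' @return list with `train` and `test` `swd` tables.
#' @export
split_train_test <- function(swd, test_partition = 4) {
  stopifnot(test_partition %in% 1:4)
  te <- swd$partition == test_partition
  train <- swd[!te, , drop = FALSE]
  test <- swd[te, , drop = FALSE]
  for (side in list(train, test))
    if (!any(side$class == "presence"))
      stop("a split side has zero presences")
  preds <- swd_predictors(swd)
  attr(train, "predictors") <- preds
  attr(test, "predictors") <- preds
  class(train) <- class(test) <- c("swd", "data.frame")
  list(train = train, test = test)
}

#' Screen pairwise predictor collinearity
#'
#' Pearson correlations over all presence and background rows; the check
#' fails when any pair reaches the threshold (|r| >= 0.7 by default).
#' Zero-variance predictors are flagged and excluded from pairs.
#'
#' @param swd an `swd` table.
#' @param threshold absolute correlation threshold (default 0.7).
#' @return list with `pass` (logical), `correlations` (data.frame
#'   `var1`, `var2`, `r`), `failing_pairs` and `zero_variance`.
#' @export
collinearity_check <- function(swd, threshold = 0.7) {
  vars <- swd_predictors(swd)
  stopifnot(length(vars) >= 2, nrow(swd) >= 3)
  m <- as.matrix(swd[vars])
  sds <- apply(m, 2, stats::sd)
  zero_var <- vars[sds == 0 | !is.finite(sds)]
  keep <- setdiff(vars, zero_var)
  cm <- stats::cor(m[, keep, drop = FALSE])
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  cors <- data.frame(var1 = keep[pairs[, 1]], var2 = keep[pairs[, 2]],
                     r = cm[pairs], stringsAsFactors = FALSE)
  failing <- cors[abs(cors$r) >= threshold, , drop = FALSE]
  list(pass = nrow(failing) == 0, correlations = cors,
       failing_pairs = failing, zero_variance = zero_var)
}

#' Read / write SWD tables as CSV
#'
#' Layout `point_id,species,x,y,class,partition,year,<var1>,...,<varK>`;
#' the reader tolerates missing `year` on background rows.
#'
#' @param swd an `swd` table.
#' @param path CSV file path.
#' @export
write_swd <- function(swd, path) {
  utils::write.csv(as.data.frame(swd), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_swd
#' @return `read_swd`: an `swd` table.
#' @export
read_swd <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$year)) df$year <- NA_integer_
  attr(df, "predictors") <- setdiff(names(df),
                                    c("point_id", "species", "x", "y",
                                      "class", "partition", "year"))
  class(df) <- c("swd", "data.frame")
  df
}
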