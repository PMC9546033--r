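#' @title Projection, range change and climate refugia
#' @description Projects a fitted model over current and future climate
#'   stacks, binarizes suitability at the 10th-percentile training
#'   threshold, summarizes extent and mean elevation of suitable cells
#'   per condition, and classifies in-situ (type 1) and ex-situ
#'   (type 2 / type 3) climate refugia plus multispecies refugia.
#' @name refugia
NULL

#' Project a fitted model over a raster stack
#'
#' Produces a cloglog suitability raster using the training
#' normalization constant and entropy.  With `clamp = FALSE` feature
#' values beyond the training range extrapolate, as when projecting into
#' warmer-than-training climates.
#'
#' @param model a fitted [maxent()] model.
#' @param climate_stack named list of climate [raster_layer()]s
#'   (`bio1`, `bio7`, `bio12`, `bio15`).
#' @param static_stack named list of non-climate predictor layers.
#' @param clamp clip features to the training range (default FALSE).
#' @return a suitability [raster_layer()] (values in (0, 1)).
#' @export
project_suitability <- function(model, climate_stack, static_stack,
                                clamp = FALSE) {
  layers <- c(climate_stack, static_stack)
  vars <- model$feature_map$vars
  miss <- setdiff(vars, names(layers))
  if (length(miss))
    stop("missing predictor layer(s): ", paste(miss, collapse = ", "))
  grid <- layers[[1]]$grid
  newdata <- as.data.frame(lapply(layers[vars], function(l)
    as.vector(l$values)))
  names(newdata) <- vars
  ok <- rowSums(is.na(newdata)) == 0
  vals <- rep(NA_real_, nrow(newdata))
  if (length(vars) == 0) {
    vals[ok] <- 1 - exp(-exp(model$H) / model$Z)
  } else {
    vals[ok] <- predict(model, newdata[ok, , drop = FALSE],
                        type = "cloglog", clamp = clamp)
  }
  raster_layer(grid, "suitability",
               matrix(vals, grid$n_rows, grid$n_cols))
}

#' Binarize a suitability map at a threshold
#'
#' A cell is suitable iff its cloglog suitability is strictly greater
#' than `tau`; nodata stays `NA`.
#'
#' @param suit suitability [raster_layer()].
#' @param tau threshold in `[0, 1]` (typically the 10th percentile of
#'   training presence scores).
#' @return logical-valued [raster_layer()].
#' @export
binarize <- function(suit, tau) {
  stopifnot(tau >= 0, tau <= 1)
  raster_layer(suit$grid, paste0(suit$name, "_bin"),
               suit$values > tau)
}

#' Suitable extent in square kilometres
#' @param mask logical [raster_layer()].
#' @return extent (km^2): count of suitable cells times the cell area.
#' @export
extent_km2 <- function(mask) {
  sum(mask$values, na.rm = TRUE) * (mask$grid$cell_size / 1000)^2
}

#' Mean elevation of suitable cells
#' @param mask logical [raster_layer()].
#' @param elevation elevation [raster_layer()] (m asl).
#' @return mean elevation (m); `NA` with a warning when the mask is
#'   empty.
#' @export
mean_elevation <- function(mask, elevation) {
  sel <- mask$values %in% TRUE
  if (!any(sel)) {
    warning("empty suitability mask: mean elevation undefined")
    return(NA_real_)
  }
  mean(elevation$values[sel])
}

#' Classify type-1/2/3 climate refugia
#'
#' Per-cell codes: 1 (in-situ refugium) iff suitable under current and
#' all four future conditions; 2 (core ex-situ) iff unsuitable now but
#' suitable under all four; 3 iff unsuitable now and suitable under
#' exactly three of four; 0 otherwise.  Codes 2 and 3 together form the
#' broad ex-situ refugia set (suitable in at least three of four
#' futures while currently unsuitable).
#'
#' @param current_mask logical [raster_layer()] of current suitability.
#' @param future_masks list of exactly four logical layers.
#' @param species label carried on the output.
#' @return integer-coded [raster_layer()] of class `refugia_map`.
#' @export
classify_refugia <- function(current_mask, future_masks,
                             species = "species") {
  if (length(future_masks) != 4)
    stop("exactly 4 future masks required, got ", length(future_masks))
  for (f in future_masks)
    if (!same_grid(f$grid, current_mask$grid))
      stop("future mask grid mismatch")
  nr <- current_mask$grid$n_rows; nc <- current_mask$grid$n_cols
  cur <- matrix(current_mask$values %in% TRUE, nr, nc)
  nfut <- matrix(Reduce(`+`, lapply(future_masks, function(f)
    f$values %in% TRUE)), nr, nc)
  code <- matrix(0L, nr, nc)
  code[cur & nfut == 4] <- 1L
  code[!cur & nfut == 4] <- 2L
  code[!cur & nfut == 3] <- 3L
  nod <- is.na(current_mask$values) |
    Reduce(`|`, lapply(future_masks, function(f) is.na(f$values)))
  code[nod] <- NA_integer_
  out <- raster_layer(current_mask$grid, paste0("refugia_", species),
                      code)
  class(out) <- c("refugia_map", class(out))
  attr(out, "species") <- species
  out
}

#' Multispecies type-1 refugia
#'
#' Cells that are type-1 (in-situ) refugia for at least `min_species`
#' of the supplied species.
#'
#' @param type1_masks list (one per species) of logical layers or
#'   `refugia_map`s (code 1 counts as membership).
#' @param min_species minimum species count (default 3).
#' @return logical [raster_layer()].
#' @export
multispecies_refugia <- function(type1_masks, min_species = 3) {
  stopifnot(length(type1_masks) >= min_species)
  g <- type1_masks[[1]]$grid
  counts <- Reduce(`+`, lapply(type1_masks, function(m) {
    v <- m$values
    if (inherits(m, "refugia_map")) (v %in% 1L) * 1L else (v %in% TRUE) * 1L
  }))
  raster_layer(g, "multispecies_refugia",
               matrix(counts >= min_species, g$n_rows, g$n_cols))
}

#' Summarize extent and elevation change across future conditions
#'
#' Per condition: suitable extent (km^2), percent change versus current,
#' and (when elevation is supplied) mean elevation of suitable cells and
#' its shift.  The mean percent change is the arithmetic mean over the
#' conditions.  Accepts either binary masks (with an elevation layer) or
#' plain numeric extents/elevations, so printed summary tables can be
#' fed back in directly.
#'
#' @param current current suitability mask ([raster_layer()]) or a
#'   numeric extent (km^2).
#' @param futures named list of future masks, or a named numeric vector
#'   of future extents.
#' @param elevation elevation [raster_layer()] (mask input), or a
#'   numeric vector `c(current, futures...)` of mean elevations
#'   (numeric input), or `NULL`.
#' @return object of class `change_summary`: data.frame with one row per
#'   condition (`condition`, `extent_km2`, `pct_change`, `mean_elev_m`,
#'   `elev_shift_m`) plus attributes `current_extent_km2`,
#'   `current_mean_elev_m` and `mean_pct_change`.
#' @export
change_summary <- function(current, futures, elevation = NULL) {
  if (inherits(current, "raster_layer")) {
    cur_ext <- extent_km2(current)
    fut_ext <- vapply(futures, extent_km2, 0)
    cur_el <- if (!is.null(elevation))
      mean_elevation(current, elevation) else NA_real_
    fut_el <- if (!is.null(elevation))
      vapply(futures, mean_elevation, 0, elevation = elevation)
    else rep(NA_real_, length(futures))
  } else {
    cur_ext <- as.numeric(current)
    fut_ext <- unlist(futures)
    if (!is.null(elevation)) {
      cur_el <- elevation[[1]]
      fut_el <- elevation[-1]
    } else {
      cur_el <- NA_real_
      fut_el <- rep(NA_real_, length(fut_ext))
    }
  }
  if (cur_ext == 0) {
    warning("current extent is zero: percent changes undefined")
    pct <- rep(NA_real_, length(fut_ext))
  } else {
    pct <- 100 * (fut_ext - cur_ext) / cur_ext
  }
  nm <- names(fut_ext) %||% paste0("condition_", seq_along(fut_ext))
  out <- data.frame(condition = nm, extent_km2 = unname(fut_ext),
                    pct_change = unname(pct),
                    mean_elev_m = unname(fut_el),
                    elev_shift_m = unname(fut_el - cur_el),
                    stringsAsFactors = FALSE)
  structure(out, current_extent_km2 = cur_ext,
            current_mean_elev_m = cur_el,
            mean_pct_change = mean(pct),
            class = c("change_summary", "data.frame"))
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("current extent: %.0f km2", attr(x, "current_extent_km2")))
  if (is.finite(attr(x, "current_mean_elev_m")))
    cat(sprintf(", mean elevation %.0f m", attr(x, "current_mean_elev_m")))
  cat("\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("mean change across conditions: %+.1f%%\n",
              attr(x, "mean_pct_change")))
  invisible(x)
}
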