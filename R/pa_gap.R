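#' @title Protected-area gap analysis
#' @description Overlays refugia masks with the protected-area system,
#'   overall and per country, optionally restricted to PAs under IUCN
#'   categories 1-4 plus selected designations.
#' @name pa-gap
NULL

#' Default designation keep-list for the IUCN-filtered PA variant
#'
#' Non-categorized protected areas retained when filtering to
#' conservation-managed PAs: Natura 2000 sites and selected national
#' designations.
#' @return character vector of designation labels.
#' @export
default_keep_designations <- function() {
  c("Natura 2000 SCI/SAC", "Natura 2000 SPA",
    "national forest reserve", "natural monument",
    "national private nature reserve")
}

#' Overlay a refugia mask with the protected-area mask
#'
#' @param refugia_mask logical [raster_layer()] (TRUE = refugium cell).
#' @param pa_mask integer [raster_layer()]; a cell is protected iff its
#'   PA id is nonzero.
#' @return list with `inside_km2`, `total_km2` and `percent`
#'   (`100 * inside / total`; `NA` with warning when the mask is empty).
#' @export
pa_overlay <- function(refugia_mask, pa_mask) {
  stopifnot(same_grid(refugia_mask$grid, pa_mask$grid))
  km2 <- (refugia_mask$grid$cell_size / 1000)^2
  ref <- refugia_mask$values %in% TRUE
  total <- sum(ref) * km2
  inside <- sum(ref & pa_mask$values > 0, na.rm = TRUE) * km2
  if (total == 0) {
    warning("empty refugia mask: percent undefined")
    return(list(inside_km2 = 0, total_km2 = 0, percent = NA_real_))
  }
  list(inside_km2 = inside, total_km2 = total,
       percent = 100 * inside / total)
}

#' Per-country protected-area coverage of refugia
#'
#' One row per country holding any refugia cells; countries without
#' refugia are omitted (with a message).
#'
#' @param refugia_mask logical [raster_layer()].
#' @param pa_mask integer PA-id [raster_layer()].
#' @param country_raster integer country partition [raster_layer()].
#' @return data.frame `country`, `refugia_km2`, `inside_km2`, `percent`.
#' @export
pa_per_country <- function(refugia_mask, pa_mask, country_raster) {
  stopifnot(same_grid(refugia_mask$grid, pa_mask$grid),
            same_grid(refugia_mask$grid, country_raster$grid))
  km2 <- (refugia_mask$grid$cell_size / 1000)^2
  ref <- refugia_mask$values %in% TRUE
  prot <- pa_mask$values > 0
  countries <- sort(unique(stats::na.omit(as.vector(
    country_raster$values))))
  rows <- lapply(countries, function(co) {
    sel <- country_raster$values == co & !is.na(country_raster$values)
    tot <- sum(ref & sel) * km2
    if (tot == 0) return(NULL)
    ins <- sum(ref & sel & prot, na.rm = TRUE) * km2
    data.frame(country = co, refugia_km2 = tot, inside_km2 = ins,
               percent = 100 * ins / tot)
  })
  skipped <- countries[vapply(rows, is.null, TRUE)]
  if (length(skipped))
    message("countries without refugia omitted: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(country = integer(0), refugia_km2 = numeric(0),
                      inside_km2 = numeric(0), percent = numeric(0))
  out
}

#' Filter the PA mask to conservation-managed protected areas
#'
#' A cell keeps its PA id iff that PA's IUCN category is in
#' `keep_categories` or its designation is in `keep_designations`.
#'
#' @param pa_mask integer PA-id [raster_layer()].
#' @param pa_table data.frame `pa_id`, `iucn_category`, `designation`.
#' @param keep_categories IUCN categories to keep (default 1-4).
#' @param keep_designations designation labels kept regardless of
#'   category (default [default_keep_designations()]).
#' @return filtered PA-id [raster_layer()].
#' @export
filter_pa <- function(pa_mask, pa_table, keep_categories = 1:4,
                      keep_designations = default_keep_designations()) {
  ids <- setdiff(unique(as.vector(pa_mask$values)), c(0, NA))
  orphan <- setdiff(ids, pa_table$pa_id)
  if (length(orphan))
    stop("PA id(s) missing from table: ", paste(orphan, collapse = ", "))
  keep_ids <- pa_table$pa_id[
    (pa_table$iucn_category %in% keep_categories) |
      (pa_table$designation %in% keep_designations)]
  v <- pa_mask$values
  v[!(v %in% keep_ids)] <- 0L
  v[is.na(pa_mask$values)] <- NA_integer_
  raster_layer(pa_mask$grid, paste0(pa_mask$name, "_filtered"), v)
}
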