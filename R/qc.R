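#' @title Occurrence record quality control
#' @description Retention rules for citizen-science occurrence records:
#'   minimum year, spatial accuracy, breeding evidence, habitat
#'   plausibility, and species-specific breeding-season windows with
#'   extended shoulder windows admitted only at higher breeding evidence.
#'   Retained records are then deduplicated to occupied 1-km cells.
#' @name occurrence-qc
NULL

BREEDING_LEVELS <- c("undefined", "none", "possible", "probable", "certain")

#' Define per-species record-retention rules
#'
#' @param species species label.
#' @param core_window `c(start, end)` month-day strings ("MM-DD") for the
#'   core breeding season; any breeding evidence above `none` is accepted
#'   inside it.
#' @param extended_windows list of `c(start, end)` month-day windows that
#'   are admitted only with breeding evidence at least
#'   `extended_min_breeding`.
#' @param extended_min_breeding minimum breeding code for extended windows
#'   (default `"probable"`).
#' @param min_year earliest retained collection year (default 2000).
#' @param max_accuracy_m maximum spatial accuracy in metres (default 1000).
#' @return object of class `species_rules`.
#' @export
species_rules <- function(species, core_window,
                          extended_windows = list(),
                          extended_min_breeding = "probable",
                          min_year = 2000, max_accuracy_m = 1000) {
  stopifnot(extended_min_breeding %in% BREEDING_LEVELS,
            match(extended_min_breeding, BREEDING_LEVELS) >=
              match("possible", BREEDING_LEVELS))
  structure(list(species = species, core_window = core_window,
                 extended_windows = extended_windows,
                 extended_min_breeding = extended_min_breeding,
                 min_year = min_year, max_accuracy_m = max_accuracy_m),
            class = "species_rules")
}

#' Built-in retention rules for the four focal alpine species
#'
#' Core windows: 1 May-31 Jul (rock ptarmigan), 15 May-31 Jul (water
#' pipit, alpine accentor), 1 Jun-31 Jul (snowfinch).  Extended windows
#' (probable/certain breeding only): April and August for rock ptarmigan,
#' early May (1-14) and August for water pipit and alpine accentor, and
#' 1-15 August for snowfinch.
#'
#' @return named list of [species_rules()].
#' @export
default_species_rules <- function() {
  list(
    `rock ptarmigan` = species_rules(
      "rock ptarmigan", c("05-01", "07-31"),
      list(c("04-01", "04-30"), c("08-01", "08-31"))),
    `water pipit` = species_rules(
      "water pipit", c("05-15", "07-31"),
      list(c("05-01", "05-14"), c("08-01", "08-31"))),
    `alpine accentor` = species_rules(
      "alpine accentor", c("05-15", "07-31"),
      list(c("05-01", "05-14"), c("08-01", "08-31"))),
    snowfinch = species_rules(
      "snowfinch", c("06-01", "07-31"),
      list(c("08-01", "08-15"))))
}

in_window <- function(monthday, window) {
  monthday >= window[1] & monthday <= window[2]
}

#' Filter occurrence records by the retention rules
#'
#' A record is kept iff its year is at or after `min_year`, its accuracy
#' is known and at most `max_accuracy_m`, its breeding code is above
#' `none`, its habitat is plausible, and its date falls in the core window
#' or in an extended window with breeding evidence at least
#' `extended_min_breeding`.  Rejections are logged with the first failing
#' rule in the fixed priority order year, accuracy, breeding, habitat,
#' season, so logs are deterministic.
#'
#' @param records data.frame as produced by [simulate_occurrences()] (or
#'   read with [read_occurrences()]).
#' @param rules a [species_rules()] object, or a named list of them to be
#'   looked up by the records' species label.
#' @return list with `kept` (data.frame of retained records) and
#'   `rejection_log` (data.frame `record_id`, `reason`).
#' @export
filter_records <- function(records, rules) {
  if (!inherits(rules, "species_rules")) {
    sp <- unique(records$species)
    if (length(sp) > 1)
      stop("records contain multiple species; filter one at a time")
    if (length(sp) == 1) {
      if (is.null(rules[[sp]])) stop("no rules for species '", sp, "'")
      rules <- rules[[sp]]
    } else {
      rules <- rules[[1]]
    }
  }
  n <- nrow(records)
  if (n == 0)
    return(list(kept = records,
                rejection_log = data.frame(record_id = integer(0),
                                           reason = character(0))))
  monthday <- format(as.Date(records$date), "%m-%d")
  breeding <- match(records$breeding_code, BREEDING_LEVELS)
  ok_year <- records$year >= rules$min_year
  ok_acc <- !is.na(records$accuracy_m) &
    records$accuracy_m <= rules$max_accuracy_m
  ok_breed <- !is.na(breeding) & breeding >= match("possible",
                                                   BREEDING_LEVELS)
  ok_hab <- records$habitat_plausible %in% TRUE
  in_core <- in_window(monthday, rules$core_window)
  in_ext <- Reduce(`|`, lapply(rules$extended_windows, in_window,
                               monthday = monthday), rep(FALSE, n))
  ok_season <- in_core |
    (in_ext & !is.na(breeding) &
       breeding >= match(rules$extended_min_breeding, BREEDING_LEVELS))
  reason <- rep(NA_character_, n)
  reason[!ok_season] <- "season"
  reason[!ok_hab] <- "habitat"
  reason[!ok_breed] <- "breeding"
  reason[!ok_acc] <- "accuracy"
  reason[!ok_year] <- "year"
  kept <- is.na(reason)
  list(kept = records[kept, , drop = FALSE],
       rejection_log = data.frame(record_id = records$record_id[!kept],
                                  reason = reason[!kept],
                                  stringsAsFactors = FALSE))
}

#' Deduplicate filtered records to occupied 1-km cells
#'
#' One presence per distinct occupied cell, placed at the cell centre.
#' Each presence carries the most recent record year in its cell (used for
#' per-year temperature extraction).  Records outside the grid are dropped
#' and logged.
#'
#' @param records filtered occurrence records.
#' @param grid a [grid_spec()].
#' @return list with `presences` (data.frame `species`, `x`, `y`, `row`,
#'   `col`, `year`) and `dropped` (data.frame `record_id`, `reason`).
#' @export
thin_to_cells <- function(records, grid) {
  idx <- cell_of(records$x, records$y, grid)
  out <- is.na(idx$row)
  dropped <- data.frame(record_id = records$record_id[out],
                        reason = rep("out of grid", sum(out)),
                        stringsAsFactors = FALSE)
  rec <- records[!out, , drop = FALSE]
  idx <- idx[!out, , drop = FALSE]
  if (nrow(rec) == 0)
    return(list(presences = data.frame(species = character(0),
                                       x = numeric(0), y = numeric(0),
                                       row = integer(0), col = integer(0),
                                       year = integer(0)),
                dropped = dropped))
  ord <- order(idx$cell, -rec$year)
  first <- !duplicated(idx$cell[ord])
  sel <- ord[first]
  ctr <- cell_center(idx$row[sel], idx$col[sel], grid)
  pres <- data.frame(species = rec$species[sel], x = ctr$x, y = ctr$y,
                     row = idx$row[sel], col = idx$col[sel],
                     year = rec$year[sel], stringsAsFactors = FALSE)
  list(presences = pres[order(pres$row, pres$col), , drop = FALSE],
       dropped = dropped)
}

#' Read / write occurrence record CSV
#'
#' Column layout
#' `species,x,y,date,year,accuracy_m,breeding_code,habitat_plausible`
#' (a `record_id` column is added on read if absent).
#'
#' @param path CSV file path.
#' @return data.frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  if (is.null(df$record_id)) df$record_id <- seq_len(nrow(df))
  df
}

#' @rdname read_occurrences
#' @param records data.frame of occurrence records.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
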