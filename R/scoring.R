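#' Prize-list size of a race
#'
#' The prize list comprises 20% of the starting pigeons; only birds on it
#' receive ace points. Rounding is `floor` with a minimum of 1 by default;
#' federations differ, so the rounding mode is configurable.
#'
#' @param n_starters Number of pigeons starting the race (vectorised).
#' @param rounding One of `"floor"`, `"round"`, `"ceiling"`.
#' @return Integer prize-list size(s), at least 1.
#' @examples
#' prize_list_size(100)  # 20
#' prize_list_size(4)    # 1
#' @export
prize_list_size <- function(n_starters, rounding = c("floor", "round", "ceiling")) {
  rounding <- match.arg(rounding)
  n_starters <- as.integer(n_starters)
  if (any(is.na(n_starters)) || any(n_starters < 1L))
    stop("n_starters must be a positive integer", call. = FALSE)
  f <- switch(rounding, floor = floor, round = round, ceiling = ceiling)
  pmax(1L, as.integer(f(0.20 * n_starters)))
}

#' Ace points for a finishing position
#'
#' `AP = (a - b + 1) / a * 100` for position `b` on a prize list of size
#' `a`; the winner always scores 100 and positions beyond the prize list
#' (or missing positions, did-not-finish) score 0.
#'
#' @param a Prize-list size(s), `>= 1`.
#' @param b Finishing position(s), `>= 1`; `NA` means did not finish.
#' @return Numeric ace points in `[0, 100]` (vectorised).
#' @examples
#' ace_points(20, 1)   # 100
#' ace_points(20, 20)  # 5
#' ace_points(20, 21)  # 0
#' @export
ace_points <- function(a, b) {
  a <- as.integer(a)
  if (any(is.na(a)) || any(a < 1L))
    stop("prize-list size a must be >= 1", call. = FALSE)
  b <- as.integer(b)
  if (any(b < 1L, na.rm = TRUE))
    stop("position b must be >= 1", call. = FALSE)
  res <- rep_len(0, length.out = max(length(a), length(b)))
  a <- rep_len(a, length(res)); b <- rep_len(b, length(res))
  on_list <- !is.na(b) & b <= a
  res[on_list] <- (a[on_list] - b[on_list] + 1) / a[on_list] * 100
  res
}

#' Race category from distance
#'
#' Short races are those up to 400 km, long races those of 500 km or more.
#' The interval (400, 500) km is undefined by the category scheme: strict
#' mode raises an error, otherwise the nearer boundary is used with a
#' warning.
#'
#' @param distance_km Positive race distance(s) in km.
#' @param strict Error on distances in (400, 500) km (default `TRUE`).
#' @return Factor with levels `"short"` and `"long"`.
#' @examples
#' categorize_race(c(300, 650))
#' @export
categorize_race <- function(distance_km, strict = TRUE) {
  distance_km <- as.numeric(distance_km)
  if (any(is.na(distance_km)) || any(distance_km <= 0))
    stop("distance_km must be positive", call. = FALSE)
  gap <- distance_km > 400 & distance_km < 500
  if (any(gap)) {
    if (strict)
      stop(sprintf("distance(s) %s km fall between the short (<=400) and long (>=500) categories",
                   paste(unique(distance_km[gap]), collapse = ", ")),
           call. = FALSE)
    warning("distance(s) in (400, 500) km assigned to the nearest category boundary",
            call. = FALSE)
  }
  factor(ifelse(distance_km <= 450, "short", "long"),
         levels = c("short", "long"))
}

#' Score race records with ace points
#'
#' Fills the `ap` column of a race-record table from each race's prize-list
#' size and the finishing positions, and adds the race `category`. Within a
#' race, positions of finishers must be unique; records with missing
#' positions (did not finish) stay in the table with `ap = 0`.
#'
#' @param records Data frame with columns `pigeon_id`, `race_id`,
#'   `distance_km`, `n_starters`, `position` (NA = did not finish) and any
#'   covariate columns, e.g. from [read_races()] or [simulate_study()].
#' @param rounding Prize-list rounding mode, see [prize_list_size()].
#' @param strict Passed to [categorize_race()].
#' @return The input data frame with columns `prize_list`, `ap` and
#'   `category` added/overwritten. Row order is preserved.
#' @export
score_races <- function(records, rounding = "floor", strict = TRUE) {
  need <- c("pigeon_id", "race_id", "distance_km", "n_starters", "position")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop(sprintf("records lack column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (any(records$position > records$n_starters, na.rm = TRUE))
    stop("position exceeds n_starters in at least one record", call. = FALSE)
  for (rid in unique(records$race_id)) {
    pos <- records$position[records$race_id == rid]
    pos <- pos[!is.na(pos)]
    if (anyDuplicated(pos))
      stop(sprintf("duplicate finishing positions in race '%s'", rid),
           call. = FALSE)
    ns <- unique(records$n_starters[records$race_id == rid])
    if (length(ns) > 1L)
      stop(sprintf("inconsistent n_starters within race '%s'", rid),
           call. = FALSE)
  }
  records$prize_list <- prize_list_size(records$n_starters, rounding = rounding)
  records$ap <- ace_points(records$prize_list, records$position)
  records$category <- categorize_race(records$distance_km, strict = strict)
  records
}
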