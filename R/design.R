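#' Define a seasonal camera-trap survey design
#'
#' A design describes how a multi-season (dynamic) occupancy survey is laid
#' out: how many camera sites, which primary periods ("seasons") were
#' surveyed, and how continuous monitoring within a season is discretized
#' into secondary occasions of fixed length. The default mirrors a
#' two-year Mediterranean survey: 60 sites, four seasons alternating wet
#' (October onward) and dry (June onward), and 13 consecutive 5-day
#' occasions per season, so each season spans exactly 65 days.
#'
#' @param n_sites Number of camera-trap sites (positive integer).
#' @param season_labels Character vector of ordered season labels.
#' @param season_starts `Date` vector of season start dates, one per label.
#'   The default tiles wet seasons from 1 October and dry seasons from
#'   1 June across consecutive years.
#' @param occasion_days Length of one secondary occasion in days.
#' @param n_occasions Number of secondary occasions per season.
#'
#' @return An object of class `survey_design`: a list with `n_sites`,
#'   `seasons` (a tibble with `label`, `start`, `end`), `occasion_days`
#'   and `n_occasions`. Each season's `end` is `start + occasion_days *
#'   n_occasions`, i.e. seasons are exactly tiled by whole occasions.
#' @examples
#' survey_design()
#' survey_design(n_sites = 20, season_labels = c("W20", "W21"),
#'               season_starts = as.Date(c("2020-10-01", "2021-10-01")))
#' @export
survey_design <- function(n_sites = 60,
                          season_labels = c("W20", "D21", "W21", "D22"),
                          season_starts = NULL,
                          occasion_days = 5,
                          n_occasions = 13) {
  stopifnot(is.numeric(n_sites), length(n_sites) == 1, n_sites >= 1,
            occasion_days >= 1, n_occasions >= 1,
            length(season_labels) >= 1, !anyDuplicated(season_labels))
  n_sites <- as.integer(n_sites)
  if (is.null(season_starts)) {
    season_starts <- default_season_starts(season_labels)
  }
  season_starts <- as.Date(season_starts)
  if (length(season_starts) != length(season_labels)) {
    stop("`season_starts` must have one date per season label", call. = FALSE)
  }
  span <- occasion_days * n_occasions
  seasons <- tibble::tibble(
    label = season_labels,
    start = season_starts,
    end   = season_starts + span
  )
  if (is.unsorted(as.numeric(seasons$start), strictly = TRUE)) {
    stop("season start dates must be strictly increasing", call. = FALSE)
  }
  if (nrow(seasons) > 1 &&
      any(seasons$end[-nrow(seasons)] > seasons$start[-1])) {
    stop("season intervals must not overlap", call. = FALSE)
  }
  structure(
    list(n_sites = n_sites, seasons = seasons,
         occasion_days = as.integer(occasion_days),
         n_occasions = as.integer(n_occasions)),
    class = "survey_design"
  )
}

# Wet seasons (labels starting "W") anchored at 1 October of 20xx, dry
# seasons ("D") at 1 June. Fallback for other labels: consecutive years
# from 2020-10-01 spaced widely enough never to overlap.
default_season_starts <- function(labels) {
  m <- regmatches(labels, regexec("^([WD])(\\d{2})$", labels))
  if (all(lengths(m) == 3)) {
    as.Date(vapply(m, function(g) {
      paste0("20", g[3], if (g[2] == "W") "-10-01" else "-06-01")
    }, character(1)))
  } else {
    as.Date("2020-10-01") + 180 * (seq_along(labels) - 1)
  }
}

#' @export
print.survey_design <- function(x, ...) {
  cat("<survey_design> ", x$n_sites, " sites, ",
      nrow(x$seasons), " seasons, ",
      x$n_occasions, " x ", x$occasion_days, "-day occasions\n", sep = "")
  print(x$seasons)
  invisible(x)
}

n_seasons <- function(design) nrow(design$seasons)

#' Occasion boundaries for one season
#'
#' Occasion `k` of a season spans days `[start + (k-1) d, start + k d)`
#' (half-open) anchored at the season's start date.
#'
#' @param design A [survey_design()].
#' @param season Season label or index.
#' @return A tibble with `occasion`, `start`, `end` (`end` exclusive).
#' @export
occasion_windows <- function(design, season) {
  s <- resolve_season(design, season)
  d <- design$occasion_days
  k <- seq_len(design$n_occasions)
  tibble::tibble(
    occasion = k,
    start = design$seasons$start[s] + (k - 1) * d,
    end   = design$seasons$start[s] + k * d
  )
}

resolve_season <- function(design, season) {
  if (is.character(season)) {
    i <- match(season, design$seasons$label)
    if (anyNA(i)) {
      stop("unknown season label: ",
           paste(season[is.na(i)], collapse = ", "), call. = FALSE)
    }
    i
  } else {
    stopifnot(all(season >= 1), all(season <= n_seasons(design)))
    as.integer(season)
  }
}
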