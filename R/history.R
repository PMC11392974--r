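#' Detection-history container
#'
#' Holds one species' detection/effort arrays over sites x seasons x
#' occasions. `y` is 1 (detected), 0 (surveyed, not detected) or `NA`
#' (occasion with effort < 1 day — the camera is considered inactive);
#' `effort` is the number of active days per occasion. The invariant
#' `is.na(y) <=> effort < 1` is enforced at construction.
#'
#' @param y Integer array, sites x seasons x occasions, in `{0, 1, NA}`.
#' @param effort Numeric array of the same shape, values in
#'   `[0, occasion_days]`.
#' @param species Species label.
#' @param design The [survey_design()] the arrays follow.
#' @return An object of class `detection_history`.
#' @export
detection_history <- function(y, effort, species, design) {
  stopifnot(inherits(design, "survey_design"))
  dm <- c(design$n_sites, n_seasons(design), design$n_occasions)
  if (!identical(dim(y), as.integer(dm)) ||
      !identical(dim(effort), as.integer(dm))) {
    stop("y and effort must be ", paste(dm, collapse = " x "),
         " arrays", call. = FALSE)
  }
  if (any(effort < 0 | effort > design$occasion_days, na.rm = TRUE)) {
    stop("effort must lie in [0, occasion_days]", call. = FALSE)
  }
  if (!all(is.na(y) == (effort < 1))) {
    stop("y must be NA exactly where effort < 1 day", call. = FALSE)
  }
  if (!all(y %in% c(0L, 1L, NA))) {
    stop("y entries must be 0, 1 or NA", call. = FALSE)
  }
  structure(list(y = y, effort = effort, species = species,
                 design = design),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  d <- dim(x$y)
  cat("<detection_history> ", x$species, ": ", d[1], " sites x ", d[2],
      " seasons x ", d[3], " occasions; ",
      sum(x$y == 1, na.rm = TRUE), " detections, ",
      sum(is.na(x$y)), " NA occasions\n", sep = "")
  invisible(x)
}

#' Build a detection history from events and deployments
#'
#' Discretizes a species' timestamped (already independence-filtered, if
#' desired) event stream into the design's consecutive occasions. Occasion
#' `k` of a season spans days `[start + (k-1) d, start + k d)` (half-open,
#' anchored at the season start); `y = 1` iff at least one event of the
#' species falls in that site-occasion. Effort is the number of occasion
#' days covered by a deployment; a partially covered day counts as covered
#' when at least 12 h of it are within a deployment. Occasions with
#' effort < 1 day become `NA`.
#'
#' Events at a site-time not covered by any of that site's deployments are
#' dropped with a warning; events outside every season are excluded
#' silently. Both counts are available in `attr(, "report")`.
#'
#' @param events Data frame with `site_id`, `species`, `timestamp`.
#' @param deployments Data frame with `site_id`, `start`, `end`
#'   (timestamps; `end` exclusive).
#' @param design A [survey_design()].
#' @param species Species label to build the history for.
#' @return A [detection_history()] with an attached `report` attribute
#'   (`n_outside_deployment`, `n_outside_season`).
#' @export
build_detection_history <- function(events, deployments, design, species) {
  n <- design$n_sites
  T <- n_seasons(design)
  K <- design$n_occasions
  d <- design$occasion_days

  deployments <- tibble::as_tibble(deployments)
  deployments$start <- parse_timestamps(deployments$start)
  deployments$end <- parse_timestamps(deployments$end)

  effort <- array(0, c(n, T, K))
  half_day <- 12 * 3600
  for (t in seq_len(T)) {
    days <- seq(design$seasons$start[t], by = 1, length.out = d * K)
    day0 <- as.numeric(as.POSIXct(days, tz = "UTC"))
    cover <- matrix(0, n, length(days))  # covered seconds per site-day
    for (r in seq_len(nrow(deployments))) {
      i <- deployments$site_id[r]
      s <- as.numeric(deployments$start[r])
      e <- as.numeric(deployments$end[r])
      ov <- pmax(0, pmin(e, day0 + 86400) - pmax(s, day0))
      cover[i, ] <- cover[i, ] + ov
    }
    active_days <- cover >= half_day
    for (k in seq_len(K)) {
      cols <- ((k - 1) * d + 1):(k * d)
      effort[, t, k] <- rowSums(active_days[, cols, drop = FALSE])
    }
  }

  y <- array(0L, c(n, T, K))
  y[effort < 1] <- NA_integer_

  ev <- tibble::as_tibble(events)
  ev <- ev[ev$species == species, , drop = FALSE]
  n_outside_dep <- 0L
  n_outside_season <- 0L
  if (nrow(ev)) {
    ev$timestamp <- parse_timestamps(ev$timestamp)
    # events must fall inside one of their site's deployments
    covered <- vapply(seq_len(nrow(ev)), function(r) {
      dd <- deployments[deployments$site_id == ev$site_id[r], ]
      any(dd$start <= ev$timestamp[r] & ev$timestamp[r] < dd$end)
    }, logical(1))
    n_outside_dep <- sum(!covered)
    if (n_outside_dep > 0) {
      warning(n_outside_dep,
              " event(s) outside any deployment interval were dropped",
              call. = FALSE)
      ev <- ev[covered, , drop = FALSE]
    }
    if (nrow(ev)) {
      starts <- as.POSIXct(design$seasons$start, tz = "UTC")
      ends <- as.POSIXct(design$seasons$end, tz = "UTC")
      for (r in seq_len(nrow(ev))) {
        ts <- ev$timestamp[r]
        t <- which(starts <= ts & ts < ends)
        if (!length(t)) {
          n_outside_season <- n_outside_season + 1L
          next
        }
        day <- floor(as.numeric(ts - starts[t], units = "days"))
        k <- day %/% d + 1
        if (k >= 1 && k <= K && !is.na(y[ev$site_id[r], t, k])) {
          y[ev$site_id[r], t, k] <- 1L
        }
      }
    }
  }
  h <- detection_history(y, effort, species, design)
  attr(h, "report") <- list(n_outside_deployment = n_outside_dep,
                            n_outside_season = n_outside_season)
  h
}

#' Naive occupancy per season
#'
#' The proportion of surveyed sites where the species was detected at
#' least once in a season, uncorrected for imperfect detection. Sites
#' whose occasions are all `NA` in a season were not surveyed then and
#' drop out of the denominator.
#'
#' @param h A [detection_history()].
#' @return A tibble with `season`, `n_surveyed`, `n_detected`,
#'   `naive_occ`. A season with zero surveyed sites gets `NA` with a
#'   warning.
#' @export
naive_occupancy <- function(h) {
  T <- dim(h$y)[2]
  out <- lapply(seq_len(T), function(t) {
    yt <- h$y[, t, , drop = FALSE]
    surveyed <- apply(!is.na(yt), 1, any)
    detected <- apply(yt == 1, 1, any, na.rm = TRUE) & surveyed
    tibble::tibble(
      season = h$design$seasons$label[t],
      n_surveyed = sum(surveyed),
      n_detected = sum(detected),
      naive_occ = if (sum(surveyed) == 0) NA_real_ else
        sum(detected) / sum(surveyed)
    )
  })
  out <- dplyr::bind_rows(out)
  if (anyNA(out$naive_occ)) {
    warning("season(s) with zero surveyed sites: naive occupancy is NA",
            call. = FALSE)
  }
  out
}

#' Restrict a history (and covariates) to a subset of seasons
#'
#' Some species are too rarely detected in part of the year to support
#' dynamics estimation (here: forest-dwelling species in dry seasons), so
#' their models use only a subset of primary periods. Slices the
#' detection/effort arrays, the design, and any season-site or observation
#' covariates consistently; transition-indexed quantities follow the new
#' season ordering.
#'
#' @param h A [detection_history()].
#' @param covs Optional [covariate_set()] to slice alongside.
#' @param keep Ordered character vector of season labels to keep.
#' @return If `covs` is `NULL`, the subset `detection_history`; otherwise
#'   `list(history, covs)`.
#' @export
subset_seasons <- function(h, covs = NULL, keep) {
  idx <- resolve_season(h$design, keep)
  design <- h$design
  design$seasons <- design$seasons[idx, ]
  h2 <- detection_history(h$y[, idx, , drop = FALSE],
                          h$effort[, idx, , drop = FALSE],
                          h$species, design)
  if (is.null(covs)) return(h2)
  covs$season_site <- lapply(covs$season_site,
                             function(m) m[, idx, drop = FALSE])
  covs$observation <- lapply(covs$observation,
                             function(a) a[, idx, , drop = FALSE])
  list(history = h2, covs = covs)
}

#' Long-format view of a detection history
#'
#' @param h A [detection_history()].
#' @return A tibble with `site`, `season`, `occasion`, `y`, `effort` —
#'   the interchange format written by [write_history_csv()].
#' @export
history_to_long <- function(h) {
  d <- dim(h$y)
  tibble::tibble(
    site = rep(seq_len(d[1]), times = d[2] * d[3]),
    season = rep(rep(h$design$seasons$label, each = d[1]), times = d[3]),
    occasion = rep(seq_len(d[3]), each = d[1] * d[2]),
    y = as.integer(h$y),
    effort = as.numeric(h$effort)
  )
}

#' Write a detection history as CSV
#'
#' Writes the long format (`site, season, occasion, y, effort`) and,
#' optionally, a compact wide format with one row per site-season and one
#' column per occasion, the layout occupancy software conventionally
#' exchanges.
#'
#' @param h A [detection_history()].
#' @param path Output file for the long format.
#' @param wide_path Optional output file for the wide format.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(h, path, wide_path = NULL) {
  long <- history_to_long(h)
  write.csv(long, path, row.names = FALSE)
  if (!is.null(wide_path)) {
    wide <- tidyr::pivot_wider(
      long[, c("site", "season", "occasion", "y")],
      names_from = "occasion", values_from = "y", names_prefix = "occ"
    )
    write.csv(wide, wide_path, row.names = FALSE)
  }
  invisible(path)
}
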