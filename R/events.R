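#' Filter camera-trap events to independent events
#'
#' Camera traps fire repeatedly while an animal lingers, so raw triggers
#' overcount visits. The conventional fix keeps only *independent* events:
#' scanning each site-species series chronologically, an event is retained
#' iff at least `window` minutes have elapsed since the last *retained*
#' event of that site and species (sliding anchor). Events exactly at the
#' window boundary are retained (closed comparison). The filter is
#' idempotent.
#'
#' @param events A data frame with columns `site_id`, `species`,
#'   `timestamp` (POSIXct, or character parseable as ISO-8601, assumed
#'   UTC).
#' @param window Independence window in minutes (> 0); default 30.
#' @return A tibble of retained events, sorted by site, species, time.
#' @examples
#' ev <- tibble::tibble(
#'   site_id = 1, species = "fox",
#'   timestamp = as.POSIXct("2020-10-01", tz = "UTC") + c(0, 20, 45) * 60
#' )
#' filter_independent_events(ev)  # keeps minutes 0 and 45
#' @export
filter_independent_events <- function(events, window = 30) {
  stopifnot(is.numeric(window), window > 0)
  events <- tibble::as_tibble(events)
  req <- c("site_id", "species", "timestamp")
  if (!all(req %in% names(events))) {
    stop("events must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events) == 0) return(events)
  events$timestamp <- parse_timestamps(events$timestamp)
  events <- dplyr::arrange(events, .data$site_id, .data$species,
                           .data$timestamp)
  keep <- unlist(lapply(
    split(seq_len(nrow(events)),
          list(events$site_id, events$species), drop = TRUE),
    function(idx) idx[independent_scan(events$timestamp[idx], window * 60)]
  ), use.names = FALSE)
  dplyr::arrange(events[sort(keep), ], .data$site_id, .data$species,
                 .data$timestamp)
}

# Chronological scan with a sliding anchor at the last retained event;
# >= comparison so a gap of exactly `window_sec` is kept.
independent_scan <- function(ts, window_sec) {
  n <- length(ts)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- as.numeric(ts[1])
  if (n > 1) {
    tn <- as.numeric(ts)
    for (i in 2:n) {
      if (tn[i] - last >= window_sec) {
        keep[i] <- TRUE
        last <- tn[i]
      }
    }
  }
  which(keep)
}

parse_timestamps <- function(ts) {
  if (inherits(ts, "POSIXct")) return(ts)
  ch <- as.character(ts)
  out <- as.POSIXct(rep(NA_real_, length(ch)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out) & !is.na(ch)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(ch[miss], fmt, tz = "UTC"))
  }
  bad <- which(is.na(out) & !is.na(ch))
  if (length(bad)) {
    stop("unparseable timestamp in row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out
}
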