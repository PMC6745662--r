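#' Regularize raw GPS fixes into nightly tracks
#'
#' Snaps raw fixes onto the regular nightly slot grid (default 15-minute
#' slots from 16:00 to 06:00, i.e. 57 slots) and codes unfilled slots as
#' missing, so that each (animal, night) becomes a single regular-interval
#' track. Slots after midnight belong to the night that began at the
#' preceding 16:00. A fix is assigned to the nearest slot if within `dt/2`
#' minutes of it; fixes falling outside the nightly window are dropped with a
#' warning. Duplicate fixes for the same slot are resolved by keeping the one
#' nearest the slot time (ties: the earlier fix). Step lengths and turning
#' angles are derived for the resulting tracks (see [steps_and_angles()]).
#'
#' @param fixes data.frame with columns `animal_id`, `timestamp` (POSIXct or
#'   ISO-8601 character), `x`, `y` and optionally `sex`.
#' @param night_start,night_end clock times "HH:MM" delimiting the nightly
#'   tracking window (spanning midnight).
#' @param dt slot spacing in minutes.
#' @return a `track_set` data.frame with one row per slot and columns
#'   `animal_id`, `sex`, `night` (date the night began), `slot`, `timestamp`
#'   (slot time), `x`, `y` (NA when missing), `step`, `angle`. Attributes
#'   `n_slots`, `dt`, and `dropped` (count of out-of-window fixes).
#' @export
build_tracks <- function(fixes, night_start = "16:00", night_end = "06:00",
                         dt = 15) {
  stopifnot(all(c("animal_id", "timestamp", "x", "y") %in% names(fixes)))
  ts <- fixes$timestamp
  if (!inherits(ts, "POSIXct"))
    ts <- as.POSIXct(ts, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  if (anyNA(ts)) stopf("unparseable timestamps in fixes")
  hm <- function(s) {
    p <- as.integer(strsplit(s, ":")[[1]])
    p[1] * 60 + p[2]
  }
  start_min <- hm(night_start)
  span_min <- (hm(night_end) - start_min) %% (24 * 60)
  n_slots <- span_min %/% dt + 1L

  epoch <- as.numeric(ts)
  rel <- epoch - start_min * 60
  night_idx <- floor(rel / 86400)
  offset <- rel - night_idx * 86400          # seconds since that 16:00
  slot <- round(offset / (dt * 60)) + 1
  dist <- abs(offset - (slot - 1) * dt * 60)
  ok <- slot >= 1 & slot <= n_slots & dist <= dt * 60 / 2
  n_drop <- sum(!ok)
  if (n_drop > 0)
    warnf("%d fix(es) outside the nightly slot grid dropped", n_drop)

  d <- data.frame(
    animal_id = fixes$animal_id[ok],
    sex = if ("sex" %in% names(fixes)) as.character(fixes$sex)[ok]
          else NA_character_,
    night = night_idx[ok], slot = as.integer(slot[ok]),
    x = fixes$x[ok], y = fixes$y[ok],
    snap_dist = dist[ok], epoch = epoch[ok],
    stringsAsFactors = FALSE
  )
  # duplicate slot resolution: nearest to slot time, then earliest
  d <- d[order(d$animal_id, d$night, d$slot, d$snap_dist, d$epoch), ]
  dup <- duplicated(d[c("animal_id", "night", "slot")])
  d <- d[!dup, ]

  # full slot grid for every (animal, night) seen
  key <- unique(d[c("animal_id", "night", "sex")])
  key <- key[order(key$animal_id, key$night), ]
  grid <- key[rep(seq_len(nrow(key)), each = n_slots), ]
  grid$slot <- rep(seq_len(n_slots), nrow(key))
  idx <- match(paste(grid$animal_id, grid$night, grid$slot),
               paste(d$animal_id, d$night, d$slot))
  grid$x <- d$x[idx]
  grid$y <- d$y[idx]
  grid$timestamp <- as.POSIXct(
    grid$night * 86400 + start_min * 60 + (grid$slot - 1) * dt * 60,
    origin = "1970-01-01", tz = "UTC")
  grid$night <- as.Date(as.POSIXct(grid$night * 86400 + start_min * 60,
                                   origin = "1970-01-01", tz = "UTC"))
  rownames(grid) <- NULL
  out <- grid[c("animal_id", "sex", "night", "slot", "timestamp", "x", "y")]
  out <- steps_and_angles(out)
  class(out) <- c("track_set", "data.frame")
  attr(out, "n_slots") <- n_slots
  attr(out, "dt") <- dt
  attr(out, "dropped") <- n_drop
  out
}

#' Derive step lengths and turning angles
#'
#' Step `l_t` is the Euclidean distance between the positions at slots
#' `t - 1` and `t` (missing if either endpoint is missing; steps are never
#' bridged across gaps, keeping the emission time scale homogeneous). The
#' bearing `b_t` is `atan2` of the displacement into slot `t`, and the
#' turning angle `phi_t = wrap(b_t - b_{t-1})` in `(-pi, pi]`,
#' counterclockwise positive; it needs the positions at slots `t - 2`,
#' `t - 1` and `t` and is missing otherwise. The first slot of a track has
#' neither step nor angle.
#'
#' @param tracks a track data.frame ordered by animal, night, slot, with
#'   columns `animal_id`, `night`, `slot`, `x`, `y`.
#' @return `tracks` with `step` and `angle` columns (re)computed.
#' @export
steps_and_angles <- function(tracks) {
  n <- nrow(tracks)
  step <- rep(NA_real_, n)
  angle <- rep(NA_real_, n)
  if (n > 0) {
    tid <- paste(tracks$animal_id, tracks$night)
    same1 <- c(FALSE, tid[-1] == tid[-n])          # same track as previous row
    dx <- c(NA, diff(tracks$x))
    dy <- c(NA, diff(tracks$y))
    ok1 <- same1 & !is.na(dx) & !is.na(dy)
    step[ok1] <- sqrt(dx[ok1]^2 + dy[ok1]^2)
    bearing <- rep(NA_real_, n)
    bearing[ok1] <- atan2(dy[ok1], dx[ok1])
    prev_b <- c(NA, bearing[-n])
    ok2 <- ok1 & same1 & c(FALSE, same1[-n]) & !is.na(prev_b)
    angle[ok2] <- wrap_angle(bearing[ok2] - prev_b[ok2])
  }
  tracks$step <- step
  tracks$angle <- angle
  tracks
}

#' Filter raw fixes
#'
#' Programmatic stand-in for manual track cleaning: removes (in order)
#' exact-duplicate timestamps per animal, all fixes on each animal's first
#' and last recorded night (collar fitting/retrieval nights), fixes inside an
#' optional exclusion mask (e.g. water bodies), and fixes implying a travel
#' speed above `max_speed` meters/minute from *both* temporal neighbors
#' (position spikes). The default 40 m/min is far above the fastest fitted
#' behavioral state (~18 m/min).
#'
#' @param fixes a fix data.frame (see [build_tracks()]).
#' @param max_speed spike threshold in meters per minute.
#' @param exclusion_mask optional [landscape_raster()]; fixes whose
#'   containing cell is nonzero in its first layer are removed.
#' @param drop_first_last_night drop each animal's first and last night?
#' @param night_start clock time "HH:MM" delimiting nights.
#' @return the filtered fixes, with attribute `removed`, a named count per
#'   rule.
#' @export
filter_fixes <- function(fixes, max_speed = 40, exclusion_mask = NULL,
                         drop_first_last_night = TRUE,
                         night_start = "16:00") {
  ts <- fixes$timestamp
  if (!inherits(ts, "POSIXct"))
    ts <- as.POSIXct(ts, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  o <- order(fixes$animal_id, ts)
  fixes <- fixes[o, ]
  ts <- ts[o]
  removed <- c(duplicate = 0L, first_last_night = 0L,
               exclusion = 0L, speed = 0L)

  dup <- duplicated(data.frame(fixes$animal_id, as.numeric(ts)))
  removed["duplicate"] <- sum(dup)
  fixes <- fixes[!dup, ]; ts <- ts[!dup]

  if (drop_first_last_night && nrow(fixes) > 0) {
    p <- as.integer(strsplit(night_start, ":")[[1]])
    night <- floor((as.numeric(ts) - (p[1] * 60 + p[2]) * 60) / 86400)
    keep <- rep(TRUE, nrow(fixes))
    for (a in unique(fixes$animal_id)) {
      ai <- fixes$animal_id == a
      keep[ai & (night == min(night[ai]) | night == max(night[ai]))] <- FALSE
    }
    removed["first_last_night"] <- sum(!keep)
    fixes <- fixes[keep, ]; ts <- ts[keep]
  }

  if (!is.null(exclusion_mask) && nrow(fixes) > 0) {
    v <- raster_extract(exclusion_mask, names(exclusion_mask$layers)[1],
                        fixes$x, fixes$y)
    excl <- !is.na(v) & v != 0
    removed["exclusion"] <- sum(excl)
    fixes <- fixes[!excl, ]; ts <- ts[!excl]
  }

  if (nrow(fixes) > 2) {
    spike <- rep(FALSE, nrow(fixes))
    for (a in unique(fixes$animal_id)) {
      ai <- which(fixes$animal_id == a)
      if (length(ai) < 3) next
      xx <- fixes$x[ai]; yy <- fixes$y[ai]
      tt <- as.numeric(ts[ai]) / 60  # minutes
      sp <- sqrt(diff(xx)^2 + diff(yy)^2) / diff(tt)
      inner <- 2:(length(ai) - 1)
      spike[ai[inner]] <- sp[inner - 1] > max_speed & sp[inner] > max_speed
    }
    removed["speed"] <- sum(spike)
    fixes <- fixes[!spike, ]
  }

  if (nrow(fixes) == 0) warnf("all fixes removed by filtering")
  rownames(fixes) <- NULL
  attr(fixes, "removed") <- removed
  fixes
}
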