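#' Vertical radar beam configuration
#'
#' @param opening_angle Full opening angle of the vertical cone, degrees
#'   (default 105, the midpoint of the 90-120 degree range typical of this
#'   radar class).
#' @param alt_min,alt_max Altitude band in which insects are counted,
#'   meters above ground (defaults 50 and 700).
#' @param rcs_min Minimum detectable radar cross section, mm^2 (default 3).
#' @param window Local counting window, hours (default `c(5, 20)`, i.e.
#'   05:00-20:00, 15 hourly values per day).
#' @return A list of class `beam_config`.
#' @export
beam_config <- function(opening_angle = 105, alt_min = 50, alt_max = 700,
                        rcs_min = 3, window = c(5, 20)) {
  stopifnot(opening_angle > 0, opening_angle < 180, alt_min > 0,
            alt_min < alt_max, rcs_min > 0,
            length(window) == 2, window[1] < window[2])
  structure(list(opening_angle = opening_angle, alt_min = alt_min,
                 alt_max = alt_max, rcs_min = rcs_min, window = window),
            class = "beam_config")
}

#' Keep detectable insect echoes
#'
#' Retains echoes classified as insects with `rcs >= rcs_min` inside the
#' beam's altitude band (both band limits inclusive).
#'
#' @param echoes data.frame `t`, `altitude_m`, `rcs_mm2`, `class`.
#' @param beam A [beam_config()].
#' @return Filtered data.frame.
#' @export
select_insect_echoes <- function(echoes, beam = beam_config()) {
  keep <- echoes$class == "insect" &
    echoes$rcs_mm2 >= beam$rcs_min &
    echoes$altitude_m >= beam$alt_min &
    echoes$altitude_m <= beam$alt_max
  echoes[keep, , drop = FALSE]
}

#' Horizontal beam width at altitude
#'
#' For a cone of full opening angle `theta`, the horizontal transect the
#' beam sweeps at altitude `a` is `w(a) = 2 a tan(theta / 2)`.
#'
#' @param altitude Altitude(s), meters.
#' @param beam A [beam_config()].
#' @return Width in meters.
#' @export
transect_width <- function(altitude, beam = beam_config()) {
  2 * altitude * tan(.deg2rad(beam$opening_angle / 2))
}

#' Hourly movement traffic rate from one hour of echoes
#'
#' Each retained echo is weighted by the ratio of the 1-km reference
#' transect to the beam width at the echo's altitude, so the hourly MoTR is
#' `sum_i 1000 / w(altitude_i)`, in insects km^-1 hr^-1 — the number of
#' insects that would have crossed a 1-km line in that hour.
#'
#' @param echoes Echoes of a single hour, already passed through
#'   [select_insect_echoes()].
#' @param beam A [beam_config()].
#' @return Hourly MoTR (0 for no echoes).
#' @export
hourly_mtr <- function(echoes, beam = beam_config()) {
  if (nrow(echoes) == 0) return(0)
  sum(1000 / transect_width(echoes$altitude_m, beam))
}

#' Daily MoTR from an hourly series
#'
#' Arithmetic mean of the hourly MoTR values inside the counting window.
#' Hours with no retained echoes count as 0; hours flagged as radar
#' downtime are excluded from the mean.
#'
#' @param hourly data.frame `hour` (local), `mtr`.
#' @param beam A [beam_config()].
#' @param off_hours Optional integer vector of local hours with no radar
#'   operation, excluded from the mean.
#' @return Daily MoTR.
#' @export
daily_motr <- function(hourly, beam = beam_config(), off_hours = integer(0)) {
  hours <- seq(beam$window[1], beam$window[2] - 1)
  hours <- setdiff(hours, off_hours)
  vals <- vapply(hours, function(h) {
    i <- which(hourly$hour == h)
    if (length(i)) hourly$mtr[i[1]] else 0
  }, numeric(1))
  mean(vals)
}

#' Hourly and daily MoTR series from an echo table
#'
#' Applies the detectability filter, bins echoes into local hours, computes
#' the per-hour MoTR and averages it within the daily counting window.
#'
#' @param echoes data.frame `t` (POSIXct UTC), `altitude_m`, `rcs_mm2`,
#'   `class`; may span many days.
#' @param beam A [beam_config()].
#' @param site A [site_config()] (UTC offset for local hours).
#' @param off_hours Optional data.frame `date`, `hour` of radar downtime.
#' @return list: `hourly` (`date`, `hour`, `mtr`) and `daily` (`date`,
#'   `motr`).
#' @export
motr_series <- function(echoes, beam = beam_config(), site = site_config(),
                        off_hours = NULL) {
  sel <- select_insect_echoes(echoes, beam)
  lt <- sel$t + site$utc_offset * 3600
  dl <- as.Date(lt, tz = "UTC")
  hr <- as.integer(format(lt, "%H", tz = "UTC"))
  days <- sort(unique(as.Date(echoes$t + site$utc_offset * 3600, tz = "UTC")))
  hourly <- daily <- vector("list", length(days))
  for (i in seq_along(days)) {
    hrs <- seq(beam$window[1], beam$window[2] - 1)
    mtr <- vapply(hrs, function(h) {
      hourly_mtr(sel[dl == days[i] & hr == h, , drop = FALSE], beam)
    }, numeric(1))
    htab <- data.frame(date = days[i], hour = hrs, mtr = mtr)
    off <- if (!is.null(off_hours))
      off_hours$hour[off_hours$date == days[i]] else integer(0)
    hourly[[i]] <- htab
    daily[[i]] <- data.frame(date = days[i],
                             motr = daily_motr(htab, beam, off))
  }
  list(hourly = do.call(rbind, hourly), daily = do.call(rbind, daily))
}
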