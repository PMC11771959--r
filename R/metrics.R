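#' Colony-distance summary for one day of fixes
#'
#' Euclidean distance of every retained fix (all tags pooled) to the colony;
#' returns the mean and the maximum.
#'
#' @param fixes data.frame of one day's fixes (`x`, `y`).
#' @param site A [site_config()].
#' @return Named numeric vector `c(mean, max)` in meters.
#' @export
colony_distance_stats <- function(fixes, site = site_config()) {
  d <- sqrt((fixes$x - site$colony_xy[1])^2 + (fixes$y - site$colony_xy[2])^2)
  c(mean = mean(d), max = max(d))
}

#' Detect colony visits from reception gaps
#'
#' The colony building blocks tag reception, so a visit appears in the data
#' as a gap between transmissions. A gap of at least `min_duration_s`
#' (exactly the threshold counts) whose bounding fixes — the last before and
#' the first after — both lie within `radius_m` of the colony is scored as a
#' visit; entry and exit times are those bounding fixes.
#'
#' @param track data.frame of one tag's time-ordered fixes for one day.
#' @param site A [site_config()].
#' @param radius_m Colony radius for visit attribution, meters.
#' @param min_duration_s Minimum visit duration, seconds.
#' @return data.frame `tag_id`, `entry`, `exit`, `duration_s` (0 rows if
#'   none).
#' @export
detect_visits <- function(track, site = site_config(), radius_m = 100,
                          min_duration_s = 60) {
  empty <- data.frame(tag_id = character(0),
                      entry = as.POSIXct(character(), tz = "UTC"),
                      exit = as.POSIXct(character(), tz = "UTC"),
                      duration_s = numeric(0))
  n <- nrow(track)
  if (n < 2) return(empty)
  d <- sqrt((track$x - site$colony_xy[1])^2 + (track$y - site$colony_xy[2])^2)
  gap <- diff(as.numeric(track$t))
  i <- which(gap >= min_duration_s & d[-n] <= radius_m & d[-1] <= radius_m)
  if (!length(i)) return(empty)
  data.frame(tag_id = track$tag_id[i], entry = track$t[i],
             exit = track$t[i + 1], duration_s = gap[i])
}

# TRUE for each step of `track` that spans a detected visit gap
.visit_steps <- function(track, visits) {
  n <- nrow(track)
  if (n < 2) return(logical(0))
  if (is.null(visits) || nrow(visits) == 0) return(logical(n - 1))
  as.numeric(track$t[-n]) %in% as.numeric(visits$entry) &
    as.numeric(track$t[-1]) %in% as.numeric(visits$exit)
}

#' Daily route length of one tag-day, subject to the coverage rule
#'
#' The cumulative step distance of the tag's day track, excluding visit
#' gaps (the bird is inside the building). Defined only for tag-days with
#' consistent activity: a daylight span of at least `min_hours` and no
#' non-visit reception gap longer than `gap_tolerance_s`; otherwise `NA`
#' (an exclusion, not an error).
#'
#' @param track One tag's fixes for one day, time-ordered.
#' @param visits Visits of that tag-day from [detect_visits()].
#' @param min_hours Minimum activity span, hours (default 10).
#' @param gap_tolerance_s Longest tolerated non-visit gap, seconds.
#' @return Route length in meters, or `NA_real_`.
#' @export
daily_route <- function(track, visits = NULL, min_hours = 10,
                        gap_tolerance_s = 900) {
  n <- nrow(track)
  if (n < 2) return(NA_real_)
  span_h <- as.numeric(difftime(track$t[n], track$t[1], units = "hours"))
  if (span_h < min_hours) return(NA_real_)
  st <- step_kinematics(track)
  is_visit <- .visit_steps(track, visits)
  if (any(st$dt_s > gap_tolerance_s & !is_visit)) return(NA_real_)
  sum(st$dist_m[!is_visit])
}

#' Colony visit frequency for one day
#'
#' Per-tag visit count divided by that tag's activity span (first to last
#' fix, hours), averaged across active tags.
#'
#' @param visits data.frame of the day's visits (may be 0-row).
#' @param activity data.frame per tag: `tag_id`, `span_h`.
#' @return Visits per tag per hour.
#' @export
visit_frequency <- function(visits, activity) {
  counts <- vapply(activity$tag_id, function(tg) {
    if (is.null(visits) || nrow(visits) == 0) 0L
    else sum(visits$tag_id == tg)
  }, integer(1))
  mean(counts / activity$span_h)
}

#' Foraging duration and its day-length-standardized complement
#'
#' Foraging duration is the daylight span of out-of-colony activity: first
#' departure to last arrival, minus total in-colony visit time. Net
#' foraging duration is the identity `day_length - foraging_duration`,
#' i.e. foraging effort expressed relative to the available day.
#'
#' @param track One tag's fixes for one day.
#' @param visits That tag-day's visits.
#' @param day_length Day length (sunset - sunrise), hours.
#' @param exclude_visit_time If `FALSE`, visit time is not subtracted
#'   (first-departure-to-last-arrival span only).
#' @return Named vector `c(foraging, net)`, hours.
#' @export
foraging_durations <- function(track, visits, day_length,
                               exclude_visit_time = TRUE) {
  n <- nrow(track)
  span <- if (n < 2) 0 else
    as.numeric(difftime(track$t[n], track$t[1], units = "hours"))
  vt <- if (exclude_visit_time && !is.null(visits) && nrow(visits) > 0)
    sum(visits$duration_s) / 3600 else 0
  f <- span - vt
  c(foraging = f, net = day_length - f)
}

#' Mean flight speed of one tag-day
#'
#' Mean of step speeds excluding steps that span colony visits.
#'
#' @param track One tag's fixes for one day.
#' @param visits That tag-day's visits.
#' @return m/s (`NA` for fewer than 2 fixes).
#' @export
mean_flight_speed <- function(track, visits = NULL) {
  if (nrow(track) < 2) return(NA_real_)
  st <- step_kinematics(track)
  keep <- !.visit_steps(track, visits)
  if (!any(keep)) return(NA_real_)
  mean(st$speed_ms[keep])
}

#' Roost arrival/departure offsets and roost duration for one tag
#'
#' Per local day: the evening colony arrival is the tag's final fix of the
#' day if it lies within the colony radius and within a 60-min window
#' around sunset; its offset is minutes after sunset (negative = before).
#' The morning departure is the first fix of the day, within the colony
#' radius and a 60-min window around sunrise, as minutes after sunrise.
#' Roost duration is next-morning departure minus evening arrival, hours,
#' assigned to the evening's day. Non-qualifying events are `NA`.
#'
#' @param track All fixes of one tag (may span many days), time-ordered.
#' @param site A [site_config()].
#' @param radius_m Colony radius, meters.
#' @param window_min Half-window around sunset/sunrise, minutes.
#' @return data.frame per day: `date`, `arrival_offset`,
#'   `departure_offset` (minutes), `roost_dur` (hours).
#' @export
roost_times <- function(track, site = site_config(), radius_m = 100,
                        window_min = 60) {
  dl <- local_date(track$t, site)
  days <- sort(unique(dl))
  sun <- sun_times(site, days)
  res <- data.frame(date = days, arrival_offset = NA_real_,
                    departure_offset = NA_real_, roost_dur = NA_real_)
  dist <- sqrt((track$x - site$colony_xy[1])^2 +
                 (track$y - site$colony_xy[2])^2)
  arr_t <- rep(as.POSIXct(NA, tz = "UTC"), length(days))
  dep_t <- rep(as.POSIXct(NA, tz = "UTC"), length(days))
  for (i in seq_along(days)) {
    j <- which(dl == days[i])
    last <- j[length(j)]; first <- j[1]
    off_a <- as.numeric(difftime(track$t[last], sun$sunset[i], units = "mins"))
    if (dist[last] <= radius_m && abs(off_a) <= window_min) {
      res$arrival_offset[i] <- off_a
      arr_t[i] <- track$t[last]
    }
    off_d <- as.numeric(difftime(track$t[first], sun$sunrise[i], units = "mins"))
    if (dist[first] <= radius_m && abs(off_d) <= window_min) {
      res$departure_offset[i] <- off_d
      dep_t[i] <- track$t[first]
    }
  }
  for (i in seq_along(days)) {
    nxt <- which(days == days[i] + 1)
    if (length(nxt) && !is.na(arr_t[i]) && !is.na(dep_t[nxt]))
      res$roost_dur[i] <- as.numeric(difftime(dep_t[nxt], arr_t[i],
                                              units = "hours"))
  }
  res
}

#' Mean inter-individual distance for one day
#'
#' Positions are averaged per bird in clock-aligned bins (default 5 min);
#' bins with fewer than `min_birds` birds are dropped; within each retained
#' bin the mean of all pairwise Euclidean distances is taken, and the daily
#' value is the mean over retained bins.
#'
#' @param fixes One day's fixes, all tags.
#' @param site A [site_config()].
#' @param bin_s Bin width, seconds (default 300; bins align to hh:00,
#'   hh:05, ... of the local clock).
#' @param min_birds Minimum simultaneous birds per bin (default 4).
#' @return Meters, or `NA_real_` if no bin qualifies.
#' @export
interindividual_distance <- function(fixes, site = site_config(),
                                     bin_s = 300, min_birds = 4) {
  if (nrow(fixes) == 0) return(NA_real_)
  bin <- floor((as.numeric(fixes$t) + site$utc_offset * 3600) / bin_s)
  key <- interaction(bin, fixes$tag_id, drop = TRUE)
  mx <- tapply(fixes$x, key, mean)
  my <- tapply(fixes$y, key, mean)
  kb <- as.numeric(sub("\\..*$", "", names(mx)))
  vals <- vapply(unique(kb), function(b) {
    i <- which(kb == b)
    if (length(i) < min_birds) return(NA_real_)
    mean(dist(cbind(mx[i], my[i])))
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Per-day behavioural metrics from filtered fixes
#'
#' Derives the whole set of day-level central-place foraging summaries:
#' colony distances, daily route (under the 10-hr consistent-activity
#' rule), visit frequency, foraging and net foraging duration, mean flight
#' speed, roost timing relative to sunset/sunrise, and inter-individual
#' distance. Day-level values are unweighted means across qualifying tags.
#'
#' @param fixes Filtered fixes (`tag_id`, `t`, `x`, `y`), time-ordered
#'   within tag.
#' @param site A [site_config()].
#' @param colony_radius_m Colony radius for visit/roost attribution.
#' @param min_visit_s Minimum visit duration, seconds.
#' @param route_min_hours Minimum activity span for the daily route.
#' @param gap_tolerance_s Longest tolerated non-visit gap for the route.
#' @param bin_s,min_birds Inter-individual distance binning parameters.
#' @param exclude_visit_time Passed to [foraging_durations()].
#' @return list: `daily` (one row per day, columns `date`, `mean_dist`,
#'   `max_dist`, `route`, `foraging_dur`, `net_foraging_dur`, `visit_freq`,
#'   `flight_speed`, `arrival_offset`, `departure_offset`, `roost_dur`,
#'   `interindiv_dist`, `n_tags`), and `visits` (per-visit table with
#'   `date`).
#' @export
compute_daily_metrics <- function(fixes, site = site_config(),
                                  colony_radius_m = 100, min_visit_s = 60,
                                  route_min_hours = 10,
                                  gap_tolerance_s = 900,
                                  bin_s = 300, min_birds = 4,
                                  exclude_visit_time = TRUE) {
  .check_track(fixes)
  dl <- local_date(fixes$t, site)
  days <- sort(unique(dl))
  sun <- sun_times(site, days)
  roost <- lapply(unique(fixes$tag_id), function(tg)
    cbind(tag_id = tg,
          roost_times(fixes[fixes$tag_id == tg, , drop = FALSE], site,
                      colony_radius_m)))
  roost <- do.call(rbind, roost)
  daily <- vector("list", length(days))
  all_visits <- list()
  for (i in seq_along(days)) {
    df <- fixes[dl == days[i], , drop = FALSE]
    tags <- unique(df$tag_id)
    cd <- colony_distance_stats(df, site)
    per_tag <- lapply(tags, function(tg) {
      tr <- df[df$tag_id == tg, , drop = FALSE]
      vis <- detect_visits(tr, site, colony_radius_m, min_visit_s)
      fd <- foraging_durations(tr, vis, sun$day_length[i],
                               exclude_visit_time)
      list(visits = vis,
           span_h = as.numeric(difftime(tr$t[nrow(tr)], tr$t[1],
                                        units = "hours")),
           route = daily_route(tr, vis, route_min_hours, gap_tolerance_s),
           foraging = fd[["foraging"]], net = fd[["net"]],
           speed = mean_flight_speed(tr, vis))
    })
    vis_day <- do.call(rbind, lapply(per_tag, `[[`, "visits"))
    if (!is.null(vis_day) && nrow(vis_day) > 0)
      all_visits[[length(all_visits) + 1]] <- cbind(date = days[i], vis_day)
    activity <- data.frame(tag_id = tags,
                           span_h = vapply(per_tag, `[[`, numeric(1), "span_h"))
    rd <- roost[roost$date == days[i], , drop = FALSE]
    daily[[i]] <- data.frame(
      date = days[i],
      mean_dist = cd[["mean"]], max_dist = cd[["max"]],
      route = mean(vapply(per_tag, `[[`, numeric(1), "route"), na.rm = TRUE),
      foraging_dur = mean(vapply(per_tag, `[[`, numeric(1), "foraging")),
      net_foraging_dur = mean(vapply(per_tag, `[[`, numeric(1), "net")),
      visit_freq = visit_frequency(vis_day, activity),
      flight_speed = mean(vapply(per_tag, `[[`, numeric(1), "speed"),
                          na.rm = TRUE),
      arrival_offset = if (all(is.na(rd$arrival_offset))) NA_real_
                       else mean(rd$arrival_offset, na.rm = TRUE),
      departure_offset = if (all(is.na(rd$departure_offset))) NA_real_
                         else mean(rd$departure_offset, na.rm = TRUE),
      roost_dur = if (all(is.na(rd$roost_dur))) NA_real_
                  else mean(rd$roost_dur, na.rm = TRUE),
      interindiv_dist = interindividual_distance(df, site, bin_s, min_birds),
      n_tags = length(tags))
    if (is.nan(daily[[i]]$route)) daily[[i]]$route <- NA_real_
  }
  list(daily = do.call(rbind, daily),
       visits = if (length(all_visits)) do.call(rbind, all_visits)
                else NULL)
}
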