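#' Filter thresholds for fix-level track cleaning
#'
#' @param vmax Maximum plausible flight speed, m/s; consecutive-fix speeds
#'   strictly above it are treated as localization errors (default 30, the
#'   maximum flight speed reported for large swifts).
#' @param iqr_k Multiplier on the interquartile range for the StdLoc upper
#'   fence (default 1.5).
#' @param min_nbs Minimum number of receiving base stations; fixes with
#'   fewer are dropped, `nbs == min_nbs` is retained (default 4).
#' @param max_step Maximum plausible displacement between consecutive
#'   fixes, meters; strictly larger steps are dropped (default 500).
#' @param min_tags_per_day Days with fewer active tags are excluded
#'   entirely (default 4).
#' @param jump_mode `"fix"` removes teleport spikes (fixes with
#'   over-length steps on both sides); `"segment"` splits the track at
#'   over-length steps and keeps only the longest segment.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(vmax = 30, iqr_k = 1.5, min_nbs = 4,
                          max_step = 500, min_tags_per_day = 4,
                          jump_mode = c("fix", "segment")) {
  stopifnot(vmax > 0, iqr_k > 0, min_nbs > 0, max_step > 0,
            min_tags_per_day > 0)
  structure(list(vmax = vmax, iqr_k = iqr_k, min_nbs = min_nbs,
                 max_step = max_step, min_tags_per_day = min_tags_per_day,
                 jump_mode = match.arg(jump_mode)),
            class = "filter_config")
}

.check_track <- function(track) {
  stopifnot(is.data.frame(track), all(c("tag_id", "t", "x", "y") %in% names(track)))
  if (nrow(track) > 1) {
    for (tg in unique(track$tag_id)) {
      tt <- track$t[track$tag_id == tg]
      dup <- duplicated(tt)
      if (any(dup))
        stop("duplicate timestamp for tag ", tg, " at ",
             format(tt[dup][1], "%Y-%m-%d %H:%M:%S", tz = "UTC"))
      if (is.unsorted(as.numeric(tt)))
        stop("fixes of tag ", tg, " are not time-ordered")
    }
  }
  invisible(track)
}

#' Step distances, time gaps and speeds along one tag's track
#'
#' @param track data.frame of time-ordered fixes of a single tag
#'   (`tag_id`, `t`, `x`, `y`).
#' @return data.frame with `n - 1` rows: `dist_m`, `dt_s`, `speed_ms`,
#'   each step linking consecutive fixes.
#' @export
step_kinematics <- function(track) {
  .check_track(track)
  n <- nrow(track)
  if (n <= 1)
    return(data.frame(dist_m = numeric(0), dt_s = numeric(0),
                      speed_ms = numeric(0)))
  dx <- diff(track$x); dy <- diff(track$y)
  dt <- diff(as.numeric(track$t))
  dist <- sqrt(dx^2 + dy^2)
  data.frame(dist_m = dist, dt_s = dt, speed_ms = dist / dt)
}

# Greedy later-fix drop: walk the track keeping an anchor fix; any
# successor whose step metric from the anchor strictly exceeds the
# threshold is dropped, otherwise it becomes the new anchor. Equivalent to
# repeatedly removing the later fix of the earliest violating pair until
# none remain (gross localization errors are isolated displaced fixes, so
# the dropped fix is the outlier itself in the common case).
.greedy_drop <- function(x, y, t, threshold, by_speed) {
  n <- length(x)
  if (n <= 1) return(logical(n))
  drop <- logical(n)
  anchor <- 1L
  for (j in 2L:n) {
    d <- sqrt((x[j] - x[anchor])^2 + (y[j] - y[anchor])^2)
    m <- if (by_speed) d / (t[j] - t[anchor]) else d
    if (m > threshold) drop[j] <- TRUE else anchor <- j
  }
  drop
}

.apply_per_tag <- function(track, fun) {
  keep <- logical(nrow(track))
  for (tg in unique(track$tag_id)) {
    i <- which(track$tag_id == tg)
    keep[i] <- fun(i)
  }
  keep
}

#' Remove fixes implying impossible flight speeds
#'
#' Iteratively drops the later fix of the earliest consecutive pair whose
#' speed strictly exceeds `cfg$vmax` (a pair at exactly `vmax` is
#' retained), per tag, until no violating pair remains.
#'
#' @param track data.frame of time-ordered fixes (may hold several tags).
#' @param cfg A [filter_config()].
#' @return list: `track` (retained fixes), `removed` (row indices of
#'   `track` input that were dropped).
#' @export
filter_speed <- function(track, cfg = filter_config()) {
  .check_track(track)
  keep <- .apply_per_tag(track, function(i) {
    !.greedy_drop(track$x[i], track$y[i], as.numeric(track$t[i]),
                  cfg$vmax, by_speed = TRUE)
  })
  list(track = track[keep, , drop = FALSE], removed = which(!keep))
}

#' Upper fence for localization standard error
#'
#' Tukey fence `Q3 + iqr_k * (Q3 - Q1)` over the pooled StdLoc values of
#' the whole dataset (quantiles by linear interpolation between order
#' statistics, `stats::quantile` type 7).
#'
#' @param stdloc Numeric vector of pooled StdLoc values (>= 4 required).
#' @param iqr_k IQR multiplier (default 1.5).
#' @return The fence, meters.
#' @export
stdloc_fence <- function(stdloc, iqr_k = 1.5) {
  stdloc <- stdloc[!is.na(stdloc)]
  if (length(stdloc) < 4)
    stop("need at least 4 StdLoc values to compute the IQR fence")
  q <- stats::quantile(stdloc, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + iqr_k * (q[2] - q[1])
}

#' Drop fixes with localization error above the fence
#' @param track data.frame of fixes with a `stdloc` column.
#' @param fence Upper limit from [stdloc_fence()]; fixes with
#'   `stdloc <= fence` are retained.
#' @return list: `track`, `removed` (row indices dropped).
#' @export
filter_stdloc <- function(track, fence) {
  keep <- track$stdloc <= fence
  list(track = track[keep, , drop = FALSE], removed = which(!keep))
}

#' Drop fixes received by too few base stations
#' @param track data.frame of fixes with an `nbs` column.
#' @param cfg A [filter_config()]; fixes with `nbs >= min_nbs` are kept.
#' @return list: `track`, `removed`.
#' @export
filter_nbs <- function(track, cfg = filter_config()) {
  keep <- track$nbs >= cfg$min_nbs
  list(track = track[keep, , drop = FALSE], removed = which(!keep))
}

# Iterative teleport-spike removal: a fix is dropped when the step to BOTH
# its current neighbours strictly exceeds the threshold (single-sided at
# the track ends, later-fix precedence for a lone violating pair), repeated
# to convergence. A genuine movement gap — the bird really covered > 500 m
# between received fixes — violates only one side of each bounding fix and
# is left alone, so quality-filter holes in a fast-moving track do not
# trigger runaway removal.
.spike_drop <- function(x, y, threshold) {
  n <- length(x)
  alive <- rep(TRUE, n)
  if (n <= 1) return(!alive & FALSE)
  repeat {
    idx <- which(alive)
    m <- length(idx)
    if (m <= 1) break
    d <- sqrt(diff(x[idx])^2 + diff(y[idx])^2)
    viol <- d > threshold
    left <- c(FALSE, viol)          # step ending at each fix
    right <- c(viol, FALSE)         # step starting at each fix
    bad <- left & right
    bad[m] <- bad[m] | left[m]      # trailing spike: only one side exists
    bad[1] <- bad[1] | (right[1] & !bad[2])  # leading spike, later-fix first
    if (!any(bad)) break
    alive[idx[bad]] <- FALSE
  }
  !alive
}

#' Remove teleport fixes implying implausible position jumps
#'
#' Applied after the speed, StdLoc and NBS filters as a backstop against
#' gross localization errors that survive the speed rule (displacements
#' across longer reception gaps). In `"fix"` mode a fix is dropped when the
#' steps to both its neighbours strictly exceed `max_step` (one-sided at
#' the track ends), iterated until stable; a step of exactly `max_step` is
#' retained, and a genuine movement gap — a single long step with ordinary
#' steps around it — removes nothing. In `"segment"` mode the track is
#' split at violating steps and only the longest segment survives.
#'
#' @inheritParams filter_speed
#' @return list: `track`, `removed`.
#' @export
filter_jump <- function(track, cfg = filter_config()) {
  .check_track(track)
  keep <- .apply_per_tag(track, function(i) {
    if (cfg$jump_mode == "fix") {
      !.spike_drop(track$x[i], track$y[i], cfg$max_step)
    } else {
      d <- sqrt(diff(track$x[i])^2 + diff(track$y[i])^2)
      seg <- cumsum(c(0, d > cfg$max_step))
      best <- names(which.max(table(seg)))
      seg == as.numeric(best)
    }
  })
  list(track = track[keep, , drop = FALSE], removed = which(!keep))
}

#' Keep only fixes between sunrise and sunset (inclusive)
#'
#' The interval is closed on both ends: a fix exactly at sunrise or sunset
#' is a measurement, not an error.
#'
#' @param track data.frame of fixes.
#' @param site A [site_config()].
#' @return list: `track`, `removed`.
#' @export
restrict_daylight <- function(track, site = site_config()) {
  if (nrow(track) == 0) return(list(track = track, removed = integer(0)))
  dl <- local_date(track$t, site)
  sun <- sun_times(site, sort(unique(dl)))
  i <- match(dl, sun$date)
  keep <- track$t >= sun$sunrise[i] & track$t <= sun$sunset[i]
  list(track = track[keep, , drop = FALSE], removed = which(!keep))
}

#' Drop whole days with too few active tags
#'
#' A tag is active on a (local) day if it retains at least one fix that
#' day; days with fewer than `min_tags_per_day` active tags are removed
#' entirely.
#'
#' @param track data.frame of fixes.
#' @param cfg A [filter_config()].
#' @param site A [site_config()].
#' @return list: `track`, `removed`, `dropped_days` (Date vector).
#' @export
filter_min_tags <- function(track, cfg = filter_config(),
                            site = site_config()) {
  if (nrow(track) == 0)
    return(list(track = track, removed = integer(0),
                dropped_days = as.Date(character())))
  dl <- local_date(track$t, site)
  tags_per_day <- tapply(track$tag_id, dl, function(z) length(unique(z)))
  bad <- names(tags_per_day)[tags_per_day < cfg$min_tags_per_day]
  keep <- !(as.character(dl) %in% bad)
  list(track = track[keep, , drop = FALSE], removed = which(!keep),
       dropped_days = as.Date(bad))
}

#' Run the full filter chain with attrition accounting
#'
#' Order: daylight restriction first, then speed, then the pooled StdLoc
#' fence (computed on the speed-filtered dataset), NBS, jump, and finally
#' the minimum-active-tags day rule. Stage fractions are reported relative
#' to the raw count entering the chain after the daylight restriction,
#' mirroring the way field attrition is usually reported.
#'
#' @param fixes data.frame of fixes (`tag_id`, `t`, `x`, `y`, `stdloc`,
#'   `nbs`), time-ordered within tag.
#' @param cfg A [filter_config()].
#' @param site A [site_config()].
#' @param fence Optional fixed StdLoc upper limit; by default the Tukey
#'   fence is estimated from the speed-filtered dataset. Passing the fence
#'   of a previous run makes the chain idempotent (a re-estimated fence
#'   always trims a little more of its own output).
#' @return list: `fixes` (retained), `attrition` (list with `raw_n`,
#'   per-stage data.frame `stages` (`stage`, `removed`, `frac_of_raw`),
#'   `stdloc_fence`, `total_removed_frac` (fix-level stages),
#'   `day_rule_frac`, `grand_total_frac`, `retained_frac`,
#'   `dropped_days`, `retained_per_tag_day`).
#' @export
run_filter_chain <- function(fixes, cfg = filter_config(),
                             site = site_config(), fence = NULL) {
  .check_track(fixes)
  day <- restrict_daylight(fixes, site)
  raw_n <- nrow(day$track)
  if (raw_n == 0) stop("no fixes remain after the daylight restriction")
  s1 <- filter_speed(day$track, cfg)
  if (is.null(fence)) fence <- stdloc_fence(s1$track$stdloc, cfg$iqr_k)
  s2 <- filter_stdloc(s1$track, fence)
  s3 <- filter_nbs(s2$track, cfg)
  s4 <- filter_jump(s3$track, cfg)
  s5 <- filter_min_tags(s4$track, cfg, site)
  removed <- c(speed = length(s1$removed), stdloc = length(s2$removed),
               nbs = length(s3$removed), jump = length(s4$removed))
  day_removed <- length(s5$removed)
  retained <- s5$track
  dl <- local_date(retained$t, site)
  per_td <- as.data.frame(table(tag_id = retained$tag_id, date = dl))
  per_td <- per_td[per_td$Freq > 0, ]
  names(per_td)[3] <- "n_fixes"
  attrition <- list(
    raw_n = raw_n,
    pre_daylight_removed = length(day$removed),
    stages = data.frame(stage = names(removed), removed = unname(removed),
                        frac_of_raw = unname(removed) / raw_n),
    stdloc_fence = fence,
    total_removed_frac = sum(removed) / raw_n,
    day_rule_frac = day_removed / raw_n,
    grand_total_frac = (sum(removed) + day_removed) / raw_n,
    retained_frac = nrow(retained) / raw_n,
    dropped_days = s5$dropped_days,
    retained_per_tag_day = per_td)
  list(fixes = retained, attrition = attrition)
}
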