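# Builders for small hand-constructed tracks used across test files.

fix_time <- function(sec, origin = "2019-04-10 09:00:00") {
  as.POSIXct(origin, tz = "UTC") + sec
}

# A track from parallel vectors; defaults give clean mid-day fixes.
make_track <- function(t_s, x, y, tag = "tagA", stdloc = 8, nbs = 7,
                       origin = "2019-04-10 09:00:00") {
  data.frame(tag_id = tag, t = fix_time(t_s, origin), x = x, y = y,
             stdloc = rep_len(stdloc, length(x)),
             nbs = rep_len(as.integer(nbs), length(x)))
}

# Random slow-moving track for property tests: speeds stay far below the
# 30 m/s limit except where a displaced fix is injected.
random_track <- function(n, step_sd = 40, dt = 8) {
  make_track(seq(0, by = dt, length.out = n),
             cumsum(rnorm(n, 0, step_sd)), cumsum(rnorm(n, 0, step_sd)))
}

# Brute-force oracle for the speed filter: repeatedly find the EARLIEST
# consecutive pair whose speed strictly exceeds vmax and drop its later
# fix, recomputing from scratch each time.
oracle_speed_filter <- function(track, vmax) {
  repeat {
    n <- nrow(track)
    if (n <= 1) return(track)
    d <- sqrt(diff(track$x)^2 + diff(track$y)^2)
    sp <- d / diff(as.numeric(track$t))
    bad <- which(sp > vmax)
    if (!length(bad)) return(track)
    track <- track[-(bad[1] + 1), , drop = FALSE]
  }
}

# The 12-fix filter fixture: exactly one violation of each fix-level rule.
#  - fix 3: displaced 1 km between 8-s neighbours (speed filter)
#  - fix 5: StdLoc 200 m, above the pooled IQR fence (StdLoc filter)
#  - fix 7: only 3 base stations (NBS filter)
#  - fix 9: displaced ~600 m between 60-s neighbours, plausible speed on
#    both sides but > 500 m steps both ways (jump filter)
filter_fixture <- function() {
  t_s <- c(0, 8, 16, 24, 32, 40, 48, 56, 116, 176, 184, 192)
  x <- c(0, 40, 1040, 120, 160, 200, 240, 280, 880, 320, 360, 400)
  y <- rep(0, 12)
  stdloc <- c(5, 6, 7, 7, 200, 5, 8, 6, 9, 8, 5, 9)
  nbs <- c(7, 6, 5, 7, 6, 4, 3, 7, 5, 6, 7, 8)
  make_track(t_s, x, y, stdloc = stdloc, nbs = nbs)
}
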