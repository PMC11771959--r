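test_that("colony distance stats are the pooled mean and max", {
  site <- site_config()
  at_colony <- make_track(c(0, 8), c(0, 0), c(0, 0))
  expect_equal(unname(colony_distance_stats(at_colony, site)), c(0, 0))
  two <- make_track(c(0, 8), c(100, 300), c(0, 0))
  expect_equal(unname(colony_distance_stats(two, site)), c(200, 300))
})

test_that("visits are reception gaps bounded by near-colony fixes", {
  near <- make_track(c(0, 70), c(20, 15), c(0, 10))
  v <- detect_visits(near)
  expect_equal(nrow(v), 1)
  expect_equal(v$duration_s, 70)

  far <- make_track(c(0, 300), c(2000, 2050), c(0, 0))
  expect_equal(nrow(detect_visits(far)), 0)   # foraging gap, not a visit

  exact <- make_track(c(0, 60), c(10, 10), c(0, 0))
  expect_equal(nrow(detect_visits(exact)), 1) # exactly 60 s counts
  short <- make_track(c(0, 59), c(10, 10), c(0, 0))
  expect_equal(nrow(detect_visits(short)), 0)
})

test_that("daily route follows the path and the 10-hr coverage rule", {
  # out-and-back to 1 km, fixes every 100 m, spread over 11 h
  xs <- c(seq(0, 1000, by = 100), seq(900, 0, by = -100))
  tr <- make_track(seq(0, by = 11 * 3600 / 20, length.out = 21), xs,
                   rep(0, 21), origin = "2019-04-10 03:30:00")
  expect_equal(daily_route(tr, gap_tolerance_s = 1e9), 2000)

  # square loop 4 x 500 m
  sq <- make_track(seq(0, by = 10.5 * 3600 / 8, length.out = 9),
                   c(0, 250, 500, 500, 500, 250, 0, 0, 0),
                   c(0, 0, 0, 250, 500, 500, 500, 250, 0),
                   origin = "2019-04-10 03:30:00")
  expect_equal(daily_route(sq, gap_tolerance_s = 1e9), 2000)

  # only 8 h of activity: excluded, not an error
  short <- make_track(c(0, 8 * 3600), c(0, 100), c(0, 0))
  expect_true(is.na(daily_route(short)))
})

test_that("visit frequency averages per-tag rates", {
  act <- data.frame(tag_id = c("a", "b"), span_h = c(10, 10))
  expect_equal(visit_frequency(NULL, act), 0)
  vis <- data.frame(tag_id = c(rep("a", 5), rep("b", 10)))
  expect_equal(visit_frequency(vis, act), 0.75)
  one <- data.frame(tag_id = "a", span_h = 10)
  expect_equal(visit_frequency(vis[vis$tag_id == "a", , drop = FALSE], one), 0.5)
})

test_that("net foraging duration is the day-length identity", {
  tr <- make_track(c(0, 11.5 * 3600), c(0, 0), c(0, 0))
  vis <- NULL
  fd <- foraging_durations(tr, vis, day_length = 13)
  expect_equal(unname(fd), c(11.5, 1.5))
  # bird never leaves: one all-day visit
  allday <- make_track(c(0, 12 * 3600), c(5, 5), c(0, 0))
  v <- detect_visits(allday)
  fd2 <- foraging_durations(allday, v, day_length = 12)
  expect_equal(fd2[["foraging"]], 0)
  expect_equal(fd2[["net"]], 12)
})

test_that("mean flight speed excludes visit gaps", {
  tr <- make_track(c(0, 10, 20), c(0, 100, 200), c(0, 0, 0))
  expect_equal(mean_flight_speed(tr), 10)
  still <- make_track(c(0, 10, 20), c(5, 5, 5), c(0, 0, 0))
  expect_equal(mean_flight_speed(still), 0)
  # 70-s visit gap at the colony between two 10 m/s legs
  vtr <- make_track(c(0, 10, 80, 90), c(100, 0, 0, 100), c(0, 0, 0, 0))
  vis <- detect_visits(vtr)
  expect_equal(nrow(vis), 1)
  expect_equal(mean_flight_speed(vtr, vis), 10)
})

test_that("roost offsets use the 60-min windows and roost spans the night", {
  site <- site_config()
  d1 <- as.Date("2019-04-10"); d2 <- d1 + 1
  s1 <- sun_times(site, d1); s2 <- sun_times(site, d2)
  mk <- function(times) data.frame(tag_id = "tagA", t = times, x = 0, y = 0,
                                   stdloc = 5, nbs = 7)
  # departure 20 min after sunrise, arrival exactly at sunset,
  # next morning 30 min after sunrise
  tr <- mk(c(s1$sunrise + 1200, s1$sunrise + 5 * 3600, s1$sunset,
             s2$sunrise + 1800, s2$sunrise + 7200))
  rt <- roost_times(tr, site)
  expect_equal(rt$arrival_offset[1], 0)
  expect_equal(rt$departure_offset[1], 20)
  expect_equal(rt$departure_offset[2], 30)
  want <- as.numeric(difftime(s2$sunrise + 1800, s1$sunset, units = "hours"))
  expect_equal(rt$roost_dur[1], want)

  # arrival 90 min after sunset: outside the window, missing
  late <- mk(c(s1$sunrise + 1200, s1$sunset + 90 * 60))
  expect_true(is.na(roost_times(late, site)$arrival_offset[1]))

  # a 19:00 entry and 05:30 exit span 10.5 h
  entry <- as.POSIXct("2019-04-10 19:00:00", tz = "UTC")
  expect_equal(as.numeric(difftime(entry + 10.5 * 3600, entry,
                                   units = "hours")), 10.5)
})

test_that("inter-individual distance handles the unit square and the 4-bird rule", {
  site <- site_config()
  t0 <- fix_time(0)
  mk <- function(tags, xs, ys) data.frame(tag_id = tags, t = t0, x = xs,
                                          y = ys, stdloc = 5, nbs = 7)
  same <- mk(c("a", "b", "c", "d"), rep(10, 4), rep(20, 4))
  expect_equal(interindividual_distance(same, site), 0)
  square <- mk(c("a", "b", "c", "d"), c(0, 100, 100, 0), c(0, 0, 100, 100))
  expect_equal(interindividual_distance(square, site),
               (4 * 100 + 2 * 100 * sqrt(2)) / 6, tolerance = 1e-9)
  three <- mk(c("a", "b", "c"), c(0, 100, 100), c(0, 0, 100))
  expect_true(is.na(interindividual_distance(three, site)))
})

test_that("inter-individual distance is label- and translation-invariant", {
  site <- site_config()
  set.seed(5)
  n <- 6
  df <- data.frame(tag_id = rep(letters[1:n], each = 20),
                   t = rep(fix_time(seq(0, by = 30, length.out = 20)), n),
                   x = rnorm(6 * 20, 0, 500), y = rnorm(6 * 20, 0, 500),
                   stdloc = 5, nbs = 7)
  base <- interindividual_distance(df, site)
  perm <- df
  perm$tag_id <- c(f = "a", a = "b", b = "c", c = "d", d = "e",
                   e = "f")[perm$tag_id]
  shifted <- df
  shifted$x <- shifted$x + 1e4; shifted$y <- shifted$y - 2e4
  expect_equal(interindividual_distance(perm, site), base)
  expect_equal(interindividual_distance(shifted, site), base)
})

test_that("route is at least twice the max colony distance on out-and-back trips", {
  cfg <- truth_config(n_days = 1, tags_per_day = 1, noise_sd_m = 0,
                      outlier_rate = 0, stdloc_high_rate = 0,
                      nbs_low_rate = 0, fix_interval_s = 8, seed = 41)
  w <- generate_tracks(cfg, generate_motr_days(cfg))
  tr <- w$fixes
  vis <- detect_visits(tr)
  route <- daily_route(tr, vis)
  maxd <- max(sqrt(tr$x^2 + tr$y^2))
  expect_gte(route, 2 * maxd - 2 * cfg$cruise_speed_ms * cfg$fix_interval_s)
})
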