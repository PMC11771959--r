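test_that("step kinematics follow the consecutive-pair definition", {
  tr <- make_track(c(0, 10), c(0, 300), c(0, 0))
  st <- step_kinematics(tr)
  expect_equal(st$speed_ms, 30)
  expect_equal(nrow(step_kinematics(make_track(0, 0, 0))), 0)
  # 3-4-5 right-angle path: consecutive distances are the legs, never the
  # hypotenuse
  tri <- make_track(c(0, 8, 16), c(0, 3, 3), c(0, 0, 4))
  expect_equal(step_kinematics(tri)$dist_m, c(3, 4))
})

test_that("duplicate timestamps are an input error naming the tag", {
  tr <- make_track(c(0, 8, 8), c(0, 1, 2), c(0, 0, 0), tag = "tagX")
  expect_error(step_kinematics(tr), "tagX")
})

test_that("speed filter removes a displaced fix and respects the strict boundary", {
  clean <- make_track(seq(0, 80, by = 8), seq(0, 1000, by = 100), rep(0, 11))
  expect_length(filter_speed(clean, filter_config())$removed, 0)

  spiked <- clean
  spiked$y[6] <- 1000  # 1 km displacement between 8-s neighbours
  res <- filter_speed(spiked)
  expect_equal(res$removed, 6L)

  at_limit <- make_track(c(0, 8), c(0, 240), c(0, 0))  # exactly 30 m/s
  expect_length(filter_speed(at_limit)$removed, 0)
})

test_that("speed filter matches the brute-force later-drop oracle on short tracks", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    tr <- random_track(n, step_sd = 150)  # some steps exceed 30 m/s
    got <- filter_speed(tr)$track
    want <- oracle_speed_filter(tr, 30)
    expect_equal(got$t, want$t)
  }
})

test_that("StdLoc fence uses interpolated quantiles and handles degenerate spread", {
  expect_equal(stdloc_fence(1:8), 6.25 + 1.5 * (6.25 - 2.75))  # 11.5
  expect_equal(stdloc_fence(rep(3.3, 10)), 3.3)
  expect_error(stdloc_fence(c(1, 2, 3)), "at least 4")
})

test_that("StdLoc and NBS filters keep exactly the compliant fixes", {
  tr <- make_track(seq(0, 40, 8), 1:6, rep(0, 6),
                   stdloc = c(2, 11, 3, 25, 4, 11.5), nbs = c(3, 4, 5, 3, 7, 4))
  s <- filter_stdloc(tr, 11.5)
  expect_equal(s$removed, 4L)            # only 25 exceeds; 11.5 == fence kept
  n <- filter_nbs(tr, filter_config())
  expect_equal(n$removed, c(1L, 4L))     # nbs = 3 dropped, nbs = 4 kept
  expect_true(all(filter_nbs(tr)$track$nbs >= 4))
})

test_that("jump filter removes a teleport spike but not a genuine movement gap", {
  # ~600 m spike with plausible speeds on both sides (60-s gaps)
  tr <- make_track(c(0, 8, 68, 128, 136), c(0, 40, 680, 120, 160), rep(0, 5))
  res <- filter_jump(tr)
  expect_equal(res$removed, 3L)

  # one genuine > 500 m step flanked by ordinary steps: nothing removed
  gap <- make_track(c(0, 8, 68, 76), c(0, 40, 640, 680), rep(0, 4))
  expect_length(filter_jump(gap)$removed, 0)

  # exactly 500 m is retained (strict inequality)
  at <- make_track(c(0, 60, 120), c(0, 500, 1000), rep(0, 3))
  expect_length(filter_jump(at)$removed, 0)
})

test_that("daylight restriction keeps the closed sunrise-sunset interval", {
  site <- site_config()
  day <- as.Date("2019-04-10")
  st <- sun_times(site, day)
  tr <- data.frame(tag_id = "tagA",
                   t = c(st$sunrise - 3600, st$sunrise, st$sunrise + 6 * 3600,
                         st$sunset, st$sunset + 60),
                   x = 1:5, y = 0, stdloc = 5, nbs = 7)
  res <- restrict_daylight(tr, site)
  expect_equal(res$removed, c(1L, 5L))
  expect_equal(nrow(res$track), 3)
})

test_that("days with fewer than four active tags are dropped entirely", {
  mk <- function(day, tags) do.call(rbind, lapply(tags, function(tg)
    make_track(c(0, 8), c(0, 10), c(0, 0), tag = tg,
               origin = paste(day, "09:00:00"))))
  tr <- rbind(mk("2019-04-10", c("a", "b", "c")),
              mk("2019-04-11", c("a", "b", "c", "d")))
  tr <- tr[order(tr$tag_id, tr$t), ]
  res <- filter_min_tags(tr)
  expect_equal(as.character(res$dropped_days), "2019-04-10")
  expect_true(all(local_date(res$track$t, site_config()) == as.Date("2019-04-11")))
  empty <- filter_min_tags(tr[0, ])
  expect_equal(nrow(empty$track), 0)
})

test_that("chain attrition accounting is consistent and idempotent under a fixed fence", {
  cfg <- truth_config(n_days = 2, tags_per_day = 4, fix_interval_s = 16,
                      outlier_rate = 0.05, seed = 29)
  w <- generate_tracks(cfg, generate_motr_days(cfg))
  res <- run_filter_chain(w$fixes)
  at <- res$attrition
  expect_equal(sum(at$stages$frac_of_raw) + at$day_rule_frac +
                 at$retained_frac, 1, tolerance = 1e-12)
  expect_equal(sum(at$stages$removed), round(at$total_removed_frac * at$raw_n))
  again <- run_filter_chain(res$fixes, fence = at$stdloc_fence)
  expect_equal(sum(again$attrition$stages$removed), 0)
  expect_length(again$attrition$dropped_days, 0)
})

test_that("raising the speed limit never removes more fixes", {
  set.seed(123)
  tr <- random_track(200, step_sd = 120)
  r30 <- length(filter_speed(tr, filter_config(vmax = 30))$removed)
  r60 <- length(filter_speed(tr, filter_config(vmax = 60))$removed)
  expect_lte(r60, r30)
  j500 <- length(filter_jump(tr, filter_config(max_step = 500))$removed)
  j900 <- length(filter_jump(tr, filter_config(max_step = 900))$removed)
  expect_lte(j900, j500)
})
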