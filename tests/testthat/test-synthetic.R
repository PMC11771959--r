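test_that("zero-variance MoTR config degenerates to a constant series", {
  cfg <- truth_config(n_days = 7, motr_sd = 0, seed = 2)
  expect_equal(generate_motr_days(cfg), rep(cfg$motr_mean, 7))
})

test_that("truncated daily MoTR keeps the configured mean and stays in range", {
  cfg <- truth_config(n_days = 10000, seed = 3)
  x <- generate_motr_days(cfg)
  expect_true(all(x >= cfg$motr_range[1] & x <= cfg$motr_range[2]))
  se <- cfg$motr_sd / sqrt(10000)
  expect_lt(abs(mean(x) - 1207.7), 3 * se)
})

test_that("mean outside the truncation range is a configuration error", {
  expect_error(truth_config(motr_mean = 100, motr_range = c(164.4, 2518.9)),
               "configuration error")
})

test_that("generators are reproducible under a fixed seed", {
  cfg <- truth_config(n_days = 3, tags_per_day = 4, fix_interval_s = 60,
                      seed = 7)
  m1 <- generate_motr_days(cfg); m2 <- generate_motr_days(cfg)
  expect_identical(m1, m2)
  w1 <- generate_tracks(cfg, m1); w2 <- generate_tracks(cfg, m2)
  expect_identical(w1$fixes, w2$fixes)
  expect_identical(w1$truth$outlier_rows, w2$truth$outlier_rows)
  e1 <- generate_echoes(cfg$start_date, 800, seed = 9)
  e2 <- generate_echoes(cfg$start_date, 800, seed = 9)
  expect_identical(e1, e2)
})

test_that("negative distance coefficient shows up in the truth record itself", {
  cfg <- truth_config(n_days = 200, tags_per_day = 1, fix_interval_s = 120,
                      seed = 13)
  motr <- generate_motr_days(cfg)
  w <- generate_tracks(cfg, motr)
  td <- w$truth$tag_days
  td$motr <- motr[match(td$date, cfg$start_date + seq_len(cfg$n_days) - 1)]
  expect_lt(spearman_test(td$motr, td$apogee_m)$rho, 0)
})

test_that("a null distance coefficient yields a slope CI covering zero", {
  cfg <- truth_config(n_days = 200, tags_per_day = 1, beta_distance = 0,
                      fix_interval_s = 120, seed = 17)
  motr <- generate_motr_days(cfg)
  td <- generate_tracks(cfg, motr)$truth$tag_days
  td$motr <- motr[match(td$date, cfg$start_date + seq_len(cfg$n_days) - 1)]
  ci <- confint(lm(log(apogee_m) ~ motr, td))["motr", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("a noiseless outlier-free world passes the speed and jump rules untouched", {
  cfg <- truth_config(n_days = 1, tags_per_day = 4, noise_sd_m = 0,
                      outlier_rate = 0, seed = 19)
  w <- generate_tracks(cfg, generate_motr_days(cfg))
  expect_length(filter_speed(w$fixes)$removed, 0)
  expect_length(filter_jump(w$fixes)$removed, 0)
})

test_that("every injected outlier index exists in the emitted fix table", {
  cfg <- truth_config(n_days = 2, tags_per_day = 3, fix_interval_s = 30,
                      seed = 23)
  w <- generate_tracks(cfg, generate_motr_days(cfg))
  expect_true(all(w$truth$outlier_rows >= 1 &
                    w$truth$outlier_rows <= nrow(w$fixes)))
  expect_gt(length(w$truth$outlier_rows), 0)
})

test_that("echo generator degenerates correctly", {
  expect_equal(nrow(generate_echoes(as.Date("2019-04-01"), 0)), 0)
  e <- generate_echoes(as.Date("2019-04-01"), 500, seed = 31)
  e$class <- "bird"
  expect_equal(motr_series(e)$daily$motr, 0)
})

test_that("sub-threshold echoes are generated and excluded by the filter", {
  beam <- beam_config()
  e <- generate_echoes(as.Date("2019-04-01"), 1000, beam,
                       frac_low_rcs = 0.2, seed = 37)
  expect_gt(sum(e$class == "insect" & e$rcs_mm2 < beam$rcs_min), 0)
  sel <- select_insect_echoes(e, beam)
  expect_true(all(sel$rcs_mm2 >= beam$rcs_min))
})
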