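test_that("an hour scores presence from one confident call, counts ignored", {
  dep <- tiny_deployment()
  a <- rbind(ann("20170701T020000", 10), ann("20170701T020000", 60),
             ann("20170701T020000", 300))
  hp <- hourly_presence(a, dep)
  i <- match(as.POSIXct("2017-07-01 02:00:00", tz = "UTC"), hp$hours)
  expect_equal(as.vector(hp$mat[i, "FW"]), 1L)
  expect_equal(sum(hp$mat), 1L)
})

test_that("chorus and uncertain annotations are excluded", {
  dep <- tiny_deployment()
  a <- rbind(ann("20170701T020000", 10, chorus = TRUE),
             ann("20170701T030000", 10, certainty = "uncertain"))
  hp <- hourly_presence(a, dep)
  expect_true(all(hp$mat == 0))
  ## strictness flag retains uncertain (but never chorus)
  hp2 <- hourly_presence(a, dep, drop_uncertain = FALSE)
  expect_equal(sum(hp2$mat), 1L)
})

test_that("empty logs give all-zero presence; out-of-window rows rejected", {
  dep <- tiny_deployment()
  hp <- hourly_presence(ann("20170701T020000", 5)[0, ], dep)
  expect_true(all(hp$mat == 0))
  expect_warning(
    hp2 <- hourly_presence(ann("20170810T020000", 5), dep),
    "rejected")
  expect_equal(nrow(hp2$rejected), 1L)
  expect_true(all(hp2$mat == 0))
})

test_that("daily percentages use hours actually recorded as denominator", {
  dep <- tiny_deployment()                       # 4 full days
  h <- sprintf("%02d", 0:23)
  files <- paste0("20170702T", h, "0000")
  ## 6 positive hours of 24
  a <- do.call(rbind, lapply(files[1:6], ann, start_s = 5))
  d <- daily_presence(hourly_presence(a, dep))
  row <- d[d$date == as.Date("2017-07-02") & d$species == "FW", ]
  expect_equal(row$positive_hours, 6)
  expect_equal(row$recorded_hours, 24)
  expect_equal(row$percentage, 25)
  ## 24 of 24
  a2 <- do.call(rbind, lapply(files, ann, start_s = 5))
  d2 <- daily_presence(hourly_presence(a2, dep))
  expect_equal(d2$percentage[d2$date == as.Date("2017-07-02")], 100)
  ## partial day: deployment starts at 16:00, 2 of 8 recorded hours
  dep3 <- deployment_spec("2017-07-01 16:00:00", "2017-07-02 00:00:00",
                          duty_on = 12)
  a3 <- rbind(ann("20170701T170000", 5), ann("20170701T210000", 5))
  d3 <- daily_presence(hourly_presence(a3, dep3))
  expect_equal(d3$recorded_hours, 8)
  expect_equal(d3$percentage, 25)
})

test_that("duty-cycle audit classifies files by the time mark", {
  dep <- tiny_deployment()
  ## detection at 9.0 min in a 12-min file: only after the 8-min mark
  a <- ann("20170701T020000", 9 * 60)
  out <- duty_cycle_audit(a, dep, mark_minutes = 8)
  expect_equal(out$only_after_mark, 1)
  expect_equal(out$before_mark, 0)
  ## 3.2 min: before the mark
  out2 <- duty_cycle_audit(ann("20170701T020000", 3.2 * 60), dep, 8)
  expect_equal(out2$before_mark, 1)
  ## any pre-mark detection claims the file for before-mark
  a3 <- rbind(ann("20170701T020000", 3.2 * 60),
              ann("20170701T020000", 9 * 60))
  out3 <- duty_cycle_audit(a3, dep, 8)
  expect_equal(out3$n_files, 1)
  expect_equal(out3$before_mark, 1)
  expect_equal(out3$only_after_mark, 0)
  ## brute-force over the file's annotations agrees
  brute <- !any(a3$start_s < 8 * 60)
  expect_equal(out3$only_after_mark == 1, brute)
  expect_error(duty_cycle_audit(a, dep, mark_minutes = 20), "exceeds")
})

test_that("monthly totals distinguish zero detections from no recording", {
  dep <- deployment_spec("2017-06-01 00:00:00", "2017-08-01 00:00:00",
                         duty_on = 12)
  h <- sprintf("%02d", 0:23)
  files <- as.vector(outer(
    paste0("201707", sprintf("%02d", 1:31)), paste0("T", h, "0000"),
    paste0))
  a <- do.call(rbind, lapply(files, ann, start_s = 5))
  hp <- hourly_presence(a, dep)
  mh <- monthly_hours(hp)
  expect_equal(mh["FW", "2017-07"], 744L)       # 31 x 24, all positive
  expect_equal(mh["FW", "2017-06"], 0L)         # recorded, nothing heard
  expect_true(is.na(mh["FW", "2017-11"]))       # recorder off
})

test_that("presence statistics are monotone, consistent and idempotent", {
  dep <- tiny_deployment()
  set.seed(31)
  hrs <- deployment_hours(dep)
  pick <- sample(hrs, 30)
  a <- do.call(rbind, lapply(format(pick, "%Y%m%dT%H%M%S"), ann,
                             start_s = 5))
  hp <- hourly_presence(a, dep)
  d <- daily_presence(hp)
  mh <- monthly_hours(hp)
  ## aggregation consistency: daily sums match the monthly entry
  jul <- sum(d$positive_hours[format(d$date, "%Y-%m") == "2017-07" &
                                d$species == "FW"])
  expect_equal(jul, unname(mh["FW", "2017-07"]))
  ## idempotence
  expect_identical(hourly_presence(a, dep)$mat, hp$mat)
  ## adding an annotation never decreases any statistic
  extra <- ann(format(setdiff(hrs, pick)[1] |> as.POSIXct(tz = "UTC"),
                      "%Y%m%dT%H%M%S"), 5)
  hp2 <- hourly_presence(rbind(a, extra), dep)
  expect_true(all(hp2$mat >= hp$mat))
  expect_gte(sum(daily_presence(hp2)$positive_hours),
             sum(d$positive_hours))
})

test_that("generator schedules survive the annotation round trip exactly", {
  cfg <- tiny_config(seed = 12,
                     dates = seq(as.Date("2017-07-01"),
                                 as.Date("2017-07-31"), by = "day"))
  env <- make_env_fields(cfg)
  sch <- make_call_schedule(cfg, env)
  dep <- deployment_spec("2017-07-01 00:00:00", "2017-08-01 00:00:00",
                         duty_on = 8, lat = cfg$recorder[1],
                         lon = cfg$recorder[2])
  a <- schedule_to_annotations(sch, dep)
  hp <- hourly_presence(a, dep, species = cfg$registry$species)
  keep <- sch$time %in% hp$hours
  expect_equal(unname(hp$mat), unname(sch$presence[keep, ]))
  ## monthly totals match the generator ground truth
  mh <- monthly_hours(hp)
  expect_equal(unname(mh[, "2017-07"]),
               unname(colSums(sch$presence[keep, ])))
})

test_that("recording-period day counts are inclusive", {
  expect_equal(n_recording_days("2017-02-10", "2017-10-12"), 245L)
  expect_equal(n_recording_days("2016-02-16", "2016-08-23"), 190L)
  expect_equal(n_recording_days("2017-07-01", "2017-07-01"), 1L)
  dep <- read_deployments(system.file("extdata", "deployments.yaml",
                                      package = "pamscape"))
  expect_equal(n_recording_days(dep$aural_2017), 245L)
})

test_that("annotation validation catches malformed logs", {
  expect_error(validate_ann <- hourly_presence(
    data.frame(file = "x", start_s = 5, end_s = 3, low_hz = 10,
               high_hz = 20, species = "FW", certainty = "confident",
               chorus = FALSE), tiny_deployment()), "start_s")
  expect_error(hourly_presence(ann("20170701T020000", 5, low = 30,
                                   high = 10), tiny_deployment()),
               "low_hz")
  expect_error(read_annotations(textConnection("x"), labels = NULL),
               "lacks columns")
})
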