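# Regularization of raw fixes into nightly 15-minute tracks.

mk_fixes <- function(times, x = NULL, y = NULL, id = "A1") {
  n <- length(times)
  data.frame(animal_id = id, sex = "F",
             timestamp = as.POSIXct(times, tz = "UTC"),
             x = x %||% seq(0, by = 10, length.out = n),
             y = y %||% rep(0, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("angle wrapping lands in (-pi, pi] and is 2*pi periodic", {
  set.seed(1)
  x <- runif(500, -30, 30)
  w <- wrap_angle(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(wrap_angle(x + 2 * pi), w, tolerance = 1e-9)
  expect_equal(wrap_angle(pi), pi)
  expect_equal(wrap_angle(-pi), pi)  # boundary maps to +pi by convention
})

test_that("a night has 57 slots and fixes snap to the nearest slot", {
  # fixes at 16:00 and 16:29: slots 1 and 3 (16:29 is nearer 16:30), slot 2
  # missing
  tr <- build_tracks(mk_fixes(c("2016-06-01 16:00:00", "2016-06-01 16:29:00")))
  expect_equal(nrow(tr), 57)
  expect_equal(attr(tr, "n_slots"), 57L)
  expect_equal(which(!is.na(tr$x)), c(1L, 3L))
  # 50 recorded fixes in one night leave 7 missing slots
  times <- as.POSIXct("2016-06-01 16:00:00", tz = "UTC") +
    900 * (seq_len(57) - 1)
  tr <- build_tracks(mk_fixes(times[1:50]))
  expect_equal(sum(is.na(tr$x)), 7)
  # slots after midnight belong to the night that began at 16:00
  tr <- build_tracks(mk_fixes(c("2016-06-01 23:45:00", "2016-06-02 00:15:00",
                                "2016-06-02 05:45:00")))
  expect_equal(length(unique(tr$night)), 1)
  expect_equal(tr$night[1], as.Date("2016-06-01"))
})

test_that("duplicate and off-grid fixes are resolved as specified", {
  # two fixes compete for slot 2: keep the nearer one (16:16)
  fx <- mk_fixes(c("2016-06-01 16:16:00", "2016-06-01 16:20:00"),
                 x = c(1, 2), y = c(0, 0))
  tr <- build_tracks(fx)
  expect_equal(tr$x[2], 1)
  # equidistant duplicates: the earlier fix wins
  fx <- mk_fixes(c("2016-06-01 16:12:00", "2016-06-01 16:18:00"),
                 x = c(5, 6), y = c(0, 0))
  tr <- build_tracks(fx)
  expect_equal(tr$x[2], 5)
  # daytime fix outside the nightly window is dropped with a warning
  expect_warning(
    tr <- build_tracks(mk_fixes(c("2016-06-01 16:00:00",
                                  "2016-06-01 11:00:00"))),
    "dropped")
  expect_equal(sum(!is.na(tr$x)), 1)
})

test_that("build_tracks is idempotent on its own output", {
  s <- small_sim()
  tr1 <- s$tracks
  obs <- tr1[!is.na(tr1$x), c("animal_id", "sex", "timestamp", "x", "y")]
  tr2 <- build_tracks(obs)
  expect_equal(tr2$x, tr1$x)
  expect_equal(tr2$step, tr1$step)
  expect_equal(tr2$angle, tr1$angle)
})

test_that("steps and angles follow the stated geometry conventions", {
  times <- as.POSIXct("2016-06-01 16:00:00", tz = "UTC") + 900 * (0:3)
  # 3-4-5 triangle step
  tr <- build_tracks(mk_fixes(times[1:2], x = c(0, 3), y = c(0, 4)))
  expect_equal(tr$step[2], 5)
  # collinear motion: zero turning angle
  tr <- build_tracks(mk_fixes(times[1:3], x = c(0, 1, 2), y = c(0, 0, 0)))
  expect_equal(tr$angle[3], 0)
  # left turn is positive (counterclockwise)
  tr <- build_tracks(mk_fixes(times[1:3], x = c(0, 1, 1), y = c(0, 0, 1)))
  expect_equal(tr$angle[3], pi / 2)
  # first slot never carries a step or an angle; gaps are not bridged
  tr <- build_tracks(mk_fixes(times[c(1, 2, 4)], x = c(0, 1, 3),
                              y = c(0, 0, 0)))
  expect_true(is.na(tr$step[1]) && is.na(tr$angle[1]))
  expect_true(is.na(tr$step[3]) && is.na(tr$step[4]))
})

test_that("the speed filter removes teleporting fixes only", {
  times <- as.POSIXct("2016-06-01 17:00:00", tz = "UTC") + 900 * (0:4)
  fx <- mk_fixes(times, x = c(0, 50, 10050, 100, 150), y = rep(0, 5))
  out <- filter_fixes(fx, max_speed = 40, drop_first_last_night = FALSE)
  # 10 km in 15 min from both neighbors (~667 m/min) -> removed
  expect_equal(attr(out, "removed")[["speed"]], 1)
  expect_false(10050 %in% out$x)
  expect_equal(nrow(out), 4)
})

test_that("first/last-night dropping and exclusion masks work", {
  times <- as.POSIXct(c("2016-06-01 17:00:00", "2016-06-02 17:00:00",
                        "2016-06-03 17:00:00"), tz = "UTC")
  fx <- mk_fixes(times)
  out <- filter_fixes(fx, drop_first_last_night = TRUE)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "removed")[["first_last_night"]], 2)
  # exclusion mask: exactly the fixes inside the masked cells are removed
  mask <- matrix(0, 10, 10)
  mask[1, 1] <- 1   # cell covering [0,30) x [0,30)
  lake <- landscape_raster(list(mask = mask), resolution = 30)
  times <- as.POSIXct("2016-06-01 17:00:00", tz = "UTC") + 900 * (0:4)
  fx <- mk_fixes(times, x = c(10, 20, 25, 100, 200), y = c(10, 10, 10, 10, 10))
  out <- filter_fixes(fx, exclusion_mask = lake, drop_first_last_night = FALSE)
  expect_equal(attr(out, "removed")[["exclusion"]], 3)
  expect_equal(out$x, c(100, 200))
})

test_that("simulator round trip recovers drawn steps and angles exactly", {
  s <- small_sim()  # gps_error_sd = 0 in this fixture
  tr <- s$tracks
  st <- s$sim$states
  key_tr <- paste(tr$animal_id, format(tr$timestamp))
  key_st <- paste(st$animal_id, format(st$timestamp))
  m <- match(key_tr, key_st)
  ok <- !is.na(tr$step)
  expect_gt(sum(ok), 100)
  expect_equal(tr$step[ok], st$step_true[m][ok], tolerance = 1e-9)
  # drawn angles are recoverable from slot 3 onward (two prior fixes needed)
  ok <- !is.na(tr$angle) & tr$slot >= 3
  expect_gt(sum(ok), 100)
  expect_equal(tr$angle[ok], st$angle_true[m][ok], tolerance = 1e-9)
})
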