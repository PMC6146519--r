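# Filtering and regularization chain.

test_that("duplicate timestamps keep the first record only", {
  fx <- raw_fixes("a", c(0, 0, 1), x = c(0, 5, 1), y = c(0, 5, 1))
  out <- clean_fixes(fx)
  expect_equal(nrow(out$fixes), 2)
  expect_equal(out$fixes$x, c(0, 1))
  expect_equal(unname(out$report$counts["duplicate_timestamp"]), 1)
})

test_that("cleaning an empty input returns empty output and zero counts", {
  fx <- raw_fixes(character(0), numeric(0), numeric(0), numeric(0))
  out <- clean_fixes(fx)
  expect_equal(nrow(out$fixes), 0)
  expect_true(all(out$report$counts == 0))
})

test_that("a planted fixture of 100 fixes loses exactly its 10 bad rows", {
  good <- raw_fixes("a", seq(0, 89), x = seq(0, 89) * 0.1, y = 0)
  dups <- good[c(3, 10, 20, 30, 40, 50, 60), ]  # 7 duplicate timestamps
  dups$x <- dups$x + 99
  miss <- raw_fixes("a", c(200, 201, 202), x = NA_real_, y = NA_real_)
  fx <- rbind(good, dups, miss)
  fx <- fx[order(fx$timestamp), ]
  expect_equal(nrow(fx), 100)
  out <- clean_fixes(fx)
  expect_equal(nrow(out$fixes), 90)
  expect_equal(unname(out$report$counts["duplicate_timestamp"]), 7)
  expect_equal(unname(out$report$counts["missing_coordinates"]), 3)
})

test_that("a 25 km/h hop loses its later member", {
  fx <- raw_fixes("a", c(0, 2), x = c(0, 50), y = c(0, 0))
  out <- speed_filter(fx, max_speed = 20)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 0)
})

test_that("stationary fixes pass the speed filter unchanged", {
  fx <- raw_fixes("a", 0:20, x = 0, y = 0)
  expect_identical(speed_filter(fx), fx)
})

test_that("teleporting spikes are removed and no violating pair remains", {
  set.seed(11)
  n <- 100
  hours <- seq(0, by = 2, length.out = n)
  x <- cumsum(rnorm(n, 0, 3))  # <= ~9 km in 2 h, always under 20 km/h
  y <- cumsum(rnorm(n, 0, 3))
  spikes <- c(15, 35, 55, 75, 95)
  x[spikes] <- x[spikes] + 500
  fx <- raw_fixes("a", hours, x, y)
  out <- speed_filter(fx, max_speed = 20)
  expect_equal(nrow(out), n - length(spikes))
  expect_false(any((fx$timestamp[spikes]) %in% out$timestamp))
  # brute-force post-condition: all consecutive speeds within bound
  sp <- sqrt(diff(out$x)^2 + diff(out$y)^2) /
    (diff(as.numeric(out$timestamp)) / 3600)
  expect_true(all(sp <= 20))
})

test_that("segmentation follows the gap and span rules", {
  # 48-h continuous track: one segment
  one <- segment_tracks(raw_fixes("a", seq(0, 48, by = 4), x = 0, y = 0))
  expect_equal(length(unique(one$g)), 1)
  expect_equal(nrow(one), 13)
  # 13-h gap inside a 30-h record leaves two sub-24-h pieces: both dropped
  fx <- raw_fixes("b", c(seq(0, 8, by = 2), seq(21, 30, by = 2)), 0, 0)
  expect_equal(nrow(segment_tracks(fx)), 0)
  # three animals with hand-enumerated structure
  fx3 <- rbind(
    raw_fixes("c1", seq(0, 30, by = 3), 0, 0),                   # 1 segment
    raw_fixes("c2", c(seq(0, 26, by = 2), seq(40, 70, by = 2)), 0, 0), # 2
    raw_fixes("c3", c(0, 5, 10, 30, 35), 0, 0))                  # 0 (gap 20h)
  seg <- segment_tracks(fx3)
  got <- tapply(seg$g, seg$animal, function(g) length(unique(g)))
  expect_equal(as.numeric(got[c("c1", "c2")]), c(1, 2))
  expect_false("c3" %in% seg$animal)
})

test_that("the dive definition is strict in both depth and duration", {
  dv <- raw_dives("a", 1:4, depth = c(10.0, 543.5, 50, 50),
                  duration = c(100, 300, 20.0, 25))
  out <- filter_dives(dv)
  expect_equal(nrow(out$dives), 2)     # the 10.0 m and 20.0 s rows drop
  expect_true(543.5 %in% out$dives$depth)
  # a fixture of 20 records with 6 planted violations keeps 14
  set.seed(12)
  dv20 <- raw_dives("a", 1:20, depth = c(runif(14, 30, 200), rep(8, 3),
                                         rep(400, 3)),
                    duration = c(runif(14, 60, 300), rep(100, 3), rep(5, 3)))
  expect_equal(nrow(filter_dives(dv20)$dives), 14)
  # negative values are rejected as invalid, not merely filtered
  bad <- raw_dives("a", 1, depth = -5, duration = 100)
  rep2 <- filter_dives(bad)
  expect_equal(unname(rep2$report$counts["invalid_record"]), 1)
})

test_that("regularization assigns intervals and fractions as defined", {
  fx <- raw_fixes("a", c(0, 6, 13, 24, 30), x = 1:5, y = 0)
  fx$g <- 1L
  dv <- raw_dives("a", c(13, 29.99), depth = c(100, 50),
                  duration = c(60, 60))
  rt <- regularize(fx, dv)
  expect_equal(rt$n_intervals, 5)      # 30 h -> 5 intervals
  expect_equal(rt$fixes$t, c(1, 2, 3, 5, 5))
  expect_equal(rt$fixes$j[1], 0)       # fix at interval start
  expect_equal(rt$fixes$j[5], 1)       # fix at final endpoint closes last
  expect_equal(rt$fixes$j[3], 1 / 6)   # hour 13 = interval 3 + 1 h
  expect_equal(rt$dives$t, c(3, 5))    # dive at hour 13 -> t = 3
  expect_equal(rt$dives$u, c(1, 1))
  # dives outside the span are dropped and counted
  dv2 <- rbind(dv, raw_dives("a", 40, depth = 100, duration = 60))
  rt2 <- regularize(fx, dv2)
  expect_equal(nrow(rt2$dives), 2)
  expect_equal(rt2$n_dropped_dives, 1)
})

test_that("exclusion windows remove exactly the flagged records", {
  fx <- raw_fixes("a", 0:99, x = 0, y = 0)
  dv <- raw_dives("a", seq(0.5, 99.5), depth = 50, duration = 60)
  none <- exclude_flagged(fx, dv, NULL)
  expect_identical(none$fixes, fx)
  all_w <- data.frame(animal = "a", start = utc("2016-03-01"),
                      end = utc("2016-03-06"))
  gone <- exclude_flagged(fx, dv, all_w)
  expect_equal(nrow(gone$fixes), 0)
  tail_w <- data.frame(animal = "a",
                       start = utc("2016-03-01") + 80 * 3600,
                       end = utc("2016-03-06"))
  kept <- exclude_flagged(fx, dv, tail_w)
  expect_equal(nrow(kept$fixes), 80)   # hours 0..79 survive
  expect_equal(nrow(kept$dives), 80)   # 0.5..79.5 survive
})

test_that("cleaning, speed filtering and dive filtering are idempotent", {
  set.seed(13)
  n <- 60
  x <- cumsum(rnorm(n, 0, 3)); y <- cumsum(rnorm(n, 0, 3))
  x[c(10, 30)] <- x[c(10, 30)] + 300
  fx <- raw_fixes("a", seq(0, by = 2, length.out = n), x, y)
  once <- speed_filter(clean_fixes(fx)$fixes)
  twice <- speed_filter(clean_fixes(once)$fixes)
  expect_identical(once, twice)
  dv <- raw_dives("a", 1:30, depth = runif(30, 5, 100),
                  duration = runif(30, 10, 100))
  d_once <- filter_dives(dv)$dives
  expect_identical(filter_dives(d_once)$dives, d_once)
})

test_that("a clean noiseless simulation passes every filter unchanged", {
  tiny <- setNames(rep(1e-9, 6), c("3", "2", "1", "0", "A", "B"))
  cfg <- simulation_config(n_animals = 2, steps_per_animal = 30,
                           missing_interval_prob = 0,
                           dives_per_interval_rate = 3, seed = 14)
  cfg$argos_sds <- tiny
  ds <- simulate_dataset(cfg)
  d <- file.path(tempdir(), "roundtrip")
  write_dataset(ds, d)
  fx <- read_fixes(file.path(d, "fixes.csv"))
  dv <- read_dives(file.path(d, "dives.csv"))
  prep <- preprocess(fx, dv)
  expect_equal(prep$report$n_fixes_out, nrow(ds$fixes))
  expect_equal(prep$report$n_dives_out, nrow(ds$dives))
  expect_equal(prep$report$n_speed_removed, 0)
  expect_equal(length(prep$tracks), 2)
})
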