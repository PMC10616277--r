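test_that("15-s epochs resample to 1440 minute sums with counts conserved", {
  set.seed(42)
  cnt <- rpois(4 * 1440, 3)
  ms <- resample_to_minute(make_epochs(cnt, spacing = 15))
  expect_s3_class(ms, "minute_series")
  expect_equal(dim(ms$counts), c(1L, 1440L))
  expect_false(anyNA(ms$counts))
  expect_equal(sum(ms$counts), sum(cnt))                 # conservation
  expect_equal(ms$counts[1, 1], sum(cnt[1:4]))
  # spec arithmetic: epochs (5,0,2,3) within one minute sum to 10
  one <- resample_to_minute(make_epochs(c(5, 0, 2, 3)))
  expect_equal(one$counts[1, 1], 10)
})

test_that("60-s input passes through unchanged and resampling is idempotent", {
  set.seed(7)
  cnt <- rpois(1440, 5)
  ms <- resample_to_minute(make_epochs(cnt, spacing = 60))
  expect_equal(as.vector(ms$counts[1, ]), cnt)
  # feeding the minute stream back as 60-s epochs reproduces it exactly
  df <- as.data.frame(ms)
  again <- resample_to_minute(data.frame(
    patient_id = df$patient_id,
    timestamp = as.POSIXct(paste(df$date, "00:00:00"), tz = "UTC") +
      60 * df$minute_of_day,
    counts = df$counts))
  expect_identical(again$counts, ms$counts)
})

test_that("dropped epochs become missing minutes; bad input is rejected", {
  ep <- make_epochs(rpois(8 * 4, 2), spacing = 15)
  ep <- ep[-(5:8), ]                       # drop minute 2 entirely
  ms <- resample_to_minute(ep)
  expect_true(is.na(ms$counts[1, 2]))
  expect_false(is.na(ms$counts[1, 1]))

  # ISO-8601 "T" separator is accepted in character timestamps
  iso <- make_epochs(c(4, 5), spacing = 60)
  iso$timestamp <- format(iso$timestamp, "%Y-%m-%dT%H:%M:%S")
  expect_equal(resample_to_minute(iso)$counts[1, 1:2], c(4, 5))

  bad <- make_epochs(c(1, 2, 3), spacing = 15)
  bad$timestamp[3] <- bad$timestamp[2] + 7  # not a multiple of 15 s
  expect_error(resample_to_minute(bad), "irregular|spacing")
  expect_error(resample_to_minute(make_epochs(c(1, -2, 3))), "non-negative")
})

test_that("zero runs are flagged only beyond 60 minutes, strictly", {
  base <- rep(50, 1440)
  day61 <- base; day61[100:160] <- 0        # 61 consecutive zeros
  day60 <- base; day60[100:159] <- 0        # exactly 60
  ms <- make_minutes(list(day61, day60))
  gm <- detect_gaps(ms)
  expect_true(all(gm$mask[1, 100:160]))
  expect_false(any(gm$mask[2, 100:159]))
  expect_true(all(gm$runs$length >= 1))
})

test_that("spike rule is two-sided at 10 global SDs", {
  # construct a record whose global mean/SD are ~100/10, then check the rule
  # against statistics recomputed directly on the finished fixture
  v <- rep(c(90, 110), 1440)                # two days, mean 100, sd ~10
  v[10] <- 210
  v[20] <- 195
  ms <- make_minutes(list(v[1:1440], v[1441:2880]))
  gm <- detect_gaps(ms)
  mu <- mean(v); s <- sd(v)
  expect_true(abs(210 - mu) >= 10 * s)      # oracle for the fixture
  expect_true(abs(195 - mu) < 10 * s)
  expect_true(gm$mask[1, 10])
  expect_false(gm$mask[1, 20])
  # adding a constant shifts the mean but flags the same minutes
  ms2 <- make_minutes(list(v[1:1440] + 37, v[1441:2880] + 37))
  expect_equal(detect_gaps(ms2)$mask, gm$mask)
})

test_that("degenerate records are handled explicitly", {
  allna <- make_minutes(list(rep(NA_real_, 1440)))
  expect_error(detect_gaps(allna), "missing")
  flat <- make_minutes(list(rep(5, 1440)))
  expect_message(detect_gaps(flat), "zero-variance")
})

test_that("valid segment selection follows the 2-day / 72-min rules", {
  clean <- function() rep(30, 1440) + rep(c(0, 1), 720)
  rows <- replicate(7, clean(), simplify = FALSE)
  ms <- make_minutes(rows)
  gm <- detect_gaps(ms)
  seg <- valid_dfa_segment(ms, gm, ms$days[7])
  expect_equal(length(seg$days), 7L)                       # all clean
  expect_equal(length(seg$counts), 7L * 1440L)

  rows4 <- rows
  rows4[[4]][200:299] <- 0                                 # 100-min gap day 4
  ms4 <- make_minutes(rows4)
  gm4 <- detect_gaps(ms4)
  seg4 <- valid_dfa_segment(ms4, gm4, ms4$days[7])
  expect_equal(seg4$days, ms4$days[5:7])                   # most recent run

  # only one clean day in the window -> no qualifying segment
  rows1 <- lapply(1:7, function(i) {
    r <- clean()
    if (i < 7) r[1:100] <- 0                               # break days 1..6
    r
  })
  ms1 <- make_minutes(rows1)
  expect_null(valid_dfa_segment(ms1, detect_gaps(ms1), ms1$days[7]))

  # property: a returned segment never contains a gap run > 72 min
  miss <- is.na(seg4$counts)
  r <- rle(miss)
  expect_true(all(r$lengths[r$values] <= 72))
})

test_that("minute series round-trips through CSV", {
  set.seed(3)
  rows <- replicate(2, as.numeric(rpois(1440, 20)), simplify = FALSE)
  rows[[1]][5:10] <- NA
  ms <- make_minutes(rows)
  f <- tempfile(fileext = ".csv")
  write_minutes_csv(ms, f, mask = detect_gaps(ms))
  back <- read_minutes_csv(f)
  expect_equal(back$series$counts, ms$counts)
  expect_equal(back$series$days, ms$days)
  unlink(f)
})
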