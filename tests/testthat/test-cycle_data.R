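test_that("a well-formed table round-trips exactly", {
  paths <- write_tiny_tables()
  rec <- read_tracking_table(paths$tracking)
  expect_equal(nrow(rec), 3L)
  expect_equal(nrow(attr(rec, "rejected")), 0L)

  out <- tempfile(fileext = ".csv")
  write_tracking_table(rec, out)
  rec2 <- read_tracking_table(out)
  attr(rec, "rejected") <- attr(rec2, "rejected") <- NULL
  expect_identical(as.data.frame(rec), as.data.frame(rec2))
})

test_that("invariant violations are rejected with reasons, not dropped silently", {
  df <- tiny_tracking()
  df$breed_lat[1] <- -10                      # southern-hemisphere breeder
  df$arr_b[2] <- "2011-03-01"                 # before dep_nb: event order
  df$dep_b[3] <- "not-a-date"
  rec <- suppressMessages(validate_tracking(df))
  rej <- attr(rec, "rejected")
  expect_equal(nrow(rec), 0L)
  expect_equal(rej$row, 1:3)
  expect_equal(rej$reason, c("southern-hemisphere breeder", "event order",
                             "unparseable date"))

  # year must contain the departure from the non-breeding site
  df2 <- tiny_tracking()
  df2$year[1] <- 2009L
  rej2 <- attr(suppressMessages(validate_tracking(df2)), "rejected")
  expect_equal(rej2$reason, "year does not match dep_nb")

  # a cycle that does not close within a year is invalid
  df3 <- tiny_tracking()
  df3$arr_nb[1] <- "2011-05-01"
  rej3 <- attr(suppressMessages(validate_tracking(df3)), "rejected")
  expect_equal(rej3$reason, "event order")
})

test_that("missing columns and files are hard errors", {
  df <- tiny_tracking()
  df$breed_lat <- NULL
  expect_error(validate_tracking(df), "breed_lat")
  expect_error(read_tracking_table(tempfile()), "not found")
})

test_that("body mass resolution follows the sex rule", {
  tr <- tiny_traits()
  expect_equal(resolve_body_mass("spA", "female", tr), 100)
  expect_equal(resolve_body_mass("spA", "male", tr), 120)
  expect_equal(resolve_body_mass("spA", "unknown", tr), 110)
  expect_equal(resolve_body_mass(c("spA", "spB"), c("male", "unknown"), tr),
               c(120, 850))
  expect_error(resolve_body_mass("spZ", "male", tr), "spZ")
})

test_that("derived durations, day indices and distances are correct", {
  paths <- write_tiny_tables()
  rec <- read_tracking_table(paths$tracking)
  d <- derive_cycle(rec, tiny_traits())

  # 27 Mar -> 2 May in a non-leap year: 36 days
  expect_equal(d$spring_duration[1], 36)
  expect_equal(d$dep_nb_doy[1], 86)
  expect_equal(d$arr_b_doy[1], 122)
  # wrap: 16 Oct -> 27 Mar next year = 365 - 289 + 86 = 162 days
  expect_equal(d$nonbreeding_duration[1], 162)
  # absolute non-breeding latitude
  expect_equal(d$nb_lat_abs[3], 30)
  # distances via the haversine, per leg
  expect_equal(d$spring_distance[1],
               great_circle_km(6, -1, 55.5, 10), tolerance = 1e-12)
  expect_equal(d$autumn_distance[1],
               great_circle_km(55.5, 10, 5, 0), tolerance = 1e-12)
  expect_equal(d$mig_dist[1],
               (d$spring_distance[1] + d$autumn_distance[1]) / 2)
})

test_that("the four durations always sum to the cycle length (incl. leap years)", {
  b <- simulate_bundle(n_species = 15, mean_records = 8, seed = 4)
  d <- derive_cycle(b$tracking, b$traits)
  expect_true(all(d$cycle_length %in% c(365, 366)))
  expect_equal(d$spring_duration + d$breeding_duration +
                 d$autumn_duration + d$nonbreeding_duration,
               d$cycle_length)
  expect_true(all(d[c("spring_duration", "breeding_duration",
                      "autumn_duration", "nonbreeding_duration")] > 0))
})

test_that("summarize_timing is a two-stage mean", {
  base <- derive_cycle(validate_tracking(tiny_tracking()), tiny_traits())
  # one species with records at doy 80 and 90 -> species and grand mean 85
  d <- base[c(1, 1), ]
  d$dep_nb_doy <- c(80, 90)
  s <- summarize_timing(d)
  expect_equal(s$species$dep_nb_doy, 85)
  expect_equal(s$overall$mean[s$overall$variable == "dep_nb_doy"], 85)

  # two species with species means 80 and 100 -> unweighted grand mean 90
  d2 <- base[c(1, 1, 1, 3), ]
  d2$dep_nb_doy <- c(70, 90, 80, 100)
  d2$species <- c("spA", "spA", "spA", "spB")
  s2 <- summarize_timing(d2)
  expect_equal(s2$overall$mean[s2$overall$variable == "dep_nb_doy"], 90)

  # invariance to record order and to duplicating a species' records
  s3 <- summarize_timing(d2[c(4, 2, 1, 3), ])
  s4 <- summarize_timing(d2[c(1, 2, 3, 1, 2, 3, 4), ])
  expect_equal(s2$overall$mean, s3$overall$mean)
  expect_equal(s2$overall$mean, s4$overall$mean)

  # degenerate single record: mean is the record, SD undefined
  s5 <- summarize_timing(base[1, ])
  expect_equal(s5$overall$mean[1], base$dep_nb_doy[1])
  expect_true(all(is.na(s5$overall$sd)))
  expect_error(summarize_timing(base[0, ]), "empty")

  # duration shares sum to 100%
  expect_equal(sum(s2$overall$pct_of_cycle, na.rm = TRUE), 100)
})

test_that("paired t on autumn vs spring durations", {
  base <- derive_cycle(validate_tracking(tiny_tracking()), tiny_traits())
  d <- base[c(1, 1, 1, 1), ]
  # all pairs equal -> t = 0
  d$autumn_duration <- d$spring_duration
  expect_equal(paired_t_autumn_vs_spring(d)$t, 0)
  # differences {+1, -1} -> t = 0, df = 1
  d2 <- base[c(1, 1), ]
  d2$autumn_duration <- d2$spring_duration + c(1, -1)
  r <- paired_t_autumn_vs_spring(d2)
  expect_equal(r$t, 0)
  expect_equal(r$df, 1)
  # df = n - 1 and agreement with stats::t.test on generic data
  d3 <- base[rep(1, 10), ]
  set.seed(9)
  d3$autumn_duration <- d3$spring_duration + rnorm(10, 5, 3)
  r3 <- paired_t_autumn_vs_spring(d3)
  ref <- t.test(d3$autumn_duration, d3$spring_duration, paired = TRUE)
  expect_equal(r3$df, 9)
  expect_equal(r3$t, unname(ref$statistic))
  expect_equal(r3$p_value, ref$p.value)
  expect_error(paired_t_autumn_vs_spring(base[1, ]), "at least 2")
})
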