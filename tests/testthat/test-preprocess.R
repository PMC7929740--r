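test_that("minute values are sums of twelve epochs; partial minutes are unobserved", {
  er <- data.frame(subject_id = "A", date = as.Date("2024-03-04"),
                   second_of_day = seq(0, 119, by = 5),
                   activity = 2)
  out <- aggregate_epochs_to_minutes(er)
  expect_equal(out$activity, c(24, 24))
  expect_true(all(out$observed))

  er2 <- er[-3, ]  # drop one epoch of minute 0
  out2 <- aggregate_epochs_to_minutes(er2)
  expect_false(out2$observed[out2$minute_of_day == 0])
  expect_true(is.na(out2$activity[out2$minute_of_day == 0]))
  expect_true(out2$observed[out2$minute_of_day == 1])

  expect_error(aggregate_epochs_to_minutes(rbind(er, er[1, ])),
               "duplicate")
})

test_that("epoch aggregation matches a brute-force group-and-sum oracle", {
  set.seed(11)
  er <- expand.grid(subject_id = c("A", "B"),
                    date = as.Date("2024-05-01") + 0:1,
                    second_of_day = seq(0, 30 * 60 - 5, by = 5))
  er$activity <- rpois(nrow(er), 4)
  er$activity[sample(nrow(er), 50)] <- NA
  out <- aggregate_epochs_to_minutes(er)
  for (i in sample(nrow(out), 25)) {
    sel <- er$subject_id == out$subject_id[i] &
      er$date == out$date[i] &
      er$second_of_day %/% 60 == out$minute_of_day[i]
    vals <- er$activity[sel]
    if (any(is.na(vals)) || sum(sel) < 12) {
      expect_false(out$observed[i])
    } else {
      expect_equal(out$activity[i], sum(vals))
    }
  }
})

test_that("the 960-observed-minute validity boundary is inclusive", {
  mr <- rbind(one_day_records("A", "2024-03-04", 960),
              one_day_records("A", "2024-03-05", 959),
              one_day_records("A", "2024-03-06", 1440))
  dc <- flag_valid_days(build_day_curves(mr))
  expect_equal(dc$meta$valid, c(TRUE, FALSE, TRUE))
})

test_that("inclusion needs at least one valid weekday and one valid weekend day", {
  # 2024-03-02/03 are Sat/Sun; 2024-03-04 is Monday
  weekend_only <- rbind(one_day_records("A", "2024-03-02", 1440),
                        one_day_records("A", "2024-03-03", 1440))
  both <- rbind(one_day_records("B", "2024-03-04", 1440),
                one_day_records("B", "2024-03-02", 1440))
  weekdays_only <- do.call(rbind, lapply(0:13, function(i) {
    d <- as.Date("2024-03-04") + i
    one_day_records("C", d, if (format(d, "%u") %in% c("6", "7")) 100
                    else 1440)
  }))
  dc <- flag_valid_days(build_day_curves(rbind(weekend_only, both,
                                               weekdays_only)))
  inc <- check_inclusion(dc)
  expect_equal(inc$inclusion$included[match(c("A", "B", "C"),
                                            inc$inclusion$subject_id)],
               c(FALSE, TRUE, FALSE))
  expect_equal(sort(unique(inc$day_curves$meta$subject_id)), "B")
  expect_match(inc$inclusion$reason[inc$inclusion$subject_id == "A"],
               "weekday")
  # count conservation: included + excluded = subjects in
  expect_equal(sum(inc$inclusion$included) + sum(!inc$inclusion$included),
               3L)
})

test_that("imputation averages the same minute across the other valid days", {
  mk <- function(date, v600) {
    r <- one_day_records("A", date, 1440, level = 20)
    if (is.na(v600)) {
      r$activity[601] <- NA
      r$observed[601] <- FALSE
    } else r$activity[601] <- v600
    r
  }
  mr <- rbind(mk("2024-03-02", 30), mk("2024-03-04", NA),
              mk("2024-03-09", 50))
  dc <- impute_missing(flag_valid_days(build_day_curves(mr)))
  expect_equal(dc$values[2, 601], 40)   # mean of 30 and 50
  # observed minutes untouched
  expect_equal(dc$values[1, 601], 30)
  expect_equal(dc$values[3, 601], 50)
})

test_that("imputation is idempotent, leaves complete data alone, and matches a loop oracle", {
  cfg <- toy_config(n_subjects = 3, days = 8, eigenvalues = c(4, 2, 1),
                    noise_sd = 1, mean_level = 60, seed = 31)
  ds <- simulate_actigraphy(cfg)
  mr <- inject_gaps(ds$minute_records, gap_rate = 3, gap_length = 40,
                    seed = 5)
  dc <- flag_valid_days(build_day_curves(mr))
  imp <- impute_missing(dc)
  # no-op on fully observed input
  dc_full <- flag_valid_days(build_day_curves(ds$minute_records))
  expect_equal(impute_missing(dc_full)$values, dc_full$values)
  # observed values never altered
  expect_equal(imp$values[imp$observed], dc$values[dc$observed])
  # idempotent
  expect_equal(impute_missing(imp)$values, imp$values)
  # brute-force per-minute oracle
  m <- dc$meta
  for (i in sample(which(m$valid), 5)) {
    for (j in sample(which(!dc$observed[i, ]), 4)) {
      donors <- which(m$subject_id == m$subject_id[i] & m$valid &
                        seq_len(nrow(m)) != i & dc$observed[, j])
      if (length(donors) > 0)
        expect_equal(imp$values[i, j], mean(dc$values[donors, j]))
    }
  }
})

test_that("minutes unobserved on all valid days fall back to grid interpolation", {
  mr <- rbind(one_day_records("A", "2024-03-02", 1440, level = 10),
              one_day_records("A", "2024-03-04", 1440, level = 30))
  # knock out minutes 700:709 on both days
  kill <- mr$minute_of_day %in% 700:709
  mr$activity[kill] <- NA
  mr$observed[kill] <- FALSE
  dc <- flag_valid_days(build_day_curves(mr))
  expect_warning(imp <- impute_missing(dc), "all valid days")
  expect_true(all(!is.na(imp$values[, 701:710])))
  # interpolated from the subject mean profile (constant 20 around the gap)
  expect_equal(imp$values[1, 705], 20, tolerance = 1e-9)
})

test_that("seasons follow the fixed astronomical boundaries", {
  expect_equal(as.character(season_of(as.Date("2021-09-25"))), "autumn")
  expect_equal(as.character(season_of(as.Date("2021-12-25"))), "winter")
  expect_equal(as.character(season_of(as.Date("2021-03-21"))), "spring")
  expect_equal(as.character(season_of(as.Date("2021-03-20"))), "winter")
  expect_equal(as.character(season_of(as.Date("2021-06-21"))), "summer")
  expect_equal(as.character(season_of(as.Date("2021-12-20"))), "autumn")
  expect_error(season_of("not-a-date"))
})
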