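test_that("night_summary computes duration, efficiency and midpoint", {
  # 7.2 h of episodes in an 8-h window -> efficiency 0.90
  spt <- list(start_h = 11, end_h = 19)
  eps <- data.frame(start_h = c(11, 15), end_h = c(14.6, 18.6))
  ns <- night_summary(spt, eps, night = 1L)
  expect_equal(ns$sleep_duration_h, 7.2)
  expect_equal(ns$efficiency, 0.9)
  # single episode filling the window: efficiency 1, midpoint = centre
  ns2 <- night_summary(spt, data.frame(start_h = 11, end_h = 19), 1L)
  expect_equal(ns2$efficiency, 1)
  expect_equal(ns2$midpoint_hspm, 27)   # window centre, 3 a.m.
  # first episode 23:00-02:00, last ends 06:30 -> midpoint 26.75 (02:45)
  eps3 <- data.frame(start_h = c(11, 15.5), end_h = c(14, 18.5))
  ns3 <- night_summary(list(start_h = 11, end_h = 18.5), eps3, 1L)
  expect_equal(ns3$midpoint_hspm, 26.75)
  # zero episodes -> invalid night
  ns4 <- night_summary(spt, data.frame(start_h = numeric(), end_h = numeric()), 1L)
  expect_false(ns4$valid)
  expect_true(is.na(ns4$efficiency))
  expect_error(night_summary(spt, data.frame(start_h = 10, end_h = 12), 1L),
               "not contained")
})

test_that("l5_m10 finds planted windows and applies conventions", {
  n <- 17280                               # noon-to-noon day, 5-s epochs
  eph <- 5 / 3600
  seg_hour <- ((seq_len(n) - 1) * eph)
  # flat minimal trough 00:30-05:30 (segment hours 12.5-17.5): L5 centred
  # at 03:00 -> 27.0 hours since previous midnight
  mag <- rep(0.1, n)
  mag[seg_hour >= 12.5 & seg_hour < 17.5] <- 0
  d <- l5_m10(mag, epoch_s = 5)
  expect_equal(d$l5_hspm, 27, tolerance = 1e-3)
  # trough centred at 02:00 -> 26.0 (the "2 a.m. = 26" convention)
  mag2 <- 0.1 + 0.05 * cos(2 * pi * (seg_hour - 2) / 24)
  d2 <- l5_m10(mag2, epoch_s = 5)
  expect_equal(d2$l5_hspm, 26, tolerance = 1e-2)
  # constant day: tie -> earliest window, midpoint = window centre
  d3 <- l5_m10(rep(1, n), epoch_s = 5)
  expect_equal(d3$l5_hspm, 2.5 + 12)
  expect_equal(d3$m10_hspm, 5 + 12)
  # wear below 16 h -> missing with wear hours reported
  w <- rep(FALSE, n); w[1:(15 * 720)] <- TRUE
  d4 <- l5_m10(rep(1, n), wear = w, epoch_s = 5)
  expect_true(is.na(d4$l5_hspm))
  expect_equal(d4$wear_h, 15)
})

test_that("diurnal_inactivity clips bouts at the window boundary", {
  spt <- list(start_h = 11.5, end_h = 20.5)
  expect_equal(diurnal_inactivity(
    data.frame(start_h = 12, end_h = 13), spt), 0)
  # a 45-min nap bout at 14:00 clock (segment hour 2)
  expect_equal(diurnal_inactivity(
    data.frame(start_h = 2, end_h = 2.75), spt), 0.75)
  # straddling bout: only the outside portion counts
  expect_equal(diurnal_inactivity(
    data.frame(start_h = 10.5, end_h = 12), spt), 1)
  # interval-clipping oracle on random fixtures
  set.seed(8)
  for (i in 1:50) {
    s <- sort(runif(6, 0, 24))
    bouts <- data.frame(start_h = s[c(1, 3, 5)], end_h = s[c(2, 4, 6)])
    win <- sort(runif(2, 0, 24))
    spt2 <- list(start_h = win[1], end_h = win[2])
    want <- 0
    for (j in 1:3) {
      grid <- seq(bouts$start_h[j], bouts$end_h[j], by = 1e-3)
      want <- want + 1e-3 * sum(grid < win[1] | grid >= win[2])
    }
    expect_equal(diurnal_inactivity(bouts, spt2), want, tolerance = 5e-3)
  }
})

test_that("aggregate_individual averages valid nights and gates the SD", {
  mk_nights <- function(durs) data.frame(
    night = seq_along(durs), sleep_duration_h = durs,
    spt_length_h = durs + 1, efficiency = durs / (durs + 1),
    n_episodes = 15L, midpoint_hspm = 27, valid = TRUE)
  days <- data.frame(night = 1:7, l5_hspm = 27, m10_hspm = 15, wear_h = 24,
                     diurnal_inactivity_h = 0.5)
  # 7 identical nights: SD 0
  r <- aggregate_individual(mk_nights(rep(7, 7)), days, "a", 7L)
  expect_equal(r$mean_sleep_duration, 7)
  expect_equal(r$sd_sleep_duration, 0)
  # 5 wear days: SD suppressed
  r2 <- aggregate_individual(mk_nights(rep(7, 5)), days[1:5, ], "b", 5L)
  expect_true(is.na(r2$sd_sleep_duration))
  # hand-computed sample SD over [6, 7, 8] with 7-day wear
  n3 <- mk_nights(c(6, 7, 8))
  n3$valid <- TRUE
  r3 <- aggregate_individual(n3, days, "c", 7L)
  expect_equal(r3$mean_sleep_duration, 7)
  expect_equal(r3$sd_sleep_duration, 1)
  # zero valid nights -> dropped with reason
  bad <- mk_nights(7); bad$valid <- FALSE
  expect_error(aggregate_individual(bad, days, "d", 7L), "zero valid nights")
})

test_that("apply_exclusions runs the cascade with logged rule ids", {
  fx <- exclusion_fixture()
  res <- apply_exclusions(fx$phenotypes, qc_counters = fx$counters)
  # p01 (2.9 h), p02 (5 episodes), p03 (counter) out; p04 boundary stays
  expect_setequal(res$cohort$individual_id[res$cohort$excluded_spt],
                  c("p01", "p02", "p03"))
  expect_equal(nrow(res$retained), 9L)
  expect_equal(res$log$rule[res$log$individual_id == "p01"],
               "rule3_duration_bounds")
  expect_equal(res$log$rule[res$log$individual_id == "p02"],
               "rule4_episode_bounds")
  expect_equal(res$log$rule[res$log$individual_id == "p03"],
               "rule2_counter_iqr")
  # rules 3-4 leave timing phenotypes usable; counter rule does not
  excl_all <- res$cohort$individual_id[res$cohort$excluded_all]
  expect_equal(excl_all, "p03")
  # idempotence on the retained set
  res2 <- apply_exclusions(res$retained[, names(fx$phenotypes)])
  expect_equal(nrow(res2$retained), 9L)
  expect_equal(nrow(res2$log), 0L)
})

test_that("apply_exclusions boundary semantics match the stated rules", {
  ph <- exclusion_fixture()$phenotypes
  ph$mean_sleep_duration <- c(3.0, 12.0, rep(7, 10))    # closed bounds kept
  ph$mean_n_episodes <- c(17, 17, 30, 5.01, rep(17, 8)) # >= 30 out, 5.01 in
  res <- apply_exclusions(ph)
  expect_setequal(res$cohort$individual_id[res$cohort$excluded_spt], "p03")
})

test_that("inverse_normal matches the Blom formula and its properties", {
  got <- inverse_normal(c(10, 20, 30))
  expect_equal(got, qnorm(c(0.625, 1.625, 2.625) / 3.25))
  expect_equal(got, c(-0.8694, 0, 0.8694), tolerance = 1e-4)
  # symmetric input sums to zero; monotone inputs stay monotone
  x <- c(-3, -1, 0, 1, 3)
  expect_equal(sum(inverse_normal(x)), 0)
  set.seed(2)
  y <- sort(rnorm(50))
  expect_true(all(diff(inverse_normal(y)) > 0))
  # ties share the mean rank
  expect_equal(inverse_normal(c(1, 1, 2))[1], inverse_normal(c(1, 1, 2))[2])
  # moments on n = 1000
  set.seed(3)
  z <- inverse_normal(rnorm(1000))
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(var(z) - 1), 0.05)
  expect_error(inverse_normal(rep(1, 5)), "constant")
  expect_error(inverse_normal(1), "at least 2")
  # NA passthrough
  expect_true(is.na(inverse_normal(c(1, NA, 2))[2]))
})

test_that("residualize removes covariate effects and keeps NA rows", {
  set.seed(9)
  n <- 200
  cov <- data.frame(age = rnorm(n, 60, 5),
                    sex = factor(sample(c("F", "M"), n, TRUE)))
  y <- 7 + 0.05 * cov$age + 0.3 * (cov$sex == "M") + rnorm(n, 0, 0.5)
  y[3] <- NA
  r <- residualize(y, cov)
  expect_true(is.na(r[3]))
  ok <- !is.na(r)
  expect_lt(abs(mean(r[ok])), 1e-10)
  expect_lt(abs(cor(r[ok], cov$age[ok])), 1e-10)
})

test_that("retained phenotype invariants hold on the synthetic cohort", {
  co <- small_cohort()
  ph <- derive_phenotypes(co$recordings)
  res <- apply_exclusions(ph)
  r <- res$retained
  expect_true(all(r$mean_efficiency > 0 & r$mean_efficiency <= 1))
  expect_true(all(r$mean_n_episodes > 5 & r$mean_n_episodes < 30))
  expect_true(all(r$n_nights_used >= 1))
  # SD phenotype present exactly for max-wear individuals
  expect_true(all(is.na(r$sd_sleep_duration) == (r$n_days_worn != 7)))
})
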