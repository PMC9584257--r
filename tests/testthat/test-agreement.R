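test_that("series alignment trims to the overlap and downsamples frames", {
  a <- collartrack:::new_presence_series(c(1L, 0L, 1L, 1L), 1, 0, "frame", 30)
  al <- align_series(a, a)
  expect_identical(al$a, al$b)
  expect_equal(al$n, 4)
  # frame series vs second series: any-presence binning then pairing
  fr <- collartrack:::new_presence_series(
    c(rep(0L, 30), rep(1L, 15), rep(0L, 45)), 1, 0, "frame", 30)
  sec <- collartrack:::new_presence_series(c(0L, 1L, 0L), 1, 0, "second", 30)
  al2 <- align_series(fr, sec)
  expect_equal(al2$resolution, "second")
  expect_identical(al2$a, c(0L, 1L, 0L))
  expect_identical(al2$b, c(0L, 1L, 0L))
  # disjoint intervals -> explicit error
  b <- collartrack:::new_presence_series(c(1L, 1L), 1, 0, "frame", 30,
                                         start = 100L)
  expect_error(align_series(a, b), "overlap")
})

test_that("kappa reproduces the worked 2x2 example exactly", {
  # table a=40, b=10, c=10, d=40: p_o = 0.8, p_e = 0.5, kappa = 0.6
  x <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  y <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  r <- cohen_kappa(x, y)
  expect_equal(r$estimate, 0.6)
  expect_equal(r$n, 100)
  expect_lt(r$p_value, 0.001)
})

test_that("kappa handles perfect, chance and degenerate agreement", {
  a <- c(1, 0, 1, 0, 1, 1, 0, 0)
  expect_equal(cohen_kappa(a, a)$estimate, 1)
  expect_true(cohen_kappa(rep(1, 10), rep(1, 10))$undefined)
  set.seed(97)
  x <- rbinom(1e4, 1, 0.5); y <- rbinom(1e4, 1, 0.5)
  expect_lt(abs(cohen_kappa(x, y)$estimate), 0.05)
})

test_that("kappa is symmetric and invariant under joint relabeling", {
  set.seed(12)
  for (i in 1:10) {
    x <- rbinom(200, 1, 0.3); y <- as.integer(x == 1 & runif(200) > 0.2)
    k1 <- cohen_kappa(x, y)$estimate
    expect_equal(cohen_kappa(y, x)$estimate, k1)
    expect_equal(cohen_kappa(1 - x, 1 - y)$estimate, k1)
  }
})

test_that("ICC matches the ANOVA mean-squares oracle", {
  # worked pairs from a small fixed set
  a <- c(1, 0, 1, 0, 1, 0); b <- c(1, 0, 0, 0, 1, 1)
  df <- data.frame(y = c(a, b), subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  BMS <- av["subj", "Mean Sq"]; JMS <- av["rater", "Mean Sq"]
  EMS <- av["Residuals", "Mean Sq"]
  n <- 6; k <- 2
  expect_equal(icc(a, b, form = "2,1")$estimate,
               (BMS - EMS) / (BMS + (k - 1) * EMS + k * (JMS - EMS) / n),
               tolerance = 1e-10)
  expect_equal(icc(a, b, form = "3,1")$estimate,
               (BMS - EMS) / (BMS + (k - 1) * EMS),
               tolerance = 1e-10)
  ow <- summary(stats::aov(y ~ subj, data = df))[[1]]
  BMS1 <- ow["subj", "Mean Sq"]; WMS <- ow["Residuals", "Mean Sq"]
  expect_equal(icc(a, b, form = "1,1")$estimate,
               (BMS1 - WMS) / (BMS1 + (k - 1) * WMS),
               tolerance = 1e-10)
  # F statistic and p value against the oracle mean squares
  r <- icc(a, b, form = "2,1")
  expect_equal(r$stat, BMS / EMS, tolerance = 1e-10)
  expect_equal(r$p_value,
               stats::pf(BMS / EMS, n - 1, (n - 1) * (k - 1),
                         lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ICC is 1 for identical series, ~0 for independent ones", {
  a <- c(1, 0, 1, 1, 0, 0, 1, 0)
  expect_equal(icc(a, a)$estimate, 1)
  set.seed(55)
  x <- rbinom(1e4, 1, 0.4); y <- rbinom(1e4, 1, 0.4)
  expect_lt(abs(icc(x, y)$estimate), 0.05)
  # symmetry
  set.seed(56)
  u <- rbinom(300, 1, 0.3); v <- as.integer(u == 1 | runif(300) < 0.1)
  expect_equal(icc(u, v)$estimate, icc(v, u)$estimate, tolerance = 1e-12)
})

test_that("degenerate ICC inputs are flagged undefined, not silent", {
  expect_true(icc(c(1, 1, 1), c(1, 1, 1))$undefined)
  expect_true(icc(1, 1)$undefined)
})

test_that("simulated coder kappa converges to its closed-form expectation", {
  n <- 1e4; prevalence <- 0.2; miss <- 0.1; fa <- 0.01
  truth <- collartrack:::with_seed(77, stats::rbinom(n, 1, prevalence))
  coded <- simulate_coder(truth, miss_rate = miss, false_alarm_rate = fa,
                          seed = 78)
  est <- cohen_kappa(truth, coded)$estimate
  # analytic kappa from the expected 2x2 table
  p11 <- prevalence * (1 - miss); p01 <- (1 - prevalence) * fa
  po <- p11 + (1 - prevalence) * (1 - fa)
  p1. <- prevalence; p.1 <- p11 + p01
  pe <- p1. * p.1 + (1 - p1.) * (1 - p.1)
  kexp <- (po - pe) / (1 - pe)
  # Monte-Carlo standard error of kappa ~ sqrt(po(1-po)/n)/(1-pe)
  se <- sqrt(po * (1 - po) / n) / (1 - pe)
  expect_lt(abs(est - kexp), 3 * se)
})

test_that("table1_analysis produces the arm-specific comparisons", {
  # synthetic detector log + zero-error coder derived from the same truth
  n_frames <- 600L
  eat <- integer(n_frames); eat[51:200] <- 1L; eat[401:500] <- 1L
  drink <- integer(n_frames); drink[251:350] <- 1L
  log <- do.call(rbind, c(
    lapply(which(eat == 1L) - 1L, function(f)
      data.frame(frame = f, timestamp = f / 30, id = 10, x = 120, y = 60,
                 rois = "1")),
    lapply(which(drink == 1L) - 1L, function(f)
      data.frame(frame = f, timestamp = f / 30, id = 10, x = 30, y = 60,
                 rois = "2"))))
  coding <- data.frame(unit = 0:(n_frames - 1), eating = eat,
                       drinking = drink, food_roi = eat, water_roi = drink)
  tab <- table1_analysis(log, coding, arm = "post_event", subject = 10,
                         food_roi = 1, water_roi = 2, n_frames = n_frames)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$icc == 1))
  expect_true(all(tab$kappa == 1))
  # degrade the coder: estimates drop below 1 but stay high
  coding2 <- coding
  coding2$eating <- simulate_coder(eat, miss_rate = 0.1,
                                   false_alarm_rate = 0.02, seed = 5)
  tab2 <- table1_analysis(log, coding2, arm = "post_event", subject = 10,
                          food_roi = 1, water_roi = 2, n_frames = n_frames)
  expect_lt(tab2$kappa[tab2$behaviour == "eating"], 1)
  expect_gt(tab2$kappa[tab2$behaviour == "eating"], 0.5)
  # real-time arm works at second resolution with eating/drinking only
  coding_s <- data.frame(unit = 0:19,
                         eating = collartrack:::downsample_any(eat, 30),
                         drinking = collartrack:::downsample_any(drink, 30))
  tab3 <- table1_analysis(log, coding_s, arm = "real_time", subject = 10,
                          food_roi = 1, water_roi = 2, n_frames = n_frames)
  expect_equal(nrow(tab3), 2)
  expect_true(all(tab3$kappa == 1))
  # corrected arm restricts the drinking comparison to the stated interval
  tab4 <- table1_analysis(log, coding, arm = "post_event_corrected",
                          subject = 10, food_roi = 1, water_roi = 2,
                          n_frames = n_frames, corrected_range = c(0, 399))
  expect_equal(tab4$n[tab4$behaviour == "drinking"], 400)
  expect_error(table1_analysis(log, coding, arm = "post_event_corrected",
                               subject = 10, n_frames = n_frames),
               "corrected_range")
  # missing required labels error
  expect_error(table1_analysis(log, coding[c("unit", "eating")],
                               arm = "post_event", subject = 10,
                               n_frames = n_frames),
               "drinking")
})

test_that("ICC form sweep reports the closest form to a reference", {
  set.seed(9)
  x <- rbinom(400, 1, 0.3)
  y <- as.integer(x == 1 & runif(400) > 0.15)
  sw <- sweep_icc_forms(align_series(x, y, resolution = "frame"),
                        reference = icc(x, y, form = "3,1")$estimate)
  expect_equal(nrow(sw), 3)
  expect_identical(sw$form[sw$matched], "3,1")
})

test_that("ethogram reader tolerates varying schemas", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time,Eating,WasDrinking",
               "0,1,0", "1,1,1", "2,0,0"), path)
  d <- read_ethogram(path, column_map = c(unit = "Time",
                                          drinking = "WasDrinking"))
  expect_identical(names(d), c("unit", "eating", "drinking"))
  expect_identical(d$drinking, c(0L, 1L, 0L))
  expect_identical(d$unit, 0:2)
})

test_that("reproduction reporting degrades gracefully without study files", {
  rep <- reproduce_published_agreement(NULL, NULL, arm = "post_event")
  expect_true(all(!rep$matched))
  expect_true(all(is.na(rep$estimate)))
  expect_match(rep$note[1], "not available")
  rep2 <- reproduce_published_agreement("/nonexistent.csv", "/none.csv",
                                        arm = "real_time")
  expect_equal(nrow(rep2), 2)
  expect_true(all(!rep2$matched))
})
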