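# qPCR call logic, standard curves, and run summaries.

test_that("delta_cq reproduces the worked example and is symmetric", {
  expect_equal(delta_cq(17.18, 15.71), 1.47)
  expect_identical(delta_cq(10, 10), 0)
  expect_identical(delta_cq(3, 9), delta_cq(9, 3))
  expect_error(delta_cq(NA, 10), "present")
  expect_error(delta_cq(10, NA), "present")
})

test_that("classify_sample reproduces the four worked patterns", {
  t <- call_thresholds()
  pos <- classify_sample(list(cq = 15.71, end_rfu = 1359.33),
                         list(cq = 17.18, end_rfu = 1533.68), t)
  expect_identical(pos$call, "positive")
  expect_equal(pos$delta_cq, 1.47)
  anom <- classify_sample(list(cq = 1.6, end_rfu = 1200),
                          list(cq = 37.1, end_rfu = 80), t)
  expect_identical(anom$call, "anomalous")
  neg <- classify_sample(list(cq = NA, end_rfu = 50),
                         list(cq = 20, end_rfu = 800), t)
  expect_identical(neg$call, "negative")
  expect_true(is.na(neg$delta_cq))
  fail <- classify_sample(list(cq = NA, end_rfu = 40),
                          list(cq = NA, end_rfu = 30), t)
  expect_identical(fail$call, "failed")
  # every call carries at least one reason
  for (x in list(pos, anom, neg, fail))
    expect_gt(nchar(paste(x$reasons, collapse = "")), 0)
})

test_that("the four calls are exhaustive and mutually exclusive", {
  t <- call_thresholds()
  # grid spanning every amplification/window/delta combination
  cqs <- c(NA, 2, 15, 24, 28, 35)
  rfus_d <- c(100, 600)
  rfus_c <- c(100, 300)
  calls <- c("positive", "negative", "anomalous", "failed")
  for (dcq in cqs) for (drfu in rfus_d) for (ccq in cqs)
    for (crfu in rfus_c) {
      got <- classify_sample(list(cq = dcq, end_rfu = drfu),
                             list(cq = ccq, end_rfu = crfu), t)
      expect_true(got$call %in% calls)
      expect_length(got$call, 1)
      # re-derive the expected call from the documented rules
      damp <- !is.na(dcq) && drfu >= t$rfu_diag && dcq >= t$cq_min &&
        dcq <= t$cq_max
      camp <- !is.na(ccq) && crfu >= t$rfu_ctrl && ccq >= t$cq_min &&
        ccq <= t$cq_max
      want <- if (!is.na(dcq) && dcq < t$cq_min && !is.na(ccq) &&
                  ccq > t$cq_max) "anomalous"
      else if (damp && camp && abs(ccq - dcq) <= t$delta_max) "positive"
      else if (damp && camp) "anomalous"
      else if (damp) "anomalous"
      else if (camp) "negative"
      else "failed"
      expect_identical(got$call, want)
    }
})

test_that("raising delta_max never demotes a positive", {
  base <- call_thresholds(delta_max = 5)
  wider <- call_thresholds(delta_max = 10)
  for (d in c(0, 2, 4.9, 5, 6, 9)) {
    got1 <- classify_sample(list(cq = 15, end_rfu = 900),
                            list(cq = 15 + d, end_rfu = 900), base)
    got2 <- classify_sample(list(cq = 15, end_rfu = 900),
                            list(cq = 15 + d, end_rfu = 900), wider)
    if (got1$call == "positive") expect_identical(got2$call, "positive")
  }
})

test_that("classify_run requires one well per channel and aggregates", {
  wells <- data.frame(
    sample_id = rep(c("a", "b"), each = 2),
    channel = rep(c("diagnostic", "control"), 2),
    cq = c(15, 16, NA, 20),
    end_rfu = c(900, 900, 50, 800), stringsAsFactors = FALSE)
  calls <- classify_run(wells)
  expect_identical(calls$call[calls$sample_id == "a"], "positive")
  expect_identical(calls$call[calls$sample_id == "b"], "negative")
  bad <- wells[-2, ]
  expect_error(classify_run(bad), "exactly one")
  expect_error(classify_run(wells[, -4]), "needs columns")
})

test_that("standard curve: perfect 2-fold-per-log10 series gives E = 100%", {
  # slope -1/log10(2) makes 10^(-1/slope) exactly 2
  slope <- -1 / log10(2)
  conc <- 10^(2:-2)
  pts <- data.frame(conc = conc, cq = 35 + slope * log10(conc))
  sc <- fit_standard_curve(pts)
  expect_equal(sc$slope, slope, tolerance = 1e-12)
  expect_equal(sc$efficiency, 1, tolerance = 1e-12)
  expect_equal(abs(sc$r), 1, tolerance = 1e-12)
  # point order does not matter
  sc2 <- fit_standard_curve(pts[sample(nrow(pts)), ])
  expect_equal(sc2$slope, sc$slope)
  # uniform concentration rescaling shifts only the intercept
  pts3 <- pts; pts3$conc <- pts3$conc * 1000
  sc3 <- fit_standard_curve(pts3)
  expect_equal(sc3$slope, sc$slope, tolerance = 1e-12)
  expect_equal(sc3$intercept, sc$intercept - 3 * slope, tolerance = 1e-9)
})

test_that("standard curve matches closed-form least squares on noisy data", {
  set.seed(12)
  conc <- rep(10^(2:-2), each = 3)
  cq <- 38 - 3.4 * log10(conc) + stats::rnorm(length(conc), 0, 0.3)
  pts <- data.frame(conc = conc, cq = cq)
  sc <- fit_standard_curve(pts)
  x <- log10(conc); y <- cq
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(sc$slope, slope, tolerance = 1e-9)
  expect_equal(sc$intercept, mean(y) - slope * mean(x), tolerance = 1e-9)
  expect_equal(sc$r, stats::cor(x, y), tolerance = 1e-12)
})

test_that("standard curve reports the detection floor and input errors", {
  pts <- data.frame(conc = rep(c(100, 10, 1, 0.1), each = 2),
                    cq = c(20, 20.1, 23, 23.2, 26.5, 26.4, 30, NA))
  sc <- fit_standard_curve(pts)
  expect_identical(sc$detection_floor, 1)  # 0.1 has a failed replicate
  expect_error(fit_standard_curve(data.frame(conc = c(1, -1, 10),
                                             cq = c(1, 2, 3))), "positive")
  expect_error(fit_standard_curve(data.frame(conc = c(1, 10),
                                             cq = c(25, 20))),
               "3 distinct")
})

test_that("summarize_run matches hand arithmetic", {
  wells <- data.frame(
    sample_id = c("a", "a", "b", "b", "c"),
    channel = c("diagnostic", "control", "diagnostic", "control",
                "diagnostic"),
    cq = c(10, 12, 20, NA, 15),
    end_rfu = c(1000, 900, 700, 60, 1200), stringsAsFactors = FALSE)
  s <- summarize_run(NULL, wells)
  cs <- s$channel_stats
  dq <- cs[cs$channel == "diagnostic" & cs$metric == "cq", ]
  # amplified diagnostic Cqs are 10, 20, 15
  expect_identical(dq$min, 10)
  expect_identical(dq$max, 20)
  expect_identical(dq$mean, 15)
  expect_equal(dq$sd, stats::sd(c(10, 20, 15)))
  # single amplified control well: SD 0 with the single-observation flag
  cq_c <- cs[cs$channel == "control" & cs$metric == "cq", ]
  expect_identical(cq_c$sd, 0)
  expect_identical(cq_c$single, 1)
  # suggested threshold: half the minimum amplified RFU, floored to 50s
  expect_identical(unname(s$suggested_rfu[["diagnostic"]]),
                   50 * floor(700 / 2 / 50))
  expect_identical(unname(s$suggested_rfu[["control"]]),
                   50 * floor(900 / 2 / 50))
  # adding a non-amplified well leaves the Cq stats unchanged
  wells2 <- rbind(wells, data.frame(sample_id = "d", channel = "diagnostic",
                                    cq = NA, end_rfu = 55))
  s2 <- summarize_run(NULL, wells2)
  dq2 <- s2$channel_stats[s2$channel_stats$channel == "diagnostic" &
                            s2$channel_stats$metric == "cq", ]
  expect_identical(dq2$mean, dq$mean)
  expect_error(summarize_run(NULL, wells[0, ]), "at least one")
  # call tally flows through
  calls <- data.frame(sample_id = c("a", "b"),
                      call = c("positive", "negative"))
  s3 <- summarize_run(calls, wells)
  expect_identical(as.integer(s3$call_tally[["positive"]]), 1L)
})

test_that("read_qpcr_wells parses the CSV dialect", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeLines(c("sample_id,channel,cq,end_rfu",
               "s1,diagnostic,15.2,1000",
               "s1,control,,80"), f)
  w <- read_qpcr_wells(f)
  expect_identical(w$cq, c(15.2, NA))
  expect_identical(w$end_rfu, c(1000, 80))
  writeLines(c("sample_id,channel,cq,end_rfu",
               "s1,green,15.2,1000"), f)
  expect_error(read_qpcr_wells(f), "unknown channel")
  writeLines(c("sample_id,cq", "s1,15"), f)
  expect_error(read_qpcr_wells(f), "missing column")
})
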