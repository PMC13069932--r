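test_that("the default cohort has the expected group structure and is seed-deterministic", {
  coh <- generate_cohort(synthetic_spec(seed = 1))
  expect_equal(nrow(coh), 182)
  expect_equal(sum(coh$fish_status == "positive"), 13)
  expect_equal(sum(coh$fish_status == "negative"), 169)
  expect_true(all(coh$ihc_category == 2))
  expect_identical(coh, generate_cohort(synthetic_spec(seed = 1)))
  expect_false(identical(coh, generate_cohort(synthetic_spec(seed = 2))))
})

test_that("draws never leave the stated truncation ranges", {
  for (s in 1:5) {
    coh <- generate_cohort(synthetic_spec(seed = s))
    neg <- coh[coh$fish_status == "negative", ]
    pos <- coh[coh$fish_status == "positive", ]
    expect_true(all(neg$mean_intensity >= 66.4 & neg$mean_intensity <= 142.8))
    expect_true(all(neg$pct_area >= 2.6 & neg$pct_area <= 13.8))
    expect_true(all(pos$mean_intensity >= 59.1 & pos$mean_intensity <= 126.4))
    expect_true(all(pos$pct_area >= 3.6 & pos$pct_area <= 11.9))
  }
})

test_that("invalid cohort specs are rejected", {
  spec <- synthetic_spec()
  bad <- spec; bad$negative$n <- 0
  expect_error(validate <- generate_cohort(bad), "at least 1")
  bad <- spec; bad$negative$intensity_sd <- 0
  expect_error(generate_cohort(bad), "positive")
  # truncation bounds excluding the mean
  bad <- spec; bad$positive$area_range <- c(10, 11.9)
  expect_error(generate_cohort(bad), "contain")
  expect_error(synthetic_spec(negative = within(spec$negative, n <- 0)),
               "at least 1")
})

test_that("group sample means converge to the truncated-normal moments", {
  # 200 replicate cohorts; the LLN limit of a group mean is the truncated
  # distribution's mean (truncation to an asymmetric range shifts it away
  # from the parent mean), with SE = truncated sd / sqrt(total draws)
  reps <- 200
  sums <- c(neg_i = 0, pos_i = 0, neg_a = 0, pos_a = 0)
  for (r in seq_len(reps)) {
    coh <- generate_cohort(synthetic_spec(seed = 1000 + r))
    neg <- coh$fish_status == "negative"
    sums <- sums + c(mean(coh$mean_intensity[neg]), mean(coh$mean_intensity[!neg]),
                     mean(coh$pct_area[neg]), mean(coh$pct_area[!neg]))
  }
  avg <- sums / reps
  mom_ni <- truncnorm_moments(113.3, 13.9, 66.4, 142.8)
  mom_pi <- truncnorm_moments(103.82, 20.8, 59.1, 126.4)
  mom_na <- truncnorm_moments(6.3, 1.9, 2.6, 13.8)
  mom_pa <- truncnorm_moments(6.8, 2.1, 3.6, 11.9)
  expect_lt(abs(avg[["neg_i"]] - mom_ni$mean), 3 * mom_ni$sd / sqrt(169 * reps))
  expect_lt(abs(avg[["pos_i"]] - mom_pi$mean), 3 * mom_pi$sd / sqrt(13 * reps))
  expect_lt(abs(avg[["neg_a"]] - mom_na$mean), 3 * mom_na$sd / sqrt(169 * reps))
  expect_lt(abs(avg[["pos_a"]] - mom_pa$mean), 3 * mom_pa$sd / sqrt(13 * reps))
})

test_that("truncated draws match closed-form moments at large n", {
  withr::local_seed(4)
  x <- rtruncnorm(2e5, 103.82, 20.8, 59.1, 126.4)
  mom <- truncnorm_moments(103.82, 20.8, 59.1, 126.4)
  expect_true(all(x >= 59.1 & x <= 126.4))
  expect_lt(abs(mean(x) - mom$mean), 4 * mom$sd / sqrt(2e5))
  expect_lt(abs(sd(x) - mom$sd), 0.15)
})

test_that("control groups are generated at the score level", {
  coh <- generate_cohort(synthetic_spec(include_controls = TRUE, seed = 6))
  expect_equal(nrow(coh), 212)
  ctrl <- coh[coh$ihc_category != 2, ]
  expect_equal(as.vector(table(ctrl$ihc_category)), c(10, 10, 10))
  expect_true(all(ctrl$fish_status == "unavailable"))
  expect_true(all(is.na(ctrl$mean_intensity)))
  expect_true(all(is.finite(ctrl$hscore)))
  r0 <- ctrl$hscore[ctrl$ihc_category == 0]
  r1 <- ctrl$hscore[ctrl$ihc_category == 1]
  r3 <- ctrl$hscore[ctrl$ihc_category == 3]
  expect_true(all(r0 >= 2.10 & r0 <= 4.51))
  expect_true(all(r1 >= 1.51 & r1 <= 4.55))
  expect_true(all(r3 >= 2.46 & r3 <= 6.75))
})

test_that("raw enrollment flags exactly the requested number of incomplete cases", {
  raw <- generate_raw_enrollment(331, 149, seed = 2)
  expect_equal(nrow(raw), 331)
  expect_equal(sum(raw$missing_clinical | raw$missing_slide), 149)
  expect_identical(raw, generate_raw_enrollment(331, 149, seed = 2))

  none <- generate_raw_enrollment(10, 0, seed = 1)
  expect_equal(sum(none$missing_clinical | none$missing_slide), 0)

  all_flagged <- generate_raw_enrollment(5, 5, seed = 1)
  expect_warning(res <- apply_exclusions(all_flagged), "all cases excluded")
  expect_equal(nrow(res$cohort), 0)

  expect_error(generate_raw_enrollment(5, 6), "n_incomplete")
})
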