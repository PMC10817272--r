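cfg <- cohort_config()

test_that("eligible index dates follow the onset/outcome ordering rules", {
  tl <- make_timeline("A", setNames(list("F43.10", "I10", "I10"),
                                    c(0, 30, 60)))
  expect_equal(eligible_index_dates(tl, cfg), day0 + c(30, 60))

  same_day <- make_timeline("B", setNames(list(c("F43.10", "F10.10"), "I10"),
                                          c(0, 30)))
  expect_length(eligible_index_dates(same_day, cfg), 0)

  prior <- make_timeline("C", setNames(list("F10.10", "F43.10", "I10"),
                                       c(0, 100, 130)))
  expect_length(eligible_index_dates(prior, cfg), 0)

  # encounters outside (first PTSD, first ASUD) are never eligible
  mid <- make_timeline("D", setNames(list("F43.10", "I10", "F10.10", "I10"),
                                     c(0, 30, 60, 90)))
  expect_equal(eligible_index_dates(mid, cfg), day0 + 30)
})

test_that("no ASUD record may fall in the washout year before an index date", {
  # any candidate before the first ASUD automatically has an ASUD-free
  # washout; a washout violation therefore coincides with the prior-ASUD
  # exclusion, which this pins from the washout side
  tl <- make_timeline("E", setNames(list("F43.10", "305.00", "I10"),
                                    c(0, 50, 200)))
  elig <- eligible_index_dates(tl, cfg)
  for (d in elig) {
    asud <- day0 + 50
    expect_false(any(asud >= d - cfg$washout_days & asud <= d))
  }
  expect_length(elig, 0)
})

test_that("index selection takes the latest eligible observable date", {
  tl <- make_timeline("F", setNames(list("F43.10", "I10", "I10", "I10"),
                                    c(0, 30, 60, 200)))
  elig <- eligible_index_dates(tl, cfg)
  expect_equal(select_index_date(elig, tl, cfg), day0 + 60)  # 200 lacks follow-up
  expect_equal(select_index_date(day0 + c(30, 60)), day0 + 60)
  expect_equal(select_index_date(day0 + 5), day0 + 5)
  expect_null(select_index_date(as.Date(character(0))))
})

test_that("labels respect the closed 90-day outcome window boundary", {
  lab_at <- function(gap) {
    tl <- make_timeline("G", setNames(list("F43.10", "I10", "F10.10"),
                                      c(0, 30, 30 + gap)))
    label_sample(tl, day0 + 30, cfg)$label
  }
  expect_identical(lab_at(60), "case")
  expect_identical(lab_at(90), "case")     # right endpoint closed
  expect_identical(lab_at(91), "control")
  expect_identical(lab_at(100), "control")
})

test_that("samples carry only lookback visits with day offsets, no leakage", {
  tl <- make_timeline("H", setNames(list("F43.10", "I10", "E78.5", "I10", "I10"),
                                    c(0, 235, 500, 600, 700)))
  s <- label_sample(tl, day0 + 600, cfg)
  offs <- vapply(s$visits, `[[`, numeric(1), "days_before")
  expect_true(all(offs >= 0 & offs <= cfg$lookback_days))
  expect_true(!is.unsorted(rev(offs)))  # oldest first
  # day-0 visit (offset 600) is outside the lookback; day-235 sits exactly
  # on the closed lookback boundary (offset 365)
  expect_equal(offs, c(365, 100, 0))
  expect_error(label_sample(tl, day0 + 601, cfg), "not an encounter date")
})

test_that("build_cohort partitions patients into case/control/excluded", {
  tls <- list(
    make_timeline("case1", setNames(list("F43.10", "I10", "I10", "F10.10"),
                                    c(0, 100, 400, 450))),
    make_timeline("ctrl1", setNames(list("F43.10", "I10", "I10"),
                                    c(0, 100, 400))),
    make_timeline("excl1", setNames(list(c("F43.10", "F10.10"), "I10"),
                                    c(0, 100)))
  )
  coh <- build_cohort(tls, cfg)
  labs <- vapply(coh$samples, `[[`, character(1), "label")
  expect_equal(sum(labs == "case"), 1)
  expect_equal(sum(labs == "control"), 1)
  expect_equal(nrow(coh$exclusions), 1)
  expect_match(coh$exclusions$reason[1], "same day")
  expect_equal(length(coh$samples) + nrow(coh$exclusions), 3)
  expect_error(build_cohort(c(tls, tls[1]), cfg), "duplicate")
  empty <- build_cohort(list(), cfg)
  expect_length(empty$samples, 0)
  expect_equal(nrow(empty$exclusions), 0)
})

test_that("labels and offsets are invariant under a global date shift", {
  sim <- generate_cohort(sim_config(n_patients = 30, seed = 31))
  shift <- function(tl, k) {
    tl$encounters <- lapply(tl$encounters, function(e) { e$date <- e$date + k; e })
    tl$notes <- lapply(tl$notes, function(n) { n$date <- n$date + k; n })
    tl
  }
  c0 <- build_cohort(sim$timelines, cfg)
  c1 <- build_cohort(lapply(sim$timelines, shift, k = 1234L), cfg)
  expect_equal(length(c0$samples), length(c1$samples))
  for (i in seq_along(c0$samples)) {
    expect_identical(c0$samples[[i]]$label, c1$samples[[i]]$label)
    expect_equal(vapply(c0$samples[[i]]$visits, `[[`, numeric(1), "days_before"),
                 vapply(c1$samples[[i]]$visits, `[[`, numeric(1), "days_before"))
  }
  expect_identical(c0$exclusions$reason, c1$exclusions$reason)
})

test_that("synthetic cohort case fraction matches generator expectation", {
  sim <- generate_cohort(sim_config(n_patients = 2000, seed = 37))
  coh <- build_cohort(sim$timelines)
  labs <- vapply(coh$samples, `[[`, character(1), "label")
  tr <- sim$truth[!is.na(sim$truth$eta), ]
  p <- plogis(tr$eta)
  se <- sqrt(sum(p * (1 - p))) / nrow(tr)
  expect_lt(abs(mean(labs == "case") - mean(p)), 3 * se + 0.01)
})
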