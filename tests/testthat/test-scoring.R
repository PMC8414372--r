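one_patient <- function(samples, t_end = 24, group = "control",
                        id = "p1") {
  build_cohort(list(list(id = id, group = group, t_end = t_end,
                         samples = samples)))
}

test_that("a single measurement time scores once, unimputed, like compute_mews", {
  co <- one_patient(samples_tbl(
    c("SBP", "HR", "RR", "TEMP", "GCS"), rep(1, 5),
    c(85, 112, 22, 38.6, 12)))
  s <- score_cohort(co, "base")
  expect_equal(nrow(s), 1)
  expect_equal(s$time_h, 1)
  expect_equal(s$total, 8L)
  expect_false(any(unlist(s[, c("SBP_imp", "HR_imp", "RR_imp", "TEMP_imp",
                                "GCS_imp")])))
})

test_that("event-driven scoring carries values forward and flags them", {
  co <- one_patient(samples_tbl(
    c("SBP", "HR", "RR", "TEMP", "HR"), c(1, 1, 1, 1, 2),
    c(120, 70, 12, 36.8, 105)))
  s <- score_cohort(co, "base")
  expect_equal(s$time_h, c(1, 2))
  # at t = 2 only HR is fresh
  expect_false(s$HR_imp[2])
  expect_true(all(unlist(s[2, c("SBP_imp", "RR_imp", "TEMP_imp")])))
  expect_equal(s$total, c(0L, 1L))  # HR 105 scores 1 at t = 2
})

test_that("no score is emitted before all mandatory parameters are seen", {
  co <- one_patient(samples_tbl(
    c("SBP", "HR", "RR", "TEMP", "GCS"), c(1, 2, 3, 4, 0.5),
    c(120, 70, 12, 36.8, 15)))
  s <- score_cohort(co, "base")
  expect_equal(min(s$time_h), 4)
})

test_that("score count equals distinct times from first completeness onward", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      co <- random_cohort(n_case = 1, n_control = 1)
      s <- score_cohort(co, "base")
      for (id in unique(co$patient_id)) {
        sam <- co[co$patient_id == id, ]
        first_complete <- max(vapply(
          mandatory_parameters(),
          function(p) min(sam$time_h[sam$parameter == p]), numeric(1)))
        expected_times <- sort(unique(sam$time_h[sam$time_h >= first_complete]))
        expect_equal(s$time_h[s$patient_id == id], expected_times)
      }
    }
  })
})

test_that("interval summaries follow the median / worst definitions", {
  base_samples <- samples_tbl(c("SBP", "RR", "TEMP", "GCS"), rep(0.2, 4),
                              c(120, 12, 36.8, 15))
  hr <- samples_tbl("HR", c(0.5, 1.0, 1.5), c(70, 100, 120))
  co <- one_patient(dplyr::bind_rows(base_samples, hr), t_end = 2)
  med <- score_cohort(co, "median", t_mews = 2)
  expect_equal(med$time_h, 2)
  expect_equal(med$HR_pts, 0L)   # element median 100
  wst <- score_cohort(co, "worst", t_mews = 2)
  expect_equal(wst$HR_pts, 2L)   # 120 attracts the most points
  # lower element median of an even count is an observed value
  hr2 <- samples_tbl("HR", c(0.5, 1.0), c(70, 100))
  co2 <- one_patient(dplyr::bind_rows(base_samples, hr2), t_end = 2)
  med2 <- score_cohort(co2, "median", t_mews = 2)
  expect_equal(med2$HR_pts, 0L)  # lower median 70 -> 0 points
})

test_that("empty intervals are scored entirely from carried-forward values", {
  s0 <- samples_tbl(c("SBP", "HR", "RR", "TEMP"), rep(0.5, 4),
                    c(120, 70, 12, 36.8))
  co <- one_patient(s0, t_end = 6)
  s <- score_cohort(co, "median", t_mews = 2)
  expect_equal(s$time_h, c(2, 4, 6))
  expect_true(all(unlist(s[2:3, c("SBP_imp", "HR_imp", "RR_imp",
                                  "TEMP_imp")])))
  expect_equal(s$total, rep(0L, 3))
})

test_that("carried values expire under a finite maximum carry-forward age", {
  s0 <- dplyr::bind_rows(
    samples_tbl(c("SBP", "HR", "RR", "TEMP"), rep(1, 4),
                c(120, 70, 12, 36.8)),
    samples_tbl("HR", c(5, 10), c(72, 75)))
  co <- one_patient(s0, t_end = 12)
  s_inf <- score_cohort(co, "base")
  expect_equal(s_inf$time_h, c(1, 5, 10))
  s_short <- score_cohort(co, "base", max_carry_h = 3)
  # at t = 5 and 10 the non-HR parameters are older than 3 h -> no score
  expect_equal(s_short$time_h, 1)
})

test_that("worst-case totals dominate median totals at aligned times", {
  withr::with_seed(7, {
    for (rep in 1:8) {
      co <- random_cohort(n_case = 2, n_control = 2)
      med <- score_cohort(co, "median", t_mews = 4)
      wst <- score_cohort(co, "worst", t_mews = 4)
      j <- dplyr::inner_join(
        tibble::as_tibble(med)[c("patient_id", "time_h", "total")],
        tibble::as_tibble(wst)[c("patient_id", "time_h", "total")],
        by = c("patient_id", "time_h"), suffix = c("_med", "_wst"))
      expect_gt(nrow(j), 0)
      expect_true(all(j$total_wst >= j$total_med))
    }
  })
})

test_that("totals equal the sum of available subscores and stay in range", {
  withr::with_seed(21, {
    co <- random_cohort(n_case = 3, n_control = 3)
    for (variant in c("base", "median", "worst")) {
      s <- score_cohort(co, variant,
                        t_mews = if (variant == "base") NULL else 6)
      pts <- as.matrix(s[, c("SBP_pts", "HR_pts", "RR_pts", "TEMP_pts",
                             "AVPU_pts")])
      expect_equal(s$total, as.integer(rowSums(pts, na.rm = TRUE)))
      expect_true(all(s$total >= 0 & s$total <= 14))
    }
    # without GCS the ceiling drops to 11
    co2 <- random_cohort(n_case = 2, n_control = 2, gcs = FALSE)
    s2 <- score_cohort(co2, "base")
    expect_true(all(s2$total <= 11))
    expect_true(all(is.na(s2$AVPU_pts)))
  })
})

test_that("adding a later measurement never changes earlier scores", {
  withr::with_seed(5, {
    co <- random_cohort(n_case = 1, n_control = 0, t_end_max = 30)
    s1 <- score_cohort(co, "base")
    t_new <- max(co$time_h) + 1
    extra <- tibble::tibble(
      patient_id = co$patient_id[1], group = co$group[1], parameter = "HR",
      time_h = t_new, value = 140, t_end_h = max(co$t_end_h, t_new + 1))
    co2 <- as_cohort(dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(co), t_end_h = extra$t_end_h), extra))
    s2 <- score_cohort(co2, "base")
    common <- s2[s2$time_h < t_new, ]
    expect_equal(common$total, s1$total)
    expect_equal(common$time_h, s1$time_h)
  })
})

test_that("score series survive a CSV round trip", {
  withr::with_seed(3, {
    co <- random_cohort(n_case = 1, n_control = 1)
    s <- score_cohort(co, "worst", t_mews = 6)
    path <- withr::local_tempfile(fileext = ".csv")
    write_scores(s, path)
    back <- read_scores(path, variant = "worst", t_mews = 6)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(s)[names(back)])
  })
})
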