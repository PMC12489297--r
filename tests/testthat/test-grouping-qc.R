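kc <- kinetic_constants()

# one-point-per-curve table for grouping tests: the grouping logic only
# looks at identifiers and dates
curve_rows <- function(curve_id, date, study_id = "s1", species = "sp",
                       genotype = "g1") {
  data.frame(study_id = study_id, curve_id = curve_id, species = species,
             genotype = genotype, date = date, tleaf = 25,
             ci = 400, a = 20, stringsAsFactors = FALSE)
}

test_that("5-day window grouping follows the greedy first-date rule", {
  # days 1 and 4 group together; day 8 starts a new group
  d <- rbind(curve_rows("c1", "2021-06-01"),
             curve_rows("c2", "2021-06-04"),
             curve_rows("c3", "2021-06-08"))
  gs <- consolidate_groups(d)
  expect_length(gs, 2L)
  expect_equal(gs[[1]]$n_group, 2L)
  expect_equal(gs[[2]]$n_group, 1L)

  # days 1, 5, 9: day 5 joins the day-1 anchor; day 9 exceeds the window
  # relative to day 1 and anchors a new group
  d <- rbind(curve_rows("c1", "2021-06-01"),
             curve_rows("c2", "2021-06-05"),
             curve_rows("c3", "2021-06-09"))
  gs <- consolidate_groups(d)
  expect_length(gs, 2L)
  expect_equal(gs[[1]]$n_group, 2L)

  # day 6 is exactly window_days after day 1 and still belongs
  d <- rbind(curve_rows("c1", "2021-06-01"),
             curve_rows("c2", "2021-06-06"),
             curve_rows("c3", "2021-06-07"))
  gs <- consolidate_groups(d)
  expect_length(gs, 2L)
})

test_that("grouping is stratified and invariant to input row order", {
  d <- rbind(curve_rows("c1", "2021-06-01"),
             curve_rows("c2", "2021-06-03"),
             curve_rows("c3", "2021-06-01", species = "sp2"),
             curve_rows("c4", "2021-06-02", genotype = "g2"),
             curve_rows("c5", "2021-06-20"))
  gs <- consolidate_groups(d)
  expect_length(gs, 4L)
  sizes <- unname(sort(vapply(gs, function(g) g$n_group, 0L)))
  expect_equal(sizes, c(1L, 1L, 1L, 2L))

  set.seed(9)
  d2 <- d[sample(nrow(d)), ]
  gs2 <- consolidate_groups(d2)
  memb <- function(gs) {
    m <- lapply(gs, function(g) sort(unique(g$points$curve_id)))
    m[order(vapply(m, paste, "", collapse = ","))]
  }
  expect_identical(memb(gs), memb(gs2))
})

test_that("curves without a date become singleton groups with a warning", {
  d <- rbind(curve_rows("c1", "2021-06-01"),
             curve_rows("c2", NA),
             curve_rows("c3", "2021-06-02"))
  expect_warning(gs <- consolidate_groups(d), "without a date")
  expect_length(gs, 2L)
  sizes <- unname(sort(vapply(gs, function(g) g$n_group, 0L)))
  expect_equal(sizes, c(1L, 2L))
})

test_that("group means and covariates are carried onto the group", {
  d <- rbind(curve_rows("c1", "2021-06-01"), curve_rows("c2", "2021-06-02"))
  d$tleaf <- c(24, 28)
  d$ppfd <- c(1400, 1600)
  d$subtype <- "NADP-ME"
  d$mean_tmax <- 31.5
  gs <- consolidate_groups(d)
  expect_equal(gs[[1]]$tleaf_mean, 26)
  expect_equal(gs[[1]]$ppfd_mean, 1500)
  expect_equal(gs[[1]]$covariates$subtype, "NADP-ME")
  expect_equal(gs[[1]]$covariates$mean_tmax, 31.5)
  expect_equal(gs[[1]]$date_first, as.Date("2021-06-01"))
})

test_that("point-count filters require two points in each Ci region", {
  expect_equal(point_count_filters(fake_fit(60, 35, 0.5, n_low = 2, n_high = 2)),
               c(keep_vpmax = TRUE, keep_amax = TRUE))
  expect_equal(point_count_filters(fake_fit(60, 35, 0.5, n_low = 1, n_high = 4)),
               c(keep_vpmax = FALSE, keep_amax = TRUE))
  expect_equal(point_count_filters(fake_fit(60, 35, 0.5, n_low = 4, n_high = 0)),
               c(keep_vpmax = TRUE, keep_amax = FALSE))
})

test_that("consistency check discards initial slopes above the saturated rate", {
  # PEPc-limited prediction at Ci = 50: 50*100/130 - 0.6
  bad <- fake_fit(vpmax = 100, amax = 30, alpha = 0.3)
  expect_equal(vp_limited_assimilation(50, bad$vpmax, bad$kp, bad$rm),
               37.8615384615, tolerance = 1e-9)
  expect_false(limitation_consistency_check(bad))
  # hyperbola variant reaches the same verdict on this example
  expect_equal(nrh_assimilation(50, 0.3, 30, 0.7, 1.2), 11.1866904487,
               tolerance = 1e-9)
  expect_false(limitation_consistency_check(bad, compare = "hyperbola"))
})

test_that("consistency check keeps healthy fits and ties", {
  good <- fake_fit(vpmax = 60, amax = 35, alpha = 0.5)
  expect_true(limitation_consistency_check(good))
  # the hyperbola variant needs the fitted light response to sit above the
  # PEPc-limited curve over the whole low-Ci grid, not just its asymptote
  steep <- fake_fit(vpmax = 60, amax = 60, alpha = 1)
  expect_true(limitation_consistency_check(steep, compare = "hyperbola"))
  # exceeds at exactly half the grid points (Ci 55..100): tie keeps
  # vp(50) = 37.86 < 39 = amax - rday < 40.14 = vp(55)
  tie <- fake_fit(vpmax = 100, amax = 40.2, alpha = 0.6)
  a_vp <- vp_limited_assimilation(seq(5, 100, 5), 100, 80, 0.6)
  expect_equal(sum(a_vp > 40.2 - 1.2), 10L)
  expect_true(limitation_consistency_check(tie))
  expect_false(limitation_consistency_check(tie, exceed_fraction = 0.45))
})

test_that("consistency check returns NA when a fit is unavailable", {
  expect_true(is.na(limitation_consistency_check(fake_fit(NA, 35, 0.5))))
  expect_true(is.na(limitation_consistency_check(fake_fit(60, NA, NA))))
})

test_that("a clean fitted curve passes the consistency check end to end", {
  fit <- fit_aci_group(make_group(vpmax = 60, amax_gross = 35,
                                  noise_sd = 0.3, seed = 2), kc)
  expect_true(limitation_consistency_check(fit))
})

test_that("run_qc accounts for every planted defect exactly once", {
  fits <- structure(list(
    fake_fit(60, 35, 0.5, group_id = "ok1"),
    fake_fit(55, 30, 0.4, group_id = "ok2"),
    fake_fit(60, 35, 0.5, n_low = 1, group_id = "lowci"),
    fake_fit(60, 35, 0.5, n_high = 1, group_id = "highci"),
    fake_fit(100, 30, 0.3, group_id = "inconsistent"),
    # fails both a point-count filter and (latently) consistency: must be
    # counted under the point-count stage only
    fake_fit(100, 30, 0.3, n_low = 0, group_id = "both")
  ), class = "aci_fit_list")
  qc <- run_qc(fits)
  expect_equal(qc$report$n_groups_formed, 6L)
  expect_equal(qc$report$n_groups_low_ci_discard, 2L)
  expect_equal(qc$report$n_groups_high_ci_discard, 1L)
  expect_equal(qc$report$n_groups_consistency_discard, 1L)
  expect_equal(qc$table$keep,
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(is.na(qc$table$keep_consistency[qc$table$group_id == "both"]))

  # idempotent: re-running on the same fits gives the identical table
  qc2 <- run_qc(fits)
  expect_identical(qc$table, qc2$table)
})

test_that("qc_report prints the staged accounting", {
  fits <- structure(list(fake_fit(60, 35, 0.5)), class = "aci_fit_list")
  out <- capture.output(print(run_qc(fits)$report))
  expect_true(any(grepl("groups formed", out)))
  expect_true(any(grepl("additional", out)))
})
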