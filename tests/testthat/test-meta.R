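# small designs keep the REML fits fast while exercising the full structure
small_design <- simulation_design(n_studies = 12, groups_per_study = c(4L, 8L))

test_that("REML fit matches the reference implementation on several datasets", {
  fml <- y ~ location + tleaf + mean_tmax + ppfd
  for (s in 1:5) {
    d <- simulate_meta_observations(small_design, seed = s)
    fit <- c4_meta(fml, d)
    # reference fit on pre-centred covariates so the designs coincide
    dc <- d
    for (cv in c("tleaf", "mean_tmax", "ppfd"))
      dc[[cv]] <- dc[[cv]] - mean(dc[[cv]])
    ref <- metafor::rma.mv(fml, V = dc$v,
                           random = list(~ 1 | study_id, ~ 1 | species,
                                         ~ 1 | group_id),
                           data = dc, method = "REML",
                           control = list(optimizer = "nlminb"))
    expect_equal(fit$beta$estimate, as.numeric(ref$beta), tolerance = 1e-4)
    expect_equal(fit$beta$se, as.numeric(ref$se), tolerance = 1e-4)
    expect_equal(unname(fit$sigma2), as.numeric(ref$sigma2), tolerance = 1e-3)
  }
})

test_that("balanced one-way layout reproduces the closed-form REML estimate", {
  k <- 10; m <- 5; v0 <- 2
  set.seed(21)
  u <- rnorm(k, 0, 3)
  d <- data.frame(study_id = rep(sprintf("s%02d", 1:k), each = m))
  d$y <- 50 + u[as.integer(factor(d$study_id))] + rnorm(k * m, 0, sqrt(v0))
  d$v <- v0
  fit <- c4_meta(y ~ 1, d, random = "study_id")
  means <- tapply(d$y, d$study_id, mean)
  closed <- max(0, var(as.numeric(means)) - v0 / m)
  expect_equal(unname(fit$sigma2), closed, tolerance = 1e-4)
  expect_equal(fit$beta$estimate, mean(means), tolerance = 1e-6)
})

test_that("GLS solution is internally consistent at the REML optimum", {
  d <- simulate_meta_observations(small_design, seed = 7)
  fit <- c4_meta(y ~ location + tleaf, d)
  V <- diag(fit$vi)
  for (f in fit$random) {
    z <- model.matrix(~ 0 + factor(d[[f]]))
    V <- V + fit$sigma2[f] * tcrossprod(z)
  }
  Vi <- solve(V)
  beta_gls <- solve(t(fit$X) %*% Vi %*% fit$X, t(fit$X) %*% Vi %*% fit$y)
  expect_equal(fit$beta$estimate, as.numeric(beta_gls), tolerance = 1e-8)
})

test_that("fit is equivariant under rescaling of the response", {
  d <- simulate_meta_observations(small_design, seed = 3)
  f1 <- c4_meta(y ~ location + tleaf, d)
  d2 <- d
  d2$y <- 10 * d2$y
  d2$v <- 100 * d2$v
  f2 <- c4_meta(y ~ location + tleaf, d2)
  expect_equal(f2$beta$estimate, 10 * f1$beta$estimate, tolerance = 1e-6)
  expect_equal(unname(f2$sigma2), 100 * unname(f1$sigma2), tolerance = 1e-4)
  expect_equal(f2$r2_marginal, f1$r2_marginal, tolerance = 1e-6)
})

test_that("centering changes coefficients but not predictions", {
  d <- simulate_meta_observations(small_design, seed = 5)
  fml <- y ~ location + tleaf * mean_tmax
  fc <- c4_meta(fml, d, center = TRUE)
  fu <- c4_meta(fml, d, center = FALSE)
  nd <- data.frame(location = c("indoor", "outdoor"),
                   tleaf = c(25, 32), mean_tmax = c(24, 30))
  expect_equal(predict(fc, nd), predict(fu, nd), tolerance = 1e-6)
  expect_false(isTRUE(all.equal(coef(fc)[["tleaf"]], coef(fu)[["tleaf"]])))
})

test_that("Wald tests flag planted effects and respect the null", {
  d <- simulate_meta_observations(simulation_design(n_studies = 30), seed = 11)
  fit <- c4_meta(y ~ location + tleaf + species_group, d)
  w <- wald_tests(fit)
  expect_equal(w$z, w$estimate / w$se)
  expect_lt(w$p[w$term == "tleaf"], 1e-4)        # true slope 3.58
  expect_lt(w$p[w$term == "locationoutdoor"], 1e-3)  # true offset -15.19
  expect_true(w$ci.lb[w$term == "tleaf"] < 3.58 &
                3.58 < w$ci.ub[w$term == "tleaf"])
})

test_that("R-squared behaves at the extremes", {
  d <- simulate_meta_observations(small_design, seed = 9)
  f0 <- c4_meta(y ~ 1, d)
  r0 <- r_squared(f0)
  expect_equal(unname(r0["r2_marginal"]), 0)
  expect_gt(unname(r0["r2_conditional"]), 0)
  expect_lt(unname(r0["r2_conditional"]), 1)
  f1 <- c4_meta(y ~ location + tleaf + mean_tmax, d)
  expect_gt(f1$r2_marginal, r_squared(f0)["r2_marginal"])
  expect_gt(f1$r2_conditional, f1$r2_marginal * 0)  # both defined
})

test_that("marginal means recover coefficient contrasts exactly", {
  d <- simulate_meta_observations(small_design, seed = 13)
  fit <- c4_meta(y ~ location + tleaf, d)
  mm <- marginal_means(fit, "location")
  b <- coef(fit)
  expect_equal(mm$mean[mm$level == "indoor"], unname(b["(Intercept)"]),
               tolerance = 1e-8)
  expect_equal(mm$mean[mm$level == "outdoor"] - mm$mean[mm$level == "indoor"],
               unname(b["locationoutdoor"]), tolerance = 1e-8)
  expect_true(all(mm$pi.lb < mm$ci.lb & mm$ci.ub < mm$pi.ub))
})

test_that("marginal means average other factors with the requested weights", {
  d <- simulate_meta_observations(small_design, seed = 15)
  fit <- c4_meta(y ~ location + growth_form + tleaf, d)
  b <- coef(fit)
  mm_eq <- marginal_means(fit, "location", weights = "equal")
  expect_equal(mm_eq$mean[mm_eq$level == "indoor"],
               unname(b["(Intercept)"] + 0.5 * b["growth_formmonocot"]),
               tolerance = 1e-8)
  p_mono <- mean(d$growth_form == "monocot")
  mm_fr <- marginal_means(fit, "location", weights = "frequency")
  expect_equal(mm_fr$mean[mm_fr$level == "indoor"],
               unname(b["(Intercept)"] + p_mono * b["growth_formmonocot"]),
               tolerance = 1e-8)
  expect_error(marginal_means(fit, "location", levels = "orbit"), "absent")
  expect_error(marginal_means(fit, "tleaf"), "not a factor")
})

test_that("prediction intervals widen with the random-effect variance", {
  d <- simulate_meta_observations(small_design, seed = 17)
  fit <- c4_meta(y ~ location + tleaf, d)
  nd <- data.frame(location = "indoor", tleaf = 30)
  ci <- predict(fit, nd, interval = "confidence")
  pi <- predict(fit, nd, interval = "prediction")
  expect_equal(ci$fit, pi$fit)
  expect_lt(pi$lwr, ci$lwr)
  expect_gt(pi$upr, ci$upr)
  expect_equal(unname(predict(fit, nd)), ci$fit)
})

test_that("prediction surface is separable without an interaction", {
  d <- simulate_meta_observations(small_design, seed = 19)
  fit <- c4_meta(y ~ location + tleaf + mean_tmax, d)
  s <- predict_surface(fit, tleaf = c(20, 30), mean_tmax = c(22, 28))
  p <- function(tl, tm) s$pred[s$tleaf == tl & s$mean_tmax == tm]
  expect_equal(p(20, 22) + p(30, 28), p(20, 28) + p(30, 22), tolerance = 1e-8)
  # interaction model breaks separability
  fit2 <- c4_meta(y ~ location + tleaf * mean_tmax, d)
  s2 <- predict_surface(fit2, tleaf = c(20, 30), mean_tmax = c(22, 28))
  p2 <- function(tl, tm) s2$pred[s2$tleaf == tl & s2$mean_tmax == tm]
  gap <- (p2(20, 22) + p2(30, 28)) - (p2(20, 28) + p2(30, 22))
  expect_equal(gap, 10 * 6 * unname(coef(fit2)["tleaf:mean_tmax"]),
               tolerance = 1e-8)
  sx <- predict_surface(fit, tleaf = c(10, 25), mean_tmax = c(25))
  expect_true(sx$extrapolated[sx$tleaf == 10])
  expect_false(sx$extrapolated[sx$tleaf == 25])
})

test_that("input validation catches the common failure modes", {
  d <- simulate_meta_observations(small_design, seed = 23)
  bad <- d; bad$v[1] <- -1
  expect_error(c4_meta(y ~ tleaf, bad), "positive")
  bad <- d; bad$tleaf[3] <- NA
  expect_error(c4_meta(y ~ tleaf, bad), "NA values")
  bad <- d; bad$twin <- bad$tleaf
  expect_error(c4_meta(y ~ tleaf + twin, bad), "rank deficient")
  expect_error(c4_meta(y ~ tleaf, d[1:5, ]), "at least 10")
  expect_error(c4_meta(y ~ nope, d), "missing column")
})

test_that("methods print, summarise and expose the fit", {
  d <- simulate_meta_observations(small_design, seed = 25)
  fit <- c4_meta(y ~ location + tleaf, d)
  out <- capture.output(summary(fit))
  expect_true(any(grepl("Variance components", out)))
  expect_true(any(grepl("Fixed effects", out)))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_true(is.finite(as.numeric(logLik(fit))))
  expect_true(fit$converged)
})
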