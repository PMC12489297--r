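#' Estimate apparent VpmaxA from the initial slope of an A/Ci curve group
#'
#' Fits A = Ci * VpmaxA / (Ci + Kp) - Rm by least squares over all pooled
#' points with Ci < 100 umol mol-1 across the group's replicate curves. Kp is
#' evaluated at the group-mean leaf temperature and converted to a mole
#' fraction at the group's pressure; Rm is \code{rm_fraction * Rday} at the
#' same temperature. The model is linear in VpmaxA, so the bounded
#' least-squares solution (regression through the origin on
#' x = Ci/(Ci + Kp), clipped to [0, 500]) is the global minimiser; the
#' sampling variance is the squared standard error from that regression.
#'
#' @param group A [curve_group()].
#' @param constants A [kinetic_constants()] object.
#' @param low_ci Strict upper Ci bound of the initial-slope region
#'   (default 100 umol mol-1).
#' @return List with \code{vpmax}, \code{var_vpmax}, \code{n_low},
#'   \code{converged}, \code{rss}, \code{kp}, \code{rm}.
#' @export
fit_vpmax <- function(group, constants = kinetic_constants(), low_ci = 100) {
  stopifnot(inherits(group, "curve_group"))
  kp <- kp_to_mole_fraction(kp_at_temperature(group$tleaf_mean, constants),
                            group$pressure)
  rm_ <- constants$rm_fraction * rday_at_temperature(group$tleaf_mean, constants)
  pts <- group$points[group$points$ci < low_ci, ]
  n_low <- nrow(pts)
  if (n_low == 0L)
    return(list(vpmax = NA_real_, var_vpmax = NA_real_, n_low = 0L,
                converged = FALSE, rss = NA_real_, kp = kp, rm = rm_))
  x <- pts$ci / (pts$ci + kp)
  y <- pts$a + rm_
  vpmax <- sum(x * y) / sum(x^2)
  at_bound <- vpmax < 0 || vpmax > 500
  vpmax <- min(max(vpmax, 0), 500)
  res <- y - vpmax * x
  rss <- sum(res^2)
  var_vpmax <- if (n_low > 1L) (rss / (n_low - 1L)) / sum(x^2) else NA_real_
  list(vpmax = vpmax, var_vpmax = var_vpmax, n_low = n_low,
       converged = !at_bound, rss = rss, kp = kp, rm = rm_)
}

#' Estimate Amax and alpha from the full A/Ci curve of a group
#'
#' Fits the non-rectangular hyperbola [nrh_assimilation()] over all pooled
#' points, with curvature theta and Rday fixed (Rday from the Q10 response at
#' the group-mean leaf temperature) and (alpha, Amax) free. Amax is the
#' horizontal asymptote of A + Rday. Bounded Gauss-Newton (\code{nls} "port")
#' with a deterministic three-point multi-start: alpha from the two
#' lowest-Ci points, Amax from the maximum observed A plus Rday, and scaled
#' variants of that pair; the lowest-RSS converged fit wins. Sampling
#' variances are the diagonal of the fit covariance.
#'
#' @inheritParams fit_vpmax
#' @param high_ci Strict lower Ci bound defining "high-Ci" points for QC
#'   counting (default 500 umol mol-1).
#' @return List with \code{amax}, \code{var_amax}, \code{alpha},
#'   \code{var_alpha}, \code{n_high}, \code{converged}, \code{rss},
#'   \code{rday}.
#' @export
fit_amax <- function(group, constants = kinetic_constants(), high_ci = 500) {
  stopifnot(inherits(group, "curve_group"))
  rday <- rday_at_temperature(group$tleaf_mean, constants)
  theta <- constants$theta
  pts <- group$points
  n_high <- sum(pts$ci > high_ci)
  out <- list(amax = NA_real_, var_amax = NA_real_, alpha = NA_real_,
              var_alpha = NA_real_, n_high = n_high, converged = FALSE,
              rss = NA_real_, rday = rday)
  if (nrow(pts) < 4L) return(out)

  lower <- c(alpha = 1e-8, amax = 1e-6)
  upper <- c(alpha = 5, amax = 200)
  ord <- order(pts$ci)
  p2 <- pts[ord[1:2], ]
  dci <- diff(p2$ci)
  alpha0 <- if (dci > 0) diff(p2$a) / dci else (p2$a[1] + rday) / max(p2$ci[1], 1)
  alpha0 <- min(max(alpha0, 0.01), 4.9)
  amax0 <- min(max(max(pts$a) + rday, 1), 199)
  starts <- list(c(alpha0, amax0),
                 c(alpha0 / 2, min(amax0 * 1.2, 199)),
                 c(min(alpha0 * 2, 4.9), amax0 * 0.9))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::nls(a ~ nrh_assimilation(ci, alpha, amax, theta, rday),
                 data = pts,
                 start = list(alpha = s[1], amax = s[2]),
                 lower = lower, upper = upper, algorithm = "port",
                 control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(out)

  cf <- stats::coef(best$fit)
  vc <- tryCatch(diag(stats::vcov(best$fit)),
                 error = function(e) c(alpha = NA_real_, amax = NA_real_))
  at_bound <- any(abs(cf - lower) < 1e-7) || any(abs(cf - upper) < 1e-7)
  list(amax = unname(cf["amax"]), var_amax = unname(vc["amax"]),
       alpha = unname(cf["alpha"]), var_alpha = unname(vc["alpha"]),
       n_high = n_high, converged = !at_bound, rss = best$rss, rday = rday)
}

#' Fit both capacity parameters of an A/Ci curve group
#'
#' Runs [fit_vpmax()] and [fit_amax()] on one consolidated group and returns
#' a classed fit object carrying estimates, sampling variances, point counts
#' and convergence flags. Fit failures are recorded, never raised, so that
#' downstream quality control can account for every group.
#'
#' @inheritParams fit_vpmax
#' @param high_ci Strict lower Ci bound for high-Ci point counting.
#' @return An object of class \code{"aci_fit"}.
#' @examples
#' kc <- kinetic_constants()
#' ci <- c(20, 50, 80, 150, 300, 600, 1000, 1500)
#' a <- blended_forward_curve(ci, vpmax = 60, amax_gross = 35,
#'                            kp = kp_at_temperature(25, kc), rday = 1.2)
#' g <- curve_group("demo", data.frame(curve_id = 1, ci = ci, a = a))
#' fit <- fit_aci_group(g, kc)
#' coef(fit)
#' @export
fit_aci_group <- function(group, constants = kinetic_constants(),
                          low_ci = 100, high_ci = 500) {
  stopifnot(inherits(group, "curve_group"))
  fv <- fit_vpmax(group, constants, low_ci = low_ci)
  fa <- fit_amax(group, constants, high_ci = high_ci)
  structure(
    list(group_id = group$group_id, study_id = group$study_id,
         species = group$species, genotype = group$genotype,
         date_first = group$date_first,
         covariates = group$covariates, n_group = group$n_group,
         n_points = nrow(group$points),
         tleaf_mean = group$tleaf_mean, ppfd_mean = group$ppfd_mean,
         pressure = group$pressure,
         kp = fv$kp, rm = fv$rm, rday = fa$rday, theta = constants$theta,
         vpmax = fv$vpmax, var_vpmax = fv$var_vpmax, n_low = fv$n_low,
         converged_vpmax = fv$converged, rss_vpmax = fv$rss,
         amax = fa$amax, var_amax = fa$var_amax,
         alpha = fa$alpha, var_alpha = fa$var_alpha, n_high = fa$n_high,
         converged_amax = fa$converged, rss_amax = fa$rss,
         points = group$points),
    class = "aci_fit"
  )
}

#' @export
print.aci_fit <- function(x, ...) {
  cat(sprintf("A/Ci group fit '%s' (%d curves, %d points)\n",
              x$group_id, x$n_group, x$n_points))
  cat(sprintf("  VpmaxA %.2f (SE %.2f, n_low %d%s)\n",
              x$vpmax, sqrt(x$var_vpmax), x$n_low,
              if (isTRUE(x$converged_vpmax)) "" else ", NOT converged"))
  cat(sprintf("  Amax   %.2f (SE %.2f)  alpha %.3f (SE %.3f)  n_high %d%s\n",
              x$amax, sqrt(x$var_amax), x$alpha, sqrt(x$var_alpha), x$n_high,
              if (isTRUE(x$converged_amax)) "" else ", NOT converged"))
  invisible(x)
}

#' @export
coef.aci_fit <- function(object, ...) {
  c(vpmax = object$vpmax, amax = object$amax, alpha = object$alpha)
}

#' Predicted assimilation from a fitted A/Ci group
#'
#' @param object An \code{"aci_fit"}.
#' @param ci Ci values at which to predict (defaults to the fitted points).
#' @param model \code{"nrh"} for the full-curve hyperbola or \code{"vp"} for
#'   the PEPc-limited initial-slope model.
#' @param ... Unused.
#' @return Numeric vector of predicted A.
#' @export
predict.aci_fit <- function(object, ci = object$points$ci,
                            model = c("nrh", "vp"), ...) {
  model <- match.arg(model)
  if (model == "nrh")
    nrh_assimilation(ci, object$alpha, object$amax, object$theta, object$rday)
  else
    vp_limited_assimilation(ci, object$vpmax, object$kp, object$rm)
}

#' @export
residuals.aci_fit <- function(object, model = c("nrh", "vp"), ...) {
  model <- match.arg(model)
  if (model == "vp") {
    pts <- object$points[object$points$ci < 100, ]
    pts$a - predict(object, pts$ci, model = "vp")
  } else {
    object$points$a - predict(object, model = "nrh")
  }
}

#' @export
plot.aci_fit <- function(x, ...) {
  pts <- x$points
  grid <- seq(0, max(pts$ci), length.out = 200)
  graphics::plot(pts$ci, pts$a, xlab = expression(C[i]~(mu*mol~mol^-1)),
                 ylab = expression(A~(mu*mol~m^-2~s^-1)),
                 main = paste("Group", x$group_id), ...)
  if (is.finite(x$amax))
    graphics::lines(grid, predict(x, grid, model = "nrh"), col = "steelblue")
  lo <- grid[grid < 150]
  if (is.finite(x$vpmax))
    graphics::lines(lo, predict(x, lo, model = "vp"), col = "firebrick",
                    lty = 2)
  invisible(x)
}

#' Fit every group of a dataset and assemble the parameter table
#'
#' @param groups List of [curve_group()] objects (e.g. from
#'   [consolidate_groups()]).
#' @param constants A [kinetic_constants()] object.
#' @return List of \code{"aci_fit"} objects with class
#'   \code{"aci_fit_list"}.
#' @export
fit_groups <- function(groups, constants = kinetic_constants()) {
  structure(lapply(groups, fit_aci_group, constants = constants),
            class = "aci_fit_list")
}

#' Parameter table from a list of group fits
#'
#' One row per group, mirroring a deposited estimates table: identifiers,
#' covariates, estimates with standard errors, point counts and convergence
#' flags.
#'
#' @param fits An \code{"aci_fit_list"} or list of \code{"aci_fit"}.
#' @return data.frame.
#' @export
parameter_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    cv <- f$covariates
    getc <- function(nm) if (!is.null(cv[[nm]])) cv[[nm]] else NA
    data.frame(
      group_id = f$group_id, study_id = f$study_id, species = f$species,
      genotype = f$genotype,
      date_first = if (!is.null(f$date_first)) as.character(f$date_first)
                   else NA_character_,
      subtype = getc("subtype"), growth_form = getc("growth_form"),
      location = getc("location"), mean_tmax = getc("mean_tmax"),
      mean_tmin = getc("mean_tmin"), growth_co2 = getc("growth_co2"),
      species_group = getc("species_group"),
      tleaf = f$tleaf_mean, ppfd = f$ppfd_mean,
      vpmax = f$vpmax, se_vpmax = sqrt(f$var_vpmax),
      amax = f$amax, se_amax = sqrt(f$var_amax),
      alpha = f$alpha, se_alpha = sqrt(f$var_alpha),
      n_group = f$n_group, n_low = f$n_low, n_high = f$n_high,
      converged_vpmax = f$converged_vpmax, converged_amax = f$converged_amax,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
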