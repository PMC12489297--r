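#' Standardized major axis slopes by leaf-temperature bin
#'
#' SMA (reduced major axis) regression treats both variables as subject to
#' error: the slope is sign(r) * sd(y)/sd(x) and the line passes through the
#' centroid. Slopes are fitted per bin and compared with the Warton-style
#' likelihood-ratio test of a common slope: under a shared slope b, the
#' residual axis y - b*x and the fitted axis y + b*x are uncorrelated within
#' every bin, so the statistic -sum(n_i * log(1 - r_i(b)^2)) evaluated at the
#' best common slope is asymptotically chi-squared with (bins - 1) degrees of
#' freedom.
#'
#' @param x,y Numeric vectors (e.g. VpmaxA and Amax estimates).
#' @param bins Factor or vector assigning each point to a bin; NULL fits a
#'   single overall SMA.
#' @return Object of class \code{"sma_fit"}: data.frame \code{slopes} (bin,
#'   n, slope, intercept, r), \code{common_slope}, \code{lr_stat},
#'   \code{df}, \code{p_common}.
#' @export
sma_fit <- function(x, y, bins = NULL) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  bins <- if (is.null(bins)) rep("all", length(x)) else as.character(bins[ok])
  sp <- split(data.frame(x = x, y = y), bins)
  sp <- sp[vapply(sp, nrow, 0L) >= 3L]
  if (!length(sp)) stop("need at least one bin with >= 3 points")
  slopes <- do.call(rbind, lapply(names(sp), function(b) {
    d <- sp[[b]]
    if (stats::sd(d$x) == 0) stop("zero variance in x within bin ", b)
    r <- stats::cor(d$x, d$y)
    sl <- sign(ifelse(r == 0, 1, r)) * stats::sd(d$y) / stats::sd(d$x)
    data.frame(bin = b, n = nrow(d), slope = sl,
               intercept = mean(d$y) - sl * mean(d$x), r = r,
               stringsAsFactors = FALSE)
  }))
  rownames(slopes) <- NULL

  lr <- df <- p <- common <- NA_real_
  if (length(sp) > 1L) {
    resid_fitted_cor2 <- function(b, d) {
      u <- d$y - b * d$x
      w <- d$y + b * d$x
      if (stats::sd(u) == 0 || stats::sd(w) == 0) return(0)
      stats::cor(u, w)^2
    }
    negll <- function(b) sum(vapply(sp, function(d)
      -nrow(d) * log(max(1 - resid_fitted_cor2(b, d), 1e-12)), 0))
    rng <- range(slopes$slope)
    pad <- diff(rng) + 0.5 * max(abs(rng)) + 1e-6
    opt <- stats::optimize(negll, c(rng[1] - pad, rng[2] + pad), tol = 1e-9)
    common <- opt$minimum
    lr <- opt$objective
    df <- length(sp) - 1
    p <- stats::pchisq(lr, df, lower.tail = FALSE)
  }
  structure(list(slopes = slopes, common_slope = common, lr_stat = lr,
                 df = df, p_common = p),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat("Standardized major axis fit\n")
  print(x$slopes, row.names = FALSE)
  if (!is.na(x$lr_stat))
    cat(sprintf("Common-slope test: LR = %.3f on %d df, p = %.4g\n",
                x$lr_stat, x$df, x$p_common))
  invisible(x)
}

#' Logarithmic relationship between Amax and VpmaxA
#'
#' Ordinary least squares of amax on log(vpmax):
#' amax = a + b * ln(vpmax). Captures the saturating coupling of the
#' CO2-saturated rate to PEPc capacity across groups.
#'
#' @param vpmax Positive numeric vector.
#' @param amax Numeric vector of the same length.
#' @return List with \code{a}, \code{b}, \code{r2} and the underlying
#'   \code{lm} fit.
#' @export
log_linear_fit <- function(vpmax, amax) {
  stopifnot(length(vpmax) == length(amax))
  bad <- which(!is.finite(vpmax) | vpmax <= 0)
  if (length(bad))
    stop("vpmax must be positive; offending row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  fit <- stats::lm(amax ~ log(vpmax))
  cf <- stats::coef(fit)
  list(a = unname(cf[1]), b = unname(cf[2]),
       r2 = summary(fit)$r.squared, fit = fit)
}
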