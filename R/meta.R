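#' Default fixed-effects structure of the capacity meta-regression
#'
#' Main effects for C4 subtype, growth form, growth location, mean maximum
#' growth temperature, growth CO2, leaf temperature, PPFD and species group,
#' plus the a priori interactions of subtype and growth form with the two
#' temperatures and PPFD, and the Tleaf x mean Tmax interaction.
#'
#' @param response Name of the response column (e.g. \code{"vpmax"}).
#' @return A formula.
#' @export
default_meta_formula <- function(response = "y") {
  stats::as.formula(paste(
    response,
    "~ subtype + growth_form + location + mean_tmax + growth_co2 + tleaf +",
    "ppfd + species_group + subtype:tleaf + subtype:mean_tmax +",
    "subtype:ppfd + growth_form:tleaf + growth_form:mean_tmax +",
    "growth_form:ppfd + tleaf:mean_tmax"))
}

#' Multilevel meta-regression with known sampling variances
#'
#' Fits y_i = x_i' beta + sum_k u_k[i] + e_i where the u_k are independent
#' random intercepts for each factor named in \code{random} (typically study,
#' species and an observation-level "group" intercept capturing residual
#' heterogeneity) and e_i ~ N(0, v_i) with v_i the known sampling variance of
#' each estimate. Variance components are estimated by restricted maximum
#' likelihood on the marginal covariance
#' V = sum_k sigma2_k Z_k Z_k' + diag(v); beta is the GLS solution at the
#' REML optimum. Continuous covariates are mean-centred before interactions
#' are formed, so main effects are evaluated at the average observed
#' conditions.
#'
#' The optimiser (\code{nlminb} over log variance components, starting at
#' var(y)/4 for every component) is deterministic: the same data always give
#' the same fit. Non-negativity of the components is enforced by the log
#' parameterisation.
#'
#' @param formula Fixed-effects formula (response on the left).
#' @param data data.frame of meta-observations; must contain the response,
#'   all covariates and the columns named in \code{v} and \code{random}.
#' @param v Name of the column holding the known sampling variances
#'   (default \code{"v"}); all values must be positive.
#' @param random Character vector of grouping-factor column names for the
#'   random intercepts (default \code{c("study_id", "species", "group_id")}).
#' @param center Centre numeric covariates before building the design
#'   (default TRUE).
#' @return Object of class \code{"c4_meta"} with elements \code{beta} (the
#'   coefficient table), \code{sigma2} (named variance components),
#'   \code{vb} (covariance of beta), \code{loglik_reml},
#'   \code{r2_marginal}, \code{r2_conditional}, \code{n_obs},
#'   \code{n_studies} and the design bookkeeping needed for prediction.
#' @examples
#' d <- simulate_meta_observations(simulation_design(n_studies = 15), seed = 1)
#' fit <- c4_meta(y ~ location + tleaf, d, random = c("study_id", "species"))
#' summary(fit)
#' @export
c4_meta <- function(formula, data, v = "v",
                    random = c("study_id", "species", "group_id"),
                    center = TRUE) {
  stopifnot(is.data.frame(data))
  if (!v %in% names(data)) stop("sampling-variance column '", v, "' not found")
  vi <- data[[v]]
  if (any(!is.finite(vi)) || any(vi <= 0))
    stop("all sampling variances must be positive and finite")
  n <- nrow(data)
  if (n < 10L) stop("need at least 10 observations")

  covars <- all.vars(formula[[3]])
  miss <- setdiff(c(all.vars(formula[[2]]), covars, random), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  has_na <- covars[vapply(covars, function(cc) anyNA(data[[cc]]), TRUE)]
  if (length(has_na))
    stop("NA values in covariate(s): ", paste(has_na, collapse = ", "))

  centers <- numeric(0)
  work <- data
  for (cv in covars) {
    if (is.character(work[[cv]])) work[[cv]] <- factor(work[[cv]])
    if (center && is.numeric(work[[cv]])) {
      centers[cv] <- mean(work[[cv]])
      work[[cv]] <- work[[cv]] - centers[cv]
    }
  }

  mf <- stats::model.frame(formula, work)
  tt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(tt, mf)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    qx <- qr(X)
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design matrix rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  random <- unique(random)
  ZZt <- lapply(random, function(f) {
    z <- stats::model.matrix(~ 0 + factor(data[[f]]))
    tcrossprod(z)
  })
  names(ZZt) <- random
  k <- length(ZZt)

  reml_pieces <- function(sig2) {
    V <- diag(vi, n)
    for (j in seq_len(k)) V <- V + sig2[j] * ZZt[[j]]
    cv <- chol(V)
    Xi <- backsolve(cv, X, transpose = TRUE)   # cv^-T X
    yi <- backsolve(cv, y, transpose = TRUE)
    xtvx <- crossprod(Xi)
    beta <- solve(xtvx, crossprod(Xi, yi))
    r <- yi - Xi %*% beta
    list(logdetV = 2 * sum(log(diag(cv))),
         logdetXtVX = determinant(xtvx, logarithm = TRUE)$modulus[1],
         quad = sum(r^2), beta = drop(beta), xtvx = xtvx)
  }
  objective <- function(lsig2) {
    pc <- reml_pieces(exp(lsig2))
    pc$logdetV + pc$logdetXtVX + pc$quad
  }

  start <- rep(log(max(stats::var(y) / 4, 1e-6)), k)
  opt <- stats::nlminb(start, objective,
                       lower = rep(log(1e-10), k),
                       upper = rep(log(1e6 * max(stats::var(y), 1)), k),
                       control = list(iter.max = 500, eval.max = 1000,
                                      rel.tol = 1e-12))
  sigma2 <- stats::setNames(exp(opt$par), random)
  pc <- reml_pieces(sigma2)
  vb <- solve(pc$xtvx)
  beta <- pc$beta
  se <- sqrt(diag(vb))
  zcrit <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = colnames(X), estimate = beta, se = se, z = beta / se,
    ci.lb = beta - zcrit * se, ci.ub = beta + zcrit * se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  loglik_reml <- -0.5 * (pc$logdetV + pc$logdetXtVX + pc$quad +
                           (n - p) * log(2 * pi))

  var_fixed <- stats::var(drop(X %*% beta))
  tot_re <- sum(sigma2)
  r2m <- if (var_fixed + tot_re > 0) var_fixed / (var_fixed + tot_re) else 0
  r2c <- (var_fixed + tot_re) / (var_fixed + tot_re + mean(vi))

  structure(
    list(beta = coefs, sigma2 = sigma2, vb = vb,
         loglik_reml = loglik_reml, converged = opt$convergence == 0,
         r2_marginal = r2m, r2_conditional = r2c,
         n_obs = n,
         n_studies = if ("study_id" %in% names(data))
           length(unique(data$study_id)) else NA_integer_,
         formula = formula, terms = tt, centers = centers,
         xlevels = stats::.getXlevels(tt, mf),
         X = X, y = y, vi = vi, random = random, data = data,
         objective = opt$objective),
    class = "c4_meta"
  )
}

#' @export
print.c4_meta <- function(x, ...) {
  cat(sprintf("Multilevel meta-regression (REML), %d obs, %s studies\n",
              x$n_obs, x$n_studies))
  cat("Variance components:\n")
  print(round(x$sigma2, 4))
  cat(sprintf("Marginal R2 %.3f, conditional R2 %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' @export
summary.c4_meta <- function(object, ...) {
  print(object)
  cat("\nFixed effects:\n")
  tab <- object$beta
  tab[, -1] <- lapply(tab[, -1], function(z) round(z, 4))
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.c4_meta <- function(object, ...) {
  stats::setNames(object$beta$estimate, object$beta$term)
}

#' @export
vcov.c4_meta <- function(object, ...) object$vb

#' @export
logLik.c4_meta <- function(object, ...) {
  structure(object$loglik_reml, df = nrow(object$beta) + length(object$sigma2),
            class = "logLik")
}

#' Per-coefficient Wald tests of a fitted meta-regression
#'
#' z = estimate/SE with two-sided normal p-values and 95 percent confidence
#' intervals, the standard large-sample inference for meta-regression.
#'
#' @param fit A \code{"c4_meta"}.
#' @return data.frame with term, estimate, se, z, ci bounds and p.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "c4_meta"))
  fit$beta
}

#' Marginal and conditional R-squared of a meta-regression
#'
#' Variance-partition R2: the marginal R2 is the share of var(X beta) in
#' var(X beta) plus all random-intercept components; the conditional R2 adds
#' the mean known sampling variance to the denominator, so it is the share
#' explained by fixed plus random effects relative to the total including
#' sampling error.
#'
#' @param fit A \code{"c4_meta"}.
#' @return Named numeric vector \code{c(r2_marginal, r2_conditional)}.
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "c4_meta"))
  c(r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional)
}

# model-matrix rows for new covariate values, applying stored centering
meta_design_rows <- function(fit, newdata) {
  for (cv in names(fit$centers))
    if (cv %in% names(newdata))
      newdata[[cv]] <- newdata[[cv]] - fit$centers[cv]
  tt <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels)
  stats::model.matrix(tt, mf)
}

#' Predict from a fitted meta-regression
#'
#' @param object A \code{"c4_meta"}.
#' @param newdata data.frame of covariates on the original (uncentred)
#'   scale; centering is re-applied internally.
#' @param interval \code{"none"}, \code{"confidence"} or
#'   \code{"prediction"} (prediction adds all random-effect variance).
#' @param level Interval level (default 0.95).
#' @param ... Unused.
#' @return Vector of predictions, or a data.frame with \code{fit},
#'   \code{lwr}, \code{upr}.
#' @export
predict.c4_meta <- function(object, newdata,
                            interval = c("none", "confidence", "prediction"),
                            level = 0.95, ...) {
  interval <- match.arg(interval)
  L <- meta_design_rows(object, newdata)
  est <- drop(L %*% coef(object))
  if (interval == "none") return(est)
  se2 <- rowSums((L %*% object$vb) * L)
  if (interval == "prediction") se2 <- se2 + sum(object$sigma2)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(fit = est, lwr = est - zc * sqrt(se2), upr = est + zc * sqrt(se2))
}

#' Model-predicted marginal means of a factor
#'
#' Means for each level of \code{factor_name} with continuous covariates at
#' their observed means (centred zero) and the other factors averaged over
#' their levels, by default with equal weights. Confidence intervals use the
#' covariance of the fixed effects; prediction intervals additionally carry
#' the summed random-effect variance, describing where a new group-level
#' estimate would fall.
#'
#' @param fit A \code{"c4_meta"}.
#' @param factor_name Name of a factor in the model.
#' @param levels Levels to report (default: all levels seen when fitting).
#' @param weights \code{"equal"} (default) or \code{"frequency"} weighting of
#'   the other factors' level combinations.
#' @return data.frame with level, mean, CI and PI bounds.
#' @export
marginal_means <- function(fit, factor_name, levels = NULL,
                           weights = c("equal", "frequency")) {
  stopifnot(inherits(fit, "c4_meta"))
  weights <- match.arg(weights)
  xl <- fit$xlevels
  if (!factor_name %in% names(xl))
    stop("'", factor_name, "' is not a factor in the model")
  if (is.null(levels)) levels <- xl[[factor_name]]
  if (!all(levels %in% xl[[factor_name]]))
    stop("level(s) absent from the fitted data: ",
         paste(setdiff(levels, xl[[factor_name]]), collapse = ", "))

  others <- setdiff(names(xl), factor_name)
  grid_base <- if (length(others))
    expand.grid(xl[others], stringsAsFactors = FALSE)
  else data.frame(row.names = 1)
  w <- if (weights == "equal" || !length(others)) {
    rep(1 / max(nrow(grid_base), 1), max(nrow(grid_base), 1))
  } else {
    obs <- fit$data[, others, drop = FALSE]
    keys <- do.call(paste, c(obs, sep = "\r"))
    gkeys <- do.call(paste, c(grid_base, sep = "\r"))
    cnt <- table(keys)[gkeys]
    cnt[is.na(cnt)] <- 0
    as.numeric(cnt) / sum(cnt)
  }
  cont <- names(fit$centers)
  zc <- stats::qnorm(0.975)
  tot_re <- sum(fit$sigma2)
  out <- lapply(levels, function(lv) {
    nd <- grid_base
    nd[[factor_name]] <- lv
    for (cv in cont) nd[[cv]] <- fit$centers[cv]  # centred to zero internally
    M <- meta_design_rows(fit, nd)
    L <- matrix(w %*% M, nrow = 1)
    est <- drop(L %*% coef(fit))
    se2 <- drop(L %*% fit$vb %*% t(L))
    data.frame(level = lv, mean = est,
               ci.lb = est - zc * sqrt(se2), ci.ub = est + zc * sqrt(se2),
               pi.lb = est - zc * sqrt(se2 + tot_re),
               pi.ub = est + zc * sqrt(se2 + tot_re),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Predicted response surface over leaf and growth temperature
#'
#' Evaluates the fitted model on a Tleaf x mean Tmax grid with every other
#' continuous covariate at its observed mean and factors at their reference
#' (first) level, for contour plotting of the temperature interaction.
#' Grid points outside the observed covariate ranges are returned but
#' flagged as extrapolation.
#'
#' @param fit A \code{"c4_meta"} whose model contains \code{tleaf} and
#'   \code{mean_tmax}.
#' @param tleaf,mean_tmax Numeric grid vectors (degC).
#' @param ref Optional named list overriding reference factor levels.
#' @return Long-format data.frame: tleaf, mean_tmax, pred, extrapolated.
#' @export
predict_surface <- function(fit, tleaf = seq(15, 40, by = 1),
                            mean_tmax = seq(15, 38, by = 1), ref = list()) {
  stopifnot(inherits(fit, "c4_meta"))
  if (!all(c("tleaf", "mean_tmax") %in% names(fit$centers)))
    stop("model must contain continuous tleaf and mean_tmax")
  grid <- expand.grid(tleaf = tleaf, mean_tmax = mean_tmax)
  for (f in names(fit$xlevels))
    grid[[f]] <- if (!is.null(ref[[f]])) ref[[f]] else fit$xlevels[[f]][1]
  for (cv in setdiff(names(fit$centers), c("tleaf", "mean_tmax")))
    grid[[cv]] <- fit$centers[cv]
  grid$pred <- predict(fit, grid)
  obs <- fit$data
  grid$extrapolated <- grid$tleaf < min(obs$tleaf) | grid$tleaf > max(obs$tleaf) |
    grid$mean_tmax < min(obs$mean_tmax) | grid$mean_tmax > max(obs$mean_tmax)
  grid[, c("tleaf", "mean_tmax", "pred", "extrapolated")]
}
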