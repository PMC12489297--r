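#' Point-count quality filters for a group fit
#'
#' A group's VpmaxA estimate is kept only if the initial-slope region had at
#' least two points (Ci < 100 umol mol-1); its Amax estimate only if the
#' saturated region had at least two points (Ci > 500 umol mol-1). Fewer
#' points leave the fit dominated by a single observation and the estimate
#' unreliable.
#'
#' @param fit An \code{"aci_fit"}.
#' @return Named logical vector \code{c(keep_vpmax, keep_amax)}.
#' @export
point_count_filters <- function(fit) {
  c(keep_vpmax = fit$n_low >= 2L, keep_amax = fit$n_high >= 2L)
}

#' Low-Ci limitation consistency check
#'
#' At low Ci, assimilation must be limited by PEP carboxylation: the fitted
#' PEPc-limited (VpmaxA) prediction should lie at or below the Amax-limited
#' rate there. The PEPc-limited prediction is evaluated on a fixed low-Ci
#' grid and the group fails when it strictly exceeds the Amax-limited rate
#' at more than half the grid points. By default the Amax-limited rate is
#' the fitted CO2-saturated ceiling (the asymptote minus Rday), which
#' discriminates cleanly between healthy curves and curves whose initial
#' slope outruns their saturated rate; \code{compare = "hyperbola"} instead
#' uses the full fitted non-rectangular hyperbola pointwise, a stricter
#' variant that also reacts to curvature mismatch between the two fitted
#' forms. Grid, exceedance rule and comparison are all configurable. Groups
#' failing this check typically reflect stressed plants or curves where the
#' initial slope does not report PEPc activity.
#'
#' @param fit An \code{"aci_fit"} whose both fits converged.
#' @param grid Ci grid (umol mol-1) on which to compare predictions.
#' @param compare \code{"asymptote"} (default) or \code{"hyperbola"}.
#' @param exceed_fraction A group is discarded when the PEPc-limited
#'   prediction exceeds the Amax-limited rate at strictly more than this
#'   fraction of the grid points (default 0.5, majority rule).
#' @return \code{TRUE} to keep the group, \code{FALSE} to discard;
#'   \code{NA} when either fit is unavailable.
#' @export
limitation_consistency_check <- function(fit, grid = seq(5, 100, by = 5),
                                         compare = c("asymptote", "hyperbola"),
                                         exceed_fraction = 0.5) {
  compare <- match.arg(compare)
  if (!is.finite(fit$vpmax) || !is.finite(fit$amax) || !is.finite(fit$alpha))
    return(NA)
  a_vp <- vp_limited_assimilation(grid, fit$vpmax, fit$kp, fit$rm)
  a_lim <- if (compare == "asymptote") {
    rep(fit$amax - fit$rday, length(grid))
  } else {
    nrh_assimilation(grid, fit$alpha, fit$amax, fit$theta, fit$rday)
  }
  exceed <- sum(a_vp > a_lim)
  exceed <= exceed_fraction * length(grid)
}

#' Apply the quality-control filters to a batch of group fits
#'
#' Filters are applied in two stages, matching how discarded groups are
#' accounted: first the point-count filters (each parameter discarded
#' independently), then the limitation-consistency check, which is evaluated
#' and counted only among groups that survived both point-count filters.
#' Fits are never mutated; every flag is recorded in the returned table so
#' the accounting is auditable, and the export step drops flagged rows.
#'
#' @param fits An \code{"aci_fit_list"} or list of \code{"aci_fit"}.
#' @param grid,compare,exceed_fraction Passed to
#'   [limitation_consistency_check()].
#' @return List with \code{table} (the [parameter_table()] plus flag columns
#'   \code{keep_vpmax}, \code{keep_amax}, \code{keep_consistency},
#'   \code{keep}) and \code{report} (class \code{"qc_report"}).
#' @export
run_qc <- function(fits, grid = seq(5, 100, by = 5),
                   compare = c("asymptote", "hyperbola"),
                   exceed_fraction = 0.5) {
  compare <- match.arg(compare)
  tab <- parameter_table(fits)
  pc <- t(vapply(fits, point_count_filters, logical(2)))
  tab$keep_vpmax <- pc[, "keep_vpmax"]
  tab$keep_amax <- pc[, "keep_amax"]
  survives_counts <- tab$keep_vpmax & tab$keep_amax
  cons <- vapply(seq_along(fits), function(i) {
    if (!survives_counts[i]) return(NA)
    limitation_consistency_check(fits[[i]], grid = grid, compare = compare,
                                 exceed_fraction = exceed_fraction)
  }, logical(1))
  tab$keep_consistency <- cons
  tab$keep <- tab$keep_vpmax & tab$keep_amax & !isFALSE_vec(cons)

  report <- structure(
    list(n_curves_in = sum(tab$n_group),
         n_groups_formed = nrow(tab),
         n_groups_low_ci_discard = sum(!tab$keep_vpmax),
         n_groups_high_ci_discard = sum(!tab$keep_amax),
         n_groups_consistency_discard = sum(!cons, na.rm = TRUE),
         flags = tab[, c("group_id", "keep_vpmax", "keep_amax",
                         "keep_consistency", "keep")]),
    class = "qc_report"
  )
  list(table = tab, report = report)
}

isFALSE_vec <- function(x) !is.na(x) & !x

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality-control report\n")
  cat(sprintf("  curves in             %d\n", x$n_curves_in))
  cat(sprintf("  groups formed         %d\n", x$n_groups_formed))
  cat(sprintf("  < 2 low-Ci points     %d group(s) lose VpmaxA\n",
              x$n_groups_low_ci_discard))
  cat(sprintf("  < 2 high-Ci points    %d group(s) lose Amax\n",
              x$n_groups_high_ci_discard))
  cat(sprintf("  limitation violated   %d additional group(s) removed\n",
              x$n_groups_consistency_discard))
  invisible(x)
}
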