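#' Construct an experimental curve group
#'
#' A group is the consolidation unit for fitting: replicate A/Ci curves of
#' the same species and genotype measured within a few days in one study.
#' Fits pool all points of a group and report one estimate per parameter
#' with its sampling variance.
#'
#' @param group_id Identifier for the group.
#' @param points data.frame with columns \code{curve_id}, \code{ci}, \code{a}
#'   (one row per gas-exchange point).
#' @param study_id,species,genotype Shared metadata of the member curves.
#' @param tleaf_mean Mean leaf temperature of the group (degC).
#' @param ppfd_mean Mean PPFD of the group (umol m-2 s-1).
#' @param pressure Atmospheric pressure (bar); default 1.013.
#' @param covariates Named list of classification variables (subtype,
#'   growth_form, location, mean_tmax, mean_tmin, growth_co2, species_group).
#' @return An object of class \code{"curve_group"}.
#' @export
curve_group <- function(group_id, points, study_id = NA, species = NA,
                        genotype = NA, tleaf_mean = 25, ppfd_mean = NA,
                        pressure = 1.013, covariates = list()) {
  stopifnot(is.data.frame(points), all(c("ci", "a") %in% names(points)))
  if (nrow(points) == 0L) stop("empty group: no gas-exchange points")
  if (is.null(points$curve_id)) points$curve_id <- 1L
  if (any(!is.finite(points$ci)) || any(points$ci < 0))
    stop("ci must be finite and >= 0")
  if (any(points$a <= -15))
    stop("implausible assimilation rate (a <= -15 umol m-2 s-1)")
  n_group <- length(unique(points$curve_id))
  if (n_group < 1L || n_group > 9L)
    warning("n_group = ", n_group, " outside the usual 1-9 range")
  structure(
    list(group_id = group_id, study_id = study_id, species = species,
         genotype = genotype, points = points[, c("curve_id", "ci", "a")],
         n_group = n_group, tleaf_mean = tleaf_mean, ppfd_mean = ppfd_mean,
         pressure = pressure, covariates = covariates),
    class = "curve_group"
  )
}

#' @export
print.curve_group <- function(x, ...) {
  cat(sprintf("Curve group '%s': %d curve(s), %d points, Tleaf %.1f degC\n",
              x$group_id, x$n_group, nrow(x$points), x$tleaf_mean))
  invisible(x)
}

#' Consolidate A/Ci curves into experimental groups
#'
#' Within each (study, species, genotype) stratum, curves are ordered by
#' measurement date and grouped greedily: a curve starts a new group when
#' its date falls more than \code{window_days} after the first date of the
#' current group. Curves without a date each form their own group (with a
#' warning). Grouping is deterministic and invariant to input row order.
#'
#' @param data Point-level data.frame following the curve-table schema
#'   (see [read_curve_table()]); must at least have \code{study_id},
#'   \code{curve_id}, \code{species}, \code{genotype}, \code{date},
#'   \code{tleaf}, \code{ci}, \code{a}.
#' @param window_days Width of the grouping window in days (default 5).
#' @return List of \code{"curve_group"} objects, ordered by group id.
#' @export
consolidate_groups <- function(data, window_days = 5) {
  req <- c("study_id", "curve_id", "species", "genotype", "ci", "a")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(data$date)) data$date <- NA
  if (is.null(data$tleaf)) data$tleaf <- 25
  if (is.null(data$ppfd)) data$ppfd <- NA_real_
  if (is.null(data$pressure)) data$pressure <- 1.013

  # one row per curve
  curves <- unique(data[, c("study_id", "curve_id", "species", "genotype", "date")])
  if (anyDuplicated(curves[, c("study_id", "curve_id")]))
    stop("curve metadata (species/genotype/date) must be constant within a curve")
  curves$date <- as.Date(curves$date)
  if (anyNA(curves$date) && !all(is.na(curves$date)))
    warning(sum(is.na(curves$date)), " curve(s) without a date assigned to singleton groups")

  key <- interaction(curves$study_id, curves$species, curves$genotype,
                     drop = TRUE, lex.order = TRUE)
  ord <- order(as.integer(key), curves$date, curves$curve_id)
  curves <- curves[ord, ]
  key <- key[ord]

  gid <- character(nrow(curves))
  counter <- 0L
  for (k in levels(key)) {
    idx <- which(key == k)
    anchor <- as.Date(NA)
    for (i in idx) {
      d <- curves$date[i]
      new_grp <- is.na(d) || is.na(anchor) ||
        as.numeric(d - anchor) > window_days
      if (new_grp) {
        counter <- counter + 1L
        anchor <- d
      }
      gid[i] <- sprintf("G%04d", counter)
    }
  }
  curves$group_id <- gid

  m <- match(interaction(data$study_id, data$curve_id, drop = TRUE),
             interaction(curves$study_id, curves$curve_id, drop = TRUE))
  data$group_id <- curves$group_id[m]

  cov_cols <- intersect(
    c("subtype", "growth_form", "location", "mean_tmax", "mean_tmin",
      "growth_co2", "species_group"), names(data))
  lapply(split(seq_len(nrow(data)), data$group_id), function(rows) {
    d <- data[rows, ]
    covs <- lapply(cov_cols, function(cc) d[[cc]][1L])
    names(covs) <- cov_cols
    g <- curve_group(
      group_id = d$group_id[1L],
      points = d[, c("curve_id", "ci", "a")],
      study_id = d$study_id[1L], species = d$species[1L],
      genotype = d$genotype[1L],
      tleaf_mean = mean(d$tleaf), ppfd_mean = mean(d$ppfd),
      pressure = mean(d$pressure), covariates = covs
    )
    g$date_first <- suppressWarnings(min(as.Date(d$date), na.rm = TRUE))
    g
  })
}
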