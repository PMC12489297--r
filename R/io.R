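curve_table_required <- c("study_id", "curve_id", "species", "genotype",
                          "date", "subtype", "growth_form", "location",
                          "mean_tmax", "mean_tmin", "growth_co2", "tleaf",
                          "ppfd", "ci", "a")

#' Read a point-level A/Ci curve table
#'
#' Comma-delimited interchange format: one row per gas-exchange point with
#' curve metadata repeated on each row. Required columns: study_id,
#' curve_id, species, genotype, date (ISO 8601), subtype, growth_form,
#' location, mean_tmax (degC), mean_tmin (degC), growth_co2 (ppm), tleaf
#' (degC), ppfd (umol m-2 s-1), ci (umol mol-1), a (umol m-2 s-1);
#' pressure (bar) is optional. Missing growth CO2 is defaulted to 400 ppm
#' and missing pressure to 1.013 bar, each substitution reported once per
#' affected curve. Physically implausible rows (ci > 3000 or |a| > 120)
#' raise warnings but are kept.
#'
#' @param path CSV file path.
#' @param aliases Optional named character vector mapping file headers to
#'   schema names, e.g. \code{c(Tleaf = "tleaf")}.
#' @return Validated data.frame of points.
#' @export
read_curve_table <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(aliases)) {
    hit <- names(d) %in% names(aliases)
    names(d)[hit] <- unname(aliases[names(d)[hit]])
  }
  miss <- setdiff(curve_table_required, names(d))
  if (length(miss))
    stop("curve table is missing required column(s): ",
         paste(miss, collapse = ", "))
  ck <- paste(d$study_id, d$curve_id)
  if (anyNA(d$growth_co2)) {
    n_cv <- length(unique(ck[is.na(d$growth_co2)]))
    message(n_cv, " curve(s) without growth CO2; defaulted to 400 ppm")
    d$growth_co2[is.na(d$growth_co2)] <- 400
  }
  if (is.null(d$pressure)) d$pressure <- NA_real_
  if (anyNA(d$pressure)) {
    n_cv <- length(unique(ck[is.na(d$pressure)]))
    message(n_cv, " curve(s) without pressure; defaulted to 1.013 bar")
    d$pressure[is.na(d$pressure)] <- 1.013
  }
  if (any(!is.finite(d$ci)) || any(!is.finite(d$a)))
    stop("non-numeric ci or a values")
  odd <- d$ci > 3000 | abs(d$a) > 120
  if (any(odd))
    warning(sum(odd), " row(s) with implausible ci or a values (kept)")
  d
}

#' Write (and filter) the estimated-parameter table
#'
#' Exports the per-group estimates in a stable column order. By default,
#' rows flagged by quality control are dropped: groups failing the low-Ci
#' point count lose their vpmax/se_vpmax values, groups failing the high-Ci
#' count lose amax/se_amax, and groups failing the consistency check are
#' removed entirely. With \code{keep_flagged = TRUE} all rows and values are
#' written together with their flags.
#'
#' @param qc Result of [run_qc()], or a plain [parameter_table()]
#'   data.frame (written as is).
#' @param path Output CSV path.
#' @param keep_flagged Keep flagged rows and estimates (default FALSE).
#' @return Invisibly, the data.frame written.
#' @export
write_parameter_table <- function(qc, path, keep_flagged = FALSE) {
  tab <- if (is.data.frame(qc)) qc else qc$table
  if (!keep_flagged && !is.null(tab$keep_vpmax)) {
    tab <- tab[is.na(tab$keep_consistency) | tab$keep_consistency, ]
    tab$vpmax[!tab$keep_vpmax] <- NA_real_
    tab$se_vpmax[!tab$keep_vpmax] <- NA_real_
    tab$amax[!tab$keep_amax] <- NA_real_
    tab$se_amax[!tab$keep_amax] <- NA_real_
    tab$alpha[!tab$keep_amax] <- NA_real_
  }
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(tab)
}

#' Read back an estimated-parameter table
#'
#' @param path CSV written by [write_parameter_table()].
#' @return data.frame.
#' @export
read_parameter_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full capacity pipeline on a curve table
#'
#' Chains the stages: consolidate curves into groups, fit VpmaxA and
#' Amax/alpha per group, apply quality control, and (optionally) fit the
#' meta-regressions for both responses on the surviving estimates. When
#' \code{outdir} is given, writes the parameter table, the QC flag table and
#' the coefficient tables as CSV files.
#'
#' @param data Point-level curve table (data.frame or CSV path).
#' @param constants A [kinetic_constants()] object.
#' @param meta_formula Fixed-effects formula for the meta-regressions; NULL
#'   skips the meta stage. The response placeholder \code{y} is replaced by
#'   the surviving vpmax and amax estimates in turn.
#' @param random Random-intercept factors for the meta stage.
#' @param outdir Optional output directory for CSV exports.
#' @return List with \code{fits}, \code{qc} (table + report), and
#'   \code{meta} (list with elements vpmax and amax, when fitted).
#' @export
run_capacity_pipeline <- function(data, constants = kinetic_constants(),
                                  meta_formula = default_meta_formula("y"),
                                  random = c("study_id", "species", "group_id"),
                                  outdir = NULL) {
  if (is.character(data)) data <- read_curve_table(data)
  groups <- consolidate_groups(data)
  fits <- fit_groups(groups, constants)
  qc <- run_qc(fits)
  out <- list(fits = fits, qc = qc, meta = NULL)

  if (!is.null(meta_formula)) {
    tab <- qc$table
    survivors <- tab[is.na(tab$keep_consistency) | tab$keep_consistency, ]
    meta <- list()
    for (resp in c("vpmax", "amax")) {
      keep <- if (resp == "vpmax") survivors$keep_vpmax else survivors$keep_amax
      d <- survivors[keep, ]
      d$y <- d[[resp]]
      d$v <- d[[paste0("se_", resp)]]^2
      d <- d[is.finite(d$y) & is.finite(d$v) & d$v > 0, ]
      meta[[resp]] <- tryCatch(
        c4_meta(meta_formula, d, v = "v", random = random),
        error = function(e) {
          warning("meta stage for ", resp, " failed: ", conditionMessage(e))
          NULL
        })
    }
    out$meta <- meta
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_parameter_table(qc, file.path(outdir, "parameter_table.csv"))
    utils::write.csv(qc$table, file.path(outdir, "qc_flags.csv"),
                     row.names = FALSE)
    for (resp in names(out$meta)) {
      if (!is.null(out$meta[[resp]]))
        utils::write.csv(wald_tests(out$meta[[resp]]),
                         file.path(outdir, paste0("meta_", resp, ".csv")),
                         row.names = FALSE)
    }
  }
  out
}
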