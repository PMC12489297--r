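#' Design of a synthetic multi-study gas-exchange dataset
#'
#' Describes the study conditions the generator emulates: a compilation of
#' A/Ci curves from many studies, with replicate curves consolidated into
#' groups, species nested in studies, and group-level covariates driving the
#' true photosynthetic-capacity parameters. Default effect sizes are the
#' observed meta-regression estimates for the significant drivers (leaf
#' temperature, growth location, mean maximum growth temperature, growth CO2
#' and PPFD); terms that were not significant (subtype, growth form, species
#' group, all interactions) default to zero, which doubles as the null for
#' type-I-error checks.
#'
#' Measurement leaf temperature is sampled as growth temperature plus a
#' bounded offset, reflecting that gas exchange is usually measured near the
#' plants' growth temperature; this keeps the generated capacities inside
#' the physiological range. The true CO2-saturated rate of each group is
#' coupled to its PEPc capacity through a logarithmic map with a ratio
#' floor, so generated curves are PEPc-limited below Ci = 100 umol mol-1
#' (the assumption the quality control tests).
#'
#' @param n_studies Number of studies (default 49).
#' @param groups_per_study Integer range, groups drawn per study
#'   (default 4 to 12, giving about 400 groups at 49 studies).
#' @param curves_per_group Integer range of replicate curves per group
#'   (default 1 to 9).
#' @param n_species Size of the species pool (default 40).
#' @param n_model_species Number of "model" crop species in the pool
#'   (default 3).
#' @param p_outdoor Probability a study is outdoor-grown (default 0.5).
#' @param subtype_probs Probabilities of NADP-ME, NAD-ME, PCK for a species.
#' @param p_monocot Probability a species is a monocot (default 0.7).
#' @param tmax_mean,tmax_sd,tmax_range Mean maximum growth temperature:
#'   truncated normal parameters and bounds (degC).
#' @param tleaf_offset_range Uniform range of (Tleaf - mean Tmax) in degC;
#'   Tleaf is clamped to [15, 42].
#' @param ppfd_range Uniform PPFD range (umol m-2 s-1).
#' @param p_co2_treatment Probability a group is a CO2 treatment rather than
#'   ambient 400 ppm; treatment CO2 is uniform on \code{co2_range}.
#' @param co2_range CO2 treatment range (ppm).
#' @param beta_vpmax,beta_amax Named true fixed-effect vectors (intercept,
#'   tleaf, mean_tmax, location_outdoor, growth_co2, ppfd), applied to
#'   covariates centred at \code{lp_centers}.
#' @param sd_study,sd_species,sd_obs Random-intercept SDs, named per
#'   response (vpmax, amax).
#' @param amax_log_a,amax_log_b,amax_log_sd Curve-level coupling
#'   amax_gross = amax_log_a + amax_log_b * ln(vpmax) + noise.
#' @param amax_ratio_floor Lower bound on amax_gross / vpmax (default 0.5,
#'   which keeps the PEPc-limited branch active at every Ci below 100).
#' @param noise_sd Gaussian measurement noise on A (umol m-2 s-1,
#'   default 0.5).
#' @param ci_ladder Ci ladder of each curve (umol mol-1); a repeat
#'   measurement at 400 is appended as an instrument stability check.
#' @param blend_mode,theta_blend Forward-curve limitation blending (see
#'   [blended_forward_curve()]).
#' @param v_meta_meanlog,v_meta_sdlog Log-normal parameters of the known
#'   sampling variances drawn for direct meta-level observations
#'   (median 4, log-sd 0.5).
#' @param clip_min Lower clip for generated capacity parameters
#'   (umol m-2 s-1).
#' @return Object of class \code{"simulation_design"}.
#' @export
simulation_design <- function(
    n_studies = 49,
    groups_per_study = c(4L, 12L),
    curves_per_group = c(1L, 9L),
    n_species = 40,
    n_model_species = 3,
    p_outdoor = 0.5,
    subtype_probs = c("NADP-ME" = 0.6, "NAD-ME" = 0.25, "PCK" = 0.15),
    p_monocot = 0.7,
    tmax_mean = 26, tmax_sd = 3.5, tmax_range = c(15, 38),
    tleaf_offset_range = c(-3, 8),
    ppfd_range = c(100, 2000),
    p_co2_treatment = 0.3, co2_range = c(180, 800),
    beta_vpmax = c(intercept = 65, tleaf = 3.580, mean_tmax = -2.549,
                   location_outdoor = -15.190, growth_co2 = -0.018,
                   ppfd = 0.014),
    beta_amax = c(intercept = 34, tleaf = 2.406, mean_tmax = 0.367,
                  location_outdoor = -6.676, growth_co2 = -0.003,
                  ppfd = 0.010),
    sd_study = c(vpmax = 6, amax = 3),
    sd_species = c(vpmax = 4, amax = 2),
    sd_obs = c(vpmax = 3, amax = 1.5),
    amax_log_a = -72, amax_log_b = 26, amax_log_sd = 2.5,
    amax_ratio_floor = 0.5,
    noise_sd = 0.5,
    ci_ladder = c(25, 50, 75, 100, 150, 200, 300, 400, 600, 800, 1000,
                  1200, 1500),
    blend_mode = "hard_min", theta_blend = 0.99,
    v_meta_meanlog = log(4), v_meta_sdlog = 0.5,
    clip_min = 5) {
  stopifnot(
    n_studies >= 1, groups_per_study[1] >= 1,
    curves_per_group[1] >= 1, curves_per_group[2] <= 9,
    all(sd_study >= 0), all(sd_species >= 0), all(sd_obs >= 0),
    noise_sd >= 0, !is.unsorted(ci_ladder),
    abs(sum(subtype_probs) - 1) < 1e-8,
    blend_mode %in% c("hard_min", "quadratic_blend")
  )
  d <- as.list(environment())
  d$lp_centers <- c(tleaf = tmax_mean + mean(tleaf_offset_range),
                    mean_tmax = tmax_mean,
                    growth_co2 = 400,
                    ppfd = mean(ppfd_range))
  structure(d, class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(
    "Simulation design: %d studies, %d-%d groups/study, %d-%d curves/group\n",
    x$n_studies, x$groups_per_study[1], x$groups_per_study[2],
    x$curves_per_group[1], x$curves_per_group[2]))
  cat(sprintf("  noise sd %.2f, blend %s, ladder %d Ci points\n",
              x$noise_sd, x$blend_mode, length(x$ci_ladder) + 1L))
  invisible(x)
}

# sample from a vector even when it has length one (sample() would then
# treat it as 1:x)
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# truncated-normal draw by inverse cdf (deterministic under set.seed)
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# species pool with trait labels
sim_species_pool <- function(design) {
  ns <- design$n_species
  data.frame(
    species = sprintf("species_%02d", seq_len(ns)),
    subtype = sample(names(design$subtype_probs), ns, replace = TRUE,
                     prob = design$subtype_probs),
    growth_form = ifelse(stats::runif(ns) < design$p_monocot,
                         "monocot", "eudicot"),
    species_group = rep(c("model", "non-model"),
                        c(design$n_model_species,
                          ns - design$n_model_species)),
    stringsAsFactors = FALSE
  )
}

# one row per group: study/species structure, covariates and the two
# fixed-effect linear predictors (before random effects)
sim_group_frame <- function(design) {
  pool <- sim_species_pool(design)
  ng <- resample(seq(design$groups_per_study[1], design$groups_per_study[2]),
                 design$n_studies, replace = TRUE)
  study <- rep(sprintf("study_%02d", seq_len(design$n_studies)), ng)
  n <- length(study)
  loc_study <- ifelse(stats::runif(design$n_studies) < design$p_outdoor,
                      "outdoor", "indoor")
  tmax_study <- rtnorm(design$n_studies, design$tmax_mean, design$tmax_sd,
                       design$tmax_range[1], design$tmax_range[2])
  idx <- rep(seq_len(design$n_studies), ng)
  sp_idx <- unlist(lapply(ng, function(k)
    sample(nrow(pool), k, replace = TRUE)))

  g <- data.frame(
    study_id = study,
    group_id = sprintf("sim_g%04d", seq_len(n)),
    species = pool$species[sp_idx],
    subtype = pool$subtype[sp_idx],
    growth_form = pool$growth_form[sp_idx],
    species_group = pool$species_group[sp_idx],
    location = loc_study[idx],
    mean_tmax = tmax_study[idx],
    stringsAsFactors = FALSE
  )
  g$mean_tmin <- g$mean_tmax - stats::runif(n, 8, 14)
  g$tleaf <- pmin(pmax(g$mean_tmax +
                         stats::runif(n, design$tleaf_offset_range[1],
                                      design$tleaf_offset_range[2]),
                       15), 42)
  g$ppfd <- stats::runif(n, design$ppfd_range[1], design$ppfd_range[2])
  g$growth_co2 <- ifelse(stats::runif(n) < design$p_co2_treatment,
                         stats::runif(n, design$co2_range[1],
                                      design$co2_range[2]), 400)
  ctr <- design$lp_centers
  lp <- function(beta) {
    beta["intercept"] +
      beta["tleaf"] * (g$tleaf - ctr["tleaf"]) +
      beta["mean_tmax"] * (g$mean_tmax - ctr["mean_tmax"]) +
      beta["location_outdoor"] * (g$location == "outdoor") +
      beta["growth_co2"] * (g$growth_co2 - ctr["growth_co2"]) +
      beta["ppfd"] * (g$ppfd - ctr["ppfd"])
  }
  g$lp_vpmax <- unname(lp(design$beta_vpmax))
  g$lp_amax <- unname(lp(design$beta_amax))
  g
}

#' Simulate a multi-study table of synthetic A/Ci curves
#'
#' Draws the study/group/species structure and covariates, forms each
#' group's true VpmaxA from its linear predictor plus study, species and
#' group random intercepts, couples the true gross CO2-saturated rate to
#' VpmaxA through the logarithmic map, and generates \code{n_group}
#' replicate curves per group from the blended forward model on the Ci
#' ladder with i.i.d. Gaussian noise on A. Fully reproducible from the seed.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed; all randomness flows through it.
#' @return List with \code{curves} (point-level data.frame in the curve-table
#'   schema) and \code{truth} (one row per group: keys, covariates, true
#'   parameters).
#' @export
simulate_curves <- function(design = simulation_design(), seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  g <- sim_group_frame(design)
  n <- nrow(g)

  u_study <- stats::rnorm(length(unique(g$study_id)), 0,
                          design$sd_study["vpmax"])
  u_species <- stats::rnorm(length(unique(g$species)), 0,
                            design$sd_species["vpmax"])
  names(u_study) <- unique(g$study_id)
  names(u_species) <- unique(g$species)
  vp <- g$lp_vpmax + u_study[g$study_id] + u_species[g$species] +
    stats::rnorm(n, 0, design$sd_obs["vpmax"])
  if (mean(vp <= 0) > 0.01)
    stop("more than 1% of generated VpmaxA values are nonpositive; ",
         "rescale the design (intercept or effect sizes)")
  n_clip <- sum(vp < design$clip_min)
  vp <- pmax(vp, design$clip_min)
  am <- design$amax_log_a + design$amax_log_b * log(vp) +
    stats::rnorm(n, 0, design$amax_log_sd)
  am <- pmax(am, design$amax_ratio_floor * vp, design$clip_min)
  if (n_clip > 0)
    warning(n_clip, " group(s) clipped at the minimum capacity of ",
            design$clip_min)

  g$vpmax_true <- unname(vp)
  g$amax_gross_true <- unname(am)
  g$n_group <- resample(seq(design$curves_per_group[1],
                            design$curves_per_group[2]), n, replace = TRUE)
  # groups of the same study/species get dates 10 days apart so the 5-day
  # consolidation window reconstructs them exactly
  strat <- interaction(g$study_id, g$species, drop = TRUE)
  g$date <- as.Date("2020-01-01") +
    10L * (stats::ave(seq_len(n), strat, FUN = seq_along) - 1L)

  ladder <- c(design$ci_ladder, 400)  # repeated 400: stability check
  constants <- kinetic_constants()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    kp <- kp_to_mole_fraction(kp_at_temperature(g$tleaf[i], constants), 1.013)
    rday <- rday_at_temperature(g$tleaf[i], constants)
    mu <- blended_forward_curve(ladder, g$vpmax_true[i], g$amax_gross_true[i],
                                kp, rday, design$theta_blend,
                                mode = design$blend_mode)
    nc <- g$n_group[i]
    rows[[i]] <- data.frame(
      study_id = g$study_id[i],
      curve_id = sprintf("%s_c%d", g$group_id[i], rep(seq_len(nc),
                                                      each = length(ladder))),
      species = g$species[i], genotype = "wt",
      date = as.character(g$date[i]),
      subtype = g$subtype[i], growth_form = g$growth_form[i],
      species_group = g$species_group[i],
      location = g$location[i], mean_tmax = g$mean_tmax[i],
      mean_tmin = g$mean_tmin[i], growth_co2 = g$growth_co2[i],
      tleaf = g$tleaf[i], ppfd = g$ppfd[i], pressure = 1.013,
      ci = rep(ladder, nc),
      a = rep(mu, nc) + stats::rnorm(length(ladder) * nc, 0, design$noise_sd),
      stringsAsFactors = FALSE
    )
  }
  list(curves = do.call(rbind, rows), truth = g)
}

#' Simulate meta-level observations directly
#'
#' Bypasses the curve stage: one observation per group with
#' y = x'beta + u_study + u_species + u_obs + e, where e ~ N(0, v) and the
#' known sampling variance v is drawn log-normal (median
#' \code{exp(v_meta_meanlog)}). Used to calibrate and test the
#' meta-regression in isolation.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @param response \code{"vpmax"} or \code{"amax"}: chooses the true
#'   fixed-effect vector and random-effect SDs.
#' @return data.frame of meta-observations (covariates, \code{y}, \code{v})
#'   with truth columns \code{true_lp}, and attributes \code{beta},
#'   \code{sd_study}, \code{sd_species}, \code{sd_obs}.
#' @export
simulate_meta_observations <- function(design = simulation_design(), seed = 1,
                                       response = c("vpmax", "amax")) {
  stopifnot(inherits(design, "simulation_design"))
  response <- match.arg(response)
  set.seed(seed + 1e6L)
  g <- sim_group_frame(design)
  n <- nrow(g)
  beta <- if (response == "vpmax") design$beta_vpmax else design$beta_amax
  lp <- if (response == "vpmax") g$lp_vpmax else g$lp_amax
  sds <- c(study = unname(design$sd_study[response]),
           species = unname(design$sd_species[response]),
           obs = unname(design$sd_obs[response]))
  u_study <- stats::setNames(stats::rnorm(length(unique(g$study_id)), 0,
                                          sds["study"]), unique(g$study_id))
  u_species <- stats::setNames(stats::rnorm(length(unique(g$species)), 0,
                                            sds["species"]),
                               unique(g$species))
  u_obs <- stats::rnorm(n, 0, sds["obs"])
  v <- stats::rlnorm(n, design$v_meta_meanlog, design$v_meta_sdlog)
  g$true_lp <- lp
  g$v <- v
  g$y <- lp + unname(u_study[g$study_id]) + unname(u_species[g$species]) +
    u_obs + stats::rnorm(n, 0, sqrt(v))
  g$lp_vpmax <- g$lp_amax <- NULL
  attr(g, "beta") <- beta
  attr(g, "sd_study") <- unname(sds["study"])
  attr(g, "sd_species") <- unname(sds["species"])
  attr(g, "sd_obs") <- unname(sds["obs"])
  g
}

#' Plant quality-control defects into a simulated curve table
#'
#' Randomly assigns defects to whole groups and labels the ground truth so
#' the QC accounting can be verified exactly: \code{"low_ci"} deletes all
#' but one point below Ci = 100 (the group loses its VpmaxA estimate);
#' \code{"high_ci"} deletes all but one point above Ci = 500 (the group
#' loses Amax); \code{"consistency"} rescales the gross assimilation of all
#' points at Ci >= 150 to 30 percent, collapsing the saturated ceiling so
#' the PEPc-limited fit exceeds it at low Ci.
#'
#' @param curves Point-level curve table from [simulate_curves()].
#' @param fraction Fraction of groups to receive a defect (default 0.1),
#'   split evenly across \code{types}; ignored when \code{counts} is given.
#' @param seed Integer seed.
#' @param types Defect types to plant.
#' @param counts Optional named integer vector of exact defect counts per
#'   type (names among \code{types}).
#' @param rday25 Reference respiration used by the consistency rescaling.
#' @return List with \code{curves} (modified table) and \code{defects}
#'   (data.frame: study_id, species, genotype, date, defect).
#' @export
plant_qc_violations <- function(curves, fraction = 0.1, seed = 1,
                                types = c("low_ci", "high_ci", "consistency"),
                                counts = NULL, rday25 = 1.2) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(seed + 2e6L)
  key <- interaction(curves$study_id, curves$species, curves$genotype,
                     curves$date, drop = TRUE)
  groups <- levels(key)
  if (is.null(counts)) {
    n_defect <- round(fraction * length(groups))
    counts <- stats::setNames(
      diff(round(seq(0, n_defect, length.out = length(types) + 1))), types)
  }
  if (sum(counts) > length(groups)) stop("more defects than groups")
  chosen <- sample(groups, sum(counts))
  defect <- rep(names(counts), counts)
  out <- curves
  drop_rows <- integer(0)
  for (j in seq_along(chosen)) {
    rows <- which(key == chosen[j])
    if (defect[j] == "low_ci") {
      low <- rows[out$ci[rows] < 100]
      if (length(low) > 1L) drop_rows <- c(drop_rows, low[-1])
    } else if (defect[j] == "high_ci") {
      high <- rows[out$ci[rows] > 500]
      if (length(high) > 1L) drop_rows <- c(drop_rows, high[-1])
    } else {
      sat <- rows[out$ci[rows] >= 150]
      rday <- rday25 * 2 ^ ((out$tleaf[sat] - 25) / 10)
      out$a[sat] <- 0.3 * (out$a[sat] + rday) - rday
    }
  }
  if (length(drop_rows)) out <- out[-drop_rows, ]
  info <- unique(curves[, c("study_id", "species", "genotype", "date")])
  ikey <- interaction(info$study_id, info$species, info$genotype, info$date,
                      drop = TRUE)
  defects <- data.frame(info[match(chosen, as.character(ikey)), ],
                        defect = defect, row.names = NULL,
                        stringsAsFactors = FALSE)
  list(curves = out, defects = defects)
}
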