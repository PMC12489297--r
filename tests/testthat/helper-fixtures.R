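# shared fixtures: noiseless / noisy synthetic groups and brute-force oracles

default_ladder <- c(25, 50, 75, 100, 150, 200, 300, 400, 600, 800, 1000,
                    1200, 1500)

# a single-curve group generated from the hard-min forward model
make_group <- function(vpmax = 60, amax_gross = 35, tleaf = 25,
                       noise_sd = 0, seed = 1, ladder = default_ladder,
                       n_curves = 1, pressure = 1.013,
                       constants = kinetic_constants(),
                       mode = "hard_min") {
  kp <- kp_to_mole_fraction(kp_at_temperature(tleaf, constants), pressure)
  rday <- rday_at_temperature(tleaf, constants)
  mu <- blended_forward_curve(ladder, vpmax, amax_gross, kp, rday,
                              mode = mode)
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(n_curves), function(k) {
    data.frame(curve_id = k, ci = ladder,
               a = mu + rnorm(length(ladder), 0, noise_sd))
  }))
  curve_group("fixture", pts, study_id = "s1", species = "sp", genotype = "g",
              tleaf_mean = tleaf, pressure = pressure)
}

# a group whose low-Ci points follow the initial-slope model exactly
make_vp_group <- function(vpmax = 50, tleaf = 25, ci = c(20, 40, 60, 80),
                          noise_sd = 0, seed = 1, pressure = 1,
                          constants = kinetic_constants()) {
  kp <- kp_to_mole_fraction(kp_at_temperature(tleaf, constants), pressure)
  rm_ <- constants$rm_fraction * rday_at_temperature(tleaf, constants)
  set.seed(seed)
  a <- vp_limited_assimilation(ci, vpmax, kp, rm_) +
    rnorm(length(ci), 0, noise_sd)
  curve_group("vpfix", data.frame(curve_id = 1, ci = ci, a = a),
              tleaf_mean = tleaf, pressure = pressure)
}

# dense 1-D grid-search oracle for the initial-slope fit
grid_oracle_vpmax <- function(group, constants = kinetic_constants(),
                              grid = seq(0, 200, by = 1e-3)) {
  kp <- kp_to_mole_fraction(kp_at_temperature(group$tleaf_mean, constants),
                            group$pressure)
  rm_ <- constants$rm_fraction *
    rday_at_temperature(group$tleaf_mean, constants)
  pts <- group$points[group$points$ci < 100, ]
  x <- pts$ci / (pts$ci + kp)
  y <- pts$a + rm_
  rss <- vapply(grid, function(v) sum((y - v * x)^2), 0)
  grid[which.min(rss)]
}

# coarse-to-fine 2-D grid search for (alpha, amax); each refinement keeps
# the dense-grid semantics but restricts the window around the incumbent
grid_oracle_amax <- function(group, constants = kinetic_constants()) {
  rday <- rday_at_temperature(group$tleaf_mean, constants)
  theta <- constants$theta
  pts <- group$points
  rss_fun <- function(alpha, amax) {
    pred <- nrh_assimilation(pts$ci, alpha, amax, theta, rday)
    sum((pts$a - pred)^2)
  }
  a_rng <- c(1e-3, 2); m_rng <- c(1e-2, 120)
  a_step <- 0.02; m_step <- 0.5
  for (pass in 1:3) {
    ag <- seq(a_rng[1], a_rng[2], by = a_step)
    mg <- seq(m_rng[1], m_rng[2], by = m_step)
    rss <- outer(ag, mg, Vectorize(rss_fun))
    ij <- arrayInd(which.min(rss), dim(rss))
    best <- c(ag[ij[1]], mg[ij[2]])
    a_rng <- c(max(best[1] - 2 * a_step, 1e-4), best[1] + 2 * a_step)
    m_rng <- c(max(best[2] - 2 * m_step, 1e-3), best[2] + 2 * m_step)
    a_step <- a_step / 10
    m_step <- m_step / 10
  }
  c(alpha = best[1], amax = best[2])
}

# minimal synthetic aci_fit for QC checks without running a fit
fake_fit <- function(vpmax, amax, alpha, kp = 80, rm = 0.6, rday = 1.2,
                     theta = 0.7, n_low = 4, n_high = 4, group_id = "f1") {
  structure(
    list(group_id = group_id, study_id = "s", species = "sp", genotype = "g",
         date_first = as.Date("2020-01-01"), covariates = list(),
         n_group = 1L, n_points = n_low + n_high,
         tleaf_mean = 25, ppfd_mean = 1500, pressure = 1,
         kp = kp, rm = rm, rday = rday, theta = theta,
         vpmax = vpmax, var_vpmax = 1, n_low = n_low,
         converged_vpmax = TRUE, rss_vpmax = 0,
         amax = amax, var_amax = 1, alpha = alpha, var_alpha = 0.01,
         n_high = n_high, converged_amax = TRUE, rss_amax = 0,
         points = data.frame(curve_id = 1, ci = c(25, 50, 600, 800),
                             a = c(5, 10, 20, 20))),
    class = "aci_fit")
}
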