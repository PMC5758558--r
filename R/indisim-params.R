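#' Simulation parameters for the individual-based yeast culture model
#'
#' Parameters of the stochastic individual-based simulator of a
#' Saccharomyces cerevisiae batch culture.  Structural biomass is measured
#' in composite carbon-nitrogen units (CN_MIC-pmol); one unit carries
#' `c_per_cn` pmol of carbon and `n_per_cn` pmol of nitrogen.  Substrates
#' live on a closed cubic lattice of `lattice_size`^3 well-stirred sites;
#' the system is sealed to everything except molecular oxygen, which under
#' the aerobic policy relaxes towards saturation each step.
#'
#' Defaults describe the reference batch scenario: low-glucose medium
#' (10 g/L glucose equivalent, scaled to a desk-size simulated volume so
#' the inoculum grows through roughly 2.5 decades), 90-min sampling, 1-min
#' time steps, and reproduction-submodel values inside the ranges normally
#' swept for this organism (`sigma_mC` 0.15-0.5, `dm_B1` 0.5-2.0, `dm_B2`
#' 1.0-25.0, `sigma_mB2` 0.02-0.75, `m_C` 5-15).
#'
#' @param condition `"aerobic"` (oxygen relaxes towards saturation each
#'   step) or `"microaerophilic"` (initially dissolved oxygen only).
#' @param lattice_size lattice side length L (sites).
#' @param step_min simulated minutes per time step.
#' @param inoculum number of cells at t = 0.
#' @param m_C mean minimum (critical) reproduction mass (CN_MIC-pmol).
#' @param sigma_mC relative variability of the per-cell Start mass draw.
#' @param dm_B1 minimum mass growth before budding can start
#'   (CN_MIC-pmol).
#' @param dm_B2 mean minimum bud growth before release (CN_MIC-pmol).
#' @param sigma_mB2 relative variability of the per-cycle release
#'   threshold.
#' @param dt2 minimum budding-phase duration (time steps).
#' @param max_B replicative lifespan limit (bud scars).
#' @param d_threshold mortality-index threshold (steps of unmet
#'   maintenance, net of recovery, a cell survives).
#' @param d_increment,d_recovery mortality-index increment per starved
#'   step and decrement per fully maintained step.
#' @param c_per_cn,n_per_cn carbon and nitrogen content of one CN_MIC-pmol
#'   of structural mass (pmol).
#' @param e_resp,e_ferm metabolic energy yield per glucose-pmol respired
#'   (1 glucose : 6 O2 -> 6 CO2) and fermented (1 glucose -> 2 ethanol +
#'   2 CO2); the ~16:1 ratio reflects the textbook ATP yields of the two
#'   pathways.
#' @param e_synth energy cost per CN_MIC-pmol of new structural mass.
#' @param k_maint maintenance energy per CN_MIC-pmol per step.
#' @param r_growth maximum relative synthesis rate (CN_MIC-pmol per
#'   CN_MIC-pmol per step).
#' @param u_glu glucose uptake rate constant (glucose-pmol per step per
#'   unit M^(2/3)); oxygen and nitrogen-source rate constants `u_o2`,
#'   `u_n` likewise.
#' @param glu_feedback,n_feedback half-saturation sizes (relative to M) of
#'   the internal-pool feedback that scales down glucose uptake when the
#'   internal C pool is full (internal C:N above target) and N uptake when
#'   the N reserve is full.
#' @param reserve_frac cap of the carbohydrate reserve R_GLU as a fraction
#'   of M (in glucose-C equivalents).
#' @param glucose_total initial glucose in the whole system
#'   (glucose-pmol).
#' @param nh4_total,cn_total initial ammonium and organic-N pools (pmol).
#' @param o2_sat_site dissolved-oxygen saturation per site (pmol).
#' @param k_aeration per-step relaxation rate of site oxygen towards
#'   saturation (aerobic policy only).
#' @param lag_mean_h,lag_sd_h mean and sd of the per-cell individual lag
#'   time (h), drawn from a normal truncated at zero; during its lag a
#'   cell does not move, take up, grow or reproduce, and its size does not
#'   change.
#' @param mass_to_volume cell volume per unit structural mass (um^3 per
#'   CN_MIC-pmol); calibrated so a mother at the critical mass projects to
#'   a diameter of 5-6 um.
#' @return a `sim_params` list.
#' @export
sim_params <- function(condition = c("aerobic", "microaerophilic"),
                       lattice_size = 30,
                       step_min = 1,
                       inoculum = 100,
                       m_C = 10, sigma_mC = 0.2,
                       dm_B1 = 1.0,
                       dm_B2 = 5.0, sigma_mB2 = 0.25,
                       dt2 = 30,
                       max_B = 25,
                       d_threshold = 720,
                       d_increment = 1, d_recovery = 2,
                       c_per_cn = 1, n_per_cn = 0.2,
                       e_resp = 16, e_ferm = 1,
                       e_synth = 2,
                       k_maint = 0.001,
                       r_growth = 0.01,
                       u_glu = 0.0172, u_o2 = 0.05, u_n = 0.01,
                       glu_feedback = 0.05, n_feedback = 0.05,
                       reserve_frac = 0.1,
                       glucose_total = 1e5,
                       nh4_total = 1e5, cn_total = 2e4,
                       o2_sat_site = 0.1,
                       k_aeration = 0.5,
                       lag_mean_h = 5, lag_sd_h = 1.5,
                       mass_to_volume = 8.7) {
  condition <- match.arg(condition)
  p <- as.list(environment())
  num <- p[!(names(p) %in% "condition")]
  stopifnot(all(vapply(num, is.numeric, TRUE)),
            all(unlist(num) >= 0),
            lattice_size >= 2, step_min > 0, inoculum >= 1,
            m_C > 0, dm_B2 > 0, e_resp > 0, e_ferm > 0,
            sigma_mC > 0, sigma_mC < 1, sigma_mB2 > 0, sigma_mB2 < 1,
            mass_to_volume > 0)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params:", x$condition, "batch culture\n")
  cat(sprintf("  lattice %d^3, step %g min, inoculum %d cells\n",
              x$lattice_size, x$step_min, x$inoculum))
  cat(sprintf("  m_C %g (sd %g), dm_B1 %g, dm_B2 %g (sd %g), dt2 %d steps\n",
              x$m_C, x$sigma_mC, x$dm_B1, x$dm_B2, x$sigma_mB2,
              as.integer(x$dt2)))
  cat(sprintf("  glucose %g pmol, O2 sat/site %g pmol (%s)\n",
              x$glucose_total, x$o2_sat_site, x$condition))
  invisible(x)
}
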