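#' Configuration for the random network and invader generator
#'
#' Collects the distributions and connectivities from which species pools,
#' mediator networks and invaders are drawn.  Rate ranges are uniform
#' distributions; connectivities are per-link Bernoulli probabilities
#' ("binomial networks").  Concentrations are handled internally in fmole/ml
#' (1 nM = 1000 fmole/ml), so the saturation range given in nM is converted
#' on network generation.
#'
#' @param n_species Number of species in the initial pool (N_c).
#' @param n_mediators Number of chemical mediators (N_m).
#' @param r0_range Uniform range of the basal net growth rate r_i0 (hr^-1).
#' @param influence_range Uniform range of the amplitude of mediator
#'   influence on growth rate, |r_ij| (hr^-1); the sign is drawn separately.
#' @param beta_range Uniform range of per-cell mediator production rates
#'   (fmole cell^-1 hr^-1).
#' @param alpha_range Uniform range of per-cell mediator consumption rates
#'   (fmole cell^-1 hr^-1).
#' @param K_range_nM Uniform range of the saturation (half-max) concentration
#'   K_ij, in nM, shared between uptake and growth influence.
#' @param q_p Connectivity of producer species to mediators: probability that
#'   a given species produces a given mediator.
#' @param q_c Connectivity of mediators to the species they influence:
#'   probability that a given mediator influences (and is consumed by) a
#'   given species.
#' @param f_fac Fraction of non-neutral influences among resident species
#'   that are facilitative (positive sign).
#' @param f_fac_inv Fraction of non-neutral influences on the invader that
#'   are facilitative.
#' @param q_p_inv,q_c_inv Invader-specific connectivities; default to `q_p`
#'   and `q_c`.
#' @param beta_scale_inv,alpha_scale_inv Multipliers applied to the invader's
#'   production / consumption rate draws (used by the rate-magnitude sweeps).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_species = 20, n_mediators = 10,
                             r0_range = c(0.08, 0.12),
                             influence_range = c(0, 0.2),
                             beta_range = c(0.05, 0.15),
                             alpha_range = c(0.25, 0.75),
                             K_range_nM = c(50, 150),
                             q_p = 0.3, q_c = 0.3,
                             f_fac = 0.5, f_fac_inv = 0.5,
                             q_p_inv = NULL, q_c_inv = NULL,
                             beta_scale_inv = 1, alpha_scale_inv = 1) {
  cfg <- list(n_species = as.integer(n_species),
              n_mediators = as.integer(n_mediators),
              r0_range = as.numeric(r0_range),
              influence_range = as.numeric(influence_range),
              beta_range = as.numeric(beta_range),
              alpha_range = as.numeric(alpha_range),
              K_range_nM = as.numeric(K_range_nM),
              q_p = q_p, q_c = q_c,
              f_fac = f_fac, f_fac_inv = f_fac_inv,
              q_p_inv = if (is.null(q_p_inv)) q_p else q_p_inv,
              q_c_inv = if (is.null(q_c_inv)) q_c else q_c_inv,
              beta_scale_inv = beta_scale_inv,
              alpha_scale_inv = alpha_scale_inv)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_species < 1L || cfg$n_mediators < 0L)
    stop("need at least one species and a non-negative mediator count")
  for (nm in c("r0_range", "influence_range", "beta_range", "alpha_range",
               "K_range_nM")) {
    rng <- cfg[[nm]]
    if (length(rng) != 2L || any(!is.finite(rng)) || any(rng < 0) ||
        rng[1] > rng[2])
      stop(sprintf("%s must be a non-negative range with low <= high", nm))
  }
  for (nm in c("q_p", "q_c", "f_fac", "f_fac_inv", "q_p_inv", "q_c_inv")) {
    p <- cfg[[nm]]
    if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
      stop(sprintf("%s must be a probability in [0, 1]", nm))
  }
  if (cfg$beta_scale_inv < 0 || cfg$alpha_scale_inv < 0)
    stop("invader rate scales must be non-negative")
  invisible(cfg)
}

# internal unit conversion: 1 nM = 1000 fmole/ml
NM_TO_FMOLE_ML <- 1000

#' Growth-dilution cycle configuration
#'
#' @param n_inoc Total inoculum density at the start of each cycle (cells/ml).
#' @param n_dil Total density that triggers dilution (cells/ml).
#' @param n_ext Extinction threshold: a species below this density after a
#'   dilution is removed permanently (cells/ml).
#' @param target_generations Total community doublings to simulate; one
#'   generation is one doubling of total density.
#' @param timestep_divisor The Euler time step is set to the shortest
#'   achievable doubling time divided by this factor (default 10).
#' @param max_cycle_time Cap on the duration of a single cycle in hours,
#'   applied in the resource model only (dilution happens at the threshold or
#'   at this time, whichever comes first).
#' @param stall_factor In the basic model a cycle lasting more than
#'   `stall_factor` times the slowest interaction-free cycle duration marks
#'   the run as stalled (community unable to reach the dilution threshold).
#' @param max_cycles Hard cap on dilution cycles per run.
#' @return An object of class `cycle_config`.
#' @export
cycle_config <- function(n_inoc = 1e4, n_dil = 1e7, n_ext = 0.1,
                         target_generations = 200,
                         timestep_divisor = 10,
                         max_cycle_time = 80,
                         stall_factor = 10,
                         max_cycles = 5000) {
  stopifnot(n_inoc > 0, n_dil > n_inoc, n_ext > 0,
            target_generations > 0, timestep_divisor > 0,
            max_cycle_time > 0, stall_factor > 0, max_cycles >= 1)
  structure(list(n_inoc = n_inoc, n_dil = n_dil, n_ext = n_ext,
                 target_generations = target_generations,
                 timestep_divisor = timestep_divisor,
                 max_cycle_time = max_cycle_time,
                 stall_factor = stall_factor,
                 max_cycles = max_cycles),
            class = "cycle_config")
}

#' Limiting-resource configuration for the explicit-resource model variant
#'
#' The resource is supplied in fresh medium at `R0`, consumed in proportion
#' to realized growth, never produced, and replenished at each dilution.
#'
#' @param R0 Resource concentration in fresh medium (fmole/ml).
#' @param KR_range Uniform range of per-species half-max concentrations
#'   K_R,i for the resource effect on growth (fmole/ml).  The default is
#'   centred on the fresh-medium concentration so that growth is
#'   resource-limited and the resource is depleted within a growth round.
#' @param alphaR_range Uniform range of per-cell resource consumption rates
#'   (fmole hr^-1).
#' @return An object of class `resource_config`.
#' @export
resource_config <- function(R0 = 1e6,
                            KR_range = c(5e5, 1.5e6),
                            alphaR_range = c(5, 15)) {
  stopifnot(R0 > 0, length(KR_range) == 2L, all(KR_range > 0),
            KR_range[1] <= KR_range[2],
            length(alphaR_range) == 2L, all(alphaR_range >= 0),
            alphaR_range[1] <= alphaR_range[2])
  structure(list(R0 = R0, KR_range = as.numeric(KR_range),
                 alphaR_range = as.numeric(alphaR_range)),
            class = "resource_config")
}
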