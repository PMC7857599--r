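#' Construct a community state
#'
#' @param species Species densities (cells/ml), one per species.
#' @param mediators Mediator concentrations (fmole/ml), one per mediator.
#' @param resource Resource concentration (fmole/ml); `NA` in the basic model.
#' @param time Elapsed time (hr).
#' @param generations Cumulative doublings of total community density.
#' @return An object of class `community_state`.
#' @export
community_state <- function(species, mediators, resource = NA_real_,
                            time = 0, generations = 0) {
  species <- as.numeric(species)
  mediators <- as.numeric(mediators)
  if (any(species < 0) || any(mediators < 0) ||
      (!is.na(resource) && resource < 0))
    stop("densities and concentrations must be non-negative")
  structure(list(species = species, mediators = mediators,
                 resource = as.numeric(resource),
                 time = time, generations = generations),
            class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("Community state at t = %.1f hr (%.2f generations)\n",
              x$time, x$generations))
  cat(sprintf("  %d/%d species alive, total density %.3g cells/ml\n",
              sum(x$species > 0), length(x$species), sum(x$species)))
  if (!is.na(x$resource))
    cat(sprintf("  resource %.3g fmole/ml\n", x$resource))
  invisible(x)
}

check_state_dims <- function(state, net) {
  if (length(state$species) != net$n_species)
    stop("state has ", length(state$species), " species but network has ",
         net$n_species)
  if (length(state$mediators) != net$n_mediators)
    stop("state has ", length(state$mediators), " mediators but network has ",
         net$n_mediators)
  invisible(TRUE)
}

#' Time derivatives of the mediator-explicit model
#'
#' The basic model: each mediator changes by production minus saturating
#' consumption summed over species, and each species grows at its basal rate
#' plus the sum of signed, saturating mediator influences:
#' \deqn{dC_i/dt = \sum_j [\beta_{ij} - \alpha_{ij} C_i/(C_i+K_{ij})] S_j}
#' \deqn{dS_j/dt = [r_{j0} + \sum_i r_{ji} C_i/(C_i+K_{ji})] S_j}
#'
#' This is the plain-R reference implementation; [run_cycles()] integrates
#' the same right-hand side in compiled code.
#'
#' @param state A [community_state()] (dimensions must match `net`, with the
#'   invader attached via [attach_invader()] if present).
#' @param net An `interaction_network`.
#' @return A list with `dS` (cells ml^-1 hr^-1) and `dC`
#'   (fmole ml^-1 hr^-1).
#' @export
derivatives <- function(state, net) {
  check_state_dims(state, net)
  S <- state$species
  C <- state$mediators
  # sat[i, j]: C_i / (C_i + K_ji), mediator i acting on species j
  sat <- C / (C + t(net$saturation))
  sat[C == 0, ] <- 0
  dC <- as.numeric((net$production_rate - net$consumption_rate * sat) %*% S)
  growth <- net$basal_rate + rowSums(net$influence_rate * t(sat))
  list(dS = growth * S, dC = dC, growth_rate = growth)
}

#' Time derivatives of the explicit-resource model variant
#'
#' As [derivatives()], but each species' growth-rate expression is
#' multiplied by a saturating resource factor R/(R+K_R,i), and the resource
#' is consumed in proportion to each species' realized growth rate:
#' \deqn{dR/dt = -\sum_j \alpha_{R,j} (R/(R+K_{R,j}))
#'   [r_{j0} + \sum_i r_{ji} C_i/(C_i+K_{ji})] S_j}
#' The resource is not produced by any species.
#'
#' @inheritParams derivatives
#' @return A list with `dS`, `dC` and `dR`.
#' @export
derivatives_resource <- function(state, net) {
  if (is.na(state$resource))
    stop("state carries no resource concentration; use derivatives() for the basic model")
  base <- derivatives(state, net)
  R <- state$resource
  rho <- if (R > 0) R / (R + net$resource_K) else rep(0, net$n_species)
  dS <- rho * base$dS
  dR <- -sum(net$resource_consumption * rho * base$growth_rate *
               state$species)
  list(dS = dS, dC = base$dC, dR = dR)
}

#' Euler time step from the shortest achievable doubling time
#'
#' The step is the doubling time at the maximum achievable growth rate
#' (basal rate plus all positive influence amplitudes, a conservative
#' bound), divided by `divisor`:
#' \deqn{dt = \ln 2 / \max_j (r_{j0} + \sum_i \max(r_{ji}, 0)) / divisor}
#'
#' @param net An `interaction_network` (attach the invader first if one
#'   takes part in the run).
#' @param divisor How many steps per shortest doubling time (default 10).
#' @return The time step in hours.
#' @export
choose_timestep <- function(net, divisor = 10) {
  max_rate <- max(net$basal_rate + rowSums(pmax(net$influence_rate, 0)))
  if (max_rate <= 0)
    stop("no species has a positive achievable growth rate")
  log(2) / max_rate / divisor
}

#' Integrate a community through growth-dilution cycles
#'
#' Forward-Euler integration of the basic or explicit-resource model.  A
#' cycle ends when total density reaches `n_dil` (or, in the resource model,
#' after `max_cycle_time` hours); the culture is then diluted back to
#' `n_inoc` total (mediators diluted by the same factor, resource reset to
#' fresh medium), and any species below `n_ext` goes permanently extinct.
#' Generations accrue per growth interval as log2 of the total-density fold
#' change; the run stops when `target_generations` is reached, possibly
#' mid-cycle.  Densities and concentrations are clamped at zero after each
#' step; clamp events are counted.
#'
#' In the basic model a cycle lasting more than `stall_factor` times the
#' slowest interaction-free cycle duration flags the run as stalled
#' (community collapse: the dilution threshold is unreachable).
#'
#' @param state0 Initial [community_state()]; total density should be about
#'   `n_inoc`.
#' @param net An `interaction_network`.
#' @param cycle_cfg A [cycle_config()].
#' @param model `"basic"` or `"resource"`.
#' @param rcfg A [resource_config()]; required for the resource model.
#' @param invader An optional `invader_spec` to attach as the last species
#'   (the state must then include its density).
#' @param dt Euler time step; defaults to [choose_timestep()] with the
#'   configured divisor.
#' @return A list with `state` (final `community_state`), and an event log:
#'   `dilutions` (data frame of time, generations and total density at each
#'   dilution), `composition` (species densities just before each dilution),
#'   `extinctions`, `n_clamps`, `n_steps`, `stalled`, `collapsed`.
#' @export
run_cycles <- function(state0, net, cycle_cfg = cycle_config(),
                       model = c("basic", "resource"), rcfg = NULL,
                       invader = NULL, dt = NULL) {
  model <- match.arg(model)
  if (!is.null(invader)) net <- attach_invader(net, invader)
  check_state_dims(state0, net)
  resource <- model == "resource"
  if (resource) {
    if (is.null(rcfg)) stop("the resource model needs a resource_config")
    if (is.na(state0$resource))
      stop("the resource model needs an initial resource concentration")
  }
  if (is.null(dt)) dt <- choose_timestep(net, cycle_cfg$timestep_divisor)

  # stall guard: 10x the cycle duration of the slowest interaction-free grower
  pos_basal <- net$basal_rate[net$basal_rate > 0]
  ref_rate <- if (length(pos_basal)) min(pos_basal)
  else log(2) / (dt * cycle_cfg$timestep_divisor) # fall back on max achievable
  stall_time <- cycle_cfg$stall_factor *
    log(cycle_cfg$n_dil / cycle_cfg$n_inoc) / ref_rate

  res <- euler_cycles_cpp(
    S0 = state0$species, C0 = state0$mediators,
    r0 = net$basal_rate, rinf = net$influence_rate,
    beta = net$production_rate, alpha = net$consumption_rate,
    Ksm = net$saturation, dt = dt,
    n_inoc = cycle_cfg$n_inoc, n_dil = cycle_cfg$n_dil,
    n_ext = cycle_cfg$n_ext,
    target_gen = cycle_cfg$target_generations,
    resource = resource,
    R_init = if (resource) state0$resource else NA_real_,
    R_fresh = if (resource) rcfg$R0 else NA_real_,
    KR = net$resource_K, alphaR = net$resource_consumption,
    max_cycle_time = if (resource) cycle_cfg$max_cycle_time else Inf,
    stall_time = stall_time,
    max_cycles = cycle_cfg$max_cycles,
    max_steps = 2e7)

  final <- community_state(res$species, res$mediators,
                           resource = res$resource,
                           time = state0$time + res$time,
                           generations = state0$generations + res$generations)
  dilutions <- data.frame(time = res$dilution_time,
                          generations = res$dilution_generations,
                          total = res$dilution_total)
  extinctions <- data.frame(species = res$extinction_species,
                            cycle = res$extinction_cycle)
  list(state = final,
       dilutions = dilutions,
       composition = res$dilution_composition,
       mediators_at_dilution = res$dilution_mediators,
       extinctions = extinctions,
       n_cycles = res$n_cycles,
       n_steps = res$n_steps,
       n_clamps = res$n_clamps,
       stalled = res$stalled,
       collapsed = res$collapsed,
       dt = dt)
}
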