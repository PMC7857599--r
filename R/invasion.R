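#' Introduce an invader into a resident community
#'
#' Residents are re-inoculated into fresh medium at the inoculum density in
#' their harvest proportions; the invader is added on top at
#' `propagule_fraction` times the resident inoculum (the normalized
#' propagule size).  Mediators are carried over from harvest, diluted by the
#' re-inoculation factor; in the resource model the resource is reset to
#' fresh medium.
#'
#' @param rc A [enrich()] result (must not be collapsed).
#' @param inv An `invader_spec` over the same mediator set.
#' @param propagule_fraction Invader cells introduced relative to the
#'   resident inoculum (> 0; the standard assay uses 0.003, i.e. 0.3%).
#' @return A [community_state()] over `n_species + 1` species (invader
#'   last), with attributes `invader_index` and `pre_survivors`.  If the
#'   propagule is below the extinction threshold the state carries the
#'   attribute `sub_detectable = TRUE`.
#' @export
introduce <- function(rc, inv, propagule_fraction = 0.003) {
  stopifnot(inherits(rc, "resident_community"), inherits(inv, "invader_spec"))
  if (rc$collapsed) stop("cannot invade a collapsed community")
  if (!is.numeric(propagule_fraction) || length(propagule_fraction) != 1L ||
      propagule_fraction <= 0)
    stop("propagule_fraction must be a positive scalar")
  base <- reinoculate(rc)
  inv_density <- propagule_fraction * rc$cycle_cfg$n_inoc
  state <- community_state(
    species = c(base$species, inv_density),
    mediators = base$mediators,
    resource = base$resource)
  attr(state, "invader_index") <- rc$network$n_species + 1L
  attr(state, "pre_survivors") <- rc$survivors
  if (inv_density < rc$cycle_cfg$n_ext)
    attr(state, "sub_detectable") <- TRUE
  state
}

outcome_levels <- c("resistance", "augmentation", "displacement", "disruption")

#' Classify an invasion outcome
#'
#' The four categories form the 2x2 of invader persistence by resident
#' richness maintenance: resistance (invader extinct, richness maintained),
#' augmentation (invader maintained, richness maintained), displacement
#' (invader maintained, richness drops), disruption (invader extinct,
#' richness drops).  Persistence means a final density above the extinction
#' threshold, for the invader and each pre-invasion survivor alike.
#'
#' @param pre_survivors Indices of the resident species alive at
#'   introduction.
#' @param final_state The [community_state()] at the end of the
#'   post-introduction run.
#' @param invader_index Index of the invader in `final_state`.
#' Residents always persist or not by the density rule.  For the invader a
#' stricter, fraction-based rule is available: maintained only if its final
#' relative abundance is at least its introduced relative abundance (the
#' density rule is the default).
#'
#' @param n_ext Extinction threshold (cells/ml).
#' @param propagule_fraction Recorded into the result; under the
#'   `"fraction"` rule it also sets the invader's introduced relative
#'   abundance, `propagule_fraction / (1 + propagule_fraction)`.
#' @param persistence `"density"` (final density above `n_ext`) or
#'   `"fraction"` (final invader fraction at least its initial fraction).
#' @return An object of class `invasion_result`.
#' @export
classify_outcome <- function(pre_survivors, final_state, invader_index,
                             n_ext = 0.1, propagule_fraction = NA_real_,
                             persistence = c("density", "fraction")) {
  persistence <- match.arg(persistence)
  S <- final_state$species
  persisted <- S[invader_index] > n_ext
  if (persistence == "fraction") {
    if (is.na(propagule_fraction))
      stop("the fraction persistence rule needs the propagule fraction")
    f0 <- propagule_fraction / (1 + propagule_fraction)
    persisted <- persisted && sum(S) > 0 &&
      S[invader_index] / sum(S) >= f0
  }
  resident_alive <- S[pre_survivors] > n_ext
  maintained <- all(resident_alive)
  outcome <- if (persisted && maintained) "augmentation"
  else if (persisted) "displacement"
  else if (maintained) "resistance"
  else "disruption"
  total <- sum(S)
  structure(list(outcome = factor(outcome, levels = outcome_levels),
                 invader_persisted = persisted,
                 richness_maintained = maintained,
                 invader_final_fraction = if (total > 0)
                   S[invader_index] / total else 0,
                 pre_richness = length(pre_survivors),
                 post_richness = sum(resident_alive),
                 propagule_fraction = propagule_fraction),
            class = "invasion_result")
}

#' Run one complete invasion assay
#'
#' Introduces the invader into the resident community, simulates the
#' configured number of further generations (default 200) of growth-dilution
#' cycles, and classifies the outcome.
#'
#' @inheritParams introduce
#' @param persistence Invader persistence rule, see [classify_outcome()].
#' @return An `invasion_result`, additionally carrying `stalled` and the
#'   final state.
#' @export
run_assay <- function(rc, inv, propagule_fraction = 0.003,
                      persistence = c("density", "fraction")) {
  state0 <- introduce(rc, inv, propagule_fraction)
  net2 <- attach_invader(rc$network, inv)
  run <- run_cycles(state0, net2, rc$cycle_cfg, model = rc$model,
                    rcfg = rc$rcfg)
  res <- classify_outcome(pre_survivors = attr(state0, "pre_survivors"),
                          final_state = run$state,
                          invader_index = attr(state0, "invader_index"),
                          n_ext = rc$cycle_cfg$n_ext,
                          propagule_fraction = propagule_fraction,
                          persistence = persistence)
  res$stalled <- run$stalled
  res$final_state <- run$state
  res
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("Invasion outcome: %s\n", as.character(x$outcome)))
  cat(sprintf("  invader %s (final fraction %.3g); resident richness %d -> %d\n",
              if (x$invader_persisted) "maintained" else "extinct",
              x$invader_final_fraction, x$pre_richness, x$post_richness))
  invisible(x)
}
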