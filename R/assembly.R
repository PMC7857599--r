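#' Assemble a stable resident community by in silico enrichment
#'
#' Inoculates the full species pool in equal proportions at the inoculum
#' density, runs growth-dilution cycles for the configured number of
#' generations (default 200), and harvests the species still above the
#' extinction threshold as the resident community.
#'
#' @param net An `interaction_network` (the species pool).
#' @param cycle_cfg A [cycle_config()].
#' @param model `"basic"` or `"resource"`.
#' @param rcfg A [resource_config()]; required for the resource model.
#' @return An object of class `resident_community`: the parent `network`,
#'   `survivors` (indices into the pool), `harvest_state` (end-of-assembly
#'   [community_state()]), `fractions` (relative abundances at harvest, full
#'   pool length, zero for extinct species), `richness`, and flags
#'   `collapsed`/`stalled`.  A collapsed instance (richness 0) is returned
#'   flagged so callers can regenerate; it must not be used in assays.
#' @export
enrich <- function(net, cycle_cfg = cycle_config(),
                   model = c("basic", "resource"), rcfg = NULL) {
  model <- match.arg(model)
  N <- net$n_species
  state0 <- community_state(
    species = rep(cycle_cfg$n_inoc / N, N),
    mediators = rep(0, net$n_mediators),
    resource = if (model == "resource") rcfg$R0 else NA_real_)
  run <- run_cycles(state0, net, cycle_cfg, model = model, rcfg = rcfg)

  S <- run$state$species
  survivors <- which(S > cycle_cfg$n_ext)
  total <- sum(S[survivors])
  fractions <- numeric(N)
  if (length(survivors) > 0) fractions[survivors] <- S[survivors] / total

  structure(list(network = net,
                 survivors = survivors,
                 harvest_state = run$state,
                 fractions = fractions,
                 richness = length(survivors),
                 model = model,
                 cycle_cfg = cycle_cfg,
                 rcfg = rcfg,
                 collapsed = run$collapsed || length(survivors) == 0,
                 stalled = run$stalled,
                 n_cycles = run$n_cycles),
            class = "resident_community")
}

#' Check the compositional stability of an assembled community
#'
#' Re-inoculates the harvested community into fresh medium and continues it
#' for additional generations.  The community is called stable if no species
#' is lost and every species' pre-dilution relative abundance drifts by less
#' than `tol` (absolute) over the final three cycles.  This is an optional,
#' stricter filter on top of the enrichment procedure, whose own criterion
#' is simply survival over the assembly generations.
#'
#' @param rc A [enrich()] result.
#' @param extra_generations How many further generations to simulate.
#' @param tol Maximum absolute drift in any species' fraction over the final
#'   three cycles.
#' @return A list: `stable` (logical), `drift` (max absolute fraction
#'   change), `richness_after`, and the continuation run.
#' @export
check_stability <- function(rc, extra_generations = 50, tol = 0.01) {
  stopifnot(inherits(rc, "resident_community"))
  if (rc$collapsed) stop("cannot stability-check a collapsed community")
  cc <- rc$cycle_cfg
  cc$target_generations <- extra_generations
  state0 <- reinoculate(rc)
  run <- run_cycles(state0, rc$network, cc, model = rc$model, rcfg = rc$rcfg)

  S <- run$state$species
  richness_after <- sum(S > cc$n_ext)

  drift <- NA_real_
  comp <- run$composition
  if (nrow(comp) >= 3) {
    tail3 <- comp[nrow(comp) - 2:0, , drop = FALSE]
    frac <- tail3 / rowSums(tail3)
    drift <- max(abs(sweep(frac, 2, frac[3, ])))
  }
  stable <- richness_after == rc$richness &&
    (!is.na(drift) && drift < tol)
  list(stable = stable, drift = drift,
       richness_after = richness_after, run = run)
}

# fresh-medium inoculation of a harvested community at n_inoc total,
# in harvest fractions, mediators carried over but diluted accordingly
reinoculate <- function(rc) {
  cc <- rc$cycle_cfg
  factor <- cc$n_inoc / sum(rc$harvest_state$species)
  community_state(
    species = rc$fractions * cc$n_inoc,
    mediators = rc$harvest_state$mediators * factor,
    resource = if (rc$model == "resource") rc$rcfg$R0 else NA_real_)
}

#' @export
print.resident_community <- function(x, ...) {
  cat("Resident community (in silico enrichment)\n")
  cat(sprintf("  richness %d of %d pool species after %d cycles (%s model)\n",
              x$richness, x$network$n_species, x$n_cycles, x$model))
  if (x$collapsed) cat("  ** collapsed: no survivors **\n")
  if (x$stalled) cat("  ** stalled before reaching target generations **\n")
  if (x$richness > 0) {
    fr <- sort(x$fractions[x$survivors], decreasing = TRUE)
    cat("  fractions:", paste(sprintf("%.3f", fr), collapse = " "), "\n")
  }
  invisible(x)
}
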