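#' Generate a random chemically-mediated interaction network
#'
#' Draws a species pool and its mediator network.  Production links
#' (mediator x species) are present independently with probability `q_p`;
#' influence links (species x mediator) with probability `q_c`.  A species
#' consumes exactly the mediators that influence it, with consumption rates
#' drawn independently of the influence amplitudes.  On existing links,
#' rates are drawn uniformly from the configured ranges; the sign of each
#' influence is positive (facilitation) with probability `f_fac`, negative
#' (inhibition) otherwise.
#'
#' Per-species resource parameters (half-max concentration and per-cell
#' consumption rate) are drawn alongside so the same network can be run
#' under the explicit-resource model variant.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed; the draw is fully reproducible.
#' @param rcfg A [resource_config()] supplying the ranges for the resource
#'   parameters.
#' @return An object of class `interaction_network` with fields
#'   `basal_rate` (length `n_species`, hr^-1), `influence_rate`
#'   (species x mediator, signed, hr^-1), `production_rate` and
#'   `consumption_rate` (mediator x species, fmole cell^-1 hr^-1),
#'   `saturation` (species x mediator, fmole/ml), the boolean adjacencies
#'   `influence_link` and `production_link`, and the per-species resource
#'   parameters `resource_K` (fmole/ml) and `resource_consumption`
#'   (fmole hr^-1 per cell).
#' @export
generate_network <- function(cfg = generator_config(), seed = 1L,
                             rcfg = resource_config()) {
  validate_generator_config(cfg)
  set.seed(seed)
  N <- cfg$n_species
  M <- cfg$n_mediators

  basal <- runif(N, cfg$r0_range[1], cfg$r0_range[2])

  production_link <- matrix(runif(M * N) < cfg$q_p, M, N)
  influence_link <- matrix(runif(N * M) < cfg$q_c, N, M)

  production <- matrix(0, M, N)
  production[production_link] <-
    runif(sum(production_link), cfg$beta_range[1], cfg$beta_range[2])

  amplitude <- matrix(0, N, M)
  amplitude[influence_link] <-
    runif(sum(influence_link), cfg$influence_range[1], cfg$influence_range[2])
  sign_pos <- matrix(runif(N * M) < cfg$f_fac, N, M)
  influence <- amplitude * ifelse(sign_pos, 1, -1)
  influence[!influence_link] <- 0

  # consumption shares the influence topology (the species taking up a
  # mediator are the ones whose growth it modulates)
  consumption <- matrix(0, M, N)
  consumption[t(influence_link)] <-
    runif(sum(influence_link), cfg$alpha_range[1], cfg$alpha_range[2])

  saturation <- matrix(
    runif(N * M, cfg$K_range_nM[1], cfg$K_range_nM[2]) * NM_TO_FMOLE_ML,
    N, M)

  resource_K <- runif(N, rcfg$KR_range[1], rcfg$KR_range[2])
  resource_consumption <- runif(N, rcfg$alphaR_range[1], rcfg$alphaR_range[2])

  structure(list(n_species = N, n_mediators = M,
                 basal_rate = basal,
                 influence_rate = influence,
                 production_rate = production,
                 consumption_rate = consumption,
                 saturation = saturation,
                 influence_link = influence_link,
                 production_link = production_link,
                 resource_K = resource_K,
                 resource_consumption = resource_consumption,
                 config = cfg, seed = as.integer(seed)),
            class = "interaction_network")
}

#' Generate a random invader for an existing network
#'
#' The invader links to the *same* mediator set as the residents (no new
#' mediators).  Its basal growth rate is drawn from the resident basal-rate
#' distribution and scaled by `r0_ratio`, so a ratio of 1.5 gives the
#' invader on average a 50% basal-rate advantage.  Influence signs on the
#' invader are positive with probability `f_fac_inv`.
#'
#' @param net An [generate_network()] result.
#' @param cfg A [generator_config()]; connectivities `q_p_inv`/`q_c_inv` and
#'   the rate scales `beta_scale_inv`/`alpha_scale_inv` apply to the invader.
#' @param r0_ratio Invader-to-resident basal growth-rate ratio (> 0).
#' @param seed Integer seed.
#' @param rcfg A [resource_config()] for the invader's resource parameters.
#' @return An object of class `invader_spec`: scalar `basal_rate`, vectors
#'   `influence_rate`, `production_rate`, `consumption_rate`, `saturation`
#'   over the network's mediators, resource parameters, and ablation flags.
#' @export
generate_invader <- function(net, cfg = net$config, r0_ratio = 1.5,
                             seed = 1L, rcfg = resource_config()) {
  stopifnot(inherits(net, "interaction_network"))
  if (!is.numeric(r0_ratio) || length(r0_ratio) != 1L || r0_ratio <= 0)
    stop("r0_ratio must be a positive scalar")
  validate_generator_config(cfg)
  set.seed(seed)
  M <- net$n_mediators

  basal <- runif(1, cfg$r0_range[1], cfg$r0_range[2]) * r0_ratio

  production_link <- runif(M) < cfg$q_p_inv
  influence_link <- runif(M) < cfg$q_c_inv

  production <- numeric(M)
  production[production_link] <-
    runif(sum(production_link), cfg$beta_range[1], cfg$beta_range[2]) *
    cfg$beta_scale_inv

  amplitude <- numeric(M)
  amplitude[influence_link] <-
    runif(sum(influence_link), cfg$influence_range[1], cfg$influence_range[2])
  sign_pos <- runif(M) < cfg$f_fac_inv
  influence <- amplitude * ifelse(sign_pos, 1, -1)
  influence[!influence_link] <- 0

  consumption <- numeric(M)
  consumption[influence_link] <-
    runif(sum(influence_link), cfg$alpha_range[1], cfg$alpha_range[2]) *
    cfg$alpha_scale_inv

  saturation <- runif(M, cfg$K_range_nM[1], cfg$K_range_nM[2]) * NM_TO_FMOLE_ML

  structure(list(n_mediators = M,
                 basal_rate = basal,
                 r0_ratio = r0_ratio,
                 influence_rate = influence,
                 production_rate = production,
                 consumption_rate = consumption,
                 saturation = saturation,
                 influence_link = influence_link,
                 production_link = production_link,
                 resource_K = runif(1, rcfg$KR_range[1], rcfg$KR_range[2]),
                 resource_consumption = runif(1, rcfg$alphaR_range[1],
                                              rcfg$alphaR_range[2]),
                 production_removed = FALSE,
                 consumption_removed = FALSE,
                 influence_removed = FALSE,
                 seed = as.integer(seed)),
            class = "invader_spec")
}

#' Remove interaction channels from an invader
#'
#' Returns a copy of the invader with the named rate vectors zeroed, leaving
#' the link bookkeeping untouched.  All eight keep/remove combinations of
#' production, consumption and mediator influence are reachable.
#'
#' @param inv An [generate_invader()] result.
#' @param production,consumption,influence Logical: remove that channel?
#' @return The modified `invader_spec`, with ablation flags set.
#' @export
ablate_invader <- function(inv, production = FALSE, consumption = FALSE,
                           influence = FALSE) {
  stopifnot(inherits(inv, "invader_spec"))
  if (production) {
    inv$production_rate[] <- 0
    inv$production_removed <- TRUE
  }
  if (consumption) {
    inv$consumption_rate[] <- 0
    inv$consumption_removed <- TRUE
  }
  if (influence) {
    inv$influence_rate[] <- 0
    inv$influence_removed <- TRUE
  }
  inv
}

#' Build an interaction network or invader by hand
#'
#' For constructed examples (e.g. two-species motifs: mutual inhibition,
#' commensal support) rather than random draws.  Link matrices are derived
#' from the nonzero rates.
#'
#' @param basal_rate Per-species basal net growth rate (hr^-1); its length
#'   sets the number of species.
#' @param influence_rate Signed species x mediator influence matrix
#'   (hr^-1); its width sets the number of mediators.
#' @param production_rate Mediator x species production matrix
#'   (fmole cell^-1 hr^-1).
#' @param consumption_rate Mediator x species consumption matrix; defaults
#'   to no consumption.
#' @param saturation Species x mediator half-max concentrations (fmole/ml);
#'   a scalar is recycled.
#' @param resource_K,resource_consumption Per-species resource parameters
#'   (scalars recycled).
#' @return An `interaction_network`.
#' @export
manual_network <- function(basal_rate, influence_rate, production_rate,
                           consumption_rate = NULL, saturation = 1e5,
                           resource_K = 1e6, resource_consumption = 10) {
  N <- length(basal_rate)
  influence_rate <- as.matrix(influence_rate)
  M <- ncol(influence_rate)
  stopifnot(nrow(influence_rate) == N)
  production_rate <- as.matrix(production_rate)
  stopifnot(nrow(production_rate) == M, ncol(production_rate) == N)
  if (is.null(consumption_rate)) consumption_rate <- matrix(0, M, N)
  consumption_rate <- as.matrix(consumption_rate)
  if (length(saturation) == 1) saturation <- matrix(saturation, N, M)
  structure(list(n_species = N, n_mediators = M,
                 basal_rate = as.numeric(basal_rate),
                 influence_rate = influence_rate,
                 production_rate = production_rate,
                 consumption_rate = consumption_rate,
                 saturation = as.matrix(saturation),
                 influence_link = influence_rate != 0,
                 production_link = production_rate != 0,
                 resource_K = rep_len(resource_K, N),
                 resource_consumption = rep_len(resource_consumption, N),
                 config = NULL, seed = NA_integer_),
            class = "interaction_network")
}

#' @rdname manual_network
#' @param n_mediators Number of mediators (for `manual_invader`, inferred
#'   from `influence_rate`).
#' @export
manual_invader <- function(basal_rate, influence_rate, production_rate,
                           consumption_rate = NULL, saturation = 1e5,
                           resource_K = 1e6, resource_consumption = 10) {
  M <- length(influence_rate)
  stopifnot(length(production_rate) == M)
  if (is.null(consumption_rate)) consumption_rate <- numeric(M)
  structure(list(n_mediators = M,
                 basal_rate = basal_rate,
                 r0_ratio = NA_real_,
                 influence_rate = as.numeric(influence_rate),
                 production_rate = as.numeric(production_rate),
                 consumption_rate = as.numeric(consumption_rate),
                 saturation = rep_len(saturation, M),
                 influence_link = influence_rate != 0,
                 production_link = production_rate != 0,
                 resource_K = resource_K,
                 resource_consumption = resource_consumption,
                 production_removed = FALSE,
                 consumption_removed = FALSE,
                 influence_removed = FALSE,
                 seed = NA_integer_),
            class = "invader_spec")
}

#' Attach an invader to a network as an extra species
#'
#' Builds the combined (n_species + 1)-species network used by the invasion
#' assay; the invader occupies the last species index.
#'
#' @param net An `interaction_network`.
#' @param inv An `invader_spec` over the same mediator set.
#' @return An `interaction_network` with one more species.
#' @export
attach_invader <- function(net, inv) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(inv, "invader_spec"))
  if (inv$n_mediators != net$n_mediators)
    stop("invader and network mediator sets differ")
  out <- net
  out$n_species <- net$n_species + 1L
  out$basal_rate <- c(net$basal_rate, inv$basal_rate)
  out$influence_rate <- rbind(net$influence_rate, inv$influence_rate)
  out$production_rate <- cbind(net$production_rate, inv$production_rate)
  out$consumption_rate <- cbind(net$consumption_rate, inv$consumption_rate)
  out$saturation <- rbind(net$saturation, inv$saturation)
  out$influence_link <- rbind(net$influence_link, inv$influence_link)
  out$production_link <- cbind(net$production_link, inv$production_link)
  out$resource_K <- c(net$resource_K, inv$resource_K)
  out$resource_consumption <- c(net$resource_consumption,
                                inv$resource_consumption)
  out$invader_index <- out$n_species
  out
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Chemically-mediated interaction network\n")
  cat(sprintf("  %d species, %d mediators (seed %d)\n",
              x$n_species, x$n_mediators, x$seed))
  cat(sprintf("  production links: %d, influence links: %d (%d facilitative)\n",
              sum(x$production_link), sum(x$influence_link),
              sum(x$influence_rate > 0)))
  cat(sprintf("  basal growth rate: %.3f-%.3f hr^-1\n",
              min(x$basal_rate), max(x$basal_rate)))
  invisible(x)
}

#' @export
print.invader_spec <- function(x, ...) {
  cat("Invader specification\n")
  cat(sprintf("  basal rate %.3f hr^-1 (ratio %.2f), %d influence links (%d facilitative), %d production links\n",
              x$basal_rate, x$r0_ratio, sum(x$influence_link),
              sum(x$influence_rate > 0), sum(x$production_link)))
  abl <- c(production = x$production_removed,
           consumption = x$consumption_removed,
           influence = x$influence_removed)
  if (any(abl))
    cat("  ablated:", paste(names(abl)[abl], collapse = ", "), "\n")
  invisible(x)
}
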