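#' Exact Clopper-Pearson binomial confidence interval
#'
#' Interval endpoints via Beta-distribution quantiles: the lower bound is
#' the (1-level)/2 quantile of Beta(k, n-k+1) (0 when k = 0) and the upper
#' bound the 1-(1-level)/2 quantile of Beta(k+1, n-k) (1 when k = n).
#' Vectorized over `k`.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param level Confidence level in (0, 1); outcome-frequency plots
#'   conventionally use 0.8.
#' @return A two-column matrix with columns `low` and `high`.
#' @export
clopper_pearson <- function(k, n, level = 0.8) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(k < 0) || any(k > n)) stop("k must lie in [0, n]")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  low <- ifelse(k == 0, 0, stats::qbeta(a, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - a, k + 1, n - k))
  cbind(low = low, high = high)
}

#' Log-spaced grid of invader propagule fractions
#'
#' @param n Number of grid points (default 20).
#' @param from,to Range of normalized propagule sizes (default 1e-4 to
#'   0.99, equally spaced in log scale).
#' @return A numeric vector.
#' @export
propagule_grid <- function(n = 20, from = 1e-4, to = 0.99) {
  stopifnot(n >= 2, from > 0, to > from)
  exp(seq(log(from), log(to), length.out = n))
}

ablation_grid <- function() {
  g <- expand.grid(production = c(FALSE, TRUE),
                   consumption = c(FALSE, TRUE),
                   influence = c(FALSE, TRUE))
  lab <- apply(g, 1, function(r) {
    removed <- c("P", "C", "I")[as.logical(r)]
    if (length(removed) == 0) "keep all" else
      paste0("no ", paste(removed, collapse = "+"))
  })
  g$label <- lab
  g
}

default_sweep_grid <- function(experiment) {
  switch(experiment,
         propagule = propagule_grid(),
         invader_growth = seq(0.5, 2.5, by = 0.25),
         f_fac_inv = seq(0.1, 0.9, by = 0.1),
         f_fac = seq(0.1, 0.9, by = 0.1),
         ablation = ablation_grid(),
         invader_influence_connectivity = seq(0.1, 0.9, by = 0.1),
         invader_production_connectivity = seq(0.1, 0.9, by = 0.1),
         invader_production_rate = c(0.25, 0.5, 1, 2, 4),
         invader_consumption_rate = c(0.25, 0.5, 1, 2, 4),
         resource_amount = 10^seq(5, 7, length.out = 5),
         stop("unknown experiment: ", experiment))
}

sweep_experiments <- c("propagule", "invader_growth", "f_fac_inv", "f_fac",
                       "ablation", "invader_influence_connectivity",
                       "invader_production_connectivity",
                       "invader_production_rate", "invader_consumption_rate",
                       "resource_amount")

#' Run one replicate of the full invasion pipeline
#'
#' Generates a species pool, assembles a resident community by enrichment,
#' draws an invader, optionally ablates its interaction channels, and runs
#' the invasion assay.  Pools whose assembly collapses, stalls, or (by
#' default) fails a compositional stability check are regenerated from a
#' fresh child seed, so every replicate analyses one stable resident
#' community; the number of regenerations is reported.  Requiring stability
#' matters: communities that merely survived assembly keep shedding slow
#' stragglers for hundreds of further generations, and that endogenous
#' attrition would otherwise be misread as invader-caused disruption.
#'
#' @param seed Replicate seed; network and invader seeds are derived from it.
#' @param cfg A [generator_config()].
#' @param cycle_cfg A [cycle_config()].
#' @param model `"basic"` or `"resource"`.
#' @param rcfg A [resource_config()].
#' @param propagule_fraction Normalized propagule size.
#' @param r0_ratio Invader basal growth-rate ratio.
#' @param ablation Optional named list of logicals
#'   (`production`/`consumption`/`influence`) passed to [ablate_invader()].
#' @param require_stable Require assembled communities to pass
#'   [check_stability()] (default on).
#' @param stability_generations,stability_tol Parameters of that check.
#' @param persistence Invader persistence rule, see [classify_outcome()].
#' @param max_regen Maximum regenerations before giving up.
#' @return A list: `result` (an `invasion_result`), `community`, `invader`,
#'   `regenerated` (count of discarded pools).
#' @export
run_invasion_chain <- function(seed, cfg = generator_config(),
                               cycle_cfg = cycle_config(),
                               model = c("basic", "resource"),
                               rcfg = resource_config(),
                               propagule_fraction = 0.003, r0_ratio = 1.5,
                               ablation = NULL,
                               require_stable = TRUE,
                               stability_generations = 50,
                               stability_tol = 0.01,
                               persistence = c("density", "fraction"),
                               max_regen = 100) {
  model <- match.arg(model)
  persistence <- match.arg(persistence)
  regen <- 0
  repeat {
    net <- generate_network(cfg, child_seed(seed, "network", regen), rcfg)
    rc <- enrich(net, cycle_cfg, model, rcfg)
    ok <- !rc$collapsed && !rc$stalled
    if (ok && require_stable)
      ok <- check_stability(rc, stability_generations, stability_tol)$stable
    if (ok) break
    regen <- regen + 1
    if (regen > max_regen)
      stop("no stable resident community after ", max_regen,
           " regenerations")
  }
  inv <- generate_invader(net, cfg, r0_ratio, child_seed(seed, "invader"),
                          rcfg)
  if (!is.null(ablation))
    inv <- do.call(ablate_invader, c(list(inv), ablation))
  res <- run_assay(rc, inv, propagule_fraction, persistence = persistence)
  list(result = res, community = rc, invader = inv, regenerated = regen)
}

#' Sweep one parameter of the invasion assay over replicate instances
#'
#' For each grid point, runs `n_instances` independent
#' (network, enrichment, invader, assay) chains from deterministically
#' derived child seeds and tallies the four invasion outcomes with
#' Clopper-Pearson confidence intervals.  Built-in sweeps:
#'
#' * `"propagule"`: normalized propagule size, 20 points log-spaced from
#'   1e-4 to 0.99;
#' * `"invader_growth"`: invader basal growth-rate ratio;
#' * `"f_fac_inv"`: fraction of facilitative influences on the invader;
#' * `"f_fac"`: fraction of facilitative influences among residents;
#' * `"ablation"`: all eight keep/remove combinations of invader
#'   production, consumption and mediator influence;
#' * `"invader_influence_connectivity"`, `"invader_production_connectivity"`:
#'   invader-specific q_c / q_p;
#' * `"invader_production_rate"`, `"invader_consumption_rate"`:
#'   multipliers on the invader's production / consumption rates;
#' * `"resource_amount"`: fresh-medium resource concentration, forcing the
#'   resource model.
#'
#' All non-swept parameters stay at the values supplied (by default, the
#' standard assay conditions: f_fac = 0.5, mostly inhibitory influence on
#' the invader f_fac_inv = 0.1, propagule 0.3%, basal-rate ratio 1.5).
#'
#' @param experiment One of the built-in sweep names.
#' @param grid Optional custom grid (numeric, or a logical data frame with
#'   columns production/consumption/influence for `"ablation"`).
#' @param n_instances Replicate instances per grid point (N_s).
#' @param seed Root seed; every replicate derives its own child seed.
#' @param cfg,cycle_cfg,rcfg Base configurations.
#' @param model `"basic"` or `"resource"` (forced to `"resource"` by the
#'   resource-amount sweep).
#' @param propagule_fraction,r0_ratio Fixed assay parameters (unless swept).
#' @param require_stable Require assembled communities to pass the
#'   compositional stability check (see [run_invasion_chain()]).
#' @param persistence Invader persistence rule, see [classify_outcome()].
#' @param level Confidence level for the Clopper-Pearson intervals.
#' @param match_seeds If `TRUE`, replicate i uses the same child seed at
#'   every grid point, so grid points differ only through the swept
#'   parameter (paired comparisons); by default each grid point gets fresh
#'   instances.
#' @param progress Print a line per grid point.
#' @return An `outcome_table`: a data frame with one row per grid point and
#'   outcome (`experiment`, `grid_value`, `grid_label`, `outcome`, `count`,
#'   `frequency`, `ci_low`, `ci_high`, `n_instances`), with the root seed,
#'   configuration snapshot, per-point mean invader final fraction and
#'   collapse-regeneration counts as attributes.
#' @export
sweep_invasion <- function(experiment = sweep_experiments, grid = NULL,
                           n_instances = 1000, seed = 1,
                           cfg = generator_config(f_fac = 0.5,
                                                  f_fac_inv = 0.1),
                           cycle_cfg = cycle_config(),
                           rcfg = resource_config(),
                           model = c("basic", "resource"),
                           propagule_fraction = 0.003, r0_ratio = 1.5,
                           require_stable = TRUE,
                           persistence = c("density", "fraction"),
                           level = 0.8, match_seeds = FALSE,
                           progress = FALSE) {
  experiment <- match.arg(experiment)
  model <- match.arg(model)
  persistence <- match.arg(persistence)
  if (experiment == "resource_amount") model <- "resource"
  if (is.null(grid)) grid <- default_sweep_grid(experiment)

  if (experiment == "ablation") {
    if (!is.data.frame(grid) ||
        !all(c("production", "consumption", "influence") %in% names(grid)))
      stop("the ablation grid must be a data frame with logical columns ",
           "production, consumption, influence")
    if (is.null(grid$label)) grid$label <- seq_len(nrow(grid))
    n_points <- nrow(grid)
    values <- seq_len(n_points)
    labels <- as.character(grid$label)
  } else {
    grid <- as.numeric(grid)
    if (any(!is.finite(grid)) || any(grid <= 0 & experiment != "f_fac" &
                                       experiment != "f_fac_inv"))
      stop("grid values must be finite and positive")
    n_points <- length(grid)
    values <- grid
    labels <- format(grid, digits = 4, trim = TRUE)
  }

  rows <- vector("list", n_points)
  mean_inv_fraction <- numeric(n_points)
  regenerations <- integer(n_points)

  for (g in seq_len(n_points)) {
    cfg_g <- cfg
    rcfg_g <- rcfg
    prop_g <- propagule_fraction
    ratio_g <- r0_ratio
    abl_g <- NULL
    v <- values[g]
    switch(experiment,
           propagule = { prop_g <- v },
           invader_growth = { ratio_g <- v },
           f_fac_inv = { cfg_g$f_fac_inv <- v },
           f_fac = { cfg_g$f_fac <- v },
           ablation = {
             abl_g <- list(production = grid$production[g],
                           consumption = grid$consumption[g],
                           influence = grid$influence[g])
           },
           invader_influence_connectivity = { cfg_g$q_c_inv <- v },
           invader_production_connectivity = { cfg_g$q_p_inv <- v },
           invader_production_rate = { cfg_g$beta_scale_inv <- v },
           invader_consumption_rate = { cfg_g$alpha_scale_inv <- v },
           resource_amount = { rcfg_g$R0 <- v })
    validate_generator_config(cfg_g)

    counts <- stats::setNames(integer(4), outcome_levels)
    inv_fracs <- numeric(n_instances)
    regen <- 0L
    for (i in seq_len(n_instances)) {
      rep_seed <- child_seed(seed, experiment,
                             if (match_seeds) 0L else g, i)
      chain <- run_invasion_chain(rep_seed, cfg_g, cycle_cfg, model, rcfg_g,
                                  propagule_fraction = prop_g,
                                  r0_ratio = ratio_g, ablation = abl_g,
                                  require_stable = require_stable,
                                  persistence = persistence)
      oc <- as.character(chain$result$outcome)
      counts[oc] <- counts[oc] + 1L
      inv_fracs[i] <- chain$result$invader_final_fraction
      regen <- regen + chain$regenerated
    }
    ci <- clopper_pearson(counts, n_instances, level)
    rows[[g]] <- data.frame(experiment = experiment,
                            grid_value = v,
                            grid_label = labels[g],
                            outcome = factor(outcome_levels,
                                             levels = outcome_levels),
                            count = as.integer(counts),
                            frequency = counts / n_instances,
                            ci_low = ci[, "low"],
                            ci_high = ci[, "high"],
                            n_instances = n_instances,
                            row.names = NULL)
    mean_inv_fraction[g] <- mean(inv_fracs)
    regenerations[g] <- regen
    if (progress)
      message(sprintf("%s [%s]: %s", experiment, labels[g],
                      paste(sprintf("%s %.3f", substr(outcome_levels, 1, 4),
                                    counts / n_instances), collapse = " ")))
  }

  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "level") <- level
  attr(out, "model") <- model
  attr(out, "config") <- cfg
  attr(out, "cycle_config") <- cycle_cfg
  attr(out, "resource_config") <- rcfg
  attr(out, "match_seeds") <- match_seeds
  attr(out, "mean_invader_fraction") <- mean_inv_fraction
  attr(out, "regenerations") <- regenerations
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Merge outcome tables into one long-format dataset
#'
#' @param ... One or more `outcome_table` objects (or a single list of
#'   them).
#' @return A plain long-format data frame with the common outcome-table
#'   columns, one row per (experiment, grid point, outcome).
#' @export
summarize_outcomes <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && !is.data.frame(tables[[1]]))
    tables <- tables[[1]]
  cols <- c("experiment", "grid_value", "grid_label", "outcome", "count",
            "frequency", "ci_low", "ci_high", "n_instances")
  for (tb in tables) {
    if (!all(cols %in% names(tb)))
      stop("not an outcome table: missing columns")
  }
  out <- do.call(rbind, lapply(tables, function(tb) {
    tb <- as.data.frame(tb)[, cols]
    rownames(tb) <- NULL
    tb
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.outcome_table <- function(x, ...) {
  cat(sprintf("Invasion outcome table: %s sweep, %d grid points, N_s = %d (seed %s)\n",
              x$experiment[1], length(unique(x$grid_label)),
              x$n_instances[1], format(attr(x, "seed"))))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Stacked outcome-frequency plot for a sweep
#'
#' @param x An `outcome_table`.
#' @param ci Draw the confidence band per outcome.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.outcome_table <- function(x, ci = TRUE, ...) {
  wide <- do.call(cbind, lapply(outcome_levels, function(oc)
    x$frequency[x$outcome == oc]))
  gv <- unique(x$grid_value)
  logx <- x$experiment[1] %in% c("propagule", "resource_amount")
  graphics::matplot(gv, wide, type = "b", pch = 1:4, lty = 1,
                    log = if (logx) "x" else "",
                    xlab = x$experiment[1], ylab = "outcome frequency",
                    ylim = c(0, 1), ...)
  if (ci) {
    for (k in seq_along(outcome_levels)) {
      oc <- outcome_levels[k]
      graphics::arrows(gv, x$ci_low[x$outcome == oc],
                       gv, x$ci_high[x$outcome == oc],
                       angle = 90, code = 3, length = 0.02, col = k)
    }
  }
  graphics::legend("topright", outcome_levels, col = 1:4, pch = 1:4,
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
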