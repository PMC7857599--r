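# Independent oracles and small fixtures used across the suite.

# standard assay conditions for the sweep experiments
std_cfg <- function(...) {
  args <- utils::modifyList(list(f_fac = 0.5, f_fac_inv = 0.1), list(...))
  do.call(generator_config, args)
}

# a comfortably settled resident community: passes a 50-generation stability
# check and holds every member above 1% relative abundance
settled_community <- function(root = 88, cfg = std_cfg()) {
  for (i in 1:50) {
    net <- generate_network(cfg, child_seed(root, "stable", i))
    rc <- enrich(net)
    if (rc$collapsed || rc$stalled) next
    if (min(rc$fractions[rc$survivors]) < 0.01) next
    if (!check_stability(rc, 50)$stable) next
    return(rc)
  }
  stop("no settled community found")
}

# naive double-loop evaluation of the model right-hand side, kept deliberately
# independent of the vectorized / compiled implementations
oracle_derivatives <- function(state, net) {
  S <- state$species; C <- state$mediators
  N <- net$n_species; M <- net$n_mediators
  dC <- numeric(M); dS <- numeric(N)
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      sat <- if (C[i] > 0) C[i] / (C[i] + net$saturation[j, i]) else 0
      dC[i] <- dC[i] +
        (net$production_rate[i, j] - net$consumption_rate[i, j] * sat) * S[j]
    }
  }
  for (j in seq_len(N)) {
    g <- net$basal_rate[j]
    for (i in seq_len(M)) {
      sat <- if (C[i] > 0) C[i] / (C[i] + net$saturation[j, i]) else 0
      g <- g + net$influence_rate[j, i] * sat
    }
    dS[j] <- g * S[j]
  }
  list(dS = dS, dC = dC)
}

# brute-force Clopper-Pearson endpoints by inverting the binomial tail
# probabilities directly (no Beta quantiles involved)
oracle_clopper_pearson <- function(k, n, level) {
  a <- (1 - level) / 2
  low <- if (k == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  high <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low, high)
}

# high-order adaptive reference trajectory for the basic model
ref_ode_state <- function(net, S0, C0, t_end) {
  rhs <- function(t, y, parms) {
    N <- net$n_species; M <- net$n_mediators
    st <- community_state(pmax(y[seq_len(N)], 0), pmax(y[N + seq_len(M)], 0))
    d <- derivatives(st, net)
    list(c(d$dS, d$dC))
  }
  out <- deSolve::ode(c(S0, C0), c(0, t_end), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-8)
  drop(out[2, -1])
}

# pure-R forward Euler through one growth cycle (same scheme as the
# compiled path, reimplemented independently)
r_euler_cycle <- function(net, S0, C0, dt, n_dil = 1e7) {
  S <- S0; C <- C0; t <- 0
  repeat {
    st <- community_state(S, C)
    d <- derivatives(st, net)
    S <- pmax(S + dt * d$dS, 0)
    C <- pmax(C + dt * d$dC, 0)
    t <- t + dt
    if (sum(S) >= n_dil) break
    if (t > 1e4) stop("r_euler_cycle: no threshold crossing")
  }
  list(S = S, C = C, t = t)
}

# paired one-sided exact test: property holds more often in `a` than `b`
mcnemar_greater <- function(a, b) {
  n10 <- sum(a & !b); n01 <- sum(!a & b)
  if (n10 + n01 == 0) return(1)
  stats::binom.test(n10, n10 + n01, 0.5, alternative = "greater")$p.value
}

# hand-built two-compartment fixtures ------------------------------------

# resident A produces m1 and is inhibited by m2; invader B produces m2 and
# is inhibited by m1; B has a slight basal advantage so that bistability
# resolves toward whichever side starts abundant
mutual_inhibition_pair <- function() {
  net <- manual_network(basal_rate = 0.10,
                        influence_rate = matrix(c(0, -0.08), 1, 2),
                        production_rate = matrix(c(0.1, 0), 2, 1))
  inv <- manual_invader(basal_rate = 0.12,
                        influence_rate = c(-0.08, 0),
                        production_rate = c(0, 0.1))
  list(net = net, inv = inv)
}

# resident A produces m1, which facilitates the slower invader B; the
# facilitation saturates at a concentration comparable to one cycle's
# mediator accumulation, so B's advantage vanishes as A becomes rare
commensal_pair <- function() {
  net <- manual_network(basal_rate = 0.10,
                        influence_rate = matrix(0, 1, 1),
                        production_rate = matrix(0.1, 1, 1))
  inv <- manual_invader(basal_rate = 0.08,
                        influence_rate = 0.12,
                        production_rate = 0,
                        saturation = 1e6)
  list(net = net, inv = inv)
}
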