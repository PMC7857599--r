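test_that("derivatives reproduce hand-computed single-link cases", {
  # single species, no links: dS/dt = r0 * S
  net <- manual_network(basal_rate = 0.1,
                        influence_rate = matrix(0, 1, 1),
                        production_rate = matrix(0, 1, 1))
  st <- community_state(1e4, 0)
  d <- derivatives(st, net)
  expect_equal(d$dS, 1e3)
  expect_equal(d$dC, 0)

  # one mediator, one producer, no consumers: dC/dt = beta * S
  netp <- manual_network(basal_rate = 0.1,
                         influence_rate = matrix(0, 1, 1),
                         production_rate = matrix(0.1, 1, 1))
  dp <- derivatives(community_state(1e4, 0), netp)
  expect_equal(dp$dC, 1e3)

  # C >> K: consumption saturates to alpha * S, influence to r_ij
  netc <- manual_network(basal_rate = 0.1,
                         influence_rate = matrix(0.15, 1, 1),
                         production_rate = matrix(0, 1, 1),
                         consumption_rate = matrix(0.5, 1, 1),
                         saturation = 1e5)
  dc <- derivatives(community_state(1e4, 1e12), netc)
  expect_equal(dc$dC, -0.5 * 1e4, tolerance = 1e-6)
  expect_equal(dc$dS, (0.1 + 0.15) * 1e4, tolerance = 1e-6)

  # dimension mismatch is a structural error
  expect_error(derivatives(community_state(c(1, 1), 0), net), "species")
})

test_that("vectorized derivatives match the double-loop oracle to 12 digits", {
  cfg3 <- generator_config(n_species = 3, n_mediators = 2)
  for (k in 1:5) {
    net <- generate_network(cfg3, seed = 600 + k)
    st <- community_state(runif(3, 1e3, 1e6), runif(2, 0, 2e5))
    d <- derivatives(st, net)
    o <- oracle_derivatives(st, net)
    expect_equal(d$dS, o$dS, tolerance = 1e-12)
    expect_equal(d$dC, o$dC, tolerance = 1e-12)
  }
})

test_that("the compiled Euler path agrees with a pure-R Euler cycle", {
  cfg3 <- generator_config(n_species = 3, n_mediators = 2)
  net <- generate_network(cfg3, seed = 777)
  S0 <- rep(1e4 / 3, 3); C0 <- c(0, 0)
  dt <- choose_timestep(net)
  run <- run_cycles(community_state(S0, C0), net,
                    cycle_config(target_generations = 15))
  ref <- r_euler_cycle(net, S0, C0, dt)
  expect_equal(run$composition[1, ], ref$S, tolerance = 1e-10)
  expect_equal(run$mediators_at_dilution[1, ], ref$C, tolerance = 1e-10)
  expect_equal(run$dilutions$time[1], ref$t, tolerance = 1e-9)
})

test_that("the time step follows the shortest-doubling-time rule", {
  # max achievable rate 0.12, divisor 10: dt = ln2 / 0.12 / 10
  net <- manual_network(basal_rate = 0.12,
                        influence_rate = matrix(0, 1, 1),
                        production_rate = matrix(0, 1, 1))
  expect_equal(choose_timestep(net), log(2) / 0.12 / 10, tolerance = 1e-12)
  expect_equal(choose_timestep(net, divisor = 1e6), log(2) / 0.12 / 1e6)

  # positive influence amplitudes raise the bound; inhibition does not
  net2 <- manual_network(basal_rate = 0.1,
                         influence_rate = matrix(c(0.2, -0.3), 1, 2),
                         production_rate = matrix(0, 2, 1))
  expect_equal(choose_timestep(net2), log(2) / 0.3 / 10)
})

test_that("a single-species cycle matches the discrete and continuous growth laws", {
  r <- 0.1
  net <- manual_network(basal_rate = r,
                        influence_rate = matrix(0, 1, 1),
                        production_rate = matrix(0, 1, 1))
  dt <- choose_timestep(net)
  run <- run_cycles(community_state(1e4, 0), net,
                    cycle_config(target_generations = 15))
  # exact discrete crossing: S_n = 1e4 (1 + r dt)^n >= 1e7
  n_cross <- ceiling(log(1000) / log1p(r * dt))
  expect_equal(run$dilutions$time[1], n_cross * dt, tolerance = 1e-9)
  expect_equal(run$dilutions$generations[1], n_cross * log2(1 + r * dt),
               tolerance = 1e-9)
  # continuous limit ln(1000)/r = 69.08 hr, within Euler's O(dt) bias
  expect_lt(abs(run$dilutions$time[1] - log(1000) / r),
            log(1000) / r * r * dt)
  # dilution factor ~ 1e-3 (slightly smaller from the overshoot)
  factor <- 1e4 / run$dilutions$total[1]
  expect_true(factor <= 1e-3 && factor > 0.9e-3)
})

test_that("200 generations of a lone grower take 20 full dilution cycles", {
  net <- manual_network(basal_rate = 0.1,
                        influence_rate = matrix(0, 1, 1),
                        production_rate = matrix(0, 1, 1))
  run <- run_cycles(community_state(1e4, 0), net, cycle_config())
  # 200 / log2(1000) = 20.07 cycles; threshold overshoot adds a little to
  # each cycle's fold, so the final partial cycle starts after 19-20 dilutions
  expect_true(run$n_cycles %in% 19:21)
  expect_gte(run$state$generations, 200)
  expect_lt(run$state$generations, 201)
})

test_that("species diluted below the extinction threshold are removed permanently", {
  # B declines at -0.1/hr: ~2.5 cells/ml at first dilution, 0.0025 after
  net <- manual_network(basal_rate = c(0.1, -0.1),
                        influence_rate = matrix(0, 2, 1),
                        production_rate = matrix(0, 1, 2))
  run <- run_cycles(community_state(c(5e3, 5e3), 0), net,
                    cycle_config(target_generations = 40))
  expect_true(2 %in% run$extinctions$species)
  expect_identical(run$state$species[2], 0)
  # and the survivor carried on alone
  expect_gt(run$state$species[1], 0)
})

test_that("generation accounting sums per-interval log2 fold changes exactly", {
  net <- generate_network(std_cfg(), seed = 314)
  cc <- cycle_config()
  run <- run_cycles(community_state(rep(500, 20), rep(0, 10)), net, cc)
  # reconstruct interval folds from the event log
  start <- 1e4
  gens <- 0
  for (k in seq_len(nrow(run$dilutions))) {
    gens <- gens + log2(run$dilutions$total[k] / start)
    post <- run$composition[k, ] * cc$n_inoc / run$dilutions$total[k]
    post[post < cc$n_ext] <- 0
    start <- sum(post)
  }
  gens <- gens + log2(sum(run$state$species) / start)
  expect_equal(run$state$generations, gens, tolerance = 1e-9)
})

test_that("state variables never go negative and Euler converges at first order", {
  cfg3 <- generator_config(n_species = 3, n_mediators = 2)
  for (k in 1:5) {
    net <- generate_network(cfg3, seed = 550 + k)
    run <- run_cycles(community_state(rep(1e4 / 3, 3), c(0, 0)), net,
                      cycle_config(target_generations = 50))
    expect_true(all(run$state$species >= 0))
    expect_true(all(run$state$mediators >= 0))
    expect_true(all(run$composition >= 0))
  }
  # first-order convergence of end-of-first-cycle composition
  net <- generate_network(cfg3, seed = 503)
  st <- community_state(rep(1e4 / 3, 3), c(0, 0))
  dt <- choose_timestep(net)
  comp <- function(d) {
    r <- run_cycles(st, net, cycle_config(target_generations = 15), dt = d)
    r$composition[1, ] / sum(r$composition[1, ])
  }
  c1 <- comp(dt); c2 <- comp(dt / 2); c4 <- comp(dt / 4)
  expect_lt(max(abs(c1 - c2)), 0.05)
  expect_lt(max(abs(c2 - c4)), max(abs(c1 - c2)))
})

test_that("the resource variant obeys its limiting cases", {
  rcfg <- resource_config()
  net <- manual_network(basal_rate = 0.1,
                        influence_rate = matrix(0, 1, 1),
                        production_rate = matrix(0, 1, 1),
                        resource_K = 1e6, resource_consumption = 10)
  # R = 0: growth arrest, no further resource drawdown
  st0 <- community_state(1e4, 0, resource = 0)
  d0 <- derivatives_resource(st0, net)
  expect_equal(d0$dS, 0)
  expect_equal(d0$dR, 0)
  # R >> K_R: reduces to the basic model
  stb <- community_state(1e4, 0, resource = 1e15)
  db <- derivatives_resource(stb, net)
  expect_equal(db$dS, derivatives(stb, net)$dS, tolerance = 1e-6)
  # single species, no mediators: dR/dt = -alphaR * R/(R+KR) * r0 * S
  str <- community_state(1e4, 0, resource = 5e5)
  dr <- derivatives_resource(str, net)
  rho <- 5e5 / (5e5 + 1e6)
  expect_equal(dr$dR, -10 * rho * 0.1 * 1e4)
  expect_equal(dr$dS, rho * 0.1 * 1e4)
  # a state without resource cannot be evaluated under the resource model
  expect_error(derivatives_resource(community_state(1e4, 0), net), "resource")
})

test_that("resource drawdown balances realized growth over a cycle", {
  # with no mediators, dR = -alphaR * dS at every Euler step, so the
  # depletion equals alphaR times the density gain exactly
  net <- manual_network(basal_rate = 0.1,
                        influence_rate = matrix(0, 1, 1),
                        production_rate = matrix(0, 1, 1),
                        resource_K = 1e6, resource_consumption = 10)
  rcfg <- resource_config(R0 = 1e8) # ample: threshold reached before 80 hr
  run <- run_cycles(community_state(1e4, 0, resource = 1e8), net,
                    cycle_config(target_generations = 5), model = "resource",
                    rcfg = rcfg)
  S_end <- sum(run$state$species)
  expect_equal(1e8 - run$state$resource, 10 * (S_end - 1e4),
               tolerance = 1e-9)
})

test_that("resource-limited cycles hit the 80-hour cap and still reach 200 generations", {
  net <- generate_network(std_cfg(), seed = 41)
  rcfg <- resource_config(R0 = 1e5)
  rc <- enrich(net, model = "resource", rcfg = rcfg)
  expect_gte(rc$harvest_state$generations, 200)
  # scarce resource supports ~1e4 cells/ml of growth per round, so far
  # more than 20 cycles are needed
  expect_gt(rc$n_cycles, 40)
})

test_that("a community that cannot reach the dilution threshold is flagged stalled", {
  # strong mutual inhibition: growth turns negative once mediators build up
  net <- manual_network(basal_rate = c(0.1, 0.1),
                        influence_rate = matrix(c(0, -0.4, -0.4, 0), 2, 2),
                        production_rate = matrix(c(0.1, 0, 0, 0.1), 2, 2))
  run <- run_cycles(community_state(c(5e3, 5e3), c(0, 0)), net,
                    cycle_config())
  expect_true(run$stalled)
  expect_lt(run$state$generations, 200)
})
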