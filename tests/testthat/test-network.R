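test_that("configuration validation rejects inverted ranges and bad probabilities", {
  expect_error(generator_config(r0_range = c(0.12, 0.08)), "low <= high")
  expect_error(generator_config(q_p = 1.3), "probability")
  expect_error(generator_config(f_fac = -0.1), "probability")
  expect_error(cycle_config(n_inoc = 1e8, n_dil = 1e7))
  expect_error(resource_config(R0 = -1))
})

test_that("degenerate connectivities give the expected link structure", {
  cfg0 <- generator_config(q_p = 0, q_c = 0)
  net0 <- generate_network(cfg0, seed = 3)
  expect_true(all(net0$production_rate == 0))
  expect_true(all(net0$consumption_rate == 0))
  expect_true(all(net0$influence_rate == 0))
  expect_false(any(net0$influence_link))

  cfg1 <- generator_config(f_fac = 1)
  net1 <- generate_network(cfg1, seed = 3)
  expect_true(all(net1$influence_rate[net1$influence_link] > 0))
})

test_that("rates respect their configured ranges and link bookkeeping", {
  cfg <- std_cfg()
  net <- generate_network(cfg, seed = 17)
  expect_true(all(net$basal_rate >= 0.08 & net$basal_rate <= 0.12))
  expect_true(all(abs(net$influence_rate[net$influence_link]) <= 0.2))
  expect_true(all(net$production_rate[net$production_link] >= 0.05 &
                    net$production_rate[net$production_link] <= 0.15))
  expect_true(all(net$consumption_rate >= 0))
  expect_true(all(net$consumption_rate[t(net$influence_link)] >= 0.25 &
                    net$consumption_rate[t(net$influence_link)] <= 0.75))
  # saturation stored in fmole/ml: 50-150 nM = 5e4-1.5e5
  expect_true(all(net$saturation >= 5e4 & net$saturation <= 1.5e5))
  # nonzero rate implies the link bit, and vice versa
  expect_identical(net$influence_rate != 0, net$influence_link)
  expect_identical(net$production_rate != 0, net$production_link)
  expect_identical(net$consumption_rate != 0, t(net$influence_link))
})

test_that("link counts follow the binomial connectivity and signs follow f_fac", {
  cfg <- std_cfg()
  n_draws <- 1000
  prod_counts <- infl_counts <- integer(n_draws)
  pos <- tot <- 0
  for (i in seq_len(n_draws)) {
    net <- generate_network(cfg, seed = child_seed(29, "gof", i))
    prod_counts[i] <- sum(net$production_link)
    infl_counts[i] <- sum(net$influence_link)
    pos <- pos + sum(net$influence_rate > 0)
    tot <- tot + sum(net$influence_link)
  }
  # expected 0.3 * 200 = 60 links on average
  expect_lt(abs(mean(prod_counts) - 60), 1)
  expect_lt(abs(mean(infl_counts) - 60), 1)
  # goodness of fit against Binomial(200, 0.3), pooling sparse tails
  probs <- dbinom(0:200, 200, 0.3)
  breaks <- c(-Inf, 50, 55, 60, 65, 70, Inf)
  obs <- table(cut(prod_counts, breaks))
  exp_p <- diff(c(0, pbinom(c(50, 55, 60, 65, 70), 200, 0.3), 1))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = exp_p))
  expect_gt(gof$p.value, 1e-3)
  # sign fraction converges to f_fac = 0.5 (tot ~ 60k draws here)
  expect_gt(tot, 10000)
  expect_lt(abs(pos / tot - 0.5), 0.02)
})

test_that("network generation is deterministic and serializes losslessly", {
  cfg <- std_cfg()
  n1 <- generate_network(cfg, seed = 99)
  n2 <- generate_network(cfg, seed = 99)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_network_json(n1, f1); write_network_json(n2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # JSON stores doubles to 16-17 significant digits; round-trip is exact to
  # well below any physically meaningful precision
  back <- read_network_json(f1)
  expect_equal(back$influence_rate, n1$influence_rate, tolerance = 1e-12)
  expect_equal(back$saturation, n1$saturation, tolerance = 1e-12)
  expect_equal(back$basal_rate, n1$basal_rate, tolerance = 1e-12)
  expect_identical(back$influence_link, n1$influence_link)
  unlink(c(f1, f2))
})

test_that("invader draws honour the basal-rate ratio and its own sign bias", {
  cfg <- std_cfg()
  net <- generate_network(cfg, seed = 5)
  expect_error(generate_invader(net, cfg, r0_ratio = -1), "positive")
  # ratio 1.5 on a 0.08-0.12 draw lands in 0.12-0.18
  basals <- sapply(1:50, function(i)
    generate_invader(net, cfg, 1.5, seed = i)$basal_rate)
  expect_true(all(basals >= 0.12 & basals <= 0.18))

  # f_fac_inv = 0.1: about 10% of influence entries positive
  cfg01 <- std_cfg()
  pos <- tot <- 0
  for (i in 1:300) {
    inv <- generate_invader(net, cfg01, 1.5, seed = child_seed(31, i))
    pos <- pos + sum(inv$influence_rate > 0)
    tot <- tot + sum(inv$influence_link)
  }
  expect_lt(abs(pos / tot - 0.1), 0.04)

  # full connectivity, no facilitation: every mediator inhibits the invader
  cfgall <- generator_config(q_c_inv = 1, f_fac_inv = 0)
  invall <- generate_invader(net, cfgall, 1.5, seed = 2)
  expect_true(all(invall$influence_rate < 0))
})

test_that("ablation zeroes rates without touching link bookkeeping", {
  net <- generate_network(std_cfg(), seed = 5)
  inv <- generate_invader(net, std_cfg(), 1.5, seed = 6)

  none <- ablate_invader(inv)
  expect_identical(none, inv)

  noP <- ablate_invader(inv, production = TRUE)
  expect_true(all(noP$production_rate == 0))
  expect_identical(noP$production_link, inv$production_link)
  expect_identical(noP$consumption_rate, inv$consumption_rate)
  expect_true(noP$production_removed)

  all3 <- ablate_invader(inv, TRUE, TRUE, TRUE)
  expect_true(all(all3$production_rate == 0))
  expect_true(all(all3$consumption_rate == 0))
  expect_true(all(all3$influence_rate == 0))
  # fully decoupled invader grows at exactly its basal rate
  net1 <- attach_invader(net, all3)
  st <- community_state(c(rep(500, 20), 30), rep(1e6, 10))
  d <- derivatives(st, net1)
  expect_equal(d$dS[21], all3$basal_rate * 30)
})

test_that("invader and community serialization round-trips", {
  net <- generate_network(std_cfg(), seed = 44)
  inv <- generate_invader(net, std_cfg(), 1.5, seed = 45)
  f <- tempfile(fileext = ".json")
  write_invader_json(inv, f)
  back <- read_invader_json(f)
  expect_equal(back$influence_rate, inv$influence_rate, tolerance = 1e-12)
  expect_equal(back$basal_rate, inv$basal_rate, tolerance = 1e-12)
  unlink(f)

  rc <- enrich(net)
  g <- tempfile(fileext = ".json")
  write_community_json(rc, g)
  rcb <- read_community_json(g)
  expect_identical(rcb$survivors, rc$survivors)
  expect_equal(rcb$fractions, rc$fractions, tolerance = 1e-12)
  expect_equal(rcb$harvest_state$species, rc$harvest_state$species,
               tolerance = 1e-12)
  expect_equal(rcb$network$influence_rate, rc$network$influence_rate,
               tolerance = 1e-12)
  # a reloaded community supports an equivalent assay
  invx <- generate_invader(net, std_cfg(), 1.5, seed = 46)
  r1 <- run_assay(rc, invx, 0.003)
  r2 <- run_assay(rcb, invx, 0.003)
  expect_identical(as.character(r1$outcome), as.character(r2$outcome))
  expect_equal(r1$invader_final_fraction, r2$invader_final_fraction,
               tolerance = 1e-4)
  unlink(g)
})
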