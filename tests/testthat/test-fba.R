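test_that("linear-chain bottleneck arithmetic is exact", {
  ## uptake <= 10, A -> ATP 1:1, biomass takes 2 ATP: objective 10/2 = 5
  m <- chain_model(atp_per_bio = 2)
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5, tolerance = 1e-9)
  ## an NGAM drain of 2 leaves (10 - 2)/2 = 4
  m2 <- chain_model(atp_per_bio = 2, with_ngam = TRUE)
  expect_equal(solve_fba(m2)$objective_value, 4, tolerance = 1e-9)
})

test_that("objective scales with the uptake bound when it binds", {
  m <- chain_model(atp_per_bio = 2)
  v1 <- solve_fba(m)$objective_value
  m2 <- set_bounds(m, "EX_a", lower = -20)
  expect_equal(solve_fba(m2)$objective_value, 2 * v1, tolerance = 1e-9)
})

test_that("every optimal solution satisfies steady state to 1e-6", {
  m <- make_toy_model()
  for (cond in toy_conditions()) {
    bm <- apply_condition(m, cond)
    sol <- solve_fba(bm)
    expect_equal(sol$status, "optimal")
    expect_lt(sol$steady_state_residual, 1e-6)
    ## bounds respected
    for (r in bm$reactions) {
      expect_gte(sol$fluxes[[r$id]], r$lower_bound - 1e-7)
      expect_lte(sol$fluxes[[r$id]], r$upper_bound + 1e-7)
    }
  }
})

test_that("apply_condition opens/closes the right exchanges", {
  m <- make_toy_model()
  conds <- toy_conditions()
  aer <- apply_condition(m, conds[["acetate-aerobic"]])
  expect_equal(get_reaction(aer, "EX_no3")$upper_bound, 0)
  expect_equal(get_reaction(aer, "EX_no3")$lower_bound, 0)
  expect_equal(get_reaction(aer, "EX_o2")$lower_bound, -30)
  expect_equal(get_reaction(aer, "EX_ac")$lower_bound, -10)
  ana <- apply_condition(m, conds[["benzoate-anaerobic"]])
  expect_equal(get_reaction(ana, "EX_o2")$upper_bound, 0)
  expect_equal(get_reaction(ana, "EX_bz")$lower_bound, -5)
  ## NGAM pinned
  expect_equal(get_reaction(ana, "NGAM")$lower_bound,
               conds[[1]]$ngam)
  expect_equal(get_reaction(ana, "NGAM")$upper_bound,
               conds[[1]]$ngam)
  expect_error(apply_condition(m, condition("bad", "EX_missing", 1,
                                            "oxygen", "EX_o2", 1)),
               "EX_missing")
})

test_that("no electron acceptor means no growth on a respiration-only network", {
  ## PHB storage disabled: without it there is no fermentative electron
  ## sink at all, so a closed acceptor must pin growth at zero
  m <- make_toy_model(toy_network_spec(include_phb = FALSE))
  cond <- condition("acetate-no-acceptor", "EX_ac", 10,
                    acceptor = "nitrate", acceptor_exchange = "EX_no3",
                    acceptor_uptake_max = 0, ngam = 0)
  sol <- solve_fba(apply_condition(m, cond))
  ## with zero NGAM the problem stays feasible but nothing can grow:
  ## biomass ATP demand cannot be met without respiration
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-8)
})

test_that("objective is monotone in the acceptor bound", {
  m <- make_toy_model()
  vals <- vapply(c(2, 5, 10, 30), function(acc) {
    cond <- condition("ac", "EX_ac", 10, "oxygen", "EX_o2", acc)
    solve_fba(apply_condition(m, cond))$objective_value
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
  ## and strictly increasing while the acceptor binds
  expect_gt(vals[2], vals[1])
})

test_that("infeasible constraint sets are reported, not silently zeroed", {
  m <- chain_model()
  ## force uptake (flux <= -5) but forbid catabolism
  m <- set_bounds(m, "EX_a", lower = -5, upper = -5)
  m <- set_bounds(m, "CAT", lower = 0, upper = 0)
  sol <- solve_fba(m)
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("FVA collapses to the FBA flux on a unique linear pathway", {
  m <- chain_model(atp_per_bio = 2)
  fv <- flux_variability(m)
  sol <- solve_fba(m)
  for (k in seq_len(nrow(fv))) {
    expect_equal(fv$min_flux[k], fv$max_flux[k], tolerance = 1e-7)
    expect_equal(fv$min_flux[k], sol$fluxes[[fv$reaction_id[k]]],
                 tolerance = 1e-7)
  }
})

test_that("two equivalent parallel routes each range over [0, total]", {
  m <- parallel_model()
  fv <- flux_variability(m)
  total <- attr(fv, "objective")
  expect_equal(total, 10, tolerance = 1e-8)
  for (id in c("R1", "R2")) {
    row <- fv[fv$reaction_id == id, ]
    expect_equal(row$min_flux, 0, tolerance = 1e-7)
    expect_equal(row$max_flux, total, tolerance = 1e-7)
  }
})

test_that("FBA flux lies inside every FVA range on the toy network", {
  m <- make_toy_model()
  bm <- apply_condition(m, toy_conditions()[["acetate-anaerobic"]])
  fv <- flux_variability(bm)
  sol <- attr(fv, "fba_fluxes")
  for (k in seq_len(nrow(fv))) {
    expect_gte(sol[[fv$reaction_id[k]]], fv$min_flux[k] - 1e-6)
    expect_lte(sol[[fv$reaction_id[k]]], fv$max_flux[k] + 1e-6)
  }
})

test_that("solver agrees with exhaustive vertex enumeration", {
  ## small random networks; the full 20-network sweep runs in the
  ## acceptance suite
  for (s in 1:6) {
    net <- random_flux_network(s)
    lp <- lp_solve(net$S, rep(0, nrow(net$S)), net$obj, net$lb, net$ub)
    or <- oracle_fba(net$S, net$lb, net$ub, net$obj)
    expect_equal(lp$status, "optimal")
    expect_equal(lp$obj, or$objective, tolerance = 1e-6)
  }
})

test_that("toy-network objectives match the enumeration oracle", {
  spec <- toy_network_spec(include_phb = FALSE, substrates = "acetate")
  m <- make_toy_model(spec)
  for (cond in toy_conditions(spec)) {
    bm <- apply_condition(m, cond)
    sol <- solve_fba(bm)
    or <- oracle_fba_model(bm)
    expect_equal(sol$objective_value, or$objective, tolerance = 1e-6,
                 label = cond$label)
  }
})

test_that("carbon yields behave at the extremes", {
  ## all carbon respired: biomass consumes no carbon
  none <- setNames(numeric(0), character(0))
  mets <- list(metabolite("a_e", compartment = "external",
                          formula = c(C = 1)),
               metabolite("a_c", formula = c(C = 1)),
               metabolite("atp", formula = none),
               metabolite("c_e", compartment = "external",
                          formula = c(C = 1)),
               metabolite("x_e", compartment = "external", formula = none))
  rxns <- list(
    reaction("EX_a", c(a_e = -1), lower_bound = -10, category = "boundary"),
    reaction("T_a", c(a_e = -1, a_c = 1), category = "transport"),
    reaction("RESP", c(a_c = -1, c_e = 1, atp = 1)),
    reaction("EX_c", c(c_e = -1), category = "boundary"),
    reaction("BIO", c(atp = -2, x_e = 1), category = "biomass"),
    reaction("EX_x", c(x_e = -1), category = "boundary"))
  m0 <- metabolic_model(mets, rxns, "BIO")
  sol0 <- solve_fba(m0)
  expect_equal(biomass_carbon_yield(sol0, m0), 0, tolerance = 1e-9)

  ## substrate assimilated 1:1 with no respiration: 100%
  m1 <- tiny_model()
  expect_equal(biomass_carbon_yield(solve_fba(m1), m1), 100,
               tolerance = 1e-9)
})

test_that("a second open carbon source demands an explicit source list", {
  spec <- toy_network_spec()
  m <- make_toy_model(spec)
  cond <- toy_conditions(spec)[["acetate-aerobic"]]
  bm <- apply_condition(m, cond)
  bm <- set_bounds(bm, "EX_bz", lower = -5)    # open a second source
  sol <- solve_fba(bm)
  expect_error(biomass_carbon_yield(sol, bm), "carbon_sources")
  y <- biomass_carbon_yield(sol, bm, carbon_sources = c("EX_ac", "EX_bz"))
  expect_true(y > 0 && y <= 100)
})
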