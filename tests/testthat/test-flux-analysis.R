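test_that("split ratios: single producer/consumer node is 100/100", {
  m <- chain_model(atp_per_bio = 2)
  sol <- solve_fba(m)
  sr <- split_ratios(m, sol, "a_c")
  expect_equal(nrow(sr$producers), 1)
  expect_equal(sr$producers$fraction, 100)
  expect_equal(sr$consumers$fraction, 100)
  expect_equal(sr$turnover, 10, tolerance = 1e-8)
})

test_that("split ratios partition 3:1 producers as 75/25", {
  none <- setNames(numeric(0), character(0))
  mets <- list(metabolite("s_e", compartment = "external",
                          formula = c(C = 1)),
               metabolite("p_c", formula = c(C = 1)),
               metabolite("x_e", compartment = "external", formula = none))
  rxns <- list(
    reaction("EX_s", c(s_e = -1), lower_bound = -4, category = "boundary"),
    reaction("MK3", c(s_e = -3, p_c = 3), upper_bound = 1),  # makes 3
    reaction("MK1", c(s_e = -1, p_c = 1), upper_bound = 1),  # makes 1
    reaction("BIO", c(p_c = -1, x_e = 1), category = "biomass"),
    reaction("EX_x", c(x_e = -1), category = "boundary"))
  m <- metabolic_model(mets, rxns, "BIO")
  sol <- solve_fba(m)
  sr <- split_ratios(m, sol, "p_c")
  expect_equal(sr$producers$fraction[sr$producers$reaction_id == "MK3"], 75,
               tolerance = 1e-8)
  expect_equal(sr$producers$fraction[sr$producers$reaction_id == "MK1"], 25,
               tolerance = 1e-8)
})

test_that("zero turnover yields an empty table, not a division error", {
  m <- make_toy_model(toy_network_spec(include_phb = TRUE))
  bm <- apply_condition(m, toy_conditions()[["acetate-aerobic"]])
  sol <- solve_fba(bm)
  sr <- split_ratios(m, sol, "phb_c")      # storage unused at optimum
  expect_equal(sr$turnover, 0)
  expect_equal(nrow(sr$producers), 0)
})

test_that("production equals consumption at every internal metabolite", {
  m <- make_toy_model()
  for (cond in toy_conditions()) {
    sol <- solve_fba(apply_condition(m, cond))
    for (met in m$metabolites) {
      if (met$compartment == "external") next
      sr <- split_ratios(m, sol, met$id)
      expect_equal(sum(sr$producers$flux), sum(sr$consumers$flux),
                   tolerance = 1e-6,
                   label = paste(cond$label, met$id))
      if (sr$turnover > 0) {
        expect_equal(sum(sr$producers$fraction), 100, tolerance = 1e-6)
        expect_equal(sum(sr$consumers$fraction), 100, tolerance = 1e-6)
      }
    }
  }
})

test_that("reversible reactions contribute by flux sign, not declared direction", {
  none <- setNames(numeric(0), character(0))
  mets <- list(metabolite("s_e", compartment = "external",
                          formula = c(C = 1)),
               metabolite("p_c", formula = c(C = 1)),
               metabolite("x_e", compartment = "external", formula = none))
  ## REV is declared p_c -> s_e but will run backwards (uptake)
  rxns <- list(
    reaction("EX_s", c(s_e = -1), lower_bound = -5, category = "boundary"),
    reaction("REV", c(p_c = -1, s_e = 1), lower_bound = -1000),
    reaction("BIO", c(p_c = -1, x_e = 1), category = "biomass"),
    reaction("EX_x", c(x_e = -1), category = "boundary"))
  m <- metabolic_model(mets, rxns, "BIO")
  sol <- solve_fba(m)
  sr <- split_ratios(m, sol, "p_c")
  expect_equal(sr$producers$reaction_id, "REV")
  expect_equal(sr$consumers$reaction_id, "BIO")
})

test_that("activity table: zero ranges are never active, biomass always is", {
  m <- make_toy_model()
  ranges <- lapply(toy_conditions(), function(cond)
    flux_variability(apply_condition(m, cond)))
  act <- activity_table(ranges)
  expect_false(any(act$active["EX_phb", ]))   # storage never pays off
  expect_true(all(act$active["BIOMASS", ]))
  expect_true(act$always_active[["BIOMASS"]])
  ## acceptor-specific chains are planted truths of the generator
  expect_equal(unname(act$active["NAR", ]),
               grepl("anaerobic", colnames(act$active)))
  expect_equal(unname(act$active["COX", ]),
               grepl("-aerobic", colnames(act$active)))
  expect_equal(act$n_always_active, sum(act$always_active))
})

test_that("activity table is invariant to reaction reordering", {
  m <- make_toy_model()
  conds <- toy_conditions()[1:2]
  ranges <- lapply(conds, function(cond)
    flux_variability(apply_condition(m, cond)))
  act1 <- activity_table(ranges)
  ranges2 <- lapply(ranges, function(rg) rg[rev(seq_len(nrow(rg))), ])
  act2 <- activity_table(ranges2)
  ids <- rownames(act1$active)
  expect_equal(act2$active[ids, ], act1$active[ids, ])
  expect_equal(act2$n_always_active, act1$n_always_active)
})

test_that("mismatched reaction sets are reported with their difference", {
  m <- make_toy_model()
  conds <- toy_conditions()[1:2]
  ranges <- lapply(conds, function(cond)
    flux_variability(apply_condition(m, cond)))
  ranges[[2]] <- ranges[[2]][-1, ]
  expect_error(activity_table(ranges), ranges[[1]]$reaction_id[1])
})

test_that("flux variation shares follow the planted arithmetic", {
  fm <- rbind(r1 = c(0, 8), r2 = c(1, 3), r3 = c(5, 5))
  colnames(fm) <- c("c1", "c2")
  sh <- flux_variation_shares(fm, list(big = "r1", small = "r2"))
  expect_equal(unname(sh["big"]), 0.8)
  expect_equal(unname(sh["small"]), 0.2)
  ## one varying reaction grouped alone takes 100%
  fm2 <- rbind(r1 = c(0, 4), r2 = c(2, 2))
  colnames(fm2) <- c("c1", "c2")
  expect_equal(unname(flux_variation_shares(fm2, list(g = "r1"))["g"]), 1)
  ## overlap is an error
  expect_error(flux_variation_shares(fm, list(a = "r1", b = c("r1", "r2"))),
               "overlap")
  ## all-constant matrix: undefined, flagged
  fm3 <- rbind(r1 = c(1, 1), r2 = c(2, 2))
  colnames(fm3) <- c("c1", "c2")
  sh3 <- flux_variation_shares(fm3, list(g = "r1"))
  expect_true(all(is.na(sh3)))
  expect_true(attr(sh3, "undefined"))
})

test_that("clustering: identical conditions merge at height zero", {
  fm <- cbind(c1 = c(1, 2, 3), c2 = c(1, 2, 3), c3 = c(9, 9, 9))
  rownames(fm) <- paste0("r", 1:3)
  cl <- cluster_conditions(fm)
  expect_equal(min(cl$merge_heights), 0)
  expect_equal(cl$cut2[["c1"]], cl$cut2[["c2"]])
  expect_false(cl$cut2[["c1"]] == cl$cut2[["c3"]])
})

test_that("clustering recovers planted block structure and is permutation-stable", {
  set.seed(42)
  block1 <- matrix(rnorm(20, mean = 5), 10, 2)
  block2 <- matrix(rnorm(20, mean = -5), 10, 2)
  fm <- cbind(block1, block2) + matrix(rnorm(40, sd = 0.1), 10, 4)
  colnames(fm) <- c("a1", "a2", "b1", "b2")
  rownames(fm) <- paste0("r", 1:10)
  cl <- cluster_conditions(fm)
  expect_equal(cl$cut2[["a1"]], cl$cut2[["a2"]])
  expect_equal(cl$cut2[["b1"]], cl$cut2[["b2"]])
  expect_false(cl$cut2[["a1"]] == cl$cut2[["b1"]])
  ## permuting columns leaves the partition unchanged
  perm <- c(3, 1, 4, 2)
  cl2 <- cluster_conditions(fm[, perm])
  for (cc in colnames(fm)) {
    same1 <- cl$cut2[[cc]] == cl$cut2[["a1"]]
    same2 <- cl2$cut2[[cc]] == cl2$cut2[["a1"]]
    expect_equal(same1, same2)
  }
})

test_that("clustering separates oxic from anoxic toy conditions", {
  m <- make_toy_model()
  conds <- toy_conditions()
  sols <- lapply(conds, function(cond)
    solve_fba(apply_condition(m, cond)))
  fm <- vapply(sols, function(s) s$fluxes, numeric(length(m$reactions)))
  rownames(fm) <- reaction_ids(m)
  uptC <- vapply(names(conds), function(lab)
    if (grepl("acetate", lab)) 10 * 2 else 5 * 7, numeric(1))
  cl <- cluster_conditions(fm, scale_by = uptC)
  anox <- grepl("anaerobic", names(conds))
  expect_equal(length(unique(cl$cut2[anox])), 1)
  expect_equal(length(unique(cl$cut2[!anox])), 1)
  expect_false(cl$cut2[anox][1] == cl$cut2[!anox][1])
})

test_that("non-finite fluxes are rejected by name", {
  fm <- cbind(c1 = c(1, NA), c2 = c(1, 2))
  rownames(fm) <- c("ra", "rb")
  expect_error(cluster_conditions(fm), "rb")
})
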