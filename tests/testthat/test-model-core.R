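test_that("a three-reaction model validates and counts its records", {
  m <- tiny_model()
  s <- model_summary(m)
  expect_equal(s$n_reactions_total, 4)
  expect_equal(s$n_metabolites, 3)
  expect_equal(unname(s$by_category[c("boundary", "transport", "biomass")]),
               c(2L, 1L, 1L))
  expect_equal(sum(s$by_category), s$n_reactions_total)
})

test_that("undeclared metabolite references are a validation error", {
  mets <- list(metabolite("a_e", compartment = "external"),
               metabolite("x_e", compartment = "external"))
  rxns <- list(reaction("EX_a", c(a_e = -1), category = "boundary"),
               reaction("R", c(a_e = -1, ghost = 1)),
               reaction("BIO", c(a_e = -1, x_e = 1), category = "biomass"))
  expect_error(metabolic_model(mets, rxns, "BIO"), "ghost")
})

test_that("duplicate ids and bad objectives are rejected", {
  mets <- list(metabolite("a_e", compartment = "external"),
               metabolite("a_e", compartment = "external"))
  expect_error(metabolic_model(mets, list(reaction("B", c(a_e = 1),
                                                   category = "biomass")),
                               "B"), "duplicate metabolite")
  m <- tiny_model()
  m2 <- m; m2$objective_id <- "T_a"
  expect_error(validate_model(m2), "biomass")
  m3 <- m; m3$objective_id <- "nope"
  expect_error(validate_model(m3), "not in model")
})

test_that("boundary reactions must touch exactly one external metabolite", {
  mets <- list(metabolite("a_e", compartment = "external"),
               metabolite("b_c"),
               metabolite("x_e", compartment = "external"))
  bad2 <- list(reaction("EX", c(a_e = -1, b_c = 1), category = "boundary"),
               reaction("BIO", c(b_c = -1, x_e = 1), category = "biomass"))
  expect_error(metabolic_model(mets, bad2, "BIO"), "exactly one")
  badint <- list(reaction("EX", c(b_c = -1), category = "boundary"),
                 reaction("BIO", c(b_c = -1, x_e = 1), category = "biomass"))
  expect_error(metabolic_model(mets, badint, "BIO"), "external")
})

test_that("enzyme-catalyzed counting follows the category/gene rule", {
  none <- setNames(numeric(0), character(0))
  mets <- list(metabolite("a_e", compartment = "external"),
               metabolite("a_c"), metabolite("x_e",
               compartment = "external", formula = none))
  rxns <- list(
    reaction("EX_a", c(a_e = -1), category = "boundary"),
    reaction("T1", c(a_e = -1, a_c = 1), category = "transport",
             gene_association = "g1"),          # counts
    reaction("T2", c(a_c = -1, a_e = 1), category = "transport"),  # not
    reaction("ENZ", c(a_c = -1, x_e = 1), category = "enzymatic"), # counts
    reaction("NG", c(a_c = -1), category = "maintenance"),         # not
    reaction("BIO", c(a_c = -1, x_e = 1), category = "biomass")    # not
  )
  m <- metabolic_model(mets, rxns, "BIO")
  expect_equal(model_summary(m)$n_enzyme_catalyzed, 2)
})

test_that("model_summary totals are invariant under reaction reordering", {
  m <- make_toy_model()
  s1 <- model_summary(m)
  set.seed(7)
  m2 <- m
  m2$reactions <- m$reactions[sample(length(m$reactions))]
  s2 <- model_summary(m2)
  expect_equal(s1$by_category, s2$by_category)
  expect_equal(s1$n_enzyme_catalyzed, s2$n_enzyme_catalyzed)
})

test_that("mass balance flags exactly the planted imbalance", {
  mets <- list(metabolite("a_c", formula = c(C = 2, H = 4, O = 2)),
               metabolite("b_c", formula = c(C = 2, H = 4, O = 2)),
               metabolite("x_e", compartment = "external",
                          formula = setNames(numeric(0), character(0))))
  rxns <- list(reaction("ISO", c(a_c = -1, b_c = 1)),
               reaction("BIO", c(b_c = -1, x_e = 1), category = "biomass"))
  m <- metabolic_model(mets, rxns, "BIO")
  expect_equal(nrow(check_mass_balance(m, c("C", "H", "O"))), 0)

  ## shrink the product to C1: one C imbalance of -1
  m$metabolites[[2]]$formula <- c(C = 1, H = 4, O = 2)
  rep_ <- check_mass_balance(m, "C")
  expect_equal(nrow(rep_), 1)
  expect_equal(rep_$reaction_id, "ISO")
  expect_equal(rep_$net, -1)
})

test_that("corrupting one toy-network coefficient yields exactly one report entry", {
  m <- make_toy_model()
  expect_equal(nrow(check_mass_balance(m, "C")), 0)
  i <- match("TCA", reaction_ids(m))
  m$reactions[[i]]$stoichiometry["co2_c"] <-
    m$reactions[[i]]$stoichiometry["co2_c"] + 1
  rep_ <- check_mass_balance(m, "C")
  expect_equal(nrow(rep_), 1)
  expect_equal(rep_$reaction_id, "TCA")
  expect_equal(rep_$net, 1)
})

test_that("reactions with unknown formulas are unchecked, not balanced", {
  mets <- list(metabolite("u_c"),                     # formula NULL
               metabolite("b_c", formula = c(C = 1)),
               metabolite("x_e", compartment = "external",
                          formula = setNames(numeric(0), character(0))))
  rxns <- list(reaction("R", c(u_c = -1, b_c = 1)),
               reaction("BIO", c(b_c = -1, x_e = 1), category = "biomass"))
  m <- metabolic_model(mets, rxns, "BIO")
  rep_ <- check_mass_balance(m, "C")
  expect_equal(nrow(rep_), 0)
  expect_equal(attr(rep_, "unchecked"), "R")
})

test_that("unsupported element symbols are skipped with a warning", {
  m <- tiny_model()
  expect_warning(check_mass_balance(m, c("C", "Xx")), "Xx")
})

test_that("the stoichiometric matrix reproduces every coefficient", {
  m <- make_toy_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(length(m$metabolites), length(m$reactions)))
  ## round trip: rebuild each reaction's stoichiometry from its column
  for (k in seq_along(m$reactions)) {
    col <- S[, k]
    rebuilt <- col[col != 0]
    orig <- m$reactions[[k]]$stoichiometry
    expect_equal(rebuilt[sort(names(rebuilt))], orig[sort(names(orig))])
  }
  ## a simple conversion column: -1 at substrate, +1 at product
  m2 <- tiny_model()
  S2 <- stoichiometric_matrix(m2)
  expect_equal(unname(S2["a_e", "T_a"]), -1)
  expect_equal(unname(S2["a_c", "T_a"]), 1)
})
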