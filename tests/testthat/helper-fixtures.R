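## Small fixtures built in code.

## minimal three-reaction model: uptake -> conversion -> biomass drain
tiny_model <- function() {
  mets <- list(
    metabolite("a_e", compartment = "external", formula = c(C = 1)),
    metabolite("a_c", formula = c(C = 1)),
    metabolite("x_e", compartment = "external",
               formula = setNames(numeric(0), character(0)))
  )
  rxns <- list(
    reaction("EX_a", c(a_e = -1), lower_bound = -10, category = "boundary"),
    reaction("T_a", c(a_e = -1, a_c = 1), category = "transport",
             gene_association = "g1"),
    reaction("BIO", c(a_c = -1, x_e = 1), category = "biomass"),
    reaction("EX_x", c(x_e = -1), category = "boundary")
  )
  metabolic_model(mets, rxns, objective_id = "BIO")
}

## linear chain with explicit ATP accounting:
## uptake A (<= 10), A -> ATP (1:1), biomass consumes `atp_per_bio` ATP,
## optional NGAM drain
chain_model <- function(atp_per_bio = 2, with_ngam = FALSE) {
  none <- setNames(numeric(0), character(0))
  mets <- list(
    metabolite("a_e", compartment = "external", formula = c(C = 1)),
    metabolite("a_c", formula = c(C = 1)),
    metabolite("atp", formula = none),
    metabolite("x_e", compartment = "external", formula = none)
  )
  rxns <- list(
    reaction("EX_a", c(a_e = -1), lower_bound = -10, category = "boundary"),
    reaction("T_a", c(a_e = -1, a_c = 1), category = "transport"),
    reaction("CAT", c(a_c = -1, atp = 1), category = "enzymatic"),
    reaction("BIO", setNames(c(-atp_per_bio, 1), c("atp", "x_e")),
             category = "biomass"),
    reaction("EX_x", c(x_e = -1), category = "boundary")
  )
  if (with_ngam)
    rxns[[length(rxns) + 1L]] <- reaction("NGAM", c(atp = -1),
                                          lower_bound = 2, upper_bound = 2,
                                          category = "maintenance")
  metabolic_model(mets, rxns, objective_id = "BIO")
}

## two equivalent parallel routes from A to B
parallel_model <- function() {
  mets <- list(
    metabolite("a_e", compartment = "external", formula = c(C = 1)),
    metabolite("a_c", formula = c(C = 1)),
    metabolite("b_c", formula = c(C = 1)),
    metabolite("x_e", compartment = "external",
               formula = setNames(numeric(0), character(0)))
  )
  rxns <- list(
    reaction("EX_a", c(a_e = -1), lower_bound = -10, category = "boundary"),
    reaction("T_a", c(a_e = -1, a_c = 1), category = "transport"),
    reaction("R1", c(a_c = -1, b_c = 1)),
    reaction("R2", c(a_c = -1, b_c = 1)),
    reaction("BIO", c(b_c = -1, x_e = 1), category = "biomass"),
    reaction("EX_x", c(x_e = -1), category = "boundary")
  )
  metabolic_model(mets, rxns, objective_id = "BIO")
}

## oracle FBA/FVA by exhaustive vertex enumeration on a raw LP description
oracle_fba <- function(S, lb, ub, obj) {
  V <- enumerate_vertices(S, lb, ub)
  stopifnot(nrow(V) > 0)
  vals <- as.vector(V %*% obj)
  opt <- max(vals)
  face <- V[vals >= opt - 1e-9, , drop = FALSE]
  list(objective = opt,
       min_flux = apply(face, 2, min),
       max_flux = apply(face, 2, max))
}

## oracle applied to a (bounded) metabolic model
oracle_fba_model <- function(model) {
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  obj <- as.numeric(reaction_ids(model) == model$objective_id)
  out <- oracle_fba(S, lb, ub, obj)
  names(out$min_flux) <- names(out$max_flux) <- reaction_ids(model)
  out
}
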