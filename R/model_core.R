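## Stoichiometric metabolic model: data structures and validation.
##
## A model is a plain list with class "metabolic_model":
##   $metabolites  list of metabolite records (id, name, compartment,
##                 formula = named integer vector or NULL, charge)
##   $reactions    list of reaction records (id, name, stoichiometry = named
##                 numeric vector keyed by metabolite id, lower_bound,
##                 upper_bound, gene_association = character vector,
##                 category)
##   $objective_id id of the biomass reaction to maximize
##   $metadata     free-form named list (name, source, ...)
##
## Flux units are mmol gDW^-1 h^-1 throughout; the biomass reaction flux is
## in h^-1 (growth rate) by the usual 1 g biomass per unit flux convention.

REACTION_CATEGORIES <- c("enzymatic", "transport", "boundary", "biomass",
                         "maintenance", "definition")
COMPARTMENTS <- c("cytoplasm", "periplasm", "external")

## element symbols accepted by the balance checker
BALANCE_ELEMENTS <- c("C", "H", "N", "O", "P", "S", "Fe", "Mg", "Co")

#' Create a metabolite record
#'
#' @param id Short unique identifier.
#' @param name Human-readable name.
#' @param compartment One of `"cytoplasm"`, `"periplasm"`, `"external"`.
#' @param formula Named integer vector of element counts (e.g.
#'   `c(C = 2, H = 3, O = 2)`). `NULL` means the composition is unknown
#'   (balance checks involving the metabolite are reported as unchecked);
#'   a length-zero numeric declares the metabolite element-free by design
#'   (pseudo-metabolites such as a proton-motive charge carrier), which is
#'   checked and contributes zero atoms.
#' @param charge Integer net charge (default 0).
#' @return A list of class `"metabolite"`.
#' @export
metabolite <- function(id, name = id, compartment = "cytoplasm",
                       formula = NULL, charge = 0L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  compartment <- match.arg(compartment, COMPARTMENTS)
  if (!is.null(formula) && length(formula) > 0L) {
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      stop("metabolite '", id, "': formula must be a named vector", call. = FALSE)
    if (any(formula < 0))
      stop("metabolite '", id, "': negative element count", call. = FALSE)
    formula <- formula[formula > 0]
  }
  if (!is.null(formula)) formula <- stats::setNames(as.numeric(formula), names(formula))
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula, charge = as.integer(charge)),
            class = "metabolite")
}

#' Create a reaction record
#'
#' Stoichiometric coefficients are signed: negative for consumed
#' metabolites, positive for produced ones.
#'
#' @param id Short unique identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param name Human-readable name.
#' @param lower_bound,upper_bound Flux bounds in mmol gDW^-1 h^-1
#'   (h^-1 for the biomass reaction). Defaults are the conventional
#'   irreversible bounds (0, 1000); pass `lower_bound = -1000` for a
#'   reversible reaction.
#' @param gene_association Character vector of locus tags (may be empty).
#' @param category One of `r paste(REACTION_CATEGORIES, collapse = ", ")`.
#' @return A list of class `"reaction"`.
#' @export
reaction <- function(id, stoichiometry, name = id,
                     lower_bound = 0, upper_bound = 1000,
                     gene_association = character(),
                     category = "enzymatic") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  category <- match.arg(category, REACTION_CATEGORIES)
  if (length(stoichiometry) == 0L)
    stop("reaction '", id, "': empty stoichiometry", call. = FALSE)
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("reaction '", id, "': stoichiometry must be named by metabolite id",
         call. = FALSE)
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction '", id, "': duplicated metabolite in stoichiometry",
         call. = FALSE)
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound", call. = FALSE)
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gene_association = as.character(gene_association),
                 category = category),
            class = "reaction")
}

#' Assemble and validate a metabolic model
#'
#' @param metabolites List of [metabolite()] records.
#' @param reactions List of [reaction()] records.
#' @param objective_id Id of the biomass reaction used as FBA objective.
#' @param metadata Named list of free-form metadata.
#' @return A validated list of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions, objective_id,
                            metadata = list()) {
  model <- structure(list(metabolites = metabolites, reactions = reactions,
                          objective_id = objective_id, metadata = metadata),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate model invariants
#'
#' Checks id uniqueness, resolution of every stoichiometry reference,
#' bound ordering, the boundary-reaction contract (exactly one metabolite,
#' which must be external), and that the objective exists and is a biomass
#' reaction. Invisibly returns the model; stops with a descriptive error
#' otherwise.
#'
#' @param model A `"metabolic_model"`.
#' @export
validate_model <- function(model) {
  met_ids <- vapply(model$metabolites, `[[`, "", "id")
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite id(s): ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  comp <- vapply(model$metabolites, `[[`, "", "compartment")
  names(comp) <- met_ids
  for (rxn in model$reactions) {
    unknown <- setdiff(names(rxn$stoichiometry), met_ids)
    if (length(unknown))
      stop("reaction '", rxn$id, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (rxn$lower_bound > rxn$upper_bound)
      stop("reaction '", rxn$id, "': lower_bound > upper_bound", call. = FALSE)
    if (rxn$category == "boundary") {
      if (length(rxn$stoichiometry) != 1L)
        stop("boundary reaction '", rxn$id,
             "' must touch exactly one metabolite", call. = FALSE)
      if (comp[names(rxn$stoichiometry)] != "external")
        stop("boundary reaction '", rxn$id,
             "' must touch an external metabolite", call. = FALSE)
    }
  }
  if (!model$objective_id %in% rxn_ids)
    stop("objective reaction '", model$objective_id, "' not in model",
         call. = FALSE)
  obj <- model$reactions[[match(model$objective_id, rxn_ids)]]
  if (obj$category != "biomass")
    stop("objective reaction '", model$objective_id,
         "' must have category 'biomass', has '", obj$category, "'",
         call. = FALSE)
  invisible(model)
}

#' Metabolite and reaction identifiers in declared order
#'
#' @param model A `"metabolic_model"`.
#' @return Character vector of ids.
#' @export
metabolite_ids <- function(model) vapply(model$metabolites, `[[`, "", "id")

#' @rdname metabolite_ids
#' @export
reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

get_reaction <- function(model, id) {
  i <- match(id, reaction_ids(model))
  if (is.na(i)) stop("no reaction '", id, "' in model", call. = FALSE)
  model$reactions[[i]]
}

get_metabolite <- function(model, id) {
  i <- match(id, metabolite_ids(model))
  if (is.na(i)) stop("no metabolite '", id, "' in model", call. = FALSE)
  model$metabolites[[i]]
}

set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- match(id, reaction_ids(model))
  if (is.na(i)) stop("no reaction '", id, "' in model", call. = FALSE)
  if (!is.null(lower)) model$reactions[[i]]$lower_bound <- lower
  if (!is.null(upper)) model$reactions[[i]]$upper_bound <- upper
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model", if (!is.null(x$metadata$name)) x$metadata$name else "",
      "\n  metabolites:", length(x$metabolites),
      "\n  reactions:  ", length(x$reactions),
      "\n  objective:  ", x$objective_id, "\n")
  invisible(x)
}

#' Per-category reaction counts
#'
#' Tabulates the model by reaction category and counts enzyme-catalyzed
#' functions. A reaction counts as enzyme-catalyzed iff its category is
#' `enzymatic`, or `transport` with a non-empty gene association; boundary,
#' biomass, maintenance and definition reactions never count.
#'
#' @param model A `"metabolic_model"`.
#' @return A list with `n_reactions_total`, `n_metabolites`, `by_category`
#'   (named integer vector over all categories) and `n_enzyme_catalyzed`.
#' @export
model_summary <- function(model) {
  validate_model(model)
  cats <- vapply(model$reactions, `[[`, "", "category")
  by_cat <- table(factor(cats, levels = REACTION_CATEGORIES))
  ngenes <- vapply(model$reactions,
                   function(r) length(r$gene_association) > 0L, logical(1))
  n_enz <- sum(cats == "enzymatic" | (cats == "transport" & ngenes))
  list(n_reactions_total = length(model$reactions),
       n_metabolites = length(model$metabolites),
       by_category = c(by_cat),
       n_enzyme_catalyzed = n_enz)
}

#' Elemental mass-balance check
#'
#' Verifies element conservation for every enzymatic, transport and
#' maintenance reaction (boundary, biomass and definition reactions
#' exchange matter with the environment or lump polymerization and are
#' exempt). A reaction whose metabolites lack a formula for a requested
#' element cannot be judged and is listed as unchecked rather than balanced.
#'
#' @param model A `"metabolic_model"`.
#' @param elements Character vector of element symbols; symbols outside the
#'   supported set (`r paste(BALANCE_ELEMENTS, collapse = ", ")`) are dropped
#'   with a warning.
#' @return A data.frame with columns `reaction_id`, `element`, `net` listing
#'   every imbalance (empty when all checked reactions conserve all requested
#'   elements), with attribute `"unchecked"` naming reactions that could not
#'   be checked.
#' @export
check_mass_balance <- function(model, elements = "C") {
  validate_model(model)
  bad <- setdiff(elements, BALANCE_ELEMENTS)
  if (length(bad)) {
    warning("unsupported element symbol(s) skipped: ",
            paste(bad, collapse = ", "))
    elements <- intersect(elements, BALANCE_ELEMENTS)
  }
  formulas <- lapply(model$metabolites, `[[`, "formula")
  names(formulas) <- metabolite_ids(model)
  has_formula <- !vapply(formulas, is.null, logical(1))
  rows <- list()
  unchecked <- character()
  for (rxn in model$reactions) {
    if (rxn$category %in% c("boundary", "biomass", "definition")) next
    mets <- names(rxn$stoichiometry)
    if (any(!has_formula[mets])) {
      unchecked <- c(unchecked, rxn$id)
      next
    }
    for (el in elements) {
      counts <- vapply(mets, function(m) {
        f <- formulas[[m]]
        if (is.null(f) || is.na(f[el])) 0 else unname(f[el])
      }, numeric(1))
      net <- sum(rxn$stoichiometry * counts)
      if (abs(net) > 1e-9)
        rows[[length(rows) + 1L]] <- data.frame(reaction_id = rxn$id,
                                                element = el, net = net)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_id = character(), element = character(),
               net = numeric())
  attr(out, "unchecked") <- unchecked
  out
}

#' Electron (degree-of-reduction) balance check
#'
#' Sums `coefficient * degree_of_reduction(metabolite)` over every
#' enzymatic, transport and maintenance reaction. A fully element- and
#' charge-balanced redox reaction nets zero; electron carriers modelled as
#' pseudo-metabolites must carry the transferred electrons in their formula
#' (e.g. an `H2` formula for a reduced carrier) for the ledger to close.
#'
#' @param model A `"metabolic_model"`.
#' @return data.frame with `reaction_id` and `net_electrons` per imbalance.
#' @export
check_electron_balance <- function(model) {
  validate_model(model)
  gam <- vapply(model$metabolites, function(m) {
    if (is.null(m$formula) || length(m$formula) == 0L) 0
    else degree_of_reduction(m$formula, m$charge)
  }, numeric(1))
  names(gam) <- metabolite_ids(model)
  rows <- list()
  for (rxn in model$reactions) {
    if (rxn$category %in% c("boundary", "biomass", "definition")) next
    net <- sum(rxn$stoichiometry * gam[names(rxn$stoichiometry)])
    if (abs(net) > 1e-9)
      rows[[length(rows) + 1L]] <- data.frame(reaction_id = rxn$id,
                                              net_electrons = net)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_id = character(), net_electrons = numeric())
}

#' Stoichiometric matrix
#'
#' @param model A `"metabolic_model"`.
#' @return Sparse matrix (class `dgCMatrix`) with one row per metabolite and
#'   one column per reaction, in declared order; entry (i, j) is the signed
#'   coefficient of metabolite i in reaction j.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- metabolite_ids(model)
  rxn_ids <- reaction_ids(model)
  i <- integer(); j <- integer(); x <- numeric()
  for (k in seq_along(model$reactions)) {
    st <- model$reactions[[k]]$stoichiometry
    i <- c(i, match(names(st), met_ids))
    j <- c(j, rep(k, length(st)))
    x <- c(x, unname(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}
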