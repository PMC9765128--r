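## Condition setup and flux balance analysis.

## default maintenance energies, taken from the E. coli K-12 tradition of
## genome-scale models; both are plain configuration values surfaced in
## every condition object and report.
DEFAULT_NGAM <- 8.39    # mmol ATP gDW^-1 h^-1, non-growth-associated
DEFAULT_GAM <- 59.81    # mmol ATP gDW^-1, growth-associated (in biomass rxn)

## reporting threshold below which a flux is considered zero
FLUX_EPS <- 1e-6

#' Define a growth condition
#'
#' A condition fixes the carbon source, the terminal electron acceptor
#' (nitrate for denitrifying growth or molecular oxygen for aerobic
#' respiration) and the maintenance demand. Exactly one acceptor exchange
#' is open; [apply_condition()] closes the other one.
#'
#' @param label Condition name, e.g. `"acetate-anaerobic"`.
#' @param substrate_exchange Boundary reaction id of the carbon source.
#' @param substrate_uptake_max Maximal uptake, mmol gDW^-1 h^-1 (>= 0).
#' @param acceptor `"nitrate"` or `"oxygen"`.
#' @param acceptor_exchange Boundary reaction id of the selected acceptor.
#' @param acceptor_uptake_max Maximal acceptor uptake, mmol gDW^-1 h^-1.
#' @param ngam Non-growth-associated ATP maintenance, mmol gDW^-1 h^-1.
#' @param gam Growth-associated ATP maintenance embedded in the biomass
#'   reaction, mmol gDW^-1 (carried for reporting; the biomass reaction
#'   itself encodes it).
#' @return A list of class `"fba_condition"`.
#' @export
condition <- function(label, substrate_exchange, substrate_uptake_max,
                      acceptor = c("nitrate", "oxygen"),
                      acceptor_exchange, acceptor_uptake_max,
                      ngam = DEFAULT_NGAM, gam = DEFAULT_GAM) {
  acceptor <- match.arg(acceptor)
  stopifnot(substrate_uptake_max >= 0, acceptor_uptake_max >= 0, ngam >= 0)
  structure(list(label = label,
                 substrate_exchange = substrate_exchange,
                 substrate_uptake_max = substrate_uptake_max,
                 acceptor = acceptor,
                 acceptor_exchange = acceptor_exchange,
                 acceptor_uptake_max = acceptor_uptake_max,
                 ngam = ngam, gam = gam),
            class = "fba_condition")
}

#' Locate acceptor exchange reactions by metabolite formula
#'
#' Scans boundary reactions for the one whose single metabolite is nitrate
#' (NO3) and the one whose metabolite is molecular oxygen (O2).
#'
#' @param model A `"metabolic_model"`.
#' @return Named list with elements `nitrate` and `oxygen` (reaction id or
#'   `NA` when the model has no such exchange).
#' @export
detect_acceptor_exchanges <- function(model) {
  out <- list(nitrate = NA_character_, oxygen = NA_character_)
  for (rxn in model$reactions) {
    if (rxn$category != "boundary") next
    met <- get_metabolite(model, names(rxn$stoichiometry))
    f <- met$formula
    if (is.null(f)) next
    f <- f[f > 0]
    if (setequal(names(f), c("N", "O")) && f["N"] == 1 && f["O"] == 3)
      out$nitrate <- rxn$id
    if (identical(names(f), "O") && f["O"] == 2)
      out$oxygen <- rxn$id
  }
  out
}

#' Bound a model for a growth condition
#'
#' Returns a copy of the model with the substrate exchange opened to the
#' uptake limit (lower bound `-substrate_uptake_max`), the selected
#' acceptor exchange opened to `-acceptor_uptake_max`, the non-selected
#' acceptor exchange closed to (0, 0), and the maintenance reaction fixed
#' at the condition's NGAM.
#'
#' @param model A `"metabolic_model"`.
#' @param cond An [condition()] object.
#' @param other_acceptor_exchange Id of the exchange to close; by default
#'   detected from metabolite formulas via [detect_acceptor_exchanges()].
#' @return A bounded `"metabolic_model"` copy with the condition attached
#'   as attribute `"condition"`.
#' @export
apply_condition <- function(model, cond, other_acceptor_exchange = NULL) {
  stopifnot(inherits(cond, "fba_condition"))
  rids <- reaction_ids(model)
  for (id in c(cond$substrate_exchange, cond$acceptor_exchange))
    if (!id %in% rids)
      stop("condition '", cond$label, "': exchange reaction '", id,
           "' not in model", call. = FALSE)
  model <- set_bounds(model, cond$substrate_exchange,
                      lower = -cond$substrate_uptake_max)
  model <- set_bounds(model, cond$acceptor_exchange,
                      lower = -cond$acceptor_uptake_max)
  if (is.null(other_acceptor_exchange)) {
    acc <- detect_acceptor_exchanges(model)
    other <- if (cond$acceptor == "nitrate") acc$oxygen else acc$nitrate
  } else other <- other_acceptor_exchange
  if (!is.null(other) && !is.na(other) && other != cond$acceptor_exchange) {
    if (!other %in% rids)
      stop("condition '", cond$label, "': exchange reaction '", other,
           "' not in model", call. = FALSE)
    model <- set_bounds(model, other, lower = 0, upper = 0)
  }
  ## anaerobic enzymes flagged as oxygen-sensitive (e.g. class I ring
  ## reductases) are shut off when the acceptor is oxygen
  if (cond$acceptor == "oxygen" &&
      !is.null(model$metadata$oxygen_sensitive)) {
    for (id in intersect(unlist(model$metadata$oxygen_sensitive), rids))
      model <- set_bounds(model, id, lower = 0, upper = 0)
  }
  cats <- vapply(model$reactions, `[[`, "", "category")
  if (any(cats == "maintenance")) {
    ngam_id <- rids[cats == "maintenance"][1]
    model <- set_bounds(model, ngam_id, lower = cond$ngam, upper = cond$ngam)
  } else if (cond$ngam > 0) {
    stop("condition '", cond$label, "' requires NGAM ", cond$ngam,
         " but the model has no maintenance reaction", call. = FALSE)
  }
  attr(model, "condition") <- cond
  model
}

#' Flux balance analysis
#'
#' Maximizes the biomass reaction flux subject to steady state
#' (`S v = 0`) and the flux bounds. With the substrate uptake fixed at its
#' measured limit this coincides with maximizing the biomass yield.
#'
#' @param model A bounded `"metabolic_model"` (usually from
#'   [apply_condition()]).
#' @return A list of class `"flux_solution"`: `fluxes` (named vector),
#'   `objective_value`, `status` (`"optimal"`/`"infeasible"`), `condition`
#'   (label or `NA`), and `steady_state_residual` (max |S v|).
#' @export
solve_fba <- function(model) {
  validate_model(model)
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  obj <- as.numeric(reaction_ids(model) == model$objective_id)
  sol <- lp_solve(S, rep(0, nrow(S)), obj, lb, ub, maximize = TRUE)
  cond <- attr(model, "condition")
  label <- if (is.null(cond)) NA_character_ else cond$label
  if (sol$status != "optimal") {
    if (sol$status == "infeasible")
      return(structure(list(fluxes = NULL, objective_value = NA_real_,
                            status = "infeasible", condition = label),
                       class = "flux_solution"))
    stop("LP solver failed with status '", sol$status, "'", call. = FALSE)
  }
  fluxes <- stats::setNames(sol$x, reaction_ids(model))
  structure(list(fluxes = fluxes, objective_value = sol$obj,
                 status = "optimal", condition = label,
                 steady_state_residual = max(abs(S %*% sol$x))),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution", if (!is.na(x$condition)) paste0("(", x$condition, ")"),
      "\n  status:   ", x$status,
      "\n  objective:", format(x$objective_value, digits = 6), "h^-1\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For every reaction, the minimal and maximal flux compatible with an
#' objective no worse than `objective_fraction` times the FBA optimum.
#' Because single FBA flux vectors are degenerate, all activity statements
#' in this package are made on these ranges, never on one solution.
#'
#' @param model A bounded `"metabolic_model"`.
#' @param objective_fraction Fraction of the optimum to retain, in (0, 1];
#'   default 1 (ranges at strict optimality, up to a 1e-9 numerical slack).
#' @return A data.frame of class `"flux_range"` with columns `reaction_id`,
#'   `min_flux`, `max_flux`, plus attributes `condition` and `objective`.
#' @export
flux_variability <- function(model, objective_fraction = 1.0) {
  stopifnot(objective_fraction > 0, objective_fraction <= 1)
  base <- solve_fba(model)
  if (base$status != "optimal")
    stop("flux_variability: FBA is ", base$status, call. = FALSE)
  S <- as.matrix(stoichiometric_matrix(model))
  n <- ncol(S)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  obj <- as.numeric(reaction_ids(model) == model$objective_id)
  ## append a slack variable s with c'v - s = 0 and s >= fraction*opt - eps
  floor_ <- objective_fraction * base$objective_value - 1e-9
  S2 <- cbind(rbind(S, obj), c(rep(0, nrow(S)), -1))
  lb2 <- c(lb, floor_)
  ub2 <- c(ub, max(abs(base$objective_value) * 10, 1e3))
  mins <- maxs <- numeric(n)
  for (j in seq_len(n)) {
    ej <- as.numeric(seq_len(n + 1) == j)
    lo <- lp_solve(S2, rep(0, nrow(S2)), ej, lb2, ub2, maximize = FALSE)
    hi <- lp_solve(S2, rep(0, nrow(S2)), ej, lb2, ub2, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("flux_variability: solver status '",
           if (lo$status != "optimal") lo$status else hi$status,
           "' for reaction '", reaction_ids(model)[j], "'", call. = FALSE)
    mins[j] <- lo$obj; maxs[j] <- hi$obj
  }
  out <- data.frame(reaction_id = reaction_ids(model),
                    min_flux = mins, max_flux = maxs,
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- base$condition
  attr(out, "objective") <- base$objective_value
  attr(out, "fba_fluxes") <- base$fluxes
  class(out) <- c("flux_range", "data.frame")
  out
}

#' Biomass carbon yield of an FBA solution
#'
#' Percent of consumed substrate carbon that ends up in biomass:
#' `100 * (biomass flux * mmol C consumed by the biomass reaction) /
#' (carbon influx through open exchanges)`.
#'
#' @param solution A `"flux_solution"` with status optimal.
#' @param model The model the solution was computed on.
#' @param carbon_sources Optional character vector of boundary reaction ids
#'   to count as carbon sources. By default the single importing
#'   carbon-bearing exchange is used; more than one importing carbon
#'   exchange without an explicit list is an error.
#' @return Yield in percent (mol C / mol C x 100).
#' @export
biomass_carbon_yield <- function(solution, model, carbon_sources = NULL) {
  if (solution$status != "optimal")
    stop("cannot compute a yield from a non-optimal solution", call. = FALSE)
  met_ids <- metabolite_ids(model)
  carbon <- vapply(model$metabolites, function(m) {
    f <- m$formula
    if (is.null(f) || is.na(f["C"])) 0 else unname(f["C"])
  }, numeric(1))
  names(carbon) <- met_ids
  ## carbon influx through boundary reactions (negative flux = import)
  importers <- character(); influx <- 0
  for (rxn in model$reactions) {
    if (rxn$category != "boundary") next
    met <- names(rxn$stoichiometry)
    if (carbon[met] == 0) next
    ## a boundary reaction's contribution coef*v to its external metabolite
    ## is the import rate (uptake shows as negative flux with the usual
    ## coef = -1 convention)
    flux_in <- solution$fluxes[[rxn$id]] * unname(rxn$stoichiometry)
    if (flux_in > FLUX_EPS) {
      importers <- c(importers, rxn$id)
      influx <- influx + flux_in * carbon[met]
    }
  }
  if (!is.null(carbon_sources)) {
    extra <- setdiff(importers, carbon_sources)
    if (length(extra))
      stop("carbon import through unlisted exchange(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
  } else if (length(importers) > 1L) {
    stop("more than one carbon source is open (",
         paste(importers, collapse = ", "),
         "); pass an explicit carbon_sources list", call. = FALSE)
  }
  if (influx <= FLUX_EPS)
    stop("no carbon uptake in this solution", call. = FALSE)
  bio <- get_reaction(model, model$objective_id)
  st <- bio$stoichiometry
  consumed <- st[st < 0]
  bio_c <- sum(-consumed * carbon[names(consumed)])
  as.numeric(100 * solution$fluxes[[model$objective_id]] * bio_c / influx)
}
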