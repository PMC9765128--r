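## Model input/output: native JSON, TSV reaction tables, SBML L3 import.

#' Load a metabolic model
#'
#' @param path Path to a model file.
#' @param format `"native-json"` (the package's own lossless format),
#'   `"tsv"` (one reaction per row with an equation string), or `"sbml"`
#'   (SBML Level 3 import, read-only).
#' @return A validated `"metabolic_model"`.
#' @export
load_model <- function(path, format = c("native-json", "tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         "native-json" = read_model_json(path),
         "tsv" = read_model_tsv(path),
         "sbml" = read_model_sbml(path))
}

#' Write a model in the native JSON format
#'
#' The native format is lossless: `load_model(save_model(m))` reproduces
#' every field of `m`.
#'
#' @param model A `"metabolic_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  validate_model(model)
  mets <- lapply(model$metabolites, function(m) {
    out <- list(id = m$id, name = m$name, compartment = m$compartment,
                charge = m$charge)
    if (!is.null(m$formula)) out$formula <- as.list(m$formula)
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, name = r$name,
         stoichiometry = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_association = I(r$gene_association),
         category = r$category)
  })
  obj <- list(metabolites = mets, reactions = rxns,
              objective_id = model$objective_id,
              metadata = model$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  for (field in c("metabolites", "reactions", "objective_id"))
    if (is.null(doc[[field]]))
      stop("model file '", path, "' lacks required field '", field, "'",
           call. = FALSE)
  mets <- lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without id in '", path, "'",
                            call. = FALSE)
    metabolite(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "cytoplasm"
                             else m$compartment,
               formula = if (is.null(m$formula)) NULL else unlist(m$formula),
               charge = if (is.null(m$charge)) 0L else m$charge)
  })
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in '", path, "'",
                            call. = FALSE)
    if (is.null(r$stoichiometry))
      stop("reaction '", r$id, "' lacks stoichiometry", call. = FALSE)
    reversible_default <- isTRUE(r$reversible)
    reaction(id = r$id,
             name = if (is.null(r$name)) r$id else r$name,
             stoichiometry = unlist(r$stoichiometry),
             lower_bound = if (is.null(r$lower_bound)) {
               if (reversible_default) -1000 else 0
             } else r$lower_bound,
             upper_bound = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
             gene_association = if (is.null(r$gene_association)) character()
                                else unlist(r$gene_association),
             category = if (is.null(r$category)) "enzymatic" else r$category)
  })
  metabolic_model(mets, rxns, objective_id = doc$objective_id,
                  metadata = if (is.null(doc$metadata)) list()
                             else doc$metadata)
}

#' Parse a reaction equation string
#'
#' Grammar: `"2 A + B -> C"` (irreversible) or `"A <-> B"` (reversible);
#' coefficients default to 1. Used by the TSV reader.
#'
#' @param eq Equation string.
#' @return List with `stoichiometry` (named numeric) and `reversible`.
#' @export
parse_equation <- function(eq) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else
           if (grepl("->", eq, fixed = TRUE)) "->" else
           stop("equation lacks '->' or '<->': '", eq, "'", call. = FALSE)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("equation must have exactly one arrow: '", eq, "'", call. = FALSE)
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    st <- numeric()
    for (tm in terms) {
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 1L) {
        st[parts] <- sign
      } else if (length(parts) == 2L &&
                 grepl("^[0-9.]+$", parts[1])) {
        st[parts[2]] <- sign * as.numeric(parts[1])
      } else stop("cannot parse term '", tm, "' in equation '", eq, "'",
                  call. = FALSE)
    }
    st
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (m %in% names(st)) st[m] else 0) + rhs[m]
  st <- st[st != 0]
  list(stoichiometry = st, reversible = arrow == "<->")
}

## TSV dialect: columns id, equation and optionally name, lower_bound,
## upper_bound, category, genes (comma separated), objective (1 marks the
## biomass reaction). Metabolite compartments from an "_e" id suffix
## (external) vs anything else (cytoplasm); formulas are not representable
## in this dialect.
read_model_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "equation")
  if (!all(need %in% names(tab)))
    stop("TSV model '", path, "' must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  rxns <- vector("list", nrow(tab))
  met_ids <- character()
  for (k in seq_len(nrow(tab))) {
    row <- tab[k, ]
    pe <- tryCatch(parse_equation(row$equation), error = function(e)
      stop("line ", k + 1L, " of '", path, "': ", conditionMessage(e),
           call. = FALSE))
    lb <- if ("lower_bound" %in% names(tab) && !is.na(row$lower_bound))
      row$lower_bound else if (pe$reversible) -1000 else 0
    ub <- if ("upper_bound" %in% names(tab) && !is.na(row$upper_bound))
      row$upper_bound else 1000
    genes <- if ("genes" %in% names(tab) && !is.na(row$genes) &&
                 nzchar(row$genes))
      trimws(strsplit(row$genes, ",")[[1]]) else character()
    cat_ <- if ("category" %in% names(tab) && !is.na(row$category) &&
                nzchar(row$category)) row$category else "enzymatic"
    rxns[[k]] <- reaction(id = row$id,
                          name = if ("name" %in% names(tab) &&
                                     !is.na(row$name)) row$name else row$id,
                          stoichiometry = pe$stoichiometry,
                          lower_bound = lb, upper_bound = ub,
                          gene_association = genes, category = cat_)
    met_ids <- union(met_ids, names(pe$stoichiometry))
  }
  mets <- lapply(met_ids, function(id)
    metabolite(id, compartment = if (grepl("_e$", id)) "external"
                                 else "cytoplasm"))
  obj_id <- if ("objective" %in% names(tab) && any(tab$objective %in% 1))
    tab$id[tab$objective %in% 1][1]
  else {
    cats <- vapply(rxns, `[[`, "", "category")
    if (!any(cats == "biomass"))
      stop("TSV model '", path, "' declares no biomass/objective reaction",
           call. = FALSE)
    tab$id[cats == "biomass"][1]
  }
  metabolic_model(mets, rxns, objective_id = obj_id,
                  metadata = list(source = path))
}

## Minimal SBML Level 3 (core + fbc) importer. Species with
## boundaryCondition="true" are mapped to external metabolites with an
## auto-created boundary exchange reaction.
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L)
    stop("SBML '", path, "' contains no species", call. = FALSE)
  parse_formula_str <- function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    toks <- regmatches(s, list(m))[[1]]
    f <- numeric()
    for (tk in toks) {
      el <- gsub("[0-9]*$", "", tk)
      n <- gsub("^[A-Za-z]*", "", tk)
      f[el] <- if (nzchar(n)) as.numeric(n) else 1
    }
    f
  }
  mets <- list(); boundary_species <- character()
  for (nd in sp_nodes) {
    id <- xml2::xml_attr(nd, "id")
    bc <- identical(xml2::xml_attr(nd, "boundaryCondition"), "true")
    if (bc) boundary_species <- c(boundary_species, id)
    chg <- xml2::xml_attr(nd, "charge")
    form <- xml2::xml_attr(nd, "chemicalFormula")
    mets[[length(mets) + 1L]] <-
      metabolite(id = id,
                 name = {nm <- xml2::xml_attr(nd, "name")
                         if (is.na(nm)) id else nm},
                 compartment = if (bc) "external" else "cytoplasm",
                 formula = parse_formula_str(form),
                 charge = if (is.na(chg)) 0L else as.integer(chg))
  }
  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- list()
  for (nd in rxn_nodes) {
    id <- xml2::xml_attr(nd, "id")
    rev <- identical(xml2::xml_attr(nd, "reversible"), "true")
    st <- numeric()
    for (ref in xml2::xml_find_all(nd, "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      coef <- xml2::xml_attr(ref, "stoichiometry")
      st[sp] <- -(if (is.na(coef)) 1 else as.numeric(coef))
    }
    for (ref in xml2::xml_find_all(nd, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      coef <- xml2::xml_attr(ref, "stoichiometry")
      st[sp] <- (if (sp %in% names(st)) st[sp] else 0) +
        (if (is.na(coef)) 1 else as.numeric(coef))
    }
    if (length(st) == 0L)
      stop("SBML reaction '", id, "' has no participants", call. = FALSE)
    nm <- xml2::xml_attr(nd, "name")
    is_biomass <- grepl("biomass", id, ignore.case = TRUE) ||
      (!is.na(nm) && grepl("biomass", nm, ignore.case = TRUE))
    rxns[[length(rxns) + 1L]] <-
      reaction(id = id, name = if (is.na(nm)) id else nm,
               stoichiometry = st,
               lower_bound = if (rev) -1000 else 0, upper_bound = 1000,
               category = if (is_biomass) "biomass" else "enzymatic")
  }
  for (sp in boundary_species) {
    rxns[[length(rxns) + 1L]] <-
      reaction(id = paste0("EX_", sp), name = paste0("exchange of ", sp),
               stoichiometry = stats::setNames(-1, sp),
               lower_bound = -1000, upper_bound = 1000,
               category = "boundary")
  }
  cats <- vapply(rxns, `[[`, "", "category")
  if (!any(cats == "biomass"))
    stop("SBML '", path, "' declares no biomass reaction (no reaction id or ",
         "name containing 'biomass')", call. = FALSE)
  obj_id <- vapply(rxns, `[[`, "", "id")[cats == "biomass"][1]
  mdl_name <- xml2::xml_attr(xml2::xml_find_first(doc, ".//model"), "id")
  metabolic_model(mets, rxns, objective_id = obj_id,
                  metadata = list(name = if (is.na(mdl_name)) basename(path)
                                         else mdl_name,
                                  source = path))
}
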