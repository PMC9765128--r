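## Synthetic facultative-anaerobe toy network.
##
## The generated model mirrors the qualitative architecture of a
## facultative aromatic-compound degrader: an acetate-like C2 and an
## aromatic benzoate-like C7 substrate, an ATP- and reductant-investing
## anaerobic ring-reduction branch versus an O2-consuming aerobic ring
## cleavage, a lumped TCA-like oxidation to CO2, a glyoxylate-shunt
## bypass feeding a C4 biomass precursor, an electron-transport chain
## (NADH dehydrogenase -> quinone pool -> denitrification lump or O2
## reductase -> proton-motive force -> ATP synthase), maintenance, PHB
## storage, and a biomass drain. Every enzymatic/transport reaction is
## carbon- and electron-balanced by construction: reduced carriers carry
## their electrons as an H2-equivalent formula, so the degree-of-reduction
## ledger closes exactly.

#' Specification of the toy network
#'
#' @param include_phb Include the PHB storage branch (default TRUE).
#' @param include_glyoxylate_shunt Include the C4-forming bypass (default
#'   TRUE; the biomass reaction requires its product, so disabling it
#'   also removes the succinate demand from biomass).
#' @param substrates Subset of `c("acetate", "benzoate")`.
#' @param p_to_o Named ATP-per-electron-pair yields for the two acceptor
#'   chains; oxygen respiration must be the more efficient one for the
#'   aerobic/anaerobic contrast the network is meant to display.
#' @param atp_per_biomass mmol ATP consumed per gDW-unit of biomass flux
#'   (a lumped growth-associated maintenance plus polymerization cost).
#' @return List of class `"toy_network_spec"`.
#' @export
toy_network_spec <- function(include_phb = TRUE,
                             include_glyoxylate_shunt = TRUE,
                             substrates = c("acetate", "benzoate"),
                             p_to_o = c(oxygen = 2, nitrate = 1),
                             atp_per_biomass = 40) {
  substrates <- match.arg(substrates, several.ok = TRUE)
  stopifnot(all(c("oxygen", "nitrate") %in% names(p_to_o)),
            all(p_to_o > 2 / 3),   # pmf bookkeeping needs positive pumping
            atp_per_biomass > 0)
  structure(list(include_phb = include_phb,
                 include_glyoxylate_shunt = include_glyoxylate_shunt,
                 substrates = substrates, p_to_o = p_to_o,
                 atp_per_biomass = atp_per_biomass),
            class = "toy_network_spec")
}

#' Generate the toy metabolic model
#'
#' @param spec A [toy_network_spec()].
#' @return A validated `"metabolic_model"` that passes
#'   [check_mass_balance()] for carbon and [check_electron_balance()]
#'   exactly.
#' @export
make_toy_model <- function(spec = toy_network_spec()) {
  stopifnot(inherits(spec, "toy_network_spec"))
  none <- stats::setNames(numeric(0), character(0))   # element-free pseudo
  mets <- list(
    metabolite("ac_e", "acetate (external)", "external",
               c(C = 2, H = 3, O = 2), -1L),
    metabolite("no3_e", "nitrate (external)", "external",
               c(N = 1, O = 3), -1L),
    metabolite("o2_e", "oxygen (external)", "external", c(O = 2), 0L),
    metabolite("co2_e", "CO2 (external)", "external", c(C = 1, O = 2), 0L),
    metabolite("n2_e", "N2 (external)", "external", c(N = 2), 0L),
    metabolite("x_e", "biomass (drain)", "external", none, 0L),
    metabolite("ac_c", "acetate", "cytoplasm", c(C = 2, H = 3, O = 2), -1L),
    metabolite("succ_c", "succinate (C4 pool)", "cytoplasm",
               c(C = 4, H = 4, O = 4), -2L),
    metabolite("co2_c", "CO2", "cytoplasm", c(C = 1, O = 2), 0L),
    metabolite("no3_c", "nitrate", "cytoplasm", c(N = 1, O = 3), -1L),
    metabolite("o2_c", "oxygen", "cytoplasm", c(O = 2), 0L),
    metabolite("n2_c", "N2", "cytoplasm", c(N = 2), 0L),
    metabolite("nadh_c", "NADH (2 e- carrier)", "cytoplasm", c(H = 2), 0L),
    metabolite("nad_c", "NAD+", "cytoplasm", none, 0L),
    metabolite("qh2_c", "quinol (2 e- carrier)", "cytoplasm", c(H = 2), 0L),
    metabolite("q_c", "quinone", "cytoplasm", none, 0L),
    metabolite("atp_c", "ATP (energy pseudo)", "cytoplasm", none, 0L),
    metabolite("adp_c", "ADP", "cytoplasm", none, 0L),
    metabolite("pi_c", "phosphate (pseudo)", "cytoplasm", none, 0L),
    metabolite("pmf_p", "proton-motive charge", "periplasm", none, 0L)
  )
  rxns <- list()
  add <- function(...) rxns[[length(rxns) + 1L]] <<- reaction(...)
  ex <- function(met, lb = 0, ub = 1000)
    add(paste0("EX_", sub("_e$", "", met)), stats::setNames(-1, met),
        name = paste("exchange of", met), lower_bound = lb,
        upper_bound = ub, category = "boundary")

  ## exchanges: substrate/acceptor exchanges ship closed; apply_condition
  ## opens the ones a condition selects
  ex("ac_e"); ex("no3_e"); ex("o2_e"); ex("co2_e"); ex("n2_e"); ex("x_e")
  add("T_ac", c(ac_e = -1, ac_c = 1), name = "acetate uptake",
      gene_association = "toy0001", category = "transport")
  add("T_no3", c(no3_e = -1, no3_c = 1), name = "nitrate uptake",
      gene_association = "toy0002", category = "transport")
  add("T_o2", c(o2_e = -1, o2_c = 1), name = "oxygen diffusion",
      category = "transport")
  add("T_co2", c(co2_c = -1, co2_e = 1), name = "CO2 export",
      category = "transport")
  add("T_n2", c(n2_c = -1, n2_e = 1), name = "N2 export",
      category = "transport")

  if ("benzoate" %in% spec$substrates) {
    mets[[length(mets) + 1L]] <- metabolite("bz_e", "benzoate (external)",
                                            "external",
                                            c(C = 7, H = 5, O = 2), -1L)
    mets[[length(mets) + 1L]] <- metabolite("bz_c", "benzoate", "cytoplasm",
                                            c(C = 7, H = 5, O = 2), -1L)
    mets[[length(mets) + 1L]] <- metabolite("bzred_c",
                                            "reduced ring intermediate",
                                            "cytoplasm",
                                            c(C = 7, H = 11, O = 2), -1L)
    ex("bz_e")
    add("T_bz", c(bz_e = -1, bz_c = 1), name = "benzoate uptake",
        gene_association = "toy0003", category = "transport")
    ## anaerobic branch: ATP-dependent ring reduction (class I reductase
    ## surrogate) followed by beta-oxidation-like breakdown
    add("RINGRED", c(bz_c = -1, nadh_c = -3, nad_c = 3, atp_c = -2,
                     adp_c = 2, pi_c = 2, bzred_c = 1),
        name = "anaerobic ring reduction",
        gene_association = c("toy0101", "toy0102"))
    add("BETAOX", c(bzred_c = -1, nad_c = -6, ac_c = 3, co2_c = 1,
                    nadh_c = 6),
        name = "ring breakdown to acetate units",
        gene_association = "toy0103")
    ## aerobic branch: dioxygenase-style ring cleavage
    add("RINGOX", c(bz_c = -1, o2_c = -1, nad_c = -1, ac_c = 3, co2_c = 1,
                    nadh_c = 1),
        name = "aerobic ring cleavage",
        gene_association = "toy0201")
  }

  add("TCA", c(ac_c = -1, nad_c = -4, adp_c = -1, pi_c = -1, co2_c = 2,
               nadh_c = 4, atp_c = 1),
      name = "TCA-like acetate oxidation",
      gene_association = c("toy0301", "toy0302"))
  if (spec$include_glyoxylate_shunt)
    add("GLYOX", c(ac_c = -2, nad_c = -1, succ_c = 1, nadh_c = 1),
        name = "glyoxylate-shunt C4 synthesis",
        gene_association = "toy0401")
  add("NADHDH", c(nadh_c = -1, q_c = -1, nad_c = 1, qh2_c = 1, pmf_p = 2),
      name = "NADH dehydrogenase",
      gene_association = "toy0501")
  ## pmf per quinol chosen so ATP/NADH over each chain equals 3 * p_to_o
  ## pmf-per-ATP: (2 from the dehydrogenase + k/electron-pairs) / 3 = P/O
  k_o2 <- 2 * (3 * spec$p_to_o[["oxygen"]] - 2)
  k_no3 <- 5 * (3 * spec$p_to_o[["nitrate"]] - 2)
  add("NAR", c(no3_c = -2, qh2_c = -5, q_c = 5, n2_c = 1, pmf_p = k_no3),
      name = "denitrification chain (NO3- to N2)",
      gene_association = c("toy0601", "toy0602", "toy0603", "toy0604"))
  add("COX", c(o2_c = -1, qh2_c = -2, q_c = 2, pmf_p = k_o2),
      name = "terminal oxidase",
      gene_association = "toy0701")
  add("ATPS", c(pmf_p = -3, adp_c = -1, pi_c = -1, atp_c = 1),
      name = "ATP synthase",
      gene_association = "toy0801")
  add("NGAM", c(atp_c = -1, adp_c = 1, pi_c = 1),
      name = "non-growth maintenance", lower_bound = 0,
      category = "maintenance")
  if (spec$include_phb) {
    mets[[length(mets) + 1L]] <- metabolite("phb_c", "PHB monomer unit",
                                            "cytoplasm",
                                            c(C = 4, H = 6, O = 2), 0L)
    mets[[length(mets) + 1L]] <- metabolite("phb_e", "PHB (stored)",
                                            "external",
                                            c(C = 4, H = 6, O = 2), 0L)
    add("PHBSYN", c(ac_c = -2, nadh_c = -1, nad_c = 1, phb_c = 1),
        name = "PHB synthesis", gene_association = "toy0901")
    add("T_phb", c(phb_c = -1, phb_e = 1), name = "PHB deposition",
        category = "transport")
    ex("phb_e")
  }
  bio_st <- c(ac_c = -8, atp_c = -spec$atp_per_biomass,
              adp_c = spec$atp_per_biomass, pi_c = spec$atp_per_biomass,
              x_e = 1)
  if (spec$include_glyoxylate_shunt) bio_st["succ_c"] <- -1
  add("BIOMASS", bio_st, name = "biomass formation",
      lower_bound = 0, category = "biomass")
  metabolic_model(mets, rxns, objective_id = "BIOMASS",
                  metadata = list(name = "toy facultative degrader network",
                                  generator = "make_toy_model",
                                  ## the anaerobic ring reductase is an
                                  ## O2-sensitive enzyme; aerobic conditions
                                  ## close it (see apply_condition)
                                  oxygen_sensitive =
                                    if ("benzoate" %in% spec$substrates)
                                      "RINGRED" else character()))
}

#' Condition presets for the toy network
#'
#' Substrate/acceptor grid over the toy model's exchanges: acetate at 10
#' and benzoate at 5 mmol gDW^-1 h^-1 uptake, acceptors at 30, NGAM at
#' the package default.
#'
#' @param spec The [toy_network_spec()] the model was generated with.
#' @param ngam Non-growth maintenance passed to every condition.
#' @return Named list of [condition()] objects.
#' @export
toy_conditions <- function(spec = toy_network_spec(), ngam = DEFAULT_NGAM) {
  uptake <- c(acetate = 10, benzoate = 5)
  exch <- c(acetate = "EX_ac", benzoate = "EX_bz")
  conds <- list()
  for (sub in spec$substrates) {
    for (acc in c("nitrate", "oxygen")) {
      lab <- paste0(sub, "-", if (acc == "oxygen") "aerobic" else
                    "anaerobic")
      conds[[lab]] <- condition(label = lab,
                                substrate_exchange = exch[[sub]],
                                substrate_uptake_max = uptake[[sub]],
                                acceptor = acc,
                                acceptor_exchange = if (acc == "nitrate")
                                  "EX_no3" else "EX_o2",
                                acceptor_uptake_max = 30,
                                ngam = ngam)
    }
  }
  conds
}
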