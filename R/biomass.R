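## Biomass-reaction assembly from macromolecular fractions and monomer
## compositions estimated from genome and proteome sequences.

#' Monomer composition of a macromolecule class
#'
#' @param fractions Named numeric, monomer id -> mole fraction; must be
#'   non-negative and sum to 1 (within 1e-9).
#' @param basis One of `"dna"`, `"rna"`, `"protein"`, `"lipid"`.
#' @return List of class `"monomer_composition"`.
#' @export
monomer_composition <- function(fractions, basis) {
  basis <- match.arg(basis, c("dna", "rna", "protein", "lipid"))
  if (any(fractions < 0))
    stop("negative mole fraction", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mole fractions must sum to 1 (got ", sum(fractions), ")",
         call. = FALSE)
  structure(list(fractions = fractions, basis = basis),
            class = "monomer_composition")
}

read_fasta_seqs <- function(x, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- if (type == "dna") Biostrings::readDNAStringSet(x)
           else Biostrings::readAAStringSet(x)
    as.character(set)
  } else as.character(x)
}

#' DNA monomer composition from a genome sequence
#'
#' Double-stranded convention: the dAMP and dTMP fractions are each
#' `(1 - GC)/2` and the dGMP/dCMP fractions `GC/2`, with GC computed from
#' the given strand ignoring N. The result is therefore invariant under
#' reverse complementation.
#'
#' @param genome FASTA path or character vector of nucleotide sequences
#'   over A, C, G, T, N (N fraction must stay below 5%).
#' @return A `"monomer_composition"` with monomers `dAMP`, `dCMP`, `dGMP`,
#'   `dTMP`.
#' @export
nucleotide_composition <- function(genome) {
  seqs <- read_fasta_seqs(genome, "dna")
  all <- paste(toupper(seqs), collapse = "")
  if (!nzchar(all)) stop("empty genome sequence", call. = FALSE)
  counts <- table(strsplit(all, "")[[1]])
  bad <- setdiff(names(counts), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("unexpected nucleotide(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n_n <- if ("N" %in% names(counts)) counts[["N"]] else 0
  total <- sum(counts) - n_n
  if (total == 0L) stop("sequence is all N", call. = FALSE)
  if (n_n / sum(counts) >= 0.05)
    stop("N fraction >= 5%; composition would be unreliable", call. = FALSE)
  gc <- sum(counts[intersect(c("G", "C"), names(counts))]) / total
  monomer_composition(c(dAMP = (1 - gc) / 2, dCMP = gc / 2,
                        dGMP = gc / 2, dTMP = (1 - gc) / 2), "dna")
}

#' RNA monomer composition from gene sequences
#'
#' Estimated from the transcribed strand of the given (coding) gene
#' sequences: U replaces T, and fractions follow the single-strand base
#' counts pooled over all genes.
#'
#' @param genes FASTA path or character vector of gene (DNA) sequences.
#' @return A `"monomer_composition"` with monomers `AMP`, `CMP`, `GMP`,
#'   `UMP`.
#' @export
rna_composition <- function(genes) {
  seqs <- read_fasta_seqs(genes, "dna")
  all <- paste(toupper(seqs), collapse = "")
  if (!nzchar(all)) stop("empty gene sequences", call. = FALSE)
  counts <- table(strsplit(all, "")[[1]])
  keep <- intersect(c("A", "C", "G", "T"), names(counts))
  total <- sum(counts[keep])
  if (total == 0L) stop("no A/C/G/T content", call. = FALSE)
  frac <- function(b) if (b %in% keep) counts[[b]] / total else 0
  monomer_composition(c(AMP = frac("A"), CMP = frac("C"),
                        GMP = frac("G"), UMP = frac("T")), "rna")
}

AA_LETTERS <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                E = "Glu", Q = "Gln", G = "Gly", H = "His", I = "Ile",
                L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

#' Amino-acid composition of a proteome
#'
#' Length-weighted residue frequencies pooled over all protein sequences;
#' ambiguous residues (X and other non-canonical letters, and trailing
#' stops) are skipped with a warning.
#'
#' @param proteome FASTA path or character vector of amino-acid sequences.
#' @return A `"monomer_composition"` keyed by three-letter residue codes.
#' @export
amino_acid_composition <- function(proteome) {
  seqs <- read_fasta_seqs(proteome, "protein")
  all <- paste(toupper(seqs), collapse = "")
  all <- gsub("\\*", "", all)
  if (!nzchar(all)) stop("empty proteome", call. = FALSE)
  counts <- table(strsplit(all, "")[[1]])
  skip <- setdiff(names(counts), names(AA_LETTERS))
  if (length(skip)) {
    warning("skipping non-canonical residue(s): ",
            paste(skip, collapse = ", "))
    counts <- counts[names(counts) %in% names(AA_LETTERS)]
  }
  if (sum(counts) == 0L) stop("no canonical residues", call. = FALSE)
  frac <- as.numeric(counts) / sum(counts)
  monomer_composition(stats::setNames(frac, AA_LETTERS[names(counts)]),
                      "protein")
}

#' Macromolecular biomass composition
#'
#' Class masses in g per g dry weight. The shipped default (see
#' [default_macro_composition()]) follows the E. coli convention; class
#' masses must sum to 1 g/gDW within 2% and are normalized to exactly 1.
#'
#' @param class_g_per_gdw Named numeric, macromolecule class -> g/gDW.
#' @param soluble_pool Named numeric of trace soluble-pool entries
#'   (vitamins, cofactors, reduction equivalents), g/gDW, informational.
#' @param check Enforce the sum-to-1-within-2% invariant and normalize
#'   (default). Disable only for deliberately partial compositions, e.g.
#'   a single macromolecule class in isolation.
#' @return List of class `"macro_composition"` with normalized masses.
#' @export
macro_composition <- function(class_g_per_gdw, soluble_pool = numeric(),
                              check = TRUE) {
  total <- sum(class_g_per_gdw) + sum(soluble_pool)
  if (check) {
    if (abs(total - 1) > 0.02)
      stop("macromolecule masses sum to ", round(total, 4),
           " g/gDW; must be 1 within 2%", call. = FALSE)
    class_g_per_gdw <- class_g_per_gdw / total
    soluble_pool <- soluble_pool / total
  }
  structure(list(class_g_per_gdw = class_g_per_gdw,
                 soluble_pool = soluble_pool),
            class = "macro_composition")
}

#' Default macromolecular fractions (E. coli convention)
#'
#' Read from the configuration table shipped with the package; never
#' hard-coded in logic so that organism-specific measurements can replace
#' it wholesale.
#'
#' @return A `"macro_composition"`.
#' @export
default_macro_composition <- function() {
  path <- system.file("extdata", "macro_ecoli.tsv", package = "aromflux",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  main <- tab$g_per_gdw[!tab$soluble]
  names(main) <- tab$class[!tab$soluble]
  sol <- tab$g_per_gdw[tab$soluble]
  names(sol) <- tab$class[tab$soluble]
  macro_composition(main, sol)
}

#' Polymerized monomer molar masses
#'
#' Residue masses inside the polymer (free monomer minus water for
#' condensation polymers), g/mol, so that the assembled biomass reaction
#' closes its mass balance.
#'
#' @return Named numeric vector over amino-acid residues (three-letter
#'   codes), deoxyribo- and ribonucleoside monophosphate residues, and a
#'   generic `lipid` building block.
#' @export
monomer_masses <- function() {
  c(## amino-acid residues (monoisotopic-free average masses, -H2O)
    Ala = 71.08, Arg = 156.19, Asn = 114.10, Asp = 115.09, Cys = 103.14,
    Glu = 129.12, Gln = 128.13, Gly = 57.05, His = 137.14, Ile = 113.16,
    Leu = 113.16, Lys = 128.17, Met = 131.20, Phe = 147.18, Pro = 97.12,
    Ser = 87.08, Thr = 101.10, Trp = 186.21, Tyr = 163.18, Val = 99.13,
    ## DNA residues (dNMP - H2O)
    dAMP = 313.21, dCMP = 289.18, dGMP = 329.21, dTMP = 304.20,
    ## RNA residues (NMP - H2O)
    AMP = 329.21, CMP = 305.18, GMP = 345.21, UMP = 306.17,
    ## generic lipid building block (average phospholipid / 2 acyl chains)
    lipid = 700.0)
}

#' Assemble a biomass reaction
#'
#' Converts macromolecular class masses and monomer mole fractions into
#' monomer consumption coefficients in mmol/gDW
#' (`class g/gDW * fraction / residue mass`, scaled so that the consumed
#' precursor mass is exactly 1 g per unit of biomass flux), and adds the
#' growth-associated maintenance ATP hydrolysis.
#'
#' @param macro A `"macro_composition"`; classes without a monomer table
#'   are dropped with a warning.
#' @param monomers Named list of `"monomer_composition"` objects keyed by
#'   macromolecule class.
#' @param masses Named monomer molar masses (default [monomer_masses()]).
#' @param gam Growth-associated maintenance, mmol ATP per gDW.
#' @param biomass_met Id of the produced biomass metabolite.
#' @param atp_id,adp_id,pi_id Metabolite ids for the maintenance
#'   hydrolysis.
#' @param normalize Rescale coefficients so consumed mass is exactly
#'   1 g/gDW (default TRUE; the pre-normalization total must be within
#'   1%).
#' @return A `"reaction"` with category `"biomass"`, with attribute
#'   `"mass_per_flux"` (g precursor consumed per unit flux, after any
#'   normalization).
#' @export
assemble_biomass <- function(macro, monomers, masses = monomer_masses(),
                             gam = DEFAULT_GAM, biomass_met = "biomass",
                             atp_id = "atp", adp_id = "adp", pi_id = "pi",
                             normalize = TRUE) {
  stopifnot(inherits(macro, "macro_composition"))
  st <- numeric()
  for (cls in names(macro$class_g_per_gdw)) {
    if (!cls %in% names(monomers)) {
      warning("no monomer table for class '", cls, "'; dropped")
      next
    }
    mc <- monomers[[cls]]
    g <- macro$class_g_per_gdw[[cls]]
    for (mono in names(mc$fractions)) {
      if (!mono %in% names(masses))
        stop("no molar mass for monomer '", mono, "'", call. = FALSE)
      ## mean residue mass of the class, so that g of polymer / mean mass
      ## gives total mmol of residues, split by mole fraction
      mean_mass <- sum(mc$fractions * masses[names(mc$fractions)])
      coef <- g * 1000 / mean_mass * mc$fractions[[mono]]   # mmol/gDW
      st[mono] <- (if (mono %in% names(st)) st[mono] else 0) - coef
    }
  }
  if (length(st) == 0L) stop("no precursors assembled", call. = FALSE)
  mass_total <- sum(-st * masses[names(st)]) / 1000   # g per unit flux
  if (normalize) {
    if (abs(mass_total - 1) > 0.01)
      stop("pre-normalization precursor mass ", round(mass_total, 4),
           " g/gDW deviates from 1 g by more than 1%", call. = FALSE)
    st <- st / mass_total
    mass_total <- 1
  }
  if (gam > 0) {
    st[atp_id] <- (if (atp_id %in% names(st)) st[atp_id] else 0) - gam
    st[adp_id] <- (if (adp_id %in% names(st)) st[adp_id] else 0) + gam
    st[pi_id] <- (if (pi_id %in% names(st)) st[pi_id] else 0) + gam
  }
  st[biomass_met] <- 1
  out <- reaction("BIOMASS", stoichiometry = st, name = "biomass assembly",
                  lower_bound = 0, upper_bound = 1000, category = "biomass")
  attr(out, "mass_per_flux") <- mass_total
  out
}
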