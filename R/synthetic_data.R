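## Seeded generators for transcript count matrices with planted metagene
## structure and for exponential growth curves with a closed carbon and
## electron ledger.

#' Specification of a planted-structure transcript simulation
#'
#' Counts are built as `W_true %*% S_true` with multiplicative relative
#' Gaussian noise clipped at zero. Each gene belongs to one of `m_true`
#' modules and carries a lognormal baseline copy number; each module's
#' score row is `1 + boost` on its own condition group (assigned round
#' robin) and `1` elsewhere, so per-condition log-count marginals stay
#' close to Normal while the noise-free scaled matrix has exact rank
#' `m_true`.
#'
#' @param n_genes,n_conditions Matrix dimensions.
#' @param m_true Planted component count, `<= min(n_genes, n_conditions)`.
#' @param boost Expression multiplier of a module on its own conditions
#'   (default 6; identifiability of the planted factors degrades as the
#'   boost approaches the baseline).
#' @param meanlog,sdlog Lognormal baseline parameters (defaults 3 and 1).
#' @param noise_sd Relative (multiplicative) noise standard deviation.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return List of class `"transcript_sim_spec"`.
#' @export
transcript_sim_spec <- function(n_genes = 500, n_conditions = 10,
                                m_true = 3, boost = 6, meanlog = 3,
                                sdlog = 1, noise_sd = 0.01, seed = 1) {
  if (m_true > min(n_genes, n_conditions) || m_true < 1)
    stop("m_true must be in 1..min(n_genes, n_conditions)", call. = FALSE)
  stopifnot(boost > 0, sdlog > 0, noise_sd >= 0)
  structure(list(n_genes = n_genes, n_conditions = n_conditions,
                 m_true = m_true, boost = boost, meanlog = meanlog,
                 sdlog = sdlog, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "transcript_sim_spec")
}

#' Generate a transcript count matrix with planted metagene structure
#'
#' @param spec A [transcript_sim_spec()].
#' @return List: `tm` (raw `"transcript_matrix"`), `W_true` (genes x
#'   m_true), `S_true` (m_true x conditions), `module` (gene module
#'   index).
#' @export
make_transcript_counts <- function(spec = transcript_sim_spec()) {
  stopifnot(inherits(spec, "transcript_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes; M <- spec$n_conditions; m <- spec$m_true
  module <- rep(seq_len(m), length.out = n)
  baseline <- stats::rlnorm(n, spec$meanlog, spec$sdlog)
  activity <- matrix(0, m, M)
  for (k in seq_len(m))
    activity[k, seq(k, M, by = m)] <- 1
  S_true <- 1 + spec$boost * activity
  W_true <- matrix(0, n, m)
  W_true[cbind(seq_len(n), module)] <- baseline
  mu <- W_true %*% S_true
  noise <- matrix(stats::rnorm(n * M), n, M) * spec$noise_sd * mu
  counts <- pmax(mu + noise, 0)
  genes <- sprintf("gene%04d", seq_len(n))
  conds <- sprintf("cond%02d", seq_len(M))
  dimnames(W_true) <- list(genes, paste0("metagene_", seq_len(m)))
  dimnames(S_true) <- list(paste0("metagene_", seq_len(m)), conds)
  list(tm = transcript_matrix(counts, genes, conds),
       W_true = W_true, S_true = S_true, module = module)
}

#' Specification of a synthetic growth experiment
#'
#' @param mu_true Growth rate, h^-1.
#' @param od0 Initial optical density.
#' @param yield_true Carbon yield as a fraction (0, 1).
#' @param substrate0_mM Initial substrate concentration.
#' @param substrate_formula,substrate_charge Substrate composition
#'   (default acetate, C2H3O2-).
#' @param acceptor `"nitrate"` or `"oxygen"`.
#' @param acceptor0_mM Initial acceptor concentration.
#' @param times Sampling times in hours.
#' @param noise_sd Fractional multiplicative noise on OD and
#'   concentration readings.
#' @param od_to_cdw Calibration slope, g CDW / L / OD.
#' @param biomass_c_wt_pct,biomass_gamma_per_c Biomass carbon content and
#'   degree of reduction per C.
#' @param seed Integer seed.
#' @return List of class `"growth_sim_spec"`.
#' @export
growth_sim_spec <- function(mu_true = 0.25, od0 = 0.02, yield_true = 0.42,
                            substrate0_mM = 8,
                            substrate_formula = c(C = 2, H = 3, O = 2),
                            substrate_charge = -1,
                            acceptor = c("nitrate", "oxygen"),
                            acceptor0_mM = 7,
                            times = seq(0, 12, by = 0.6),
                            noise_sd = 0.02, od_to_cdw = 0.35,
                            biomass_c_wt_pct = 48,
                            biomass_gamma_per_c = 4.07, seed = 1) {
  acceptor <- match.arg(acceptor)
  stopifnot(mu_true > 0, od0 > 0, yield_true > 0, yield_true < 1,
            substrate0_mM > 0, noise_sd >= 0)
  structure(list(mu_true = mu_true, od0 = od0, yield_true = yield_true,
                 substrate0_mM = substrate0_mM,
                 substrate_formula = substrate_formula,
                 substrate_charge = substrate_charge,
                 acceptor = acceptor, acceptor0_mM = acceptor0_mM,
                 times = times, noise_sd = noise_sd,
                 od_to_cdw = od_to_cdw,
                 biomass_c_wt_pct = biomass_c_wt_pct,
                 biomass_gamma_per_c = biomass_gamma_per_c,
                 seed = as.integer(seed)),
            class = "growth_sim_spec")
}

#' Generate a synthetic growth curve
#'
#' Exponential OD with multiplicative noise; the substrate is drawn down
#' so that the formed biomass carbon over the consumed substrate carbon
#' equals `yield_true` exactly (before noise), and the acceptor series
#' follows the electron ledger of [acceptor_demand()]. Sampling past
#' substrate exhaustion truncates the curve (flagged in the result).
#'
#' @param spec A [growth_sim_spec()].
#' @return List: `curve` (a `"growth_curve"`), `truth` (the generating
#'   parameters plus the noise-free series), `truncated` (logical).
#' @export
make_growth_curve <- function(spec = growth_sim_spec()) {
  stopifnot(inherits(spec, "growth_sim_spec"))
  set.seed(spec$seed)
  t <- spec$times
  od <- spec$od0 * exp(spec$mu_true * t)
  cdw <- od * spec$od_to_cdw                          # g/L
  c_per_g <- (spec$biomass_c_wt_pct / 100) / 12.011 * 1000   # mmol C/g
  n_c <- unname(spec$substrate_formula["C"])
  gamma_s <- degree_of_reduction(spec$substrate_formula,
                                 spec$substrate_charge)
  assim_c <- (cdw - cdw[1]) * c_per_g                 # mmol C / L
  substrate <- spec$substrate0_mM - assim_c / (n_c * spec$yield_true)
  truncated <- FALSE
  if (any(substrate < 0)) {
    truncated <- TRUE
    keep <- substrate >= 0
    t <- t[keep]; od <- od[keep]; cdw <- cdw[keep]
    assim_c <- assim_c[keep]; substrate <- substrate[keep]
  }
  consumed <- spec$substrate0_mM - substrate          # mM substrate
  e_diss <- consumed * gamma_s - assim_c * spec$biomass_gamma_per_c
  acceptor_used <- e_diss / ACCEPTOR_ELECTRONS[[spec$acceptor]]
  acceptor_series <- spec$acceptor0_mM - acceptor_used
  jitter <- function(x) {
    if (spec$noise_sd == 0) return(x)
    pmax(x * (1 + stats::rnorm(length(x), 0, spec$noise_sd)), 0)
  }
  curve <- growth_curve(time = t, od = jitter(od),
                        substrate_mM = jitter(substrate),
                        nitrate_mM = if (spec$acceptor == "nitrate")
                          jitter(acceptor_series) else NULL,
                        od_to_cdw = spec$od_to_cdw)
  list(curve = curve,
       truth = list(spec = spec, od = od, substrate_mM = substrate,
                    acceptor_mM = acceptor_series),
       truncated = truncated)
}
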