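## Growth-physiology calculations: exponential rate fitting, elemental
## composition with oxygen by difference, degree of reduction, electron
## balances over nitrate / O2, and carbon yields.

## ash content of dried cells in weight percent (includes S), used when
## deriving the O content by difference
ASH_WT_PCT <- 12.03

## electrons accepted per mole of acceptor: full denitrification
## NO3- -> 1/2 N2 takes 5 e-, O2 -> 2 H2O takes 4 e-; reduction only to
## nitrite takes 2 e- (the remaining 3 are available downstream)
ACCEPTOR_ELECTRONS <- c(nitrate = 5, oxygen = 4, nitrite_only = 2)

#' Assemble a growth curve
#'
#' @param time Sampling times in hours, strictly increasing.
#' @param od Optical density at 660 nm.
#' @param substrate_mM,nitrate_mM,nitrite_mM Optional concentration series.
#' @param od_to_cdw Calibration slope, g cell dry weight per litre per OD
#'   unit.
#' @return A list of class `"growth_curve"`.
#' @export
growth_curve <- function(time, od, substrate_mM = NULL, nitrate_mM = NULL,
                         nitrite_mM = NULL, od_to_cdw = 0.35) {
  stopifnot(length(time) == length(od), length(time) >= 2L)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  for (s in list(substrate_mM, nitrate_mM, nitrite_mM))
    if (!is.null(s) && length(s) != length(time))
      stop("concentration series must match time", call. = FALSE)
  structure(list(time = time, od = od, substrate_mM = substrate_mM,
                 nitrate_mM = nitrate_mM, nitrite_mM = nitrite_mM,
                 od_to_cdw = od_to_cdw),
            class = "growth_curve")
}

#' Fit the exponential growth rate
#'
#' Least-squares slope of `ln(OD)` against time over a window. Without an
#' explicit window the longest contiguous stretch of at least three points
#' with ln-linear R^2 >= 0.98 is chosen (ties broken by higher R^2).
#'
#' @param curve A `"growth_curve"`.
#' @param window Optional numeric length-2 time interval `c(t0, t1)`.
#' @return List with `mu` (h^-1), `t_d` (doubling time, h; `NA` when
#'   `mu <= 0`), `r_squared`, `window`, `n_points`.
#' @export
fit_growth_rate <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  fit_idx <- function(idx) {
    t <- curve$time[idx]; o <- curve$od[idx]
    if (any(o <= 0))
      stop("non-positive OD inside the fit window", call. = FALSE)
    fm <- stats::lm(log(o) ~ t)
    mu <- unname(stats::coef(fm)[2])
    r2 <- if (length(idx) == 2L) 1 else
      suppressWarnings(summary(fm)$r.squared)   # exact fits warn in summary
    ## a perfectly flat series has zero total variance; the fit is exact
    if (!is.finite(r2))
      r2 <- if (sum(stats::residuals(fm)^2) < 1e-12) 1 else NA_real_
    list(mu = mu, r2 = r2)
  }
  n <- length(curve$time)
  if (!is.null(window)) {
    idx <- which(curve$time >= window[1] & curve$time <= window[2])
    if (length(idx) < 3L)
      stop("fewer than 3 points in the fit window", call. = FALSE)
    f <- fit_idx(idx)
  } else {
    best <- NULL
    for (i in 1:(n - 2)) for (j in (i + 2):n) {
      idx <- i:j
      if (any(curve$od[idx] <= 0)) next
      f1 <- fit_idx(idx)
      if (f1$r2 >= 0.98) {
        if (is.null(best) || length(idx) > best$len ||
            (length(idx) == best$len && f1$r2 > best$f$r2))
          best <- list(idx = idx, f = f1, len = length(idx))
      }
    }
    if (is.null(best))
      stop("no contiguous window of >= 3 points reaches ln-linear R^2 ",
           ">= 0.98; pass an explicit window", call. = FALSE)
    idx <- best$idx; f <- best$f
  }
  mu <- f$mu
  list(mu = mu,
       t_d = if (mu > 1e-12) log(2) / mu else NA_real_,
       r_squared = f$r2,
       window = range(curve$time[idx]),
       n_points = length(idx))
}

#' Oxygen content of dried cells by difference
#'
#' `O = 100 - C - H - N - ash`, with the ash content (which includes S)
#' fixed at `r ASH_WT_PCT` wt%.
#'
#' @param c_wt,h_wt,n_wt Measured C, H, N contents in weight percent.
#' @param ash_wt_pct Ash constant, wt%.
#' @return O content in weight percent.
#' @export
oxygen_by_difference <- function(c_wt, h_wt, n_wt, ash_wt_pct = ASH_WT_PCT) {
  stopifnot(c_wt >= 0, h_wt >= 0, n_wt >= 0)
  o <- 100 - c_wt - h_wt - n_wt - ash_wt_pct
  if (o < 0)
    stop("inconsistent elemental analysis: C+H+N+ash exceeds 100 wt%",
         call. = FALSE)
  o
}

#' Degree of reduction
#'
#' Available electrons per mole relative to the CO2 / H2O / NH3 reference
#' states: `gamma = 4 C + 1 H - 2 O - 3 N + 6 S - charge`.
#'
#' @param formula Named vector of element counts over C, H, N, O, S.
#' @param charge Net charge (an anion, charge -1, carries one extra
#'   electron).
#' @return Electrons per mole.
#' @export
degree_of_reduction <- function(formula, charge = 0) {
  weights <- c(C = 4, H = 1, O = -2, N = -3, S = 6)
  formula <- formula[formula != 0]
  unknown <- setdiff(names(formula), names(weights))
  if (length(unknown))
    stop("degree of reduction undefined for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (length(formula) == 0L) return(-as.numeric(charge))
  sum(weights[names(formula)] * formula) - charge
}

#' Predicted electron-acceptor consumption
#'
#' Electron ledger: the substrate's electrons minus those assimilated into
#' biomass are dissimilated to the terminal acceptor. Nitrate accepts 5
#' electrons (full denitrification to N2; pass `acceptor = "nitrite_only"`
#' for the 2-electron reduction to nitrite), O2 accepts 4.
#'
#' @param substrate_mmol Substrate consumed, mmol.
#' @param substrate_gamma Degree of reduction of the substrate (e- per
#'   mol).
#' @param assimilated_c_mmol Carbon assimilated into biomass, mmol C.
#' @param biomass_gamma_per_c Degree of reduction of biomass per mol of
#'   biomass carbon.
#' @param acceptor One of `"nitrate"`, `"oxygen"`, `"nitrite_only"`.
#' @return Predicted acceptor consumption in mmol, with attribute
#'   `"dissimilated_electrons"` (mmol e-).
#' @export
acceptor_demand <- function(substrate_mmol, substrate_gamma,
                            assimilated_c_mmol = 0,
                            biomass_gamma_per_c = 0,
                            acceptor = c("nitrate", "oxygen",
                                         "nitrite_only")) {
  acceptor <- match.arg(acceptor)
  stopifnot(substrate_mmol >= 0, assimilated_c_mmol >= 0)
  e_supply <- substrate_mmol * substrate_gamma
  e_assim <- assimilated_c_mmol * biomass_gamma_per_c
  e_diss <- e_supply - e_assim
  if (e_diss < -1e-9)
    stop("assimilated electrons exceed the substrate's supply", call. = FALSE)
  out <- max(e_diss, 0) / ACCEPTOR_ELECTRONS[[acceptor]]
  attr(out, "dissimilated_electrons") <- max(e_diss, 0)
  out
}

#' Carbon yield from measured deltas
#'
#' `yield % = 100 * (mol C in formed biomass) / (mol C in consumed
#' substrate)`, with biomass carbon from the cell dry weight and its C
#' content, per litre of culture.
#'
#' @param delta_cdw Cell dry weight formed, g/L.
#' @param biomass_c_wt_pct Biomass carbon content, wt%.
#' @param delta_substrate_mM Substrate consumed, mM.
#' @param n_c Carbon atoms per substrate molecule.
#' @return Yield in percent (mol C / mol C x 100).
#' @export
carbon_yield <- function(delta_cdw, biomass_c_wt_pct, delta_substrate_mM,
                         n_c) {
  if (delta_substrate_mM <= 0)
    stop("no substrate consumption", call. = FALSE)
  if (delta_cdw < 0)
    stop("negative biomass formation", call. = FALSE)
  biomass_c_mmol <- delta_cdw * (biomass_c_wt_pct / 100) / 12.011 * 1000
  substrate_c_mmol <- delta_substrate_mM * n_c
  100 * biomass_c_mmol / substrate_c_mmol
}

#' Physiological summary of one growth experiment
#'
#' Combines the exponential fit, the carbon yield and the electron ledger
#' into one record: growth rate and doubling time, biomass-specific carbon
#' and reducing-equivalent consumption rates, the dissimilated carbon
#' share, and the predicted acceptor demand for the measured substrate
#' consumption.
#'
#' @param curve A `"growth_curve"` with a substrate series.
#' @param substrate_formula,substrate_charge Substrate composition.
#' @param biomass_c_wt_pct Biomass carbon content, wt% (default 48).
#' @param biomass_gamma_per_c Biomass degree of reduction per mol C
#'   (default 4.07, from a typical CH1.77O0.49N0.24 cell formula).
#' @param acceptor `"nitrate"` or `"oxygen"`.
#' @param window Optional fit window for [fit_growth_rate()].
#' @return A list of class `"stoichiometry_summary"`.
#' @export
stoichiometry_summary <- function(curve, substrate_formula,
                                  substrate_charge = 0,
                                  biomass_c_wt_pct = 48,
                                  biomass_gamma_per_c = 4.07,
                                  acceptor = c("nitrate", "oxygen"),
                                  window = NULL) {
  acceptor <- match.arg(acceptor)
  if (is.null(curve$substrate_mM))
    stop("growth curve lacks a substrate series", call. = FALSE)
  fit <- fit_growth_rate(curve, window)
  n <- length(curve$time)
  delta_cdw <- (curve$od[n] - curve$od[1]) * curve$od_to_cdw
  delta_s <- curve$substrate_mM[1] - curve$substrate_mM[n]
  n_c <- unname(substrate_formula["C"])
  gamma_s <- degree_of_reduction(substrate_formula, substrate_charge)
  yield <- carbon_yield(delta_cdw, biomass_c_wt_pct, delta_s, n_c)
  ## biomass-specific rates at the fitted mu
  c_per_g <- (biomass_c_wt_pct / 100) / 12.011 * 1000   # mmol C per g CDW
  q_c <- fit$mu * c_per_g / (yield / 100)               # mmol C /gCDW/h
  q_h <- q_c / n_c * gamma_s                            # mmol e- /gCDW/h
  assim_c <- delta_cdw * c_per_g
  demand <- acceptor_demand(delta_s, gamma_s, assim_c, biomass_gamma_per_c,
                            acceptor)
  structure(list(mu = fit$mu, t_d = fit$t_d, r_squared = fit$r_squared,
                 q_c_per_x = q_c, q_h_per_x = q_h,
                 yield_cc = yield,
                 dissimilated_fraction = 100 - yield,
                 predicted_acceptor_mM = as.numeric(demand),
                 acceptor = acceptor),
            class = "stoichiometry_summary")
}
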