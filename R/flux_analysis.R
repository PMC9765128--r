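## Post-FBA analytics: metabolite-centric split ratios, cross-condition
## activity, flux-variation decomposition, hierarchical clustering.

#' Split-ratio analysis at a metabolite node
#'
#' At steady state every metabolite's total production equals its total
#' consumption; the split ratio of a reaction is its fractional
#' contribution to that turnover. Reversible reactions contribute to
#' production or consumption according to the sign of their flux, not
#' their declared direction.
#'
#' @param model A `"metabolic_model"`.
#' @param solution An optimal `"flux_solution"`.
#' @param metabolite_id The node to analyze.
#' @param threshold Fluxes with absolute contribution below this are
#'   ignored (default `1e-6` mmol gDW^-1 h^-1).
#' @return A list of class `"split_ratio_table"` with `metabolite_id`,
#'   `turnover` (total production flux), and data.frames `producers` and
#'   `consumers` (columns `reaction_id`, `flux`, `fraction` in percent).
#' @export
split_ratios <- function(model, solution, metabolite_id,
                         threshold = FLUX_EPS) {
  if (solution$status != "optimal")
    stop("split_ratios needs an optimal solution", call. = FALSE)
  if (!metabolite_id %in% metabolite_ids(model))
    stop("no metabolite '", metabolite_id, "' in model", call. = FALSE)
  prod <- cons <- list()
  for (rxn in model$reactions) {
    coef <- rxn$stoichiometry[metabolite_id]
    if (is.na(coef)) next
    rate <- unname(coef) * solution$fluxes[[rxn$id]]
    if (rate > threshold)
      prod[[length(prod) + 1L]] <- data.frame(reaction_id = rxn$id,
                                              flux = rate)
    else if (rate < -threshold)
      cons[[length(cons) + 1L]] <- data.frame(reaction_id = rxn$id,
                                              flux = -rate)
  }
  mk <- function(lst) {
    if (!length(lst))
      return(data.frame(reaction_id = character(), flux = numeric(),
                        fraction = numeric()))
    df <- do.call(rbind, lst)
    df <- df[order(-df$flux), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  producers <- mk(prod); consumers <- mk(cons)
  turnover <- sum(producers$flux)
  if (turnover > threshold) {
    producers$fraction <- 100 * producers$flux / turnover
    consumers$fraction <- 100 * consumers$flux / sum(consumers$flux)
  } else {
    turnover <- 0
    producers$fraction <- numeric(nrow(producers))
    consumers$fraction <- numeric(nrow(consumers))
  }
  structure(list(metabolite_id = metabolite_id, turnover = turnover,
                 producers = producers, consumers = consumers,
                 condition = solution$condition),
            class = "split_ratio_table")
}

#' @export
print.split_ratio_table <- function(x, ...) {
  cat("Split ratios at", x$metabolite_id,
      if (!is.na(x$condition)) paste0("(", x$condition, ")"),
      "- turnover", format(x$turnover, digits = 5), "mmol/gDW/h\n")
  cat("producers:\n"); print(x$producers, digits = 4)
  cat("consumers:\n"); print(x$consumers, digits = 4)
  invisible(x)
}

#' Reaction activity across conditions
#'
#' A reaction is active in a condition when its flux-variability range is
#' not identically zero beyond a threshold; activity is a property of the
#' range, never of a single degenerate FBA solution.
#'
#' @param ranges List of `"flux_range"` tables (one per condition), all
#'   over the same reaction set.
#' @param threshold Activity threshold on |min| and |max|.
#' @return A list of class `"activity_matrix"`: logical `active` matrix
#'   (reactions x conditions), `always_active` (logical per reaction), and
#'   `n_always_active`.
#' @export
activity_table <- function(ranges, threshold = FLUX_EPS) {
  stopifnot(length(ranges) >= 1L)
  ids <- ranges[[1]]$reaction_id
  for (k in seq_along(ranges)) {
    idk <- ranges[[k]]$reaction_id
    if (!setequal(idk, ids) || length(idk) != length(ids)) {
      diff <- union(setdiff(idk, ids), setdiff(ids, idk))
      stop("flux ranges disagree on the reaction set: ",
           paste(diff, collapse = ", "), call. = FALSE)
    }
  }
  labels <- vapply(seq_along(ranges), function(k) {
    lab <- attr(ranges[[k]], "condition")
    if (is.null(lab) || is.na(lab)) paste0("condition_", k) else lab
  }, "")
  act <- sapply(ranges, function(rg) {
    rg <- rg[match(ids, rg$reaction_id), ]
    abs(rg$min_flux) > threshold | abs(rg$max_flux) > threshold
  })
  dimnames(act) <- list(ids, labels)
  always <- rowSums(act) == ncol(act)
  structure(list(active = act, always_active = always,
                 n_always_active = sum(always)),
            class = "activity_matrix")
}

#' Share of cross-condition flux variation per reaction group
#'
#' The variation of a reaction is its max-minus-min flux across
#' conditions; a group's share is its summed variation over the total of
#' all reactions in the matrix.
#'
#' @param flux_matrix Numeric matrix, reactions (rows, named) x conditions.
#' @param groups Named list of reaction-id vectors; groups must not
#'   overlap.
#' @return Named numeric vector of shares (fractions of 1) with attribute
#'   `"undefined"` = TRUE when there is no variation at all (all shares
#'   NA).
#' @export
flux_variation_shares <- function(flux_matrix, groups) {
  stopifnot(is.matrix(flux_matrix), !is.null(rownames(flux_matrix)))
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("groups overlap: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(all_ids, rownames(flux_matrix))
  if (length(missing))
    stop("grouped reaction(s) not in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  variation <- apply(flux_matrix, 1, function(v) max(v) - min(v))
  total <- sum(variation)
  shares <- vapply(groups, function(ids) sum(variation[ids]) / total,
                   numeric(1))
  if (total < 1e-12) {
    shares[] <- NA_real_
    attr(shares, "undefined") <- TRUE
  } else attr(shares, "undefined") <- FALSE
  shares
}

#' Hierarchical clustering of condition flux profiles
#'
#' Conditions are clustered on their flux vectors, by default after
#' per-condition normalization by substrate carbon uptake so that
#' uptake-rate magnitudes do not dominate the metric.
#'
#' @param flux_matrix Numeric matrix, reactions x conditions (named
#'   columns).
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"ward.D2"`.
#' @param scale_by Optional positive numeric per condition (e.g. carbon
#'   uptake flux); each column is divided by it before clustering.
#' @return List of class `"condition_clustering"`: `hclust` (the tree),
#'   `cut2` (two-group labels, named by condition), `merge_heights`.
#' @export
cluster_conditions <- function(flux_matrix, metric = "euclidean",
                               linkage = "ward.D2", scale_by = NULL) {
  stopifnot(is.matrix(flux_matrix), ncol(flux_matrix) >= 2L)
  if (any(!is.finite(flux_matrix))) {
    bad <- which(!is.finite(flux_matrix), arr.ind = TRUE)[1, ]
    stop("non-finite flux for reaction '", rownames(flux_matrix)[bad[1]],
         "' in condition '", colnames(flux_matrix)[bad[2]], "'",
         call. = FALSE)
  }
  if (!is.null(scale_by)) {
    stopifnot(length(scale_by) == ncol(flux_matrix), all(scale_by > 0))
    flux_matrix <- sweep(flux_matrix, 2, scale_by, "/")
  }
  d <- stats::dist(t(flux_matrix), method = metric)
  hc <- stats::hclust(d, method = linkage)
  cut2 <- stats::cutree(hc, k = 2)
  structure(list(hclust = hc, cut2 = cut2, merge_heights = hc$height),
            class = "condition_clustering")
}
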