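## Transcriptional variance analysis: column scaling, non-negative matrix
## factorization into metagene expression types, explained-variance
## bookkeeping and the minimal-component selection rule.

#' Build a transcript matrix
#'
#' @param counts Non-negative numeric matrix, genes x conditions.
#' @param genes,conditions Row and column identifiers (defaults taken from
#'   dimnames).
#' @param scale One of `"raw"`, `"linear-normalized"`, `"log-normalized"`.
#' @return List of class `"transcript_matrix"`.
#' @export
transcript_matrix <- function(counts, genes = rownames(counts),
                              conditions = colnames(counts),
                              scale = "raw") {
  counts <- as.matrix(counts)
  scale <- match.arg(scale, c("raw", "linear-normalized", "log-normalized"))
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(counts)))
  if (is.null(conditions)) conditions <- paste0("c", seq_len(ncol(counts)))
  stopifnot(length(genes) == nrow(counts),
            length(conditions) == ncol(counts))
  dimnames(counts) <- list(genes, conditions)
  structure(list(counts = counts, genes = genes, conditions = conditions,
                 scale = scale),
            class = "transcript_matrix")
}

#' Scale a raw count matrix for factorization
#'
#' In `log` mode the transform `log(1 + c)` is applied entrywise first
#' (damping the highly expressed upper tail of the lognormal copy-number
#' distribution), then every condition's column is normalized to sum to 1.
#' In `linear` mode only the column normalization is applied.
#'
#' @param tm A `"transcript_matrix"` (raw counts).
#' @param mode `"linear"` or `"log"`.
#' @param count_floor Entries strictly below this raw count are zeroed
#'   before anything else (default 0, i.e. off; upstream RNA-seq
#'   pipelines often apply a raw-count cutoff such as 50).
#' @return A normalized `"transcript_matrix"`.
#' @export
prepare_matrix <- function(tm, mode = c("linear", "log"), count_floor = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(tm, "transcript_matrix"))
  x <- tm$counts
  if (count_floor > 0) x[x < count_floor] <- 0
  if (mode == "log") x <- log1p(x)
  cs <- colSums(x)
  if (any(cs == 0))
    stop("all-zero column(s): ",
         paste(tm$conditions[cs == 0], collapse = ", "), call. = FALSE)
  x <- sweep(x, 2, cs, "/")
  transcript_matrix(x, tm$genes, tm$conditions,
                    scale = if (mode == "log") "log-normalized"
                            else "linear-normalized")
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes the scaled transcript matrix `T` (genes x conditions) into
#' non-negative `W` (genes x m metagene weights) and `S` (m x conditions
#' metagene scores) minimizing the Frobenius loss `||T - W S||_F^2` with
#' the classical multiplicative update rules, keeping the best of several
#' random restarts. Deterministic given `(seed, restarts)`.
#'
#' @param tm A normalized `"transcript_matrix"`.
#' @param m Number of metagene expression types, `1 <= m <=
#'   min(genes, conditions)`.
#' @param seed Integer seed (mandatory: part of the result's provenance).
#' @param restarts Random initializations (default 10).
#' @param max_iter Update iterations per restart (default 2000).
#' @param tol Relative loss-change convergence tolerance (default 1e-6),
#'   checked every 10 iterations.
#' @param trace Record the loss after every update iteration (slower;
#'   default FALSE). The best restart's trace is returned as `trace`.
#' @return A list of class `"metagene_decomposition"`: `W`, `S`, `m`,
#'   `loss`, `seed`, `restarts`, `converged`, and optionally `trace`.
#' @export
fit_nmf <- function(tm, m, seed, restarts = 10, max_iter = 2000,
                    tol = 1e-6, trace = FALSE) {
  stopifnot(inherits(tm, "transcript_matrix"))
  if (tm$scale == "raw")
    stop("fit_nmf expects a prepared (normalized) matrix; see ",
         "prepare_matrix()", call. = FALSE)
  x <- tm$counts
  N <- nrow(x); M <- ncol(x)
  if (m < 1 || m > min(N, M))
    stop("m must be in 1..min(genes, conditions) = ", min(N, M),
         call. = FALSE)
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + 1000L * (r - 1L))
    W <- matrix(stats::runif(N * m, 0.1, 1), N, m) * sqrt(mean(x) / m)
    S <- matrix(stats::runif(m * M, 0.1, 1), m, M) * sqrt(mean(x) / m)
    loss_prev <- Inf
    converged <- FALSE
    losses <- if (trace) numeric(max_iter) else NULL
    for (it in seq_len(max_iter)) {
      S <- S * crossprod(W, x) / (crossprod(W) %*% S + eps)
      W <- W * (x %*% t(S)) / (W %*% tcrossprod(S) + eps)
      if (trace) losses[it] <- sum((x - W %*% S)^2)
      if (it %% 10 == 0) {
        loss <- if (trace) losses[it] else sum((x - W %*% S)^2)
        if (is.finite(loss_prev) &&
            (loss_prev - loss) <= tol * max(loss_prev, eps)) {
          converged <- TRUE
          break
        }
        loss_prev <- loss
      }
    }
    loss <- sum((x - W %*% S)^2)
    if (is.null(best) || loss < best$loss)
      best <- list(W = W, S = S, loss = loss, converged = converged,
                   trace = if (trace) losses[seq_len(it)] else NULL)
  }
  dimnames(best$W) <- list(tm$genes, paste0("metagene_", seq_len(m)))
  dimnames(best$S) <- list(paste0("metagene_", seq_len(m)), tm$conditions)
  structure(list(W = best$W, S = best$S, m = m, loss = best$loss,
                 seed = seed, restarts = restarts,
                 converged = best$converged, trace = best$trace),
            class = "metagene_decomposition")
}

#' Explained variance of a metagene decomposition
#'
#' Uncentered convention (a non-negative factorization has no intercept):
#' per condition `EV_j = 1 - ||T_j - (WS)_j||^2 / ||T_j||^2`, total
#' `EV = 1 - ||T - WS||_F^2 / ||T||_F^2`. The cumulative sequence refits
#' at ranks 1..m with the decomposition's own seed. Pathological fits
#' (worse than the zero reconstruction) are clipped at 0 and flagged.
#'
#' @param tm The normalized `"transcript_matrix"` that was factorized.
#' @param dec A `"metagene_decomposition"`.
#' @param cumulative Also refit at ranks `1..m` (default FALSE; refits
#'   cost one NMF run each).
#' @param centered Subtract column means first (sensitivity variant;
#'   default FALSE).
#' @return List of class `"variance_report"`: `total`, `per_condition`,
#'   `cumulative` (or NULL), `clipped`.
#' @export
explained_variance <- function(tm, dec, cumulative = FALSE,
                               centered = FALSE) {
  x <- tm$counts
  stopifnot(nrow(x) == nrow(dec$W), ncol(x) == ncol(dec$S))
  recon <- dec$W %*% dec$S
  if (centered) {
    mu <- colMeans(x)
    x <- sweep(x, 2, mu); recon <- sweep(recon, 2, mu)
  }
  denom <- colSums(x^2)
  if (any(denom == 0)) stop("zero-norm column", call. = FALSE)
  per_cond <- 1 - colSums((x - recon)^2) / denom
  total <- 1 - sum((x - recon)^2) / sum(x^2)
  clipped <- any(per_cond < 0) || total < 0
  per_cond <- pmax(per_cond, 0); total <- max(total, 0)
  cum <- NULL
  if (cumulative) {
    cum <- vapply(seq_len(dec$m), function(k) {
      f <- fit_nmf(tm, k, seed = dec$seed, restarts = dec$restarts)
      max(1 - sum((tm$counts - f$W %*% f$S)^2) / sum(tm$counts^2), 0)
    }, numeric(1))
    cum <- cummax(cum)    # nested reporting: EV cannot drop with rank
  }
  structure(list(total = total, per_condition = per_cond,
                 cumulative = cum, clipped = clipped),
            class = "variance_report")
}

#' Select the number of metagene expression types
#'
#' The smallest `m <= m_max` whose decomposition explains at least
#' `threshold` of the condition-wise variance in every condition; the
#' scan reuses the same seed at every rank for comparability.
#'
#' @param tm A normalized `"transcript_matrix"`.
#' @param threshold Condition-wise explained-variance requirement,
#'   in (0, 1); default 0.9.
#' @param m_max Largest rank to try (default `min(genes, conditions)`).
#' @param seed,restarts Passed to [fit_nmf()].
#' @return List with `m`, `fit` (the selected decomposition), `report`
#'   (its `"variance_report"`), and `scan` (min condition-wise EV per
#'   tried rank).
#' @export
select_components <- function(tm, threshold = 0.9,
                              m_max = min(nrow(tm$counts),
                                          ncol(tm$counts)),
                              seed, restarts = 10) {
  stopifnot(threshold > 0, threshold < 1)
  if (m_max < 1) stop("m_max must be >= 1", call. = FALSE)
  scan <- numeric(0)
  for (m in seq_len(m_max)) {
    f <- fit_nmf(tm, m, seed = seed, restarts = restarts)
    rep_ <- explained_variance(tm, f)
    scan[m] <- min(rep_$per_condition)
    if (scan[m] >= threshold)
      return(list(m = m, fit = f, report = rep_, scan = scan))
  }
  stop("no m <= ", m_max, " reaches condition-wise explained variance ",
       threshold, "; best attained ", round(max(scan), 4), call. = FALSE)
}

#' Ranked gene lists and score table of a decomposition
#'
#' @param dec A `"metagene_decomposition"`.
#' @param annotations Optional named character vector mapping gene id ->
#'   annotation text.
#' @param top_n Genes listed per metagene (capped at the gene count).
#' @return List with `top_genes` (one data.frame per metagene: gene,
#'   weight, annotation) and `score_table` (conditions x metagenes,
#'   transposed scores as drawn in heat maps).
#' @export
metagene_report <- function(dec, annotations = NULL, top_n = 20) {
  top_n <- min(top_n, nrow(dec$W))
  tops <- lapply(seq_len(dec$m), function(k) {
    ord <- order(dec$W[, k], decreasing = TRUE)[seq_len(top_n)]
    df <- data.frame(gene = rownames(dec$W)[ord],
                     weight = dec$W[ord, k], row.names = NULL)
    if (!is.null(annotations))
      df$annotation <- unname(annotations[df$gene])
    df
  })
  names(tops) <- colnames(dec$W)
  list(top_genes = tops, score_table = t(dec$S))
}

#' Match fitted metagenes to a planted truth by cosine similarity
#'
#' Best assignment over component permutations (exhaustive for the small
#' m used here), maximizing the mean cosine between fitted and true gene
#' weight columns.
#'
#' @param W Fitted weights (genes x m).
#' @param W_true Planted weights (genes x m).
#' @return Numeric vector: cosine similarity of each true component with
#'   its matched fitted component, with attribute `"permutation"`.
#' @export
match_components <- function(W, W_true) {
  m <- ncol(W_true)
  stopifnot(ncol(W) == m, nrow(W) == nrow(W_true))
  cs <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m))
    cs[a, b] <- sum(W[, a] * W_true[, b]) /
      sqrt(sum(W[, a]^2) * sum(W_true[, b]^2))
  perms <- all_permutations(m)
  best <- -Inf; best_v <- NULL; best_p <- NULL
  for (p in perms) {
    v <- cs[cbind(p, seq_len(m))]
    if (mean(v) > best) { best <- mean(v); best_v <- v; best_p <- p }
  }
  attr(best_v, "permutation") <- best_p
  best_v
}

all_permutations <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(m - 1))
    for (pos in seq_len(m))
      out[[length(out) + 1L]] <- append(p, m, after = pos - 1)
  out
}
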