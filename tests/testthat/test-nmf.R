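test_that("prepare_matrix normalizes columns in both modes", {
  tm <- transcript_matrix(cbind(a = c(1, 3)))
  lin <- prepare_matrix(tm, "linear")
  expect_equal(unname(lin$counts[, 1]), c(0.25, 0.75))
  tm2 <- transcript_matrix(cbind(a = c(0, exp(1) - 1)))
  lg <- prepare_matrix(tm2, "log")
  expect_equal(unname(lg$counts[, 1]), c(0, 1))
  ## idempotence: re-preparing a normalized matrix changes nothing
  lin2 <- prepare_matrix(lin, "linear")
  expect_equal(lin2$counts, lin$counts)
  expect_error(prepare_matrix(transcript_matrix(cbind(a = c(1, 1),
                                                      b = c(0, 0)))),
               "b")
})

test_that("the raw-count floor zeroes sub-threshold entries first", {
  tm <- transcript_matrix(cbind(a = c(10, 40, 50)))
  fl <- prepare_matrix(tm, "linear", count_floor = 50)
  expect_equal(unname(fl$counts[, 1]), c(0, 0, 1))
})

test_that("an exact rank-1 matrix is reconstructed at m = 1", {
  set.seed(2)
  w <- runif(30, 0.5, 2); s <- runif(6, 0.5, 2)
  tm <- prepare_matrix(transcript_matrix(outer(w, s)))
  fit <- fit_nmf(tm, 1, seed = 7)
  expect_lt(fit$loss, 1e-8)
  rep_ <- explained_variance(tm, fit)
  expect_equal(rep_$total, 1, tolerance = 1e-6)
})

test_that("m = M reproduces every column", {
  set.seed(8)
  tm <- prepare_matrix(transcript_matrix(matrix(runif(40, 0.1, 1), 10, 4)))
  fit <- fit_nmf(tm, 4, seed = 3, restarts = 5)
  rep_ <- explained_variance(tm, fit)
  expect_true(all(rep_$per_condition >= 1 - 1e-4))
})

test_that("explained variance has the right extremes and block closed form", {
  set.seed(4)
  tm <- prepare_matrix(transcript_matrix(matrix(runif(40, 0.1, 1), 10, 4)))
  perfect <- list(W = tm$counts, S = diag(4), m = 4, seed = 1, restarts = 1)
  rep_p <- explained_variance(tm, perfect)
  expect_equal(rep_p$total, 1)
  expect_equal(unname(rep_p$per_condition), rep(1, 4))
  zero <- list(W = matrix(0, 10, 1), S = matrix(0, 1, 4), m = 1,
               seed = 1, restarts = 1)
  expect_equal(explained_variance(tm, zero)$total, 0)

  ## orthogonal block matrix: EV of a fit reproducing only block A equals
  ## block A's share of the squared norm
  A <- matrix(c(2, 1), 2, 1) %*% t(c(1, 1))     # genes 1:2, conds 1:2
  B <- matrix(c(1, 3), 2, 1) %*% t(c(1, 2))     # genes 3:4, conds 3:4
  X <- rbind(cbind(A, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), B))
  tmb <- transcript_matrix(X, scale = "raw")
  tmb$scale <- "linear-normalized"   # keep raw values; test the algebra
  recon <- rbind(cbind(A, matrix(0, 2, 2)), matrix(0, 2, 4))
  dec <- list(W = recon, S = diag(4), m = 4, seed = 1, restarts = 1)
  ev <- explained_variance(tmb, dec)
  expect_equal(ev$total, sum(A^2) / sum(X^2), tolerance = 1e-12)
})

test_that("loss is non-increasing along the update trace", {
  g <- make_transcript_counts(transcript_sim_spec(n_genes = 120, m_true = 2,
                                                  seed = 5))
  tm <- prepare_matrix(g$tm)
  fit <- fit_nmf(tm, 2, seed = 5, restarts = 2, trace = TRUE)
  expect_true(all(diff(fit$trace) <= 1e-12 * (1 + fit$trace[-1])))
})

test_that("W and S stay non-negative and reproducible for a fixed seed", {
  g <- make_transcript_counts(transcript_sim_spec(n_genes = 80, m_true = 2,
                                                  seed = 6))
  tm <- prepare_matrix(g$tm)
  f1 <- fit_nmf(tm, 2, seed = 11, restarts = 3)
  f2 <- fit_nmf(tm, 2, seed = 11, restarts = 3)
  expect_true(all(f1$W >= 0) && all(f1$S >= 0))
  expect_identical(f1$W, f2$W)
  expect_identical(f1$loss, f2$loss)
})

test_that("explained variance is monotone in rank for shared seeds", {
  g <- make_transcript_counts(transcript_sim_spec(n_genes = 150, m_true = 3,
                                                  seed = 13))
  tm <- prepare_matrix(g$tm)
  evs <- vapply(1:4, function(m) {
    f <- fit_nmf(tm, m, seed = 13, restarts = 5)
    explained_variance(tm, f)$total
  }, numeric(1))
  ## allow a whisker of NMF non-optimality at each rank
  expect_true(all(diff(evs) >= -1e-3))
})

test_that("the cumulative report is nested and non-decreasing", {
  g <- make_transcript_counts(transcript_sim_spec(n_genes = 100, m_true = 2,
                                                  seed = 17))
  tm <- prepare_matrix(g$tm)
  f <- fit_nmf(tm, 3, seed = 17, restarts = 3)
  rep_ <- explained_variance(tm, f, cumulative = TRUE)
  expect_equal(length(rep_$cumulative), 3)
  expect_true(all(diff(rep_$cumulative) >= 0))
  expect_true(all(rep_$cumulative >= 0 & rep_$cumulative <= 1))
})

test_that("component selection hits rank 1 for a rank-1 matrix", {
  set.seed(19)
  tm <- prepare_matrix(transcript_matrix(outer(runif(40, 0.5, 2),
                                               runif(8, 0.5, 2))))
  sel <- select_components(tm, threshold = 0.9, seed = 19)
  expect_equal(sel$m, 1)
  expect_error(select_components(tm, threshold = 0.9, m_max = 0, seed = 1),
               "m_max")
})

test_that("column permutation permutes scores but preserves components", {
  g <- make_transcript_counts(transcript_sim_spec(n_genes = 200, m_true = 3,
                                                  noise_sd = 0, seed = 23))
  tm <- prepare_matrix(g$tm)
  perm <- c(3, 1, 2, 5, 4, 7, 6, 10, 9, 8)
  tm_p <- transcript_matrix(tm$counts[, perm], tm$genes,
                            tm$conditions[perm], scale = tm$scale)
  f1 <- fit_nmf(tm, 3, seed = 23, restarts = 5)
  f2 <- fit_nmf(tm_p, 3, seed = 23, restarts = 5)
  ## exact-rank input: the two fits land on essentially the same factors
  ## up to component order (a small tolerance absorbs the optimizer's
  ## path dependence on column order)
  cos <- match_components(f2$W, f1$W)
  expect_true(all(cos > 0.98))
})

test_that("metagene reports rank genes by weight", {
  W <- cbind(metagene_1 = c(0, 0, 1), metagene_2 = c(0.6, 0.3, 0.1))
  rownames(W) <- c("gA", "gB", "gC")
  S <- matrix(runif(4), 2, 2,
              dimnames = list(colnames(W), c("c1", "c2")))
  dec <- list(W = W, S = S, m = 2, seed = 1, restarts = 1)
  rep_ <- metagene_report(dec, top_n = 2)
  expect_equal(rep_$top_genes$metagene_1$gene[1], "gC")
  expect_equal(rep_$top_genes$metagene_2$gene[1], "gA")
  ## top_n larger than N returns the full ranking
  rep_full <- metagene_report(dec, top_n = 100)
  expect_equal(nrow(rep_full$top_genes$metagene_1), 3)
  expect_equal(dim(rep_$score_table), c(2, 2))
})

test_that("planted module members top their matched metagene", {
  spec <- transcript_sim_spec(n_genes = 150, m_true = 3, seed = 29)
  g <- make_transcript_counts(spec)
  tm <- prepare_matrix(g$tm)
  fit <- fit_nmf(tm, 3, seed = 29)
  cos <- match_components(fit$W, g$W_true)
  perm <- attr(cos, "permutation")
  rep_ <- metagene_report(fit, top_n = 10)
  for (k in seq_len(3)) {
    fitted_col <- perm[k]          # fitted component matched to truth k
    top <- rep_$top_genes[[fitted_col]]$gene
    truth_members <- rownames(g$W_true)[g$module == k]
    expect_gte(mean(top %in% truth_members), 0.8)
  }
})
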