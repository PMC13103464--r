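# Group inference: edge screening, components, NBS permutation behavior,
# RM-ANOVA against a sums-of-squares oracle, and multiplicity corrections.

test_that("edge-wise paired t matches the hand-computed toy case", {
  a <- lapply(1:3, function(s)
    connectivity_matrix(matrix(c(0, s, s, 0), 2), "hbo-z"))
  b <- lapply(1:3, function(s) connectivity_matrix(matrix(0, 2, 2), "hbo-z"))
  res <- paired_t_edges(a, b)
  expect_equal(res$t, sqrt(3) * 2 / 1, tolerance = 1e-10)   # 3.4641
  # identical conditions: all t zero, empty mask, zero-variance edges logged
  res0 <- paired_t_edges(a, a)
  expect_true(all(res0$t == 0))
  expect_false(any(res0$mask))
  expect_equal(res0$excluded, 1L)
  # a strong constant shift is suprathreshold
  set.seed(1)
  aa <- random_fc_stack(16, 6, cbind(1, 2), 0)
  bb <- lapply(aa, function(m) {
    m2 <- unclass(m); m2[1, 2] <- m2[2, 1] <- m2[1, 2] + 5 + rnorm(1, sd = 0.1)
    connectivity_matrix(m2, "hbo-z")
  })
  resd <- paired_t_edges(bb, aa)
  expect_true(resd$mask[1])   # edge (1,2) is the first upper-triangle edge
  expect_error(paired_t_edges(aa[1:2], aa[1:2]), "at least 3")
})

test_that("suprathreshold edges cluster into components sized by edge count", {
  cp <- components_from_edges(rbind(c(1, 2), c(2, 3), c(5, 6)), 6)
  expect_length(cp, 2)
  expect_setequal(vapply(cp, `[[`, integer(1), "size"), c(2L, 1L))
  tri <- components_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3)), 46)
  expect_length(tri, 1)
  expect_equal(tri[[1]]$size, 3L)
  single <- components_from_edges(rbind(c(4, 9)), 46)
  expect_equal(single[[1]]$size, 1L)
  expect_length(components_from_edges(logical(15), 6), 0)
})

test_that("NBS is deterministic in its seed and invariant to subject relabeling", {
  set.seed(2)
  a <- random_fc_stack(10, 8)
  b <- random_fc_stack(10, 8, cbind(c(1, 2, 3), c(2, 3, 4)), 1.2)
  r1 <- nbs(b, a, n_perm = 300, seed = 9)
  r2 <- nbs(b, a, n_perm = 300, seed = 9)
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_identical(vapply(r1$components, `[[`, numeric(1), "p"),
                   vapply(r2$components, `[[`, numeric(1), "p"))
  # relabeling subjects leaves the observed components identical and the
  # permutation p unchanged up to Monte-Carlo error
  perm <- sample(10)
  r4 <- nbs(b[perm], a[perm], n_perm = 2000, seed = 9)
  r5 <- nbs(b, a, n_perm = 2000, seed = 9)
  expect_equal(vapply(r4$components, `[[`, integer(1), "size"),
               vapply(r5$components, `[[`, integer(1), "size"))
  expect_lt(max(abs(vapply(r4$components, `[[`, numeric(1), "p") -
                      vapply(r5$components, `[[`, numeric(1), "p"))), 0.02)
  # identical conditions: no significant component
  r0 <- nbs(a, a, n_perm = 200, seed = 1)
  expect_length(r0$components, 0)
  expect_length(r0$null_distribution, 200)
  expect_warning(nbs(b, a, n_perm = 50, seed = 1), "coarse")
})

test_that("NBS detects a planted connected effect and its p-values use the +1 rule", {
  set.seed(3)
  edges <- cbind(1:5, 2:6)
  a <- random_fc_stack(16, 20)
  b <- random_fc_stack(16, 20, edges, 1.5)
  r <- nbs(b, a, n_perm = 500, seed = 5)
  sig <- r$components[vapply(r$components, `[[`, logical(1), "significant")]
  expect_gte(length(sig), 1)
  ps <- vapply(r$components, `[[`, numeric(1), "p")
  expect_true(all(ps >= 1 / 501 & ps <= 1))
})

test_that("RM-ANOVA F equals the sums-of-squares decomposition", {
  set.seed(4)
  for (k in 1:20) {
    v <- matrix(rnorm(16 * 3), 16, 3)
    res <- rm_anova(v)
    gm <- mean(v); cm <- colMeans(v); sm <- rowMeans(v)
    ss_cond <- 16 * sum((cm - gm)^2)
    ss_err <- sum((sweep(sweep(v, 2, cm), 1, sm) + gm)^2)
    expect_equal(res$F, (ss_cond / 2) / (ss_err / 30), tolerance = 1e-10)
    expect_equal(res$df1, 2); expect_equal(res$df2, 30)
  }
  # identical phase means per subject: F = 0, p = 1
  same <- matrix(rep(rnorm(5), 3), 5, 3)
  r0 <- rm_anova(same)
  expect_equal(r0$F, 0); expect_equal(r0$p, 1)
  # perfectly additive table: zero error mean square, flagged
  add <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  ra <- rm_anova(add)
  expect_true(ra$flagged)
  expect_equal(ra$p, 0)
  expect_error(rm_anova(matrix(1:4, 2, 2)), "at least 3")
})

test_that("RM-ANOVA p-values are calibrated under the exchangeable null", {
  set.seed(5)
  ps <- vapply(1:200, function(k) rm_anova(matrix(rnorm(12 * 3), 12, 3))$p,
               numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("BH-FDR rejects the documented step-up set and dominates raw p", {
  f <- fdr_bh(c(0.001, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(which(f$rejected), 1:3)
  expect_true(all(f$adjusted >= c(0.001, 0.02, 0.03, 0.5) - 1e-15))
  expect_false(any(fdr_bh(rep(1, 6))$rejected))
  one <- fdr_bh(0.04)
  expect_true(one$rejected)
  expect_equal(one$adjusted, 0.04)
  expect_length(fdr_bh(numeric(0))$adjusted, 0)
  # monotone in raw p
  p <- sort(runif(30))
  expect_true(all(diff(fdr_bh(p)$adjusted) >= -1e-15))
})

test_that("Bonferroni post hocs multiply by the number of pairs and cap at 1", {
  set.seed(6)
  v <- matrix(rnorm(30), 10, 3); colnames(v) <- c("pre", "on", "post")
  ph <- bonferroni_posthoc(v)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adjusted, pmin(1, ph$p_raw * 3))
  same <- cbind(pre = v[, 1], on = v[, 1], post = v[, 1])
  expect_true(all(bonferroni_posthoc(same)$p_adjusted == 1))
  shift <- cbind(pre = v[, 1], on = v[, 1] + 1)
  ps <- bonferroni_posthoc(shift)
  expect_true(ps$flagged[1])
  expect_equal(ps$p_adjusted[1], 0)
})

test_that("nodal RM-ANOVA corrects over the ROI family", {
  set.seed(7)
  arr <- array(rnorm(10 * 3 * 8), c(10, 3, 8),
               dimnames = list(NULL, c("pre", "on", "post"),
                               paste0("R", 1:8)))
  arr[, 2, 1] <- arr[, 2, 1] + 3   # one responsive node
  res <- nodal_rm_anova(arr)
  expect_equal(nrow(res), 8)
  expect_true(res$rejected[1])
  expect_true(all(res$p_fdr >= res$p - 1e-15))
})
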