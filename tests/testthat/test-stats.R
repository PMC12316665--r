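test_that("pearson reproduces exact and simulated correlations", {
  x <- c(1, 2, 3, 4, 5)
  ct <- pearson(x, 2 * x + 1)
  expect_equal(ct$r, 1)
  expect_lt(ct$p, 1e-6)
  set.seed(77)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(pearson(a, b)$r), 0.1)
  # symmetry and affine invariance with positive slope
  set.seed(78)
  u <- rnorm(30); w <- 0.4 * u + rnorm(30)
  expect_equal(pearson(u, w)$r, pearson(w, u)$r)
  expect_equal(pearson(3 * u + 2, w)$r, pearson(u, w)$r)
  # pairwise-complete deletion
  w2 <- w; w2[c(3, 9)] <- NA
  expect_equal(pearson(u, w2)$n, 28)
  expect_error(pearson(u, rep(1, 30)), "variance")
  expect_error(pearson(1:2, 1:2), "3")
})

test_that("kruskal-wallis matches a brute-force tie-corrected H", {
  gt <- list(a = c(1, 1, 2, 2, 3), b = c(2, 2, 3, 3, 3), c = c(1, 2, 2, 3, 1))
  kw <- kruskal_wallis(gt)
  expect_equal(kw$H, kw_brute_force(gt))
  g2 <- list(a = c(4, 7, 2, 9, 5), b = c(8, 11, 6, 13, 9), c = c(1, 3, 2, 5, 4))
  expect_equal(kruskal_wallis(g2)$H, kw_brute_force(g2))
  # identical groups: H = 0, p = 1
  kw0 <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
  # clearly separated groups are detected
  ks <- kruskal_wallis(list(a = 1:3, b = 10:12, c = 20:22))
  expect_lt(ks$p, 0.05)
  # invariance under strictly monotone transforms of the pooled data
  expect_equal(kruskal_wallis(lapply(g2, exp))$H, kruskal_wallis(g2)$H)
})

test_that("steel-dwass agrees with exact enumeration and wilcoxon at k = 2", {
  g <- list(a = c(4, 7, 2, 9, 5), b = c(8, 11, 6, 13, 9),
            c = c(1, 3, 2, 5, 4))
  pa <- steel_dwass(g, "asymptotic")
  pe <- steel_dwass(g, "exact")
  expect_lt(max(abs(pa$p - pe$p), na.rm = TRUE), 0.02)
  expect_equal(pa$p, t(pa$p))
  # the clearly separated pair has the smallest p
  expect_equal(min(pa$p, na.rm = TRUE), pa$p["b", "c"])
  # three identical groups: all pairwise p ~ 1
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  expect_true(all(steel_dwass(same)$p > 0.99, na.rm = TRUE))
  # k = 2 asymptotic p equals the normal-approximation wilcoxon p
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4); y <- c(2.0, 6.3, 5.5, 7.1, 6.6)
  s2 <- suppressWarnings(steel_dwass(list(x = x, y = y)))
  w <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(s2$p[1, 2], w$p.value, tolerance = 1e-10)
  expect_warning(steel_dwass(list(a = 1, b = c(2, 3), c = c(4, 5))), "size 1")
})

test_that("fisher exact tests enumerate hypergeometric tables", {
  f <- fisher_pairwise_bonferroni(matrix(c(5, 0, 0, 5), 2))
  expect_equal(f$p_overall, 2 / 252)
  # identical columns: p = 1
  expect_equal(fisher_pairwise_bonferroni(matrix(c(3, 4, 3, 4), 2))$p_overall, 1)
  # pairwise bonferroni: adjusted >= raw, capped at 1
  tab <- matrix(c(8, 1, 2, 7, 5, 4), 2,
                dimnames = list(NULL, c("g1", "g2", "g3")))
  f3 <- fisher_pairwise_bonferroni(tab)
  expect_equal(f3$n_pairs, 3L)
  for (ij in list(c(1, 2), c(1, 3), c(2, 3))) {
    raw <- stats::fisher.test(tab[, ij])$p.value
    nm <- paste(colnames(tab)[ij], collapse = " vs ")
    expect_gte(f3$p_pairwise[[nm]], raw)
    expect_lte(f3$p_pairwise[[nm]], 1)
    expect_equal(f3$p_pairwise[[nm]], min(1, 3 * raw))
  }
  expect_error(fisher_pairwise_bonferroni(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(fisher_pairwise_bonferroni(matrix(c(1.5, 1, 1, 1), 2)),
               "integer")
})

test_that("sensitivity and specificity count the confusion table", {
  ss <- sens_spec(c(0.9, 1.2, 1.4, 1.9), c(0, 0, 1, 1), 1.3)
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$specificity, 1)
  # perfectly separated with cutoff between the classes
  ss2 <- sens_spec(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE), 5)
  expect_equal(c(ss2$sensitivity, ss2$specificity), c(1, 1))
  # all below cutoff: nothing called positive
  ss3 <- sens_spec(c(1, 2, 3, 4), c(0, 1, 0, 1), 10)
  expect_equal(c(ss3$sensitivity, ss3$specificity), c(0, 1))
  # ties at the cutoff are positive
  ss4 <- sens_spec(c(1, 2), c(0, 1), 2)
  expect_equal(ss4$sensitivity, 1)
  expect_error(sens_spec(1:3, c(1, 1, 1), 2), "both classes")
})

test_that("correlate_indices returns a tidy grid of correlations", {
  set.seed(99)
  d <- data.frame(cov = rnorm(20), total = rnorm(20))
  d$e_prime <- 0.8 * scale(d$cov)[, 1] + 0.3 * rnorm(20)
  out <- correlate_indices(d, c("cov", "total"), "e_prime")
  expect_equal(nrow(out), 2)
  expect_equal(out$r[1], pearson(d$cov, d$e_prime)$r)
})
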