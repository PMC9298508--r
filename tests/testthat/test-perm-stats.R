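test_that("one-way ANOVA matches the t-squared identity and direction", {
  set.seed(15)
  x <- rnorm(12, 0, 1)
  y <- rnorm(12, 1.5, 1)
  res <- oneway_anova(c(x, y), rep(c("a", "b"), each = 12))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  # separated groups with tight noise -> tiny p
  res2 <- oneway_anova(c(1, 1.1, 0.9, 5, 5.1, 4.9),
                       rep(c("a", "b"), each = 3))
  expect_lt(res2$p_value, 1e-4)
  expect_error(oneway_anova(1:3, c("a", "a", "b")), "2 observations")
  expect_warning(oneway_anova(rep(1, 6), rep(c("a", "b"), each = 3)),
                 "undefined")
})

test_that("mann-whitney matches exhaustive enumeration at small n", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.4, 6.3, 1.9, 8.8)
  res <- mann_whitney_u(x, y)
  expect_true(res$exact)
  expect_equal(res$p_value, oracle_mw_exact_p(x, y), tolerance = 1e-12)
  # complete separation hits the U bounds
  lo <- mann_whitney_u(1:4, 11:14)
  expect_equal(unname(lo$U), 0)
  hi <- mann_whitney_u(11:14, 1:4)
  expect_equal(unname(hi$U), 16)
  # identical samples are not distinguishable
  same <- mann_whitney_u(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(same$p_value, 0.9)
})

test_that("permanova matches exhaustive enumeration on separated groups", {
  # two perfectly separated groups of 3: within-distance 0, between 1
  m <- matrix(1, 6, 6)
  m[1:3, 1:3] <- 0
  m[4:6, 4:6] <- 0
  diag(m) <- 0
  res <- permanova(m, rep(c("a", "b"), each = 3), exhaustive = TRUE)
  expect_equal(res$p_value, 2 / 20) # 2 label splits out of C(6,3) reach F
  expect_equal(res$R2, 1)
  expect_error(permanova(m, c("a", "a", "a", "a", "a", "b")),
               "single sample")
})

test_that("permanova agrees with vegan::adonis2 on the observed statistic", {
  set.seed(33)
  X <- matrix(rnorm(12 * 4), 12)
  rownames(X) <- paste0("s", 1:12)
  d <- dist(X)
  lab <- rep(c("a", "b", "c"), each = 4)
  ours <- permanova(d, lab, n_perm = 199, seed = 1)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = lab), permutations = 199)
  expect_equal(ours$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("permanova R2 is invariant to duplicating the design", {
  set.seed(44)
  X <- matrix(rnorm(8 * 3), 8)
  lab <- rep(c("a", "b"), each = 4)
  d1 <- as.matrix(dist(X))
  r1 <- permanova(d1, lab, n_perm = 49, seed = 1)$R2
  X2 <- rbind(X, X)
  d2 <- as.matrix(dist(X2))
  r2 <- permanova(d2, c(lab, lab), n_perm = 49, seed = 1)$R2
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("mantel matches exhaustive enumeration and hits r = 1 limits", {
  set.seed(6)
  X <- matrix(rnorm(4 * 3), 4)
  rownames(X) <- paste0("s", 1:4)
  d1 <- dist(X)
  d2 <- dist(matrix(rnorm(4 * 3), 4, dimnames = list(paste0("s", 1:4))))
  res <- mantel_test(d1, d2, exhaustive = TRUE)
  # oracle: enumerate all 24 orderings directly
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  v1 <- m1[upper.tri(m1)]
  perms <- rbind(
    c(1,2,3,4),c(1,2,4,3),c(1,3,2,4),c(1,3,4,2),c(1,4,2,3),c(1,4,3,2),
    c(2,1,3,4),c(2,1,4,3),c(2,3,1,4),c(2,3,4,1),c(2,4,1,3),c(2,4,3,1),
    c(3,1,2,4),c(3,1,4,2),c(3,2,1,4),c(3,2,4,1),c(3,4,1,2),c(3,4,2,1),
    c(4,1,2,3),c(4,1,3,2),c(4,2,1,3),c(4,2,3,1),c(4,3,1,2),c(4,3,2,1))
  rs <- apply(perms, 1, function(o) {
    mo <- m2[o, o]
    cor(v1, mo[upper.tri(mo)])
  })
  expect_equal(res$p_value, mean(rs >= res$statistic - 1e-12))
  # self-comparison and affine transforms give r = 1
  expect_equal(mantel_test(d1, d1, n_perm = 9, seed = 1)$statistic, 1)
  expect_equal(mantel_test(d1, 0.5 * as.matrix(d1) + 0,
                           n_perm = 9, seed = 1)$statistic, 1)
  expect_error(mantel_test(d1, dist(matrix(rnorm(10), 5))), "size")
})

test_that("mantel agrees with vegan::mantel on the observed statistic", {
  set.seed(61)
  d1 <- dist(matrix(rnorm(10 * 3), 10))
  d2 <- dist(matrix(rnorm(10 * 3), 10))
  ours <- mantel_test(d1, d2, n_perm = 99, seed = 2)
  ref <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(ours$statistic, ref$statistic, tolerance = 1e-10)
})

test_that("MRM recovers exact linear combinations and the mantel identity", {
  set.seed(71)
  n <- 10
  A <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  B <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  Y <- 2 * A + 3 * B + 1
  diag(Y) <- 0
  res <- mrm(Y, list(a = A, b = B), n_perm = 49, seed = 1)
  expect_equal(res$R2, 1, tolerance = 1e-9)
  est <- res$coefficients$estimate
  expect_equal(est[res$coefficients$term == "a"], 2, tolerance = 1e-9)
  expect_equal(est[res$coefficients$term == "b"], 3, tolerance = 1e-9)
  # single predictor: R2 equals the squared Mantel pearson r
  r <- mantel_test(A, B, n_perm = 9, seed = 1)$statistic
  expect_equal(mrm(A, list(b = B), n_perm = 9, seed = 1)$R2, r^2,
               tolerance = 1e-10)
  # collinear predictors are flagged
  expect_warning(mrm(Y, list(a = A, a2 = 2 * A), n_perm = 9, seed = 1),
                 "collinear")
})

test_that("linear regression recovers exact fits and is shift-covariant", {
  x <- c(1, 2, 3, 4, 5)
  # exact fit makes summary.lm warn about a perfect fit; that is the point
  res <- suppressWarnings(linear_regression(x, 2 * x + 1))
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(res$R2, 1)
  set.seed(20)
  x2 <- rnorm(30); y2 <- 0.5 * x2 + rnorm(30, 0, 0.3)
  a <- linear_regression(x2, y2)
  b <- linear_regression(x2 - mean(x2), y2)
  expect_equal(a$slope, b$slope)
  expect_equal(a$R2, b$R2)
  expect_equal(b$intercept, a$intercept + a$slope * mean(x2))
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("permutation p-values respect the add-one floor", {
  set.seed(80)
  d1 <- dist(matrix(rnorm(8 * 2), 8))
  res <- mantel_test(d1, d1, n_perm = 99, seed = 3)
  expect_gte(res$p_value, 1 / 100)
  pv <- permanova(d1, rep(c("a", "b"), each = 4), n_perm = 99, seed = 4)
  expect_gte(pv$p_value, 1 / 100)
  mm <- mrm(as.matrix(d1), list(x = as.matrix(d1)), n_perm = 99, seed = 5)
  expect_true(all(mm$coefficients$p_value >= 1 / 100, na.rm = TRUE))
})

test_that("permutation tests are invariant to sample order", {
  set.seed(90)
  X <- matrix(rnorm(10 * 3), 10, dimnames = list(paste0("s", 1:10), NULL))
  d <- as.matrix(dist(X))
  lab <- rep(c("a", "b"), each = 5)
  perm <- sample(10)
  r1 <- permanova(d, lab, n_perm = 199, seed = 7)
  r2 <- permanova(d[perm, perm], lab[perm], n_perm = 199, seed = 7)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_equal(r1$R2, r2$R2, tolerance = 1e-10)
})

test_that("enrichment ratio recovers planted fold-changes and nulls", {
  frame <- tibble::tibble(
    sample_id = paste0("s", 1:40),
    disturbance = rep(c("P", "C"), each = 20),
    surface = "G", block = rep(c("P1", "C1"), each = 20),
    site = rep(1:20, 2))
  cfg <- community_config(
    n_otus = 100,
    enriched_sets = list(list(group = "P:G", otus = paste0("otu", 1:20),
                              log2fc = 2)),
    seed = 55)
  ct <- generate_counts(frame, cfg, "bacteria")
  rep1 <- suppressMessages(
    enrichment_ratio(ct, frame, focal_group = "P:G", control_group = "C"))
  expect_equal(rep1$n_otus_tested, 100)
  expect_lt(abs(rep1$ratio - 0.20), 0.05)
  # focal = control labels (null): ratio stays near alpha/2
  null_frame <- dplyr::mutate(frame,
                              disturbance = rep(c("P", "C"), 20))
  cfg0 <- community_config(n_otus = 100, seed = 56)
  ct0 <- generate_counts(null_frame, cfg0, "bacteria")
  rep0 <- suppressMessages(
    enrichment_ratio(ct0, null_frame, focal_group = "P:G",
                     control_group = "C"))
  expect_lt(rep0$ratio, 0.1)
  # all-zero OTUs leave the denominator
  m <- cbind(as_count_matrix(ct)[, 1:10], dead = 0L)
  ctz <- count_table(m, "bacteria")
  expect_message(
    repz <- enrichment_ratio(ctz, frame, "P:G", "C"),
    "absent from both")
  expect_equal(repz$n_otus_tested, 10)
})

test_that("tidiers expose broom-shaped summaries", {
  set.seed(101)
  d <- dist(matrix(rnorm(8 * 2), 8))
  pv <- permanova(d, rep(c("a", "b"), each = 4), n_perm = 49, seed = 1)
  td <- tidy(pv)
  expect_true(all(c("statistic", "R2", "p.value") %in% names(td)))
  gl <- glance(pv)
  expect_equal(gl$n, 8)
  mt <- mantel_test(d, d, n_perm = 49, seed = 1)
  expect_equal(tidy(mt)$estimate, 1)
  reg <- linear_regression(1:5, c(1, 2, 3, 4, 5.1))
  expect_equal(nrow(tidy(reg)), 2)
  expect_equal(glance(reg)$nobs, 5)
})
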