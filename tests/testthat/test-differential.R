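# independent Welch oracle: textbook formulas at full double precision
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

test_that("Welch t handles textbook and degenerate cases", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4, tolerance = 1e-9)
  expect_equal(r$p, 0.0213, tolerance = 1e-3)

  # swapping the groups negates t and preserves p
  rr <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rr$t, -r$t)
  expect_equal(rr$p, r$p)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
  zz <- welch_t(c(5, 5, 5), c(5, 5))   # both constant, equal means
  expect_equal(zz$p, 1)
})

test_that("Welch t matches the high-precision oracle on random cases", {
  set.seed(7001)
  for (i in 1:100) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
    got <- welch_t(a, b)
    want <- welch_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("fold change is the plain ratio of group means", {
  expect_equal(fold_change(10, 5), 2.0)
  expect_equal(fold_change(5, 10), 0.5)
  expect_equal(fold_change(7, 7), 1.0)
  expect_error(fold_change(5, 0), "positive")
  expect_error(fold_change(5, -1), "positive")
})

test_that("PLS-DA extracts orthogonal scores and needs two classes", {
  set.seed(88)
  X <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("s", 1:30), paste0("v", 1:8)))
  y <- rep(c(0, 1), each = 15)
  X[y == 1, 1:3] <- X[y == 1, 1:3] + 2
  m <- fit_plsda(X, y, n_components = 3)
  g <- crossprod(m$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  expect_true(all(abs(colSums(m$weights^2) - 1) < 1e-12))  # unit-norm weights
  expect_error(fit_plsda(X, rep(1, 30)), "two classes")
})

test_that("permuted labels leave almost no class variance to explain", {
  set.seed(3120)
  X <- matrix(rnorm(60 * 5), 60, 5,
              dimnames = list(paste0("s", 1:60), paste0("v", 1:5)))
  y <- sample(rep(c(0, 1), each = 30))
  m <- fit_plsda(X, y, n_components = 2)
  expect_true(all(m$y_variance_explained < 0.15))
})

test_that("a single-component fit recovers the covariance direction", {
  set.seed(12)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(20, 1, 0.5); y[1:2] <- c(0, 1)  # ensure both classes
  m <- fit_plsda(X, y, n_components = 1, scale = FALSE)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  w_expected <- drop(crossprod(Xc, yc))
  w_expected <- w_expected / sqrt(sum(w_expected^2))
  expect_equal(drop(m$weights), w_expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("VIP follows its closed form and sums of squares equal p", {
  # single species: normalization forces VIP = 1
  one <- structure(list(weights = matrix(1, 1, 1), ssy = 2,
                        species = "only"), class = "pls_model")
  expect_equal(unname(vip(one)), 1)

  # one component with weights (0.8, 0.6): VIP = sqrt(2 * w^2)
  two <- structure(list(weights = matrix(c(0.8, 0.6), 2, 1), ssy = 5,
                        species = c("a", "b")), class = "pls_model")
  expect_equal(unname(vip(two)), c(sqrt(1.28), sqrt(0.72)), tolerance = 1e-12)

  none <- structure(list(weights = matrix(1, 1, 1), ssy = 0,
                         species = "x"), class = "pls_model")
  expect_error(vip(none), "VIP undefined")
})

test_that("sum of squared VIPs equals the species count on random fits", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(8:20, 1); p <- sample(3:12, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    y <- sample(rep(c(0, 1), length.out = n))
    m <- fit_plsda(X, y, n_components = sample(1:3, 1))
    v <- vip(m)
    expect_equal(sum(v^2), length(v), tolerance = 1e-8)
  }
})

test_that("the selection rule applies strict thresholds and a stable order", {
  recs <- data.frame(
    species_name = c("PC(20:4/0:0)", "lowfc", "edge", "tie_b", "tie_a"),
    fold_change = c(6.7425, 1.9, 2.01, 3.0, 3.0),
    vip = c(1.54297, 1.5, 1.11, 1.2, 1.3),
    p_value = c(4.729e-6, 0.001, 0.049, 0.01, 0.01),
    stringsAsFactors = FALSE
  )
  sel <- select_biomarkers(recs)
  expect_true("PC(20:4/0:0)" %in% sel$species_name)
  expect_false("lowfc" %in% sel$species_name)       # FC fails
  expect_true("edge" %in% sel$species_name)          # all strictly pass
  # fold-change descending, name ascending on ties
  expect_equal(sel$species_name,
               c("PC(20:4/0:0)", "tie_a", "tie_b", "edge"))
  # invariant to input order
  sel2 <- select_biomarkers(recs[sample(nrow(recs)), ])
  expect_equal(sel2, sel)

  # values exactly at a threshold are rejected (strict inequalities)
  at <- data.frame(species_name = "at", fold_change = 2.0, vip = 1.1,
                   p_value = 0.05, stringsAsFactors = FALSE)
  expect_equal(nrow(select_biomarkers(at)), 0L)
})

test_that("biomarker statistics combine t-test, fold change and VIP", {
  lib <- generate_library(77)
  set.seed(2024)
  n <- 12
  base <- rlnorm(nrow(lib), log(100), 0.5)
  X <- matrix(rlnorm(n * nrow(lib), log(rep(base, each = n)), 0.1),
              n, nrow(lib), dimnames = list(paste0("s", 1:n), lib$name))
  groups <- rep(c("premature", "mature"), each = 6)
  X[groups == "mature", 1] <- X[groups == "mature", 1] * 5  # planted marker
  tab <- biomarker_stats(as_intensity_matrix(X / rowSums(X), TRUE), groups)
  expect_s3_class(tab, "biomarker_table")
  expect_equal(tab$species_name, lib$name)
  expect_true(tab$selected[1])
  expect_gt(tab$fold_change[1], 2)
  expect_lt(tab$p_value[1], 0.05)
  expect_equal(which.max(tab$vip), 1L)
  expect_equal(sum(tab$selected), 1L)
})
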