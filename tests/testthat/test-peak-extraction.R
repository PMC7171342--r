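test_that("ppm error follows its definition, signed", {
  expect_equal(ppm_error(500.0025, 500.0), 5.0)
  expect_equal(ppm_error(500.0, 500.0), 0.0)
  expect_equal(ppm_error(760.99620, 761.0), -4.994, tolerance = 1e-3)
  expect_error(ppm_error(500, 0), "positive")
  expect_error(ppm_error(500, -10), "positive")
})

test_that("intensity extraction matches within tolerance and resolves ties", {
  lib <- tiny_library()
  sp <- lib[1, ]
  one <- data.frame(mz = sp$mz * (1 + 2e-6), rt = sp$expected_rt,
                    intensity = 1000)
  expect_equal(extract_intensity(one, sp), 1000)

  two <- data.frame(mz = sp$mz * (1 + c(2, -3) * 1e-6),
                    rt = rep(sp$expected_rt, 2), intensity = c(800, 1200))
  expect_equal(extract_intensity(two, sp), 1200)          # max rule
  expect_equal(extract_intensity(two, sp, multiple = "sum"), 2000)

  far <- data.frame(mz = sp$mz * (1 + 6e-6), rt = sp$expected_rt,
                    intensity = 500)
  expect_equal(extract_intensity(far, sp), 0)

  # the ppm boundary is inclusive: a peak sitting exactly at the tolerance
  # (as computed by ppm_error itself) still matches
  edge <- data.frame(mz = sp$mz * (1 + 5e-6), rt = sp$expected_rt,
                     intensity = 77)
  tol <- abs(ppm_error(edge$mz, sp$mz))
  expect_equal(extract_intensity(edge, sp, ppm_tol = tol), 77)

  # outside the RT window
  late <- data.frame(mz = sp$mz, rt = sp$expected_rt + 0.5, intensity = 99)
  expect_equal(extract_intensity(late, sp), 0)
  expect_equal(extract_intensity(empty_peaks(), sp), 0)
})

test_that("matrix building honours shape, order and absences", {
  lib <- tiny_library()
  pls <- list(
    s1 = peaks_at(lib, intensities = 1:8),
    s2 = peaks_at(lib, intensities = rep(10, 8)),
    s3 = empty_peaks()
  )
  mat <- build_matrix(pls, lib)
  expect_equal(dim(mat), c(3L, 8L))
  expect_identical(colnames(mat), lib$name)
  expect_identical(rownames(mat), c("s1", "s2", "s3"))
  expect_equal(unname(mat["s3", ]), rep(0, 8))
  expect_false(is_normalized(mat))

  # permuting peak rows within a sample changes nothing
  shuffled <- pls
  shuffled$s1 <- pls$s1[sample(nrow(pls$s1)), ]
  expect_equal(build_matrix(shuffled, lib), mat)

  # permuting samples permutes rows identically
  perm <- build_matrix(pls[c(3, 1, 2)], lib)
  strip <- function(m) { m <- unclass(m); attr(m, "normalized") <- NULL; m }
  expect_equal(strip(perm), strip(mat)[c(3, 1, 2), ])

  expect_error(build_matrix(stats::setNames(pls, c("a", "a", "b")), lib),
               "duplicate")
  expect_error(build_matrix(list(), lib), "at least one")
})

test_that("TIC normalization rescales rows to unit sum and is idempotent", {
  lib <- tiny_library()
  m <- matrix(c(2, 2, 4, 0, 0, 0, 1, 1,
                1, 2, 3, 4, 5, 6, 7, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), lib$name))
  m <- as_intensity_matrix(m)
  n <- tic_normalize(m)
  expect_equal(unname(n["a", 1:3]), c(0.2, 0.2, 0.4))
  expect_equal(unname(rowSums(n)), c(1, 1))
  expect_true(is_normalized(n))
  expect_equal(unclass(tic_normalize(n)), unclass(n))  # idempotent
  # scale invariance is exact
  m2 <- m; m2["a", ] <- m2["a", ] * 1337
  expect_identical(unclass(tic_normalize(m2))["a", ], unclass(n)["a", ])
  # all-zero row names the sample
  m3 <- m; m3["b", ] <- 0
  expect_error(tic_normalize(m3), "b")
})

test_that("QC CVs use the n-1 standard deviation and class averaging", {
  lib <- tiny_library()
  reps <- matrix(100, nrow = 3, ncol = 8,
                 dimnames = list(paste0("QC", 1:3), lib$name))
  reps[, 1] <- c(90, 100, 110)       # sd 10, mean 100 -> CV 10%
  reps[, 5] <- c(100, 100, 100)      # CV 0
  reps[, 8] <- 0                     # zero mean -> NA, excluded
  rep_obj <- qc_cv(as_intensity_matrix(reps), lib)
  expect_equal(unname(rep_obj$per_species_cv[1]), 10.0)
  expect_equal(unname(rep_obj$per_species_cv[5]), 0.0)
  expect_true(is.na(rep_obj$per_species_cv[8]))
  # PC class: species 1 has CV 10, species 2-4 have CV 0 -> mean 2.5
  expect_equal(unname(rep_obj$class_average_cv[["PC"]]), 2.5)
  expect_true(is.nan(rep_obj$class_average_cv[["Cer"]]))
  expect_error(qc_cv(as_intensity_matrix(reps[1, , drop = FALSE]), lib),
               "2 QC replicates")
})

test_that("class average is the arithmetic mean of member CVs", {
  lib <- tiny_library()
  reps <- matrix(100, nrow = 4, ncol = 8,
                 dimnames = list(paste0("QC", 1:4), lib$name))
  reps[, 5] <- c(98, 100, 100, 102) # SM 1
  reps[, 6] <- c(96, 100, 100, 104) # SM 2, CV twice SM 1
  rep_obj <- qc_cv(as_intensity_matrix(reps), lib)
  cvs <- rep_obj$per_species_cv[5:6]
  expect_equal(unname(rep_obj$class_average_cv[["SM"]]), mean(cvs))
  expect_equal(rep_obj$sphingomyelin_average_cv, mean(cvs))
})

test_that("PCA scores are orthogonal and match an SVD oracle", {
  set.seed(421)
  x <- matrix(rnorm(20), nrow = 5, ncol = 4,
              dimnames = list(paste0("s", 1:5), paste0("v", 1:4)))
  res <- pca_scores(as_intensity_matrix(x), n_components = 3,
                    scaling = "center")
  # orthogonality
  g <- crossprod(res$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  # independent oracle: scores are U %*% D of the centered matrix's SVD
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  oracle <- sv$u %*% diag(sv$d)
  for (k in 1:3) {
    same <- max(abs(res$scores[, k] - oracle[, k]))
    flipped <- max(abs(res$scores[, k] + oracle[, k]))
    expect_lt(min(same, flipped), 1e-10)
  }
  # explained variance is non-increasing
  expect_true(all(diff(res$explained_variance) <= 1e-12))
})

test_that("PCA flags rank deficiency and constant columns", {
  profile <- c(1, 2, 3, 4)
  x <- outer(c(1, 2, 3.5, 0.2), profile)  # rank 1
  dimnames(x) <- list(paste0("s", 1:4), paste0("v", 1:4))
  res <- pca_scores(as_intensity_matrix(x), n_components = 2,
                    scaling = "center")
  expect_lt(res$explained_variance[2], 1e-9)

  xc <- x; xc[, 2] <- 7  # constant column breaks unit-variance scaling
  expect_error(pca_scores(as_intensity_matrix(xc), 2, "unit_variance"), "v2")
  expect_error(pca_scores(as_intensity_matrix(x), 10), "n_components")
})
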