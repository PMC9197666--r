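test_that("gaussian_weight matches its closed form and is symmetric", {
  expect_equal(gaussian_weight(c(0, 0, 0), 3.7), 1)
  # ||delta|| = M gives exp(-1/2)
  expect_equal(gaussian_weight(c(2, 0, 0), 2), exp(-0.5))
  expect_equal(gaussian_weight(c(1, 1, 1) / sqrt(3) * 5, 5), exp(-0.5))
  # per-axis bandwidth divides componentwise
  expect_equal(gaussian_weight(c(2, 3, 4), c(2, 3, 4)),
               exp(-3 / 2))
  # even function: w(d) = w(-d)
  set.seed(99)
  for (i in 1:100) {
    d <- rnorm(3, sd = 3)
    expect_identical(gaussian_weight(d, 1.5), gaussian_weight(-d, 1.5))
  }
  expect_error(gaussian_weight(c(NA, 0, 0), 1), "finite")
  expect_error(gaussian_weight(c(0, 0, 0), -1), "positive")
})

test_that("build_local_system gathers the cube with the parity convention", {
  # fully filled 5^3 volume, then empty its center voxel
  g <- recon_grid(c(0, 0, 0), c(1, 1, 1), c(5, 5, 5))
  a <- array(runif(125), c(5, 5, 5))
  vol <- recon_volume(g, a, array(TRUE, c(5, 5, 5)),
                      array(1L, c(5, 5, 5)))
  vol$filled[3, 3, 3] <- FALSE
  vol$intensity[3, 3, 3] <- NA
  vol$count[3, 3, 3] <- 0L

  # ksize 3: all 26 face/edge/corner neighbours, offsets in {-1,0,1}^3
  sys <- build_local_system(vol, c(2, 2, 2), kernel_params(ksize = 3))
  expect_equal(sys$n, 26L)
  expect_true(all(sys$design[, 1] == 1))
  expect_true(all(sys$design[, 2:4] %in% c(-1, 0, 1)))
  expect_false(any(rowSums(abs(sys$design[, 2:4])) == 0))

  # ksize 4 (even): offsets span {-2,-1,0,1}; brute-force candidate count
  sys4 <- build_local_system(vol, c(2, 2, 2), kernel_params(ksize = 4))
  brute <- expand.grid(-2:1, -2:1, -2:1)
  brute <- brute[rowSums(abs(brute)) > 0, ]
  in_grid <- rowSums(cbind(brute[, 1] + 2 >= 0 & brute[, 1] + 2 < 5,
                           brute[, 2] + 2 >= 0 & brute[, 2] + 2 < 5,
                           brute[, 3] + 2 >= 0 & brute[, 3] + 2 < 5)) == 3
  expect_equal(nrow(brute), 4^3 - 1)
  expect_equal(sys4$n, sum(in_grid))
  expect_true(all(sys4$design[, 2:4] >= -2 & sys4$design[, 2:4] <= 1))

  # no filled voxels in the cube yields an empty system
  empty_vol <- recon_volume(g, array(NA_real_, c(5, 5, 5)),
                            array(FALSE, c(5, 5, 5)),
                            array(0L, c(5, 5, 5)))
  expect_equal(build_local_system(empty_vol, c(2, 2, 2),
                                  kernel_params())$n, 0L)

  # distances are world mm: anisotropic spacing scales the design
  g2 <- recon_grid(c(0, 0, 0), c(0.5, 1, 2), c(5, 5, 5))
  vol2 <- vol; vol2$grid <- g2
  s2 <- build_local_system(vol2, c(2, 2, 2),
                           kernel_params(ksize = 3, bandwidth = 1))
  expect_true(all(s2$design[, 2] %in% c(-0.5, 0, 0.5)))
  expect_true(all(s2$design[, 4] %in% c(-2, 0, 2)))

  expect_error(build_local_system(vol, c(5, 0, 0), kernel_params()),
               "outside")
})

test_that("local regression reproduces constants, affine fields and the weighted mean", {
  sys <- random_local_system(12, seed = 1)

  # constant neighbour values give back the constant at any order
  sys_c <- sys; sys_c$values <- rep(4.25, 12)
  expect_equal(solve_local_regression(sys_c, kernel_params())$estimate,
               4.25, tolerance = 1e-10)
  expect_equal(solve_local_regression(
    sys_c, kernel_params(order = 0))$estimate, 4.25, tolerance = 1e-12)

  # local-linear exactness: values a + b . d recover intercept a
  a <- 3.5; b <- c(0.8, -1.2, 0.4)
  sys_l <- sys
  sys_l$values <- a + drop(sys_l$design[, 2:4] %*% b)
  fit <- solve_local_regression(sys_l, kernel_params(ridge = 0))
  expect_equal(fit$estimate, a, tolerance = 1e-8)
  expect_equal(fit$coefficients[-1], b, tolerance = 1e-8,
               ignore_attr = TRUE)

  # order 0 is the closed-form weighted mean
  est0 <- solve_local_regression(sys, kernel_params(order = 0))$estimate
  expect_equal(est0, sum(sys$weights * sys$values) / sum(sys$weights),
               tolerance = 1e-14)
})

test_that("solver matches the brute-force normal-equations oracle", {
  for (seed in 1:100) {
    n <- sample(5:30, 1)
    sys <- random_local_system(n, seed = seed)
    fit <- solve_local_regression(sys, kernel_params(min_neighbors = 4,
                                                     ridge = 0))
    expect_equal(fit$status, "ok")
    oracle <- oracle_wls(sys$design, sys$weights, sys$values)
    expect_equal(fit$estimate, oracle[1], tolerance = 1e-8)
  }
})

test_that("insufficient support and degenerate geometry are signalled", {
  sys3 <- random_local_system(3, seed = 5)
  expect_equal(solve_local_regression(sys3, kernel_params())$status,
               "insufficient_support")
  expect_equal(solve_local_regression(
    sys3, kernel_params(order = 0, min_neighbors = 5))$status,
    "insufficient_support")

  # coplanar neighbours (all d3 = 0) cannot identify the out-of-plane
  # slope, and an unidentified slope would bias the intercept by the
  # field gradient times the plane offset, so the system is flagged
  # degenerate with or without the tiny default ridge
  sys <- random_local_system(10, seed = 6)
  sys$design[, 4] <- 0
  fit <- solve_local_regression(sys, kernel_params(min_neighbors = 4,
                                                   ridge = 0))
  expect_equal(fit$status, "degenerate")
  fit_r <- solve_local_regression(sys, kernel_params(min_neighbors = 4))
  expect_equal(fit_r$status, "degenerate")
})

test_that("order-0 estimates stay within the neighbour value range", {
  for (seed in 1:1000) {
    sys <- random_local_system(sample(1:15, 1), seed = seed)
    est <- solve_local_regression(sys, kernel_params(order = 0))$estimate
    expect_gte(est, min(sys$values))
    expect_lte(est, max(sys$values))
  }
})

make_affine_volume <- function(dims = c(7, 7, 7), origin = c(0, 0, 0),
                               spacing = c(1, 1, 1),
                               a = 2, b = c(0.5, -0.25, 1)) {
  g <- recon_grid(origin, spacing, dims)
  idx <- as.matrix(expand.grid(seq_len(dims[1]) - 1L,
                               seq_len(dims[2]) - 1L,
                               seq_len(dims[3]) - 1L))
  vals <- evaluate_phantom(phantom_spec("affine", a = a, b = b),
                           voxel_to_world(idx, g))
  recon_volume(g, array(vals, dims), array(TRUE, dims),
               array(1L, dims))
}

poke_holes <- function(vol, lin) {
  vol$filled[lin] <- FALSE
  vol$intensity[lin] <- NA
  vol$count[lin] <- 0L
  vol$provenance[lin] <- 0L
  vol
}

test_that("reconstruct_volume is a no-op on full input and fills holes exactly", {
  vol <- make_affine_volume()
  rec <- reconstruct_volume(vol, kernel_params())
  expect_identical(rec$intensity, vol$intensity)
  expect_equal(fill_report(rec)$filled_by_kr, 0L)

  # a single hole surrounded by a constant field refills with it
  cvol <- vol
  cvol$intensity[] <- 8
  cvol <- poke_holes(cvol, 172)  # an interior voxel
  rec_c <- reconstruct_volume(cvol, kernel_params())
  expect_equal(rec_c$intensity[172], 8, tolerance = 1e-10)
  expect_equal(rec_c$provenance[172], 2L)

  # a hole in an affine field refills with the field value (order 1)
  hole <- c(3, 3, 3)
  lin <- 1 + hole[1] + 7 * (hole[2] + 7 * hole[3])
  avol <- poke_holes(vol, lin)
  for (engine in c("cpp", "r")) {
    rec_a <- reconstruct_volume(avol, kernel_params(ridge = 0),
                                engine = engine)
    truth <- evaluate_phantom(phantom_spec("affine", a = 2,
                                           b = c(0.5, -0.25, 1)),
                              voxel_to_world(hole, vol$grid))
    expect_equal(rec_a$intensity[lin], truth, tolerance = 1e-8)
  }
})

test_that("compiled and reference engines agree voxel for voxel", {
  set.seed(21)
  g <- recon_grid(c(0, 0, 0), c(1, 0.8, 1.2), c(10, 10, 10))
  cl <- sample_cloud(
    cbind(runif(400, 0, 9), runif(400, 0, 7.2), runif(400, 0, 10.8)),
    runif(400, 0, 100))
  vol <- bin_fill(cl, g)
  for (fb in c("order0", "expand_once", "leave_empty")) {
    p <- kernel_params(ksize = 3, fallback = fb)
    rc <- reconstruct_volume(vol, p, engine = "cpp")
    rr <- reconstruct_volume(vol, p, engine = "r")
    expect_identical(rc$provenance, rr$provenance)
    expect_equal(rc$intensity, rr$intensity, tolerance = 1e-10)
  }
})

test_that("estimates depend only on the pre-pass state (single-pass purity)", {
  set.seed(31)
  g <- recon_grid(c(0, 0, 0), c(1, 1, 1), c(8, 8, 8))
  cl <- sample_cloud(matrix(runif(900, 0, 7), ncol = 3), runif(300, 0, 50))
  vol <- bin_fill(cl, g)
  p <- kernel_params(ksize = 3, fallback = "leave_empty")
  rec <- reconstruct_volume(vol, p)
  # every regression-filled voxel must match an isolated re-solve
  # against the original (pre-pass) volume
  kr <- which(rec$provenance == 2L, arr.ind = TRUE) - 1L
  resolved <- kernel_params(ksize = 3, fallback = "leave_empty",
                            bandwidth = 3 * g$spacing / 4)
  for (r in seq_len(min(nrow(kr), 50))) {
    sys <- build_local_system(vol, kr[r, ], resolved)
    fit <- solve_local_regression(sys, resolved)
    lin <- 1 + kr[r, 1] + 8 * (kr[r, 2] + 8 * kr[r, 3])
    expect_equal(rec$intensity[lin], fit$estimate, tolerance = 1e-10)
  }
})

test_that("estimates are invariant to world translation and affine intensity maps", {
  set.seed(41)
  g <- recon_grid(c(0, 0, 0), c(1, 1, 1), c(8, 8, 8))
  cl <- sample_cloud(matrix(runif(600, 0, 7), ncol = 3), runif(200, 0, 9))
  vol <- bin_fill(cl, g)
  p <- kernel_params(ksize = 3)
  rec <- reconstruct_volume(vol, p)

  # translation: shift grid origin and cloud together
  shift <- c(103.5, -47.25, 9)
  g2 <- recon_grid(g$origin + shift, g$spacing, g$dims)
  cl2 <- sample_cloud(sweep(cl$positions, 2, shift, "+"), cl$intensities)
  rec2 <- reconstruct_volume(bin_fill(cl2, g2), p)
  expect_identical(rec$provenance, rec2$provenance)
  expect_equal(rec$intensity, rec2$intensity, tolerance = 1e-10)

  # intensity linearity: alpha * v + beta commutes with reconstruction
  alpha <- 2.5; beta <- -7
  cl3 <- sample_cloud(cl$positions, alpha * cl$intensities + beta)
  rec3 <- reconstruct_volume(bin_fill(cl3, g), p)
  expect_equal(rec3$intensity, alpha * rec$intensity + beta,
               tolerance = 1e-10)
})

test_that("huge bandwidth reduces order 0 to the unweighted neighbourhood mean", {
  g <- recon_grid(c(0, 0, 0), c(1, 1, 1), c(5, 5, 5))
  set.seed(51)
  a <- array(runif(125, 0, 10), c(5, 5, 5))
  vol <- recon_volume(g, a, array(TRUE, c(5, 5, 5)),
                      array(1L, c(5, 5, 5)))
  vol <- poke_holes(vol, 63)  # center voxel (2,2,2)
  p <- kernel_params(ksize = 3, order = 0, bandwidth = 1e6 * 5)
  rec <- reconstruct_volume(vol, p)
  nb <- a[2:4, 2:4, 2:4]
  expect_equal(rec$intensity[63], mean(nb[-14]), tolerance = 1e-6)
})

test_that("kernel_params validates its arguments", {
  expect_error(kernel_params(ksize = 1), "ksize")
  expect_error(kernel_params(order = 2), "order")
  expect_error(kernel_params(order = 1, min_neighbors = 3),
               "min_neighbors >= 4")
  expect_error(kernel_params(bandwidth = -1), "bandwidth")
  expect_error(kernel_params(ridge = -1), "ridge")
})
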