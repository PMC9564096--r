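test_that("the default bank has 18 DC-free filters over evenly spaced orientations", {
  bank <- test_bank()
  expect_equal(bank$n, 18L)
  expect_equal(sort(unique(bank$filters$orientation)),
               (0:5) * pi / 6, tolerance = 1e-12)
  kerns <- gabor_kernels(bank)
  expect_lt(max(vapply(kerns, function(k) abs(sum(k)), numeric(1))), 1e-3)
})

test_that("a filter at orientation theta + pi/2 is the transpose of the theta filter", {
  bank <- test_bank()
  i0 <- which(bank$filters$orientation == 0 &
                bank$filters$wavelength == bank$config$wavelengths[1])
  i90 <- which(abs(bank$filters$orientation - pi / 2) < 1e-9 &
                 bank$filters$wavelength == bank$config$wavelengths[1])
  kerns <- gabor_kernels(bank)
  expect_equal(kerns[[i90]], t(kerns[[i0]]), tolerance = 1e-12)
})

test_that("place tokens are linear and vanish on constant patches", {
  bank <- test_bank()
  img1 <- textured_image(101, seed = 2)
  img2 <- textured_image(101, seed = 3)
  c0 <- c(50, 50)
  p1 <- image_patch(img1, c0, bank = bank)
  p2 <- image_patch(img2, c0, bank = bank)
  pc <- p1; pc$values <- matrix(0.7, bank$side, bank$side)
  # DC residual comes from the analytic correction plus support truncation
  expect_lt(max(abs(place_token(pc, bank))), 5e-3 * 0.7)
  mix <- p1; mix$values <- 2.5 * p1$values - 0.5 * p2$values
  expect_equal(place_token(mix, bank),
               2.5 * place_token(p1, bank) - 0.5 * place_token(p2, bank),
               tolerance = 1e-8)
})

test_that("a pure sinusoid at a bank frequency drives its matched filter hardest", {
  bank <- test_bank()
  lam <- bank$config$wavelengths[2]
  img <- matrix(0, 101, 101)
  xs <- rep(0:100, each = 101)
  img[] <- 0.5 + 0.2 * cos(2 * pi / lam * xs)
  p <- image_patch(img, c(50, 50), bank = bank)
  tok <- place_token(p, bank)
  matched <- which(bank$filters$orientation == 0 &
                     bank$filters$wavelength == lam)
  expect_equal(which.max(abs(tok)), matched)
})

test_that("warped tokens reduce to place tokens at the identity and commute with shifts", {
  bank <- test_bank()
  img <- textured_image(151, seed = 4)
  p <- image_patch(img, c(75, 75), bank = bank)
  expect_equal(warped_token(p, bank, affine_identity()),
               place_token(p, bank), tolerance = 1e-12)
  # pure integer shift: token equals the re-centred place token exactly
  sh <- affine_params(tx = 3, ty = -2)
  p_shift <- image_patch(img, c(78, 73), bank = bank)
  expect_equal(warped_token(p, bank, sh), place_token(p_shift, bank),
               tolerance = 1e-10)
})

test_that("tokens are affine-invariant through the conjugate warp (within 5%)", {
  bank <- test_bank()
  set.seed(11)
  worst <- 0
  for (trial in 1:15) {
    # texture with its pass band at the bank's coarser wavelengths, where
    # resampling is faithful; content near the finest wavelength is
    # attenuated by any interpolator
    img <- textured_image(181, seed = 100 + trial, s1 = 1.8, s2 = 3.2)
    ctr <- c(90, 90)
    p1 <- image_patch(img, ctr, bank = bank)
    th <- runif(1, -0.08, 0.08); sc <- runif(1, 0.93, 1.07)
    shr <- runif(1, -0.04, 0.04)
    A <- sc * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                     byrow = TRUE) %*%
      matrix(c(1, shr, 0, 1), 2, 2, byrow = TRUE)
    tr <- runif(2, -3, 3)
    a <- affine_params(A[1, 1], A[1, 2], A[2, 1], A[2, 2], tr[1], tr[2])
    img2 <- apply_affine(img, a, center = ctr, clamp = TRUE)
    p2 <- image_patch(img2, ctr, bank = bank)
    g1 <- place_token(p1, bank)
    g2 <- warped_token(p2, bank, a)
    worst <- max(worst, sqrt(sum((g2 - g1)^2) / sum(g1^2)))
  }
  expect_lt(worst, 0.05)
})

test_that("every Lie germ kernel matches finite differences of the warped filter", {
  bank <- test_bank()
  germs <- lie_germ_bank(bank)
  h <- 1e-3
  worst <- 0
  for (k in 1:6) {
    e <- c(1, 0, 0, 1, 0, 0); e[k] <- e[k] + h
    ah <- affine_params(e[1], e[2], e[3], e[4], e[5], e[6])
    for (i in c(1, 8, 18)) {
      fd <- (warped_gabor_kernel(bank, i, ah) -
               warped_gabor_kernel(bank, i, affine_identity())) / h
      g <- germs[, , i, k]
      worst <- max(worst, sqrt(sum((fd - g)^2) / sum(g^2)))
    }
  }
  expect_lt(worst, 0.01)
})

test_that("the energy vanishes for identical patches and is minimised at the true transform", {
  bank <- test_bank()
  img <- textured_image(151, seed = 21)
  ctr <- c(75, 75)
  p1 <- image_patch(img, ctr, bank = bank)
  expect_equal(energy(affine_identity(), p1, p1, bank), 0, tolerance = 1e-20)
  a0 <- affine_params(1.03, 0.01, -0.02, 0.98, 1.2, -0.8)
  img2 <- apply_affine(img, a0, center = ctr, clamp = TRUE)
  p2 <- image_patch(img2, ctr, bank = bank)
  E0 <- energy(a0, p1, p2, bank)
  expect_gte(E0, 0)
  # coarse grid around the truth: each single-parameter perturbation and a
  # handful of joint ones cost more energy than the truth
  set.seed(31)
  deltas <- list()
  for (k in 1:4) for (s in c(-0.06, 0.06)) {
    d <- numeric(6); d[k] <- s; deltas <- c(deltas, list(d))
  }
  for (k in 5:6) for (s in c(-1, -0.5, 0.5, 1)) {
    d <- numeric(6); d[k] <- s; deltas <- c(deltas, list(d))
  }
  for (j in 1:10) {
    deltas <- c(deltas, list(c(runif(4, -0.05, 0.05), runif(2, -0.8, 0.8))))
  }
  for (d in deltas) {
    expect_gt(energy(unclass(a0) + d, p1, p2, bank), E0)
  }
})

test_that("solve_affine recovers identity, shifts and fails on unrelated textures", {
  bank <- test_bank()
  img <- textured_image(151, seed = 41)
  ctr <- c(75, 75)
  p1 <- image_patch(img, ctr, bank = bank)
  fit0 <- solve_affine(p1, p1, bank)
  expect_true(fit0$converged)
  expect_lt(fit0$rel_residual, 1e-6)
  expect_equal(unclass(fit0$params), unclass(affine_identity()),
               tolerance = 1e-3)
  # integer shift: cross-correlation oracle picks the same displacement
  sh <- affine_params(tx = 2, ty = 0)
  img2 <- apply_affine(img, sh, center = ctr, clamp = TRUE)
  p2 <- image_patch(img2, ctr, bank = bank)
  fit <- solve_affine(p1, p2, bank)
  expect_true(fit$converged)
  cc <- sapply(-3:3, function(dx) {
    a <- img[(66:86), (66:86)]
    b <- img2[(66:86), (66:86) + dx]
    sum((a - mean(a)) * (b - mean(b)))
  })
  oracle_dx <- (-3:3)[which.max(cc)]
  expect_equal(oracle_dx, 2)  # content moved +2 px rightward
  expect_equal(fit$params[["tx"]], 2, tolerance = 0.1)
  expect_lt(max(abs(unclass(fit$params)[c(1, 4)] - 1)), 0.02)
  expect_lt(max(abs(unclass(fit$params)[c(2, 3, 6)])), 0.05)
  # unrelated textures admit no diffeomorphism
  img3 <- textured_image(151, seed = 42)
  p3 <- image_patch(img3, ctr, bank = bank)
  fit3 <- solve_affine(p1, p3, bank)
  expect_false(diffeo_exists(fit3))
})

test_that("diffeo existence follows the normalised-residual rule", {
  r_ok <- structure(list(params = affine_identity(), residual = 0,
                         rel_residual = 0, converged = TRUE,
                         n_iterations = 1L, token_norm = 1),
                    class = "diffeo_result")
  expect_true(diffeo_exists(r_ok))
  expect_true(diffeo_exists(r_ok, tol = 0.01))
  r_bad <- r_ok; r_bad$converged <- FALSE; r_bad$rel_residual <- 0.4
  expect_false(diffeo_exists(r_bad))
  r_mid <- r_ok; r_mid$rel_residual <- 0.03
  expect_false(diffeo_exists(r_mid, tol = 0.01))
})

test_that("patches must lie inside the frame with their margin", {
  bank <- test_bank()
  img <- textured_image(101)
  half <- bank$half
  expect_silent(image_patch(img, c(half, half), bank = bank))
  expect_error(image_patch(img, c(half - 1, half), bank = bank), "bounds")
})
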