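test_that("gradient operators and their transposes form adjoint pairs", {
  set.seed(21)
  for (rep in 1:20) {
    u <- matrix(rnorm(12 * 10), 12, 10)
    g <- matrix(rnorm(12 * 10), 12, 10)
    expect_equal(sum(piccs:::grad_x(u) * g), sum(u * piccs:::grad_x_t(g)),
                 tolerance = 1e-12)
    expect_equal(sum(piccs:::grad_y(u) * g), sum(u * piccs:::grad_y_t(g)),
                 tolerance = 1e-12)
  }
  # Neumann consistency: D then D^T of a constant is zero
  const <- matrix(3, 9, 9)
  expect_true(all(piccs:::grad_x_t(piccs:::grad_x(const)) == 0))
  expect_true(all(piccs:::grad_y_t(piccs:::grad_y(const)) == 0))
})

test_that("apply_K reduces to the identity and is symmetric", {
  g <- tiny_parallel_geom(n = 12L, n_angles = 8L, n_det = 18L)
  hp_id <- piccs_hyperparameters(mu = 1e-12, lam = 1e-12, alpha = 0, gamma = 1)
  hp_id$mu <- 0; hp_id$lam <- 0   # exact identity limit: 2*0 + 1 = 1
  set.seed(31)
  u <- matrix(rnorm(144), 12)
  expect_equal(apply_K(ct_image(u, g$pixel_size), g, hp_id)$values, u,
               tolerance = 1e-14)
  hp <- piccs_hyperparameters(mu = 1.3, lam = 0.2, alpha = 0.4, gamma = 0.9)
  for (rep in 1:100) {
    a <- matrix(rnorm(144), 12)
    b <- matrix(rnorm(144), 12)
    Ka <- apply_K(ct_image(a, g$pixel_size), g, hp)$values
    Kb <- apply_K(ct_image(b, g$pixel_size), g, hp)$values
    rel <- abs(sum(Ka * b) - sum(a * Kb)) /
      max(sqrt(sum(Ka^2)) * sqrt(sum(b^2)), .Machine$double.eps)
    expect_lt(rel, 1e-6)
  }
})

test_that("apply_K matches the explicitly assembled dense operator", {
  g <- tiny_parallel_geom()
  hp <- piccs_hyperparameters(mu = 1.3, lam = 0.2, alpha = 0.4, gamma = 0.9)
  Fm <- dense_forward_matrix(g)
  D <- dense_grad_matrices(6, 6)
  Kd <- hp$mu * crossprod(Fm) + hp$lam * (crossprod(D$Dx) + crossprod(D$Dy)) +
    (2 * hp$alpha + hp$gamma) * diag(36)
  set.seed(5)
  u <- matrix(rnorm(36), 6)
  expect_equal(as.vector(apply_K(ct_image(u, 1), g, hp)$values),
               as.vector(Kd %*% as.vector(u)), tolerance = 1e-8)
})

test_that("build_rhs isolates its terms and matches the dense recomputation", {
  g <- tiny_parallel_geom()
  f0 <- ct_sinogram(matrix(0, 8, 10), g$angles, g$det_spacing, "parallel")
  st <- piccs:::new_sb_state(ct_image(matrix(0, 6, 6), 1), f0)
  zero_prior <- ct_image(matrix(0, 6, 6), 1)
  hp <- piccs_hyperparameters(mu = 1.3, lam = 0.2, alpha = 0.4, gamma = 0.9)
  expect_true(all(build_rhs(st, zero_prior, g, hp)$values == 0))

  # mu = lam = gamma = 0 leaves only 2 alpha u_p
  hp0 <- hp; hp0$mu <- 0; hp0$lam <- 0; hp0$gamma <- 0
  up <- ct_image(matrix(rnorm(36), 6), 1)
  expect_equal(build_rhs(st, up, g, hp0)$values, 2 * hp$alpha * up$values,
               tolerance = 1e-14)

  # dense oracle on a random state
  set.seed(8)
  st$dx <- matrix(rnorm(36), 6); st$dy <- matrix(rnorm(36), 6)
  st$bx <- matrix(rnorm(36), 6); st$by <- matrix(rnorm(36), 6)
  st$v <- matrix(rnorm(36), 6); st$bv <- matrix(rnorm(36), 6)
  st$f_k$values <- matrix(rnorm(80), 8)
  Fm <- dense_forward_matrix(g)
  D <- dense_grad_matrices(6, 6)
  r_dense <- hp$mu * crossprod(Fm, as.vector(st$f_k$values)) +
    2 * hp$alpha * as.vector(up$values) +
    hp$lam * (crossprod(D$Dx, as.vector(st$dx - st$bx)) +
              crossprod(D$Dy, as.vector(st$dy - st$by))) +
    hp$gamma * as.vector(st$v - st$bv)
  expect_equal(as.vector(build_rhs(st, up, g, hp)$values), as.vector(r_dense),
               tolerance = 1e-10)
})

test_that("the u-subproblem solver recovers closed-form and manufactured solutions", {
  g <- tiny_parallel_geom()
  f0 <- ct_sinogram(matrix(0, 8, 10), g$angles, g$det_spacing, "parallel")
  up <- ct_image(matrix(rnorm(36), 6), 1)

  # lam = mu = 0: diagonal K, u = 2 alpha u_p / (2 alpha + gamma)
  hp0 <- piccs_hyperparameters(mu = 1, lam = 1, alpha = 0.4, gamma = 0.9,
                               krylov_tol = 1e-12, krylov_maxiter = 200)
  hp0$mu <- 0; hp0$lam <- 0
  st <- piccs:::new_sb_state(ct_image(matrix(0, 6, 6), 1), f0)
  u <- solve_u_subproblem(st, up, g, hp0)
  expect_equal(u$values, 2 * 0.4 * up$values / (2 * 0.4 + 0.9), tolerance = 1e-8)

  # manufactured solution through the full operator
  hp <- piccs_hyperparameters(mu = 1.3, lam = 0.2, alpha = 0.4, gamma = 0.9,
                              krylov_tol = 1e-10, krylov_maxiter = 500)
  set.seed(13)
  u_star <- matrix(runif(36), 6)
  Fm <- dense_forward_matrix(g)
  D <- dense_grad_matrices(6, 6)
  Kd <- hp$mu * crossprod(Fm) + hp$lam * (crossprod(D$Dx) + crossprod(D$Dy)) +
    (2 * hp$alpha + hp$gamma) * diag(36)
  applyA <- function(v) apply_K(ct_image(v, 1), g, hp)$values
  sol <- piccs:::cg_solve(applyA, matrix(Kd %*% as.vector(u_star), 6),
                          matrix(0, 6, 6), 1e-10, 500)
  expect_equal(sol$x, u_star, tolerance = 1e-6)

  # direct dense solve agreement on a random right-hand side
  r <- matrix(rnorm(36), 6)
  dense <- matrix(solve(Kd, as.vector(r)), 6)
  sol2 <- piccs:::cg_solve(applyA, r, matrix(0, 6, 6), 1e-12, 1000)
  expect_equal(sol2$x, dense, tolerance = 1e-6)
})

test_that("isotropic shrinkage matches a per-pixel numeric minimization", {
  # closed cases
  gx <- matrix(c(3, 0, 0.1), 1); gy <- matrix(c(4, 0, 0.1), 1)
  out <- shrink_gradients(gx, gy, 1)
  expect_equal(out$dx[1], 2.4, tolerance = 1e-12)
  expect_equal(out$dy[1], 3.2, tolerance = 1e-12)
  expect_equal(out$dx[2], 0)           # s = 0
  expect_equal(out$dx[3], 0)           # s < threshold: full shrinkage
  expect_identical(shrink_gradients(gx, gy, 0), list(dx = gx, dy = gy))

  # numeric oracle: minimize thr*||d|| + 0.5*||d - g||^2 along the radial
  # direction (the objective is radially symmetric about g's direction)
  set.seed(17)
  cases <- expand.grid(gmag = c(0, 0.05, 0.5, 1, 3, 10),
                       thr = c(0, 0.1, 1, 2.5))
  for (i in seq_len(nrow(cases))) {
    gmag <- cases$gmag[i]; thr <- cases$thr[i]
    ang <- runif(1, 0, 2 * pi)
    gx <- matrix(gmag * cos(ang)); gy <- matrix(gmag * sin(ang))
    got <- shrink_gradients(gx, gy, thr)
    if (gmag == 0) {
      expect_identical(c(got$dx[1], got$dy[1]), c(0, 0))
    } else {
      obj <- function(t) thr * t + 0.5 * (t - gmag)^2
      t_hat <- optimize(obj, c(0, gmag + thr + 1), tol = 1e-10)$minimum
      if (obj(0) <= obj(t_hat)) t_hat <- 0
      expect_equal(sqrt(got$dx[1]^2 + got$dy[1]^2), t_hat, tolerance = 1e-6)
      # direction preserved
      if (t_hat > 1e-9)
        expect_equal(atan2(got$dy[1], got$dx[1]), atan2(sin(ang), cos(ang)),
                     tolerance = 1e-9)
    }
  }
})

test_that("positivity projection clamps negatives only", {
  expect_identical(project_positive(matrix(c(-1, 2), 1)), matrix(c(0, 2), 1))
  img <- ct_image(matrix(c(0.1, 0.2), 1), 1)
  expect_identical(project_positive(img)$values, img$values)
  neg <- ct_image(matrix(-1, 2, 2), 1)
  expect_true(all(project_positive(neg)$values == 0))
})

test_that("Bregman updates hold fixed points and isolate the add-back term", {
  g <- tiny_parallel_geom()
  set.seed(23)
  u <- ct_image(matrix(runif(36), 6), 1)
  f <- forward_project(u, g)
  st <- piccs:::new_sb_state(u, f)
  st$dx <- piccs:::grad_x(u$values); st$dy <- piccs:::grad_y(u$values)
  st$v <- u$values
  st2 <- update_bregman(st, u, f, g)
  expect_equal(st2$bx, st$bx, tolerance = 1e-12)
  expect_equal(st2$by, st$by, tolerance = 1e-12)
  expect_equal(st2$bv, st$bv, tolerance = 1e-12)
  expect_equal(st2$f_k$values, st$f_k$values, tolerance = 1e-10)

  # zero u_next, zero d/v, zero iterators: f_k gains exactly f
  st0 <- piccs:::new_sb_state(ct_image(matrix(0, 6, 6), 1), f)
  st0$v <- matrix(0, 6, 6)
  st3 <- update_bregman(st0, ct_image(matrix(0, 6, 6), 1), f, g)
  expect_equal(st3$f_k$values, 2 * f$values, tolerance = 1e-14)
  expect_true(all(st3$bx == 0) && all(st3$by == 0) && all(st3$bv == 0))
})

test_that("one full outer cycle matches the dense-matrix reference", {
  g <- tiny_parallel_geom()
  hp <- piccs_hyperparameters(mu = 1.3, lam = 0.2, alpha = 0.4, gamma = 0.9,
                              n_outer = 1, krylov_tol = 1e-12,
                              krylov_maxiter = 500, stop_tol = 0)
  set.seed(42)
  u_true <- matrix(runif(36), 6)
  Fm <- dense_forward_matrix(g)
  f <- ct_sinogram(matrix(Fm %*% as.vector(u_true), 8), g$angles,
                   g$det_spacing, "parallel")
  prior <- ct_image(u_true + 0.1 * matrix(rnorm(36), 6), 1)
  fit <- reconstruct_l2piccs(f, g, prior, hp)

  # dense reference for the same single cycle
  D <- dense_grad_matrices(6, 6)
  Kd <- hp$mu * crossprod(Fm) + hp$lam * (crossprod(D$Dx) + crossprod(D$Dy)) +
    (2 * hp$alpha + hp$gamma) * diag(36)
  u0 <- fbp_reconstruct(f, g)$values
  v0 <- pmax(u0, 0)
  rhs <- hp$mu * crossprod(Fm, as.vector(f$values)) +
    2 * hp$alpha * as.vector(prior$values) + hp$gamma * as.vector(v0)
  u1 <- matrix(solve(Kd, rhs), 6)
  gx <- matrix(D$Dx %*% as.vector(u1), 6)
  gy <- matrix(D$Dy %*% as.vector(u1), 6)
  s <- sqrt(gx^2 + gy^2); thr <- (1 - hp$alpha) / hp$lam
  fac <- ifelse(s > 0, pmax(s - thr, 0) / s, 0)
  dx1 <- fac * gx; dy1 <- fac * gy
  v1 <- pmax(u1, 0)
  bx1 <- gx - dx1; by1 <- gy - dy1; bv1 <- u1 - v1
  fk1 <- f$values + f$values - matrix(Fm %*% as.vector(u1), 8)

  expect_equal(fit$state$u$values, u1, tolerance = 1e-6)
  expect_equal(fit$state$dx, dx1, tolerance = 1e-6)
  expect_equal(fit$state$dy, dy1, tolerance = 1e-6)
  expect_equal(fit$state$v, v1, tolerance = 1e-6)
  expect_equal(fit$state$bx, bx1, tolerance = 1e-6)
  expect_equal(fit$state$by, by1, tolerance = 1e-6)
  expect_equal(fit$state$bv, bv1, tolerance = 1e-6)
  expect_equal(fit$state$f_k$values, fk1, tolerance = 1e-6)
})

test_that("with alpha = 0 the prior has no influence at all", {
  pr <- small_problem(n = 48L, n_views = 60L)
  hp <- piccs_hyperparameters(alpha = 0, n_outer = 5, krylov_maxiter = 15)
  p1 <- fabricate_prior(pr$truth, prior_spec(blur_sigma = 2))
  p2 <- ct_image(matrix(0.05, 48, 48), pr$truth$pixel_size)
  f1 <- reconstruct_l2piccs(pr$sino, pr$geom, p1, hp)
  f2 <- reconstruct_l2piccs(pr$sino, pr$geom, p2, hp)
  expect_lt(max(abs(f1$image$values - f2$image$values)), 1e-10)
})

test_that("the solver output is positive and pulled toward the data", {
  pr <- small_problem(n = 48L, n_views = 60L)
  prior <- fabricate_prior(pr$truth, prior_spec(TRUE, 1.5))
  hp <- piccs_hyperparameters(n_outer = 10, stop_tol = 0)
  fit <- reconstruct_l2piccs(pr$sino, pr$geom, prior, hp)
  expect_gte(min(fit$image$values), -1e-8)
  h <- fit$history
  expect_lt(h$data_residual[10], h$data_residual[1])
})

test_that("reconstruction beats FBP when the prior is the truth on full data", {
  pr <- small_problem(n = 64L, n_views = 90L)
  fbp <- fbp_reconstruct(pr$sino, pr$geom)
  fit <- reconstruct_l2piccs(pr$sino, pr$geom, pr$truth, piccs_preset("synthetic"))
  expect_gte(psnr(fit$image, pr$truth), psnr(fbp, pr$truth))
})

test_that("increasing alpha does not increase the distance to the prior", {
  # weak monotonicity on noiseless full-view data, 1% tolerance per step
  pr <- small_problem(n = 48L, n_views = 120L)
  prior <- fabricate_prior(pr$truth, prior_spec(TRUE, 1.5))
  dists <- vapply(c(0, 0.5, 0.9), function(al) {
    hp <- piccs_hyperparameters(alpha = al, n_outer = 15)
    fit <- reconstruct_l2piccs(pr$sino, pr$geom, prior, hp)
    sqrt(sum((fit$image$values - prior$values)^2))
  }, double(1))
  expect_true(all(diff(dists) <= 0.01 * dists[-length(dists)]))
})

test_that("SART reduces the data residual and approaches FBP quality", {
  pr <- small_problem(n = 48L, n_views = 60L)
  z <- ct_sinogram(matrix(0, 60, pr$geom$n_det), pr$geom$angles,
                   pr$geom$det_spacing, "parallel")
  expect_true(all(sart_reconstruct(z, pr$geom, 3L, 1.0)$values == 0))
  expect_error(sart_reconstruct(pr$sino, pr$geom, 10L, 2.5), "relax")

  res <- vapply(1:10, function(k) {
    u <- sart_reconstruct(pr$sino, pr$geom, k, 1.0)
    sqrt(sum((forward_project(u, pr$geom)$values - pr$sino$values)^2))
  }, double(1))
  expect_true(all(diff(res) < 0))

  pr128 <- small_problem(n = 128L, n_views = 180L, phantom = "disk", seed = 1L)
  fbp_q <- psnr(fbp_reconstruct(pr128$sino, pr128$geom), pr128$truth)
  sart_q <- psnr(sart_reconstruct(pr128$sino, pr128$geom, 40L, 1.0), pr128$truth)
  expect_gt(sart_q, fbp_q - 3)
})

test_that("alpha above one warns about gradient amplification", {
  expect_warning(piccs_hyperparameters(alpha = 3), "amplified")
  expect_silent(piccs_preset("lsa"))
  expect_equal(piccs_preset("lnp_r1")$mu, 1.6)
  expect_equal(piccs_preset("lnp_r2")$alpha, 0.9)
  expect_equal(piccs_preset("lsa")$alpha, 3)
})
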