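arc <- fiducial_arc()

test_that("identity and pure-translation pairs register exactly", {
  fit <- horn_register(arc, arc)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$transform$scale, 1, tolerance = 1e-12)
  expect_lt(fit$residual_e, 1e-10)

  shifted <- arc
  shifted$coords <- sweep(arc$coords, 2, c(10, -5, 2), "+")
  fit <- horn_register(arc, shifted)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$transform$translation, c(10, -5, 2), tolerance = 1e-9)
  expect_equal(fit$transform$scale, 1, tolerance = 1e-12)
  expect_lt(fit$residual_e, 1e-9)
})

test_that("a known similarity transform is recovered to machine precision", {
  truth <- similarity_transform(
    compose_euler_rotation(0, 0, 10 * pi / 180),  # 10 deg about axial axis
    translation = c(5, -3, 2), scale = 1.02)
  post <- apply_transform(truth, arc)
  fit <- horn_register(arc, post)
  expect_lt(max(abs(fit$transform$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - truth$translation)), 1e-9)
  expect_lt(abs(fit$transform$scale - truth$scale), 1e-9)
  expect_lt(fit$residual_e, 1e-9)
  # and beats (or ties) a multi-start iterative least-squares fit
  expect_lte(fit$residual_ss, oracle_nls_ss(arc, post) + 1e-8)
})

test_that("noiseless synthetic transforms are recovered across random draws", {
  set.seed(42)
  for (k in 1:25) {
    truth <- similarity_transform(random_rotation(),
                                  translation = stats::rnorm(3, sd = 30),
                                  scale = stats::runif(1, 0.9, 1.1))
    fit <- horn_register(arc, apply_transform(truth, arc))
    expect_lt(max(abs(fit$transform$rotation - truth$rotation)), 1e-8)
    expect_lt(max(abs(fit$transform$translation - truth$translation)), 1e-8)
    expect_lt(abs(fit$transform$scale - truth$scale), 1e-8)
    expect_lt(fit$residual_e, 1e-8)
    r <- fit$transform$rotation
    expect_lt(max(abs(crossprod(r) - diag(3))), 1e-9)
    expect_lt(abs(det(r) - 1), 1e-9)
  }
})

test_that("closed form is optimal against a multi-start iterative oracle on noisy data", {
  set.seed(7)
  worse <- 0
  for (k in 1:12) {
    truth <- similarity_transform(random_rotation(),
                                  translation = stats::rnorm(3, sd = 10),
                                  scale = stats::runif(1, 0.95, 1.05))
    post <- apply_transform(truth, arc)
    post$coords <- post$coords + matrix(stats::rnorm(27, sd = 0.5), 9, 3)
    fit <- horn_register(arc, post)
    expect_lte(fit$residual_ss, oracle_nls_ss(arc, post, seed = 100 + k) + 1e-6)
  }
})

test_that("residual statistic is the RMS per-fiducial distance and exposes the raw sum", {
  post <- arc
  post$coords[3, 1] <- post$coords[3, 1] + 0.1  # one fiducial off by 0.1 mm
  res <- registration_residual(arc, post, similarity_transform())
  expect_equal(res$per_point_residuals,
               c(0, 0, 0.1, 0, 0, 0, 0, 0, 0), tolerance = 1e-12)
  expect_equal(res$residual_e, 0.1 / 3, tolerance = 1e-12)
  expect_equal(res$residual_ss, 0.01, tolerance = 1e-12)

  perfect <- registration_residual(arc, arc, similarity_transform())
  expect_identical(perfect$residual_e, 0)
  expect_true(all(perfect$per_point_residuals == 0))
})

test_that("mean residual after optimal registration matches an independent SVD registration", {
  set.seed(13)
  mine <- numeric(200); svd_rms <- numeric(200)
  for (k in 1:200) {
    noisy1 <- arc$coords + matrix(stats::rnorm(27, sd = 0.1), 9, 3)
    noisy2 <- arc$coords + matrix(stats::rnorm(27, sd = 0.1), 9, 3)
    mine[k] <- horn_register(point_set(noisy1), point_set(noisy2))$residual_e
    svd_rms[k] <- oracle_svd_register(noisy1, noisy2)$rms
  }
  expect_equal(mean(mine), mean(svd_rms), tolerance = 0.05)
  # and pairwise the two solvers find the same optimum
  expect_lt(max(abs(mine - svd_rms)), 1e-8)
})

test_that("residual_e is invariant to a common rigid motion of both point sets", {
  set.seed(5)
  pair <- simulate_scan_pair(arc, simulation_config(noise_sd = 0.2, seed = 5))
  base <- horn_register(pair$F1, pair$F2)$residual_e
  common <- similarity_transform(random_rotation(),
                                 translation = c(12, -4, 7))
  moved <- horn_register(apply_transform(common, pair$F1),
                         apply_transform(common, pair$F2))$residual_e
  expect_equal(base, moved, tolerance = 1e-9)
})

test_that("with_scale = FALSE forces s = 1 and agrees with scaled fit on scale-free data", {
  truth <- similarity_transform(compose_euler_rotation(0.2, -0.1, 0.3),
                                translation = c(1, 2, 3))
  post <- apply_transform(truth, arc)
  rigid <- horn_register(arc, post, with_scale = FALSE)
  scaled <- horn_register(arc, post, with_scale = TRUE)
  expect_identical(rigid$transform$scale, 1)
  expect_lt(max(abs(rigid$transform$rotation - scaled$transform$rotation)), 1e-9)
  expect_lt(max(abs(rigid$transform$translation - scaled$transform$translation)), 1e-9)
  expect_lt(abs(scaled$transform$scale - 1), 1e-9)
})

test_that("degenerate and mismatched inputs are rejected with informative errors", {
  expect_error(horn_register(point_set(arc$coords[1:2, ]),
                             point_set(arc$coords[1:2, ])),
               "at least three")
  expect_error(horn_register(arc, point_set(arc$coords[1:5, ])),
               "correspondence")
  line <- point_set(cbind(1:5, 2 * (1:5), -(1:5)))  # collinear
  expect_error(horn_register(line, line), "collinear")
})

test_that("apply_transform follows s*R*p + t with labels preserved", {
  expect_equal(apply_transform(similarity_transform(), c(4, 5, 6)),
               c(x = 4, y = 5, z = 6))
  expect_equal(apply_transform(similarity_transform(translation = c(1, 2, 3)),
                               c(0, 0, 0)),
               c(x = 1, y = 2, z = 3))
  rot90z <- compose_euler_rotation(0, 0, pi / 2)
  expect_equal(apply_transform(similarity_transform(rot90z, scale = 2),
                               c(1, 0, 0)),
               c(x = 0, y = 2, z = 0), tolerance = 1e-12)
  out <- apply_transform(similarity_transform(translation = c(1, 1, 1)), arc)
  expect_identical(out$labels, arc$labels)
})

test_that("euler composition matches entry-by-entry elemental products and round-trips", {
  expect_equal(compose_euler_rotation(0, 0, 0), diag(3))
  expect_equal(compose_euler_rotation(0.3, -0.2, 0.1),
               oracle_euler(0.3, -0.2, 0.1), tolerance = 1e-14)
  expect_equal(decompose_rotation(diag(3)),
               c(alpha = 0, beta = 0, gamma = 0))
  ang <- decompose_rotation(compose_euler_rotation(0.3, -0.2, 0.1))
  expect_equal(unname(ang), c(0.3, -0.2, 0.1), tolerance = 1e-9)

  set.seed(21)
  worst <- 0
  for (k in 1:200) {
    r <- random_rotation()
    expect_lt(max(abs(crossprod(r) - diag(3))), 1e-12)
    a <- decompose_rotation(r)
    r2 <- compose_euler_rotation(a["alpha"], a["beta"], a["gamma"])
    worst <- max(worst, max(abs(r - r2)))
  }
  expect_lt(worst, 1e-8)
  # gimbal lock: canonical alpha = 0 representative still reproduces R
  rl <- compose_euler_rotation(0.4, pi / 2, -0.1)
  al <- decompose_rotation(rl)
  expect_identical(unname(al["alpha"]), 0)
  expect_equal(compose_euler_rotation(al["alpha"], al["beta"], al["gamma"]),
               rl, tolerance = 1e-9)
  expect_error(decompose_rotation(matrix(1:9 / 5, 3, 3)), "orthonormal")
})
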