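test_that("Kabsch fit recovers a constructed rigid transform", {
  set.seed(21)
  mob <- scatter_reference(12, seed = 21)
  tr_id <- kabsch_fit(mob, mob)
  expect_equal(tr_id$rotation, diag(3), tolerance = 1e-10)
  expect_lt(tr_id$rmsd, 1e-10)
  # 90 degrees about z plus translation (1, 2, 3)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  target <- sweep(mob %*% t(Rz), 2, c(1, 2, 3), "+")
  tr <- kabsch_fit(mob, target)
  expect_lt(max(abs(apply_rigid_transform(mob, tr) - target)), 1e-10)
  expect_equal(tr$rotation, Rz, tolerance = 1e-10)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
})

test_that("mirror images yield a proper rotation with nonzero residual", {
  set.seed(22)
  mob <- scatter_reference(10, seed = 22)
  target <- mob
  target[, 1] <- -target[, 1]  # reflection
  tr <- kabsch_fit(mob, target)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
  expect_gt(tr$rmsd, 0.1)
})

test_that("Kabsch agrees with an independent superposition implementation", {
  set.seed(23)
  mob <- scatter_reference(15, seed = 23)
  target <- sweep(mob %*% t(random_rotation()), 2, c(-2, 5, 1), "+") +
    matrix(rnorm(45, sd = 0.1), 15, 3)
  tr <- kabsch_fit(mob, target)
  fitted <- apply_rigid_transform(mob, tr)
  ref_fit <- bio3d::fit.xyz(fixed = as.numeric(t(target)),
                            mobile = matrix(as.numeric(t(mob)), nrow = 1),
                            fixed.inds = 1:45, mobile.inds = 1:45)
  expect_equal(as.numeric(t(fitted)), as.numeric(ref_fit), tolerance = 1e-8)
})

test_that("degenerate fits are rejected", {
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_fit(line, line + 1), "collinear")
})

test_that("two-step fit of identical frames gives zero fluctuations", {
  fr <- scatter_reference(8, seed = 24)
  frames <- array(rep(fr, each = 5), c(5, 8, 3))
  fit <- two_step_average_fit(frames)
  expect_equal(fit$average_coords, fr, tolerance = 1e-10)
  expect_lt(max(bfactors_from_fit(fit)), 1e-18)
})

test_that("frames differing only by rigid transforms have no residual fluctuation", {
  set.seed(25)
  base <- scatter_reference(10, seed = 25)
  frames <- array(NA_real_, c(12, 10, 3))
  for (f in 1:12) {
    frames[f, , ] <- sweep(base %*% t(random_rotation()), 2, rnorm(3, sd = 5), "+")
  }
  fit <- two_step_average_fit(frames)
  expect_lt(max(abs(fit$rmsd_to_reference)), 1e-8)
  expect_lt(max(bfactors_from_fit(fit)), 1e-8)
})

test_that("isotropic Gaussian jitter recovers 3 sigma^2 per atom", {
  set.seed(26)
  n <- 100; sigma <- 0.2; nf <- 1e4
  base <- scatter_reference(n, seed = 26)
  frames <- array(rep(base, each = nf), c(nf, n, 3)) +
    array(rnorm(nf * n * 3, sd = sigma), c(nf, n, 3))
  fit <- two_step_average_fit(frames)
  msf <- bfactors_from_fit(fit) * 3 / (8 * pi^2)
  expect_equal(mean(msf), 3 * sigma^2, tolerance = 0.05)
})

test_that("step-2 total RMSD never exceeds step-1 total RMSD", {
  set.seed(27)
  base <- scatter_reference(10, seed = 27)
  frames <- array(rep(base, each = 50), c(50, 10, 3)) +
    array(rnorm(50 * 30, sd = 0.3), c(50, 10, 3))
  fit <- two_step_average_fit(frames)
  expect_lte(sum(fit$rmsd_to_reference), sum(fit$rmsd_step1))
})

test_that("fluctuations are invariant under global and per-frame rigid motion", {
  set.seed(28)
  base <- scatter_reference(10, seed = 28)
  nf <- 40
  frames <- array(rep(base, each = nf), c(nf, 10, 3)) +
    array(rnorm(nf * 30, sd = 0.25), c(nf, 10, 3))
  B0 <- bfactors_from_fit(two_step_average_fit(frames))
  # one global transform
  Rg <- random_rotation(); tg <- c(3, -7, 2)
  glob <- frames
  for (f in seq_len(nf)) glob[f, , ] <- sweep(frames[f, , ] %*% t(Rg), 2, tg, "+")
  expect_lt(max(abs(bfactors_from_fit(two_step_average_fit(glob)) - B0)), 1e-10)
  # independent transforms per frame
  per <- frames
  for (f in seq_len(nf)) {
    per[f, , ] <- sweep(frames[f, , ] %*% t(random_rotation()), 2,
                        rnorm(3, sd = 10), "+")
  }
  expect_lt(max(abs(bfactors_from_fit(two_step_average_fit(per)) - B0)), 1e-8)
})

test_that("fluctuations do not depend on the order of frames 2..n", {
  set.seed(29)
  base <- scatter_reference(8, seed = 29)
  nf <- 30
  frames <- array(rep(base, each = nf), c(nf, 8, 3)) +
    array(rnorm(nf * 24, sd = 0.2), c(nf, 8, 3))
  B0 <- bfactors_from_fit(two_step_average_fit(frames))
  perm <- c(1, sample(2:nf))
  expect_equal(bfactors_from_fit(two_step_average_fit(frames[perm, , ])), B0,
               tolerance = 1e-12)
})
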