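test_that("J1 counts non-white pixels after Otsu binarization", {
  expect_identical(cost_J1(phase_map(matrix(0.7, 64, 64))), 0L)
  v <- matrix(pi / 2, 64, 64)
  v[20:29, 31:40] <- -pi / 2
  expect_equal(cost_J1(phase_map(v)), 100)
})

test_that("J1 grows with curvature miscompensation", {
  p <- std_params(128)
  sp <- spherical_wavefront(3e4, 3e4, h = 64, g = 64)
  us <- conjugate_spherical_wave(sp, p)
  field <- complex_field(Conj(us$values), p)
  j1_at <- function(f) cost_J1(compensate_sphere(field,
    spherical_wavefront(f * 3e4, f * 3e4, h = 64, g = 64)))
  expect_gte(j1_at(1.2), j1_at(1.0))
})

test_that("J2 is the phase standard deviation", {
  expect_equal(cost_J2(phase_map(matrix(1.2, 32, 32))), 0)
  set.seed(4)
  v <- matrix(runif(512^2, -pi, pi), 512, 512)
  v[v <= -pi] <- pi
  expect_equal(cost_J2(phase_map(v)), 2 * pi / sqrt(12), tolerance = 0.02 / 1.8)
})

test_that("J2 at true parameters beats +/-20% curvature errors", {
  p <- std_params(128)
  sp <- spherical_wavefront(3e4, 3e4, h = 64, g = 64)
  field <- complex_field(Conj(conjugate_spherical_wave(sp, p)$values), p)
  j2_at <- function(f) cost_J2(compensate_sphere(field,
    spherical_wavefront(f * 3e4, f * 3e4, h = 64, g = 64)))
  expect_lt(j2_at(1.0), j2_at(0.8))
  expect_lt(j2_at(1.0), j2_at(1.2))
})

test_that("sphere-only cost landscapes bottom out at the true curvature", {
  p <- std_params(128)
  C <- 3e4
  field <- complex_field(
    Conj(conjugate_spherical_wave(
      spherical_wavefront(C, C, h = 64, g = 64), p)$values), p)
  fac <- seq(0.5, 1.5, by = 0.01)
  j1 <- vapply(fac, function(f) as.numeric(cost_J1(compensate_sphere(field,
    spherical_wavefront(f * C, f * C, h = 64, g = 64)))), numeric(1))
  j2 <- vapply(fac, function(f) cost_J2(compensate_sphere(field,
    spherical_wavefront(f * C, f * C, h = 64, g = 64))), numeric(1))
  expect_equal(fac[which.min(j1)], 1.0, tolerance = 1e-9)
  expect_equal(fac[which.min(j2)], 1.0, tolerance = 1e-9)
})

test_that("every minimizer lands near the minimum of a convex quadratic", {
  target <- c(0.9, 1.1)
  fn <- function(p) sum((p - target)^2)
  for (alg in c("fmc", "fmu", "fso", "sa", "pts", "ga", "ps", "ga_ps")) {
    res <- minimize_cost(fn, par0 = c(1.4, 0.7), lower = c(0.5, 0.5),
                         upper = c(1.5, 1.5), algorithm = alg, rng_seed = 3)
    expect_lt(max(abs(res$par - target)), 0.01 * max(abs(target)),
              label = paste("algorithm", alg))
    expect_gte(res$evaluations, 1)
    expect_equal(res$value, fn(res$par), tolerance = 1e-12)
  }
})

test_that("a minimum outside the box clamps to the boundary", {
  fn <- function(p) sum((p - c(2, 2))^2)
  for (alg in c("fmc", "fmu", "fso", "ps", "ga_ps")) {
    res <- minimize_cost(fn, par0 = c(1, 1), lower = c(0.5, 0.5),
                         upper = c(1.5, 1.5), algorithm = alg, rng_seed = 3)
    expect_equal(res$par, c(1.5, 1.5), tolerance = 1e-3,
                 label = paste("algorithm", alg))
  }
})

test_that("stochastic minimizers are reproducible under a fixed seed", {
  fn <- function(p) (p[1] - 0.8)^2 + 2 * (p[2] - 1.2)^2 + 0.1 * sin(9 * p[1])
  for (alg in c("sa", "pts", "ga", "ga_ps")) {
    r1 <- minimize_cost(fn, c(1, 1), c(0.5, 0.5), c(1.5, 1.5),
                        algorithm = alg, rng_seed = 42)
    r2 <- minimize_cost(fn, c(1, 1), c(0.5, 0.5), c(1.5, 1.5),
                        algorithm = alg, rng_seed = 42)
    expect_identical(r1$par, r2$par, label = paste("algorithm", alg))
    expect_identical(r1$value, r2$value)
  }
})

test_that("the hybrid never returns a worse cost than its GA stage", {
  fn <- function(p) (p[1] - 0.9)^2 + (p[2] - 1.1)^2 + 0.05 * cos(20 * p[1])
  ga <- minimize_cost(fn, c(1.3, 0.7), c(0.5, 0.5), c(1.5, 1.5),
                      algorithm = "ga", rng_seed = 9)
  hy <- minimize_cost(fn, c(1.3, 0.7), c(0.5, 0.5), c(1.5, 1.5),
                      algorithm = "ga_ps", rng_seed = 9)
  expect_lte(hy$value, ga$value + 1e-12)
})

test_that("non-finite costs abort with the offending parameters", {
  fn <- function(p) if (p[1] > 1.2) NaN else sum(p^2)
  expect_error(
    minimize_cost(fn, c(1, 1), c(0.5, 0.5), c(1.5, 1.5), algorithm = "ps"),
    "evaluation failed")
})

test_that("optimize_sphere recovers curvature from a 25%-off seed", {
  p <- std_params(256)
  C <- 6.5e4
  field <- complex_field(
    Conj(conjugate_spherical_wave(
      spherical_wavefront(C, C, h = 128, g = 128), p)$values), p)
  seed <- spherical_wavefront(1.25 * C, 1.25 * C, h = 128, g = 128)
  opt <- optimize_sphere(field, seed, cost = "J2", algorithm = "ga_ps",
                         rng_seed = 5)
  expect_lte(percent_error(opt$best$C_x, C), 1)
  expect_lte(percent_error(opt$best$C_y, C), 1)
  expect_s3_class(opt, "dhm_optimization")
  expect_true(all(c("par1", "par2", "cost") %in% colnames(opt$trace)))
})

test_that("SSIM obeys identity, symmetry and inversion ordering", {
  set.seed(8)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ssim_metric(a, a), 1, tolerance = 1e-9)
  expect_equal(ssim_metric(a, b), ssim_metric(b, a), tolerance = 1e-12)
  expect_lt(ssim_metric(a, 1 - a), ssim_metric(a, a))
  expect_error(ssim_metric(a, matrix(0, 32, 32)), "equal shapes")
})
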