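test_that("sample stretches are equidistant interval endpoints", {
  pts <- sample_stretch_points(1.25, 20)
  expect_length(pts, 20L)
  expect_equal(pts[1], 1.0125)
  expect_equal(pts[20], 1.25)
  expect_equal(unique(round(diff(pts), 12)), 0.0125)
  expect_equal(sample_stretch_points(1.25, 1), 1.25)
})

test_that("squared error matches a brute-force summation oracle", {
  tgt <- synth_target_curve(32.8, 8.22, 1.25, 100)
  sim <- synth_target_curve(30, 8.22, 1.25, 100)
  pts <- sample_stretch_points(1.25, 20)
  expect_equal(squared_error(tgt, tgt, pts), 0)
  # brute force: direct evaluation of the closed forms at the points
  m1 <- ogden_material(32.8, 8.22); m2 <- ogden_material(30, 8.22)
  brute <- sum((uniaxial_nominal_stress(pts, m1) -
                  uniaxial_nominal_stress(pts, m2))^2)
  expect_equal(squared_error(tgt, sim, pts), brute, tolerance = 1e-5)
  # constant offset d at m points gives m d^2
  off <- stress_stretch_curve(tgt$lambda[-1], tgt$S_kPa[-1] + 0.7,
                              "synthetic")
  tgt_no1 <- stress_stretch_curve(tgt$lambda[-1], tgt$S_kPa[-1], "synthetic")
  expect_equal(squared_error(tgt_no1, off, pts), 20 * 0.7^2,
               tolerance = 1e-9)
  expect_error(squared_error(tgt, sim, c(pts, 1.3)), "extrapolation")
})

test_that("golden-section search follows the textbook scheme", {
  quad <- function(m) (m - 33)^2
  gs <- golden_section_search(quad, c(20, 50), 1.0)
  # first evaluated point is the lower interior point of (20, 50)
  expect_equal(gs$trace$mu_kPa[1], 20 + (1 - 1 / ((sqrt(5) + 1) / 2)) * 30,
               tolerance = 1e-9)
  expect_equal(round(gs$trace$mu_kPa[1], 2), 31.46)
  # exactly 9 evaluations to tolerance 1 on a width-30 bracket
  expect_identical(gs$n_evals, 9L)
  # the minimum is bracketed to within the tolerance; brute-force grid
  # oracle agrees
  grid <- seq(20, 50, by = 1e-3)
  expect_lte(abs(gs$minimum - grid[which.min(quad(grid))]), 1.0)
  # evaluation count is forced by the bracket and tolerance alone
  for (obj in list(function(x) abs(x - 41), function(x) cos(x / 5),
                   function(x) (x - 25)^4)) {
    g <- golden_section_search(obj, c(20, 50), 1.0)
    expect_identical(g$n_evals, 9L)
  }
  # count formula: ceil(log(tol/(b-a)) / log(1/phi)) + 1
  invphi <- 2 / (sqrt(5) + 1)
  for (cs in list(c(20, 50, 1), c(0, 1, 0.05), c(10, 12, 0.5))) {
    g <- golden_section_search(function(x) (x - mean(cs[1:2]))^2,
                               cs[1:2], cs[3])
    expect_identical(g$n_evals,
                     as.integer(ceiling(log(cs[3] / (cs[2] - cs[1])) /
                                          log(invphi))) + 1L)
    # uncertainty width after n evaluations
    expect_lte((cs[2] - cs[1]) * invphi^(g$n_evals - 1), cs[3])
  }
  # degenerate bracket: a single evaluation returning the bracket value
  gd <- golden_section_search(quad, c(30, 30), 1.0)
  expect_identical(gd$n_evals, 1L)
  expect_identical(gd$minimum, 30)
  expect_error(golden_section_search(quad, c(50, 20), 1.0),
               "configuration error")
})

test_that("identification recovers the modulus of an analytic forward model", {
  # closed-form 'forward model': tissue responds as a uniaxial Ogden
  # medium whose modulus is the axon modulus itself
  fwd <- function(mu) synth_target_curve(mu, 8.22, 1.25, 60)
  target <- synth_target_curve(33, 8.22, 1.25, 60)
  fit <- identify_shear_modulus(inverse_problem(target, fwd,
                                                bracket = c(20, 50),
                                                tol = 1.0))
  expect_lte(abs(fit$mu_kPa - 33), 1.0)
  expect_identical(fit$n_evals, 9L)
  expect_identical(nrow(fit$trace), 9L)
  expect_true(all(fit$trace$E_kPa2 >= 0))
  # degenerate bracket returns the bracket value after one forward run
  fit30 <- identify_shear_modulus(inverse_problem(target, fwd,
                                                  bracket = c(30, 30),
                                                  tol = 1.0))
  expect_identical(fit30$mu_kPa, 30)
  expect_identical(fit30$n_evals, 1L)
})
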