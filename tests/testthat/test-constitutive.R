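test_that("Ogden energy matches direct evaluation and is isotropic", {
  mat <- ogden_ref()
  expect_equal(ogden_energy(c(1, 1, 1), mat), 0)
  # frozen value: (2*32.8/8.22^2) * (1.06^8.22 + 2*1.06^(-4.11) - 3)
  lam <- c(1.06, 1.06^-0.5, 1.06^-0.5)
  expect_equal(ogden_energy(lam, mat), 0.1829865, tolerance = 1e-6)
  # isotropy: permutations leave W unchanged
  for (p in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1)))
    expect_identical(ogden_energy(lam[p], mat), ogden_energy(lam, mat))
  expect_error(ogden_energy(c(1, -1, 1), mat), "positive")
  expect_error(ogden_material(-1, 8.22), "positive")
  expect_error(ogden_material(10, 8.22, bulk_penalty = 20), "bulk_penalty")
})

test_that("uniaxial nominal stress is the derivative of the energy", {
  mat <- ogden_ref()
  expect_equal(uniaxial_nominal_stress(1, mat), 0)
  # independent oracle: central difference of W along the incompressible
  # uniaxial path
  oracle <- function(lam, h = 1e-6) {
    W <- function(l) ogden_energy(c(l, l^-0.5, l^-0.5), mat)
    (W(lam + h) - W(lam - h)) / (2 * h)
  }
  for (lam in c(1.03, 1.06, 1.12, 1.25))
    expect_equal(uniaxial_nominal_stress(lam, mat), oracle(lam),
                 tolerance = 1e-6)
  # frozen values from that oracle
  expect_equal(uniaxial_nominal_stress(1.06, mat), 6.2292, tolerance = 1e-4)
  expect_equal(uniaxial_nominal_stress(1.25, mat), 37.417, tolerance = 1e-4)
  # strictly increasing on [1, 1.3]
  g <- uniaxial_nominal_stress(seq(1, 1.3, by = 0.01), mat)
  expect_true(all(diff(g) > 0))
  # tangent modulus consistent with the stress
  for (lam in c(1.02, 1.1, 1.24))
    expect_equal(uniaxial_tangent_modulus(lam, mat),
                 (uniaxial_nominal_stress(lam + 1e-6, mat) -
                    uniaxial_nominal_stress(lam - 1e-6, mat)) / 2e-6,
                 tolerance = 1e-5)
})

test_that("stress evaluation is objective and consistent with the energy", {
  mat <- ogden_material(32.8, 8.22, 3280)
  expect_equal(stress_and_tangent(diag(3), mat)$cauchy, matrix(0, 3, 3),
               tolerance = 1e-12)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  # pure rotation carries no stress
  expect_equal(stress_and_tangent(R, mat)$cauchy, matrix(0, 3, 3),
               tolerance = 1e-9)
  set.seed(42)
  for (k in 1:5) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
    st <- stress_and_tangent(F, mat)
    # objectivity: sigma(R F) = R sigma(F) R'
    st_rot <- stress_and_tangent(R %*% F, mat)
    expect_equal(st_rot$cauchy, R %*% st$cauchy %*% t(R), tolerance = 1e-7)
    # dW/dF (finite difference of the energy) matches the first Piola
    # stress to 1e-6 relative
    Wof <- function(Fm) ogden_energy(svd(Fm)$d, mat)
    G <- matrix(0, 3, 3)
    for (n in 1:9) {
      Fp <- F; Fm <- F
      Fp[n] <- Fp[n] + 1e-6; Fm[n] <- Fm[n] - 1e-6
      G[n] <- (Wof(Fp) - Wof(Fm)) / 2e-6
    }
    expect_lt(max(abs(G - st$pk1)) / max(abs(st$pk1)), 1e-6)
    # major symmetry of the tangent
    expect_lt(max(abs(st$tangent - t(st$tangent))) / max(abs(st$tangent)),
              1e-8)
  }
  expect_error(stress_and_tangent(diag(c(1, 1, -1)), mat, element_id = 7),
               "element 7")
})

test_that("isochoric energy is nonnegative, zero only at identity", {
  mat <- ogden_ref()
  set.seed(7)
  for (k in 1:50) {
    l12 <- exp(rnorm(2, sd = 0.2))
    lam <- c(l12, 1 / prod(l12))  # J = 1
    w <- ogden_energy(lam, mat)
    expect_gte(w, 0)
    if (max(abs(lam - 1)) > 1e-3) expect_gt(w, 1e-8)
  }
})
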