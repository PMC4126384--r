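test_that("reference state is stress-free with a symmetric consistent tangent", {
  rve <- fixture("rve_small", function() small_rve())
  model <- fe_model(rve, wm_materials(32.8), mesh_size = 0.6)
  u0 <- numeric(model$ndof)
  sys0 <- assemble_system(model, u0, want_tangent = TRUE)
  expect_lt(max(abs(sys0$r[model$free])), 1e-10)
  expect_equal(homogenized_nominal_stress(model, u0), 0, tolerance = 1e-10)
  expect_true(all(von_mises_field(model, u0) < 1e-10))
  # tangent symmetry
  expect_lt(max(abs(sys0$K - Matrix::t(sys0$K))) / max(abs(sys0$K)), 1e-8)
  # Taylor test at a random perturbed state: finite-difference directional
  # derivative of the residual matches tangent * direction
  set.seed(5)
  u <- rnorm(model$ndof) * 0.01
  sys <- assemble_system(model, u, want_tangent = TRUE)
  d <- rnorm(model$ndof); d <- d / sqrt(sum(d^2))
  h <- 1e-6
  fd <- (assemble_system(model, u + h * d, want_tangent = FALSE)$r -
           assemble_system(model, u - h * d, want_tangent = FALSE)$r) / (2 * h)
  Kd <- as.numeric(sys$K %*% d)
  expect_lt(sqrt(sum((fd - Kd)^2)) / sqrt(sum(fd^2)), 1e-5)
})

test_that("a homogeneous matrix reproduces the incompressible closed form", {
  rve0 <- build_rve(rve_config(target_volume_fraction = 0), seed = 1)
  mats <- list(ecm = ogden_material(32.8, 8.22), axon = ogden_ref())
  res <- fixture("patch_small", function()
    staged_simulation(rve0, mats, load_program(1.06, 3), mesh_size = 0.5,
                      keep_model = TRUE))
  s_fe <- res$curve$S33_kPa[nrow(res$curve)]
  s_cf <- uniaxial_nominal_stress(1.06, ogden_ref())
  expect_lt(abs(s_fe - s_cf) / s_cf, 0.02)
  # curve is strictly increasing and starts at S33(1) = 0
  expect_equal(res$curve$S33_kPa[1], 0)
  expect_true(all(diff(res$curve$S33_kPa) > 0))
  # boundary-reaction homogenization equals the volume-averaged P33
  expect_lt(abs(axonrve:::volume_averaged_P33(res$model, res$u) - s_fe) /
              s_fe, 0.01)
  # von Mises of the (uniaxial) element stress equals the axial Cauchy
  # stress sigma33 ~ lambda * S33
  vm <- von_mises_field(res$model, res$u)
  expect_lt(abs(mean(vm) - 1.06 * s_cf) / (1.06 * s_cf), 0.03)
  expect_lt(diff(range(vm)) / mean(vm), 1e-4)  # homogeneous field
})

test_that("axons stiffen the response and runs are deterministic", {
  rve <- fixture("rve_vf20", function() small_rve(seed = 8, vf = 0.2))
  mats <- wm_materials(32.8)
  pr <- load_program(1.06, 3)
  with_fibers <- staged_simulation(rve, mats, pr, mesh_size = 0.6)
  rve0 <- build_rve(rve_config(target_volume_fraction = 0), seed = 8)
  matrix_only <- staged_simulation(rve0, list(ecm = mats$ecm, axon = mats$axon),
                                   pr, mesh_size = 0.6)
  s1 <- with_fibers$curve$S33_kPa[nrow(with_fibers$curve)]
  s0 <- matrix_only$curve$S33_kPa[nrow(matrix_only$curve)]
  expect_gte(s1, s0 * (1 - 1e-6))
  # determinism: identical configuration gives identical curves
  rep2 <- staged_simulation(rve, mats, pr, mesh_size = 0.6)
  expect_identical(with_fibers$curve$S33_kPa, rep2$curve$S33_kPa)
})

test_that("uncoupled undulated axons straighten faster than coupled ones", {
  rve1 <- build_rve(rve_config(target_volume_fraction = 0.035), seed = 11)
  expect_length(rve1$axons, 1L)
  expect_gt(rve1$axons[[1]]$tortuosity, 1.08)  # above threshold: uncoupled
  pr <- load_program(c(1.06, 1.12), 3)
  free_rule <- coupling_rule()
  tied_rule <- coupling_rule(threshold_undulation = 99,
                             stage_breaks = c(1.06, 1.12),
                             stage_fractions = c(1, 1))
  ru <- staged_simulation(rve1, wm_materials(32.8), pr, free_rule,
                          mesh_size = 0.6)
  rc <- staged_simulation(rve1, wm_materials(32.8), pr, tied_rule,
                          mesh_size = 0.6)
  # tortuosity never increases with stretch in either case
  for (res in list(ru, rc)) {
    tr <- tortuosity_trace(res)
    expect_true(all(diff(tr$tortuosity[order(tr$lambda)]) <= 1e-9))
  }
  drop_u <- subset(ru$trace, lambda == 1)$tortuosity -
    subset(ru$trace, lambda == 1.12)$tortuosity
  drop_c <- subset(rc$trace, lambda == 1)$tortuosity -
    subset(rc$trace, lambda == 1.12)$tortuosity
  expect_gt(drop_u, drop_c)
})

test_that("solving to the current stretch is a no-op", {
  rve <- fixture("rve_small", function() small_rve())
  model <- fe_model(rve, wm_materials(32.8), mesh_size = 0.6)
  st <- fe_state(model)
  st2 <- newton_solve(model, st, 1, substeps = 4)
  expect_identical(st2$u, st$u)
  expect_identical(nrow(st2$curve), 1L)
  expect_error(newton_solve(model, st2, 0.99), "current stretch")
})
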