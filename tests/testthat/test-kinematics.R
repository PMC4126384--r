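test_that("coupling rule returns the staged fractions below threshold", {
  expect_equal(coupling_fraction(1.05, 1.03), 0.08)
  expect_equal(coupling_fraction(1.05, 1.10), 0.20)
  expect_equal(coupling_fraction(1.05, 1.20), 0.44)
  expect_equal(coupling_fraction(1.20, 1.10), 0)
  # beyond the last break the last fraction applies
  expect_equal(coupling_fraction(1.05, 1.40), 0.44)
  # a stretch exactly at a break closes that stage
  expect_equal(coupling_fraction(1.05, 1.06), 0.08)
  expect_error(coupling_fraction(1.05, 0.98), "domain error")
})

test_that("threshold is sharp: strictly below 1.08 couples", {
  eps <- 1e-9
  expect_gt(coupling_fraction(1.08 - 1e-6, 1.10), 0)
  expect_equal(coupling_fraction(1.08, 1.10), 0)
  expect_equal(coupling_fraction(1.08 + eps, 1.10), 0)
})

test_that("coupled fraction is a non-decreasing step function of stretch", {
  lams <- seq(1, 1.4, by = 0.01)
  fr <- coupling_fraction(rep(1.04, length(lams)), lams)
  expect_true(all(diff(fr) >= 0))
  expect_setequal(unique(fr), c(0.08, 0.20, 0.44))
})

test_that("sub-segment selection honours size, policy and monotone growth", {
  p <- generate_axon_path(21, 1.15)
  s20 <- select_coupled_subsegments(p, 0.20)
  expect_length(s20, 10L)
  expect_length(select_coupled_subsegments(p, 0), 0L)
  # straightest-first: selected segments have the lowest local tortuosity
  lt <- p$subsegments$local_tortuosity
  expect_lte(max(lt[s20]), min(lt[-s20]))
  # random policy is reproducible under a fixed seed
  r1 <- select_coupled_subsegments(p, 0.2, seed = 4, policy = "random")
  r2 <- select_coupled_subsegments(p, 0.2, seed = 4, policy = "random")
  expect_identical(r1, r2)
  # growth keeps previously coupled segments
  s44 <- select_coupled_subsegments(p, 0.44, previous = s20)
  expect_length(s44, 22L)
  expect_true(all(s20 %in% s44))
  # from-ends grows inward from the axon ends
  fe <- select_coupled_subsegments(p, 0.08, policy = "from_ends")
  expect_true(all(c(1L, 50L) %in% fe))
})

test_that("coupling state update gates on undulation and grows sets", {
  paths <- lapply(1:4, function(s) generate_axon_path(s + 40, 1.15))
  # all above threshold: only end ties, empty coupled sets
  st <- update_coupling_state(NULL, paths, applied_stretch = 1.25)
  expect_true(all(vapply(st$coupled_sets, length, integer(1)) == 0L))
  # straightened fibers (scaled toward the chord) drop below threshold
  flat <- lapply(paths, function(p) {
    cl <- fiber_nodes <- p$centerline[p$subsegments$breaks, ]
    chord_dir <- colMeans(cl)
    cl[, 2] <- mean(cl[, 2]) + 0.2 * (cl[, 2] - mean(cl[, 2]))
    cl
  })
  st2 <- update_coupling_state(st, paths, flat, applied_stretch = 1.12)
  expect_true(all(st2$tortuosity < 1.08))
  expect_true(all(vapply(st2$coupled_sets, length, integer(1)) == 10L))
  # growth to the next stage keeps stage-2 segments
  st3 <- update_coupling_state(st2, paths, flat, applied_stretch = 1.25)
  for (i in seq_along(paths)) {
    expect_true(all(st2$coupled_sets[[i]] %in% st3$coupled_sets[[i]]))
    expect_length(st3$coupled_sets[[i]], 22L)
  }
  # idempotence: repeating an update changes nothing
  st4 <- update_coupling_state(st3, paths, flat, applied_stretch = 1.25)
  expect_identical(st3$coupled_sets, st4$coupled_sets)
})
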