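test_that("tortuosity is arc length over chord", {
  expect_equal(compute_tortuosity(rbind(c(0, 0, 0), c(0, 0, 5.68))), 1.0)
  # analytic: arc 2*sqrt(2) over chord 2
  expect_equal(compute_tortuosity(rbind(c(0, 0, 0), c(0, 1, 1), c(0, 0, 2))),
               sqrt(2), tolerance = 1e-6)
  # definition ratio: measured length 6.248 over chord 5.68
  expect_equal(6.248 / 5.68, 1.10, tolerance = 1e-3)
  expect_error(compute_tortuosity(rbind(c(0, 0, 0))), "at least 2")
  expect_error(compute_tortuosity(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 1, 0))),
               "coincident")
})

test_that("axon generator calibrates tortuosity and spans the z-faces", {
  dom <- box_domain()
  p0 <- generate_axon_path(5, 1.0, dom)
  expect_equal(p0$tortuosity, 1.0, tolerance = 1e-9)
  p <- generate_axon_path(5, 1.15, dom)
  expect_gte(p$tortuosity, 1.13)
  expect_lte(p$tortuosity, 1.17)
  for (s in c(2, 9, 31)) {
    pp <- generate_axon_path(s, 1.12, dom)
    expect_equal(pp$centerline[1, 3], 0)
    expect_equal(pp$centerline[nrow(pp$centerline), 3], dom$size_z)
    # inside the box
    for (k in 1:3)
      expect_true(all(pp$centerline[, k] >= -1e-12 &
                        pp$centerline[, k] <= axonrve:::box_sizes(dom)[k] + 1e-12))
  }
  # reproducibility and seed sensitivity
  expect_identical(generate_axon_path(5, 1.15, dom)$centerline, p$centerline)
  expect_false(identical(generate_axon_path(6, 1.15, dom)$centerline,
                         p$centerline))
  expect_error(generate_axon_path(1, 0.9, dom))
})

test_that("generator calibration error stays small across many axons", {
  tgt <- seq(1.03, 1.28, length.out = 100)
  err <- vapply(seq_along(tgt), function(i)
    abs(generate_axon_path(1000L + i, tgt[i])$tortuosity - tgt[i]),
    numeric(1))
  expect_lte(mean(err), 0.02)
})

test_that("clipping projects onto the faces and never adds tortuosity", {
  dom <- box_domain(0.4, 10, 5.68)
  p <- generate_axon_path(3, 1.1, dom)
  expect_equal(clip_to_domain(p, dom)$centerline, p$centerline)  # interior
  # a sample at y = 10.3 in a 10 um box is projected to y = 10
  cl <- cbind(0.2, c(5, 10.3, 5), c(0, 2.8, 5.68))
  pc <- clip_to_domain(manual_path(cl, n_sub = 2L), dom)
  expect_lte(max(pc$centerline[, 2]), 10)
  # clipping a path against a narrower box cannot increase tortuosity
  wide <- box_domain(0.4, 20, 5.68)
  for (s in 1:10) {
    pw <- generate_axon_path(s, 1.2, wide)
    expect_lte(clip_to_domain(pw, dom)$tortuosity, pw$tortuosity + 1e-9)
  }
})

test_that("axon volume is the swept-circle volume", {
  straight <- manual_path(cbind(0.2, 5, seq(0, 5.68, length.out = 9)))
  expect_equal(axon_volume(straight), pi * 0.04 * 5.68, tolerance = 1e-9)
  expect_equal(axon_volume(straight), 0.71377, tolerance = 1e-4)
  r0 <- manual_path(cbind(0.2, 5, seq(0, 5.68, length.out = 9)), radius = 0)
  expect_equal(axon_volume(r0), 0)
  # undulated: volume = pi r^2 * tortuosity * chord (tortuosity 1.1 at
  # chord 5.68 gives 0.78515 um^3)
  p <- generate_axon_path(8, 1.1)
  chord <- sqrt(sum((p$centerline[nrow(p$centerline), ] -
                       p$centerline[1, ])^2))
  expect_equal(axon_volume(p), pi * 0.04 * p$tortuosity * chord,
               tolerance = 1e-9)
  expect_equal(pi * 0.2^2 * 1.1 * 5.68, 0.78515, tolerance = 1e-5)
})

test_that("sub-segment partition is contiguous and equal-arc", {
  p <- generate_axon_path(4, 1.18)
  ss <- p$subsegments
  expect_identical(ss$n, 50L)
  expect_length(ss$arc_lengths, 50L)
  # equal arc lengths within 1%
  expect_lt(diff(range(ss$arc_lengths)) / mean(ss$arc_lengths), 0.01)
  # conservation: piece lengths sum to the total arc length
  expect_equal(sum(ss$arc_lengths),
               sum(sqrt(rowSums(diff(p$centerline)^2))), tolerance = 1e-12)
  p1 <- partition_subsegments(p, 1L)
  expect_identical(p1$subsegments$n, 1L)
  expect_error(partition_subsegments(p, 0L), "configuration error")
})

test_that("RVE builder hits the volume fraction and undulation range", {
  rve <- fixture("rve_seed1", function() build_rve(rve_config(), seed = 1))
  expect_lte(abs(rve$achieved_volume_fraction - 0.53), 0.01)
  # volume-fraction identity holds exactly by construction
  vb <- prod(axonrve:::box_sizes(rve$domain))
  expect_equal(sum(vapply(rve$axons, axon_volume, numeric(1))) / vb,
               rve$achieved_volume_fraction, tolerance = 1e-12)
  mt <- mean(vapply(rve$axons, function(p) p$tortuosity, numeric(1)))
  expect_gte(mt, 1.05)
  expect_lte(mt, 1.25)
  expect_gt(length(rve$axons), 5L)
  # zero target produces an empty population
  empty <- build_rve(rve_config(target_volume_fraction = 0), seed = 1)
  expect_length(empty$axons, 0L)
  expect_equal(empty$achieved_volume_fraction, 0)
  expect_error(build_rve(rve_config(target_volume_fraction = 0.95), seed = 1),
               "packing bound")
})

test_that("RVE serialization is deterministic and round-trips", {
  rve <- fixture("rve_seed1", function() build_rve(rve_config(), seed = 1))
  js1 <- rve_to_json(rve)
  js2 <- rve_to_json(build_rve(rve_config(), seed = 1))
  expect_identical(as.character(js1), as.character(js2))
  expect_false(identical(as.character(js1),
                         as.character(rve_to_json(build_rve(rve_config(),
                                                            seed = 2)))))
  f <- tempfile(fileext = ".json")
  rve_to_json(rve, f)
  back <- rve_from_json(f)
  expect_equal(length(back$axons), length(rve$axons))
  expect_equal(back$axons[[3]]$centerline, rve$axons[[3]]$centerline,
               tolerance = 1e-9)
  expect_equal(back$achieved_volume_fraction, rve$achieved_volume_fraction,
               tolerance = 1e-12)
  # VTK polyline export writes a parseable header
  v <- tempfile(fileext = ".vtk")
  write_vtk_polylines(rve, v)
  expect_match(readLines(v, n = 4)[4], "POLYDATA")
})
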