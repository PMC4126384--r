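test_that("structured meshing applies the per-axis rounding rule", {
  m <- mesh_box(box_domain(1, 1, 1), 0.5)
  expect_identical(m$nelem, c(2L, 2L, 2L))
  expect_identical(nrow(m$conn), 8L)
  expect_identical(nrow(m$nodes), 27L)
  m1 <- mesh_box(box_domain(1, 1, 1), 2)  # single-element box
  expect_identical(nrow(m1$conn), 1L)
  expect_identical(nrow(m1$nodes), 8L)
  # default white-matter box at 0.2 um: counts (2, 50, 28)
  md <- mesh_box(box_domain(), 0.2)
  expect_identical(md$nelem, c(2L, 50L, 28L))
  expect_identical(nrow(md$conn), 2800L)
  # face sets cover the z-faces
  expect_identical(length(md$z0), 3L * 51L)
  expect_identical(length(md$z1), 3L * 51L)
})

test_that("embedded-point location returns trilinear partition of unity", {
  m <- mesh_box(box_domain(1, 1, 1), 0.5)
  # element centroid: eight weights of 1/8
  loc <- locate_host_and_weights(c(0.25, 0.25, 0.25), m)
  expect_equal(loc$weights, rep(1 / 8, 8))
  expect_identical(loc$element, 1L)
  # a mesh node gets weight 1 on itself
  locn <- locate_host_and_weights(c(0.5, 0.5, 0.5), m)
  expect_equal(sort(locn$weights, decreasing = TRUE)[1], 1)
  hit <- locn$nodes[which.max(locn$weights)]
  expect_equal(m$nodes[hit, ], c(0.5, 0.5, 0.5))
  # partition of unity and interpolation of coordinates at random points
  set.seed(12)
  for (k in 1:25) {
    pt <- runif(3)
    l <- locate_host_and_weights(pt, m)
    expect_lt(abs(sum(l$weights) - 1), 1e-12)
    expect_equal(as.numeric(l$weights %*% m$nodes[l$nodes, ]), pt,
                 tolerance = 1e-12)
  }
  expect_error(locate_host_and_weights(c(1.2, 0.5, 0.5), m),
               "geometry error")
})
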