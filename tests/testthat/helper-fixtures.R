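# Shared fixtures, all generated in code.  Expensive objects are memoized
# per test file through this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small, fast RVE (a couple of axons) for FE-level unit tests
small_rve <- function(seed = 11, vf = 0.07)
  build_rve(rve_config(target_volume_fraction = vf), seed = seed)

# hand-made axon path from an explicit centerline (bypasses the generator)
manual_path <- function(centerline, radius = 0.2, n_sub = 50L) {
  p <- structure(list(waypoints = centerline, centerline = centerline,
                      radius = radius,
                      tortuosity = compute_tortuosity(centerline),
                      subsegments = NULL, seed = 0L,
                      target_tortuosity = NA_real_),
                 class = "axon_path")
  partition_subsegments(p, n_sub)
}

ogden_ref <- function() ogden_material(32.8, 8.22)
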