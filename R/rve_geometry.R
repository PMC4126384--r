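## RVE geometry: randomized pseudo-3D populations of undulated axons in a
## cuboid extracellular-matrix domain.

#' Cuboid RVE domain
#'
#' @param size_x,size_y,size_z edge lengths in micrometres, all > 0.
#'   Defaults give the standard white-matter RVE of 0.4 x 10 x 5.68 um,
#'   loaded along z.
#' @return Object of class `box_domain`.
#' @export
box_domain <- function(size_x = 0.4, size_y = 10, size_z = 5.68) {
  s <- c(size_x, size_y, size_z)
  stopifnot(is.numeric(s), length(s) == 3L)
  if (any(!is.finite(s)) || any(s <= 0)) stop("all box sizes must be > 0")
  structure(list(size_x = size_x, size_y = size_y, size_z = size_z),
            class = "box_domain")
}

box_sizes <- function(domain) c(domain$size_x, domain$size_y, domain$size_z)

#' Tortuosity (undulation) of a sampled path
#'
#' Total polyline path length divided by the end-to-end (chord) length;
#' 1.0 for a straight path.
#'
#' @param points numeric matrix with one 3D sample per row (>= 2 rows).
#' @return Dimensionless ratio >= 1 (up to floating-point tolerance).
#' @examples
#' compute_tortuosity(rbind(c(0, 0, 0), c(0, 0, 5.68)))
#' @export
compute_tortuosity <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L || nrow(points) < 2L)
    stop("invalid geometry: need a numeric n x 3 matrix with at least 2 points")
  d <- diff(points)
  arc <- sum(sqrt(rowSums(d^2)))
  chord <- sqrt(sum((points[nrow(points), ] - points[1L, ])^2))
  if (chord <= .Machine$double.eps^0.5)
    stop("invalid geometry: coincident path endpoints (zero chord)")
  arc / chord
}

## Evaluate code with a private, restored RNG stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

arc_lengths <- function(points) sqrt(rowSums(diff(points)^2))

## Resample a polyline at n points equally spaced in arc length.
resample_equal_arc <- function(points, n) {
  s <- c(0, cumsum(arc_lengths(points)))
  if (s[length(s)] <= 0) stop("invalid geometry: zero arc length")
  # guard against repeated samples (possible after clipping)
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; points <- points[keep, , drop = FALSE]
  tgt <- seq(0, s[length(s)], length.out = n)
  out <- vapply(1:3, function(k) approx(s, points[, k], xout = tgt)$y,
                numeric(n))
  out
}

## Dense splined + clipped centerline for one amplitude scale.
axon_centerline <- function(draw, scale, domain, n_waypoints, n_dense = 801) {
  sz <- box_sizes(domain)
  tfrac <- seq(0, 1, length.out = n_waypoints + 2L)
  xw <- draw$x0 + (draw$x1 - draw$x0) * tfrac
  yw <- draw$y0 + (draw$y1 - draw$y0) * tfrac
  zw <- sz[3] * tfrac
  idx <- seq_len(n_waypoints) + 1L
  xw[idx] <- xw[idx] + scale * draw$dx
  yw[idx] <- yw[idx] + scale * draw$dy
  # keep the backbone inside the thin x-dimension
  xw <- pmin(pmax(xw, min(draw$radius, sz[1] / 2)),
             max(sz[1] - draw$radius, sz[1] / 2))
  tt <- seq_along(zw)
  td <- seq(1, length(zw), length.out = n_dense)
  cl <- cbind(splinefun(tt, xw, method = "natural")(td),
              splinefun(tt, yw, method = "natural")(td),
              splinefun(tt, zw, method = "natural")(td))
  # project out-of-bounds samples onto the box faces
  for (k in 1:3) cl[, k] <- pmin(pmax(cl[, k], 0), sz[k])
  list(waypoints = cbind(xw, yw, zw), centerline = cl)
}

#' Generate one undulated axon path
#'
#' Draws random waypoints between the two z-faces of the domain, smooths
#' them with a natural cubic spline, clips to the box, and iteratively
#' scales the transverse waypoint amplitudes until the realized tortuosity
#' matches `target_tortuosity`.  The centerline is resampled at equal arc
#' length and partitioned into `n_subsegments` sub-segments.
#'
#' @param seed integer seed; the same seed and arguments reproduce the path
#'   exactly.
#' @param target_tortuosity desired undulation, >= 1.
#' @param domain a [box_domain()].
#' @param n_waypoints number of interior waypoints (>= 2, default 8).
#' @param radius fiber radius in um (default 0.2, i.e. the fixed 0.4 um
#'   axon diameter).
#' @param n_subsegments number of equal-arc sub-segments (default 50).
#' @param end_offset_sd standard deviation (um) of the transverse offset of
#'   the exit point relative to the entry point; keeps the population
#'   axially aligned.
#' @param calib_tol tolerance on |realized - target| tortuosity.
#' @return Object of class `axon_path` with fields `waypoints`,
#'   `centerline` (equal-arc samples), `radius`, `tortuosity`,
#'   `subsegments`, `seed`, `target_tortuosity`.
#' @export
generate_axon_path <- function(seed, target_tortuosity, domain = box_domain(),
                               n_waypoints = 8L, radius = 0.2,
                               n_subsegments = 50L, end_offset_sd = 0.5,
                               calib_tol = 2e-3) {
  stopifnot(target_tortuosity >= 1, n_waypoints >= 2L, radius >= 0)
  sz <- box_sizes(domain)
  draw <- with_seed(seed, {
    x0 <- runif(1, min(radius, sz[1] / 2), max(sz[1] - radius, sz[1] / 2))
    y0 <- runif(1, min(radius, sz[2] / 2), max(sz[2] - radius, sz[2] / 2))
    x1 <- min(max(x0 + rnorm(1, 0, 0.05), min(radius, sz[1] / 2)),
              max(sz[1] - radius, sz[1] / 2))
    y1 <- min(max(y0 + rnorm(1, 0, end_offset_sd), min(radius, sz[2] / 2)),
              max(sz[2] - radius, sz[2] / 2))
    list(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
         dx = rnorm(n_waypoints, 0, 0.05), dy = rnorm(n_waypoints, 0, 1),
         radius = radius)
  })

  tort_at <- function(s) {
    cl <- axon_centerline(draw, s, domain, n_waypoints)$centerline
    compute_tortuosity(resample_equal_arc(cl, 4L * n_subsegments + 1L))
  }

  scale <- 0
  if (target_tortuosity > 1 + calib_tol) {
    hi <- 1
    t_hi <- tort_at(hi)
    while (t_hi < target_tortuosity && hi < 4096) {
      hi <- hi * 2
      t_new <- tort_at(hi)
      if (t_new <= t_hi + 1e-9 && t_new < target_tortuosity)
        stop(sprintf(paste0("calibration failure: target tortuosity %.4f is ",
                            "unreachable with %d waypoints (max attainable ",
                            "~ %.4f)"), target_tortuosity, n_waypoints, t_new))
      t_hi <- t_new
    }
    if (t_hi < target_tortuosity)
      stop(sprintf(paste0("calibration failure: target tortuosity %.4f is ",
                          "unreachable with %d waypoints (max attainable ",
                          "~ %.4f)"), target_tortuosity, n_waypoints, t_hi))
    lo <- 0
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      tm <- tort_at(mid)
      if (abs(tm - target_tortuosity) <= calib_tol) { lo <- hi <- mid; break }
      if (tm < target_tortuosity) lo <- mid else hi <- mid
    }
    scale <- (lo + hi) / 2
  }

  geo <- axon_centerline(draw, scale, domain, n_waypoints)
  cl <- resample_equal_arc(geo$centerline, 4L * n_subsegments + 1L)
  path <- structure(list(waypoints = geo$waypoints, centerline = cl,
                         radius = radius,
                         tortuosity = compute_tortuosity(cl),
                         subsegments = NULL, seed = as.integer(seed),
                         target_tortuosity = target_tortuosity),
                    class = "axon_path")
  partition_subsegments(path, n_subsegments)
}

#' Clip an axon path to the RVE box
#'
#' Out-of-bounds centerline and waypoint coordinates are projected onto the
#' nearest box face (the fiber axis is clamped, samples are never deleted).
#' Tortuosity and sub-segment partition are recomputed.
#'
#' @param path an `axon_path`.
#' @param domain a [box_domain()].
#' @return The clipped `axon_path`.
#' @export
clip_to_domain <- function(path, domain) {
  stopifnot(inherits(path, "axon_path"))
  cl <- path$centerline
  if (is.null(cl) || nrow(cl) < 2L)
    stop("invalid geometry: empty path")
  sz <- box_sizes(domain)
  for (k in 1:3) cl[, k] <- pmin(pmax(cl[, k], 0), sz[k])
  if (identical(cl, path$centerline) && !is.null(path$subsegments))
    return(path)  # fully interior: clipping is the identity
  for (k in 1:3)
    path$waypoints[, k] <- pmin(pmax(path$waypoints[, k], 0), sz[k])
  path$centerline <- cl
  path$tortuosity <- compute_tortuosity(cl)
  n <- if (is.null(path$subsegments)) 50L else path$subsegments$n
  partition_subsegments(path, n)
}

#' Swept-circle volume of an axon
#'
#' `pi * radius^2 * arc length` of the centerline; curvature corrections
#' and fiber overlap are ignored (the embedded-element approach does not
#' subtract axon volume from the matrix).
#'
#' @param path an `axon_path`.
#' @return Volume in um^3.
#' @export
axon_volume <- function(path) {
  stopifnot(inherits(path, "axon_path"))
  pi * path$radius^2 * sum(arc_lengths(path$centerline))
}

#' Partition an axon into equal-arc sub-segments
#'
#' Resamples the centerline at `4 n + 1` equal-arc points and records the
#' sub-segment boundaries as centerline indices, together with per-piece
#' arc lengths and local tortuosities (used by the straightest-first
#' coupling policy).
#'
#' @param path an `axon_path`.
#' @param n number of sub-segments (default 50).
#' @return The `axon_path` with an updated `subsegments` field.
#' @export
partition_subsegments <- function(path, n = 50L) {
  stopifnot(inherits(path, "axon_path"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("configuration error: need n >= 1 sub-segments")
  cl <- resample_equal_arc(path$centerline, 4L * n + 1L)
  breaks <- seq(1L, 4L * n + 1L, by = 4L)
  seg <- arc_lengths(cl)
  piece_arc <- vapply(seq_len(n), function(i)
    sum(seg[(4 * (i - 1) + 1):(4 * i)]), numeric(1))
  local_tort <- vapply(seq_len(n), function(i) {
    pts <- cl[breaks[i]:breaks[i + 1L], , drop = FALSE]
    compute_tortuosity(pts)
  }, numeric(1))
  path$centerline <- cl
  path$tortuosity <- compute_tortuosity(cl)
  path$subsegments <- list(n = n, breaks = breaks, arc_lengths = piece_arc,
                           local_tortuosity = local_tort)
  path
}

#' @export
print.axon_path <- function(x, ...) {
  cat(sprintf("axon path: radius %g um, tortuosity %.4f, %d sub-segments\n",
              x$radius, x$tortuosity,
              if (is.null(x$subsegments)) 0L else x$subsegments$n))
  invisible(x)
}

#' RVE generator configuration
#'
#' Defaults are the standard white-matter study conditions: 0.4 x 10 x
#' 5.68 um box, 0.4 um axon diameter, 53% axon volume fraction, and target
#' undulations drawn from a truncated normal (mean 1.13, sd 0.06, support
#' `[1.02, 1.30]`) so that the population mean lies in the physiological
#' 1.05-1.25 range.
#'
#' @param domain a [box_domain()].
#' @param radius axon radius in um.
#' @param target_volume_fraction axon volume fraction to reach.
#' @param vf_tolerance allowed |achieved - target| (default 0.01).
#' @param packing_bound configuration upper bound on the reachable volume
#'   fraction; targets above it are rejected.
#' @param tortuosity list with `mean`, `sd`, `min`, `max` of the truncated
#'   normal target-undulation distribution.
#' @param n_waypoints interior waypoints per axon.
#' @param n_subsegments sub-segments per axon.
#' @param end_offset_sd transverse exit-point offset sd in um.
#' @param max_axons safety cap on the population size.
#' @return Object of class `rve_config`.
#' @export
rve_config <- function(domain = box_domain(), radius = 0.2,
                       target_volume_fraction = 0.53, vf_tolerance = 0.01,
                       packing_bound = 0.9,
                       tortuosity = list(mean = 1.13, sd = 0.06,
                                         min = 1.02, max = 1.30),
                       n_waypoints = 8L, n_subsegments = 50L,
                       end_offset_sd = 0.5, max_axons = 1000L) {
  stopifnot(inherits(domain, "box_domain"), radius >= 0,
            target_volume_fraction >= 0, vf_tolerance > 0,
            tortuosity$min >= 1, tortuosity$max >= tortuosity$min)
  structure(list(domain = domain, radius = radius,
                 target_volume_fraction = target_volume_fraction,
                 vf_tolerance = vf_tolerance, packing_bound = packing_bound,
                 tortuosity = tortuosity, n_waypoints = as.integer(n_waypoints),
                 n_subsegments = as.integer(n_subsegments),
                 end_offset_sd = end_offset_sd,
                 max_axons = as.integer(max_axons)),
            class = "rve_config")
}

## truncated-normal draw under an isolated stream
draw_trunc_normal <- function(seed, m, s, lo, hi) {
  with_seed(seed, {
    for (i in 1:10000) {
      x <- rnorm(1, m, s)
      if (x >= lo && x <= hi) return(x)
    }
    stop("truncated-normal rejection sampling failed")
  })
}

axon_sub_seed <- function(seed, i, salt = 0L)
  as.integer((as.double(seed) + 9973 * i + 104729 * salt) %% 2147483647)

#' Build a randomized RVE
#'
#' Adds axons one at a time (target undulations sampled from the configured
#' truncated normal, per-axon sub-seeds derived from `seed` by a counter
#' scheme so axon i does not depend on how many axons follow) until the
#' summed swept-circle volume first reaches the target volume fraction.
#' The population is then trimmed to whichever of n or n-1 axons is closer
#' to the target, and all undulation amplitudes are rescaled by a single
#' factor so the achieved fraction matches the target to well within
#' `vf_tolerance`.
#'
#' @param config an [rve_config()].
#' @param seed integer seed; reproducible bit-for-bit.
#' @return Object of class `rve_geometry` with fields `domain`, `axons`,
#'   `target_volume_fraction`, `achieved_volume_fraction`, `seed`, `config`.
#' @export
build_rve <- function(config = rve_config(), seed = 1L) {
  stopifnot(inherits(config, "rve_config"))
  tgt <- config$target_volume_fraction
  if (tgt > config$packing_bound)
    stop(sprintf(paste0("configuration error: target volume fraction %.3f ",
                        "exceeds the geometric packing bound %.3f"),
                 tgt, config$packing_bound))
  dom <- config$domain
  vbox <- prod(box_sizes(dom))
  area <- pi * config$radius^2

  make_axon <- function(i, tau) {
    generate_axon_path(axon_sub_seed(seed, i), tau, dom,
                       n_waypoints = config$n_waypoints,
                       radius = config$radius,
                       n_subsegments = config$n_subsegments,
                       end_offset_sd = config$end_offset_sd)
  }

  axons <- list(); taus <- numeric(0); vols <- numeric(0)
  if (tgt > 0 && area > 0) {
    i <- 0L
    while (sum(vols) < tgt * vbox) {
      i <- i + 1L
      if (i > config$max_axons)
        stop("configuration error: axon cap reached before target fraction")
      tau <- draw_trunc_normal(axon_sub_seed(seed, i, 1L),
                               config$tortuosity$mean, config$tortuosity$sd,
                               config$tortuosity$min, config$tortuosity$max)
      p <- make_axon(i, tau)
      axons[[i]] <- p; taus[i] <- p$tortuosity; vols[i] <- axon_volume(p)
    }
    n <- length(axons)
    if (n > 1L) {
      over <- sum(vols) - tgt * vbox
      under <- tgt * vbox - sum(vols[-n])
      if (under < over) {
        axons <- axons[-n]; taus <- taus[-n]; vols <- vols[-n]
        n <- n - 1L
      }
    }
    # single amplitude rescale tau' = 1 + gamma (tau - 1) to land on target
    chords <- vapply(axons, function(p)
      sqrt(sum((p$centerline[nrow(p$centerline), ] - p$centerline[1, ])^2)),
      numeric(1))
    den <- sum(chords * (taus - 1))
    if (den > 1e-9) {
      gamma <- (tgt * vbox / area - sum(chords)) / den
      taus2 <- pmax(1, 1 + gamma * (taus - 1))
      axons <- lapply(seq_len(n), function(i) make_axon(i, taus2[i]))
    }
  }

  achieved <- if (length(axons)) sum(vapply(axons, axon_volume, numeric(1))) / vbox else 0
  structure(list(domain = dom, axons = axons, target_volume_fraction = tgt,
                 achieved_volume_fraction = achieved, seed = as.integer(seed),
                 config = config),
            class = "rve_geometry")
}

#' @export
print.rve_geometry <- function(x, ...) {
  mt <- if (length(x$axons))
    mean(vapply(x$axons, function(p) p$tortuosity, numeric(1))) else NA_real_
  cat(sprintf(paste0("RVE: %g x %g x %g um, %d axons, volume fraction ",
                     "%.3f (target %.3f), mean tortuosity %.3f, seed %d\n"),
              x$domain$size_x, x$domain$size_y, x$domain$size_z,
              length(x$axons), x$achieved_volume_fraction,
              x$target_volume_fraction, mt, x$seed))
  invisible(x)
}

#' Serialize an RVE to JSON
#'
#' Writes domain, per-axon waypoints, centerline samples, radius,
#' tortuosity, sub-segment boundaries and the generation seed.  The same
#' seed and configuration produce a byte-identical file.
#'
#' @param rve an `rve_geometry`.
#' @param path output file; if `NULL`, the JSON string is returned.
#' @export
rve_to_json <- function(rve, path = NULL) {
  stopifnot(inherits(rve, "rve_geometry"))
  lst <- list(
    domain = unclass(rve$domain),
    target_volume_fraction = rve$target_volume_fraction,
    achieved_volume_fraction = rve$achieved_volume_fraction,
    seed = rve$seed,
    axons = lapply(rve$axons, function(p) list(
      waypoints = unname(p$waypoints), centerline = unname(p$centerline),
      radius = p$radius, tortuosity = p$tortuosity,
      subsegment_breaks = p$subsegments$breaks, seed = p$seed,
      target_tortuosity = p$target_tortuosity)))
  js <- jsonlite::toJSON(lst, digits = I(15), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read an RVE back from its JSON serialization
#'
#' @param path file written by [rve_to_json()].
#' @return An `rve_geometry` (axon sub-segment tables are recomputed from
#'   the stored centerlines).
#' @export
rve_from_json <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  dom <- box_domain(lst$domain$size_x, lst$domain$size_y, lst$domain$size_z)
  ax <- lst$axons
  n_ax <- if (is.null(ax) || length(ax) == 0) 0L else length(ax$radius)
  axons <- lapply(seq_len(n_ax), function(i) {
    cl <- ax$centerline[[i]]
    breaks <- as.integer(ax$subsegment_breaks[[i]])
    n <- length(breaks) - 1L
    seg <- arc_lengths(cl)
    piece_arc <- vapply(seq_len(n), function(k)
      sum(seg[breaks[k]:(breaks[k + 1L] - 1L)]), numeric(1))
    local_tort <- vapply(seq_len(n), function(k)
      compute_tortuosity(cl[breaks[k]:breaks[k + 1L], , drop = FALSE]),
      numeric(1))
    structure(list(waypoints = ax$waypoints[[i]], centerline = cl,
                   radius = ax$radius[i], tortuosity = ax$tortuosity[i],
                   subsegments = list(n = n, breaks = breaks,
                                      arc_lengths = piece_arc,
                                      local_tortuosity = local_tort),
                   seed = ax$seed[i],
                   target_tortuosity = ax$target_tortuosity[i]),
              class = "axon_path")
  })
  structure(list(domain = dom, axons = axons,
                 target_volume_fraction = lst$target_volume_fraction,
                 achieved_volume_fraction = lst$achieved_volume_fraction,
                 seed = lst$seed, config = NULL),
            class = "rve_geometry")
}

#' Export axon centerlines as legacy-VTK polylines
#'
#' @param rve an `rve_geometry`.
#' @param path output `.vtk` file.
#' @export
write_vtk_polylines <- function(rve, path) {
  stopifnot(inherits(rve, "rve_geometry"))
  pts <- do.call(rbind, lapply(rve$axons, function(p) p$centerline))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axon centerlines", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", if (is.null(pts)) 0L else nrow(pts))),
             con)
  if (!is.null(pts) && nrow(pts))
    write(t(pts), file = con, ncolumns = 3)
  sizes <- vapply(rve$axons, function(p) nrow(p$centerline), integer(1))
  writeLines(sprintf("LINES %d %d", length(sizes), sum(sizes + 1L)), con)
  off <- 0L
  for (s in sizes) {
    writeLines(paste(c(s, seq(off, off + s - 1L)), collapse = " "), con)
    off <- off + s
  }
  invisible(path)
}
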