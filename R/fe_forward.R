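## Staged forward simulation of uniaxial tension on an RVE, with coupling
## updates between stages, and post-processing of the homogenized response.

#' Staged uniaxial tension simulation
#'
#' Solves the RVE under the staged loading protocol (default stretches
#' 1.06, 1.12, 1.25 along z).  Before each stage the transitional
#' kinematic rule is evaluated at that stage's stretch using every axon's
#' current (deformed) undulation, the coupled sub-segment sets are grown
#' monotonically, and the penalty-spring stiffnesses are rebuilt; this
#' realizes the protocol of updating embedded-element interactions after
#' each step.  The homogenized nominal stress S33 is recorded at every
#' accepted substep and per-axon tortuosities at the reference state and
#' every stage stretch.
#'
#' @param rve an `rve_geometry`.
#' @param materials a [wm_materials()] list.
#' @param program a [load_program()].
#' @param rule a [coupling_rule()].
#' @param mesh_size hex edge length in um.
#' @param control a [newton_control()].
#' @param k_high_factor,k_low_factor,policy passed to [fe_model()].
#' @param keep_model keep the FE model and final displacements in the
#'   result (needed for field export)?
#' @param verbose print per-stage progress?
#' @return Object of class `homogenized_result`: `curve` (lambda,
#'   S33_kPa), `trace` (axon, lambda, tortuosity), `von_mises` (list of
#'   per-element fields, one per stage), `coupling_log`, and optionally
#'   `model`, `u`.
#' @export
staged_simulation <- function(rve, materials, program = load_program(),
                              rule = coupling_rule(), mesh_size = 0.2,
                              control = newton_control(),
                              k_high_factor = 1e3, k_low_factor = 1e-3,
                              policy = "straightest", keep_model = FALSE,
                              verbose = FALSE) {
  model <- fe_model(rve, materials, mesh_size = mesh_size, rule = rule,
                    k_high_factor = k_high_factor,
                    k_low_factor = k_low_factor, policy = policy)
  paths <- rve$axons
  n_ax <- length(paths)
  fiber_pos <- function(u) lapply(seq_len(n_ax), function(i) {
    ids <- model$node_blocks[[i]]
    model$X[ids, , drop = FALSE] +
      cbind(u[3 * (ids - 1) + 1], u[3 * (ids - 1) + 2], u[3 * (ids - 1) + 3])
  })

  coupling <- if (n_ax) update_coupling_state(NULL, paths,
                                              applied_stretch = program$stages[1],
                                              rule = rule, policy = policy)
              else NULL
  state <- fe_state(model, coupling)
  trace <- if (n_ax)
    data.frame(axon = seq_len(n_ax), lambda = 1,
               tortuosity = vapply(paths, function(p)
                 compute_tortuosity(fiber_nodes_of_path(p)), numeric(1)))
  else data.frame(axon = integer(0), lambda = numeric(0),
                  tortuosity = numeric(0))
  clog <- if (!is.null(coupling)) coupling$log else NULL
  vm <- list()

  for (k in seq_along(program$stages)) {
    lam_k <- program$stages[k]
    if (verbose)
      message(sprintf("stage %d: loading to lambda = %.4f", k, lam_k))
    state <- newton_solve(model, state, lam_k, program$substeps[k], control)
    pos <- fiber_pos(state$u)
    if (n_ax)
      trace <- rbind(trace,
                     data.frame(axon = seq_len(n_ax), lambda = lam_k,
                                tortuosity = vapply(pos, compute_tortuosity,
                                                    numeric(1))))
    vm[[k]] <- von_mises_field(model, state$u)
    if (k < length(program$stages) && n_ax) {
      coupling <- update_coupling_state(coupling, paths, pos,
                                        applied_stretch = program$stages[k + 1],
                                        rule = rule, policy = policy)
      clog <- rbind(clog, coupling$log)
      state$coupling <- coupling
      state$springs <- coupling_stiffness(model, coupling, state$u)
    }
  }

  out <- list(curve = state$curve, trace = trace, von_mises = vm,
              coupling_log = clog, stages = program$stages,
              n_axons = n_ax, mesh_size = mesh_size)
  if (keep_model) { out$model <- model; out$u <- state$u }
  structure(out, class = "homogenized_result")
}

#' @export
print.homogenized_result <- function(x, ...) {
  cat(sprintf("homogenized uniaxial response: %d axons, %d curve points, S33(%.2f) = %.3f kPa\n",
              x$n_axons, nrow(x$curve), max(x$curve$lambda),
              x$curve$S33_kPa[nrow(x$curve)]))
  invisible(x)
}

#' Per-element von Mises stress field
#'
#' Deviatoric invariant of the element-averaged Cauchy stress of the
#' matrix phase.
#'
#' @param model an [fe_model()].
#' @param u converged displacement vector.
#' @return Numeric vector, one value per hex element, in kPa.
#' @export
von_mises_field <- function(model, u) {
  ecm <- model$materials$ecm
  st <- cpp_hex_stress(model$mesh$nodes, model$mesh$conn,
                       u[seq_len(3L * model$nm)],
                       ecm$mu, ecm$alpha, ecm$bulk_penalty)
  s <- st$cauchy
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                (s[, 3] - s[, 1])^2) +
         3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

## volume-averaged first Piola P33 of the matrix phase (cross-check for
## the boundary-reaction homogenization)
volume_averaged_P33 <- function(model, u) {
  ecm <- model$materials$ecm
  st <- cpp_hex_stress(model$mesh$nodes, model$mesh$conn,
                       u[seq_len(3L * model$nm)],
                       ecm$mu, ecm$alpha, ecm$bulk_penalty)
  mean(st$P33)
}

#' Tortuosity trace of a staged simulation
#'
#' @param result a `homogenized_result`.
#' @return Data frame `(axon, lambda, tortuosity)` with the population
#'   mean per stretch level attached as attribute `"population_mean"`.
#' @export
tortuosity_trace <- function(result) {
  stopifnot(inherits(result, "homogenized_result"))
  tr <- result$trace
  mn <- if (nrow(tr))
    stats::aggregate(tortuosity ~ lambda, tr, mean)
  else data.frame(lambda = numeric(0), tortuosity = numeric(0))
  attr(tr, "population_mean") <- mn
  tr
}

#' Write a stress-stretch curve to CSV
#'
#' @param curve data frame with columns `lambda`, `S33_kPa` (or a
#'   `stress_stretch_curve`).
#' @param path output file.
#' @export
write_curve_csv <- function(curve, path) {
  if (inherits(curve, "stress_stretch_curve"))
    curve <- data.frame(lambda = curve$lambda, S33_kPa = curve$S_kPa)
  stopifnot(all(c("lambda", "S33_kPa") %in% names(curve)))
  write.csv(curve[, c("lambda", "S33_kPa")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Export the deformed mesh with fields as legacy VTK
#'
#' Unstructured hex grid with point displacements and the per-element von
#' Mises stress.
#'
#' @param model an [fe_model()].
#' @param u converged displacement vector.
#' @param path output `.vtk` file.
#' @export
write_vtk_fields <- function(model, u, path) {
  mesh <- model$mesh
  nm <- model$nm
  disp <- matrix(u[seq_len(3 * nm)], ncol = 3, byrow = TRUE)
  vm <- von_mises_field(model, u)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "axonrve fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nm)), con)
  write(t(mesh$nodes), file = con, ncolumns = 3)
  nel <- nrow(mesh$conn)
  writeLines(sprintf("CELLS %d %d", nel, 9L * nel), con)
  write(t(cbind(8L, mesh$conn - 1L)), file = con, ncolumns = 9)
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  write(rep(12L, nel), file = con, ncolumns = 1)
  writeLines(c(sprintf("POINT_DATA %d", nm),
               "VECTORS displacement double"), con)
  write(t(disp), file = con, ncolumns = 3)
  writeLines(c(sprintf("CELL_DATA %d", nel),
               "SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
  write(vm, file = con, ncolumns = 1)
  invisible(path)
}
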