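## Total-Lagrangian FE model of an RVE: hexahedral Ogden matrix, embedded
## nonlinear truss chains for the axons, and penalty springs realizing the
## fractional embedded-element coupling.

#' Matrix/axon material pair for the white-matter RVE
#'
#' The axon shear modulus is `mu_ratio` times the extracellular-matrix
#' modulus (default 3), both phases share the nonlinearity `alpha`, and the
#' matrix receives a volumetric penalty of `bulk_factor * mu_ecm`.
#'
#' @param mu_axon axon shear modulus in kPa.
#' @param alpha shared Ogden nonlinearity (default 8.22).
#' @param mu_ratio axon:matrix stiffness ratio (default 3).
#' @param bulk_factor volumetric penalty as a multiple of the matrix
#'   modulus (default 100, approximately Poisson 0.495).
#' @return List with `ecm` and `axon` [ogden_material()] objects.
#' @export
wm_materials <- function(mu_axon, alpha = 8.22, mu_ratio = 3,
                         bulk_factor = 100) {
  stopifnot(mu_axon > 0, mu_ratio > 0, bulk_factor >= 10)
  mu_ecm <- mu_axon / mu_ratio
  list(ecm = ogden_material(mu_ecm, alpha, bulk_factor * mu_ecm),
       axon = ogden_material(mu_axon, alpha, bulk_factor * mu_axon))
}

#' Staged uniaxial loading program
#'
#' @param stages strictly increasing stage stretches, all > 1 (default
#'   1.06, 1.12, 1.25); the stretch is imposed by fixing `U_z = 0` on the
#'   `z = 0` face and prescribing `U_z` on the opposite face.
#' @param substeps Newton load increments per stage (scalar or per-stage).
#' @return Object of class `load_program`.
#' @export
load_program <- function(stages = c(1.06, 1.12, 1.25), substeps = 6L) {
  stopifnot(length(stages) >= 1L, all(stages > 1))
  if (any(diff(stages) <= 0)) stop("stage stretches must be strictly increasing")
  substeps <- as.integer(rep_len(substeps, length(stages)))
  stopifnot(all(substeps >= 1L))
  structure(list(stages = stages, substeps = substeps),
            class = "load_program")
}

#' Newton solver controls
#'
#' @param rtol relative residual tolerance (vs the first residual of each
#'   increment), default 1e-8.
#' @param atol absolute residual tolerance in force units (kPa um^2).
#' @param max_iter maximum Newton iterations per increment.
#' @param ls_max maximum step halvings in the backtracking line search.
#' @param step_cap trust-region cap on the infinity norm of a Newton step,
#'   in um; protects the nearly force-free transverse modes of uncoupled
#'   fiber chains from huge excursions.
#' @export
newton_control <- function(rtol = 1e-8, atol = 1e-8, max_iter = 60L,
                           ls_max = 10L, step_cap = 0.25) {
  list(rtol = rtol, atol = atol, max_iter = as.integer(max_iter),
       ls_max = as.integer(ls_max), step_cap = step_cap)
}

## homogeneous incompressible uniaxial map used as incremental predictor
affine_displacement <- function(X, lambda)
  cbind((lambda^-0.5 - 1) * X[, 1], (lambda^-0.5 - 1) * X[, 2],
        (lambda - 1) * X[, 3])

#' Assemble the FE model of an RVE
#'
#' Meshes the box with hexahedra, places one fiber node per sub-segment
#' boundary of every axon, chains them with nonlinear truss segments
#' (axial nominal stress from the incompressible uniaxial Ogden law times
#' the fiber cross-section), and precomputes the embedding interpolation
#' used by the penalty coupling springs.
#'
#' @param rve an `rve_geometry`.
#' @param materials a [wm_materials()] list.
#' @param mesh_size target hex edge length in um (default 0.2).
#' @param rule a [coupling_rule()].
#' @param k_high_factor,k_low_factor penalty spring stiffnesses for coupled
#'   and uncoupled fiber nodes, as multiples of `mu_ecm * h` (defaults 1e3
#'   and 1e-3; the low value only regularizes otherwise transversely
#'   floating truss nodes).
#' @param policy sub-segment selection policy, see
#'   [select_coupled_subsegments()].
#' @return Object of class `fe_model`.
#' @export
fe_model <- function(rve, materials, mesh_size = 0.2, rule = coupling_rule(),
                     k_high_factor = 1e3, k_low_factor = 1e-3,
                     policy = "straightest") {
  stopifnot(inherits(rve, "rve_geometry"))
  mesh <- mesh_box(rve$domain, mesh_size)
  nm <- nrow(mesh$nodes)
  paths <- rve$axons
  n_ax <- length(paths)
  fib <- lapply(paths, fiber_nodes_of_path)
  n_per <- vapply(fib, nrow, integer(1))
  nf <- sum(n_per)
  Xf <- if (nf) do.call(rbind, fib) else matrix(0, 0, 3)
  X <- rbind(mesh$nodes, Xf)

  # truss chain connectivity (global node ids) and reference lengths
  off <- nm + c(0L, cumsum(n_per))
  seg_a <- integer(0); seg_b <- integer(0); seg_axon <- integer(0)
  for (i in seq_len(n_ax)) {
    ids <- off[i] + seq_len(n_per[i])
    seg_a <- c(seg_a, ids[-length(ids)])
    seg_b <- c(seg_b, ids[-1L])
    seg_axon <- c(seg_axon, rep.int(i, n_per[i] - 1L))
  }
  L0 <- if (length(seg_a)) sqrt(rowSums((X[seg_b, , drop = FALSE] -
                                           X[seg_a, , drop = FALSE])^2))
        else numeric(0)
  ok <- L0 > 1e-9
  if (!all(ok)) {
    seg_a <- seg_a[ok]; seg_b <- seg_b[ok]; seg_axon <- seg_axon[ok]
    L0 <- L0[ok]
  }

  # embedding interpolation: gap operator g = u_fiber - W u_matrix
  if (nf) {
    hosts <- matrix(0L, nf, 8); wts <- matrix(0, nf, 8)
    for (f in seq_len(nf)) {
      loc <- locate_host_and_weights(Xf[f, ], mesh)
      hosts[f, ] <- loc$nodes; wts[f, ] <- loc$weights
    }
    G <- Matrix::sparseMatrix(
      i = c(seq_len(nf), rep(seq_len(nf), 8L)),
      j = c(nm + seq_len(nf), as.integer(hosts)),
      x = c(rep(1, nf), -as.numeric(wts)),
      dims = c(nf, nm + nf))
    Gc <- Matrix::kronecker(G, Matrix::Diagonal(3))
  } else Gc <- NULL

  # per-axon fiber node index blocks and node->subsegment adjacency
  node_blocks <- lapply(seq_len(n_ax), function(i) off[i] + seq_len(n_per[i]))

  # boundary conditions on the matrix mesh
  sz <- box_sizes(rve$domain)
  zdof <- function(n) 3L * (n - 1L) + 3L
  nn <- mesh$nnode
  pin1 <- 1L                      # node at (0, 0, 0): fix ux, uy
  pin2 <- 1L + (nn[2] - 1L) * nn[1]  # node at (0, size_y, 0): fix ux
  presc_idx <- c(zdof(mesh$z0), zdof(mesh$z1),
                 3L * (pin1 - 1L) + 1L, 3L * (pin1 - 1L) + 2L,
                 3L * (pin2 - 1L) + 1L)
  presc_val <- function(lambda) c(rep(0, length(mesh$z0)),
                                  rep((lambda - 1) * sz[3], length(mesh$z1)),
                                  0, 0, 0)
  ndof <- 3L * (nm + nf)
  free <- setdiff(seq_len(ndof), presc_idx)

  h_mean <- prod(mesh$h)^(1 / 3)
  structure(list(rve = rve, mesh = mesh, materials = materials, rule = rule,
                 policy = policy, nm = nm, nf = nf, X = X, ndof = ndof,
                 seg_a = seg_a, seg_b = seg_b, seg_axon = seg_axon, L0 = L0,
                 fiber_area = pi * (if (n_ax) paths[[1]]$radius else 0)^2,
                 Gc = Gc, node_blocks = node_blocks, n_per = n_per,
                 presc_idx = presc_idx, presc_val = presc_val, free = free,
                 k_high = k_high_factor * materials$ecm$mu * h_mean,
                 k_low = k_low_factor * materials$ecm$mu * h_mean),
            class = "fe_model")
}

## Penalty-spring system for a coupling state.  Fiber nodes adjacent to a
## coupled sub-segment use k_high; the first and last node of every axon
## are always tied (k_high); all others use k_low.  The springs penalize
## the embedding gap g = u_fiber - W u_matrix relative to the gap `g0`
## recorded when the coupling was (re)established, so a newly coupled
## node is tied at its *current* position rather than snapped back to the
## affine image of its reference location.  Returns the stiffness matrix
## `K` and the constant force vector `f0 = Gc' Kd g0` (zero at the
## reference state).
coupling_stiffness <- function(model, coupling, u = NULL) {
  if (model$nf == 0L) {
    Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              x = numeric(0),
                              dims = c(model$ndof, model$ndof))
    return(list(K = Z, f0 = numeric(model$ndof)))
  }
  k <- numeric(model$nf)
  for (i in seq_along(model$node_blocks)) {
    nloc <- model$n_per[i]
    kk <- rep(model$k_low, nloc)
    if (!is.null(coupling)) {
      segs <- coupling$coupled_sets[[i]]
      if (length(segs)) kk[sort(unique(c(segs, segs + 1L)))] <- model$k_high
    }
    kk[c(1L, nloc)] <- model$k_high  # end ties at the RVE surfaces
    k[model$node_blocks[[i]] - model$nm] <- kk
  }
  kd <- rep(k, each = 3L)
  K <- Matrix::crossprod(model$Gc, Matrix::Diagonal(x = kd) %*% model$Gc)
  f0 <- numeric(model$ndof)
  if (!is.null(u)) {
    g0 <- as.numeric(model$Gc %*% u)
    f0 <- as.numeric(Matrix::crossprod(model$Gc, kd * g0))
  }
  list(K = K, f0 = f0)
}

## Truss residual contributions and (optionally) tangent triplets.
truss_assemble <- function(model, u, want_tangent) {
  ns <- length(model$seg_a)
  if (ns == 0L)
    return(list(r = NULL, i = integer(0), j = integer(0), v = numeric(0)))
  A <- model$fiber_area
  mat <- model$materials$axon
  ia <- 3L * (model$seg_a - 1L); ib <- 3L * (model$seg_b - 1L)
  xa <- model$X[model$seg_a, , drop = FALSE] +
    cbind(u[ia + 1L], u[ia + 2L], u[ia + 3L])
  xb <- model$X[model$seg_b, , drop = FALSE] +
    cbind(u[ib + 1L], u[ib + 2L], u[ib + 3L])
  d <- xb - xa
  l <- sqrt(rowSums(d^2))
  if (any(l <= 1e-12)) stop("degenerate truss segment (zero current length)")
  nrm <- d / l
  lam <- l / model$L0
  N <- A * uniaxial_nominal_stress(lam, mat)
  a <- mat$alpha
  Wuni <- (2 * mat$mu / a^2) * (lam^a + 2 * lam^(-a / 2) - 3)
  ri <- c(ib + 1L, ib + 2L, ib + 3L, ia + 1L, ia + 2L, ia + 3L)
  rv <- c(N * nrm[, 1], N * nrm[, 2], N * nrm[, 3],
          -N * nrm[, 1], -N * nrm[, 2], -N * nrm[, 3])
  out <- list(r = list(i = ri, v = rv),
              energy = A * sum(model$L0 * Wuni))
  if (want_tangent) {
    km <- A * uniaxial_tangent_modulus(lam, mat) / model$L0
    kg <- N / l
    ti <- tj <- integer(36L * ns); tv <- numeric(36L * ns)
    pos <- 0L
    for (p in 1:3) for (q in 1:3) {
      v <- km * nrm[, p] * nrm[, q] + kg * ((p == q) - nrm[, p] * nrm[, q])
      blk_i <- c(ia + p, ib + p, ia + p, ib + p)
      blk_j <- c(ia + q, ib + q, ib + q, ia + q)
      blk_v <- c(v, v, -v, -v)
      idx <- pos + seq_len(4L * ns)
      ti[idx] <- blk_i; tj[idx] <- blk_j; tv[idx] <- blk_v
      pos <- pos + 4L * ns
    }
    out$i <- ti; out$j <- tj; out$v <- tv
  } else {
    out$i <- integer(0); out$j <- integer(0); out$v <- numeric(0)
  }
  out
}

#' Assemble the global residual and tangent
#'
#' Internal forces of the hexahedral Ogden matrix (2x2x2 Gauss), axial
#' forces of the fiber truss segments, and the penalty coupling springs;
#' the tangent is consistent (finite-difference exact to truncation) and
#' symmetric.
#'
#' @param model an [fe_model()].
#' @param u global displacement vector (matrix dofs then fiber dofs).
#' @param springs precomputed coupling-spring system (list `K`, `f0` from
#'   the current coupling state); `NULL` means end-ties only, anchored at
#'   the reference state.
#' @param want_tangent assemble the sparse tangent as well?
#' @return List with `r` (residual), `K` (sparse tangent or `NULL`),
#'   `energy` (total strain + spring energy, the potential whose gradient
#'   is `r`, up to a constant), and `min_detF`.
#' @export
assemble_system <- function(model, u, springs = NULL, want_tangent = TRUE) {
  stopifnot(inherits(model, "fe_model"), length(u) == model$ndof)
  ecm <- model$materials$ecm
  hx <- cpp_hex_assemble(model$mesh$nodes, model$mesh$conn,
                         u[seq_len(3L * model$nm)],
                         ecm$mu, ecm$alpha, ecm$bulk_penalty, want_tangent)
  if (hx$bad_element > 0L)
    stop(sprintf("element inversion in hex element %d (det F <= 0)",
                 hx$bad_element))
  r <- numeric(model$ndof)
  r[seq_len(3L * model$nm)] <- hx$r
  energy <- hx$energy
  tr <- truss_assemble(model, u, want_tangent)
  if (!is.null(tr$r)) {
    add <- Matrix::sparseMatrix(i = tr$r$i, j = rep(1L, length(tr$r$i)),
                                x = tr$r$v, dims = c(model$ndof, 1L))
    r <- r + as.numeric(add)
    energy <- energy + tr$energy
  }
  if (is.null(springs)) springs <- coupling_stiffness(model, NULL)
  spr <- as.numeric(springs$K %*% u)
  r <- r + spr - springs$f0
  energy <- energy + 0.5 * sum(u * spr) - sum(u * springs$f0)
  K <- NULL
  if (want_tangent) {
    K <- Matrix::sparseMatrix(i = c(hx$i, tr$i), j = c(hx$j, tr$j),
                              x = c(hx$v, tr$v),
                              dims = c(model$ndof, model$ndof)) + springs$K
  }
  list(r = r, K = K, energy = energy, min_detF = hx$min_detF)
}

solve_linear <- function(K, b) {
  tryCatch(as.numeric(Matrix::solve(Matrix::forceSymmetric(K), b)),
           error = function(e) as.numeric(Matrix::solve(K, b)))
}

#' Newton continuation to a target stretch
#'
#' Loads the model from the state's current stretch to `target_stretch` in
#' equal displacement increments, solving each with a full Newton
#' iteration (backtracking line search) on the free degrees of freedom.
#'
#' @param model an [fe_model()].
#' @param state list with `u` (displacements), `lambda` (current applied
#'   stretch) and `springs` (current coupling-spring system); use
#'   [fe_state()] for the reference state.
#' @param target_stretch stretch to reach (>= current).
#' @param substeps number of equal increments.
#' @param control a [newton_control()] list.
#' @param curve_callback optional `function(lambda, S33)` called at every
#'   accepted increment.
#' @return Updated state; `state$curve` accumulates `(lambda, S33)` rows.
#' @export
newton_solve <- function(model, state, target_stretch, substeps = 6L,
                         control = newton_control(), curve_callback = NULL) {
  stopifnot(inherits(model, "fe_model"))
  if (target_stretch < state$lambda - 1e-12)
    stop("target stretch must be >= the current stretch")
  if (is.null(state$springs))
    state$springs <- coupling_stiffness(model, state$coupling)
  u <- state$u
  free <- model$free
  lams <- if (target_stretch > state$lambda + 1e-12)
    seq(state$lambda, target_stretch, length.out = substeps + 1L)[-1L]
  else numeric(0)

  lam_prev <- state$lambda
  for (lam in lams) {
    # affine predictor: every free node follows the incremental
    # homogeneous incompressible map
    dup <- affine_displacement(model$X, lam) -
      affine_displacement(model$X, lam_prev)
    u <- u + as.numeric(t(dup))
    lam_prev <- lam
    u[model$presc_idx] <- model$presc_val(lam)
    sys <- assemble_system(model, u, state$springs, want_tangent = FALSE)
    rn <- sqrt(sum(sys$r[free]^2))
    en <- sys$energy
    ref <- max(rn, control$atol)
    iter <- 0L
    while (rn > max(control$rtol * ref, control$atol)) {
      iter <- iter + 1L
      if (iter > control$max_iter)
        stop(sprintf(paste0("Newton failed to converge: lambda = %.5f, ",
                            "%d iterations, residual %.3e"),
                     lam, iter - 1L, rn))
      sysK <- assemble_system(model, u, state$springs, want_tangent = TRUE)
      Kff <- sysK$K[free, free]
      g <- sysK$r[free]
      # Newton direction; Levenberg diagonal shift if the tangent is
      # indefinite or the direction is not a descent direction of the
      # potential energy
      tau <- 0
      tau0 <- 1e-8 * mean(abs(Matrix::diag(Kff)))
      repeat {
        Ks <- if (tau > 0) Kff + tau * Matrix::Diagonal(length(free)) else Kff
        du <- tryCatch(
          as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Ks),
                                                    perm = TRUE), -g)),
          error = function(e) NULL)
        if (!is.null(du) && sum(g * du) < 0) break
        tau <- if (tau == 0) tau0 else tau * 100
        if (tau > 1e12 * tau0) { du <- -g; break }
      }
      # backtracking Armijo line search on the potential energy,
      # starting from the trust-region-capped step
      gd <- sum(g * du)
      stepl <- min(1, control$step_cap / max(abs(du)))
      best <- NULL
      for (ls in 0:control$ls_max) {
        ut <- u
        ut[free] <- u[free] + stepl * du
        st <- tryCatch(assemble_system(model, ut, state$springs,
                                       want_tangent = FALSE),
                       error = function(e) NULL)
        if (!is.null(st)) {
          if (st$energy <= en + 1e-4 * stepl * gd) {
            best <- list(u = ut, sys = st); break
          }
          if (is.null(best) || st$energy < best$sys$energy)
            best <- list(u = ut, sys = st)
        }
        stepl <- stepl / 2
      }
      if (is.null(best))
        stop(sprintf(paste0("Newton line search failed: lambda = %.5f, ",
                            "iteration %d, residual %.3e"), lam, iter, rn))
      rn_new <- sqrt(sum(best$sys$r[free]^2))
      stalled <- rn_new > 0.99 * rn
      u <- best$u
      rn <- rn_new
      en <- best$sys$energy
      # round-off floor of the finite-difference tangent: accept a
      # stagnated iterate once the residual is far below the load scale
      if (stalled && rn <= 1e-4 * ref) break
    }
    state$n_iter_last <- iter
    s33 <- homogenized_nominal_stress(model, u, state$springs)
    state$curve <- rbind(state$curve,
                         data.frame(lambda = lam, S33_kPa = s33))
    if (!is.null(curve_callback)) curve_callback(lam, s33)
  }
  state$u <- u
  state$lambda <- target_stretch
  state
}

#' Reference FE state
#'
#' @param model an [fe_model()].
#' @param coupling optional initial `coupling_state`.
#' @return State list for [newton_solve()] with zero displacements, unit
#'   stretch and an empty stress-stretch curve.
#' @export
fe_state <- function(model, coupling = NULL) {
  list(u = numeric(model$ndof), lambda = 1, coupling = coupling,
       springs = coupling_stiffness(model, coupling),
       curve = data.frame(lambda = 1, S33_kPa = 0))
}

#' Homogenized nominal stress
#'
#' Sum of the z-reactions on the `z = size_z` face divided by the
#' reference cross-sectional area `size_x * size_y`.
#'
#' @param model an [fe_model()].
#' @param u converged global displacement vector.
#' @param springs coupling-spring system of the current coupling state
#'   (the end ties contribute to the face reactions); `NULL` means
#'   end-ties only.
#' @return Nominal stress S33 in kPa.
#' @export
homogenized_nominal_stress <- function(model, u, springs = NULL) {
  # reactions = internal forces at the prescribed face (hex + springs)
  sys <- assemble_system(model, u, springs, want_tangent = FALSE)
  zd <- 3L * (model$mesh$z1 - 1L) + 3L
  sum(sys$r[zd]) / (model$mesh$domain$size_x * model$mesh$domain$size_y)
}
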