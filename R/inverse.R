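## Inverse identification of the axon shear modulus: squared stress-stretch
## error minimized by golden-section search over a fixed bracket.

#' Stress-stretch curve container
#'
#' @param lambda strictly increasing stretches.
#' @param S_kPa nominal stresses in kPa, same length; must be 0 where
#'   `lambda == 1`.
#' @param source one of `"experimental"`, `"simulated"`, `"synthetic"`.
#' @return Object of class `stress_stretch_curve`.
#' @export
stress_stretch_curve <- function(lambda, S_kPa,
                                 source = c("experimental", "simulated",
                                            "synthetic")) {
  source <- match.arg(source)
  stopifnot(is.numeric(lambda), is.numeric(S_kPa),
            length(lambda) == length(S_kPa), length(lambda) >= 1L)
  if (any(diff(lambda) <= 0)) stop("stretches must be strictly increasing")
  if (any(abs(S_kPa[abs(lambda - 1) < 1e-12]) > 1e-9))
    stop("nominal stress must vanish at lambda = 1")
  structure(list(lambda = lambda, S_kPa = S_kPa, source = source),
            class = "stress_stretch_curve")
}

#' @export
print.stress_stretch_curve <- function(x, ...) {
  cat(sprintf("%s stress-stretch curve: %d points, lambda in [%g, %g], S up to %.3f kPa\n",
              x$source, length(x$lambda), min(x$lambda), max(x$lambda),
              max(x$S_kPa)))
  invisible(x)
}

as_curve <- function(x, source = "simulated") {
  if (inherits(x, "stress_stretch_curve")) return(x)
  if (inherits(x, "homogenized_result"))
    return(stress_stretch_curve(x$curve$lambda, x$curve$S33_kPa, "simulated"))
  if (is.data.frame(x)) {
    ln <- intersect(c("lambda"), names(x))
    sn <- intersect(c("S_kPa", "S33_kPa"), names(x))
    if (length(ln) && length(sn))
      return(stress_stretch_curve(x[[ln]], x[[sn[1]]], source))
  }
  stop("cannot interpret object as a stress-stretch curve")
}

#' Sample stretches at equidistant intervals
#'
#' `m` interval endpoints over `(1, lambda_max]`: the trivial zero-stress
#' point at `lambda = 1` is excluded.
#'
#' @param lambda_max upper stretch, > 1.
#' @param m number of intervals/points (default 20).
#' @return Stretches `1 + i (lambda_max - 1) / m`, `i = 1..m`.
#' @export
sample_stretch_points <- function(lambda_max, m = 20L) {
  stopifnot(lambda_max > 1, m >= 1L)
  1 + seq_len(m) * (lambda_max - 1) / m
}

#' Squared stress-stretch error
#'
#' \eqn{E = \sum_i (S_{exp}(\lambda_i) - S_{sim}(\lambda_i))^2} with both
#' curves linearly interpolated at the sample stretches.
#'
#' @param target,simulated stress-stretch curves (any object accepted by
#'   the internal converter: `stress_stretch_curve`, simulation result, or
#'   data frame).
#' @param points sample stretches; must lie inside both curves' ranges.
#' @return Squared error in kPa^2.
#' @export
squared_error <- function(target, simulated, points) {
  target <- as_curve(target, "experimental")
  simulated <- as_curve(simulated, "simulated")
  eps <- 1e-9
  for (cv in list(target, simulated))
    if (any(points < min(cv$lambda) - eps) ||
        any(points > max(cv$lambda) + eps))
      stop("extrapolation error: sample point outside a curve's range")
  st <- approx(target$lambda, target$S_kPa, xout = pmin(points, max(target$lambda)))$y
  ss <- approx(simulated$lambda, simulated$S_kPa,
               xout = pmin(points, max(simulated$lambda)))$y
  sum((st - ss)^2)
}

#' Golden-section search
#'
#' Textbook two-interior-point golden-section minimization on a bracket,
#' lower interior point evaluated first; one new evaluation per
#' iteration.  Terminates when the uncertainty interval (the inverse
#' golden ratio times the outer bracket) is at most `tol`.  With bracket
#' `(20, 50)` and `tol = 1`, the first evaluated point is 31.46 and
#' exactly 9 evaluations are performed, independent of the objective.
#'
#' @param objective function of one numeric argument.
#' @param bracket numeric `c(min, max)`; equal values return immediately
#'   after a single evaluation.
#' @param tol termination tolerance on the uncertainty interval (same
#'   units as the argument).
#' @return List with `minimum`, `objective_value`, `n_evals`, and `trace`
#'   (one row per evaluation: `iteration`, `mu_kPa`, `E_kPa2`).
#' @export
golden_section_search <- function(objective, bracket, tol = 1.0) {
  stopifnot(length(bracket) == 2L, tol > 0)
  a <- bracket[1]; b <- bracket[2]
  if (a > b) stop("configuration error: bracket must satisfy min <= max")
  trace <- data.frame(iteration = integer(0), mu_kPa = numeric(0),
                      E_kPa2 = numeric(0))
  ev <- function(x) {
    fx <- objective(x)
    trace[nrow(trace) + 1L, ] <<- list(nrow(trace) + 1L, x, fx)
    fx
  }
  if (a == b) {
    fa <- ev(a)
    return(list(minimum = a, objective_value = fa, n_evals = 1L,
                trace = trace))
  }
  invphi <- (sqrt(5) - 1) / 2
  x1 <- a + (1 - invphi) * (b - a)
  x2 <- a + invphi * (b - a)
  f1 <- ev(x1)  # lower interior point first
  f2 <- ev(x2)
  while (invphi * (b - a) > tol) {
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- a + (1 - invphi) * (b - a)
      f1 <- ev(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + invphi * (b - a)
      f2 <- ev(x2)
    }
  }
  if (f1 < f2) list(minimum = x1, objective_value = f1,
                    n_evals = nrow(trace), trace = trace)
  else list(minimum = x2, objective_value = f2,
            n_evals = nrow(trace), trace = trace)
}

#' Configure a forward model parameterized by the axon shear modulus
#'
#' Builds the RVE-dependent pieces once and returns a memoizing function
#' `forward(mu_axon)` that runs the staged simulation with
#' `mu_ecm = mu_axon / mu_ratio` and the shared `alpha`, returning the
#' homogenized stress-stretch curve.  The RVE geometry, mesh and seed are
#' held fixed across evaluations.
#'
#' @param rve an `rve_geometry`.
#' @param alpha shared Ogden nonlinearity.
#' @param mu_ratio axon:matrix stiffness ratio (default 3).
#' @param program a [load_program()].
#' @param rule a [coupling_rule()].
#' @param mesh_size hex edge length in um.
#' @param control a [newton_control()].
#' @param cache optional environment shared between forward models to
#'   reuse evaluations (keyed on `alpha` and `mu` quantized at 1e-6 kPa).
#' @return Function `forward(mu_axon)` -> `stress_stretch_curve`.
#' @export
forward_model <- function(rve, alpha = 8.22, mu_ratio = 3,
                          program = load_program(), rule = coupling_rule(),
                          mesh_size = 0.2, control = newton_control(),
                          cache = new.env(parent = emptyenv())) {
  force(rve); force(alpha); force(mu_ratio); force(program); force(rule)
  force(mesh_size); force(control)
  function(mu_axon) {
    stopifnot(mu_axon > 0)
    key <- sprintf("a%.6f_m%.6f", alpha, round(mu_axon * 1e6) / 1e6)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- staged_simulation(rve, wm_materials(mu_axon, alpha, mu_ratio),
                             program = program, rule = rule,
                             mesh_size = mesh_size, control = control)
    cv <- as_curve(res)
    cache[[key]] <- cv
    cv
  }
}

#' Inverse identification problem
#'
#' @param target target stress-stretch curve (experimental or synthetic).
#' @param forward a [forward_model()] function.
#' @param bracket shear-modulus solution bracket in kPa (default 20, 50).
#' @param tol golden-search tolerance in kPa (default 1.0).
#' @param m number of equidistant sample points (default 20).
#' @param lambda_max upper stretch of the comparison window; defaults to
#'   the target curve's maximum stretch.
#' @return Object of class `inverse_problem`.
#' @export
inverse_problem <- function(target, forward, bracket = c(20, 50), tol = 1.0,
                            m = 20L, lambda_max = NULL) {
  target <- as_curve(target, "experimental")
  stopifnot(is.function(forward), length(bracket) == 2L, tol > 0, m >= 1L)
  if (bracket[1] > bracket[2])
    stop("configuration error: bracket must satisfy min <= max")
  if (is.null(lambda_max)) lambda_max <- max(target$lambda)
  structure(list(target = target, forward = forward, bracket = bracket,
                 tol = tol, m = as.integer(m), lambda_max = lambda_max),
            class = "inverse_problem")
}

#' Identify the axon shear modulus
#'
#' Minimizes the squared error between the target curve and the forward
#' simulation over the bracket by golden-section search; every forward run
#' is logged in the search trace and memoized on the quantized modulus.
#'
#' @param problem an [inverse_problem()].
#' @return List with `mu_kPa` (the optimum), `E_kPa2`, `n_evals`, `trace`
#'   (iteration, mu_kPa, E_kPa2), and `fitted_curve` (the forward curve at
#'   the optimum).
#' @export
identify_shear_modulus <- function(problem) {
  stopifnot(inherits(problem, "inverse_problem"))
  pts <- sample_stretch_points(problem$lambda_max, problem$m)
  memo <- new.env(parent = emptyenv())
  objective <- function(mu) {
    key <- sprintf("%.6f", round(mu * 1e6) / 1e6)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- squared_error(problem$target, problem$forward(mu), pts)
    memo[[key]] <- val
    val
  }
  gs <- golden_section_search(objective, problem$bracket, problem$tol)
  list(mu_kPa = gs$minimum, E_kPa2 = gs$objective_value,
       n_evals = gs$n_evals, trace = gs$trace,
       fitted_curve = problem$forward(gs$minimum))
}

#' Sensitivity of the identified modulus to the nonlinearity exponent
#'
#' Repeats the identification for each `alpha` (the target curve is held
#' fixed; only the forward model is re-parameterized) and reports the
#' relative deviation of each optimum from the nominal-alpha result.
#'
#' @param rve an `rve_geometry` (fixed across all runs).
#' @param target target stress-stretch curve.
#' @param alphas nonlinearity exponents to scan (first or `nominal_alpha`
#'   is the reference).
#' @param nominal_alpha reference exponent (default 8.22).
#' @param bracket,tol,m passed to [inverse_problem()].
#' @param ... passed to [forward_model()] (e.g. `mesh_size`, `program`).
#' @return Data frame `(alpha, mu_kPa, E_kPa2, rel_dev)` where `rel_dev`
#'   is `|mu - mu_nominal| / mu_nominal`.
#' @export
sensitivity_scan <- function(rve, target, alphas = c(6.95, 8.22, 9.49),
                             nominal_alpha = 8.22, bracket = c(20, 50),
                             tol = 1.0, m = 20L, ...) {
  stopifnot(all(alphas > 1))
  if (!nominal_alpha %in% alphas) alphas <- c(nominal_alpha, alphas)
  cache <- new.env(parent = emptyenv())
  fits <- lapply(alphas, function(a) {
    fwd <- forward_model(rve, alpha = a, cache = cache, ...)
    identify_shear_modulus(inverse_problem(target, fwd, bracket = bracket,
                                           tol = tol, m = m))
  })
  mu <- vapply(fits, `[[`, numeric(1), "mu_kPa")
  ee <- vapply(fits, `[[`, numeric(1), "E_kPa2")
  mu_nom <- mu[match(nominal_alpha, alphas)]
  data.frame(alpha = alphas, mu_kPa = mu, E_kPa2 = ee,
             rel_dev = abs(mu - mu_nom) / mu_nom)
}
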