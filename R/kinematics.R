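## Transitional kinematic model (TKM): stretch-dependent fractional
## coupling of each axon to the surrounding matrix.

#' Transitional kinematic coupling rule
#'
#' An axon whose current undulation is below `threshold_undulation` is
#' coupled to the matrix over a staged fraction of its length: with the
#' default table, 8%, 20% and 44% of its length for applied stretches up
#' to 1.06, 1.12 and 1.25 respectively.  An axon at or above the threshold
#' does not interact with the matrix (its ends remain tied at the RVE
#' surfaces).
#'
#' @param threshold_undulation coupling threshold (default 1.08).
#' @param stage_breaks strictly increasing applied-stretch levels closing
#'   each stage.
#' @param stage_fractions coupled length fractions per stage, in `[0, 1]`,
#'   non-decreasing, same length as `stage_breaks`.
#' @return Object of class `coupling_rule`.
#' @export
coupling_rule <- function(threshold_undulation = 1.08,
                          stage_breaks = c(1.06, 1.12, 1.25),
                          stage_fractions = c(0.08, 0.20, 0.44)) {
  stopifnot(length(stage_breaks) == length(stage_fractions),
            length(stage_breaks) >= 1L)
  if (any(diff(stage_breaks) <= 0))
    stop("stage_breaks must be strictly increasing")
  if (any(stage_fractions < 0 | stage_fractions > 1))
    stop("stage_fractions must lie in [0, 1]")
  if (any(diff(stage_fractions) < 0))
    stop("stage_fractions must be non-decreasing")
  structure(list(threshold_undulation = threshold_undulation,
                 stage_breaks = stage_breaks,
                 stage_fractions = stage_fractions),
            class = "coupling_rule")
}

#' Coupled length fraction of an axon
#'
#' Returns 0 when the undulation is at or above the threshold (the strict
#' "less than" convention: exactly 1.08 is uncoupled).  Otherwise returns
#' the fraction of the smallest stage break that is >= the applied
#' stretch; stretches beyond the last break use the last fraction.
#' Vectorized over `undulation` and `applied_stretch`.
#'
#' @param undulation current axon undulation (>= 1).
#' @param applied_stretch applied tissue stretch (>= 1).
#' @param rule a [coupling_rule()].
#' @return Coupled fraction(s) in `[0, 1]`.
#' @examples
#' coupling_fraction(1.05, 1.10)  # 0.20
#' coupling_fraction(1.20, 1.10)  # 0 (above threshold)
#' @export
coupling_fraction <- function(undulation, applied_stretch,
                              rule = coupling_rule()) {
  stopifnot(inherits(rule, "coupling_rule"))
  if (any(applied_stretch < 1))
    stop("domain error: applied stretch must be >= 1")
  n <- max(length(undulation), length(applied_stretch))
  undulation <- rep_len(undulation, n)
  applied_stretch <- rep_len(applied_stretch, n)
  stage <- vapply(applied_stretch, function(s) {
    k <- which(rule$stage_breaks >= s - 1e-12)
    if (length(k)) k[1L] else length(rule$stage_breaks)
  }, integer(1))
  frac <- rule$stage_fractions[stage]
  frac[undulation >= rule$threshold_undulation] <- 0
  frac
}

order_policy <- function(path, policy, seed) {
  n <- path$subsegments$n
  switch(policy,
         straightest = order(path$subsegments$local_tortuosity,
                             seq_len(n)),
         random = with_seed(if (is.null(seed)) path$seed else seed,
                            sample.int(n)),
         from_ends = order(pmin(seq_len(n) - 1L, n - seq_len(n)),
                           seq_len(n)),
         stop(sprintf("unknown coupling policy '%s'", policy)))
}

#' Select which sub-segments carry the coupling
#'
#' Chooses `round(fraction * n)` sub-segments by the configured policy:
#' `"straightest"` (default) couples lowest local tortuosity first, ties
#' broken by index; `"random"` uses the seed; `"from_ends"` grows inward
#' from the axon ends.
#'
#' @param path an `axon_path` with a sub-segment partition.
#' @param fraction coupled length fraction in `[0, 1]`.
#' @param seed used only by the `"random"` policy.
#' @param policy selection policy.
#' @param previous optional integer set of already-coupled sub-segments;
#'   the returned set is grown from it so a coupled segment never
#'   uncouples.
#' @return Sorted integer vector of coupled sub-segment indices.
#' @export
select_coupled_subsegments <- function(path, fraction, seed = NULL,
                                       policy = c("straightest", "random",
                                                  "from_ends"),
                                       previous = integer(0)) {
  stopifnot(inherits(path, "axon_path"), !is.null(path$subsegments))
  policy <- match.arg(policy)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  n <- path$subsegments$n
  target <- round(fraction * n)
  keep <- sort(unique(as.integer(previous)))
  if (length(keep) >= target) return(keep)
  ord <- order_policy(path, policy, seed)
  add <- setdiff(ord, keep)
  sort(c(keep, add[seq_len(target - length(keep))]))
}

#' Update per-axon coupling states
#'
#' Recomputes each axon's undulation from its current (deformed) fiber
#' polyline, evaluates the coupling rule at the applied stretch, and grows
#' the coupled sub-segment sets monotonically (stage k sets are subsets of
#' stage k+1 sets).
#'
#' @param state previous `coupling_state` or `NULL` for the initial update.
#' @param paths list of `axon_path` objects (reference partition; supplies
#'   the selection ordering).
#' @param fiber_positions list of current fiber-node coordinate matrices,
#'   one per axon (51 x 3 for 50 sub-segments); defaults to the reference
#'   sub-segment boundary points.
#' @param applied_stretch the stretch level the rule is evaluated at.
#' @param rule a [coupling_rule()].
#' @param policy,seed passed to [select_coupled_subsegments()].
#' @return Object of class `coupling_state`: `lambda_applied`, per-axon
#'   `tortuosity`, `fraction`, `coupled_sets`, and a per-axon `log` table.
#' @export
update_coupling_state <- function(state, paths, fiber_positions = NULL,
                                  applied_stretch = 1,
                                  rule = coupling_rule(),
                                  policy = "straightest", seed = NULL) {
  stopifnot(is.list(paths))
  n_ax <- length(paths)
  if (is.null(fiber_positions))
    fiber_positions <- lapply(paths, fiber_nodes_of_path)
  tort <- vapply(seq_len(n_ax), function(i)
    compute_tortuosity(fiber_positions[[i]]), numeric(1))
  frac <- if (n_ax) coupling_fraction(tort, applied_stretch, rule) else numeric(0)
  prev <- if (is.null(state)) rep(list(integer(0)), n_ax) else state$coupled_sets
  sets <- lapply(seq_len(n_ax), function(i)
    select_coupled_subsegments(paths[[i]], frac[i], seed = seed,
                               policy = policy, previous = prev[[i]]))
  log <- data.frame(axon = seq_len(n_ax), lambda = rep(applied_stretch, n_ax),
                    tortuosity = tort, fraction = frac,
                    n_coupled = vapply(sets, length, integer(1)))
  structure(list(lambda_applied = applied_stretch, tortuosity = tort,
                 fraction = frac, coupled_sets = sets, log = log),
            class = "coupling_state")
}

## Sub-segment boundary points of the reference centerline: the fiber
## nodes used by the mechanical truss chain.
fiber_nodes_of_path <- function(path) {
  stopifnot(inherits(path, "axon_path"), !is.null(path$subsegments))
  path$centerline[path$subsegments$breaks, , drop = FALSE]
}
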