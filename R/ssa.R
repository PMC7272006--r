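#' Simulation configuration
#'
#' Bundles the population-ensemble simulation parameters. One *iteration*
#' advances every population member by `reactions_per_iteration` Gillespie
#' events (default: the number of reaction nodes `M`, reversible pairs
#' counting once). A run equilibrates for `dt_eq` iterations and then records
#' `dt_av` averaging iterations, one sample per member per iteration.
#'
#' @param n_pop population size (independent identical network copies).
#' @param dt_eq equilibration iterations per simulation window.
#' @param dt_av averaging (recording) iterations per simulation window.
#' @param reactions_per_iteration events per member per iteration, or `NULL`
#'   to use the number of reaction nodes of the simulated network.
#' @param dt_init extra equilibration iterations used once, when a run starts
#'   from a fresh random population rather than a carried-over state.
#' @param n_bins number of equal-width count bins per axis for joint
#'   histograms (mutual-information estimation).
#' @param seed optional integer seed applied before the run.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_pop = 1000, dt_eq = 200, dt_av = 200,
                       reactions_per_iteration = NULL, dt_init = 1000,
                       n_bins = 10, seed = NULL) {
  stopifnot(n_pop >= 1, dt_eq >= 0, dt_av >= 0, dt_init >= 0, n_bins >= 2)
  structure(list(n_pop = as.integer(n_pop), dt_eq = as.integer(dt_eq),
                 dt_av = as.integer(dt_av),
                 reactions_per_iteration = reactions_per_iteration,
                 dt_init = as.integer(dt_init), n_bins = as.integer(n_bins),
                 seed = seed),
            class = "sim_config")
}

#' Initialize a population of network copies
#'
#' Every count (including driven species) is drawn uniformly in
#' `[0, x_max)`. Driven-species counts are drawn here once and then held
#' fixed by the dynamics: each member carries its own externally imposed
#' signal level, so the population-level marginal of a driven species is
#' uniform at all times.
#'
#' @param net a `reaction_network`.
#' @param n_pop number of members.
#' @return a `population_state`: list with `counts` (`n_pop x N` integer
#'   matrix) and `iteration` counter.
#' @export
init_population <- function(net, n_pop) {
  ns <- n_species(net)
  counts <- vapply(seq_len(ns), function(i)
    sample.int(net$species$x_max[i], n_pop, replace = TRUE) - 1L,
    integer(n_pop))
  counts <- matrix(as.integer(counts), nrow = n_pop, ncol = ns)
  structure(list(counts = counts, iteration = 0L), class = "population_state")
}

#' Draw the next Gillespie event
#'
#' Inverse-transform draw of the waiting time and next reaction index from
#' the joint density `eta_r exp(-eta tau)`: `tau = log(1/u1)/eta` and `r` is
#' the smallest index whose cumulative propensity exceeds `u2 * eta`.
#'
#' @param net a `reaction_network`.
#' @param counts current count vector.
#' @param u1,u2 uniform(0,1) variates.
#' @return list with `tau` and `r`, or `NULL` when the state is absorbing
#'   (zero total propensity).
#' @export
draw_next_event <- function(net, counts, u1, u2) {
  eta <- propensities(net, counts)
  tot <- sum(eta)
  if (tot <= 0) return(NULL)
  list(tau = log(1 / u1) / tot,
       r = which(cumsum(eta) > u2 * tot)[1])
}

#' Advance a population by one iteration
#'
#' Each member independently advances by `reactions_per_iteration` Gillespie
#' events; members in absorbing states are carried forward unchanged.
#'
#' @param state a `population_state`.
#' @param net a `reaction_network`.
#' @param config a `sim_config` (only `reactions_per_iteration` is used).
#' @return the advanced `population_state`.
#' @export
step_iteration <- function(state, net, config = sim_config()) {
  rpi <- config$reactions_per_iteration
  if (is.null(rpi)) rpi <- n_reaction_nodes(net)
  a <- net_arrays(net)
  res <- cpp_run_ensemble(state$counts, a$nu_minus, a$nu_plus, a$kappa, a$driven,
                          a$x_max, a$omega, 1L, 0L, as.integer(rpi),
                          matrix(0L, 0, 2), 2L, numeric(n_species(net)), FALSE)
  state$counts <- res$counts
  state$iteration <- state$iteration + 1L
  state
}

# internal: signal-response species pairs of a network, one row per pair
signal_response_pairs <- function(net) {
  out <- NULL
  for (s in net$signals) {
    for (j in net$responses[[as.character(s)]]) out <- rbind(out, c(s, j))
  }
  if (is.null(out)) matrix(0L, 0, 2) else matrix(as.integer(out), ncol = 2)
}

#' Run an ensemble simulation window
#'
#' Equilibrates the population for `dt_eq` iterations (plus `dt_init` when no
#' initial state is supplied), then records `dt_av` iterations. Returns the
#' final population state together with summary statistics over the
#' `n_pop * dt_av` recorded samples: per-species means, standard deviations,
#' sign frequencies `Pr(X_i > X_i*)`, binned joint histograms for the
#' requested species pairs (by default all signal-response pairs), the
#' per-pair mutual information and the objective `E`.
#'
#' @param net a `reaction_network`.
#' @param config a `sim_config`.
#' @param initial optional `population_state` to continue from; when omitted
#'   a fresh population is drawn and pre-equilibrated for `dt_init`
#'   iterations.
#' @param pairs optional 2-column integer matrix of species pairs (1-based)
#'   for joint-histogram estimation.
#' @param keep_buffer if `TRUE`, also return the raw sample buffer as an
#'   `n_pop x N x dt_av` integer array.
#' @param thresholds per-species sign thresholds `X_i*` (default `x_max/2`).
#' @return list with elements `state` (`population_state`), `stats` (an
#'   `ensemble_summary`) and `buffer` (array or `NULL`).
#' @export
run_ensemble <- function(net, config = sim_config(), initial = NULL,
                         pairs = NULL, keep_buffer = FALSE, thresholds = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ns <- n_species(net)
  if (is.null(thresholds)) thresholds <- net$species$x_max / 2
  if (is.null(pairs)) pairs <- signal_response_pairs(net)
  storage.mode(pairs) <- "integer"
  rpi <- config$reactions_per_iteration
  if (is.null(rpi)) rpi <- n_reaction_nodes(net)
  dt_eq <- config$dt_eq
  if (is.null(initial)) {
    initial <- init_population(net, config$n_pop)
    dt_eq <- dt_eq + config$dt_init
  }
  a <- net_arrays(net)
  res <- cpp_run_ensemble(initial$counts, a$nu_minus, a$nu_plus, a$kappa,
                          a$driven, a$x_max, a$omega,
                          as.integer(dt_eq), as.integer(config$dt_av),
                          as.integer(rpi), pairs - 1L, config$n_bins,
                          as.numeric(thresholds), keep_buffer)
  state <- structure(list(counts = res$counts,
                          iteration = initial$iteration + dt_eq + config$dt_av),
                     class = "population_state")
  stats <- NULL
  if (config$dt_av > 0) {
    n <- res$n_samples
    mean_x <- res$sum / n
    var_x <- pmax(0, res$sumsq / n - mean_x^2)
    n_pairs <- nrow(pairs)
    joints <- vector("list", n_pairs)
    mi <- numeric(n_pairs)
    jarr <- array(res$joints, dim = c(n_pairs, config$n_bins, config$n_bins))
    for (p in seq_len(n_pairs)) {
      jt <- jarr[p, , ] / n
      joints[[p]] <- jt
      mi[p] <- mutual_information(jt)
    }
    names(joints) <- names(mi) <- apply(pairs, 1, paste, collapse = ",")
    stats <- structure(list(
      n_samples = n, mean = mean_x, sd = sqrt(var_x),
      sign_freq = res$sign_pos / n,
      concentration = mean_x / net$species$x_max,
      thresholds = thresholds, pairs = pairs, joints = joints, mi = mi,
      objective = objective_from_pair_mi(mi, pairs, net)),
      class = "ensemble_summary")
  }
  buffer <- NULL
  if (keep_buffer && config$dt_av > 0)
    buffer <- array(res$buffer, dim = c(config$n_pop, ns, config$dt_av))
  list(state = state, stats = stats, buffer = buffer)
}

#' Simulate independent copies on a real-time grid
#'
#' Plain (clock-time) Gillespie simulation of `n_pop` independent members,
#' recording every member's counts at the given times. Used to compare
#' ensemble means against the mean-field ODE.
#'
#' @param net a `reaction_network`.
#' @param initial `population_state` (or integer count matrix).
#' @param times increasing vector of recording times (starting after 0).
#' @return integer array `n_pop x N x length(times)`.
#' @export
ssa_time_ensemble <- function(net, initial, times) {
  counts <- if (inherits(initial, "population_state")) initial$counts else initial
  storage.mode(counts) <- "integer"
  a <- net_arrays(net)
  cpp_ssa_timegrid(counts, a$nu_minus, a$nu_plus, a$kappa, a$driven,
                   a$x_max, a$omega, as.numeric(times))
}

# continuous-state mass-action propensity (no cap blocking), for the ODE
eta_continuous <- function(net, x) {
  m <- n_reactions_directed(net)
  vapply(seq_len(m), function(r) {
    vm <- net$nu_minus[r, ]
    left <- which(vm > 0)
    a <- net$kappa[r] * net$omega^(-(length(left) - 1))
    for (i in left) a <- a * max(0, choose(x[i], vm[i]))
    a
  }, numeric(1))
}

#' Mean-field ODE trajectory
#'
#' Integrates `d<X_i>/dt = sum_r (nu+_r(i) - nu-_r(i)) eta_r(<X>)`, the
#' deterministic rate equation obtained by evaluating the mass-action
#' propensities at the mean counts. Exact for networks whose propensities are
#' linear in the counts and away from the copy-number caps; used as an
#' independent oracle for the stochastic engine. Driven species are held at
#' their initial value.
#'
#' @param net a `reaction_network`.
#' @param x0 initial (mean) counts.
#' @param times output time grid (must start at 0).
#' @return matrix of means, one row per time, one column per species.
#' @export
mean_field_ode <- function(net, x0, times) {
  stoich <- t(net$nu_plus - net$nu_minus)   # N x M_dir
  stoich[net$species$driven, ] <- 0
  deriv <- function(t, x, parms) list(as.numeric(stoich %*% eta_continuous(net, x)))
  out <- deSolve::ode(y = as.numeric(x0), times = times, func = deriv, parms = NULL)
  unname(out[, -1, drop = FALSE])
}
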