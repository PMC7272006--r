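#' Optimizer configuration for the healthy-state search
#'
#' Parameters of the zero-temperature Monte Carlo search over reaction
#' rates. Each proposal perturbs all directed rates jointly by additive
#' uniform noise of half-width `proposal_width`, reflected into the open
#' rate bounds; a proposal is accepted only when the (re-estimated)
#' objective strictly increases.
#'
#' @param n_steps number of Monte Carlo steps.
#' @param proposal_width half-width of the uniform rate perturbation.
#' @param rate_bounds open interval constraining the rates.
#' @param dt_eq0 equilibration iterations per objective evaluation.
#' @param dt_av0 averaging iterations per objective evaluation.
#' @param seed optional integer seed.
#' @return an `optimizer_config`.
#' @export
optimizer_config <- function(n_steps = 200, proposal_width = 0.05,
                             rate_bounds = c(0, 2), dt_eq0 = 4000,
                             dt_av0 = 1000, seed = NULL) {
  stopifnot(n_steps >= 0, proposal_width >= 0, rate_bounds[1] >= 0,
            dt_eq0 >= 0, dt_av0 >= 1)
  structure(list(n_steps = as.integer(n_steps), proposal_width = proposal_width,
                 rate_bounds = rate_bounds, dt_eq0 = as.integer(dt_eq0),
                 dt_av0 = as.integer(dt_av0), seed = seed),
            class = "optimizer_config")
}

#' Propose perturbed reaction rates
#'
#' Adds an independent uniform draw in `[-width, width]` to every rate and
#' reflects the result into the open interval `bounds` (a tiny margin keeps
#' the rates strictly inside).
#'
#' @param current numeric vector of rates within `bounds`.
#' @param width perturbation half-width.
#' @param bounds length-2 numeric interval.
#' @return proposed rate vector, always inside `bounds`.
#' @export
propose_rates <- function(current, width, bounds = c(0, 2)) {
  prop <- current + stats::runif(length(current), -width, width)
  lo <- bounds[1]; hi <- bounds[2]
  for (k in 1:3) { # reflect (width << range, so one pass suffices in practice)
    prop <- ifelse(prop < lo, 2 * lo - prop, prop)
    prop <- ifelse(prop > hi, 2 * hi - prop, prop)
  }
  eps <- 1e-9 * (hi - lo)
  pmin(pmax(prop, lo + eps), hi - eps)
}

#' Zero-temperature Monte Carlo search for the healthy network
#'
#' Starting from random rates (default) or the network's current rates,
#' iterates propose -> simulate -> evaluate `E` -> accept iff `E` increases.
#' Each objective evaluation simulates a fresh population for
#' `dt_eq0 + dt_av0` iterations. The incumbent objective is *not*
#' re-simulated: a new estimate is compared against the stored value, as in
#' a plain hill-climbing loop with noisy evaluations.
#'
#' @param net a `reaction_network`.
#' @param opt_config an `optimizer_config`.
#' @param config a `sim_config` supplying the population size and binning
#'   (its `dt_eq`/`dt_av` are overridden by `dt_eq0`/`dt_av0`).
#' @param init `"random"` to start from uniform random rates in the bounds,
#'   `"current"` to start from the network's rates.
#' @return list with `network` (rates set to the optimum), `trace`
#'   (accepted-objective value after each step, non-decreasing), `measured`
#'   (every evaluated objective) and `accepted` (logical per step).
#' @export
optimize_rates <- function(net, opt_config = optimizer_config(),
                           config = sim_config(), init = c("random", "current")) {
  init <- match.arg(init)
  if (!is.null(opt_config$seed)) set.seed(opt_config$seed)
  b <- opt_config$rate_bounds
  eval_cfg <- config
  eval_cfg$dt_eq <- opt_config$dt_eq0
  eval_cfg$dt_av <- opt_config$dt_av0
  eval_cfg$dt_init <- 0L
  eval_cfg$seed <- NULL
  m <- n_reactions_directed(net)
  kappa <- if (init == "random")
    stats::runif(m, b[1] + 1e-6, b[2] - 1e-6) else net$kappa
  eval_E <- function(k) {
    run_ensemble(set_rates(net, k), eval_cfg)$stats$objective
  }
  e_old <- eval_E(kappa)
  trace <- numeric(opt_config$n_steps)
  measured <- numeric(opt_config$n_steps)
  accepted <- logical(opt_config$n_steps)
  for (s in seq_len(opt_config$n_steps)) {
    prop <- propose_rates(kappa, opt_config$proposal_width, b)
    e_new <- eval_E(prop)
    measured[s] <- e_new
    if (e_new > e_old) {
      kappa <- prop
      e_old <- e_new
      accepted[s] <- TRUE
    }
    trace[s] <- e_old
  }
  list(network = set_rates(net, kappa), trace = trace, measured = measured,
       accepted = accepted, e_final = e_old)
}
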