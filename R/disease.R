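#' Defect pattern over reaction nodes
#'
#' A defect pattern marks the subset of reaction nodes whose rates undergo
#' mutational drift; an *elementary* defect marks exactly one node. The
#' all-zero pattern is the healthy control.
#'
#' @param m number of reaction nodes of the target network.
#' @param nodes integer vector of defective node indices (possibly empty).
#' @return a `defect_pattern` with binary vector `d` and cardinality `size`.
#' @export
defect_pattern <- function(m, nodes = integer()) {
  stopifnot(all(nodes >= 1), all(nodes <= m))
  d <- rep(0L, m)
  d[nodes] <- 1L
  structure(list(d = d, size = sum(d)), class = "defect_pattern")
}

#' Mutation and acceptance schedules of the disease dynamics
#'
#' The reverse-annealing dynamics is controlled by a per-node mutation
#' probability ramping linearly from 0 to 1 over `tau_alpha` steps and a
#' global acceptance inverse-temperature decaying linearly from `beta0` to 0
#' over `tau_beta` steps. Each mutation event shifts a rate by
#' `+/- delta_kappa` (sign uniform), clipped to the open `rate_bounds`.
#'
#' @param tau_alpha mutation time scale, scalar or per reaction node.
#' @param tau_beta acceptance time scale (scalar).
#' @param beta0 initial inverse temperature.
#' @param delta_kappa rate mutation step.
#' @param t_max number of disease-evolution steps.
#' @param rate_bounds open interval for the rates.
#' @return a `disease_schedules`.
#' @export
disease_schedules <- function(tau_alpha = 100, tau_beta = 100, beta0 = 100,
                              delta_kappa = 0.05, t_max = 500,
                              rate_bounds = c(0, 2)) {
  stopifnot(all(tau_alpha > 0), tau_beta > 0, beta0 >= 0, delta_kappa > 0,
            t_max >= 0)
  structure(list(tau_alpha = tau_alpha, tau_beta = tau_beta, beta0 = beta0,
                 delta_kappa = delta_kappa, t_max = as.integer(t_max),
                 rate_bounds = rate_bounds),
            class = "disease_schedules")
}

#' Mutation-probability schedule
#'
#' Linear ramp `alpha(t) = min(1, t/tau_alpha)`: negligible early in the
#' process, saturating at 1 after `tau_alpha` steps.
#'
#' @param t step index (>= 0), vectorized.
#' @param tau_alpha time scale (> 0).
#' @return probability in `[0, 1]`.
#' @export
alpha_schedule <- function(t, tau_alpha) pmin(1, t / tau_alpha)

#' Acceptance inverse-temperature schedule
#'
#' Linear decay `beta(t) = max(0, beta0 (1 - t/tau_beta))`: a large inverse
#' temperature (mutations that decrease the objective are essentially always
#' rejected) relaxing to 0 (all mutations accepted).
#'
#' @param t step index (>= 0), vectorized.
#' @param beta0 initial inverse temperature.
#' @param tau_beta time scale (> 0).
#' @return non-negative inverse temperature.
#' @export
beta_schedule <- function(t, beta0, tau_beta) pmax(0, beta0 * (1 - t / tau_beta))

#' Combine the rates of two interacting defects
#'
#' Two independent defects combine like independent Poisson processes,
#' `1/tau = 1/tau_a + 1/tau_b`; an interaction adds `lambda * rate_int`.
#' The same formula serves the mutation (`1/tau_r`) and acceptance
#' (`1/tau_beta`) time scales.
#'
#' @param rate_a,rate_b non-negative rates `1/tau` of the two defects.
#' @param lambda interaction coupling.
#' @param rate_int interaction rate `1/tau(a*b)`.
#' @return combined rate; errors if negative.
#' @export
combine_defect_rates <- function(rate_a, rate_b, lambda = 0, rate_int = 0) {
  stopifnot(all(rate_a >= 0), all(rate_b >= 0), all(rate_int >= 0))
  out <- rate_a + rate_b + lambda * rate_int
  if (any(out < 0)) stop("combined defect rate is negative")
  out
}

#' Acceptance probability of a rate mutation
#'
#' Metropolis-like rule of the reverse annealing: a mutation that does not
#' decrease the objective is always accepted; a detrimental one is accepted
#' with probability `exp(beta * delta_E)`.
#'
#' @param delta_E objective change (new - old), vectorized.
#' @param beta non-negative inverse temperature.
#' @return probability in `(0, 1]`.
#' @export
accept_probability <- function(delta_E, beta) {
  ifelse(delta_E >= 0, 1, exp(beta * delta_E))
}

#' Reverse-annealing disease evolution of a reaction network
#'
#' Starting from the healthy (optimized) network and an equilibrated
#' population, each step `t = 1 ... t_max`: (1) every defective reaction
#' node mutates its rates by `+/- delta_kappa` with probability
#' `alpha(t)` (both directions of a reversible pair under one draw, with
#' independent signs); (2) the population is advanced `dt_eq + dt_av`
#' iterations under the proposed rates and the objective `E_new` measured;
#' (3) the mutation is accepted per [accept_probability()], otherwise the
#' rates revert while the chemical population state keeps evolving. When no
#' mutation occurs at a step the rates and the stored objective are
#' unchanged (there is nothing to accept), but the step is still simulated
#' and recorded.
#'
#' @param net healthy `reaction_network` (rates already optimized).
#' @param defect a `defect_pattern` over the network's reaction nodes.
#' @param schedules a `disease_schedules`.
#' @param config a `sim_config` (per-step window `dt_eq`/`dt_av`; `dt_init`
#'   is the initial healthy equilibration when `initial` is missing).
#' @param initial optional `population_state` to start from.
#' @param record_detail keep the full per-step rate matrix.
#' @return an `evolution_trajectory`: per-step data frame `steps` (objective
#'   `E` as measured, accepted objective, acceptance/mutation flags,
#'   schedule values, distance `d` from the initial concentration profile)
#'   plus matrices of per-member sign frequencies, concentrations,
#'   macroscopic sign states (the binarized coarse activities
#'   `S_i(t) = sign(<X_i> - X_i*)` used by the diagnostic model) and,
#'   optionally, rates.
#' @export
evolve_disease <- function(net, defect, schedules, config = sim_config(),
                           initial = NULL, record_detail = TRUE) {
  m_nodes <- n_reaction_nodes(net)
  stopifnot(length(defect$d) == m_nodes)
  ns <- n_species(net)
  t_max <- schedules$t_max
  tau_alpha <- rep_len(schedules$tau_alpha, m_nodes)
  b <- schedules$rate_bounds
  eps <- 1e-6
  thresholds <- net$species$x_max / 2
  def_nodes <- which(defect$d == 1L)

  kappa <- net$kappa
  res <- run_ensemble(set_rates(net, kappa), config, initial = initial)
  state <- res$state
  e_old <- res$stats$objective
  c0 <- res$stats$concentration

  n_rows <- t_max + 1L
  steps <- data.frame(t = 0:t_max, E = NA_real_, E_accepted = NA_real_,
                      accepted = FALSE, mutated = FALSE, alpha = NA_real_,
                      beta = NA_real_, d = NA_real_)
  sign_freq <- matrix(NA_real_, n_rows, ns)
  conc <- matrix(NA_real_, n_rows, ns)
  signs <- matrix(NA_integer_, n_rows, ns)
  kap_mat <- if (record_detail) matrix(NA_real_, n_rows, length(kappa)) else NULL

  record <- function(row, stats) {
    steps$E[row] <<- stats$objective
    steps$E_accepted[row] <<- e_old
    steps$d[row] <<- state_distance(stats$concentration, c0)
    sign_freq[row, ] <<- stats$sign_freq
    conc[row, ] <<- stats$concentration
    signs[row, ] <<- ifelse(stats$mean > thresholds, 1L, -1L)
    if (!is.null(kap_mat)) kap_mat[row, ] <<- kappa
  }
  steps$alpha[1] <- 0; steps$beta[1] <- schedules$beta0
  record(1L, res$stats)

  for (t in seq_len(t_max)) {
    row <- t + 1L
    alpha_t <- alpha_schedule(t, tau_alpha)
    beta_t <- beta_schedule(t, schedules$beta0, schedules$tau_beta)
    prop <- kappa
    mutated <- FALSE
    for (q in def_nodes) {
      if (stats::runif(1) < alpha_t[q]) {
        dirs <- which(net$node == q)
        prop[dirs] <- prop[dirs] +
          sample(c(-1, 1), length(dirs), replace = TRUE) * schedules$delta_kappa
        mutated <- TRUE
      }
    }
    prop <- pmin(pmax(prop, b[1] + eps), b[2] - eps)
    res <- run_ensemble(set_rates(net, prop), config, initial = state)
    state <- res$state
    e_new <- res$stats$objective
    acc <- FALSE
    if (mutated) {
      if (stats::runif(1) < accept_probability(e_new - e_old, beta_t)) {
        kappa <- prop
        e_old <- e_new
        acc <- TRUE
      }
    }
    steps$accepted[row] <- acc
    steps$mutated[row] <- mutated
    steps$alpha[row] <- if (length(def_nodes)) mean(alpha_t[def_nodes]) else 0
    steps$beta[row] <- beta_t
    record(row, res$stats)
  }

  structure(list(steps = steps, sign_freq = sign_freq, conc = conc,
                 signs = signs, kappa = kap_mat,
                 n_pop = config$n_pop, n_species = ns,
                 defect = defect, schedules = schedules),
            class = "evolution_trajectory")
}

#' Run a cohort of disease-evolution realizations
#'
#' Independent seeded realizations of [evolve_disease()] for each defect
#' pattern in `defects` (include the all-zero pattern, conventionally named
#' `"healthy"`, to obtain the no-defect baseline needed by the diagnostic
#' model). Realization seeds are derived reproducibly from `seed`.
#'
#' @param net healthy `reaction_network`.
#' @param defects named list of `defect_pattern`s.
#' @param schedules a `disease_schedules`.
#' @param n_realizations realizations per defect pattern.
#' @param config a `sim_config`.
#' @param seed integer seed for the whole cohort.
#' @return a `cohort_archive`: nested list `runs[[label]][[realization]]` of
#'   light trajectories, plus bookkeeping fields.
#' @export
run_cohort <- function(net, defects, schedules, n_realizations,
                       config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- names(defects)
  stopifnot(!is.null(labels), all(nzchar(labels)))
  seeds <- matrix(sample.int(.Machine$integer.max, length(defects) * n_realizations),
                  nrow = length(defects))
  runs <- vector("list", length(defects))
  names(runs) <- labels
  for (k in seq_along(defects)) {
    runs[[k]] <- vector("list", n_realizations)
    for (j in seq_len(n_realizations)) {
      set.seed(seeds[k, j])
      runs[[k]][[j]] <- evolve_disease(net, defects[[k]], schedules, config,
                                       record_detail = FALSE)
    }
  }
  structure(list(runs = runs, labels = labels, defects = defects,
                 t_max = schedules$t_max, n_species = n_species(net),
                 n_pop = config$n_pop, schedules = schedules),
            class = "cohort_archive")
}

#' Cohort mean and standard error of a per-step quantity
#'
#' @param archive a `cohort_archive`.
#' @param quantity column of the per-step table: `"E"`, `"E_accepted"` or
#'   `"d"`.
#' @return named list per defect label, each a data.frame
#'   `(t, mean, se, n)`.
#' @export
cohort_stats <- function(archive, quantity = c("E", "E_accepted", "d")) {
  quantity <- match.arg(quantity)
  lapply(archive$runs, function(trajs) {
    mat <- vapply(trajs, function(tr) tr$steps[[quantity]],
                  numeric(archive$t_max + 1L))
    mat <- matrix(mat, nrow = archive$t_max + 1L)
    data.frame(t = 0:archive$t_max,
               mean = rowMeans(mat),
               se = apply(mat, 1, stats::sd) / sqrt(ncol(mat)),
               n = ncol(mat))
  })
}

#' @export
print.evolution_trajectory <- function(x, ...) {
  s <- x$steps
  cat("<evolution_trajectory> ", nrow(s) - 1, " steps, ", x$n_species,
      " species, defect nodes: ",
      if (x$defect$size) paste(which(x$defect$d == 1L), collapse = ", ")
      else "none (healthy control)", "\n", sep = "")
  cat(sprintf("  E: %.3f -> %.3f   d(t_max) = %.3f   accepted moves: %d\n",
              s$E[1], s$E[nrow(s)], s$d[nrow(s)], sum(s$accepted)))
  invisible(x)
}

#' @export
print.cohort_archive <- function(x, ...) {
  cat("<cohort_archive> ", length(x$labels), " cohorts x ",
      length(x$runs[[1]]), " realizations, t_max = ", x$t_max,
      ", n_pop = ", x$n_pop, "\n", sep = "")
  cat("  cohorts: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}
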