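#' Construct a mass-action reaction network
#'
#' A network holds `N` species and `M_dir` directed reactions given by
#' stoichiometric coefficient matrices. A reversible reaction is stored as two
#' directed reactions with independent rates linked through `partner`; both
#' directions share a reaction *node*, and the disease machinery mutates
#' nodes, touching both directions of a reversible pair. Species flagged as
#' `driven` are externally imposed: they enter propensities as reactants but
#' their counts are never changed by a firing.
#'
#' @param species data.frame with columns `name` (character), `driven`
#'   (logical) and `x_max` (integer copy-number cap, default 1000).
#' @param nu_minus,nu_plus `M_dir x N` non-negative integer matrices of
#'   reactant and product coefficients.
#' @param kappa numeric vector of directed reaction rates (dimensionless).
#' @param partner integer vector: for each directed reaction, the index of its
#'   reverse direction, or `NA` for an irreversible reaction.
#' @param node integer vector assigning each directed reaction to a reaction
#'   node (reversible pairs share a node). Defaults to pairing via `partner`.
#' @param signals integer vector of signal species indices (1-based).
#' @param responses named list mapping each signal index (as character) to a
#'   non-empty integer vector of response species indices.
#' @param omega system volume; the propensity of a reaction with `L` distinct
#'   reactant species is scaled by `omega^-(L-1)`.
#' @param rate_bounds open interval constraining every `kappa`.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, nu_minus, nu_plus, kappa,
                             partner = NULL, node = NULL,
                             signals = integer(), responses = list(),
                             omega = 1, rate_bounds = c(0, 2)) {
  if (is.null(species$x_max)) species$x_max <- 1000L
  species$x_max <- as.integer(species$x_max)
  species$driven <- as.logical(species$driven)
  nu_minus <- as.matrix(nu_minus); storage.mode(nu_minus) <- "integer"
  nu_plus <- as.matrix(nu_plus); storage.mode(nu_plus) <- "integer"
  m <- nrow(nu_minus)
  if (is.null(partner)) partner <- rep(NA_integer_, m)
  if (is.null(node)) {
    node <- integer(m); nid <- 0L
    for (r in seq_len(m)) {
      if (node[r] == 0L) {
        nid <- nid + 1L
        node[r] <- nid
        if (!is.na(partner[r])) node[partner[r]] <- nid
      }
    }
  }
  net <- structure(list(
    species = species, nu_minus = nu_minus, nu_plus = nu_plus,
    kappa = as.numeric(kappa), partner = as.integer(partner),
    node = as.integer(node), signals = as.integer(signals),
    responses = responses, omega = omega, rate_bounds = rate_bounds
  ), class = "reaction_network")
  validate_network(net)
  net
}

#' Validate a reaction network
#'
#' Checks coefficient non-negativity, rate bounds, partner-link consistency
#' and that the signal/response assignment refers to existing species with a
#' non-empty response set per signal.
#'
#' @param net a `reaction_network`.
#' @return `net`, invisibly; errors name the offending field.
#' @export
validate_network <- function(net) {
  ns <- nrow(net$species)
  if (any(net$nu_minus < 0)) stop("nu_minus: negative stoichiometric coefficient")
  if (any(net$nu_plus < 0)) stop("nu_plus: negative stoichiometric coefficient")
  if (ncol(net$nu_minus) != ns || ncol(net$nu_plus) != ns)
    stop("nu matrices: column count must equal number of species")
  if (nrow(net$nu_plus) != nrow(net$nu_minus)) stop("nu_plus: row count mismatch")
  if (length(net$kappa) != nrow(net$nu_minus)) stop("kappa: length mismatch")
  if (any(net$kappa < 0)) stop("kappa: negative rate")
  b <- net$rate_bounds
  if (any(net$kappa <= b[1] - 1e-12) || any(net$kappa >= b[2] + 1e-12))
    stop("kappa: rate outside the configured bounds")
  for (r in seq_along(net$partner)) {
    p <- net$partner[r]
    if (!is.na(p) && (is.na(net$partner[p]) || net$partner[p] != r))
      stop("partner: reversible pair links are not mutually consistent")
  }
  if (length(net$signals) && (any(net$signals < 1) || any(net$signals > ns)))
    stop("signals: species index out of range")
  for (i in net$signals) {
    ri <- net$responses[[as.character(i)]]
    if (is.null(ri) || length(ri) == 0) stop("responses: empty response set for a signal")
    if (any(ri < 1) || any(ri > ns)) stop("responses: species index out of range")
  }
  if (net$omega <= 0) stop("omega: must be positive")
  invisible(net)
}

#' Number of species / directed reactions / reaction nodes
#' @param net a `reaction_network`.
#' @return integer count.
#' @export
n_species <- function(net) nrow(net$species)

#' @rdname n_species
#' @export
n_reactions_directed <- function(net) nrow(net$nu_minus)

#' @rdname n_species
#' @export
n_reaction_nodes <- function(net) max(net$node)

#' Mass-action propensity of one directed reaction
#'
#' Computes `kappa_r * prod_i choose(X_i, nu-_r(i)) * omega^-(|L_r|-1)` over
#' the reactant species `L_r`. The propensity is zero when any reactant is
#' insufficient or when firing would push a non-driven species above its
#' copy-number cap (cap enforcement blocks the firing rather than truncating
#' products).
#'
#' @param net a `reaction_network`.
#' @param counts integer vector of current copy numbers.
#' @param r directed reaction index.
#' @return non-negative numeric scalar.
#' @export
propensity <- function(net, counts, r) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (net$kappa[r] < 0) stop("kappa must be non-negative")
  vm <- net$nu_minus[r, ]
  left <- which(vm > 0)
  if (any(counts[left] < vm[left])) return(0)
  d <- net$nu_plus[r, ] - vm
  d[net$species$driven] <- 0L
  after <- counts + d
  if (any(after > net$species$x_max) || any(after < 0)) return(0)
  a <- net$kappa[r] * net$omega^(-(length(left) - 1))
  for (i in left) a <- a * choose(counts[i], vm[i])
  a
}

#' All directed-reaction propensities at a state
#' @inheritParams propensity
#' @return numeric vector of length `n_reactions_directed(net)`.
#' @export
propensities <- function(net, counts) {
  vapply(seq_len(n_reactions_directed(net)), function(r) propensity(net, counts, r),
         numeric(1))
}

#' Total propensity (sum over all directed reactions)
#' @inheritParams propensity
#' @return non-negative numeric scalar; zero iff no reaction can fire.
#' @export
total_propensity <- function(net, counts) sum(propensities(net, counts))

#' Fire one reaction
#'
#' Updates counts by `nu_plus - nu_minus` for non-driven species. Firing an
#' unfireable reaction (zero propensity at this state) is a contract
#' violation and errors.
#'
#' @inheritParams propensity
#' @return updated count vector.
#' @export
apply_reaction <- function(net, counts, r) {
  if (propensity(net, counts, r) <= 0)
    stop("apply_reaction: reaction ", r, " is not fireable at this state")
  d <- net$nu_plus[r, ] - net$nu_minus[r, ]
  d[net$species$driven] <- 0L
  counts + d
}

#' Replace reaction rates
#' @param net a `reaction_network`.
#' @param kappa numeric vector of new directed rates.
#' @return the network with rates replaced.
#' @export
set_rates <- function(net, kappa) {
  stopifnot(length(kappa) == n_reactions_directed(net))
  net$kappa <- as.numeric(kappa)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$species), " species, ",
      n_reaction_nodes(x), " reaction nodes (",
      n_reactions_directed(x), " directed)\n", sep = "")
  cat("  driven: ", paste(x$species$name[x$species$driven], collapse = ", "), "\n", sep = "")
  cat("  signals: ", paste(x$species$name[x$signals], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# internal: low-level arrays handed to the C++ core
net_arrays <- function(net) {
  list(nu_minus = net$nu_minus, nu_plus = net$nu_plus, kappa = net$kappa,
       driven = net$species$driven, x_max = net$species$x_max, omega = net$omega)
}
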