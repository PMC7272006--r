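#' Build a network from a readable reaction list
#'
#' Convenience constructor used by the catalog and by user code: species are
#' referred to by name and each reaction is a list with `from` and `to`
#' (named coefficient vectors), an optional `kappa` (forward rate, default 1),
#' `reversible` flag and `kappa_rev` (default equal to `kappa`).
#'
#' @param species character vector of species names.
#' @param driven character vector of externally driven species names.
#' @param reactions list of reaction descriptions (see above).
#' @param signals character vector of signal species names.
#' @param responses named list: signal name -> character vector of response
#'   species names.
#' @param x_max copy-number cap (scalar or per species).
#' @param omega system volume.
#' @param rate_bounds open interval constraining the rates (default `(0, 2)`).
#' @return a `reaction_network`.
#' @export
build_network <- function(species, driven = character(), reactions,
                          signals = character(), responses = list(),
                          x_max = 1000, omega = 1, rate_bounds = c(0, 2)) {
  ns <- length(species)
  sp <- data.frame(name = species, driven = species %in% driven,
                   x_max = as.integer(rep_len(x_max, ns)),
                   stringsAsFactors = FALSE)
  idx <- function(nm) {
    i <- match(nm, species)
    if (anyNA(i)) stop("unknown species name: ", paste(nm[is.na(i)], collapse = ", "))
    i
  }
  nm_list <- list(); np_list <- list(); kap <- numeric(); partner <- integer()
  node <- integer(); nid <- 0L
  for (rx in reactions) {
    nid <- nid + 1L
    vm <- integer(ns); vp <- integer(ns)
    vm[idx(names(rx$from))] <- as.integer(rx$from)
    vp[idx(names(rx$to))] <- as.integer(rx$to)
    k <- if (is.null(rx$kappa)) 1 else rx$kappa
    rev <- isTRUE(rx$reversible)
    r_fwd <- length(kap) + 1L
    nm_list[[r_fwd]] <- vm; np_list[[r_fwd]] <- vp
    kap[r_fwd] <- k; node[r_fwd] <- nid
    if (rev) {
      r_bwd <- r_fwd + 1L
      nm_list[[r_bwd]] <- vp; np_list[[r_bwd]] <- vm
      kap[r_bwd] <- if (is.null(rx$kappa_rev)) k else rx$kappa_rev
      node[r_bwd] <- nid
      partner[r_fwd] <- r_bwd; partner[r_bwd] <- r_fwd
    } else {
      partner[r_fwd] <- NA_integer_
    }
  }
  sig_i <- idx(signals)
  resp <- stats::setNames(lapply(signals, function(s) idx(responses[[s]])),
                          as.character(sig_i))
  reaction_network(sp, do.call(rbind, nm_list), do.call(rbind, np_list),
                   kappa = kap, partner = partner, node = node,
                   signals = sig_i, responses = resp, omega = omega,
                   rate_bounds = rate_bounds)
}

# a reversible conversion chain head -> ... -> tail
chain_reactions <- function(names, reversible = TRUE) {
  lapply(seq_len(length(names) - 1), function(i) {
    list(from = stats::setNames(1L, names[i]), to = stats::setNames(1L, names[i + 1]),
         reversible = reversible)
  })
}

#' Catalog of small signalling network topologies
#'
#' Returns one of ten built-in topologies (`"a"` to `"j"`) of signal
#' transduction pathways: single and multiple conversion chains whose head
#' species are externally driven signals, optionally coupled through shared
#' reactions, shared species, connecting links or cycles. Panel `"j"` is the
#' larger network of three interacting pathways with `N = 13` species and
#' `M = 6` reversible reaction nodes, with signals `X0, X3, X6` and responses
#' `X2, X5, X8`. The exact reaction schemes behind the published topologies
#' are not available, so these are caption-faithful renderings: the pathway
#' count, coupling style, species/reaction counts and signal/response
#' assignments match the described panels.
#'
#' @param id one of `"a"` ... `"j"`.
#' @param reversible override the panel's default reversibility: `TRUE`
#'   forces every reaction node reversible, `FALSE` keeps only the forward
#'   directions, `NULL` (default) keeps the panel's own mix.
#' @param x_max copy-number cap applied to every species (default 1000;
#'   smaller caps give proportionally faster relaxation and are convenient
#'   for scaled-down studies).
#' @return a `reaction_network`.
#' @export
catalog_network <- function(id = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j"),
                            reversible = NULL, x_max = 1000) {
  id <- match.arg(id)
  rev1 <- function(x) if (is.null(reversible)) x else reversible
  lk <- function(from, to, rev) list(from = stats::setNames(1L, from),
                                     to = stats::setNames(1L, to), reversible = rev)
  two_chains <- function() c(chain_reactions(c("X0", "X1", "X2"), rev1(TRUE)),
                             chain_reactions(c("X3", "X4", "X5"), rev1(TRUE)))
  net <- switch(id,
    a = build_network(
      species = c("X0", "X1", "X2"), driven = "X0",
      reactions = chain_reactions(c("X0", "X1", "X2"), rev1(TRUE)),
      signals = "X0", responses = list(X0 = "X2")),
    b = build_network(
      species = paste0("X", 0:5), driven = c("X0", "X3"),
      reactions = two_chains(),
      signals = c("X0", "X3"), responses = list(X0 = "X2", X3 = "X5")),
    c = build_network(
      species = paste0("X", 0:4), driven = c("X0", "X1"),
      reactions = list(
        list(from = c(X0 = 1L, X1 = 1L), to = c(X2 = 1L), reversible = rev1(TRUE)),
        list(from = c(X2 = 1L), to = c(X3 = 1L, X4 = 1L), reversible = rev1(TRUE))),
      signals = c("X0", "X1"), responses = list(X0 = "X3", X1 = "X4")),
    d = build_network(
      species = paste0("X", 0:4), driven = c("X0", "X1"),
      reactions = list(lk("X0", "X4", rev1(TRUE)), lk("X4", "X2", rev1(TRUE)),
                       lk("X1", "X4", rev1(TRUE)), lk("X4", "X3", rev1(TRUE))),
      signals = c("X0", "X1"), responses = list(X0 = "X2", X1 = "X3")),
    e = build_network(
      species = paste0("X", 0:5), driven = c("X0", "X3"),
      reactions = c(two_chains(), list(lk("X1", "X4", rev1(TRUE)))),
      signals = c("X0", "X3"), responses = list(X0 = "X2", X3 = "X5")),
    f = build_network(
      species = paste0("X", 0:5), driven = c("X0", "X3"),
      reactions = c(two_chains(), list(lk("X1", "X4", rev1(FALSE)))),
      signals = c("X0", "X3"), responses = list(X0 = "X2", X3 = "X5")),
    g = build_network(
      species = paste0("X", 0:5), driven = c("X0", "X3"),
      reactions = c(two_chains(),
                    list(lk("X1", "X4", rev1(FALSE)), lk("X4", "X1", rev1(FALSE)))),
      signals = c("X0", "X3"), responses = list(X0 = "X2", X3 = "X5")),
    h = build_network(
      species = paste0("X", 0:5), driven = c("X0", "X3"),
      reactions = c(two_chains(),
                    list(lk("X1", "X4", rev1(FALSE)), lk("X5", "X2", rev1(FALSE)))),
      signals = c("X0", "X3"), responses = list(X0 = "X2", X3 = "X5")),
    i = build_network(
      species = paste0("X", 0:4), driven = c("X0", "X3", "X4"),
      reactions = list(
        lk("X0", "X1", rev1(TRUE)),
        list(from = c(X1 = 1L, X3 = 1L), to = c(X2 = 1L, X3 = 1L), reversible = rev1(FALSE)),
        list(from = c(X2 = 1L, X4 = 1L), to = c(X1 = 1L, X4 = 1L), reversible = rev1(FALSE))),
      signals = "X0", responses = list(X0 = "X2")),
    j = build_network(
      species = paste0("X", 0:12), driven = c("X0", "X3", "X6"),
      reactions = list(
        list(from = c(X0 = 1L, X9 = 1L),  to = c(X1 = 1L, X10 = 1L), reversible = rev1(TRUE)),
        list(from = c(X1 = 1L),           to = c(X2 = 1L, X9 = 1L),  reversible = rev1(TRUE)),
        list(from = c(X3 = 1L, X10 = 1L), to = c(X4 = 1L, X11 = 1L), reversible = rev1(TRUE)),
        list(from = c(X4 = 1L),           to = c(X5 = 1L, X10 = 1L), reversible = rev1(TRUE)),
        list(from = c(X6 = 1L, X11 = 1L), to = c(X7 = 1L, X12 = 1L), reversible = rev1(TRUE)),
        list(from = c(X7 = 1L, X12 = 1L), to = c(X8 = 1L, X9 = 1L),  reversible = rev1(TRUE))),
      signals = c("X0", "X3", "X6"),
      responses = list(X0 = "X2", X3 = "X5", X6 = "X8")))
  net$species$x_max <- as.integer(rep_len(x_max, nrow(net$species)))
  net
}
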