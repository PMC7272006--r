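#' Read / write a reaction network as JSON
#'
#' Networks are persisted in a small JSON schema (version 1.0): species as
#' `{name, driven, x_max}` records; one record per reaction *node* holding the
#' forward-direction stoichiometry as sparse maps from 0-based species index
#' to coefficient, the rate `kappa` (a pair `[forward, backward]` for a
#' reversible node), and a `reversible` flag; signal indices and the
#' signal -> response map (0-based); and the volume `omega`. `write_network`
#' followed by `read_network` is the identity on the network structure.
#'
#' @param net a `reaction_network`.
#' @param path file path.
#' @return `read_network` returns a `reaction_network`; `write_network`
#'   returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  fwd <- which(is.na(net$partner) | net$partner > seq_along(net$partner))
  sparse <- function(v) {
    nz <- which(v > 0)
    stats::setNames(as.list(as.integer(v[nz])), as.character(nz - 1L))
  }
  rxs <- lapply(fwd, function(r) {
    rev <- !is.na(net$partner[r])
    list(nu_minus = sparse(net$nu_minus[r, ]),
         nu_plus = sparse(net$nu_plus[r, ]),
         kappa = if (rev) c(net$kappa[r], net$kappa[net$partner[r]]) else net$kappa[r],
         reversible = rev)
  })
  doc <- list(
    schema_version = "1.0",
    species = lapply(seq_len(nrow(net$species)), function(i)
      list(name = net$species$name[i], driven = net$species$driven[i],
           x_max = net$species$x_max[i])),
    reactions = rxs,
    signals = as.list(net$signals - 1L),
    responses = stats::setNames(
      lapply(net$responses, function(v) as.list(v - 1L)),
      as.character(as.integer(names(net$responses)) - 1L)),
    omega = net$omega,
    rate_bounds = net$rate_bounds)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path)
  need <- function(key) {
    if (is.null(doc[[key]])) stop("network file: missing required key '", key, "'")
    doc[[key]]
  }
  spl <- need("species")
  sp <- data.frame(
    name = vapply(spl, function(s) as.character(s$name), character(1)),
    driven = vapply(spl, function(s) isTRUE(s$driven), logical(1)),
    x_max = vapply(spl, function(s) as.integer(if (is.null(s$x_max)) 1000L else s$x_max),
                   integer(1)),
    stringsAsFactors = FALSE)
  ns <- nrow(sp)
  dense <- function(m, what, r) {
    v <- integer(ns)
    if (length(m)) {
      i <- as.integer(names(m)) + 1L
      if (anyNA(i) || any(i < 1) || any(i > ns))
        stop("network file: reaction ", r, " ", what, ": bad species index")
      co <- vapply(m, as.numeric, numeric(1))
      if (any(co < 0)) stop("network file: reaction ", r, " ", what, ": negative coefficient")
      v[i] <- as.integer(co)
    }
    v
  }
  nm_list <- list(); np_list <- list(); kap <- numeric()
  partner <- integer(); node <- integer()
  for (r in seq_along(need("reactions"))) {
    rx <- doc$reactions[[r]]
    vm <- dense(rx$nu_minus, "nu_minus", r)
    vp <- dense(rx$nu_plus, "nu_plus", r)
    k <- vapply(if (is.list(rx$kappa)) rx$kappa else list(rx$kappa), as.numeric, numeric(1))
    if (any(k < 0)) stop("network file: reaction ", r, ": kappa is negative")
    i <- length(kap) + 1L
    nm_list[[i]] <- vm; np_list[[i]] <- vp; kap[i] <- k[1]; node[i] <- r
    if (isTRUE(rx$reversible)) {
      nm_list[[i + 1L]] <- vp; np_list[[i + 1L]] <- vm
      kap[i + 1L] <- if (length(k) > 1) k[2] else k[1]
      node[i + 1L] <- r
      partner[i] <- i + 1L; partner[i + 1L] <- i
    } else partner[i] <- NA_integer_
  }
  sig <- vapply(doc$signals, as.integer, integer(1)) + 1L
  resp <- doc$responses
  responses <- stats::setNames(
    lapply(resp, function(v) vapply(v, as.integer, integer(1)) + 1L),
    as.character(as.integer(names(resp)) + 1L))
  reaction_network(sp, do.call(rbind, nm_list), do.call(rbind, np_list),
                   kappa = kap, partner = partner, node = node,
                   signals = sig, responses = responses,
                   omega = if (is.null(doc$omega)) 1 else as.numeric(doc$omega),
                   rate_bounds = if (is.null(doc$rate_bounds)) c(0, 2)
                                 else vapply(doc$rate_bounds, as.numeric, numeric(1)))
}
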