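#' Enumerate the state space reachable from an origin
#'
#' Breadth-first closure of the origin under the network's reaction vectors,
#' traversed in both directions along transitions with positive propensity,
#' restricted to nonnegative integer states (and to sup-norm `<= bound` when
#' a truncation level is given). A candidate state is admitted only where
#' every rate law evaluates to a finite nonnegative value, so spaces cut out
#' by occupancy constraints (e.g. a total-nucleosome budget entering a rate
#' factor) are respected without declaring them separately. The final
#' ordering is lexicographic, so enumeration is deterministic.
#'
#' When a `bound` is given the space carries a one-step collar: states with
#' sup-norm in `(bound, bound + max |v|]` reachable from the core are kept
#' and flagged `core = FALSE`. Truncated dynamics freeze there (all
#' propensities zero), mirroring the usual treatment of countably infinite
#' chains; analyses that need a proper finite chain drop the collar.
#'
#' @param network a [reaction_network()].
#' @param origin nonnegative integer state vector (species order).
#' @param bound optional sup-norm truncation level M; required when the
#'   reachable set is infinite.
#' @param cap guard on the number of enumerated states.
#' @param states optional explicit state list (matrix, rows = states) that
#'   bypasses the reachability closure for spaces chosen by hand.
#' @return An object of class `state_space`: list with `states` (n x d
#'   integer matrix, lexicographic row order), `index` lookup, `origin`,
#'   `bound`, `core` (logical vector) and the species names.
#' @export
enumerate_states <- function(network, origin, bound = NULL, cap = 200000L,
                             states = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  d <- network$d
  origin <- as.integer(origin)
  stopifnot(length(origin) == d, all(origin >= 0))
  ts <- transition_structure(network)
  V <- ts$vectors                       # d x n
  n <- ncol(V)

  if (!is.null(states)) {
    states <- as.matrix(states)
    storage.mode(states) <- "integer"
    stopifnot(ncol(states) == d, all(states >= 0), !anyDuplicated(states))
    return(.finish_space(network, states, origin, bound, V))
  }

  maxstep <- if (n) max(abs(V)) else 0L
  eff_bound <- if (is.null(bound)) NULL else as.integer(bound) + maxstep
  if (!is.null(bound) && max(abs(origin)) > bound)
    stop("origin lies outside the truncation bound")

  key <- function(x) paste(x, collapse = ",")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  valid <- function(x) {
    if (any(x < 0)) return(FALSE)
    if (!is.null(eff_bound) && max(x) > eff_bound) return(FALSE)
    lam <- tryCatch(.propensity_matrix(network, matrix(x, nrow = 1),
                                       check = FALSE)[, 1],
                    error = function(e) NA_real_)
    all(is.finite(lam)) && all(lam >= 0)
  }
  if (!valid(origin)) stop("origin is not an admissible state")
  rates_at <- function(x)
    .vector_rates(.propensity_matrix(network, matrix(x, nrow = 1),
                                     check = FALSE)[, 1, drop = TRUE], ts)

  queue <- list(origin)
  assign(key(origin), TRUE, envir = seen)
  out <- list(origin)
  count <- 1L
  while (length(queue)) {
    x <- queue[[1]]
    queue <- queue[-1]
    ux <- rates_at(x)
    for (j in seq_len(n)) {
      cands <- list()
      if (ux[j] > 0) cands <- c(cands, list(x + V[, j]))
      y <- x - V[, j]
      if (all(y >= 0) && (is.null(eff_bound) || max(y) <= eff_bound)) {
        uy <- tryCatch(rates_at(y), error = function(e) NULL)
        if (!is.null(uy) && uy[j] > 0) cands <- c(cands, list(y))
      }
      for (z in cands) {
        kz <- key(z)
        if (!exists(kz, envir = seen) && valid(z)) {
          assign(kz, TRUE, envir = seen)
          count <- count + 1L
          if (count > cap) {
            if (is.null(bound))
              stop("reachable state space exceeds ", cap,
                   " states; supply a truncation bound")
            stop("state space exceeds the configured cap of ", cap, " states")
          }
          queue <- c(queue, list(z))
          out <- c(out, list(z))
        }
      }
    }
  }
  states <- do.call(rbind, out)
  storage.mode(states) <- "integer"
  .finish_space(network, states, origin, bound, V)
}

.finish_space <- function(network, states, origin, bound, V) {
  ord <- do.call(order, as.data.frame(states))
  states <- states[ord, , drop = FALSE]
  colnames(states) <- network$species
  keys <- apply(states, 1, paste, collapse = ",")
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(keys)) assign(keys[i], i, envir = index)
  core <- if (is.null(bound)) rep(TRUE, nrow(states))
          else apply(abs(states), 1, max) <= bound
  structure(list(states = states, index = index, origin = origin,
                 bound = bound, core = core, species = network$species,
                 d = network$d),
            class = "state_space")
}

#' Position of a state in an enumerated space (NA when absent)
#' @param space a [enumerate_states()] result.
#' @param x state vector.
#' @export
state_index <- function(space, x) {
  k <- paste(as.integer(x), collapse = ",")
  if (exists(k, envir = space$index)) get(k, envir = space$index) else NA_integer_
}

#' @export
print.state_space <- function(x, ...) {
  cat("state space:", nrow(x$states), "states in", x$d, "dimensions")
  if (!is.null(x$bound))
    cat(" (truncation bound ", x$bound, ", ", sum(x$core), " core states)",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Distinct transition vectors and reaction grouping of a network
#'
#' Collects the distinct nonzero net vectors \eqn{v_j = v^+ - v^-} in first
#' occurrence order and records, for each, the set of reactions sharing it;
#' the aggregated propensity of direction j is the sum of those reactions'
#' rates.
#'
#' @param network a [reaction_network()].
#' @return List with `vectors` (d x n integer matrix), `source_groups`
#'   (list of reaction index vectors) and `n`.
#' @export
transition_structure <- function(network) {
  nets <- vapply(network$reactions, function(r) r$vnet, integer(network$d))
  nets <- matrix(nets, nrow = network$d)
  keys <- apply(nets, 2, paste, collapse = ",")
  uk <- unique(keys)
  groups <- lapply(uk, function(k) which(keys == k))
  V <- nets[, match(uk, keys), drop = FALSE]
  list(vectors = V, n = ncol(V), source_groups = groups)
}

# aggregate per-reaction rates into per-direction rates
.vector_rates <- function(lambda, ts) {
  vapply(ts$source_groups, function(g)
    if (length(g) == 1L) lambda[g] else sum(lambda[g]), numeric(1))
}

# n x N matrix of aggregated direction rates over an enumerated space,
# with the boundary contract applied: a direction is zeroed at states whose
# target is absent from the space, and (freeze-style truncation) at collar
# states of a bounded space.
.direction_rates <- function(network, space, ts) {
  L <- .propensity_matrix(network, space$states, check = TRUE)
  N <- nrow(space$states)
  U <- matrix(0, ts$n, N)
  for (j in seq_len(ts$n)) {
    g <- ts$source_groups[[j]]
    U[j, ] <- if (length(g) == 1L) L[g, ] else colSums(L[g, , drop = FALSE])
  }
  tr <- .target_index(space, ts$vectors)
  U[is.na(tr)] <- 0
  U[, !space$core] <- 0
  U
}

# n x N matrix of target state indices (NA if x + v_j is not in the space)
.target_index <- function(space, V) {
  N <- nrow(space$states)
  n <- ncol(V)
  tr <- matrix(NA_integer_, n, N)
  for (j in seq_len(n)) {
    targets <- sweep(space$states, 2, V[, j], `+`)
    keys <- apply(targets, 1, paste, collapse = ",")
    tr[j, ] <- vapply(keys, function(k)
      if (exists(k, envir = space$index)) get(k, envir = space$index)
      else NA_integer_, integer(1), USE.NAMES = FALSE)
  }
  tr
}

#' Compile a comparable pair of networks on a shared state space
#'
#' The two networks must live on the same species list and are compared
#' through the shared list of distinct transition vectors (the union, in
#' first-occurrence order of the base network). The returned object carries
#' the enumerated space, the aggregated direction rates of both networks
#' with the boundary contract applied, and the target index table; it is the
#' common input of the condition checkers and the coupled simulator.
#'
#' @param base,modified [reaction_network()] objects on the same species.
#' @param origin nonnegative integer state vector.
#' @param bound optional sup-norm truncation level (needed for infinite
#'   spaces); checks are then performed on the truncation.
#' @param truncation how a bound is interpreted: `"freeze"` keeps full
#'   rates on the core and lets chains exit into a one-step collar where
#'   they stop (the truncation used when the bounded model stands in for an
#'   infinite chain); `"box"` zeroes any rate whose target leaves the core,
#'   defining a proper finite chain on the box. Ignored without a bound.
#' @param cap passed to [enumerate_states()].
#' @return Object of class `propensity_pair`.
#' @export
propensity_pair <- function(base, modified, origin, bound = NULL,
                            truncation = c("freeze", "box"),
                            cap = 200000L) {
  truncation <- match.arg(truncation)
  stopifnot(inherits(base, "reaction_network"),
            inherits(modified, "reaction_network"),
            identical(base$species, modified$species))
  ts_b <- transition_structure(base)
  ts_m <- transition_structure(modified)
  kb <- apply(ts_b$vectors, 2, paste, collapse = ",")
  km <- apply(ts_m$vectors, 2, paste, collapse = ",")
  extra <- setdiff(km, kb)
  V <- cbind(ts_b$vectors,
             ts_m$vectors[, match(extra, km), drop = FALSE])
  keys <- c(kb, extra)
  # per-network group lists aligned to the shared vector order
  align <- function(ts, net_keys) {
    lapply(keys, function(k) {
      p <- match(k, net_keys)
      if (is.na(p)) integer(0) else ts$source_groups[[p]]
    })
  }
  shared_b <- list(vectors = V, n = ncol(V), source_groups = align(ts_b, kb))
  shared_m <- list(vectors = V, n = ncol(V), source_groups = align(ts_m, km))

  space <- enumerate_states(base, origin, bound = bound, cap = cap)
  # the modified network may reach further states; grow the space if so
  space2 <- enumerate_states(modified, origin, bound = bound, cap = cap)
  if (!identical(space$states, space2$states)) {
    all_states <- unique(rbind(space$states, space2$states))
    space <- .finish_space(base, all_states, as.integer(origin), bound, V)
  }
  if (!is.null(bound) && truncation == "box") {
    states <- space$states[space$core, , drop = FALSE]
    space <- .finish_space(base, states, as.integer(origin), NULL, V)
  }

  rates_of <- function(network, ts) {
    L <- .propensity_matrix(network, space$states, check = TRUE)
    U <- matrix(0, ncol(V), nrow(space$states))
    for (j in seq_len(ncol(V))) {
      g <- ts$source_groups[[j]]
      if (length(g) == 1L) U[j, ] <- L[g, ]
      else if (length(g) > 1L) U[j, ] <- colSums(L[g, , drop = FALSE])
    }
    U
  }
  U  <- rates_of(base, shared_b)
  Ub <- rates_of(modified, shared_m)
  tr <- .target_index(space, V)
  U[is.na(tr)] <- 0; Ub[is.na(tr)] <- 0
  U[, !space$core] <- 0; Ub[, !space$core] <- 0

  structure(list(space = space, vectors = V, n = ncol(V),
                 U = U, Ub = Ub, target = tr,
                 base = base, modified = modified),
            class = "propensity_pair")
}

#' @export
print.propensity_pair <- function(x, ...) {
  cat("propensity pair:", x$n, "shared transition vectors on",
      nrow(x$space$states), "states\n")
  invisible(x)
}

#' Build the infinitesimal generator over an enumerated space
#'
#' Sparse rate matrix with \eqn{Q_{x, x+v_j} = \Upsilon_j(x)} and diagonal
#' minus the row sum. For bounded spaces the collar is dropped and rates
#' whose target leaves the core are zeroed (restriction-style truncation),
#' giving a proper finite-chain surrogate suitable for stationary and
#' first-passage analysis.
#'
#' @param network a [reaction_network()].
#' @param space an [enumerate_states()] result for that network.
#' @return List of class `generator_matrix`: `Q` (sparse dgCMatrix over the
#'   core states), `space` (core-only state space), `boundary` (logical:
#'   states at which some rate was zeroed by the restriction).
#' @export
build_generator <- function(network, space) {
  ts <- transition_structure(network)
  U <- .direction_rates(network, space, ts)
  tr <- .target_index(space, ts$vectors)
  keep <- space$core
  if (!all(keep)) {
    idx_map <- cumsum(keep)          # old index -> new index (core only)
    states <- space$states[keep, , drop = FALSE]
    U <- U[, keep, drop = FALSE]
    tr <- tr[, keep, drop = FALSE]
    dropped <- !is.na(tr) & !keep[ifelse(is.na(tr), 1L, tr)]
    U[dropped] <- 0
    tr[dropped] <- NA_integer_
    tr[!is.na(tr)] <- idx_map[tr[!is.na(tr)]]
    space <- .finish_space(network, states, space$origin, NULL, ts$vectors)
    space$bound_used <- TRUE
  }
  N <- nrow(space$states)
  ii <- jj <- integer(0); vv <- numeric(0)
  for (j in seq_len(nrow(U))) {
    pos <- which(U[j, ] > 0 & !is.na(tr[j, ]))
    ii <- c(ii, pos); jj <- c(jj, tr[j, pos]); vv <- c(vv, U[j, pos])
  }
  Q0 <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  Q <- Q0 - Matrix::Diagonal(N, Matrix::rowSums(Q0))
  # states whose raw rates include a zeroed (off-space or off-core) direction
  raw <- .raw_direction_rates(network, space)
  boundary <- colSums(is.na(tr) & raw > 0) > 0
  structure(list(Q = methods::as(Q, "CsparseMatrix"), space = space,
                 boundary = boundary),
            class = "generator_matrix")
}

# raw aggregated direction rates, before the boundary contract
.raw_direction_rates <- function(network, space) {
  ts <- transition_structure(network)
  L <- .propensity_matrix(network, space$states, check = FALSE)
  U <- matrix(0, ts$n, nrow(space$states))
  for (j in seq_len(ts$n)) {
    g <- ts$source_groups[[j]]
    U[j, ] <- if (length(g) == 1L) L[g, ] else colSums(L[g, , drop = FALSE])
  }
  U
}

#' @export
print.generator_matrix <- function(x, ...) {
  cat("generator:", nrow(x$Q), "states,", length(x$Q@x), "nonzeros\n")
  invisible(x)
}
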