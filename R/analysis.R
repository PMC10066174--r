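# strongly connected components of the positive-rate graph
.communicating <- function(Q) {
  Qd <- methods::as(Q, "TsparseMatrix")
  keep <- Qd@x > 0 & Qd@i != Qd@j
  g <- igraph::graph_from_data_frame(
    data.frame(from = Qd@i[keep] + 1L, to = Qd@j[keep] + 1L),
    directed = TRUE,
    vertices = data.frame(name = seq_len(nrow(Q))))
  igraph::components(g, mode = "strong")$membership
}

#' Stationary distribution of a finite generator
#'
#' Solves \eqn{\pi Q = 0}, \eqn{\sum \pi = 1} by a sparse direct solve after
#' verifying irreducibility (strong connectivity of the positive-rate
#' graph). For generators obtained by truncating an infinite chain the
#' report carries the probability mass sitting on states within one
#' transition of the truncation boundary; a non-negligible value there
#' means the truncation level is too low for the stationary law to be
#' trusted.
#'
#' @param gen a [build_generator()] result (or a square generator matrix).
#' @param boundary optional logical vector marking truncation-boundary
#'   states (taken from `gen` when available).
#' @return Object of class `stationary_distribution`: `pi` (probability
#'   vector over the space ordering), `space`, `boundary_mass`.
#' @export
stationary <- function(gen, boundary = NULL) {
  if (inherits(gen, "generator_matrix")) {
    Q <- gen$Q; space <- gen$space
    if (is.null(boundary)) boundary <- gen$boundary
  } else { Q <- gen; space <- NULL }
  N <- nrow(Q)
  comp <- .communicating(Q)
  if (max(comp) > 1) {
    closed <- vapply(seq_len(max(comp)), function(c) {
      idx <- which(comp == c)
      all(Matrix::rowSums(abs(Q[idx, -idx, drop = FALSE])) == 0)
    }, logical(1))
    stop("chain is reducible: ", sum(closed), " closed communicating ",
         "class(es), e.g. states {",
         paste(utils::head(which(comp == which(closed)[1]), 8), collapse = ","),
         "}")
  }
  # replace one balance equation by the normalization constraint
  M <- Matrix::t(Q)
  M[N, ] <- 1
  b <- c(rep(0, N - 1), 1)
  piv <- as.numeric(Matrix::solve(M, b))
  piv[piv < 0 & piv > -1e-12] <- 0
  if (any(piv < 0)) stop("stationary solve produced negative mass")
  piv <- piv / sum(piv)
  res <- as.numeric(piv %*% Q)
  if (max(abs(res)) > 1e-8 * max(abs(Q@x)))
    warning("stationary residual larger than expected: ", max(abs(res)))
  bm <- if (!is.null(boundary) && any(boundary)) sum(piv[boundary]) else 0
  structure(list(pi = piv, space = space, boundary_mass = bm),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat("stationary distribution over", length(x$pi), "states")
  if (x$boundary_mass > 0)
    cat(" (truncation-boundary mass ", format(x$boundary_mass, digits = 3),
        ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Stationary law of a countably infinite chain via self-checked truncation
#'
#' Restricts the chain to the sup-norm ball of radius `bound`, solves for
#' the stationary law, and accepts the result only when the probability
#' mass on truncation-boundary states is below `tol`; otherwise the bound
#' is doubled (at most `max_doublings` times). The restriction (zeroing
#' outbound rates) is the standard finite-projection surrogate; the
#' boundary-mass criterion quantifies how far the surrogate can be trusted.
#'
#' @param network a [reaction_network()].
#' @param origin state fixing the compatibility class.
#' @param bound initial truncation level.
#' @param tol acceptable truncation-boundary mass.
#' @param max_doublings retry budget.
#' @export
stationary_truncated <- function(network, origin, bound, tol = 1e-8,
                                 max_doublings = 5L) {
  for (k in 0:max_doublings) {
    sp <- enumerate_states(network, origin, bound = bound)
    st <- stationary(build_generator(network, sp))
    if (st$boundary_mass < tol) return(st)
    bound <- bound * 2L
    warning("truncation-boundary mass ", signif(st$boundary_mass, 3),
            " above tolerance; doubling bound to ", bound)
  }
  stop("stationary law did not stabilise within the truncation budget")
}

#' Product-form stationary law of the open enzyme kinetics network
#'
#' For the reversible enzyme network with substrate inflow/outflow
#' (complex-balanced mass-action kinetics) the stationary distribution on a
#' compatibility class factorizes as two Poisson laws for substrate and
#' product and a binomial law over the enzyme/complex split:
#' \deqn{\pi_x \propto e^{-c_1} \frac{c_1^{x_1}}{x_1!}
#'       e^{-c_2} \frac{c_2^{x_2}}{x_2!}
#'       E_{tot}! \frac{c_3^{x_3}}{x_3!} \frac{c_4^{x_4}}{x_4!},}
#' where \eqn{c = (c_1, .., c_4)} is the complex-balanced equilibrium:
#' \eqn{c_1 = \kappa_5/\kappa_6},
#' \eqn{c_2 = \kappa_1\kappa_3\kappa_5 / (\kappa_2\kappa_4\kappa_6)},
#' \eqn{c_3 = 1/(1 + \kappa_1\kappa_5/(\kappa_2\kappa_6))} and
#' \eqn{c_4 = 1 - c_3}. The law is evaluated on the truncated class and
#' renormalized.
#'
#' @param kappa numeric vector of the six rate constants (order: binding,
#'   unbinding, catalysis, reverse catalysis, inflow, outflow).
#' @param E_tot total enzyme count.
#' @param bound sup-norm truncation level for substrate/product counts.
#' @return A `stationary_distribution` whose space is the truncated class,
#'   with the equilibrium `c` attached.
#' @export
product_form_pi <- function(kappa, E_tot, bound) {
  stopifnot(length(kappa) == 6, all(kappa > 0), E_tot >= 1)
  c1 <- kappa[5] / kappa[6]
  c2 <- kappa[1] * kappa[3] * kappa[5] / (kappa[2] * kappa[4] * kappa[6])
  r <- kappa[1] * kappa[5] / (kappa[2] * kappa[6])
  c3 <- 1 / (1 + r)
  c4 <- r / (1 + r)
  net <- make_example("ek2", E_tot = E_tot, kappa = kappa)$base
  space <- enumerate_states(net, c(0, 0, E_tot, 0), bound = bound)
  keep <- space$core
  states <- space$states[keep, , drop = FALSE]
  space <- .finish_space(net, states, space$origin, NULL,
                         transition_structure(net)$vectors)
  x <- space$states
  logpi <- x[, 1] * log(c1) - lfactorial(x[, 1]) +
    x[, 2] * log(c2) - lfactorial(x[, 2]) +
    x[, 3] * log(c3) - lfactorial(x[, 3]) +
    x[, 4] * log(c4) - lfactorial(x[, 4])
  piv <- exp(logpi - max(logpi))
  piv <- piv / sum(piv)
  structure(list(pi = piv, space = space, boundary_mass = 0,
                 c = c(c1, c2, c3, c4)),
            class = "stationary_distribution")
}

#' Mean first passage times to a target set
#'
#' Solves the restricted linear system \eqn{Q_{\setminus\Gamma} h = -1}
#' with \eqn{h \equiv 0} on \eqn{\Gamma}. States from which the target is
#' not almost surely reached (those that can wander into a closed set
#' disjoint from the target) get `+Inf` rather than a solver failure.
#'
#' @param gen a [build_generator()] result.
#' @param target integer indices (or logical vector) of the target states.
#' @return Numeric vector of expected hitting times over the space
#'   ordering.
#' @export
mfpt <- function(gen, target) {
  stopifnot(inherits(gen, "generator_matrix"))
  Q <- gen$Q
  N <- nrow(Q)
  tgt <- .member_logical(gen$space, target)
  if (!any(tgt)) stop("target set is empty")
  h <- numeric(N)
  rest <- which(!tgt)
  if (!length(rest)) return(h)
  # states that can reach the target: reverse reachability through non-target
  Qd <- methods::as(Q, "TsparseMatrix")
  pos <- Qd@x > 0 & Qd@i != Qd@j
  from <- Qd@i[pos] + 1L; to <- Qd@j[pos] + 1L
  can <- tgt
  repeat {
    new <- unique(from[to %in% which(can) & !can[from]])
    new <- new[!tgt[new]]
    if (!length(new)) break
    can[new] <- TRUE
  }
  # a non-target state is safe only if no path through non-target states
  # leads to the cannot-reach set
  dead <- !can
  if (any(dead)) {
    doomed <- dead
    repeat {
      new <- unique(from[to %in% which(doomed) & !doomed[from] & !tgt[from]])
      if (!length(new)) break
      doomed[new] <- TRUE
    }
  } else doomed <- rep(FALSE, N)
  h[doomed] <- Inf
  free <- which(!tgt & !doomed)
  if (length(free)) {
    Qff <- Q[free, free, drop = FALSE]
    sol <- tryCatch(as.numeric(Matrix::solve(Qff, rep(-1, length(free)))),
                    error = function(e)
                      stop("restricted first-passage system is singular: ",
                           conditionMessage(e)))
    if (any(sol < -1e-9)) stop("first-passage solve produced negative times")
    h[free] <- pmax(sol, 0)
  }
  h
}

# uniformized-series transition distribution: row of exp(tQ) from x0
.transient_distribution <- function(Q, i0, t, tol = 1e-12) {
  N <- nrow(Q)
  if (t <= 0) { out <- numeric(N); out[i0] <- 1; return(out) }
  lam <- max(-Matrix::diag(Q)) * 1.0001 + 1e-12
  if (lam <= 0) { out <- numeric(N); out[i0] <- 1; return(out) }
  P <- Q / lam + Matrix::Diagonal(N)
  w <- numeric(N); w[i0] <- 1
  lt <- lam * t
  logw <- -lt                      # log Poisson(k = 0) weight
  acc <- exp(logw) * w
  covered <- exp(logw)
  k <- 0
  while (covered < 1 - tol && k < 100000) {
    k <- k + 1
    w <- as.numeric(w %*% P)
    logw <- logw + log(lt) - log(k)
    pk <- exp(logw)
    acc <- acc + pk * w
    covered <- covered + pk
  }
  acc / sum(acc)
}

#' Transient occupation probability
#'
#' \eqn{P(X(t) \in \Gamma \mid X(0) = x_0)} by the uniformized power
#' series, truncated when the neglected Poisson tail is below `1e-12`.
#'
#' @param gen a [build_generator()] result.
#' @param x0 initial state (vector or index).
#' @param t time.
#' @param target integer indices or logical vector over states.
#' @export
transient_prob <- function(gen, x0, t, target) {
  stopifnot(inherits(gen, "generator_matrix"))
  i0 <- if (length(x0) == 1L) as.integer(x0) else state_index(gen$space, x0)
  if (is.na(i0)) stop("x0 not in the state space")
  tgt <- .member_logical(gen$space, target)
  p <- .transient_distribution(gen$Q, i0, t)
  sum(p[tgt])
}

#' First-passage-time dominance between two comparable chains
#'
#' Computes the exact survival functions of the hitting times
#' \eqn{T_\Gamma} (base chain from \eqn{x^\circ}) and
#' \eqn{\breve T_\Gamma} (modified chain from \eqn{\breve x^\circ}) by
#' making the target absorbing and evaluating transient probabilities on a
#' time grid, together with both mean first passage times. When the
#' ordering conditions hold and \eqn{\Gamma} is increasing, the modified
#' chain hits first in the usual stochastic order (survival dominated
#' pointwise and mean dominated); for decreasing \eqn{\Gamma} the
#' inequalities reverse. The target must be increasing or decreasing for
#' the comparison to be meaningful; anything else is an error.
#'
#' @param pair a [propensity_pair()] (finite space).
#' @param A comparison matrix.
#' @param target integer indices or logical vector over the core states.
#' @param starts list with `x0` (base start) and `xb0` (modified start),
#'   ordered `x0` below `xb0`.
#' @param t_grid times at which the survival functions are compared.
#' @return List with the grid, both survival functions, both means, the
#'   target's monotonicity direction and the logical `dominated` verdict.
#' @export
hitting_dominance <- function(pair, A, target, starts, t_grid) {
  A <- .as_cmp(A)
  gen  <- build_generator(pair$base, pair$space)
  genb <- build_generator(pair$modified, pair$space)
  sp <- gen$space
  tgt <- .member_logical(sp, target)
  inc <- is_increasing(A, sp, tgt)
  dec <- is_decreasing(A, sp, tgt)
  if (!inc && !dec)
    stop("target set is neither increasing nor decreasing: ",
         "first-passage dominance does not apply")
  if (!leq_A(A, starts$x0, starts$xb0)) stop("starts are not ordered")
  absorbing <- function(Q) { Q[which(tgt), ] <- 0; Q }
  Qa  <- absorbing(gen$Q)
  Qba <- absorbing(genb$Q)
  i0  <- state_index(sp, starts$x0)
  ib0 <- state_index(sp, starts$xb0)
  surv  <- vapply(t_grid, function(t)
    1 - sum(.transient_distribution(Qa, i0, t)[tgt]), numeric(1))
  survb <- vapply(t_grid, function(t)
    1 - sum(.transient_distribution(Qba, ib0, t)[tgt]), numeric(1))
  m  <- mfpt(gen, tgt)[i0]
  mb <- mfpt(genb, tgt)[ib0]
  tol <- 1e-9
  dominated <- if (inc) all(survb <= surv + tol) && mb <= m + tol
               else all(surv <= survb + tol) && m <= mb + tol
  list(t_grid = t_grid, survival_base = surv, survival_modified = survb,
       mean_base = m, mean_modified = mb,
       direction = if (inc) "increasing" else "decreasing",
       dominated = dominated)
}
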