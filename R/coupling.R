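#' Uniformization rate for a comparable pair
#'
#' A shared thinning rate \eqn{\lambda} strictly dominating n times the
#' larger of the two total-rate suprema over the (possibly truncated) state
#' space, so that every acceptance probability \eqn{\Upsilon_j(x)/\lambda}
#' stays below 1/n and the per-direction acceptance intervals fit inside
#' disjoint subintervals of [0, 1). A 0.1% margin is applied over the strict
#' bound.
#'
#' @param pair a [propensity_pair()].
#' @export
uniformization_rate <- function(pair) {
  tot <- max(max(colSums(pair$U)), max(colSums(pair$Ub)))
  if (!is.finite(tot) || tot <= 0)
    stop("total propensity is zero or not finite on this space")
  (1 + 1e-3) * pair$n * tot
}

# derived per-pair seed: deterministic in (master seed, pair index) and
# independent of simulation order
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
               k * 7919) %% 2147483629L + 1L
}

#' One-step acceptance map of the uniformized skeleton
#'
#' Maps (state, uniform draw) to the next skeleton state: the draw selects
#' candidate direction \eqn{j = \lfloor un \rfloor + 1} and the jump is
#' accepted when the draw falls in
#' \eqn{I_j(x) = [(j-1)/n, (j-1)/n + \Upsilon_j(x)/\lambda)}; otherwise the
#' step is a self-loop. `psi_map` is the grouped variant: directions sharing
#' an image \eqn{A v_j} occupy one block of [0,1) with their acceptance
#' subintervals stacked end to end, so a shared draw couples whole groups
#' rather than single directions. The draw u = 1 (a probability-zero event)
#' is a self-loop by convention.
#'
#' @param pair a [propensity_pair()].
#' @param x state vector (must lie in the pair's space).
#' @param u a number in [0, 1].
#' @param lambda uniformization rate; defaults to [uniformization_rate()].
#' @param network `"base"` or `"modified"`: whose propensities drive the map.
#' @return The next state vector.
#' @export
phi_map <- function(pair, x, u, lambda = NULL,
                    network = c("base", "modified")) {
  network <- match.arg(network)
  if (is.null(lambda)) lambda <- uniformization_rate(pair)
  U <- if (network == "base") pair$U else pair$Ub
  ix <- state_index(pair$space, x)
  if (is.na(ix)) stop("state is not in the enumerated space")
  n <- pair$n
  j0 <- floor(u * n) + 1
  if (j0 >= 1 && j0 <= n && (u - (j0 - 1) / n) < U[j0, ix] / lambda)
    return(pair$space$states[pair$target[j0, ix], ])
  x
}

#' @rdname phi_map
#' @param A comparison matrix defining the grouping (see
#'   [group_structure()]).
#' @export
psi_map <- function(pair, A, x, u, lambda = NULL,
                    network = c("base", "modified")) {
  network <- match.arg(network)
  if (is.null(lambda)) lambda <- uniformization_rate(pair)
  U <- if (network == "base") pair$U else pair$Ub
  ix <- state_index(pair$space, x)
  if (is.na(ix)) stop("state is not in the enumerated space")
  gs <- group_structure(A, pair$vectors)
  n <- pair$n
  pos <- floor(u * n) + 1
  if (pos < 1 || pos > n) return(x)
  k <- findInterval(pos - 1e-9, gs$p)     # block containing this position
  off <- u - gs$p[k] / n
  for (q in (gs$p[k] + 1L):gs$p[k + 1L]) {
    w <- U[gs$sigma[q], ix] / lambda
    if (off < w)
      return(pair$space$states[pair$target[gs$sigma[q], ix], ])
    off <- off - w
  }
  x
}

# tight inner loop shared by couple_paths / couple_ensemble; operates on
# state indices and returns a summary plus (optionally) the jump records
.couple_core <- function(pair, AX, lambda, ix, iy, t_max,
                         grouped = NULL, store = FALSE) {
  n <- pair$n
  U <- pair$U / lambda
  Ub <- pair$Ub / lambda
  tr <- pair$target
  core <- pair$space$core
  m <- nrow(AX)
  K <- rpois(1, lambda * t_max)
  times <- if (K > 0) sort(runif(K)) * t_max else numeric(0)
  us <- if (K > 0) runif(K) else numeric(0)
  ord_ok <- TRUE
  exit_time <- NA_real_
  thinned <- 0L
  if (store) {
    jx_t <- numeric(0); jx_s <- integer(0)
    jy_t <- numeric(0); jy_s <- integer(0)
  }
  if (!is.null(grouped)) {
    sig <- grouped$sigma; p <- grouped$p
    block_of <- rep(seq_len(grouped$s), lengths(grouped$groups))
  }
  tolp <- .scrn_tol$preorder
  for (k in seq_len(K)) {
    u <- us[k]
    moved <- FALSE
    if (is.null(grouped)) {
      j0 <- floor(u * n) + 1
      if (j0 <= n) {
        off <- u - (j0 - 1) / n
        if (off < U[j0, ix]) { ix <- tr[j0, ix]; moved <- TRUE
          if (store) { jx_t <- c(jx_t, times[k]); jx_s <- c(jx_s, ix) } }
        if (off < Ub[j0, iy]) { iy <- tr[j0, iy]; moved <- TRUE
          if (store) { jy_t <- c(jy_t, times[k]); jy_s <- c(jy_s, iy) } }
      }
    } else {
      pos <- floor(u * n) + 1
      if (pos <= n) {
        kb <- block_of[pos]
        off <- u - p[kb] / n
        o1 <- off
        for (q in (p[kb] + 1L):p[kb + 1L]) {
          w <- U[sig[q], ix]
          if (o1 < w) { ix <- tr[sig[q], ix]; moved <- TRUE
            if (store) { jx_t <- c(jx_t, times[k]); jx_s <- c(jx_s, ix) }
            break }
          o1 <- o1 - w
        }
        o2 <- off
        for (q in (p[kb] + 1L):p[kb + 1L]) {
          w <- Ub[sig[q], iy]
          if (o2 < w) { iy <- tr[sig[q], iy]; moved <- TRUE
            if (store) { jy_t <- c(jy_t, times[k]); jy_s <- c(jy_s, iy) }
            break }
          o2 <- o2 - w
        }
      }
    }
    if (!moved) thinned <- thinned + 1L
    else {
      if (ord_ok) {
        diff <- AX[, iy] - AX[, ix]
        for (r in seq_len(m))
          if (diff[r] < -tolp) { ord_ok <- FALSE; break }
      }
      if (is.na(exit_time) && (!core[ix] || !core[iy]))
        exit_time <- times[k]
    }
  }
  out <- list(ix = ix, iy = iy, order_ok = ord_ok,
              exited = !is.na(exit_time), exit_time = exit_time,
              n_events = K, thinned = thinned)
  if (store) out <- c(out, list(jx_t = jx_t, jx_s = jx_s,
                                jy_t = jy_t, jy_s = jy_s))
  out
}

.verify_pair <- function(pair, A, verify) {
  rep <- switch(verify,
                none = NULL,
                general = check_general(pair, A),
                boundary = check_boundary(pair, A),
                grouped = check_grouped(pair, A),
                stop("unknown verification mode: ", verify))
  if (!is.null(rep) && !rep$pass)
    stop("comparison conditions (", rep$theorem, ") do not hold; ",
         nrow(rep$witnesses), " violations. Pass verify = \"none\" to ",
         "co-simulate anyway (negative testing).")
  rep
}

#' Co-simulate two ordered chains with a shared uniformization clock
#'
#' Both chains are driven by one Poisson(\eqn{\lambda}) arrival stream and
#' one shared uniform draw per arrival, fed through the acceptance maps of
#' [phi_map()] (or [psi_map()] for `scheme = "grouped"`). When the
#' comparison conditions hold and the initial states are ordered, every
#' event time satisfies \eqn{A(\breve X - X) \ge 0} almost surely; the
#' simulator asserts this and treats a violation under verified conditions
#' as an internal error. On truncated spaces the chains freeze outside the
#' core and the first exit is recorded.
#'
#' @param pair a [propensity_pair()].
#' @param A comparison matrix.
#' @param x0,xb0 initial states with `x0` below `xb0` in the preorder.
#' @param t_max simulation horizon.
#' @param seed integer seed (one stream drives both chains).
#' @param scheme `"ungrouped"` (per-direction coupling) or `"grouped"`.
#' @param verify which condition check to run first: `"auto"` picks
#'   `"grouped"` for the grouped scheme and `"boundary"` when the matrix
#'   qualifies, falling back to `"general"`; `"none"` skips verification
#'   (for negative testing).
#' @param auto_extend on a truncated space, retry with the bound doubled
#'   (up to 5 times, fresh derived seed, with a warning) whenever a chain
#'   exits the truncation before the horizon.
#' @return A `coupled_paths` object: jump times and states of both chains,
#'   `order_ok`, exit metadata, `lambda` and event counts.
#' @export
couple_paths <- function(pair, A, x0, xb0, t_max, seed,
                         scheme = c("ungrouped", "grouped"),
                         verify = "auto", auto_extend = FALSE) {
  if (auto_extend && !is.null(pair$space$bound)) {
    bound <- pair$space$bound
    for (retry in 0:5) {
      res <- couple_paths(pair, A, x0, xb0, t_max,
                          seed = if (retry == 0) seed
                                 else .derive_seed(seed, 1000 + retry),
                          scheme = scheme, verify = verify,
                          auto_extend = FALSE)
      if (!res$exited) return(res)
      if (retry == 5) {
        warning("trajectory still exits the truncation after 5 doublings")
        return(res)
      }
      bound <- bound * 2L
      warning("truncation exit at t = ", signif(res$exit_time, 4),
              "; doubling bound to ", bound)
      pair <- propensity_pair(pair$base, pair$modified,
                              pair$space$origin, bound = bound)
    }
  }
  scheme <- match.arg(scheme)
  A <- .as_cmp(A)
  if (!leq_A(A, x0, xb0)) stop("initial states are not ordered: x0 must be below xb0")
  if (verify == "auto") {
    verify <- if (scheme == "grouped") "grouped"
    else if (isTRUE(attr(A, "integer_entries")) &&
             all((unclass(A) %*% pair$vectors) %in% c(-1, 0, 1))) "boundary"
    else "general"
  }
  verified <- !identical(verify, "none")
  .verify_pair(pair, A, verify)
  lambda <- uniformization_rate(pair)
  ix <- state_index(pair$space, x0); iy <- state_index(pair$space, xb0)
  if (is.na(ix) || is.na(iy)) stop("initial state not in the enumerated space")
  AX <- .ax_table(A, pair$space)
  gs <- if (scheme == "grouped") group_structure(A, pair$vectors) else NULL
  set.seed(as.integer(seed))
  res <- .couple_core(pair, AX, lambda, ix, iy, t_max, grouped = gs,
                      store = TRUE)
  if (verified && !res$order_ok)
    stop("internal error: order violated although conditions were verified")
  structure(list(
    x = list(times = c(0, res$jx_t),
             states = pair$space$states[c(state_index(pair$space, x0), res$jx_s),
                                        , drop = FALSE]),
    xb = list(times = c(0, res$jy_t),
              states = pair$space$states[c(state_index(pair$space, xb0), res$jy_s),
                                         , drop = FALSE]),
    order_ok = res$order_ok, exited = res$exited, exit_time = res$exit_time,
    n_events = res$n_events, thinned = res$thinned, lambda = lambda,
    t_max = t_max, seed = seed, scheme = scheme),
    class = "coupled_paths")
}

#' @export
print.coupled_paths <- function(x, ...) {
  cat("coupled pair of trajectories to t =", x$t_max,
      "(lambda =", format(x$lambda, digits = 4), ")\n")
  cat("  events:", x$n_events, "| accepted jumps:",
      length(x$x$times) - 1, "/", length(x$xb$times) - 1,
      "| order preserved:", x$order_ok, "\n")
  if (x$exited) cat("  exited truncation at t =", x$exit_time, "\n")
  invisible(x)
}

#' Ensemble of coupled pairs
#'
#' Runs `n_pairs` independent coupled simulations; the conditions are
#' verified once up front and each pair uses a seed derived from
#' (master seed, pair index), so the ensemble is reproducible and
#' independent of execution order.
#'
#' @inheritParams couple_paths
#' @param n_pairs number of independent coupled pairs.
#' @return A data.frame with one row per pair: `order_ok`, `exited`,
#'   `exit_time`, final state indices `ix`, `iy`, event counts. The
#'   uniformization rate is attached as attribute `lambda`.
#' @export
couple_ensemble <- function(pair, A, x0, xb0, t_max, n_pairs, seed,
                            scheme = c("ungrouped", "grouped"),
                            verify = "auto") {
  scheme <- match.arg(scheme)
  A <- .as_cmp(A)
  if (!leq_A(A, x0, xb0)) stop("initial states are not ordered")
  if (verify == "auto") {
    verify <- if (scheme == "grouped") "grouped"
    else if (isTRUE(attr(A, "integer_entries")) &&
             all((unclass(A) %*% pair$vectors) %in% c(-1, 0, 1))) "boundary"
    else "general"
  }
  .verify_pair(pair, A, verify)
  lambda <- uniformization_rate(pair)
  ix0 <- state_index(pair$space, x0); iy0 <- state_index(pair$space, xb0)
  AX <- .ax_table(A, pair$space)
  gs <- if (scheme == "grouped") group_structure(A, pair$vectors) else NULL
  out <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    set.seed(.derive_seed(seed, k))
    r <- .couple_core(pair, AX, lambda, ix0, iy0, t_max, grouped = gs,
                      store = FALSE)
    out[[k]] <- data.frame(pair = k, order_ok = r$order_ok,
                           exited = r$exited, exit_time = r$exit_time,
                           ix = r$ix, iy = r$iy, n_events = r$n_events)
  }
  res <- do.call(rbind, out)
  attr(res, "lambda") <- lambda
  res
}

#' Plain stochastic simulation (direct method)
#'
#' Reference simulator for a single chain: exponential holding times with
#' the total rate, jump direction drawn proportionally to the per-direction
#' rates. Serves as the independent marginal oracle for the coupled
#' simulator.
#'
#' @param network a [reaction_network()].
#' @param x0 initial state.
#' @param t_max horizon.
#' @param seed integer seed.
#' @param bound optional truncation level passed to [enumerate_states()].
#' @param space optional pre-enumerated space (must contain `x0`).
#' @return A `trajectory` object: `times`, `states` (matrix, one row per
#'   epoch starting at `x0`), right-continuous piecewise-constant path.
#' @export
ssa_path <- function(network, x0, t_max, seed, bound = NULL, space = NULL) {
  if (is.null(space)) space <- enumerate_states(network, x0, bound = bound)
  ts <- transition_structure(network)
  U <- .direction_rates(network, space, ts)
  tr <- .target_index(space, ts$vectors)
  ix <- state_index(space, x0)
  if (is.na(ix)) stop("x0 not in the state space")
  set.seed(as.integer(seed))
  t <- 0
  times <- 0
  path <- ix
  repeat {
    rates <- U[, ix]
    tot <- sum(rates)
    if (tot <= 0) break                      # absorbed
    t <- t + rexp(1, tot)
    if (t > t_max) break
    j <- sample.int(length(rates), 1L, prob = rates)
    ix <- tr[j, ix]
    times <- c(times, t)
    path <- c(path, ix)
  }
  structure(list(times = times,
                 states = space$states[path, , drop = FALSE],
                 space = space, t_max = t_max),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory with", length(x$times) - 1, "jumps on [0,", x$t_max, "]\n")
  invisible(x)
}
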