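#' Built-in worked example networks
#'
#' Factories for five networks commonly used to illustrate stochastic
#' ordering of reaction networks, each returned as an `example_bundle`: a
#' base/modified network pair (the modified network scales one
#' distinguished rate constant, by 2 unless overridden), the recommended
#' comparison matrix, canonical initial states, named target sets and the
#' sharpest applicable condition check.
#'
#' \describe{
#'   \item{`ek1`}{Closed Michaelis--Menten enzyme kinetics
#'     (S + E <-> SE -> P + E) on the compatibility class fixed by
#'     `S_tot`, `E_tot`. Distinguished constant: the catalytic rate
#'     `kappa[3]`. Targets `s` (all substrate) and `p` (all product).}
#'   \item{`ek2`}{Open enzyme kinetics with substrate exchange and
#'     reversible catalysis (six reactions); countably infinite state
#'     space, so analyses need a truncation bound. Distinguished constant:
#'     the inflow rate `kappa[5]`. Complex balanced, hence the product-form
#'     stationary law of [product_form_pi()].}
#'   \item{`braess`}{A four-species relay network with two routes from S1
#'     to S4 and a cross-link reaction (rate `kappa[5]`) reminiscent of
#'     Braess' paradox. With `kappa[2] == kappa[4]` the grouped boundary
#'     conditions hold for any change of `kappa[5]`, so the time to fully
#'     convert S1 into S4 is insensitive to the cross-link.}
#'   \item{`chromatin`}{Reduced two-species histone modification circuit
#'     (repressed and active nucleosome counts, total budget `D_tot`),
#'     with occupancy-limited non-mass-action kinetics. Distinguished
#'     constant: the asymmetry `mu` multiplying the erasure rate of the
#'     repressive modification. Targets `a` (fully active, maximal) and
#'     `r` (fully repressed, minimal).}
#'   \item{`chromatin_tf`}{The same circuit extended by an expressed
#'     protein enabling positive autoregulation through a bounded
#'     increasing function of the protein count (a Hill function with
#'     parameters `K`, `h`). Distinguished constant: the protein
#'     production rate `k5a`. Target `Theta` (fully active nucleosomes,
#'     any protein count); the protein coordinate is unbounded, so a
#'     truncation bound is required.}
#' }
#'
#' @param name one of `"ek1"`, `"ek2"`, `"braess"`, `"chromatin"`,
#'   `"chromatin_tf"`.
#' @param S_tot,E_tot,D_tot totals fixing the compatibility class.
#' @param kappa rate constants of the base network (length 3, 6 or 5 for
#'   the mass-action examples).
#' @param scale factor applied to the distinguished constant in the
#'   modified network (default 2).
#' @param mu,params chromatin parameters (see Details in the source);
#'   `params` overrides individual named constants.
#' @param K,h Hill parameters of the autoregulation function.
#' @param bound suggested truncation level recorded in the bundle (used by
#'   downstream calls for the infinite-state examples).
#' @return An `example_bundle` list: `base`, `modified`, `A`, `origin`,
#'   `states` (named canonical states), `targets` (named state vectors or
#'   predicate functions over the state matrix), `theorem`, `bound`.
#' @export
make_example <- function(name = c("ek1", "ek2", "braess", "chromatin",
                                  "chromatin_tf"),
                         S_tot = 3L, E_tot = 2L, D_tot = 3L,
                         kappa = NULL, scale = 2, mu = 1,
                         params = list(), K = 10, h = 2, bound = NULL) {
  name <- match.arg(name)
  switch(name,
    ek1 = .example_ek1(S_tot, E_tot, kappa %||% c(1, 1, 1), scale),
    ek2 = .example_ek2(E_tot, kappa %||% rep(1, 6), scale, bound %||% 30L),
    braess = .example_braess(S_tot, kappa %||% rep(1, 5), scale),
    chromatin = .example_chromatin(D_tot, mu, params, scale),
    chromatin_tf = .example_chromatin_tf(D_tot, mu, params, K, h, scale,
                                         bound %||% 20L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.bundle <- function(...) structure(list(...), class = "example_bundle")

#' @export
print.example_bundle <- function(x, ...) {
  cat("example bundle '", x$name, "': ", x$base$d, " species, ",
      length(x$base$reactions), " reactions; check: ", x$theorem, "\n",
      sep = "")
  invisible(x)
}

.example_ek1 <- function(S_tot, E_tot, kappa, scale) {
  stopifnot(S_tot >= 1, E_tot >= 1, length(kappa) == 3, all(kappa > 0))
  build <- function(k) reaction_network(
    species = c("S", "P", "E", "SE"),
    reactions = list(
      reaction(c(S = 1, E = 1), c(SE = 1), mass_action(k[1])),
      reaction(c(SE = 1), c(S = 1, E = 1), mass_action(k[2])),
      reaction(c(SE = 1), c(P = 1, E = 1), mass_action(k[3]))))
  kb <- kappa; kb[3] <- kb[3] * scale
  s <- c(S_tot, 0, E_tot, 0)
  p <- c(0, S_tot, E_tot, 0)
  .bundle(name = "ek1", base = build(kappa), modified = build(kb),
          A = comparison_matrix(rbind(c(-1, 0, 0, 0), c(0, 1, 0, 0))),
          origin = s, bound = NULL,
          states = list(s = s, p = p),
          targets = list(p = p, s = s),
          theorem = "boundary")
}

.example_ek2 <- function(E_tot, kappa, scale, bound) {
  stopifnot(E_tot >= 1, length(kappa) == 6, all(kappa > 0))
  build <- function(k) reaction_network(
    species = c("S", "P", "E", "SE"),
    reactions = list(
      reaction(c(S = 1, E = 1), c(SE = 1), mass_action(k[1])),
      reaction(c(SE = 1), c(S = 1, E = 1), mass_action(k[2])),
      reaction(c(SE = 1), c(P = 1, E = 1), mass_action(k[3])),
      reaction(c(P = 1, E = 1), c(SE = 1), mass_action(k[4])),
      reaction(integer(0), c(S = 1), mass_action(k[5])),
      reaction(c(S = 1), integer(0), mass_action(k[6]))))
  kb <- kappa; kb[5] <- kb[5] * scale
  z <- c(0, 0, E_tot, 0)
  .bundle(name = "ek2", base = build(kappa), modified = build(kb),
          A = comparison_matrix(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                                      c(0, 0, -1, 0))),
          origin = z, bound = bound,
          states = list(z = z),
          targets = list(),
          theorem = "boundary")
}

.example_braess <- function(S_tot, kappa, scale) {
  stopifnot(S_tot >= 1, length(kappa) == 5, all(kappa >= 0), all(kappa[1:4] > 0))
  build <- function(k) reaction_network(
    species = c("S1", "S2", "S3", "S4"),
    reactions = list(
      reaction(c(S1 = 1), c(S2 = 1), mass_action(k[1])),
      reaction(c(S2 = 1), c(S4 = 1), mass_action(k[2])),
      reaction(c(S1 = 1), c(S3 = 1), mass_action(k[3])),
      reaction(c(S3 = 1), c(S4 = 1), mass_action(k[4])),
      reaction(c(S2 = 1), c(S3 = 1), mass_action(k[5]))))
  kb <- kappa; kb[5] <- kb[5] * scale
  start <- c(S_tot, 0, 0, 0)
  finish <- c(0, 0, 0, S_tot)
  .bundle(name = "braess", base = build(kappa), modified = build(kb),
          A = comparison_matrix(rbind(c(-1, 0, 0, 0), c(0, -1, -1, 0))),
          origin = start, bound = NULL,
          states = list(start = start, finish = finish),
          targets = list(finish = finish),
          theorem = "grouped")
}

.chromatin_params <- function(mu, params) {
  p <- list(k1a = 1, k1b = 1, k2a = 1, k2b = 1, k3a = 1, k3b = 1, cc = 1,
            mu = mu)
  p[names(params)] <- params
  if (p$mu <= 0 || p$cc <= 0) stop("chromatin asymmetry parameters must be positive")
  p
}

.example_chromatin <- function(D_tot, mu, params, scale) {
  stopifnot(D_tot >= 1)
  pars <- .chromatin_params(mu, params)
  build <- function(p) reaction_network(
    species = c("DR", "DA"),
    reactions = list(
      reaction(integer(0), c(DA = 1),
               rate_expression("(Dtot - (x1 + x2)) * (k1a + k1b * x2)")),
      reaction(integer(0), c(DR = 1),
               rate_expression("(Dtot - (x1 + x2)) * (k2a + k2b * x1)")),
      reaction(c(DA = 1), integer(0),
               rate_expression("x2 * (k3a + k3b * x1)")),
      reaction(c(DR = 1), integer(0),
               rate_expression("x1 * mu * (cc * k3a + k3b * x2)"))),
    parameters = c(Dtot = D_tot, unlist(p)))
  parsb <- pars; parsb$mu <- parsb$mu * scale
  r <- c(D_tot, 0)
  a <- c(0, D_tot)
  .bundle(name = "chromatin", base = build(pars), modified = build(parsb),
          A = comparison_matrix(rbind(c(-1, 0), c(0, 1))),
          origin = r, bound = NULL,
          states = list(r = r, a = a),
          targets = list(a = a, r = r),
          theorem = "boundary")
}

.example_chromatin_tf <- function(D_tot, mu, params, K, h, scale, bound) {
  stopifnot(D_tot >= 1, K > 0, h >= 1)
  pars <- .chromatin_params(mu, params)
  extra <- list(k1a0 = 1, k1a1 = 1, k5a = 1, k6a = 1)
  extra[names(params)[names(params) %in% names(extra)]] <-
    params[names(params) %in% names(extra)]
  build <- function(p, e) reaction_network(
    species = c("DR", "DA", "P"),
    reactions = list(
      reaction(integer(0), c(DA = 1),
               rate_expression(
                 "(Dtot - (x1 + x2)) * (k1a0 + k1a1 * hill(x3, K, h) + k1b * x2)")),
      reaction(integer(0), c(DR = 1),
               rate_expression("(Dtot - (x1 + x2)) * (k2a + k2b * x1)")),
      reaction(c(DA = 1), integer(0),
               rate_expression("x2 * (k3a + k3b * x1)")),
      reaction(c(DR = 1), integer(0),
               rate_expression("x1 * mu * (cc * k3a + k3b * x2)")),
      reaction(c(DA = 1), c(DA = 1, P = 1), mass_action(e$k5a)),
      reaction(c(P = 1), integer(0), mass_action(e$k6a))),
    parameters = c(Dtot = D_tot, unlist(p), k1a0 = e$k1a0, k1a1 = e$k1a1,
                   K = K, h = h))
  extrab <- extra; extrab$k5a <- extrab$k5a * scale
  r <- c(D_tot, 0, 0)
  .bundle(name = "chromatin_tf", base = build(pars, extra),
          modified = build(pars, extrab),
          A = comparison_matrix(diag(c(-1, 1, 1))),
          origin = r, bound = bound,
          states = list(r = r),
          targets = list(Theta = function(states) states[, 2] == D_tot),
          theorem = "boundary")
}

#' Resolve a bundle target to state indices
#'
#' @param target an element of an `example_bundle`'s `targets`: either a
#'   state vector or a predicate function over the state matrix.
#' @param space the enumerated space.
#' @export
target_indices <- function(target, space) {
  if (is.function(target)) which(target(space$states))
  else {
    i <- state_index(space, target)
    if (is.na(i)) stop("target state not in the space")
    i
  }
}

#' Random desk-scale comparable network pair
#'
#' Deterministic-in-seed generator of small mass-action network pairs on a
#' bounded box (a proper finite chain: rates leaving the box are zero),
#' with perturbed rate constants and a random integer comparison matrix
#' whose entries and images \eqn{A v_j} lie in \{-1, 0, 1\}. Used for
#' property-based validation of the condition checkers against the
#' brute-force oracle. Draws that fail the structural constraints are
#' rejected; an exhausted rejection budget restarts from the incremented
#' seed (recorded in the `seed_used` field).
#'
#' @param seed integer seed.
#' @param d_max,n_max,state_cap caps on species count, reaction count and
#'   enumerated states.
#' @return List: `base`, `modified`, `A`, `origin`, `bound`, `pair` (a
#'   compiled [propensity_pair()] with box truncation), `seed_used`.
#' @export
random_network <- function(seed, d_max = 3L, n_max = 6L, state_cap = 14L) {
  stopifnot(d_max <= 3L, n_max <= 6L, state_cap <= 14L)
  for (s in seed + 0:24) {
    out <- .try_random_network(s, d_max, n_max, state_cap)
    if (!is.null(out)) { out$seed_used <- s; return(out) }
  }
  stop("rejection budget exhausted for random_network")
}

.try_random_network <- function(seed, d_max, n_max, state_cap) {
  set.seed(seed)
  for (attempt in 1:40) {
    d <- sample.int(d_max, 1)
    nr <- sample.int(min(n_max, 4L), 1) + (d > 1)
    sp <- paste0("Z", seq_len(d))
    rxs <- list()
    ok <- TRUE
    for (r in seq_len(nr)) {
      for (try2 in 1:20) {
        vm <- sample(0:1, d, replace = TRUE)
        vp <- sample(0:1, d, replace = TRUE)
        if (!all(vm == vp)) break
      }
      if (all(vm == vp)) { ok <- FALSE; break }
      rxs[[r]] <- list(vm = vm, vp = vp)
    }
    if (!ok) next
    used <- Reduce(`|`, lapply(rxs, function(r) r$vm > 0 | r$vp > 0))
    if (!all(used)) next
    k <- round(runif(nr, 0.2, 2), 3)
    kb <- k
    tweak <- runif(nr) < 0.6
    kb[tweak] <- round(kb[tweak] * runif(sum(tweak), 0.5, 2), 3)
    mk <- function(kv) reaction_network(sp, lapply(seq_len(nr), function(r)
      reaction(setNames(rxs[[r]]$vm, sp)[rxs[[r]]$vm > 0],
               setNames(rxs[[r]]$vp, sp)[rxs[[r]]$vp > 0],
               mass_action(kv[r]))))
    base <- mk(k); modified <- mk(kb)
    origin <- sample(0:1, d, replace = TRUE)
    bound <- if (d == 1) sample(2:4, 1) else 1L + (d < 3)
    pair <- tryCatch(
      propensity_pair(base, modified, origin, bound = bound,
                      truncation = "box", cap = 4096L),
      error = function(e) NULL)
    if (is.null(pair) || nrow(pair$space$states) > state_cap ||
        nrow(pair$space$states) < 2) next
    V <- pair$vectors
    A <- NULL
    for (try3 in 1:60) {
      m <- sample.int(2L, 1)
      cand <- matrix(sample(-1:1, m * d, replace = TRUE), m, d)
      if (any(rowSums(abs(cand)) == 0)) next
      if (all((cand %*% V) %in% c(-1, 0, 1))) { A <- cand; break }
    }
    if (is.null(A)) next
    return(list(base = base, modified = modified,
                A = comparison_matrix(A), origin = origin, bound = bound,
                pair = pair))
  }
  NULL
}
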