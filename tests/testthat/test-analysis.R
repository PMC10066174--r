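test_that("stationary laws solve the balance equations", {
  # two-state chain: closed form pi = (b, a) / (a + b)
  bd <- birth_death(a = 2, b = 3)          # rates 2 up, 3x down
  sp <- enumerate_states(bd, 0L, bound = 1)
  st <- stationary(build_generator(bd, sp))
  expect_equal(st$pi, c(3, 2) / 5)
  expect_equal(sum(st$pi), 1, tolerance = 1e-10)
  expect_true(all(st$pi >= 0))
  # chromatin circuit: residual of the balance equations is tiny
  ch <- make_example("chromatin")
  g <- build_generator(ch$base, enumerate_states(ch$base, ch$origin))
  stc <- stationary(g)
  expect_lt(max(abs(as.numeric(stc$pi %*% g$Q))), 1e-10)
  # reducible chain (absorbing product state) is refused with a diagnosis
  ex <- make_example("ek1")
  ge <- build_generator(ex$base, enumerate_states(ex$base, ex$origin))
  expect_error(stationary(ge), "reducible")
})

test_that("the product-form law matches the truncated solve and its marginals", {
  pf <- product_form_pi(rep(1, 6), E_tot = 2, bound = 25)
  expect_equal(unname(pf$c), c(1, 1, 0.5, 0.5))
  # complementary occupancy fractions for any rate constants
  k <- c(2, 0.5, 3, 1, 0.7, 1.3)
  pf2 <- product_form_pi(k, E_tot = 3, bound = 20)
  expect_equal(pf2$c[3] + pf2$c[4], 1)
  # enzyme-complex marginal is binomial(E_tot, c4)
  x4 <- pf2$space$states[, 4]
  marg <- vapply(0:3, function(v) sum(pf2$pi[x4 == v]), numeric(1))
  expect_equal(marg, dbinom(0:3, 3, pf2$c[4]), tolerance = 1e-10)
  # the generator solve agrees with the renormalized product form at every
  # truncation level (the restricted chain inherits the product-form law,
  # so the agreement is at solver precision rather than merely improving
  # with the bound)
  ek2 <- make_example("ek2")
  sup_err <- vapply(c(8, 12, 16), function(M) {
    sp <- enumerate_states(ek2$base, ek2$origin, bound = M)
    st <- stationary(build_generator(ek2$base, sp))
    max(abs(st$pi - product_form_pi(rep(1, 6), 2, M)$pi))
  }, numeric(1))
  expect_true(all(sup_err < 1e-10))
  # the self-checking wrapper accepts a bound with negligible boundary mass
  st <- stationary_truncated(ek2$base, ek2$origin, bound = 16)
  expect_lt(st$boundary_mass, 1e-8)
})

test_that("mean first passage times solve the restricted system", {
  # irreversible conversion: exponential mean 1/kappa
  net <- conversion(kappa = 4)
  g <- build_generator(net, enumerate_states(net, c(1L, 0L)))
  tgt <- state_index(g$space, c(0L, 1L))
  h <- mfpt(g, tgt)
  expect_equal(h[state_index(g$space, c(1L, 0L))], 1 / 4)
  expect_equal(h[tgt], 0)
  # target = whole space: identically zero
  expect_true(all(mfpt(g, seq_len(2)) == 0))
  # unreachable target: +Inf, not a solver failure
  h2 <- mfpt(g, state_index(g$space, c(1L, 0L)))
  expect_identical(h2[state_index(g$space, c(0L, 1L))], Inf)
})

test_that("mean first passage agrees with the integral of the survival function", {
  ch <- make_example("chromatin", D_tot = 2)
  pair <- propensity_pair(ch$base, ch$modified, ch$origin)
  g <- build_generator(ch$base, pair$space)
  tgt <- target_indices(ch$targets$a, g$space)
  m <- mfpt(g, tgt)[state_index(g$space, ch$states$r)]
  Qa <- g$Q
  Qa[tgt, ] <- 0
  i0 <- state_index(g$space, ch$states$r)
  surv <- function(t) vapply(t, function(ti)
    1 - sum(scrncmp:::.transient_distribution(Qa, i0, ti)[tgt]), numeric(1))
  quad <- stats::integrate(surv, 0, Inf, rel.tol = 1e-9)$value
  expect_equal(quad, m, tolerance = 1e-6)
})

test_that("transient probabilities interpolate the degenerate and ergodic limits", {
  ch <- make_example("chromatin")
  sp <- enumerate_states(ch$base, ch$origin)
  g <- build_generator(ch$base, sp)
  tgt <- target_indices(ch$targets$a, sp)
  expect_identical(transient_prob(g, ch$states$a, 0, tgt), 1)
  expect_identical(transient_prob(g, ch$states$r, 0, tgt), 0)
  st <- stationary(g)
  expect_equal(transient_prob(g, ch$states$r, 300, tgt), sum(st$pi[tgt]),
               tolerance = 1e-9)
})

test_that("hitting-time dominance holds exactly where the theory predicts", {
  # larger catalysis rate converts substrate faster: survival and mean both
  # dominated for the increasing target {p}
  ex <- make_example("ek1")
  pair <- propensity_pair(ex$base, ex$modified, ex$origin)
  hd <- hitting_dominance(pair, ex$A, target_indices(ex$targets$p, pair$space),
                          list(x0 = ex$states$s, xb0 = ex$states$s),
                          t_grid = c(0.5, 1, 2, 5, 10))
  expect_true(hd$dominated)
  expect_identical(hd$direction, "increasing")
  expect_lt(hd$mean_modified, hd$mean_base)
  # identical chains and starts: the two laws coincide
  pid <- propensity_pair(ex$base, ex$base, ex$origin)
  hd0 <- hitting_dominance(pid, ex$A, target_indices(ex$targets$p, pid$space),
                           list(x0 = ex$states$s, xb0 = ex$states$s),
                           t_grid = c(0.5, 1, 2))
  expect_equal(hd0$survival_base, hd0$survival_modified, tolerance = 1e-12)
  expect_equal(hd0$mean_base, hd0$mean_modified, tolerance = 1e-12)
  # a target that is neither increasing nor decreasing is refused
  mid <- state_index(pair$space, c(2, 0, 1, 1))
  expect_error(hitting_dominance(pair, ex$A, mid,
                                 list(x0 = ex$states$s, xb0 = ex$states$s),
                                 c(1, 2)),
               "neither increasing nor decreasing")
  # chromatin memory loss: repressed-mark erasure asymmetry shortens the
  # climb to the active state and lengthens the fall back
  ch <- make_example("chromatin")
  pc <- propensity_pair(ch$base, ch$modified, ch$origin)
  up <- hitting_dominance(pc, ch$A, target_indices(ch$targets$a, pc$space),
                          list(x0 = ch$states$r, xb0 = ch$states$r), c(1, 5))
  expect_true(up$dominated)
  down <- hitting_dominance(pc, ch$A, target_indices(ch$targets$r, pc$space),
                            list(x0 = ch$states$a, xb0 = ch$states$a), c(1, 5))
  expect_identical(down$direction, "decreasing")
  expect_true(down$dominated)
})

test_that("transient dominance holds for every increasing set on a verified pair", {
  ch <- make_example("chromatin", D_tot = 2)
  pair <- propensity_pair(ch$base, ch$modified, ch$origin)
  expect_true(check_boundary(pair, ch$A)$pass)
  g <- build_generator(ch$base, pair$space)
  gb <- build_generator(ch$modified, pair$space)
  sp <- g$space
  N <- nrow(sp$states)
  gammas <- enumerate_increasing_sets(ch$A, sp)
  ok <- TRUE
  for (t in c(0.1, 1, 10)) {
    P  <- t(vapply(seq_len(N), function(i)
      scrncmp:::.transient_distribution(g$Q, i, t), numeric(N)))
    Pb <- t(vapply(seq_len(N), function(i)
      scrncmp:::.transient_distribution(gb$Q, i, t), numeric(N)))
    for (gam in gammas) {
      if (!length(gam)) next
      pG  <- rowSums(P[, gam, drop = FALSE])
      pGb <- rowSums(Pb[, gam, drop = FALSE])
      for (i in seq_len(N)) for (j in seq_len(N)) {
        if (leq_A(ch$A, sp$states[i, ], sp$states[j, ]) &&
            pG[i] > pGb[j] + 1e-9) ok <- FALSE
      }
    }
  }
  expect_true(ok)
})

test_that("the relay conversion time is insensitive to the cross-link", {
  ms <- vapply(c(0, 1, 5), function(k5) {
    b <- make_example("braess", S_tot = 3, kappa = c(1, 2, 1, 2, k5))
    s <- enumerate_states(b$base, b$origin)
    g <- build_generator(b$base, s)
    mfpt(g, target_indices(b$targets$finish, s))[state_index(s, b$states$start)]
  }, numeric(1))
  expect_lt(diff(range(ms)) / ms[1], 1e-8)
})
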