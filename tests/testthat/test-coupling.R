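test_that("the uniformization rate strictly dominates n times the total rate", {
  ex <- make_example("ek1", S_tot = 3, E_tot = 2, kappa = c(1, 1, 1), scale = 1)
  pair <- propensity_pair(ex$base, ex$modified, ex$origin)
  lam <- uniformization_rate(pair)
  expect_gt(lam, 3 * 6)            # sup of the total rate is 6, n = 3
  expect_lt(max(pair$U) / lam, 1 / pair$n)
  expect_lt(max(pair$Ub) / lam, 1 / pair$n)
  # unbounded space: enumeration refuses without a truncation level
  ek2 <- make_example("ek2")
  expect_error(propensity_pair(ek2$base, ek2$modified, ek2$origin, cap = 2000L),
               "bound")
})

test_that("the acceptance map places jumps by half-open intervals", {
  bd <- birth_death(a = 1, b = 1)
  pair <- propensity_pair(bd, bd, 0L, bound = 5, truncation = "box")
  # state 2: birth rate 1, death rate 2; choose lambda = 10 so the
  # acceptance widths are 0.1 and 0.2 inside blocks [0,.5) and [.5,1)
  x <- 2L
  pm <- function(u) unname(phi_map(pair, x, u, lambda = 10))
  expect_equal(pm(0.05), 3L)
  expect_equal(pm(0.09999), 3L)
  expect_equal(pm(0.1), 2L)        # right-open end of the birth interval
  expect_equal(pm(0.2), 2L)
  expect_equal(pm(0.5), 1L)
  expect_equal(pm(0.69), 1L)
  expect_equal(pm(0.72), 2L)       # past the death interval
  expect_equal(pm(1), 2L)          # u = 1 self-loops by convention
  # all rates zero: the map is the identity for every draw
  absorbed <- conversion()
  pa <- propensity_pair(absorbed, absorbed, c(0L, 1L))
  for (u in seq(0, 1, by = 0.25))
    expect_equal(unname(phi_map(pa, c(0L, 1L), u)), c(0L, 1L))
})

test_that("interval lengths reproduce the uniformized skeleton kernel", {
  # deterministic check of the one-step law: the measure of draws sending
  # x to x + v_j equals Upsilon_j(x) / lambda, i.e. the (1/lambda) Q + I row
  ex <- make_example("ek1")
  pair <- propensity_pair(ex$base, ex$modified, ex$origin)
  lam <- uniformization_rate(pair)
  x <- c(2, 0, 1, 1)
  ix <- state_index(pair$space, x)
  us <- seq(0, 1 - 1e-6, length.out = 20001)
  du <- us[2] - us[1]
  moves <- vapply(us, function(u) {
    y <- phi_map(pair, x, u, lambda = lam)
    paste(y, collapse = ",")
  }, character(1))
  emp <- table(moves) * du
  for (j in seq_len(pair$n)) {
    tgt <- pair$space$states[pair$target[j, ix], ]
    key <- paste(tgt, collapse = ",")
    p_exact <- pair$U[j, ix] / lam
    p_emp <- if (key %in% names(emp)) emp[[key]] else 0
    expect_lt(abs(p_emp - p_exact), 2 * du)
  }
})

test_that("the grouped map coincides with the per-direction map for singletons", {
  ex <- make_example("ek1")
  pair <- propensity_pair(ex$base, ex$modified, ex$origin)
  lam <- uniformization_rate(pair)
  set.seed(13)
  for (rep in 1:60) {
    i <- sample(nrow(pair$space$states), 1)
    u <- runif(1)
    x <- pair$space$states[i, ]
    expect_identical(psi_map(pair, ex$A, x, u, lambda = lam),
                     phi_map(pair, x, u, lambda = lam))
  }
})

test_that("the one-step maps are monotone under the verified conditions", {
  # per-direction map on the enzyme pair (pointwise conditions hold)
  ex <- make_example("ek1")
  pair <- propensity_pair(ex$base, ex$modified, ex$origin)
  lam <- uniformization_rate(pair)
  sp <- pair$space
  us <- seq(0, 1, length.out = 401)
  ok <- TRUE
  for (i in seq_len(nrow(sp$states))) for (j in seq_len(nrow(sp$states))) {
    if (!leq_A(ex$A, sp$states[i, ], sp$states[j, ])) next
    for (u in us) {
      xn <- phi_map(pair, sp$states[i, ], u, lambda = lam, network = "base")
      yn <- phi_map(pair, sp$states[j, ], u, lambda = lam, network = "modified")
      if (!leq_A(ex$A, xn, yn)) ok <- FALSE
    }
  }
  expect_true(ok)
  # grouped map on the relay pair (grouped conditions hold, pointwise fail)
  br <- make_example("braess", S_tot = 2)
  pb <- propensity_pair(br$base, br$modified, br$origin)
  lamb <- uniformization_rate(pb)
  spb <- pb$space
  usb <- seq(0, 1, length.out = 201)
  okb <- TRUE
  for (i in seq_len(nrow(spb$states))) for (j in seq_len(nrow(spb$states))) {
    if (!leq_A(br$A, spb$states[i, ], spb$states[j, ])) next
    for (u in usb) {
      xn <- psi_map(pb, br$A, spb$states[i, ], u, lambda = lamb, network = "base")
      yn <- psi_map(pb, br$A, spb$states[j, ], u, lambda = lamb, network = "modified")
      if (!leq_A(br$A, xn, yn)) okb <- FALSE
    }
  }
  expect_true(okb)
})

test_that("coupled simulation is deterministic in the seed and order-preserving", {
  ex <- make_example("ek1")
  pair <- propensity_pair(ex$base, ex$modified, ex$origin)
  a <- couple_paths(pair, ex$A, ex$states$s, ex$states$s, t_max = 10, seed = 99)
  b <- couple_paths(pair, ex$A, ex$states$s, ex$states$s, t_max = 10, seed = 99)
  expect_identical(a, b)
  expect_true(a$order_ok)
  # identical dynamics and starts consume identical randomness
  pid <- propensity_pair(ex$base, ex$base, ex$origin)
  cpi <- couple_paths(pid, ex$A, ex$states$s, ex$states$s, t_max = 5, seed = 3)
  expect_identical(cpi$x, cpi$xb)
  # ensembles never violate the order under verified conditions
  ens <- couple_ensemble(pair, ex$A, ex$states$s, ex$states$s, t_max = 10,
                         n_pairs = 60, seed = 17)
  expect_true(all(ens$order_ok))
  # refusing unordered starts and failed conditions
  expect_error(couple_paths(pair, ex$A, ex$states$p, ex$states$s, 1, 1),
               "not ordered")
  exn <- make_example("ek1", scale = 0.5)
  pn <- propensity_pair(exn$base, exn$modified, exn$origin)
  expect_error(couple_paths(pn, exn$A, exn$states$s, exn$states$s, 1, 1),
               "do not hold")
})

test_that("plain stochastic simulation matches closed forms", {
  # one irreversible conversion: hitting time is exponential(kappa)
  net <- conversion(kappa = 2)
  sp <- enumerate_states(net, c(1L, 0L))
  hits <- vapply(1:4000, function(k) {
    tr <- ssa_path(net, c(1L, 0L), t_max = 50, seed = 20000 + k, space = sp)
    if (length(tr$times) > 1) tr$times[2] else NA_real_
  }, numeric(1))
  hits <- hits[!is.na(hits)]
  se <- (1 / 2) / sqrt(length(hits))
  expect_lt(abs(mean(hits) - 1 / 2), 3 * se)
  # absorbed immediately when no reaction can fire
  tr0 <- ssa_path(net, c(0L, 1L), t_max = 5, seed = 1, space = sp)
  expect_identical(length(tr0$times), 1L)
  # embedded jump frequencies at a monitored state follow the rate ratios
  ex <- make_example("ek1")
  spe <- enumerate_states(ex$base, ex$origin)
  x <- c(2, 0, 1, 1)   # rates: binding 2, unbinding 1, catalysis 1
  firsts <- vapply(1:3000, function(k) {
    tr <- ssa_path(ex$base, x, t_max = 100, seed = 50000 + k, space = spe)
    paste(tr$states[2, ], collapse = ",")
  }, character(1))
  freq <- table(firsts) / length(firsts)
  expect_lt(abs(freq[["1,0,0,2"]] - 0.5), 3 * sqrt(0.25 / 3000))
  expect_lt(abs(freq[["3,0,2,0"]] - 0.25), 3 * sqrt(0.1875 / 3000))
  expect_lt(abs(freq[["2,1,2,0"]] - 0.25), 3 * sqrt(0.1875 / 3000))
})

test_that("truncated co-simulation freezes on exit and can auto-extend", {
  # a pure birth chain leaves a tight truncation almost surely
  bd <- birth_death(a = 30, b = 0.01)
  pair <- propensity_pair(bd, bd, 0L, bound = 3)
  cp <- couple_paths(pair, matrix(1, 1, 1), 0L, 0L, t_max = 5, seed = 8)
  expect_true(cp$exited)
  final <- cp$x$states[nrow(cp$x$states), ]
  expect_lte(final, 3 + 1)          # one-step collar, then frozen
  # with a short horizon a couple of doublings contain the trajectory
  ws <- capture_warnings(
    cpe <- couple_paths(pair, matrix(1, 1, 1), 0L, 0L, t_max = 0.2, seed = 8,
                        auto_extend = TRUE))
  expect_true(any(grepl("doubling", ws)))
  expect_false(cpe$exited)
})
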