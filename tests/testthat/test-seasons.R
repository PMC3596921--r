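test_that("bilinear interpolation reproduces corners, center and hand cases", {
  corners <- c(1, 2, 3, 4)  # dry-cold, dry-warm, wet-cold, wet-warm
  expect_identical(bilinear_interp(leaf_env(0, 0), corners), 1)
  expect_identical(bilinear_interp(leaf_env(1, 0), corners), 2)
  expect_identical(bilinear_interp(leaf_env(0, 1), corners), 3)
  expect_identical(bilinear_interp(leaf_env(1, 1), corners), 4)
  expect_equal(bilinear_interp(leaf_env(0.5, 0.5), corners), 2.5)
  # hand evaluation at temperature 0.25, humidness 0.75:
  # 0.75*0.25*1 + 0.25*0.25*2 + 0.75*0.75*3 + 0.75*0.25*4 = 2.75
  expect_equal(bilinear_interp(leaf_env(0.25, 0.75), corners), 2.75)
  expect_error(leaf_env(1.2, 0.5), "\\[0, 1\\]")
  expect_error(leaf_env(0.5, -0.1), "\\[0, 1\\]")
})

test_that("self-retention probability obeys the half-life law", {
  spec <- make_default_spec(3, seed = 5)
  env <- leaf_env(0.3, 0.7)
  expect_identical(p_stay(env, 0, 1, spec), 1)
  tau <- bilinear_interp(env, spec$tau_corners[2, ])
  expect_equal(p_stay(env, tau, 2, spec), 0.5, tolerance = 1e-12)
  expect_error(p_stay(env, -1, 1, spec), "non-negative")

  # tau = 10, t = 5 gives 2^(-1/2)
  spec10 <- senescence_spec(c("a", "b"),
                            tau_corners = matrix(10, 2, 4),
                            X_corners = {
                              X <- array(0, c(2, 2, 4)); X[1, 2, ] <- 1; X
                            },
                            absorbing = "b")
  expect_equal(p_stay(leaf_env(0.5, 0.5), 5, 1, spec10), 2^-0.5,
               tolerance = 1e-12)

  # property: half-life identity, monotone decay, exponential semigroup
  for (k in 1:200) {
    u <- leafcycle:::hash_uniform(99, k, 1:7)
    env <- leaf_env(u[1], u[2])
    spec_k <- senescence_spec(
      c("s0", "s1"),
      tau_corners = matrix(5 + 55 * u[3:6], 2, 4, byrow = TRUE)[c(1, 1), ],
      X_corners = {
        X <- array(0, c(2, 2, 4)); X[1, 2, ] <- 1; X
      },
      absorbing = "s1")
    tau <- bilinear_interp(env, spec_k$tau_corners[1, ])
    expect_equal(p_stay(env, tau, 1, spec_k), 0.5, tolerance = 1e-12)
    t1 <- 20 * u[7]
    expect_lt(p_stay(env, t1 + 1, 1, spec_k), p_stay(env, t1, 1, spec_k))
    expect_equal(p_stay(env, t1 + tau, 1, spec_k),
                 p_stay(env, t1, 1, spec_k) * p_stay(env, tau, 1, spec_k),
                 tolerance = 1e-12)
  }
})

test_that("transition matrices are row-stochastic with the prescribed split", {
  # worked case: P_ii = 0.6 with two successors at renormalized weight 0.5
  spec <- senescence_spec(
    c("green", "yellow", "red"),
    tau_corners = matrix(10, 3, 4),
    X_corners = {
      X <- array(0, c(3, 3, 4))
      X[1, 2, ] <- 0.5
      X[1, 3, ] <- 0.5
      X[2, 3, ] <- 1
      X
    },
    absorbing = "red")
  env <- leaf_env(0.5, 0.5)
  t6 <- 10 * log(1 / 0.6) / log(2)  # p_stay = 0.6 exactly at this t
  P <- transition_matrix(env, t6, spec)
  expect_equal(P[1, 1], 0.6, tolerance = 1e-12)
  expect_equal(P[1, 2], 0.2, tolerance = 1e-12)
  expect_equal(P[1, 3], 0.2, tolerance = 1e-12)
  expect_equal(unname(P[3, ]), c(0, 0, 1))  # absorbing row

  # t = 0 gives the identity
  expect_equal(unname(transition_matrix(env, 0, spec)), diag(3))

  # random specs/environments: rows sum to one
  for (k in 1:50) {
    u <- leafcycle:::hash_uniform(7, k, 1:3)
    spec_k <- make_default_spec(2 + (k %% 4), seed = k)
    P <- transition_matrix(leaf_env(u[1], u[2]), 30 * u[3], spec_k)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0))
  }

  # a non-absorbing state that can never be left is a specification error
  expect_error(
    senescence_spec(c("a", "b"), matrix(10, 2, 4),
                    array(0, c(2, 2, 4)), absorbing = "b"),
    "must be able to leave")
})

test_that("population evolution is seeded, Markovian and matches the
           analytic chain", {
  spec <- make_default_spec(3, seed = 1)
  env <- leaf_env(0.5, 0.5)
  sched <- replicate(5, list(env = env, duration = 10), simplify = FALSE)

  # single-state spec: the population cannot move
  one <- senescence_spec("only", matrix(10, 1, 4), array(0, c(1, 1, 4)),
                         absorbing = "only")
  pop1 <- evolve_population(leaf_population(100), sched, one, seed = 3)
  expect_true(all(pop1$history == 100))

  # determinism: identical seeds give bit-identical histories
  a <- evolve_population(leaf_population(2000), sched, spec, seed = 11)
  b <- evolve_population(leaf_population(2000), sched, spec, seed = 11)
  expect_identical(a$history, b$history)
  c <- evolve_population(leaf_population(2000), sched, spec, seed = 12)
  expect_false(identical(a$history, c$history))

  # counts conserve the population each epoch
  expect_true(all(rowSums(a$history) == 2000))

  # Monte Carlo fractions track the matrix-power prediction (3 sigma)
  pop <- evolve_population(leaf_population(10000), sched, spec, seed = 1)
  P <- transition_matrix(env, 10, spec)
  d <- c(1, 0, 0)
  for (ep in 1:5) {
    d <- as.vector(d %*% P)
    emp <- pop$history[ep + 1, ] / 10000
    tol <- 3 * sqrt(pmax(d * (1 - d), 0) / 10000)
    expect_true(all(abs(emp - d) <= tol + 1e-12))
  }

  # absorption: the fallen fraction is non-decreasing and approaches one
  long <- replicate(60, list(env = env, duration = 10), simplify = FALSE)
  popl <- evolve_population(leaf_population(2000), long, spec, seed = 2)
  fallen <- popl$history[, 3]
  expect_true(all(diff(fallen) >= 0))
  expect_gt(fallen[61] / 2000, 0.99)
})
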