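# Core rate functions and the RK4 integrator.

test_that("sigmoid rate matches the closed form and its limits", {
  p <- list(r0 = 0.1, r1 = 70, g = 1, Vstar = 4)
  # midpoint
  expect_equal(sigmoid_rate(4, p), 0.1 + 35, tolerance = 1e-12)
  # limits
  expect_equal(sigmoid_rate(-1e4, p), 0.1, tolerance = 1e-9)
  expect_equal(sigmoid_rate(1e4, p), 70.1, tolerance = 1e-9)
  # V = V* + g against direct evaluation
  expect_equal(sigmoid_rate(5, p), 0.1 + 70 / (1 + exp(-1)),
               tolerance = 1e-12)
  # strictly increasing, bounded
  v <- seq(-30, 30, by = 0.5)
  r <- sigmoid_rate(v, p)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= p$r0 & r <= p$r0 + p$r1))
  expect_error(sigmoid_rate(NaN, p), "non-finite")
})

test_that("tonic/burst blend interpolates between the two sigmoids", {
  p <- list(RT = 70, VT = 4, gT = 1, RB = 250, VB = -2, gB = 0.5, L = 0.05)
  tonic <- function(V) 70 / (1 + exp(-(V - 4) / 1))
  burst <- function(V) 250 / (1 + exp(-(V + 2) / 0.5))
  # u = 0: pure tonic
  expect_equal(burst_tonic_rate(1.3, 0, p), tonic(1.3), tolerance = 1e-12)
  # u -> -inf: pure burst
  expect_equal(burst_tonic_rate(1.3, -1e4, p), burst(1.3),
               tolerance = 1e-9)
  # intermediate u: hand-computed weighted sum
  u <- -30; w <- exp(0.05 * u)
  expect_equal(burst_tonic_rate(-1, u, p),
               w * tonic(-1) + (1 - w) * burst(-1), tolerance = 1e-12)
  # positive u violates the burst-variable domain
  expect_error(burst_tonic_rate(0, 1, p), "u must be")
})

test_that("adapted strength is the decreasing sigmoid of c", {
  p <- list(J0 = 0.8, gc = 2, cstar = 10)
  expect_equal(adapted_strength(10, p), 0.4, tolerance = 1e-12)
  expect_equal(adapted_strength(-1e4, p), 0.8, tolerance = 1e-9)
  expect_equal(adapted_strength(10 + 3 * 2, p), 0.8 / (1 + exp(3)),
               tolerance = 1e-12)
  cc <- seq(0, 40, by = 0.5)
  expect_true(all(diff(adapted_strength(cc, p)) < 0))
  expect_true(all(adapted_strength(cc, p) > 0 &
                    adapted_strength(cc, p) < 0.8))
})

test_that("R and compiled derivatives agree on random states", {
  p <- model_params()
  set.seed(42)
  w <- somnet:::build_weights(p)
  for (i in 1:20) {
    s <- stats::setNames(stats::rnorm(17, 0, 3), somnet:::.state_names)
    s[c("u_e", "u_i")] <- -abs(s[c("u_e", "u_i")]) * 30
    s[c("c_CA3", "c_CA1", "c_CX", "c_CXp")] <-
      abs(s[c("c_CA3", "c_CA1", "c_CX", "c_CXp")])
    d_r <- model_derivatives(s, p)
    d_c <- somnet:::.model_deriv_cpp(as.numeric(s), w)
    expect_equal(unname(d_r), unname(d_c), tolerance = 1e-12)
  }
})

test_that("derivatives error when a pathway constant is missing", {
  p <- model_params()
  p$J.ee.CA3 <- NULL
  s <- stats::setNames(numeric(17), somnet:::.state_names)
  expect_error(model_derivatives(s, p), "J.ee.CA3")
})

test_that("uncoupled leak configuration decays exactly and a zero state is a fixed point", {
  p <- model_params()
  for (k in grep("^(J|I|dc)\\.", names(p), value = TRUE)) p[[k]] <- 0
  p$f.max.MD <- 0; p$f.max.TRN <- 0
  p$b.MD <- 0; p$b.TRN <- 0
  s0 <- stats::setNames(numeric(17), somnet:::.state_names)
  d <- model_derivatives(s0, p)
  expect_true(all(abs(d) < 1e-12))
  # pure-leak decay: V(t) = V0 exp(-t/tau), RK4 relative error < 1e-6
  # over 100 steps at dt/tau = 0.1
  s0["Ve_CX"] <- 5
  tr <- simulate_network(p, duration = 0.1, dt = 1e-3, burn_in = 0,
                         init = s0, seed = NULL)
  tau <- p$tau.e.CX
  expect_equal(p$tau.e.CX, 0.03) # shipped value; dt/tau ~ 0.03
  v_num <- tr$states[, "Ve_CX"]
  v_ref <- 5 * exp(-tr$time / tau)
  expect_lt(max(abs(v_num - v_ref) / v_ref), 1e-6)
})

test_that("integration is deterministic for identical inputs", {
  p <- model_params()
  a <- simulate_network(p, duration = 22, burn_in = 20, seed = 7)
  b <- simulate_network(p, duration = 22, burn_in = 20, seed = 7)
  expect_identical(a$states, b$states)
  # and with the optional noise, the same seed reproduces bit-identically
  a2 <- simulate_network(p, duration = 21, burn_in = 20, seed = 3,
                         noise_sd = 1)
  b2 <- simulate_network(p, duration = 21, burn_in = 20, seed = 3,
                         noise_sd = 1)
  expect_identical(a2$states, b2$states)
})

test_that("halving the step shows fourth-order convergence on a smooth nonlinear system", {
  # nonlinear configuration with the burst switch disabled (b = 0)
  # so the vector field is smooth over the horizon
  p <- model_params(b.MD = 0, b.TRN = 0)
  s0 <- initial_state(seed = 5, sd = 0.5)
  run <- function(dt) {
    tr <- simulate_network(p, duration = 1, dt = dt, burn_in = 0,
                           init = s0, seed = NULL)
    tr$states[nrow(tr$states), c("Ve_CX", "Vi_CX", "c_CX")]
  }
  e1 <- run(2e-3); e2 <- run(1e-3); e3 <- run(5e-4)
  # error(dt) ~ C dt^4: successive differences shrink ~16x
  d12 <- max(abs(e1 - e2)); d23 <- max(abs(e2 - e3))
  expect_gt(d12 / d23, 8)   # at least ~3rd order in practice
})

test_that("trace firing rates respect the sigmoid bounds", {
  p <- model_params()
  tr <- simulate_network(p, duration = 25, burn_in = 20, seed = 1)
  r <- trace_rates(tr)
  sig <- r[, c("re_CA3", "ri_CA3", "re_CA1", "ri_CA1", "re_CX", "ri_CX",
               "re_CXp", "ri_CXp", "r_REU")]
  expect_true(all(sig >= p$r0 - 1e-9))
  expect_true(all(sig <= p$r0 + p$r1 + 1e-9))
  expect_true(all(r[, c("r_MD", "r_TRN")] >= 0))
})

test_that("parameter file round trip preserves every constant", {
  p <- model_params()
  f <- tempfile(fileext = ".txt")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(unlist(q[names(p)]), unlist(p), tolerance = 1e-9)
  expect_error(model_params(not.a.parameter = 1), "unknown parameter")
})
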