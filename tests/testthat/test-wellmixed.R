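test_that("the four steady states match the closed forms", {
  ss <- steady_states(cdi_params(alpha = 2, beta = 1, c = 2))
  expect_equal(nrow(ss), 4)
  int <- ss[ss$name == "interior", ]
  expect_equal(c(int$u, int$v), c(0.5, 0.5))
  expect_true(int$feasible)

  # second substitution check
  ss2 <- steady_states(cdi_params(alpha = 3.5, beta = 1, c = 6))
  int2 <- ss2[ss2$name == "interior", ]
  expect_equal(c(int2$u, int2$v), c(1 - 2.5 / 6, 2.5 / 6), tolerance = 1e-12)

  # alpha = beta: interior coincides with the v-only boundary state
  ss3 <- steady_states(cdi_params(alpha = 1, beta = 1, c = 2))
  int3 <- ss3[ss3$name == "interior", ]
  expect_equal(c(int3$u, int3$v), c(1, 0))

  # c = 0: interior undefined, three states with a message
  expect_message(ss4 <- steady_states(cdi_params(alpha = 2, beta = 1, c = 0)))
  expect_equal(nrow(ss4), 3)
})

test_that("region labels partition the parameter plane", {
  expect_identical(wellmixed_region(2, 0.5), "u_always_wins")
  expect_identical(wellmixed_region(0.5, 2), "v_always_wins")
  expect_identical(wellmixed_region(2, 2), "bistable")
  expect_identical(wellmixed_region(c(1, 3), c(5, 2)),
                   c("boundary", "boundary"))
})

test_that("stability classification matches analytic eigenvalues", {
  # eigenvalues at (alpha, 0): -alpha and beta - alpha;
  # at (0, beta): -beta and alpha - beta (1 + c)
  p <- cdi_params(alpha = 2, beta = 1, c = 2)
  cs <- classify_stability(p)
  expect_identical(cs$region, "bistable")
  st <- cs$states
  uo <- st[st$name == "u_only", ]
  expect_equal(sort(c(uo$lambda1, uo$lambda2)), sort(c(-2, 1 - 2)))
  expect_identical(uo$stability, "stable")
  vo <- st[st$name == "v_only", ]
  expect_equal(sort(c(vo$lambda1, vo$lambda2)), sort(c(-1, 2 - 1 * 3)))
  expect_identical(vo$stability, "stable")
  expect_identical(st$stability[st$name == "interior"], "saddle")

  cs2 <- classify_stability(cdi_params(alpha = 2, beta = 1, c = 0.5))
  expect_identical(cs2$region, "u_always_wins")
  st2 <- cs2$states
  expect_identical(st2$stability[st2$name == "u_only"], "stable")
  expect_false(st2$stability[st2$name == "v_only"] == "stable")

  expect_identical(classify_stability(cdi_params(alpha = 0.5, beta = 1,
                                                 c = 2))$region,
                   "v_always_wins")
})

test_that("analytic Jacobian agrees with finite differences", {
  p <- cdi_params(alpha = 2.7, beta = 1.3, c = 1.9)
  for (pt in list(c(1, 1), c(0.3, 0.9), c(2.7, 0))) {
    J <- wellmixed_jacobian(pt[1], pt[2], p)
    h <- 1e-6
    fd <- matrix(0, 2, 2)
    f <- function(u, v) {
      d <- cdi_rhs(structure(list(u = u, v = v, time = 0, dim = 0L),
                             class = "cdi_state"), p)
      c(d$du, d$dv)
    }
    fd[, 1] <- (f(pt[1] + h, pt[2]) - f(pt[1] - h, pt[2])) / (2 * h)
    fd[, 2] <- (f(pt[1], pt[2] + h) - f(pt[1], pt[2] - h)) / (2 * h)
    expect_equal(unname(J), fd, tolerance = 1e-6)
  }
})

test_that("stability of the extinction states flips at the region edges", {
  eps <- 1e-6
  # (0, beta) flips at alpha/beta = 1 + c
  for (cc in c(0.5, 2)) {
    below <- classify_stability(cdi_params(alpha = 1 + cc - eps, beta = 1,
                                           c = cc))$states
    above <- classify_stability(cdi_params(alpha = 1 + cc + eps, beta = 1,
                                           c = cc))$states
    expect_identical(below$stability[below$name == "v_only"], "stable")
    expect_false(above$stability[above$name == "v_only"] == "stable")
  }
  # (alpha, 0) flips at alpha/beta = 1
  below <- classify_stability(cdi_params(alpha = 1 - eps, beta = 1,
                                         c = 2))$states
  above <- classify_stability(cdi_params(alpha = 1 + eps, beta = 1,
                                         c = 2))$states
  expect_false(below$stability[below$name == "u_only"] == "stable")
  expect_identical(above$stability[above$name == "u_only"], "stable")
})

test_that("Lyapunov surface has the right critical structure", {
  p <- cdi_params(alpha = 2, beta = 1, c = 2)
  # flow-weighted gradient (u dV/du, v dV/dv) vanishes at every steady state
  dVdu <- function(u, v) -(p$alpha - u - (1 + p$c) * v)
  dVdv <- function(u, v) -(1 + p$c) * (p$beta - u - v)
  ss <- steady_states(p)
  for (i in seq_len(nrow(ss))) {
    u <- ss$u[i]; v <- ss$v[i]
    expect_equal(c(u * dVdu(u, v), v * dVdv(u, v)), c(0, 0),
                 tolerance = 1e-12)
  }
  # single-species states are local minima within the quadrant
  V <- function(u, v) lyapunov_value(p, u, v)
  expect_true(V(2, 0) < V(2 + 0.05, 0) && V(2, 0) < V(2 - 0.05, 0) &&
                V(2, 0) < V(2, 0.05))
  expect_true(V(0, 1) < V(0, 1.05) && V(0, 1) < V(0, 0.95) &&
                V(0, 1) < V(0.05, 1))
  # interior steady state (0.5, 0.5): full gradient vanishes, Hessian is
  # indefinite, and V rises/falls along the corresponding eigendirections
  expect_equal(c(dVdu(0.5, 0.5), dVdv(0.5, 0.5)), c(0, 0), tolerance = 1e-12)
  H <- matrix(c(1, 1 + p$c, 1 + p$c, 1 + p$c), 2, 2)  # Hessian of V
  eh <- eigen(H)
  expect_true(min(eh$values) < 0 && max(eh$values) > 0)
  t <- 0.02
  vneg <- eh$vectors[, which.min(eh$values)]
  vpos <- eh$vectors[, which.max(eh$values)]
  expect_lt(V(0.5 + t * vneg[1], 0.5 + t * vneg[2]), V(0.5, 0.5))
  expect_gt(V(0.5 + t * vpos[1], 0.5 + t * vpos[2]), V(0.5, 0.5))

  # V is non-increasing along simulated trajectories
  for (ic in list(c(1.5, 0.3), c(0.4, 0.9), c(1.1, 0.6))) {
    run <- integrate_cdi(cdi_state(ic[1], ic[2]), p,
                         integration_settings(max_time = 50),
                         save_interval = 0.25)
    vals <- lyapunov_value(p, run$trajectory[, 2], run$trajectory[, 3])
    expect_true(all(diff(vals) <= 1e-10))
  }

  # grid evaluation matches pointwise evaluation
  M <- lyapunov_surface(p, c(0, 0.5, 2), c(0, 0.5, 1))
  expect_equal(M[2, 2], lyapunov_value(p, 0.5, 0.5))
  expect_equal(dim(M), c(3L, 3L))
})

test_that("random-IC trajectory ensembles reproduce the regime outcomes", {
  # unanimous winners in the white regions, both winners in the grey region
  e1 <- wellmixed_ensemble(cdi_params(alpha = 2, beta = 1, c = 0.5),
                           n = 30, seed = 2)
  expect_true(all(e1$winner == "u"))
  e2 <- wellmixed_ensemble(cdi_params(alpha = 0.5, beta = 1, c = 2),
                           n = 30, seed = 2)
  expect_true(all(e2$winner == "v"))
  e3 <- wellmixed_ensemble(cdi_params(alpha = 2, beta = 1, c = 2),
                           n = 30, seed = 2)
  expect_setequal(unique(e3$winner), c("u", "v"))
})
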