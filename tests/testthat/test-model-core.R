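test_that("parameter container enforces invariants and derives c1, c2", {
  p <- cdi_params(alpha = 3.5, beta = 1, c = 6, D = 1e-3)
  expect_identical(p$c1, 2)
  expect_identical(p$c2, 1.2)
  expect_equal(p$delta, 10 / 32)

  # inhibition can be given through any single alias
  expect_equal(cdi_params(alpha = 2, beta = 1, c1 = 2)$c, 6)
  expect_equal(cdi_params(alpha = 2, beta = 1, c2 = 1)$c, 5)
  expect_error(cdi_params(alpha = 2, beta = 1, c = 6, c1 = 2), "exactly one")
  expect_error(cdi_params(alpha = 2, beta = 1), "exactly one")

  expect_error(cdi_params(alpha = 0, beta = 1, c = 1), "alpha")
  expect_error(cdi_params(alpha = 1, beta = 1, c = -1), "c must be")
  expect_error(cdi_params(alpha = 1, beta = 1, c = 1, D = -1), "D must be")
  expect_error(cdi_params(alpha = 1, beta = 1, c = 1, n_grid = 2), "n_grid")
})

test_that("state container checks shape, nonnegativity, and geometry", {
  s <- cdi_state(rep(1, 8), rep(0, 8))
  expect_identical(s$dim, 1L)
  expect_identical(cdi_state(1, 2)$dim, 0L)
  expect_identical(cdi_state(matrix(1, 4, 4), matrix(0, 4, 4))$dim, 2L)
  expect_error(cdi_state(rep(1, 8), rep(1, 7)), "identical shape")
  expect_error(cdi_state(matrix(1, 4, 3), matrix(1, 4, 3)), "square")
  expect_error(cdi_state(-1, 1), "nonnegative")
})

test_that("well-mixed RHS matches hand-evaluated fixed points and values", {
  p <- cdi_params(alpha = 2, beta = 1, c = 2)
  # single-species carrying capacity is a fixed point
  d <- cdi_rhs(cdi_state(2, 0), p)
  expect_identical(c(d$du, d$dv), c(0, 0))
  # interior steady state (beta - (alpha-beta)/c, (alpha-beta)/c) = (0.5, 0.5)
  d <- cdi_rhs(cdi_state(0.5, 0.5), p)
  expect_equal(c(d$du, d$dv), c(0, 0), tolerance = 1e-15)
  # hand evaluation at (1, 1): du = 1*(2-1-3) = -2, dv = 1*(1-1-1) = -1
  d <- cdi_rhs(cdi_state(1, 1), p)
  expect_equal(c(d$du, d$dv), c(-2, -1))
})

test_that("uniform fields reduce the spatial RHS to the well-mixed RHS", {
  set.seed(42)
  for (k in 1:5) {
    a <- runif(1, 0.5, 4); b <- runif(1, 0.5, 2); cc <- runif(1, 0, 6)
    D <- runif(1, 0, 0.1); u0 <- runif(1, 0, a); v0 <- runif(1, 0, b)
    wm <- cdi_rhs(cdi_state(u0, v0), cdi_params(alpha = a, beta = b, c = cc))
    p1 <- cdi_params(alpha = a, beta = b, c = cc, D = D, n_grid = 16)
    d1 <- cdi_rhs(cdi_state(rep(u0, 16), rep(v0, 16)), p1)
    expect_equal(d1$du, rep(wm$du, 16), tolerance = 1e-13)
    expect_equal(d1$dv, rep(wm$dv, 16), tolerance = 1e-13)
    p2 <- cdi_params(alpha = a, beta = b, c = cc, D = D, n_grid = 8)
    d2 <- cdi_rhs(cdi_state(matrix(u0, 8, 8), matrix(v0, 8, 8)), p2)
    expect_equal(as.vector(d2$du), rep(wm$du, 64), tolerance = 1e-13)
    expect_equal(as.vector(d2$dv), rep(wm$dv, 64), tolerance = 1e-13)
  }
})

test_that("all four homogeneous steady states have zero uniform derivative", {
  p <- cdi_params(alpha = 3.5, beta = 1, c = 6, D = 1e-3, n_grid = 12)
  ss <- steady_states(p)
  for (i in seq_len(nrow(ss))) {
    if (!ss$feasible[i]) next
    d <- cdi_rhs(cdi_state(rep(ss$u[i], 12), rep(ss$v[i], 12)), p)
    expect_equal(max(abs(c(d$du, d$dv))), 0, tolerance = 1e-13)
  }
})

test_that("1D RHS is equivariant under cyclic shifts", {
  p <- p_pattern()
  set.seed(7)
  st <- random_ic(p, "1d", seed = 99)
  d0 <- cdi_rhs(st, p)
  for (k in c(1, 5, 31)) {
    sh <- cdi_state(cdipatterns:::shift1(st$u, k), cdipatterns:::shift1(st$v, k))
    dk <- cdi_rhs(sh, p)
    expect_equal(dk$du, cdipatterns:::shift1(d0$du, k), tolerance = 1e-14)
    expect_equal(dk$dv, cdipatterns:::shift1(d0$dv, k), tolerance = 1e-14)
  }
})

test_that("2D inhibition stencil touches only the von-Neumann neighborhood", {
  p <- cdi_params(alpha = 3.5, beta = 1, c2 = 1, D = 0, n_grid = 7)
  u <- matrix(3.5, 7, 7); v <- matrix(0, 7, 7)
  v[4, 4] <- 0.5; u[4, 4] <- 0   # below beta, so the lone v site still grows
  d <- cdi_rhs(cdi_state(u, v), p)
  # inhibition (du < 0) exactly at the 4 von-Neumann neighbors of (4,4)
  inhibited <- which(d$du < 0, arr.ind = TRUE)
  expect_setequal(paste(inhibited[, 1], inhibited[, 2]),
                  c("3 4", "5 4", "4 3", "4 5"))
  # the v site itself grows (u = 0 there, so du = 0; dv > 0 only there)
  expect_true(d$dv[4, 4] > 0)
  expect_equal(sum(d$dv != 0), 1)
})

test_that("R and compiled RHS agree on random states in all geometries", {
  set.seed(11)
  for (k in 1:3) {
    p <- cdi_params(alpha = runif(1, 1, 4), beta = 1, c = runif(1, 0, 7),
                    D = 10^runif(1, -4, -1), n_grid = 16)
    st <- random_ic(p, "1d", seed = k)
    d_r <- cdi_rhs(st, p)
    d_c <- cdipatterns:::rhs_cpp(st$u, st$v, 1L, 0L, p$alpha, p$beta, p$c,
                                 p$D / p$delta^2, FALSE)
    expect_equal(d_c$du, d_r$du, tolerance = 1e-13)
    expect_equal(d_c$dv, d_r$dv, tolerance = 1e-13)
    st2 <- random_ic(p, "2d", seed = k)
    d_r2 <- cdi_rhs(st2, p)
    d_c2 <- cdipatterns:::rhs_cpp(as.vector(st2$u), as.vector(st2$v), 2L, 16L,
                                  p$alpha, p$beta, p$c, p$D / p$delta^2, FALSE)
    expect_equal(d_c2$du, as.vector(d_r2$du), tolerance = 1e-13)
    expect_equal(d_c2$dv, as.vector(d_r2$dv), tolerance = 1e-13)
  }
})

test_that("parameters and states round-trip through their text formats", {
  p <- cdi_params(alpha = 3.5, beta = 1, c1 = 2.1, D = 1e-3)
  f <- tempfile(fileext = ".cfg")
  write_cdi_params(p, f)
  expect_equal(read_cdi_params(f), p)

  st <- random_ic(p, "1d", seed = 5)
  f2 <- tempfile(fileext = ".csv")
  write_cdi_state(st, f2)
  df <- read.csv(f2)
  expect_equal(df$u, st$u)
  expect_equal(df$v, st$v)

  st2 <- random_ic(p, "2d", seed = 5)
  df2 <- as.data.frame(st2)
  expect_equal(df2$u[df2$row == 3 & df2$col == 7], st2$u[3, 7])
})
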