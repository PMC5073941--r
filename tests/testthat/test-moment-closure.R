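# symbolic moment ODE derivation, zero closure, integration

test_that("gene expression order-1 equations match the hand derivation", {
  net <- builtin_model("gene_expression")
  sys <- derive_moment_odes(net, 1)
  expect_true(sys$closed)  # monomolecular network: no overhang
  # d/dt E[X1] = -b E[X1] + a E[X2]; d/dt E[X2] = +b E[X1] - a E[X2];
  # d/dt E[X3] = c E[X1].  Evaluate at an arbitrary moment vector.
  y <- c(0.37, 0.63, 12.5)
  dy <- eval_rhs(sys, theta_gene, y)
  a <- theta_gene[["a"]]; b <- theta_gene[["b"]]; cc <- theta_gene[["c"]]
  expect_equal(dy, c(-b * y[1] + a * y[2],
                     b * y[1] - a * y[2],
                     cc * y[1]))
})

test_that("pure birth gives d/dt E[X] = c and dimerization pulls in E[X^2]", {
  birth <- derive_moment_odes(fix_birth(), 1)
  expect_equal(eval_rhs(birth, c(c = 0.7), 5), 0.7)

  dim_sys <- derive_moment_odes(fix_dimer(), 1)
  expect_false(dim_sys$closed)
  # pre-closure: d/dt E[X] = c1 - c2 E[X^2] + c2 E[X]
  # (state y = E[X], overhang slot y2 = E[X^2])
  y <- c(3, 11)
  expect_equal(eval_rhs(dim_sys, c(c1 = 2, c2 = 0.5), y),
               2 - 0.5 * 11 + 0.5 * 3)
})

test_that("zero closure substitutes E[X^2] -> mu^2 at k = 1", {
  sys <- apply_zero_closure(derive_moment_odes(fix_dimer(), 1))
  expect_true(sys$closed)
  mu <- 3
  expect_equal(eval_rhs(sys, c(c1 = 2, c2 = 0.5), mu),
               2 - 0.5 * mu^2 + 0.5 * mu)
  # closure of an already-closed system is the identity
  mono <- derive_moment_odes(builtin_model("gene_expression"), 2)
  expect_identical(apply_zero_closure(mono), mono)
})

test_that("closed-form means: birth c*t, death x0*exp(-d t), variance bound", {
  birth <- apply_zero_closure(derive_moment_odes(fix_birth(), 2))
  tr <- integrate_moment_system(birth, c(c = 1.3), times = c(0, 2, 5))
  expect_equal(unname(stochmom:::trajectory_moments(tr, 1L)[, 1]),
               1.3 * c(0, 2, 5), tolerance = 1e-7)
  death <- apply_zero_closure(derive_moment_odes(fix_death(x0 = 40), 2))
  tr2 <- integrate_moment_system(death, c(d = 0.25), times = c(1, 4))
  expect_equal(unname(stochmom:::trajectory_moments(tr2, 1L)[, 1]),
               40 * exp(-0.25 * c(1, 4)), tolerance = 1e-7)
  # E[X^2] >= E[X]^2 along the way
  m <- stochmom:::trajectory_moments(tr2, rbind(1L, 2L))
  expect_true(all(m[, 2] >= m[, 1]^2 - 1e-8))
})

test_that("pre-closure derivation matches a truncated-CME oracle on a bimolecular model", {
  net <- fix_dimer()
  th <- c(c1 = 2, c2 = 0.08)
  smax <- 60
  # CME distribution at two times; the state box carries < 1e-10 mass loss
  for (t_obs in c(1, 4)) {
    p <- cme_propagate(net, th, smax, x0 = 0, t_end = t_obs)
    expect_lt(abs(sum(p) - 1), 1e-8)
    # moments up to order 3 + overhang order 4 from the CME
    m <- vapply(1:4, cme_moment, 0, p = p, smax = smax)
    sys <- derive_moment_odes(net, 3)
    dy <- eval_rhs(sys, th, m)
    # oracle derivative: d/dt E[X^r] = sum_x x^r dp/dt, dp/dt from generator
    dp <- cme_propagate(net, th, smax, x0 = 0, t_end = t_obs + 1e-4) -
      cme_propagate(net, th, smax, x0 = 0, t_end = t_obs - 1e-4)
    dmdt <- vapply(1:3, function(r) sum((0:smax)^r * dp) / 2e-4, 0)
    expect_equal(dy, dmdt, tolerance = 1e-4)
  }
})

test_that("closed system tracks the CME moments of the dimerization model", {
  net <- fix_dimer()
  th <- c(c1 = 2, c2 = 0.08)
  smax <- 60
  p <- cme_propagate(net, th, smax, x0 = 0, t_end = 4)
  sys <- apply_zero_closure(derive_moment_odes(net, 4))
  tr <- integrate_moment_system(sys, th, times = 4)
  m_cme <- vapply(1:2, cme_moment, 0, p = p, smax = smax)
  m_ode <- stochmom:::trajectory_moments(tr, rbind(1L, 2L))[1, ]
  # closure is approximate for bimolecular systems: a few percent is expected
  expect_equal(unname(m_ode), m_cme, tolerance = 0.05)
})

test_that("species permutation permutes the system consistently", {
  cfg1 <- c("[species]", "A 1 high", "B 0 high",
            "[reactions]", "A -> B : k1", "B -> A : k2", "A + B -> 0 : k3",
            "[parameters]", "k1 0 1", "k2 0 1", "k3 0 1")
  cfg2 <- c("[species]", "B 0 high", "A 1 high",
            "[reactions]", "A -> B : k1", "B -> A : k2", "A + B -> 0 : k3",
            "[parameters]", "k1 0 1", "k2 0 1", "k3 0 1")
  th <- c(k1 = 0.4, k2 = 0.2, k3 = 0.05)
  s1 <- apply_zero_closure(derive_moment_odes(parse_network(cfg1), 2))
  s2 <- apply_zero_closure(derive_moment_odes(parse_network(cfg2), 2))
  t1 <- integrate_moment_system(s1, th, times = 3)
  t2 <- integrate_moment_system(s2, th, times = 3)
  # E[A], E[B], E[AB], E[A^2], E[B^2] agree under the relabeling
  expect_equal(stochmom:::trajectory_moments(t1, rbind(c(1L, 0L), c(0L, 1L),
                                                       c(1L, 1L), c(2L, 0L))),
               stochmom:::trajectory_moments(t2, rbind(c(0L, 1L), c(1L, 0L),
                                                       c(1L, 1L), c(0L, 2L))),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("gene expression order-4 moments agree with SSA within Monte Carlo error", {
  net <- builtin_model("gene_expression")
  sys <- apply_zero_closure(derive_moment_odes(net, 4))
  tr <- integrate_moment_system(sys, theta_gene, times = 100)
  ds <- sample_snapshots(net, theta_gene, 100, "mRNA", 20000, seed = 77)
  y <- as.numeric(ds$samples[[1]][, 1])
  for (r in 1:4) {
    m_ode <- stochmom:::trajectory_moments(tr, c(0L, 0L, r))[1]
    se <- sd(y^r) / sqrt(length(y))
    expect_lt(abs(mean(y^r) - m_ode) / se, 4)
  }
})

test_that("the exported listing is one line per equation and integrable systems refuse overhang", {
  sys <- derive_moment_odes(fix_dimer(), 2)
  expect_length(moment_system_listing(sys), 2L)
  expect_error(integrate_moment_system(sys, c(c1 = 1, c2 = 0.1), times = 1),
               "closed")
})
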