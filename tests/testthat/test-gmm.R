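# GMM machinery: sample/theoretical moments, weight matrices, objective,
# estimator variants

test_that("sample moments reproduce hand arithmetic (incl. mixed products)", {
  d1 <- make_dataset(list(matrix(c(1, 2, 3), 3, 1)), times = 10, "X")
  net1 <- fix_birth()
  s1 <- moment_condition_spec(net1, "X", 2, 10)
  m <- sample_moment_vector(d1, s1)
  expect_equal(unname(m[1, ]), c(2, 14 / 3))

  cfg <- c("[species]", "X 0 high", "Y 0 high",
           "[reactions]", "0 -> X : c", "0 -> Y : d",
           "[parameters]", "c 0 10", "d 0 10")
  net2 <- parse_network(cfg)
  d2 <- make_dataset(list(rbind(c(1, 2), c(3, 4))), times = 5, c("X", "Y"))
  s2 <- moment_condition_spec(net2, c("X", "Y"), 2, 5)
  m2 <- sample_moment_vector(d2, s2)
  # graded-lex conditions: E[X], E[Y], E[XY], E[X^2], E[Y^2]
  expect_equal(s2$k_per_time, 5L)
  expect_equal(unname(m2[1, match("1,1", colnames(m2))]),
               (1 * 2 + 3 * 4) / 2)  # = 7
})

test_that("F2 reproduces the printed toy covariance cov(XY, X^2) = 20", {
  cfg <- c("[species]", "X 0 high", "Y 0 high",
           "[reactions]", "0 -> X : c", "0 -> Y : d",
           "[parameters]", "c 0 10", "d 0 10")
  net <- parse_network(cfg)
  d <- make_dataset(list(rbind(c(1, 2), c(3, 4))), times = 5, c("X", "Y"))
  spec <- moment_condition_spec(net, c("X", "Y"), 2, 5)
  F2 <- estimate_F2(d, spec)[[1]]
  i_xy <- match("1,1", colnames(sample_moment_vector(d, spec)))
  i_x2 <- match("2,0", colnames(sample_moment_vector(d, spec)))
  # (1/2)[(2-7)(1-5) + (12-7)(9-5)] = 20
  expect_equal(F2[i_xy, i_x2], 20)
  # permutation invariance
  d_rev <- make_dataset(list(rbind(c(3, 4), c(1, 2))), times = 5,
                        c("X", "Y"))
  expect_equal(estimate_F2(d_rev, spec)[[1]], F2)
  # constant samples give the zero matrix, flagged singular on inversion
  d_const <- make_dataset(list(rbind(c(2, 2), c(2, 2))), times = 5,
                          c("X", "Y"))
  F2c <- estimate_F2(d_const, spec)[[1]]
  expect_true(all(F2c == 0))
  expect_true(attr(stochmom:::sym_pinv(F2c), "singular"))
})

test_that("algebraic identity F1(theta) = F2 + g g^T holds to machine precision", {
  net <- fix_birth_death()
  th <- c(c = 4, d = 0.5)
  ds <- sample_snapshots(net, th, 6, "X", 300, seed = 13)
  spec <- moment_condition_spec(net, "X", 3, 6)
  th_tilde <- c(c = 3.1, d = 0.44)
  F1 <- estimate_F1(ds, th_tilde, spec)[[1]]
  F2 <- estimate_F2(ds, spec)[[1]]
  g <- sample_moment_vector(ds, spec)[1, ] -
    theoretical_moment_vector(net, th_tilde, spec)[1, ]
  expect_equal(F1, F2 + outer(g, g), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("gmm_objective matches brute-force double sums and edge cases", {
  expect_equal(gmm_objective(c(0, 0), diag(2)), 0)
  expect_equal(gmm_objective(c(1, 2), diag(2)), 5)
  set.seed(7)
  for (rep in 1:10) {
    g <- rnorm(4)
    A <- matrix(rnorm(16), 4); W <- crossprod(A)
    brute <- sum(outer(g, g) * W)
    expect_equal(gmm_objective(g, W), brute, tolerance = 1e-12)
    expect_gte(gmm_objective(g, W), 0)
    # invariance under simultaneous permutation of conditions
    p <- sample(4)
    expect_equal(gmm_objective(g[p], W[p, p]), brute, tolerance = 1e-12)
  }
  # two time points sum their quadratic forms
  expect_equal(gmm_objective(list(c(1, 0), c(0, 2)),
                             list(diag(2), diag(2))), 5)
  expect_error(gmm_objective(c(1, 2, 3), diag(2)), "dimension")
})

test_that("weight_identity has the condition-count dimension per time", {
  cfg <- c("[species]", "X 0 high", "Y 0 high",
           "[reactions]", "0 -> X : c", "0 -> Y : d",
           "[parameters]", "c 0 10", "d 0 10")
  net <- parse_network(cfg)
  W <- weight_identity(moment_condition_spec(net, c("X", "Y"), 2, c(1, 2)))
  expect_length(W, 2L)
  expect_equal(dim(W[[1]]), c(5L, 5L))
  W1 <- weight_identity(moment_condition_spec(fix_birth(), "X", 1, 3))
  expect_equal(dim(W1[[1]]), c(1L, 1L))
})

test_that("theoretical moments at t = 0 are the initial monomials", {
  net <- builtin_model("gene_expression")
  spec <- moment_condition_spec(net, "mRNA", 3, 0)
  for (eng in c("standard", "hybrid")) {
    m <- theoretical_moment_vector(net, theta_gene, spec, engine = eng)
    expect_equal(unname(m[1, ]), c(10, 100, 1000))
  }
})

test_that("theoretical mRNA mean matches the telegraph closed form", {
  net <- builtin_model("gene_expression")
  a <- theta_gene[["a"]]; b <- theta_gene[["b"]]; cc <- theta_gene[["c"]]
  tt <- 35
  spec <- moment_condition_spec(net, "mRNA", 1, tt)
  m <- theoretical_moment_vector(net, theta_gene, spec, engine = "hybrid")
  # E[mRNA](t) = 10 + c * int_0^t pON(s) ds, pON(s) = a/(a+b)(1 - e^{-(a+b)s})
  ab <- a + b
  mean_true <- 10 + cc * (a / ab * tt - a / ab^2 * (1 - exp(-ab * tt)))
  expect_equal(unname(m[1, 1]), mean_true, tolerance = 1e-6)
})

test_that("an exactly matched sample moment yields objective ~0 at theta0", {
  # birth process: E[X](5) = 5c; with c0 = 0.2 the mean is 1, matched
  # exactly by a dataset of alternating 0/2 counts
  net <- fix_birth()
  ds <- make_dataset(list(matrix(rep(c(0L, 2L), 50), ncol = 1)),
                     times = 5, "X")
  spec <- moment_condition_spec(net, "X", 1, 5)
  fit <- estimate_parameters(ds, net, spec, estimator = "identity",
                             optimizer_config = list(n_starts = 5,
                                                     maxit = 100),
                             seed = 2)
  expect_equal(unname(fit$theta_hat[["c"]]), 0.2, tolerance = 1e-4)
  expect_lt(fit$objective, 1e-10)
})

test_that("under-identification is refused unless explicitly allowed", {
  net <- builtin_model("gene_expression")
  ds <- sample_snapshots(net, theta_gene, 50, "mRNA", 100, seed = 1)
  spec <- moment_condition_spec(net, "mRNA", 1, 50)
  expect_error(estimate_parameters(ds, net, spec, estimator = "identity"),
               "under-identified")
  fit <- estimate_parameters(ds, net, spec, estimator = "identity",
                             optimizer_config = list(n_starts = 2,
                                                     maxit = 30),
                             seed = 1, allow_underidentified = TRUE)
  expect_s3_class(fit, "gmm_result")
})

test_that("all estimator variants run and recover a birth-death rate pair", {
  net <- fix_birth_death()
  th0 <- c(c = 4, d = 0.5)
  ds <- sample_snapshots(net, th0, c(4, 8), "X", 4000, seed = 19)
  spec <- moment_condition_spec(net, "X", 2, c(4, 8))
  cfg <- list(n_starts = 4, maxit = 80)
  b <- param_bounds(net)
  for (est in c("identity", "two_step", "demean", "demean_diagonal",
                "iterated", "continuous_update")) {
    fit <- estimate_parameters(ds, net, spec, estimator = est,
                               optimizer_config = cfg, seed = 3)
    expect_s3_class(fit, "gmm_result")
    expect_true(all(fit$theta_hat >= b[, "lo"] & fit$theta_hat <= b[, "hi"]))
    expect_equal(unname(fit$theta_hat[["c"]]), 4, tolerance = 0.25)
    expect_equal(unname(fit$theta_hat[["d"]]), 0.5, tolerance = 0.25)
  }
  # two-step carries its first step in the history
  fit2 <- estimate_parameters(ds, net, spec, estimator = "two_step",
                              optimizer_config = cfg, seed = 3)
  expect_length(fit2$step_history, 2L)
  expect_match(fit2$step_history[[1]]$step, "W = I")
  # iterated default stops after the second weight update at the latest
  fit3 <- estimate_parameters(ds, net, spec, estimator = "iterated",
                              optimizer_config = cfg, seed = 3)
  expect_lte(length(fit3$step_history), 4L)
})

test_that("diagnose_weights normalizes by the mean-condition weight", {
  A <- matrix(c(4, 1, 1, 3), 2)
  d <- diagnose_weights(A, A)
  expect_equal(d$max_abs_diff, 0)
  expect_equal(d$normalized_a[1, 1], 1)
  B <- matrix(c(8, 2, 2, 6), 2)  # scalar multiple: identical after scaling
  expect_equal(diagnose_weights(A, B)$max_abs_diff, 0)
})

test_that("demean weight structure on the gene fixture matches the reported signs", {
  net <- builtin_model("gene_expression")
  ds <- sample_snapshots(net, theta_gene, 100, "mRNA", 10000, seed = 29)
  spec <- moment_condition_spec(net, "mRNA", 3, 100)
  W_dm <- lapply(estimate_F2(ds, spec), stochmom:::sym_pinv)
  Wn <- diagnose_weights(W_dm[[1]], W_dm[[1]])$normalized_a
  expect_equal(Wn[1, 1], 1)
  # mean/second-moment and second/third-moment weights are negative
  expect_lt(Wn[1, 2], 0)
  expect_lt(Wn[2, 3], 0)
  # mean carries the largest weight
  expect_equal(which.max(abs(diag(Wn))), 1L)
  # two-step weights at a near-truth first step are close in structure
  F1 <- estimate_F1(ds, theta_gene, spec, engine = "hybrid")
  W_ts <- lapply(F1, stochmom:::sym_pinv)
  d <- diagnose_weights(W_ts, W_dm)
  expect_lt(d$max_abs_diff, 0.05)  # "nearly identical weights"
})
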