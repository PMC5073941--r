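# hybrid method of conditional moments

test_that("mode enumeration finds the promoter states", {
  gene <- builtin_model("gene_expression")
  ms <- enumerate_modes(gene)
  expect_equal(ms$low, c(1L, 2L))
  expect_setequal(apply(ms$modes, 1, paste, collapse = ","),
                  c("0,1", "1,0"))

  sw <- builtin_model("exclusive_switch")
  ms2 <- enumerate_modes(sw)
  expect_equal(nrow(ms2$modes), 3L)  # free, P1-bound, P2-bound
  expect_setequal(apply(ms2$modes, 1, paste, collapse = ","),
                  c("1,0,0", "0,1,0", "0,0,1"))

  # reactions never touching the low species: a single mode
  cfg <- c("[species]", "G 1 low", "X 0 high",
           "[reactions]", "G -> G + X : c", "X -> 0 : d",
           "[parameters]", "c 0 10", "d 0 1")
  ms3 <- enumerate_modes(parse_network(cfg))
  expect_equal(nrow(ms3$modes), 1L)
  expect_equal(as.integer(ms3$modes[1, ]), 1L)
})

test_that("the mode cap catches misclassified low-copy species", {
  net <- fix_birth_death()
  net$species$copy_class <- "low"
  expect_error(enumerate_modes(reaction_network(net$species, net$reactions,
                                                net$parameters), cap = 16),
               "cap")
})

test_that("hybrid equation bookkeeping: 45 equations for the switch at order 4", {
  sw <- builtin_model("exclusive_switch")
  hs <- derive_hybrid_system(sw, max_order = 4)
  expect_equal(nrow(hs$high_indices), 14L)  # per-mode partial moments
  expect_equal(hs$n_equations, 3L * (14L + 1L))
  expect_length(moment_system_listing(hs), 45L)

  gene <- builtin_model("gene_expression")
  hg <- derive_hybrid_system(gene, max_order = 2)
  expect_equal(hg$n_equations, 2L * (1L + 2L))
})

test_that("telegraph mode probabilities reach a/(a+b) and are conserved", {
  gene <- builtin_model("gene_expression")
  hs <- derive_hybrid_system(gene, max_order = 2)
  tr <- integrate_hybrid_system(hs, theta_gene, times = c(0, 5, 20, 60, 200))
  p <- hybrid_mode_probabilities(tr)
  expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-6)
  a <- theta_gene[["a"]]; b <- theta_gene[["b"]]
  expect_equal(unname(p[5, "p(1,0)"]), a / (a + b), tolerance = 1e-6)
  # transient closed form from OFF start: p_ON(t) = a/(a+b)(1 - e^{-(a+b)t})
  expect_equal(unname(p[2, "p(1,0)"]),
               a / (a + b) * (1 - exp(-(a + b) * 5)), tolerance = 1e-6)
})

test_that("a single-mode hybrid system reproduces the standard closure", {
  cfg <- c("[species]", "G 1 low", "X 0 high",
           "[reactions]", "G -> G + X : c", "X -> 0 : d",
           "[parameters]", "c 0 10", "d 0 1")
  net <- parse_network(cfg)
  th <- c(c = 4, d = 0.3)
  hs <- derive_hybrid_system(net, max_order = 3)
  htr <- integrate_hybrid_system(hs, th, times = c(2, 8))
  expect_equal(unname(hybrid_mode_probabilities(htr)[, 1]), c(1, 1),
               tolerance = 1e-8)
  rec <- reconstruct_unconditional_moments(htr)
  std <- integrate_moment_system(
    apply_zero_closure(derive_moment_odes(net, 3)), th, times = c(2, 8))
  idx <- cbind(0L, 1:3)  # E[X], E[X^2], E[X^3]
  expect_equal(stochmom:::trajectory_moments(rec, idx),
               stochmom:::trajectory_moments(std, idx),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("gene expression: hybrid equals standard closure to order 3 (both exact)", {
  gene <- builtin_model("gene_expression")
  hs <- derive_hybrid_system(gene, max_order = 3)
  htr <- integrate_hybrid_system(hs, theta_gene, times = c(30, 100))
  rec <- reconstruct_unconditional_moments(htr)
  std <- integrate_moment_system(
    apply_zero_closure(derive_moment_odes(gene, 3)), theta_gene,
    times = c(30, 100))
  idx <- rbind(c(1L, 0L, 0L), c(0L, 0L, 1L), c(1L, 0L, 1L), c(0L, 0L, 2L),
               c(0L, 0L, 3L))
  expect_equal(stochmom:::trajectory_moments(rec, idx),
               stochmom:::trajectory_moments(std, idx),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("law of total expectation: unconditional mean = sum of partial means", {
  gene <- builtin_model("gene_expression")
  hs <- derive_hybrid_system(gene, max_order = 2)
  tr <- integrate_hybrid_system(hs, theta_gene, times = 50)
  rec <- reconstruct_unconditional_moments(tr, indices = rbind(c(0L, 0L, 1L)))
  # partial means are state slots 2 and 5 (mode 1 and mode 2, E[mRNA])
  H <- nrow(hs$high_indices)
  pm <- tr$values[1, c(stochmom:::hyb_pos_m(1, 1, H),
                       stochmom:::hyb_pos_m(2, 1, H))]
  expect_equal(unname(rec$values[1, 1]), sum(pm), tolerance = 1e-12)
})

test_that("conditional moments divide out the mode probability", {
  gene <- builtin_model("gene_expression")
  hs <- derive_hybrid_system(gene, max_order = 2)
  tr <- integrate_hybrid_system(hs, theta_gene, times = 80)
  p <- hybrid_mode_probabilities(tr)
  cm <- hybrid_conditional_moments(tr)
  H <- nrow(hs$high_indices)
  for (a in 1:2) {
    pm <- tr$values[1, stochmom:::hyb_pos_m(a, 1, H)]
    expect_equal(unname(cm[[a]][1, 1]), unname(pm / p[1, a]),
                 tolerance = 1e-12)
  }
})

test_that("hybrid moments beat the standard closure on the exclusive switch", {
  # scaled-down version of the moment-accuracy comparison: SSA reference at
  # 30,000 samples, engines derived at order 5, first four moments of P1
  sw <- builtin_model("exclusive_switch")
  ds <- sample_snapshots(sw, theta_switch, 100, "P1", 30000, seed = 55)
  y <- as.numeric(ds$samples[[1]][, 1])
  m_ssa <- vapply(1:4, function(r) mean(y^r), 0)

  hs <- derive_hybrid_system(sw, max_order = 5)
  htr <- integrate_hybrid_system(hs, theta_switch, times = 100)
  idxP1 <- matrix(0L, 4, 5); idxP1[, 4] <- 1:4
  m_hyb <- stochmom:::trajectory_moments(
    reconstruct_unconditional_moments(htr, idxP1), idxP1)[1, ]
  std <- integrate_moment_system(
    apply_zero_closure(derive_moment_odes(sw, 5)), theta_switch, times = 100)
  m_std <- stochmom:::trajectory_moments(std, idxP1)[1, ]

  err_hyb <- abs(m_hyb - m_ssa) / m_ssa
  err_std <- abs(m_std - m_ssa) / m_ssa
  # hybrid is closer for every one of the first four moments
  expect_true(all(err_hyb < err_std))
})
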