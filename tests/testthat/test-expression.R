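test_that("M and A statistics follow their closed forms", {
  eq <- compute_ma(c(4, 7, 9), c(4, 7, 9))
  expect_equal(eq$M, 0)

  one <- compute_ma(8, 1)
  expect_equal(one$M, 3)
  expect_equal(one$A, 1.5)

  expect_error(compute_ma(c(1, -2), c(1, 1)), "positive")

  # direct recomputation on a random paired table
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(4, 1, 1000); c0 <- runif(4, 1, 1000)
    ma <- compute_ma(p, c0)
    expect_equal(ma$M, mean(log2(p) - log2(c0)))
    expect_equal(ma$A, mean(c(log2(p), log2(c0))))
    expect_equal(ma$m_values, log2(p / c0))
  }
})

test_that("replicate p values honor the degenerate-input conventions", {
  zv <- replicate_pvalue(c(1, 1, 1))
  expect_equal(zv$p_value, 0)
  expect_equal(zv$flag, "zero_variance")

  null0 <- replicate_pvalue(c(0, 0, 0))
  expect_equal(null0$p_value, 1)

  sym <- replicate_pvalue(c(1, -1))
  expect_equal(sym$p_value, 1.0)

  single <- replicate_pvalue(2.5)
  expect_true(is.na(single$p_value))
  expect_equal(single$flag, "undefined")
})

test_that("the per-gene test keeps its nominal type-I error", {
  set.seed(17)
  m <- matrix(rnorm(10000 * 4), ncol = 4)
  p <- apply(m, 1, function(r) replicate_pvalue(r)$p_value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("vectorized expression summary agrees with the scalar path", {
  set.seed(23)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:50))
  for (r in 1:3) tab[[sprintf("pert_%d", r)]] <- runif(50, 1, 500)
  for (r in 1:3) tab[[sprintf("ctrl_%d", r)]] <- runif(50, 1, 500)
  rec <- summarize_expression(tab)
  for (i in c(1, 10, 50)) {
    ma <- compute_ma(as.numeric(tab[i, 2:4]), as.numeric(tab[i, 5:7]))
    expect_equal(rec$M[i], ma$M)
    expect_equal(rec$A[i], ma$A)
    expect_equal(rec$p_value[i], replicate_pvalue(ma$m_values)$p_value)
  }
})

test_that("target classification applies the fivefold / p rule exactly", {
  crit <- de_criteria()
  mk <- function(M, p) data.frame(gene_id = "g", M = M, p_value = p)
  expect_equal(classify_targets(mk(-log2(6), 0.01), "g", crit)$class,
               "direct_repressed")
  expect_equal(classify_targets(mk(-2.0, 0.01), "g", crit)$class,
               "bound_unchanged")  # 4-fold misses the 5-fold cutoff
  expect_equal(classify_targets(mk(3.0, 0.001), character(0), crit)$class,
               "unbound_DE")
  expect_error(classify_targets(rbind(mk(1, 1), mk(1, 1)), "g", crit),
               "duplicate")
})

test_that("classification is exhaustive, order-invariant and consistent", {
  grid <- expand.grid(
    M = c(-3.5, -log2(5), -2.0, 0, 2.0, log2(5), 3.5),
    p = c(0.001, 0.049, 0.05, 0.5),
    bound = c(TRUE, FALSE)
  )
  records <- data.frame(gene_id = sprintf("g%02d", seq_len(nrow(grid))),
                        M = grid$M, p_value = grid$p)
  bound_genes <- records$gene_id[grid$bound]
  calls <- classify_targets(records, bound_genes)
  for (i in seq_len(nrow(grid))) {
    de <- abs(grid$M[i]) >= log2(5) && grid$p[i] < 0.05
    expected <- if (grid$bound[i] && de && grid$M[i] < 0) {
      "direct_repressed"
    } else if (grid$bound[i] && de && grid$M[i] > 0) {
      "direct_activated"
    } else if (grid$bound[i] && !de) {
      "bound_unchanged"
    } else if (!grid$bound[i] && de) {
      "unbound_DE"
    } else "none"
    expect_equal(calls$class[i], expected, label = paste("row", i))
  }
  # permutation invariance and class-count conservation
  perm <- sample(nrow(records))
  calls_perm <- classify_targets(records[perm, ], bound_genes)
  expect_equal(calls_perm$class,
               calls$class[perm])
  expect_equal(sum(table(calls$class)), nrow(records))
})

test_that("qPCR relative change follows 2^-dCt and is reciprocal", {
  expect_equal(qpcr_relative_change(20, 20)$relative_change, 1.0)
  expect_equal(qpcr_relative_change(21, 20)$relative_change, 0.5)
  expect_equal(qpcr_relative_change(18, 20)$relative_change, 4.0)
  expect_equal(qpcr_relative_change(20, 20)$delta_ct, 0)

  set.seed(29)
  a <- runif(20, 10, 35); b <- runif(20, 10, 35)
  expect_equal(qpcr_relative_change(a, b)$relative_change *
                 qpcr_relative_change(b, a)$relative_change,
               rep(1, 20))
})

test_that("reporter gating recovers induced fractions against the control", {
  set.seed(41)
  ctrl <- flow_sample(rlnorm(100000, log(50), 0.4))
  same <- gate_induced_fraction(ctrl, ctrl, quantile = 0.995)
  expect_lt(abs(same - 0.005), 0.002)

  # 20% of events shifted far above the control maximum
  n <- 100000
  base <- rlnorm(n, log(50), 0.4)
  shifted <- base
  hot <- sample(n, 0.2 * n)
  shifted[hot] <- max(ctrl$events) * 10 + runif(length(hot))
  frac <- gate_induced_fraction(flow_sample(shifted), ctrl, 0.995)
  expect_lt(abs(frac - (0.20 + 0.8 * 0.005)), 0.01)

  low <- flow_sample(rep(min(ctrl$events) / 2, 100))
  expect_equal(gate_induced_fraction(low, ctrl), 0.0)

  expect_error(gate_induced_fraction(ctrl, ctrl, quantile = 1.2),
               "quantile")
})
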