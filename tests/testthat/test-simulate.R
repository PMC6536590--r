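test_that("genome simulation is deterministic with the stated GC", {
  a <- simulate_genome(length_bp = 50000, n_genes = 40, seed = 4)
  b <- simulate_genome(length_bp = 50000, n_genes = 40, seed = 4)
  expect_identical(a$contigs[[1]]$sequence, b$contigs[[1]]$sequence)
  expect_identical(a$genes, b$genes)

  big <- simulate_genome(length_bp = 500000, n_genes = 0, seed = 4)
  gc <- sum(strsplit(big$contigs[[1]]$sequence, "")[[1]] %in%
              c("G", "C")) / 500000
  expect_lt(abs(gc - 0.54), 0.01)
  expect_equal(nrow(big$genes), 0L)

  expect_error(simulate_genome(length_bp = 1000, n_genes = 10),
               "infeasible layout")
  # both divergent and convergent gene pairs occur
  g <- a$genes
  pairs <- paste0(g$strand[-nrow(g)], g$strand[-1])
  expect_true("+-" %in% pairs)  # convergent
  expect_true("-+" %in% pairs)  # divergent
})

test_that("site planting honors counts, purity and palindromicity", {
  ann <- simulate_genome(length_bp = 200000, n_genes = 160, seed = 6)
  pl <- plant_sites(ann, n_sites = 30, promoter_fraction = 0.8,
                    mutation_rate = 0, seed = 6)
  sites <- pl$truth$sites
  expect_equal(nrow(sites), 30L)
  expect_equal(sum(sites$in_promoter), 24L)
  expect_equal(sum(!sites$in_promoter), 6L)
  # mutation_rate 0 plants the exact consensus everywhere
  expect_true(all(sites$seq == default_palindrome()))
  # and the planted sequence is present in the genome at each center
  ct <- pl$annotation$contigs[[1]]
  for (i in seq_len(nrow(sites))) {
    got <- extract_sequence(ct, sites$center[i] - 9, sites$center[i] + 9)
    if (sites$strand[i] == "-") got <- revcomp(got)
    expect_equal(got, sites$seq[i])
  }
  # site PWM of a self-reverse-complement consensus is fully palindromic
  expect_equal(palindromicity(pwm_from_sites(sites$seq, 0)), 1.0)
  # centers keep the configured minimum separation
  d <- as.vector(dist(sites$center))
  expect_true(all(d >= 2000))

  tiny <- simulate_genome(length_bp = 20000, n_genes = 16, seed = 6)
  expect_error(plant_sites(tiny, n_sites = 30, seed = 6),
               "not enough")
})

test_that("coverage simulation matches its Poisson rate model", {
  ann <- simulate_genome(length_bp = 100000, n_genes = 0, seed = 8)
  bg <- simulate_coverage(ann, truth = NULL, seed = 8)
  lambda <- 20
  expect_lt(abs(mean(bg$values) - lambda),
            3 * sqrt(lambda / 100000))
  expect_identical(simulate_coverage(ann, NULL, seed = 8)$values,
                   bg$values)

  ann2 <- simulate_genome(length_bp = 100000, n_genes = 80, seed = 8)
  pl <- plant_sites(ann2, n_sites = 5, seed = 8,
                    min_separation_bp = 5000)
  cov <- simulate_coverage(pl$annotation, pl$truth, seed = 8)
  # near-site coverage approaches background * enrichment_fold
  at_sites <- vapply(pl$truth$sites$center, function(cc) {
    mean(cov$values[(cc - 10):(cc + 10)])
  }, numeric(1))
  expect_true(all(at_sites > 100))  # background 20, fold 10
  expect_lt(abs(mean(at_sites) - 200) / 200, 0.15)
})

test_that("expression simulation recovers effects in the noiseless limit", {
  ann <- simulate_genome(length_bp = 100000, n_genes = 80, seed = 10)
  pl <- plant_sites(ann, n_sites = 10, seed = 10,
                    min_separation_bp = 3000)
  ex <- simulate_expression(pl$annotation, pl$truth, noise_sd = 0,
                            offtarget_fraction = 0, seed = 10)
  rec <- summarize_expression(ex$table)
  expect_equal(rec$M, ex$effects$true_effect, tolerance = 1e-12)
  targets <- ex$effects$is_direct_target
  expect_true(all(ex$effects$true_effect[targets] == -2.8))
  expect_true(all(ex$effects$true_effect[!targets] == 0))

  # null genes center on zero at scale
  ex2 <- simulate_expression(pl$annotation, pl$truth,
                             offtarget_fraction = 0, seed = 11)
  null_m <- summarize_expression(ex2$table)$M[!targets]
  expect_lt(abs(mean(null_m)), 0.05)

  expect_identical(
    simulate_expression(pl$annotation, pl$truth,
                        offtarget_fraction = 0, seed = 11)$table,
    ex2$table)
})

test_that("flow simulation honors its mixture fraction and guards", {
  fl <- simulate_flow(n_events = 50000, induced_fraction = 0.2, seed = 12)
  expect_equal(fl$sample$n_events, 50000L)
  frac <- gate_induced_fraction(fl$sample, fl$control)
  expect_lt(abs(frac - 0.2), 0.01)

  none <- simulate_flow(n_events = 20000, induced_fraction = 0, seed = 12)
  f0 <- gate_induced_fraction(none$sample, none$control)
  expect_lt(f0, 0.02)

  expect_error(simulate_flow(n_events = 0, induced_fraction = 0.5),
               "positive")
  expect_error(simulate_flow(induced_fraction = 1.5), "induced_fraction")
  expect_identical(simulate_flow(n_events = 1000, seed = 3)$sample$events,
                   simulate_flow(n_events = 1000, seed = 3)$sample$events)
})
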