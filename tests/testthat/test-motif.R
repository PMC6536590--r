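test_that("PWM construction from sites matches the counting formula", {
  p0 <- pwm_from_sites(c("AT", "AT"), pseudocount = 0)
  expect_equal(p0$probs[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(p0$probs[2, ], c(A = 0, C = 0, G = 0, T = 1))

  p1 <- pwm_from_sites("A", pseudocount = 0.5)
  expect_equal(unname(p1$probs[1, ]), c(1.5, 0.5, 0.5, 0.5) / 3)

  expect_error(pwm_from_sites(c("AA", "AAA")), "equal length")
  expect_error(pwm_from_sites(character(0)), "at least one")

  # independent counting oracle on random sites
  set.seed(5)
  sites <- replicate(20, paste(sample(c("A", "C", "G", "T"), 12,
                                      replace = TRUE), collapse = ""))
  p <- pwm_from_sites(sites, pseudocount = 0.5)
  mat <- do.call(rbind, strsplit(sites, ""))
  for (i in 1:12) {
    counts <- table(factor(mat[, i], levels = c("A", "C", "G", "T")))
    expect_equal(unname(p$probs[i, ]),
                 unname((as.numeric(counts) + 0.5) / (20 + 2)))
  }
})

test_that("information content follows the closed forms", {
  degenerate <- pwm(matrix(c(1, 0, 0, 0), nrow = 1))
  expect_equal(information_content(degenerate)$total, 2.0)

  uniform <- pwm(matrix(0.25, nrow = 3, ncol = 4))
  expect_equal(information_content(uniform)$total, 0.0)

  half <- pwm(matrix(c(0.5, 0, 0, 0.5), nrow = 1))
  expect_equal(information_content(half)$total, 1.0)

  expect_error(information_content(uniform, background = c(0, 1, 0, 0)),
               "positive")

  # brute-force recomputation on random PWMs
  set.seed(9)
  for (rep in 1:50) {
    m <- matrix(rgamma(4 * 8, 1), ncol = 4)
    m <- m / rowSums(m)
    p <- pwm(m)
    manual <- sum(apply(m, 1, function(r) {
      t <- r * log2(r / 0.25); sum(t[r > 0])
    }))
    expect_equal(information_content(p)$total, manual)
  }
})

test_that("AT content and palindromicity score as defined", {
  at <- pwm(matrix(rep(c(0.5, 0, 0, 0.5), 4), ncol = 4, byrow = TRUE))
  expect_equal(at_content(at), 1.0)
  expect_equal(palindromicity(at), 1.0)  # equals its reverse complement

  uniform <- pwm(matrix(0.25, nrow = 5, ncol = 4))
  expect_equal(at_content(uniform), 0.5)

  allA <- pwm(matrix(rep(c(1, 0, 0, 0), 2), ncol = 4, byrow = TRUE))
  expect_equal(palindromicity(allA), 0.0)

  set.seed(13)
  for (rep in 1:20) {
    m <- matrix(rgamma(4 * 6, 1), ncol = 4)
    m <- m / rowSums(m)
    p <- pwm(m)
    s <- palindromicity(p)
    expect_gte(s, 0); expect_lte(s, 1)
    # oracle recomputation from the definition
    rc <- m[6:1, c(4, 3, 2, 1)]
    expect_equal(s, 1 - sum(abs(m - rc)) / 12)
  }
})

test_that("ZOOPS-EM recovers a planted consensus and its positions", {
  consensus <- default_palindrome()
  set.seed(7)
  offsets <- integer(20)
  win <- character(20)
  for (i in 1:20) {
    bg <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
    o <- sample(0:(100 - 18), 1)
    site <- if (sample(c(TRUE, FALSE), 1)) consensus else revcomp(consensus)
    s <- paste(bg, collapse = "")
    substr(s, o + 1, o + 18) <- site
    offsets[i] <- o
    win[i] <- s
  }
  fit <- zoops_em(win, width = 18, rng_seed = 7)
  expect_equal(pwm_consensus(fit$pwm), consensus)
  expect_gte(palindromicity(fit$pwm), 0.999)
  hit_offsets <- merge(data.frame(window = 1:20, truth = offsets),
                       fit$hits, by = "window")
  expect_gte(sum(hit_offsets$offset == hit_offsets$truth), 18)

  # pure-background windows carry less information than planted ones
  set.seed(8)
  noise <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
          collapse = "")
  }, character(1))
  fit_noise <- zoops_em(noise, width = 18, rng_seed = 7)
  expect_lt(information_content(fit_noise$pwm)$total,
            information_content(fit$pwm)$total)

  expect_error(zoops_em(win[1]), "at least 2")
  expect_error(zoops_em(c("ACGT", "ACGT"), width = 18),
               "exceeds the shortest window")
})

test_that("the EM objective is non-decreasing for every restart seed", {
  set.seed(21)
  win <- vapply(1:15, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
    o <- sample(0:(80 - 18), 1)
    substr(s, o + 1, o + 18) <- default_palindrome()
    s
  }, character(1))
  for (rs in 0:3) {
    fit <- zoops_em(win, width = 18, n_seeds = 3, rng_seed = rs)
    expect_true(all(diff(fit$objective_trace) >= -1e-9))
    expect_gte(palindromicity(fit$pwm), 0.999)
  }
})

test_that("motif recovery is accurate over repeated simulations", {
  # planted palindromic AT-rich 18-mer in 60 windows, mutated at 10%;
  # mean per-column Euclidean distance to the planting PWM stays small
  consensus <- default_palindrome()
  planted_probs <- local({
    idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
    m <- matrix(0.1 / 3, nrow = 18, ncol = 4)
    m[cbind(1:18, idx)] <- 0.9
    m
  })
  dists <- vapply(1:5, function(sim) {
    set.seed(100 + sim)
    win <- vapply(1:60, function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                 collapse = "")
      o <- sample(0:(100 - 18), 1)
      site <- strsplit(consensus, "")[[1]]
      mut <- runif(18) < 0.1
      site[mut] <- vapply(site[mut], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      substr(s, o + 1, o + 18) <- paste(site, collapse = "")
      s
    }, character(1))
    fit <- zoops_em(win, width = 18, rng_seed = sim)
    mean(sqrt(rowSums((fit$pwm$probs - planted_probs)^2)))
  }, numeric(1))
  expect_lte(mean(dists), 0.15)
})

test_that("width scanning picks an informative width deterministically", {
  set.seed(31)
  win <- vapply(1:20, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    o <- sample(0:(60 - 18), 1)
    substr(s, o + 1, o + 18) <- default_palindrome()
    s
  }, character(1))
  scan <- scan_motif_widths(win, widths = c(14L, 18L, 22L),
                            n_seeds = 3, rng_seed = 2)
  expect_true(scan$best_width %in% c(14L, 18L, 22L))
  expect_equal(nrow(scan$table), 3L)
  scan2 <- scan_motif_widths(win, widths = c(14L, 18L, 22L),
                             n_seeds = 3, rng_seed = 2)
  expect_identical(scan$best_fit$pwm$probs, scan2$best_fit$pwm$probs)
})
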