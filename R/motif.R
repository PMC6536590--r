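# Binding-motif model and discovery. The motif is a position weight
# matrix (PWM); discovery is a zero-or-one-occurrence-per-sequence (ZOOPS)
# expectation-maximization finder with optional reverse-complement
# symmetrization, reflecting the palindromic operators typical of
# homodimeric MarR-family regulators.

DNA_BASES <- c("A", "C", "G", "T")

# integer encoding A=1 C=2 G=3 T=4; errors on other characters
encode_dna <- function(x) {
  v <- match(strsplit(toupper(x), "")[[1L]], DNA_BASES)
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T}")
  v
}

#' Construct a PWM
#'
#' @param probs Numeric matrix, width x 4 with columns A,C,G,T; rows must
#'   sum to 1.
#' @param pseudocount Pseudocount used at construction (metadata).
#' @return Object of class `pwm`.
#' @export
pwm <- function(probs, pseudocount = NA_real_) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4L, nrow(probs) >= 1L, all(probs >= 0))
  if (any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("PWM rows must sum to 1")
  }
  colnames(probs) <- DNA_BASES
  structure(list(probs = probs, width = nrow(probs),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s\n", x$width, pwm_consensus(x)))
  invisible(x)
}

#' Build a PWM from aligned binding sites
#'
#' `probs[i, b] = (count_i(b) + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param sites Character vector of equal-length sequences over A,C,G,T.
#' @param pseudocount Added to every count (default 0.5).
#' @export
pwm_from_sites <- function(sites, pseudocount = 0.5) {
  if (length(sites) < 1L) stop("need at least one site")
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites must have equal length")
  n <- length(sites)
  mat <- vapply(sites, encode_dna, integer(w))
  if (w == 1L) mat <- matrix(mat, nrow = 1L)
  counts <- t(apply(mat, 1L, tabulate, nbins = 4L))
  pwm((counts + pseudocount) / (n + 4 * pseudocount), pseudocount)
}

#' Reverse complement of a PWM
#'
#' Reverses the column (position) order and swaps A with T and C with G.
#' @param p A [pwm()].
#' @export
pwm_reverse_complement <- function(p) {
  pr <- p$probs[rev(seq_len(p$width)), c(4L, 3L, 2L, 1L), drop = FALSE]
  pwm(pr, p$pseudocount)
}

#' Information content of a PWM
#'
#' Per-position `IC_i = sum_b p_ib log2(p_ib / q_b)` with `0 log 0 = 0`,
#' i.e. the letter heights of a sequence logo, plus the total.
#'
#' @param p A [pwm()].
#' @param background Background base probabilities (A,C,G,T); default
#'   uniform. Zero entries are an error.
#' @return List with `per_position` (bits) and `total` (bits).
#' @export
information_content <- function(p, background = rep(0.25, 4)) {
  stopifnot(length(background) == 4L)
  if (any(background <= 0)) stop("background probabilities must be positive")
  pr <- p$probs
  term <- pr * log2(sweep(pr, 2L, background, "/"))
  term[pr == 0] <- 0
  per <- rowSums(term)
  list(per_position = per, total = sum(per))
}

#' Mean A+T probability of a PWM
#'
#' @param p A [pwm()].
#' @return Mean over positions of `p(A) + p(T)`; 1 for a pure AT motif.
#' @export
at_content <- function(p) {
  mean(p$probs[, "A"] + p$probs[, "T"])
}

#' Palindromicity score of a PWM
#'
#' `1 - (1 / (2 * width)) * sum |p - p'|` where `p'` is the
#' reverse-complement PWM; 1 for a perfectly palindromic matrix, down to
#' 0 for maximal asymmetry (e.g. an all-A consensus).
#'
#' @param p A [pwm()].
#' @return Score in `[0, 1]`.
#' @export
palindromicity <- function(p) {
  rc <- pwm_reverse_complement(p)
  1 - sum(abs(p$probs - rc$probs)) / (2 * p$width)
}

#' Consensus sequence of a PWM
#'
#' Per-position argmax base; ties resolve to the alphabetically first
#' base, so the result is deterministic.
#' @param p A [pwm()].
#' @export
pwm_consensus <- function(p) {
  paste(DNA_BASES[apply(p$probs, 1L, which.max)], collapse = "")
}

#' Write a PWM in MEME minimal motif format
#'
#' @param p A [pwm()].
#' @param path Output path.
#' @param name Motif name.
#' @param nsites Number of contributing sites (metadata line).
#' @export
write_meme_motif <- function(p, path, name = "motif1", nsites = 20L) {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            p$width, nsites),
    apply(p$probs, 1L, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                           r[1], r[2], r[3], r[4]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Evaluate code under a temporary RNG state
#'
#' Seeds the generator with `seed`, evaluates `code`, and restores the
#' caller's `.Random.seed` afterwards, so seeded helpers do not disturb
#' the surrounding random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' ZOOPS expectation-maximization motif discovery
#'
#' Fits a zero-or-one-occurrence-per-sequence mixture: each window either
#' contains one motif instance at an unknown offset and strand, or is
#' pure background. The background is a 0-order model estimated from the
#' input windows. The M-step re-estimates the PWM from posterior-weighted
#' counts with a pseudocount of 0.5; with `symmetric = TRUE` it is then
#' constrained to equal its reverse complement (averaging the counts with
#' their reverse-complemented mirror), so the returned motif is exactly
#' palindromic. `n_seeds` random restarts are run, each initialized from
#' a randomly chosen window k-mer, and the restart with the best final
#' objective wins.
#'
#' The EM objective is the ZOOPS log-likelihood plus the Dirichlet
#' pseudocount penalty; it is non-decreasing across iterations and is
#' returned as `objective_trace`.
#'
#' @param windows Character vector of at least two sequences, each at
#'   least `width` long.
#' @param width Motif width (default 18).
#' @param symmetric Constrain the PWM to be reverse-complement symmetric
#'   (default TRUE).
#' @param max_iter Maximum EM iterations per restart (default 200).
#' @param tol Convergence tolerance on the objective (default 1e-6).
#' @param n_seeds Number of random restarts (default 10).
#' @param rng_seed Seed for the restarts (default 0); results are fully
#'   deterministic given this seed.
#' @param pseudocount M-step pseudocount (default 0.5).
#' @return List of class `zoops_fit` with elements `pwm`, `hits`
#'   (data.frame: `window`, `offset` 0-based, `strand`, `score_bits`,
#'   `posterior`), `gamma` (estimated fraction of windows with a site),
#'   `background`, `objective_trace`, `log_likelihood_trace`,
#'   `n_iter`, `converged` and `seed_objectives`.
#' @export
zoops_em <- function(windows, width = 18L, symmetric = TRUE,
                     max_iter = 200L, tol = 1e-6, n_seeds = 10L,
                     rng_seed = 0L, pseudocount = 0.5) {
  if (length(windows) < 2L) stop("need at least 2 windows")
  width <- as.integer(width)
  if (any(nchar(windows) < width)) {
    stop("motif width exceeds the shortest window")
  }
  enc <- lapply(windows, encode_dna)
  # 0-order background from all windows
  bg_counts <- tabulate(unlist(enc), nbins = 4L) + 1
  q <- bg_counts / sum(bg_counts)
  logq <- log(q)
  nwin <- length(enc)
  pre <- lapply(enc, function(x) {
    L <- length(x)
    m <- L - width + 1L
    cb <- c(0, cumsum(logq[x]))
    list(x = x, xc = 5L - x, m = m, total_bg = cb[L + 1L],
         site_bg = cb[(width + 1L):(L + 1L)] - cb[1L:m])
  })

  # posterior responsibilities over (absent, offset x strand) per window
  e_step <- function(probs, gamma) {
    logP <- log(probs)
    ll <- 0
    Z <- vector("list", nwin)
    for (j in seq_len(nwin)) {
      pj <- pre[[j]]
      m <- pj$m
      sp <- numeric(m)  # site log-prob, + strand
      sm <- numeric(m)  # - strand
      for (i in seq_len(width)) {
        sp <- sp + logP[i, pj$x[i:(i + m - 1L)]]
        sm <- sm + logP[i, pj$xc[(width - i + 1L):(width - i + m)]]
      }
      a0 <- log1p(-gamma) + pj$total_bg
      ap <- log(gamma) - log(2 * m) + pj$total_bg - pj$site_bg + sp
      am <- log(gamma) - log(2 * m) + pj$total_bg - pj$site_bg + sm
      llj <- log_sum_exp(c(a0, ap, am))
      ll <- ll + llj
      Z[[j]] <- list(z0 = exp(a0 - llj), zp = exp(ap - llj),
                     zm = exp(am - llj), sp = sp, sm = sm)
    }
    list(Z = Z, ll = ll)
  }

  run_em <- function(init_probs) {
    probs <- init_probs
    gamma <- 0.5
    obj_trace <- numeric(0)
    ll_trace <- numeric(0)
    converged <- FALSE
    state <- NULL
    for (iter in seq_len(max_iter)) {
      es <- e_step(probs, gamma)
      Z <- es$Z
      ll <- es$ll
      obj <- ll + pseudocount * sum(log(probs))
      obj_trace <- c(obj_trace, obj)
      ll_trace <- c(ll_trace, ll)
      state <- Z
      if (iter > 1L &&
          obj - obj_trace[iter - 1L] < tol) {
        converged <- TRUE
        break
      }
      # M-step
      counts <- matrix(0, nrow = width, ncol = 4L)
      present <- 0
      for (j in seq_len(nwin)) {
        pj <- pre[[j]]; zj <- Z[[j]]
        m <- pj$m
        present <- present + (1 - zj$z0)
        for (i in seq_len(width)) {
          vp <- pj$x[i:(i + m - 1L)]
          vm <- pj$xc[(width - i + 1L):(width - i + m)]
          for (b in 1:4) {
            counts[i, b] <- counts[i, b] + sum(zj$zp[vp == b]) +
              sum(zj$zm[vm == b])
          }
        }
      }
      gamma <- min(max(present / nwin, 1e-6), 1 - 1e-6)
      counts <- counts + pseudocount
      if (symmetric) {
        rc <- counts[rev(seq_len(width)), c(4L, 3L, 2L, 1L), drop = FALSE]
        counts <- (counts + rc) / 2
      }
      probs <- counts / rowSums(counts)
    }
    if (!converged) {
      # refresh the responsibilities so the reported hits match the
      # returned (post-M-step) parameters
      es <- e_step(probs, gamma)
      obj_trace <- c(obj_trace, es$ll + pseudocount * sum(log(probs)))
      ll_trace <- c(ll_trace, es$ll)
      state <- es$Z
    }
    list(probs = probs, gamma = gamma, obj = obj_trace[length(obj_trace)],
         obj_trace = obj_trace, ll_trace = ll_trace, Z = state,
         n_iter = length(obj_trace), converged = converged)
  }

  seed_init <- function(k) {
    j <- sample.int(nwin, 1L)
    o <- sample.int(pre[[j]]$m, 1L)
    site <- pre[[j]]$x[o:(o + width - 1L)]
    probs <- matrix(0.4 / 3, nrow = width, ncol = 4L)
    probs[cbind(seq_len(width), site)] <- 0.6
    if (symmetric) {
      rc <- probs[rev(seq_len(width)), c(4L, 3L, 2L, 1L), drop = FALSE]
      probs <- (probs + rc) / 2
    }
    probs
  }

  fits <- with_seed(rng_seed, {
    lapply(seq_len(n_seeds), function(k) run_em(seed_init(k)))
  })
  objs <- vapply(fits, function(f) f$obj, numeric(1))
  best <- fits[[which.max(objs)]]

  final_pwm <- pwm(best$probs, pseudocount)
  # maximum-posterior hit per window, or none
  hits <- do.call(rbind, lapply(seq_len(nwin), function(j) {
    zj <- best$Z[[j]]
    p_present <- 1 - zj$z0
    if (p_present <= 0.5) return(NULL)
    zp_max <- max(zj$zp); zm_max <- max(zj$zm)
    if (zp_max >= zm_max) {
      o <- which.max(zj$zp); strand <- "+"
      score <- (zj$sp[o] - pre[[j]]$site_bg[o]) / log(2)
    } else {
      o <- which.max(zj$zm); strand <- "-"
      score <- (zj$sm[o] - pre[[j]]$site_bg[o]) / log(2)
    }
    data.frame(window = j, offset = o - 1L, strand = strand,
               score_bits = score, posterior = p_present)
  }))
  if (is.null(hits)) {
    hits <- data.frame(window = integer(0), offset = integer(0),
                       strand = character(0), score_bits = numeric(0),
                       posterior = numeric(0))
  }
  structure(
    list(pwm = final_pwm, hits = hits, gamma = best$gamma,
         background = stats::setNames(q, DNA_BASES),
         objective_trace = best$obj_trace,
         log_likelihood_trace = best$ll_trace,
         n_iter = best$n_iter, converged = best$converged,
         seed_objectives = objs),
    class = "zoops_fit"
  )
}

#' Scan motif widths and pick the most informative
#'
#' Runs [zoops_em()] over a range of widths and selects the width with
#' the highest total information content per position (IC per free
#' parameter), a simple guard against the monotone growth of raw IC with
#' width.
#'
#' @param windows Sequences as for [zoops_em()].
#' @param widths Candidate widths (default 14 to 22 in steps of 2).
#' @param ... Passed to [zoops_em()].
#' @return List with `best_width`, `best_fit` and a `table` of width,
#'   total IC and IC per position.
#' @export
scan_motif_widths <- function(windows, widths = seq(14L, 22L, by = 2L),
                              ...) {
  fits <- lapply(widths, function(w) zoops_em(windows, width = w, ...))
  ic <- vapply(fits, function(f) information_content(f$pwm)$total,
               numeric(1))
  per <- ic / widths
  best <- which.max(per)
  list(best_width = widths[best], best_fit = fits[[best]],
       table = data.frame(width = widths, total_ic = ic,
                          ic_per_position = per))
}
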