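grid_variants <- function(M, step = 1000L, chrom = "chr1") {
  data.frame(chrom = chrom, pos = step * seq_len(M),
             vid = as.character(seq_len(M)), maf = 0.01,
             stringsAsFactors = FALSE)
}

test_that("sharing counts respect the closed +-d boundary and cap one per individual", {
  v <- grid_variants(5)   # positions 1000..5000
  # one individual, one candidate exactly d away from variant 1
  c1 <- as_candidates(data.frame(individual = "a", chrom = "chr1", pos = 3000))
  prof <- count_sharing(v, c1, d_kb = 2)            # window 2000 bp
  expect_equal(prof$nf, c(1L, 1L, 1L, 1L, 1L))      # 1000 is exactly 2000 away
  prof_n <- count_sharing(v, c1, d_kb = 1.999)      # 1999 bp: variant 1 out
  expect_equal(prof_n$nf[1], 0L)

  # several candidates of the same individual never count twice
  c2 <- as_candidates(data.frame(individual = "a", chrom = "chr1",
                                 pos = c(2000, 2500, 3000)))
  expect_equal(max(count_sharing(v, c2, d_kb = 5)$nf), 1L)

  # no candidates -> all zero
  c0 <- as_candidates(data.frame(individual = character(),
                                 chrom = character(), pos = numeric()))
  expect_equal(count_sharing(v, c0, d_kb = 5)$nf, rep(0L, 5))

  # chromosome mismatch is an error naming the label
  c3 <- as_candidates(data.frame(individual = "a", chrom = "chrX", pos = 1))
  expect_error(count_sharing(v, c3, d_kb = 5), "chrX")
})

test_that("sharing counts equal the brute-force double loop on random instances", {
  for (rep in 1:100) {
    set.seed(1000 + rep)
    M <- sample(20:1000, 1)
    N <- sample(1:10, 1)
    chroms <- if (rep %% 5 == 0) c("chr1", "chr2") else "chr1"
    v <- do.call(rbind, lapply(chroms, function(ch)
      data.frame(chrom = ch, pos = sort(sample.int(M * 300L, M)),
                 vid = paste0(ch, "_", seq_len(M)), maf = 0.01)))
    cands <- do.call(rbind, lapply(seq_len(N), function(i) {
      k <- sample(0:5, 1)
      if (k == 0) return(NULL)
      idx <- sample.int(nrow(v), k)
      data.frame(individual = paste0("i", i), chrom = v$chrom[idx],
                 pos = v$pos[idx])
    }))
    if (is.null(cands)) next
    cands <- as_candidates(cands)
    d_kb <- sample(c(1, 5, 20, 100), 1)
    prof <- count_sharing(v, cands, d_kb)
    expect_equal(prof$nf, as.integer(brute_nf(v, cands, d_kb)))
  }
})

test_that("N_f is monotone non-decreasing in d at every variant", {
  set.seed(5)
  v <- grid_variants(300)
  cands <- simulate_candidates(8, c(2, 6), v, seed = 5)
  nf_by_d <- sapply(c(2, 5, 10, 50, 200), function(d)
    count_sharing(v, cands, d)$nf)
  expect_true(all(diff(t(nf_by_d)) >= 0))
  expect_true(all(nf_by_d >= 0 & nf_by_d <= 8))
})

test_that("stamped coverage equals the merged-interval union length", {
  set.seed(6)
  v <- grid_variants(500)
  for (i in 1:10) {
    centers <- sort(sample(v$pos, sample(2:8, 1)))
    d_bp <- sample(c(3000, 10000, 40000), 1)
    cands <- as_candidates(data.frame(individual = "a", chrom = "chr1",
                                      pos = centers))
    prof <- count_sharing(v, cands, d_bp / 1000)
    covered <- sum(vapply(v$pos, function(p)
      any(abs(centers - p) <= d_bp), logical(1)))
    expect_equal(sum(prof$nf), covered)
  }
})

test_that("permutation null is deterministic in the seed and invariant to individual relabelling", {
  v <- grid_variants(400)
  a <- permutation_null(v, c(3, 5, 2), 20, n_perm = 200, seed = 9)
  b <- permutation_null(v, c(3, 5, 2), 20, n_perm = 200, seed = 9)
  expect_identical(a, b)
  relab <- permutation_null(v, c(5, 2, 3), 20, n_perm = 2000, seed = 9)
  # same k multiset: distributions agree within Monte-Carlo error
  big <- permutation_null(v, c(3, 5, 2), 20, n_perm = 2000, seed = 10)
  expect_true(all(abs(relab$p - big$p) <=
                    3 * sqrt(relab$se^2 + big$se^2) + 1e-12))
  expect_error(permutation_null(v, c(3, 401), 20, n_perm = 10), "exceeds")
})

test_that("null table is a proper exceedance table", {
  v <- grid_variants(300)
  nt <- permutation_null(v, rep(3, 6), 10, n_perm = 500, seed = 2)
  expect_equal(nt$p[1], 1)                  # P(N_f >= 0) = 1
  expect_true(all(diff(nt$p) <= 0))         # non-increasing in t
  expect_true(all(nt$p >= 1 / nt$n_perm & nt$p <= 1))
})

test_that("pooled null matches the hypergeometric/binomial closed form on a uniform grid", {
  # scaled-down version of the big acceptance check, multiple chromosomes of
  # parameters: enough to catch stamping or pooling errors quickly
  v <- grid_variants(2000)                  # 2 Mb at 1 kb spacing
  N <- 10; k <- 4; d_kb <- 10
  nt <- permutation_null(v, rep(k, N), d_kb, n_perm = 800, seed = 3)
  for (t in 1:3) {
    expected <- closed_form_tail(v$pos, d_kb * 1000, N, k, t)
    expect_lt(abs(nt$p[t + 1] - expected), 3 * nt$se[t + 1] + 1e-9)
  }
})

test_that("per-variant null mode draws one pseudo-N_f per sample at the target", {
  v <- grid_variants(500)
  N <- 6; k <- 3; d_kb <- 20
  nt <- permutation_null(v, rep(k, N), d_kb, n_perm = 3000, seed = 4,
                         mode = "per_variant", target_pos = 250000,
                         keep_samples = TRUE)
  draws <- attr(nt, "samples")
  expect_length(draws, 3000)
  # each individual captures the interior target with q = 1 - C(M-w,k)/C(M,k)
  M <- 500; w <- 41
  q <- 1 - exp(lchoose(M - w, k) - lchoose(M, k))
  expect_lt(abs(mean(draws) - N * q), 3 * sd(draws) / sqrt(3000))
})

test_that("empirical p-values look up N_f in the null and label the floor", {
  v <- grid_variants(200)
  cands <- simulate_candidates(6, c(2, 4), v, n_true_shared = 6,
                               true_pos = 100000, seed = 11)
  prof <- count_sharing(v, cands, 5)
  nt <- permutation_null(v, candidate_k(cands), 5, n_perm = 400, seed = 1,
                         observed = cands)
  pv <- empirical_pvalues(prof, nt)
  expect_equal(pv$p[prof$nf == 0], rep(1, sum(prof$nf == 0)))
  # equal N_f -> equal p (p depends on N_f and d only)
  expect_true(all(tapply(pv$p, pv$nf, function(x) length(unique(x))) == 1))
  # the implanted variant is at the floor, labelled as "<"
  at_max <- which.max(prof$nf)
  expect_equal(prof$nf[at_max], 6L)
  expect_match(pv$p_label[at_max], "^<")
  expect_equal(min(pv$p), 1 / 400)
  # d mismatch is refused
  expect_error(empirical_pvalues(count_sharing(v, cands, 10), nt),
               "different d_kb")
})

test_that("significance table flags the smallest significant count per d and is monotone", {
  v <- grid_variants(1500)
  k <- rep(4, 12)
  nulls <- lapply(c(5, 20, 50), function(d)
    permutation_null(v, k, d, n_perm = 600, seed = 21))
  sig <- significance_table(nulls)
  # columns non-increasing in t, rows non-decreasing in d
  expect_true(all(apply(sig$p, 2, function(col) all(diff(col) <= 0))))
  expect_true(all(apply(sig$p, 1, function(row) all(diff(row) >= 0))))
  for (j in seq_along(sig$d_kb)) {
    tf <- sig$t_flag[j]
    if (!is.na(tf)) {
      expect_lt(sig$p[tf, j], 0.05)
      if (tf > 1) expect_gte(sig$p[tf - 1, j], 0.05)
    }
  }
  expect_equal(unname(sig$n_crit), unname(pmax(sig$t_flag, 3L)))
})
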