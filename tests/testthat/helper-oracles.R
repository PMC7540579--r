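# Independent reference implementations used as oracles. These deliberately
# use the slow, direct definition of each quantity and share no code with
# the package internals.

# N_f by the O(M * N * k) double loop: for every variant, count individuals
# with at least one candidate on the same chromosome within d_kb * 1000 bp.
brute_nf <- function(variants, cands, d_kb) {
  d <- d_kb * 1000
  inds <- unique(cands$individual)
  pos_by <- lapply(inds, function(i) {
    sel <- cands$individual == i
    split(cands$pos[sel], cands$chrom[sel])
  })
  vapply(seq_len(nrow(variants)), function(v) {
    sum(vapply(pos_by, function(pb) {
      pp <- pb[[variants$chrom[v]]]
      !is.null(pp) && any(abs(pp - variants$pos[v]) <= d)
    }, logical(1)))
  }, numeric(1))
}

# Window heterozygosity by per-index recount of a single genotype vector
# (codes 0/1/NA), one chromosome.
brute_window_h <- function(x, m) {
  M <- length(x)
  h <- rep(NA_real_, M)
  if (M < 2 * m + 1) return(h)
  for (i in (m + 1):(M - m)) {
    w <- x[(i - m):(i + m)]
    nh <- sum(w == 1, na.rm = TRUE)
    ng <- sum(w == 0, na.rm = TRUE)
    if (nh + ng > 0) h[i] <- nh / (nh + ng)
  }
  h
}

# Significant runs by a naive linear scan over one chromosome.
naive_runs <- function(pos, nf, n_crit) {
  runs <- list()
  cur <- NULL
  for (i in seq_along(nf)) {
    if (nf[i] >= n_crit) {
      if (is.null(cur)) cur <- c(start = i, end = i) else cur["end"] <- i
    } else if (!is.null(cur)) {
      runs[[length(runs) + 1]] <- cur; cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  if (!length(runs))
    return(data.frame(start_pos = numeric(), end_pos = numeric(),
                      n_variants = integer(), max_nf = numeric()))
  do.call(rbind, lapply(runs, function(r) data.frame(
    start_pos = pos[r["start"]], end_pos = pos[r["end"]],
    n_variants = r["end"] - r["start"] + 1L,
    max_nf = max(nf[r["start"]:r["end"]]), row.names = NULL)))
}

# Closed-form pooled null exceedance P(N_f >= t) for a uniform variant grid
# with fixed k per individual: an individual's k uniform draws (without
# replacement) miss the w_v variants within +-d of variant v with
# probability choose(M - w_v, k) / choose(M, k), so the capture probability
# is q_v and N_f(v) ~ Binomial(N, q_v). Averaged exactly over all variants
# (w_v counted per variant, so chromosome edges are handled).
closed_form_tail <- function(pos, d_bp, N, k, t) {
  M <- length(pos)
  mean(vapply(seq_len(M), function(v) {
    w_v <- sum(abs(pos - pos[v]) <= d_bp)
    q_v <- 1 - exp(lchoose(M - w_v, k) - lchoose(M, k))
    1 - pbinom(t - 1, N, q_v)
  }, numeric(1)))
}

# Small hand-built genotype matrix: codes by row = individual.
toy_gm <- function(codes, pos = NULL, chrom = "chr1", maf = NULL,
                   ids = NULL) {
  codes <- as.matrix(codes)
  M <- ncol(codes)
  pos <- pos %||% (seq_len(M) * 100L)
  n_called <- colSums(!is.na(codes))
  maf <- maf %||% ifelse(n_called > 0,
                         pmin(colSums(codes == 1, na.rm = TRUE) / (2 * n_called), 0.5),
                         NA_real_)
  ids <- ids %||% sprintf("s%d", seq_len(nrow(codes)))
  genotype_matrix(codes, data.frame(chrom = chrom, pos = pos,
                                    vid = sprintf("v%d", seq_len(M)),
                                    maf = maf, stringsAsFactors = FALSE), ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random genotype matrix with i.i.d. codes, optionally with missing calls.
random_gm <- function(n_ind, M, p_het = 0.3, p_miss = 0, seed = 1,
                      chrom = "chr1") {
  set.seed(seed)
  codes <- matrix(rbinom(n_ind * M, 1, p_het), nrow = n_ind)
  if (p_miss > 0) codes[runif(n_ind * M) < p_miss] <- NA_integer_
  toy_gm(codes, pos = sort(sample.int(M * 200L, M)), chrom = chrom)
}
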