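#' Count individuals sharing each variant
#'
#' For every variant v, computes the sharing statistic `N_f(v)`: the number
#' of individuals having at least one candidate position c on the same
#' chromosome with `|pos(c) - pos(v)| <= d_kb * 1000` (closed interval; the
#' boundary distance counts). Each individual contributes at most 1 at any
#' variant regardless of how many of its candidates fall in the window —
#' each individual's candidate windows are merged before stamping.
#'
#' @param variants Variant table (data frame with `chrom`, `pos`), or a
#'   [genotype_matrix()] whose variant table will be used.
#' @param candidates An [as_candidates()] object.
#' @param d_kb Window half-width d in kilobases; the shared segment around a
#'   variant has width 2d.
#' @return An object of class `sharing_profile`: list with `variants`,
#'   `d_kb`, `n_individuals` (size of the candidate roster) and `nf`, an
#'   integer vector aligned to the variant table.
#' @export
count_sharing <- function(variants, candidates, d_kb) {
  variants <- as_variant_table(variants)
  stopifnot(is.numeric(d_kb), length(d_kb) == 1L, d_kb > 0)
  roster <- attr(candidates, "individuals") %||% unique(candidates$individual)
  unmatched <- setdiff(unique(candidates$chrom), unique(variants$chrom))
  if (length(unmatched))
    stop("candidate chromosome label(s) not in variant table: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  d_bp <- d_kb * 1000
  M <- nrow(variants)
  delta <- numeric(M + 1L)
  chrom_idx <- split(seq_len(M), factor(variants$chrom, levels = unique(variants$chrom)))
  by_ind <- split(candidates[c("chrom", "pos")], candidates$individual)
  for (ind in names(by_ind)) {
    cc <- by_ind[[ind]]
    for (ch in unique(cc$chrom)) {
      vidx <- chrom_idx[[ch]]
      vpos <- variants$pos[vidx]
      w <- merge_windows(cc$pos[cc$chrom == ch], d_bp)
      for (j in seq_along(w$lo)) {
        rng <- interval_index_range(vpos, w$lo[j], w$hi[j])
        if (rng[1] <= rng[2]) {
          delta[vidx[rng[1]]] <- delta[vidx[rng[1]]] + 1
          delta[vidx[rng[2]] + 1L] <- delta[vidx[rng[2]] + 1L] - 1
        }
      }
    }
  }
  nf <- as.integer(cumsum(delta[seq_len(M)]))
  structure(list(variants = variants, d_kb = d_kb,
                 n_individuals = length(roster), nf = nf),
            class = "sharing_profile")
}

as_variant_table <- function(variants) {
  if (inherits(variants, "genotype_matrix")) variants <- variants$variants
  variants <- as.data.frame(variants)
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  variants
}

#' @export
print.sharing_profile <- function(x, ...) {
  cat("<sharing_profile> d = ", x$d_kb, " kb, N = ", x$n_individuals,
      " individuals, ", length(x$nf), " variants, max N_f = ",
      max(x$nf), "\n", sep = "")
  invisible(x)
}

#' Permutation null distribution of the sharing statistic
#'
#' Builds the null in which each individual's candidate positions can fall
#' anywhere in the variant universe (the heterogeneity null of equivalence
#' testing): in every permutation sample, each individual's k candidate
#' positions are re-drawn uniformly without replacement from the variant
#' positions, independently across individuals, and the pseudo sharing
#' counts N_f are recomputed at every variant.
#'
#' In the default pooled mode the exceedance probability `P(N_f >= t)` is
#' estimated from the pseudo-N_f values pooled over all variants and
#' samples, giving one p per (t, d) as in a genome-wide significance table.
#' In `mode = "per_variant"` the pseudo-N_f is recorded at a single target
#' variant only, one value per permutation sample.
#'
#' If `observed` candidate sets are supplied they are counted as one of the
#' `n_perm` samples, so the smallest attainable p is `1 / n_perm`; without
#' them `n_perm` random samples are drawn and p is still floored at
#' `1 / n_perm`.
#'
#' @param variants Variant table (or [genotype_matrix()]).
#' @param k_per_individual Integer vector: number of candidate positions per
#'   individual (its length is N).
#' @param d_kb Window half-width in kb.
#' @param n_perm Number of permutation samples, including the observed data
#'   when supplied; default 10000.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param observed Optional [as_candidates()] object counted as one sample.
#' @param mode `"pooled"` (default) or `"per_variant"`.
#' @param target_pos,target_chrom Target variant for `mode = "per_variant"`.
#' @param keep_samples Keep the per-sample exceedance fractions (pooled
#'   mode) or pseudo-N_f draws (per-variant mode) in the `samples`
#'   attribute; default FALSE.
#' @return An object of class `null_table`: list with `d_kb`, `n_perm`,
#'   `mode`, `thresholds` (0..N), `p` (non-increasing, in
#'   `[1/n_perm, 1]`, `p[t=0] = 1`), `se` (Monte-Carlo standard error of
#'   each p) and `sd` (between-sample standard deviation of the exceedance
#'   fraction, the sampling scale of one data set's worth of variants).
#' @export
permutation_null <- function(variants, k_per_individual, d_kb,
                             n_perm = 10000, seed = 1, observed = NULL,
                             mode = c("pooled", "per_variant"),
                             target_pos = NULL, target_chrom = NULL,
                             keep_samples = FALSE) {
  mode <- match.arg(mode)
  variants <- as_variant_table(variants)
  k <- as.integer(k_per_individual)
  N <- length(k)
  M <- nrow(variants)
  stopifnot(n_perm >= 2, d_kb > 0, N >= 1)
  if (any(k > M))
    stop("k (", max(k), ") exceeds the number of variants (", M, ")",
         call. = FALSE)
  d_bp <- d_kb * 1000
  set.seed(as.integer(seed))
  n_draw <- if (is.null(observed)) n_perm else n_perm - 1L
  chroms <- factor(variants$chrom, levels = unique(variants$chrom))
  chrom_id <- as.integer(chroms)
  chrom_idx <- split(seq_len(M), chroms)
  pos <- variants$pos

  if (mode == "per_variant") {
    if (is.null(target_pos))
      stop("mode = 'per_variant' needs target_pos", call. = FALSE)
    target_chrom <- target_chrom %||% levels(chroms)[1]
    tch <- match(target_chrom, levels(chroms))
    pseudo <- integer(n_draw)
    pk <- k[k > 0]
    for (s in seq_len(n_draw)) {
      cnt <- 0L
      for (ki in pk) {
        draw <- sample.int(M, ki)
        if (any(chrom_id[draw] == tch & abs(pos[draw] - target_pos) <= d_bp))
          cnt <- cnt + 1L
      }
      pseudo[s] <- cnt
    }
    if (!is.null(observed)) {
      op <- count_sharing(variants, observed, d_kb)
      vi <- which(chrom_id == tch & pos == target_pos)
      if (!length(vi)) stop("target_pos is not a variant position", call. = FALSE)
      pseudo <- c(op$nf[vi[1]], pseudo)
    }
    thresholds <- 0:N
    exceed <- vapply(thresholds, function(t) mean(pseudo >= t), numeric(1))
    p <- pmin(1, pmax(exceed, 1 / n_perm))
    se <- sqrt(pmax(exceed * (1 - exceed), 0) / length(pseudo))
    nt <- structure(list(d_kb = d_kb, n_perm = n_perm, mode = mode,
                         n_individuals = N, thresholds = thresholds,
                         p = p, se = se, sd = se * sqrt(length(pseudo))),
                    class = "null_table")
    if (keep_samples) attr(nt, "samples") <- pseudo
    return(nt)
  }

  # pooled mode: per-sample fraction of variants with pseudo-N_f >= t
  frac <- matrix(0, nrow = n_draw, ncol = N)
  pk <- k[k > 0]
  for (s in seq_len(n_draw)) {
    delta <- numeric(M + 1L)
    for (ki in pk) {
      draw <- sample.int(M, ki)
      for (ch in unique(chrom_id[draw])) {
        vidx <- chrom_idx[[ch]]
        vpos <- pos[vidx]
        w <- merge_windows(pos[draw[chrom_id[draw] == ch]], d_bp)
        for (j in seq_along(w$lo)) {
          rng <- interval_index_range(vpos, w$lo[j], w$hi[j])
          if (rng[1] <= rng[2]) {
            delta[vidx[rng[1]]] <- delta[vidx[rng[1]]] + 1
            delta[vidx[rng[2]] + 1L] <- delta[vidx[rng[2]] + 1L] - 1
          }
        }
      }
    }
    nf <- cumsum(delta[seq_len(M)])
    tab <- tabulate(nf, nbins = N)
    frac[s, ] <- rev(cumsum(rev(tab))) / M
  }
  if (!is.null(observed)) {
    op <- count_sharing(variants, observed, d_kb)
    tab <- tabulate(op$nf, nbins = N)
    frac <- rbind(rev(cumsum(rev(tab))) / M, frac)
  }
  exceed <- colMeans(frac)
  p <- c(1, pmin(1, pmax(exceed, 1 / n_perm)))
  sd_s <- apply(frac, 2, sd)
  nt <- structure(list(d_kb = d_kb, n_perm = n_perm, mode = mode,
                       n_individuals = N, thresholds = 0:N,
                       p = p, se = c(0, sd_s / sqrt(nrow(frac))),
                       sd = c(0, sd_s)),
                  class = "null_table")
  if (keep_samples) attr(nt, "samples") <- frac
  nt
}

#' @export
print.null_table <- function(x, ...) {
  cat("<null_table> d = ", x$d_kb, " kb, n_perm = ", x$n_perm,
      ", mode = ", x$mode, "\n", sep = "")
  print(data.frame(N_f = x$thresholds, p = signif(x$p, 4)), row.names = FALSE)
  invisible(x)
}

#' Empirical p-values for observed sharing counts
#'
#' Looks each variant's observed `N_f` up in the permutation null: `p(v)` is
#' the estimated null probability of a pseudo-N_f at least as large. The
#' smallest attainable value is `1 / n_perm`; such values should be read as
#' "< 1/n_perm" and are labelled that way in the `p_label` column.
#'
#' @param profile A `sharing_profile` from [count_sharing()].
#' @param null A `null_table` from [permutation_null()] with the same
#'   `d_kb`.
#' @return Data frame with columns `chrom`, `pos`, `nf`, `p`, `p_label`,
#'   one row per variant.
#' @export
empirical_pvalues <- function(profile, null) {
  stopifnot(inherits(profile, "sharing_profile"), inherits(null, "null_table"))
  if (!isTRUE(all.equal(profile$d_kb, null$d_kb)))
    stop("profile and null were computed with different d_kb (",
         profile$d_kb, " vs ", null$d_kb, ")", call. = FALSE)
  # counts beyond the tabulated range take the floor value
  t_idx <- pmin(profile$nf, max(null$thresholds)) + 1L
  p <- null$p[t_idx]
  floor_p <- 1 / null$n_perm
  lab <- format(p, digits = 4, scientific = FALSE, trim = TRUE)
  at_floor <- p <= floor_p
  lab[at_floor] <- paste0("<", format(floor_p, scientific = FALSE, trim = TRUE))
  data.frame(chrom = profile$variants$chrom, pos = profile$variants$pos,
             nf = profile$nf, p = p, p_label = lab, stringsAsFactors = FALSE)
}

#' Significance table over a grid of window half-widths
#'
#' Assembles the p(t, d) matrix of null exceedance probabilities — one
#' column per half-width d, rows t = 1..N — and flags, per column, the
#' smallest sharing count t whose p-value falls below `alpha` (the
#' bold-cell convention: the largest p below the significance level).
#' `N_crit(d)` is that t floored at `floor`.
#'
#' @param nulls List of `null_table` objects, one per d (pooled mode).
#' @param alpha Significance level, default 0.05.
#' @param floor Minimum admissible `N_crit`, default 3.
#' @return An object of class `sgs_sig_table`: list with `d_kb`, matrix `p`
#'   (rows t, columns d), `t_flag` (smallest significant t per d, NA if
#'   none) and `n_crit`.
#' @export
significance_table <- function(nulls, alpha = 0.05, floor = 3) {
  if (inherits(nulls, "null_table")) nulls <- list(nulls)
  stopifnot(length(nulls) >= 1, all(vapply(nulls, inherits, TRUE, "null_table")))
  d_kb <- vapply(nulls, function(x) x$d_kb, numeric(1))
  o <- order(d_kb)
  nulls <- nulls[o]; d_kb <- d_kb[o]
  tmax <- max(vapply(nulls, function(x) max(x$thresholds), numeric(1)))
  p <- matrix(NA_real_, nrow = tmax, ncol = length(nulls),
              dimnames = list(N_f = 1:tmax, d_kb = d_kb))
  for (j in seq_along(nulls)) {
    nt <- nulls[[j]]
    idx <- pmin(1:tmax, max(nt$thresholds)) + 1L
    p[, j] <- nt$p[idx]
  }
  t_flag <- apply(p, 2, function(col) {
    hit <- which(col < alpha)
    if (length(hit)) hit[1] else NA_integer_
  })
  n_crit <- ifelse(is.na(t_flag), NA_integer_, pmax(as.integer(t_flag), floor))
  structure(list(d_kb = d_kb, p = p, alpha = alpha, floor = floor,
                 t_flag = t_flag, n_crit = n_crit),
            class = "sgs_sig_table")
}

#' @export
print.sgs_sig_table <- function(x, ...) {
  cat("<sgs_sig_table> alpha = ", x$alpha, ", N_crit floor = ", x$floor,
      "\n", sep = "")
  print(signif(x$p, 4))
  cat("N_crit:", paste0("d=", x$d_kb, ":", x$n_crit, collapse = "  "), "\n")
  invisible(x)
}

#' Write a significance table as TSV
#'
#' @param sig_table An `sgs_sig_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sig_table <- function(sig_table, path) {
  df <- data.frame(N_f = seq_len(nrow(sig_table$p)), sig_table$p,
                   check.names = FALSE)
  names(df) <- c("N_f", paste0("d", sig_table$d_kb))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
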