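#' Sliding-window average heterozygosity for one individual
#'
#' Slides a window of `2m + 1` adjacent variants along each chromosome and
#' computes, at every interior variant, the average heterozygosity
#' `H = h / (g + h)` where `h` and `g` count the individual's heterozygous
#' and homozygous genotypes in the window. Missing genotypes are excluded
#' from both counts (they shrink the denominator); `H` is undefined (NA)
#' where `g + h = 0`. The first and last `m` variants of each chromosome
#' have no `H` value. Variants close to a rare dominant disease allele show
#' a heterozygote excess, so `H` peaks near such an allele in carriers.
#'
#' @param gm A [genotype_matrix()].
#' @param individual Sample identifier present in `gm$individuals`.
#' @param m Window half-width in variants (window is `2m + 1` wide);
#'   default 50.
#' @return An object of class `h_profile`: a list with `individual`, `m`,
#'   the variant table, and `h` — a numeric vector aligned to the variants,
#'   NA outside the defined range. Chromosomes with fewer than `2m + 1`
#'   variants are skipped with a warning.
#' @export
window_heterozygosity <- function(gm, individual, m = 50) {
  stopifnot(inherits(gm, "genotype_matrix"), m >= 1)
  m <- as.integer(m)
  row_i <- match(individual, gm$individuals)
  if (is.na(row_i)) stop("individual '", individual, "' not in genotype matrix",
                         call. = FALSE)
  x <- gm$codes[row_i, ]
  h <- rep(NA_real_, length(x))
  for (ch in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == ch)
    len <- length(idx)
    if (len < 2L * m + 1L) {
      warning("chromosome ", ch, " has ", len, " variants (< 2m+1 = ",
              2L * m + 1L, "); skipped", call. = FALSE)
      next
    }
    xc <- x[idx]
    cs_h <- cumsum(c(0L, !is.na(xc) & xc == GT_HET))
    cs_g <- cumsum(c(0L, !is.na(xc) & xc == GT_HOM))
    ctr <- (m + 1L):(len - m)
    nh <- cs_h[ctr + m + 1L] - cs_h[ctr - m]
    ng <- cs_g[ctr + m + 1L] - cs_g[ctr - m]
    denom <- nh + ng
    hv <- ifelse(denom > 0, nh / denom, NA_real_)
    h[idx[ctr]] <- hv
  }
  structure(list(individual = as.character(individual), m = m,
                 variants = gm$variants, h = h),
            class = "h_profile")
}

#' @export
print.h_profile <- function(x, ...) {
  cat("<h_profile> individual ", x$individual, ", m = ", x$m, ", ",
      sum(!is.na(x$h)), "/", length(x$h), " defined H values\n", sep = "")
  invisible(x)
}

#' Detect peaks of window heterozygosity
#'
#' Partitions the profile into maximal segments in which `H` is
#' non-decreasing up to a peak and non-increasing after it, then keeps the
#' segments with at least `min_rise` strict increases before the peak, at
#' least `min_fall` strict decreases after it, and a prominence (peak `H`
#' minus the larger endpoint `H`) of at least `min_prominence`. Window
#' averages change slowly, so plateaus are common: non-strict monotonicity
#' is allowed within a segment and the peak position is the first variant
#' of the maximal-`H` plateau. Consecutive segments may share their
#' boundary variant. Variants with undefined `H` are excluded before
#' segmentation.
#'
#' @param hp An `h_profile` from [window_heterozygosity()].
#' @param min_rise Minimum number of strict increases before the peak
#'   (default 3).
#' @param min_fall Minimum number of strict decreases after the peak
#'   (default 3).
#' @param min_prominence Minimum peak prominence in H units (default 0.1).
#' @return Data frame with one row per retained segment: `individual`,
#'   `chrom`, `start_pos`, `end_pos`, `peak_pos`, `peak_h`, `n_rise`,
#'   `n_fall`, `prominence`. May have zero rows.
#' @export
detect_hmax_segments <- function(hp, min_rise = 3, min_fall = 3,
                                 min_prominence = 0.1) {
  stopifnot(inherits(hp, "h_profile"))
  out <- list()
  for (ch in unique(hp$variants$chrom)) {
    vidx <- which(hp$variants$chrom == ch)
    def <- vidx[!is.na(hp$h[vidx])]
    if (length(def) < 3L) next
    hv <- hp$h[def]
    segs <- unimodal_segments(hv)
    if (!nrow(segs)) next
    keep <- segs$n_rise >= min_rise & segs$n_fall >= min_fall &
      segs$prominence >= min_prominence
    segs <- segs[keep, , drop = FALSE]
    if (!nrow(segs)) next
    out[[ch]] <- data.frame(
      individual = hp$individual, chrom = ch,
      start_pos = hp$variants$pos[def[segs$a]],
      end_pos = hp$variants$pos[def[segs$b]],
      peak_pos = hp$variants$pos[def[segs$peak]],
      peak_h = segs$peak_h,
      n_rise = segs$n_rise, n_fall = segs$n_fall,
      prominence = segs$prominence,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(individual = character(), chrom = character(),
                      start_pos = numeric(), end_pos = numeric(),
                      peak_pos = numeric(), peak_h = numeric(),
                      n_rise = integer(), n_fall = integer(),
                      prominence = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Split a numeric sequence into maximal rise-then-fall segments.
# Boundaries fall at direction changes from down to up; trailing flat steps
# after a fall belong to the earlier segment, and adjacent segments share
# the boundary point. Returns point indices a (start), peak, b (end) plus
# counts of strict up/down steps and the prominence.
unimodal_segments <- function(hv) {
  n <- length(hv)
  s <- sign(diff(hv))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bounds <- integer(0)
  phase_fall <- FALSE
  for (j in seq_along(r$values)) {
    v <- r$values[j]
    if (v == 0) next
    if (v > 0 && phase_fall) {
      bounds <- c(bounds, starts[j])   # rise restarts at point starts[j]
      phase_fall <- FALSE
    } else if (v < 0) phase_fall <- TRUE
  }
  a <- c(1L, bounds)
  b <- c(bounds, n)
  peak <- integer(length(a)); peak_h <- numeric(length(a))
  n_rise <- integer(length(a)); n_fall <- integer(length(a))
  prom <- numeric(length(a))
  for (i in seq_along(a)) {
    seg <- hv[a[i]:b[i]]
    pm <- max(seg)
    pk <- a[i] - 1L + which(seg == pm)[1]
    peak[i] <- pk; peak_h[i] <- pm
    n_rise[i] <- if (pk > a[i]) sum(s[a[i]:(pk - 1L)] == 1) else 0L
    n_fall[i] <- if (pk < b[i]) sum(s[pk:(b[i] - 1L)] == -1) else 0L
    prom[i] <- pm - max(hv[a[i]], hv[b[i]])
  }
  data.frame(a = a, b = b, peak = peak, peak_h = peak_h,
             n_rise = n_rise, n_fall = n_fall, prominence = prom)
}

#' Scan all individuals for candidate disease-variant positions
#'
#' Runs [window_heterozygosity()] and [detect_hmax_segments()] for every
#' individual and collects the peak positions into one candidate set per
#' individual. The per-individual candidate counts k and the total are
#' attached as the `k_summary` attribute.
#'
#' @inheritParams window_heterozygosity
#' @inheritParams detect_hmax_segments
#' @return An [as_candidates()] object over the full individual roster
#'   (individuals without any segment contribute k = 0), with attribute
#'   `segments` holding the full segment table.
#' @export
scan_all <- function(gm, m = 50, min_rise = 3, min_fall = 3,
                     min_prominence = 0.1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  segs <- vector("list", length(gm$individuals))
  for (i in seq_along(gm$individuals)) {
    hp <- window_heterozygosity(gm, gm$individuals[i], m = m)
    segs[[i]] <- detect_hmax_segments(hp, min_rise = min_rise,
                                      min_fall = min_fall,
                                      min_prominence = min_prominence)
  }
  seg_tab <- do.call(rbind, segs)
  cands <- as_candidates(
    data.frame(individual = seg_tab$individual, chrom = seg_tab$chrom,
               pos = seg_tab$peak_pos, peak_h = seg_tab$peak_h,
               stringsAsFactors = FALSE),
    individuals = gm$individuals)
  k <- candidate_k(cands)
  attr(cands, "k_summary") <- list(k = k, total = sum(k), mean = mean(k))
  attr(cands, "segments") <- seg_tab
  cands
}
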