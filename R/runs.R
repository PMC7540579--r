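#' Runs of consecutive significantly shared variants
#'
#' Scans the variants in position order within each chromosome and returns
#' every maximal run of consecutive variants whose sharing count `N_f` is at
#' least `n_crit`; a run breaks at any variant below the threshold or at a
#' chromosome boundary. Adjacency is strict (no gap tolerance). A run's
#' length is the bp span between its first and last variant, so a
#' single-variant run has length 0 but still counts towards the number of
#' runs `N_r`.
#'
#' @param profile A `sharing_profile` from [count_sharing()].
#' @param n_crit Run-inclusion threshold (smallest significant sharing
#'   count), `>= 1`.
#' @return An object of class `sgs_runs`: a data frame with columns
#'   `chrom`, `start_pos`, `end_pos`, `n_variants`, `max_nf`, `length_kb`,
#'   plus attributes `n_crit`, `n_runs` (N_r), `n_var` (total variants at or
#'   above threshold) and `l_avg_kb` (mean run length, NA when no runs).
#' @export
find_runs <- function(profile, n_crit) {
  stopifnot(inherits(profile, "sharing_profile"),
            is.numeric(n_crit), length(n_crit) == 1L, n_crit >= 1)
  out <- list()
  for (ch in unique(profile$variants$chrom)) {
    idx <- which(profile$variants$chrom == ch)
    hit <- profile$nf[idx] >= n_crit
    if (!any(hit)) next
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    out[[ch]] <- data.frame(
      chrom = ch,
      start_pos = profile$variants$pos[idx[starts[sel]]],
      end_pos = profile$variants$pos[idx[ends[sel]]],
      n_variants = r$lengths[sel],
      max_nf = vapply(sel, function(j)
        max(profile$nf[idx[starts[j]:ends[j]]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  runs <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start_pos = numeric(),
               end_pos = numeric(), n_variants = integer(),
               max_nf = numeric(), stringsAsFactors = FALSE)
  rownames(runs) <- NULL
  runs$length_kb <- (runs$end_pos - runs$start_pos) / 1000
  structure(runs, class = c("sgs_runs", "data.frame"),
            n_crit = n_crit, n_runs = nrow(runs),
            n_var = sum(runs$n_variants),
            l_avg_kb = if (nrow(runs)) mean(runs$length_kb) else NA_real_)
}

#' @export
print.sgs_runs <- function(x, ...) {
  cat("<sgs_runs> N_r = ", attr(x, "n_runs"), " runs at N_crit = ",
      attr(x, "n_crit"), "; N_var = ", attr(x, "n_var"),
      "; L_avg = ", signif(attr(x, "l_avg_kb"), 4), " kb\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Select the run-inclusion threshold N_crit for a half-width d
#'
#' `N_crit(d)` is the smallest sharing count t with `p(t, d)` below the
#' significance level, floored at `floor` (default 3) so that runs are
#' never driven by fewer than `floor` individuals.
#'
#' @param sig_table An `sgs_sig_table` from [significance_table()].
#' @param d_kb The half-width whose column to use; must be in the table.
#' @param floor Minimum admissible value, default 3.
#' @return Integer N_crit.
#' @export
select_n_crit <- function(sig_table, d_kb, floor = 3) {
  stopifnot(inherits(sig_table, "sgs_sig_table"))
  j <- match(d_kb, sig_table$d_kb)
  if (is.na(j))
    stop("d = ", d_kb, " kb not in significance table (available: ",
         paste(sig_table$d_kb, collapse = ", "), ")", call. = FALSE)
  hit <- which(sig_table$p[, j] < sig_table$alpha)
  if (!length(hit))
    stop("no sharing count reaches p < ", sig_table$alpha, " at d = ", d_kb,
         " kb; consider more individuals or a smaller d", call. = FALSE)
  max(floor, hit[1])
}

#' Flag runs overlapping a region of interest
#'
#' Marks each run whose closed interval intersects the region (touching
#' endpoints count as overlap) — e.g. a disease gene extended by a flank —
#' and reports the overlapping runs' lengths.
#'
#' @param runs An `sgs_runs` table from [find_runs()].
#' @param roi Region of interest: a `chrom:start-end` string or a list with
#'   `chrom`, `start_pos`, `end_pos` (see [parse_region()]).
#' @return `runs` with a logical `in_roi` column added; the lengths of
#'   overlapping runs are in the `roi_lengths_kb` attribute.
#' @export
overlap_regions <- function(runs, roi) {
  roi <- parse_region(roi)
  df <- as.data.frame(runs)
  in_roi <- if (nrow(df)) df$chrom == roi$chrom &
    df$start_pos <= roi$end_pos & df$end_pos >= roi$start_pos else logical(0)
  runs$in_roi <- in_roi
  attr(runs, "roi") <- roi
  attr(runs, "roi_lengths_kb") <- df$length_kb[in_roi]
  runs
}

#' Write runs and a run-index summary as TSV
#'
#' The summary mirrors a run-index plot: consecutive run number, the
#' maximum number of individuals N in the run, and (when present) the
#' region-of-interest flag.
#'
#' @param runs An `sgs_runs` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_runs <- function(runs, path) {
  df <- as.data.frame(runs)
  df <- cbind(run = seq_len(nrow(df)), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
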