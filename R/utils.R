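`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a genomic region string
#'
#' Converts `"chr17:40077143-42185502"` (1-based, closed) into a region list
#' usable as a region of interest in [overlap_regions()].
#'
#' @param x Region string `chrom:start-end`, or a list/data.frame already
#'   holding `chrom`, `start_pos`, `end_pos`.
#' @return A list with elements `chrom`, `start_pos`, `end_pos`.
#' @examples
#' parse_region("chr17:40077143-42185502")
#' @export
parse_region <- function(x) {
  if (is.list(x)) {
    reg <- list(chrom = as.character(x$chrom),
                start_pos = as.numeric(x$start_pos %||% x$start),
                end_pos = as.numeric(x$end_pos %||% x$end))
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
    if (length(m) != 4L)
      stop("cannot parse region '", x, "'; expected chrom:start-end", call. = FALSE)
    reg <- list(chrom = m[2], start_pos = as.numeric(m[3]), end_pos = as.numeric(m[4]))
  }
  if (!(reg$start_pos < reg$end_pos))
    stop("region start must be < end", call. = FALSE)
  reg
}

# First (smallest) index i with v[i] >= lo, and last index j with v[j] <= hi,
# for a sorted numeric vector v of integral positions; closed interval.
interval_index_range <- function(v, lo, hi) {
  i <- findInterval(lo - 0.5, v) + 1L
  j <- findInterval(hi + 0.5, v)
  c(i, j)
}

# Merge overlapping closed intervals given sorted centre positions and a
# half-width; returns two vectors lo, hi of disjoint intervals.
merge_windows <- function(centers, halfwidth) {
  centers <- sort(centers)
  lo <- centers - halfwidth
  hi <- centers + halfwidth
  if (length(centers) <= 1L) return(list(lo = lo, hi = hi))
  keep_lo <- lo[1]
  out_lo <- numeric(0); out_hi <- numeric(0)
  cur_hi <- hi[1]
  for (i in seq_along(centers)[-1]) {
    if (lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      out_lo <- c(out_lo, keep_lo); out_hi <- c(out_hi, cur_hi)
      keep_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  list(lo = c(out_lo, keep_lo), hi = c(out_hi, cur_hi))
}
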