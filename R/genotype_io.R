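# Genotype codes used throughout: 0 = HOM (either homozygote), 1 = HET,
# NA = missing. Only het/hom status matters to the heterozygosity scan, so
# hom-ref and hom-alt are deliberately collapsed.
GT_HOM <- 0L
GT_HET <- 1L

#' Construct a genotype matrix object
#'
#' A `genotype_matrix` holds diploid genotypes coded as HOM/HET/missing for
#' `n` individuals at `M` variants, together with a variant table
#' (`chrom`, `pos`, `vid`, `maf`). Positions are 1-based base pairs and
#' strictly increasing within each chromosome.
#'
#' @param codes Integer matrix, individuals x variants, entries 0 (HOM),
#'   1 (HET) or NA (missing).
#' @param variants Data frame with columns `chrom`, `pos`, `vid`, `maf`.
#' @param individuals Character vector of sample identifiers (row order of
#'   `codes`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, variants, individuals) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  stopifnot(nrow(codes) == length(individuals),
            ncol(codes) == nrow(variants),
            all(c("chrom", "pos", "vid", "maf") %in% names(variants)))
  bad <- codes[!is.na(codes) & !(codes %in% c(GT_HOM, GT_HET))]
  if (length(bad))
    stop("genotype codes must be 0 (HOM), 1 (HET) or NA", call. = FALSE)
  if (any(variants$maf < 0 | variants$maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]", call. = FALSE)
  norm <- normalise_variants(variants, codes)
  structure(list(codes = norm$codes, variants = norm$variants,
                 individuals = as.character(individuals)),
            class = "genotype_matrix")
}

# Sort variants by (chromosome in order of first appearance, position) and
# drop duplicate (chrom, pos) records keeping the first; both with a warning,
# since the scan needs a strictly ordered position vector.
normalise_variants <- function(variants, codes) {
  variants <- as.data.frame(variants)
  rownames(variants) <- NULL
  lv <- unique(variants$chrom)
  o <- order(match(variants$chrom, lv), variants$pos)
  if (any(o != seq_along(o))) {
    warning("variant positions not sorted; sorting by (chrom, pos)", call. = FALSE)
    variants <- variants[o, , drop = FALSE]
    codes <- codes[, o, drop = FALSE]
    rownames(variants) <- NULL
  }
  dup <- duplicated(variants[c("chrom", "pos")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (chrom, pos) record(s); keeping first occurrence",
            call. = FALSE)
    variants <- variants[!dup, , drop = FALSE]
    codes <- codes[, !dup, drop = FALSE]
    rownames(variants) <- NULL
  }
  list(variants = variants, codes = codes)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$individuals), " individuals x ",
      nrow(x$variants), " variants on ",
      length(unique(x$variants$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$individuals), nrow(x$variants))

# Classify diploid GT strings ("0/1", "1|0", "./.", ".") into codes.
# Any missing allele -> NA; two identical called alleles -> HOM; two distinct
# called alleles -> HET (multi-allelic sites included). Errors on non-diploid
# calls, naming the first offending record.
classify_gt_matrix <- function(gt, chrom, pos) {
  vals <- as.vector(gt)
  u <- unique(vals)
  codes_u <- integer(length(u))
  for (i in seq_along(u)) {
    g <- u[i]
    if (is.na(g) || g == "." || g == "") { codes_u[i] <- NA_integer_; next }
    al <- strsplit(chartr("|", "/", g), "/", fixed = TRUE)[[1]]
    if (length(al) != 2L) {
      hit <- which(gt == g, arr.ind = TRUE)[1, ]
      stop("non-diploid genotype '", g, "' at variant ", chrom[hit[1]], ":",
           pos[hit[1]], call. = FALSE)
    }
    codes_u[i] <- if (any(al %in% c(".", ""))) NA_integer_
                  else if (al[1] == al[2]) GT_HOM else GT_HET
  }
  code <- codes_u[match(vals, u)]
  matrix(code, nrow = nrow(gt), dimnames = dimnames(gt))
}

# Allele-dosage MAF per variant from raw GT strings (variants x samples):
# collapse all alternate alleles, maf = min(p_alt, 1 - p_alt). Missing
# alleles excluded from the denominator.
gt_maf <- function(gt) {
  vals <- as.vector(gt)
  u <- unique(vals)
  called_u <- integer(length(u)); alt_u <- integer(length(u))
  for (i in seq_along(u)) {
    g <- u[i]
    if (is.na(g) || g == "" || g == ".") next
    al <- strsplit(chartr("|", "/", g), "/", fixed = TRUE)[[1]]
    ok <- !(al %in% c(".", ""))
    called_u[i] <- sum(ok)
    alt_u[i] <- sum(ok & al != "0")
  }
  idx <- match(vals, u)
  called <- matrix(called_u[idx], nrow = nrow(gt))
  alt <- matrix(alt_u[idx], nrow = nrow(gt))
  n_called <- rowSums(called)
  n_alt <- rowSums(alt)
  p <- ifelse(n_called > 0, n_alt / n_called, NA_real_)
  pmin(p, 1 - p)
}

#' Read a multi-sample genotype file
#'
#' Reads diploid genotypes from a VCF 4.x file (plain or gzip-compressed) or
#' from the package's TSV genotype dialect, classifies each call as HOM
#' (two identical alleles), HET (two distinct alleles) or missing (any
#' missing allele), and computes the minor allele frequency of every variant
#' from the loaded sample. Phasing is ignored. Unsorted positions are sorted
#' with a warning; duplicate (chrom, pos) records keep the first occurrence.
#'
#' For VCF input the MAF is the allele-dosage frequency (all alternate
#' alleles collapsed, missing alleles excluded from the denominator). The TSV
#' dialect carries het/hom codes only, so its MAF is estimated as
#' `#HET / (2 * #called)` — exact whenever no individual is homozygous for
#' the minor allele, which holds for the rare variants this method targets.
#'
#' The TSV dialect is: a header row `chrom pos id <sample ids...>`, then one
#' row per variant with codes 0 = HOM, 1 = HET, 9 = missing.
#'
#' @param path Path to the genotype file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  switch(format, vcf = read_genotypes_vcf(path), tsv = read_genotypes_tsv(path))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  vid <- as.character(fix[, "ID"])
  vid[is.na(vid) | vid == "."] <- paste0(chrom, ":", pos)[is.na(vid) | vid == "."]
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path, call. = FALSE)
  codes_vm <- classify_gt_matrix(gt, chrom, pos)     # variants x samples
  maf <- gt_maf(gt)
  variants <- data.frame(chrom = chrom, pos = pos, vid = vid, maf = maf,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(codes_vm), variants, colnames(gt))
}

read_genotypes_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L || !identical(names(df)[1:3], c("chrom", "pos", "id")))
    stop("TSV genotype dialect needs columns chrom, pos, id, then sample columns: ",
         path, call. = FALSE)
  samples <- names(df)[-(1:3)]
  codes_vm <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(codes_vm) <- "integer"
  if (any(!is.na(codes_vm) & !(codes_vm %in% c(0L, 1L, 9L))))
    stop("TSV genotype codes must be 0 (HOM), 1 (HET) or 9 (missing): ", path,
         call. = FALSE)
  codes_vm[codes_vm == 9L] <- NA_integer_
  n_called <- rowSums(!is.na(codes_vm))
  n_het <- rowSums(codes_vm == 1L, na.rm = TRUE)
  maf <- ifelse(n_called > 0, n_het / (2 * n_called), NA_real_)
  variants <- data.frame(chrom = as.character(df$chrom), pos = as.integer(df$pos),
                         vid = as.character(df$id), maf = pmin(maf, 0.5),
                         stringsAsFactors = FALSE)
  genotype_matrix(t(codes_vm), variants, samples)
}

#' Write a genotype matrix
#'
#' `write_genotypes_tsv()` writes the package's TSV genotype dialect;
#' `write_genotypes_vcf()` writes a minimal single-allele-pair VCF rendering
#' (HOM is emitted as `0/0`, HET as `0/1`, missing as `./.`; REF/ALT are
#' placeholder bases since only het/hom status is represented).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(gm, path) {
  codes_vm <- t(gm$codes)
  codes_vm[is.na(codes_vm)] <- 9L
  df <- data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos,
                   id = gm$variants$vid, codes_vm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("chrom", "pos", "id", gm$individuals)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$individuals), collapse = "\t")), con)
  gt_str <- matrix("./.", nrow = nrow(gm$variants), ncol = length(gm$individuals))
  codes_vm <- t(gm$codes)
  gt_str[!is.na(codes_vm) & codes_vm == GT_HOM] <- "0/0"
  gt_str[!is.na(codes_vm) & codes_vm == GT_HET] <- "0/1"
  body <- paste(gm$variants$chrom, gm$variants$pos, gm$variants$vid, "A", "C",
                ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Filter variants on polymorphism and allele frequency
#'
#' Removes monomorphic variants (`maf == 0`) and then common variants with
#' `maf > maf_max` (strict inequality, so a variant at exactly `maf_max` is
#' retained). The counts removed at each step are attached as the
#' `filter_counts` attribute for logging. The filter is idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param maf_max Maximum minor allele frequency retained, in `(0, 0.5]`.
#'   Default 0.05.
#' @return The filtered [genotype_matrix()], with attribute `filter_counts`
#'   (a list: `n_input`, `n_monomorphic`, `n_common`, `n_retained`).
#' @export
filter_variants <- function(gm, maf_max = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"),
            is.numeric(maf_max), length(maf_max) == 1L,
            maf_max > 0, maf_max <= 0.5)
  maf <- gm$variants$maf
  mono <- !is.na(maf) & maf == 0
  common <- !mono & !is.na(maf) & maf > maf_max
  keep <- !mono & !common & !is.na(maf)
  if (!any(keep))
    stop("all variants removed by filtering; review maf_max (", maf_max, ")",
         call. = FALSE)
  out <- gm
  out$variants <- gm$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$codes <- gm$codes[, keep, drop = FALSE]
  attr(out, "filter_counts") <- list(n_input = length(maf),
                                     n_monomorphic = sum(mono),
                                     n_common = sum(common),
                                     n_retained = sum(keep))
  out
}

#' Candidate disease-variant positions per individual
#'
#' A candidate set holds, for each individual, the genomic positions of its
#' window-heterozygosity peaks (the candidate dominant disease-variant
#' locations). It is represented as a long data frame with columns
#' `individual`, `chrom`, `pos`, `peak_h`, sorted by (individual, chrom,
#' pos), with the full individual roster (including zero-candidate
#' individuals) kept in the `individuals` attribute.
#'
#' @param df Data frame with columns `individual`, `chrom`, `pos` and
#'   optionally `peak_h`.
#' @param individuals Optional full roster of sample identifiers; defaults to
#'   the individuals present in `df`.
#' @return An object of class `sgs_candidates` (a data frame).
#' @export
as_candidates <- function(df, individuals = NULL) {
  df <- as.data.frame(df)
  need <- c("individual", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("candidates need columns individual, chrom, pos", call. = FALSE)
  if (is.null(df$peak_h)) df$peak_h <- rep(NA_real_, nrow(df))
  df <- df[c("individual", "chrom", "pos", "peak_h")]
  df$individual <- as.character(df$individual)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df <- df[order(df$individual, df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  individuals <- as.character(individuals %||% unique(df$individual))
  if (!all(df$individual %in% individuals))
    stop("candidate rows reference individuals absent from the roster", call. = FALSE)
  structure(df, class = c("sgs_candidates", "data.frame"),
            individuals = individuals)
}

#' Number of candidates per individual
#'
#' @param cands An [as_candidates()] object.
#' @return Named integer vector of k values over the full roster (zeros for
#'   individuals with no candidate).
#' @export
candidate_k <- function(cands) {
  roster <- attr(cands, "individuals") %||% unique(cands$individual)
  k <- table(factor(cands$individual, levels = roster))
  setNames(as.integer(k), roster)
}

#' Write / read candidate sets as TSV
#'
#' The on-disk format is a TSV with columns `individual`, `chrom`, `pos`,
#' `peak_H`; the header is written even for an empty candidate list.
#' `read_candidates(write_candidates(x))` returns `x` up to the roster of
#' zero-candidate individuals, which the file cannot represent.
#'
#' @param cands An [as_candidates()] object.
#' @param path File path.
#' @return `write_candidates()` returns `path` invisibly; `read_candidates()`
#'   returns an [as_candidates()] object.
#' @export
write_candidates <- function(cands, path) {
  df <- as.data.frame(cands)
  names(df) <- c("individual", "chrom", "pos", "peak_H")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("individual", "chrom", "pos", "peak_H")
  if (!all(need %in% names(df)))
    stop("candidates file needs columns ", paste(need, collapse = ", "),
         ": ", path, call. = FALSE)
  pos <- suppressWarnings(as.numeric(df$pos))
  ph <- suppressWarnings(as.numeric(ifelse(df$peak_H %in% c("NA", ""), NA, df$peak_H)))
  bad <- which(is.na(pos))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, " of ", path,
         " (pos not numeric)", call. = FALSE)
  as_candidates(data.frame(individual = df$individual, chrom = df$chrom,
                           pos = pos, peak_h = ph, stringsAsFactors = FALSE))
}

#' Write significant runs as BED
#'
#' Converts 1-based closed run intervals to BED's 0-based half-open
#' convention (`start - 1`, `end`). The score column carries the maximum
#' sharing count in the run.
#'
#' @param runs A run table from [find_runs()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_runs_bed <- function(runs, path) {
  df <- as.data.frame(runs)
  bed <- data.frame(chrom = df$chrom,
                    start = as.integer(df$start_pos) - 1L,
                    end = as.integer(df$end_pos),
                    name = paste0("run", seq_len(nrow(df))),
                    score = df$max_nf)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
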