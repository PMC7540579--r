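#' Run the full shared-genomic-segment pipeline
#'
#' Wires the stages together: obtain genotypes (simulate, or read from
#' file), filter variants, scan each individual for heterozygosity peaks
#' (skipped when precomputed candidates are supplied), compute sharing
#' counts and the permutation null over a grid of half-widths d, build the
#' significance table, select `N_crit` and extract significant runs,
#' optionally flagging those overlapping a region of interest. All tables
#' are written as TSV (runs additionally as BED) together with a JSON
#' manifest recording the package version, parameters, input checksums and
#' output checksums; re-running with the same inputs and seed reproduces
#' the outputs bit for bit.
#'
#' @param out_dir Output directory (created if absent).
#' @param genotypes A [genotype_matrix()] or path to a VCF/TSV genotype
#'   file; ignored when `candidates` is supplied.
#' @param sim A [sim_config()]; used to simulate genotypes when `genotypes`
#'   is NULL.
#' @param candidates An [as_candidates()] object or candidates TSV path;
#'   when supplied, the simulate/scan stages are skipped.
#' @param m Window half-width in variants for the heterozygosity scan.
#' @param maf_max MAF filter threshold (strict removal above it).
#' @param min_rise,min_fall,min_prominence Peak-detection thresholds, see
#'   [detect_hmax_segments()].
#' @param d_grid_kb Grid of half-widths d in kb.
#' @param d_run_kb The d used for run extraction; default 50 if on the
#'   grid, else the grid median.
#' @param n_perm Number of permutation samples (the observed data counts as
#'   one of them).
#' @param seed Integer seed for the permutation null.
#' @param n_crit_floor Floor for N_crit, default 3.
#' @param roi Optional region of interest (`chrom:start-end` or list).
#' @param alpha Significance level, default 0.05.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `candidates`, `profiles`, `nulls`,
#'   `sig_table`, `n_crit`, `runs`, `manifest` and the filter accounting.
#' @export
sgs_pipeline <- function(out_dir, genotypes = NULL, sim = NULL,
                         candidates = NULL, m = 50, maf_max = 0.05,
                         min_rise = 3, min_fall = 3, min_prominence = 0.1,
                         d_grid_kb = c(2, 5, 10, 20, 50, 100, 200, 500),
                         d_run_kb = NULL, n_perm = 10000, seed = 1,
                         n_crit_floor = 3, roi = NULL, alpha = 0.05,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  input_files <- character(0)
  accounting <- NULL

  if (is.null(candidates)) {
    if (is.character(genotypes)) {
      input_files <- c(input_files, genotypes)
      say("reading genotypes from ", genotypes)
      gm <- read_genotypes(genotypes)
    } else if (inherits(genotypes, "genotype_matrix")) {
      gm <- genotypes
    } else if (!is.null(sim)) {
      say("simulating genotypes (M = ", sim$n_variants, ", N = ",
          sim$n_carriers, ")")
      gm <- simulate_genotypes(sim)
    } else {
      stop("supply genotypes, sim, or candidates", call. = FALSE)
    }
    n0 <- nrow(gm$variants)
    gm <- filter_variants(gm, maf_max = maf_max)
    fc <- attr(gm, "filter_counts")
    accounting <- data.frame(step = c("loaded", "after monomorphic filter",
                                      "after MAF filter"),
                             n_variants = c(fc$n_input,
                                            fc$n_input - fc$n_monomorphic,
                                            fc$n_retained))
    say("variants: ", n0, " loaded, ", fc$n_monomorphic, " monomorphic and ",
        fc$n_common, " common (MAF > ", maf_max, ") removed, ",
        fc$n_retained, " retained")
    variants <- gm$variants
    say("scanning ", length(gm$individuals), " individuals (m = ", m, ")")
    candidates <- scan_all(gm, m = m, min_rise = min_rise,
                           min_fall = min_fall,
                           min_prominence = min_prominence)
  } else {
    if (is.character(candidates)) {
      input_files <- c(input_files, candidates)
      candidates <- read_candidates(candidates)
    }
    if (is.character(genotypes)) {
      input_files <- c(input_files, genotypes)
      genotypes <- read_genotypes(genotypes)
    }
    if (inherits(genotypes, "genotype_matrix")) {
      variants <- filter_variants(genotypes, maf_max = maf_max)$variants
    } else if (!is.null(sim)) {
      variants <- simulate_genotypes(sim)$variants
    } else {
      stop("precomputed candidates still need a variant universe: ",
           "supply genotypes or sim", call. = FALSE)
    }
  }
  k <- candidate_k(candidates)
  say("candidates: total k = ", sum(k), " over ", length(k),
      " individuals (mean ", round(mean(k), 1), ")")
  write_candidates(candidates, file.path(out_dir, "candidates.tsv"))

  profiles <- list(); nulls <- list()
  for (d in d_grid_kb) {
    say("d = ", d, " kb: sharing counts + ", n_perm, " permutation samples")
    prof <- count_sharing(variants, candidates, d)
    null <- permutation_null(variants, k, d, n_perm = n_perm, seed = seed,
                             observed = candidates)
    pv <- empirical_pvalues(prof, null)
    write.table(pv, file.path(out_dir, sprintf("sharing_d%g.tsv", d)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    profiles[[as.character(d)]] <- prof
    nulls[[as.character(d)]] <- null
  }
  sig <- significance_table(nulls, alpha = alpha, floor = n_crit_floor)
  write_sig_table(sig, file.path(out_dir, "sigtable.tsv"))

  d_run_kb <- d_run_kb %||% (if (50 %in% d_grid_kb) 50 else
    d_grid_kb[ceiling(length(d_grid_kb) / 2)])
  n_crit <- select_n_crit(sig, d_run_kb, floor = n_crit_floor)
  runs <- find_runs(profiles[[as.character(d_run_kb)]], n_crit)
  if (!is.null(roi)) runs <- overlap_regions(runs, roi)
  say("d = ", d_run_kb, " kb: N_crit = ", n_crit, ", N_r = ",
      attr(runs, "n_runs"), " runs, N_var = ", attr(runs, "n_var"))
  write_runs(runs, file.path(out_dir, "runs.tsv"))
  write_runs_bed(runs, file.path(out_dir, "runs.bed"))
  if (!is.null(accounting))
    write.table(accounting, file.path(out_dir, "accounting.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- write_manifest(out_dir, input_files, params = list(
    m = m, maf_max = maf_max, min_rise = min_rise, min_fall = min_fall,
    min_prominence = min_prominence, d_grid_kb = d_grid_kb,
    d_run_kb = d_run_kb, n_perm = n_perm, seed = seed,
    n_crit_floor = n_crit_floor, alpha = alpha,
    roi = if (is.null(roi)) NULL else parse_region(roi)))
  invisible(list(candidates = candidates, profiles = profiles,
                 nulls = nulls, sig_table = sig, n_crit = n_crit,
                 runs = runs, accounting = accounting, manifest = manifest))
}

# One manifest per output directory: version, parameters, checksums.
write_manifest <- function(out_dir, input_files, params) {
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    tool = "segshare",
    version = as.character(packageVersion("segshare")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = params,
    inputs = if (length(input_files))
      as.list(tools::md5sum(input_files)) else list(),
    outputs = as.list(setNames(unname(tools::md5sum(file.path(out_dir, outputs))),
                               outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
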