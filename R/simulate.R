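#' Simulation configuration for carrier genotype matrices
#'
#' Describes a synthetic chromosome of rare variants carried by N affected
#' individuals, with a dominant disease variant implanted at `disease_pos`.
#' Away from the disease position, a variant with population minor allele
#' frequency f is heterozygous with the Hardy-Weinberg probability
#' `2 f (1 - f)`. Within `elevation_halfwidth_bp` of the disease position,
#' carriers are heterozygous with probability `p_het_near`, which must
#' exceed `1 - max(maf_range)` — the heterozygote-excess inequality
#' `P(H) > 1 - f` that holds for variants flanking a rare dominant allele.
#' Genotypes are independent across variants (no linkage disequilibrium):
#' the sharing method works one variant at a time and does not appeal to
#' LD, so correctness tests do not require it.
#'
#' @param n_variants Number of variants M on the chromosome.
#' @param chrom_length_bp Chromosome length L in bp.
#' @param spacing `"uniform_grid"` (evenly spaced) or `"uniform_random"`
#'   (positions drawn uniformly without replacement).
#' @param chrom Chromosome label, default `"chr1"`.
#' @param n_carriers Number of affected carriers N.
#' @param maf_range Range of per-variant population minor allele
#'   frequencies f, drawn uniformly; must lie in (0, 0.05].
#' @param disease_pos Implanted disease-variant position in bp; defaults to
#'   the chromosome midpoint. `NA` disables the implant (pure null).
#' @param elevation_halfwidth_bp Half-width w of the heterozygote-excess
#'   zone around `disease_pos`, default 1 Mb.
#' @param p_het_near Heterozygosity probability inside the zone, default 1.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_variants = 20000, chrom_length_bp = 2e7,
                       spacing = c("uniform_grid", "uniform_random"),
                       chrom = "chr1", n_carriers = 5,
                       maf_range = c(0.001, 0.05), disease_pos = NULL,
                       elevation_halfwidth_bp = 1e6, p_het_near = 1,
                       seed = 1) {
  spacing <- match.arg(spacing)
  disease_pos <- disease_pos %||% round(chrom_length_bp / 2)
  cfg <- list(n_variants = as.integer(n_variants),
              chrom_length_bp = chrom_length_bp, spacing = spacing,
              chrom = chrom, n_carriers = as.integer(n_carriers),
              maf_range = maf_range, disease_pos = disease_pos,
              elevation_halfwidth_bp = elevation_halfwidth_bp,
              p_het_near = p_het_near, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_variants < 1 || n_variants > chrom_length_bp)
      stop("need 1 <= n_variants <= chrom_length_bp", call. = FALSE)
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.05 ||
        maf_range[1] > maf_range[2])
      stop("maf_range must lie in (0, 0.05] with min <= max", call. = FALSE)
    if (p_het_near < 0 || p_het_near > 1)
      stop("p_het_near must be a probability", call. = FALSE)
    if (!is.na(disease_pos)) {
      if (p_het_near <= 1 - maf_range[2])
        stop("p_het_near (", p_het_near, ") must exceed 1 - max f (",
             1 - maf_range[2], "): no heterozygote excess otherwise",
             call. = FALSE)
      if (elevation_halfwidth_bp <= 0 || elevation_halfwidth_bp >= chrom_length_bp)
        stop("need 0 < elevation_halfwidth_bp < chrom_length_bp", call. = FALSE)
      if (disease_pos < 1 || disease_pos > chrom_length_bp)
        stop("disease_pos outside the chromosome", call. = FALSE)
    }
    if (n_carriers < 1) stop("need n_carriers >= 1", call. = FALSE)
  })
  invisible(cfg)
}

#' Simulate a carrier genotype matrix with an implanted dominant variant
#'
#' Draws variant positions and per-variant population frequencies f per the
#' configuration, then samples each carrier's genotype at each variant
#' independently: HET with probability `p_het_near` within the
#' heterozygote-excess zone around the disease position, else with the
#' background probability `2 f (1 - f)`; HOM otherwise. The variant table's
#' `maf` column carries the generating population frequency f (the truth),
#' not a carrier-sample estimate: near the disease position the engineered
#' heterozygote excess would inflate a carriers-only estimate and a
#' frequency filter would strip the very signal under study, whereas real
#' analyses estimate MAF from the full population sample.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] of `n_carriers` individuals
#'   (`carrier_01..`), with attribute `truth` recording `disease_pos` and
#'   `halfwidth_bp`. Deterministic given `cfg$seed`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  M <- cfg$n_variants
  pos <- if (cfg$spacing == "uniform_grid") {
    step <- cfg$chrom_length_bp / M
    as.integer(round(step * seq_len(M)))
  } else sort(sample.int(cfg$chrom_length_bp, M))
  f <- runif(M, cfg$maf_range[1], cfg$maf_range[2])
  p_het <- 2 * f * (1 - f)
  if (!is.na(cfg$disease_pos)) {
    near <- abs(pos - cfg$disease_pos) <= cfg$elevation_halfwidth_bp
    p_het[near] <- cfg$p_het_near
  }
  N <- cfg$n_carriers
  codes <- matrix(rbinom(N * M, 1L, rep(p_het, each = N)), nrow = N)
  ids <- sprintf("carrier_%02d", seq_len(N))
  variants <- data.frame(chrom = cfg$chrom, pos = pos,
                         vid = sprintf("v%06d", seq_len(M)), maf = f,
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(codes, variants, ids)
  attr(gm, "truth") <- list(disease_pos = cfg$disease_pos,
                            halfwidth_bp = cfg$elevation_halfwidth_bp)
  gm
}

#' Simulate candidate-position sets directly
#'
#' Draws, for each individual, k ~ uniform over `k_range` candidate
#' positions uniformly without replacement from the variant positions —
#' the heterogeneity null in which candidates can fall anywhere. The first
#' `n_true_shared` individuals additionally receive one candidate at a
#' variant within `true_halfwidth_bp` of `true_pos` (the nearest variant
#' when the window contains none or when the half-width is 0), implanting
#' a shared signal.
#'
#' @param n_individuals Number of individuals.
#' @param k_range Length-2 integer range of per-individual candidate counts.
#' @param variants Variant table (or [genotype_matrix()]).
#' @param n_true_shared How many individuals share the implanted candidate;
#'   default 0 (pure null). Must not exceed `n_individuals`.
#' @param true_pos Implanted position in bp (required when
#'   `n_true_shared > 0`).
#' @param true_halfwidth_bp Scatter of the implanted candidates around
#'   `true_pos`, default 0.
#' @param seed Integer seed.
#' @return An [as_candidates()] object. Deterministic given `seed`.
#' @export
simulate_candidates <- function(n_individuals, k_range, variants,
                                n_true_shared = 0, true_pos = NULL,
                                true_halfwidth_bp = 0, seed = 1) {
  variants <- as_variant_table(variants)
  M <- nrow(variants)
  k_range <- as.integer(k_range)
  stopifnot(length(k_range) == 2L, k_range[1] >= 0, k_range[2] <= M,
            k_range[1] <= k_range[2])
  if (n_true_shared > n_individuals)
    stop("n_true_shared (", n_true_shared, ") exceeds n_individuals (",
         n_individuals, ")", call. = FALSE)
  if (n_true_shared > 0 && is.null(true_pos))
    stop("true_pos required when n_true_shared > 0", call. = FALSE)
  set.seed(as.integer(seed))
  ids <- sprintf("ind_%03d", seq_len(n_individuals))
  rows <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    k <- if (k_range[1] == k_range[2]) k_range[1] else
      sample(k_range[1]:k_range[2], 1L)
    idx <- if (k > 0) sample.int(M, k) else integer(0)
    if (i <= n_true_shared) {
      elig <- which(abs(variants$pos - true_pos) <= true_halfwidth_bp)
      if (!length(elig)) elig <- which.min(abs(variants$pos - true_pos))
      extra <- if (length(elig) == 1L) elig else sample(elig, 1L)
      idx <- unique(c(idx, extra))
    }
    if (length(idx))
      rows[[i]] <- data.frame(individual = ids[i],
                              chrom = variants$chrom[idx],
                              pos = variants$pos[idx],
                              peak_h = round(runif(length(idx), 0.55, 0.95), 3),
                              stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(individual = character(), chrom = character(),
                     pos = numeric(), peak_h = numeric(),
                     stringsAsFactors = FALSE)
  as_candidates(df, individuals = ids)
}
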