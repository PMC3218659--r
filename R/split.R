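#' Split a panel into two subpopulations by SNP allele
#'
#' Rows carrying allele 0 at the SNP go to the first subpanel, allele 1 to
#' the second; sizes sum to the panel size.
#'
#' @param panel A [haplotype_panel()].
#' @param snp SNP column index; must be polymorphic.
#' @return List with elements `panel0`, `panel1` (both `haplotype_panel`) and
#'   `sides` (integer vector, the allele of each input row).
#' @export
split_by_allele <- function(panel, snp) {
  stopifnot(inherits(panel, "haplotype_panel"))
  col <- panel$haplotypes[, snp]
  if (all(col == col[1L]))
    stop("SNP column ", snp, " is monomorphic; cannot split")
  list(panel0 = subset_panel(panel, rows = which(col == 0L)),
       panel1 = subset_panel(panel, rows = which(col == 1L)),
       sides = col)
}

#' Normalized hotspot strength difference
#'
#' `delta_rho = (rho0 - rho1) / (rho0 + rho1)`, the difference of hotspot
#' strengths normalized by their sum; 0 when both strengths are 0.
#' Antisymmetric in its arguments and bounded in `[-1, 1]`.
#'
#' @param rho0,rho1 Nonnegative hotspot strengths.
#' @return Value in `[-1, 1]`.
#' @export
delta_rho <- function(rho0, rho1) {
  if (any(rho0 < 0) || any(rho1 < 0)) stop("strengths must be nonnegative")
  s <- rho0 + rho1
  ifelse(s == 0, 0, (rho0 - rho1) / s)
}

#' Candidate SNPs for a hotspot
#'
#' SNPs inside the hotspot plus at most `span_snps` SNPs beyond each boundary,
#' restricted to minor allele frequency at least `maf_min` (the MAF floor is
#' needed for the smaller allele subpopulation to support rate estimation).
#' Monomorphic columns are never candidates.
#'
#' @param panel A [haplotype_panel()].
#' @param hotspot A one-row data frame (or list) with `start` and `end` in bp.
#' @param maf_min MAF threshold (default 0.3).
#' @param span_snps Number of SNPs considered beyond each boundary
#'   (default 200).
#' @return Integer vector of SNP column indices.
#' @export
candidate_snps <- function(panel, hotspot, maf_min = 0.3, span_snps = 200L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  pos <- panel$snps$position
  inside <- which(pos >= hotspot$start & pos < hotspot$end)
  left <- which(pos < hotspot$start)
  right <- which(pos >= hotspot$end)
  left <- utils::tail(left, span_snps)
  right <- utils::head(right, span_snps)
  idx <- c(left, inside, right)
  maf <- minor_allele_freq(panel, idx)
  idx[maf >= maf_min & !panel$snps$monomorphic[idx]]
}

# side assignment for one random split; returns 0/1 vector over rows
.random_sides <- function(n, min_fraction, mode = c("ideal", "fifty_fifty"),
                          sizes = NULL, individual_ids = NULL,
                          keep_pairs = FALSE) {
  mode <- match.arg(mode)
  lo <- ceiling(min_fraction * n)
  hi <- floor((1 - min_fraction) * n)
  if (lo > hi)
    stop("min_fraction ", min_fraction, " infeasible for ", n, " chromosomes")
  if (!is.null(sizes)) {
    n1 <- sizes[2L]
    stopifnot(sizes[1L] + sizes[2L] == n)
  } else if (mode == "fifty_fifty") {
    n1 <- floor(n / 2)
  } else {
    n1 <- sample(seq.int(lo, hi), 1L)
  }
  sides <- integer(n)
  if (keep_pairs) {
    if (is.null(individual_ids))
      stop("keep_pairs requires individual ids")
    inds <- unique(individual_ids)
    if (n1 %% 2L != 0L) n1 <- n1 + 1L
    pick <- sample(inds, n1 / 2L)
    sides[individual_ids %in% pick] <- 1L
  } else {
    sides[sample.int(n, n1)] <- 1L
  }
  sides
}

#' Random balanced split of a panel
#'
#' Uniformly random split into two subsamples, each containing at least
#' `min_fraction` of the chromosomes.  Under the default `"ideal"` mode the
#' smaller-side size is drawn uniformly over all feasible sizes; the
#' `"fifty_fifty"` mode splits into halves, and `keep_pairs` keeps the two
#' homologous chromosomes of each individual on the same side.
#'
#' @param panel A [haplotype_panel()] with at least 4 chromosomes.
#' @param min_fraction Minimum fraction of chromosomes per side (default 0.3).
#' @param mode `"ideal"` or `"fifty_fifty"`.
#' @param sizes Optional `c(n0, n1)` forcing the two side sizes.
#' @param keep_pairs Permute homologous chromosomes of one individual
#'   together.
#' @return As [split_by_allele()]: `panel0`, `panel1`, `sides`.  Reproducible
#'   under a fixed RNG seed.
#' @export
random_split <- function(panel, min_fraction = 0.3,
                         mode = c("ideal", "fifty_fifty"), sizes = NULL,
                         keep_pairs = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- nrow(panel$haplotypes)
  if (n < 4L) stop("panel too small to split")
  sides <- .random_sides(n, min_fraction, mode, sizes,
                         panel$individual_ids, keep_pairs)
  list(panel0 = subset_panel(panel, rows = which(sides == 0L)),
       panel1 = subset_panel(panel, rows = which(sides == 1L)),
       sides = sides)
}
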