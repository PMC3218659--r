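#' Construct a phased haplotype panel
#'
#' The universal input container: a phased, biallelic 0/1 haplotype matrix with
#' one row per chromosome and one column per SNP, plus per-SNP metadata.
#'
#' @param haplotypes Integer matrix of 0/1 values; rows are chromosomes,
#'   columns are SNPs.  No missing entries are allowed: the method assumes a
#'   complete phased panel, and silent imputation would bias the strength
#'   contrast between allele subpopulations.
#' @param positions Integer vector of 1-based physical positions, strictly
#'   increasing, one per column.
#' @param snp_ids Optional character vector of SNP identifiers.
#' @param allele0,allele1 Optional character vectors naming the two alleles
#'   (nucleotides or symbolic "0"/"1").
#' @param ancestral_state Optional character vector with entries in
#'   `c("allele0", "allele1", "unknown")`, used by the derived-allele
#'   temperature tabulation.
#' @param chromosome_ids Optional character vector of per-row chromosome
#'   labels (unique).
#' @param individual_ids Optional character vector of per-row individual
#'   labels; the two homologous chromosomes of one diploid individual share a
#'   label.  Defaults to pairing consecutive rows.
#' @param chrom_name Name of the chromosome/region the panel covers.
#'
#' @return An object of class `haplotype_panel`: a list with elements
#'   `haplotypes`, `snps` (data frame of SNP metadata), `chromosome_ids`,
#'   `individual_ids` and `chrom_name`.  Monomorphic columns are retained but
#'   flagged in `snps$monomorphic`; they are excluded from candidate-SNP and
#'   r-squared computations downstream.
#' @export
#' @examples
#' h <- matrix(c(0L,0L,1L,1L, 0L,1L,0L,1L, 1L,1L,0L,0L), nrow = 4)
#' p <- haplotype_panel(h, positions = c(100L, 220L, 305L))
#' p
haplotype_panel <- function(haplotypes, positions, snp_ids = NULL,
                            allele0 = NULL, allele1 = NULL,
                            ancestral_state = NULL,
                            chromosome_ids = NULL, individual_ids = NULL,
                            chrom_name = "chr") {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (anyNA(haplotypes))
    stop("haplotype matrix contains missing entries; panels must be complete")
  if (!all(haplotypes %in% c(0L, 1L)))
    stop("haplotype matrix must contain only 0/1 (biallelic, phased)")
  if (nrow(haplotypes) < 1L)
    stop("a panel needs at least 1 chromosome")
  dimnames(haplotypes) <- NULL
  L <- ncol(haplotypes)
  positions <- as.integer(positions)
  if (length(positions) != L)
    stop("positions must have one entry per SNP column")
  if (any(positions <= 0L))
    stop("positions must be positive (1-based)")
  if (L > 1L && any(diff(positions) <= 0L))
    stop("SNP positions must be strictly increasing")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(L))
  if (is.null(allele0)) allele0 <- rep("0", L)
  if (is.null(allele1)) allele1 <- rep("1", L)
  if (any(allele0 == allele1))
    stop("allele0 and allele1 must differ at every site (biallelic only)")
  if (is.null(ancestral_state)) ancestral_state <- rep("unknown", L)
  stopifnot(all(ancestral_state %in% c("allele0", "allele1", "unknown")))
  n <- nrow(haplotypes)
  if (is.null(chromosome_ids))
    chromosome_ids <- paste0("hap", seq_len(n))
  if (anyDuplicated(chromosome_ids))
    stop("chromosome_ids must be unique per row")
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", rep(seq_len(ceiling(n / 2)), each = 2L))[seq_len(n)]
  counts <- colSums(haplotypes)
  snps <- data.frame(
    snp_id = as.character(snp_ids),
    position = positions,
    allele0 = as.character(allele0),
    allele1 = as.character(allele1),
    ancestral_state = as.character(ancestral_state),
    monomorphic = counts == 0L | counts == n,
    stringsAsFactors = FALSE
  )
  structure(
    list(haplotypes = haplotypes, snps = snps,
         chromosome_ids = as.character(chromosome_ids),
         individual_ids = as.character(individual_ids),
         chrom_name = chrom_name),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Phased haplotype panel (", x$chrom_name, ")\n", sep = "")
  cat("  chromosomes: ", nrow(x$haplotypes),
      "  (", length(unique(x$individual_ids)), " individuals)\n", sep = "")
  cat("  SNPs: ", ncol(x$haplotypes),
      "  [", sum(x$snps$monomorphic), " monomorphic in panel]\n", sep = "")
  cat("  span: ", x$snps$position[1L], "-",
      x$snps$position[nrow(x$snps)], " bp\n", sep = "")
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$haplotypes)

#' Subset a panel by chromosomes (rows) and/or SNPs (columns)
#'
#' @param panel A [haplotype_panel()].
#' @param rows,cols Index vectors (integer or logical) into chromosomes and
#'   SNPs respectively; `NULL` keeps everything.
#' @return A `haplotype_panel` with the selected rows/columns.  Monomorphic
#'   flags are recomputed on the subset.
#' @export
subset_panel <- function(panel, rows = NULL, cols = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.null(rows)) rows <- seq_len(nrow(panel$haplotypes))
  if (is.null(cols)) cols <- seq_len(ncol(panel$haplotypes))
  haplotype_panel(
    panel$haplotypes[rows, cols, drop = FALSE],
    positions = panel$snps$position[cols],
    snp_ids = panel$snps$snp_id[cols],
    allele0 = panel$snps$allele0[cols],
    allele1 = panel$snps$allele1[cols],
    ancestral_state = panel$snps$ancestral_state[cols],
    chromosome_ids = panel$chromosome_ids[rows],
    individual_ids = panel$individual_ids[rows],
    chrom_name = panel$chrom_name
  )
}

#' Minor allele frequency of one SNP column
#'
#' @param panel A [haplotype_panel()].
#' @param snp SNP column index.
#' @return `min(f, 1 - f)` where `f` is the mean of the 0/1 column; a value in
#'   `[0, 0.5]`.  Invariant under relabeling the two alleles.
#' @export
minor_allele_freq <- function(panel, snp) {
  stopifnot(inherits(panel, "haplotype_panel"))
  snp <- as.integer(snp)
  if (any(snp < 1L | snp > ncol(panel$haplotypes)))
    stop("snp index out of range")
  f <- colMeans(panel$haplotypes[, snp, drop = FALSE])
  unname(pmin(f, 1 - f))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Computes `D^2 / (p_a (1-p_a) p_b (1-p_b))` from phased haplotype
#' frequencies, where `D` is the haplotype-frequency covariance between the
#' two 0/1 columns.  Symmetric in its arguments and invariant to row order.
#'
#' @param panel A [haplotype_panel()].
#' @param a,b SNP column indices; both must be polymorphic in the panel.
#' @return r-squared in `[0, 1]`.
#' @export
r_squared <- function(panel, a, b) {
  stopifnot(inherits(panel, "haplotype_panel"))
  xa <- panel$haplotypes[, a]
  xb <- panel$haplotypes[, b]
  pa <- mean(xa); pb <- mean(xb)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("r_squared undefined for monomorphic columns")
  D <- mean(xa * xb) - pa * pb
  unname(D^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

#' Greedy LD-block (tag SNP) selection
#'
#' Clusters SNPs into LD blocks by the greedy maximal-bin rule: repeatedly take
#' the SNP that covers the most yet-unassigned SNPs at `r^2 >=` the threshold
#' as the tag of a new block, assign those SNPs to it, and continue until every
#' SNP is assigned.  Blocks partition the input set and every member has
#' `r^2 >=` threshold with its tag.
#'
#' @param panel A [haplotype_panel()].
#' @param snp_set Integer vector of SNP column indices to cluster
#'   (monomorphic columns are dropped with a warning).
#' @param r2_threshold LD threshold in `(0, 1]`; the conventional value for
#'   tag-SNP de-duplication is 0.8.
#' @return A list of blocks, each a list with elements `tag_snp` (column
#'   index) and `member_snps` (integer vector including the tag).
#' @export
select_ld_blocks <- function(panel, snp_set, r2_threshold = 0.8) {
  stopifnot(inherits(panel, "haplotype_panel"),
            length(snp_set) > 0L, r2_threshold > 0, r2_threshold <= 1)
  snp_set <- as.integer(unique(snp_set))
  mono <- panel$snps$monomorphic[snp_set]
  if (any(mono)) {
    warning("dropping ", sum(mono), " monomorphic SNPs from LD clustering")
    snp_set <- snp_set[!mono]
  }
  if (length(snp_set) == 0L) return(list())
  m <- length(snp_set)
  # full r^2 matrix over the set; set sizes here are small (per-hotspot pools)
  X <- panel$haplotypes[, snp_set, drop = FALSE]
  p <- colMeans(X)
  Dm <- crossprod(X) / nrow(X) - tcrossprod(p)
  denom <- tcrossprod(sqrt(p * (1 - p)))
  r2 <- (Dm / denom)^2
  covered <- r2 >= r2_threshold
  diag(covered) <- TRUE
  unassigned <- rep(TRUE, m)
  blocks <- list()
  while (any(unassigned)) {
    cover_counts <- colSums(covered & unassigned)
    cover_counts[!unassigned] <- -1L
    tag <- which.max(cover_counts)   # ties: smallest index, deterministic
    members <- which(unassigned & covered[, tag])
    unassigned[members] <- FALSE
    blocks[[length(blocks) + 1L]] <- list(
      tag_snp = snp_set[tag],
      member_snps = snp_set[members]
    )
  }
  blocks
}

#' Drop low-MAF columns from a panel
#'
#' Convenience filter used by the simulation benchmarks: rare variants carry
#' little linkage-disequilibrium information relative to their cost in the
#' copying-model likelihood, so benchmark panels are thinned to a MAF floor
#' before rate estimation.  Columns listed in `keep_cols` (e.g. a causal SNP)
#' are always retained, and a `"truth"` attribute, when present, has its
#' causal column index remapped.
#'
#' @param panel A [haplotype_panel()].
#' @param maf_min MAF floor (default 0.05).
#' @param keep_cols Column indices exempt from the filter.
#' @return The thinned `haplotype_panel`.
#' @export
filter_low_maf <- function(panel, maf_min = 0.05, keep_cols = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  truth <- attr(panel, "truth")
  if (!is.null(truth) && !is.na(truth$causal_col))
    keep_cols <- c(keep_cols, truth$causal_col)
  maf <- minor_allele_freq(panel, seq_len(ncol(panel$haplotypes)))
  keep <- sort(unique(c(which(maf >= maf_min), keep_cols)))
  out <- subset_panel(panel, cols = keep)
  if (!is.null(truth)) {
    if (!is.na(truth$causal_col))
      truth$causal_col <- match(truth$causal_col, keep)
    attr(out, "truth") <- truth
  }
  out
}
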