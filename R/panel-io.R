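#' Read a phased haplotype panel from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`matrix_tsv`}{Tab-separated 0/1 matrix, rows = chromosomes.  The
#'     canonical dialect written by [write_panel()] has a first column
#'     `chromosome_id` and remaining columns named `<snp_id>@<position>`; a
#'     bare headerless 0/1 matrix is also accepted, with synthetic ids and
#'     unit-spaced positions.}
#'   \item{`hapmap_phased`}{Phased-haplotype text: a header row of chromosome
#'     ids preceded by `rsID position a0 a1`, then one row per SNP carrying
#'     the two alleles and one 0/1 value per chromosome.  Transposed on load.}
#'   \item{`vcf`}{Phased VCF (parsed with \pkg{vcfR}).  Every genotype must be
#'     phased (`|` separator) and biallelic; violations are rejected with the
#'     offending locus named.}
#' }
#'
#' @param path File path.
#' @param format One of `"matrix_tsv"`, `"hapmap_phased"`, `"vcf"`.
#' @return A [haplotype_panel()].
#' @export
load_panel <- function(path, format = c("matrix_tsv", "hapmap_phased", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         matrix_tsv = .load_matrix_tsv(path),
         hapmap_phased = .load_hapmap_phased(path),
         vcf = .load_vcf(path))
}

#' Write a haplotype panel to disk
#'
#' @param panel A [haplotype_panel()].
#' @param path Output file path.
#' @param format `"matrix_tsv"` (canonical dialect, round-trips exactly) or
#'   `"vcf"` (plain-text VCFv4.2 with phased genotypes).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("matrix_tsv", "vcf")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  format <- match.arg(format)
  switch(format,
         matrix_tsv = .write_matrix_tsv(panel, path),
         vcf = .write_vcf(panel, path))
  invisible(path)
}

.load_matrix_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chromosome_id", first, fixed = TRUE)
  if (has_header) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- df[[1L]]
    mat <- as.matrix(df[, -1L, drop = FALSE])
    parts <- strsplit(colnames(mat), "@", fixed = TRUE)
    snp_ids <- vapply(parts, `[`, "", 1L)
    positions <- as.integer(vapply(parts, `[`, "", 2L))
    if (anyNA(positions))
      stop("matrix_tsv header columns must be named <snp_id>@<position>")
    haplotype_panel(mat, positions = positions, snp_ids = snp_ids,
                    chromosome_ids = ids)
  } else {
    mat <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
    haplotype_panel(mat, positions = seq_len(ncol(mat)))
  }
}

.write_matrix_tsv <- function(panel, path) {
  mat <- panel$haplotypes
  colnames(mat) <- paste0(panel$snps$snp_id, "@", panel$snps$position)
  df <- data.frame(chromosome_id = panel$chromosome_ids, mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.load_hapmap_phased <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[1L], "[ \t]+")[[1L]]
  if (length(header) < 5L || header[1L] != "rsID")
    stop("hapmap_phased header must start with: rsID position a0 a1 <ids...>")
  ids <- header[-(1:4)]
  body <- strsplit(lines[-1L], "[ \t]+")
  L <- length(body)
  snp_ids <- character(L); positions <- integer(L)
  a0 <- character(L); a1 <- character(L)
  mat <- matrix(NA_integer_, nrow = length(ids), ncol = L)
  for (j in seq_len(L)) {
    f <- body[[j]]
    if (length(f) != 4L + length(ids))
      stop("hapmap_phased row ", j, " has ", length(f), " fields, expected ",
           4L + length(ids))
    snp_ids[j] <- f[1L]; positions[j] <- as.integer(f[2L])
    a0[j] <- f[3L]; a1[j] <- f[4L]
    v <- f[-(1:4)]
    x <- integer(length(v))
    x[v == a1[j]] <- 1L
    bad <- !(v %in% c("0", "1", a0[j], a1[j]))
    if (any(bad))
      stop("unrecognized allele '", v[which(bad)[1L]], "' at SNP ", snp_ids[j])
    x[v == "1"] <- 1L
    mat[, j] <- x
  }
  haplotype_panel(mat, positions = positions, snp_ids = snp_ids,
                  allele0 = a0, allele1 = a1, chromosome_ids = ids)
}

#' @importFrom vcfR read.vcfR
.load_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multiallelic site at ", fix[which(multi)[1L], "CHROM"], ":",
         fix[which(multi)[1L], "POS"], "; biallelic records only")
  gt <- vcfR::extract.gt(v, element = "GT")
  unphased <- grepl("/", gt, fixed = TRUE)
  dim(unphased) <- dim(gt)
  if (any(unphased)) {
    idx <- which(unphased, arr.ind = TRUE)[1L, ]
    stop("unphased genotype at ", fix[idx[1L], "CHROM"], ":",
         fix[idx[1L], "POS"], " sample ", colnames(gt)[idx[2L]],
         "; panels must be fully phased")
  }
  alleles <- strsplit(gt, "|", fixed = TRUE)
  if (any(lengths(alleles) != 2L))
    stop("each VCF genotype must carry exactly two phased alleles")
  ha <- vapply(alleles, `[`, "", 1L)
  hb <- vapply(alleles, `[`, "", 2L)
  if (anyNA(gt) || any(ha == ".") || any(hb == "."))
    stop("missing genotypes are not accepted; panels must be complete")
  dim(ha) <- dim(gt); dim(hb) <- dim(gt)
  samples <- colnames(gt)
  # interleave the two haplotypes of each sample: rows = chromosomes
  n <- length(samples)
  mat <- matrix(NA_integer_, nrow = 2L * n, ncol = nrow(gt))
  mat[seq(1L, 2L * n, by = 2L), ] <- t(matrix(as.integer(ha), nrow = nrow(gt)))
  mat[seq(2L, 2L * n, by = 2L), ] <- t(matrix(as.integer(hb), nrow = nrow(gt)))
  haplotype_panel(
    mat,
    positions = as.integer(fix[, "POS"]),
    snp_ids = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                     paste0("snp", seq_len(nrow(gt))), fix[, "ID"]),
    allele0 = fix[, "REF"], allele1 = fix[, "ALT"],
    chromosome_ids = paste0(rep(samples, each = 2L), c("_a", "_b")),
    individual_ids = rep(samples, each = 2L),
    chrom_name = fix[1L, "CHROM"]
  )
}

.write_vcf <- function(panel, path) {
  n <- nrow(panel$haplotypes)
  if (n %% 2L != 0L)
    stop("VCF export needs an even number of chromosomes (diploid samples)")
  samples <- unique(panel$individual_ids)
  if (length(samples) != n / 2L)
    stop("VCF export needs two chromosomes per individual")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ldsplit",
    paste0("##contig=<ID=", panel$chrom_name, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  idx <- split(seq_len(n), factor(panel$individual_ids, levels = samples))
  if (any(lengths(idx) != 2L))
    stop("VCF export needs two chromosomes per individual")
  ha <- panel$haplotypes[vapply(idx, `[`, 1L, 1L), , drop = FALSE]
  hb <- panel$haplotypes[vapply(idx, `[`, 1L, 2L), , drop = FALSE]
  L <- ncol(panel$haplotypes)
  gt <- matrix(paste0(ha, "|", hb), nrow = length(samples))
  a0 <- panel$snps$allele0; a1 <- panel$snps$allele1
  a0[a0 == "0"] <- "A"; a1[a1 == "1"] <- "T"   # symbolic alleles need bases
  rows <- vapply(seq_len(L), function(j) {
    paste(c(panel$chrom_name, panel$snps$position[j], panel$snps$snp_id[j],
            a0[j], a1[j], ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
}
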