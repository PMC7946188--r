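#' Construct a genotype matrix
#'
#' The central genotype container: a SNP panel with genetic positions, an
#' individual table, and a calls matrix. Calls are stored as an integer matrix
#' with one row per SNP and one column per individual, holding the alt-allele
#' dosage (`0/1/2` for diploid data, `0/1` for pseudo-haploid data) with `NA`
#' for missing.
#'
#' @param ind data.frame with columns `individual_id`, `declared_sex`
#'   (one of "M", "F", "U"), `group_label`.
#' @param snp data.frame with columns `snp_id`, `chromosome` (character,
#'   without a "chr" prefix), `genetic_pos` (Morgans), `physical_pos`
#'   (1-based bp), `ref_allele`, `alt_allele`.
#' @param calls integer matrix, `nrow(snp)` x `nrow(ind)`.
#' @param ploidy `"pseudo_haploid"` or `"diploid"`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(ind, snp, calls, ploidy = c("diploid", "pseudo_haploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(is.data.frame(ind), is.data.frame(snp), is.matrix(calls))
  if (nrow(ind) == 0L) stop("individual list is empty")
  if (anyDuplicated(ind$individual_id))
    stop("duplicate individual ids: ",
         paste(unique(ind$individual_id[duplicated(ind$individual_id)]), collapse = ", "))
  if (nrow(calls) != nrow(snp) || ncol(calls) != nrow(ind))
    stop(sprintf("calls is %d x %d but there are %d SNPs and %d individuals",
                 nrow(calls), ncol(calls), nrow(snp), nrow(ind)))
  vals <- calls[!is.na(calls)]
  maxv <- if (ploidy == "pseudo_haploid") 1L else 2L
  if (length(vals) && (any(vals < 0L) || any(vals > maxv)))
    stop(sprintf("calls outside {0..%d, NA} for ploidy %s", maxv, ploidy))
  if (any(snp$ref_allele == snp$alt_allele))
    stop("ref and alt allele identical at some SNPs")
  snp$chromosome <- sub("^chr", "", as.character(snp$chromosome))
  colnames(calls) <- ind$individual_id
  structure(list(ind = ind, snp = snp, calls = calls, ploidy = ploidy),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs (%s)\n",
              nrow(x$ind), nrow(x$snp), x$ploidy))
  invisible(x)
}

#' Read genotypes in EIGENSTRAT ASCII format
#'
#' Reads the classic three-file EIGENSTRAT representation: a `.geno` file with
#' one row per SNP and one digit per individual (`0/1/2` = alt-allele dosage,
#' `9` = missing), a `.snp` file (snp id, chromosome, genetic position in
#' Morgans, physical position, ref allele, alt allele) and a `.ind` file
#' (individual id, sex, group label). Packed binary geno files are not
#' supported.
#'
#' @param geno_path,snp_path,ind_path File paths.
#' @param ploidy Ploidy mode of the stored calls; `"auto"` infers
#'   `"pseudo_haploid"` when no digit 2 occurs, `"diploid"` otherwise.
#' @return A [genotype_matrix()].
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path, ploidy = "auto") {
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) stop("file not found: ", p)

  ind <- utils::read.table(ind_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("individual_id", "declared_sex", "group_label"),
                           colClasses = "character")
  snp <- utils::read.table(snp_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("snp_id", "chromosome", "genetic_pos",
                                         "physical_pos", "ref_allele", "alt_allele"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  lines <- readLines(geno_path)
  if (length(lines) != nrow(snp))
    stop(sprintf("geno has %d rows but snp file lists %d SNPs",
                 length(lines), nrow(snp)))
  widths <- nchar(lines)
  bad <- which(widths != nrow(ind))
  if (length(bad))
    stop(sprintf("geno row %d has width %d, expected %d individuals",
                 bad[1], widths[bad[1]], nrow(ind)))
  codes <- utf8ToInt(paste(lines, collapse = "")) - 48L
  ok <- codes %in% c(0L, 1L, 2L, 9L)
  if (!all(ok)) {
    first <- which(!ok)[1]
    row <- (first - 1L) %/% nrow(ind) + 1L
    stop(sprintf("non-genotype character in geno row %d", row))
  }
  codes[codes == 9L] <- NA_integer_
  calls <- matrix(codes, nrow = nrow(snp), ncol = nrow(ind), byrow = TRUE)
  if (identical(ploidy, "auto"))
    ploidy <- if (any(codes == 2L, na.rm = TRUE)) "diploid" else "pseudo_haploid"
  genotype_matrix(ind, snp, calls, ploidy = ploidy)
}

#' Write genotypes in EIGENSTRAT ASCII format
#'
#' Inverse of [read_eigenstrat()]; a written matrix reads back identically.
#'
#' @param mat A [genotype_matrix()].
#' @param geno_path,snp_path,ind_path Output paths.
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_eigenstrat <- function(mat, geno_path, snp_path, ind_path) {
  stopifnot(inherits(mat, "genotype_matrix"))
  if (nrow(mat$ind) == 0L) stop("individual list is empty")
  codes <- mat$calls
  codes[is.na(codes)] <- 9L
  lines <- vapply(seq_len(nrow(codes)),
                  function(i) paste(codes[i, ], collapse = ""), character(1))
  writeLines(lines, geno_path)
  utils::write.table(mat$snp, snp_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(mat$ind, ind_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(geno = geno_path, snp = snp_path, ind = ind_path))
}

#' Pseudo-haploidize a diploid genotype matrix
#'
#' Randomly samples one allele per individual per SNP, the standard
#' representation for low-coverage ancient DNA: homozygotes map
#' deterministically (0 -> 0, 2 -> 1), heterozygotes to 0 or 1 with equal
#' probability, missing stays missing.
#'
#' @param mat A diploid [genotype_matrix()].
#' @param seed Seed for the allele sampling; the same seed gives identical
#'   output. `NULL` uses the current RNG stream.
#' @return A pseudo-haploid [genotype_matrix()].
#' @export
pseudo_haploidize <- function(mat, seed = NULL) {
  stopifnot(inherits(mat, "genotype_matrix"))
  if (mat$ploidy != "diploid")
    stop("matrix is already pseudo-haploid")
  calls <- mat$calls
  out <- calls
  out[calls == 2L] <- 1L
  het <- which(calls == 1L)
  if (length(het)) {
    draws <- with_seed(seed, stats::runif(length(het)) < 0.5)
    out[het] <- as.integer(draws)
  }
  genotype_matrix(mat$ind, mat$snp, out, ploidy = "pseudo_haploid")
}

#' Per-individual count of non-missing calls
#'
#' Coverage in the SNP-panel sense: the number of panel SNPs with a genotype
#' call, used by the eligibility rules (>100,000 SNPs for the kinship
#' baseline cohort, >=400,000 for the ROH screen).
#'
#' @param mat A [genotype_matrix()].
#' @return Named integer vector, one entry per individual.
#' @export
snp_coverage <- function(mat) {
  stopifnot(inherits(mat, "genotype_matrix"))
  n <- colSums(!is.na(mat$calls))
  names(n) <- mat$ind$individual_id
  n
}
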