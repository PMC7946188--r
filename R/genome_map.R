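#' Default autosomal genetic map
#'
#' Sex-averaged genetic lengths of the 22 human autosomes, totalling about
#' 35.4 Morgans. Used as the default map for ROH expectations, coalescent ROH
#' simulation, and genetic-map block construction.
#'
#' @return A data.frame with columns `chromosome` (character, "1".."22") and
#'   `length_morgans` (numeric).
#' @export
default_genome_map <- function() {
  data.frame(
    chromosome = as.character(1:22),
    length_morgans = c(
      2.863, 2.686, 2.234, 2.146, 2.041, 1.920, 1.872, 1.680, 1.664, 1.811,
      1.582, 1.747, 1.259, 1.202, 1.419, 1.340, 1.285, 1.172, 1.079, 1.083,
      0.628, 0.741
    ),
    stringsAsFactors = FALSE
  )
}

validate_genome_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("chromosome", "length_morgans") %in% names(map)))
  if (any(map$length_morgans <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(map$chromosome)) stop("duplicate chromosome in map")
  map$chromosome <- as.character(map$chromosome)
  map
}

# Assign each SNP to a contiguous genetic-map block of `block_cm` centimorgans
# within its chromosome. Returns an integer block id per SNP (ids unique
# across chromosomes). Used by the block jackknife.
map_blocks <- function(snp, block_cm = 5) {
  stopifnot(block_cm > 0)
  chrom <- as.character(snp$chromosome)
  pos_cm <- snp$genetic_pos * 100
  within <- floor(pos_cm / block_cm)
  ids <- paste(chrom, within, sep = ":")
  match(ids, unique(ids))
}
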