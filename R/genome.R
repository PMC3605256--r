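#' Toy genome manifest
#'
#' A small genome used throughout the simulation and test machinery: 22
#' autosomes of 10 Mb each, an 8 Mb X and a 3 Mb Y. Chromosome-scale
#' contrasts (autosome vs X vs Y compartments) are preserved while keeping
#' interval arithmetic fast. Real manifests (e.g. read with
#' [read_genome_manifest()]) are accepted everywhere a `genome` argument
#' appears.
#'
#' @param autosome_bp Length of each autosome in base pairs.
#' @param x_bp,y_bp Lengths of the X and Y chromosomes.
#' @return A tibble with columns `chrom` and `length`.
#' @export
#' @examples
#' toy_genome()
toy_genome <- function(autosome_bp = 1e7, x_bp = 8e6, y_bp = 3e6) {
  tibble::tibble(
    chrom = c(paste0("chr", 1:22), "chrX", "chrY"),
    length = c(rep(autosome_bp, 22), x_bp, y_bp)
  )
}

validate_genome <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("chrom", "length") %in% names(genome)))
  if (anyDuplicated(genome$chrom)) abort("duplicate chromosomes in genome manifest")
  if (any(genome$length <= 0)) abort("non-positive chromosome length in genome manifest")
  invisible(genome)
}

#' Chromosome compartment of an interval
#'
#' Maps chromosome labels to the three compartments used in burden analyses:
#' autosome, X or Y. Labels are matched with or without a `chr` prefix.
#'
#' @param chrom Character vector of chromosome labels.
#' @param genome Genome manifest (tibble with `chrom`); labels not present in
#'   the manifest are an error.
#' @return Character vector in `c("autosome", "X", "Y")`.
#' @export
#' @examples
#' compartment_of(c("chr9", "chrX", "chrY"))
compartment_of <- function(chrom, genome = toy_genome()) {
  validate_genome(genome)
  unknown <- setdiff(unique(chrom), genome$chrom)
  if (length(unknown) > 0) {
    abort(paste0("chromosome(s) not in genome manifest: ",
                 paste(unknown, collapse = ", ")))
  }
  stripped <- sub("^chr", "", chrom)
  dplyr::case_when(
    stripped %in% c("X", "x") ~ "X",
    stripped %in% c("Y", "y") ~ "Y",
    TRUE ~ "autosome"
  )
}
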