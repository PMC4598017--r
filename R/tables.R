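#' Multi-allele MHC genotype table
#'
#' One row per individual carrying a *set* of 2-5 allele identifiers plus a
#' population label. Allele sets (rather than per-locus diploid pairs) are
#' the natural unit when several unresolvable loci co-amplify in one
#' amplicon.
#'
#' @param individual character vector of individual ids.
#' @param population character vector of population labels.
#' @param alleles list of character vectors (one allele-id set per
#'   individual); stored sorted and de-duplicated.
#' @return data frame of class `mhc_geno` with columns `individual`,
#'   `population` and list column `alleles`.
#' @export
mhc_genotypes <- function(individual, population, alleles) {
  if (length(individual) != length(population) ||
      length(individual) != length(alleles)) {
    stop("individual, population and alleles must have equal length")
  }
  if (anyDuplicated(individual)) stop("duplicated individual ids")
  alleles <- lapply(alleles, function(a) sort(unique(as.character(a))))
  if (any(lengths(alleles) < 1)) stop("every individual needs at least one allele")
  x <- data.frame(individual = as.character(individual),
                  population = as.character(population),
                  stringsAsFactors = FALSE)
  x$alleles <- alleles
  class(x) <- c("mhc_geno", "data.frame")
  x
}

#' @export
print.mhc_geno <- function(x, ...) {
  cat(sprintf("MHC genotype table: %d individuals, %d populations, %d distinct alleles\n",
              nrow(x), length(unique(x$population)),
              length(unique(unlist(x$alleles)))))
  invisible(x)
}

#' Diploid microsatellite genotype table
#'
#' @param individual,population character vectors.
#' @param genotypes integer/numeric matrix with two columns per locus
#'   (`<locus>.1`, `<locus>.2`); `NA` encodes missing data.
#' @param loci locus names; defaults are derived from the column names.
#' @return data frame of class `msat_geno`; the locus list is stored in the
#'   `loci` attribute.
#' @export
msat_genotypes <- function(individual, population, genotypes, loci = NULL) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) %% 2 != 0) stop("genotypes must have two columns per locus")
  if (nrow(genotypes) != length(individual)) {
    stop("genotypes must have one row per individual")
  }
  if (is.null(loci)) {
    loci <- unique(sub("\\.[12]$", "", colnames(genotypes)))
  }
  if (length(loci) != ncol(genotypes) / 2) stop("locus names do not match columns")
  colnames(genotypes) <- paste(rep(loci, each = 2), c(1, 2), sep = ".")
  x <- data.frame(individual = as.character(individual),
                  population = as.character(population),
                  genotypes, check.names = FALSE, stringsAsFactors = FALSE)
  attr(x, "loci") <- loci
  class(x) <- c("msat_geno", "data.frame")
  x
}

#' @export
print.msat_geno <- function(x, ...) {
  cat(sprintf("Microsatellite genotype table: %d individuals, %d populations, %d loci\n",
              nrow(x), length(unique(x$population)), length(attr(x, "loci"))))
  invisible(x)
}

# Unordered diploid pair matrix (n x 2) for one locus, rows with any NA kept.
locus_pairs <- function(x, locus) {
  as.matrix(x[, paste(locus, c(1, 2), sep = ".")])
}

#' Read and write the package's plain-text interchange formats
#'
#' FASTA i/o goes through `Biostrings`; genotype tables are tab-delimited
#' with a header row, MHC allele sets semicolon-joined; coordinates are CSV.
#'
#' @param x object to write.
#' @param path file path.
#' @param width FASTA line width (0 = single-line records).
#' @name mhcpopgen-io
NULL

#' @rdname mhcpopgen-io
#' @export
write_fasta <- function(x, path, width = 0) {
  seqs <- Biostrings::DNAStringSet(unlist(x))
  w <- if (width <= 0) max(1L, max(Biostrings::width(seqs))) else as.integer(width)
  Biostrings::writeXStringSet(seqs, path, width = w)
  invisible(path)
}

#' @rdname mhcpopgen-io
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' @rdname mhcpopgen-io
#' @export
write_mhc_genotypes <- function(x, path) {
  stopifnot(inherits(x, "mhc_geno"))
  df <- data.frame(individual = x$individual, population = x$population,
                   alleles = vapply(x$alleles, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname mhcpopgen-io
#' @export
read_mhc_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mhc_genotypes(df$individual, df$population, strsplit(df$alleles, ";", fixed = TRUE))
}

#' @rdname mhcpopgen-io
#' @export
write_msat_genotypes <- function(x, path) {
  stopifnot(inherits(x, "msat_geno"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname mhcpopgen-io
#' @export
read_msat_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(df[, setdiff(names(df), c("individual", "population"))])
  msat_genotypes(df$individual, df$population, geno)
}

#' @rdname mhcpopgen-io
#' @export
write_coordinates <- function(x, path) {
  utils::write.csv(x[, c("population", "lon", "lat")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname mhcpopgen-io
#' @export
read_coordinates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname mhcpopgen-io
#' @export
write_square_matrix <- function(x, path) {
  df <- data.frame(population = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mhcpopgen-io
#' @export
read_square_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
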