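#' Write pipeline tables to CSV
#'
#' Thin wrappers pinning the on-disk schemas: occurrence tables are
#' `(species, lon, lat, <env columns>)`, fitness tables one row per
#' transplanted clone, trait tables one row per genotype.  Coordinates
#' are (longitude, latitude) in decimal degrees, WGS84 assumed.
#'
#' @param x Table to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_occurrences <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_fitness <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_traits <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Record simulation parameters and seed in a YAML sidecar
#'
#' @param params A [simulation_params()] object.
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  p <- unclass(params)
  p$gardens <- as.list(p$gardens)
  p$taxa <- as.list(p$taxa)
  p$trait_loadings <- list(values = as.vector(p$trait_loadings),
                           rows = rownames(p$trait_loadings),
                           cols = colnames(p$trait_loadings))
  yaml::write_yaml(p, path)
  invisible(path)
}

#' Write genotypes as a plain matrix TSV (plus a population map)
#'
#' The matrix file has loci as rows (first column `locus`) and one column
#' per individual holding the 0/1/2 alternative-allele count (`NA` for
#' missing).  The population map is a two-column CSV
#' `(individual, population)`.  `read -> write -> read` is lossless.
#'
#' @param gm A `"genotype_matrix"`.
#' @param path Matrix TSV path.
#' @param pop_path Population-map CSV path; default `<path>.pops.csv`.
#' @return `path`, invisibly.
#' @export
write_genotypes_matrix <- function(gm, path, pop_path = paste0(path, ".pops.csv")) {
  m <- data.frame(locus = rownames(gm$genotypes), gm$genotypes,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(data.frame(individual = names(gm$populations),
                       population = unname(gm$populations)),
            pop_path, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF (biallelic SNPs, GT field)
#'
#' Emits VCFv4.2 with one biallelic record per locus (`REF = A`,
#' `ALT = T`), genotypes coded `0/0`, `0/1`, `1/1` and missing as `./.`.
#'
#' @param gm A `"genotype_matrix"`.
#' @param path Output `.vcf` path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  g <- gm$genotypes
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  gt[is.na(g)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=adaptscape",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  body <- paste("1", seq_len(nrow(g)), rownames(g), "A", "T", ".", ".", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype matrix from VCF or plain-matrix TSV
#'
#' VCF input keeps biallelic SNP records only (multiallelic records are
#' skipped and counted); `GT` fields are mapped to alternative-allele
#' counts 0/1/2, with `./.` (or any call containing `.`) read as missing.
#' Phased (`|`) and unphased (`/`) separators are treated identically.
#' Matrix input is the [write_genotypes_matrix()] format.
#'
#' @param path Genotype file path.
#' @param format `"vcf"` or `"matrix"`.
#' @param pop_map Named character vector individual -> population, or the
#'   path of a `(individual, population)` CSV.
#' @return A `"genotype_matrix"` with attribute `n_skipped_multiallelic`
#'   (VCF only).
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix"), pop_map) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map)) {
    pm <- read.csv(pop_map, stringsAsFactors = FALSE)
    pop_map <- setNames(pm$population, pm$individual)
  }
  n_skipped <- 0L
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    bi <- vcfR::is.biallelic(vcf)
    n_skipped <- sum(!bi)
    vcf <- vcf[bi, ]
    gt <- vcfR::extract.gt(vcf, element = "GT")
    alt_count <- function(s) {
      if (is.na(s) || grepl("\\.", s)) return(NA_integer_)
      sum(as.integer(strsplit(s, "[/|]")[[1]]) > 0L)
    }
    g <- matrix(vapply(gt, alt_count, integer(1)), nrow = nrow(gt),
                dimnames = dimnames(gt))
    ids <- vcfR::getID(vcf)
    if (!anyNA(ids) && !anyDuplicated(ids)) rownames(g) <- ids
  } else {
    m <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
    g <- as.matrix(m[-1])
    storage.mode(g) <- "integer"
    rownames(g) <- m$locus
  }
  missing_ind <- setdiff(colnames(g), names(pop_map))
  if (length(missing_ind))
    stop("individual(s) missing from population map: ",
         paste(utils::head(missing_ind, 10), collapse = ", "))
  out <- structure(list(genotypes = g,
                        populations = pop_map[colnames(g)]),
                   class = "genotype_matrix")
  attr(out, "n_skipped_multiallelic") <- n_skipped
  out
}
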