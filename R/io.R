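#' Write a haploid genotype matrix as VCF
#'
#' Plain-text VCFv4.2 with CHROM "Y", 1-based positions, haploid GT
#' values \code{0}, \code{1} or \code{.}; two alternative alleles at one
#' position are written as two records.
#'
#' @param gm a \code{\link{geno_matrix}}.
#' @param path output file.
#' @param ref,alt reference/alternate allele letters (default "A"/"G").
#' @export
write_genotype_vcf <- function(gm, path, ref = "A", alt = "G") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=Y>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gm$samples),
                     collapse = "\t")), con)
  if (length(gm$pos)) {
    gt <- gm$geno
    gts <- matrix(as.character(gt), nrow(gt), ncol(gt))
    gts[is.na(gt)] <- "."
    body <- paste("Y", format(gm$pos, scientific = FALSE, trim = TRUE),
                  ".", ref, alt, ".", "PASS", ".", "GT",
                  apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a haploid VCF into a genotype matrix
#'
#' Parses via \pkg{vcfR} when installed, otherwise with a minimal
#' tab-delimited reader. Haploid GT fields \code{0}/\code{1}/\code{.}
#' map to 0/1/NA.
#'
#' @param path VCF file.
#' @param platform,mask optional metadata forwarded to
#'   \code{\link{geno_matrix}}.
#' @return a \code{\link{geno_matrix}}.
#' @export
read_genotype_vcf <- function(path, platform = NULL, mask = NULL) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    pos <- as.numeric(v@fix[, "POS"])
    samples <- colnames(gt)
  } else {
    ln <- readLines(path)
    hdr <- ln[startsWith(ln, "#CHROM")]
    samples <- strsplit(hdr, "\t")[[1L]][-(1:9)]
    body <- ln[!startsWith(ln, "#")]
    fields <- strsplit(body, "\t")
    pos <- as.numeric(vapply(fields, `[[`, "", 2L))
    gt <- t(vapply(fields, function(f) f[-(1:9)], character(length(samples))))
    if (length(samples) == 1L) gt <- matrix(gt, ncol = 1L)
    colnames(gt) <- samples
  }
  g <- suppressWarnings(matrix(as.integer(substr(gt, 1L, 1L)),
                               nrow(gt), ncol(gt),
                               dimnames = list(NULL, samples)))
  geno_matrix(g, pos, samples = samples, platform = platform, mask = mask)
}

#' Read/write region masks as BED
#'
#' Three-column BED: chromosome, 0-based start, end (half-open).
#'
#' @param mask a \code{\link{region_mask}}.
#' @param path file path.
#' @param chrom chromosome name (default "Y").
#' @export
write_bed <- function(mask, path, chrom = "Y") {
  df <- data.frame(chrom = chrom,
                   start = format(mask$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(mask$end, scientific = FALSE, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end"))
  o <- order(df$start)
  region_mask(df$start[o], df$end[o])
}

#' Write/read dated trees as Newick (branch lengths in years)
#'
#' @param tree a \code{phylo}.
#' @param path file path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_tree_newick
#' @export
read_tree_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a posterior trace / generic table as TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}
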