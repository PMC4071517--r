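#' Read a dominant genotype table
#'
#' Delimited text with the individual id in the first column and a header row
#' of locus ids; entries are 0, 1 or a missing token (blank by default). The
#' delimiter is auto-detected among comma and tab unless given.
#'
#' @param path file path.
#' @param sep field delimiter; \code{NULL} (default) auto-detects "," vs tab
#'   from the header line.
#' @param missing token standing for a missing genotype (default \code{""}).
#' @param quiet suppress the parse summary message.
#' @return a \linkS4class{DominantGenotypes}; individuals in file order.
#' @export
readGenotypes <- function(path, sep = NULL, missing = "", quiet = FALSE) {
  sep <- sep %||% detectSep(path)
  d <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                         colClasses = "character", stringsAsFactors = FALSE)
  ids <- d[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicated individual id in %s: %s", path,
                 ids[duplicated(ids)][1L]))
  loci <- names(d)[-1L]
  m <- as.matrix(d[, -1L, drop = FALSE])
  m[m == missing | m == "NA"] <- NA_character_
  bad <- which(!is.na(m) & !(m %in% c("0", "1")), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary genotype token '%s' at individual '%s', locus '%s'",
                 m[bad[1L, , drop = FALSE]], ids[bad[1L, 1L]], loci[bad[1L, 2L]]))
  g <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = list(ids, loci))
  if (!quiet)
    message(sprintf("read %d individuals x %d loci (%d missing entries)",
                    nrow(g), ncol(g), sum(is.na(g))))
  DominantGenotypes(g)
}

detectSep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) >=
      lengths(regmatches(hdr, gregexpr(",", hdr)))) "\t" else ","
}

#' Write a dominant genotype table
#'
#' Inverse of \code{\link{readGenotypes}}: values round-trip exactly.
#'
#' @param x a \linkS4class{DominantGenotypes}.
#' @param path output file.
#' @param sep delimiter (default tab).
#' @param missing token written for \code{NA} (default \code{""}).
#' @export
writeGenotypes <- function(x, path, sep = "\t", missing = "") {
  g <- genotypeValues(x)
  m <- matrix(as.character(g), nrow(g), ncol(g))
  m[is.na(m)] <- missing
  d <- data.frame(id = rownames(g), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d) <- c("id", colnames(g))
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Drop loci failing the replicate-mismatch error filter
#'
#' AFLP scoring error is assessed by genotyping a subset of individuals
#' twice; a locus whose replicate scores disagree too often is unreliable and
#' removed. Mismatches are counted per locus over all replicate pairs
#' (\code{mode = "summed"}, the default) or the per-pair maximum can be used
#' instead (\code{mode = "per_pair"}); a locus is dropped when the count
#' exceeds \code{maxMismatches}.
#'
#' @param genotypes a \linkS4class{DominantGenotypes} (the accepted scores).
#' @param replicates numeric matrix of replicate scores: one row per
#'   replicate assay, rownames naming the individual each re-runs (duplicates
#'   allowed), colnames a subset of the genotype loci.
#' @param maxMismatches tolerated mismatch count per locus (default 1: loci
#'   with more than one mismatch are removed).
#' @param mode count mismatches summed over pairs or per pair (see above).
#' @param quiet suppress the report message.
#' @return the filtered \linkS4class{DominantGenotypes}, with attribute
#'   \code{"dropped"} listing removed loci and their mismatch counts.
#' @export
filterLociByReplicates <- function(genotypes, replicates, maxMismatches = 1L,
                                   mode = c("summed", "per_pair"),
                                   quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(maxMismatches >= 0)
  g <- genotypeValues(genotypes)
  if (is.null(rownames(replicates)))
    stop("replicates must have rownames naming individuals")
  absent <- setdiff(rownames(replicates), rownames(g))
  if (length(absent))
    stop(sprintf("replicate individual(s) absent from genotypes: %s",
                 paste(absent, collapse = ", ")))
  loci <- intersect(colnames(replicates), colnames(g))
  if (!length(loci)) stop("replicates share no loci with genotypes")
  orig <- g[rownames(replicates), loci, drop = FALSE]
  rep2 <- replicates[, loci, drop = FALSE]
  mm <- (orig != rep2) & !is.na(orig) & !is.na(rep2)
  counts <- if (mode == "summed") colSums(mm) else {
    apply(mm, 2L, function(col) max(tapply(col, rownames(replicates), sum)))
  }
  dropped <- loci[counts > maxMismatches]
  if (!quiet)
    message(sprintf("replicate filter: %d of %d assayed loci dropped (> %d mismatches)",
                    length(dropped), length(loci), maxMismatches))
  keep <- setdiff(colnames(g), dropped)
  out <- DominantGenotypes(g[, keep, drop = FALSE])
  attr(out, "dropped") <- data.frame(locus = dropped,
                                     mismatches = unname(counts[dropped]))
  out
}

#' Remove monomorphic loci
#'
#' Kinship referenced to sample allele frequencies is undefined at loci where
#' every non-missing score is the same, so such loci are removed before
#' estimation.
#'
#' @param genotypes a \linkS4class{DominantGenotypes}.
#' @param quiet suppress the report message.
#' @return filtered \linkS4class{DominantGenotypes} with attribute
#'   \code{"dropped"} naming the removed loci.
#' @export
dropMonomorphic <- function(genotypes, quiet = FALSE) {
  g <- genotypeValues(genotypes)
  f <- colMeans(g, na.rm = TRUE)
  nObs <- colSums(!is.na(g))
  poly <- nObs > 0L & f > 0 & f < 1
  if (!any(poly)) stop("no polymorphic loci")
  if (!quiet)
    message(sprintf("dropped %d monomorphic of %d loci", sum(!poly), length(poly)))
  out <- DominantGenotypes(g[, poly, drop = FALSE])
  attr(out, "dropped") <- colnames(g)[!poly]
  out
}
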