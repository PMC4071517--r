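#' Read a sample table
#'
#' Delimited text with mandatory columns \code{id}, \code{lon}, \code{lat},
#' \code{association}, plus one numeric column per environmental variable.
#'
#' @param path file path.
#' @param sep delimiter; auto-detected among comma/tab when \code{NULL}.
#' @param envVars environmental column names; default: all remaining numeric
#'   columns.
#' @return a \linkS4class{SampleTable}.
#' @export
readSampleTable <- function(path, sep = NULL, envVars = NULL) {
  sep <- sep %||% detectSep(path)
  d <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  SampleTable(d, envVars = envVars)
}

#' Write a sample table
#'
#' @param x a \linkS4class{SampleTable}.
#' @param path output file.
#' @param sep delimiter (default tab).
#' @export
writeSampleTable <- function(x, path, sep = "\t") {
  utils::write.table(sampleData(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read an association -> species lookup
#'
#' Long-format delimited text with columns \code{association} and
#' \code{species}; one row per (association, species) co-occurrence.
#'
#' @param path file path.
#' @param sep delimiter; auto-detected when \code{NULL}.
#' @return named list mapping association label to a character vector of
#'   co-occurring species.
#' @export
readAssociationLookup <- function(path, sep = NULL) {
  sep <- sep %||% detectSep(path)
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("association", "species") %in% names(d)))
  lk <- split(as.character(d$species), d$association)
  if (any(!lengths(lk))) stop("association with empty species set")
  lk
}

#' Write an association -> species lookup
#'
#' @param lookup named list as returned by \code{\link{readAssociationLookup}}.
#' @param path output file.
#' @param sep delimiter (default tab).
#' @export
writeAssociationLookup <- function(lookup, path, sep = "\t") {
  d <- data.frame(association = rep(names(lookup), lengths(lookup)),
                  species = unlist(lookup, use.names = FALSE))
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Write a pairwise matrix
#'
#' Square delimited text with the id header row/column, or long format
#' (id_i, id_j, value) over the strict lower triangle.
#'
#' @param x a \linkS4class{PairwiseMatrix}.
#' @param path output file.
#' @param format \code{"square"} or \code{"long"}.
#' @param sep delimiter (default tab).
#' @export
writePairwiseMatrix <- function(x, path, format = c("square", "long"),
                                sep = "\t") {
  format <- match.arg(format)
  if (format == "square") {
    d <- data.frame(id = x@ids, x@values, check.names = FALSE)
    names(d) <- c("id", x@ids)
    utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE,
                       eol = "\n")
  } else {
    v <- unfold(x)
    ij <- do.call(rbind, strsplit(names(v), "|", fixed = TRUE))
    d <- data.frame(id_i = ij[, 1L], id_j = ij[, 2L], value = unname(v))
    utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE,
                       eol = "\n")
  }
  invisible(path)
}

#' Read a square pairwise matrix
#'
#' @param path file written by \code{\link{writePairwiseMatrix}}
#'   (format "square").
#' @param kind matrix kind tag.
#' @param sep delimiter; auto-detected when \code{NULL}.
#' @return a \linkS4class{PairwiseMatrix}.
#' @export
readPairwiseMatrix <- function(path, kind = "distance", sep = NULL) {
  sep <- sep %||% detectSep(path)
  d <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  newPairwiseMatrix(m, ids, kind)
}
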