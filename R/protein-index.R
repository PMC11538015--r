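#' Protein index
#'
#' An ordered set of protein identifiers defining the row order of every
#' adjacency, feature, attribute and label matrix in an analysis. Identifiers
#' must be unique; positions are 1-based row indices.
#'
#' @param ids Character vector of unique protein identifiers.
#' @return An object of class `protein_index`.
#' @export
#' @examples
#' idx <- protein_index(c("P1", "P2", "P3"))
#' length(idx)
#' protein_position(idx, c("P3", "P1"))
protein_index <- function(ids) {
  ids <- as.character(ids)
  if (anyNA(ids) || any(ids == "")) {
    stop("protein identifiers must be non-missing, non-empty strings")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated protein identifiers: ", paste(head(dup, 5), collapse = ", "))
  }
  structure(list(ids = ids), class = "protein_index")
}

#' @export
length.protein_index <- function(x) length(x$ids)

#' @export
print.protein_index <- function(x, ...) {
  cat("protein_index with", length(x$ids), "proteins\n")
  invisible(x)
}

#' Look up row positions of protein identifiers
#'
#' @param index A [protein_index()].
#' @param ids Character vector of identifiers to resolve.
#' @param strict Error on unknown identifiers (default) instead of returning NA.
#' @return Integer vector of 1-based positions.
#' @export
protein_position <- function(index, ids, strict = TRUE) {
  stopifnot(inherits(index, "protein_index"))
  pos <- match(as.character(ids), index$ids)
  if (strict && anyNA(pos)) {
    bad <- unique(ids[is.na(pos)])
    stop("unknown protein identifier(s): ", paste(head(bad, 5), collapse = ", "))
  }
  pos
}

#' Read / write a protein index as a one-identifier-per-line text file
#'
#' @param path File path.
#' @return `read_protein_index` returns a [protein_index()];
#'   `write_protein_index` returns `path` invisibly.
#' @export
read_protein_index <- function(path) {
  protein_index(readLines(path, warn = FALSE))
}

#' @param index A [protein_index()].
#' @rdname read_protein_index
#' @export
write_protein_index <- function(index, path) {
  stopifnot(inherits(index, "protein_index"))
  writeLines(index$ids, path)
  invisible(path)
}
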