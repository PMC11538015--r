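# Readers and filters for STRING-style evidence networks, GO annotation
# tables and protein attribute matrices, plus the CAFA-style temporal split.

# fread that also accepts gzip-compressed text via a connection
fread_text <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    data.table::fread(text = readLines(con, warn = FALSE), ...)
  } else {
    data.table::fread(path, ...)
  }
}

#' Evidence network
#'
#' A weighted, symmetric adjacency matrix for one STRING evidence channel.
#' Scores are stored as given by the source; use [minmax_normalize()] to map
#' them into `[0, 1]`.
#'
#' @param adjacency Symmetric numeric n x n matrix with non-negative entries;
#'   dimnames give the protein identifiers.
#' @param channel Channel name, one of [string_channels()].
#' @return An object of class `evidence_network`.
#' @export
evidence_network <- function(adjacency, channel) {
  channel <- match.arg(channel, STRING_CHANNELS)
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (any(adjacency < 0)) stop("adjacency entries must be non-negative")
  if (!isSymmetric(unname(adjacency))) stop("adjacency must be symmetric")
  structure(list(adjacency = adjacency, channel = channel),
            class = "evidence_network")
}

#' @export
print.evidence_network <- function(x, ...) {
  nz <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat(sprintf("evidence_network '%s': %d proteins, %d edges\n",
              x$channel, nrow(x$adjacency), nz))
  invisible(x)
}

#' Read a STRING-style edge list for one evidence channel
#'
#' Accepts either a three-column file `protein1 protein2 score` or a combined
#' file with one named score column per channel. An interaction exists exactly
#' where the channel score is positive; zero-score rows are ignored. A pair
#' listed more than once (e.g. in both orders) keeps its maximum score, which
#' makes the result order-independent. Gzipped files are accepted.
#'
#' @param path TSV (or .gz) file path.
#' @param channel Evidence channel name; selects the score column in combined
#'   files.
#' @param index [protein_index()] defining the node set; rows naming proteins
#'   outside the index are an error.
#' @return An [evidence_network()] with raw (un-normalized) scores.
#' @export
read_string_edges <- function(path, channel, index) {
  channel <- match.arg(channel, STRING_CHANNELS)
  stopifnot(inherits(index, "protein_index"))
  n <- length(index)
  adj <- matrix(0, n, n, dimnames = list(index$ids, index$ids))
  dt <- fread_text(path, header = "auto", colClasses = list(character = 1:2))
  if (nrow(dt) == 0) {
    return(evidence_network(adj, channel))
  }
  if (ncol(dt) < 3) stop("edge list needs at least 3 columns: ", path)
  if (channel %in% names(dt)) {
    score <- dt[[channel]]
  } else if (ncol(dt) == 3) {
    score <- dt[[3]]
  } else {
    stop("cannot locate a score column for channel '", channel, "' in ", path)
  }
  if (!is.numeric(score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(score))))[1]
    stop("malformed score in row ", bad, " of ", path, ": '", score[bad], "'")
  }
  if (anyNA(score)) stop("missing score values in ", path)
  p1 <- as.character(dt[[1]])
  p2 <- as.character(dt[[2]])
  i <- match(p1, index$ids)
  j <- match(p2, index$ids)
  if (anyNA(i) || anyNA(j)) {
    row <- which(is.na(i) | is.na(j))[1]
    stop(sprintf("unknown protein id in row %d of %s: %s - %s",
                 row, path, p1[row], p2[row]))
  }
  keep <- score > 0
  i <- i[keep]; j <- j[keep]; score <- score[keep]
  # duplicate pairs (either order) keep the maximum score
  for (r in seq_along(i)) {
    s <- max(adj[i[r], j[r]], score[r])
    adj[i[r], j[r]] <- s
    adj[j[r], i[r]] <- s
  }
  evidence_network(adj, channel)
}

#' Write an evidence network back to an edge-list TSV
#'
#' Emits one row per undirected edge (upper triangle plus any nonzero
#' diagonal), full precision, so that [read_string_edges()] reproduces the
#' adjacency exactly.
#'
#' @param net An [evidence_network()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(net, path) {
  stopifnot(inherits(net, "evidence_network"))
  adj <- net$adjacency
  ids <- rownames(adj)
  idx <- which(upper.tri(adj, diag = TRUE) & adj > 0, arr.ind = TRUE)
  dt <- data.table::data.table(
    protein1 = ids[idx[, 1]],
    protein2 = ids[idx[, 2]],
    score = adj[idx])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' GO annotation table
#'
#' Validates a data frame of dated GO annotations. Expected columns:
#' `protein`, `go_term`, `evidence`, `date` (YYYY-MM-DD), `aspect`
#' (BP / MF / CC). Records with unparseable dates are dropped with a warning.
#'
#' @param df Data frame (or path readable by [read_annotations()]).
#' @return The validated data frame with class `annotation_table` and a
#'   `Date`-typed `date` column.
#' @export
annotation_table <- function(df) {
  need <- c("protein", "go_term", "evidence", "date", "aspect")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  bad_aspect <- !df$aspect %in% c("BP", "MF", "CC")
  if (any(bad_aspect)) stop("invalid aspect value(s): ",
                            paste(unique(df$aspect[bad_aspect]), collapse = ", "))
  d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  n_bad <- sum(is.na(d))
  if (n_bad > 0) {
    warning(n_bad, " annotation record(s) with unparseable dates dropped")
    df <- df[!is.na(d), , drop = FALSE]
    d <- d[!is.na(d)]
  }
  df$date <- d
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read a GO annotation TSV
#'
#' @param path TSV path with columns protein, go_term, evidence, date, aspect.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path) {
  annotation_table(fread_text(path, colClasses = "character"))
}

#' CAFA-style temporal split of proteins by annotation date
#'
#' Assigns each annotated protein to train / val / test by its earliest
#' annotation date (in the chosen aspect, if given): dates up to and
#' including `train_until` are training, dates up to `val_until` are
#' validation, later dates are test. The defaults reproduce the windows
#' "before 2018-01-01" (train), "2018-01-02 to 2020-12-31" (validation) and
#' "2021-01-01 onwards" (test); the boundary day 2018-01-01 itself goes to
#' train.
#'
#' @param table An [annotation_table()].
#' @param aspect Optional aspect (BP/MF/CC) to restrict the dating to.
#' @param train_until,val_until Window boundaries (inclusive), `Date` or
#'   string.
#' @return Named factor (levels train/val/test) over the annotated proteins.
#' @export
temporal_split <- function(table, aspect = NULL,
                           train_until = "2018-01-01",
                           val_until = "2020-12-31") {
  stopifnot(inherits(table, "annotation_table"))
  if (!is.null(aspect)) {
    aspect <- match.arg(aspect, c("BP", "MF", "CC"))
    table <- table[table$aspect == aspect, , drop = FALSE]
  }
  if (nrow(table) == 0) stop("no annotation records to split")
  train_until <- as.Date(train_until)
  val_until <- as.Date(val_until)
  first <- tapply(table$date, table$protein, min)
  first <- as.Date(first, origin = "1970-01-01")
  split <- ifelse(first <= train_until, "train",
                  ifelse(first <= val_until, "val", "test"))
  factor(setNames(split, names(first)), levels = c("train", "val", "test"))
}

#' One-hot encode GO labels with an evidence-code whitelist
#'
#' `y[i, k] = 1` iff protein `i` carries at least one annotation of term `k`
#' in the chosen aspect whose evidence code is whitelisted. Duplicated
#' records are idempotent.
#'
#' @param table An [annotation_table()].
#' @param index [protein_index()] giving the row order; annotations for
#'   proteins outside the index are ignored.
#' @param aspect GO aspect: "BP", "MF" or "CC".
#' @param evidence Whitelisted evidence codes
#'   (default [go_experimental_codes()]); must be non-empty.
#' @return Binary matrix, rows = index proteins, columns = sorted GO terms
#'   that have at least one whitelisted annotation.
#' @export
onehot_labels <- function(table, index, aspect,
                          evidence = go_experimental_codes()) {
  stopifnot(inherits(table, "annotation_table"), inherits(index, "protein_index"))
  aspect <- match.arg(aspect, c("BP", "MF", "CC"))
  if (length(evidence) == 0) stop("evidence whitelist must be non-empty")
  keep <- table$aspect == aspect &
    table$evidence %in% evidence &
    table$protein %in% index$ids
  tab <- table[keep, , drop = FALSE]
  terms <- sort(unique(tab$go_term))
  y <- matrix(0L, length(index), length(terms),
              dimnames = list(index$ids, terms))
  if (nrow(tab) > 0) {
    y[cbind(match(tab$protein, index$ids), match(tab$go_term, terms))] <- 1L
  }
  y
}

#' Label matrix with train/val/test splits
#'
#' Packages a full protein x GO-term binary matrix into per-split matrices.
#'
#' @param y Binary matrix with protein-identifier rownames.
#' @param split Named factor (levels train/val/test) as produced by
#'   [temporal_split()]; proteins absent from `y`'s rownames are ignored and
#'   `y` rows without a split assignment are dropped.
#' @return An object of class `label_matrix` with elements `y` (list of three
#'   matrices), `terms` and `splits` (list of protein-id vectors).
#' @export
label_matrix <- function(y, split) {
  stopifnot(is.matrix(y), !is.null(rownames(y)))
  split <- split[names(split) %in% rownames(y)]
  lv <- c("train", "val", "test")
  ids <- lapply(setNames(lv, lv), function(s) names(split)[split == s])
  ys <- lapply(ids, function(v) y[v, , drop = FALSE])
  structure(list(y = ys, terms = colnames(y), splits = ids),
            class = "label_matrix")
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf(
    "label_matrix: %d terms; train/val/test proteins = %d/%d/%d\n",
    length(x$terms), nrow(x$y$train), nrow(x$y$val), nrow(x$y$test)))
  invisible(x)
}

#' Filter GO terms by per-split support and a global frequency cap
#'
#' Retains terms with at least `min_train`, `min_val`, `min_test` positive
#' proteins in the corresponding splits and at most `max_frac` of the network
#' proteins overall. The default thresholds (10/5/1 and 5%) follow the CAFA
#' filtering convention. Column order is preserved; the operation is
#' idempotent.
#'
#' @param labels A [label_matrix()].
#' @param n_network Number of proteins in the PPI network (the universe the
#'   5% cap refers to).
#' @param min_train,min_val,min_test Minimum per-split positive counts.
#' @param max_frac Maximum total positive fraction of `n_network`.
#' @return A filtered [label_matrix()].
#' @export
filter_labels <- function(labels, n_network, min_train = 10, min_val = 5,
                          min_test = 1, max_frac = 0.05) {
  stopifnot(inherits(labels, "label_matrix"))
  ct_train <- colSums(labels$y$train)
  ct_val <- colSums(labels$y$val)
  ct_test <- colSums(labels$y$test)
  total <- ct_train + ct_val + ct_test
  keep <- ct_train >= min_train & ct_val >= min_val & ct_test >= min_test &
    total <= max_frac * n_network
  if (!any(keep)) stop("no GO terms survive the label filters")
  labels$y <- lapply(labels$y, function(m) m[, keep, drop = FALSE])
  labels$terms <- labels$terms[keep]
  labels
}

#' Read a protein attribute table
#'
#' @param path TSV with a protein-id first column and one binary indicator
#'   column per attribute (Pfam domain / subcellular location).
#' @param index [protein_index()] giving the row order; proteins missing from
#'   the file get all-zero rows.
#' @return Numeric matrix n x d with attribute-id colnames.
#' @export
read_attributes <- function(path, index) {
  stopifnot(inherits(index, "protein_index"))
  dt <- fread_text(path, colClasses = list(character = 1))
  ids <- dt[[1]]
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  out <- matrix(0, length(index), ncol(m),
                dimnames = list(index$ids, colnames(m)))
  hit <- ids %in% index$ids
  out[ids[hit], ] <- m[hit, , drop = FALSE]
  out
}

#' Drop attributes supported by too few proteins
#'
#' Removes indicator columns with fewer than `min_support` positive proteins
#' (default 6, i.e. "fewer than six proteins are removed").
#'
#' @param attrs Binary attribute matrix (proteins x attributes).
#' @param min_support Minimum column sum to retain.
#' @return The filtered matrix; warns if no columns survive.
#' @export
filter_attributes <- function(attrs, min_support = 6) {
  stopifnot(is.matrix(attrs))
  keep <- colSums(attrs > 0) >= min_support
  if (!any(keep)) warning("no attribute columns survive the support filter")
  attrs[, keep, drop = FALSE]
}
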