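# Shared in-code fixtures: everything is generated programmatically.

# tiny three-protein index used by the I/O unit tests
tiny_index <- function() protein_index(c("A", "B", "C"))

# write an edge-list TSV and return its path
write_edges_tsv <- function(rows, path = tempfile(fileext = ".tsv"),
                            header = c("protein1", "protein2", "score")) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

# a small annotation table covering the three split windows
tiny_annotations <- function() {
  annotation_table(data.frame(
    protein = c("A", "A", "B", "C", "D"),
    go_term = c("GO:1", "GO:2", "GO:1", "GO:1", "GO:2"),
    evidence = c("IDA", "IEA", "IMP", "EXP", "IC"),
    date = c("2017-12-31", "2016-05-01", "2019-06-01", "2021-03-01",
             "2018-01-01"),
    aspect = "BP"))
}

# a deterministic random scores/labels pair for metric tests
random_scores_labels <- function(n, K, density = 0.3) {
  p <- matrix(runif(n * K), n, K)
  y <- matrix(rbinom(n * K, 1, density), n, K)
  list(p = p, y = y)
}

# small planted dataset for fast training unit tests (still passes the
# 10/5/1 and 5% label filters)
small_planted <- function(seed = 1) {
  generate_planted_dataset(synthetic_spec(n = 400, d_f = 32, K = 8,
                                          seed = seed))
}

# fast training config for mechanism (not performance) tests
fast_config <- function(seed = 1, ...) {
  train_config(E1 = 6, E2 = 3, E3 = 2, seed = seed, ...)
}

# independent brute-force protein-centric precision/recall (loops, no reuse
# of package internals beyond basic arithmetic)
brute_pr <- function(p, y, tau) {
  n <- nrow(p)
  prec_terms <- c()
  rec_terms <- c()
  s_tau <- 0
  for (i in seq_len(n)) {
    pred <- which(p[i, ] > tau)
    pos <- which(y[i, ] == 1)
    if (length(pred) > 0) {
      s_tau <- s_tau + 1
      prec_terms <- c(prec_terms, length(intersect(pred, pos)) / length(pred))
    }
    if (length(pos) > 0) {
      rec_terms <- c(rec_terms, length(intersect(pred, pos)) / length(pos))
    }
  }
  precision <- if (s_tau > 0) mean(prec_terms) else 0
  recall <- if (length(rec_terms) > 0) mean(rec_terms) else 0
  c(precision = precision, recall = recall, s_tau = s_tau)
}

brute_fmax <- function(p, y, grid = seq(0.01, 0.99, by = 0.01)) {
  best <- 0
  for (tau in grid) {
    pr <- brute_pr(p, y, tau)
    f <- if (pr[1] + pr[2] == 0) 0 else 2 * pr[1] * pr[2] / (pr[1] + pr[2])
    if (f > best) best <- f
  }
  unname(best)
}
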