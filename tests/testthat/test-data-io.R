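test_that("edge reader keeps only positive scores and symmetrizes", {
  idx <- tiny_index()
  path <- write_edges_tsv(list(c("A", "B", 700), c("B", "C", 0),
                               c("A", "C", 150)))
  net <- read_string_edges(path, "experimental", idx)
  expect_equal(net$adjacency["A", "B"], 700)
  expect_equal(net$adjacency["B", "A"], 700)
  expect_equal(net$adjacency["B", "C"], 0)  # zero score: no interaction
  expect_equal(net$adjacency["A", "C"], 150)
  expect_true(isSymmetric(unname(net$adjacency)))
})

test_that("empty edge list gives an all-zero adjacency", {
  path <- write_edges_tsv(list())
  net <- read_string_edges(path, "fusion", tiny_index())
  expect_equal(net$adjacency, matrix(0, 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
})

test_that("duplicate pairs keep the maximum score in either order", {
  idx <- tiny_index()
  path <- write_edges_tsv(list(c("A", "B", 700), c("B", "A", 500)))
  net <- read_string_edges(path, "database", idx)
  expect_equal(net$adjacency["A", "B"], 700)
  path2 <- write_edges_tsv(list(c("B", "A", 500), c("A", "B", 700)))
  net2 <- read_string_edges(path2, "database", idx)
  expect_equal(net2$adjacency, net$adjacency)  # order-independent
})

test_that("edge reader rejects unknown proteins and malformed scores", {
  idx <- tiny_index()
  bad <- write_edges_tsv(list(c("A", "Z", 10)))
  expect_error(read_string_edges(bad, "fusion", idx), "unknown protein.*Z")
  mal <- write_edges_tsv(list(c("A", "B", "high")))
  expect_error(read_string_edges(mal, "fusion", idx), "malformed score")
})

test_that("combined multi-channel files select the named column", {
  idx <- tiny_index()
  path <- write_edges_tsv(
    list(c("A", "B", 100, 0), c("A", "C", 0, 250)),
    header = c("protein1", "protein2", "coexpression", "textmining"))
  net <- read_string_edges(path, "textmining", idx)
  expect_equal(net$adjacency["A", "C"], 250)
  expect_equal(net$adjacency["A", "B"], 0)
})

test_that("edge-list round trip reproduces the adjacency exactly", {
  set.seed(11)
  ids <- sprintf("P%02d", 1:12)
  adj <- matrix(0, 12, 12, dimnames = list(ids, ids))
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  hit <- pairs[sample(nrow(pairs), 20), ]
  w <- round(runif(20) * 1000) / 7  # non-trivial decimals
  adj[hit] <- w
  adj[hit[, c(2, 1)]] <- w
  net <- evidence_network(adj, "coexpression")
  path <- tempfile(fileext = ".tsv")
  write_string_edges(net, path)
  back <- read_string_edges(path, "coexpression", protein_index(ids))
  expect_equal(back$adjacency, net$adjacency)
})

test_that("gzipped edge lists read identically to plain ones", {
  idx <- tiny_index()
  rows <- list(c("A", "B", 700), c("A", "C", 150))
  plain <- write_edges_tsv(rows)
  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(plain), con)
  close(con)
  expect_equal(read_string_edges(gz, "textmining", idx)$adjacency,
               read_string_edges(plain, "textmining", idx)$adjacency)
})

test_that("temporal split follows the CAFA windows with earliest dates", {
  sp <- temporal_split(tiny_annotations())
  # A: earliest 2016-05-01 -> train; boundary day 2018-01-01 -> train
  expect_equal(as.character(sp[["A"]]), "train")
  expect_equal(as.character(sp[["D"]]), "train")
  expect_equal(as.character(sp[["B"]]), "val")   # 2019-06-01
  expect_equal(as.character(sp[["C"]]), "test")  # 2021-03-01
})

test_that("temporal split partitions the annotated proteins", {
  set.seed(21)
  n <- 60
  df <- data.frame(
    protein = sprintf("Q%03d", sample(n, 200, replace = TRUE)),
    go_term = sample(c("GO:1", "GO:2", "GO:3"), 200, replace = TRUE),
    evidence = "IDA",
    date = format(as.Date("2014-01-01") + sample.int(3300, 200, TRUE), "%Y-%m-%d"),
    aspect = "BP")
  tab <- annotation_table(df)
  sp <- temporal_split(tab)
  expect_setequal(names(sp), unique(df$protein))
  expect_false(anyNA(sp))
  # brute-force recount of the assignment
  for (pr in sample(names(sp), 10)) {
    d <- min(tab$date[tab$protein == pr])
    want <- if (d <= as.Date("2018-01-01")) "train"
            else if (d <= as.Date("2020-12-31")) "val" else "test"
    expect_equal(as.character(sp[[pr]]), want)
  }
})

test_that("unparseable dates are dropped with a warning", {
  df <- data.frame(protein = c("A", "B"), go_term = "GO:1", evidence = "IDA",
                   date = c("2017-01-01", "not-a-date"), aspect = "BP")
  expect_warning(tab <- annotation_table(df), "unparseable")
  expect_equal(nrow(tab), 1)
})

test_that("one-hot labels honor the evidence whitelist and are idempotent", {
  idx <- protein_index(c("A", "B", "C", "D"))
  y <- onehot_labels(tiny_annotations(), idx, "BP")
  expect_equal(y["A", "GO:1"], 1L)  # IDA whitelisted
  expect_equal(y["A", "GO:2"], 0L)  # IEA not whitelisted
  expect_equal(y["D", "GO:2"], 1L)  # IC whitelisted
  # duplicated record stays binary
  dup <- annotation_table(rbind(as.data.frame(tiny_annotations()),
    data.frame(protein = "A", go_term = "GO:1", evidence = "EXP",
               date = "2015-01-01", aspect = "BP")))
  expect_equal(onehot_labels(dup, idx, "BP")["A", "GO:1"], 1L)
  expect_error(onehot_labels(tiny_annotations(), idx, "BP", evidence = character(0)),
               "non-empty")
})

test_that("label filter applies the 10/5/1 and 5% rules at their boundaries", {
  set.seed(5)
  make_lm <- function(counts, n = 1000) {
    # counts: list of c(train, val, test) per term
    ids <- sprintf("P%04d", seq_len(n))
    split <- factor(rep(c("train", "val", "test"), times = c(600, 250, 150)),
                    levels = c("train", "val", "test"))
    names(split) <- ids
    K <- length(counts)
    y <- matrix(0L, n, K, dimnames = list(ids, sprintf("GO:%d", seq_len(K))))
    for (k in seq_len(K)) {
      ct <- counts[[k]]
      y[which(split == "train")[seq_len(ct[1])], k] <- 1L
      y[which(split == "val")[seq_len(ct[2])], k] <- 1L
      y[which(split == "test")[seq_len(ct[3])], k] <- 1L
    }
    label_matrix(y, split)
  }
  lm <- make_lm(list(c(12, 6, 2),    # retained: all thresholds met, total 20
                     c(9, 6, 2),     # removed: 9 < 10 train
                     c(12, 4, 2),    # removed: 4 < 5 val
                     c(12, 6, 0),    # removed: no test protein
                     c(40, 15, 5)))  # removed: total 60 > 50 = 5% of 1000
  fl <- filter_labels(lm, n_network = 1000)
  expect_equal(fl$terms, "GO:1")
  # boundary: exactly 5% stays
  lm2 <- make_lm(list(c(40, 9, 1)))  # total 50 == cap
  expect_equal(filter_labels(lm2, 1000)$terms, "GO:1")
  expect_error(filter_labels(make_lm(list(c(1, 1, 1))), 1000), "no GO terms")
})

test_that("label filter is idempotent and matches a brute-force recount", {
  set.seed(6)
  ds <- small_planted(seed = 3)
  lm <- ds$labels
  fl <- filter_labels(lm, n_network = 400)
  expect_identical(filter_labels(fl, n_network = 400), fl)
  # brute force from the full y
  for (k in seq_along(fl$terms)) {
    ct <- sapply(fl$y, function(m) sum(m[, k]))
    expect_true(ct[1] >= 10 && ct[2] >= 5 && ct[3] >= 1 && sum(ct) <= 20)
  }
})

test_that("attribute filter drops columns with fewer than six proteins", {
  x <- cbind(a = c(rep(1, 6), rep(0, 14)),
             b = c(rep(1, 5), rep(0, 15)),
             c = rep(0, 20))
  out <- filter_attributes(x)
  expect_equal(colnames(out), "a")   # support 6 retained, 5 and 0 removed
  expect_warning(filter_attributes(x[, "b", drop = FALSE]), "no attribute")
})

test_that("protein index enforces uniqueness and resolves positions", {
  expect_error(protein_index(c("A", "A")), "duplicated")
  idx <- tiny_index()
  expect_equal(protein_position(idx, c("C", "A")), c(3L, 1L))
  expect_error(protein_position(idx, "Z"), "unknown")
  path <- tempfile()
  write_protein_index(idx, path)
  expect_equal(read_protein_index(path)$ids, idx$ids)
})
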