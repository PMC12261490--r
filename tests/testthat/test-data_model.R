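# Loading, validation, preprocessing, batching, and task splits.

test_that("expression_series validates shapes and values", {
  m1 <- matrix(1, 3, 4); m2 <- matrix(2, 2, 4)
  es <- expression_series(list(m1, m2), paste0("g", 1:4), c("d0", "d2"),
                          list(rep("A", 3), rep("A", 2)))
  expect_s3_class(es, "expression_series")
  expect_equal(dim(es), c(5L, 4L))
  expect_error(expression_series(list(m1), paste0("g", 1:5), "d0",
                                 list(rep("A", 3))), "columns")
  expect_error(expression_series(list(-m1), paste0("g", 1:4), "d0",
                                 list(rep("A", 3))), "nonnegative")
  expect_error(expression_series(list(m1 * NA), paste0("g", 1:4), "d0",
                                 list(rep("A", 3))), "finite")
})

test_that("write/load round-trip preserves matrices, labels, and gene order", {
  sim <- small_sim()
  dir <- file.path(tempdir(), "rt")
  write_expression_series(sim$series, dir)
  mtx <- sort(list.files(dir, pattern = "\\.mtx$", full.names = TRUE))
  back <- load_expression(mtx, file.path(dir, "metadata.tsv"),
                          file.path(dir, "genes.txt"),
                          tf_path = file.path(dir, "tfs.txt"))
  expect_equal(back$gene_names, sim$series$gene_names)
  expect_equal(back$tf_indices, sim$series$tf_indices)
  expect_equal(back$cell_types, sim$series$cell_types)
  for (t in seq_along(back$matrices)) {
    expect_equal(back$matrices[[t]], sim$series$matrices[[t]],
                 ignore_attr = TRUE)
  }
})

test_that("load_expression rejects mismatched gene lists and cell counts", {
  sim <- small_sim()
  dir <- file.path(tempdir(), "bad")
  write_expression_series(sim$series, dir)
  mtx <- sort(list.files(dir, pattern = "\\.mtx$", full.names = TRUE))
  genes5 <- file.path(dir, "genes5.txt")
  writeLines(c(sim$series$gene_names, "EXTRA"), genes5)
  expect_error(load_expression(mtx, file.path(dir, "metadata.tsv"), genes5),
               "gene columns")
  # a single file with several time labels is read as a combined matrix,
  # so the cell-count mismatch is caught
  expect_error(load_expression(mtx[1L], file.path(dir, "metadata.tsv"),
                               file.path(dir, "genes.txt")),
               "metadata lists")
})

test_that("a cell type missing at one time point still loads", {
  m <- matrix(1, 2, 3)
  es <- expression_series(list(m, m), paste0("g", 1:3), c("t1", "t2"),
                          list(c("A", "B"), c("A", "A")))
  expect_true("B" %in% es$cell_type_levels)
  es$tf_indices <- 1L
  # the type is merely unavailable for batching at the time point it misses
  expect_error(sample_temporal_batch(es, "B", 1L), "t2")
  expect_silent(sample_temporal_batch(es, "A", 1L))
})

test_that("edge database loads with dedup, mode retention, and row skipping", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("A\tX\tActivation", "A\tX\tActivation", "B\tY\tRepression",
               "C\t", "D\tD"), f)
  expect_warning(expect_warning(db <- load_edge_database(f), "malformed"),
                 "self-loop")
  expect_equal(nrow(db), 3L)
  expect_equal(sort(unique(db$tf)), c("A", "B", "D"))
  expect_equal(db$mode[db$tf == "B"], "Repression")
  expect_true(db$self_loop[db$tf == "D"])
  # header detection
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("TF\ttarget", "A\tX"), f2)
  expect_equal(nrow(load_edge_database(f2)), 1L)
  f3 <- tempfile(fileext = ".tsv")
  writeLines(character(0), f3)
  expect_error(load_edge_database(f3), "empty")
})

test_that("restriction to database genes recomputes the TF universe and is idempotent", {
  m <- matrix(1:10, 2, 5)
  es <- expression_series(list(m), c("A", "B", "X", "Y", "Z"), "t1",
                          list(c("c1", "c2")))
  db <- data.frame(tf = c("A", "B"), target = c("X", "Y"))
  r1 <- restrict_to_database_genes(es, db)
  expect_equal(r1$gene_names, c("A", "B", "X", "Y"))
  expect_equal(r1$gene_names[r1$tf_indices], c("A", "B"))
  r2 <- restrict_to_database_genes(r1, db)
  expect_equal(r2$gene_names, r1$gene_names)
  expect_equal(r2$matrices, r1$matrices)
  db_none <- data.frame(tf = "Q", target = "W")
  expect_error(restrict_to_database_genes(es, db_none), "no expression genes")
})

test_that("preprocess normalizes to the median library and drops empty cells", {
  m <- rbind(c(1, 3), c(2, 2), c(0, 0))
  es <- expression_series(list(m), c("g1", "g2"), "t1",
                          list(c("A", "A", "B")))
  expect_warning(pp <- preprocess(es), "all-zero")
  expect_equal(nrow(pp$matrices[[1L]]), 2L)
  # both remaining cells have library 4 = median; values log1p(counts)
  expect_equal(pp$matrices[[1L]][1L, ], log1p(c(1, 3)), ignore_attr = TRUE)
  # determinism: identical cells give identical normalized rows
  m2 <- rbind(c(2, 4), c(2, 4))
  pp2 <- preprocess(expression_series(list(m2), c("g1", "g2"), "t1",
                                      list(c("A", "A"))))
  expect_equal(pp2$matrices[[1L]][1L, ], pp2$matrices[[1L]][2L, ])
})

test_that("temporal batches contain a single cell type and are seed-reproducible", {
  sim <- small_sim()
  pre <- preprocess(sim$series)
  set.seed(1); b1 <- sample_temporal_batch(pre, "type1", 8L)
  set.seed(1); b2 <- sample_temporal_batch(pre, "type1", 8L)
  expect_identical(b1$x, b2$x)
  expect_equal(vapply(b1$x, nrow, integer(1)), rep(8L, 2L))
  expect_equal(ncol(b1$tf_view[[1L]]), length(pre$tf_indices))
  # property: sampled rows always come from the requested type
  set.seed(2)
  for (rep in 1:20) {
    ct <- sample(pre$cell_type_levels, 1L)
    bb <- suppressWarnings(sample_temporal_batch(pre, ct, 40L))
    for (t in seq_along(bb$x)) {
      pool <- pre$matrices[[t]][pre$cell_types[[t]] == ct, , drop = FALSE]
      found <- apply(bb$x[[t]], 1L, function(r) {
        any(colSums(abs(t(pool) - r)) < 1e-12)
      })
      expect_true(all(found))
    }
  }
  # with-replacement fallback warns (once per short time point)
  w <- capture_warnings(sample_temporal_batch(pre, "type1", 1000L))
  expect_true(all(grepl("replacement", w)))
  expect_gt(length(w), 0L)
  # absent type errors with the time point named
  es <- expression_series(list(matrix(1, 2, 3), matrix(1, 2, 3)),
                          paste0("g", 1:3), c("t1", "t2"),
                          list(c("A", "B"), c("A", "A")), tf_indices = 1L)
  expect_error(sample_temporal_batch(es, "B", 1L), "t2")
})

test_that("task splits are disjoint, covering, deterministic, and tie toward support", {
  sim <- small_sim()
  pre <- preprocess(sim$series)
  set.seed(9); s1 <- make_task_splits(pre, 0.5)
  set.seed(9); s2 <- make_task_splits(pre, 0.5)
  expect_identical(s1, s2)
  for (ct in names(s1)) {
    for (t in seq_along(s1[[ct]]$support)) {
      sup <- s1[[ct]]$support[[t]]; qry <- s1[[ct]]$query[[t]]
      expect_length(intersect(sup, qry), 0L)
      expect_setequal(c(sup, qry), which(pre$cell_types[[t]] == ct))
      expect_gt(length(sup), 0L); expect_gt(length(qry), 0L)
    }
  }
  # 3 cells at fraction 0.5 -> support gets 2
  es <- expression_series(list(matrix(1, 6, 3)), paste0("g", 1:3), "t1",
                          list(c("A", "A", "A", "B", "B", "B")),
                          tf_indices = 1L)
  set.seed(1)
  sp <- make_task_splits(es, 0.5)
  expect_length(sp$A$support[[1L]], 2L)  # ceiling(0.5 * 3): support wins ties
  es2 <- expression_series(list(matrix(1, 4, 3)), paste0("g", 1:3), "t1",
                           list(c("A", "A", "A", "B")), tf_indices = 1L)
  expect_warning(sp2 <- make_task_splits(es2, 0.5), "excluded")
  expect_named(sp2, "A")
})
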