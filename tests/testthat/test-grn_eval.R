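# Sparsification, overlap statistics, IoU, gene ranking, and recovery
# metrics.

test_that("top-fraction sparsification keeps exact counts with the stated tie rule", {
  set.seed(50)
  A <- matrix(runif(100 * 50), 100, 50)
  E <- sparsify_top_fraction(A, 0.02)
  expect_equal(nrow(E), 100L)  # ceiling(0.02 * 5000)
  expect_equal(nrow(sparsify_top_fraction(A, 1)), 5000L)
  expect_true(all(diff(E$weight) <= 0))
  # the retained edges are exactly the largest entries
  expect_equal(sort(E$weight, decreasing = TRUE),
               sort(A, decreasing = TRUE)[1:100])
  # all-equal entries: deterministic index-ordered selection
  Aeq <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4), paste0("f", 1:3)))
  Eeq <- sparsify_top_fraction(Aeq, 0.5)
  expect_equal(nrow(Eeq), 6L)
  # smaller (gene, TF) index first, gene-major
  expect_equal(Eeq$target, paste0("g", c(1, 1, 1, 2, 2, 2)))
  expect_equal(Eeq$tf, paste0("f", c(1, 2, 3, 1, 2, 3)))
})

test_that("Fisher overlap matches the enumeration oracle and fisher.test", {
  genes <- paste0("g", 1:10); tfs <- paste0("f", 1:2)  # universe of 20
  mk <- function(keys) {
    data.frame(tf = sub("_.*", "", keys), target = sub(".*_", "", keys))
  }
  all_pairs <- as.vector(outer(tfs, genes, paste, sep = "_"))
  db <- mk(all_pairs[1:4])
  pred <- mk(all_pairs[c(1, 2, 3, 7, 15)])  # overlap 3 of 5 predicted
  fo <- fisher_overlap(pred, db, genes, tfs)
  expect_equal(c(fo$a, fo$b, fo$c, fo$d), c(3, 2, 1, 14))
  expect_equal(fo$p_value, enum_hyper_tail(20, 4, 5, 3), tolerance = 1e-12)
  ft <- fisher.test(matrix(c(3, 2, 1, 14), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(fo$p_value, ft$p.value, tolerance = 1e-10)
  # empty prediction: a = 0, p = 1
  f0 <- fisher_overlap(mk(character(0)), db, genes, tfs)
  expect_equal(f0$a, 0); expect_equal(f0$p_value, 1)
  # degenerate margins: everything predicted and everything in the database
  f1 <- fisher_overlap(mk(all_pairs), mk(all_pairs), genes, tfs)
  expect_equal(f1$p_value, 1)
  expect_error(fisher_overlap(pred, db, character(0), tfs), "empty")
})

test_that("BH correction reproduces the hand-computed step-up values", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(0.37), 0.37)
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  # independent step-up implementation on random vectors
  set.seed(51)
  for (rep in 1:5) {
    p <- runif(7)
    n <- length(p)
    o <- order(p)
    hand <- numeric(n)
    hand[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
    hand <- pmin(hand, 1)
    expect_equal(bh_correct(p), hand, tolerance = 1e-12)
  }
  expect_error(bh_correct(c(0.5, 1.2)))
})

test_that("edge-set IoU has the forced values and properties", {
  mk <- function(...) data.frame(tf = c(...), target = c(...))
  a <- data.frame(tf = c("a", "b"), target = c("x", "y"))
  b <- data.frame(tf = c("b", "c"), target = c("y", "z"))
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(iou(a, data.frame(tf = "q", target = "q")), 0)
  expect_equal(iou(a[0, ], b[0, ]), 1)  # both empty
  expect_equal(iou(a, b), iou(b, a))
  set.seed(52)
  for (rep in 1:20) {
    E1 <- data.frame(tf = sample(letters[1:4], 6, TRUE),
                     target = sample(letters[5:9], 6, TRUE))
    E2 <- data.frame(tf = sample(letters[1:4], 6, TRUE),
                     target = sample(letters[5:9], 6, TRUE))
    v <- iou(E1, E2)
    expect_gte(v, 0); expect_lte(v, 1)
    if (v == 1) expect_setequal(marlene:::edge_keys(E1), marlene:::edge_keys(E2))
  }
})

test_that("newly regulated genes are targets gaining their first regulator", {
  E0 <- data.frame(tf = character(0), target = character(0))
  E1 <- data.frame(tf = "a", target = "x")
  expect_equal(newly_regulated_genes(E0, E1), "x")
  expect_equal(newly_regulated_genes(E1, data.frame(tf = "b", target = "x")),
               character(0))
  E2 <- data.frame(tf = c("a", "a", "b"), target = c("x", "y", "z"))
  expect_setequal(newly_regulated_genes(E1, E2), c("y", "z"))
})

test_that("top regulated genes rank by incoming sparsified weight", {
  A <- matrix(0, 4, 2, dimnames = list(paste0("g", 1:4), paste0("f", 1:2)))
  A[2, ] <- c(0.6, 0.7)   # g2 holds the most incoming weight
  A[3, 1] <- 0.9
  expect_equal(top_regulated_genes(A, 2L, fraction = 1)[1L], "g2")
  expect_equal(top_regulated_genes(A, 4L, fraction = 1),
               c("g2", "g3", "g1", "g4"))  # zero-mass ties resolve by index
  expect_equal(top_regulated_genes(A, 4L, fraction = 0.5, method = "count")[1L],
               "g2")
  expect_error(top_regulated_genes(A, 9L), "exceeds")
})

test_that("gene-set overlap test matches the hypergeometric oracle", {
  uni <- paste0("G", 1:50)
  ref <- uni[1:10]
  drawn <- uni[c(1:4, 30)]  # overlap 4 of 5 drawn
  expect_equal(geneset_overlap_test(drawn, ref, uni),
               enum_hyper_tail(50, 10, 5, 4), tolerance = 1e-12)
  expect_equal(geneset_overlap_test(uni, uni, uni), 1)
  expect_gt(geneset_overlap_test(uni[30:31], ref, uni), 0.5)
  expect_error(geneset_overlap_test("a", "b", character(0)), "empty")
})

test_that("recovery metrics behave at the informative and uninformative extremes", {
  set.seed(53)
  g <- 30L; p <- 5L
  genes <- c(paste0("TF", 1:p), paste0("G", (p + 1):g))
  planted <- matrix(rbinom(g * p, 1, 0.1), g, p,
                    dimnames = list(genes, genes[1:p]))
  diag(planted[1:p, ]) <- 0
  pl <- list(planted)
  # near-perfect scores rank planted edges first
  noisy <- planted + matrix(runif(g * p, 0, 1e-3), g, p)
  m1 <- recovery_metrics(list(noisy), pl)
  expect_gt(m1$auprc, 0.99)
  expect_gt(m1$auroc, 0.99)
  # constant scores: average precision equals prevalence
  m2 <- recovery_metrics(list(matrix(0.5, g, p)), pl)
  expect_equal(m2$auprc, m2$prevalence, tolerance = 1e-12)
  # random scores hover at chance AUROC over repetitions
  aur <- replicate(30, {
    recovery_metrics(list(matrix(runif(g * p), g, p)), pl)$auroc
  })
  expect_lt(abs(mean(aur) - 0.5), 0.05)
  expect_error(recovery_metrics(list(noisy, noisy), pl), "time point")
})

test_that("gene-set files load and the report helpers assemble correctly", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("setA\tG1", "setA\tG2", "setB\tG3"), f)
  gs <- load_gene_sets(f)
  expect_named(gs, c("setA", "setB"))
  expect_equal(gs$setA, c("G1", "G2"))
  # report helpers over a hand-built adjacency series
  genes <- c("TF1", "TF2", paste0("G", 3:8))
  tfs <- genes[1:2]
  set.seed(54)
  mk_adj <- function() {
    A <- lapply(1:2, function(t) {
      m <- matrix(runif(16), 8, 2, dimnames = list(genes, tfs))
      m / rowSums(m)
    })
    structure(list(A = A, tf_indices = 1:2), class = "adjacency_series")
  }
  grns <- list(typeA = mk_adj(), typeB = mk_adj())
  db <- data.frame(tf = c("TF1", "TF2"), target = c("G3", "G4"))
  rep_ <- grn_overlap_report(grns, db, genes, tfs, fraction = 0.25)
  expect_equal(nrow(rep_), 4L)  # 2 types x 2 time points
  expect_true(all(rep_$a + rep_$b + rep_$c + rep_$d == 16L))
  expect_true(all(rep_$FDR >= rep_$p))
  expect_equal(rep_$FDR, bh_correct(rep_$p))
  it <- grn_iou_table(grns, genes, tfs, fraction = 0.25)
  expect_equal(nrow(it), 2L)
  expect_true(all(it$iou >= 0 & it$iou <= 1))
})
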