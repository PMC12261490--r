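# GRN sparsification and the evaluation statistics: Fisher overlap against a
# reference edge database, BH correction, transition IoU, newly regulated
# genes, top regulated genes, gene-set overlap, and edge-recovery metrics.

edge_keys <- function(E) {
  if (is.data.frame(E)) paste(E$tf, E$target, sep = "\r") else as.character(E)
}

#' Keep the top fraction of edges of a weighted adjacency matrix
#'
#' Retains the `ceiling(fraction * g * p)` largest entries as directed
#' TF -> target edges. Ties are broken by larger weight first, then by
#' smaller (gene, TF) index.
#'
#' @param A_t g x p weighted adjacency (rows = genes/targets, columns = TFs);
#'   row and column names, if present, name the edges.
#' @param fraction fraction of the g*p possible edges to keep, in (0, 1].
#' @param gene_names,tf_names optional names overriding dimnames.
#' @return a data frame with columns `tf`, `target`, `weight`, ordered by
#'   decreasing weight.
#' @export
sparsify_top_fraction <- function(A_t, fraction, gene_names = rownames(A_t),
                                  tf_names = colnames(A_t)) {
  stopifnot(fraction > 0, fraction <= 1)
  g <- nrow(A_t); p <- ncol(A_t)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(g))
  if (is.null(tf_names)) tf_names <- paste0("tf", seq_len(p))
  m <- ceiling(fraction * g * p)
  gi <- rep(seq_len(g), times = p)
  ti <- rep(seq_len(p), each = g)
  w <- as.vector(A_t)
  ord <- order(-w, gi, ti)[seq_len(m)]
  out <- data.frame(tf = tf_names[ti[ord]], target = gene_names[gi[ord]],
                    weight = w[ord], stringsAsFactors = FALSE)
  class(out) <- c("grn_edges", "data.frame")
  out
}

# Sparsify a whole adjacency series into a weighted GRN edge table.
grn_from_adjacency <- function(adj, fraction, gene_names, tf_names,
                               time_labels = NULL) {
  A <- if (inherits(adj, "adjacency_series")) adj$A else adj
  if (is.null(time_labels)) time_labels <- seq_along(A)
  rows <- lapply(seq_along(A), function(t) {
    e <- sparsify_top_fraction(A[[t]], fraction, gene_names, tf_names)
    cbind(data.frame(time = time_labels[t]), e)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("weighted_grn", "data.frame")
  out
}

#' Write a weighted GRN to a TSV file
#'
#' Columns `time`, `TF`, `target`, `weight`, one edge per row.
#'
#' @param grn a `"weighted_grn"` data frame (see [predict.marlene()]).
#' @param path output file.
#' @export
write_grn <- function(grn, path) {
  out <- data.frame(time = grn$time, TF = grn$tf, target = grn$target,
                    weight = grn$weight)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fisher's exact overlap test between predicted and database edges
#'
#' Builds the 2x2 contingency table of predicted vs database edges over the
#' universe of all (TF, gene) pairs, and computes the one-sided (enrichment)
#' exact hypergeometric p-value and the odds ratio `(a d) / (b c)` (with a
#' 0.5 continuity correction when any cell is zero).
#'
#' @param pred predicted edge set: data frame with `tf` and `target` columns.
#' @param db an [load_edge_database()] result (or any data frame with `tf`,
#'   `target`); edges outside the universe are dropped.
#' @param genes gene universe (targets).
#' @param tfs TF universe (sources).
#' @return list with `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`.
#' @export
fisher_overlap <- function(pred, db, genes, tfs) {
  N <- length(genes) * length(tfs)
  if (N == 0L) stop("empty edge universe")
  in_universe <- function(E) {
    keep <- E$tf %in% tfs & E$target %in% genes
    unique(edge_keys(E[keep, , drop = FALSE]))
  }
  P <- in_universe(pred)
  D <- in_universe(db)
  a <- length(intersect(P, D))
  b <- length(P) - a
  c_ <- length(D) - a
  d <- N - a - b - c_
  # P(X >= a) with |D| successes among N, |P| draws
  p <- stats::phyper(a - 1, length(D), N - length(D), length(P),
                     lower.tail = FALSE)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(a = a, b = b, c = c_, d = d, odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotonized and capped at 1;
#' order-preserving with the input.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_correct <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Intersection-over-union of two edge sets
#'
#' Edges are compared by (TF, target) identity, ignoring weights; defined
#' as 1 when both sets are empty.
#'
#' @param E_a,E_b edge sets: data frames with `tf`, `target` columns (or
#'   character key vectors).
#' @return numeric in `[0, 1]`.
#' @export
iou <- function(E_a, E_b) {
  A <- unique(edge_keys(E_a))
  B <- unique(edge_keys(E_b))
  u <- length(union(A, B))
  if (u == 0L) return(1)
  length(intersect(A, B)) / u
}

#' Genes newly regulated at the next time point
#'
#' Targets with at least one incoming edge in `E_next` but none in `E_t`.
#'
#' @param E_t,E_next sparsified edge sets (data frames with `tf`, `target`).
#' @return character vector of gene names.
#' @export
newly_regulated_genes <- function(E_t, E_next) {
  setdiff(unique(E_next$target), unique(E_t$target))
}

#' Rank genes by total incoming regulatory weight
#'
#' Sparsifies the adjacency to its top `fraction` of edges, sums incoming
#' edge weight per target gene (or counts incoming edges with
#' `method = "count"`), and returns the `n` highest-ranked genes (ties go to
#' the smaller gene index).
#'
#' @param A_t g x p weighted adjacency with gene row names.
#' @param n number of genes to return.
#' @param fraction sparsification fraction applied first.
#' @param method `"weight"` (sum of incoming weights) or `"count"`
#'   (indegree).
#' @return character vector of n gene names, most regulated first.
#' @export
top_regulated_genes <- function(A_t, n, fraction = 0.02,
                                method = c("weight", "count")) {
  method <- match.arg(method)
  if (n > nrow(A_t)) stop("n exceeds the number of genes")
  gene_names <- rownames(A_t)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(nrow(A_t)))
  E <- sparsify_top_fraction(A_t, fraction, gene_names, colnames(A_t))
  val <- if (method == "weight") {
    tapply(E$weight, factor(E$target, levels = gene_names), sum, default = 0)
  } else {
    tapply(rep(1, nrow(E)), factor(E$target, levels = gene_names), sum,
           default = 0)
  }
  ord <- order(-as.numeric(val), seq_along(val))
  gene_names[ord][seq_len(n)]
}

#' Hypergeometric gene-set overlap test
#'
#' One-sided tail probability `P(X >= |genes intersect reference|)` for
#' drawing `|genes|` genes from the universe containing `|reference|`
#' successes.
#'
#' @param genes query gene set (e.g. top regulated genes).
#' @param reference reference set (e.g. a curated signature), restricted to
#'   the universe.
#' @param universe all candidate genes.
#' @return p-value.
#' @export
geneset_overlap_test <- function(genes, reference, universe) {
  if (!length(universe)) stop("empty gene universe")
  genes <- intersect(unique(genes), universe)
  reference <- intersect(unique(reference), universe)
  x <- length(intersect(genes, reference))
  stats::phyper(x - 1, length(reference),
                length(universe) - length(reference), length(genes),
                lower.tail = FALSE)
}

#' Overlap report for a fitted model's GRNs
#'
#' For every cell type and time point, sparsifies the averaged adjacency,
#' tests its overlap with the reference edge database (one-sided Fisher), and
#' BH-corrects the p-values jointly across all cell types and time points
#' reported together.
#'
#' @param grns named list per cell type of dense `"adjacency_series"`
#'   objects (from [predict.marlene()] with `fraction = NULL`).
#' @param db reference [load_edge_database()].
#' @param gene_names,tf_names the analyzed gene and TF universes.
#' @param fraction edge fraction retained per time point.
#' @param time_labels optional time labels for the report.
#' @return data frame with cell_type, time, a, b, c, d, odds_ratio, p, FDR.
#' @export
grn_overlap_report <- function(grns, db, gene_names, tf_names,
                               fraction = 0.02, time_labels = NULL) {
  rows <- NULL
  for (ct in names(grns)) {
    A <- grns[[ct]]$A
    if (is.null(time_labels)) time_labels <- seq_along(A)
    for (t in seq_along(A)) {
      E <- sparsify_top_fraction(A[[t]], fraction, gene_names, tf_names)
      fo <- fisher_overlap(E, db, gene_names, tf_names)
      rows <- rbind(rows, data.frame(
        cell_type = ct, time = time_labels[t], a = fo$a, b = fo$b, c = fo$c,
        d = fo$d, odds_ratio = fo$odds_ratio, p = fo$p_value))
    }
  }
  rows$FDR <- bh_correct(rows$p)
  rows
}

#' Transition IoU table for a fitted model's GRNs
#'
#' IoU between the sparsified edge sets of consecutive time points, per
#' cell type.
#'
#' @inheritParams grn_overlap_report
#' @return data frame with cell_type, transition, iou.
#' @export
grn_iou_table <- function(grns, gene_names, tf_names, fraction = 0.02,
                          time_labels = NULL) {
  rows <- NULL
  for (ct in names(grns)) {
    A <- grns[[ct]]$A
    if (is.null(time_labels)) time_labels <- seq_along(A)
    E <- lapply(A, sparsify_top_fraction, fraction = fraction,
                gene_names = gene_names, tf_names = tf_names)
    for (t in seq_len(length(A) - 1L)) {
      rows <- rbind(rows, data.frame(
        cell_type = ct,
        transition = paste(time_labels[t], time_labels[t + 1L], sep = "->"),
        iou = iou(E[[t]], E[[t + 1L]])))
    }
  }
  rows
}

# ---- edge-recovery metrics against planted ground truth ----

average_precision <- function(scores, labels) {
  n_pos <- sum(labels)
  if (!n_pos) return(NA_real_)
  # tied scores form one PR step each, so an uninformative constant scorer
  # lands exactly at prevalence
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  pos_in <- tapply(l, grp, sum)
  size <- tapply(rep(1, length(l)), grp, sum)
  cum_n <- cumsum(size)
  cum_pos <- cumsum(pos_in)
  sum(pos_in * (cum_pos / cum_n)) / n_pos
}

rank_auroc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (!n1 || !n0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Edge-recovery metrics against a planted network series
#'
#' Scores the dense predicted adjacency matrices against the planted binary
#' networks of one cell type: per time point, the area under the
#' precision-recall curve (average precision) and the ROC curve of the dense
#' weights, the precision of the top `fraction` edge set, and the IoU of
#' that edge set with the planted edges. Structural self-pairs (a TF
#' regulating itself) are excluded from scoring.
#'
#' @param pred an `"adjacency_series"` or list of g x p weight matrices.
#' @param planted list of g x p binary matrices (one per time point), e.g.
#'   one element of [plant_networks()]'s `networks`.
#' @param fraction edge fraction for the sparsified precision/IoU.
#' @param gene_names,tf_names edge names; default from the planted matrices.
#' @return data frame with time, auprc, auroc, precision_top, iou_top,
#'   prevalence.
#' @export
recovery_metrics <- function(pred, planted, fraction = 0.02,
                             gene_names = rownames(planted[[1L]]),
                             tf_names = colnames(planted[[1L]])) {
  A <- if (inherits(pred, "adjacency_series")) pred$A else pred
  if (length(A) != length(planted)) stop("time point counts differ")
  if (!all(dim(A[[1L]]) == dim(planted[[1L]]))) stop("matrix shapes differ")
  g <- nrow(planted[[1L]]); p <- ncol(planted[[1L]])
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(g))
  if (is.null(tf_names)) tf_names <- paste0("tf", seq_len(p))
  self <- outer(gene_names, tf_names, `==`)
  keep <- !as.vector(self)
  rows <- NULL
  for (t in seq_along(A)) {
    sc <- as.vector(A[[t]])[keep]
    lb <- as.vector(planted[[t]])[keep]
    Et <- sparsify_top_fraction(A[[t]], fraction, gene_names, tf_names)
    Pt <- which(planted[[t]] == 1, arr.ind = TRUE)
    planted_edges <- data.frame(tf = tf_names[Pt[, 2L]],
                                target = gene_names[Pt[, 1L]])
    inter <- length(intersect(edge_keys(Et), edge_keys(planted_edges)))
    rows <- rbind(rows, data.frame(
      time = t,
      auprc = average_precision(sc, lb),
      auroc = rank_auroc(sc, lb),
      precision_top = inter / nrow(Et),
      iou_top = iou(Et, planted_edges),
      prevalence = mean(lb)))
  }
  rows
}

#' Per-time-point TF-target correlation scores
#'
#' A simple association baseline: the absolute Pearson correlation between
#' every gene and every TF across the cells of each time point (pooling all
#' cell types, or one type if given). Useful as an uninformative-vs-informative
#' signal check on simulated data.
#'
#' @param series an [expression_series()] with TF indices.
#' @param cell_type optional cell type restriction.
#' @return list of g x p score matrices, one per time point.
#' @export
correlation_scores <- function(series, cell_type = NULL) {
  tf <- series$tf_indices
  lapply(seq_along(series$matrices), function(t) {
    m <- series$matrices[[t]]
    if (!is.null(cell_type)) {
      m <- m[series$cell_types[[t]] == cell_type, , drop = FALSE]
    }
    suppressWarnings(cc <- abs(stats::cor(m, m[, tf, drop = FALSE])))
    cc[!is.finite(cc)] <- 0
    rownames(cc) <- series$gene_names
    colnames(cc) <- series$gene_names[tf]
    cc
  })
}
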