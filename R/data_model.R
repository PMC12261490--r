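# Time-series single-cell expression containers, loaders, preprocessing,
# batching, and MAML task splits.

#' Construct a time-series expression container
#'
#' Holds one cell-by-gene matrix per time point together with gene names,
#' the TF index set, ordered time labels, and per-cell cell-type labels.
#' Validates the shared invariants: identical gene order across time points,
#' nonnegative finite values, at least one cell per time point, and valid TF
#' indices.
#'
#' @param matrices list of T nonnegative c_t x g matrices (cells x genes).
#' @param gene_names character vector of g unique gene names.
#' @param time_labels T ordered time labels.
#' @param cell_types list of T character vectors (length c_t each).
#' @param tf_indices integer indices into `gene_names` marking TF genes (may
#'   be empty until an edge database defines the TF universe).
#' @return an object of class `"expression_series"`.
#' @export
expression_series <- function(matrices, gene_names, time_labels, cell_types,
                              tf_indices = integer(0)) {
  T_ <- length(matrices)
  if (T_ < 1L) stop("need at least one time point")
  if (length(time_labels) != T_) stop("one time label per matrix required")
  if (length(cell_types) != T_) stop("one cell-type vector per matrix required")
  g <- length(gene_names)
  if (anyDuplicated(gene_names)) stop("gene names must be unique")
  for (t in seq_len(T_)) {
    m <- matrices[[t]]
    if (!is.matrix(m)) {
      m <- as.matrix(m)
      matrices[[t]] <- m
    }
    if (ncol(m) != g) {
      stop(sprintf("time point %s: matrix has %d columns but %d gene names",
                   time_labels[t], ncol(m), g))
    }
    if (nrow(m) < 1L) stop(sprintf("time point %s has no cells", time_labels[t]))
    if (length(cell_types[[t]]) != nrow(m)) {
      stop(sprintf("time point %s: %d cells but %d cell-type labels",
                   time_labels[t], nrow(m), length(cell_types[[t]])))
    }
    if (!all(is.finite(m))) stop("expression values must be finite")
    if (any(m < 0)) stop("expression values must be nonnegative")
  }
  tf_indices <- as.integer(tf_indices)
  if (length(tf_indices)) {
    if (anyDuplicated(tf_indices)) stop("tf_indices must be distinct")
    if (any(tf_indices < 1L | tf_indices > g)) stop("tf_indices out of range")
    if (length(tf_indices) >= g) stop("need at least one non-TF gene")
  }
  structure(list(
    matrices = matrices,
    gene_names = as.character(gene_names),
    tf_indices = tf_indices,
    time_labels = time_labels,
    cell_types = lapply(cell_types, as.character),
    cell_type_levels = sort(unique(unlist(lapply(cell_types, as.character))))
  ), class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("expression series: %d time points, %d genes (%d TFs), %d cell types\n",
              length(x$matrices), length(x$gene_names), length(x$tf_indices),
              length(x$cell_type_levels)))
  for (t in seq_along(x$matrices)) {
    cat(sprintf("  t=%s: %d cells\n", x$time_labels[t], nrow(x$matrices[[t]])))
  }
  invisible(x)
}

#' @export
dim.expression_series <- function(x) {
  c(sum(vapply(x$matrices, nrow, integer(1))), length(x$gene_names))
}

read_expr_matrix <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    as.matrix(Matrix::readMM(path))
  } else {
    m <- as.matrix(read.delim(path, header = FALSE))
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  }
}

#' Load a time-series expression dataset from files
#'
#' Accepts either one matrix file per time point (MatrixMarket `.mtx` or
#' delimited text, cells x genes), or a single combined matrix that is split
#' by the metadata's time column. The metadata table must contain `cell_id`,
#' `time`, and `cell_type` columns; within each time point, metadata row
#' order matches matrix row order. Time points are ordered by first
#' appearance in the metadata.
#'
#' @param matrix_paths character vector of matrix file paths (length T or 1).
#' @param metadata_path path to the metadata TSV.
#' @param genes_path path to the gene list (one name per line).
#' @param tf_path optional path to a TF name list; matching genes become the
#'   TF index set.
#' @return an [expression_series()].
#' @export
load_expression <- function(matrix_paths, metadata_path, genes_path,
                            tf_path = NULL) {
  meta <- read.delim(metadata_path, header = TRUE, colClasses = "character")
  need <- c("cell_id", "time", "cell_type")
  if (!all(need %in% names(meta))) {
    stop("metadata must contain columns cell_id, time, cell_type")
  }
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  times <- unique(meta$time)
  per_time <- split(seq_len(nrow(meta)), factor(meta$time, levels = times))
  if (length(matrix_paths) == 1L && length(times) > 1L) {
    big <- read_expr_matrix(matrix_paths)
    if (ncol(big) != length(genes)) {
      stop(sprintf("%s: expected %d gene columns, found %d",
                   matrix_paths, length(genes), ncol(big)))
    }
    if (nrow(big) != nrow(meta)) {
      stop(sprintf("%s: %d rows but metadata lists %d cells",
                   matrix_paths, nrow(big), nrow(meta)))
    }
    mats <- unname(lapply(per_time, function(ii) big[ii, , drop = FALSE]))
  } else {
    if (length(matrix_paths) != length(times)) {
      stop(sprintf("found %d time labels in metadata but %d matrix files",
                   length(times), length(matrix_paths)))
    }
    mats <- vector("list", length(times))
    for (t in seq_along(times)) {
      m <- read_expr_matrix(matrix_paths[t])
      if (ncol(m) != length(genes)) {
        stop(sprintf("%s: expected %d gene columns, found %d",
                     matrix_paths[t], length(genes), ncol(m)))
      }
      if (nrow(m) != length(per_time[[t]])) {
        stop(sprintf("%s: expected %d cells at time %s, found %d",
                     matrix_paths[t], length(per_time[[t]]), times[t], nrow(m)))
      }
      mats[[t]] <- m
    }
  }
  ctypes <- unname(lapply(per_time, function(ii) meta$cell_type[ii]))
  tf_idx <- integer(0)
  if (!is.null(tf_path)) {
    tfs <- readLines(tf_path)
    tf_idx <- which(genes %in% tfs[nzchar(tfs)])
  }
  expression_series(mats, genes, times, ctypes, tf_idx)
}

#' Write an expression series to a directory
#'
#' Emits one sparse MatrixMarket matrix per time point (`X_<t>.mtx`), a
#' metadata TSV, a gene list, and a TF list; [load_expression()] on these
#' files reproduces the series.
#'
#' @param series an [expression_series()].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory path.
#' @export
write_expression_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  T_ <- length(series$matrices)
  meta <- NULL
  paths <- character(T_)
  for (t in seq_len(T_)) {
    m <- series$matrices[[t]]
    paths[t] <- file.path(dir, sprintf("X_%02d.mtx", t))
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), paths[t])
    meta <- rbind(meta, data.frame(
      cell_id = sprintf("cell_t%02d_%04d", t, seq_len(nrow(m))),
      time = as.character(series$time_labels[t]),
      cell_type = series$cell_types[[t]],
      stringsAsFactors = FALSE
    ))
  }
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(series$gene_names, file.path(dir, "genes.txt"))
  writeLines(series$gene_names[series$tf_indices], file.path(dir, "tfs.txt"))
  invisible(dir)
}

#' Load a TF-target edge database (TRRUST dialect)
#'
#' Tab-separated rows `TF<TAB>target[<TAB>mode]`. Duplicate (TF, target)
#' pairs are collapsed; malformed rows are skipped with one warning giving
#' the count; self-loops are kept but flagged.
#'
#' @param path file path.
#' @param tf_column,target_column,mode_column column positions.
#' @param header `"auto"` (skip a first row that looks like column names),
#'   `TRUE`, or `FALSE`.
#' @return an object of class `"edge_db"`: data frame with columns `tf`,
#'   `target`, `mode`, `self_loop`.
#' @export
load_edge_database <- function(path, tf_column = 1L, target_column = 2L,
                               mode_column = 3L, header = "auto") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("edge database %s is empty", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(header, "auto")) {
    f1 <- tolower(trimws(fields[[1L]]))
    header <- length(f1) >= tf_column &&
      f1[tf_column] %in% c("tf", "source", "regulator")
  }
  if (isTRUE(header)) fields <- fields[-1L]
  if (!length(fields)) stop(sprintf("edge database %s has no data rows", path))
  need <- max(tf_column, target_column)
  ok <- vapply(fields, function(f) {
    length(f) >= need && nzchar(trimws(f[tf_column])) &&
      nzchar(trimws(f[target_column]))
  }, logical(1))
  if (any(!ok)) {
    warning(sprintf("skipped %d malformed row(s) in %s", sum(!ok), path))
    fields <- fields[ok]
  }
  if (!length(fields)) stop(sprintf("edge database %s has no valid rows", path))
  tf <- vapply(fields, function(f) trimws(f[tf_column]), character(1))
  target <- vapply(fields, function(f) trimws(f[target_column]), character(1))
  mode <- vapply(fields, function(f) {
    if (!is.null(mode_column) && length(f) >= mode_column)
      trimws(f[mode_column]) else NA_character_
  }, character(1))
  keep <- !duplicated(paste0(tf, "\r", target))
  db <- data.frame(tf = tf[keep], target = target[keep], mode = mode[keep],
                   stringsAsFactors = FALSE)
  db$self_loop <- db$tf == db$target
  if (any(db$self_loop)) {
    warning(sprintf("%d self-loop edge(s) present in %s", sum(db$self_loop), path))
  }
  class(db) <- c("edge_db", "data.frame")
  db
}

#' @export
print.edge_db <- function(x, ...) {
  cat(sprintf("edge database: %d edges, %d TFs, %d targets\n",
              nrow(x), length(unique(x$tf)), length(unique(x$target))))
  invisible(x)
}

#' Load reference gene sets
#'
#' TSV with one `set_name<TAB>gene` pair per line.
#'
#' @param path file path.
#' @return named list of character vectors (genes per set).
#' @export
load_gene_sets <- function(path) {
  d <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(d) < 2L) stop("gene set file needs two tab-separated columns")
  split(d[[2L]], d[[1L]])
}

#' Restrict an expression series to genes covered by an edge database
#'
#' Keeps genes appearing in the database as TF or target (order preserved)
#' and recomputes the TF index set as the genes appearing as a TF. This
#' defines the candidate TF universe used for the adjacency columns.
#'
#' @param series an [expression_series()].
#' @param db an [load_edge_database()] result.
#' @return the restricted [expression_series()].
#' @export
restrict_to_database_genes <- function(series, db) {
  covered <- series$gene_names %in% c(db$tf, db$target)
  if (!any(covered)) stop("no expression genes appear in the edge database")
  keep <- which(covered)
  genes <- series$gene_names[keep]
  tf_idx <- which(genes %in% unique(db$tf))
  if (!length(tf_idx)) stop("no database TF is present in the expression data")
  if (length(tf_idx) == length(genes)) stop("no non-TF target genes survive restriction")
  mats <- lapply(series$matrices, function(m) m[, keep, drop = FALSE])
  expression_series(mats, genes, series$time_labels, series$cell_types, tf_idx)
}

#' Normalize and transform raw counts
#'
#' Per time point: drops all-zero cells (with a warning), scales every cell's
#' counts to the median library size of that time point, then applies
#' `log1p`. An optional minimum-total-count gene filter runs first.
#'
#' @param series an [expression_series()] of raw counts.
#' @param min_counts drop genes whose total count across all time points is
#'   below this value (0 disables).
#' @return the preprocessed [expression_series()].
#' @export
preprocess <- function(series, min_counts = 0) {
  mats <- series$matrices
  genes <- series$gene_names
  tf_idx <- series$tf_indices
  if (min_counts > 0) {
    tot <- Reduce(`+`, lapply(mats, colSums))
    keep <- which(tot >= min_counts)
    if (!length(keep)) stop("min_counts filter removed every gene")
    mats <- lapply(mats, function(m) m[, keep, drop = FALSE])
    tf_idx <- match(intersect(tf_idx, keep), keep)
    genes <- genes[keep]
  }
  ctypes <- series$cell_types
  for (t in seq_along(mats)) {
    lib <- rowSums(mats[[t]])
    zero <- lib == 0
    if (any(zero)) {
      warning(sprintf("dropped %d all-zero cell(s) at time %s",
                      sum(zero), series$time_labels[t]))
      mats[[t]] <- mats[[t]][!zero, , drop = FALSE]
      ctypes[[t]] <- ctypes[[t]][!zero]
      lib <- lib[!zero]
    }
    target <- stats::median(lib)
    mats[[t]] <- log1p(mats[[t]] * (target / lib))
  }
  expression_series(mats, genes, series$time_labels, ctypes, tf_idx)
}

#' Sample a single-cell-type temporal batch
#'
#' Independently samples `b` cells of one cell type at every time point
#' (cells are never paired across time points). When fewer than `b` cells
#' are available at a time point, sampling is with replacement (a warning is
#' issued) so tensor shapes stay fixed.
#'
#' @param series an [expression_series()] with a nonempty TF index set.
#' @param cell_type the cell type to sample.
#' @param b cells per time point.
#' @param indices optional list (per time point) of admissible cell indices,
#'   e.g. a support or query split.
#' @return a `"temporal_batch"`: list with `x` (T matrices b x g), `tf_view`
#'   (T matrices b x p), `tf` (TF indices), `cell_type`, and `y` (the label's
#'   index among the series' cell-type levels).
#' @export
sample_temporal_batch <- function(series, cell_type, b, indices = NULL) {
  if (!length(series$tf_indices)) stop("series has no TF index set")
  T_ <- length(series$matrices)
  x <- vector("list", T_)
  for (t in seq_len(T_)) {
    pool <- which(series$cell_types[[t]] == cell_type)
    if (!is.null(indices)) pool <- intersect(pool, indices[[t]])
    if (!length(pool)) {
      stop(sprintf("cell type '%s' absent at time point %s",
                   cell_type, series$time_labels[t]))
    }
    if (length(pool) < b) {
      warning(sprintf(
        "cell type '%s' has %d < %d cells at time %s; sampling with replacement",
        cell_type, length(pool), b, series$time_labels[t]))
      take <- sample(pool, b, replace = TRUE)
    } else {
      take <- sample(pool, b, replace = FALSE)
    }
    x[[t]] <- series$matrices[[t]][take, , drop = FALSE]
  }
  structure(list(
    x = x,
    tf_view = lapply(x, function(m) m[, series$tf_indices, drop = FALSE]),
    tf = series$tf_indices,
    cell_type = cell_type,
    y = match(cell_type, series$cell_type_levels)
  ), class = "temporal_batch")
}

#' Partition cells into MAML support and query splits
#'
#' Per cell type and time point, cells are split into disjoint support and
#' query sets by `support_fraction` (the support set takes the ceiling, so
#' ties favour support). Cell types with fewer than 2 cells at any time point
#' are excluded from training with a warning.
#'
#' @param series an [expression_series()].
#' @param support_fraction fraction of cells assigned to support, in (0, 1).
#' @return a `"task_split"`: named list per trained cell type with `support`
#'   and `query`, each a list of per-time-point cell index vectors.
#' @export
make_task_splits <- function(series, support_fraction = 0.5) {
  stopifnot(support_fraction > 0, support_fraction < 1)
  T_ <- length(series$matrices)
  out <- list()
  for (ct in series$cell_type_levels) {
    counts <- vapply(seq_len(T_), function(t) {
      sum(series$cell_types[[t]] == ct)
    }, integer(1))
    if (any(counts < 2L)) {
      warning(sprintf(
        "cell type '%s' has fewer than 2 cells at some time point; excluded from training",
        ct))
      next
    }
    sup <- qry <- vector("list", T_)
    for (t in seq_len(T_)) {
      pool <- which(series$cell_types[[t]] == ct)
      perm <- sample(pool)
      n_s <- ceiling(support_fraction * length(pool))
      if (n_s >= length(pool)) n_s <- length(pool) - 1L
      sup[[t]] <- sort(perm[seq_len(n_s)])
      qry[[t]] <- sort(perm[-seq_len(n_s)])
    }
    out[[ct]] <- list(support = sup, query = qry)
  }
  if (!length(out)) stop("no cell type has enough cells to train on")
  structure(out, class = "task_split")
}
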