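# Over-classed LDA, mechanism-class LDA, and PCA ----------------------------

#' Within- and between-class scatter of a cell table
#'
#' In `compound_by_concentration` mode every (compound, concentration) pair
#' is its own class and all control cells form one class; with many compounds
#' this "over-classed" design yields a ranking of discriminative directions
#' rather than a fixed low-dimensional discriminant. Variation across
#' concentrations of one compound is then between-class, not within-class
#' variation. In `mechanism_class` mode all cells treated with any dose of
#' any compound of one mechanism class form a class, and cells of unmapped
#' compounds plus controls form a null class.
#'
#' With the default pooled weighting, `within` is the cell-count-weighted
#' pooled covariance of cells about their class means and `between` the
#' cell-count-weighted covariance of class means about the grand mean (both
#' with denominator N), so `within + between` equals the total covariance of
#' all cells. `unweighted` averages per-class covariances and class means
#' without count weights.
#'
#' @param table control-normalized cell table.
#' @param class_definition `"compound_by_concentration"` or
#'   `"mechanism_class"`.
#' @param class_labels named character vector compound -> mechanism class
#'   (required for `mechanism_class` mode; unmapped or `"Unspecified"`
#'   compounds join the null class).
#' @param weighting `"pooled"` (default) or `"unweighted"`.
#' @return an object of class `"scatter_decomposition"` with elements
#'   `within`, `between`, `n_classes`, `n_cells`, `class_definition`,
#'   `weighting`, `feature_names`.
#' @export
compute_scatter <- function(table,
                            class_definition = c("compound_by_concentration",
                                                 "mechanism_class"),
                            class_labels = NULL,
                            weighting = c("pooled", "unweighted")) {
  class_definition <- match.arg(class_definition)
  weighting <- match.arg(weighting)
  feats <- cell_features(table)
  X <- cell_feature_matrix(table, feats)
  cls <- if (class_definition == "compound_by_concentration") {
    ifelse(table$role == "control", "CONTROL",
           paste(table$compound_id, table$concentration_level, sep = "@"))
  } else {
    if (is.null(class_labels))
      stop("compute_scatter: `class_labels` required for mechanism_class ",
           "mode", call. = FALSE)
    lab <- class_labels[table$compound_id]
    lab[is.na(lab) | lab == "Unspecified" | table$role == "control"] <-
      "NULL_CLASS"
    lab
  }
  cls <- factor(cls)
  counts <- as.vector(table(cls))
  if (nlevels(cls) < 2L)
    stop("compute_scatter: need at least 2 classes", call. = FALSE)
  small <- counts < 2L
  if (any(small))
    warning("compute_scatter: ", sum(small), " class(es) with < 2 cells ",
            "excluded from the within-class scatter")
  means <- rowsum(X, cls) / counts  # levels(cls) order

  d <- ncol(X)
  if (weighting == "pooled") {
    keep <- !small[as.integer(cls)]
    Xc <- X - means[as.integer(cls), , drop = FALSE]
    W <- crossprod(Xc[keep, , drop = FALSE]) / sum(counts[!small])
    grand <- colSums(X) / nrow(X)
    Mc <- sweep(means, 2L, grand) * sqrt(counts)
    B <- crossprod(Mc) / nrow(X)
  } else {
    W <- matrix(0, d, d)
    for (k in which(!small)) {
      W <- W + cov(X[as.integer(cls) == k, , drop = FALSE])
    }
    W <- W / sum(!small)
    B <- cov(means)
  }
  W <- (W + t(W)) / 2
  B <- (B + t(B)) / 2
  dimnames(W) <- dimnames(B) <- list(feats, feats)
  structure(list(within = W, between = B, n_classes = nlevels(cls),
                 n_cells = nrow(X), class_definition = class_definition,
                 weighting = weighting, feature_names = feats),
            class = "scatter_decomposition")
}

#' @export
print.scatter_decomposition <- function(x, ...) {
  cat("Scatter decomposition (", x$class_definition, ", ", x$weighting,
      "): ", x$n_classes, " classes, ", x$n_cells, " cells, ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

new_projection_basis <- function(loadings, eigenvalues, method,
                                 feature_names) {
  colnames(loadings) <- sprintf("%s%d",
                                if (method == "pca") "PC" else "LD",
                                seq_len(ncol(loadings)))
  rownames(loadings) <- feature_names
  structure(list(loadings = loadings, eigenvalues = eigenvalues,
                 method = method, feature_names = feature_names),
            class = "projection_basis")
}

#' @export
print.projection_basis <- function(x, ...) {
  cat("Projection basis (", x$method, "): ", length(x$feature_names),
      " features -> ", ncol(x$loadings), " dimensions\n", sep = "")
  cat("eigenvalues:", signif(head(x$eigenvalues, 8), 4),
      if (length(x$eigenvalues) > 8) "...\n" else "\n")
  invisible(x)
}

# deterministic orientation: largest-magnitude loading positive
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Fit a multi-class LDA basis from a scatter decomposition
#'
#' Solves the symmetric generalized eigenproblem
#' `between v = lambda (within + ridge I) v` and returns the top-`m`
#' eigenvectors (Euclidean unit norm, largest-magnitude loading positive) in
#' decreasing eigenvalue order. The `m` leading eigenvectors of the
#' within-inverse-between operator span the most discriminative
#' `m`-dimensional subspace.
#'
#' @param scatter a [compute_scatter()] result.
#' @param m number of dimensions to retain (default 16, the
#'   bias-variance sweet spot for mechanism classification in this pipeline).
#' @param ridge nonnegative ridge added to the within-class scatter before
#'   inversion; default `1e-6 * trace(within) / d`. Over-classed designs can
#'   leave the within-class scatter ill-conditioned.
#' @return a `"projection_basis"` with method `"lda_overclassed"` or
#'   `"lda_mechanism"`.
#' @export
fit_lda <- function(scatter, m = 16, ridge = NULL) {
  stopifnot(inherits(scatter, "scatter_decomposition"))
  d <- length(scatter$feature_names)
  if (m > d)
    stop("fit_lda: `m` must not exceed the number of features", call. = FALSE)
  W <- scatter$within
  B <- scatter$between
  ridge <- ridge %||% (1e-6 * sum(diag(W)) / d)
  if (ridge < 0) stop("fit_lda: `ridge` must be >= 0", call. = FALSE)
  Wr <- W + diag(ridge, d)
  R <- tryCatch(chol(Wr), error = function(e)
    stop("fit_lda: within-class scatter is singular; increase `ridge`",
         call. = FALSE))
  # whiten: eigenvectors of R^-T B R^-1, mapped back through R
  Bt <- backsolve(R, t(backsolve(R, t(B), transpose = TRUE)),
                  transpose = TRUE)
  Bt <- (Bt + t(Bt)) / 2
  eig <- eigen(Bt, symmetric = TRUE)
  if (any(eig$values < -1e-8 * max(abs(eig$values), 1)))
    warning("fit_lda: between-class scatter not PSD within tolerance")
  V <- backsolve(R, eig$vectors[, seq_len(m), drop = FALSE])
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  V <- fix_signs(V)
  method <- if (scatter$class_definition == "mechanism_class")
    "lda_mechanism" else "lda_overclassed"
  new_projection_basis(V, pmax(eig$values[seq_len(m)], 0), method,
                       scatter$feature_names)
}

#' Fit a PCA basis
#'
#' All features are scaled to unit variance before decomposition. The
#' returned loadings fold that scaling in, so projection is a plain linear
#' map of the (control-normalized) feature matrix: no additional centering is
#' applied at projection time, which keeps mean-zero control populations
#' mean-zero in the projected space.
#'
#' @param table control-normalized cell table.
#' @param m number of principal dimensions to retain.
#' @return a `"projection_basis"` with method `"pca"`; `eigenvalues` are the
#'   component variances of the unit-variance-scaled data.
#' @export
fit_pca <- function(table, m = 16) {
  feats <- cell_features(table)
  X <- cell_feature_matrix(table, feats)
  if (m > ncol(X))
    stop("fit_pca: `m` must not exceed the number of features", call. = FALSE)
  sds <- apply(X, 2L, sd)
  zero <- feats[sds == 0 | !is.finite(sds)]
  if (length(zero))
    stop("fit_pca: zero-variance feature(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  Xs <- X * rep(1 / sds, each = nrow(X))
  eig <- eigen(cov(Xs), symmetric = TRUE)
  V <- fix_signs(eig$vectors[, seq_len(m), drop = FALSE])
  loadings <- V / sds  # rows = features: scaling folded into the map
  new_projection_basis(loadings, eig$values[seq_len(m)], "pca", feats)
}

#' Project cells into a reduced phenotypic space
#'
#' Replaces the measurement columns by their coordinates in the basis
#' (metadata columns are preserved). Purely linear: mean-zero populations
#' stay mean-zero.
#'
#' @param table cell table whose features match `basis$feature_names`.
#' @param basis a `"projection_basis"` from [fit_lda()] or [fit_pca()].
#' @return cell table with projected feature columns (`LD1..` / `PC1..`).
#' @export
project_cells <- function(table, basis) {
  stopifnot(inherits(basis, "projection_basis"))
  missing <- setdiff(basis$feature_names, names(table))
  if (length(missing))
    stop("project_cells: table lacks feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  P <- cell_feature_matrix(table, basis$feature_names) %*% basis$loadings
  out <- cbind(table[, intersect(.meta_cols, names(table)), drop = FALSE],
               as.data.frame(P))
  rownames(out) <- NULL
  out
}

#' Serialize / deserialize a projection basis
#'
#' The loadings go to CSV (rows = features, columns = dimensions) with a JSON
#' sidecar holding eigenvalues and method.
#'
#' @param basis a `"projection_basis"`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `path` (write) or the basis (read).
#' @export
write_basis <- function(basis, path) {
  write.csv(data.frame(feature = basis$feature_names, basis$loadings,
                       check.names = FALSE),
            path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(method = basis$method,
                            eigenvalues = basis$eigenvalues),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  loadings <- as.matrix(tab[, -1, drop = FALSE])
  new_projection_basis(loadings, side$eigenvalues, side$method,
                       tab$feature)
}
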