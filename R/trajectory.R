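# Gaussian phenotype distributions and dose-ordered trajectories ------------

#' Construct a phenotype distribution
#'
#' A Gaussian summary of one cell population in projected phenotypic space:
#' mean vector, covariance matrix and cell count.
#'
#' @param mean numeric mean vector.
#' @param cov symmetric positive semidefinite covariance matrix.
#' @param n number of cells summarized (>= 0).
#' @param level dose level index (`NA` for controls).
#' @param degenerate flag for distributions estimated from too few cells;
#'   degenerate distributions take weighted overlap 0 but keep their cell
#'   count in denominators.
#' @return an object of class `"pheno_dist"`.
#' @export
pheno_dist <- function(mean, cov, n, level = NA_integer_,
                       degenerate = FALSE) {
  mean <- unname(as.numeric(mean))
  cov <- unname(as.matrix(cov))
  if (nrow(cov) != length(mean) || ncol(cov) != length(mean))
    stop("pheno_dist: covariance dimensions must match the mean",
         call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-8 * max(abs(cov), 1))
    stop("pheno_dist: covariance must be symmetric", call. = FALSE)
  if (n < 0) stop("pheno_dist: `n` must be >= 0", call. = FALSE)
  structure(list(mean = mean, cov = (cov + t(cov)) / 2, n = as.integer(n),
                 level = as.integer(level), degenerate = isTRUE(degenerate)),
            class = "pheno_dist")
}

#' @export
print.pheno_dist <- function(x, ...) {
  cat("Phenotype distribution: dim ", length(x$mean), ", n = ", x$n,
      if (!is.na(x$level)) paste0(", level ", x$level),
      if (x$degenerate) ", degenerate", "\n", sep = "")
  invisible(x)
}

# moment estimate with diagonal shrinkage and an identity floor; extra
# shrinkage toward scaled identity when the count cannot support a full
# covariance estimate
estimate_dist <- function(X, n, level, min_cells, shrinkage) {
  m <- ncol(X)
  if (n == 0L) {
    return(pheno_dist(rep(0, m), diag(1e-8, m), 0L, level,
                      degenerate = TRUE))
  }
  mu <- colMeans(X)
  S <- if (n >= 2L) cov(X) else matrix(0, m, m)
  S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), m)
  if (n < m + 2L) {
    scale <- mean(diag(S))
    if (scale <= 0) scale <- 1
    S <- 0.5 * S + 0.5 * diag(scale, m)
  }
  eps <- 1e-8 * max(mean(diag(S)), 1e-8)
  S <- S + diag(eps, m)
  pheno_dist(mu, S, n, level, degenerate = n < min_cells)
}

#' Build phenotypic trajectories from projected cells
#'
#' Pools cells across replicate plates per (compound, concentration level),
#' estimates a Gaussian phenotype distribution for each level, and assembles
#' the dose-ordered sequence per compound, together with one pooled control
#' distribution. Covariances are shrunk toward their diagonal by `shrinkage`
#' and floored to keep determinants usable; levels with fewer than
#' `min_cells` cells (including wiped-out zero-cell levels) are flagged
#' degenerate.
#'
#' @param projected projected cell table (from [project_cells()]).
#' @param min_cells minimum cells for a usable distribution; default
#'   `m + 2` where `m` is the projected dimension.
#' @param shrinkage diagonal shrinkage weight in `[0, 1]`.
#' @param levels dose levels each trajectory should cover; defaults to
#'   `1:max(observed level)`. Missing (zero-cell) levels are emitted with
#'   `n = 0`.
#' @return an object of class `"trajectory_set"`: list with `trajectories`
#'   (named list of `"pheno_trajectory"` objects) and `control` (the pooled
#'   control `"pheno_dist"`).
#' @export
build_trajectories <- function(projected, min_cells = NULL, shrinkage = 0.1,
                               levels = NULL) {
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  feats <- cell_features(projected)
  m <- length(feats)
  min_cells <- as.integer(min_cells %||% (m + 2L))
  X <- cell_feature_matrix(projected, feats)
  ctrl <- projected$role == "control"
  if (sum(ctrl) < min_cells)
    stop("build_trajectories: fewer than `min_cells` control cells",
         call. = FALSE)
  control <- estimate_dist(X[ctrl, , drop = FALSE], sum(ctrl), NA_integer_,
                           min_cells, shrinkage)

  treated <- which(!ctrl)
  compounds <- sort(unique(projected$compound_id[treated]))
  levels <- levels %||%
    seq_len(max(projected$concentration_level[treated], 1L))
  trajectories <- list()
  for (cmpd in compounds) {
    rows <- treated[projected$compound_id[treated] == cmpd]
    lev_of <- projected$concentration_level[rows]
    dists <- vector("list", length(levels))
    usable <- 0L
    for (i in seq_along(levels)) {
      sel <- rows[lev_of == levels[i]]
      dists[[i]] <- estimate_dist(X[sel, , drop = FALSE], length(sel),
                                  levels[i], min_cells, shrinkage)
      if (!dists[[i]]$degenerate) usable <- usable + 1L
    }
    if (usable == 0L) {
      warning("build_trajectories: compound ", cmpd,
              " has no usable levels; excluded")
      next
    }
    trajectories[[cmpd]] <- structure(
      list(compound_id = cmpd, distributions = dists, control = control),
      class = "pheno_trajectory")
  }
  structure(list(trajectories = trajectories, control = control),
            class = "trajectory_set")
}

#' @export
print.pheno_trajectory <- function(x, ...) {
  cat("Phenotypic trajectory for ", x$compound_id, ": ",
      length(x$distributions), " levels, dim ",
      length(x$distributions[[1]]$mean), "\n", sep = "")
  invisible(x)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Trajectory set: ", length(x$trajectories), " compounds, control n = ",
      x$control$n, "\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize trajectories as JSON
#'
#' @param ts a `"trajectory_set"`.
#' @param path JSON file path.
#' @return `path` (write) or a `"trajectory_set"` (read).
#' @export
write_trajectories <- function(ts, path) {
  enc_dist <- function(d) list(mean = d$mean, cov = d$cov, n = d$n,
                               level = d$level, degenerate = d$degenerate)
  payload <- list(
    control = enc_dist(ts$control),
    trajectories = lapply(ts$trajectories, function(t)
      list(compound_id = t$compound_id,
           distributions = lapply(t$distributions, enc_dist))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE)
  dec_dist <- function(d) pheno_dist(d$mean, d$cov, d$n,
                                     d$level %||% NA_integer_,
                                     isTRUE(d$degenerate))
  control <- dec_dist(payload$control)
  trajectories <- lapply(payload$trajectories, function(t) {
    structure(list(compound_id = t$compound_id,
                   distributions = lapply(t$distributions, dec_dist),
                   control = control),
              class = "pheno_trajectory")
  })
  names(trajectories) <- vapply(trajectories, `[[`, "", "compound_id")
  structure(list(trajectories = trajectories, control = control),
            class = "trajectory_set")
}
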