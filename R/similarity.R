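# Distribution overlap, MSWO trajectory similarity, phenotypic activity -----

# log-determinant of a PSD matrix via Cholesky
logdet <- function(S) {
  2 * sum(log(diag(chol(S))))
}

#' Overlap between two Gaussian phenotype distributions
#'
#' \deqn{O(D_1, D_2) = \frac{|4\Sigma_1\Sigma_2|^{1/2}}{|\Sigma_1+\Sigma_2|}
#'   \exp\left(-\tfrac12 (\mu_1-\mu_2)^T (\Sigma_1+\Sigma_2)^{-1}
#'   (\mu_1-\mu_2)\right)}
#'
#' Equal to 1 for identical distributions; drops as means separate or
#' covariances diverge. Computed via log-determinants (Cholesky) and clamped
#' to `[0, 1]` to absorb rounding.
#'
#' @param d1,d2 `"pheno_dist"` objects of equal dimension with nonsingular
#'   covariance.
#' @return overlap in `[0, 1]`.
#' @export
overlap <- function(d1, d2) {
  if (length(d1$mean) != length(d2$mean))
    stop("overlap: dimension mismatch", call. = FALSE)
  m <- length(d1$mean)
  Ssum <- d1$cov + d2$cov
  R <- tryCatch(chol(Ssum), error = function(e)
    stop("overlap: singular covariance sum", call. = FALSE))
  ld1 <- tryCatch(logdet(d1$cov), error = function(e)
    stop("overlap: singular covariance", call. = FALSE))
  ld2 <- tryCatch(logdet(d2$cov), error = function(e)
    stop("overlap: singular covariance", call. = FALSE))
  delta <- d1$mean - d2$mean
  quad <- sum(backsolve(R, delta, transpose = TRUE)^2)
  lo <- m * log(2) + 0.5 * (ld1 + ld2) - 2 * sum(log(diag(R))) - 0.5 * quad
  min(max(exp(lo), 0), 1)
}

#' Control-weighted overlap
#'
#' \deqn{O_W(D_1, D_2) = O(D_1, D_2)\,(1 - O(D_1, D_0))\,(1 - O(D_2, D_0))}
#'
#' Similarity between two phenotypes counts only insofar as both phenotypes
#' differ from the untreated-control distribution `d0`.
#'
#' @param d1,d2 `"pheno_dist"` objects.
#' @param d0 control `"pheno_dist"`.
#' @return weighted overlap in `[0, 1]`; symmetric in `(d1, d2)`.
#' @export
weighted_overlap <- function(d1, d2, d0) {
  overlap(d1, d2) * (1 - overlap(d1, d0)) * (1 - overlap(d2, d0))
}

# per-trajectory cached quantities: counts, degeneracy flags, and (1 - O(D,
# D0)) control-dissimilarity weights
trajectory_terms <- function(t) {
  n <- vapply(t$distributions, `[[`, 0L, "n")
  deg <- vapply(t$distributions, `[[`, NA, "degenerate")
  w0 <- numeric(length(n))
  for (k in seq_along(n)) {
    w0[k] <- if (deg[k]) 0 else 1 - overlap(t$distributions[[k]], t$control)
  }
  list(n = n, deg = deg, w0 = w0)
}

# pairwise (weighted) overlap matrix between the levels of two trajectories;
# degenerate levels take 0
overlap_matrix <- function(ti, tj, weighted = TRUE,
                           terms_i = trajectory_terms(ti),
                           terms_j = trajectory_terms(tj)) {
  Li <- length(ti$distributions)
  Lj <- length(tj$distributions)
  W <- matrix(0, Li, Lj)
  for (k in seq_len(Li)) {
    if (terms_i$deg[k]) next
    for (l in seq_len(Lj)) {
      if (terms_j$deg[l]) next
      o <- overlap(ti$distributions[[k]], tj$distributions[[l]])
      W[k, l] <- if (weighted) o * terms_i$w0[k] * terms_j$w0[l] else o
    }
  }
  W
}

#' MSWO dynamic program on a precomputed overlap matrix
#'
#' Maximizes, over pairs of equal-length strictly increasing index
#' subsequences of the two trajectories, the sum of cell-count-weighted
#' overlap terms `(n_i[k] + n_j[l]) * W[k, l]`, normalized by
#' `sum(n_i) + sum(n_j)`. The recursion
#' `SO(k, l) = (n_i[k] + n_j[l]) W[k, l] + max_{k' < k, l' < l} SO(k', l')`
#' is evaluated in `O(L^2)` with running prefix maxima.
#'
#' @param W matrix of (weighted) overlaps between levels of the two
#'   trajectories.
#' @param ni,nj cell counts per level of each trajectory.
#' @return similarity in `[0, 1]`.
#' @export
mswo_dp <- function(W, ni, nj) {
  Li <- length(ni)
  Lj <- length(nj)
  stopifnot(nrow(W) == Li, ncol(W) == Lj)
  denom <- sum(ni) + sum(nj)
  if (denom <= 0) {
    warning("mswo: empty trajectories (no cells)")
    return(0)
  }
  M <- matrix(-Inf, Li, Lj)  # prefix maxima of SO over indices <= (k, l)
  best <- 0
  for (k in seq_len(Li)) {
    for (l in seq_len(Lj)) {
      so <- (ni[k] + nj[l]) * W[k, l]
      if (k > 1L && l > 1L && M[k - 1L, l - 1L] > 0) {
        so <- so + M[k - 1L, l - 1L]
      }
      if (so > best) best <- so
      M[k, l] <- max(so,
                     if (k > 1L) M[k - 1L, l] else -Inf,
                     if (l > 1L) M[k, l - 1L] else -Inf)
    }
  }
  min(max(best / denom, 0), 1)
}

#' Maximum sequential weighted overlap between two trajectories
#'
#' The MSWO similarity: subsequences of equal length (not necessarily
#' consecutive, dose order preserved) are chosen from each trajectory so that
#' the summed cell-count-weighted, control-attenuated overlaps between
#' corresponding distributions are maximal; the score is normalized by the
#' total cell count of both trajectories. Order-preserving matching makes the
#' measure insensitive to potency shifts along the serial-dilution axis.
#'
#' @param ti,tj `"pheno_trajectory"` objects sharing dimension and control.
#' @param weighted use control-weighted overlap (default); `FALSE` uses the
#'   simple overlap, for ablation.
#' @param single_point match only the highest usable concentration of each
#'   trajectory, for ablation of the dose-response information.
#' @return similarity in `[0, 1]`; symmetric and 1 only for identical,
#'   strongly control-distinct trajectories.
#' @export
mswo <- function(ti, tj, weighted = TRUE, single_point = FALSE) {
  if (single_point) {
    ti <- top_level_trajectory(ti)
    tj <- top_level_trajectory(tj)
  }
  terms_i <- trajectory_terms(ti)
  terms_j <- trajectory_terms(tj)
  W <- overlap_matrix(ti, tj, weighted, terms_i, terms_j)
  mswo_dp(W, terms_i$n, terms_j$n)
}

# restrict a trajectory to its highest non-degenerate level
top_level_trajectory <- function(t) {
  deg <- vapply(t$distributions, `[[`, NA, "degenerate")
  keep <- which(!deg)
  if (!length(keep)) keep <- length(t$distributions)
  k <- max(keep)
  structure(list(compound_id = t$compound_id,
                 distributions = t$distributions[k], control = t$control),
            class = "pheno_trajectory")
}

#' Brute-force MSWO oracle
#'
#' Exhaustively enumerates all pairs of equal-length strictly increasing
#' index subsequences (factorial search, trajectories capped at 8 levels) and
#' maximizes the summed weighted overlap terms. Must agree with [mswo()] to
#' machine precision; exists as an independent check of the dynamic program.
#'
#' @inheritParams mswo
#' @return similarity in `[0, 1]`.
#' @export
mswo_bruteforce <- function(ti, tj, weighted = TRUE) {
  Li <- length(ti$distributions)
  Lj <- length(tj$distributions)
  if (Li > 8L || Lj > 8L)
    stop("mswo_bruteforce: trajectories longer than 8 levels", call. = FALSE)
  terms_i <- trajectory_terms(ti)
  terms_j <- trajectory_terms(tj)
  W <- overlap_matrix(ti, tj, weighted, terms_i, terms_j)
  mswo_bruteforce_matrix(W, terms_i$n, terms_j$n)
}

# enumeration core, shared with tests that drive synthetic overlap matrices
mswo_bruteforce_matrix <- function(W, ni, nj) {
  Li <- length(ni)
  Lj <- length(nj)
  denom <- sum(ni) + sum(nj)
  if (denom <= 0) return(0)
  best <- 0
  for (len in seq_len(min(Li, Lj))) {
    sub_i <- combn(Li, len)
    sub_j <- combn(Lj, len)
    for (a in seq_len(ncol(sub_i))) {
      ia <- sub_i[, a]
      for (b in seq_len(ncol(sub_j))) {
        jb <- sub_j[, b]
        s <- sum((ni[ia] + nj[jb]) * W[cbind(ia, jb)])
        if (s > best) best <- s
      }
    }
  }
  min(max(best / denom, 0), 1)
}

#' Phenotypic activity of a trajectory
#'
#' Cell-count-weighted average dissimilarity from the untreated-control
#' distribution across the dose series:
#' \deqn{A_P(C) = \frac{\sum_k N_k (1 - O(D_k, D_0))}{\sum_k N_k}}
#' High values mark compounds whose phenotype is distinctive at most doses.
#' Degenerate levels (too few surviving cells) take overlap 0, i.e. count as
#' maximally distinct from healthy controls.
#'
#' @param t a `"pheno_trajectory"`.
#' @return activity in `[0, 1]`.
#' @export
phenotypic_activity <- function(t) {
  terms <- trajectory_terms(t)
  if (sum(terms$n) == 0) {
    warning("phenotypic_activity: trajectory has no cells")
    return(0)
  }
  # w0 is already 1 - O(D_k, D0); degenerate levels take O = 0
  sum(terms$n * ifelse(terms$deg, 1, terms$w0)) / sum(terms$n)
}

#' Phenotypic activity table for a trajectory set
#'
#' @param ts a `"trajectory_set"`.
#' @return named numeric vector of activities per compound.
#' @export
activity_table <- function(ts) {
  vapply(ts$trajectories, phenotypic_activity, 0)
}

#' All-pairs MSWO similarity matrix
#'
#' @param ts a `"trajectory_set"`.
#' @inheritParams mswo
#' @return symmetric numeric matrix (compound x compound) of MSWO values in
#'   `[0, 1]`; the diagonal holds each compound's self-similarity.
#' @export
similarity_matrix <- function(ts, weighted = TRUE, single_point = FALSE) {
  trajs <- ts$trajectories
  if (length(trajs) < 2L)
    stop("similarity_matrix: need at least 2 trajectories", call. = FALSE)
  if (single_point) trajs <- lapply(trajs, top_level_trajectory)
  ids <- names(trajs)
  n <- length(trajs)
  terms <- lapply(trajs, trajectory_terms)
  S <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      W <- overlap_matrix(trajs[[i]], trajs[[j]], weighted,
                          terms[[i]], terms[[j]])
      S[i, j] <- S[j, i] <- mswo_dp(W, terms[[i]]$n, terms[[j]]$n)
    }
  }
  S
}

#' Write a similarity matrix or activity table as CSV
#'
#' @param x square similarity matrix or named activity vector.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(x, path) {
  if (is.matrix(x)) {
    write.csv(data.frame(compound_id = rownames(x), x, check.names = FALSE),
              path, row.names = FALSE, quote = FALSE)
  } else {
    write.csv(data.frame(compound_id = names(x), phenotypic_activity = x),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 2L && names(tab)[2] == "phenotypic_activity")
    return(setNames(tab[[2]], tab[[1]]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
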