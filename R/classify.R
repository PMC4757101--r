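# Exemplar-based classification with an "Unspecified" rejection threshold ---

as_named_vector <- function(x, value_col, id_col = "compound_id") {
  if (is.data.frame(x)) setNames(x[[value_col]], x[[id_col]]) else x
}

#' Select exemplar classes and compounds
#'
#' A mechanism class is usable for classification only if it contains at
#' least `min_members` compounds with phenotypic activity above
#' `pa_threshold`; those qualifying compounds become the class's exemplars.
#' This guarantees that leave-one-out scoring always compares against at
#' least `min_members - 1` phenotypically active exemplars.
#'
#' @param activities named numeric vector (or `data.frame` with columns
#'   `compound_id`, `phenotypic_activity`) of phenotypic activities.
#' @param class_map named character vector (or `data.frame` with columns
#'   `compound_id`, `true_class`/`class`) mapping every compound to a
#'   mechanism class or `"Unspecified"`.
#' @param pa_threshold phenotypic activity an exemplar must exceed.
#' @param min_members minimum qualifying compounds per surviving class.
#' @return an object of class `"exemplar_set"`: list with `classes` (named
#'   list of exemplar compound ids per class), `pa_threshold`, `min_members`.
#' @export
select_exemplars <- function(activities, class_map, pa_threshold = 0.4,
                             min_members = 4) {
  activities <- as_named_vector(activities, "phenotypic_activity")
  class_map <- as_class_map(class_map)
  missing <- setdiff(names(activities), names(class_map))
  if (length(missing))
    stop("select_exemplars: compounds missing from `class_map`: ",
         paste(missing, collapse = ", "), call. = FALSE)
  classes <- setdiff(unique(class_map[names(activities)]), "Unspecified")
  keep <- list()
  for (cls in sort(classes)) {
    members <- names(activities)[class_map[names(activities)] == cls]
    qualifying <- members[activities[members] > pa_threshold]
    if (length(qualifying) >= min_members) keep[[cls]] <- sort(qualifying)
  }
  if (!length(keep))
    stop("select_exemplars: configuration error, no class has ",
         min_members, " compounds with activity above ", pa_threshold,
         call. = FALSE)
  structure(list(classes = keep, pa_threshold = pa_threshold,
                 min_members = as.integer(min_members)),
            class = "exemplar_set")
}

as_class_map <- function(class_map) {
  if (is.data.frame(class_map)) {
    col <- intersect(c("true_class", "class", "mechanism_class"),
                     names(class_map))[1]
    setNames(class_map[[col]], class_map$compound_id)
  } else class_map
}

#' @export
print.exemplar_set <- function(x, ...) {
  cat("Exemplar set: ", length(x$classes), " classes (activity > ",
      x$pa_threshold, ", >= ", x$min_members, " members)\n", sep = "")
  for (cls in names(x$classes))
    cat("  ", cls, ": ", length(x$classes[[cls]]), " exemplars\n", sep = "")
  invisible(x)
}

#' Similarity of one compound to each exemplar class
#'
#' Per class, the arithmetic mean of the compound's MSWO similarity to that
#' class's exemplar compounds, optionally excluding the compound itself (the
#' leave-one-out contract for compounds that are themselves exemplars).
#'
#' @param compound compound id (must index `sim`).
#' @param exemplars an [select_exemplars()] result.
#' @param sim similarity matrix.
#' @param exclude_self drop the compound from its own class's exemplar list.
#' @return named numeric vector class -> mean similarity.
#' @export
class_similarity <- function(compound, exemplars, sim,
                             exclude_self = FALSE) {
  if (!compound %in% rownames(sim))
    stop("class_similarity: compound not in similarity matrix", call. = FALSE)
  out <- numeric(0)
  for (cls in names(exemplars$classes)) {
    ex <- exemplars$classes[[cls]]
    if (exclude_self) ex <- setdiff(ex, compound)
    if (!length(ex)) {
      warning("class_similarity: class ", cls,
              " empty after self-exclusion; skipped")
      next
    }
    out[cls] <- mean(sim[compound, ex])
  }
  out
}

#' Fit the MAP threshold separating classified from unclassified compounds
#'
#' Each compound's best exemplar-class similarity is normalized by its
#' phenotypic activity (division, floored at `floor` before the log). The
#' log-normalized scores of in-exemplar-class compounds and of all other
#' compounds are each summarized by a Gaussian; the threshold `m_t` is the
#' decision boundary below which a compound is more likely unclassified a
#' posteriori given prior `p_c` of being classified.
#'
#' Two fitting methods are available. `"printed"` uses the closed forms
#' \deqn{\log m_t = \frac{\sigma_c \mu_u + \sigma_u \mu_c}{\sigma_c +
#'   \sigma_u} \quad (p_c = 0.5)}
#' and, for general priors,
#' \deqn{\log m_t = \frac{\sigma_c^2\mu_u - \sigma_u^2\mu_c + \sigma_c
#'   \sigma_u \sqrt{(\mu_c-\mu_u)^2 + (\sigma_c^2-\sigma_u^2)
#'   \log\left(\frac{\sigma_c^2}{\sigma_u^2}
#'   \frac{p_c}{1-p_c}\right)}}{\sigma_c^2 - \sigma_u^2}.}
#' These omit part of the log-variance/prior term of the exact two-Gaussian
#' boundary (see the methods vignette); `"exact"` solves the full MAP
#' equality `p_c N(x; mu_c, s2_c) = (1 - p_c) N(x; mu_u, s2_u)`. When the two
#' variances coincide both reduce to the analytic limit
#' `log m_t = (mu_c + mu_u)/2 + s2 log(p_c / (1 - p_c)) / (mu_c - mu_u)`.
#'
#' @param best_scores named numeric vector of best exemplar-class
#'   similarities per compound.
#' @param activities phenotypic activities (named vector or `data.frame`).
#' @param is_classified named logical vector: does the compound's annotated
#'   class belong to the exemplar classes?
#' @param p_c prior probability that a compound is classified, in (0, 1).
#' @param method `"printed"` (default) or `"exact"`.
#' @param floor positive floor applied to normalized scores before the log.
#' @return an object of class `"threshold_model"` with fields `mu_c`,
#'   `sigma2_c`, `mu_u`, `sigma2_u`, `p_c`, `m_t` (original scale),
#'   `log_m_t`, `method`.
#' @export
fit_threshold <- function(best_scores, activities, is_classified, p_c = 0.5,
                          method = c("printed", "exact"), floor = 1e-6) {
  method <- match.arg(method)
  stopifnot(floor > 0, p_c > 0, p_c < 1)
  activities <- as_named_vector(activities, "phenotypic_activity")
  ids <- names(best_scores)
  z <- log(pmax(best_scores / pmax(activities[ids], floor), floor))
  cls <- is_classified[ids]
  if (sum(cls) < 2L || sum(!cls) < 2L)
    stop("fit_threshold: need at least 2 compounds in each group",
         call. = FALSE)
  mu_c <- mean(z[cls]); s2_c <- var(z[cls])
  mu_u <- mean(z[!cls]); s2_u <- var(z[!cls])
  if (s2_c <= 0 || s2_u <= 0)
    stop("fit_threshold: numerical error, degenerate score variance ",
         "(all scores equal within a group)", call. = FALSE)
  log_mt <- threshold_boundary(mu_c, s2_c, mu_u, s2_u, p_c, method)
  structure(list(mu_c = mu_c, sigma2_c = s2_c, mu_u = mu_u, sigma2_u = s2_u,
                 p_c = p_c, log_m_t = log_mt, m_t = exp(log_mt),
                 method = method),
            class = "threshold_model")
}

# decision-boundary location on the log scale; exposed internally so the
# closed forms can be exercised directly on stated moments
threshold_boundary <- function(mu_c, s2_c, mu_u, s2_u, p_c, method) {
  sc <- sqrt(s2_c); su <- sqrt(s2_u)
  rel_tol <- 1e-12 * max(s2_c, s2_u)
  if (abs(s2_c - s2_u) <= rel_tol) {
    # equal-variance analytic limit (the quadratic term vanishes)
    s2 <- (s2_c + s2_u) / 2
    return((mu_c + mu_u) / 2 + s2 * log(p_c / (1 - p_c)) / (mu_c - mu_u))
  }
  if (method == "printed") {
    if (p_c == 0.5) return((sc * mu_u + su * mu_c) / (sc + su))
    disc <- (mu_c - mu_u)^2 +
      (s2_c - s2_u) * log(s2_c / s2_u * p_c / (1 - p_c))
    disc <- max(disc, 0)
    roots <- (s2_c * mu_u - s2_u * mu_c + c(1, -1) * sc * su * sqrt(disc)) /
      (s2_c - s2_u)
  } else {
    # exact two-Gaussian MAP boundary: roots of
    # (s2_c - s2_u) x^2 - 2 (s2_c mu_u - s2_u mu_c) x
    #   + s2_c mu_u^2 - s2_u mu_c^2 + 2 s2_c s2_u log(p_c su / ((1-p_c) sc))
    Lg <- log(p_c * su / ((1 - p_c) * sc))
    disc <- s2_c * s2_u * ((mu_c - mu_u)^2 - 2 * (s2_c - s2_u) * Lg)
    disc <- max(disc, 0)
    roots <- (s2_c * mu_u - s2_u * mu_c + c(1, -1) * sqrt(disc)) /
      (s2_c - s2_u)
  }
  pick_boundary_root(roots, mu_c, mu_u)
}

# prefer the root between the two group means; else the one nearest their
# midpoint
pick_boundary_root <- function(roots, mu_c, mu_u) {
  lo <- min(mu_c, mu_u); hi <- max(mu_c, mu_u)
  inside <- roots >= lo & roots <= hi
  if (any(inside)) roots[inside][1]
  else roots[which.min(abs(roots - (lo + hi) / 2))]
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Threshold model (", x$method, "): m_t = ", signif(x$m_t, 6),
      " (log ", signif(x$log_m_t, 6), ")\n", sep = "")
  cat("  classified:   mu = ", signif(x$mu_c, 6), ", s2 = ",
      signif(x$sigma2_c, 6), "\n", sep = "")
  cat("  unclassified: mu = ", signif(x$mu_u, 6), ", s2 = ",
      signif(x$sigma2_u, 6), "  p_c = ", x$p_c, "\n", sep = "")
  invisible(x)
}

#' Classify all compounds by leave-one-out exemplar similarity
#'
#' Each compound is scored against every exemplar class (mean similarity to
#' exemplars, with the compound removed from every exemplar list); the best
#' class is assigned when the compound's activity-normalized best score
#' reaches the MAP threshold, else the compound is "Unspecified". Under the
#' leave-one-out contract the threshold for compound X is fitted on all
#' compounds except X.
#'
#' @param sim similarity matrix over all compounds.
#' @param activities phenotypic activities (named vector or `data.frame`).
#' @param class_map annotated mechanism classes (named vector or
#'   `data.frame`); `"Unspecified"` marks compounds with no shared mechanism.
#' @param exemplars optional pre-built [select_exemplars()] result; by
#'   default built from `activities` and `class_map`.
#' @param p_c prior probability a compound is classified, or `"auto"` to use
#'   the observed proportion of compounds annotated with an exemplar class
#'   (recomputed without the held-out compound).
#' @param pa_threshold,min_members exemplar selection parameters.
#' @param threshold_method passed to [fit_threshold()].
#' @param loo apply the leave-one-out contract (default). `FALSE` scores
#'   against the full exemplar lists and a single threshold fit, for novel
#'   (test-set) compounds that were never exemplars.
#' @return an object of class `"classification_result"`: `data.frame` with
#'   columns `compound_id`, `expected_class`, `phenotypic_activity`,
#'   `best_match_class`, `best_match_score`, `normalized_score`, `m_t`,
#'   `predicted_class`; attribute `threshold` holds a reference
#'   `"threshold_model"` fitted on all compounds.
#' @export
classify_all <- function(sim, activities, class_map, exemplars = NULL,
                         p_c = "auto", pa_threshold = 0.4, min_members = 4,
                         threshold_method = "printed", loo = TRUE) {
  activities <- as_named_vector(activities, "phenotypic_activity")
  class_map <- as_class_map(class_map)
  exemplars <- exemplars %||%
    select_exemplars(activities, class_map, pa_threshold, min_members)
  ids <- rownames(sim)
  floor <- 1e-6

  # per-compound best exemplar-class match, self excluded
  best_class <- character(length(ids))
  best_score <- numeric(length(ids))
  for (i in seq_along(ids)) {
    scores <- class_similarity(ids[i], exemplars, sim,
                               exclude_self = loo)
    k <- which.max(scores)
    best_class[i] <- names(scores)[k]
    best_score[i] <- scores[k]
  }
  names(best_score) <- ids
  is_classified <- setNames(class_map[ids] %in% names(exemplars$classes),
                            ids)
  norm_score <- pmax(best_score / pmax(activities[ids], floor), floor)

  # reference threshold on all compounds (reported with the results)
  p_all <- if (identical(p_c, "auto")) mean(is_classified) else p_c
  full_model <- fit_threshold(best_score, activities, is_classified,
                              p_c = p_all, method = threshold_method,
                              floor = floor)

  m_t <- numeric(length(ids))
  predicted <- character(length(ids))
  for (i in seq_along(ids)) {
    model <- if (loo) {
      others <- setdiff(ids, ids[i])
      p_i <- if (identical(p_c, "auto")) mean(is_classified[others]) else p_c
      fit_threshold(best_score[others], activities, is_classified,
                    p_c = p_i, method = threshold_method, floor = floor)
    } else full_model
    m_t[i] <- model$m_t
    predicted[i] <- if (norm_score[i] >= model$m_t) best_class[i]
                    else "Unspecified"
  }

  out <- data.frame(compound_id = ids,
                    expected_class = unname(class_map[ids]),
                    phenotypic_activity = unname(activities[ids]),
                    best_match_class = best_class,
                    best_match_score = best_score,
                    normalized_score = unname(norm_score),
                    m_t = m_t,
                    predicted_class = predicted,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- full_model
  class(out) <- c("classification_result", class(out))
  out
}

#' Classification accuracy
#'
#' Fraction of compounds whose predicted class equals the annotated class
#' (annotation `"Unspecified"` counts as correct when predicted
#' `"Unspecified"`).
#'
#' @param results a [classify_all()] result.
#' @param subset optional logical or character index of compounds to score.
#' @return accuracy in `[0, 1]`.
#' @export
classification_accuracy <- function(results, subset = NULL) {
  df <- as.data.frame(results)
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- df$compound_id %in% subset
    df <- df[subset, , drop = FALSE]
  }
  mean(df$predicted_class == df$expected_class)
}

#' Intra- to inter-class similarity ratio
#'
#' Mean similarity between compounds annotated with the same mechanism class
#' divided by the mean similarity between compounds of different classes
#' (compounds annotated `"Unspecified"` are excluded). `Inf` when the classes
#' are perfectly separated.
#'
#' @param sim similarity matrix.
#' @param class_map annotated classes (named vector or `data.frame`).
#' @return the ratio (possibly `Inf`).
#' @export
intra_inter_ratio <- function(sim, class_map) {
  class_map <- as_class_map(class_map)
  ids <- rownames(sim)[class_map[rownames(sim)] != "Unspecified"]
  lab <- class_map[ids]
  s <- sim[ids, ids, drop = FALSE]
  same <- outer(lab, lab, "==") & upper.tri(s)
  diff <- outer(lab, lab, "!=") & upper.tri(s)
  mean(s[same]) / mean(s[diff])
}

#' Compare similarity models
#'
#' For each analysis model (e.g. LDA vs PCA bases at several
#' dimensionalities, weighted vs unweighted overlap, dose-response vs
#' single-point) computes the intra/inter class similarity ratio and the
#' leave-one-out classification accuracy.
#'
#' @param models named list; each element a list with components `sim`
#'   (similarity matrix) and `activities` (activity vector) from that model.
#' @param class_map annotated classes.
#' @param ... passed to [classify_all()].
#' @return `data.frame` with columns `model`, `intra_inter_ratio`,
#'   `accuracy`.
#' @export
comparison_metrics <- function(models, class_map, ...) {
  class_map <- as_class_map(class_map)
  rows <- lapply(names(models), function(name) {
    mod <- models[[name]]
    res <- classify_all(mod$sim, mod$activities, class_map, ...)
    data.frame(model = name,
               intra_inter_ratio = intra_inter_ratio(mod$sim, class_map),
               accuracy = classification_accuracy(res),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write classification results as TSV
#'
#' Columns mirror the per-compound report of the screen: compound, expected
#' class, phenotypic activity, best match and predicted class.
#'
#' @param results a [classify_all()] result.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_classification <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
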