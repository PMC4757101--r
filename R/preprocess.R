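# Reading, transforms, normalization and QC for per-cell feature tables -----

#' Read a per-cell feature table
#'
#' Reads the cell-table CSV dialect: header
#' `plate_id,well_id,compound_id,concentration_level,role,<feature1>,...`,
#' UTF-8, `.` decimal, `role` in `{treated, control}`, control rows at
#' concentration level 0.
#'
#' @param path file path.
#' @return a cell table `data.frame`.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path))
    stop("read_cell_table: file not found: ", path, call. = FALSE)
  table <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(.meta_cols, names(table))
  if (length(missing))
    stop("read_cell_table: format error, missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (f in cell_features(table)) {
    if (!is.numeric(table[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(table[[f]]))) &
                     !is.na(table[[f]]))
      stop("read_cell_table: format error, non-numeric measurement `", f,
           "` (first bad row ", if (length(bad)) bad[1] else NA, ")",
           call. = FALSE)
    }
  }
  table$concentration_level <- as.integer(table$concentration_level)
  if (anyNA(table$concentration_level[table$role == "treated"]) ||
      any(table$concentration_level[table$role == "treated"] < 1L))
    stop("read_cell_table: format error, treated rows need ",
         "`concentration_level` >= 1", call. = FALSE)
  table
}

#' Quality-control filtering of a cell table
#'
#' Two filters: (i) optionally drop each compound's highest tested
#' concentration, whose responses are typically noisy and divergent (edge
#' effects, precipitation); (ii) drop wells whose mean nuclear-stain
#' intensity lies well above the distribution over wells (contamination),
#' operationalized as a robust z-cut at `median + contamination_z * MAD` of
#' per-well means. Control wells are never removed by the top-level rule.
#'
#' @param table cell table.
#' @param drop_top_level drop each compound's maximum concentration level?
#' @param contamination_z robust z-score cut for the contamination filter
#'   (must be positive).
#' @param stain_feature name of the nuclear-stain intensity feature.
#' @return a list with elements `table` (the filtered cell table) and
#'   `report` (a QC report: `wells_dropped_contamination`, `levels_dropped`,
#'   `rows_in`, `rows_out`).
#' @export
qc_filter <- function(table, drop_top_level = TRUE, contamination_z = 5,
                      stain_feature = "nuc_intensity_dna") {
  if (!is.finite(contamination_z) || contamination_z <= 0)
    stop("qc_filter: `contamination_z` must be > 0", call. = FALSE)
  rows_in <- nrow(table)
  levels_dropped <- data.frame(compound_id = character(),
                               concentration_level = integer(),
                               stringsAsFactors = FALSE)
  if (drop_top_level) {
    treated <- table$role == "treated"
    top <- tapply(table$concentration_level[treated],
                  table$compound_id[treated], max)
    is_top <- treated & table$concentration_level ==
      top[table$compound_id]
    levels_dropped <- unique(data.frame(
      compound_id = table$compound_id[is_top],
      concentration_level = table$concentration_level[is_top],
      stringsAsFactors = FALSE))
    levels_dropped <- levels_dropped[order(levels_dropped$compound_id), ]
    rownames(levels_dropped) <- NULL
    table <- table[!is_top, , drop = FALSE]
  }
  wells_dropped <- data.frame(plate_id = character(), well_id = character(),
                              stringsAsFactors = FALSE)
  if (stain_feature %in% names(table)) {
    key <- paste(table$plate_id, table$well_id, sep = "\r")
    well_mean <- tapply(table[[stain_feature]], key, mean)
    cut <- median(well_mean) + contamination_z * mad(well_mean)
    bad <- names(well_mean)[well_mean > cut]
    if (length(bad)) {
      parts <- strsplit(bad, "\r", fixed = TRUE)
      wells_dropped <- data.frame(
        plate_id = vapply(parts, `[[`, "", 1L),
        well_id = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE)
      table <- table[!(key %in% bad), , drop = FALSE]
    }
  }
  if (nrow(table) == 0L)
    stop("qc_filter: no rows remain after filtering", call. = FALSE)
  rownames(table) <- NULL
  list(table = table,
       report = list(wells_dropped_contamination = wells_dropped,
                     levels_dropped = levels_dropped,
                     rows_in = rows_in, rows_out = nrow(table)))
}

#' Normalize a stain-intensity feature to per-well background
#'
#' Removes well-to-well variation in overall stain/illumination intensity by
#' dividing the designated feature by a per-well background estimate. When no
#' external background measurement is supplied, the per-well 10th percentile
#' of the feature across cells serves as a robust background proxy (the raw
#' background image intensity is not available from a feature table).
#'
#' @param table cell table on the raw (pre-transform) measurement scale.
#' @param feature feature to normalize.
#' @param background optional named numeric vector of per-well backgrounds,
#'   names `"<plate_id>\r<well_id>"` or `"<plate_id>:<well_id>"`; all values
#'   must be positive and every well present.
#' @param probs quantile used for the background proxy when `background` is
#'   `NULL`.
#' @return the cell table with `feature` divided by its well background.
#' @export
normalize_stain_background <- function(table, feature, background = NULL,
                                       probs = 0.1) {
  if (!feature %in% names(table))
    stop("normalize_stain_background: unknown feature `", feature, "`",
         call. = FALSE)
  key <- paste(table$plate_id, table$well_id, sep = "\r")
  if (is.null(background)) {
    background <- tapply(table[[feature]], key, quantile, probs = probs,
                         names = FALSE)
  } else {
    names(background) <- gsub(":", "\r", names(background), fixed = TRUE)
  }
  wells <- unique(key)
  missing <- setdiff(wells, names(background))
  if (length(missing))
    stop("normalize_stain_background: no background for well(s) ",
         paste(gsub("\r", ":", missing), collapse = ", "), call. = FALSE)
  bg <- background[wells]
  if (any(!is.finite(bg)) || any(bg <= 0))
    stop("normalize_stain_background: background must be positive for ",
         "every well (offending well ",
         gsub("\r", ":", wells[which(!is.finite(bg) | bg <= 0)[1]]), ")",
         call. = FALSE)
  table[[feature]] <- table[[feature]] / background[key]
  table
}

#' Default transform specification inferred from data
#'
#' Features confined to `[0, 1]` get a logit transform, strictly positive
#' features a log transform, anything else identity.
#'
#' @param table cell table on the raw measurement scale.
#' @return named character vector feature -> `"log"|"logit"|"identity"`.
#' @export
infer_transform_spec <- function(table) {
  feats <- cell_features(table)
  kind <- vapply(feats, function(f) {
    x <- table[[f]]
    if (all(x >= 0 & x <= 1, na.rm = TRUE)) "logit"
    else if (all(x > 0, na.rm = TRUE)) "log"
    else "identity"
  }, "")
  setNames(kind, feats)
}

#' Apply measurement transforms
#'
#' Maps each feature toward normality: log features `x -> log(x + epsilon)`,
#' logit features clamped to `[epsilon, 1 - epsilon]` then
#' `x -> log(x / (1 - x))`, identity unchanged. Every feature must have a
#' spec entry; output values are finite everywhere.
#'
#' @param table cell table on the raw measurement scale.
#' @param spec named character vector (or list) feature ->
#'   `"log"|"logit"|"identity"`, e.g. from [screen_transform_spec()] or
#'   [infer_transform_spec()].
#' @param epsilon boundary clamp, on the feature's native scale.
#' @return the transformed cell table.
#' @export
apply_transforms <- function(table, spec, epsilon = 1e-6) {
  stopifnot(epsilon > 0)
  spec <- unlist(spec)
  feats <- cell_features(table)
  missing <- setdiff(feats, names(spec))
  if (length(missing))
    stop("apply_transforms: no transform specified for feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad_kind <- setdiff(unique(spec[feats]), c("log", "logit", "identity"))
  if (length(bad_kind))
    stop("apply_transforms: unknown transform kind(s): ",
         paste(bad_kind, collapse = ", "), call. = FALSE)
  for (f in feats) {
    x <- table[[f]]
    y <- switch(spec[[f]],
      log = {
        if (any(x + epsilon <= 0, na.rm = TRUE))
          stop("apply_transforms: negative value under log for feature `",
               f, "`", call. = FALSE)
        log(x + epsilon)
      },
      logit = qlogis(pmin(pmax(x, epsilon), 1 - epsilon)),
      identity = x)
    table[[f]] <- y
  }
  table
}

# inverse of apply_transforms away from the clamps (used for validation)
invert_transforms <- function(table, spec, epsilon = 1e-6) {
  spec <- unlist(spec)
  for (f in cell_features(table)) {
    x <- table[[f]]
    table[[f]] <- switch(spec[[f]],
                         log = exp(x) - epsilon,
                         logit = plogis(x),
                         identity = x)
  }
  table
}

#' Normalize measurements to plate controls
#'
#' Per plate and per feature, subtracts the mean over that plate's control
#' cells from every row, removing additive inter-plate variation. After
#' normalization the pooled control population has mean 0 in every
#' measurement, the premise the control-weighted overlap relies on.
#'
#' @param table transformed cell table; every plate must contain at least one
#'   control row.
#' @return the plate-normalized cell table.
#' @export
normalize_to_plate_controls <- function(table) {
  feats <- cell_features(table)
  plates <- unique(table$plate_id)
  no_ctrl <- plates[!plates %in%
                      unique(table$plate_id[table$role == "control"])]
  if (length(no_ctrl))
    stop("normalize_to_plate_controls: plate(s) without control wells: ",
         paste(no_ctrl, collapse = ", "), call. = FALSE)
  X <- cell_feature_matrix(table, feats)
  ctrl <- table$role == "control"
  ctrl_means <- rowsum(X[ctrl, , drop = FALSE], table$plate_id[ctrl]) /
    as.vector(table(factor(table$plate_id[ctrl],
                           levels = sort(unique(table$plate_id[ctrl])))))
  table[, feats] <- X - ctrl_means[table$plate_id, , drop = FALSE]
  table
}
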