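# End-to-end convenience wrappers -------------------------------------------

#' Preprocess a raw per-cell feature table
#'
#' Runs, in order: QC filtering ([qc_filter()]), per-well stain-background
#' normalization of the designated intensity feature
#' ([normalize_stain_background()]), measurement transforms
#' ([apply_transforms()]) and plate-control normalization
#' ([normalize_to_plate_controls()]).
#'
#' @param cells raw cell table.
#' @param spec transform specification; default inferred from the data.
#' @param background_feature stain feature to background-normalize (`NULL`
#'   to skip; skipped automatically when absent from the table).
#' @param stain_feature nuclear-stain feature for the contamination filter.
#' @param drop_top_level,contamination_z QC parameters ([qc_filter()]).
#' @return list with `table` (normalized cell table) and `qc` (QC report).
#' @export
preprocess_cells <- function(cells, spec = NULL,
                             background_feature = "cyto_intensity_ph2ax",
                             stain_feature = "nuc_intensity_dna",
                             drop_top_level = FALSE, contamination_z = 5) {
  spec <- spec %||% infer_transform_spec(cells)
  qc <- qc_filter(cells, drop_top_level = drop_top_level,
                  contamination_z = contamination_z,
                  stain_feature = stain_feature)
  table <- qc$table
  if (!is.null(background_feature) && background_feature %in% names(table))
    table <- normalize_stain_background(table, background_feature)
  table <- apply_transforms(table, spec)
  table <- normalize_to_plate_controls(table)
  list(table = table, qc = qc$report)
}

#' Phenotypic profile of a normalized screen
#'
#' Fits the requested projection basis, projects the cells, builds
#' per-compound trajectories, and computes phenotypic activities and the
#' all-pairs MSWO similarity matrix.
#'
#' @param table normalized cell table (from [preprocess_cells()]).
#' @param dims number of projected dimensions.
#' @param method `"lda"` (over-classed), `"lda_mechanism"`, or `"pca"`.
#' @param class_map mechanism annotation, required for `"lda_mechanism"`.
#' @param weighted,single_point similarity options ([mswo()]).
#' @param min_cells,shrinkage trajectory options ([build_trajectories()]).
#' @return list with `basis`, `trajectories` (a `"trajectory_set"`),
#'   `activities` and `sim`.
#' @export
phenotypic_profile <- function(table, dims = 16,
                               method = c("lda", "lda_mechanism", "pca"),
                               class_map = NULL, weighted = TRUE,
                               single_point = FALSE, min_cells = NULL,
                               shrinkage = 0.1) {
  method <- match.arg(method)
  basis <- switch(method,
    lda = fit_lda(compute_scatter(table, "compound_by_concentration"),
                  m = dims),
    lda_mechanism = fit_lda(
      compute_scatter(table, "mechanism_class",
                      class_labels = as_class_map(class_map)), m = dims),
    pca = fit_pca(table, m = dims))
  projected <- project_cells(table, basis)
  ts <- build_trajectories(projected, min_cells = min_cells,
                           shrinkage = shrinkage)
  list(basis = basis, trajectories = ts,
       activities = activity_table(ts),
       sim = similarity_matrix(ts, weighted = weighted,
                               single_point = single_point))
}

#' Analyze a screen end to end
#'
#' [preprocess_cells()] followed by [phenotypic_profile()].
#'
#' @param cells raw cell table.
#' @param ... arguments passed on to [preprocess_cells()] (`spec`,
#'   `background_feature`, `stain_feature`, `drop_top_level`,
#'   `contamination_z`) and [phenotypic_profile()] (`dims`, `method`,
#'   `class_map`, `weighted`, `single_point`, `min_cells`, `shrinkage`).
#' @return the [phenotypic_profile()] list, plus `qc`.
#' @export
analyze_screen <- function(cells, ...) {
  args <- list(...)
  pre_names <- c("spec", "background_feature", "stain_feature",
                 "drop_top_level", "contamination_z")
  pre <- do.call(preprocess_cells,
                 c(list(cells), args[intersect(names(args), pre_names)]))
  prof <- do.call(phenotypic_profile,
                  c(list(pre$table),
                    args[setdiff(names(args), pre_names)]))
  c(prof, list(qc = pre$qc))
}
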