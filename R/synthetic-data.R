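# Synthetic screen generator -------------------------------------------------
#
# Emulates the post-image-analysis output of a dose-response high-content
# screen: per-well multivariate-Gaussian cell populations (on the transformed
# scale) whose means move along class-specific latent tracks with dose,
# cell counts that decline with dose for cytotoxic compounds, plate-level
# additive offsets, and a per-well multiplicative background artifact on one
# designated stain-intensity feature. Ground-truth mechanism classes, potency
# shifts and activity flags are returned for downstream validation.

# Canonical measurement panel (23 features): stain intensities and
# morphometrics on a positive scale (log-transformed for analysis) plus shape
# factors bounded in [0, 1] (logit-transformed). The nuclear DNA stain is the
# QC/contamination feature; the cytoplasmic DNA-damage stain carries the
# per-well background artifact.
.canonical_log_features <- c(
  "nuc_intensity_dna", "cyto_intensity_ph2ax", "nuc_intensity_ph2ax",
  "cyto_intensity_tubulin", "nuc_intensity_tubulin", "nuc_area",
  "nuc_perimeter", "nuc_radius_mean", "nuc_axis_major", "nuc_axis_minor",
  "cell_area", "cell_perimeter", "cell_radius_mean", "cell_radius_max",
  "cell_intensity_dna", "dna_content_total", "tubulin_edge_intensity",
  "ph2ax_spot_intensity")
.canonical_logit_features <- c(
  "nuc_roundness", "cell_roundness", "cell_compactness",
  "nuc_cell_area_frac", "cell_eccentricity")

#' Measurement names used by the synthetic screen generator
#'
#' @param feature_dim number of measurements. Up to 23, names are drawn from a
#'   canonical panel of stain intensities, morphometrics and bounded shape
#'   factors; beyond 23 generic positive-scale measurements are appended.
#' @return character vector of length `feature_dim`.
#' @export
screen_features <- function(feature_dim = 23) {
  base <- c(.canonical_log_features, .canonical_logit_features)
  if (feature_dim <= length(base)) {
    # keep shape factors (logit features) in the panel when room allows
    n_logit <- max(0L, feature_dim - length(.canonical_log_features))
    c(head(.canonical_log_features, feature_dim - n_logit),
      head(.canonical_logit_features, n_logit))
  } else {
    c(base, sprintf("extra_measure_%02d", seq_len(feature_dim - length(base))))
  }
}

# kind ("log" or "logit") for each generated feature
feature_kinds <- function(features) {
  setNames(ifelse(features %in% .canonical_logit_features, "logit", "log"),
           features)
}

#' Transform specification for generator output
#'
#' Mirrors the measurement panel of [screen_features()]: sizes, areas and
#' intensities are log features; bounded shape factors are logit features.
#'
#' @param features character vector of measurement names.
#' @return named character vector mapping feature to `"log"`/`"logit"`,
#'   usable with [apply_transforms()].
#' @export
screen_transform_spec <- function(features = screen_features()) {
  feature_kinds(features)
}

#' Configuration of a synthetic high-content screen
#'
#' Defaults describe a screen of 5 mechanism classes of 8 compounds each plus
#' 6 idiosyncratic compounds, assayed at 9 retained concentration levels
#' (3-fold serial dilution, top dose already excluded) on triplicate plates
#' with 300 cells per control well.
#'
#' @param n_classes number of ground-truth mechanism classes.
#' @param compounds_per_class compounds per mechanism class.
#' @param n_unclassified idiosyncratic compounds belonging to no class
#'   (alternately phenotypically active and inactive).
#' @param n_levels retained concentration levels per compound (1 = lowest).
#' @param latent_dim dimension of the latent phenotype space the tracks live
#'   in (must be at least 2 and at most `feature_dim`).
#' @param feature_dim number of emitted measurements.
#' @param cells_per_control_well cells in an untreated well.
#' @param n_control_wells control (vehicle) wells per plate.
#' @param potency_spread SD, in dose-level units on the log-dilution axis, of
#'   the per-compound potency shift applied to its class track.
#' @param effect_amplitude track amplitude at top dose, in units of the
#'   per-cell noise SD (population SDs of phenotype displacement).
#' @param track_shape per-class track geometry, recycled across classes:
#'   `"monotone"` (phenotype moves steadily outward with dose) or
#'   `"rise-and-return"` (phenotype peaks at an interior dose and relaxes,
#'   as DNA-damage responses do at cytotoxic doses).
#' @param kill_ec50_level,kill_hill dose level of half-maximal cell loss and
#'   Hill slope of the cytotoxicity curve for active compounds.
#' @param plate_offset_sd SD of the additive per-plate, per-feature offset
#'   (transformed scale).
#' @param background_artifact_sd SD of the log multiplicative per-well
#'   background applied to the designated stain feature.
#' @param cell_noise_sd per-cell, per-feature isotropic noise SD
#'   (transformed scale).
#' @param n_noise_dims,structured_noise_sd number and SD of latent
#'   cell-to-cell variation directions shared by all wells (cell-cycle
#'   stage, spreading, overall staining): large, correlated, and carrying no
#'   mechanism information. They dominate global variance, hence the leading
#'   principal components, while the class tracks live partly in
#'   low-variance directions.
#' @param inactive_class if `TRUE`, the last mechanism class is generated
#'   near-control (phenotypically inactive), emulating classes too weak to
#'   profile.
#' @param n_plates replicate plates.
#' @param seed integer seed; identical configurations generate identical
#'   screens.
#' @return an object of class `"screen_config"`.
#' @export
screen_config <- function(n_classes = 5, compounds_per_class = 8,
                          n_unclassified = 6, n_levels = 9, latent_dim = 10,
                          feature_dim = 23, cells_per_control_well = 300,
                          n_control_wells = 8, potency_spread = 0.75,
                          effect_amplitude = 4,
                          track_shape = c("monotone", "rise-and-return"),
                          kill_ec50_level = 7, kill_hill = 3,
                          plate_offset_sd = 0.3, background_artifact_sd = 0.3,
                          cell_noise_sd = 1, n_noise_dims = 3,
                          structured_noise_sd = 3, inactive_class = TRUE,
                          n_plates = 3, seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes),
              compounds_per_class = as.integer(compounds_per_class),
              n_unclassified = as.integer(n_unclassified),
              n_levels = as.integer(n_levels),
              latent_dim = as.integer(latent_dim),
              feature_dim = as.integer(feature_dim),
              cells_per_control_well = as.integer(cells_per_control_well),
              n_control_wells = as.integer(n_control_wells),
              potency_spread = potency_spread,
              effect_amplitude = effect_amplitude,
              track_shape = track_shape,
              kill_ec50_level = kill_ec50_level, kill_hill = kill_hill,
              plate_offset_sd = plate_offset_sd,
              background_artifact_sd = background_artifact_sd,
              cell_noise_sd = cell_noise_sd,
              n_noise_dims = as.integer(n_noise_dims),
              structured_noise_sd = structured_noise_sd,
              inactive_class = isTRUE(inactive_class),
              n_plates = as.integer(n_plates),
              seed = as.integer(seed))
  class(cfg) <- "screen_config"
  validate_screen_config(cfg)
  cfg
}

validate_screen_config <- function(cfg) {
  counts <- c("n_classes", "compounds_per_class", "n_levels", "latent_dim",
              "feature_dim", "cells_per_control_well", "n_control_wells",
              "n_plates")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("screen_config: `", f, "` must be a count >= 1", call. = FALSE)
  }
  if (cfg$n_unclassified < 0L)
    stop("screen_config: `n_unclassified` must be >= 0", call. = FALSE)
  if (cfg$n_levels < 2L)
    stop("screen_config: `n_levels` must be >= 2", call. = FALSE)
  if (cfg$latent_dim < 2L)
    stop("screen_config: `latent_dim` must be >= 2", call. = FALSE)
  if (cfg$latent_dim > cfg$feature_dim)
    stop("screen_config: `latent_dim` must not exceed `feature_dim`",
         call. = FALSE)
  if (cfg$n_noise_dims < 0L ||
      cfg$n_noise_dims > cfg$feature_dim - cfg$latent_dim)
    stop("screen_config: `n_noise_dims` must be between 0 and ",
         "feature_dim - latent_dim", call. = FALSE)
  sds <- c("potency_spread", "effect_amplitude", "plate_offset_sd",
           "background_artifact_sd", "cell_noise_sd", "structured_noise_sd")
  for (f in sds) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop("screen_config: `", f, "` must be a nonnegative number",
           call. = FALSE)
  }
  if (!all(cfg$track_shape %in% c("monotone", "rise-and-return")))
    stop("screen_config: `track_shape` must be 'monotone' or ",
         "'rise-and-return'", call. = FALSE)
  invisible(cfg)
}

#' @export
print.screen_config <- function(x, ...) {
  n_cmpd <- x$n_classes * x$compounds_per_class + x$n_unclassified
  cat("Synthetic screen configuration\n",
      "  ", x$n_classes, " classes x ", x$compounds_per_class,
      " compounds + ", x$n_unclassified, " unclassified (",
      n_cmpd, " compounds)\n",
      "  ", x$n_levels, " dose levels, ", x$n_plates, " plates, ",
      x$feature_dim, " measurements, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# deterministic per-class orthonormal latent direction pair
class_directions <- function(class_index, config) {
  subseed <- (abs(config$seed) %% 100000L) * 211L + class_index * 7919L + 11L
  with_seed(subseed, {
    qr.Q(qr(matrix(rnorm(config$latent_dim * 2L), config$latent_dim, 2L)))
  })
}

class_shape <- function(class_index, config) {
  rep(config$track_shape, length.out = config$n_classes)[class_index]
}

# near-control amplitude for the designated inactive class
class_amplitude_factor <- function(class_index, config) {
  if (config$inactive_class && class_index == config$n_classes) 0.15 else 1
}

# Track position at a (possibly fractional) dose coordinate x in [0, 1].
# Monotone: norm nondecreasing in dose. Rise-and-return: norm peaks at an
# interior dose; a slow secondary component keeps the return path from
# retracing the outbound one.
track_position <- function(x, shape, dirs, amplitude) {
  if (shape == "monotone") {
    g1 <- x
    g2 <- x^2
  } else {
    g1 <- sin(pi * x)
    g2 <- x
  }
  amplitude * (g1 * dirs[, 1] + 0.4 * g2 * dirs[, 2])
}

#' Latent track template for a mechanism class
#'
#' Deterministic latent-space mean phenotype of class `class_index` at a dose
#' level, before per-compound potency shifts and noise. Monotone tracks have
#' nondecreasing norm in dose; rise-and-return tracks peak at an interior
#' level.
#'
#' @param class_index class number in `1:n_classes`.
#' @param level dose level in `1:n_levels`.
#' @param config a [screen_config()].
#' @return numeric latent vector of length `config$latent_dim`.
#' @export
trajectory_template <- function(class_index, level, config) {
  stopifnot(inherits(config, "screen_config"))
  if (length(level) != 1L || is.na(level) || level < 1 ||
      level > config$n_levels)
    stop("trajectory_template: `level` out of range 1..", config$n_levels,
         call. = FALSE)
  if (class_index < 1 || class_index > config$n_classes)
    stop("trajectory_template: `class_index` out of range", call. = FALSE)
  dirs <- class_directions(class_index, config)
  track_position(level / config$n_levels, class_shape(class_index, config),
                 dirs, config$effect_amplitude *
                   class_amplitude_factor(class_index, config))
}

# Template evaluated at fractional level p (linear interpolation between
# integer template points, with the zero vector at p <= 0 and the top-level
# value beyond p >= n_levels). Implements per-compound potency as a shift
# along the serial-dilution axis.
template_at_fraction <- function(p, shape, dirs, amplitude, n_levels) {
  p <- min(max(p, 0), n_levels)
  lo <- floor(p)
  hi <- ceiling(p)
  w <- p - lo
  at <- function(l) {
    if (l <= 0) rep(0, nrow(dirs))
    else track_position(l / n_levels, shape, dirs, amplitude)
  }
  if (lo == hi) at(lo) else (1 - w) * at(lo) + w * at(hi)
}

#' Generate a synthetic screen with known ground truth
#'
#' Produces a per-cell feature table on the raw measurement scale (positive
#' intensities/sizes, bounded shape factors) together with a ground-truth
#' table. Treated wells cover every compound at every dose level on every
#' plate; control wells appear on every plate. Cell counts decay with dose
#' for cytotoxic compounds via a Hill curve; wells whose rounded count is 0
#' are recorded in the well table but contribute no rows.
#'
#' @param config a [screen_config()].
#' @return an object of class `"synthetic_screen"`: a list with elements
#'   `cells` (the cell table), `truth` (`compound_id`, `true_class`,
#'   `log_potency_shift`, `is_active`), `wells` (per-well bookkeeping
#'   including zero-cell wells) and `config`.
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  validate_screen_config(config)
  features <- screen_features(config$feature_dim)
  kinds <- feature_kinds(features)
  d <- config$feature_dim
  q <- config$latent_dim
  L <- config$n_levels
  bg_feature <- if ("cyto_intensity_ph2ax" %in% features)
    "cyto_intensity_ph2ax" else features[min(2L, d)]

  with_seed(config$seed, {
    # one orthonormal frame: the first q columns mix the latent tracks into
    # feature space, the next columns carry structured (class-uninformative)
    # cell-to-cell variation orthogonal to every track
    k <- config$n_noise_dims
    frame <- qr.Q(qr(matrix(rnorm(d * (q + k)), d, q + k)))
    mixing <- frame[, seq_len(q), drop = FALSE]
    noise_dirs <- frame[, q + seq_len(k), drop = FALSE]

    # compound roster ------------------------------------------------------
    comp <- list()
    for (ci in seq_len(config$n_classes)) {
      cls <- sprintf("class_%02d", ci)
      for (j in seq_len(config$compounds_per_class)) {
        comp[[length(comp) + 1L]] <- list(
          compound_id = sprintf("cmpd_%02d_%02d", ci, j),
          true_class = if (class_amplitude_factor(ci, config) >= 0.5) cls
                       else "Unspecified",
          class_index = ci,
          dirs = class_directions(ci, config),
          shape = class_shape(ci, config),
          amplitude = config$effect_amplitude *
            class_amplitude_factor(ci, config),
          is_active = class_amplitude_factor(ci, config) >= 0.5,
          shift = rnorm(1, 0, config$potency_spread))
      }
    }
    for (j in seq_len(config$n_unclassified)) {
      active <- (j %% 2L) == 1L  # alternate active/inactive idiosyncratics
      subseed <- (abs(config$seed) %% 100000L) * 211L + 500000L + j * 37L
      dirs <- with_seed(subseed, {
        qr.Q(qr(matrix(rnorm(q * 2L), q, 2L)))
      })
      comp[[length(comp) + 1L]] <- list(
        compound_id = sprintf("cmpd_unsp_%02d", j),
        true_class = "Unspecified", class_index = NA_integer_,
        dirs = dirs, shape = "monotone",
        amplitude = config$effect_amplitude * if (active) 1 else 0.1,
        is_active = active,
        shift = rnorm(1, 0, config$potency_spread))
    }

    truth <- data.frame(
      compound_id = vapply(comp, `[[`, "", "compound_id"),
      true_class = vapply(comp, `[[`, "", "true_class"),
      log_potency_shift = vapply(comp, `[[`, 0, "shift"),
      is_active = vapply(comp, `[[`, NA, "is_active"),
      stringsAsFactors = FALSE)

    # well layout -----------------------------------------------------------
    wells <- list()
    for (p in seq_len(config$n_plates)) {
      plate <- sprintf("plate_%d", p)
      for (w in seq_len(config$n_control_wells)) {
        wells[[length(wells) + 1L]] <- data.frame(
          plate_id = plate, well_id = sprintf("ctrl_%02d", w),
          compound_id = "CONTROL", concentration_level = 0L,
          role = "control", comp_index = NA_integer_,
          n_cells = config$cells_per_control_well,
          stringsAsFactors = FALSE)
      }
      for (i in seq_along(comp)) {
        cm <- comp[[i]]
        for (lev in seq_len(L)) {
          if (cm$is_active) {
            eff <- max(lev + cm$shift, 0)
            surv <- 1 / (1 + (eff / config$kill_ec50_level)^config$kill_hill)
          } else {
            surv <- 1
          }
          wells[[length(wells) + 1L]] <- data.frame(
            plate_id = plate,
            well_id = sprintf("w_%s_L%d", cm$compound_id, lev),
            compound_id = cm$compound_id, concentration_level = lev,
            role = "treated", comp_index = i,
            n_cells = max(0L, as.integer(round(
              config$cells_per_control_well * surv))),
            stringsAsFactors = FALSE)
        }
      }
    }
    wells <- do.call(rbind, wells)

    # per-well latent means -> feature-space means --------------------------
    latent_means <- matrix(0, nrow(wells), q)
    for (i in seq_len(nrow(wells))) {
      ci <- wells$comp_index[i]
      if (!is.na(ci)) {
        cm <- comp[[ci]]
        latent_means[i, ] <- template_at_fraction(
          wells$concentration_level[i] + cm$shift, cm$shape, cm$dirs,
          cm$amplitude, L)
      }
    }
    well_means <- latent_means %*% t(mixing)  # n_wells x d, transformed scale

    plate_ids <- sprintf("plate_%d", seq_len(config$n_plates))
    plate_offsets <- matrix(rnorm(config$n_plates * d, 0,
                                  config$plate_offset_sd),
                            config$n_plates, d,
                            dimnames = list(plate_ids, features))
    well_bg <- exp(rnorm(nrow(wells), 0, config$background_artifact_sd))

    # per-cell draws --------------------------------------------------------
    n_total <- sum(wells$n_cells)
    idx <- rep(seq_len(nrow(wells)), wells$n_cells)
    Z <- well_means[idx, , drop = FALSE] +
      plate_offsets[match(wells$plate_id[idx], plate_ids), , drop = FALSE] +
      matrix(rnorm(n_total * d, 0, config$cell_noise_sd), n_total, d)
    if (k > 0L && config$structured_noise_sd > 0) {
      Z <- Z + matrix(rnorm(n_total * k, 0, config$structured_noise_sd),
                      n_total, k) %*% t(noise_dirs)
    }
    colnames(Z) <- features
    # multiplicative background artifact on the designated stain (log scale)
    Z[, bg_feature] <- Z[, bg_feature] + log(well_bg[idx])
    raw <- Z
    for (f in features) {
      raw[, f] <- if (kinds[[f]] == "logit") plogis(Z[, f]) else exp(Z[, f])
    }

    cells <- data.frame(plate_id = wells$plate_id[idx],
                        well_id = wells$well_id[idx],
                        compound_id = wells$compound_id[idx],
                        concentration_level = wells$concentration_level[idx],
                        role = wells$role[idx],
                        stringsAsFactors = FALSE)
    cells <- cbind(cells, as.data.frame(raw))
    rownames(cells) <- NULL

    out <- list(cells = cells, truth = truth,
                wells = wells[, setdiff(names(wells), "comp_index")],
                background_feature = bg_feature, config = config)
    class(out) <- "synthetic_screen"
    out
  })
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat("Synthetic screen: ", nrow(x$cells), " cells, ",
      nrow(x$truth), " compounds, ", x$config$n_plates, " plates\n", sep = "")
  invisible(x)
}

#' Write / read screen tables
#'
#' `write_cell_table()` writes the cell table CSV dialect (header
#' `plate_id,well_id,compound_id,concentration_level,role,<features...>`;
#' control rows use compound `CONTROL` at level 0). `write_ground_truth()`
#' writes the ground-truth TSV.
#'
#' @param table cell table or ground-truth `data.frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
write_ground_truth <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
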