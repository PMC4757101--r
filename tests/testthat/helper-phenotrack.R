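# shared fixtures and independent oracles (built in code, no stored data)

# random symmetric positive-definite matrix
random_psd <- function(m, scale = 1) {
  A <- matrix(rnorm(m * m), m, m)
  crossprod(A) / m * scale + diag(0.1 * scale, m)
}

random_dist <- function(m, n = 100, spread = 2) {
  pheno_dist(rnorm(m, 0, spread), random_psd(m), n)
}

# trajectory of L random distributions around a shared control at the origin
random_trajectory <- function(L, m, control, id = "t",
                              n_range = c(20, 200), spread = 2) {
  dists <- lapply(seq_len(L), function(l) {
    pheno_dist(rnorm(m, 0, spread), random_psd(m),
               sample(n_range[1]:n_range[2], 1), level = l)
  })
  structure(list(compound_id = id, distributions = dists, control = control),
            class = "pheno_trajectory")
}

# small fast screen configuration for unit tests
small_config <- function(seed = 1, ...) {
  args <- list(n_classes = 3, compounds_per_class = 3, n_unclassified = 2,
               n_levels = 5, latent_dim = 4, feature_dim = 10,
               cells_per_control_well = 80, n_control_wells = 4,
               n_plates = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(screen_config, args)
}

# Naive UPGMA oracle: cluster distances recomputed from scratch as the mean
# of the original leaf-to-leaf distances across the two clusters (the
# defining invariant of average linkage), same lexicographic tie-breaking.
upgma_oracle <- function(sim) {
  n <- nrow(sim)
  labels <- rownames(sim)
  D0 <- 1 - sim
  diag(D0) <- 0
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    dmin <- Inf
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        dv <- mean(D0[clusters[[a]], clusters[[b]]])
        reps <- sort(c(min(labels[clusters[[a]]]),
                       min(labels[clusters[[b]]])))
        if (dv < dmin ||
            (dv == dmin && (reps[1] < best$reps[1] ||
                            (reps[1] == best$reps[1] &&
                             reps[2] < best$reps[2])))) {
          dmin <- dv
          best <- list(a = a, b = b, reps = reps)
        }
      }
    }
    a <- best$a; b <- best$b
    first <- if (min(labels[clusters[[a]]]) <= min(labels[clusters[[b]]]))
      c(a, b) else c(b, a)
    merge[step, ] <- c(ids[first[1]], ids[first[2]])
    height[step] <- dmin
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    ids[a] <- step
    clusters[[b]] <- NULL
    ids <- ids[-b]
  }
  list(merge = merge, height = height, labels = labels)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  d <- choose(sum(tab), 2)
  expected <- b * c_ / d
  (a - expected) / ((b + c_) / 2 - expected)
}

# cache of end-to-end analyses used by the acceptance tests (several blocks
# share the same simulated screens)
.e2e_cache <- new.env(parent = emptyenv())

e2e_models <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  cfg <- screen_config(seed = seed)
  scr <- generate_screen(cfg)
  pre <- preprocess_cells(scr$cells, spec = screen_transform_spec(),
                          drop_top_level = FALSE)
  lda16 <- phenotypic_profile(pre$table, dims = 16, method = "lda")
  lda8 <- phenotypic_profile(pre$table, dims = 8, method = "lda")
  pca8 <- phenotypic_profile(pre$table, dims = 8, method = "pca")
  ts16 <- lda16$trajectories
  out <- list(
    truth = scr$truth,
    lda16 = lda16, lda8 = lda8, pca8 = pca8,
    sim_unweighted = similarity_matrix(ts16, weighted = FALSE),
    sim_single = similarity_matrix(ts16, single_point = TRUE))
  .e2e_cache[[key]] <- out
  out
}
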