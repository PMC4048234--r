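# Independent oracles and small fixture builders used across the suite.

# Exhaustive optimal two-cluster threshold on the count-weighted intensity
# histogram: enumerate every boundary between occupied bins and minimise the
# within-cluster sum of squares. Independent of the Lloyd iteration in
# separate_staining().
oracle_threshold_mask <- function(channel, bins = 256L) {
  nb <- as.integer(bins)
  bi <- pmin(floor(pmax(channel, 0) * nb) + 1L, nb)
  counts <- tabulate(bi, nbins = nb)
  centers <- (seq_len(nb) - 0.5) / nb
  occ <- which(counts > 0L)
  stopifnot(length(occ) >= 2L)
  x <- centers[occ]
  w <- counts[occ]
  best_k <- NA_integer_
  best_wcss <- Inf
  for (k in seq_len(length(occ) - 1L)) {
    lo <- seq_len(k)
    hi <- seq.int(k + 1L, length(occ))
    m1 <- sum(w[lo] * x[lo]) / sum(w[lo])
    m2 <- sum(w[hi] * x[hi]) / sum(w[hi])
    wcss <- sum(w[lo] * (x[lo] - m1)^2) + sum(w[hi] * (x[hi] - m2)^2)
    if (wcss < best_wcss) {
      best_wcss <- wcss
      best_k <- k
    }
  }
  matrix(bi >= occ[best_k + 1L], nrow(channel), ncol(channel))
}

# Random bimodal test image: background and stain levels with Gaussian noise.
random_bimodal_image <- function(seed, h = 80, w = 80) {
  set.seed(seed)
  bg <- runif(1, 0.05, 0.30)
  st <- runif(1, 0.50, 0.95)
  frac <- runif(1, 0.1, 0.9)
  sd <- runif(1, 0.02, 0.10)
  base <- ifelse(runif(h * w) < frac, st, bg)
  matrix(pmin(pmax(base + rnorm(h * w, 0, sd), 0), 1), h, w)
}

# Greedy nearest-pair matching of detected centroids against ground truth.
# Returns matched truth/detection index pairs within `radius` pixels.
match_centroids <- function(truth, detected, radius) {
  if (nrow(truth) == 0L || nrow(detected) == 0L) {
    return(data.frame(truth = integer(), det = integer()))
  }
  d <- outer(truth$row, detected$row, "-")^2 + outer(truth$col, detected$col, "-")^2
  d <- sqrt(d)
  pairs <- list()
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > radius) break
    i <- (m - 1) %% nrow(d) + 1
    j <- (m - 1) %/% nrow(d) + 1
    pairs[[length(pairs) + 1L]] <- c(i, j)
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  out <- do.call(rbind, pairs)
  if (is.null(out)) return(data.frame(truth = integer(), det = integer()))
  data.frame(truth = out[, 1], det = out[, 2])
}

# Nucleus detection and label-accuracy summary on one synthetic islet.
detection_summary <- function(syn, scored, match_radius = 2 * syn$params$nucleus_radius) {
  truth <- syn$truth$nuclei
  det <- scored$nuclei$centroids
  pairs <- match_centroids(truth, det, match_radius)
  labels <- scored$cells$label[pairs$det]
  classes <- truth$class[pairs$truth]
  list(
    recall = nrow(pairs) / nrow(truth),
    precision = if (nrow(det)) nrow(pairs) / nrow(det) else NA_real_,
    label_accuracy = if (nrow(pairs)) mean(labels == classes) else NA_real_
  )
}

# Small fast generator settings for unit tests.
small_params <- function(seed, ...) {
  synth_params(height = 140, width = 170, n_nuclei = 8, seed = seed, ...)
}

# A stain map built directly from a logical mask, for unit tests that need a
# controlled mask without crafting an image first.
stain_map_from_mask <- function(mask) {
  structure(
    list(stained = mask, threshold = 0.5,
         cluster_centers = c(background = 0.1, staining = 0.9),
         boundary = 0.5, degenerate = FALSE, histogram_bins = 256L),
    class = "stain_map"
  )
}

# An empty/manual nucleus set for arithmetic tests.
manual_nuclei <- function(centroids, mask) {
  nucleus_set(centroids, mask)
}

table1_path <- function() {
  system.file("extdata", "cohort_table1.csv", package = "isletscore")
}
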