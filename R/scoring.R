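# Core scoring mathematics: adaptive stain/background separation by 1-D
# two-cluster k-means on the intensity histogram, per-pixel classification,
# patch-based alpha/beta majority voting, and the islet features (area score
# in [0, 3], islet size, beta-cell density).

#' Separate staining from background by histogram k-means
#'
#' Builds a count-weighted intensity histogram of the whole image and splits
#' it into two clusters (background vs staining) with one-dimensional k-means
#' (k = 2). The split is fully adaptive: no per-image threshold has to be
#' chosen, and because the histogram is computed over the whole image the
#' split is robust to smooth illumination artefacts. Initial centres sit at
#' the 10th and 90th percentile points of the occupied intensity range and
#' Lloyd iterations run on the weighted bin centres until centre movement
#' falls below 1e-6 (at most 100 iterations); a final deterministic boundary
#' refinement moves the cut while the within-cluster sum of squares strictly
#' decreases, resolving near-tied boundary bins. The result has no random
#' component.
#'
#' Pixels are assigned by their histogram bin's cluster; the reported
#' `threshold` is the midpoint between the two final centres and agrees with
#' the mask to within one bin width. If the histogram occupies a single bin,
#' or the final centres are closer than two bin widths, the image is flagged
#' degenerate and everything is background (an unstained islet scores 0).
#'
#' @param channel Numeric matrix with intensities in `[0, 1]`.
#' @param histogram_bins Number of equal-width histogram bins on `[0, 1]`.
#' @return An object of class `stain_map`: `stained` (logical matrix),
#'   `threshold`, `cluster_centers` (named `background`, `staining`),
#'   `boundary` (the bin edge separating the clusters), `degenerate`,
#'   `histogram_bins`.
#' @export
separate_staining <- function(channel, histogram_bins = 256L) {
  if (!is.matrix(channel) || !is.numeric(channel) || length(channel) == 0L) {
    stop_parameter("`channel` must be a non-empty numeric matrix")
  }
  check_number(histogram_bins, "histogram_bins", lower = 2, integer = TRUE)
  nb <- as.integer(histogram_bins)
  bin_width <- 1 / nb
  bin_idx <- pmin(floor(pmax(channel, 0) * nb) + 1L, nb)
  counts <- tabulate(bin_idx, nbins = nb)
  centers_of_bins <- (seq_len(nb) - 0.5) * bin_width
  occupied <- which(counts > 0L)

  degenerate_map <- function() {
    structure(
      list(stained = matrix(FALSE, nrow(channel), ncol(channel)),
           threshold = NA_real_,
           cluster_centers = c(background = NA_real_, staining = NA_real_),
           boundary = NA_real_, degenerate = TRUE, histogram_bins = nb),
      class = "stain_map"
    )
  }
  if (length(occupied) < 2L) return(degenerate_map())

  lo <- centers_of_bins[occupied[1]]
  hi <- centers_of_bins[occupied[length(occupied)]]
  centers <- c(lo + 0.1 * (hi - lo), lo + 0.9 * (hi - lo))
  x <- centers_of_bins[occupied]
  w <- counts[occupied]
  for (iter in seq_len(100L)) {
    upper <- abs(x - centers[2]) < abs(x - centers[1])
    new_centers <- c(
      if (any(!upper)) sum(w[!upper] * x[!upper]) / sum(w[!upper]) else centers[1],
      if (any(upper)) sum(w[upper] * x[upper]) / sum(w[upper]) else centers[2]
    )
    moved <- max(abs(new_centers - centers))
    centers <- new_centers
    if (moved < 1e-6) break
  }
  if (diff(centers) < 2 * bin_width) return(degenerate_map())

  # Lloyd can stall on one of two adjacent fixed points when the boundary bin
  # is a near-tie; refine the cut by moving it while the within-cluster sum
  # of squares strictly decreases (deterministic, no randomness).
  upper <- abs(x - centers[2]) < abs(x - centers[1])
  k <- max(1L, min(length(x) - 1L, sum(!upper)))
  cw <- cumsum(w); cwx <- cumsum(w * x); cwx2 <- cumsum(w * x^2)
  tw <- cw[length(x)]; twx <- cwx[length(x)]; twx2 <- cwx2[length(x)]
  wcss_at <- function(k) {
    (cwx2[k] - cwx[k]^2 / cw[k]) +
      ((twx2 - cwx2[k]) - (twx - cwx[k])^2 / (tw - cw[k]))
  }
  repeat {
    cur <- wcss_at(k)
    lower_k <- if (k > 1L) wcss_at(k - 1L) else Inf
    upper_k <- if (k < length(x) - 1L) wcss_at(k + 1L) else Inf
    if (lower_k < cur && lower_k <= upper_k) {
      k <- k - 1L
    } else if (upper_k < cur) {
      k <- k + 1L
    } else {
      break
    }
  }
  centers <- c(cwx[k] / cw[k], (twx - cwx[k]) / (tw - cw[k]))
  if (diff(centers) < 2 * bin_width) return(degenerate_map())
  first_stained_bin <- occupied[k + 1L]
  boundary <- (first_stained_bin - 1L) * bin_width
  stained <- matrix(bin_idx >= first_stained_bin, nrow(channel), ncol(channel))
  structure(
    list(stained = stained,
         threshold = mean(centers),
         cluster_centers = c(background = centers[1], staining = centers[2]),
         boundary = boundary, degenerate = FALSE, histogram_bins = nb),
    class = "stain_map"
  )
}

#' @export
print.stain_map <- function(x, ...) {
  if (x$degenerate) {
    cat("<stain_map> degenerate (single intensity mode): all background\n")
  } else {
    cat(sprintf(
      "<stain_map> threshold %.4f (centers %.4f / %.4f), %d stained px\n",
      x$threshold, x$cluster_centers[1], x$cluster_centers[2], sum(x$stained)
    ))
  }
  invisible(x)
}

#' Classify cells as alpha or beta by patch majority voting
#'
#' For every detected nucleus, stained pixels of the 488 (beta marker) and
#' 555 (alpha counterstain) layers are counted within a disc of
#' `patch_radius` pixels around the centroid (clipped at image borders). A
#' strict majority of 488 evidence labels the cell `beta`, of 555 evidence
#' `alpha`; ties — including zero evidence on both channels — stay
#' `unclassified`.
#'
#' @param nuclei A [nucleus_set()] from [detect_nuclei()].
#' @param map488,map555 [separate_staining()] maps of the two stain layers.
#' @param patch_radius Patch disc radius in pixels.
#' @return A tibble of class `cell_classification` with one row per nucleus:
#'   `nucleus`, `row`, `col`, `count488`, `count555`, `label`.
#' @export
classify_cells <- function(nuclei, map488, map555, patch_radius = 8) {
  stopifnot(inherits(nuclei, "nucleus_set"),
            inherits(map488, "stain_map"), inherits(map555, "stain_map"))
  check_number(patch_radius, "patch_radius", lower = 1)
  check_same_dims(map488$stained, map555$stained, "488 map", "555 map")
  h <- nrow(map488$stained); w <- ncol(map488$stained)
  offs <- disc_offsets(patch_radius)
  n <- nuclei$n
  count488 <- integer(n); count555 <- integer(n)
  for (i in seq_len(n)) {
    r <- round(nuclei$centroids$row[i]); c <- round(nuclei$centroids$col[i])
    rr <- offs[, 1] + r; cc <- offs[, 2] + c
    keep <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    idx <- cbind(rr[keep], cc[keep])
    count488[i] <- sum(map488$stained[idx])
    count555[i] <- sum(map555$stained[idx])
  }
  label <- ifelse(count488 > count555, "beta",
                  ifelse(count555 > count488, "alpha", "unclassified"))
  out <- tibble(
    nucleus = seq_len(n),
    row = nuclei$centroids$row, col = nuclei$centroids$col,
    count488 = count488, count555 = count555, label = label
  )
  if (n == 0L) {
    out <- tibble(nucleus = integer(), row = numeric(), col = numeric(),
                  count488 = integer(), count555 = integer(), label = character())
  }
  attr(out, "patch_radius") <- patch_radius
  class(out) <- c("cell_classification", class(out))
  out
}

#' Beta-cell area score of an islet
#'
#' The stained fraction is the number of stained pixels inside the islet,
#' excluding nucleus pixels, divided by the islet area; the area score maps
#' it linearly onto the pathologist's `[0, 3]` scale (`score = 3 x
#' fraction`). The default denominator is the full islet area; set
#' `denominator = "islet_minus_nuclei"` to exclude nucleus pixels from the
#' denominator as well.
#'
#' @param stain A [separate_staining()] map of the scored channel.
#' @param islet An [islet_mask()].
#' @param nuclei A [nucleus_set()]; its mask is excluded from the numerator.
#' @param denominator `"islet"` (default) or `"islet_minus_nuclei"`.
#' @return A list with `area_score` in `[0, 3]` and `stained_fraction` in
#'   `[0, 1]`.
#' @export
area_score <- function(stain, islet, nuclei,
                       denominator = c("islet", "islet_minus_nuclei")) {
  stopifnot(inherits(stain, "stain_map"), inherits(islet, "islet_mask"),
            inherits(nuclei, "nucleus_set"))
  denominator <- match.arg(denominator)
  check_same_dims(stain$stained, islet$mask, "stain map", "islet mask")
  check_same_dims(stain$stained, nuclei$mask, "stain map", "nuclei mask")
  num <- sum(stain$stained & islet$mask & !nuclei$mask)
  den <- if (denominator == "islet") {
    islet$area_px
  } else {
    islet$area_px - sum(nuclei$mask & islet$mask)
  }
  if (den <= 0) stop_parameter("denominator islet area is zero")
  fraction <- num / den
  list(area_score = 3 * fraction, stained_fraction = fraction)
}

#' Islet size in pixels and physical units
#'
#' @param islet An [islet_mask()].
#' @param pixel_size Optional micrometres per pixel edge.
#' @return A list with `islet_size_px` and `islet_size_um2` (`NA` when
#'   `pixel_size` is unknown).
#' @export
islet_size <- function(islet, pixel_size = NULL) {
  stopifnot(inherits(islet, "islet_mask"))
  if (!is.null(pixel_size)) check_number(pixel_size, "pixel_size", lower = 1e-12)
  list(
    islet_size_px = islet$area_px,
    islet_size_um2 = if (is.null(pixel_size)) NA_real_ else islet$area_px * pixel_size^2
  )
}

#' Beta-cell density of an islet
#'
#' Number of cells classified as beta-marker positive, normalised to the
#' islet area. Reported per 10^4 px^2, and per mm^2 when the pixel size is
#' known. Unclassified cells count toward the nucleus total but never toward
#' the density.
#'
#' @param cells A [classify_cells()] result.
#' @param islet An [islet_mask()].
#' @param pixel_size Optional micrometres per pixel edge.
#' @return A list with `n_beta`, `beta_density_per_1e4px` and
#'   `beta_density_per_mm2` (`NA` without `pixel_size`).
#' @export
beta_density <- function(cells, islet, pixel_size = NULL) {
  stopifnot(inherits(cells, "cell_classification"), inherits(islet, "islet_mask"))
  if (!is.null(pixel_size)) check_number(pixel_size, "pixel_size", lower = 1e-12)
  n_beta <- sum(cells$label == "beta")
  list(
    n_beta = n_beta,
    beta_density_per_1e4px = n_beta / islet$area_px * 1e4,
    beta_density_per_mm2 = if (is.null(pixel_size)) NA_real_ else
      n_beta / (islet$area_px * pixel_size^2) * 1e6
  )
}

#' Surrogate of the pathologist's manual score
#'
#' The manual score combines the staining intensity (an integer grade 0-3)
#' with the percentage of stained cells in the islet, on a `[0, 3]` scale in
#' steps of 0.25. The exact decision rule of the original scoring sheet is
#' not published; this surrogate multiplies the intensity grade by the
#' stained-cell fraction and rounds half-up to the nearest 0.25 step. It is a
#' documented approximation, not a claim of equivalence.
#'
#' @param intensity_level Integer staining intensity grade in `0:3`.
#' @param stained_cell_fraction Fraction of stained cells in `[0, 1]`.
#' @return Score in `[0, 3]`, quantised to multiples of 0.25. Vectorised.
#' @examples
#' manual_score_surrogate(2, 0.6) # 1.2 -> 1.25
#' @export
manual_score_surrogate <- function(intensity_level, stained_cell_fraction) {
  if (!is.numeric(intensity_level) || any(!intensity_level %in% 0:3)) {
    stop_parameter("`intensity_level` must be integer grade(s) in 0:3")
  }
  if (!is.numeric(stained_cell_fraction) || any(is.na(stained_cell_fraction)) ||
      any(stained_cell_fraction < 0) || any(stained_cell_fraction > 1)) {
    stop_parameter("`stained_cell_fraction` must lie in [0, 1]")
  }
  raw <- intensity_level * stained_cell_fraction
  floor(raw / 0.25 + 0.5) * 0.25
}

#' Scoring pipeline configuration
#'
#' @param histogram_bins Histogram bins for [separate_staining()].
#' @param min_radius,max_radius Expected nucleus radius range in pixels for
#'   [detect_nuclei()].
#' @param patch_radius Voting patch radius in pixels; defaults to
#'   `2.5 * min_radius`.
#' @param denominator Area-score denominator mode, see [area_score()].
#' @param target_channel Channel carrying the scored marker, `"target488"`
#'   (default) or `"counter555"`.
#' @param pixel_size Optional micrometres per pixel.
#' @return A list of class `score_config`.
#' @export
score_config <- function(histogram_bins = 256L, min_radius = 3, max_radius = 8,
                         patch_radius = 2.5 * min_radius,
                         denominator = c("islet", "islet_minus_nuclei"),
                         target_channel = c("target488", "counter555"),
                         pixel_size = NULL) {
  check_number(histogram_bins, "histogram_bins", lower = 2, integer = TRUE)
  check_number(min_radius, "min_radius", lower = 0.5)
  check_number(max_radius, "max_radius", lower = min_radius)
  check_number(patch_radius, "patch_radius", lower = 1)
  if (!is.null(pixel_size)) check_number(pixel_size, "pixel_size", lower = 1e-12)
  structure(
    list(histogram_bins = as.integer(histogram_bins), min_radius = min_radius,
         max_radius = max_radius, patch_radius = patch_radius,
         denominator = match.arg(denominator),
         target_channel = match.arg(target_channel), pixel_size = pixel_size),
    class = "score_config"
  )
}

#' Score one islet end to end
#'
#' Runs the full per-islet pipeline: nucleus detection on the DAPI layer,
#' stain/background separation of the 488 and 555 layers, patch-based
#' alpha/beta voting, and the three islet features (area score, islet size,
#' beta-cell density).
#'
#' @param stack A [channel_stack()].
#' @param islet The matching [islet_mask()].
#' @param config A [score_config()].
#' @param verbose Emit per-stage summary messages.
#' @return An object of class `islet_score` holding all intermediate results
#'   plus `features`, a one-row tibble; see [tidy.islet_score()].
#' @examples
#' syn <- generate_islet(synth_params(seed = 7))
#' sc <- score_islet(syn$stack, syn$islet)
#' tidy(sc)
#' @export
score_islet <- function(stack, islet, config = score_config(), verbose = FALSE) {
  stopifnot(inherits(stack, "channel_stack"), inherits(islet, "islet_mask"),
            inherits(config, "score_config"))
  check_same_dims(stack$dapi, islet$mask, "image", "islet mask")
  say <- function(fmt, ...) if (verbose) message("[score_islet] ", sprintf(fmt, ...))
  pixel_size <- config$pixel_size %||% stack$pixel_size

  nuclei <- detect_nuclei(stack$dapi, islet,
                          min_radius = config$min_radius,
                          max_radius = config$max_radius,
                          histogram_bins = config$histogram_bins)
  say("nuclei detected: %d", nuclei$n)
  map488 <- separate_staining(stack$target488, config$histogram_bins)
  map555 <- separate_staining(stack$counter555, config$histogram_bins)
  say("488 threshold: %s; 555 threshold: %s",
      format(map488$threshold), format(map555$threshold))
  cells <- classify_cells(nuclei, map488, map555, config$patch_radius)
  target_map <- if (config$target_channel == "target488") map488 else map555
  sc <- area_score(target_map, islet, nuclei, config$denominator)
  say("stained fraction: %.4f (area score %.3f)", sc$stained_fraction, sc$area_score)
  size <- islet_size(islet, pixel_size)
  dens <- beta_density(cells, islet, pixel_size)

  features <- tibble(
    area_score = sc$area_score,
    stained_fraction = sc$stained_fraction,
    islet_size_px = size$islet_size_px,
    islet_size_um2 = size$islet_size_um2,
    n_nuclei = nuclei$n,
    n_beta = sum(cells$label == "beta"),
    n_alpha = sum(cells$label == "alpha"),
    n_unclassified = sum(cells$label == "unclassified"),
    beta_density_per_1e4px = dens$beta_density_per_1e4px,
    beta_density_per_mm2 = dens$beta_density_per_mm2,
    threshold488 = map488$threshold,
    threshold555 = map555$threshold
  )
  structure(
    list(features = features, nuclei = nuclei, map488 = map488,
         map555 = map555, cells = cells, config = config, islet = islet,
         stack = stack),
    class = "islet_score"
  )
}

#' @export
print.islet_score <- function(x, ...) {
  f <- x$features
  cat(sprintf(
    "<islet_score> area score %.3f (stained fraction %.3f), islet %d px\n  %d nuclei: %d beta / %d alpha / %d unclassified; beta density %.2f per 1e4 px^2\n",
    f$area_score, f$stained_fraction, f$islet_size_px, f$n_nuclei, f$n_beta,
    f$n_alpha, f$n_unclassified, f$beta_density_per_1e4px
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
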