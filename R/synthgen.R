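# Seeded synthetic islet images with full ground truth. The imaging model:
# an elliptical islet on a dark background; one Gaussian-profile DAPI blob
# per nucleus; each beta cell stains part of a cytoplasmic annulus in the 488
# layer and each alpha cell in the 555 layer; a smooth multiplicative
# illumination field and additive Gaussian noise on top. Ground truth records
# the pre-noise masks, so every downstream stage can be scored against it.

#' Parameters of the synthetic islet image model
#'
#' Defaults draw a quarter-scale (344 x 258 pixel) canvas relative to the
#' 1376 x 1032 acquisition format, holding 40 cells in an elliptical islet.
#' Signal-to-noise ratio in this model is
#' `(stain_level - background_level) / noise_sd`.
#'
#' @param height,width Canvas size in pixels.
#' @param islet_center `c(row, col)` of the islet ellipse centre; defaults to
#'   the canvas centre.
#' @param islet_axes `c(row, col)` semi-axes of the islet ellipse in pixels;
#'   defaults to 38% of each canvas dimension.
#' @param n_nuclei Number of cells (nuclei) placed in the islet.
#' @param nucleus_radius Nucleus radius in pixels; the DAPI blob profile is a
#'   Gaussian of scale `nucleus_radius / 1.5` and the nucleus mask is the disc
#'   of this radius.
#' @param cytoplasm_radius Outer radius of the stained cytoplasmic annulus in
#'   pixels (inner radius is `nucleus_radius`).
#' @param beta_fraction Fraction of cells that are beta cells (stain in 488);
#'   the rest are alpha cells (stain in 555).
#' @param stain_fraction_per_beta Fraction of a cell's annulus pixels that
#'   actually stain, applied to both cell types.
#' @param stain_level,background_level Pre-noise intensities of stained and
#'   unstained pixels, in `(0, 1]` and `[0, 1)`; `background_level` must be
#'   below `stain_level` for the classes to be separable.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @param illumination_gradient Amplitude in `[0, 1)` of a smooth low-order
#'   polynomial multiplicative illumination field `1 + a * P(row, col)` with
#'   `max |P| = 1`.
#' @param well_separated If `TRUE` (default), nucleus centres are placed at
#'   least `min_separation` apart so that cytoplasmic annuli do not overlap
#'   and per-cell patch votes are unambiguous.
#' @param min_separation Minimum centre-to-centre distance in pixels; defaults
#'   to `2 * cytoplasm_radius` in well-separated mode (disjoint annuli, which
#'   also guarantees at least `2 * nucleus_radius`) and `0` otherwise.
#' @param target_stained_fraction Optional value in `[0, 1]`: after the annuli
#'   are drawn, stained 488 pixels are added among (or removed from) the
#'   non-nuclear islet pixels until the ground-truth stained fraction equals
#'   this value to pixel resolution. Used to sweep the true area score.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(height = 258, width = 344,
                         islet_center = NULL, islet_axes = NULL,
                         n_nuclei = 40, nucleus_radius = 4,
                         cytoplasm_radius = 2.5 * nucleus_radius,
                         beta_fraction = 0.7, stain_fraction_per_beta = 0.9,
                         stain_level = 0.75, background_level = 0.12,
                         noise_sd = 0.05, illumination_gradient = 0.15,
                         well_separated = TRUE, min_separation = NULL,
                         target_stained_fraction = NULL, seed = 1L) {
  check_number(height, "height", lower = 16, integer = TRUE)
  check_number(width, "width", lower = 16, integer = TRUE)
  if (is.null(islet_center)) islet_center <- c(height, width) / 2
  if (is.null(islet_axes)) islet_axes <- 0.38 * c(height, width)
  check_number(n_nuclei, "n_nuclei", lower = 1, integer = TRUE)
  check_number(nucleus_radius, "nucleus_radius", lower = 1)
  check_number(cytoplasm_radius, "cytoplasm_radius", lower = nucleus_radius)
  check_number(beta_fraction, "beta_fraction", lower = 0, upper = 1)
  check_number(stain_fraction_per_beta, "stain_fraction_per_beta", lower = 0, upper = 1)
  check_number(stain_level, "stain_level", lower = 1e-6, upper = 1)
  check_number(background_level, "background_level", lower = 0, upper = 1 - 1e-6)
  if (background_level >= stain_level) {
    stop_parameter("`background_level` must be below `stain_level`")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(illumination_gradient, "illumination_gradient", lower = 0, upper = 1 - 1e-9)
  if (is.null(min_separation)) {
    min_separation <- if (well_separated) 2 * cytoplasm_radius else 0
  }
  if (well_separated && min_separation < 2 * nucleus_radius) {
    stop_parameter("well-separated mode needs `min_separation` >= 2 * nucleus_radius")
  }
  check_number(target_stained_fraction, "target_stained_fraction",
               lower = 0, upper = 1, allow_null = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(height = as.integer(height), width = as.integer(width),
         islet_center = as.numeric(islet_center),
         islet_axes = as.numeric(islet_axes),
         n_nuclei = as.integer(n_nuclei), nucleus_radius = nucleus_radius,
         cytoplasm_radius = cytoplasm_radius, beta_fraction = beta_fraction,
         stain_fraction_per_beta = stain_fraction_per_beta,
         stain_level = stain_level, background_level = background_level,
         noise_sd = noise_sd, illumination_gradient = illumination_gradient,
         well_separated = well_separated, min_separation = min_separation,
         target_stained_fraction = target_stained_fraction,
         seed = as.integer(seed)),
    class = "synth_params"
  )
}

place_centers <- function(params) {
  n <- params$n_nuclei
  ctr <- params$islet_center
  ax <- pmax(params$islet_axes - params$cytoplasm_radius, 1)
  centers <- matrix(NA_real_, nrow = n, ncol = 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 500L * n
  min_sep2 <- params$min_separation^2
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(sprintf(
        "could not place %d nuclei at separation %.1f px inside the islet (placed %d)",
        n, params$min_separation, placed
      ), class = "isletscore_error_generation")
    }
    r <- ctr[1] + ax[1] * (2 * runif(1) - 1)
    c <- ctr[2] + ax[2] * (2 * runif(1) - 1)
    if (((r - ctr[1]) / ax[1])^2 + ((c - ctr[2]) / ax[2])^2 > 1) next
    if (placed > 0L && min_sep2 > 0) {
      d2 <- (centers[seq_len(placed), 1] - r)^2 + (centers[seq_len(placed), 2] - c)^2
      if (min(d2) < min_sep2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- c(r, c)
  }
  centers
}

# Pixel coordinates (row, col) of the annulus r_in < d <= r_out around a
# centre, clipped to the canvas.
annulus_coords_at <- function(center, r_in, r_out, height, width) {
  r0 <- max(1L, floor(center[1] - r_out)); r1 <- min(height, ceiling(center[1] + r_out))
  c0 <- max(1L, floor(center[2] - r_out)); c1 <- min(width, ceiling(center[2] + r_out))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, "+")
  sel <- d2 <= r_out^2 & d2 > r_in^2
  idx <- which(sel, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(integer(0), ncol = 2))
  cbind(rows[idx[, 1]], cols[idx[, 2]])
}

#' Generate one synthetic islet image with ground truth
#'
#' @param params A [synth_params()] object.
#' @return A list of class `synthetic_islet` with elements
#'   \describe{
#'     \item{stack}{the noisy [channel_stack()]}
#'     \item{islet}{the [islet_mask()]}
#'     \item{truth}{a list with `nuclei` (tibble of `row`, `col`, `class`),
#'       `nuclei_mask`, `stained488`, `stained555` (pre-noise logical masks)
#'       and `true_stained_fraction`, the stained non-nuclear islet pixels of
#'       the 488 layer divided by the islet area}
#'   }
#' @examples
#' syn <- generate_islet(synth_params(n_nuclei = 12, seed = 42))
#' syn$truth$true_stained_fraction
#' @export
generate_islet <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  h <- params$height; w <- params$width
  with_seed(params$seed, {
    rows <- seq_len(h); cols <- seq_len(w)
    ctr <- params$islet_center; ax <- params$islet_axes
    islet <- outer(((rows - ctr[1]) / ax[1])^2, ((cols - ctr[2]) / ax[2])^2, "+") <= 1

    centers <- place_centers(params)
    n <- params$n_nuclei
    n_beta <- round(params$beta_fraction * n)
    classes <- sample(c(rep("beta", n_beta), rep("alpha", n - n_beta)))

    bg <- params$background_level; st <- params$stain_level
    dapi <- matrix(bg, h, w)
    nuclei_mask <- matrix(FALSE, h, w)
    stained488 <- matrix(FALSE, h, w)
    stained555 <- matrix(FALSE, h, w)
    sigma <- params$nucleus_radius / 1.5

    for (i in seq_len(n)) {
      ce <- centers[i, ]
      ext <- ceiling(3 * sigma)
      r0 <- max(1L, floor(ce[1] - ext)); r1 <- min(h, ceiling(ce[1] + ext))
      c0 <- max(1L, floor(ce[2] - ext)); c1 <- min(w, ceiling(ce[2] + ext))
      d2 <- outer((r0:r1 - ce[1])^2, (c0:c1 - ce[2])^2, "+")
      blob <- (st - bg) * exp(-d2 / (2 * sigma^2))
      dapi[r0:r1, c0:c1] <- pmin(dapi[r0:r1, c0:c1] + blob, st)
      nuc <- d2 <= params$nucleus_radius^2
      nuclei_mask[r0:r1, c0:c1] <- nuclei_mask[r0:r1, c0:c1] | nuc

      ann <- annulus_coords_at(ce, params$nucleus_radius, params$cytoplasm_radius, h, w)
      if (nrow(ann)) {
        k <- round(params$stain_fraction_per_beta * nrow(ann))
        pick <- if (k >= nrow(ann)) seq_len(nrow(ann)) else sample(nrow(ann), k)
        sel <- ann[pick, , drop = FALSE]
        if (classes[i] == "beta") {
          stained488[sel] <- TRUE
        } else {
          stained555[sel] <- TRUE
        }
      }
    }

    area <- sum(islet)
    if (!is.null(params$target_stained_fraction)) {
      candidates <- islet & !nuclei_mask
      need <- round(params$target_stained_fraction * area)
      if (need > sum(candidates)) {
        stop_parameter(sprintf(
          "target_stained_fraction %.3f needs %d stained pixels but only %d non-nuclear islet pixels exist",
          params$target_stained_fraction, need, sum(candidates)
        ))
      }
      have_idx <- which(stained488 & candidates)
      if (length(have_idx) < need) {
        pool <- which(candidates & !stained488)
        add <- sample(pool, need - length(have_idx))
        stained488[add] <- TRUE
      } else if (length(have_idx) > need) {
        drop <- sample(have_idx, length(have_idx) - need)
        stained488[drop] <- FALSE
      }
    }

    ch488 <- matrix(bg, h, w); ch488[stained488] <- st
    ch555 <- matrix(bg, h, w); ch555[stained555] <- st

    if (params$illumination_gradient > 0) {
      u <- if (h > 1) 2 * (rows - 1) / (h - 1) - 1 else rep(0, h)
      v <- if (w > 1) 2 * (cols - 1) / (w - 1) - 1 else rep(0, w)
      a <- runif(5, -1, 1)
      P <- a[1] * outer(u, rep(1, w)) + a[2] * outer(rep(1, h), v) +
        a[3] * outer(u, v) + a[4] * outer(u^2, rep(1, w)) +
        a[5] * outer(rep(1, h), v^2)
      P <- P / max(abs(P))
      L <- 1 + params$illumination_gradient * P
      dapi <- dapi * L; ch488 <- ch488 * L; ch555 <- ch555 * L
    }
    if (params$noise_sd > 0) {
      dapi <- dapi + rnorm(h * w, 0, params$noise_sd)
      ch488 <- ch488 + rnorm(h * w, 0, params$noise_sd)
      ch555 <- ch555 + rnorm(h * w, 0, params$noise_sd)
    }
    clip <- function(x) pmin(pmax(x, 0), 1)

    truth <- list(
      nuclei = tibble(row = centers[, 1], col = centers[, 2], class = classes),
      nuclei_mask = nuclei_mask,
      stained488 = stained488,
      stained555 = stained555,
      true_stained_fraction = sum(stained488 & islet & !nuclei_mask) / area
    )
    structure(
      list(stack = channel_stack(clip(dapi), clip(ch488), clip(ch555)),
           islet = islet_mask(islet),
           truth = truth,
           params = params),
      class = "synthetic_islet"
    )
  })
}

#' @export
print.synthetic_islet <- function(x, ...) {
  cat(sprintf(
    "<synthetic_islet> %d x %d px, %d nuclei (%d beta), islet %d px, true stained fraction %.3f\n",
    x$params$height, x$params$width, nrow(x$truth$nuclei),
    sum(x$truth$nuclei$class == "beta"), x$islet$area_px,
    x$truth$true_stained_fraction
  ))
  invisible(x)
}

#' Generate a synthetic two-group cohort of per-islet scores
#'
#' Emulates the feature layer of a scored cohort: each patient carries a
#' latent mean area score around their group mean, and each islet draws its
#' score around the patient mean. Group BMI and age distributions default to
#' the observed cohort characteristics (ND: BMI 26 +/- 3, age 66 +/- 14;
#' T2D: BMI 30 +/- 4, age 64 +/- 10). Scores are expressed on the `[0, 3]`
#' area-score scale (score = 3 x stained fraction).
#'
#' @param n_nd,n_t2d Patients per group (each at least 2).
#' @param islets_per_patient Scored islets per patient.
#' @param effect Group difference in mean area score (ND mean minus T2D
#'   mean), in score units.
#' @param noise Between-islet standard deviation of the score.
#' @param seed Integer seed.
#' @param baseline_score Mean ND area score.
#' @param between_patient_sd Standard deviation of patient-level means around
#'   their group mean.
#' @return A list of class `synthetic_cohort`: `features`, a tibble with one
#'   row per islet (`patient_id`, `group`, `age`, `bmi`, `islet`,
#'   `area_score`), and `truth`, the latent group and patient means.
#' @export
generate_cohort <- function(n_nd = 20, n_t2d = 20, islets_per_patient = 9,
                            effect = 0.8, noise = 0.3, seed = 1L,
                            baseline_score = 1.8, between_patient_sd = 0.1) {
  check_number(n_nd, "n_nd", lower = 2, integer = TRUE)
  check_number(n_t2d, "n_t2d", lower = 2, integer = TRUE)
  check_number(islets_per_patient, "islets_per_patient", lower = 1, integer = TRUE)
  check_number(effect, "effect")
  check_number(noise, "noise", lower = 0)
  check_number(baseline_score, "baseline_score", lower = 0, upper = 3)
  check_number(between_patient_sd, "between_patient_sd", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  if (baseline_score - effect < 0 || baseline_score - effect > 3) {
    stop_parameter("`effect` pushes the T2D mean score outside [0, 3] (stained fraction outside [0, 1])")
  }
  with_seed(seed, {
    pts <- tibble(
      patient_id = c(sprintf("SND%02d", seq_len(n_nd)),
                     sprintf("ST2D%02d", seq_len(n_t2d))),
      group = c(rep("ND", n_nd), rep("T2D", n_t2d))
    )
    pts$bmi <- ifelse(pts$group == "ND", rnorm(nrow(pts), 26, 3), rnorm(nrow(pts), 30, 4))
    pts$age <- ifelse(pts$group == "ND", rnorm(nrow(pts), 66, 14), rnorm(nrow(pts), 64, 10))
    group_mean <- ifelse(pts$group == "ND", baseline_score, baseline_score - effect)
    pts$latent_mean <- group_mean + rnorm(nrow(pts), 0, between_patient_sd)

    features <- tidyr::expand_grid(patient_id = pts$patient_id,
                                   islet = seq_len(islets_per_patient)) %>%
      left_join(pts, by = "patient_id") %>%
      mutate(area_score = pmin(pmax(rnorm(n(), .data$latent_mean, noise), 0), 3)) %>%
      select("patient_id", "group", "age", "bmi", "islet", "area_score")

    structure(
      list(features = features,
           truth = list(
             group_means = c(ND = baseline_score, T2D = baseline_score - effect),
             patients = pts
           )),
      class = "synthetic_cohort"
    )
  })
}
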