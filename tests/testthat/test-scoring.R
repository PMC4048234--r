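test_that("histogram k-means splits a two-point histogram at the midpoint", {
  x <- matrix(c(rep(0.1, 1000), rep(0.9, 500)), nrow = 30)
  sm <- separate_staining(x)
  expect_false(sm$degenerate)
  expect_equal(unname(sm$cluster_centers), c(0.1, 0.9), tolerance = 1 / 512)
  expect_equal(sm$threshold, 0.5, tolerance = 1 / 512)
  expect_equal(sum(sm$stained), 500L)
})

test_that("a symmetric two-Gaussian mixture is thresholded near its midpoint", {
  set.seed(21)
  v <- c(rnorm(10000, 0.2, 0.05), rnorm(10000, 0.8, 0.05))
  x <- matrix(pmin(pmax(v, 0), 1), nrow = 100)
  sm <- separate_staining(x, histogram_bins = 256L)
  expect_equal(sm$threshold, 0.5, tolerance = 1 / 256)
})

test_that("constant images are flagged degenerate with nothing stained", {
  sm <- separate_staining(matrix(0.5, 20, 20))
  expect_true(sm$degenerate)
  expect_false(any(sm$stained))
})

test_that("the k-means split equals the exhaustive optimal-threshold oracle", {
  for (seed in 1:10) {
    img <- random_bimodal_image(seed)
    sm <- separate_staining(img)
    expect_identical(sm$stained, oracle_threshold_mask(img),
                     label = sprintf("seed %d", seed))
  }
})

test_that("patch voting follows the strict-majority rule with ties unclassified", {
  h <- 40; w <- 40
  nuc <- manual_nuclei(
    tibble::tibble(row = c(10, 20, 30), col = c(10, 20, 30),
                   area_px = c(10L, 10L, 10L)),
    matrix(FALSE, h, w)
  )
  m488 <- matrix(FALSE, h, w)
  m555 <- matrix(FALSE, h, w)
  m488[6:13, 6:10] <- TRUE  # 40 px for nucleus 1
  m555[9:13, 9] <- TRUE     # 5 px for nucleus 1
  # nucleus 2 at (20, 20): 17 vs 17 inside the radius-6 patch -> tie
  m488[15:17, 17:21] <- TRUE; m488[18, 17:18] <- TRUE  # 17 px
  m555[22:24, 19:23] <- TRUE; m555[21, 22:23] <- TRUE  # 17 px
  # nucleus 3 at (30, 30): 0 vs 0 -> no evidence

  cls <- classify_cells(nuc, stain_map_from_mask(m488),
                        stain_map_from_mask(m555), patch_radius = 6)
  expect_equal(cls$label, c("beta", "unclassified", "unclassified"))
  expect_equal(cls$count488[1], 40L)
  expect_equal(cls$count555[1], 5L)
  expect_equal(cls$count488[2], cls$count555[2])
  expect_equal(cls$count488[3] + cls$count555[3], 0L)
  # conservation on every input
  expect_equal(sum(cls$label == "beta") + sum(cls$label == "alpha") +
                 sum(cls$label == "unclassified"), nuc$n)
})

test_that("area score is the stained non-nuclear fraction mapped to [0, 3]", {
  h <- 40; w <- 40
  im <- matrix(FALSE, h, w); im[1:25, 1:40] <- TRUE # 1000-px islet
  islet <- islet_mask(im)
  nm <- matrix(FALSE, h, w); nm[1:5, 1:40] <- TRUE # 200 nucleus px, all stained
  nuc <- manual_nuclei(tibble::tibble(row = 3, col = 20, area_px = 200L), nm)
  st <- matrix(FALSE, h, w)
  st[1:5, 1:40] <- TRUE    # the 200 nuclear pixels
  st[6:15, 1:40] <- TRUE   # 400 further stained non-nuclear px
  sc <- area_score(stain_map_from_mask(st), islet, nuc)
  expect_equal(sc$stained_fraction, 0.4)
  expect_equal(sc$area_score, 1.2)
  # alternative denominator excludes nuclei from the denominator too
  sc2 <- area_score(stain_map_from_mask(st), islet, nuc,
                    denominator = "islet_minus_nuclei")
  expect_equal(sc2$stained_fraction, 400 / 800)

  # bounds
  all_st <- stain_map_from_mask(im)
  none <- stain_map_from_mask(matrix(FALSE, h, w))
  empty_nuc <- manual_nuclei(tibble::tibble(row = numeric(), col = numeric(),
                                            area_px = integer()),
                             matrix(FALSE, h, w))
  expect_equal(area_score(all_st, islet, empty_nuc)$area_score, 3)
  expect_equal(area_score(none, islet, empty_nuc)$area_score, 0)
})

test_that("area score is monotone in stained pixels and blind outside the islet", {
  set.seed(5)
  h <- 30; w <- 30
  im <- matrix(FALSE, h, w); im[5:25, 5:25] <- TRUE
  islet <- islet_mask(im)
  empty_nuc <- manual_nuclei(tibble::tibble(row = numeric(), col = numeric(),
                                            area_px = integer()),
                             matrix(FALSE, h, w))
  st <- matrix(runif(h * w) < 0.3, h, w)
  base <- area_score(stain_map_from_mask(st), islet, empty_nuc)$area_score
  # add stained pixels inside the islet
  st2 <- st; st2[10:12, 10:12] <- TRUE
  expect_gte(area_score(stain_map_from_mask(st2), islet, empty_nuc)$area_score,
             base)
  # flip pixels outside the islet only: score unchanged
  st3 <- st; st3[1:4, ] <- !st3[1:4, ]
  expect_equal(area_score(stain_map_from_mask(st3), islet, empty_nuc)$area_score,
               base)
  # conservation: score = 3 x fraction by definition
  sc <- area_score(stain_map_from_mask(st), islet, empty_nuc)
  expect_identical(sc$area_score, 3 * sc$stained_fraction)
})

test_that("islet size and beta density handle physical units", {
  m <- matrix(FALSE, 10, 10); m[3:6, 4:7] <- TRUE
  islet <- islet_mask(m)
  expect_equal(islet_size(islet)$islet_size_px, 16L)
  expect_true(is.na(islet_size(islet)$islet_size_um2))
  expect_equal(islet_size(islet, pixel_size = 0.5)$islet_size_um2, 4)
  expect_error(islet_size(islet, pixel_size = -1),
               class = "isletscore_error_parameter")

  im <- matrix(FALSE, 40, 40); im[1:25, 1:40] <- TRUE # 1000 px
  big <- islet_mask(im)
  nuc <- manual_nuclei(
    tibble::tibble(row = seq(2, 20, 2), col = seq(2, 20, 2),
                   area_px = rep(5L, 10)),
    matrix(FALSE, 40, 40)
  )
  cls <- classify_cells(nuc, stain_map_from_mask(im),
                        stain_map_from_mask(matrix(FALSE, 40, 40)),
                        patch_radius = 2)
  expect_true(all(cls$label == "beta"))
  d <- beta_density(cls, big)
  expect_equal(d$n_beta, 10L)
  expect_equal(d$beta_density_per_1e4px, 100)
  expect_equal(beta_density(cls, big, pixel_size = 1)$beta_density_per_mm2, 10000)
  none <- classify_cells(nuc, stain_map_from_mask(matrix(FALSE, 40, 40)),
                         stain_map_from_mask(matrix(FALSE, 40, 40)),
                         patch_radius = 2)
  expect_equal(beta_density(none, big)$beta_density_per_1e4px, 0)
})

test_that("the manual-score surrogate quantises to 0.25 steps, half up", {
  expect_equal(manual_score_surrogate(3, 1.0), 3.0)
  expect_equal(manual_score_surrogate(0, 0.73), 0.0)
  expect_equal(manual_score_surrogate(2, 0.6), 1.25) # 1.2 -> 1.25
  expect_equal(manual_score_surrogate(1, 0.875), 1.0) # 0.875 rounds half-up
  expect_error(manual_score_surrogate(4, 0.5),
               class = "isletscore_error_parameter")
  expect_error(manual_score_surrogate(2, 1.5),
               class = "isletscore_error_parameter")
})

test_that("score_islet recovers synthetic islets and is deterministic", {
  syn <- generate_islet(small_params(seed = 17, noise_sd = 0,
                                     illumination_gradient = 0,
                                     target_stained_fraction = 0.3))
  a <- score_islet(syn$stack, syn$islet)
  b <- score_islet(syn$stack, syn$islet)
  expect_identical(a$features, b$features)
  expect_equal(a$features$area_score, 3 * syn$truth$true_stained_fraction,
               tolerance = 3 / syn$islet$area_px)
  # label conservation
  f <- a$features
  expect_equal(f$n_beta + f$n_alpha + f$n_unclassified, f$n_nuclei)

  # degenerate all-background islet scores zero with no beta cells
  flat <- channel_stack(matrix(0.2, 60, 60), matrix(0.2, 60, 60),
                        matrix(0.2, 60, 60))
  islet <- islet_mask(matrix(TRUE, 60, 60))
  z <- score_islet(flat, islet)
  expect_equal(z$features$area_score, 0)
  expect_equal(z$features$n_beta, 0L)
})
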