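# helper: render one 3D Gaussian on a constant background, no noise
planted_gaussian <- function(center, dim = c(15L, 41L, 41L), amp = 100,
                             sigma_xy = 1.5, sigma_z = 1.0, bg = 10) {
  a <- array(bg, dim)
  gz <- exp(-(seq_len(dim[1]) - center[1])^2 / (2 * sigma_z^2))
  gy <- exp(-(seq_len(dim[2]) - center[2])^2 / (2 * sigma_xy^2))
  gx <- exp(-(seq_len(dim[3]) - center[3])^2 / (2 * sigma_xy^2))
  a + amp * outer(outer(gz, gy), gx)
}

test_that("otsu_threshold separates a bimodal image", {
  set.seed(1)
  x <- c(rnorm(500, 10, 2), rnorm(500, 60, 2))
  thr <- otsu_threshold(x)
  # threshold separates the two classes perfectly
  expect_identical(x > thr, rep(c(FALSE, TRUE), each = 500))
  expect_gt(thr, 16); expect_lt(thr, 55)
  expect_equal(otsu_threshold(rep(3, 100)), Inf)
})

test_that("segmentation: blank field yields zero cells", {
  blank <- array(5, c(3, 40, 40))
  seg <- segment_cells(blank, blank)
  expect_equal(seg$n_cells, 0L)
  expect_true(all(seg$cells == 0L))
})

test_that("segmentation recovers well-separated planted disks exactly", {
  f <- simulate_smfish_stack(n_cells = 2L, dim = c(7L, 120L, 64L),
                             n_cyto = 0L, n_sites = 0L, noise_sd = 0,
                             seed = 5)
  seg <- segment_cells(f$nuclear, f$fish)
  expect_equal(seg$n_cells, 2L)
  # noiseless field: pixel-exact agreement with the planted masks
  # (labels may be permuted; compare as partitions)
  for (lab in 1:2) {
    planted <- f$truth$cells == lab
    got <- seg$cells == seg$cells[which(planted)[1]]
    expect_identical(got, planted)
  }
  # nuclei sit inside their cells
  inside <- seg$nuclei > 0L
  expect_true(all(seg$cells[inside] == seg$nuclei[inside]))
})

test_that("touching disks are split into two labels by seeded growth", {
  nuc <- array(0, c(3, 60, 100))
  fish <- array(0, c(3, 60, 100))
  yy <- matrix(seq_len(60), 60, 100)
  xx <- matrix(seq_len(100), 60, 100, byrow = TRUE)
  cellmask <- ((yy - 30)^2 + (xx - 35)^2 <= 18^2) |
    ((yy - 30)^2 + (xx - 66)^2 <= 18^2)   # overlapping disks
  nucmask1 <- (yy - 30)^2 + (xx - 35)^2 <= 7^2
  nucmask2 <- (yy - 30)^2 + (xx - 66)^2 <= 7^2
  for (z in 1:3) {
    fish[z, , ][cellmask] <- 50
    nuc[z, , ][nucmask1 | nucmask2] <- 100
  }
  seg <- segment_cells(nuc, fish)
  expect_equal(seg$n_cells, 2L)
  # split is near the equidistant midline between the two nuclei
  left <- seg$cells[30, 45]; right <- seg$cells[30, 56]
  expect_true(left != right && left > 0L && right > 0L)
})

test_that("detect_spots on empty and single-spot stacks", {
  expect_equal(nrow(detect_spots(array(0, c(5, 20, 20)))), 0L)

  truth <- c(8.3, 20.6, 17.2)
  a <- planted_gaussian(truth)
  sp <- detect_spots(a)
  expect_equal(nrow(sp), 1L)
  expect_lt(max(abs(c(sp$z, sp$y, sp$x) - truth)), 0.1)
  # integrated intensity close to amplitude * Gaussian volume
  expect_equal(sp$intensity, 100 * (2 * pi)^1.5 * 1.5^2 * 1.0,
               tolerance = 0.1)
})

test_that("detection is intensity-scale equivariant", {
  truth <- c(7.5, 15.5, 25.5)
  a <- planted_gaussian(truth, dim = c(15L, 31L, 41L))
  s1 <- detect_spots(a)
  s2 <- detect_spots(a * 7.3)
  expect_equal(s1[, c("z", "y", "x")], s2[, c("z", "y", "x")],
               tolerance = 1e-6)
  expect_equal(s2$intensity, 7.3 * s1$intensity, tolerance = 1e-6)
})

test_that("quantify_cells assigns by mask and drops zero-spot cells", {
  seg <- list(cells = matrix(0L, 30, 30), nuclei = matrix(0L, 30, 30),
              n_cells = 2L)
  seg$cells[1:15, ] <- 1L
  seg$cells[16:30, ] <- 2L
  seg$nuclei[5:10, 5:10] <- 1L
  class(seg) <- "CellSegmentation"
  spots <- data.frame(z = 1, y = c(6, 12, 40), x = c(6, 20, 12),
                      intensity = c(10, 20, 30))
  q <- quantify_cells(spots, seg)
  expect_equal(q$tally[["assigned"]], 2L)
  expect_equal(q$tally[["unassigned_spots"]], 1L)  # y=40 outside the field
  expect_equal(q$tally[["zero_spot_cells"]], 1L)   # cell 2 has no spot
  expect_equal(q$cells$cell, 1L)
  expect_equal(q$cells$n_nuclear, 1L)
  expect_equal(q$cells$n_cytoplasmic, 1L)
  # point-in-mask brute force over the assigned spots
  for (i in seq_len(nrow(q$spots))) {
    expect_equal(q$spots$cell[i],
                 seg$cells[round(q$spots$y[i]), round(q$spots$x[i])])
  }
})

test_that("spot count conservation: assigned + unassigned == detected", {
  f <- simulate_smfish_stack(n_cells = 4L, dim = c(9L, 120L, 120L),
                             n_cyto = 8L, seed = 23)
  seg <- segment_cells(f$nuclear, f$fish)
  sp <- detect_spots(f$fish)
  q <- quantify_cells(sp, seg)
  expect_equal(q$tally[["assigned"]] + q$tally[["unassigned_spots"]],
               nrow(sp))
})

test_that("transcription-site classification thresholds at 2.5 RNAs inclusive", {
  spots <- data.frame(
    z = 1, y = 1, x = 1,
    intensity = c(10, 10, 10, 25, 10 * 2.5, 9),
    cell = c(1L, 1L, 1L, 1L, 2L, 2L),
    compartment = c("cytoplasmic", "cytoplasmic", "cytoplasmic",
                    "nuclear", "nuclear", "cytoplasmic"))
  q <- list(spots = spots,
            cells = data.frame(cell = 1:2, n_spots = c(4L, 2L),
                               n_nuclear = c(1L, 1L),
                               n_cytoplasmic = c(3L, 1L)))
  calls <- classify_transcription_sites(q, probe = "MS2")
  # normalizer = median(10, 10, 10, 9) = 10
  expect_equal(attr(calls, "normalizer"), 10)
  expect_equal(calls$rna_equivalents[calls$cell == 1], 2.5)
  expect_true(calls$active[calls$cell == 1])    # boundary inclusive
  expect_true(calls$active[calls$cell == 2])
  calls1 <- classify_transcription_sites(
    list(spots = transform(spots, intensity = replace(intensity, 4, 10)),
         cells = q$cells), probe = "MS2")
  expect_false(calls1$active[calls1$cell == 1])  # 1.0x median: inactive

  # Sox2 probes: two calls per cell, missing sites inactive at zero
  calls2 <- classify_transcription_sites(q, probe = "Sox2")
  expect_equal(nrow(calls2), 4L)
  expect_equal(calls2$rna_equivalents[calls2$cell == 1 & calls2$rank == 2], 0)

  # no cytoplasmic spot anywhere: no normalizer
  qn <- list(spots = spots[spots$compartment == "nuclear", ],
             cells = q$cells)
  expect_error(classify_transcription_sites(qn), "no normalizer")
})

test_that("median cytoplasmic spot has RNA-equivalent 1 on synthetic data", {
  f <- simulate_smfish_stack(n_cells = 4L, dim = c(11L, 120L, 120L),
                             n_cyto = 12L, seed = 41)
  seg <- segment_cells(f$nuclear, f$fish)
  q <- quantify_cells(detect_spots(f$fish), seg)
  calls <- classify_transcription_sites(q, probe = "Sox2")
  cyto <- q$spots$intensity[q$spots$compartment == "cytoplasmic"]
  expect_equal(median(cyto) / attr(calls, "normalizer"), 1)
})
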