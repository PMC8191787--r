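test_that("identical rounds register with zero shift", {
  vol <- render_spots(c(8, 32, 32), rbind(c(4, 10, 10), c(5, 22, 18)))
  st <- lapply(1:2, function(r)
    round_stack(array(rep(vol, 4), c(dim(vol), 4)), r))
  reg <- register_rounds(st)
  expect_equal(unname(reg$shifts[2, ]), c(0L, 0L, 0L))
  expect_false(any(reg$low_confidence))
})

test_that("a planted integer translation is recovered exactly", {
  vol <- render_spots(c(12, 40, 40), rbind(c(6, 12, 14), c(7, 30, 26)))
  shifted <- splintseq:::.translate3(vol, c(3L, 2L, 1L))
  mk <- function(v, r) round_stack(array(rep(v, 4), c(dim(v), 4)), r)
  reg <- register_rounds(list(mk(vol, 1), mk(shifted, 2)))
  expect_equal(unname(reg$shifts[2, ]), c(3L, 2L, 1L))
  ## the registered volume is translated back onto the reference
  back <- splintseq:::.channel_sum(reg$stacks[[2]]) / 4
  inner <- vol[4:9, 10:35, 10:35]
  expect_equal(back[4:9, 10:35, 10:35], inner, tolerance = 1e-8)
})

test_that("pure-noise rounds are flagged low confidence within the shift bound", {
  set.seed(3)
  mk <- function(r) round_stack(array(abs(rnorm(8 * 24 * 24 * 4)),
                                      c(8, 24, 24, 4)), r)
  reg <- register_rounds(list(mk(1), mk(2)), max_shift = 5)
  expect_true(all(abs(reg$shifts) <= 5))
  expect_true(reg$low_confidence[2])
})

test_that("background subtraction removes flats and keeps punctate peaks", {
  flat <- array(7, c(4, 16, 16))
  expect_true(all(subtract_background(flat) == 0))
  spike <- array(0, c(3, 11, 11))
  spike[2, 6, 6] <- 50
  out <- subtract_background(spike)
  expect_equal(out[2, 6, 6], 50)   # opening removes an isolated peak fully
  set.seed(4)
  noisy <- array(abs(rnorm(5 * 20 * 20 * 2)), c(5, 20, 20, 2))
  expect_true(all(subtract_background(noisy) >= 0))
})

test_that("composites sum rounds and channels commutatively", {
  set.seed(5)
  mk <- function(v, r) round_stack(v, r)
  v1 <- array(runif(4 * 10 * 10 * 4), c(4, 10, 10, 4))
  v2 <- array(runif(4 * 10 * 10 * 4), c(4, 10, 10, 4))
  zero <- array(0, c(4, 10, 10, 4))
  c12 <- make_composite(list(mk(v1, 1), mk(v2, 2)))
  c21 <- make_composite(list(mk(v2, 1), mk(v1, 2)))
  expect_equal(c12, c21)
  ## R identical rounds of value v give R * channel-sum
  cR <- make_composite(list(mk(v1, 1), mk(v1, 2), mk(v1, 3)))
  expect_equal(cR, 3 * splintseq:::.channel_sum(mk(v1, 1)))
  ## all-zero round contributes nothing
  cz <- make_composite(list(mk(v1, 1), mk(zero, 2)))
  expect_equal(cz, splintseq:::.channel_sum(mk(v1, 1)))
  expect_error(make_composite(list(mk(v1, 1),
                                   mk(array(0, c(3, 10, 10, 4)), 2))))
})

test_that("z interpolation matches the reference monotone cubic per column", {
  set.seed(6)
  y <- matrix(rnorm(12 * 5), 12, 5)
  xi <- seq(1, 12, by = 0.5)
  mine <- splintseq:::.pchip_columns(y, xi)
  for (col in 1:5) {
    ref <- pracma::pchip(1:12, y[, col], xi)
    expect_equal(mine[, col], ref, tolerance = 1e-8)
  }
})

test_that("well-separated spots segment into the right number of amplicons", {
  comp <- render_spots(c(10, 48, 48), rbind(c(5, 12, 12), c(5, 36, 34)))
  seg <- segment_amplicons(comp, z_interp_factor = 2)
  expect_equal(nrow(seg$amplicons), 2L)
  ## labels partition the foreground: disjoint by construction, and the
  ## voxel counts add up
  expect_equal(sum(seg$labels > 0), sum(seg$amplicons$n_voxels))
  expect_equal(sort(unique(as.vector(seg$labels))), 0:2)
  ## centroids near the planted positions
  got <- seg$amplicons[order(seg$amplicons$y), ]
  expect_lt(abs(got$y[1] - 12), 1.5)
  expect_lt(abs(got$x[2] - 34), 1.5)
})

test_that("touching spots with two maxima are split by the seeded watershed", {
  comp <- render_spots(c(6, 32, 32), rbind(c(3, 14, 12), c(3, 14, 19)),
                       sigma = 1.8)
  seg <- segment_amplicons(comp, z_interp_factor = 2, dog_sigmas = c(1, 3))
  expect_equal(nrow(seg$amplicons), 2L)
})

test_that("an empty volume yields no labels, with a warning", {
  expect_warning(seg <- segment_amplicons(array(0, c(6, 20, 20)),
                                          z_interp_factor = 2))
  expect_equal(nrow(seg$amplicons), 0L)
  expect_true(all(seg$labels == 0L))
})

test_that("quantile normalisation equalises channel distributions", {
  set.seed(7)
  v <- array(0, c(4, 16, 16, 4))
  v[, , , 1] <- rexp(1024, 1)
  v[, , , 2] <- runif(1024, 0, 10)
  v[, , , 3] <- rnorm(1024, 5, 1)
  v[, , , 4] <- rexp(1024, 0.1)
  ns <- quantile_normalize_round(round_stack(v, 1))
  sorted <- apply(matrix(ns$volume, ncol = 4), 2, sort)
  for (ch in 2:4) expect_equal(sorted[, ch], sorted[, 1], tolerance = 1e-10)
})

test_that("basecalling picks the brightest channel and truncates top-k", {
  v <- array(0, c(4, 12, 12, 4))
  vox <- which(render_spots(c(4, 12, 12), rbind(c(2, 6, 6))) > 1)
  v[vox + 1 * prod(c(4, 12, 12))] <- 100   # bright in channel 2 only
  st <- round_stack(v, 1)
  bc <- basecall_round(vox, st, top_k = 30)
  expect_equal(bc$base, "C")               # channel 2 maps to C
  expect_false(bc$tie)
  ## 10 voxels with top_k = 30: means use all 10 values
  vox10 <- vox[1:10]
  bc10 <- basecall_round(vox10, st, top_k = 30)
  expect_equal(bc10$intensities[2], mean(v[vox10 + prod(c(4, 12, 12))]))
  expect_error(basecall_round(integer(0), st))
  ## all-zero voxels tie across channels and are flagged
  ztie <- basecall_round(vox, round_stack(array(0, c(4, 12, 12, 4)), 1))
  expect_true(ztie$tie)
  expect_equal(ztie$base, "A")             # first channel in config order
})

test_that("basecalling is invariant to monotone rescaling of one channel", {
  set.seed(8)
  truth <- make_field(n_cells = 2, amplicons_per_cell = 10,
                      field_shape = c(8, 96, 96),
                      code = assign_barcodes(generate_code(4, 1, n_needed = 6),
                                             sprintf("g%d", 1:6)),
                      scatter_sd = 12, nucleus_radius = 8, seed = 8)
  rend <- render_rounds(truth, noise_sd = 2, seed = 8)
  st <- subtract_background_rounds(rend$stacks)
  comp <- make_composite(st)
  seg <- segment_amplicons(comp, z_interp_factor = 2)
  base_a <- basecall_all(seg$labels, st, truth$code)
  ## square intensities of channel 3 (monotone) in every round
  st2 <- lapply(st, function(s) {
    s$volume[, , , 3] <- s$volume[, , , 3]^2
    s
  })
  base_b <- basecall_all(seg$labels, st2, truth$code)
  expect_equal(base_a$barcode, base_b$barcode)
})

test_that("round count must match the barcode length", {
  code <- assign_barcodes(generate_code(8, 3, n_needed = 4),
                          sprintf("g%d", 1:4))
  st <- list(round_stack(array(0, c(2, 8, 8, 4)), 1))
  labels <- array(0L, c(2, 8, 8))
  expect_error(basecall_all(labels, st, code), "round count")
})
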