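test_that("disjoint disks segment into the right number of nuclei", {
  grid <- expand.grid(x = c(30, 80, 130, 180), y = c(30, 80, 130, 180, 230))
  centres <- cbind(x = grid$x, y = grid$y)
  img <- disk_image(260, 210, centres, radius = 10)
  seg <- segment_nuclei(img, tophat_size = 31)
  expect_equal(nrow(seg$cells), 20L)
  ## centroids match the planted centres
  for (k in seq_len(nrow(centres))) {
    d <- sqrt((seg$cells$x - centres[k, 1])^2 +
                (seg$cells$y - centres[k, 2])^2)
    expect_lt(min(d), 2)
  }
})

test_that("overlapping disks with distinct peaks are split by watershed", {
  img <- disk_image(80, 80, cbind(x = c(32, 48), y = c(40, 40)), radius = 10)
  seg <- segment_nuclei(img, tophat_size = 41)
  expect_equal(nrow(seg$cells), 2L)
})

test_that("a blank image yields no nuclei, with a warning", {
  expect_warning(seg <- segment_nuclei(matrix(0, 40, 40)))
  expect_equal(nrow(seg$cells), 0L)
})

test_that("perinuclear zones contain their nuclei and stay disjoint", {
  img <- disk_image(100, 100, cbind(x = c(35, 62), y = c(50, 50)),
                    radius = 9)
  seg <- segment_nuclei(img, tophat_size = 41)
  z0 <- perinuclear_zones(seg$labels, n_dilations = 0)
  expect_identical(z0, seg$labels)       # zero dilations: zone = nucleus
  z <- perinuclear_zones(seg$labels, n_dilations = 6)
  ## nucleus pixels keep their label inside the zone
  nz <- seg$labels > 0
  expect_true(all(z[nz] == seg$labels[nz]))
  ## zones grew strictly
  expect_gt(sum(z > 0), sum(seg$labels > 0))
  ## adjacent zones share no pixel (single label map is disjoint by
  ## construction) and both cells gained area
  expect_equal(sort(unique(as.vector(z))), 0:2)
  expect_gt(sum(z == 1), sum(seg$labels == 1))
  expect_gt(sum(z == 2), sum(seg$labels == 2))
})

test_that("affinity propagation recovers planted point clusters", {
  set.seed(2)
  pts <- rbind(cbind(rnorm(15, 0, 0.5), rnorm(15, 0, 0.5)),
               cbind(rnorm(15, 6, 0.5), rnorm(15, 0, 0.5)),
               cbind(rnorm(15, 3, 0.5), rnorm(15, 6, 0.5)))
  S <- -as.matrix(dist(pts))^2
  fit <- affinity_propagation_k(S, k = 3)
  expect_equal(fit$k_achieved, 3L)
  cl <- as.integer(factor(fit$clusters))
  truth <- rep(1:3, each = 15)
  ## perfect agreement up to relabelling
  expect_equal(length(unique(paste(cl, truth))), 3L)
})

test_that("amplicons inside a zone are assigned to that cell directly", {
  img <- disk_image(100, 100, cbind(x = c(30, 70), y = c(50, 50)),
                    radius = 8)
  seg <- segment_nuclei(img, tophat_size = 41)
  zones <- perinuclear_zones(seg$labels, n_dilations = 5)
  ## amplicon right on nucleus 2's centre
  a <- data.frame(x = seg$cells$x[2], y = seg$cells$y[2])
  expect_equal(assign_amplicons(a, seg$cells, zones),
               seg$cells$cell_id[2])
})

test_that("with a single nucleus all amplicons go to it", {
  img <- disk_image(60, 60, cbind(x = 30, y = 30), radius = 8)
  seg <- segment_nuclei(img, tophat_size = 41)
  zones <- perinuclear_zones(seg$labels, n_dilations = 3)
  a <- data.frame(x = c(5, 55, 30), y = c(5, 55, 30))
  expect_equal(assign_amplicons(a, seg$cells, zones),
               rep(seg$cells$cell_id[1], 3))
})

test_that("assignment on well-separated synthetic cells is at least 95% accurate", {
  code <- assign_barcodes(generate_code(4, 1, n_needed = 20),
                          sprintf("g%02d", 1:20))
  tr <- make_field(n_cells = 10, amplicons_per_cell = 40,
                   field_shape = c(8, 512, 512), code = code,
                   nucleus_radius = 15, scatter_sd = 18, min_amp_sep = 4,
                   seed = 3)
  dapi <- disk_image(512, 512, cbind(x = tr$nuclei$x, y = tr$nuclei$y),
                     radius = 15)
  nuc <- segment_nuclei(dapi, tophat_size = 41)
  expect_equal(nrow(nuc$cells), 10L)
  zones <- perinuclear_zones(nuc$labels, n_dilations = 10)
  a <- tr$amplicons
  cell_of <- assign_amplicons(data.frame(x = a$x, y = a$y), nuc$cells,
                              zones)
  seg_of_true <- vapply(seq_len(nrow(tr$nuclei)), function(k)
    which.min((nuc$cells$x - tr$nuclei$x[k])^2 +
                (nuc$cells$y - tr$nuclei$y[k])^2), integer(1))
  acc <- mean(cell_of == nuc$cells$cell_id[seg_of_true][a$cell])
  expect_gte(acc, 0.95)
})

test_that("count matrix counts decoded amplicons and conserves totals", {
  cell_of <- c(1L, 1L, 1L, 2L, 2L, NA, 1L)
  dec <- data.frame(
    status = c("perfect", "perfect", "corrected", "perfect",
               "discarded_ambiguous", "perfect", "discarded_distance"),
    gene = c("g1", "g1", "g1", "g2", "g2", "g1", NA))
  m <- build_count_matrix(cell_of, dec)
  expect_equal(m["1", "g1"], 3L)
  expect_equal(m["2", "g2"], 1L)
  ## discarded and unassigned amplicons contribute nothing
  expect_equal(sum(m), 4L)
})

test_that("matrix filtering honours both detection boundaries and is idempotent", {
  ## 20 cells x 6 genes; gene "fail" detected in exactly 4 cells,
  ## gene "pass" in exactly 5
  m <- matrix(1L, 20, 6, dimnames = list(paste0("c", 1:20),
                                         c(paste0("g", 1:4), "pass", "fail")))
  m[, "fail"] <- 0L; m[1:4, "fail"] <- 1L
  m[, "pass"] <- 0L; m[1:5, "pass"] <- 1L
  f <- filter_matrix(m, expression_threshold = 1,
                     gene_det_in_min_cells = 5,
                     min_det_genes_per_cell = 2)
  expect_true("pass" %in% colnames(f))
  expect_false("fail" %in% colnames(f))
  ## cell boundary: 14 detected genes dropped, 15 kept
  m2 <- matrix(0L, 6, 20, dimnames = list(paste0("c", 1:6),
                                          paste0("g", 1:20)))
  m2[1:5, ] <- 1L              # five dense cells keep all genes detectable
  m2[6, 1:14] <- 1L            # boundary cell: 14 detected genes
  f2 <- filter_matrix(m2, 1, 5, 15)
  expect_false("c6" %in% rownames(f2))
  m2[6, 15] <- 1L              # now 15 genes
  f3 <- filter_matrix(m2, 1, 5, 15)
  expect_true("c6" %in% rownames(f3))
  ## identity on an already-passing matrix, and idempotence
  expect_equal(filter_matrix(f3, 1, 5, 15), f3)
})
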