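test_that("binarize is inclusive at the threshold and monotone", {
  st <- image_stack(array(0L, dim = c(3, 3, 1)), c(1, 1, 1), bit_depth = 8)
  expect_true(all(binarize(st, 0)))
  st2 <- image_stack(array(100L, dim = c(2, 2, 1)), c(1, 1, 1),
                     bit_depth = 8)
  expect_false(any(binarize(st2, 99)))
  st3 <- image_stack(array(c(50L, 150L, 250L), dim = c(3, 1, 1)), c(1, 1, 1))
  expect_equal(as.vector(binarize(st3, 150)), c(TRUE, TRUE, FALSE))

  # monotonicity: B_t subset of B_t' for t <= t'
  set.seed(3)
  st4 <- image_stack(array(sample(0:255, 200, TRUE), dim = c(10, 10, 2)),
                     c(1, 1, 1), bit_depth = 8)
  for (t in c(10, 80, 200))
    expect_true(all(binarize(st4, t) <= binarize(st4, t + 30)))
})

test_that("min_projection takes the per-pixel minimum over a central slab", {
  one <- image_stack(array(7L, dim = c(4, 4, 1)), c(1, 1, 1), bit_depth = 8)
  expect_equal(min_projection(one, 30), matrix(7L, 4, 4))

  two <- array(10L, dim = c(3, 3, 2)); two[, , 2] <- 20L
  st <- image_stack(two, c(1, 1, 5), bit_depth = 8)
  expect_equal(min_projection(st, 30), matrix(10L, 3, 3))

  # brute-force per-pixel min over the central slab
  set.seed(4)
  a <- array(sample(0:255, 6 * 6 * 10, TRUE), dim = c(6, 6, 10))
  st2 <- image_stack(a, c(1, 1, 1), bit_depth = 8)
  M <- min_projection(st2, 4)   # 4 central slices: 4..7
  ref <- apply(a[, , 4:7], c(1, 2), min)
  expect_equal(M, ref)
  # slab thinner than one z-step: single central slice
  expect_equal(min_projection(st2, 0.5), a[, , 5])
})

test_that("count_objects filters by physical area and matches flood fill", {
  expect_equal(count_objects(matrix(FALSE, 8, 8), 16, 1), 0L)
  # three disks of 25 um^2 at 1 um^2 pixels
  m <- matrix(FALSE, 30, 10)
  for (cx in c(4, 14, 24)) m[cx + (-2:2), 3:7] <- TRUE
  expect_equal(count_objects(m, 16, 1), 3L)
  # 10 um^2 blob fails the floor, 50 um^2 passes
  m2 <- matrix(FALSE, 30, 12)
  m2[2:6, 2:3] <- TRUE    # 10 px
  m2[15:24, 5:9] <- TRUE  # 50 px
  expect_equal(count_objects(m2, 16, 1), 1L)
  expect_equal(count_objects(m2, 16, 1), bf_count_objects(m2, 16, 1))
  # randomized agreement with the flood-fill oracle
  set.seed(9)
  for (i in 1:5) {
    r <- matrix(runif(400) < 0.35, 20, 20)
    expect_equal(count_objects(r, 3, 1), bf_count_objects(r, 3, 1))
  }
})

test_that("multilevel Otsu separates modes and matches exhaustive search", {
  img <- c(rep(50L, 40), rep(200L, 60))
  th <- multilevel_otsu(img, 1)
  expect_true(th >= 50 && th < 200)

  img4 <- rep(c(10L, 80L, 160L, 240L), times = c(30, 25, 20, 25))
  th3 <- multilevel_otsu(img4, 3)
  expect_true(all(diff(th3) > 0))
  expect_true(th3[1] >= 10 && th3[1] < 80)
  expect_true(th3[2] >= 80 && th3[2] < 160)
  expect_true(th3[3] >= 160 && th3[3] < 240)

  # exhaustive-search oracle agreement, k = 1..3
  set.seed(21)
  for (i in 1:20) {
    vals <- sort(sample(0:255, sample(6:10, 1)))
    img <- rep(vals, times = sample(1:40, length(vals), TRUE))
    for (k in 1:3)
      expect_equal(multilevel_otsu(img, k), bf_otsu(img, k))
  }

  expect_error(multilevel_otsu(rep(7L, 10), 1), "constant")
  expect_warning(multilevel_otsu(c(1L, 2L, 3L), 5), "reduced")
})

test_that("criterion is the normalized count difference with masking", {
  expect_equal(criterion(c(10, 10)), 0)
  expect_equal(criterion(c(10, 30)), 0.5)
  expect_equal(criterion(c(30, 10)), -0.5)
  expect_equal(criterion(c(0, 0, 4)), c(NA, 1))
  expect_error(criterion(c(-1, 2)), "non-negative")
  # sign symmetry on random sequences
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:30, 6, TRUE)
    expect_equal(criterion(n), -criterion(rev(n))[5:1])
  }
})

test_that("soma threshold sits at the minimum growth transition", {
  th <- c(10, 20, 30, 40, 50, 60)
  cr <- c(0.8, 0.1, 0.6, -0.3, -0.5)
  res <- find_soma_threshold(th, cr)
  expect_equal(res$index, 3L)        # transition 2 -> upper threshold t_3
  expect_equal(res$threshold, 30)

  # tie: positions 2 and 3 both at 0.1; forward differences 0.0 and 0.4,
  # so the first tied position wins
  cr2 <- c(0.3, 0.1, 0.1, 0.5, -0.2)
  res2 <- find_soma_threshold(th, cr2)
  expect_equal(res2$index, 3L)

  # leading undefined entries are skipped, not fatal
  cr3 <- c(NA, 0.5, 0.2, 0.9, -1)
  expect_equal(find_soma_threshold(th, cr3)$index, 4L)

  expect_error(find_soma_threshold(th, c(-0.2, 0.5, 0.1, 0.2, 0.3)),
               "no soma level")
})

test_that("background threshold maximizes the raw-intensity object count", {
  # four squares; the fourth (152) appears only above 151, and a 190-bridge
  # merges two squares at the last Otsu level, so the raw-intensity count
  # peaks strictly inside the level set, 2 above t_max
  img <- matrix(240L, 40, 40)
  img[2:11, 2:11] <- 60L
  img[20:29, 2:11] <- 100L
  img[2:11, 20:29] <- 150L
  img[20:29, 20:29] <- 152L
  img[12:19, 24] <- 190L
  th <- c(60, 100, 150, 200)
  counts <- vapply(th, function(t) count_objects(img <= t, 16, 1), 0L)
  expect_equal(counts, c(1L, 2L, 3L, 3L))
  bg <- find_background_threshold(th, counts, img, 16, 1)
  # exhaustive oracle over the full intensity range
  allc <- vapply(min(img):max(img),
                 function(t) count_objects(img <= t, 16, 1), 0L)
  expect_equal(bg$count, max(allc))
  expect_equal(bg$threshold, 152)

  # flat neighborhood: t_b = t_max
  img2 <- matrix(240L, 20, 20); img2[3:12, 3:12] <- 50L
  th2 <- c(50, 120, 200)
  c2 <- vapply(th2, function(t) count_objects(img2 <= t, 16, 1), 0L)
  bg2 <- find_background_threshold(th2, c2, img2, 16, 1)
  expect_equal(bg2$threshold, th2[which.max(c2)])
})

test_that("label_somas keeps large components with centroids in bounds", {
  a <- array(200L, dim = c(40, 40, 12))
  st0 <- image_stack(a, c(1, 1, 1), bit_depth = 8)
  # one solid ball: centroid at its centre
  v <- microgliar:::.paint_ball(a, c(1, 1, 1), c(12, 12, 6), 4, 30L)
  st <- image_stack(v, c(1, 1, 1), bit_depth = 8)
  lab <- label_somas(st, 100)
  expect_equal(nrow(lab$table), 1L)
  expect_true(all(abs(lab$table[1, c("cx", "cy", "cz")] - c(13, 13, 7)) <= 1))

  # two separated balls -> two labels; sub-floor speck ignored
  v2 <- microgliar:::.paint_ball(v, c(1, 1, 1), c(30, 30, 6), 4, 30L)
  v2 <- microgliar:::.paint_ball(v2, c(1, 1, 1), c(30, 10, 6), 1, 30L)
  st2 <- image_stack(v2, c(1, 1, 1), bit_depth = 8)
  lab2 <- label_somas(st2, 100)
  expect_equal(nrow(lab2$table), 2L)
  expect_error(label_somas(st0, 100), "no soma")
})
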