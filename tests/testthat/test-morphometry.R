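test_that("segment volume reduces to cylinder and cone closed forms", {
  r <- c(0.5, 1, 2.5); h <- c(1, 3, 10)
  for (i in seq_along(r)) {
    expect_equal(segment_volume(r[i], r[i], h[i]), pi * r[i]^2 * h[i])
    expect_equal(segment_volume(0, r[i], h[i]), pi * r[i]^2 * h[i] / 3)
  }
  expect_equal(segment_volume(1, 2, 3), 7 * pi)
  expect_equal(segment_area(1, 3, 2), 8)
  expect_equal(segment_area(2, 2, 5), 2 * 2 * 5)
  expect_equal(segment_area(1, 2, 0), 0)
  expect_error(segment_volume(-1, 1, 1), "negative")
  expect_error(segment_area(1, -2, 1), "negative")
  # monotone in radii
  expect_gt(segment_volume(1.2, 2, 3), segment_volume(1, 2, 3))
})

test_that("radii come from spur records, then parent/child interpolation", {
  mk <- function(parents, spur = data.frame(node = integer(),
                                            length = numeric()),
                 soma_size = 4 / 3 * pi * 27) {
    n <- length(parents)
    cell_tree(data.frame(id = 1:n, parent = parents,
                         type = c(1L, rep(3L, n - 1)),
                         x = seq(0, by = 4, length.out = n), y = 0, z = 0,
                         radius = NA_real_),
              spur = spur, soma_size = soma_size)
  }
  # category 1: spur lengths become radii
  tr <- mk(c(NA, 1L, 2L), spur = data.frame(node = c(2L, 3L),
                                            length = c(2, 4)))
  r <- estimate_radii(tr)$nodes$radius
  expect_equal(r[2:3], c(2, 4))
  expect_equal(r[1], 3)                     # equivalent-sphere soma radius

  # interpolation: A(2) - X(unset) - B(4) -> X = 3
  tr2 <- mk(c(NA, 1L, 2L, 3L), spur = data.frame(node = c(2L, 4L),
                                                 length = c(2, 4)))
  expect_equal(estimate_radii(tr2)$nodes$radius[3], 3)

  # inheritance: no measured descendant after A(2)
  tr3 <- mk(c(NA, 1L, 2L, 3L, 4L), spur = data.frame(node = 2L,
                                                     length = 2))
  expect_equal(estimate_radii(tr3)$nodes$radius[3:5], rep(2, 3))

  # branch starting point without own spur takes the child's radius
  tr4 <- mk(c(NA, 1L, 2L, 3L), spur = data.frame(node = 3L, length = 1.5))
  expect_equal(estimate_radii(tr4)$nodes$radius[2], 1.5)

  # no spur at all: documented default below the root
  tr5 <- mk(c(NA, 1L, 2L))
  expect_equal(estimate_radii(tr5)$nodes$radius[2:3], c(0.5, 0.5))
  expect_true(all(estimate_radii(tr5)$nodes$radius > 0))
})

test_that("quantify extracts NPB, NBP, lengths and sizes", {
  # root with 3 children, no bifurcations
  star <- cell_tree(data.frame(
    id = 1:7, parent = c(NA, 1L, 1L, 1L, 2L, 3L, 4L),
    type = c(1L, rep(3L, 6)),
    x = c(0, 2, -2, 0, 8, -8, 0), y = c(0, 0, 0, 2, 0, 0, 8), z = 0,
    radius = 1), soma_size = 100)
  q <- quantify(star, dims = 3)
  expect_equal(q$n_primary, 3L)
  expect_equal(q$n_branch_points, 0L)
  expect_equal(q$branch_length_um, 6 + 6 + 6)   # root-child segments excluded
  expect_equal(q$soma_size, 100)
  expect_equal(q$cell_size, 100 + 3 * pi * 1^2 * 6)

  # single Y branch: one branch point
  y <- cell_tree(data.frame(
    id = 1:5, parent = c(NA, 1L, 2L, 3L, 3L), type = c(1L, rep(3L, 4)),
    x = c(0, 2, 8, 12, 12), y = c(0, 0, 0, 3, -3), z = 0, radius = 1),
    soma_size = 50)
  expect_equal(quantify(y, dims = 3)$n_branch_points, 1L)

  # 2D path uses areas
  q2 <- quantify(star, dims = 2)
  expect_equal(q2$cell_size, 100 + 3 * segment_area(1, 1, 6))

  # radii must be set first
  un <- star; un$nodes$radius <- NA_real_
  expect_error(quantify(un, dims = 3), "radii")
})

test_that("report appends the per-cell mean row", {
  r1 <- data.frame(cell_id = 1L, n_primary = 2L, n_branch_points = 1L,
                   branch_length_um = 10, soma_size = 100, cell_size = 150)
  r2 <- r1; r2$cell_id <- 2L; r2$n_primary <- 4L
  out <- report(list(r1, r2))
  expect_equal(nrow(out), 3L)
  expect_equal(out$cell_id[3], "mean")
  expect_equal(out$n_primary[3], 3)
  one <- report(list(r1))
  expect_equal(one$n_primary[2], r1$n_primary)
})

test_that("cylinder phantom recovers soma size exactly and length closely", {
  ph <- generate_phantom(
    phantom_spec(n_cells = 1, n_primaries = c(1L, 1L),
                 branch_length_um = c(30, 30), bifurcation_per_um = 0,
                 tortuosity = 0, radius_taper_um = c(1.2, 1.2),
                 soma_radius_um = c(5, 5), noise_sigma = 0), seed = 4)
  res <- run_pipeline(ph$stack, pipeline_config(), write = FALSE)
  q <- res$quant[res$quant$cell_id != "mean", ]
  # the soma component at t_s is the nominal ball
  expect_equal(q$soma_size, ph$truth_quant$soma_size, tolerance = 0.02)
  # skeleton zigzag inflates the traced path by ~10-15% at this sampling
  expect_lt(abs(q$branch_length_um - 30) / 30, 0.20)
  # radii from pruned spurs overestimate the cross-section by the zigzag of
  # the spur path; the estimate stays within a factor two of the truth
  truth <- ph$truth_quant$soma_size + pi * 1.2^2 * 30
  expect_lt(q$cell_size / truth, 2)
  expect_gt(q$cell_size / truth, 0.75)
})
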