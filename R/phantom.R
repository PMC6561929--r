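#' Phantom specification
#'
#' Parameters of the synthetic microglia generator. A phantom is a dark
#' tree-shaped cell (or several) on a light background: each cell is a
#' two-tone soma ball (darker core, slightly lighter rim) with tapering,
#' tortuous branches whose centreline is darkest and whose intensity rises
#' quadratically toward the tube wall and gradually toward the branch tips —
#' the intensity ordering real dark-foreground fluorescence stacks show.
#' A field of small isolated blobs with staggered intensities emulates the
#' out-of-focus debris that makes the thresholded object count grow
#' steadily between the soma and background levels; sub-counting-size
#' specks extend the low-intensity plateau the soma-threshold search keys
#' on. All sizes are micrometres; intensities are 8-bit.
#'
#' @param n_cells number of cells (default 1).
#' @param xy_um lateral field size; defaults to `110 + 45 * (n_cells - 1)`
#'   so that each cell's tracing boundary box has clear background around
#'   it.
#' @param z_um stack depth (default 30, one fixed slice).
#' @param voxel_size `(dx, dy, dz)` micrometres; the default
#'   `(0.5, 0.5, 1)` mirrors typical high-NA confocal sampling with a 1 μm
#'   z-step.
#' @param soma_radius_um range of the nominal soma radius.
#' @param rim_um thickness of the brighter soma rim (inside the nominal
#'   radius).
#' @param n_primaries inclusive range of primary branches per cell.
#' @param branch_length_um range of primary branch lengths.
#' @param child_length_um range of secondary (post-bifurcation) branch
#'   lengths.
#' @param bifurcation_per_um probability of spawning a secondary branch per
#'   micrometre of primary branch.
#' @param max_bifurcations cap on bifurcations per cell.
#' @param step_um skeleton sampling step.
#' @param tortuosity standard deviation of the per-step direction
#'   perturbation (radians-equivalent on the unit sphere).
#' @param radius_taper_um branch radius at the soma and at the tip.
#' @param soma_values intensities of the soma core and rim.
#' @param speck_values intensities of the two sub-counting-size speck
#'   populations.
#' @param branch_core_values centreline intensity at the branch start and
#'   at the tip.
#' @param edge_value intensity at the tube wall.
#' @param texture_amp amplitude of the deterministic fluorophore-granularity
#'   texture added to branch voxels. Real fluorescence is granular; without
#'   texture the synthetic tubes have perfectly nested iso-intensity shells,
#'   a degeneracy no real image exhibits. The texture is a seed-mixed
#'   coordinate hash, so phantoms stay bit-reproducible.
#' @param background background intensity.
#' @param n_blobs,blob_values,blob_radius_um the debris-blob field: count,
#'   intensity range (blobs get evenly staggered values) and radius.
#' @param n_specks,speck_radius_um the speck field (half per tone).
#' @param noise_sigma Gaussian noise standard deviation (default 2;
#'   0 = noise-free).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_cells = 1L,
                         xy_um = NULL,
                         z_um = 30,
                         voxel_size = c(0.5, 0.5, 1),
                         soma_radius_um = c(3.5, 5),
                         rim_um = 0.7,
                         n_primaries = c(2L, 6L),
                         branch_length_um = c(12, 25),
                         child_length_um = c(8, 14),
                         bifurcation_per_um = 0.03,
                         max_bifurcations = 5L,
                         step_um = 2,
                         tortuosity = 0.18,
                         radius_taper_um = c(1.4, 0.8),
                         soma_values = c(40L, 50L),
                         speck_values = c(58L, 66L),
                         branch_core_values = c(78, 150),
                         edge_value = 215,
                         texture_amp = 0,
                         background = 230L,
                         n_blobs = 34L,
                         blob_values = c(80, 218),
                         blob_radius_um = 2.5,
                         n_specks = 14L,
                         speck_radius_um = 1.2,
                         noise_sigma = 2) {
  if (is.null(xy_um)) xy_um <- 110 + 45 * (n_cells - 1)
  spec <- list(n_cells = as.integer(n_cells), xy_um = xy_um, z_um = z_um,
               voxel_size = voxel_size, soma_radius_um = soma_radius_um,
               rim_um = rim_um, n_primaries = as.integer(n_primaries),
               branch_length_um = branch_length_um,
               child_length_um = child_length_um,
               bifurcation_per_um = bifurcation_per_um,
               max_bifurcations = as.integer(max_bifurcations),
               step_um = step_um, tortuosity = tortuosity,
               radius_taper_um = radius_taper_um,
               soma_values = soma_values, speck_values = speck_values,
               branch_core_values = branch_core_values,
               edge_value = edge_value, texture_amp = texture_amp,
               background = background,
               n_blobs = as.integer(n_blobs), blob_values = blob_values,
               blob_radius_um = blob_radius_um,
               n_specks = as.integer(n_specks),
               speck_radius_um = speck_radius_um,
               noise_sigma = noise_sigma)
  stopifnot(spec$n_cells >= 1, all(spec$voxel_size > 0),
            spec$soma_values[1] < spec$soma_values[2],
            spec$soma_values[2] < spec$branch_core_values[1])
  structure(spec, class = "phantom_spec")
}

# paint `value` into vol (min-combined) inside the ball |p - c| <= r
.paint_ball <- function(vol, vs, cen, r, value) {
  d <- dim(vol)
  lo <- pmax(1L, floor((cen - r) / vs) + 1L)
  hi <- pmin(d, ceiling((cen + r) / vs) + 1L)
  xs <- (lo[1]:hi[1] - 1) * vs[1] - cen[1]
  ys <- (lo[2]:hi[2] - 1) * vs[2] - cen[2]
  zs <- (lo[3]:hi[3] - 1) * vs[3] - cen[3]
  d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub[d2 <= r^2] <- pmin(sub[d2 <= r^2], value)
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  vol
}

# deterministic per-voxel texture in [-amp, amp]: a seed-mixed coordinate
# hash emulating fluorophore granularity, reproducible across runs
.texture <- function(ix, iy, iz, seed, amp) {
  h <- (ix * 73856.093 + iy * 19349.663 + iz * 83492.791 + seed * 7919.77)
  (2 * (h - floor(h)) - 1) * amp
}

# paint a tapering tube segment p1 -> p2: radius and centreline value are
# interpolated along the segment, intensity rises quadratically from the
# centreline value to `edge` at the local radius (sharp wall beyond)
.paint_segment <- function(vol, vs, p1, p2, r1, r2, v1, v2, edge,
                           tex_amp = 0, tex_seed = 0) {
  d <- dim(vol)
  rmax <- max(r1, r2)
  lo <- pmax(1L, floor((pmin(p1, p2) - rmax) / vs) + 1L)
  hi <- pmin(d, ceiling((pmax(p1, p2) + rmax) / vs) + 1L)
  xs <- (lo[1]:hi[1] - 1) * vs[1]
  ys <- (lo[2]:hi[2] - 1) * vs[2]
  zs <- (lo[3]:hi[3] - 1) * vs[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  u <- p2 - p1
  L2 <- sum(u^2)
  t <- if (L2 > 0)
    pmin(1, pmax(0, ((g$x - p1[1]) * u[1] + (g$y - p1[2]) * u[2] +
                     (g$z - p1[3]) * u[3]) / L2))
  else rep(0, nrow(g))
  px <- p1[1] + t * u[1]; py <- p1[2] + t * u[2]; pz <- p1[3] + t * u[3]
  dist <- sqrt((g$x - px)^2 + (g$y - py)^2 + (g$z - pz)^2)
  rl <- r1 + t * (r2 - r1)
  cv <- v1 + t * (v2 - v1)
  inside <- dist <= rl & rl > 0
  if (any(inside)) {
    val <- cv[inside] + (edge - cv[inside]) * (dist[inside] / rl[inside])^2
    if (tex_amp > 0) {
      gi <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
      val <- val + .texture(gi$x[inside], gi$y[inside], gi$z[inside],
                            tex_seed, tex_amp)
      val <- pmin(val, edge + tex_amp)
    }
    sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub[inside] <- pmin(sub[inside], as.integer(round(val)))
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  }
  vol
}

.unit <- function(v) v / sqrt(sum(v^2))

# one step of a biased random walk, reflected off the field margins
.walk_step <- function(p, dir, step, tort, lo, hi) {
  dir <- .unit(dir + stats::rnorm(3, sd = tort) * c(1, 1, 0.4))
  cand <- p + dir * step
  for (ax in 1:3) {
    if (cand[ax] < lo[ax] || cand[ax] > hi[ax]) {
      dir[ax] <- -dir[ax]
      cand <- p + dir * step
    }
  }
  list(p = pmin(pmax(cand, lo), hi), dir = dir)
}

#' Generate a synthetic microglia phantom
#'
#' Builds the stack described by a [phantom_spec()] together with its exact
#' ground truth: one [cell_tree()] per cell (root at the soma centre,
#' skeleton nodes every `step_um`, true radii) and the true quantification
#' table. The same `spec` and `seed` always reproduce the identical stack
#' and truth.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer random seed.
#' @return list with `stack` (an [image_stack()]), `truth` (list of
#'   `cell_tree`), `truth_quant` (data.frame as from [quantify()]), and
#'   `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  vs <- spec$voxel_size
  ext <- c(spec$xy_um, spec$xy_um, spec$z_um)
  dims <- pmax(2L, as.integer(round(ext / vs)))
  ext <- (dims - 1L) * vs                        # physical span of centres
  # cells are confined to a 56 μm box around their centroid so each fits the
  # standard 60 μm tracing boundary; the wall margin reserves that box
  reach <- 28
  margin <- min(reach + 3, spec$xy_um / 2 - 5)

  # --- soma placement: separation > 2 * reach keeps foregrounds disjoint
  centres <- matrix(0, 0, 3)
  for (i in seq_len(spec$n_cells)) {
    ok <- FALSE
    for (try in 1:500) {
      c_i <- c(stats::runif(2, margin, ext[1:2] - margin),
               stats::runif(1, 0.45, 0.55) * ext[3])
      if (nrow(centres) == 0 ||
          min(sqrt(rowSums(sweep(centres, 2, c_i)^2))) >= 2 * reach + 6) {
        centres <- rbind(centres, c_i); ok <- TRUE; break
      }
    }
    if (!ok) stop("infeasible soma placement")
  }

  zpad <- min(4, ext[3] / 4)
  vol <- array(as.integer(spec$background), dim = dims)
  trees <- vector("list", spec$n_cells)

  for (ci in seq_len(spec$n_cells)) {
    cen <- centres[ci, ]
    lo_b <- pmax(cen - reach, c(0, 0, zpad))
    hi_b <- pmin(cen + reach, c(ext[1], ext[2], ext[3] - zpad))
    R <- stats::runif(1, spec$soma_radius_um[1], spec$soma_radius_um[2])
    k <- if (spec$n_primaries[1] == spec$n_primaries[2]) spec$n_primaries[1]
         else sample(spec$n_primaries[1]:spec$n_primaries[2], 1)

    # nodes: root first; branches appended as chains
    nodes <- data.frame(id = 1L, parent = NA_integer_, type = 1L,
                        x = cen[1], y = cen[2], z = cen[3], radius = R)
    nbif <- 0L
    add_node <- function(p, parent, radius) {
      id <- nrow(nodes) + 1L
      nodes[id, ] <<- list(id, parent, 3L, p[1], p[2], p[3], radius)
      id
    }
    grow <- function(start, dir, len, parent_id, r_start, v_start) {
      p <- start; s <- 0
      last <- parent_id
      spawned <- list()
      while (s + spec$step_um <= len + 1e-9) {
        st <- .walk_step(p, dir, spec$step_um, spec$tortuosity, lo_b, hi_b)
        p <- st$p; dir <- st$dir; s <- s + spec$step_um
        r <- r_start + (spec$radius_taper_um[2] - r_start) * s / len
        last <- add_node(p, last, r)
        # both daughters of a bifurcation must stay clearly above the 5 μm
        # pruning floor once sampled at the 5 μm seed-box resolution
        can_bif <- s >= 4 && (len - s) >= 8 && nbif < spec$max_bifurcations
        if (can_bif && stats::runif(1) <
            spec$bifurcation_per_um * spec$step_um) {
          nbif <<- nbif + 1L
          ang <- stats::runif(1, 45, 70) * pi / 180
          perp <- .unit(.cross3(dir, stats::rnorm(3)))
          spawned[[length(spawned) + 1]] <-
            list(p = p, dir = .unit(dir * cos(ang) + perp * sin(ang)),
                 len = stats::runif(1, spec$child_length_um[1],
                                    spec$child_length_um[2]),
                 parent = last, r = r,
                 v = v_start + (spec$branch_core_values[2] - v_start) * s / len)
        }
      }
      spawned
    }
    if (k > 0) {
      dirs <- .spread_directions(k)
      children <- list()
      for (p_i in seq_len(k)) {
        dir <- dirs[p_i, ]
        start <- cen + R * dir
        sid <- add_node(start, 1L, spec$radius_taper_um[1])
        len <- stats::runif(1, spec$branch_length_um[1],
                            spec$branch_length_um[2])
        children <- c(children,
                      grow(start, dir, len, sid, spec$radius_taper_um[1],
                           spec$branch_core_values[1]))
      }
      for (ch in children)
        grow(ch$p, ch$dir, ch$len, ch$parent, ch$r, ch$v)
    }

    # rasterize: soma (rim then core), then every skeleton segment
    vol <- .paint_ball(vol, vs, cen, R, spec$soma_values[2])
    vol <- .paint_ball(vol, vs, cen, max(R - spec$rim_um, 0.5),
                       spec$soma_values[1])
    vmap <- .branch_values(nodes, spec)
    for (j in which(!is.na(nodes$parent) & nodes$parent != 1L)) {
      pj <- nodes$parent[j]
      vol <- .paint_segment(vol, vs,
                            as.numeric(nodes[pj, c("x", "y", "z")]),
                            as.numeric(nodes[j, c("x", "y", "z")]),
                            nodes$radius[pj], nodes$radius[j],
                            vmap[pj], vmap[j], spec$edge_value,
                            spec$texture_amp, seed)
    }

    soma_vox <- sum(.ball_voxels(dims, vs, cen, R))
    trees[[ci]] <- cell_tree(nodes, soma_id = ci,
                             soma_size = soma_vox * prod(vs))
  }

  # --- debris blobs (counted) and specks (below the counting floor),
  #     outside every cell's tracing boundary box
  place_far <- function(n, radius) {
    out <- matrix(0, 0, 3)
    guard <- 0
    while (nrow(out) < n && guard < 4000) {
      guard <- guard + 1
      p <- c(stats::runif(2, radius + 2, ext[1:2] - radius - 2),
             stats::runif(1, zpad, ext[3] - zpad))
      if (min(pmax(abs(centres[, 1] - p[1]), abs(centres[, 2] - p[2]))) <
          30 + radius + 2) next
      if (nrow(out) && min(sqrt(rowSums(sweep(out, 2, p)^2))) <
          2 * radius + 2) next
      out <- rbind(out, p)
    }
    out
  }
  blobs <- place_far(spec$n_blobs, spec$blob_radius_um)
  if (nrow(blobs)) {
    bv <- round(seq(spec$blob_values[1], spec$blob_values[2],
                    length.out = nrow(blobs)))
    for (j in seq_len(nrow(blobs)))
      vol <- .paint_ball(vol, vs, blobs[j, ], spec$blob_radius_um, bv[j])
  }
  specks <- place_far(spec$n_specks, spec$speck_radius_um)
  for (j in seq_len(nrow(specks)))
    vol <- .paint_ball(vol, vs, specks[j, ], spec$speck_radius_um,
                       spec$speck_values[1 + j %% 2])

  if (spec$noise_sigma > 0) {
    vol <- vol + as.integer(round(stats::rnorm(length(vol),
                                               sd = spec$noise_sigma)))
    vol[vol < 0L] <- 0L
    vol[vol > 255L] <- 255L
    dim(vol) <- dims
  }

  stack <- image_stack(vol, vs, polarity = "dark", bit_depth = 8)
  tq <- report(lapply(trees, quantify, dims = if (dims[3] > 1) 3 else 2))
  list(stack = stack, truth = trees,
       truth_quant = tq[tq$cell_id != "mean", , drop = FALSE], spec = spec)
}

# logical mask of voxels whose centre lies in the ball
.ball_voxels <- function(dims, vs, cen, r) {
  xs <- ((1:dims[1]) - 1) * vs[1] - cen[1]
  ys <- ((1:dims[2]) - 1) * vs[2] - cen[2]
  zs <- ((1:dims[3]) - 1) * vs[3] - cen[3]
  outer(outer(xs^2, ys^2, `+`), zs^2, `+`) <= r^2
}

# centreline intensity per truth node: distance-from-soma ramp between the
# branch core start and tip values
.branch_values <- function(nodes, spec) {
  if (nrow(nodes) < 2) return(rep(spec$branch_core_values[1], nrow(nodes)))
  # path length from the root along parents
  plen <- rep(0, nrow(nodes))
  for (j in 2:nrow(nodes)) {
    pj <- nodes$parent[j]
    seg <- sqrt(sum((nodes[j, c("x", "y", "z")] -
                     nodes[pj, c("x", "y", "z")])^2))
    plen[j] <- if (pj == 1L) 0 else plen[pj] + seg
  }
  mx <- max(plen, 1)
  vv <- spec$branch_core_values[1] +
    (spec$branch_core_values[2] - spec$branch_core_values[1]) * plen / mx
  vv[1] <- spec$branch_core_values[1]
  vv
}

# k unit vectors spread over the sphere by pairwise repulsion, so that
# primary branch origins stay separated at the soma-surface sampling
# resolution (microglia primaries emerge all around the soma)
.spread_directions <- function(k) {
  d <- matrix(stats::rnorm(3 * k), k, 3)
  d <- d / sqrt(rowSums(d^2))
  if (k > 1) {
    for (it in 1:200) {
      f <- matrix(0, k, 3)
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        diff <- d[i, ] - d[j, ]
        rep_f <- diff / (sum(diff^2) + 1e-6)
        f[i, ] <- f[i, ] + rep_f
        f[j, ] <- f[j, ] - rep_f
      }
      d <- d + 0.08 * f
      d <- d / sqrt(rowSums(d^2))
    }
  }
  d
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
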