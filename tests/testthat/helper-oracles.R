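# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, breadth-first flood fills) so they are
# independent of the package's compiled implementations.

# flood-fill connected-component labeling, 26-connectivity
bf_label <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) { dim(mask) <- c(d, 1L); d <- dim(mask) }
  lab <- array(0L, dim = d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (i0 in which(mask & lab == 0L)) {
    if (lab[i0] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(arrayInd(i0, d), ncol = 3)
    lab[i0] <- nxt
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(offs))) {
        nb <- cur + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

bf_count_objects <- function(mask, min_area, px_area) {
  lab <- bf_label(mask)
  if (max(lab) == 0) return(0L)
  sum(vapply(seq_len(max(lab)),
             function(l) sum(lab == l) * px_area > min_area, TRUE))
}

# exhaustive multilevel Otsu: maximize between-class variance over all
# k-subsets of cut values
bf_otsu <- function(image, k) {
  vals <- sort(unique(as.integer(image)))
  counts <- tabulate(match(as.integer(image), vals), nbins = length(vals))
  w <- counts / sum(counts)
  score <- function(cuts) {
    bounds <- c(-Inf, vals[cuts], Inf)
    s <- 0
    for (c in seq_len(length(bounds) - 1)) {
      in_c <- vals > bounds[c] & vals <= bounds[c + 1]
      wc <- sum(w[in_c])
      if (wc > 0) s <- s + wc * (sum(w[in_c] * vals[in_c]) / wc)^2
    }
    s
  }
  combos <- utils::combn(length(vals) - 1L, k)
  best <- -Inf; arg <- NULL
  for (j in seq_len(ncol(combos))) {
    sc <- score(combos[, j])
    if (sc > best + 1e-12) { best <- sc; arg <- combos[, j] }
  }
  vals[arg]
}

# double-loop nearest-neighbour distances
bf_nn <- function(a, b) {
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b)))
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    out[i] <- best
  }
  out
}

# component-labeling + Euclidean restricted-distance oracle
bf_restricted <- function(k, seeds, fg, window_um, vs) {
  d <- dim(fg)
  hw <- pmax(1L, as.integer(round((window_um / 2) / vs)))
  lo <- pmax(k - hw, 1L); hi <- pmin(k + hw, d)
  crop <- fg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  kc <- k - lo + 1L
  lab <- bf_label(crop)
  comp <- lab[kc[1], kc[2], kc[3]]
  out <- rep(Inf, nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (any(s < lo) || any(s > hi)) next
    sc <- s - lo + 1L
    if (lab[sc[1], sc[2], sc[3]] == comp && comp > 0)
      out[i] <- sqrt(sum(((s - k) * vs)^2))
  }
  out
}

# hand-built stack: straight dark tube along +x from a dark soma ball, on a
# light background; intensities follow the dark-foreground ordering
make_tube_stack <- function(nx = 90, ny = 40, nz = 13, vs = c(0.5, 0.5, 1),
                            soma = c(10, 10, 6), R = 4, r_tube = 1.4,
                            core = c(80, 150), len = 28) {
  dims <- c(nx, ny, nz)
  vol <- array(230L, dim = dims)
  p_soma <- (soma - 1) * vs
  vol <- microgliar:::.paint_ball(vol, vs, p_soma, R, 50L)
  vol <- microgliar:::.paint_ball(vol, vs, p_soma, R - 0.7, 40L)
  p1 <- p_soma + c(R, 0, 0)
  nseg <- ceiling(len / 2)
  for (s in seq_len(nseg)) {
    a <- p1 + c((s - 1) * 2, 0, 0)
    b <- p1 + c(min(s * 2, len), 0, 0)
    v1 <- core[1] + (core[2] - core[1]) * (s - 1) * 2 / len
    v2 <- core[1] + (core[2] - core[1]) * min(s * 2, len) / len
    vol <- microgliar:::.paint_segment(vol, vs, a, b, r_tube, r_tube,
                                       v1, v2, 215)
  }
  # far-away debris blobs with staggered intensities give the object count
  # the rising profile the background-threshold search expects
  ext <- (dims - 1) * vs
  bx <- seq(6, ext[1] - 6, length.out = 4)
  bv <- c(100L, 140L, 180L, 210L)
  for (j in 1:4)
    vol <- microgliar:::.paint_ball(vol, vs, c(bx[j], ext[2] - 3.5, ext[3] / 2),
                                    2.5, bv[j])
  image_stack(vol, vs, bit_depth = 8)
}

# random valid cell tree with n nodes (root + random parents)
random_tree <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA_integer_, vapply(2:n, function(i)
    sample.int(i - 1L, 1), 1L))
  cell_tree(data.frame(
    id = 1:n, parent = parent,
    type = c(1L, rep(3L, n - 1)),
    x = round(runif(n, 0, 100), 3), y = round(runif(n, 0, 100), 3),
    z = round(runif(n, 0, 30), 3),
    radius = round(runif(n, 0.3, 3), 3)))
}

# the standard recovery batch used by the acceptance tests: 20 noise-free
# phantoms, 1-3 cells each
recovery_batch <- function(n_phantoms = 20) {
  out <- list()
  for (i in seq_len(n_phantoms)) {
    ph <- generate_phantom(
      phantom_spec(n_cells = (i %% 3) + 1, noise_sigma = 0), seed = i)
    res <- run_pipeline(ph$stack, pipeline_config(), write = FALSE)
    tm <- suppressWarnings(truth_metrics(ph$truth, res$trees,
                                         voxel_size = ph$spec$voxel_size))
    rq <- res$quant[res$quant$cell_id != "mean", , drop = FALSE]
    per_cell <- do.call(rbind, lapply(seq_len(nrow(tm$topology)), function(k) {
      j <- tm$topology$matched[k]
      data.frame(
        phantom = i, cell = k,
        npb_truth = tm$topology$npb_truth[k],
        npb_traced = tm$topology$npb_traced[k],
        nbp_truth = tm$topology$nbp_truth[k],
        nbp_traced = tm$topology$nbp_traced[k],
        blen_truth = ph$truth_quant$branch_length_um[k],
        blen_traced = rq$branch_length_um[j],
        sd = skeleton_distance(ph$truth[[k]], res$trees[[j]],
                               voxel_size = ph$spec$voxel_size)$sd)
    }))
    out[[i]] <- per_cell
  }
  do.call(rbind, out)
}
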