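#' Component-restricted distances from a node to candidate seeds
#'
#' Distances used by the tracer: the foreground (stack thresholded at the
#' background threshold) is cropped to a window centred on the connected
#' node `k`; seeds lying in the same connected component of the crop as `k`
#' get their anisotropy-scaled Euclidean distance to `k`, all others —
#' outside the window or across a background gap — are unreachable and get
#' `Inf`. Restricting to the component prevents jumps across gaps between
#' nearby but unconnected structures.
#'
#' @param k voxel coordinate (length-3, 1-based) of a connected node. If `k`
#'   is not itself foreground it is snapped to the nearest foreground voxel
#'   in the window (error if the window holds none).
#' @param seeds integer matrix of candidate voxel coordinates (rows).
#' @param foreground logical array, the cell-voxel mask at `t_b`.
#' @param window_um physical side of the cropping window (micrometres).
#' @param voxel_size `(dx, dy, dz)` micrometres.
#' @return numeric vector of distances in micrometres (`Inf` = discarded).
#' @export
restricted_distance <- function(k, seeds, foreground, window_um, voxel_size) {
  d <- dim(foreground)
  k <- as.integer(k)
  if (any(k < 1L) || any(k > d)) stop("node outside the stack")
  hw <- pmax(1L, as.integer(round((window_um / 2) / voxel_size)))
  lo <- pmax(k - hw, 1L)
  hi <- pmin(k + hw, d)
  crop <- foreground[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  kc <- k - lo + 1L
  if (!crop[kc[1], kc[2], kc[3]]) {
    fg <- which(crop)
    if (length(fg) == 0) stop("no foreground voxel in the window")
    co <- arrayInd(fg, dim(crop))
    dd <- sweep(co, 2, kc)
    dd <- sweep(dd, 2, voxel_size, `*`)
    kc <- co[which.min(rowSums(dd^2)), ]
  }
  lab <- .cc_label(crop, 26L)
  comp <- lab[kc[1], kc[2], kc[3]]
  if (!is.matrix(seeds)) seeds <- matrix(seeds, ncol = 3)
  out <- rep(Inf, nrow(seeds))
  inside <- seeds[, 1] >= lo[1] & seeds[, 1] <= hi[1] &
            seeds[, 2] >= lo[2] & seeds[, 2] <= hi[2] &
            seeds[, 3] >= lo[3] & seeds[, 3] <= hi[3]
  if (any(inside)) {
    sc <- sweep(seeds[inside, , drop = FALSE], 2, lo - 1L)
    same <- lab[sc] == comp
    kphys <- (kc + lo - 1L) * voxel_size
    dd <- sweep(sweep(seeds[inside, , drop = FALSE], 2, voxel_size, `*`),
                2, kphys)
    ed <- sqrt(rowSums(dd^2))
    ed[!same] <- Inf
    out[inside] <- ed
  }
  out
}

#' Trace one cell
#'
#' Grows a tree for a single soma by greedy prioritized seed connection.
#' The connected set starts as the root (soma centroid) plus the soma's
#' surface seeds joined directly to the root; the disconnected set holds
#' seeds within the reachability box of any connected node. Each iteration
#' withdraws, among the reachable seeds of the lowest pending intensity
#' level, the (seed, parent) pair with minimum component-restricted
#' distance, attaches the seed, and lets the new node recruit its in-box
#' neighbours. Connecting one seed at a time keeps the result a tree.
#' Only seeds inside the boundary cube centred on the soma take part.
#'
#' @param stack an [image_stack()].
#' @param foreground logical array: [binarize()] at the background
#'   threshold.
#' @param soma_row one row of a [label_somas()] table.
#' @param seeds seed data.frame from [collect_seeds()] (possibly already
#'   filtered of seeds claimed by other cells).
#' @param params a [pipeline_config()] or list with `boundary_um`,
#'   `reach_um`.
#' @param log if TRUE, also return the attachment log (one row per greedy
#'   step: the attached seed's pool coordinates, level, chosen parent node
#'   and distance), for auditing the greedy selection.
#' @return list with `tree` (an unpruned [cell_tree()]), `used` (row
#'   indices into `seeds` that were attached) and, with `log = TRUE`,
#'   `log` (data.frame of greedy steps).
#' @export
trace_cell <- function(stack, foreground, soma_row, seeds, params,
                       log = FALSE) {
  vs <- stack$voxel_size
  cen <- as.integer(soma_row[c("cx", "cy", "cz")])
  half_b <- params$boundary_um / 2
  phys <- function(v) sweep(sweep(v, 2, 1), 2, vs, `*`)
  sc <- as.matrix(seeds[, c("x", "y", "z")])
  inb <- abs(sweep(phys(sc), 2, (cen - 1) * vs)) <= half_b
  inb <- inb[, 1] & inb[, 2] & inb[, 3]

  is_surf <- seeds$level == 0L & !is.na(seeds$soma) &
             seeds$soma == soma_row[["label"]]
  surf_idx <- which(is_surf & inb)
  branch_idx <- which(seeds$level > 0L & inb)

  # connected nodes: voxel coords; node 1 = root at the soma centroid
  nvx <- matrix(cen, ncol = 3)
  nparent <- NA_integer_
  ntype <- 1L
  for (i in surf_idx) {
    nvx <- rbind(nvx, as.integer(seeds[i, c("x", "y", "z")]))
    nparent <- c(nparent, 1L)
    ntype <- c(ntype, 3L)
  }

  if (length(branch_idx)) {
    pool <- seeds[branch_idx, , drop = FALSE]
    pc <- as.matrix(pool[, c("x", "y", "z")])
    best_d <- rep(Inf, nrow(pool))
    best_p <- rep(NA_integer_, nrow(pool))
    active <- rep(FALSE, nrow(pool))
    done <- rep(FALSE, nrow(pool))
    half_r <- params$reach_um / 2

    recruit <- function(node_id) {
      kvx <- nvx[node_id, ]
      open <- which(!done)
      if (!length(open)) return()
      db <- abs(sweep(sweep(pc[open, , drop = FALSE], 2, kvx), 2, vs, `*`))
      inbox <- db[, 1] <= half_r & db[, 2] <= half_r & db[, 3] <= half_r
      cand <- open[inbox]
      if (!length(cand)) return()
      dist <- restricted_distance(kvx, pc[cand, , drop = FALSE], foreground,
                                  params$reach_um, vs)
      upd <- dist < best_d[cand]
      best_d[cand[upd]] <<- dist[upd]
      best_p[cand[upd]] <<- node_id
      active[cand] <<- TRUE
    }
    for (id in seq_len(nrow(nvx))) recruit(id)

    steps <- list()
    repeat {
      open <- which(active & !done & is.finite(best_d))
      if (!length(open)) break
      lvl <- min(pool$level[open])
      atlvl <- open[pool$level[open] == lvl]
      pick <- atlvl[which.min(best_d[atlvl])]   # ties: seed insertion order
      done[pick] <- TRUE
      nvx <- rbind(nvx, pc[pick, ])
      nparent <- c(nparent, best_p[pick])
      ntype <- c(ntype, 3L)
      if (log)
        steps[[length(steps) + 1]] <- data.frame(
          x = pc[pick, 1], y = pc[pick, 2], z = pc[pick, 3],
          level = pool$level[pick], parent_node = best_p[pick],
          dist = best_d[pick], node = nrow(nvx))
      recruit(nrow(nvx))
    }
    used <- branch_idx[done]
  } else {
    steps <- list()
    used <- integer()
  }

  xyz <- sweep(sweep(nvx, 2, 1), 2, vs, `*`)
  tree <- cell_tree(
    data.frame(id = seq_len(nrow(nvx)), parent = nparent, type = ntype,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               radius = NA_real_,
               vx = nvx[, 1], vy = nvx[, 2], vz = nvx[, 3]),
    soma_id = as.integer(soma_row[["label"]]))
  out <- list(tree = tree, used = c(surf_idx, used))
  if (log) out$log <- if (length(steps)) do.call(rbind, steps)
                      else data.frame()
  out
}

#' Prune short terminal branches
#'
#' Terminal branches — the chain from a leaf back to (but excluding) the
#' nearest junction (root or node with more than one child) — shorter than
#' `prune_min_um` are removed, iterating until none remain (removing one
#' spur can expose another). The chain length includes the segment from the
#' junction to the chain, except when the junction is the root: root-child
#' segments run through the soma interior and do not count, so a surface
#' seed without descendants has length 0 and is always pruned. Each removed
#' spur's length is recorded at its junction node; these records later
#' serve as local branch-radius estimates (a pruned side twig typically
#' spans the branch cross-section). Multiple spurs at one node keep the
#' maximum length.
#'
#' @param tree a [cell_tree()].
#' @param prune_min_um minimum surviving terminal-branch length
#'   (micrometres, default 5).
#' @return the pruned `cell_tree` with its `spur` records.
#' @export
prune <- function(tree, prune_min_um = 5) {
  spur <- stats::setNames(as.list(tree$spur$length), tree$spur$node)
  nodes <- tree$nodes
  root <- nodes$id[is.na(nodes$parent)]
  repeat {
    ids <- nodes$id
    nkids <- table(factor(nodes$parent, levels = ids))
    leaves <- ids[nkids[as.character(ids)] == 0 & ids != root]
    if (!length(leaves)) break
    seg <- stats::setNames(rep(NA_real_, length(ids)), ids)
    pidx <- match(nodes$parent, ids)
    seg[] <- sqrt((nodes$x - nodes$x[pidx])^2 + (nodes$y - nodes$y[pidx])^2 +
                  (nodes$z - nodes$z[pidx])^2)
    removed <- FALSE
    drop <- logical(length(ids))
    for (lf in leaves) {
      chain <- lf
      len <- 0
      cur <- lf
      repeat {
        par <- nodes$parent[match(cur, ids)]
        if (is.na(par)) break                       # reached the root
        if (nkids[[as.character(par)]] > 1 || par == root) {
          # junction: count the junction->chain segment unless it is a
          # root->child (intra-soma) segment
          if (par != root) len <- len + seg[[as.character(cur)]]
          junction <- par
          break
        }
        len <- len + seg[[as.character(cur)]]
        chain <- c(chain, par)
        cur <- par
      }
      if (is.na(nodes$parent[match(cur, ids)])) next  # whole chain to root?
      if (len < prune_min_um) {
        drop[match(chain, ids)] <- TRUE
        key <- as.character(junction)
        spur[[key]] <- max(len, if (is.null(spur[[key]])) -Inf
                           else spur[[key]])
        removed <- TRUE
        break  # re-derive child counts before pruning the next leaf
      }
    }
    if (!removed) break
    nodes <- nodes[!drop, , drop = FALSE]
  }
  # drop spur records at nodes that were themselves pruned away
  spur <- spur[names(spur) %in% as.character(nodes$id)]
  spur_df <- data.frame(
    node = as.integer(names(spur)),
    length = if (length(spur)) unlist(spur, use.names = FALSE) else numeric())
  cell_tree(nodes, soma_id = tree$soma_id, spur = spur_df,
            soma_size = tree$soma_size)
}

#' Trace every cell in a stack
#'
#' Runs [trace_cell()] followed by [prune()] for each labeled soma in
#' ascending label order, inside its own boundary cube. Seeds attached to
#' one cell are withdrawn from the pool before tracing the next, so cells
#' with overlapping boundary boxes never duplicate structures. A cell whose
#' tracing fails yields an empty (root-only) tree with a warning and never
#' aborts the batch.
#'
#' @param stack an [image_stack()].
#' @param profile a [threshold_profile()].
#' @param somas a [label_somas()] result.
#' @param params a [pipeline_config()].
#' @return list of pruned [cell_tree()] objects, one per soma.
#' @export
trace_all <- function(stack, profile, somas, params = pipeline_config()) {
  foreground <- binarize(stack, profile$background_threshold)
  sd <- collect_seeds(stack, profile, somas, params$seed_box_um)
  seeds <- sd$seeds
  avail <- rep(TRUE, nrow(seeds))
  trees <- vector("list", nrow(somas$table))
  labs <- sort(somas$table$label)
  for (i in seq_along(labs)) {
    row <- somas$table[somas$table$label == labs[i], ]
    res <- tryCatch({
      sub <- seeds[avail, , drop = FALSE]
      r <- trace_cell(stack, foreground, row, sub, params)
      avail[which(avail)[r$used]] <- FALSE
      prune(r$tree, params$prune_min_um)
    }, error = function(e) {
      warning("cell ", labs[i], ": ", conditionMessage(e))
      vs <- stack$voxel_size
      cell_tree(data.frame(id = 1L, parent = NA_integer_, type = 1L,
                           x = (row$cx - 1) * vs[1], y = (row$cy - 1) * vs[2],
                           z = (row$cz - 1) * vs[3], radius = NA_real_,
                           vx = row$cx, vy = row$cy, vz = row$cz),
                soma_id = as.integer(labs[i]))
    })
    trees[[i]] <- res
  }
  trees
}
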