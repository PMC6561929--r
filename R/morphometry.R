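#' Volume of a conical (frustum) segment
#'
#' Volume of the solid of revolution between two consecutive skeleton nodes
#' with cross-section radii `r1`, `r2` and centreline length `h`:
#' \deqn{v = \frac{\pi}{3} h (r_1^2 + r_1 r_2 + r_2^2).}
#' Reduces to a cylinder for `r1 == r2` and a cone for `r1 == 0`.
#'
#' @param r1,r2 radii at the segment ends (micrometres, >= 0).
#' @param h segment length (micrometres, >= 0).
#' @return volume in cubic micrometres (vectorised).
#' @export
segment_volume <- function(r1, r2, h) {
  if (any(c(r1, r2, h) < 0)) stop("negative input")
  pi / 3 * h * (r1^2 + r1 * r2 + r2^2)
}

#' Area of a trapezoidal segment (2D)
#'
#' The 2D analogue of [segment_volume()]: the area swept between half-widths
#' `r1` and `r2` over length `h`, \eqn{a = h (r_1 + r_2)}.
#'
#' @inheritParams segment_volume
#' @return area in square micrometres (vectorised).
#' @export
segment_area <- function(r1, r2, h) {
  if (any(c(r1, r2, h) < 0)) stop("negative input")
  h * (r1 + r2)
}

# ids of descendants of `id` in BFS order (nearest first)
.bfs_down <- function(kids, id) {
  out <- integer()
  frontier <- kids[[as.character(id)]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, function(i) kids[[as.character(i)]]))
  }
  out
}

#' Estimate a radius for every skeleton node
#'
#' Pruned short branches span the cross-section of the branch they were
#' attached to, so their recorded lengths are direct thickness measurements:
#' nodes holding a (positive-length) spur record take that length as their
#' radius. The rest are filled in a root-to-tip traversal: a branch starting
#' point (child of the root) with no measurement takes the radius of its
#' nearest measured descendant; any other unset node takes the mean of its
#' parent's radius and its nearest measured descendant's, or inherits the
#' parent radius when the remaining branch holds no measurement. The root
#' radius is the equivalent-sphere (3D) or equivalent-circle (2D) radius of
#' the soma size. A tree without any usable spur gets `default_radius`
#' everywhere below the root.
#'
#' @param tree a pruned [cell_tree()] with `spur` records.
#' @param dims 2 or 3 (controls the root's equivalent radius).
#' @param default_radius fallback radius in micrometres (default 0.5).
#' @return the tree with `radius` set (> 0) on every node.
#' @export
estimate_radii <- function(tree, dims = 3, default_radius = 0.5) {
  n <- tree$nodes
  ids <- n$id
  root <- .root_id(tree)
  rad <- stats::setNames(rep(NA_real_, length(ids)), ids)
  sp <- tree$spur[tree$spur$length > 0, , drop = FALSE]
  rad[as.character(sp$node)] <- sp$length
  rad[as.character(root)] <-
    if (!is.na(tree$soma_size)) {
      if (dims == 3) (3 * tree$soma_size / (4 * pi))^(1 / 3)
      else sqrt(tree$soma_size / pi)
    } else default_radius
  kids <- split(ids[!is.na(n$parent)], n$parent[!is.na(n$parent)])
  ord <- .topo_order(tree)
  for (id in ord) {
    key <- as.character(id)
    if (!is.na(rad[[key]])) next
    par <- n$parent[match(id, ids)]
    desc <- .bfs_down(kids, id)
    dr <- rad[as.character(desc)]
    dr <- dr[!is.na(dr)][1]          # nearest measured descendant, if any
    rad[[key]] <-
      if (par == root) { if (!is.na(dr)) dr else default_radius }
      else {
        pr <- rad[[as.character(par)]]
        if (!is.na(dr)) (pr + dr) / 2 else pr
      }
  }
  tree$nodes$radius <- as.numeric(rad[as.character(ids)])
  tree
}

#' Quantify one reconstructed cell
#'
#' Extracts the morphometric features: number of primary branches (children
#' of the root), number of branch points (non-root nodes with more than one
#' child), total branch length (sum of segment lengths, excluding the
#' root-to-child segments that run through the soma interior), soma size
#' (physical size of the labeled soma component) and cell size (sum of
#' frustum volumes in 3D or trapezoid areas in 2D over all branch segments,
#' plus the soma size).
#'
#' @param tree a [cell_tree()] with radii set (see [estimate_radii()]).
#' @param soma_size physical soma size; defaults to the tree's own record.
#' @param dims 2 or 3.
#' @return one-row data.frame: `cell_id`, `n_primary`, `n_branch_points`,
#'   `branch_length_um`, `soma_size`, `cell_size`.
#' @export
quantify <- function(tree, soma_size = tree$soma_size, dims = 3) {
  n <- tree$nodes
  if (nrow(n) > 1 && anyNA(n$radius)) stop("radii unset: run estimate_radii()")
  root <- .root_id(tree)
  npb <- sum(n$parent == root, na.rm = TRUE)
  kids <- table(factor(n$parent, levels = n$id))
  nbp <- sum(kids > 1 & names(kids) != as.character(root))
  seg <- .segment_lengths(tree)
  keep <- !is.na(n$parent) & n$parent != root
  blen <- sum(seg[keep])
  pidx <- match(n$parent, n$id)
  segsz <- if (dims == 3)
    segment_volume(n$radius[pidx][keep], n$radius[keep], seg[keep])
  else
    segment_area(n$radius[pidx][keep], n$radius[keep], seg[keep])
  ssz <- if (is.na(soma_size)) 0 else soma_size
  data.frame(cell_id = if (is.na(tree$soma_id)) NA_integer_ else tree$soma_id,
             n_primary = npb, n_branch_points = nbp,
             branch_length_um = blen, soma_size = ssz,
             cell_size = sum(segsz) + ssz)
}

#' Dataset-level quantification report
#'
#' Stacks per-cell quantification rows and appends the per-cell mean row.
#'
#' @param reports list of [quantify()] rows (or a data.frame of them).
#' @return data.frame with one row per cell plus a final `"mean"` row.
#' @export
report <- function(reports) {
  if (is.data.frame(reports)) tab <- reports
  else tab <- do.call(rbind, reports)
  if (nrow(tab) < 1) stop("need at least one cell")
  tab$cell_id <- as.character(tab$cell_id)
  num <- vapply(tab[-1], mean, 0)
  rbind(tab, data.frame(cell_id = "mean", as.list(num)))
}
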