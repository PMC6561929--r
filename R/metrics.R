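#' Skeleton-to-skeleton distance metrics
#'
#' Benchmarks one reconstruction against another (typically automated vs
#' ground truth) with three node-distance measures:
#' \describe{
#'   \item{SD}{spatial distance — for each node of `a` the Euclidean
#'     distance to the nearest node of `b` and vice versa; SD is the mean of
#'     the two directional means (symmetric).}
#'   \item{SSD}{substantial spatial distance — the mean nearest-node
#'     distance over the *substantial* nodes only, i.e. those farther than
#'     the threshold (default 2 voxels), both directions pooled; 0 when no
#'     node is substantial.}
#'   \item{SSD\%}{fraction of nodes (both directions pooled) that are
#'     substantial, in `[0, 1]`.}
#' }
#' Soma nodes (SWC tag 1) are excluded from the comparison.
#'
#' @param a,b a `cell_tree`, a list of them, or a numeric matrix of node
#'   coordinates (micrometres, 3 columns).
#' @param threshold_voxels substantial-distance threshold in voxels
#'   (default 2), converted to micrometres with the mean in-plane voxel
#'   size.
#' @param voxel_size `(dx, dy, dz)` in micrometres used for the voxel ->
#'   micrometre conversion of the threshold.
#' @return object of class `skeleton_distances`: list with `sd`, `ssd`,
#'   `ssd_pct`, `threshold_um`, and the directional means `sd_ab`, `sd_ba`.
#' @export
skeleton_distance <- function(a, b, threshold_voxels = 2,
                              voxel_size = c(1, 1, 1)) {
  A <- .node_matrix(a)
  B <- .node_matrix(b)
  if (nrow(A) == 0 || nrow(B) == 0)
    stop("empty node set (after excluding soma nodes)")
  dab <- .nn_min_dist(A, B)
  dba <- .nn_min_dist(B, A)
  thr <- threshold_voxels * mean(voxel_size[1:2])
  pooled <- c(dab, dba)
  subst <- pooled > thr
  structure(list(
    sd = (mean(dab) + mean(dba)) / 2,
    ssd = if (any(subst)) mean(pooled[subst]) else 0,
    ssd_pct = mean(subst),
    threshold_um = thr,
    sd_ab = mean(dab), sd_ba = mean(dba),
    n_a = nrow(A), n_b = nrow(B)), class = "skeleton_distances")
}

.node_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "cell_tree")) x <- list(x)
  if (!is.list(x)) stop("expected cell_tree(s) or a coordinate matrix")
  rows <- lapply(x, function(tr) {
    n <- tr$nodes
    n <- n[n$type != 1L, c("x", "y", "z"), drop = FALSE]  # drop soma nodes
    as.matrix(n)
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- NULL
  out
}

#' @export
print.skeleton_distances <- function(x, ...) {
  cat(sprintf("SD = %.3f μm | SSD = %.3f μm | SSD%% = %.3f (threshold %.2f μm)\n",
              x$sd, x$ssd, x$ssd_pct, x$threshold_um))
  invisible(x)
}

#' Recovery summary of a traced reconstruction against ground truth
#'
#' Convenience wrapper combining [skeleton_distance()] with per-cell
#' topology deltas (difference in primary-branch and branch-point counts).
#' Cells are paired by root position (each truth root with the nearest
#' traced root); a count mismatch is reported, not fatal.
#'
#' @param truth,traced lists of [cell_tree()] objects.
#' @param threshold_voxels,voxel_size passed to [skeleton_distance()].
#' @return list with `distances` (a `skeleton_distances`), and `topology`
#'   (data.frame: per-cell `npb_truth`, `npb_traced`, `nbp_truth`,
#'   `nbp_traced`).
#' @export
truth_metrics <- function(truth, traced, threshold_voxels = 2,
                          voxel_size = c(1, 1, 1)) {
  if (inherits(truth, "cell_tree")) truth <- list(truth)
  if (inherits(traced, "cell_tree")) traced <- list(traced)
  if (length(truth) != length(traced))
    warning("cell count mismatch: ", length(truth), " truth vs ",
            length(traced), " traced")
  root_xyz <- function(tr) unlist(tr$nodes[is.na(tr$nodes$parent),
                                           c("x", "y", "z")])
  rt <- t(vapply(truth, root_xyz, numeric(3)))
  rr <- t(vapply(traced, root_xyz, numeric(3)))
  k <- min(length(truth), length(traced))
  topo <- do.call(rbind, lapply(seq_len(k), function(i) {
    j <- which.min(colSums((t(rr) - rt[i, ])^2))
    st <- summary(truth[[i]]); sr <- summary(traced[[j]])
    data.frame(cell = i, matched = j,
               npb_truth = st$primary_branches,
               npb_traced = sr$primary_branches,
               nbp_truth = st$branch_points,
               nbp_traced = sr$branch_points)
  }))
  list(distances = skeleton_distance(truth, traced, threshold_voxels,
                                     voxel_size),
       topology = topo)
}
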