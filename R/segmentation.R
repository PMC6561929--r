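#' Count sufficiently large objects in a binary image
#'
#' Connected components (8-connectivity) of a 2D binary image are counted,
#' ignoring components whose physical area does not exceed `min_area_um2`.
#' The area floor (16 square micrometres by default elsewhere in the
#' pipeline) suppresses noise specks and isolated branch fragments so that
#' the object count tracks somas and substantial structures.
#'
#' @param binary logical matrix.
#' @param min_area_um2 minimum area (exclusive) for a component to count.
#' @param pixel_area_um2 physical area of one pixel.
#' @return integer count.
#' @export
count_objects <- function(binary, min_area_um2, pixel_area_um2) {
  stopifnot(is.matrix(binary) || length(dim(binary)) == 3)
  if (min_area_um2 < 0) stop("`min_area_um2` must be >= 0")
  lab <- .cc_label(binary, 26L)
  if (max(lab) == 0L) return(0L)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  sum(sizes * pixel_area_um2 > min_area_um2)
}

#' Multilevel Otsu thresholds
#'
#' Computes `levels` ascending thresholds maximizing the between-class
#' variance of the image histogram (the multi-class generalisation of Otsu's
#' method), solved exactly by dynamic programming over one histogram bin per
#' integer intensity present in the image.
#'
#' @param image integer matrix or array of intensities.
#' @param levels number of thresholds (default 20). If the image has fewer
#'   than `levels + 1` distinct intensities the count is reduced with a
#'   warning; a constant image is an error.
#' @return integer vector of strictly ascending thresholds. Class `k` of the
#'   induced partition is the set of intensities in `(t_{k-1}, t_k]`.
#' @export
multilevel_otsu <- function(image, levels = 20L) {
  vals <- sort(unique(as.integer(image)))
  if (length(vals) < 2) stop("constant image: no threshold exists")
  levels <- as.integer(levels)
  if (levels < 1) stop("`levels` must be >= 1")
  if (length(vals) < levels + 1) {
    levels <- length(vals) - 1L
    warning("fewer distinct intensities than levels + 1; reduced to ",
            levels, " levels")
  }
  counts <- tabulate(match(as.integer(image), vals), nbins = length(vals))
  idx <- .multiotsu_dp(as.numeric(counts), as.numeric(vals), levels)
  vals[idx]
}

#' Normalized differential criterion of an object-count sequence
#'
#' For counts \eqn{n_{t_1}, \dots, n_{t_K}} at ascending thresholds, the
#' criterion at each adjacent pair is
#' \deqn{c_i = (n_{t_{i+1}} - n_{t_i}) / (n_{t_{i+1}} + n_{t_i}),}
#' a growth rate normalized to \eqn{[-1, 1]}. Pairs whose counts are both
#' zero are undefined and returned as `NA`.
#'
#' @param counts non-negative numeric vector of object counts.
#' @return numeric vector of length `length(counts) - 1`.
#' @export
criterion <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  num <- diff(counts)
  den <- counts[-length(counts)] + counts[-1]
  out <- ifelse(den > 0, num / den, NA_real_)
  as.numeric(out)
}

#' Locate the soma threshold on a criterion sequence
#'
#' Somas are the compact dark cores, so their count stabilizes while the
#' count is still growing overall: within the initial run of non-negative
#' criterion values, the transition with the *minimum* growth rate marks the
#' soma level. Ties on the minimum are broken at the position where the
#' forward difference `c[i+1] - c[i]` is smallest (an interior tie beats the
#' run's last position, whose forward difference is taken as `+Inf`). The
#' soma threshold is the upper threshold of the winning transition.
#'
#' @param thresholds ascending thresholds `t_1..t_K`.
#' @param crit criterion values `c_1..c_{K-1}` as from [criterion()].
#' @return list with `index` (position of `t_s` in `thresholds`) and
#'   `threshold` (`t_s` itself).
#' @export
find_soma_threshold <- function(thresholds, crit) {
  stopifnot(length(crit) == length(thresholds) - 1)
  def <- which(!is.na(crit))
  if (length(def) == 0) stop("no soma level found")
  f <- def[1]
  if (crit[f] < 0) stop("no soma level found")
  q <- f
  while (q + 1 <= length(crit) && !is.na(crit[q + 1]) && crit[q + 1] >= 0)
    q <- q + 1
  run <- f:q
  cmin <- min(crit[run])
  tied <- run[crit[run] == cmin]
  if (length(tied) > 1) {
    fwd <- vapply(tied, function(p) {
      if (p + 1 <= length(crit) && !is.na(crit[p + 1])) crit[p + 1] - crit[p]
      else Inf
    }, 0)
    tied <- tied[which.min(fwd)]
  }
  i_star <- tied[1]
  list(index = i_star + 1L, threshold = thresholds[i_star + 1L])
}

#' Locate the background threshold
#'
#' The background threshold is where the object count is globally maximal
#' over raw intensities: beyond it, objects merge into one solid covering
#' the image. Scanning every intensity is slow, but the count maximum over
#' the Otsu levels (`t_max`) is close, so only a small neighbourhood of raw
#' intensities around `t_max` is searched — half the gap to the adjacent
#' levels on each side, extended to the intensity extremes when `t_max` is
#' the first or last level.
#'
#' @param thresholds,counts the Otsu levels and their object counts.
#' @param image 2D integer image the counts were computed on (the
#'   minimum projection).
#' @param min_area_um2,pixel_area_um2 as in [count_objects()].
#' @return list with `threshold` (`t_b`), `count` (objects at `t_b`) and
#'   `index` (position of `t_max` in `thresholds`).
#' @export
find_background_threshold <- function(thresholds, counts, image,
                                      min_area_um2, pixel_area_um2) {
  stopifnot(length(thresholds) == length(counts))
  m <- which.max(counts)
  t_max <- thresholds[m]
  K <- length(thresholds)
  lo <- if (m > 1) ceiling(t_max - (t_max - thresholds[m - 1]) / 2)
        else min(image)
  hi <- if (m < K) floor(t_max + (thresholds[m + 1] - t_max) / 2)
        else max(image)
  cand <- lo:hi
  cnt <- vapply(cand, function(t)
    count_objects(image <= t, min_area_um2, pixel_area_um2), 0L)
  best <- which(cnt == max(cnt))
  # prefer the candidate nearest t_max (then the smaller intensity)
  best <- best[order(abs(cand[best] - t_max), cand[best])][1]
  list(threshold = cand[best], count = cnt[best], index = m)
}

#' Threshold profile of a stack
#'
#' Runs the full threshold-selection procedure: minimum projection over a
#' central slab, multilevel Otsu levels, per-level object counts, the
#' normalized differential criterion, and the soma (`t_s`) and background
#' (`t_b`) thresholds.
#'
#' @param stack an [image_stack()].
#' @param levels number of Otsu levels (default 20).
#' @param slab_um projection slab thickness, micrometres (default 30).
#' @param min_count_area_um2 object-count area floor (default 16).
#' @return object of class `threshold_profile`: list with `thresholds`,
#'   `counts`, `criterion`, `soma_index`, `soma_threshold`,
#'   `background_index`, `background_threshold`, `projection`.
#' @export
threshold_profile <- function(stack, levels = 20L, slab_um = 30,
                              min_count_area_um2 = 16) {
  stopifnot(inherits(stack, "image_stack"))
  M <- min_projection(stack, slab_um)
  px_area <- stack$voxel_size[1] * stack$voxel_size[2]
  th <- multilevel_otsu(M, levels)
  counts <- vapply(th, function(t)
    count_objects(M <= t, min_count_area_um2, px_area), 0L)
  cr <- criterion(counts)
  soma <- find_soma_threshold(th, cr)
  bg <- find_background_threshold(th, counts, M, min_count_area_um2, px_area)
  if (soma$threshold >= bg$threshold)
    stop("soma threshold is not below the background threshold; ",
         "the stack may lack separable somas")
  structure(list(thresholds = th, counts = counts, criterion = cr,
                 soma_index = soma$index, soma_threshold = soma$threshold,
                 background_index = bg$index,
                 background_threshold = bg$threshold,
                 background_count = bg$count,
                 projection = M),
            class = "threshold_profile")
}

#' @export
print.threshold_profile <- function(x, ...) {
  cat(sprintf("<threshold_profile> %d levels\n", length(x$thresholds)))
  cat(sprintf("  t_s = %d (level %d), t_b = %d (near level %d, %d objects)\n",
              x$soma_threshold, x$soma_index, x$background_threshold,
              x$background_index, x$background_count))
  invisible(x)
}

#' Label soma volumes
#'
#' Connected components (26-connectivity) of the stack thresholded at the
#' soma threshold, keeping components above a physical size floor. Each
#' component is a soma candidate with a centroid (rounded to the nearest
#' voxel) and a physical size (cubic micrometres in 3D, square micrometres
#' for single-slice stacks).
#'
#' @param stack an [image_stack()].
#' @param t_s soma threshold.
#' @param min_size minimum physical size (exclusive). Defaults to the 2D
#'   counting floor of 16 square micrometres scaled by one z-step in 3D, or
#'   16 square micrometres in 2D.
#' @return object of class `soma_labels`: list with `labels` (integer array),
#'   `table` (data.frame: `label`, `cx`, `cy`, `cz` voxel centroids, `size`),
#'   and `unit_size` (physical size of one voxel).
#' @export
label_somas <- function(stack, t_s, min_size = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  vs <- stack$voxel_size
  unit <- if (d[3] > 1) prod(vs) else vs[1] * vs[2]
  if (is.null(min_size))
    min_size <- if (d[3] > 1) 16 * vs[3] else 16
  lab <- .cc_label(binarize(stack, t_s), 26L)
  nlab <- max(lab)
  if (nlab == 0L) stop("no soma found")
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(sizes * unit > min_size)
  if (length(keep) == 0L) stop("no soma found")
  out <- array(0L, dim = d)
  tab <- data.frame(label = seq_along(keep), cx = 0, cy = 0, cz = 0,
                    size = sizes[keep] * unit)
  for (j in seq_along(keep)) {
    idx <- which(lab == keep[j])
    out[idx] <- j
    co <- arrayInd(idx, d)
    cen <- round(colMeans(co))
    tab[j, c("cx", "cy", "cz")] <- pmin(pmax(cen, 1L), d)
  }
  structure(list(labels = out, table = tab, unit_size = unit),
            class = "soma_labels")
}

#' @export
print.soma_labels <- function(x, ...) {
  cat(sprintf("<soma_labels> %d soma(s)\n", nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
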