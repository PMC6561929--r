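#' Intensity level masks between the soma and background thresholds
#'
#' Voxels with intensities between `t_s` and `t_b` carry the branch detail
#' used for tracing. The effective threshold ladder is `t_s`, the Otsu
#' levels strictly between `t_s` and `t_b`, then `t_b` itself; the mask of
#' level `i` is the set difference of consecutive binarizations, i.e. voxels
#' whose intensity lies in `(tau_{i-1}, tau_i]`. Masks are pairwise disjoint
#' and their union is exactly the foreground-at-`t_b` minus the
#' foreground-at-`t_s`.
#'
#' @param stack an [image_stack()].
#' @param profile a [threshold_profile()].
#' @return list with `masks` (list of logical arrays, ascending level) and
#'   `ladder` (the bounding thresholds, length `length(masks) + 1`).
#' @export
level_masks <- function(stack, profile) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(profile, "threshold_profile"))
  t_s <- profile$soma_threshold
  t_b <- profile$background_threshold
  if (t_s >= t_b) stop("soma threshold must be below background threshold")
  mid <- profile$thresholds[profile$thresholds > t_s &
                            profile$thresholds < t_b]
  ladder <- c(t_s, mid, t_b)
  masks <- vector("list", length(ladder) - 1)
  for (j in seq_along(masks))
    masks[[j]] <- stack$data > ladder[j] & stack$data <= ladder[j + 1]
  list(masks = masks, ladder = ladder)
}

# per-axis box edge in voxels for a sampling cube of physical side box_um
.box_edges <- function(voxel_size, box_um) {
  pmax(1L, as.integer(round(box_um / voxel_size)))
}

#' Sample seed points from a level mask
#'
#' The stack is partitioned into axis-aligned boxes of physical side
#' `box_um` (default 5 micrometres; per-axis voxel counts are rounded and
#' floored at one voxel to handle anisotropy). From every box containing
#' mask voxels, the darkest voxel is emitted: dark intensity tracks
#' proximity to the branch centreline, so per-box minima land on or near
#' the centreline. Intensity ties inside a box go to the lexicographically
#' smallest coordinate, which keeps sampling deterministic.
#'
#' @param stack an [image_stack()].
#' @param mask logical array (one entry of [level_masks()]).
#' @param box_um sampling box side in micrometres.
#' @return data.frame with columns `x`, `y`, `z` (1-based voxel indices) and
#'   `intensity`; zero rows for an empty mask.
#' @export
sample_level <- function(stack, mask, box_um = 5) {
  stopifnot(inherits(stack, "image_stack"))
  if (box_um <= 0) stop("`box_um` must be > 0")
  idx <- which(mask)
  if (length(idx) == 0)
    return(data.frame(x = integer(), y = integer(), z = integer(),
                      intensity = integer()))
  d <- dim(stack$data)
  co <- arrayInd(idx, d)
  ints <- stack$data[idx]
  be <- .box_edges(stack$voxel_size, box_um)
  nbx <- (d[1] - 1L) %/% be[1] + 1L
  nby <- (d[2] - 1L) %/% be[2] + 1L
  box <- (co[, 1] - 1L) %/% be[1] +
         nbx * ((co[, 2] - 1L) %/% be[2]) +
         nbx * nby * ((co[, 3] - 1L) %/% be[3])
  ord <- order(box, ints, co[, 1], co[, 2], co[, 3])
  first <- ord[!duplicated(box[ord])]
  data.frame(x = co[first, 1], y = co[first, 2], z = co[first, 3],
             intensity = ints[first])
}

# mask of voxels of `comp` whose 6-neighbourhood (face-adjacent; axes with
# extent 1 are skipped) leaves the component or the array
.surface_mask <- function(comp) {
  d <- dim(comp)
  inside <- array(TRUE, dim = d)
  shift_in <- function(ax, s) {
    out <- array(FALSE, dim = d)
    n <- d[ax]
    src <- if (s > 0) 1:(n - 1) else 2:n
    dst <- if (s > 0) 2:n else 1:(n - 1)
    ix <- list(1:d[1], 1:d[2], 1:d[3])
    jx <- ix
    ix[[ax]] <- dst; jx[[ax]] <- src
    out[ix[[1]], ix[[2]], ix[[3]]] <- comp[jx[[1]], jx[[2]], jx[[3]]]
    out
  }
  for (ax in 1:3) {
    if (d[ax] == 1) next
    inside <- inside & shift_in(ax, 1) & shift_in(ax, -1)
  }
  comp & !inside
}

#' Seed points on soma surfaces
#'
#' The surface shell of each labeled soma (component voxels with at least
#' one face-adjacent neighbour outside the component) is sampled with the
#' same box procedure as [sample_level()]. Surface seeds take the highest
#' priority level (0) and anchor the primary branches during tracing.
#'
#' @param stack an [image_stack()].
#' @param somas a [label_somas()] result.
#' @param box_um sampling box side in micrometres.
#' @return data.frame with columns `x`, `y`, `z`, `intensity`, `soma`.
#' @export
soma_surface_seeds <- function(stack, somas, box_um = 5) {
  stopifnot(inherits(somas, "soma_labels"))
  out <- vector("list", nrow(somas$table))
  for (j in somas$table$label) {
    surf <- .surface_mask(somas$labels == j)
    s <- sample_level(stack, surf, box_um)
    if (nrow(s)) s$soma <- j
    else s <- cbind(s, data.frame(soma = integer()))
    out[[j]] <- s
  }
  do.call(rbind, out)
}

#' All prioritized seed points of a stack
#'
#' Combines soma-surface seeds (level 0, highest priority) with per-level
#' branch seeds (level 1 upward, ascending intensity).
#'
#' @inheritParams soma_surface_seeds
#' @param profile a [threshold_profile()].
#' @return list with `seeds` (data.frame: `x`, `y`, `z`, `intensity`,
#'   `level`, `soma` — `soma` is `NA` for branch seeds) and `ladder` from
#'   [level_masks()].
#' @export
collect_seeds <- function(stack, profile, somas, box_um = 5) {
  lm <- level_masks(stack, profile)
  surf <- soma_surface_seeds(stack, somas, box_um)
  surf$level <- 0L
  parts <- list(surf[, c("x", "y", "z", "intensity", "level", "soma")])
  for (i in seq_along(lm$masks)) {
    s <- sample_level(stack, lm$masks[[i]], box_um)
    if (nrow(s)) {
      s$level <- i
      s$soma <- NA_integer_
      parts[[length(parts) + 1]] <- s
    }
  }
  list(seeds = do.call(rbind, parts), ladder = lm$ladder)
}
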