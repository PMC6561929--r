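#' Cell tree container
#'
#' A rooted tree of skeleton nodes for one cell. Coordinates are physical
#' (micrometres; voxel `(1,1,1)` maps to the origin). The root sits at the
#' soma centroid with tag 1; all other nodes are process (branch) nodes
#' with tag 3.
#'
#' @param nodes data.frame with columns `id` (1..n, root first), `parent`
#'   (`NA` for the root, else the id of an existing node), `type` (SWC tag),
#'   `x`, `y`, `z` (micrometres), `radius` (micrometres, `NA` until
#'   estimated). Optional voxel-index columns `vx`, `vy`, `vz` are kept if
#'   present.
#' @param soma_id integer label of the originating soma (NA if unknown).
#' @param spur data.frame of pruned-branch records (`node`, `length`): the
#'   length in micrometres of the longest branch pruned at each node, later
#'   reused as a local radius estimate.
#' @param soma_size physical soma size (set during quantification).
#' @return object of class `cell_tree`.
#' @export
cell_tree <- function(nodes, soma_id = NA_integer_,
                      spur = data.frame(node = integer(), length = numeric()),
                      soma_size = NA_real_) {
  need <- c("id", "parent", "type", "x", "y", "z", "radius")
  if (!all(need %in% names(nodes))) stop("missing node columns")
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  tr <- structure(list(nodes = nodes, soma_id = soma_id, spur = spur,
                       soma_size = soma_size),
                  class = "cell_tree")
  validate_tree(tr)
  tr
}

#' Validate a cell tree
#'
#' Checks the tree invariants: exactly one root, every parent exists,
#' no cycles.
#'
#' @param tree a [cell_tree()].
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_tree <- function(tree) {
  n <- tree$nodes
  if (nrow(n) == 0) stop("empty tree")
  if (any(duplicated(n$id))) stop("duplicate node ids")
  roots <- which(is.na(n$parent))
  if (length(roots) != 1) stop("tree must have exactly one root")
  nonroot <- n$parent[!is.na(n$parent)]
  if (!all(nonroot %in% n$id)) stop("orphaned node: parent not in tree")
  # cycle check by walking each node to the root
  pmap <- stats::setNames(n$parent, n$id)
  for (id in n$id) {
    seen <- integer()
    cur <- id
    while (!is.na(pmap[[as.character(cur)]])) {
      if (cur %in% seen) stop("cycle detected")
      seen <- c(seen, cur)
      cur <- pmap[[as.character(cur)]]
      if (length(seen) > nrow(n)) stop("cycle detected")
    }
  }
  invisible(tree)
}

# integer vector of children ids of `id`
.children <- function(tree, id) {
  tree$nodes$id[!is.na(tree$nodes$parent) & tree$nodes$parent == id]
}

.root_id <- function(tree) tree$nodes$id[is.na(tree$nodes$parent)]

# physical length of the segment from each non-root node to its parent
.segment_lengths <- function(tree) {
  n <- tree$nodes
  idx <- match(n$parent, n$id)
  len <- sqrt((n$x - n$x[idx])^2 + (n$y - n$y[idx])^2 + (n$z - n$z[idx])^2)
  len[is.na(n$parent)] <- NA_real_
  len
}

#' @export
print.cell_tree <- function(x, ...) {
  nb <- sum(!is.na(x$nodes$parent))
  cat(sprintf("<cell_tree> soma %s: %d nodes, %d edges, %d pruned spur(s)\n",
              ifelse(is.na(x$soma_id), "?", x$soma_id), nrow(x$nodes), nb,
              nrow(x$spur)))
  invisible(x)
}

#' @export
summary.cell_tree <- function(object, ...) {
  n <- object$nodes
  root <- .root_id(object)
  kids <- table(factor(n$parent, levels = n$id))
  out <- list(
    nodes = nrow(n),
    primary_branches = sum(n$parent == root, na.rm = TRUE),
    branch_points = sum(kids > 1 & names(kids) != as.character(root)),
    total_length = sum(.segment_lengths(object)[n$parent != root],
                       na.rm = TRUE)
  )
  class(out) <- "summary.cell_tree"
  out
}

#' @export
print.summary.cell_tree <- function(x, ...) {
  cat(sprintf(
    "nodes: %d | primary branches: %d | branch points: %d | length: %.1f μm\n",
    x$nodes, x$primary_branches, x$branch_points, x$total_length))
  invisible(x)
}

#' @export
plot.cell_tree <- function(x, ..., add = FALSE, col = "grey20") {
  n <- x$nodes
  idx <- match(n$parent, n$id)
  ok <- !is.na(idx)
  if (!add)
    graphics::plot(n$x, n$y, type = "n", asp = 1, xlab = "x (μm)",
                   ylab = "y (μm)", ...)
  graphics::segments(n$x[ok], n$y[ok], n$x[idx[ok]], n$y[idx[ok]], col = col)
  root <- is.na(n$parent)
  graphics::points(n$x[root], n$y[root], pch = 19, col = "firebrick")
  invisible(x)
}

# depth-first order from the root, children visited in ascending id:
# guarantees every parent precedes its children
.topo_order <- function(tree) {
  n <- tree$nodes
  kids <- split(n$id[!is.na(n$parent)], n$parent[!is.na(n$parent)])
  out <- integer(nrow(n))
  stack <- .root_id(tree)
  k <- 0L
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- cur
    ch <- kids[[as.character(cur)]]
    if (!is.null(ch)) stack <- c(stack, sort(ch, decreasing = TRUE))
  }
  out
}

#' Write cell trees to an SWC file
#'
#' One concatenated SWC file: per tree the root is emitted first (tag 1,
#' parent -1) and every child after its parent; indices are contiguous from
#' 1 across the whole file. Coordinates and radii are written in micrometres
#' with six decimals, space-delimited, after a single `#` header line.
#' Unset radii are written as the 0.5 micrometre default.
#'
#' @param trees a `cell_tree` or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trees, path) {
  if (inherits(trees, "cell_tree")) trees <- list(trees)
  lines <- "# index tag x y z radius parent"
  offset <- 0L
  for (tr in trees) {
    validate_tree(tr)
    ord <- .topo_order(tr)
    n <- tr$nodes[match(ord, tr$nodes$id), , drop = FALSE]
    newid <- stats::setNames(seq_len(nrow(n)) + offset, n$id)
    par <- ifelse(is.na(n$parent), -1L, newid[as.character(n$parent)])
    rad <- ifelse(is.na(n$radius), 0.5, n$radius)
    lines <- c(lines, sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                              newid[as.character(n$id)], n$type,
                              n$x, n$y, n$z, rad, par))
    offset <- offset + nrow(n)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an SWC file
#'
#' Parses the 7-field whitespace-delimited format (`#` comments skipped) and
#' rebuilds one [cell_tree()] per root. Every non-root record must reference
#' an earlier index; a dangling or forward parent reference is an error.
#'
#' @param path SWC file.
#' @return list of `cell_tree` objects, in order of root appearance.
#' @export
read_swc <- function(path) {
  raw <- readLines(path)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (length(raw) == 0) stop("no records in SWC file")
  fields <- strsplit(raw, "[[:space:]]+")
  if (any(lengths(fields) != 7)) stop("malformed SWC row")
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("malformed SWC row")
  idx <- as.integer(m[, 1]); par <- as.integer(m[, 7])
  if (any(duplicated(idx))) stop("duplicate SWC indices")
  pos <- match(par, idx)
  bad <- par != -1L & (is.na(pos) | pos >= seq_along(idx))
  if (any(bad)) stop("dangling or forward parent index in SWC file")
  # assign tree membership by following parents back to the roots
  tree_of <- integer(length(idx))
  for (i in seq_along(idx))
    tree_of[i] <- if (par[i] == -1L) max(tree_of) + 1L else tree_of[pos[i]]
  lapply(seq_len(max(tree_of)), function(tn) {
    sel <- which(tree_of == tn)
    newid <- match(idx[sel], idx[sel])
    newpar <- ifelse(par[sel] == -1L, NA_integer_,
                     match(par[sel], idx[sel]))
    cell_tree(data.frame(id = newid, parent = newpar,
                         type = as.integer(m[sel, 2]),
                         x = m[sel, 3], y = m[sel, 4], z = m[sel, 5],
                         radius = m[sel, 6]))
  })
}
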