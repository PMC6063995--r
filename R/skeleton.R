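# Skeletons: rooted trees of 3D nodes in nm ----------------------------------

#' Construct a skeleton
#'
#' A rooted tree of 3D points with radii, SWC-backed; coordinates in nm.
#'
#' @param nodes data.frame with columns \code{id}, \code{type}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{parent} (parent id, -1 for the
#'   root). One root, unique ids, parents must exist, no cycles.
#' @return object of class \code{skeleton}.
#' @export
skeleton <- function(nodes) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nodes))) stopf("nodes need columns: %s", paste(req, collapse = ", "))
  nodes <- as.data.frame(nodes)[, req]
  for (cl in req) nodes[[cl]] <- as.numeric(nodes[[cl]])
  if (nrow(nodes) == 0) stopf("empty skeleton")
  if (anyDuplicated(nodes$id)) stopf("duplicate node ids")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stopf("non-finite coordinates")
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1)
    stopf("skeleton must have exactly one root (found %d)", length(roots))
  pidx <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1 & is.na(pidx))
  if (length(bad))
    stopf("node %s has undefined parent %s (line %d)",
          nodes$id[bad[1]], nodes$parent[bad[1]], bad[1])
  # cycle check: every node must reach the root
  depth <- rep(NA_integer_, nrow(nodes)); depth[roots] <- 0L
  for (pass in seq_len(nrow(nodes))) {
    upd <- which(is.na(depth) & !is.na(depth[pidx]))
    if (!length(upd)) break
    depth[upd] <- depth[pidx[upd]] + 1L
  }
  if (anyNA(depth)) stopf("parent links contain a cycle or disconnected nodes")
  structure(list(nodes = nodes), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d nodes, cable %.2f um\n", nrow(x$nodes),
              cable_length(x) / 1000))
  invisible(x)
}

skel_coords <- function(s) as.matrix(s$nodes[, c("x", "y", "z")])

# Edge list as (child row index, parent row index).
skel_edges <- function(s) {
  pidx <- match(s$nodes$parent, s$nodes$id)
  ch <- which(s$nodes$parent != -1)
  cbind(child = ch, parent = pidx[ch])
}

#' Total cable length of a skeleton
#' @param s \code{skeleton}.
#' @return sum of parent-child Euclidean distances, nm.
#' @export
cable_length <- function(s) {
  e <- skel_edges(s)
  if (nrow(e) == 0) return(0)
  xyz <- skel_coords(s)
  sum(sqrt(rowSums((xyz[e[, 1], , drop = FALSE] - xyz[e[, 2], , drop = FALSE])^2)))
}

#' Read a skeleton from an SWC file
#'
#' Seven whitespace-separated columns (id type x y z radius parent), \code{#}
#' comments allowed; coordinates interpreted as nm; root parent is -1.
#'
#' @param path SWC file path.
#' @return \code{skeleton}.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stopf("no data lines in %s", path)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nbad <- which(lengths(fields) != 7)
  if (length(nbad))
    stopf("SWC line %d does not have 7 columns", which(keep)[nbad[1]])
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stopf("non-numeric field in SWC file %s", path)
  skeleton(data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7]))
}

#' Write a skeleton to an SWC file
#'
#' @param s \code{skeleton}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_swc <- function(s, path) {
  n <- s$nodes
  lines <- sprintf("%s %s %s %s %s %s %s",
                   format(n$id, trim = TRUE, scientific = FALSE),
                   format(n$type, trim = TRUE, scientific = FALSE),
                   format(n$x, trim = TRUE, scientific = FALSE, digits = 15),
                   format(n$y, trim = TRUE, scientific = FALSE, digits = 15),
                   format(n$z, trim = TRUE, scientific = FALSE, digits = 15),
                   format(n$radius, trim = TRUE, scientific = FALSE, digits = 15),
                   format(n$parent, trim = TRUE, scientific = FALSE))
  writeLines(c("# SWC: id type x y z radius parent (nm)", lines), path)
  invisible(path)
}

# Children row indices per node row index.
skel_children <- function(s) {
  e <- skel_edges(s)
  split(e[, 1], factor(e[, 2], levels = seq_len(nrow(s$nodes))))
}

# Unbranched segments: each is a row-index path from a segment start (root or
# branch node) to the next branch node or leaf, inclusive.
skel_segments <- function(s) {
  ch <- skel_children(s)
  nch <- lengths(ch)
  root <- which(s$nodes$parent == -1)
  is_junction <- nch >= 2
  segs <- list()
  # starts: every child of the root and of each junction node
  starts <- unlist(lapply(which(is_junction | seq_along(nch) == root), function(v) ch[[v]]))
  for (st in starts) {
    path <- c(if (TRUE) match(s$nodes$parent[st], s$nodes$id), st)
    cur <- st
    while (nch[cur] == 1 && !is_junction[cur]) {
      cur <- ch[[cur]][1]
      path <- c(path, cur)
    }
    segs[[length(segs) + 1]] <- path
  }
  segs
}

# Root-to-leaf row-index paths.
skel_leaf_paths <- function(s) {
  ch <- skel_children(s)
  pidx <- match(s$nodes$parent, s$nodes$id)
  leaves <- which(lengths(ch) == 0)
  lapply(leaves, function(lf) {
    path <- lf
    while (!is.na(pidx[path[1]])) path <- c(pidx[path[1]], path)
    path
  })
}
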