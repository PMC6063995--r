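# Skeleton-based reconstruction QC metrics -----------------------------------

#' Resample a skeleton at a fixed arc-length interval
#'
#' Each unbranched segment is re-parameterized by arc length with node spacing
#' at most \code{interval}; branch nodes and end points are preserved, so the
#' tree topology is unchanged and (for intervals below the local node spacing)
#' total cable length is preserved.
#'
#' @param s \code{skeleton}.
#' @param interval spacing, nm (80 for agreement analysis, 1000 for geometry).
#' @return resampled \code{skeleton} (new sequential ids).
#' @export
resample_skeleton <- function(s, interval) {
  check_number(interval, "interval", positive = TRUE)
  xyz <- skel_coords(s)
  rad <- s$nodes$radius; typ <- s$nodes$type
  if (nrow(xyz) == 1) return(s)
  segs <- skel_segments(s)
  # process segments root-down so every segment start already has a new id
  pidx <- match(s$nodes$parent, s$nodes$id)
  depth <- rep(0L, nrow(xyz))
  repeat {
    nd <- ifelse(s$nodes$parent == -1, 0L, depth[pidx] + 1L)
    if (identical(nd, depth)) break
    depth <- nd
  }
  segs <- segs[order(vapply(segs, function(p) depth[p[1]], 0L))]
  # original preserved nodes: root, junctions, leaves
  keep <- sort(unique(c(which(s$nodes$parent == -1),
                        unlist(lapply(segs, function(p) p[c(1, length(p))])))))
  new_id_of <- rep(NA_integer_, nrow(xyz))
  out <- list(); nid <- 0L
  add_node <- function(x, y, z, r, t, parent_new) {
    nid <<- nid + 1L
    out[[nid]] <<- c(nid, t, x, y, z, r, parent_new)
    nid
  }
  root <- which(s$nodes$parent == -1)
  new_id_of[root] <- add_node(xyz[root, 1], xyz[root, 2], xyz[root, 3],
                              rad[root], typ[root], -1L)
  for (p in segs) {
    d <- sqrt(rowSums((xyz[p[-1], , drop = FALSE] - xyz[p[-length(p)], , drop = FALSE])^2))
    cs <- c(0, cumsum(d)); L <- cs[length(cs)]
    start <- p[1]; end <- p[length(p)]
    prev <- new_id_of[start]
    if (L > 0) {
      n_new <- max(1L, ceiling(L / interval))
      ss <- seq(0, L, length.out = n_new + 1)[-c(1, n_new + 1)]
      for (sv in ss) {
        j <- findInterval(sv, cs, rightmost.closed = TRUE)
        f <- if (d[j] > 0) (sv - cs[j]) / d[j] else 0
        a <- p[j]; b <- p[j + 1]
        prev <- add_node((1 - f) * xyz[a, 1] + f * xyz[b, 1],
                         (1 - f) * xyz[a, 2] + f * xyz[b, 2],
                         (1 - f) * xyz[a, 3] + f * xyz[b, 3],
                         (1 - f) * rad[a] + f * rad[b], typ[b], prev)
      }
    }
    new_id_of[end] <- add_node(xyz[end, 1], xyz[end, 2], xyz[end, 3],
                               rad[end], typ[end], prev)
  }
  m <- do.call(rbind, out)
  skeleton(data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7]))
}

#' Gaussian-smooth a skeleton along its arc length
#'
#' Coordinates are convolved with a Gaussian of standard deviation
#' \code{sigma} along the arc length of each root-to-leaf path (kernel
#' truncated at 3 sigma and renormalized); nodes shared by several paths take
#' the mean of their per-path smoothed positions. Topology is unchanged.
#'
#' @param s \code{skeleton}.
#' @param sigma kernel standard deviation, nm (default 12000 = 12 um).
#' @return smoothed \code{skeleton} (same ids and parents).
#' @export
smooth_skeleton <- function(s, sigma = 12000) {
  check_number(sigma, "sigma", positive = TRUE)
  xyz <- skel_coords(s)
  acc <- matrix(0, nrow(xyz), 3); cnt <- numeric(nrow(xyz))
  for (p in skel_leaf_paths(s)) {
    P <- xyz[p, , drop = FALSE]
    m <- nrow(P)
    d <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-m, , drop = FALSE])^2))
    cs <- c(0, cumsum(d))
    # mirror the path at both ends so boundary kernels stay symmetric (a
    # straight line is then exactly invariant and nodes do not slide along
    # the curve near endpoints)
    L <- cs[m]
    reach <- 3 * sigma + 2 * max(d, 1)   # mirrors extend past the kernel cut
    head_j <- which(cs - cs[1] <= reach & seq_len(m) > 1)
    tail_j <- which(L - cs <= reach & seq_len(m) < m)
    mir <- function(idx, n3) if (length(idx)) n3[idx, , drop = FALSE] else
      matrix(numeric(0), 0, ncol(n3))
    cs_aug <- c(2 * cs[1] - cs[head_j], cs, 2 * L - cs[tail_j])
    P_aug <- rbind(
      if (length(head_j)) matrix(2 * P[1, ], length(head_j), 3, byrow = TRUE) -
        mir(head_j, P) else matrix(numeric(0), 0, 3),
      P,
      if (length(tail_j)) matrix(2 * P[m, ], length(tail_j), 3, byrow = TRUE) -
        mir(tail_j, P) else matrix(numeric(0), 0, 3))
    # trapezoidal quadrature weights: unevenly spaced nodes (e.g. across a
    # misaligned section) must not bias the kernel average
    o <- order(cs_aug)
    cs_aug <- cs_aug[o]; P_aug <- P_aug[o, , drop = FALSE]
    na <- length(cs_aug)
    dseg <- diff(cs_aug)
    q <- c(dseg[1] / 2, (dseg[-1] + dseg[-length(dseg)]) / 2, dseg[length(dseg)] / 2)
    q <- pmax(q, 1e-12)
    sm <- matrix(0, m, 3)
    for (i in seq_len(m)) {
      in_win <- which(abs(cs_aug - cs[i]) <= 3 * sigma)
      w <- exp(-(cs_aug[in_win] - cs[i])^2 / (2 * sigma^2)) * q[in_win]
      sm[i, ] <- colSums(P_aug[in_win, , drop = FALSE] * w) / sum(w)
    }
    acc[p, ] <- acc[p, ] + sm
    cnt[p] <- cnt[p] + 1
  }
  out <- s
  out$nodes[, c("x", "y", "z")] <- acc / cnt
  out
}

#' Per-section alignment displacement from reconstructed skeletons
#'
#' Each skeleton is smoothed along its arc length; the distance from each
#' original node to its smoothed counterpart is pooled over all skeletons per
#' section (section index = round(z / section_thickness)), and the
#' displacement of a section is the absolute difference between its mean
#' distance and that of the preceding populated section. Spikes flag
#' misaligned sections.
#'
#' @param skeletons a \code{skeleton} or list of skeletons.
#' @param section_thickness nm per section (default 35).
#' @param sigma smoothing kernel sigma, nm (default 12000).
#' @return object of class \code{displacement_series}: data.frame
#'   \code{sections} (section, mean_dist_um), data.frame \code{displacements}
#'   (section, displacement_um), \code{median_um}, \code{p95_um}.
#' @export
section_displacement <- function(skeletons, section_thickness = 35, sigma = 12000) {
  if (inherits(skeletons, "skeleton")) skeletons <- list(skeletons)
  sec_all <- numeric(0); dist_all <- numeric(0)
  for (s in skeletons) {
    sm <- smooth_skeleton(s, sigma = sigma)
    d <- sqrt(rowSums((skel_coords(s) - skel_coords(sm))^2)) / 1000  # um
    sec_all <- c(sec_all, round(s$nodes$z / section_thickness))
    dist_all <- c(dist_all, d)
  }
  mu <- tapply(dist_all, sec_all, mean)
  secs <- as.integer(names(mu))
  o <- order(secs); secs <- secs[o]; mu <- as.numeric(mu[o])
  pair <- which(diff(secs) == 1L)
  if (!length(pair)) stopf("no consecutive populated section pair")
  disp <- abs(mu[pair + 1] - mu[pair])
  structure(list(sections = data.frame(section = secs, mean_dist_um = mu),
                 displacements = data.frame(section = secs[pair + 1],
                                            displacement_um = disp),
                 median_um = median(disp),
                 p95_um = as.numeric(quantile(disp, 0.95))),
            class = "displacement_series")
}

# Chunked nearest-neighbor distances from each row of A to the point set B.
nn_dist <- function(A, B, chunk = 512L) {
  out <- numeric(nrow(A))
  b2 <- rowSums(B^2)
  for (i0 in seq(1, nrow(A), by = chunk)) {
    ii <- i0:min(nrow(A), i0 + chunk - 1L)
    G <- A[ii, , drop = FALSE] %*% t(B)
    d2 <- outer(rowSums(A[ii, , drop = FALSE]^2), b2, `+`) - 2 * G
    out[ii] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Skeleton-to-skeleton agreement and error accounting
#'
#' Both skeletons are resampled at \code{resample_interval}; a test node is
#' consistent iff it lies within \code{match_radius} of some gold node. Gold
#' nodes with no test node within \code{match_radius} are "missed"; each
#' connected component of missed gold nodes (in the gold tree) counts as one
#' error, with its missed cable length measured along the gold tree. Cable
#' length per error is total gold cable / error count, optionally split by
#' backbone/twig node labels.
#'
#' @param test,gold \code{skeleton}s (test vs gold standard).
#' @param resample_interval nm (default 80).
#' @param match_radius nm (default 800).
#' @param backbone_labels optional vector of gold node ids (pre-resampling)
#'   labeled backbone; all other gold nodes are twigs.
#' @return object of class \code{agreement_report}: \code{n_errors},
#'   \code{missed_lengths_um}, \code{total_gold_cable_um}, \code{um_per_error},
#'   \code{n_inconsistent_test}, and optionally \code{by_class}.
#' @export
skeleton_agreement <- function(test, gold, resample_interval = 80,
                               match_radius = 800, backbone_labels = NULL) {
  tr <- resample_skeleton(test, resample_interval)
  gr <- resample_skeleton(gold, resample_interval)
  Tc <- skel_coords(tr); Gc <- skel_coords(gr)
  miss <- nn_dist(Gc, Tc) > match_radius
  incons <- sum(nn_dist(Tc, Gc) > match_radius)
  e <- skel_edges(gr)
  el <- sqrt(rowSums((Gc[e[, 1], , drop = FALSE] - Gc[e[, 2], , drop = FALSE])^2))
  total_um <- sum(el) / 1000
  # components of missed nodes in the gold tree
  parent <- seq_len(nrow(Gc))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  both <- miss[e[, 1]] & miss[e[, 2]]
  for (r in which(both)) {
    a <- find(e[r, 1]); b <- find(e[r, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(which(miss), find, 0L)
  comps <- split(which(miss), comp)
  lens <- vapply(comps, function(nodes) {
    sum(el[both & e[, 1] %in% nodes]) / 1000
  }, 0)
  n_err <- length(comps)
  rep <- list(n_errors = n_err,
              missed_lengths_um = unname(lens),
              total_gold_cable_um = total_um,
              um_per_error = if (n_err > 0) total_um / n_err else Inf,
              n_inconsistent_test = incons)
  if (!is.null(backbone_labels)) {
    lab0 <- gold$nodes$id %in% backbone_labels
    # label each resampled gold node by its nearest original gold node
    G0 <- skel_coords(gold)
    lab <- logical(nrow(Gc))
    for (i0 in seq(1, nrow(Gc), by = 512L)) {
      ii <- i0:min(nrow(Gc), i0 + 511L)
      d2 <- outer(rowSums(Gc[ii, , drop = FALSE]^2), rowSums(G0^2), `+`) -
        2 * Gc[ii, , drop = FALSE] %*% t(G0)
      lab[ii] <- lab0[apply(d2, 1, which.min)]
    }
    edge_bb <- lab[e[, 1]] & lab[e[, 2]]
    cable_bb <- sum(el[edge_bb]) / 1000
    err_bb <- sum(vapply(comps, function(nodes) mean(lab[nodes]) >= 0.5, TRUE))
    rep$by_class <- data.frame(
      class = c("backbone", "twig"),
      cable_um = c(cable_bb, total_um - cable_bb),
      errors = c(err_bb, n_err - err_bb),
      um_per_error = c(if (err_bb > 0) cable_bb / err_bb else Inf,
                       if (n_err - err_bb > 0) (total_um - cable_bb) / (n_err - err_bb) else Inf))
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d errors over %.1f um gold cable (%.1f um/error)\n",
              x$n_errors, x$total_gold_cable_um,
              if (is.finite(x$um_per_error)) x$um_per_error else NA))
  invisible(x)
}

#' Pairwise arbor distance between two skeletons
#'
#' Both skeletons are resampled; the forward distance is the mean over query
#' nodes of the distance to the nearest target node, the reverse distance the
#' same with roles swapped, and the pairwise distance the smaller of the two
#' (robust to one arbor being much longer).
#'
#' @param a,b \code{skeleton}s.
#' @param resample_interval nm (default 1000 = 1 um).
#' @return pairwise distance in um.
#' @export
pairwise_arbor_distance <- function(a, b, resample_interval = 1000) {
  ar <- resample_skeleton(a, resample_interval)
  br <- resample_skeleton(b, resample_interval)
  A <- skel_coords(ar); B <- skel_coords(br)
  fwd <- mean(nn_dist(A, B)); rev <- mean(nn_dist(B, A))
  min(fwd, rev) / 1000
}

#' Clip a skeleton to an axis-aligned box
#'
#' Nodes outside the box are removed; edges crossing the boundary are cut at
#' the intersection point (a new node is inserted there). The result may be a
#' forest; each connected component is re-rooted.
#'
#' @param s \code{skeleton}.
#' @param box numeric \code{c(xmin, xmax, ymin, ymax, zmin, zmax)}, nm.
#' @return object of class \code{skeleton_forest}: list \code{components} of
#'   \code{skeleton}s and logical \code{empty}.
#' @export
clip_to_box <- function(s, box) {
  if (length(box) != 6 || box[1] >= box[2] || box[3] >= box[4] || box[5] >= box[6])
    stopf("box must be c(xmin, xmax, ymin, ymax, zmin, zmax) with min < max")
  lo <- box[c(1, 3, 5)]; hi <- box[c(2, 4, 6)]
  xyz <- skel_coords(s); rad <- s$nodes$radius
  inside <- xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
    xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
    xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
  # clip each edge to the box (Liang-Barsky): returns NULL or two endpoints
  clip_seg <- function(p, q) {
    t0 <- 0; t1 <- 1; d <- q - p
    for (k in 1:3) {
      for (side in 1:2) {
        if (side == 1) { pk <- -d[k]; qk <- p[k] - lo[k] }
        else { pk <- d[k]; qk <- hi[k] - p[k] }
        if (pk == 0) { if (qk < 0) return(NULL) }
        else {
          tt <- qk / pk
          if (pk < 0) { if (tt > t1) return(NULL); if (tt > t0) t0 <- tt }
          else { if (tt < t0) return(NULL); if (tt < t1) t1 <- tt }
        }
      }
    }
    c(t0, t1)
  }
  pts <- list(); edges <- list()
  key_of <- rep(NA_integer_, nrow(xyz))
  add_pt <- function(coord, r) { pts[[length(pts) + 1]] <<- c(coord, r); length(pts) }
  for (i in which(inside)) key_of[i] <- add_pt(xyz[i, ], rad[i])
  e <- skel_edges(s)
  for (r in seq_len(nrow(e))) {
    ci <- e[r, 1]; pi <- e[r, 2]
    p <- xyz[pi, ]; q <- xyz[ci, ]
    tt <- clip_seg(p, q)
    if (is.null(tt) || tt[1] >= tt[2]) next
    a <- if (tt[1] == 0 && inside[pi]) key_of[pi] else add_pt(p + tt[1] * (q - p), (1 - tt[1]) * rad[pi] + tt[1] * rad[ci])
    b <- if (tt[2] == 1 && inside[ci]) key_of[ci] else add_pt(p + tt[2] * (q - p), (1 - tt[2]) * rad[pi] + tt[2] * rad[ci])
    edges[[length(edges) + 1]] <- c(a, b)
  }
  if (length(pts) == 0)
    return(structure(list(components = list(), empty = TRUE), class = "skeleton_forest"))
  P <- do.call(rbind, pts)
  n <- nrow(P)
  adj <- vector("list", n)
  for (ed in edges) {
    adj[[ed[1]]] <- c(adj[[ed[1]]], ed[2])
    adj[[ed[2]]] <- c(adj[[ed[2]]], ed[1])
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (st in seq_len(n)) {
    if (seen[st]) next
    # BFS from st: becomes the component root
    order_idx <- st; seen[st] <- TRUE
    par <- c(-1L); head_i <- 1L
    while (head_i <= length(order_idx)) {
      v <- order_idx[head_i]
      for (w in adj[[v]]) if (!seen[w]) {
        seen[w] <- TRUE
        order_idx <- c(order_idx, w)
        par <- c(par, head_i)  # parent position within component
      }
      head_i <- head_i + 1L
    }
    m <- length(order_idx)
    comps[[length(comps) + 1]] <- skeleton(data.frame(
      id = seq_len(m), type = 0,
      x = P[order_idx, 1], y = P[order_idx, 2], z = P[order_idx, 3],
      radius = P[order_idx, 4],
      parent = ifelse(par == -1L, -1L, par)))
  }
  structure(list(components = comps, empty = FALSE), class = "skeleton_forest")
}

#' Total active-bout time of tracing event logs
#'
#' Per user, events are split into active bouts wherever successive
#' timestamps differ by more than \code{gap}; a bout's duration is last minus
#' first timestamp (a single-event bout has duration 0). Returns the summed
#' duration over users and bouts, in hours.
#'
#' @param events data.frame with columns \code{user} and \code{timestamp}
#'   (seconds, or anything \code{as.numeric}-able such as POSIXct).
#' @param gap bout-splitting pause, seconds (default 180 = 3 min).
#' @return total active time in hours.
#' @export
active_bout_time <- function(events, gap = 180) {
  if (is.null(events) || nrow(events) == 0) return(0)
  ts <- as.numeric(events$timestamp)
  total <- 0
  for (u in unique(events$user)) {
    t <- sort(ts[events$user == u])
    brk <- c(0, which(diff(t) > gap), length(t))
    for (k in seq_len(length(brk) - 1)) {
      seg <- t[(brk[k] + 1):brk[k + 1]]
      total <- total + (max(seg) - min(seg))
    }
  }
  total / 3600
}

#' Read a tracing event log from CSV
#'
#' Expected columns: \code{user}, \code{neuron}, \code{timestamp} (ISO-8601 or
#' numeric seconds), \code{action}.
#'
#' @param path CSV path.
#' @return data.frame with numeric \code{timestamp} seconds.
#' @export
read_trace_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("user", "timestamp") %in% names(ev)))
    stopf("event log needs 'user' and 'timestamp' columns")
  if (is.character(ev$timestamp)) {
    suppressWarnings(num <- as.numeric(ev$timestamp))
    ev$timestamp <- if (anyNA(num))
      as.numeric(as.POSIXct(ev$timestamp, tz = "UTC")) else num
  }
  ev
}
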