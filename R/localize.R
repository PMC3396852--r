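#' Detect bright spherical fiducials in a volume
#'
#' Voxels above `threshold` are grouped into 26-connected components;
#' components smaller than `min_voxels` are discarded as noise; each
#' surviving component yields an intensity-weighted centroid in world mm.
#' Because a marker sphere straddles voxel boundaries, its image is a
#' cluster of mixed partial-volume intensities (appearing slightly oval on
#' anisotropic grids); weighting the centroid by intensity above the
#' background level recovers the sphere centre to a fraction of a voxel.
#' The background level is estimated as the median of sub-threshold
#' intensities, which makes the detections invariant to adding a constant
#' background below threshold.
#'
#' @param volume a [voxel_grid()].
#' @param threshold intensity cutoff separating marker voxels from
#'   background.
#' @param expected_count number of fiducials that must be found.
#' @param min_voxels smallest component kept (default 3 voxels, rejecting
#'   single-voxel noise while keeping small spheres at coarse spacing).
#' @return A data frame with one row per detection — the `expected_count`
#'   largest components by total (background-subtracted) intensity, sorted
#'   decreasing — and columns `x_mm`, `y_mm`, `z_mm` (weighted centroid),
#'   `voxel_count`, `total_intensity`.
#' @examples
#' arc <- fiducial_arc()
#' vol <- rasterize_spheres(arc, radius = 2.5)
#' head(detect_fiducials(vol, threshold = 50, expected_count = 9), 3)
#' @export
detect_fiducials <- function(volume, threshold, expected_count,
                             min_voxels = 3L) {
  stopifnot(inherits(volume, "voxel_grid"), expected_count >= 1L)
  arr <- volume$intensities
  fg <- which(arr > threshold)
  if (length(fg) == 0L) {
    stop("detection failure: found 0 fiducial candidates, expected ",
         expected_count, call. = FALSE)
  }
  below <- arr[arr <= threshold]
  background <- if (length(below)) stats::median(below) else 0
  comp <- connected_components(dim(arr), fg)

  rows <- lapply(comp, function(vox) {
    if (length(vox) < min_voxels) return(NULL)
    idx0 <- arrayInd(vox, dim(arr)) - 1L
    w <- arr[vox] - background
    w[w < 0] <- 0
    world <- voxel_to_world(volume, idx0)
    ctr <- colSums(world * w) / sum(w)
    data.frame(x_mm = ctr[1], y_mm = ctr[2], z_mm = ctr[3],
               voxel_count = length(vox), total_intensity = sum(w))
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) < expected_count) {
    stop(sprintf("detection failure: found %d fiducial candidates, expected %d",
                 if (is.null(rows)) 0L else nrow(rows), expected_count),
         call. = FALSE)
  }
  rows <- rows[order(rows$total_intensity, decreasing = TRUE), , drop = FALSE]
  rows <- rows[seq_len(expected_count), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

# 26-connected components over a set of linear voxel indices.
# Returns a list of integer vectors of linear indices.
connected_components <- function(dims, voxels) {
  if (length(voxels) == 0L) return(list())
  idx <- arrayInd(voxels, dims)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  # forward half of the 26-neighbourhood is enough for an undirected graph
  off <- off[off[, 3] > 0L | (off[, 3] == 0L & (off[, 2] > 0L |
             (off[, 2] == 0L & off[, 1] > 0L))), , drop = FALSE]
  pos <- match(voxels, voxels)  # identity, but keeps types aligned
  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nb <- sweep(idx, 2L, off[k, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1L) +
           dims[1] * dims[2] * (nb[ok, 3] - 1L)
    hit <- match(lin, voxels)
    keep <- !is.na(hit)
    if (!any(keep)) next
    edges[[k]] <- cbind(pos[ok][keep], hit[keep])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(voxels), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  split(voxels, memb)
}

#' Locate a cannula-tip hypointensity
#'
#' Post-operative scans show the cannula tip as a very small volume of
#' hypointensity (here, the centre of the infusate distribution). Within a
#' spherical region of interest, voxels are split into a darker and a
#' brighter class by Otsu's threshold; the darker-class voxels are grouped
#' into 26-connected components and the *unweighted* geometric centroid of
#' the largest component is returned in world mm — the centre of the dark
#' volume is taken as the tip location, with no intensity weighting.
#'
#' @param volume a [voxel_grid()].
#' @param roi_centre world-mm centre of the spherical region of interest
#'   (length-3 numeric).
#' @param roi_radius ROI radius in mm.
#' @return Named numeric vector `c(x=, y=, z=)`, world mm.
#' @export
locate_tip <- function(volume, roi_centre, roi_radius) {
  stopifnot(inherits(volume, "voxel_grid"),
            length(roi_centre) == 3L, roi_radius > 0)
  arr <- volume$intensities
  d <- dim(arr)
  # bounding box of the ROI in voxel indices
  lo <- floor(world_to_voxel(volume, matrix(roi_centre - roi_radius, 1, 3)))
  hi <- ceiling(world_to_voxel(volume, matrix(roi_centre + roi_radius, 1, 3)))
  lo <- pmax(as.integer(lo), 0L)
  hi <- pmin(as.integer(hi), d - 1L)
  if (any(lo > hi)) stop("ROI does not intersect the volume", call. = FALSE)
  idx0 <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  world <- voxel_to_world(volume, idx0)
  inside <- rowSums(sweep(world, 2L, roi_centre)^2) <= roi_radius^2
  if (!any(inside)) stop("ROI does not intersect the volume", call. = FALSE)
  idx0 <- idx0[inside, , drop = FALSE]
  lin <- idx0[, 1] + 1L + d[1] * idx0[, 2] + d[1] * d[2] * idx0[, 3]
  vals <- arr[lin]
  thr <- otsu_threshold(vals)
  if (is.na(thr)) {
    stop("tip not found: no hypointense component in the region of interest",
         call. = FALSE)
  }
  dark <- lin[vals <= thr]
  comp <- connected_components(d, sort(dark))
  sizes <- lengths(comp)
  vox <- comp[[which.max(sizes)]]
  ctr <- colMeans(voxel_to_world(volume, arrayInd(vox, d) - 1L))
  c(x = ctr[[1]], y = ctr[[2]], z = ctr[[3]])
}

# Otsu's between-class-variance threshold on a numeric vector.
# Returns NA for (near-)uniform input where no split exists.
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  if (!is.finite(between[k])) return(NA_real_)
  mids[k]
}

#' Order detections to match a reference fiducial geometry
#'
#' Detected fiducial centres come out in arbitrary order; registration
#' needs them in the reference arc's label order. After aligning the
#' centroids of the two sets (removing any gross translation), each
#' reference point is matched to a detected point by the optimal one-to-one
#' assignment minimizing the total squared distance (solved exactly with
#' the Hungarian algorithm). Matching is reliable whenever the inter-marker
#' spacing is large compared with localization noise.
#'
#' @param detected n x 3 numeric matrix of detected centres (world mm), a
#'   data frame with `x_mm`/`y_mm`/`z_mm` columns, or a [point_set()].
#' @param reference [point_set()] of the reference geometry (e.g.
#'   [fiducial_arc()]).
#' @param max_distance matches farther than this gate (mm, after centroid
#'   alignment) raise an ambiguous-match error. Default 10 mm.
#' @return A [point_set()] containing the detected coordinates re-ordered
#'   and re-labelled to follow `reference`.
#' @export
match_fiducials <- function(detected, reference, max_distance = 10) {
  stopifnot(inherits(reference, "point_set"))
  if (inherits(detected, "point_set")) {
    det <- detected$coords
  } else if (is.data.frame(detected)) {
    det <- as.matrix(detected[, c("x_mm", "y_mm", "z_mm")])
  } else {
    det <- matrix(as.numeric(detected), ncol = 3)
  }
  n <- n_points(reference)
  if (nrow(det) != n) {
    stop(sprintf("correspondence error: %d detections vs %d reference fiducials",
                 nrow(det), n), call. = FALSE)
  }
  ref <- reference$coords
  det_c <- sweep(det, 2L, colMeans(det))
  ref_c <- sweep(ref, 2L, colMeans(ref))
  # cost[i, j]: squared distance from reference i to detection j
  cost <- outer(rowSums(ref_c^2), rep(1, n)) +
          outer(rep(1, n), rowSums(det_c^2)) -
          2 * ref_c %*% t(det_c)
  assign <- solve_assignment(cost)
  dist <- sqrt(pmax(cost[cbind(seq_len(n), assign)], 0))
  if (any(dist > max_distance)) {
    bad <- which(dist > max_distance)
    stop(sprintf("ambiguous match: fiducial(s) %s beyond the %g mm gate (max %.2f mm)",
                 paste(reference$labels[bad], collapse = ", "),
                 max_distance, max(dist)), call. = FALSE)
  }
  point_set(det[assign, , drop = FALSE], labels = reference$labels)
}

# Exact linear-sum assignment (Hungarian algorithm, shortest augmenting
# path formulation, O(n^3)). Returns for each row the assigned column.
# No installed package exposes an assignment solver, so this small exact
# solver is kept internal.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 1L) return(1L)
  u <- numeric(n)          # row potentials, rows 1..n
  v <- numeric(n + 1L)     # column potentials, index j+1 for column j (0 virtual)
  p <- integer(n + 1L)     # p[j+1]: row currently assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])            # candidate real columns
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd] + 1L] <- j0
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      su <- which(used)
      p_su <- p[su]
      u[p_su[p_su > 0L]] <- u[p_su[p_su > 0L]] + delta
      v[su] <- v[su] - delta
      minv[!used[-1L]] <- minv[!used[-1L]] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  out[p[-1L]] <- seq_len(n)   # out[row] = column
  out
}
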