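#' Kd-tree radius search
#'
#' Finds, for each query point, all cloud points within the closed Euclidean
#' ball of radius `radius`.
#'
#' @param cloud A point cloud (the dataset the tree is built over).
#' @param query A length-3 vector or an M x 3 matrix / data frame of queries.
#' @param radius Search radius (same units as the cloud); must be positive.
#' @return For a single query, a sorted integer vector of row indices; for a
#'   matrix of queries, a list of such vectors.
#' @export
radius_search <- function(cloud, query, radius) {
  cloud <- as_point_cloud(cloud)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("radius must be a positive number")
  }
  single <- is.numeric(query) && is.null(dim(query))
  if (single) {
    if (length(query) != 3) abort("a single query must have 3 coordinates")
    query <- matrix(query, 1, 3)
  } else if (is.data.frame(query)) {
    query <- cloud_coords(as_point_cloud(query))
  } else {
    query <- as.matrix(query)
  }
  res <- cpp_radius_search(cloud_coords(cloud), query, radius)
  if (single) res[[1]] else res
}

#' Map silique labels from a sparse cloud onto the dense cloud
#'
#' The sparse-to-dense mapping stage: every dense point within `radius` of at
#' least one silique-labeled (label 1) sparse point is retained (union over
#' the silique seeds; stem seeds play no role). This recovers the dense canopy
#' silique cloud from a network-labeled downsampled cloud.
#'
#' @param sparse A labeled point cloud (the downsampled, segmented cloud).
#' @param dense The dense point cloud to recover from.
#' @param radius Search radius; the published value is 0.01 in cloud units.
#' @param normalize If `TRUE`, coordinates are scaled by the dense cloud's
#'   bounding-box diagonal before searching, so `radius` is interpreted in
#'   normalized units.
#' @return The retained subset of `dense` (no duplicates), with the dense row
#'   indices in attribute `"index"`.
#' @export
map_sparse_to_dense <- function(sparse, dense, radius = 0.01,
                                normalize = FALSE) {
  sparse <- as_point_cloud(sparse)
  dense <- as_point_cloud(dense)
  if (!is_labeled(sparse)) abort("`sparse` must carry labels")
  if (radius <= 0) abort("radius must be positive")
  seeds <- sparse[sparse$label == 1L, , drop = FALSE]
  if (nrow(seeds) == 0) {
    warn("no silique-labeled points in the sparse cloud; returning an empty cloud")
    out <- dense[integer(0), , drop = FALSE]
    attr(out, "index") <- integer(0)
    return(out)
  }
  dc <- cloud_coords(dense)
  qc <- cloud_coords(seeds)
  if (normalize) {
    diag_len <- sqrt(sum((apply(dc, 2, max) - apply(dc, 2, min))^2))
    dc <- dc / diag_len
    qc <- qc / diag_len
  }
  idx <- cpp_radius_union(dc, qc, radius)
  out <- as_point_cloud(dense[idx, , drop = FALSE])
  attr(out, "index") <- idx
  out
}
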