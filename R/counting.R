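#' Counting stage parameters
#'
#' All thresholds of the clustering + RANSAC line-fitting counting stage in one
#' validated record. Defaults follow the published configuration: a straight-
#' line model of width 0.03-0.05 m, an inlier distance band of 0.018 m, and at
#' least 200 points per fitted line; a fit collapsing below 200 points is
#' discarded and ends the cluster's fitting loop.
#'
#' @param cluster_tolerance Euclidean clustering distance threshold (m).
#' @param min_cluster_size Minimum points per cluster.
#' @param inlier_threshold Point-to-line inlier distance (m).
#' @param width_lo,width_hi Accepted line-model width band (m); width is the
#'   bounding-cylinder diameter of the inliers about the refit axis.
#' @param min_line_points Minimum consensus size per fitted line.
#' @param ransac_iterations RANSAC hypotheses per fit.
#' @param axial_gap A silique is a bounded segment, not an infinite line:
#'   consensus points are sorted along the fitted axis and split wherever
#'   consecutive projections gap by more than `axial_gap` (m); only the
#'   largest contiguous run is kept, so a line cannot swallow a distant,
#'   roughly collinear pod.
#' @param max_edge_fraction Maximum fraction of a line's inliers allowed in
#'   the outer third of the inlier band. A genuine pod's cross-section
#'   concentrates near its axis, so a fit whose residual mass piles toward the
#'   band edge (the signature of a single line forced through two crossing
#'   pods) is discarded.
#' @param scoring_band RANSAC hypotheses are ranked by the number of points in
#'   this tight core band (m) around the candidate axis rather than in the
#'   full inlier band: pod points concentrate near their axis, so a true pod
#'   axis outranks the bisector of two crossing pods, which spreads its
#'   consensus across the full band. The inlier set itself is always taken at
#'   `inlier_threshold`.
#' @param seed Integer seed for the RANSAC draws.
#' @return A `counting_params` list.
#' @export
counting_params <- function(cluster_tolerance = 0.02, min_cluster_size = 200,
                            inlier_threshold = 0.018, width_lo = 0.03,
                            width_hi = 0.05, min_line_points = 200,
                            ransac_iterations = 1000,
                            axial_gap = cluster_tolerance,
                            max_edge_fraction = 0.25,
                            scoring_band = inlier_threshold / 3,
                            seed = NULL) {
  stopifnot(cluster_tolerance > 0, min_cluster_size > 0, inlier_threshold > 0,
            width_lo > 0, width_lo < width_hi, min_line_points > 0,
            ransac_iterations > 0, axial_gap > 0, scoring_band > 0,
            scoring_band <= inlier_threshold,
            max_edge_fraction > 0, max_edge_fraction <= 1)
  structure(list(cluster_tolerance = cluster_tolerance,
                 axial_gap = axial_gap, scoring_band = scoring_band,
                 max_edge_fraction = max_edge_fraction,
                 min_cluster_size = as.integer(min_cluster_size),
                 inlier_threshold = inlier_threshold,
                 width_lo = width_lo, width_hi = width_hi,
                 min_line_points = as.integer(min_line_points),
                 ransac_iterations = as.integer(ransac_iterations),
                 seed = seed),
            class = "counting_params")
}

#' Euclidean cluster extraction
#'
#' Partitions a cloud into the connected components of the graph linking
#' points at distance `<= tolerance`, discarding components smaller than
#' `min_size`.
#'
#' @param cloud A point cloud (or data frame with x/y/z).
#' @param tolerance Distance threshold (m).
#' @param min_size Minimum cluster size to keep.
#' @return A list of strictly increasing integer row-index vectors, ordered by
#'   their smallest member; possibly empty.
#' @export
euclidean_cluster <- function(cloud, tolerance = 0.02, min_size = 200) {
  cloud <- as_point_cloud(cloud)
  comp <- cpp_euclidean_cluster(cloud_coords(cloud), tolerance)
  cl <- split(seq_along(comp), comp)
  cl <- cl[lengths(cl) >= min_size]
  cl <- unname(cl[order(vapply(cl, function(i) i[1], 1L))])
  cl
}

point_line_distance <- function(pts, anchor, direction) {
  rel <- sweep(pts, 2, anchor)
  t <- as.vector(rel %*% direction)
  sqrt(pmax(0, rowSums(rel^2) - t^2))
}

# keep the largest contiguous run of inliers along the line axis; runs are
# separated by projection gaps larger than `gap`
largest_axial_run <- function(pts, inl, anchor, direction, gap) {
  if (length(inl) < 2) return(inl)
  t <- as.vector(sweep(pts[inl, , drop = FALSE], 2, anchor) %*% direction)
  o <- order(t)
  brk <- which(diff(t[o]) > gap)
  run_id <- cumsum(c(1L, as.integer(seq_along(o)[-1] %in% (brk + 1L))))
  runs <- split(o, run_id)
  inl[sort(runs[[which.max(lengths(runs))]])]
}

#' Fit one silique line by RANSAC
#'
#' Draws `ransac_iterations` two-point line hypotheses, keeps the largest
#' consensus within `inlier_threshold`, refits the direction as the principal
#' axis through the inlier centroid, and recomputes the consensus about the
#' refit axis. Returns `NULL` when the final consensus falls below
#' `min_line_points` or the inlier width (bounding-cylinder diameter) lies
#' outside `[width_lo, width_hi]` -- the discarded-misidentification rule.
#'
#' @param points An M x 3 coordinate matrix (or point cloud).
#' @param params A [counting_params()].
#' @return A `line_model` list (`anchor`, unit `direction`, `inlier_indices`,
#'   `width`, `length`, `centroid`) or `NULL`.
#' @export
ransac_line <- function(points, params = counting_params()) {
  if (is.data.frame(points)) points <- cloud_coords(as_point_cloud(points))
  points <- as.matrix(points)
  if (nrow(points) < 2) abort("need at least two points to fit a line")
  fit <- ransac_line_candidate(points, params)
  if (is.null(fit)) return(NULL)
  finalize_line(points, fit$inliers, fit$anchor, fit$direction, params)
}

# one RANSAC draw + refit; returns the candidate line (anchor, unit direction,
# axially-trimmed full-band inlier indices) without the size/width checks
ransac_line_candidate <- function(points, params, subset = NULL) {
  sub <- subset %||% seq_len(nrow(points))
  if (length(sub) < 2) return(NULL)
  best <- cpp_ransac_line(points[sub, , drop = FALSE],
                          params$ransac_iterations, params$inlier_threshold,
                          params$scoring_band)
  if (best$count < 1) return(NULL)
  a <- points[sub[best$i], ]
  d <- points[sub[best$j], ] - a
  d <- d / sqrt(sum(d^2))
  # least-squares refit of the axis on the core-band consensus only: the full
  # band around one arm of two crossing pods also covers much of the partner,
  # and refitting on that bimodal set would drag the axis to the bisector
  ctr <- a
  for (it in 1:3) { # trimmed refit, iterated so the axis snaps onto one pod
    core <- which(point_line_distance(points, ctr, d) <= params$scoring_band)
    core <- largest_axial_run(points, core, ctr, d, params$axial_gap)
    if (length(core) < 2) {
      core <- which(point_line_distance(points, ctr, d) <=
                      params$inlier_threshold)
      core <- largest_axial_run(points, core, ctr, d, params$axial_gap)
      if (length(core) < 2) return(NULL)
    }
    ctr <- colMeans(points[core, , drop = FALSE])
    rel <- sweep(points[core, , drop = FALSE], 2, ctr)
    d <- eigen(crossprod(rel), symmetric = TRUE)$vectors[, 1]
  }
  if (d[3] < 0 || (d[3] == 0 && (d[1] < 0 || (d[1] == 0 && d[2] < 0)))) d <- -d
  inl <- which(point_line_distance(points, ctr, d) <= params$inlier_threshold)
  inl <- largest_axial_run(points, inl, ctr, d, params$axial_gap)
  if (length(inl) < 2) return(NULL)
  list(anchor = ctr, direction = d, inliers = inl)
}

finalize_line <- function(points, inl, ctr, d, params) {
  if (length(inl) < params$min_line_points) return(NULL)
  dist_final <- point_line_distance(points[inl, , drop = FALSE], ctr, d)
  width <- 2 * max(dist_final)
  if (width < params$width_lo || width > params$width_hi) return(NULL)
  # residual-concentration check: a real pod's cross-section concentrates
  # near its axis, while the bisector of two crossing pods piles residual
  # mass toward the band edge
  edge <- mean(dist_final > 2 / 3 * params$inlier_threshold)
  if (edge > params$max_edge_fraction) return(NULL)
  t <- as.vector(sweep(points[inl, , drop = FALSE], 2, ctr) %*% d)
  structure(list(anchor = ctr, direction = d, inlier_indices = inl,
                 width = width, length = diff(range(t)),
                 centroid = colMeans(points[inl, , drop = FALSE])),
            class = "line_model")
}

# distance of every point to the bounded axis of a candidate line (projection
# clamped to the candidate's inlier extent)
point_segment_axis_distance <- function(points, anchor, direction, t_range) {
  rel <- sweep(points, 2, anchor)
  t <- as.vector(rel %*% direction)
  tc <- pmin(pmax(t, t_range[1]), t_range[2])
  sqrt(pmax(0, rowSums(rel^2) - t^2 + (t - tc)^2))
}

# Multi-line recovery within one Euclidean cluster. Adhering pods cross at
# steep angles, so removing a recorded line's full 0.018 m inlier band would
# starve its partner. Instead: (1) detect candidate axes by repeated
# core-band-scored RANSAC, removing only the tight core of each detected axis
# and skipping candidates duplicating an already-detected axis; (2) assign
# every cluster point to the nearest detected axis within the inlier band;
# (3) keep the assigned, axially-trimmed sets that still satisfy the
# min-point and width rules.
fit_cluster_lines <- function(points, params) {
  n <- nrow(points)
  rem <- rep(TRUE, n)
  cands <- list()
  fails <- 0L
  cap <- ceiling(n / params$min_line_points) + 3L
  # detection keeps going below min_line_points unexplained points: a pod
  # whose core was eaten by an earlier candidate can still be a valid model,
  # since validity is judged on its full-band membership in the whole cluster
  floor_n <- max(2L, params$min_line_points %/% 4L)
  while (sum(rem) >= floor_n && fails < 4L && length(cands) < cap) {
    fit <- ransac_line_candidate(points, params, subset = which(rem))
    if (is.null(fit)) break
    t <- as.vector(sweep(points[fit$inliers, , drop = FALSE], 2,
                         fit$anchor) %*% fit$direction)
    cand <- list(anchor = fit$anchor, direction = fit$direction,
                 inliers = fit$inliers, t_range = range(t))
    ok_size <- length(fit$inliers) >= params$min_line_points
    # a diagonal refit through one pod's own noise is (near-)fully contained
    # in an existing model's inlier set, while a genuine crossing partner
    # keeps an exclusive far region; containment is density-independent
    contained <- FALSE
    if (length(cands) > 0) {
      explained <- unique(unlist(lapply(cands, `[[`, "inliers")))
      contained <- mean(fit$inliers %in% explained) >= 0.95
    }
    dup <- FALSE
    for (ex in cands) {
      ang_cos <- abs(sum(cand$direction * ex$direction))
      axis_d <- min(point_segment_axis_distance(
        matrix(cand$anchor, 1, 3), ex$anchor, ex$direction, ex$t_range))
      if (ang_cos > cos(12 * pi / 180) && axis_d < params$inlier_threshold) {
        dup <- TRUE
        break
      }
    }
    if (ok_size && !contained && !dup) {
      cands[[length(cands) + 1L]] <- cand
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
    core <- point_segment_axis_distance(points, cand$anchor, cand$direction,
                                        cand$t_range) <=
      params$inlier_threshold / 2
    core <- core & rem
    if (!any(core)) break
    rem[core] <- FALSE
  }
  if (length(cands) == 0) return(list())
  # nearest-axis assignment within the inlier band, with backward
  # elimination: an axis whose assigned, trimmed support fails the
  # minimum-point or width rule is dropped (weakest first) and its points are
  # reassigned -- a bisector of two crossing pods keeps only the crossing
  # sliver once the true arms exist, so it is pruned here
  D <- vapply(cands, function(cn)
    point_segment_axis_distance(points, cn$anchor, cn$direction, cn$t_range),
    numeric(n))
  D <- matrix(D, nrow = n)
  active <- seq_along(cands)
  repeat {
    Da <- D[, active, drop = FALSE]
    nearest <- max.col(-Da, ties.method = "first")
    nearest[Da[cbind(seq_len(n), nearest)] > params$inlier_threshold] <- 0L
    fits <- vector("list", length(active))
    sizes <- integer(length(active))
    for (ai in seq_along(active)) {
      idx <- which(nearest == ai)
      sizes[ai] <- length(idx)
      if (length(idx) < 2) next
      cn <- cands[[active[ai]]]
      # contiguity along the axis is judged on every point in the model's
      # inlier band (a pod continues underneath a crossing partner even
      # where the crossing points are assigned to the partner); membership
      # stays assignment-based
      band <- which(D[, active[ai]] <= params$inlier_threshold)
      run <- largest_axial_run(points, band, cn$anchor, cn$direction,
                               params$axial_gap)
      tr_run <- range(as.vector(sweep(points[run, , drop = FALSE], 2,
                                      cn$anchor) %*% cn$direction))
      ti <- as.vector(sweep(points[idx, , drop = FALSE], 2,
                            cn$anchor) %*% cn$direction)
      idx <- idx[ti >= tr_run[1] & ti <= tr_run[2]]
      if (length(idx) < 2) next
      # refit on the assigned set
      ctr <- colMeans(points[idx, , drop = FALSE])
      rel <- sweep(points[idx, , drop = FALSE], 2, ctr)
      d <- eigen(crossprod(rel), symmetric = TRUE)$vectors[, 1]
      if (d[3] < 0 || (d[3] == 0 && (d[1] < 0 || (d[1] == 0 && d[2] < 0)))) {
        d <- -d
      }
      fits[ai] <- list(finalize_line(points, idx, ctr, d, params))
    }
    bad <- which(vapply(fits, is.null, TRUE))
    if (length(bad) == 0 || length(active) == 1) break
    drop_ai <- bad[which.min(sizes[bad])]
    active <- active[-drop_ai]
  }
  fits[!vapply(fits, is.null, TRUE)]
}

#' Count siliques by clustering and iterative RANSAC line fitting
#'
#' Clusters the canopy cloud, then within each cluster repeatedly fits
#' core-band-scored RANSAC lines until fewer than `min_line_points`
#' unexplained points remain or fitting stops making progress; cluster points
#' are then assigned to the nearest fitted axis within `inlier_threshold`,
#' and assigned sets that still satisfy the minimum-point and width rules are
#' recorded (so two pods crossing in one cluster come out as two lines with
#' disjoint inlier sets). The number of returned lines is the silique count.
#'
#' @param cloud The dense canopy-silique point cloud.
#' @param params A [counting_params()].
#' @return A `silique_lines` tibble: one row per fitted pod with anchor,
#'   direction, inlier count, width, length, inlier centroid, originating
#'   cluster and an `inliers` list-column of cloud row indices. Attribute
#'   `"params"` carries the parameters used.
#' @export
count_siliques <- function(cloud, params = counting_params()) {
  cloud <- as_point_cloud(cloud)
  pts <- cloud_coords(cloud)
  with_seed_or_current(params$seed, {
    clusters <- euclidean_cluster(cloud, params$cluster_tolerance,
                                  params$min_cluster_size)
    rows <- list()
    for (ci in seq_along(clusters)) {
      cluster_idx <- clusters[[ci]]
      fits <- fit_cluster_lines(pts[cluster_idx, , drop = FALSE], params)
      for (fit in fits) {
        rows[[length(rows) + 1L]] <- tibble(
          cluster_id = ci,
          anchor_x = fit$anchor[1], anchor_y = fit$anchor[2],
          anchor_z = fit$anchor[3],
          dir_x = fit$direction[1], dir_y = fit$direction[2],
          dir_z = fit$direction[3],
          n_inliers = length(fit$inlier_indices),
          width = fit$width, length = fit$length,
          centroid_x = fit$centroid[1], centroid_y = fit$centroid[2],
          centroid_z = fit$centroid[3],
          inliers = list(cluster_idx[fit$inlier_indices])
        )
      }
    }
    out <- if (length(rows) == 0) {
      tibble(cluster_id = integer(), anchor_x = numeric(), anchor_y = numeric(),
             anchor_z = numeric(), dir_x = numeric(), dir_y = numeric(),
             dir_z = numeric(), n_inliers = integer(), width = numeric(),
             length = numeric(), centroid_x = numeric(), centroid_y = numeric(),
             centroid_z = numeric(), inliers = list())
    } else {
      dplyr::bind_rows(rows)
    }
    out <- dplyr::mutate(out, silique_id = dplyr::row_number(), .before = 1)
    class(out) <- unique(c("silique_lines", class(out)))
    attr(out, "params") <- params
    out
  })
}

#' Per-plant counting metrics
#'
#' Computes the per-plant identification precision `100 * correct / true`, the
#' column totals, the mean absolute percentage error of the counts and the
#' coefficient of determination of identity prediction
#' `1 - SS_res / SS_tot`.
#'
#' @param true Vector of true (manually counted) siliques per plant.
#' @param correct Vector of correctly identified siliques per plant
#'   (`correct <= true` elementwise).
#' @param plant_id Optional plant identifiers.
#' @return A `count_report` object; see [tidy.count_report()] and
#'   [glance.count_report()].
#' @export
counting_metrics <- function(true, correct, plant_id = NULL) {
  if (length(true) != length(correct)) {
    abort("`true` and `correct` must have the same length")
  }
  if (any(true <= 0) || any(correct < 0) || any(correct > true)) {
    abort("need positive `true` counts and 0 <= correct <= true")
  }
  plant_id <- plant_id %||% seq_along(true)
  per_plant <- tibble(
    plant_id = plant_id,
    true_count = as.integer(true),
    correct_count = as.integer(correct),
    missed_count = as.integer(true - correct),
    precision_percent = 100 * correct / true
  )
  totals <- list(true = sum(per_plant$true_count),
                 correct = sum(per_plant$correct_count),
                 missed = sum(per_plant$missed_count),
                 precision_percent = 100 * sum(correct) / sum(true))
  mape <- mean(100 * (true - correct) / true)
  r2 <- 1 - sum((true - correct)^2) / sum((true - mean(true))^2)
  structure(list(per_plant = per_plant, totals = totals,
                 mape_percent = mape, r_squared = r2),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat("Silique count report:", nrow(x$per_plant), "plants\n")
  cat(sprintf("  totals: true %d, correct %d, missed %d\n",
              x$totals$true, x$totals$correct, x$totals$missed))
  cat(sprintf("  precision %.2f%%, MAPE %.2f%%, R^2 %.4f\n",
              x$totals$precision_percent, x$mape_percent, x$r_squared))
  invisible(x)
}

#' Tidy a count report
#'
#' @param x A `count_report`.
#' @param ... Unused.
#' @return The per-plant tibble (one row per plant).
#' @export
tidy.count_report <- function(x, ...) x$per_plant

#' One-row summary of a count report
#'
#' @param x A `count_report`.
#' @param ... Unused.
#' @return A one-row tibble with totals, total precision, MAPE and R squared.
#' @export
glance.count_report <- function(x, ...) {
  tibble(n_plants = nrow(x$per_plant), true_total = x$totals$true,
         correct_total = x$totals$correct, missed_total = x$totals$missed,
         precision_percent = x$totals$precision_percent,
         mape_percent = x$mape_percent, r_squared = x$r_squared)
}
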