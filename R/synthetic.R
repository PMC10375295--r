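#' Synthetic plant specification
#'
#' Parameters of the ground-truthed rapeseed plant generator: a vertical noisy
#' stem plus `n_siliques` slender pod segments emanating outward and upward
#' from the canopy region, each rendered as points along a line segment with
#' Gaussian radial noise. Defaults mimic a mature plant at the silique stage:
#' a ~1 m stem, pods 5-8 cm long with a radial noise sigma of 5.5 mm, and a
#' dense cloud in the 10^5 range.
#'
#' @param n_siliques Number of pods.
#' @param stem_height Stem height in meters.
#' @param stem_radius Stem radial jitter sigma (m).
#' @param silique_length_range Pod length interval (m).
#' @param silique_radius Pod radial noise sigma (m); keep `<= 0.006` so that
#'   essentially all pod points fall within the 0.018 m RANSAC inlier band.
#' @param points_per_silique Points rendered per pod.
#' @param stem_points Points rendered on the stem.
#' @param adhesion_fraction Fraction of pods placed crossing a neighbour at
#'   40-80 degrees (the adhering-pod case).
#' @param canopy_range Fractions of `stem_height` between which pod bases sit.
#' @param base_offset_range Radial offset of pod bases from the stem axis (m),
#'   standing in for the unmodelled branch/pedicel geometry.
#' @param clearance Minimum axis-to-axis distance between non-adhering pods
#'   (m); at least twice the default RANSAC inlier threshold.
#' @param seed Integer seed.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(n_siliques = 120, stem_height = 1.0, stem_radius = 0.004,
                       silique_length_range = c(0.05, 0.08),
                       silique_radius = 0.0055, points_per_silique = 1800,
                       stem_points = 34000, adhesion_fraction = 0,
                       canopy_range = c(0.5, 0.95),
                       base_offset_range = c(0.04, 0.22),
                       clearance = 0.045, seed = NULL) {
  stopifnot(n_siliques >= 0, stem_height > 0, stem_radius > 0,
            all(silique_length_range > 0), silique_radius > 0,
            points_per_silique > 0, stem_points > 0,
            adhesion_fraction >= 0, adhesion_fraction <= 1, clearance > 0)
  structure(list(n_siliques = as.integer(n_siliques),
                 stem_height = stem_height, stem_radius = stem_radius,
                 silique_length_range = silique_length_range,
                 silique_radius = silique_radius,
                 points_per_silique = as.integer(points_per_silique),
                 stem_points = as.integer(stem_points),
                 adhesion_fraction = adhesion_fraction,
                 canopy_range = canopy_range,
                 base_offset_range = base_offset_range,
                 clearance = clearance, seed = seed),
            class = "plant_spec")
}

# Minimum distance between segment (p1,p2) and segments (q1[m,], q2[m,]);
# vectorised closest-point-between-segments.
segment_segment_distance <- function(p1, p2, q1, q2) {
  q1 <- matrix(q1, ncol = 3); q2 <- matrix(q2, ncol = 3)
  d1 <- p2 - p1
  d2 <- q2 - q1
  r <- matrix(p1, nrow(q1), 3, byrow = TRUE) - q1
  a <- sum(d1 * d1)
  e <- rowSums(d2 * d2)
  f <- rowSums(d2 * r)
  cc <- as.vector(r %*% d1) # dot(d1, p1 - q1) per segment
  b <- as.vector(d2 %*% d1)
  denom <- a * e - b * b
  s <- ifelse(denom > 1e-300, pmin(pmax((b * f - cc * e) / denom, 0), 1), 0)
  t <- (b * s + f) / e
  tlo <- t < 0
  thi <- t > 1
  t <- pmin(pmax(t, 0), 1)
  s[tlo] <- pmin(pmax(-cc[tlo] / a, 0), 1)
  s[thi] <- pmin(pmax((b[thi] - cc[thi]) / a, 0), 1)
  cp <- matrix(p1, nrow(q1), 3, byrow = TRUE) + outer(s, d1)
  cq <- q1 + d2 * t
  sqrt(rowSums((cp - cq)^2))
}

rand_unit_perp <- function(d) {
  # a unit vector perpendicular to d, rotated by a random angle about d
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  th <- runif(1, 0, 2 * pi)
  cos(th) * u + sin(th) * v
}

#' Generate a ground-truthed synthetic rapeseed plant
#'
#' Builds a labeled dense cloud (stem = 0, silique = 1) together with the true
#' pod axes, for validating segmentation, mapping and counting without real
#' scans. Non-adhering pods keep a pairwise axis clearance of at least
#' `spec$clearance`; adhering pods are placed crossing a partner pod at
#' 40-80 degrees.
#'
#' @param spec A [plant_spec()].
#' @return A list with elements `cloud` (labeled `point_cloud`) and `truth`
#'   (tibble of true segments: `silique_id`, base/tip coordinates, `length`,
#'   `adheres_to`).
#' @export
make_plant <- function(spec = plant_spec()) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed_or_current(spec$seed, make_plant_impl(spec))
}

make_plant_impl <- function(spec) {
  n_adh <- round(spec$adhesion_fraction * spec$n_siliques)
  if (n_adh > 0 && spec$n_siliques < 2) n_adh <- 0
  n_free <- spec$n_siliques - n_adh
  bases <- tips <- matrix(NA_real_, spec$n_siliques, 3)
  partner <- rep(NA_integer_, spec$n_siliques)
  lens <- numeric(spec$n_siliques)
  max_try <- 400L
  zlo <- spec$canopy_range[1] * spec$stem_height
  zhi <- spec$canopy_range[2] * spec$stem_height
  for (i in seq_len(spec$n_siliques)) {
    adhering <- i > n_free
    placed <- FALSE
    for (try in seq_len(max_try)) {
      len <- runif(1, spec$silique_length_range[1], spec$silique_length_range[2])
      if (!adhering) {
        h <- runif(1, zlo, zhi)
        phi <- runif(1, 0, 2 * pi)
        rho <- runif(1, spec$base_offset_range[1], spec$base_offset_range[2])
        out <- c(cos(phi), sin(phi), 0)
        alpha <- runif(1, 20, 70) * pi / 180 # elevation above horizontal
        dir <- cos(alpha) * out + sin(alpha) * c(0, 0, 1)
        tang <- runif(1, -0.3, 0.3) * c(-sin(phi), cos(phi), 0)
        dir <- dir + tang
        dir <- dir / sqrt(sum(dir^2))
        base <- c(rho * cos(phi), rho * sin(phi), h)
        tip <- base + len * dir
      } else {
        p <- sample.int(n_free, 1)
        pd <- (tips[p, ] - bases[p, ]) / lens[p]
        q <- bases[p, ] + runif(1, 0.3, 0.7) * lens[p] * pd
        theta <- runif(1, 40, 80) * pi / 180
        perp <- rand_unit_perp(pd)
        dir <- cos(theta) * pd + sin(theta) * perp
        off <- runif(1, 0, 0.003) * rand_unit_perp(dir)
        mid <- q + off
        base <- mid - runif(1, 0.35, 0.65) * len * dir
        tip <- base + len * dir
        partner[i] <- p
      }
      ok <- TRUE
      prev <- seq_len(i - 1)
      prev <- prev[!is.na(bases[prev, 1])]
      if (!adhering) prev_chk <- prev else prev_chk <- setdiff(prev, partner[i])
      if (length(prev_chk) > 0) {
        dmin <- segment_segment_distance(base, tip,
                                         bases[prev_chk, , drop = FALSE],
                                         tips[prev_chk, , drop = FALSE])
        ok <- all(dmin >= spec$clearance)
      }
      if (ok) {
        bases[i, ] <- base
        tips[i, ] <- tip
        lens[i] <- len
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(paste0("could not place silique ", i, " with clearance ",
                   spec$clearance, " m after ", max_try, " tries"))
    }
  }
  # stem points: vertical axis with radial Gaussian jitter
  sz <- runif(spec$stem_points, 0, spec$stem_height)
  sphi <- runif(spec$stem_points, 0, 2 * pi)
  srad <- abs(rnorm(spec$stem_points, 0, spec$stem_radius))
  stem <- cbind(srad * cos(sphi), srad * sin(sphi), sz)
  # silique points: uniform along each axis + 2-D Gaussian radial noise
  sil <- vector("list", spec$n_siliques)
  for (i in seq_len(spec$n_siliques)) {
    d <- (tips[i, ] - bases[i, ]) / lens[i]
    ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * d) * d
    u <- u / sqrt(sum(u^2))
    v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    t <- runif(spec$points_per_silique, 0, lens[i])
    n1 <- rnorm(spec$points_per_silique, 0, spec$silique_radius)
    n2 <- rnorm(spec$points_per_silique, 0, spec$silique_radius)
    sil[[i]] <- matrix(bases[i, ], spec$points_per_silique, 3, byrow = TRUE) +
      outer(t, d) + outer(n1, u) + outer(n2, v)
  }
  coords <- rbind(stem, do.call(rbind, sil))
  labels <- c(rep(0L, spec$stem_points),
              rep(1L, spec$n_siliques * spec$points_per_silique))
  cloud <- point_cloud(coords[, 1], coords[, 2], coords[, 3], label = labels)
  truth <- tibble(
    silique_id = seq_len(spec$n_siliques),
    base_x = bases[, 1], base_y = bases[, 2], base_z = bases[, 3],
    tip_x = tips[, 1], tip_y = tips[, 2], tip_z = tips[, 3],
    length = lens, adheres_to = partner
  )
  list(cloud = cloud, truth = truth, spec = spec)
}

#' Generate a synthetic video frame sequence
#'
#' Renders a fixed random texture under a slowly varying similarity transform
#' (rotation plus drift per frame); the frames named in `blur_indices` are
#' additionally Gaussian-blurred, emulating motion blur from hand shake.
#' Ground truth (blur set, per-frame transform) is attached as attribute
#' `"truth"`.
#'
#' @param n_frames Number of frames.
#' @param blur_indices 0-based indices of frames to blur.
#' @param texture_seed Integer seed for the texture and motion.
#' @param size Image side length in pixels.
#' @param rot_per_frame Rotation per frame in degrees.
#' @param drift_per_frame Translation per frame in pixels.
#' @param blur_sigma Gaussian sigma (pixels) applied to blurred frames.
#' @return A list of [image_frame()] objects with indices `0:(n_frames-1)`.
#' @export
make_frame_sequence <- function(n_frames, blur_indices = integer(),
                                texture_seed = 0, size = 128,
                                rot_per_frame = 1.2, drift_per_frame = 0.4,
                                blur_sigma = 3) {
  stopifnot(n_frames >= 1)
  blur_indices <- as.integer(blur_indices)
  if (length(blur_indices) > 0 &&
      (min(blur_indices) < 0 || max(blur_indices) >= n_frames)) {
    abort("blur_indices must lie in [0, n_frames)")
  }
  with_seed_or_current(texture_seed, {
    tex <- matrix(runif(size * size), size, size)
    tex <- cpp_gauss_blur(tex, 1.2)
    tex <- (tex - min(tex)) / (max(tex) - min(tex)) * 255
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      ang <- (t - 1) * rot_per_frame * pi / 180
      tx <- (t - 1) * drift_per_frame
      px <- cpp_warp_similarity(tex, ang, 1.0, tx * 0.6, tx * 0.3)
      if ((t - 1L) %in% blur_indices) px <- cpp_gauss_blur(px, blur_sigma)
      frames[[t]] <- image_frame(t - 1L, px)
    }
    attr(frames, "truth") <- tibble(index = 0:(n_frames - 1),
                                    blurred = (0:(n_frames - 1)) %in% blur_indices,
                                    angle_deg = (0:(n_frames - 1)) * rot_per_frame)
    frames
  })
}

#' Match recovered silique lines to generator ground truth
#'
#' Greedy one-to-one matching of fitted lines (by decreasing consensus size)
#' to true pod axes: a line matches the nearest true segment whose axis lies
#' within `max_dist` of the line's inlier centroid and within `max_angle`
#' degrees of its direction. Used to score counting runs on synthetic plants.
#'
#' @param lines A `silique_lines` tibble from [count_siliques()].
#' @param truth The `truth` tibble from [make_plant()].
#' @param max_dist Maximum centroid-to-axis distance (m) for a match.
#' @param max_angle Maximum direction angle (degrees) for a match.
#' @return A list: `n_true`, `n_lines`, `n_recovered`, `n_spurious`,
#'   `recovery_percent`, `spurious_percent` and the per-line match table.
#' @export
evaluate_counting <- function(lines, truth, max_dist = 0.012, max_angle = 15) {
  n_true <- nrow(truth)
  n_lines <- nrow(lines)
  if (n_lines == 0) {
    return(list(n_true = n_true, n_lines = 0L, n_recovered = 0L,
                n_spurious = 0L, recovery_percent = 0,
                spurious_percent = 0, matches = tibble()))
  }
  bases <- as.matrix(truth[, c("base_x", "base_y", "base_z")])
  tips <- as.matrix(truth[, c("tip_x", "tip_y", "tip_z")])
  tdir <- (tips - bases) / truth$length
  ord <- order(-lines$n_inliers)
  taken <- rep(FALSE, n_true)
  match_id <- rep(NA_integer_, n_lines)
  match_d <- rep(NA_real_, n_lines)
  for (i in ord) {
    ctr <- c(lines$centroid_x[i], lines$centroid_y[i], lines$centroid_z[i])
    d <- segment_segment_distance(ctr, ctr + 1e-9 * c(0, 0, 1), bases, tips)
    ang <- acos(pmin(1, abs(tdir %*% c(lines$dir_x[i], lines$dir_y[i],
                                       lines$dir_z[i])))) * 180 / pi
    cand <- which(!taken & d <= max_dist & ang <= max_angle)
    if (length(cand) > 0) {
      best <- cand[which.min(d[cand])]
      taken[best] <- TRUE
      match_id[i] <- best
      match_d[i] <- d[best]
    }
  }
  n_rec <- sum(!is.na(match_id))
  list(n_true = n_true, n_lines = n_lines, n_recovered = n_rec,
       n_spurious = n_lines - n_rec,
       recovery_percent = 100 * n_rec / max(1, n_true),
       spurious_percent = 100 * (n_lines - n_rec) / max(1, n_lines),
       matches = tibble(silique_id = lines$silique_id,
                        matched_true = match_id, dist = match_d))
}
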