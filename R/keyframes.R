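#' Video frame objects
#'
#' A frame is its 0-based position in the sequence plus an 8-bit intensity
#' grid: either a grayscale matrix or an H x W x 3 color array, values in
#' `[0, 255]`. The Laplacian-variance sharpness value is computed lazily and
#' cached.
#'
#' @param index Non-negative integer frame position.
#' @param pixels Numeric matrix (grayscale) or H x W x 3 array, values 0-255.
#' @return An `image_frame` object.
#' @export
image_frame <- function(index, pixels) {
  index <- as.integer(index)
  if (is.na(index) || index < 0) abort("frame index must be a non-negative integer")
  if (!is.numeric(pixels) || length(pixels) == 0) abort("pixels must be numeric")
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3 &&
                                dim(pixels)[3] %in% c(1, 3)))) {
    abort("pixels must be a matrix or an H x W x 3 array")
  }
  structure(list(index = index, pixels = pixels, sharpness = NULL),
            class = "image_frame")
}

# ITU-R BT.601 luma conversion; grayscale input passes through.
to_gray <- function(pixels) {
  if (is.matrix(pixels)) return(pixels)
  if (dim(pixels)[3] == 1) return(pixels[, , 1])
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

laplacian_kernel <- function() {
  matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
}

#' Laplacian-variance sharpness score
#'
#' Blur metric for frame rejection: the image is bilateral-filtered (noise
#' removal that preserves edges), converted to grayscale, convolved with the
#' 4-neighbour Laplacian kernel (reflect border), and scored by the population
#' variance of the response. Blurry frames lose high-frequency content and
#' score low; a constant image scores exactly 0.
#'
#' @param pixels A frame's pixel grid (matrix or H x W x 3 array, 0-255), or
#'   an [image_frame()].
#' @param bilateral_d Bilateral filter window diameter (pixels).
#' @param sigma_color Bilateral range sigma (intensity units).
#' @param sigma_space Bilateral spatial sigma (pixels).
#' @return The non-negative sharpness value.
#' @export
sharpness_score <- function(pixels, bilateral_d = 9, sigma_color = 75,
                            sigma_space = 75) {
  if (inherits(pixels, "image_frame")) pixels <- pixels$pixels
  d <- dim(pixels)
  if (is.null(d) || d[1] < 3 || d[2] < 3) {
    abort("sharpness_score needs an image of at least 3 x 3 pixels")
  }
  if (is.matrix(pixels)) {
    filtered <- cpp_bilateral(pixels, bilateral_d, sigma_color, sigma_space)
  } else {
    filtered <- pixels
    for (ch in seq_len(d[3])) {
      filtered[, , ch] <- cpp_bilateral(pixels[, , ch], bilateral_d,
                                        sigma_color, sigma_space)
    }
  }
  gray <- to_gray(filtered)
  lap <- cpp_conv3_reflect(gray, laplacian_kernel())
  mean((lap - mean(lap))^2)
}

frame_sharpness <- function(frame, ...) {
  frame$sharpness %||% sharpness_score(frame$pixels, ...)
}

#' Detect corner features and patch descriptors
#'
#' The built-in pluggable detector: Harris corner response (Sobel gradients,
#' Gaussian-smoothed structure tensor, k = 0.04), 3 x 3 non-maximum
#' suppression, strongest `max_keypoints` corners, each described by its
#' mean/contrast-normalized square intensity patch.
#'
#' @param gray A grayscale matrix (0-255).
#' @param max_keypoints Maximum number of corners to keep.
#' @param patch Descriptor patch side length (odd).
#' @return A list with `keypoints` (tibble of `row`, `col`, `response`) and
#'   `descriptors` (one row per keypoint).
#' @export
detect_features <- function(gray, max_keypoints = 200, patch = 11) {
  stopifnot(is.matrix(gray), patch %% 2 == 1)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) # d/dcol
  ix <- cpp_conv3_reflect(gray, sx)
  iy <- cpp_conv3_reflect(gray, t(sx))
  sxx <- cpp_gauss_blur(ix * ix, 1.5)
  syy <- cpp_gauss_blur(iy * iy, 1.5)
  sxy <- cpp_gauss_blur(ix * iy, 1.5)
  resp <- (sxx * syy - sxy^2) - 0.04 * (sxx + syy)^2
  nr <- nrow(gray); nc <- ncol(gray)
  rad <- (patch - 1) / 2
  # 3x3 non-max suppression
  is_max <- resp > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs, cs] <- resp[rs - dr, cs - dc]
    is_max <- is_max & (resp >= shifted)
  }
  is_max[c(seq_len(rad), nr - seq_len(rad) + 1), ] <- FALSE
  is_max[, c(seq_len(rad), nc - seq_len(rad) + 1)] <- FALSE
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(list(keypoints = tibble(row = integer(), col = integer(),
                                   response = numeric()),
                descriptors = matrix(numeric(), 0, patch^2)))
  }
  rv <- resp[hits]
  keep <- head(order(-rv), max_keypoints)
  hits <- hits[keep, , drop = FALSE]
  desc <- matrix(NA_real_, nrow(hits), patch^2)
  for (i in seq_len(nrow(hits))) {
    p <- gray[hits[i, 1] + (-rad:rad), hits[i, 2] + (-rad:rad)]
    p <- p - mean(p)
    nrm <- sqrt(sum(p^2))
    desc[i, ] <- if (nrm > 1e-12) as.vector(p) / nrm else as.vector(p)
  }
  list(keypoints = tibble(row = hits[, 1], col = hits[, 2],
                          response = resp[hits]),
       descriptors = desc)
}

match_result <- function(matches, match_num) {
  similarity <- if (matches > 0) 100 * match_num / matches else 0
  structure(list(matches = as.integer(matches),
                 match_num = as.integer(match_num),
                 similarity = similarity),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("frame similarity: %d/%d ratio-test matches -> %.1f\n",
              x$match_num, x$matches, x$similarity))
  invisible(x)
}

#' Feature-matching similarity between two frames
#'
#' Both frames are converted to grayscale, features are detected and
#' described, each descriptor of `frame_a` is matched to its two nearest
#' neighbours in `frame_b`, and Lowe's ratio test at `ratio_threshold` keeps
#' the unambiguous matches. The similarity is
#' `100 * MatchNum / Matches`, where `Matches` counts the candidate 2-NN
#' pairs before the ratio test and `MatchNum` those surviving it.
#'
#' @param frame_a,frame_b [image_frame()] objects (or pixel grids).
#' @param ratio_threshold Ratio-test threshold in (0, 1); the standard
#'   empirical value is 0.7.
#' @param detector Pluggable detector function with the signature of
#'   [detect_features()].
#' @param max_keypoints Passed to the detector.
#' @return A `match_result` with fields `matches`, `match_num`, `similarity`.
#' @export
frame_similarity <- function(frame_a, frame_b, ratio_threshold = 0.7,
                             detector = detect_features, max_keypoints = 200) {
  pa <- if (inherits(frame_a, "image_frame")) frame_a$pixels else frame_a
  pb <- if (inherits(frame_b, "image_frame")) frame_b$pixels else frame_b
  fa <- detector(to_gray(pa), max_keypoints = max_keypoints)
  fb <- detector(to_gray(pb), max_keypoints = max_keypoints)
  na <- nrow(fa$descriptors); nb <- nrow(fb$descriptors)
  if (na == 0 || nb == 0) {
    warn("no features detected in one of the frames")
    return(match_result(0, 0))
  }
  # squared descriptor distances a -> b
  d2 <- outer(rowSums(fa$descriptors^2), rowSums(fb$descriptors^2), "+") -
    2 * tcrossprod(fa$descriptors, fb$descriptors)
  d2 <- pmax(d2, 0)
  matches <- na
  if (nb == 1) {
    match_num <- na # no second neighbour to disambiguate against
  } else {
    match_num <- 0L
    for (i in seq_len(na)) {
      two <- sort.int(d2[i, ], partial = 2)[1:2]
      if (sqrt(two[1]) <= ratio_threshold * sqrt(two[2]) || two[1] < 1e-18) {
        match_num <- match_num + 1L
      }
    }
  }
  match_result(matches, match_num)
}

#' Keyframe selection parameters
#'
#' @param interval_k Sampling stride K between an accepted keyframe and the
#'   next candidate.
#' @param s1,s2 Lower / upper similarity bounds of the acceptance band (0-100):
#'   below `s1` the candidate is too dissimilar (view gap), above `s2` too
#'   redundant.
#' @param step_i Fine-adjustment stride (`< interval_k`).
#' @param blur_threshold Minimum sharpness; `NULL` (default) calibrates it per
#'   sequence as the 10th percentile of the frames' sharpness scores.
#' @param ratio_threshold Ratio-test threshold for the similarity computation.
#' @return A `keyframe_params` list.
#' @export
keyframe_params <- function(interval_k, s1 = 25, s2 = 65,
                            step_i = max(1, interval_k %/% 5),
                            blur_threshold = NULL, ratio_threshold = 0.7) {
  stopifnot(interval_k >= 1, s1 >= 0, s2 <= 100, s1 < s2,
            step_i >= 1, step_i < interval_k,
            ratio_threshold > 0, ratio_threshold < 1)
  structure(list(interval_k = as.integer(interval_k), s1 = s1, s2 = s2,
                 step_i = as.integer(step_i), blur_threshold = blur_threshold,
                 ratio_threshold = ratio_threshold),
            class = "keyframe_params")
}

default_keyframe_params <- function(n_frames) {
  k <- max(2L, as.integer(round(n_frames / 120)))
  keyframe_params(interval_k = k, step_i = max(1L, k %/% 5L))
}

#' Select keyframes from a frame sequence
#'
#' Walks the sequence per the similarity-band rule: the first sharp frame
#' starts the selection; from each accepted frame the candidate at distance
#' `interval_k` is tested (blurred frames are skipped); a candidate whose
#' similarity to the previous accepted keyframe falls in `[s1, s2]` is
#' accepted, one above `s2` (too redundant) is advanced by `step_i`, one below
#' `s1` (too dissimilar) is retreated by `step_i`. Selection stops when the
#' sequence is exhausted. If the +/- `step_i` adjustment revisits a tested
#' frame, the walk jumps forward by `interval_k` past the highest tested
#' position (oscillation guard).
#'
#' @param frames List of [image_frame()] objects, in sequence order.
#' @param params A [keyframe_params()]; `NULL` uses sequence-derived defaults
#'   (`K = max(2, round(n/120))`, `I = max(1, K %/% 5)`, band 25-65, blur
#'   threshold at the 10th sharpness percentile).
#' @return Strictly increasing integer vector of selected frame indices (the
#'   frames' own `index` values), with the per-frame sharpness scores in
#'   attribute `"sharpness"`.
#' @export
select_keyframes <- function(frames, params = NULL) {
  n <- length(frames)
  if (n == 0) abort("empty frame sequence")
  params <- params %||% default_keyframe_params(n)
  scores <- vapply(frames, frame_sharpness, numeric(1))
  thr <- params$blur_threshold %||% unname(quantile(scores, 0.10))
  sharp <- scores >= thr
  sel <- integer()
  if (!any(sharp)) {
    warn("all frames fall below the blur threshold; no keyframes selected")
    return(structure(integer(), sharpness = scores))
  }
  a <- which(sharp)[1]
  sel <- a
  repeat {
    cand <- a + params$interval_k
    tested <- integer()
    accepted <- NA_integer_
    repeat {
      while (cand <= n && !sharp[cand]) cand <- cand + 1L
      if (cand > n) break
      if (cand <= a) cand <- a + 1L
      if (cand %in% tested) {
        # oscillation guard: jump past the highest tested position
        cand <- max(tested) + params$interval_k
        tested <- integer()
        next
      }
      sim <- frame_similarity(frames[[a]], frames[[cand]],
                              ratio_threshold = params$ratio_threshold)$similarity
      if (sim >= params$s1 && sim <= params$s2) {
        accepted <- cand
        break
      }
      tested <- c(tested, cand)
      cand <- if (sim > params$s2) cand + params$step_i else cand - params$step_i
    }
    if (is.na(accepted)) break
    sel <- c(sel, accepted)
    a <- accepted
  }
  structure(vapply(frames[sel], function(f) f$index, integer(1)),
            sharpness = scores)
}

#' Read a directory of PNG frames
#'
#' Frames are read in lexicographic filename order and indexed 0, 1, 2, ...
#'
#' @param dir Directory containing `.png` files.
#' @return A list of [image_frame()] objects.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("no PNG frames found in ", dir))
  lapply(seq_along(files), function(i) {
    px <- png::readPNG(files[i]) * 255
    if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3] # drop alpha
    image_frame(i - 1L, px)
  })
}

#' Write selected keyframes and a manifest
#'
#' Writes each selected frame as a numbered PNG plus a `manifest.json`
#' recording index, sharpness and similarity to the previous keyframe.
#'
#' @param frames The full frame list.
#' @param selection The index vector from [select_keyframes()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_keyframes <- function(frames, selection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx_of <- vapply(frames, function(f) f$index, integer(1))
  manifest <- vector("list", length(selection))
  prev <- NULL
  for (i in seq_along(selection)) {
    f <- frames[[match(selection[i], idx_of)]]
    px <- f$pixels / 255
    png::writePNG(px, file.path(dir, sprintf("keyframe_%04d.png", f$index)))
    sim <- if (is.null(prev)) NA_real_ else
      frame_similarity(prev, f)$similarity
    manifest[[i]] <- list(index = f$index, sharpness = frame_sharpness(f),
                          similarity_to_previous = sim)
    prev <- f
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
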