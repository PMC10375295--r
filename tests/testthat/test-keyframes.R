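test_that("sharpness score matches its definition and orders blur correctly", {
  # constant image has zero Laplacian response everywhere
  expect_equal(sharpness_score(matrix(128, 32, 32)), 0)

  # blurring strictly lowers the score
  withr::with_seed(1, {
    tex <- matrix(runif(64 * 64) * 255, 64, 64)
  })
  fr <- make_frame_sequence(1, texture_seed = 5, size = 64)[[1]]
  blurred <- make_frame_sequence(1, blur_indices = 0, texture_seed = 5,
                                 size = 64)[[1]]
  expect_gt(sharpness_score(fr), sharpness_score(blurred))

  # fixed checkerboard against the explicit double-loop evaluation
  board <- 255 * outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(sharpness_score(board), oracle_sharpness(board),
               tolerance = 1e-9)
  # and a second, non-symmetric image
  withr::with_seed(2, {
    img <- matrix(runif(96) * 255, 8, 12)
  })
  expect_equal(sharpness_score(img), oracle_sharpness(img), tolerance = 1e-9)

  expect_error(sharpness_score(matrix(1, 2, 2)), "3 x 3")
  # grayscale-preserving channel permutation of a gray color image
  gray3 <- array(rep(board, 3), dim = c(8, 8, 3))
  perm3 <- gray3[, , c(2, 3, 1)]
  expect_equal(sharpness_score(gray3), sharpness_score(perm3))
})

test_that("frame similarity follows the match-ratio definition", {
  frames <- make_frame_sequence(3, texture_seed = 7)
  self <- frame_similarity(frames[[1]], frames[[1]])
  expect_gte(self$similarity, 95)
  expect_equal(self$similarity, 100 * self$match_num / self$matches)

  withr::with_seed(2, {
    n1 <- matrix(runif(128 * 128) * 255, 128, 128)
    n2 <- matrix(runif(128 * 128) * 255, 128, 128)
  })
  expect_lt(frame_similarity(n1, n2)$similarity, 20)

  # arithmetic of the similarity formula
  mr <- siliqueseg:::match_result(50, 35)
  expect_equal(mr$similarity, 70)

  # ratio threshold -> 1 passes every candidate pair
  loose <- frame_similarity(frames[[1]], frames[[2]], ratio_threshold = 0.999)
  expect_equal(loose$match_num, loose$matches)

  # featureless frames give a zero result with a warning, not an error
  expect_warning(res <- frame_similarity(matrix(0, 32, 32), n1),
                 "no features")
  expect_equal(res$similarity, 0)
})

test_that("similarity decays with viewpoint distance", {
  frames <- make_frame_sequence(40, texture_seed = 3)
  s1 <- frame_similarity(frames[[1]], frames[[2]])$similarity
  s8 <- frame_similarity(frames[[1]], frames[[9]])$similarity
  s20 <- frame_similarity(frames[[1]], frames[[21]])$similarity
  expect_gt(s1, s8)
  expect_gt(s8, s20)
})

test_that("keyframe selection skips blurred frames and terminates", {
  frames <- make_frame_sequence(60, blur_indices = c(5, 17), texture_seed = 11)
  sel <- select_keyframes(frames,
                          keyframe_params(interval_k = 6, s1 = 25, s2 = 65,
                                          step_i = 1))
  expect_false(any(c(5, 17) %in% sel))
  expect_true(all(diff(sel) > 0))
  scores <- attr(sel, "sharpness")
  truth <- attr(frames, "truth")
  expect_true(all(scores[truth$blurred] < min(scores[!truth$blurred])))
})

test_that("identical frames collapse to a single keyframe", {
  base <- make_frame_sequence(1, texture_seed = 9)[[1]]
  frames <- lapply(0:9, function(i) image_frame(i, base$pixels))
  sel <- select_keyframes(frames,
                          keyframe_params(interval_k = 3, s1 = 20, s2 = 90,
                                          step_i = 1, blur_threshold = 0))
  expect_identical(as.integer(sel), 0L)
})

test_that("an in-band sequence is sampled at exactly the stride", {
  # i.i.d. additive noise puts every pairwise similarity in the band
  base <- make_frame_sequence(1, texture_seed = 13)[[1]]$pixels
  withr::with_seed(4, {
    frames <- lapply(0:19, function(i) {
      image_frame(i, pmin(pmax(base + matrix(rnorm(length(base), 0, 8),
                                             nrow(base)), 0), 255))
    })
  })
  sims <- vapply(2:6, function(i)
    frame_similarity(frames[[1]], frames[[i]])$similarity, numeric(1))
  expect_true(all(sims >= 30 & sims <= 62)) # calibration holds
  sel <- select_keyframes(frames,
                          keyframe_params(interval_k = 4, s1 = 25, s2 = 65,
                                          step_i = 1, blur_threshold = 0))
  expect_identical(as.integer(sel), as.integer(seq(0, 19, by = 4)))
})

test_that("selection is unchanged by frames after the last keyframe", {
  frames <- make_frame_sequence(30, texture_seed = 17)
  p <- keyframe_params(interval_k = 5, s1 = 25, s2 = 65, step_i = 1,
                       blur_threshold = 0)
  sel_full <- select_keyframes(frames, p)
  keep <- max(sel_full) + 1 # frames are 0-indexed
  sel_cut <- select_keyframes(frames[seq_len(keep)], p)
  expect_identical(as.integer(sel_full), as.integer(sel_cut))
})

test_that("frames round-trip through PNG directories", {
  frames <- make_frame_sequence(4, texture_seed = 19, size = 32)
  dir <- withr::local_tempdir()
  for (f in frames) {
    png::writePNG(f$pixels / 255, file.path(dir, sprintf("f%03d.png", f$index)))
  }
  back <- read_frames(dir)
  expect_length(back, 4)
  expect_equal(back[[2]]$pixels, frames[[2]]$pixels, tolerance = 1 / 255)

  out <- withr::local_tempdir()
  manifest <- write_keyframes(frames, c(0, 2), out)
  expect_true(file.exists(manifest))
  m <- jsonlite::read_json(manifest)
  expect_length(m, 2)
  expect_equal(m[[2]]$index, 2)
})
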