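test_that("the plant generator honours its own spec", {
  bare <- make_plant(plant_spec(n_siliques = 0, stem_points = 500, seed = 1))
  expect_true(all(bare$cloud$label == 0L))
  expect_equal(nrow(bare$truth), 0)

  pl <- make_plant(plant_spec(n_siliques = 25, points_per_silique = 200,
                              stem_points = 1000, seed = 2))
  expect_equal(nrow(pl$truth), 25)
  expect_equal(sum(pl$cloud$label == 1L), 25 * 200)
  expect_equal(sum(pl$cloud$label == 0L), 1000)

  # pairwise axis clearance holds for non-adhering pods
  bases <- as.matrix(pl$truth[, c("base_x", "base_y", "base_z")])
  tips <- as.matrix(pl$truth[, c("tip_x", "tip_y", "tip_z")])
  ssd <- siliqueseg:::segment_segment_distance
  for (i in 1:24) {
    d <- ssd(bases[i, ], tips[i, ], bases[(i + 1):25, , drop = FALSE],
             tips[(i + 1):25, , drop = FALSE])
    expect_true(all(d >= 2 * 0.018))
  }

  # deterministic per seed
  again <- make_plant(plant_spec(n_siliques = 25, points_per_silique = 200,
                                 stem_points = 1000, seed = 2))
  expect_identical(as.data.frame(pl$cloud), as.data.frame(again$cloud))
  expect_identical(pl$truth, again$truth)
})

test_that("segment distances agree with a dense parameter-grid oracle", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      p1 <- runif(3); p2 <- runif(3); q1 <- runif(3); q2 <- runif(3)
      got <- siliqueseg:::segment_segment_distance(p1, p2, q1, q2)
      tg <- seq(0, 1, length.out = 200)
      A <- outer(tg, p2 - p1) + matrix(p1, 200, 3, byrow = TRUE)
      B <- outer(tg, q2 - q1) + matrix(q1, 200, 3, byrow = TRUE)
      grid <- min(sqrt(outer(rowSums(A^2), rowSums(B^2), "+") -
                         2 * A %*% t(B)))
      expect_lte(got, grid + 1e-9)
      expect_gte(got, grid - 2e-3) # grid resolution bound
    }
  })
})

test_that("generated pods are recoverable line segments", {
  spec <- plant_spec(n_siliques = 10, points_per_silique = 200,
                     stem_points = 500, seed = 7)
  pl <- make_plant(spec)
  sil <- pl$cloud[pl$cloud$label == 1, ]
  pod_of <- rep(1:10, each = 200)
  for (i in 1:10) {
    pts <- as.matrix(sil[pod_of == i, c("x", "y", "z")])
    a <- unlist(pl$truth[i, c("base_x", "base_y", "base_z")])
    b <- unlist(pl$truth[i, c("tip_x", "tip_y", "tip_z")])
    d <- (b - a) / pl$truth$length[i]
    dist <- siliqueseg:::point_line_distance(pts, a, d)
    expect_gte(mean(dist <= 0.018), 0.9)
  }
})

test_that("adhering pods cross a partner at 40-80 degrees", {
  pl <- make_plant(plant_spec(n_siliques = 20, points_per_silique = 50,
                              stem_points = 300, adhesion_fraction = 0.2,
                              seed = 15))
  adh <- which(!is.na(pl$truth$adheres_to))
  expect_equal(length(adh), 4)
  dirs <- with(pl$truth, cbind(tip_x - base_x, tip_y - base_y,
                               tip_z - base_z) / length)
  ssd <- siliqueseg:::segment_segment_distance
  for (i in adh) {
    p <- pl$truth$adheres_to[i]
    ang <- acos(abs(sum(dirs[i, ] * dirs[p, ]))) * 180 / pi
    expect_gte(ang, 39.9)
    expect_lte(ang, 80.1)
    d <- ssd(unlist(pl$truth[i, c("base_x", "base_y", "base_z")]),
             unlist(pl$truth[i, c("tip_x", "tip_y", "tip_z")]),
             unlist(pl$truth[p, c("base_x", "base_y", "base_z")]),
             unlist(pl$truth[p, c("tip_x", "tip_y", "tip_z")]))
    expect_lte(d, 0.004)
  }
})

test_that("frame sequences carry usable blur ground truth", {
  frames <- make_frame_sequence(12, blur_indices = c(3, 7), texture_seed = 21)
  truth <- attr(frames, "truth")
  expect_equal(which(truth$blurred) - 1L, c(3L, 7L))
  scores <- vapply(frames, sharpness_score, numeric(1))
  expect_true(max(scores[truth$blurred]) < min(scores[!truth$blurred]))

  one <- make_frame_sequence(1, texture_seed = 2)
  sel <- select_keyframes(one, keyframe_params(interval_k = 2, step_i = 1,
                                               blur_threshold = 0))
  expect_identical(as.integer(sel), 0L)

  expect_error(make_frame_sequence(5, blur_indices = 9), "blur_indices")
  a <- make_frame_sequence(4, texture_seed = 3)
  b <- make_frame_sequence(4, texture_seed = 3)
  expect_identical(a[[4]]$pixels, b[[4]]$pixels)
})
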