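test_that("Euclidean clustering finds separated blobs and applies the size rule", {
  withr::with_seed(5, {
    b1 <- cbind(rnorm(300, 0, 0.005), rnorm(300, 0, 0.005), rnorm(300, 0, 0.005))
    b2 <- b1 + matrix(c(1, 0, 0), 300, 3, byrow = TRUE)
  })
  cl <- as_point_cloud(as.data.frame(rbind(b1, b2)) |>
                         stats::setNames(c("x", "y", "z")))
  cls <- euclidean_cluster(cl, 0.05, 100)
  expect_length(cls, 2)
  expect_identical(sort(unlist(cls)), 1:600)

  small <- as_point_cloud(as.data.frame(b1[1:150, ]) |>
                            stats::setNames(c("x", "y", "z")))
  expect_length(euclidean_cluster(small, 0.05, 200), 0)
})

test_that("clustering equals the union-find oracle", {
  withr::with_seed(13, {
    pts <- cbind(runif(2000, 0, 0.5), runif(2000, 0, 0.5), runif(2000, 0, 0.5))
  })
  cl <- as_point_cloud(stats::setNames(as.data.frame(pts), c("x", "y", "z")))
  got <- euclidean_cluster(cl, 0.03, 1)
  want <- oracle_union_find(pts, 0.03)
  canon <- function(l) unname(l[order(vapply(l, min, 1L))])
  expect_identical(canon(lapply(got, sort)), canon(lapply(want, sort)))
})

test_that("RANSAC line fitting recovers a noisy pod axis", {
  withr::with_seed(17, {
    t <- runif(500, 0, 0.1)
    pts <- cbind(rnorm(500, 0, 0.004), rnorm(500, 0, 0.004), t)
  })
  # the generated pod is ~28 mm wide, so the width band is set around it
  p <- counting_params(width_lo = 0.015, width_hi = 0.05, seed = 3)
  lm <- ransac_line(pts, p)
  expect_s3_class(lm, "line_model")
  ang <- acos(abs(sum(lm$direction * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 2)
  expect_gte(length(lm$inlier_indices), 450)
  expect_equal(sqrt(sum(lm$direction^2)), 1)
  d <- siliqueseg:::point_line_distance(pts[lm$inlier_indices, ], lm$anchor,
                                        lm$direction)
  expect_true(all(d <= p$inlier_threshold))
})

test_that("RANSAC refuses undersized and shapeless consensus sets", {
  line150 <- cbind(0, 0, seq(0, 0.1, length.out = 150))
  expect_null(ransac_line(line150, counting_params(width_lo = 1e-6,
                                                   seed = 1)))
  withr::with_seed(23, {
    cube <- cbind(runif(500, 0, 0.5), runif(500, 0, 0.5), runif(500, 0, 0.5))
  })
  expect_null(ransac_line(cube, counting_params(seed = 2)))
  expect_error(ransac_line(cube[1, , drop = FALSE], counting_params(seed = 1)),
               "two points")
})

test_that("well-separated pods are counted exactly", {
  pl <- make_plant(plant_spec(n_siliques = 25, points_per_silique = 400,
                              stem_points = 2000, seed = 42))
  canopy <- pl$cloud[pl$cloud$label == 1, ]
  lines <- count_siliques(canopy, counting_params(seed = 7))
  expect_equal(nrow(lines), 25)
  ev <- evaluate_counting(lines, pl$truth)
  expect_equal(ev$n_recovered, 25)
  expect_equal(ev$n_spurious, 0)
  # inlier sets are pairwise disjoint and within the cloud
  all_inl <- unlist(lines$inliers)
  expect_false(any(duplicated(all_inl)))
  expect_lte(length(all_inl), nrow(canopy))
  expect_true(all(lines$width >= 0.03 & lines$width <= 0.05))
  expect_true(all(lines$n_inliers >= 200))
})

test_that("two pods crossing at 60 degrees give two disjoint lines", {
  # two noisy segments through a common midpoint, 60 degrees apart
  len <- 0.065
  d1 <- c(0, 0, 1)
  d2 <- c(sin(pi / 3), 0, cos(pi / 3))
  withr::with_seed(11, {
    mk <- function(d) {
      t <- runif(400, -len / 2, len / 2)
      u <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- u - sum(u * d) * d
      u <- u / sqrt(sum(u^2))
      v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
             d[1] * u[2] - d[2] * u[1])
      outer(t, d) + outer(rnorm(400, 0, 0.0055), u) +
        outer(rnorm(400, 0, 0.0055), v)
    }
    pts <- rbind(mk(d1), mk(d2))
  })
  cl <- point_cloud(pts[, 1], pts[, 2], pts[, 3])
  expect_length(euclidean_cluster(cl, 0.02, 200), 1) # one shared cluster
  lines <- count_siliques(cl, counting_params(seed = 5))
  expect_equal(nrow(lines), 2)
  expect_length(intersect(lines$inliers[[1]], lines$inliers[[2]]), 0)
  got <- as.matrix(lines[, c("dir_x", "dir_y", "dir_z")])
  angs <- acos(pmin(abs(got %*% cbind(d1, d2)), 1)) * 180 / pi
  # each fitted axis aligns with a distinct true axis
  expect_lt(max(apply(angs, 2, min)), 10)
  expect_equal(sort(apply(angs, 1, which.min)), 1:2)
})

test_that("an empty canopy and rigid motions behave predictably", {
  empty <- point_cloud(0, 0, 0)
  expect_equal(nrow(count_siliques(empty, counting_params(seed = 1))), 0)

  pl <- small_plant(8, seed = 21, pps = 300)
  canopy <- pl$cloud[pl$cloud$label == 1, ]
  base <- count_siliques(canopy, counting_params(min_cluster_size = 150,
                                                 min_line_points = 150,
                                                 seed = 9))
  withr::with_seed(31, {
    for (i in 1:5) {
      th <- runif(3, 0, 2 * pi)
      Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                     0, -sin(th[1]), cos(th[1])), 3, 3)
      Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                     0, 0, 1), 3, 3)
      R <- Rx %*% Rz
      shift <- runif(3, -1, 1)
      m <- sweep(as.matrix(canopy[, c("x", "y", "z")]) %*% R, 2, shift, "+")
      moved <- point_cloud(m[, 1], m[, 2], m[, 3])
      got <- count_siliques(moved, counting_params(min_cluster_size = 150,
                                                   min_line_points = 150,
                                                   seed = 9))
      expect_equal(nrow(got), nrow(base))
    }
  })
})

test_that("counting metrics reproduce the published per-plant arithmetic", {
  counts <- example_plant_counts()
  rep <- counting_metrics(counts$true_count, counts$correct_count,
                          counts$plant_id)
  # the printed per-plant pairs sum to 1454/29, not the published total row
  # (1457/32); counting_metrics reports the arithmetic of its actual input
  expect_equal(rep$totals$true, 1454)
  expect_equal(rep$totals$correct, 1425)
  expect_equal(rep$totals$missed, 29)
  expect_equal(rep$totals$precision_percent, 100 * 1425 / 1454)
  expect_equal(rep$mape_percent, 1.96, tolerance = 0.005)
  expect_equal(rep$r_squared, 0.9905, tolerance = 1e-4)
  # invariants
  pp <- tidy(rep)
  expect_true(all(pp$correct_count + pp$missed_count == pp$true_count))
  expect_equal(pp$precision_percent,
               100 * pp$correct_count / pp$true_count)
  g <- glance(rep)
  expect_equal(g$true_total, 1454)

  perfect <- counting_metrics(c(10, 20), c(10, 20))
  expect_equal(perfect$totals$precision_percent, 100)
  expect_equal(perfect$mape_percent, 0)
  expect_equal(perfect$r_squared, 1)

  expect_error(counting_metrics(1:3, 1:2), "length")
  expect_error(counting_metrics(c(10, 10), c(11, 9)), "correct")
})
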