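test_that("labeled TXT parses and round-trips bit-exactly", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0 0", "1 1 1 1"), f)
  cl <- read_cloud(f)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$label, c(0L, 1L))

  set.seed(0)
  big <- point_cloud(rnorm(1000), rnorm(1000), rnorm(1000),
                     label = sample(0:1, 1000, replace = TRUE))
  write_cloud(big, f)
  back <- read_cloud(f)
  expect_identical(back$x, big$x)
  expect_identical(back$y, big$y)
  expect_identical(back$z, big$z)
  expect_identical(back$label, big$label)
})

test_that("PLY and PCD round-trip coordinates and labels", {
  cl <- small_plant(3, seed = 2, pps = 40)$cloud
  for (fmt in c("ply", "pcd")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_cloud(cl, f)
    back <- read_cloud(f)
    expect_equal(as.data.frame(back), as.data.frame(cl), tolerance = 1e-12)
  }
})

test_that("malformed input is rejected with a useful message", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0", "1 oops 1"), f)
  expect_error(read_cloud(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 0",
               "property float x", "property float y", "property float z",
               "end_header"), f2)
  expect_error(read_cloud(f2), "no vertices")
  expect_error(read_cloud("cloud.docx"), "format")
})

test_that("passthrough keeps exactly the closed-interval points", {
  cl <- point_cloud(c(0, 0, 0), c(0, 0, 0), c(0, 0.5, 1))
  out <- passthrough(cl, "z", 0.2, 0.7)
  expect_equal(out$z, 0.5)
  # full-box range is the identity
  expect_equal(as.data.frame(passthrough(cl, "z", -1, 2)), as.data.frame(cl))
  # brute-force mask oracle on a uniform cube
  withr::with_seed(1, {
    cube <- point_cloud(runif(10000), runif(10000), runif(10000))
  })
  out <- passthrough(cube, "z", 0.25, 0.75)
  expect_equal(nrow(out), sum(cube$z >= 0.25 & cube$z <= 0.75))
  expect_error(passthrough(cl, "z", 1, 0))
  expect_error(passthrough(cl, "z", 5, 6), "every point")
})

test_that("passthrough is idempotent and axis-commutative", {
  withr::with_seed(7, {
    cube <- point_cloud(runif(2000), runif(2000), runif(2000))
  })
  a <- passthrough(cube, "z", 0.2, 0.9)
  expect_equal(as.data.frame(passthrough(a, "z", 0.2, 0.9)), as.data.frame(a))
  xy <- passthrough(passthrough(cube, "x", 0.1, 0.8), "y", 0.3, 0.9)
  yx <- passthrough(passthrough(cube, "y", 0.3, 0.9), "x", 0.1, 0.8)
  expect_equal(as.data.frame(xy), as.data.frame(yx))
})

test_that("downsampling returns exact subsets with the requested size", {
  cl <- small_plant(2, seed = 3, pps = 60)$cloud
  full <- downsample(cl, nrow(cl), method = "fps", seed = 1)
  expect_setequal(attr(full, "index"), seq_len(nrow(cl)))

  # farthest-point selection keeps the extremes of a collinear triple
  tri <- point_cloud(c(0, 0.4, 1), c(0, 0, 0), c(0, 0, 0))
  two <- downsample(tri, 2, method = "fps", start = 1)
  expect_setequal(two$x, c(0, 1))

  r1 <- downsample(cl, 100, method = "random", seed = 42)
  r2 <- downsample(cl, 100, method = "random", seed = 42)
  expect_identical(attr(r1, "index"), attr(r2, "index"))
  expect_true(all(attr(r1, "index") %in% seq_len(nrow(cl))))
  expect_error(downsample(cl, nrow(cl) + 1, seed = 1))
})

test_that("fps spreads points better than random subsampling", {
  min_pair_dist <- function(cl) min(dist(as.matrix(cl[, c("x", "y", "z")])))
  wins <- 0L
  for (s in 1:20) {
    withr::with_seed(s, {
      cl <- point_cloud(runif(300), runif(300), runif(300))
    })
    f <- downsample(cl, 40, method = "fps", seed = s)
    r <- downsample(cl, 40, method = "random", seed = s)
    if (min_pair_dist(f) >= min_pair_dist(r)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 19L)
})
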