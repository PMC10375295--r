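test_that("the kNN graph matches brute force and handles edge cases", {
  line <- cbind(c(0, 1, 2, 10), 0, 0)
  expect_equal(unname(build_knn_graph(line, 1)[, 1]), c(2L, 1L, 2L, 3L))

  withr::with_seed(3, {
    pts <- matrix(rnorm(600), 200, 3)
  })
  expect_identical(unname(build_knn_graph(pts, 8)),
                   unname(oracle_knn(pts, 8)))

  # exact duplicates are mutual nearest neighbours
  dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(5, 5, 5))
  g <- build_knn_graph(dup, 1)
  expect_equal(g[1, 1], 2L)
  expect_equal(g[2, 1], 1L)

  expect_error(build_knn_graph(dup, 3), "smaller")
})

test_that("EdgeConv features equal a per-edge loop oracle", {
  withr::with_seed(5, {
    x <- matrix(rnorm(96), 32, 3)
  })
  g <- build_knn_graph(x, 4)
  mlp <- edgeconv_mlp(3, c(7, 5), seed = 5)
  got <- edgeconv_features(x, g, mlp)
  # explicit loop: per edge, concat(x_i, x_j - x_i) -> MLP -> max over k
  want <- matrix(-Inf, 32, 5)
  for (i in 1:32) {
    for (j in g[i, ]) {
      e <- c(x[i, ], x[j, ] - x[i, ])
      for (l in mlp) e <- pmax(as.vector(e %*% l$W) + l$b, 0)
      want[i, ] <- pmax(want[i, ], e)
    }
  }
  expect_equal(got, want, tolerance = 1e-12)

  # a zero-difference edge reduces to MLP(x_i, 0)
  two <- rbind(c(1, 2, 3), c(1, 2, 3))
  g2 <- matrix(c(2L, 1L), 2, 1)
  e <- c(1, 2, 3, 0, 0, 0)
  for (l in mlp) e <- pmax(as.vector(e %*% l$W) + l$b, 0)
  expect_equal(as.vector(edgeconv_features(two, g2, mlp)[1, ]), e)

  expect_error(edgeconv_features(x, g[1:10, ], mlp), "disagree")
})

test_that("the segmentation loss matches the cross-entropy definition", {
  expect_equal(segmentation_loss(matrix(1, 4, 2), rep(0L, 4)), log(2))
  expect_lt(segmentation_loss(matrix(c(1000, 0), 1, 2), 0L), 1e-12)

  withr::with_seed(7, {
    scores <- matrix(rnorm(100), 50, 2)
    labels <- sample(0:1, 50, replace = TRUE)
  })
  want <- 0
  for (i in 1:50) {
    want <- want - log(exp(scores[i, labels[i] + 1]) / sum(exp(scores[i, ])))
  }
  expect_equal(segmentation_loss(scores, labels), want / 50, tolerance = 1e-9)

  # invariance under per-point score shifts
  shifted <- scores + matrix(rnorm(50), 50, 2)[, c(1, 1)]
  expect_equal(segmentation_loss(shifted, labels),
               segmentation_loss(scores, labels), tolerance = 1e-9)

  expect_error(segmentation_loss(scores, rep(2L, 50)), "range")
})

test_that("analytic gradients match finite differences", {
  cfg <- dgcnn_config(profile = "desk", k_neighbors = 3,
                      edgeconv_widths = list(c(5, 4), 4), emb_width = 6,
                      head_widths = 7, n_points = 12, epochs = 1,
                      batch_size = 1, seed = 3)
  model <- dgcnn_init(cfg)
  fwd <- siliqueseg:::dgcnn_forward
  bwd <- siliqueseg:::dgcnn_backward
  withr::with_seed(1, {
    coords <- matrix(rnorm(60), 20, 3)
    labels <- sample(0:1, 20, replace = TRUE)
  })
  p <- model$params
  f <- fwd(p, coords, cfg, keep_cache = TRUE)
  g <- bwd(p, f$cache, cfg, siliqueseg:::softmax_grad(f$scores, labels))
  eps <- 1e-6
  withr::with_seed(2, {
    for (nm in names(p)) {
      for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
        p2 <- p
        p2[[nm]][i] <- p2[[nm]][i] + eps
        l1 <- segmentation_loss(fwd(p2, coords, cfg)$scores, labels)
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
        l2 <- segmentation_loss(fwd(p2, coords, cfg)$scores, labels)
        expect_equal(g[[nm]][i], (l1 - l2) / (2 * eps), tolerance = 1e-4)
      }
    }
  })
})

test_that("the input alignment transform starts at identity, deterministically", {
  cfg <- dgcnn_config(profile = "desk", n_points = 128, seed = 5)
  model <- dgcnn_init(cfg)
  withr::with_seed(9, {
    coords <- matrix(rnorm(300), 100, 3)
  })
  Tm <- spatial_transform(coords, model)
  expect_equal(Tm, diag(3))
  expect_identical(spatial_transform(coords, model),
                   spatial_transform(coords, model))
  expect_equal(dim(Tm), c(3L, 3L))
})

test_that("a zero learning rate leaves the network untouched", {
  pl <- small_plant(6, seed = 2, pps = 60)$cloud
  cfg <- dgcnn_config(profile = "desk", n_points = 256, epochs = 3,
                      batch_size = 2, learning_rate = 0, seed = 4)
  m <- dgcnn_train(list(pl), list(), cfg)
  init <- dgcnn_init(cfg)
  for (nm in names(init$params)) {
    expect_equal(max(abs(m$params[[nm]] - init$params[[nm]])), 0)
  }
  expect_lt(stats::sd(m$log$train_loss), 1e-12)
  expect_error(dgcnn_train(list(), list(), cfg), "empty")
})

test_that("segmentation is permutation-equivariant", {
  model <- dgcnn_init(dgcnn_config(profile = "desk", n_points = 128,
                                   seed = 5))
  cl <- small_plant(4, seed = 3, pps = 60)$cloud[1:300, ]
  s1 <- segment_cloud(cl, model)
  withr::with_seed(8, {
    perm <- sample(300)
  })
  s2 <- segment_cloud(cl[perm, ], model)
  expect_identical(s1$label[perm], s2$label)
  expect_equal(s1$score_silique[perm], s2$score_silique, tolerance = 1e-9)
})

test_that("the geometric baseline separates crown siliques from the stem", {
  pl <- crown_plant(25, seed = 33)
  bs <- baseline_segment(pl$cloud, height_quantile = 0.4)
  m <- segmentation_metrics(bs$label, pl$cloud$label)
  sil <- m[m$class == "silique", ]
  expect_gt(sil$precision, 90)
  expect_gt(sil$recall, 90)

  # quantile 1 gates everything out; quantile 0 keeps a pure-pod cloud whole
  all_stem <- baseline_segment(pl$cloud, height_quantile = 1.0)
  expect_true(all(all_stem$label == 0L))
  seg <- point_cloud(rep(0, 50), rep(0, 50), seq(0, 0.06, length.out = 50))
  all_sil <- baseline_segment(seg, height_quantile = 0)
  expect_true(all(all_sil$label == 1L))

  flat <- point_cloud(rep(1, 20), rep(1, 20), rep(1, 20))
  expect_warning(deg <- baseline_segment(flat), "degenerate")
  expect_true(all(deg$label == 0L))
})
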