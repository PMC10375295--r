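test_that("augmentation applies scale-then-translate with recorded draws", {
  cl <- point_cloud(1, 1, 1, label = 1L)
  # degenerate ranges give the identity transform
  ident <- augment_cloud(cl, augment_params(translation_range = c(0, 0),
                                            scale_range = c(1, 1),
                                            copies = 3, seed = 1))
  for (cp in ident) expect_equal(as.data.frame(cp)[1:4], as.data.frame(cl))

  # read back the drawn transform and verify the arithmetic on one point
  one <- augment_cloud(cl, augment_params(copies = 1, seed = 5))[[1]]
  tr <- attr(one, "transform")
  expect_true(all(tr$translation >= -0.2 & tr$translation <= 0.2))
  expect_true(all(tr$scale >= 0.65 & tr$scale <= 1.7))
  expect_equal(c(one$x, one$y, one$z), 1 * tr$scale + tr$translation)

  # 90 source clouds times six copies is the full training corpus
  src <- small_plant(2, seed = 1, pps = 10)$cloud
  expanded <- unlist(lapply(1:90, function(i)
    augment_cloud(src, augment_params(seed = i))), recursive = FALSE)
  expect_length(expanded, 540)

  expect_error(augment_cloud(point_cloud(1, 2, 3)), "labeled")
})

test_that("augmentation preserves labels and maps the bounding box exactly", {
  cl <- small_plant(3, seed = 4, pps = 50)$cloud
  cp <- augment_cloud(cl, augment_params(copies = 1, seed = 9))[[1]]
  expect_identical(cp$label, cl$label)
  tr <- attr(cp, "transform")
  for (ax in c("x", "y", "z")) {
    i <- match(ax, c("x", "y", "z"))
    expect_equal(range(cp[[ax]]),
                 sort(range(cl[[ax]]) * tr$scale[i] + tr$translation[i]))
  }
})

test_that("dataset splitting uses round-nearest with remainder to train", {
  sp <- split_dataset(as.list(1:540), seed = 1)
  expect_equal(lengths(sp$indices), c(train = 378L, validation = 81L,
                                      test = 81L))
  sp10 <- split_dataset(as.list(1:10), seed = 1)
  expect_equal(lengths(sp10$indices), c(train = 8L, validation = 1L,
                                        test = 1L))
  # disjoint and covering
  all_idx <- sort(unname(unlist(sp10$indices)))
  expect_identical(all_idx, 1:10)
  # deterministic per seed
  sp10b <- split_dataset(as.list(1:10), seed = 1)
  expect_identical(sp10$indices, sp10b$indices)
  expect_error(split_dataset(as.list(1:2), seed = 1), "at least 3")
})

test_that("grouped splitting keeps augmented copies of a source together", {
  clouds <- as.list(1:60)
  groups <- rep(1:10, each = 6)
  sp <- split_dataset(clouds, seed = 3, groups = groups)
  for (part in sp$indices) {
    gs <- groups[part]
    for (g in unique(gs)) expect_equal(sum(groups == g), sum(gs == g))
  }
})
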