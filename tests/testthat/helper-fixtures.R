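# small ground-truthed fixtures shared across test files; everything is
# generated in code under fixed seeds

small_plant <- function(n_siliques = 10, seed = 1, adhesion = 0, pps = 250) {
  make_plant(plant_spec(n_siliques = n_siliques, points_per_silique = pps,
                        stem_points = 1500, stem_height = 0.6,
                        adhesion_fraction = adhesion, seed = seed))
}

# plant whose canopy sits strictly above the stem, for the geometric baseline
crown_plant <- function(n_siliques = 25, seed = 33) {
  make_plant(plant_spec(n_siliques = n_siliques, points_per_silique = 300,
                        stem_points = 5000, stem_height = 0.5,
                        canopy_range = c(1.0, 1.12), seed = seed))
}

training_plants <- function(n = 8) {
  lapply(seq_len(n), function(i)
    make_plant(plant_spec(n_siliques = 20, points_per_silique = 150,
                          stem_points = 1200, stem_height = 0.6,
                          seed = i))$cloud)
}

# brute-force helpers used as independent oracles
oracle_knn <- function(pts, k) {
  d2 <- as.matrix(dist(pts))^2
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

oracle_union_find <- function(pts, tol) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d <- as.matrix(dist(pts))
  for (i in seq_len(n - 1)) {
    for (j in which(d[i, ] <= tol)) {
      if (j > i) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(seq_len(n), match(roots, unique(roots))))
}

# direct evaluation of the sharpness definition: bilateral filter, grayscale,
# 4-neighbour Laplacian with symmetric-reflect border, population variance --
# all as explicit loops
oracle_sharpness <- function(img, d = 9, sc = 75, ss = 75) {
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  nr <- nrow(img)
  nc <- ncol(img)
  rad <- d %/% 2
  bf <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    wsum <- 0
    vsum <- 0
    for (dr in -rad:rad) for (dc in -rad:rad) {
      v <- img[refl(r + dr, nr), refl(c + dc, nc)]
      w <- exp(-(dr^2 + dc^2) / (2 * ss^2) - (v - img[r, c])^2 / (2 * sc^2))
      wsum <- wsum + w
      vsum <- vsum + w * v
    }
    bf[r, c] <- vsum / wsum
  }
  ker <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1) {
      acc <- acc + ker[dr + 2, dc + 2] * bf[refl(r + dr, nr), refl(c + dc, nc)]
    }
    lap[r, c] <- acc
  }
  m <- mean(lap)
  sum((lap - m)^2) / (nr * nc)
}
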