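test_that("cleaning drops bad records and thinning enforces the distance", {
  occ <- data.frame(
    species = "s",
    longitude = c(0, -110, -110.001, -110.3, 200, -110, NA),
    latitude = c(0, 40, 40.0005, 40.2, 41, 40, 40))
  out <- clean_and_thin(occ, min_km = 1)
  expect_equal(nrow(out), 2)  # (0,0), out-of-range, dup, NA, near-dup gone
  # two points ~0.5 km apart with 1 km threshold: one retained
  occ2 <- data.frame(species = "s", longitude = c(0, 0.0045),
                     latitude = c(45, 45))
  expect_equal(nrow(clean_and_thin(occ2, min_km = 1)), 1)
  # property: retained pairwise distances >= min_km over random clouds
  set.seed(121)
  for (rep in 1:20) {
    occ3 <- data.frame(species = "s",
                       longitude = runif(40, -100.2, -100),
                       latitude = runif(40, 39.9, 40.1))
    thin <- clean_and_thin(occ3, min_km = 5)
    if (nrow(thin) > 1) {
      d <- geosphere::distm(cbind(thin$longitude, thin$latitude)) / 1000
      expect_gte(min(d[upper.tri(d)]), 5)
    }
  }
  # bounding box filter
  out4 <- clean_and_thin(
    data.frame(species = "s", longitude = c(-110, -50), latitude = c(40, 40)),
    bounds = c(lon_min = -130, lon_max = -60, lat_min = 20, lat_max = 60),
    min_km = 0)
  expect_equal(out4$longitude, -110)
})

test_that("the Albers projection preserves areas on the sphere", {
  proj <- albers_projection(lat0 = 40, lon0 = -110, lat1 = 35, lat2 = 45)
  # a 1-degree x 1-degree cell at the center: spherical area vs projected
  R <- 6371.0072
  lat <- seq(39.5, 40.5, length.out = 60)
  lon <- seq(-110.5, -109.5, length.out = 60)
  sph_area <- R^2 * (sin(max(lat) * pi / 180) - sin(min(lat) * pi / 180)) *
    (diff(range(lon)) * pi / 180)
  corners <- proj(cbind(c(-110.5, -109.5, -109.5, -110.5),
                        c(39.5, 39.5, 40.5, 40.5)))
  # shoelace on the projected (nearly straight-edged) cell
  xs <- corners[, 1]; ys <- corners[, 2]
  shoelace <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  expect_equal(shoelace, sph_area, tolerance = 0.002 * sph_area)
})

test_that("buffered range areas match closed forms", {
  a <- build_range(xy = cbind(0, 0), buffer_km = 10, species = "a")
  expect_equal(a$area_km2, pi * 100, tolerance = 0.005 * pi * 100)
  # two points farther apart than 2 * buffer: two full circles
  b <- build_range(xy = rbind(c(0, 0), c(50, 0)), buffer_km = 10)
  expect_equal(b$area_km2, 2 * pi * 100, tolerance = 1e-8)
  # two-disc lens by closed form
  d <- 5; r <- 10
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  u <- build_range(xy = rbind(c(0, 0), c(d, 0)), buffer_km = r)
  expect_equal(u$area_km2, 2 * pi * r^2 - lens, tolerance = 1e-8)
  # zero buffer: degenerate flagged
  expect_warning(z <- build_range(xy = cbind(0, 0), buffer_km = 0),
                 "degenerate")
  expect_equal(z$area_km2, 0)
})

test_that("disc-union areas agree with the rasterization oracle", {
  set.seed(122)
  for (rep in 1:5) {
    pts <- cbind(runif(12, 0, 40), runif(12, 0, 30))
    r <- runif(1, 3, 8)
    exact <- silenemorph:::disc_union_area(pts, r)
    approx <- raster_area(disc_union_inside(pts, r),
                          xlim = range(pts[, 1]) + c(-r - 1, r + 1),
                          ylim = range(pts[, 2]) + c(-r - 1, r + 1),
                          h = 0.05)
    expect_equal(exact, approx, tolerance = 0.005 * exact)
  }
})

test_that("the overlap index follows the non-overlap-normalized formula", {
  # disjoint
  r1 <- build_range(xy = cbind(0, 0), buffer_km = 10)
  r2 <- build_range(xy = cbind(1000, 0), buffer_km = 10)
  ov <- overlap_index(r1, r2)
  expect_equal(ov$overlap_area, 0)
  expect_equal(ov$index, 0)
  expect_false(ov$sympatric)
  # analytic rectangles: areas 2 and 1, overlap 1 -> index 1
  q1 <- range_rect("q1", 0, 2, 0, 1)
  q2 <- range_rect("q2", 1, 3, 0, 1)
  expect_equal(overlap_index(q1, q2)$overlap_area, 1)
  expect_equal(overlap_index(q1, q2)$index, 1 / (1 + 1))
  big <- range_rect("big", 0, 2, 0, 1)
  inner <- range_rect("inner", 0, 1, 0, 1)
  expect_equal(overlap_index(big, inner)$index, 1 / (1 + 0))
  # half-overlapping unit squares -> 0.5
  u1 <- range_rect("u1", 0, 1, 0, 1)
  u2 <- range_rect("u2", 0.5, 1.5, 0, 1)
  expect_equal(overlap_index(u1, u2)$index, 0.5)
  # identical ranges: sentinel infinity, sympatric
  same <- overlap_index(u1, u1)
  expect_true(is.infinite(same$index))
  expect_true(same$sympatric)
  # exact symmetry on disc unions
  set.seed(123)
  p1 <- cbind(runif(6, 0, 20), runif(6, 0, 20))
  p2 <- cbind(runif(6, 10, 30), runif(6, 0, 20))
  g1 <- build_range(xy = p1, buffer_km = 6, species = "g1")
  g2 <- build_range(xy = p2, buffer_km = 6, species = "g2")
  o12 <- overlap_index(g1, g2); o21 <- overlap_index(g2, g1)
  expect_identical(o12$overlap_area, o21$overlap_area)
  expect_identical(o12$index, o21$index)
  expect_gt(o12$overlap_area, 0)
})

test_that("pairwise disparity tables are complete, symmetric, and exact", {
  S <- matrix(c(2, -1.5, 0, 1, 3, -2), 3, 2,
              dimnames = list(c("b", "a", "c"), c("PC1", "PC2")))
  tab <- pairwise_disparity(S)
  expect_equal(nrow(tab), 3)
  ab <- tab[tab$species_a == "a" & tab$species_b == "b", ]
  expect_equal(ab$disparity_PC1, abs(2 - (-1.5)))
  expect_equal(ab$disparity_PC2, abs(1 - 3))
  # canonical sorted pair keys: reordering rows changes nothing
  tab2 <- pairwise_disparity(S[c(3, 1, 2), ])
  expect_equal(tab, tab2)
  S10 <- matrix(rnorm(20), 10, 2,
                dimnames = list(paste0("s", 1:10), c("PC1", "PC2")))
  expect_equal(nrow(pairwise_disparity(S10)), 45)
})

test_that("Kruskal-Wallis wrapper matches hand rank arithmetic", {
  res <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(res$H, 2.4, tolerance = 1e-10)
  expect_equal(res$df, 1)
  same <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), 3))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  # hand formula with tie correction on a random dataset
  set.seed(124)
  y <- sample(1:8); g <- rep(c("a", "b"), each = 4)
  rk <- rank(y)
  Hhand <- 12 / (8 * 9) * sum(tapply(rk, g, sum)^2 / 4) - 3 * 9
  expect_equal(kruskal_wallis(y, g)$H, Hhand, tolerance = 1e-10)
})

test_that("aligned-rank two-way ANOVA separates the acting factor", {
  set.seed(125)
  n <- 120
  A <- factor(sample(letters[1:3], n, replace = TRUE))
  B <- factor(sample(c("x", "y"), n, replace = TRUE))
  hitsA <- 0; hitsB <- 0
  for (rep in 1:40) {
    y <- rnorm(n) + 1.2 * (A == "b") + 2.4 * (A == "c")  # pure A effect
    res <- art_two_way(y, A, B)
    if (res$p_value[res$effect == "A"] < 0.05) hitsA <- hitsA + 1
    if (res$p_value[res$effect == "B"] < 0.05) hitsB <- hitsB + 1
  }
  expect_gte(hitsA / 40, 0.9)
  expect_lte(hitsB / 40, 0.2)
  # aligned ranks sum to n(n+1)/2 per effect
  y <- rnorm(n)
  cm <- tapply(y, list(A, B), mean)
  resid <- y - cm[cbind(as.integer(A), as.integer(B))]
  aligned <- resid + (rowMeans(cm)[as.integer(A)] - mean(cm))
  expect_equal(sum(rank(aligned)), n * (n + 1) / 2)
  # empty cell errors
  Abad <- factor(rep(c("a", "b"), each = 4))
  Bbad <- factor(c(rep("x", 4), rep("y", 4)))
  expect_error(art_two_way(rnorm(8), Abad, Bbad), "empty cell")
})

test_that("aligned-rank ANOVA keeps type-I error near nominal under the null", {
  set.seed(126)
  reject <- c(A = 0, B = 0, `A:B` = 0)
  n_sims <- 150
  for (rep in 1:n_sims) {
    n <- 60
    A <- factor(sample(letters[1:2], n, replace = TRUE))
    B <- factor(sample(c("x", "y"), n, replace = TRUE))
    if (any(table(A, B) == 0)) next
    res <- art_two_way(rnorm(n), A, B)
    for (eff in res$effect)
      if (res$p_value[res$effect == eff] < 0.05)
        reject[eff] <- reject[eff] + 1
  }
  rates <- reject / n_sims
  expect_true(all(rates >= 0.0 & rates <= 0.12))
})

test_that("rank ANCOVA tests the group effect net of the covariate", {
  set.seed(127)
  hits <- 0
  for (rep in 1:40) {
    n <- 80
    g <- factor(rep(c("symp", "allo"), each = n / 2))
    cov <- rnorm(n)  # pure noise covariate
    y <- rnorm(n) + 1.0 * (g == "symp")
    if (rank_ancova(y, g, cov)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)
  # response a monotone function of the covariate only: p roughly uniform
  set.seed(128)
  ps <- replicate(60, {
    n <- 60
    g <- factor(rep(c("symp", "allo"), each = n / 2))
    cov <- runif(n)
    y <- exp(cov) + rnorm(n, 0, 0.1)
    rank_ancova(y, g, cov)$p_value
  })
  expect_gt(mean(ps > 0.05), 0.8)
  # invariant to monotone rescaling of covariate units
  n <- 30; g <- factor(rep(c("a", "b"), 15)); cov <- runif(n); y <- rnorm(n)
  r1 <- rank_ancova(y, g, cov)
  r2 <- rank_ancova(y, g, 1000 * cov^3)
  expect_equal(r1$F, r2$F, tolerance = 1e-10)
  expect_warning(rank_ancova(y, g, rep(1, n)), "constant covariate")
})

test_that("overlap-disparity correlations behave at the extremes", {
  pairs <- data.frame(
    species_a = letters[1:6], species_b = letters[7:12],
    disparity_PC1 = c(1, 2, 3, 4, 5, 6),
    disparity_PC2 = rnorm(6),
    overlap_area = c(10, 20, 30, 40, 50, 60),
    overlap_index = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    sympatric = TRUE, stringsAsFactors = FALSE)
  res <- overlap_disparity_correlation(pairs)
  expect_equal(res$rho[res$measure == "overlap_index" &
                         res$component == "PC1"], 1)
  # independence: small |rho| on average
  set.seed(129)
  rhos <- replicate(30, {
    p2 <- pairs[rep(1:6, 5), ]
    p2$disparity_PC1 <- rnorm(30)
    p2$overlap_index <- runif(30)
    p2$overlap_area <- runif(30)
    overlap_disparity_correlation(p2)$rho[1]
  })
  expect_lt(abs(mean(rhos)), 0.15)
})
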