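## Occurrence cleaning, Albers equal-area projection, buffered range polygons
## (disc unions with exact arc-based areas), the range-overlap index, and the
## disparity-by-geography statistics.

#' Clean and spatially thin occurrence records
#'
#' Drops records at (0, 0), outside valid coordinates, outside an optional
#' bounding box, and exact duplicates; then thins greedily (deterministic
#' order: sort by latitude then longitude) so that no two retained points are
#' closer than `min_km` great-circle kilometres.
#'
#' @param occ Data frame with columns `species`, `longitude`, `latitude`.
#' @param bounds Optional named vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param min_km Minimum retained pairwise distance in km (default 1).
#' @return Cleaned data frame (same columns).
#' @export
clean_and_thin <- function(occ, bounds = NULL, min_km = 1) {
  stopifnot(all(c("species", "longitude", "latitude") %in% names(occ)))
  occ <- occ[is.finite(occ$longitude) & is.finite(occ$latitude), ]
  occ <- occ[!(occ$longitude == 0 & occ$latitude == 0), ]
  occ <- occ[abs(occ$latitude) <= 90 & abs(occ$longitude) <= 180, ]
  if (!is.null(bounds)) {
    occ <- occ[occ$longitude >= bounds[["lon_min"]] &
                 occ$longitude <= bounds[["lon_max"]] &
                 occ$latitude >= bounds[["lat_min"]] &
                 occ$latitude <= bounds[["lat_max"]], ]
  }
  occ <- occ[!duplicated(occ[, c("species", "longitude", "latitude")]), ]
  out <- lapply(split(occ, occ$species), function(d) {
    d <- d[order(d$latitude, d$longitude), ]
    if (nrow(d) <= 1 || min_km <= 0) return(d)
    keep <- 1L
    for (i in seq(2, nrow(d))) {
      dists <- geosphere::distHaversine(
        cbind(d$longitude[keep], d$latitude[keep]),
        c(d$longitude[i], d$latitude[i])) / 1000
      if (all(dists >= min_km)) keep <- c(keep, i)
    }
    d[keep, ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!nrow(res)) warning("no occurrence records survive cleaning")
  res
}

## ---- Albers equal-area projection ------------------------------------------

#' Spherical Albers equal-area conic projection
#'
#' Closed-form Albers equal-area conic on the authalic sphere
#' (R = 6371.0072 km). Standard parallels default to the 1/6 and 5/6
#' latitude quantiles of the data (the usual rule of thumb); the projection
#' preserves areas, so buffering and area computation are done in this plane
#' in km.
#'
#' @param lat0,lon0 Projection origin (degrees).
#' @param lat1,lat2 Standard parallels (degrees).
#' @return Object of class `albers_projection`: a function
#'   `project(lonlat)` mapping a 2-column lon/lat matrix to x/y km, with the
#'   parameters as attributes.
#' @export
albers_projection <- function(lat0, lon0, lat1, lat2) {
  R <- 6371.0072
  d2r <- pi / 180
  phi1 <- lat1 * d2r; phi2 <- lat2 * d2r
  n <- (sin(phi1) + sin(phi2)) / 2
  if (abs(n) < 1e-12)
    stop("degenerate Albers projection: standard parallels symmetric about equator",
         call. = FALSE)
  Cc <- cos(phi1)^2 + 2 * n * sin(phi1)
  rho <- function(phi) R * sqrt(pmax(Cc - 2 * n * sin(phi), 0)) / n
  rho0 <- rho(lat0 * d2r)
  f <- function(lonlat) {
    lonlat <- matrix(lonlat, ncol = 2)
    theta <- n * (lonlat[, 1] - lon0) * d2r
    r <- rho(lonlat[, 2] * d2r)
    cbind(x = r * sin(theta), y = rho0 - r * cos(theta))
  }
  structure(f, class = "albers_projection",
            params = list(lat0 = lat0, lon0 = lon0, lat1 = lat1,
                          lat2 = lat2, R = R))
}

#' Fit an Albers projection to a set of occurrence points
#'
#' @param occ Data frame with `longitude`, `latitude`.
#' @return An [albers_projection()] with standard parallels at the 1/6 and
#'   5/6 latitude quantiles.
#' @export
fit_albers <- function(occ) {
  q <- stats::quantile(occ$latitude, c(1 / 6, 5 / 6), names = FALSE)
  if (diff(q) < 0.5) q <- q + c(-0.5, 0.5)  # avoid coincident parallels
  albers_projection(lat0 = mean(occ$latitude), lon0 = mean(occ$longitude),
                    lat1 = q[1], lat2 = q[2])
}

## ---- range polygons ---------------------------------------------------------

#' Build a buffered species range from occurrence points
#'
#' Projects the species' points into an equal-area plane, buffers each by
#' `buffer_km`, and takes the union of the discs. Areas (km^2) of disc
#' unions are computed exactly by tracing the uncovered boundary arcs
#' (Green's theorem); no rasterization is involved.
#'
#' @param occ Data frame with `species`, `longitude`, `latitude` for one
#'   species (or use `xy` for pre-projected km coordinates).
#' @param buffer_km Buffer radius in km (default 10).
#' @param proj An [albers_projection()]; required when `occ` is geographic.
#' @param xy Optional 2-column matrix of projected km coordinates (overrides
#'   `occ`/`proj`).
#' @param species Species id (defaults to `occ$species[1]`).
#' @return Object of class `species_range` (type `"discs"`) with `area_km2`.
#' @export
build_range <- function(occ = NULL, buffer_km = 10, proj = NULL, xy = NULL,
                        species = NULL) {
  if (is.null(xy)) {
    stopifnot(!is.null(occ), nrow(occ) >= 1)
    if (is.null(proj)) proj <- fit_albers(occ)
    if (is.null(species)) species <- as.character(occ$species[1])
    xy <- proj(cbind(occ$longitude, occ$latitude))
  } else {
    xy <- matrix(xy, ncol = 2)
  }
  if (is.null(species)) species <- "unknown"
  xy <- unique(round(xy, 9))
  if (buffer_km < 0) stop("negative buffer", call. = FALSE)
  area <- if (buffer_km == 0) 0 else disc_union_area(xy, buffer_km)
  if (buffer_km == 0)
    warning("buffer 0: degenerate zero-area range for ", species)
  structure(list(species = species, type = "discs", centers = xy,
                 r = buffer_km, area_km2 = area),
            class = "species_range")
}

#' Rectangular range (analytic test geometry)
#'
#' @param species Species id.
#' @param xmin,xmax,ymin,ymax Rectangle bounds in km.
#' @return A `species_range` of type `"rect"`.
#' @export
range_rect <- function(species, xmin, xmax, ymin, ymax) {
  stopifnot(xmax >= xmin, ymax >= ymin)
  structure(list(species = species, type = "rect",
                 bounds = c(xmin = xmin, xmax = xmax, ymin = ymin,
                            ymax = ymax),
                 area_km2 = (xmax - xmin) * (ymax - ymin)),
            class = "species_range")
}

#' @export
print.species_range <- function(x, ...) {
  cat("Species range (", x$type, "): ", x$species, ", area = ",
      signif(x$area_km2, 6), " km^2\n", sep = "")
  invisible(x)
}

# Exact area of a union of discs with common radius r via Green's theorem:
# sum the line-integral contribution of every boundary arc not covered by
# another disc.
disc_union_area <- function(centers, r) {
  centers <- matrix(centers, ncol = 2)
  n <- nrow(centers)
  if (n == 0 || r <= 0) return(0)
  total <- 0
  for (i in seq_len(n)) {
    ci <- centers[i, ]
    d <- sqrt((centers[, 1] - ci[1])^2 + (centers[, 2] - ci[2])^2)
    others <- which(d > 1e-12 & d < 2 * r)
    # coincident duplicates were removed upstream; a disc is never strictly
    # inside another of equal radius unless coincident
    if (!length(others)) {
      total <- total + pi * r^2
      next
    }
    ints <- lapply(others, function(j) {
      alpha <- atan2(centers[j, 2] - ci[2], centers[j, 1] - ci[1])
      beta <- acos(pmin(1, pmax(-1, d[j] / (2 * r))))
      c(alpha - beta, alpha + beta)
    })
    free <- free_arcs(do.call(rbind, ints))
    for (k in seq_len(nrow(free))) {
      th1 <- free[k, 1]; th2 <- free[k, 2]
      total <- total + 0.5 * (r^2 * (th2 - th1) +
        r * (ci[1] * (sin(th2) - sin(th1)) -
             ci[2] * (cos(th2) - cos(th1))))
    }
  }
  total
}

# Complement of a set of angular intervals on the circle; returns a matrix of
# [start, end] arcs with end > start (possibly wrapping beyond 2*pi).
free_arcs <- function(ints) {
  two_pi <- 2 * pi
  # normalize starts into [0, 2pi); split wrapping intervals
  norm <- list()
  for (k in seq_len(nrow(ints))) {
    a <- ints[k, 1] %% two_pi
    len <- ints[k, 2] - ints[k, 1]
    if (len >= two_pi) return(matrix(numeric(0), 0, 2))
    b <- a + len
    if (b <= two_pi) norm[[length(norm) + 1L]] <- c(a, b)
    else {
      norm[[length(norm) + 1L]] <- c(a, two_pi)
      norm[[length(norm) + 1L]] <- c(0, b - two_pi)
    }
  }
  m <- do.call(rbind, norm)
  m <- m[order(m[, 1]), , drop = FALSE]
  # merge overlapping
  merged <- list(m[1, ])
  for (k in seq_len(nrow(m))[-1]) {
    last <- merged[[length(merged)]]
    if (m[k, 1] <= last[2] + 1e-12)
      merged[[length(merged)]] <- c(last[1], max(last[2], m[k, 2]))
    else merged[[length(merged) + 1L]] <- m[k, ]
  }
  m <- do.call(rbind, merged)
  if (m[1, 1] <= 1e-12 && m[nrow(m), 2] >= two_pi - 1e-12 && nrow(m) == 1)
    return(matrix(numeric(0), 0, 2))
  # gaps between merged covered intervals
  gaps <- list()
  for (k in seq_len(nrow(m))) {
    nxt <- if (k < nrow(m)) m[k + 1, 1] else m[1, 1] + two_pi
    if (nxt > m[k, 2] + 1e-12)
      gaps[[length(gaps) + 1L]] <- c(m[k, 2], nxt)
  }
  if (!length(gaps)) return(matrix(numeric(0), 0, 2))
  do.call(rbind, gaps)
}

## ---- overlap ----------------------------------------------------------------

range_intersection_area <- function(a, b) {
  if (a$type == "rect" && b$type == "rect") {
    w <- max(0, min(a$bounds["xmax"], b$bounds["xmax"]) -
               max(a$bounds["xmin"], b$bounds["xmin"]))
    h <- max(0, min(a$bounds["ymax"], b$bounds["ymax"]) -
               max(a$bounds["ymin"], b$bounds["ymin"]))
    return(w * h)
  }
  if (a$type == "discs" && b$type == "discs") {
    if (abs(a$r - b$r) > 1e-9)
      stop("disc ranges with different buffer radii", call. = FALSE)
    both <- unique(rbind(a$centers, b$centers))
    # canonical point order so the result is bit-identical under (a, b) swap
    both <- both[order(both[, 1], both[, 2]), , drop = FALSE]
    u <- disc_union_area(both, a$r)
    return(max(0, a$area_km2 + b$area_km2 - u))
  }
  stop("unsupported range-geometry combination", call. = FALSE)
}

#' Range overlap index and sympatry classification
#'
#' `index = overlap / ((area_A - overlap) + (area_B - overlap))`; a pair is
#' sympatric exactly when the overlap area is positive. Identical ranges
#' (zero denominator) report `Inf` as a sentinel with `sympatric = TRUE`.
#'
#' @param a,b `species_range` objects in the same projection.
#' @return List with `overlap_area`, `index`, `sympatric`. Symmetric in
#'   `(a, b)`.
#' @export
overlap_index <- function(a, b) {
  stopifnot(inherits(a, "species_range"), inherits(b, "species_range"))
  ov <- range_intersection_area(a, b)
  if (ov <= 1e-9) ov <- 0
  denom <- (a$area_km2 - ov) + (b$area_km2 - ov)
  idx <- if (ov == 0) 0 else if (denom <= 1e-9) Inf else ov / denom
  list(overlap_area = ov, index = idx, sympatric = ov > 0)
}

## ---- disparity & tests ------------------------------------------------------

#' Pairwise phenotypic disparity on component scores
#'
#' Absolute score difference per component for every unordered species pair
#' (`n(n-1)/2` rows), with a canonical sorted pair key so the table is stable
#' under species reordering.
#'
#' @param fit A `phyl_pca` or a score matrix with species rownames.
#' @param components Component indices (default 1:2).
#' @return Data frame with `species_a`, `species_b` and one
#'   `disparity_PC<k>` column per component.
#' @export
pairwise_disparity <- function(fit, components = c(1, 2)) {
  S <- if (inherits(fit, "phyl_pca")) fit$scores else as.matrix(fit)
  sp <- sort(rownames(S))
  prs <- utils::combn(sp, 2)
  out <- data.frame(species_a = prs[1, ], species_b = prs[2, ],
                    stringsAsFactors = FALSE)
  for (k in components)
    out[[paste0("disparity_PC", k)]] <-
      abs(S[prs[1, ], k] - S[prs[2, ], k])
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Wrapper over [stats::kruskal.test()] (tie-corrected H, chi-squared
#' p-value); the fully tied degenerate case returns `H = 0, p = 1`.
#'
#' @param values Numeric response.
#' @param groups Grouping factor.
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1, p_value = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Two-way aligned-rank-transform ANOVA
#'
#' Nonparametric factorial ANOVA by the aligned-rank-transform procedure:
#' for each effect (A, B, A:B) the response is aligned by stripping the
#' estimated other effects from a cell-mean decomposition, the aligned
#' values are ranked (average ties), and a factorial ANOVA is run on the
#' ranks; only that effect's F is read from each ANOVA.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (>= 2 levels each; all cells non-empty).
#' @return Data frame with one row per effect: `F`, `df1`, `df2`, `p_value`.
#' @export
art_two_way <- function(values, factor_a, factor_b) {
  A <- factor(factor_a); B <- factor(factor_b)
  stopifnot(nlevels(A) >= 2, nlevels(B) >= 2)
  cells <- table(A, B)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: ", rownames(cells)[idx[1]], " x ",
         colnames(cells)[idx[2]], call. = FALSE)
  }
  cell_mean <- tapply(values, list(A, B), mean)
  mu_ab <- cell_mean[cbind(as.integer(A), as.integer(B))]
  mu_a <- rowMeans(cell_mean)[as.integer(A)]
  mu_b <- colMeans(cell_mean)[as.integer(B)]
  mu <- mean(cell_mean)
  resid <- values - mu_ab
  aligned <- list(
    A = resid + (mu_a - mu),
    B = resid + (mu_b - mu),
    `A:B` = resid + (mu_ab - mu_a - mu_b + mu)
  )
  effect_row <- c(A = "A", B = "B", `A:B` = "A:B")
  out <- lapply(names(aligned), function(eff) {
    rk <- rank(aligned[[eff]])
    tab <- stats::anova(stats::lm(rk ~ A * B))
    row <- tab[effect_row[[eff]], ]
    data.frame(effect = eff, F = row[["F value"]], df1 = row[["Df"]],
               df2 = tab["Residuals", "Df"], p_value = row[["Pr(>F)"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank-based ANCOVA of disparity on sympatry with a covariate
#'
#' Robust rank-transform ANCOVA under homogeneous slopes: the ranked
#' response is regressed on the ranked covariate, and the group effect is
#' tested by the drop in residual dispersion between the covariate-only and
#' covariate-plus-group fits (F test). A constant covariate degrades to a
#' Kruskal-Wallis test with a warning.
#'
#' @param response Numeric response (e.g. pairwise disparity).
#' @param group Factor (e.g. sympatric/allopatric).
#' @param covariate Numeric covariate (e.g. phylogenetic distance). Rank
#'   invariant: monotone rescaling of its units leaves the test unchanged.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
rank_ancova <- function(response, group, covariate) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  if (length(unique(covariate)) == 1) {
    warning("constant covariate: reducing to Kruskal-Wallis")
    kw <- kruskal_wallis(response, group)
    return(list(F = NA_real_, df1 = kw$df, df2 = NA_real_,
                p_value = kw$p_value))
  }
  ry <- rank(response); rx <- rank(covariate)
  full <- stats::lm(ry ~ rx + group)
  reduced <- stats::lm(ry ~ rx)
  cmp <- stats::anova(reduced, full)
  list(F = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
       p_value = cmp$`Pr(>F)`[2])
}

#' Assemble the pairwise geography-disparity table
#'
#' All unordered species pairs with overlap area, overlap index, sympatry
#' flag, per-component disparities, phylogenetic distance (from the
#' non-ultrametric tree's cophenetic distances when a tree is supplied), and
#' the color-pair label (ordered red, pink, white).
#'
#' @param ranges Named list of `species_range` objects.
#' @param fit `phyl_pca` or score matrix.
#' @param colors Named colors per species.
#' @param tree Optional `phylo` tree for phylogenetic distances.
#' @param components Components for disparity.
#' @return Data frame, one row per pair present in all inputs.
#' @export
pairwise_geo_table <- function(ranges, fit, colors, tree = NULL,
                               components = c(1, 2)) {
  disp <- pairwise_disparity(fit, components)
  sp <- intersect(names(ranges), unique(c(disp$species_a, disp$species_b)))
  disp <- disp[disp$species_a %in% sp & disp$species_b %in% sp, ]
  pd <- if (!is.null(tree)) cophenetic_distances(tree) else NULL
  prio <- c(red = 1, pink = 2, white = 3)
  rows <- lapply(seq_len(nrow(disp)), function(i) {
    a <- disp$species_a[i]; b <- disp$species_b[i]
    ov <- overlap_index(ranges[[a]], ranges[[b]])
    ca <- colors[[a]]; cb <- colors[[b]]
    pairlab <- paste(c(ca, cb)[order(prio[c(ca, cb)])], collapse = "-")
    cbind(disp[i, , drop = FALSE],
          data.frame(overlap_area = ov$overlap_area,
                     overlap_index = ov$index, sympatric = ov$sympatric,
                     color_pair = pairlab,
                     phylo_distance = if (!is.null(pd)) pd[a, b]
                                      else NA_real_,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman association between range overlap and disparity
#'
#' Among sympatric pairs only: Spearman correlation of the overlap index and
#' the overlap area with each component's disparity.
#'
#' @param pairs Output of [pairwise_geo_table()].
#' @param components Component indices.
#' @return Data frame with `measure`, `component`, `rho`, `p_value`.
#' @export
overlap_disparity_correlation <- function(pairs, components = c(1, 2)) {
  s <- pairs[pairs$sympatric & is.finite(pairs$overlap_index), ]
  if (nrow(s) < 3) stop("need >= 3 sympatric pairs", call. = FALSE)
  rows <- list()
  for (meas in c("overlap_index", "overlap_area")) for (k in components) {
    ct <- suppressWarnings(stats::cor.test(
      s[[meas]], s[[paste0("disparity_PC", k)]], method = "spearman"))
    rows[[paste(meas, k)]] <- data.frame(
      measure = meas, component = paste0("PC", k),
      rho = unname(ct$estimate), p_value = ct$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
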