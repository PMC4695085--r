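#' Project GPS coordinates to planar meters
#'
#' Converts WGS84 latitude/longitude to universal transverse Mercator
#' (UTM) easting/northing using the standard ellipsoidal series; the zone
#' is taken from the centroid so that all points of a survey share one
#' zone (Ofu Island falls in zone 2, southern hemisphere). A local
#' equirectangular projection about the centroid is available as a
#' fallback; over a backreef pool's extent the two agree to well under a
#' meter.
#'
#' @param latitude,longitude Decimal degrees; samples with missing
#'   coordinates are excluded with a warning.
#' @param sample_id Optional ids carried into the result.
#' @param method "utm" (default) or "equirect".
#' @return Data.frame with `sample_id`, `x`, `y` (meters) and attributes
#'   `method`, `zone`, `hemisphere`.
#' @export
project_positions <- function(latitude, longitude, sample_id = NULL,
                              method = c("utm", "equirect")) {
  method <- match.arg(method)
  if (is.null(sample_id)) sample_id <- as.character(seq_along(latitude))
  ok <- !is.na(latitude) & !is.na(longitude)
  if (any(!ok))
    warning("excluding ", sum(!ok), " sample(s) without GPS coordinates: ",
            paste(sample_id[!ok], collapse = ", "))
  lat <- latitude[ok]; lon <- longitude[ok]
  stopifnot(all(abs(lat) <= 90), all(abs(lon) <= 180))
  if (method == "utm") {
    zone <- floor((mean(lon) + 180) / 6) + 1
    xy <- utm_forward(lat, lon, zone)
    south <- mean(lat) < 0
    if (south) xy$y <- xy$y + 1e7
    out <- data.frame(sample_id = sample_id[ok], x = xy$x, y = xy$y,
                      stringsAsFactors = FALSE)
    attr(out, "zone") <- zone
    attr(out, "hemisphere") <- if (south) "S" else "N"
  } else {
    lat0 <- mean(lat) * pi / 180
    r <- 6371008.8
    out <- data.frame(sample_id = sample_id[ok],
                      x = r * cos(lat0) * (lon - mean(lon)) * pi / 180,
                      y = r * (lat - mean(lat)) * pi / 180,
                      stringsAsFactors = FALSE)
  }
  attr(out, "method") <- method
  out
}

# WGS84 transverse Mercator forward projection (Snyder's series).
utm_forward <- function(lat, lon, zone) {
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  lam0 <- (-183 + 6 * zone) * pi / 180
  phi <- lat * pi / 180; lam <- lon * pi / 180
  nu <- a / sqrt(1 - e2 * sin(phi)^2)
  t2 <- tan(phi)^2
  c <- ep2 * cos(phi)^2
  A <- (lam - lam0) * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  x <- 500000 + k0 * nu * (A + (1 - t2 + c) * A^3 / 6 +
    (5 - 18 * t2 + t2^2 + 72 * c - 58 * ep2) * A^5 / 120)
  y <- k0 * (M + nu * tan(phi) * (A^2 / 2 +
    (5 - t2 + 9 * c + 4 * c^2) * A^4 / 24 +
    (61 - 58 * t2 + t2^2 + 600 * c - 330 * ep2) * A^6 / 720))
  list(x = x, y = y)
}

#' Euclidean geographic distance matrix from projected positions
#'
#' @param pos Output of [project_positions()] (or any data.frame with
#'   `sample_id`, `x`, `y`).
#' @return A `dist` labelled by sample id.
#' @export
geo_distances <- function(pos) {
  m <- as.matrix(pos[, c("x", "y")])
  rownames(m) <- pos$sample_id
  dist(m)
}

#' Mantel test of matrix correlation
#'
#' Pearson correlation between the lower triangles of two distance
#' matrices, with significance from simultaneous row/column permutation
#' of the second matrix. The default alternative is one-tailed positive
#' autocorrelation.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same
#'   samples, in the same order (checked via labels when present).
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed.
#' @param alternative "greater" (default) or "two.sided".
#' @param permutations Optional explicit permutation matrix (rows are
#'   permutations of `1:n`), e.g. the full permutation group for exact
#'   tests on tiny n.
#' @return List of class `sym_mantel` with `r`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1,
                        alternative = c("greater", "two.sided"),
                        permutations = NULL) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  stopifnot(nrow(m1) == nrow(m2))
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("matrices must share sample ids in the same order")
  n <- nrow(m1)
  if (n < 4) stop("Mantel test needs at least 4 samples")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  if (sd(v1) == 0 || sd(m2[lt]) == 0)
    stop("zero variance in a distance matrix")
  r_obs <- cor(v1, m2[lt])
  if (is.null(permutations)) {
    set.seed(seed)
    permutations <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                             integer(n)))
  }
  stat <- function(p) cor(v1, m2[p, p][lt])
  r_perm <- apply(permutations, 1, stat)
  np <- length(r_perm)
  p <- if (alternative == "greater")
    (sum(r_perm >= r_obs - 1e-12) + 1) / (np + 1)
  else
    (sum(abs(r_perm) >= abs(r_obs) - 1e-12) + 1) / (np + 1)
  structure(list(r = r_obs, p_value = p, n_perm = np, seed = seed,
                 alternative = alternative), class = "sym_mantel")
}

#' @export
print.sym_mantel <- function(x, ...) {
  cat(sprintf("<sym_mantel> r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p_value, x$alternative, x$n_perm))
  invisible(x)
}

#' Spatial autocorrelation of community dissimilarity
#'
#' Convenience wrapper: subset samples, project their GPS coordinates,
#' and run the Mantel test of geographic distance against Bray-Curtis
#' dissimilarity of square-root transformed relative abundances.
#'
#' @param x A `sym_counts` table with latitude/longitude metadata.
#' @param compartment,pool,species Optional subset selectors.
#' @param n_perm,seed,alternative Passed to [mantel_test()].
#' @return A `sym_mantel` result (or NULL with a warning when fewer than
#'   4 samples carry coordinates).
#' @export
spatial_autocorrelation <- function(x, compartment = NULL, pool = NULL,
                                    species = NULL, n_perm = 999, seed = 1,
                                    alternative = "greater") {
  sub <- subset_counts(x, compartment = compartment, pool = pool,
                       species = species)
  md <- sub$metadata
  pos <- project_positions(md$latitude, md$longitude, md$sample_id)
  if (nrow(pos) < 4) {
    warning("fewer than 4 samples with coordinates; Mantel test skipped")
    return(NULL)
  }
  keep <- md$sample_id %in% pos$sample_id
  comm <- bray_curtis(sqrt_relative(sub$counts[keep, , drop = FALSE]))
  mantel_test(geo_distances(pos), comm, n_perm = n_perm, seed = seed,
              alternative = alternative)
}
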