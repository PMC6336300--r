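# Independent oracles and small fixture builders. All oracles are coded as
# plain loops/enumeration, deliberately independent of the package internals
# they check.

# points on a circle (optionally a limited arc, optionally noisy)
circlePoints <- function(n, center = c(0, 0), r = 1,
                         arc = c(0, 2 * pi), sigma = 0) {
  th <- seq(arc[1], arc[2], length.out = n + 1)[seq_len(n)]
  xy <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  if (sigma > 0) xy <- xy + matrix(rnorm(2 * n, sd = sigma), ncol = 2)
  xy
}

# a bare single-stem (or multi-stem) synthetic plot without crown clutter
makeStemPlot <- function(stems, extent = 12, ground = groundModel("flat"),
                         crown = NULL) {
  stems <- as.data.frame(stems)
  if (is.null(stems$taper)) stems$taper <- rep(0, nrow(stems))
  if (is.null(stems$id)) stems$id <- seq_len(nrow(stems))
  if (is.null(crown))
    crown <- data.frame(stem_id = integer(), x = numeric(), y = numeric(),
                        z = numeric(), radius = numeric())
  new("SyntheticPlot", extent = extent, stems = stems, ground = ground,
      crown = crown, seed = 1L)
}

# O(n^2) union-find single-linkage clustering with the pairwise
# adjacency-threshold rule; returns a membership vector
oracleCluster <- function(xy, ranges, delta_phi, delta_theta, k) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      rm <- (ranges[i] + ranges[j]) / 2
      dab <- sqrt(2 * rm^2 * (1 - cos(delta_phi * pi / 180)))
      dac <- sqrt(2 * rm^2 * (1 - cos(delta_theta * pi / 180)))
      if (d < k * max(dab, dac)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# exhaustive per-point KNN mean distances (full sort, no partial tricks)
oracleKnnMeans <- function(pts, k) {
  M <- nrow(pts)
  vapply(seq_len(M), function(i) {
    d <- numeric(0)
    for (j in seq_len(M)) {
      if (j == i) next
      d <- c(d, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
    mean(sort(d)[seq_len(min(k, length(d)))])
  }, numeric(1))
}

# analytic first-intersection range of a ray with a vertical cylinder,
# derived in the horizontal plane: distance from the ray's plan projection
# to the circle, divided by cos(elevation)
oracleCylinderRange <- function(origin, theta_deg, phi_deg, center, radius,
                                z_bottom, z_top) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  u2 <- c(cos(th) * cos(ph), cos(th) * sin(ph))
  ct <- sqrt(sum(u2^2))            # horizontal speed |cos(theta)|
  if (ct < 1e-12) return(Inf)
  w <- u2 / ct
  rel <- center - origin[1:2]
  proj <- sum(rel * w)
  perp2 <- sum(rel^2) - proj^2
  if (perp2 > radius^2) return(Inf)
  s <- proj - sqrt(radius^2 - perp2)   # plan distance to the near surface
  if (s <= 0) return(Inf)
  t <- s / ct
  z <- origin[3] + t * sin(th)
  if (z < z_bottom || z > z_top) return(Inf)
  t
}

# membership vectors describe the same partition?
samePartition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
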