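# Independent pure-R oracles used to cross-check the package's interpolation
# and region-labelling code. These deliberately take different computational
# routes from the implementation.

# Sutherland-Hodgman clip of a polygon (2-column matrix) by a*x + b*y <= c.
clip_poly_r <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- a * poly[i, 1] + b * poly[i, 2] - c
    dj <- a * poly[j, 1] + b * poly[j, 2] - c
    if (di <= 0) out <- rbind(out, poly[i, ])
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

area_poly_r <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
}

# Voronoi cell of point index i (or of an external point `pt`) within a big
# bounding box, clipped against all other sites.
voronoi_cell_r <- function(sites, i = NULL, pt = NULL, box) {
  p <- if (is.null(pt)) sites[i, ] else pt
  poly <- box
  for (j in seq_len(nrow(sites))) {
    if (!is.null(i) && j == i) next
    s <- sites[j, ]
    if (all(s == p)) next
    a <- s[1] - p[1]; b <- s[2] - p[2]
    c <- a * (p[1] + s[1]) / 2 + b * (p[2] + s[2]) / 2
    poly <- clip_poly_r(poly, a, b, c)
    if (nrow(poly) == 0) break
  }
  poly
}

# Sibson weights by the "stolen area" formulation: weight_i is the area the
# inserted query steals from site i's original Voronoi cell.
sibson_oracle <- function(sites, q) {
  rng <- apply(sites, 2, range)
  pad <- 10 * max(diff(rng[, 1]), diff(rng[, 2]), 1)
  box <- rbind(c(rng[1, 1] - pad, rng[1, 2] - pad),
               c(rng[2, 1] + pad, rng[1, 2] - pad),
               c(rng[2, 1] + pad, rng[2, 2] + pad),
               c(rng[1, 1] - pad, rng[2, 2] + pad))
  n <- nrow(sites)
  stolen <- numeric(n)
  for (i in seq_len(n)) {
    old_cell <- voronoi_cell_r(sites, i = i, box = box)
    a <- sites[i, 1] - q[1]; b <- sites[i, 2] - q[2]
    cc <- a * (q[1] + sites[i, 1]) / 2 + b * (q[2] + sites[i, 2]) / 2
    # the part of i's old cell closer to q than to site i is what q steals
    stolen_region <- clip_poly_r(old_cell, a, b, cc)
    stolen[i] <- area_poly_r(stolen_region)
  }
  stolen / sum(stolen)
}

# Direct dense-solve RBF oracle (multiquadric + linear tail), built with
# explicit loops and solved by QR.
rbf_oracle <- function(sites, values, queries, eps) {
  n <- nrow(sites)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- sqrt(sum((sites[i, ] - sites[j, ])^2))
    K[i, j] <- sqrt(r^2 + eps^2)
  }
  P <- cbind(1, sites)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- qr.solve(A, c(values, 0, 0, 0))
  out <- numeric(nrow(queries))
  for (k in seq_len(nrow(queries))) {
    r <- sqrt(rowSums(t(t(sites) - queries[k, ])^2))
    out[k] <- sum(coef[1:n] * sqrt(r^2 + eps^2)) +
      coef[n + 1] + coef[n + 2] * queries[k, 1] + coef[n + 3] * queries[k, 2]
  }
  out
}

# Brute-force 8-connected labelling of equal nonzero values by repeated
# neighbourhood scans.
label8_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (m[r, c] == 0L || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cur[1] + dr; cc <- cur[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            lab[rr, cc] == 0L && m[rr, cc] == m[r, c]) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Random site configuration with queries strictly inside the convex hull
# (random convex combinations of the sites with interior-biased weights).
random_site_config <- function(n_sites, n_queries = 3) {
  sites <- cbind(runif(n_sites), runif(n_sites))
  values <- rnorm(n_sites, 50, 15)
  qs <- t(vapply(seq_len(n_queries), function(i) {
    w <- rgamma(n_sites, 1)
    w <- w / sum(w)
    colSums(sites * w)
  }, numeric(2)))
  list(sites = sites, values = values, queries = qs)
}

# A small injection scenario on pile A1: moderate plateau (no baseline hot
# spots), anomalies placed on deep probes at given (distance, day) pairs.
make_injection_scenario <- function(at, type = "hot", seed = 1L,
                                    noise_temp_sd = 0) {
  a1 <- pilespot:::pick_pile(default_pile_specs(), "A1")
  sc <- scenario_config(a1, n_cycles = 6,
                        thermal = thermal_params(plateau_C = 45),
                        noise_sd = c(temp_C = noise_temp_sd),
                        seed = seed)
  inject_at_probes(sc, at, type = type)
}

deep_at <- function(distance_m, day) {
  tibble::tibble(distance_m = distance_m, side = "deep", level = "mid-deep",
                 day = day)
}
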