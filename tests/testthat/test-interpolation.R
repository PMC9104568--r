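test_that("natural-neighbor interpolation is exact, convex and symmetric", {
  # four corners of a square with pairwise values: centre must average
  sites <- tibble::tibble(u = c(0, 1, 1, 0), v = c(0, 0, 1, 1),
                          value = c(0, 0, 10, 10))
  centre <- natural_neighbor_interpolate(sites, tibble::tibble(u = .5, v = .5))
  expect_equal(centre$value, 5)
  w <- sibson_weights(sites, tibble::tibble(u = .5, v = .5))
  expect_equal(as.numeric(w$weights), rep(0.25, 4))
  # exact at sites
  at_sites <- natural_neighbor_interpolate(sites, sites[, c("u", "v")])
  expect_equal(at_sites$value, sites$value)
  # constant field
  const <- sites
  const$value <- 7.25
  q <- tibble::tibble(u = runif(20), v = runif(20))
  expect_equal(natural_neighbor_interpolate(const, q)$value, rep(7.25, 20))
})

test_that("degenerate site sets raise instructive errors", {
  expect_error(
    natural_neighbor_interpolate(
      tibble::tibble(u = c(0, 1), v = c(0, 0), value = c(1, 2)),
      tibble::tibble(u = .5, v = .5)),
    "boundary")
  expect_error(
    natural_neighbor_interpolate(
      tibble::tibble(u = c(0, 1, 2), v = c(0, 1, 2), value = 1:3),
      tibble::tibble(u = .5, v = .5)),
    "collinear")
  # duplicate with conflicting values is an error; same value is redundant
  dup_ok <- tibble::tibble(u = c(0, 1, 0, 0), v = c(0, 0, 1, 0),
                           value = c(1, 2, 3, 1))
  base <- tibble::tibble(u = c(0, 1, 0), v = c(0, 0, 1), value = c(1, 2, 3))
  qq <- tibble::tibble(u = 0.2, v = 0.2)
  expect_equal(natural_neighbor_interpolate(dup_ok, qq)$value,
               natural_neighbor_interpolate(base, qq)$value,
               tolerance = 1e-6)
  dup_bad <- dup_ok
  dup_bad$value[4] <- 99
  expect_error(natural_neighbor_interpolate(dup_bad, qq), "conflicting")
})

test_that("Sibson weights agree with the brute-force Voronoi-area oracle", {
  withr::local_seed(42)
  for (rep in 1:25) {
    cfg <- random_site_config(sample(5:12, 1), n_queries = 2)
    w <- sibson_weights(
      tibble::tibble(u = cfg$sites[, 1], v = cfg$sites[, 2],
                     value = cfg$values),
      tibble::tibble(u = cfg$queries[, 1], v = cfg$queries[, 2]))
    for (k in seq_len(nrow(cfg$queries))) {
      expect_false(w$exterior[k])
      wk <- w$weights[k, ]
      expect_true(all(wk >= -1e-12))
      expect_lt(abs(sum(wk) - 1), 1e-9)
      oracle <- sibson_oracle(cfg$sites, cfg$queries[k, ])
      expect_equal(wk, oracle, tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("natural-neighbor fields respect min-max bounds on random inputs", {
  withr::local_seed(7)
  for (rep in 1:20) {
    cfg <- random_site_config(sample(5:12, 1), n_queries = 10)
    sites <- tibble::tibble(u = cfg$sites[, 1], v = cfg$sites[, 2],
                            value = cfg$values)
    res <- natural_neighbor_interpolate(
      sites, tibble::tibble(u = cfg$queries[, 1], v = cfg$queries[, 2]))
    expect_true(all(res$value >= min(cfg$values) - 1e-9))
    expect_true(all(res$value <= max(cfg$values) + 1e-9))
  }
})

test_that("RBF interpolation is exact at sites and reproduces affine fields", {
  withr::local_seed(11)
  sites <- tibble::tibble(u = runif(8), v = runif(8), value = rnorm(8, 40, 10))
  at_sites <- rbf_interpolate(sites, sites[, c("u", "v")])
  expect_lt(max(abs(at_sites$value - sites$value)) / max(abs(sites$value)),
            1e-8)
  # affine reproduction through the polynomial tail
  aff <- sites
  aff$value <- 3 + 2 * aff$u - 5 * aff$v
  q <- tibble::tibble(u = runif(30, -0.5, 1.5), v = runif(30, -0.5, 1.5))
  got <- rbf_interpolate(aff, q)
  expect_equal(got$value, 3 + 2 * q$u - 5 * q$v, tolerance = 1e-7)
  # constants for every kernel
  const <- sites
  const$value <- 9.5
  for (k in c("multiquadric", "thin-plate", "gaussian")) {
    expect_equal(rbf_interpolate(const, q, kernel = k)$value,
                 rep(9.5, 30), tolerance = 1e-7)
  }
  # single site: exact at the site
  one <- tibble::tibble(u = 0.3, v = 0.4, value = 12)
  expect_equal(rbf_interpolate(one, one[, c("u", "v")])$value, 12)
  # duplicates are singular
  expect_error(rbf_interpolate(dplyr::bind_rows(sites, sites[1, ]), q),
               "singular")
})

test_that("RBF matches an independent dense-solve oracle", {
  withr::local_seed(23)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    S <- cbind(runif(n), runif(n))
    vals <- rnorm(n, 0, 5)
    Q <- cbind(runif(20), runif(20))
    eps <- 0.3
    got <- rbf_interpolate(
      tibble::tibble(u = S[, 1], v = S[, 2], value = vals),
      tibble::tibble(u = Q[, 1], v = Q[, 2]), shape_param = eps)
    expect_equal(got$value, rbf_oracle(S, vals, Q, eps), tolerance = 1e-8)
  }
})

test_that("boundary assembly places ambient ring and channel overrides", {
  piles <- default_pile_specs()
  outline <- cross_section_outline(piles, "A1")
  amb <- ambient_conditions(temp_C = 20, o2_pct = 20.9)
  bnd <- assemble_boundary(outline, amb)
  expect_true(all(bnd$o2_pct == 20.9))
  expect_true(all(bnd$temp_C == 20))
  expect_equal(sum(bnd$source == "channel"), 3L)
  # boundary points sit on the outline, never strictly interior
  shrunk <- outline$vertices
  centr <- c(mean(shrunk$y), mean(shrunk$z))
  shrunk$y <- centr[1] + (shrunk$y - centr[1]) * 0.999
  shrunk$z <- centr[2] + (shrunk$z - centr[2]) * 0.999
  inner <- pilespot:::points_in_outline(
    structure(list(vertices = shrunk), class = "cross_section_outline"),
    bnd$u, bnd$v)
  expect_true(all(!inner | bnd$v == 0))  # base points lie on the base edge
  # channel override: 3 channels at 18 degrees on a 20 degree day
  bnd2 <- assemble_boundary(outline, amb,
                            channel_records = tibble::tibble(
                              temp_C = 18, o2_pct = 20.9, co2_pct = 0.04,
                              co_ppm = 0))
  expect_equal(sum(bnd2$temp_C == 18), 3L)
})

test_that("cross-section fields are exact, bounded and clamped", {
  piles <- default_pile_specs()
  a1 <- piles[piles$pile_id == "A1", ]
  grid <- build_sampling_grid(a1)
  sec <- grid[grid$distance_m == 17.5, ]
  sec$day <- 22L
  amb <- ambient_conditions(temp_C = 18)
  # uniform interior at ambient -> uniform field
  sec$temp_C <- 18
  fg <- cross_section_field(sec, a1, "temp_C", ambient = amb)
  expect_equal(range(fg$values[fg$mask]), c(18, 18))
  # one hot probe among ambient: maximum at that probe's node, bounds hold
  sec$temp_C <- 18
  sec$temp_C[sec$side == "deep"] <- 70
  fg2 <- cross_section_field(sec, a1, "temp_C", ambient = amb)
  vals <- fg2$values[fg2$mask]
  expect_gte(min(vals), 18 - 1e-9)
  expect_lte(max(vals), 70 + 1e-9)
  co <- pilespot:::grid_node_coords(fg2)
  peak <- which(fg2$values == max(vals), arr.ind = TRUE)
  deep <- sec[sec$side == "deep", ]
  expect_lt(abs(co$u[peak[1, 2]] - deep$y_m), 0.15)
  expect_lt(abs(co$v[peak[1, 1]] - deep$z_m), 0.15)
  # gas clamping: negative overshoot impossible for NN, but clamp counts are
  # recorded on the grid object
  expect_equal(fg2$n_clamped, 0L)
  # no usable record -> skip with warning, NULL result
  empty <- sec[0, ]
  expect_warning(out <- cross_section_field(empty, a1, "temp_C", ambient = amb),
                 "Skip|No usable")
  expect_null(out)
})

test_that("longitudinal fields reproduce probe values and need two distances", {
  piles <- default_pile_specs()
  a1 <- piles[piles$pile_id == "A1", ]
  grid <- build_sampling_grid(a1)
  left <- grid[grid$side == "left", ]
  left$day <- 22L
  # monotone values along x reproduce exactly at probe nodes
  left$temp_C <- 20 + left$x_m / 2 + left$z_m
  lf <- longitudinal_field(left, a1, "temp_C",
                           ambient = ambient_conditions(temp_C = 18))
  co <- pilespot:::grid_node_coords(lf)
  for (i in seq_len(nrow(left))) {
    ri <- which.min(abs(co$v - left$z_m[i]))
    ci <- which.min(abs(co$u - left$x_m[i]))
    # nearest node within half a cell of the probe: close to the probe value
    expect_lt(abs(lf$values[ri, ci] - left$temp_C[i]), 1.5)
  }
  expect_error(longitudinal_field(left[left$distance_m == 2.5, ], a1,
                                  "temp_C"),
               "two distances")
  # constant input (matching ambient) stays constant
  left$temp_C <- 18
  lf2 <- longitudinal_field(left, a1, "temp_C",
                            ambient = ambient_conditions(temp_C = 18))
  expect_equal(range(lf2$values[lf2$mask]), c(18, 18), tolerance = 1e-6)
})

test_that("field grids tidy and summarize consistently", {
  vals <- matrix(1:12, 3, 4)
  mask <- matrix(TRUE, 3, 4)
  g <- pilespot:::new_field_grid(vals, mask, c(0, 0), 0.5, "cross-section",
                                 "temp_C")
  td <- tidy(g)
  expect_equal(nrow(td), 12L)
  expect_equal(sort(unique(td$u)), c(0.25, 0.75, 1.25, 1.75))
  expect_equal(sort(unique(td$v)), c(0.25, 0.75, 1.25))
  gl <- glance(g)
  expect_equal(gl$n_nodes, 12L)
  expect_equal(gl$min, 1)
  expect_equal(gl$max, 12)
})
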