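#' Masked regular-grid field over a pile section
#'
#' A `field_grid` holds one reconstructed variable (temperature or a gas) on
#' a regular grid over a cross-section (u = y across the pile, v = z) or a
#' longitudinal section (u = x along the pile, v = z). `values` is an
#' `n_rows x n_cols` matrix whose first row is the TOP of the section (so it
#' writes directly as an ESRI ASCII raster); `mask` marks nodes inside the
#' pile outline. Values are defined exactly where the mask is `TRUE`.
#'
#' @param values,mask Matrices of equal dimension.
#' @param origin `(u, v)` of the lower-left grid corner.
#' @param cell_size_m Grid cell size, metres.
#' @param plane `"cross-section"` or `"longitudinal"`.
#' @param variable One of `"temp_C"`, `"o2_pct"`, `"co2_pct"`, `"co_ppm"`.
#' @param pile_id,day,distance_m,side Optional provenance metadata.
#' @param n_clamped Number of nodes clamped to physical gas bounds.
#' @return A `field_grid` object.
#' @keywords internal
new_field_grid <- function(values, mask, origin, cell_size_m, plane,
                           variable, pile_id = NA_character_,
                           day = NA_integer_, distance_m = NA_real_,
                           side = NA_character_, n_clamped = 0L) {
  stopifnot(identical(dim(values), dim(mask)))
  structure(list(values = values, mask = mask, origin = origin,
                 cell_size_m = cell_size_m, plane = plane,
                 variable = variable, pile_id = pile_id, day = day,
                 distance_m = distance_m, side = side,
                 n_clamped = as.integer(n_clamped)),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat("field_grid [", x$plane, "] ", x$variable, ": ",
      nrow(x$values), " x ", ncol(x$values), " @ ", x$cell_size_m, " m, ",
      sum(x$mask), " masked-in nodes\n", sep = "")
  invisible(x)
}

# Node coordinates of a field grid, aligned with values/mask in column-major
# order. Row 1 of the matrix is the top row (largest v).
grid_node_coords <- function(grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  cs <- grid$cell_size_m
  u <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  v <- grid$origin[2] + (nr - seq_len(nr) + 0.5) * cs
  list(u = u, v = v)
}

#' Tidy a field grid into a long tibble
#'
#' @param x A `field_grid`.
#' @param ... Unused.
#' @return A tibble with `u`, `v`, `value` for masked-in nodes.
#' @method tidy field_grid
#' @export
tidy.field_grid <- function(x, ...) {
  co <- grid_node_coords(x)
  idx <- which(x$mask, arr.ind = TRUE)
  tibble(u = co$u[idx[, 2]], v = co$v[idx[, 1]],
         value = x$values[idx],
         variable = x$variable)
}

#' @method glance field_grid
#' @export
glance.field_grid <- function(x, ...) {
  vals <- x$values[x$mask]
  tibble(plane = x$plane, variable = x$variable,
         pile_id = x$pile_id, day = x$day,
         n_rows = nrow(x$values), n_cols = ncol(x$values),
         cell_size_m = x$cell_size_m, n_nodes = sum(x$mask),
         min = min(vals), max = max(vals), mean = mean(vals),
         n_clamped = x$n_clamped)
}

#' Heatmap of a reconstructed field
#'
#' @param object A `field_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot field_grid
#' @export
autoplot.field_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = object$variable) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = if (identical(object$plane, "longitudinal")) "x (m, from fan)" else "y (m)",
      y = "z (m)",
      title = paste0(object$pile_id, " day ", object$day, " — ",
                     object$variable, " (", object$plane, ")")
    ) +
    ggplot2::theme_minimal()
}

check_sites <- function(sites, min_sites = 3L, require_non_collinear = TRUE) {
  sites <- as_tibble(sites)
  stopifnot(all(c("u", "v", "value") %in% names(sites)))
  dup <- duplicated(sites[, c("u", "v")])
  if (any(dup)) {
    # a repeated site with the same value is redundant, not contradictory
    full_dup <- duplicated(sites[, c("u", "v", "value")])
    if (!all(dup == full_dup))
      abort("Duplicate site coordinates with conflicting values.")
    sites <- sites[!dup, ]
  }
  if (nrow(sites) < min_sites)
    abort(paste0("At least ", min_sites, " sites are required; add boundary ",
                 "points (ambient ring / aeration channels) to thicken the set."))
  if (require_non_collinear && nrow(sites) >= 3) {
    m <- cbind(sites$u - mean(sites$u), sites$v - mean(sites$v))
    if (qr(m)$rank < 2)
      abort("All sites are collinear; add boundary points off the line.")
  }
  sites
}

#' Natural-neighbor (Sibson) interpolation of scattered sites
#'
#' The value at a query point is the area-stealing convex combination of the
#' neighbouring sites' values: inserting the query into the sites' Voronoi
#' diagram, each weight is the fraction of the new cell's area stolen from
#' that site's old cell. Weights are nonnegative and sum to one, so the
#' interpolant is exact at sites and bounded by the input min/max. Queries
#' outside the sites' convex hull (where Sibson coordinates are undefined)
#' fall back to the nearest site's value and are flagged; with the standard
#' ambient boundary ring the hull covers the whole outline, so masked queries
#' are always interior.
#'
#' @param sites Tibble with columns `u`, `v`, `value`; at least 3
#'   non-collinear sites, no duplicate coordinates.
#' @param queries Tibble (or matrix) with columns `u`, `v`.
#' @return A tibble `u`, `v`, `value`, `exterior`.
#' @export
natural_neighbor_interpolate <- function(sites, queries) {
  sites <- check_sites(sites)
  q <- as_tibble(queries)
  res <- cpp_sibson(as.matrix(sites[, c("u", "v")]), sites$value,
                    as.matrix(q[, c("u", "v")]))
  if (any(res$exterior))
    inform(paste0(sum(res$exterior), " query point(s) outside the site hull; ",
                  "nearest-site fallback used."))
  tibble(u = q$u, v = q$v, value = res$value, exterior = res$exterior)
}

#' Sibson weights of query points
#'
#' Exposes the natural-neighbor weight vectors themselves (one row per query,
#' one column per site); rows are `NA` for queries outside the site hull.
#'
#' @inheritParams natural_neighbor_interpolate
#' @return A list with `weights` (matrix) and `exterior` (logical).
#' @export
sibson_weights <- function(sites, queries) {
  sites <- check_sites(sites)
  q <- as_tibble(queries)
  cpp_sibson_weights(as.matrix(sites[, c("u", "v")]),
                     as.matrix(q[, c("u", "v")]))
}

rbf_kernel_fun <- function(kernel, eps) {
  switch(kernel,
    multiquadric = function(r) sqrt(r^2 + eps^2),
    `thin-plate` = function(r) ifelse(r > 0, r^2 * log(r), 0),
    gaussian = function(r) exp(-(r / eps)^2),
    abort(paste0("Unknown RBF kernel '", kernel, "'."))
  )
}

#' Radial-basis-function interpolation of scattered sites
#'
#' Exact scattered-data interpolation as a weighted sum of radial kernels
#' augmented with a linear polynomial tail (so constant and affine fields are
#' reproduced exactly). The default kernel is the multiquadric with shape
#' parameter equal to the mean nearest-neighbour site spacing. Duplicate
#' sites make the system singular and raise an error; an ill-conditioned
#' solve falls back to a small ridge with a warning.
#'
#' @param sites Tibble with `u`, `v`, `value`; at least 1 site.
#' @param queries Tibble with `u`, `v`.
#' @param kernel `"multiquadric"`, `"thin-plate"` or `"gaussian"`.
#' @param shape_param Kernel shape parameter; default mean nearest-neighbour
#'   spacing of the sites.
#' @return A tibble `u`, `v`, `value`.
#' @export
rbf_interpolate <- function(sites, queries,
                            kernel = c("multiquadric", "thin-plate", "gaussian"),
                            shape_param = NULL) {
  kernel <- match.arg(kernel)
  sites <- as_tibble(sites)
  stopifnot(all(c("u", "v", "value") %in% names(sites)))
  n <- nrow(sites)
  if (n < 1) abort("At least one site is required.")
  S <- as.matrix(sites[, c("u", "v")])
  if (anyDuplicated(S))
    abort("Duplicate site coordinates make the RBF system singular.")
  D <- as.matrix(stats::dist(S))
  if (is.null(shape_param)) {
    if (n >= 2) {
      nn <- apply(D + diag(Inf, n), 1, min)
      shape_param <- mean(nn)
    } else shape_param <- 1
  }
  phi <- rbf_kernel_fun(kernel, shape_param)
  K <- phi(D)
  P <- cbind(1, S)
  np <- ncol(P)
  use_poly <- n >= np  # polynomial tail needs enough sites to be determined
  if (use_poly) {
    A <- rbind(cbind(K, P), cbind(t(P), matrix(0, np, np)))
    rhs <- c(sites$value, rep(0, np))
  } else {
    A <- K
    rhs <- sites$value
  }
  scale <- mean(abs(A[seq_len(n), seq_len(n)])) + 1e-300
  coef <- tryCatch(solve(A, rhs), error = function(e) NULL)
  kappa <- if (!is.null(coef)) kappa(A, exact = FALSE) else Inf
  if (is.null(coef) || kappa > 1e12) {
    warn(paste0("RBF system ill-conditioned (kappa ~ ",
                format(kappa, digits = 3),
                "); ridge-regularized solve used."))
    ridge <- 1e-10 * scale
    Ar <- A
    diag(Ar)[seq_len(n)] <- diag(Ar)[seq_len(n)] + ridge
    coef <- solve(Ar, rhs)
  }
  q <- as_tibble(queries)
  Q <- as.matrix(q[, c("u", "v")])
  # kernel evaluations query-by-site
  Dq <- sqrt(outer(Q[, 1], S[, 1], "-")^2 + outer(Q[, 2], S[, 2], "-")^2)
  pred <- phi(Dq) %*% coef[seq_len(n)]
  if (use_poly)
    pred <- pred + cbind(1, Q) %*% coef[n + seq_len(np)]
  tibble(u = q$u, v = q$v, value = as.numeric(pred))
}

# Evenly spaced points along a closed polygon, by arc length.
polygon_ring_points <- function(vertices, n) {
  v <- as.matrix(vertices)
  v <- rbind(v, v[1, ])
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  per <- sum(seg)
  s <- (seq_len(n) - 1) / n * per
  cum <- c(0, cumsum(seg))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  t <- (s - cum[idx]) / seg[idx]
  tibble(u = v[idx, 1] + t * (v[idx + 1, 1] - v[idx, 1]),
         v = v[idx, 2] + t * (v[idx + 1, 2] - v[idx, 2]))
}

#' Assemble boundary conditions for a cross-section
#'
#' Places `n_boundary` points evenly (by arc length) along the cross-section
#' outline carrying ambient values (atmospheric gases, outside temperature),
#' plus the three aeration-channel positions on the base carrying channel
#' measurements when provided, otherwise the forced-air default (ambient
#' gases at ambient temperature). Ring points falling on top of a channel
#' position are dropped in favour of the channel value.
#'
#' @param outline A `cross_section_outline`.
#' @param ambient A one-row tibble from [ambient_conditions()].
#' @param channel_records Optional tibble with `temp_C`, `o2_pct`, `co2_pct`,
#'   `co_ppm` per channel (recycled if one row).
#' @param n_boundary Number of outline points (default 24).
#' @return A tibble `u`, `v`, `temp_C`, `o2_pct`, `co2_pct`, `co_ppm`,
#'   `source` (`"ambient"` / `"channel"`).
#' @export
assemble_boundary <- function(outline, ambient, channel_records = NULL,
                              n_boundary = 24) {
  stopifnot(inherits(outline, "cross_section_outline"))
  ring <- polygon_ring_points(outline$vertices[, c("y", "z")], n_boundary)
  # always include the outline vertices so the site hull covers the whole
  # (convex) section and no masked query is exterior
  ring <- dplyr::distinct(dplyr::bind_rows(
    ring, tibble(u = outline$vertices$y, v = outline$vertices$z)))
  ring$temp_C <- ambient$temp_C
  ring$o2_pct <- ambient$o2_pct
  ring$co2_pct <- ambient$co2_pct
  ring$co_ppm <- ambient$co_ppm
  ring$source <- "ambient"
  ch <- tibble(u = outline$channels$y, v = outline$channels$z)
  if (is.null(channel_records)) {
    ch$temp_C <- ambient$temp_C
    ch$o2_pct <- ambient$o2_pct
    ch$co2_pct <- ambient$co2_pct
    ch$co_ppm <- ambient$co_ppm
  } else {
    cr <- as_tibble(channel_records)
    if (nrow(cr) == 1L) cr <- cr[rep(1, nrow(ch)), ]
    if (nrow(cr) != nrow(ch))
      abort("`channel_records` must have 1 row or one row per channel.")
    ch$temp_C <- cr$temp_C
    ch$o2_pct <- cr$o2_pct
    ch$co2_pct <- cr$co2_pct
    ch$co_ppm <- cr$co_ppm
  }
  ch$source <- "channel"
  # drop ring points that collide with a channel position
  tol <- 0.25 * (sum(sqrt(diff(c(outline$vertices$y, outline$vertices$y[1]))^2 +
                          diff(c(outline$vertices$z, outline$vertices$z[1]))^2)) /
                   n_boundary)
  too_close <- purrr::map_lgl(seq_len(nrow(ring)), function(i)
    any(sqrt((ring$u[i] - ch$u)^2 + (ring$v[i] - ch$v)^2) < tol))
  dplyr::bind_rows(ring[!too_close, ], ch)
}

gas_bounds <- list(o2_pct = c(0, 21), co2_pct = c(0, 100), co_ppm = c(0, Inf))

clamp_field <- function(values, mask, variable) {
  b <- gas_bounds[[variable]]
  if (is.null(b)) return(list(values = values, n_clamped = 0L))
  inside <- which(mask)
  v <- values[inside]
  n_cl <- sum(v < b[1] | v > b[2], na.rm = TRUE)
  values[inside] <- pmin(pmax(v, b[1]), b[2])
  list(values = values, n_clamped = n_cl)
}

# Build the empty masked grid over a polygon outline.
make_masked_grid <- function(vertices, cell_size_m) {
  u_rng <- range(vertices[[1]])
  v_rng <- range(vertices[[2]])
  nc <- max(1L, ceiling(diff(u_rng) / cell_size_m))
  nr <- max(1L, ceiling(diff(v_rng) / cell_size_m))
  origin <- c(u_rng[1], v_rng[1])
  u <- origin[1] + (seq_len(nc) - 0.5) * cell_size_m
  v <- origin[2] + (nr - seq_len(nr) + 0.5) * cell_size_m
  nodes <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  pu <- u[nodes$col]
  pv <- v[nodes$row]
  bnd <- as.matrix(vertices)
  bnd <- rbind(bnd, bnd[1, ])
  inside <- as.logical(mgcv::in.out(bnd, cbind(pu, pv)))
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(nodes$row, nodes$col)] <- inside
  list(mask = mask, origin = origin, nr = nr, nc = nc, u = u, v = v,
       nodes = nodes, pu = pu, pv = pv, inside = inside)
}

#' Reconstruct a cross-section field by natural-neighbor interpolation
#'
#' Builds the masked grid over the pile's cross-section outline, combines the
#' interior probe readings at this (pile, day, distance) with the ambient
#' boundary ring and channel points, and interpolates with Sibson
#' natural-neighbor coordinates. Gas fields are clamped to physical bounds
#' post hoc (clamp count recorded on the grid). A section with no usable
#' interior record is skipped with a warning and returns `NULL`, mirroring
#' the rejection of incomplete sections before modelling.
#'
#' @param records Measurement tibble for one (pile, day, distance): columns
#'   `side`, `level`, `y_m`, `z_m` (probe tip coordinates) and the variable.
#' @param pile A one-row `pile_spec`.
#' @param variable `"temp_C"`, `"o2_pct"`, `"co2_pct"` or `"co_ppm"`.
#' @param ambient Ambient conditions for the day ([ambient_conditions()]).
#' @param channel_records Optional channel measurements (see
#'   [assemble_boundary()]).
#' @param cell_size_m Grid resolution, metres (default 0.1).
#' @param n_boundary Boundary ring size (default 24).
#' @return A `field_grid`, or `NULL` if no interior record is available.
#' @export
cross_section_field <- function(records, pile, variable,
                                ambient = ambient_conditions(),
                                channel_records = NULL,
                                cell_size_m = 0.1, n_boundary = 24) {
  stopifnot(nrow(pile) == 1L)
  recs <- as_tibble(records)
  recs <- recs[!is.na(recs[[variable]]), ]
  if (nrow(recs) == 0L) {
    warn("No usable interior record for this section; skipping.")
    return(NULL)
  }
  outline <- cross_section_outline(pile)
  bnd <- assemble_boundary(outline, ambient, channel_records, n_boundary)
  sites <- dplyr::bind_rows(
    tibble(u = recs$y_m, v = recs$z_m, value = recs[[variable]]),
    tibble(u = bnd$u, v = bnd$v, value = bnd[[variable]])
  )
  g <- make_masked_grid(outline$vertices[, c("y", "z")], cell_size_m)
  vals <- matrix(NA_real_, g$nr, g$nc)
  if (any(g$inside)) {
    qin <- tibble(u = g$pu[g$inside], v = g$pv[g$inside])
    interp <- natural_neighbor_interpolate(sites, qin)
    vals[cbind(g$nodes$row[g$inside], g$nodes$col[g$inside])] <- interp$value
  }
  cl <- clamp_field(vals, g$mask, variable)
  new_field_grid(cl$values, g$mask, g$origin, cell_size_m,
                 plane = "cross-section", variable = variable,
                 pile_id = pile$pile_id,
                 day = if (!is.null(recs$day)) recs$day[1] else NA_integer_,
                 distance_m = if (!is.null(recs$distance_m)) recs$distance_m[1] else NA_real_,
                 n_clamped = cl$n_clamped)
}

#' Reconstruct a longitudinal-section field by RBF interpolation
#'
#' Builds the (x, z) field along one side of the pile from that side's probe
#' readings at all cross-section distances, with ambient boundary points
#' along the top and both ends and channel/forced-air values along the base,
#' interpolated with a multiquadric RBF plus linear tail. Requires records
#' from at least two distances.
#'
#' @param records Measurement tibble for one (pile, day, side) across
#'   distances: columns `distance_m` (or `x_m`), `z_m` and the variable.
#' @inheritParams cross_section_field
#' @param kernel,shape_param Passed to [rbf_interpolate()].
#' @return A `field_grid` on the longitudinal plane.
#' @export
longitudinal_field <- function(records, pile, variable,
                               ambient = ambient_conditions(),
                               channel_records = NULL,
                               cell_size_m = 0.1, n_boundary = 24,
                               kernel = "multiquadric", shape_param = NULL) {
  stopifnot(nrow(pile) == 1L)
  recs <- as_tibble(records)
  if (!"x_m" %in% names(recs)) recs$x_m <- recs$distance_m
  recs <- recs[!is.na(recs[[variable]]), ]
  if (length(unique(recs$x_m)) < 2L)
    abort("Longitudinal reconstruction needs records from at least two distances.")
  L <- pile$length_m
  h <- pile$height_m
  rect <- tibble(u = c(0, L, L, 0), v = c(0, 0, h, h))
  ring <- dplyr::distinct(dplyr::bind_rows(polygon_ring_points(rect, n_boundary),
                                           rect))
  base <- ring$v <= 1e-9
  ch_temp <- if (!is.null(channel_records)) mean(channel_records$temp_C) else ambient$temp_C
  ch_vals <- list(
    temp_C = ch_temp,
    o2_pct = if (!is.null(channel_records)) mean(channel_records$o2_pct) else ambient$o2_pct,
    co2_pct = if (!is.null(channel_records)) mean(channel_records$co2_pct) else ambient$co2_pct,
    co_ppm = if (!is.null(channel_records)) mean(channel_records$co_ppm) else ambient$co_ppm
  )
  ring$value <- ifelse(base, ch_vals[[variable]], ambient[[variable]])
  sites <- dplyr::bind_rows(
    tibble(u = recs$x_m, v = recs$z_m, value = recs[[variable]]),
    tibble(u = ring$u, v = ring$v, value = ring$value)
  )
  g <- make_masked_grid(rect, cell_size_m)
  qs <- tibble(u = g$pu[g$inside], v = g$pv[g$inside])
  interp <- rbf_interpolate(sites, qs, kernel = kernel,
                            shape_param = shape_param)
  vals <- matrix(NA_real_, g$nr, g$nc)
  vals[cbind(g$nodes$row[g$inside], g$nodes$col[g$inside])] <- interp$value
  cl <- clamp_field(vals, g$mask, variable)
  new_field_grid(cl$values, g$mask, g$origin, cell_size_m,
                 plane = "longitudinal", variable = variable,
                 pile_id = pile$pile_id,
                 day = if (!is.null(recs$day)) recs$day[1] else NA_integer_,
                 side = if (!is.null(recs$side)) recs$side[1] else NA_character_,
                 n_clamped = cl$n_clamped)
}
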