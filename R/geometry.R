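#' Define a pile (static bioreactor) specification
#'
#' A pile spec records the geometry, construction and campaign design of one
#' aerated static-pile bioreactor: overall dimensions, the three probing
#' heights H1 < H2 < H3, whether the pile has concrete sidewalls, and the
#' weekly sampling design (number of cycles, cross-section distances from the
#' aeration fan, points per cross-section).
#'
#' The standard design probes each cross-section at three heights on both
#' sides of the pile plus one "deep" point at mid height, i.e. 7 points per
#' cross-section, at four distances along the 50 m pile axis.
#'
#' @param pile_id Pile label, e.g. `"A1"`.
#' @param length_m,width_m,height_m Pile dimensions in metres.
#' @param h1_m,h2_m,h3_m Probing heights in metres, `0 < h1 < h2 < h3 < height_m`.
#' @param has_sidewalls Does the pile have vertical concrete sidewalls?
#' @param n_cycles Number of weekly measurement cycles.
#' @param cross_section_distances_m Distances of the sampling cross-sections
#'   from the fan end, metres. Default `c(2.5, 17.5, 32.5, 47.5)`.
#' @param n_points_per_cross_section Probes per cross-section (default 7).
#' @param process_days Total duration of the biostabilization process, days.
#' @param initial_mass_Mg Initial waste mass in megagrams (optional).
#' @param covered Is the pile membrane-covered? Default `TRUE`.
#' @param apex_frac Top width of the membrane cover as a fraction of the base
#'   width (default 0.25).
#' @param wall_height_m Height of the concrete sidewalls for sidewall piles,
#'   metres (default 1; must lie between H1 and H2 so that H1 probing is
#'   blocked by the wall but H2 is not).
#'
#' @return A one-row tibble of class `pile_spec`.
#' @examples
#' a1 <- pile_spec("A1", height_m = 2.5, width_m = 8.1,
#'                 h1_m = 0.625, h2_m = 1.25, h3_m = 1.875, n_cycles = 10,
#'                 process_days = 69)
#' @export
pile_spec <- function(pile_id, length_m = 50, width_m, height_m,
                      h1_m, h2_m, h3_m,
                      has_sidewalls = FALSE, n_cycles,
                      cross_section_distances_m = c(2.5, 17.5, 32.5, 47.5),
                      n_points_per_cross_section = 7L,
                      process_days = NA_real_, initial_mass_Mg = NA_real_,
                      covered = TRUE, apex_frac = 0.25, wall_height_m = 1) {
  if (!is.finite(width_m) || width_m <= 0)
    abort("`width_m` must be positive.")
  if (!is.finite(height_m) || height_m <= 0)
    abort("`height_m` must be positive.")
  if (!(0 < h1_m && h1_m < h2_m && h2_m < h3_m && h3_m < height_m))
    abort("Probing heights must satisfy 0 < H1 < H2 < H3 < height_m.")
  if (any(cross_section_distances_m < 0 | cross_section_distances_m > length_m))
    abort("All cross-section distances must lie within [0, length_m].")
  if (has_sidewalls && !(wall_height_m > h1_m && wall_height_m < h2_m))
    abort("`wall_height_m` must lie strictly between H1 and H2 for sidewall piles.")
  out <- tibble(
    pile_id = as.character(pile_id),
    length_m = length_m, width_m = width_m, height_m = height_m,
    h1_m = h1_m, h2_m = h2_m, h3_m = h3_m,
    has_sidewalls = isTRUE(has_sidewalls),
    n_cycles = as.integer(n_cycles),
    n_cross_sections = length(cross_section_distances_m),
    cross_section_distances_m = list(cross_section_distances_m),
    n_points_per_cross_section = as.integer(n_points_per_cross_section),
    process_days = process_days,
    initial_mass_Mg = initial_mass_Mg,
    covered = isTRUE(covered),
    apex_frac = apex_frac,
    wall_height_m = wall_height_m
  )
  class(out) <- c("pile_spec", class(out))
  out
}

#' Read pile specifications from a structured config file
#'
#' The config is a YAML document with one block per pile under a `piles` key;
#' field names match the arguments of [pile_spec()]. The packaged default
#' config (`system.file("extdata", "pile_config.yaml", package = "pilespot")`)
#' encodes the six-pile industrial campaign: membrane piles A1, A2, B1, B2 and
#' sidewall piles C1, C2, 50 m long, probed at four cross-sections with seven
#' points each.
#'
#' @param path Path to a YAML pile config. Default: the packaged config.
#' @return A tibble of class `pile_spec`, one row per pile.
#' @export
read_pile_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pile_config.yaml",
                                package = "pilespot", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$piles)) abort("Pile config must contain a `piles` block.")
  specs <- purrr::map(cfg$piles, function(p) {
    rlang::exec(pile_spec, !!!p)
  })
  out <- dplyr::bind_rows(specs)
  class(out) <- c("pile_spec", setdiff(class(out), "pile_spec"))
  out
}

#' @rdname read_pile_config
#' @export
default_pile_specs <- function() read_pile_config()

pick_pile <- function(piles, pile_id) {
  row <- piles[piles$pile_id == pile_id, ]
  if (nrow(row) != 1L)
    abort(paste0("Pile '", pile_id, "' not found (or not unique) in the spec table."))
  row
}

#' Cross-section outline polygon of a pile
#'
#' Membrane-only piles are modelled as an isosceles trapezoid (base =
#' `width_m`, top = `apex_frac * width_m` at `height_m`); sidewall piles have
#' vertical left/right edges up to `wall_height_m`, then the sloped membrane
#' to the apex. Three aeration channels are evenly spaced across the base at
#' 1/4, 1/2 and 3/4 of the width.
#'
#' @param pile A one-row `pile_spec` (or a multi-row table plus `pile_id`).
#' @param pile_id Pile to select when `pile` has several rows.
#' @return A list of class `cross_section_outline` with elements `vertices`
#'   (tibble `y`, `z`, counter-clockwise, not closed) and `channels`
#'   (tibble `y`, `z = 0`).
#' @export
cross_section_outline <- function(pile, pile_id = NULL) {
  if (!is.null(pile_id)) pile <- pick_pile(pile, pile_id)
  stopifnot(nrow(pile) == 1L)
  w2 <- pile$width_m / 2
  wt2 <- pile$apex_frac * pile$width_m / 2
  h <- pile$height_m
  if (pile$has_sidewalls) {
    wh <- pile$wall_height_m
    verts <- tibble(
      y = c(-w2, w2, w2, wt2, -wt2, -w2),
      z = c(0, 0, wh, h, h, wh)
    )
  } else {
    verts <- tibble(
      y = c(-w2, w2, wt2, -wt2),
      z = c(0, 0, h, h)
    )
  }
  channels <- tibble(y = c(-1, 0, 1) * pile$width_m / 4, z = 0)
  structure(list(vertices = verts, channels = channels,
                 pile_id = pile$pile_id, width_m = pile$width_m,
                 height_m = pile$height_m),
            class = "cross_section_outline")
}

# Half-width of the pile cross-section at height z (outline surface |y|).
half_width_at <- function(pile, z) {
  w2 <- pile$width_m / 2
  wt2 <- pile$apex_frac * pile$width_m / 2
  h <- pile$height_m
  if (pile$has_sidewalls) {
    wh <- pile$wall_height_m
    ifelse(z <= wh, w2, w2 + (wt2 - w2) * (z - wh) / (h - wh))
  } else {
    w2 + (wt2 - w2) * z / h
  }
}

# Strict point-in-polygon test against an outline.
points_in_outline <- function(outline, y, z) {
  bnd <- as.matrix(outline$vertices[, c("y", "z")])
  bnd <- rbind(bnd, bnd[1, ])
  as.logical(mgcv::in.out(bnd, cbind(y, z)))
}

#' Cartesian coordinates of a probe tip
#'
#' Probes enter horizontally from the pile surface at the requested height and
#' the tip sits `insertion_depth_m` along the probe axis inside the waste.
#' Exception: on sidewall piles the lowest measurement (H1) is made at a 45
#' degree downward angle over the wall, so the tip is offset by
#' `insertion_depth_m / sqrt(2)` in both y and z from its entry point on the
#' surface (the entry height is chosen so the tip lands exactly at H1). Deep
#' measurements sit on the pile centreline at mid height (H2).
#'
#' Coordinates: x along the pile axis from the fan end, y across the width
#' (0 at the centreline, left negative), z above ground.
#'
#' @param pile A one-row `pile_spec`.
#' @param distance_m Distance of the cross-section from the fan, metres.
#' @param side `"left"`, `"right"` or `"deep"`.
#' @param level `"H1"`, `"H2"`, `"H3"` or `"mid-deep"`.
#' @param insertion_depth_m Probe insertion depth, metres (>= 1.25).
#' @return A tibble with `x_m`, `y_m`, `z_m`.
#' @export
probe_coordinates <- function(pile, distance_m, side, level,
                              insertion_depth_m = 1.25) {
  stopifnot(nrow(pile) == 1L)
  if (insertion_depth_m < 1.25)
    abort("Probes must be inserted at least 1.25 m deep.")
  side <- match.arg(side, c("left", "right", "deep"))
  if (side == "deep") {
    if (!identical(level, "mid-deep"))
      abort("Deep measurements use level 'mid-deep'.")
    return(tibble(x_m = distance_m, y_m = 0, z_m = pile$h2_m))
  }
  lv <- c(H1 = pile$h1_m, H2 = pile$h2_m, H3 = pile$h3_m)
  if (!level %in% names(lv))
    abort(paste0("Unknown probe level '", level, "'."))
  z <- unname(lv[[level]])
  sgn <- if (side == "left") -1 else 1
  if (pile$has_sidewalls && level == "H1") {
    # 45-degree insertion over the wall: entry on the surface above, tip at H1
    off <- insertion_depth_m / sqrt(2)
    z_entry <- z + off
    y_entry <- half_width_at(pile, z_entry)
    y <- sgn * (y_entry - off)
  } else {
    y <- sgn * (half_width_at(pile, z) - insertion_depth_m)
  }
  tibble(x_m = distance_m, y_m = y, z_m = z)
}

#' Generate the probe sampling grid for one measurement cycle
#'
#' For each cross-section distance the design places probes at H1, H2, H3 on
#' both sides of the pile plus one deep point at mid height on one side
#' (`deep_side`): 7 points per cross-section, so the standard four-section
#' design yields 28 locations per cycle. Every generated location is checked
#' to lie strictly inside the cross-section outline; a probe whose required
#' depth would push it outside the pile is a hard error naming the location.
#'
#' @param piles A `pile_spec` table (one or more piles).
#' @param insertion_depth_m Probe insertion depth, metres. Default 1.25.
#' @param deep_side Side carrying the deep measurement (`"right"` default).
#' @return A tibble with one row per probe location: `pile_id`, `distance_m`,
#'   `side`, `level`, `x_m`, `y_m`, `z_m`, `insertion_depth_m`, `probe_id`.
#' @examples
#' grid <- build_sampling_grid(default_pile_specs())
#' nrow(dplyr::filter(grid, pile_id == "A1"))  # 28
#' @export
build_sampling_grid <- function(piles, insertion_depth_m = 1.25,
                                deep_side = c("right", "left")) {
  deep_side <- match.arg(deep_side)
  rows <- purrr::map(seq_len(nrow(piles)), function(i) {
    pile <- piles[i, ]
    if (pile$n_cross_sections == 0L) return(NULL)
    dists <- pile$cross_section_distances_m[[1]]
    design <- dplyr::bind_rows(
      tidyr::expand_grid(distance_m = dists,
                         side = c("left", "right"),
                         level = c("H1", "H2", "H3")),
      tibble(distance_m = dists, side = "deep", level = "mid-deep")
    )
    design <- dplyr::arrange(design, .data$distance_m,
                             factor(.data$side, c("left", "right", "deep")),
                             .data$level)
    coords <- purrr::pmap(design, function(distance_m, side, level) {
      probe_coordinates(pile, distance_m, side, level, insertion_depth_m)
    })
    out <- dplyr::bind_cols(pile_id = pile$pile_id, design,
                            dplyr::bind_rows(coords))
    outline <- cross_section_outline(pile)
    inside <- points_in_outline(outline, out$y_m, out$z_m)
    if (!all(inside)) {
      bad <- out[!inside, ][1, ]
      abort(paste0(
        "Probe at required depth exits the pile outline: ",
        bad$pile_id, " ", bad$distance_m, " m ", bad$side, " ", bad$level, "."))
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(pile_id = character(), distance_m = double(),
                  side = character(), level = character(), x_m = double(),
                  y_m = double(), z_m = double(),
                  insertion_depth_m = double(), probe_id = character()))
  }
  out$insertion_depth_m <- insertion_depth_m
  # deep side convention: deep probes sit on the centreline, but record which
  # side the lance comes from
  out$side[out$side == "deep"] <- "deep"
  out$probe_id <- paste(out$pile_id, out$distance_m, out$side, out$level,
                        sep = "_")
  out
}

#' Campaign design arithmetic
#'
#' The campaign point count of a design is `n_cycles * n_cross_sections *
#' n_points_per_cross_section` summed over piles; the standard six-pile
#' industrial campaign totals 1288 measurements.
#'
#' @param piles A `pile_spec` table.
#' @return A tibble with per-pile `points_per_cycle` and `campaign_points`.
#' @export
campaign_design <- function(piles) {
  piles |>
    as_tibble() |>
    dplyr::transmute(
      pile_id = .data$pile_id,
      n_cycles = .data$n_cycles,
      points_per_cycle = .data$n_cross_sections * .data$n_points_per_cross_section,
      campaign_points = .data$n_cycles * .data$points_per_cycle
    )
}

#' Zone labels for probe locations
#'
#' Maps each probe location to a non-empty subset of the controlled vocabulary
#' `{center, bottom, top, left, right, near-sidewall}` used in spot
#' localization reports: deep probes are central; H1 contributes `bottom`, H3
#' `top`; the probe side contributes `left`/`right`; on sidewall piles, probes
#' within `margin_m` of the wall plane — and the 45-degree H1 probes, which
#' are the wall-adjacent samples by design — add `near-sidewall`.
#'
#' @param grid A probe-location tibble from [build_sampling_grid()].
#' @param piles A `pile_spec` table covering all piles in `grid`.
#' @param margin_m Near-sidewall margin from the wall plane, metres.
#' @return `grid` with an added list-column `zones` (character vectors).
#' @export
zone_label <- function(grid, piles, margin_m = 0.5) {
  info <- as_tibble(piles)[, c("pile_id", "width_m", "has_sidewalls")]
  g <- dplyr::left_join(as_tibble(grid), info, by = "pile_id")
  g$zones <- purrr::pmap(
    list(g$side, g$level, g$y_m, g$width_m, g$has_sidewalls),
    function(side, level, y, width, walls) {
      if (side == "deep" || level == "mid-deep") return("center")
      z <- character()
      if (level == "H1") z <- c(z, "bottom")
      if (level == "H3") z <- c(z, "top")
      z <- c(z, side)
      if (isTRUE(walls) &&
          (abs(y) >= width / 2 - margin_m || level == "H1"))
        z <- c(z, "near-sidewall")
      if (length(z) == 0L) z <- "center"
      z
    })
  g$width_m <- NULL
  g$has_sidewalls <- NULL
  g
}
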