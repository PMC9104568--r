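#' Hot/cold spot criteria
#'
#' A hot spot is a localized region where, simultaneously, temperature
#' exceeds 60 degrees C, O2 falls below 15 % and CO2 exceeds 5 % (an
#' overheated, oxygen-starved zone); a cold spot has temperature below 30,
#' O2 above 15 and CO2 below 5 (an under-sanitized zone). Inequalities are
#' strict by default (a reading exactly at a threshold is not a spot); CO is
#' deliberately not part of either criterion and is reported alongside spots
#' for interpretation only.
#'
#' @param hot_temp_gt,hot_o2_lt,hot_co2_gt Hot-spot thresholds.
#' @param cold_temp_lt,cold_o2_gt,cold_co2_lt Cold-spot thresholds.
#' @param strict Use strict inequalities (default `TRUE`).
#' @return A list of class `spot_criteria`.
#' @export
spot_criteria <- function(hot_temp_gt = 60, hot_o2_lt = 15, hot_co2_gt = 5,
                          cold_temp_lt = 30, cold_o2_gt = 15, cold_co2_lt = 5,
                          strict = TRUE) {
  if (!(hot_temp_gt > cold_temp_lt))
    abort("Hot temperature threshold must exceed the cold one.")
  if (any(c(hot_temp_gt, hot_o2_lt, hot_co2_gt,
            cold_temp_lt, cold_o2_gt, cold_co2_lt) <= 0))
    abort("Spot thresholds must be positive.")
  structure(list(hot_temp_gt = hot_temp_gt, hot_o2_lt = hot_o2_lt,
                 hot_co2_gt = hot_co2_gt, cold_temp_lt = cold_temp_lt,
                 cold_o2_gt = cold_o2_gt, cold_co2_lt = cold_co2_lt,
                 strict = isTRUE(strict)),
            class = "spot_criteria")
}

#' Classify a reading as hot spot, cold spot or neither
#'
#' Vectorized over the three inputs. All three conditions of a type must be
#' met at the same place and time; hot and cold are mutually exclusive by
#' construction (their temperature conditions cannot hold together).
#'
#' @param temp_C,o2_pct,co2_pct Readings (finite; `NA` classifies as `NA`).
#' @param criteria A [spot_criteria()].
#' @return Character vector in `{"hot", "cold", "none"}`.
#' @examples
#' classify_point(65, 10, 7)   # "hot"
#' classify_point(25, 18, 2)   # "cold"
#' classify_point(60, 15, 5)   # "none": thresholds are strict
#' @export
classify_point <- function(temp_C, o2_pct, co2_pct,
                           criteria = spot_criteria()) {
  gt <- if (criteria$strict) `>` else `>=`
  lt <- if (criteria$strict) `<` else `<=`
  hot <- gt(temp_C, criteria$hot_temp_gt) &
    lt(o2_pct, criteria$hot_o2_lt) & gt(co2_pct, criteria$hot_co2_gt)
  cold <- lt(temp_C, criteria$cold_temp_lt) &
    gt(o2_pct, criteria$cold_o2_gt) & lt(co2_pct, criteria$cold_co2_lt)
  out <- ifelse(hot, "hot", ifelse(cold, "cold", "none"))
  out[is.na(temp_C) | is.na(o2_pct) | is.na(co2_pct)] <- NA_character_
  out
}

#' Detect hot/cold spots from probe records
#'
#' For each (pile, day, cross-section distance) with at least one probe
#' classified hot (resp. cold), emits exactly one spot record of that type —
#' the counting unit is the distance occurrence, not the probe, matching how
#' campaign inventories are tallied. Zones are the union of the triggering
#' probes' zone labels; a distance may yield both a hot and a cold record on
#' the same day if different probes trigger each. Records missing any of
#' temperature, O2 or CO2 are rejected first.
#'
#' @param records Measurement tibble (`pile_id`, `day`, `distance_m`, `side`,
#'   `level`, `temp_C`, `o2_pct`, `co2_pct`, ...).
#' @param criteria A [spot_criteria()].
#' @param piles A `pile_spec` table for zone labelling; defaults to the
#'   packaged six-pile config.
#' @param provenance Provenance tag for the resulting inventory.
#' @return A spot inventory tibble: `pile_id`, `day`, `distance_m`, `type`,
#'   `zones` (list), `probes` (list), `localization`.
#' @export
detect_spots <- function(records, criteria = spot_criteria(),
                         piles = default_pile_specs(),
                         provenance = "measured") {
  recs <- reject_incomplete(records)$kept
  recs <- recs[recs$side %in% c("left", "right", "deep"), ]
  if (nrow(recs) == 0L)
    return(empty_inventory(provenance))
  recs$type <- classify_point(recs$temp_C, recs$o2_pct, recs$co2_pct, criteria)
  hits <- recs[recs$type != "none", ]
  if (nrow(hits) == 0L)
    return(empty_inventory(provenance))
  grid <- zone_label(build_sampling_grid(piles), piles)
  zl <- grid[, c("pile_id", "distance_m", "side", "level", "zones")]
  hits <- dplyr::left_join(hits, zl,
                           by = c("pile_id", "distance_m", "side", "level"))
  hits$zones <- purrr::map(hits$zones, function(z) z %||% "center")
  if (!"probe_id" %in% names(hits))
    hits$probe_id <- paste(hits$pile_id, hits$distance_m, hits$side,
                           hits$level, sep = "_")
  out <- hits |>
    dplyr::group_by(.data$pile_id, .data$day, .data$distance_m, .data$type) |>
    dplyr::summarise(
      zones = list(sort(unique(unlist(.data$zones)))),
      probes = list(sort(unique(.data$probe_id))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$pile_id, .data$day, .data$distance_m, .data$type)
  out$localization <- purrr::map_chr(out$zones, zones_to_phrase)
  new_spot_inventory(out, provenance = provenance)
}

empty_inventory <- function(provenance) {
  new_spot_inventory(
    tibble(pile_id = character(), day = integer(), distance_m = double(),
           type = character(), zones = list(), probes = list(),
           localization = character()),
    provenance = provenance)
}

# Human-readable localization phrase from zone tags, in the reporting style
# of campaign inventories ("in the bottom, left side, near to sidewalls").
zones_to_phrase <- function(zones) {
  if (length(zones) == 0L) return("")
  bits <- c(
    if ("center" %in% zones) "in the center",
    if ("top" %in% zones) "in the top",
    if ("bottom" %in% zones) "in the bottom",
    if ("left" %in% zones) "left side",
    if ("right" %in% zones) "right side",
    if ("near-sidewall" %in% zones) "near to sidewalls"
  )
  paste(bits, collapse = ", ")
}

#' Exclusion windows for spot inventories
#'
#' An exclusion window removes spot records of one type for one pile within
#' a day range — e.g. cold-spot records during the startup weeks when the
#' whole pile is still near ambient temperature and "cold" is not a
#' localized anomaly. The default windows exclude cold spots for piles A1
#' and A2 during days 1–16 (their extended startup lag).
#'
#' @param pile_id,type,day_start,day_end Window fields (vectorized).
#' @return A tibble of windows.
#' @export
exclusion_window <- function(pile_id, type, day_start, day_end) {
  tibble(pile_id = pile_id, type = type,
         day_start = as.integer(day_start), day_end = as.integer(day_end))
}

#' @rdname exclusion_window
#' @export
default_exclusion_windows <- function() {
  exclusion_window(c("A1", "A2"), "cold", 1L, 16L)
}

#' Remove spot records falling inside exclusion windows
#'
#' @param inventory A spot inventory.
#' @param windows A tibble from [exclusion_window()]; an empty or `NULL`
#'   window set is the identity.
#' @return The filtered inventory (provenance preserved).
#' @export
apply_exclusions <- function(inventory, windows = default_exclusion_windows()) {
  if (is.null(windows) || nrow(windows) == 0L) return(inventory)
  prov <- attr(inventory, "provenance")
  inv <- as_tibble(inventory)
  drop <- rep(FALSE, nrow(inv))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    drop <- drop | (inv$pile_id == w$pile_id & inv$type == w$type &
                      inv$day >= w$day_start & inv$day <= w$day_end)
  }
  new_spot_inventory(inv[!drop, ], provenance = prov)
}

#' Count spot records for one pile and type
#'
#' Each (distance, day) occurrence counts once.
#'
#' @param inventory A spot inventory.
#' @param pile_id Pile label.
#' @param type `"hot"` or `"cold"`.
#' @return An integer count.
#' @export
count_spots <- function(inventory, pile_id, type) {
  inv <- as_tibble(inventory)
  sum(inv$pile_id == pile_id & inv$type == type)
}

#' Per-pile hot/cold spot counts
#'
#' @param inventory A spot inventory.
#' @return A tibble `pile_id`, `hot`, `cold`.
#' @export
spot_counts <- function(inventory) {
  inv <- as_tibble(inventory)
  if (nrow(inv) == 0L)
    return(tibble(pile_id = character(), hot = integer(), cold = integer()))
  wide <- inv |>
    dplyr::count(.data$pile_id, .data$type) |>
    tidyr::pivot_wider(names_from = "type", values_from = "n",
                       values_fill = 0L)
  for (col in c("hot", "cold"))
    if (!col %in% names(wide)) wide[[col]] <- 0L
  dplyr::arrange(wide[, c("pile_id", "hot", "cold")], .data$pile_id)
}

#' @method glance spot_inventory
#' @export
glance.spot_inventory <- function(x, ...) {
  tibble(provenance = attr(x, "provenance"),
         n_records = nrow(x),
         n_hot = sum(x$type == "hot"),
         n_cold = sum(x$type == "cold"),
         n_piles = dplyr::n_distinct(x$pile_id))
}

#' @method tidy spot_inventory
#' @export
tidy.spot_inventory <- function(x, ...) {
  out <- as_tibble(x)
  out$zones <- purrr::map_chr(out$zones, paste, collapse = ";")
  out$probes <- purrr::map_chr(out$probes, paste, collapse = ";")
  out
}

#' Campaign spot-occurrence timeline
#'
#' @param object A spot inventory.
#' @param ... Unused.
#' @return A ggplot: day vs cross-section distance, faceted by pile, coloured
#'   by spot type.
#' @method autoplot spot_inventory
#' @export
autoplot.spot_inventory <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$distance_m,
                                   colour = .data$type,
                                   shape = .data$type)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~pile_id) +
    ggplot2::scale_colour_manual(values = c(hot = "#d7301f", cold = "#0570b0")) +
    ggplot2::labs(x = "day of process", y = "distance from fan (m)") +
    ggplot2::theme_bw()
}

#' Connected hot/cold regions of reconstructed fields
#'
#' Generalizes the point criteria to continuous fields: every masked grid
#' node is classified against the criteria, same-type nodes are grouped by
#' 8-connectivity, and regions smaller than `min_area_m2` are discarded.
#' Useful for localizing and sizing anomalies on reconstructed sections.
#'
#' @param temp_grid,o2_grid,co2_grid `field_grid`s sharing plane, mask,
#'   origin and resolution.
#' @param criteria A [spot_criteria()].
#' @param min_area_m2 Minimum region area to keep (default 0.05).
#' @return A tibble: `type`, `region_id`, `n_nodes`, `area_m2`,
#'   `centroid_u`, `centroid_v`.
#' @export
field_spot_regions <- function(temp_grid, o2_grid, co2_grid,
                               criteria = spot_criteria(),
                               min_area_m2 = 0.05) {
  same <- function(a, b) {
    identical(dim(a$values), dim(b$values)) &&
      identical(a$mask, b$mask) &&
      isTRUE(all.equal(a$origin, b$origin)) &&
      isTRUE(all.equal(a$cell_size_m, b$cell_size_m))
  }
  if (!same(temp_grid, o2_grid) || !same(temp_grid, co2_grid))
    abort("Field grids must share plane, mask, origin and resolution.")
  cls <- classify_point(temp_grid$values, o2_grid$values, co2_grid$values,
                        criteria)
  code <- matrix(0L, nrow(temp_grid$values), ncol(temp_grid$values))
  code[!is.na(cls) & cls == "hot" & temp_grid$mask] <- 1L
  code[!is.na(cls) & cls == "cold" & temp_grid$mask] <- 2L
  lab <- cpp_label8(code)
  if (max(lab) == 0L)
    return(tibble(type = character(), region_id = integer(),
                  n_nodes = integer(), area_m2 = double(),
                  centroid_u = double(), centroid_v = double()))
  co <- grid_node_coords(temp_grid)
  cell_area <- temp_grid$cell_size_m^2
  idx <- which(lab > 0L, arr.ind = TRUE)
  df <- tibble(label = lab[idx],
               type = c("hot", "cold")[code[idx]],
               u = co$u[idx[, 2]], v = co$v[idx[, 1]])
  out <- df |>
    dplyr::group_by(.data$label, .data$type) |>
    dplyr::summarise(n_nodes = dplyr::n(),
                     centroid_u = mean(.data$u),
                     centroid_v = mean(.data$v), .groups = "drop") |>
    dplyr::mutate(area_m2 = .data$n_nodes * cell_area) |>
    dplyr::filter(.data$area_m2 >= min_area_m2) |>
    dplyr::arrange(dplyr::desc(.data$area_m2)) |>
    dplyr::mutate(region_id = dplyr::row_number()) |>
    dplyr::select("type", "region_id", "n_nodes", "area_m2",
                  "centroid_u", "centroid_v")
  out
}
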