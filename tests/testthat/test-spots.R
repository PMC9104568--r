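test_that("point classification follows the simultaneous threshold criteria", {
  expect_equal(classify_point(65, 10, 7), "hot")
  expect_equal(classify_point(25, 18, 2), "cold")
  expect_equal(classify_point(60, 15, 5), "none")   # boundary fails strict
  expect_equal(classify_point(65, 16, 7), "none")   # one condition missing
  # vectorized, NA-propagating
  expect_equal(classify_point(c(65, 25, NA), c(10, 18, 10), c(7, 2, 7)),
               c("hot", "cold", NA))
  # non-strict mode admits boundary readings
  ns <- spot_criteria(strict = FALSE)
  expect_equal(classify_point(60, 15, 5, ns), "hot")
  # criteria invariants
  expect_error(spot_criteria(hot_temp_gt = 25), "exceed")
})

test_that("classification is monotone in each variable", {
  withr::local_seed(5)
  base <- list(temp = runif(50, 55, 65), o2 = runif(50, 10, 20),
               co2 = runif(50, 3, 7))
  cls <- classify_point(base$temp, base$o2, base$co2)
  # raising temperature never turns hot into none
  hotter <- classify_point(base$temp + 5, base$o2, base$co2)
  expect_true(all(!(cls == "hot" & hotter == "none")))
  # lowering O2 never turns hot into none
  lower_o2 <- classify_point(base$temp, pmax(base$o2 - 5, 0), base$co2)
  expect_true(all(!(cls == "hot" & lower_o2 == "none")))
  # dual statements for cold
  colder <- classify_point(base$temp - 5, base$o2, base$co2)
  expect_true(all(!(cls == "cold" & colder == "none")))
  higher_o2 <- classify_point(base$temp, base$o2 + 5, base$co2)
  expect_true(all(!(cls == "cold" & higher_o2 == "none")))
})

make_day_records <- function(pile = "A1", day = 22L) {
  piles <- default_pile_specs()
  g <- build_sampling_grid(piles[piles$pile_id == pile, ])
  g$day <- day
  g$temp_C <- 40
  g$o2_pct <- 18
  g$co2_pct <- 2
  g$co_ppm <- 50
  g
}

test_that("spot detection emits one record per triggering distance", {
  recs <- make_day_records()
  # one hot probe at 2.5 m
  i <- which(recs$distance_m == 2.5 & recs$side == "deep")
  recs$temp_C[i] <- 70
  recs$o2_pct[i] <- 8
  recs$co2_pct[i] <- 9
  inv <- detect_spots(recs)
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$distance_m, 2.5)
  expect_equal(inv$type, "hot")
  expect_equal(inv$zones[[1]], "center")
  # three hot probes at 17.5 m still one record; probes accumulate
  j <- which(recs$distance_m == 17.5 & recs$level %in% c("H1", "H2") &
               recs$side == "left")
  k <- which(recs$distance_m == 17.5 & recs$side == "deep")
  idx <- c(j, k)
  recs$temp_C[idx] <- 70; recs$o2_pct[idx] <- 8; recs$co2_pct[idx] <- 9
  inv2 <- detect_spots(recs)
  expect_equal(nrow(inv2), 2L)
  at17 <- inv2[inv2$distance_m == 17.5, ]
  expect_equal(length(at17$probes[[1]]), 3L)
  expect_setequal(at17$zones[[1]], c("center", "bottom", "left"))
  # hot and cold can coexist at one distance via different probes
  m <- which(recs$distance_m == 17.5 & recs$side == "right" &
               recs$level == "H1")
  recs$temp_C[m] <- 25; recs$o2_pct[m] <- 18; recs$co2_pct[m] <- 2
  inv3 <- detect_spots(recs)
  expect_setequal(inv3$type[inv3$distance_m == 17.5], c("hot", "cold"))
  # all ambient -> empty
  expect_equal(nrow(detect_spots(make_day_records())), 0L)
})

test_that("detected spot count never exceeds distances per day per type", {
  withr::local_seed(99)
  for (rep in 1:10) {
    recs <- make_day_records()
    n <- nrow(recs)
    recs$temp_C <- runif(n, 15, 75)
    recs$o2_pct <- runif(n, 2, 21)
    recs$co2_pct <- runif(n, 0, 12)
    inv <- detect_spots(recs)
    per <- dplyr::count(tibble::as_tibble(inv), day, type)
    expect_true(all(per$n <= length(unique(recs$distance_m))))
  }
})

test_that("exclusion windows remove matching records only", {
  inv <- load_published_inventory()
  # the A1 cold record on day 20 survives the default window (days 1-16)
  kept <- apply_exclusions(inv, default_exclusion_windows())
  expect_equal(nrow(kept), nrow(inv))
  # a wider cold window removes A1 cold day 20 but not A1 hot day 20
  w <- exclusion_window("A1", "cold", 1L, 21L)
  out <- apply_exclusions(inv, w)
  expect_equal(count_spots(out, "A1", "cold"), 2L)   # day-28 records remain
  expect_equal(count_spots(out, "A1", "hot"), 6L)
  # empty window list is the identity; provenance preserved
  same <- apply_exclusions(inv, NULL)
  expect_identical(as.data.frame(tidy(same)), as.data.frame(tidy(inv)))
  expect_equal(attr(out, "provenance"), "published-fixture")
})

test_that("counts use (pile, day, distance) occurrences", {
  inv <- load_published_inventory()
  expect_equal(count_spots(inv, "A1", "hot"), 6L)
  expect_equal(count_spots(inv, "C1", "hot"), 1L)
  expect_equal(count_spots(pilespot:::empty_inventory("measured"),
                           "A1", "hot"), 0L)
  counts <- spot_counts(inv)
  expect_equal(counts$hot[counts$pile_id == "B2"], 8L)
  expect_equal(counts$cold[counts$pile_id == "C2"], 12L)
})

make_classified_grids <- function(n = 41, cell = 0.1, hot_centre = c(2, 1.5),
                                  hot_radius = 0.5) {
  mask <- matrix(TRUE, n, n)
  mk <- function(inside_val, outside_val) {
    vals <- matrix(outside_val, n, n)
    g0 <- pilespot:::new_field_grid(vals, mask, c(0, 0), cell,
                                    "cross-section", "temp_C")
    co <- pilespot:::grid_node_coords(g0)
    for (r in seq_len(n)) for (c in seq_len(n)) {
      d <- sqrt((co$u[c] - hot_centre[1])^2 + (co$v[r] - hot_centre[2])^2)
      if (d <= hot_radius) vals[r, c] <- inside_val
    }
    pilespot:::new_field_grid(vals, mask, c(0, 0), cell, "cross-section",
                              "temp_C")
  }
  list(temp = mk(70, 40), o2 = mk(8, 18), co2 = mk(9, 2))
}

test_that("field regions find an injected anomaly and match oracles", {
  g <- make_classified_grids()
  regions <- field_spot_regions(g$temp, g$o2, g$co2)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$type, "hot")
  expect_equal(regions$centroid_u, 2, tolerance = 0.05)
  expect_equal(regions$centroid_v, 1.5, tolerance = 0.05)
  expect_equal(regions$area_m2, pi * 0.5^2, tolerance = 0.1)
  # brute-force node-scan oracle: count nodes satisfying all three criteria
  cls <- classify_point(g$temp$values, g$o2$values, g$co2$values)
  expect_equal(regions$n_nodes, sum(cls == "hot"))
  # independent labelling oracle on the classification codes
  code <- matrix(0L, nrow(g$temp$values), ncol(g$temp$values))
  code[cls == "hot"] <- 1L
  expect_equal(max(label8_oracle(code)), 1L)
  # EBImage connected-component cross-check
  eb <- EBImage::bwlabel(code)
  expect_equal(max(eb), 1)
  # all-ambient grids -> no regions
  amb <- make_classified_grids(hot_radius = -1)
  expect_equal(nrow(field_spot_regions(amb$temp, amb$o2, amb$co2)), 0L)
  # mismatched grids are a hard error
  small <- make_classified_grids(n = 21)
  expect_error(field_spot_regions(g$temp, small$o2, g$co2), "share")
})

test_that("region area shrinks as the CO2 threshold rises", {
  # smooth CO2 bump: higher co2_gt admits fewer nodes
  n <- 41
  mask <- matrix(TRUE, n, n)
  mkgrid <- function(f) {
    vals <- outer(seq_len(n), seq_len(n), function(r, c)
      f(sqrt(((c - 21) * 0.1)^2 + ((r - 21) * 0.1)^2)))
    pilespot:::new_field_grid(vals, mask, c(0, 0), 0.1, "cross-section", "x")
  }
  temp <- mkgrid(function(d) 70 + 0 * d)
  o2 <- mkgrid(function(d) 8 + 0 * d)
  co2 <- mkgrid(function(d) 12 * exp(-d^2))
  areas <- vapply(c(3, 5, 7, 9), function(th) {
    r <- field_spot_regions(temp, o2, co2,
                            spot_criteria(hot_co2_gt = th),
                            min_area_m2 = 0)
    if (nrow(r)) sum(r$area_m2[r$type == "hot"]) else 0
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_gt(areas[1], 0)
})
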