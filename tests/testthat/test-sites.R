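# circular site polygon helper (24-gon, radius in m)
circle_poly <- function(id, habitat, lon, lat, r_m = 500, clc = NA_integer_) {
  ang <- 2 * pi * (0:23) / 24
  ring <- laea_unproject(r_m * cos(ang), r_m * sin(ang), lon, lat)
  colnames(ring) <- c("lon", "lat")
  tibble::tibble(polygon_id = id, clc_code = clc, habitat = habitat,
                 geometry = list(list(ring)))
}

test_that("Corine reclassification follows the 14-class mapping", {
  expect_equal(reclassify_habitat(132), "Landfills")
  expect_equal(reclassify_habitat(131), "Landfills")  # misclassified dump sites
  expect_equal(reclassify_habitat(213), "Rice fields")
  expect_equal(reclassify_habitat(c(111, 112, 121)), rep("Urban areas", 3))
  # multi-label codes: defaults and overrides
  expect_equal(reclassify_habitat(512), "Lakes and ponds")
  expect_equal(reclassify_habitat(512, "Dams"), "Dams")
  expect_equal(reclassify_habitat(422), "Salines")
  expect_equal(reclassify_habitat(422, "Fish aquaculture"), "Fish aquaculture")
  expect_error(reclassify_habitat(999), "999")
  expect_error(reclassify_habitat(512, "Castle"), "override")
})

test_that("nearby same-habitat polygons merge by single linkage", {
  km <- function(d) d / 111.1950787   # degrees of latitude per km
  base <- dplyr::bind_rows(
    circle_poly("a", "Landfills", -5, 37),
    circle_poly("b", "Landfills", -5, 37 + km(5)))
  nodes <- merge_nearby(base, site_config(shoreline_buffer_m = 0))
  expect_equal(nrow(nodes), 1)

  far <- dplyr::bind_rows(
    circle_poly("a", "Landfills", -5, 37),
    circle_poly("b", "Landfills", -5, 37 + km(12)))
  expect_equal(nrow(merge_nearby(far, site_config(shoreline_buffer_m = 0))), 2)

  # chain A-B 6 km, B-C 6 km, A-C 12 km: one node under single linkage
  chain <- dplyr::bind_rows(
    circle_poly("a", "Landfills", -5, 37),
    circle_poly("b", "Landfills", -5, 37 + km(6)),
    circle_poly("c", "Landfills", -5, 37 + km(12)))
  expect_equal(nrow(merge_nearby(chain, site_config(shoreline_buffer_m = 0))), 1)

  # different habitats never merge
  mixed <- dplyr::bind_rows(
    circle_poly("a", "Landfills", -5, 37),
    circle_poly("b", "Marshes", -5, 37 + km(2)))
  expect_equal(nrow(merge_nearby(mixed, site_config(shoreline_buffer_m = 0))), 2)
})

test_that("merging is order-invariant and monotone in the merge radius", {
  set.seed(7)
  polys <- dplyr::bind_rows(lapply(1:8, function(i)
    circle_poly(paste0("p", i), sample(c("Landfills", "Marshes"), 1),
                runif(1, -5.3, -4.7), runif(1, 36.8, 37.3), r_m = 300)))
  cfg <- site_config(merge_km = 10, shoreline_buffer_m = 0)
  a <- merge_nearby(polys, cfg)
  b <- merge_nearby(polys[sample(nrow(polys)), ], cfg)
  expect_equal(a$centroid_lat, b$centroid_lat, tolerance = 1e-12)
  expect_equal(a$habitat, b$habitat)
  n_by_radius <- vapply(c(1, 5, 10, 30), function(r)
    nrow(merge_nearby(polys, site_config(merge_km = r,
                                         shoreline_buffer_m = 0))),
    numeric(1))
  expect_true(all(diff(n_by_radius) <= 0))
})

test_that("fixes map to containing nodes with deterministic tie-breaks", {
  km <- function(d) d / 111.1950787
  polys <- dplyr::bind_rows(
    circle_poly("a", "Landfills", -5, 37),
    circle_poly("b", "Marshes", -5, 37 + km(15)))
  nodes <- merge_nearby(polys, site_config(shoreline_buffer_m = 0))
  fx <- tibble::tibble(
    bird_id = "A",
    timestamp = as.POSIXct("2019-10-01", tz = "UTC") + 1:3,
    lon = c(nodes$centroid_lon[1], nodes$centroid_lon[2], 0),
    lat = c(nodes$centroid_lat[1], nodes$centroid_lat[2], 45))
  out <- assign_fixes(fx, nodes)
  expect_equal(out$node_id, c(nodes$node_id[1], nodes$node_id[2], NA))

  # overlapping different-habitat nodes: smallest node id wins, with warning
  over <- dplyr::bind_rows(
    circle_poly("a", "Landfills", -5, 37),
    circle_poly("b", "Marshes", -5 + km(0.4), 37))
  onodes <- merge_nearby(over, site_config(shoreline_buffer_m = 0))
  centre <- tibble::tibble(bird_id = "A",
                           timestamp = as.POSIXct("2019-10-01", tz = "UTC"),
                           lon = -5 + km(0.2), lat = 37)
  expect_warning(hit <- assign_fixes(centre, onodes), "overlap")
  expect_equal(hit$node_id, min(onodes$node_id))
})

test_that("occupancy cutoff uses the lower median south of the cutoff latitude", {
  nodes <- tibble::tibble(
    node_id = 1:9, habitat = "Landfills",
    centroid_lon = -5, centroid_lat = c(rep(36, 7), 40, 41),
    n_polygons = 1, geometry = vector("list", 9),
    birdyear_count = c(1L, 2L, 6L, 6L, 7L, 9L, 11L, 5L, 30L))
  out <- occupancy_filter(nodes, site_config())
  expect_equal(attr(out, "occupancy_threshold"), 6)
  # the count-5 node north of the cutoff is dropped too (network-wide rule)
  expect_false(8 %in% out$node_id)
  expect_true(9 %in% out$node_id)
  # even candidate count: lower of the two middle values
  even <- nodes[1:6, ]
  out2 <- occupancy_filter(even, site_config())
  expect_equal(attr(out2, "occupancy_threshold"), 6)   # sorted 1 2 6 6 7 9
  # override reproduces the applied cutoff directly
  out3 <- occupancy_filter(nodes, site_config(min_birdyears_override = 6))
  expect_equal(sort(out3$node_id), sort(out$node_id))
  # idempotent at the same threshold
  out4 <- occupancy_filter(out3, site_config(min_birdyears_override = 6))
  expect_equal(out4$node_id, out3$node_id)
  # subset property
  expect_true(all(out$node_id %in% nodes$node_id))
  # no candidates below the latitude: explicit override demanded
  north <- nodes[8:9, ]
  expect_error(occupancy_filter(north, site_config()), "override")
})

test_that("bird-year occupancy counts unique bird-years per node", {
  km <- function(d) d / 111.1950787
  polys <- dplyr::bind_rows(
    circle_poly("a", "Landfills", -5, 37),
    circle_poly("b", "Marshes", -5, 37 + km(15)))
  nodes <- merge_nearby(polys, site_config(shoreline_buffer_m = 0))
  fx <- tibble::tibble(
    bird_id = c("A", "A", "B"),
    timestamp = as.POSIXct("2019-10-01", tz = "UTC") + 1:3,
    lon = rep(nodes$centroid_lon[1], 3),
    lat = rep(nodes$centroid_lat[1], 3),
    birdyear = c("A-2019", "A-2019", "B-2019"))
  out <- node_occupancy(assign_fixes(fx, nodes), nodes)
  expect_equal(out$birdyear_count[out$node_id == nodes$node_id[1]], 2L)
  expect_equal(out$birdyear_count[out$node_id == nodes$node_id[2]], 0L)
})

test_that("GeoJSON round-trips polygons and properties", {
  polys <- dplyr::bind_rows(
    circle_poly("a", "Landfills", -5, 37),
    circle_poly("b", "Marshes", -4.5, 37.2, clc = 411L))
  path <- tempfile(fileext = ".geojson")
  write_geojson(polys, path)
  back <- read_habitat_geojson(path)
  expect_equal(back$polygon_id, polys$polygon_id)
  expect_equal(back$habitat, polys$habitat)
  expect_equal(back$geometry[[1]][[1]], polys$geometry[[1]][[1]],
               tolerance = 1e-12)
})
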