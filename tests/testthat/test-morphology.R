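test_that("segment_geometry matches closed-form cylinder geometry", {
  g <- segment_geometry(100, 2)
  expect_equal(g$lateral_area, 200 * pi, tolerance = 1e-12)
  expect_equal(g$lateral_area, 628.32, tolerance = 1e-4)
  expect_equal(g$volume, 100 * pi, tolerance = 1e-12)
  expect_equal(g$volume, 314.16, tolerance = 1e-4)
  expect_equal(g$cross_section, pi, tolerance = 1e-12)
  # algebraic identity: L = 1, d = 2/pi -> lateral area exactly 2
  expect_equal(segment_geometry(1, 2 / pi)$lateral_area, 2)
  expect_error(segment_geometry(10, 0), "invalid geometry")
  expect_error(segment_geometry(-1, 2), "invalid geometry")
})

test_that("morphology constructor enforces the tree invariants", {
  ok <- data.frame(id = 1:3, parent = c(NA, 1, 2), length = 10, diam = 1,
                   region = "soma")
  expect_s3_class(morphology(ok), "morphology")
  dup <- ok; dup$id <- c(1, 1, 3)
  expect_error(morphology(dup), "duplicate")
  orphan <- ok; orphan$parent <- c(NA, 99, 2)
  expect_error(morphology(orphan), "does not exist")
  two_roots <- ok; two_roots$parent <- c(NA, NA, 2)
  expect_error(morphology(two_roots), "exactly one root")
  cyc <- data.frame(id = 1:3, parent = c(NA, 3, 2), length = 10, diam = 1,
                    region = "soma")
  expect_error(morphology(cyc), "cycl|connected")
})

test_that("subdivision preserves total membrane area and volume", {
  for (kind in c("mitral_like", "pyramidal_like", "purkinje_like")) {
    m1 <- build_archetype(kind)
    for (n in c(2L, 3L, 5L)) {
      mn <- subdivide(m1, n)
      expect_equal(nrow(mn$segments), n * nrow(m1$segments))
      expect_equal(total_area(mn), total_area(m1), tolerance = 1e-12)
      expect_equal(total_volume(mn), total_volume(m1), tolerance = 1e-12)
    }
  }
})

test_that("load_swc computes inter-sample geometry and maps types", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 3 0 0 0 1.0 -1",
               "2 3 10 0 0 1.0 1",
               "3 3 10 10 0 0.5 2"), f)
  m <- load_swc(f)
  s <- m$segments
  expect_equal(nrow(s), 3L)           # single root sample -> root cylinder
  expect_equal(sort(s$length[!is.na(s$parent)]), c(10, 10))
  expect_equal(s$diam[s$id == 3], 1.0)
  expect_true(all(s$region[!is.na(s$parent)] == "dendrite_proximal"))
})

test_that("load_swc reports format errors with line numbers", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(character(0), f)
  expect_error(load_swc(f), "empty file")
  writeLines(c("1 1 0 0 0 5 -1",
               "2 3 10 0 0 1 1",
               "3 3 20 0 0 1 2",
               "4 3 30 0 0 1 3",
               "5 3 40 0 0 1 99"), f)
  expect_error(load_swc(f), "line 5.*99|99.*line 5")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 1", "2 3 20 0 0 1 1"), f)
  expect_error(load_swc(f), "duplicate")
})

test_that("SWC round trip is idempotent on geometry", {
  for (kind in c("mitral_like", "purkinje_like")) {
    m <- build_archetype(kind)
    f <- withr::local_tempfile(fileext = ".swc")
    write_swc(m, f)
    m2 <- load_swc(f)
    expect_equal(total_area(m2), total_area(m), tolerance = 1e-9)
    expect_equal(total_volume(m2), total_volume(m), tolerance = 1e-9)
    expect_equal(nrow(m2$segments), nrow(m$segments))
    # second round trip is exact
    f2 <- withr::local_tempfile(fileext = ".swc")
    write_swc(m2, f2)
    m3 <- load_swc(f2)
    o2 <- m2$segments[order(m2$segments$id), c("length", "diam")]
    o3 <- m3$segments[order(m3$segments$id), c("length", "diam")]
    expect_equal(o3, o2, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("archetypes carry the required regions", {
  mit <- build_archetype("mitral_like")
  expect_equal(sum(mit$segments$region == "AIS"), 1L)
  pur <- build_archetype("purkinje_like")
  expect_gte(sum(pur$segments$region == "axon_node"), 3L)
  expect_true(any(pur$segments$diam > 2.2 &
                  grepl("dendrite", pur$segments$region)))
  expect_error(build_archetype("pyramidal_like",
                               params = list(dist_L = 0, dist_n = 1)),
               "invalid geometry|positive")
  expect_error(build_archetype("unknown_kind"))
})

test_that("path_distance and remove_region behave on trees", {
  m <- build_archetype("pyramidal_like")
  pd <- path_distance(m)
  s <- m$segments
  expect_equal(pd[is.na(s$parent)], s$length[is.na(s$parent)] / 2)
  expect_true(all(diff(pd[s$region == "dendrite_distal"]) > 0))
  m2 <- remove_region(m, c("dendrite_proximal", "dendrite_distal", "tuft"))
  expect_true(all(m2$segments$region %in% c("soma", "AIS")))
  expect_error(remove_region(m, unique(s$region)), "no segments")
})
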