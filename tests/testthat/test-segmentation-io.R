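writeLinesCsv <- function(lines, path) writeLines(lines, path)

test_that("write then read is the identity on counts, roles and coordinates", {
  gen <- presetSection("small-fascicle", seed = 3)
  tf <- withr::local_tempfile(fileext = ".csv")
  writeCrossSection(gen$section, tf)
  xs2 <- readCrossSection(tf)

  ft1 <- fiberTable(gen$section)
  ft2 <- fiberTable(xs2)
  expect_equal(nrow(ft1), 39)           # 11 myelinated + 28 unmyelinated
  expect_equal(sum(ft1$myelinated), 11)
  expect_equal(ft2$entity_id, ft1$entity_id)
  expect_equal(ft2$myelinated, ft1$myelinated)
  expect_equal(ft2$x, ft1$x, tolerance = 1e-9)
  expect_equal(ft2$y, ft1$y, tolerance = 1e-9)

  fa1 <- gen$section@fascicles[[1]]
  fa2 <- xs2@fascicles[[1]]
  expect_equal(vertices(fa2@outer), vertices(fa1@outer), tolerance = 1e-9)
  expect_equal(length(fa2@nuclei), length(fa1@nuclei))
  expect_equal(contourRole(fa2@inner), "perineurium_inner")

  # SAE diameters recomputed after reload match to 1e-9
  expect_equal(ft2$diameter, ft1$diameter, tolerance = 1e-9)
  expect_equal(ft2$g_ratio, ft1$g_ratio, tolerance = 1e-9)

  # metadata round trip via the JSON sidecar
  expect_equal(donorId(xs2), donorId(gen$section))
})

test_that("empty cross-section round trips", {
  xs <- NerveCrossSection(donorId = "empty", side = "left", sex = "female")
  tf <- withr::local_tempfile(fileext = ".csv")
  writeCrossSection(xs, tf)
  xs2 <- readCrossSection(tf)
  expect_length(fascicles(xs2), 0)
  expect_equal(nerveSide(xs2), "left")
})

test_that("schema violations are rejected with the entity named", {
  tf <- withr::local_tempfile(fileext = ".csv")
  hdr <- "entity_id,role,parent_id,fascicle_id,vertex_index,x_um,y_um"
  writeLinesCsv(c(hdr,
                  "c1,unmyelinated_axon,,,0,0,0",
                  "c1,unmyelinated_axon,,,1,1,0"), tf)
  expect_error(readCrossSection(tf), "schema error.*c1")

  writeLinesCsv(c("entity_id,role,vertex_index,x_um,y_um",
                  "c1,unmyelinated_axon,0,0,0"), tf)
  expect_error(readCrossSection(tf), "schema error.*missing")

  writeLinesCsv(c(hdr, "c1,astrocyte,,,0,0,0", "c1,astrocyte,,,1,1,0",
                  "c1,astrocyte,,,2,0,1"), tf)
  expect_error(readCrossSection(tf), "schema error.*role")
})

test_that("myelin pairing and fascicle assignment errors name the entity", {
  tf <- withr::local_tempfile(fileext = ".csv")
  hdr <- "entity_id,role,parent_id,fascicle_id,vertex_index,x_um,y_um"
  shell <- c(
    sprintf("F1.PO,perineurium_outer,,F1,%d,%.4f,%.4f",
            0:31, 50 * cos(2 * pi * (0:31) / 32),
            50 * sin(2 * pi * (0:31) / 32)),
    sprintf("F1.PI,perineurium_inner,,F1,%d,%.4f,%.4f",
            0:31, 45 * cos(2 * pi * (0:31) / 32),
            45 * sin(2 * pi * (0:31) / 32)))
  tri <- function(id, role, parent, cx, r = 2)
    sprintf("%s,%s,%s,,%d,%.4f,%.4f", id, role, parent, 0:15,
            cx + r * cos(2 * pi * (0:15) / 16),
            r * sin(2 * pi * (0:15) / 16))

  # myelin outer with no inner partner
  writeLinesCsv(c(hdr, shell, tri("m1:out", "myelin_outer", "", 0)), tf)
  expect_error(readCrossSection(tf), "pairing error.*m1:out")

  # inner naming an unknown outer
  writeLinesCsv(c(hdr, shell, tri("m1:out", "myelin_outer", "", 0),
                  tri("m1:in", "myelin_inner", "ghost", 0, r = 1.2)), tf)
  expect_error(readCrossSection(tf), "pairing error.*m1:in")

  # fiber centroid outside every fascicle
  writeLinesCsv(c(hdr, shell, tri("u1", "unmyelinated_axon", "", 500)), tf)
  expect_error(readCrossSection(tf), "assignment error.*u1")
})

test_that("fiber assignment is independent of row order", {
  gen <- threeSubfascicleSection(8L, 12L, seed = 31)
  tf <- withr::local_tempfile(fileext = ".csv")
  writeCrossSection(gen$section, tf)
  lines <- readLines(tf)
  set.seed(99)
  shuffled <- c(lines[1], sample(lines[-1]))
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(shuffled, tf2)
  file.copy(sub("\\.csv$", ".json", tf), sub("\\.csv$", ".json", tf2))

  ft1 <- fiberTable(readCrossSection(tf))
  ft2 <- fiberTable(readCrossSection(tf2))
  expect_equal(ft2$entity_id, ft1$entity_id)
  expect_equal(ft2$subfascicle_id, ft1$subfascicle_id)
  expect_equal(ft2$diameter, ft1$diameter, tolerance = 1e-12)
})

test_that("validation reports violations without throwing", {
  gen <- presetSection("small-fascicle", seed = 6)
  expect_equal(nrow(validateCrossSection(gen$section)), 0)

  # myelin inner area >= outer area (constructed via new() to bypass the
  # constructor invariant)
  big <- Contour(regularPolygon(64, 5), "myelin_inner", "bad:in", "bad:out")
  small <- Contour(regularPolygon(64, 3), "myelin_outer", "bad:out")
  badFiber <- methods::new("MyelinatedFiber", outer = small, inner = big,
                           fiberDiameter = 6, axonDiameter = 10,
                           myelinThickness = -2, gRatio = 10 / 6,
                           centroid = c(0, 0))
  outer <- Contour(regularPolygon(64, 50), "perineurium_outer", "F1.PO")
  inner <- Contour(regularPolygon(64, 45), "perineurium_inner", "F1.PI")
  xs <- NerveCrossSection(list(Fascicle("F1", outer, inner,
                                        myelinated = list(badFiber))))
  rep <- validateCrossSection(xs)
  expect_true("inner_lt_outer_area" %in% rep$invariant)
  expect_true("g_ratio_range" %in% rep$invariant)
  expect_true(all(rep$entityId[rep$invariant == "inner_lt_outer_area"] ==
                  "bad:out"))

  # overlapping fascicle outer polygons, built by translation
  f1 <- Fascicle("F1", outer, inner)
  outer2 <- Contour(regularPolygon(64, 50, center = c(30, 0)),
                    "perineurium_outer", "F2.PO")
  inner2 <- Contour(regularPolygon(64, 45, center = c(30, 0)),
                    "perineurium_inner", "F2.PI")
  rep2 <- validateCrossSection(NerveCrossSection(list(
    f1, Fascicle("F2", outer2, inner2))))
  expect_true("fascicles_disjoint" %in% rep2$invariant)

  # self-intersecting (bowtie) contour
  bow <- methods::new("Contour", role = "unmyelinated_axon",
                      vertices = rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)),
                      entityId = "bow", parentId = NA_character_)
  xs3 <- NerveCrossSection(list(Fascicle(
    "F1", outer, inner,
    unmyelinated = list(methods::new("UnmyelinatedFiber", outline = bow,
                                     axonDiameter = 1,
                                     centroid = c(1, 1))))))
  expect_true("simple_polygon" %in% validateCrossSection(xs3)$invariant)
})

test_that("duplicated terminal vertex is dropped and orientation normalized", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 0))  # closed + CW
  cn <- Contour(sq, "unmyelinated_axon", "u1")
  expect_equal(nrow(vertices(cn)), 4)
  expect_gt(vagomorph:::polygonSignedArea(vertices(cn)), 0)
})
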