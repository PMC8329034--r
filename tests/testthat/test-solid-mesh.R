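test_that("a planar patch extrudes to a slab of the prescribed thickness", {
  p <- plate_preset("A")
  p$h[] <- 0
  patch <- loft_undersurface(build_skeleton(
    build_feature_points(p, plane_surface(300), heights = "parametric")))
  solid <- extrude_solid(patch, p, n_u = 21, n_v = 9)
  v <- solid$mesh$vertices
  xs <- sort(unique(round(v[, 1], 6)))
  expect_equal(length(xs), 2L)
  expect_equal(abs(diff(xs)), 3, tolerance = 1e-6)
  expect_true(0 %in% xs)
  wt <- mesh_watertight(solid$mesh)
  expect_true(wt$watertight)
  expect_equal(wt$euler, 2L)
})

test_that("constant-thickness shells measure the prescribed normal thickness everywhere", {
  d <- mean_design()
  solid <- d$solid
  n <- nrow(solid$mesh$vertices) / 2
  bottom <- solid$mesh$vertices[1:n, ]
  top <- solid$mesh$vertices[n + (1:n), ]
  th <- sqrt(rowSums((top - bottom)^2))
  expect_equal(th, rep(3, n), tolerance = 1e-3 / 3)
  expect_true(mesh_watertight(solid$mesh)$watertight)
})

test_that("offset beyond the local curvature radius is refused", {
  p <- mean_femur_parameters()
  surf <- generate_bone_surface(p, resolution = 12)
  sem <- derive_semantic_parameters(p)
  sem$t1 <- sem$t2 <- 40 # far beyond the ~13 mm concave-side radius
  patch <- mean_design()$patch
  expect_error(extrude_solid(patch, sem), "curvature|self-intersection")
})

test_that("tail hole count follows the closed form and spacing is exact arc length", {
  d <- mean_design()
  holes <- d$solid$holes
  tail <- holes[holes$kind == "tail", ]
  p <- d$semantic
  expect_equal(nrow(tail), floor((p$l1 - p$d1) / (p$s1 + p$d1)) + 1)
  expect_equal(diff(tail$arc), rep(p$s1 + p$d1, nrow(tail) - 1), tolerance = 1e-6)
  expect_equal(nrow(holes[holes$kind == "head", ]), 2L)
  expect_equal(holes$diameter[holes$kind == "head"], c(p$d2, p$d3))
})

test_that("hole count closed form holds over a sweep of l1, d1, s1", {
  d <- mean_design()
  for (case in list(c(229, 7, 6), c(100, 5, 4), c(60, 7, 20), c(229, 7, 1e6))) {
    p <- d$semantic
    p$l1 <- case[1]
    p$d1 <- case[2]
    p$s1 <- case[3]
    sol <- place_holes(d$solid, p)
    expect_equal(sum(sol$holes$kind == "tail"),
                 floor((case[1] - case[2]) / (case[3] + case[2])) + 1)
  }
  # enormous clear spacing: exactly one tail hole
  p <- d$semantic
  p$s1 <- 1e6
  expect_equal(sum(place_holes(d$solid, p)$holes$kind == "tail"), 1L)
})

test_that("hole axes are the local surface normals", {
  d <- mean_design()
  holes <- d$solid$holes
  nr <- patch_normal(d$patch, holes$u, holes$v)
  expect_lt(max(abs(nr - as.matrix(holes[, c("ax", "ay", "az")]))), 1e-6)
})

test_that("oversized tail holes are refused", {
  d <- mean_design()
  p <- d$semantic
  p$d1 <- 50
  expect_error(place_holes(d$solid, p), "minimum tail width")
})

test_that("STL round trip is exact to float32 precision and welds the soup", {
  d <- mean_design()
  mesh <- d$solid$mesh
  path <- withr::local_tempfile(fileext = ".stl")
  export_mesh(mesh, path)
  back <- read_mesh(path)
  expect_equal(nrow(back$faces), nrow(mesh$faces))
  # float32 quantization bound at the plate's coordinate magnitude
  bound <- max(abs(mesh$vertices)) * 2^-23 + 1e-7
  expect_lt(max(abs(sort(as.vector(back$vertices)) - sort(as.vector(mesh$vertices)))),
            bound)
  expect_true(mesh_watertight(back)$watertight)
})

test_that("OBJ and PLY round trips preserve vertices and faces", {
  d <- mean_design()
  mesh <- d$solid$mesh
  for (ext in c(".obj", ".ply")) {
    path <- withr::local_tempfile(fileext = ext)
    export_mesh(mesh, path)
    back <- read_mesh(path)
    expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
    expect_equal(back$faces, mesh$faces)
  }
})

test_that("empty meshes and unknown formats are refused", {
  empty <- tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  expect_error(export_mesh(empty, tempfile()), "empty")
  d <- mean_design()
  expect_error(export_mesh(d$solid$mesh, tempfile(), format = "step"), "unknown")
})

test_that("an independent mesh reader parses the exported shell as watertight", {
  d <- mean_design()
  path <- withr::local_tempfile(fileext = ".stl")
  export_mesh(d$solid$mesh, path)
  script <- sprintf(
    "import trimesh\nm = trimesh.load('%s')\nprint(int(m.is_watertight), len(m.faces))",
    path
  )
  out <- tryCatch(
    system2("python", "-", input = script, stdout = TRUE, stderr = TRUE),
    error = function(e) NULL
  )
  expect_false(is.null(out))
  parsed <- strsplit(tail(out, 1), " ")[[1]]
  expect_equal(parsed[1], "1")
  expect_equal(as.integer(parsed[2]), nrow(d$solid$mesh$faces))
})

test_that("bone surface meshes export and read back through every writer", {
  surf <- generate_bone_surface(mean_femur_parameters(), resolution = 12)
  path <- withr::local_tempfile(fileext = ".ply")
  export_mesh(surf$mesh, path)
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), nrow(surf$mesh$vertices))
})
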