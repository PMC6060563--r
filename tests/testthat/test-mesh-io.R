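test_that("meshes survive a write/read round trip in every format", {
  tet <- spine_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  sphere <- mesh_icosphere(1, radius = 0.8, center = c(0.3, -0.2, 1.1))
  for (mesh in list(tet, sphere)) for (fmt in c("off", "obj", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(mesh, path)
    back <- read_mesh(path)
    expect_equal(back$faces, mesh$faces)
    expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-5)
  }
  ## STL stores a triangle soup: vertex positions survive per-face.
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(tet, path)
  soup <- read_mesh(path)
  expect_equal(nrow(soup$faces), nrow(tet$faces))
  welded <- read_mesh(path, weld = TRUE)
  expect_equal(nrow(welded$vertices), 4L)
  expect_true(validate_mesh(welded)$watertight)
})

test_that("read_mesh reads known fixtures with exact counts", {
  off <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 4 0",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 1 2 3", "3 0 3 2"), off)
  tet <- read_mesh(off)
  expect_equal(nrow(tet$vertices), 4L)
  expect_equal(nrow(tet$faces), 4L)
  expect_true(validate_mesh(tet)$watertight)

  ## Triangulated unit cube: 8 vertices, 12 faces.
  obj <- withr::local_tempfile(fileext = ".obj")
  v <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  quads <- rbind(c(1, 3, 4, 2), c(5, 6, 8, 7), c(1, 2, 6, 5),
                 c(3, 7, 8, 4), c(1, 5, 7, 3), c(2, 4, 8, 6))
  f <- do.call(rbind, lapply(seq_len(6), function(i)
    rbind(quads[i, c(1, 2, 3)], quads[i, c(1, 3, 4)])))
  writeLines(c(sprintf("v %g %g %g", v$x, v$y, v$z),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), obj)
  cube <- read_mesh(obj)
  expect_equal(nrow(cube$vertices), 8L)
  expect_equal(nrow(cube$faces), 12L)
  expect_equal(mesh_volume(cube), 1, tolerance = 1e-12)
})

test_that("non-triangular faces raise a format error naming the face", {
  obj <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), obj)
  expect_error(read_mesh(obj), "face 1")
  off <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), off)
  expect_error(read_mesh(off), "face 1")
  expect_error(read_mesh(withr::local_tempfile(fileext = ".ply")),
               "no such file")
})

test_that("binary little-endian PLY files are read", {
  path <- withr::local_tempfile(fileext = ".ply")
  mesh <- mesh_icosphere(1)
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  writeBin(as.vector(t(mesh$vertices)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(mesh$faces))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
             endian = "little")
  }
  close(con)
  back <- read_mesh(path)
  expect_equal(back$faces, mesh$faces)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
})

test_that("validate_mesh agrees with a union-find oracle and counts boundary edges", {
  one <- mesh_icosphere(2)
  rep1 <- validate_mesh(one)
  expect_equal(rep1$n_components, 1)
  expect_true(rep1$watertight)
  expect_equal(rep1$n_nonmanifold_edges, 0L)

  ## Two disjoint icospheres in one container.
  two <- spine_mesh(rbind(one$vertices, one$vertices + 5),
                    rbind(one$faces, one$faces + nrow(one$vertices)))
  rep2 <- validate_mesh(two)
  expect_equal(rep2$n_components, 2)
  expect_true(rep2$watertight)
  expect_equal(rep2$n_components, uf_face_components(two))
  expect_equal(rep1$n_components, uf_face_components(one))

  ## One face removed: 3 boundary edges, not watertight.
  holed <- spine_mesh(one$vertices, one$faces[-1, , drop = FALSE])
  rep3 <- validate_mesh(holed)
  expect_false(rep3$watertight)
  expect_equal(rep3$n_nonmanifold_edges, 3L)
  expect_error(validate_mesh(spine_mesh(matrix(0, 0, 3),
                                        matrix(0L, 0, 3))), "empty")
})

test_that("insertion-point and metadata tables are read and validated", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("spine_id,x,y,z", "a,0,0,0", "b,1,2,3"), csv)
  ins <- read_insertion_points(csv)
  expect_equal(ins$spine_id, c("a", "b"))
  writeLines(c("spine_id,x,y,z", "a,0,0,0", "a,1,2,3"), csv)
  expect_error(read_insertion_points(csv), "duplicate")
  writeLines(c("id,x,y,z", "a,0,0,0"), csv)
  expect_error(read_insertion_points(csv), "header")
})

test_that("read_spine_records pairs meshes with insertions and flags detachment", {
  dir <- withr::local_tempdir()
  sp <- make_synthetic_spine(spine_spec("stubby"))
  write_mesh(sp$mesh, file.path(dir, "s1.ply"))
  ins <- data.frame(spine_id = "s1", x = sp$insertion[1],
                    y = sp$insertion[2], z = sp$insertion[3])
  recs <- read_spine_records(dir, ins)
  expect_length(recs, 1)
  expect_false(recs[[1]]$detached)
  ins$z <- ins$z - 1
  recs <- read_spine_records(dir, ins)
  expect_true(recs[[1]]$detached)
  expect_error(read_spine_records(dir, data.frame(spine_id = "zz", x = 0,
                                                  y = 0, z = 0)),
               "no insertion point")
})
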