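# Mesh construction, components, smoothing, ROIs, surface I/O.

test_that("icospheres have the expected counts and Euler characteristic", {
  m0 <- build_icosphere(0, 80)
  expect_equal(nrow(m0$vertices), 12)
  expect_equal(nrow(m0$faces), 20)
  expect_equal(nrow(ico2$vertices), 162)
  for (m in list(m0, ico2, ico3)) {
    V <- nrow(m$vertices); E <- nrow(m$edges); F <- nrow(m$faces)
    expect_equal(V - E + F, 2)
    expect_equal(sqrt(rowSums(m$vertices^2)), rep(80, V), tolerance = 1e-12)
  }
})

test_that("adjacency is symmetric and consistent with the edge set", {
  m <- ico2
  for (v in seq_along(m$adjacency)) {
    for (w in m$adjacency[[v]]) expect_true(v %in% m$adjacency[[w]])
  }
  n_adj <- sum(lengths(m$adjacency))
  expect_equal(n_adj, 2 * nrow(m$edges))
})

test_that("surface_mesh validates its inputs", {
  v <- matrix(rnorm(9), 3, 3)
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  expect_error(surface_mesh(v[, 1:2], rbind(c(1, 2, 3))), "3 columns")
})

test_that("connected components partition the mask deterministically", {
  expect_equal(connected_components(ico2, rep(FALSE, 162)), integer(162))
  full <- connected_components(ico2, rep(TRUE, 162))
  expect_equal(unique(full), 1L)

  # two discs separated by an unmasked ring
  d1 <- geodesic_disc(ico2, 1, 25)
  far <- which.max(geodesic_distances(ico2, 1))
  d2 <- geodesic_disc(ico2, far, 25)
  expect_equal(sum(d1 & d2), 0)
  labels <- connected_components(ico2, d1 | d2)
  expect_equal(max(labels), 2)
  expect_equal(sum(labels == labels[1]), sum(d1))
  expect_equal(sum(labels == labels[far]), sum(d2))
  # labels ordered by smallest member index and matching the oracle partition
  expect_equal(labels[1], 1L)
  expect_equal(labels > 0, (d1 | d2))
  oracle <- oracle_components(ico2, d1 | d2)
  expect_equal(labels, oracle)
})

test_that("smoothing is calibrated, linear, sum- and positivity-preserving", {
  x <- rnorm(162)
  expect_identical(smooth_metric(ico2, x, 0), x)
  expect_equal(smooth_metric(ico2, rep(3.5, 162), 15), rep(3.5, 162),
               tolerance = 1e-12)

  sx <- smooth_metric(ico2, x, 18)
  expect_equal(sum(sx), sum(x), tolerance = 1e-9 * abs(sum(x)) + 1e-9)
  y <- rnorm(162)
  expect_equal(smooth_metric(ico2, 2 * x - 3 * y, 18), 2 * sx -
                 3 * smooth_metric(ico2, y, 18), tolerance = 1e-12)
  xp <- abs(x)
  expect_true(all(smooth_metric(ico2, xp, 18) >= 0))

  # empirical kernel width: smooth a delta, fit a Gaussian profile in
  # squared geodesic distance; FWHM within 15% of requested
  m <- build_icosphere(4, 80)
  d <- geodesic_distances(m, 1)
  for (fwhm in c(20, 30)) {
    delta <- numeric(nrow(m$vertices)); delta[1] <- 1
    sm <- smooth_metric(m, delta, fwhm)
    keep <- sm > max(sm) * 0.01
    sig <- sqrt(-1 / (2 * coef(lm(log(sm[keep]) ~ I(d[keep]^2)))[[2]]))
    expect_lt(abs(2.3548 * sig - fwhm) / fwhm, 0.15)
  }
  expect_error(smooth_metric(ico2, x, -1), "nonnegative")
})

test_that("sphere ROIs select vertices by Euclidean distance", {
  center <- ico2$vertices[7, ]
  expect_equal(sum(sphere_roi(ico2, center + c(0, 0, 500), 10)), 0)
  expect_equal(sum(sphere_roi(ico2, c(0, 0, 0), 1000)), 162)
  mask <- sphere_roi(ico2, center, 30)
  brute <- sqrt(colSums((t(ico2$vertices) - center)^2)) <= 30
  expect_equal(mask, brute)
  expect_true(mask[7])
})

test_that("geodesic discs match an independent Dijkstra oracle", {
  expect_equal(which(geodesic_disc(ico2, 11, 0)), 11L)
  d_oracle <- oracle_dijkstra(ico2, 11)
  for (r in c(20, 45, 80)) {
    disc <- geodesic_disc(ico2, 11, r)
    expect_equal(disc, d_oracle <= r)
    # discs are edge-connected
    labels <- connected_components(ico2, disc)
    expect_equal(max(labels), 1L)
  }
  expect_error(geodesic_disc(ico2, 0, 10), "outside mesh")
})

test_that("GIFTI surface and metric files round-trip", {
  surf <- withr::local_tempfile(fileext = ".surf.gii")
  write_gifti_surface(ico2, surf)
  back <- read_gifti_surface(surf)
  expect_equal(back$vertices, unname(ico2$vertices), tolerance = 1e-6)
  expect_identical(back$faces, ico2$faces)

  fun <- withr::local_tempfile(fileext = ".func.gii")
  vals <- matrix(rnorm(3 * 162), 3, 162)
  write_gifti_metric(vals, fun)
  expect_equal(read_gifti_metric(fun), vals, tolerance = 1e-6)

  # ASCII-encoded data arrays parse too
  ascii <- withr::local_tempfile(fileext = ".func.gii")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n<GIFTI Version="1.0" ',
    'NumberOfDataArrays="1">\n<DataArray Intent="NIFTI_INTENT_NONE" ',
    'DataType="NIFTI_TYPE_FLOAT32" Dimensionality="1" Dim0="4" ',
    'Encoding="ASCII" Endian="LittleEndian">\n',
    "<Data>1.5 -2 0.25 4e2</Data>\n</DataArray>\n</GIFTI>"), ascii)
  expect_equal(as.vector(read_gifti_metric(ascii)), c(1.5, -2, 0.25, 400))
})

test_that("plain-array mesh and metric files round-trip", {
  co <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_mesh_arrays(ico2, co, fa)
  back <- read_mesh_arrays(co, fa)
  expect_equal(back$vertices, unname(ico2$vertices), tolerance = 1e-12)
  expect_identical(back$faces, ico2$faces)

  mt <- withr::local_tempfile(fileext = ".tsv")
  vals <- matrix(rnorm(2 * 162), 2, 162)
  write_metric_tsv(vals, mt)
  expect_equal(read_metric_tsv(mt), vals, tolerance = 1e-12)
})
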