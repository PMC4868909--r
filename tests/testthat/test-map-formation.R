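# Reaction-diffusion lattice: multistable reaction, evolution, statistics.

test_that("reaction has stable integer roots and repelling separatrices", {
  for (d in 0:3) expect_equal(reaction(d, 4), 0)
  for (s in c(0.5, 1.5, 2.5)) expect_equal(reaction(s, 4), 0)
  expect_gt(reaction(1.9, 4), 0)    # drifts up toward 2
  expect_lt(reaction(2.1, 4), 0)    # drifts down toward 2
  expect_gt(reaction(-0.7, 4), 0)   # below the lattice: pulled back to 0
  expect_lt(reaction(3.7, 4), 0)    # above: pulled back to D-1
  # locally attracting: a small displacement shrinks under the update
  for (x0 in c(1.1, 1.95, 3.2)) {
    x <- x0
    for (i in 1:200) x <- x + 0.5 * reaction(x, 4)
    expect_equal(x, round(x0), tolerance = 1e-6)
  }
  expect_error(reaction(1, 1), "D must be")
})

test_that("without diffusion every site converges to its nearest root", {
  # uniform init inside a basin
  lat <- rdLattice(4, 4, D = 4, alpha = 0.5, dU = 0, seed = 1)
  lat@X[] <- 2.2
  expect_true(all(abs(evolveNoDiffusion(lat, 100)@X - 2) < 1e-6))
  # exact roots are fixed points
  lat@X <- matrix(rep(0:3, 4) + 0, 4, 4)
  expect_equal(evolveNoDiffusion(lat, 50)@X, lat@X)
  # seeded 32 x 32 lattice matches the nearest-root oracle at every site
  lat32 <- rdLattice(32, 32, D = 4, alpha = 0.5, dU = 0, seed = 11)
  oracle <- pmin(pmax(round(lat32@X), 0), 3)
  expect_equal(evolveNoDiffusion(lat32, 150)@X, oracle, tolerance = 1e-9)
})

test_that("stability bounds and divergence are enforced with alpha named", {
  bad <- rdLattice(4, 4, D = 4, alpha = 0.999, dU = 0)
  bad@alpha <- 1.2
  expect_error(evolveNoDiffusion(bad, 10), "alpha")
  badD <- rdLattice(4, 4, D = 4, alpha = 0.5, dU = 0.3)
  expect_error(evolveRD(badD, 10), "dU")
  div <- rdLattice(4, 4, D = 4, alpha = 0.9, dU = 0)
  div@X[] <- 12   # far outside every basin: the cubic overshoots
  expect_error(evolveNoDiffusion(div, 50), "alpha")
})

test_that("zero diffusion reduces evolveRD to the reaction-only dynamics", {
  a <- rdLattice(16, 16, D = 4, alpha = 0.5, dU = 0, seed = 5)
  b <- rdLattice(16, 16, D = 4, alpha = 0.5, dU = 0, seed = 5)
  expect_equal(evolveRD(a, 60)@X, evolveNoDiffusion(b, 60)@X)
})

test_that("with negligible reaction and wrap boundary diffusion reaches the mean", {
  lat <- rdLattice(16, 16, D = 4, alpha = 1e-9, dU = 0.2, seed = 2,
                   boundary = "wrap")
  m <- mean(lat@X)
  ev <- evolveRD(lat, 2000)
  expect_lt(max(abs(ev@X - m)), 1e-6)
})

test_that("diffusion smooths and consolidates clusters while keeping diversity", {
  res <- t(vapply(1:5, function(s) {
    l0 <- rdLattice(64, 64, D = 4, alpha = 0.5, dU = 0, seed = s)
    lr <- rdLattice(64, 64, D = 4, alpha = 0.5, dU = 0.04, seed = s)
    s0 <- mapStats(evolveNoDiffusion(l0, 200))
    sr <- mapStats(evolveRD(lr, 200))
    c(s0@continuity, sr@continuity, sr@diversity,
      s0@clusterCount, sr@clusterCount)
  }, numeric(5)))
  expect_true(all(res[, 2] < res[, 1]))  # smoother with diffusion
  expect_true(all(res[, 3] == 1))        # all four disparities survive
  expect_true(all(res[, 5] < res[, 4]))  # fewer, larger clusters
})

test_that("cluster interiors vary by less than one disparity", {
  lat <- evolveRD(rdLattice(64, 64, D = 4, alpha = 0.5, dU = 0.04, seed = 3),
                  300)
  st <- mapStats(lat)
  X <- lat@X; lab <- st@clusterLabels
  sameH <- lab[, -1] == lab[, -ncol(lab)]
  sameV <- lab[-1, ] == lab[-nrow(lab), ]
  dh <- abs(X[, -1] - X[, -ncol(X)])[sameH]
  dv <- abs(X[-1, ] - X[-nrow(X), ])[sameV]
  expect_true(all(c(dh, dv) <= 1))
})

test_that("map statistics are exact on constant and checkerboard lattices", {
  con <- rdLattice(6, 6, D = 4, alpha = 0.5, dU = 0)
  con@X[] <- 2
  st <- mapStats(con)
  expect_equal(st@continuity, 0)
  expect_equal(st@diversity, 1 / 4)
  expect_identical(st@clusterCount, 1L)
  chk <- rdLattice(6, 6, D = 4, alpha = 0.5, dU = 0)
  chk@X <- matrix(3 * ((outer(1:6, 1:6, "+") %% 2)), 6, 6)
  stc <- mapStats(chk)
  expect_equal(stc@continuity, 3)        # D - 1 at every neighbour pair
  expect_equal(stc@diversity, 2 / 4)
  expect_identical(stc@clusterCount, 36L)
})

test_that("lattices serialize to CSV and render to PGM", {
  lat <- rdLattice(8, 8, D = 4, seed = 4)
  csv <- tempfile(fileext = ".csv")
  writeLatticeCSV(lat, csv)
  expect_equal(unname(readLatticeCSV(csv)), lat@X, tolerance = 1e-12)
  pgm <- tempfile(fileext = ".pgm")
  rounded <- latticeToPGM(lat, pgm)
  expect_true(file.exists(pgm))
  expect_true(all(rounded %in% 0:3))
})
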