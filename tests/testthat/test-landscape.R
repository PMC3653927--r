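test_that("patch labeling follows the 8-neighbour rule and the 2 m gap", {
  # touching diagonally -> one patch
  m <- willow_mask(diag(2))
  expect_equal(label_patches(m)$n_patches, 1)

  # two pixels 3 m apart with a 2 m merge gap -> two patches
  g <- matrix(0, 1, 20)
  g[1, 1] <- 1; g[1, 16] <- 1          # centres 15 px * 0.2 m = 3 m apart
  expect_equal(label_patches(willow_mask(g), merge_gap_m = 2)$n_patches, 2)

  # 1.8 m apart -> merged into one patch
  g2 <- matrix(0, 1, 20)
  g2[1, 1] <- 1; g2[1, 10] <- 1        # 9 px = 1.8 m
  expect_equal(label_patches(willow_mask(g2), merge_gap_m = 2)$n_patches, 1)

  # labels are deterministic, row-major by first pixel
  g3 <- matrix(0, 5, 5)
  g3[1, 4] <- 1; g3[4, 1] <- 1
  lab <- label_patches(willow_mask(g3, pixel_size = 10), merge_gap_m = 2)$labels
  expect_equal(lab[1, 4], 1)
  expect_equal(lab[4, 1], 2)
})

test_that("labeling matches the brute-force flood-fill + pairwise-merge oracle", {
  set.seed(42)
  for (rep in 1:25) {
    m <- random_mask(30, 30, p = runif(1, 0.05, 0.4))
    got <- label_patches(m, merge_gap_m = 2)$labels
    want <- oracle_label(m$grid, m$pixel_size, 2)
    expect_identical(got, want)
  }
})

test_that("edge length counts interior willow/non-willow interfaces", {
  # single willow pixel: 4 sides x 0.2 m
  g <- matrix(0, 5, 5); g[3, 3] <- 1
  expect_equal(edge_length(willow_mask(g)), 0.8)
  # 2 x 2 block: perimeter of 8 pixel sides
  g2 <- matrix(0, 6, 6); g2[3:4, 3:4] <- 1
  expect_equal(edge_length(willow_mask(g2)), 1.6)
  # full grid: no interior edges, border uncounted
  expect_equal(edge_length(willow_mask(matrix(1, 4, 4))), 0)

  set.seed(5)
  for (rep in 1:20) {
    m <- random_mask(20, 20, p = runif(1, 0.1, 0.9))
    expect_equal(edge_length(m), oracle_edge(m$grid, m$pixel_size))
  }
})

test_that("edge length is complementation-invariant", {
  set.seed(9)
  for (rep in 1:10) {
    m <- random_mask(25, 25, 0.3)
    inv <- willow_mask(1 - m$grid, m$pixel_size)
    expect_equal(edge_length(m), edge_length(inv))
  }
})

test_that("quadrat extraction windows and bounds", {
  # 2000 x 2000 grid at 0.2 m, centre in the middle -> 1000 x 1000 window
  big <- willow_mask(matrix(0L, 2000, 2000), pixel_size = 0.2)
  q <- quadrat(centre = c(200, 200), side = 200)
  sub <- extract_quadrat(big, q)
  expect_equal(dim(sub$grid), c(1000, 1000))
  expect_lt(attr(sub, "snap_m"), 0.2)

  # centre at the raster corner -> out of bounds, with overlap reported
  expect_error(extract_quadrat(big, quadrat(c(0, 0), 200)),
               "out of bounds.*overlap")

  # side 2 m at 1 m pixels -> 2 x 2 window
  small <- willow_mask(matrix(1:0, 4, 4), pixel_size = 1)
  sub2 <- extract_quadrat(small, quadrat(c(2, 2), 2))
  expect_equal(dim(sub2$grid), c(2, 2))
})

test_that("metrics invariants: degenerate quadrats, translation, monotonicity", {
  full <- thicket_metrics(willow_mask(matrix(1, 100, 100)))
  expect_equal(full$area_pct, 100)
  expect_equal(full$patch_density, 1)
  expect_equal(full$edge_density, 0)

  empty <- thicket_metrics(willow_mask(matrix(0, 100, 100)))
  expect_equal(unlist(empty), c(area_pct = 0, patch_density = 0,
                                edge_density = 0))

  # translation invariance: shift mask and quadrat centre together
  set.seed(21)
  g <- matrix(rbinom(2500, 1, 0.25), 50, 50)
  big <- matrix(0, 120, 120)
  big[31:80, 31:80] <- g
  m <- willow_mask(big, pixel_size = 0.2)
  q1 <- quadrat(c(0.2 * 54.5, 0.2 * 54.5), side = 10)  # pixel-centre (55, 55)
  big2 <- matrix(0, 120, 120)
  big2[41:90, 46:95] <- g
  m2 <- willow_mask(big2, pixel_size = 0.2)
  q2 <- quadrat(c(0.2 * 69.5, 0.2 * 64.5), side = 10)  # shifted +15 col, +10 row
  expect_equal(thicket_metrics(m, q1), thicket_metrics(m2, q2))

  # adding willow pixels never decreases area_pct
  m3 <- m
  zero <- which(m3$grid == 0)
  m3$grid[sample(zero, 50)] <- 1L
  expect_gt(thicket_metrics(m3, q1)$area_pct + 1e-12,
            thicket_metrics(m, q1)$area_pct)
})

test_that("disk raster metrics equal exhaustive pixel enumeration", {
  # synthetic disk: enumerate pixels explicitly
  n <- 101; px <- 0.2
  centre <- (n + 1) / 2
  g <- matrix(0L, n, n)
  for (r in 1:n) for (cc in 1:n)
    if ((r - centre)^2 + (cc - centre)^2 <= 20^2) g[r, cc] <- 1L
  m <- willow_mask(g, pixel_size = px)
  got <- thicket_metrics(m)
  expect_equal(got$area_pct, 100 * sum(g) / n^2)
  expect_equal(got$patch_density, 1)
  expect_equal(got$edge_density, oracle_edge(g, px))
})

test_that("text-grid masks round-trip", {
  set.seed(13)
  m <- random_mask(15, 23, 0.3, pixel_size = 0.25)
  tmp <- tempfile(fileext = ".txt")
  write_mask_text(m, tmp)
  m2 <- read_mask_text(tmp)
  expect_identical(m2$grid, m$grid)
  expect_equal(m2$pixel_size, m$pixel_size)
})
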