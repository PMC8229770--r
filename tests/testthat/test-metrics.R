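test_that("dsc counts voxels and honours the empty-mask conventions", {
  m1 <- array(0, c(3, 4, 4)); m1[2, 2, 2] <- 1; m1[2, 2, 3] <- 1
  m2 <- array(0, c(3, 4, 4)); m2[2, 2, 2] <- 1; m2[2, 3, 3] <- 1
  a <- binary_mask(m1); b <- binary_mask(m2)
  expect_equal(dsc(a, b), 0.5)                       # 2*1 / (2+2)
  expect_equal(dsc(a, b), dsc(b, a))
  expect_equal(dsc(a, a), 1)
  z <- binary_mask(array(0, c(3, 4, 4)))
  expect_equal(dsc(a, z), 0)
  expect_equal(dsc(z, z), 1)
  bad <- binary_mask(array(0, c(3, 4, 5)))
  expect_error(dsc(a, bad), "grid mismatch")
})

test_that("boundary extraction returns voxel-centred mm coordinates", {
  m <- array(0, c(4, 4, 4)); m[2, 2, 2] <- 1
  sp <- extract_boundary(binary_mask(m))
  expect_equal(nrow(sp$points), 1)
  expect_equal(unname(sp$points[1, ]), c(1, 1, 1))

  ## solid 3x3x3 cube: all but the centre voxel are boundary
  cube <- array(0, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1
  expect_equal(nrow(extract_boundary(binary_mask(cube))$points), 26)

  ## anisotropic spacing scales coordinates: R index 4 = 0-based 3 -> 6 mm
  m2 <- array(0, c(6, 4, 4)); m2[4, 1, 1] <- 1
  p <- extract_boundary(binary_mask(m2, spacing = c(2, 1, 1)))$points
  expect_equal(unname(p[1, ]), c(6, 0, 0))

  expect_error(extract_boundary(binary_mask(array(0, c(2, 2, 2)))), "empty mask")
})

test_that("directed and symmetric surface distances match hand-computed values", {
  A <- surface_points(rbind(c(0, 0, 0)))
  B <- surface_points(rbind(c(3, 4, 0)))
  expect_equal(directed_avg_distance(A, B), 5)

  A2 <- surface_points(rbind(c(0, 0, 0), c(10, 0, 0)))
  B2 <- surface_points(rbind(c(0, 0, 0)))
  expect_equal(directed_avg_distance(A2, B2), 5)     # (0 + 10) / 2
  expect_equal(directed_avg_distance(B2, A2), 0)
  expect_equal(asd(A2, B2), 2.5)
  expect_equal(asd(B2, A2), 2.5)                     # symmetric
  expect_equal(hd(A2, B2), 10)
  expect_equal(hd(B2, A2), 10)
  expect_equal(asd(A2, A2), 0)
  expect_equal(hd(A2, A2), 0)
  expect_equal(hd95(A2, A2), 0)
  expect_error(directed_avg_distance(A, surface_points(matrix(0, 0, 3))), "empty")
})

test_that("hd95 takes the 95th percentile of directed nearest distances", {
  ## 96 points at distance 1 from the origin, 4 at distance 10
  set.seed(1)
  dirs <- matrix(rnorm(300), 100, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  A <- surface_points(dirs * c(rep(1, 96), rep(10, 4)))
  B <- surface_points(rbind(c(0, 0, 0)))
  ## directed 95th percentile sits inside the 96 unit distances
  expect_equal(hd95(A, B), 1)
  expect_lte(hd95(A, B), hd(A, B))
})

test_that("metrics agree with a naive all-pairs oracle on random anisotropic pairs", {
  for (sd in 1:25) {
    pr <- random_mask_pair(sd)
    pa <- extract_boundary(pr$a); pb <- extract_boundary(pr$b)
    A <- pa$points; B <- pb$points
    expect_equal(asd(pa, pb), oracle_asd(A, B), tolerance = 1e-9)
    expect_equal(hd(pa, pb), oracle_hd(A, B), tolerance = 1e-9)
    expect_equal(hd95(pa, pb), oracle_hd95(A, B), tolerance = 1e-9)
    ## ordering and symmetry
    expect_lte(asd(pa, pb), hd(pa, pb))
    expect_lte(hd95(pa, pb), hd(pa, pb))
    expect_equal(asd(pa, pb), asd(pb, pa))
    expect_equal(hd(pa, pb), hd(pb, pa))
    expect_equal(hd95(pa, pb), hd95(pb, pa))
  }
})

test_that("boundary definition matches the enumeration oracle", {
  for (sd in c(3, 14)) {
    pr <- random_mask_pair(sd, dim3 = c(8, 8, 8))
    got <- extract_boundary(pr$a)$points
    want <- oracle_boundary(pr$a$labels, pr$a$spacing)
    expect_equal(nrow(got), nrow(want))
    ord <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
    expect_equal(unname(ord(got)), unname(ord(want)), tolerance = 1e-12)
  }
})

test_that("distances scale linearly with spacing while dsc is unchanged", {
  pr <- random_mask_pair(8)
  s <- 3.7
  a2 <- binary_mask(pr$a$labels, spacing = pr$a$spacing * s)
  b2 <- binary_mask(pr$b$labels, spacing = pr$b$spacing * s)
  expect_equal(dsc(a2, b2), dsc(pr$a, pr$b))
  expect_equal(asd(extract_boundary(a2), extract_boundary(b2)),
               s * asd(extract_boundary(pr$a), extract_boundary(pr$b)), tolerance = 1e-9)
  expect_equal(hd(extract_boundary(a2), extract_boundary(b2)),
               s * hd(extract_boundary(pr$a), extract_boundary(pr$b)), tolerance = 1e-9)
  expect_equal(hd95(extract_boundary(a2), extract_boundary(b2)),
               s * hd95(extract_boundary(pr$a), extract_boundary(pr$b)), tolerance = 1e-9)
})

test_that("evaluate_pair assembles the full report and flags empty predictions", {
  ph <- generate_phantom(phantom_spec(shape = c(8, 32, 32), spacing = c(1.5, 0.8, 0.8),
                                      arch_radius_mm = 8, limb_thickness_mm = 4,
                                      artifact_fraction = 0, noise_sigma = 0, seed = 2))
  r <- evaluate_pair(ph$mask, ph$mask)
  expect_equal(r$dsc, 1)
  expect_equal(r$asd_mm, 0)
  expect_equal(r$hd95_mm, 0)
  expect_equal(r$hd_mm, 0)

  empty <- binary_mask(array(0, dim(ph$mask$labels)), spacing = ph$mask$spacing)
  re <- evaluate_pair(empty, ph$mask)
  expect_equal(re$dsc, 0)
  expect_false(re$distances_defined)
  expect_true(is.na(re$asd_mm) && is.na(re$hd95_mm) && is.na(re$hd_mm))

  ## against a 1-voxel 6-neighbour dilation, verified by the oracle
  lab <- ph$mask$labels
  dil <- lab
  d <- dim(lab)
  dil[c(2:d[1]), , ] <- pmax(dil[2:d[1], , ], lab[1:(d[1] - 1), , ])
  dil[1:(d[1] - 1), , ] <- pmax(dil[1:(d[1] - 1), , ], lab[2:d[1], , ])
  dil[, 2:d[2], ] <- pmax(dil[, 2:d[2], ], lab[, 1:(d[2] - 1), ])
  dil[, 1:(d[2] - 1), ] <- pmax(dil[, 1:(d[2] - 1), ], lab[, 2:d[2], ])
  dil[, , 2:d[3]] <- pmax(dil[, , 2:d[3]], lab[, , 1:(d[3] - 1)])
  dil[, , 1:(d[3] - 1)] <- pmax(dil[, , 1:(d[3] - 1)], lab[, , 2:d[3]])
  pred <- binary_mask(dil, spacing = ph$mask$spacing)
  rr <- evaluate_pair(pred, ph$mask)
  A <- extract_boundary(pred)$points; B <- extract_boundary(ph$mask)$points
  expect_equal(rr$dsc, 2 * sum(dil * lab) / (sum(dil) + sum(lab)))
  expect_equal(rr$asd_mm, oracle_asd(A, B), tolerance = 1e-9)
  expect_equal(rr$hd_mm, oracle_hd(A, B), tolerance = 1e-9)
  expect_equal(rr$hd95_mm, oracle_hd95(A, B), tolerance = 1e-9)
})
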