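test_that("phantom generation is bit-reproducible and respects the artifact budget", {
  spec <- phantom_spec(artifact_fraction = 0.25, seed = 33)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$mask$labels, b$mask$labels)
  expect_identical(a$corrupted_slices, b$corrupted_slices)

  ## ceiling(0.25 * 16) = 4 corrupted slices, all valid indices
  expect_length(a$corrupted_slices, 4)
  expect_true(all(a$corrupted_slices %in% seq_len(16)))

  ## anatomical connectivity: adjacent mask slices always overlap
  for (t in 1:15) {
    inter <- sum(a$mask$labels[t, , ] * a$mask$labels[t + 1, , ])
    expect_gt(2 * inter / (sum(a$mask$labels[t, , ]) + sum(a$mask$labels[t + 1, , ])), 0)
  }
})

test_that("noiseless artifact-free phantoms are recovered exactly by midpoint thresholding", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0, artifact_fraction = 0, seed = 5))
  expect_identical(ph$corrupted_slices, integer(0))
  rec <- array(as.numeric(ph$volume$intensities > 0.5), dim(ph$volume$intensities))
  expect_identical(rec, ph$mask$labels)
})

test_that("streak corruption changes intensities but never the ground-truth mask", {
  base <- generate_phantom(phantom_spec(artifact_fraction = 0, noise_sigma = 0, seed = 9))
  corr <- generate_phantom(phantom_spec(artifact_fraction = 0.5, noise_sigma = 0, seed = 9))
  expect_identical(base$mask$labels, corr$mask$labels)
  expect_false(identical(base$volume$intensities, corr$volume$intensities))
  ## corruption is confined to the reported slices
  clean <- setdiff(seq_len(16), corr$corrupted_slices)
  expect_identical(base$volume$intensities[clean, , ],
                   corr$volume$intensities[clean, , ])
})

test_that("the ground-truth mask is a single 26-connected component", {
  for (sd in c(1, 2)) {
    ph <- generate_phantom(phantom_spec(seed = sd))
    expect_equal(oracle_n_components(ph$mask$labels), 1L)
  }
  ## taller stack with protrusions still connected
  tall <- generate_phantom(phantom_spec(shape = c(24, 64, 64), seed = 3))
  expect_equal(oracle_n_components(tall$mask$labels), 1L)
  ## and without protrusions
  nop <- generate_phantom(phantom_spec(protrusion_count = 0, seed = 4))
  expect_equal(oracle_n_components(nop$mask$labels), 1L)
})

test_that("increasing noise degrades a fixed-threshold segmenter on average", {
  sigmas <- c(0.05, 0.15, 0.3, 0.6)
  mean_dsc <- vapply(sigmas, function(sg) {
    mean(vapply(1:10, function(sd) {
      ph <- generate_phantom(phantom_spec(shape = c(12, 32, 32), spacing = c(1, 1, 1),
                                          arch_radius_mm = 9, limb_thickness_mm = 5,
                                          noise_sigma = sg, artifact_fraction = 0,
                                          seed = sd))
      seg <- binary_mask(array(as.numeric(ph$volume$intensities > 0.5),
                               dim(ph$volume$intensities)))
      dsc(seg, ph$mask)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dsc) < 0))
})

test_that("phantom geometry errors and dataset jitter behave as specified", {
  expect_error(generate_phantom(phantom_spec(shape = c(8, 24, 24), arch_radius_mm = 20)),
               "geometry error")
  expect_error(generate_dataset(0, phantom_spec()), "argument error|n must be")

  ds <- generate_dataset(5, small_phantom_spec(), seed = 77)
  ds2 <- generate_dataset(5, small_phantom_spec(), seed = 77)
  expect_identical(lapply(ds, function(cs) cs$volume$intensities),
                   lapply(ds2, function(cs) cs$volume$intensities))
  ## varied sequence lengths
  n_slices <- vapply(ds, function(cs) dim(cs$volume$intensities)[1], numeric(1))
  expect_gt(length(unique(n_slices)), 1)
  ## no two cases identical
  for (i in 1:4) for (j in (i + 1):5) {
    a <- ds[[i]]$mask$labels; b <- ds[[j]]$mask$labels
    expect_false(identical(dim(a), dim(b)) && identical(a, b))
  }
})
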