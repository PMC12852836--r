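vesselImage <- function(seed, extent = c(0.96, 0.96, 0.15), vox = 5) {
  spec <- PhantomSpec(extentMm = extent, voxelUm = vox, nVessels = 10,
                      radiusRangeUm = c(30, 60), seed = seed)
  ph <- generateVesselPhantom(spec)
  projectMip(ph@cHbO2 + ph@cHbR)
}

test_that("facet splitting partitions and recombines losslessly", {
  img <- vesselImage(31)
  facetOf <- rep(0:5, length.out = nrow(img))
  stacks <- splitByFacet(img, facetOf)
  expect_length(stacks, 6L)
  expect_equal(sum(vapply(stacks, nrow, integer(1))), nrow(img))
  expect_equal(interleaveFacets(stacks, nRow = nrow(img)), img)
  ## single-facet data: identity behavior
  one <- splitByFacet(img, rep(0L, nrow(img)))
  expect_length(one, 1L)
  expect_equal(one[[1]], img, ignore_attr = TRUE)
  expect_error(splitByFacet(img, NULL), "provenance")
})

test_that("facet transforms are recovered from injected misalignment", {
  img <- vesselImage(32, extent = c(0.96, 1.44, 0.15))
  facetOf <- rep(0:5, length.out = nrow(img))
  stacks <- splitByFacet(img, facetOf)
  ## zero misalignment on identical stacks: identity within 0.1 px
  ident <- lapply(1:6, function(f) stacks[[1]])
  tr00 <- estimateFacetTransforms(ident, referenceFacet = 1L)
  expect_lt(max(abs(tr00@shifts)), 0.1)
  ## zero misalignment on real interleaved stacks: identity within the
  ## half-pixel alignment budget (facets sample different slow-axis rows)
  tr0 <- estimateFacetTransforms(stacks, referenceFacet = 1L)
  expect_lt(max(abs(tr0@shifts)), 0.5)

  ## the worked offset pattern, in pixels, with 20-dB noise
  offs <- c(0, 6, -4, 2, -2, 4)
  shifted <- lapply(1:6, function(f) {
    m <- dcpam:::translateImage(stacks[[f]], 0, offs[f])
    m <- addNoise(m, 20, seed = 40 + f)
    attr(m, "rows") <- attr(stacks[[f]], "rows")
    m
  })
  tr <- estimateFacetTransforms(shifted, referenceFacet = 1L)
  expect_true(all(abs(tr@shifts[, "fast"] - offs) <= 0.5))

  ## two facets, one a (3, 0)-px shifted copy of the other
  a <- img[1:48, ]
  b <- dcpam:::translateImage(a, 0, 3)
  pair <- list(a, b)
  trp <- estimateFacetTransforms(pair, referenceFacet = 1L)
  expect_lt(abs(trp@shifts[2, "fast"] - 3), 0.25)
  expect_lt(abs(trp@shifts[2, "slow"]), 0.25)

  expect_error(estimateFacetTransforms(list(matrix(1, 8, 8),
                                            matrix(1, 8, 8))),
               "insufficient structure")
})

test_that("applying transforms aligns and merges the facets", {
  img <- vesselImage(33)
  facetOf <- rep(0:5, length.out = nrow(img))
  stacks <- splitByFacet(img, facetOf)
  idTr <- new("FacetTransform", shifts = matrix(0, 6, 2,
                dimnames = list(NULL, c("fast", "slow"))),
              gains = rep(1, 6), referenceFacet = 1L)
  expect_equal(applyFacetTransforms(stacks, idTr, nRow = nrow(img)), img)

  ## inverse-apply restores the unperturbed image (SSIM >= 0.98)
  offs <- c(0, 7.5, -5, 2.5, -9, 4)
  shifted <- lapply(1:6, function(f) {
    m <- dcpam:::translateImage(stacks[[f]], 0, offs[f])
    attr(m, "rows") <- attr(stacks[[f]], "rows")
    m
  })
  tr <- estimateFacetTransforms(shifted, referenceFacet = 1L)
  merged <- applyFacetTransforms(shifted, tr, nRow = nrow(img))
  interior <- 12:(ncol(img) - 12)     # ignore translation zero-padding
  expect_gte(ssim(merged[, interior], img[, interior]), 0.98)
  ## alignment must not reduce the mean pairwise facet correlation
  pairCor <- function(m) {
    s <- splitByFacet(m, facetOf)
    n <- min(vapply(s, nrow, integer(1)))
    cc <- utils::combn(6, 2, function(ij)
      stats::cor(as.vector(s[[ij[1]]][1:n, ]),
                 as.vector(s[[ij[2]]][1:n, ])))
    mean(cc)
  }
  expect_gte(pairCor(merged), pairCor(interleaveFacets(shifted,
                                                       nRow = nrow(img))))
  ## all-zero stacks map to an all-zero merge
  zero <- lapply(stacks, function(m) {
    z <- m * 0; attr(z, "rows") <- attr(m, "rows"); z
  })
  expect_true(all(applyFacetTransforms(zero, idTr, nRow = nrow(img)) == 0))
})

test_that("frame stabilization inverts synthetic translations", {
  img <- vesselImage(34)[1:72, 1:72]
  expect_equal(stabilizeFrames(list(img))$shifts, matrix(0, 1, 2),
               ignore_attr = TRUE)
  same <- stabilizeFrames(list(img, img, img))
  expect_true(all(abs(same$shifts) < 1e-6))

  shifts <- rbind(c(0, 0), c(3, -5), c(-6, 2), c(9, 7))
  frames <- lapply(seq_len(nrow(shifts)), function(k)
    dcpam:::translateImage(img, shifts[k, 1], shifts[k, 2]))
  st <- stabilizeFrames(frames, maxShift = 12)
  expect_true(all(abs(st$shifts - shifts) <= 0.5))
  expect_false(any(st$lowConfidence))

  noise <- lapply(1:3, function(k)
    withr_seed(50 + k, matrix(rnorm(72 * 72), 72, 72)))
  stN <- stabilizeFrames(noise)
  expect_true(all(stN$lowConfidence[-1]))
})

test_that("spline upsampling preserves samples and linear structure", {
  img <- vesselImage(35)[1:40, 1:40]
  expect_identical(upsampleImage(img, 1), img)
  up <- upsampleImage(matrix(7, 5, 5), 4)
  expect_true(all(abs(up - 7) < 1e-12))
  ramp <- outer(seq_len(20), seq_len(15), function(i, j) 2 * i + 3 * j)
  upr <- upsampleImage(ramp, 2)
  want <- outer(seq(1, 20, by = 0.5), seq(1, 15, by = 0.5),
                function(i, j) 2 * i + 3 * j)
  expect_equal(upr, want, tolerance = 1e-9)
  ## original sites preserved
  up2 <- upsampleImage(img, 3)
  expect_equal(up2[seq(1, nrow(up2), by = 3), seq(1, ncol(up2), by = 3)],
               img, tolerance = 1e-9)
  expect_error(upsampleImage(img, 0.5), ">= 1")
})

test_that("spectral unmixing solves the two-wavelength system", {
  tab <- defaultExtinctionTable()
  E <- log(10) * dcpam:::extinctionMatrix2(tab)
  amp <- matrix(runif(64, 0.5, 2), 8, 8)
  ## amplitudes proportional to the HbO2 column: sO2 = 1
  pure1 <- unmixSO2(amp * E[1, 1], amp * E[2, 1], tab, maskThresholdFactor = 0)
  expect_true(all(validMask(pure1)))
  expect_equal(unname(so2Values(pure1)), matrix(1, 8, 8), tolerance = 1e-9)
  ## HbR column: sO2 = 0
  pure0 <- unmixSO2(amp * E[1, 2], amp * E[2, 2], tab, maskThresholdFactor = 0)
  expect_equal(unname(so2Values(pure0)), matrix(0, 8, 8), tolerance = 1e-9)
  ## a known mixture round-trips through the forward 2x2 system
  cTrue <- c(0.75, 0.25) * 2.3e-3
  a <- as.vector(E %*% cTrue)
  mixed <- unmixSO2(matrix(a[1], 4, 4), matrix(a[2], 4, 4), tab, maskThresholdFactor = 0)
  expect_equal(unname(so2Values(mixed)), matrix(0.75, 4, 4),
               tolerance = 1e-9)
  ## zero-amplitude pixels are excluded from the mask
  az <- matrix(c(0, 1, 1, 1), 2, 2)
  m <- unmixSO2(az * E[1, 1], az * E[2, 1], tab, maskThresholdFactor = 0)
  expect_false(validMask(m)[1, 1])
  expect_true(is.na(so2Values(m)[1, 1]))
  expect_error(unmixSO2(matrix(1, 2, 2), matrix(1, 3, 3), tab),
               "identical shape")
})

test_that("region metrics summarize masked means per frame", {
  img <- matrix(4.2, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:6, 2:8] <- TRUE
  expect_equal(regionMetric(img, mask), 4.2)
  one <- matrix(FALSE, 10, 10); one[4, 5] <- TRUE
  img2 <- img; img2[4, 5] <- 9.9
  expect_equal(regionMetric(img2, one), 9.9)
  frames <- list(img, img * 1.6)
  series <- regionMetric(frames, mask)
  expect_equal(series[2] / series[1], 1.6, tolerance = 1e-12)
  expect_error(regionMetric(img, matrix(FALSE, 10, 10)), "empty")
})
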