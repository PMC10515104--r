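gridImage <- function(m, domain = "mz")
  new("IntensityImage", values = m, label = "", center = NA_real_,
      halfWidth = NA_real_, domain = domain)

test_that("ion image extraction: TIC window, point extraction, domain guard", {
  ds <- smallDataset(width = 3, height = 2, nPoints = 400)
  # a window covering the whole axis gives per-pixel total ion current
  ax <- axisValues(spectra(ds)[[1]])
  full <- ionImage(ds, mean(range(ax)), diff(range(ax)))
  expect_equal(imageValues(full), imageValues(totalIonImage(ds)))
  # tol = 0 extracts the nearest axis point
  pt <- ionImage(ds, ax[37] + 0.2 * (ax[2] - ax[1]), 0)
  cc <- pixelCoords(ds)
  for (i in seq_len(pixelCount(ds)))
    expect_equal(imageValues(pt)[cc$y[i], cc$x[i]],
                 intensityValues(spectra(ds)[[i]])[37])
  # mass-domain input is refused
  fx <- ckbFixture()
  expect_error(ionImage(fx$res$dataset, 5000, 10),
               class = "msi_contract_error")
  expect_error(massImage(ds, 85170, 10), class = "msi_contract_error")
})

test_that("ion images are additive over grid-aligned window splits", {
  ds <- smallDataset(width = 2, height = 2, nPoints = 500)
  ax <- axisValues(spectra(ds)[[1]])
  step <- ax[2] - ax[1]
  # [a, b] and (b, c] partition the axis points when the split falls
  # between grid points
  a <- ax[100]; b <- ax[250] + step / 2; c <- ax[400]
  whole <- ionImage(ds, (a + c) / 2, (c - a) / 2)
  left <- ionImage(ds, (a + b) / 2, (b - a) / 2)
  right <- ionImage(ds, (b + c) / 2, (c - b) / 2)
  expect_equal(imageValues(whole),
               imageValues(left) + imageValues(right), tolerance = 1e-12)
})

test_that("mass image of a species follows its generated pattern", {
  fx <- ckbFixture()
  # the canonical homodimer window: 85,170 +/- 10 Da
  img <- massImage(fx$res$dataset, 85170, 10)
  truthMap <- fx$sim$truth[[1]]$abundance
  expect_true(all(imageValues(img)[truthMap > 0] > 0))
  expect_gte(cosineSimilarity(imageValues(img), truthMap), 99)
  # a window in an empty mass region is all zero
  empty <- massImage(fx$res$dataset, 89000, 10)
  expect_true(all(imageValues(empty) == 0))
})

test_that("composite ion images sum charge states", {
  fx <- ckbFixture()
  dsMz <- fx$sim$dataset
  imgs <- lapply(13:16, function(z) ionImage(dsMz, mzForCharge(85170, z), 3))
  comp <- compositeIonImage(imgs)
  # identity on one image
  expect_equal(imageValues(compositeIonImage(imgs[1])),
               imageValues(imgs[[1]]))
  # permutation-invariant and associative
  expect_equal(imageValues(compositeIonImage(imgs[c(3, 1, 4, 2)])),
               imageValues(comp))
  expect_equal(imageValues(compositeIonImage(list(comp))),
               imageValues(compositeIonImage(imgs)))
  # mirrors the composite-vs-mass-image comparison: >= 95% similar
  mImg <- massImage(fx$res$dataset, 85170, 10)
  expect_gte(cosineSimilarity(comp, mImg), 95)
  # dimension mismatch is refused
  expect_error(compositeIonImage(list(comp, gridImage(matrix(1, 2, 2)))),
               class = "msi_contract_error")
})

test_that("cosine similarity: identity, orthogonality, worked vector case", {
  A <- gridImage(matrix(c(1, 2, 2, 3), 2))
  expect_equal(cosineSimilarity(A, A), 100)
  # disjoint support scores zero
  B1 <- gridImage(matrix(c(1, 1, 0, 0), 2))
  B2 <- gridImage(matrix(c(0, 0, 2, 5), 2))
  expect_equal(cosineSimilarity(B1, B2), 0)
  # hand-computed: dot 8 over norms 3 * 3
  expect_equal(cosineSimilarity(c(1, 2, 2), c(2, 1, 2)), 800 / 9,
               tolerance = 1e-12)
  expect_equal(round(cosineSimilarity(c(1, 2, 2), c(2, 1, 2)), 2), 88.89)
  # symmetric, scale-invariant, bounded
  expect_equal(cosineSimilarity(B2, B1), cosineSimilarity(B1, B2))
  for (c0 in c(0.2, 7)) {
    sA <- gridImage(c0 * imageValues(A))
    expect_equal(cosineSimilarity(sA, B2), cosineSimilarity(A, B2))
  }
  expect_error(cosineSimilarity(A, gridImage(matrix(0, 2, 2))),
               class = "msi_contract_error")
  expect_error(cosineSimilarity(c(1, 2), c(1, 2, 3)),
               class = "msi_contract_error")
})

test_that("identical low-signal padding inflates similarity toward 100%", {
  # the empty-slide caveat: pixels that are low and identical everywhere
  # raise the score of genuinely dissimilar images
  a <- c(rep(1, 8), rep(0, 8))
  b <- c(rep(0, 8), rep(1, 8))
  sims <- vapply(c(0, 8, 64, 512, 2048), function(k) {
    pad <- rep(0.3, k)
    cosineSimilarity(c(a, pad), c(b, pad))
  }, numeric(1))
  expect_equal(sims[1], 0)
  expect_true(all(diff(sims) > 0))
  expect_gt(sims[length(sims)], 90)
})

test_that("charge-series report validates channels and flags confounders", {
  fx <- twoSpeciesFixture()
  rep <- chargeSeriesReport(fx$massA, fx$sim$dataset, fx$res$dataset,
                            charges = c(13:16, 18L), tolMz = 3, tolMass = 40)
  own <- rep[rep$z %in% 13:16, ]
  expect_true(all(own$similarity >= 95))
  expect_true(!any(own$flagged))
  # the 18+ channel is really the confounder's 15+ peak: different pattern
  conf <- rep[rep$z == 18L, ]
  expect_lt(conf$similarity, 80)
  expect_true(conf$flagged)
  expect_true(is.finite(attr(rep, "empty_pixel_fraction")))
  # single charge, tol 0: one-row table
  one <- chargeSeriesReport(fx$massA, fx$sim$dataset, fx$res$dataset,
                            charges = 14L, tolMz = 0, tolMass = 40)
  expect_equal(nrow(one), 1)
  expect_error(chargeSeriesReport(fx$massA, fx$sim$dataset, fx$res$dataset,
                                  charges = integer(0)),
               class = "msi_contract_error")
})

test_that("similarity reports round-trip through the TSV writer", {
  fx <- twoSpeciesFixture()
  rep <- chargeSeriesReport(fx$massA, fx$sim$dataset, fx$res$dataset,
                            charges = 13:16, tolMz = 3, tolMass = 40)
  path <- file.path(withr::local_tempdir(), "report.tsv")
  writeSimilarityReport(rep, path)
  lines <- readLines(path)
  expect_match(lines[1], "cutoff_percent")
  expect_match(lines[2], "near_empty_pixel_fraction")
  tab <- utils::read.delim(path, skip = 2)
  expect_equal(tab$z, rep$z)
  expect_equal(tab$similarity, rep$similarity, tolerance = 1e-4)
})

test_that("rendering writes a PNG and a faithful numeric side-car", {
  vals <- matrix(seq(0, 30, length.out = 12), 3, 4)
  img <- gridImage(vals, domain = "mass")
  path <- file.path(withr::local_tempdir(), "img.png")
  out <- renderImage(img, path)
  expect_true(file.exists(out$png))
  expect_true(file.exists(out$sidecar))
  back <- as.matrix(utils::read.table(out$sidecar, sep = "\t"))
  dimnames(back) <- NULL
  expect_equal(back, vals)
  # gradient renders monotone: the PNG rows follow the value gradient
  px <- png::readPNG(out$png)
  expect_equal(dim(px)[1:2], dim(vals))
  # an all-zero image renders uniformly
  out0 <- renderImage(gridImage(matrix(0, 2, 2)),
                      file.path(withr::local_tempdir(), "z.png"))
  px0 <- png::readPNG(out0$png)
  expect_equal(length(unique(as.vector(px0[, , 1]))), 1)
})
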