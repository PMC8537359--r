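test_that("channel split is lossless and merge inverts it", {
  sc <- small_scene(3, shape = c(96, 96), seed = 2)
  ch <- split_channels(sc$img)
  expect_identical(ch$cqd, sc$img$channels$cqd)
  expect_identical(ch$nuclear, sc$img$channels$nuclear)
  back <- merge_channels(ch, bit_depth = sc$img$bit_depth)
  expect_identical(back$channels, sc$img$channels)
  only_cqd <- multichannel_image(list(cqd = ch$cqd), 16)
  expect_error(split_channels(only_cqd), "nuclear")
})

test_that("grayscale conversion is the identity on a single channel", {
  m <- matrix(sample(0:255, 64), 8, 8)
  expect_identical(to_grayscale(m), m)
  sc <- small_scene(2, shape = c(96, 96), seed = 3)
  expect_error(to_grayscale(sc$img), "single channel")
})

test_that("fixed thresholding is exact and constant images reject Otsu", {
  m <- matrix(c(0, 100, 0, 100, 100, 0), 2, 3)
  r <- threshold_mask(m, "fixed", fixed_value = 50)
  expect_identical(r$mask, m == 100)
  expect_equal(r$threshold, 50)
  expect_error(threshold_mask(matrix(0, 4, 4), "otsu"), "fixed")
  expect_error(threshold_mask(m, "fixed"), "fixed_value")
})

test_that("Otsu equals the exhaustive between-class-variance maximiser", {
  for (s in 1:20) {
    set.seed(s)
    # dense 8-bit histogram (every level populated in expectation) so the
    # variance maximiser is unique, not a plateau across empty bins
    v <- sample(0:255, 4000, replace = TRUE, prob = runif(256) + 0.05)
    gray <- matrix(v, 50, 80)
    r <- threshold_mask(gray, "otsu", bit_depth = 8)
    expect_equal(r$threshold, oracle_otsu(gray, 256))
    expect_identical(r$mask, gray > oracle_otsu(gray, 256))
  }
})

test_that("nuclei seeds label blobs, drop specks and locate centroids", {
  m <- matrix(0, 40, 40)
  m[5:12, 5:12] <- 200    # 64 px
  m[25:30, 25:30] <- 220  # 36 px
  m[35, 35] <- 210        # 1 px speck
  r <- nuclei_seeds(m, "fixed", fixed_value = 100, min_nucleus_area = 10)
  expect_equal(nrow(r$centroids), 2)
  expect_setequal(unique(r$labels[r$labels > 0]), 1:2)
  expect_equal(sort(r$centroids$area), c(36, 64))

  r2 <- nuclei_seeds(m, "fixed", fixed_value = 100, min_nucleus_area = 50)
  expect_equal(nrow(r2$centroids), 1)
  expect_warning(nuclei_seeds(matrix(0, 8, 8), "fixed", fixed_value = 10),
                 "no nuclei")
})

test_that("nuclei found on clean renders match ground truth one-to-one", {
  sc <- small_scene(9, shape = c(300, 300), seed = 8, gaussian_sd = 0)
  nuc <- nuclei_seeds(sc$img$channels$nuclear, "otsu", bit_depth = 16)
  expect_equal(nrow(nuc$centroids), 9)
  for (i in seq_len(9)) {
    d <- sqrt((sc$field$truth$center_row - nuc$centroids$row[i])^2 +
                (sc$field$truth$center_col - nuc$centroids$col[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("one seed claims its whole connected foreground", {
  fg <- matrix(TRUE, 20, 20)
  seeds <- matrix(0L, 20, 20); seeds[10, 10] <- 1L
  lab <- seeded_segmentation(fg, seeds)
  expect_true(all(lab == 1))
})

test_that("seeded growth equals the brute-force nearest-seed partition", {
  for (s in 1:15) {
    fx <- random_seg_fixture(s)
    got <- suppressWarnings(seeded_segmentation(fx$foreground, fx$seeds))
    want <- oracle_nearest_seed(fx$seeds, fx$foreground)
    expect_identical(got, want)
  }
})

test_that("equidistant pixels break ties toward the smaller label", {
  fg <- matrix(TRUE, 5, 9)
  seeds <- matrix(0L, 5, 9)
  seeds[3, 2] <- 2L
  seeds[3, 8] <- 1L
  lab <- seeded_segmentation(fg, seeds)
  # the middle column is equidistant from both seeds: label 1 wins
  expect_true(all(lab[, 5] == 1L))
  expect_true(all(lab[, 1:4] == 2L))
  expect_true(all(lab[, 6:9] == 1L))
})

test_that("unseeded foreground stays background; stranded seeds keep their pixels", {
  fg <- matrix(FALSE, 10, 10)
  fg[2:4, 2:4] <- TRUE    # component with a seed
  fg[7:9, 7:9] <- TRUE    # component without a seed
  seeds <- matrix(0L, 10, 10); seeds[3, 3] <- 1L
  lab <- seeded_segmentation(fg, seeds)
  expect_true(all(lab[7:9, 7:9] == 0))
  expect_true(all(lab[2:4, 2:4] == 1))

  seeds2 <- matrix(0L, 10, 10); seeds2[6, 1] <- 4L   # outside all foreground
  expect_warning(lab2 <- seeded_segmentation(fg, seeds2), "outside")
  expect_equal(sum(lab2 == 4), 1)
  expect_equal(lab2[6, 1], 4L)
})

test_that("adding a seed never steals pixels closer to existing seeds", {
  for (s in 31:38) {
    fx <- random_seg_fixture(s)
    base <- suppressWarnings(seeded_segmentation(fx$foreground, fx$seeds))
    new_seeds <- fx$seeds
    free <- which(fx$foreground & fx$seeds == 0)
    if (!length(free)) next
    set.seed(s); pos <- sample(free, 1)
    newlab <- max(fx$seeds) + 1L
    new_seeds[pos] <- newlab
    grown <- suppressWarnings(seeded_segmentation(fx$foreground, new_seeds))
    d_old <- Reduce(pmin, lapply(sort(unique(fx$seeds[fx$seeds > 0])),
      function(l) oracle_geodesic_dist(fx$seeds == l, fx$foreground)))
    d_new <- oracle_geodesic_dist(new_seeds == newlab, fx$foreground)
    strictly_closer <- which(d_old < d_new & base > 0)
    expect_identical(grown[strictly_closer], base[strictly_closer])
  }
})

test_that("cell labels restricted to seeded foreground form a partition", {
  for (s in 41:45) {
    fx <- random_seg_fixture(s)
    lab <- suppressWarnings(seeded_segmentation(fx$foreground, fx$seeds))
    # no assignment outside foreground except seed pixels themselves
    outside <- lab > 0 & !fx$foreground
    expect_true(all(fx$seeds[outside] > 0))
    # every labelled foreground pixel has exactly one label by storage;
    # audit reachability: labelled iff geodesically connected to a seed
    labs <- sort(unique(fx$seeds[fx$seeds > 0]))
    if (length(labs)) {
      d_any <- Reduce(pmin, lapply(labs, function(l)
        oracle_geodesic_dist(fx$seeds == l, fx$foreground)))
      fgpx <- which(fx$foreground)
      expect_identical((lab > 0)[fgpx],
                       (is.finite(d_any) | fx$seeds > 0)[fgpx])
    }
  }
})

test_that("cytoplasm labels are the per-cell set difference", {
  # synthetic annulus: cell = disc, nucleus = inner disc
  nr <- 31; nc <- 31
  idx <- expand.grid(r = 1:nr, c = 1:nc)
  d <- sqrt((idx$r - 16)^2 + (idx$c - 16)^2)
  cell <- matrix(as.integer(d <= 12), nr, nc)
  nucleus <- matrix(d <= 5, nr, nc)
  fg <- matrix(TRUE, nr, nc)
  cyto <- cytoplasm_labels(cell, nucleus, fg)
  want <- which(cell == 1 & !nucleus)
  expect_setequal(which(cyto == 1), want)
  expect_length(intersect(which(cyto > 0), which(nucleus)), 0)

  # cell entirely nucleus -> empty cytoplasm
  cyto2 <- cytoplasm_labels(cell, matrix(d <= 12, nr, nc), fg)
  expect_true(all(cyto2 == 0))
  expect_error(cytoplasm_labels(cell, nucleus[1:10, ], fg), "dimensions")
})

test_that("the full workflow finds every generated cell on clean scenes", {
  for (s in c(1, 2, 3)) {
    sc <- small_scene(8, shape = c(280, 280), q = 0.8, seed = 100 + s,
                      gaussian_sd = 0)
    seg <- segment_image(sc$img)
    m <- measure_objects(seg$cyto_labels, seg$cqd_gray, min_area = 100)
    expect_equal(nrow(m), 8)
    expect_length(intersect(which(seg$cyto_labels > 0),
                            which(seg$nuclei$labels > 0)), 0)
  }
})

test_that("default-noise detection rate stays above 95% across seeds", {
  found <- 0; total <- 0
  for (s in 1:20) {
    sc <- small_scene(6, shape = c(256, 256), q = 0.6, seed = 200 + s)
    seg <- segment_image(sc$img)
    m <- measure_objects(seg$cyto_labels, seg$cqd_gray, min_area = 100)
    found <- found + min(nrow(m), 6)
    total <- total + 6
  }
  expect_gte(found / total, 0.95)
})
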