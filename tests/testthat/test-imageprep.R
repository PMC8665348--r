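test_that("TIFF and PNG round-trips preserve pixel values to quantization", {
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  for (ext in c("png", "tif")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_image(img, path)
    back <- read_image(path)
    expect_equal(dim(back), dim(img))
    expect_true(max(abs(back - img)) <= 1 / 255)
  }
  # 16-bit TIFF: finer quantization, and the max code maps to 1.0
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path, bits = 16L)
  expect_true(max(abs(read_image(path) - img)) <= 1 / 65535)
  write_image(array(1, c(2, 2, 1)), path, bits = 16L)
  expect_equal(max(read_image(path)), 1.0)
  # 3-channel PNG keeps its channels; unsupported format errors
  path3 <- withr::local_tempfile(fileext = ".png")
  write_image(img, path3)
  expect_equal(dim(read_image(path3))[3], 3L)
  expect_error(read_image(withr::local_tempfile(fileext = ".bmp")), "read")
})

test_that("center_crop follows the floor((H - side)/2) convention", {
  ramp <- array(seq_len(6 * 6), c(6, 6, 1))
  expect_equal(center_crop(ramp, 2), ramp[3:4, 3:4, , drop = FALSE])
  # odd remainder biases up-left: 5x5 -> side 2 starts at offset 1
  r5 <- array(seq_len(25), c(5, 5, 1))
  expect_equal(center_crop(r5, 2), r5[2:3, 2:3, , drop = FALSE])
  img <- tiny_scene(64, 2, seed = 3)
  expect_equal(dim(center_crop(img, 30)), c(30L, 30L, 3L))
  expect_identical(center_crop(img, 64), img)
  expect_error(center_crop(img, 65), "exceeds")
  # idempotence
  expect_equal(center_crop(center_crop(img, 40), 40), center_crop(img, 40))
})

test_that("resize_bilinear matches the half-pixel-center closed form", {
  # 2x2 -> 4x4: output coordinate i samples s = (i + .5)/2 - .5, so the
  # interior weights are 3/4-1/4 mixes; computed here independently
  x <- matrix(c(0, 1, 2, 4), 2, 2)
  out <- resize_bilinear(array(x, c(2, 2, 1)), 4)[, , 1]
  s <- pmin(pmax((seq_len(4) - 0.5) / 2 - 0.5, 0), 1)
  expected <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j) {
    r0 <- floor(s[i]); c0 <- floor(s[j])
    fr <- s[i] - r0; fc <- s[j] - c0
    r1 <- min(r0 + 1, 1); c1 <- min(c0 + 1, 1)
    x[r0 + 1, c0 + 1] * (1 - fr) * (1 - fc) + x[r1 + 1, c0 + 1] * fr * (1 - fc) +
      x[r0 + 1, c1 + 1] * (1 - fr) * fc + x[r1 + 1, c1 + 1] * fr * fc
  }))
  expect_equal(out, expected, tolerance = 1e-12)
  # constants map to constants; 536 -> 134 shape; range bounds preserved
  expect_equal(resize_bilinear(array(0.5, c(8, 8, 3)), 3),
               array(0.5, c(3, 3, 3)))
  img <- tiny_scene(536 %/% 4, 3, seed = 5)  # small stand-in for shape check
  big <- array(runif(536 * 536 * 3), c(536, 536, 3))
  small <- resize_bilinear(big, 134)
  expect_equal(dim(small), c(134L, 134L, 3L))
  expect_gte(min(small), min(big))
  expect_lte(max(small), max(big))
})

test_that("standardize centers, scales, guards constants, ignores affine maps", {
  img <- tiny_scene(64, 3, seed = 7)
  z <- standardize(img)
  expect_lt(abs(mean(z)), 1e-5)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-3)
  # constant image -> zeros (guarded denominator)
  expect_equal(standardize(array(0.3, c(5, 5, 1))), array(0, c(5, 5, 1)))
  # two-valued image {0,1} equally -> +/-1
  tv <- array(rep(c(0, 1), each = 8), c(4, 4, 1))
  expect_equal(sort(unique(as.vector(standardize(tv)))), c(-1, 1))
  # invariance to positive affine transforms
  expect_equal(standardize(0.2 * img + 0.4), standardize(img), tolerance = 1e-9)
})

test_that("sorting grid crop partitions a 1608-square frame into 9 tiles", {
  img <- array(runif(1608 * 1608), c(1608, 1608, 1))
  tiles <- grid_crop_sorting(img)
  expect_length(tiles, 9L)
  expect_true(all(vapply(tiles, function(t) all(dim(t) == c(536, 536, 1)),
                         logical(1))))
  # exact partition: tile sums add to the source sum, reassembly restores it
  expect_equal(sum(vapply(tiles, sum, numeric(1))), sum(img))
  reassembled <- array(0, dim(img))
  k <- 1
  for (i in 0:2) for (j in 0:2) {
    reassembled[(i * 536 + 1):((i + 1) * 536), (j * 536 + 1):((j + 1) * 536), ] <-
      tiles[[k]]
    k <- k + 1
  }
  expect_identical(reassembled, img)
  # tile (1,1) in 0-based grid coordinates = source rows/cols 537..1072
  expect_equal(tiles[[5]], img[537:1072, 537:1072, , drop = FALSE])
  expect_error(grid_crop_sorting(array(0, c(100, 100, 1))), "1608")
})

test_that("reconstruction grid crop yields 16 covering 388-tiles", {
  img <- array(runif(1608 * 1608), c(1608, 1608, 1))
  tiles <- grid_crop_reconstruction(img)
  expect_length(tiles, 16L)
  expect_true(all(vapply(tiles, function(t) all(dim(t) == c(388, 388, 1)),
                         logical(1))))
  expect_equal(tiles[[1]], img[1:388, 1:388, , drop = FALSE])
  # 16 tiles of 388 px span at most 1552 px per axis, so full coverage of a
  # 1608 frame is impossible; the near-uniform flush offsets leave exactly
  # three narrow gaps of 18-19 px per axis
  covered <- rep(FALSE, 1608)
  for (i in c(0, 406, 813, 1220)) covered[(i + 1):(i + 388)] <- TRUE
  expect_equal(sum(covered), 4 * 388)
  runs <- rle(covered)
  expect_equal(runs$lengths[!runs$values], c(18L, 19L, 19L))
  # last tile flush with the frame edge
  expect_equal(tiles[[16]], img[1221:1608, 1221:1608, , drop = FALSE])
  expect_error(grid_crop_reconstruction(array(0, c(536, 536, 1))), "1608")
})

test_that("symmetric_pad mirrors without the edge pixel and inverts by crop", {
  x <- array(rep(c(1, 2, 3), each = 3), c(3, 3, 1))  # x[i, j] = j
  padded <- symmetric_pad(x, 7)
  expect_equal(padded[4, , 1], c(3, 2, 1, 2, 3, 2, 1))
  expect_equal(dim(symmetric_pad(array(0, c(388, 388, 1)), 572)),
               c(572L, 572L, 1L))
  img <- tiny_scene(64, 2, seed = 9)
  expect_equal(center_crop(symmetric_pad(img, 92), 64), img)
  expect_error(symmetric_pad(img, 67), "even")
  expect_error(symmetric_pad(img, 60), "smaller")
})

test_that("tile_and_restitch with an identity functional is the identity", {
  img <- tiny_scene(64, 2, seed = 11)
  f_id <- function(ctx) center_crop(ctx, 20)
  out <- tile_and_restitch(img, f_id, model_in = 40, model_out = 20)
  expect_equal(out, img)
  # output always matches the input size, including non-multiples
  img2 <- array(runif(70 * 53 * 1), c(70, 53, 1))
  out2 <- tile_and_restitch(img2, function(ctx) center_crop(ctx, 20),
                            model_in = 40, model_out = 20)
  expect_equal(dim(out2), dim(img2))
  expect_equal(out2, img2)
  # single-tile path equals symmetric_pad + f
  img3 <- array(runif(20 * 20), c(20, 20, 1))
  f <- function(ctx) center_crop(ctx^2, 20)
  expect_equal(tile_and_restitch(img3, f, 40, 20),
               f(symmetric_pad(img3, 40)))
})
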