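test_that("tiling uses floor division and drops partial edge strips", {
  # exact division at the native patch size
  s <- slide_image(uniform_patch(600, c(255, 255, 255)), "exact")
  g <- tile_slide(s, 300)
  expect_identical(c(g$n_rows, g$n_cols), c(2L, 2L))
  expect_true(all(g$tissue_mask))

  # same floor arithmetic, scaled geometry: 3050 x 2999 at p = 300 is
  # 10 x 9; here 305 x 299 at p = 30
  px <- array(100L, c(305, 299, 3))
  g2 <- tile_slide(slide_image(px, "edges"), 30)
  expect_identical(c(g2$n_rows, g2$n_cols), c(10L, 9L))

  # a 10x scaled version of the 3000 x 3000 example
  g3 <- tile_slide(slide_image(array(0L, c(300, 300, 3)), "square"), 30)
  expect_identical(g3$n_rows * g3$n_cols, 100L)
})

test_that("a slide smaller than one patch is rejected", {
  s <- slide_image(uniform_patch(299, c(10, 10, 10)), "tiny")
  expect_error(tile_slide(s, 300), "smaller than one")
  expect_error(tile_slide(slide_image(array(0L, c(299, 300, 3))), 300),
               "smaller than one")
})

test_that("retained patch pixel ranges partition the covered raster", {
  s <- slide_image(array(7L, c(65, 47, 3)), "part")
  g <- tile_slide(s, 16)
  covered <- matrix(0L, 65, 47)
  for (i in seq_len(g$n_rows)) for (j in seq_len(g$n_cols)) {
    rows <- ((i - 1) * 16 + 1):(i * 16)
    cols <- ((j - 1) * 16 + 1):(j * 16)
    covered[rows, cols] <- covered[rows, cols] + 1L
  }
  expect_true(all(covered[1:(g$n_rows * 16), 1:(g$n_cols * 16)] == 1L))
  expect_true(all(covered[, (g$n_cols * 16 + 1):47] == 0L))
  expect_true(all(covered[(g$n_rows * 16 + 1):65, ] == 0L))
})

test_that("background clauses evaluate as specified", {
  crit <- background_criteria()
  # uniform white: both clauses fire
  expect_true(is_background(uniform_patch(10, c(255, 255, 255)), crit))
  # uniform mid-gray: range clause fires even though dark
  expect_true(is_background(uniform_patch(10, c(128, 128, 128)), crit))
  # H&E-like alternation: high channel range, dark -> tissue
  expect_false(is_background(stained_patch(10), crit))
  # non-8-bit input errors
  bad <- array(0.5, c(10, 10, 3))
  expect_error(is_background(bad, crit), "8-bit")
})

test_that("background decision is a pixel-set statistic (permutation invariant)", {
  set.seed(11)
  patch <- stained_patch(8)
  perm <- sample(64)
  shuffled <- patch
  for (ch in 1:3) {
    plane <- patch[, , ch]
    shuffled[, , ch] <- matrix(plane[perm], 8, 8)
  }
  crit <- background_criteria()
  expect_identical(is_background(patch, crit), is_background(shuffled, crit))
})

test_that("background flagging is monotone in the thresholds", {
  # uniform patches spanning channel ranges 0..50 and all brightness levels
  set.seed(23)
  patches <- replicate(40, {
    base <- sample(0:205, 1)
    r <- sample(0:50, 1)
    uniform_patch(8, c(base, base + r %/% 2, base + r))
  }, simplify = FALSE)
  loose <- background_criteria(channel_range_max = 40,
                               brightness_threshold = 180)
  strict <- background_criteria(channel_range_max = 20,
                                brightness_threshold = 220)
  flag_strict <- vapply(patches, is_background, TRUE, criteria = strict)
  flag_loose <- vapply(patches, is_background, TRUE, criteria = loose)
  # raising channel_range_max / lowering brightness_threshold only adds
  # background flags
  expect_true(all(flag_loose | !flag_strict))
  expect_true(any(flag_strict))    # both outcomes are exercised
  expect_true(any(!flag_loose))
})

test_that("filter_background toggles only the tissue mask", {
  # all-white slide: everything background
  s <- slide_image(uniform_patch(40, c(255, 255, 255)), "white")
  g <- filter_background(tile_slide(s, 10), s)
  expect_identical(c(g$n_rows, g$n_cols), c(4L, 4L))
  expect_false(any(g$tissue_mask))

  # one stained 2x2-patch block at the origin on white
  px <- uniform_patch(40, c(255, 255, 255))
  px[1:20, 1:20, ] <- stained_patch(20)
  s2 <- slide_image(px, "block")
  g2 <- filter_background(tile_slide(s2, 10), s2)
  want <- matrix(FALSE, 4, 4); want[1:2, 1:2] <- TRUE
  expect_identical(g2$tissue_mask, want)

  # grid/slide mismatch errors
  other <- slide_image(uniform_patch(40, c(0, 0, 0)), "other")
  expect_error(filter_background(g2, other), "does not match")
})

test_that("surface_fraction = 1 cannot fire the brightness clause", {
  # half stained, half white: bright fraction is exactly 0.5
  px <- uniform_patch(10, c(255, 255, 255))
  px[1:5, , ] <- stained_patch(10)[1:5, , ]
  crit <- background_criteria(surface_fraction = 0.99)
  expect_false(is_background(px, crit))
})

test_that("literal brightness direction is available behind the flag", {
  dark <- stained_patch(10)  # all pixels darker than 220
  literal <- background_criteria(bright_is_background = FALSE)
  expect_true(is_background(dark, literal))
})

test_that("grayscale conversion uses BT.601 luma", {
  expect_equal(to_grayscale(uniform_patch(2, c(255, 255, 255)))[1, 1], 255L)
  expect_equal(to_grayscale(uniform_patch(2, c(255, 0, 0)))[1, 1], 76L)
  expect_equal(to_grayscale(uniform_patch(2, c(0, 0, 0)))[1, 1], 0L)
})

test_that("patch manifest round-trips coordinates in the declared convention", {
  s <- slide_image(uniform_patch(30, c(255, 255, 255)), "m")
  g <- filter_background(tile_slide(s, 10), s)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_patch_manifest(g, path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_identical(nrow(df), 9L)
  expect_identical(sort(unique(df$row)), 0:2)
  expect_true(all(df$x0 == df$col * 10))
  expect_true(all(df$is_tissue == 0L))
})
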