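write_png_fixture <- function(path, n = 24) {
  png::writePNG(matrix(runif(n * n), n, n), path)
}

test_that("empty directories load as empty indexes", {
  dir <- withr::local_tempdir()
  idx <- load_deposit(dir)
  expect_equal(nrow(idx), 0)
  tab <- summarize_counts(idx)
  expect_equal(sum(tab), 0)
  expect_error(load_deposit(file.path(dir, "nope")), "does not exist")
})

test_that("annotation tables with ellipse records rasterize correctly", {
  dir <- withr::local_tempdir()
  set.seed(13)
  for (f in c("a.png", "b.png")) write_png_fixture(file.path(dir, f), 24)
  write.csv(data.frame(filename = c("a.png", "b.png"),
                       cx = c(12, 8), cy = c(10, 14), a = c(6, 4),
                       b = c(4, 3), angle = c(0, 0.5),
                       class = c("mouse", "human"),
                       blink = c(FALSE, FALSE), eye_present = TRUE),
            file.path(dir, "annotations.csv"), row.names = FALSE)
  idx <- load_deposit(dir)
  expect_equal(nrow(idx), 2)
  expect_equal(idx$annotation, c("ellipse", "ellipse"))
  frames <- load_labeled_frames(idx)
  expect_equal(sum(frames[[1]]$mask),
               oracle_ellipse_pixel_count(24, c(12, 10), c(6, 4), 0))
  expect_equal(sum(frames[[2]]$mask),
               oracle_ellipse_pixel_count(24, c(8, 14), c(4, 3), 0.5))
})

test_that("polygon annotations rasterize by the pixel-centre rule", {
  dir <- withr::local_tempdir()
  write_png_fixture(file.path(dir, "sq.png"), 32)
  write.csv(data.frame(filename = "sq.png",
                       polygon = "10 10;20 10;20 20;10 20",
                       class = "human"),
            file.path(dir, "annotations.csv"), row.names = FALSE)
  idx <- load_deposit(dir)
  frames <- load_labeled_frames(idx)
  # half-open square [10,20) x [10,20): exactly 100 pixel centres
  expect_equal(sum(frames[[1]]$mask), 100)
})

test_that("records with missing annotations are excluded with a warning", {
  dir <- withr::local_tempdir()
  write_png_fixture(file.path(dir, "ok.png"))
  write_png_fixture(file.path(dir, "bad.png"))
  write_png_fixture(file.path(dir, "ok_mask.png"))
  expect_warning(idx <- load_deposit(dir), "missing mask")
  expect_equal(nrow(idx), 1)
  expect_match(idx$image[1], "ok.png")
})

test_that("paired images/ + masks/ layouts are detected", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "images")); dir.create(file.path(dir, "masks"))
  for (f in c("x.png", "y.png")) {
    write_png_fixture(file.path(dir, "images", f), 16)
    png::writePNG(matrix(c(0, 1), 16, 16), file.path(dir, "masks", f))
  }
  idx <- load_deposit(dir)
  expect_equal(nrow(idx), 2)
  frames <- load_labeled_frames(idx)
  expect_equal(sum(frames[[1]]$mask), 128)
})

test_that("count summaries are exhaustive with consistent margins", {
  frames <- make_training_set(40, blink_fraction = 0.25, seed = 14,
                              image_size = 16)
  dir <- withr::local_tempdir()
  write_eye_dataset(frames, dir)
  idx <- load_deposit(dir)
  tab <- summarize_counts(idx)
  expect_equal(unname(tab["Total", "Total"]), 40)
  # margins sum: row/column totals agree with the grand total
  classes <- setdiff(rownames(tab), "Total")
  expect_equal(sum(tab[classes, "Total"]), 40)
  # counts match the generator's own bookkeeping
  got_blinks <- sum(vapply(frames, function(f) f$blink, logical(1)))
  expect_equal(unname(tab["Total", "TRUE"]), got_blinks)
  cls <- vapply(frames, function(f) attr(f, "class_tag"), character(1))
  cls <- pupilkit:::normalize_class(cls)
  for (cl in classes)
    expect_equal(unname(tab[cl, "Total"]), sum(cls == cl))
})
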