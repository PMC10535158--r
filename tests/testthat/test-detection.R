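test_that("the mock detector honours its ground-truth contract", {
  vid <- local_test_video(3, seed = 2)
  det_fn <- mock_detector(vid$annotations)
  e <- vid$schedule$events[1, ]
  mid <- e$start_frame + (e$end_frame - e$start_frame) %/% 4L
  d <- detect(vid$frames[[mid + 1L]], det_fn, frame_index = mid)
  a <- vid$annotations[[mid + 1L]]
  expect_equal(unname(d$bbox), unname(as.numeric(a$bbox)))
  expect_equal(d$class_label, a$species)

  empty_frame <- which(!vapply(vid$annotations, `[[`, logical(1),
                               "present"))[1L]
  expect_null(detect(vid$frames[[empty_frame]], det_fn,
                     frame_index = empty_frame - 1L))
})

test_that("a jittered mock detector stays above IoU 0.8 for typical blob sizes", {
  # typical full-resolution animal boxes are hundreds of pixels across
  # (the study's mean box was 560x540), so 2 px of corner jitter barely
  # moves the IoU; construct annotations at that scale directly
  set.seed(13)
  anns <- lapply(1:40, function(i) {
    structure(list(present = TRUE, species = "crab",
                   bbox = c(x = runif(1, 0, 600), y = runif(1, 0, 200),
                            w = runif(1, 400, 600), h = runif(1, 350, 550))),
              class = "scene_annotation")
  })
  det_fn <- mock_detector(anns, jitter_sd = 2, seed = 1)
  dummy <- matrix(0, 2, 2)
  ious <- vapply(seq_along(anns), function(f) {
    d <- detect(dummy, det_fn, frame_index = f - 1L)
    bbox_iou(unname(d$bbox), unname(as.numeric(anns[[f]]$bbox)))
  }, numeric(1))
  expect_gt(min(ious), 0.8)
})

test_that("the blob detector localises the synthetic animal without ground truth", {
  g <- generate_frame(TRUE, "top",
                      pose = list(center = c(60, 34), angle = 0.4, scale = 11),
                      image_size = c(128, 72), species = "crab", seed = 3)
  d <- blob_detector()(g$image)
  expect_s3_class(d, "detection")
  expect_gt(bbox_iou(unname(d$bbox), unname(as.numeric(g$annotation$bbox))),
            0.5)
  lob <- generate_frame(TRUE, "top",
                        pose = list(center = c(60, 34), angle = 1.2,
                                    scale = 13),
                        image_size = c(128, 72), species = "lobster", seed = 4)
  expect_equal(blob_detector()(lob$image)$class_label, "lobster")
  bg <- generate_frame(FALSE, image_size = c(128, 72), seed = 5)
  expect_null(blob_detector()(bg$image))
})

test_that("derive_crop_size averages box dimensions with even rounding", {
  same <- replicate(4, detection(c(0, 0, 100, 80), "crab"),
                    simplify = FALSE)
  cs <- derive_crop_size(same)
  expect_equal(c(cs$crop_w, cs$crop_h), c(100L, 80L))

  mixed <- list(detection(c(0, 0, 550, 530), "crab"),
                detection(c(0, 0, 570, 550), "lobster"))
  cs2 <- derive_crop_size(mixed)
  expect_equal(c(cs2$crop_w, cs2$crop_h), c(560L, 540L))

  one <- derive_crop_size(list(detection(c(0, 0, 33, 41), "crab")))
  expect_equal(c(one$crop_w, one$crop_h), c(34L, 42L))  # ties round up
  expect_error(derive_crop_size(list()), "no detections")
})

test_that("crop_fixed is a pure translation clamped inside the image", {
  set.seed(50)
  img <- matrix(sample(0:255, 100 * 140, replace = TRUE), nrow = 100)
  spec <- crop_spec(40, 30)
  # centred bbox
  d <- detection(c(60, 40, 20, 20), "crab")
  cr <- crop_fixed(img, d, spec)
  expect_equal(dim(cr$image), c(30, 40))
  expect_equal(cr$x0, 50L); expect_equal(cr$y0, 35L)
  # pure copy: crop pixels equal source pixels at translated coordinates
  expect_identical(cr$image, img[36:65, 51:90])

  # random boxes vs an interval oracle for the clamped window
  for (i in 1:25) {
    b <- c(runif(1, -5, 120), runif(1, -5, 90), runif(1, 5, 30),
           runif(1, 5, 25))
    d <- detection(b, "lobster")
    cr <- crop_fixed(img, d, spec)
    x0_oracle <- min(max(round(b[1] + b[3] / 2 - 20), 0), 140 - 40)
    y0_oracle <- min(max(round(b[2] + b[4] / 2 - 15), 0), 100 - 30)
    expect_equal(cr$x0, as.integer(x0_oracle))
    expect_equal(cr$y0, as.integer(y0_oracle))
    expect_equal(dim(cr$image), c(30, 40))
    expect_identical(cr$image,
                     img[(cr$y0 + 1):(cr$y0 + 30), (cr$x0 + 1):(cr$x0 + 40)])
  }
  expect_error(crop_fixed(img, d, crop_spec(200, 30)), "never downscale")
})

test_that("frame/crop keypoint transforms are exact inverses", {
  img <- matrix(0, 60, 80)
  cr <- crop_fixed(img, detection(c(30, 20, 10, 10), "crab"),
                   crop_spec(20, 16))
  pts <- cbind(x = c(31.5, 40), y = c(22.25, 29))
  expect_equal(to_frame_coords(to_crop_coords(pts, cr), cr), pts)
})

test_that("detections export to CSV", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(list(detection(c(1, 2, 3, 4), "crab", 0.9)), 7L, p)
  df <- read.csv(p)
  expect_equal(df$frame, 7L)
  expect_equal(df$class, "crab")
  write_detections_csv(list(), integer(0), p)
  expect_equal(nrow(read.csv(p)), 0L)
})
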