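test_that("the 14-value encoding round-trips losslessly in canonical order", {
  set.seed(60)
  m <- matrix(runif(14, 0, 500), ncol = 2,
              dimnames = list(keypoint_names(), c("x", "y")))
  kp <- keypoint_set(m)
  v <- encode_keypoints(kp)
  expect_length(v, 14L)
  expect_equal(v[1:2], unname(m["crab_left", ]))
  expect_equal(unclass(decode_keypoints(v)), unclass(kp))

  # order-independence of construction
  shuffled <- m[sample(7), , drop = FALSE]
  expect_equal(unclass(keypoint_set(shuffled)), unclass(kp))
  expect_error(keypoint_set(m[1:6, ]), "7 canonical")
})

test_that("predict_keypoints emits exactly 7 named points and rejects wrong shapes", {
  spec <- crop_spec(16, 16)
  net <- keypoint_network(spec, widths = c(4, 8), dense_units = 8, seed = 1)
  crop <- matrix(runif(256, 0, 255), 16, 16)
  kp <- predict_keypoints(crop, net)
  expect_s3_class(kp, "keypoint_set")
  expect_equal(rownames(kp), keypoint_names())
  expect_length(encode_keypoints(kp), 14L)
  expect_error(predict_keypoints(matrix(0, 15, 16), net), "never resize")
})

test_that("a zero-initialised head outputs exactly its bias", {
  spec <- crop_spec(16, 16)
  net <- keypoint_network(spec, widths = c(4, 8), dense_units = 8, seed = 2)
  last <- length(net$layers)
  net$layers[[last]]$W[] <- 0
  net$layers[[last]]$b[] <- 3.5
  kp <- predict_keypoints(matrix(runif(256, 0, 255), 16, 16), net)
  expect_true(all(encode_keypoints(kp) == 3.5))
})

test_that("MEE matches hand values and a brute-force loop oracle", {
  set.seed(61)
  truth <- lapply(1:4, function(i) {
    keypoint_set(matrix(runif(14, 0, 100), ncol = 2,
                        dimnames = list(keypoint_names(), c("x", "y"))))
  })
  expect_equal(mean_euclidean_error(truth, truth), 0)

  shifted <- lapply(truth, function(kp)
    keypoint_set(sweep(unclass(kp), 2, c(3, 4), `+`)))
  expect_equal(mean_euclidean_error(shifted, truth), 5.0)

  pred <- lapply(truth, function(kp)
    keypoint_set(unclass(kp) + matrix(rnorm(14), ncol = 2)))
  # independent loop oracle
  total <- 0; count <- 0
  for (i in 1:4) {
    for (nm in keypoint_names()) {
      dx <- unclass(pred[[i]])[nm, 1] - unclass(truth[[i]])[nm, 1]
      dy <- unclass(pred[[i]])[nm, 2] - unclass(truth[[i]])[nm, 2]
      total <- total + sqrt(dx^2 + dy^2); count <- count + 1
    }
  }
  expect_equal(mean_euclidean_error(pred, truth), total / count,
               tolerance = 1e-12)

  # invariance under common translation
  t_pred <- lapply(pred, function(kp)
    keypoint_set(sweep(unclass(kp), 2, c(17, -9), `+`)))
  t_truth <- lapply(truth, function(kp)
    keypoint_set(sweep(unclass(kp), 2, c(17, -9), `+`)))
  expect_equal(mean_euclidean_error(t_pred, t_truth),
               mean_euclidean_error(pred, truth), tolerance = 1e-9)
})

test_that("relative error is MEE over mean bbox diagonal, as a percentage", {
  expect_equal(relative_error(0, 300), 0)
  expect_equal(relative_error(5, 100), 5)
  expect_error(relative_error(5, 0), "positive")
  # consistency of the published pair under the diagonal convention
  size <- 100 * 28.09 / 5.76
  expect_equal(relative_error(28.09, size), 5.76, tolerance = 1e-9)
  expect_equal(mean_bbox_diagonal(list(c(0, 0, 3, 4), c(10, 10, 6, 8))),
               mean(c(5, 10)))
})

test_that("species keypoint subsets partition the 7 names", {
  crab <- species_keypoints("crab")
  lob <- species_keypoints("lobster")
  expect_length(crab, 2L)
  expect_length(lob, 5L)
  expect_setequal(c(crab, lob), keypoint_names())
  expect_length(intersect(crab, lob), 0L)
  expect_error(species_keypoints("haddock"), "unknown class")
})

test_that("brief training strictly reduces MEE on held-out synthetic crops", {
  ds <- synthetic_keypoint_dataset(40, frame_size = c(48, 48),
                                   spec = crop_spec(32, 32), seed = 70)
  hold <- synthetic_keypoint_dataset(15, frame_size = c(48, 48),
                                     spec = crop_spec(32, 32), seed = 71)
  net <- keypoint_network(crop_spec(32, 32), widths = c(8, 16), seed = 70)
  mee_of <- function(m) mean_euclidean_error(
    lapply(hold$crops, predict_keypoints, model = m), hold$targets)
  before <- mee_of(net)
  trained <- train_keypoint_model(net, ds$crops, ds$targets, epochs = 5,
                                  seed = 70)
  expect_lt(mee_of(trained), before)
})

test_that("VIA keypoint exports import into canonical keypoint sets", {
  via <- list(
    "crab1.jpg123" = list(
      filename = "crab1.jpg",
      regions = lapply(seq_along(keypoint_names()), function(i) list(
        shape_attributes = list(name = "point", cx = i * 10, cy = i * 5 + 1),
        region_attributes = list(name = keypoint_names()[i])))),
    "partial.jpg9" = list(
      filename = "partial.jpg",
      regions = list(list(
        shape_attributes = list(name = "point", cx = 1, cy = 2),
        region_attributes = list(name = "left_eye")))))
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(via, p, auto_unbox = TRUE)
  expect_warning(kps <- import_via_keypoints(p), "partial.jpg")
  expect_length(kps, 1L)
  kp <- kps[["crab1.jpg"]]
  expect_equal(rownames(kp), keypoint_names())
  expect_equal(unname(unclass(kp)["left_eye", ]), c(30, 16))
})

test_that("keypoint predictions export to CSV with NA rows for undetected contigs", {
  kp <- decode_keypoints(as.numeric(1:14))
  rec <- data.frame(contig_id = 0:1, class_label = c("crab", "undetected"))
  rec$keypoints <- list(kp, NULL)
  p <- withr::local_tempfile(fileext = ".csv")
  write_keypoints_csv(rec, p)
  df <- read.csv(p)
  expect_equal(nrow(df), 2L)
  expect_equal(df$crab_left_x[1], 1)
  expect_true(is.na(df$crab_left_x[2]))
})
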