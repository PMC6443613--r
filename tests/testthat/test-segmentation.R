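test_that("training reduces the loss and records a finite trace", {
  fx <- seg_fixture()
  trace <- fx$model$loss_trace
  expect_true(all(is.finite(trace)))
  expect_lt(trace[length(trace)], trace[1])
})

test_that("training is deterministic under a fixed seed", {
  fx <- seg_fixture()
  again <- train_segmenter(fx$volumes[1:4], fx$masks[1:4],
                           patch_spec(11L, c(1, 3)),
                           list(epochs = 4L, samples_per_volume = 400L,
                                seed = 1L))
  expect_identical(again$loss_trace, fx$model$loss_trace)
})

test_that("all-empty masks are rejected", {
  vol <- ct_volume(array(0, c(16, 16, 16)))
  expect_error(train_segmenter(list(vol), list(array(0L, c(16, 16, 16)))),
               "empty")
})

test_that("segmentation output lives on the input grid with binary values", {
  fx <- seg_fixture()
  mask <- segment_volume(fx$model, fx$volumes[[5]], stride = 2)
  expect_identical(dim(mask), dim(fx$volumes[[5]]$data))
  expect_true(all(mask %in% c(0L, 1L)))
  # deterministic inference
  expect_identical(mask, segment_volume(fx$model, fx$volumes[[5]], stride = 2))
})

test_that("a spacing mismatch with the training convention is rejected", {
  fx <- seg_fixture()
  odd <- ct_volume(fx$volumes[[5]]$data, spacing = c(2, 2, 2))
  expect_error(segment_volume(fx$model, odd), "spacing")
})

test_that("pure background volumes produce an almost empty mask", {
  fx <- seg_fixture()
  bg <- ct_volume(array(-50, c(32, 32, 32)) +
                    lvmtriage:::with_seed(3, array(rnorm(32^3, 0, 15),
                                                   c(32, 32, 32))))
  mask <- segment_volume(fx$model, bg, stride = 2, cleanup = FALSE)
  expect_lt(mean(mask), 0.05)
})

test_that("segmentation QC passes true masks and enumerates failures", {
  fx <- seg_fixture()
  qc <- qc_segmentation(fx$masks[[5]])
  expect_true(qc$pass)
  expect_length(qc$reasons, 0)

  empty <- qc_segmentation(array(0L, c(16, 16, 16)))
  expect_false(empty$pass)
  expect_match(empty$reasons, "below minimum", all = FALSE)

  # a distant spurious blob holding ~40% of the mask trips the
  # connected-component check (largest component < 80% of voxels)
  m <- fx$masks[[5]]
  blob_n <- round(0.4 * sum(m))
  big <- array(0L, dim(m) + 14L)
  big[seq_len(dim(m)[1]), seq_len(dim(m)[2]), seq_len(dim(m)[3])] <- m
  corner <- which(big == 0L & slice.index(big, 1) > dim(m)[1] + 2 &
                    slice.index(big, 2) > dim(m)[2] + 2 &
                    slice.index(big, 3) > dim(m)[3] + 2)
  big[corner[seq_len(blob_n)]] <- 1L
  qc2 <- qc_segmentation(big)
  expect_false(qc2$pass)
  expect_match(qc2$reasons, "connected component", all = FALSE)
})

test_that("connected-component labelling separates disjoint blobs", {
  m <- array(0L, c(10, 10, 10))
  m[1:3, 1:3, 1:3] <- 1L
  m[8:10, 8:10, 8:10] <- 1L
  lab <- lvmtriage:::label_components(m)
  expect_equal(sort(unique(lab[lab > 0])), c(1L, 2L))
  expect_equal(sum(lab == 1), 27)
  expect_equal(sum(lab == 2), 27)
  # diagonal touch is not 6-connected
  m2 <- array(0L, c(4, 4, 4))
  m2[1, 1, 1] <- 1L
  m2[2, 2, 2] <- 1L
  expect_equal(max(lvmtriage:::label_components(m2)), 2L)
})

test_that("checkpoints round-trip with the embedded patch specification", {
  fx <- seg_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  save_segmenter(fx$model, path)
  loaded <- load_segmenter(path)
  expect_identical(loaded$patch_spec, fx$model$patch_spec)
  a <- segment_volume(fx$model, fx$volumes[[5]], stride = 4)
  b <- segment_volume(loaded, fx$volumes[[5]], stride = 4)
  expect_identical(a, b)
})
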