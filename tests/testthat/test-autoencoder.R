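test_that("auto-encoder training reduces reconstruction loss deterministically", {
  fx <- cae_fixture()
  trace <- fx$model$loss_trace
  expect_true(all(is.finite(trace)))
  expect_lt(trace[length(trace)], trace[1])
  again <- train_autoencoder(fx$patches, 16L, list(epochs = 5L, seed = 1L))
  expect_identical(again$loss_trace, trace)
})

test_that("an encoding dimension without compression is rejected", {
  fx <- cae_fixture()
  expect_error(train_autoencoder(fx$patches, 256L), "compression")
  expect_error(train_autoencoder(fx$patches, 300L), "compression")
})

test_that("encode_lvm yields one encoding per masked voxel", {
  fx <- cae_fixture()
  ph <- fx$phantom
  enc <- encode_lvm(fx$model, ph$volume, ph$mask, stride = 1)
  expect_equal(nrow(enc$encodings), sum(ph$mask))
  expect_equal(ncol(enc$encodings), 16)
  expect_false(any(duplicated(enc$voxels)))
  expect_true(all(ph$mask[enc$voxels] == 1))
  expect_error(encode_lvm(fx$model, ph$volume, array(0L, dim(ph$mask))),
               "empty")
})

test_that("a constant volume yields identical encodings everywhere", {
  fx <- cae_fixture()
  vol <- array(100, c(20, 20, 20))
  mask <- array(0L, c(20, 20, 20))
  mask[8:12, 8:12, 8:12] <- 1L
  enc <- encode_lvm(fx$model, vol, mask)
  expect_equal(max(apply(enc$encodings, 2, function(x) diff(range(x)))), 0)
})

test_that("encodings are deterministic and separate lesion from normal tissue", {
  fx <- cae_fixture()
  ph <- fx$phantom
  enc1 <- encode_lvm(fx$model, ph$volume, ph$mask, stride = 2)
  enc2 <- encode_lvm(fx$model, ph$volume, ph$mask, stride = 2)
  expect_identical(enc1$encodings, enc2$encodings)

  # the same geometry without a lesion identifies the lesion-sector voxels
  spec <- tiny_spec(effect_size = 60)
  pp <- phantom_params(spec, seed = 101)
  neg <- generate_phantom_volume(pp, FALSE, spec)
  depressed <- ph$volume$data - neg$volume$data < -30  # lesion plateau voxels
  lesion_vox <- which(ph$mask != 0 & depressed)
  normal_vox <- which(ph$mask != 0 & !depressed)
  enc <- encode_lvm(fx$model, ph$volume, ph$mask)
  lin <- enc$voxels[, 1] + (enc$voxels[, 2] - 1) * dim(ph$mask)[1] +
    (enc$voxels[, 3] - 1) * dim(ph$mask)[1] * dim(ph$mask)[2]
  in_lesion <- lin %in% lesion_vox
  in_normal <- lin %in% normal_vox
  pvals <- vapply(seq_len(16), function(k)
    stats::t.test(enc$encodings[in_lesion, k],
                  enc$encodings[in_normal, k])$p.value, numeric(1))
  expect_lt(min(pvals), 1e-6)
})

test_that("reconstruction matches shapes, stays finite, beats the untrained model", {
  fx <- cae_fixture()
  patch <- fx$patches[, , 1, 1]
  rec <- reconstruct(fx$model, patch)
  expect_identical(dim(rec), dim(patch))
  expect_true(all(is.finite(rec)))
  expect_error(reconstruct(fx$model, matrix(0, 8, 8)), "shape")
  # zero input through the untrained network still yields finite output
  untrained <- train_autoencoder(fx$patches, 16L, list(epochs = 0L, seed = 1L))
  expect_true(all(is.finite(reconstruct(untrained, matrix(0, 16, 16)))))
  # trained reconstruction error beats the untrained baseline with equal seed
  err <- function(m) {
    mean(vapply(1:200, function(i)
      mean((reconstruct(m, fx$patches[, , 1, i]) - fx$patches[, , 1, i])^2),
      numeric(1)))
  }
  expect_lt(err(fx$model), err(untrained))
})
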