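# Unsupervised characterization of the myocardium: a convolutional
# auto-encoder over axial in-plane patches centred on myocardial voxels.
# The encoder stacks convolution + max-pooling blocks into a dense
# bottleneck; the decoder expands the bottleneck back to the patch.

cae_default_config <- function() {
  list(epochs = 10L, batch = 64L, lr = 1e-3, seed = 1L, filters = c(8L, 8L),
       patch_size = 16L)
}

cae_geometry <- function(q, filters) {
  map1 <- build_im2col_idx(q, q, 1L, 3L)
  h1 <- map1$oh %/% 2L
  if (h1 - 2L < 2L) stop("`patch_size` too small for the encoder (need >= 9)")
  map2 <- build_im2col_idx(h1, h1, filters[1], 3L)
  h2 <- map2$oh %/% 2L
  list(map1 = map1, map2 = map2, h1 = h1, h2 = h2,
       flat = h2 * h2 * filters[2], q = q)
}

cae_init_params <- function(geom, filters, encoding_dim) {
  list(conv1 = conv_init(3L, 1L, filters[1]),
       conv2 = conv_init(3L, filters[1], filters[2]),
       enc = dense_init(geom$flat, encoding_dim),
       dec = dense_init(encoding_dim, geom$q * geom$q, sd = sqrt(1 / encoding_dim)))
}

cae_encode_forward <- function(par, geom, x, keep_cache = TRUE) {
  c1 <- conv_forward(x, par$conv1, geom$map1)
  a1 <- relu(c1$out)
  p1 <- maxpool_forward(a1)
  c2 <- conv_forward(p1$out, par$conv2, geom$map2)
  a2 <- relu(c2$out)
  p2 <- maxpool_forward(a2)
  flat <- matrix(p2$out, ncol = dim(x)[4])
  code <- dense_forward(flat, par$enc)
  if (!keep_cache) return(list(code = code))
  list(code = code, c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2,
       flat = flat)
}

cae_forward <- function(par, geom, x, keep_cache = TRUE) {
  enc <- cae_encode_forward(par, geom, x, keep_cache)
  recon <- dense_forward(enc$code, par$dec)     # (q*q, N)
  c(enc, list(recon = recon))
}

cae_backward <- function(par, geom, cache, x, target) {
  N <- dim(x)[4]
  grads <- list()
  drecon <- 2 * (cache$recon - target) / (nrow(target) * N)
  gdec <- dense_backward(drecon, par$dec, cache$code)
  grads$dec <- gdec
  genc <- dense_backward(gdec$dx, par$enc, cache$flat)
  grads$enc <- genc
  dp2 <- array(genc$dx, dim(cache$p2$out))
  da2 <- maxpool_backward(dp2, cache$p2)
  dc2 <- relu_backward(da2, cache$a2)
  gc2 <- conv_backward(dc2, par$conv2, geom$map2, cache$c2)
  grads$conv2 <- gc2
  da1 <- maxpool_backward(gc2$dx, cache$p1)
  dc1 <- relu_backward(da1, cache$a1)
  grads$conv1 <- conv_backward(dc1, par$conv1, geom$map1, cache$c1)
  grads
}

# Axial in-plane patches (q x q, channel 1) around given voxels, reflect
# padded, as network input. Even q centres the voxel at (q/2, q/2).
extract_axial_patches <- function(vol, voxels, q) {
  half_lo <- q %/% 2L - 1L + (q %% 2L)
  offs <- seq(-half_lo, q - 1L - half_lo)
  pl <- extract_plane_batch(vol, voxels, "axial", offs)
  array(pl, c(q, q, 1L, nrow(voxels)))
}

#' Train a convolutional auto-encoder on myocardial patches
#'
#' Learns an unsupervised low-dimensional encoding of local myocardial
#' appearance. Input patches are compressed by two convolution + max-pooling
#' blocks into a dense bottleneck of length `encoding_dim` and expanded back
#' to the patch by the decoder; training minimizes mean squared
#' reconstruction error. Deterministic given `config$seed`.
#'
#' @param patches array `(q, q, 1, n)` of HU patches (as produced internally
#'   from masked voxels), or a list of `q x q` matrices.
#' @param encoding_dim bottleneck length; must be smaller than the patch
#'   pixel count (otherwise nothing is compressed).
#' @param config named list overriding `epochs` (5), `batch` (64), `lr`
#'   (1e-3), `seed` (1), `filters` (c(8, 8)).
#' @return An object of class `lvm_cae` with the trained weights, the
#'   reconstruction-loss trace (element 1 = untrained loss) and metadata.
#' @export
train_autoencoder <- function(patches, encoding_dim = 16L, config = list()) {
  cfg <- utils::modifyList(cae_default_config(), config)
  if (is.list(patches) && !is.array(patches)) {
    q <- nrow(patches[[1]])
    arr <- array(0, c(q, q, 1L, length(patches)))
    for (i in seq_along(patches)) arr[, , 1, i] <- patches[[i]]
    patches <- arr
  }
  stopifnot(is.array(patches), length(dim(patches)) == 4)
  q <- dim(patches)[1]
  n <- dim(patches)[4]
  if (n < 1) stop("at least one patch is required")
  encoding_dim <- as.integer(encoding_dim)
  if (encoding_dim >= q * q)
    stop(sprintf("`encoding_dim` (%d) must be smaller than the patch pixel count (%d): no compression",
                 encoding_dim, q * q))
  geom <- cae_geometry(q, cfg$filters)
  x <- patches / HU_SCALE
  target <- matrix(x, ncol = n)

  with_seed(cfg$seed, {
    par <- cae_init_params(geom, cfg$filters, encoding_dim)
    state <- adam_init(par)
    fw0 <- cae_forward(par, geom, x, keep_cache = FALSE)
    trace <- mean((fw0$recon - target)^2)
    t <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_losses <- c()
      for (b0 in seq(1L, n, by = cfg$batch)) {
        sel <- ord[b0:min(b0 + cfg$batch - 1L, n)]
        bx <- x[, , , sel, drop = FALSE]
        bt <- target[, sel, drop = FALSE]
        cache <- cae_forward(par, geom, bx)
        ep_losses <- c(ep_losses, mean((cache$recon - bt)^2))
        grads <- cae_backward(par, geom, cache, bx, bt)
        t <- t + 1L
        upd <- adam_step(par, grads, state, cfg$lr, t)
        par <- upd$params
        state <- upd$state
      }
      trace <- c(trace, mean(ep_losses))
    }
    structure(list(params = par, geom = geom, encoding_dim = encoding_dim,
                   patch_size = q, config = cfg, loss_trace = trace,
                   n_train = n),
              class = "lvm_cae")
  })
}

#' @export
print.lvm_cae <- function(x, ...) {
  cat(sprintf("<lvm_cae> %dx%d patches -> %d-dim encoding, %d epochs, loss %.5f -> %.5f\n",
              x$patch_size, x$patch_size, x$encoding_dim, x$config$epochs,
              x$loss_trace[1], x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Encode every myocardial voxel of a segmented volume
#'
#' Runs the trained encoder on the axial patch around each masked voxel
#' (optionally on a regular voxel stride) and returns one encoding vector
#' per visited voxel.
#'
#' @param model an [train_autoencoder()] model.
#' @param volume a [ct_volume()] (or 3D array).
#' @param mask binary myocardium mask on the same grid; must be non-empty
#'   (an empty mask is a segmentation/QC failure, not a valid input).
#' @param stride positive integer stride over voxel coordinates.
#' @param patient_id provenance tag stored with the encodings.
#' @param batch voxels encoded per forward pass.
#' @return An object of class `voxel_encoding_set`: list with `voxels`
#'   (m x 3 index matrix), `encodings` (m x encoding_dim matrix),
#'   `patient_id` and `encoding_dim`.
#' @export
encode_lvm <- function(model, volume, mask, stride = 1L, patient_id = NA_character_,
                       batch = 4096L) {
  stopifnot(inherits(model, "lvm_cae"))
  vol <- if (inherits(volume, "ct_volume")) volume$data else volume
  stopifnot(identical(dim(vol), dim(mask)))
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("empty myocardium mask: nothing to encode")
  vox <- arrayInd(idx, dim(mask))
  if (stride > 1L) {
    keep <- (vox[, 1] - 1L) %% stride == 0L & (vox[, 2] - 1L) %% stride == 0L &
      (vox[, 3] - 1L) %% stride == 0L
    if (!any(keep)) keep[1] <- TRUE  # never return an empty set for a non-empty mask
    vox <- vox[keep, , drop = FALSE]
  }
  m <- nrow(vox)
  enc <- matrix(0, m, model$encoding_dim)
  for (b0 in seq(1L, m, by = batch)) {
    sel <- b0:min(b0 + batch - 1L, m)
    x <- extract_axial_patches(vol, vox[sel, , drop = FALSE], model$patch_size) / HU_SCALE
    enc[sel, ] <- t(cae_encode_forward(model$params, model$geom, x,
                                       keep_cache = FALSE)$code)
  }
  structure(list(voxels = vox, encodings = enc, patient_id = patient_id,
                 encoding_dim = model$encoding_dim),
            class = "voxel_encoding_set")
}

#' @export
print.voxel_encoding_set <- function(x, ...) {
  cat(sprintf("<voxel_encoding_set> %d voxels x %d dims (patient %s)\n",
              nrow(x$encodings), x$encoding_dim, x$patient_id))
  invisible(x)
}

#' Reconstruct a patch through the auto-encoder
#'
#' @param model an `lvm_cae`.
#' @param patch a `q x q` matrix of HU values matching the model's patch size.
#' @return The reconstructed `q x q` HU patch (finite values).
#' @export
reconstruct <- function(model, patch) {
  stopifnot(inherits(model, "lvm_cae"))
  patch <- as.matrix(patch)
  if (!identical(dim(patch), c(model$patch_size, model$patch_size)))
    stop(sprintf("patch shape %s does not match the model's %dx%d input",
                 paste(dim(patch), collapse = "x"),
                 model$patch_size, model$patch_size))
  x <- array(patch / HU_SCALE, c(model$patch_size, model$patch_size, 1L, 1L))
  out <- cae_forward(model$params, model$geom, x, keep_cache = FALSE)$recon
  matrix(out * HU_SCALE, model$patch_size, model$patch_size)
}

#' Save / load an auto-encoder checkpoint
#' @param model an `lvm_cae`.
#' @param path checkpoint file path.
#' @export
save_autoencoder <- function(model, path) {
  stopifnot(inherits(model, "lvm_cae"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "lvm_cae"))
  model
}
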