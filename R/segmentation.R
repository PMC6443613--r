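# Voxelwise LVM segmentation: a two-stream multiscale convolutional network
# over triplanar patches, plus automated segmentation quality control.

HU_SCALE <- 200  # intensities are divided by this before entering a network

seg_default_config <- function() {
  list(epochs = 10L, batch = 64L, lr = 1e-3, seed = 1L,
       samples_per_volume = 1000L, filters = c(8L, 16L), hidden = 32L)
}

# Layer geometry shared by both streams for a given patch edge.
seg_geometry <- function(patch_edge, filters) {
  p <- patch_edge
  map1 <- build_im2col_idx(p, p, 3L, 3L)
  h1 <- map1$oh %/% 2L
  if (h1 - 2L < 2L)
    stop("`patch_edge` too small for two conv + max-pool blocks (need >= 11)")
  map2 <- build_im2col_idx(h1, h1, filters[1], 3L)
  h2 <- map2$oh %/% 2L
  list(map1 = map1, map2 = map2, h1 = h1, h2 = h2,
       flat = h2 * h2 * filters[2])
}

seg_init_params <- function(geom, filters, hidden) {
  par <- list()
  for (s in c("f", "c")) {
    par[[paste0(s, "_conv1")]] <- conv_init(3L, 3L, filters[1])
    par[[paste0(s, "_conv2")]] <- conv_init(3L, filters[1], filters[2])
  }
  par$fc1 <- dense_init(2L * geom$flat, hidden)
  par$fc2 <- dense_init(hidden, 1L)
  par
}

seg_forward <- function(par, geom, xf, xc, keep_cache = TRUE) {
  stream <- function(x, prefix) {
    c1 <- conv_forward(x, par[[paste0(prefix, "_conv1")]], geom$map1)
    a1 <- relu(c1$out)
    p1 <- maxpool_forward(a1)
    c2 <- conv_forward(p1$out, par[[paste0(prefix, "_conv2")]], geom$map2)
    a2 <- relu(c2$out)
    p2 <- maxpool_forward(a2)
    flat <- matrix(p2$out, ncol = dim(x)[4])
    list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2, flat = flat)
  }
  sf <- stream(xf, "f")
  sc <- stream(xc, "c")
  concat <- rbind(sf$flat, sc$flat)
  h_pre <- dense_forward(concat, par$fc1)
  h <- relu(h_pre)
  z <- dense_forward(h, par$fc2)
  prob <- stats::plogis(as.vector(z))
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, sf = sf, sc = sc, concat = concat, h = h, z = z)
}

seg_backward <- function(par, geom, cache, xf, xc, y) {
  N <- length(y)
  grads <- list()
  dz <- matrix((cache$prob - y) / N, nrow = 1)
  g2 <- dense_backward(dz, par$fc2, cache$h)
  grads$fc2 <- g2
  dh <- relu_backward(g2$dx, cache$h)
  g1 <- dense_backward(dh, par$fc1, cache$concat)
  grads$fc1 <- g1
  flat <- geom$flat
  stream_back <- function(scache, dflat, prefix) {
    dp2 <- array(dflat, dim(scache$p2$out))
    da2 <- maxpool_backward(dp2, scache$p2)
    dc2 <- relu_backward(da2, scache$a2)
    gc2 <- conv_backward(dc2, par[[paste0(prefix, "_conv2")]], geom$map2, scache$c2)
    dp1 <- gc2$dx
    da1 <- maxpool_backward(dp1, scache$p1)
    dc1 <- relu_backward(da1, scache$a1)
    gc1 <- conv_backward(dc1, par[[paste0(prefix, "_conv1")]], geom$map1, scache$c1)
    grads[[paste0(prefix, "_conv2")]] <<- gc2
    grads[[paste0(prefix, "_conv1")]] <<- gc1
  }
  stream_back(cache$sf, g1$dx[seq_len(flat), , drop = FALSE], "f")
  stream_back(cache$sc, g1$dx[flat + seq_len(flat), , drop = FALSE], "c")
  grads
}

bce_loss <- function(prob, y, eps = 1e-12) {
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

#' Train the two-stream multiscale triplanar segmentation network
#'
#' Learns to classify single voxels as myocardium or background from six
#' triplanar patches (axial/coronal/sagittal at a fine and a coarse scale).
#' Each scale feeds its own stream of two convolution + max-pooling blocks;
#' the streams are fused by fully connected layers ending in a logistic
#' output. Training samples equal numbers of myocardium and background
#' voxels per volume (masks are a small voxel minority), and is fully
#' deterministic given `config$seed`.
#'
#' @param volumes list of [ct_volume()] training volumes (identical spacing).
#' @param masks list of binary myocardium masks on the same grids.
#' @param spec a [patch_spec()].
#' @param config named list overriding any of: `epochs` (4), `batch` (64),
#'   `lr` (1e-3), `seed` (1), `samples_per_volume` (1000, half myocardium),
#'   `filters` (c(8, 16)), `hidden` (32); an optional `loss_tsv` path writes
#'   the per-epoch loss trace as TSV.
#' @return An object of class `lvm_segmenter` carrying the trained weights,
#'   the patch specification, the training voxel spacing and the per-epoch
#'   loss trace (element 1 is the pre-training loss).
#' @export
train_segmenter <- function(volumes, masks, spec = patch_spec(), config = list()) {
  cfg <- utils::modifyList(seg_default_config(), config)
  stopifnot(length(volumes) >= 1, length(volumes) == length(masks))
  volumes <- lapply(volumes, as_ct_volume)
  if (all(vapply(masks, function(m) sum(m != 0), numeric(1)) == 0))
    stop("all training masks are empty: nothing to learn")
  spacing <- volumes[[1]]$spacing
  geom <- seg_geometry(spec$patch_edge, cfg$filters)

  with_seed(cfg$seed, {
    xs_f <- list(); xs_c <- list(); ys <- list()
    half <- max(1L, cfg$samples_per_volume %/% 2L)
    for (v in seq_along(volumes)) {
      vol <- volumes[[v]]$data
      msk <- masks[[v]]
      pos <- which(msk != 0)
      neg <- which(msk == 0)
      if (length(pos) == 0) next
      sel <- c(pos[sample.int(length(pos), half, replace = length(pos) < half)],
               neg[sample.int(length(neg), half, replace = length(neg) < half)])
      vox <- arrayInd(sel, dim(msk))
      xs_f[[v]] <- extract_patch_batch(vol, vox, spec$patch_edge, spec$scales[1]) / HU_SCALE
      xs_c[[v]] <- extract_patch_batch(vol, vox, spec$patch_edge, spec$scales[2]) / HU_SCALE
      ys[[v]] <- rep(c(1, 0), each = half)
    }
    bind4 <- function(lst) {
      lst <- Filter(Negate(is.null), lst)
      n <- sum(vapply(lst, function(a) dim(a)[4], numeric(1)))
      out <- array(0, c(dim(lst[[1]])[1:3], n))
      at <- 0L
      for (a in lst) {
        k <- dim(a)[4]
        out[, , , at + seq_len(k)] <- a
        at <- at + k
      }
      out
    }
    xf <- bind4(xs_f)
    xc <- bind4(xs_c)
    y <- unlist(ys)
    n <- length(y)

    par <- seg_init_params(geom, cfg$filters, cfg$hidden)
    state <- adam_init(par)
    loss0 <- bce_loss(seg_forward(par, geom, xf, xc, keep_cache = FALSE)$prob, y)
    trace <- loss0
    t <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_losses <- c()
      for (b0 in seq(1L, n, by = cfg$batch)) {
        sel <- ord[b0:min(b0 + cfg$batch - 1L, n)]
        bxf <- xf[, , , sel, drop = FALSE]
        bxc <- xc[, , , sel, drop = FALSE]
        by <- y[sel]
        cache <- seg_forward(par, geom, bxf, bxc)
        ep_losses <- c(ep_losses, bce_loss(cache$prob, by))
        grads <- seg_backward(par, geom, cache, bxf, bxc, by)
        t <- t + 1L
        upd <- adam_step(par, grads, state, cfg$lr, t)
        par <- upd$params
        state <- upd$state
      }
      trace <- c(trace, mean(ep_losses))
    }
    if (!is.null(cfg$loss_tsv))
      utils::write.table(
        data.frame(epoch = seq_along(trace) - 1L, loss = trace),
        cfg$loss_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    structure(list(params = par, geom = geom, patch_spec = spec,
                   spacing = spacing, config = cfg, loss_trace = trace,
                   n_train = n),
              class = "lvm_segmenter")
  })
}

#' @export
print.lvm_segmenter <- function(x, ...) {
  cat(sprintf(
    "<lvm_segmenter> triplanar two-stream CNN, patch %d, scales %s\n",
    x$patch_spec$patch_edge, paste(signif(x$patch_spec$scales, 3), collapse = "/")))
  cat(sprintf("  trained on %d patches, %d epochs, loss %.4f -> %.4f (seed %d)\n",
              x$n_train, x$config$epochs, x$loss_trace[1],
              x$loss_trace[length(x$loss_trace)], x$config$seed))
  invisible(x)
}

#' Segment the left ventricular myocardium of a CT volume
#'
#' Classifies voxels with a trained [train_segmenter()] model. Voxels may be
#' visited on a regular stride, with intervening voxels filled by the nearest
#' classified voxel's label; `stride = 1` classifies every voxel. With
#' `cleanup = TRUE` (default) only the largest 6-connected component of the
#' foreground is kept.
#'
#' @param model an `lvm_segmenter`.
#' @param volume a [ct_volume()] with the training voxel spacing.
#' @param stride positive integer voxel stride.
#' @param cleanup keep only the largest connected component.
#' @param batch voxels classified per forward pass.
#' @return Integer \{0,1\} mask on the input grid.
#' @export
segment_volume <- function(model, volume, stride = 1L, cleanup = TRUE,
                           batch = 2048L) {
  stopifnot(inherits(model, "lvm_segmenter"))
  volume <- as_ct_volume(volume)
  if (max(abs(volume$spacing - model$spacing)) > 1e-6)
    stop(sprintf("voxel spacing (%s) mm differs from the training convention (%s) mm",
                 paste(signif(volume$spacing, 4), collapse = ", "),
                 paste(signif(model$spacing, 4), collapse = ", ")))
  d <- dim(volume$data)
  zi <- seq(1L, d[1], by = stride)
  yi <- seq(1L, d[2], by = stride)
  xi <- seq(1L, d[3], by = stride)
  grid <- as.matrix(expand.grid(z = zi, y = yi, x = xi))
  spec <- model$patch_spec
  probs <- numeric(nrow(grid))
  for (b0 in seq(1L, nrow(grid), by = batch)) {
    sel <- b0:min(b0 + batch - 1L, nrow(grid))
    vox <- grid[sel, , drop = FALSE]
    xf <- extract_patch_batch(volume$data, vox, spec$patch_edge, spec$scales[1]) / HU_SCALE
    xc <- extract_patch_batch(volume$data, vox, spec$patch_edge, spec$scales[2]) / HU_SCALE
    probs[sel] <- seg_forward(model$params, model$geom, xf, xc,
                              keep_cache = FALSE)$prob
  }
  lab <- array(as.integer(probs > 0.5), c(length(zi), length(yi), length(xi)))
  if (stride == 1L) {
    mask <- lab
  } else {
    nearest <- function(n, si) clamp(as.integer(round((seq_len(n) - 1) / stride)) + 1L,
                                     1L, length(si))
    mask <- lab[nearest(d[1], zi), nearest(d[2], yi), nearest(d[3], xi), drop = FALSE]
    dim(mask) <- d
  }
  if (cleanup && sum(mask) > 0) {
    comp <- label_components(mask)
    sizes <- tabulate(comp[comp > 0])
    mask <- array(as.integer(comp == which.max(sizes)), d)
  }
  mask
}

# 6-connected component labelling by vectorized wavefront flood fill.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  fg <- which(mask != 0)
  comp <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    lab[s] <- comp
    frontier <- s
    while (length(frontier)) {
      ci <- arrayInd(frontier, d)
      nbrs <- vector("list", 6)
      j <- 0L
      for (axis in 1:3) for (step in c(-1L, 1L)) {
        j <- j + 1L
        nb <- ci
        nb[, axis] <- nb[, axis] + step
        ok <- nb[, axis] >= 1L & nb[, axis] <= d[axis]
        nbrs[[j]] <- nb[ok, , drop = FALSE]
      }
      nb <- do.call(rbind, nbrs)
      if (nrow(nb) == 0) break
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- unique(lin[mask[lin] != 0 & lab[lin] == 0L])
      lab[lin] <- comp
      frontier <- lin
    }
  }
  lab
}

#' Quality control of an automatic myocardium segmentation
#'
#' Mirrors the study-design exclusion of failed or badly incomplete
#' segmentations with two automated heuristics: the masked volume must fall
#' inside a plausible range, and the largest 6-connected component must hold
#' at least a configured fraction of the masked voxels (fragmented masks
#' indicate failure).
#'
#' @param mask binary mask array.
#' @param spacing voxel spacing `(z, y, x)` in mm.
#' @param min_volume_ml,max_volume_ml plausible masked-volume range (mL).
#' @param min_cc_fraction minimum fraction of masked voxels in the largest
#'   connected component.
#' @return list with `pass` (logical) and `reasons` (character vector
#'   enumerating every failed check; empty when passing).
#' @export
qc_segmentation <- function(mask, spacing = c(1, 1, 1),
                            min_volume_ml = 1, max_volume_ml = 500,
                            min_cc_fraction = 0.8) {
  stopifnot(all(mask %in% c(0, 1)))
  reasons <- character()
  vol_ml <- sum(mask) * prod(spacing) / 1000
  if (vol_ml < min_volume_ml)
    reasons <- c(reasons, sprintf("volume below minimum (%.2f < %.2f mL)",
                                  vol_ml, min_volume_ml))
  if (vol_ml > max_volume_ml)
    reasons <- c(reasons, sprintf("volume above maximum (%.2f > %.2f mL)",
                                  vol_ml, max_volume_ml))
  if (sum(mask) > 0) {
    comp <- label_components(mask)
    sizes <- tabulate(comp[comp > 0])
    frac <- max(sizes) / sum(mask)
    if (frac < min_cc_fraction)
      reasons <- c(reasons, sprintf(
        "largest connected component holds %.2f of masked voxels (< %.2f)",
        frac, min_cc_fraction))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Save / load a trained segmenter checkpoint
#'
#' The checkpoint embeds the patch specification and training metadata so a
#' loaded model enforces the same extraction geometry at inference.
#'
#' @param model an `lvm_segmenter`.
#' @param path checkpoint file path.
#' @return `save_segmenter` returns `path` invisibly; `load_segmenter`
#'   returns the model.
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "lvm_segmenter"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "lvm_segmenter"))
  model
}
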