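# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small all-intermediate cohort spec used by phantom-level tests.
tiny_spec <- function(effect_size = 60, noise_sd = 15, seed = 11,
                      n_patients = 6L) {
  cohort_spec(n_patients = n_patients, prevalence = 0.5,
              category_counts = c(0L, 0L, n_patients %/% 2L,
                                  n_patients - n_patients %/% 2L, 0L),
              effect_size = effect_size, noise_sd = noise_sd, seed = seed)
}

make_phantom <- function(label = TRUE, seed = 101, effect_size = 60,
                         noise_sd = 15) {
  spec <- tiny_spec(effect_size = effect_size, noise_sd = noise_sd)
  generate_phantom_volume(phantom_params(spec, seed = seed), label, spec)
}

# Five phantoms (4 train + 1 held out) and a segmenter trained on the first
# four; shared by segmentation unit tests.
seg_fixture <- function() {
  cached("seg_fixture", {
    spec <- tiny_spec()
    vols <- list(); msks <- list()
    for (i in 1:5) {
      ph <- generate_phantom_volume(phantom_params(spec, seed = 100 + i),
                                    i %% 2 == 0, spec)
      vols[[i]] <- ph$volume
      msks[[i]] <- ph$mask
    }
    model <- train_segmenter(vols[1:4], msks[1:4], patch_spec(11L, c(1, 3)),
                             list(epochs = 4L, samples_per_volume = 400L,
                                  seed = 1L))
    list(volumes = vols, masks = msks, model = model, spec = spec)
  })
}

# A trained auto-encoder over patches of one high-effect phantom.
cae_fixture <- function() {
  cached("cae_fixture", {
    ph <- make_phantom(TRUE, seed = 101)
    idx <- which(ph$mask != 0)
    sel <- lvmtriage:::with_seed(2, sample(idx, 600))
    patches <- lvmtriage:::extract_axial_patches(
      ph$volume$data, arrayInd(sel, dim(ph$mask)), 16L)
    model <- train_autoencoder(patches, 16L, list(epochs = 5L, seed = 1L))
    list(phantom = ph, patches = patches, model = model)
  })
}

# Brute-force triplanar patch oracle: nested loops + scalar reflection and
# bilinear interpolation, independent of the package's vectorized gather.
oracle_reflect <- function(i, n) {
  if (n == 1) return(1)
  period <- 2 * n - 2
  r <- (i - 1) %% period
  if (r >= n) r <- period - r
  r + 1
}

oracle_sample_plane <- function(vol, fixed_axis, fixed_val, row_axis, col_axis,
                                row_c, col_c, offs) {
  p <- length(offs)
  out <- matrix(0, p, p)
  d <- dim(vol)
  at <- function(z, y, x) vol[z, y, x]
  get_vox <- function(rv, cv) {
    co <- c(NA, NA, NA)
    co[fixed_axis] <- fixed_val
    co[row_axis] <- rv
    co[col_axis] <- cv
    vol[co[1], co[2], co[3]]
  }
  for (i in 1:p) for (j in 1:p) {
    rv <- row_c + offs[i]
    cv <- col_c + offs[j]
    r0 <- floor(rv); fr <- rv - r0
    c0 <- floor(cv); fc <- cv - c0
    g <- function(rr, cc) get_vox(oracle_reflect(rr, d[row_axis]),
                                  oracle_reflect(cc, d[col_axis]))
    out[i, j] <- (1 - fr) * (1 - fc) * g(r0, c0) +
      fr * (1 - fc) * g(r0 + 1, c0) +
      (1 - fr) * fc * g(r0, c0 + 1) +
      fr * fc * g(r0 + 1, c0 + 1)
  }
  out
}

oracle_triplanar <- function(vol, voxel, edge, scale) {
  h <- (edge - 1) / 2
  offs <- seq(-h, h) * scale
  list(
    axial = oracle_sample_plane(vol, 1, voxel[1], 2, 3, voxel[2], voxel[3], offs),
    coronal = oracle_sample_plane(vol, 2, voxel[2], 1, 3, voxel[1], voxel[3], offs),
    sagittal = oracle_sample_plane(vol, 3, voxel[3], 1, 2, voxel[1], voxel[2], offs))
}
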