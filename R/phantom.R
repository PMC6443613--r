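#' Specification of a synthetic CT cohort
#'
#' Collects the knobs of the synthetic phantom cohort generator: how many
#' patients, what fraction carry a functionally significant stenosis, the
#' per-category patient counts over the five CCTA stenosis grades, the lesion
#' contrast, and the imaging grid. The defaults reproduce a 126-patient cohort
#' with grade composition 2/8/10/91/15 and 81 positives, the composition the
#' evaluation harness assumes.
#'
#' @param n_patients number of patients.
#' @param prevalence fraction of patients with a functionally significant
#'   stenosis; `prevalence * n_patients` must round cleanly to an integer.
#' @param category_counts optional exact patient counts per stenosis grade
#'   (ordered `G0, G1, G2, G3, G4`); must sum to `n_patients`. `NULL` draws
#'   grades from the default composition proportions.
#' @param effect_size mean HU depression of ischemic myocardial lesions
#'   (non-negative; 0 means positives are radiologically identical to
#'   negatives).
#' @param lesion_fraction fraction of the myocardial shell circumference
#'   affected by the lesion sector, in `[0, 1]`.
#' @param noise_sd Gaussian image noise standard deviation in HU.
#' @param grid_shape volume grid `(z, y, x)` in voxels.
#' @param voxel_spacing voxel spacing `(z, y, x)` in mm.
#' @param ffr_path_prob fraction of positive patients realized through the
#'   FFR pathway (minimum FFR at or below 0.80) rather than through an
#'   angiographic high-grade (at least 90 percent) stenosis.
#' @param prior_event_rate fraction of patients flagged with a prior
#'   myocardial infarction, PCI or CABG.
#' @param seed integer master seed; every random draw in the generator is a
#'   deterministic function of it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 126L,
                        prevalence = 81 / 126,
                        category_counts = c(2L, 8L, 10L, 91L, 15L),
                        effect_size = 25,
                        lesion_fraction = 0.25,
                        noise_sd = 15,
                        grid_shape = c(32L, 32L, 32L),
                        voxel_spacing = c(1, 1, 1),
                        ffr_path_prob = 0.85,
                        prior_event_rate = 23 / 126,
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 0)
    stop("`n_patients` must be a non-negative integer")
  if (prevalence < 0 || prevalence > 1) stop("`prevalence` must lie in [0, 1]")
  n_pos <- prevalence * n_patients
  if (abs(n_pos - round(n_pos)) > 1e-8)
    stop("`prevalence * n_patients` must be an integer count of positives")
  if (!is.null(category_counts)) {
    category_counts <- as.integer(category_counts)
    if (length(category_counts) != 5 || any(category_counts < 0))
      stop("`category_counts` must be five non-negative counts (G0..G4)")
    if (sum(category_counts) != n_patients)
      stop("`category_counts` must sum to `n_patients`")
  }
  if (effect_size < 0) stop("`effect_size` must be non-negative")
  if (lesion_fraction < 0 || lesion_fraction > 1)
    stop("`lesion_fraction` must lie in [0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0))
  voxel_spacing <- as.numeric(voxel_spacing)
  stopifnot(length(voxel_spacing) == 3, all(voxel_spacing > 0))
  if (ffr_path_prob < 0 || ffr_path_prob > 1)
    stop("`ffr_path_prob` must lie in [0, 1]")
  structure(list(
    n_patients = n_patients, prevalence = prevalence,
    category_counts = category_counts, effect_size = effect_size,
    lesion_fraction = lesion_fraction, noise_sd = noise_sd,
    grid_shape = grid_shape, voxel_spacing = voxel_spacing,
    ffr_path_prob = ffr_path_prob, prior_event_rate = prior_event_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d patients, prevalence %.3f, effect size %.1f HU, noise %.1f HU\n",
              x$n_patients, x$prevalence, x$effect_size, x$noise_sd))
  if (!is.null(x$category_counts))
    cat("  grade composition (G0..G4):", paste(x$category_counts, collapse = "/"), "\n")
  cat(sprintf("  grid %s voxels at %s mm, seed %d\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$voxel_spacing, 3), collapse = "x"), x$seed))
  invisible(x)
}

#' Geometry and attenuation parameters of one myocardial shell phantom
#'
#' The phantom is an ellipsoidal shell (the left ventricular myocardium)
#' around a contrast-enhanced blood pool, embedded in a soft-tissue-like
#' background. All randomized quantities (centre jitter, semi-axes, wall
#' thickness, lesion sector placement) are drawn deterministically from
#' `seed`.
#'
#' @param spec a [cohort_spec()]; supplies the grid and spacing.
#' @param seed integer seed for this phantom's geometry.
#' @param center,axes,thickness optional overrides in mm: shell centre
#'   `(z, y, x)`, outer semi-axes `(z, y, x)`, and wall thickness.
#' @param myocardium_hu,bloodpool_hu,background_hu attenuation levels (HU);
#'   the blood pool must be brighter than the myocardium (contrast-enhanced
#'   cavity).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(spec, seed,
                           center = NULL, axes = NULL, thickness = NULL,
                           myocardium_hu = 100, bloodpool_hu = 400,
                           background_hu = -50) {
  extent <- (spec$grid_shape - 1) * spec$voxel_spacing
  geom <- with_seed(seed, {
    ctr <- center %||% (extent / 2 + stats::runif(3, -1.5, 1.5))
    ax <- axes %||% (c(0.36, 0.33, 0.30) * min(extent) * stats::runif(3, 0.92, 1.05))
    th <- thickness %||% stats::runif(1, 2.5, 3.5)
    theta0 <- stats::runif(1, -pi, pi)
    list(center = ctr, axes = ax, thickness = th, lesion_theta0 = theta0)
  })
  if (geom$thickness <= 0) stop("shell thickness must be positive")
  if (bloodpool_hu <= myocardium_hu)
    stop("`bloodpool_hu` must exceed `myocardium_hu` (contrast-enhanced cavity)")
  lo <- geom$center - geom$axes
  hi <- geom$center + geom$axes
  if (any(lo < 0) || any(hi > extent))
    stop(sprintf(
      "phantom shell does not fit in the grid: centre (%s) mm with semi-axes (%s) mm exceeds extent (%s) mm",
      paste(signif(geom$center, 3), collapse = ", "),
      paste(signif(geom$axes, 3), collapse = ", "),
      paste(signif(extent, 3), collapse = ", ")))
  structure(list(
    center = geom$center, axes = geom$axes, thickness = geom$thickness,
    lesion_theta0 = geom$lesion_theta0,
    myocardium_hu = myocardium_hu, bloodpool_hu = bloodpool_hu,
    background_hu = background_hu, seed = as.integer(seed)
  ), class = "phantom_params")
}

# Smooth angular lesion weight: 1 on the sector core, cosine ramp over the
# outer 30% of the half-width, 0 outside. `d` is the absolute angular
# distance from the sector centre.
lesion_taper <- function(d, half_width) {
  if (half_width <= 0) return(rep(0, length(d)))
  core <- 0.7 * half_width
  w <- numeric(length(d))
  w[d <= core] <- 1
  ramp <- d > core & d < half_width
  w[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - core) / (half_width - core)))
  w
}

#' Generate one synthetic myocardial phantom volume
#'
#' Voxelizes an ellipsoidal myocardial shell around a bright blood pool. When
#' `label` is `TRUE` a contiguous angular sector of the shell is depressed by
#' `spec$effect_size` HU (cosine-tapered edges, full depression on the sector
#' core), emulating hypo-attenuation associated with a functionally
#' significant stenosis. Gaussian noise of sd `spec$noise_sd` is added
#' everywhere. Identical parameters and seed give bit-identical output.
#'
#' @param params a [phantom_params()].
#' @param label logical; `TRUE` inserts the hypo-attenuating lesion sector.
#' @param spec a [cohort_spec()] (grid, spacing, effect size, noise).
#' @return A list with `volume` (a [ct_volume()]) and `mask` (integer
#'   \{0,1\} array; exactly the voxelized shell).
#' @export
generate_phantom_volume <- function(params, label, spec) {
  stopifnot(inherits(params, "phantom_params"), inherits(spec, "cohort_spec"))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  zc <- ((seq_len(d[1]) - 1) * sp[1] - params$center[1]) / params$axes[1]
  ycy <- (seq_len(d[2]) - 1) * sp[2] - params$center[2]
  xcx <- (seq_len(d[3]) - 1) * sp[3] - params$center[3]
  yc <- ycy / params$axes[2]
  xc <- xcx / params$axes[3]
  # squared ellipsoidal radius on the full grid, outer and inner surfaces
  q_outer <- outer(outer(zc^2, yc^2, "+"), xc^2, "+")
  inner_axes <- pmax(params$axes - params$thickness, 0.1)
  q_inner <- outer(outer((zc * params$axes[1] / inner_axes[1])^2,
                         (yc * params$axes[2] / inner_axes[2])^2, "+"),
                   (xc * params$axes[3] / inner_axes[3])^2, "+")
  shell <- q_outer <= 1 & q_inner > 1
  cavity <- q_inner <= 1
  vol <- array(params$background_hu, d)
  vol[cavity] <- params$bloodpool_hu
  vol[shell] <- params$myocardium_hu
  if (isTRUE(label) && spec$effect_size > 0 && spec$lesion_fraction > 0) {
    # azimuth in the axial (y, x) plane, identical on every slice
    th_plane <- atan2(matrix(rep(ycy, times = d[3]), d[2], d[3]),
                      matrix(rep(xcx, each = d[2]), d[2], d[3]))
    half <- spec$lesion_fraction * pi
    ctr_angle <- params$lesion_theta0
    dd <- abs(atan2(sin(th_plane - ctr_angle), cos(th_plane - ctr_angle)))
    w_plane <- lesion_taper(dd, half)
    w3 <- array(rep(w_plane, each = d[1]), d)
    depress <- spec$effect_size * w3
    vol[shell] <- vol[shell] - depress[shell]
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(derive_seed(params$seed, 7L),
                       array(stats::rnorm(prod(d), 0, spec$noise_sd), d))
    vol <- vol + noise
  }
  list(volume = ct_volume(vol, sp), mask = array(as.integer(shell), d))
}

# Analytic volume of the ellipsoidal shell (mm^3), for construction checks.
shell_volume_mm3 <- function(params) {
  inner <- pmax(params$axes - params$thickness, 0.1)
  4 / 3 * pi * (prod(params$axes) - prod(inner))
}
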