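test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(n_patients = 10, prevalence = 0.5,
                           category_counts = c(1, 1, 1, 1, 1)),
               "sum to")
  expect_error(cohort_spec(n_patients = 10, prevalence = 0.55,
                           category_counts = NULL),
               "integer count")
  expect_error(cohort_spec(effect_size = -1), "non-negative")
  expect_error(phantom_params(tiny_spec(), seed = 1,
                              center = c(2, 2, 2), axes = c(12, 12, 12)),
               "does not fit")
  expect_error(phantom_params(tiny_spec(), seed = 1, myocardium_hu = 500),
               "contrast-enhanced")
})

test_that("zero effect size makes positive and negative phantoms identical", {
  spec <- tiny_spec(effect_size = 0)
  pp <- phantom_params(spec, seed = 42)
  a <- generate_phantom_volume(pp, TRUE, spec)
  b <- generate_phantom_volume(pp, FALSE, spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask, b$mask)
})

test_that("noiseless construction puts the myocardium exactly at its HU level", {
  spec <- tiny_spec(noise_sd = 0)
  pp <- phantom_params(spec, seed = 7)
  ph <- generate_phantom_volume(pp, TRUE, spec)
  # outside the lesion sector (weight 0) masked voxels are exactly 100 HU
  vals <- ph$volume$data[ph$mask != 0]
  expect_true(any(vals == pp$myocardium_hu))
  expect_equal(max(vals), pp$myocardium_hu)
  # plateau of the lesion is depressed by exactly effect_size
  expect_equal(min(vals), pp$myocardium_hu - spec$effect_size)
  neg <- generate_phantom_volume(pp, FALSE, spec)
  expect_equal(mean(neg$volume$data[neg$mask != 0]), pp$myocardium_hu)
})

test_that("voxelized shell volume matches the analytic ellipsoid shell", {
  for (seed in c(3, 17, 91)) {
    spec <- tiny_spec()
    pp <- phantom_params(spec, seed = seed)
    ph <- generate_phantom_volume(pp, FALSE, spec)
    vox_volume <- sum(ph$mask) * prod(spec$voxel_spacing)
    expect_lt(abs(vox_volume - lvmtriage:::shell_volume_mm3(pp)) /
                lvmtriage:::shell_volume_mm3(pp), 0.10)
  }
})

test_that("phantom generation is bit-identical under a fixed seed", {
  spec <- tiny_spec()
  pp <- phantom_params(spec, seed = 5)
  a <- generate_phantom_volume(pp, TRUE, spec)
  b <- generate_phantom_volume(pp, TRUE, spec)
  expect_identical(a$volume$data, b$volume$data)
})

test_that("mean masked HU decreases strictly with effect size", {
  means <- vapply(c(0, 20, 40, 60), function(eff) {
    spec <- tiny_spec(effect_size = eff)
    pp <- phantom_params(spec, seed = 9)
    ph <- generate_phantom_volume(pp, TRUE, spec)
    mean(ph$volume$data[ph$mask != 0])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("assign_physiology realizes the reference rule for both labels", {
  neg <- assign_physiology(FALSE, c("G2", "G3"), seed = 4)
  expect_true(all(neg$ffr > 0.80, na.rm = TRUE))
  expect_true(all(neg$ica_ds < 90))
  # majority (FFR) pathway: min FFR at or below the inclusive 0.80 boundary
  pos <- assign_physiology(TRUE, c("G3"), seed = 8, ffr_path_prob = 1)
  expect_lte(min(pos$ffr, na.rm = TRUE), 0.80)
  # minority pathway: angiographic high-grade stenosis, FFR all above 0.80
  pos2 <- assign_physiology(TRUE, c("G3", "G4"), seed = 8, ffr_path_prob = 0)
  expect_gte(max(pos2$ica_ds), 90)
  expect_true(all(pos2$ffr > 0.80, na.rm = TRUE))
  expect_error(assign_physiology(TRUE, character(0), seed = 1), "vessel")
})

test_that("the FFR-pathway fraction matches its configured probability", {
  hits <- vapply(1:1000, function(s) {
    phys <- assign_physiology(TRUE, c("G3", "G3"), seed = s, ffr_path_prob = 0.85)
    any(phys$ffr <= 0.80, na.rm = TRUE)
  }, logical(1))
  # binomial 99% bounds around 0.85 at n = 1000
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.85) / 1000
  expect_gte(mean(hits), bounds[1])
  expect_lte(mean(hits), bounds[2])
})

test_that("generate_cohort honours composition, labels and reproducibility", {
  expect_length(generate_cohort(cohort_spec(n_patients = 0, category_counts = NULL),
                                volumes = FALSE)$records, 0)

  spec <- cohort_spec(n_patients = 126, prevalence = 81 / 126,
                      category_counts = c(2L, 8L, 10L, 91L, 15L),
                      effect_size = 30, seed = 77)
  co <- generate_cohort(spec, volumes = FALSE)
  expect_length(co$records, 126)
  cats <- vapply(co$records, `[[`, character(1), "category")
  expect_equal(as.integer(table(factor(cats, levels = grade_levels))),
               c(2L, 8L, 10L, 91L, 15L))
  labs <- vapply(co$records, `[[`, logical(1), "true_label")
  expect_equal(sum(labs), 81L)
  # no positives below 25% stenosis
  expect_false(any(labs[cats %in% c("G0", "G1")]))
  # label recoverability: the reference rule reproduces every stored label
  expect_equal(vapply(co$records, reference_label, logical(1)), labs)
  # every record carries at least one physiology value
  expect_true(all(vapply(co$records, function(r)
    any(!is.na(r$ffr_values)) || any(!is.na(r$ica_ds_percent)), logical(1))))
  # the patient's maximum diagnostic grade equals the assigned category
  expect_equal(vapply(co$records, function(r)
    patient_max_grade(r$vessel_grades), character(1)), cats)
})

test_that("the written cohort table is byte-identical across identical runs", {
  spec <- cohort_spec(n_patients = 12, prevalence = 0.5,
                      category_counts = c(0L, 2L, 2L, 6L, 2L), seed = 19)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(spec, dir = d1, volumes = FALSE)
  generate_cohort(spec, dir = d2, volumes = FALSE)
  expect_identical(readBin(file.path(d1, "cohort.csv"), "raw", 1e6),
                   readBin(file.path(d2, "cohort.csv"), "raw", 1e6))
})
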