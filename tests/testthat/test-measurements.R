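zone_grid <- function(lab, spacing = c(1, 1, 1)) {
  voxel_grid(lab, spacing, kind = "label", label_set = 0:2)
}

test_that("the whole prostate is the union of PZ and CG", {
  lab <- array(0L, c(10, 10, 4))
  expect_equal(sum(whole_prostate_mask(zone_grid(lab))$data), 0)
  lab[2:4, 2:4, 1] <- 1L
  lab[6:8, 6:8, 2] <- 2L
  wp <- whole_prostate_mask(zone_grid(lab))
  expect_equal(sum(wp$data), sum(lab == 1L) + sum(lab == 2L))
  ph <- tiny_phantom()
  expect_identical(whole_prostate_mask(ph$zones_gt)$data > 0,
                   ph$zones_gt$data > 0)
})

test_that("lengths use the voxel-footprint convention", {
  one <- array(0L, c(5, 5, 3)); one[3, 3, 2] <- 1L
  l1 <- prostate_lengths(voxel_grid(one, c(0.5, 0.5, 3), kind = "label",
                                    label_set = 0:1))
  expect_equal(unname(l1), c(0.05, 0.05, 0.30))
  box <- array(0L, c(50, 40, 12)); box[1:40, 1:30, 1:10] <- 1L
  l2 <- prostate_lengths(voxel_grid(box, c(1, 1, 1), kind = "label",
                                    label_set = 0:1))
  expect_equal(unname(l2), c(4.0, 3.0, 1.0))
  expect_error(prostate_lengths(voxel_grid(array(0L, c(3, 3, 3)),
                                           kind = "label",
                                           label_set = 0:1)), "empty")
})

test_that("phantom lengths approach the analytic diameters", {
  spec <- phantom_spec(grid_shape = c(96L, 76L, 116L),
                       spacing = c(0.5, 0.5, 0.5),
                       wp_semi_axes = c(20, 15, 25),
                       cg_semi_axes = c(12, 9, 15), lesions = list())
  ph <- generate_phantom(spec)
  lens <- prostate_lengths(whole_prostate_mask(ph$zones_gt))
  expect_lt(abs(lens[1] - 4.0), 0.1)
  expect_lt(abs(lens[2] - 3.0), 0.1)
  expect_lt(abs(lens[3] - 5.0), 0.1)
})

test_that("mask volume is voxel count times voxel volume", {
  cube <- array(0L, c(12, 12, 12)); cube[1:10, 1:10, 1:10] <- 1L
  g <- voxel_grid(cube, c(1, 1, 1), kind = "label", label_set = 0:1)
  expect_equal(mask_volume(g), 1.0)
  expect_equal(mask_volume(voxel_grid(array(0L, c(3, 3, 3)),
                                      kind = "label", label_set = 0:1)), 0)
  ph <- generate_phantom(phantom_spec(
    grid_shape = c(96L, 76L, 116L), spacing = c(0.5, 0.5, 0.5),
    wp_semi_axes = c(20, 15, 25), cg_semi_axes = c(12, 9, 15),
    lesions = list()))
  wp_vol <- mask_volume(whole_prostate_mask(ph$zones_gt))
  expect_lt(abs(wp_vol - 31.4159) / 31.4159, 0.02)
})

test_that("PSA density is PSA over volume with unit checks", {
  expect_equal(psa_density(10, 50), 0.2)
  expect_equal(psa_density(0, 31.4), 0)
  expect_error(psa_density(10, 0), "> 0")
  # a typical mid-size prostate: PSA 10.53 over ~31.4 cm^3
  expect_equal(psa_density(10.53, 31.4159), 0.3352, tolerance = 1e-3)
})

test_that("zonal volumes are additive: WP = PZ + CG", {
  ph <- tiny_phantom()
  m <- prostate_measurements(ph$zones_gt, psa = 10)
  expect_equal(m$wp_volume_cm3, m$pz_volume_cm3 + m$cg_volume_cm3)
  expect_equal(m$psa_density, 10 / m$wp_volume_cm3)
})

test_that("the thirds rule assigns base, midgland and apex by physical z", {
  lab <- array(0L, c(8, 8, 36))
  lab[3:6, 3:6, 3:32] <- 1L  # WP spans slices 3..32 (30 slices)
  wp <- voxel_grid(lab, c(1, 1, 1), kind = "label", label_set = 0:2)
  # caudal third: slices 3..12.99 -> apex (z increases cranially)
  expect_equal(centroid_region(6, wp), "apex")
  expect_equal(centroid_region(18, wp), "midgland")
  expect_equal(centroid_region(30, wp), "base")
  # boundaries go to the midgland
  expect_equal(centroid_region(3 + 29 / 3, wp), "midgland")
  expect_error(centroid_region(35, wp), "outside")
})

test_that("thirds are split by physical length under anisotropic spacing", {
  lab <- array(0L, c(6, 6, 12))
  lab[2:5, 2:5, 2:11] <- 1L
  wp <- voxel_grid(lab, c(1, 1, 3.6), kind = "label", label_set = 0:2)
  expect_equal(centroid_region(3, wp), "apex")
  expect_equal(centroid_region(6.5, wp), "midgland")
  expect_equal(centroid_region(10, wp), "base")
})

test_that("lesion characterization derives zone, region, ADC and flags", {
  ph <- generate_phantom(phantom_spec(
    grid_shape = c(48L, 48L, 20L), spacing = c(1, 1, 2.4),
    wp_semi_axes = c(18, 14, 18), cg_semi_axes = c(11, 8, 11),
    lesions = list(list(center = c(0, 0, 0), semi_axes = c(4, 4, 4),
                        adc = 0.8e-3, is_cspca = TRUE)),
    psa = 10, seed = 3))
  zones <- ph$zones_gt
  wp <- whole_prostate_mask(zones)
  comp <- list(mask = ph$lesions_gt[[1]]$mask, score = 0.9)
  l <- characterize_lesion(comp, zones, wp, ph$adc_gt)
  expect_equal(l$centroid_zone, "CG")       # centred lesion sits in the CG
  expect_equal(l$centroid_region, "midgland")
  expect_equal(l$min_adc, 8.0e-4)
  expect_false(l$extracapsular)
  expect_equal(l$probability, 0.9)
  # analytic lesion volume ~ (4/3) pi 4^3 = 268 mm^3
  expect_lt(abs(l$volume_cm3 - 0.268) / 0.268, 0.15)

  # a lesion protruding beyond the prostate flags extracapsular
  out_mask <- ph$lesions_gt[[1]]$mask
  od <- out_mask$data
  od[1, 1, 1] <- 1L  # a voxel far outside the WP
  l2 <- characterize_lesion(list(mask = with_data(out_mask, od),
                                 score = 0.5), zones, wp, ph$adc_gt)
  expect_true(l2$extracapsular)
  expect_error(characterize_lesion(
    list(mask = with_data(out_mask, od * 0L), score = 0.5),
    zones, wp, ph$adc_gt), "empty")
})

test_that("lesions are ranked by descending probability with stable ties", {
  mk <- function(p, id) structure(list(probability = p, id = id),
                                  class = "lesion_candidate")
  ranked <- rank_lesions(list(mk(0.46, "a"), mk(0.95, "b"), mk(0.07, "c")))
  expect_equal(vapply(ranked, `[[`, numeric(1), "probability"),
               c(0.95, 0.46, 0.07))
  expect_length(rank_lesions(list(mk(0.5, "only"))), 1)
  tied <- rank_lesions(list(mk(0.5, "first"), mk(0.5, "second")))
  expect_equal(vapply(tied, `[[`, character(1), "id"),
               c("first", "second"))
})
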