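test_that("intensity weight maps [t_min, t_min + 4 sigma] onto [0.25, 1]", {
  expect_equal(intensity_weight(500, t_min = 500, hu_sd = 150), 0.25)
  expect_equal(intensity_weight(500 + 4 * 150, t_min = 500, hu_sd = 150), 1)
  expect_equal(intensity_weight(800, t_min = 500, hu_sd = 150), 0.625)
  expect_equal(intensity_weight(5000, t_min = 500, hu_sd = 150), 1) # clamped
  expect_equal(intensity_weight(100, t_min = 500, hu_sd = 150), 0.25) # clamped low
  # degenerate scale: sigma = 0 gives full weight at/above threshold
  expect_equal(intensity_weight(500, t_min = 500, hu_sd = 0), 1)
  expect_equal(intensity_weight(400, t_min = 500, hu_sd = 0), 0.25)
  # quartile stepping rounds up to the next quarter
  expect_equal(intensity_weight(c(500, 650, 800, 1100), 500, 150, steps = "quartile"),
               c(0.25, 0.5, 0.75, 1))
})

test_that("intensity weight is invariant under affine HU rescaling", {
  set.seed(3)
  hu <- runif(200, 300, 1500)
  w0 <- intensity_weight(hu, t_min = 480, hu_sd = 120)
  for (a in c(0.5, 2, 10)) {
    for (b in c(-100, 0, 250)) {
      w1 <- intensity_weight(a * hu + b, t_min = a * 480 + b, hu_sd = a * 120)
      expect_equal(w1, w0, tolerance = 1e-8)
    }
  }
  expect_true(all(w0 >= 0.25 & w0 <= 1))
})

test_that("region assignment follows ring edges, cusp midlines and clamping", {
  ph <- small_phantom(seed = 1, deposits = tibble::tibble(
    rho = c(0.1, 0.5, 0.9), phi = c(300, 300, 300), zeta = 0.2,
    radius_mm = 1.5, hu = 900, hu_sd = 10
  ))
  # sectors: [0,120) LCC, [120,240) RCC, [240,360) NCC; phi = 300 is the NCC midline
  seg <- segment_calcium(ph$volume, ph$roi_mask, 600)
  lab <- assign_regions(seg, ph$frame, region_config())
  inside <- lab[!is.na(lab$region), ]
  expect_true(all(inside$cusp[inside$phi >= 240] == "NCC"))
  # the voxel nearest each deposit centre lies in rings 1, 2, 3 respectively
  pts <- voxel_coords(ph$volume, as.matrix(inside[, c("i", "j", "k")]))
  for (dd in 1:3) {
    ctr <- from_cylindrical(c(0.1, 0.5, 0.9)[dd], 300, 0.2, ph$frame)
    nearest <- which.min(rowSums(sweep(pts, 2, as.numeric(ctr))^2))
    expect_equal(inside$ring[nearest], dd)
    expect_equal(inside$cusp[nearest], "NCC")
  }
  # rho beyond the outer edge clamps into ring 3
  far <- to_cylindrical(from_cylindrical(1.5, 10, 0.1, ph$frame), ph$frame)
  expect_equal(min(findInterval(far$rho, c(1 / 3, 2 / 3, 1)) + 1L, 3L), 3L)
})

test_that("every in-window voxel gets exactly one region; conservation holds", {
  for (seed in c(4, 8)) {
    ph <- small_phantom(seed = seed, deposits = random_deposits(4, seed + 100))
    seg <- segment_calcium(ph$volume, ph$roi_mask, 600)
    cfg <- region_config()
    lab <- assign_regions(seg, ph$frame, cfg)
    expect_equal(nrow(lab), seg$n_voxels)
    expect_true(all(!is.na(lab$region) |
                      lab$zeta < cfg$zeta_lower | lab$zeta > cfg$zeta_upper))
    tbl <- regional_table(seg, lab, cfg)
    expect_equal(sum(tbl$volume_mm3) + attr(tbl, "excluded_volume_mm3"),
                 calcific_volume(seg), tolerance = 1e-9)
  }
})

test_that("regional table aggregates volume and mean HU per region", {
  ph <- small_phantom(seed = 2, deposits = tibble::tibble(
    rho = 0.5, phi = 300, zeta = 0.25, radius_mm = 2, hu = 900, hu_sd = 0
  ))
  seg <- segment_calcium(ph$volume, ph$roi_mask, 600)
  lab <- assign_regions(seg, ph$frame)
  tbl <- regional_table(seg, lab)
  expect_equal(nrow(tbl), 18L)
  expect_equal(tbl$region, paste0("R", 1:18))
  occupied <- tbl[tbl$n_voxels > 0, ]
  expect_true(all(occupied$cusp == "NCC"))
  expect_equal(sum(occupied$volume_mm3), calcific_volume(seg), tolerance = 1e-9)
  expect_true(all(abs(occupied$mean_hu - 900) < 1e-9)) # hu_sd = 0 deposit
  # empty regions carry volume 0, weight 0.25, mean_hu = t_min
  empty_rows <- tbl[tbl$n_voxels == 0, ]
  expect_true(all(empty_rows$weight == 0.25))
  expect_true(all(empty_rows$mean_hu == seg$t_min))
  expect_equal(tbl$weighted_volume_mm3, tbl$volume_mm3 * tbl$weight)
})

test_that("regional mean HU matches hand-computed means on crafted voxels", {
  # craft a segmentation-like object directly
  d <- c(3, 1, 1)
  vol <- voxel_volume(array(c(500, 700, 900), d))
  seg <- segment_calcium(vol, array(TRUE, d), 400, 0)
  fr <- aortic_frame(
    c(1, -5, 0), c(1, -5, 10),
    list(NCC_LCC = c(11, -5, 0), LCC_RCC = c(-4, 3.66, 0), RCC_NCC = c(-4, -13.66, 0)),
    annular_area = pi * 100
  )
  lab <- assign_regions(seg, fr, region_config())
  tbl <- regional_table(seg, lab, region_config())
  by_region <- split(lab$hu[!is.na(lab$region)], lab$region[!is.na(lab$region)])
  for (rg in names(by_region)) {
    expect_equal(tbl$mean_hu[tbl$region == rg], mean(by_region[[rg]]))
  }
})

test_that("cusp scores sum six weighted regions and respect weight bounds", {
  ph <- small_phantom(seed = 6, deposits = random_deposits(3, 61))
  seg <- segment_calcium(ph$volume, ph$roi_mask, 600)
  tbl <- regional_table(seg, assign_regions(seg, ph$frame))
  sc <- cusp_scores(tbl)
  expect_named(sc, c("NCC", "RCC", "LCC"))
  unweighted <- tapply(tbl$volume_mm3, tbl$cusp, sum)
  for (cu in c("NCC", "RCC", "LCC")) {
    expect_lte(sc[[cu]], unweighted[[cu]] + 1e-12)
    expect_gte(sc[[cu]], 0.25 * unweighted[[cu]] - 1e-12)
  }
  # identity weighting: force weights to 1 and recover raw cusp volume
  tbl2 <- tbl
  tbl2$weight <- 1
  tbl2$weighted_volume_mm3 <- tbl2$volume_mm3
  sc2 <- cusp_scores(tbl2)
  expect_equal(unname(unlist(sc2)), as.numeric(unweighted[c("NCC", "RCC", "LCC")]))
  # hand example: volumes 10 and 20 with weights 0.25 and 1 -> 22.5
  tbl3 <- tbl2
  tbl3$volume_mm3[] <- 0
  tbl3$weighted_volume_mm3[] <- 0
  tbl3$volume_mm3[tbl3$region == "R1"] <- 10
  tbl3$weight[tbl3$region == "R1"] <- 0.25
  tbl3$volume_mm3[tbl3$region == "R2"] <- 20
  tbl3$weight[tbl3$region == "R2"] <- 1
  tbl3$weighted_volume_mm3 <- tbl3$volume_mm3 * tbl3$weight
  expect_equal(cusp_scores(tbl3)$NCC, 22.5)
  expect_error(cusp_scores(tbl[1:10, ]), "incomplete")
})

test_that("empty segmentation yields an all-zero table and zero scores", {
  d <- c(4, 4, 4)
  seg <- segment_calcium(voxel_volume(array(0, d)), array(TRUE, d), 500)
  fr <- small_phantom(seed = 1, deposits = tibble::tibble(
    rho = numeric(), phi = numeric(), zeta = numeric(), radius_mm = numeric()
  ))$frame
  tbl <- regional_table(seg, assign_regions(seg, fr))
  expect_equal(sum(tbl$volume_mm3), 0)
  sc <- cusp_scores(tbl)
  expect_equal(unname(unlist(sc)), c(0, 0, 0))
})

test_that("bullseye CSV round-trips volumes bit-exactly in R1..R18 order", {
  ph <- small_phantom(seed = 12)
  seg <- segment_calcium(ph$volume, ph$roi_mask, 600)
  tbl <- regional_table(seg, assign_regions(seg, ph$frame))
  path <- withr::local_tempfile(fileext = ".csv")
  bullseye_export(tbl, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 18L)
  expect_equal(back$region, paste0("R", 1:18))
  expect_identical(back$volume_mm3, tbl$volume_mm3)
  expect_identical(back$weighted_volume_mm3, tbl$weighted_volume_mm3)
})

test_that("raising a deposit's HU never lowers its cusp score", {
  base <- tibble::tibble(rho = 0.5, phi = 300, zeta = 0.25, radius_mm = 2.5,
                         hu = 700, hu_sd = 40)
  scores <- vapply(c(700, 800, 900, 1100), function(hu) {
    dep <- base
    dep$hu <- hu
    ph <- small_phantom(seed = 42, deposits = dep)
    seg <- segment_calcium(ph$volume, ph$roi_mask, 600)
    cusp_scores(regional_table(seg, assign_regions(seg, ph$frame)))$NCC
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("bullseye autoplot builds a polar ggplot", {
  ph <- small_phantom(seed = 12)
  seg <- segment_calcium(ph$volume, ph$roi_mask, 600)
  tbl <- regional_table(seg, assign_regions(seg, ph$frame))
  p <- autoplot(tbl)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_bullseye(tbl, fill = "mean_hu"), "ggplot")
})
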