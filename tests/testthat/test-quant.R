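# Threshold-based muscle quantification against a voxel-by-voxel oracle and
# its analytic invariants.

test_that("quantification agrees exactly with the naive voxel oracle", {
  withr::with_seed(101, {
    for (i in 1:200) {
      gr <- random_grid()
      thr <- sample(c(100, 200, 350), 1)
      expected <- naive_quant(gr$intens, gr$labels, gr$spacing, thr)
      expect_equal(compute_csa_total(gr$masks, gr$map), expected$csa_total,
                   tolerance = 1e-12)
      expect_equal(compute_csa_fatfree(gr$masks, gr$map, threshold = thr),
                   expected$csa_fatfree, tolerance = 1e-12)
      expect_equal(compute_pdff_muscle(gr$masks, gr$map),
                   expected$pdff_muscle, tolerance = 1e-12)
    }
  })
})

test_that("total CSA is voxel count times pixel area, empty masks warn", {
  labels <- matrix(0L, 40, 40)
  labels[3:27, 1:40] <- 1L  # 25 x 40 = 1000 voxels
  map <- pdff_map(matrix(100, 40, 40), pixel_spacing = 1.5)
  masks <- compartment_masks(labels, check_connected = FALSE)
  expect_equal(compute_csa_total(masks, map), 1000 * 2.25)
  empty <- compartment_masks(matrix(0L, 40, 40))
  expect_warning(v <- compute_csa_total(empty, map), "empty")
  expect_equal(v, 0)
})

test_that("fat-free CSA follows the threshold formula", {
  labels <- matrix(0L, 10, 10)
  labels[1:10, 1:10] <- 1L
  # everything below threshold
  map_low <- pdff_map(matrix(100, 10, 10), pixel_spacing = 2)
  masks <- compartment_masks(labels)
  expect_equal(compute_csa_fatfree(masks, map_low),
               compute_csa_total(masks, map_low))
  # half at 150, half at 500 -> half the total
  intens <- matrix(rep(c(150, 500), each = 50), 10, 10)
  map_half <- pdff_map(intens, pixel_spacing = 2)
  expect_equal(compute_csa_fatfree(masks, map_half),
               0.5 * compute_csa_total(masks, map_half))
  # threshold contract
  expect_error(compute_csa_fatfree(masks, map_low, threshold = 0))
  expect_error(compute_csa_fatfree(masks, map_low, threshold = 1500))
})

test_that("the threshold intensity corresponds to 20% fat", {
  expect_identical(intensity_to_fat_fraction(200), 20)
  expect_identical(fat_fraction_to_intensity(20), 200)
})

test_that("index and ratio formulas", {
  expect_equal(compute_ammi(8670, 1.7), 3000, tolerance = 1e-12)
  expect_equal(compute_ammi(0, 1.9), 0)
  expect_equal(compute_ammi(12000, 2), 3000)
  expect_equal(compute_ammi(1234.5, 1), 1234.5)
  expect_error(compute_ammi(100, 0))
  expect_equal(compute_ratio(5, 5), 100)
  expect_equal(compute_ratio(0, 3), 0)
  # direct division of the printed cohort-mean indices (a mean-of-ratios at
  # cohort level is a different quantity)
  expect_equal(compute_ratio(1709.5, 2954.6), 100 * 1709.5 / 2954.6,
               tolerance = 1e-12)
  expect_error(compute_ratio(1, 0), class = "musclemap_undefined")
  expect_error(compute_ratio(4, 3))
})

test_that("mean muscle PDFF scale anchors", {
  labels <- matrix(1L, 6, 6)
  masks <- compartment_masks(labels)
  expect_equal(compute_pdff_muscle(masks, pdff_map(matrix(115, 6, 6))), 11.5)
  expect_equal(compute_pdff_muscle(masks, pdff_map(matrix(0, 6, 6))), 0)
  half <- matrix(rep(c(0, 1000), each = 18), 6, 6)
  expect_equal(compute_pdff_muscle(masks, pdff_map(half)), 50)
  empty <- compartment_masks(matrix(0L, 6, 6))
  expect_error(compute_pdff_muscle(empty, pdff_map(matrix(0, 6, 6))),
               class = "musclemap_undefined")
})

test_that("raising the threshold never decreases fat-free CSA", {
  withr::with_seed(102, {
    gr <- random_grid()
    prev <- -Inf
    for (thr in seq(50, 1000, by = 50)) {
      cur <- compute_csa_fatfree(gr$masks, gr$map, threshold = thr)
      expect_gte(cur, prev)
      prev <- cur
    }
    expect_equal(compute_csa_fatfree(gr$masks, gr$map, threshold = 1000),
                 compute_csa_total(gr$masks, gr$map))
  })
})

test_that("doubling pixel spacing quadruples CSAs, leaves ratio and PDFF alone", {
  withr::with_seed(103, {
    gr <- random_grid()
    map2 <- pdff_map(gr$intens, pixel_spacing = 2 * gr$spacing)
    m1 <- quantify_subject(gr$map, gr$masks, height = 1.7)
    m2 <- quantify_subject(map2, gr$masks, height = 1.7)
    expect_equal(m2$csa_total, 4 * m1$csa_total)
    expect_equal(m2$csa_fatfree, 4 * m1$csa_fatfree)
    expect_equal(m2$ratio, m1$ratio)
    expect_equal(m2$pdff_muscle, m1$pdff_muscle)
  })
})

test_that("compartment relabelling leaves aggregate measures unchanged", {
  withr::with_seed(104, {
    gr <- random_grid()
    perm <- sample(1:8)
    relab <- gr$labels
    relab[gr$labels > 0L] <- perm[gr$labels[gr$labels > 0L]]
    masks2 <- compartment_masks(relab, check_connected = FALSE)
    m1 <- quantify_subject(gr$map, gr$masks, height = 1.6)
    m2 <- quantify_subject(gr$map, masks2, height = 1.6)
    expect_equal(m1[, c("csa_total", "csa_fatfree", "ratio", "pdff_muscle")],
                 m2[, c("csa_total", "csa_fatfree", "ratio", "pdff_muscle")])
  })
})

test_that("quantify_subject populates consistent measures", {
  withr::with_seed(105, {
    gr <- random_grid()
    m <- quantify_subject(gr$map, gr$masks, height = 1.75, id = "X1")
    expect_true(m$csa_fatfree >= 0 && m$csa_fatfree <= m$csa_total)
    expect_equal(m$ratio, 100 * m$ammi_fatfree / m$ammi_total)
    expect_true(m$pdff_muscle >= 0 && m$pdff_muscle <= 100)
    expect_equal(m$compartments[[1]]$n_voxels |> sum(),
                 sum(gr$labels > 0))
    # empty masks name the subject
    empty <- compartment_masks(matrix(0L, nrow(gr$labels), ncol(gr$labels)))
    expect_error(quantify_subject(gr$map, empty, height = 1.75, id = "X1"),
                 "X1")
  })
})

test_that("grid mismatch and out-of-range intensities are contract events", {
  map <- pdff_map(matrix(10, 5, 5))
  masks <- compartment_masks(matrix(1L, 6, 6))
  expect_error(compute_csa_total(masks, map), class = "musclemap_contract")
  expect_warning(m <- pdff_map(matrix(c(-5, 1200, 10, 10), 2, 2)), "clamped")
  expect_equal(m$clamped, 2)
  expect_equal(range(m$intensities), c(0, 1000))
})
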