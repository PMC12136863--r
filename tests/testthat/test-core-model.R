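test_that("relative composition divides each tissue by the total mass", {
  rc <- relative_composition(tissue_masses(300, 650, 50))
  expect_equal(unname(rc), c(0.30, 0.65, 0.05))
  expect_named(rc, c("adipose", "muscle", "bone"))

  # scale invariance: grams vs hectograms give the same composition
  rc_small <- relative_composition(tissue_masses(3, 6.5, 0.5))
  expect_equal(rc, rc_small)

  expect_error(relative_composition(tissue_masses(0, 0, 0)), "zero total mass")
  expect_error(relative_composition(tissue_masses(0, 0, 0), region = "thigh"),
               "thigh")
  expect_error(tissue_masses(-1, 5, 1), "non-negative")
})

test_that("relative composition normalizes and is scale invariant on random masses", {
  set.seed(11)
  for (i in 1:500) {
    m <- tissue_masses(runif(1, 0.01, 5000), runif(1, 0.01, 5000),
                       runif(1, 0.01, 500))
    rc <- relative_composition(m)
    expect_lt(abs(sum(rc) - 1), 1e-9)
    k <- runif(1, 1e-3, 1e3)
    expect_equal(relative_composition(m * k), rc)
  }
})

test_that("discrepancy ratio is the signed fractional mass excess", {
  expect_equal(mt_discrepancy_ratio(1.18 * 1000, 1000), 0.18)
  expect_equal(mt_discrepancy_ratio(1000, 1000), 0)
  expect_equal(mt_discrepancy_ratio(900, 1000), -0.10)
  expect_error(mt_discrepancy_ratio(100, 0), "positive")
  expect_error(mt_discrepancy_ratio(100, -5), "positive")
})

test_that("swapping affected and contralateral maps r to -r/(1+r)", {
  set.seed(12)
  for (i in 1:200) {
    a <- runif(1, 10, 5000); b <- runif(1, 10, 5000)
    r <- mt_discrepancy_ratio(a, b)
    expect_equal(mt_discrepancy_ratio(b, a), -r / (1 + r), tolerance = 1e-12)
  }
})

test_that("LO is called at the inclusive 10% boundary", {
  expect_true(call_lo(0.18))
  expect_false(call_lo(0.08))
  expect_false(call_lo(0.07))
  expect_false(call_lo(0.09))
  expect_true(call_lo(0.10))   # boundary inclusive
  expect_false(call_lo(-0.15)) # undergrowth is never LO of this side
  cfg <- analysis_config(lo_threshold = 0.05, near_threshold_band = 0.02)
  expect_true(call_lo(0.07, cfg))
})

test_that("dRC is the componentwise RC difference in percentage points", {
  d <- delta_rc(c(adipose = 0.32, muscle = 0.65, bone = 0.03),
                c(adipose = 0.30, muscle = 0.67, bone = 0.03))
  expect_equal(unname(d), c(2, -2, 0))

  rc <- c(adipose = 0.25, muscle = 0.71, bone = 0.04)
  expect_equal(unname(delta_rc(rc, rc)), c(0, 0, 0))

  # subgroup-mean-level arithmetic: adipose and bone reproduce the direct
  # subtraction of the printed column means; muscle absorbs the simplex
  # closure of the other two
  aff <- c(adipose = 0.313, bone = 0.028)
  con <- c(adipose = 0.292, bone = 0.031)
  d <- delta_rc(c(aff, muscle = 1 - sum(aff))[c("adipose", "muscle", "bone")],
                c(con, muscle = 1 - sum(con))[c("adipose", "muscle", "bone")])
  expect_equal(d[["adipose"]], 2.1, tolerance = 1e-9)
  expect_equal(d[["bone"]], -0.3, tolerance = 1e-9)
  expect_equal(d[["muscle"]], -(d[["adipose"]] + d[["bone"]]), tolerance = 1e-9)

  expect_error(delta_rc(c(adipose = 0.5, muscle = 0.4, bone = 0.2),
                        c(adipose = 0.3, muscle = 0.65, bone = 0.05)),
               "sum to 1")
})

test_that("dRC components sum to zero for random composition pairs", {
  set.seed(13)
  for (i in 1:500) {
    a <- c(runif(1, 0.05, 0.6), runif(1, 0.01, 0.1))
    b <- c(runif(1, 0.05, 0.6), runif(1, 0.01, 0.1))
    rc1 <- c(adipose = a[1], muscle = 1 - sum(a), bone = a[2])
    rc2 <- c(adipose = b[1], muscle = 1 - sum(b), bone = b[2])
    expect_lt(abs(sum(delta_rc(rc1, rc2))), 1e-9)
  }
})

test_that("predominant tissue is the dRC argmax with fixed tie priority", {
  expect_equal(classify_predominant(c(adipose = 2.0, muscle = -1.5, bone = -0.3)),
               "adipose")
  expect_equal(classify_predominant(c(adipose = -0.5, muscle = 0.8, bone = -0.2)),
               "muscle")
  # exact tie: fixed priority adipose > muscle > bone
  expect_equal(classify_predominant(c(adipose = 1.0, muscle = 1.0, bone = -2.0)),
               "adipose")
  expect_equal(classify_predominant(c(adipose = -1.0, muscle = 0.5, bone = 0.5)),
               "muscle")
  # tie order is configurable
  cfg <- analysis_config(tie_order = c("bone", "muscle", "adipose"))
  expect_equal(classify_predominant(c(adipose = 0.5, muscle = -1, bone = 0.5), cfg),
               "bone")
})

test_that("predominant classification agrees with a brute-force argmax", {
  set.seed(14)
  for (i in 1:1000) {
    a <- rnorm(1, 0, 3); b <- rnorm(1, 0, 0.5)
    d <- c(adipose = a, muscle = -(a + b), bone = b)
    expect_equal(classify_predominant(d),
                 names(d)[which.max(d)]) # which.max: first max, same priority
  }
})

test_that("aggregation sums tissue masses over the affected set and its mirror", {
  m <- data.frame(
    region = rep(c("thigh", "leg"), each = 2),
    side = rep(c("left", "right"), 2),
    fat_mass_g = c(100, 90, 50, 45),
    lean_mass_g = c(200, 180, 100, 90),
    bmc_g = c(10, 9, 5, 4.5)
  )
  scan <- patient_scan("p1", m)
  agg <- aggregate_regions(scan, data.frame(region = c("thigh", "leg"),
                                            side = "left"))
  expect_equal(unname(agg$affected), c(150, 300, 15))
  expect_equal(unname(agg$contralateral), c(135, 270, 13.5))

  single <- aggregate_regions(scan, data.frame(region = "thigh", side = "left"))
  expect_equal(unname(single$affected), c(100, 200, 10))

  expect_error(aggregate_regions(scan, data.frame(region = character(),
                                                  side = character())),
               "empty affected set")
  expect_error(aggregate_regions(scan, data.frame(region = c("thigh", "thigh"),
                                                  side = c("left", "right"))),
               "both sides")
  expect_error(aggregate_regions(scan, data.frame(region = "foot", side = "left")),
               "not measured")
})

test_that("aggregate totals equal the sum of per-region totals", {
  scan <- make_scan(mult = c("thigh.left" = 1.3, "leg.left" = 1.15))
  regions <- data.frame(region = c("thigh", "leg", "foot"), side = "left")
  agg <- aggregate_regions(scan, regions)
  per_region <- lapply(seq_len(nrow(regions)), function(i) {
    aggregate_regions(scan, regions[i, , drop = FALSE])$affected
  })
  expect_equal(total_mass(agg$affected),
               sum(vapply(per_region, total_mass, numeric(1))))
})

test_that("a fully symmetric scan scores zero everywhere", {
  scan <- make_scan()
  res <- score_patient(scan)
  expect_equal(nrow(res$regions), 8)
  expect_equal(res$regions$discrepancy_ratio, rep(0, 8))
  expect_false(any(res$regions$lo_call))
  expect_null(res$aggregate)
})

test_that("a 20% heavier thigh is the only LO call, anchored on the heavier side", {
  scan <- make_scan(mult = c("thigh.left" = 1.2))
  res <- score_patient(scan)
  thigh <- res$regions[res$regions$region == "thigh", ]
  expect_equal(thigh$discrepancy_ratio, 0.2, tolerance = 1e-12)
  expect_equal(thigh$affected_side, "left")
  expect_equal(thigh$orientation, "heavier")
  expect_true(thigh$lo_call)
  expect_false(any(res$regions$lo_call[res$regions$region != "thigh"]))
})

test_that("a singleton clinical set makes the aggregate equal its region result", {
  scan <- make_scan(mult = c("thigh.left" = 1.2),
                    clinical = data.frame(region = "thigh", side = "left"))
  res <- score_patient(scan)
  thigh <- res$regions[res$regions$region == "thigh", ]
  expect_equal(thigh$orientation, "clinical")
  agg <- res$aggregate
  for (col in c("mt_affected_g", "mt_contra_g", "discrepancy_ratio",
                "delta_rc_adipose", "delta_rc_muscle", "delta_rc_bone")) {
    expect_equal(agg[[col]], thigh[[col]])
  }
  expect_true(agg$lo_call)
  expect_true(agg$predominant_tissue %in% lo_tissues())
})

test_that("the clinical label anchors the ratio even when that side is lighter", {
  scan <- make_scan(mult = c("thigh.left" = 1.2),
                    clinical = data.frame(region = "thigh", side = "right"))
  res <- score_patient(scan)
  thigh <- res$regions[res$regions$region == "thigh", ]
  expect_equal(thigh$affected_side, "right")
  expect_equal(thigh$discrepancy_ratio, -0.2 / 1.2, tolerance = 1e-12)
  expect_false(thigh$lo_call)
})

test_that("a region missing one side is skipped with a warning, not imputed", {
  scan <- make_scan(drop = "hand.right")
  expect_warning(res <- score_patient(scan), "hand")
  expect_equal(nrow(res$regions), 7)
  expect_false("hand" %in% res$regions$region)
})

test_that("analysis configuration rejects invalid thresholds", {
  expect_error(analysis_config(lo_threshold = 0), "lo_threshold")
  expect_error(analysis_config(lo_threshold = 1.2), "lo_threshold")
  expect_error(analysis_config(near_threshold_band = 0.2), "near_threshold_band")
  expect_error(analysis_config(tie_order = c("adipose", "muscle")), "permutation")
})
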