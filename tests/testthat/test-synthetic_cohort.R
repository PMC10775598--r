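cfg48 <- phantom_config(shape = c(48, 48, 48))

test_that("phantom is deterministic and satisfies containment", {
  ph1 <- build_phantom(cfg48, seed = 1)
  ph2 <- build_phantom(cfg48, seed = 1)
  expect_identical(ph1$ctv$flags, ph2$ctv$flags)
  expect_identical(ph1$ptv$flags, ph2$ptv$flags)
  expect_true(all(ph1$ctv$flags <= ph1$ptv$flags))
  expect_true(all(ph1$ptv$flags <= ph1$body$flags))
  for (o in ph1$oars) {
    expect_true(all(o$flags <= ph1$body$flags))
    expect_false(any(o$flags & ph1$ctv$flags))
  }
})

test_that("CTV volume is within 10% of the analytic ellipsoid", {
  ph <- build_phantom(cfg48)
  analytic <- 4 / 3 * pi * prod(ph$config$ctv$semi)
  voxel <- sum(ph$ctv$flags) * prod(ph$config$spacing)
  expect_lt(abs(voxel - analytic) / analytic, 0.10)
})

test_that("PTV sits one planning margin outside the CTV", {
  ph <- build_phantom(cfg48)
  sd_ptv <- signed_distance(ph$ptv)
  # every CTV voxel lies at least (margin - voxel diagonal) inside the PTV
  diag <- sqrt(sum(ph$config$spacing^2))
  expect_lte(max(sd_ptv[ph$ctv$flags]),
             -(ph$config$planning_margin_mm - diag))
})

test_that("overlapping OAR configuration is rejected", {
  bad <- cfg48
  bad$oars$parotid_l$centre <- bad$ctv$centre
  expect_error(build_phantom(bad), "overlaps the CTV")
})

test_that("shift samples are seeded and reproducible", {
  mc <- motion_config()
  s1 <- sample_shifts(50, mc, seed = 9)
  s2 <- sample_shifts(50, mc, seed = 9)
  s3 <- sample_shifts(50, mc, seed = 10)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_setequal(
    setdiff(names(s1), "fraction"),
    c(paste0("inter_", c("z", "y", "x", letters[1:8])),
      paste0("intra_", c("z", "y", "x", letters[1:8]))))
})

test_that("sampler recovers its configured percentile targets", {
  mc <- motion_config()
  s <- sample_shifts(2000, mc, seed = 7)
  # unit-gain landmarks (b and g) against the configured targets
  for (lm in c("b", "g")) {
    expect_lt(abs(percentile_os(abs(s[[paste0("inter_", lm)]]), 0.95) -
                    mc$inter_p95_mm), 1)
    expect_lt(abs(percentile_os(abs(s[[paste0("intra_", lm)]]), 0.95) -
                    mc$intra_p95_mm), 1)
  }
  # non-unit gains against the sampler's own numerically integrated quantile
  reg <- landmark_registry()
  for (i in c(1, 5)) {
    target <- landmark_abs_quantile(0.95, scales = mc$s_inter, df = mc$df,
                                    noise_sd = mc$noise_sd_mm,
                                    gain = reg$gain[i])
    emp <- percentile_os(abs(s[[paste0("inter_", reg$key[i])]]), 0.95)
    expect_lt(abs(emp - target), 1)
  }
})

test_that("inter and intra absolute shifts correlate per the coupling", {
  mc0 <- motion_config(rho = 0)
  s0 <- sample_shifts(1000, mc0, seed = 3)
  r0 <- cor(abs(s0$inter_z), abs(s0$intra_z), method = "spearman")
  expect_lt(abs(r0), 0.1)
  mc5 <- motion_config(rho = 0.5)
  s5 <- sample_shifts(1000, mc5, seed = 3)
  r5 <- cor(abs(s5$inter_z), abs(s5$intra_z), method = "spearman")
  expect_gt(r5, 0.3)
  expect_error(motion_config(rho = 1.2), "rho")
})

test_that("intra spread is smaller than inter spread (sign test)", {
  mc <- motion_config()
  s <- sample_shifts(2000, mc, seed = 21)
  delta <- abs(s$inter_g) - abs(s$intra_g)
  expect_gt(median(delta), 0)
  # one-sided binomial sign test
  expect_lt(binom.test(sum(delta > 0), sum(delta != 0),
                       alternative = "greater")$p.value, 1e-6)
})

test_that("reference plan is bounded and covers the CTV", {
  ph <- build_phantom(cfg48)
  plan <- reference_plan(ph)
  rx <- ph$config$prescription
  expect_lte(max(plan$dose$values), 1.15 * rx)
  p <- eud_params(-20, rx)
  expect_gt(as.numeric(normalized_eud(plan$dose, ph$ctv, p)), 100)
})

test_that("zero shift leaves scheduled CTV metrics at reference values", {
  ph <- build_phantom(cfg48)
  plan <- reference_plan(ph)
  p <- eud_params(-20, ph$config$prescription)
  ref <- metric_row(plan$dose, ph$ctv, p, "ref", "reference")
  day <- shifted_ctv(ph, c(0, 0, 0))
  sched <- metric_row(make_scheduled_dose(ph, plan, c(0, 0, 0)), day, p,
                      "f1", "scheduled")
  expect_equal(sched$eud_pct, ref$eud_pct, tolerance = 1e-12)
  expect_equal(sched$d99_pct, ref$d99_pct, tolerance = 1e-12)
})

test_that("large interfractional shifts break scheduled coverage", {
  ph <- build_phantom(cfg48)
  plan <- reference_plan(ph)
  p <- eud_params(-20, ph$config$prescription)
  big <- c(0, 0, ph$config$planning_margin_mm + 3 * ph$config$sigma_penumbra_mm)
  day <- shifted_ctv(ph, big)
  expect_lt(as.numeric(normalized_eud(plan$dose, day, p)), 95)
})

test_that("adaptive plan restores coverage; residual motion degrades it", {
  ph <- build_phantom(cfg48)
  plan <- reference_plan(ph)
  p <- eud_params(-20, ph$config$prescription)
  inter <- c(4, -6, 2)
  day <- shifted_ctv(ph, inter)
  ad <- make_adaptive_dose(ph, plan, inter)
  ref <- normalized_eud(plan$dose, ph$ctv, p)
  # zero intra: adaptive coverage equals reference coverage
  expect_equal(as.numeric(normalized_eud(ad, day, p)), as.numeric(ref),
               tolerance = 1e-6)
  # intra beyond margin + penumbra: adaptive degrades below 100%
  intra <- c(0, ph$config$adaptive_margin_mm +
               3 * ph$config$sigma_penumbra_mm, 0)
  delivered <- shifted_ctv(ph, inter + intra)
  expect_lt(as.numeric(normalized_eud(ad, delivered, p)), 100)
  # shifting the CTV outside the BODY is an error
  expect_error(shifted_ctv(ph, c(0, 0, 500)), "outside the BODY")
})

test_that("adaptive beats scheduled on the delivered anatomy for large shifts", {
  ph <- build_phantom(cfg48)
  plan <- reference_plan(ph)
  p <- eud_params(-20, ph$config$prescription)
  mc <- motion_config()
  s <- sample_shifts(150, mc, seed = 42)
  wins <- 0L; tot <- 0L
  for (i in seq_len(nrow(s))) {
    inter <- as.numeric(s[i, c("inter_z", "inter_y", "inter_x")])
    intra <- as.numeric(s[i, c("intra_z", "intra_y", "intra_x")])
    if (sqrt(sum(inter^2)) <= 5) next
    res <- tryCatch({
      delivered <- shifted_ctv(ph, inter + intra)
      es <- as.numeric(normalized_eud(plan$dose, delivered, p))
      ea <- as.numeric(normalized_eud(make_adaptive_dose(ph, plan, inter),
                                      delivered, p))
      ea >= es
    }, error = function(e) NA)  # shift outside BODY: skip
    if (is.na(res)) next
    tot <- tot + 1L; wins <- wins + res
    if (tot >= 40L) break
  }
  expect_gte(tot, 30L)
  expect_gte(wins / tot, 0.9)
})

test_that("displacement field is zero outside the influence region", {
  ph <- build_phantom(cfg48)
  fld <- displacement_field(ph, c(5, -3, 2))
  influence <- expand(ph$ctv, ph$config$taper_mm)$flags
  for (k in 1:3) {
    comp <- fld[, , , k]
    expect_true(all(comp[!influence] == 0))
  }
  # rigid inside the CTV
  expect_true(all(fld[, , , 1][ph$ctv$flags] == 5))
})

test_that("warping the shifted CTV back recovers the reference CTV", {
  ph <- build_phantom()  # 2 mm voxels as stated
  sh <- c(4, 3, -5)
  fld <- displacement_field(ph, sh)
  day <- shifted_ctv(ph, sh)
  dims <- dim(day$flags); sp <- ph$ctv$spacing
  base <- lapply(1:3, function(ax)
    as.numeric(slice.index(array(0, dims), ax) - 1))
  s <- artdose:::.trilinear_sample(
    as.numeric(day$flags), dims,
    base[[1]] + as.numeric(fld[, , , 1]) / sp[1],
    base[[2]] + as.numeric(fld[, , , 2]) / sp[2],
    base[[3]] + as.numeric(fld[, , , 3]) / sp[3], 0)
  rec <- array(s$values >= 0.5, dims)
  dice <- 2 * sum(rec & ph$ctv$flags) / (sum(rec) + sum(ph$ctv$flags))
  expect_gte(dice, 0.95)
})

test_that("selection policy ties go to the scheduled plan", {
  ph <- build_phantom(cfg48)
  plan <- reference_plan(ph)
  p <- eud_params(-20, ph$config$prescription)
  m <- metric_row(plan$dose, ph$ctv, p, "f1", "scheduled")
  m2 <- m; m2$plan_type <- "adaptive"
  expect_equal(select_delivered(m, m2), "scheduled")
  m3 <- m2; m3$eud_pct <- m3$eud_pct + 1
  expect_equal(select_delivered(m, m3), "adaptive")
  # OAR worsening beyond tolerance blocks adaptation
  oar_s <- m; oar_s$structure <- "parotid_l"
  oar_a <- oar_s; oar_a$plan_type <- "adaptive"
  oar_a$eud_pct <- oar_a$eud_pct + 5
  expect_equal(select_delivered(rbind(m, oar_s), rbind(m3, oar_a)),
               "scheduled")
  expect_equal(select_delivered(rbind(m, oar_s), rbind(m3, oar_a),
                                selection_policy(oar_tolerance = 10)),
               "adaptive")
})
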