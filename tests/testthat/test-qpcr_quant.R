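# Replicate QC, standard-curve fitting, and the copy-number scaling chain.

test_that("replicate filter removes at most one outlier and flags the rest", {
  tight <- filter_replicates(c(20.0, 20.1, 20.2))
  expect_equal(tight$kept, c(20.0, 20.1, 20.2))
  expect_true(tight$valid)

  # SD of the triplet ~3.4 > 0.5; dropping 26.0 leaves SD ~0.07
  one_out <- filter_replicates(c(20.0, 20.1, 26.0))
  expect_equal(sort(one_out$kept), c(20.0, 20.1))
  expect_equal(one_out$removed, 26.0)
  expect_true(one_out$valid)
  expect_true(any(grepl("outlier_removed", one_out$flags)))

  # after one removal SD is still 1.41 > 0.5 -> the group is invalid
  bad <- filter_replicates(c(18.0, 20.0, 22.0))
  expect_false(bad$valid)
  expect_length(bad$kept, 0)

  nd <- filter_replicates(c(NA_real_, NA_real_, NA_real_))
  expect_false(nd$valid)
  expect_equal(nd$flags, "all_nd")

  single <- filter_replicates(c(21.3, NA))
  expect_true(single$valid)
  expect_true("singleton" %in% single$flags)
})

test_that("lowering the SD threshold never increases kept replicates", {
  set.seed(42)
  for (i in 1:50) {
    cts <- 20 + rnorm(3, 0, runif(1, 0.05, 3))
    kept <- vapply(c(2, 1, 0.5, 0.25, 0.1),
                   function(th) length(filter_replicates(cts, th)$kept),
                   numeric(1))
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("dilution series infers concentrations from the anchor", {
  s <- dilution_series(anchor_ng = 2, n_steps = 4, fold = 10)
  expect_equal(s$ng, c(2, 0.2, 0.02, 0.002))
  s2 <- dilution_series(anchor_ng = 0.05, n_steps = 4, fold = 10,
                        anchor_step = 2)
  expect_equal(s2$ng, c(0.5, 0.05, 0.005, 5e-4))
  expect_error(dilution_series(0, 4), "anchor_ng")
})

test_that("noiseless curves recover slope, intercept and efficiency", {
  # perfect doubling: Ct = -log10(C)/0.30103 + const
  perfect <- gen_standard_series(true_curve(1, b = 2), ct_sd = 0, seed = 1)
  fit <- fit_standard_curve(perfect$plate, perfect$series)
  expect_equal(fit$efficiency, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$b, 2, tolerance = 1e-9)

  # per-cycle fold 1.95 -> efficiency 95%
  g <- gen_standard_series(true_curve(0.95), ct_sd = 0, seed = 1)
  fit95 <- fit_standard_curve(g$plate, g$series)
  expect_equal(fit95$efficiency, 0.95, tolerance = 1e-9)
  expect_true(fit95$m < 0)
})

test_that("noiseless series recover any per-cycle fold in (1, 2]", {
  for (f in c(1.05, 1.3, 1.5, 1.8, 1.92, 1.98, 2)) {
    g <- gen_standard_series(true_curve(f - 1), ct_sd = 0, seed = 7)
    fit <- fit_standard_curve(g$plate, g$series)
    expect_lt(abs(fit$efficiency - (f - 1)), 0.005)
  }
})

test_that("noisy 7-point curves keep a high coefficient of determination", {
  set.seed(123)
  r2 <- replicate(20, {
    g <- gen_standard_series(true_curve(0.95), ct_sd = 0.15)
    fit_standard_curve(g$plate, g$series)$r_squared
  })
  expect_gt(mean(r2), 0.99)
})

test_that("curve fitting needs 3 valid points and flags non-monotonic Cts", {
  g <- gen_standard_series(true_curve(0.95), n_points = 3, ct_sd = 0,
                           seed = 1)
  short <- g$plate[g$plate$dilution != "d3", ]
  expect_error(fit_standard_curve(short, g$series), "fewer than 3")

  flipped <- g$plate
  flipped$ct[flipped$dilution == "d2"] <-
    max(flipped$ct) + 1  # middle dilution now latest Ct
  fit <- fit_standard_curve(flipped, g$series)
  expect_true("nonmonotonic_ct" %in% fit$flags)
})

test_that("ct_to_ng is the antilog of the curve and round-trips", {
  g <- gen_standard_series(true_curve(0.95, b = 1.2), ct_sd = 0, seed = 2)
  curve <- fit_standard_curve(g$plate, g$series)
  # Ct at which m*ct + b = 0 gives exactly 1 ng
  ct0 <- -curve$b / curve$m
  expect_equal(as.numeric(ct_to_ng(ct0, curve)), 1, tolerance = 1e-9)
  ct3 <- (-3 - curve$b) / curve$m
  expect_equal(as.numeric(ct_to_ng(ct3, curve)), 1e-3, tolerance = 1e-9)
  # ng -> Ct -> ng round trip
  for (ng in c(5e-4, 0.02, 1.7)) {
    ct <- (log10(ng) - curve$b) / curve$m
    expect_equal(as.numeric(ct_to_ng(ct, curve)), ng,
                 tolerance = 1e-9 * ng)
  }
  expect_true(any(attr(ct_to_ng(c(ct0, 1e4), curve), "extrapolated")))
})

test_that("ng_to_copies applies the printed constants", {
  p <- workflow_params()
  expect_equal(ng_to_copies(0, p), 0)
  # independent hand arithmetic: 6.022e23 / (69 * 330 * 1e9)
  expect_equal(ng_to_copies(1, p), 6.022e23 / (69 * 330 * 1e9),
               tolerance = 1e-12)
  # halving the amplicon length doubles the copies
  p35 <- workflow_params(amplicon_bp = 69 / 2)
  expect_equal(ng_to_copies(1, p35), 2 * ng_to_copies(1, p),
               tolerance = 1e-12)
  expect_error(ng_to_copies(-1, p), "non-negative")
})

test_that("the four-step chain scales reaction copies to prep copies", {
  p <- workflow_params(cdna_dilution = 100, cdna_volume_ul = 20,
                       rna_volume_ul = 4, elution_volume_ul = 30,
                       prep_volume_ul = 5)
  t <- copies_per_ul_prep(1000, p)
  expect_equal(t$copies_per_ul_prep, 3.0e6)
  # multiplicative factors equal to their divisors -> identity
  id <- workflow_params(cdna_dilution = 1, cdna_volume_ul = 20,
                        rna_volume_ul = 20, elution_volume_ul = 5,
                        prep_volume_ul = 5)
  expect_equal(copies_per_ul_prep(777, id)$copies_per_ul_prep, 777)
  expect_error(workflow_params(prep_volume_ul = 0), "positive")
})

test_that("the whole chain is linear in the input", {
  p <- workflow_params()
  for (ng in c(1e-6, 1e-3, 0.5)) {
    expect_equal(ng_to_copies(2 * ng, p), 2 * ng_to_copies(ng, p))
    c1 <- copies_per_ul_prep(ng_to_copies(ng, p), p)$copies_per_ul_prep
    c2 <- copies_per_ul_prep(ng_to_copies(2 * ng, p), p)$copies_per_ul_prep
    expect_equal(c2, 2 * c1, tolerance = 1e-12)
  }
})

test_that("simulated preps round-trip exactly without noise", {
  p <- workflow_params()
  tc <- true_curve(0.95)
  std <- gen_standard_series(tc, ct_sd = 0, seed = 3)
  curve <- fit_standard_curve(std$plate, std$series)
  preps <- gen_prep_samples(6e6, tc, p, n_preps = 3, ct_sd = 0, seed = 3)
  for (prep in unique(preps$plate$sample)) {
    cts <- preps$plate$ct[preps$plate$sample == prep &
                            preps$plate$role == "test"]
    q <- quantify_sample(cts, curve, p)
    expect_equal(q$copies_per_ul_prep, 6e6, tolerance = 1e-9 * 6e6)
  }
})

test_that("plasmid load per genome normalizes against the control gene", {
  tc <- true_curve(0.95)
  std <- gen_standard_series(tc, ct_sd = 0, seed = 4)
  curve <- fit_standard_curve(std$plate, std$series)
  p <- workflow_params()
  # identical Cts and identical curves: plasmid copies == control copies,
  # so with 2 control copies per genome the load is 200 per 100 genomes
  load <- plasmid_load_per_genome(c(25, 25, 25), c(25, 25, 25),
                                  curve, curve, p, p)
  expect_equal(load$copies_per_100_genomes, 200, tolerance = 1e-9)
  # plasmid non-detect reports 0 with a flag
  nd <- plasmid_load_per_genome(c(NA, NA, NA), c(25, 25, 25),
                                curve, curve, p, p)
  expect_equal(nd$copies_per_100_genomes, 0)
  expect_true("plasmid_nd" %in% nd$flags)
  # control failure makes the sample non-quantifiable
  bad <- plasmid_load_per_genome(c(25, 25, 25), c(NA, NA, NA),
                                 curve, curve, p, p)
  expect_false(bad$valid)
})

test_that("synthetic truth is recovered within tolerance under Ct noise", {
  # smaller companion of the acceptance-scale study: same conditions
  set.seed(11)
  p <- workflow_params()
  tc <- true_curve(0.95)
  err <- replicate(40, {
    std <- gen_standard_series(tc, ct_sd = 0.2)
    curve <- fit_standard_curve(std$plate, std$series)
    pr <- gen_prep_samples(6e6, tc, p, n_preps = 1, ct_sd = 0.2)
    cts <- pr$plate$ct[pr$plate$role == "test"]
    abs(quantify_sample(cts, curve, p)$copies_per_ul_prep - 6e6) / 6e6
  })
  expect_lt(stats::median(err), 0.15)
})

test_that("plate files read ND as non-detect", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("sample,target,role,dilution,replicate,ct",
               "p1,scaffold,test,test,1,21.5",
               "p1,scaffold,test,test,2,ND",
               "p1,scaffold,NTC,none,1,"), tf)
  df <- read_plate(tf)
  expect_equal(df$ct, c(21.5, NA, NA))
  writeLines("sample,ct\np,1", tf)
  expect_error(read_plate(tf), "missing column")
})
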