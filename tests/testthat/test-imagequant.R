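test_that("sum projection matches an explicit per-pixel loop", {
  set.seed(8)
  st <- array(runif(6 * 7 * 5), c(6, 7, 5))
  proj <- sum_project(st)
  loop <- matrix(0, 6, 7)
  for (i in 1:6) for (j in 1:7) for (z in 1:5) loop[i, j] <- loop[i, j] + st[i, j, z]
  expect_equal(proj, loop)
  # two identical slices double the slice; a single 2-D slice is identity
  sl <- matrix(runif(12), 3, 4)
  expect_equal(sum_project(array(c(sl, sl), c(3, 4, 2))), 2 * sl)
  expect_equal(sum_project(sl), sl)
  expect_error(sum_project(array(0, c(3, 4, 0))), class = "hsdquant_param_error")
})

test_that("ROI quantification subtracts the moved-ROI background", {
  img <- matrix(10, 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[3:6, 3:6] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[12:15, 12:15] <- TRUE
  expect_equal(roi_quant(img, roi, bg)$corrected, 0) # uniform image
  # planted integrated intensity on a flat background
  img2 <- img; img2[4:5, 4:5] <- img2[4:5, 4:5] + 25 # adds 4 * 25 = 100
  q <- roi_quant(img2, roi, bg)
  expect_equal(q$corrected, 100)
  expect_equal(q$corrected, q$raw_sum - q$background_sum)
  # brighter background: negative value, with warning
  img3 <- img; img3[12:15, 12:15] <- 50
  expect_warning(qn <- roi_quant(img3, roi, bg), "negative")
  expect_lt(qn$corrected, 0)
  # unequal areas rejected unless normalization requested
  bg2 <- bg; bg2[16, 16] <- TRUE
  expect_error(roi_quant(img, roi, bg2), class = "hsdquant_param_error")
  expect_equal(roi_quant(img, roi, bg2, area_normalize = TRUE)$corrected, 0)
})

test_that("ROI correction cancels a constant offset", {
  set.seed(4)
  img <- matrix(runif(400, 5, 10), 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[2:5, 2:5] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[10:13, 10:13] <- TRUE
  q1 <- roi_quant(img, roi, bg)$corrected
  q2 <- roi_quant(img + 7.3, roi, bg)$corrected
  expect_equal(q1, q2, tolerance = 1e-9)
})

test_that("ratiometric normalization divides corrected values", {
  img <- matrix(1, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[2:3, 2:3] <- TRUE
  bg <- matrix(FALSE, 10, 10); bg[7:8, 7:8] <- TRUE
  sig <- roi_quant(img + 2 * (row(img) < 5), roi, bg)
  expect_equal(ratiometric(sig, sig), 1.0)
  expect_equal(ratiometric(2, 1), 2.0)
  expect_error(ratiometric(1, 0), class = "hsdquant_undefined_ratio")
  expect_error(ratiometric(1, -2), class = "hsdquant_undefined_ratio")
})

test_that("line profiles reproduce an analytic column gradient", {
  img <- matrix(rep(0:19, each = 10), 10, 20) # intensity = column index
  lp <- extract_line_profile(img, c(5, 2), c(5, 17), width_px = 5)
  expect_equal(lp$positions[1], 0)
  expect_equal(lp$positions[length(lp$positions)], 1)
  expect_equal(lp$intensities, 2 + lp$positions * 15, tolerance = 1e-9)
})

test_that("line profiles are constant on uniform images, any width", {
  img <- matrix(3.7, 30, 30)
  lp1 <- extract_line_profile(img, c(5, 5), c(22, 25), width_px = 1)
  lp15 <- extract_line_profile(img, c(5, 5), c(22, 25), width_px = 15)
  expect_true(all(abs(lp1$intensities - 3.7) < 1e-9))
  expect_equal(lp1$intensities, lp15$intensities, tolerance = 1e-9)
  expect_error(extract_line_profile(img, c(5, 5), c(5, 5)),
               class = "hsdquant_param_error")
  expect_error(extract_line_profile(img, c(-1, 5), c(5, 5)),
               class = "hsdquant_param_error")
})

test_that("center:surround ratio follows the window definition exactly", {
  x <- seq(0, 1, by = 0.005)
  y <- rep(1, length(x))
  expect_equal(tgph_membrane_ratio(list(positions = x, intensities = y)), 1.0)
  y2 <- ifelse(x >= 0.45 & x <= 0.55, 2, 1)
  expect_equal(tgph_membrane_ratio(list(positions = x, intensities = y2)), 2.0)
  # scale invariance
  prof <- list(positions = x, intensities = y2 * runif(1, 10, 100))
  expect_equal(tgph_membrane_ratio(prof), 2.0)
  # boundary membership: a sample at exactly 0.45 is center, not surround
  xb <- c(0, 0.35, 0.40, 0.45, 0.5, 0.55, 0.60, 0.65, 1)
  yb <- c(9, 1, 1, 5, 5, 5, 1, 1, 9)
  expect_equal(tgph_membrane_ratio(list(positions = xb, intensities = yb)), 5.0)
  expect_error(
    tgph_membrane_ratio(list(positions = c(0, 1), intensities = c(1, 1))),
    class = "hsdquant_param_error")
})

test_that("planted membrane enrichment is recovered from simulated tissue", {
  fb <- sim_fatbody_image(image_sim_params(shape = c(200, 200), n_cells = 9,
                                           membrane_enrichment = 2,
                                           noise_sd = 1, seed = 5))
  tr <- fb$truth
  expect_gte(nrow(tr$pairs), 10)
  ratios <- apply(tr$pairs, 1, function(pr) {
    lp <- extract_line_profile(fb$stack$reporter, tr$nuclei[pr[1], ],
                               tr$nuclei[pr[2], ])
    tgph_membrane_ratio(lp)
  })
  expect_lt(abs(mean(ratios) - 2.0), 0.15)
})

test_that("a flat reporter yields a unit membrane ratio", {
  fb <- sim_fatbody_image(image_sim_params(shape = c(128, 128), n_cells = 4,
                                           membrane_enrichment = 1,
                                           noise_sd = 0, seed = 2))
  pr <- fb$truth$pairs[1, ]
  lp <- extract_line_profile(fb$stack$reporter, fb$truth$nuclei[pr[1], ],
                             fb$truth$nuclei[pr[2], ])
  expect_equal(tgph_membrane_ratio(lp), 1.0)
})

test_that("droplet area fraction recovers the planted fraction", {
  fb <- sim_fatbody_image(image_sim_params(shape = c(200, 200), n_cells = 4,
                                           droplet_area_fraction = 0.25,
                                           noise_sd = 2, seed = 3))
  fr <- vapply(1:4, function(i) {
    droplet_area_fraction(fb$stack$droplet, fb$truth$cell_labels == i)
  }, numeric(1))
  expect_true(all(abs(fr - 0.25) < 0.03))
  expect_true(all(fr >= 0 & fr <= 1))
  # zero planted fraction: empty truth mask, zero estimate
  fb0 <- sim_fatbody_image(image_sim_params(shape = c(128, 128), n_cells = 4,
                                            droplet_area_fraction = 0, seed = 3))
  expect_false(any(fb0$truth$droplet_mask))
  expect_equal(droplet_area_fraction(fb0$stack$droplet,
                                     fb0$truth$cell_labels == 1), 0)
  # numeric threshold edge: everything above -> 1.0
  img <- matrix(10, 8, 8)
  expect_equal(droplet_area_fraction(img, matrix(TRUE, 8, 8), threshold = 5), 1.0)
  expect_error(droplet_area_fraction(img, matrix(FALSE, 8, 8)),
               class = "hsdquant_param_error")
})

test_that("fat-body simulator enforces geometric preconditions", {
  expect_error(sim_fatbody_image(image_sim_params(shape = c(40, 40),
                                                  n_cells = 9)),
               class = "hsdquant_param_error")
  # membrane pixels carry the planted enrichment before noise
  fb <- sim_fatbody_image(image_sim_params(shape = c(128, 128), n_cells = 4,
                                           membrane_enrichment = 2.5,
                                           noise_sd = 0, seed = 1))
  mem <- fb$stack$reporter[fb$truth$membrane_mask]
  cyt <- fb$stack$reporter[fb$truth$cell_labels > 0 & !fb$truth$membrane_mask]
  expect_equal(mean(mem) / mean(cyt), 2.5)
})

test_that("gcamp series averages per-neuron ratios per frame", {
  sim <- sim_neuron_frames(n_neurons = 2, n_frames = 6, baseline_ratio = 1,
                           noise_sd = 0, seed = 1)
  # plant per-neuron ratios 1 and 3 manually
  frames <- lapply(sim$frames, function(fr) {
    g <- fr$tdtomato
    g[sim$soma_rois[[2]]] <- 3 * g[sim$soma_rois[[2]]]
    image_stack(gcamp = g, tdtomato = fr$tdtomato)
  })
  s <- gcamp_ratio_series(frames, sim$soma_rois)
  expect_equal(s, rep(2.0, 6))
})

test_that("gcamp series is invariant to per-frame illumination rescaling", {
  sim <- sim_neuron_frames(n_neurons = 3, n_frames = 8, baseline_ratio = 1.4,
                           transient_times = 5, transient_amp = 2.8,
                           noise_sd = 0, seed = 2)
  s0 <- gcamp_ratio_series(sim$frames, sim$soma_rois)
  scaled <- lapply(seq_along(sim$frames), function(f) {
    k <- 0.5 + 0.1 * f
    image_stack(gcamp = sim$frames[[f]]$gcamp * k,
                tdtomato = sim$frames[[f]]$tdtomato * k)
  })
  expect_equal(gcamp_ratio_series(scaled, sim$soma_rois), s0, tolerance = 1e-12)
})

test_that("planted calcium events appear at the planted frames", {
  sim <- sim_neuron_frames(n_neurons = 4, n_frames = 20, baseline_ratio = 1,
                           transient_times = 10, transient_amp = 2,
                           noise_sd = 0, seed = 1)
  s <- gcamp_ratio_series(sim$frames, sim$soma_rois)
  expect_equal(which.max(s), 10L)
  expect_equal(s[-10], rep(1, 19))
  # with noise, the recovered baseline stays within 3 SE of the planted value
  simn <- sim_neuron_frames(n_neurons = 4, n_frames = 40, baseline_ratio = 1.5,
                            noise_sd = 3, seed = 6)
  sn <- gcamp_ratio_series(simn$frames, simn$soma_rois)
  se <- sd(sn) / sqrt(length(sn))
  expect_lt(abs(mean(sn) - 1.5), 3 * se + 1e-6)
  # KCl challenge elevates the tail of the series
  simk <- sim_neuron_frames(n_neurons = 2, n_frames = 10, baseline_ratio = 1,
                            kcl_frame = 8, kcl_amp = 3, noise_sd = 0, seed = 1)
  sk <- gcamp_ratio_series(simk$frames, simk$soma_rois)
  expect_equal(sk[8:10], rep(3, 3))
  expect_error(sim_neuron_frames(n_frames = 10, transient_times = 11),
               class = "hsdquant_param_error")
  expect_error(sim_neuron_frames(n_frames = 10, kcl_frame = 10),
               class = "hsdquant_param_error")
})
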