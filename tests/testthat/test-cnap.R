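test_that("conduction velocity laws and monotonicity", {
  expect_equal(conductionVelocity(10, TRUE), 60)
  expect_equal(conductionVelocity(1, FALSE), 1.7)
  expect_equal(conductionVelocity(4, FALSE), 1.7 * 2)
  d <- sort(runif(50, 0.3, 15))
  for (my in c(TRUE, FALSE))
    expect_true(all(diff(conductionVelocity(d, my)) > 0))
  expect_error(conductionVelocity(-1, TRUE), "positive")
})

test_that("fiber classification partitions the velocity axis", {
  expect_equal(classifyFiber(0.8, FALSE), "C")
  expect_equal(classifyFiber(10, TRUE), "Adelta")
  expect_equal(classifyFiber(10, TRUE, preganglionic = TRUE), "B")
  expect_equal(classifyFiber(80, TRUE), "Aalpha")
  # boundary goes to the faster class
  expect_equal(classifyFiber(30, TRUE), "Abeta")
  expect_equal(classifyFiber(15, TRUE), "Agamma")
  expect_equal(classifyFiber(3, FALSE), "unclassified")

  # exhaustive scan: each velocity maps to exactly one label (or none)
  tab <- defaultFiberClasses()
  for (my in c(TRUE, FALSE)) for (pg in c(TRUE, FALSE)) {
    vs <- seq(0.1, 130, by = 0.1)
    cand <- tab[tab$myelinated == my & tab$preganglionic == pg, ]
    hits <- vapply(vs, function(v)
      sum(v >= cand$vMin & v < cand$vMax & !(cand$vMin == 0 & v == 0)),
      numeric(1))
    expect_true(all(hits <= 1))
    lab <- classifyFiber(vs, my, pg)
    expect_true(all(lab == "unclassified" | hits == 1))
  }
})

test_that("SFAP latency, differential cancellation and distance scaling", {
  dt <- 1 / 100  # one sample at 100 kHz, ms
  rec <- recordingConfig(mode = "single_ended", conductionDistance = 10,
                         electrodeSpacing = 2)
  s <- sfapWaveform(10, TRUE, rec)
  expect_equal(s@latency, 10 / 60, tolerance = 1e-12)
  expect_lt(abs(s@time[which.min(s@samples)] - s@latency), dt + 1e-12)

  # vanishing electrode spacing cancels the differential trace
  recd <- recordingConfig(conductionDistance = 10, electrodeSpacing = 1e-8)
  sd <- sfapWaveform(10, TRUE, recd)
  expect_lt(max(abs(sd@samples)), 1e-6 * max(abs(s@samples)))

  # single-ended mode never cancels
  expect_gt(max(abs(s@samples)), 0.5 * 10^2)

  # doubling the distance doubles the latency, shape unchanged
  # (12 -> 24 mm keeps the latency on the sample grid, so the sampled
  # waveforms around the peak must agree exactly)
  s1 <- sfapWaveform(10, TRUE, recordingConfig(mode = "single_ended",
                                               conductionDistance = 12))
  s2 <- sfapWaveform(10, TRUE, recordingConfig(mode = "single_ended",
                                               conductionDistance = 24))
  expect_equal(s2@latency, 2 * s1@latency)
  i1 <- which.min(s1@samples); i2 <- which.min(s2@samples)
  k <- -15:15
  expect_equal(s2@samples[i2 + k], s1@samples[i1 + k], tolerance = 1e-9)

  # both templates put the negative peak at the latency
  pb <- fiberModelParams(template = "biphasic_sine")
  sb <- sfapWaveform(10, TRUE, rec, pb)
  expect_lt(abs(sb@time[which.min(sb@samples)] - sb@latency), dt + 1e-12)

  # explicit too-short window is extended with a warning, never truncated
  recShort <- recordingConfig(mode = "single_ended", conductionDistance = 10,
                              window = 0.05)
  expect_warning(sw <- sfapWaveform(10, TRUE, recShort), "extended")
  expect_gte(max(sw@time), s@latency)
})

test_that("CNAP superposition: empty, single-fiber, additivity, homogeneity", {
  rec <- recordingConfig(conductionDistance = 10, electrodeSpacing = 2)
  zero <- predictCnap(data.frame(), rec)
  expect_true(all(cnapTotal(zero) == 0))
  expect_equal(zero@nFibers, 0L)

  one <- data.frame(entity_id = "a", fascicle_id = "F1",
                    subfascicle_id = NA, myelinated = TRUE, diameter = 6,
                    axon_diameter = 4, g_ratio = 0.66, x = 0, y = 0)
  rec@window <- autoWindow(one, rec)
  cn1 <- predictCnap(one, rec)
  sf <- sfapWaveform(6, TRUE, rec)
  expect_identical(cnapTotal(cn1), sf@samples)

  # additivity over disjoint sets + total = sum(perBin)
  gen <- threeSubfascicleSection(10L, 14L, seed = 41)
  fa <- gen$section@fascicles[[1]]
  ft <- fiberTable(fa)
  rec@window <- autoWindow(ft, rec)
  whole <- predictCnap(ft, rec)
  expect_equal(rowSums(cnapPerBin(whole)), cnapTotal(whole),
               tolerance = 1e-12)
  parts <- lapply(subfascicles(fa), function(s)
    predictCnap(fiberTable(s), rec))
  tot <- Reduce(`+`, lapply(parts, cnapTotal))
  expect_lt(max(abs(tot - cnapTotal(whole))),
            1e-9 * max(abs(cnapTotal(whole))))

  # homogeneity: duplicating the fiber set doubles the trace
  cnDouble <- predictCnap(rbind(ft, ft), rec)
  expect_equal(cnapTotal(cnDouble), 2 * cnapTotal(whole),
               tolerance = 1e-12)
})

test_that("sweep: grid consistency, linear latency law, amplitude ordering", {
  gen <- presetSection("small-fascicle", seed = 8)
  ft <- fiberTable(gen$section)
  rec <- recordingConfig()
  sw <- cnapSweep(ft, rec, distances = 10, spacings = 2)
  expect_length(sw, 1)
  rec1 <- recordingConfig(conductionDistance = 10, electrodeSpacing = 2)
  expect_equal(cnapTotal(sw[[1]]), cnapTotal(predictCnap(ft, rec1)))

  # fastest-volley peak latency grows linearly with distance
  dists <- c(5, 10, 20, 30, 40)
  lat <- vapply(dists, function(d) {
    cn <- predictCnap(ft, recordingConfig(conductionDistance = d,
                                          electrodeSpacing = 2))
    pk <- cnapPeaks(cn)
    min(pk$latency_ms[pk$polarity < 0])
  }, numeric(1))
  fit <- summary(lm(lat ~ dists))
  expect_gt(fit$r.squared, 0.999)

  # a superset fascicle dominates peak-to-peak amplitude on every grid point
  sub <- ft[ft$myelinated, ]
  for (d in c(5, 20)) for (s in c(1, 4)) {
    rc <- recordingConfig(conductionDistance = d, electrodeSpacing = s)
    rc@window <- autoWindow(ft, rc)
    p2p <- function(x) diff(range(cnapTotal(x)))
    expect_gte(p2p(predictCnap(ft, rc)), p2p(predictCnap(sub, rc)))
  }
})

test_that("velocity-domain transform: peak mapping and round trip", {
  rec <- recordingConfig(mode = "single_ended", conductionDistance = 10)
  one <- data.frame(entity_id = "a", fascicle_id = "F1",
                    subfascicle_id = NA, myelinated = TRUE, diameter = 10,
                    axon_diameter = 7, g_ratio = 0.7, x = 0, y = 0)
  cn <- predictCnap(one, rec)
  vd <- velocityDomain(cn)
  v0 <- conductionVelocity(10, TRUE)
  vPeak <- vd$velocity_m_s[which.min(vd$amplitude)]
  # within one grid step of the true velocity
  iT <- which.min(cn@total)
  stepV <- abs(rec@conductionDistance / cn@time[iT] -
               rec@conductionDistance / cn@time[iT + 1])
  expect_lt(abs(vPeak - v0), stepV + 1e-9)

  # two well-separated fibers produce two distinct volleys
  two <- rbind(one, within(one, { entity_id <- "b"; myelinated <- FALSE
                                  diameter <- 0.346 }))
  # unmyelinated 0.346 um -> 1.7 * sqrt(0.346) ~ 1 m/s
  cn2 <- predictCnap(two, rec)
  vd2 <- velocityDomain(cn2)
  fast <- vd2[vd2$velocity_m_s > 30, ]
  slow <- vd2[vd2$velocity_m_s < 3, ]
  expect_lt(min(fast$amplitude), -0.1 * max(abs(vd2$amplitude)))
  expect_lt(min(slow$amplitude), 0)

  # v -> t -> v is the identity on the sample grid
  tBack <- rec@conductionDistance / vd$velocity_m_s
  expect_equal(sort(tBack), cn@time[cn@time > 0], tolerance = 1e-12)
})

test_that("diameter binning: manual validation, auto optimality", {
  b1 <- binFibers(c(1, 2, 3), k = 1)
  expect_length(binEdges(b1), 2)
  expect_true(binEdges(b1)[1] <= 1 && binEdges(b1)[2] >= 3)

  b2 <- binFibers(c(rep(1.9, 50), rep(9.2, 50)), k = 2)
  e <- binEdges(b2)
  expect_length(e, 3)
  expect_true(e[2] > 1.9 && e[2] < 9.2)

  expect_error(binFibers(c(1, 5), mode = "manual", edges = c(2, 6)),
               "cover")
  bm <- binFibers(c(1, 5), mode = "manual", edges = c(0, 3, 6))
  expect_equal(binEdges(bm), c(0, 3, 6))

  # DP within-bin variance equals the brute-force contiguous-split oracle
  ssqOf <- function(x) if (length(x) < 2) 0 else sum((x - mean(x))^2)
  set.seed(17)
  for (rep in 1:10) {
    x <- sort(runif(60, 0, 12))
    b <- binFibers(x, k = 3)
    idx <- findInterval(x, binEdges(b), rightmost.closed = TRUE)
    dpCost <- sum(tapply(x, idx, ssqOf))
    best <- Inf
    for (i in 1:58) for (j in (i + 1):59) {
      cost <- ssqOf(x[1:i]) + ssqOf(x[(i + 1):j]) + ssqOf(x[(j + 1):60])
      best <- min(best, cost)
    }
    expect_equal(dpCost, best, tolerance = 1e-9)
  }
})

test_that("fiber selection composes predicates by intersection", {
  gen <- presetSection("large-fascicle", seed = 9)
  ft <- fiberTable(gen$section)
  fa <- gen$section@fascicles[[1]]

  expect_equal(nrow(selectFibers(gen$section)), nrow(ft))

  # diameter window [8, 11]: only large-mode fibers (generator labels)
  tr <- gen$truth$fibers
  sel <- selectFibers(gen$section, diameterRange = c(8, 11))
  lab <- tr$component[match(sel$entity_id, tr$entity_id)]
  expect_true(all(lab == 2))
  expect_true(all(tr$category[match(sel$entity_id, tr$entity_id)] ==
                  "myelinated"))
  inRange <- tr$entity_id[tr$diameter_um >= 8 & tr$diameter_um <= 11]
  expect_setequal(sel$entity_id, inRange)

  # region predicate: full fascicle inner polygon selects everything
  selR <- selectFibers(gen$section, region = fa@inner)
  expect_equal(nrow(selR), nrow(ft))

  # myelination flag + composition
  selM <- selectFibers(gen$section, diameterRange = c(0, 100),
                       myelinated = TRUE)
  expect_equal(nrow(selM), sum(ft$myelinated))

  # region = one sub-fascicle polygon matches the load-time assignment
  gen2 <- threeSubfascicleSection(8L, 10L, seed = 43)
  fa2 <- gen2$section@fascicles[[1]]
  s1 <- subfascicles(fa2)[[1]]
  selS <- selectFibers(gen2$section, region = s1@inner)
  expect_setequal(selS$entity_id, fiberTable(s1)$entity_id)
})
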