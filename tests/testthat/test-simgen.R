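test_that("with all event rates zero, hybrids are exact parental sums", {
  ref <- tiny_reference()
  ped <- pedigree(data.frame(
    node = c("fa", "fb", "h"), role = c("founder", "founder", "hybrid"),
    parent1 = c(NA, NA, "fa"), parent2 = c(NA, NA, "fb"),
    species = c("Aaa", "Bbb", NA)))
  par <- sim_params(loss_rate = 0, gain_rate = 0, transloc_rate = 0,
                    seed = 3)
  gt <- simulate_pedigree_karyotypes(ped, ref, par)
  expect_equal(gt$karyotypes$h$copies$copies,
               gt$karyotypes$fa$copies$copies +
                 gt$karyotypes$fb$copies$copies)
  expect_equal(nrow(gt$events), 0L)
  # founders are euploid diploids of their own species only
  fa <- gt$karyotypes$fa$copies
  expect_true(all(fa$copies[fa$species == "Aaa"] == 2L))
  expect_true(all(fa$copies[fa$species != "Aaa"] == 0L))
})

test_that("identical seeds give identical ground truth", {
  ref <- saccharomyces_reference(c("Scer", "Suva", "Skud"))
  ped <- pedigree(data.frame(
    node = c("f1", "f2", "f3", "h1", "h2", "e1"),
    role = c("founder", "founder", "founder", "hybrid", "hybrid", "evolved"),
    parent1 = c(NA, NA, NA, "f1", "h1", "h2"),
    parent2 = c(NA, NA, NA, "f2", "f3", NA),
    species = c("Scer", "Suva", "Skud", NA, NA, NA)))
  par <- sim_params(seed = 17)
  gt1 <- simulate_pedigree_karyotypes(ped, ref, par)
  gt2 <- simulate_pedigree_karyotypes(ped, ref, par)
  expect_identical(gt1, gt2)
  gt3 <- simulate_pedigree_karyotypes(ped, ref, sim_params(seed = 18))
  expect_false(identical(gt1$karyotypes, gt3$karyotypes))
})

test_that("loss counts follow the binomial expectation over replicates", {
  # cross of two diploid founders: 2 species x 16 chroms x 2 copies = 64
  ref <- saccharomyces_reference(c("Scer", "Suva"))
  ped <- pedigree(data.frame(
    node = c("f1", "f2", "h"), role = c("founder", "founder", "hybrid"),
    parent1 = c(NA, NA, "f1"), parent2 = c(NA, NA, "f2"),
    species = c("Scer", "Suva", NA)))
  p <- 0.05
  n_copies <- 64
  losses <- vapply(1:1000, function(s) {
    gt <- simulate_pedigree_karyotypes(
      ped, ref, sim_params(loss_rate = p, gain_rate = 0, transloc_rate = 0,
                           seed = s))
    sum(gt$events$type == "loss")
  }, numeric(1))
  se <- sqrt(n_copies * p * (1 - p) / 1000)
  expect_lt(abs(mean(losses) - n_copies * p), 3 * se)
})

test_that("event logs reconcile parent sums with child karyotypes", {
  ref <- saccharomyces_reference(c("Scer", "Spar", "Smik", "Sarb"))
  ped <- pedigree(data.frame(
    node = c("f1", "f2", "f3", "f4", "h1", "h2", "h4", "e"),
    role = c(rep("founder", 4), "hybrid", "hybrid", "hybrid", "evolved"),
    parent1 = c(rep(NA, 4), "f1", "f3", "h1", "h4"),
    parent2 = c(rep(NA, 4), "f2", "f4", "h2", NA),
    species = c("Scer", "Spar", "Smik", "Sarb", rep(NA, 4))))
  for (seed in c(2, 23, 101)) {
    par <- sim_params(seed = seed, loss_rate = 0.08, gain_rate = 0.04,
                      transloc_rate = 0.03)
    gt <- simulate_pedigree_karyotypes(ped, ref, par)
    for (node in c("h1", "h2", "h4", "e")) {
      parents <- ped$node[match(node, ped$node)] # via pedigree columns
      i <- which(ped$node == node)
      pk <- gt$karyotypes[stats::na.omit(c(ped$parent1[i], ped$parent2[i]))]
      base <- expected_karyotype(pk, ref)
      ev <- gt$events[gt$events$node == node, ]
      delta <- gt$karyotypes[[node]]$copies$copies - base$copies$copies
      slot <- paste(base$copies$species, base$copies$chromosome, sep = "-")
      logged <- rep(0L, length(slot))
      for (j in seq_len(nrow(ev))) {
        if (ev$type[j] == "translocation") next
        k <- match(paste(ev$species[j], ev$chromosome[j], sep = "-"), slot)
        logged[k] <- logged[k] + ifelse(ev$type[j] == "gain", 1L, -1L)
      }
      expect_equal(delta, logged)
      # each new segment call corresponds to one logged translocation
      new_seg <- sum(!(paste(gt$karyotypes[[node]]$segments$species,
                             gt$karyotypes[[node]]$segments$chromosome) %in%
                       paste(base$segments$species,
                             base$segments$chromosome)))
      expect_equal(new_seg, sum(ev$type == "translocation"))
    }
  }
})

test_that("simulated coverage reflects copies, noise and dropout", {
  ref <- combined_reference(
    data.frame(species = "Aaa", chromosome = "chr1", length = 5e6), 10000)
  kar <- karyotype(data.frame(species = "Aaa", chromosome = "chr1",
                              copies = 3), ref)
  noiseless <- sim_params(noise_sigma = 0, mappability_dropout = 0,
                          depth_per_copy = 10, seed = 4)
  cov <- simulate_coverage(kar, ref, noiseless)
  expect_true(all(cov$mean_depth == 30))

  zero <- karyotype(data.frame(species = "Aaa", chromosome = "chr1",
                               copies = 0), ref)
  cov0 <- simulate_coverage(zero, ref, noiseless)
  expect_true(all(cov0$mean_depth == 0))

  # lognormal mean oracle: E[depth] = 30 * exp(sigma^2 / 2)
  noisy <- sim_params(noise_sigma = 0.2, mappability_dropout = 0,
                      depth_per_copy = 10, seed = 4)
  covn <- simulate_coverage(kar, ref, noisy, "n")
  mu <- 30 * exp(0.02)
  se <- mu * sqrt(exp(0.04) - 1) / sqrt(nrow(covn))
  expect_gte(nrow(covn), 500L)
  expect_lt(abs(mean(covn$mean_depth) - mu), 3 * se)

  drop <- sim_params(noise_sigma = 0, mappability_dropout = 0.1,
                     depth_per_copy = 10, seed = 4)
  covd <- simulate_coverage(kar, ref, drop, "d")
  fr <- mean(covd$mean_depth == 0)
  expect_lt(abs(fr - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(covd)))
})

test_that("segmented chromosomes get side-specific coverage", {
  ref <- combined_reference(
    data.frame(species = "Aaa", chromosome = "chr1", length = 1e6), 10000)
  kar <- karyotype(
    data.frame(species = "Aaa", chromosome = "chr1", copies = 3),
    ref,
    segments = data.frame(species = "Aaa", chromosome = "chr1",
                          breakpoint = 4e5, left_copies = 2L,
                          right_copies = 3L))
  par <- sim_params(noise_sigma = 0, mappability_dropout = 0,
                    depth_per_copy = 10, seed = 1)
  cov <- simulate_coverage(kar, ref, par)
  expect_true(all(cov$mean_depth[cov$end <= 4e5] == 20))
  expect_true(all(cov$mean_depth[cov$start >= 4e5] == 30))
})

test_that("mt coverage encodes homoplasmic, heteroplasmic and recombinant states", {
  ref <- tiny_reference()
  par <- sim_params(noise_sigma = 0, seed = 9)
  dpc <- par$depth_per_copy

  homo <- simulate_mt_coverage(
    list(class = "homoplasmic", donors = "Aaa", breakpoint_frac = NA),
    ref, par)
  amt <- homo[homo$species == "Aaa", ]
  bmt <- homo[homo$species == "Bbb", ]
  expect_true(all(amt$mean_depth == dpc))
  expect_true(all(bmt$mean_depth == 0))

  het <- simulate_mt_coverage(
    list(class = "heteroplasmic", donors = c("Aaa", "Bbb"),
         breakpoint_frac = NA), ref, par)
  expect_true(all(het$mean_depth == dpc))

  rec <- simulate_mt_coverage(
    list(class = "recombinant", donors = c("Aaa", "Bbb"),
         breakpoint_frac = 0.6), ref, par)
  a <- rec[rec$species == "Aaa", ]
  cov_frac <- mean(a$mean_depth > 0)
  expect_lt(abs(cov_frac - 0.6), 1 / nrow(a) + 1e-9) # within one window
  b <- rec[rec$species == "Bbb", ]
  expect_lt(abs(mean(b$mean_depth > 0) - 0.4), 1 / nrow(b) + 1e-9)
})

test_that("fluorescence is proportional to genome size", {
  p0 <- sim_params(fcm_cv = 0, seed = 5)
  a <- simulate_fcm(12e6, p0, n_events = 100)
  b <- simulate_fcm(24e6, p0, n_events = 100)
  expect_equal(unique(b) / unique(a), 2)
  expect_equal(simulate_fcm(12e6, p0, 10), simulate_fcm(12e6, p0, 10))

  p <- sim_params(fcm_cv = 0.05, seed = 5)
  x <- simulate_fcm(12e6, p, n_events = 1e4)
  cv <- sd(x) / mean(x)
  expect_gt(cv, 0.04)
  expect_lt(cv, 0.06)
})

test_that("growth curves honor mu, lag and the seed", {
  p <- sim_params(od_noise_sd = 0, seed = 7)
  flat <- simulate_growth_curve(0, p, background = 0.09, od_init = 0.05)
  expect_true(all(abs(flat$od - 0.14) < 1e-12))

  p2 <- sim_params(seed = 8)
  g1 <- simulate_growth_curve(0.3, p2, label = "a")
  g2 <- simulate_growth_curve(0.3, p2, label = "a")
  expect_identical(g1, g2)
  expect_error(simulate_growth_curve(-0.1, p2), ">= 0")

  # noiseless curve's steepest log-slope equals mu_true
  g <- simulate_growth_curve(0.25, p, lag_h = 2)
  lo <- log(g$od - 0.09)
  sl <- diff(lo) / diff(g$time_h)
  expect_equal(max(sl), 0.25, tolerance = 0.01)
})

test_that("cell areas follow the 2/3-power genome-size scaling", {
  p0 <- sim_params(area_cv = 0, seed = 2)
  expect_equal(unique(simulate_cell_areas(12e6, 12e6, 20, p0, n = 5)), 20)
  a <- simulate_cell_areas(12e6 * 3.375, 12e6, 20, p0, n = 3)
  expect_equal(unique(a) / 20, 2.25) # 3.375^(2/3)
  expect_length(simulate_cell_areas(5e7, 12e6, 20, sim_params(seed = 3),
                                    n = 17), 17L)
  expect_error(simulate_cell_areas(12e6, 12e6, 20, p0, n = 0), ">= 1")
})
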