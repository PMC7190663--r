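test_that("depth per copy by mass conservation and by density mode", {
  ref <- saccharomyces_reference("Scer")
  cov <- flat_coverage(ref, 30)
  # uniform 30x over 12.07 Mb, cytometry genome 2x: 30 * Gs / (2 Gs) = 15
  gs <- unname(genome_sizes(ref)["Scer"])
  expect_equal(estimate_depth_per_copy(cov, ref, genome_size_fcm = 2 * gs),
               15)

  # no cytometry: lowest substantial mode of the window means
  set.seed(21)
  modes <- sample(c(10, 20, 30), 1207, replace = TRUE) +
    rnorm(1207, 0, 0.3)
  cov2 <- flat_coverage(ref, function(n) modes[seq_len(n)])
  expect_equal(estimate_depth_per_copy(cov2, ref), 10, tolerance = 0.05)

  zero <- flat_coverage(ref, 0)
  expect_error(estimate_depth_per_copy(zero, ref), "all-zero")
  expect_error(estimate_depth_per_copy(cov, ref, genome_size_fcm = -1),
               "positive")
})

test_that("copy numbers are recovered exactly for levels 1..8 at zero noise", {
  ref <- saccharomyces_reference("Scer")
  nuc <- ref$chrom[!ref$chrom$mt, ]
  copies <- rep_len(1:8, nrow(nuc))
  kar <- karyotype(data.frame(species = nuc$species,
                              chromosome = nuc$chromosome,
                              copies = copies), ref)
  par <- sim_params(noise_sigma = 0, mappability_dropout = 0,
                    depth_per_copy = 12, seed = 1)
  cov <- simulate_coverage(kar, ref, par)
  called <- call_copy_numbers(cov, ref, 12)
  expect_equal(called$copies$copies, copies)

  # all-zero chromosome: 0 copies with the absent flag
  kar0 <- karyotype(data.frame(species = nuc$species,
                               chromosome = nuc$chromosome,
                               copies = c(0L, copies[-1])), ref)
  cov0 <- simulate_coverage(kar0, ref, par)
  called0 <- call_copy_numbers(cov0, ref, 12)
  expect_equal(called0$copies$copies[1], 0L)
  expect_equal(called0$copies$flag[1], "absent")
})

test_that("rounding is half away from zero and capped", {
  ref <- combined_reference(
    data.frame(species = "Aaa", chromosome = "chr1", length = 2e5), 10000)
  cov <- flat_coverage(ref, 6.5 * 10) # 6.5 copies at depth 10
  called <- call_copy_numbers(cov, ref, 10)
  expect_equal(called$copies$copies, 7L)
  cov2 <- flat_coverage(ref, 99 * 10)
  expect_equal(call_copy_numbers(cov2, ref, 10)$copies$copies, 12L)
})

test_that("the karyotype is invariant to depth rescaling", {
  ref <- saccharomyces_reference(c("Scer", "Suva"))
  par <- sim_params(seed = 31)
  ped <- example_pedigree()
  gt <- simulate_pedigree_karyotypes(
    pedigree(data.frame(node = c("f1", "f2", "h"),
                        role = c("founder", "founder", "hybrid"),
                        parent1 = c(NA, NA, "f1"), parent2 = c(NA, NA, "f2"),
                        species = c("Scer", "Suva", NA))), ref, par)
  cov <- simulate_coverage(gt$karyotypes$h, ref, par, "h")
  k1 <- call_karyotype(cov, ref, 30)
  c_scale <- 3.7
  cov2 <- cov
  cov2$mean_depth <- cov2$mean_depth * c_scale
  k2 <- call_karyotype(cov2, ref, 30 * c_scale)
  expect_equal(k1$copies, k2$copies)
  expect_equal(k1$segments, k2$segments)
})

test_that("called copies are monotone in true copies at zero noise", {
  ref <- combined_reference(
    data.frame(species = "Aaa", chromosome = "chr1", length = 5e5), 10000)
  par <- sim_params(noise_sigma = 0, mappability_dropout = 0,
                    depth_per_copy = 10, seed = 1)
  prev <- -1L
  for (cc in 0:12) {
    kar <- karyotype(data.frame(species = "Aaa", chromosome = "chr1",
                                copies = cc), ref)
    cov <- simulate_coverage(kar, ref, par)
    called <- call_copy_numbers(cov, ref, 10)$copies$copies
    expect_gte(called, prev)
    prev <- called
  }
})

test_that("changepoint detection finds arm-level copy steps", {
  ref <- combined_reference(
    data.frame(species = "Aaa", chromosome = "chr1", length = 1e6), 10000)

  const <- flat_coverage(ref, 30)
  expect_null(detect_unbalanced_translocations(const, ref, "Aaa", "chr1", 10))

  zero <- flat_coverage(ref, 0)
  expect_null(detect_unbalanced_translocations(zero, ref, "Aaa", "chr1", 10))

  # left 40% at 2 copies, right 60% at 3, lognormal noise sigma 0.1
  set.seed(55)
  truth <- c(rep(2, 40), rep(3, 60))
  depths <- truth * 10 * exp(rnorm(100, 0, 0.1))
  cov <- flat_coverage(ref, function(n) depths[seq_len(n)])
  call <- detect_unbalanced_translocations(cov, ref, "Aaa", "chr1", 10)
  expect_false(is.null(call))
  expect_equal(call$left_copies, 2L)
  expect_equal(call$right_copies, 3L)
  expect_lte(abs(call$breakpoint - 4e5), 10000) # within one window
})

test_that("changepoint calls match a brute-force SSE minimizer", {
  ws <- 10000
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(20:200, 1)
    len <- n * ws
    ref <- combined_reference(
      data.frame(species = "Aaa", chromosome = "chr1", length = len), ws)
    has_step <- seed %% 2 == 0
    base <- sample(1:6, 1)
    truth <- rep(base, n)
    if (has_step) {
      k <- sample(floor(n * 0.3):ceiling(n * 0.7), 1)
      truth[(k + 1):n] <- base + sample(c(-1, 1), 1)
      truth <- pmax(truth, 0)
    }
    depths <- truth * 10 * exp(rnorm(n, 0, 0.1))
    cov <- flat_coverage(ref, function(m) depths[seq_len(m)])
    call <- detect_unbalanced_translocations(cov, ref, "Aaa", "chr1", 10)

    y <- depths / 10
    ends <- (1:n) * ws
    oracle <- brute_force_changepoint(y, ends, len, 0.2, ws)
    if (!is.null(call)) {
      expect_equal(call$breakpoint, ends[oracle$k])
    } else if (!is.na(oracle$k)) {
      # no call must mean the oracle's best split fails a gate:
      # equal rounded sides or insufficient SSE reduction
      l <- y[1:oracle$k]
      r <- y[(oracle$k + 1):n]
      sse1 <- sum((y - mean(y))^2)
      gate_fail <- round(median(l[l > 0])) == round(median(r[r > 0])) ||
        sse1 / oracle$sse < 1.5
      expect_true(gate_fail)
    }
  }
})

test_that("cytometry ploidy estimation reads the G1 peak ratio", {
  p0 <- sim_params(fcm_cv = 0, seed = 6)
  a <- simulate_fcm(12e6, p0, n_events = 500)
  est <- estimate_ploidy_fcm(a, a, 12e6)
  expect_equal(est$fluorescence_ratio, 1)
  expect_equal(est$mean_copies, 1)

  b <- simulate_fcm(24e6, p0, n_events = 500)
  est2 <- estimate_ploidy_fcm(b, a, 12e6)
  expect_equal(est2$mean_copies, 2)
  expect_equal(est2$genome_size_fcm, 24e6)

  # fluorescence ratio 8: the mean-copies reading of the largest hybrid
  p <- sim_params(fcm_cv = 0.05, seed = 6)
  s8 <- simulate_fcm(8 * 12e6, p, n_events = 5000, label = "s8")
  hap <- simulate_fcm(12e6, p, n_events = 5000, label = "hap")
  est8 <- estimate_ploidy_fcm(s8, hap, 12e6)
  expect_equal(est8$mean_copies, 8, tolerance = 0.05)

  expect_error(estimate_ploidy_fcm(numeric(0), a, 12e6), "non-empty")
})

test_that("the G1 peak is found below a G2 population", {
  # mixture with a G2 peak at twice the G1 position and comparable mass
  set.seed(77)
  g1 <- rnorm(4000, 1000, 50)
  g2 <- rnorm(3000, 2000, 80)
  refv <- rnorm(4000, 500, 25)
  est <- estimate_ploidy_fcm(c(g1, g2), refv, 12e6)
  expect_equal(est$fluorescence_ratio, 2, tolerance = 0.05)
})

test_that("cytometry and karyotype genome sizes rank-agree on a cohort", {
  ref <- saccharomyces_reference()
  ped <- example_pedigree()
  par <- sim_params(seed = 13)
  gt <- simulate_pedigree_karyotypes(ped, ref, par)
  hap <- unname(genome_sizes(ref)["Scer"])
  refv <- simulate_fcm(hap, par, n_events = 3000, label = "hapref")
  nodes <- ped$node[ped$role != "founder"]
  gs_kar <- gs_fcm <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    n <- nodes[i]
    gs_true <- genome_size_from_karyotype(gt$karyotypes[[n]], ref)
    fl <- simulate_fcm(gs_true, par, n_events = 3000, label = n)
    pl <- estimate_ploidy_fcm(fl, refv, hap)
    cov <- simulate_coverage(gt$karyotypes[[n]], ref, par, n)
    dpc <- estimate_depth_per_copy(cov, ref, pl$genome_size_fcm)
    called <- call_karyotype(cov, ref, dpc)
    gs_kar[i] <- genome_size_from_karyotype(called, ref)
    gs_fcm[i] <- pl$genome_size_fcm
  }
  expect_gte(cor(gs_kar, gs_fcm, method = "spearman"), 0.9)
})
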