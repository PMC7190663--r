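#' Simulation parameters
#'
#' Controls for the synthetic allopolyploid generator. Event rates are per
#' chromosome copy (loss, gain) or per chromosome (translocation) per
#' cross; observation-noise parameters set how far each simulated readout
#' departs from its noiseless value.
#'
#' Defaults emulate the study conditions the package targets: 30x mean
#' depth per chromosome copy, lognormal window noise sigma 0.2, 2% of
#' windows zeroed by mappability dropout, losses more frequent than gains,
#' occasional heteroplasmy and a strong bias toward one parent's mitotype.
#'
#' @param depth_per_copy mean read depth contributed by one chromosome copy.
#' @param noise_sigma sd (log scale) of the multiplicative lognormal window
#'   noise.
#' @param mappability_dropout fraction of windows forced to depth 0.
#' @param loss_rate per-copy probability of loss at a cross.
#' @param gain_rate per-copy probability of duplication at a cross (gains
#'   duplicate an existing copy, so copy-0 chromosomes never gain).
#' @param transloc_rate per-chromosome probability of an unbalanced
#'   translocation at a cross.
#' @param heteroplasmy_prob probability both parental mitotype sets persist
#'   in a hybrid.
#' @param mt_bias probability that the designated donor (first parent)
#'   fixes its mitotype when heteroplasmy does not occur.
#' @param mt_recomb_prob probability of a recombinant mitotype when both
#'   parents are single-donor homoplasmic (and heteroplasmy did not occur).
#' @param fcm_cv coefficient of variation of simulated G1 fluorescence.
#' @param od_noise_sd additive sd of simulated OD readings.
#' @param area_cv lognormal coefficient of variation of simulated cell
#'   areas.
#' @param seed integer master seed; every simulator draws from a substream
#'   derived from `(seed, label)` so results are reproducible regardless of
#'   call order.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(depth_per_copy = 30, noise_sigma = 0.2,
                       mappability_dropout = 0.02, loss_rate = 0.05,
                       gain_rate = 0.02, transloc_rate = 0.01,
                       heteroplasmy_prob = 0.15, mt_bias = 0.8,
                       mt_recomb_prob = 0.05, fcm_cv = 0.05,
                       od_noise_sd = 0.002, area_cv = 0.2, seed = 1L) {
  p <- list(depth_per_copy = depth_per_copy, noise_sigma = noise_sigma,
            mappability_dropout = mappability_dropout, loss_rate = loss_rate,
            gain_rate = gain_rate, transloc_rate = transloc_rate,
            heteroplasmy_prob = heteroplasmy_prob, mt_bias = mt_bias,
            mt_recomb_prob = mt_recomb_prob, fcm_cv = fcm_cv,
            od_noise_sd = od_noise_sd, area_cv = area_cv,
            seed = as.integer(seed))
  probs <- c("mappability_dropout", "loss_rate", "gain_rate",
             "transloc_rate", "heteroplasmy_prob", "mt_bias",
             "mt_recomb_prob")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must be in [0, 1]")
  if (p$depth_per_copy <= 0) stop("depth_per_copy must be > 0")
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(p, class = "sim_params")
}

# Deterministic 31-bit substream seed from (seed, label); independent of
# traversal order because it hashes the label string.
derive_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(as.character(label)))
    h <- (h * 31 + c) %% 2147480009
  as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}

#' Simulate ground-truth karyotypes along a pedigree
#'
#' Walks the pedigree in topological order. Founders receive euploid
#' diploid karyotypes of their own species. Each hybrid starts from the
#' elementwise sum of its parents' karyotypes (whole-genome fusion); each
#' evolved isolate starts from its ancestor's karyotype. One round of
#' stochastic events is then applied in the fixed order loss, gain,
#' translocation, drawing from a PRNG substream keyed by `(seed, node)`.
#' Chromosomes already carrying a segment call are exempt from further
#' events, so each chromosome holds at most one breakpoint pedigree-wide.
#'
#' Mitotypes: founders are homoplasmic for their own species. At a cross,
#' with probability `heteroplasmy_prob` the union of both parents' donors
#' persists (heteroplasmic); otherwise, when both parents are single-donor
#' homoplasmic, a recombinant mitotype arises with probability
#' `mt_recomb_prob` (breakpoint fraction uniform in the middle 60%); in all
#' remaining cases one parent's mitotype state fixes, the first parent's
#' with probability `mt_bias`. Evolved isolates keep their ancestor's
#' state.
#'
#' @param ped a [pedigree]; founders must carry a `species` entry.
#' @param reference a [combined_reference].
#' @param params a [sim_params].
#' @return A list of class `ground_truth` with elements `karyotypes`
#'   (named list of [karyotype]), `mt_states` (named list with `class`,
#'   `donors`, `breakpoint_frac`), and `events` (data.frame `node`, `type`,
#'   `species`, `chromosome`, one row per event: one row per copy lost or
#'   gained, one row per translocation).
#' @export
simulate_pedigree_karyotypes <- function(ped, reference, params) {
  stopifnot(inherits(ped, "pedigree"), inherits(params, "sim_params"))
  topo <- attr(ped, "topo")
  kars <- list()
  mts <- list()
  events <- list()
  nuc <- reference$chrom[!reference$chrom$mt, , drop = FALSE]

  for (node in topo) {
    i <- which(ped$node == node)
    role <- ped$role[i]
    if (role == "founder") {
      sp <- ped$species[i]
      if (is.na(sp) || !nzchar(sp))
        stop("founder ", node, " has no species tag")
      kars[[node]] <- founder_karyotype(reference, sp)
      mts[[node]] <- list(class = "homoplasmic", donors = sp,
                          breakpoint_frac = NA_real_)
      next
    }
    parents <- pedigree_parents(ped, node)
    base <- expected_karyotype(kars[parents], reference)

    set.seed(derive_seed(params$seed, paste0("kar:", node)))
    cp <- base$copies
    seg <- base$segments
    segkey <- paste(seg$species, seg$chromosome, sep = "-")
    ev <- list()
    for (j in seq_len(nrow(cp))) {
      k <- paste(cp$species[j], cp$chromosome[j], sep = "-")
      if (k %in% segkey) next # segmented chromosomes are left untouched
      cc <- cp$copies[j]
      if (cc == 0L) next
      nl <- stats::rbinom(1L, cc, params$loss_rate)
      cc <- cc - nl
      ng <- 0L
      if (nl == 0L && cc > 0L)
        ng <- stats::rbinom(1L, cc, params$gain_rate)
      cc <- cc + ng
      cp$copies[j] <- cc
      if (nl + ng > 0L)
        ev[[length(ev) + 1L]] <- data.frame(
          node = node,
          type = rep(c("loss", "gain"), c(nl, ng)),
          species = cp$species[j], chromosome = cp$chromosome[j],
          stringsAsFactors = FALSE)
      if (cc > 0L && stats::runif(1L) < params$transloc_rate) {
        len <- nuc$length[nuc$species == cp$species[j] &
                          nuc$chromosome == cp$chromosome[j]]
        f <- stats::runif(1L, 0.2, 0.8)
        bp <- round(f * len)
        delta <- sample(c(-1L, 1L), 1L)
        # the shorter arm takes the change, so the slot-level (majority)
        # copy number is untouched by a translocation
        if (f < 0.5) {
          left <- cc + delta; right <- cc
        } else {
          left <- cc; right <- cc + delta
        }
        if (left >= 0L && right >= 0L) {
          seg <- rbind(seg, data.frame(
            species = cp$species[j], chromosome = cp$chromosome[j],
            breakpoint = bp, left_copies = left, right_copies = right,
            stringsAsFactors = FALSE))
          segkey <- c(segkey, k)
          ev[[length(ev) + 1L]] <- data.frame(
            node = node, type = "translocation",
            species = cp$species[j], chromosome = cp$chromosome[j],
            stringsAsFactors = FALSE)
        }
      }
    }
    cp$flag <- NA_character_
    kars[[node]] <- karyotype(cp, reference, seg)
    if (length(ev) > 0L) events[[node]] <- do.call(rbind, ev)

    # mitotype
    if (role == "evolved") {
      mts[[node]] <- mts[[parents[1L]]]
    } else {
      set.seed(derive_seed(params$seed, paste0("mt:", node)))
      m1 <- mts[[parents[1L]]]
      m2 <- mts[[parents[2L]]]
      u <- stats::runif(1L)
      if (u < params$heteroplasmy_prob) {
        donors <- union(m1$donors, m2$donors)
        mts[[node]] <- list(
          class = if (length(donors) > 1L) "heteroplasmic" else "homoplasmic",
          donors = donors, breakpoint_frac = NA_real_)
      } else if (m1$class == "homoplasmic" && m2$class == "homoplasmic" &&
                 length(m1$donors) == 1L && length(m2$donors) == 1L &&
                 m1$donors != m2$donors &&
                 stats::runif(1L) < params$mt_recomb_prob) {
        mts[[node]] <- list(class = "recombinant",
                            donors = c(m1$donors, m2$donors),
                            breakpoint_frac = stats::runif(1L, 0.2, 0.8))
      } else {
        pick <- if (stats::runif(1L) < params$mt_bias) m1 else m2
        mts[[node]] <- pick
      }
    }
  }
  ev <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(node = character(), type = character(), species = character(),
               chromosome = character(), stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  structure(list(karyotypes = kars, mt_states = mts, events = ev),
            class = "ground_truth")
}

#' Simulate windowed nuclear coverage for a karyotype
#'
#' Window mean depth is `copies * depth_per_copy` times a multiplicative
#' lognormal noise factor `exp(N(0, noise_sigma))`, with a
#' `mappability_dropout` fraction of windows forced to 0. Chromosomes at
#' copy 0 are all-zero; segmented chromosomes get side-specific copies
#' (window assigned by its midpoint relative to the breakpoint).
#'
#' @param kar a [karyotype].
#' @param reference a [combined_reference].
#' @param params a [sim_params].
#' @param label substream label (e.g. the node id) combined with
#'   `params$seed`.
#' @return A [windowed_coverage] over the nuclear chromosomes.
#' @export
simulate_coverage <- function(kar, reference, params, label = "") {
  stopifnot(inherits(kar, "karyotype"), inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, paste0("cov:", label)))
  ws <- reference$window_size
  nuc <- reference$chrom[!reference$chrom$mt, , drop = FALSE]
  out <- vector("list", nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    len <- nuc$length[i]
    nwin <- ceiling(len / ws)
    starts <- (seq_len(nwin) - 1) * ws
    ends <- pmin(starts + ws, len)
    prof <- karyotype_profile(kar, reference, nuc$species[i],
                              nuc$chromosome[i])
    mid <- (starts + ends) / 2
    copies <- prof$copies[findInterval(mid, prof$start)]
    depth <- copies * params$depth_per_copy
    if (params$noise_sigma > 0)
      depth <- depth * exp(stats::rnorm(nwin, 0, params$noise_sigma))
    if (params$mappability_dropout > 0)
      depth[stats::runif(nwin) < params$mappability_dropout] <- 0
    out[[i]] <- data.frame(
      species = nuc$species[i], chromosome = nuc$chromosome[i],
      start = starts, end = ends, mean_depth = depth,
      stringsAsFactors = FALSE)
  }
  windowed_coverage(do.call(rbind, out), reference)
}

#' Simulate mitochondrial windowed coverage
#'
#' Homoplasmic states cover the donor's mitochondrial genome fully and all
#' others not at all; heteroplasmic states cover each retained donor fully;
#' a recombinant state with breakpoint fraction f covers the first donor on
#' `[0, f * L)` of its own mt genome and the second donor on the
#' complementary tail of its genome.
#'
#' @param mt_state list with `class`, `donors`, `breakpoint_frac` (as in
#'   the `mt_states` of [simulate_pedigree_karyotypes()]).
#' @param reference a [combined_reference] containing mt chromosomes.
#' @param params a [sim_params] (covered windows get depth
#'   `depth_per_copy` with lognormal noise; no dropout is applied to mt
#'   windows).
#' @param label substream label.
#' @return A [windowed_coverage] over the mt chromosomes.
#' @export
simulate_mt_coverage <- function(mt_state, reference, params, label = "") {
  stopifnot(inherits(params, "sim_params"))
  mt <- reference$chrom[reference$chrom$mt, , drop = FALSE]
  if (nrow(mt) == 0L) stop("reference has no mt chromosomes")
  set.seed(derive_seed(params$seed, paste0("mt-cov:", label)))
  ws <- reference$window_size
  out <- vector("list", nrow(mt))
  for (i in seq_len(nrow(mt))) {
    len <- mt$length[i]
    nwin <- ceiling(len / ws)
    starts <- (seq_len(nwin) - 1) * ws
    ends <- pmin(starts + ws, len)
    mid <- (starts + ends) / 2
    sp <- mt$species[i]
    covered <- rep(FALSE, nwin)
    if (mt_state$class %in% c("homoplasmic", "heteroplasmic")) {
      if (sp %in% mt_state$donors) covered[] <- TRUE
    } else if (mt_state$class == "recombinant") {
      f <- mt_state$breakpoint_frac
      if (sp == mt_state$donors[1L]) covered <- mid < f * len
      if (sp == mt_state$donors[2L]) covered <- mid >= f * len
    }
    depth <- ifelse(covered, params$depth_per_copy, 0)
    if (params$noise_sigma > 0)
      depth <- depth * exp(stats::rnorm(nwin, 0, params$noise_sigma))
    out[[i]] <- data.frame(
      species = sp, chromosome = mt$chromosome[i],
      start = starts, end = ends, mean_depth = depth,
      stringsAsFactors = FALSE)
  }
  windowed_coverage(do.call(rbind, out), reference)
}

#' Simulate G1 fluorescence values
#'
#' Fluorescence is proportional to DNA content: each event is
#' `gain * genome_size_bp * (1 + e)` with `e ~ N(0, fcm_cv)`. The same
#' function called at the haploid reference genome size provides the
#' calibration sample.
#'
#' @param genome_size_bp genome size in bp.
#' @param params a [sim_params].
#' @param n_events number of cells (>= 1).
#' @param label substream label.
#' @param gain arbitrary detector gain (fluorescence units per bp).
#' @return Numeric vector of `n_events` fluorescence values.
#' @export
simulate_fcm <- function(genome_size_bp, params, n_events = 10000,
                         label = "", gain = 1e-4) {
  stopifnot(inherits(params, "sim_params"))
  if (n_events < 1) stop("n_events must be >= 1")
  set.seed(derive_seed(params$seed,
                       paste0("fcm:", label, ":", genome_size_bp)))
  base <- gain * genome_size_bp
  if (params$fcm_cv > 0)
    base * (1 + stats::rnorm(n_events, 0, params$fcm_cv))
  else rep(base, n_events)
}

#' Simulate an OD growth curve
#'
#' Logistic growth sampled every 15 minutes, parameterized so that the
#' steepest log-slope of the noiseless curve equals `mu_true` exactly: the
#' logistic rate is `mu_true / (1 - od_init / carrying_capacity)`, whose
#' specific growth rate at inoculation is `mu_true`. A flat lag of
#' `lag_h` hours precedes growth; a constant `background` absorbance and
#' additive Gaussian reading noise (`od_noise_sd`) are added.
#'
#' @param mu_true maximum specific growth rate, 1/h (>= 0).
#' @param params a [sim_params].
#' @param lag_h lag duration in hours.
#' @param carrying_capacity maximum culture OD.
#' @param background constant background absorbance.
#' @param od_init inoculation OD (above background).
#' @param duration_h total monitored time in hours.
#' @param dt_h sampling interval in hours (15 min default).
#' @param label substream label.
#' @return A data.frame of class `growth_curve` with columns `time_h`,
#'   `od`; the background used is stored in the `background` attribute.
#' @export
simulate_growth_curve <- function(mu_true, params, lag_h = 2,
                                  carrying_capacity = 1.2,
                                  background = 0.09, od_init = 0.05,
                                  duration_h = 48, dt_h = 0.25,
                                  label = "") {
  stopifnot(inherits(params, "sim_params"))
  if (mu_true < 0) stop("mu_true must be >= 0")
  set.seed(derive_seed(params$seed, paste0("growth:", label)))
  t <- seq(0, duration_h, by = dt_h)
  tau <- pmax(0, t - lag_h)
  n0 <- od_init
  k <- carrying_capacity
  if (mu_true == 0) {
    n <- rep(n0, length(t))
  } else {
    r <- mu_true / (1 - n0 / k)
    n <- k * n0 * exp(r * tau) / (k + n0 * (exp(r * tau) - 1))
  }
  od <- n + background
  if (params$od_noise_sd > 0)
    od <- od + stats::rnorm(length(t), 0, params$od_noise_sd)
  structure(data.frame(time_h = t, od = od),
            class = c("growth_curve", "data.frame"),
            background = background)
}

#' Simulate cell area measurements
#'
#' Mean cell volume is taken proportional to genome size; for spherical
#' cells the projected area then scales as the 2/3 power of the genome-size
#' ratio. Individual areas are lognormal around
#' `ref_area * (genome_size_bp / ref_size_bp)^(2/3)` with coefficient of
#' variation `area_cv` (mean-corrected, so the noiseless mean equals the
#' scaling law exactly).
#'
#' @param genome_size_bp strain genome size in bp.
#' @param ref_size_bp reference genome size in bp.
#' @param ref_area mean cell area of the reference strain (um^2).
#' @param params a [sim_params].
#' @param n number of cells (>= 1).
#' @param label substream label.
#' @return Numeric vector of `n` areas (um^2).
#' @export
simulate_cell_areas <- function(genome_size_bp, ref_size_bp, ref_area,
                                params, n = 60, label = "") {
  stopifnot(inherits(params, "sim_params"))
  if (n < 1) stop("n must be >= 1")
  set.seed(derive_seed(params$seed, paste0("area:", label)))
  m <- ref_area * (genome_size_bp / ref_size_bp)^(2 / 3)
  if (params$area_cv > 0) {
    s <- sqrt(log(1 + params$area_cv^2))
    m * stats::rlnorm(n, -s^2 / 2, s)
  } else rep(m, n)
}
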