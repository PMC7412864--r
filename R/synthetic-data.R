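# Seeded generators emulating every measured input of a PBAE screening
# study: a block-correlated descriptor matrix with latent structure, uptake
# replicates, transient permeation traces, and GAG timecourses. All are pure
# functions of (config, seed) so downstream stages have known ground truth.

#' Configuration for the synthetic PBAE library generator
#'
#' The defaults mirror a combinatorial library of 3 diacrylates x 12 amines
#' (36 backbones, each testable with two end-capping agents) characterised by
#' ~30 physicochemical descriptors whose strong mutual correlations arise
#' from a low-dimensional latent structure.
#'
#' @param n_amines Number of amine monomers (default 12).
#' @param n_acrylates Number of diacrylate monomers (default 3; coded A, B,
#'   C, ...).
#' @param n_descriptors Number of descriptor columns (default 30).
#' @param n_latent Number of latent chemical factors driving both descriptors
#'   and uptake (default 5); must not exceed `n_descriptors`.
#' @param block_correlation Target within-block descriptor correlation in
#'   `[0, 1)` (default 0.7). Descriptors are assigned round-robin to
#'   `n_latent` blocks; two descriptors in the same block share a latent
#'   factor and correlate at this level, between blocks they are independent.
#' @param noise_sd_x Standard deviation of descriptor measurement noise
#'   (default 0.5). With `noise_sd_x = 0` the descriptor matrix is exactly
#'   rank `n_latent`.
#' @param noise_sd_y Standard deviation of log-uptake-ratio noise
#'   (default 0.1).
#' @param loadings_seed,noise_seed Seeds for the loading draw and the noise
#'   draw; splitting them lets one redraw noise under fixed loadings.
#' @return A validated list of class `library_sim_config`.
#' @export
library_sim_config <- function(n_amines = 12L, n_acrylates = 3L,
                               n_descriptors = 30L, n_latent = 5L,
                               block_correlation = 0.7,
                               noise_sd_x = 0.5, noise_sd_y = 0.1,
                               loadings_seed = 1L, noise_seed = 2L) {
  cfg <- list(n_amines = as.integer(n_amines),
              n_acrylates = as.integer(n_acrylates),
              n_descriptors = as.integer(n_descriptors),
              n_latent = as.integer(n_latent),
              block_correlation = block_correlation,
              noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
              loadings_seed = as.integer(loadings_seed),
              noise_seed = as.integer(noise_seed))
  with(cfg, {
    if (n_amines < 1L || n_acrylates < 1L) stop("need >= 1 amine and acrylate")
    if (n_latent < 1L || n_latent > n_descriptors) {
      stop("n_latent must be in [1, n_descriptors]")
    }
    if (block_correlation < 0 || block_correlation >= 1) {
      stop("block_correlation must be in [0, 1)")
    }
    if (noise_sd_x < 0 || noise_sd_y < 0) stop("noise sds must be >= 0")
  })
  structure(cfg, class = "library_sim_config")
}

#' Generate a synthetic PBAE library with known ground truth
#'
#' Draws latent scores `T` (backbones x latent factors, standard normal),
#' builds descriptors `X = T P' + E` with block-structured loadings `P`
#' calibrated so that same-block descriptor pairs correlate at
#' `block_correlation`, and uptake-ratio responses for the two end-capping
#' agents as `r = exp(T Q' + F)` — positive and log-linear in the latent
#' scores, so the log ratio is the natural modelling scale.
#'
#' @param config A [library_sim_config()].
#' @return A list with elements `descriptors` (a [descriptor_table()] of the
#'   backbones), `responses` (data frame: `polymer_id`, `e1`, `e2` uptake
#'   ratios), and `truth` (list: `latent_scores`, `x_loadings`, `y_loadings`,
#'   `true_uptake_ratio`, `descriptor_block`).
#' @export
generate_library <- function(config = library_sim_config()) {
  stopifnot(inherits(config, "library_sim_config"))
  n <- config$n_amines * config$n_acrylates
  p <- config$n_descriptors
  L <- config$n_latent
  rho <- config$block_correlation

  acr <- LETTERS[(seq_len(n) - 1L) %/% config$n_amines + 1L]
  ami <- (seq_len(n) - 1L) %% config$n_amines + 1L
  ids <- format_polymer_id(acr, ami, "none")

  block <- (seq_len(p) - 1L) %% L + 1L
  # loading magnitude giving within-block correlation rho at this noise level
  lambda <- if (config$noise_sd_x == 0) 1 else {
    config$noise_sd_x * sqrt(rho / (1 - rho))
  }

  withr_seed(config$loadings_seed, {
    sgn <- sample(c(-1, 1), p, replace = TRUE)
    Q <- matrix(stats::rnorm(L * 2L, sd = 0.6 / sqrt(L)), nrow = L, ncol = 2L,
                dimnames = list(NULL, c("e1", "e2")))
  })
  P <- matrix(0, nrow = p, ncol = L)
  P[cbind(seq_len(p), block)] <- sgn * lambda

  withr_seed(config$noise_seed, {
    Tm <- matrix(stats::rnorm(n * L), nrow = n, ncol = L)
    E <- matrix(stats::rnorm(n * p, sd = config$noise_sd_x), nrow = n)
    Fm <- matrix(stats::rnorm(n * 2L, sd = config$noise_sd_y), nrow = n)
  })

  X <- Tm %*% t(P) + E
  colnames(X) <- sprintf("desc_%02d", seq_len(p))
  meta <- rep(c("amine", "acrylate", "repeat_unit", "experimental"),
              length.out = p)
  eta <- Tm %*% Q
  ratio <- exp(eta + Fm)
  true_ratio <- exp(eta)

  list(
    descriptors = descriptor_table(X, polymer_ids = ids, column_meta = meta),
    responses = data.frame(polymer_id = ids, e1 = ratio[, 1L],
                           e2 = ratio[, 2L], stringsAsFactors = FALSE),
    truth = list(latent_scores = Tm, x_loadings = P, y_loadings = Q,
                 true_uptake_ratio = stats::setNames(
                   as.data.frame(true_ratio), c("e1", "e2")),
                 descriptor_block = block)
  )
}

# run code under a temporary RNG state; restores .Random.seed afterwards
withr_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Simulate a replicated drug-uptake experiment
#'
#' Emulates the paired-arm uptake measurement: a reference arm (the clinical
#' phosphate prodrug formulation) and a conjugate arm whose expected uptake is
#' `true_ratio` times the reference. Replicates are lognormal around the arm
#' mean — uptake is a positive mass-per-mass quantity, and multiplicative
#' noise cannot produce negative masses at realistic coefficients of
#' variation. The lognormal is parameterised so the arithmetic arm mean is
#' exact: `sdlog = sqrt(log(1 + cv^2))`, `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param true_ratio Positive scalar (or vector over time points): expected
#'   conjugate/reference uptake ratio.
#' @param n_reps Replicates per arm and time point (default 3, >= 2).
#' @param cv Coefficient of variation of replicate noise (>= 0).
#' @param seed Integer seed.
#' @param times Exposure times in minutes (default `c(1, 5, 10)`).
#' @param reference_mean Expected reference-arm uptake, ug drug per mg wet
#'   cartilage (default 0.5).
#' @return Data frame with columns `arm`, `time_min`, `replicate`,
#'   `uptake_ug_per_mg`.
#' @export
simulate_uptake_experiment <- function(true_ratio, n_reps = 3L, cv = 0.1,
                                       seed = 1L, times = c(1, 5, 10),
                                       reference_mean = 0.5) {
  if (n_reps < 2L) stop("n_reps must be >= 2 (downstream t-test needs >= 2)")
  if (cv < 0) stop("cv must be >= 0")
  if (any(true_ratio <= 0)) stop("true_ratio must be positive")
  true_ratio <- rep_len(true_ratio, length(times))
  draw <- function(m, k) {
    if (cv == 0) return(rep(m, k))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(k, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  withr_seed(seed, {
    rows <- lapply(seq_along(times), function(i) {
      rbind(
        data.frame(arm = "reference", time_min = times[i],
                   replicate = seq_len(n_reps),
                   uptake_ug_per_mg = draw(reference_mean, n_reps)),
        data.frame(arm = "conjugate", time_min = times[i],
                   replicate = seq_len(n_reps),
                   uptake_ug_per_mg = draw(true_ratio[i] * reference_mean,
                                           n_reps))
      )
    })
    do.call(rbind, rows)
  })
}

#' Transient one-way membrane permeation solution
#'
#' Receiver/donor fluorescence ratio for one-way diffusion through a slab of
#' thickness `delta` at diffusivity `D`, in the classical time-lag form:
#' \deqn{R(t) = K \delta \left[\frac{D t}{\delta^2} - \frac{1}{6}
#'   - \frac{2}{\pi^2} \sum_{n=1}^{N} \frac{(-1)^n}{n^2}
#'   e^{-D n^2 \pi^2 t / \delta^2}\right]}
#' truncated at `n_terms` and clipped at zero. Its late-time asymptote is the
#' straight line `K D / delta * (t - t_lag)` with break-through time
#' `t_lag = delta^2 / (6 D)`.
#'
#' @param times Times, minutes.
#' @param D Diffusion coefficient, mm^2/min.
#' @param delta Slab thickness, mm.
#' @param K Steady-state scale factor absorbing partition coefficient and
#'   instrument gain (default 1).
#' @param n_terms Series truncation (default 50).
#' @return Numeric vector of ratios (>= 0).
#' @export
permeation_series <- function(times, D, delta, K = 1, n_terms = 50L) {
  stopifnot(D > 0, delta > 0)
  n <- seq_len(n_terms)
  s <- vapply(times, function(t) {
    sum(((-1)^n / n^2) * exp(-D * n^2 * pi^2 * t / delta^2))
  }, 0)
  r <- K * delta * (D * times / delta^2 - 1 / 6 - (2 / pi^2) * s)
  pmax(r, 0)
}

#' Simulate a fluorescence-ratio permeation trace
#'
#' Forward model for the diffusion-coefficient experiment: the noiseless
#' trace follows [permeation_series()]; Gaussian measurement noise is added
#' and the ratio re-clipped at zero (fluorescence ratios cannot be negative).
#'
#' @param D True diffusion coefficient, mm^2/min (> 0).
#' @param thickness Cartilage sample thickness, mm (> 0; the study's disks
#'   are ~0.4 mm).
#' @param times Strictly increasing, nonnegative sampling times (minutes).
#' @param noise_sd Gaussian noise SD on the ratio axis (>= 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param K Steady-state scale factor (default 1).
#' @param polymer,replicate Optional labels carried into the trace.
#' @return An object of class `diffusion_trace`: list with `times`, `ratio`,
#'   `thickness`, `polymer`, `replicate`.
#' @export
simulate_diffusion_trace <- function(D, thickness, times, noise_sd = 0,
                                     seed = 1L, K = 1, polymer = NA_character_,
                                     replicate = 1L) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times < 0)) stop("times must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  r <- permeation_series(times, D = D, delta = thickness, K = K)
  if (noise_sd > 0) {
    withr_seed(seed, r <- r + stats::rnorm(length(r), sd = noise_sd))
    r <- pmax(r, 0)
  }
  diffusion_trace(times = times, ratio = r, thickness = thickness,
                  polymer = polymer, replicate = replicate)
}

#' Simulate GAG content timecourses for treatment groups
#'
#' Each sample's glycosaminoglycan content follows exponential growth or
#' decay, `GAG(t) = GAG(0) exp(rate t) (1 + eps)`, sampled on the study's
#' measurement days. A positive rate emulates matrix accretion in healthy
#' explants; a negative rate emulates cytokine-driven degradation.
#'
#' @param group_rates Named numeric vector: per-day exponential rate for each
#'   treatment group. `gag_study_rates()` gives a set echoing the study's
#'   observed endpoints.
#' @param n_samples Samples per group (default 6, >= 2).
#' @param noise_sd Relative measurement noise SD (>= 0).
#' @param seed Integer seed.
#' @param days Measurement days (default `c(0, 2, 4, 6, 8)`).
#' @param baseline_gag Mean day-0 GAG content, ug per sample (default 40).
#' @return Data frame with columns `group`, `sample_id`, `day`, `gag_ug`.
#' @export
simulate_gag_timecourses <- function(group_rates, n_samples = 6L,
                                     noise_sd = 0.05, seed = 1L,
                                     days = c(0, 2, 4, 6, 8),
                                     baseline_gag = 40) {
  if (is.null(names(group_rates)) || any(!nzchar(names(group_rates)))) {
    stop("group_rates must be a named vector")
  }
  if (n_samples < 2L) stop("n_samples must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  withr_seed(seed, {
    out <- lapply(names(group_rates), function(g) {
      rate <- group_rates[[g]]
      do.call(rbind, lapply(seq_len(n_samples), function(s) {
        eps <- if (noise_sd == 0) rep(0, length(days)) else {
          stats::rnorm(length(days), sd = noise_sd)
        }
        data.frame(group = g,
                   sample_id = sprintf("%s_%02d", g, s),
                   day = days,
                   gag_ug = baseline_gag * exp(rate * days) * (1 + eps),
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, out)
  })
}

#' Study-condition GAG rates
#'
#' Per-day exponential rates reproducing the observed 8-day endpoints of the
#' ex vivo post-traumatic model: healthy controls gain up to ~70% GAG,
#' IL-1alpha-treated explants lose >50%, continuous steroid delivery rescues
#' to control level, polymer alone holds GAG at baseline, and a single
#' steroid dose limits the loss to ~10%.
#'
#' @return Named numeric vector of per-day rates.
#' @export
gag_study_rates <- function() {
  c(control          = log(1.7) / 8,
    il1a             = log(0.5) / 8,
    il1a_dex_cont    = log(1.7) / 8,
    il1a_pbae        = 0,
    il1a_dex_single  = log(0.9) / 8)
}

#' Write a complete simulated study bundle
#'
#' Emits every synthetic input as CSV into a directory: descriptor table,
#' uptake-ratio responses, per-polymer uptake replicates, permeation traces,
#' and GAG timecourses. Used by the end-to-end pipeline and handy for
#' exercising the file-based interfaces.
#'
#' @param dir Output directory (created if absent).
#' @param config A [library_sim_config()].
#' @param seed Master seed. Drives the measurement-level generators and
#'   offsets the library's `loadings_seed`/`noise_seed`, so different seeds
#'   give independent replicates of the same design family.
#' @return Named character vector of written file paths, invisibly.
#' @export
write_study_bundle <- function(dir, config = library_sim_config(), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  offset <- 17L * (as.integer(seed) %% 1000000L)  # keep well inside 32 bits
  cfg$loadings_seed <- config$loadings_seed + offset
  cfg$noise_seed <- config$noise_seed + offset + 1L
  lib <- generate_library(cfg)
  paths <- c(descriptors = file.path(dir, "descriptors.csv"),
             responses = file.path(dir, "responses.csv"),
             uptake = file.path(dir, "uptake_measurements.csv"),
             traces = file.path(dir, "diffusion_traces.csv"),
             gag = file.path(dir, "gag_timecourses.csv"))
  write_descriptor_table(lib$descriptors, paths[["descriptors"]])
  utils::write.csv(lib$responses, paths[["responses"]], row.names = FALSE)

  n <- nrow(lib$responses)
  upt <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(c("e1", "e2"), function(ec) {
      u <- simulate_uptake_experiment(lib$responses[[ec]][i],
                                      seed = seed + 7L * i +
                                        ifelse(ec == "e1", 0L, 1L))
      cbind(polymer_id = lib$responses$polymer_id[i], endcap = ec, u)
    }))
  }))
  utils::write.csv(upt, paths[["uptake"]], row.names = FALSE)

  withr_seed(seed, {
    Dtrue <- 10^stats::runif(n, -3.5, -2.5)  # mm^2/min, one decade
  })
  tr <- do.call(rbind, lapply(seq_len(n), function(i) {
    tl <- 0.4^2 / (6 * Dtrue[i])
    tt <- seq(0, 10 * tl, length.out = 60L)
    trc <- simulate_diffusion_trace(Dtrue[i], 0.4, tt, noise_sd = 0.01,
                                    seed = seed + 13L * i,
                                    polymer = lib$responses$polymer_id[i])
    data.frame(polymer_id = trc$polymer, replicate = trc$replicate,
               time_min = trc$times, ratio = trc$ratio, thickness_mm = 0.4)
  }))
  utils::write.csv(tr, paths[["traces"]], row.names = FALSE)

  gag <- simulate_gag_timecourses(gag_study_rates(), seed = seed + 101L)
  utils::write.csv(gag, paths[["gag"]], row.names = FALSE)
  invisible(paths)
}
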