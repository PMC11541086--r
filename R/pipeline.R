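# Study orchestration: a single self-describing config drives
# generate -> analyze -> compare -> report on synthetic two-cohort studies,
# with a seed and config hash embedded in every output artifact.

.default_config <- function() {
  list(
    species_profile = NULL,          # mandatory: "human" or "mouse"
    seed = 1,
    force = FALSE,
    bands = NULL,                    # filled from the profile
    cohorts = list(
      control = list(coupling = list(), seed_offset = 0),
      carrier = list(coupling = list(), seed_offset = 100000)),
    n_subjects = 12,
    analysis = list(
      fs = 250, duration = 30,
      coherence_L = 500, taper = "hann",
      pac_bins = 18,
      wavelet_freqs = 1:100, n_cycles = 3),
    stages = c("coherence", "pac", "power", "microstates", "evoked"),
    microstates = list(k = 4, n_restarts = 20, duration = 30, fs = 250,
                       mean_dwell = 100, snr = 5),
    evoked = list(n_epochs = 20, pre = 0.5, post = 2.5, fs = 250,
                  noise_sd = 0.1, response = list(amp = 1, freq = 10, decay = 0.3)),
    compare = list(n_mcmc = 100000, burn = 2000)
  )
}

.check_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown config key: ", paste0(path, extra[1]))
  for (nm in intersect(names(cfg), c("analysis", "microstates", "evoked", "compare")))
    .check_keys(cfg[[nm]], ref[[nm]], paste0(nm, "$"))
}

#' Validate and normalize a study configuration
#'
#' Fills documented defaults, enforces the mandatory species profile,
#' rejects unknown keys (naming the offending path), and guards against
#' profile/band mismatches: bands inconsistent with the chosen profile are
#' an error unless `force = TRUE`. Idempotent:
#' `validate_config(validate_config(x))` equals `validate_config(x)`.
#'
#' @param config a (partial) configuration list, or a path to a JSON file.
#' @return the normalized configuration (class `study_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (inherits(config, "study_config")) config <- unclass(config)
  ref <- .default_config()
  .check_keys(config, ref)
  cfg <- utils::modifyList(ref, config)
  if (!is.null(config$cohorts)) cfg$cohorts <- config$cohorts   # replace, not merge
  if (is.null(cfg$species_profile))
    stop("species_profile is mandatory (\"human\" or \"mouse\")")
  cfg$species_profile <- match.arg(cfg$species_profile, c("human", "mouse"))
  profile_bands <- band_profile(cfg$species_profile)
  cfg$bands <- utils::modifyList(profile_bands,
                                 lapply(as.list(cfg$bands %||% list()), as.numeric))
  mismatch <- !isTRUE(all.equal(unname(cfg$bands$theta),
                                unname(profile_bands$theta)))
  if (mismatch && !isTRUE(cfg$force))
    stop(sprintf("theta band %g-%g Hz does not match the %s profile (%g-%g Hz); set force = TRUE to override",
                 cfg$bands$theta[1], cfg$bands$theta[2], cfg$species_profile,
                 profile_bands$theta[1], profile_bands$theta[2]))
  cfg$stages <- match.arg(cfg$stages,
                          c("coherence", "pac", "power", "microstates", "evoked"),
                          several.ok = TRUE)
  structure(cfg, class = "study_config")
}

# small rolling polynomial hash over the serialized config (no external
# digest package in the dependency set)
.config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

.study_measures_subject <- function(cfg, cohort, subj_seed, topographies) {
  an <- cfg$analysis
  prof <- cfg$species_profile
  phase_freq <- if (prof == "mouse") 10 else 5
  base_spec <- list(theta_freq = phase_freq, gamma_freq = 60,
                    theta_amp = 1, gamma_amp = 0.5, d = 0.5, w = 0.3,
                    noise_sd = 0.5, fs = an$fs, duration = an$duration,
                    theta_band = cfg$bands$theta, gamma_band = cfg$bands$gamma)
  spec_args <- utils::modifyList(base_spec, cohort$coupling)
  spec_args$seed <- subj_seed
  pair <- gen_coupled_pair(do.call(coupling_spec, spec_args))
  xa <- as.numeric(pair$region_A$data[1, ])
  xb <- as.numeric(pair$region_B$data[1, ])
  out <- list()
  if ("coherence" %in% cfg$stages) {
    ch <- coherence(xa, xb, L = an$coherence_L, fs = an$fs, taper = an$taper)
    out$coherence_theta <- band_summary(ch, cfg$bands$theta)$mean_value
    out$coherence_gamma <- band_summary(ch, cfg$bands$gamma)$mean_value
  }
  if ("pac" %in% cfg$stages) {
    out$pac_m <- pac_binned(xa, xb, phase_freq = spec_args$theta_freq,
                            amp_band = cfg$bands$gamma, n_bins = an$pac_bins,
                            fs = an$fs,
                            direction = c("region_A", "region_B"))$modulation_index
  }
  if ("power" %in% cfg$stages) {
    wp <- wavelet_power(xa, an$fs, freqs = an$wavelet_freqs,
                        n_cycles = an$n_cycles)
    out$theta_power <- band_summary(wp, cfg$bands$theta)$mean_value
    wpb <- wavelet_power(xb, an$fs, freqs = an$wavelet_freqs,
                         n_cycles = an$n_cycles)
    out$gamma_power <- band_summary(wpb, cfg$bands$gamma)$mean_value
  }
  if ("microstates" %in% cfg$stages) {
    ms <- cfg$microstates
    mspec <- microstate_spec(topographies, mean_dwell = ms$mean_dwell,
                             fs = ms$fs, duration = ms$duration, snr = ms$snr,
                             seed = subj_seed + 7)
    sim <- gen_microstate_eeg(mspec)
    st <- microstate_stats(backfit(sim$eeg,
                                   cluster_topographies(
                                     average_reference(sim$eeg)$data[, find_gfp_peaks(gfp(sim$eeg), 2), drop = FALSE],
                                     k = ms$k, n_restarts = ms$n_restarts,
                                     seed = subj_seed + 11)),
                           ms$fs)
    out$microstate_duration <- mean(st$duration_ms)
    out$microstate_occurrence <- mean(st$occurrence_per_s)
  }
  if ("evoked" %in% cfg$stages) {
    ev <- cfg$evoked
    resp <- ev$response
    if (!is.null(cohort$coupling$gamma_amp))   # scale evoked with cohort drive
      resp$amp <- resp$amp * cohort$coupling$gamma_amp / 0.5
    ep <- gen_evoked_epochs(ev$n_epochs, ev$pre, ev$post, ev$fs,
                            response_spec = resp, seed = subj_seed + 13,
                            noise_sd = ev$noise_sd)
    out$gmfp_peak <- max(gmfp(ep)$gmfp)
  }
  out
}

#' Run an end-to-end synthetic-cohort study
#'
#' Generates two synthetic cohorts from the config's coupling (and
#' microstate / evoked) parameters, derives per-subject measures with the
#' spectral, PAC, microstate and evoked modules, and compares every measure
#' between cohorts with the Bayesian two-group model. All randomness derives
#' from `config$seed` plus per-cohort `seed_offset`s; two cohorts with
#' identical parameters and identical offsets produce literally identical
#' subjects (a deterministic null).
#'
#' @param config a [validate_config()]-ready configuration.
#' @param out_dir optional directory; when given, writes `scores.csv`,
#'   `comparisons.csv` and `manifest.json` (config hash, seed, package
#'   version).
#' @return list with `scores` (tidy per-subject table), `comparisons` (a
#'   `comparison_table`), `config`, and `manifest`.
#' @export
run_study <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  topo <- random_topographies(19, cfg$microstates$k, seed = cfg$seed + 3)
  scores <- list()
  for (ci in seq_along(cfg$cohorts)) {
    cohort <- cfg$cohorts[[ci]]
    cname <- names(cfg$cohorts)[ci]
    off <- cohort$seed_offset %||% ((ci - 1) * 100000)
    for (si in seq_len(cfg$n_subjects)) {
      subj_seed <- (cfg$seed %% 100000) * 20000 + off + si * 17
      m <- tryCatch(
        .study_measures_subject(cfg, cohort, subj_seed, topo),
        error = function(e) stop("stage failure for cohort '", cname,
                                 "' subject ", si, ": ", conditionMessage(e)))
      scores[[length(scores) + 1]] <-
        data.frame(measure = names(m), group = cname,
                   subject = sprintf("%s_%02d", cname, si),
                   value = as.numeric(unlist(m)))
    }
  }
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL
  comparisons <- compare_table(scores[, c("measure", "group", "value")],
                               n_mcmc = cfg$compare$n_mcmc,
                               burn = cfg$compare$burn, seed = cfg$seed)
  manifest <- list(package = "oscbayes",
                   version = as.character(utils::packageVersion("oscbayes")),
                   seed = cfg$seed, config_hash = .config_hash(unclass(cfg)),
                   species_profile = cfg$species_profile,
                   stages = cfg$stages,
                   n_subjects = cfg$n_subjects)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(comparisons),
                     file.path(out_dir, "comparisons.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(scores = scores, comparisons = comparisons, config = cfg,
       manifest = manifest)
}

#' Write / read epochs as delimited text plus a JSON sidecar
#'
#' Epochs are stored as a channels-by-(samples x epochs) matrix (epochs
#' concatenated along columns) with a sidecar recording `fs`, `t0_index`,
#' `n_epochs` and labels.
#'
#' @param ep an [epochs()] object.
#' @param path matrix file path; sidecar at `paste0(path, ".json")`.
#' @return `write_epochs` the path invisibly; `read_epochs` an `epochs`.
#' @export
write_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "epochs"))
  d <- dim(ep$data)
  m <- matrix(ep$data, d[1], d[2] * d[3])
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = ep$fs, t0_index = which.min(abs(ep$time)),
                            n_epochs = d[3], n_samples = d[2],
                            channel_labels = ep$channel_labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  arr <- array(m, dim = c(nrow(m), meta$n_samples, meta$n_epochs))
  epochs(arr, fs = meta$fs, t0_index = meta$t0_index,
         channel_labels = meta$channel_labels)
}
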