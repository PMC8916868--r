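#' Configuration of the end-to-end studies
#'
#' Bundles every tunable of the two study pipelines: the B-mode phantom and
#' noise levels of the denoising benchmark, the elasticity phantom, cohort
#' and shell widths of the simulated SWE diagnostic study, and one global
#' seed from which each stage derives its own child seed (so stages are
#' independently reproducible).
#'
#' @param phantom [skin_phantom_spec()] for the benchmark image.
#' @param noise_sigmas Noise standard deviations swept by the benchmark.
#' @param n_seeds Noise realizations per sigma.
#' @param cfg_classic,cfg_improved [nlm_config()]s for the two denoisers.
#' @param admm [admm_config()] for the improved denoiser.
#' @param elasticity [elasticity_phantom_spec()] template for the SWE study.
#' @param cohort [cohort_spec()] for the simulated subjects; its `base_mean`
#'   and `base_sd` describe the subject-level lesion modulus (kPa).
#' @param shell_widths_mm Shell widths at which modulus statistics are read.
#' @param stage_counts Named lesion counts per pathological stage.
#' @param thickness_base_mm,thickness_sd_mm Control-group dermal thickness
#'   mean and SD used in the thickness comparison arm.
#' @param seed Global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = skin_phantom_spec(),
                       noise_sigmas = c(10, 15, 20, 25),
                       n_seeds = 10L,
                       cfg_classic = nlm_config(gamma = 0),
                       cfg_improved = nlm_config(),
                       admm = admm_config(),
                       elasticity = elasticity_phantom_spec(),
                       cohort = cohort_spec(base_mean = 60, base_sd = 8,
                                            effect_size = 3),
                       shell_widths_mm = c(1, 2),
                       stage_counts = c(edema = 7, sclerotic = 42,
                                        atrophic = 47),
                       thickness_base_mm = 2, thickness_sd_mm = 0.3,
                       seed = 1L) {
  structure(list(phantom = phantom, noise_sigmas = noise_sigmas,
                 n_seeds = as.integer(n_seeds), cfg_classic = cfg_classic,
                 cfg_improved = cfg_improved, admm = admm,
                 elasticity = elasticity, cohort = cohort,
                 shell_widths_mm = shell_widths_mm,
                 stage_counts = stage_counts,
                 thickness_base_mm = thickness_base_mm,
                 thickness_sd_mm = thickness_sd_mm,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration as JSON
#'
#' The JSON round trip preserves every field: `load_run_config(save_run_config(cfg))`
#' reproduces `cfg`.
#'
#' @param cfg A [run_config()].
#' @param path JSON file path.
#' @return `save_run_config` returns `path` invisibly; `load_run_config`
#'   returns the rebuilt `run_config`.
#' @export
save_run_config <- function(cfg, path) {
  if (!inherits(cfg, "run_config")) abort_validation("`cfg` must be a run_config")
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x))) as.list(x)  # keep names of named vectors
    else x
  }
  jsonlite::write_json(strip(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(constructor, fields) do.call(constructor, fields)
  li <- raw$phantom$layer_intensities
  run_config(
    phantom = rebuild(skin_phantom_spec,
                      utils::modifyList(raw$phantom,
                                        list(layer_intensities = unlist(li)))),
    noise_sigmas = raw$noise_sigmas,
    n_seeds = raw$n_seeds,
    cfg_classic = rebuild(nlm_config, raw$cfg_classic),
    cfg_improved = rebuild(nlm_config, raw$cfg_improved),
    admm = rebuild(admm_config, raw$admm),
    elasticity = rebuild(elasticity_phantom_spec, raw$elasticity),
    cohort = rebuild(cohort_spec, raw$cohort),
    shell_widths_mm = raw$shell_widths_mm,
    stage_counts = unlist(raw$stage_counts),
    thickness_base_mm = raw$thickness_base_mm,
    thickness_sd_mm = raw$thickness_sd_mm,
    seed = raw$seed)
}

# polynomial rolling hash of the serialized config, for the run manifest
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_run_config(cfg, tmp)
  bytes <- as.integer(charToRaw(paste(readLines(tmp, warn = FALSE),
                                      collapse = "\n")))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(cfg, outdir, stage) {
  jsonlite::write_json(
    list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg),
         package = "sweshell",
         version = as.character(utils::packageVersion("sweshell")),
         r_version = R.version.string),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Run the denoising benchmark study
#'
#' Generates the layered-skin phantom, sweeps the configured noise levels
#' for the noisy baseline, classic NLM, and the improved denoiser, writes
#' `metrics.csv`, a `verdict.json` stating whether the improved variant
#' dominates classic NLM (lower MSE, higher PSNR and SSIM at every sigma),
#' and a `manifest.json` sufficient to reproduce the run.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `metrics` (the sweep tibble) and
#'   `verdict`.
#' @export
run_denoise_benchmark <- function(cfg = run_config(), outdir = tempfile()) {
  if (!inherits(cfg, "run_config")) abort_validation("`cfg` must be a run_config")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ph <- make_skin_phantom(cfg$phantom, derive_seed(cfg$seed, "phantom"))
  sweep <- sweep_noise_levels(
    ph$image, cfg$noise_sigmas, n_seeds = cfg$n_seeds,
    seed = derive_seed(cfg$seed, "benchmark"),
    cfg_classic = cfg$cfg_classic, cfg_improved = cfg$cfg_improved,
    admm = cfg$admm)
  wide <- tidyr::pivot_wider(sweep, names_from = "method",
                             values_from = c("mse", "psnr", "ssim"))
  dominates <- all(wide$mse_nlm_improved < wide$mse_nlm &
                   wide$psnr_nlm_improved > wide$psnr_nlm &
                   wide$ssim_nlm_improved > wide$ssim_nlm)
  beats_noisy <- all(wide$mse_nlm < wide$mse_noisy &
                     wide$mse_nlm_improved < wide$mse_noisy)
  write.csv(sweep, file.path(outdir, "metrics.csv"), row.names = FALSE)
  verdict <- list(improved_dominates_classic = dominates,
                  both_beat_noisy = beats_noisy)
  jsonlite::write_json(verdict, file.path(outdir, "verdict.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, outdir, "denoise_benchmark")
  invisible(list(metrics = sweep, verdict = verdict, outdir = outdir))
}

simulate_swe_subject <- function(cfg, lesion_kpa, seed) {
  tmpl <- cfg$elasticity
  spec <- elasticity_phantom_spec(
    height = tmpl$height, width = tmpl$width,
    pixel_spacing = tmpl$pixel_spacing,
    background_kpa = tmpl$background_kpa,
    lesion_center = tmpl$lesion_center,
    lesion_radius_px = tmpl$lesion_radius_px,
    lesion_kpa = lesion_kpa,
    ring_width_mm = tmpl$ring_width_mm,
    ring_kpa = if (is.null(tmpl$ring_width_mm)) NULL else 1.5 * lesion_kpa,
    jitter_sigma_kpa = 0.05 * lesion_kpa)
  make_elasticity_phantom(spec, seed)
}

#' Run the simulated SWE diagnostic study
#'
#' Simulates a cohort of elasticity phantoms (cases with a stiffer lesion
#' and proportionally stiffer hard-ring margin; the subject-level lesion
#' modulus follows the configured [cohort_spec()]), reads Emax/Emean/Esd in
#' the lesion ROI and in each configured shell ring, and evaluates ROC /
#' AUC / Youden cutoff for every statistic x shell-width combination
#' (`table1.csv`). Also writes the lesion-stage summary (`table2.csv`) and
#' a two-group comparison of simulated dermal thickness
#' (`thickness_test.json`).
#'
#' @inheritParams run_denoise_benchmark
#' @return Invisibly, a list with `roc_table`, `stage_table`,
#'   `thickness_test`, `scores`.
#' @export
run_swe_study <- function(cfg = run_config(), outdir = tempfile()) {
  if (!inherits(cfg, "run_config")) abort_validation("`cfg` must be a run_config")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ch <- cfg$cohort
  subjects <- make_cohort(cohort_spec(
    n_cases = ch$n_cases, n_controls = ch$n_controls,
    effect_size = ch$effect_size, base_mean = ch$base_mean,
    base_sd = ch$base_sd, seed = derive_seed(cfg$seed, "swe_cohort")))
  rois <- c("lesion", sprintf("shell_%gmm", cfg$shell_widths_mm))
  scores <- purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    phi <- simulate_swe_subject(cfg, max(subjects$measurement[i], 1),
                                derive_seed(cfg$seed, paste0("subject", i)))
    stats_for <- function(roi_mask, roi_name) {
      dplyr::mutate(modulus_stats(phi$map, roi_mask), roi = roi_name,
                    .before = 1)
    }
    res <- list(stats_for(phi$mask, "lesion"))
    for (w in cfg$shell_widths_mm) {
      ring <- shell_ring(phi$mask, w, phi$pixel_spacing)
      res <- c(res, list(stats_for(ring, sprintf("shell_%gmm", w))))
    }
    dplyr::mutate(dplyr::bind_rows(res),
                  subject_id = subjects$subject_id[i],
                  group = subjects$group[i], .before = 1)
  })
  long <- tidyr::pivot_longer(scores, c("emax", "emean", "esd"),
                              names_to = "statistic", values_to = "value")
  roc_table <- long |>
    dplyr::group_by(.data$roi, .data$statistic) |>
    dplyr::group_modify(function(d, key) {
      glance(diagnostic_eval(d, .data$value, .data$group))
    }) |>
    dplyr::ungroup()
  stage_table <- stage_summary(cfg$stage_counts)
  thickness <- make_cohort(cohort_spec(
    n_cases = ch$n_cases, n_controls = ch$n_controls,
    effect_size = ch$effect_size, base_mean = cfg$thickness_base_mm,
    base_sd = cfg$thickness_sd_mm,
    seed = derive_seed(cfg$seed, "thickness")))
  thickness_test <- compare_groups(thickness, .data$measurement, .data$group)
  write.csv(roc_table, file.path(outdir, "table1.csv"), row.names = FALSE)
  write.csv(stage_table, file.path(outdir, "table2.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(thickness_test),
                       file.path(outdir, "thickness_test.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, outdir, "swe_study")
  invisible(list(roc_table = roc_table, stage_table = stage_table,
                 thickness_test = thickness_test, scores = scores,
                 outdir = outdir))
}
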