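# Scenario orchestration: one call simulates an acquisition, fabricates (or
# predicts) a prior, reconstructs with FBP, SART and the prior-constrained
# solver, and scores everything against the monochromatic ground truth.

#' Scenario run configuration
#'
#' Bundles every knob of an end-to-end run. All stochastic components carry
#' explicit seeds, so a configuration reproduces its artifacts exactly.
#'
#' @param scheme_kind acquisition scenario: `"SD"`, `"LD"`, `"LSA"` or
#'   `"LNP"`.
#' @param n reconstruction grid size (square).
#' @param n_views number of full-rotation views before subsampling.
#' @param geometry geometry preset name (see [geom_preset()]).
#' @param phantom phantom kind (see [make_phantom()]).
#' @param spectrum spectrum preset for the measured data (see
#'   [spectrum_preset()]); the single-bin reference spectrum defines the
#'   ground truth.
#' @param noise_i0 photons per bin for counting noise, or `NULL` for
#'   noiseless data.
#' @param prior_provider `"fabricated"` (default) or `"model"` (a trained
#'   [train_prior_model()] handle passed as `prior_model`).
#' @param prior_blur_sigma,prior_halluc prior degradation: blur in pixels
#'   and a list of [hallucination()] blobs.
#' @param hp a [piccs_hyperparameters()] or preset name.
#' @param sart_iters,sart_relax SART baseline settings.
#' @param seed master seed; scheme/noise/phantom seeds derive from it.
#' @param out_dir if non-`NULL`, artifacts are written there.
#' @param prior_model optional trained model for `prior_provider = "model"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scheme_kind = "LNP", n = 128L, n_views = 360L,
                       geometry = "parallel_default", phantom = "shell_skull",
                       spectrum = "poly3", noise_i0 = NULL,
                       prior_provider = c("fabricated", "model"),
                       prior_blur_sigma = 1.5, prior_halluc = list(),
                       hp = "synthetic", sart_iters = 40L, sart_relax = 1.0,
                       seed = 1L, out_dir = NULL, prior_model = NULL) {
  prior_provider <- match.arg(prior_provider)
  if (is.character(hp)) hp <- piccs_preset(hp)
  if (!inherits(hp, "piccs_hyperparameters"))
    stop_input("`hp` must be a preset name or piccs_hyperparameters()")
  if (prior_provider == "model" && is.null(prior_model))
    stop_input("`prior_provider = \"model\"` needs a trained `prior_model`")
  structure(
    list(scheme_kind = scheme_kind, n = check_count(n, "n", 32L),
         n_views = check_count(n_views, "n_views", 2L),
         geometry = geometry, phantom = phantom, spectrum = spectrum,
         noise_i0 = noise_i0, prior_provider = prior_provider,
         prior_blur_sigma = prior_blur_sigma, prior_halluc = prior_halluc,
         hp = hp, sart_iters = sart_iters, sart_relax = sart_relax,
         seed = as.integer(seed), out_dir = out_dir,
         prior_model = prior_model),
    class = "run_config"
  )
}

#' Stable hash of a run configuration
#'
#' Hashes every reproducibility-relevant field (the output directory and any
#' in-memory model handle are excluded); embedded in all artifact sidecars.
#'
#' @param config a [run_config()].
#' @return A character hash.
#' @export
config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("out_dir", "prior_model"))]
  rlang::hash(cfg)
}

#' Run one end-to-end scenario
#'
#' Pipeline: simulate polychromatic full-rotation data of the phantom,
#' subsample per the acquisition scheme (optionally adding counting noise),
#' reconstruct with FBP, fabricate or predict the prior from the
#' monochromatic ground truth / the FBP, run the prior-constrained solver
#' and the SART baseline, and evaluate all reconstructions against the
#' ground truth. With `out_dir` set, every artifact is written with a JSON
#' sidecar embedding the configuration hash and seeds.
#'
#' @param config a [run_config()].
#' @return A list with elements `target`, `sino_full`, `sino`, `geom_sub`,
#'   `fbp`, `prior`, `piccs`, `sart`, `metrics` (a [tibble][tibble::tibble]
#'   with one row per method) and `config_hash`.
#' @export
run_scenario <- function(config) {
  geom <- geom_preset(config$geometry, n = config$n, n_views = config$n_views)
  ph <- make_phantom(config$phantom, config$n, geom$pixel_size,
                     seed = config$seed)
  spec <- spectrum_preset(config$spectrum)
  # ground truth: the hardening-free image at the spectrum's effective energy
  ref <- effective_mono_spectrum(spec)
  target <- phantom_attenuation(ph, ref, 1L)

  sino_full <- project_polychromatic(ph, geom, spec)
  scheme <- sampling_scheme(config$scheme_kind, seed = config$seed + 1L)
  sino <- subsample_projections(sino_full, scheme)
  geom_sub <- subset_geometry(geom, attr(sino, "kept"))
  if (!is.null(config$noise_i0))
    sino <- add_counting_noise(sino, config$noise_i0, seed = config$seed + 2L)

  fbp <- fbp_reconstruct(sino, geom_sub)

  prior <- if (config$prior_provider == "fabricated") {
    fabricate_prior(target, prior_spec(
      use_half_size_roundtrip = TRUE,
      blur_sigma = config$prior_blur_sigma,
      hallucinations = config$prior_halluc,
      seed = config$seed + 3L))
  } else {
    half <- downsample_half(fbp)
    up <- predict_prior(config$prior_model, half)
    upsample_bilinear(up, config$n, config$n)
  }

  fit <- reconstruct_l2piccs(sino, geom_sub, prior, config$hp, u0 = fbp)
  sart <- sart_reconstruct(sino, geom_sub, config$sart_iters, config$sart_relax)

  dr <- max(target$values) - min(target$values)
  score <- function(img) metrics_report(img, target, dr)
  reports <- list(fbp = score(fbp), prior = score(prior),
                  piccs = score(fit$image), sart = score(sart))
  metrics <- tibble::tibble(
    method = names(reports),
    psnr_db = vapply(reports, function(r) r$psnr_db, double(1)),
    ssim = vapply(reports, function(r) r$ssim, double(1)),
    cc = vapply(reports, function(r) r$cc, double(1))
  )

  hash <- config_hash(config)
  out <- list(target = target, sino_full = sino_full, sino = sino,
              geom_sub = geom_sub, fbp = fbp, prior = prior, piccs = fit,
              sart = sart, metrics = metrics, config_hash = hash)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(config_hash = hash, seed = config$seed,
                 scheme = config$scheme_kind)
    p <- function(f) file.path(config$out_dir, f)
    write_image_tiff(target, p("target.tif"), meta)
    write_sinogram(sino, p("sinogram.csv"), meta)
    write_image_tiff(fbp, p("fbp.tif"), meta)
    write_image_tiff(prior, p("prior.tif"), meta)
    write_image_tiff(fit$image, p("piccs.tif"), meta)
    write_image_tiff(sart, p("sart.tif"), meta)
    write.csv(fit$history, p("piccs_history.csv"), row.names = FALSE)
    jsonlite::write_json(c(meta, list(metrics = metrics)), p("metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  out
}

#' Read / write a run configuration as YAML
#'
#' Round-trips every serializable field (the optional in-memory
#' `prior_model` handle is carried by reference only and is not written).
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly (writer); a [run_config()] (reader).
#' @export
write_run_config <- function(config, path) {
  cfg <- config[setdiff(names(config), "prior_model")]
  cfg$hp <- unclass(cfg$hp)
  cfg$prior_halluc <- lapply(cfg$prior_halluc, unclass)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  hp <- do.call(piccs_hyperparameters, cfg$hp)
  halluc <- lapply(cfg$prior_halluc, function(h) do.call(hallucination, h))
  run_config(scheme_kind = cfg$scheme_kind, n = cfg$n, n_views = cfg$n_views,
             geometry = cfg$geometry, phantom = cfg$phantom,
             spectrum = cfg$spectrum, noise_i0 = cfg$noise_i0,
             prior_provider = cfg$prior_provider,
             prior_blur_sigma = cfg$prior_blur_sigma, prior_halluc = halluc,
             hp = hp, sart_iters = cfg$sart_iters, sart_relax = cfg$sart_relax,
             seed = cfg$seed, out_dir = cfg$out_dir)
}
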