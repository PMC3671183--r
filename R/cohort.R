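# Cohort presets and the simulate -> scan -> average convenience layer.

#' Preset epithelium model mimicking the olfactory-epithelium study design
#'
#' Four layers along normalized depth: supporting (sustentacular) cells
#' (0-0.25), mature OSN (0.25-0.63), immature OSN (0.63-0.93) and basal cells
#' (0.93-1). Three probes:
#' \itemize{
#'   \item `Gb1` spans the full neuron layer (mature + immature OSN, 0.8),
#'   \item `Gg13` is strong in mature OSN (0.8) and reduced in immature OSN
#'     (0.35), designed so that the normalized windowed-integral ratio
#'     Gb1 : Gg13 over the basal marker window \[0.63, 0.93\] is exactly 2,
#'   \item `GAP43` marks the immature-OSN band (0.8 on \[0.63, 0.93\] only),
#'     so its half-max span recovers that window.
#' }
#' The default geometry (256 x 512 px at 0.372 um/px, lamina near row 180)
#' gives an epithelium roughly 58 um deep, matching typical line-scan
#' lengths; pass larger dimensions for full-frame (2048 x 2048) simulations.
#'
#' @param image_height_px,image_width_px image dimensions.
#' @param lamina_baseline_px,lamina_amplitude_px,lamina_wavelength_px lamina
#'   geometry.
#' @param noise_sd pixel noise sd (default 0.05).
#' @param blob_density_per_um2 0 for continuous mode (default; designed
#'   expectations are exact), > 0 for cell-body blob texture.
#' @param seed integer seed.
#' @return an [epithelium_model()].
#' @export
moe_cohort_model <- function(image_height_px = 256L, image_width_px = 512L,
                             lamina_baseline_px = 180,
                             lamina_amplitude_px = 12,
                             lamina_wavelength_px = 480,
                             noise_sd = 0.05,
                             blob_density_per_um2 = 0,
                             seed = 1L) {
  epithelium_model(
    image_height_px = image_height_px, image_width_px = image_width_px,
    pixel_size_um = 0.372,
    lamina_baseline_px = lamina_baseline_px,
    lamina_amplitude_px = lamina_amplitude_px,
    lamina_wavelength_px = lamina_wavelength_px,
    layer_boundaries = c(0.25, 0.63, 0.93),
    layer_names = c("sus", "mosn", "iosn", "basal"),
    probe_profiles = list(
      Gb1 = c(sus = 0, mosn = 0.8, iosn = 0.8, basal = 0),
      Gg13 = c(sus = 0, mosn = 0.8, iosn = 0.35, basal = 0),
      GAP43 = c(sus = 0, mosn = 0, iosn = 0.8, basal = 0)
    ),
    blob_density_per_um2 = blob_density_per_um2,
    background_level = 0.1, noise_sd = noise_sd, seed = seed
  )
}

#' Render a synthetic image as a brightfield-style micrograph
#'
#' Colorimetric label appears dark on a bright field; the generator's signal
#' field is therefore flipped (`1 - pixels`) to emulate the acquired image.
#' Running [invert_image()] on the result recovers the signal-bright field
#' and satisfies the scanning contract.
#'
#' @param img a real-valued, non-inverted `rish_image`.
#' @return a `rish_image` with `inverted = FALSE`.
#' @export
as_brightfield <- function(img) {
  stopifnot(inherits(img, "rish_image"), img$dtype == "real", !img$inverted)
  img$pixels <- 1 - img$pixels
  img
}

#' Anchor columns for evenly spaced scans, away from the lateral edges
#' @noRd
scan_anchor_cols <- function(image_width_px, n_scans) {
  round(image_width_px * seq_len(n_scans) / (n_scans + 1))
}

#' Simulate a multi-animal cohort of line-scan profiles
#'
#' Generates, per animal x image x probe, an independent synthetic section
#' (seeded from deterministic substreams of `seed`), renders it as a
#' brightfield micrograph, inverts it, takes `scans_per_image` scans
#' perpendicular to the lamina from evenly spaced anchor columns (each scan
#' running from the basal lamina to the apical edge), and normalizes each
#' profile to its own maxima.
#'
#' @param model an [epithelium_model()] (e.g. [moe_cohort_model()]).
#' @param probes probes to simulate (default: all in the model).
#' @param n_animals,images_per_animal,scans_per_image cohort design
#'   (defaults 3 x 2 x 2, i.e. 4 scans per animal per probe).
#' @param seed integer seed for the whole cohort.
#' @param step_px sampling step along scans, in pixels.
#' @return list with `profiles` (normalized `intensity_profile`s) and
#'   `truth` (one `ground_truth` per probe).
#' @export
simulate_cohort <- function(model, probes = names(model$probe_profiles),
                            n_animals = 3L, images_per_animal = 2L,
                            scans_per_image = 2L, seed = 1L, step_px = 1) {
  stopifnot(inherits(model, "epithelium_model"))
  profiles <- list()
  truth <- list()
  for (p in probes) {
    for (a in seq_len(n_animals)) {
      for (i in seq_len(images_per_animal)) {
        s <- seed_substream(seed, sprintf("%s/a%d/i%d", p, a, i))
        gen <- generate_epithelium_image(model, p, seed = s)
        if (is.null(truth[[p]])) truth[[p]] <- gen$truth
        img <- invert_image(as_brightfield(gen$image))
        trace <- gen$truth$lamina_trace
        for (k in seq_len(scans_per_image)) {
          col <- scan_anchor_cols(model$image_width_px, scans_per_image)[k]
          sl <- scan_line(trace, anchor_index = col + 1L, length_um = NULL,
                          pixel_size_um = model$pixel_size_um,
                          step_um = step_px * model$pixel_size_um)
          prof <- extract_scan(img, sl, meta = list(
            probe = p, animal_id = sprintf("a%d", a),
            image_id = sprintf("i%d", i), scan_id = sprintf("s%d", k)))
          profiles[[length(profiles) + 1L]] <- normalize_profile(prof)
        }
      }
    }
  }
  list(profiles = profiles, truth = truth)
}

#' Group-level averaged curves per probe from cohort profiles
#'
#' @param profiles normalized profiles (as from [simulate_cohort()]).
#' @param cfg an [averaging_config()].
#' @return named list of group-level `averaged_profile`s, one per probe.
#' @export
group_curves <- function(profiles, cfg = averaging_config()) {
  probes <- vapply(profiles, function(p) p$meta$probe, character(1))
  lapply(split(profiles, probes), hierarchical_average, cfg = cfg)
}

#' Windowed comparison of two probes in a cohort
#'
#' Averages the cohort hierarchically, computes windowed integrals for all
#' probes and the Kolmogorov-Smirnov comparison for one probe pair.
#'
#' @param profiles normalized cohort profiles.
#' @param pair length-2 character vector of probe names to compare.
#' @param window a [marker_window()], or the name of a marker probe whose
#'   half-max span defines the window.
#' @param cfg an [averaging_config()].
#' @param mode KS mode (see [ks_compare()]).
#' @param n_for_p sample-size convention for the KS p-value; the workflow
#'   default is `"scans"` (see [ks_compare()]).
#' @return list with `curves`, `window`, `integrals`
#'   (a `windowed_integrals`), and `ks` (a `ks_result`).
#' @export
cohort_window_stats <- function(profiles, pair, window = marker_window(),
                                cfg = averaging_config(),
                                mode = "pointwise_values",
                                n_for_p = "scans") {
  curves <- group_curves(profiles, cfg)
  if (is.character(window)) {
    if (!window %in% names(curves)) stop("marker probe '", window,
                                         "' not in cohort", call. = FALSE)
    window <- derive_window(curves[[window]])
  }
  if (!all(pair %in% names(curves))) stop("pair probes not in cohort",
                                          call. = FALSE)
  ints <- compare_windowed_integrals(curves[pair], window)
  ks <- ks_compare(curves[[pair[1]]], curves[[pair[2]]], window, mode = mode,
                   n_for_p = n_for_p)
  list(curves = curves, window = window, integrals = ints, ks = ks)
}
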