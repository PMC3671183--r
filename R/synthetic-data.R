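# Seeded ground-truth generators: layered epithelium images and qPCR Ct tables.

#' Describe a synthetic layered epithelium
#'
#' Parameterizes a simulated coronal section of a layered sensory epithelium.
#' Image row 0 is the apical edge; the basal lamina follows
#' `row = lamina_baseline_px + lamina_amplitude_px * sin(2*pi*col / lamina_wavelength_px)`.
#' Normalized depth runs from 0 at the apical surface to 1 at the basal
#' lamina, and `layer_boundaries` (strictly increasing fractions in (0,1))
#' split that depth range into `length(layer_boundaries) + 1` named layers.
#' Each probe assigns one mean signal intensity in \[0,1\] to every layer;
#' signal sits on top of `background_level`, which must stay below the
#' smallest positive layer intensity so that label is distinguishable.
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param pixel_size_um physical pixel size (default 0.372 um/pixel, a common
#'   20x brightfield configuration).
#' @param lamina_baseline_px mean basal lamina depth from the apical edge.
#' @param lamina_amplitude_px,lamina_wavelength_px sinusoidal curvature of the
#'   lamina (amplitude >= 0, wavelength > 0).
#' @param layer_boundaries strictly increasing depth fractions in (0,1).
#' @param layer_names names for the `length(layer_boundaries) + 1` layers.
#' @param probe_profiles named list: probe -> numeric vector of per-layer mean
#'   signal intensities in \[0,1\], one per layer (named or positional).
#' @param blob_density_per_um2 cell-body density; 0 selects continuous mode
#'   (each layer painted at its mean intensity), > 0 selects blob mode
#'   (Gaussian cell-body kernels at Poisson-distributed centers, combined by
#'   pixelwise maximum).
#' @param blob_radius_um cell-body radius (Gaussian sigma = radius / 2).
#' @param background_level base intensity in \[0,1).
#' @param noise_sd additive Gaussian pixel noise standard deviation.
#' @param seed integer seed; identical (model, seed) gives identical images.
#' @return an object of class `epithelium_model`.
#' @seealso [generate_epithelium_image()], [moe_cohort_model()]
#' @export
epithelium_model <- function(image_height_px = 2048L,
                             image_width_px = 2048L,
                             pixel_size_um = 0.372,
                             lamina_baseline_px = 170,
                             lamina_amplitude_px = 10,
                             lamina_wavelength_px = 1024,
                             layer_boundaries = c(0.25, 0.63, 0.93),
                             layer_names = NULL,
                             probe_profiles = list(),
                             blob_density_per_um2 = 0,
                             blob_radius_um = 2,
                             background_level = 0.1,
                             noise_sd = 0,
                             seed = 1L) {
  assert_scalar_num(image_height_px, "image_height_px", lower = 2)
  assert_scalar_num(image_width_px, "image_width_px", lower = 2)
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-9)
  assert_scalar_num(lamina_baseline_px, "lamina_baseline_px", lower = 1)
  assert_scalar_num(lamina_amplitude_px, "lamina_amplitude_px", lower = 0)
  assert_scalar_num(lamina_wavelength_px, "lamina_wavelength_px", lower = 1e-9)
  assert_scalar_num(blob_density_per_um2, "blob_density_per_um2", lower = 0)
  assert_scalar_num(blob_radius_um, "blob_radius_um", lower = 1e-9)
  assert_scalar_num(background_level, "background_level", lower = 0, upper = 1 - 1e-9)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(seed, "seed")
  if (lamina_baseline_px + lamina_amplitude_px >= image_height_px) {
    stop("basal lamina exits the image: lamina_baseline_px + lamina_amplitude_px ",
         "must be < image_height_px", call. = FALSE)
  }
  if (length(layer_boundaries) < 1L ||
      any(layer_boundaries <= 0) || any(layer_boundaries >= 1) ||
      any(diff(layer_boundaries) <= 0)) {
    stop("layer_boundaries must be strictly increasing fractions in (0,1)",
         call. = FALSE)
  }
  n_layers <- length(layer_boundaries) + 1L
  if (is.null(layer_names)) layer_names <- paste0("layer", seq_len(n_layers))
  if (length(layer_names) != n_layers) {
    stop("need exactly ", n_layers, " layer names", call. = FALSE)
  }
  if (length(probe_profiles) == 0L) stop("at least one probe profile is required",
                                         call. = FALSE)
  probe_profiles <- lapply(probe_profiles, function(p) {
    if (length(p) != n_layers || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop("each probe profile must give one intensity in [0,1] per layer",
           call. = FALSE)
    }
    stats::setNames(as.numeric(p), layer_names)
  })
  pos <- unlist(probe_profiles)
  pos <- pos[pos > 0]
  if (length(pos) && background_level >= min(pos)) {
    stop("background_level must be below the smallest positive layer intensity",
         call. = FALSE)
  }
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = pixel_size_um,
    lamina_baseline_px = lamina_baseline_px,
    lamina_amplitude_px = lamina_amplitude_px,
    lamina_wavelength_px = lamina_wavelength_px,
    layer_boundaries = as.numeric(layer_boundaries),
    layer_names = layer_names,
    probe_profiles = probe_profiles,
    blob_density_per_um2 = blob_density_per_um2,
    blob_radius_um = blob_radius_um,
    background_level = background_level,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "epithelium_model")
}

#' @export
print.epithelium_model <- function(x, ...) {
  cat(sprintf("<epithelium_model> %d x %d px @ %.3f um/px\n",
              x$image_height_px, x$image_width_px, x$pixel_size_um))
  cat(sprintf("  lamina: %.1f + %.1f*sin(2*pi*col/%.0f) px\n",
              x$lamina_baseline_px, x$lamina_amplitude_px, x$lamina_wavelength_px))
  cat("  layers:", paste(x$layer_names, collapse = ", "), "at boundaries",
      paste(format(x$layer_boundaries), collapse = ", "), "\n")
  cat("  probes:", paste(names(x$probe_profiles), collapse = ", "), "\n")
  mode <- if (x$blob_density_per_um2 > 0) "blob" else "continuous"
  cat(sprintf("  mode: %s, background %.2f, noise sd %.3f, seed %d\n",
              mode, x$background_level, x$noise_sd, x$seed))
  invisible(x)
}

#' Basal lamina row as a function of 0-based column index
#' @noRd
lamina_row_at <- function(model, col) {
  model$lamina_baseline_px +
    model$lamina_amplitude_px * sin(2 * pi * col / model$lamina_wavelength_px)
}

#' Render one synthetic RISH image with its ground truth
#'
#' Paints the epithelium above the basal lamina with the probe's per-layer
#' signal added to the background; pixels below the lamina carry background
#' only. In continuous mode every pixel of a layer equals
#' `background + intensity`; in blob mode Gaussian cell-body kernels of
#' amplitude equal to the layer intensity are seeded at Poisson-distributed
#' centers and combined by pixelwise maximum, approximating label confined to
#' scattered somata. Additive Gaussian noise of sd `noise_sd` is applied last
#' and the image is clipped to \[0,1\]. Output is reproducible: identical
#' (model, seed) yields bitwise-identical images.
#'
#' The returned ground truth carries the exact lamina polyline, the layer
#' boundaries, and the expected noiseless continuous-mode profile (a
#' piecewise-constant function of normalized depth) for the probe.
#'
#' @param model an [epithelium_model()].
#' @param probe name of a probe in `model$probe_profiles`.
#' @param seed optional seed overriding `model$seed`.
#' @return list with elements `image` (a `rish_image`, real-valued, not
#'   inverted) and `truth` (class `ground_truth`: `lamina_trace`,
#'   `layer_boundaries`, `expected_profile` with `breaks`/`values`, and
#'   `expected_profile_fun(x)`).
#' @export
generate_epithelium_image <- function(model, probe, seed = NULL) {
  stopifnot(inherits(model, "epithelium_model"))
  if (!probe %in% names(model$probe_profiles)) {
    stop("unknown probe '", probe, "'", call. = FALSE)
  }
  seed <- seed %||% model$seed
  H <- model$image_height_px; W <- model$image_width_px
  cols0 <- 0:(W - 1L)
  lam <- lamina_row_at(model, cols0)             # lamina row per column
  breaks <- c(0, model$layer_boundaries, 1)
  levels <- model$probe_profiles[[probe]]

  # normalized depth of every pixel relative to the local lamina row
  depth <- outer(0:(H - 1L), 1 / lam)            # H x W
  inside <- depth <= 1
  layer_idx <- matrix(findInterval(pmin(depth, 1), breaks,
                                   rightmost.closed = TRUE), nrow = H)

  img <- with_seed(seed, {
    if (model$blob_density_per_um2 > 0) {
      signal <- blob_signal_field(model, lam, layer_idx, inside, levels)
    } else {
      signal <- matrix(levels[layer_idx], nrow = H)
      signal[!inside] <- 0
    }
    out <- model$background_level + signal
    if (model$noise_sd > 0) {
      out <- out + matrix(stats::rnorm(H * W, sd = model$noise_sd), nrow = H)
    }
    pmin(pmax(out, 0), 1)
  })

  trace <- lamina_trace(cbind(row = lam, col = cols0))
  truth <- structure(list(
    probe = probe,
    lamina_trace = trace,
    layer_boundaries = model$layer_boundaries,
    expected_profile = list(breaks = breaks,
                            values = model$background_level + unname(levels)),
    expected_profile_fun = local({
      b <- breaks; v <- model$background_level + unname(levels)
      function(x) v[findInterval(pmin(pmax(x, 0), 1), b, rightmost.closed = TRUE)]
    })
  ), class = "ground_truth")

  list(
    image = rish_image(img, pixel_size_um = model$pixel_size_um,
                       source_id = paste0("synthetic:", probe, ":seed", seed)),
    truth = truth
  )
}

#' Blob-mode signal field: max-combined Gaussian cell bodies
#' @noRd
blob_signal_field <- function(model, lam, layer_idx, inside, levels) {
  H <- model$image_height_px; W <- model$image_width_px
  px <- model$pixel_size_um
  r_px <- model$blob_radius_um / px
  sigma <- r_px / 2
  half <- ceiling(3 * sigma)                     # kernel support half-width
  lam_max <- max(lam)
  # Poisson process on the bounding box, thinned to the epithelium region
  density_px2 <- model$blob_density_per_um2 * px^2
  n_box <- stats::rpois(1, density_px2 * (lam_max + 1) * W)
  signal <- matrix(0, nrow = H, ncol = W)
  if (n_box == 0) { signal[!inside] <- 0; return(signal) }
  cr <- stats::runif(n_box, 0, lam_max)
  cc <- stats::runif(n_box, 0, W - 1)
  keep <- cr <= lam[floor(cc) + 1L]
  cr <- cr[keep]; cc <- cc[keep]
  if (length(cr)) {
    dk <- -half:half
    for (i in seq_along(cr)) {
      lay <- layer_idx[floor(cr[i]) + 1L, floor(cc[i]) + 1L]
      amp <- levels[lay]
      if (amp <= 0) next
      rows <- (round(cr[i]) + dk); cols <- (round(cc[i]) + dk)
      rok <- rows >= 0 & rows <= H - 1; cok <- cols >= 0 & cols <= W - 1
      if (!any(rok) || !any(cok)) next
      kr <- exp(-((rows[rok] - cr[i])^2) / (2 * sigma^2))
      kc <- exp(-((cols[cok] - cc[i])^2) / (2 * sigma^2))
      patch <- amp * outer(kr, kc)
      ri <- rows[rok] + 1L; ci <- cols[cok] + 1L
      signal[ri, ci] <- pmax(signal[ri, ci], patch)
    }
  }
  signal[!inside] <- 0
  signal
}

#' Expected within-layer mean intensity of the blob model
#'
#' Closed form for the untruncated max-combined Gaussian Boolean model:
#' `background + amplitude * beta / (1 + beta)` with
#' `beta = 2 * pi * density * sigma^2` and `sigma = radius / 2`. Used as an
#' independent oracle for the blob renderer.
#'
#' @param amplitude layer signal intensity.
#' @param density_per_um2 blob density.
#' @param radius_um blob radius.
#' @param background background level.
#' @return expected mean pixel intensity inside the layer.
#' @export
blob_expected_mean <- function(amplitude, density_per_um2, radius_um,
                               background = 0) {
  sigma <- radius_um / 2
  beta <- 2 * pi * density_per_um2 * sigma^2
  background + amplitude * beta / (1 + beta)
}

# ---------------------------------------------------------------------------
# qPCR Ct table generation

#' Design a synthetic qPCR experiment
#'
#' Encodes designed relative expressions (targets of the 2^-dCt transform
#' against the reference gene) together with biological and technical noise.
#' The reference gene's relative expression is fixed at 1 by construction.
#'
#' @param true_rel_expression named positive numeric vector of designed
#'   expression relative to the reference gene; the reference gene is added
#'   with value 1 if absent.
#' @param reference_gene name of the internal reference (default "Gapdh").
#' @param n_biological biological samples per group.
#' @param n_technical technical replicates per (sample, gene).
#' @param ct_reference_mean mean Ct of the reference gene (default 18).
#' @param ct_noise_sd Gaussian noise sd applied independently as a biological
#'   (per sample x gene) and a technical (per replicate) component.
#' @param group_folds optional named list: group -> named multiplier vector
#'   applied to `true_rel_expression` (genes absent from the vector keep
#'   multiplier 1). Default is a single group "g1" with no modification.
#' @param seed integer seed.
#' @return object of class `ct_design`.
#' @export
ct_design <- function(true_rel_expression,
                      reference_gene = "Gapdh",
                      n_biological = 3L,
                      n_technical = 3L,
                      ct_reference_mean = 18,
                      ct_noise_sd = 0.2,
                      group_folds = NULL,
                      seed = 1L) {
  if (is.null(names(true_rel_expression)) || any(names(true_rel_expression) == "")) {
    stop("true_rel_expression must be a named vector", call. = FALSE)
  }
  if (any(true_rel_expression <= 0)) stop("relative expressions must be > 0",
                                          call. = FALSE)
  if (!reference_gene %in% names(true_rel_expression)) {
    true_rel_expression <- c(stats::setNames(1, reference_gene),
                             true_rel_expression)
  }
  if (abs(true_rel_expression[[reference_gene]] - 1) > 1e-12) {
    stop("the reference gene's relative expression must equal 1", call. = FALSE)
  }
  assert_scalar_num(n_biological, "n_biological", lower = 1)
  assert_scalar_num(n_technical, "n_technical", lower = 1)
  assert_scalar_num(ct_noise_sd, "ct_noise_sd", lower = 0)
  if (is.null(group_folds)) group_folds <- list(g1 = numeric(0))
  structure(list(
    genes = names(true_rel_expression),
    true_rel_expression = true_rel_expression,
    reference_gene = reference_gene,
    n_biological = as.integer(n_biological),
    n_technical = as.integer(n_technical),
    ct_reference_mean = ct_reference_mean,
    ct_noise_sd = ct_noise_sd,
    group_folds = group_folds,
    seed = as.integer(seed)
  ), class = "ct_design")
}

#' Generate a synthetic Ct table
#'
#' For every group, biological sample, gene and technical replicate emits
#' `Ct = ct_reference_mean - log2(rel * group_fold) + noise`, where `noise`
#' is one independent Gaussian draw of sd `ct_noise_sd` per Ct measurement,
#' covering biological and technical variation at the per-well scale (0.2
#' cycles is a typical SYBR-assay magnitude). With `ct_noise_sd = 0` the
#' table inverts exactly to the designed relative expressions under the
#' 2^-dCt transform.
#'
#' @param design a [ct_design()].
#' @param seed optional seed overriding `design$seed`.
#' @return a `ct_table`: data.frame with columns `sample_id`, `group`,
#'   `gene`, `technical_replicate`, `ct`, plus attributes `reference_gene`
#'   and `design`.
#' @export
generate_ct_table <- function(design, seed = NULL) {
  stopifnot(inherits(design, "ct_design"))
  seed <- seed %||% design$seed
  genes <- design$genes
  groups <- names(design$group_folds)
  rows <- with_seed(seed, {
    out <- vector("list", length(groups) * design$n_biological)
    k <- 0L
    for (g in groups) {
      fold_mult <- design$group_folds[[g]]
      for (s in seq_len(design$n_biological)) {
        k <- k + 1L
        sample_id <- sprintf("%s_s%02d", g, s)
        rel <- design$true_rel_expression[genes]
        mult <- ifelse(genes %in% names(fold_mult), fold_mult[genes], 1)
        mu <- design$ct_reference_mean - log2(rel * mult)
        tech <- matrix(stats::rnorm(length(genes) * design$n_technical,
                                    sd = design$ct_noise_sd),
                       nrow = length(genes))
        out[[k]] <- data.frame(
          sample_id = sample_id,
          group = g,
          gene = rep(genes, each = design$n_technical),
          technical_replicate = rep(seq_len(design$n_technical), length(genes)),
          ct = as.vector(t(mu + tech)),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
  structure(rows, reference_gene = design$reference_gene, design = design,
            class = c("ct_table", "data.frame"))
}
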