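# Synthetic leaf-image generator and laboratory label utilities.
#
# The generator emits single elliptical "leaves" on a near-white board whose
# mean colour is affine in a latent nitrogen value and whose mottling
# amplitude decreases with nitrogen (nitrogen-starved leaves are patchier),
# optionally corrupted by pixel noise and a multiplicative affine
# illumination field. It is the canonical test input for every downstream
# stage of the pipeline.

#' Leaf nitrogen mass fraction from a digestion/flow-analysis reading
#'
#' Converts a continuous-flow analyser reading into a leaf N mass fraction
#' via `N = m * V / M * 1e-3`, where `m` is the instrument reading (mg/L),
#' `V` the fixed volume (mL) and `M` the dry sample mass (g). The raw
#' formula value is returned; unit interpretation is left to the caller.
#'
#' @param m instrument reading, mg/L. Strictly positive.
#' @param V fixed volume, mL. Strictly positive.
#' @param M sample mass, g. Strictly positive.
#' @return The N mass fraction value `m * V / M * 1e-3`.
#' @examples
#' n_content(m = 10, V = 150, M = 0.1) # 15
#' @export
n_content <- function(m, V, M) {
  assert_scalar_number(m, "m", lower = 0, strict_lower = TRUE)
  assert_scalar_number(V, "V", lower = 0, strict_lower = TRUE)
  assert_scalar_number(M, "M", lower = 0, strict_lower = TRUE)
  m * V / M * 1e-3
}

#' Configuration for the synthetic leaf-image generator
#'
#' Defaults emulate the study conditions the pipeline is built for: 60
#' single-leaf photographs per growth stage against a white board, with leaf
#' colour and texture statistically coupled to a latent N value in
#' `[0.8, 2.2]` (mass-fraction %), corrupted by pixel noise and a
#' multiplicative affine illumination field.
#'
#' Two growth stages are provided as two independent parameter sets
#' (different colour bases/slopes), mirroring separate tillering and
#' elongation datasets.
#'
#' @param n_samples number of leaves to generate (>= 2).
#' @param image_size integer `(H, W)`, both >= 32.
#' @param n_range interval the latent N value is drawn from (uniform).
#' @param color_base mean leaf sRGB colour at N = 0, named `R`, `G`, `B`.
#' @param color_slopes per-channel affine slope of mean leaf colour per unit
#'   N. Higher N gives a darker, greener leaf under the defaults.
#' @param color_noise_sd per-pixel additive Gaussian noise SD.
#' @param texture_coupling `c(a0, a1)`: amplitude of the spatially
#'   correlated mottling added to the leaf is `a0 + a1 * N` (floored at
#'   0.005). The default negative slope makes low-N leaves patchier, giving
#'   GLCM entropy/energy a monotone dependence on N.
#' @param texture_scale Gaussian correlation length of the mottle field, px.
#' @param illumination logical: apply a multiplicative affine illumination
#'   ramp of random direction.
#' @param illumination_strength peak-to-peak relative strength of the ramp
#'   along its direction.
#' @param background_value near-white board level, in `(0.9, 1]`.
#' @param stage `"tillering"` or `"elongation"`; selects the stage-specific
#'   colour parameter set when `color_base`/`color_slopes` are not given.
#' @param seed integer seed; identical configs and seeds give bitwise
#'   identical datasets.
#' @return A `generator_config` list.
#' @seealso [generate_dataset()], [noiseless_config()]
#' @export
generator_config <- function(n_samples = 60L,
                             image_size = c(256L, 256L),
                             n_range = c(0.8, 2.2),
                             color_base = NULL,
                             color_slopes = NULL,
                             color_noise_sd = 0.012,
                             texture_coupling = c(a0 = 0.07, a1 = -0.02),
                             texture_scale = 3,
                             illumination = TRUE,
                             illumination_strength = 0.25,
                             background_value = 0.96,
                             stage = c("tillering", "elongation"),
                             seed = 1L) {
  stage <- match.arg(stage)
  if (is.null(color_base)) {
    color_base <- switch(stage,
      tillering  = c(R = 0.62, G = 0.78, B = 0.45),
      elongation = c(R = 0.60, G = 0.80, B = 0.42))
  }
  if (is.null(color_slopes)) {
    color_slopes <- switch(stage,
      tillering  = c(R = -0.16, G = -0.10, B = -0.10),
      elongation = c(R = -0.13, G = -0.12, B = -0.09))
  }
  assert_scalar_number(n_samples, "n_samples", lower = 2)
  if (length(image_size) != 2L || any(image_size < 32)) {
    stop("`image_size` must be two dimensions >= 32", call. = FALSE)
  }
  if (length(n_range) != 2L || diff(n_range) <= 0) {
    stop("`n_range` must be a nonempty interval", call. = FALSE)
  }
  assert_scalar_number(background_value, "background_value",
                       lower = 0.9, upper = 1, strict_lower = TRUE)
  assert_scalar_number(color_noise_sd, "color_noise_sd", lower = 0)
  stopifnot(length(color_base) == 3L, length(color_slopes) == 3L,
            length(texture_coupling) == 2L)
  structure(list(
    n_samples = as.integer(n_samples),
    image_size = as.integer(image_size),
    n_range = as.numeric(n_range),
    color_base = stats::setNames(as.numeric(color_base), c("R", "G", "B")),
    color_slopes = stats::setNames(as.numeric(color_slopes), c("R", "G", "B")),
    color_noise_sd = color_noise_sd,
    texture_coupling = stats::setNames(as.numeric(texture_coupling), c("a0", "a1")),
    texture_scale = texture_scale,
    illumination = isTRUE(illumination),
    illumination_strength = illumination_strength,
    background_value = background_value,
    stage = stage,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Noise-free generator configuration
#'
#' Convenience wrapper: pixel noise off and illumination off, so per-sample
#' leaf-mean channels are exact affine functions of the latent N value
#' (the mottle field is mean-centred over the leaf and does not shift
#' channel means).
#'
#' @param ... passed to [generator_config()].
#' @return A `generator_config`.
#' @export
noiseless_config <- function(...) {
  generator_config(color_noise_sd = 0, illumination = FALSE, ...)
}

#' Generate a seeded synthetic leaf-image dataset
#'
#' Each sample is an elliptical leaf (randomised axes and orientation) whose
#' mean colour is `color_base + color_slopes * N`, overlaid with a
#' mean-centred, Gaussian-correlated mottle field of amplitude
#' `a0 + a1 * N`, on a near-white board, plus optional pixel noise, then
#' multiplied by an affine illumination ramp when enabled. The ground-truth
#' mask is the exact ellipse.
#'
#' @param config a [generator_config()].
#' @return A list of class `synthetic_dataset`; each element has `image`
#'   ([rgb_image()]), `true_mask` (logical matrix), `n_value` and
#'   `stage_label`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  samples <- with_seed(config$seed, {
    lapply(seq_len(config$n_samples), function(i) generate_sample(config))
  })
  structure(samples, class = "synthetic_dataset", config = config)
}

generate_sample <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  n_val <- stats::runif(1, cfg$n_range[1], cfg$n_range[2])

  # elliptical leaf geometry
  cy <- H / 2 + stats::runif(1, -0.05, 0.05) * H
  cx <- W / 2 + stats::runif(1, -0.05, 0.05) * W
  ra <- stats::runif(1, 0.55, 0.85) * 0.45 * min(H, W)
  rb <- ra * stats::runif(1, 0.25, 0.5)
  theta <- stats::runif(1, 0, pi)
  yy <- matrix(seq_len(H) - cy, H, W)
  xx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  u <- (xx * cos(theta) + yy * sin(theta)) / ra
  v <- (-xx * sin(theta) + yy * cos(theta)) / rb
  mask <- (u^2 + v^2) <= 1

  leaf_col <- cfg$color_base + cfg$color_slopes * n_val

  # mottle: Gaussian-filtered white noise, unit SD, mean-centred on the leaf
  # so channel means stay exactly affine in N
  field <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), cfg$texture_scale)
  field <- field / stats::sd(field)
  field[mask] <- field[mask] - mean(field[mask])
  amp <- max(cfg$texture_coupling["a0"] + cfg$texture_coupling["a1"] * n_val, 0.005)

  px <- array(cfg$background_value, dim = c(H, W, 3L))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[mask] <- leaf_col[ch] + amp * field[mask]
    px[, , ch] <- plane
  }

  if (cfg$color_noise_sd > 0) {
    # truncated at +/- 2 SD so the board stays within a bounded band of
    # background_value (keeps whiteboard segmentation well-posed)
    noise <- stats::rnorm(length(px), sd = cfg$color_noise_sd)
    lim <- 2 * cfg$color_noise_sd
    px <- px + array(pmin(pmax(noise, -lim), lim), dim = dim(px))
  }

  if (cfg$illumination) {
    phi <- stats::runif(1, 0, 2 * pi)
    t <- (xx / W) * cos(phi) + (yy / H) * sin(phi)
    L <- 1 + cfg$illumination_strength * t
    px <- px * array(rep(L, 3L), dim = dim(px))
  }

  px <- pmin(pmax(px, 0), 1)
  list(image = rgb_image(px, metadata = list(stage = cfg$stage)),
       true_mask = mask,
       n_value = n_val,
       stage_label = cfg$stage)
}

#' Deterministic unit-test fixture images
#'
#' @param kind one of `"flat"` (constant image), `"gradient"` (constant
#'   reflectance times a left-to-right linear multiplicative ramp),
#'   `"checkerboard"` (alternating two-level pattern), `"two_tone"`
#'   (left/right half split).
#' @param size integer `(H, W)`, both >= 2.
#' @param value constant level for `"flat"`.
#' @param base,strength for `"gradient"`: ramp runs linearly from
#'   `base * (1 - strength)` to `base * (1 + strength)`.
#' @param levels two levels for `"checkerboard"`/`"two_tone"`.
#' @return An [rgb_image()] with equal channels.
#' @examples
#' generate_fixture("checkerboard", size = c(2, 2), levels = c(0, 1))
#' @export
generate_fixture <- function(kind = c("flat", "gradient", "checkerboard", "two_tone"),
                             size = c(64L, 64L), value = 0.5,
                             base = 0.5, strength = 0.5, levels = c(0.2, 0.8)) {
  kind <- match.arg(kind)
  if (length(size) != 2L || any(size < 2L)) stop("size must be >= 2 x 2", call. = FALSE)
  H <- size[1]; W <- size[2]
  m <- switch(kind,
    flat = matrix(value, H, W),
    gradient = {
      ramp <- seq(1 - strength, 1 + strength, length.out = W)
      base * matrix(ramp, H, W, byrow = TRUE)
    },
    checkerboard = {
      idx <- outer(seq_len(H), seq_len(W), "+") %% 2L
      matrix(levels[1], H, W) + idx * (levels[2] - levels[1])
    },
    two_tone = {
      m <- matrix(levels[1], H, W)
      m[, seq_len(W %/% 2) + W - W %/% 2] <- levels[2]
      m
    })
  rgb_image(m, metadata = list(fixture = kind))
}

#' Write a synthetic dataset to disk
#'
#' Writes 8-bit PNG images, `{0, 255}` single-channel PNG masks, and a CSV
#' manifest (`sample_id`, `stage`, `n_value`, `image_path`, `mask_path`).
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    id <- sprintf("%s_%03d", s$stage_label, i)
    ip <- file.path(dir, paste0(id, ".png"))
    mp <- file.path(dir, paste0(id, "_mask.png"))
    write_image(s$image, ip)
    write_image(s$true_mask, mp)
    data.frame(sample_id = id, stage = s$stage_label, n_value = s$n_value,
               image_path = ip, mask_path = mp, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Latent N values of a synthetic dataset
#' @param dataset a `synthetic_dataset`.
#' @return Numeric vector of N values.
#' @export
dataset_n_values <- function(dataset) {
  vapply(dataset, function(s) s$n_value, numeric(1))
}
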