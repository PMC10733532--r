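# Synthetic fundus photographs with exact vessel masks.
#
# The generator emulates the geometry that matters to a vessel-segmentation
# pipeline: a circular field of view on a dark border, a smoothly textured
# reddish background, and a dark branching vascular tree whose rasterization
# is returned bit-for-bit as the ground-truth mask.

#' Synthetic fundus configuration
#'
#' @param seed integer seed; the same configuration always renders the same
#'   image/mask pair.
#' @param size square image side in pixels.
#' @param n_trees number of vascular trees emanating from the disc region.
#' @param branch_depth recursion depth of each tree (a depth-`d` tree has
#'   `2^d - 1` branches).
#' @param root_width width of a root branch in pixels.
#' @param width_decay per-generation width multiplier, in (0, 1).
#' @param vessel_intensity 8-bit grey level of vessel pixels (dark).
#' @param background_intensity 8-bit grey level of the retinal background.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   (8-bit levels).
#' @param fov_radius_frac field-of-view radius as a fraction of `size/2`,
#'   in (0, 1].
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(seed, size = 128L, n_trees = 4L,
                             branch_depth = 4L, root_width = 3,
                             width_decay = 0.8, vessel_intensity = 70,
                             background_intensity = 170, noise_sd = 8,
                             fov_radius_frac = 0.94) {
  if (width_decay <= 0 || width_decay >= 1)
    stop("width_decay must lie in (0, 1)")
  if (fov_radius_frac <= 0 || fov_radius_frac > 1)
    stop("fov_radius_frac must lie in (0, 1]")
  if (size < 16) stop("size must be at least 16 pixels")
  if (n_trees < 0 || branch_depth < 1) stop("invalid tree configuration")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_trees = as.integer(n_trees),
                 branch_depth = as.integer(branch_depth),
                 root_width = root_width, width_decay = width_decay,
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, fov_radius_frac = fov_radius_frac),
            class = "synthetic_config")
}

# Stamp a filled disc of diameter `w` at (h0, w0) into logical matrix `m`.
stamp_disc <- function(m, h0, w0, w) {
  s <- nrow(m)
  r <- max(w / 2, 0.5)
  h1 <- max(1, ceiling(h0 - r)); h2 <- min(s, floor(h0 + r))
  w1 <- max(1, ceiling(w0 - r)); w2 <- min(s, floor(w0 + r))
  if (h1 > h2 || w1 > w2) return(m) # disc entirely outside the canvas
  hr <- h1:h2; wr <- w1:w2
  dh <- (hr - h0)^2
  dw <- (wr - w0)^2
  m[hr, wr] <- m[hr, wr] | outer(dh, dw, "+") <= r^2
  m
}

# Smooth background texture: coarse Gaussian grid, bilinearly upsampled.
texture_field <- function(size, amplitude = 10) {
  g <- max(4L, size %/% 16L)
  coarse <- matrix(rnorm((g + 1)^2, 0, amplitude), g + 1, g + 1)
  u <- seq(1, g + 1, length.out = size)
  i0 <- pmin(floor(u), g); f <- u - i0
  # separable bilinear interpolation
  rows <- coarse[i0, , drop = FALSE] * (1 - f) + coarse[i0 + 1, , drop = FALSE] * f
  rows[, i0, drop = FALSE] * rep(1 - f, each = size) +
    rows[, i0 + 1, drop = FALSE] * rep(f, each = size)
}

#' Generate a synthetic fundus sample
#'
#' Renders a circular field of view containing a textured background and
#' `n_trees` recursively branching dark vessel trees; the returned mask is
#' exactly the set of rendered vessel pixels (clipped to the field of view).
#' Deterministic for a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @return a `fundus_sample`: list with `image` (`size x size x 3` array in
#'   `[0, 1]`), `mask` (`size x size` 0/1 matrix), `image_id`, `source`
#'   (`"synthetic"`), `annotator` (`NA`) and the `config` used.
#' @export
generate_synthetic_fundus <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a synthetic_config")
  with_seed(config$seed, {
    s <- config$size
    ctr <- (s + 1) / 2
    fov_r <- config$fov_radius_frac * s / 2
    d2 <- outer((seq_len(s) - ctr)^2, (seq_len(s) - ctr)^2, "+")
    fov <- d2 <= fov_r^2

    mask <- matrix(FALSE, s, s)
    if (config$n_trees > 0) {
      # vessels emanate from an off-center disc region, as around the optic disc
      disc_ang <- runif(1, 0, 2 * pi)
      disc <- c(ctr + 0.45 * fov_r * sin(disc_ang),
                ctr + 0.45 * fov_r * cos(disc_ang))
      grow <- function(p, ang, width, depth, len) {
        nstep <- max(2L, ceiling(len))
        for (i in seq_len(nstep)) {
          ang <- ang + rnorm(1, 0, 0.09)
          p <- p + c(sin(ang), cos(ang))
          mask <<- stamp_disc(mask, p[1], p[2], width)
        }
        if (depth > 1) {
          spread <- runif(2, 0.2, 0.55)
          w2 <- max(width * config$width_decay, 1)
          grow(p, ang + spread[1], w2, depth - 1, len * 0.85)
          grow(p, ang - spread[2], w2, depth - 1, len * 0.85)
        }
      }
      for (t in seq_len(config$n_trees)) {
        ang0 <- atan2(ctr - disc[1], ctr - disc[2]) +
          runif(1, -pi / 2, pi / 2) * 1.6
        grow(disc, ang0, config$root_width, config$branch_depth,
             len = s * runif(1, 0.14, 0.22))
      }
      mask <- mask & fov
    }

    grey <- config$background_intensity + texture_field(s)
    grey[mask] <- config$vessel_intensity
    grey <- grey + matrix(rnorm(s * s, 0, config$noise_sd), s, s)
    grey <- pmin(pmax(grey, 0), 255)
    grey[!fov] <- 0
    # quantize to the 8-bit grid so PNG write/read round trips are bit-exact
    img <- array(0, c(s, s, 3))
    for (ch in 1:3) img[, , ch] <- round(grey * c(1, 0.62, 0.35)[ch]) / 255

    structure(list(image = img, mask = matrix(as.integer(mask), s, s),
                   image_id = sprintf("synthetic_%06d", config$seed),
                   source = "synthetic", annotator = NA_character_,
                   config = config),
              class = "fundus_sample")
  })
}

#' @export
print.fundus_sample <- function(x, ...) {
  cat(sprintf("<fundus_sample %s [%s]: %d x %d, vessel fraction %.3f>\n",
              x$image_id, x$source, nrow(x$mask), ncol(x$mask),
              mean(x$mask)))
  invisible(x)
}

#' Fraction of vessel pixels within the field of view
#'
#' @param sample a `fundus_sample`.
#' @return fraction in `[0, 1]`.
#' @export
vessel_fraction <- function(sample) {
  s <- nrow(sample$mask)
  ctr <- (s + 1) / 2
  frac <- if (inherits(sample$config, "synthetic_config"))
    sample$config$fov_radius_frac else 1
  d2 <- outer((seq_len(s) - ctr)^2, (seq_len(s) - ctr)^2, "+")
  fov <- d2 <= (frac * s / 2)^2
  sum(sample$mask[fov]) / sum(fov)
}

#' Generate and write a synthetic dataset
#'
#' Renders `n` samples with seeds `seed + 0:(n-1)`, writes paired PNG files
#' under `dir/images` and `dir/masks` plus a `manifest.csv`
#' (image_id, image, mask, seed), in the layout read back by
#' [load_dataset()] with `layout = "synthetic"`.
#'
#' @param dir output directory (created).
#' @param n number of samples.
#' @param seed base seed.
#' @param ... further arguments to [synthetic_config()].
#' @return the manifest data.frame, invisibly.
#' @export
write_synthetic_dataset <- function(dir, n, seed = 1L, ...) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    sm <- generate_synthetic_fundus(synthetic_config(seed = seed + i - 1L, ...))
    ip <- file.path(dir, "images", paste0(sm$image_id, ".png"))
    mp <- file.path(dir, "masks", paste0(sm$image_id, ".png"))
    raster_write(sm$image, ip)
    raster_write(sm$mask, mp)
    data.frame(image_id = sm$image_id, image = ip, mask = mp,
               seed = seed + i - 1L, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
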