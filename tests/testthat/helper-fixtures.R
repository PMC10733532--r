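# Shared fixtures: tiny configurations, an independent parameter-count
# oracle, and mock dataset trees built from synthetic rasters.

tiny_schedule <- c(4L, 8L, 16L, 32L, 64L)

tiny_model <- function(variant, ...) {
  build_model(model_config(variant, channel_schedule = tiny_schedule, ...))
}

# Independent layer-walking oracle: closed-form cost of every learned layer
# (k^2 * c_in * c_out + c_out per convolution with bias, 2c per batch norm).
# count_params() instead enumerates the allocated weight arrays.
closed_form_params <- function(model) {
  tot <- 0
  for (ly in model$modules) {
    tot <- tot + if (ly$kind == "conv") ly$k^2 * ly$cin * ly$cout + ly$cout
                 else 2 * ly$c
  }
  tot
}

random_mask <- function(n = 16, p = 0.5) {
  matrix(rbinom(n * n, 1, p), n, n)
}

# Brute-force per-pixel enumeration of the confusion counts.
enumerate_confusion <- function(pred, gt) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1
    else if (pred[i] == 0 && gt[i] == 0) tn <- tn + 1
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1
    else fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

synth_batch <- function(n, seed0, size = 32L, ...) {
  lapply(seq_len(n), function(i)
    generate_synthetic_fundus(synthetic_config(seed = seed0 + i - 1L,
                                               size = size, ...)))
}

write_grey_png <- function(path, size = 12L, value = 0.5) {
  m <- matrix(value, size, size)
  naunet:::raster_write(m, path)
}

write_rgb_raster <- function(path, size = 12L) {
  a <- array(runif(size * size * 3), c(size, size, 3))
  naunet:::raster_write(a, path)
}

# Mock directory trees in the three public-dataset layouts, populated with
# small synthetic rasters (PNG/TIFF stand-ins for the original formats).
mock_drive_tree <- function(root) {
  for (split in c("training", "test")) {
    idir <- file.path(root, split, "images")
    mdir <- file.path(root, split, "1st_manual")
    dir.create(idir, recursive = TRUE)
    dir.create(mdir, recursive = TRUE)
    ids <- if (split == "test") 1:20 else 21:40
    for (i in ids) {
      write_rgb_raster(file.path(idir, sprintf("%02d_%s.tif", i, split)))
      write_grey_png(file.path(mdir, sprintf("%02d_manual1.png", i)),
                     value = 1)
    }
  }
  root
}

mock_hrf_tree <- function(root, with_glaucoma = TRUE) {
  idir <- file.path(root, "images")
  mdir <- file.path(root, "manual1")
  dir.create(idir, recursive = TRUE)
  dir.create(mdir, recursive = TRUE)
  for (i in 1:15) {
    for (kind in c("h", "dr")) {
      write_rgb_raster(file.path(idir, sprintf("%02d_%s.jpg", i, kind)))
      write_grey_png(file.path(mdir, sprintf("%02d_%s.tif", i, kind)), value = 1)
    }
    if (with_glaucoma && i <= 2)
      write_rgb_raster(file.path(idir, sprintf("%02d_g.jpg", i)))
  }
  root
}

mock_chasedb_tree <- function(root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (i in 1:14) {
    for (side in c("L", "R")) {
      stem <- sprintf("Image_%02d%s", i, side)
      write_rgb_raster(file.path(root, paste0(stem, ".jpg")))
      write_grey_png(file.path(root, paste0(stem, "_1stHO.png")), value = 1)
    }
  }
  root
}
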