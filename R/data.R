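# Dataset readers and preprocessing.
#
# Images are kept as (H, W, C) arrays in [0, 1] and masks as H x W 0/1
# matrices; EBImage (which stores rasters transposed, x-major) handles the
# actual file formats.

raster_read <- function(path) {
  if (tolower(tools::file_ext(path)) == "gif")
    stop("cannot read GIF raster ", path,
         "; convert the mask to PNG or TIFF first")
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2L) return(t(a))
  if (length(dim(a)) >= 3L) {
    a <- a[, , 1:min(dim(a)[3], 3), drop = FALSE]
    if (dim(a)[3] == 1L) return(t(a[, , 1]))
    return(aperm(a, c(2, 1, 3)))
  }
  stop("unsupported raster in ", path)
}

raster_write <- function(x, path) {
  if (is.matrix(x)) {
    im <- EBImage::Image(t(x))
  } else {
    im <- EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color")
  }
  EBImage::writeImage(im, path)
  invisible(path)
}

resize_raster <- function(x, size, bilinear = TRUE) {
  filt <- if (bilinear) "bilinear" else "none"
  if (is.matrix(x)) {
    a <- EBImage::imageData(EBImage::resize(EBImage::Image(t(x)),
                                            w = size, h = size, filter = filt))
    t(a)
  } else {
    a <- EBImage::imageData(EBImage::resize(
      EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color"),
      w = size, h = size, filter = filt))
    aperm(a, c(2, 1, 3))
  }
}

new_sample <- function(image, mask, image_id, source, annotator = NA_character_) {
  structure(list(image = image, mask = mask, image_id = image_id,
                 source = source, annotator = annotator),
            class = "fundus_sample")
}

# Find the mask file for image id `id` in `dir`, trying the readable raster
# extensions first so converted DRIVE masks are picked up before the GIFs.
find_mask <- function(dir, stem) {
  for (ext in c("png", "tif", "tiff", "jpg", "jpeg", "gif")) {
    p <- file.path(dir, paste0(stem, ".", ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

read_pair <- function(image_path, mask_path, image_id, source, annotator) {
  img <- raster_read(image_path)
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  msk <- raster_read(mask_path)
  if (!is.matrix(msk)) msk <- msk[, , 1]
  msk <- matrix(as.integer(msk > 0), nrow(msk), ncol(msk))
  if (!identical(dim(img)[1:2], dim(msk)))
    stop("image and mask dims differ for ", image_id)
  new_sample(img, msk, image_id, source, annotator)
}

load_drive <- function(root, split, annotator) {
  sub <- if (split == "train") "training" else "test"
  idir <- file.path(root, sub, "images")
  mdir <- file.path(root, sub, if (annotator == 1) "1st_manual" else "2nd_manual")
  imgs <- sort(list.files(idir, pattern = "\\.(tif|tiff|png|jpg|jpeg)$",
                          ignore.case = TRUE))
  if (!length(imgs)) stop("no DRIVE images found under ", idir)
  lapply(imgs, function(f) {
    id <- sub("_.*$", "", tools::file_path_sans_ext(f))
    mp <- find_mask(mdir, sprintf("%s_manual%d", id, annotator))
    if (is.null(mp))
      stop("missing DRIVE manual mask for image ", f, " (expected ",
           file.path(mdir, sprintf("%s_manual%d.*", id, annotator)), ")")
    read_pair(file.path(idir, f), mp, id, "drive", as.character(annotator))
  })
}

load_hrf <- function(root, split) {
  idir <- file.path(root, "images")
  mdir <- file.path(root, "manual1")
  imgs <- sort(list.files(idir, pattern = "\\.(jpg|jpeg|png|tif|tiff)$",
                          ignore.case = TRUE))
  # healthy and diabetic-retinopathy images only; the glaucoma subset
  # (*_g.*) is excluded
  imgs <- imgs[!grepl("_g\\.", imgs, ignore.case = TRUE)]
  if (!length(imgs)) stop("no HRF images found under ", idir)
  n_train <- 26L
  keep <- if (split == "train") seq_len(min(n_train, length(imgs)))
          else setdiff(seq_along(imgs), seq_len(min(n_train, length(imgs))))
  if (!length(keep)) stop("HRF ", split, " split is empty with ",
                          length(imgs), " images present")
  lapply(imgs[keep], function(f) {
    stem <- tools::file_path_sans_ext(f)
    mp <- find_mask(mdir, stem)
    if (is.null(mp)) stop("missing HRF mask for image ", f, " under ", mdir)
    read_pair(file.path(idir, f), mp, stem, "hrf", "1")
  })
}

load_chasedb <- function(root, split, annotator) {
  imgs <- sort(list.files(root, pattern = "^Image_.*\\.(jpg|jpeg|png)$",
                          ignore.case = TRUE))
  imgs <- imgs[!grepl("stHO|ndHO", imgs)]
  if (!length(imgs)) stop("no CHASE_DB1 images found under ", root)
  n_train <- 21L
  keep <- if (split == "train") seq_len(min(n_train, length(imgs)))
          else setdiff(seq_along(imgs), seq_len(min(n_train, length(imgs))))
  if (!length(keep)) stop("CHASE_DB1 ", split, " split is empty with ",
                          length(imgs), " images present")
  suffix <- if (annotator == 1) "_1stHO" else "_2ndHO"
  lapply(imgs[keep], function(f) {
    stem <- tools::file_path_sans_ext(f)
    mp <- find_mask(root, paste0(stem, suffix))
    if (is.null(mp))
      stop("missing CHASE_DB1 mask for image ", f, " (expected ",
           file.path(root, paste0(stem, suffix, ".*")), ")")
    read_pair(file.path(root, f), mp, stem, "chasedb", as.character(annotator))
  })
}

load_synthetic <- function(root) {
  idir <- file.path(root, "images")
  mdir <- file.path(root, "masks")
  imgs <- sort(list.files(idir, pattern = "\\.png$", ignore.case = TRUE))
  if (!length(imgs)) stop("no synthetic images found under ", idir)
  lapply(imgs, function(f) {
    mp <- file.path(mdir, f)
    if (!file.exists(mp)) stop("missing synthetic mask ", mp)
    read_pair(file.path(idir, f), mp, tools::file_path_sans_ext(f),
              "synthetic", NA_character_)
  })
}

#' Load a fundus dataset
#'
#' Reads image/mask pairs from the directory layouts of the DRIVE, HRF and
#' CHASE_DB1 public datasets, or from the paired-PNG layout written by
#' [write_synthetic_dataset()]. Masks are binarized at `> 0`. Ordering is
#' deterministic (sorted by image id). Split conventions: DRIVE ships
#' separate `training/` and `test/` trees (20/20); HRF uses the first 26 of
#' the 30 healthy + diabetic-retinopathy images for training and the
#' remaining 4 for testing; CHASE_DB1 uses the first 21 of 28 for training
#' and the remaining 7 for testing. The synthetic layout has no canonical
#' split and always returns every sample.
#'
#' @param root dataset root directory.
#' @param layout `"drive"`, `"hrf"`, `"chasedb"` or `"synthetic"`.
#' @param split `"train"` or `"test"`.
#' @param annotator 1 or 2 (DRIVE and CHASE_DB1 carry two expert markings;
#'   the first is the default ground truth).
#' @return list of `fundus_sample`s.
#' @export
load_dataset <- function(root, layout = c("drive", "hrf", "chasedb", "synthetic"),
                         split = c("train", "test"), annotator = 1L) {
  layout <- match.arg(layout)
  split <- match.arg(split)
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  if (!annotator %in% 1:2) stop("annotator must be 1 or 2")
  switch(layout,
         drive = load_drive(root, split, annotator),
         hrf = load_hrf(root, split),
         chasedb = load_chasedb(root, split, annotator),
         synthetic = load_synthetic(root))
}

#' Preprocess a sample for the network
#'
#' Resizes the image to `size x size` (bilinear), scales to `[0, 1]` and
#' normalizes each channel with the ImageNet statistics
#' mean = (0.485, 0.456, 0.406), sd = (0.229, 0.224, 0.225); the mask is
#' resized with nearest-neighbor interpolation so it stays binary.
#'
#' @param sample a `fundus_sample`.
#' @param size target square side (must be divisible by 16 for the network).
#' @return list with `x` (`size x size x 3` normalized array), `mask`
#'   (`size x size` 0/1 matrix) and `image_id`.
#' @export
preprocess <- function(sample, size = 576L) {
  img <- sample$image
  if (nrow(img) != size || ncol(img) != size)
    img <- resize_raster(img, size, bilinear = TRUE)
  mn <- c(0.485, 0.456, 0.406)
  sdv <- c(0.229, 0.224, 0.225)
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - mn[ch]) / sdv[ch]
  msk <- sample$mask
  if (nrow(msk) != size || ncol(msk) != size) {
    msk <- resize_raster(msk + 0, size, bilinear = FALSE)
    msk <- matrix(as.integer(msk > 0.5), size, size)
  }
  list(x = img, mask = msk, image_id = sample$image_id)
}
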