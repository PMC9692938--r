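## Image pre-processing: load class-subdirectory trees, grayscale (BT.601
## luma), bilinear resize (EBImage), row-major vectorization, [0,1]
## normalization, and stratified 80-20 splits.

#' Create an image record
#'
#' @param pixels H x W matrix (grayscale) or H x W x 3 array (RGB) of
#'   intensities in `[0, 255]`
#' @param label class label string
#' @param id record identifier
#' @return a list of class `"ImageRecord"`
#' @export
imageRecord <- function(pixels, label, id) {
  if (length(dim(pixels)) == 2L) dimnames(pixels) <- NULL
  if (!all(is.finite(pixels))) stop("pixel intensities must be finite")
  structure(list(pixels = pixels, label = as.character(label),
                 id = as.character(id)),
            class = "ImageRecord")
}

#' Load a directory tree of labeled images
#'
#' Expects `path/<class>/<image>.png|jpg|jpeg`; the subdirectory name becomes
#' the label. Records are returned in deterministic lexicographic order
#' (class, then file name). Unreadable files are skipped with a warning.
#' Intensities are scaled to `[0, 255]`.
#'
#' @param path directory containing class-named subdirectories
#' @return list of [imageRecord()]s
#' @export
loadImageDir <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  records <- list()
  for (cl in classes) {
    files <- sort(list.files(file.path(path, cl),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      img <- tryCatch(EBImage::readImage(f), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping unreadable image: ", f)
        next
      }
      px <- .ebimage_to_pixels(img)
      records[[length(records) + 1L]] <-
        imageRecord(px, label = cl, id = file.path(cl, basename(f)))
    }
  }
  if (length(records) == 0L) stop("no readable images under ", path)
  records
}

# EBImage stores x (width) as the first dimension in [0,1]; convert to an
# H x W (x 3) array in [0,255]
.ebimage_to_pixels <- function(img) {
  a <- EBImage::imageData(img) * 255
  if (length(dim(a)) == 2L) return(t(a))
  if (dim(a)[3] >= 3L) return(aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)))
  t(a[, , 1L])
}

#' Convert an image record to grayscale
#'
#' Uses the BT.601 luma combination `0.299 R + 0.587 G + 0.114 B`, rounded to
#' the nearest integer to preserve 8-bit semantics. Grayscale input passes
#' through unchanged.
#'
#' @param record an [imageRecord()]
#' @return grayscale [imageRecord()]
#' @export
toGrayscale <- function(record) {
  px <- record$pixels
  if (length(dim(px)) == 2L) return(record)
  g <- round(0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L])
  imageRecord(g, record$label, record$id)
}

#' Resize an image record with bilinear interpolation
#'
#' Delegates to EBImage's bilinear filter (center-aligned sampling with edge
#' clamping).
#'
#' @param record an [imageRecord()] (grayscale or RGB)
#' @param height,width positive target dimensions
#' @return resized [imageRecord()]
#' @export
resizeImage <- function(record, height, width) {
  if (height < 1L || width < 1L) stop("target dimensions must be positive")
  px <- record$pixels
  gray <- length(dim(px)) == 2L
  # back to EBImage orientation (x = width first)
  a <- if (gray) t(px) else aperm(px, c(2, 1, 3))
  out <- EBImage::resize(EBImage::Image(a / 255,
                                        colormode = if (gray) "Grayscale"
                                        else "Color"),
                         w = width, h = height, filter = "bilinear")
  imageRecord(.ebimage_to_pixels(out), record$label, record$id)
}

#' Flatten a grayscale image row-major into a vector
#'
#' Order is `(r0c0, r0c1, ..., r0c(W-1), r1c0, ...)`; a 64 x 64 image yields
#' length 4096.
#'
#' @param record a grayscale [imageRecord()]
#' @return numeric vector of length `H * W`
#' @export
vectorizeImage <- function(record) {
  px <- record$pixels
  if (length(dim(px)) != 2L) stop("vectorizeImage needs a grayscale image")
  as.vector(t(px))
}

#' Normalize pixel intensities from [0, 255] to [0, 1]
#'
#' @param x numeric vector/matrix of intensities in `[0, 255]`
#' @return rescaled values; 0 maps to 0 and 255 maps to 1 exactly
#' @export
normalizePixels <- function(x) x / 255

#' Pre-process image records into a labeled FeatureTable
#'
#' The standard auto-encoder path: grayscale, bilinear resize to
#' `size x size`, row-major vectorization and (optionally) normalization to
#' `[0, 1]`.
#'
#' @param records list of [imageRecord()]s
#' @param size target side length (default 64, giving 4096 pixels)
#' @param normalize divide by 255 (default TRUE)
#' @return a \linkS4class{FeatureTable} with labels from the records
#' @export
prepImages <- function(records, size = 64L, normalize = TRUE) {
  vecs <- lapply(records, function(r)
    vectorizeImage(resizeImage(toGrayscale(r), size, size)))
  X <- do.call(rbind, vecs)
  if (normalize) X <- normalizePixels(X)
  rownames(X) <- vapply(records, `[[`, character(1), "id")
  FeatureTable(X, y = vapply(records, `[[`, character(1), "label"),
               featureIds = paste0("px", seq_len(ncol(X)) - 1L))
}

#' Stratified train/test split
#'
#' Within each class, samples are shuffled with the given seed and the first
#' `rounding(trainFraction * n)` go to the training set. `"floor_train"`
#' takes the floor; `"nearest_train"` rounds half up. Both subsets together
#' partition the input.
#'
#' @param labels factor/character vector of class labels (or a list of
#'   [imageRecord()]s, whose `label` fields are used)
#' @param trainFraction fraction of each class assigned to training,
#'   in (0, 1); default 0.8
#' @param rounding `"floor_train"` or `"nearest_train"`
#' @param seed shuffle seed
#' @return list with integer index vectors `train` and `test`
#' @examples
#' sp <- stratifiedSplit(rep(c("a", "b"), c(930, 708)),
#'                       rounding = "nearest_train", seed = 1)
#' length(sp$train)  # 744 + 566
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.8,
                            rounding = c("floor_train", "nearest_train"),
                            seed = 1L) {
  rounding <- match.arg(rounding)
  if (is.list(labels))
    labels <- vapply(labels, `[[`, character(1), "label")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  y <- as.factor(labels)
  if (any(table(y) < 2L)) stop("every class needs at least 2 samples")
  .with_seed(seed, {
    train <- integer(0)
    for (lv in levels(y)) {
      idx <- which(y == lv)
      nTr <- if (rounding == "floor_train")
        floor(trainFraction * length(idx))
      else
        floor(trainFraction * length(idx) + 0.5)
      nTr <- max(1L, min(length(idx) - 1L, as.integer(nTr)))
      idx <- idx[sample.int(length(idx))]
      train <- c(train, idx[seq_len(nTr)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

#' Write a split manifest as two-column text
#'
#' @param records list of [imageRecord()]s (or a character vector of ids)
#' @param split list with `train`/`test` from [stratifiedSplit()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSplitManifest <- function(records, split, path) {
  ids <- if (is.character(records)) records else
    vapply(records, `[[`, character(1), "id")
  part <- rep("test", length(ids))
  part[split$train] <- "train"
  utils::write.table(data.frame(id = ids, partition = part), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- external CNN backbone adapter -----------------------------------

.backbones <- new.env(parent = emptyenv())

# contract dimensionalities of the conventional backbones
.known_backbone_dims <- c(alexnet = 4096L, googlenet = 1000L,
                          resnet50 = 2048L, densenet201 = 1920L)

#' Register an external CNN feature-extractor backbone
#'
#' The package does not bundle pre-trained networks; it defines the adapter
#' contract. A backbone is a function taking a list of [imageRecord()]s and
#' returning a numeric matrix with one row per record whose width equals the
#' declared dimensionality. The conventional names `alexnet` (4096),
#' `googlenet` (1000), `resnet50` (2048) and `densenet201` (1920) must be
#' registered at those widths.
#'
#' @param name backbone name
#' @param fn extractor function `records -> matrix`
#' @param dim declared output width; defaults to the conventional width for
#'   known names
#' @return `name`, invisibly
#' @export
registerBackbone <- function(name, fn, dim = NULL) {
  if (is.null(dim)) {
    if (!name %in% names(.known_backbone_dims))
      stop("dim must be given for non-conventional backbone names")
    dim <- .known_backbone_dims[[name]]
  } else if (name %in% names(.known_backbone_dims) &&
             dim != .known_backbone_dims[[name]]) {
    stop("backbone '", name, "' must have width ",
         .known_backbone_dims[[name]])
  }
  assign(name, list(fn = fn, dim = as.integer(dim)), envir = .backbones)
  invisible(name)
}

#' @rdname registerBackbone
#' @export
registeredBackbones <- function() sort(ls(.backbones))

#' Extract features through a registered CNN backbone
#'
#' @param records list of [imageRecord()]s
#' @param backboneName a name previously passed to [registerBackbone()]
#' @return a labeled \linkS4class{FeatureTable} whose width equals the
#'   backbone's declared dimensionality
#' @export
cnnFeatureAdapter <- function(records, backboneName) {
  if (!exists(backboneName, envir = .backbones))
    stop("backbone '", backboneName, "' is not registered; registered: ",
         if (length(registeredBackbones()))
           paste(registeredBackbones(), collapse = ", ") else "(none)")
  bb <- get(backboneName, envir = .backbones)
  X <- bb$fn(records)
  if (!is.matrix(X) || nrow(X) != length(records) || ncol(X) != bb$dim)
    stop("backbone '", backboneName, "' violated its contract (expected ",
         length(records), " x ", bb$dim, ")")
  FeatureTable(X, y = vapply(records, `[[`, character(1), "label"),
               featureIds = paste0(backboneName, "_",
                                   seq_len(ncol(X)) - 1L))
}
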