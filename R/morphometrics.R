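## Morphometrics: black-background photograph -> masks -> contour ->
## aligned shape parameters (area, length, width, aspect ratio).

#' Segment a black-background image into per-object masks
#'
#' Global Otsu thresholding followed by connected-component labeling; one
#' binary mask is returned per foreground component with at least
#' `min_object_px` pixels. A featureless (constant) image yields an empty
#' list rather than an error.
#'
#' @param image single-channel numeric matrix with values in `[0, 1]`.
#' @param min_object_px minimum component size in pixels.
#' @return list of logical mask matrices (possibly empty), disjoint by
#'   construction.
#' @export
segment_image <- function(image, min_object_px = 50L) {
  if (length(dim(image)) != 2L || !is.numeric(image)) {
    stop_invalid("'image' must be a single-channel numeric matrix")
  }
  if (diff(range(image)) == 0) return(list())
  thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  mask <- image > thr
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_object_px)
  lapply(keep, function(k) lab == k)
}

#' Extract the outer boundary contour of a mask
#'
#' Traces the 0.5-level isoline of the largest connected component (marching
#' squares on the zero-padded mask), so boundary vertices sit on pixel-box
#' edges and the enclosed polygon area tracks the pixel count closely.
#' Coordinates follow the math convention: x along columns, y increasing
#' upward.
#'
#' @param mask logical or 0/1 matrix.
#' @param calibration optional mm-per-pixel factor stored on the contour.
#' @return a `"sepal_contour"`.
#' @export
mask_to_contour <- function(mask, calibration = NULL) {
  m <- (as.matrix(mask) > 0) * 1
  npx <- sum(m)
  if (npx == 0) stop_invalid("empty mask")
  if (npx < 4) stop_invalid("degenerate mask: fewer than 4 foreground pixels")
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  m <- (lab == which.max(sizes)) * 1
  pad <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  cl <- grDevices::contourLines(x = seq_len(nrow(pad)), y = seq_len(ncol(pad)),
                                z = pad, levels = 0.5)
  if (length(cl) == 0) stop_invalid("no boundary found")
  areas <- vapply(cl, function(p) abs(shoelace_area(cbind(p$x, p$y))),
                  numeric(1))
  best <- cl[[which.max(areas)]]
  ## contourLines' x runs along matrix rows (image y, downward); convert to
  ## x = column, y upward
  as_contour(cbind(x = best$y, y = -best$x), calibration = calibration)
}

#' Align a contour to its principal axes
#'
#' Translates the arc-length-weighted centroid to the origin and rotates the
#' principal axis (largest-variance direction of the vertex coordinates,
#' weighted by arc length) onto the vertical axis. If the two axes tie in
#' variance, or the rotation leaves the horizontal extent larger than the
#' vertical one, the contour is rotated a further 90 degrees so that the
#' longer extent always ends up vertical. Vertex order is preserved.
#'
#' @param contour a `"sepal_contour"`.
#' @return the aligned `"sepal_contour"`.
#' @export
align_contour <- function(contour) {
  stopifnot(inherits(contour, "sepal_contour"))
  v <- contour$vertices
  if (abs(shoelace_area(v)) < 1e-12 * max(diff(range(v[, 1])),
                                          diff(range(v[, 2])), 1)^2) {
    stop_invalid("degenerate (zero-area) contour")
  }
  seg <- sqrt(rowSums((v[c(2:nrow(v), 1), ] - v)^2))  # edge i: v[i] -> v[i+1]
  w <- (seg + c(seg[nrow(v)], seg[-nrow(v)])) / 2
  w <- w / sum(w)
  ctr <- colSums(v * w)
  vc <- sweep(v, 2, ctr)
  cov <- crossprod(vc * sqrt(w))
  e <- eigen(cov, symmetric = TRUE)
  ax <- e$vectors[, 1]  # principal direction
  ## rotate principal axis onto +y
  R <- rbind(c(ax[2], -ax[1]), c(ax[1], ax[2]))
  vr <- vc %*% t(R)
  if (diff(range(vr[, 1])) > diff(range(vr[, 2]))) {
    vr <- cbind(-vr[, 2], vr[, 1])  # extra quarter turn: long extent vertical
  }
  out <- contour
  out$vertices <- vr
  colnames(out$vertices) <- c("x", "y")
  out
}

#' Measure shape parameters of an aligned contour
#'
#' Area is the shoelace polygon area, length the vertical (principal-axis)
#' extent, width the horizontal extent, and aspect ratio their quotient.
#' When the contour carries a calibration, area is in mm^2 and length/width
#' in mm; otherwise units are pixels.
#'
#' @param contour an aligned `"sepal_contour"` (see [align_contour()]).
#' @return one-row data frame with `area`, `length`, `width`,
#'   `aspect_ratio`.
#' @export
measure_contour <- function(contour) {
  stopifnot(inherits(contour, "sepal_contour"))
  v <- contour$vertices
  cal <- if (is.null(contour$calibration)) 1 else contour$calibration
  len <- diff(range(v[, 2])) * cal
  wid <- diff(range(v[, 1])) * cal
  if (wid <= 0) stop_invalid("zero-width contour")
  data.frame(area = abs(shoelace_area(v)) * cal^2,
             length = len, width = wid, aspect_ratio = len / wid)
}

#' Measure every sepal found in a directory of photographs
#'
#' Reads each image, segments it, aligns each detected object and measures
#' its shape parameters. Labels can be supplied per file; otherwise the file
#' name (sans extension) is used as the genotype and the batch is `NA`.
#' Unreadable files are skipped with a warning and recorded in the
#' `"skipped"` attribute.
#'
#' @param images directory of PNG/TIFF images, or a character vector of
#'   image paths.
#' @param calibration mm per pixel (default 1: pixel units).
#' @param labels optional data frame with columns `file`, `genotype`,
#'   `batch` (file = base name).
#' @param min_object_px minimum object size passed to [segment_image()].
#' @return measurement table (genotype, batch, sepal_id, length, width,
#'   area, aspect_ratio), one row per detected sepal; zero rows if nothing
#'   is detected.
#' @export
measure_images <- function(images, calibration = 1, labels = NULL,
                           min_object_px = 50L) {
  files <- if (length(images) == 1L && dir.exists(images)) {
    list.files(images, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
               full.names = TRUE)
  } else {
    images
  }
  files <- sort(files)
  skipped <- character(0)
  rows <- list()
  for (f in files) {
    img <- tryCatch(read_image(f), error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable image: ", f, call. = FALSE)
      skipped <- c(skipped, f)
      next
    }
    base <- basename(f)
    geno <- tools::file_path_sans_ext(base)
    batch <- NA_character_
    if (!is.null(labels)) {
      hit <- match(base, labels$file)
      if (!is.na(hit)) {
        geno <- labels$genotype[hit]
        if ("batch" %in% names(labels)) batch <- labels$batch[hit]
      }
    }
    masks <- segment_image(img, min_object_px = min_object_px)
    for (k in seq_along(masks)) {
      cont <- align_contour(mask_to_contour(masks[[k]],
                                            calibration = calibration))
      sp <- measure_contour(cont)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(genotype = norm_label(geno), batch = norm_label(batch),
                   sepal_id = sprintf("%s#%d", base, k),
                   stringsAsFactors = FALSE),
        sp[, c("length", "width", "area", "aspect_ratio")]
      )
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(genotype = character(0), batch = character(0),
               sepal_id = character(0), length = numeric(0),
               width = numeric(0), area = numeric(0),
               aspect_ratio = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
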