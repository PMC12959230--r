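## Closed-contour container plus the synthetic outline generator and the
## deterministic rasterizer used to build image fixtures.

#' Construct a closed sepal contour
#'
#' Normalizes a vertex list into the package's contour container: consecutive
#' duplicate vertices are removed, a repeated closing vertex is dropped, and
#' orientation is made counter-clockwise.
#'
#' @param vertices two-column numeric matrix (or data frame) of x, y
#'   coordinates; at least 3 distinct vertices.
#' @param calibration optional mm-per-pixel factor carried through to
#'   [measure_contour()]; `NULL` means measurements stay in vertex units.
#' @return an object of class `"sepal_contour"`.
#' @export
as_contour <- function(vertices, calibration = NULL) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || !is.numeric(v)) {
    stop_invalid("'vertices' must be a two-column numeric matrix")
  }
  if (anyNA(v)) stop_invalid("contour vertices contain missing values")
  ## drop repeated closing vertex and consecutive duplicates
  n <- nrow(v)
  if (n >= 2L && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) >= 2L) {
    dup <- c(FALSE, rowSums(abs(diff(v))) == 0)
    v <- v[!dup, , drop = FALSE]
  }
  if (nrow(v) < 3L) stop_invalid("a contour needs at least 3 distinct vertices")
  if (shoelace_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  colnames(v) <- c("x", "y")
  structure(list(vertices = v, closed = TRUE, calibration = calibration),
            class = "sepal_contour")
}

#' Signed polygon area (shoelace formula); positive for counter-clockwise
#' @noRd
shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' @export
print.sepal_contour <- function(x, ...) {
  v <- x$vertices
  cat(sprintf("Closed contour: %d vertices, area %.4g, bbox %.4g x %.4g%s\n",
              nrow(v), abs(shoelace_area(v)),
              diff(range(v[, 1])), diff(range(v[, 2])),
              if (is.null(x$calibration)) "" else
                sprintf(" (calibration %g mm/px)", x$calibration)))
  invisible(x)
}

#' Generate a synthetic sepal outline
#'
#' Produces a superellipse-shaped closed polygon with the long axis vertical:
#' `|x/(width/2)|^p + |y/(length/2)|^p = 1` with exponent
#' `p = tip_sharpness`. `tip_sharpness = 2` gives an exact ellipse; larger
#' values square off the tip, smaller values sharpen it. Optional radial
#' noise perturbs each vertex multiplicatively.
#'
#' @param length,width extents along the long (vertical) and short axes;
#'   `length >= width > 0`.
#' @param tip_sharpness superellipse exponent (default 2, an ellipse).
#' @param noise_sd standard deviation of the multiplicative radial noise;
#'   0 yields a noise-free, simple polygon.
#' @param n_vertices number of polygon vertices (>= 8).
#' @param seed RNG seed for the boundary noise.
#' @return a `"sepal_contour"`.
#' @examples
#' cont <- sepal_contour(2, 1, n_vertices = 512)
#' measure_contour(cont)
#' @export
sepal_contour <- function(length, width, tip_sharpness = 2, noise_sd = 0,
                          n_vertices = 256L, seed = 1L) {
  if (!is.finite(length) || !is.finite(width) || width <= 0 || length < width) {
    stop_invalid("need length >= width > 0")
  }
  if (n_vertices < 8L) stop_invalid("'n_vertices' must be >= 8")
  if (noise_sd < 0) stop_invalid("'noise_sd' must be non-negative")
  a <- length / 2; b <- width / 2; p <- tip_sharpness
  t <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  x <- b * sign(cos(t)) * abs(cos(t))^(2 / p)
  y <- a * sign(sin(t)) * abs(sin(t))^(2 / p)
  if (noise_sd > 0) {
    f <- with_seed(seed, 1 + stats::rnorm(n_vertices, 0, noise_sd))
    x <- x * f
    y <- y * f
  }
  as_contour(cbind(x, y))
}

#' Rasterize a closed contour into a binary grayscale image
#'
#' Deterministic even-odd scan-line fill over pixel centers: no
#' anti-aliasing, so background pixels hold exactly `background` and
#' foreground pixels exactly `foreground`. By default the polygon is scaled
#' to fit the image with a margin; pass `scale` (pixels per coordinate unit)
#' for explicit control.
#'
#' @param contour a `"sepal_contour"` or two-column vertex matrix.
#' @param image_size `c(height, width)` in pixels.
#' @param scale pixels per contour unit; `NULL` auto-fits with `margin`.
#' @param margin fractional border kept clear during auto-fit.
#' @param background,foreground intensities in `[0, 1]`.
#' @return numeric matrix `height x width` with values in `[0, 1]`; row 1 is
#'   the top of the image.
#' @export
rasterize_contour <- function(contour, image_size = c(200L, 200L),
                              scale = NULL, margin = 0.1,
                              background = 0, foreground = 1) {
  if (!inherits(contour, "sepal_contour")) contour <- as_contour(contour)
  v <- contour$vertices
  if (abs(shoelace_area(v)) == 0) stop_invalid("degenerate (zero-area) polygon")
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  if (H < 1L || W < 1L) stop_invalid("'image_size' must be positive")
  bx <- range(v[, 1]); by <- range(v[, 2])
  if (is.null(scale)) {
    scale <- (1 - 2 * margin) * min(W / diff(bx), H / diff(by))
  }
  ## center the bounding box on the image center
  x <- (v[, 1] - mean(bx)) * scale + W / 2
  y <- (v[, 2] - mean(by)) * scale + H / 2
  if (min(x) < 0 || max(x) > W || min(y) < 0 || max(y) > H) {
    stop_invalid("polygon does not fit inside the image at this scale")
  }
  img <- matrix(background, nrow = H, ncol = W)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (i in seq_len(H)) {
    yc <- H - i + 0.5  # row 1 = top of image, y increasing upward
    cross <- (y <= yc) != (y2 <= yc)
    if (!any(cross)) next
    xc <- sort(x[cross] + (yc - y[cross]) * (x2[cross] - x[cross]) /
                 (y2[cross] - y[cross]))
    for (k in seq(1L, base::length(xc) - 1L, by = 2L)) {
      j1 <- floor(xc[k] + 0.5) + 1L
      j2 <- ceiling(xc[k + 1] + 0.5) - 1L
      if (j1 <= j2) img[i, j1:j2] <- foreground
    }
  }
  img
}

#' Write a grayscale image to an 8-bit PNG file
#'
#' @param img numeric matrix with values in `[0, 1]`; row 1 is the image top.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Read a PNG or TIFF image as a grayscale matrix
#'
#' RGB images are converted by the Rec. 709 luminance weights.
#'
#' @param path image file; `.png`, `.tif` or `.tiff` (TIFF needs the
#'   `tiff` package).
#' @return numeric matrix with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop_invalid("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop_invalid("unsupported image format: '", ext, "'")
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img
}
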