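#' Read a grayscale brain-section image
#'
#' Reads a PNG or TIFF raster and returns a numeric matrix of 8-bit
#' intensities (0-255). Multi-channel images are rejected unless
#' `channel` selects one.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param channel for multi-channel images, the channel index to extract;
#'   `NULL` (default) requires a single-channel image.
#' @return A numeric matrix (rows = y, columns = x), values in 0-255.
#' @export
read_section_image <- function(path, channel = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) {
    if (is.null(channel))
      stop("multi-channel image; pass `channel` to select one")
    img <- img[, , channel]
  }
  round(img * 255)
}

#' Write a grayscale image
#'
#' @param image numeric matrix, intensities 0-255.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_section_image <- function(image, path) {
  scaled <- pmin(pmax(image / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Define a region-of-interest box
#'
#' ROI boxes have the same shape, size and location for a given region
#' across all section images of an experiment, one per hemisphere.
#'
#' @param region region label (e.g. `"anterior"`, `"ventral"`, `"lateral"`,
#'   `"posterior"`).
#' @param hemisphere `"left"` or `"right"`.
#' @param x0,y0 top-left pixel (1-based).
#' @param w,h width and height in pixels.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(region, hemisphere = c("left", "right"), x0, y0, w, h) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(x0 >= 1, y0 >= 1, w >= 1, h >= 1)
  structure(list(region = region, hemisphere = hemisphere,
                 x0 = as.integer(x0), y0 = as.integer(y0),
                 w = as.integer(w), h = as.integer(h)),
            class = "roi_box")
}

#' Read ROI boxes from YAML
#'
#' The YAML is a list of entries with fields `region`, `hemisphere`,
#' `x0`, `y0`, `w`, `h`.
#'
#' @param path path to the YAML file.
#' @return A list of [roi_box()] objects.
#' @export
read_rois <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(e)
    roi_box(e$region, e$hemisphere, e$x0, e$y0, e$w, e$h))
}

#' Binarize a grayscale image at a global threshold
#'
#' Foreground is every pixel at or above the threshold. The threshold is a
#' single global value chosen once per experiment and shared across all its
#' images. Dark-signal images (signal darker than background, as in DAB
#' staining photographed on bright field) are inverted first with
#' `invert = TRUE`.
#'
#' @param image numeric matrix of intensities (0-255).
#' @param threshold global intensity threshold.
#' @param invert invert intensities (`255 - image`) before thresholding.
#' @return A logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(image, threshold, invert = FALSE) {
  if (length(dim(image)) != 2L)
    stop("binarize expects a single-channel image matrix")
  if (invert) image <- 255 - image
  image >= threshold
}

# label 8-connected foreground components of a logical matrix;
# returns an integer matrix, 0 = background
label_components <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  fg <- which(binary)
  for (p in fg) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    stack <- p
    lab[p] <- cur
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((q - 1L) %% nr) + 1L
      cl <- ((q - 1L) %/% nr) + 1L
      for (dc in -1:1) {
        cc <- cl + dc
        if (cc < 1L || cc > nc) next
        base <- (cc - 1L) * nr
        for (dr in -1:1) {
          rr <- r + dr
          if (rr < 1L || rr > nr) next
          nq <- base + rr
          if (binary[nq] && lab[nq] == 0L) {
            lab[nq] <- cur
            stack <- c(stack, nq)
          }
        }
      }
    }
  }
  lab
}

# chain-code perimeter by Moore boundary tracing: 1 per axial step,
# sqrt(2) per diagonal step; isolated pixels get a unit square boundary
trace_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (sum(mask) == 1L) return(4)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  fg <- which(pad)
  start <- fg[1L]  # column-major: first foreground of leftmost column
  sr <- ((start - 1L) %% (nr + 2L)) + 1L
  sc <- ((start - 1L) %/% (nr + 2L)) + 1L
  # Moore neighborhood in clockwise order starting west
  drs <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dcs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  per <- 0
  r <- sr; cl <- sc
  backtrack <- 1L  # came from the west
  first_next <- NULL
  repeat {
    found <- FALSE
    k <- backtrack
    for (step in 0:7) {
      k2 <- ((k - 1L + step) %% 8L) + 1L
      rr <- r + drs[k2]; cc <- cl + dcs[k2]
      if (pad[rr, cc]) {
        # next backtrack: neighbor index pointing back towards previous cell
        per <- per + if (drs[k2] != 0L && dcs[k2] != 0L) sqrt(2) else 1
        prev_r <- r; prev_cl <- cl
        r <- rr; cl <- cc
        # direction from new cell back to previous cell
        back_dr <- prev_r - r; back_dcl <- prev_cl - cl
        backtrack <- which(drs == back_dr & dcs == back_dcl)
        # rotate one step clockwise from the backtrack direction
        backtrack <- (backtrack %% 8L) + 1L
        found <- TRUE
        break
      }
    }
    if (!found) return(4)  # isolated pixel reached via degenerate mask
    if (is.null(first_next)) {
      first_next <- c(r, cl)
    } else if (r == sr && cl == sc) {
      # stop on returning to start heading the same way (Jacob's criterion)
      nk <- backtrack
      for (step in 0:7) {
        k2 <- ((nk - 1L + step) %% 8L) + 1L
        rr <- r + drs[k2]; cc <- cl + dcs[k2]
        if (pad[rr, cc]) break
      }
      if (rr == first_next[1L] && cc == first_next[2L]) break
    }
    if (per > 8 * (nr * nc)) break  # safety net
  }
  per
}

#' Count particles within an ROI box
#'
#' Re-implements the classic particle-analyzer step used for c-Fos+ cell
#' counting: 8-connected components of the binary image clipped to the ROI
#' are measured (area in pixels, chain-code perimeter, circularity
#' `4 * pi * area / perimeter^2`, capped at 1) and kept when area and
#' circularity fall inside the filter ranges. The standard filter is area
#' 5-2000 px and circularity 0.5-1.0. Particles touching the ROI edge are
#' kept by default.
#'
#' @param binary logical matrix from [binarize()].
#' @param roi a [roi_box()], or `NULL` to use the whole image.
#' @param size length-2 numeric, inclusive area range in pixels
#'   (default `c(5, 2000)`).
#' @param circ length-2 numeric, inclusive circularity range
#'   (default `c(0.5, 1)`).
#' @param exclude_edge drop particles touching the ROI border
#'   (default `FALSE`).
#' @return A list with `count` and `particles` (data.frame `label`, `area`,
#'   `perimeter`, `circularity`, `kept`).
#' @export
count_particles <- function(binary, roi = NULL, size = c(5, 2000),
                            circ = c(0.5, 1), exclude_edge = FALSE) {
  if (!is.logical(binary) || length(dim(binary)) != 2L)
    stop("binary must be a logical matrix")
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_box"))
    rows <- roi$y0:(roi$y0 + roi$h - 1L)
    cols <- roi$x0:(roi$x0 + roi$w - 1L)
    if (max(rows) > nrow(binary) || max(cols) > ncol(binary))
      stop("ROI extends beyond the image")
    binary <- binary[rows, cols, drop = FALSE]
  }
  if (!length(binary)) stop("empty ROI")
  lab <- label_components(binary)
  n <- max(lab)
  if (n == 0L)
    return(list(count = 0L,
                particles = data.frame(label = integer(), area = numeric(),
                                       perimeter = numeric(),
                                       circularity = numeric(),
                                       kept = logical())))
  parts <- lapply(seq_len(n), function(i) {
    mask <- lab == i
    area <- sum(mask)
    per <- trace_perimeter(mask)
    circy <- if (per > 0) min(1, 4 * pi * area / per^2) else 1
    idx <- which(mask, arr.ind = TRUE)
    on_edge <- any(idx[, 1L] == 1L | idx[, 1L] == nrow(mask) |
                     idx[, 2L] == 1L | idx[, 2L] == ncol(mask))
    data.frame(label = i, area = area, perimeter = per,
               circularity = circy, on_edge = on_edge)
  })
  parts <- do.call(rbind, parts)
  parts$kept <- parts$area >= size[1L] & parts$area <= size[2L] &
    parts$circularity >= circ[1L] & parts$circularity <= circ[2L]
  if (exclude_edge) parts$kept <- parts$kept & !parts$on_edge
  parts$on_edge <- NULL
  list(count = sum(parts$kept), particles = parts)
}

#' Average c-Fos counts across hemispheres
#'
#' For each region the reported count is the arithmetic mean of the left
#' and right hemisphere counts. A region with only one hemisphere
#' available is carried through with a flag; a region missing both raises
#' an error.
#'
#' @param counts a data.frame with columns `region`, `hemisphere`,
#'   `count`.
#' @return A data.frame with one row per region: `region`, `count`
#'   (mean), `n_hemispheres`, `incomplete`.
#' @export
hemisphere_average <- function(counts) {
  need <- c("region", "hemisphere", "count")
  if (!all(need %in% names(counts)))
    stop("counts must have columns region, hemisphere, count")
  out <- do.call(rbind, lapply(split(counts, counts$region), function(d) {
    ok <- !is.na(d$count)
    if (!any(ok))
      stop("region ", d$region[1L], ": no hemisphere counts available")
    data.frame(region = d$region[1L], count = mean(d$count[ok]),
               n_hemispheres = sum(ok), incomplete = sum(ok) < 2L)
  }))
  rownames(out) <- NULL
  out
}
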