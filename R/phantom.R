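#' Specify a synthetic head phantom
#'
#' Builds a validated specification for a co-registered T1/T2 phantom slice
#' pair with a known tumor mask. The phantom emulates the intensity structure
#' the segmentation pipeline assumes: an elliptical head on a zero (air)
#' background, a skull rim, gray/white matter, CSF-filled lateral ventricles,
#' and an elliptical tumor that is conspicuously bright on T2. Anatomy is
#' left-right symmetric except for the tumor, so bilateral-histogram
#' laterality analysis sees asymmetry only where a lateral tumor sits.
#'
#' Each tissue class carries a per-class heterogeneity `sd`: intensities vary
#' smoothly inside the class (a low-frequency texture field scaled by `sd`),
#' which broadens the class histogram the way partial-volume and biological
#' variation do in real slices. Independent per-pixel Gaussian acquisition
#' noise of standard deviation `noise_sd` is added on top, to every tissue
#' but not to air, so that zero intensity delimits the head.
#'
#' @param width,height image size in pixels.
#' @param tumor_position `"left"`, `"right"` or `"midline"`.
#' @param tumor `TRUE` for the default tumor (T1 120, T2 210, sd 3,
#'   semi-axes scaled from (32, 27) px at 256x256), `FALSE`/`NULL` for a
#'   tumor-free phantom, or a list overriding any of `t1_mean`, `t2_mean`,
#'   `sd`, `axes` (semi-axes, px), `center` (x, y in pixel coordinates).
#' @param edema `TRUE` to add an edema ring around the tumor (T2 between
#'   tumor and normal tissue), or a list overriding `t1_mean`, `t2_mean`,
#'   `sd`, `thickness`.
#' @param noise_sd acquisition noise standard deviation (8-bit units).
#' @param tissue_classes optional `data.frame` with columns `name`,
#'   `t1_mean`, `t2_mean`, `sd` replacing the default anatomy. Recognized
#'   names `gray_matter`, `white_matter`, `csf`, `skull` map to their
#'   anatomical regions; a single unrecognized class fills the whole brain.
#' @param seed integer RNG seed; a fixed seed gives byte-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(width = 256, height = 256,
                         tumor_position = c("left", "right", "midline"),
                         tumor = TRUE, edema = FALSE, noise_sd = 5,
                         tissue_classes = NULL, seed = 1) {
  tumor_position <- match.arg(tumor_position)
  if (width < 32 || height < 32)
    stop("phantom must be at least 32x32", call. = FALSE)
  sx <- width / 256; sy <- height / 256
  cx <- (width + 1) / 2; cy <- (height + 1) / 2

  if (is.null(tissue_classes)) {
    tissue_classes <- data.frame(
      name    = c("scalp", "skull", "gray_matter", "white_matter", "csf"),
      t1_mean = c(190, 60, 110, 150, 45),
      t2_mean = c(105, 45, 100, 80, 180),
      sd      = c(10, 5, 24, 24, 12),
      stringsAsFactors = FALSE)
  }
  if (!all(c("name", "t1_mean", "t2_mean", "sd") %in% names(tissue_classes)))
    stop("`tissue_classes` needs columns name, t1_mean, t2_mean, sd", call. = FALSE)
  if (any(tissue_classes$t1_mean < 0 | tissue_classes$t1_mean > 255 |
          tissue_classes$t2_mean < 0 | tissue_classes$t2_mean > 255))
    stop("tissue class means must lie in [0, 255]", call. = FALSE)

  tum <- NULL
  if (isTRUE(tumor) || is.list(tumor)) {
    tum <- list(t1_mean = 120, t2_mean = 210, sd = 3,
                axes = c(31 * sx, 25 * sy), center = NULL)
    if (is.list(tumor)) tum[names(tumor)] <- tumor
    if (is.null(tum$center)) {
      tum$center <- switch(tumor_position,
        left    = c(cx - 44 * sx, cy),
        right   = c(cx + 44 * sx, cy),
        midline = c(cx, cy - 46.5 * sy))
    }
    if (tum$t1_mean < 0 || tum$t1_mean > 255 || tum$t2_mean < 0 || tum$t2_mean > 255)
      stop("tumor means must lie in [0, 255]", call. = FALSE)
  }

  ede <- NULL
  if (isTRUE(edema) || is.list(edema)) {
    if (is.null(tum)) stop("edema requires a tumor", call. = FALSE)
    ede <- list(t1_mean = 100, t2_mean = 165, sd = 5, thickness = 10 * sx)
    if (is.list(edema)) ede[names(edema)] <- edema
  }

  spec <- structure(list(
    width = as.integer(width), height = as.integer(height),
    tumor_position = tumor_position,
    tissue_classes = tissue_classes,
    tumor = tum, edema = ede,
    noise_sd = noise_sd, seed = as.integer(seed),
    # geometry (pixel coordinates, x = column, y = row)
    brain_center = c(cx, cy),
    scalp_outer  = c(102 * sx, 122 * sy),
    skull_outer  = c(96 * sx, 116 * sy),
    brain_axes   = c(88 * sx, 108 * sy),
    wm_axes      = c(58 * sx, 76 * sy),
    vent_offset  = c(17 * sx, -8 * sy),
    vent_axes    = c(9 * sx, 15 * sy),
    vent_carve   = 5 * sx
  ), class = "phantom_spec")

  if (!is.null(spec$tumor)) {
    th <- seq(0, 2 * pi, length.out = 181)
    ex <- spec$tumor$center[1] + spec$tumor$axes[1] * cos(th)
    ey <- spec$tumor$center[2] + spec$tumor$axes[2] * sin(th)
    r2 <- ((ex - cx) / spec$brain_axes[1])^2 + ((ey - cy) / spec$brain_axes[2])^2
    if (any(r2 > 1))
      stop("tumor ellipse extends outside the brain ellipse; shrink `axes` or move `center`",
           call. = FALSE)
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Head phantom spec: %dx%d, tumor %s, noise sd %.1f, seed %d\n",
              x$width, x$height,
              if (is.null(x$tumor)) "none" else x$tumor_position,
              x$noise_sd, x$seed))
  if (!is.null(x$edema)) cat("  with edema ring\n")
  invisible(x)
}

# pixel-center rasterization of an ellipse
ellipse_mask <- function(width, height, center, axes) {
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  ((xs - center[1]) / axes[1])^2 + ((ys - center[2]) / axes[2])^2 <= 1
}

# Standardized tissue-texture field: a sum of fine- and coarse-scale
# box-blurred white noise (separable, 3 passes ~ Gaussian), so that
# intensity variation is multi-scale as in real MR tissue and compact
# smooth islands do not dominate. The field is mirror-symmetrized about the
# vertical midline: anatomy and tissue texture are roughly bilaterally
# symmetric, so only the tumor and the acquisition noise break left-right
# symmetry. Rescaled to zero mean / unit sd.
smooth_field <- function(height, width, radii = c(4, 12), passes = 3) {
  blur1 <- function(m, r) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    up <- pmin(seq_len(n) + r, n); lo <- pmax(seq_len(n) - r, 1)
    (cs[up + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (up - lo + 1)
  }
  f <- matrix(0, height, width)
  for (radius in radii) {
    g <- matrix(rnorm(height * width), height, width)
    for (i in seq_len(passes)) g <- t(blur1(t(blur1(g, radius)), radius))
    f <- f + (g - mean(g)) / sd(as.vector(g))
  }
  f <- (f + f[, width:1L]) / 2
  (f - mean(f)) / sd(as.vector(f))
}

#' Generate a synthetic T1/T2 phantom pair with ground truth
#'
#' Rasterizes the phantom described by a [phantom_spec()]: paints the tissue
#' classes, the optional edema ring and the tumor ellipse, modulates each
#' class by a smooth texture field scaled by the class `sd`, adds Gaussian
#' acquisition noise to every non-air pixel, and clips/rounds to 8-bit.
#' The returned ground-truth mask is exactly the rasterized tumor ellipse.
#'
#' @param spec a `phantom_spec` object.
#' @return an object of class `phantom`: a list with integer matrices `t1`,
#'   `t2` (values in 0..255), logical `tumor_mask`, integer `class_map`
#'   (0 = air) with class names in `attr(,"classes")`, and the `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(tumor_position = "left", seed = 7))
#' range(ph$t1); sum(ph$tumor_mask)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  set.seed(spec$seed)
  w <- spec$width; h <- spec$height
  ctr <- spec$brain_center

  head_m  <- ellipse_mask(w, h, ctr, spec$scalp_outer)
  skull_m <- ellipse_mask(w, h, ctr, spec$skull_outer)
  brain_m <- ellipse_mask(w, h, ctr, spec$brain_axes)
  cls <- spec$tissue_classes
  known <- c("scalp", "skull", "gray_matter", "white_matter", "csf")

  class_map <- matrix(0L, h, w)
  labels <- character(0)
  paint <- function(region, label) {
    labels <<- c(labels, label)
    class_map[region] <<- length(labels)
  }

  if (!all(cls$name %in% known)) {
    # custom anatomy: first class fills the brain, others by recognized name
    paint(brain_m, cls$name[1])
  } else {
    gm <- if ("gray_matter" %in% cls$name) "gray_matter" else cls$name[1]
    paint(brain_m, gm)
  }
  if ("white_matter" %in% cls$name)
    paint(brain_m & ellipse_mask(w, h, ctr, spec$wm_axes), "white_matter")
  if ("csf" %in% cls$name) {
    # lateral ventricles as crescents: an ellipse with a medially shifted
    # copy carved out, concave like real frontal horns
    crescent <- function(side) {
      c0 <- ctr + c(side * spec$vent_offset[1], spec$vent_offset[2])
      ellipse_mask(w, h, c0, spec$vent_axes) &
        !ellipse_mask(w, h, c0 - c(side * spec$vent_carve, 0), spec$vent_axes)
    }
    paint(brain_m & (crescent(-1) | crescent(1)), "csf")
  }
  if ("skull" %in% cls$name)
    paint(skull_m & !brain_m, "skull")
  if ("scalp" %in% cls$name)
    paint(head_m & !skull_m, "scalp")

  tumor_mask <- matrix(FALSE, h, w)
  if (!is.null(spec$edema)) {
    ring <- ellipse_mask(w, h, spec$tumor$center,
                         spec$tumor$axes + spec$edema$thickness) &
      !ellipse_mask(w, h, spec$tumor$center, spec$tumor$axes)
    paint(ring & brain_m, "edema")
  }
  if (!is.null(spec$tumor)) {
    tumor_mask <- ellipse_mask(w, h, spec$tumor$center, spec$tumor$axes)
    paint(tumor_mask, "tumor")
  }

  params <- rbind(
    cls[, c("name", "t1_mean", "t2_mean", "sd")],
    if (!is.null(spec$edema))
      data.frame(name = "edema", t1_mean = spec$edema$t1_mean,
                 t2_mean = spec$edema$t2_mean, sd = spec$edema$sd),
    if (!is.null(spec$tumor))
      data.frame(name = "tumor", t1_mean = spec$tumor$t1_mean,
                 t2_mean = spec$tumor$t2_mean, sd = spec$tumor$sd))

  f1 <- smooth_field(h, w)
  f2 <- smooth_field(h, w)
  t1 <- matrix(0, h, w); t2 <- matrix(0, h, w)
  for (k in seq_along(labels)) {
    p <- params[match(labels[k], params$name), ]
    reg <- class_map == k
    t1[reg] <- p$t1_mean + p$sd * f1[reg]
    t2[reg] <- p$t2_mean + p$sd * f2[reg]
  }
  tissue <- class_map > 0L
  if (spec$noise_sd > 0) {
    t1[tissue] <- t1[tissue] + rnorm(sum(tissue), 0, spec$noise_sd)
    t2[tissue] <- t2[tissue] + rnorm(sum(tissue), 0, spec$noise_sd)
  }
  t1 <- matrix(as.integer(pmin(255, pmax(0, round(t1)))), h, w)
  t2 <- matrix(as.integer(pmin(255, pmax(0, round(t2)))), h, w)
  attr(class_map, "classes") <- labels

  structure(list(t1 = t1, t2 = t2, tumor_mask = tumor_mask,
                 class_map = class_map, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Synthetic T1/T2 phantom %dx%d: %d tumor px (%s), classes: %s\n",
              nrow(x$t1), ncol(x$t1), sum(x$tumor_mask),
              if (is.null(x$spec$tumor)) "no tumor" else x$spec$tumor_position,
              paste(attr(x$class_map, "classes"), collapse = ", ")))
  invisible(x)
}

#' Write a phantom to PNG files
#'
#' Writes `<prefix>_t1.png`, `<prefix>_t2.png` and `<prefix>_mask.png`
#' (mask as 0/255) into `dir`.
#'
#' @param phantom a `phantom` object.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the three file paths.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_t1.png", "_t2.png", "_mask.png")))
  png::writePNG(phantom$t1 / 255, paths[1])
  png::writePNG(phantom$t2 / 255, paths[2])
  png::writePNG(phantom$tumor_mask * 1.0, paths[3])
  invisible(paths)
}
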