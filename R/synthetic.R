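#' Synthetic IR-retina cohort specification
#'
#' Parameters of the seeded case/control generator. The two classes share
#' vessel and optic-disc anatomy but differ in the spatial correlation length
#' of the background reflectance field (cases have a shorter correlation
#' length, i.e. rougher texture) and in case-only lesion speckle emulating
#' exudates and microaneurysms. The defaults mirror a 41-image clinical
#' cohort: 23 cases and 18 controls.
#'
#' @param n_cases,n_controls number of case / control images (defaults 23/18).
#' @param height,width image size in pixels (>= 32).
#' @param bit_depth 8 or 16.
#' @param corr_length_control,corr_length_case Gaussian smoothing scale (px)
#'   of the background random field for each group; larger values give
#'   smoother backgrounds and higher GLCM correlation.
#' @param lesion_count,lesion_radius_range,lesion_amplitude case-only Gaussian
#'   blob speckle: count, radius range (px) and peak amplitude (intensity
#'   units of the declared bit depth).
#' @param vessel_count,vessel_width,vessel_contrast dark random-walk vessel
#'   tracks with a 1-px bright central reflex streak.
#' @param disc_center_jitter,disc_radius,disc_brightness bright optic disc:
#'   uniform jitter (px) of the center around a nasal-side anchor, radius (px)
#'   and plateau brightness (intensity units).
#' @param noise_sd standard deviation of additive Gaussian sensor noise
#'   (intensity units), applied after compositing.
#' @param seed integer master seed; the cohort is a pure function of the spec.
#' @param null_cohort if `TRUE` both groups are generated with the control
#'   parameters and no lesions anywhere (for type-I-error studies).
#' @return A `cohort_spec` list.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_cases = 23L, n_controls = 18L,
                        height = 256L, width = 256L, bit_depth = 8L,
                        corr_length_control = 8, corr_length_case = 2,
                        lesion_count = 30L, lesion_radius_range = c(2, 6),
                        lesion_amplitude = 60,
                        vessel_count = 6L, vessel_width = 3,
                        vessel_contrast = 50,
                        disc_center_jitter = 20, disc_radius = 30,
                        disc_brightness = 240,
                        noise_sd = 4, seed = 1L, null_cohort = FALSE) {
  spec <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    height = as.integer(height), width = as.integer(width),
    bit_depth = as.integer(bit_depth),
    corr_length_control = corr_length_control,
    corr_length_case = corr_length_case,
    lesion_count = as.integer(lesion_count),
    lesion_radius_range = lesion_radius_range,
    lesion_amplitude = lesion_amplitude,
    vessel_count = as.integer(vessel_count),
    vessel_width = vessel_width, vessel_contrast = vessel_contrast,
    disc_center_jitter = disc_center_jitter, disc_radius = disc_radius,
    disc_brightness = disc_brightness,
    noise_sd = noise_sd, seed = as.integer(seed),
    null_cohort = isTRUE(null_cohort)
  )
  with(spec, {
    if (n_cases < 0L || n_controls < 0L || n_cases + n_controls < 1L) {
      stop("need n_cases >= 0, n_controls >= 0 and at least one image")
    }
    if (corr_length_control <= 0 || corr_length_case <= 0) {
      stop("correlation lengths must be > 0")
    }
    if (height < 32L || width < 32L) stop("image size must be >= 32 px")
    if (lesion_radius_range[1] > lesion_radius_range[2]) {
      stop("lesion_radius_range is inverted")
    }
    if (vessel_width < 1) stop("vessel_width must be >= 1")
    if (disc_radius <= 0) stop("disc_radius must be > 0")
  })
  structure(spec, class = "cohort_spec")
}

# Deterministic per-image substream seed; keyed by (master seed, index) so a
# subset of the cohort is reproducible independently of the rest.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

#' Background reflectance field
#'
#' Gaussian random field: white noise smoothed with an isotropic Gaussian
#' kernel of scale `corr_length` and linearly rescaled into the lower part of
#' the intensity range (so vessels, disc and lesions have contrast headroom).
#' Expected GLCM correlation increases monotonically with `corr_length`;
#' scales below 0.3 px are treated as unsmoothed i.i.d. noise.
#'
#' Uses the calling R session's random-number stream; seed beforehand for
#' reproducibility ([generate_cohort()] does this per image).
#'
#' @param spec a [cohort_spec()].
#' @param group `"control"` or `"case"`; selects the group's correlation
#'   length.
#' @return A [gray_image()].
#' @export
make_background <- function(spec, group = c("control", "case")) {
  group <- match.arg(group)
  cl <- if (group == "control") spec$corr_length_control else
    spec$corr_length_case
  if (cl <= 0) stop("correlation length must be > 0")
  z <- matrix(rnorm(spec$height * spec$width), spec$height, spec$width)
  if (cl >= 0.3) z <- as.matrix(EBImage::gblur(z, sigma = cl))
  top <- 2^spec$bit_depth - 1
  rng <- range(z)
  if (rng[1] == rng[2]) {
    px <- matrix(0.4 * top, spec$height, spec$width)
  } else {
    px <- (z - rng[1]) / (rng[2] - rng[1]) * 0.70 * top + 0.05 * top
  }
  clip_gray(px, spec$bit_depth)
}

#' Composite a bright optic disc onto an image
#'
#' Raises pixels within `radius` of `center` toward `brightness` with a
#' narrow (3 px) linear falloff band at the rim, clipped to the intensity
#' range. Discs partially outside the frame are clipped to the frame; a disc
#' entirely outside is an error.
#'
#' @param img a [gray_image()].
#' @param center numeric `(row, col)` disc center.
#' @param radius disc radius in pixels (> 0).
#' @param brightness plateau intensity.
#' @return A [gray_image()].
#' @export
add_optic_disc <- function(img, center, radius, brightness) {
  stopifnot(is_gray_image(img))
  if (radius <= 0) stop("disc radius must be > 0")
  h <- nrow(img); w <- ncol(img)
  if (center[1] < 1 - radius || center[1] > h + radius ||
      center[2] < 1 - radius || center[2] > w + radius) {
    stop("optic disc lies entirely outside the image")
  }
  d <- sqrt(outer((seq_len(h) - center[1])^2,
                  (seq_len(w) - center[2])^2, `+`))
  wgt <- pmin(pmax((radius - d) / 3, 0), 1)
  px <- unclass(img) + (brightness - unclass(img)) * wgt
  clip_gray(px, attr(img, "bit_depth"))
}

# Stamp a filled disc of given radius at each (row, col) path point into a
# logical mask. Points outside the frame are clipped.
stamp_disc_mask <- function(mask, rows, cols, radius) {
  h <- nrow(mask); w <- ncol(mask)
  r <- ceiling(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, , drop = FALSE]
  for (k in seq_len(nrow(off))) {
    rr <- rows + off$dr[k]
    cc <- cols + off$dc[k]
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    mask[cbind(rr[keep], cc[keep])] <- TRUE
  }
  mask
}

#' Composite vessel tracks onto an image
#'
#' Draws `vessel_count` dark curvilinear tracks (random walks entering from a
#' border with slowly wandering direction) of width `vessel_width`, each
#' darkened by `vessel_contrast` and carrying a 1-px central reflex streak
#' brightened by `0.5 * vessel_contrast` (the specular light streak seen along
#' vessels in IR reflectance images). `vessel_count = 0` is the identity.
#'
#' @inheritParams make_background
#' @param img a [gray_image()].
#' @return A [gray_image()].
#' @export
add_vessels <- function(img, spec) {
  stopifnot(is_gray_image(img))
  if (spec$vessel_width < 1) stop("vessel_width must be >= 1")
  if (spec$vessel_count == 0L) return(img)
  h <- nrow(img); w <- ncol(img)
  body <- matrix(FALSE, h, w)
  streak <- matrix(FALSE, h, w)
  n_steps <- ceiling(1.5 * max(h, w))
  for (v in seq_len(spec$vessel_count)) {
    side <- sample.int(4L, 1L)
    pos <- switch(side,
      c(1, runif(1, 1, w)),           # top
      c(h, runif(1, 1, w)),           # bottom
      c(runif(1, 1, h), 1),           # left
      c(runif(1, 1, h), w))           # right
    theta <- switch(side, pi / 2, -pi / 2, 0, pi) + runif(1, -0.6, 0.6)
    rows <- numeric(n_steps); cols <- numeric(n_steps)
    n_used <- 0L
    for (s in seq_len(n_steps)) {
      pos <- pos + c(sin(theta), cos(theta))
      if (pos[1] < 1 || pos[1] > h || pos[2] < 1 || pos[2] > w) break
      n_used <- s
      rows[s] <- pos[1]; cols[s] <- pos[2]
      theta <- theta + rnorm(1, sd = 0.15)
    }
    if (n_used == 0L) next
    rows <- rows[seq_len(n_used)]; cols <- cols[seq_len(n_used)]
    body <- stamp_disc_mask(body, round(rows), round(cols),
                            spec$vessel_width / 2)
    streak[cbind(round(rows), round(cols))] <- TRUE
  }
  px <- unclass(img)
  px[body] <- px[body] - spec$vessel_contrast
  px[streak] <- px[streak] + 1.5 * spec$vessel_contrast
  clip_gray(px, attr(img, "bit_depth"))
}

#' Composite lesion speckle onto an image
#'
#' Adds `lesion_count` bright Gaussian blobs (radius drawn uniformly from
#' `lesion_radius_range`, peak `lesion_amplitude`, sd = radius / 2) at
#' uniform seeded positions, emulating exudate/microaneurysm speckle. The
#' realized geometry is attached as attribute `"lesions"` (a data frame with
#' `row`, `col`, `radius`) so ground truth can be reconstructed.
#'
#' @inheritParams add_vessels
#' @return A [gray_image()] with attribute `"lesions"`.
#' @export
add_lesions <- function(img, spec) {
  stopifnot(is_gray_image(img))
  rr <- spec$lesion_radius_range
  if (rr[1] > rr[2]) stop("lesion_radius_range is inverted")
  truth <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
  if (spec$lesion_count == 0L || spec$lesion_amplitude == 0) {
    attr(img, "lesions") <- truth
    return(img)
  }
  h <- nrow(img); w <- ncol(img)
  px <- unclass(img)
  for (l in seq_len(spec$lesion_count)) {
    rad <- runif(1, rr[1], rr[2])
    cr <- runif(1, 1 + rad, h - rad)
    cc <- runif(1, 1 + rad, w - rad)
    win <- ceiling(3 * rad / 2)
    ri <- max(1, floor(cr - win)):min(h, ceiling(cr + win))
    ci <- max(1, floor(cc - win)):min(w, ceiling(cc + win))
    d2 <- outer((ri - cr)^2, (ci - cc)^2, `+`)
    px[ri, ci] <- px[ri, ci] +
      spec$lesion_amplitude * exp(-d2 / (2 * (rad / 2)^2))
    truth <- rbind(truth, data.frame(row = cr, col = cc, radius = rad))
  }
  out <- clip_gray(px, attr(img, "bit_depth"))
  attr(out, "lesions") <- truth
  out
}

# Render one cohort image under its per-image substream.
render_image <- function(spec, group, index) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(spec$seed, index))

  eff_group <- if (spec$null_cohort) "control" else group
  img <- make_background(spec, eff_group)
  img <- add_vessels(img, spec)
  center <- c(spec$height / 2 + runif(1, -1, 1) * spec$disc_center_jitter,
              spec$width * 0.25 + runif(1, -1, 1) * spec$disc_center_jitter)
  img <- add_optic_disc(img, center, spec$disc_radius, spec$disc_brightness)
  lesions_on <- !spec$null_cohort && group == "case"
  if (lesions_on) {
    img <- add_lesions(img, spec)
    lesions <- attr(img, "lesions")
  } else {
    lesions <- data.frame(row = numeric(0), col = numeric(0),
                          radius = numeric(0))
  }
  if (spec$noise_sd > 0) {
    img <- clip_gray(unclass(img) +
                       rnorm(length(img), sd = spec$noise_sd),
                     spec$bit_depth)
  }
  attr(img, "lesions") <- NULL
  list(image = img, label = group,
       truth = list(disc_center = center, disc_radius = spec$disc_radius,
                    lesions = lesions))
}

#' Generate a labeled synthetic cohort
#'
#' Produces `n_cases + n_controls` labeled IR-like images. Each image is
#' rendered under its own RNG substream keyed by `(seed, index)`, so the same
#' spec always yields a bit-identical cohort and any subset is reproducible.
#' Cases are rendered first (indices `1..n_cases`), then controls.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `ir_cohort`; each record has `image_id`, `image`
#'   (a [gray_image()]), `label` (`"case"` or `"control"`) and `truth`
#'   (realized disc and lesion geometry).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_cases = 2, n_controls = 2,
#'                                    height = 64, width = 64, seed = 7))
#' sapply(coh, `[[`, "label")
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  if (n < 1L) stop("cohort must contain at least one image")
  labels <- c(rep("case", spec$n_cases), rep("control", spec$n_controls))
  records <- vector("list", n)
  n_digits <- max(2L, nchar(n))
  counters <- c(case = 0L, control = 0L)
  for (i in seq_len(n)) {
    counters[labels[i]] <- counters[labels[i]] + 1L
    rec <- render_image(spec, labels[i], i)
    rec$image_id <- sprintf("%s_%0*d", labels[i], n_digits,
                            counters[labels[i]])
    records[[i]] <- rec[c("image_id", "image", "label", "truth")]
  }
  structure(records, class = "ir_cohort", spec = spec)
}

#' @export
print.ir_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("<ir_cohort> %d images (%d case, %d control), %dx%d, %d-bit\n",
              length(x), sum(labs == "case"), sum(labs == "control"),
              attr(x, "spec")$height, attr(x, "spec")$width,
              attr(x, "spec")$bit_depth))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one grayscale image per record (PNG for 8-bit, TIFF for 16-bit), a
#' `labels.csv` with columns `image_id,label`, and a `truth.json` with the
#' realized per-image geometry.
#'
#' @param cohort an `ir_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ir_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (attr(cohort, "spec")$bit_depth == 8L) "png" else "tiff"
  for (rec in cohort) {
    write_gray_image(rec$image, file.path(dir,
                                          paste0(rec$image_id, ".", ext)))
  }
  labels <- data.frame(image_id = vapply(cohort, `[[`, "", "image_id"),
                       label = vapply(cohort, `[[`, "", "label"))
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  truth <- lapply(cohort, `[[`, "truth")
  names(truth) <- labels$image_id
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
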