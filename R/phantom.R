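## Synthetic chest phantom generator with stage-wise ground truth.
##
## A phantom emulates the confusion structure of a 2D chest CT slice:
## two dark lung fields inside a brighter thorax ellipse, bright
## circular nodules inside the parenchyma, bright thin vessel
## cross-sections inside the parenchyma (candidates but not nodules,
## drawn at the same intensity as nodules so only shape separates them),
## bright distractor blobs outside the parenchyma (rib/sternum stand-ins
## that stage-1 masking must remove), and additive Gaussian noise.
## Everything is driven by R's RNG under an explicit seed, so a fixed
## (params, seed) pair reproduces a phantom bit-exactly.

#' Phantom generation parameters
#'
#' Intensities are already normalized to `[0, 1]` (CT windowing for real
#' scans lives in [normalize_hu()]).
#'
#' @param image_size pixels per side (>= 32).
#' @param nodule_count_range integer interval for the nodule count.
#' @param nodule_diameter_range nodule diameter interval in pixels.
#' @param vessel_count_range integer interval for vessel cross-sections.
#' @param distractor_count_range integer interval for outside-lung blobs.
#' @param noise_sigma additive Gaussian noise standard deviation (>= 0).
#' @param parenchyma_intensity,tissue_intensity,lesion_intensity,distractor_intensity
#'   intensity levels in `[0, 1]` for the lung fields, the surrounding
#'   thorax, nodules/vessels, and the outside-lung blobs.
#' @return object of class `"phantom_params"`.
#' @export
phantom_params <- function(image_size = 64L,
                           nodule_count_range = c(1L, 4L),
                           nodule_diameter_range = c(5, 11),
                           vessel_count_range = c(2L, 5L),
                           distractor_count_range = c(1L, 3L),
                           noise_sigma = 0.03,
                           parenchyma_intensity = 0.2,
                           tissue_intensity = 0.55,
                           lesion_intensity = 0.75,
                           distractor_intensity = 0.85) {
  p <- list(image_size = as.integer(image_size),
            nodule_count_range = as.integer(round(nodule_count_range)),
            nodule_diameter_range = as.numeric(nodule_diameter_range),
            vessel_count_range = as.integer(round(vessel_count_range)),
            distractor_count_range = as.integer(round(distractor_count_range)),
            noise_sigma = noise_sigma,
            parenchyma_intensity = parenchyma_intensity,
            tissue_intensity = tissue_intensity,
            lesion_intensity = lesion_intensity,
            distractor_intensity = distractor_intensity)
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (p$image_size < 32L) {
    stop("image_size must be at least 32 to contain two lung fields ",
         "plus margins, got ", p$image_size)
  }
  if (!rng_ok(p$nodule_count_range) || !rng_ok(p$nodule_diameter_range) ||
      !rng_ok(p$vessel_count_range) || !rng_ok(p$distractor_count_range)) {
    stop("all ranges must be non-empty (low <= high)")
  }
  if (p$nodule_diameter_range[1] <= 0) stop("nodule diameters must be positive")
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0")
  ints <- c(p$parenchyma_intensity, p$tissue_intensity, p$lesion_intensity,
            p$distractor_intensity)
  if (any(ints < 0 | ints > 1)) stop("intensities must lie in [0, 1]")
  invisible(p)
}

# preserve the caller's RNG state across seeded generation
with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# two lung-field ellipses: centers and semi-axes (rows, cols), as
# fractions of the image size
phantom_geometry <- function(L) {
  list(
    thorax = list(c = c(0.50, 0.50) * L, a = c(0.40, 0.47) * L),
    lungs = list(
      list(c = c(0.50, 0.30) * L, a = c(0.28, 0.155) * L),
      list(c = c(0.50, 0.70) * L, a = c(0.28, 0.155) * L)
    )
  )
}

in_ellipse <- function(rr, cc, e, shrink = 0) {
  a <- pmax(e$a - shrink, 1e-6)
  ((rr - e$c[1]) / a[1])^2 + ((cc - e$c[2]) / a[2])^2 <= 1
}

disc_pixels <- function(L, cr, cc, d) {
  r <- d / 2
  lo_r <- max(1L, floor(cr - r)); hi_r <- min(L, ceiling(cr + r))
  lo_c <- max(1L, floor(cc - r)); hi_c <- min(L, ceiling(cc + r))
  rows <- lo_r:hi_r; cols <- lo_c:hi_c
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - cr)^2 + (g$col - cc)^2 <= r^2
  cbind(g$row[keep], g$col[keep])
}

#' Generate one synthetic chest phantom
#'
#' Deterministic for a fixed `(params, seed)`. The returned sample
#' carries the image plus nested ground truth: the parenchyma mask, the
#' candidate mask (nodules and vessels), the nodule mask (annotated
#' discs only), and the annotation table. Mask nesting
#' `nodule <= candidate <= parenchyma` holds pixel-wise, and the nodule
#' mask is exactly the union of the annotated discs.
#'
#' @param params a [phantom_params()].
#' @param seed integer RNG seed.
#' @return object of class `"phantom_sample"` with elements `image`
#'   (an [image_slice()]), `parenchyma_mask`, `candidate_mask`,
#'   `nodule_mask` (0/1 integer matrices), `nodules` (data frame with
#'   `id`, `center_row`, `center_col`, `diameter`, `contrast`), and
#'   `seed`.
#' @export
generate_phantom <- function(params = phantom_params(), seed = 1L) {
  validate_phantom_params(params)
  with_seed(seed, {
    L <- params$image_size
    geo <- phantom_geometry(L)
    rr <- matrix(seq_len(L), L, L)
    cc <- matrix(seq_len(L), L, L, byrow = TRUE)

    thorax <- in_ellipse(rr, cc, geo$thorax)
    lung1 <- in_ellipse(rr, cc, geo$lungs[[1]])
    lung2 <- in_ellipse(rr, cc, geo$lungs[[2]])
    parenchyma <- lung1 | lung2

    img <- matrix(0.05, L, L)
    img[thorax] <- params$tissue_intensity
    img[parenchyma] <- params$parenchyma_intensity

    nodule_mask <- matrix(FALSE, L, L)
    vessel_mask <- matrix(FALSE, L, L)

    # a disc of radius r fits inside a lung if its center lies in the
    # ellipse shrunk by r + 1 (conservative margin)
    fits_lung <- function(r0, c0, rad) {
      any(vapply(geo$lungs, function(e) {
        in_ellipse(r0, c0, e, shrink = rad + 1)
      }, logical(1)))
    }

    # --- nodules ---
    n_nod <- sample_int_range(params$nodule_count_range)
    placed <- data.frame(center_row = numeric(0), center_col = numeric(0),
                         diameter = numeric(0))
    for (k in seq_len(n_nod)) {
      d <- stats::runif(1, params$nodule_diameter_range[1],
                        params$nodule_diameter_range[2])
      ok <- FALSE
      for (try in seq_len(200L)) {
        r0 <- stats::runif(1, 1, L); c0 <- stats::runif(1, 1, L)
        if (!fits_lung(r0, c0, d / 2)) next
        if (nrow(placed) > 0) {
          sep <- sqrt((placed$center_row - r0)^2 + (placed$center_col - c0)^2)
          if (any(sep < (placed$diameter + d) / 2 + 3)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) next # crowded lung: skip, annotations stay consistent
      placed <- rbind(placed, data.frame(center_row = r0, center_col = c0,
                                         diameter = d))
      px <- disc_pixels(L, r0, c0, d)
      nodule_mask[px] <- TRUE
      img[px] <- params$lesion_intensity
    }

    # --- vessel cross-sections: thin bright curves, same intensity as
    #     nodules, kept clear of nodules so lesions stay separable ---
    n_ves <- sample_int_range(params$vessel_count_range)
    for (k in seq_len(n_ves)) {
      for (try in seq_len(50L)) {
        r0 <- stats::runif(1, 1, L); c0 <- stats::runif(1, 1, L)
        if (fits_lung(r0, c0, 2)) break
      }
      theta <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 8, 18)
      pos <- c(r0, c0)
      for (s in seq_len(round(len))) {
        px <- disc_pixels(L, pos[1], pos[2], 2.4)
        inside <- parenchyma[px]
        if (nrow(placed) > 0) {
          clear <- vapply(seq_len(nrow(px)), function(j) {
            all(sqrt((placed$center_row - px[j, 1])^2 +
                     (placed$center_col - px[j, 2])^2) >
                  placed$diameter / 2 + 2.5)
          }, logical(1))
          inside <- inside & clear
        }
        px <- px[inside, , drop = FALSE]
        vessel_mask[px] <- TRUE
        img[px] <- params$lesion_intensity
        theta <- theta + stats::rnorm(1, 0, 0.3)
        pos <- pos + c(cos(theta), sin(theta))
      }
    }

    # --- outside-lung distractors (rib/sternum blobs) ---
    n_dis <- sample_int_range(params$distractor_count_range)
    for (k in seq_len(n_dis)) {
      for (try in seq_len(100L)) {
        r0 <- stats::runif(1, 1, L); c0 <- stats::runif(1, 1, L)
        d <- stats::runif(1, 4, 9)
        inside_thorax <- in_ellipse(r0, c0, geo$thorax, shrink = d / 2)
        outside_lungs <- !any(vapply(geo$lungs, function(e) {
          in_ellipse(r0, c0, e, shrink = -(d / 2 + 2))
        }, logical(1)))
        if (inside_thorax && outside_lungs) break
      }
      px <- disc_pixels(L, r0, c0, d)
      px <- px[!parenchyma[px], , drop = FALSE]
      img[px] <- params$distractor_intensity
    }

    if (params$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(L * L, 0, params$noise_sigma), L, L)
    }
    img <- pmin(pmax(img, 0), 1)

    nodules <- if (nrow(placed) > 0) {
      data.frame(id = seq_len(nrow(placed)),
                 center_row = placed$center_row,
                 center_col = placed$center_col,
                 diameter = placed$diameter,
                 contrast = params$lesion_intensity - params$parenchyma_intensity)
    } else {
      data.frame(id = integer(0), center_row = numeric(0),
                 center_col = numeric(0), diameter = numeric(0),
                 contrast = numeric(0))
    }

    structure(list(
      image = image_slice(img),
      parenchyma_mask = matrix(as.integer(parenchyma), L, L),
      candidate_mask = matrix(as.integer(nodule_mask | vessel_mask), L, L),
      nodule_mask = matrix(as.integer(nodule_mask), L, L),
      nodules = nodules,
      seed = as.integer(seed),
      params = params
    ), class = "phantom_sample")
  })
}

sample_int_range <- function(r) {
  if (r[1] == r[2]) return(r[1])
  r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
}

#' @export
print.phantom_sample <- function(x, ...) {
  L <- nrow(x$image$values)
  cat(sprintf("<phantom_sample> %dx%d, %d nodule(s), %d candidate px, seed %d\n",
              L, L, nrow(x$nodules), sum(x$candidate_mask), x$seed))
  invisible(x)
}

# deterministic per-sample seed derivation from the master seed
phantom_derived_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 100000) * 20011 + i * 7919) %% 2147483647L
}

#' Generate a seeded phantom dataset
#'
#' Per-sample seeds derive deterministically from the master seed. A
#' configurable fraction of samples is negative (zero nodules), so the
#' empty-ground-truth branch of the dice loss is exercised during
#' training.
#'
#' @param n number of samples (>= 1).
#' @param params a [phantom_params()].
#' @param seed master seed.
#' @param negative_fraction fraction of samples generated with zero
#'   nodules; `round(n * negative_fraction)` samples, chosen by a seeded
#'   draw.
#' @return list of [generate_phantom()] samples.
#' @export
generate_dataset <- function(n, params = phantom_params(), seed = 1L,
                             negative_fraction = 0.3) {
  stopifnot(n >= 1, negative_fraction >= 0, negative_fraction <= 1)
  k <- round(n * negative_fraction)
  neg_idx <- with_seed(seed, sample.int(n, k))
  neg_params <- params
  neg_params$nodule_count_range <- c(0L, 0L)
  lapply(seq_len(n), function(i) {
    p <- if (i %in% neg_idx) neg_params else params
    generate_phantom(p, phantom_derived_seed(seed, i))
  })
}

#' Write / read a phantom dataset on disk
#'
#' One directory per sample: `image.png` (16-bit grayscale),
#' `parenchyma.png` / `candidates.png` / `nodules.png` (binary 8-bit),
#' and `annotations.csv`; a dataset-level `manifest.json` lists the
#' sample directories and the master seed.
#'
#' @param samples list of phantom samples.
#' @param dir output directory.
#' @param seed master seed recorded in the manifest.
#' @export
write_phantom_dataset <- function(samples, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  names <- sprintf("sample_%04d", seq_along(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    sd <- file.path(dir, names[i])
    dir.create(sd, showWarnings = FALSE)
    write_png16(s$image$values, file.path(sd, "image.png"))
    png::writePNG(s$parenchyma_mask + 0, file.path(sd, "parenchyma.png"))
    png::writePNG(s$candidate_mask + 0, file.path(sd, "candidates.png"))
    png::writePNG(s$nodule_mask + 0, file.path(sd, "nodules.png"))
    write_annotations(s$nodules, file.path(sd, "annotations.csv"))
  }
  jsonlite::write_json(
    list(samples = names, master_seed = seed, n = length(samples)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_phantom_dataset
#' @export
read_phantom_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a phantom dataset (no manifest.json): ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  lapply(manifest$samples, function(nm) {
    sd <- file.path(dir, nm)
    img <- png::readPNG(file.path(sd, "image.png"))
    msk <- function(f) {
      m <- png::readPNG(file.path(sd, f))
      matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    }
    structure(list(
      image = image_slice(img),
      parenchyma_mask = msk("parenchyma.png"),
      candidate_mask = msk("candidates.png"),
      nodule_mask = msk("nodules.png"),
      nodules = read_annotations(file.path(sd, "annotations.csv")),
      seed = NA_integer_,
      params = NULL
    ), class = "phantom_sample")
  })
}
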