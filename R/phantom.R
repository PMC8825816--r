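# Synthetic OCT-like B-scan phantoms with ground truth.

# run code with a temporary RNG state seeded from `seed`; restores the
# caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Phantom B-scan specification
#'
#' Describes a synthetic OCT-like B-scan: horizontal layer bands, dark
#' elliptical cysts, vertical vessel-shadow bands, and multiplicative
#' speckle-like noise.
#'
#' @param m,n image dimensions (rows, columns).
#' @param layers list of bands, each `list(top, bottom, intensity)` with
#'   optional `intensity_bottom` for a linear vertical gradient within the
#'   band. Bands must be ordered top to bottom, non-overlapping, and cover
#'   all rows.
#' @param cysts list of ellipses, each `list(center_row, center_col,
#'   semi_row, semi_col, intensity)`. Cyst interiors must be darker than the
#'   band they sit in (fluid appears dark between retinal layers).
#' @param shadows list of column bands, each `list(col_start, col_end,
#'   attenuation, from_row)`: intensities in the columns are multiplied by
#'   `attenuation` (in `(0, 1)`) for all rows at or below `from_row`,
#'   mimicking the beam attenuation beneath a retinal vessel.
#' @param noise_sigma speckle strength: each pixel is multiplied by
#'   `1 + noise_sigma * z` with `z` standard normal, then clipped to
#'   `[0, 255]`. Default 0.05.
#' @param seed RNG seed for the noise field (`NULL` = use the current RNG
#'   state).
#' @return A `phantom_spec` object (list).
#' @seealso [dme_phantom_spec()] for the standard preset.
#' @export
phantom_spec <- function(m, n, layers, cysts = list(), shadows = list(),
                         noise_sigma = 0.05, seed = NULL) {
  m <- as.integer(m); n <- as.integer(n)
  if (m < 7L || n < 7L) stop("phantom must be at least 7 x 7", call. = FALSE)
  tops <- vapply(layers, `[[`, numeric(1), "top")
  bots <- vapply(layers, `[[`, numeric(1), "bottom")
  ord <- order(tops)
  tops <- tops[ord]; bots <- bots[ord]; layers <- layers[ord]
  if (tops[1] != 1L || bots[length(bots)] != m ||
      (length(tops) > 1L && any(tops[-1] != bots[-length(bots)] + 1L))) {
    stop("layer bands must be non-overlapping and cover rows 1..m",
         call. = FALSE)
  }
  for (cy in cysts) {
    band <- which(tops <= cy$center_row & bots >= cy$center_row)
    if (length(band) == 1L) {
      bi <- layers[[band]]$intensity
      if (cy$intensity >= bi) {
        stop("cyst interior intensity must be darker than its enclosing band",
             call. = FALSE)
      }
    } else {
      warning("cyst centred outside all bands")
    }
  }
  for (sh in shadows) {
    if (sh$attenuation <= 0 || sh$attenuation >= 1) {
      stop("shadow attenuation must lie in (0, 1)", call. = FALSE)
    }
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(list(m = m, n = n, layers = layers, cysts = cysts,
                 shadows = shadows, noise_sigma = noise_sigma, seed = seed),
            class = "phantom_spec")
}

#' Standard DME-like phantom preset
#'
#' A 100 x 256 phantom emulating a B-scan with diabetic macular edema:
#' dark vitreous (intensity 30, rows 1-19), a bright inner band (180, rows
#' 20-28), mid retinal tissue (120, rows 29-70), the bright outer band
#' corresponding to the retinal pigment epithelium (200, rows 71-80), a
#' moderately bright choroid (140, rows 81-90) and a linear posterior
#' signal roll-off back to 30 (rows 91-100). Real B-scans do not end in a
#' hard bright-to-black edge below the outer band — signal decays gradually
#' through the choroid — and the preset reproduces that so the outer band's
#' lower boundary is the only strong bottom transition.
#'
#' @param cystic include one dark elliptical cyst (centre (50, 128),
#'   semi-axes 10 rows x 24 columns, interior intensity 35) in the mid
#'   tissue. Default `TRUE`.
#' @param shadow include one vessel-shadow band (columns 60-70, attenuation
#'   0.2 applied from row 29 down). Default `FALSE`.
#' @param noise_sigma,seed see [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
dme_phantom_spec <- function(cystic = TRUE, shadow = FALSE,
                             noise_sigma = 0.05, seed = NULL) {
  layers <- list(
    list(top = 1,  bottom = 19,  intensity = 30),
    list(top = 20, bottom = 28,  intensity = 180),
    list(top = 29, bottom = 70,  intensity = 120),
    list(top = 71, bottom = 80,  intensity = 200),
    list(top = 81, bottom = 90,  intensity = 140),
    list(top = 91, bottom = 100, intensity = 140, intensity_bottom = 30)
  )
  cysts <- if (isTRUE(cystic)) {
    list(list(center_row = 50, center_col = 128,
              semi_row = 10, semi_col = 24, intensity = 35))
  } else {
    list()
  }
  shadows <- if (isTRUE(shadow)) {
    list(list(col_start = 60, col_end = 70, attenuation = 0.2, from_row = 29))
  } else {
    list()
  }
  phantom_spec(100, 256, layers, cysts, shadows,
               noise_sigma = noise_sigma, seed = seed)
}

#' Generate a phantom B-scan with ground truth
#'
#' Renders the layer bands, then the cysts (overwriting band intensity
#' inside each ellipse), then the shadows (multiplying intensities in the
#' shadow columns at and below `from_row` by the attenuation factor), then
#' applies multiplicative speckle-like noise and clips to `[0, 255]`.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_scan`: a list with `image` (an
#'   [oct_image()]), `truth_label` (`"cystic"` iff any cyst is present),
#'   `cyst_mask` (logical matrix covering exactly the ellipse interiors),
#'   `true_shadow_columns` (integer vector) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  m <- spec$m; n <- spec$n
  img <- matrix(0, m, n)
  for (ly in spec$layers) {
    rows <- ly$top:ly$bottom
    if (is.null(ly$intensity_bottom)) {
      img[rows, ] <- ly$intensity
    } else {
      grad <- seq(ly$intensity, ly$intensity_bottom, length.out = length(rows))
      img[rows, ] <- matrix(grad, length(rows), n)
    }
  }
  mask <- matrix(FALSE, m, n)
  if (length(spec$cysts) > 0L) {
    ii <- matrix(seq_len(m), m, n)
    jj <- matrix(seq_len(n), m, n, byrow = TRUE)
    for (cy in spec$cysts) {
      inside <- ((ii - cy$center_row) / cy$semi_row)^2 +
        ((jj - cy$center_col) / cy$semi_col)^2 <= 1
      img[inside] <- cy$intensity
      mask <- mask | inside
    }
  }
  shadow_cols <- integer()
  for (sh in spec$shadows) {
    cols <- sh$col_start:sh$col_end
    rows <- sh$from_row:m
    img[rows, cols] <- img[rows, cols] * sh$attenuation
    shadow_cols <- union(shadow_cols, cols)
  }
  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed,
                     img * (1 + spec$noise_sigma * matrix(rnorm(m * n), m, n)))
  }
  img <- pmin(pmax(img, 0), 255)
  structure(list(
    image = oct_image(img),
    truth_label = if (any(mask)) "cystic" else "non-cystic",
    cyst_mask = mask,
    true_shadow_columns = sort(shadow_cols),
    spec = spec
  ), class = "phantom_scan")
}

#' @export
print.phantom_scan <- function(x, ...) {
  cat(sprintf("<phantom_scan> %d x %d, %s, %d cyst pixel(s), %d shadow column(s)\n",
              nrow(x$image), ncol(x$image), x$truth_label,
              sum(x$cyst_mask), length(x$true_shadow_columns)))
  invisible(x)
}

#' Generate a reproducible batch of phantom scans
#'
#' Produces `n_cystic` scans with one randomly placed cyst, `n_clean` scans
#' with layers only, and `n_shadow_only` scans with one randomly placed
#' vessel-shadow band, all on the [dme_phantom_spec()] layer geometry.
#' Cyst centres, semi-axes and interior intensity, and shadow position,
#' width and attenuation, are drawn from uniform ranges chosen to span the
#' appearance of DME cysts and vessel shadows (see the package vignette).
#' Reproducible for a fixed `seed`; scans are returned shuffled-free, cystic
#' first.
#'
#' @param n_cystic,n_clean,n_shadow_only non-negative counts.
#' @param base_spec a `phantom_spec` providing geometry, layers and noise
#'   level (cysts/shadows in it are ignored); default [dme_phantom_spec()]
#'   without cyst or shadow.
#' @param seed integer seed driving all randomness in the batch.
#' @return A list of `phantom_scan` objects.
#' @export
generate_batch <- function(n_cystic, n_clean, n_shadow_only,
                           base_spec = dme_phantom_spec(cystic = FALSE),
                           seed = 1L) {
  stopifnot(n_cystic >= 0, n_clean >= 0, n_shadow_only >= 0)
  n_tot <- n_cystic + n_clean + n_shadow_only
  if (n_tot == 0L) return(list())
  with_seed(seed, {
    scan_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
    kinds <- rep(c("cystic", "clean", "shadow"),
                 c(n_cystic, n_clean, n_shadow_only))
    lapply(seq_len(n_tot), function(k) {
      sp <- base_spec
      sp$cysts <- list()
      sp$shadows <- list()
      sp$seed <- scan_seeds[k]
      if (kinds[k] == "cystic") {
        sp$cysts <- list(list(
          center_row = round(runif(1, 44, 56)),
          center_col = round(runif(1, 60, sp$n - 60)),
          semi_row = round(runif(1, 7, 12)),
          semi_col = round(runif(1, 16, 30)),
          intensity = runif(1, 30, 42)
        ))
      } else if (kinds[k] == "shadow") {
        start <- round(runif(1, 30, sp$n - 45))
        sp$shadows <- list(list(
          col_start = start,
          col_end = start + round(runif(1, 8, 14)),
          attenuation = runif(1, 0.15, 0.3),
          from_row = 29
        ))
      }
      generate_phantom(sp)
    })
  })
}

#' Write a phantom scan to disk
#'
#' Writes the image as an 8-bit grayscale PNG, the ground truth as a JSON
#' sidecar (`<name>.truth.json`: label and shadow columns) and the cyst mask
#' as a binary PNG (`<name>.mask.png`).
#'
#' @param scan a `phantom_scan`.
#' @param dir output directory (created if needed).
#' @param name file stem (default `"phantom"`).
#' @return The image path, invisibly.
#' @export
write_phantom <- function(scan, dir, name = "phantom") {
  stopifnot(inherits(scan, "phantom_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".png"))
  write_oct_png(scan$image, img_path)
  png::writePNG(matrix(as.numeric(scan$cyst_mask),
                       nrow(scan$cyst_mask), ncol(scan$cyst_mask)),
                target = file.path(dir, paste0(name, ".mask.png")))
  jsonlite::write_json(
    list(label = scan$truth_label,
         shadow_columns = scan$true_shadow_columns),
    file.path(dir, paste0(name, ".truth.json")),
    auto_unbox = TRUE
  )
  invisible(img_path)
}

#' Write a batch of phantoms plus a manifest CSV
#'
#' @param scans list of `phantom_scan` objects.
#' @param dir output directory.
#' @return Path of the manifest CSV (columns `path`, `label`), invisibly.
#' @export
write_batch <- function(scans, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(scans), function(k) {
    write_phantom(scans[[k]], dir, sprintf("phantom_%03d", k))
  }, character(1))
  manifest <- data.frame(
    path = basename(paths),
    label = vapply(scans, `[[`, character(1), "truth_label"),
    stringsAsFactors = FALSE
  )
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
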