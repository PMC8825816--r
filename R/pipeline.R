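# Full pipeline: denoise -> boundary detection -> shadow removal -> label.

#' Pipeline parameters
#'
#' @param detection a [detection_params()] object.
#' @param shadow a [shadow_params()] object.
#' @param median_kernel odd median-filter window size in pixels; 1 disables
#'   denoising. Default 3, the minimal speckle-suppressing window (the
#'   detector's accuracy is insensitive to the choice of denoiser).
#' @param shadow_margin column distance within which candidates are
#'   discarded around flagged shadow columns. `NULL` (default) resolves to
#'   `t`, the patch width: a candidate whose patch could overlap a shadow
#'   column is suspect.
#' @param min_candidates number of surviving candidates required to label a
#'   scan cystic (default 1; one accepted patch already certifies at least
#'   `num + 1` boundary pixels).
#' @param remove_shadows logical; set `FALSE` to skip the shadow-removal
#'   phase entirely (useful for quantifying its effect on specificity).
#' @return A `pipeline_params` object (list).
#' @export
pipeline_params <- function(detection = detection_params(),
                            shadow = shadow_params(),
                            median_kernel = 3L,
                            shadow_margin = NULL,
                            min_candidates = 1L,
                            remove_shadows = TRUE) {
  stopifnot(inherits(detection, "detection_params"),
            inherits(shadow, "shadow_params"))
  median_kernel <- as.integer(median_kernel)
  if (is.na(median_kernel) || median_kernel < 1L || median_kernel %% 2L == 0L) {
    stop("`median_kernel` must be odd and >= 1", call. = FALSE)
  }
  if (!is.null(shadow_margin) &&
      (!is.numeric(shadow_margin) || shadow_margin < 0)) {
    stop("`shadow_margin` must be >= 0", call. = FALSE)
  }
  min_candidates <- as.integer(min_candidates)
  if (is.na(min_candidates) || min_candidates < 1L) {
    stop("`min_candidates` must be >= 1", call. = FALSE)
  }
  structure(list(detection = detection, shadow = shadow,
                 median_kernel = median_kernel,
                 shadow_margin = shadow_margin,
                 min_candidates = min_candidates,
                 remove_shadows = isTRUE(remove_shadows)),
            class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  print(x$detection)
  print(x$shadow)
  cat(sprintf("  median_kernel = %d, shadow_margin = %s, min_candidates = %d, remove_shadows = %s\n",
              x$median_kernel,
              if (is.null(x$shadow_margin)) "t" else format(x$shadow_margin),
              x$min_candidates, x$remove_shadows))
  invisible(x)
}

#' Median-filter denoising
#'
#' Per-pixel median over a square window, with image edges handled by
#' reflection. Speckle noise in coherent imaging is impulsive enough that a
#' small median window suppresses it without displacing layer edges.
#'
#' @param img an [oct_image()] or numeric matrix.
#' @param kernel odd window size in pixels; `kernel = 1` returns the input
#'   unchanged.
#' @return A matrix of the same dimensions (an [oct_image()] when the input
#'   was one).
#' @export
denoise_median <- function(img, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel < 1L || kernel %% 2L == 0L) {
    stop("`kernel` must be odd and >= 1", call. = FALSE)
  }
  if (kernel > min(nrow(img), ncol(img))) {
    stop("`kernel` must not exceed the smaller image dimension", call. = FALSE)
  }
  if (kernel == 1L) return(img)
  out <- .median_filter_cpp(unclass(img), kernel)
  if (inherits(img, "oct_image")) oct_image(out) else out
}

#' Remove candidates near shadow columns
#'
#' Drops every candidate whose seed column lies within `margin` columns of
#' any flagged shadow column; the order of survivors is preserved. Dark
#' vessel shadows produce boundary-like transitions that are easily mistaken
#' for cyst boundaries, so discarding candidates near detected shadow
#' columns suppresses false positives.
#'
#' @param candidates a [detect_candidates()] result.
#' @param shadow a [detect_shadow_columns()] result.
#' @param margin non-negative column distance.
#' @return A `cyst_candidates` object (subset of the input).
#' @export
remove_near_shadow <- function(candidates, shadow, margin) {
  stopifnot(inherits(candidates, "cyst_candidates"),
            inherits(shadow, "shadow_profile"))
  if (!is.numeric(margin) || margin < 0) {
    stop("`margin` must be >= 0", call. = FALSE)
  }
  sc <- shadow$shadow_columns
  if (length(sc) == 0L || nrow(candidates) == 0L) return(candidates)
  near <- vapply(candidates$seed_col,
                 function(j) min(abs(j - sc)) <= margin,
                 logical(1))
  subset_candidates(candidates, !near)
}

#' Classify a B-scan as cystic or non-cystic
#'
#' Runs the full pipeline: median denoising, boundary pixel determination
#' with patch voting, shadow-column detection, removal of candidates near
#' shadow columns, and labelling. The scan is labelled `"cystic"` when at
#' least `min_candidates` candidates survive shadow removal. Fully
#' deterministic for a fixed input and parameter set.
#'
#' @param img an [oct_image()] (or numeric matrix on the `[0, 255]` scale).
#' @param params a [pipeline_params()] object.
#' @return An object of class `oct_scan_result`: a list with `label`
#'   (`"cystic"` or `"non-cystic"`), `candidates_raw`, `candidates_kept`
#'   (both `cyst_candidates`), `shadow` (a `shadow_profile`), and
#'   `params_used` (the fully resolved parameter set, including the
#'   per-image `thv` and `shadow_margin`).
#' @examples
#' scan <- generate_phantom(dme_phantom_spec(seed = 7))
#' res <- classify_scan(scan$image)
#' res$label
#' @export
classify_scan <- function(img, params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  if (!is.matrix(img)) stop("`img` must be a matrix image", call. = FALSE)
  img <- if (inherits(img, "oct_image")) img else oct_image(img)
  den <- denoise_median(img, params$median_kernel)
  raw <- detect_candidates(den, params$detection)
  shadow <- detect_shadow_columns(den, params$shadow)
  margin <- if (is.null(params$shadow_margin)) params$detection$t
            else params$shadow_margin
  kept <- if (params$remove_shadows) {
    remove_near_shadow(raw, shadow, margin)
  } else {
    raw
  }
  label <- if (nrow(kept) >= params$min_candidates) "cystic" else "non-cystic"
  resolved <- params
  resolved$detection$thv <- attr(raw, "thv")
  resolved$shadow$jump_thr <- shadow$jump_thr
  resolved$shadow_margin <- margin
  structure(list(label = label,
                 candidates_raw = raw,
                 candidates_kept = kept,
                 shadow = shadow,
                 params_used = resolved),
            class = "oct_scan_result")
}

#' @export
print.oct_scan_result <- function(x, ...) {
  cat(sprintf("<oct_scan_result> label = %s (%d raw, %d kept, %d shadow column(s))\n",
              x$label, nrow(x$candidates_raw), nrow(x$candidates_kept),
              length(x$shadow$shadow_columns)))
  invisible(x)
}

#' Serialize a scan result to JSON-friendly form
#'
#' @param result an [classify_scan()] result.
#' @return A list ready for [jsonlite::write_json()]: label, counts, the
#'   candidate table (1-based coordinates, member coordinates included) and
#'   the shadow profile.
#' @export
scan_result_payload <- function(result) {
  stopifnot(inherits(result, "oct_scan_result"))
  cand_list <- function(cands) {
    mems <- attr(cands, "members")
    lapply(seq_len(nrow(cands)), function(r) {
      list(seed_row = cands$seed_row[r], seed_col = cands$seed_col[r],
           side = cands$side[r],
           patch = list(row_min = cands$row_min[r], row_max = cands$row_max[r],
                        col_min = cands$col_min[r], col_max = cands$col_max[r]),
           member_count = cands$member_count[r],
           members = apply(mems[[r]], 1, function(v)
             list(row = unname(v[1]), col = unname(v[2])), simplify = FALSE))
    })
  }
  list(
    label = result$label,
    n_raw = nrow(result$candidates_raw),
    n_kept = nrow(result$candidates_kept),
    thv = attr(result$candidates_raw, "thv"),
    candidates = cand_list(result$candidates_kept),
    shadow = list(
      alpha = result$shadow$alpha,
      jump_thr = result$shadow$jump_thr,
      columns = result$shadow$shadow_columns,
      q = result$shadow$q
    )
  )
}

#' Render a detection overlay as an RGB PNG
#'
#' Draws accepted patch rectangles in blue with the seed pixel marked in
#' red, and tints flagged shadow columns, over the grayscale scan.
#'
#' @param img the [oct_image()] that was classified.
#' @param result an [classify_scan()] result.
#' @param path output PNG path.
#' @param which_candidates `"kept"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(img, result, path, which_candidates = c("kept", "raw")) {
  which_candidates <- match.arg(which_candidates)
  stopifnot(inherits(result, "oct_scan_result"))
  g <- pmin(pmax(unclass(img) / 255, 0), 1)
  rgb <- array(rep(g, 3L), dim = c(nrow(g), ncol(g), 3L))
  sc <- result$shadow$shadow_columns
  if (length(sc) > 0L) {  # yellow tint on shadow columns
    rgb[, sc, 1] <- pmin(rgb[, sc, 1] * 0.6 + 0.4, 1)
    rgb[, sc, 2] <- pmin(rgb[, sc, 2] * 0.6 + 0.4, 1)
  }
  cands <- if (which_candidates == "kept") result$candidates_kept
           else result$candidates_raw
  for (r in seq_len(nrow(cands))) {
    r0 <- cands$row_min[r]; r1 <- cands$row_max[r]
    c0 <- cands$col_min[r]; c1 <- cands$col_max[r]
    rgb[c(r0, r1), c0:c1, 1] <- 0; rgb[c(r0, r1), c0:c1, 2] <- 0
    rgb[c(r0, r1), c0:c1, 3] <- 1
    rgb[r0:r1, c(c0, c1), 1] <- 0; rgb[r0:r1, c(c0, c1), 2] <- 0
    rgb[r0:r1, c(c0, c1), 3] <- 1
    rgb[cands$seed_row[r], cands$seed_col[r], ] <- c(1, 0, 0)
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}
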