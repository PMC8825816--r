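# Boundary pixel determination: vertical-transition seeds confirmed by
# diagonal-transition patch voting.

#' Detection parameters for boundary pixel determination
#'
#' @param thv absolute significance threshold on the difference maps, in
#'   intensity units on the `[0, 255]` scale. If `NULL` (default) the
#'   threshold is resolved per image as `thv_rel` times the intensity range
#'   of the (denoised) image, which keeps behavior stable across
#'   acquisition brightness.
#' @param thv_rel relative threshold used when `thv` is `NULL`. The default
#'   0.25 places the threshold between typical inter-layer transition
#'   contrast and the larger contrast of fluid against surrounding tissue;
#'   calibrate with [sweep_params()] for other acquisition settings.
#' @param s,t patch row and column counts in pixels (defaults 11 and 11).
#' @param num patch acceptance count: a patch is accepted when it contains
#'   strictly more than `num` significant diagonal-transition pixels
#'   (default 10, so every accepted patch certifies at least `num + 1`
#'   member pixels, plus the seed).
#' @param a,b averaging-window half-widths passed to [diff_maps()]
#'   (defaults 1 and 1).
#' @return A `detection_params` object (list).
#' @export
detection_params <- function(thv = NULL, thv_rel = 0.25, s = 11L, t = 11L,
                             num = 10L, a = 1L, b = 1L) {
  if (!is.null(thv) && (!is.numeric(thv) || thv <= 0)) {
    stop("`thv` must be > 0", call. = FALSE)
  }
  if (is.null(thv) && (!is.numeric(thv_rel) || thv_rel <= 0 || thv_rel >= 1)) {
    stop("`thv_rel` must lie in (0, 1)", call. = FALSE)
  }
  s <- as.integer(s); t <- as.integer(t); num <- as.integer(num)
  if (is.na(s) || s < 1L) stop("`s` must be >= 1", call. = FALSE)
  if (is.na(t) || t < 1L) stop("`t` must be >= 1", call. = FALSE)
  if (is.na(num) || num < 0L) stop("`num` must be >= 0", call. = FALSE)
  if (num >= s * t) stop("`num` must be < s * t", call. = FALSE)
  if (a < 1L || b < 1L) stop("`a` and `b` must be >= 1", call. = FALSE)
  structure(list(thv = thv, thv_rel = thv_rel, s = s, t = t, num = num,
                 a = as.integer(a), b = as.integer(b)),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  thv <- if (is.null(x$thv)) sprintf("%.2f x image range", x$thv_rel)
         else sprintf("%.2f", x$thv)
  cat(sprintf("<detection_params> thv = %s, s = %d, t = %d, num = %d, a = %d, b = %d\n",
              thv, x$s, x$t, x$num, x$a, x$b))
  invisible(x)
}

# Resolve the absolute threshold for a given (denoised) image.
resolve_thv <- function(params, img) {
  if (!is.null(params$thv)) return(params$thv)
  params$thv_rel * (max(img) - min(img))
}

#' Seed pixels with significant vertical light-to-dark transitions
#'
#' Returns the set `V`: pixels where `dv` is a strict vertical local maximum,
#' `dv > 0` (brighter above than below, the entrance point of a possible
#' cyst) and `|dv| > thv`.
#'
#' @param diff an [diff_maps()] result.
#' @param thv absolute significance threshold (> 0).
#' @return A two-column integer matrix of 1-based `(row, col)` seed
#'   coordinates, with the generating logical mask as attribute `"mask"`.
#' @export
find_vertical_seeds <- function(diff, thv) {
  stopifnot(inherits(diff, "oct_diff_maps"))
  if (!is.numeric(thv) || thv <= 0) stop("`thv` must be > 0", call. = FALSE)
  mask <- local_max_mask(diff$dv, "vertical")
  ok <- !is.na(diff$dv) & diff$dv > 0 & abs(diff$dv) > thv
  ok[is.na(ok)] <- FALSE
  mask <- mask & ok
  seeds <- which(mask, arr.ind = TRUE)
  dimnames(seeds) <- list(NULL, c("row", "col"))
  attr(seeds, "mask") <- mask
  seeds
}

#' Pixels with significant diagonal light-to-dark transitions
#'
#' Returns the sets `L` and `R` as logical masks. A pixel belongs to `L`
#' when `dl > 0`, `dl > thv` and `dl` is a strict local maximum along the
#' down-right diagonal — a diagonal transition at the left side of a dark
#' region; `R` is the symmetric condition on `dr` along the down-left
#' diagonal.
#'
#' @inheritParams find_vertical_seeds
#' @return A list with logical matrices `L` and `R`.
#' @export
find_diagonal_sets <- function(diff, thv) {
  stopifnot(inherits(diff, "oct_diff_maps"))
  if (!is.numeric(thv) || thv <= 0) stop("`thv` must be > 0", call. = FALSE)
  mk <- function(map, direction) {
    mask <- local_max_mask(map, direction)
    ok <- !is.na(map) & map > 0 & map > thv
    ok[is.na(ok)] <- FALSE
    mask & ok
  }
  list(L = mk(diff$dl, "diag-down-right"),
       R = mk(diff$dr, "diag-down-left"))
}

# Patch row/column ranges for a seed at (i, j), clipped to the image.
patch_rows <- function(i, s, m) {
  max(1L, i - floor(s / 2)):min(m, i + ceiling(s / 2) - 1L)
}
patch_cols <- function(j, t, n, side) {
  cc <- if (side == "left") (j - t):(j - 1L) else (j + 1L):(j + t)
  cc[cc >= 1L & cc <= n]
}

#' Detect cyst-boundary candidates by patch voting
#'
#' Runs the full boundary pixel determination phase on an image (already
#' denoised; see [classify_scan()] for the full pipeline). For every seed in
#' `V` two rectangular patches of `s` rows and `t` columns are formed: the
#' left patch spans the `t` columns immediately left of the seed column and
#' the right patch the `t` columns immediately right, both vertically
#' centred on the seed row (for even `s` the extra row falls below).
#' The members of `L` inside the left patch form `Lp`, the members of `R`
#' inside the right patch form `Rp`; each patch whose member count strictly
#' exceeds `num` emits one candidate. A seed passing on both sides emits two
#' candidates. Patches are clipped at the image border and the count is
#' compared against the unchanged `num`.
#'
#' @param img an [oct_image()] (typically the denoised scan).
#' @param params a [detection_params()] object.
#' @return An object of class `cyst_candidates`: a data frame with one row
#'   per accepted patch and columns `seed_row`, `seed_col`, `side`
#'   (`"left"`/`"right"`), `row_min`, `row_max`, `col_min`, `col_max`,
#'   `member_count`. The member pixel coordinates (sets `Lp`/`Rp`) are kept
#'   in the attribute `"members"`, a list of two-column matrices parallel to
#'   the rows; the resolved absolute threshold is attribute `"thv"`.
#' @examples
#' scan <- generate_phantom(dme_phantom_spec(seed = 7))
#' cands <- detect_candidates(denoise_median(scan$image), detection_params())
#' nrow(cands)
#' @export
detect_candidates <- function(img, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  x <- unclass(img)
  m <- nrow(x)
  n <- ncol(x)
  thv <- resolve_thv(params, x)
  dm <- diff_maps(x, params$a, params$b)
  seeds <- find_vertical_seeds(dm, thv)
  sets <- find_diagonal_sets(dm, thv)

  rows <- list()
  members <- list()
  k <- 0L
  for (idx in seq_len(nrow(seeds))) {
    i <- seeds[idx, 1L]
    j <- seeds[idx, 2L]
    rr <- patch_rows(i, params$s, m)
    for (side in c("left", "right")) {
      cc <- patch_cols(j, params$t, n, side)
      if (length(cc) == 0L) next
      mask <- if (side == "left") sets$L else sets$R
      sub <- mask[rr, cc, drop = FALSE]
      cnt <- sum(sub)
      if (cnt > params$num) {
        mem <- which(sub, arr.ind = TRUE)
        mem <- cbind(row = rr[mem[, 1L]], col = cc[mem[, 2L]])
        k <- k + 1L
        rows[[k]] <- data.frame(
          seed_row = i, seed_col = j, side = side,
          row_min = min(rr), row_max = max(rr),
          col_min = min(cc), col_max = max(cc),
          member_count = cnt,
          stringsAsFactors = FALSE
        )
        members[[k]] <- mem
      }
    }
  }
  out <- if (k > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(seed_row = integer(), seed_col = integer(),
               side = character(), row_min = integer(), row_max = integer(),
               col_min = integer(), col_max = integer(),
               member_count = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out,
            members = members,
            thv = thv,
            params = params,
            class = c("cyst_candidates", "data.frame"))
}

#' @export
print.cyst_candidates <- function(x, ...) {
  cat(sprintf("<cyst_candidates> %d accepted patch(es), thv = %.2f\n",
              nrow(x), attr(x, "thv")))
  if (nrow(x) > 0L) print.data.frame(x, ...)
  invisible(x)
}

# Subset candidates by row index, keeping the members attribute in step.
subset_candidates <- function(cands, keep) {
  out <- as.data.frame(cands)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            members = attr(cands, "members")[keep],
            thv = attr(cands, "thv"),
            params = attr(cands, "params"),
            class = c("cyst_candidates", "data.frame"))
}
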