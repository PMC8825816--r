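# Sensitivity/specificity evaluation and parameter sweeps.

#' Confusion counts for binary cystic/non-cystic labels
#'
#' `"cystic"` is the positive class.
#'
#' @param pred,truth character vectors of equal length with values
#'   `"cystic"` or `"non-cystic"`.
#' @return A `confusion_counts` object: list with integer `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  }
  lv <- c("cystic", "non-cystic")
  pred <- as.character(pred); truth <- as.character(truth)
  if (!all(pred %in% lv) || !all(truth %in% lv)) {
    stop("labels must be 'cystic' or 'non-cystic'", call. = FALSE)
  }
  structure(list(
    TP = sum(pred == "cystic" & truth == "cystic"),
    FP = sum(pred == "cystic" & truth == "non-cystic"),
    TN = sum(pred == "non-cystic" & truth == "non-cystic"),
    FN = sum(pred == "non-cystic" & truth == "cystic")
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP = %d, FP = %d, TN = %d, FN = %d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Sensitivity and specificity
#'
#' `SE = TP / (TP + FN)` and `SP = TN / (TN + FP)`. A ratio with zero
#' denominator is undefined and reported as `NA` with a warning — never
#' silently imputed as 0 or 1, which would corrupt parameter sweeps on
#' degenerate batches.
#'
#' @param counts a [confusion()] result.
#' @return A named list with numeric `SE` and `SP` (possibly `NA`).
#' @export
se_sp <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  se <- if (counts$TP + counts$FN == 0L) {
    warning("SE undefined: no positive cases (TP + FN = 0)")
    NA_real_
  } else {
    counts$TP / (counts$TP + counts$FN)
  }
  sp <- if (counts$TN + counts$FP == 0L) {
    warning("SP undefined: no negative cases (TN + FP = 0)")
    NA_real_
  } else {
    counts$TN / (counts$TN + counts$FP)
  }
  list(SE = se, SP = sp)
}

# extract images and truth labels from a list of phantom_scan or from
# a list of oct_image plus an explicit truth vector
batch_inputs <- function(scans, truth = NULL) {
  if (length(scans) > 0L && inherits(scans[[1]], "phantom_scan")) {
    list(images = lapply(scans, `[[`, "image"),
         truth = vapply(scans, `[[`, character(1), "truth_label"))
  } else {
    if (is.null(truth)) {
      stop("`truth` labels required when `scans` are plain images",
           call. = FALSE)
    }
    list(images = scans, truth = truth)
  }
}

#' Evaluate the pipeline on a labelled batch
#'
#' Classifies every scan with [classify_scan()] and compares against ground
#' truth.
#'
#' @param scans list of `phantom_scan` objects, or list of [oct_image()]s
#'   (then `truth` is required).
#' @param params a [pipeline_params()] object.
#' @param truth optional character vector of true labels.
#' @return A list with `pred` (character vector), `counts`
#'   (`confusion_counts`), `SE` and `SP`.
#' @export
evaluate_batch <- function(scans, params = pipeline_params(), truth = NULL) {
  inp <- batch_inputs(scans, truth)
  pred <- vapply(inp$images,
                 function(im) classify_scan(im, params)$label,
                 character(1))
  counts <- confusion(pred, inp$truth)
  rates <- se_sp(counts)
  list(pred = pred, counts = counts, SE = rates$SE, SP = rates$SP)
}

# build a pipeline_params from a base and one grid row of overrides
apply_overrides <- function(base, row) {
  det <- unclass(base$detection)
  sha <- unclass(base$shadow)
  pip <- list(median_kernel = base$median_kernel,
              shadow_margin = base$shadow_margin,
              min_candidates = base$min_candidates,
              remove_shadows = base$remove_shadows)
  for (nm in names(row)) {
    val <- row[[nm]]
    if (is.na(val)) next
    if (nm %in% c("thv", "thv_rel", "s", "t", "num")) {
      det[[nm]] <- val
      if (nm == "thv") det$thv_rel <- 0.25  # absolute wins; keep valid rel
    } else if (nm %in% c("alpha", "jump_thr")) {
      sha[[nm]] <- val
    } else if (nm %in% names(pip)) {
      pip[[nm]] <- val
    } else if (nm %in% c("a", "b")) {
      det[[nm]] <- val
      sha[[nm]] <- val
    } else {
      stop("unknown sweep parameter: ", nm, call. = FALSE)
    }
  }
  pipeline_params(
    detection = do.call(detection_params, det),
    shadow = do.call(shadow_params, sha),
    median_kernel = pip$median_kernel,
    shadow_margin = pip$shadow_margin,
    min_candidates = pip$min_candidates,
    remove_shadows = pip$remove_shadows
  )
}

#' Parameter sweep over a labelled batch
#'
#' Evaluates the full pipeline once per grid row and tabulates SE and SP,
#' in the style of an operating-characteristics table. Grid columns may be
#' any of `thv`, `thv_rel`, `s`, `t`, `num`, `alpha`, `jump_thr`, `a`, `b`,
#' `median_kernel`, `shadow_margin`, `min_candidates`, `remove_shadows`;
#' `NA` entries fall back to the base parameter value. Deterministic given
#' its inputs.
#'
#' @param scans list of `phantom_scan` objects or images (see
#'   [evaluate_batch()]).
#' @param grid data frame, one row per parameter combination.
#' @param base a [pipeline_params()] giving values not in the grid.
#' @param truth optional truth labels for plain-image batches.
#' @return A data frame: the grid columns plus `TP`, `FP`, `TN`, `FN`,
#'   `SE`, `SP`.
#' @export
sweep_params <- function(scans, grid, base = pipeline_params(), truth = NULL) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop("`grid` must be a non-empty data frame", call. = FALSE)
  }
  if (length(scans) == 0L) stop("`scans` must be non-empty", call. = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    p <- apply_overrides(base, as.list(grid[r, , drop = FALSE]))
    ev <- suppressWarnings(evaluate_batch(scans, p, truth))
    data.frame(TP = ev$counts$TP, FP = ev$counts$FP,
               TN = ev$counts$TN, FN = ev$counts$FN,
               SE = ev$SE, SP = ev$SP)
  })
  cbind(grid, do.call(rbind, res))
}

#' Read truth labels from a CSV manifest
#'
#' @param path CSV with columns `path` and `label` (values `"cystic"` /
#'   `"non-cystic"`).
#' @return A data frame with columns `path` and `label`.
#' @export
read_truth_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df))) {
    stop("truth CSV must have columns 'path' and 'label'", call. = FALSE)
  }
  df
}
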