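#' Two-channel reporter image pair
#'
#' Container for one worm's aligned GFP and mCherry intensity rasters plus
#' the intestine mask. All three must share dimensions; intensities must be
#' non-negative and the mask non-empty.
#'
#' @param gfp_channel,mcherry_channel numeric matrices (AU).
#' @param intestine_mask logical matrix.
#' @param worm_id identifier.
#' @return an object of class `reporter_image_pair`.
#' @export
reporter_image_pair <- function(gfp_channel, mcherry_channel, intestine_mask,
                                worm_id = "worm") {
  stopifnot(
    is.matrix(gfp_channel), is.matrix(mcherry_channel),
    is.matrix(intestine_mask), is.logical(intestine_mask),
    identical(dim(gfp_channel), dim(mcherry_channel)),
    identical(dim(gfp_channel), dim(intestine_mask))
  )
  if (!any(intestine_mask)) abort_ss("intestine mask is empty", "empty_mask")
  if (any(gfp_channel < 0) || any(mcherry_channel < 0))
    abort_ss("intensities must be non-negative", "bad_intensity")
  structure(list(
    gfp_channel = gfp_channel, mcherry_channel = mcherry_channel,
    intestine_mask = intestine_mask, worm_id = as.character(worm_id)
  ), class = "reporter_image_pair")
}

# summed-area table padded with a zero row/column, so the pixel count of the
# box with top-left origin (r, c) and side b is
#   S[r+b, c+b] - S[r, c+b] - S[r+b, c] + S[r, c]
integral_image <- function(mask) {
  S <- matrix(0, nrow(mask) + 1L, ncol(mask) + 1L)
  S[-1L, -1L] <- apply(apply(mask, 2L, cumsum), 1L, cumsum) |> t()
  S
}

#' Sample square ROI boxes inside or outside a mask
#'
#' Draws axis-aligned `box_size` x `box_size` boxes uniformly over all valid
#' placements. A placement is valid `inside_mask` when at least
#' `min_inside_fraction` of its pixels fall in the mask, and `outside_mask`
#' when no pixel does. Boxes may overlap; when there are at least `n_rois`
#' valid placements they are drawn without replacement.
#'
#' @param mask logical matrix.
#' @param n_rois number of boxes to return.
#' @param box_size box side in pixels (default 60, the screen's ROI size).
#' @param region `"inside_mask"` (intestine ROIs) or `"outside_mask"`
#'   (background ROIs).
#' @param seed integer seed, or `NULL` to use the ambient RNG.
#' @param min_inside_fraction in-mask pixel fraction required of an
#'   `inside_mask` placement.
#' @return data frame with columns `row`, `col` (1-based top-left origin),
#'   `height`, `width`.
#' @export
sample_rois <- function(mask, n_rois, box_size = 60L,
                        region = c("inside_mask", "outside_mask"),
                        seed = NULL, min_inside_fraction = 0.9) {
  region <- match.arg(region)
  stopifnot(is.matrix(mask), is.logical(mask), is_count(n_rois),
            is_count(box_size))
  if (region == "inside_mask" && !any(mask))
    abort_ss("no valid ROI placement: mask is empty", "roi_placement_failure")
  nr <- nrow(mask); nc <- ncol(mask)
  if (box_size > nr || box_size > nc)
    abort_ss("no valid ROI placement: box larger than frame", "roi_placement_failure")
  S <- integral_image(mask)
  orr <- seq_len(nr - box_size + 1L); occ <- seq_len(nc - box_size + 1L)
  cnt <- S[orr + box_size, occ + box_size, drop = FALSE] -
    S[orr, occ + box_size, drop = FALSE] -
    S[orr + box_size, occ, drop = FALSE] +
    S[orr, occ, drop = FALSE]
  valid <- if (region == "inside_mask") {
    cnt >= min_inside_fraction * box_size^2
  } else {
    cnt == 0
  }
  idx <- which(valid)
  if (length(idx) == 0L)
    abort_ss(sprintf("no valid ROI placement for region '%s'", region),
             "roi_placement_failure")
  pick <- with_seed(seed, sample(idx, n_rois, replace = length(idx) < n_rois))
  data.frame(
    row = orr[(pick - 1L) %% length(orr) + 1L],
    col = occ[(pick - 1L) %/% length(orr) + 1L],
    height = box_size, width = box_size
  )
}

# logical mask covering the union of boxes (pixels in several boxes count once)
boxes_union_mask <- function(boxes, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(boxes))) {
    m[boxes$row[i]:(boxes$row[i] + boxes$height[i] - 1L),
      boxes$col[i]:(boxes$col[i] + boxes$width[i] - 1L)] <- TRUE
  }
  m
}

#' Quantify one worm's GFP/mCherry ratio by ROI sampling
#'
#' Samples `n_rois` intestinal boxes (>= 90 percent in-mask) and
#' `n_background` background boxes (fully off-mask), averages pixel
#' intensity over the union of each box set per channel, subtracts the
#' background mean from the intestinal mean per channel, and reports
#' `ratio = corrected_gfp / corrected_mcherry`.
#'
#' A worm whose corrected mCherry is not positive has no defined ratio: the
#' quant is returned with `ratio = NA` and an `exclusion_reason`, and a
#' warning is raised, so group statistics can exclude and count it.
#'
#' @param pair a [reporter_image_pair()].
#' @param n_rois intestinal ROI count (default 8).
#' @param n_background background ROI count (default 3).
#' @param box_size ROI side in pixels (default 60).
#' @param seed integer seed controlling ROI placement.
#' @param min_inside_fraction in-mask pixel fraction required of an
#'   intestinal ROI placement (1 forces fully in-mask boxes).
#' @return an object of class `worm_quant`.
#' @export
quantify_worm <- function(pair, n_rois = 8L, n_background = 3L,
                          box_size = 60L, seed = 1L,
                          min_inside_fraction = 0.9) {
  stopifnot(inherits(pair, "reporter_image_pair"))
  shape <- dim(pair$gfp_channel)
  res <- with_seed(seed, {
    roi <- sample_rois(pair$intestine_mask, n_rois, box_size, "inside_mask",
                       min_inside_fraction = min_inside_fraction)
    bg <- sample_rois(pair$intestine_mask, n_background, box_size, "outside_mask")
    list(roi = roi, bg = bg)
  })
  roi_mask <- boxes_union_mask(res$roi, shape)
  bg_mask <- boxes_union_mask(res$bg, shape)
  mean_in_g <- mean(pair$gfp_channel[roi_mask])
  mean_in_m <- mean(pair$mcherry_channel[roi_mask])
  mean_bg_g <- mean(pair$gfp_channel[bg_mask])
  mean_bg_m <- mean(pair$mcherry_channel[bg_mask])
  corr_g <- mean_in_g - mean_bg_g
  corr_m <- mean_in_m - mean_bg_m
  excl <- NA_character_
  ratio <- NA_real_
  if (corr_m <= 0) {
    excl <- "corrected mCherry not positive; ratio undefined"
    warning(sprintf("worm '%s' excluded: %s", pair$worm_id, excl))
  } else {
    ratio <- corr_g / corr_m
  }
  structure(list(
    worm_id = pair$worm_id,
    mean_intestine_gfp = mean_in_g, mean_intestine_mcherry = mean_in_m,
    mean_background_gfp = mean_bg_g, mean_background_mcherry = mean_bg_m,
    corrected_gfp = corr_g, corrected_mcherry = corr_m,
    ratio = ratio, exclusion_reason = excl,
    roi_boxes = res$roi, background_boxes = res$bg
  ), class = "worm_quant")
}

#' Per-group summary of worm ratios
#'
#' @param quants list of [quantify_worm()] results.
#' @param group_label condition label.
#' @return an object of class `group_ratio_stats` with the per-worm ratios,
#'   their mean and SEM, `n_worms`, and the count of excluded
#'   (undefined-ratio) worms.
#' @export
group_ratio_stats <- function(quants, group_label = "group") {
  if (length(quants) == 0L) abort_ss("empty group", "empty_group")
  stopifnot(all(vapply(quants, inherits, logical(1), "worm_quant")))
  ratios <- vapply(quants, function(q) q$ratio, numeric(1))
  excluded <- sum(is.na(ratios))
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0L)
    abort_ss("no worm in the group has a defined ratio", "empty_group")
  structure(list(
    group_label = as.character(group_label),
    per_worm_ratios = ratios,
    mean_ratio = mean(ratios),
    sem = sem(ratios),
    n_worms = length(ratios),
    n_excluded = excluded
  ), class = "group_ratio_stats")
}

#' @rdname group_ratio_stats
#' @param ratios numeric vector of per-worm ratios (already quantified, e.g.
#'   read from a per-worm table).
#' @export
group_from_ratios <- function(ratios, group_label = "group") {
  stopifnot(is.numeric(ratios), length(ratios) >= 1L, all(is.finite(ratios)))
  structure(list(
    group_label = as.character(group_label),
    per_worm_ratios = as.numeric(ratios),
    mean_ratio = mean(ratios),
    sem = sem(ratios),
    n_worms = length(ratios),
    n_excluded = 0L
  ), class = "group_ratio_stats")
}

#' Relative change in group mean ratio, with a t-test
#'
#' `relative_change = 100 * (mean_treated - mean_control) / mean_control`;
#' the p-value is a two-sided unpaired Student's t-test (equal variances) on
#' the per-worm ratios.
#'
#' @param treated,control [group_ratio_stats()] objects.
#' @return list with `relative_change` (percent), `p_value`, and the group
#'   means.
#' @export
relative_ratio_change <- function(treated, control) {
  stopifnot(inherits(treated, "group_ratio_stats"),
            inherits(control, "group_ratio_stats"))
  if (control$mean_ratio <= 0)
    abort_ss("control mean ratio must be positive", "bad_control_mean")
  rel <- 100 * (treated$mean_ratio - control$mean_ratio) / control$mean_ratio
  p <- if (stats::sd(c(treated$per_worm_ratios, control$per_worm_ratios)) == 0) {
    1
  } else {
    stats::t.test(treated$per_worm_ratios, control$per_worm_ratios,
                  var.equal = TRUE)$p.value
  }
  list(relative_change = rel, p_value = p,
       mean_treated = treated$mean_ratio, mean_control = control$mean_ratio)
}

#' Call screen hits across validation rounds
#'
#' A compound is a hit only when its treated group shows a positive relative
#' GFP/mCherry change with `p < alpha` in every scored round (primary screen
#' plus validation rounds).
#'
#' @param per_round_stats named list: compound id -> list of rounds, each a
#'   list with elements `treated` and `control` ([group_ratio_stats()]).
#' @param alpha per-round significance level.
#' @param min_rounds minimum number of scored rounds required per compound.
#' @return data frame with one row per compound (`compound_id`, `n_rounds`,
#'   `is_hit`) and the per-round evidence as attribute `"rounds"` (a data
#'   frame with `compound_id`, `round`, `relative_change`, `p_value`).
#' @export
call_screen_hits <- function(per_round_stats, alpha = 0.05, min_rounds = 3L) {
  stopifnot(is.list(per_round_stats), length(per_round_stats) >= 1L,
            is_number(alpha), alpha > 0, alpha < 1, is_count(min_rounds))
  rounds_tab <- list()
  decisions <- lapply(names(per_round_stats), function(cmpd) {
    rounds <- per_round_stats[[cmpd]]
    if (length(rounds) < min_rounds)
      abort_ss(sprintf("compound '%s' has fewer than %d scored rounds",
                       cmpd, min_rounds), "too_few_rounds")
    ev <- lapply(seq_along(rounds), function(r) {
      rd <- rounds[[r]]
      if (is.null(rd$control) || is.null(rd$treated))
        abort_ss(sprintf("compound '%s' round %d is missing a group", cmpd, r),
                 "missing_group")
      ch <- relative_ratio_change(rd$treated, rd$control)
      data.frame(compound_id = cmpd, round = r,
                 relative_change = ch$relative_change,
                 p_value = ch$p_value, stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, ev)
    rounds_tab[[cmpd]] <<- ev
    data.frame(
      compound_id = cmpd, n_rounds = nrow(ev),
      is_hit = all(ev$relative_change > 0 & ev$p_value < alpha),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, decisions)
  rownames(out) <- NULL
  attr(out, "rounds") <- do.call(rbind, rounds_tab)
  out
}
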