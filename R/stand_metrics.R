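#' Round heights to whole meters
#'
#' Inventory stand heights are recorded in whole meters, so LiDAR heights
#' are brought to the same scale before any comparison. The default mode is
#' round-half-up (18.5 -> 19), matching the convention of field height
#' records; a ceiling mode is available for strict "rounded up" readings,
#' but it would bias LiDAR-minus-inventory differences by about +0.5 m.
#'
#' @param x numeric heights (m).
#' @param mode `"half_up"` (default) or `"ceiling"`.
#' @return integer meters.
#' @export
round_height <- function(x, mode = c("half_up", "ceiling")) {
  mode <- match.arg(mode)
  switch(mode,
         half_up = floor(x + 0.5),
         ceiling = ceiling(x))
}

#' Occurrence-weighted stand height of one forest unit
#'
#' Emulates a surveyor's representative-tree average: individual detected
#' top heights are first rounded to whole meters, occurrences of each
#' rounded height are counted, and the stand height is the weighted mean
#' `sum(w_i * h_i) / sum(w_i)` over the distinct rounded heights `h_i` with
#' occurrence counts `w_i`. Algebraically this equals the plain arithmetic
#' mean of the rounded heights; the histogram form is kept because it is
#' what gets reported and audited per unit. The reported stand height is the
#' weighted mean rounded again to whole meters.
#'
#' @param heights numeric vector of top heights in one unit (>= 1 value).
#' @param rounding rounding mode, see [round_height()].
#' @return list with `n_tops`, `histogram` (named integer vector,
#'   rounded height -> count), `mean_height` (unrounded weighted mean) and
#'   `height` (whole-meter stand height).
#' @export
stand_height <- function(heights, rounding = "half_up") {
  heights <- heights[!is.na(heights)]
  if (!length(heights)) stop("stand_height needs at least one top")
  hr <- round_height(heights, rounding)
  tab <- table(hr)
  h_i <- as.numeric(names(tab))
  w_i <- as.numeric(tab)
  hbar <- sum(w_i * h_i) / sum(w_i)
  list(n_tops = length(heights),
       histogram = setNames(as.integer(w_i), names(tab)),
       mean_height = hbar,
       height = as.integer(round_height(hbar, rounding)))
}

#' Stand heights for all units from filtered tree tops
#'
#' @param tops output of [filter_treetops()] (tops with `forest_address`).
#' @param rounding rounding mode, see [round_height()].
#' @return data.table with one row per unit: `forest_address`, `n_tops`,
#'   `mean_height`, `height`.
#' @export
stand_heights <- function(tops, rounding = "half_up") {
  tp <- as.data.table(tops)
  tp[, {
    s <- stand_height(height, rounding)
    list(n_tops = s$n_tops, mean_height = s$mean_height, height = s$height)
  }, by = forest_address]
}

#' Height difference and its class
#'
#' Difference is LiDAR stand height minus inventory height (whole meters).
#' Differences from -8 to -6 m fall in one pooled class (labelled
#' `"[-8,-6]"`); -5 to 6 m map to their own integer class. Differences
#' outside \[-8, 6\] do not belong to any analysis class (class `NA`); on
#' the positive side those are the gross-error candidates handled by
#' [flag_gross_errors()].
#'
#' @param lidar_h,inventory_h whole-meter stand heights (vectorized).
#' @return data.table with columns `difference` and `diff_class`
#'   (character; `NA` when either height is missing or out of class range).
#' @export
height_difference <- function(lidar_h, inventory_h) {
  d <- lidar_h - inventory_h
  cls <- rep(NA_character_, length(d))
  pooled <- !is.na(d) & d >= -8 & d <= -6
  single <- !is.na(d) & d >= -5 & d <= 6
  cls[pooled] <- "[-8,-6]"
  cls[single] <- as.character(d[single])
  data.table(difference = d, diff_class = cls)
}

#' Class labels of the height-difference partition
#'
#' @return character vector: `"[-8,-6]"`, `"-5"` ... `"6"`.
#' @export
diff_class_levels <- function() c("[-8,-6]", as.character(-5:6))

#' Flag gross errors in a unit's height comparison
#'
#' Positive differences of 8 m and above are physically implausible for a
#' stand-level comparison and are flagged `gross_positive` (incorrectly
#' placed NEAs, wrong unit contours, residual trees or multi-tier stands are
#' the usual causes); flagged units are excluded from agreement statistics.
#' A stand whose documented age is at or below `age_threshold` years cannot
#' have canopy at or above the 7 m detection floor, so detected tops there
#' are flagged `young_stand_conflict`. Large negative differences are *not*
#' exclusions: they stay in their (pooled) class.
#'
#' @param difference whole-meter height difference (LiDAR - inventory).
#' @param age stand age in years (optional, `NA` to skip the age rule).
#' @param error_min smallest difference treated as a gross error (default
#'   8 m).
#' @param age_threshold young-stand age limit in years (default 15).
#' @return character vector of flags: `"ok"`, `"gross_positive"` or
#'   `"young_stand_conflict"`.
#' @export
flag_gross_errors <- function(difference, age = NA_real_,
                              error_min = 8, age_threshold = 15) {
  n <- length(difference)
  age <- rep_len(age, n)
  flag <- rep("ok", n)
  flag[!is.na(difference) & difference >= error_min] <- "gross_positive"
  young <- flag == "ok" & !is.na(age) & age <= age_threshold &
    !is.na(difference)
  flag[young] <- "young_stand_conflict"
  flag
}

#' Per-unit increment pairs from two-epoch stand heights
#'
#' Joins whole-meter LiDAR and inventory stand heights of matched units
#' across the two epochs and computes the height increments
#' `lidar_increment = h_new - h_old` (LiDAR) and `inventory_increment`
#' (inventory). Units flagged as gross errors in either epoch are excluded
#' (reason kept in `attr(out, "excluded")`), as are units missing a height
#' in either epoch or source.
#'
#' @param matches filtered output of [match_units()] /[filter_matched()].
#' @param lidar_old,lidar_new outputs of [stand_heights()] for the two
#'   epochs (addresses of the respective epoch's layer).
#' @return data.table with one row per analysed unit: addresses, per-epoch
#'   LiDAR and inventory heights, per-epoch differences and classes,
#'   increments and error flags.
#' @export
increment_pairs <- function(matches, lidar_old, lidar_new) {
  m <- as.data.table(matches)
  lo <- as.data.table(lidar_old)[, .(address_old = forest_address,
                                     lidar_old = height,
                                     n_tops_old = n_tops)]
  ln <- as.data.table(lidar_new)[, .(address_new = forest_address,
                                     lidar_new = height,
                                     n_tops_new = n_tops)]
  out <- merge(m, lo, by = "address_old", all.x = TRUE)
  out <- merge(out, ln, by = "address_new", all.x = TRUE)
  d_old <- height_difference(out$lidar_old, out$height_old)
  d_new <- height_difference(out$lidar_new, out$height_new)
  out[, `:=`(diff_old = d_old$difference, class_old = d_old$diff_class,
             diff_new = d_new$difference, class_new = d_new$diff_class)]
  out[, flag_old := flag_gross_errors(diff_old, age_old)]
  out[, flag_new := flag_gross_errors(diff_new, age_new)]
  excl_reason <- rep(NA_character_, nrow(out))
  excl_reason[is.na(out$lidar_old) | is.na(out$lidar_new)] <- "missing_lidar"
  miss_inv <- is.na(excl_reason) &
    (is.na(out$height_old) | is.na(out$height_new))
  excl_reason[miss_inv] <- "missing_inventory"
  flagged <- is.na(excl_reason) &
    (out$flag_old != "ok" | out$flag_new != "ok")
  excl_reason[flagged] <- "gross_error_flag"
  keep <- is.na(excl_reason)
  excluded <- data.table(address_new = out$address_new[!keep],
                         reason = excl_reason[!keep])
  out <- out[keep]
  out[, lidar_increment := lidar_new - lidar_old]
  out[, inventory_increment := height_new - height_old]
  if ("overlap" %in% names(out)) out[, overlap := NULL]
  setattr(out, "excluded", excluded)
  out[]
}
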