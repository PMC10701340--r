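#' Ground sampling distance of a nadir UAS image
#'
#' Converts flight metadata to the size of one image pixel at the subject,
#' the standard photogrammetric scale factor: altitude above the subject
#' times the ratio of sensor width to focal length, divided by the image
#' width in pixels.
#'
#' @param altitude Altitude above the subject, metres. Vectorised.
#' @param focal_length Lens focal length, millimetres.
#' @param sensor_width Camera sensor width, millimetres.
#' @param image_width Image width, pixels.
#'
#' @return Metres per pixel (numeric, same length as the inputs after
#'   recycling).
#' @examples
#' ground_sampling_distance(100, 10, 10, 1000) # 0.1 m/px
#' @export
ground_sampling_distance <- function(altitude, focal_length, sensor_width,
                                     image_width) {
  if (any(!is.finite(altitude)) || any(altitude <= 0)) {
    stop("invalid flight metadata: altitude must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(focal_length)) || any(focal_length <= 0)) {
    stop("invalid flight metadata: focal_length must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(sensor_width)) || any(sensor_width <= 0)) {
    stop("invalid flight metadata: sensor_width must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(image_width)) || any(image_width < 1)) {
    stop("invalid flight metadata: image_width must be >= 1 pixel",
         call. = FALSE)
  }
  altitude * (sensor_width / focal_length) / image_width
}

#' Convert a pixel length to metres
#'
#' @param length_px Length in pixels (>= 0). Vectorised.
#' @inheritParams ground_sampling_distance
#' @return Length in metres.
#' @export
pixels_to_meters <- function(length_px, altitude, focal_length, sensor_width,
                             image_width) {
  if (any(length_px < 0, na.rm = TRUE)) {
    stop("pixel lengths must be non-negative", call. = FALSE)
  }
  length_px * ground_sampling_distance(altitude, focal_length, sensor_width,
                                       image_width)
}

# Width stations along the body axis: 5%, 10%, ..., 95% of TL from the
# rostrum (rostrum = 0 convention).
#' Body-axis width stations
#'
#' The 19 canonical perpendicular-width stations, as fractions of total
#' length measured from the rostrum.
#' @return Numeric vector `c(0.05, 0.10, ..., 0.95)`, named `w05` ... `w95`.
#' @export
width_stations <- function() {
  s <- seq(0.05, 0.95, by = 0.05)
  names(s) <- sprintf("w%02d", round(100 * s))
  s
}

#' Body area index (BAI)
#'
#' A scale-invariant, unitless body-condition metric: the dorsal surface
#' area over a head-tail range of the body (trapezoidal integration of the
#' perpendicular widths along the body axis), standardized by total length.
#' With surface area \eqn{SA} integrated from fraction \eqn{l} to \eqn{u}
#' of TL, \eqn{BAI = 100 \, SA / ((u - l) \, TL)^2}.
#'
#' @param TL Total length, metres (> 0).
#' @param widths Perpendicular widths in metres at the 19 stations
#'   5\%,...,95\% of TL (see [width_stations()]). Either a full length-19
#'   vector (optionally named `w05`...`w95`) or a named vector covering at
#'   least every station inside `head_tail_range`. `NA` at stations outside
#'   the range is tolerated.
#' @param head_tail_range Fraction pair delimiting the integrated body
#'   segment; endpoints must be multiples of 0.05. Default `c(0.20, 0.90)`.
#'
#' @return Unitless BAI (scalar).
#' @examples
#' compute_bai(20, rep(2, 19)) # rectangle body: 100*28/14^2 = 14.2857...
#' @export
compute_bai <- function(TL, widths, head_tail_range = c(0.20, 0.90)) {
  if (!is.finite(TL) || TL <= 0) stop("TL must be > 0", call. = FALSE)
  stations <- width_stations()
  lo <- head_tail_range[1]
  hi <- head_tail_range[2]
  if (lo >= hi || lo < 0.05 || hi > 0.95 ||
      abs(lo / 0.05 - round(lo / 0.05)) > 1e-9 ||
      abs(hi / 0.05 - round(hi / 0.05)) > 1e-9) {
    stop("head_tail_range endpoints must be multiples of 0.05 within [0.05, 0.95]",
         call. = FALSE)
  }
  if (is.null(names(widths))) {
    if (length(widths) != length(stations)) {
      stop("unnamed widths must have exactly ", length(stations), " entries",
           call. = FALSE)
    }
    names(widths) <- names(stations)
  }
  keep <- stations >= lo - 1e-9 & stations <= hi + 1e-9
  need <- names(stations)[keep]
  if (!all(need %in% names(widths)) || anyNA(widths[need])) {
    stop("incomplete record: missing width station(s) inside the BAI range: ",
         paste(setdiff(need, names(widths)[!is.na(widths)]), collapse = ", "),
         call. = FALSE)
  }
  w <- as.numeric(widths[need])
  x <- stations[keep] * TL
  sa <- sum(diff(x) * (utils::head(w, -1) + utils::tail(w, -1)) / 2)
  100 * sa / ((hi - lo) * TL)^2
}

#' Standardize morphological measurements by total length
#'
#' Divides each measurement by TL, yielding unitless fractions of body
#' length (the scale on which populations are compared).
#'
#' @param measurements Named numeric vector of metric measurements
#'   (e.g. RB, JL, EE, Tail, Fs), metres.
#' @param TL Total length, metres (> 0).
#' @return Named numeric vector of `measurement / TL`.
#' @export
standardize_by_tl <- function(measurements, TL) {
  if (!is.finite(TL) || TL <= 0) stop("TL must be > 0", call. = FALSE)
  measurements / TL
}

#' Quality-filter digitized whale records
#'
#' Applies the standard exclusions before analysis: per-measurement values
#' with quality score 3 (poor) are dropped; known calves are removed
#' entirely; and the number of images per whale is capped (best mean
#' quality first, ties broken by input order).
#'
#' @param records Tibble of long-format digitized measurements with at
#'   least columns `whale_id`, `image_id`, `measurement`, `quality`
#'   (integer 1, 2 or 3) and `is_calf` (logical). Extra columns pass
#'   through.
#' @param max_images_per_whale Cap on retained images per whale
#'   (default 5).
#'
#' @return A list with `records` (the retained rows) and `audit`
#'   (a tibble of excluded rows with a `reason` column:
#'   `"calf"`, `"quality_3"` or `"image_cap"`).
#' @export
filter_records <- function(records, max_images_per_whale = 5) {
  stopifnot(is.data.frame(records))
  need <- c("whale_id", "image_id", "measurement", "quality", "is_calf")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(records$quality %in% c(1L, 2L, 3L))) {
    stop("quality scores must all be 1, 2 or 3", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  records$.row <- seq_len(nrow(records))

  audit <- list()
  is_calf <- records$is_calf
  audit$calf <- dplyr::mutate(records[is_calf, ], reason = "calf")
  records <- records[!is_calf, ]

  q3 <- records$quality == 3L
  audit$q3 <- dplyr::mutate(records[q3, ], reason = "quality_3")
  records <- records[!q3, ]

  # Image cap: rank each whale's images by mean quality of the surviving
  # measurements, then by first appearance in the input.
  img <- dplyr::summarise(
    dplyr::group_by(records, .data$whale_id, .data$image_id),
    mean_quality = mean(.data$quality),
    first_row = min(.data$.row),
    .groups = "drop"
  )
  img <- dplyr::arrange(img, .data$whale_id, .data$mean_quality,
                        .data$first_row)
  img <- dplyr::mutate(dplyr::group_by(img, .data$whale_id),
                       rank = dplyr::row_number())
  keep_imgs <- dplyr::ungroup(dplyr::filter(img, .data$rank <= max_images_per_whale))
  capped <- !paste(records$whale_id, records$image_id) %in%
    paste(keep_imgs$whale_id, keep_imgs$image_id)
  audit$cap <- dplyr::mutate(records[capped, ], reason = "image_cap")
  records <- records[!capped, ]

  audit <- dplyr::bind_rows(audit)
  audit$.row <- NULL
  records$.row <- NULL
  list(records = records, audit = audit)
}

#' Convert digitized pixel measurements to metric morphology
#'
#' Adds a `value_m` column to a long record table using each image's
#' ground sampling distance. Rows already in metres (`unit == "m"`) pass
#' through unchanged; rows in pixels (`unit == "px"` or no `unit`
#' column) are scaled.
#'
#' @param records Long tibble with columns `value`, `altitude`,
#'   `focal_length`, `sensor_width`, `image_width` and optionally `unit`.
#' @return The input tibble with a `value_m` column.
#' @export
convert_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("value", "altitude", "focal_length", "sensor_width", "image_width")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  unit <- if ("unit" %in% names(records)) records$unit else rep("px", nrow(records))
  gsd <- ground_sampling_distance(records$altitude, records$focal_length,
                                  records$sensor_width, records$image_width)
  records$value_m <- ifelse(unit == "m", records$value, records$value * gsd)
  records
}

#' Per-image metric morphology summaries
#'
#' Pivots a converted long record table to one row per whale image with
#' metric TL, the named morphological measurements, standardized measures
#' and BAI.
#'
#' @param records Long tibble as returned by [convert_records()], with
#'   `measurement` values `TL`, `RB`, `JL`, `EE`, `Tail`, `Fs`, `Fw` and
#'   width stations `w05`...`w95`.
#' @param head_tail_range BAI integration range (see [compute_bai()]).
#' @return Tibble, one row per (whale_id, image_id), with columns
#'   `TL`...`Fw` in metres, `BAI`, and `RB_std`...`Fs_std`.
#' @export
morphology_per_image <- function(records, head_tail_range = c(0.20, 0.90)) {
  stopifnot(is.data.frame(records), "value_m" %in% names(records))
  std_measures <- c("RB", "JL", "EE", "Tail", "Fs")
  wide <- tidyr::pivot_wider(
    dplyr::select(records, dplyr::any_of(c("whale_id", "image_id", "population",
                                           "platform_id")),
                  "measurement", "value_m"),
    names_from = "measurement", values_from = "value_m"
  )
  wnames <- names(width_stations())
  have_w <- intersect(wnames, names(wide))
  wide$BAI <- vapply(seq_len(nrow(wide)), function(i) {
    w <- rep(NA_real_, length(wnames))
    names(w) <- wnames
    w[have_w] <- as.numeric(wide[i, have_w])
    tl <- wide$TL[i]
    if (!is.finite(tl)) return(NA_real_)
    tryCatch(compute_bai(tl, w, head_tail_range), error = function(e) NA_real_)
  }, numeric(1))
  for (m in std_measures) {
    if (m %in% names(wide)) {
      wide[[paste0(m, "_std")]] <- wide[[m]] / wide$TL
    }
  }
  wide
}
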