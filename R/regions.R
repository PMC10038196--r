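#' Cortical region definitions for the 44-channel frontotemporal montage
#'
#' The montage covers bilateral frontal and temporal cortices with 44
#' source-detector channels: left frontal lobe (channels 1-10), left temporal
#' lobe (11-22), right frontal lobe (23-32) and right temporal lobe (33-44).
#' Hemispheres are the unions of their two lobes. Channel numbering is 1-based
#' in all user-facing interfaces.
#'
#' @param name Region name, one of `"whole"`, `"left_hemisphere"`,
#'   `"right_hemisphere"`, `"left_frontal"`, `"left_temporal"`,
#'   `"right_frontal"`, `"right_temporal"`.
#' @return `region_spec()` returns an object of class `"region_spec"`: a list
#'   with elements `name` and `channels` (ordered 1-based channel numbers).
#' @examples
#' region_spec("left_frontal")$channels  # 1:10
#' channel_region(23)                    # right_frontal, right hemisphere
#' @export
region_spec <- function(name = c("whole", "left_hemisphere", "right_hemisphere",
                                 "left_frontal", "left_temporal",
                                 "right_frontal", "right_temporal")) {
  name <- match.arg(name)
  channels <- switch(name,
    whole            = 1:44,
    left_hemisphere  = 1:22,
    right_hemisphere = 23:44,
    left_frontal     = 1:10,
    left_temporal    = 11:22,
    right_frontal    = 23:32,
    right_temporal   = 33:44
  )
  structure(list(name = name, channels = channels), class = "region_spec")
}

#' @rdname region_spec
#' @export
region_names <- function() {
  c("left_hemisphere", "right_hemisphere", "left_frontal", "left_temporal",
    "right_frontal", "right_temporal")
}

#' @rdname region_spec
#' @param channel Integer vector of 1-based channel numbers in 1..44.
#' @return `channel_region()` returns a data frame with columns `channel`,
#'   `region` and `hemisphere`.
#' @export
channel_region <- function(channel) {
  if (!is.numeric(channel) || any(!is.finite(channel)) ||
      any(channel != as.integer(channel))) {
    stopf("`channel` must be whole numbers")
  }
  if (any(channel < 1 | channel > 44)) {
    stopf("channel out of range 1..44: %s",
          paste(channel[channel < 1 | channel > 44], collapse = ", "))
  }
  region <- ifelse(channel <= 10, "left_frontal",
            ifelse(channel <= 22, "left_temporal",
            ifelse(channel <= 32, "right_frontal", "right_temporal")))
  data.frame(channel = as.integer(channel),
             region = region,
             hemisphere = ifelse(channel <= 22, "left", "right"),
             stringsAsFactors = FALSE)
}

#' Select region channels from an attribute matrix
#'
#' Reorders and subsets the columns of an `m x c` single-attribute matrix to a
#' region's channel list.
#'
#' @param x Numeric matrix, samples in rows, channels in columns.
#' @param region A [region_spec()] object, or a region name, or an integer
#'   vector of 1-based channel numbers.
#' @return Matrix with `length(channels)` columns in region order.
#' @export
subset_region <- function(x, region) {
  if (!is.matrix(x)) stopf("`x` must be a matrix")
  if (identical(region, "whole") ||
      (inherits(region, "region_spec") && region$name == "whole")) {
    return(x)  # all channels of the data, whatever the montage size
  }
  channels <- if (inherits(region, "region_spec")) region$channels
              else if (is.character(region)) region_spec(region)$channels
              else as.integer(region)
  if (any(channels < 1) || any(channels > ncol(x))) {
    stopf("region channels out of range for a %d-channel matrix", ncol(x))
  }
  x[, channels, drop = FALSE]
}
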