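# Eight-direction compass used by both the cue display and the numeric keypad.
# Angles are measured in degrees from the top (N = 0), increasing clockwise,
# so that a response to the right of the cue carries a positive error.

.DIRECTIONS <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

.DIR_ANGLE <- c(
  N = 0, NE = 45, E = 90, SE = 135,
  S = 180, SW = 225, W = 270, NW = 315
)

# keypad layout: 8 = top, 6 = right, 2 = bottom, 4 = left, diagonals on 7/9/1/3
.KEY_TO_DIR <- c(
  `8` = "N", `9` = "NE", `6` = "E", `3` = "SE",
  `2` = "S", `1` = "SW", `4` = "W", `7` = "NW"
)

#' Compass directions of the localization task
#'
#' The eight possible cue positions surrounding the central fixation point
#' (or central vibromotor), named as compass directions. Angles run clockwise
#' from the top, so `N` is 0 degrees and `E` is 90 degrees.
#'
#' @return Character vector of the eight direction labels, in clockwise order.
#' @export
#' @examples
#' compass_directions()
compass_directions <- function() .DIRECTIONS

#' @rdname compass_directions
#' @param direction Character vector of direction labels.
#' @return `direction_angle()` returns the angle in degrees, in `[0, 360)`,
#'   clockwise from the top.
#' @export
direction_angle <- function(direction) {
  direction <- as.character(direction)
  bad <- !direction %in% .DIRECTIONS
  if (any(bad)) {
    abort(sprintf(
      "Invalid direction label(s): %s. Valid labels are %s.",
      paste(unique(direction[bad]), collapse = ", "),
      paste(.DIRECTIONS, collapse = ", ")
    ))
  }
  unname(.DIR_ANGLE[direction])
}

#' Numeric-keypad mapping of the eight directions
#'
#' Responses are given on the number pad: 8 is the top direction, 9 top-right,
#' 6 right, 3 bottom-right, 2 bottom, 1 bottom-left, 4 left, 7 top-left.
#' The center key (5) and any non-direction key are invalid responses.
#'
#' @param key Numeric or character vector of keypad keys.
#' @return `key_to_direction()` returns the compass labels.
#' @export
#' @examples
#' key_to_direction(c(8, 6, 4))
#' direction_to_key("NE")
key_to_direction <- function(key) {
  key <- as.character(key)
  bad <- !key %in% names(.KEY_TO_DIR)
  if (any(bad)) {
    abort(sprintf(
      "Invalid direction key(s): %s. Valid keys are %s (5 is not a direction).",
      paste(unique(key[bad]), collapse = ", "),
      paste(names(.KEY_TO_DIR), collapse = ", ")
    ))
  }
  unname(.KEY_TO_DIR[key])
}

#' @rdname key_to_direction
#' @param direction Character vector of direction labels.
#' @return `direction_to_key()` returns the keypad keys as integers.
#' @export
direction_to_key <- function(direction) {
  direction <- as.character(direction)
  dir_to_key <- setNames(as.integer(names(.KEY_TO_DIR)), .KEY_TO_DIR)
  bad <- !direction %in% names(dir_to_key)
  if (any(bad)) {
    abort(sprintf(
      "Invalid direction label(s): %s.",
      paste(unique(direction[bad]), collapse = ", ")
    ))
  }
  unname(dir_to_key[direction])
}

#' Nearest compass direction to a continuous angle
#'
#' Bins a continuous angle (degrees clockwise from the top) to the nearest of
#' the eight compass directions; used to discretize the latent continuous
#' response direction of the synthetic observer onto the keypad.
#'
#' @param angle_deg Numeric vector of angles in degrees (any real value).
#' @return Character vector of direction labels.
#' @export
#' @examples
#' nearest_direction(c(10, 100, -30))
nearest_direction <- function(angle_deg) {
  if (!is.numeric(angle_deg)) abort("`angle_deg` must be numeric.")
  idx <- (round(angle_deg / 45) %% 8) + 1
  .DIRECTIONS[idx]
}

#' Signed angular error between cue and response directions
#'
#' Computes the angular deviation of the chosen direction from the presented
#' direction on the eight-direction compass. Clockwise deviations are
#' positive; the error is wrapped to `(-180, 180]` degrees, so exact
#' opposition returns `+180` by convention. A cue at the top answered with
#' the right key is an error of `+90`; answered with the left key, `-90`.
#'
#' @param true_dir Direction label(s) of the presented cue.
#' @param resp_dir Direction label(s) of the response.
#' @return Numeric vector of errors in degrees, each one of
#'   `0, +-45, +-90, +-135, +180`.
#' @export
#' @examples
#' signed_angular_error("N", "E") #  +90
#' signed_angular_error("N", "W") #  -90
signed_angular_error <- function(true_dir, resp_dir) {
  d <- (direction_angle(resp_dir) - direction_angle(true_dir)) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}
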