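#' Channel geometry
#'
#' Describes the microphone array on the chest surface. Coordinates are in
#' cm: `x` lateral (negative = patient's left), `y` antero-posterior depth
#' (0 = posterior surface, increasing toward the front), `z` cranio-caudal
#' height (0 = lung base). Each channel carries a side label (`left` /
#' `right`) and a chest quadrant (`top-left`, `top-right`, `bottom-left`,
#' `bottom-right`). The ipsilateral set of a channel is every channel with
#' the same side label.
#'
#' @param channels data.frame with columns `channel` (integer id), `x`,
#'   `y`, `z` (cm), `side` and `quadrant`.
#' @param sound_speed propagation speed used for arrival-time modelling,
#'   in cm/ms.
#' @return an object of class `channel_geometry`.
#' @export
channel_geometry <- function(channels, sound_speed = 3) {
  need <- c("channel", "x", "y", "z", "side", "quadrant")
  miss <- setdiff(need, names(channels))
  if (length(miss))
    stop("geometry is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(channels$channel))
    stop("duplicate channel ids in geometry", call. = FALSE)
  if (!all(channels$side %in% c("left", "right")))
    stop("channel side labels must be 'left' or 'right'", call. = FALSE)
  quads <- c("top-left", "top-right", "bottom-left", "bottom-right")
  if (!all(channels$quadrant %in% quads))
    stop("channel quadrant labels must be one of: ",
         paste(quads, collapse = ", "), call. = FALSE)
  if (!is.numeric(sound_speed) || sound_speed <= 0)
    stop("sound_speed must be positive (cm/ms)", call. = FALSE)
  channels <- as.data.frame(channels)[, need]
  structure(list(channels = channels, sound_speed = sound_speed),
            class = "channel_geometry")
}

#' Default posterior microphone array
#'
#' A 16-channel array: 14 microphones over the posterior chest (7 per
#' side, alternating between a paraspinal and a lateral column) plus two
#' anterior channels when `n_channels = 16`. Use `n_channels = 14` for the
#' posterior-only array.
#'
#' @param n_channels 14 (posterior only) or 16 (with two anterior
#'   channels).
#' @param sound_speed cm/ms, passed to [channel_geometry()].
#' @return a `channel_geometry`.
#' @export
default_geometry <- function(n_channels = 16, sound_speed = 3) {
  if (!n_channels %in% c(14, 16))
    stop("n_channels must be 14 or 16", call. = FALSE)
  # posterior grid, one side: alternate |x| between 6 and 11 cm down the back
  zs <- c(26, 22, 18, 14, 10, 6, 2)
  xs <- c(6, 11, 6, 11, 6, 11, 6)
  one_side <- function(sgn, side, id0) {
    data.frame(channel = id0 + seq_along(zs),
               x = sgn * xs, y = 0, z = zs,
               side = side,
               quadrant = paste0(ifelse(zs >= 14, "top-", "bottom-"), side))
  }
  ch <- rbind(one_side(-1, "left", 0L), one_side(+1, "right", 7L))
  if (n_channels == 16) {
    ch <- rbind(ch, data.frame(
      channel = c(15L, 16L),
      x = c(-6, 6), y = 20, z = 16,
      side = c("left", "right"),
      quadrant = c("top-left", "top-right")))
  }
  channel_geometry(ch, sound_speed = sound_speed)
}

#' Ipsilateral channel set
#'
#' @param geometry a `channel_geometry`.
#' @param channel a channel id present in the geometry.
#' @return integer vector of all channel ids sharing the channel's side
#'   (including `channel` itself).
#' @export
ipsilateral_channels <- function(geometry, channel) {
  ch <- geometry$channels
  i <- match(channel, ch$channel)
  if (is.na(i)) stop("unknown channel ", channel, call. = FALSE)
  ch$channel[ch$side == ch$side[i]]
}

channel_position <- function(geometry, channel) {
  ch <- geometry$channels
  i <- match(channel, ch$channel)
  if (anyNA(i)) stop("unknown channel id", call. = FALSE)
  as.matrix(ch[i, c("x", "y", "z"), drop = FALSE])
}

channel_side <- function(geometry, channel) {
  ch <- geometry$channels
  ch$side[match(channel, ch$channel)]
}

channel_quadrant <- function(geometry, channel) {
  ch <- geometry$channels
  ch$quadrant[match(channel, ch$channel)]
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat("<channel_geometry>", nrow(x$channels), "channels,",
      sum(x$channels$side == "left"), "left /",
      sum(x$channels$side == "right"), "right, sound speed",
      x$sound_speed, "cm/ms\n")
  invisible(x)
}

#' Read / write geometry as YAML
#'
#' @param path file path.
#' @return `read_geometry_yaml` returns a `channel_geometry`;
#'   `write_geometry_yaml` returns `path` invisibly.
#' @export
read_geometry_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  channel_geometry(do.call(rbind.data.frame, y$channels),
                   sound_speed = y$sound_speed %||% 3)
}

#' @rdname read_geometry_yaml
#' @param geometry a `channel_geometry` to serialize.
#' @export
write_geometry_yaml <- function(geometry, path) {
  rows <- lapply(seq_len(nrow(geometry$channels)), function(i)
    as.list(geometry$channels[i, ]))
  yaml::write_yaml(list(sound_speed = geometry$sound_speed, channels = rows),
                   path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
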