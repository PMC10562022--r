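#' Equal-width HU partition
#'
#' Splits an HU interval into `n_segments` equal segments; each segment is
#' carried by one 8-bit image channel. The default full-range three-way
#' partition of \[-1024, 3071\] has edges -1024, 341, 1706, 3071.
#'
#' @param lo,hi HU bounds, `hi > lo`.
#' @param n_segments number of segments (channels), at least 1.
#' @return An object of class `hu_partition` with field `edges`
#'   (length `n_segments + 1`, strictly increasing).
#' @export
partition_edges <- function(lo = -1024, hi = 3071, n_segments = 3L) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  n_segments <- as.integer(n_segments)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("`hi` must exceed `lo`", call. = FALSE)
  if (n_segments < 1L) stop("`n_segments` must be >= 1", call. = FALSE)
  edges <- lo + (0:n_segments) * (hi - lo) / n_segments
  structure(list(edges = edges), class = "hu_partition")
}

#' @export
print.hu_partition <- function(x, ...) {
  cat("<hu_partition> edges:", paste(signif(x$edges, 6), collapse = ", "), "\n")
  invisible(x)
}

n_segments <- function(part) length(part$edges) - 1L

# round half away from zero, so quantisation is platform-independent
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Encode an HU slice into saturating 8-bit channels
#'
#' Each channel carries one HU segment rescaled to \[0, 255\]: channel `c` is
#' `round(255 * clip((h - e_c) / (e_{c+1} - e_c), 0, 1))`. A pixel saturates
#' every channel below its segment to 255 and leaves every channel above at 0
#' (a thermometer code), so the HU value can be recovered as an affine
#' function of the channel sum. Values outside the partition range saturate.
#'
#' @param hu numeric matrix of HU values (one axial slice).
#' @param part an [partition_edges()] result.
#' @return An object of class `channelized_slice`: integer array
#'   `H x W x n_segments` with values in \[0, 255\].
#' @export
encode_slice <- function(hu, part) {
  stopifnot(is.matrix(hu), inherits(part, "hu_partition"))
  ns <- n_segments(part)
  e <- part$edges
  ch <- array(0L, c(nrow(hu), ncol(hu), ns))
  for (k in seq_len(ns)) {
    f <- (hu - e[k]) / (e[k + 1] - e[k])
    f <- pmin(pmax(f, 0), 1)
    ch[, , k] <- as.integer(round_half_away(255 * f))
  }
  structure(list(channels = ch), class = "channelized_slice")
}

#' Decode 8-bit channels back to HU
#'
#' Inverts the saturating encoding by the channel sum:
#' `h = e_0 + sum_c (v_c / 255) * (e_{c+1} - e_c)`. For slices produced by
#' [encode_slice()] this recovers the clipped HU value to within half a
#' quantisation step per channel (at most ~2.68 HU for the default
#' three-segment full-range partition).
#'
#' @param cs a `channelized_slice`, or a numeric `H x W x n_segments` array
#'   with values in \[0, 255\].
#' @param part the [partition_edges()] used for encoding.
#' @return Numeric matrix of HU values.
#' @export
decode_slice <- function(cs, part) {
  stopifnot(inherits(part, "hu_partition"))
  ch <- if (inherits(cs, "channelized_slice")) cs$channels else cs
  if (!is.array(ch) || length(dim(ch)) != 3L || dim(ch)[3] != n_segments(part))
    stop("channel array does not match the partition", call. = FALSE)
  if (min(ch) < 0 || max(ch) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  e <- part$edges
  widths <- diff(e)
  hu <- matrix(e[1], nrow(ch), ncol(ch))
  for (k in seq_along(widths)) {
    hu <- hu + (ch[, , k] / 255) * widths[k]
  }
  hu
}

#' Export a channelized slice as an 8-bit RGB PNG preview
#'
#' Channels map to R, G, B in low-to-high HU order. The preview is for visual
#' inspection; exact HU recovery goes through [decode_slice()].
#'
#' @param cs a `channelized_slice` with 3 channels.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(cs, path) {
  stopifnot(inherits(cs, "channelized_slice"))
  if (dim(cs$channels)[3] != 3L) stop("PNG preview needs exactly 3 channels", call. = FALSE)
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  png::writePNG(cs$channels / 255, path)
  invisible(path)
}
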