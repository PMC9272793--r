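#' Parse hex colors into an RGB palette table
#'
#' Parses `#RRGGBB` (or `#RGB` shorthand) color strings into unit-interval
#' RGB channels. Channels are exactly `byte / 255`, so parsing is invertible
#' for 8-bit colors via [format_hex()].
#'
#' @param hex Character vector of colors, each `#RRGGBB` or `#RGB`
#'   (case-insensitive).
#' @return A tibble with one row per color and columns `hex` (the input
#'   string, byte-for-byte), `r`, `g`, `b` (channels on \[0, 1\]).
#' @examples
#' parse_palette(c("#FFFFFF", "#000000", "#ff8000"))
#' @export
parse_palette <- function(hex) {
  if (!is.character(hex) || length(hex) == 0) {
    stop("`hex` must be a non-empty character vector of color strings",
         call. = FALSE)
  }
  ok_long  <- grepl("^#[0-9a-fA-F]{6}$", hex)
  ok_short <- grepl("^#[0-9a-fA-F]{3}$", hex)
  bad <- which(!(ok_long | ok_short))
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed hex color '%s' at position %d (expected #RRGGBB or #RGB)",
      hex[bad[1]], bad[1]), call. = FALSE)
  }
  expanded <- hex
  if (any(ok_short)) {
    # "#abc" -> "#aabbcc"
    parts <- substring(hex[ok_short], 2:4, 2:4)
    dim(parts) <- c(sum(ok_short), 3L)
    expanded[ok_short] <- paste0(
      "#", parts[, 1], parts[, 1], parts[, 2], parts[, 2],
      parts[, 3], parts[, 3])
  }
  byte <- function(k) strtoi(substr(expanded, 2L * k, 2L * k + 1L), 16L)
  tibble::tibble(
    hex = hex,
    r = byte(1L) / 255,
    g = byte(2L) / 255,
    b = byte(3L) / 255
  )
}

#' Format RGB channels as hex strings
#'
#' Inverse of [parse_palette()] for 8-bit-representable channels: channels
#' are scaled by 255 and rounded to the nearest byte.
#'
#' @param colors A data frame with numeric columns `r`, `g`, `b` on \[0, 1\].
#' @return Character vector of `#RRGGBB` strings (upper case).
#' @examples
#' format_hex(parse_palette("#1A2B3C"))
#' @export
format_hex <- function(colors) {
  colors <- check_colors(colors)
  sprintf("#%02X%02X%02X",
          as.integer(round(colors$r * 255)),
          as.integer(round(colors$g * 255)),
          as.integer(round(colors$b * 255)))
}

# Validate an r/g/b color table; returns it as a tibble.
check_colors <- function(colors) {
  if (!is.data.frame(colors) || !all(c("r", "g", "b") %in% names(colors))) {
    stop("`colors` must be a data frame with columns r, g, b ",
         "(see parse_palette())", call. = FALSE)
  }
  ch <- as.matrix(colors[, c("r", "g", "b")])
  if (!is.numeric(ch) || anyNA(ch) || any(ch < 0) || any(ch > 1)) {
    stop("color channels must be numeric values in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(colors)
}

# Validate RGB channel weights: three nonnegative values, not all zero.
check_weights <- function(weights) {
  if (!is.numeric(weights) || length(weights) != 3 || anyNA(weights) ||
      any(weights < 0) || all(weights == 0)) {
    stop("`weights` must be three nonnegative numbers (r, g, b) with at ",
         "least one positive", call. = FALSE)
  }
  as.numeric(weights)
}

#' Weighted RGB distance between two colors
#'
#' Euclidean distance between RGB channel triples, with optional per-channel
#' weights inside the square root:
#' `sqrt(w_r (e_r - f_r)^2 + w_g (e_g - f_g)^2 + w_b (e_b - f_b)^2)`.
#' Channel weights let users emphasize channels the eye resolves better
#' (e.g. down-weighting blue).
#'
#' @param e,f Numeric length-3 RGB vectors on \[0, 1\], or single-row data
#'   frames with columns `r`, `g`, `b`.
#' @param weights Three nonnegative channel weights, default `c(1, 1, 1)`.
#' @return A nonnegative scalar.
#' @examples
#' color_distance(c(0, 0, 0), c(1, 1, 1)) # sqrt(3)
#' @export
color_distance <- function(e, f, weights = c(1, 1, 1)) {
  as_rgb <- function(x) {
    if (is.data.frame(x)) x <- unlist(x[1, c("r", "g", "b")], use.names = FALSE)
    if (!is.numeric(x) || length(x) != 3) {
      stop("colors must be length-3 RGB vectors or r/g/b data-frame rows",
           call. = FALSE)
    }
    x
  }
  w <- check_weights(weights)
  d <- as_rgb(e) - as_rgb(f)
  sqrt(sum(w * d^2))
}

#' Pairwise weighted RGB distance matrix for a palette
#'
#' Computes the full symmetric matrix of weighted RGB distances between all
#' palette colors, optionally after simulating color-vision deficiency
#' ([simulate_cvd()]) so that distances reflect how a CVD viewer perceives
#' the palette.
#'
#' @param palette Character vector of hex colors, or a color table from
#'   [parse_palette()].
#' @param weights Three nonnegative RGB channel weights, default `c(1,1,1)`.
#' @param cvd One of `"none"`, `"protan"`, `"deutan"`, `"tritan"`.
#' @param severity CVD severity on \[0, 1\]; 0 is the identity, 1 (default)
#'   full dichromacy.
#' @return An M x M symmetric numeric matrix with zero diagonal; rows and
#'   columns follow palette order and are named by the input hex strings.
#' @examples
#' color_distance_matrix(c("#000000", "#FFFFFF"))
#' @export
color_distance_matrix <- function(palette, weights = c(1, 1, 1),
                                  cvd = "none", severity = 1) {
  colors <- if (is.data.frame(palette)) check_colors(palette) else
    parse_palette(palette)
  w <- check_weights(weights)
  if (anyDuplicated(colors$hex)) {
    warning("palette contains duplicate colors; their pairwise distance is ",
            "zero and they may be assigned to overlapping clusters",
            call. = FALSE)
  }
  colors <- simulate_cvd(colors, cvd = cvd, severity = severity)
  dr <- outer(colors$r, colors$r, "-")
  dg <- outer(colors$g, colors$g, "-")
  db <- outer(colors$b, colors$b, "-")
  D <- sqrt(w[1] * dr^2 + w[2] * dg^2 + w[3] * db^2)
  diag(D) <- 0
  dimnames(D) <- list(colors$hex, colors$hex)
  D
}
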