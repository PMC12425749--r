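#' Build a parametric head phantom
#'
#' Constructs a labelled activity grid emulating a digital head phantom:
#' an elliptical head outline enclosing a gray-matter shell and a
#' white-matter core, with a small square lesion centred on the grid.
#' Region codes are 0 = background, 1 = gray matter, 2 = white matter,
#' 3 = lesion.
#'
#' The geometry is parametric (normalized ellipse semi-axes) so that a
#' real segmented atlas can be substituted by passing a custom label
#' grid to downstream functions; the default shapes are a look-alike,
#' not a registered atlas.
#'
#' @param side Grid side length in pixels (odd, default 111).
#' @param lesion_side Side of the central square lesion in pixels
#'   (odd, default 5).
#' @param geometry Named list of normalized ellipse semi-axes
#'   (fractions of the half-side): `gray_a`, `gray_b` for the outer
#'   gray-matter boundary and `white_a`, `white_b` for the white-matter
#'   core.
#' @return An object of class `pet_phantom`: list with `label_grid`
#'   (side x side integer matrix), `region_codes`, `region_names`,
#'   `side`, `lesion_side`, `pixel_size`.
#' @examples
#' ph <- make_phantom(side = 31, lesion_side = 3)
#' table(ph$label_grid)
#' @export
make_phantom <- function(side = 111L, lesion_side = 5L,
                         geometry = list(gray_a = 0.90, gray_b = 0.78,
                                         white_a = 0.58, white_b = 0.48)) {
  side <- as.integer(side)
  lesion_side <- as.integer(lesion_side)
  if (side < 1L || lesion_side < 1L)
    stop("'side' and 'lesion_side' must be positive")
  if (side %% 2L == 0L || lesion_side %% 2L == 0L)
    stop("'side' and 'lesion_side' must be odd so the lesion centres exactly on the grid")
  if (lesion_side > side)
    stop("'lesion_side' cannot exceed 'side'")

  half <- (side - 1) / 2
  # normalized pixel-centre coordinates in [-1, 1]
  u <- (seq_len(side) - 1 - half) / half
  U <- matrix(u, side, side, byrow = TRUE)   # column coordinate
  V <- matrix(u, side, side, byrow = FALSE)  # row coordinate

  lab <- matrix(0L, side, side)
  lab[(U / geometry$gray_a)^2 + (V / geometry$gray_b)^2 <= 1] <- 1L
  lab[(U / geometry$white_a)^2 + (V / geometry$white_b)^2 <= 1] <- 2L

  ctr <- (side + 1L) / 2L
  hw <- (lesion_side - 1L) / 2L
  idx <- (ctr - hw):(ctr + hw)
  lab[idx, idx] <- 3L

  structure(list(label_grid = lab,
                 region_codes = c(background = 0L, gray = 1L,
                                  white = 2L, lesion = 3L),
                 region_names = c(`0` = "background", `1` = "gray",
                                  `2` = "white", `3` = "lesion"),
                 side = side, lesion_side = lesion_side,
                 pixel_size = 1),
            class = "pet_phantom")
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat("Parametric head phantom:", x$side, "x", x$side, "pixels\n")
  tab <- table(factor(x$label_grid, levels = x$region_codes,
                      labels = names(x$region_codes)))
  print(tab)
  invisible(x)
}

#' Logical pixel masks for the phantom regions
#'
#' @param phantom A `pet_phantom`.
#' @return Named list of logical vectors (length side^2, column-major
#'   pixel order) for background, gray, white and lesion.
#' @export
region_masks <- function(phantom) {
  stopifnot(inherits(phantom, "pet_phantom"))
  lab <- as.vector(phantom$label_grid)
  lapply(as.list(phantom$region_codes), function(code) lab == code)
}
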