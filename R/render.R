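#' Render a dot array to a grayscale raster
#'
#' Produces a square matrix covering the virtual circle: mid-gray (0.5)
#' background, black dots at 0, white dots at 1.  Intended as a visual and
#' round-trip check (metrics recomputed from the raster agree with the
#' spec up to pixel quantization), not as display code.
#'
#' @param spec A `dot_array` from [place_dots()].
#' @param pixels_per_degree Raster resolution (> 0).
#' @return A numeric matrix in `[0, 1]` with attribute `pixels_per_degree`;
#'   rows index y (top row = largest y), columns index x.
#' @export
render_stimulus <- function(spec, pixels_per_degree = 32) {
  if (pixels_per_degree <= 0) stop("pixels_per_degree must be > 0", call. = FALSE)
  fd <- attr(spec, "field_diameter")
  stopifnot(!is.null(fd))
  npx <- ceiling(fd * pixels_per_degree)
  # pixel-center coordinates in degrees, origin at fixation
  coord <- (seq_len(npx) - 0.5) / pixels_per_degree - fd / 2
  img <- matrix(0.5, nrow = npx, ncol = npx)
  xg <- matrix(coord, nrow = npx, ncol = npx, byrow = TRUE)
  yg <- matrix(rev(coord), nrow = npx, ncol = npx)
  for (i in seq_len(nrow(spec))) {
    inside <- (xg - spec$x[i])^2 + (yg - spec$y[i])^2 <= (spec$diameter[i] / 2)^2
    img[inside] <- if (spec$polarity[i] == "black") 0 else 1
  }
  attr(img, "pixels_per_degree") <- pixels_per_degree
  attr(img, "field_diameter") <- fd
  img
}

#' Recompute array metrics from a rendered raster
#'
#' Segments non-background pixels into connected components (4-neighbour
#' flood fill) and derives numerosity, per-dot equivalent diameters and
#' areas.  Used for round-trip checks of [render_stimulus()].
#'
#' @param img A raster from [render_stimulus()].
#' @return A one-row tibble matching [array_metrics()] plus
#'   `n_black`/`n_white` component counts.
#' @export
raster_metrics <- function(img) {
  ppd <- attr(img, "pixels_per_degree")
  fd <- attr(img, "field_diameter")
  stopifnot(!is.null(ppd), !is.null(fd))
  labs <- label_components(img != 0.5)
  ncomp <- max(labs)
  px_area <- 1 / ppd^2
  areas <- tabulate(labs[labs > 0], nbins = ncomp) * px_area
  pol <- vapply(seq_len(ncomp), function(k) img[which(labs == k)[1]], numeric(1))
  tibble::tibble(
    numerosity = ncomp,
    mean_item_diameter = mean(2 * sqrt(areas / pi)),
    mean_item_area = mean(areas),
    total_surface_area = sum(areas),
    density = ncomp / (pi * (fd / 2)^2),
    n_black = sum(pol == 0),
    n_white = sum(pol == 1)
  )
}

# 4-connected component labelling by iterative flood fill (no imaging
# dependency in the environment); masks here are tiny (< 300x300).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labs <- matrix(0L, nr, nc)
  nextlab <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labs[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    labs[start] <- nextlab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      nb <- c(
        if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
        if (c > 1L) cur - nr, if (c < nc) cur + nr
      )
      nb <- nb[mask[nb] & labs[nb] == 0L]
      labs[nb] <- nextlab
      stack <- c(stack, nb)
    }
  }
  labs
}

#' Plot a dot array
#'
#' @param object A `dot_array`.
#' @param ... Unused.
#' @return A ggplot object showing the dots at true scale inside the
#'   virtual circle, on a mid-gray background.
#' @export
autoplot.dot_array <- function(object, ...) {
  fd <- attr(object, "field_diameter")
  circ <- tibble::tibble(
    t = seq(0, 2 * pi, length.out = 200),
    x = fd / 2 * cos(.data$t), y = fd / 2 * sin(.data$t)
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circ, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(
      ggplot2::aes(size = .data$diameter, fill = .data$polarity),
      shape = 21, colour = NA, show.legend = FALSE
    ) +
    ggplot2::scale_fill_manual(values = c(black = "black", white = "white")) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(panel.background = ggplot2::element_rect(fill = "grey50"))
}
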