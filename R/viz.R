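#' @include AllClasses.R
NULL

#' Extract suprathreshold inter-brain links
#'
#' Scans an N1 x N2 inter-brain block in row-major order and keeps cells
#' whose value exceeds the threshold (signed comparison by default; set
#' \code{mode = "abs"} for |value|).
#'
#' @param inter numeric inter-brain block (participant-1 channels in rows,
#'   participant-2 channels in columns).
#' @param threshold user threshold; only values over it are kept.
#' @param mode "signed" (default) or "abs".
#' @return A \linkS4class{LinkSet} (possibly empty).
#' @seealso [render2dInter()]
#' @export
extractLinks <- function(inter, threshold, mode = c("signed", "abs")) {
  mode <- match.arg(mode)
  inter <- as.matrix(inter)
  keep <- if (mode == "signed") inter > threshold else abs(inter) > threshold
  idx <- which(t(keep))                       # row-major ordering
  j <- (idx - 1L) %% ncol(inter) + 1L
  i <- (idx - 1L) %/% ncol(inter) + 1L
  links <- data.frame(i = i, j = j, value = inter[cbind(i, j)],
                      rendered = rep(TRUE, length(i)))
  new("LinkSet", links = links, threshold = threshold, mode = mode)
}

## Bernstein evaluation of a degree-10 Bezier at parameters t
bezierEval <- function(ctrl, t) {
  n <- nrow(ctrl) - 1L
  B <- vapply(0:n, function(k) choose(n, k) * t^k * (1 - t)^(n - k),
              numeric(length(t)))
  B <- matrix(B, nrow = length(t))
  out <- B %*% ctrl
  out[t == 0, ] <- matrix(ctrl[1L, ], sum(t == 0), 2L, byrow = TRUE)
  out[t == 1, ] <- matrix(ctrl[n + 1L, ], sum(t == 1), 2L, byrow = TRUE)
  out
}

#' Arched 10th-order Bezier polyline between two sensors
#'
#' The first and last of the 11 control points are the sensor coordinates;
#' the 9 interior points are linear interpolations between them, displaced
#' perpendicular to the segment by a fixed sine arch (peak height a quarter
#' of the sensor distance, on the canonical upward side), which lifts the
#' curve toward the inter-head midline. The polyline samples the curve at
#' \code{steps + 1} equally spaced parameters; endpoints equal the inputs
#' exactly, and swapping the endpoints yields the same point set reversed.
#'
#' @param pStart,pEnd length-2 numeric 2-D sensor coordinates.
#' @param steps number of polyline segments (>= 1); \code{steps = 1} gives a
#'   2-point polyline.
#' @return (steps + 1) x 2 polyline matrix.
#' @export
bezierLink <- function(pStart, pEnd, steps = 10L) {
  stopifnot(length(pStart) == 2L, length(pEnd) == 2L, steps >= 1L)
  u <- seq(0, 1, length.out = 11L)
  base <- outer(1 - u, pStart) + outer(u, pEnd)
  seg <- pEnd - pStart
  len <- sqrt(sum(seg^2))
  if (len > 0) {
    perp <- c(-seg[2L], seg[1L]) / len
    ## canonical side: arch opens upward (ties broken toward +x)
    if (perp[2L] < 0 || (perp[2L] == 0 && perp[1L] < 0)) perp <- -perp
    ctrl <- base + outer(0.25 * len * sin(pi * u), perp)
  } else {
    ctrl <- base
  }
  t <- seq(0, 1, length.out = steps + 1L)
  bezierEval(ctrl, t)
}

## project one head's sensors and normalize to unit head radius
headLayout <- function(e, centerX) {
  p2 <- azimuthalProjection(chPositions(e))
  rmax <- max(sqrt(rowSums(p2^2)))
  p2 <- p2 / max(rmax, 1e-12) * 0.85
  data.frame(x = p2[, 1L] + centerX, y = p2[, 2L],
             label = chNames(e), bad = chNames(e) %in% badChannels(e))
}

circleOutline <- function(centerX, r = 1, n = 120L) {
  a <- seq(0, 2 * pi, length.out = n)
  cbind(centerX + r * cos(a), r * sin(a))
}

#' Two-head topographic rendering of inter-brain links
#'
#' Lays the two participants' sensors out on side-by-side head outlines
#' (azimuthal-equidistant projection per head, fixed gap), draws good
#' sensors as points and bad channels as crosses, and renders every
#' suprathreshold inter-brain link as an arched Bezier polyline. Positive
#' values use the sequential red colormap, negative values the blue one, and
#' line width grows linearly with |value|. The returned
#' \linkS4class{InterBrainFigure} is a deterministic description (same
#' inputs, same figure); \code{plot()} draws it with ggplot2.
#'
#' @param e1,e2 \linkS4class{EpochArray} objects with sensor positions.
#' @param inter N1 x N2 inter-brain block (e.g. a standardized block from
#'   [sliceBlocks()]).
#' @param threshold link threshold (see [extractLinks()]).
#' @param steps Bezier polyline segments per link (default 10).
#' @param labels draw channel labels (default FALSE).
#' @param mode "signed" or "abs" thresholding.
#' @param widthRange c(min, max) line widths mapped linearly onto |value|.
#' @return An \linkS4class{InterBrainFigure}.
#' @seealso [extractLinks()], [bezierLink()], [linkCount()]
#' @export
render2dInter <- function(e1, e2, inter, threshold = 2, steps = 10L,
                          labels = FALSE, mode = c("signed", "abs"),
                          widthRange = c(0.4, 2.5)) {
  mode <- match.arg(mode)
  if (positionFree(e1) || positionFree(e2))
    stop("topographic rendering refuses position-free containers; ",
         "attach 3-D sensor positions first")
  ls <- extractLinks(inter, threshold, mode)
  sens1 <- headLayout(e1, -1.6)
  sens2 <- headLayout(e2, +1.6)
  sens1$head <- 1L; sens2$head <- 2L
  sensors <- rbind(sens1, sens2)
  lk <- ls@links
  vmax <- if (nrow(lk)) max(abs(lk$value)) else 1
  paths <- vector("list", nrow(lk))
  cols <- character(nrow(lk))
  wds <- numeric(nrow(lk))
  redRamp <- grDevices::colorRamp(c("#fcae91", "#a50f15"))
  blueRamp <- grDevices::colorRamp(c("#bdd7e7", "#08519c"))
  for (r in seq_len(nrow(lk))) {
    p1 <- c(sens1$x[lk$i[r]], sens1$y[lk$i[r]])
    p2 <- c(sens2$x[lk$j[r]], sens2$y[lk$j[r]])
    paths[[r]] <- bezierLink(p1, p2, steps)
    z <- min(abs(lk$value[r]) / max(vmax, 1e-12), 1)
    rgb <- if (lk$value[r] >= 0) redRamp(z) else blueRamp(z)
    cols[r] <- grDevices::rgb(rgb[1L], rgb[2L], rgb[3L],
                              maxColorValue = 255)
    wds[r] <- widthRange[1L] +
      diff(widthRange) * min(abs(lk$value[r]) / max(vmax, 1e-12), 1)
  }
  lk$color <- cols
  lk$width <- wds
  new("InterBrainFigure",
      sensors = sensors, links = lk, paths = paths,
      outlines = list(circleOutline(-1.6), circleOutline(1.6)),
      params = list(threshold = threshold, steps = steps, labels = labels,
                    mode = mode, widthRange = widthRange))
}

#' @describeIn render2dInter draw the figure with ggplot2
#' @param x an \linkS4class{InterBrainFigure}
#' @param y ignored
#' @param ... ignored
#' @export
setMethod("plot", signature(x = "InterBrainFigure", y = "missing"),
  function(x, y, ...) {
    g <- ggplot2::ggplot()
    for (o in x@outlines) {
      od <- data.frame(x = o[, 1L], y = o[, 2L])
      g <- g + ggplot2::geom_path(data = od,
                                  ggplot2::aes(x = .data$x, y = .data$y),
                                  colour = "grey40")
    }
    for (r in seq_along(x@paths)) {
      pd <- data.frame(x = x@paths[[r]][, 1L], y = x@paths[[r]][, 2L])
      g <- g + ggplot2::geom_path(
        data = pd, ggplot2::aes(x = .data$x, y = .data$y),
        colour = x@links$color[r], linewidth = x@links$width[r])
    }
    good <- x@sensors[!x@sensors$bad, , drop = FALSE]
    bad <- x@sensors[x@sensors$bad, , drop = FALSE]
    g <- g + ggplot2::geom_point(
      data = good, ggplot2::aes(x = .data$x, y = .data$y), size = 1.4)
    if (nrow(bad))
      g <- g + ggplot2::geom_point(
        data = bad, ggplot2::aes(x = .data$x, y = .data$y),
        shape = 4, size = 2, stroke = 1)
    if (isTRUE(x@params$labels))
      g <- g + ggplot2::geom_text(
        data = x@sensors,
        ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
        size = 2.4, vjust = -1)
    g + ggplot2::coord_equal() + ggplot2::theme_void()
  })

#' Topographic map of per-channel statistics
#'
#' Scatter of the projected sensor layout with nonzero values highlighted
#' (diverging color by sign) and zero-masked channels drawn as hollow grey
#' points, for displaying t maps masked to significant channels.
#'
#' @param values per-channel statistic (e.g. \code{tObsPlot} of
#'   [permTtestFdr()]); length must equal the channel count.
#' @param e an \linkS4class{EpochArray} with positions.
#' @return A \linkS4class{SensorMapFigure}; \code{plot()} draws it.
#' @export
plotSignificantSensors <- function(values, e) {
  stopifnot(is(e, "EpochArray"))
  if (length(values) != nChannels(e))
    stop("shape error: ", length(values), " values for ", nChannels(e),
         " channels")
  if (positionFree(e))
    stop("topographic rendering refuses position-free containers")
  p2 <- azimuthalProjection(chPositions(e))
  rmax <- max(sqrt(rowSums(p2^2)))
  p2 <- p2 / max(rmax, 1e-12)
  sensors <- data.frame(x = p2[, 1L], y = p2[, 2L], label = chNames(e),
                        value = as.numeric(values),
                        highlighted = as.numeric(values) != 0)
  new("SensorMapFigure", sensors = sensors, params = list())
}

#' @describeIn plotSignificantSensors draw the figure with ggplot2
#' @param x a \linkS4class{SensorMapFigure}
#' @param y ignored
#' @param ... ignored
#' @export
setMethod("plot", signature(x = "SensorMapFigure", y = "missing"),
  function(x, y, ...) {
    s <- x@sensors
    g <- ggplot2::ggplot() +
      ggplot2::geom_point(
        data = s[!s$highlighted, , drop = FALSE],
        ggplot2::aes(x = .data$x, y = .data$y),
        shape = 1, colour = "grey60", size = 2)
    hi <- s[s$highlighted, , drop = FALSE]
    if (nrow(hi))
      g <- g + ggplot2::geom_point(
        data = hi,
        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$value),
        size = 3) +
        ggplot2::scale_colour_gradient2(low = "#08519c", mid = "white",
                                        high = "#a50f15", midpoint = 0)
    g + ggplot2::coord_equal() + ggplot2::theme_void()
  })
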