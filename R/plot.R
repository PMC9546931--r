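# Base-graphics plot methods. Forward-direction points and lines are blue,
# backward orange; solid lines for interpretable significant slopes, dashed
# for significant but uninterpretable ones, no line otherwise.

#' @export
plot.refer_fit <- function(x, main = "REFER plot", highlight = NULL, ...) {
  d <- x$data
  ylim <- range(d$logk, d$logkb)
  graphics::plot(d$logK, d$logk, col = "blue", pch = 16,
                 xlab = expression(log[10] ~ K),
                 ylab = expression(log[10] ~ "rate"),
                 ylim = ylim, main = main, ...)
  graphics::points(d$logK, d$logkb, col = "orange", pch = 16)
  if (!is.null(highlight)) {
    i <- d$residue_id %in% highlight
    graphics::points(d$logK[i], d$logk[i], col = "green3", pch = 1, cex = 1.8)
    graphics::points(d$logK[i], d$logkb[i], col = "magenta", pch = 1,
                     cex = 1.8)
  }
  add_line <- function(int, slope, cls, col) {
    if (is.na(cls) || cls == "none") return(invisible())
    graphics::abline(int, slope, col = col,
                     lty = if (cls == "solid") 1 else 2)
  }
  add_line(x$intercept_f, x$slope_f, x$line_class_f, "blue")
  add_line(x$intercept_b, x$slope_b, x$line_class_b, "orange")
  invisible(x)
}

#' @export
plot.kk_class <- function(x, main = NULL, ...) {
  if (is.null(main)) {
    main <- sprintf("log k vs log k' (type %s, f = %.2f)", x$kk_type,
                    x$flatness)
  }
  # drawn with log k horizontal and log k' vertical, the convention under
  # which a type-V cloud is vertically flattened
  m <- x$points[, c(2, 1)]
  # equal axis ranges so the flatness reads correctly from the figure
  half <- max(diff(range(m[, 1])), diff(range(m[, 2])), x$ellipse$a * 2) / 2
  cx <- mean(range(m[, 1])); cy <- mean(range(m[, 2]))
  graphics::plot(m[, 1], m[, 2], pch = 16, asp = 1,
                 xlim = cx + c(-half, half), ylim = cy + c(-half, half),
                 xlab = expression(log[10] ~ k),
                 ylab = expression(log[10] ~ "k'"), main = main, ...)
  th <- seq(0, 2 * pi, length.out = 181)
  ang <- (90 - x$ellipse$angle) * pi / 180
  ex <- x$ellipse$center[2] + x$ellipse$a * cos(th) * cos(ang) -
    x$ellipse$b * sin(th) * sin(ang)
  ey <- x$ellipse$center[1] + x$ellipse$a * cos(th) * sin(ang) +
    x$ellipse$b * sin(th) * cos(ang)
  graphics::lines(ex, ey, col = "gray40")
  invisible(x)
}
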