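#' Total color difference in CIELab space
#'
#' \deqn{\Delta E = \sqrt{(L - L_0)^2 + (a - a_0)^2 + (b - b_0)^2},}
#' the Euclidean distance between two colors in CIELab coordinates. It is a
#' metric: symmetric, zero only for identical colors, and satisfying the
#' triangle inequality.
#'
#' @param sample,reference Colors from [lab_color()], or plain numeric
#'   vectors `c(L, a, b)`.
#' @return The dimensionless color difference.
#' @export
#' @examples
#' delta_e(lab_color(50, 3, 4), lab_color(47, -1, 4))
delta_e <- function(sample, reference) {
  s <- as_lab(sample)
  r <- as_lab(reference)
  sqrt(sum((s - r)^2))
}

#' CIELab color triplet
#'
#' @param L Lightness, 0-100.
#' @param a Red-green axis.
#' @param b Yellow-blue axis.
#' @return A `lab_color` numeric vector.
#' @export
lab_color <- function(L, a, b) {
  stopifnot(L >= 0, L <= 100)
  structure(c(L = L, a = a, b = b), class = "lab_color")
}

as_lab <- function(x) {
  if (inherits(x, "lab_color")) return(unclass(x))
  stopifnot(is.numeric(x), length(x) == 3)
  v <- unname(x)
  if (v[1] < 0 || v[1] > 100) stop("L must be in [0, 100]", call. = FALSE)
  v
}

#' Average replicate color readings in Lab space
#'
#' Instrument practice is several readings per leaf over several replicate
#' leaves; readings are averaged coordinate-wise in Lab space before any
#' color difference is taken, giving one color per sample/time.
#'
#' @param colors A data.frame or matrix with columns `L`, `a`, `b` (one row
#'   per reading).
#' @return A single `lab_color`.
#' @export
average_lab <- function(colors) {
  m <- as.data.frame(colors)
  stopifnot(all(c("L", "a", "b") %in% names(m)))
  lab_color(mean(m$L), mean(m$a), mean(m$b))
}

#' Relative burst strength of a leaf
#'
#' Ratio of the maximum puncture force of a sample to that of the reference
#' (untreated or day-0) leaf. Values above 1 indicate toughening; below 1,
#' softening.
#'
#' @param force Maximum puncture force, N (> 0).
#' @param reference_force Reference puncture force, N (> 0).
#' @return Dimensionless force ratio.
#' @export
relative_burst_strength <- function(force, reference_force) {
  if (any(reference_force <= 0)) {
    stop("reference force must be positive", call. = FALSE)
  }
  if (any(force <= 0)) stop("force must be positive", call. = FALSE)
  force / reference_force
}
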