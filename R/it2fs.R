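#' Construct a trapezoidal interval type-2 fuzzy set
#'
#' An interval type-2 trapezoidal fuzzy set is a pair of trapezoids: an
#' upper membership bound and a lower one, each described by four abscissae
#' `a1 <= a2 <= a3 <= a4` and two membership heights in (0, 1]. The lower
#' trapezoid must lie within the support of the upper one and its heights
#' must not exceed the upper heights.
#'
#' @param upper,lower Numeric vectors `c(a1, a2, a3, a4, h1, h2)`.
#' @return Object of class `it2fs`.
#' @examples
#' it2fs(c(9, 10, 10, 10, 1, 1), c(9.5, 10, 10, 10, 0.9, 0.9))  # "VH"
#' @export
it2fs <- function(upper, lower) {
  chk <- function(tr, lab) {
    stopifnot(is.numeric(tr), length(tr) == 6L, all(is.finite(tr)))
    a <- tr[1:4]; h <- tr[5:6]
    if (any(diff(a) < -1e-12)) {
      stop(lab, " trapezoid vertices must be nondecreasing", call. = FALSE)
    }
    if (any(h <= 0) || any(h > 1)) {
      stop(lab, " heights must lie in (0, 1]", call. = FALSE)
    }
    unname(as.numeric(tr))
  }
  upper <- chk(upper, "upper")
  lower <- chk(lower, "lower")
  if (lower[1] < upper[1] - 1e-12 || lower[4] > upper[4] + 1e-12) {
    stop("lower trapezoid support must lie within the upper support",
         call. = FALSE)
  }
  if (any(lower[5:6] > upper[5:6] + 1e-12)) {
    stop("lower heights must not exceed upper heights", call. = FALSE)
  }
  structure(list(upper = upper, lower = lower), class = "it2fs")
}

#' @export
print.it2fs <- function(x, ...) {
  fmt <- function(tr) sprintf("(%s; %s, %s)",
                              paste(format(tr[1:4]), collapse = ", "),
                              format(tr[5]), format(tr[6]))
  cat("<it2fs ", fmt(x$upper), " / ", fmt(x$lower), ">\n", sep = "")
  invisible(x)
}

#' The seven-term linguistic scale
#'
#' Default mapping from the seven graded linguistic terms (VL, L, ML, M,
#' MH, H, VH) to interval type-2 trapezoidal fuzzy sets on the 0-10
#' support, as used for expert judgments. The scale's ranking values are
#' strictly increasing from VL to VH. A custom scale may be loaded from a
#' YAML file mapping each term to `upper`/`lower` six-vectors.
#'
#' @param path Optional YAML file overriding the default scale.
#' @return Named list of [it2fs()] objects of class `linguistic_scale`,
#'   ordered worst to best.
#' @examples
#' sc <- linguistic_scale()
#' names(sc)
#' @export
linguistic_scale <- function(path = NULL) {
  if (is.null(path)) {
    raw <- list(
      VL = list(c(0, 1, 1, 3, 1, 1),    c(0.5, 1, 1, 2, 0.9, 0.9)),
      L  = list(c(1, 3, 3, 5, 1, 1),    c(2, 3, 3, 4, 0.9, 0.9)),
      ML = list(c(3, 5, 5, 7, 1, 1),    c(4, 5, 5, 6, 0.9, 0.9)),
      M  = list(c(5, 7, 7, 9, 1, 1),    c(6, 7, 7, 8, 0.9, 0.9)),
      MH = list(c(7, 9, 9, 10, 1, 1),   c(8, 9, 9, 9.5, 0.9, 0.9)),
      H  = list(c(8, 9, 10, 10, 1, 1),  c(9, 9, 9, 10, 0.9, 0.9)),
      VH = list(c(9, 10, 10, 10, 1, 1), c(9.5, 10, 10, 10, 0.9, 0.9)))
  } else {
    y <- yaml::read_yaml(path)
    raw <- lapply(y, function(d) list(as.numeric(d$upper),
                                      as.numeric(d$lower)))
  }
  out <- lapply(raw, function(p) it2fs(p[[1]], p[[2]]))
  structure(out, class = c("linguistic_scale", "list"))
}

#' Convert a linguistic term to its fuzzy set
#'
#' @param term Term label present in `scale` (e.g. `"MH"`).
#' @param scale A [linguistic_scale()].
#' @return The corresponding [it2fs()].
#' @export
from_linguistic <- function(term, scale = linguistic_scale()) {
  stopifnot(is.character(term), length(term) == 1L)
  if (!term %in% names(scale)) {
    stop("unknown linguistic term '", term, "'; valid terms: ",
         paste(names(scale), collapse = ", "), call. = FALSE)
  }
  scale[[term]]
}

#' Scale a fuzzy set by a nonnegative crisp weight
#'
#' Multiplies all eight vertices by `w`; membership heights are unchanged.
#'
#' @param w Nonnegative scalar.
#' @param v An [it2fs()].
#' @return The scaled [it2fs()].
#' @export
scale_it2fs <- function(w, v) {
  stopifnot(inherits(v, "it2fs"), is.numeric(w), length(w) == 1L)
  if (!is.finite(w) || w < 0) stop("weight must be >= 0", call. = FALSE)
  it2fs(c(w * v$upper[1:4], v$upper[5:6]),
        c(w * v$lower[1:4], v$lower[5:6]))
}

# Population standard deviation over a numeric vector.
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Ranking value of an interval type-2 fuzzy set
#'
#' Defuzzifies an IT2FS to a scalar used to order fuzzy quantities:
#' the sum over both trapezoids of the three consecutive-vertex means
#' `M_p = (a_p + a_{p+1}) / 2`, minus one quarter of the sum of the vertex
#' spreads (population standard deviations of each consecutive pair
#' `S_1..S_3` and of all four vertices `S_4`), plus the heights term.
#'
#' Two variants of the heights term are provided. The default,
#' `hw = "heights"`, adds the four membership heights `h1, h2` of both
#' trapezoids, following the ranking-value construction for trapezoidal
#' IT2FS on which this pipeline is based; it makes the seven-term
#' linguistic scale strictly increasing. The alternative `hw = "vertex"`
#' adds the second and third vertices instead, matching a variant reading
#' in which the heights symbol indexes vertices; it is kept selectable for
#' comparison.
#'
#' For a crisp-degenerate set `((v,v,v,v; 1,1), (v,v,v,v; 1,1))` the
#' default ranking value is exactly `6 v + 4`.
#'
#' @param v An [it2fs()].
#' @param hw `"heights"` (default) or `"vertex"`.
#' @return Object of class `rank_breakdown`: list with `M` (6 means),
#'   `S` (8 spreads), `H` (4 height terms) and `rank_value`
#'   `= sum(M) - sum(S)/4 + sum(H)`.
#' @examples
#' rank_value(from_linguistic("VH"))$rank_value  # about 62.700
#' @export
rank_value <- function(v, hw = c("heights", "vertex")) {
  stopifnot(inherits(v, "it2fs"))
  hw <- match.arg(hw)
  M <- numeric(0); S <- numeric(0); H <- numeric(0)
  for (side in c("upper", "lower")) {
    a <- v[[side]][1:4]
    h <- v[[side]][5:6]
    M <- c(M, (a[1:3] + a[2:4]) / 2)
    S <- c(S, vapply(1:3, function(q) .pop_sd(a[q:(q + 1)]), numeric(1)),
           .pop_sd(a))
    H <- c(H, if (hw == "heights") h else a[2:3])
  }
  structure(list(M = M, S = S, H = H,
                 rank_value = sum(M) - sum(S) / 4 + sum(H),
                 hw = hw),
            class = "rank_breakdown")
}

#' @export
print.rank_breakdown <- function(x, ...) {
  cat(sprintf("<rank_breakdown (%s): %.6f>\n", x$hw, x$rank_value))
  invisible(x)
}

#' Serialise / restore an IT2FS as JSON
#'
#' `it2fs_to_json()` writes `{"upper": [a1..a4, h1, h2], "lower": [...]}`;
#' `it2fs_from_json()` is its exact inverse (bit-exact for the default
#' linguistic scale).
#'
#' @param v An [it2fs()]; `txt` a JSON string.
#' @return A JSON string, resp. an [it2fs()].
#' @export
it2fs_to_json <- function(v) {
  stopifnot(inherits(v, "it2fs"))
  jsonlite::toJSON(list(upper = v$upper, lower = v$lower), digits = NA)
}

#' @rdname it2fs_to_json
#' @param txt JSON string produced by `it2fs_to_json()`.
#' @export
it2fs_from_json <- function(txt) {
  d <- jsonlite::fromJSON(txt)
  it2fs(d$upper, d$lower)
}
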