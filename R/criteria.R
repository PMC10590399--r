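#' Define an evaluation criterion
#'
#' A criterion belongs to one of the three WSR stages. Wuli criteria are
#' hard constraints and must carry a threshold and comparator; Shili and
#' Renli criteria carry a benefit/cost direction instead.
#'
#' @param id Short unique identifier (used as a column name).
#' @param name Display name. Defaults to `id`.
#' @param stage One of `"wuli"`, `"shili"`, `"renli"`.
#' @param direction `"benefit"` (larger is better) or `"cost"` (smaller is
#'   better). Ignored for Wuli criteria.
#' @param units Free-text unit annotation (documentation only; values are
#'   never converted).
#' @param wuli_threshold Numeric threshold for a Wuli constraint.
#' @param wuli_comparator One of `"ge"`, `"gt"`, `"le"`, `"lt"`: the
#'   comparison an observed value must satisfy against the threshold for
#'   the candidate to survive. `"ge"` means "observed >= threshold passes",
#'   so a requirement of "at least 20 m" is `threshold = 20, comparator =
#'   "ge"` and exactly 20 m passes.
#'
#' @return An object of class `criterion_spec`.
#' @examples
#' criterion_spec("greening", stage = "wuli",
#'                wuli_threshold = 20, wuli_comparator = "ge")
#' criterion_spec("hospital_km", stage = "shili", direction = "cost",
#'                units = "km")
#' @export
criterion_spec <- function(id, name = id,
                           stage = c("shili", "wuli", "renli"),
                           direction = c("benefit", "cost"),
                           units = "",
                           wuli_threshold = NULL,
                           wuli_comparator = NULL) {
  stage <- match.arg(stage)
  direction <- match.arg(direction)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(name), length(name) == 1L)
  if (stage == "wuli") {
    if (is.null(wuli_threshold) || is.null(wuli_comparator)) {
      stop("wuli criterion '", id,
           "' needs both `wuli_threshold` and `wuli_comparator`",
           call. = FALSE)
    }
    wuli_comparator <- match.arg(wuli_comparator, c("ge", "gt", "le", "lt"))
    stopifnot(is.numeric(wuli_threshold), length(wuli_threshold) == 1L,
              is.finite(wuli_threshold))
  } else if (!is.null(wuli_threshold) || !is.null(wuli_comparator)) {
    stop("criterion '", id, "' is not a wuli criterion but carries a ",
         "wuli threshold/comparator", call. = FALSE)
  }
  structure(
    list(id = id, name = name, stage = stage, direction = direction,
         units = units,
         wuli_threshold = if (stage == "wuli") wuli_threshold else NA_real_,
         wuli_comparator = if (stage == "wuli") wuli_comparator else NA_character_),
    class = "criterion_spec")
}

#' @export
print.criterion_spec <- function(x, ...) {
  extra <- if (x$stage == "wuli") {
    sprintf(" [%s %s]", x$wuli_comparator, format(x$wuli_threshold))
  } else {
    sprintf(" (%s)", x$direction)
  }
  cat(sprintf("<criterion %s: %s, stage %s%s>\n", x$id, x$name, x$stage, extra))
  invisible(x)
}

# Coerce a list of criterion_spec into a data frame, checking id uniqueness.
spec_table <- function(specs) {
  if (inherits(specs, "criterion_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "criterion_spec")))
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate criterion ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    id = ids,
    name = vapply(specs, `[[`, character(1), "name"),
    stage = vapply(specs, `[[`, character(1), "stage"),
    direction = vapply(specs, `[[`, character(1), "direction"),
    units = vapply(specs, `[[`, character(1), "units"),
    wuli_threshold = vapply(specs, `[[`, numeric(1), "wuli_threshold"),
    wuli_comparator = vapply(specs, `[[`, character(1), "wuli_comparator"),
    stringsAsFactors = FALSE)
}

#' Validate and normalise a criterion weight vector
#'
#' Weights must be named, nonnegative and sum to one (within `1e-9` unless
#' `renormalize = TRUE`, in which case any positive-sum vector is rescaled).
#'
#' @param w Named numeric vector of weights.
#' @param criteria Optional character vector of criterion ids the weights
#'   must cover, in order; `w` is reordered to match.
#' @param renormalize If `TRUE`, rescale weights to sum to one (with a
#'   warning when the adjustment exceeds `1e-9`).
#' @return Named numeric weight vector summing to one.
#' @examples
#' weight_vector(c(a = 0.25, b = 0.75))
#' @export
weight_vector <- function(w, criteria = NULL, renormalize = FALSE) {
  stopifnot(is.numeric(w), length(w) >= 1L)
  if (is.null(names(w)) || any(!nzchar(names(w)))) {
    stop("weights must be named by criterion id", call. = FALSE)
  }
  if (anyDuplicated(names(w))) stop("duplicate weight names", call. = FALSE)
  if (!is.null(criteria)) {
    missing <- setdiff(criteria, names(w))
    if (length(missing)) {
      stop("weights missing for criteria: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    w <- w[criteria]
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and nonnegative", call. = FALSE)
  }
  s <- sum(w)
  if (abs(s - 1) > 1e-9) {
    if (!renormalize || s <= 0) {
      stop(sprintf("weights sum to %.6f, not 1", s), call. = FALSE)
    }
    warning(sprintf("weights sum to %.6f; renormalizing", s), call. = FALSE)
    w <- w / s
  }
  w
}
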