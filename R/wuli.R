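#' Stage 1: hard-constraint (Wuli) screening
#'
#' Applies every Wuli constraint in `specs` to the candidates in `dm`.
#' A candidate survives only if it satisfies all constraints
#' (conjunction); each violated constraint is recorded separately in the
#' exclusion audit trail. With no Wuli criteria configured all candidates
#' survive vacuously.
#'
#' @param dm A [decision_matrix()] whose columns include every Wuli
#'   criterion's attribute.
#' @param specs Optional list of [criterion_spec()]; defaults to the Wuli
#'   criteria already present in `dm$specs`.
#' @return An object of class `wuli_report`: a list with
#'   \describe{
#'     \item{survivors}{[alternative_set()] tagged `post_wuli`, file order
#'       preserved.}
#'     \item{exclusions}{Data frame `(id, criterion, value, threshold,
#'       comparator)`, one row per violated constraint.}
#'   }
#' @examples
#' dm <- decision_matrix(matrix(c(25, 19.9, 20), ncol = 1),
#'   alternatives = c("A", "B", "C"),
#'   specs = list(criterion_spec("greening", stage = "wuli",
#'                               wuli_threshold = 20,
#'                               wuli_comparator = "ge")))
#' apply_hard_constraints(dm)
#' @export
apply_hard_constraints <- function(dm, specs = NULL) {
  stopifnot(inherits(dm, "decision_matrix"))
  st <- if (is.null(specs)) {
    dm$specs[dm$specs$stage == "wuli", , drop = FALSE]
  } else {
    s <- spec_table(specs)
    s[s$stage == "wuli", , drop = FALSE]
  }
  if (nrow(st) > 0 && any(is.na(st$wuli_threshold) | is.na(st$wuli_comparator))) {
    stop("wuli criterion without threshold/comparator", call. = FALSE)
  }
  missing <- setdiff(st$id, colnames(dm$values))
  if (length(missing)) {
    stop("matrix lacks wuli attribute(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(dm$values)
  pass <- rep(TRUE, n)
  excl <- list()
  for (k in seq_len(nrow(st))) {
    val <- dm$values[, st$id[k]]
    ok <- switch(st$wuli_comparator[k],
                 ge = val >= st$wuli_threshold[k],
                 gt = val >  st$wuli_threshold[k],
                 le = val <= st$wuli_threshold[k],
                 lt = val <  st$wuli_threshold[k])
    bad <- which(!ok)
    if (length(bad)) {
      excl[[length(excl) + 1L]] <- data.frame(
        id = dm$alternatives$id[bad],
        criterion = st$id[k],
        value = unname(val[bad]),
        threshold = st$wuli_threshold[k],
        comparator = st$wuli_comparator[k],
        stringsAsFactors = FALSE)
    }
    pass <- pass & ok
  }
  exclusions <- if (length(excl)) {
    do.call(rbind, excl)
  } else {
    data.frame(id = character(), criterion = character(), value = numeric(),
               threshold = numeric(), comparator = character(),
               stringsAsFactors = FALSE)
  }
  rownames(exclusions) <- NULL
  if (!any(pass)) {
    warning("no candidate satisfies all wuli constraints", call. = FALSE)
  }
  survivors <- alternative_set(dm$alternatives[pass, , drop = FALSE],
                               stage_tag = "post_wuli")
  structure(list(survivors = survivors, exclusions = exclusions),
            class = "wuli_report")
}

#' @export
print.wuli_report <- function(x, ...) {
  cat(sprintf("<wuli_report: %d survivors, %d excluded (%d violations)>\n",
              nrow(x$survivors$members),
              length(unique(x$exclusions$id)),
              nrow(x$exclusions)))
  invisible(x)
}
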