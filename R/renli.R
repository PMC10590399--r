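#' Construct a fuzzy decision matrix from linguistic terms
#'
#' @param terms Character matrix (alternatives x criteria) of linguistic
#'   term labels, with dimnames, or a data frame of term columns.
#' @param alternatives Data frame (`id`, `name`, `category`) or character
#'   vector of ids, one per row.
#' @param criteria Character vector of criterion ids, one per column.
#' @param scale A [linguistic_scale()].
#' @return Object of class `fuzzy_decision_matrix`: list with `cells`
#'   (list of rows of [it2fs()]), `terms` (provenance), `alternatives`,
#'   `criteria`, `scale`.
#' @export
fuzzy_decision_matrix <- function(terms, alternatives, criteria,
                                  scale = linguistic_scale()) {
  terms <- as.matrix(terms)
  m <- nrow(terms); n <- ncol(terms)
  stopifnot(m >= 1, n >= 1)
  if (is.character(alternatives)) {
    alternatives <- data.frame(id = alternatives, name = alternatives,
                               category = NA_character_,
                               stringsAsFactors = FALSE)
  }
  if (is.null(alternatives$category)) alternatives$category <- NA_character_
  stopifnot(nrow(alternatives) == m, length(criteria) == n)
  cells <- vector("list", m)
  for (i in seq_len(m)) {
    row <- vector("list", n)
    for (j in seq_len(n)) {
      t_ <- terms[i, j]
      if (is.na(t_) || !nzchar(t_)) {
        stop(sprintf("empty judgment at row %d ('%s'), column '%s'",
                     i, alternatives$id[i], criteria[j]), call. = FALSE)
      }
      if (!t_ %in% names(scale)) {
        stop(sprintf(
          "unknown linguistic term '%s' at row %d ('%s'), column '%s'; valid terms: %s",
          t_, i, alternatives$id[i], criteria[j],
          paste(names(scale), collapse = ", ")), call. = FALSE)
      }
      row[[j]] <- scale[[t_]]
    }
    cells[[i]] <- row
  }
  dimnames(terms) <- list(alternatives$id, criteria)
  structure(list(cells = cells, terms = terms,
                 alternatives = alternatives[, c("id", "name", "category")],
                 criteria = criteria, scale = scale),
            class = "fuzzy_decision_matrix")
}

#' @export
print.fuzzy_decision_matrix <- function(x, ...) {
  cat(sprintf("<fuzzy_decision_matrix: %d alternatives x %d criteria>\n",
              length(x$cells), length(x$criteria)))
  if (!is.null(x$terms)) print(x$terms)
  invisible(x)
}

#' Read a linguistic judgment matrix from CSV
#'
#' Expects header `id,name[,category],<criterion-id>,...` with each cell a
#' term of `scale` (e.g. `VL` ... `VH`).
#'
#' @param path CSV file path.
#' @param criteria Optional criterion ids to select (default: all columns
#'   after the identity columns, in file order).
#' @param scale A [linguistic_scale()].
#' @return A [fuzzy_decision_matrix()].
#' @export
read_linguistic_matrix <- function(path, criteria = NULL,
                                   scale = linguistic_scale()) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 encoding = "UTF-8")
  if (!"id" %in% names(df)) stop("missing 'id' column in ", path, call. = FALSE)
  if (!"name" %in% names(df)) df$name <- df$id
  if (!"category" %in% names(df)) df$category <- NA_character_
  idcols <- c("id", "name", "category")
  if (is.null(criteria)) criteria <- setdiff(names(df), idcols)
  missing <- setdiff(criteria, names(df))
  if (length(missing)) {
    stop("judgment file lacks criterion column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fuzzy_decision_matrix(as.matrix(df[, criteria, drop = FALSE]),
                        alternatives = df[, idcols],
                        criteria = criteria, scale = scale)
}

#' Normalise a fuzzy decision matrix
#'
#' Rescales each criterion column onto a common dimensionless range.
#' For a benefit criterion, every vertex of every element in the column is
#' divided by the column's largest upper-trapezoid right endpoint
#' `a* = max_i a4u`. For a cost criterion, the element is inverted:
#' vertices become `(a-/a4, a-/a3, a-/a2, a-/a1)` per trapezoid with
#' `a- = min_i a1u` over the column (all vertices must be positive).
#' Heights are unchanged and the trapezoid ordering/containment
#' invariants are preserved.
#'
#' Denominators are computed per criterion, over alternatives: elements
#' are compared against the best value in their column, which is what
#' makes the normalised columns comparable across criteria.
#'
#' @param fm A [fuzzy_decision_matrix()].
#' @param directions Character vector (`"benefit"`/`"cost"`), recycled
#'   over columns.
#' @return A [fuzzy_decision_matrix()] with normalised cells (provenance
#'   terms retained).
#' @export
normalize_fuzzy_matrix <- function(fm, directions = "benefit") {
  stopifnot(inherits(fm, "fuzzy_decision_matrix"))
  m <- length(fm$cells); n <- length(fm$criteria)
  directions <- rep_len(match.arg(directions, c("benefit", "cost"),
                                  several.ok = TRUE), n)
  out <- fm
  for (j in seq_len(n)) {
    col <- lapply(seq_len(m), function(i) fm$cells[[i]][[j]])
    if (directions[j] == "benefit") {
      astar <- max(vapply(col, function(v) v$upper[4], numeric(1)))
      if (astar <= 0) {
        stop("benefit column '", fm$criteria[j],
             "' has nonpositive maximum; cannot normalise", call. = FALSE)
      }
      for (i in seq_len(m)) {
        v <- col[[i]]
        out$cells[[i]][[j]] <- it2fs(c(v$upper[1:4] / astar, v$upper[5:6]),
                                     c(v$lower[1:4] / astar, v$lower[5:6]))
      }
    } else {
      if (any(vapply(col, function(v) min(v$upper[1:4], v$lower[1:4]),
                     numeric(1)) <= 0)) {
        stop("cost column '", fm$criteria[j],
             "' contains nonpositive vertices; reciprocal normalisation ",
             "undefined", call. = FALSE)
      }
      aminus <- min(vapply(col, function(v) v$upper[1], numeric(1)))
      for (i in seq_len(m)) {
        v <- col[[i]]
        out$cells[[i]][[j]] <- it2fs(c(aminus / rev(v$upper[1:4]),
                                       v$upper[5:6]),
                                     c(aminus / rev(v$lower[1:4]),
                                       v$lower[5:6]))
      }
    }
  }
  out
}

#' Interval type-2 fuzzy TOPSIS
#'
#' The Renli-stage ranking engine. Pipeline: normalise the fuzzy judgment
#' matrix ([normalize_fuzzy_matrix()]), scale each column's elements by
#' its criterion weight ([scale_it2fs()]), defuzzify every weighted
#' element to its ranking value ([rank_value()]), take per-criterion
#' maxima/minima of the ranking values as positive/negative ideals,
#' compute Euclidean distances of each alternative's ranking-value row to
#' the two ideal vectors, and rank by descending relative closeness
#' `E = d- / (d+ + d-)`.
#'
#' A criterion on which all alternatives agree contributes zero to both
#' distances and is allowed; if every criterion is degenerate the input
#' cannot be ranked and an error is raised. Exact closeness ties are
#' broken by the supplied Shili closeness (higher wins), else by input
#' order, and flagged in the `tied` column.
#'
#' @param fm A [fuzzy_decision_matrix()] (raw judgments; normalisation is
#'   applied internally).
#' @param weights Named weight vector over `fm$criteria` (e.g. from
#'   [solve_bwm()]).
#' @param directions Benefit/cost direction per criterion (recycled).
#' @param shili_tiebreak Optional `topsis_result` from the Shili stage
#'   used to break exact closeness ties.
#' @param hw Heights-term variant passed to [rank_value()].
#' @return Object of class `fuzzy_topsis_result`: data frame `id`, `name`,
#'   `d_plus`, `d_minus`, `closeness`, `rank`, `tied`, with attributes
#'   `rank_matrix` (defuzzified weighted values), `ideal_plus`,
#'   `ideal_minus`.
#' @examples
#' fm <- fuzzy_decision_matrix(
#'   rbind(c("VH", "H"), c("L", "ML"), c("M", "M")),
#'   alternatives = c("a", "b", "c"), criteria = c("op", "eff"))
#' it2f_topsis(fm, c(op = 0.6, eff = 0.4))
#' @export
it2f_topsis <- function(fm, weights, directions = "benefit",
                        shili_tiebreak = NULL,
                        hw = c("heights", "vertex")) {
  stopifnot(inherits(fm, "fuzzy_decision_matrix"))
  hw <- match.arg(hw)
  m <- length(fm$cells); n <- length(fm$criteria)
  if (m < 2) stop("ranking needs at least two alternatives", call. = FALSE)
  w <- weight_vector(weights, criteria = fm$criteria)
  R <- normalize_fuzzy_matrix(fm, directions)
  RM <- matrix(NA_real_, m, n, dimnames = list(fm$alternatives$id,
                                               fm$criteria))
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      v <- scale_it2fs(w[[j]], R$cells[[i]][[j]])
      RM[i, j] <- rank_value(v, hw = hw)$rank_value
    }
  }
  vp <- apply(RM, 2, max)
  vm <- apply(RM, 2, min)
  if (all(vp == vm)) {
    stop("degenerate input: every criterion rates all alternatives equally",
         call. = FALSE)
  }
  dp <- sqrt(rowSums(sweep(RM, 2, vp)^2))
  dm_ <- sqrt(rowSums(sweep(RM, 2, vm)^2))
  closeness <- dm_ / (dp + dm_)
  tb <- rep(0, m)
  if (!is.null(shili_tiebreak)) {
    idx <- match(fm$alternatives$id, shili_tiebreak$id)
    tb <- ifelse(is.na(idx), 0, shili_tiebreak$closeness[idx])
  }
  ord <- order(-closeness, -tb)
  rank <- integer(m); rank[ord] <- seq_len(m)
  tied <- duplicated(closeness) | duplicated(closeness, fromLast = TRUE)
  out <- data.frame(id = fm$alternatives$id, name = fm$alternatives$name,
                    d_plus = unname(dp), d_minus = unname(dm_),
                    closeness = unname(closeness), rank = rank, tied = tied,
                    stringsAsFactors = FALSE)
  structure(out, rank_matrix = RM, ideal_plus = vp, ideal_minus = vm,
            hw = hw, class = c("fuzzy_topsis_result", "data.frame"))
}
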