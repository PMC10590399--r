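#' Min-max normalisation of a crisp decision matrix
#'
#' Benefit columns are mapped affinely so the column maximum becomes 1 and
#' the minimum 0; cost columns are reflected (minimum becomes 1). The
#' result is invariant to any positive affine rescaling `b -> a*b + c`
#' (`a > 0`) of a raw column. A constant column carries no discriminating
#' information: it is set to all zeros with a warning (and subsequently
#' receives zero entropy weight) rather than crashing on the zero range.
#'
#' @param dm A [decision_matrix()] with at least two alternatives. Only
#'   non-Wuli columns are normalised; Wuli columns, if present, are
#'   dropped (they belong to stage 1).
#' @return Object of class `normalized_matrix`: like a decision matrix but
#'   with all values in \[0, 1\]; constant columns flagged in
#'   `attr(, "constant_columns")`.
#' @examples
#' dm <- decision_matrix(matrix(c(10, 20, 30, 3, 2, 1), ncol = 2),
#'   alternatives = c("a", "b", "c"),
#'   specs = list(criterion_spec("cap", stage = "shili"),
#'                criterion_spec("dist", stage = "shili",
#'                               direction = "cost")))
#' minmax_normalize(dm)$values
#' @export
minmax_normalize <- function(dm) {
  stopifnot(inherits(dm, "decision_matrix"))
  keep <- dm$specs$stage != "wuli"
  st <- dm$specs[keep, , drop = FALSE]
  vals <- dm$values[, st$id, drop = FALSE]
  if (nrow(vals) < 2) {
    stop("normalisation needs at least two alternatives", call. = FALSE)
  }
  lo <- apply(vals, 2, min)
  hi <- apply(vals, 2, max)
  rng <- hi - lo
  const <- rng == 0
  out <- vals
  for (j in seq_len(ncol(vals))) {
    if (const[j]) {
      out[, j] <- 0
    } else if (st$direction[j] == "benefit") {
      out[, j] <- (vals[, j] - lo[j]) / rng[j]
    } else {
      out[, j] <- (hi[j] - vals[, j]) / rng[j]
    }
  }
  if (any(const)) {
    warning("constant column(s) normalised to zero: ",
            paste(st$id[const], collapse = ", "), call. = FALSE)
  }
  structure(list(values = out, alternatives = dm$alternatives, specs = st),
            class = c("normalized_matrix", "decision_matrix"),
            constant_columns = st$id[const])
}

#' Entropy-method criterion weights
#'
#' Objective weights from the dispersion of each (normalised) criterion
#' column: column shares `p_ij = f_ij / sum_i f_ij`, Shannon entropy
#' `e_j = -(1/ln m) * sum_i p_ij ln p_ij` (with `0 ln 0 := 0`), divergence
#' `d_j = 1 - e_j`, and weights `w_j = d_j / sum_j d_j`. Columns with no
#' discriminating power (zero column sum, or uniform shares) get weight 0;
#' a more dispersed column always receives a larger weight than a more
#' uniform one.
#'
#' @param nm A `normalized_matrix` from [minmax_normalize()] (any
#'   nonnegative matrix-like object with `values` works).
#' @return Named weight vector summing to 1, ordered like the columns.
#' @examples
#' dm <- decision_matrix(matrix(c(0, 5, 10, 9, 10, 9.5), ncol = 2),
#'   alternatives = c("a", "b", "c"),
#'   specs = list(criterion_spec("c1"), criterion_spec("c2")))
#' entropy_weights(minmax_normalize(dm))
#' @export
entropy_weights <- function(nm) {
  vals <- if (is.matrix(nm)) nm else nm$values
  stopifnot(is.numeric(vals), nrow(vals) >= 2)
  if (any(vals < 0)) stop("entropy weighting needs nonnegative values",
                          call. = FALSE)
  m <- nrow(vals)
  ej <- apply(vals, 2, function(col) {
    s <- sum(col)
    if (s == 0) return(1)  # no information -> entropy treated as maximal
    p <- col / s
    p <- p[p > 0]
    -sum(p * log(p)) / log(m)
  })
  dj <- 1 - ej
  # guard tiny negatives from rounding
  dj[dj < 0 & dj > -1e-12] <- 0
  if (all(dj == 0)) {
    stop("degenerate input: no column discriminates between alternatives",
         call. = FALSE)
  }
  w <- dj / sum(dj)
  names(w) <- colnames(vals)
  w
}

#' Crisp TOPSIS ranking
#'
#' Weights the normalised matrix (`h_ij = w_j f_ij`), takes the
#' column-wise maxima/minima as the positive/negative ideal solutions,
#' computes each alternative's Euclidean distances `d+`, `d-` to the two
#' ideals, and ranks by descending relative closeness
#' `E = d- / (d+ + d-)`. Ties on closeness are broken by input order and
#' reported via the `tied` column.
#'
#' @param nm A `normalized_matrix` (values in \[0, 1\]).
#' @param weights Named weight vector covering the matrix columns (see
#'   [weight_vector()]); typically from [entropy_weights()].
#' @return Object of class `topsis_result`: a data frame with columns
#'   `id`, `name`, `d_plus`, `d_minus`, `closeness`, `rank`, `tied`, in
#'   input order, with the ideal vectors in `attr(, "ideal_plus")` /
#'   `attr(, "ideal_minus")`.
#' @examples
#' dm <- decision_matrix(matrix(c(10, 20, 30, 1, 3, 2), ncol = 2),
#'   alternatives = c("a", "b", "c"),
#'   specs = list(criterion_spec("c1"), criterion_spec("c2")))
#' nm <- minmax_normalize(dm)
#' topsis_rank(nm, entropy_weights(nm))
#' @export
topsis_rank <- function(nm, weights) {
  vals <- if (is.matrix(nm)) nm else nm$values
  stopifnot(is.numeric(vals), nrow(vals) >= 2)
  w <- weight_vector(weights, criteria = colnames(vals))
  H <- sweep(vals, 2, w, `*`)
  hp <- apply(H, 2, max)
  hm <- apply(H, 2, min)
  dp <- sqrt(rowSums(sweep(H, 2, hp)^2))
  dm_ <- sqrt(rowSums(sweep(H, 2, hm)^2))
  tot <- dp + dm_
  if (all(tot == 0)) {
    stop("degenerate input: all alternatives identical", call. = FALSE)
  }
  closeness <- ifelse(tot == 0, 0.5, dm_ / tot)
  # descending closeness, stable in input order
  ord <- order(-closeness)
  rank <- integer(length(closeness))
  rank[ord] <- seq_along(ord)
  tied <- duplicated(closeness) | duplicated(closeness, fromLast = TRUE)
  alts <- if (is.matrix(nm)) {
    ids <- rownames(vals)
    if (is.null(ids)) ids <- paste0("alt", seq_len(nrow(vals)))
    data.frame(id = ids, name = ids, stringsAsFactors = FALSE)
  } else {
    nm$alternatives
  }
  out <- data.frame(id = alts$id, name = alts$name,
                    d_plus = unname(dp), d_minus = unname(dm_),
                    closeness = unname(closeness), rank = rank,
                    tied = tied, stringsAsFactors = FALSE)
  structure(out, ideal_plus = hp, ideal_minus = hm,
            class = c("topsis_result", "data.frame"))
}

#' Retain the top fraction of a ranking
#'
#' Keeps the best `ceiling(fraction * m)` alternatives by rank. If a
#' closeness tie straddles the cut, every tied alternative is kept: a
#' candidate indistinguishable from a kept one is never discarded.
#'
#' @param result A `topsis_result` (or any data frame with `id`, `name`,
#'   `closeness`, `rank`).
#' @param fraction Fraction in (0, 1\] of alternatives to retain.
#' @param stage_tag Stage tag for the returned set (default
#'   `"post_shili"`).
#' @return An [alternative_set()] in rank order.
#' @export
retain_top_fraction <- function(result, fraction = 0.5,
                                stage_tag = "post_shili") {
  stopifnot(is.data.frame(result), is.numeric(fraction),
            length(fraction) == 1L, fraction > 0, fraction <= 1)
  m <- nrow(result)
  k <- ceiling(fraction * m)
  ord <- result[order(result$rank), , drop = FALSE]
  if (k < m) {
    cut_close <- ord$closeness[k]
    while (k < m && ord$closeness[k + 1L] == cut_close) k <- k + 1L
  }
  kept <- ord[seq_len(k), , drop = FALSE]
  members <- data.frame(id = kept$id, name = kept$name,
                        category = if (!is.null(kept$category)) {
                          kept$category
                        } else {
                          NA_character_
                        },
                        stringsAsFactors = FALSE)
  alternative_set(members, stage_tag = stage_tag)
}
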