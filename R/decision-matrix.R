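#' Construct a crisp decision matrix
#'
#' Rows are candidate facilities (alternatives), columns are criteria.
#' This is the container consumed by the Wuli screen and the Shili stage.
#'
#' @param values Numeric matrix (or object coercible to one), one row per
#'   alternative and one column per criterion, no missing cells.
#' @param alternatives Data frame with columns `id`, `name` and optionally
#'   `category`, one row per matrix row; or a character vector of ids.
#' @param specs List of [criterion_spec()] objects, one per matrix column,
#'   in column order.
#' @return An object of class `decision_matrix` with elements `values`
#'   (dimnamed numeric matrix), `alternatives` (data frame) and `specs`
#'   (data frame, one row per criterion).
#' @examples
#' dm <- decision_matrix(
#'   matrix(c(25, 19, 22, 1200, 800, 950), ncol = 2),
#'   alternatives = c("a", "b", "c"),
#'   specs = list(
#'     criterion_spec("greening", stage = "wuli",
#'                    wuli_threshold = 20, wuli_comparator = "ge"),
#'     criterion_spec("beds", stage = "shili")))
#' dm
#' @export
decision_matrix <- function(values, alternatives, specs) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.character(alternatives)) {
    alternatives <- data.frame(id = alternatives, name = alternatives,
                               category = NA_character_,
                               stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(alternatives),
            all(c("id", "name") %in% names(alternatives)))
  if (is.null(alternatives$category)) alternatives$category <- NA_character_
  alternatives <- alternatives[, c("id", "name", "category")]
  if (anyDuplicated(alternatives$id)) {
    stop("alternative ids must be unique", call. = FALSE)
  }
  st <- spec_table(specs)
  if (nrow(alternatives) != nrow(values)) {
    stop("`alternatives` has ", nrow(alternatives), " rows but `values` has ",
         nrow(values), call. = FALSE)
  }
  if (nrow(st) != ncol(values)) {
    stop(nrow(st), " criteria but ", ncol(values), " value columns",
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("decision matrix contains missing or non-finite cells", call. = FALSE)
  }
  dimnames(values) <- list(alternatives$id, st$id)
  structure(list(values = values, alternatives = alternatives, specs = st),
            class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("<decision_matrix: %d alternatives x %d criteria (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$specs$stage), collapse = "+")))
  print(head(x$values, 10))
  if (nrow(x$values) > 10) cat("...\n")
  invisible(x)
}

# Subset a decision matrix to the given alternative ids, keeping file order.
subset_matrix <- function(dm, ids) {
  keep <- dm$alternatives$id %in% ids
  out <- dm
  out$values <- dm$values[keep, , drop = FALSE]
  out$alternatives <- dm$alternatives[keep, , drop = FALSE]
  rownames(out$alternatives) <- NULL
  out
}

#' Create a staged alternative set
#'
#' Tracks which candidates are alive at each stage boundary. Sets carry a
#' stage tag; [check_containment()] enforces the chain
#' initial ⊇ post_wuli ⊇ post_shili ⊇ final.
#'
#' @param alternatives Data frame with columns `id`, `name`, `category`
#'   (or a character vector of ids).
#' @param stage_tag One of `"initial"`, `"post_wuli"`, `"post_shili"`,
#'   `"final"`.
#' @return Object of class `alternative_set`.
#' @export
alternative_set <- function(alternatives,
                            stage_tag = c("initial", "post_wuli",
                                          "post_shili", "final")) {
  stage_tag <- match.arg(stage_tag)
  if (is.character(alternatives)) {
    alternatives <- data.frame(id = alternatives, name = alternatives,
                               category = NA_character_,
                               stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(alternatives), "id" %in% names(alternatives))
  if (is.null(alternatives$name)) alternatives$name <- alternatives$id
  if (is.null(alternatives$category)) alternatives$category <- NA_character_
  if (anyDuplicated(alternatives$id)) {
    stop("alternative ids must be unique", call. = FALSE)
  }
  rownames(alternatives) <- NULL
  structure(list(stage_tag = stage_tag,
                 members = alternatives[, c("id", "name", "category")]),
            class = "alternative_set")
}

#' @export
print.alternative_set <- function(x, ...) {
  cat(sprintf("<alternative_set [%s]: %d members>\n",
              x$stage_tag, nrow(x$members)))
  invisible(x)
}

#' Check the stage containment chain of two alternative sets
#'
#' @param inner,outer `alternative_set` objects; `inner` must be a subset
#'   of `outer` (by id) and at the same or a later stage.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
check_containment <- function(inner, outer) {
  stopifnot(inherits(inner, "alternative_set"),
            inherits(outer, "alternative_set"))
  stages <- c(initial = 1L, post_wuli = 2L, post_shili = 3L, final = 4L)
  if (stages[[inner$stage_tag]] < stages[[outer$stage_tag]]) {
    stop("stage '", inner$stage_tag, "' precedes '", outer$stage_tag, "'",
         call. = FALSE)
  }
  extra <- setdiff(inner$members$id, outer$members$id)
  if (length(extra)) {
    stop("alternatives not present upstream: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a crisp decision matrix from CSV
#'
#' Expects a UTF-8, comma-separated file with header
#' `id,name[,category],<criterion-id>,...`. Criterion columns are matched
#' by name against `specs` and reordered to the spec order; row order
#' follows the file.
#'
#' @param path CSV file path.
#' @param specs List of [criterion_spec()] objects naming the required
#'   criterion columns.
#' @return A [decision_matrix()].
#' @export
read_decision_matrix <- function(path, specs) {
  st <- spec_table(specs)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 encoding = "UTF-8")
  if (!"id" %in% names(df)) stop("missing 'id' column in ", path, call. = FALSE)
  if (!"name" %in% names(df)) df$name <- df$id
  if (!"category" %in% names(df)) df$category <- NA_character_
  missing <- setdiff(st$id, names(df))
  if (length(missing)) {
    stop("matrix file ", path, " lacks criterion column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- df[, st$id, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                     bad[1], st$id[j], path), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  decision_matrix(as.matrix(vals),
                  alternatives = df[, c("id", "name", "category")],
                  specs = specs)
}

#' Write a crisp decision matrix to CSV
#'
#' Inverse of [read_decision_matrix()]: values are printed with full
#' double precision so that a read/write round trip reproduces the matrix
#' to better than `1e-12` relative error.
#'
#' @param dm A [decision_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "decision_matrix"))
  df <- cbind(dm$alternatives,
              as.data.frame(dm$values, check.names = FALSE))
  # full precision: format numerics via 17 significant digits
  for (j in seq_len(ncol(df))) {
    if (is.numeric(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 17,
                                                format = "g")
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a ranking table to CSV
#'
#' Writes any ranking result carrying `id`, `closeness` and `rank` columns
#' (e.g. [topsis_rank()] or [it2f_topsis()] output), sorted by rank.
#'
#' @param result Data frame with at least `id`, `closeness`, `rank`.
#' @param path Output CSV path.
#' @param digits Decimals used to render `closeness` (default 9, the
#'   precision of the published final ranking table). Rendering precision
#'   never feeds back into computation.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, path, digits = 9) {
  stopifnot(is.data.frame(result),
            all(c("id", "closeness", "rank") %in% names(result)))
  out <- as.data.frame(result)[order(result$rank), , drop = FALSE]
  out$closeness <- formatC(out$closeness, format = "f", digits = digits)
  write.csv(out, path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}
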