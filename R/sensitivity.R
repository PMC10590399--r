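#' Run weight-perturbation sensitivity cases
#'
#' Re-runs the weighting-and-ranking portion of a stage under alternative
#' criterion weight vectors, holding everything upstream (normalisation,
#' judgments, tie-break data) fixed, and reports rank shifts against the
#' baseline weights. Case weight rows that do not sum to one are
#' renormalised with a warning.
#'
#' @param cases Data frame with a `case_id` column (labels) and one
#'   numeric column per criterion, one row per case (e.g. from
#'   [shanghai_sensitivity_cases()]).
#' @param baseline_weights Named weight vector of the main pipeline
#'   (entropy weights for Shili, BWM weights for Renli).
#' @param rank_fun Function taking a weight vector and returning a
#'   ranking data frame with columns `id` and `rank` (e.g. a closure over
#'   [topsis_rank()] or [it2f_topsis()]).
#' @return Object of class `sensitivity_report`: list with
#'   \describe{
#'     \item{rankings}{Long data frame `(case_id, id, closeness, rank)`
#'       including the `"baseline"` case.}
#'     \item{shifts}{Data frame `(case_id, id, shift)` of signed rank
#'       differences versus baseline.}
#'     \item{baseline}{The baseline ranking.}
#'   }
#' @export
run_sensitivity_cases <- function(cases, baseline_weights, rank_fun) {
  stopifnot(is.data.frame(cases), "case_id" %in% names(cases))
  wcols <- setdiff(names(cases), "case_id")
  stopifnot(length(wcols) >= 1)
  baseline_weights <- weight_vector(baseline_weights, criteria = wcols)
  base <- rank_fun(baseline_weights)
  stopifnot(all(c("id", "rank") %in% names(base)))
  runs <- list(data.frame(case_id = "baseline", id = base$id,
                          closeness = base$closeness, rank = base$rank,
                          stringsAsFactors = FALSE))
  for (r in seq_len(nrow(cases))) {
    w <- unlist(cases[r, wcols])
    s <- sum(w)
    if (abs(s - 1) > 1e-9) {
      warning(sprintf("case %s weights sum to %.4f; renormalizing",
                      cases$case_id[r], s), call. = FALSE)
      w <- w / s
    }
    res <- rank_fun(weight_vector(w))
    runs[[length(runs) + 1L]] <- data.frame(
      case_id = as.character(cases$case_id[r]), id = res$id,
      closeness = res$closeness, rank = res$rank, stringsAsFactors = FALSE)
  }
  rankings <- do.call(rbind, runs)
  base_rank <- setNames(base$rank, base$id)
  shifts <- data.frame(case_id = rankings$case_id, id = rankings$id,
                       shift = rankings$rank - base_rank[rankings$id],
                       stringsAsFactors = FALSE)
  rownames(shifts) <- NULL
  structure(list(rankings = rankings, shifts = shifts, baseline = base),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  ncases <- length(unique(x$rankings$case_id)) - 1L
  cat(sprintf("<sensitivity_report: %d cases x %d alternatives, max |shift| %d>\n",
              ncases, nrow(x$baseline), max(abs(x$shifts$shift))))
  invisible(x)
}

#' Summarise rank shifts and top/bottom stability
#'
#' @param report A `sensitivity_report` from [run_sensitivity_cases()].
#' @param k Size of the head and tail sets whose stability is assessed.
#' @return List with `per_alternative` (data frame `id`, `max_abs_shift`),
#'   `top_k_stable` and `bottom_k_stable` (logical: the identity of the
#'   best/worst `k` alternatives is identical in every case), and `k`.
#' @export
rank_shift_stats <- function(report, k = 3) {
  stopifnot(inherits(report, "sensitivity_report"))
  sh <- report$shifts
  per_alt <- aggregate(abs(sh$shift), by = list(id = sh$id), FUN = max)
  names(per_alt)[2] <- "max_abs_shift"
  m <- nrow(report$baseline)
  k <- min(k, m)
  sets <- split(report$rankings, report$rankings$case_id)
  topsets <- lapply(sets, function(d) sort(d$id[d$rank <= k]))
  botsets <- lapply(sets, function(d) sort(d$id[d$rank > m - k]))
  same <- function(l) all(vapply(l, identical, logical(1), l[[1]]))
  list(per_alternative = per_alt,
       top_k_stable = same(topsets),
       bottom_k_stable = same(botsets),
       k = k)
}

#' Published sensitivity-analysis weight cases
#'
#' The ten alternative weight vectors per stage used in the published
#' Shanghai case study's sensitivity analysis, shipped as plain-text
#' fixtures exactly as printed. Shili columns: air, rail and road
#' accessibility, distance to hospital, space scale. Renli columns:
#' operability, post-pandemic recovery, operational effect,
#' implementation efficiency.
#'
#' @param stage `"shili"` or `"renli"`.
#' @return Data frame with `case_id` and one weight column per criterion.
#' @export
shanghai_sensitivity_cases <- function(stage = c("shili", "renli")) {
  stage <- match.arg(stage)
  path <- system.file("extdata", "shanghai",
                      paste0("sensitivity_cases_", stage, ".csv"),
                      package = "wsrsite", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$case_id <- as.character(df$case_id)
  df
}
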