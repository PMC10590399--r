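#' Pipeline configuration
#'
#' Bundles the options of the three-stage workflow. The canonical stage
#' order is Wuli, then Shili, then Renli; other permutations are
#' supported mechanically (each stage operates on the set left by its
#' predecessor) but the staged screening logic of the methodology
#' presumes the default order.
#'
#' @param stage_order Permutation of `c("wuli", "shili", "renli")`.
#' @param retain_fraction Fraction of the Shili ranking retained for the
#'   next stage, in (0, 1].
#' @param renli_weights_source `"bwm"` (solve comparison vectors) or
#'   `"explicit"` (weights supplied directly).
#' @param rank_hw Heights-term variant of [rank_value()].
#' @param linguistic_scale_path Optional YAML overriding the seven-term
#'   scale.
#' @param precision Decimals used when rendering closeness in output
#'   files.
#' @param seed Integer seed forwarded to any synthetic steps.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(stage_order = c("wuli", "shili", "renli"),
                            retain_fraction = 0.5,
                            renli_weights_source = c("explicit", "bwm"),
                            rank_hw = c("heights", "vertex"),
                            linguistic_scale_path = NULL,
                            precision = 9,
                            seed = 1L) {
  renli_weights_source <- match.arg(renli_weights_source)
  rank_hw <- match.arg(rank_hw)
  structure(list(stage_order = stage_order,
                 retain_fraction = retain_fraction,
                 renli_weights_source = renli_weights_source,
                 rank_hw = rank_hw,
                 linguistic_scale_path = linguistic_scale_path,
                 precision = precision, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns findings instead of throwing, so a driver can report all
#' problems at once. Criteria may be supplied as raw lists (e.g. parsed
#' YAML) or [criterion_spec()] objects.
#'
#' @param config A [pipeline_config()] or a raw list with the same
#'   fields.
#' @param criteria Optional list of criteria to validate alongside.
#' @return Data frame `(level, field, message)`; zero rows when valid.
#' @export
validate_config <- function(config, criteria = NULL) {
  findings <- list()
  add <- function(level, field, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  # absent fields fall back to pipeline_config() defaults; only present
  # but invalid values are findings
  so <- config$stage_order
  if (!is.null(so) && (length(so) != 3L ||
                       !setequal(so, c("wuli", "shili", "renli")))) {
    add("error", "stage_order",
        "must be a permutation of wuli, shili, renli")
  }
  rf <- config$retain_fraction
  if (!is.null(rf) && (!is.numeric(rf) || length(rf) != 1L ||
                       !is.finite(rf) || rf <= 0 || rf > 1)) {
    add("error", "retain_fraction", "must lie in (0, 1]")
  }
  if (!is.null(config$renli_weights_source) &&
      !config$renli_weights_source %in% c("bwm", "explicit")) {
    add("error", "renli_weights_source", "must be 'bwm' or 'explicit'")
  }
  if (!is.null(config$rank_hw)) {
    if (!config$rank_hw %in% c("heights", "vertex")) {
      add("error", "rank_hw", "must be 'heights' or 'vertex'")
    } else if (config$rank_hw == "vertex") {
      add("warning", "rank_hw",
          "non-default heights variant 'vertex' selected")
    }
  }
  for (cr in criteria) {
    cl <- if (inherits(cr, "criterion_spec")) unclass(cr) else cr
    id <- if (!is.null(cl$id)) cl$id else "<unnamed>"
    if (is.null(cl$stage) || !cl$stage %in% c("wuli", "shili", "renli")) {
      add("error", paste0("criteria.", id), "unknown stage")
      next
    }
    has_thr <- !is.null(cl$wuli_threshold) && !is.na(cl$wuli_threshold)
    if (cl$stage == "wuli" && !has_thr) {
      add("error", paste0("criteria.", id),
          "wuli criterion lacks threshold/comparator")
    }
    if (cl$stage != "wuli" && has_thr) {
      add("error", paste0("criteria.", id),
          "non-wuli criterion carries a wuli threshold")
    }
  }
  if (length(findings)) {
    do.call(rbind, findings)
  } else {
    data.frame(level = character(), field = character(),
               message = character(), stringsAsFactors = FALSE)
  }
}

#' Run the full three-stage pipeline on in-memory inputs
#'
#' Executes the staged workflow: hard-constraint screening, entropy-
#' weighted TOPSIS ranking with top-fraction retention, and interval
#' type-2 fuzzy TOPSIS over the retained candidates, with Shili closeness
#' as the Renli tie-breaker. Containment of every stage's survivor set in
#' its predecessor's is asserted at each boundary.
#'
#' @param matrix A [decision_matrix()] holding the Wuli attribute columns
#'   and the Shili criterion columns for all initial candidates.
#' @param renli A [fuzzy_decision_matrix()] of linguistic judgments
#'   covering at least the candidates that reach the Renli stage.
#' @param renli_weights Named weight vector over the Renli criteria, or a
#'   [bwm_input()] (or list of them) solved via [solve_bwm()] when
#'   `config$renli_weights_source == "bwm"`.
#' @param config A [pipeline_config()].
#' @return Object of class `staged_report`: list with `initial`, `wuli`
#'   (a `wuli_report`), `shili` (list `weights`, `ranking`, `retained`),
#'   `renli` (list `weights`, `ranking`), `final` ([alternative_set()] in
#'   final rank order), `warnings` (per-stage character vectors) and
#'   `config`.
#' @examples
#' case <- generate_case(synthetic_spec(n_facilities = 8, seed = 7,
#'                                      noise_sd = 0))
#' rep <- run_pipeline(case$matrix, case$renli,
#'                     c(operability = 0.4, recovery = 0.1,
#'                       operational_effect = 0.2,
#'                       implementation_efficiency = 0.3))
#' rep$final$members$id
#' @export
run_pipeline <- function(matrix, renli, renli_weights,
                         config = pipeline_config()) {
  stopifnot(inherits(matrix, "decision_matrix"),
            inherits(config, "pipeline_config"))
  cf <- validate_config(config)
  if (any(cf$level == "error")) {
    stop("invalid pipeline config: ",
         paste(cf$message[cf$level == "error"], collapse = "; "),
         call. = FALSE)
  }
  warnings_by_stage <- list()
  note <- function(stage, w) {
    warnings_by_stage[[stage]] <<- c(warnings_by_stage[[stage]], w)
  }
  initial <- alternative_set(matrix$alternatives, stage_tag = "initial")
  current <- initial
  wuli_out <- NULL; shili_out <- NULL; renli_out <- NULL
  final_ranking <- NULL

  for (stage in config$stage_order) {
    if (stage == "wuli") {
      dm <- subset_matrix(matrix, current$members$id)
      wuli_out <- withCallingHandlers(
        apply_hard_constraints(dm),
        warning = function(w) {
          note("wuli", conditionMessage(w)); invokeRestart("muffleWarning")
        })
      check_containment(wuli_out$survivors, current)
      current <- wuli_out$survivors
      if (nrow(current$members) == 0) {
        stop("wuli stage left no survivors", call. = FALSE)
      }
    } else if (stage == "shili") {
      dm <- subset_matrix(matrix, current$members$id)
      nm <- withCallingHandlers(
        minmax_normalize(dm),
        warning = function(w) {
          note("shili", conditionMessage(w)); invokeRestart("muffleWarning")
        })
      w_s <- entropy_weights(nm)
      ranking <- topsis_rank(nm, w_s)
      retained <- retain_top_fraction(ranking, config$retain_fraction)
      retained$members <- dm$alternatives[
        match(retained$members$id, dm$alternatives$id), , drop = FALSE]
      rownames(retained$members) <- NULL
      check_containment(retained, current)
      shili_out <- list(weights = w_s, ranking = ranking,
                        retained = retained)
      current <- retained
    } else { # renli
      stopifnot(inherits(renli, "fuzzy_decision_matrix"))
      missing <- setdiff(current$members$id, renli$alternatives$id)
      if (length(missing)) {
        stop("no renli judgments for: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      keep <- renli$alternatives$id %in% current$members$id
      sub <- renli
      sub$cells <- renli$cells[keep]
      sub$alternatives <- renli$alternatives[keep, , drop = FALSE]
      sub$terms <- renli$terms[keep, , drop = FALSE]
      w_r <- if (inherits(renli_weights, "bwm_input") ||
                 (is.list(renli_weights) &&
                  !is.numeric(renli_weights))) {
        solve_bwm(renli_weights)$weights
      } else {
        weight_vector(renli_weights, criteria = renli$criteria)
      }
      tiebreak <- if (!is.null(shili_out)) shili_out$ranking
      ranking <- it2f_topsis(sub, w_r, shili_tiebreak = tiebreak,
                             hw = config$rank_hw)
      renli_out <- list(weights = w_r, ranking = ranking)
      ord <- ranking[order(ranking$rank), ]
      members <- sub$alternatives[match(ord$id, sub$alternatives$id), ,
                                  drop = FALSE]
      rownames(members) <- NULL
      current <- alternative_set(
        members,
        stage_tag = if (stage == config$stage_order[3]) "final"
                    else "post_shili")
      final_ranking <- ranking
    }
  }
  final <- current
  final$stage_tag <- "final"
  check_containment(final, initial)
  structure(list(initial = initial, wuli = wuli_out, shili = shili_out,
                 renli = renli_out, final = final,
                 final_ranking = if (!is.null(final_ranking)) {
                   final_ranking
                 } else if (!is.null(shili_out)) {
                   shili_out$ranking
                 },
                 warnings = warnings_by_stage, config = config),
            class = "staged_report")
}

#' @export
print.staged_report <- function(x, ...) {
  cat("<staged_report>\n")
  cat(sprintf("  initial:    %d candidates\n", nrow(x$initial$members)))
  if (!is.null(x$wuli)) {
    cat(sprintf("  post-wuli:  %d survivors (%d excluded)\n",
                nrow(x$wuli$survivors$members),
                length(unique(x$wuli$exclusions$id))))
  }
  if (!is.null(x$shili)) {
    cat(sprintf("  post-shili: %d retained of %d ranked\n",
                nrow(x$shili$retained$members), nrow(x$shili$ranking)))
  }
  if (!is.null(x$renli)) {
    top <- x$renli$ranking
    cat(sprintf("  final:      %d ranked; best = %s\n",
                nrow(top), top$name[top$rank == 1]))
  }
  invisible(x)
}

#' Run the pipeline from files
#'
#' File-based front end for [run_pipeline()]: reads the Shili decision
#' matrix, Renli linguistic judgments and Renli weights (explicit YAML
#' weights or Best-Worst comparison vectors), then writes the staged
#' outputs (survivor, weight and ranking CSVs) to `out_dir` when given.
#'
#' @param matrix_path CSV with id/name/category plus Wuli attribute and
#'   Shili criterion columns.
#' @param specs Criterion specs describing those columns.
#' @param renli_path CSV of linguistic judgments.
#' @param renli_weights_path YAML: either `weights: {id: w, ...}` or
#'   Best-Worst comparison vectors (see [read_bwm_yaml()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return The `staged_report`, invisibly when `out_dir` is given.
#' @export
run_full <- function(matrix_path, specs, renli_path, renli_weights_path,
                     config = pipeline_config(), out_dir = NULL) {
  dm <- read_decision_matrix(matrix_path, specs)
  scale <- linguistic_scale(config$linguistic_scale_path)
  renli <- read_linguistic_matrix(renli_path, scale = scale)
  y <- yaml::read_yaml(renli_weights_path)
  rw <- if (!is.null(y$weights)) {
    weight_vector(unlist(y$weights))
  } else {
    read_bwm_yaml(renli_weights_path)
  }
  if (inherits(rw, "bwm_input") || (is.list(rw) && !is.numeric(rw))) {
    rw_solved <- solve_bwm(rw)$weights
  } else {
    rw_solved <- rw
  }
  report <- run_pipeline(dm, renli, rw_solved, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$wuli)) {
      write.csv(report$wuli$survivors$members,
                file.path(out_dir, "wuli_survivors.csv"),
                row.names = FALSE, fileEncoding = "UTF-8")
      write.csv(report$wuli$exclusions,
                file.path(out_dir, "wuli_exclusions.csv"),
                row.names = FALSE, fileEncoding = "UTF-8")
    }
    if (!is.null(report$shili)) {
      jsonlite::write_json(as.list(report$shili$weights),
                           file.path(out_dir, "shili_weights.json"),
                           auto_unbox = TRUE, digits = NA)
      write_ranking(report$shili$ranking,
                    file.path(out_dir, "shili_ranking.csv"),
                    digits = config$precision)
    }
    if (!is.null(report$renli)) {
      jsonlite::write_json(as.list(report$renli$weights),
                           file.path(out_dir, "renli_weights.json"),
                           auto_unbox = TRUE, digits = NA)
      write_ranking(report$renli$ranking,
                    file.path(out_dir, "final_ranking.csv"),
                    digits = config$precision)
    }
    return(invisible(report))
  }
  report
}
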