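# Consistency index by the 1-9 value of a_BW, from the standard published
# BWM table; CR = xi* / CI.
.bwm_ci <- c(`1` = 0.00, `2` = 0.44, `3` = 1.00, `4` = 1.63, `5` = 2.30,
             `6` = 3.00, `7` = 3.73, `8` = 4.47, `9` = 5.23)

#' Validate Best-Worst Method comparison vectors
#'
#' @param criteria Character vector of criterion ids (length n).
#' @param best,worst Ids of the best and worst criterion.
#' @param best_to_others Named (or ordered) integer vector `a_Bj` in 1..9:
#'   preference of the best criterion over each criterion.
#' @param others_to_worst Named (or ordered) integer vector `a_jW` in
#'   1..9: preference of each criterion over the worst.
#' @return A validated list of class `bwm_input`.
#' @export
bwm_input <- function(criteria, best, worst, best_to_others,
                      others_to_worst) {
  n <- length(criteria)
  stopifnot(n >= 1, !anyDuplicated(criteria),
            best %in% criteria, worst %in% criteria)
  if (n >= 2 && best == worst) {
    stop("best and worst criterion must differ when n >= 2", call. = FALSE)
  }
  fix <- function(v, lab) {
    if (!is.null(names(v))) {
      missing <- setdiff(criteria, names(v))
      if (length(missing)) {
        stop(lab, " missing entries for: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      v <- v[criteria]
    }
    if (length(v) != n) stop(lab, " must have one entry per criterion",
                             call. = FALSE)
    if (any(v < 1 | v > 9 | v != round(v))) {
      stop(lab, " entries must be integers in 1..9", call. = FALSE)
    }
    setNames(as.numeric(v), criteria)
  }
  aB <- fix(best_to_others, "best_to_others")
  aW <- fix(others_to_worst, "others_to_worst")
  if (aB[[best]] != 1) stop("a_BB must equal 1", call. = FALSE)
  if (aW[[worst]] != 1) stop("a_WW must equal 1", call. = FALSE)
  aBW <- aB[[worst]]
  if (aBW != max(aB, aW)) {
    stop("a_BW must be the maximum of both comparison vectors", call. = FALSE)
  }
  structure(list(criteria = criteria, best = best, worst = worst,
                 best_to_others = aB, others_to_worst = aW),
            class = "bwm_input")
}

#' Solve the linear Best-Worst Method
#'
#' Solves the linear BWM program: minimise `xi` subject to
#' `|w_B - a_Bj w_j| <= xi`, `|w_j - a_jW w_W| <= xi` for all j,
#' `sum(w) = 1`, `w >= 0`. The linear model yields a unique weight vector
#' (unlike the original ratio formulation, which can produce weight
#' intervals). `xi* = 0` exactly when the comparisons are fully
#' consistent, i.e. `a_Bj * a_jW = a_BW` for every j. The consistency
#' ratio `CR = xi* / CI(a_BW)` uses the standard published consistency
#' index table; `CR > 0.25` triggers a warning, never an error.
#'
#' Several inputs (one per decision maker) may be supplied as a list; each
#' is solved separately and the weight vectors are averaged arithmetically
#' and renormalised, with per-DM consistency reported.
#'
#' @param input A [bwm_input()], or a list of them.
#' @param cr_warn Warning threshold on the consistency ratio.
#' @return Object of class `bwm_solution`: list with `weights` (named,
#'   sums to 1), `xi_star`, `consistency_ratio`, `model = "linear"`; for
#'   multiple DMs also `per_dm` (a list of individual solutions).
#' @examples
#' inp <- bwm_input(c("c1", "c2", "c3", "c4"), best = "c1", worst = "c4",
#'                  best_to_others = c(1, 2, 4, 8),
#'                  others_to_worst = c(8, 4, 2, 1))
#' solve_bwm(inp)$weights  # (8, 4, 2, 1) / 15
#' @export
solve_bwm <- function(input, cr_warn = 0.25) {
  if (is.list(input) && !inherits(input, "bwm_input")) {
    sols <- lapply(input, solve_bwm, cr_warn = cr_warn)
    wbar <- Reduce(`+`, lapply(sols, `[[`, "weights")) / length(sols)
    wbar <- wbar / sum(wbar)
    return(structure(list(weights = wbar,
                          xi_star = max(vapply(sols, `[[`, numeric(1),
                                               "xi_star")),
                          consistency_ratio = max(vapply(sols, `[[`,
                                                         numeric(1),
                                                         "consistency_ratio")),
                          model = "linear (mean of DMs)",
                          per_dm = sols),
                     class = "bwm_solution"))
  }
  stopifnot(inherits(input, "bwm_input"))
  n <- length(input$criteria)
  if (n == 1L) {
    return(structure(list(weights = setNames(1, input$criteria),
                          xi_star = 0, consistency_ratio = 0,
                          model = "linear"),
                     class = "bwm_solution"))
  }
  aB <- input$best_to_others
  aW <- input$others_to_worst
  B <- match(input$best, input$criteria)
  W <- match(input$worst, input$criteria)
  # variables: (w_1..w_n, xi); minimise xi
  obj <- c(rep(0, n), 1)
  rows <- list()
  for (j in seq_len(n)) {
    r <- rep(0, n + 1); r[B] <- r[B] + 1; r[j] <- r[j] - aB[[j]]; r[n + 1] <- -1
    rows[[length(rows) + 1L]] <- r
    r <- rep(0, n + 1); r[B] <- r[B] - 1; r[j] <- r[j] + aB[[j]]; r[n + 1] <- -1
    rows[[length(rows) + 1L]] <- r
    r <- rep(0, n + 1); r[j] <- r[j] + 1; r[W] <- r[W] - aW[[j]]; r[n + 1] <- -1
    rows[[length(rows) + 1L]] <- r
    r <- rep(0, n + 1); r[j] <- r[j] - 1; r[W] <- r[W] + aW[[j]]; r[n + 1] <- -1
    rows[[length(rows) + 1L]] <- r
  }
  A1 <- do.call(rbind, rows)
  sol <- boot::simplex(a = obj, A1 = A1, b1 = rep(0, nrow(A1)),
                       A3 = matrix(c(rep(1, n), 0), nrow = 1), b3 = 1)
  if (sol$solved != 1) {
    stop("internal error: BWM linear program did not solve", call. = FALSE)
  }
  w <- setNames(as.numeric(sol$soln[seq_len(n)]), input$criteria)
  w <- pmax(w, 0)
  w <- w / sum(w)
  xi <- max(0, as.numeric(sol$value))
  aBW <- aB[[input$worst]]
  ci <- .bwm_ci[[as.character(aBW)]]
  cr <- if (ci == 0) 0 else xi / ci
  if (cr > cr_warn) {
    warning(sprintf("BWM consistency ratio %.3f exceeds %.2f; weights kept",
                    cr, cr_warn), call. = FALSE)
  }
  structure(list(weights = w, xi_star = xi, consistency_ratio = cr,
                 model = "linear"),
            class = "bwm_solution")
}

#' @export
print.bwm_solution <- function(x, ...) {
  cat(sprintf("<bwm_solution (%s): xi* = %.6g, CR = %.4f>\n",
              x$model, x$xi_star, x$consistency_ratio))
  print(round(x$weights, 6))
  invisible(x)
}

#' Read Best-Worst Method comparisons from YAML
#'
#' Expected schema (one document per decision maker, or a list under
#' `dms:`):
#' \preformatted{
#' criteria: [c1, c2, c3]
#' best: c1
#' worst: c3
#' best_to_others: {c1: 1, c2: 2, c3: 8}
#' others_to_worst: {c1: 8, c2: 4, c3: 1}
#' }
#'
#' @param path YAML file path.
#' @return A [bwm_input()] or a list of them (when `dms:` is present).
#' @export
read_bwm_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  parse_one <- function(d) {
    crit <- if (!is.null(d$criteria)) as.character(d$criteria)
            else names(d$best_to_others)
    bwm_input(criteria = crit, best = d$best, worst = d$worst,
              best_to_others = unlist(d$best_to_others),
              others_to_worst = unlist(d$others_to_worst))
  }
  if (!is.null(y$dms)) lapply(y$dms, parse_one) else parse_one(y)
}
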