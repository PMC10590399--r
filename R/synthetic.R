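#' Specify a synthetic siting case
#'
#' Describes a complete, seeded synthetic input bundle emulating the
#' structure of a real siting study: a facility table with greening
#' clearances straddling the Wuli threshold, transport-hub and hospital
#' tables feeding the criterion calculators, and a linguistic judgment
#' table over the Renli criteria. Every facility carries a latent quality
#' in \[0, 1\]; all criteria are monotone transforms of it plus
#' independent noise, so with zero noise the true end-to-end ranking is
#' the latent ordering — the ground truth real data cannot provide.
#'
#' @param n_facilities Number of candidate facilities (>= 2).
#' @param wuli_fail_fraction Fraction in \[0, 1) of facilities whose
#'   greening clearance is drawn below the 20 m threshold; exactly
#'   `floor(fraction * n)` fail.
#' @param n_hubs Number of air and of rail hubs.
#' @param noise_sd Standard deviation of the Gaussian noise added to each
#'   latent-driven criterion, on the latent \[0, 1\] scale (0 = exact
#'   monotone transforms).
#' @param linguistic_noise Probability that a Renli judgment is perturbed
#'   by one vocabulary step.
#' @param ground_truth_weights Optional named weight vector from which
#'   consistent Best-Worst comparison vectors are built (ratios rounded
#'   into 1..9, with a warning when clipping loses exactness).
#' @param dominant If `TRUE`, the first facility is made weakly best on
#'   every criterion (and rated `VH` throughout), giving a dominance
#'   ground truth.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_facilities = 20, wuli_fail_fraction = 0.3,
                           n_hubs = 2, noise_sd = 0.05,
                           linguistic_noise = 0,
                           ground_truth_weights = NULL,
                           dominant = FALSE, seed = 1L) {
  stopifnot(n_facilities >= 2, wuli_fail_fraction >= 0,
            wuli_fail_fraction < 1, n_hubs >= 1, noise_sd >= 0,
            linguistic_noise >= 0, linguistic_noise <= 1)
  if (!is.null(ground_truth_weights)) {
    ground_truth_weights <- weight_vector(ground_truth_weights)
  }
  structure(list(n_facilities = as.integer(n_facilities),
                 wuli_fail_fraction = wuli_fail_fraction,
                 n_hubs = as.integer(n_hubs), noise_sd = noise_sd,
                 linguistic_noise = linguistic_noise,
                 ground_truth_weights = ground_truth_weights,
                 dominant = isTRUE(dominant), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Renli criterion ids used by the generator.
.renli_criteria <- c("operability", "recovery", "operational_effect",
                     "implementation_efficiency")

#' Generate a complete synthetic siting case
#'
#' @param spec A [synthetic_spec()].
#' @return List with `facilities`, `air_hubs`, `rail_hubs`, `hospitals`
#'   (data frames), `shili_specs` (criterion specs: greening Wuli
#'   constraint plus five Shili criteria), `matrix` (the assembled
#'   [decision_matrix()] over all six columns), `renli` (a
#'   [fuzzy_decision_matrix()] over four criteria), `bwm` (a
#'   [bwm_input()] or `NULL`), `latent_quality`, and `spec`.
#' @examples
#' case <- generate_case(synthetic_spec(n_facilities = 8, seed = 42))
#' apply_hard_constraints(case$matrix)
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_facilities
  set.seed(spec$seed)
  q <- runif(n)
  if (spec$dominant) q[1] <- 1
  ids <- sprintf("fac%02d", seq_len(n))
  cat_pool <- c("gymnasium", "exhibition centre")
  category <- sample(cat_pool, n, replace = TRUE, prob = c(0.75, 0.25))
  noise <- function() rnorm(n, 0, spec$noise_sd)

  # greening: exactly floor(fraction * n) facilities below 20 m
  nfail <- floor(spec$wuli_fail_fraction * n)
  fail_idx <- if (nfail > 0) {
    pool <- if (spec$dominant) 2:n else 1:n
    sample(pool, nfail)
  } else integer(0)
  greening <- 20 + runif(n, 0.5, 20)
  greening[fail_idx] <- runif(nfail, 5, 19.5)

  # hub tables: distances decrease (so potential indices increase) in q
  hub_tab <- function(prefix) {
    caps <- 100 * seq_len(spec$n_hubs)
    do.call(rbind, lapply(seq_len(spec$n_hubs), function(h) {
      data.frame(facility_id = ids, hub_id = sprintf("%s%d", prefix, h),
                 capacity = caps[h],
                 distance_km = 5 + 30 * pmin(pmax(1 - q + noise(), 0.01), 1.2),
                 stringsAsFactors = FALSE)
    }))
  }
  air_hubs <- hub_tab("air")
  rail_hubs <- hub_tab("rail")
  hospitals <- do.call(rbind, lapply(1:2, function(h) {
    data.frame(facility_id = ids, hospital_id = sprintf("hosp%d", h),
               distance_km = 0.5 + (10 + 2 * h) *
                 pmin(pmax(1 - q + noise(), 0.01), 1.2),
               stringsAsFactors = FALSE)
  }))
  facilities <- data.frame(
    id = ids, name = sprintf("Synthetic facility %02d", seq_len(n)),
    category = category, greening_m = greening,
    road_coverage = 5 + 95 * pmin(pmax(q + noise(), 0), 1.5),
    area_m2 = 5000 + 95000 * pmin(pmax(q + noise(), 0.01), 1.5),
    stringsAsFactors = FALSE)

  crit <- shili_criterion_table(facilities, air_hubs, rail_hubs, hospitals,
                                per_capita_m2 = 4)
  vals <- cbind(greening_m = facilities$greening_m,
                as.matrix(crit[, c("air_access", "rail_access",
                                   "road_access", "hospital_km", "beds")]))
  specs <- c(list(criterion_spec("greening_m", "Greening clearance",
                                 stage = "wuli", units = "m",
                                 wuli_threshold = 20,
                                 wuli_comparator = "ge")),
             shanghai_shili_specs())
  if (spec$dominant) {
    # force weak dominance of facility 1 on every ranked criterion
    for (j in 2:ncol(vals)) {
      dir <- specs[[j]]$direction
      vals[1, j] <- if (dir == "benefit") max(vals[, j]) else min(vals[, j])
    }
  }
  dm <- decision_matrix(vals, facilities[, c("id", "name", "category")],
                        specs)

  # Renli judgments: latent-quality quantile bins over the 7-term scale
  terms <- names(linguistic_scale())
  bin <- findInterval(q, seq(0, 1, length.out = 8L),
                      rightmost.closed = TRUE, all.inside = TRUE)
  tmat <- matrix(terms[bin], nrow = n, ncol = length(.renli_criteria))
  if (spec$linguistic_noise > 0) {
    flip <- matrix(runif(length(tmat)) < spec$linguistic_noise,
                   nrow = n)
    step <- matrix(sample(c(-1L, 1L), length(tmat), replace = TRUE),
                   nrow = n)
    idx <- matrix(match(tmat, terms), nrow = n)
    idx[flip] <- pmin(pmax(idx[flip] + step[flip], 1L), 7L)
    tmat <- matrix(terms[idx], nrow = n)
  }
  if (spec$dominant) tmat[1, ] <- "VH"
  renli <- fuzzy_decision_matrix(tmat, facilities[, c("id", "name",
                                                      "category")],
                                 .renli_criteria)

  bwm <- if (!is.null(spec$ground_truth_weights)) {
    consistent_bwm_input(spec$ground_truth_weights)
  }
  list(facilities = facilities, air_hubs = air_hubs, rail_hubs = rail_hubs,
       hospitals = hospitals, shili_specs = specs, matrix = dm,
       renli = renli, bwm = bwm, latent_quality = q, spec = spec)
}

#' Build consistent Best-Worst comparison vectors from known weights
#'
#' Inverts the consistent-case relation `a_Bj = w_B / w_j`,
#' `a_jW = w_j / w_W`, rounding ratios into the 1..9 vocabulary. When a
#' true ratio exceeds 9 (not representable) the entry is clipped with a
#' warning; when all ratios are integers in 1..9, solving the resulting
#' input recovers the weights exactly.
#'
#' @param w Named weight vector (the ground truth).
#' @return A [bwm_input()].
#' @export
consistent_bwm_input <- function(w) {
  w <- weight_vector(w)
  n <- length(w)
  best <- names(w)[which.max(w)]
  worst <- names(w)[which.min(w)]
  if (best == worst && n >= 2) worst <- setdiff(names(w), best)[n - 1L]
  aB <- round(w[[best]] / w)
  aW <- round(w / w[[worst]])
  if (any(aB > 9) || any(aW > 9)) {
    warning("weight ratios exceed 9; comparison vectors clipped ",
            "(recovery will be approximate)", call. = FALSE)
    aB <- pmin(aB, 9); aW <- pmin(aW, 9)
  }
  aB <- pmax(aB, 1); aW <- pmax(aW, 1)
  # keep the defining identities exact after rounding
  aB[[best]] <- 1
  aW[[worst]] <- 1
  aBW <- max(aB, aW)
  aB[[worst]] <- aBW
  aW[[best]] <- aBW
  bwm_input(names(w), best = best, worst = worst,
            best_to_others = aB, others_to_worst = aW)
}

#' Weight-recovery experiment for the Best-Worst Method
#'
#' Repeatedly builds consistent comparison vectors from a ground-truth
#' weight vector under random criterion orderings and solves them,
#' reporting the recovery error per repetition. With representable
#' (integer, <= 9) ratios the recovery is exact to solver precision.
#'
#' @param ground_truth Named weight vector.
#' @param reps Number of repetitions.
#' @param seed Integer seed (fixed seed gives an identical table).
#' @return Data frame `(rep, max_abs_error, xi_star)`.
#' @export
recover_weights_experiment <- function(ground_truth, reps = 100,
                                       seed = 1L) {
  w <- weight_vector(ground_truth)
  set.seed(seed)
  out <- lapply(seq_len(reps), function(r) {
    perm <- sample(names(w))
    sol <- solve_bwm(consistent_bwm_input(w[perm]))
    data.frame(rep = r,
               max_abs_error = max(abs(sol$weights[names(w)] - w)),
               xi_star = sol$xi_star)
  })
  do.call(rbind, out)
}

#' Write a synthetic case to the pipeline's file formats
#'
#' Emits the CSV/YAML files [run_full()] and the command-line driver
#' consume: `facilities.csv`, `air_hubs.csv`, `rail_hubs.csv`,
#' `hospitals.csv`, `shili_matrix.csv`, `renli_judgments.csv` and, when
#' ground-truth weights are present, `bwm.yaml`.
#'
#' @param case Output of [generate_case()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case_csv <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE,
                                  quote = TRUE, fileEncoding = "UTF-8")
  wr(case$facilities, "facilities.csv")
  wr(case$air_hubs, "air_hubs.csv")
  wr(case$rail_hubs, "rail_hubs.csv")
  wr(case$hospitals, "hospitals.csv")
  write_decision_matrix(case$matrix, file.path(dir, "shili_matrix.csv"))
  terms_df <- cbind(case$renli$alternatives,
                    as.data.frame(case$renli$terms, check.names = FALSE))
  wr(terms_df, "renli_judgments.csv")
  if (!is.null(case$bwm)) {
    yaml::write_yaml(list(
      criteria = case$bwm$criteria, best = case$bwm$best,
      worst = case$bwm$worst,
      best_to_others = as.list(case$bwm$best_to_others),
      others_to_worst = as.list(case$bwm$others_to_worst)),
      file.path(dir, "bwm.yaml"))
  }
  invisible(dir)
}
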