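#' Published Shanghai case fixtures
#'
#' Loads the plain-text fixtures transcribing the published Shanghai
#' Fangcang shelter-hospital case study: the printed Shili entropy
#' weights and TOPSIS ranking of the 22 post-screening candidates, the
#' Renli Best-Worst-Method weights and final fuzzy-TOPSIS ranking of the
#' 11 finalists, and the sensitivity weight cases.
#'
#' The study's raw inputs (the 22x5 Shili evaluation matrix and the
#' linguistic judgment table) were published only as supplementary files
#' and are not redistributed. If present as
#' `shili_matrix_moesm1.csv` / `renli_judgments_moesm2.csv` in the
#' package's `extdata/shanghai` directory they are loaded under
#' `shili_matrix` / `renli_judgments`; otherwise those elements are
#' `NULL`. A clearly-labelled synthetic reconstruction of the judgment
#' table is always available under `renli_judgments_reconstructed` (see
#' [shanghai_renli_judgments()]).
#'
#' @return List with elements `shili_weights`, `shili_ranking`,
#'   `renli_weights`, `renli_ranking` (data frames), `shili_matrix`,
#'   `renli_judgments` (or `NULL`), and `renli_judgments_reconstructed`
#'   (a [fuzzy_decision_matrix()]).
#' @examples
#' sh <- shanghai_case()
#' head(sh$shili_ranking)
#' @export
shanghai_case <- function() {
  dir <- system.file("extdata", "shanghai", package = "wsrsite",
                     mustWork = TRUE)
  rd <- function(f) read.csv(file.path(dir, f), check.names = FALSE,
                             stringsAsFactors = FALSE, encoding = "UTF-8")
  moesm1 <- file.path(dir, "shili_matrix_moesm1.csv")
  moesm2 <- file.path(dir, "renli_judgments_moesm2.csv")
  list(
    shili_weights = rd("shili_weights.csv"),
    shili_ranking = rd("shili_ranking.csv"),
    renli_weights = rd("renli_weights.csv"),
    renli_ranking = rd("renli_ranking.csv"),
    shili_matrix = if (file.exists(moesm1)) {
      read_decision_matrix(moesm1, shanghai_shili_specs())
    },
    renli_judgments = if (file.exists(moesm2)) {
      read_linguistic_matrix(moesm2)
    },
    renli_judgments_reconstructed = shanghai_renli_judgments())
}

#' Shili criterion specifications of the Shanghai case
#'
#' Air, rail and road accessibility and space scale are benefit criteria;
#' distance to the nearest designated hospital is a cost criterion.
#'
#' @return List of [criterion_spec()] objects in the published column
#'   order.
#' @export
shanghai_shili_specs <- function() {
  list(
    criterion_spec("air_access", "Air accessibility", stage = "shili",
                   units = "capacity/km"),
    criterion_spec("rail_access", "Rail accessibility", stage = "shili",
                   units = "capacity/km"),
    criterion_spec("road_access", "Road accessibility", stage = "shili",
                   units = "settlements in 15 min"),
    criterion_spec("hospital_km", "Distance to hospital", stage = "shili",
                   direction = "cost", units = "km"),
    criterion_spec("beds", "Space scale", stage = "shili", units = "beds"))
}

#' Reconstructed Renli judgment table (synthetic)
#'
#' The linguistic judgments behind the published final ranking are only
#' available as a non-redistributed supplementary file. This fixture is a
#' \strong{synthetic reconstruction}: the seven-term assignment found by
#' exhaustive search whose fuzzy-TOPSIS closeness (default engine,
#' published weights 0.57/0.06/0.14/0.23) reproduces the printed
#' nine-decimal closeness values with max deviation 3.9e-4. Because it
#' was fitted to the published output, agreement with that output shows
#' the engine's internal consistency, not independent reproduction.
#'
#' @return A [fuzzy_decision_matrix()] of 11 facilities x 4 criteria.
#' @export
shanghai_renli_judgments <- function() {
  path <- system.file("extdata", "shanghai",
                      "renli_judgments_reconstructed.csv",
                      package = "wsrsite", mustWork = TRUE)
  read_linguistic_matrix(path)
}
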