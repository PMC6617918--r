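#' Default destination-altitude pool
#'
#' Named high-altitude cities with the empirical frequencies observed in a
#' 50-patient sea-level cohort (1 Lhasa, 3 Guiyang, 5 Kunming), the
#' remainder travelling within the coastal lowlands (uniform 0-150 m).
#'
#' @return A tibble with columns `name`, `altitude_m` (NA marks the
#'   uniform coastal stratum), `prob`.
#' @export
default_altitude_pool <- function() {
  tibble(name = c("coastal", "guiyang", "kunming", "lhasa"),
         altitude_m = c(NA, 1277, 1842, 3490),
         prob = c(0.82, 0.06, 0.10, 0.02))
}

#' Simulate a synthetic patient cohort
#'
#' Generates cohorts with the statistical structure of a post-vitrectomy
#' gas-tamponade travel cohort, for pipeline testing and
#' parameter-recovery studies. Surgeon-judged interface heights are
#' uniform over `height_range_pct`; the patient's judgment differs by a
#' fixed interobserver bias plus Gaussian noise
#' (`surgeon - patient = bias + N(0, sd)`), clipped to \[0, 100\].
#' Destinations are drawn from an altitude pool dominated by low coastal
#' values with a long tail to 3490 m; travel modes and Likert responses
#' come from fixed categorical distributions. Every patient departs from
#' the origin altitude (default 10 m, a sea-level centre).
#'
#' @param n Number of patients (>= 1). Default 50.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   cohort and is recorded in the cohort's provenance.
#' @param height_range_pct Range of surgeon-judged heights, percent.
#' @param judgment_bias_pct Mean of `surgeon - patient` differences,
#'   percent. Default -0.3.
#' @param judgment_sd_pct SD of the interobserver noise, percent.
#'   Default 2.8 (chosen so the default 95% limits of agreement span
#'   about 11 percentage points).
#' @param altitude_pool Destination pool; see [default_altitude_pool()].
#' @param coastal_range_m Altitude range of the coastal stratum, metres.
#' @param mode_probs Probabilities for airplane / train / car_bus.
#' @param highspeed_prob Probability a train traveller takes the
#'   high-speed train (11/15 by default).
#' @param likert_probs Response probabilities for levels 1..5; mass
#'   concentrated on 4-5 (a generally positive attitude).
#' @param origin_altitude_m Common origin altitude, metres.
#' @return A cohort tibble (class `gasrisk_cohort`); see [read_cohort()]
#'   for the schema.
#' @examples
#' simulate_cohort(n = 5, seed = 1)
#' @export
simulate_cohort <- function(n = 50, seed = NULL,
                            height_range_pct = c(9, 78),
                            judgment_bias_pct = -0.3,
                            judgment_sd_pct = 2.8,
                            altitude_pool = default_altitude_pool(),
                            coastal_range_m = c(0, 150),
                            mode_probs = c(airplane = 0.38, train = 0.30,
                                           car_bus = 0.32),
                            highspeed_prob = 11 / 15,
                            likert_probs = c(0.02, 0.03, 0.10, 0.35, 0.50),
                            origin_altitude_m = 10) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("Cohort must be nonempty: `n` must be >= 1.",
          class = "gasrisk_config_error")
  }
  n <- as.integer(n)
  if (judgment_sd_pct < 0 || diff(range(height_range_pct)) < 0) {
    abort("`judgment_sd_pct` must be >= 0 and `height_range_pct` ordered.",
          class = "gasrisk_config_error")
  }
  for (p in list(mode_probs, likert_probs, altitude_pool$prob)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort("Probabilities must be nonnegative and sum to 1.",
            class = "gasrisk_config_error")
    }
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }

  surgeon <- stats::runif(n, height_range_pct[1], height_range_pct[2])
  patient <- surgeon - (judgment_bias_pct +
                          stats::rnorm(n, 0, judgment_sd_pct))
  patient <- pmin(100, pmax(0, patient))

  stratum <- sample(altitude_pool$name, n, replace = TRUE,
                    prob = altitude_pool$prob)
  dest <- altitude_pool$altitude_m[match(stratum, altitude_pool$name)]
  coastal <- is.na(dest)
  dest[coastal] <- stats::runif(sum(coastal), coastal_range_m[1],
                                coastal_range_m[2])

  group <- sample(names(mode_probs), n, replace = TRUE, prob = mode_probs)
  mode <- ifelse(group == "train",
                 ifelse(stats::runif(n) < highspeed_prob,
                        "train_highspeed", "train_ordinary"),
                 group)

  acuity_pool <- c("CF", "HM", "20/200", "20/100", "20/63", "20/40",
                   "20/25")
  df <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = sample(18:70, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4)),
    surgeon_interface_pct = round(surgeon),
    patient_interface_pct = round(patient),
    origin_altitude_m = origin_altitude_m,
    destination_altitude_m = round(dest),
    travel_mode = mode,
    visual_acuity = sample(acuity_pool, n, replace = TRUE),
    likert_item1 = sample(1:5, n, replace = TRUE, prob = likert_probs),
    likert_item2 = sample(1:5, n, replace = TRUE, prob = likert_probs))
  validate_cohort_rows(df)
  new_cohort(df, provenance = list(source = "simulate_cohort",
                                   seed = seed, n = n))
}
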