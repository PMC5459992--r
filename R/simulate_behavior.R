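#' Configuration for the operant-behaviour simulator
#'
#' Defaults describe a 4 h fixed-ratio cocaine self-administration session in
#' which an average rat emits about 200 active presses at FR5 (about 40
#' injections), with animal-to-animal variation driven by a latent lognormal
#' "incentive motivation" factor that raises both FR5 pressing and
#' progressive-ratio capacity.
#'
#' @param n_animals cohort size (>= 3)
#' @param base_fr5_mean mean active presses per FR5 session at motivation 0
#' @param fr5_dispersion negative-binomial size parameter for session presses
#' @param motivation_sd SD of the latent motivation (log scale, >= 0)
#' @param motivation_effect_fr5,motivation_effect_bp log-scale coefficients of
#'   motivation on FR5 pressing and PR capacity
#' @param bp_capacity_base press capacity against the PR ladder at motivation 0
#' @param seed master seed; behaviour draws use the "behavior" substream
#' @return a validated list of class `behavior_sim_config`
#' @export
behavior_sim_config <- function(n_animals = 134, base_fr5_mean = 200,
                                fr5_dispersion = 8, motivation_sd = 0.3,
                                motivation_effect_fr5 = 1,
                                motivation_effect_bp = 1,
                                bp_capacity_base = 120, seed = 1) {
  if (!is.numeric(n_animals) || n_animals < 3 || n_animals != trunc(n_animals))
    stop_config("n_animals", "must be an integer >= 3 (z-scores undefined below)")
  check_positive(base_fr5_mean, "base_fr5_mean")
  check_positive(fr5_dispersion, "fr5_dispersion")
  check_nonneg(motivation_sd, "motivation_sd")
  check_positive(bp_capacity_base, "bp_capacity_base")
  if (!is.numeric(motivation_effect_fr5) || length(motivation_effect_fr5) != 1L)
    stop_config("motivation_effect_fr5", "must be a single number")
  if (!is.numeric(motivation_effect_bp) || length(motivation_effect_bp) != 1L)
    stop_config("motivation_effect_bp", "must be a single number")
  structure(list(
    n_animals = as.integer(n_animals), base_fr5_mean = base_fr5_mean,
    fr5_dispersion = fr5_dispersion, motivation_sd = motivation_sd,
    motivation_effect_fr5 = motivation_effect_fr5,
    motivation_effect_bp = motivation_effect_bp,
    bp_capacity_base = bp_capacity_base, seed = seed
  ), class = "behavior_sim_config")
}

#' Simulate an operant self-administration cohort
#'
#' Each animal is trained FR1 for 5 sessions, FR3 for 2, FR5 for 5, then runs
#' one progressive-ratio session. Active presses per fixed-ratio session are
#' negative-binomial with mean `base_fr5_mean * (ratio/5) * exp(effect * m_i)`
#' for latent motivation `m_i ~ N(0, motivation_sd)`. The PR session walks the
#' requirement ladder until the next requirement exceeds the animal's press
#' capacity `bp_capacity_base * exp(effect_bp * m_i)`; the logged break point
#' is the requirement of the last injection earned.
#'
#' @param cfg a [behavior_sim_config()]
#' @return list with `sessions` (one row per animal x session: animal_id,
#'   session_index, schedule, active_presses, inactive_presses, injections,
#'   break_point) and `animals` (animal_id, motivation)
#' @export
simulate_behavior_cohort <- function(cfg = behavior_sim_config()) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(cfg$seed, "behavior"))

  n <- cfg$n_animals
  ids <- sprintf("R%03d", seq_len(n))
  m <- stats::rnorm(n, 0, cfg$motivation_sd)
  schedules <- c(rep("FR1", 5), rep("FR3", 2), rep("FR5", 5), "PR")
  ratio <- c(FR1 = 1, FR3 = 3, FR5 = 5)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    mu_fr5 <- cfg$base_fr5_mean * exp(cfg$motivation_effect_fr5 * m[i])
    rec <- data.frame(
      animal_id = ids[i], session_index = seq_along(schedules),
      schedule = schedules, active_presses = 0L, inactive_presses = 0L,
      injections = 0L, break_point = NA_integer_, stringsAsFactors = FALSE
    )
    for (s in seq_along(schedules)) {
      sched <- schedules[s]
      if (sched != "PR") {
        mu <- mu_fr5 * ratio[[sched]] / 5
        ap <- stats::rnbinom(1, size = cfg$fr5_dispersion, mu = mu)
        rec$active_presses[s] <- ap
        rec$inactive_presses[s] <- stats::rpois(1, 10)
        rec$injections[s] <- ap %/% ratio[[sched]]
      } else {
        capacity <- cfg$bp_capacity_base * exp(cfg$motivation_effect_bp * m[i])
        inj <- 0L
        while (pr_requirement(inj + 1L) <= capacity) inj <- inj + 1L
        rec$injections[s] <- inj
        rec$break_point[s] <-
          if (inj > 0) pr_requirement(inj) else 0L
        rec$active_presses[s] <-
          if (inj > 0) sum(pr_requirement(seq_len(inj))) else
            as.integer(floor(capacity))
        rec$inactive_presses[s] <- stats::rpois(1, 10)
      }
    }
    rows[[i]] <- rec
  }
  list(
    sessions = do.call(rbind, rows),
    animals = data.frame(animal_id = ids, motivation = m,
                         stringsAsFactors = FALSE)
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
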