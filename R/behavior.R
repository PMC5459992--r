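#' Progressive-ratio response requirement
#'
#' Presses required to earn injection `i` under the exponential
#' progressive-ratio schedule requirement(i) = Int(scale * e^(rate * i) - scale),
#' with Int(.) read as truncation toward zero (floor for the positive
#' arguments that arise here). `rounding = "round"` switches to the
#' nearest-integer convention used by part of the operant literature.
#'
#' @param i injection index (vectorised, non-negative integers)
#' @param scale,rate schedule constants; defaults 5 and 0.25
#' @param rounding "floor" (default) or "round"
#' @return integer vector of required presses, non-decreasing in `i`
#' @examples
#' pr_requirement(0:8)
#' @export
pr_requirement <- function(i, scale = 5, rate = 0.25,
                           rounding = c("floor", "round")) {
  rounding <- match.arg(rounding)
  check_positive(scale, "scale")
  check_positive(rate, "rate")
  if (any(!is.finite(i)) || any(i < 0) || any(i != trunc(i)))
    stop("injection index must be a non-negative integer", call. = FALSE)
  raw <- scale * exp(rate * i) - scale
  if (rounding == "floor") as.integer(floor(raw)) else as.integer(round(raw))
}

#' Break point of a progressive-ratio session
#'
#' The break point is the number of lever presses required for the last
#' injection earned before responding ceased. A session with zero injections
#' has break point 0 and carries a warning attribute.
#'
#' @param injections injections earned in the PR session (single count)
#' @param scale,rate,rounding passed to [pr_requirement()]
#' @return break point in presses; attribute `no_injection` is TRUE when
#'   `injections == 0`
#' @export
extract_break_point <- function(injections, scale = 5, rate = 0.25,
                                rounding = "floor") {
  if (!is.numeric(injections) || length(injections) != 1L ||
      is.na(injections) || injections < 0 || injections != trunc(injections))
    stop("injections must be a single non-negative integer", call. = FALSE)
  if (injections == 0) {
    warning("no injection earned in PR session; break point set to 0",
            call. = FALSE)
    return(structure(0L, no_injection = TRUE))
  }
  pr_requirement(injections, scale = scale, rate = rate, rounding = rounding)
}

#' Combined drug-seeking behavioural score
#'
#' Standardises FR5 lever pressing and PR break point within the cohort
#' (z = (x - mean) / sd) and sums the two z-scores into the combined score
#' used to rank animals.
#'
#' @param fr5_means per-animal mean FR5 active presses per session
#' @param break_points per-animal PR break points
#' @param animal_ids optional identifiers (default A1..An)
#' @param sd_type "sample" (n - 1 denominator, default) or "population" (n)
#' @return a `cohort_scores` data frame with columns animal_id, fr5_mean,
#'   break_point, z_fr5, z_bp, combined, label (label unset, NA)
#' @export
combined_score <- function(fr5_means, break_points, animal_ids = NULL,
                           sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  n <- length(fr5_means)
  if (length(break_points) != n)
    stop("fr5_means and break_points must have the same length", call. = FALSE)
  if (n < 3)
    stop("at least 3 animals are required to standardise scores", call. = FALSE)
  if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(n))
  zscore <- function(x, metric) {
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((n - 1) / n)
    if (!is.finite(s) || s == 0)
      stop(sprintf("degenerate cohort: zero variance in %s", metric),
           call. = FALSE)
    (x - mean(x)) / s
  }
  z_fr5 <- zscore(fr5_means, "fr5_mean")
  z_bp <- zscore(break_points, "break_point")
  out <- data.frame(
    animal_id = as.character(animal_ids),
    fr5_mean = fr5_means,
    break_point = break_points,
    z_fr5 = z_fr5,
    z_bp = z_bp,
    combined = z_fr5 + z_bp,
    label = NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_scores", "data.frame")
  out
}

#' Classify animals into Addict / Non-addict / Intermediate
#'
#' The floor(top_fraction * n) highest combined scores become Addict and the
#' floor(bottom_fraction * n) lowest become Non-addict; the remainder are
#' Intermediate. Ties are broken deterministically by (combined score,
#' animal_id), so classification is reproducible for any input order.
#'
#' @param scores a `cohort_scores` data frame from [combined_score()]
#' @param top_fraction fraction labelled Addict (default 0.25)
#' @param bottom_fraction fraction labelled Non-addict (default 0.40)
#' @return `scores` with the label column filled in
#' @export
classify_cohort <- function(scores, top_fraction = 0.25,
                            bottom_fraction = 0.40) {
  check_fraction(top_fraction, "top_fraction")
  check_fraction(bottom_fraction, "bottom_fraction")
  if (top_fraction + bottom_fraction > 1)
    stop_config("top_fraction + bottom_fraction", "must not exceed 1")
  if (any(!is.finite(scores$combined)))
    stop("combined scores must be finite", call. = FALSE)
  n <- nrow(scores)
  n_top <- floor(top_fraction * n)
  n_bot <- floor(bottom_fraction * n)
  ord_desc <- order(-scores$combined, scores$animal_id)
  ord_asc <- order(scores$combined, scores$animal_id)
  label <- rep("Intermediate", n)
  if (n_top > 0) label[ord_desc[seq_len(n_top)]] <- "Addict"
  if (n_bot > 0) label[ord_asc[seq_len(n_bot)]] <- "Non-addict"
  scores$label <- label
  scores
}

#' @export
print.cohort_scores <- function(x, ...) {
  cat(sprintf("Cohort scores: %d animals", nrow(x)))
  if (!all(is.na(x$label))) {
    tab <- table(factor(x$label, c("Addict", "Intermediate", "Non-addict")))
    cat(sprintf(" (Addict %d, Intermediate %d, Non-addict %d)",
                tab[["Addict"]], tab[["Intermediate"]], tab[["Non-addict"]]))
  }
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("... %d more animals\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.cohort_scores <- function(object, ...) {
  out <- list(
    n = nrow(object),
    labels = table(object$label, useNA = "ifany"),
    fr5 = summary(object$fr5_mean),
    break_point = summary(object$break_point),
    combined = summary(object$combined)
  )
  class(out) <- "summary.cohort_scores"
  out
}

#' @export
print.summary.cohort_scores <- function(x, ...) {
  cat(sprintf("Cohort of %d animals\n", x$n))
  print(x$labels)
  cat("FR5 mean presses:\n"); print(x$fr5)
  cat("Break point:\n"); print(x$break_point)
  invisible(x)
}

#' Score a cohort from session logs
#'
#' Computes each animal's mean FR5 active pressing and its PR break point
#' (from the logged injection count, via the PR requirement ladder) and
#' standardises them into the combined behavioural score.
#'
#' @param sessions a session-log data frame with columns animal_id,
#'   session_index, schedule, active_presses, inactive_presses, injections
#' @param scale,rate,rounding PR schedule constants, see [pr_requirement()]
#' @param sd_type standardisation denominator, see [combined_score()]
#' @return a `cohort_scores` data frame (labels unset)
#' @export
score_cohort <- function(sessions, scale = 5, rate = 0.25, rounding = "floor",
                         sd_type = "sample") {
  validate_session_log(sessions)
  ids <- sort(unique(sessions$animal_id))
  fr5 <- vapply(ids, function(a) {
    x <- sessions$active_presses[sessions$animal_id == a &
                                   sessions$schedule == "FR5"]
    if (!length(x)) stop(sprintf("animal %s has no FR5 session", a),
                         call. = FALSE)
    mean(x)
  }, numeric(1))
  bp <- vapply(ids, function(a) {
    inj <- sessions$injections[sessions$animal_id == a &
                                 sessions$schedule == "PR"]
    if (length(inj) != 1L)
      stop(sprintf("animal %s must have exactly one PR session", a),
           call. = FALSE)
    if (inj == 0) 0
    else as.numeric(pr_requirement(inj, scale, rate, rounding))
  }, numeric(1))
  combined_score(fr5, bp, animal_ids = ids, sd_type = sd_type)
}

validate_session_log <- function(sessions) {
  need <- c("animal_id", "session_index", "schedule", "active_presses",
            "inactive_presses", "injections")
  miss <- setdiff(need, names(sessions))
  if (length(miss))
    stop("session log is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(sessions$schedule %in% c("FR1", "FR3", "FR5", "PR")))
    stop("schedule must be one of FR1, FR3, FR5, PR", call. = FALSE)
  cnt <- c(sessions$active_presses, sessions$inactive_presses,
           sessions$injections)
  if (any(cnt < 0)) stop("counts must be non-negative", call. = FALSE)
  invisible(sessions)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two samples by rank sum. For combined sizes of at
#' most 12 the null distribution is enumerated exactly over all group
#' assignments of the (mid)ranks; otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b numeric vectors (each of length >= 2)
#' @param exact_max largest combined size for the exact enumeration branch
#' @return list with elements `statistic` (Z for the normal branch, NA for the
#'   exact branch), `W` (rank sum of `a`), `p.value`, and `method`
#' @export
rank_sum_test <- function(a, b, exact_max = 12) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group must contain at least 2 values", call. = FALSE)
  if (any(!is.finite(c(a, b))))
    stop("values must be finite", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (n <= exact_max) {
    idx <- utils::combn(n, na)
    Wall <- colSums(matrix(r[idx], nrow = na))
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
    return(list(statistic = NA_real_, W = W, p.value = p,
                method = "exact enumeration"))
  }
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- W - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  list(statistic = z, W = W,
       p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation with tie and continuity correction")
}
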