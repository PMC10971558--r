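#' Specification of one synthetic treatment group
#'
#' Target statistics for a group of animals in a synthetic cohort.  Mean
#' and SD may be scalars (same every day) or vectors matching the day list
#' passed to [generate_cohort()].
#'
#' @param label group label (e.g. `"control"`, `"RT2Gy"`, `"FUS-HT"`,
#'   `"FUS-HT+RT2Gy"`).
#' @param n number of animals.
#' @param mean target mean tumor volume(s) in mm^3.
#' @param sd target volume SD(s) in mm^3.
#' @param aspect_range range of the length/width aspect ratio used when
#'   converting a volume to caliper measurements (>= 1).
#' @export
group_spec <- function(label, n, mean, sd, aspect_range = c(1, 1.6)) {
  stopifnot(n >= 1, all(mean > 0), all(sd >= 0),
            length(aspect_range) == 2, all(aspect_range >= 1),
            aspect_range[1] <= aspect_range[2])
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd,
                 aspect_range = aspect_range),
            class = "group_spec")
}

# Location parameter of a floor-truncated normal whose *truncated* mean
# equals the target, so that group means are recovered without bias.
truncnorm_location <- function(target, sd, floor) {
  if (sd == 0 || target > floor + 8 * sd) return(target)
  f <- function(mu) {
    a <- (floor - mu) / sd
    mu + sd * exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE,
                                               log.p = TRUE)) - target
  }
  uniroot(f, lower = target - 6 * sd, upper = target, tol = 1e-10)$root
}

rtruncnorm_floor <- function(n, target, sd, floor) {
  if (sd == 0) return(rep(target, n))
  mu <- truncnorm_location(target, sd, floor)
  plo <- pnorm((floor - mu) / sd)
  u <- runif(n, plo, 1)
  mu + sd * qnorm(u)
}

#' Generate a synthetic caliper cohort
#'
#' Draws per-animal, per-day tumor volumes from a normal distribution
#' truncated at a small positive floor (location-adjusted so group means
#' hit their targets), draws an aspect ratio a >= 1 uniformly from the
#' group's range, and inverts V = L W^2 / 2 with L = a W into caliper
#' length/width pairs.  Seeded runs are bit-reproducible.
#'
#' @param specs list of [group_spec()]s.
#' @param days numeric vector of measurement days.
#' @param seed integer RNG seed; `NULL` uses (and advances) the session RNG.
#' @param floor truncation floor in mm^3.
#' @return caliper data.frame: `animal_id`, `group`, `day`, `length_mm`,
#'   `width_mm`.
#' @export
generate_cohort <- function(specs, days = 7, seed = NULL, floor = 1) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, logical(1),
                                           "group_spec")))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rows <- list()
  for (sp in specs) {
    means <- rep_len(sp$mean, length(days))
    sds <- rep_len(sp$sd, length(days))
    if (any(means <= floor))
      stop("infeasible spec for group ", sp$label,
           ": mean must exceed the truncation floor")
    ids <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", sp$label),
                   seq_len(sp$n))
    for (d in seq_along(days)) {
      vol <- rtruncnorm_floor(sp$n, means[d], sds[d], floor)
      a <- runif(sp$n, sp$aspect_range[1], sp$aspect_range[2])
      w <- (2 * vol / a)^(1 / 3)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = ids, group = sp$label, day = days[d],
        length_mm = a * w, width_mm = w)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Built-in cohort presets
#'
#' Group parameters emulating a four-arm preclinical
#' hyperthermia-radiosensitization experiment in a subcutaneous rodent
#' glioma model (control, FUS hyperthermia, 2 Gy radiotherapy, combined)
#' plus a three-arm radiation dose-escalation pilot:
#' * `"four-arm-day7"` - one week post-treatment volumes, the primary
#'   analysis day (control 1174 +/- 554 n=8; FUS-HT 1483 +/- 702 n=10;
#'   RT2Gy 609 +/- 300 n=8; combined 259 +/- 186 n=10).
#' * `"four-arm-day0"` - treatment-day volumes, statistically homogeneous
#'   across arms.
#' * `"dose-escalation"` - control / 2 Gy / 5 Gy pilot, n=3 per arm.
#'
#' @param name preset name.
#' @return list with `specs` (list of [group_spec()]) and default `days`.
#' @export
cohort_preset <- function(name = c("four-arm-day7", "four-arm-day0",
                                   "dose-escalation")) {
  name <- match.arg(name)
  switch(name,
    "four-arm-day7" = list(
      specs = list(
        group_spec("control", 8, 1174, 554),
        group_spec("RT2Gy", 8, 609, 300),
        group_spec("FUS-HT", 10, 1483, 702),
        group_spec("FUS-HT+RT2Gy", 10, 259, 186)),
      days = 7),
    "four-arm-day0" = list(
      specs = list(
        group_spec("control", 8, 108, 56),
        group_spec("RT2Gy", 8, 101, 45),
        group_spec("FUS-HT", 10, 134, 48),
        group_spec("FUS-HT+RT2Gy", 10, 100, 36)),
      days = 0),
    "dose-escalation" = list(
      specs = list(
        group_spec("control", 3, 1657, 397),
        group_spec("RT2Gy", 3, 1160, 545),
        group_spec("RT5Gy", 3, 595, 259)),
      days = 7))
}
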