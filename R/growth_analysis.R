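#' Tumor volume from orthogonal caliper measurements
#'
#' Modified-ellipsoid estimate V = length * width^2 / 2 with length the
#' longest dimension and width the perpendicular one.
#'
#' @param length_mm tumor length in mm.
#' @param width_mm tumor width in mm; must not exceed length.
#' @return volume in mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0))
    stop("length and width must be positive")
  if (any(width_mm > length_mm * (1 + 1e-12)))
    stop("width must not exceed length (orientation violation)")
  length_mm * width_mm^2 / 2
}

#' Percent volume reduction relative to control
#'
#' @param mean_treated mean treated-group volume in mm^3.
#' @param mean_control mean control-group volume in mm^3 (positive).
#' @return reduction in percent of the control mean.
#' @export
percent_reduction <- function(mean_treated, mean_control) {
  if (any(mean_control <= 0)) stop("control mean must be positive")
  100 * (mean_control - mean_treated) / mean_control
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "volume_mm3") %in% names(groups)))
    groups <- split(groups$volume_mm3, groups$group)
  }
  stopifnot(is.list(groups), !is.null(names(groups)))
  lapply(groups, as.numeric)
}

#' Volumes per group from a caliper table at one day
#'
#' @param records data.frame with columns `animal_id`, `group`, `day`,
#'   `length_mm`, `width_mm`.
#' @param day analysis day (default 7, one week post-treatment).
#' @return named list of volume vectors (mm^3), one per group.
#' @export
volumes_by_group <- function(records, day = 7) {
  stopifnot(all(c("group", "day", "length_mm", "width_mm") %in%
                  names(records)))
  rec <- records[records$day == day, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records at day ", day)
  split(tumor_volume(rec$length_mm, rec$width_mm), rec$group)
}

#' Per-group mean and SD of tumor volumes
#'
#' @param records caliper table (see [volumes_by_group()]).
#' @param day analysis day.
#' @return data.frame with `group`, `day`, `n`, `mean_mm3`, `sd_mm3`.
#' @export
group_summaries <- function(records, day = 7) {
  vols <- volumes_by_group(records, day)
  data.frame(group = names(vols), day = day,
             n = vapply(vols, length, integer(1)),
             mean_mm3 = vapply(vols, mean, numeric(1)),
             sd_mm3 = vapply(vols, sd, numeric(1)),
             row.names = NULL)
}

#' One-way fixed-effects ANOVA across treatment groups
#'
#' Classical equal-variance one-way ANOVA on raw volumes.
#'
#' @param groups named list of per-group numeric volume vectors, or a
#'   data.frame with `group` and `volume_mm3` columns.
#' @return list with `statistic` (F), `df` (between, within), `p_value`.
#' @export
anova_oneway <- function(groups) {
  gl <- as_group_list(groups)
  if (length(gl) < 2) stop("need at least two groups")
  if (any(vapply(gl, length, integer(1)) < 2))
    stop("every group needs at least two observations")
  dat <- data.frame(
    value = unlist(gl, use.names = FALSE),
    group = factor(rep(names(gl), times = vapply(gl, length, integer(1)))))
  if (sd(dat$value) == 0)  # degenerate: no variation anywhere
    return(list(statistic = 0,
                df = c(length(gl) - 1, nrow(dat) - length(gl)),
                p_value = 1))
  ft <- oneway.test(value ~ group, data = dat, var.equal = TRUE)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = unname(ft$p.value))
}

#' Pairwise Welch t-tests with Bonferroni correction
#'
#' Two-sided Welch unequal-variance t-tests (Welch-Satterthwaite degrees of
#' freedom) for the requested group pairs, with Bonferroni multiplier `m`
#' (default: the number of comparisons performed).
#'
#' @param groups named list of per-group numeric volume vectors, or a
#'   data.frame with `group` and `volume_mm3` columns.
#' @param comparisons list of length-2 character vectors naming the group
#'   pairs to compare.
#' @param m Bonferroni correction count.
#' @param alpha significance level for the flag.
#' @return data.frame of comparison results: test name, groups, t
#'   statistic, Welch df, raw and adjusted p, significance flag.
#' @export
welch_pairwise <- function(groups, comparisons, m = length(comparisons),
                           alpha = 0.05) {
  gl <- as_group_list(groups)
  stopifnot(length(comparisons) >= 1, m >= 1)
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2)
    if (!all(cmp %in% names(gl)))
      stop("unknown group in comparison: ", paste(cmp, collapse = " vs "))
    a <- gl[[cmp[1]]]; b <- gl[[cmp[2]]]
    if (length(a) < 2 || length(b) < 2)
      stop("need n >= 2 per group for a Welch test")
    tt <- t.test(a, b, var.equal = FALSE)
    p_adj <- min(1, tt$p.value * m)
    data.frame(test = "welch_t", group1 = cmp[1], group2 = cmp[2],
               statistic = unname(tt$statistic),
               df = unname(tt$parameter),
               p_value = tt$p.value, p_adjusted = p_adj,
               significant = p_adj < alpha)
  })
  do.call(rbind, rows)
}

#' Cross-sectional growth analysis of a caliper table
#'
#' Runs the full statistical chain at one analysis day: per-group
#' summaries, one-way ANOVA across all groups, and pairwise Welch tests
#' with Bonferroni correction for the requested comparisons.
#'
#' @param records caliper table (`animal_id`, `group`, `day`, `length_mm`,
#'   `width_mm`).
#' @param day analysis day (default 7).
#' @param comparisons list of group pairs for Welch tests; default compares
#'   the combined arm against control, radiation alone and hyperthermia
#'   alone when those groups are present.
#' @param alpha significance level.
#' @return list with `summaries`, `anova`, `welch` (NULL if no comparisons
#'   apply).
#' @export
analyze_growth <- function(records, day = 7, comparisons = NULL,
                           alpha = 0.05) {
  vols <- volumes_by_group(records, day)
  if (is.null(comparisons)) {
    combo <- "FUS-HT+RT2Gy"
    others <- c("control", "RT2Gy", "FUS-HT")
    if (combo %in% names(vols))
      comparisons <- lapply(intersect(others, names(vols)),
                            function(g) c(combo, g))
  }
  list(summaries = group_summaries(records, day),
       anova = anova_oneway(vols),
       welch = if (length(comparisons))
         welch_pairwise(vols, comparisons, alpha = alpha) else NULL)
}

#' Read / write caliper measurement tables
#'
#' Plain-CSV interchange with columns `animal_id`, `group`, `day`,
#' `length_mm`, `width_mm`.
#'
#' @param path file path.
#' @rdname caliper_io
#' @export
read_caliper_csv <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "day", "length_mm", "width_mm")
  if (!all(need %in% names(rec)))
    stop("caliper CSV must have columns: ", paste(need, collapse = ", "))
  rec
}

#' @param records caliper table to write.
#' @rdname caliper_io
#' @export
write_caliper_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
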