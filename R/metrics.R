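# Track metrics: minimum total distance, mean speeds with the <10-location
# rule, migration-onset detection at the 1000-m isobath, grouped speed
# summaries, and the two-factor ANOVA + Newman-Keuls design used for
# category-by-phase speed comparisons.

#' Minimum total track distance
#'
#' Sum of consecutive great-circle legs over the regularized locations —
#' "minimum" because straight 12-h legs undercut the true path length.
#'
#' @param locations time-sorted regularized locations (`lon`, `lat`).
#' @return distance in km.
#' @export
track_distance_km <- function(locations) {
  if (nrow(locations) < 2) {
    stop("track distance undefined for fewer than 2 locations")
  }
  sum(leg_lengths_km(locations$lon, locations$lat))
}

#' Mean travel speed
#'
#' Mean of per-segment speeds (leg distance over leg duration) over
#' consecutive regularized locations; on a regular 12-h grid this equals
#' total distance divided by total elapsed time. Following the convention
#' for sparse tracks, speed is not estimated from fewer than 10 locations:
#' the result is `NA` with attribute `reason = "not-estimated"`.
#'
#' @param locations time-sorted locations (`time_h`, `lon`, `lat`).
#' @param min_locations minimum locations required (default 10).
#' @return mean speed in km/h, or `NA` (not estimated).
#' @export
mean_speed_kmh <- function(locations, min_locations = 10) {
  if (nrow(locations) < min_locations) {
    return(structure(NA_real_, reason = "not-estimated"))
  }
  d <- leg_lengths_km(locations$lon, locations$lat)
  dt <- diff(locations$time_h)
  if (any(dt <= 0)) stop("locations must be strictly time-increasing")
  mean(d / dt)
}

#' Per-segment speeds with grouping columns
#'
#' Expands a whale's regularized track into one row per 12-h segment with
#' its speed and the phase (breeding / migration) it belongs to; segments
#' spanning the onset count as migration.
#'
#' @param locations one whale's locations (`whale_id`, `time_h`, `lon`,
#'   `lat`).
#' @param onset_time_h migration onset (hours) or `NA` for never-migrating.
#' @return data.frame: `whale_id`, `t_mid_h`, `speed_kmh`, `phase`.
#' @export
segment_speeds <- function(locations, onset_time_h = NA) {
  n <- nrow(locations)
  if (n < 2) {
    return(data.frame(whale_id = character(0), t_mid_h = numeric(0),
                      speed_kmh = numeric(0), phase = character(0)))
  }
  d <- leg_lengths_km(locations$lon, locations$lat)
  dt <- diff(locations$time_h)
  t_end <- locations$time_h[-1]
  phase <- if (is.na(onset_time_h)) {
    rep("breeding", n - 1)
  } else {
    ifelse(t_end > onset_time_h, "migration", "breeding")
  }
  data.frame(whale_id = locations$whale_id[1],
             t_mid_h = (locations$time_h[-n] + t_end) / 2,
             speed_kmh = d / dt, phase = phase, stringsAsFactors = FALSE)
}

#' Detect migration onset from depth
#'
#' A whale is considered migrating once it crosses the 1000-m isobath and
#' keeps travelling over deep water: onset is the first regularized
#' location deeper than `isobath_m` whose next `sustain_steps` locations
#' all remain deeper, so a brief excursion over deep water does not count.
#'
#' @param locations one whale's time-sorted locations.
#' @param bathymetry a [bathymetry_grid()] covering the track.
#' @param isobath_m depth threshold, metres (positive magnitude).
#' @param sustain_steps number of subsequent locations that must stay deep
#'   (4 steps = 2 days on a 12-h grid).
#' @return onset time (hours, same clock as `time_h`) or `NA` if the whale
#'   never sustains deep-water travel.
#' @export
detect_migration_onset <- function(locations, bathymetry, isobath_m = 1000,
                                   sustain_steps = 4) {
  depth <- sample_depth(bathymetry, locations$lon, locations$lat)
  deep <- depth < -abs(isobath_m)
  n <- length(deep)
  for (i in seq_len(n)) {
    if (!deep[i]) next
    j <- i + seq_len(sustain_steps)
    j <- j[j <= n]
    if (length(j) == sustain_steps && all(deep[j])) {
      return(locations$time_h[i])
    }
  }
  NA_real_
}

#' Grouped speed summary by reproductive category and phase
#'
#' Pooled per-segment speeds grouped by category (M / F / MC) and phase
#' (breeding / migration), as mean, SD and segment count. Empty groups are
#' absent from the output rather than reported as zero.
#'
#' @param segments row-bound [segment_speeds()] output for all whales.
#' @param meta metadata with `whale_id` and `category`.
#' @return data.frame: `category`, `phase`, `mean_kmh`, `sd_kmh`, `n`.
#' @export
speed_summary <- function(segments, meta) {
  segs <- merge(segments, meta[, c("whale_id", "category")], by = "whale_id")
  if (nrow(segs) == 0) {
    return(data.frame(category = character(0), phase = character(0),
                      mean_kmh = numeric(0), sd_kmh = numeric(0),
                      n = integer(0)))
  }
  agg <- aggregate(speed_kmh ~ category + phase, data = segs,
                   FUN = function(x) c(mean = mean(x), sd = sd(x),
                                       n = length(x)))
  data.frame(category = agg$category, phase = agg$phase,
             mean_kmh = agg$speed_kmh[, "mean"],
             sd_kmh = agg$speed_kmh[, "sd"],
             n = as.integer(agg$speed_kmh[, "n"]),
             stringsAsFactors = FALSE)
}

#' Two-factor ANOVA on segment speeds
#'
#' Fixed-effects two-way ANOVA of speed on reproductive category and phase.
#' Designs here are almost always unbalanced (whales contribute unequal
#' segment counts), so Type-II sums of squares are used. If any
#' category-by-phase cell is empty the interaction is dropped with a
#' warning; with a single level in one factor the decomposition reduces to
#' the one-way ANOVA.
#'
#' @param speeds numeric response (per-segment speeds, km/h).
#' @param category factor 1 (reproductive category).
#' @param phase factor 2 (breeding / migration).
#' @return data.frame with one row per term: `term`, `sum_sq`, `df`, `F`,
#'   `p`; residuals row included.
#' @export
two_factor_anova <- function(speeds, category, phase) {
  category <- factor(category); phase <- factor(phase)
  stopifnot(length(speeds) == length(category),
            length(speeds) == length(phase))
  d <- data.frame(y = speeds, A = category, B = phase)
  if (isTRUE(all(speeds == speeds[1]))) {
    # a constant response carries no variance to decompose
    terms <- c("category", "phase", "category:phase", "residuals")
    return(data.frame(term = terms, sum_sq = 0,
                      df = c(nlevels(category) - 1, nlevels(phase) - 1,
                             (nlevels(category) - 1) * (nlevels(phase) - 1),
                             length(speeds) - nlevels(category) * nlevels(phase)),
                      F = c(0, 0, 0, NA), p = c(1, 1, 1, NA),
                      stringsAsFactors = FALSE))
  }
  one_way <- nlevels(category) < 2 || nlevels(phase) < 2
  if (one_way) {
    fac <- if (nlevels(category) >= 2) "A" else "B"
    fit <- lm(stats::reformulate(fac, "y"), data = d)
    tab <- stats::anova(fit)
    out <- data.frame(
      term = c(if (fac == "A") "category" else "phase", "residuals"),
      sum_sq = tab$`Sum Sq`, df = tab$Df, F = tab$`F value`,
      p = tab$`Pr(>F)`, stringsAsFactors = FALSE)
    return(out)
  }
  empty_cell <- any(table(category, phase) == 0)
  form <- if (empty_cell) y ~ A + B else y ~ A * B
  if (empty_cell) {
    warning("empty category-by-phase cell: interaction term dropped")
  }
  fit <- lm(form, data = d)
  tab <- car::Anova(fit, type = 2)
  terms <- rownames(tab)
  pretty <- c(A = "category", B = "phase", `A:B` = "category:phase",
              Residuals = "residuals")
  data.frame(term = unname(pretty[terms]), sum_sq = tab$`Sum Sq`,
             df = tab$Df, F = tab$`F value`, p = tab$`Pr(>F)`,
             stringsAsFactors = FALSE)
}

#' Newman-Keuls stepwise post hoc comparisons
#'
#' Student-Newman-Keuls test on ordered group means: the studentized range
#' of each pair is compared against the critical value for the number of
#' means spanned (not the total number of groups), stepping down; a pair is
#' declared significant only if no non-significant span contains it.
#' Unequal group sizes use the harmonic mean (Tukey-Kramer style).
#'
#' @param y response vector.
#' @param g grouping factor.
#' @param alpha significance level.
#' @param mse optional error mean square and `df_err` its degrees of
#'   freedom (e.g. from a two-way fit); defaults to the one-way residuals.
#' @param df_err see `mse`.
#' @return data.frame of pairwise rows: `group1`, `group2`, `diff`, `q`,
#'   `span`, `p`, `significant`.
#' @export
newman_keuls <- function(y, g, alpha = 0.05, mse = NULL, df_err = NULL) {
  g <- factor(g)
  k <- nlevels(g)
  stopifnot(k >= 2)
  ns <- tapply(y, g, length)
  means <- tapply(y, g, mean)
  if (is.null(mse)) {
    fit <- stats::anova(lm(y ~ g))
    mse <- fit$`Mean Sq`[2]
    df_err <- fit$Df[2]
  }
  ord <- order(means)
  means <- means[ord]; ns <- ns[ord]
  out <- NULL
  # all pairs, widest spans first so the containment rule can be applied
  nonsig_spans <- list()
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      nh <- 2 / (1 / ns[i] + 1 / ns[j])
      se <- sqrt(mse / nh)
      q <- (means[j] - means[i]) / se
      p <- 1 - ptukey(q, span, df_err)
      contained <- any(vapply(nonsig_spans, function(s) {
        i >= s[1] && j <= s[2]
      }, TRUE))
      sig <- !contained && p < alpha
      if (!sig) nonsig_spans <- c(nonsig_spans, list(c(i, j)))
      out <- rbind(out, data.frame(
        group1 = names(means)[i], group2 = names(means)[j],
        diff = unname(means[j] - means[i]), q = unname(q),
        span = span, p = unname(p), significant = sig,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-whale tracking summary table
#'
#' One row per whale in the layout of published tracking summaries:
#' duration, sex/category, minimum total distance, overall / breeding /
#' migratory mean speeds (1-decimal, half-up; `NA` when not estimated or
#' the phase is absent), and the percentage of locations in each
#' behavioural mode.
#'
#' @param locations regularized locations for all whales.
#' @param meta whale metadata.
#' @param onsets named numeric: migration onset per whale (hours), `NA` if
#'   none.
#' @return data.frame, one row per whale.
#' @export
whale_summary_table <- function(locations, meta, onsets) {
  rows <- lapply(split(locations, locations$whale_id), function(loc) {
    id <- loc$whale_id[1]
    onset <- if (id %in% names(onsets)) onsets[[id]] else NA_real_
    dur_days <- (max(loc$time_h) - min(loc$time_h)) / 24
    dist <- if (nrow(loc) >= 2) track_distance_km(loc) else NA
    spd <- function(x) {
      v <- mean_speed_kmh(x)
      if (is.na(v)) NA_real_ else round_half_up(v, 1)
    }
    breeding <- loc[is.na(onset) | loc$time_h <= onset, , drop = FALSE]
    migr <- if (is.na(onset)) loc[0, ] else
      loc[loc$time_h >= onset, , drop = FALSE]
    pct <- function(m) round_half_up(100 * mean(loc$mode == m), 1)
    data.frame(whale_id = id, tag_duration_days = dur_days,
               sex = meta$sex[match(id, meta$whale_id)],
               category = meta$category[match(id, meta$whale_id)],
               min_total_distance_km = dist,
               mean_speed = spd(loc),
               breeding_speed = spd(breeding),
               migratory_speed = if (nrow(migr) == 0) NA_real_ else spd(migr),
               pct_ARS = pct("ARS"), pct_transit = pct("transit"),
               pct_uncertain = pct("uncertain"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
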