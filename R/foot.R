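#' Row-to-region map for the insole grid
#'
#' Assigns the 12 sensor rows (toe row = row 1) to forefoot, midfoot and
#' rearfoot. Every row must be assigned exactly once and each region must be
#' contiguous. The default split (1-5 / 6-8 / 9-12) approximates anatomical
#' proportions.
#'
#' @param forefoot,midfoot,rearfoot Integer row vectors.
#' @param n_rows Total number of rows (default 12).
#' @return An object of class `region_map`.
#' @export
region_map <- function(forefoot = 1:5, midfoot = 6:8, rearfoot = 9:12,
                       n_rows = 12) {
  m <- list(forefoot = forefoot, midfoot = midfoot, rearfoot = rearfoot)
  all_rows <- sort(unname(unlist(m)))
  if (!identical(as.integer(all_rows), seq_len(n_rows))) {
    stop("regions must partition rows 1..", n_rows)
  }
  for (r in names(m)) {
    if (!identical(sort(m[[r]]), seq(min(m[[r]]), max(m[[r]])))) {
      stop("region ", r, " must be contiguous")
    }
  }
  structure(m, class = "region_map")
}

#' Normalize an insole recording by subject weight
#'
#' Divides every element (and hence the total load) by the subject's weight
#' in kg, making recordings comparable across subjects.
#'
#' @param series A [pressure_series()] carrying a positive `weight`
#'   attribute.
#' @return The normalised series (attribute `normalized = TRUE`).
#' @export
normalize_by_weight <- function(series) {
  stopifnot(inherits(series, "pressure_series"))
  w <- attr(series, "weight")
  if (is.na(w) || w <= 0) stop("subject weight must be > 0")
  series$grid <- series$grid / w
  series$sum_load <- series$sum_load / w
  attr(series, "normalized") <- TRUE
  series
}

#' Per-frame region loads
#'
#' Sums the (normalised) elements of each frame per region. The three region
#' sums add up to the frame total exactly.
#'
#' @param series A [pressure_series()] with the insole grid.
#' @param map A [region_map()].
#' @return A data frame: `t`, `forefoot`, `midfoot`, `rearfoot`, `total`.
#' @export
region_loads <- function(series, map = region_map()) {
  stopifnot(inherits(series, "pressure_series"), inherits(map, "region_map"))
  if (dim(series$grid)[2] < max(unlist(map))) {
    stop("grid has fewer rows than the region map expects")
  }
  sums <- lapply(map, function(rows)
    apply(series$grid[, rows, , drop = FALSE], 1, sum))
  data.frame(t = series$t, forefoot = sums$forefoot, midfoot = sums$midfoot,
             rearfoot = sums$rearfoot,
             total = sums$forefoot + sums$midfoot + sums$rearfoot)
}

#' Group-level insole summary
#'
#' For every shoe group and foot region: the mean weight-normalised load
#' over all frames of all subjects, and the peak load (each subject's
#' maximum frame value, averaged across the group's subjects).
#'
#' @param insoles List of [pressure_series()] with `weight` and `shoe_group`
#'   attributes set (normalised internally).
#' @param map A [region_map()].
#' @return A data frame: `group`, `region`, `mean_load`, `peak_load`, `n`.
#' @export
group_summary <- function(insoles, map = region_map()) {
  per_subject <- lapply(insoles, function(s) {
    rl <- region_loads(normalize_by_weight(s), map)
    data.frame(group = attr(s, "shoe_group"),
               region = c("forefoot", "midfoot", "rearfoot", "total"),
               mean_load = c(mean(rl$forefoot), mean(rl$midfoot),
                             mean(rl$rearfoot), mean(rl$total)),
               peak_load = c(max(rl$forefoot), max(rl$midfoot),
                             max(rl$rearfoot), max(rl$total)),
               frames = nrow(rl))
  })
  all <- do.call(rbind, per_subject)
  groups <- intersect(c("orthopedic", "regular", "control"),
                      unique(all$group))
  rows <- list()
  for (g in groups) {
    for (r in c("forefoot", "midfoot", "rearfoot", "total")) {
      sub <- all[all$group == g & all$region == r, , drop = FALSE]
      ## mean over all frames of all subjects = frame-weighted subject mean
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, region = r,
        mean_load = sum(sub$mean_load * sub$frames) / sum(sub$frames),
        peak_load = mean(sub$peak_load),
        n = nrow(sub))
    }
  }
  do.call(rbind, rows)
}
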