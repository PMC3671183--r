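# Normalization and two-level interpolated averaging of line-scan profiles.

#' Averaging configuration
#'
#' Point counts for the two averaging levels. Scans are averaged within an
#' animal on a 500-point grid and animal curves across animals on a
#' 100-point grid, both uniform on \[0,1\] with endpoints included.
#'
#' @param n_points_animal grid size for the within-animal average.
#' @param n_points_group grid size for the across-animal average
#'   (must not exceed `n_points_animal`).
#' @param interpolation only `"linear"` is supported.
#' @return object of class `averaging_config`.
#' @export
averaging_config <- function(n_points_animal = 500L, n_points_group = 100L,
                             interpolation = "linear") {
  assert_scalar_num(n_points_animal, "n_points_animal", lower = 2)
  assert_scalar_num(n_points_group, "n_points_group", lower = 2)
  if (n_points_group > n_points_animal) {
    stop("n_points_group must be <= n_points_animal", call. = FALSE)
  }
  interpolation <- match.arg(interpolation, "linear")
  structure(list(n_points_animal = as.integer(n_points_animal),
                 n_points_group = as.integer(n_points_group),
                 interpolation = interpolation),
            class = "averaging_config")
}

#' Normalize a profile to its own maxima
#'
#' Both axes are scaled to the highest respective value in the profile:
#' `x' = x / max(x)` so depth runs 0 (apical start) to exactly 1 (basal
#' lamina), and `y' = y / max(y)` so peak intensity is exactly 1.
#'
#' @param p an unnormalized `intensity_profile` with `max(y) > 0`.
#' @return the normalized `intensity_profile`.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "intensity_profile"))
  if (p$normalized) stop("profile is already normalized", call. = FALSE)
  if (max(p$y) <= 0) {
    stop("all-zero intensity profile cannot be normalized; exclude this scan",
         call. = FALSE)
  }
  intensity_profile(p$x / max(p$x), p$y / max(p$y), normalized = TRUE,
                    meta = p$meta)
}

#' Averaged profile container
#' @noRd
new_averaged_profile <- function(x_grid, mean, sem, n_contributing, level,
                                 probe, n_scans = n_contributing) {
  structure(list(x_grid = x_grid, mean = mean, sem = sem,
                 n_contributing = as.integer(n_contributing),
                 n_scans = as.integer(n_scans),
                 level = level, probe = probe),
            class = "averaged_profile")
}

#' @export
print.averaged_profile <- function(x, ...) {
  cat(sprintf("<averaged_profile> probe=%s level=%s, %d points, n=%d\n",
              x$probe %||% "?", x$level, length(x$x_grid), x$n_contributing))
  invisible(x)
}

uniform_grid <- function(n) seq(0, 1, length.out = n)

#' Average normalized profiles on a fixed interpolation grid
#'
#' Each profile is linearly interpolated onto a uniform `n_points` grid on
#' \[0,1\] (endpoints included) and the pointwise arithmetic mean is taken.
#' SEM is left empty at this level; it is reported by
#' [hierarchical_average()] across animals.
#'
#' @param profiles nonempty list of normalized `intensity_profile`s sharing
#'   one probe.
#' @param n_points grid size (default 500).
#' @param level label for the result (`"animal"` by default).
#' @return an `averaged_profile`.
#' @export
average_profiles <- function(profiles, n_points = 500L, level = "animal") {
  if (length(profiles) == 0L) stop("no profiles to average", call. = FALSE)
  probes <- unique(vapply(profiles, function(p) p$meta$probe %||% NA_character_,
                          character(1)))
  if (length(probes) > 1L) stop("profiles mix probes: ",
                                paste(probes, collapse = ", "), call. = FALSE)
  if (any(!vapply(profiles, function(p) p$normalized, logical(1)))) {
    stop("all profiles must be normalized", call. = FALSE)
  }
  grid <- uniform_grid(n_points)
  mat <- vapply(profiles, function(p) lin_interp(p$x, p$y, grid),
                numeric(n_points))
  mat <- matrix(mat, nrow = n_points)
  new_averaged_profile(grid, rowMeans(mat), sem = numeric(0),
                       n_contributing = length(profiles), level = level,
                       probe = probes[[1]], n_scans = length(profiles))
}

#' Two-level hierarchical average with per-point SEM
#'
#' Implements the scans-to-animal-to-group averaging scheme: scans of each
#' animal are averaged on the `n_points_animal` grid, each animal curve is
#' renormalized to peak 1 (within-animal normalization), animal curves are
#' interpolated onto the `n_points_group` grid and averaged pointwise, and
#' per-point SEM is `sd / sqrt(n_animals)`. The group curve itself is not
#' renormalized again, so its peak may fall slightly below 1.
#'
#' @param profiles list of normalized `intensity_profile`s; animal membership
#'   is taken from `meta$animal_id` unless `animal_ids` is given.
#' @param cfg an [averaging_config()].
#' @param animal_ids optional vector overriding `meta$animal_id`.
#' @return an `averaged_profile` with `level = "group"` and
#'   `n_contributing = number of animals`.
#' @export
hierarchical_average <- function(profiles, cfg = averaging_config(),
                                 animal_ids = NULL) {
  stopifnot(inherits(cfg, "averaging_config"))
  if (length(profiles) == 0L) stop("no profiles", call. = FALSE)
  if (is.null(animal_ids)) {
    animal_ids <- vapply(profiles, function(p) {
      id <- p$meta$animal_id
      if (is.null(id)) stop("profile without animal_id", call. = FALSE)
      as.character(id)
    }, character(1))
  }
  by_animal <- split(profiles, animal_ids)
  grid_g <- uniform_grid(cfg$n_points_group)
  curves <- vapply(by_animal, function(ps) {
    a <- average_profiles(ps, n_points = cfg$n_points_animal, level = "animal")
    m <- a$mean / max(a$mean)              # within-animal renormalization
    lin_interp(a$x_grid, m, grid_g)
  }, numeric(cfg$n_points_group))
  curves <- matrix(curves, nrow = cfg$n_points_group)
  n_a <- ncol(curves)
  mean_g <- rowMeans(curves)
  sem_g <- if (n_a > 1L) apply(curves, 1, stats::sd) / sqrt(n_a) else
    rep(0, cfg$n_points_group)
  probe <- profiles[[1]]$meta$probe %||% NA_character_
  new_averaged_profile(grid_g, mean_g, sem_g, n_contributing = n_a,
                       level = "group", probe = probe,
                       n_scans = length(profiles))
}

#' Animal-level averaged curve (averaged then renormalized to peak 1)
#'
#' Convenience wrapper producing the intermediate per-animal curve of
#' [hierarchical_average()].
#'
#' @param profiles normalized profiles of one animal.
#' @param n_points grid size (default 500).
#' @return an `averaged_profile` with `level = "animal"`, peak exactly 1.
#' @export
animal_average <- function(profiles, n_points = 500L) {
  a <- average_profiles(profiles, n_points = n_points, level = "animal")
  a$mean <- a$mean / max(a$mean)
  a
}

#' Write / read averaged profiles as CSV
#'
#' Long format with columns `probe`, `level`, `x`, `mean`, `sem`, `n`.
#'
#' @param curves named list of `averaged_profile` (or a single one).
#' @param path CSV file.
#' @return `path` invisibly (write); named list of `averaged_profile` (read).
#' @export
write_averaged <- function(curves, path) {
  if (inherits(curves, "averaged_profile")) curves <- list(curves)
  rows <- lapply(curves, function(a) {
    data.frame(probe = a$probe %||% NA_character_, level = a$level,
               x = a$x_grid, mean = a$mean,
               sem = if (length(a$sem)) a$sem else NA_real_,
               n = a$n_contributing,
               n_scans = a$n_scans %||% a$n_contributing,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_averaged
#' @export
read_averaged <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, interaction(df$probe, df$level, drop = TRUE)),
                function(d) {
    d <- d[order(d$x), ]
    new_averaged_profile(d$x, d$mean,
                         sem = if (all(is.na(d$sem))) numeric(0) else d$sem,
                         n_contributing = d$n[1], level = d$level[1],
                         probe = d$probe[1],
                         n_scans = if (is.null(d$n_scans)) d$n[1] else
                           d$n_scans[1])
  })
  stats::setNames(out, vapply(out, function(a) a$probe, character(1)))
}

#' Plot an averaged profile with its SEM band
#'
#' @param x an `averaged_profile`.
#' @param col curve color.
#' @param add add to an existing plot?
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.averaged_profile <- function(x, col = "black", add = FALSE, ...) {
  if (!add) {
    plot(x$x_grid, x$mean, type = "n", xlab = "normalized depth (apical 0, basal 1)",
         ylab = "normalized intensity", ylim = c(0, 1.05), ...)
  }
  if (length(x$sem)) {
    polygon(c(x$x_grid, rev(x$x_grid)),
            c(x$mean + x$sem, rev(x$mean - x$sem)),
            border = NA, col = grDevices::adjustcolor(col, alpha.f = 0.2))
  }
  lines(x$x_grid, x$mean, col = col, lwd = 2)
  invisible(x)
}
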