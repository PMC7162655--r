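#' Per-frame filopodium length series
#'
#' Length at each frame is the Euclidean distance from the tip position to
#' the base point (the first recorded tip position when no base is given,
#' matching manual tracks that record the tip only).
#'
#' @param track an `lsfm_track` from [read_tracks()] (or a data frame with
#'   `x_um, y_um, z_um`).
#' @param base optional `(x, y, z)` µm base point.
#' @return numeric vector of lengths (µm), one per frame.
#' @export
filopodium_lengths <- function(track, base = NULL) {
  pos <- track_positions(track)
  if (is.null(base)) base <- pos[1, ]
  unname(sqrt(rowSums((pos - matrix(base, nrow(pos), 3, byrow = TRUE))^2)))
}

#' @noRd
track_positions <- function(track) {
  if (inherits(track, "lsfm_track")) return(track$positions)
  as.matrix(track[, c("x_um", "y_um", "z_um")])
}

#' Filopodium kinematics from a length series
#'
#' Appearance is the first frame with length above `eps_um`; disappearance
#' the first later frame at or below it (when the filopodium never returns
#' to baseline the track is right-censored and the last frame + 1 is used).
#' Lifetime spans the half-open alive interval. Maximum length is taken over
#' the alive interval; extension and retraction speeds are the means of the
#' positive and negative per-frame length rates respectively.
#'
#' @param lengths numeric length series (µm).
#' @param dt_min frame interval, minutes.
#' @param eps_um presence threshold (default 0.5 µm).
#' @return `filopodium_stats` list: `max_length_um`, `lifetime_min`,
#'   `censored`, `extension_speed_um_min`, `retraction_speed_um_min`,
#'   `no_retraction` flag (speed reported as 0 for monotone growth).
#' @export
filopodium_stats <- function(lengths, dt_min, eps_um = 0.5) {
  lengths <- unname(as.numeric(lengths))
  if (length(lengths) == 0) lsfm_stop("empty length series")
  if (dt_min <= 0) lsfm_stop("dt_min must be > 0")
  alive <- which(lengths > eps_um)
  if (length(alive) == 0) lsfm_stop("no filopodium: series never exceeds eps")
  a0 <- alive[1]
  after <- which(seq_along(lengths) > a0 & lengths <= eps_um)
  censored <- length(after) == 0
  a1 <- if (censored) length(lengths) + 1L else after[1]
  seg <- lengths[a0:min(a1, length(lengths))]
  rates <- diff(lengths[max(1, a0 - 1):min(a1, length(lengths))]) / dt_min
  ext <- rates[rates > 0]; ret <- rates[rates < 0]
  structure(list(max_length_um = max(seg),
                 lifetime_min = (a1 - a0) * dt_min,
                 censored = censored,
                 extension_speed_um_min = if (length(ext)) mean(ext) else 0,
                 retraction_speed_um_min = if (length(ret)) mean(-ret) else 0,
                 no_retraction = length(ret) == 0),
            class = "filopodium_stats")
}

#' Actin-bundle kinematics from a position track
#'
#' @param track an `lsfm_track` or data frame with `x_um, y_um, z_um` in
#'   frame order (>= 2 frames).
#' @param dt_min frame interval, minutes.
#' @return `bundle_stats` list: `path_length_um` (summed step lengths),
#'   `net_displacement_um`, `duration_min`, `average_speed_um_min`,
#'   `cumulative_um` per-frame distance curve.
#' @export
bundle_stats <- function(track, dt_min) {
  pos <- track_positions(track)
  if (nrow(pos) < 2) lsfm_stop("bundle track needs at least 2 frames")
  if (dt_min <= 0) lsfm_stop("dt_min must be > 0")
  steps <- sqrt(rowSums((pos[-1, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE])^2))
  path <- sum(steps)
  duration <- (nrow(pos) - 1) * dt_min
  structure(list(path_length_um = path,
                 net_displacement_um = sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2)),
                 duration_min = duration,
                 average_speed_um_min = path / duration,
                 cumulative_um = c(0, cumsum(steps))),
            class = "bundle_stats")
}

#' Summarise kinematic metrics per condition
#'
#' @param stats list of [filopodium_stats()] or [bundle_stats()] results.
#' @param grouping factor/character of the same length (condition labels).
#' @param metrics which numeric fields to summarise (default: all scalar
#'   numeric fields).
#' @param test run an unpaired two-sample t-test (Student) per metric when
#'   exactly two groups are present.
#' @return list with `summary` data frame (group, metric, n, mean, median,
#'   sd) and optional `tests`.
#' @export
summarize_condition <- function(stats, grouping = rep("all", length(stats)),
                                metrics = NULL, test = FALSE) {
  if (length(stats) == 0) lsfm_stop("no records to summarise")
  grouping <- as.character(grouping)
  if (length(grouping) != length(stats)) lsfm_stop("grouping length mismatch")
  scalar_fields <- function(s) names(s)[vapply(s, function(v)
    is.numeric(v) && length(v) == 1, logical(1))]
  if (is.null(metrics)) metrics <- scalar_fields(stats[[1]])
  rows <- list()
  values <- list()
  for (m in metrics) {
    v <- vapply(stats, function(s) as.numeric(s[[m]]), numeric(1))
    values[[m]] <- v
    for (gname in unique(grouping)) {
      x <- v[grouping == gname]
      rows[[length(rows) + 1]] <- data.frame(group = gname, metric = m,
                                             n = length(x), mean = mean(x),
                                             median = median(x), sd = sd(x))
    }
  }
  out <- list(summary = do.call(rbind, rows))
  if (test && length(unique(grouping)) == 2) {
    gs <- unique(grouping)
    out$tests <- lapply(values, function(v)
      safe_t_test(v[grouping == gs[1]], v[grouping == gs[2]], var.equal = TRUE))
  }
  out
}
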