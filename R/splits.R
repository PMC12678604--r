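#' Construct a sprint split table
#'
#' A split table holds the timing data for one race: distances of the
#' intermediate marks (e.g. every 10 m), the cumulative time at each
#' mark, and the reaction time between the gun and movement onset.
#' All model fitting works on net times, i.e. cumulative times with the
#' reaction time subtracted.
#'
#' @param distance_marks Numeric vector of split distances in metres,
#'   strictly increasing; the last mark must equal `total_distance`.
#' @param cumulative_times Numeric vector of cumulative (gun) times in
#'   seconds at each mark, strictly increasing.
#' @param reaction_time Reaction time in seconds (default 0.15 s, a
#'   typical elite value used when the measured reaction time is
#'   unavailable).
#' @param total_distance Race distance in metres. Defaults to the last
#'   distance mark.
#' @param max_velocity Optional highest measured instantaneous velocity
#'   (m/s), e.g. from radar or photo-cell data; used by
#'   [adjust_peak_velocity()] when available.
#'
#' @return An object of class `split_table`: a list with fields
#'   `distance_marks`, `cumulative_times`, `reaction_time`,
#'   `total_distance`, `finish_time` and optionally `max_velocity`.
#' @examples
#' marks <- seq(10, 100, by = 10)
#' times <- c(1.89, 2.88, 3.78, 4.64, 5.47, 6.29, 7.10, 7.92, 8.75, 9.58)
#' st <- split_table(marks, times, reaction_time = 0.146)
#' st
#' @seealso [read_split_table()], [fit_acceleration()]
#' @export
split_table <- function(distance_marks, cumulative_times,
                        reaction_time = 0.15,
                        total_distance = NULL,
                        max_velocity = NULL) {
  distance_marks <- as.numeric(distance_marks)
  cumulative_times <- as.numeric(cumulative_times)
  if (length(distance_marks) != length(cumulative_times)) {
    stop("`distance_marks` and `cumulative_times` must have the same length")
  }
  if (length(distance_marks) < 3) {
    stop("at least 3 splits are required to fit the acceleration model")
  }
  if (any(diff(distance_marks) <= 0) || any(distance_marks <= 0)) {
    stop("`distance_marks` must be positive and strictly increasing")
  }
  if (any(diff(cumulative_times) <= 0)) {
    stop("`cumulative_times` must be strictly increasing")
  }
  if (!is.numeric(reaction_time) || length(reaction_time) != 1 ||
      reaction_time < 0) {
    stop("`reaction_time` must be a single non-negative number")
  }
  if (cumulative_times[1] <= reaction_time) {
    stop("all cumulative times must exceed the reaction time")
  }
  if (is.null(total_distance)) {
    total_distance <- distance_marks[length(distance_marks)]
  }
  if (abs(distance_marks[length(distance_marks)] - total_distance) > 1e-9) {
    stop("the last distance mark must equal `total_distance`")
  }
  structure(
    list(
      distance_marks = distance_marks,
      cumulative_times = cumulative_times,
      reaction_time = reaction_time,
      total_distance = total_distance,
      finish_time = cumulative_times[length(cumulative_times)],
      max_velocity = max_velocity
    ),
    class = "split_table"
  )
}

#' @export
print.split_table <- function(x, ...) {
  cat("Sprint split table:", x$total_distance, "m in",
      sprintf("%.2f s", x$finish_time),
      sprintf("(reaction time %.3f s)\n", x$reaction_time))
  df <- data.frame(
    distance_m = x$distance_marks,
    cumulative_time_s = x$cumulative_times
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Interval summary of a split table
#'
#' Computes, for each timing interval, the average velocity and the net
#' midpoint time (reaction time subtracted). The first interval runs
#' from the start line (gun time = reaction time) to the first mark.
#' These interval averages, placed at interval time-midpoints, are the
#' data to which the exponential acceleration model is fitted.
#'
#' @param splits A [split_table()].
#' @return A data.frame with columns `t_mid` (s, net), `v_avg` (m/s),
#'   `d_from`, `d_to` (m), `t_from`, `t_to` (s, net).
#' @export
split_intervals <- function(splits) {
  stopifnot(inherits(splits, "split_table"))
  d <- c(0, splits$distance_marks)
  t_net <- c(0, splits$cumulative_times - splits$reaction_time)
  dv <- diff(d) / diff(t_net)
  data.frame(
    t_mid = (t_net[-1] + t_net[-length(t_net)]) / 2,
    v_avg = dv,
    d_from = d[-length(d)],
    d_to = d[-1],
    t_from = t_net[-length(t_net)],
    t_to = t_net[-1]
  )
}

#' Read a split table from a CSV file
#'
#' The file must contain columns `distance_m` and `cumulative_time_s`
#' (header required). Race metadata not stored in the CSV is supplied
#' as arguments.
#'
#' @param file Path to a CSV file.
#' @inheritParams split_table
#' @return A [split_table()].
#' @export
read_split_table <- function(file, reaction_time = 0.15,
                             total_distance = NULL, max_velocity = NULL) {
  df <- utils::read.csv(file)
  if (!all(c("distance_m", "cumulative_time_s") %in% names(df))) {
    stop("CSV must contain columns `distance_m` and `cumulative_time_s`")
  }
  split_table(df$distance_m, df$cumulative_time_s,
              reaction_time = reaction_time,
              total_distance = total_distance,
              max_velocity = max_velocity)
}

#' Write a split table to a CSV file
#'
#' Writes the `distance_m` / `cumulative_time_s` columns. Metadata
#' (reaction time, total distance) is not stored in the CSV.
#'
#' @param splits A [split_table()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_split_table <- function(splits, file) {
  stopifnot(inherits(splits, "split_table"))
  utils::write.csv(
    data.frame(
      distance_m = splits$distance_marks,
      cumulative_time_s = splits$cumulative_times
    ),
    file, row.names = FALSE
  )
  invisible(file)
}
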