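#' Hemisphere amplitude of a grand-averaged response
#'
#' The amplitude of one hemisphere is derived from the per-channel maxima of
#' `|dHbO|` over the task interval. With `mode = "max"` (default) it is the
#' amplitude of the single most active channel in the set (max of maxima);
#' with `mode = "mean"` it is the mean across the set's channels of the
#' per-channel maxima.
#'
#' @param grand_avg Channels x samples matrix (e.g. from [grand_average()]).
#' @param channel_set Channel ids to aggregate (non-empty).
#' @param t_rel Time axis in seconds matching the columns of `grand_avg`.
#' @param interval Task interval in seconds, default \[0, 60\].
#' @param mode `"max"` or `"mean"` channel aggregation.
#' @return Non-negative scalar amplitude.
#' @export
hemisphere_amplitude <- function(grand_avg, channel_set, t_rel,
                                 interval = c(0, 60),
                                 mode = c("max", "mean")) {
  mode <- match.arg(mode)
  assert_that(length(channel_set) >= 1, "channel_set must be non-empty")
  assert_that(all(channel_set >= 1 & channel_set <= nrow(grand_avg)),
              "channel_set outside the layout")
  assert_that(length(t_rel) == ncol(grand_avg),
              "t_rel must match the sample dimension")
  cols <- which(t_rel >= interval[1] - 1e-9 & t_rel <= interval[2] + 1e-9)
  assert_that(length(cols) > 0, "interval outside the epoch window")
  per_channel <- apply(abs(grand_avg[channel_set, cols, drop = FALSE]), 1, max)
  if (mode == "max") max(per_channel) else mean(per_channel)
}

#' Laterality index from hemisphere amplitudes
#'
#' `LIS = (R - L) / (R + L)` with `R` and `L` the maximum absolute dHbO
#' amplitudes of the right- and left-hemisphere channel sets. Values lie in
#' \[-1, 1\]; positive values indicate right lateralization, negative values
#' left dominance. Antisymmetric in its arguments.
#'
#' @param R,L Non-negative hemisphere amplitudes with `R + L > 0`.
#' @return Scalar in \[-1, 1\].
#' @export
#' @examples
#' compute_lis(3, 1)  # 0.5
compute_lis <- function(R, L) {
  assert_that(is_scalar_number(R) && is_scalar_number(L) && R >= 0 && L >= 0,
              "R and L must be non-negative scalars")
  if (R + L == 0) {
    stop_nirslat("laterality undefined: both hemisphere amplitudes are zero",
                 "nirslat_undefined_laterality")
  }
  (R - L) / (R + L)
}

#' Laterality table per group and session
#'
#' For every (group, session) cell, pools the participants' baseline-corrected
#' epochs (mean over trials within participant, then over participants),
#' takes the right- (channels 1-7) and left-hemisphere (channels 9-15)
#' amplitudes of the pooled grand-averaged dHbO -- the midline channel is
#' excluded -- and computes the laterality index. A per-participant laterality
#' index (same computation on each participant's own grand average) supplies
#' the standard error across participants.
#'
#' @param epoch_table A data frame-like list with one element per
#'   participant-session: each entry a list with fields `group`, `session`,
#'   and `epochs` (a baseline-corrected `epoch_set`). Built by
#'   [run_pipeline()] or manually.
#' @param layout A [channel_layout()].
#' @param interval Task interval for the amplitudes, default \[0, 60\] s.
#' @param mode Channel aggregation, see [hemisphere_amplitude()].
#' @return A `lis_table` data frame with columns `group`, `session`, `R`,
#'   `L`, `lis`, `lis_se`, `n`, `aggregation_mode`.
#' @export
lis_by_group_session <- function(epoch_table, layout = channel_layout(),
                                 interval = c(0, 60),
                                 mode = c("max", "mean")) {
  mode <- match.arg(mode)
  assert_that(length(epoch_table) > 0, "epoch_table is empty")
  groups <- vapply(epoch_table, function(e) e$group, "")
  sessions <- vapply(epoch_table, function(e) e$session, 1)
  out <- list()
  for (gr in unique(groups)) {
    for (ses in sort(unique(sessions))) {
      sel <- which(groups == gr & sessions == ses)
      assert_that(length(sel) > 0,
                  sprintf("no participants for group '%s' session %d", gr, ses))
      eps <- lapply(epoch_table[sel], function(e) e$epochs)
      t_rel <- eps[[1]]$t_rel
      ga <- grand_average(eps, "hbo")
      R <- hemisphere_amplitude(ga, layout$right_channels, t_rel, interval, mode)
      L <- hemisphere_amplitude(ga, layout$left_channels, t_rel, interval, mode)
      per_part <- vapply(eps, function(e) {
        gai <- grand_average(e, "hbo")
        compute_lis(
          hemisphere_amplitude(gai, layout$right_channels, t_rel, interval, mode),
          hemisphere_amplitude(gai, layout$left_channels, t_rel, interval, mode))
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        group = gr, session = as.integer(ses), R = R, L = L,
        lis = compute_lis(R, L),
        lis_se = sd(per_part) / sqrt(length(per_part)),
        n = length(sel),
        aggregation_mode = mode
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("lis_table", "data.frame")
  res
}

#' Compare a laterality table against reference values
#'
#' Joins a computed `lis_table` with a reference table of published or
#' previously computed laterality indices and flags agreement at a given
#' absolute tolerance. Used when reproducing reported group/session values
#' from an external recording set.
#'
#' @param lis_table A `lis_table` from [lis_by_group_session()].
#' @param reference Data frame with columns `group`, `session`, `lis`.
#' @param tol Absolute agreement tolerance, default 0.02.
#' @return The joined data frame with columns `lis`, `lis_ref`, `delta`,
#'   `agree`.
#' @export
compare_lis_tables <- function(lis_table, reference, tol = 0.02) {
  assert_that(all(c("group", "session", "lis") %in% names(reference)),
              "reference needs columns group, session, lis")
  m <- merge(as.data.frame(lis_table)[c("group", "session", "lis")],
             reference, by = c("group", "session"),
             suffixes = c("", "_ref"))
  m$delta <- m$lis - m$lis_ref
  m$agree <- abs(m$delta) <= tol
  m
}

#' Write a laterality table as CSV
#' @param lis_table A `lis_table` from [lis_by_group_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lis_table <- function(lis_table, path) {
  utils::write.csv(as.data.frame(lis_table), path, row.names = FALSE)
  invisible(path)
}
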