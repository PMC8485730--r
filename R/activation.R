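#' Count stimulation-activated cells per epoch
#'
#' A cell counts as activated in an epoch when its mean trace over the epoch
#' exceeds its mean over the immediately preceding baseline window (same
#' length as the epoch) by more than `k_mads` times the MAD of that baseline
#' window. Epochs whose baseline window would start before the recording are
#' skipped with a warning.
#'
#' @param traces `K x T` matrix (ground-truth or extracted).
#' @param schedule a `stim_schedule`.
#' @param k_mads activation threshold in baseline-MAD units (default 3).
#' @return object of class `activation_counts`: data.frame with one row per
#'   scored epoch: `epoch`, `frequency_hz`, `n_activated`, `n_cells`;
#'   attribute `activated` is the `K x n_epoch` logical matrix.
#' @export
count_activated_cells <- function(traces, schedule, k_mads = 3) {
  ep <- schedule$epochs
  K <- nrow(traces)
  if (nrow(ep) > 0 && max(ep$end_frame) > ncol(traces))
    stop("epochs extend beyond the traces")
  rows <- list()
  act <- NULL
  for (i in seq_len(nrow(ep))) {
    len <- ep$end_frame[i] - ep$start_frame[i]
    b_start <- ep$start_frame[i] - len
    if (b_start < 0) {
      warning(sprintf("epoch %d has no full pre-epoch baseline window; skipped", i))
      next
    }
    stim_idx <- epoch_frames(schedule, i)
    base_idx <- seq.int(b_start + 1L, ep$start_frame[i])
    activated <- vapply(seq_len(K), function(c_i) {
      b <- traces[c_i, base_idx]
      s_mean <- mean(traces[c_i, stim_idx])
      s_mean > mean(b) + k_mads * max(mad(b), 1e-12)
    }, logical(1))
    act <- cbind(act, activated)
    rows[[length(rows) + 1]] <- data.frame(
      epoch = i, frequency_hz = ep$frequency_hz[i],
      n_activated = sum(activated), n_cells = K)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(epoch = integer(0), frequency_hz = numeric(0),
                         n_activated = integer(0), n_cells = integer(0))
  class(out) <- c("activation_counts", class(out))
  attr(out, "activated") <- act
  attr(out, "k_mads") <- k_mads
  out
}
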